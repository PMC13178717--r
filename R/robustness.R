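# Robust-accuracy curves over an epsilon grid and their AUC summaries.

#' Evaluate adversarial robustness over an epsilon grid
#'
#' For each bound in `epsGrid`, generates fresh attacks at that epsilon on
#' the (never-augmented) evaluation set and records top-1 accuracy under
#' attack. The default grid is the seven benchmark thresholds
#' `1/255 ... 7/255`. An optional `epsilon = 0` anchor equal to clean
#' accuracy can be requested with `includeCleanAnchor`; by default the curve
#' starts at `1/255`, matching the conventional grid.
#'
#' @param model a classifier implementing the [model-interface]
#' @param images N x H x W x 3 evaluation images (or N x D matrix)
#' @param labelsVec integer ground-truth labels
#' @param epsGrid strictly increasing perturbation bounds (pixel scale)
#' @param config [AttackConfig-class] template; its epsilon and step size are
#'   re-derived at each grid point (step size `epsilon/4` for l-infinity,
#'   `2.5 epsilon / steps` for l2)
#' @param includeCleanAnchor prepend an `epsilon = 0` point equal to clean
#'   accuracy
#' @return a [RobustnessCurve-class]
#' @export
evaluateRobustness <- function(model, images, labelsVec,
                               epsGrid = (1:7) / 255,
                               config = attackConfig(),
                               includeCleanAnchor = FALSE) {
  if (length(epsGrid) == 0L) stop("epsGrid must be nonempty")
  X <- asInputMatrix(images)
  y <- as.integer(labelsVec)
  if (nrow(X) == 0L) stop("empty evaluation set")
  stopifnot(length(y) == nrow(X))
  clean <- mean(predictClasses(model, X) == y)
  acc <- vapply(epsGrid, function(eps) {
    cfg <- attackConfig(norm = config@norm, epsilon = eps,
                        steps = config@steps, stepSize = NULL,
                        randomInit = config@randomInit, seed = config@seed)
    res <- pgdCore(model, X, y, cfg)
    mean(res$advPred == y)
  }, numeric(1))
  if (includeCleanAnchor) {
    epsGrid <- c(0, epsGrid)
    acc <- c(clean, acc)
  }
  auc <- if (length(epsGrid) >= 2L) trapz(epsGrid, acc) else NA_real_
  new("RobustnessCurve", epsilons = epsGrid, accuracies = acc,
      cleanAccuracy = clean, auc = auc)
}

#' Area under a robustness curve
#'
#' Trapezoidal area of top-1 accuracy over the tested epsilon grid, on the
#' pixel (`/255`) scale: a constant accuracy `a` over `[1/255, 7/255]` gives
#' `a * 6/255`. Higher is more robust.
#'
#' @param curve a [RobustnessCurve-class] with at least two grid points
#' @return scalar AUC (accuracy x epsilon units)
#' @aliases robustAUC
#' @export
setMethod("robustAUC", "RobustnessCurve", function(curve) {
  if (length(curve@epsilons) < 2L)
    stop("need at least two grid points for an AUC")
  trapz(curve@epsilons, curve@accuracies)
})

#' Robustness improvement over a baseline model
#'
#' Difference in robust AUC between a model and the baseline evaluated on the
#' same epsilon grid. Positive values indicate increased robustness.
#'
#' @param modelCurve,baselineCurve [RobustnessCurve-class] objects on
#'   identical grids
#' @return scalar AUC difference
#' @export
relativeAUC <- function(modelCurve, baselineCurve) {
  if (!isTRUE(all.equal(modelCurve@epsilons, baselineCurve@epsilons)))
    stop("robustness curves are on different epsilon grids")
  robustAUC(modelCurve) - robustAUC(baselineCurve)
}

#' @describeIn evaluateRobustness tested perturbation bounds
#' @param x a `RobustnessCurve`
#' @export
setMethod("epsilons", "RobustnessCurve", function(x) x@epsilons)

#' @describeIn evaluateRobustness top-1 accuracy under attack per bound
#' @export
setMethod("accuracies", "RobustnessCurve", function(x) x@accuracies)

#' @describeIn evaluateRobustness top-1 accuracy without attack
#' @export
setMethod("cleanAccuracy", "RobustnessCurve", function(x) x@cleanAccuracy)

setMethod("show", "RobustnessCurve", function(object) {
  cat("RobustnessCurve over", length(object@epsilons), "epsilon value(s);",
      sprintf("clean accuracy %.3f, AUC %.5f\n", object@cleanAccuracy,
              object@auc))
  cat(sprintf("  eps*255: %s\n", paste(format(object@epsilons * 255),
                                       collapse = " ")))
  cat(sprintf("  acc:     %s\n", paste(sprintf("%.3f", object@accuracies),
                                       collapse = " ")))
})

#' Export a robustness curve as a data.frame
#'
#' @param curve a [RobustnessCurve-class]
#' @return data.frame with `epsilon`, `epsilon_255`, `accuracy`
#' @export
curveAsDataFrame <- function(curve) {
  data.frame(epsilon = curve@epsilons, epsilon_255 = curve@epsilons * 255,
             accuracy = curve@accuracies)
}
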