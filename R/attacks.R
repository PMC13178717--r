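# Bounded gradient attacks: PGD (l-infinity / l2) and FGSM, plus the
# success filter that retains decision-flipping perturbations for spectral
# analysis. All attacks operate on raw [0, 1] pixels, matching the
# training-time input scale of the fixture models.

#' Configure a bounded gradient attack
#'
#' @param norm `"linf"` (default) or `"l2"`
#' @param epsilon perturbation bound on the `[0, 1]` pixel scale; the
#'   benchmark value is `4/255`
#' @param steps PGD iterations (default 10)
#' @param stepSize per-step magnitude; `NULL` selects `epsilon/4` for
#'   l-infinity and `2.5 * epsilon / steps` for l2
#' @param randomInit initialize from uniform noise in the epsilon ball
#'   (standard PGD); `FALSE` starts from zero
#' @param seed integer seed for the random initialization
#' @return an [AttackConfig-class]
#' @export
attackConfig <- function(norm = c("linf", "l2"), epsilon = 4 / 255,
                         steps = 10L, stepSize = NULL, randomInit = TRUE,
                         seed = 0L) {
  norm <- match.arg(norm)
  if (epsilon <= 0) stop("epsilon must be > 0")
  steps <- as.integer(steps)
  if (steps < 1L) stop("steps must be >= 1")
  if (is.null(stepSize))
    stepSize <- if (norm == "linf") epsilon / 4 else 2.5 * epsilon / steps
  new("AttackConfig", norm = norm, epsilon = epsilon, steps = steps,
      stepSize = stepSize, randomInit = randomInit, seed = as.integer(seed))
}

# Project rows of delta onto the epsilon ball and keep x + delta in [0, 1].
projectDelta <- function(delta, X, norm, epsilon) {
  if (norm == "linf") {
    delta <- pmin(pmax(delta, -epsilon), epsilon)
  } else {
    nrm <- sqrt(rowSums(delta^2))
    over <- nrm > epsilon
    if (any(over)) delta[over, ] <- delta[over, , drop = FALSE] *
        (epsilon / nrm[over])
  }
  pmin(pmax(delta, -X), 1 - X)
}

# Vectorized PGD over a batch of flattened images. Returns the delta matrix
# plus clean/adversarial predictions.
pgdCore <- function(model, X, y, config) {
  n <- nrow(X); D <- ncol(X)
  cleanPred <- predictClasses(model, X)
  delta <- withSeed(config@seed, {
    if (config@randomInit) {
      if (config@norm == "linf") {
        matrix(runif(n * D, -config@epsilon, config@epsilon), n, D)
      } else {
        d <- matrix(rnorm(n * D), n, D)
        d <- d / sqrt(rowSums(d^2))
        d * (runif(n)^(1 / D) * config@epsilon)
      }
    } else {
      matrix(0, n, D)
    }
  })
  delta <- projectDelta(delta, X, config@norm, config@epsilon)
  ok <- rep(TRUE, n)
  for (s in seq_len(config@steps)) {
    g <- inputGradient(model, X + delta, y)
    bad <- !apply(is.finite(g), 1L, all)
    if (any(bad & ok)) {
      warning(sum(bad & ok), " image(s) produced non-finite gradients; ",
              "aborting the attack for those images")
      ok <- ok & !bad
      g[bad, ] <- 0
    }
    if (config@norm == "linf") {
      delta <- delta + config@stepSize * sign(g)
    } else {
      nrm <- sqrt(rowSums(g^2))
      nz <- nrm > 0
      g[nz, ] <- g[nz, , drop = FALSE] / nrm[nz]
      delta <- delta + config@stepSize * g
    }
    delta <- projectDelta(delta, X, config@norm, config@epsilon)
  }
  advPred <- predictClasses(model, X + delta)
  list(delta = delta, cleanPred = cleanPred, advPred = advPred, ok = ok)
}

wrapPerturbations <- function(res, y, size, epsilon, norm) {
  lapply(seq_along(y), function(i) {
    new("Perturbation",
        delta = unflattenImage(res$delta[i, ], size),
        epsilon = epsilon, norm = norm,
        success = res$ok[i] && res$cleanPred[i] == y[i] &&
          res$advPred[i] != y[i],
        cleanLabel = as.integer(y[i]), advLabel = as.integer(res$advPred[i]))
  })
}

#' Projected gradient descent attack
#'
#' Finds a norm-bounded perturbation `tau` that approximately maximizes the
#' classification loss, `argmax_{||tau|| <= epsilon} L(f(x + tau), y)`, by
#' iterated gradient ascent with projection back onto the epsilon ball after
#' every step (and onto the valid `[0, 1]` pixel range). l-infinity PGD is
#' initialized with uniform noise `U(-epsilon, epsilon)` and steps by
#' `stepSize * sign(gradient)`; the l2 variant normalizes the gradient and
#' projects onto the l2 ball. A perturbation is marked successful iff the
#' model's top-1 prediction was correct on the clean input and wrong on the
#' perturbed one. No early stopping: all `steps` iterations run.
#'
#' @param model a classifier implementing the [model-interface]
#' @param image H x W x 3 array in `[0, 1]`, or an N x H x W x 3 batch
#' @param label integer ground-truth label(s)
#' @param config an [AttackConfig-class]
#' @return a [Perturbation-class] (or a list of them for a batch input)
#' @examples
#' # a constant-logit model has zero gradients: no ascent direction, no flip
#' m <- linearClassifier(matrix(0, 16 * 16 * 3, 2))
#' img <- array(runif(16 * 16 * 3), c(16, 16, 3))
#' pgdAttack(m, img, 1L, attackConfig(steps = 3L))
#' @export
pgdAttack <- function(model, image, label, config = attackConfig()) {
  stopifnot(is(config, "AttackConfig"))
  validObject(config)
  single <- length(dim(image)) == 3L
  X <- asInputMatrix(image)
  y <- as.integer(label)
  size <- if (single) dim(image)[1L] else dim(image)[2L]
  res <- pgdCore(model, X, y, config)
  out <- wrapPerturbations(res, y, size, config@epsilon, config@norm)
  if (single) out[[1L]] else out
}

#' Fast gradient sign method
#'
#' Single-step attack `delta = epsilon * sign(grad_x L(f(x), y))`, clipped so
#' the perturbed image stays in `[0, 1]`. `sign(0)` is 0, so a model with
#' identically zero gradients yields a zero perturbation. Equivalent to
#' one-step l-infinity PGD with zero initialization and step size `epsilon`.
#'
#' @inheritParams pgdAttack
#' @param epsilon perturbation bound on the `[0, 1]` pixel scale
#' @return a [Perturbation-class] (or a list of them for a batch input)
#' @export
fgsmAttack <- function(model, image, label, epsilon = 4 / 255) {
  cfg <- attackConfig(norm = "linf", epsilon = epsilon, steps = 1L,
                      stepSize = epsilon, randomInit = FALSE)
  pgdAttack(model, image, label, cfg)
}

#' Keep only decision-flipping perturbations
#'
#' Retains exactly the perturbations whose clean prediction was correct and
#' whose adversarial prediction differs from the label — the subset whose
#' spectral content reflects decision-relevant feature sensitivity. Everything
#' downstream ([radialProfile()], [bandDeltaAUC()]) should be fed this subset.
#'
#' @param perturbations list of [Perturbation-class] objects
#' @return the successful subset, as a list
#' @export
filterSuccessful <- function(perturbations) {
  stopifnot(is.list(perturbations))
  Filter(function(p) isTRUE(p@success), perturbations)
}

setMethod("show", "Perturbation", function(object) {
  d <- dim(object@delta)
  cat("Perturbation ", d[1L], "x", d[2L], "x", d[3L], " (", object@norm,
      ", eps = ", format(object@epsilon), "): ",
      if (object@success) "success" else "no flip",
      " (clean ", object@cleanLabel, " -> adv ", object@advLabel, ")\n",
      sep = "")
})

setMethod("show", "AttackConfig", function(object) {
  cat("AttackConfig: ", object@norm, " PGD, eps = ", format(object@epsilon),
      ", ", object@steps, " step(s) of ", format(object@stepSize),
      if (object@randomInit) ", random init" else ", zero init",
      ", seed ", object@seed, "\n", sep = "")
})
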