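# Representational similarity analysis: Euclidean RDMs compared by Spearman
# rank correlation of their upper triangles, plus the synthetic reference
# generator that stands in for measured response patterns.

#' Construct a response matrix
#'
#' @param values numeric matrix, images x units, no missing values
#' @param source `"model_penultimate"` or `"reference"`
#' @param ids image identifiers; defaults to rownames or `img1..imgN`
#' @return a [ResponseMatrix-class]
#' @export
responseMatrix <- function(values,
                           source = c("model_penultimate", "reference"),
                           ids = NULL) {
  source <- match.arg(source)
  values <- as.matrix(values)
  if (is.null(ids))
    ids <- if (!is.null(rownames(values))) rownames(values)
           else paste0("img", seq_len(nrow(values)))
  new("ResponseMatrix", values = values, source = source,
      imageIds = as.character(ids))
}

#' @describeIn responseMatrix the images x units matrix
#' @param x a `ResponseMatrix` or `RDM`
#' @export
setMethod("responseValues", "ResponseMatrix", function(x) x@values)

#' @rdname responseMatrix
#' @export
setMethod("imageIds", "ResponseMatrix", function(x) x@imageIds)

setMethod("show", "ResponseMatrix", function(object) {
  cat("ResponseMatrix (", object@source, "): ", nrow(object@values),
      " images x ", ncol(object@values), " units\n", sep = "")
})

#' Representational dissimilarity matrix
#'
#' Pairwise Euclidean distances between the rows (image response patterns) of
#' a response matrix, on the raw patterns with no row normalization — entry
#' `(i, j)` is `||r_i - r_j||_2`. The result is symmetric with a zero
#' diagonal and characterizes the representational geometry of the source.
#'
#' @param responses a [ResponseMatrix-class] (or plain images x units matrix)
#' @return an [RDM-class]
#' @export
computeRDM <- function(responses) {
  if (is(responses, "ResponseMatrix")) {
    vals <- responses@values
    ids <- responses@imageIds
  } else {
    vals <- as.matrix(responses)
    ids <- if (!is.null(rownames(vals))) rownames(vals)
           else paste0("img", seq_len(nrow(vals)))
  }
  if (any(!is.finite(vals))) stop("response matrix contains missing values")
  if (nrow(vals) < 3L) stop("need at least 3 images")
  d <- as.matrix(dist(vals, method = "euclidean"))
  dimnames(d) <- NULL
  new("RDM", dissimilarities = d, imageIds = as.character(ids))
}

#' @describeIn computeRDM the pairwise distance matrix
#' @param x an `RDM`
#' @export
setMethod("dissimilarities", "RDM", function(x) x@dissimilarities)

#' @rdname computeRDM
#' @export
setMethod("imageIds", "RDM", function(x) x@imageIds)

setMethod("show", "RDM", function(object) {
  n <- nrow(object@dissimilarities)
  up <- object@dissimilarities[upper.tri(object@dissimilarities)]
  cat("RDM over ", n, " images; distance range [",
      format(min(up)), ", ", format(max(up)), "]\n", sep = "")
})

#' Second-order representational similarity of two RDMs
#'
#' Spearman rank correlation between the vectorized strictly-upper triangles
#' (diagonal excluded) of two RDMs over the same ordered image set. Rank
#' correlation makes the comparison invariant to any monotone transform of
#' either RDM's distances.
#'
#' @param rdmA,rdmB [RDM-class] objects over the same images in the same
#'   order
#' @return a [CorrelationResult-class]
#' @export
rsaSimilarity <- function(rdmA, rdmB) {
  stopifnot(is(rdmA, "RDM"), is(rdmB, "RDM"))
  if (!identical(rdmA@imageIds, rdmB@imageIds))
    stop("RDMs cover different image sets or orderings")
  up <- upper.tri(rdmA@dissimilarities)
  a <- rdmA@dissimilarities[up]
  b <- rdmB@dissimilarities[up]
  res <- spearmanRho(a, b)
  new("CorrelationResult", rho = res$rho, pValue = res$p,
      n = as.integer(length(a)), method = res$method)
}

#' Synthetic reference responses with a known representational geometry
#'
#' Generates a reference response matrix (a stand-in for measured response
#' patterns such as voxel activations) as a random linear readout of source
#' features plus additive Gaussian noise. Features are centered per unit and
#' rescaled by a single global factor to unit root-mean-square (both
#' geometry-preserving), then mapped to `nUnits` units through a
#' Haar-distributed random partial isometry (orthonormal readout weights).
#' With `nUnits >= ncol(features)` and zero noise the pairwise distances —
#' hence the RDM, hence the representational geometry — are preserved
#' exactly, so [rsaSimilarity()] against the source is 1; noise degrades the
#' second-order similarity gracefully. Because signal has unit RMS, `noiseSd`
#' reads directly as a noise-to-signal ratio (0.5 mild, 2 severe).
#'
#' @param sourceFeatures a [ResponseMatrix-class] or images x features matrix
#'   (e.g. [penultimateFeatures()] of a model)
#' @param nUnits number of reference units, >= 1; fewer units than feature
#'   dimensions gives a random orthogonal projection onto a subspace
#' @param noiseSd standard deviation of additive Gaussian noise, >= 0,
#'   relative to unit signal RMS
#' @param seed integer seed; generation is bit-reproducible under (arguments, seed)
#' @return a [ResponseMatrix-class] with `source = "reference"`
#' @export
generateReferenceResponses <- function(sourceFeatures, nUnits, noiseSd = 0,
                                       seed = 0L) {
  feats <- if (is(sourceFeatures, "ResponseMatrix")) sourceFeatures@values
           else as.matrix(sourceFeatures)
  ids <- if (is(sourceFeatures, "ResponseMatrix")) sourceFeatures@imageIds
         else paste0("img", seq_len(nrow(feats)))
  nUnits <- as.integer(nUnits)
  if (nUnits < 1L) stop("nUnits must be >= 1")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  d <- ncol(feats)
  Z <- sweep(feats, 2L, colMeans(feats))
  rms <- sqrt(mean(Z^2))
  if (rms > 0) Z <- Z / rms
  withSeed(seed, {
    if (nUnits >= d) {
      G <- matrix(rnorm(nUnits * d), nUnits, d)
      Q <- qr.Q(qr(G))[, seq_len(d), drop = FALSE]  # nUnits x d, Q'Q = I_d
      resp <- Z %*% t(Q)
    } else {
      G <- matrix(rnorm(d * nUnits), d, nUnits)
      Q <- qr.Q(qr(G))[, seq_len(nUnits), drop = FALSE]
      resp <- Z %*% Q
    }
    if (noiseSd > 0)
      resp <- resp + matrix(rnorm(length(resp), sd = noiseSd),
                            nrow(resp), ncol(resp))
    responseMatrix(resp, source = "reference", ids = ids)
  })
}
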