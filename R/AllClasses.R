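# S4 classes for the SF-reliance pipeline. All frequency-domain matrices use
# the natural (unshifted) DFT layout of stats::fft: the DC coefficient sits at
# [1, 1] and signed frequency indices wrap around, so masks multiply fft()
# output directly without any fftshift.

#' FrequencyGrid: radial-frequency geometry of a 2-D DFT
#'
#' Holds the per-coefficient radial frequency \eqn{r = \sqrt{u^2 + v^2}} in
#' cycles per image (cpi), where \eqn{(u, v)} are the signed integer frequency
#' indices of the 2-D DFT, and the Nyquist limit `min(H, W) / 2` beyond which
#' axis frequencies are not resolvable (112 cpi for 224 x 224 images).
#'
#' @slot height,width image dimensions in pixels
#' @slot radialFreq numeric matrix (height x width, unshifted DFT layout) of
#'   radial frequencies in cpi; 0 at the DC coefficient
#' @slot nyquistCpi highest resolvable axis frequency, `min(height, width)/2`
#' @seealso [frequencyGrid()]
#' @exportClass FrequencyGrid
setClass("FrequencyGrid",
  slots = c(
    height = "integer",
    width = "integer",
    radialFreq = "matrix",
    nyquistCpi = "numeric"
  )
)

setValidity("FrequencyGrid", function(object) {
  msg <- character()
  if (object@height < 2L || object@width < 2L)
    msg <- c(msg, "height and width must be >= 2")
  if (!identical(dim(object@radialFreq), c(object@height, object@width)))
    msg <- c(msg, "radialFreq dimensions must match height x width")
  if (length(object@radialFreq) && object@radialFreq[1L, 1L] != 0)
    msg <- c(msg, "radial frequency at DC must be 0")
  if (!isTRUE(all.equal(object@nyquistCpi,
                        min(object@height, object@width) / 2)))
    msg <- c(msg, "nyquistCpi must equal min(height, width)/2")
  if (length(msg)) msg else TRUE
})

#' SFMask: radially symmetric spatial-frequency mask
#'
#' Per-coefficient weights in `[0, 1]` on a [FrequencyGrid-class]. Weight 1
#' preserves the original Fourier phase at that coefficient during
#' [phaseScramble()]; weight 0 fully randomizes it; intermediate weights blend.
#' The same weights act multiplicatively on coefficients in [filterAugment()].
#'
#' @slot weights numeric matrix of weights in `[0, 1]`, unshifted DFT layout
#' @slot condition provenance label, one of `"human_channel"`, `"extreme_lsf"`,
#'   `"fixed_sigma_lsf"`, `"mixed_sigma_lsf"`, `"combined_channel"`,
#'   `"inverse_human"`, `"inverse_extreme_lsf"`, `"custom"`
#' @slot muOctaves Gaussian center in octaves (log2 cpi), or `NA`
#' @slot sigma bandwidth parameter (octaves for log-frequency Gaussians,
#'   pixels for blur-derived masks), or `NA`
#' @slot unitPeak whether the maximum weight over non-DC coefficients is 1
#' @seealso [gaussianLogFreqMask()], [blurMagnitudeMask()], [invertMask()]
#' @exportClass SFMask
setClass("SFMask",
  slots = c(
    weights = "matrix",
    condition = "character",
    muOctaves = "numeric",
    sigma = "numeric",
    unitPeak = "logical"
  )
)

setValidity("SFMask", function(object) {
  w <- object@weights
  msg <- character()
  if (!all(is.finite(w)))
    msg <- c(msg, "mask weights must be finite")
  else if (min(w) < -1e-9 || max(w) > 1 + 1e-9)
    msg <- c(msg, "mask weights must lie in [0, 1]")
  if (length(object@condition) != 1L)
    msg <- c(msg, "condition must be a single string")
  if (isTRUE(object@unitPeak) && abs(max(w) - 1) > 1e-9)
    msg <- c(msg, "unit-peak mask must have maximum weight 1")
  if (length(msg)) msg else TRUE
})

#' OctaveBands: spatial-frequency band partition
#'
#' Ordered half-open bands `[lo, hi)` in cpi used to aggregate radial power
#' profiles. The default partition on a 224-pixel grid is
#' `(0, 3.5), [3.5, 7), [7, 14), [14, 28), [28, 56), [56, 112)`: the two lowest
#' octaves are merged (sparse Fourier sampling at low frequencies) and every
#' band above 3.5 cpi spans exactly one octave (upper edge = 2 x lower edge).
#' DC is excluded from the lowest band.
#'
#' @slot edges numeric vector of band boundaries, strictly increasing
#' @slot labels one name per band
#' @seealso [octaveBands()], [bandDeltaAUC()]
#' @exportClass OctaveBands
setClass("OctaveBands",
  slots = c(edges = "numeric", labels = "character")
)

setValidity("OctaveBands", function(object) {
  msg <- character()
  if (length(object@edges) < 2L)
    msg <- c(msg, "need at least two edges")
  if (any(diff(object@edges) <= 0))
    msg <- c(msg, "edges must be strictly increasing")
  if (length(object@labels) != length(object@edges) - 1L)
    msg <- c(msg, "need one label per band")
  if (length(msg)) msg else TRUE
})

#' SFProfile: normalized radial power profile
#'
#' Proportion of total (DC-removed) perturbation power per unit-width radial
#' frequency bin; bin `k` covers `[k - 0.5, k + 0.5)` cpi and coefficients with
#' radial frequency above the Nyquist limit are excluded. Proportions are
#' nonnegative and sum to 1. Optional bootstrap 95% confidence bounds are
#' attached by [meanProfileWithCI()].
#'
#' @slot binCenters radial frequency of each bin in cpi (integers 1..Nyquist)
#' @slot proportions fraction of total power per bin; sums to 1
#' @slot nPerturbations number of perturbations aggregated into this profile
#' @slot ciLow,ciHigh per-bin bootstrap 95% bounds, or `numeric(0)`
#' @seealso [radialProfile()], [meanProfileWithCI()]
#' @exportClass SFProfile
setClass("SFProfile",
  slots = c(
    binCenters = "numeric",
    proportions = "numeric",
    nPerturbations = "integer",
    ciLow = "numeric",
    ciHigh = "numeric"
  )
)

setValidity("SFProfile", function(object) {
  msg <- character()
  if (length(object@proportions) != length(object@binCenters))
    msg <- c(msg, "proportions and binCenters must have equal length")
  if (any(object@proportions < -1e-12))
    msg <- c(msg, "proportions must be nonnegative")
  if (abs(sum(object@proportions) - 1) > 1e-9)
    msg <- c(msg, "proportions must sum to 1")
  if (length(object@ciLow) &&
      length(object@ciLow) != length(object@proportions))
    msg <- c(msg, "ciLow length must match proportions")
  if (length(object@ciHigh) &&
      length(object@ciHigh) != length(object@proportions))
    msg <- c(msg, "ciHigh length must match proportions")
  if (length(msg)) msg else TRUE
})

#' BandStats: per-octave power-allocation shift relative to a baseline
#'
#' For each band, the model's share of perturbation power minus the baseline
#' model's share (Delta AUC of the percent-power profile). Values lie in
#' `[-1, 1]` and sum to 0 across bands when the bands tile the retained
#' spectrum.
#'
#' @slot bands the [OctaveBands-class] partition used
#' @slot deltaAUC per-band model-minus-baseline power share
#' @slot modelId label of the probed model
#' @slot ciLow,ciHigh optional bootstrap bounds per band, or `numeric(0)`
#' @seealso [bandDeltaAUC()]
#' @exportClass BandStats
setClass("BandStats",
  slots = c(
    bands = "OctaveBands",
    deltaAUC = "numeric",
    modelId = "character",
    ciLow = "numeric",
    ciHigh = "numeric"
  )
)

setValidity("BandStats", function(object) {
  msg <- character()
  nb <- length(object@bands@labels)
  if (length(object@deltaAUC) != nb)
    msg <- c(msg, "need one deltaAUC per band")
  if (any(abs(object@deltaAUC) > 1 + 1e-9))
    msg <- c(msg, "per-band deltaAUC must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' AttackConfig: parameters of a bounded gradient attack
#'
#' @slot norm `"linf"` or `"l2"`
#' @slot epsilon perturbation bound on the `[0, 1]` pixel scale (e.g. `4/255`)
#' @slot steps iteration count (1 for FGSM-style single step)
#' @slot stepSize per-step magnitude; defaults to `epsilon/4` for l-infinity
#'   and `2.5 * epsilon / steps` for l2
#' @slot randomInit start from uniform noise in the epsilon ball
#' @slot seed integer seed for the random initialization
#' @seealso [attackConfig()], [pgdAttack()]
#' @exportClass AttackConfig
setClass("AttackConfig",
  slots = c(
    norm = "character",
    epsilon = "numeric",
    steps = "integer",
    stepSize = "numeric",
    randomInit = "logical",
    seed = "integer"
  )
)

setValidity("AttackConfig", function(object) {
  msg <- character()
  if (!object@norm %in% c("linf", "l2"))
    msg <- c(msg, "norm must be 'linf' or 'l2'")
  if (object@epsilon <= 0) msg <- c(msg, "epsilon must be > 0")
  if (object@steps < 1L) msg <- c(msg, "steps must be >= 1")
  if (object@stepSize <= 0) msg <- c(msg, "stepSize must be > 0")
  if (length(msg)) msg else TRUE
})

#' Perturbation: one bounded adversarial delta with its outcome
#'
#' @slot delta H x W x 3 additive image perturbation
#' @slot epsilon the bound it was generated under
#' @slot norm `"linf"` or `"l2"`
#' @slot success `TRUE` iff the model was correct on the clean input and wrong
#'   on the perturbed input (top-1)
#' @slot cleanLabel ground-truth class index
#' @slot advLabel predicted class on the perturbed input
#' @seealso [pgdAttack()], [filterSuccessful()], [perturbationPowerSpectrum()]
#' @exportClass Perturbation
setClass("Perturbation",
  slots = c(
    delta = "array",
    epsilon = "numeric",
    norm = "character",
    success = "logical",
    cleanLabel = "integer",
    advLabel = "integer"
  )
)

setValidity("Perturbation", function(object) {
  msg <- character()
  if (length(dim(object@delta)) != 3L || dim(object@delta)[3L] != 3L)
    msg <- c(msg, "delta must be an H x W x 3 array")
  if (!all(is.finite(object@delta)))
    msg <- c(msg, "delta must be finite")
  d <- object@delta
  tol <- 1e-9
  if (object@norm == "linf" && max(abs(d)) > object@epsilon + tol)
    msg <- c(msg, "l-infinity norm of delta exceeds epsilon")
  if (object@norm == "l2" && sqrt(sum(d^2)) > object@epsilon + 1e-6)
    msg <- c(msg, "l2 norm of delta exceeds epsilon")
  if (length(msg)) msg else TRUE
})

#' RobustnessCurve: top-1 accuracy under attack over an epsilon grid
#'
#' @slot epsilons strictly increasing perturbation bounds (pixel scale)
#' @slot accuracies top-1 accuracy under attack at each epsilon
#' @slot cleanAccuracy top-1 accuracy on unattacked inputs
#' @slot auc trapezoidal area under the accuracy curve over the grid
#' @seealso [evaluateRobustness()], [robustAUC()]
#' @exportClass RobustnessCurve
setClass("RobustnessCurve",
  slots = c(
    epsilons = "numeric",
    accuracies = "numeric",
    cleanAccuracy = "numeric",
    auc = "numeric"
  )
)

setValidity("RobustnessCurve", function(object) {
  msg <- character()
  if (length(object@accuracies) != length(object@epsilons))
    msg <- c(msg, "one accuracy per epsilon required")
  if (any(diff(object@epsilons) <= 0))
    msg <- c(msg, "epsilons must be strictly increasing")
  if (any(object@accuracies < -1e-12 | object@accuracies > 1 + 1e-12))
    msg <- c(msg, "accuracies must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' ResponseMatrix: images x units response patterns
#'
#' Rows are images, columns are response units (penultimate-layer features of
#' a model, or reference units such as voxels). Used to build RDMs.
#'
#' @slot values numeric matrix, images x units, no missing values
#' @slot source `"model_penultimate"` or `"reference"`
#' @slot imageIds ordered image identifiers, one per row
#' @seealso [responseMatrix()], [computeRDM()], [generateReferenceResponses()]
#' @exportClass ResponseMatrix
setClass("ResponseMatrix",
  slots = c(values = "matrix", source = "character", imageIds = "character")
)

setValidity("ResponseMatrix", function(object) {
  msg <- character()
  if (nrow(object@values) < 3L)
    msg <- c(msg, "need at least 3 images")
  if (any(!is.finite(object@values)))
    msg <- c(msg, "values must be finite (no NA/NaN)")
  if (length(object@imageIds) != nrow(object@values))
    msg <- c(msg, "need one imageId per row")
  if (!object@source %in% c("model_penultimate", "reference"))
    msg <- c(msg, "source must be 'model_penultimate' or 'reference'")
  if (length(msg)) msg else TRUE
})

#' RDM: representational dissimilarity matrix
#'
#' Symmetric, zero-diagonal matrix of pairwise Euclidean distances between the
#' rows of a [ResponseMatrix-class].
#'
#' @slot dissimilarities N x N symmetric nonnegative matrix, zero diagonal
#' @slot imageIds image identifiers in row/column order
#' @seealso [computeRDM()], [rsaSimilarity()]
#' @exportClass RDM
setClass("RDM",
  slots = c(dissimilarities = "matrix", imageIds = "character")
)

setValidity("RDM", function(object) {
  d <- object@dissimilarities
  msg <- character()
  if (nrow(d) != ncol(d)) msg <- c(msg, "matrix must be square")
  if (any(!is.finite(d))) msg <- c(msg, "dissimilarities must be finite")
  else {
    if (max(abs(d - t(d))) > 1e-8) msg <- c(msg, "matrix must be symmetric")
    if (max(abs(diag(d))) > 1e-10) msg <- c(msg, "diagonal must be zero")
    if (min(d) < -1e-12) msg <- c(msg, "dissimilarities must be nonnegative")
  }
  if (length(object@imageIds) != nrow(d))
    msg <- c(msg, "need one imageId per row")
  if (length(msg)) msg else TRUE
})

#' CorrelationResult: Spearman rank correlation with a p-value
#'
#' @slot rho Spearman rank correlation (average ranks for ties)
#' @slot pValue two-sided p-value
#' @slot n number of paired observations
#' @slot method how the p-value was obtained (`"t-approximation"` or
#'   `"exact-permutation"`)
#' @seealso [correlateBandWithRobustness()], [rsaSimilarity()]
#' @exportClass CorrelationResult
setClass("CorrelationResult",
  slots = c(rho = "numeric", pValue = "numeric", n = "integer",
            method = "character")
)

setValidity("CorrelationResult", function(object) {
  if (abs(object@rho) > 1 + 1e-12) "rho must lie in [-1, 1]" else TRUE
})

#' AugmentationPolicy: per-image replacement rule for training batches
#'
#' With probability `replaceProb` an image is replaced by its band-selectively
#' phase-scrambled version; the mask applied to a replaced image is drawn from
#' `masks` with probabilities `maskProbs` (exactly one mask per image per
#' step). Evaluation data never passes through a policy.
#'
#' @slot replaceProb probability in `[0, 1]` that an image is replaced
#' @slot masks list of [SFMask-class] objects
#' @slot maskProbs selection probability per mask; sums to 1
#' @seealso [augmentationPolicy()], [applyPolicy()], [mixedSigmaPolicy()]
#' @exportClass AugmentationPolicy
setClass("AugmentationPolicy",
  slots = c(replaceProb = "numeric", masks = "list", maskProbs = "numeric")
)

setValidity("AugmentationPolicy", function(object) {
  msg <- character()
  if (object@replaceProb < 0 || object@replaceProb > 1)
    msg <- c(msg, "replaceProb must lie in [0, 1]")
  if (length(object@masks) != length(object@maskProbs))
    msg <- c(msg, "need one probability per mask")
  if (length(object@maskProbs)) {
    if (any(object@maskProbs < 0))
      msg <- c(msg, "mask probabilities must be nonnegative")
    if (abs(sum(object@maskProbs) - 1) > 1e-9)
      msg <- c(msg, "mask probabilities must sum to 1")
  } else if (object@replaceProb > 0) {
    msg <- c(msg, "a policy with replaceProb > 0 needs at least one mask")
  }
  if (!all(vapply(object@masks, is, logical(1), class2 = "SFMask")))
    msg <- c(msg, "masks must all be SFMask objects")
  if (length(msg)) msg else TRUE
})

#' MLPClassifier: small differentiable image classifier
#'
#' A one-hidden-layer ReLU network on flattened pixels,
#' `logits = relu(x W1 + b1) W2 + b2`, written in plain matrix algebra so that
#' logits, penultimate features, and exact input gradients are all available
#' to the attack and RSA stages. With the default 8 hidden units on
#' 64 x 64 x 3 inputs it has just under 100k parameters and trains to high
#' accuracy on band-coded synthetic data in seconds on one CPU.
#'
#' @slot W1 input-to-hidden weights (D x H)
#' @slot b1 hidden biases
#' @slot W2 hidden-to-logit weights (H x K)
#' @slot b2 logit biases
#' @slot imageSize input side length in pixels (square RGB inputs)
#' @slot nClasses number of classes
#' @slot trained whether [trainClassifier()] has been run
#' @seealso [makeFixtureClassifier()], [trainClassifier()], [pgdAttack()]
#' @exportClass MLPClassifier
setClass("MLPClassifier",
  slots = c(
    W1 = "matrix", b1 = "numeric", W2 = "matrix", b2 = "numeric",
    imageSize = "integer", nClasses = "integer", trained = "logical"
  )
)

setValidity("MLPClassifier", function(object) {
  msg <- character()
  D <- as.integer(object@imageSize)^2 * 3L
  if (nrow(object@W1) != D)
    msg <- c(msg, "W1 rows must equal imageSize^2 * 3")
  if (ncol(object@W1) != length(object@b1))
    msg <- c(msg, "b1 length must equal hidden width")
  if (nrow(object@W2) != ncol(object@W1))
    msg <- c(msg, "W2 rows must equal hidden width")
  if (ncol(object@W2) != object@nClasses ||
      length(object@b2) != object@nClasses)
    msg <- c(msg, "W2/b2 must match nClasses")
  if (length(msg)) msg else TRUE
})

#' LinearClassifier: linear softmax model
#'
#' `logits = x W + b` with no hidden layer. Mainly useful as an analytically
#' tractable target for attack oracles: the worst-case l-infinity perturbation
#' of a linear model has a closed form.
#'
#' @slot W weight matrix (D x K)
#' @slot b bias vector (length K)
#' @seealso [linearClassifier()], [pgdAttack()]
#' @exportClass LinearClassifier
setClass("LinearClassifier", slots = c(W = "matrix", b = "numeric"))

setValidity("LinearClassifier", function(object) {
  if (ncol(object@W) != length(object@b))
    "b length must equal ncol(W)" else TRUE
})

#' BandCodedDataset: synthetic labeled images with known SF ground truth
#'
#' Each class has a fixed random template whose Fourier support is confined to
#' `band` (cpi); images are the class template plus broadband Gaussian noise,
#' mapped into `[0, 1]`. Phase structure, not amplitude, carries class
#' identity, so the informative band is recoverable by the spectral probe.
#'
#' @slot images N x H x W x 3 array in `[0, 1]`
#' @slot labels integer class labels in 1..K
#' @slot templates K x H x W x 3 array of class templates (signal component)
#' @slot band informative band `[lo, hi)` in cpi
#' @slot snr in-band class-signal power over out-of-band noise power
#' @slot noiseSd pixel-scale standard deviation of the broadband noise
#' @slot seed generator seed
#' @seealso [generateBandCodedDataset()]
#' @exportClass BandCodedDataset
setClass("BandCodedDataset",
  slots = c(
    images = "array", labels = "integer", templates = "array",
    band = "numeric", snr = "numeric", noiseSd = "numeric", seed = "integer"
  )
)

setValidity("BandCodedDataset", function(object) {
  msg <- character()
  if (length(dim(object@images)) != 4L)
    msg <- c(msg, "images must be N x H x W x 3")
  if (dim(object@images)[1L] != length(object@labels))
    msg <- c(msg, "need one label per image")
  if (length(object@band) != 2L || object@band[1L] >= object@band[2L])
    msg <- c(msg, "band must be c(lo, hi) with lo < hi")
  if (object@snr <= 0) msg <- c(msg, "snr must be > 0")
  if (length(msg)) msg else TRUE
})
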