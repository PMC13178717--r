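# Band-selective soft phase scrambling and the filter-based alternative.
# Images are H x W x 3 arrays in [0, 1]; augmentation operates on these raw
# pixel values, before any dataset normalization.

#' Sample a random phase field for phase scrambling
#'
#' Draws one phase value per DFT coefficient, uniform on `(-pi, pi]`, with the
#' Hermitian antisymmetry `phi(-u, -v) = -phi(u, v)` required for a real
#' reconstruction (self-conjugate coefficients — DC and the Nyquist lines —
#' get phase 0 or pi). The field is built as the phase of the DFT of white
#' Gaussian noise, which has exactly these properties. One field is shared
#' across the three color channels of an image to preserve color coherence.
#'
#' @param grid a [FrequencyGrid-class]
#' @param seed integer seed; the same seed always yields the same field
#' @return numeric matrix of phases in `(-pi, pi]`, unshifted DFT layout
#' @export
samplePhaseField <- function(grid, seed = NULL) {
  stopifnot(is(grid, "FrequencyGrid"))
  noise <- withSeed(seed, matrix(rnorm(grid@height * grid@width),
                                 grid@height, grid@width))
  Arg(fft(noise))
}

#' Band-selective soft phase scrambling
#'
#' Replaces the phase of each Fourier coefficient by the angle of a soft blend
#' of the original and a random phasor,
#' \deqn{\phi'_c(u,v) = \angle\left(M(u,v)\, e^{i\phi_c(u,v)} +
#'   (1 - M(u,v))\, e^{i\phi_r(u,v)}\right),}
#' and reconstructs each channel from its \emph{original} amplitude spectrum
#' with the blended phase. Mask weight 1 preserves the original phase, weight
#' 0 yields full scrambling, intermediate weights partial scrambling. The
#' amplitude spectrum — hence the total spectral energy — of every channel is
#' preserved exactly before range handling. The random phase field is shared
#' across the three color channels; DC phase is always kept so mean luminance
#' survives.
#'
#' When the two phasors are antipodal and `M = 0.5` the blend is the angle of
#' a (numerically) zero vector; the original phase is kept in that degenerate
#' case (blend magnitude below 1e-12), a deterministic, bias-free tie-break.
#'
#' Reconstruction can push a few pixels outside `[0, 1]`; `clip` selects the
#' range handling: `"clamp"` (default, reproducible hard clip), `"tanh"` (a
#' smooth compressor that saturates near the violated boundary), or `"none"`
#' (return the raw reconstruction, useful for amplitude-conservation checks).
#'
#' @param image H x W x 3 array in `[0, 1]`
#' @param mask an [SFMask-class] on the image's grid
#' @param phaseField optional phase matrix from [samplePhaseField()]; must be
#'   Hermitian-antisymmetric. Drawn fresh (under `seed`) when `NULL`.
#' @param seed seed used when `phaseField` is `NULL`
#' @param clip out-of-range handling: `"clamp"`, `"tanh"`, or `"none"`
#' @return H x W x 3 array; in `[0, 1]` unless `clip = "none"`
#' @examples
#' g <- frequencyGrid(32, 32)
#' img <- array(runif(32 * 32 * 3), c(32, 32, 3))
#' m <- conditionMask(g, "extreme_lsf")
#' out <- phaseScramble(img, m, seed = 1, clip = "none")
#' # per-channel amplitude spectra are preserved exactly
#' max(abs(Mod(fft(out[, , 1])) - Mod(fft(img[, , 1]))))
#' @export
phaseScramble <- function(image, mask, phaseField = NULL, seed = NULL,
                          clip = c("clamp", "tanh", "none")) {
  clip <- match.arg(clip)
  d <- dim(image)
  if (length(d) != 3L || d[3L] != 3L)
    stop("image must be an H x W x 3 array")
  if (!all(is.finite(image)))
    stop("image must be finite")
  M <- maskWeights(mask)
  if (!identical(dim(M), d[1:2]))
    stop("mask grid (", paste(dim(M), collapse = " x "),
         ") does not match image (", paste(d[1:2], collapse = " x "), ")")
  if (is.null(phaseField)) {
    grid <- frequencyGrid(d[1L], d[2L])
    phaseField <- samplePhaseField(grid, seed = seed)
  }
  if (!identical(dim(phaseField), d[1:2]))
    stop("phase field dimensions do not match the image")
  if (!checkHermitianPhase(phaseField))
    stop("phase field is not Hermitian-antisymmetric; ",
         "reconstruction would not be real")
  randPhasor <- exp(1i * phaseField)
  out <- array(0, d)
  for (c in 1:3) {
    F <- fft(image[, , c])
    A <- Mod(F)
    phi <- Arg(F)
    z <- M * exp(1i * phi) + (1 - M) * randPhasor
    phiNew <- Arg(z)
    degenerate <- Mod(z) < 1e-12
    phiNew[degenerate] <- phi[degenerate]
    phiNew[1L, 1L] <- phi[1L, 1L]  # DC phase always preserved
    out[, , c] <- ifft2Real(A * exp(1i * phiNew))
  }
  rangeHandle(out, clip)
}

#' Filter-based frequency manipulation
#'
#' The conventional alternative to phase scrambling: multiplies each channel's
#' Fourier coefficients by the mask weights and reconstructs. Unlike
#' [phaseScramble()], the amplitude spectrum is \emph{not} preserved — energy
#' outside the passband is attenuated rather than phase-randomized, so the
#' image's power spectrum changes.
#'
#' @inheritParams phaseScramble
#' @return H x W x 3 array; in `[0, 1]` unless `clip = "none"`
#' @export
filterAugment <- function(image, mask, clip = c("clamp", "tanh", "none")) {
  clip <- match.arg(clip)
  d <- dim(image)
  if (length(d) != 3L || d[3L] != 3L)
    stop("image must be an H x W x 3 array")
  M <- maskWeights(mask)
  if (!identical(dim(M), d[1:2]))
    stop("mask grid does not match image dimensions")
  out <- array(0, d)
  for (c in 1:3) {
    out[, , c] <- ifft2Real(fft(image[, , c]) * M)
  }
  rangeHandle(out, clip)
}

#' Construct an augmentation policy
#'
#' Bundles a replacement probability with a distribution over masks. During
#' training each image is independently replaced by its phase-scrambled
#' version with probability `replaceProb`; a replaced image receives exactly
#' one mask, drawn from `masks` with probabilities `maskProbs`. The
#' conventional strengths are `replaceProb = 0.3` (weak bias) and `0.5`
#' (strong bias). The combined-channel condition uses two masks at 50/50; the
#' mixed-sigma conditions use the printed per-width probabilities (see
#' [mixedSigmaPolicy()]), with the residual mass leaving images unmodified.
#'
#' @param replaceProb probability an image is replaced, in `[0, 1]`
#' @param masks list of [SFMask-class] objects (or a single mask)
#' @param maskProbs selection probabilities, one per mask, summing to 1;
#'   defaults to uniform
#' @return an [AugmentationPolicy-class]
#' @export
augmentationPolicy <- function(replaceProb, masks, maskProbs = NULL) {
  if (is(masks, "SFMask")) masks <- list(masks)
  if (is.null(maskProbs))
    maskProbs <- rep(1 / length(masks), length(masks))
  new("AugmentationPolicy", replaceProb = replaceProb, masks = masks,
      maskProbs = maskProbs)
}

#' Mixed-sigma augmentation policy on a grid
#'
#' Builds the executable [AugmentationPolicy-class] for the mixed-sigma-LSF
#' condition: one blur-magnitude mask per kernel width, selected with the
#' printed per-width probabilities. The total replacement probability is the
#' sum of the printed probabilities (0.3063 weak, 0.8 strong); the residual
#' mass leaves the image unmodified.
#'
#' @param grid a [FrequencyGrid-class]
#' @param variant `"weak"` or `"strong"`
#' @return an [AugmentationPolicy-class]
#' @export
mixedSigmaAugmentation <- function(grid, variant = c("weak", "strong")) {
  pol <- mixedSigmaPolicy(match.arg(variant))
  masks <- lapply(pol$sigmas, function(s) {
    m <- blurMagnitudeMask(grid, s)
    m@condition <- "mixed_sigma_lsf"
    m
  })
  total <- sum(pol$probs)
  augmentationPolicy(total, masks, pol$probs / total)
}

#' Apply an augmentation policy to a batch of images
#'
#' Independently replaces each image with its phase-scrambled version with the
#' policy's probability; a replaced image gets exactly one mask (drawn from
#' the policy's mask distribution) and a fresh random phase field. Intended
#' for training batches only — evaluation data must never pass through this
#' function.
#'
#' @param batch list of H x W x 3 arrays, or an N x H x W x 3 array
#' @param policy an [AugmentationPolicy-class]
#' @param seed integer seed making the whole batch reproducible
#' @param clip out-of-range handling passed to [phaseScramble()]
#' @return the batch in its input form (list in, list out), with a logical
#'   attribute `"replaced"` marking which images were scrambled
#' @export
applyPolicy <- function(batch, policy, seed = NULL,
                        clip = c("clamp", "tanh", "none")) {
  clip <- match.arg(clip)
  stopifnot(is(policy, "AugmentationPolicy"))
  validObject(policy)
  asArray <- !is.list(batch)
  if (asArray) {
    stopifnot(length(dim(batch)) == 4L)
    n <- dim(batch)[1L]
    getImg <- function(i) batch[i, , , ]
  } else {
    n <- length(batch)
    getImg <- function(i) batch[[i]]
  }
  out <- batch
  replaced <- logical(n)
  withSeed(seed, {
    for (i in seq_len(n)) {
      u <- runif(1)
      if (u < policy@replaceProb) {
        replaced[i] <- TRUE
        k <- if (length(policy@masks) == 1L) 1L
             else sample.int(length(policy@masks), 1L,
                             prob = policy@maskProbs)
        img <- getImg(i)
        scr <- phaseScramble(img, policy@masks[[k]], clip = clip)
        if (asArray) out[i, , , ] <- scr else out[[i]] <- scr
      }
    }
  })
  attr(out, "replaced") <- replaced
  out
}

setMethod("show", "AugmentationPolicy", function(object) {
  cat("AugmentationPolicy: p(replace) =", object@replaceProb, "over",
      length(object@masks), "mask(s)\n")
  if (length(object@masks)) {
    conds <- vapply(object@masks, maskCondition, character(1))
    for (i in seq_along(conds))
      cat(sprintf("  %.4f  %s\n", object@maskProbs[i], conds[i]))
  }
})
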