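# Spatial-frequency mask families. All masks are radially symmetric weights
# in [0, 1] over a FrequencyGrid, stored in unshifted DFT layout.

newSFMask <- function(weights, condition, muOctaves = NA_real_,
                      sigma = NA_real_, unitPeak = TRUE) {
  new("SFMask", weights = weights, condition = condition,
      muOctaves = muOctaves, sigma = sigma, unitPeak = unitPeak)
}

#' Gaussian band-pass mask in log-frequency space
#'
#' Builds the radially symmetric phase-preserving mask
#' \deqn{M(f) \propto \exp\left(-\frac{(\log_2 f - \mu)^2}{2\sigma^2}\right)}
#' for radial frequency \eqn{f > 0} in cpi, normalized to unit peak over the
#' non-DC coefficients. With `mu = 4.5` octaves and `sigma = 0.4246` octaves
#' (the defaults) this is the "human channel" band-pass mask on a 224-pixel
#' grid. With `hardPassBelowCenter = TRUE` all frequencies at or below the
#' center `2^mu` additionally receive weight 1, turning the mask into a smooth
#' low-pass with a Gaussian rolloff — the "extreme-LSF" construction, whose
#' center is the geometric mean of 1.75 and 3.5 cpi.
#'
#' The DC coefficient is excluded from the log-frequency formula (log2 of 0 is
#' undefined): pure band-pass masks assign it weight 0, hard-pass (low-pass
#' style) masks assign it weight 1, and `dcWeight` overrides either. Phase
#' scrambling preserves DC phase regardless, so this choice only matters for
#' [filterAugment()], where it decides whether mean luminance is kept.
#'
#' @param grid a [FrequencyGrid-class]
#' @param mu center frequency in octaves (log2 cpi); default 4.5
#' @param sigma bandwidth in octaves, > 0; default 0.4246
#' @param hardPassBelowCenter keep weight 1 for all `0 < f <= 2^mu`
#' @param dcWeight weight of the DC coefficient, or `NULL` for the policy
#'   above
#' @param condition provenance label stored on the mask
#' @return an [SFMask-class] with unit peak
#' @examples
#' g <- frequencyGrid(224, 224)
#' m <- gaussianLogFreqMask(g)                 # human channel
#' max(maskWeights(m)[radialFreq(g) > 0])      # 1 at f ~ 2^4.5 cpi
#' @export
gaussianLogFreqMask <- function(grid, mu = 4.5, sigma = 0.4246,
                                hardPassBelowCenter = FALSE, dcWeight = NULL,
                                condition = if (hardPassBelowCenter)
                                  "extreme_lsf" else "human_channel") {
  stopifnot(is(grid, "FrequencyGrid"))
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("sigma must be a single value > 0")
  r <- grid@radialFreq
  w <- matrix(0, nrow(r), ncol(r))
  pos <- r > 0
  w[pos] <- exp(-(log2(r[pos]) - mu)^2 / (2 * sigma^2))
  if (hardPassBelowCenter)
    w[pos & r <= 2^mu] <- 1
  peak <- max(w[pos])
  if (peak <= 0)
    stop("mask is numerically zero everywhere: the center 2^mu lies too ",
         "far outside the grid's resolvable frequency range")
  w[pos] <- w[pos] / peak
  w[1L, 1L] <- if (!is.null(dcWeight)) dcWeight
               else if (hardPassBelowCenter) 1 else 0
  newSFMask(w, condition, muOctaves = mu, sigma = sigma)
}

#' Low-pass mask from the magnitude response of a Gaussian blur kernel
#'
#' Derives a soft low-pass mask as the unit-peak-normalized DFT magnitude of a
#' discretized isotropic Gaussian kernel with standard deviation `sigmaPx`
#' pixels. Images are never actually blurred: the magnitude response only
#' defines which frequencies keep their phase during scrambling. `sigmaPx =
#' 1.5` gives the "fixed-sigma-LSF" mask; the mixed-sigma conditions draw
#' `sigmaPx` from a discrete distribution (see [mixedSigmaPolicy()]).
#'
#' The kernel is truncated at radius `ceiling(4 * sigmaPx)` (odd support),
#' normalized to unit sum, zero-padded to the grid size with its center at the
#' origin, and transformed; the resulting mask has weight 1 at DC and decays
#' with radial frequency. If the truncated support would exceed the grid, the
#' radius is reduced to fit.
#'
#' @param grid a [FrequencyGrid-class]
#' @param sigmaPx kernel standard deviation in pixels, > 0
#' @return an [SFMask-class] with weight 1 at DC
#' @examples
#' g <- frequencyGrid(64, 64)
#' m <- blurMagnitudeMask(g, 1.5)
#' maskWeights(m)[1, 1]  # 1 at DC
#' @export
blurMagnitudeMask <- function(grid, sigmaPx) {
  stopifnot(is(grid, "FrequencyGrid"))
  if (!is.numeric(sigmaPx) || length(sigmaPx) != 1L || sigmaPx <= 0)
    stop("sigmaPx must be a single value > 0")
  h <- grid@height; w <- grid@width
  R <- min(ceiling(4 * sigmaPx), (min(h, w) - 1L) %/% 2L)
  R <- max(R, 1L)
  off <- (-R):R
  k <- exp(-outer(off^2, off^2, `+`) / (2 * sigmaPx^2))
  k <- k / sum(k)
  padded <- matrix(0, h, w)
  # place the kernel center at the origin with wrap-around, so the DFT has
  # zero phase and its magnitude is the radial frequency response
  idx <- function(d, n) ((d %% n) + n) %% n + 1L
  padded[idx(off, h), idx(off, w)] <- k
  mag <- Mod(fft(padded))
  mag <- mag / max(mag)
  mag <- pmin(pmax(mag, 0), 1)
  newSFMask(mag, "fixed_sigma_lsf", sigma = sigmaPx)
}

#' Mixed-sigma mask-width distribution
#'
#' The discrete distribution over Gaussian blur-kernel widths used by the
#' mixed-sigma-LSF augmentation conditions, replicating a developmentally
#' motivated mixture of low-pass strengths. The weak variant uses
#' `sigma in {1, 2, 3, 4, 5}` pixels with probabilities
#' `{0.2129, 0.0653, 0.0200, 0.0062, 0.0019}`; the strong variant uses
#' `sigma in {1, 2, 4, 8}` each with probability 0.2. Probabilities sum to
#' less than 1: the residual mass leaves the training image unmodified, and a
#' replaced image receives exactly one mask per training step.
#'
#' @param variant `"weak"` or `"strong"`
#' @return a list with elements `sigmas`, `probs` (per-sigma replacement
#'   probabilities), and `residualProb` (probability the image is left
#'   unmodified)
#' @examples
#' mixedSigmaPolicy("weak")$residualProb   # 1 - 0.3063
#' mixedSigmaPolicy("strong")$probs        # 0.2 0.2 0.2 0.2
#' @seealso [augmentationPolicy()] to turn this into an executable policy
#' @export
mixedSigmaPolicy <- function(variant = c("weak", "strong")) {
  variant <- match.arg(variant)
  if (variant == "weak") {
    sigmas <- c(1, 2, 3, 4, 5)
    probs <- c(0.2129, 0.0653, 0.0200, 0.0062, 0.0019)
  } else {
    sigmas <- c(1, 2, 4, 8)
    probs <- rep(0.2, 4L)
  }
  list(sigmas = sigmas, probs = probs, residualProb = 1 - sum(probs))
}

#' Invert a spatial-frequency mask
#'
#' Returns the complementary mask `1 - M`, exactly. Used for necessity
#' checks: where the original mask preserved phase in a band, the inverse
#' concentrates phase scrambling inside that band and preserves everything
#' outside it. Inversion is an involution: `invertMask(invertMask(m))`
#' reproduces `m`'s weights bit for bit.
#'
#' @param mask an [SFMask-class] with weights in `[0, 1]`
#' @return an [SFMask-class]; the condition label gains or loses an
#'   `inverse_` prefix
#' @aliases invertMask
#' @export
setMethod("invertMask", "SFMask", function(mask) {
  inv <- 1 - mask@weights
  cond <- if (startsWith(mask@condition, "inverse_"))
    sub("^inverse_", "", mask@condition)
  else paste0("inverse_", mask@condition)
  new("SFMask", weights = inv, condition = cond,
      muOctaves = mask@muOctaves, sigma = mask@sigma, unitPeak = FALSE)
})

#' @describeIn gaussianLogFreqMask mask weight matrix (unshifted DFT layout)
#' @param x an `SFMask`
#' @export
setMethod("maskWeights", "SFMask", function(x) x@weights)

#' @describeIn gaussianLogFreqMask provenance label of the mask
#' @export
setMethod("maskCondition", "SFMask", function(x) x@condition)

setMethod("show", "SFMask", function(object) {
  d <- dim(object@weights)
  cat("SFMask '", object@condition, "' on ", d[1L], " x ", d[2L],
      " grid", sep = "")
  if (!is.na(object@muOctaves))
    cat(", mu =", format(object@muOctaves), "octaves")
  if (!is.na(object@sigma))
    cat(", sigma =", format(object@sigma))
  cat("\n  weight range [", format(min(object@weights)), ", ",
      format(max(object@weights)), "]\n", sep = "")
})

#' Build the named augmentation-condition masks
#'
#' Convenience constructor for the five mask conditions by name, with centers
#' rescaled to the grid's Nyquist frequency (parameters are stated on the
#' reference 224-pixel grid and shift by `log2(nyquist/112)` octaves on other
#' grids, so a mask targets the same relative band everywhere). Inverse
#' conditions are obtained by [invertMask()] on the corresponding mask.
#'
#' * `human_channel`: Gaussian log-frequency band-pass, `mu = 4.5`,
#'   `sigma = 0.4246` octaves.
#' * `extreme_lsf`: Gaussian centered at the geometric mean of 1.75 and
#'   3.5 cpi with a hard pass below the center (all frequencies below `2^mu`
#'   retained); `sigma = 0.4246` octaves.
#' * `fixed_sigma_lsf`: blur-magnitude mask with `sigmaPx = 1.5`.
#'
#' @param grid a [FrequencyGrid-class]
#' @param condition one of `"human_channel"`, `"extreme_lsf"`,
#'   `"fixed_sigma_lsf"`, `"inverse_human"`, `"inverse_extreme_lsf"`
#' @return an [SFMask-class]
#' @export
conditionMask <- function(grid,
                          condition = c("human_channel", "extreme_lsf",
                                        "fixed_sigma_lsf", "inverse_human",
                                        "inverse_extreme_lsf")) {
  condition <- match.arg(condition)
  shift <- log2(grid@nyquistCpi / 112)
  switch(condition,
    human_channel = gaussianLogFreqMask(grid, mu = 4.5 + shift),
    extreme_lsf = gaussianLogFreqMask(
      grid, mu = log2(sqrt(1.75 * 3.5)) + shift,
      hardPassBelowCenter = TRUE),
    fixed_sigma_lsf = blurMagnitudeMask(grid, 1.5),
    inverse_human = invertMask(conditionMask(grid, "human_channel")),
    inverse_extreme_lsf = invertMask(conditionMask(grid, "extreme_lsf"))
  )
}

#' One-dimensional magnitude response of a mask
#'
#' Averages mask weights over coefficients at (numerically) equal radial
#' frequency, giving the 1-D weight-vs-frequency curve suitable for plotting
#' or CSV export. Because every shipped mask is radially symmetric the average
#' equals the common value at each radius.
#'
#' @param mask an [SFMask-class]
#' @param grid the [FrequencyGrid-class] the mask was built on
#' @return a data.frame with columns `f_cpi` and `weight`, ordered by
#'   frequency (DC row first)
#' @export
maskResponseCurve <- function(mask, grid) {
  stopifnot(is(mask, "SFMask"), is(grid, "FrequencyGrid"))
  if (!identical(dim(mask@weights), dim(grid@radialFreq)))
    stop("mask and grid dimensions differ")
  r <- round(grid@radialFreq, 9)
  agg <- tapply(as.vector(mask@weights), as.vector(r), mean)
  data.frame(f_cpi = as.numeric(names(agg)), weight = as.numeric(agg),
             row.names = NULL)
}
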