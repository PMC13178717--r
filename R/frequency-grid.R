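#' Build the radial-frequency geometry of a 2-D DFT grid
#'
#' Computes, for every DFT coefficient of an `height` x `width` image, the
#' radial frequency \eqn{r = \sqrt{u^2 + v^2}} in cycles per image (cpi),
#' where \eqn{(u, v)} are the signed integer frequency indices of the centered
#' 2-D DFT. The map is stored in the natural (unshifted) layout of
#' [stats::fft()], so it aligns elementwise with `fft(image_channel)`. The
#' highest resolvable axis frequency is `min(height, width) / 2`: 112 cpi for
#' the 224 x 224 grid standard in ImageNet-scale work. For non-square images
#' the signed indices are used directly, so "cpi" then refers to cycles per
#' axis length; all shipped analyses use square grids.
#'
#' @param height,width image dimensions in pixels, both >= 2
#' @return a [FrequencyGrid-class]
#' @examples
#' g <- frequencyGrid(224, 224)
#' nyquistCpi(g)  # 112
#' @export
frequencyGrid <- function(height, width = height) {
  height <- as.integer(height)
  width <- as.integer(width)
  if (is.na(height) || is.na(width) || height < 2L || width < 2L)
    stop("height and width must be integers >= 2")
  u <- fftIndices(height)
  v <- fftIndices(width)
  r <- sqrt(outer(u^2, v^2, `+`))
  new("FrequencyGrid", height = height, width = width,
      radialFreq = r, nyquistCpi = min(height, width) / 2)
}

#' @describeIn frequencyGrid highest resolvable axis frequency in cpi
#' @param x a `FrequencyGrid`
#' @export
setMethod("nyquistCpi", "FrequencyGrid", function(x) x@nyquistCpi)

#' @describeIn frequencyGrid per-coefficient radial frequency matrix (cpi,
#'   unshifted DFT layout)
#' @export
setMethod("radialFreq", "FrequencyGrid", function(x) x@radialFreq)

setMethod("show", "FrequencyGrid", function(object) {
  cat("FrequencyGrid ", object@height, " x ", object@width,
      " (Nyquist ", object@nyquistCpi, " cpi)\n", sep = "")
})

#' Octave-band partition of the spatial-frequency axis
#'
#' Returns the half-open bands `[lo, hi)` in cpi used to aggregate radial
#' power profiles. On the reference 224-pixel grid (Nyquist 112 cpi) the bands
#' are `(0, 3.5), [3.5, 7), [7, 14), [14, 28), [28, 56), [56, 112)`: the two
#' lowest octaves are merged into a single extreme-LSF band because Fourier
#' coefficients are sparse at low radii, and every band above 3.5 cpi spans
#' exactly one octave. The `[28, 56)` octave is the mid-frequency "human
#' channel" reported as critical for human object recognition. For other grid
#' sizes the edges scale proportionally with the Nyquist frequency (e.g.
#' Nyquist 32 gives `(0, 1), [1, 2), [2, 4), [4, 8), [8, 16), [16, 32)`).
#'
#' @param nyquist highest resolvable frequency in cpi (112 for 224-pixel
#'   grids); edges scale as `nyquist / 112`
#' @return an [OctaveBands-class]
#' @examples
#' b <- octaveBands()
#' bandEdges(b)   # 0 3.5 7 14 28 56 112
#' bandLabels(b)
#' @export
octaveBands <- function(nyquist = 112) {
  stopifnot(nyquist > 0)
  edges <- c(0, 3.5, 7, 14, 28, 56, 112) * (nyquist / 112)
  new("OctaveBands",
      edges = edges,
      labels = c("extreme_lsf", "band2", "band3", "band4",
                 "human_channel", "hsf"))
}

#' @describeIn octaveBands band boundaries in cpi
#' @param x an `OctaveBands`
#' @export
setMethod("bandEdges", "OctaveBands", function(x) x@edges)

#' @describeIn octaveBands per-band names
#' @export
setMethod("bandLabels", "OctaveBands", function(x) x@labels)

setMethod("show", "OctaveBands", function(object) {
  n <- length(object@labels)
  cat("OctaveBands with", n, "bands (cpi):\n")
  for (i in seq_len(n)) {
    cat(sprintf("  %-14s [%g, %g)\n", object@labels[i],
                object@edges[i], object@edges[i + 1L]))
  }
})
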