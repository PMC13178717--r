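# Internal helpers.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. seed = NULL runs expr with the ambient RNG.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Trapezoidal integral of y over x.
trapz <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  sum(diff(x) * (head(y, -1L) + tail(y, -1L)) / 2)
}

# Signed DFT frequency indices for an axis of length n, in fft()'s natural
# (unshifted) order: 0, 1, ..., floor(n/2), -(ceiling(n/2)-1), ..., -1.
fftIndices <- function(n) {
  k <- seq_len(n) - 1L
  ifelse(k <= n %/% 2, k, k - n)
}

# Map out-of-range pixel values back into [0, 1].
# "clamp": hard clip. "tanh": identity on [s, 1-s], smooth saturation outside,
# bounded by [0, 1]. "none": leave untouched (diagnostics/invariant checks).
rangeHandle <- function(x, clip = c("clamp", "tanh", "none"), s = 0.05) {
  clip <- match.arg(clip)
  if (clip == "none") return(x)
  if (clip == "clamp") return(pmin(pmax(x, 0), 1))
  hi <- x > 1 - s
  lo <- x < s
  x[hi] <- (1 - s) + s * tanh((x[hi] - (1 - s)) / s)
  x[lo] <- s + s * tanh((x[lo] - s) / s)
  x
}

# 2-D inverse DFT returning the real part, with the imaginary residual checked
# to be numerical noise only.
ifft2Real <- function(z, tol = 1e-6) {
  out <- fft(z, inverse = TRUE) / length(z)
  imax <- max(abs(Im(out)))
  scale <- max(1, max(abs(Re(out))))
  if (imax / scale > tol)
    stop("inverse DFT produced a non-negligible imaginary part (",
         format(imax), "); input spectrum is not Hermitian")
  Re(out)
}

# Flatten an H x W x 3 image array (or an N x H x W x 3 stack) to row
# vector(s), column-major within each image.
flattenImages <- function(x) {
  d <- dim(x)
  if (length(d) == 3L) {
    matrix(as.vector(x), nrow = 1L)
  } else if (length(d) == 4L) {
    matrix(aperm(x, c(2L, 3L, 4L, 1L)), nrow = d[1L], byrow = TRUE)
  } else {
    stop("expected an H x W x 3 image or an N x H x W x 3 stack")
  }
}

unflattenImage <- function(v, size) {
  array(v, dim = c(size, size, 3L))
}

# Validate that a phase-field matrix is Hermitian-antisymmetric:
# value(-u, -v) = -value(u, v) up to 2*pi wrapping.
checkHermitianPhase <- function(phi, tol = 1e-8) {
  h <- nrow(phi); w <- ncol(phi)
  iNeg <- c(1L, rev(seq_len(h - 1L) + 1L))
  jNeg <- c(1L, rev(seq_len(w - 1L) + 1L))
  mirrored <- phi[iNeg, jNeg, drop = FALSE]
  resid <- (phi + mirrored) %% (2 * pi)
  resid <- pmin(resid, 2 * pi - resid)
  max(resid) <= tol
}

softmaxRows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}
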