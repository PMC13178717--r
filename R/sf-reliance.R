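# The spectral probe: perturbation power spectra, radial SF reliance
# profiles, per-octave power-allocation shifts, and their correlation with
# robustness gains.

#' Channel-averaged power spectrum of a perturbation
#'
#' Computes \eqn{P(u,v) = \frac{1}{3}\sum_c |\mathcal{F}(\tau_c)(u,v)|^2},
#' the squared DFT magnitude of the perturbation averaged over the three
#' color channels, in unshifted DFT layout.
#'
#' @param perturbation a [Perturbation-class] or a plain H x W x 3 array
#' @return numeric H x W matrix of power values
#' @export
perturbationPowerSpectrum <- function(perturbation) {
  delta <- if (is(perturbation, "Perturbation")) perturbation@delta
           else perturbation
  stopifnot(length(dim(delta)) == 3L, dim(delta)[3L] == 3L)
  if (!all(is.finite(delta))) stop("perturbation must be finite")
  (Mod(fft(delta[, , 1L]))^2 + Mod(fft(delta[, , 2L]))^2 +
     Mod(fft(delta[, , 3L]))^2) / 3
}

#' Radial SF reliance profile of a power spectrum
#'
#' Rotationally aggregates a 2-D power map over unit-width radial frequency
#' bins (bin `k` covers `[k - 0.5, k + 0.5)` cpi, `k = 1..Nyquist`) and
#' normalizes by total retained power, yielding the proportion-of-energy
#' distribution over spatial frequency. The DC coefficient is removed, and
#' corner coefficients with radial frequency above the Nyquist limit
#' (`min(H, W)/2`, up to `sqrt(2)` times higher at the grid corners) are
#' excluded as unresolvable.
#'
#' @param powerMap H x W power matrix from [perturbationPowerSpectrum()]
#' @param grid the matching [FrequencyGrid-class]
#' @return an [SFProfile-class]; errors on an all-zero spectrum, for which
#'   the proportion profile is undefined
#' @export
radialProfile <- function(powerMap, grid) {
  stopifnot(is(grid, "FrequencyGrid"))
  if (!identical(dim(powerMap), dim(grid@radialFreq)))
    stop("power map and grid dimensions differ")
  ny <- floor(grid@nyquistCpi)
  r <- grid@radialFreq
  keep <- r > 0 & r <= grid@nyquistCpi
  if (!any(powerMap[keep] > 0))
    stop("all-zero power spectrum: the reliance profile is undefined")
  bin <- pmin(pmax(round(r[keep]), 1), ny)
  power <- vapply(seq_len(ny), function(k) sum(powerMap[keep][bin == k]),
                  numeric(1))
  new("SFProfile", binCenters = as.numeric(seq_len(ny)),
      proportions = power / sum(power), nPerturbations = 1L,
      ciLow = numeric(0), ciHigh = numeric(0))
}

#' @describeIn radialProfile bin-center frequencies in cpi
#' @param x an `SFProfile`
#' @export
setMethod("binCenters", "SFProfile", function(x) x@binCenters)

#' @describeIn radialProfile proportion of total power per bin
#' @export
setMethod("profileProportions", "SFProfile", function(x) x@proportions)

setMethod("show", "SFProfile", function(object) {
  cat("SFProfile over ", length(object@binCenters), " radial bins (",
      object@nPerturbations, " perturbation",
      if (object@nPerturbations != 1L) "s", ")\n", sep = "")
  top <- order(object@proportions, decreasing = TRUE)[1:3]
  cat("  top bins (cpi: share):",
      paste(sprintf("%g: %.3f", object@binCenters[top],
                    object@proportions[top]), collapse = ", "), "\n")
})

#' Mean SF profile with bootstrap confidence intervals
#'
#' Averages per-perturbation profiles bin by bin and attaches percentile 95%
#' confidence intervals from bootstrap resampling across perturbations
#' (default 10,000 resamples). Deterministic under `seed`.
#'
#' @param profiles list of [SFProfile-class] objects on identical bins
#' @param nBoot number of bootstrap resamples
#' @param seed integer seed for resampling
#' @return an [SFProfile-class] with `ciLow`/`ciHigh` filled in
#' @export
meanProfileWithCI <- function(profiles, nBoot = 10000L, seed = 0L) {
  if (!is.list(profiles) || length(profiles) < 2L)
    stop("need at least two profiles")
  centers <- profiles[[1L]]@binCenters
  for (p in profiles) {
    if (!identical(p@binCenters, centers))
      stop("profiles have mismatched bin geometry")
  }
  mat <- do.call(rbind, lapply(profiles, profileProportions))
  n <- nrow(mat)
  means <- colMeans(mat)
  bootMeans <- withSeed(seed, {
    idx <- matrix(sample.int(n, n * nBoot, replace = TRUE), nBoot, n)
    t(apply(idx, 1L, function(i) colMeans(mat[i, , drop = FALSE])))
  })
  ci <- apply(bootMeans, 2L, quantile, probs = c(0.025, 0.975), names = FALSE)
  new("SFProfile", binCenters = centers,
      proportions = means / sum(means),
      nPerturbations = as.integer(n),
      ciLow = ci[1L, ], ciHigh = ci[2L, ])
}

#' Per-band power-allocation shift relative to a baseline model
#'
#' For each octave band, computes the model's share of perturbation power in
#' the band minus the baseline model's share — the discrete area-under-curve
#' difference of the percent-power SF reliance spectra (Delta AUC). A
#' positive value in a band means the probed model concentrates more of its
#' decision-relevant sensitivity there than the baseline does. Band AUC is
#' the sum of the unit-width bin proportions whose centers fall in
#' `[lo, hi)`; because both profiles sum to 1, the shifts sum to 0 across a
#' partition that tiles the retained spectrum.
#'
#' @param modelProfile,baselineProfile [SFProfile-class] objects on the same
#'   bins
#' @param bands an [OctaveBands-class]
#' @param modelId label stored on the result
#' @return a [BandStats-class]
#' @export
bandDeltaAUC <- function(modelProfile, baselineProfile,
                         bands = octaveBands(), modelId = "model") {
  if (!identical(modelProfile@binCenters, baselineProfile@binCenters))
    stop("profiles have mismatched bin geometry")
  centers <- modelProfile@binCenters
  edges <- bands@edges
  nb <- length(bands@labels)
  delta <- vapply(seq_len(nb), function(b) {
    inBand <- centers >= edges[b] & centers < edges[b + 1L]
    sum(modelProfile@proportions[inBand]) -
      sum(baselineProfile@proportions[inBand])
  }, numeric(1))
  new("BandStats", bands = bands, deltaAUC = delta, modelId = modelId,
      ciLow = numeric(0), ciHigh = numeric(0))
}

#' @describeIn bandDeltaAUC per-band model-minus-baseline power shares
#' @param x a `BandStats`
#' @export
setMethod("deltaAUC", "BandStats", function(x) {
  stats::setNames(x@deltaAUC, x@bands@labels)
})

setMethod("show", "BandStats", function(object) {
  cat("BandStats for '", object@modelId, "':\n", sep = "")
  for (i in seq_along(object@deltaAUC))
    cat(sprintf("  %-14s %+0.4f\n", object@bands@labels[i],
                object@deltaAUC[i]))
})

# Average ranks (ties get the mean of the ranks they span).
avgRank <- function(x) rank(x, ties.method = "average")

# Spearman rho with average ranks; p two-sided. Exact permutation p supported
# for n <= 10 (enumeration in chunks); otherwise the large-sample t
# approximation t = rho * sqrt((n-2)/(1-rho^2)) on n - 2 df.
spearmanRho <- function(x, y, exact = FALSE) {
  n <- length(x)
  stopifnot(length(y) == n)
  rx <- avgRank(x); ry <- avgRank(y)
  rho <- cor(rx, ry)
  if (exact) {
    if (n > 10L)
      stop("exact permutation p-value supported for n <= 10 only")
    sx <- sd(rx); sy <- sd(ry)
    if (sx == 0 || sy == 0) return(list(rho = NA_real_, p = NA_real_))
    rhoOf <- function(Sperm)  # rho from sum(rx * ry[perm])
      (Sperm / n - mean(rx) * mean(ry)) * n / ((n - 1) * sx * sy)
    obs <- abs(rho)
    count <- 0; total <- 0
    # rows of a permutation matrix reorder ry; S_i = sum(rx * ry[perm_i])
    tally <- function(permIdx) {
      S <- as.vector(matrix(ry[permIdx], nrow(permIdx)) %*% rx)
      rhos <- rhoOf(S)
      count <<- count + sum(abs(rhos) >= obs - 1e-12)
      total <<- total + length(rhos)
    }
    if (n <= 8L) {
      tally(permuteAll(seq_len(n)))
    } else {
      # fix the first two slots and enumerate the rest in chunks, keeping
      # the working set small for n = 9, 10
      rest <- permuteAll(seq_len(n - 2L))
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i == j) next
        others <- setdiff(seq_len(n), c(i, j))
        tally(cbind(i, j, matrix(others[rest], nrow(rest))))
      }
    }
    return(list(rho = rho, p = count / total, method = "exact-permutation"))
  }
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    t <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(t), df = n - 2)
  }
  list(rho = rho, p = p, method = "t-approximation")
}

# All permutations of v as a matrix with one permutation per row.
permuteAll <- function(v) {
  n <- length(v)
  if (n == 1L) return(matrix(v, 1L))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    sub <- permuteAll(v[-i])
    out[[i]] <- cbind(v[i], sub)
  }
  do.call(rbind, out)
}

#' Correlate per-band power shifts with robustness gains across models
#'
#' Spearman rank correlation (average ranks for ties) between one band's
#' Delta-AUC values across a set of models and those models' robustness
#' improvements (differences in robust AUC vs the baseline). A strong
#' positive rho indicates that models relying more on the band tend to be
#' more robust. The two-sided p-value uses the large-sample t approximation
#' by default; `exact = TRUE` enumerates all permutations (n <= 10).
#'
#' @param deltaAucs numeric vector, one band Delta-AUC per model
#' @param robustnessGains numeric vector of robust-AUC improvements, same
#'   order
#' @param exact use the exact permutation null for the p-value
#' @return a [CorrelationResult-class]
#' @export
correlateBandWithRobustness <- function(deltaAucs, robustnessGains,
                                        exact = FALSE) {
  n <- length(deltaAucs)
  if (length(robustnessGains) != n)
    stop("vectors must have equal length")
  if (n < 3L) stop("need at least 3 models")
  res <- spearmanRho(deltaAucs, robustnessGains, exact = exact)
  new("CorrelationResult", rho = res$rho, pValue = res$p, n = as.integer(n),
      method = res$method)
}

setMethod("show", "CorrelationResult", function(object) {
  cat(sprintf("Spearman rho = %.4f, p = %.4g (n = %d, %s)\n",
              object@rho, object@pValue, object@n, object@method))
})

#' Export an SF profile as a data.frame
#'
#' @param profile an [SFProfile-class]
#' @return data.frame with `f_cpi`, `proportion`, and (when present)
#'   `ci_low`, `ci_high`
#' @export
profileAsDataFrame <- function(profile) {
  df <- data.frame(f_cpi = profile@binCenters,
                   proportion = profile@proportions)
  if (length(profile@ciLow)) {
    df$ci_low <- profile@ciLow
    df$ci_high <- profile@ciHigh
  }
  df
}
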