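# The spectral probe: power spectra, radial profiles, band statistics,
# and the rank correlation with robustness.

test_that("perturbation power spectra follow Fourier arithmetic", {
  size <- 32L
  zero <- array(0, c(size, size, 3))
  expect_equal(perturbationPowerSpectrum(zero),
               matrix(0, size, size))
  # single-channel pure cosine at axis frequency u0: power at (+-u0, 0)
  u0 <- 5L
  d <- array(0, c(size, size, 3))
  d[, , 1] <- cos(2 * pi * u0 * (seq_len(size) - 1) / size) %o%
    rep(1, size)
  P <- perturbationPowerSpectrum(d)
  hot <- order(P, decreasing = TRUE)[1:2]
  want <- c((u0 + 1) + size * 0, (size - u0 + 1) + size * 0)
  expect_setequal(hot, want)
  expect_gt(sum(P[hot]) / sum(P), 0.999)

  # Parseval oracle: total spectral power equals N * pixel energy per
  # channel, averaged over channels
  set.seed(1)
  rd <- array(rnorm(size^2 * 3), c(size, size, 3))
  Pr <- perturbationPowerSpectrum(rd)
  want <- size^2 * mean(apply(rd, 3, function(ch) sum(ch^2)))
  expect_equal(sum(Pr), want, tolerance = 1e-9)
})

test_that("radial profiles aggregate power by rounded radius", {
  size <- 32L
  g <- frequencyGrid(size, size)
  # pure 10 cpi sinusoid: >= 99% of the profile in the 10-cpi bin
  d <- array(0, c(size, size, 3))
  d[, , 2] <- cos(2 * pi * 10 * (seq_len(size) - 1) / size) %o% rep(1, size)
  prof <- radialProfile(perturbationPowerSpectrum(d), g)
  expect_gte(profileProportions(prof)[binCenters(prof) == 10], 0.99)
  expect_equal(sum(profileProportions(prof)), 1, tolerance = 1e-9)

  # brute-force binning oracle on a random spectrum
  set.seed(2)
  P <- matrix(rexp(size^2), size, size)
  prof2 <- radialProfile(P, g)
  r <- radialFreq(g)
  want <- vapply(1:16, function(k) {
    inBin <- r > 0 & r <= 16 & pmin(pmax(round(r), 1), 16) == k
    sum(P[inBin])
  }, numeric(1))
  expect_equal(profileProportions(prof2), want / sum(want),
               tolerance = 1e-8)
  # DC and corner coefficients are excluded: retained power accounts for
  # exactly the coefficients with 0 < r <= Nyquist
  expect_equal(sum(want), sum(P[r > 0 & r <= 16]))
  # coefficient bookkeeping: DC + retained + excluded corners = all
  expect_equal(1L + sum(r > 0 & r <= 16) + sum(r > 16), length(r))

  expect_error(radialProfile(matrix(0, size, size), g), "all-zero")
})

test_that("white-noise profiles follow per-bin coefficient counts", {
  size <- 32L
  g <- frequencyGrid(size, size)
  set.seed(3)
  acc <- numeric(16)
  nDraw <- 60
  for (i in seq_len(nDraw)) {
    d <- array(rnorm(size^2 * 3), c(size, size, 3))
    acc <- acc + profileProportions(radialProfile(
      perturbationPowerSpectrum(d), g))
  }
  meanProp <- acc / nDraw
  r <- radialFreq(g)
  counts <- vapply(1:16, function(k)
    sum(r > 0 & r <= 16 & pmin(pmax(round(r), 1), 16) == k), numeric(1))
  expect_gt(cor(meanProp, counts / sum(counts)), 0.99)
})

test_that("mean profiles carry bootstrap intervals with sane endpoints", {
  size <- 16L
  g <- frequencyGrid(size, size)
  set.seed(4)
  mk <- function() radialProfile(perturbationPowerSpectrum(
    array(rnorm(size^2 * 3), c(size, size, 3))), g)
  # identical profiles: zero-width intervals
  p1 <- mk()
  same <- meanProfileWithCI(list(p1, p1, p1), nBoot = 200, seed = 1)
  expect_equal(same@ciLow, profileProportions(same), tolerance = 1e-12)
  expect_equal(same@ciHigh, profileProportions(same), tolerance = 1e-12)

  # two-profile set: bootstrap means can only be the three resample
  # averages; verify against exhaustive enumeration
  p2 <- mk()
  mp <- meanProfileWithCI(list(p1, p2), nBoot = 400, seed = 2)
  a <- profileProportions(p1); b <- profileProportions(p2)
  possible <- rbind(a, (a + b) / 2, b)
  binIdx <- 3L
  bootVals <- withr::with_seed(2, {
    idx <- matrix(sample.int(2, 2 * 400, replace = TRUE), 400, 2)
    apply(idx, 1, function(i) mean(c(a[binIdx], b[binIdx])[i]))
  })
  expect_true(all(bootVals %in% possible[, binIdx]))
  expect_true(mp@ciLow[binIdx] >= min(possible[, binIdx]) - 1e-12)
  expect_true(mp@ciHigh[binIdx] <= max(possible[, binIdx]) + 1e-12)
  expect_equal(profileProportions(mp), (a + b) / 2, tolerance = 1e-9)

  expect_error(meanProfileWithCI(list(p1)), "at least two")
})

test_that("band delta-AUC measures power-share shifts and sums to zero", {
  g <- frequencyGrid(64, 64)
  bands <- octaveBands(nyquist = 32)
  set.seed(5)
  mk <- function(d) radialProfile(perturbationPowerSpectrum(d), g)
  d1 <- array(rnorm(64^2 * 3), c(64, 64, 3))
  p1 <- mk(d1)
  # model == baseline: all zero
  bs0 <- bandDeltaAUC(p1, p1, bands)
  expect_equal(unname(deltaAUC(bs0)), rep(0, 6))

  # concentrated profile vs broadband baseline: hand-computed shift
  conc <- array(0, c(64, 64, 3))
  conc[, , 1] <- cos(2 * pi * 10 * (seq_len(64) - 1) / 64) %o% rep(1, 64)
  pc <- mk(conc)        # all power in the [8, 16) octave
  bsc <- bandDeltaAUC(pc, p1, bands)
  inBand <- binCenters(p1) >= 8 & binCenters(p1) < 16
  want <- sum(profileProportions(pc)[inBand]) -
    sum(profileProportions(p1)[inBand])
  expect_equal(unname(deltaAUC(bsc)["human_channel"]), want,
               tolerance = 1e-12)
  expect_gt(want, 0.7)  # all of the model's power is in that octave; the
                        # broadband baseline holds only its count share

  # the shifts sum to 0 when all retained power lies strictly below the
  # Nyquist bin (the top band is half-open, so the Nyquist bin itself is
  # outside the partition)
  belowNyq <- function(d) {
    sp <- perturbationPowerSpectrum(d)
    sp[radialFreq(g) > 31.5] <- 0
    radialProfile(sp, g)
  }
  pb1 <- belowNyq(d1)
  pb2 <- belowNyq(array(rnorm(64^2 * 3), c(64, 64, 3)))
  expect_equal(sum(deltaAUC(bandDeltaAUC(pb2, pb1, bands))), 0,
               tolerance = 1e-9)

  pShort <- radialProfile(perturbationPowerSpectrum(
    array(rnorm(16^2 * 3), c(16, 16, 3))), frequencyGrid(16, 16))
  expect_error(bandDeltaAUC(pShort, p1, bands), "mismatched")
})

test_that("Spearman correlation matches rank-then-Pearson and cor.test", {
  up <- correlateBandWithRobustness(1:8, (1:8)^3)
  expect_equal(up@rho, 1)
  down <- correlateBandWithRobustness(1:8, -(1:8))
  expect_equal(down@rho, -1)

  set.seed(6)
  x <- rnorm(10); y <- 0.5 * x + rnorm(10)
  got <- correlateBandWithRobustness(x, y)
  # brute-force oracle: Pearson formula applied to ranks by explicit sums
  rx <- rank(x); ry <- rank(y)
  n <- 10
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(got@rho, num / den, tolerance = 1e-12)
  # independent cross-check against stats::cor.test
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(got@rho, unname(ct$estimate), tolerance = 1e-12)
  tstat <- got@rho * sqrt((n - 2) / (1 - got@rho^2))
  expect_equal(got@pValue, 2 * pt(-abs(tstat), n - 2), tolerance = 1e-12)

  # exact permutation p agrees with cor.test's exact p for small n
  x7 <- c(3, 1, 4, 1.5, 9, 2.6, 5.3)
  y7 <- c(2, 7, 1, 8, 2.8, 1.8, 2.9)
  ex <- correlateBandWithRobustness(x7, y7, exact = TRUE)
  ctEx <- cor.test(x7, y7, method = "spearman", exact = TRUE)
  expect_equal(ex@pValue, ctEx$p.value, tolerance = 1e-12)
  expect_equal(ex@method, "exact-permutation")

  expect_error(correlateBandWithRobustness(1:2, 1:2), "at least 3")
  expect_error(correlateBandWithRobustness(1:4, 1:5), "equal length")
})

test_that("ties get average ranks in the correlation", {
  x <- c(1, 1, 2, 3, 3, 4)
  y <- c(2, 2, 3, 5, 5, 7)
  got <- correlateBandWithRobustness(x, y)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(got@rho, unname(ct$estimate), tolerance = 1e-12)
})
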