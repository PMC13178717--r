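# Frequency geometry and the spatial-frequency mask families.

test_that("frequency grid geometry matches signed-index arithmetic", {
  g <- frequencyGrid(224, 224)
  expect_equal(nyquistCpi(g), 112)
  expect_equal(radialFreq(g)[1, 1], 0)

  g2 <- frequencyGrid(2, 2)
  expect_equal(sort(as.vector(radialFreq(g2))), c(0, 1, 1, sqrt(2)))

  # brute-force signed-index oracle on 8x8
  g8 <- frequencyGrid(8, 8)
  idx <- function(k, n) if (k - 1 <= n %/% 2) k - 1 else k - 1 - n
  oracle <- matrix(0, 8, 8)
  for (i in 1:8) for (j in 1:8)
    oracle[i, j] <- sqrt(idx(i, 8)^2 + idx(j, 8)^2)
  expect_equal(radialFreq(g8), oracle)

  # symmetry under (u,v) -> (-u,-v): mirrored layout equals original
  r <- radialFreq(g8)
  neg <- c(1, 8:2)
  expect_equal(r, r[neg, neg])

  expect_error(frequencyGrid(1, 16), "must be integers >= 2")
  expect_error(frequencyGrid(-4, 16))
})

test_that("octave bands tile (0, Nyquist) with doubling edges", {
  b <- octaveBands()
  expect_equal(bandEdges(b), c(0, 3.5, 7, 14, 28, 56, 112))
  e <- bandEdges(b)
  # every band above 3.5 cpi spans exactly one octave
  expect_equal(e[3:7] / e[2:6], rep(2, 5))
  # the human channel is the [28, 56) band
  hc <- which(bandLabels(b) == "human_channel")
  expect_equal(e[hc], 28)
  expect_equal(e[hc + 1], 56)
  # proportional rescaling to a 64-pixel grid
  b64 <- octaveBands(nyquist = 32)
  expect_equal(bandEdges(b64), c(0, 1, 2, 4, 8, 16, 32))
})

test_that("Gaussian log-frequency mask has the stated peak and rolloff", {
  g <- frequencyGrid(224, 224)
  m <- gaussianLogFreqMask(g, mu = 4.5, sigma = 0.4246)
  r <- radialFreq(g)
  w <- maskWeights(m)
  # unit peak at the center frequency 2^4.5 ~ 22.6 cpi
  expect_equal(max(w[r > 0]), 1)
  peakR <- r[r > 0][which.max(w[r > 0])]
  expect_lt(abs(log2(peakR) - 4.5), 0.05)
  # one-sigma point: weight exp(-1/2) relative to peak
  onesig <- 2^(4.5 + 0.4246)
  i <- which(abs(r - onesig) == min(abs(r - onesig)))[1]
  gaussAt <- function(f) exp(-(log2(f) - 4.5)^2 / (2 * 0.4246^2))
  expect_equal(w[i], gaussAt(r[i]), tolerance = 1e-10)
  expect_equal(gaussAt(onesig), exp(-1 / 2), tolerance = 1e-12)
  # DC policy: band-pass excludes DC
  expect_equal(w[1, 1], 0)
  expect_error(gaussianLogFreqMask(g, sigma = 0), "> 0")
})

test_that("extreme-LSF hard pass keeps everything at or below the center", {
  g <- frequencyGrid(224, 224)
  mu <- log2(sqrt(1.75 * 3.5))
  m <- gaussianLogFreqMask(g, mu = mu, hardPassBelowCenter = TRUE)
  r <- radialFreq(g)
  w <- maskWeights(m)
  low <- r > 0 & r <= 2^mu
  expect_true(all(w[low] == 1))
  expect_equal(w[1, 1], 1)  # low-pass style mask keeps DC
  # above the center the Gaussian rolloff applies
  expect_true(all(w[r > 2^mu] < 1))
})

test_that("masks are radially symmetric", {
  g <- frequencyGrid(32, 32)
  spreadOf <- function(m) {
    w <- maskWeights(m)
    r <- round(radialFreq(g), 9)
    max(tapply(as.vector(w), as.vector(r), function(v) diff(range(v))))
  }
  # analytic log-frequency masks are exactly radial
  expect_lt(spreadOf(gaussianLogFreqMask(g, mu = 3, sigma = 0.5)), 1e-9)
  expect_lt(spreadOf(conditionMask(g, "extreme_lsf")), 1e-9)
  # blur-derived masks are radial up to the square truncation of the
  # discretized kernel
  expect_lt(spreadOf(blurMagnitudeMask(g, 1.5)), 1e-3)
})

test_that("blur-magnitude mask matches a direct-summation DFT oracle", {
  g <- frequencyGrid(32, 32)
  sigma <- 1.5
  m <- blurMagnitudeMask(g, sigma)
  w <- maskWeights(m)
  expect_equal(w[1, 1], 1)  # low-pass peak at DC
  # rebuild the truncated kernel exactly as documented and evaluate its DFT
  # by direct summation at a few coefficients
  R <- ceiling(4 * sigma)
  off <- (-R):R
  k <- exp(-outer(off^2, off^2, `+`) / (2 * sigma^2))
  k <- k / sum(k)
  padded <- matrix(0, 32, 32)
  padded[((off %% 32)) + 1, ((off %% 32)) + 1] <- k
  dc <- Mod(directDFT(padded, 0, 0))
  for (uv in list(c(1, 0), c(3, 2), c(8, 8), c(15, 0))) {
    want <- Mod(directDFT(padded, uv[1], uv[2])) / dc
    got <- w[uv[1] + 1, uv[2] + 1]
    expect_equal(got, want, tolerance = 1e-8)
  }
  # near-delta kernel: all-pass
  tiny <- blurMagnitudeMask(g, 1e-4)
  expect_true(all(maskWeights(tiny) > 1 - 1e-6))
  expect_error(blurMagnitudeMask(g, 0), "> 0")
})

test_that("mixed-sigma distributions reproduce the printed tables", {
  weak <- mixedSigmaPolicy("weak")
  expect_equal(weak$sigmas, c(1, 2, 3, 4, 5))
  expect_equal(weak$probs, c(0.2129, 0.0653, 0.0200, 0.0062, 0.0019))
  expect_equal(weak$residualProb, 1 - sum(weak$probs))
  strong <- mixedSigmaPolicy("strong")
  expect_equal(strong$sigmas, c(1, 2, 4, 8))
  expect_equal(strong$probs, rep(0.2, 4))
  expect_error(mixedSigmaPolicy("medium"))

  # empirical sampling frequencies within 3 standard errors
  set.seed(42)
  n <- 1e5
  draws <- sample(c(weak$sigmas, 0), n, replace = TRUE,
                  prob = c(weak$probs, weak$residualProb))
  for (i in seq_along(weak$sigmas)) {
    p <- weak$probs[i]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(draws == weak$sigmas[i]) - p), 3 * se)
  }
})

test_that("mask inversion is exact and involutive", {
  g <- frequencyGrid(64, 64)
  m <- conditionMask(g, "human_channel")
  inv <- invertMask(m)
  expect_identical(maskWeights(inv), 1 - maskWeights(m))
  # double inversion recovers the mask (up to rounding of 1 - (1 - w) for
  # weights near the double-precision floor)
  expect_equal(maskWeights(invertMask(inv)), maskWeights(m),
               tolerance = 1e-12)
  expect_equal(maskCondition(inv), "inverse_human_channel")
  # the inverse has weight 0 where the original peaked
  r <- radialFreq(g)
  peak <- which(maskWeights(m) == 1 & r > 0)
  expect_true(all(maskWeights(inv)[peak] == 0))
  # all-ones mask inverts to all-zeros
  ones <- m
  ones@weights[] <- 1
  expect_true(all(maskWeights(invertMask(ones)) == 0))
  # a numerically-zero band-pass (center far outside the grid) is rejected
  expect_error(gaussianLogFreqMask(g, mu = 20, sigma = 0.1),
               "resolvable frequency range")
})

test_that("mask response curves export one weight per radius", {
  g <- frequencyGrid(32, 32)
  m <- conditionMask(g, "fixed_sigma_lsf")
  df <- maskResponseCurve(m, g)
  expect_true(all(c("f_cpi", "weight") %in% names(df)))
  expect_equal(df$weight[df$f_cpi == 0], 1)
  expect_true(all(diff(df$f_cpi) > 0))
})
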