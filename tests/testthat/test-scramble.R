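# Soft phase scrambling, filtering, phase fields, and augmentation policies.

allPassMask <- function(size) {
  m <- gaussianLogFreqMask(frequencyGrid(size, size), mu = 0, sigma = 1,
                           dcWeight = 1)
  m@weights[] <- 1
  m
}

zeroMask <- function(size, dc = 0) {
  m <- allPassMask(size)
  m@weights[] <- 0
  m@weights[1, 1] <- dc
  m@unitPeak <- FALSE
  m
}

test_that("M = 1 scrambling reproduces the input", {
  img <- randomImage(32, seed = 1)
  out <- phaseScramble(img, allPassMask(32), seed = 3)
  expect_lt(max(abs(out - img)), 1e-6)
})

test_that("M = 0 with the original phases as the random field is identity", {
  img <- randomImage(32, seed = 2)
  phi <- Arg(fft(img[, , 1]))
  # feed channel-1 phases back; only channel 1 must reproduce exactly
  out <- phaseScramble(img, zeroMask(32), phaseField = phi, clip = "none")
  expect_lt(max(abs(out[, , 1] - img[, , 1])), 1e-6)
})

test_that("soft blend matches a coefficientwise complex-arithmetic oracle", {
  size <- 16L
  img <- randomImage(size, seed = 4)
  g <- frequencyGrid(size, size)
  phi_r <- samplePhaseField(g, seed = 9)
  m <- allPassMask(size)
  m@weights[] <- 0.5
  m@unitPeak <- FALSE
  out <- phaseScramble(img, m, phaseField = phi_r, clip = "none")
  for (c in 1:3) {
    F <- fft(img[, , c])
    # independent oracle: midpoint of the two unit phasors, original
    # amplitude, DC phase kept
    zmid <- 0.5 * exp(1i * Arg(F)) + 0.5 * exp(1i * phi_r)
    phiNew <- Arg(zmid)
    phiNew[Mod(zmid) < 1e-12] <- Arg(F)[Mod(zmid) < 1e-12]
    phiNew[1, 1] <- Arg(F)[1, 1]
    want <- Re(fft(Mod(F) * exp(1i * phiNew), inverse = TRUE)) / size^2
    expect_equal(out[, , c], want, tolerance = 1e-10)
  }
})

test_that("phase scrambling preserves amplitude spectra and energy", {
  set.seed(11)
  g <- frequencyGrid(64, 64)
  masks <- list(conditionMask(g, "human_channel"),
                conditionMask(g, "extreme_lsf"),
                conditionMask(g, "fixed_sigma_lsf"),
                conditionMask(g, "inverse_human"),
                blurMagnitudeMask(g, 4))
  for (m in masks) {
    img <- randomImage(64)
    out <- phaseScramble(img, m, seed = 5, clip = "none")
    for (c in 1:3) {
      A0 <- Mod(fft(img[, , c]))
      A1 <- Mod(fft(out[, , c]))
      expect_lt(max(abs(A1 - A0)) / max(A0), 1e-6)
      # Parseval: pixel-domain energy preserved pre-clip
      expect_equal(sum(out[, , c]^2), sum(img[, , c]^2), tolerance = 1e-9)
    }
  }
})

test_that("scrambled output is real and clipped output stays in range", {
  img <- randomImage(48, seed = 6)
  m <- conditionMask(frequencyGrid(48, 48), "extreme_lsf")
  out <- phaseScramble(img, m, seed = 7)  # default clamp
  expect_true(all(out >= 0 & out <= 1))
  soft <- phaseScramble(img, m, seed = 7, clip = "tanh")
  expect_true(all(soft >= 0 & soft <= 1))
})

test_that("phase scrambling validates its inputs", {
  img <- randomImage(32, seed = 8)
  mWrong <- allPassMask(16)
  expect_error(phaseScramble(img, mWrong), "does not match")
  badPhase <- matrix(runif(32 * 32, -pi, pi), 32, 32)
  expect_error(phaseScramble(img, allPassMask(32), phaseField = badPhase),
               "Hermitian")
})

test_that("phase fields are seeded, Hermitian, and uniform", {
  g <- frequencyGrid(64, 64)
  f1 <- samplePhaseField(g, seed = 123)
  f2 <- samplePhaseField(g, seed = 123)
  expect_identical(f1, f2)
  expect_true(sfreliance:::checkHermitianPhase(f1))
  # self-conjugate coefficients carry phase 0 or pi
  selfconj <- c(f1[1, 1], f1[1, 33], f1[33, 1], f1[33, 33])
  expect_true(all(abs(sin(selfconj)) < 1e-12))

  # Kolmogorov-Smirnov uniformity on (-pi, pi] over ~1e5 phases from a
  # half-plane (excluding the mirrored copies, which are dependent)
  big <- samplePhaseField(frequencyGrid(450, 450), seed = 77)
  half <- big[, 2:225]
  ks <- suppressWarnings(ks.test(as.vector(half), "punif", -pi, pi))
  expect_gt(ks$p.value, 0.01)
})

test_that("filtering multiplies coefficients and loses out-of-band energy", {
  size <- 32L
  img <- randomImage(size, seed = 10)
  expect_lt(max(abs(filterAugment(img, allPassMask(size)) - img)), 1e-6)
  # DC-only mask yields the constant channel means
  out <- filterAugment(img, zeroMask(size, dc = 1))
  for (c in 1:3)
    expect_equal(out[, , c],
                 matrix(mean(img[, , c]), size, size), tolerance = 1e-9)
  # single-coefficient oracle: a pure sinusoid attenuated by the mask weight
  g <- frequencyGrid(size, size)
  u0 <- 10
  xs <- outer(rep(1, size), seq_len(size) - 1)
  cosimg <- array(0.5 + 0.25 * cos(2 * pi * u0 * t(xs) / size),
                  c(size, size, 3))
  m <- blurMagnitudeMask(g, 0.8)  # soft low-pass, partial attenuation at u0
  wAt <- maskWeights(m)[u0 + 1, 1]
  filt <- filterAugment(cosimg, m, clip = "none")
  ac0 <- cosimg[, , 1] - mean(cosimg[, , 1])
  ac1 <- filt[, , 1] - mean(filt[, , 1])
  expect_equal(sum(ac1^2) / sum(ac0^2), wAt^2, tolerance = 1e-6)
})

test_that("augmentation policies replace the right fraction of a batch", {
  g <- frequencyGrid(16, 16)
  mask <- conditionMask(g, "extreme_lsf")
  batch <- lapply(1:50, function(i) randomImage(16, seed = 100 + i))
  same <- applyPolicy(batch, augmentationPolicy(0, list(mask)), seed = 1)
  expect_identical(unclass(same)[seq_along(batch)], batch)
  expect_false(any(attr(same, "replaced")))

  all <- applyPolicy(batch, augmentationPolicy(1, mask), seed = 2)
  expect_true(all(attr(all, "replaced")))
  # amplitude spectra preserved for every replaced image
  for (i in c(1, 25, 50)) {
    A0 <- Mod(fft(batch[[i]][, , 1]))
    A1 <- Mod(fft(all[[i]][, , 1]))
    # clamp can nudge amplitudes; compare at a loose tolerance
    expect_lt(max(abs(A1 - A0)) / max(A0), 0.05)
  }

  # binomial check at p = 0.5 over many small images
  nbig <- 2000L
  tiny <- lapply(seq_len(nbig), function(i)
    array(0.5, c(16, 16, 3)))
  pol <- augmentationPolicy(0.5, mask)
  res <- applyPolicy(tiny, pol, seed = 3)
  frac <- mean(attr(res, "replaced"))
  se <- sqrt(0.25 / nbig)
  expect_lt(abs(frac - 0.5), 3 * se)
})

test_that("mixed-sigma policies carry the printed mask mixture", {
  g <- frequencyGrid(16, 16)
  polW <- mixedSigmaAugmentation(g, "weak")
  expect_equal(polW@replaceProb, sum(c(0.2129, 0.0653, 0.02, 0.0062, 0.0019)))
  expect_equal(length(polW@masks), 5L)
  expect_equal(sum(polW@maskProbs), 1)
  polS <- mixedSigmaAugmentation(g, "strong")
  expect_equal(polS@replaceProb, 0.8)
  expect_equal(polS@maskProbs, rep(0.25, 4))
})

test_that("the scramble pipeline is bit-reproducible under a seed", {
  batch <- lapply(1:5, function(i) randomImage(16, seed = 200 + i))
  pol <- augmentationPolicy(0.7, conditionMask(frequencyGrid(16, 16),
                                               "human_channel"))
  a <- applyPolicy(batch, pol, seed = 99)
  b <- applyPolicy(batch, pol, seed = 99)
  expect_identical(a, b)
})
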