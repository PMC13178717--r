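# Shared fixtures, built lazily and cached for the session so expensive
# objects (trained models) are constructed once across test files.

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixtureCache)) {
    assign(key, force(expr), envir = .fixtureCache)
  }
  get(key, envir = .fixtureCache)
}

randomImage <- function(size = 32L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(runif(size * size * 3L), c(size, size, 3L))
}

# A trained fixture model on mid-band data plus its splits; used by the
# attack, robustness, and RSA tests.
midBandFixture <- function() {
  cached("midBandFixture", {
    cfg <- experimentConfig()
    ds <- generateBandCodedDataset(band = c(8, 16), seed = 5L,
                                   imagesPerClass = 125L)
    sp <- splitDataset(ds, 100L)
    fit <- trainModel(cfg, sp$train$images, sp$train$labels, seed = 11L)
    list(cfg = cfg, ds = ds, split = sp, fit = fit)
  })
}

# An independently initialized second model on the same data (RSA tests).
midBandFixtureB <- function() {
  cached("midBandFixtureB", {
    fx <- midBandFixture()
    trainModel(fx$cfg, fx$split$train$images, fx$split$train$labels,
               seed = 22L)
  })
}

# Independent direct-summation 2-D DFT magnitude at one frequency index pair
# (u, v are signed integers); oracle for blur-mask and spectrum tests.
directDFT <- function(x, u, v) {
  h <- nrow(x); w <- ncol(x)
  i <- (seq_len(h) - 1L); j <- (seq_len(w) - 1L)
  ph <- outer(i * u / h, j * v / w, `+`)
  sum(x * exp(-2i * pi * ph))
}
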