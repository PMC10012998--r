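test_that("a pure tone maps to a single spectral peak in every pixel", {
  t <- seq(0, 10 - 0.002, by = 0.002) * 1000
  tr <- sin(2 * pi * 1 * t / 1000)
  mv <- opticalMovie(array(rep(tr, each = 9), c(3, 3, length(tr))))
  fs <- ffiTransform(mv, detrend = FALSE)
  b1 <- which.min(abs(freqAxis(fs) - 1))
  expect_equal(freqAxis(fs)[b1], 1)
  for (i in 1:3) for (j in 1:3) {
    a <- fs@amplitude[i, j, ]
    expect_equal(which.max(a), b1)
    expect_lt(max(a[-b1]) / a[b1], 1e-9)
  }
  ## constant movie: no non-DC content
  mc <- opticalMovie(array(2, c(2, 2, 500)))
  fc <- ffiTransform(mc, detrend = FALSE)
  expect_lt(max(fc@amplitude[, , -1]), 1e-9)
})

test_that("the windowed transform satisfies Parseval's identity", {
  set.seed(11)
  tr <- rnorm(400)
  mv <- opticalMovie(array(rep(tr, each = 4), c(2, 2, 400)))
  fs <- ffiTransform(mv, detrend = FALSE)
  a <- fs@amplitude[1, 1, ]
  n <- 400
  ## recompose the two-sided energy from the one-sided stack
  twoSided <- a[1]^2 + a[n / 2 + 1]^2 + 2 * sum(a[2:(n / 2)]^2)
  expect_equal(twoSided, n * sum(tr^2), tolerance = 1e-9)
})

test_that("amplitude scales with gain while phase is invariant", {
  t <- seq(0, 4 - 0.002, by = 0.002) * 1000
  tr <- cos(2 * pi * 2.5 * t / 1000 + 0.7)
  m1 <- opticalMovie(array(tr, c(1, 1, length(tr))))
  m2 <- opticalMovie(array(5 * tr, c(1, 1, length(tr))))
  f1 <- ffiTransform(m1, detrend = FALSE)
  f2 <- ffiTransform(m2, detrend = FALSE)
  b <- which.min(abs(freqAxis(f1) - 2.5))
  expect_equal(f2@amplitude[1, 1, b], 5 * f1@amplitude[1, 1, b])
  expect_equal(f2@phase[1, 1, b], f1@phase[1, 1, b], tolerance = 1e-9)
})

test_that("bin selection stays within half the frequency resolution", {
  mv <- opticalMovie(array(rnorm(4 * 1000), c(2, 2, 1000)))
  fs <- ffiTransform(mv)
  windowS <- 1000 * 2 / 1000
  for (f in c(0.5, 1.23, 4, 7.77)) {
    m <- extractFrequencyMap(fs, f)
    expect_lte(abs(m$freq - f), 0.5 / windowS + 1e-12)
  }
  expect_error(extractFrequencyMap(fs, 1000), "Nyquist")
  expect_error(ffiTransform(mv, window = c(1, 2000)), "window")
})

test_that("frequency-series maps show the subharmonic ridge only for alternating movies", {
  mk <- function(fp, pattern, d = 15) {
    tr <- generateAPTrain(rhythmSpec(fp, pattern, apdBase = 90, d = d),
                          duration = 8, seed = 21)
    opticalMovie(array(rep(tr, each = 16), c(4, 4, length(tr))))
  }
  movies <- list(mk(6, "one_to_one"), mk(8, "two_two"))
  fsm <- buildFrequencySeries(movies, fp = c(6, 8))
  ridge <- function(row, f, m = fsm) max(m$map[row, abs(m$freq - f) <= 0.15])
  ## fundamental ridge in both columns
  expect_gt(ridge(1, 6), 0.9)
  expect_gt(ridge(2, 8), 0.9)
  ## subharmonic ridge only for the 2:2 column
  expect_lt(ridge(1, 3), 0.05)
  expect_gt(ridge(2, 4), 0.1)
  ## a broadband column has an elevated baseline and no discrete ridge
  bb <- mk(8, "broadband")
  fsb <- buildFrequencySeries(list(movies[[2]], bb), fp = c(8, 8.2))
  off <- fsb$freq > 2 & fsb$freq < 12
  expect_gt(median(fsb$map[2, off]), 5 * median(fsb$map[1, off]))
  expect_error(buildFrequencySeries(movies[1], fp = 6), "length")
  expect_error(buildFrequencySeries(movies, fp = c(6, 8),
                                    roi = matrix(FALSE, 4, 4)), "ROI")
})

test_that("rhythms classify from their spectral peak structure", {
  cls <- function(fp, pattern, ...) {
    tr <- generateAPTrain(rhythmSpec(fp, pattern, ...), duration = 10,
                          seed = 9)
    sp <- refSpectrum(tr)
    classifyRhythm(sp$amp, sp$freq, fp)
  }
  expect_equal(cls(3.2, "one_to_one", apdBase = 180)$label, "one_to_one")
  c22 <- cls(8.5, "two_two", apdBase = 85, d = 15)
  expect_equal(c22$label, "two_two")
  expect_equal(c22$fHalfFreqs, 4.25, tolerance = 0.06)
  c44 <- cls(8, "four_four", apdBase = 85, d1 = 18, d2 = 8)
  expect_equal(c44$label, "four_four")
  ## white noise classifies as fibrillation (and warns about entrainment)
  set.seed(4)
  spn <- refSpectrum(rnorm(5000))
  expect_warning(cn <- classifyRhythm(spn$amp, spn$freq, 8), "entrainment")
  expect_equal(cn$label, "fibrillation")
})

test_that("the ultrastructure field is recovered and pacing-site invariant", {
  g <- generateUltrastructureField(32, 32, correlationLength = 8,
                                   cv = 0.2, seed = 13)
  mvA <- generateMovie(uniformScene(nx = 32, ultrastructure = g,
                                    stimEdge = "top", seed = 5))
  mvB <- generateMovie(uniformScene(nx = 32, ultrastructure = g,
                                    stimEdge = "left", seed = 6))
  a05A <- extractUltrastructure(mvA)
  a05B <- extractUltrastructure(mvB)
  expect_gt(cor(as.vector(a05A), as.vector(g)), 0.9)
  expect_gt(cor(as.vector(a05A), as.vector(a05B)), 0.9)
  ## uniform baseline: relative dispersion at the noise floor
  mvU <- generateMovie(uniformScene(nx = 16, seed = 8, noiseSigma = 0.005))
  a05U <- extractUltrastructure(mvU)
  expect_lt(sd(a05U) / mean(a05U), 0.05)
  ## resolution guard
  short <- generateMovie(uniformScene(nx = 8, duration = 2, seed = 2))
  expect_error(extractUltrastructure(short), "window too short")
})
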