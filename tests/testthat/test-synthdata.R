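test_that("1:1 trains carry no subharmonic content", {
  tr <- generateAPTrain(rhythmSpec(3.2, "one_to_one", apdBase = 180),
                        duration = 10)
  sp <- refSpectrum(tr)
  pk <- function(f) sp$amp[which.min(abs(sp$freq - f))]
  expect_lt(pk(1.6), 0.01 * pk(3.2))
})

test_that("2:2 trains alternate with the designed APD amplitude", {
  tr <- generateAPTrain(rhythmSpec(5, "two_two", apdBase = 120, d = 20),
                        duration = 6)
  s <- extractAPDSequence(tr, frameInterval = 2)
  a <- apd(s)
  expect_gt(length(a), 20)
  expect_equal(a[seq(1, 20, 2)], rep(140, 10), tolerance = 2 / 140)
  expect_equal(a[seq(2, 20, 2)], rep(100, 10), tolerance = 2 / 100)
  ## the antiphase variant starts on the short beat instead
  tr2 <- generateAPTrain(rhythmSpec(5, "two_two", apdBase = 120, d = 20,
                                    phase = pi), duration = 6)
  a2 <- apd(extractAPDSequence(tr2, frameInterval = 2))
  expect_equal(a2[1], 100, tolerance = 2 / 100)
})

test_that("4:4 trains put spectral lines at quarter multiples with f_p/2 dominant", {
  fp <- 8
  tr <- generateAPTrain(rhythmSpec(fp, "four_four", apdBase = 85,
                                   d1 = 18, d2 = 8), duration = 10)
  sp <- refSpectrum(tr)
  pk <- function(f) sp$amp[which.min(abs(sp$freq - f))]
  lines <- c(pk(fp / 4), pk(fp / 2), pk(3 * fp / 4))
  base <- median(sp$amp[sp$freq > 0.5 & sp$freq < fp])
  expect_true(all(lines > 10 * base))
  expect_equal(which.max(lines), 2L)
})

test_that("the ultrastructure field has unit mean and the designed correlation length", {
  g <- generateUltrastructureField(64, 64, correlationLength = 10,
                                   cv = 0.15, seed = 4)
  expect_equal(mean(g), 1, tolerance = 1e-6)
  expect_true(all(g > 0))
  expect_equal(sd(g) / mean(g), 0.15, tolerance = 0.5)
  ## autocorrelation half-width along rows
  ac <- function(lag) {
    a <- as.vector(g[1:(64 - lag), ]); b <- as.vector(g[(1 + lag):64, ])
    cor(a, b)
  }
  lags <- 1:20
  acv <- vapply(lags, ac, 0)
  half <- lags[which(acv < 0.5)[1]]
  expect_gte(half, 7)
  expect_lte(half, 13)
  ## determinism
  g2 <- generateUltrastructureField(64, 64, correlationLength = 10,
                                    cv = 0.15, seed = 4)
  expect_identical(g, g2)
})

test_that("movie generation is deterministic and background pixels hold noise only", {
  mask <- matrix(FALSE, 16, 16); mask[4:13, 4:13] <- TRUE
  sc <- sceneSpec(nx = 16, ny = 16, duration = 3, mask = mask,
                  regionMap = matrix(as.integer(mask), 16, 16),
                  rhythms = list(rhythmSpec(4, apdBase = 150)),
                  noiseSigma = 0.02, seed = 11)
  m1 <- generateMovie(sc)
  m2 <- generateMovie(sc)
  expect_identical(frames(m1), frames(m2))
  bg <- frames(m1)[1, 1, ]
  expect_lt(diff(range(bg)), 0.25)        # noise-only excursion
  fg <- frames(m1)[8, 8, ]
  expect_gt(diff(range(fg)), 0.5)         # full AP excursion
})

test_that("generated movies pass through the analyzers they are built for", {
  sc <- daScene(nx = 32, duration = 6)
  mv <- generateMovie(sc)
  expect_s4_class(mv, "OpticalMovie")
  expect_true(validObject(mv))
  ## single-region 1:1 movie: label none, nodal fraction near 1
  m1 <- generateMovie(uniformScene(nx = 16, seed = 9))
  dm <- classifyPattern(deltaAPDMap(preprocessMovie(m1)))
  expect_equal(patternLabel(dm), "none")
  ok <- !is.na(deltaAPD(dm))
  expect_gt(mean(nodalMask(dm)[ok]), 0.95)
})
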