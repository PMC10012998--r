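test_that("the SNR mask recovers a tissue polygon from a noisy movie", {
  nx <- 32
  mask <- matrix(FALSE, nx, nx)
  mask[6:27, 4:30] <- TRUE
  mask[12:15, 10:14] <- FALSE       # an interior hole, to be filled
  sc <- sceneSpec(nx = nx, ny = nx, duration = 4, mask = mask,
                  regionMap = matrix(as.integer(mask), nx, nx),
                  rhythms = list(rhythmSpec(4, apdBase = 150)),
                  noiseSigma = 0.03, seed = 17)
  mv <- generateMovie(sc)
  est <- computeTissueMask(mv)
  truth <- matrix(FALSE, nx, nx); truth[6:27, 4:30] <- TRUE
  jaccard <- sum(est & truth) / sum(est | truth)
  expect_gt(jaccard, 0.95)
  ## the enclosed hole is filled
  expect_true(all(est[12:15, 10:14]))
  ## pure noise: no pixel qualifies
  noise <- opticalMovie(array(rnorm(16 * 16 * 600, sd = 0.05),
                              c(16, 16, 600)))
  expect_error(computeTissueMask(noise), "empty tissue mask")
  ## noiseless full-frame signal covers the frame
  clean <- generateMovie(uniformScene(nx = 12, noiseSigma = 0, seed = 2))
  expect_true(all(computeTissueMask(clean)))
})

test_that("heterogeneity maps satisfy the normalization algebra exactly", {
  h <- makeHeterogeneityMap(matrix(c(1, 2, 3), 1), delta = 0.5,
                            smoothRadius = 0)
  expect_equal(as.vector(hetField(h)), c(0.5, 1.0, 1.5))
  ## arbitrary field: mask-mean exactly 1 and max deviation exactly delta
  set.seed(2)
  a <- matrix(runif(400, 1, 7), 20)
  mask <- matrix(runif(400) > 0.2, 20)
  h2 <- makeHeterogeneityMap(a, delta = 0.37, mask = mask, smoothRadius = 0)
  expect_equal(mean(hetField(h2)[mask]), 1, tolerance = 1e-9)
  expect_equal(max(abs(hetField(h2)[mask] - 1)), 0.37, tolerance = 1e-9)
  expect_true(all(hetField(h2)[!mask] == 1))
  ## delta = 0 and constant input both collapse to the uniform map
  expect_true(all(hetField(makeHeterogeneityMap(a, delta = 0,
                                                smoothRadius = 0)) == 1))
  hc <- makeHeterogeneityMap(matrix(5, 3, 3), delta = 0.5, smoothRadius = 0)
  expect_true(hc@degenerate)
  expect_true(all(hetField(hc) == 1))
  expect_error(makeHeterogeneityMap(a, delta = 1.5), "delta")
})

test_that("the reciprocal map renormalizes the inverted field", {
  h1 <- makeHeterogeneityMap(matrix(c(1, 2, 3), 1), delta = 0.5,
                             smoothRadius = 0)
  h2 <- makeReciprocalMap(h1, delta = 0.5)
  ## reciprocal {2, 1, 2/3}, mean 11/9, renormalized to {1.5, 6/7, 9/14}
  expect_equal(as.vector(hetField(h2)), c(1.5, 6 / 7, 9 / 14))
  expect_equal(h2@source, "reciprocal")
  expect_equal(mean(hetField(h2)), 1, tolerance = 1e-9)
  ## constant input stays uniform
  hc <- makeReciprocalMap(matrix(2, 2, 2), delta = 0.5)
  expect_true(all(hetField(hc) == 1))
  expect_error(makeReciprocalMap(matrix(c(-1, 1), 1), delta = 0.5),
               "nonpositive")
})

test_that("variants gate which parameters the maps touch", {
  g <- generateUltrastructureField(12, 12, correlationLength = 4, seed = 3)
  h1 <- makeHeterogeneityMap(g, delta = 0.5, smoothRadius = 0)
  h2 <- makeReciprocalMap(h1, delta = 0.5)
  p <- apParameters()
  hom <- applyHeterogeneity(p, modelVariant("homogeneous"), 12, 12)
  expect_true(all(hom$DPar == 0.010) && all(hom$tauScale == 1))
  vH1 <- applyHeterogeneity(p, modelVariant("H1", diffusivityMap = h1))
  expect_true(all(vH1$tauScale == 1))
  expect_equal(vH1$DPar, 0.010 * hetField(h1))
  vH2 <- applyHeterogeneity(p, modelVariant("H2", apdMap = h2))
  expect_true(all(vH2$DPar == 0.010))
  vH3 <- applyHeterogeneity(p, modelVariant("H3", h1, h2))
  ## delta = 0.5 bounds: D_par within [0.005, 0.015] cm^2/ms and
  ## tau_si = 2.9013 * tauScale within [1.45065, 4.35195] ms
  expect_true(all(vH3$DPar >= 0.005 - 1e-12 & vH3$DPar <= 0.015 + 1e-12))
  tsi <- 2.9013 * vH3$tauScale
  expect_true(all(tsi >= 1.45065 - 1e-9 & tsi <= 4.35195 + 1e-9))
  expect_error(modelVariant("H3", diffusivityMap = h1), "APD")
  expect_error(modelVariant("H1"), "diffusivity")
})

test_that("uniform diffusivity scaling moves CV like the square root", {
  p <- apParameters()
  cv1 <- conductionVelocity(p, "par", n = 80L, dx = 0.05, dt = 0.02)
  cv2 <- conductionVelocity(p, "par", n = 80L, dx = 0.05, dt = 0.02,
                            DScale = 1.25)
  expect_equal(cv2 / cv1, sqrt(1.25), tolerance = 0.03)
})

test_that("1D cuts sample the field with bilinear interpolation", {
  g <- matrix(rep(seq(1, 2, length.out = 10), 10), 10)
  h <- makeHeterogeneityMap(g, delta = 0.5, smoothRadius = 0)
  ## axis-aligned path matches direct row extraction
  cut <- extract1dCut(h, cbind(1:10, 5))
  expect_equal(cut$H, hetField(h)[, 5], tolerance = 1e-12)
  ## constant field: constant profile, arc length preserved
  hc <- makeHeterogeneityMap(matrix(1, 8, 8), delta = 0.5, smoothRadius = 0)
  cc <- extract1dCut(hc, cbind(c(1, 8, 8), c(1, 1, 8)))
  expect_true(all(cc$H == 1))
  expect_equal(max(cc$arc_px), 14)
  ## a path leaving the mask fails
  hm <- makeHeterogeneityMap(g, delta = 0.5,
                             mask = cbind(matrix(TRUE, 10, 5),
                                          matrix(FALSE, 10, 5)),
                             smoothRadius = 0)
  expect_error(extract1dCut(hm, cbind(1:10, 8)), "mask")
})

test_that("resampling preserves the normalization on the target grid", {
  g <- generateUltrastructureField(24, 24, correlationLength = 6, seed = 5)
  h <- makeHeterogeneityMap(g, delta = 0.5, smoothRadius = 0)
  hr <- resampleHeterogeneityMap(h, 40, 40)
  expect_equal(dim(hetField(hr)), c(40L, 40L))
  expect_equal(mean(hetField(hr)), 1, tolerance = 1e-9)
  expect_equal(max(abs(hetField(hr) - 1)), 0.5, tolerance = 1e-9)
  ## large-scale structure survives: correlation with a direct bilinear
  ## resample of the source field
  src <- hetField(h)
  xi <- outer(seq(1, 24, length.out = 40), rep(1, 40))
  yi <- outer(rep(1, 40), seq(1, 24, length.out = 40))
  ref <- cardialt:::.bilinear(src, xi, yi)
  expect_gt(cor(as.vector(hetField(hr)), as.vector(ref)), 0.99)
})
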