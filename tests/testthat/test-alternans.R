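test_that("preprocessing removes trends and preserves constants", {
  mv <- squarePulseMovie()
  ## with detrending off, the filters leave a constant movie unchanged
  mc <- opticalMovie(array(3, c(4, 4, 100)))
  out <- preprocessMovie(mc, detrend = FALSE)
  expect_equal(frames(out), frames(mc))
  ## a linear ramp is removed by the detrend
  d <- dim(frames(mv))
  ramp <- array(rep(0.01 * seq_len(d[3]), each = d[1] * d[2]), d)
  mr <- opticalMovie(frames(mv) + ramp, frameInterval = 2)
  pr <- preprocessMovie(mr, spatialRadius = 0, temporalWindow = 1)
  resid <- apply(frames(pr) - frames(preprocessMovie(mv, spatialRadius = 0,
                                                     temporalWindow = 1)),
                 c(1, 2), function(x) coef(lm(x ~ seq_along(x)))[2])
  expect_lt(max(abs(resid)), 1e-6)
  expect_error(preprocessMovie(opticalMovie(array(1, c(2, 2, 5)))), "shorter")
})

test_that("an impulse spreads with the stated temporal and spatial footprint", {
  nx <- 21
  st <- array(0, c(nx, nx, 31))
  st[11, 11, 15] <- 1
  mv <- opticalMovie(st)
  out <- frames(preprocessMovie(mv, detrend = FALSE))
  ## temporal footprint: 7-frame rectangular window around the impulse
  ctr <- out[11, 11, ]
  expect_true(all(ctr[12:18] > 0))
  expect_equal(sum(ctr > 1e-9), 7)
  ## spatial footprint: monotone Gaussian decay, truncated at radius 4
  frame <- out[, , 15]
  prof <- frame[11:16, 11]
  expect_true(all(diff(prof[1:5]) < 0))
  expect_equal(frame[16, 11], 0)              # beyond the kernel radius
  ## Gaussian shape: log-ratio of successive offsets follows -d^2/(2 s^2)
  expect_equal(log(prof[2] / prof[1]), -1 / (2 * 4), tolerance = 0.05)
})

test_that("APD extraction recovers square-pulse geometry with sub-frame precision", {
  mv <- squarePulseMovie(widthsMs = rep(100, 4))
  s <- extractAPDSequence(frames(mv)[1, 1, ], frameInterval = 2)
  expect_length(apd(s), 4)
  expect_equal(apd(s), rep(100, 4), tolerance = 2 / 100)
  alt <- squarePulseMovie(widthsMs = c(120, 80, 120, 80, 120, 80))
  sa <- extractAPDSequence(frames(alt)[2, 2, ], frameInterval = 2)
  expect_equal(sa@apds, c(120, 80, 120, 80, 120, 80), tolerance = 2 / 80)
  ## no beats: flat trace yields an empty flagged sequence
  s0 <- extractAPDSequence(rep(0, 100), frameInterval = 2)
  expect_length(apd(s0), 0)
})

test_that("APDs from a model trace survive resampling to the optical frame rate", {
  p <- apParameters()
  sq <- runCellPacing(p, cycleLength = 500, nBeats = 4, dt = 0.02,
                      recordInterval = 0.5)
  tr <- attr(sq, "trace")
  coarse <- tr[seq(1, length(tr), by = 4)]         # 2 ms sampling
  sc <- extractAPDSequence(coarse, frameInterval = 2)
  expect_equal(apd(sc), apd(sq), tolerance = 2 / min(apd(sq)))
})

test_that("dAPD maps obey the beat-difference sign convention and antisymmetry", {
  alt <- squarePulseMovie(widthsMs = c(120, 80, 120, 80))
  m12 <- deltaAPDMap(alt, beats = c(1, 2))
  m23 <- deltaAPDMap(alt, beats = c(2, 3))
  expect_equal(mean(deltaAPD(m12)), -40, tolerance = 0.05)
  expect_equal(deltaAPD(m23), -deltaAPD(m12), tolerance = 1e-6)
  expect_false(any(nodalMask(m12)))
  ## a non-alternating movie is nodal everywhere
  mono <- squarePulseMovie(widthsMs = rep(100, 4))
  mm <- deltaAPDMap(mono, beats = c(1, 2))
  expect_true(all(nodalMask(mm)))
  expect_equal(patternLabel(classifyPattern(mm)), "none")
})

test_that("antiphase regions produce a sign flip across a nodal boundary", {
  mv <- generateMovie(daScene(nx = 32, duration = 6, noiseSigma = 0.01))
  m <- classifyPattern(deltaAPDMap(preprocessMovie(mv)))
  expect_equal(patternLabel(m), "DA")
  expect_gte(m@components$count, 2)
  d <- deltaAPD(m)
  ## opposite mean signs in the two region interiors
  expect_lt(mean(d[1:10, ], na.rm = TRUE) * mean(d[23:32, ], na.rm = TRUE), 0)
  ## the interface band is nodal on the temporally filtered map (spatial
  ## smoothing blends the steep alternation ramp across the sub-pixel
  ## nodal line, so it is turned off for this geometric check)
  mt <- deltaAPDMap(preprocessMovie(mv, spatialRadius = 0))
  expect_gt(mean(nodalMask(mt)[16:17, ]), 0.8)
})

test_that("pattern labels follow the area rules", {
  base <- squarePulseMovie(widthsMs = c(120, 80, 120, 80), nx = 10)
  ## concordant: whole tissue same sign
  expect_equal(patternLabel(classifyPattern(deltaAPDMap(base, c(1, 2)))), "CA")
  ## discordant: flip the beat order in half the pixels
  st <- frames(base)
  stFlip <- st
  stFlip[6:10, , ] <- frames(squarePulseMovie(c(80, 120, 80, 120),
                                              nx = 10))[6:10, , ]
  md <- classifyPattern(deltaAPDMap(opticalMovie(stFlip), c(1, 2)))
  expect_equal(patternLabel(md), "DA")
  expect_gte(md@components$count, 2)
})

test_that("APD-difference dispersion grows with coarser temporal resolution", {
  ## the +/- 2 ms nodal band reflects the measurement resolution: on a
  ## non-alternating noisy movie, the spread of measured dAPD widens as
  ## the frame interval coarsens
  mv <- generateMovie(uniformScene(nx = 24, noiseSigma = 0.05, seed = 31))
  m2 <- deltaAPDMap(preprocessMovie(mv, spatialRadius = 0))
  idx <- seq(1, nFrames(mv), by = 4)                 # 8 ms frames
  mv8 <- opticalMovie(frames(mv)[, , idx], frameInterval = 8)
  m8 <- deltaAPDMap(preprocessMovie(mv8, spatialRadius = 0))
  ok <- !is.na(deltaAPD(m2)) & !is.na(deltaAPD(m8))
  q2 <- quantile(abs(deltaAPD(m2)[ok]), 0.95)
  q8 <- quantile(abs(deltaAPD(m8)[ok]), 0.95)
  expect_gt(q8, q2)
  ## hence the nodal band captures less of the (truly nodal) tissue
  expect_lte(mean(nodalMask(m8)[ok]), mean(nodalMask(m2)[ok]))
})

test_that("transition counting ignores the quiescent label", {
  expect_equal(countTransitions(c("none", "CA", "CA", "DA")), 1L)
  expect_equal(countTransitions(c("CA", "DA", "CA", "DA")), 3L)
  expect_equal(countTransitions(c("none", "none", "none")), 0L)
  expect_equal(countTransitions(c("CA", "none", "CA", "DA")), 1L)
})
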