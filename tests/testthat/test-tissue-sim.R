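test_that("the diffusion tensor follows the fiber-angle rotation formulas", {
  f0 <- buildDiffusionField(0, 0.010, 0.003, nx = 3, ny = 3)
  expect_true(all(f0@D11 == 0.010) && all(f0@D22 == 0.003) &&
                all(f0@D12 == 0))
  f45 <- buildDiffusionField(pi / 4, 0.010, 0.003, nx = 2, ny = 2)
  expect_equal(f45@D11[1, 1], 0.0065)
  expect_equal(f45@D22[1, 1], 0.0065)
  expect_equal(f45@D12[1, 1], 0.0035)
  ## isotropy: any angle leaves an isotropic tensor unchanged
  a <- matrix(runif(9, 0, pi), 3)
  fi <- buildDiffusionField(a, 0.007, 0.007)
  expect_equal(fi@D11, matrix(0.007, 3, 3))
  expect_equal(fi@D12, matrix(0, 3, 3), tolerance = 1e-15)
  expect_error(buildDiffusionField(matrix(0, 2, 2), matrix(1, 3, 3), 1),
               "mismatch")
})

test_that("the divergence-form Laplacian annihilates constants and linear fields", {
  dom <- tissueDomain(16, 16, dx = 0.025)
  expect_equal(heterogeneousLaplacian(matrix(3, 16, 16), dom),
               matrix(0, 16, 16))
  lin <- outer(seq_len(16), rep(1, 16)) * 0.025
  lapLin <- heterogeneousLaplacian(lin, dom)
  expect_lt(max(abs(lapLin[2:15, 2:15])), 1e-12)
  ## quadratic: d/dx(D11 du/dx) of u = x^2 is 2 D11
  quad <- (outer(seq_len(16), rep(1, 16)) * 0.025)^2
  lapQ <- heterogeneousLaplacian(quad, dom)
  expect_equal(lapQ[5:12, 5:12], matrix(2 * 0.010, 8, 8), tolerance = 1e-9)
  expect_error(heterogeneousLaplacian(matrix(0, 4, 4), dom), "dim")
})

test_that("pure diffusion conserves the spatial mean under zero flux", {
  set.seed(8)
  dom <- tissueDomain(20, 20, dx = 0.025, alpha = pi / 5)
  st <- list(u = matrix(runif(400), 20), v = matrix(1, 20, 20),
             w = matrix(1, 20, 20), s = matrix(0, 20, 20))
  out <- stepTissue(st, dom, dt = 0.01, nSteps = 200L,
                    includeCurrents = FALSE)
  expect_equal(mean(out$u), mean(st$u), tolerance = 1e-13)
  ## gates untouched in the pure-diffusion mode
  expect_identical(out$v, st$v)
})

test_that("the uniform resting grid is a fixed point and exterior pixels stay frozen", {
  p <- apParameters()
  mask <- matrix(FALSE, 30, 30)
  mask[11:20, 11:20] <- TRUE
  dom <- tissueDomain(30, 30, dx = 0.05, mask = mask, params = p)
  r <- restingState(p)
  out <- stepTissue(NULL, dom, p, dt = 0.02, nSteps = 100L)
  expect_equal(max(abs(out$u - r[["u"]])), 0)
  expect_equal(max(abs(out$s - r[["s"]])), 0)
  ## stimulate the interior; far-exterior pixels must not move
  stim <- matrix(FALSE, 30, 30); stim[14:16, 14:16] <- TRUE
  out2 <- stepTissue(NULL, dom, p, dt = 0.02, nSteps = 500L,
                     stimMask = stim, stimAmplitude = 0.6)
  expect_gt(max(out2$u[mask]), 0.5)
  far <- phaseField(dom) < 1e-3
  expect_gt(sum(far), 0)
  expect_equal(max(abs(out2$u[far] - r[["u"]])), 0)
  ## the excitation stays bounded across the phase-field boundary band
  expect_lt(max(abs(out2$u)), 2)
})

test_that("time steps beyond the explicit stability bound are rejected", {
  dom <- tissueDomain(10, 10, dx = 0.025)
  expect_error(stepTissue(NULL, dom, dt = 0.05), "stability")
  expect_warning(stepTissue(NULL, dom, dt = 0.05, nSteps = 1L,
                            onInstability = "warning"), "stability")
  prot <- stimulusProtocol(dom, schedule = data.frame(frequency_hz = 3,
                                                      beats = 1))
  expect_error(runProtocol(dom, protocol = prot, dt = 0.05), "stability")
})

test_that("a planar wave crosses the sheet at the measured conduction velocity", {
  p <- apParameters()
  dom <- tissueDomain(80, 6, dx = 0.05, params = p)
  prot <- stimulusProtocol(dom, site = "rv_anterior",
                           schedule = data.frame(frequency_hz = 2,
                                                 beats = 1))
  rec <- runProtocol(dom, p, prot, dt = 0.02, recordInterval = 0.5)
  cv <- measureCV(rec, "x")
  ## arrival at the far edge agrees with length / CV
  traces <- uStack(rec)[78, 3, ]
  tArr <- rec@times[which(traces > 0.5)[1]]
  expect_equal(tArr, 77 * 0.05 / cv, tolerance = 0.1)
  ## frame accounting: one stage of b beats at f Hz yields
  ## b / f / recordInterval frames
  expect_equal(nFrames(rec), round(1 / 2 * 1000 / 0.5))
  expect_error(measureCV(rec, "y"), "propagation")
})

test_that("a degenerate heterogeneity run reproduces the homogeneous run bitwise", {
  p <- apParameters()
  hc <- makeHeterogeneityMap(matrix(1, 30, 30), delta = 0.5,
                             smoothRadius = 0)      # degenerate: H = 1
  fld <- applyHeterogeneity(p, modelVariant("H3", hc, hc))
  domHet <- tissueDomain(30, 30, dx = 0.05, DPar = fld$DPar,
                         DPerp = fld$DPerp, tauScale = fld$tauScale,
                         params = p)
  domHom <- tissueDomain(30, 30, dx = 0.05, params = p)
  sched <- data.frame(frequency_hz = 4, beats = 2)
  r1 <- runProtocol(domHet, p, stimulusProtocol(domHet, schedule = sched),
                    dt = 0.02)
  r2 <- runProtocol(domHom, p, stimulusProtocol(domHom, schedule = sched),
                    dt = 0.02)
  expect_identical(uStack(r1), uStack(r2))
})

test_that("simulated recordings convert losslessly into optical movies", {
  p <- apParameters()
  dom <- tissueDomain(12, 12, dx = 0.05, params = p)
  prot <- stimulusProtocol(dom, schedule = data.frame(frequency_hz = 4,
                                                      beats = 2))
  rec <- runProtocol(dom, p, prot, dt = 0.02, recordInterval = 2)
  mv <- asOpticalMovie(rec)
  expect_s4_class(mv, "OpticalMovie")
  expect_identical(frames(mv), uStack(rec))
  expect_equal(provenance(mv), "simulated")
  expect_equal(pixelSize(mv), 0.05 * 1e4)
  sub <- asOpticalMovie(rec, frameRange = c(11, 20))
  expect_equal(nFrames(sub), 10)
  expect_identical(frames(sub)[, , 1], uStack(rec)[, , 11])
})
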