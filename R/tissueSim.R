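.asGrid <- function(x, nx, ny, what = "field") {
  if (is.matrix(x)) {
    if (!all(dim(x) == c(nx, ny)))
      stop(what, " grid shape mismatch: expected ", nx, " x ", ny)
    x
  } else matrix(x, nx, ny)
}

#' Build the anisotropic diffusion tensor field
#'
#' Per-pixel symmetric tensor from a local fiber-angle field alpha
#' (radians) and the diffusivities along (D_par) and across (D_perp) the
#' fibers:
#' D11 = D_par cos^2 a + D_perp sin^2 a,
#' D22 = D_par sin^2 a + D_perp cos^2 a,
#' D12 = D21 = (D_par - D_perp) cos a sin a.
#'
#' @param alpha Fiber angle field (radians), scalar or matrix.
#' @param DPar,DPerp Diffusivities (cm^2/ms), scalar or per-pixel grids.
#' @param nx,ny Grid size; inferred when any argument is a matrix.
#' @return A [DiffusionField-class].
#' @examples
#' f <- buildDiffusionField(pi / 4, 0.010, 0.003, nx = 2, ny = 2)
#' f@D12[1, 1]  # 0.0035
#' @export
buildDiffusionField <- function(alpha, DPar, DPerp, nx = NULL, ny = NULL) {
  mats <- Filter(is.matrix, list(alpha, DPar, DPerp))
  if (is.null(nx)) {
    if (!length(mats)) stop("grid size required when all inputs are scalar")
    nx <- nrow(mats[[1]]); ny <- ncol(mats[[1]])
  }
  a <- .asGrid(alpha, nx, ny, "alpha")
  dp <- .asGrid(DPar, nx, ny, "D_par")
  dq <- .asGrid(DPerp, nx, ny, "D_perp")
  ca <- cos(a); sa <- sin(a)
  new("DiffusionField",
      D11 = dp * ca^2 + dq * sa^2,
      D22 = dp * sa^2 + dq * ca^2,
      D12 = (dp - dq) * ca * sa)
}

#' Construct a 2D tissue domain
#'
#' Assembles the simulation grid: spacing, a smooth phase field obtained by
#' Gaussian smoothing of the binary tissue mask (zero-flux boundary
#' conditions on arbitrary shapes), the diffusion tensor field, and the
#' per-pixel multiplier for the APD-regulating time constants.
#'
#' @param nx,ny Grid size in pixels.
#' @param dx Grid spacing in cm (0.025 for convergence-grade runs, 0.06 to
#'   match the optical-mapping pixel pitch).
#' @param mask Logical tissue mask; default full rectangle.
#' @param alpha Fiber-angle field (radians), scalar or matrix.
#' @param DPar,DPerp Diffusivity fields (cm^2/ms); default from
#'   \code{params}.  Pass per-pixel grids for heterogeneous tissue.
#' @param tauScale Per-pixel multiplier on tau_w+, tau_so, tau_si.
#' @param params An [APModelParameters-class] supplying default
#'   diffusivities.
#' @param phaseFieldSigma Gaussian width (pixels) used to smooth the mask
#'   into the phase field; 0 keeps the binary mask.
#' @return A [TissueDomain-class].
#' @export
tissueDomain <- function(nx, ny, dx = 0.025, mask = NULL, alpha = 0,
                         DPar = NULL, DPerp = NULL, tauScale = 1,
                         params = apParameters(), phaseFieldSigma = 2) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (is.null(mask)) mask <- matrix(TRUE, nx, ny)
  stopifnot(all(dim(mask) == c(nx, ny)))
  if (is.null(DPar)) DPar <- parValues(params)[["D_par"]]
  if (is.null(DPerp)) DPerp <- parValues(params)[["D_perp"]]
  phi <- if (phaseFieldSigma > 0 && !all(mask)) {
    all1 <- matrix(TRUE, nx, ny)
    cpp_gaussian_blur(matrix(as.numeric(mask), nx, ny), phaseFieldSigma,
                      as.integer(ceiling(3 * phaseFieldSigma)), all1)
  } else matrix(as.numeric(mask), nx, ny)
  phi[phi < 0] <- 0; phi[phi > 1] <- 1
  new("TissueDomain", nx = nx, ny = ny, dx = dx, phi = phi,
      diffusion = buildDiffusionField(alpha, DPar, DPerp, nx = nx, ny = ny),
      tauScale = .asGrid(tauScale, nx, ny, "tauScale"))
}

#' Divergence-form heterogeneous anisotropic Laplacian
#'
#' Evaluates (1/phi) div(phi D grad u) on the domain grid, including the
#' cross-derivative D12 term, with phase-field weighting so that zero-flux
#' holds on tissue boundaries of arbitrary shape.  All terms are assembled
#' from face fluxes (diffusivities averaged harmonically on faces for the
#' diagonal terms, arithmetically for the cross term), which conserves the
#' phi-weighted total of u exactly under pure diffusion.
#'
#' @param u Numeric matrix matching the domain grid.
#' @param domain A [TissueDomain-class].
#' @return Matrix of the same shape, in 1/ms when u is dimensionless.
#' @export
heterogeneousLaplacian <- function(u, domain) {
  stopifnot(all(dim(u) == c(domain@nx, domain@ny)))
  d <- domain@diffusion
  cpp_laplacian(u, d@D11, d@D12, d@D22, domain@phi, domain@dx)
}

.stabilityLimit <- function(domain) {
  dmax <- max(domain@diffusion@D11, domain@diffusion@D22)
  domain@dx^2 / (4 * dmax)
}

#' Advance the tissue model
#'
#' Explicit-Euler update(s) of the monodomain reaction-diffusion model on
#' the domain grid: gates updated pointwise, u updated with diffusion,
#' currents and stimulus.  Pixels outside the phase-field support are
#' frozen.
#'
#' @param state List of matrices \code{u}, \code{v}, \code{w}, \code{s};
#'   defaults to the uniform resting state.
#' @param domain A [TissueDomain-class].
#' @param params An [APModelParameters-class].
#' @param dt Time step in ms; checked against the explicit stability bound
#'   dx^2 / (4 max D).
#' @param nSteps Number of steps.
#' @param stimMask Logical matrix of stimulated pixels (or NULL).
#' @param stimAmplitude Stimulus current (1/ms) applied on stimMask for the
#'   whole call.
#' @param includeCurrents Set FALSE for pure diffusion (gates untouched).
#' @param onInstability \code{"error"} or \code{"warning"}.
#' @return Updated state list.
#' @export
stepTissue <- function(state = NULL, domain, params = apParameters(),
                       dt = 0.01, nSteps = 1L, stimMask = NULL,
                       stimAmplitude = 0, includeCurrents = TRUE,
                       onInstability = c("error", "warning")) {
  onInstability <- match.arg(onInstability)
  lim <- .stabilityLimit(domain)
  if (dt > lim) {
    msg <- sprintf("dt = %g ms exceeds the stability bound dx^2/(4 max D) = %g ms",
                   dt, lim)
    if (onInstability == "error") stop(msg) else warning(msg)
  }
  if (is.null(state)) {
    r <- restingState(params)
    state <- list(u = matrix(r[["u"]], domain@nx, domain@ny),
                  v = matrix(r[["v"]], domain@nx, domain@ny),
                  w = matrix(r[["w"]], domain@nx, domain@ny),
                  s = matrix(r[["s"]], domain@nx, domain@ny))
  }
  if (is.null(stimMask)) stimMask <- matrix(FALSE, domain@nx, domain@ny)
  d <- domain@diffusion
  res <- cpp_simulate_tissue(
    state$u, state$v, state$w, state$s, .parVector(params),
    d@D11, d@D12, d@D22, domain@tauScale, domain@phi, domain@dx, dt,
    as.integer(nSteps), matrix(as.numeric(stimMask), domain@nx, domain@ny),
    if (stimAmplitude != 0) 0 else numeric(0),
    nSteps * dt * 2, stimAmplitude, 0L, includeCurrents)
  list(u = res$u, v = res$v, w = res$w, s = res$s)
}

#' Define a pacing protocol
#'
#' @param domain A [TissueDomain-class] (used for the site geometry).
#' @param site \code{"base"} (strip along the top edge), \code{"rv_anterior"}
#'   (strip along the left edge), or a logical matrix of stimulated pixels.
#' @param stripWidth Width of the edge strip in pixels.
#' @param pulseDuration Stimulus duration in ms.
#' @param amplitude Stimulus current in 1/ms (about twice the diastolic
#'   threshold at the defaults).
#' @param schedule data.frame with columns \code{frequency_hz} and
#'   \code{beats}; a pacing-down protocol lists increasing frequencies,
#'   10 beats per stage by default.
#' @return A [StimulusProtocol-class].
#' @export
stimulusProtocol <- function(domain, site = "base", stripWidth = 3L,
                             pulseDuration = 2, amplitude = 0.6,
                             schedule = data.frame(frequency_hz = 3,
                                                   beats = 10)) {
  nx <- domain@nx; ny <- domain@ny
  tissue <- domain@phi > 0.5
  if (is.character(site)) {
    m <- matrix(FALSE, nx, ny)
    if (site == "base") m[, seq_len(min(stripWidth, ny))] <- TRUE
    else if (site == "rv_anterior") m[seq_len(min(stripWidth, nx)), ] <- TRUE
    else stop("unknown site preset: ", site)
    site <- m & tissue
  } else {
    stopifnot(is.logical(site), all(dim(site) == c(nx, ny)))
    if (!any(site & tissue)) stop("stimulation site lies outside the tissue")
    site <- site & tissue
  }
  new("StimulusProtocol", site = site, pulseDuration = pulseDuration,
      amplitude = amplitude, schedule = schedule)
}

#' Run a pacing protocol on a tissue domain
#'
#' Executes the pacing schedule (for the pacing-down protocol: stages of
#' increasing pacing frequency, a 10-beat train per stage so the tissue
#' reaches a stationary regime), recording u at a fixed frame interval.
#' The stage table marks the frames covering the last two beats of each
#' stage for alternans analysis, and reports the activated-tissue fraction
#' per stage; conduction block is recorded there, not raised.
#'
#' @param domain A [TissueDomain-class].
#' @param params An [APModelParameters-class].
#' @param protocol A [StimulusProtocol-class].
#' @param dt Integration step in ms.
#' @param recordInterval Frame interval of the recording in ms.
#' @param state Optional initial state (list of u, v, w, s matrices).
#' @return A [SimulationRecording-class].
#' @export
runProtocol <- function(domain, params = apParameters(), protocol,
                        dt = 0.01, recordInterval = 2, state = NULL) {
  lim <- .stabilityLimit(domain)
  if (dt > lim)
    stop(sprintf("dt = %g ms exceeds the stability bound %g ms", dt, lim))
  sched <- protocol@schedule
  cl <- 1000 / sched$frequency_hz
  stageDur <- sched$beats * cl
  tStart <- cumsum(c(0, stageDur))[seq_len(nrow(sched))]
  stimTimes <- unlist(lapply(seq_len(nrow(sched)), function(k)
    tStart[k] + (seq_len(sched$beats[k]) - 1) * cl[k]))
  total <- sum(stageDur)
  recEvery <- max(1L, as.integer(round(recordInterval / dt)))
  nSteps <- as.integer(ceiling(total / dt / recEvery) * recEvery)
  if (is.null(state)) {
    r <- restingState(params)
    state <- list(u = matrix(r[["u"]], domain@nx, domain@ny),
                  v = matrix(r[["v"]], domain@nx, domain@ny),
                  w = matrix(r[["w"]], domain@nx, domain@ny),
                  s = matrix(r[["s"]], domain@nx, domain@ny))
  }
  d <- domain@diffusion
  res <- cpp_simulate_tissue(
    state$u, state$v, state$w, state$s, .parVector(params),
    d@D11, d@D12, d@D22, domain@tauScale, domain@phi, domain@dx, dt,
    nSteps, matrix(as.numeric(protocol@site), domain@nx, domain@ny),
    stimTimes, protocol@pulseDuration, protocol@amplitude, recEvery)
  times <- res$times
  tissue <- domain@phi > 0.5
  stagesDf <- do.call(rbind, lapply(seq_len(nrow(sched)), function(k) {
    tEnd <- tStart[k] + stageDur[k]
    idx <- which(times > tStart[k] & times <= tEnd)
    last2 <- which(times > tEnd - 2 * cl[k] & times <= tEnd)
    act <- if (length(idx)) {
      peak <- apply(res$stack[, , idx, drop = FALSE], c(1, 2), max)
      mean(peak[tissue] > 0.5)
    } else NA_real_
    data.frame(stage = k, frequency_hz = sched$frequency_hz[k],
               cycle_ms = cl[k], beats = sched$beats[k],
               t_start = tStart[k], t_end = tEnd,
               first_frame = if (length(idx)) min(idx) else NA_integer_,
               last_frame = if (length(idx)) max(idx) else NA_integer_,
               last2_first_frame = if (length(last2)) min(last2) else NA_integer_,
               activated_fraction = act,
               block = !is.na(act) && act < 0.5)
  }))
  new("SimulationRecording", stack = res$stack, times = times,
      dx = domain@dx, frameInterval = recEvery * dt, stages = stagesDf,
      mask = tissue, protocol = protocol)
}

#' Convert a simulation recording to an optical movie
#'
#' Re-packages the simulated voltage stack as an [OpticalMovie-class] with
#' provenance \code{"simulated"}, so the identical FFI and alternans code
#' path runs on simulated and recorded data.
#'
#' @param recording A [SimulationRecording-class].
#' @param frameRange Optional integer pair restricting the frames.
#' @return An [OpticalMovie-class].
#' @export
asOpticalMovie <- function(recording, frameRange = NULL) {
  st <- recording@stack
  if (!is.null(frameRange))
    st <- st[, , frameRange[1]:frameRange[2], drop = FALSE]
  new("OpticalMovie", frames = st,
      frameInterval = recording@frameInterval,
      pixelSize = recording@dx * 1e4, mask = recording@mask,
      provenance = "simulated")
}

#' Measure conduction velocity from a planar-wave recording
#'
#' Activation time is the first upward 20%-amplitude crossing per pixel;
#' CV is the inverse slope of a linear fit of activation time against
#' distance along the propagation direction, taken on the central line of
#' the grid and restricted to its middle portion (away from the stimulus
#' and the far boundary).
#'
#' @param recording A [SimulationRecording-class].
#' @param direction \code{"x"} (along rows) or \code{"y"} (along columns).
#' @param thresholdFraction Activation threshold as a fraction of the
#'   local AP amplitude.
#' @param trim Fraction of the line discarded at both ends.
#' @return CV in cm/ms.
#' @export
measureCV <- function(recording, direction = c("x", "y"),
                      thresholdFraction = 0.2, trim = 0.2) {
  direction <- match.arg(direction)
  st <- recording@stack
  d <- dim(st)
  traces <- if (direction == "x") {
    j <- max(1L, d[2] %/% 2)
    t(st[, j, ])                      # nt x nx
  } else {
    i <- max(1L, d[1] %/% 2)
    t(st[i, , ])                      # nt x ny
  }
  np <- ncol(traces)
  dtF <- recording@frameInterval
  tAct <- rep(NA_real_, np)
  for (k in seq_len(np)) {
    x <- traces[, k]
    amp <- max(x) - min(x)
    if (amp < 0.3) next               # never activated
    thr <- min(x) + thresholdFraction * amp
    i1 <- which(x[-1] >= thr & x[-length(x)] < thr)[1]
    if (is.na(i1)) next
    tAct[k] <- (i1 - 1 + (thr - x[i1]) / (x[i1 + 1] - x[i1])) * dtF
  }
  keep <- seq_len(np) > trim * np & seq_len(np) <= (1 - trim) * np &
    !is.na(tAct)
  if (sum(keep) < 3) stop("no propagation detected along ", direction)
  dist <- (which(keep) - 1) * recording@dx
  fit <- lm(tAct[keep] ~ dist)
  sl <- coef(fit)[[2]]
  if (!is.finite(sl) || sl <= 0) stop("no propagation detected along ", direction)
  1 / sl
}

#' Conduction velocity of a planar wave in a homogeneous strip
#'
#' Convenience wrapper: builds a thin homogeneous strip (a pseudo-1D
#' cable), paces one end once, and measures CV with [measureCV()].
#'
#' @param params An [APModelParameters-class].
#' @param direction \code{"par"} (along fibers) or \code{"perp"}.
#' @param n Strip length in pixels.
#' @param dx Grid spacing in cm.
#' @param dt Time step in ms.
#' @param DScale Multiplier applied to both diffusivities.
#' @return CV in cm/ms.
#' @export
conductionVelocity <- function(params = apParameters(),
                               direction = c("par", "perp"), n = 120L,
                               dx = 0.025, dt = 0.01, DScale = 1) {
  direction <- match.arg(direction)
  pv <- parValues(params)
  ## fibers along x: "par" propagates along x, "perp" along y of a strip
  ## re-oriented so the wave always travels along the strip (x) axis.
  D <- if (direction == "par") pv[["D_par"]] else pv[["D_perp"]]
  dom <- tissueDomain(n, 5L, dx = dx, alpha = 0, DPar = D * DScale,
                      DPerp = D * DScale, params = params)
  ## stimulus strip of fixed physical width (0.15 cm) so excitation
  ## stays suprathreshold under mesh refinement
  prot <- stimulusProtocol(dom, site = "rv_anterior",
                           stripWidth = max(3L, as.integer(ceiling(0.15 / dx))),
                           schedule = data.frame(frequency_hz = 1000 /
                                                   (3 * n * dx / 0.03),
                                                 beats = 1))
  ## one beat; duration covers the crossing generously
  rec <- runProtocol(dom, params, prot, dt = dt, recordInterval = 0.5)
  measureCV(rec, direction = "x")
}
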