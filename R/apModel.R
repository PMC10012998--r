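#' Construct the minimal-model parameter set
#'
#' Returns the constants of the four-variable minimal ventricular action
#' potential model, defaulting to the canine endocardial tuning at
#' physiological temperature.  Any constant can be overridden by name.
#' The voltage variable u is dimensionless; membrane potential in mV is
#' recovered with [rescaleVoltage()].
#'
#' @param ... Named overrides, e.g. \code{apParameters(tau_si = 3)}.
#' @return An [APModelParameters-class] object.
#' @examples
#' p <- apParameters()
#' parValues(p)[["tau_fi"]]
#' @export
apParameters <- function(...) {
  v <- c(
    u_o = 0, u_u = 1.56, u_s = 0.9087, u_so = 0.65,
    u_w_minus = 0.00615, u_w_plus = 0.0005, w_inf_star = 0.78,
    theta_v = 0.3, theta_v_minus = 0.2, theta_w = 0.13, theta_o = 0.006,
    tau_v_plus = 1.4506, tau_v1_minus = 55, tau_v2_minus = 40,
    tau_w1_plus = 175, tau_w2_plus = 230, tau_w1_minus = 40,
    tau_w2_minus = 115, tau_w_inf = 0.0273,
    tau_fi = 0.10, tau_si = 2.9013, tau_s1 = 2.7342, tau_s2 = 2,
    tau_so1 = 40, tau_so2 = 1.2, tau_o1 = 470, tau_o2 = 6,
    k_w_plus = 8, k_w_minus = 20, k_s = 2.0994, k_so = 2,
    D_par = 0.010, D_perp = 0.003)
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(v))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    v[names(ov)] <- unlist(ov)
  }
  new("APModelParameters", values = v)
}

#' @rdname apParameters
#' @param params An [APModelParameters-class] object.
#' @export
parValues <- function(params) params@values

## parameter vector in the canonical order expected by the compiled core
.parVector <- function(params) {
  stopifnot(is(params, "APModelParameters"))
  unname(params@values[.PAR_NAMES])
}

#' Read or write model parameters as a flat JSON/YAML document
#'
#' Parameters are serialized as a flat name/value mapping using the ASCII
#' model symbol names (tau_v1_minus, theta_w, ...).
#'
#' @param params An [APModelParameters-class] object.
#' @param path Output (or input) file; format chosen by extension
#'   (\code{.json} or \code{.yaml}/\code{.yml}).
#' @return \code{readParameters} returns an [APModelParameters-class].
#' @export
writeParameters <- function(params, path) {
  v <- as.list(params@values)
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(v, path)
  else jsonlite::write_json(v, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeParameters
#' @export
readParameters <- function(path) {
  v <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
       else jsonlite::read_json(path)
  do.call(apParameters, v)
}

.heaviside <- function(x) as.numeric(x >= 0)

#' Voltage-dependent gating rates and asymptotes
#'
#' Evaluates the piecewise and sigmoidal time "constants" and asymptotic
#' gate values of the minimal model at a membrane voltage u.  The Heaviside
#' step uses the right-continuous convention Theta(0) = 1 throughout the
#' package.
#'
#' @param u Dimensionless membrane voltage (vectorized).
#' @param params An [APModelParameters-class] object.
#' @return A data.frame with columns \code{tau_v_minus}, \code{tau_w_plus},
#'   \code{tau_w_minus}, \code{tau_so}, \code{tau_s}, \code{tau_o},
#'   \code{v_inf}, \code{w_inf}.
#' @examples
#' evaluateRateFunctions(c(0, 0.5), apParameters())
#' @export
evaluateRateFunctions <- function(u, params) {
  stopifnot(all(is.finite(u)))
  p <- as.list(params@values)
  Hvm <- .heaviside(u - p$theta_v_minus)
  Hw <- .heaviside(u - p$theta_w)
  Ho <- .heaviside(u - p$theta_o)
  data.frame(
    tau_v_minus = (1 - Hvm) * p$tau_v1_minus + Hvm * p$tau_v2_minus,
    tau_w_plus = p$tau_w1_plus + (p$tau_w2_plus - p$tau_w1_plus) *
      (1 + tanh(p$k_w_plus * (u - p$u_w_plus))) / 2,
    tau_w_minus = p$tau_w1_minus + (p$tau_w2_minus - p$tau_w1_minus) *
      (1 + tanh(p$k_w_minus * (u - p$u_w_minus))) / 2,
    tau_so = p$tau_so1 + (p$tau_so2 - p$tau_so1) *
      (1 + tanh(p$k_so * (u - p$u_so))) / 2,
    tau_s = (1 - Hw) * p$tau_s1 + Hw * p$tau_s2,
    tau_o = (1 - Ho) * p$tau_o1 + Ho * p$tau_o2,
    v_inf = 1 - Hvm,
    w_inf = (1 - Ho) * (1 - u / p$tau_w_inf) + Ho * p$w_inf_star)
}

#' Transmembrane currents of the minimal model
#'
#' Fast-inward, slow-outward and slow-inward current densities (1/ms) at a
#' given state, with Heaviside gating (Theta(0) = 1).
#'
#' @param state Numeric vector \code{c(u, v, w, s)} or a named list.
#' @param params An [APModelParameters-class] object.
#' @return Named numeric vector \code{c(J_fi, J_so, J_si)}.
#' @examples
#' evaluateCurrents(c(u = 0, v = 1, w = 1, s = 0), apParameters())
#' @export
evaluateCurrents <- function(state, params) {
  state <- unlist(state)
  if (any(!is.finite(state))) stop("invalid state: non-finite values")
  u <- state[[1]]; v <- state[[2]]; w <- state[[3]]; s <- state[[4]]
  p <- as.list(params@values)
  r <- evaluateRateFunctions(u, params)
  Hv <- .heaviside(u - p$theta_v)
  Hw <- .heaviside(u - p$theta_w)
  c(J_fi = -Hv * (u - p$theta_v) * (p$u_u - u) * v / p$tau_fi,
    J_so = (1 - Hw) * (u - p$u_o) / r$tau_o + Hw / r$tau_so,
    J_si = -Hw * w * s / p$tau_si)
}

#' Resting state of the minimal model
#'
#' The stationary state at u = 0 with no stimulus: v = w = 1 and the gate s
#' at its sigmoid asymptote.
#'
#' @param params An [APModelParameters-class] object.
#' @return Numeric vector \code{c(u, v, w, s)}.
#' @export
restingState <- function(params) {
  p <- params@values
  c(u = 0, v = 1, w = 1,
    s = (1 + tanh(p[["k_s"]] * (0 - p[["u_s"]]))) / 2)
}

#' Advance the single-cell model by explicit Euler steps
#'
#' One (or several) forward-Euler updates of the 0D model with an optional
#' constant stimulus current added to du/dt.
#'
#' @param state Numeric vector \code{c(u, v, w, s)}.
#' @param dt Time step in ms; must be positive and below the stability
#'   limit of the gating kinetics.
#' @param iStim Stimulus current in 1/ms.
#' @param params An [APModelParameters-class] object.
#' @param nSteps Number of Euler steps to take.
#' @return The updated state vector.
#' @export
stepCell <- function(state, dt, iStim = 0, params = apParameters(),
                     nSteps = 1L) {
  if (dt <= 0) stop("dt must be positive")
  if (any(!is.finite(unlist(state)))) stop("invalid state: non-finite values")
  res <- cpp_integrate_cell(unlist(state), .parVector(params), dt,
                            as.integer(nSteps),
                            if (iStim != 0) 0 else numeric(0),
                            nSteps * dt + dt, iStim, as.integer(nSteps))
  out <- res$final
  names(out) <- c("u", "v", "w", "s")
  out
}

#' Pace the single-cell model and measure per-beat APDs
#'
#' Integrates the 0D model under a periodic train of rectangular stimulus
#' pulses and extracts the APD of each beat by threshold crossing at a
#' fraction of the AP amplitude above the diastolic level (default 20%,
#' matching the optical analysis convention).  Loss of 1:1 capture is
#' reported in the \code{captured} slot, not as an error.
#'
#' @param params An [APModelParameters-class] object.
#' @param cycleLength Pacing cycle length in ms.
#' @param nBeats Number of delivered stimuli (>= 2).
#' @param thresholdFraction APD detection threshold as a fraction of the
#'   AP amplitude.
#' @param dt Integration step in ms.
#' @param stimDuration,stimAmplitude Rectangular pulse shape (ms, 1/ms).
#' @param recordInterval Sampling interval of the stored voltage trace (ms).
#' @param state Initial state; defaults to [restingState()].
#' @param tauScale Multiplier on the APD-regulating time constants
#'   (tau_w+, tau_so, tau_si), as used for heterogeneous tissue.
#' @return An [APDSequence-class]; the voltage trace and its sampling
#'   interval are attached as attributes \code{trace} and \code{dtTrace}.
#' @examples
#' seq <- runCellPacing(cycleLength = 500, nBeats = 4)
#' apd(seq)
#' @export
runCellPacing <- function(params = apParameters(), cycleLength, nBeats = 10,
                          thresholdFraction = 0.2, dt = 0.01,
                          stimDuration = 2, stimAmplitude = 0.6,
                          recordInterval = 0.5, state = restingState(params),
                          tauScale = 1) {
  stopifnot(cycleLength > stimDuration, nBeats >= 2)
  stimTimes <- (seq_len(nBeats) - 1) * cycleLength
  total <- nBeats * cycleLength
  recEvery <- max(1L, as.integer(round(recordInterval / dt)))
  nSteps <- as.integer(ceiling(total / dt / recEvery) * recEvery)
  res <- cpp_integrate_cell(unlist(state), .parVector(params), dt, nSteps,
                            stimTimes, stimDuration, stimAmplitude, recEvery,
                            tauScale)
  dtTrace <- recEvery * dt
  det <- cpp_apd_traces(matrix(res$u, ncol = 1), dtTrace, thresholdFraction,
                        0.1, as.integer(nBeats + 2))
  n <- det$n_beats[1]
  apds <- det$apd[seq_len(n), 1]
  ups <- det$t_up[seq_len(n), 1]
  out <- new("APDSequence", apds = apds, upstrokes = ups,
             cycleLength = cycleLength,
             thresholdFraction = thresholdFraction,
             captured = n == nBeats)
  attr(out, "trace") <- res$u
  attr(out, "dtTrace") <- dtTrace
  out
}

#' Steady-state APD restitution by a pacing-down scan
#'
#' Runs [runCellPacing()] over a vector of cycle lengths and reports, for
#' each, the APDs of the last two beats and the alternans magnitude.
#'
#' @param params An [APModelParameters-class] object.
#' @param cycleLengths Cycle lengths in ms (scanned in decreasing order).
#' @param nBeats Beats per stage.
#' @param ... Passed to [runCellPacing()].
#' @return data.frame with columns \code{cycle_ms}, \code{apd_last},
#'   \code{apd_prev}, \code{delta_apd}, \code{captured}.
#' @export
restitutionScan <- function(params = apParameters(), cycleLengths,
                            nBeats = 10, ...) {
  cycleLengths <- sort(cycleLengths, decreasing = TRUE)
  rows <- lapply(cycleLengths, function(cl) {
    s <- runCellPacing(params, cycleLength = cl, nBeats = nBeats, ...)
    a <- apd(s)
    n <- length(a)
    data.frame(cycle_ms = cl,
               apd_last = if (n >= 1) a[n] else NA_real_,
               apd_prev = if (n >= 2) a[n - 1] else NA_real_,
               delta_apd = if (n >= 2) a[n] - a[n - 1] else NA_real_,
               captured = s@captured)
  })
  do.call(rbind, rows)
}

#' Rescale the dimensionless voltage to millivolts
#'
#' Applies the affine scaling u_m = 85.7 u - 84 mV.
#'
#' @param u Dimensionless voltage (vectorized).
#' @return Membrane potential in mV.
#' @examples
#' rescaleVoltage(0)   # -84 mV
#' rescaleVoltage(1)   # 1.7 mV
#' @export
rescaleVoltage <- function(u) 85.7 * u - 84

#' Export an APD sequence as CSV
#'
#' Writes columns \code{beat_index}, \code{apd_ms}, \code{di_ms},
#' \code{cycle_length_ms}.
#'
#' @param x An [APDSequence-class].
#' @param path Output CSV path.
#' @export
writeAPDSequence <- function(x, path) {
  n <- length(x@apds)
  di <- c(diastolicIntervals(x), NA_real_)
  df <- data.frame(beat_index = seq_len(n), apd_ms = x@apds,
                   di_ms = if (n) di else numeric(0),
                   cycle_length_ms = rep(x@cycleLength, n))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
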