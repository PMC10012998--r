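#' @include AllGenerics.R
NULL

.PAR_NAMES <- c(
  "u_o", "u_u", "u_s", "u_so", "u_w_minus", "u_w_plus", "w_inf_star",
  "theta_v", "theta_v_minus", "theta_w", "theta_o",
  "tau_v_plus", "tau_v1_minus", "tau_v2_minus",
  "tau_w1_plus", "tau_w2_plus", "tau_w1_minus", "tau_w2_minus", "tau_w_inf",
  "tau_fi", "tau_si", "tau_s1", "tau_s2", "tau_so1", "tau_so2",
  "tau_o1", "tau_o2",
  "k_w_plus", "k_w_minus", "k_s", "k_so",
  "D_par", "D_perp")

#' Minimal ventricular action potential model parameters
#'
#' Holds the constants of the four-variable minimal ventricular model:
#' dimensionless voltages and thresholds, gating time constants (ms),
#' sigmoid slopes, and the diffusivities along and across the fiber
#' direction (cm^2/ms).  Defaults are the canine endocardial tuning at
#' 37 degrees Celsius.  Use [apParameters()] to construct.
#'
#' @slot values Named numeric vector of all model constants.
#' @export
setClass("APModelParameters", representation(values = "numeric"))

setValidity("APModelParameters", function(object) {
  v <- object@values
  if (!identical(names(v), .PAR_NAMES))
    return("parameter vector must contain all model constants in canonical order")
  if (any(!is.finite(v))) return("all parameters must be finite")
  taus <- v[grepl("^tau_", names(v))]
  if (any(taus <= 0)) return("all time constants must be positive")
  if (v["D_perp"] <= 0 || v["D_par"] < v["D_perp"])
    return("diffusivities must satisfy D_par >= D_perp > 0")
  TRUE
})

#' Optical-mapping movie
#'
#' An intensity stack I(x, y, t) with acquisition metadata: frame interval
#' (ms), pixel size (um), a boolean tissue mask, and a provenance tag
#' (\code{"experimental"}, \code{"simulated"} or \code{"synthetic"}).
#' Construct with [opticalMovie()].
#'
#' @slot frames 3D numeric array (nx, ny, nt).
#' @slot frameInterval Frame interval in ms.
#' @slot pixelSize Pixel edge length in um.
#' @slot mask Logical matrix (nx, ny) marking tissue pixels.
#' @slot provenance Character tag.
#' @export
setClass("OpticalMovie", representation(
  frames = "array", frameInterval = "numeric", pixelSize = "numeric",
  mask = "matrix", provenance = "character"))

setValidity("OpticalMovie", function(object) {
  d <- dim(object@frames)
  if (length(d) != 3L) return("frames must be a 3D array (nx, ny, nt)")
  if (d[3] < 2L) return("movie must contain at least 2 frames")
  if (object@frameInterval <= 0) return("frameInterval must be positive")
  if (!all(dim(object@mask) == d[1:2]))
    return("mask shape must match the frames")
  if (!object@provenance %in% c("experimental", "simulated", "synthetic"))
    return("provenance must be experimental, simulated or synthetic")
  TRUE
})

#' Pixel-wise Fourier stack
#'
#' The result of Fourier transformation imaging: per-pixel amplitude
#' |F(f)| and phase arg F(f) on a one-sided frequency axis, together with
#' the analysis window metadata.  Construct with [ffiTransform()].
#'
#' @slot amplitude 3D array (nx, ny, nf) of spectral amplitudes.
#' @slot phase 3D array (nx, ny, nf) of phases in (-pi, pi].
#' @slot freq Frequency axis in Hz.
#' @slot frameInterval Sampling interval of the windowed signal (ms).
#' @slot window Integer first/last frame of the analysis window.
#' @slot detrended Whether a per-pixel linear detrend was applied.
#' @export
setClass("FourierStack", representation(
  amplitude = "array", phase = "array", freq = "numeric",
  frameInterval = "numeric", window = "integer", detrended = "logical"))

setValidity("FourierStack", function(object) {
  da <- dim(object@amplitude)
  if (!identical(da, dim(object@phase)))
    return("amplitude and phase must share dimensions")
  if (length(object@freq) != da[3])
    return("frequency axis must match the third dimension")
  if (any(object@amplitude < 0)) return("amplitudes must be non-negative")
  TRUE
})

#' Per-beat action potential duration sequence
#'
#' APDs (ms) ordered by beat number, with the upstroke times, the pacing
#' cycle length when known, and the detection threshold.  Returned by
#' [extractAPDSequence()] and [runCellPacing()].
#'
#' @slot apds Numeric vector of APDs in ms.
#' @slot upstrokes Upstroke (threshold-crossing) times in ms.
#' @slot cycleLength Pacing cycle length in ms (NA when unknown).
#' @slot thresholdFraction Fraction of the AP amplitude used as threshold.
#' @slot captured Logical: one detected beat per delivered stimulus
#'   (NA when no stimulus count is available).
#' @export
setClass("APDSequence", representation(
  apds = "numeric", upstrokes = "numeric", cycleLength = "numeric",
  thresholdFraction = "numeric", captured = "logical"))

setValidity("APDSequence", function(object) {
  if (length(object@apds) != length(object@upstrokes))
    return("apds and upstrokes must have equal length")
  if (any(object@apds <= 0, na.rm = TRUE)) return("all APDs must be positive")
  TRUE
})

#' Anisotropic diffusion tensor field
#'
#' Per-pixel components of the symmetric 2D diffusion tensor derived from a
#' fiber-angle field and the parallel/perpendicular diffusivities.
#' Construct with [buildDiffusionField()].
#'
#' @slot D11,D12,D22 Numeric matrices (cm^2/ms).
#' @export
setClass("DiffusionField", representation(
  D11 = "matrix", D12 = "matrix", D22 = "matrix"))

setValidity("DiffusionField", function(object) {
  if (!all(dim(object@D11) == dim(object@D22)) ||
      !all(dim(object@D11) == dim(object@D12)))
    return("tensor component grids must share shape")
  det <- object@D11 * object@D22 - object@D12^2
  if (any(det < -1e-12) || any(object@D11 < 0) || any(object@D22 < 0))
    return("per-pixel tensors must be positive semi-definite")
  TRUE
})

#' Two-dimensional tissue domain
#'
#' The simulation grid: spacing dx (cm), a smooth 0-1 phase field marking
#' tissue versus exterior, the diffusion tensor field, and the per-pixel
#' multiplier applied to the APD-regulating time constants.  Construct with
#' [tissueDomain()].
#'
#' @slot nx,ny Grid size.
#' @slot dx Grid spacing in cm.
#' @slot phi Phase field in [0, 1].
#' @slot diffusion A [DiffusionField-class].
#' @slot tauScale Matrix of multipliers for the APD-regulating constants.
#' @export
setClass("TissueDomain", representation(
  nx = "integer", ny = "integer", dx = "numeric", phi = "matrix",
  diffusion = "DiffusionField", tauScale = "matrix"))

setValidity("TissueDomain", function(object) {
  if (object@dx <= 0) return("dx must be positive")
  if (!all(dim(object@phi) == c(object@nx, object@ny)))
    return("phase field shape must match the grid")
  if (any(object@phi < 0 | object@phi > 1))
    return("phase field must lie in [0, 1]")
  if (!all(dim(object@diffusion@D11) == c(object@nx, object@ny)))
    return("diffusion field shape must match the grid")
  if (!all(dim(object@tauScale) == c(object@nx, object@ny)))
    return("tauScale shape must match the grid")
  if (any(object@tauScale <= 0)) return("tauScale must be positive")
  TRUE
})

#' Pacing protocol
#'
#' Stimulation site (pixel mask), rectangular pulse shape, and a schedule
#' of pacing stages (frequency in Hz, number of beats).  Construct with
#' [stimulusProtocol()].
#'
#' @slot site Logical matrix of stimulated pixels.
#' @slot pulseDuration Pulse duration in ms.
#' @slot amplitude Pulse amplitude in 1/ms.
#' @slot schedule data.frame with columns \code{frequency_hz}, \code{beats}.
#' @export
setClass("StimulusProtocol", representation(
  site = "matrix", pulseDuration = "numeric", amplitude = "numeric",
  schedule = "data.frame"))

setValidity("StimulusProtocol", function(object) {
  s <- object@schedule
  if (!all(c("frequency_hz", "beats") %in% names(s)))
    return("schedule needs columns frequency_hz and beats")
  if (any(s$frequency_hz <= 0)) return("pacing frequencies must be positive")
  if (any(s$beats < 1)) return("each stage needs at least one beat")
  if (!any(object@site)) return("stimulation site is empty")
  if (object@pulseDuration <= 0 || object@amplitude <= 0)
    return("pulse duration and amplitude must be positive")
  TRUE
})

#' Simulation recording
#'
#' The membrane-potential stack u(x, y, t) sampled at a fixed frame
#' interval during [runProtocol()], with grid metadata, the protocol echo,
#' and a stage table mapping frames to pacing stages (including the frames
#' of the last two beats of each stage for alternans analysis).
#'
#' @slot stack 3D array (nx, ny, nt) of u.
#' @slot times Frame times in ms.
#' @slot dx Grid spacing in cm.
#' @slot frameInterval Recording interval in ms.
#' @slot stages data.frame: one row per pacing stage.
#' @slot mask Logical matrix of tissue pixels (phase field > 0.5).
#' @slot protocol The [StimulusProtocol-class] that was run.
#' @export
setClass("SimulationRecording", representation(
  stack = "array", times = "numeric", dx = "numeric",
  frameInterval = "numeric", stages = "data.frame", mask = "matrix",
  protocol = "StimulusProtocol"))

setValidity("SimulationRecording", function(object) {
  d <- dim(object@stack)
  if (length(d) != 3L) return("stack must be 3D")
  if (length(object@times) != d[3]) return("times must match frames")
  TRUE
})

#' Tissue heterogeneity map
#'
#' A positive scalar field H(x, y) with mask-mean 1 and maximal deviation
#' delta, derived from the low-frequency optical ultrastructure (direct or
#' reciprocal form) and used as a multiplicative modulation of model
#' parameters.  Construct with [makeHeterogeneityMap()] or
#' [makeReciprocalMap()].
#'
#' @slot H Numeric matrix; equals 1 outside the mask.
#' @slot delta Maximal variation, in [0, 1].
#' @slot source \code{"direct"} or \code{"reciprocal"}.
#' @slot mask Logical tissue mask.
#' @slot smoothing List of smoothing metadata (radius, sigma).
#' @slot degenerate TRUE when the input field was constant.
#' @export
setClass("HeterogeneityMap", representation(
  H = "matrix", delta = "numeric", source = "character", mask = "matrix",
  smoothing = "list", degenerate = "logical"))

setValidity("HeterogeneityMap", function(object) {
  if (object@delta < 0 || object@delta > 1)
    return("delta must lie in [0, 1]")
  if (!all(dim(object@H) == dim(object@mask)))
    return("H and mask must share shape")
  ## H = 0 can occur only at the delta = 1 boundary (full variation)
  if (any(object@H < 0) || (object@delta < 1 && any(object@H == 0)))
    return("H must be strictly positive")
  m <- object@mask
  if (any(m)) {
    if (abs(mean(object@H[m]) - 1) > 1e-8)
      return("H must average to 1 over the mask")
    dev <- max(abs(object@H[m] - 1))
    if (!object@degenerate && abs(dev - object@delta) > 1e-8)
      return("maximal deviation of H must equal delta")
  }
  if (!object@source %in% c("direct", "reciprocal"))
    return("source must be direct or reciprocal")
  TRUE
})

#' Beat-to-beat APD difference map
#'
#' Pixelwise difference of APD between two subsequent beats, the nodal mask
#' (|dAPD| within the nodal band, default 2 ms), pixels lacking two beats,
#' and -- after [classifyPattern()] -- the concordant/discordant label and
#' connected-component summary.
#'
#' @slot delta Numeric matrix of APD differences (ms); NA where missing.
#' @slot nodal Logical matrix: within the nodal band.
#' @slot missing Logical matrix: fewer than two detected beats.
#' @slot mask Logical tissue mask.
#' @slot beats Integer pair (n, n + 1).
#' @slot nodalBand Half-width of the nodal band in ms.
#' @slot label \code{"unclassified"}, \code{"none"}, \code{"CA"} or \code{"DA"}.
#' @slot components List with per-component areas and signs.
#' @export
setClass("DeltaAPDMap", representation(
  delta = "matrix", nodal = "matrix", missing = "matrix", mask = "matrix",
  beats = "integer", nodalBand = "numeric", label = "character",
  components = "list"))

setValidity("DeltaAPDMap", function(object) {
  if (!all(dim(object@delta) == dim(object@nodal)))
    return("delta and nodal must share shape")
  if (!object@label %in% c("unclassified", "none", "CA", "DA"))
    return("invalid pattern label")
  ok <- !is.na(object@delta)
  if (any(object@nodal[ok] != (abs(object@delta[ok]) <= object@nodalBand)))
    return("nodal mask inconsistent with the nodal band rule")
  TRUE
})

#' Rhythm specification for the synthetic generator
#'
#' Pacing frequency, rhythm pattern (1:1, 2:2, 4:4 or broadband), the base
#' APD and the repeating APD-offset cycle, and the alternation phase
#' (0 or pi; antiphase regions start on the opposite beat).
#'
#' @slot fp Pacing frequency in Hz.
#' @slot pattern One of \code{"one_to_one"}, \code{"two_two"},
#'   \code{"four_four"}, \code{"broadband"}.
#' @slot apdBase Mean APD in ms.
#' @slot apdDeltas Repeating APD offsets in ms (length 1, 2 or 4).
#' @slot phase 0 or pi.
#' @export
setClass("RhythmSpec", representation(
  fp = "numeric", pattern = "character", apdBase = "numeric",
  apdDeltas = "numeric", phase = "numeric"))

setValidity("RhythmSpec", function(object) {
  if (object@fp <= 0) return("pacing frequency must be positive")
  if (!object@pattern %in% c("one_to_one", "two_two", "four_four", "broadband"))
    return("unknown rhythm pattern")
  need <- c(one_to_one = 1L, two_two = 2L, four_four = 4L, broadband = 1L)
  if (length(object@apdDeltas) != need[[object@pattern]])
    return("apdDeltas length inconsistent with the pattern period")
  cl <- 1000 / object@fp
  if (object@pattern != "broadband" &&
      max(object@apdBase + abs(object@apdDeltas)) >= cl)
    return("APD must stay below the cycle length (wave fusion)")
  if (!object@phase %in% c(0, pi)) return("phase must be 0 or pi")
  TRUE
})

#' Synthetic optical-mapping scene
#'
#' Full description of a synthetic recording: acquisition geometry, tissue
#' mask, a region map assigning a [RhythmSpec-class] to each sub-domain,
#' the multiplicative baseline-amplitude ultrastructure field, additive
#' noise and drift, plane-wave conduction velocity, and the RNG seed.
#' Construct with [sceneSpec()].
#'
#' @slot nx,ny Grid size in pixels.
#' @slot pixelSize Pixel edge in um.
#' @slot frameInterval Frame interval in ms.
#' @slot duration Recording length in s.
#' @slot mask Logical tissue mask.
#' @slot regionMap Integer matrix: 0 outside tissue, 1..K region labels.
#' @slot rhythms List of K [RhythmSpec-class] objects.
#' @slot ultrastructure Baseline amplitude field g(x, y), mean 1.
#' @slot noiseSigma Additive Gaussian noise sd (fraction of AP amplitude).
#' @slot baselineWander Amplitude of the slow (sub-Hz) multiplicative
#'   baseline fluctuation, as a fraction of the AP amplitude.
#' @slot driftSlope Linear intensity drift per frame.
#' @slot cv Plane-wave conduction velocity (cm/ms) used for travel delays.
#' @slot stimEdge Edge the wave starts from: top/bottom/left/right.
#' @slot nodalBandPx Half-width (px) of the linear alternation ramp between
#'   antiphase regions.
#' @slot seed RNG seed.
#' @export
setClass("SceneSpec", representation(
  nx = "integer", ny = "integer", pixelSize = "numeric",
  frameInterval = "numeric", duration = "numeric", mask = "matrix",
  regionMap = "matrix", rhythms = "list", ultrastructure = "matrix",
  noiseSigma = "numeric", baselineWander = "numeric",
  driftSlope = "numeric", cv = "numeric",
  stimEdge = "character", nodalBandPx = "numeric", seed = "integer"))

setValidity("SceneSpec", function(object) {
  if (!all(dim(object@mask) == c(object@nx, object@ny)))
    return("mask shape must match the grid")
  if (!all(dim(object@regionMap) == c(object@nx, object@ny)))
    return("regionMap shape must match the grid")
  k <- max(object@regionMap)
  if (k < 1 || length(object@rhythms) != k)
    return("rhythms must contain one RhythmSpec per region label")
  if (!all(vapply(object@rhythms, is, TRUE, "RhythmSpec")))
    return("rhythms must be RhythmSpec objects")
  if (any(object@regionMap[object@mask] == 0))
    return("regions must partition the tissue mask")
  if (!object@stimEdge %in% c("top", "bottom", "left", "right"))
    return("stimEdge must be one of top/bottom/left/right")
  if (object@noiseSigma < 0) return("noiseSigma must be non-negative")
  TRUE
})

## ---- accessors -----------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("frames", "OpticalMovie", function(x) x@frames)

#' @rdname accessors
#' @export
setMethod("frameInterval", "OpticalMovie", function(x) x@frameInterval)

#' @rdname accessors
#' @export
setMethod("frameInterval", "SimulationRecording", function(x) x@frameInterval)

#' @rdname accessors
#' @export
setMethod("pixelSize", "OpticalMovie", function(x) x@pixelSize)

#' @rdname accessors
#' @export
setMethod("tissueMask", "OpticalMovie", function(x) x@mask)

#' @rdname accessors
#' @export
setMethod("tissueMask", "HeterogeneityMap", function(x) x@mask)

#' @rdname accessors
#' @export
setMethod("provenance", "OpticalMovie", function(x) x@provenance)

#' @rdname accessors
#' @export
setMethod("nFrames", "OpticalMovie", function(x) dim(x@frames)[3])

#' @rdname accessors
#' @export
setMethod("nFrames", "SimulationRecording", function(x) dim(x@stack)[3])

#' @rdname accessors
#' @export
setMethod("freqAxis", "FourierStack", function(x) x@freq)

#' @rdname accessors
#' @export
setMethod("hetField", "HeterogeneityMap", function(x) x@H)

#' @rdname accessors
#' @export
setMethod("hetDelta", "HeterogeneityMap", function(x) x@delta)

#' @rdname accessors
#' @export
setMethod("apd", "APDSequence", function(x) x@apds)

#' @rdname accessors
#' @export
setMethod("upstrokeTimes", "APDSequence", function(x) x@upstrokes)

#' @rdname accessors
#' @export
setMethod("diastolicIntervals", "APDSequence", function(x) {
  n <- length(x@apds)
  if (n < 2) return(numeric(0))
  ends <- x@upstrokes[-n] + x@apds[-n]
  x@upstrokes[-1] - ends
})

#' @rdname accessors
#' @export
setMethod("deltaAPD", "DeltaAPDMap", function(x) x@delta)

#' @rdname accessors
#' @export
setMethod("nodalMask", "DeltaAPDMap", function(x) x@nodal)

#' @rdname accessors
#' @export
setMethod("patternLabel", "DeltaAPDMap", function(x) x@label)

#' @rdname accessors
#' @export
setMethod("phaseField", "TissueDomain", function(x) x@phi)

#' @rdname accessors
#' @export
setMethod("spacing", "TissueDomain", function(x) x@dx)

#' @rdname accessors
#' @export
setMethod("spacing", "SimulationRecording", function(x) x@dx)

#' @rdname accessors
#' @export
setMethod("uStack", "SimulationRecording", function(x) x@stack)

#' @rdname accessors
#' @export
setMethod("stages", "SimulationRecording", function(x) x@stages)

## ---- show methods --------------------------------------------------------

setMethod("show", "APModelParameters", function(object) {
  v <- object@values
  cat("APModelParameters (four-variable minimal ventricular model)\n")
  cat(sprintf("  D_par = %g, D_perp = %g cm^2/ms; tau_fi = %g ms, tau_si = %g ms\n",
              v["D_par"], v["D_perp"], v["tau_fi"], v["tau_si"]))
  cat(sprintf("  %d constants; voltage scaling u_m = (85.7 u - 84) mV\n",
              length(v)))
})

setMethod("show", "OpticalMovie", function(object) {
  d <- dim(object@frames)
  cat(sprintf("OpticalMovie: %d x %d px, %d frames @ %g ms (%g s), %g um/px\n",
              d[1], d[2], d[3], object@frameInterval,
              d[3] * object@frameInterval / 1000, object@pixelSize))
  cat(sprintf("  provenance: %s; tissue pixels: %d (%.1f%%)\n",
              object@provenance, sum(object@mask),
              100 * mean(object@mask)))
})

setMethod("show", "FourierStack", function(object) {
  d <- dim(object@amplitude)
  cat(sprintf("FourierStack: %d x %d px, %d frequency bins (0 - %.3g Hz)\n",
              d[1], d[2], d[3], max(object@freq)))
  cat(sprintf("  resolution %.4g Hz; window frames %d - %d; detrended: %s\n",
              object@freq[2] - object@freq[1], object@window[1],
              object@window[2], object@detrended))
})

setMethod("show", "APDSequence", function(object) {
  n <- length(object@apds)
  cat(sprintf("APDSequence: %d beats", n))
  if (n) cat(sprintf("; APD %.1f - %.1f ms", min(object@apds), max(object@apds)))
  if (!is.na(object@cycleLength))
    cat(sprintf("; CL %g ms", object@cycleLength))
  if (!is.na(object@captured) && !object@captured) cat("; capture lost")
  cat("\n")
})

setMethod("show", "TissueDomain", function(object) {
  cat(sprintf("TissueDomain: %d x %d @ dx = %g cm (%.2g x %.2g cm)\n",
              object@nx, object@ny, object@dx, object@nx * object@dx,
              object@ny * object@dx))
  cat(sprintf("  tissue fraction %.2f; max D11 = %g cm^2/ms\n",
              mean(object@phi > 0.5), max(object@diffusion@D11)))
})

setMethod("show", "SimulationRecording", function(object) {
  d <- dim(object@stack)
  cat(sprintf("SimulationRecording: %d x %d px, %d frames @ %g ms, %d stage(s)\n",
              d[1], d[2], d[3], object@frameInterval, nrow(object@stages)))
})

setMethod("show", "HeterogeneityMap", function(object) {
  cat(sprintf("HeterogeneityMap (%s): delta = %g, range [%.3g, %.3g]%s\n",
              object@source, object@delta, min(object@H), max(object@H),
              if (object@degenerate) " (degenerate: constant input)" else ""))
})

setMethod("show", "DeltaAPDMap", function(object) {
  ok <- !is.na(object@delta) & object@mask
  cat(sprintf("DeltaAPDMap beats (%d, %d): label %s; nodal fraction %.2f\n",
              object@beats[1], object@beats[2], object@label,
              if (any(ok)) mean(object@nodal[ok]) else NA_real_))
})

setMethod("show", "SceneSpec", function(object) {
  cat(sprintf("SceneSpec: %d x %d px, %g s @ %g ms, %d region(s), noise sd %g\n",
              object@nx, object@ny, object@duration, object@frameInterval,
              max(object@regionMap), object@noiseSigma))
})
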