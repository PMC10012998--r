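---
title: "Frequency imaging of cardiac alternans and ultrastructure-based model assimilation"
author: "cardialt authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency imaging of cardiac alternans and ultrastructure-based model assimilation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardialt)
```

## The scientific problem

Cardiac alternans — a beat-to-beat alternation of action potential
duration (APD) at a fixed pacing rate — precedes and predicts serious
arrhythmias.  In tissue, alternans can be spatially *concordant* (CA, the
whole tissue alternates in phase) or *discordant* (DA, at least two
regions alternate out of phase, separated by non-alternating *nodal
lines*).  Voltage-sensitive optical mapping images these patterns at high
resolution, but the classical ΔAPD analysis requires heavy pre-filtering.
`cardialt` implements the complementary frequency-domain view (Fourier
transformation imaging, FFI) together with a minimal ionic tissue model
and a data-assimilation procedure that transfers optically observed
tissue heterogeneity into the model, closing the loop between
measurement, analysis and simulation.

The package has five analysis layers:

1. **FFI** (`ffiTransform`, `extractFrequencyMap`): the per-pixel
   temporal discrete Fourier transform of the intensity movie
   $I_{x,y}(t) \rightarrow F_{x,y}(f)$, recomposed into amplitude
   $|F_{x,y}(f)|$ and phase $\arg F_{x,y}(f)$ maps without any spatial
   filtering.  A 2:2 rhythm paced at $f_p$ puts a subharmonic peak at
   $f_{1/2}=f_p/2$; the two antiphase regions of a DA pattern appear as a
   phase jump of $\pi$ at $f_{1/2}$, and the nodal line as an amplitude
   valley.  A 4:4 rhythm adds lines at $f_p/4$ and $3f_p/4$; fibrillation
   appears as an elevated broadband baseline (`classifyRhythm`).
2. **ΔAPD maps** (`preprocessMovie`, `deltaAPDMap`, `classifyPattern`):
   the classical analysis — detrending, a 7-frame rectangular temporal
   average, Gaussian spatial smoothing (radius 4 px), APD by threshold
   crossing at 20% of the signal amplitude, and the beat-pair difference
   $\Delta \mathrm{APD}_n = \mathrm{APD}_{n+1} - \mathrm{APD}_n$ with a
   $0 \pm 2$ ms nodal band (set by the 2 ms frame interval of the
   recordings the pipeline is designed for).
3. **Minimal ventricular model** (`apParameters`, `runCellPacing`,
   `runProtocol`): the four-variable model with voltage $u$ and gates
   $v, w, s$, fast-inward / slow-outward / slow-inward currents, and
   Heaviside-switched rate functions, on 2D anisotropic tissue
   $\partial_t u = \nabla\!\cdot\!(D\nabla u) - (J_{fi}+J_{so}+J_{si})$
   with a fiber-angle-rotated diffusion tensor and phase-field boundary
   conditions.  The default constants are a canine endocardial tuning;
   $u_m = (85.7u - 84)$ mV recovers millivolts.
4. **Heterogeneity assimilation** (`extractUltrastructure`,
   `makeHeterogeneityMap`, `applyHeterogeneity`): the low-frequency
   (0.5 Hz) FFI amplitude is a pacing-site- and rate-independent
   "optical ultrastructure" of the tissue.  It is smoothed (Gaussian,
   radius 6 px, variance 5 px²) and normalized to
   $H(x,y) = \delta\, r/\max|r| + 1$, $r = s - \bar s$: a field with
   mask-mean exactly 1 and maximal deviation $\delta \in [0,1]$.  $H_1$
   (direct) multiplies the diffusivities; $H_2$ (the renormalized
   reciprocal, emphasizing low-amplitude areas) multiplies the
   APD-governing time constants $\tau_{w}^+$, $\tau_{so}$, $\tau_{si}$
   (both sub-constants of each aggregate, which equals scaling the
   aggregate since the voltage dependence is affine in them).  The model
   variants are: homogeneous, H1 (diffusivity only), H2 (APD constants
   only), H3 (both).
5. **Synthetic data** (`sceneSpec`, `generateMovie`): a generator for
   optical-mapping movies with controlled rhythm, DA layout,
   ultrastructure and noise — the validation stand-in for recordings
   that are not publicly deposited.

## A worked example

A synthetic discordant 2:2 movie paced at 8 Hz, analyzed with both
pipelines:

```{r, eval = FALSE}
scene <- sceneSpec(
  nx = 48, ny = 48, duration = 10,
  regionMap = antiphaseRegions(48, 48),
  rhythms = list(rhythmSpec(8, "two_two", apdBase = 90, d = 12),
                 rhythmSpec(8, "two_two", apdBase = 90, d = 12, phase = pi)),
  noiseSigma = 0.02, cv = 0.2, seed = 3)
movie <- generateMovie(scene)

stack <- ffiTransform(movie)
fmap  <- extractFrequencyMap(stack, 4)     # f_p / 2
dapd  <- classifyPattern(deltaAPDMap(preprocessMovie(movie)))
patternLabel(dapd)                          # "DA"
```

The phase map at 4 Hz shows two plateaus separated by ≈ π; the ΔAPD map
shows the same two regions with opposite sign and a nodal line between
them; `phasePartition` recovers the same spatial partition from either.

## Model behaviour and pacing protocols

The single-cell model rests at $(u,v,w,s) = (0, 1, 1, s_\infty(0))$ with
$s_\infty(0) = (1+\tanh(k_s(0-u_s)))/2 \approx 0.02155$; this state is
stationary to machine precision.  Under periodic stimulation
(rectangular pulses, 2 ms, 0.6 ms⁻¹ — about twice the diastolic
threshold) the steady-state APD restitution is monotone in cycle length,
with no alternans at 1000 ms and a 2:2 bifurcation appearing near a
250–260 ms cycle length (`restitutionScan`).  Scaling the
APD-regulating constants by the $H_2$ map moves this onset strongly:
at 20% longer constants the bifurcation reaches into cycle lengths above
300 ms, which is what lets heterogeneity fields desynchronize alternans
across the tissue.

Tissue runs follow the pacing-down protocol: stages of increasing pacing
frequency, 10 beats per stage so the tissue reaches a stationary regime,
with alternans evaluated on the last two beats of each stage
(`runProtocol` tags those frames).  The protocol description uses
frequency stages exactly as the experimental one; we read the
"pacing-down" name as pacing the cycle length down (frequency up), which
matches how the pacing-down frequency maps are assembled.

## Numerical choices

* **Discretization.** Explicit Euler, Δx = 0.025 cm and Δt = 0.01 ms for
  convergence-grade runs; movie-emulation and validation runs use
  Δx = 0.05–0.06 cm (0.06 cm matches the 600 μm optical pixel) with
  Δt = 0.02 ms, which changes APDs by well under 1% (the suite checks a
  10× refinement) and keeps the explicit stability bound
  Δt ≤ Δx²/(4 max D) satisfied at every heterogeneity level up to
  δ = 1.  The solver refuses a time step beyond the bound.
* **Operator.** The divergence-form operator is assembled from face
  fluxes: harmonic face averages for the diagonal tensor entries (exact
  zero-flux across zero-diffusivity faces), arithmetic averages for the
  cross term with centered first derivatives, and phase-field weighting
  (φ D ∇u)/φ with a floor φ ≥ 10⁻³; pixels with φ below the floor are
  frozen.  Face-flux assembly makes the φ-weighted total of u exactly
  conserved under pure diffusion, which the suite asserts to machine
  precision.
* **Phase field.** Gaussian smoothing of the binary tissue mask
  (σ = 2 px); the band of small-φ boundary pixels keeps the explicit
  scheme stable because the face weights shrink together with φ.
* **Rate-function tables.** The tissue kernel evaluates the four
  tanh-shaped terms from lookup tables on a 2⁻¹⁰-spaced grid with linear
  interpolation.  Grid nodes are exact — u = 0 is a node, so the resting
  state stays a machine-precision fixed point — and the interpolation
  error (< 4·10⁻⁵) is far below the Euler discretization error.  The 0D
  integrator keeps the closed-form expressions.
* **Heaviside convention.** Θ(0) = 1 everywhere (right-continuous).
* **APD detection.** Threshold at 20% of the amplitude above the
  per-trace 10th-percentile baseline, sub-frame resolution by linear
  interpolation; partial beats at the trace edges are discarded.  The
  same detector serves model traces and optical movies.
* **FFI windowing.** Rectangular window over the whole recording by
  default (optional Hann), per-pixel linear detrend for experimental and
  synthetic movies (photobleaching drift), no detrend for simulated
  voltage stacks.  The ultrastructure extraction requires at least
  2/f s of signal for a bin at f and applies a Hann taper by default:
  with a rectangular window, leakage of the pacing harmonics into the
  low-frequency band depends on the local activation delay and would
  imprint the pacing site on the ultrastructure map.
* **Beat registration.** The per-pixel "last two beats" of a ΔAPD map
  are registered across pixels by upstroke time (using the estimated
  cycle length): beats clipped at either end of a recording shift a
  pixel's beat indexing by one, which would otherwise flip the measured
  alternans sign pixel-by-pixel.
* **δ = 1 boundary.** At full variation the direct map can reach
  H = 0 at its most negative pixel.  A zero diffusivity is an
  admissible, physically meaningful decoupled spot, so it is allowed;
  a zero time-constant scale is not, so the APD map must stay positive —
  which the reciprocal construction guarantees in practice, and which can
  always be achieved by deriving the reciprocal map from the raw
  (strictly positive) ultrastructure amplitude instead of the normalized
  H₁ map (`makeReciprocalMap` supports both sources).

## What the synthetic generator does and does not emulate

The generator reproduces the acquisition geometry (600 μm pixels, 2 ms
frames), plane-wave propagation delays at a configurable conduction
velocity, per-region rhythms (1:1, 2:2, amplitude-modulated 2:2 for 4:4,
and a broadband fibrillation stand-in), a linear alternation ramp to zero
over ≈ 3 px at antiphase-region interfaces (the synthetic nodal line), a
multiplicative baseline-amplitude ultrastructure with a slow (0.3–0.7 Hz,
2% of amplitude) shared baseline fluctuation that carries the
ultrastructure into the low-frequency spectral band, additive Gaussian
noise, and linear drift.  It does **not** emulate optics (blur, specular
reflection), motion artifacts, calcium signals, or the true cellular
electrophysiology of alternans onset — so passing tests on synthetic
movies validate the *analysis chain*, not the biology of any particular
recording.  Default noise (2% of amplitude) is a deliberately clean
regime; all levels are configurable.

For the closed-loop validation the pipeline is exercised end-to-end on
simulated data as well: `runProtocol` recordings are converted by
`asOpticalMovie` and pass through the *identical* FFI and ΔAPD code
path as synthetic and experimental movies.

## Validation problem sizes

The shipped validation suite and the acceptance script use reduced
problem sizes chosen as the smallest domains on which each phenomenon is
cleanly expressed: single-cell scans for restitution and alternans
onset; 80 × 6 strips (pseudo-1D cables) for conduction-velocity physics;
a 128 × 128 sheet at Δx = 0.06 cm — the full 7.7 cm optical field of
view — for the pacing-down, discordant-alternans and δ-sweep
experiments, with a four-stage schedule (3.0, 4.0, 4.6, 5.2 Hz); and
32–64 px movies of 6–10 s for the spectral analyses.  On the tissue
sheet, discordance during pacing-down requires domains comparable to the
full field of view: nodal-line spacing is set by conduction-velocity
restitution and is of the order of centimetres, so small sheets
synchronize into purely concordant alternans.

## Known limitations

* 2D monodomain only: no transmural anisotropy, bidomain effects, or
  mechanical deformation.
* The fiber-angle field defaults to uniform; rotational gradients must
  be supplied explicitly.
* The rhythm classifier's thresholds (5% subharmonic peak, 20% broadband
  baseline) are pragmatic defaults — the underlying experimental
  classification is visual — and are exposed as arguments.
* The choice of 0.5 Hz for the ultrastructure is the stable default of
  the pipeline; nearby low-frequency bins give similar but not identical
  maps, so analyses should state the bin used (`extractFrequencyMap`
  records it).
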