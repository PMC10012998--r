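## run expr with a fixed RNG seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specify a pacing rhythm for the synthetic generator
#'
#' Convenience constructor for [RhythmSpec-class].  A 2:2 rhythm
#' alternates APDs base +/- d; a 4:4 rhythm is an amplitude-modulated 2:2
#' with APD cycle (base + d1, base - d1, base + d2, base - d2), d1 != d2.
#'
#' @param fp Pacing frequency in Hz.
#' @param pattern \code{"one_to_one"}, \code{"two_two"},
#'   \code{"four_four"} or \code{"broadband"}.
#' @param apdBase Mean APD in ms.
#' @param d Alternans half-amplitude in ms (2:2).
#' @param d1,d2 The two alternans half-amplitudes of a 4:4 rhythm (ms).
#' @param phase 0 or pi; antiphase regions start on the opposite beat.
#' @return A [RhythmSpec-class].
#' @export
rhythmSpec <- function(fp, pattern = "one_to_one", apdBase = 150,
                       d = 20, d1 = 25, d2 = 15, phase = 0) {
  deltas <- switch(pattern,
    one_to_one = 0,
    two_two = c(d, -d),
    four_four = c(d1, -d1, d2, -d2),
    broadband = 0,
    stop("unknown rhythm pattern: ", pattern))
  new("RhythmSpec", fp = fp, pattern = pattern, apdBase = apdBase,
      apdDeltas = deltas, phase = phase)
}

## Parametric AP waveform: exponential upstroke (tau = 2 ms) times a
## sigmoidal repolarization placed so that the 20%-amplitude duration
## equals `apd`.  tau (ms) is time since the beat onset.
.apShape <- function(tau, apd, riseTau = 2, repolK = 8) {
  ## 20% crossings: rise at riseTau*log(1.25); fall at t50 + repolK*log(4)
  t50 <- apd - repolK * log(4) + riseTau * log(1.25)
  out <- (1 - exp(-tau / riseTau)) / (1 + exp((tau - t50) / repolK))
  out[tau < 0] <- 0
  out
}

## per-beat APD sequence for a rhythm, with alternation scaled by lambda
## and an antiphase beat offset for phase = pi
.apdSeq <- function(rhythm, nBeats, lambda = 1) {
  P <- length(rhythm@apdDeltas)
  off <- if (rhythm@phase == pi) P %/% 2 else 0
  idx <- ((seq_len(nBeats) - 1 + off) %% P) + 1
  rhythm@apdBase + lambda * rhythm@apdDeltas[idx]
}

## evaluate an AP train at times t (ms) for a beat-onset delay (ms)
.apTrain <- function(t, delay, cl, apds) {
  j <- floor((t - delay) / cl)
  tau <- t - delay - j * cl
  ok <- j >= 0 & j < length(apds)
  a <- rep(apds[1], length(t))
  a[ok] <- apds[j[ok] + 1]
  v <- .apShape(tau, a)
  v[!ok] <- 0
  v
}

#' Generate a synthetic action potential train
#'
#' A periodic train of parametric AP waveforms whose per-beat APDs follow
#' the repeating cycle of the rhythm (1:1, 2:2, or amplitude-modulated
#' 2:2 for 4:4).  The \code{"broadband"} pattern yields an aperiodic
#' band-limited noise trace emulating fibrillation.
#'
#' @param rhythm A [RhythmSpec-class].
#' @param duration Trace length in s.
#' @param frameInterval Sampling interval in ms.
#' @param delay Onset delay of the first beat in ms.
#' @param seed RNG seed (used by the broadband pattern only).
#' @return Numeric trace sampled at the frame times.
#' @export
generateAPTrain <- function(rhythm, duration = 10, frameInterval = 2,
                            delay = 0, seed = NULL) {
  nt <- round(duration * 1000 / frameInterval)
  t <- (seq_len(nt) - 1) * frameInterval
  if (rhythm@pattern == "broadband") {
    return(.withSeed(seed, {
      x <- stats::filter(rnorm(nt + 8), rep(1 / 5, 5), sides = 2)
      x <- x[!is.na(x)][seq_len(nt)]
      0.5 + 0.35 * x
    }))
  }
  cl <- 1000 / rhythm@fp
  nBeats <- ceiling((duration * 1000 - delay) / cl) + 1
  .apTrain(t, delay, cl, .apdSeq(rhythm, nBeats))
}

#' Generate a smooth random ultrastructure field
#'
#' Exponentiated Gaussian-filtered white noise (log-normal marginals)
#' rescaled to mean 1 with a configurable coefficient of variation: the
#' synthetic analogue of the pacing-independent low-frequency amplitude
#' structure of real tissue.  The field is strictly positive and mildly
#' right-skewed, like fluorescence emission strength.
#'
#' @param nx,ny Grid size.
#' @param correlationLength Autocorrelation half-width in pixels.
#' @param cv Coefficient of variation of the field.
#' @param seed RNG seed.
#' @return Positive matrix with mean 1.
#' @export
generateUltrastructureField <- function(nx, ny, correlationLength = 10,
                                        cv = 0.15, seed = NULL) {
  .withSeed(seed, {
    z <- matrix(rnorm(nx * ny), nx, ny)
    sig <- correlationLength / (2 * sqrt(log(2)))
    sm <- cpp_gaussian_blur(z, sig, as.integer(ceiling(3 * sig)),
                            matrix(TRUE, nx, ny))
    lsig <- sqrt(log(1 + cv^2))
    g <- exp(lsig * (sm - mean(sm)) / sd(sm))
    g / mean(g)
  })
}

#' Describe a synthetic optical-mapping scene
#'
#' Defaults mirror the acquisition geometry of whole-ventricle optical
#' mapping (600 um pixels, 2 ms frames) at a reduced field of view.  The
#' default scene is a single 1:1 region covering the full frame with a
#' uniform baseline field.
#'
#' @param nx,ny Grid size in pixels.
#' @param pixelSize Pixel edge in um.
#' @param frameInterval Frame interval in ms.
#' @param duration Recording length in s.
#' @param mask Logical tissue mask (default: all pixels).
#' @param regionMap Integer region labels (default: one region).
#' @param rhythms List of [RhythmSpec-class], one per region label.
#' @param ultrastructure Baseline amplitude field g (default uniform 1).
#' @param noiseSigma Additive Gaussian noise sd (fraction of amplitude).
#' @param baselineWander Amplitude of the slow multiplicative baseline
#'   fluctuation; this sub-Hz component carries the ultrastructure into
#'   the low-frequency spectral band.
#' @param driftSlope Linear drift per frame (photobleaching emulation).
#' @param cv Plane-wave conduction velocity in cm/ms.
#' @param stimEdge Edge the wave enters from.
#' @param nodalBandPx Alternation ramp half-width between antiphase
#'   regions (px).
#' @param seed RNG seed; a fixed seed makes the movie bitwise
#'   reproducible.
#' @return A [SceneSpec-class].
#' @export
sceneSpec <- function(nx = 64, ny = 64, pixelSize = 600, frameInterval = 2,
                      duration = 10, mask = NULL, regionMap = NULL,
                      rhythms = list(rhythmSpec(3.2)),
                      ultrastructure = NULL, noiseSigma = 0.02,
                      baselineWander = 0.02, driftSlope = 0, cv = 0.05,
                      stimEdge = "top", nodalBandPx = 3, seed = 1L) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (is.null(mask)) mask <- matrix(TRUE, nx, ny)
  if (is.null(regionMap)) regionMap <- matrix(as.integer(mask), nx, ny)
  if (is.null(ultrastructure)) ultrastructure <- matrix(1, nx, ny)
  new("SceneSpec", nx = nx, ny = ny, pixelSize = pixelSize,
      frameInterval = frameInterval, duration = duration, mask = mask,
      regionMap = matrix(as.integer(regionMap), nx, ny), rhythms = rhythms,
      ultrastructure = ultrastructure, noiseSigma = noiseSigma,
      baselineWander = baselineWander, driftSlope = driftSlope, cv = cv,
      stimEdge = stimEdge, nodalBandPx = nodalBandPx,
      seed = as.integer(seed))
}

#' Two antiphase regions split down the middle
#'
#' Helper building a region map with two labels split along x (rows) or
#' y (columns), the canonical discordant-alternans layout.
#'
#' @param nx,ny Grid size.
#' @param along \code{"x"} or \code{"y"}: the axis across which the
#'   tissue is split.
#' @return Integer matrix with labels 1 and 2.
#' @export
antiphaseRegions <- function(nx, ny, along = "x") {
  m <- matrix(1L, nx, ny)
  if (along == "x") m[seq_len(nx) > nx / 2, ] <- 2L
  else m[, seq_len(ny) > ny / 2] <- 2L
  m
}

## ring distance (in px) from the interface between different regions,
## capped at `cap`; interface-adjacent pixels get 0.
.interfaceDistance <- function(regionMap, mask, cap) {
  nx <- nrow(regionMap); ny <- ncol(regionMap)
  shift <- function(m, di, dj) {
    out <- matrix(NA, nx, ny)
    xi <- seq_len(nx) + di; yi <- seq_len(ny) + dj
    okx <- xi >= 1 & xi <= nx; oky <- yi >= 1 & yi <= ny
    out[okx, oky] <- m[xi[okx], yi[oky]]
    out
  }
  r <- regionMap
  r[!mask] <- NA
  iface <- matrix(FALSE, nx, ny)
  for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    nb <- shift(r, d[1], d[2])
    iface <- iface | (!is.na(r) & !is.na(nb) & nb != r)
  }
  dist <- matrix(cap, nx, ny)
  dist[iface] <- 0
  cur <- iface
  k <- 0
  while (k < cap && any(cur)) {
    k <- k + 1
    grown <- cur
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      nb <- shift(cur, d[1], d[2])
      nb[is.na(nb)] <- FALSE
      grown <- grown | nb
    }
    newly <- grown & !cur
    dist[newly & dist > k] <- k
    cur <- grown
  }
  dist
}

#' Generate a synthetic optical-mapping movie
#'
#' Builds I(x, y, t) = g(x, y) (AP(t - delay) + wander(t)) + drift t +
#' noise: each region plays its rhythm's AP train delayed by a plane wave
#' from the stimulated edge; antiphase regions implement discordant
#' alternans, with the alternation amplitude ramping linearly to zero over
#' a narrow band at the region interface (the nodal line); g is the
#' multiplicative baseline-amplitude ultrastructure; wander is a shared
#' slow (0.3 - 0.7 Hz) baseline fluctuation; background pixels contain
#' noise only.  A fixed scene seed makes the output bitwise reproducible.
#'
#' @param scene A [SceneSpec-class].
#' @return An [OpticalMovie-class] with provenance \code{"synthetic"}.
#' @export
generateMovie <- function(scene) {
  nx <- scene@nx; ny <- scene@ny
  nt <- round(scene@duration * 1000 / scene@frameInterval)
  t <- (seq_len(nt) - 1) * scene@frameInterval
  pxCm <- scene@pixelSize / 1e4
  distPx <- switch(scene@stimEdge,
    top = matrix(rep(seq_len(ny) - 1, each = nx), nx, ny),
    bottom = matrix(rep(rev(seq_len(ny)) - 1, each = nx), nx, ny),
    left = matrix(rep(seq_len(nx) - 1, ny), nx, ny),
    right = matrix(rep(rev(seq_len(nx)) - 1, ny), nx, ny))
  delay <- distPx * pxCm / scene@cv
  lambda <- if (max(scene@regionMap) > 1)
    pmin(.interfaceDistance(scene@regionMap, scene@mask,
                            ceiling(scene@nodalBandPx) + 1L) /
           scene@nodalBandPx, 1)
  else matrix(1, nx, ny)
  .withSeed(scene@seed, {
    wanderPhases <- runif(3, 0, 2 * pi)
    wander <- scene@baselineWander *
      (0.5 * sin(2 * pi * 0.3 * t / 1000 + wanderPhases[1]) +
       0.3 * sin(2 * pi * 0.5 * t / 1000 + wanderPhases[2]) +
       0.2 * sin(2 * pi * 0.7 * t / 1000 + wanderPhases[3]))
    stack <- array(0, c(nx, ny, nt))
    for (j in seq_len(ny)) for (i in seq_len(nx)) {
      if (!scene@mask[i, j]) next
      reg <- scene@regionMap[i, j]
      rh <- scene@rhythms[[reg]]
      tr <- if (rh@pattern == "broadband") {
        x <- stats::filter(rnorm(nt + 8), rep(1 / 5, 5), sides = 2)
        0.5 + 0.35 * x[!is.na(x)][seq_len(nt)]
      } else {
        cl <- 1000 / rh@fp
        nBeats <- ceiling(max(t) / cl) + 2
        .apTrain(t, delay[i, j], cl, .apdSeq(rh, nBeats, lambda[i, j]))
      }
      stack[i, j, ] <- scene@ultrastructure[i, j] * (tr + wander)
    }
    drift <- scene@driftSlope * (seq_len(nt) - 1)
    stack <- stack + rep(drift, each = nx * ny)
    if (scene@noiseSigma > 0)
      stack <- stack + array(rnorm(length(stack), sd = scene@noiseSigma),
                             dim(stack))
    opticalMovie(stack, frameInterval = scene@frameInterval,
                 pixelSize = scene@pixelSize, mask = scene@mask,
                 provenance = "synthetic")
  })
}
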