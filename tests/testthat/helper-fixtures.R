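## Shared fixtures, built in code at test time.

## canonical discordant 2:2 scene: two antiphase regions split across the
## pacing direction, realistic plane-wave CV so travel-delay phase spread
## stays small against the pi jump
daScene <- function(nx = 48, fp = 8, apdBase = 90, d = 12, duration = 10,
                    noiseSigma = 0.02, cv = 0.2, seed = 3,
                    ultrastructure = NULL, baselineWander = 0.02) {
  sceneSpec(nx = nx, ny = nx, duration = duration,
            regionMap = antiphaseRegions(nx, nx),
            rhythms = list(
              rhythmSpec(fp, "two_two", apdBase = apdBase, d = d),
              rhythmSpec(fp, "two_two", apdBase = apdBase, d = d,
                         phase = pi)),
            ultrastructure = ultrastructure, noiseSigma = noiseSigma,
            baselineWander = baselineWander, cv = cv, stimEdge = "top",
            seed = seed)
}

## single uniform-rhythm movie over an optional baseline field
uniformScene <- function(nx = 32, fp = 4, apdBase = 150, duration = 6,
                         noiseSigma = 0.02, ultrastructure = NULL,
                         stimEdge = "top", seed = 5, pattern = "one_to_one",
                         d = 15) {
  sceneSpec(nx = nx, ny = nx, duration = duration,
            rhythms = list(rhythmSpec(fp, pattern, apdBase = apdBase,
                                      d = d)),
            ultrastructure = ultrastructure, noiseSigma = noiseSigma,
            cv = 0.2, stimEdge = stimEdge, seed = seed)
}

## movie of identical square pulses at every pixel (plus optional per-pixel
## alternation), for APD geometry tests
squarePulseMovie <- function(widthsMs = c(100, 100, 100, 100), nx = 4,
                             frameInterval = 2, gapMs = 150) {
  nt <- as.integer(sum(widthsMs + gapMs) / frameInterval) + 10L
  tr <- numeric(nt)
  t0 <- gapMs / 2
  for (w in widthsMs) {
    i0 <- round(t0 / frameInterval) + 1L
    i1 <- round((t0 + w) / frameInterval)
    tr[i0:i1] <- 1
    t0 <- t0 + w + gapMs
  }
  opticalMovie(array(rep(tr, each = nx * nx), c(nx, nx, nt)),
               frameInterval = frameInterval)
}

## one-sided amplitude spectrum of a trace (simple reference oracle,
## independent of the FourierStack pipeline)
refSpectrum <- function(x, frameInterval = 2) {
  n <- length(x)
  a <- Mod(fft(x - mean(x)))[seq_len(n %/% 2 + 1)]
  list(amp = a, freq = (seq_len(n %/% 2 + 1) - 1) / (n * frameInterval / 1000))
}
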