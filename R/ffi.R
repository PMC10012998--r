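#' Construct an optical movie
#'
#' @param frames 3D numeric array (nx, ny, nt).
#' @param frameInterval Frame interval in ms.
#' @param pixelSize Pixel edge in um.
#' @param mask Logical tissue mask; default all pixels.
#' @param provenance \code{"experimental"}, \code{"simulated"} or
#'   \code{"synthetic"}.
#' @return An [OpticalMovie-class].
#' @export
opticalMovie <- function(frames, frameInterval = 2, pixelSize = 600,
                         mask = NULL, provenance = "synthetic") {
  d <- dim(frames)
  if (is.null(mask)) mask <- matrix(TRUE, d[1], d[2])
  new("OpticalMovie", frames = frames, frameInterval = frameInterval,
      pixelSize = pixelSize, mask = mask, provenance = provenance)
}

.detrendColumns <- function(m) {
  ## remove per-column least-squares line; m is nt x np
  nt <- nrow(m)
  t0 <- seq_len(nt) - (nt + 1) / 2
  denom <- sum(t0^2)
  slope <- crossprod(t0, m) / denom       # 1 x np
  inter <- colMeans(m)
  m - outer(t0, drop(slope)) - rep(inter, each = nt)
}

#' Fourier transformation imaging
#'
#' Pixel-wise discrete Fourier transform of an intensity movie over an
#' analysis window, recomposed into per-pixel amplitude and phase maps on
#' a one-sided frequency axis.  No spatial filtering is applied.  By
#' default the window drops the first beat-length worth of frames only
#' when requested via \code{window}; experimental and synthetic movies are
#' linearly detrended per pixel before transforming (simulated voltage
#' stacks are not).
#'
#' @param movie An [OpticalMovie-class].
#' @param window Integer pair (first, last frame); default whole movie.
#' @param detrend Per-pixel linear detrend; default TRUE except for
#'   simulated movies.
#' @param taper \code{"rect"} (default) or \code{"hann"}.
#' @return A [FourierStack-class].
#' @examples
#' tr <- sin(2 * pi * 1 * seq(0, 9.998, by = 0.002))
#' mv <- opticalMovie(array(rep(tr, each = 4), c(2, 2, length(tr))))
#' fs <- ffiTransform(mv, detrend = FALSE)
#' freqAxis(fs)[which.max(fs@amplitude[1, 1, -1]) + 1]  # 1 Hz
#' @export
ffiTransform <- function(movie, window = NULL,
                         detrend = provenance(movie) != "simulated",
                         taper = c("rect", "hann")) {
  taper <- match.arg(taper)
  d <- dim(movie@frames)
  if (is.null(window)) window <- c(1L, d[3])
  window <- as.integer(window)
  if (window[1] < 1 || window[2] > d[3] || window[2] - window[1] < 1)
    stop("analysis window exceeds the movie length")
  nt <- window[2] - window[1] + 1L
  m <- matrix(movie@frames[, , window[1]:window[2]], d[1] * d[2], nt)
  m <- t(m)                                  # nt x npix
  if (detrend) m <- .detrendColumns(m)
  if (taper == "hann")
    m <- m * (0.5 - 0.5 * cos(2 * pi * (seq_len(nt) - 1) / (nt - 1)))
  Fm <- mvfft(m)
  nf <- nt %/% 2 + 1L
  Fm <- Fm[seq_len(nf), , drop = FALSE]
  fs <- (seq_len(nf) - 1) / (nt * movie@frameInterval / 1000)
  amp <- array(t(Mod(Fm)), c(d[1], d[2], nf))
  ph <- array(t(Arg(Fm)), c(d[1], d[2], nf))
  new("FourierStack", amplitude = amp, phase = ph, freq = fs,
      frameInterval = movie@frameInterval, window = window,
      detrended = detrend)
}

.nearestBin <- function(stack, fTarget) {
  fNyq <- max(stack@freq)
  if (fTarget > fNyq)
    stop(sprintf("target frequency %g Hz above Nyquist (%g Hz)", fTarget, fNyq))
  which.min(abs(stack@freq - fTarget))
}

#' Extract amplitude and phase maps at a target frequency
#'
#' Selects the frequency bin nearest to the target and returns the
#' amplitude and phase maps at that bin, with the bin choice recorded.
#'
#' @param stack A [FourierStack-class].
#' @param fTarget Target frequency in Hz (within the Nyquist range).
#' @return List with \code{amplitude}, \code{phase} (matrices), \code{bin},
#'   \code{freq} (the bin's frequency in Hz).
#' @export
extractFrequencyMap <- function(stack, fTarget) {
  b <- .nearestBin(stack, fTarget)
  list(amplitude = stack@amplitude[, , b], phase = stack@phase[, , b],
       bin = b, freq = stack@freq[b])
}

#' Circular mean of phase angles
#'
#' @param theta Angles in radians.
#' @return Mean angle in (-pi, pi].
#' @export
circularMean <- function(theta) Arg(mean(exp(1i * theta)))

#' Wrapped phase difference
#'
#' @param a,b Angles in radians.
#' @return Difference wrapped to (-pi, pi].
#' @export
phaseDifference <- function(a, b) Arg(exp(1i * (a - b)))

#' Pacing-frequency series map
#'
#' Assembles, for a set of movies paced at different frequencies, the
#' ROI-averaged amplitude spectrum of each movie, normalized to its own
#' maximum (excluding the DC bin), into a pacing-frequency x spectral-
#' frequency map.  2:2 rhythms appear as a ridge at f_p / 2, 4:4 rhythms
#' add a ridge at 3 f_p / 4, and fibrillation shows an elevated broadband
#' baseline.
#'
#' @param movies List of [OpticalMovie-class] objects.
#' @param fp Numeric vector of their pacing frequencies (Hz).
#' @param roi Logical matrix selecting the ROI pixels; default the tissue
#'   mask of each movie.
#' @param freqMax Upper edge of the reported spectral axis in Hz.
#' @param nBins Number of spectral bins the spectra are interpolated onto.
#' @return List with \code{map} (length(fp) x nBins matrix), \code{fp},
#'   and \code{freq}.
#' @export
buildFrequencySeries <- function(movies, fp, roi = NULL, freqMax = 12,
                                 nBins = 241L) {
  stopifnot(length(movies) >= 2, length(movies) == length(fp))
  fGrid <- seq(0, freqMax, length.out = nBins)
  rows <- lapply(seq_along(movies), function(k) {
    mv <- movies[[k]]
    r <- if (is.null(roi)) tissueMask(mv) else roi
    if (!any(r)) stop("empty ROI")
    st <- ffiTransform(mv)
    nf <- length(st@freq)
    ampM <- matrix(st@amplitude, prod(dim(st@amplitude)[1:2]), nf)
    spec <- colMeans(ampM[as.vector(r), , drop = FALSE])
    spec[1] <- 0                            # drop DC
    spec <- spec / max(spec)
    approx(st@freq, spec, xout = fGrid, rule = 2)$y
  })
  ord <- order(fp)
  list(map = do.call(rbind, rows)[ord, , drop = FALSE], fp = sort(fp),
       freq = fGrid)
}

#' Extract the low-frequency optical ultrastructure
#'
#' The spectral amplitude map at a low frequency (default 0.5 Hz),
#' restricted to the tissue mask: a pacing-independent indicator of local
#' tissue properties and the input field for heterogeneity assimilation.
#'
#' A Hann taper is applied by default: with a rectangular window, spectral
#' leakage of the pacing harmonics into the low-frequency band depends on
#' the local activation delay, which would imprint the pacing site on the
#' ultrastructure; the taper suppresses it.
#'
#' @param movie An [OpticalMovie-class] with at least 2 / fLow seconds of
#'   signal (frequency-resolution constraint).
#' @param fLow Target frequency in Hz.
#' @param window Optional analysis window (frames).
#' @param taper Window taper; see [ffiTransform()].
#' @return Amplitude matrix; NA outside the tissue mask.
#' @export
extractUltrastructure <- function(movie, fLow = 0.5, window = NULL,
                                  taper = "hann") {
  d <- dim(movie@frames)
  nt <- if (is.null(window)) d[3] else diff(window) + 1
  if (nt * movie@frameInterval / 1000 < 2 / fLow)
    stop(sprintf("window too short: need >= %g s for %g Hz resolution",
                 2 / fLow, fLow))
  st <- ffiTransform(movie, window = window, taper = taper)
  a <- extractFrequencyMap(st, fLow)$amplitude
  a[!movie@mask] <- NA_real_
  a
}

#' Classify the rhythm of a pixel spectrum
#'
#' Peak tests on a single amplitude spectrum taken at pacing frequency
#' f_p: a subharmonic peak near f_p / 2 labels 2:2; an additional peak
#' near 3 f_p / 4 labels 4:4; an elevated broadband baseline labels
#' fibrillation; otherwise 1:1.  A peak "exists" when it is a local
#' maximum over +/- 2 bins and its amplitude is at least
#' \code{peakFraction} of the f_p peak; peaks within +/- 15% of f_p / 2
#' count as the f_1/2 line (their multiplicity is reported, covering split
#' lines).  Fibrillation is flagged when the median off-peak amplitude
#' over (0.25 f_p, 2 f_p) is at least \code{baselineFraction} of the f_p
#' peak.
#'
#' @param amplitude Amplitude spectrum (one pixel or ROI average).
#' @param freq Frequency axis in Hz.
#' @param fp Pacing frequency in Hz.
#' @param peakFraction,baselineFraction Classification thresholds.
#' @return List: \code{label} (one of \code{one_to_one}, \code{two_two},
#'   \code{four_four}, \code{fibrillation}), \code{entrained} (is the f_p
#'   bin dominant), \code{fHalfMultiplicity}, and the detected peak
#'   frequencies.
#' @export
classifyRhythm <- function(amplitude, freq, fp, peakFraction = 0.05,
                           baselineFraction = 0.2) {
  stopifnot(length(amplitude) == length(freq))
  a <- amplitude
  a[freq < 0.25] <- 0                       # drop DC/drift bins
  bFp <- which.min(abs(freq - fp))
  aFp <- a[bFp]
  nb <- length(a)
  isPeak <- function(b) {
    lo <- max(1, b - 2); hi <- min(nb, b + 2)
    a[b] >= max(a[lo:hi]) && a[b] >= peakFraction * aFp
  }
  localPeaks <- which(vapply(seq_len(nb), isPeak, TRUE))
  entrained <- length(localPeaks) == 0 ||
    aFp >= max(a[setdiff(which(freq > 0.25), (bFp - 2):(bFp + 2))])
  if (!entrained)
    warning("pacing-frequency bin is not dominant: entrainment failure?")
  ## f_1/2 line: any peak within +/- 15% of f_p / 2
  fHalfPeaks <- localPeaks[abs(freq[localPeaks] - fp / 2) <= 0.15 * fp / 2]
  f34Peaks <- localPeaks[abs(freq[localPeaks] - 3 * fp / 4) <= 0.075 * fp]
  f34Peaks <- setdiff(f34Peaks, fHalfPeaks)
  ## broadband baseline over (0.25 f_p, 2 f_p) excluding peak neighborhoods
  inBand <- freq > 0.25 * fp & freq < 2 * fp
  near <- rep(FALSE, nb)
  for (b in c(bFp, fHalfPeaks, f34Peaks,
              which.min(abs(freq - fp / 4)), which.min(abs(freq - 2 * fp))))
    near[max(1, b - 2):min(nb, b + 2)] <- TRUE
  off <- a[inBand & !near]
  broadband <- length(off) > 0 && median(off) >= baselineFraction * aFp
  label <- if (broadband) "fibrillation"
  else if (length(f34Peaks) && length(fHalfPeaks)) "four_four"
  else if (length(fHalfPeaks)) "two_two"
  else "one_to_one"
  list(label = label, entrained = entrained,
       fHalfMultiplicity = length(fHalfPeaks),
       fHalfFreqs = freq[fHalfPeaks], f34Freqs = freq[f34Peaks])
}

#' Bipartition a phase map along its dominant axis
#'
#' For a phase map whose values cluster around two angles separated by pi
#' (the discordant-alternans signature at f_p / 2), finds the dominant
#' axis from the circular second moment and assigns each pixel to one of
#' the two half-planes.  Robust to a smooth propagation-delay phase
#' gradient as long as its spread stays below pi / 2.
#'
#' @param phase Phase matrix (radians).
#' @param mask Logical matrix restricting the partition.
#' @return List with \code{partition} (logical matrix, NA outside the
#'   mask) and \code{axis} (the axis angle in radians).
#' @export
phasePartition <- function(phase, mask = NULL) {
  if (is.null(mask)) mask <- !is.na(phase)
  z <- exp(2i * phase[mask])
  psi <- Arg(mean(z)) / 2
  part <- matrix(NA, nrow(phase), ncol(phase))
  part[mask] <- cos(phase[mask] - psi) >= 0
  list(partition = part, axis = psi)
}
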