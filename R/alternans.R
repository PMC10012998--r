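#' Pre-filter an optical movie for APD analysis
#'
#' Applies, in order: per-pixel linear detrend (least-squares line
#' removal), nearest-neighbor temporal averaging with a rectangular window
#' (default 7 frames), and spatial Gaussian smoothing (default kernel
#' truncated at a 4-pixel radius with sigma = 2 px).  Spatial smoothing is
#' mask-aware: no intensity bleeds across the tissue boundary.
#'
#' @param movie An [OpticalMovie-class] with more than
#'   \code{temporalWindow} frames.
#' @param temporalWindow Width of the rectangular moving average (frames).
#' @param spatialRadius Truncation radius of the Gaussian kernel (px).
#' @param spatialSigma Gaussian sigma (px).
#' @param detrend Apply the per-pixel detrend.
#' @return A preprocessed [OpticalMovie-class].
#' @export
preprocessMovie <- function(movie, temporalWindow = 7L, spatialRadius = 4L,
                            spatialSigma = 2, detrend = TRUE) {
  d <- dim(movie@frames)
  if (d[3] <= temporalWindow)
    stop("movie shorter than the temporal averaging window")
  m <- t(matrix(movie@frames, d[1] * d[2], d[3]))   # nt x npix
  if (detrend) m <- .detrendColumns(m)
  if (temporalWindow > 1) {
    kern <- rep(1 / temporalWindow, temporalWindow)
    m2 <- stats::filter(m, kern, sides = 2)
    ## fill the filter's NA margins with the nearest valid value
    half <- (temporalWindow - 1) %/% 2
    for (k in seq_len(half)) {
      m2[k, ] <- m2[half + 1, ]
      m2[d[3] - k + 1, ] <- m2[d[3] - half - ifelse(temporalWindow %% 2, 0, 1), ]
    }
    m <- m2
  }
  st <- array(t(m), d)
  if (spatialRadius > 0) {
    for (k in seq_len(d[3]))
      st[, , k] <- cpp_gaussian_blur(st[, , k], spatialSigma,
                                     as.integer(spatialRadius), movie@mask)
  }
  new("OpticalMovie", frames = st, frameInterval = movie@frameInterval,
      pixelSize = movie@pixelSize, mask = movie@mask,
      provenance = movie@provenance)
}

#' Extract the per-beat APD sequence of a single trace
#'
#' APD per beat is the time between the upward and the following downward
#' crossing of the threshold set at \code{thresholdFraction} of the trace
#' amplitude above the diastolic baseline (the per-trace 10th percentile),
#' with sub-frame resolution by linear interpolation.
#'
#' @param trace Numeric intensity/voltage trace.
#' @param frameInterval Sampling interval in ms.
#' @param thresholdFraction Threshold as a fraction of the amplitude
#'   (default 0.2, i.e. 20% of max).
#' @param baselineQuantile Quantile used as the diastolic baseline.
#' @param cycleLength Optional known pacing cycle length (ms), stored in
#'   the result.
#' @return An [APDSequence-class]; empty (zero beats) when no
#'   suprathreshold deflection exists.
#' @examples
#' tr <- rep(c(rep(1, 50), rep(0, 50)), 4)
#' apd(extractAPDSequence(tr, frameInterval = 2))  # ~100 ms each
#' @export
extractAPDSequence <- function(trace, frameInterval,
                               thresholdFraction = 0.2,
                               baselineQuantile = 0.1,
                               cycleLength = NA_real_) {
  det <- cpp_apd_traces(matrix(trace, ncol = 1), frameInterval,
                        thresholdFraction, baselineQuantile,
                        as.integer(length(trace)))
  n <- det$n_beats[1]
  new("APDSequence",
      apds = if (n) det$apd[seq_len(n), 1] else numeric(0),
      upstrokes = if (n) det$t_up[seq_len(n), 1] else numeric(0),
      cycleLength = cycleLength, thresholdFraction = thresholdFraction,
      captured = NA)
}

## per-pixel APD matrices for a whole movie: returns list(apd, t_up, n_beats)
.apdPixelwise <- function(movie, thresholdFraction = 0.2,
                          baselineQuantile = 0.1, maxBeats = 64L) {
  d <- dim(movie@frames)
  traces <- t(matrix(movie@frames, d[1] * d[2], d[3]))
  cpp_apd_traces(traces, movie@frameInterval, thresholdFraction,
                 baselineQuantile, as.integer(maxBeats))
}

#' Beat-to-beat APD difference map
#'
#' Computes pixel-wise dAPD(n) = APD(n+1) - APD(n) for a beat pair and
#' flags the nodal band |dAPD| <= 2 ms (non-alternating tissue and nodal
#' lines; the band reflects the temporal resolution of the recordings).
#' Pixels without both beats are flagged missing.
#'
#' @param movie An [OpticalMovie-class] (normally preprocessed with
#'   [preprocessMovie()]).
#' @param beats Beat pair: integer (n, n+1) indices, or \code{"last2"} for
#'   the last two fully detected beats, with the pair aligned across
#'   pixels (modal beat count) so clipped final beats cannot flip the
#'   sign parity.
#' @param nodalBand Half-width of the nodal band in ms.
#' @param thresholdFraction APD detection threshold fraction.
#' @return A [DeltaAPDMap-class] with label \code{"unclassified"}.
#' @export
deltaAPDMap <- function(movie, beats = "last2", nodalBand = 2,
                        thresholdFraction = 0.2) {
  d <- dim(movie@frames)
  det <- .apdPixelwise(movie, thresholdFraction)
  nb <- matrix(det$n_beats, d[1], d[2])
  delta <- matrix(NA_real_, d[1], d[2])
  if (identical(beats, "last2")) {
    ## last two detected beats per pixel, with the beat parity registered
    ## across pixels by upstroke time: beats clipped at either end of the
    ## movie shift a pixel's indexing by one beat, which would flip the
    ## alternans sign if pairs were matched by index alone
    valid <- which(movie@mask & nb >= 2)
    if (!length(valid)) stop("no pixel with two detected beats")
    tLast <- vapply(valid, function(k) det$t_up[nb[k], k], 0)
    clPx <- vapply(valid, function(k)
      if (nb[k] >= 3) median(diff(det$t_up[seq_len(nb[k]), k])) else NA_real_,
      0)
    clEst <- median(clPx, na.rm = TRUE)
    ref <- median(tLast)
    for (i in seq_along(valid)) {
      k <- valid[i]
      raw <- det$apd[nb[k], k] - det$apd[nb[k] - 1, k]
      par <- if (is.finite(clEst) && clEst > 0)
        round((ref - tLast[i]) / clEst) %% 2 else 0
      delta[k] <- if (par == 1) -raw else raw
    }
    bt <- c(NA_integer_, NA_integer_)
  } else {
    beats <- as.integer(beats)
    stopifnot(length(beats) == 2, beats[2] == beats[1] + 1L)
    idx <- which(nb >= beats[2])
    for (k in idx) delta[k] <- det$apd[beats[2], k] - det$apd[beats[1], k]
    bt <- beats
  }
  delta[!movie@mask] <- NA_real_
  missing <- is.na(delta) & movie@mask
  nodal <- !is.na(delta) & abs(delta) <= nodalBand
  new("DeltaAPDMap", delta = delta, nodal = nodal, missing = missing,
      mask = movie@mask, beats = bt, nodalBand = nodalBand,
      label = "unclassified", components = list())
}

#' Classify a dAPD map as concordant or discordant alternans
#'
#' Takes the connected components of sign(dAPD) outside the nodal band.
#' The label is \code{"none"} when the alternating area is below
#' \code{minAlternansFraction} of the tissue, \code{"CA"} when one sign
#' covers at least \code{concordantFraction} of the alternating area
#' (the whole tissue alternates in phase), and \code{"DA"} otherwise (at
#' least two out-of-phase regions separated by nodal lines).
#'
#' @param map A [DeltaAPDMap-class].
#' @param minAlternansFraction,concordantFraction Area thresholds.
#' @param minComponentPx Components smaller than this are ignored in the
#'   region summary.
#' @return The map with \code{label} and \code{components} filled in; the
#'   component summary lists per-region sign and area and the nodal-line
#'   pixel count.
#' @export
classifyPattern <- function(map, minAlternansFraction = 0.05,
                            concordantFraction = 0.95,
                            minComponentPx = 4L) {
  tissue <- map@mask & !is.na(map@delta)
  alt <- tissue & !map@nodal
  areaT <- sum(tissue)
  comps <- list(count = 0L, areas = integer(0), signs = integer(0),
                nodal_px = sum(map@nodal & tissue))
  if (areaT == 0 || sum(alt) < minAlternansFraction * areaT) {
    label <- "none"
  } else {
    out <- list()
    for (sgn in c(1, -1)) {
      m <- alt & (sign(map@delta) == sgn)
      m[is.na(m)] <- FALSE
      lab <- cpp_label_components(m)
      if (max(lab) > 0) {
        sz <- tabulate(lab[lab > 0])
        keep <- which(sz >= minComponentPx)
        for (ci in keep)
          out[[length(out) + 1L]] <- c(sign = sgn, area = sz[ci])
      }
    }
    if (length(out)) {
      sgns <- vapply(out, `[[`, 0, "sign")
      areas <- vapply(out, `[[`, 0, "area")
      comps <- list(count = length(out), areas = areas, signs = sgns,
                    nodal_px = sum(map@nodal & tissue))
      posArea <- sum(areas[sgns > 0]); negArea <- sum(areas[sgns < 0])
      label <- if (max(posArea, negArea) >=
                   concordantFraction * (posArea + negArea)) "CA" else "DA"
    } else label <- "none"
  }
  initialize(map, label = label, components = comps)
}

#' Count concordant/discordant transitions along a pacing-down sequence
#'
#' Number of CA <-> DA label changes along an ordered sequence of
#' classified maps (or labels); transitions into or out of \code{"none"}
#' are not counted.
#'
#' @param maps List of classified [DeltaAPDMap-class] objects, or a
#'   character vector of labels.
#' @return Integer transition count.
#' @examples
#' countTransitions(c("none", "CA", "CA", "DA"))  # 1
#' @export
countTransitions <- function(maps) {
  labels <- if (is.character(maps)) maps
  else vapply(maps, patternLabel, "")
  stopifnot(length(labels) >= 2)
  lab <- labels[labels %in% c("CA", "DA")]
  if (length(lab) < 2) return(0L)
  sum(lab[-1] != lab[-length(lab)])
}

#' Export a dAPD map summary
#'
#' Writes the dAPD grid as CSV plus a one-row summary (label, component
#' count and areas, nodal fraction).
#'
#' @param map A classified [DeltaAPDMap-class].
#' @param path Output path prefix; writes \code{<path>_dapd.csv} and
#'   \code{<path>_summary.csv}.
#' @export
writeDeltaAPDMap <- function(map, path) {
  write.csv(map@delta, paste0(path, "_dapd.csv"), row.names = FALSE)
  tissue <- map@mask & !is.na(map@delta)
  df <- data.frame(label = map@label,
                   n_components = map@components$count %||% 0L,
                   nodal_fraction = if (any(tissue))
                     mean(map@nodal[tissue]) else NA_real_,
                   areas = paste(map@components$areas %||% integer(0),
                                 collapse = ";"))
  write.csv(df, paste0(path, "_summary.csv"), row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
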