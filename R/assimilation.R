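#' Extract the tissue mask from a movie by signal-to-noise analysis
#'
#' Per-pixel SNR is the peak-to-peak range of the temporally smoothed,
#' detrended signal divided by a robust noise estimate (the median
#' absolute deviation of the first difference of the raw trace, scaled to
#' a sample standard deviation).  The mask keeps pixels with SNR at or
#' above the threshold, then retains the largest connected component and
#' fills enclosed holes.
#'
#' @param movie An [OpticalMovie-class] with at least 1 s of signal.
#' @param snrThreshold Minimum SNR (default 3).
#' @param temporalWindow Frames of temporal smoothing for the signal
#'   estimate.
#' @return Logical matrix.
#' @export
computeTissueMask <- function(movie, snrThreshold = 3, temporalWindow = 7L) {
  d <- dim(movie@frames)
  if (d[3] * movie@frameInterval < 1000)
    stop("need at least 1 s of signal for the SNR mask")
  m <- t(matrix(movie@frames, d[1] * d[2], d[3]))   # nt x npix
  noise <- apply(m, 2, function(x) mad(diff(x)) / sqrt(2))
  md <- .detrendColumns(m)
  sm <- stats::filter(md, rep(1 / temporalWindow, temporalWindow), sides = 2)
  p2p <- apply(sm, 2, function(x) diff(range(x, na.rm = TRUE)))
  ## reference: the expected peak-to-peak excursion of pure noise after the
  ## same temporal smoothing, so that noise-only pixels score near 1
  noiseP2P <- noise / sqrt(temporalWindow) * 2 * sqrt(2 * log(d[3]))
  snr <- p2p / pmax(noiseP2P, .Machine$double.eps)
  mask <- matrix(snr >= snrThreshold, d[1], d[2])
  if (!any(mask)) stop("empty tissue mask: no pixel reaches the SNR threshold")
  lab <- cpp_label_components(mask)
  sz <- tabulate(lab[lab > 0])
  mask <- lab == which.max(sz)
  ## fill holes: background components not touching the frame border
  bg <- cpp_label_components(!mask)
  border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  hole <- !(bg %in% setdiff(border, 0L)) & bg > 0
  mask | matrix(hole, d[1], d[2])
}

.normalizeH <- function(s, delta, mask) {
  r <- s - mean(s[mask])
  mx <- max(abs(r[mask]))
  if (mx == 0) {
    H <- matrix(1, nrow(s), ncol(s))
    list(H = H, degenerate = TRUE)
  } else {
    H <- delta * r / mx + 1
    H[!mask] <- 1
    list(H = H, degenerate = FALSE)
  }
}

#' Build a heterogeneity map from the optical ultrastructure
#'
#' Smooths the low-frequency amplitude field on the tissue mask (Gaussian
#' kernel, default radius 6 px with variance 5 px^2), then normalizes it
#' to H = delta * r / max|r| + 1 with r = s - mean(s): a positive field
#' with mask-mean exactly 1 and maximal deviation delta.  H is 1 outside
#' the mask.  A constant input yields H = 1 with the degenerate flag set.
#'
#' @param a05 Ultrastructure amplitude field (matrix; NAs allowed outside
#'   the mask), e.g. from [extractUltrastructure()].
#' @param delta Desired maximal variation, in [0, 1].
#' @param mask Logical tissue mask; default the non-NA pixels of a05.
#' @param smoothRadius Kernel truncation radius in px (0 disables).
#' @param smoothSigma Gaussian sigma in px (default sqrt(5)).
#' @return A [HeterogeneityMap-class] with source \code{"direct"}.
#' @examples
#' h <- makeHeterogeneityMap(matrix(1:3, 1), delta = 0.5, smoothRadius = 0)
#' hetField(h)  # 0.5, 1.0, 1.5
#' @export
makeHeterogeneityMap <- function(a05, delta = 0.5, mask = NULL,
                                 smoothRadius = 6L, smoothSigma = sqrt(5)) {
  stopifnot(delta >= 0, delta <= 1)
  if (is.null(mask)) mask <- !is.na(a05)
  if (!any(mask)) stop("empty mask")
  s <- a05
  s[!mask] <- 0
  if (smoothRadius > 0)
    s <- cpp_gaussian_blur(s, smoothSigma, as.integer(smoothRadius), mask)
  nh <- .normalizeH(s, delta, mask)
  new("HeterogeneityMap", H = nh$H, delta = delta, source = "direct",
      mask = mask, degenerate = nh$degenerate,
      smoothing = list(radius = smoothRadius, sigma = smoothSigma))
}

#' Reciprocal heterogeneity map
#'
#' Takes the pixel-wise reciprocal of an existing (normalized)
#' heterogeneity field and renormalizes it to mean 1 and maximal
#' variation delta: the reciprocal map emphasizes low-amplitude areas of
#' the ultrastructure and is the default source for the APD-regulating
#' parameter heterogeneity.
#'
#' @param h A [HeterogeneityMap-class], or a positive matrix (e.g. the raw
#'   ultrastructure amplitude; this alternative source stays strictly
#'   positive even at delta = 1, where the reciprocal of a normalized map
#'   can be undefined).
#' @param delta Maximal variation of the result, in [0, 1].
#' @param mask Tissue mask; default taken from \code{h}.
#' @param smoothRadius,smoothSigma Optional Gaussian smoothing (px),
#'   applied to raw-matrix input before inversion (normalized maps are
#'   already smoothed).
#' @return A [HeterogeneityMap-class] with source \code{"reciprocal"}.
#' @export
makeReciprocalMap <- function(h, delta = 0.5, mask = NULL,
                              smoothRadius = 0L, smoothSigma = sqrt(5)) {
  stopifnot(delta >= 0, delta <= 1)
  if (is(h, "HeterogeneityMap")) {
    if (is.null(mask)) mask <- h@mask
    h <- h@H
    smoothRadius <- 0L
  }
  if (is.null(mask)) mask <- !is.na(h)
  h[!mask] <- 1
  if (any(h[mask] <= 0)) stop("nonpositive values: reciprocal undefined")
  if (smoothRadius > 0)
    h <- cpp_gaussian_blur(h, smoothSigma, as.integer(smoothRadius), mask)
  nh <- .normalizeH(1 / h, delta, mask)
  new("HeterogeneityMap", H = nh$H, delta = delta, source = "reciprocal",
      mask = mask, degenerate = nh$degenerate,
      smoothing = list(radius = smoothRadius, sigma = smoothSigma))
}

#' Model variants of the heterogeneity assimilation
#'
#' Bundles which heterogeneity field multiplies the diffusivities
#' (D_par, D_perp) and which multiplies the APD-regulating time constants
#' (tau_w+, tau_so, tau_si): \code{homogeneous} uses neither, \code{H1}
#' only diffusivity, \code{H2} only the APD constants, \code{H3} both.
#'
#' @param name One of \code{"homogeneous"}, \code{"H1"}, \code{"H2"},
#'   \code{"H3"}.
#' @param diffusivityMap A [HeterogeneityMap-class] (required for H1/H3).
#' @param apdMap A [HeterogeneityMap-class] (required for H2/H3).
#' @return List of class \code{"modelVariant"}.
#' @export
modelVariant <- function(name = c("homogeneous", "H1", "H2", "H3"),
                         diffusivityMap = NULL, apdMap = NULL) {
  name <- match.arg(name)
  if (name %in% c("H1", "H3") && is.null(diffusivityMap))
    stop(name, " needs a diffusivity heterogeneity map")
  if (name %in% c("H2", "H3") && is.null(apdMap))
    stop(name, " needs an APD heterogeneity map")
  if (name %in% c("homogeneous", "H2")) diffusivityMap <- NULL
  if (name %in% c("homogeneous", "H1")) apdMap <- NULL
  structure(list(name = name, diffusivity = diffusivityMap, apd = apdMap),
            class = "modelVariant")
}

#' Apply a heterogeneity variant to the model parameters
#'
#' Produces the per-pixel parameter fields p(x, y) = p_bar * H(x, y): the
#' diffusivity map scales D_par and D_perp; the APD map scales the
#' aggregate constants tau_w+ and tau_so (both sub-constants of each) and
#' tau_si, exposed as a single tauScale grid.  All other parameters stay
#' uniform.
#'
#' @param params An [APModelParameters-class].
#' @param variant A variant from [modelVariant()].
#' @param nx,ny Grid size (required for the homogeneous variant; otherwise
#'   taken from the maps).
#' @return List with matrices \code{DPar}, \code{DPerp}, \code{tauScale},
#'   ready for [tissueDomain()].
#' @export
applyHeterogeneity <- function(params, variant, nx = NULL, ny = NULL) {
  pv <- parValues(params)
  hD <- variant$diffusivity
  hA <- variant$apd
  ref <- if (!is.null(hD)) hD@H else if (!is.null(hA)) hA@H
  if (is.null(ref)) {
    if (is.null(nx)) stop("grid size required for the homogeneous variant")
    ref <- matrix(1, nx, ny)
  }
  nx <- nrow(ref); ny <- ncol(ref)
  gD <- if (is.null(hD)) matrix(1, nx, ny) else hD@H
  gA <- if (is.null(hA)) matrix(1, nx, ny) else hA@H
  if (!all(dim(gA) == c(nx, ny)))
    stop("heterogeneity maps must share the domain grid")
  ## a vanishing time-constant scale is nonphysical; vanishing diffusivity
  ## (an uncoupled spot, the delta = 1 boundary) is admissible
  if (any(gD < 0) || any(gA <= 0))
    stop("nonphysical heterogeneity: H must be positive")
  list(DPar = pv[["D_par"]] * gD, DPerp = pv[["D_perp"]] * gD,
       tauScale = gA)
}

#' Resample a heterogeneity map onto a simulation grid
#'
#' Bilinear interpolation of H from the movie resolution onto an nx-by-ny
#' solver grid, followed by renormalization to mask-mean 1 and maximal
#' deviation delta.
#'
#' @param h A [HeterogeneityMap-class].
#' @param nx,ny Target grid size.
#' @return A [HeterogeneityMap-class] on the target grid (full-grid mask).
#' @export
resampleHeterogeneityMap <- function(h, nx, ny) {
  H <- h@H
  sx <- seq(1, nrow(H), length.out = nx)
  sy <- seq(1, ncol(H), length.out = ny)
  out <- .bilinear(H, outer(sx, rep(1, ny)), outer(rep(1, nx), sy))
  mask <- matrix(TRUE, nx, ny)
  nh <- .normalizeH(out, h@delta, mask)
  new("HeterogeneityMap", H = nh$H, delta = h@delta, source = h@source,
      mask = mask, degenerate = nh$degenerate, smoothing = h@smoothing)
}

.bilinear <- function(m, xi, yi) {
  nx <- nrow(m); ny <- ncol(m)
  x0 <- pmin(pmax(floor(xi), 1), nx - 1); y0 <- pmin(pmax(floor(yi), 1), ny - 1)
  fx <- xi - x0; fy <- yi - y0
  i00 <- cbind(as.vector(x0), as.vector(y0))
  i10 <- cbind(as.vector(x0 + 1), as.vector(y0))
  i01 <- cbind(as.vector(x0), as.vector(y0 + 1))
  i11 <- cbind(as.vector(x0 + 1), as.vector(y0 + 1))
  out <- (1 - fx) * (1 - fy) * m[i00] + fx * (1 - fy) * m[i10] +
    (1 - fx) * fy * m[i01] + fx * fy * m[i11]
  if (is.matrix(xi)) matrix(out, nrow(xi), ncol(xi)) else out
}

#' Sample a heterogeneity map along a polyline
#'
#' Bilinear interpolation of H along a pixel-coordinate polyline, with the
#' arc-length coordinate attached: a 1D cut usable as a cable parameter
#' profile.
#'
#' @param h A [HeterogeneityMap-class].
#' @param path Two-column matrix of (x, y) pixel coordinates (vertices of
#'   the polyline).
#' @param step Sampling step along the path in pixels.
#' @return data.frame with columns \code{arc_px}, \code{x}, \code{y},
#'   \code{H}.
#' @export
extract1dCut <- function(h, path, step = 1) {
  stopifnot(ncol(path) == 2, nrow(path) >= 2)
  pts <- NULL
  for (k in seq_len(nrow(path) - 1)) {
    a <- path[k, ]; b <- path[k + 1, ]
    len <- sqrt(sum((b - a)^2))
    tt <- seq(0, 1, by = step / max(len, step))
    seg <- cbind(a[1] + tt * (b[1] - a[1]), a[2] + tt * (b[2] - a[2]))
    if (k > 1) seg <- seg[-1, , drop = FALSE]
    pts <- rbind(pts, seg)
  }
  xi <- pts[, 1]; yi <- pts[, 2]
  nearest <- cbind(pmin(pmax(round(xi), 1), nrow(h@H)),
                   pmin(pmax(round(yi), 1), ncol(h@H)))
  if (any(!h@mask[nearest])) stop("path exits the tissue mask")
  d <- c(0, cumsum(sqrt(diff(xi)^2 + diff(yi)^2)))
  data.frame(arc_px = d, x = xi, y = yi, H = .bilinear(h@H, xi, yi))
}
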