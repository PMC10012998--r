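.sidecarPath <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

## atomic write: write to a temp file in the same directory, then rename
.atomically <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = paste0(".", basename(path)))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Write / read an optical movie as multi-page TIFF with a JSON sidecar
#'
#' The canonical interchange container: one TIFF page per frame (32-bit
#' float by default, or 16-bit unsigned with a recorded scale) plus a JSON
#' sidecar holding \code{frame_interval_ms}, \code{pixel_size_um},
#' provenance, bit depth and the tissue mask.  Writes are atomic
#' (temp file + rename).  \code{readMovie} errors naming any missing
#' metadata field.
#'
#' @param movie An [OpticalMovie-class].
#' @param path Output TIFF path; the sidecar goes to the same basename
#'   with extension \code{.json}.
#' @param bits 32 (float) or 16 (unsigned, exact for integer data in
#'   [0, 65535]).
#' @return \code{readMovie} returns an [OpticalMovie-class].
#' @export
writeMovie <- function(movie, path, bits = 32L) {
  stopifnot(bits %in% c(16L, 32L))
  d <- dim(movie@frames)
  ## TIFF samples live in [0, 1]; keep the affine map in the sidecar
  if (bits == 16L) {
    offset <- 0; scale <- 65535
  } else {
    rng <- range(movie@frames)
    offset <- rng[1]
    scale <- if (diff(rng) > 0) diff(rng) else 1
  }
  pages <- lapply(seq_len(d[3]), function(k)
    (movie@frames[, , k] - offset) / scale)
  .atomically(path, function(tmp)
    tiff::writeTIFF(pages, tmp, bits.per.sample = bits))
  meta <- list(frame_interval_ms = movie@frameInterval,
               pixel_size_um = movie@pixelSize,
               provenance = movie@provenance, bits = bits,
               offset = offset, scale = scale,
               nx = d[1], ny = d[2], nt = d[3],
               mask = apply(movie@mask, 1, as.integer))
  .atomically(.sidecarPath(path), function(tmp)
    jsonlite::write_json(meta, tmp, auto_unbox = TRUE, digits = NA))
  invisible(path)
}

#' @rdname writeMovie
#' @export
readMovie <- function(path) {
  sc <- .sidecarPath(path)
  if (!file.exists(sc))
    stop("missing sidecar ", sc,
         ": required fields frame_interval_ms, pixel_size_um absent")
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  need <- c("frame_interval_ms", "pixel_size_um")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("movie metadata missing field(s): ", paste(miss, collapse = ", "))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  d <- c(dim(pages[[1]])[1:2], length(pages))
  st <- array(unlist(pages), d)
  st <- st * (meta$scale %||% 1) + (meta$offset %||% 0)
  mask <- if (!is.null(meta$mask)) t(matrix(as.logical(meta$mask),
                                            ncol = d[1])) else NULL
  opticalMovie(st, frameInterval = meta$frame_interval_ms,
               pixelSize = meta$pixel_size_um, mask = mask,
               provenance = meta$provenance %||% "experimental")
}

.paletteDAPD <- function(delta, nodalBand, lim) {
  ramp <- colorRamp(c("#2166ac", "#f7f7f7", "#b2182b"))
  z <- pmax(pmin(delta / lim, 1), -1) / 2 + 0.5
  col <- ramp(z) / 255
  nodal <- !is.na(delta) & abs(delta) <= nodalBand
  col[nodal, ] <- matrix(rep(c(0.55, 0.55, 0.55), each = sum(nodal)),
                         ncol = 3)
  col
}

#' Render maps to PNG
#'
#' dAPD maps use a diverging palette with the nodal band in a neutral
#' grey; phase maps use a cyclic palette (so -pi and pi render
#' identically); amplitude maps use a linear palette scaled min-max over
#' the mask.  Pixels outside the mask are black.
#'
#' @param map Matrix, or a [DeltaAPDMap-class] for \code{type = "dapd"}.
#' @param path Output PNG path.
#' @param type \code{"dapd"}, \code{"phase"} or \code{"amplitude"}.
#' @param mask Logical matrix; defaults to finite pixels.
#' @param nodalBand Nodal half-width (ms) for dAPD rendering.
#' @return The path, invisibly.
#' @export
renderMaps <- function(map, path, type = c("dapd", "phase", "amplitude"),
                       mask = NULL, nodalBand = 2) {
  type <- match.arg(type)
  if (is(map, "DeltaAPDMap")) {
    if (is.null(mask)) mask <- map@mask
    nodalBand <- map@nodalBand
    map <- map@delta
  }
  if (is.null(mask)) mask <- is.finite(map)
  v <- as.vector(map)
  img <- matrix(0, length(v), 3)
  ok <- as.vector(mask) & is.finite(v)
  if (any(ok)) {
    if (type == "dapd") {
      lim <- max(abs(v[ok]), nodalBand * 1.5)
      img[ok, ] <- .paletteDAPD(v[ok], nodalBand, lim)
    } else if (type == "phase") {
      img[ok, ] <- t(grDevices::col2rgb(hsv(((v[ok] + pi) / (2 * pi)) %% 1,
                                            0.9, 0.95))) / 255
    } else {
      rng <- range(v[ok])
      z <- if (diff(rng) > 0) (v[ok] - rng[1]) / diff(rng) else 0.5
      img[ok, ] <- colorRamp(c("black", "#35608d", "#35b779",
                               "#fde725"))(z) / 255
    }
  }
  arr <- aperm(array(img, c(nrow(map), ncol(map), 3)), c(2, 1, 3))
  .atomically(path, function(tmp) png::writePNG(arr, tmp))
  invisible(path)
}

.defaultPipelineConfig <- function() {
  list(
    seed = 1L,
    scene = list(nx = 48L, ny = 48L, duration = 10, frameInterval = 2,
                 fp = 7, pattern = "two_two", apdBase = 100, d = 15,
                 noiseSigma = 0.02, correlationLength = 8, cvField = 0.15),
    delta = 0.5,
    variant = "H3",
    sim = list(nx = 60L, ny = 60L, dx = 0.05, dt = 0.02,
               frequencies = c(3, 5), beats = 6L, site = "base",
               recordInterval = 2))
}

.validateConfig <- function(config) {
  if (!is.numeric(config$delta) || config$delta < 0 || config$delta > 1)
    stop("config validation: delta must lie in [0, 1]")
  if (!config$variant %in% c("homogeneous", "H1", "H2", "H3"))
    stop("config validation: unknown variant ", config$variant)
  s <- config$sim
  if (any(s$frequencies <= 0) || s$beats < 1)
    stop("config validation: pacing frequencies must be positive, beats >= 1")
  if (s$dt <= 0 || s$dx <= 0)
    stop("config validation: dt and dx must be positive")
  sc <- config$scene
  if (sc$noiseSigma < 0)
    stop("config validation: noiseSigma must be non-negative")
  invisible(TRUE)
}

#' Run the closed-loop demonstration pipeline
#'
#' Orchestrates the full loop on synthetic data: (1) generate a synthetic
#' movie over a random ultrastructure; (2) extract the tissue mask and the
#' 0.5 Hz ultrastructure and build the H1 (direct) and H2 (reciprocal)
#' heterogeneity maps; (3) simulate the chosen model variant under the
#' pacing schedule; (4) run FFI and dAPD analysis on the simulated
#' recording; (5) render maps.  Writes a manifest (config echo, seeds,
#' package version, file checksums) and is deterministic for fixed seeds.
#'
#' @param config Nested configuration list; missing entries fall back to
#'   the defaults (see the vignette).  May also be a path to a YAML file.
#' @param outDir Output directory (created if needed).
#' @return Invisibly, a list with the manifest and the main in-memory
#'   results.
#' @export
runPipeline <- function(config = list(), outDir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- modifyList(.defaultPipelineConfig(), config)
  .validateConfig(config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  stagesDone <- character(0)
  logStage <- function(name) {
    message(sprintf("[%s] stage %s", format(Sys.time(), "%H:%M:%S"), name))
    stagesDone <<- c(stagesDone, name)
  }
  sc <- config$scene

  logStage("synth")
  g <- generateUltrastructureField(sc$nx, sc$ny, sc$correlationLength,
                                   sc$cvField, seed = config$seed)
  scene <- sceneSpec(nx = sc$nx, ny = sc$ny, duration = sc$duration,
                     frameInterval = sc$frameInterval,
                     regionMap = antiphaseRegions(sc$nx, sc$ny),
                     rhythms = list(
                       rhythmSpec(sc$fp, sc$pattern, apdBase = sc$apdBase,
                                  d = sc$d),
                       rhythmSpec(sc$fp, sc$pattern, apdBase = sc$apdBase,
                                  d = sc$d, phase = pi)),
                     ultrastructure = g, noiseSigma = sc$noiseSigma,
                     seed = config$seed + 1L)
  movie <- generateMovie(scene)
  writeMovie(movie, file.path(outDir, "movie.tif"))

  logStage("assimilate")
  mask <- computeTissueMask(movie)
  a05 <- extractUltrastructure(movie)
  h1 <- makeHeterogeneityMap(a05, delta = config$delta, mask = mask)
  h2 <- makeReciprocalMap(h1, delta = config$delta)
  renderMaps(a05, file.path(outDir, "ultrastructure.png"), "amplitude",
             mask = mask)

  logStage("simulate")
  simc <- config$sim
  variant <- modelVariant(config$variant,
                          diffusivityMap = resampleHeterogeneityMap(
                            h1, simc$nx, simc$ny),
                          apdMap = resampleHeterogeneityMap(
                            h2, simc$nx, simc$ny))
  params <- apParameters()
  fields <- applyHeterogeneity(params, variant, simc$nx, simc$ny)
  dom <- tissueDomain(simc$nx, simc$ny, dx = simc$dx, DPar = fields$DPar,
                      DPerp = fields$DPerp, tauScale = fields$tauScale,
                      params = params)
  prot <- stimulusProtocol(dom, site = simc$site,
                           schedule = data.frame(
                             frequency_hz = simc$frequencies,
                             beats = simc$beats))
  rec <- runProtocol(dom, params, prot, dt = simc$dt,
                     recordInterval = simc$recordInterval)

  logStage("ffi")
  stg <- stages(rec)
  lastStage <- stg[nrow(stg), ]
  simMovie <- asOpticalMovie(rec, frameRange = c(lastStage$first_frame,
                                                 lastStage$last_frame))
  fs <- ffiTransform(simMovie)
  fmap <- extractFrequencyMap(fs, lastStage$frequency_hz / 2)
  renderMaps(fmap$phase, file.path(outDir, "phase_fhalf.png"), "phase",
             mask = simMovie@mask)

  logStage("apd")
  dmap <- classifyPattern(deltaAPDMap(
    asOpticalMovie(rec, frameRange = c(lastStage$last2_first_frame,
                                       lastStage$last_frame))))
  renderMaps(dmap, file.path(outDir, "dapd.png"))
  writeDeltaAPDMap(dmap, file.path(outDir, "dapd"))

  files <- list.files(outDir, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest <- list(
    package = "cardialt",
    version = as.character(utils::packageVersion("cardialt")),
    config = config, stages = stagesDone,
    checksums = as.list(tools::md5sum(sort(files))))
  .atomically(file.path(outDir, "manifest.json"), function(tmp)
    jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA))
  invisible(list(manifest = manifest, movie = movie, mask = mask,
                 h1 = h1, h2 = h2, recording = rec, phaseMap = fmap,
                 dapd = dmap))
}
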