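#' Read a frame stack from disk
#'
#' Supports a multi-page TIFF file or a directory of single-frame images
#' (PNG or TIFF), taken in lexicographic filename order. All frames must
#' share dimensions; color images are converted to grayscale by channel
#' averaging.
#'
#' @param path TIFF file or directory.
#' @param fps frame rate metadata (Hz).
#' @param mmPerPx world-scale hint.
#' @return a [FrameStack-class] (8-bit).
#' @export
readFrames <- function(path, fps = 500, mmPerPx = 10 / 30) {
  toGray <- function(img) {
    if (length(dim(img)) == 3L) img <- apply(img, c(1L, 2L), mean)
    img
  }
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (!length(files)) stop("no PNG/TIFF frames found in ", path)
    frames <- lapply(files, function(f) {
      img <- if (grepl("\\.png$", f, ignore.case = TRUE))
        png::readPNG(f) else tiff::readTIFF(f)
      toGray(img)
    })
  } else {
    if (!file.exists(path)) stop("no such file: ", path)
    frames <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(frames)) frames <- list(frames)
    frames <- lapply(frames, toGray)
  }
  dims <- unique(lapply(frames, dim))
  if (length(dims) != 1L)
    stop("frames have mixed dimensions: ",
         paste(vapply(dims, paste, "", collapse = "x"), collapse = " vs "))
  frames <- lapply(frames, function(f) .roundHalfAway(f * 255))
  frameStack(frames, fps = fps, mmPerPx = mmPerPx)
}

#' Write a frame stack as a multi-page 8-bit TIFF
#'
#' @param stack a [FrameStack-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeFrames <- function(stack, path) {
  frames <- lapply(seq_len(nFrames(stack)), function(i)
    pmin(pmax(stack@frames[, , i] / stack@range, 0), 1))
  tiff::writeTIFF(frames, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read and write run configuration
#'
#' The run configuration is a YAML file holding input paths, filter and
#' tracker settings, stride options and the seed; an annotated default
#' ships with the package (`system.file("extdata", "config.yaml",
#' package = "HexaTrack")`).
#'
#' @param path YAML file.
#' @return `readRunConfig`: a list with elements `paths`, `filter`
#'   ([FilterSettings-class]), `tracker` ([TrackerSettings-class]),
#'   `strides` (list), `seed`.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  fs <- do.call(filterSettings, as.list(cfg$filter %||% list()))
  ts <- do.call(trackerSettings, as.list(cfg$tracker %||% list()))
  list(paths = cfg$paths %||% list(), filter = fs, tracker = ts,
       strides = cfg$strides %||% list(band = c(0.5, 15)),
       seed = cfg$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.settingsHash <- function(...) {
  objs <- list(...)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(objs, tmp, version = 2L, compress = FALSE)
  unname(tools::md5sum(tmp))
}

.fileHashes <- function(paths) {
  paths <- unlist(paths)
  if (!length(paths)) return(list())
  paths <- paths[file.exists(paths)]
  if (!length(paths)) return(list())
  as.list(tools::md5sum(paths))
}

#' Export the full set of run results
#'
#' Writes the canonical data products to `outDir`: tracked positions
#' (`track.csv`, plus a lossless `track.json`), joint angles
#' (`angles.csv`), stride events and summaries (`stride_events.csv`,
#' `stride_summary.csv`), the body frame (`body_frame.yaml`), and a
#' `manifest.json` capturing package version, settings hash, seed, input
#' hashes and per-product row counts - enough to reproduce the run.
#'
#' @param state a [TrackState-class] (raw coordinates).
#' @param angles data.frame from [computeAllAngles()] (or NULL).
#' @param analysis list from [analyzeStrides()] (or NULL).
#' @param outDir output directory (created if needed).
#' @param bodyFrame a [BodyFrame-class] (or NULL).
#' @param settings a [TrackerSettings-class] used for the run.
#' @param filter a [FilterSettings-class] used for the run.
#' @param seed seed recorded in the manifest.
#' @param inputs named list of input file paths to hash.
#' @return the manifest, invisibly.
#' @export
exportResults <- function(state, angles = NULL, analysis = NULL,
                          outDir = ".", bodyFrame = NULL,
                          settings = trackerSettings(),
                          filter = filterSettings(), seed = 1L,
                          inputs = list()) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  counts <- list()
  writeTrackCsv(state, file.path(outDir, "track.csv"))
  writeTrackJson(state, file.path(outDir, "track.json"))
  counts$track_rows <- nFrames(state) * length(state@markers)
  counts$estimates_3d <- nEstimates3d(state)
  counts$points_2d <- nPoints2d(state)
  counts$reverted <- sum(state@status == 3L)
  if (!is.null(angles)) {
    writeAnglesCsv(angles, file.path(outDir, "angles.csv"))
    counts$angle_rows <- nrow(angles)
  }
  if (!is.null(analysis)) {
    writeStridesCsv(analysis, file.path(outDir, "stride_events.csv"),
                    file.path(outDir, "stride_summary.csv"))
    counts$stride_events <- nrow(analysis$events@events)
    counts$strides <- nrow(analysis$strides)
  }
  if (!is.null(bodyFrame))
    writeBodyFrame(bodyFrame, file.path(outDir, "body_frame.yaml"))
  manifest <- list(
    package = "HexaTrack",
    version = as.character(utils::packageVersion("HexaTrack")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    settings_hash = .settingsHash(settings, filter),
    settings = list(
      tracker = list(baseRadius = settings@baseRadius,
                     depthScale = settings@depthScale,
                     thcRadius = settings@thcRadius,
                     enlargeFactor = settings@enlargeFactor,
                     maxEnlarge = settings@maxEnlarge,
                     triErrorMax = settings@triErrorMax,
                     segLenFactor = settings@segLenFactor,
                     dimFraction = settings@dimFraction,
                     dimFloor = settings@dimFloor),
      filter = list(nBackgroundFrames = filter@nBackgroundFrames,
                    backgroundSigma = filter@backgroundSigma,
                    medianWidth = filter@medianWidth)),
    inputs = .fileHashes(inputs),
    counts = counts,
    schemas = list(
      track.csv = "frame,marker,x,y,z,status,tri_error",
      angles.csv = "frame,time_s,leg,joint,angle_deg,status",
      stride_events.csv = "leg,method,type,time_s,inherited",
      stride_summary.csv = paste0("leg,method,n,mean_period,sd_period,",
                                  "sem_period,mean_duty,sd_duty,sem_duty")))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Summarize tracking error against a gold standard
#'
#' Reproduces the accuracy evaluation used to validate assisted tracking
#' against manual digitization: per-marker mean and standard deviation of
#' the 3D Euclidean distance between two tracks of the same bout.
#'
#' @param state a [TrackState-class] (or array) being evaluated.
#' @param truth a [TrackState-class] (or nframes x nmarkers x 3 array)
#'   gold standard, same marker order.
#' @param markers optional character subset of markers.
#' @return data.frame `marker`, `n`, `mean_mm`, `sd_mm`, plus an
#'   `overall` attribute with the pooled mean.
#' @export
evaluateTrack <- function(state, truth, markers = NULL) {
  p <- if (is(state, "TrackState")) state@pos3d else state
  q <- if (is(truth, "TrackState")) truth@pos3d else truth
  mk <- if (is(state, "TrackState")) state@markers else dimnames(p)[[2L]]
  if (!identical(dim(p), dim(q)))
    stop("track and truth dimensions differ")
  sel <- if (is.null(markers)) seq_along(mk) else match(markers, mk)
  if (anyNA(sel)) stop("unknown marker in selection")
  rows <- lapply(sel, function(mi) {
    d <- sqrt(rowSums((p[, mi, ] - q[, mi, ])^2))
    d <- d[is.finite(d)]
    data.frame(marker = mk[mi], n = length(d), mean_mm = mean(d),
               sd_mm = stats::sd(d))
  })
  out <- do.call(rbind, rows)
  alld <- unlist(lapply(sel, function(mi) {
    d <- sqrt(rowSums((p[, mi, ] - q[, mi, ])^2))
    d[is.finite(d)]
  }))
  attr(out, "overall") <- mean(alld)
  out
}
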