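.STATUS_LEVELS <- c("none", "user", "tracked", "reverted")

#' Construct an empty track state
#'
#' @param nframes number of frames.
#' @param topology a [MarkerTopology-class] (or character marker names).
#' @param fps frame rate (Hz).
#' @return a [TrackState-class] with all entries untracked.
#' @export
trackState <- function(nframes, topology, fps = 500) {
  mk <- if (is(topology, "MarkerTopology")) markers(topology)
        else as.character(topology)
  nm <- length(mk)
  new("TrackState",
      pos3d = array(NA_real_, c(nframes, nm, 3L)),
      pos2d = array(NA_real_, c(nframes, nm, 2L, 2L)),
      status = matrix(0L, nframes, nm, dimnames = list(NULL, mk)),
      triError = matrix(NA_real_, nframes, nm),
      markers = mk, fps = fps)
}

#' @rdname TrackState-class
#' @export
setMethod("nFrames", "TrackState", function(object) dim(object@pos3d)[1L])

#' @rdname TrackState-class
#' @export
setMethod("positions3d", "TrackState", function(object) object@pos3d)

#' @rdname TrackState-class
#' @export
setMethod("positions2d", "TrackState", function(object) object@pos2d)

#' @rdname TrackState-class
#' @export
setMethod("trackStatus", "TrackState", function(object) object@status)

#' @rdname TrackState-class
#' @export
setMethod("triangulationErrors", "TrackState",
          function(object) object@triError)

#' @rdname nEstimates3d
#' @export
setMethod("nEstimates3d", "TrackState", function(object)
  sum(object@status > 0L))

#' @rdname nEstimates3d
#' @export
setMethod("nPoints2d", "TrackState", function(object)
  2L * sum(object@status > 0L))

setMethod("show", "TrackState", function(object) {
  st <- object@status
  cat(sprintf("TrackState: %d frames x %d markers @ %g fps\n",
              nrow(st), ncol(st), object@fps))
  tab <- table(factor(.STATUS_LEVELS[st + 1L], levels = .STATUS_LEVELS))
  cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
      "\n", sep = "")
  invisible(object)
})

# --- keyframes --------------------------------------------------------------

#' Construct a keyframe set
#'
#' @param annotations named list (names = frame indices); each element a
#'   named list mapping marker to `list(cam1 = c(u, v), cam2 = c(u, v))`.
#' @return a [KeyframeSet-class].
#' @export
keyframeSet <- function(annotations = list()) {
  if (length(annotations))
    annotations <- annotations[order(as.integer(names(annotations)))]
  new("KeyframeSet", annotations = annotations)
}

#' @rdname keyframeIndices
#' @export
setMethod("keyframeIndices", "KeyframeSet", function(object)
  sort(as.integer(names(object@annotations))))

setMethod("show", "KeyframeSet", function(object) {
  idx <- keyframeIndices(object)
  cat(sprintf("KeyframeSet: %d keyframes", length(idx)))
  if (length(idx)) cat(" at frames ", paste(idx, collapse = ", "), sep = "")
  cat("\n")
  invisible(object)
})

# build a keyframe annotation from projected 3D marker positions
.annotateFromPositions <- function(pos3d, cameras, markerNames) {
  ann <- list()
  for (i in seq_along(markerNames)) {
    ann[[markerNames[i]]] <- list(
      cam1 = as.numeric(projectPoints(cameras[[1L]], pos3d[i, ])),
      cam2 = as.numeric(projectPoints(cameras[[2L]], pos3d[i, ])))
  }
  ann
}

#' Read and write keyframe annotations as JSON
#'
#' Format: an object mapping frame index to marker to per-camera `[u, v]`
#' arrays (`{"12": {"R1.ThC": {"cam1": [u, v], "cam2": [u, v]}}}`).
#'
#' @param keyframes a [KeyframeSet-class].
#' @param path JSON file path.
#' @return `readKeyframes` a [KeyframeSet-class]; `writeKeyframes` the
#'   path, invisibly.
#' @export
writeKeyframes <- function(keyframes, path) {
  jsonlite::write_json(keyframes@annotations, path, auto_unbox = FALSE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeKeyframes
#' @export
readKeyframes <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  ann <- lapply(raw, function(fr) lapply(fr, function(mk)
    lapply(mk, function(uv) as.numeric(unlist(uv)))))
  keyframeSet(ann)
}

# --- single tracking step ---------------------------------------------------

#' Track one marker from one frame to the next
#'
#' The core tracking step: the best a-priori estimate of a marker at the
#' target frame is its last known position. A search ellipsoid built there
#' (see [buildSearchEllipsoid()]) is projected into each camera; the
#' brightness-weighted centroid inside each ellipse is the new 2D
#' measurement. A centroid dimmer than `dimFraction` of the frame's median
#' brightness triggers an enlarged retry for that camera only (at most
#' `maxEnlarge` times); a region with no signal at all marks the point
#' lost outright. The two centroids are triangulated; the step is
#' accepted only if both centroids are bright enough, the triangulation
#' error is within `triErrorMax`, and the leg segment length changed by at
#' most `segLenFactor` relative to `refLength`. Otherwise the marker is
#' deemed lost (possibly occluded) and reverts to its last known 3D
#' position.
#'
#' @param lastPos numeric(3), marker position at the source frame.
#' @param proximalPos numeric(3) position of the proximal neighbour at the
#'   target frame (already updated; NULL at the ThC root).
#' @param depth chain depth k.
#' @param refLength reference segment length (at the nearest user-defined
#'   frame); NA skips the segment gate.
#' @param cameras list of two [CameraModel-class] objects.
#' @param images list of two preprocessed frame matrices (target frame).
#' @param medianBrightness numeric(2), per-camera median brightness of the
#'   target frames.
#' @param settings a [TrackerSettings-class].
#' @return list with `pos` (numeric(3)), `pos2d` (2 x 2, rows = cameras),
#'   `triError`, `status` ("tracked" or "reverted").
#' @export
trackPointStep <- function(lastPos, proximalPos, depth, refLength,
                           cameras, images, medianBrightness,
                           settings = trackerSettings()) {
  cents <- vector("list", 2L)
  bright <- c(FALSE, FALSE)
  for (ci in 1:2) {
    thr <- max(settings@dimFraction * medianBrightness[ci],
               settings@dimFloor)
    enlarge <- 0L
    repeat {
      e <- buildSearchEllipsoid(lastPos, proximalPos, depth, settings,
                                enlarge)
      ell <- tryCatch(projectEllipsoid(cameras[[ci]], e),
                      error = function(err) NULL)
      wc <- if (is.null(ell)) list(point = c(NA, NA), brightness = 0,
                                   ok = FALSE)
            else weightedCentroid(images[[ci]], ell)
      if (wc$ok && wc$brightness >= thr) {
        cents[[ci]] <- wc$point; bright[ci] <- TRUE
        break
      }
      # a region with no signal at all means the marker is gone (likely
      # occluded): enlarging would only capture a neighbouring marker.
      # Only a present-but-dim centroid earns an enlarged retry.
      if (!wc$ok || enlarge >= settings@maxEnlarge) {
        cents[[ci]] <- wc$point
        break
      }
      enlarge <- enlarge + 1L
    }
  }
  accept <- all(bright)
  pos <- lastPos; err <- NA_real_
  if (accept) {
    r1 <- backProject(cameras[[1L]], cents[[1L]])
    r2 <- backProject(cameras[[2L]], cents[[2L]])
    tri <- .triangulate(r1@origin, r1@direction, r2@origin, r2@direction)
    err <- tri$error
    if (err > settings@triErrorMax) accept <- FALSE
    if (accept && depth > 0L && !is.null(proximalPos) &&
        is.finite(refLength)) {
      L <- sqrt(sum((tri$point - proximalPos)^2))
      ratio <- max(L, refLength) / max(min(L, refLength),
                                       .Machine$double.eps)
      if (ratio > settings@segLenFactor) accept <- FALSE
    }
    if (accept) pos <- tri$point
  }
  if (accept) {
    list(pos = pos, pos2d = rbind(cents[[1L]], cents[[2L]]),
         triError = err, status = "tracked")
  } else {
    p2 <- rbind(as.numeric(projectPoints(cameras[[1L]], lastPos)),
                as.numeric(projectPoints(cameras[[2L]], lastPos)))
    list(pos = lastPos, pos2d = p2, triError = err, status = "reverted")
  }
}

# --- propagation ------------------------------------------------------------

# set user annotations of one keyframe into the state; returns the state
.applyKeyframe <- function(state, frame, ann, cameras) {
  for (mk in names(ann)) {
    mi <- match(mk, state@markers)
    if (is.na(mi)) stop("annotation for unknown marker: ", mk)
    uv1 <- as.numeric(ann[[mk]][[1L]]); uv2 <- as.numeric(ann[[mk]][[2L]])
    if (anyNA(uv1) || anyNA(uv2)) next
    r1 <- backProject(cameras[[1L]], uv1)
    r2 <- backProject(cameras[[2L]], uv2)
    tri <- .triangulate(r1@origin, r1@direction, r2@origin, r2@direction)
    state@pos3d[frame, mi, ] <- tri$point
    state@pos2d[frame, mi, 1L, ] <- uv1
    state@pos2d[frame, mi, 2L, ] <- uv2
    state@triError[frame, mi] <- tri$error
    state@status[frame, mi] <- 1L
  }
  state
}

# per-marker segment lengths (to proximal neighbour) at one frame
.segmentLengths <- function(state, topology, frame) {
  df <- topology@markers
  out <- rep(NA_real_, nrow(df))
  names(out) <- df$marker
  for (i in seq_len(nrow(df))) {
    if (df$depth[i] == 0L) next
    mi <- match(df$marker[i], state@markers)
    pi <- match(df$proximal[i], state@markers)
    a <- state@pos3d[frame, mi, ]; b <- state@pos3d[frame, pi, ]
    if (!anyNA(a) && !anyNA(b)) out[i] <- sqrt(sum((a - b)^2))
  }
  out
}

# run one directional pass from `origin` over `frames` (ordered)
.runPass <- function(state, topology, origin, frames, cameras, stacks,
                     medians, settings, refLengths) {
  if (!length(frames)) return(state)
  df <- topology@markers
  legOrders <- lapply(legs(topology), function(lg) .legOrder(topology, lg))
  cur <- state@pos3d[origin, , ]
  if (anyNA(cur))
    stop("propagation origin frame ", origin, " is not fully tracked")
  rownames(cur) <- state@markers
  for (t in frames) {
    imgs <- list(stacks[[1L]]@frames[, , t], stacks[[2L]]@frames[, , t])
    med <- c(medians[[1L]][t], medians[[2L]][t])
    for (lo in legOrders) {
      for (i in seq_len(nrow(lo))) {
        mk <- lo$marker[i]
        mi <- match(mk, state@markers)
        if (state@status[t, mi] == 1L) {           # user-defined: keep
          cur[mi, ] <- state@pos3d[t, mi, ]
          next
        }
        prox <- if (lo$depth[i] == 0L) NULL
                else cur[match(lo$proximal[i], state@markers), ]
        res <- trackPointStep(cur[mi, ], prox, lo$depth[i],
                              refLengths[[mk]], cameras, imgs, med,
                              settings)
        state@pos3d[t, mi, ] <- res$pos
        state@pos2d[t, mi, , ] <- res$pos2d
        state@triError[t, mi] <- res$triError
        state@status[t, mi] <- if (res$status == "tracked") 2L else 3L
        cur[mi, ] <- res$pos
      }
    }
  }
  state
}

# coverage plan for a set of keyframes over n frames: each keyframe
# propagates forward and backward, never beyond halfway to its neighbour
.propagationPlan <- function(kfIdx, n) {
  kfIdx <- sort(kfIdx)
  plans <- list()
  for (i in seq_along(kfIdx)) {
    k <- kfIdx[i]
    lo <- if (i == 1L) 1L else (kfIdx[i - 1L] + k) %/% 2L + 1L
    hi <- if (i == length(kfIdx)) n else (k + kfIdx[i + 1L]) %/% 2L
    if (k > lo)
      plans[[length(plans) + 1L]] <- list(origin = k, direction = "backward",
                                          frames = seq(k - 1L, lo))
    if (hi > k)
      plans[[length(plans) + 1L]] <- list(origin = k, direction = "forward",
                                          frames = seq(k + 1L, hi))
  }
  plans
}

#' Propagate marker tracks from keyframes through a movie
#'
#' From every user-defined keyframe, tracking proceeds both forward and
#' backward through the movie, leg by leg from the thorax-coxa root
#' distally (see [trackPointStep()]). Between two keyframes each pass
#' covers up to the midpoint (floor division): propagation never extends
#' more than halfway to another user-defined frame, and user-defined
#' entries are preserved verbatim. Segment-length gates reference the
#' lengths measured at the pass's own keyframe.
#'
#' @param keyframes a [KeyframeSet-class]; at least one keyframe must
#'   annotate all markers.
#' @param stacks list of two preprocessed [FrameStack-class] objects.
#' @param cameras list of two [CameraModel-class] objects.
#' @param topology a [MarkerTopology-class].
#' @param settings a [TrackerSettings-class].
#' @param medians list of two per-frame median-brightness vectors (as
#'   returned by [preprocessStack()]); computed from the stacks if NULL.
#' @param state optional existing [TrackState-class] to update in place
#'   (used for re-propagation after user updates).
#' @param plan optional list of passes (origin/frames) overriding the
#'   default full-coverage plan.
#' @return a [TrackState-class].
#' @export
propagateTrack <- function(keyframes, stacks, cameras, topology,
                           settings = trackerSettings(), medians = NULL,
                           state = NULL, plan = NULL) {
  n <- nFrames(stacks[[1L]])
  if (nFrames(stacks[[2L]]) != n)
    stop("the two stacks must have the same number of frames")
  kfIdx <- keyframeIndices(keyframes)
  if (!length(kfIdx)) stop("at least one keyframe is required")
  if (any(kfIdx < 1L | kfIdx > n)) stop("keyframe outside the movie")
  if (is.null(medians))
    medians <- lapply(stacks, function(s)
      apply(s@frames, 3L, stats::median))
  if (is.null(state)) state <- trackState(n, topology, fps = stacks[[1L]]@fps)
  for (k in kfIdx)
    state <- .applyKeyframe(state, k,
                            keyframes@annotations[[as.character(k)]],
                            cameras)
  full <- vapply(kfIdx, function(k) all(state@status[k, ] > 0L), logical(1L))
  if (is.null(plan) && !any(full))
    stop("at least one keyframe must annotate all markers")
  if (is.null(plan)) plan <- .propagationPlan(kfIdx, n)
  done <- rep(FALSE, length(plan))
  repeat {
    progressed <- FALSE
    for (i in seq_along(plan)) {
      if (done[i]) next
      org <- plan[[i]]$origin
      if (anyNA(state@pos3d[org, , 1L])) {
        # partial keyframe: inherit missing markers from the nearest
        # frame that already carries an estimate for them
        miss <- which(is.na(state@pos3d[org, , 1L]))
        for (mi in miss) {
          got <- which(state@status[, mi] > 0L)
          if (!length(got)) next
          src <- got[which.min(abs(got - org))]
          state@pos3d[org, mi, ] <- state@pos3d[src, mi, ]
          state@pos2d[org, mi, , ] <- state@pos2d[src, mi, , ]
          state@status[org, mi] <- 2L
        }
        if (anyNA(state@pos3d[org, , 1L])) next
      }
      refLengths <- .segmentLengths(state, topology, org)
      state <- .runPass(state, topology, org, plan[[i]]$frames, cameras,
                        stacks, medians, settings, refLengths)
      done[i] <- TRUE
      progressed <- TRUE
    }
    if (all(done) || !progressed) break
  }
  if (!all(done))
    stop("could not complete propagation: some keyframes never became ",
         "fully defined")
  state
}

#' Register a user update and plan its re-propagation
#'
#' Marks `frame` as user-defined with the given (possibly partial)
#' annotations and returns the re-propagation plan: tracking from the
#' updated frame proceeds forward and backward but never more than halfway
#' to an adjacent previously user-defined frame, so verified positions are
#' not overwritten.
#'
#' @param keyframes the current [KeyframeSet-class].
#' @param frame frame index of the update.
#' @param annotations named list (marker -> list(cam1, cam2) pixel pairs).
#' @param nframes total movie length.
#' @param topology a [MarkerTopology-class] (validates marker names).
#' @return list with `keyframes` (updated set) and `plan` (list of passes
#'   with `origin`, `direction`, `frames`) for [propagateTrack()].
#' @export
applyUserUpdate <- function(keyframes, frame, annotations, nframes,
                            topology) {
  bad <- setdiff(names(annotations), markers(topology))
  if (length(bad))
    stop("annotation for unknown marker: ", paste(bad, collapse = ", "))
  prev <- keyframeIndices(keyframes)
  key <- as.character(frame)
  ann <- keyframes@annotations
  if (!is.null(ann[[key]])) {
    ann[[key]][names(annotations)] <- annotations   # in-place replacement
  } else {
    ann[[key]] <- annotations
  }
  kf <- keyframeSet(ann)
  others <- setdiff(prev, frame)
  below <- others[others < frame]; above <- others[others > frame]
  lo <- if (length(below)) (max(below) + frame) %/% 2L + 1L else 1L
  hi <- if (length(above)) (frame + min(above)) %/% 2L else nframes
  plan <- list()
  if (frame > lo)
    plan[[length(plan) + 1L]] <- list(origin = frame, direction = "backward",
                                      frames = seq(frame - 1L, lo))
  if (hi > frame)
    plan[[length(plan) + 1L]] <- list(origin = frame, direction = "forward",
                                      frames = seq(frame + 1L, hi))
  list(keyframes = kf, plan = plan)
}

#' Track a stereo bout end to end
#'
#' Convenience wrapper: preprocesses both raw stacks (see
#' [preprocessStack()]) and propagates the keyframes through the movie.
#'
#' @param stack1,stack2 raw [FrameStack-class] movies (camera 1 and 2).
#' @param cameras list of two [CameraModel-class] objects.
#' @param keyframes a [KeyframeSet-class].
#' @param topology a [MarkerTopology-class].
#' @param settings a [TrackerSettings-class].
#' @param filter a [FilterSettings-class].
#' @param verbose print per-stage progress counts.
#' @return a [TrackState-class].
#' @export
trackBout <- function(stack1, stack2, cameras, keyframes,
                      topology = hexapodTopology(),
                      settings = trackerSettings(),
                      filter = filterSettings(), verbose = FALSE) {
  if (verbose) message("preprocessing camera 1 (", nFrames(stack1),
                       " frames)")
  p1 <- preprocessStack(stack1, filter)
  if (verbose) message("preprocessing camera 2 (", nFrames(stack2),
                       " frames)")
  p2 <- preprocessStack(stack2, filter)
  if (verbose) message("propagating ", length(keyframeIndices(keyframes)),
                       " keyframes")
  st <- propagateTrack(keyframes, list(p1$stack, p2$stack), cameras,
                       topology, settings,
                       medians = list(p1$medians, p2$medians))
  if (verbose) {
    nrev <- sum(st@status == 3L)
    message("done: ", nEstimates3d(st), " 3D estimates, ", nrev,
            " reverted")
  }
  st
}

# --- export -----------------------------------------------------------------

#' Convert a track to a tidy data frame
#'
#' One row per frame per marker: `frame`, `marker`, `x`, `y`, `z`,
#' `status`, `tri_error`.
#'
#' @param state a [TrackState-class].
#' @return a data.frame.
#' @export
trackToDataFrame <- function(state) {
  n <- nFrames(state); m <- length(state@markers)
  data.frame(frame = rep(seq_len(n), times = m),
             marker = rep(state@markers, each = n),
             x = as.numeric(state@pos3d[, , 1L]),
             y = as.numeric(state@pos3d[, , 2L]),
             z = as.numeric(state@pos3d[, , 3L]),
             status = .STATUS_LEVELS[as.integer(state@status) + 1L],
             tri_error = as.numeric(state@triError),
             stringsAsFactors = FALSE)
}

#' Read and write tracks
#'
#' CSV holds the tidy per-frame table (see [trackToDataFrame()]); JSON
#' round-trips the complete state including the 2D measurements.
#'
#' @param state a [TrackState-class].
#' @param path output path.
#' @return read functions return a [TrackState-class]; write functions the
#'   path, invisibly.
#' @export
writeTrackCsv <- function(state, path) {
  utils::write.csv(trackToDataFrame(state), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTrackCsv
#' @param fps frame rate of the restored state.
#' @export
readTrackCsv <- function(path, fps = 500) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  mk <- unique(df$marker)
  n <- max(df$frame)
  st <- trackState(n, mk, fps = fps)
  mi <- match(df$marker, mk)
  idx3 <- cbind(df$frame, mi)
  st@pos3d[cbind(idx3, 1L)] <- df$x
  st@pos3d[cbind(idx3, 2L)] <- df$y
  st@pos3d[cbind(idx3, 3L)] <- df$z
  st@status[idx3] <- match(df$status, .STATUS_LEVELS) - 1L
  st@triError[idx3] <- df$tri_error
  st
}

#' @rdname writeTrackCsv
#' @export
writeTrackJson <- function(state, path) {
  rec <- list(markers = state@markers, fps = state@fps,
              nframes = nFrames(state),
              pos3d = as.numeric(state@pos3d),
              pos2d = as.numeric(state@pos2d),
              status = as.integer(state@status),
              triError = as.numeric(state@triError))
  jsonlite::write_json(rec, path, auto_unbox = FALSE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname writeTrackCsv
#' @export
readTrackJson <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  n <- rec$nframes; m <- length(rec$markers)
  new("TrackState",
      pos3d = array(as.numeric(rec$pos3d), c(n, m, 3L)),
      pos2d = array(as.numeric(rec$pos2d), c(n, m, 2L, 2L)),
      status = matrix(as.integer(rec$status), n, m,
                      dimnames = list(NULL, rec$markers)),
      triError = matrix(as.numeric(rec$triError), n, m),
      markers = rec$markers, fps = as.numeric(rec$fps))
}
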