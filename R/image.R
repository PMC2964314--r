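#' Construct filter settings
#'
#' Defaults follow the recording conditions the pipeline was designed for:
#' a background averaged from 100 evenly spaced, Gaussian-filtered
#' (sigma = 5 px) frames, and a 5 px median filter after subtraction.
#'
#' @param nBackgroundFrames frames averaged into the background.
#' @param backgroundSigma Gaussian sigma in px.
#' @param medianWidth odd median-filter width in px.
#' @return a [FilterSettings-class].
#' @export
filterSettings <- function(nBackgroundFrames = 100L, backgroundSigma = 5,
                           medianWidth = 5L) {
  new("FilterSettings", nBackgroundFrames = as.integer(nBackgroundFrames),
      backgroundSigma = as.numeric(backgroundSigma),
      medianWidth = as.integer(medianWidth))
}

#' Construct a frame stack
#'
#' @param frames a 3D numeric/integer array `[row, col, frame]`, or a list
#'   of equal-sized matrices.
#' @param fps frame rate in Hz.
#' @param mmPerPx world-scale hint (mm per pixel).
#' @param range maximum intensity (default 255, 8-bit).
#' @return a [FrameStack-class].
#' @export
frameStack <- function(frames, fps = 500, mmPerPx = 10 / 30, range = 255) {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1L)
      stop("all frames must share dimensions")
    frames <- array(unlist(frames, use.names = FALSE),
                    dim = c(dims[[1L]], length(frames)))
  }
  storage.mode(frames) <- "integer"
  new("FrameStack", frames = frames, fps = fps, mmPerPx = mmPerPx,
      range = range)
}

#' @rdname FrameStack-class
#' @export
setMethod("nFrames", "FrameStack", function(object) dim(object@frames)[3L])

#' @rdname FrameStack-class
#' @export
setMethod("getFrame", "FrameStack", function(object, i)
  object@frames[, , i])

setMethod("show", "FrameStack", function(object) {
  d <- dim(object@frames)
  cat(sprintf("FrameStack: %d frames of %d x %d px @ %g fps (%.3g mm/px)\n",
              d[3L], d[2L], d[1L], object@fps, object@mmPerPx))
  invisible(object)
})

# reflect-pad a matrix by `k` pixels on every side
.padReflect <- function(m, k) {
  if (k < 1L) return(m)
  nr <- nrow(m); nc <- ncol(m)
  k <- min(k, nr - 1L, nc - 1L)
  ri <- c(rev(seq_len(k) + 1L), seq_len(nr), nr - seq_len(k))
  ci <- c(rev(seq_len(k) + 1L), seq_len(nc), nc - seq_len(k))
  m[ri, ci]
}

.gaussianBlur <- function(m, sigma) {
  k <- as.integer(2L * ceiling(3 * sigma) + 1L)
  pad <- (k - 1L) %/% 2L
  mp <- .padReflect(m, pad)
  g <- EBImage::gblur(mp, sigma = sigma, radius = k)
  g[(pad + 1L):(pad + nrow(m)), (pad + 1L):(pad + ncol(m))]
}

.medianFilter <- function(m, width, range = 255) {
  if (width <= 1L) return(m)
  pad <- (width - 1L) %/% 2L
  mp <- .padReflect(m, pad)
  mf <- EBImage::medianFilter(mp / range, size = pad) * range
  mf[(pad + 1L):(pad + nrow(m)), (pad + 1L):(pad + ncol(m))]
}

#' Compute the average background image of a movie
#'
#' Selects `nBackgroundFrames` evenly spaced frames (indices
#' `floor(i * T / n)`, i = 0..n-1), Gaussian-filters each with
#' `backgroundSigma`, and averages them pixelwise. With markers occupying a
#' small fraction of frames per pixel, the average converges to the static
#' scene and subtracting it leaves the moving markers as the dominant
#' bright features.
#'
#' @param stack a [FrameStack-class] (length >= `nBackgroundFrames`).
#' @param settings a [FilterSettings-class].
#' @return a numeric matrix, same shape as one frame.
#' @export
computeBackground <- function(stack, settings = filterSettings()) {
  n <- nFrames(stack)
  if (n < 1L) stop("empty frame stack")
  nb <- min(settings@nBackgroundFrames, n)
  idx <- unique(floor((seq_len(nb) - 1L) * n / nb) + 1L)
  acc <- matrix(0, dim(stack@frames)[1L], dim(stack@frames)[2L])
  for (i in idx)
    acc <- acc + .gaussianBlur(stack@frames[, , i], settings@backgroundSigma)
  acc / length(idx)
}

#' Preprocess one frame for marker tracking
#'
#' Subtracts the background image (clipping at zero: markers are bright on
#' dark, negative residuals are clutter) and applies a median filter of
#' `medianWidth` px, leaving painted markers as the dominant bright blobs.
#' Both filters use reflect padding at the borders.
#'
#' @param frame numeric matrix (one raw frame).
#' @param background matrix from [computeBackground()].
#' @param settings a [FilterSettings-class].
#' @param range maximum intensity (clips the subtraction result).
#' @return numeric matrix of non-negative filtered intensities.
#' @export
preprocessFrame <- function(frame, background, settings = filterSettings(),
                            range = 255) {
  if (!all(dim(frame) == dim(background)))
    stop("frame and background shapes differ")
  d <- pmin(pmax(frame - background, 0), range)
  .medianFilter(d, settings@medianWidth, range = range)
}

#' Preprocess a whole stack
#'
#' Convenience wrapper: computes the background once and preprocesses every
#' frame, returning a new [FrameStack-class] (rounded back to integers) plus
#' the per-frame median brightness used by the tracker's dim-centroid gate.
#'
#' @param stack a [FrameStack-class].
#' @param settings a [FilterSettings-class].
#' @param background optional precomputed background matrix.
#' @return list with `stack` (processed [FrameStack-class]), `background`,
#'   and `medians` (numeric per-frame median brightness).
#' @export
preprocessStack <- function(stack, settings = filterSettings(),
                            background = NULL) {
  if (is.null(background)) background <- computeBackground(stack, settings)
  n <- nFrames(stack)
  out <- array(0L, dim = dim(stack@frames))
  med <- numeric(n)
  for (i in seq_len(n)) {
    f <- preprocessFrame(stack@frames[, , i], background, settings,
                         range = stack@range)
    fi <- as.integer(.roundHalfAway(f))
    out[, , i] <- fi
    med[i] <- stats::median(fi)
  }
  list(stack = frameStack(out, fps = stack@fps, mmPerPx = stack@mmPerPx,
                          range = stack@range),
       background = background, medians = med)
}
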