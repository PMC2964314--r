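#' Estimate the step frequency of a trial
#'
#' The per-leg step frequency is the peak of the discrete Fourier magnitude
#' spectrum of the foot (TiTa) x-coordinate, after mean removal, searched
#' within a physiological band (default 0.5-15 Hz; excludes DC and
#' tracking jitter). The trial frequency f is the mean of the per-leg
#' peaks, and the transition search window is w = 1/(4 f) seconds.
#'
#' @param xSeries named list (or single numeric vector) of per-leg foot
#'   x-coordinate series.
#' @param fps sampling rate (Hz); at least 2 s of data are required.
#' @param band numeric(2), frequency search band (Hz).
#' @return a [StrideModel-class] (cluster slots empty until
#'   [fitZClusters()] results are attached via [strideModel()]).
#' @export
estimateStepFrequency <- function(xSeries, fps, band = c(0.5, 15)) {
  if (!is.list(xSeries)) xSeries <- list(leg = xSeries)
  n <- length(xSeries[[1L]])
  if (n < 2 * fps) stop("need at least 2 s of data")
  freqs <- vapply(names(xSeries), function(lg) {
    x <- xSeries[[lg]]
    x <- x - mean(x)
    if (max(abs(x)) < 1e-12)
      stop("no spectral peak above DC for leg ", lg, ": series is constant")
    sp <- Mod(stats::fft(x))[seq_len(floor(length(x) / 2))]
    fr <- (seq_along(sp) - 1L) * fps / length(x)
    keep <- fr >= band[1L] & fr <= band[2L]
    if (!any(keep)) stop("no spectral content in the search band")
    fr[keep][which.max(sp[keep])]
  }, numeric(1L))
  strideModel(legFreqs = freqs)
}

#' Construct a stride model
#'
#' @param legFreqs named per-leg peak frequencies (Hz).
#' @param f trial frequency; defaults to `mean(legFreqs)`.
#' @param mu,sigma optional named per-leg stance-cluster parameters.
#' @return a [StrideModel-class] (w is derived as 1/(4 f)).
#' @export
strideModel <- function(legFreqs, f = mean(legFreqs),
                        mu = numeric(), sigma = numeric()) {
  new("StrideModel", legFreqs = legFreqs, f = f, mu = mu, sigma = sigma,
      w = 1 / (4 * f))
}

setMethod("show", "StrideModel", function(object) {
  cat(sprintf("StrideModel: f = %.4g Hz (window w = %.1f ms)\n",
              object@f, 1000 * object@w))
  if (length(object@legFreqs))
    cat("  per-leg peaks:",
        paste(sprintf("%s=%.3g", names(object@legFreqs), object@legFreqs),
              collapse = " "), "Hz\n")
  if (length(object@mu))
    cat("  stance cluster mu:",
        paste(sprintf("%.3g", object@mu), collapse = " "), "\n")
  invisible(object)
})

# zero-delay 4th-order Butterworth lowpass: point-mirror the series at
# both ends, filter forward and backward, then trim. The pad must cover
# the IIR startup transient, which scales with 1/cutoff (the 3-filter-
# length rule of FIR practice is far too short at the low normalized
# cutoffs used here).
.zeroPhaseLowpass <- function(x, cutoff, fps, order = 4L) {
  wn <- min(cutoff / (fps / 2), 0.99)
  bf <- signal::butter(order, wn, type = "low")
  flen <- max(length(bf$b), length(bf$a))
  pad <- min(max(3L * flen, ceiling(9 / wn)), length(x) - 1L)
  xp <- c(2 * x[1L] - x[pad:1L + 1L], x, 2 * x[length(x)] -
            x[length(x) - seq_len(pad)])
  y <- signal::filter(bf, xp)
  y <- rev(as.numeric(signal::filter(bf, rev(as.numeric(y)))))
  y[(pad + 1L):(pad + length(x))]
}

#' Candidate stride-transition times
#'
#' Lowpass-filters the foot x-series with a zero-delay fourth-order
#' Butterworth filter cut off at `2 f`, estimates the derivative by central
#' differences, and returns the times at which the derivative changes sign
#' - the initial estimates of switches between forward and backward foot
#' motion. A sign change from + to - is a candidate stance onset (the foot
#' starts moving backward at the anterior extreme); - to + a candidate
#' swing onset.
#'
#' @param x foot x-coordinate series.
#' @param f trial step frequency (Hz).
#' @param fps sampling rate (Hz).
#' @return data.frame with `index` (1-based sample), `time_s`, `type`
#'   ("stance"/"swing").
#' @export
candidateTransitions <- function(x, f, fps) {
  xf <- .zeroPhaseLowpass(x, 2 * f, fps)
  n <- length(xf)
  d <- c(NA, (xf[3:n] - xf[1:(n - 2L)]) / 2, NA)
  s <- sign(d)
  idx <- which(!is.na(s[-n]) & !is.na(s[-1L]) & s[-n] != 0 &
                 s[-1L] != 0 & s[-n] != s[-1L])
  if (!length(idx))
    return(data.frame(index = integer(), time_s = numeric(),
                      type = character(), stringsAsFactors = FALSE))
  type <- ifelse(s[idx] > 0, "stance", "swing")
  data.frame(index = idx, time_s = (idx - 1L) / fps, type = type,
             stringsAsFactors = FALSE)
}

# enforce strict alternation, keeping the earliest of runs of equal type
.alternate <- function(ev) {
  if (nrow(ev) < 2L) return(ev)
  ev <- ev[order(ev$time_s), , drop = FALSE]
  keep <- c(TRUE, ev$type[-1L] != ev$type[-nrow(ev)])
  ev[keep, , drop = FALSE]
}

#' Stride transitions from anterior/posterior extreme positions
#'
#' The classical one-dimensional definition: within a window of width
#' w = 1/(4 f) seconds centered on each candidate, the stance onset is the
#' time of maximum x (the anterior extreme position, AEP) and the swing
#' onset the time of minimum x (the posterior extreme position, PEP). Ties
#' break to the earliest sample; windows are truncated at the series
#' bounds, and events within w/2 of the bounds are dropped.
#'
#' @param x foot x-coordinate series.
#' @param candidates data.frame from [candidateTransitions()].
#' @param w window width in seconds (1/(4 f)).
#' @param fps sampling rate (Hz).
#' @return data.frame `index`, `time_s`, `type`, `inherited` (all FALSE).
#' @export
extremaTransitions <- function(x, candidates, w, fps) {
  half <- max(1L, round(w * fps / 2))
  n <- length(x)
  rows <- lapply(seq_len(nrow(candidates)), function(i) {
    c0 <- candidates$index[i]
    lo <- max(1L, c0 - half); hi <- min(n, c0 + half)
    seg <- x[lo:hi]
    pick <- if (candidates$type[i] == "stance") which.max(seg)
            else which.min(seg)
    idx <- lo + pick - 1L
    data.frame(index = idx, time_s = (idx - 1L) / fps,
               type = candidates$type[i], inherited = FALSE,
               stringsAsFactors = FALSE)
  })
  ev <- do.call(rbind, c(rows,
                         list(data.frame(index = integer(),
                                         time_s = numeric(),
                                         type = character(),
                                         inherited = logical()))))
  ev <- ev[ev$index > half & ev$index <= n - half, , drop = FALSE]
  .alternate(ev)
}

#' Fit the stance cluster of foot heights
#'
#' Clusters the z-values into "stance" and "swing" bins with 2-means
#' (a two-component Gaussian mixture fit by the k-means algorithm, seeded
#' deterministically at the 5th and 95th percentiles), and returns the
#' mean and standard deviation of the lower-valued cluster - the
#' ground-contact heights.
#'
#' @param z foot height series (canonical frame, substrate near z = 0).
#' @return list with `mu`, `sigma`, and the full per-cluster fit
#'   (`means`, `sds`, `sizes`).
#' @export
fitZClusters <- function(z) {
  z <- z[is.finite(z)]
  if (length(unique(z)) < 2L)
    stop("degenerate height distribution: need at least 2 distinct values")
  init <- stats::quantile(z, c(0.05, 0.95), names = FALSE)
  if (diff(init) < .Machine$double.eps)
    stop("degenerate height distribution: clusters are not separable")
  km <- stats::kmeans(z, centers = matrix(init), algorithm = "Lloyd",
                      iter.max = 100L)
  lower <- which.min(km$centers)
  zin <- z[km$cluster == lower]
  list(mu = mean(zin),
       sigma = if (length(zin) > 1L) stats::sd(zin) else 0,
       means = as.numeric(km$centers),
       sds = vapply(seq_len(2L), function(k) {
         zi <- z[km$cluster == k]
         if (length(zi) > 1L) stats::sd(zi) else 0
       }, numeric(1L)),
       sizes = km$size)
}

#' Stride transitions from foot height
#'
#' The complementary ground-contact definition: within the same
#' w = 1/(4 f) window around each candidate, the beginning of swing is the
#' earliest time at which the z-value goes above mu + sigma (upward
#' crossing), and the beginning of stance the latest time at which it goes
#' below mu + 2 sigma (downward crossing; mu, sigma from the stance
#' cluster, [fitZClusters()]). If no sample in the
#' window satisfies the rule, the event is inherited from the extrema
#' method and flagged.
#'
#' @param z foot height series.
#' @param candidates data.frame from [candidateTransitions()].
#' @param mu,sigma stance-cluster parameters.
#' @param w window width (s).
#' @param fps sampling rate (Hz).
#' @param fallback optional data.frame of extrema events (same candidate
#'   order) used when the rule finds no sample.
#' @return data.frame `index`, `time_s`, `type`, `inherited`.
#' @export
zheightTransitions <- function(z, candidates, mu, sigma, w, fps,
                               fallback = NULL) {
  half <- max(1L, round(w * fps / 2))
  n <- length(z)
  rows <- lapply(seq_len(nrow(candidates)), function(i) {
    c0 <- candidates$index[i]
    lo <- max(1L, c0 - half); hi <- min(n, c0 + half)
    seg <- z[lo:hi]
    inherited <- FALSE
    if (candidates$type[i] == "swing") {
      # earliest upward crossing of mu + sigma in the window
      up <- which(seg[-1L] > mu + sigma & seg[-length(seg)] <= mu + sigma)
      idx <- if (length(up)) lo + up[1L] else NA_integer_
    } else {
      # latest downward crossing of mu + 2 sigma in the window
      dn <- which(seg[-1L] < mu + 2 * sigma &
                    seg[-length(seg)] >= mu + 2 * sigma)
      idx <- if (length(dn)) lo + dn[length(dn)] else NA_integer_
    }
    if (is.na(idx)) {
      if (!is.null(fallback) && i <= nrow(fallback)) {
        idx <- fallback$index[i]; inherited <- TRUE
      } else {
        return(NULL)
      }
    }
    data.frame(index = idx, time_s = (idx - 1L) / fps,
               type = candidates$type[i], inherited = inherited,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  ev <- do.call(rbind, c(rows,
                         list(data.frame(index = integer(),
                                         time_s = numeric(),
                                         type = character(),
                                         inherited = logical()))))
  ev <- ev[ev$index > half & ev$index <= n - half, , drop = FALSE]
  .alternate(ev)
}

#' Per-stride period and duty cycle
#'
#' A complete stride runs from one stance onset to the next; its duty
#' cycle is the stance duration (stance onset to the following swing
#' onset) divided by the period. Incomplete boundary strides are
#' discarded.
#'
#' @param events data.frame of alternating events (`type`, `time_s`) for
#'   one leg and method.
#' @return data.frame with one row per complete stride: `t_stance`,
#'   `period_s`, `duty`; zero rows when no complete stride exists.
#' @export
strideStatistics <- function(events) {
  ev <- events[order(events$time_s), , drop = FALSE]
  st <- which(ev$type == "stance")
  out <- list()
  for (i in st) {
    nxtStance <- st[st > i]
    if (!length(nxtStance)) break
    j <- nxtStance[1L]
    sw <- which(ev$type == "swing" & seq_len(nrow(ev)) > i &
                  seq_len(nrow(ev)) < j)
    if (length(sw) != 1L) next
    period <- ev$time_s[j] - ev$time_s[i]
    duty <- (ev$time_s[sw] - ev$time_s[i]) / period
    out[[length(out) + 1L]] <- data.frame(t_stance = ev$time_s[i],
                                          period_s = period, duty = duty)
  }
  if (!length(out))
    return(data.frame(t_stance = numeric(), period_s = numeric(),
                      duty = numeric()))
  do.call(rbind, out)
}

#' Full stride analysis of a tracked bout
#'
#' Runs the complete stride pipeline on canonical-frame foot trajectories:
#' spectral step-frequency estimate, zero-delay lowpass + central-
#' difference candidates, then both segmentation methods per leg, plus
#' per-leg and per-trial summaries.
#'
#' @param feet named list (per leg) of data.frames or lists with `x` and
#'   `z` numeric series (canonical frame).
#' @param fps sampling rate (Hz).
#' @param band spectral search band (Hz).
#' @return list with `model` ([StrideModel-class]), `events`
#'   ([StrideEvents-class]), `strides` (per-stride data.frame with `leg`
#'   and `method`), and `summary` (per leg x method: n, mean/sd period,
#'   mean/sd duty, s.e.m.s).
#' @export
analyzeStrides <- function(feet, fps, band = c(0.5, 15)) {
  xs <- lapply(feet, function(f) f$x)
  model <- estimateStepFrequency(xs, fps, band)
  f <- model@f; w <- model@w
  mu <- sigma <- stats::setNames(numeric(length(feet)), names(feet))
  evAll <- list(); strAll <- list()
  for (lg in names(feet)) {
    x <- feet[[lg]]$x; z <- feet[[lg]]$z
    cand <- candidateTransitions(x, f, fps)
    evx <- extremaTransitions(x, cand, w, fps)
    fit <- fitZClusters(z)
    mu[lg] <- fit$mu; sigma[lg] <- fit$sigma
    evz <- zheightTransitions(z, cand, fit$mu, fit$sigma, w, fps,
                              fallback = evx)
    for (mth in c("extrema", "zheight")) {
      ev <- if (mth == "extrema") evx else evz
      if (nrow(ev)) {
        evAll[[length(evAll) + 1L]] <-
          cbind(leg = lg, method = mth, ev[, c("type", "time_s",
                                               "inherited")])
        ss <- strideStatistics(ev)
        if (nrow(ss))
          strAll[[length(strAll) + 1L]] <- cbind(leg = lg, method = mth, ss)
      }
    }
  }
  model <- strideModel(model@legFreqs, mu = mu, sigma = sigma)
  events <- new("StrideEvents",
                events = if (length(evAll)) do.call(rbind, evAll)
                         else data.frame(leg = character(),
                                         method = character(),
                                         type = character(),
                                         time_s = numeric(),
                                         inherited = logical()))
  strides <- if (length(strAll)) do.call(rbind, strAll)
             else data.frame(leg = character(), method = character(),
                             t_stance = numeric(), period_s = numeric(),
                             duty = numeric())
  rownames(strides) <- NULL
  summ <- do.call(rbind, lapply(split(strides,
                                      list(strides$leg, strides$method),
                                      drop = TRUE), function(s) {
    data.frame(leg = s$leg[1L], method = s$method[1L], n = nrow(s),
               mean_period = mean(s$period_s), sd_period =
                 stats::sd(s$period_s), sem_period =
                 stats::sd(s$period_s) / sqrt(nrow(s)),
               mean_duty = mean(s$duty), sd_duty = stats::sd(s$duty),
               sem_duty = stats::sd(s$duty) / sqrt(nrow(s)))
  }))
  if (!is.null(summ)) rownames(summ) <- NULL
  list(model = model, events = events, strides = strides, summary = summ)
}

#' Extract per-leg foot series from a canonical track
#'
#' @param state a [TrackState-class] in canonical coordinates (or an
#'   array).
#' @param topology a [MarkerTopology-class].
#' @return named list of per-leg lists with `x` and `z` series, suitable
#'   for [analyzeStrides()].
#' @export
footSeries <- function(state, topology = hexapodTopology()) {
  pos <- if (is(state, "TrackState")) state@pos3d else state
  mk <- if (is(state, "TrackState")) state@markers else markers(topology)
  out <- list()
  for (lg in legs(topology)) {
    mi <- match(paste0(lg, ".TiTa"), mk)
    out[[lg]] <- list(x = pos[, mi, 1L], z = pos[, mi, 3L])
  }
  out
}

#' Write stride events and summaries to CSV
#'
#' @param analysis list from [analyzeStrides()].
#' @param eventsPath,summaryPath output CSV paths (NULL skips).
#' @return invisibly, the paths written.
#' @export
writeStridesCsv <- function(analysis, eventsPath = NULL,
                            summaryPath = NULL) {
  if (!is.null(eventsPath))
    utils::write.csv(analysis$events@events, eventsPath, row.names = FALSE)
  if (!is.null(summaryPath) && !is.null(analysis$summary))
    utils::write.csv(analysis$summary, summaryPath, row.names = FALSE)
  invisible(c(eventsPath, summaryPath))
}
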