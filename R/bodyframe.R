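#' Estimate the ground normal from per-leg median foot points
#'
#' Under the tethered, oiled-plate preparation the median position of each
#' foot (TiTa) marker lies on the substrate, so the six leg medians span
#' the ground plane. The normal is the normalized mean of the sign-aligned
#' cross products of leg-to-leg difference vectors
#' `(l_i - l_1) x (l_j - l_1)` over all pairs i < j, each flipped so all
#' products share a common hemisphere; the result is oriented from the
#' substrate toward the animal via `towards`.
#'
#' @param legMedians 6 x 3 matrix (rows `l_1..l_6` of median TiTa points);
#'   at least 3 non-collinear rows are required.
#' @param towards optional numeric(3): a point on the animal's side of the
#'   plane (e.g. the mean ThC position); the normal is oriented toward it.
#' @return unit numeric(3), the z-axis.
#' @export
estimateGroundNormal <- function(legMedians, towards = NULL) {
  l <- as.matrix(legMedians)
  if (nrow(l) < 3L) stop("need at least 3 leg medians")
  d <- sweep(l[-1L, , drop = FALSE], 2L, l[1L, ])
  crosses <- list()
  nd <- nrow(d)
  for (i in seq_len(nd - 1L)) for (j in seq(i + 1L, nd)) {
    cp <- .cross3(d[i, ], d[j, ])
    if (sqrt(sum(cp^2)) > 1e-12 * max(1, sum(d[i, ]^2)))
      crosses[[length(crosses) + 1L]] <- cp
  }
  if (!length(crosses))
    stop("leg medians are collinear; ground plane is undefined")
  ref <- crosses[[1L]]
  aligned <- vapply(crosses, function(cp)
    if (sum(cp * ref) < 0) -cp else cp, numeric(3L))
  z <- .unit(rowMeans(aligned))
  if (!is.null(towards)) {
    s <- sum(z * (as.numeric(towards) - colMeans(l)))
    if (s < 0) z <- -z
  }
  z
}

#' Estimate the long body axis
#'
#' The best-fit line (first principal component) through three anchor
#' points: the mean CTr position of the middle legs, of the hind legs, and
#' the mean ThC position of the front legs; oriented so the front of the
#' animal has the larger x-value.
#'
#' @param ctrMid,ctrRear,thcFront numeric(3) anchor points.
#' @return unit numeric(3), the (unprojected) body axis.
#' @export
estimateBodyAxis <- function(ctrMid, ctrRear, thcFront) {
  A <- rbind(ctrMid, ctrRear, thcFront)
  ctr <- colMeans(A)
  Ac <- sweep(A, 2L, ctr)
  if (max(abs(Ac)) < 1e-12) stop("anchor points are coincident")
  sv <- svd(Ac)
  ax <- sv$v[, 1L]
  # orient from rear to front
  if (sum(ax * (thcFront - ctrRear)) < 0) ax <- -ax
  .unit(ax)
}

#' Build the animal-centered body frame from tracked data
#'
#' Chains the two estimators: z from the ground normal of the per-leg
#' median TiTa points; x from the body axis after projecting out z (the
#' frame is rotated about z until x is parallel to the body axis, front
#' positive); y = z x x. Translations: z places the median TiTa plane at
#' z = 0, x centers the data (origin near the geometric center), and y is
#' shifted by the mean of the per-leg median CTr y-values.
#'
#' @param state a [TrackState-class] (raw jig coordinates), or an
#'   nframes x nmarkers x 3 array.
#' @param topology a [MarkerTopology-class].
#' @return a [BodyFrame-class].
#' @export
buildBodyFrame <- function(state, topology = hexapodTopology()) {
  pos <- if (is(state, "TrackState")) state@pos3d else state
  mk <- if (is(state, "TrackState")) state@markers else markers(topology)
  df <- topology@markers
  lgs <- legs(topology)
  medOf <- function(marker) {
    mi <- match(marker, mk)
    apply(pos[, mi, , drop = FALSE], 3L, stats::median, na.rm = TRUE)
  }
  missing <- lgs[!vapply(lgs, function(lg)
    any(is.finite(pos[, match(paste0(lg, ".TiTa"), mk), 1L])),
    logical(1L))]
  if (length(missing))
    stop("no tracked data for legs: ", paste(missing, collapse = ", "))
  tita <- t(vapply(paste0(lgs, ".TiTa"), medOf, numeric(3L)))
  thcAll <- t(vapply(paste0(lgs, ".ThC"), medOf, numeric(3L)))
  z <- estimateGroundNormal(tita, towards = colMeans(thcAll))
  meanOf <- function(markerNames) {
    mis <- match(markerNames, mk)
    colMeans(apply(pos[, mis, , drop = FALSE], 3L, identity), na.rm = TRUE)
  }
  mid <- lgs[df$pair[match(paste0(lgs, ".ThC"), df$marker)] == "middle"]
  hind <- lgs[df$pair[match(paste0(lgs, ".ThC"), df$marker)] == "hind"]
  front <- lgs[df$pair[match(paste0(lgs, ".ThC"), df$marker)] == "front"]
  ctrMid <- meanOf(paste0(mid, ".CTr"))
  ctrRear <- meanOf(paste0(hind, ".CTr"))
  thcFront <- meanOf(paste0(front, ".ThC"))
  ax <- estimateBodyAxis(ctrMid, ctrRear, thcFront)
  x <- ax - sum(ax * z) * z
  if (sqrt(sum(x^2)) < 1e-9)
    stop("body axis is parallel to the ground normal")
  x <- .unit(x)
  y <- .cross3(z, x)
  R <- rbind(x, y, z, deparse.level = 0)
  # translations in the rotated frame
  allPts <- matrix(aperm(pos, c(1L, 2L, 3L)), ncol = 3L)
  allPts <- allPts[stats::complete.cases(allPts), , drop = FALSE]
  rot <- allPts %*% t(R)
  titaR <- tita %*% t(R)
  ctrMedR <- t(vapply(paste0(lgs, ".CTr"), medOf, numeric(3L))) %*% t(R)
  tx <- -mean(rot[, 1L])
  ty <- -mean(ctrMedR[, 2L])
  tz <- -stats::median(titaR[, 3L])
  new("BodyFrame", rotation = R, translation = c(tx, ty, tz),
      provenance = list(legMedianTiTa = tita,
                        anchors = rbind(ctrMid = ctrMid, ctrRear = ctrRear,
                                        thcFront = thcFront)))
}

#' Apply (or invert) a body frame
#'
#' Rigid map `q = R p + t`; pairwise distances are preserved exactly.
#'
#' @param frame a [BodyFrame-class].
#' @param points numeric(3), an n x 3 matrix, or an nframes x nmarkers x 3
#'   array.
#' @param inverse apply the inverse transform.
#' @return transformed points, same shape as the input.
#' @export
applyFrame <- function(frame, points, inverse = FALSE) {
  R <- frame@rotation; tr <- frame@translation
  f <- if (inverse) {
    function(p) .applyRigid(t(R), as.numeric(-t(R) %*% tr), p)
  } else {
    function(p) .applyRigid(R, tr, p)
  }
  if (is.null(dim(points)) || length(dim(points)) == 2L) return(f(points))
  d <- dim(points)
  flat <- matrix(points, nrow = d[1L] * d[2L], ncol = 3L)
  array(f(flat), dim = d)
}

setMethod("show", "BodyFrame", function(object) {
  cat("BodyFrame (q = R p + t)\n")
  cat("  rotation:\n")
  print(round(object@rotation, 6))
  cat(sprintf("  translation: (%.4g, %.4g, %.4g)\n",
              object@translation[1L], object@translation[2L],
              object@translation[3L]))
  invisible(object)
})

#' Read and write body frames
#'
#' @param frame a [BodyFrame-class].
#' @param path YAML (or `.json`) file path.
#' @return `readBodyFrame` a [BodyFrame-class]; `writeBodyFrame` the path,
#'   invisibly.
#' @export
writeBodyFrame <- function(frame, path) {
  rec <- list(rotation = as.numeric(t(frame@rotation)),
              translation = frame@translation)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(rec, path, auto_unbox = FALSE, digits = NA)
  else yaml::write_yaml(rec, path, precision = 15L)
  invisible(path)
}

#' @rdname writeBodyFrame
#' @export
readBodyFrame <- function(path) {
  rec <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  R <- matrix(as.numeric(unlist(rec$rotation)), 3L, 3L, byrow = TRUE)
  sv <- svd(R)
  R <- sv$u %*% t(sv$v)
  if (det(R) < 0) R <- sv$u %*% diag(c(1, 1, -1)) %*% t(sv$v)
  new("BodyFrame", rotation = R,
      translation = as.numeric(unlist(rec$translation)),
      provenance = list())
}
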