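#' Interior angle at the middle of a point triplet
#'
#' The angle at `b` between rays `b -> a` and `b -> c`, via the arccosine
#' of the normalized dot product. Used for the FTi joint (TiTa-FTi-CTr
#' triplet) and the CTr joint (FTi-CTr-ThC triplet).
#'
#' @param a,b,c numeric(3) points, or n x 3 matrices (rowwise).
#' @return angle(s) in degrees, in \[0, 180\].
#' @export
angleThreePoints <- function(a, b, c) {
  a <- if (is.null(dim(a))) matrix(a, 1L) else as.matrix(a)
  b <- if (is.null(dim(b))) matrix(b, 1L) else as.matrix(b)
  c <- if (is.null(dim(c))) matrix(c, 1L) else as.matrix(c)
  u <- a - b; v <- c - b
  nu <- sqrt(rowSums(u^2)); nv <- sqrt(rowSums(v^2))
  bad <- nu < 1e-12 | nv < 1e-12
  if (all(bad) && length(bad) == 1L)
    stop("zero-length ray: the middle point coincides with an endpoint")
  ct <- rowSums(u * v) / (nu * nv)
  ct <- pmin(1, pmax(-1, ct))
  out <- .deg(acos(ct))
  out[bad] <- NA_real_
  out
}

#' Trochanter-femur (TrF) plane angle
#'
#' The angle between the plane through TiTa-FTi-CTr and the plane through
#' FTi-CTr-ThC, folded into \[0, 180\] degrees; 0 means the leg is planar.
#' Normals are oriented by the chain winding before folding. Frames where
#' either triplet is collinear are flagged absent (NA).
#'
#' @param tita,fti,ctr,thc numeric(3) points or n x 3 matrices.
#' @return angle(s) in degrees, NA where undefined.
#' @export
trfAngle <- function(tita, fti, ctr, thc) {
  m <- function(p) if (is.null(dim(p))) matrix(p, 1L) else as.matrix(p)
  tita <- m(tita); fti <- m(fti); ctr <- m(ctr); thc <- m(thc)
  crossRows <- function(u, v)
    cbind(u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L],
          u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L],
          u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L])
  n1 <- crossRows(tita - fti, ctr - fti)
  n2 <- crossRows(fti - ctr, thc - ctr)
  l1 <- sqrt(rowSums(n1^2)); l2 <- sqrt(rowSums(n2^2))
  scale2 <- pmax(rowSums((tita - fti)^2), rowSums((thc - ctr)^2))
  bad <- l1 < 1e-9 * scale2 | l2 < 1e-9 * scale2 | l1 == 0 | l2 == 0
  ct <- rowSums(n1 * n2) / (l1 * l2)
  ct <- pmin(1, pmax(-1, ct))
  out <- .deg(acos(ct))
  out[bad] <- NA_real_
  out
}

#' Thorax-coxa promotion and abduction angles
#'
#' For the coxa vector `v = CTr - ThC`: ThC1 (promotion/remotion) is the
#' signed angle of v's xz-projection from the downward vertical, positive
#' toward +x (promotion). ThC2 (adduction/abduction) is the signed angle
#' from vertical of v rotated back by -ThC1 about y and projected into the
#' yz-plane; positive means abduction away from the body, i.e. toward +y on
#' the left side and -y on the right (mirrored so the two sides are
#' comparable). Both are defined in the canonical body frame only.
#'
#' @param ctr,thc numeric(3) or n x 3 canonical coordinates.
#' @param side "L" or "R" (sign convention for ThC2).
#' @return list with `thc1` and `thc2` in degrees ( (-180, 180\] ); NA
#'   where the xz-projection vanishes.
#' @export
thcAngles <- function(ctr, thc, side = c("L", "R")) {
  side <- match.arg(side)
  s <- if (side == "L") 1 else -1
  m <- function(p) if (is.null(dim(p))) matrix(p, 1L) else as.matrix(p)
  v <- m(ctr) - m(thc)
  nv <- sqrt(rowSums(v^2))
  rxz <- sqrt(v[, 1L]^2 + v[, 3L]^2)
  bad <- nv < 1e-12 | rxz < 1e-9 * nv
  th1 <- atan2(v[, 1L], -v[, 3L])
  # rotate v back by -th1 about y: v' = (0, vy, -rxz), so the signed angle
  # from the downward vertical within the yz-plane is atan2(vy, rxz)
  th2 <- atan2(s * v[, 2L], rxz)
  th1[bad] <- NA_real_; th2[bad] <- NA_real_
  list(thc1 = .deg(th1), thc2 = .deg(th2))
}

#' Coxal long-axis rotation (ThC3, front legs)
#'
#' The third rotational degree of freedom of the front-leg thorax-coxa
#' joint. The reference plane is the yz-plane rotated by ThC1 and then
#' ThC2 in kinematic order (the second rotation acts about the plane's own
#' normal and leaves the plane invariant as a set); by construction this
#' plane contains the ThC->CTr direction, so its intersection with the
#' coxal plane (through ThC, CTr and the extra coxal marker) is the coxal
#' long axis. ThC3 is the signed dihedral angle between the two planes
#' about that axis; it is 0 when the coxal marker lies in the reference
#' plane, and invariant to in-plane displacements of the marker.
#'
#' @param ctr,thc,coxal numeric(3) or n x 3 canonical coordinates.
#' @param side "L" or "R" (mirrors the sign so sides are comparable).
#' @return degrees in (-180, 180\]; NA where the coxal marker is collinear
#'   with the ThC-CTr segment.
#' @export
thc3Angle <- function(ctr, thc, coxal, side = c("L", "R")) {
  side <- match.arg(side)
  s <- if (side == "L") 1 else -1
  m <- function(p) if (is.null(dim(p))) matrix(p, 1L) else as.matrix(p)
  ctr <- m(ctr); thc <- m(thc); coxal <- m(coxal)
  n <- nrow(ctr)
  out <- numeric(n)
  for (i in seq_len(n)) {
    v <- ctr[i, ] - thc[i, ]
    w <- coxal[i, ] - thc[i, ]
    rxz <- sqrt(v[1L]^2 + v[3L]^2)
    if (sqrt(sum(v^2)) < 1e-12 || rxz < 1e-9 * sqrt(sum(v^2))) {
      out[i] <- NA_real_; next
    }
    th1 <- atan2(v[1L], -v[3L])
    nref <- as.numeric(.rotY(th1) %*% c(1, 0, 0))
    ncox <- .cross3(v, w)
    if (sqrt(sum(ncox^2)) < 1e-9 * sum(v^2)) {    # collinear marker
      out[i] <- NA_real_; next
    }
    ncox <- ncox / sqrt(sum(ncox^2))
    axis <- v / sqrt(sum(v^2))
    out[i] <- s * .deg(atan2(sum(.cross3(nref, ncox) * axis),
                             sum(nref * ncox)))
    # fold to the equivalent plane orientation in (-90, 90] when the
    # normal convention flips the sign range
    if (!is.na(out[i]) && out[i] > 90) out[i] <- out[i] - 180
    if (!is.na(out[i]) && out[i] <= -90) out[i] <- out[i] + 180
  }
  out
}

#' Compute all joint-angle time series
#'
#' Per frame and leg, from canonical-frame coordinates: FTi and CTr triplet
#' angles for every leg; the TrF plane angle for middle and hind legs only
#' (the joint is effectively fixed on the front legs); ThC1/ThC2 for every
#' leg; ThC3 for the front legs only (requires the extra coxal marker).
#' Frames whose contributing markers are reverted or untracked yield
#' absent (NA) angles - they are never silently interpolated.
#'
#' @param state a [TrackState-class] in canonical coordinates, or an
#'   nframes x nmarkers x 3 array (all entries then count as tracked).
#' @param topology a [MarkerTopology-class].
#' @param fps frame rate (Hz), used for the `time_s` column; taken from
#'   `state` when it is a [TrackState-class].
#' @return tidy data.frame: `frame`, `time_s`, `leg`, `joint`,
#'   `angle_deg`, `status` ("ok"/"absent").
#' @export
computeAllAngles <- function(state, topology = hexapodTopology(),
                             fps = NULL) {
  if (is(state, "TrackState")) {
    pos <- state@pos3d; mk <- state@markers
    good <- state@status == 1L | state@status == 2L
    if (is.null(fps)) fps <- state@fps
  } else {
    pos <- state; mk <- markers(topology)
    good <- matrix(TRUE, dim(pos)[1L], dim(pos)[2L])
    if (is.null(fps)) fps <- 500
  }
  n <- dim(pos)[1L]
  df <- topology@markers
  out <- list()
  P <- function(lg, joint) pos[, match(paste(lg, joint, sep = "."), mk), ,
                               drop = TRUE]
  G <- function(lg, joint) good[, match(paste(lg, joint, sep = "."), mk)]
  for (lg in legs(topology)) {
    side <- df$side[match(paste0(lg, ".ThC"), df$marker)]
    pair <- df$pair[match(paste0(lg, ".ThC"), df$marker)]
    thc <- P(lg, "ThC"); ctr <- P(lg, "CTr")
    fti <- P(lg, "FTi"); tita <- P(lg, "TiTa")
    if (n == 1L) {
      thc <- matrix(thc, 1L); ctr <- matrix(ctr, 1L)
      fti <- matrix(fti, 1L); tita <- matrix(tita, 1L)
    }
    add <- function(joint, values, okMask) {
      values[!okMask] <- NA_real_
      out[[length(out) + 1L]] <<- data.frame(
        frame = seq_len(n), time_s = (seq_len(n) - 1L) / fps, leg = lg,
        joint = joint, angle_deg = values,
        status = ifelse(is.na(values), "absent", "ok"),
        stringsAsFactors = FALSE)
    }
    add("FTi", angleThreePoints(tita, fti, ctr),
        G(lg, "TiTa") & G(lg, "FTi") & G(lg, "CTr"))
    add("CTr", angleThreePoints(fti, ctr, thc),
        G(lg, "FTi") & G(lg, "CTr") & G(lg, "ThC"))
    if (pair != "front")
      add("TrF", trfAngle(tita, fti, ctr, thc),
          G(lg, "TiTa") & G(lg, "FTi") & G(lg, "CTr") & G(lg, "ThC"))
    th <- thcAngles(ctr, thc, side = side)
    add("ThC1", th$thc1, G(lg, "CTr") & G(lg, "ThC"))
    add("ThC2", th$thc2, G(lg, "CTr") & G(lg, "ThC"))
    if (pair == "front") {
      cx <- P(lg, "Cx")
      if (n == 1L) cx <- matrix(cx, 1L)
      add("ThC3", thc3Angle(ctr, thc, cx, side = side),
          G(lg, "CTr") & G(lg, "ThC") & G(lg, "Cx"))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write joint angles to a tidy CSV
#'
#' @param angles data.frame from [computeAllAngles()].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeAnglesCsv <- function(angles, path) {
  utils::write.csv(angles, path, row.names = FALSE)
  invisible(path)
}
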