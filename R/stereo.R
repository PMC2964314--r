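#' Construct a camera model
#'
#' @param focal numeric(2) (or a single value, recycled), focal lengths in px.
#' @param principal numeric(2), principal point in px.
#' @param rotation 3x3 orthonormal world-to-camera rotation.
#' @param translation numeric(3), world-to-camera translation.
#' @param k1 radial distortion coefficient (default 0; ideal lens).
#' @return a [CameraModel-class].
#' @examples
#' cam <- cameraModel(focal = 750, principal = c(159.5, 139.5))
#' projectPoints(cam, c(0, 0, 250))
#' @export
cameraModel <- function(focal = c(1, 1), principal = c(0, 0),
                        rotation = diag(3), translation = c(0, 0, 0),
                        k1 = 0) {
  if (length(focal) == 1L) focal <- rep(focal, 2L)
  new("CameraModel", focal = as.numeric(focal),
      principal = as.numeric(principal),
      rotation = rotation, translation = as.numeric(translation),
      k1 = as.numeric(k1))
}

#' @rdname CameraModel-class
#' @export
setMethod("focal", "CameraModel", function(object) object@focal)

#' @rdname CameraModel-class
#' @export
setMethod("principal", "CameraModel", function(object) object@principal)

#' @rdname CameraModel-class
#' @export
setMethod("rotation", "CameraModel", function(object) object@rotation)

#' @rdname CameraModel-class
#' @export
setMethod("translation", "CameraModel", function(object) object@translation)

#' @rdname CameraModel-class
#' @export
setMethod("cameraCenter", "CameraModel", function(object)
  as.numeric(-crossprod(object@rotation, object@translation)))

setMethod("show", "CameraModel", function(object) {
  cat("CameraModel\n")
  cat(sprintf("  focal     : (%.6g, %.6g) px\n",
              object@focal[1], object@focal[2]))
  cat(sprintf("  principal : (%.6g, %.6g) px\n",
              object@principal[1], object@principal[2]))
  cat(sprintf("  center    : (%.6g, %.6g, %.6g)\n",
              cameraCenter(object)[1], cameraCenter(object)[2],
              cameraCenter(object)[3]))
  if (object@k1 != 0) cat(sprintf("  k1        : %.4g\n", object@k1))
  invisible(object)
})

#' Project 3D points into a camera image
#'
#' Standard pinhole forward model: `x_cam = R X + t`, perspective division,
#' optional single-coefficient radial distortion, then the focal/principal
#' affinity. Points at or behind the camera plane (non-positive camera-frame
#' depth) are flagged invalid and returned as NA.
#'
#' @param camera a [CameraModel-class].
#' @param points numeric(3) or an n x 3 matrix of world points.
#' @return an n x 2 matrix of pixel coordinates (u, v); NA rows mark invalid
#'   projections. A single input point returns a 1 x 2 matrix.
#' @export
projectPoints <- function(camera, points) {
  p <- if (is.null(dim(points))) matrix(points, 1L, 3L) else as.matrix(points)
  stopifnot(ncol(p) == 3L)
  pc <- p %*% t(camera@rotation)
  pc <- sweep(pc, 2L, camera@translation, "+")
  bad <- pc[, 3L] <= .Machine$double.eps
  x <- pc[, 1L] / pc[, 3L]
  y <- pc[, 2L] / pc[, 3L]
  if (camera@k1 != 0) {
    r2 <- x^2 + y^2
    d <- 1 + camera@k1 * r2
    x <- x * d; y <- y * d
  }
  uv <- cbind(camera@focal[1L] * x + camera@principal[1L],
              camera@focal[2L] * y + camera@principal[2L])
  uv[bad, ] <- NA_real_
  colnames(uv) <- c("u", "v")
  uv
}

#' Back-project a pixel to a 3D ray
#'
#' A 2D image point becomes the 3D ray from the camera center into space;
#' every 3D point on the ray projects back to the same pixel. Distortion is
#' inverted by fixed-point iteration when `k1 != 0`.
#'
#' @param camera a [CameraModel-class].
#' @param q numeric(2) pixel coordinates (u, v).
#' @return a [Ray3D-class].
#' @export
backProject <- function(camera, q) {
  x <- (q[1L] - camera@principal[1L]) / camera@focal[1L]
  y <- (q[2L] - camera@principal[2L]) / camera@focal[2L]
  if (camera@k1 != 0) {
    xd <- x; yd <- y
    for (i in 1:20) {
      r2 <- x^2 + y^2
      d <- 1 + camera@k1 * r2
      x <- xd / d; y <- yd / d
    }
  }
  dirw <- as.numeric(crossprod(camera@rotation, c(x, y, 1)))
  new("Ray3D", origin = cameraCenter(camera), direction = .unit(dirw))
}

#' Triangulate two camera rays (midpoint method)
#'
#' Finds the unique mutual-perpendicular segment between two skew rays; the
#' returned point is its midpoint and the triangulation error is its length
#' (the distance between the rays at closest approach), a confidence
#' measure for the correspondence of the two image points.
#'
#' @param r1,r2 [Ray3D-class] objects. Parallel rays are an error.
#' @return a [TriangulationResult-class].
#' @export
triangulateRays <- function(r1, r2) {
  res <- .triangulate(r1@origin, r1@direction, r2@origin, r2@direction)
  new("TriangulationResult", point = res$point, error = res$error)
}

# fast internal path (no S4 construction); assumes unit directions
.triangulate <- function(o1, d1, o2, d2) {
  w0 <- o1 - o2
  b <- sum(d1 * d2)
  den <- 1 - b * b
  if (den < 1e-12)
    stop("cannot triangulate parallel rays")
  dd <- sum(d1 * w0); e <- sum(d2 * w0)
  s <- (b * e - dd) / den
  t <- (e - b * dd) / den
  p1 <- o1 + s * d1
  p2 <- o2 + t * d2
  list(point = (p1 + p2) / 2, error = sqrt(sum((p1 - p2)^2)))
}

#' Reprojection error of a 3D point
#'
#' Euclidean pixel distance between the projection of an estimated 3D point
#' and the observed image point.
#'
#' @param camera a [CameraModel-class].
#' @param p3 numeric(3) world point.
#' @param qObs numeric(2) observed pixel position.
#' @return distance in pixels.
#' @export
reprojectionError <- function(camera, p3, qObs) {
  uv <- projectPoints(camera, p3)
  sqrt(sum((as.numeric(uv) - as.numeric(qObs))^2))
}

#' Retriangulation error against known 3D points
#'
#' Mean Euclidean distance between points triangulated from paired
#' detections and their known 3D positions; the whole-rig accuracy metric
#' for a calibrated stereo pair.
#'
#' @param cameras list of two [CameraModel-class] objects.
#' @param detections1,detections2 n x 2 matrices of pixel detections, one
#'   row per point, same order as `truth`.
#' @param truth n x 3 matrix of known 3D positions.
#' @return mean distance in world length units.
#' @export
retriangulationError <- function(cameras, detections1, detections2, truth) {
  detections1 <- as.matrix(detections1)
  detections2 <- as.matrix(detections2)
  truth <- as.matrix(truth)
  if (nrow(detections1) != nrow(truth) || nrow(detections2) != nrow(truth))
    stop("detections and truth must have matching lengths")
  d <- vapply(seq_len(nrow(truth)), function(i) {
    r1 <- backProject(cameras[[1L]], detections1[i, ])
    r2 <- backProject(cameras[[2L]], detections2[i, ])
    res <- .triangulate(r1@origin, r1@direction, r2@origin, r2@direction)
    sqrt(sum((res$point - truth[i, ])^2))
  }, numeric(1L))
  mean(d)
}

# --- calibration ------------------------------------------------------------

.checkJig <- function(p3, q2) {
  if (nrow(p3) < 6L)
    stop("calibration needs at least 6 point correspondences, got ",
         nrow(p3))
  ctr <- colMeans(p3)
  sv <- svd(sweep(p3, 2L, ctr))$d
  if (sv[3L] < 1e-8 * sv[1L])
    stop("calibration jig points are coplanar; a non-coplanar jig is required")
  if (nrow(q2) != nrow(p3))
    stop("detections and jig points must have matching lengths")
  invisible(TRUE)
}

# Direct Linear Transform: returns the 3x4 projection matrix (Hartley
# normalization on both sides).
.dlt <- function(p3, q2) {
  n <- nrow(p3)
  # normalize 2D
  c2 <- colMeans(q2)
  s2 <- sqrt(2) / mean(sqrt(rowSums(sweep(q2, 2L, c2)^2)))
  T2 <- rbind(c(s2, 0, -s2 * c2[1L]), c(0, s2, -s2 * c2[2L]), c(0, 0, 1))
  # normalize 3D
  c3 <- colMeans(p3)
  s3 <- sqrt(3) / mean(sqrt(rowSums(sweep(p3, 2L, c3)^2)))
  T3 <- rbind(cbind(diag(3) * s3, -s3 * c3), c(0, 0, 0, 1))
  q2n <- cbind(q2, 1) %*% t(T2)
  p3n <- cbind(p3, 1) %*% t(T3)
  A <- matrix(0, 2L * n, 12L)
  for (i in seq_len(n)) {
    X <- p3n[i, ]
    u <- q2n[i, 1L]; v <- q2n[i, 2L]
    A[2L * i - 1L, ] <- c(X, rep(0, 4L), -u * X)
    A[2L * i, ] <- c(rep(0, 4L), X, -v * X)
  }
  sv <- svd(A)
  P <- matrix(sv$v[, 12L], 3L, 4L, byrow = TRUE)
  P <- solve(T2) %*% P %*% T3
  P / sqrt(sum(P[3L, 1:3]^2))
}

# Decompose P = K [R | t] with K upper-triangular (zero skew enforced in the
# returned model; the refinement step absorbs any residual skew). P must be
# signed so that jig depths are positive.
.decomposeP <- function(P) {
  M <- P[, 1:3]
  # RQ decomposition via QR of the reversed-transposed matrix
  E <- diag(3)[3:1, ]
  qr_ <- qr(t(E %*% M))
  Rm <- qr.R(qr_); Qm <- qr.Q(qr_)
  K <- E %*% t(Rm) %*% E
  R <- E %*% t(Qm)
  S <- diag(sign(diag(K)))
  K <- K %*% S
  R <- S %*% R
  K <- K / K[3L, 3L]
  t <- as.numeric(solve(K, P[, 4L]))
  list(K = K, R = R, t = t)
}

.camFromParams <- function(par) {
  cameraModel(focal = par[1:2], principal = par[3:4],
              rotation = .rodrigues(par[5:7]), translation = par[8:10])
}

.meanReprojection <- function(cam, p3, q2) {
  uv <- projectPoints(cam, p3)
  mean(sqrt(rowSums((uv - q2)^2)))
}

#' Calibrate a camera from a jig of known geometry
#'
#' Direct Linear Transform on at least six non-coplanar 3D-2D
#' correspondences, decomposed into intrinsic and extrinsic parameters, then
#' (optionally) refined by nonlinear least squares on the reprojection
#' error. With noiseless correspondences the recovered model reprojects the
#' jig exactly (to numerical precision).
#'
#' @param jigPoints n x 3 matrix of known jig coordinates.
#' @param detections n x 2 matrix of the corresponding pixel detections.
#' @param refine logical; run the nonlinear refinement (default TRUE).
#' @return a [CameraModel-class].
#' @export
calibrateCamera <- function(jigPoints, detections, refine = TRUE) {
  p3 <- as.matrix(jigPoints); q2 <- as.matrix(detections)
  .checkJig(p3, q2)
  P <- .dlt(p3, q2)
  # sign P so the jig sits in front of the camera
  depths <- cbind(p3, 1) %*% P[3L, ]
  if (stats::median(depths) < 0) P <- -P
  dec <- .decomposeP(P)
  cam <- cameraModel(focal = c(dec$K[1L, 1L], dec$K[2L, 2L]),
                     principal = c(dec$K[1L, 3L], dec$K[2L, 3L]),
                     rotation = dec$R, translation = dec$t)
  if (refine) {
    par0 <- c(cam@focal, cam@principal, .rodriguesInv(cam@rotation),
              cam@translation)
    obj <- function(par) {
      cm <- try(.camFromParams(par), silent = TRUE)
      if (inherits(cm, "try-error")) return(1e12)
      uv <- projectPoints(cm, p3)
      if (anyNA(uv)) return(1e12)
      sum((uv - q2)^2)
    }
    opt <- stats::optim(par0, obj, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
    cam2 <- .camFromParams(opt$par)
    if (.meanReprojection(cam2, p3, q2) < .meanReprojection(cam, p3, q2))
      cam <- cam2
  }
  cam
}

# --- serialization ----------------------------------------------------------

#' Read and write camera models
#'
#' Cameras serialize to YAML (or JSON by extension) with a row-major
#' rotation matrix.
#'
#' @param camera a [CameraModel-class].
#' @param path file path; `.json` selects JSON, anything else YAML.
#' @return `readCamera` returns a [CameraModel-class]; `writeCamera` the
#'   path, invisibly.
#' @export
writeCamera <- function(camera, path) {
  rec <- list(focal = camera@focal, principal = camera@principal,
              rotation = as.numeric(t(camera@rotation)),
              translation = camera@translation, k1 = camera@k1)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(rec, path, auto_unbox = FALSE, digits = NA)
  } else {
    yaml::write_yaml(rec, path, precision = 15L)
  }
  invisible(path)
}

#' @rdname writeCamera
#' @export
readCamera <- function(path) {
  rec <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  R <- matrix(as.numeric(unlist(rec$rotation)), 3L, 3L, byrow = TRUE)
  # re-orthonormalize against serialization rounding
  sv <- svd(R)
  R <- sv$u %*% t(sv$v)
  if (det(R) < 0) R <- sv$u %*% diag(c(1, 1, -1)) %*% t(sv$v)
  cameraModel(focal = as.numeric(unlist(rec$focal)),
              principal = as.numeric(unlist(rec$principal)),
              rotation = R,
              translation = as.numeric(unlist(rec$translation)),
              k1 = if (is.null(rec$k1)) 0 else as.numeric(rec$k1))
}

#' Read and write calibration jig files
#'
#' Plain CSV with one row per jig point:
#' `x,y,z,cam1_u,cam1_v,cam2_u,cam2_v`.
#'
#' @param jig list with `points` (n x 3) and `detections` (list of two
#'   n x 2 matrices).
#' @param path CSV file path.
#' @return `readJig` returns such a list; `writeJig` the path, invisibly.
#' @export
writeJig <- function(jig, path) {
  df <- data.frame(x = jig$points[, 1L], y = jig$points[, 2L],
                   z = jig$points[, 3L],
                   cam1_u = jig$detections[[1L]][, 1L],
                   cam1_v = jig$detections[[1L]][, 2L],
                   cam2_u = jig$detections[[2L]][, 1L],
                   cam2_v = jig$detections[[2L]][, 2L])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeJig
#' @export
readJig <- function(path) {
  df <- utils::read.csv(path)
  list(points = as.matrix(df[, c("x", "y", "z")]),
       detections = list(as.matrix(df[, c("cam1_u", "cam1_v")]),
                         as.matrix(df[, c("cam2_u", "cam2_v")])))
}
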