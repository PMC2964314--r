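#' Construct tracker settings
#'
#' Defaults are sized for a rig at roughly 30 px/cm (mm world units):
#' base ellipsoid long radius 1 mm scaled by 1.3 per chain depth, a 0.5 mm
#' ThC sphere, doubling enlargement with at most two retries, a 1 mm
#' triangulation-error gate and a 1.3x segment-length-change gate.
#'
#' @param baseRadius,depthScale,thcRadius,enlargeFactor,maxEnlarge
#'   see [TrackerSettings-class].
#' @param triErrorMax,segLenFactor,dimFraction,dimFloor
#'   see [TrackerSettings-class].
#' @return a [TrackerSettings-class].
#' @export
trackerSettings <- function(baseRadius = 1.0, depthScale = 1.3,
                            thcRadius = 0.5, enlargeFactor = 2,
                            maxEnlarge = 2L, triErrorMax = 1.0,
                            segLenFactor = 1.3, dimFraction = 0.5,
                            dimFloor = 1) {
  new("TrackerSettings", baseRadius = baseRadius, depthScale = depthScale,
      thcRadius = thcRadius, enlargeFactor = enlargeFactor,
      maxEnlarge = as.integer(maxEnlarge), triErrorMax = triErrorMax,
      segLenFactor = segLenFactor, dimFraction = dimFraction,
      dimFloor = dimFloor)
}

#' Build the search ellipsoid for one marker step
#'
#' The search volume is centered at the marker's last known position. For
#' chain depth k >= 1 it is a flattened sphere: long radius
#' `r0 * g^k`, short radius half that, with the short axis along the leg
#' segment (from the already-updated proximal point to the last known
#' position of the current point) - leg segments resist length change while
#' the joint rotation is unconstrained. For the ThC root (k = 0), or when
#' the two points coincide and the segment direction is undefined, the
#' volume degenerates to a sphere.
#'
#' @param lastPos numeric(3), last known marker position.
#' @param proximalPos numeric(3) or NULL (ThC root).
#' @param depth chain depth k (0 at ThC).
#' @param settings a [TrackerSettings-class].
#' @param enlarge non-negative integer; number of enlargement retries
#'   already applied (each multiplies the radii by `enlargeFactor`).
#' @return a [SearchEllipsoid-class].
#' @export
buildSearchEllipsoid <- function(lastPos, proximalPos, depth,
                                 settings = trackerSettings(),
                                 enlarge = 0L) {
  gain <- settings@enlargeFactor^enlarge
  if (depth == 0L || is.null(proximalPos)) {
    return(new("SearchEllipsoid", center = as.numeric(lastPos),
               longRadius = settings@thcRadius * gain,
               shortAxis = c(0, 0, 1), sphere = TRUE))
  }
  r <- settings@baseRadius * settings@depthScale^depth * gain
  seg <- as.numeric(lastPos) - as.numeric(proximalPos)
  if (sqrt(sum(seg^2)) < 1e-9) {
    return(new("SearchEllipsoid", center = as.numeric(lastPos),
               longRadius = r, shortAxis = c(0, 0, 1), sphere = TRUE))
  }
  new("SearchEllipsoid", center = as.numeric(lastPos), longRadius = r,
      shortAxis = .unit(seg), sphere = FALSE)
}

# 3x3 shape matrix M with (x-c)' M (x-c) = 1 on the surface
.ellipsoidShape <- function(e) {
  r <- e@longRadius
  if (e@sphere) return(diag(3) / r^2)
  s <- e@shortAxis
  (4 / r^2) * tcrossprod(s) + (1 / r^2) * (diag(3) - tcrossprod(s))
}

# sample points on the ellipsoid surface (Fibonacci sphere mapped by axes)
.ellipsoidSurface <- function(e, n = 64L) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  th <- pi * (1 + sqrt(5)) * i
  sph <- cbind(sin(phi) * cos(th), sin(phi) * sin(th), cos(phi))
  r <- e@longRadius
  if (e@sphere) {
    pts <- sph * r
  } else {
    s <- e@shortAxis
    a <- if (abs(s[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    u <- .unit(.cross3(s, a)); v <- .cross3(s, u)
    B <- cbind(u * r, v * r, s * r / 2)
    pts <- sph %*% t(B)
  }
  sweep(pts, 2L, e@center, "+")
}

.boundingEllipseOfPoints <- function(uv) {
  lo <- apply(uv, 2L, min); hi <- apply(uv, 2L, max)
  ctr <- (lo + hi) / 2
  half <- pmax((hi - lo) / 2, 1e-6)
  ax <- half * sqrt(2) * 1.02   # circumscribes the bounding box
  list(center = ctr, E = diag(1 / ax^2), semiAxes = ax, angle = 0)
}

#' Project a search ellipsoid into a camera image
#'
#' Computes the exact conic outline of the ellipsoid's silhouette (the
#' projection of the dual quadric). If the conic is numerically
#' ill-conditioned, or the camera has lens distortion, falls back to the
#' bounding ellipse of 64 projected surface samples; in both cases the
#' returned ellipse contains the full silhouette.
#'
#' @param camera a [CameraModel-class].
#' @param e a [SearchEllipsoid-class], fully in front of the camera.
#' @return list with `center` (pixels), `E` (2x2 matrix; inside means
#'   `(p - center)' E (p - center) <= 1`), `semiAxes`, `angle` (radians).
#' @export
projectEllipsoid <- function(camera, e) {
  depth <- (camera@rotation %*% e@center + camera@translation)[3L]
  if (depth <= e@longRadius)
    stop("ellipsoid is not fully in front of the camera")
  if (camera@k1 != 0)
    return(.boundingEllipseOfPoints(projectPoints(camera,
                                                  .ellipsoidSurface(e))))
  conic <- tryCatch(.silhouetteConic(camera, e), error = function(err) NULL)
  if (is.null(conic))
    return(.boundingEllipseOfPoints(projectPoints(camera,
                                                  .ellipsoidSurface(e))))
  conic
}

.silhouetteConic <- function(camera, e) {
  M <- .ellipsoidShape(e)
  c0 <- e@center
  Q <- rbind(cbind(M, -M %*% c0),
             c(-as.numeric(crossprod(c0, M)),
               as.numeric(crossprod(c0, M %*% c0)) - 1))
  K <- rbind(c(camera@focal[1L], 0, camera@principal[1L]),
             c(0, camera@focal[2L], camera@principal[2L]),
             c(0, 0, 1))
  P <- K %*% cbind(camera@rotation, camera@translation)
  Qstar <- solve(Q)
  Cstar <- P %*% Qstar %*% t(P)
  C <- solve(Cstar)
  C <- (C + t(C)) / 2
  A <- C[1:2, 1:2]; b <- C[1:2, 3L]; cc <- C[3L, 3L]
  ctr <- as.numeric(-solve(A, b))
  f0 <- cc - sum(b * solve(A, b))
  E <- A / (-f0)
  ev <- eigen(E, symmetric = TRUE)
  if (any(ev$values <= 0) || !all(is.finite(ev$values)))
    stop("silhouette conic is not an ellipse")
  ax <- 1 / sqrt(ev$values)
  list(center = ctr, E = E, semiAxes = ax,
       angle = atan2(ev$vectors[2L, which.max(ax)],
                     ev$vectors[1L, which.max(ax)]))
}

#' Brightness-weighted centroid inside an image ellipse
#'
#' First central image moments over the pixels inside the ellipse:
#' `centroid = sum(I * p) / sum(I)`. The reported brightness is the image
#' value at the pixel nearest the centroid. An empty or all-zero region is
#' flagged as having no signal.
#'
#' @param image numeric matrix (`[v + 1, u + 1]` indexing, 0-based pixel
#'   centers).
#' @param ellipse list as returned by [projectEllipsoid()].
#' @return list with `point` (numeric(2) pixel centroid), `brightness`,
#'   and `ok` (FALSE when the region carries no signal).
#' @export
weightedCentroid <- function(image, ellipse) {
  nr <- nrow(image); nc <- ncol(image)
  B <- solve(ellipse$E)
  du <- sqrt(max(B[1L, 1L], 0)); dv <- sqrt(max(B[2L, 2L], 0))
  u0 <- max(0L, floor(ellipse$center[1L] - du))
  u1 <- min(nc - 1L, ceiling(ellipse$center[1L] + du))
  v0 <- max(0L, floor(ellipse$center[2L] - dv))
  v1 <- min(nr - 1L, ceiling(ellipse$center[2L] + dv))
  if (u0 > u1 || v0 > v1)
    return(list(point = c(NA_real_, NA_real_), brightness = 0, ok = FALSE))
  us <- u0:u1; vs <- v0:v1
  duu <- us - ellipse$center[1L]; dvv <- vs - ellipse$center[2L]
  E <- ellipse$E
  # quadratic form on the pixel grid (rows = v, cols = u)
  qf <- outer(dvv^2 * E[2L, 2L], duu^2 * E[1L, 1L], "+") +
    2 * E[1L, 2L] * outer(dvv, duu)
  inside <- qf <= 1
  if (!any(inside))
    return(list(point = c(NA_real_, NA_real_), brightness = 0, ok = FALSE))
  sub <- image[vs + 1L, us + 1L, drop = FALSE]
  w <- sub * inside
  tot <- sum(w)
  if (tot <= 0)
    return(list(point = c(NA_real_, NA_real_), brightness = 0, ok = FALSE))
  uc <- sum(t(t(w) * us)) / tot
  vc <- sum(w * vs) / tot
  ui <- min(nc - 1L, max(0L, .roundHalfAway(uc)))
  vi <- min(nr - 1L, max(0L, .roundHalfAway(vc)))
  list(point = c(uc, vc), brightness = image[vi + 1L, ui + 1L], ok = TRUE)
}
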