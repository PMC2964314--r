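# Small numeric helpers shared across modules. Internal.

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < .Machine$double.eps^0.75)
    stop("cannot normalize a (near-)zero vector")
  v / n
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Round half away from zero (the pixel quantization convention; base round()
# is half-to-even).
.roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

# Rotation about a coordinate axis, world convention (right-handed).
.rotY <- function(theta) {
  c_ <- cos(theta); s_ <- sin(theta)
  matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3, 3, byrow = TRUE)
}

.rotX <- function(theta) {
  c_ <- cos(theta); s_ <- sin(theta)
  matrix(c(1, 0, 0, 0, c_, -s_, 0, s_, c_), 3, 3, byrow = TRUE)
}

.rotZ <- function(theta) {
  c_ <- cos(theta); s_ <- sin(theta)
  matrix(c(c_, -s_, 0, s_, c_, 0, 0, 0, 1), 3, 3, byrow = TRUE)
}

# Rodrigues: rotation vector -> matrix and back.
.rodrigues <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-12) return(diag(3))
  k <- w / th
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

.rodriguesInv <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  ct <- min(1, max(-1, ct))
  th <- acos(ct)
  if (th < 1e-12) return(c(0, 0, 0))
  if (abs(pi - th) < 1e-6) {
    # near pi: extract axis from R + I
    A <- (R + diag(3)) / 2
    k <- sqrt(pmax(diag(A), 0))
    i <- which.max(k)
    k <- A[, i] / k[i]
    return(.unit(k) * th)
  }
  ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
    (2 * sin(th))
  ax * th
}

# Rotation about an arbitrary unit axis.
.rotAxis <- function(axis, theta) .rodrigues(.unit(axis) * theta)

# Angle helpers
.deg <- function(rad) rad * 180 / pi
.rad <- function(deg) deg * pi / 180

# Rigid transform applied to an n x 3 matrix (or length-3 vector):
# q = R p + t
.applyRigid <- function(R, t, p) {
  if (is.null(dim(p))) return(as.numeric(R %*% p + t))
  sweep(p %*% t(R), 2, -t, "-")
}

# Orthonormal look-at rotation: camera z toward `target`, camera y chosen
# with no roll about the world y axis (camera x stays in the world xz-plane).
.lookAtRotation <- function(center, target) {
  z <- .unit(target - center)
  x <- c(z[3], 0, -z[1])
  nx <- sqrt(sum(x^2))
  x <- if (nx < 1e-9) c(1, 0, 0) else x / nx
  if (x[1] < 0) x <- -x
  y <- .cross3(z, x)
  rbind(x, y, z, deparse.level = 0)
}
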