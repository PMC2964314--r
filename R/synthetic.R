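.TRIPOD_PHASES <- c(R1 = 0, L1 = 0.5, R2 = 0.5, L2 = 0, R3 = 0, L3 = 0.5)

# default per-leg chain geometry (mm, canonical frame: x forward, y left,
# z up, substrate at z = 0, thorax-coxa roots at tether height ~14 mm)
.defaultGeometry <- function() {
  base <- list(
    front  = list(thc = c(18, 9, 14),  foot = c(28, 20, 0),
                  seg = c(7, 10, 12), elbow = c(-0.6, 0.3, 0.75)),
    middle = list(thc = c(0, 10, 14),  foot = c(2, 26, 0),
                  seg = c(8, 12, 14), elbow = c(0.6, 0.3, 0.75)),
    hind   = list(thc = c(-16, 10, 14), foot = c(-26, 22, 0),
                  seg = c(9, 14, 17), elbow = c(0.6, 0.3, 0.75)))
  out <- list()
  for (lg in c("R1", "L1", "R2", "L2", "R3", "L3")) {
    pair <- switch(substr(lg, 2L, 2L), "1" = "front", "2" = "middle",
                   "3" = "hind")
    side <- if (substr(lg, 1L, 1L) == "L") 1 else -1
    g <- base[[pair]]
    thc <- g$thc * c(1, side, 1)
    foot <- g$foot * c(1, side, 1)
    d <- foot - thc
    dxy <- sqrt(d[1L]^2 + d[2L]^2)
    coxaDir <- .unit(c(d[1L], d[2L], -0.7 * dxy))
    # sprawled posture: knees are displaced horizontally from the feet
    # (anterior-dorsal for middle/hind, posterior-dorsal for front), so
    # the femur-tibia chain is not viewed end-on by the ventral camera
    out[[lg]] <- list(thc = thc, foot = foot, seg = g$seg,
                      coxaDir = coxaDir,
                      elbow = .unit(g$elbow * c(1, side, 1)))
  }
  out
}

#' Construct a programmed gait specification
#'
#' Defaults describe a tethered cockroach-like hexapod stepping in a
#' tripod pattern at 4 Hz with duty cycle 0.55, 10 mm strides and 3 mm
#' swing lift, with the thorax-coxa roots ~14 mm above the substrate.
#'
#' @param freq step frequency (Hz).
#' @param duty stance fraction of the cycle.
#' @param phases named per-leg phase offsets (fraction of cycle).
#' @param strideLength,liftHeight foot excursion and swing apex (mm).
#' @param xLead fraction of the cycle by which backward foot motion leads
#'   touchdown (and trails liftoff); 0 makes the foot extremes coincide
#'   with the contact transitions.
#' @param coxaSwing coxal rocking amplitude (degrees).
#' @param geometry per-leg chain geometry; NULL for the built-in default.
#' @param seed integer seed for stochastic rendering.
#' @return a [GaitSpec-class].
#' @export
gaitSpec <- function(freq = 4, duty = 0.55, phases = .TRIPOD_PHASES,
                     strideLength = 10, liftHeight = 3, xLead = 0,
                     coxaSwing = 4, geometry = NULL, seed = 1L) {
  if (is.null(geometry)) geometry <- .defaultGeometry()
  new("GaitSpec", freq = freq, duty = duty,
      phases = phases[c("R1", "L1", "R2", "L2", "R3", "L3")],
      strideLength = strideLength, liftHeight = liftHeight, xLead = xLead,
      coxaSwing = coxaSwing, geometry = geometry, seed = as.integer(seed))
}

#' Construct a rendering specification
#'
#' Defaults emulate the reference recording conditions: 320 x 280 px
#' frames at 500 fps and ~30 px/cm, Gaussian marker blobs of sigma 1.5 px
#' peaking at 220/255, static low-frequency clutter up to 30% of the blob
#' peak, and additive sensor noise of sd 2.
#'
#' @param imageSize,scalePxPerCm,blobSigma,blobPeak,clutterAmp,noiseSd,fps
#'   see [RenderSpec-class].
#' @param occlusions occlusion schedule data.frame (`marker`, `from`,
#'   `to`, `camera`).
#' @return a [RenderSpec-class].
#' @export
renderSpec <- function(imageSize = c(320L, 280L), scalePxPerCm = 30,
                       blobSigma = 1.5, blobPeak = 220, clutterAmp = 0.3,
                       noiseSd = 2, fps = 500,
                       occlusions = data.frame(marker = character(),
                                               from = integer(),
                                               to = integer(),
                                               camera = integer())) {
  new("RenderSpec", imageSize = as.integer(imageSize),
      scalePxPerCm = scalePxPerCm, blobSigma = blobSigma,
      blobPeak = blobPeak, clutterAmp = clutterAmp, noiseSd = noiseSd,
      occlusions = occlusions, fps = fps)
}

# foot x-offset (relative to neutral) and z at cycle phase p
.footWave <- function(p, duty, A, h, lead) {
  d <- duty
  x <- numeric(length(p)); z <- numeric(length(p))
  if (lead <= 0) {
    st <- p < d
    x[st] <- A * (1 - 2 * p[st] / d)
    q <- (p[!st] - d) / (1 - d)
    x[!st] <- -A * cos(pi * q)
    z[!st] <- h * sin(pi * q)
  } else {
    drop <- A * min(0.3, 4 * lead)
    x0 <- A - drop; x1 <- -A + drop
    st <- p < d
    x[st] <- x0 + (x1 - x0) * p[st] / d
    sw <- !st
    q <- p[sw]
    z[sw] <- h * sin(pi * (q - d) / (1 - d))
    xa <- q >= d & q < d + lead
    xb <- q >= d + lead & q < 1 - lead
    xc <- q >= 1 - lead
    sA <- (p[sw][xa] - d) / lead
    x[sw][xa] <- -A + (x1 + A) * (1 - sA)^2
    sB <- (p[sw][xb] - d - lead) / (1 - d - 2 * lead)
    x[sw][xb] <- -A * cos(pi * sB)
    sC <- (p[sw][xc] - (1 - lead)) / lead
    x[sw][xc] <- A - (A - x0) * sC^2
  }
  list(x = x, z = z)
}

#' Generate ground-truth hexapod marker trajectories
#'
#' The foot (TiTa) of each leg follows the programmed stance (linear
#' backward at z = 0) / swing (forward with sinusoidal lift) cycle at the
#' given frequency, duty cycle and per-leg phases. Proximal markers follow
#' through a fixed-segment-length kinematic chain: the coxa direction
#' rocks slowly about the body y-axis (amplitude `coxaSwing`), and the
#' knee (FTi) solves the two-segment inverse kinematics with a
#' deterministic dorsal elbow choice. True swing/stance onset times are
#' recorded per leg.
#'
#' @param spec a [GaitSpec-class].
#' @param nFrames number of frames.
#' @param fps frame rate (Hz).
#' @param topology a [MarkerTopology-class].
#' @return list with `positions` (nFrames x 26 x 3 array, markers in
#'   topology order), `events` (data.frame `leg`, `type`, `time_s`),
#'   `fps`, and `spec`.
#' @export
generateTrajectories <- function(spec, nFrames, fps = 500,
                                 topology = hexapodTopology()) {
  mk <- markers(topology)
  n <- as.integer(nFrames)
  tt <- (seq_len(n) - 1L) / fps
  pos <- array(NA_real_, c(n, length(mk), 3L),
               dimnames = list(NULL, mk, c("x", "y", "z")))
  A <- spec@strideLength / 2
  events <- list()
  for (lg in names(spec@geometry)) {
    g <- spec@geometry[[lg]]
    ph <- spec@phases[[lg]]
    p <- (spec@freq * tt + ph) %% 1
    wave <- .footWave(p, spec@duty, A, spec@liftHeight, spec@xLead)
    foot <- cbind(g$foot[1L] + wave$x, rep(g$foot[2L], n),
                  g$foot[3L] + wave$z)
    # coxa root is fixed; the coxa rocks about the body y-axis
    amp <- .rad(spec@coxaSwing)
    aRock <- amp * sin(2 * pi * p)
    L1 <- g$seg[1L]; L2 <- g$seg[2L]; L3 <- g$seg[3L]
    ctr <- matrix(NA_real_, n, 3L)
    fti <- matrix(NA_real_, n, 3L)
    for (i in seq_len(n)) {
      u <- as.numeric(.rotY(aRock[i]) %*% g$coxaDir)
      c0 <- g$thc + L1 * u
      ctr[i, ] <- c0
      dvec <- foot[i, ] - c0
      d <- sqrt(sum(dvec^2))
      if (d > L2 + L3 - 1e-9 || d < abs(L2 - L3) + 1e-9)
        stop("unreachable pose for leg ", lg, " at frame ", i,
             ": |CTr-TiTa| = ", signif(d, 4), " with femur+tibia = ",
             L2 + L3)
      axis <- dvec / d
      a_ <- (L2^2 - L3^2 + d^2) / (2 * d)
      h2 <- L2^2 - a_^2
      if (h2 <= 0)
        stop("unreachable pose for leg ", lg, " at frame ", i)
      w <- g$elbow - sum(g$elbow * axis) * axis
      nw <- sqrt(sum(w^2))
      if (nw < 1e-9) w <- c(0, 0, 1) - axis[3L] * axis else w <- w / nw
      fti[i, ] <- c0 + a_ * axis + sqrt(h2) * w
    }
    pos[, paste0(lg, ".ThC"), ] <- matrix(g$thc, n, 3L, byrow = TRUE)
    pos[, paste0(lg, ".CTr"), ] <- ctr
    pos[, paste0(lg, ".FTi"), ] <- fti
    pos[, paste0(lg, ".TiTa"), ] <- foot
    cxName <- paste0(lg, ".Cx")
    if (cxName %in% mk) {
      # coxal marker: midway along the coxa, offset perpendicular to it
      m3 <- matrix(NA_real_, n, 3L)
      for (i in seq_len(n)) {
        u <- as.numeric(.rotY(aRock[i]) %*% g$coxaDir)
        mvec <- .cross3(u, c(0, 0, 1))
        mvec <- .unit(mvec)
        if (mvec[1L] < 0) mvec <- -mvec
        m3[i, ] <- g$thc + 0.5 * L1 * u + 0.45 * L1 * mvec
      }
      pos[, cxName, ] <- m3
    }
    # true transition times: touchdown at phase 0, liftoff at phase = duty
    T <- (n - 1L) / fps
    kmax <- ceiling(spec@freq * T) + 1L
    for (k in 0:kmax) {
      tStance <- (k - ph) / spec@freq
      tSwing <- (k + spec@duty - ph) / spec@freq
      if (tStance >= 0 && tStance <= T)
        events[[length(events) + 1L]] <-
          data.frame(leg = lg, type = "stance", time_s = tStance)
      if (tSwing >= 0 && tSwing <= T)
        events[[length(events) + 1L]] <-
          data.frame(leg = lg, type = "swing", time_s = tSwing)
    }
  }
  ev <- do.call(rbind, events)
  ev <- ev[order(ev$leg, ev$time_s), ]
  rownames(ev) <- NULL
  list(positions = pos, events = ev, fps = fps, spec = spec)
}

#' Build the default synthetic stereo rig
#'
#' Two pinhole cameras below the working plane (the glass plate the animal
#' walks on): one ventral camera looking straight up and one tilted toward
#' the animal's front, with optical axes `alphaDeg` apart. Focal lengths
#' are set so the scale at the working volume is `scalePxPerCm`. The
#' default separation of 60 degrees reproduces the characteristic error
#' anisotropy of a below-plate rig: quantization-limited z errors roughly
#' twice the x/y errors.
#'
#' @param distance camera distance from the volume center (mm).
#' @param alphaDeg angle between the optical axes (degrees).
#' @param imageSize integer(2) width x height (px).
#' @param scalePxPerCm working-volume scale (px/cm).
#' @param center numeric(3), center of the tracking volume (mm).
#' @return list of two [CameraModel-class] objects.
#' @export
makeStereoRig <- function(distance = 250, alphaDeg = 60,
                          imageSize = c(320L, 280L), scalePxPerCm = 30,
                          center = c(0, 0, 10)) {
  f <- scalePxPerCm / 10 * distance
  pp <- c((imageSize[1L] - 1) / 2, (imageSize[2L] - 1) / 2)
  a <- .rad(alphaDeg)
  C1 <- center - c(0, 0, distance)
  C2 <- center + distance * c(-sin(a), 0, -cos(a))
  mkcam <- function(C) {
    R <- .lookAtRotation(C, center)
    cameraModel(focal = f, principal = pp, rotation = R,
                translation = as.numeric(-R %*% C))
  }
  list(mkcam(C1), mkcam(C2))
}

#' Generate a synthetic calibration jig
#'
#' A non-coplanar 3D grid of points spanning the tracking volume, plus the
#' exact (optionally noisy) pixel detections in each camera.
#'
#' @param cameras list of two [CameraModel-class] objects.
#' @param extent numeric(3), jig side lengths (mm).
#' @param center numeric(3), jig center (mm).
#' @param grid integer(3), points per axis (default 3 x 3 x 3 = 27).
#' @param noiseSd detection noise sd (px; 0 = exact).
#' @return list with `points` (n x 3) and `detections` (list of two
#'   n x 2 matrices).
#' @export
makeJig <- function(cameras, extent = c(20, 20, 10), center = c(0, 0, 5),
                    grid = c(3L, 3L, 3L), noiseSd = 0) {
  ax <- lapply(1:3, function(i)
    seq(center[i] - extent[i] / 2, center[i] + extent[i] / 2,
        length.out = grid[i]))
  pts <- as.matrix(expand.grid(x = ax[[1L]], y = ax[[2L]], z = ax[[3L]]))
  det <- lapply(cameras, function(cam) {
    uv <- projectPoints(cam, pts)
    if (noiseSd > 0)
      uv <- uv + matrix(stats::rnorm(length(uv), 0, noiseSd), ncol = 2L)
    uv
  })
  list(points = pts, detections = det)
}

# static low-frequency clutter field in [0, amp * peak]
.clutterField <- function(h, w, amp, peak, sigma = 25) {
  if (amp <= 0) return(matrix(0, h, w))
  raw <- matrix(stats::rnorm(h * w), h, w)
  sm <- .gaussianBlur(raw, sigma)
  rng <- range(sm)
  if (diff(rng) < 1e-12) return(matrix(0, h, w))
  (sm - rng[1L]) / diff(rng) * amp * peak
}

#' Render synchronized stereo video of a marker trajectory set
#'
#' Each frame is a static low-frequency clutter background plus a Gaussian
#' blob at every visible marker's projected position plus i.i.d. Gaussian
#' sensor noise, quantized to 8 bits. Markers listed in the occlusion
#' schedule are omitted for the scheduled frames (and camera), emulating
#' transient occlusions. Rendering is bit-deterministic given `seed`.
#'
#' @param truth nFrames x nMarkers x 3 array (world coordinates, marker
#'   names as dimnames), e.g. from [generateTrajectories()].
#' @param cameras list of two [CameraModel-class] objects.
#' @param rspec a [RenderSpec-class].
#' @param seed integer RNG seed.
#' @return list of two [FrameStack-class] objects.
#' @export
renderStereo <- function(truth, cameras, rspec = renderSpec(),
                         seed = 1L) {
  set.seed(seed)
  n <- dim(truth)[1L]; nm <- dim(truth)[2L]
  mk <- dimnames(truth)[[2L]]
  w <- rspec@imageSize[1L]; h <- rspec@imageSize[2L]
  rb <- as.integer(ceiling(4 * rspec@blobSigma))
  occ <- rspec@occlusions
  stacks <- vector("list", 2L)
  flat <- matrix(truth, nrow = n * nm, ncol = 3L)
  warnedOutside <- FALSE
  for (ci in 1:2) {
    uvAll <- projectPoints(cameras[[ci]], flat)
    uvArr <- array(uvAll, c(n, nm, 2L))
    clutter <- .clutterField(h, w, rspec@clutterAmp, rspec@blobPeak)
    frames <- array(0L, c(h, w, n))
    for (t in seq_len(n)) {
      img <- clutter + matrix(stats::rnorm(h * w, 0, rspec@noiseSd), h, w)
      for (m in seq_len(nm)) {
        if (nrow(occ)) {
          hit <- occ$marker == mk[m] & occ$from <= t & occ$to >= t &
            (is.na(occ$camera) | occ$camera == ci)
          if (any(hit)) next
        }
        u <- uvArr[t, m, 1L]; v <- uvArr[t, m, 2L]
        if (is.na(u)) next
        if ((u < -rb || u > w - 1 + rb || v < -rb || v > h - 1 + rb)) {
          if (!warnedOutside) {
            warning("marker projected outside the image; blob clipped")
            warnedOutside <- TRUE
          }
          next
        }
        c0 <- max(0L, as.integer(floor(u)) - rb)
        c1 <- min(w - 1L, as.integer(ceiling(u)) + rb)
        r0 <- max(0L, as.integer(floor(v)) - rb)
        r1 <- min(h - 1L, as.integer(ceiling(v)) + rb)
        if (c0 > c1 || r0 > r1) next
        us <- c0:c1; vs <- r0:r1
        blob <- rspec@blobPeak *
          exp(-(outer((vs - v)^2, (us - u)^2, "+")) /
                (2 * rspec@blobSigma^2))
        img[vs + 1L, us + 1L] <- img[vs + 1L, us + 1L] + blob
      }
      frames[, , t] <- as.integer(pmin(255, pmax(0, .roundHalfAway(img))))
    }
    stacks[[ci]] <- frameStack(frames, fps = rspec@fps,
                               mmPerPx = 10 / rspec@scalePxPerCm)
  }
  stacks
}

#' Simulate a complete synthetic walking bout
#'
#' End-to-end fixture generator: programmed gait trajectories, a rigid
#' body-to-world (jig) transform, the default below-plate stereo rig, a
#' calibration jig, rendered stereo video, and keyframe annotations
#' (projected ground truth) at the requested cadence - everything needed
#' to exercise the full pipeline with known ground truth.
#'
#' @param nFrames number of frames.
#' @param gait a [GaitSpec-class].
#' @param rspec a [RenderSpec-class].
#' @param cameras optional rig (default [makeStereoRig()] sized to the
#'   gait's working volume).
#' @param worldRotationDeg rotation of the body frame about z into world
#'   (jig) coordinates.
#' @param worldTranslation numeric(3) translation of the same transform.
#' @param keyframeEvery cadence (frames) of full ground-truth keyframes
#'   (1 = first frame only, emulating an initial user annotation; smaller
#'   cadences emulate the user's occasional corrections).
#' @param seed integer seed (overrides the gait seed).
#' @return list with `truthBody`, `truthWorld` (arrays), `events`,
#'   `stacks`, `cameras`, `jig`, `keyframes`, `world` (a
#'   [BodyFrame-class] holding the world-to-body rigid transform),
#'   `gait`, `rspec`, `topology`.
#' @export
simulateBout <- function(nFrames, gait = gaitSpec(), rspec = renderSpec(),
                         cameras = NULL, worldRotationDeg = 25,
                         worldTranslation = c(5, -3, 0),
                         keyframeEvery = NA_integer_, seed = NULL) {
  if (is.null(seed)) seed <- gait@seed
  topo <- hexapodTopology()
  gen <- generateTrajectories(gait, nFrames, fps = rspec@fps,
                              topology = topo)
  Rz <- .rotZ(.rad(worldRotationDeg))
  world <- new("BodyFrame", rotation = t(Rz),
               translation = as.numeric(-t(Rz) %*% worldTranslation),
               provenance = list(role = "world-to-body"))
  truthWorld <- applyFrame(world, gen$positions, inverse = TRUE)
  dimnames(truthWorld) <- dimnames(gen$positions)
  if (is.null(cameras))
    cameras <- makeStereoRig(center = c(0, 0, 10),
                             imageSize = rspec@imageSize,
                             scalePxPerCm = rspec@scalePxPerCm)
  stacks <- renderStereo(truthWorld, cameras, rspec, seed = seed)
  jig <- makeJig(cameras, extent = c(80, 60, 30), center = c(0, 0, 15))
  kfIdx <- if (is.na(keyframeEvery)) 1L
           else unique(c(seq(1L, nFrames, by = keyframeEvery)))
  ann <- list()
  for (k in kfIdx)
    ann[[as.character(k)]] <-
      .annotateFromPositions(truthWorld[k, , ], cameras, markers(topo))
  list(truthBody = gen$positions, truthWorld = truthWorld,
       events = gen$events, stacks = stacks, cameras = cameras, jig = jig,
       keyframes = keyframeSet(ann), world = world, gait = gait,
       rspec = rspec, topology = topo)
}
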