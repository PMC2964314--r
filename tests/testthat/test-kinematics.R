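test_that("triplet angles match the law-of-cosines oracle", {
  expect_equal(angleThreePoints(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)), 180)
  expect_equal(angleThreePoints(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)), 90)
  set.seed(31)
  for (i in 1:25) {
    a <- runif(3, -5, 5); b <- runif(3, -5, 5); c_ <- runif(3, -5, 5)
    ab <- sqrt(sum((a - b)^2)); cb <- sqrt(sum((c_ - b)^2))
    ac <- sqrt(sum((a - c_)^2))
    oracle <- acos(min(1, max(-1, (ab^2 + cb^2 - ac^2) /
                                (2 * ab * cb)))) * 180 / pi
    expect_equal(angleThreePoints(a, b, c_), oracle, tolerance = 1e-9)
  }
  expect_error(angleThreePoints(c(1, 1, 1), c(1, 1, 1), c(0, 0, 0)),
               "zero-length")
})

test_that("the TrF plane angle measures leg non-planarity", {
  thc <- c(0, 0, 10); ctr <- c(2, 3, 8); fti <- c(5, 7, 5)
  tita0 <- fti + 1.6 * (fti - ctr) + c(0.5, -0.3, 0.2)
  # force coplanarity: project tita into the fti/ctr/thc plane
  n <- HexaTrack:::.unit(HexaTrack:::.cross3(fti - ctr, thc - ctr))
  titaP <- tita0 - sum((tita0 - ctr) * n) * n
  expect_lt(trfAngle(titaP, fti, ctr, thc), 1e-6)
  # rotating the distal point about the CTr-FTi axis by 30 deg gives 30
  ax <- fti - ctr
  Rr <- HexaTrack:::.rotAxis(ax, 30 * pi / 180)
  titaR <- as.numeric(Rr %*% (titaP - fti)) + fti
  expect_equal(trfAngle(titaR, fti, ctr, thc), 30, tolerance = 1e-6)
  # perpendicular planes
  expect_equal(trfAngle(c(0, 1, 1), c(0, 0, 1), c(0, 0, 0), c(1, 0, 0)),
               90, tolerance = 1e-9)
  # collinear triplet is flagged absent
  expect_true(is.na(trfAngle(c(2, 0, 0), c(1, 0, 0), c(0, 0, 0),
                             c(5, 5, 5))))
})

test_that("ThC promotion/abduction angles invert their construction", {
  thc <- c(0, 0, 0)
  # coxa straight down
  a <- thcAngles(c(0, 0, -1), thc, side = "L")
  expect_equal(c(a$thc1, a$thc2), c(0, 0))
  # pure promotion by 30 degrees
  a2 <- thcAngles(c(sin(pi / 6), 0, -cos(pi / 6)), thc, side = "L")
  expect_equal(a2$thc1, 30, tolerance = 1e-9)
  expect_equal(a2$thc2, 0, tolerance = 1e-9)
  # forward-kinematics round trip for random vectors, both sides
  set.seed(41)
  for (side in c("L", "R")) {
    s <- if (side == "L") 1 else -1
    for (i in 1:20) {
      v <- c(runif(1, -1, 1), runif(1, -1, 1), -runif(1, 0.2, 1.5))
      a <- thcAngles(thc + v, thc, side = side)
      th1 <- a$thc1 * pi / 180; th2 <- a$thc2 * pi / 180
      r <- sqrt(sum(v^2))
      vrec <- as.numeric(HexaTrack:::.rotY(th1) %*%
                           c(0, s * r * sin(th2), -r * cos(th2)))
      expect_lt(max(abs(vrec - v)), 1e-9)
    }
  }
  # vertical coxa vector (xz-projection null) is flagged
  a3 <- thcAngles(c(0, 1, 0), c(0, 0, 0), side = "L")
  expect_true(is.na(a3$thc1))
})

test_that("ThC3 measures coxal rotation about the coxa axis", {
  thc <- c(0, 0, 0)
  v <- c(0.4, 0.3, -0.9)            # ThC -> CTr
  ctr <- thc + v
  th1 <- atan2(v[1], -v[3])
  nref <- as.numeric(HexaTrack:::.rotY(th1) %*% c(1, 0, 0))
  # an in-plane coxal marker defines the zero pose
  w <- HexaTrack:::.cross3(nref, v)      # in the reference plane
  cox0 <- thc + 0.5 * v + 0.3 * w
  expect_lt(abs(thc3Angle(ctr, thc, cox0, side = "L")), 1e-9)
  # rotating the marker about the coxa axis by 25 deg reads 25
  Rr <- HexaTrack:::.rotAxis(v, 25 * pi / 180)
  cox25 <- as.numeric(Rr %*% (cox0 - thc)) + thc
  expect_equal(abs(thc3Angle(ctr, thc, cox25, side = "L")), 25,
               tolerance = 1e-9)
  # in-plane displacement of the marker leaves the angle unchanged
  cox25b <- cox25 + 0.4 * v
  expect_equal(thc3Angle(ctr, thc, cox25, side = "L"),
               thc3Angle(ctr, thc, cox25b, side = "L"),
               tolerance = 1e-9)
  # collinear marker is flagged
  expect_true(is.na(thc3Angle(ctr, thc, thc + 0.7 * v, side = "L")))
})

test_that("triplet and plane angles are rigid-transform invariant", {
  gait <- gaitSpec(seed = 14)
  gen <- generateTrajectories(gait, 100)
  topo <- hexapodTopology()
  ang0 <- computeAllAngles(gen$positions, topo)
  R <- randomRotation(51); tr <- c(12, -5, 30)
  flat <- sweep(matrix(gen$positions, ncol = 3) %*% t(R), 2, -tr)
  moved <- array(flat, dim = dim(gen$positions))
  dimnames(moved) <- dimnames(gen$positions)
  ang1 <- computeAllAngles(moved, topo)
  for (joint in c("FTi", "CTr", "TrF")) {
    i0 <- ang0$joint == joint
    expect_lt(max(abs(ang0$angle_deg[i0] - ang1$angle_deg[i0]),
                  na.rm = TRUE), 1e-6)
  }
  # ThC angles are frame-dependent by definition: they do change
  iT <- ang0$joint == "ThC1"
  expect_gt(max(abs(ang0$angle_deg[iT] - ang1$angle_deg[iT]),
                na.rm = TRUE), 1)
})

test_that("angle series are complete, continuous, and in range", {
  gait <- gaitSpec(seed = 15)
  gen <- generateTrajectories(gait, 250)
  topo <- hexapodTopology()
  ang <- computeAllAngles(gen$positions, topo)
  # TrF only for middle/hind legs; ThC3 only for front legs
  expect_setequal(unique(ang$leg[ang$joint == "TrF"]),
                  c("R2", "L2", "R3", "L3"))
  expect_setequal(unique(ang$leg[ang$joint == "ThC3"]), c("R1", "L1"))
  expect_true(all(ang$status == "ok"))
  trip <- ang$joint %in% c("FTi", "CTr", "TrF")
  expect_true(all(ang$angle_deg[trip] >= 0 & ang$angle_deg[trip] <= 180))
  # no wrap discontinuities within the programmed gait
  for (key in split(ang, list(ang$leg, ang$joint), drop = TRUE)) {
    expect_lt(max(abs(diff(key$angle_deg))), 20)
  }
})

test_that("angles from reverted markers are flagged absent", {
  gait <- gaitSpec(seed = 16)
  gen <- generateTrajectories(gait, 10)
  topo <- hexapodTopology()
  st <- trackState(10, topo)
  st@pos3d <- unname(gen$positions)
  st@status[] <- 2L
  st@status[4, match("R2.FTi", st@markers)] <- 3L
  ang <- computeAllAngles(st, topo)
  bad <- ang[ang$leg == "R2" & ang$frame == 4 &
               ang$joint %in% c("FTi", "CTr", "TrF"), ]
  expect_true(all(bad$status == "absent"))
  expect_true(all(is.na(bad$angle_deg)))
  ok <- ang[ang$leg == "R2" & ang$frame == 5, ]
  expect_true(all(ok$status == "ok"))
})
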