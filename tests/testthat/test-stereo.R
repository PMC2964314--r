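test_that("forward projection follows the pinhole model", {
  cam <- cameraModel(focal = c(1, 1), principal = c(0, 0))
  # x/z, y/z scaling
  expect_equal(as.numeric(projectPoints(cam, c(1, 2, 4))), c(0.25, 0.5))
  # a point on the optical axis lands on the principal point
  cam2 <- cameraModel(focal = 750, principal = c(159.5, 139.5))
  expect_equal(as.numeric(projectPoints(cam2, c(0, 0, 123))),
               c(159.5, 139.5))
  # behind the camera is flagged invalid
  expect_true(all(is.na(projectPoints(cam, c(0, 0, -1)))))
})

test_that("projection matches the homogeneous 3x4 matrix oracle", {
  set.seed(11)
  for (i in 1:20) {
    R <- randomRotation(i)
    cam <- cameraModel(focal = runif(2, 300, 900),
                       principal = runif(2, 100, 200), rotation = R,
                       translation = c(runif(2, -20, 20), runif(1, 150, 300)))
    K <- rbind(c(cam@focal[1], 0, cam@principal[1]),
               c(0, cam@focal[2], cam@principal[2]), c(0, 0, 1))
    P <- K %*% cbind(cam@rotation, cam@translation)
    p <- runif(3, -30, 30)
    ph <- as.numeric(P %*% c(p, 1))
    if (ph[3] <= 0) next
    expect_equal3(projectPoints(cam, p), ph[1:2] / ph[3], tol = 1e-8)
  }
})

test_that("back-projection inverts projection (100 random pixels)", {
  set.seed(21)
  rig <- defaultRig()
  for (cam in rig) {
    uv <- cbind(runif(50, 0, 319), runif(50, 0, 279))
    for (i in seq_len(nrow(uv))) {
      ray <- backProject(cam, uv[i, ])
      p <- ray@origin + 260 * ray@direction   # a scene point on the ray
      expect_equal3(projectPoints(cam, p), uv[i, ], tol = 1e-9 * 300)
    }
  }
  # principal point maps to the optical axis
  cam <- rig[[1]]
  ray <- backProject(cam, cam@principal)
  zAxis <- as.numeric(crossprod(cam@rotation, c(0, 0, 1)))
  expect_equal3(abs(sum(ray@direction * zAxis)), 1, tol = 1e-12)
})

test_that("calibration recovers a camera exactly from noiseless data", {
  rig <- defaultRig()
  jig <- makeJig(rig, extent = c(80, 60, 30), center = c(0, 0, 15))
  for (ci in 1:2) {
    cam <- calibrateCamera(jig$points, jig$detections[[ci]])
    errs <- vapply(seq_len(nrow(jig$points)), function(i)
      reprojectionError(cam, jig$points[i, ], jig$detections[[ci]][i, ]),
      numeric(1))
    expect_lt(max(errs), 1e-6)
  }
  # an 8-corner cube jig is enough
  cube <- as.matrix(expand.grid(x = c(-10, 10), y = c(-10, 10),
                                z = c(5, 25)))
  det1 <- projectPoints(rig[[1]], cube)
  cam <- calibrateCamera(cube, det1)
  errs <- vapply(1:8, function(i)
    reprojectionError(cam, cube[i, ], det1[i, ]), numeric(1))
  expect_lt(max(errs), 1e-6)
})

test_that("calibration rejects degenerate jigs", {
  rig <- defaultRig()
  flat <- as.matrix(expand.grid(x = c(-10, 0, 10), y = c(-10, 0, 10),
                                z = 10))
  expect_error(calibrateCamera(flat, projectPoints(rig[[1]], flat)),
               "coplanar")
  few <- flat[1:4, ]
  expect_error(calibrateCamera(few, projectPoints(rig[[1]], few)),
               "at least 6")
  expect_error(
    retriangulationError(rig, matrix(0, 2, 2), matrix(0, 3, 2),
                         matrix(0, 3, 3)),
    "matching lengths")
})

test_that("noisy calibration residuals follow least-squares theory", {
  rig <- defaultRig()
  jig <- makeJig(rig, extent = c(80, 60, 30), center = c(0, 0, 15))
  sigma <- 0.5
  n <- nrow(jig$points)
  set.seed(31)
  meanErr <- replicate(100, {
    noisy <- jig$detections[[1]] + matrix(rnorm(2 * n, 0, sigma), n, 2)
    cam <- calibrateCamera(jig$points, noisy)
    mean(sqrt(rowSums((projectPoints(cam, jig$points) - noisy)^2)))
  })
  # 10 free parameters leave (2n - 10)/2n of the noise variance in the
  # residuals; the mean distance of a 2D Gaussian is sigma * sqrt(pi/2)
  theory <- sigma * sqrt(pi / 2) * sqrt(1 - 10 / (2 * n))
  expect_lt(abs(mean(meanErr) - theory), 0.1)
  # realism check: same order as the reference system's 0.3-0.9 px
  expect_gt(mean(meanErr), 0.3)
  expect_lt(mean(meanErr), 0.9)
})

test_that("midpoint triangulation handles intersecting and skew rays", {
  # rays through a common point
  p <- c(3, -2, 7)
  r1 <- new("Ray3D", origin = c(0, 0, 0), direction = HexaTrack:::.unit(p))
  r2 <- new("Ray3D", origin = c(10, 0, 0),
            direction = HexaTrack:::.unit(p - c(10, 0, 0)))
  res <- triangulateRays(r1, r2)
  expect_equal3(res@point, p, tol = 1e-12)
  expect_lt(res@error, 1e-12)
  # skew rays offset by exactly d at closest approach
  d <- 0.37
  r3 <- new("Ray3D", origin = c(0, 0, 0), direction = c(1, 0, 0))
  r4 <- new("Ray3D", origin = c(0, 0, d), direction = c(0, 1, 0))
  res <- triangulateRays(r3, r4)
  expect_equal(res@error, d, tolerance = 1e-12)
  expect_equal3(res@point, c(0, 0, d / 2), tol = 1e-12)
  # symmetry in the arguments
  res2 <- triangulateRays(r4, r3)
  expect_identical(res@point, res2@point)
  expect_identical(res@error, res2@error)
  # parallel rays fail
  r5 <- new("Ray3D", origin = c(0, 1, 0), direction = c(1, 0, 0))
  expect_error(triangulateRays(r3, r5), "parallel")
})

test_that("reprojection error is the Euclidean pixel distance", {
  cam <- cameraModel(focal = 750, principal = c(159.5, 139.5))
  p <- c(5, -3, 250)
  uv <- as.numeric(projectPoints(cam, p))
  expect_equal(reprojectionError(cam, p, uv), 0)
  expect_equal(reprojectionError(cam, p, uv + c(3, 4)), 5)
  # batch mean equals the mean of per-point values
  pts <- matrix(runif(30, -20, 20), 10, 3)
  pts[, 3] <- pts[, 3] + 250
  obs <- projectPoints(cam, pts) + 0.3
  per <- vapply(1:10, function(i)
    reprojectionError(cam, pts[i, ], obs[i, ]), numeric(1))
  expect_equal(mean(per), mean(sqrt(rowSums(
    (projectPoints(cam, pts) - obs)^2))))
})

test_that("retriangulation error is zero for exact detections and matches
           a per-point oracle for quantized ones", {
  rig <- defaultRig()
  jig <- makeJig(rig, extent = c(20, 20, 10), center = c(0, 0, 10))
  expect_lt(retriangulationError(rig, jig$detections[[1]],
                                 jig$detections[[2]], jig$points), 1e-9)
  q1 <- HexaTrack:::.roundHalfAway(jig$detections[[1]])
  q2 <- HexaTrack:::.roundHalfAway(jig$detections[[2]])
  got <- retriangulationError(rig, q1, q2, jig$points)
  oracle <- mean(vapply(seq_len(nrow(jig$points)), function(i) {
    t1 <- backProject(rig[[1]], q1[i, ])
    t2 <- backProject(rig[[2]], q2[i, ])
    sqrt(sum((triangulateRays(t1, t2)@point - jig$points[i, ])^2))
  }, numeric(1)))
  expect_equal(got, oracle, tolerance = 1e-12)
})

test_that("camera serialization round-trips through YAML and JSON", {
  cam <- defaultRig()[[2]]
  for (ext in c(".yaml", ".json")) {
    path <- tempfile(fileext = ext)
    writeCamera(cam, path)
    back <- readCamera(path)
    expect_equal(back@focal, cam@focal, tolerance = 1e-9)
    expect_equal(back@principal, cam@principal, tolerance = 1e-9)
    expect_lt(max(abs(back@rotation - cam@rotation)), 1e-9)
    expect_equal(back@translation, cam@translation, tolerance = 1e-9)
    unlink(path)
  }
})
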