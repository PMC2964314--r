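# A shared noiseless bout fixture for this file (rendered once).
.boutEnv <- new.env()
getCleanBout <- function() {
  if (is.null(.boutEnv$bout)) .boutEnv$bout <- cleanBout(40, seed = 5)
  .boutEnv$bout
}
getCleanTrack <- function() {
  if (is.null(.boutEnv$track)) {
    b <- getCleanBout()
    .boutEnv$p1 <- preprocessStack(b$stacks[[1]])
    .boutEnv$p2 <- preprocessStack(b$stacks[[2]])
    .boutEnv$track <- propagateTrack(
      b$keyframes, list(.boutEnv$p1$stack, .boutEnv$p2$stack), b$cameras,
      b$topology, medians = list(.boutEnv$p1$medians, .boutEnv$p2$medians))
  }
  .boutEnv$track
}

test_that("the topology describes 26 markers in proximal order", {
  topo <- hexapodTopology()
  expect_equal(nMarkers(topo), 26L)
  expect_equal(length(legs(topo)), 6L)
  df <- topo@markers
  expect_equal(sum(df$joint == "Cx"), 2L)         # front coxal markers
  for (lg in legs(topo)) {
    ord <- HexaTrack:::.legOrder(topo, lg)
    for (i in seq_len(nrow(ord))[-1]) {
      prox <- ord$proximal[i]
      expect_lt(match(prox, ord$marker), i)       # proximal before distal
    }
  }
})

test_that("noiseless tracking accepts every frame with sub-blob error", {
  b <- getCleanBout()
  st <- getCleanTrack()
  expect_equal(sum(trackStatus(st) == 3L), 0L)
  expect_equal(nEstimates3d(st), 40L * 26L)
  res <- evaluateTrack(st, b$truthWorld)
  blobSigmaMm <- b$rspec@blobSigma * 10 / b$rspec@scalePxPerCm
  expect_lt(attr(res, "overall"), 0.5 * blobSigmaMm)
})

test_that("tracking is deterministic", {
  b <- getCleanBout()
  st1 <- getCleanTrack()
  st2 <- propagateTrack(
    b$keyframes, list(.boutEnv$p1$stack, .boutEnv$p2$stack), b$cameras,
    b$topology, medians = list(.boutEnv$p1$medians, .boutEnv$p2$medians))
  expect_identical(positions3d(st1), positions3d(st2))
  expect_identical(trackStatus(st1), trackStatus(st2))
})

test_that("occluded markers revert and freeze at the last position", {
  occ <- data.frame(marker = "R2.FTi", from = 15L, to = 24L,
                    camera = NA_integer_)
  b <- simulateBout(40, gait = gaitSpec(seed = 5),
                    rspec = renderSpec(clutterAmp = 0, noiseSd = 0,
                                       occlusions = occ),
                    keyframeEvery = NA, seed = 5)
  st <- trackBout(b$stacks[[1]], b$stacks[[2]], b$cameras, b$keyframes,
                  b$topology)
  mi <- match("R2.FTi", st@markers)
  stt <- trackStatus(st)[, mi]
  expect_true(all(stt[16:24] == 3L))      # reverted during the gap
  # frozen at the last accepted position
  frozen <- positions3d(st)[16:24, mi, ]
  expect_lt(max(abs(sweep(frozen, 2, positions3d(st)[15, mi, ]))), 1e-12)
  # resumes afterwards
  expect_true(any(stt[28:40] == 2L))
})

test_that("a closed triangulation gate reverts every tracked step", {
  b <- getCleanBout()
  st <- propagateTrack(
    b$keyframes, list(.boutEnv$p1$stack, .boutEnv$p2$stack), b$cameras,
    b$topology, settings = trackerSettings(triErrorMax = 1e-12),
    medians = list(.boutEnv$p1$medians, .boutEnv$p2$medians))
  stt <- trackStatus(st)
  expect_true(all(stt[-1, ] == 3L))       # everything but the keyframe
})

test_that("gating is monotone in the triangulation threshold", {
  b <- getCleanBout()
  loose <- getCleanTrack()
  tight <- propagateTrack(
    b$keyframes, list(.boutEnv$p1$stack, .boutEnv$p2$stack), b$cameras,
    b$topology, settings = trackerSettings(triErrorMax = 0.02),
    medians = list(.boutEnv$p1$medians, .boutEnv$p2$medians))
  # accepted under the tight gate implies accepted under the loose gate
  expect_true(all(trackStatus(loose)[trackStatus(tight) == 2L] == 2L))
})

test_that("propagation respects the halfway rule between keyframes", {
  plan <- HexaTrack:::.propagationPlan(c(1L, 101L), 120L)
  origins <- vapply(plan, `[[`, integer(1), "origin")
  fwd <- plan[[which(origins == 1L)]]
  bwd <- plan[[which(origins == 101L & vapply(plan, `[[`, "",
                                              "direction") == "backward")]]
  expect_equal(range(fwd$frames), c(2L, 51L))
  expect_equal(range(bwd$frames), c(52L, 100L))
  # a lone keyframe mid-movie covers the whole movie
  plan1 <- HexaTrack:::.propagationPlan(60L, 120L)
  covered <- sort(unique(c(60L, unlist(lapply(plan1, `[[`, "frames")))))
  expect_equal(covered, 1:120)
})

test_that("user updates re-propagate at most halfway to their neighbours", {
  topo <- hexapodTopology()
  kf <- keyframeSet(stats::setNames(list(list(), list()), c("1", "101")))
  up <- applyUserUpdate(kf, 1L, list(), 120L, topo)
  # update at the first of keyframes {1, 101}: coverage at most frames 1-51
  fwd <- up$plan[[which(vapply(up$plan, `[[`, "", "direction") ==
                          "forward")]]
  expect_equal(max(fwd$frames), 51L)
  # an interior update splits into two bounded sub-intervals
  up2 <- applyUserUpdate(up$keyframes, 60L, list(), 120L, topo)
  dirs <- vapply(up2$plan, `[[`, "", "direction")
  expect_setequal(dirs, c("forward", "backward"))
  bwd <- up2$plan[[which(dirs == "backward")]]
  fwd2 <- up2$plan[[which(dirs == "forward")]]
  expect_equal(min(bwd$frames), 31L)       # halfway back toward 1
  expect_equal(max(fwd2$frames), 80L)      # halfway on toward 101
  # updating an existing keyframe replaces it in place
  up3 <- applyUserUpdate(up2$keyframes, 60L,
                         list(R1.ThC = list(cam1 = c(1, 2),
                                            cam2 = c(3, 4))), 120L, topo)
  expect_equal(keyframeIndices(up3$keyframes), c(1L, 60L, 101L))
  expect_error(applyUserUpdate(kf, 5L, list(bogus = list()), 120L, topo),
               "unknown marker")
})

test_that("a static scene bridged by two identical keyframes tracks
           constantly with no seam at the meeting point", {
  topo <- hexapodTopology()
  gait <- gaitSpec(seed = 3)
  gen <- generateTrajectories(gait, 1)
  pose <- gen$positions[rep(1, 30), , ]      # frozen animal
  dimnames(pose) <- dimnames(gen$positions)
  rig <- makeStereoRig()
  stacks <- renderStereo(pose, rig, renderSpec(clutterAmp = 0,
                                               noiseSd = 0), seed = 2)
  ann <- HexaTrack:::.annotateFromPositions(pose[1, , ], rig,
                                            markers(topo))
  kf <- keyframeSet(list(`1` = ann, `30` = ann))
  st <- trackBout(stacks[[1]], stacks[[2]], rig, kf, topo)
  p <- positions3d(st)
  for (mi in seq_len(26)) {
    rng <- apply(p[, mi, ], 2, function(v) diff(range(v)))
    expect_lt(max(rng), 0.05)   # no discontinuity anywhere, incl. frame 15/16
  }
})

test_that("partial keyframes keep user markers and inherit the rest", {
  b <- getCleanBout()
  st0 <- getCleanTrack()
  # user fixes one marker mid-bout with its true projections
  truth20 <- b$truthWorld[20, , ]
  mk <- markers(b$topology)
  ann <- HexaTrack:::.annotateFromPositions(
    truth20[match("R3.TiTa", mk), , drop = FALSE], b$cameras, "R3.TiTa")
  up <- applyUserUpdate(b$keyframes, 20L, ann, 40L, b$topology)
  st <- propagateTrack(up$keyframes,
                       list(.boutEnv$p1$stack, .boutEnv$p2$stack),
                       b$cameras, b$topology,
                       medians = list(.boutEnv$p1$medians,
                                      .boutEnv$p2$medians),
                       state = st0, plan = up$plan)
  mi <- match("R3.TiTa", st@markers)
  expect_equal(unname(trackStatus(st)[20, mi]), 1L) # user flag preserved
  expect_lt(sqrt(sum((positions3d(st)[20, mi, ] -
                        truth20[match("R3.TiTa", mk), ])^2)), 0.2)
  # other markers at that frame remain non-user
  expect_true(all(trackStatus(st)[20, -mi] != 1L))
})

test_that("track state round-trips through CSV and JSON", {
  st <- getCleanTrack()
  csv <- tempfile(fileext = ".csv")
  writeTrackCsv(st, csv)
  back <- readTrackCsv(csv, fps = st@fps)
  expect_equal(positions3d(back), unname(positions3d(st)),
               tolerance = 1e-9)
  expect_identical(unname(trackStatus(back)), unname(trackStatus(st)))
  js <- tempfile(fileext = ".json")
  writeTrackJson(st, js)
  back2 <- readTrackJson(js)
  expect_equal(positions3d(back2), positions3d(st), tolerance = 1e-12)
  expect_equal(positions2d(back2), positions2d(st), tolerance = 1e-12)
  unlink(c(csv, js))
})

test_that("keyframe sets round-trip through JSON", {
  b <- getCleanBout()
  path <- tempfile(fileext = ".json")
  writeKeyframes(b$keyframes, path)
  back <- readKeyframes(path)
  expect_equal(keyframeIndices(back), keyframeIndices(b$keyframes))
  a0 <- b$keyframes@annotations[["1"]]
  a1 <- back@annotations[["1"]]
  expect_equal(a1[["R2.FTi"]][["cam1"]],
               as.numeric(a0[["R2.FTi"]][["cam1"]]), tolerance = 1e-12)
  unlink(path)
})
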