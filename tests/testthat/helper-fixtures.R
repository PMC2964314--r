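# Shared fixtures for the test suite. Everything is generated in code;
# seeds are fixed so the suite is deterministic.

defaultRig <- function() makeStereoRig()

randomRotation <- function(seed = 1) {
  set.seed(seed)
  HexaTrack:::.rodrigues(stats::runif(3, -1, 1))
}

# a small noiseless bout fixture (full image size, clean render)
cleanBout <- function(nFrames = 60, seed = 5, keyframeEvery = NA) {
  simulateBout(nFrames,
               gait = gaitSpec(seed = seed),
               rspec = renderSpec(clutterAmp = 0, noiseSd = 0),
               keyframeEvery = keyframeEvery, seed = seed)
}

# mid/hind marker names
midHindMarkers <- function(topology = hexapodTopology())
  grep("^(R2|L2|R3|L3)", markers(topology), value = TRUE)

expect_equal3 <- function(a, b, tol = 1e-9)
  expect_lt(max(abs(as.numeric(a) - as.numeric(b))), tol)
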