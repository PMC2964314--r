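test_that("the spectral peak finds the step frequency", {
  fps <- 500; n <- 4096
  t <- (0:(n - 1)) / fps
  x <- sin(2 * pi * 4 * t)
  m <- estimateStepFrequency(list(leg = x), fps)
  binW <- fps / n
  expect_lt(abs(m@legFreqs[["leg"]] - 4), binW + 1e-9)
  # the trial frequency is the mean of the per-leg peaks
  m2 <- estimateStepFrequency(list(a = sin(2 * pi * 4.0 * t),
                                   b = sin(2 * pi * 4.2 * t)), fps)
  expect_equal(m2@f, mean(m2@legFreqs), tolerance = 1e-12)
  expect_lt(abs(m2@f - 4.1), binW)
  expect_error(estimateStepFrequency(list(leg = rep(1, n)), fps),
               "constant")
  expect_error(estimateStepFrequency(list(leg = x[1:100]), fps),
               "2 s")
})

test_that("the transition window is 1/(4f) seconds", {
  expect_equal(strideModel(c(leg = 2))@w, 0.125)
  expect_equal(strideModel(c(leg = 10))@w, 0.025)
})

test_that("derivative sign changes of the filtered series mark candidate
           transitions", {
  fps <- 500; f <- 4; n <- 2000
  t <- (0:(n - 1)) / fps
  x <- 5 * cos(2 * pi * f * t)
  cand <- candidateTransitions(x, f, fps)
  cand <- cand[cand$index > 125 & cand$index < n - 125, ]
  expect_gt(nrow(cand), 10)
  # peaks of cos at t = k/f; troughs at (k + 1/2)/f
  for (i in seq_len(nrow(cand))) {
    ph <- cand$time_s[i] * f
    dist <- if (cand$type[i] == "stance") abs(ph - round(ph))
            else abs(ph - 0.5 - round(ph - 0.5))
    expect_lt(dist / f * fps, 1.5)   # within ~1 sample of an extremum
  }
  # the zero-delay filter introduces no phase shift below cutoff
  xf <- HexaTrack:::.zeroPhaseLowpass(x, 2 * f, fps)
  mid <- 300:1700
  lag <- which.max(stats::ccf(xf[mid], x[mid], lag.max = 5,
                              plot = FALSE)$acf) - 6
  expect_equal(lag, 0L)
  # a monotone ramp has no candidates
  expect_equal(nrow(candidateTransitions(seq_len(n) * 0.01, f, fps)), 0L)
})

test_that("extrema transitions find the windowed AEP and PEP exactly", {
  fps <- 100
  # sawtooth: 1 s period, peak at integer seconds (sample 101, 201, ...)
  n <- 1000
  ph <- ((0:(n - 1)) / fps) %% 1
  x <- ifelse(ph < 0.5, 1 - 2 * ph, 2 * ph - 1)
  cand <- candidateTransitions(x, 1, fps)
  ev <- extremaTransitions(x, cand, w = 0.25, fps = fps)
  expect_true(all(ev$type %in% c("stance", "swing")))
  # stance onsets at the sawtooth maxima (phase 0), swing at minima (0.5)
  stance <- ev$time_s[ev$type == "stance"]
  swing <- ev$time_s[ev$type == "swing"]
  expect_lt(max(abs(stance - round(stance))), 1e-9)
  expect_lt(max(abs(swing - 0.5 - round(swing - 0.5))), 1e-9)
  # ties break to the earliest sample
  xf <- c(0, 0, 0, 0, 1, 1, 0, -1, -1, 0, 1, 1, 0, -1, 0, 0, 0)
  cnd <- data.frame(index = c(5L, 8L), time_s = c(4, 7) / fps,
                    type = c("stance", "swing"))
  evt <- extremaTransitions(xf, cnd, w = 4 / fps, fps = fps)
  expect_equal(evt$index, c(5L, 8L))
})

test_that("k-means cluster fit recovers the stance distribution", {
  z <- c(rep(0, 500), rep(5, 500))
  fit <- fitZClusters(z)
  expect_equal(fit$mu, 0)
  expect_equal(fit$sigma, 0)
  set.seed(61)
  z2 <- c(rnorm(2048, 0, 0.2), rnorm(2048, 3, 0.5))
  fit2 <- fitZClusters(z2)
  expect_lt(abs(fit2$mu - 0), 0.05)
  expect_lt(abs(fit2$sigma - 0.2), 0.05)
  expect_error(fitZClusters(rep(1, 100)), "degenerate")
})

test_that("z-height transitions fire at the threshold crossings", {
  fps <- 100
  # square wave: stance (z = 0) for samples 1-50, swing (z = 5) 51-100, ...
  z <- rep(c(rep(0, 50), rep(5, 50)), 5)
  n <- length(z)
  cand <- data.frame(index = c(51L, 101L, 151L, 201L),
                     time_s = c(50, 100, 150, 200) / fps,
                     type = c("swing", "stance", "swing", "stance"))
  ev <- zheightTransitions(z, cand, mu = 0, sigma = 0.1, w = 0.2,
                           fps = fps)
  # swing onset at the rising edge (sample 51), stance at falling (101)
  expect_equal(ev$index[ev$type == "swing"], c(51L, 151L))
  expect_equal(ev$index[ev$type == "stance"], c(101L, 201L))
  expect_false(any(ev$inherited))
  # no crossing in the window -> inherits the extrema time, flagged
  cand2 <- data.frame(index = 75L, time_s = 74 / fps, type = "swing")
  fb <- data.frame(index = 74L, time_s = 73 / fps, type = "swing",
                   inherited = FALSE)
  ev2 <- zheightTransitions(z, cand2, mu = 0, sigma = 0.1, w = 0.1,
                            fps = fps, fallback = fb)
  expect_true(ev2$inherited[1])
  expect_equal(ev2$index[1], 74L)
})

test_that("stride statistics compute period and duty per complete stride", {
  ev <- data.frame(type = c("stance", "swing", "stance", "swing",
                            "stance"),
                   time_s = c(1.0, 1.6, 2.0, 2.5, 3.1))
  ss <- strideStatistics(ev)
  expect_equal(ss$period_s, c(1.0, 1.1))
  expect_equal(ss$duty, c(0.6, 0.5 / 1.1))
  expect_true(all(ss$duty >= 0 & ss$duty <= 1))
  # no complete stride -> empty result
  expect_equal(nrow(strideStatistics(
    data.frame(type = "stance", time_s = 1))), 0L)
})

test_that("events alternate, shift with time, and the z method is
           amplitude invariant", {
  gait <- gaitSpec(freq = 4, duty = 0.55, seed = 2)
  gen <- generateTrajectories(gait, 1500)
  feet <- footSeries(gen$positions)
  an <- analyzeStrides(feet, 500)
  ev <- an$events@events
  for (lg in unique(ev$leg)) for (m in unique(ev$method)) {
    e <- ev[ev$leg == lg & ev$method == m, ]
    expect_true(all(diff(e$time_s) > 0))
    expect_true(all(e$type[-1] != e$type[-nrow(e)]))
  }
  # time-shift equivariance: drop the first k samples
  k <- 100L
  x <- feet$R1$x; z <- feet$R1$z
  f <- an$model@f; w <- an$model@w
  c1 <- candidateTransitions(x, f, 500)
  c2 <- candidateTransitions(x[-(1:k)], f, 500)
  e1 <- extremaTransitions(x, c1, w, 500)
  e2 <- extremaTransitions(x[-(1:k)], c2, w, 500)
  sh <- e1$index[e1$index > k + 31 & e1$index < 1500 - 31] - k
  expect_true(all(sh %in% e2$index))
  # affine rescaling of z rescales the cluster and keeps the events
  fit <- fitZClusters(z)
  fitA <- fitZClusters(2.5 * z + 10)
  expect_equal(fitA$mu, 2.5 * fit$mu + 10, tolerance = 1e-9)
  expect_equal(fitA$sigma, 2.5 * fit$sigma, tolerance = 1e-9)
  ez1 <- zheightTransitions(z, c1, fit$mu, fit$sigma, w, 500)
  ez2 <- zheightTransitions(2.5 * z + 10, c1, fitA$mu, fitA$sigma, w, 500)
  expect_equal(ez1$index, ez2$index)
})

test_that("programmed frequency and duty are recovered across the gait
           grid", {
  fps <- 500
  for (f in c(2, 8)) for (duty in c(0.4, 0.7)) {
    gen <- generateTrajectories(gaitSpec(freq = f, duty = duty), 1500,
                                fps = fps)
    an <- analyzeStrides(footSeries(gen$positions), fps)
    expect_lt(abs(an$model@f - f), fps / 1500 + 1e-9)   # one FFT bin
    dEx <- mean(an$strides$duty[an$strides$method == "extrema"])
    expect_lt(abs(dEx - duty), 0.03)
  }
})

test_that("with pre-touchdown backward foot motion the AEP/PEP duty
           exceeds the z-height duty", {
  gen <- generateTrajectories(gaitSpec(freq = 4, duty = 0.55,
                                       xLead = 0.04), 2000)
  an <- analyzeStrides(footSeries(gen$positions), 500)
  dEx <- mean(an$strides$duty[an$strides$method == "extrema"])
  dZ <- mean(an$strides$duty[an$strides$method == "zheight"])
  expect_gt(dEx, dZ)
  # the gap matches the programmed pre-touchdown/post-liftoff motion:
  # the extrema-bounded stance is longer by up to 2 * xLead of the cycle
  expect_lt(dEx - dZ, 2 * 0.04 + 0.02)
})
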