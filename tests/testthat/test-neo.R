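test_that("the energy operator matches its definition", {
  expect_equal(neo(c(0, 2, 0)), c(0, 4, 0))
  expect_equal(neo(rep(3.7, 50)), rep(0, 50))
  expect_error(neo(c(1, 2)), "at least 3")
  # closed form for a sinusoid: psi = A^2 sin^2(omega), constant inside
  A <- 1; om <- 0.2
  s <- A * sin(om * (0:499))
  psi <- neo(s)
  expect_lt(max(abs(psi[2:499] - A^2 * sin(om)^2)), 1e-9)
})

test_that("automatic threshold is a calibrated multiple of the mean energy", {
  expect_equal(auto_threshold(rep(2.5, 10), c_mult = 1), 2.5)
  g <- auto_threshold(c(0, 0, 0), c_mult = 8)
  expect_equal(as.numeric(g), 0)
  expect_true(isTRUE(attr(g, "degenerate")))
  # law of large numbers: uniform(0,1) values, c_mult = 2 -> gamma ~ 1
  set.seed(1)
  expect_lt(abs(auto_threshold(runif(1e6), c_mult = 2) - 1), 0.02)
})

test_that("single-channel detection recovers inserted templates", {
  tp <- make_templates(1, 64, seed = 3)[[1]]
  cfg <- detector_config()
  # one spike, noiseless
  tr <- toy_trace(2000, tp$waveform, peaks = 700)
  det <- detect_channel(tr, cfg)
  expect_length(det, 1)
  expect_identical(det$peak_index, 700L)
  expect_equal(det$waveforms[1, cfg$peak_offset + 1], max(tp$waveform))
  # threshold above the global NEO maximum -> nothing
  psi <- neo(tr)
  det0 <- detect_channel(tr, detector_config(gamma = max(psi) * 1.01))
  expect_length(det0, 0)
  # two identical templates 5*m apart -> exactly the two true peaks
  tr2 <- toy_trace(3000, tp$waveform, peaks = c(1000, 1000 + 5 * 64))
  det2 <- detect_channel(tr2, cfg)
  expect_identical(det2$peak_index, c(1000L, 1320L))
})

test_that("hits overrunning the window boundary are discarded", {
  tp <- make_templates(1, 64, seed = 4)[[1]]
  # peak so close to the start that the aligned window would underrun
  tr <- toy_trace(300, tp$waveform, peaks = 40)
  det <- detect_channel(tr, detector_config(peak_offset = 48L))
  expect_length(det, 0)
})

test_that("accepted hits are spaced by at least the dead time", {
  cfg <- detector_config()
  for (s in 1:20) {
    set.seed(s)
    tr <- rnorm(3000)
    det <- detect_channel(tr, cfg)
    if (length(det) > 1) {
      expect_true(all(diff(det$peak_index) >= cfg$dead_time))
    }
  }
})

test_that("detection equals the literal per-sample oracle on random traces", {
  cfg <- detector_config(m = 32L, peak_offset = 8L, dead_time = 16L)
  tp <- make_templates(1, 32, seed = 5)[[1]]
  for (s in 1:100) {
    set.seed(s)
    n <- 1500
    tr <- rnorm(n, 0, 0.3)
    for (pk in sample(100:(n - 100), 4)) {
      idx <- (pk - tp$peak_index + 1):(pk - tp$peak_index + 32)
      tr[idx] <- tr[idx] + tp$waveform
    }
    psi <- neo(tr)
    gamma <- auto_threshold(psi, cfg$c_mult)
    det <- detect_channel(tr, cfg)
    oracle <- brute_force_detect(tr, cfg$m, cfg$peak_offset, cfg$dead_time,
                                 as.numeric(gamma))
    expect_identical(det$peak_index, as.integer(oracle))
  }
})

test_that("multi-channel detection merges in round-robin time order", {
  tp <- make_templates(1, 64, seed = 6)[[1]]
  cfg <- detector_config()
  # single channel: detect_all == detect_channel
  tr <- toy_trace(2000, tp$waveform, peaks = 800)
  one <- detect_all(matrix(tr, ncol = 1), cfg)
  expect_identical(one$peak_index, detect_channel(tr, cfg)$peak_index)
  # two channels with simultaneous events: channel 1 precedes channel 2
  both <- cbind(toy_trace(2000, tp$waveform, peaks = 900),
                toy_trace(2000, tp$waveform, peaks = 900))
  det2 <- detect_all(both, cfg)
  expect_identical(det2$channel, c(1L, 2L))
  expect_true(all(diff(det2$detect_time) > 0))
  # four channels, one event each, distinct times -> sorted by time
  peaks <- c(600, 400, 1000, 800)
  four <- sapply(peaks, function(p) toy_trace(2000, tp$waveform, peaks = p))
  det4 <- detect_all(four, cfg)
  expect_identical(det4$channel, order(peaks))
  expect_identical(sort(det4$peak_index), det4$peak_index[order(det4$peak_index)])
})

test_that("detection sensitivity holds at the study SNR levels", {
  # hit rate (true peaks recovered within +-3 samples) >= 95% at 10 dB and
  # non-increasing towards 6 dB within Monte-Carlo error, 20 trials per level
  rate <- sapply(c(10, 8, 6), function(snr) {
    hits <- sapply(1:20, function(s) {
      cfg <- gen_config(n_neurons = 2, snr_db = snr, duration_s = 4, seed = s)
      gen <- generate_recording(cfg)
      det <- detect_all(gen$recording, detector_config())
      lab <- match_spikes_to_truth(det, gen$truth, window = 3)
      n_true <- nrow(gen$truth$events)
      (n_true - attr(lab, "n_missed")) / n_true
    })
    mean(hits)
  })
  expect_gte(rate[1], 0.95)
  expect_lte(rate[2], rate[1] + 0.02)   # Monte-Carlo slack
  expect_lte(rate[3], rate[2] + 0.02)
})
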