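test_that("a lone spike on an idle server is serviced, never discarded", {
  arr <- data.frame(channel = 1L, cycle = 100)
  res <- stream_schedule(arr, M = 1, latency_P = 40, total_cycles = 1000)
  expect_identical(res$serviced, 1L)
  expect_identical(res$discarded, 0L)
  expect_identical(res$service_order, 1L)
  expect_identical(res$pending, 0L)
})

test_that("worst-case traffic at the capacity bound loses no spikes", {
  # M = Mmax for (Q, P, rc) = (16, 40, 1 MHz): the published design point
  rs <- 24000; rc <- 1e6; Q <- 16; P <- latency_cycles(64, 2, 8)
  Mmax <- max_channels(Q, P, rs, rc)
  expect_identical(Mmax, 16L)
  arr <- worst_case_hits(Mmax, Q, rs, rc, n_rounds = 50)
  res <- stream_schedule(arr, Mmax, P,
                         total_cycles = max(arr$cycle) + (Mmax + 2) * P)
  expect_identical(res$discarded, 0L)
  # one channel beyond the bound: at least one overwrite
  M2 <- Mmax + 1L
  arr2 <- worst_case_hits(M2, Q, rs, rc, n_rounds = 200)
  res2 <- stream_schedule(arr2, M2, P,
                          total_cycles = max(arr2$cycle) + (M2 + 2) * P)
  expect_gte(res2$discarded, 1L)
})

test_that("hits are conserved across serviced, discarded and pending", {
  set.seed(5)
  for (r in 1:20) {
    M <- sample(2:8, 1); P <- sample(c(16, 40, 72), 1)
    n <- 60
    arr <- data.frame(channel = sample.int(M, n, replace = TRUE),
                      cycle = sort(sample.int(2000, n)))
    res <- stream_schedule(arr, M, P, total_cycles = 2000 + 10 * P)
    expect_identical(res$hits,
                     res$serviced + res$discarded + res$pending)
    # event log timestamps non-decreasing
    expect_true(!is.unsorted(res$events$t_cycles))
  }
})

test_that("service is first-come-first-serve in arrival order", {
  # spaced arrivals, no overwrites: service order == arrival order and
  # start times follow the queueing recursion
  arr <- data.frame(channel = c(1L, 2L, 3L, 1L, 2L),
                    cycle = c(0, 5, 10, 500, 505))
  P <- 40
  res <- stream_schedule(arr, 3, P, total_cycles = 2000)
  expect_identical(res$service_order, arr$channel)
  starts <- res$events$t_cycles[res$events$kind == "gha_start"]
  expect_equal(starts, fcfs_start_times(arr$cycle, P))
})

test_that("an overwrite re-enqueues the channel at the tail", {
  # channel 1 fires twice while the server is still busy with channel 2's
  # long job; the stale spike is discarded and channel 1 re-queued
  arr <- data.frame(channel = c(2L, 1L, 1L, 3L),
                    cycle = c(0, 1, 30, 35))
  res <- stream_schedule(arr, 3, latency_P = 100, total_cycles = 1000)
  expect_identical(res$discarded_per_channel, c(1L, 0L, 0L))
  expect_identical(res$serviced, 3L)
  # channel 1 was re-enqueued at cycle 30, so it is served before channel 3
  expect_identical(res$service_order, c(2L, 1L, 3L))
  expect_identical(res$events$kind[res$events$t_cycles == 30 &
                                     res$events$kind == "overwrite"],
                   "overwrite")
})

test_that("busy fractions account for the active cycles of each component", {
  # silent recording: server fraction 0
  none <- stream_schedule(data.frame(channel = integer(0), cycle = numeric(0)),
                          M = 2, latency_P = 40, total_cycles = 1000,
                          n_samples = 24, rc = 1e6, rs = 24000)
  bf <- busy_fraction(none)
  expect_identical(unname(bf["gha_server"]), 0)
  # single spike in a long recording: exactly latency_P / total_cycles
  one <- stream_schedule(data.frame(channel = 1L, cycle = 10),
                         M = 1, latency_P = 40, total_cycles = 4000,
                         n_samples = 96, rc = 1e6, rs = 24000)
  expect_identical(unname(busy_fraction(one)["gha_server"]), 40 / 4000)
  # saturated server: fraction 1 within 1/total_cycles
  sat <- stream_schedule(data.frame(channel = rep(1:2, 50),
                                    cycle = seq(0, by = 10, length.out = 100)),
                         M = 2, latency_P = 200, total_cycles = 1000)
  expect_gte(busy_fraction(sat)["gha_server"], 1 - 1 / 1000)
})

test_that("run_stream enforces the round-robin sampling feasibility bound", {
  rec <- matrix(rnorm(200 * 50), 200, 50)
  expect_error(run_stream(rec, detector_config(m = 16L, peak_offset = 4L,
                                               dead_time = 8L),
                          rc = 1e6, latency_P = 40),
               "rc >= M\\*rs")
})

test_that("run_stream services detected spikes end to end", {
  tp <- make_templates(1, 64, seed = 6)[[1]]
  tr <- toy_trace(24000, tp$waveform, peaks = c(5000, 12000, 20000))
  rec <- structure(list(traces = matrix(tr, ncol = 1), rs = 24000, m = 64L,
                        seed = 1L), class = "spike_recording")
  res <- run_stream(rec, detector_config(), rc = 1e6, latency_P = 40)
  expect_identical(res$hits, 3L)
  expect_identical(res$serviced, 3L)
  expect_identical(res$discarded, 0L)
})
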