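test_that("fuzzy c-means satisfies its closed-form and separation contracts", {
  set.seed(1)
  x <- matrix(rnorm(60 * 2), 60)
  # k = 1: center is the mean, all memberships 1
  one <- fcm(x, 1, seed = 1)
  expect_equal(as.numeric(one$centers), colMeans(x), tolerance = 1e-6)
  expect_true(all(abs(one$memberships - 1) < 1e-12))
  # two well-separated clouds: hard labels equal nearest-center assignment
  # and split the clouds exactly
  a <- matrix(rnorm(80, 0, 0.1), 40) ; b <- matrix(rnorm(80, 5, 0.1), 40)
  xy <- rbind(a, b)
  two <- fcm(xy, 2, seed = 2)
  truth <- rep(1:2, each = 40)
  expect_identical(csr(two$hard_labels, truth)$csr_percent, 100)
  d2 <- cbind(rowSums(sweep(xy, 2, two$centers[1, ])^2),
              rowSums(sweep(xy, 2, two$centers[2, ])^2))
  expect_identical(two$hard_labels, max.col(-d2, ties.method = "first"))
  # membership rows sum to one
  expect_true(all(abs(rowSums(two$memberships) - 1) < 1e-9))
  # objective trace non-increasing
  expect_true(all(diff(two$objective_trace) <= 1e-9))
  # deterministic given seed
  expect_identical(fcm(xy, 2, seed = 7)$centers, fcm(xy, 2, seed = 7)$centers)
})

test_that("fcm agrees with an independent implementation on easy data", {
  skip_if_not_installed("e1071")
  set.seed(3)
  xy <- rbind(matrix(rnorm(100, 0, 0.3), 50), matrix(rnorm(100, 4, 0.3), 50))
  ours <- fcm(xy, 2, seed = 3)
  ref <- e1071::cmeans(xy, 2, m = 2, iter.max = 300)
  # same partition up to label permutation
  expect_identical(csr(ours$hard_labels, as.integer(ref$cluster))$csr_percent,
                   100)
  # same centers up to row permutation
  perm <- if (sum((ours$centers[1, ] - ref$centers[1, ])^2) <
              sum((ours$centers[1, ] - ref$centers[2, ])^2)) 1:2 else 2:1
  expect_equal(unname(ours$centers), unname(ref$centers[perm, ]),
               tolerance = 1e-3)
})

test_that("classification success rate maximizes over label matchings", {
  expect_identical(csr(c(1, 1, 2, 2), c(1, 1, 2, 2))$csr_percent, 100)
  expect_identical(csr(c(2, 2, 1, 1), c(1, 1, 2, 2))$csr_percent, 100)
  # confusion [[40,10],[10,40]] -> 80%
  hard <- rep(c(1, 2, 1, 2), c(40, 10, 10, 40))
  true <- rep(c(1, 1, 2, 2), c(40, 10, 10, 40))
  rep80 <- csr(hard, true)
  expect_identical(rep80$csr_percent, 80)
  expect_identical(sum(rep80$confusion), 100L)
  # permutation invariance and chance floor
  set.seed(4)
  lab <- sample(1:3, 300, replace = TRUE)
  prd <- sample(1:3, 300, replace = TRUE)
  expect_identical(csr(prd, lab)$csr_percent,
                   csr(c(3, 1, 2)[prd], lab)$csr_percent)
  expect_gte(csr(prd, lab)$csr_percent, 100 / 3 - 10)
  expect_error(csr(1:9, rep(1:9, 1)), "at most 8")
})

test_that("detections are matched to ground truth within the window", {
  tp <- make_templates(1, 64, seed = 8)[[1]]
  truth <- structure(list(events = data.frame(channel = c(1L, 1L, 2L),
                                              neuron_id = c(1L, 2L, 1L),
                                              peak_sample = c(100L, 300L, 100L)),
                          templates = list(tp)), class = "ground_truth")
  sp <- spikegha:::new_spike_set(channel = c(1L, 1L, 2L),
                                 peak_index = c(102L, 290L, 100L),
                                 detect_time = c(102, 290, 100),
                                 waveforms = matrix(0, 3, 64), m = 64L,
                                 peak_offset = 16L, gamma = 1)
  lab <- match_spikes_to_truth(sp, truth, window = 3)
  expect_identical(as.integer(lab), c(1L, NA_integer_, 1L))
  expect_identical(attr(lab, "n_missed"), 1L)
})

test_that("the noiseless pipeline classifies perfectly", {
  for (s in 1:3) {
    cfg <- gen_config(n_neurons = 2, snr_db = 60, duration_s = 4, seed = s)
    res <- run_pipeline_once(cfg, backend = "float")
    expect_identical(res$csr$csr_percent, 100)
  }
})

test_that("float features are no worse than fixed-point on a matched run", {
  cfg <- gen_config(n_neurons = 3, snr_db = 6, duration_s = 5, seed = 2)
  fl <- run_pipeline_once(cfg, k = 3, backend = "float")
  fx <- run_pipeline_once(cfg, k = 3, backend = "fixed17")
  expect_gte(fl$csr$csr_percent, fx$csr$csr_percent - 1)
})

test_that("the evaluation table reports per-SNR means over seeds", {
  tab <- evaluate_pipeline(gen_config(duration_s = 4), snr_levels = c(10, 60),
                           seeds = 1:2, backend = "float")
  expect_s3_class(tab, "csr_table")
  expect_identical(nrow(tab), 2L)
  expect_true(all(tab$mean_csr >= 0 & tab$mean_csr <= 100))
  expect_identical(tab$n_runs, c(2L, 2L))
  per_run <- attr(tab, "per_run")
  expect_identical(nrow(per_run), 4L)
})
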