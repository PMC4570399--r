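#' Fuzzy c-means clustering
#'
#' Standard alternating-optimization FCM: soft memberships
#' `u_ic = 1 / sum_l (d_ic/d_il)^(2/(fuzzifier-1))` given centers, then
#' fuzzified centroid updates given memberships, iterated until the largest
#' center shift falls below `tol`. Several seeded restarts are run and the
#' solution with the lowest objective `J = sum u^fuzzifier * d^2` is kept.
#' The per-iteration objective trace is returned; alternating minimization
#' makes it non-increasing.
#'
#' @param x n-by-p feature matrix (rows are observations).
#' @param k number of clusters (`1 <= k <= n`).
#' @param fuzzifier fuzziness exponent, > 1 (default 2).
#' @param tol convergence tolerance on the center shift (default 1e-6).
#' @param max_iter iteration cap per restart (default 300).
#' @param nstart number of random restarts (default 5).
#' @param seed integer seed for the restarts (default 1).
#' @return an object of class `fcm`: `memberships` (n-by-k, rows sum to 1),
#'   `centers` (k-by-p), `hard_labels`, `objective`, `objective_trace`,
#'   `iterations`.
#' @export
fcm <- function(x, k, fuzzifier = 2, tol = 1e-6, max_iter = 300L,
                nstart = 5L, seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(n >= k, k >= 1, fuzzifier > 1, max_iter >= 1, nstart >= 1)
  local_seed(seed)
  best <- NULL
  for (r in seq_len(nstart)) {
    centers <- draw_initial_centers(x, k)
    res <- fcm_once(x, centers, fuzzifier, tol, max_iter)
    if (is.null(best) || res$objective < best$objective) best <- res
  }
  best
}

draw_initial_centers <- function(x, k, max_tries = 100L) {
  for (tr in seq_len(max_tries)) {
    centers <- x[sample.int(nrow(x), k), , drop = FALSE]
    if (k == 1 || !anyDuplicated(centers)) return(centers)
  }
  stop("could not draw ", k, " distinct initial centers; ",
       "too few distinct observations")
}

fcm_once <- function(x, centers, fuzzifier, tol, max_iter) {
  k <- nrow(centers)
  e <- 1 / (fuzzifier - 1)
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    d2 <- squared_distances(x, centers)
    u <- memberships_from_d2(d2, e)
    uf <- u^fuzzifier
    denom <- colSums(uf)
    new_centers <- (t(uf) %*% x) / denom
    trace <- c(trace, sum(uf * d2))
    shift <- max(abs(new_centers - centers))
    centers <- new_centers
    if (shift < tol) break
  }
  d2 <- squared_distances(x, centers)
  u <- memberships_from_d2(d2, e)
  structure(list(memberships = u, centers = centers,
                 hard_labels = max.col(u, ties.method = "first"),
                 objective = sum(u^fuzzifier * d2),
                 objective_trace = trace, iterations = it),
            class = "fcm")
}

squared_distances <- function(x, centers) {
  n <- nrow(x); k <- nrow(centers)
  d2 <- matrix(0, n, k)
  for (c in seq_len(k)) {
    d2[, c] <- rowSums(sweep(x, 2, centers[c, ])^2)
  }
  d2
}

memberships_from_d2 <- function(d2, e) {
  n <- nrow(d2); k <- ncol(d2)
  u <- matrix(0, n, k)
  zero <- d2 <= .Machine$double.xmin
  has_zero <- rowSums(zero) > 0
  w <- (1 / pmax(d2, .Machine$double.xmin))^e
  u <- w / rowSums(w)
  if (any(has_zero)) {
    u[has_zero, ] <- zero[has_zero, , drop = FALSE] /
      rowSums(zero[has_zero, , drop = FALSE])
  }
  u
}

#' @export
print.fcm <- function(x, ...) {
  cat(sprintf("Fuzzy c-means: %d clusters, %d observations, objective %.6g (%d iterations)\n",
              ncol(x$memberships), nrow(x$memberships), x$objective,
              x$iterations))
  invisible(x)
}

#' Classification success rate
#'
#' Fraction of spikes whose cluster label matches their true unit, maximized
#' over all injective assignments of cluster ids to unit ids (exhaustive
#' search; intended for k <= 8). Invariant under permutation of either
#' labelling.
#'
#' @param hard_labels integer cluster labels.
#' @param true_labels integer ground-truth unit labels, same length.
#' @return an object of class `csr_report`: `csr_percent` in `[0, 100]`,
#'   `confusion` (true-by-predicted counts) and `matching` (named vector:
#'   predicted cluster -> true unit).
#' @export
csr <- function(hard_labels, true_labels) {
  stopifnot(length(hard_labels) == length(true_labels),
            length(hard_labels) >= 1)
  tl <- factor(true_labels); pl <- factor(hard_labels)
  if (nlevels(tl) > 8 || nlevels(pl) > 8) {
    stop("exhaustive label matching supports at most 8 clusters")
  }
  conf <- table(true = tl, predicted = pl)
  kt <- nrow(conf); kp <- ncol(conf)
  best <- -1L; best_assign <- NULL
  # assign each predicted cluster an exclusive true unit (or none when kp>kt)
  perms <- permutations(max(kt, kp))
  for (r in seq_len(nrow(perms))) {
    assign <- perms[r, seq_len(kp)]        # predicted c -> true assign[c]
    s <- 0L
    for (c in seq_len(kp)) {
      if (assign[c] <= kt) s <- s + conf[assign[c], c]
    }
    if (s > best) { best <- s; best_assign <- assign }
  }
  matching <- stats::setNames(levels(tl)[pmin(best_assign, kt)], levels(pl))
  matching[best_assign > kt] <- NA
  structure(list(csr_percent = 100 * best / length(true_labels),
                 confusion = conf, matching = matching,
                 n = length(true_labels)),
            class = "csr_report")
}

permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 0L
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    for (r in seq_len(nrow(sub))) {
      row <- row + 1L
      out[row, ] <- c(i, rest[sub[r, ]])
    }
  }
  out
}

#' @export
print.csr_report <- function(x, ...) {
  cat(sprintf("Classification success rate: %.2f%% of %d spikes\n",
              x$csr_percent, x$n))
  print(x$confusion)
  invisible(x)
}

#' Match detected spikes to ground-truth events
#'
#' Pairs each detection with the nearest unmatched true peak on the same
#' channel within `window` samples. Detections with no match are false
#' alarms; matched detections inherit the true unit id.
#'
#' @param spikes a `spike_set`.
#' @param truth a `ground_truth` (see [generate_recording()]).
#' @param window matching half-width in samples (default 3).
#' @return integer vector, one entry per detection: the matched `neuron_id`
#'   or `NA` for false alarms. Attribute `n_missed` counts true events with
#'   no matched detection.
#' @export
match_spikes_to_truth <- function(spikes, truth, window = 3L) {
  ev <- truth$events
  out <- rep(NA_integer_, length(spikes$peak_index))
  used <- logical(nrow(ev))
  for (i in seq_along(spikes$peak_index)) {
    on_ch <- which(ev$channel == spikes$channel[i] & !used)
    if (!length(on_ch)) next
    d <- abs(ev$peak_sample[on_ch] - spikes$peak_index[i])
    j <- which.min(d)
    if (d[j] <= window) {
      out[i] <- ev$neuron_id[on_ch[j]]
      used[on_ch[j]] <- TRUE
    }
  }
  attr(out, "n_missed") <- sum(!used)
  out
}

#' Run the full sorting pipeline once and score it
#'
#' generate -> detect -> train GHA -> extract features -> FCM -> CSR.
#' Detections are matched to ground truth within `match_window` samples;
#' unmatched detections are excluded from the CSR and reported as false
#' alarms.
#'
#' @param cfg a [gen_config()].
#' @param detector_cfg a [detector_config()].
#' @param p number of principal components (default 2).
#' @param k number of clusters (defaults to `cfg$n_neurons`).
#' @param backend `"float"` or `"fixed17"`.
#' @param match_window ground-truth matching half-width in samples.
#' @param ... further arguments to [gha()] (eta, epochs, ...).
#' @return list with `csr` (a `csr_report`), `n_matched`, `n_false_alarms`,
#'   `n_missed`, `fit` (the `gha` model), `clusters` (the `fcm` object) and
#'   `features` for the matched spikes.
#' @export
run_pipeline_once <- function(cfg, detector_cfg = detector_config(),
                              p = 2L, k = cfg$n_neurons,
                              backend = c("float", "fixed17"),
                              match_window = 3L, ...) {
  backend <- match.arg(backend)
  gen <- generate_recording(cfg)
  det <- detect_all(gen$recording, detector_cfg)
  if (length(det) < max(k, 2L)) {
    stop("too few detected spikes (", length(det), ") to cluster")
  }
  fit <- gha(det, p = p, backend = backend, seed = cfg$seed, ...)
  feats <- predict(fit)
  labels <- match_spikes_to_truth(det, gen$truth, window = match_window)
  matched <- !is.na(labels)
  cl <- fcm(feats[matched, , drop = FALSE], k = k, seed = cfg$seed)
  report <- csr(cl$hard_labels, labels[matched])
  list(csr = report, n_matched = sum(matched),
       n_false_alarms = sum(!matched),
       n_missed = attr(labels, "n_missed"),
       fit = fit, clusters = cl, features = feats[matched, , drop = FALSE])
}

#' Classification success rate across SNR levels
#'
#' Repeats [run_pipeline_once()] over seeds for each SNR level and tabulates
#' the mean and standard deviation of the CSR, plus detection accounting.
#'
#' @param cfg base [gen_config()]; its `snr_db` and `seed` are overridden.
#' @param snr_levels SNR levels in dB (default `c(6, 8, 10)`).
#' @param seeds integer vector of generator seeds (one run per seed).
#' @param backend `"float"` or `"fixed17"`.
#' @param detector_cfg,p,k,... passed to [run_pipeline_once()].
#' @return a data.frame of class `csr_table` with one row per SNR level:
#'   `snr_db`, `mean_csr`, `sd_csr`, `min_csr`, `mean_matched`,
#'   `mean_false_alarms`, `n_runs`, plus a `per_run` attribute with the
#'   individual CSR values.
#' @export
evaluate_pipeline <- function(cfg = gen_config(), snr_levels = c(6, 8, 10),
                              seeds = 1:5, backend = c("float", "fixed17"),
                              detector_cfg = detector_config(), p = 2L,
                              k = cfg$n_neurons, ...) {
  backend <- match.arg(backend)
  per_run <- expand.grid(seed = seeds, snr_db = snr_levels,
                         KEEP.OUT.ATTRS = FALSE)
  per_run$csr <- NA_real_
  per_run$matched <- NA_integer_
  per_run$false_alarms <- NA_integer_
  for (i in seq_len(nrow(per_run))) {
    cfg_i <- cfg
    cfg_i$snr_db <- per_run$snr_db[i]
    cfg_i$seed <- as.integer(per_run$seed[i])
    res <- run_pipeline_once(cfg_i, detector_cfg, p = p, k = k,
                             backend = backend, ...)
    per_run$csr[i] <- res$csr$csr_percent
    per_run$matched[i] <- res$n_matched
    per_run$false_alarms[i] <- res$n_false_alarms
  }
  tab <- do.call(rbind, lapply(split(per_run, per_run$snr_db), function(d) {
    data.frame(snr_db = d$snr_db[1], mean_csr = mean(d$csr),
               sd_csr = stats::sd(d$csr), min_csr = min(d$csr),
               mean_matched = mean(d$matched),
               mean_false_alarms = mean(d$false_alarms),
               n_runs = nrow(d))
  }))
  tab <- tab[order(tab$snr_db), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "per_run") <- per_run
  attr(tab, "backend") <- backend
  class(tab) <- c("csr_table", "data.frame")
  tab
}

#' @export
print.csr_table <- function(x, ...) {
  cat(sprintf("Classification success rates (%s backend, %d runs per SNR)\n",
              attr(x, "backend"), x$n_runs[1]))
  df <- as.data.frame(x)
  df$mean_csr <- sprintf("%.2f%%", df$mean_csr)
  df$sd_csr <- sprintf("%.2f", df$sd_csr)
  df$min_csr <- sprintf("%.2f%%", df$min_csr)
  print(df, row.names = FALSE)
  invisible(x)
}
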