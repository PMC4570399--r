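#' Nonlinear energy operator
#'
#' Computes `psi[k] = s[k]^2 - s[k-1]*s[k+1]` for interior samples of a
#' voltage trace; the two endpoints are defined as 0. The operator responds to
#' simultaneous amplitude and frequency content, which makes brief, sharp
#' action potentials stand out against slower background fluctuations.
#'
#' @param trace numeric vector of at least 3 samples.
#' @return numeric vector of NEO values, same length as `trace`.
#' @export
neo <- function(trace) {
  n <- length(trace)
  if (n < 3) stop("trace must contain at least 3 samples")
  psi <- numeric(n)
  k <- 2:(n - 1)
  psi[k] <- trace[k]^2 - trace[k - 1] * trace[k + 1]
  psi
}

#' Automatic NEO detection threshold
#'
#' The detection threshold is a multiple of the mean NEO energy of the trace:
#' `gamma = c_mult * mean(neo_values)`. If the trace is identically zero the
#' returned threshold is 0 and carries a `degenerate` attribute (nothing can
#' exceed it).
#'
#' @param neo_values output of [neo()].
#' @param c_mult positive multiplier; default 8 (see the methods vignette
#'   for the calibration rationale).
#' @return the threshold `gamma`, with attribute `degenerate` set to `TRUE`
#'   when all NEO values are zero.
#' @export
auto_threshold <- function(neo_values, c_mult = 8) {
  stopifnot(c_mult > 0, length(neo_values) >= 1)
  gamma <- c_mult * mean(neo_values)
  if (all(neo_values == 0)) {
    attr(gamma, "degenerate") <- TRUE
  }
  gamma
}

#' Spike detector configuration
#'
#' @param m spike window length in samples (default 64).
#' @param peak_offset number of samples preceding the peak inside the window
#'   (default 16), so the peak sits at window position `peak_offset + 1`.
#' @param gamma absolute NEO threshold; when `NULL` (default) it is computed
#'   per channel by [auto_threshold()] with `c_mult`.
#' @param c_mult multiplier for the automatic threshold.
#' @param dead_time minimum spacing in samples between accepted hits on one
#'   channel (default `m/2`), suppressing multiple detections of one spike.
#' @return a validated list of class `detector_config`.
#' @export
detector_config <- function(m = 64L, peak_offset = 16L, gamma = NULL,
                            c_mult = 8, dead_time = m %/% 2L) {
  stopifnot(m >= 8, peak_offset >= 0, peak_offset < m, dead_time >= 1,
            is.null(gamma) || gamma > 0, c_mult > 0)
  structure(list(m = as.integer(m), peak_offset = as.integer(peak_offset),
                 gamma = gamma, c_mult = c_mult,
                 dead_time = as.integer(dead_time)),
            class = "detector_config")
}

#' Detect and align spikes on a single channel
#'
#' A hit is accepted at sample `k` when the NEO value exceeds the threshold,
#' `trace[k]` is the maximum of the raw trace over the window
#' `[k - dead_time, k + dead_time]` (clipped to the trace bounds; this peak
#' refinement anchors alignment at the spike peak), the aligned m-sample
#' window fits inside the trace, and the hit is at least `dead_time` samples
#' after the previously accepted hit (earliest wins). The emitted waveform is
#' `trace[(k - peak_offset):(k - peak_offset + m - 1)]`, so the peak sits at
#' window position `peak_offset + 1`.
#'
#' @param trace numeric vector, length >= `cfg$m`.
#' @param cfg a [detector_config()].
#' @param channel channel id stored with the detections.
#' @return an object of class `spike_set` with fields `channel`, `peak_index`,
#'   `detect_time` (global multiplexed sample counter), `waveforms`
#'   (one row per spike), `m`, `peak_offset` and the `gamma` used.
#' @export
detect_channel <- function(trace, cfg = detector_config(), channel = 1L) {
  stopifnot(inherits(cfg, "detector_config"), length(trace) >= cfg$m)
  psi <- neo(trace)
  gamma <- cfg$gamma
  if (is.null(gamma)) gamma <- auto_threshold(psi, cfg$c_mult)
  n <- length(trace)
  cand <- which(psi > as.numeric(gamma))
  keep <- logical(length(cand))
  dt <- cfg$dead_time
  for (i in seq_along(cand)) {
    k <- cand[i]
    lo <- max(1L, k - dt); hi <- min(n, k + dt)
    keep[i] <- trace[k] == max(trace[lo:hi])
  }
  cand <- cand[keep]
  # discard hits whose aligned window overruns the trace
  start <- cand - cfg$peak_offset
  inside <- start >= 1L & start + cfg$m - 1L <= n
  cand <- cand[inside]
  # suppress hits closer than dead_time to the previous accepted hit
  accepted <- integer(0)
  last <- -Inf
  for (k in cand) {
    if (k - last >= dt) { accepted <- c(accepted, k); last <- k }
  }
  wf <- matrix(0, nrow = length(accepted), ncol = cfg$m)
  for (i in seq_along(accepted)) {
    s <- accepted[i] - cfg$peak_offset
    wf[i, ] <- trace[s:(s + cfg$m - 1L)]
  }
  new_spike_set(channel = rep(as.integer(channel), length(accepted)),
                peak_index = accepted,
                detect_time = accepted,   # single channel: time == sample
                waveforms = wf, m = cfg$m, peak_offset = cfg$peak_offset,
                gamma = as.numeric(gamma))
}

#' Detect spikes on every channel of a recording
#'
#' Applies [detect_channel()] to each channel (with a per-channel automatic
#' threshold unless an absolute `gamma` is given) and merges the results in
#' global round-robin sample order: detections are ordered by peak sample
#' time, ties broken by channel index ascending.
#'
#' @param recording a `spike_recording` (see [generate_recording()]) or an
#'   n-by-M numeric matrix.
#' @param cfg a [detector_config()].
#' @return a `spike_set` covering all channels, ordered by `detect_time`.
#' @export
detect_all <- function(recording, cfg = detector_config()) {
  traces <- if (inherits(recording, "spike_recording")) recording$traces
            else as.matrix(recording)
  M <- ncol(traces)
  parts <- lapply(seq_len(M), function(ch) {
    detect_channel(traces[, ch], cfg, channel = ch)
  })
  channel <- unlist(lapply(parts, `[[`, "channel"))
  peak_index <- unlist(lapply(parts, `[[`, "peak_index"))
  waveforms <- do.call(rbind, lapply(parts, `[[`, "waveforms"))
  detect_time <- (peak_index - 1L) * M + channel
  ord <- order(detect_time)
  new_spike_set(channel = channel[ord], peak_index = peak_index[ord],
                detect_time = detect_time[ord],
                waveforms = waveforms[ord, , drop = FALSE],
                m = cfg$m, peak_offset = cfg$peak_offset,
                gamma = vapply(parts, `[[`, numeric(1), "gamma"))
}

new_spike_set <- function(channel, peak_index, detect_time, waveforms, m,
                          peak_offset, gamma) {
  structure(list(channel = as.integer(channel),
                 peak_index = as.integer(peak_index),
                 detect_time = as.numeric(detect_time),
                 waveforms = waveforms, m = as.integer(m),
                 peak_offset = as.integer(peak_offset), gamma = gamma),
            class = "spike_set")
}

#' @export
print.spike_set <- function(x, ...) {
  cat(sprintf("Detected spikes: %d event(s) on %d channel(s), window m = %d (peak offset %d)\n",
              length(x$peak_index), length(unique(x$channel)), x$m,
              x$peak_offset))
  invisible(x)
}

#' @export
length.spike_set <- function(x) length(x$peak_index)

#' @export
as.data.frame.spike_set <- function(x, ...) {
  data.frame(channel = x$channel, peak_index = x$peak_index,
             detect_time = x$detect_time)
}
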