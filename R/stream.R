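#' Cycle-level simulation of the shared spike-sorting datapath
#'
#' Behavioural model of the streaming architecture: channels are sampled
#' round-robin (channel h's sample of period s is fetched at clock cycle
#' `floor(s * rc/rs) + h - 1`), each channel owns a one-spike memory unit, a
#' FIFO records the channels awaiting service, and a single feature-extraction
#' server removes FIFO heads first-come-first-serve, occupying `latency_P`
#' cycles per spike. A hit on a channel whose memory still holds an unserviced
#' spike overwrites it: the stale spike is discarded, its FIFO entry removed,
#' and the channel re-enqueued at the tail. When a service start and a hit
#' fall on the same cycle the service starts first.
#'
#' @param arrivals data.frame with columns `channel` (1-based) and `cycle`
#'   (non-decreasing integer clock cycle of each hit).
#' @param M number of channels.
#' @param latency_P per-spike service latency in cycles.
#' @param total_cycles length of the simulation; services starting at or after
#'   this cycle do not happen (their spikes stay pending).
#' @param n_samples number of sampling periods represented (used only for the
#'   detection-buffer activity accounting); `NULL` to omit.
#' @param rc,rs clock and sampling rate, used with `n_samples` for activity
#'   accounting.
#' @return a list of class `stream_result`: `events` (data.frame
#'   `t_cycles`, `kind`, `channel` with kinds hit/overwrite/gha_start/
#'   gha_done), `hits`, `serviced`, `discarded_per_channel`, `pending`,
#'   `service_order` (channels in order served), `gha_busy_cycles`,
#'   `total_cycles`, `M`, `latency_P`, and sampling metadata.
#' @export
stream_schedule <- function(arrivals, M, latency_P, total_cycles,
                            n_samples = NULL, rc = NULL, rs = NULL) {
  stopifnot(latency_P >= 1, M >= 1)
  nh <- nrow(arrivals)
  ch <- as.integer(arrivals$channel)
  tt <- as.numeric(arrivals$cycle)
  if (is.unsorted(tt)) stop("arrivals must be ordered by cycle")
  # FIFO with tombstones; per-channel position for O(1) stale removal
  cap <- 2L * nh + 4L
  f_ch <- integer(cap); f_enq <- numeric(cap); f_alive <- logical(cap)
  head <- 1L; tail <- 0L
  pos <- integer(M)                  # fifo slot of each pending channel, 0 = none
  occupied <- logical(M)
  overwritten <- integer(M)
  serviced <- 0L
  service_order <- integer(nh)
  server_free <- 0
  gha_busy <- 0
  # event log (preallocated)
  ev_cap <- 4L * nh + 8L
  ev_t <- numeric(ev_cap); ev_k <- character(ev_cap); ev_c <- integer(ev_cap)
  ne <- 0L
  log_ev <- function(t, k, c) {
    ne <<- ne + 1L
    ev_t[ne] <<- t; ev_k[ne] <<- k; ev_c[ne] <<- c
  }
  run_services <- function(until) {
    # start any service that can begin at a cycle <= until (< total_cycles)
    while (head <= tail) {
      if (!f_alive[head]) { head <<- head + 1L; next }
      start <- max(server_free, f_enq[head])
      if (start > until || start >= total_cycles) break
      q <- f_ch[head]
      f_alive[head] <<- FALSE; head <<- head + 1L
      pos[q] <<- 0L
      occupied[q] <<- FALSE
      serviced <<- serviced + 1L
      service_order[serviced] <<- q
      log_ev(start, "gha_start", q)
      done <- start + latency_P
      log_ev(done, "gha_done", q)
      gha_busy <<- gha_busy + (min(done, total_cycles) - start)
      server_free <<- done
    }
  }
  for (i in seq_len(nh)) {
    t <- tt[i]; h <- ch[i]
    run_services(t)
    if (occupied[h]) {
      overwritten[h] <- overwritten[h] + 1L
      if (pos[h] > 0L) f_alive[pos[h]] <- FALSE
      log_ev(t, "overwrite", h)
    }
    occupied[h] <- TRUE
    tail <- tail + 1L
    f_ch[tail] <- h; f_enq[tail] <- t; f_alive[tail] <- TRUE
    pos[h] <- tail
    log_ev(t, "hit", h)
  }
  run_services(total_cycles)
  events <- data.frame(t_cycles = ev_t[seq_len(ne)],
                       kind = ev_k[seq_len(ne)],
                       channel = ev_c[seq_len(ne)])
  events <- events[order(events$t_cycles,
                         match(events$kind,
                               c("gha_start", "gha_done", "overwrite",
                                 "hit"))), , drop = FALSE]
  rownames(events) <- NULL
  structure(list(events = events, hits = nh, serviced = serviced,
                 discarded_per_channel = overwritten,
                 discarded = sum(overwritten),
                 pending = sum(occupied),
                 service_order = service_order[seq_len(serviced)],
                 gha_busy_cycles = gha_busy,
                 total_cycles = total_cycles, M = M, latency_P = latency_P,
                 n_samples = n_samples, rc = rc, rs = rs),
            class = "stream_result")
}

#' Run the streaming datapath on a recording
#'
#' Detects spikes on every channel ([detect_all()]), converts peak times to
#' clock cycles of the round-robin multiplexed datapath, and feeds them to
#' [stream_schedule()]. Requires the sampling feasibility condition
#' `rc >= M * rs` (one sample per channel per sampling period).
#'
#' @param recording a `spike_recording` or n-by-M matrix.
#' @param detector_cfg a [detector_config()].
#' @param rc clock rate (cycles/s).
#' @param latency_P per-spike service latency in cycles (see
#'   [latency_cycles()]).
#' @return a `stream_result`, see [stream_schedule()].
#' @export
run_stream <- function(recording, detector_cfg = detector_config(), rc,
                       latency_P) {
  traces <- if (inherits(recording, "spike_recording")) recording$traces
            else as.matrix(recording)
  rs <- if (inherits(recording, "spike_recording")) recording$rs else 24000
  M <- ncol(traces)
  if (rc < M * rs) {
    stop("clock rate too low for round-robin sampling: need rc >= M*rs ",
         "(M*Tc <= Ts), got rc = ", rc, ", M*rs = ", M * rs)
  }
  det <- detect_all(traces, detector_cfg)
  cyc <- floor((det$peak_index - 1) * rc / rs) + det$channel - 1
  ord <- order(cyc)
  arrivals <- data.frame(channel = det$channel[ord], cycle = cyc[ord])
  n_samples <- nrow(traces)
  stream_schedule(arrivals, M = M, latency_P = latency_P,
                  total_cycles = ceiling(n_samples * rc / rs),
                  n_samples = n_samples, rc = rc, rs = rs)
}

#' Worst-case hit schedule at the minimum inter-peak gap
#'
#' Adversarial traffic for the capacity analysis: every one of the M channels
#' fires a detected spike every Q samples, phase-aligned, so the round-robin
#' hit cycles of round j are `floor(j*Q*rc/rs) + h - 1` for channel h.
#'
#' @param M channels.
#' @param Q inter-peak gap in samples.
#' @param rs,rc sampling and clock rate.
#' @param n_rounds number of firing rounds.
#' @return data.frame of arrivals (`channel`, `cycle`) ordered by cycle.
#' @export
worst_case_hits <- function(M, Q, rs, rc, n_rounds) {
  rounds <- rep(seq_len(n_rounds) - 1L, each = M)
  channel <- rep(seq_len(M), times = n_rounds)
  cycle <- floor(rounds * Q * rc / rs) + channel - 1
  data.frame(channel = channel, cycle = cycle)
}

#' Active-cycle fractions of the datapath components
#'
#' Software analogue of the clock-gating accounting: the fraction of clock
#' cycles each component is active. The detection buffer is active for M
#' fetch cycles per sampling period; the spike buffer for one write cycle per
#' hit and one read cycle per service; the feature-extraction server for
#' `latency_P` cycles per serviced spike.
#'
#' @param result a `stream_result`.
#' @return named numeric vector with entries `neo_buffer`, `spike_buffer`,
#'   `gha_server`, each in `[0, 1]` (`neo_buffer` is `NA` when the result has
#'   no sampling metadata).
#' @export
busy_fraction <- function(result) {
  stopifnot(inherits(result, "stream_result"))
  tc <- result$total_cycles
  neo_frac <- if (!is.null(result$n_samples)) {
    min(1, result$M * result$n_samples / tc)
  } else NA_real_
  c(neo_buffer = neo_frac,
    spike_buffer = min(1, (result$hits + result$serviced) / tc),
    gha_server = result$gha_busy_cycles / tc)
}

#' @export
print.stream_result <- function(x, ...) {
  cat(sprintf("Stream simulation: M = %d channels, P = %d cycles, %g cycles simulated\n",
              x$M, x$latency_P, x$total_cycles))
  cat(sprintf("  hits %d | serviced %d | discarded %d | pending %d\n",
              x$hits, x$serviced, x$discarded, x$pending))
  invisible(x)
}
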