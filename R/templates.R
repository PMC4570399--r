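#' Generate distinguishable spike waveform templates
#'
#' Draws `n_neurons` smooth biphasic/triphasic action-potential templates of
#' length `m` samples. Each template has a sharp positive depolarization lobe,
#' a slower negative repolarization lobe and a small after-wave, is tapered to
#' zero at both ends and normalized to unit peak amplitude. Templates are
#' redrawn until every pair has absolute zero-lag normalized cross-correlation
#' below 0.95, so that the shapes are distinguishable by their principal
#' components.
#'
#' @param n_neurons number of templates (>= 1).
#' @param m template length in samples (>= 8). At 24 kHz the default window of
#'   64 samples spans about 2.7 ms.
#' @param seed integer seed; templates are deterministic given the seed.
#' @param max_tries bound on redraws before a degenerate configuration error.
#' @return an object of class `spike_templates`: a list of templates, each a
#'   list with `template_id`, `waveform` (length `m`, peak amplitude 1) and
#'   `peak_index` (1-based index of the maximum absolute amplitude).
#' @export
make_templates <- function(n_neurons, m, seed = 1L, max_tries = 200L) {
  stopifnot(n_neurons >= 1, m >= 8)
  local_seed(seed)
  templates <- vector("list", n_neurons)
  n_done <- 0L
  tries <- 0L
  while (n_done < n_neurons) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop("could not draw ", n_neurons, " mutually distinguishable templates ",
           "(pairwise |correlation| < 0.95) in ", max_tries,
           " tries; degenerate configuration")
    }
    w <- random_template_shape(m)
    # the sorter aligns windows at the raw-trace maximum, so the global
    # extremum must be the positive lobe, with margin over the trough
    ok <- max(w) >= 0.999 && -min(w) < 0.95 * max(w)
    if (ok && n_done > 0L) {
      for (j in seq_len(n_done)) {
        rho <- zero_lag_correlation(w, templates[[j]]$waveform)
        rho_a <- aligned_correlation(w, templates[[j]]$waveform)
        # distinguishability is needed in the peak-aligned geometry the
        # feature extractor sees, not just at the native window offsets
        if (abs(rho) >= 0.95 || abs(rho_a) >= 0.80) { ok <- FALSE; break }
      }
    }
    if (ok) {
      n_done <- n_done + 1L
      templates[[n_done]] <- list(template_id = n_done, waveform = w,
                                  peak_index = which.max(abs(w)))
    }
  }
  structure(templates, class = "spike_templates", m = m, seed = seed)
}

# One random triphasic shape: sharp Gaussian depolarization lobe, wider
# negative repolarization, small slow positive after-wave; cosine-tapered ends.
random_template_shape <- function(m) {
  i <- seq_len(m) - 1
  c1 <- stats::runif(1, 0.25 * m, 0.42 * m)
  w1 <- stats::runif(1, 1.1, 2.0)       # sharp sodium peak (~50-80 us SD)
  gap <- stats::runif(1, 3, 9)
  w2 <- stats::runif(1, 3.5, 8)
  a2 <- stats::runif(1, 0.35, 0.7)
  c3 <- c1 + gap + stats::runif(1, 6, 14)
  w3 <- stats::runif(1, 8, 14)
  a3 <- stats::runif(1, 0.03, 0.18)
  y <- exp(-0.5 * ((i - c1) / w1)^2) -
    a2 * exp(-0.5 * ((i - c1 - gap) / w2)^2) +
    a3 * exp(-0.5 * ((i - c3) / w3)^2)
  y <- y * taper_window(m, ramp = max(4L, m %/% 8L))
  y / max(abs(y))
}

# Tukey-style cosine ramps forcing both endpoints to zero.
taper_window <- function(m, ramp) {
  w <- rep(1, m)
  r <- seq_len(ramp)
  w[r] <- 0.5 * (1 - cos(pi * (r - 1) / ramp))
  w[m + 1 - r] <- w[r]
  w
}

zero_lag_correlation <- function(a, b) {
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

# Correlation after shifting both waveforms so their maxima coincide,
# mirroring the peak alignment performed by the detector.
aligned_correlation <- function(a, b) {
  m <- length(a)
  shift_to <- function(w, at) {
    s <- which.max(w) - at
    out <- numeric(m)
    idx <- seq_len(m) + s
    ok <- idx >= 1 & idx <= m
    out[ok] <- w[idx[ok]]
    out
  }
  at <- m %/% 2L
  zero_lag_correlation(shift_to(a, at), shift_to(b, at))
}

#' @export
print.spike_templates <- function(x, ...) {
  cat("Spike templates:", length(x), "neuron(s), m =", attr(x, "m"),
      "samples\n")
  for (tp in x) {
    cat(sprintf("  #%d  peak at sample %d, min %.3f, max %.3f\n",
                tp$template_id, tp$peak_index, min(tp$waveform),
                max(tp$waveform)))
  }
  invisible(x)
}

# Run the calling function's remaining code under a fixed RNG seed,
# restoring the caller's RNG state when that function exits.
local_seed <- function(seed, env = parent.frame()) {
  withr::local_seed(as.integer(seed), .local_envir = env)
  invisible(NULL)
}
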