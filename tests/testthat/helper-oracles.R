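# Independent reference implementations used as oracles. These deliberately
# avoid the package's own code paths: literal per-sample scans, the direct
# textbook update rule, and integer-grid rational arithmetic.

# Literal NEO detector: evaluate the energy operator at every sample, apply
# the threshold, local-max refinement, boundary and dead-time rules in one
# sequential scan.
brute_force_detect <- function(trace, m, peak_offset, dead_time, gamma) {
  n <- length(trace)
  accepted <- integer(0)
  last <- -Inf
  for (k in 2:(n - 1)) {
    psi <- trace[k]^2 - trace[k - 1] * trace[k + 1]
    if (psi <= gamma) next
    lo <- max(1, k - dead_time); hi <- min(n, k + dead_time)
    if (trace[k] != max(trace[lo:hi])) next
    if (k - peak_offset < 1 || k - peak_offset + m - 1 > n) next
    if (k - last < dead_time) next
    accepted <- c(accepted, k)
    last <- k
  }
  accepted
}

# Direct form of the Hebbian update: w_ji' = w_ji + eta*(y_j x_i -
# y_j * sum_{k<=j} w_ki y_k), evaluated component by component.
gha_update_direct <- function(x, W, eta) {
  p <- nrow(W); m <- ncol(W)
  y <- numeric(p)
  for (j in seq_len(p)) y[j] <- sum(W[j, ] * x)
  W2 <- W
  for (j in seq_len(p)) {
    for (i in seq_len(m)) {
      s <- 0
      for (k in seq_len(j)) s <- s + W[k, i] * y[k]
      W2[j, i] <- W[j, i] + eta * (y[j] * x[i] - y[j] * s)
    }
  }
  W2
}

# Exact integer-grid arithmetic for the Q-format oracle. Values are carried
# as integer multiples of 2^-frac (exact in doubles far below 2^53).
rational_quantize <- function(v_num, v_den_pow, frac, total) {
  # v = v_num / 2^v_den_pow; returns integer grid count at 2^-frac
  v_num <- as.numeric(v_num)   # counts exceed .Machine$integer.max
  shift <- v_den_pow - frac
  if (shift <= 0) {
    q <- v_num * 2^(-shift)
  } else {
    den <- 2^shift
    base <- floor(v_num / den)
    rem <- v_num - base * den
    half <- den / 2
    q <- if (rem > half) base + 1
         else if (rem < half) base
         else if (base %% 2 == 0) base else base + 1
  }
  lo <- -2^(total - 1); hi <- 2^(total - 1) - 1
  min(max(q, lo), hi)
}

# One fixed MAC on the integer grid: product of two frac-grid numbers is a
# 2*frac-grid number; re-quantize to frac, saturating add on the grid.
rational_mac <- function(a_int, b_int, acc_int, frac, total) {
  p_int <- rational_quantize(as.numeric(a_int) * as.numeric(b_int),
                             2 * frac, frac, total)
  lo <- -2^(total - 1); hi <- 2^(total - 1) - 1
  min(max(acc_int + p_int, lo), hi)
}

# Gaussian sample with prescribed covariance eigenstructure.
gaussian_with_spectrum <- function(n, evals, seed) {
  set.seed(seed)
  m <- length(evals)
  Q <- qr.Q(qr(matrix(stats::rnorm(m * m), m)))
  matrix(stats::rnorm(n * m), n) %*% diag(sqrt(evals)) %*% t(Q)
}

# FCFS start-time recursion (no-overwrite regime): start_i =
# max(arrival_i, start_{i-1} + P).
fcfs_start_times <- function(arrival_cycles, P) {
  starts <- numeric(length(arrival_cycles))
  prev <- -Inf
  for (i in seq_along(arrival_cycles)) {
    starts[i] <- max(arrival_cycles[i], if (i == 1) 0 else prev + P)
    prev <- starts[i]
  }
  starts
}

# Small recording with one template inserted at known peaks, plus optional
# white noise; used where ground truth must be trivial.
toy_trace <- function(n, template, peaks, noise_sd = 0, seed = 1) {
  set.seed(seed)
  tr <- stats::rnorm(n, 0, noise_sd)
  pk_idx <- which.max(abs(template))
  for (pk in peaks) {
    idx <- (pk - pk_idx + 1):(pk - pk_idx + length(template))
    tr[idx] <- tr[idx] + template
  }
  tr
}
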