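#' Project a spike onto the learned weight vectors
#'
#' Service-mode feature extraction: `y[j]` is the inner product of weight
#' vector `w_j` with the spike `x`.
#'
#' @param x numeric vector of length m.
#' @param W p-by-m numeric weight matrix (one weight vector per row).
#' @return numeric feature vector of length p.
#' @export
gha_project <- function(x, W) {
  stopifnot(is.matrix(W), length(x) == ncol(W))
  as.numeric(W %*% x)
}

#' One generalized Hebbian (Sanger's rule) weight update
#'
#' Updates all p weight vectors from a single training spike using the
#' factored deflation recursion: with `y = W x` computed from the pre-update
#' weights, set `z_0 = x` and, for `j = 1..p`,
#' `z_j = z_{j-1} - y_j w_j` followed by `w_j <- w_j + eta * y_j * z_j`.
#' This is algebraically identical to the direct rule
#' `w_ji <- w_ji + eta * (y_j x_i - y_j * sum_{k<=j} w_ki y_k)` but reuses the
#' running residual `z`, the form used by streaming implementations.
#'
#' @param x training spike (length m).
#' @param W p-by-m weight matrix.
#' @param eta learning rate (> 0; `eta = 0` returns `W` unchanged).
#' @return the updated weight matrix.
#' @export
gha_update <- function(x, W, eta) {
  stopifnot(is.matrix(W), length(x) == ncol(W), eta >= 0)
  # left-to-right summation, matching the single-segment streamed path bit
  # for bit (avoids BLAS-order differences)
  y <- vapply(seq_len(nrow(W)), function(j) sum(W[j, ] * x), numeric(1))
  z <- x
  for (j in seq_len(nrow(W))) {
    z <- z - y[j] * W[j, ]
    W[j, ] <- W[j, ] + eta * y[j] * z
  }
  if (!all(is.finite(W))) {
    stop("GHA update diverged (non-finite weights); use a smaller eta")
  }
  W
}

#' Segment-streamed GHA update
#'
#' Performs the same update as [gha_update()] but fetches the vectors one
#' length-L segment at a time, the way a shared datapath with L multipliers
#' streams them from its weight buffers: the inner products are accumulated
#' segment by segment, then the residual/weight updates are applied segment by
#' segment. Segmentation only reorders floating-point additions, so the result
#' agrees with [gha_update()] to round-off. The returned cycle count follows
#' the calibrated latency model `2*p*b + 8` with `b = m/L`
#' (see [latency_cycles()]).
#'
#' @inheritParams gha_update
#' @param L segment length; must divide m.
#' @return list with `W` (updated weights) and `cycles` (latency in clock
#'   cycles of the modelled datapath).
#' @export
gha_update_segmented <- function(x, W, eta, L) {
  m <- ncol(W); p <- nrow(W)
  stopifnot(length(x) == m, L >= 1)
  if (m %% L != 0) stop("segment length L = ", L, " does not divide m = ", m)
  b <- m %/% L
  segs <- split(seq_len(m), rep(seq_len(b), each = L))
  # SOP: feature vector accumulated one segment at a time
  y <- numeric(p)
  for (j in seq_len(p)) {
    acc <- 0
    for (sg in segs) acc <- acc + sum(W[j, sg] * x[sg])
    y[j] <- acc
  }
  # SWU: residual deflation and weight update, segment by segment
  z <- x
  for (j in seq_len(p)) {
    for (sg in segs) {
      z[sg] <- z[sg] - y[j] * W[j, sg]
      W[j, sg] <- W[j, sg] + eta * y[j] * z[sg]
    }
  }
  if (!all(is.finite(W))) {
    stop("GHA update diverged (non-finite weights); use a smaller eta")
  }
  list(W = W, cycles = latency_cycles(m, p, L))
}

#' Fit streaming principal components to spike waveforms
#'
#' Trains p synaptic weight vectors on a stream of spike waveforms with the
#' generalized Hebbian algorithm (Sanger's rule). The weight vectors converge
#' to the leading eigenvectors of the data covariance without ever forming
#' the covariance matrix, which is what makes the method attractive for
#' implanted hardware. Two arithmetic backends are available: `"float"`
#' (double precision) and `"fixed17"`, which quantizes every stored sample,
#' weight and intermediate to an emulated 17-bit fixed-point format
#' (see [fixed_format()]).
#'
#' @param x spike waveforms: an n-by-m matrix (one spike per row) or a
#'   `spike_set` from [detect_all()].
#' @param p number of principal components to learn (default 2).
#' @param eta learning rate (default 0.03, stable for unit-amplitude spikes
#'   at m = 64).
#' @param epochs passes over the spike stream (default 40).
#' @param decay_tau time constant of the optional learning-rate schedule
#'   `eta_n = eta / (1 + n/decay_tau)`; `Inf` (default) keeps eta constant.
#' @param backend `"float"` or `"fixed17"`.
#' @param seed seed for the small random weight initialization
#'   (iid uniform on (-0.01, 0.01)).
#' @param normalize logical; scale waveforms by their global maximum absolute
#'   amplitude into `[-1, 1]` before training (default `TRUE`). Required for
#'   the fixed-point backend's number range and applied in float mode too for
#'   comparability.
#' @param L optional segment length recorded for latency accounting; does not
#'   change the fitted weights.
#' @param fmt fixed-point format used when `backend = "fixed17"`.
#' @return an object of class `"gha"` with components `weights` (p-by-m),
#'   `n_updates`, `scale`, `backend`, and the training settings. Methods:
#'   `print`, `summary`, `coef`, `predict`, `fitted`, `residuals`, `plot`.
#' @seealso [extract_features()], [gha_update()], [fcm()]
#' @export
gha <- function(x, p = 2L, eta = 0.03, epochs = 40L, decay_tau = Inf,
                backend = c("float", "fixed17"), seed = 1L, normalize = TRUE,
                L = NULL, fmt = fixed_format()) {
  backend <- match.arg(backend)
  xm <- spike_matrix(x)
  n_spikes <- nrow(xm); m <- ncol(xm)
  stopifnot(n_spikes >= 1, p >= 1, eta >= 0, epochs >= 1)
  if (!is.null(L)) stopifnot(m %% L == 0)
  scale <- 1
  if (normalize) {
    scale <- max(abs(xm))
    if (scale == 0) scale <- 1
    xm <- xm / scale
  }
  local_seed(seed)
  W <- matrix(stats::runif(p * m, -0.01, 0.01), nrow = p, ncol = m)
  if (backend == "fixed17") {
    xm <- fx_quantize(xm, fmt)
    W <- fx_quantize(W, fmt)
  }
  n_upd <- 0L
  for (ep in seq_len(epochs)) {
    for (i in seq_len(n_spikes)) {
      eta_n <- if (is.finite(decay_tau)) eta / (1 + n_upd / decay_tau) else eta
      W <- if (backend == "fixed17") {
        gha_update_fixed(xm[i, ], W, eta_n, fmt)
      } else {
        gha_update(xm[i, ], W, eta_n)
      }
      n_upd <- n_upd + 1L
    }
  }
  fit <- structure(list(weights = W, p = as.integer(p), m = as.integer(m),
                        eta = eta, epochs = as.integer(epochs),
                        decay_tau = decay_tau, backend = backend,
                        scale = scale, n_updates = n_upd,
                        seed = as.integer(seed), L = L, fmt = fmt,
                        x = xm, call = match.call()),
                   class = "gha")
  fit
}

spike_matrix <- function(x) {
  if (inherits(x, "spike_set")) x$waveforms
  else if (is.matrix(x)) x
  else matrix(x, nrow = 1)
}

#' Extract feature vectors from spikes
#'
#' Service-mode projection of each spike onto the learned weight vectors,
#' using the arithmetic backend the model was trained with. Equivalent to
#' `predict(fit, spikes)`.
#'
#' @param spikes a `spike_set` or n-by-m matrix of waveforms (raw scale; the
#'   model's training normalization is applied internally).
#' @param fit a fitted [gha()] model.
#' @return n-by-p matrix of feature vectors.
#' @export
extract_features <- function(spikes, fit) {
  stopifnot(inherits(fit, "gha"))
  xm <- spike_matrix(spikes) / fit$scale
  if (fit$backend == "fixed17") {
    xm <- fx_quantize(xm, fit$fmt)
    project_rows_fixed(xm, fit$weights, fit$fmt)
  } else {
    xm %*% t(fit$weights)
  }
}

project_rows_fixed <- function(xm, W, fmt) {
  feats <- matrix(0, nrow(xm), nrow(W))
  for (i in seq_len(nrow(xm))) {
    feats[i, ] <- gha_project_fixed(xm[i, ], W, fmt)
  }
  feats
}

#' @export
predict.gha <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    feats <- if (object$backend == "fixed17") {
      project_rows_fixed(object$x, object$weights, object$fmt)
    } else {
      object$x %*% t(object$weights)
    }
  } else {
    feats <- extract_features(newdata, object)
  }
  colnames(feats) <- paste0("PC", seq_len(object$p))
  feats
}

#' @export
coef.gha <- function(object, ...) {
  W <- object$weights
  rownames(W) <- paste0("PC", seq_len(nrow(W)))
  W
}

#' @export
fitted.gha <- function(object, ...) {
  y <- predict(object)
  (y %*% object$weights) * object$scale
}

#' @export
residuals.gha <- function(object, ...) {
  object$x * object$scale - fitted(object)
}

#' @export
print.gha <- function(x, ...) {
  cat(sprintf("Streaming PCA (generalized Hebbian algorithm), backend = %s\n",
              x$backend))
  cat(sprintf("  %d component(s) of dimension %d; %d update(s), eta = %g\n",
              x$p, x$m, x$n_updates, x$eta))
  nrm <- sqrt(rowSums(x$weights^2))
  cat("  weight vector norms:", paste(sprintf("%.3f", nrm), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
summary.gha <- function(object, ...) {
  y <- predict(object)
  xv <- sum(apply(object$x, 2, stats::var))
  comp_var <- apply(y, 2, stats::var)
  res <- residuals(object) / object$scale
  out <- list(backend = object$backend, p = object$p, m = object$m,
              n_updates = object$n_updates,
              norms = sqrt(rowSums(object$weights^2)),
              component_variance = comp_var,
              variance_fraction = comp_var / xv,
              mean_sq_residual = mean(res^2),
              max_cross_dot = if (object$p > 1) {
                G <- object$weights %*% t(object$weights)
                max(abs(G[upper.tri(G)]))
              } else 0)
  class(out) <- "summary.gha"
  out
}

#' @export
print.summary.gha <- function(x, ...) {
  cat(sprintf("GHA fit (%s backend): %d components, %d updates\n",
              x$backend, x$p, x$n_updates))
  for (j in seq_len(x$p)) {
    cat(sprintf("  PC%d: |w| = %.3f, var captured = %.4f (%.1f%% of total)\n",
                j, x$norms[j], x$component_variance[j],
                100 * x$variance_fraction[j]))
  }
  cat(sprintf("  mean squared reconstruction residual: %.3g\n",
              x$mean_sq_residual))
  if (x$p > 1) {
    cat(sprintf("  max |w_i . w_j| (i != j): %.3g\n", x$max_cross_dot))
  }
  invisible(x)
}

#' @export
plot.gha <- function(x, which = c("weights", "features"), ...) {
  which <- match.arg(which)
  if (which == "weights") {
    graphics::matplot(t(x$weights), type = "l", lty = 1,
                      xlab = "sample", ylab = "weight",
                      main = "Learned weight vectors", ...)
    graphics::legend("topright", legend = paste0("PC", seq_len(x$p)),
                     col = seq_len(x$p), lty = 1, bty = "n")
  } else {
    y <- predict(x)
    if (x$p < 2) stop("feature scatter needs p >= 2")
    graphics::plot(y[, 1], y[, 2], xlab = "PC1", ylab = "PC2",
                   main = "Feature vectors", pch = 20, ...)
  }
  invisible(x)
}
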