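#' Fixed-point number format
#'
#' Describes a signed two's-complement fixed-point representation. The default
#' Q1.16 format (17 bits total, 16 fractional) represents multiples of 2^-16
#' in `[-1, 1 - 2^-16]`, matching the number range of amplitude-normalized
#' spikes and near-unit-norm weight vectors. Sum-of-products accumulation uses
#' a widened format with `guard_bits` extra integer bits (default 6) so that
#' 64-term inner products do not saturate pathologically mid-sum.
#'
#' @param total_bits total width including the sign bit (default 17).
#' @param frac_bits fractional bits (default 16).
#' @param guard_bits extra integer bits for the internal accumulator.
#' @param rounding `"nearest_even"` (default) or `"truncate"`.
#' @param overflow `"saturate"` (default) or `"wrap"` (two's-complement
#'   wraparound), exposed for sensitivity studies.
#' @return a list of class `fixed_format` with derived fields `lsb`, `min`,
#'   `max`.
#' @export
fixed_format <- function(total_bits = 17L, frac_bits = 16L, guard_bits = 6L,
                         rounding = c("nearest_even", "truncate"),
                         overflow = c("saturate", "wrap")) {
  rounding <- match.arg(rounding)
  overflow <- match.arg(overflow)
  stopifnot(frac_bits >= 1, frac_bits <= total_bits - 1, guard_bits >= 0)
  lsb <- 2^(-frac_bits)
  hi <- 2^(total_bits - frac_bits - 1)
  structure(list(total_bits = as.integer(total_bits),
                 frac_bits = as.integer(frac_bits),
                 guard_bits = as.integer(guard_bits),
                 rounding = rounding, overflow = overflow,
                 lsb = lsb, min = -hi, max = hi - lsb),
            class = "fixed_format")
}

#' @export
print.fixed_format <- function(x, ...) {
  cat(sprintf("Q%d.%d fixed point (%d bits, %s rounding, %s overflow), range [%g, %g]\n",
              x$total_bits - x$frac_bits - 1L, x$frac_bits, x$total_bits,
              x$rounding, x$overflow, x$min, x$max))
  invisible(x)
}

# Widened accumulator format: same fractional grid, guard_bits extra
# integer bits.
acc_format <- function(fmt) {
  fixed_format(total_bits = fmt$total_bits + fmt$guard_bits,
               frac_bits = fmt$frac_bits, guard_bits = 0L,
               rounding = fmt$rounding, overflow = fmt$overflow)
}

#' Quantize values onto a fixed-point grid
#'
#' Rounds each value to the nearest multiple of `2^-frac_bits`
#' (round-half-to-even by default) and resolves overflow by saturation to the
#' format bounds (or two's-complement wraparound when configured). Values are
#' returned as doubles that are exact on the grid; quantization is idempotent.
#'
#' @param v finite numeric vector or matrix.
#' @param fmt a [fixed_format()].
#' @return quantized values with the shape of `v`.
#' @export
fx_quantize <- function(v, fmt = fixed_format()) {
  if (!all(is.finite(v))) stop("cannot quantize non-finite values")
  scaled <- v / fmt$lsb
  r <- if (fmt$rounding == "nearest_even") round(scaled) else trunc(scaled)
  lo <- fmt$min / fmt$lsb
  hi <- fmt$max / fmt$lsb
  if (fmt$overflow == "saturate") {
    r <- pmin(pmax(r, lo), hi)
  } else {
    span <- hi - lo + 1
    r <- ((r - lo) %% span) + lo
  }
  out <- r * fmt$lsb
  if (is.matrix(v)) dim(out) <- dim(v)
  out
}

#' Fixed-point multiply-accumulate
#'
#' Models one multiplier+adder stage of the sum-of-products datapath: the
#' product `a*b` is computed exactly, re-quantized to the given format, and
#' added to the accumulator with saturating (or wrapping) arithmetic in the
#' same format. Passing the widened [acc_format()] reproduces the guarded
#' accumulation used inside the projection kernels.
#'
#' @param a,b factors (already on the grid of `fmt`).
#' @param acc running accumulator value.
#' @param fmt a [fixed_format()].
#' @return the updated accumulator.
#' @export
fixed_mac <- function(a, b, acc, fmt = fixed_format()) {
  prod_q <- fx_quantize(a * b, fmt)
  fx_quantize(acc + prod_q, fmt)
}

# Inner product of two grid vectors accumulated in the widened format.
# Fast path: products of two frac_bits-grid numbers are exact in doubles
# (<= 34 bits of mantissa used), and their partial sums stay on the 2^-frac
# grid, so only range clipping can differ from a plain sum; the elementwise
# loop is needed only when a partial sum leaves the accumulator range.
fixed_dot <- function(a, b, fmt) {
  af <- acc_format(fmt)
  prods <- fx_quantize(a * b, af)
  cs <- cumsum(prods)
  if (all(cs >= af$min & cs <= af$max)) {
    cs[length(cs)]
  } else {
    acc <- 0
    for (i in seq_along(prods)) acc <- fx_quantize(acc + prods[i], af)
    acc
  }
}

# Service-mode projection: y_j held on the widened accumulator grid (same
# LSB as fmt, guard integer bits). A feature value can exceed 1 in magnitude
# (|y| <= |x||w| ~ 2.5 for unit-norm weights), so the y registers need the
# guard bits; the stored weights and samples remain in the narrow format.
gha_project_fixed <- function(x, W, fmt = fixed_format()) {
  vapply(seq_len(nrow(W)), function(j) fixed_dot(W[j, ], x, fmt), numeric(1))
}

# One Sanger-rule update on the quantized datapath: y_j and the running
# residual z_j live on the guard-bit accumulator grid; the weight store is
# re-quantized to the narrow format after each update.
gha_update_fixed <- function(x, W, eta, fmt = fixed_format()) {
  p <- nrow(W)
  af <- acc_format(fmt)
  eta_q <- fx_quantize(eta, fmt)
  y <- gha_project_fixed(x, W, fmt)
  z <- x
  for (j in seq_len(p)) {
    z <- fx_quantize(z - fx_quantize(y[j] * W[j, ], af), af)
    step <- fx_quantize(eta_q * y[j], af)
    W[j, ] <- fx_quantize(W[j, ] + fx_quantize(step * z, af), fmt)
  }
  W
}
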