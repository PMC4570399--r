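#' Per-spike latency of the segment-streamed GHA datapath
#'
#' Clock cycles needed to process one detected spike when the m-dimensional
#' vectors are streamed in `b = m/L` segments: `p*b` segment-cycles for the
#' sum-of-products (feature) pass, `p*b` for the weight-update pass, plus a
#' fixed 8-cycle overhead: `P = 2*p*b + 8`. For m = 64, p = 2 this gives
#' P = 264, 136, 72, 40, 24, 16 cycles at L = 1, 2, 4, 8, 16, 32. The fixed
#' overhead is calibrated at p = 2; its extrapolation in p is a modelling
#' assumption, not a measured quantity.
#'
#' @param m spike dimension (default 64).
#' @param p number of principal components (default 2).
#' @param L segment length; must divide m.
#' @return latency P in clock cycles.
#' @export
latency_cycles <- function(m = 64L, p = 2L, L = 8L) {
  stopifnot(m >= 1, p >= 1, L >= 1)
  if (m %% L != 0) stop("segment length L = ", L, " does not divide m = ", m)
  b <- m %/% L
  2L * as.integer(p) * as.integer(b) + 8L
}

#' Channel limit imposed by round-robin sample multiplexing
#'
#' The shared detection core must fetch one sample from every channel within
#' one sampling period, so `M * Tc <= Ts`, i.e. at most `floor(rc/rs)`
#' channels.
#'
#' @param rs sampling rate (samples/s).
#' @param rc clock rate (cycles/s).
#' @return `floor(rc/rs)`.
#' @export
neo_limit <- function(rs, rc) {
  stopifnot(rs > 0, rc > 0)
  as.integer(floor(rc / rs))
}

#' Maximum channel count with no discarded spikes
#'
#' A detected spike is discarded when it is overwritten in its channel's
#' one-spike memory before the feature-extraction core serves it. Under
#' worst-case first-come-first-serve backlog, with minimum inter-peak gap Q
#' samples and per-spike latency P cycles, no spike is discarded when
#' `M * P * Tc <= Q * Ts`. Combined with the round-robin sampling limit
#' ([neo_limit()]):
#' `Mmax = floor((Q/P) * (Ts/Tc))` when `Q < P`, else `floor(Ts/Tc)`,
#' where `Ts/Tc = rc/rs`.
#'
#' @param Q minimum number of samples between peaks of successive detected
#'   spikes on one channel.
#' @param P per-spike latency in clock cycles (see [latency_cycles()]).
#' @param rs sampling rate (samples/s).
#' @param rc clock rate (cycles/s).
#' @return the maximum number of channels Mmax.
#' @export
max_channels <- function(Q, P, rs, rc) {
  stopifnot(Q >= 1, P >= 1, rs > 0, rc > 0)
  if (Q < P) as.integer(floor((Q * rc) / (P * rs)))
  else neo_limit(rs, rc)
}

#' Capacity table over design parameters
#'
#' Tabulates the per-spike latency P and the no-discard channel limit Mmax
#' for combinations of minimum inter-peak gap Q, segment length L and clock
#' rate rc at a fixed sampling rate.
#'
#' @param Q_list,L_list,rc_list parameter grids.
#' @param rs sampling rate (samples/s), default 24,000.
#' @param m,p GHA dimensions, defaults 64 and 2.
#' @return a data.frame of class `capacity_table` with columns
#'   `Q`, `L`, `P`, `rc`, `neo_limit`, `Mmax`.
#' @export
capacity_table <- function(Q_list, L_list, rc_list, rs = 24000, m = 64L,
                           p = 2L) {
  grid <- expand.grid(rc = rc_list, L = L_list, Q = Q_list,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, c("Q", "L", "rc")]
  grid$P <- vapply(grid$L, function(L) latency_cycles(m, p, L), integer(1))
  grid$neo_limit <- vapply(grid$rc, function(rc) neo_limit(rs, rc),
                           integer(1))
  grid$Mmax <- mapply(function(Q, P, rc) max_channels(Q, P, rs, rc),
                      grid$Q, grid$P, grid$rc)
  grid <- grid[, c("Q", "L", "P", "rc", "neo_limit", "Mmax")]
  attr(grid, "rs") <- rs; attr(grid, "m") <- m; attr(grid, "p") <- p
  class(grid) <- c("capacity_table", "data.frame")
  grid
}

#' @export
print.capacity_table <- function(x, ...) {
  cat(sprintf("Channel capacity (rs = %g samples/s, m = %d, p = %d)\n",
              attr(x, "rs"), attr(x, "m"), attr(x, "p")))
  wide <- stats::reshape(as.data.frame(x)[, c("Q", "L", "P", "rc", "Mmax")],
                         idvar = c("Q", "L", "P"), timevar = "rc",
                         direction = "wide")
  names(wide) <- sub("^Mmax\\.", "Mmax @ rc=", names(wide))
  print(wide, row.names = FALSE)
  invisible(x)
}
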