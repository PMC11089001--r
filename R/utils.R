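#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join bind_rows n row_number
#' @importFrom stats fft quantile rpois runif rnorm sd ks.test
NULL

# Deterministic substream derivation: every source of randomness in the
# package draws its seed from the single user seed plus a stream name, so
# stages can be re-run independently yet bit-reproducibly.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- 2166136261 %% 2147483647
  for (ch in utf8ToInt(stream)) {
    h <- bitwXor(as.integer(h), as.integer(ch))
    h <- (as.numeric(h) * 16777619) %% 2147483647
  }
  as.integer((as.numeric(seed) * 69069 + h) %% 2147483647)
}

with_stream_seed <- function(seed, stream, code) {
  withr::with_seed(derive_seed(seed, stream), code)
}

#' Wrap angles to the circular interval (-180, 180]
#'
#' The package-wide phase convention places 0 degrees at the peak of the
#' band-passed oscillation and +/-180 degrees at the trough.
#'
#' @param deg numeric vector of angles in degrees.
#' @return angles wrapped to (-180, 180].
#' @export
wrap_deg <- function(deg) {
  w <- ((deg + 180) %% 360) - 180
  w[w == -180] <- 180
  w
}

#' Circular mean of angles in degrees
#'
#' @param deg angles in degrees.
#' @param w optional non-negative weights.
#' @return mean direction in (-180, 180], or `NA` for empty input.
#' @export
circ_mean_deg <- function(deg, w = NULL) {
  if (length(deg) == 0) return(NA_real_)
  r <- deg * pi / 180
  if (is.null(w)) w <- rep(1, length(r))
  atan2(sum(w * sin(r)), sum(w * cos(r))) * 180 / pi
}

# Smallest absolute angular difference in degrees.
circ_diff_deg <- function(a, b) abs(wrap_deg(a - b))

#' Rayleigh test of circular uniformity
#'
#' Tests whether a sample of phases is uniformly distributed on the circle
#' against a unimodal alternative, using the resultant-length statistic
#' Z = n * R^2 with the standard series approximation for the p-value.
#'
#' @param deg phases in degrees.
#' @return a tibble with `n`, `r_bar` (mean resultant length), `z` and
#'   `p_value`.
#' @export
rayleigh_test <- function(deg) {
  n <- length(deg)
  if (n < 2) abort("rayleigh_test() needs at least 2 phases")
  r <- deg * pi / 180
  rbar <- sqrt(mean(cos(r))^2 + mean(sin(r))^2)
  z <- n * rbar^2
  p <- exp(-z) * (1 + (2 * z - z^2) / (4 * n) -
    (24 * z - 132 * z^2 + 76 * z^3 - 9 * z^4) / (288 * n^2))
  tibble(n = n, r_bar = rbar, z = z, p_value = max(min(p, 1), 0))
}

# Analytic signal via FFT: zero out negative frequencies, double positive
# ones. Phase of the result is the instantaneous (Hilbert) phase.
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(fft(x) * h, inverse = TRUE) / n
}

# Runs of TRUE in a logical vector as (start, end) sample indices.
logical_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  tibble(start = starts[keep], end = ends[keep])
}

# Total overlap (seconds) between one interval and a set of intervals.
interval_overlap <- function(start, end, starts, ends) {
  if (length(starts) == 0) return(0)
  sum(pmax(0, pmin(end, ends) - pmax(start, starts)))
}

assert_ethogram <- function(eth) {
  stopifnot(all(c("behavior", "start_s", "end_s") %in% names(eth)))
  if (nrow(eth) == 0) return(invisible(eth))
  if (any(eth$end_s <= eth$start_s)) {
    abort("ethogram has intervals with end_s <= start_s")
  }
  o <- order(eth$start_s)
  s <- eth$start_s[o]; e <- eth$end_s[o]
  if (any(s[-1] < e[-length(e)] - 1e-9)) {
    abort("ethogram has overlapping intervals")
  }
  invisible(eth)
}
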