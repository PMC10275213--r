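# Developmental growth of the circuit from neuronal birthtimes.

#' Build cumulative daily class-size series
#'
#' The day-`i` circuit contains the classified neurons born on day `i`
#' or before (embryo = day 0, through day 9), so class sizes grow
#' cumulatively, reaching the full partition on day 9. Class proportions
#' are recomputed per day over the assigned neurons present that day.
#'
#' @param partition A `consensus_partition` (or an integer label vector
#'   with `NA` for unassigned neurons).
#' @param birthtimes Factor or character vector over the same neurons
#'   with levels among [birthtime_levels()]; no missing values allowed
#'   for classified neurons.
#' @return Object of class `daily_series`: `days` (0:9), `n` (cumulative
#'   classified neuron count per day), `sizes` (`kappa x 10` class-size
#'   matrix) and `rho` (per-day class proportions).
#' @export
build_daily_series <- function(partition, birthtimes) {
  labels <- if (inherits(partition, "consensus_partition"))
    partition$labels else as.integer(partition)
  lv <- birthtime_levels()
  bt <- factor(as.character(birthtimes), levels = lv)
  if (length(bt) != length(labels))
    stopf("`birthtimes` must cover the same neurons as the partition")
  classified <- !is.na(labels)
  if (any(is.na(bt[classified])))
    stopf("classified neurons with missing birthtimes: %d",
          sum(is.na(bt[classified])))
  kappa <- max(labels, na.rm = TRUE)
  day <- as.integer(bt) - 1L  # embryo = 0
  sizes <- vapply(0:9, function(i) {
    tabulate(labels[classified & day <= i], nbins = kappa)
  }, integer(kappa))
  sizes <- matrix(sizes, nrow = kappa)
  n_i <- colSums(sizes)
  rho <- sweep(sizes, 2L, ifelse(n_i > 0, n_i, 1), "/")
  structure(list(days = 0:9, n = n_i, sizes = sizes, rho = rho,
                 kappa = kappa),
            class = "daily_series")
}

#' Per-class growth percentages relative to uniform growth
#'
#' On day `i` the actual size of class `k` is `n_i * rho_k^i`; the
#' reference size under uniform (proportional) growth is `n_i * rho_k^9`,
#' the final-day composition scaled down to the day-`i` circuit. Growth
#' is the percentage difference
#' `g_k^i = 100 * (n_i rho_k^i - n_i rho_k^9) / (n_i rho_k^9)`.
#' The final day is its own reference, so `g_k^9 = 0`; a class absent
#' until late shows `g = -100` early on. Entries with zero expected size
#' (final proportion zero, or an empty day) are undefined and flagged.
#'
#' @param series A `daily_series`.
#' @return Object of class `growth_profile`: matrix `g` (`kappa x 10`,
#'   `NA` where undefined) and `undefined` (logical matrix).
#' @export
growth_percentages <- function(series) {
  if (!inherits(series, "daily_series")) stopf("`series` must be a `daily_series`")
  rho9 <- series$rho[, 10L]
  if (any(rho9 <= 0))
    warning("classes with zero final-day proportion have undefined growth")
  g <- 100 * sweep(sweep(series$rho, 1L, rho9, "-"), 1L, rho9, "/")
  undefined <- matrix(rho9 <= 0, series$kappa, 10L) |
    matrix(series$n <= 0, series$kappa, 10L, byrow = TRUE)
  g[undefined] <- NA_real_
  structure(list(g = g, undefined = undefined, days = series$days),
            class = "growth_profile")
}

#' Critical growth periods per class
#'
#' Ranks, per class, the day-over-day growth differences
#' `g_k^i - g_k^(i-1)` (the embryo day uses `g_k^0 - 0`: growth from an
#' empty circuit) and flags the days in the top 25th percentile of the
#' greatest rate of growth. Ties share rank. The percentile is taken per
#' class, so each class gets its own critical period.
#'
#' @param profile A `growth_profile`.
#' @param pct Percentile defining "critical" (default top 25%).
#' @return Logical `kappa x 10` matrix of critical-day flags, with
#'   attribute `rates` (the ranked differences).
#' @export
critical_periods <- function(profile, pct = 25) {
  if (!inherits(profile, "growth_profile"))
    stopf("`profile` must be a `growth_profile`")
  g <- profile$g
  if (ncol(g) < 2) stopf("need at least 2 days")
  rates <- cbind(g[, 1L], g[, -1L, drop = FALSE] - g[, -ncol(g), drop = FALSE])
  flags <- matrix(FALSE, nrow(g), ncol(g))
  for (k in seq_len(nrow(g))) {
    r <- rates[k, ]
    thr <- top_threshold(r, pct)
    if (!is.na(thr)) flags[k, ] <- !is.na(r) & r >= thr
  }
  attr(flags, "rates") <- rates
  flags
}
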