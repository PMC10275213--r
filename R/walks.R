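# Random-walk analysis on the mesoscale circuit: step costs, absorption
# (average simple-path length), driftiness (absorption over shortest
# path) and percentile-based key-node/key-edge flagging.

#' Build the random-walk view of a circuit
#'
#' Scales the class sizes by their minimum
#' (`scaled_sizes[i] = |V_i| / min |V|`, so the smallest class has scaled
#' size 1) and precomputes the step-cost matrix
#' `c(i, j) = 1 / (P(i, j) * scaled_i * scaled_j)`: the larger the
#' expected number of neuron-level edges between two classes, the cheaper
#' the step. Absent edges and self-loops carry infinite cost (walks are
#' simple and ignore self-loops).
#'
#' @param circuit A `circuit` (from [floor_to_circuit()]) or a list with
#'   elements `p` (`kappa x kappa` probabilities) and `class_sizes`.
#' @return Object of class `walk_circuit`: `kappa`, `sizes`,
#'   `scaled_sizes`, `p`, `cost` (dense matrix, `Inf` = unusable step).
#' @export
walk_circuit <- function(circuit) {
  p <- circuit$p
  sizes <- circuit$class_sizes
  kappa <- nrow(p)
  if (length(sizes) != kappa) stopf("class sizes do not match the matrix")
  if (any(sizes <= 0)) stopf("class sizes must be positive")
  scaled <- sizes / min(sizes)
  cost <- 1 / (p * outer(scaled, scaled))
  cost[p <= 0] <- Inf
  diag(cost) <- Inf
  structure(list(kappa = kappa, sizes = sizes, scaled_sizes = scaled,
                 p = p, cost = cost),
            class = "walk_circuit")
}

as_walk_circuit <- function(x) {
  if (inherits(x, "walk_circuit")) x else walk_circuit(x)
}

#' Cost of a single step between two classes
#'
#' @param circuit A `walk_circuit` (or coercible `circuit`).
#' @param i,j Source and destination class indices.
#' @return Positive finite cost, or `Inf` when no usable edge exists.
#' @export
step_cost <- function(circuit, i, j) {
  wc <- as_walk_circuit(circuit)
  wc$cost[i, j]
}

walk_adjacency <- function(wc) {
  lapply(seq_len(wc$kappa), function(i)
    as.integer(which(is.finite(wc$cost[i, ]))) - 1L)
}

#' Absorption by exhaustive simple-path enumeration
#'
#' Enumerates every simple directed path from class `s` to class `t`
#' (the target is terminal, so edges out of `t` are irrelevant) and
#' returns the mean total step cost -- the absorption `A(s -> t)` -- along
#' with the path count. The number of simple paths grows faster than
#' `kappa!`, so enumeration is only attempted up to `kappa_cap` classes.
#'
#' @param circuit `walk_circuit` or `circuit`.
#' @param s,t Source and target class indices; `s == t` returns 0 by
#'   convention.
#' @param kappa_cap Largest circuit size for which enumeration is
#'   allowed.
#' @return List with `absorption` (mean path cost, `NA` if `t` is
#'   unreachable), `n_paths`, `sd` (path-cost standard deviation) and
#'   `defined`.
#' @export
enumerate_absorption <- function(circuit, s, t, kappa_cap = 10L) {
  wc <- as_walk_circuit(circuit)
  if (wc$kappa > kappa_cap)
    stopf("kappa = %d exceeds the enumeration cap (%d); use sample_absorption",
          wc$kappa, kappa_cap)
  if (s == t)
    return(list(absorption = 0, n_paths = 0L, sd = 0, defined = TRUE))
  res <- cpp_enumerate_paths(walk_adjacency(wc), wc$cost,
                             as.integer(s - 1L), as.integer(t - 1L),
                             max_paths = Inf)
  if (res$count == 0)
    return(list(absorption = NA_real_, n_paths = 0L, sd = NA_real_,
                defined = FALSE))
  mean_cost <- res$sum / res$count
  varc <- max(res$sumsq / res$count - mean_cost^2, 0)
  list(absorption = mean_cost, n_paths = as.integer(res$count),
       sd = sqrt(varc), defined = TRUE)
}

#' Absorption by Monte-Carlo path sampling
#'
#' Samples `m` simple paths from `s` to `t` by self-avoiding walks that
#' pick the next class uniformly among unvisited out-neighbours,
#' resampling walks that dead-end or fail to arrive. That sampling law
#' does not weight paths uniformly, so by default each path is reweighted
#' by the product of its branching factors (the inverse of its sampling
#' probability), making the weighted average converge to the
#' uniform-over-paths mean computed by [enumerate_absorption()].
#' `weighted = FALSE` gives the naive (biased toward short paths)
#' estimator.
#'
#' @inheritParams enumerate_absorption
#' @param m Number of sampled paths.
#' @param seed Optional seed.
#' @param weighted Apply the importance-weight correction (default).
#' @param max_attempts Attempt budget before giving up.
#' @return List with `absorption`, `se` (Monte-Carlo standard error of
#'   the estimator), `m` (paths actually accepted), `attempts` and
#'   `defined`.
#' @export
sample_absorption <- function(circuit, s, t, m, seed = NULL, weighted = TRUE,
                              max_attempts = 100 * m) {
  wc <- as_walk_circuit(circuit)
  check_scalar(m, "m", lower = 1, integer = TRUE)
  if (s == t)
    return(list(absorption = 0, se = 0, m = 0L, attempts = 0, defined = TRUE))
  res <- with_seed(seed,
    cpp_sample_paths(walk_adjacency(wc), wc$cost,
                     as.integer(s - 1L), as.integer(t - 1L),
                     as.integer(m), max_attempts))
  len <- res$lengths
  if (!length(len))
    return(list(absorption = NA_real_, se = NA_real_, m = 0L,
                attempts = res$attempts, defined = FALSE))
  if (weighted) {
    w <- res$weights / sum(res$weights)
    est <- sum(w * len)
    se <- sqrt(sum(w^2 * (len - est)^2))
  } else {
    est <- mean(len)
    se <- stats::sd(len) / sqrt(length(len))
  }
  list(absorption = est, se = se, m = length(len),
       attempts = res$attempts, defined = TRUE)
}

circuit_igraph <- function(wc) {
  finite <- which(is.finite(wc$cost), arr.ind = TRUE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = finite[, 1L], to = finite[, 2L],
               weight = wc$cost[finite]),
    directed = TRUE,
    vertices = data.frame(name = seq_len(wc$kappa)))
  g
}

#' Shortest-path cost between two classes
#'
#' Minimal total step cost over directed paths (Dijkstra on the
#' cost-weighted circuit); `delta(s, s) = 0`.
#'
#' @inheritParams enumerate_absorption
#' @return The cost, `Inf` when `t` is unreachable from `s`.
#' @export
shortest_path_cost <- function(circuit, s, t) {
  wc <- as_walk_circuit(circuit)
  d <- igraph::distances(circuit_igraph(wc), v = as.character(s),
                         to = as.character(t), mode = "out")
  as.numeric(d)
}

#' Pairwise and average absorption, shortest paths and driftiness
#'
#' Computes the full `kappa x kappa` absorption matrix `A` (exhaustive
#' enumeration when `kappa <= exact_cap`, importance-weighted sampling
#' with `m` paths otherwise), the shortest-path cost matrix `delta`, the
#' driftiness `D = A / delta` (`>= 1` wherever defined: no average of
#' simple-path costs can beat the cheapest path), and per-class averages
#' over the `kappa - 1` counterpart classes (self excluded):
#' out-absorption `A_o`, in-absorption `A_i`, out- and in-driftiness
#' `D_o`, `D_i`. Unreachable pairs are excluded from averages and
#' counted.
#'
#' @param circuit `walk_circuit` or `circuit` with `kappa >= 2`.
#' @param m Sampled paths per pair when enumeration is infeasible.
#' @param seed Master seed for the sampling fallback.
#' @param exact_cap Largest `kappa` for exhaustive enumeration.
#' @return Object of class `walk_stats` with matrices `absorption`,
#'   `shortest`, `driftiness`, `n_paths`, vectors `A_o`, `A_i`, `D_o`,
#'   `D_i`, the count of `undefined_pairs`, `m` and `method`.
#' @export
walk_stats <- function(circuit, m = 1e5, seed = NULL, exact_cap = 10L) {
  wc <- as_walk_circuit(circuit)
  kappa <- wc$kappa
  if (kappa < 2) stopf("need at least 2 classes")
  exact <- kappa <= exact_cap
  A <- matrix(NA_real_, kappa, kappa)
  NP <- matrix(0, kappa, kappa)
  seeds <- spawn_seeds(seed, kappa^2)
  for (s in seq_len(kappa)) {
    for (t in seq_len(kappa)) {
      if (s == t) { A[s, t] <- 0; next }
      if (exact) {
        r <- enumerate_absorption(wc, s, t, kappa_cap = exact_cap)
        NP[s, t] <- r$n_paths
      } else {
        r <- sample_absorption(wc, s, t, m = m,
                               seed = seeds[[(s - 1L) * kappa + t]])
        NP[s, t] <- r$m
      }
      A[s, t] <- r$absorption
    }
  }
  delta <- igraph::distances(circuit_igraph(wc), mode = "out")
  ord <- order(as.integer(rownames(delta)))
  delta <- delta[ord, ord, drop = FALSE]
  dimnames(delta) <- NULL
  D <- A / delta
  diag(D) <- NA_real_
  D[!is.finite(delta)] <- NA_real_
  avg_excl_self <- function(M, margin) {
    idx <- seq_len(kappa)
    vapply(idx, function(i) {
      vals <- if (margin == 1L) M[i, -i] else M[-i, i]
      vals <- vals[!is.na(vals) & is.finite(vals)]
      if (length(vals)) mean(vals) else NA_real_
    }, numeric(1))
  }
  structure(list(absorption = A, shortest = delta, driftiness = D,
                 n_paths = NP,
                 A_o = avg_excl_self(A, 1L), A_i = avg_excl_self(A, 2L),
                 D_o = avg_excl_self(D, 1L), D_i = avg_excl_self(D, 2L),
                 undefined_pairs = sum(is.na(A[row(A) != col(A)])),
                 m = if (exact) NA_real_ else m,
                 method = if (exact) "enumeration" else "sampling"),
            class = "walk_stats")
}

#' @export
print.walk_stats <- function(x, ...) {
  cat(sprintf("Walk stats (%s): kappa = %d, %d undefined pair(s)\n",
              x$method, nrow(x$absorption), x$undefined_pairs))
  invisible(x)
}

#' Percentile-based flags for key classes and critical links
#'
#' Flags classes in the bottom `low_pct` percentile of average
#' in-absorption (easily reached: accessible) and of average
#' out-absorption (signals readily originate there), and class pairs in
#' the top `high_pct` percentile of pairwise driftiness (critical,
#' non-redundant communication links). Percentiles are rank-based with
#' ties sharing rank, so at most `ceiling(pct/100 * n)` items are flagged
#' when values are distinct.
#'
#' @param stats A `walk_stats`.
#' @param low_pct Percentile for the absorption (accessibility) flags.
#' @param high_pct Percentile for the driftiness (critical-link) flags.
#' @return List with logical vectors `accessible` (bottom `low_pct` of
#'   `A_i`), `originator` (bottom `low_pct` of `A_o`), and logical matrix
#'   `critical_link` (top `high_pct` of pairwise driftiness).
#' @export
percentile_flags <- function(stats, low_pct = 20, high_pct = 10) {
  thr_in <- bottom_threshold(stats$A_i, low_pct)
  thr_out <- bottom_threshold(stats$A_o, low_pct)
  D <- stats$driftiness
  thr_d <- top_threshold(D[!is.na(D)], high_pct)
  list(accessible = !is.na(stats$A_i) & stats$A_i <= thr_in,
       originator = !is.na(stats$A_o) & stats$A_o <= thr_out,
       critical_link = !is.na(D) & D >= thr_d)
}
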