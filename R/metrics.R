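# Graph-theoretic hub detection, SBM goodness-of-fit, distribution
# comparison, connectome summary statistics and the subsample-robustness
# protocol.

#' Weighted degree of each circuit class
#'
#' Sum of the incoming and outgoing connection probabilities of a class,
#' multiplied by the number of neurons in that class:
#' `(sum_j p[i, j] + sum_j p[j, i]) * |V_i|`. A self-loop contributes to
#' both the incoming and the outgoing sum.
#'
#' @param circuit A `circuit`.
#' @return Numeric vector of weighted degrees.
#' @export
weighted_degree <- function(circuit) {
  (rowSums(circuit$p) + colSums(circuit$p)) * circuit$class_sizes
}

#' Directed betweenness centrality on the unweighted circuit
#'
#' Fraction of hop-count shortest paths passing through each class,
#' computed on the simplified circuit whose edges are unweighted
#' (self-loops dropped), normalized by `(kappa - 1)(kappa - 2)`.
#'
#' @param circuit A `circuit` with at least 3 classes.
#' @return Numeric vector in `[0, 1]`.
#' @export
betweenness_unweighted <- function(circuit) {
  kappa <- circuit$kappa
  if (kappa < 3) stopf("need at least 3 classes")
  adj <- circuit$p > 0
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "directed")
  igraph::betweenness(g, directed = TRUE, weights = NA) /
    ((kappa - 1) * (kappa - 2))
}

#' Identify hub classes
#'
#' Classes strictly above the given quantile on BOTH weighted degree and
#' betweenness centrality are graph-theoretic hubs of the circuit.
#'
#' @param circuit A `circuit`.
#' @param quantile Quantile cutoff applied to both measures.
#' @return Object of class `hub_report`: `weighted_degree`,
#'   `betweenness`, `hubs` (class indices) and the `quantile` used.
#' @export
hub_report <- function(circuit, quantile = 0.9) {
  wd <- weighted_degree(circuit)
  btw <- betweenness_unweighted(circuit)
  hubs <- identify_hubs(wd, btw, quantile)
  structure(list(weighted_degree = wd, betweenness = btw, hubs = hubs,
                 quantile = quantile),
            class = "hub_report")
}

#' @rdname hub_report
#' @param wd,btw Per-class weighted degree and betweenness vectors.
#' @export
identify_hubs <- function(wd, btw, quantile = 0.9) {
  which(wd > stats::quantile(wd, quantile) &
          btw > stats::quantile(btw, quantile))
}

#' @export
print.hub_report <- function(x, ...) {
  cat(sprintf("Hub report: %d class(es) above the %.0f%% quantile: %s\n",
              length(x$hubs), 100 * x$quantile,
              if (length(x$hubs)) paste(x$hubs, collapse = ", ") else "none"))
  invisible(x)
}

#' Binomial goodness-of-fit of the block model
#'
#' Under the fitted SBM, the number of neurons in `V_j` that a given
#' neuron in `V_i` connects to is Binomial(`|V_j|`, `p_hat[i, j]`). For
#' every block pair, the per-neuron out-connection counts into `V_j` are
#' pooled across all `G` graphs and compared with the interval
#' `|V_j| p_hat +/- 2 sqrt(|V_j| p_hat (1 - p_hat))`; the fraction of
#' observations inside is reported. Pairs with `p_hat` of 0 or 1 have a
#' degenerate (zero-width) interval and are flagged.
#'
#' @param partition A `consensus_partition`.
#' @param ensemble The `binary_ensemble`.
#' @param P_hat A `block_probability` (defaults to re-estimating it).
#' @return List with `fraction` (`kappa x kappa` matrix), `degenerate`
#'   (logical matrix) and `n_obs` (observation counts).
#' @export
binomial_fit_fraction <- function(partition, ensemble, P_hat = NULL) {
  if (is.null(P_hat)) P_hat <- estimate_block_probabilities(partition, ensemble)
  kappa <- partition$kappa
  sizes <- partition$class_sizes
  p <- P_hat$p_hat
  lo <- sizes[col(p)] * p - 2 * sqrt(sizes[col(p)] * p * (1 - p))
  hi <- sizes[col(p)] * p + 2 * sqrt(sizes[col(p)] * p * (1 - p))
  dim(lo) <- dim(hi) <- dim(p)
  within <- total <- matrix(0, kappa, kappa)
  for (g in ensemble) {
    lab <- partition$labels[g$index]
    use <- !is.na(lab)
    lab <- lab[use]
    if (!length(lab)) next
    A <- g$matrix[use, use, drop = FALSE]
    Mm <- Matrix::sparseMatrix(i = seq_along(lab), j = lab, x = 1,
                               dims = c(length(lab), kappa))
    counts <- as.matrix(A %*% Mm)  # neuron x target-class out-counts
    for (i in seq_len(kappa)) {
      rows <- lab == i
      if (!any(rows)) next
      for (j in seq_len(kappa)) {
        obs <- counts[rows, j]
        within[i, j] <- within[i, j] + sum(obs >= lo[i, j] & obs <= hi[i, j])
        total[i, j] <- total[i, j] + length(obs)
      }
    }
  }
  list(fraction = ifelse(total > 0, within / total, NA_real_),
       degenerate = matrix(p %in% c(0, 1), nrow(p)),
       n_obs = total)
}

#' Histogram intersection between two samples
#'
#' Area under the pointwise minimum of the two density-normalized
#' histograms on a common binning; 1 means perfect overlap, 0 disjoint
#' supports. Integer-valued samples get integer-aligned unit bins by
#' default (the compared quantities are counts).
#'
#' @param sample_a,sample_b Nonempty numeric samples.
#' @param bins Optional vector of break points covering both samples.
#' @return Intersection value in `[0, 1]`.
#' @export
histogram_intersection <- function(sample_a, sample_b, bins = NULL) {
  if (!length(sample_a) || !length(sample_b)) stopf("samples must be nonempty")
  all_int <- all(c(sample_a, sample_b) == round(c(sample_a, sample_b)))
  if (is.null(bins)) {
    rng <- range(sample_a, sample_b)
    bins <- if (all_int) seq(rng[1] - 0.5, rng[2] + 0.5, by = 1)
            else seq(rng[1], rng[2], length.out = 51L)
  }
  ha <- graphics::hist(sample_a, breaks = bins, plot = FALSE)
  hb <- graphics::hist(sample_b, breaks = bins, plot = FALSE)
  widths <- diff(bins)
  sum(pmin(ha$density, hb$density) * widths)
}

#' Connectome summary statistics
#'
#' Sparsity (nonzero fraction of entries), average vertex degree (mean
#' in+out edges per neuron) and average edge strength (mean of nonzero
#' weights). For a `binary_ensemble`, returns the mean and standard
#' deviation of each statistic across the `G` graphs (computed over the
#' full neuron index).
#'
#' @param x Strength matrix or `binary_ensemble`.
#' @return List with `sparsity`, `avg_degree`, `avg_strength` (each a
#'   single number, or `c(mean, sd)` for an ensemble); `avg_strength` is
#'   `NA` for an empty matrix.
#' @export
connectome_summary <- function(x) {
  one <- function(A, n) {
    nnz <- Matrix::nnzero(A)
    list(sparsity = nnz / n^2,
         avg_degree = 2 * nnz / n,
         avg_strength = if (nnz) mean(A@x) else NA_real_)
  }
  if (inherits(x, "binary_ensemble")) {
    n <- attr(x, "n_total")
    per <- lapply(x, function(g) one(g$matrix, n))
    agg <- function(field) {
      v <- vapply(per, `[[`, numeric(1), field)
      c(mean = mean(v), sd = stats::sd(v))
    }
    list(sparsity = agg("sparsity"), avg_degree = agg("avg_degree"),
         avg_strength = agg("avg_strength"))
  } else {
    A <- as(as(as(x, "dMatrix"), "generalMatrix"), "CsparseMatrix")
    one(A, nrow(A))
  }
}

#' Robustness of the classification to neuron sample size
#'
#' Reruns the full clustering pipeline on simple random subsamples
#' (without replacement) of the neurons, scaling the minimum class size
#' proportionally (`c_size * n_s / n`), and reports pairwise adjusted
#' Rand indices between the resulting partitions (restricted to neurons
#' classified by both) together with the percentage of all neurons
#' classified by both.
#'
#' @param strengths Strength matrix.
#' @param fractions Subsampling fractions in `(0, 1]`.
#' @param config A [pipeline_config()]; its `c_size` is scaled per
#'   fraction.
#' @param seed Master seed (subsampling and pipeline streams).
#' @return List with `ari` and `pct_both` (upper-triangular matrices over
#'   the fractions) and `partitions` (full-index label vectors).
#' @export
subsample_robustness <- function(strengths, fractions, config, seed = NULL) {
  A <- as_strength_matrix(strengths)
  n <- nrow(A)
  if (any(fractions <= 0 | fractions > 1))
    stopf("`fractions` must lie in (0, 1]")
  seeds <- spawn_seeds(seed, 2L * length(fractions))
  labels <- vector("list", length(fractions))
  for (f in seq_along(fractions)) {
    ns <- round(fractions[f] * n)
    if (ns < max(50, 5 * config$k_max))
      stopf(paste("subsample of %d neurons is too small to support",
                  "kappa << n inference; use a larger fraction"), ns)
    sub <- with_seed(seeds[[f]], sort(sample.int(n, ns)))
    cfg <- config
    cfg$c_size <- max(1L, as.integer(round(config$c_size * ns / n)))
    cfg$seed <- seeds[[length(fractions) + f]]
    res <- run_pipeline(A[sub, sub, drop = FALSE], config = cfg,
                        stages = "consensus")
    lab <- rep(NA_integer_, n)
    lab[sub] <- res$partition$labels
    labels[[f]] <- lab
  }
  k <- length(fractions)
  ari <- pct <- matrix(NA_real_, k, k,
                       dimnames = list(fractions, fractions))
  for (i in seq_len(k)) {
    for (j in i:k) {
      both <- !is.na(labels[[i]]) & !is.na(labels[[j]])
      pct[i, j] <- 100 * mean(both)
      if (sum(both) >= 2)
        ari[i, j] <- adjusted_rand_index(labels[[i]], labels[[j]])
    }
  }
  list(ari = ari, pct_both = pct, partitions = labels)
}
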