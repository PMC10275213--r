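# Block probability estimation and circuit construction.

# Shared estimator: average, over graphs, of the proportion of ordered
# neuron pairs between two classes that carry an edge. `mask` restricts
# numerators and denominators to a neuron subset. Within-class
# denominators exclude self-pairs (|V_i| (|V_i| - 1)) since the graphs
# have no self-loops. Neurons trimmed from a graph contribute neither
# edges nor pairs in that graph; a class absent from a graph contributes
# zero for that graph.
block_prob_core <- function(partition, ensemble, mask = NULL) {
  if (!inherits(partition, "consensus_partition"))
    stopf("`partition` must be a `consensus_partition`")
  if (!inherits(ensemble, "binary_ensemble"))
    stopf("`ensemble` must be a `binary_ensemble`")
  kappa <- partition$kappa
  if (kappa == 0L) stopf("partition has no classes")
  n <- length(partition$labels)
  if (is.null(mask)) mask <- rep(TRUE, n)
  G <- length(ensemble)
  acc <- matrix(0, kappa, kappa)
  for (g in ensemble) {
    lab <- partition$labels[g$index]
    use <- !is.na(lab) & mask[g$index]
    lab <- lab[use]
    if (!length(lab)) next
    A <- g$matrix[use, use, drop = FALSE]
    Mm <- Matrix::sparseMatrix(i = seq_along(lab), j = lab, x = 1,
                               dims = c(length(lab), kappa))
    cnt <- as.matrix(Matrix::t(Mm) %*% A %*% Mm)
    sz <- tabulate(lab, nbins = kappa)
    denom <- outer(sz, sz)
    diag(denom) <- sz * (sz - 1)
    ratio <- ifelse(denom > 0, cnt / denom, 0)
    acc <- acc + ratio
  }
  acc / G
}

new_block_probability <- function(p_hat, class_sizes, restricted = FALSE) {
  structure(list(p_hat = p_hat, class_sizes = class_sizes,
                 kappa = nrow(p_hat), restricted = restricted),
            class = "block_probability")
}

#' Estimate block connection probabilities from the ensemble
#'
#' The `(i, j)` entry is the average, across the `G` binary graphs, of
#' the number of edges from class `V_i` to class `V_j` divided by the
#' number of ordered neuron pairs between the two classes present in that
#' graph (self-pairs excluded within a class). Values always lie in
#' `[0, 1]`.
#'
#' @param partition A `consensus_partition` with at least one class.
#' @param ensemble The `binary_ensemble` the partition was derived from.
#' @return Object of class `block_probability`: `p_hat`
#'   (`kappa x kappa`), `class_sizes` (global class sizes) and `kappa`.
#' @export
estimate_block_probabilities <- function(partition, ensemble) {
  p_hat <- block_prob_core(partition, ensemble)
  new_block_probability(p_hat, partition$class_sizes)
}

#' Block probabilities restricted to a neuron subset
#'
#' Recomputes the estimator of [estimate_block_probabilities()] using
#' only the masked neurons (e.g. dopaminergic cells) in both numerator
#' and denominators; classes with no masked neuron get zero rows and
#' columns. With the full mask this equals the unrestricted estimate
#' exactly.
#'
#' @inheritParams estimate_block_probabilities
#' @param neuron_mask Logical vector over the common neuron index.
#' @return A `block_probability` with `restricted = TRUE` and
#'   `class_sizes` counting masked neurons per class. An empty overall
#'   mask yields an all-zero matrix with a warning.
#' @export
restricted_block_probabilities <- function(partition, ensemble, neuron_mask) {
  neuron_mask <- as.logical(neuron_mask)
  if (length(neuron_mask) != length(partition$labels))
    stopf("`neuron_mask` must have length %d", length(partition$labels))
  if (!any(neuron_mask & !is.na(partition$labels)))
    warning("mask selects no classified neurons; estimates are all zero")
  p_hat <- block_prob_core(partition, ensemble, mask = neuron_mask)
  sizes <- tabulate(partition$labels[neuron_mask & !is.na(partition$labels)],
                    nbins = partition$kappa)
  new_block_probability(p_hat, sizes, restricted = TRUE)
}

#' @export
print.block_probability <- function(x, ...) {
  cat(sprintf("Block probability matrix: %d x %d%s, %d nonzero entries\n",
              x$kappa, x$kappa, if (x$restricted) " (restricted)" else "",
              sum(x$p_hat > 0)))
  invisible(x)
}

circuit_edges <- function(p) {
  idx <- which(p > 0, arr.ind = TRUE)
  data.frame(from = idx[, 1L], to = idx[, 2L], p = p[idx])
}

new_circuit <- function(p, class_sizes, floor_threshold) {
  structure(list(p = p, class_sizes = class_sizes,
                 kappa = nrow(p), floor_threshold = floor_threshold,
                 edges = circuit_edges(p)),
            class = "circuit")
}

#' Floor weak block probabilities to build the mesoscale circuit
#'
#' Sets to zero all entries of the estimated block probability matrix up
#' to the largest value that can be removed while every class keeps at
#' least one incident (incoming or outgoing) edge. Candidate thresholds
#' are scanned in ascending order of the distinct nonzero values; because
#' removing edges only reduces incidence, the feasible thresholds form a
#' downward-closed set and the returned threshold is the largest feasible
#' one. Rebuilding the circuit with the returned threshold (keep entries
#' strictly above it) reproduces the same edge set.
#'
#' @param P_hat A `block_probability`.
#' @return Object of class `circuit`: floored matrix `p`, `class_sizes`,
#'   `floor_threshold` (0 when nothing could be removed) and an `edges`
#'   data frame (`from`, `to`, `p`).
#' @export
floor_to_circuit <- function(P_hat) {
  if (!inherits(P_hat, "block_probability"))
    stopf("`P_hat` must be a `block_probability`")
  p <- P_hat$p_hat
  if (!any(p > 0)) stopf("block probability matrix is all zero")
  covered <- function(mat) {
    inc <- rowSums(mat > 0) + colSums(mat > 0)
    all(inc > 0)
  }
  if (!covered(p))
    stopf("some class has no incident edge even before flooring")
  threshold <- 0
  for (v in sort(unique(p[p > 0]))) {
    trial <- p
    trial[trial <= v] <- 0
    if (!covered(trial)) break
    threshold <- v
  }
  floored <- p
  floored[floored <= threshold] <- 0
  new_circuit(floored, P_hat$class_sizes, threshold)
}

#' @export
print.circuit <- function(x, ...) {
  cat(sprintf(
    "Circuit: %d classes, %d directed edges (floor threshold %.4g)\n",
    x$kappa, nrow(x$edges), x$floor_threshold))
  invisible(x)
}

#' Keep only the heaviest fraction of circuit edges
#'
#' Retains the `ceiling(fraction * #edges)` heaviest edges; ties at the
#' cutoff weight are all kept. Nodes left without edges are retained and
#' reported via the `isolated` attribute.
#'
#' @param circuit A `circuit`.
#' @param fraction Fraction of edges to keep, in `(0, 1]`.
#' @return A `circuit` on the same node set.
#' @export
top_fraction_edges <- function(circuit, fraction) {
  check_scalar(fraction, "fraction", lower = 0, upper = 1, open_lower = TRUE)
  w <- circuit$edges$p
  if (!length(w)) return(circuit)
  cutoff <- sort(w, decreasing = TRUE)[ceiling(fraction * length(w))]
  p <- circuit$p
  p[p < cutoff] <- 0
  out <- new_circuit(p, circuit$class_sizes, circuit$floor_threshold)
  attr(out, "isolated") <- which(rowSums(p > 0) + colSums(p > 0) == 0)
  out
}
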