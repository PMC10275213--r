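# Modified iterative voting consensus: merge G per-graph clusterings into
# one final partition.

ensemble_label_matrix <- function(ensemble) {
  M <- if (inherits(ensemble, "clustering_ensemble")) unclass(ensemble)
       else as.matrix(ensemble)
  storage.mode(M) <- "integer"
  if (ncol(M) < 2L) stopf("need at least G = 2 clusterings")
  M
}

#' One iterative-voting-consensus update against a reference clustering
#'
#' Starting from `reference`, repeats until a fixed point: (i) for each
#' reference cluster compute its center vector, the per-clustering
#' majority label among the cluster's members; (ii) reassign every neuron
#' to the reference cluster whose center vector is nearest in Hamming
#' distance to the neuron's own label vector across the `G` clusterings.
#' Ties (majority label and nearest center alike) break toward the lowest
#' numeric label/cluster, making the update deterministic. Clusters
#' emptied by a pass are dropped and iteration continues. A neuron absent
#' from a trimmed graph carries an `NA` label there, which never matches
#' any center coordinate (it counts as a mismatch for every cluster
#' equally).
#'
#' @param reference Integer label vector over the common neuron index
#'   (`NA` allowed for neurons the reference graph trimmed away; they are
#'   assigned on the first pass).
#' @param ensemble `clustering_ensemble` or integer `n x G` label matrix
#'   with `NA` for trimmed neurons.
#' @param max_iter Iteration cap; hitting it sets `converged = FALSE`.
#' @return List with `labels` (complete integer labeling), `converged`
#'   and `iterations`.
#' @export
ivc_update_one <- function(reference, ensemble, max_iter = 100L) {
  M <- ensemble_label_matrix(ensemble)
  n <- nrow(M); G <- ncol(M)
  if (length(reference) != n)
    stopf("`reference` must have length %d", n)
  pi_star <- as.integer(reference)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    clusters <- sort(unique(pi_star[!is.na(pi_star)]))
    if (!length(clusters)) stopf("reference clustering has no labels")
    K <- length(clusters)
    # centers[k, j]: majority label of cluster k under clustering j
    centers <- matrix(NA_integer_, K, G)
    for (k in seq_len(K)) {
      members <- which(pi_star == clusters[k])
      for (j in seq_len(G)) {
        lab <- M[members, j]
        lab <- lab[!is.na(lab)]
        if (length(lab)) {
          tab <- tabulate(lab)
          centers[k, j] <- which.max(tab)  # lowest label wins ties
        }
      }
    }
    D <- matrix(0, n, K)
    for (j in seq_len(G)) {
      mis <- outer(M[, j], centers[, j], "!=")
      mis[is.na(mis)] <- TRUE
      D <- D + mis
    }
    new_labels <- clusters[max.col(-D, ties.method = "first")]
    if (identical(new_labels, pi_star)) { converged <- TRUE; break }
    pi_star <- new_labels
  }
  list(labels = pi_star, converged = converged, iterations = iter)
}

#' Iterative voting consensus over all clusterings
#'
#' Applies [ivc_update_one()] with each of the `G` clusterings as the
#' reference in turn. Each update reads only the original ensemble, so
#' the result is independent of the processing order.
#'
#' @inheritParams ivc_update_one
#' @param max_iter Per-reference iteration cap.
#' @return List with `labels` (`n x G` matrix of updated clusterings)
#'   and `converged` (logical per reference).
#' @export
ivc_update_all <- function(ensemble, max_iter = 100L) {
  M <- ensemble_label_matrix(ensemble)
  out <- matrix(NA_integer_, nrow(M), ncol(M))
  conv <- logical(ncol(M))
  for (l in seq_len(ncol(M))) {
    upd <- ivc_update_one(M[, l], M, max_iter = max_iter)
    out[, l] <- upd$labels
    conv[l] <- upd$converged
  }
  list(labels = out, converged = conv)
}

#' Pairwise co-clustering similarity matrix
#'
#' Entry `(i, j)` is the proportion of the `G` (updated) clusterings that
#' place neurons `i` and `j` in the same cluster; entries are exact
#' multiples of `1/G`, the matrix is symmetric with unit diagonal. A
#' neuron carrying `NA` in some clustering counts as "not together" with
#' every other neuron there (absence is treated as evidence against
#' association).
#'
#' @param updated `n x G` label matrix (e.g. `labels` from
#'   [ivc_update_all()]).
#' @return Dense `n x n` numeric similarity matrix.
#' @export
similarity_matrix <- function(updated) {
  M <- as.matrix(updated)
  n <- nrow(M); G <- ncol(M)
  S <- matrix(0, n, n)
  for (l in seq_len(G)) {
    same <- outer(M[, l], M[, l], "==")
    same[is.na(same)] <- FALSE
    S <- S + same
  }
  S <- S / G
  diag(S) <- 1
  S
}

#' Partition neurons by tau-chain equivalence
#'
#' Two neurons are equivalent when a chain of neurons connects them in
#' which every adjacent pair is clustered together in at least a
#' proportion `tau` of the clusterings (`s_ij >= tau`, i.e. at least
#' `tau * G` times). The partition is the set of connected components of
#' the thresholded similarity graph. Components can only be refined, never
#' merged, as `tau` increases.
#'
#' @param S Similarity matrix from [similarity_matrix()].
#' @param tau Proportion threshold in `(0, 1]`.
#' @return Integer component membership vector.
#' @export
chain_components <- function(S, tau) {
  check_scalar(tau, "tau", lower = 0, upper = 1, open_lower = TRUE)
  adj <- S >= tau
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "max")
  as.integer(igraph::components(g)$membership)
}

#' Apply the minimum-class-size cutoff to a partition
#'
#' Components smaller than `c_size` are moved to the unassigned pool;
#' the surviving classes are renumbered `1..kappa_hat` by decreasing size
#' (ties by first occurrence).
#'
#' @param membership Integer component membership (e.g. from
#'   [chain_components()]).
#' @param c_size Minimum class size (`>= 1`).
#' @param tau Recorded threshold (metadata only).
#' @return Object of class `consensus_partition`: `labels` (integer class
#'   per neuron, `NA` = unassigned), `kappa`, `class_sizes`, `unassigned`
#'   (indices), `c_size`, `tau` and `assigned_fraction`. `kappa = 0` is
#'   flagged with a warning.
#' @export
size_filter <- function(membership, c_size, tau = NA_real_) {
  check_scalar(c_size, "c_size", lower = 1, integer = TRUE)
  membership <- as.integer(membership)
  sizes <- table(membership)
  keep_ids <- as.integer(names(sizes))[sizes >= c_size]
  ord <- order(-as.integer(sizes[as.character(keep_ids)]),
               match(keep_ids, membership))
  keep_ids <- keep_ids[ord]
  labels <- match(membership, keep_ids)  # NA for filtered components
  kappa <- length(keep_ids)
  if (kappa == 0L)
    warning("all components fell below c_size; partition is empty")
  structure(list(labels = labels, kappa = kappa,
                 class_sizes = if (kappa) as.integer(table(labels))
                               else integer(0),
                 unassigned = which(is.na(labels)),
                 c_size = as.integer(c_size), tau = tau,
                 assigned_fraction = mean(!is.na(labels))),
            class = "consensus_partition")
}

#' @export
print.consensus_partition <- function(x, ...) {
  cat(sprintf(
    "Consensus partition: kappa = %d classes, %.2f%% of %d neurons assigned\n",
    x$kappa, 100 * x$assigned_fraction, length(x$labels)))
  if (x$kappa)
    cat("  class sizes:", paste(x$class_sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Full consensus clustering of an ensemble of clusterings
#'
#' Runs [ivc_update_all()], [similarity_matrix()], [chain_components()]
#' and [size_filter()] in sequence.
#'
#' @inheritParams ivc_update_one
#' @param tau Chain-equivalence proportion threshold.
#' @param c_size Minimum class size.
#' @param keep_similarity Attach the dense similarity matrix to the
#'   result (memory-heavy for large `n`).
#' @return A `consensus_partition` (with attribute `similarity` if
#'   requested, and `ivc_converged` flags).
#' @export
consensus_cluster <- function(ensemble, tau = 0.95, c_size = 100L,
                              max_iter = 100L, keep_similarity = FALSE) {
  upd <- ivc_update_all(ensemble, max_iter = max_iter)
  S <- similarity_matrix(upd$labels)
  part <- size_filter(chain_components(S, tau), c_size, tau = tau)
  attr(part, "ivc_converged") <- upd$converged
  if (keep_similarity) attr(part, "similarity") <- S
  part
}
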