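#' Convert connection strengths to connection probabilities
#'
#' Each overlapping axonal-dendritic segment pair is assumed to form a
#' synaptic connection independently with probability `p_conn`, so a
#' neuron pair with strength `a_c` connects with probability
#' `a_p = 1 - (1 - p_conn)^a_c`. Zero strengths map to zero probability,
#' preserving the sparsity pattern.
#'
#' @param strengths Square nonnegative integer matrix (sparse or dense)
#'   with zero diagonal; the weighted potential connectome.
#' @param p_conn Per-overlap success probability in `(0, 1]`.
#' @return Sparse `dgCMatrix` of connection probabilities with attribute
#'   `p_conn`.
#' @export
strength_to_probability <- function(strengths, p_conn) {
  check_scalar(p_conn, "p_conn", lower = 0, upper = 1, open_lower = TRUE)
  A <- as_strength_matrix(strengths)
  A@x <- 1 - (1 - p_conn)^A@x
  attr(A, "p_conn") <- p_conn
  A
}

#' Select the per-overlap connection probability
#'
#' Scans a grid of candidate `p_conn` values and returns the one whose
#' induced mean connection probability among potentially connected neuron
#' pairs (nonzero strengths) is closest to `target_mean`. The default
#' 0.01-step grid matches the two-decimal precision at which the
#' parameter is conventionally reported.
#'
#' @param strengths Strength matrix with at least one nonzero entry.
#' @param target_mean Desired mean of nonzero connection probabilities.
#' @param grid Candidate values in `(0, 1]`.
#' @return The selected `p_conn` (ties broken toward the smaller value).
#' @export
choose_p_conn <- function(strengths, target_mean = 0.5,
                          grid = seq(0.01, 1, by = 0.01)) {
  A <- as_strength_matrix(strengths)
  if (!length(A@x)) stopf("`strengths` has no nonzero entries")
  check_scalar(target_mean, "target_mean", lower = 0, upper = 1)
  tab <- table(A@x)
  w <- as.numeric(names(tab))
  cnt <- as.numeric(tab)
  dev <- vapply(grid, function(p) {
    abs(sum(cnt * (1 - (1 - p)^w)) / sum(cnt) - target_mean)
  }, numeric(1))
  grid[which.min(dev)]
}

#' Trim a binary connectome to neurons with both inputs and outputs
#'
#' Iteratively removes neurons lacking either an incoming or an outgoing
#' edge until none remain (a fixed point), since each removal can strip
#' other neurons of their last edge. Trimming is idempotent.
#'
#' @param A Square binary matrix (sparse or dense).
#' @return List with `matrix` (trimmed binary `dgCMatrix`, possibly
#'   0 x 0) and `index` (original indices of the retained neurons).
#' @export
trim_matrix <- function(A) {
  A <- as(as(as(A, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (nrow(A) != ncol(A)) stopf("`A` must be square")
  index <- seq_len(nrow(A))
  repeat {
    keep <- Matrix::rowSums(A) > 0 & Matrix::colSums(A) > 0
    if (all(keep)) break
    A <- A[keep, keep, drop = FALSE]
    index <- index[keep]
    if (!length(index)) break
  }
  list(matrix = A, index = index)
}

#' Sample an ensemble of binary connectomes
#'
#' Each matrix `A^(l)` is an independent realisation of the probability
#' matrix: entry `(i, j)` is Bernoulli with probability `a_p[i, j]`.
#' Every realisation is then trimmed with [trim_matrix()] so no retained
#' neuron lacks inputs or outputs. One master seed spawns an independent
#' substream per matrix, so individual graphs are reproducible.
#'
#' @param probs Sparse probability matrix from [strength_to_probability()].
#' @param G Number of binary graphs to sample (`>= 1`).
#' @param seed Optional master seed.
#' @return Object of class `binary_ensemble`: a list of `G` elements, each
#'   with `matrix` (trimmed binary adjacency), `index` (retained original
#'   neuron indices) and `seed`. Attribute `n_total` records the original
#'   neuron count; attribute `degenerate` flags an ensemble in which some
#'   realisation trimmed away every neuron.
#' @export
sample_binary_ensemble <- function(probs, G, seed = NULL) {
  check_scalar(G, "G", lower = 1, integer = TRUE)
  P <- as(as(as(probs, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (any(P@x < 0) || any(P@x > 1)) stopf("`probs` entries must be in [0, 1]")
  n <- nrow(P)
  seeds <- spawn_seeds(seed, G)
  trip <- Matrix::mat2triplet(P)
  graphs <- lapply(seq_len(G), function(l) {
    with_seed(seeds[[l]], {
      hit <- runif(length(trip$x)) < trip$x
      A <- Matrix::sparseMatrix(i = trip$i[hit], j = trip$j[hit],
                                x = rep(1, sum(hit)), dims = c(n, n))
      tr <- trim_matrix(A)
      list(matrix = tr$matrix, index = tr$index, seed = seeds[[l]])
    })
  })
  structure(graphs, class = "binary_ensemble", n_total = n,
            degenerate = any(vapply(graphs, function(g) length(g$index) == 0L,
                                    logical(1))))
}

#' @export
print.binary_ensemble <- function(x, ...) {
  kept <- vapply(x, function(g) length(g$index), integer(1))
  cat(sprintf("Binary ensemble: G = %d graphs over %d neurons (retained %s)\n",
              length(x), attr(x, "n_total"),
              paste(range(kept), collapse = "-")))
  if (isTRUE(attr(x, "degenerate")))
    cat("  [degenerate: at least one realisation is empty]\n")
  invisible(x)
}
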