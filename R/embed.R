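# Adjacency spectral embedding and embedding-dimension selection.

# Exact decomposition via LAPACK; returns full singular value vector.
svd_exact <- function(A) {
  s <- svd(as.matrix(A))
  list(u = s$u, d = s$d, v = s$v)
}

# Randomized truncated SVD (range finder with power iterations). Cheap on
# large sparse adjacency matrices; leading singular pairs are accurate for
# the well-separated spectra of SBM graphs.
svd_randomized <- function(A, k, q = 3L, oversample = 10L, seed = NULL) {
  n <- nrow(A)
  k <- min(k, n)
  p <- min(n, k + oversample)
  with_seed(seed, {
    Omega <- matrix(rnorm(n * p), n, p)
    Yr <- as.matrix(A %*% Omega)
    for (i in seq_len(q)) {
      Yr <- qr.Q(qr(Yr))
      Yr <- as.matrix(A %*% as.matrix(Matrix::crossprod(A, Yr)))
    }
    Q <- qr.Q(qr(Yr))
    B <- as.matrix(Matrix::crossprod(Q, A))
    s <- svd(B)
    list(u = Q %*% s$u[, seq_len(k), drop = FALSE],
         d = s$d[seq_len(k)],
         v = s$v[, seq_len(k), drop = FALSE])
  })
}

#' Adjacency spectral embedding of a binary connectome
#'
#' Approximates the adjacency matrix by a rank-`d` singular value
#' decomposition `A ~ U_d D_d V_d'` and embeds each neuron as the
#' concatenation of its scaled left and right singular vectors,
#' `[X | Y] = [U_d sqrt(D_d) | V_d sqrt(D_d)]`. The left half captures
#' out-connectivity, the right half in-connectivity; `X Y'` is the best
#' rank-`d` approximation of `A` in Frobenius norm (exact method).
#'
#' When `d = NULL`, the embedding rank is chosen by the profile-likelihood
#' elbow of the singular values ([select_dimension()]).
#'
#' @param A Square (binary) adjacency matrix, sparse or dense.
#' @param d Embedding rank, `1 <= d <= rank(A)`; `NULL` to select
#'   automatically.
#' @param method `"exact"` (full LAPACK SVD), `"randomized"` (truncated,
#'   for large sparse graphs) or `"auto"` (exact up to 800 neurons).
#' @param n_sv Number of leading singular values computed by the
#'   randomized method (also the maximum selectable `d`).
#' @param seed Seed for the randomized range finder.
#' @return Object of class `ase_embedding`: `latent` (`n x 2d` matrix),
#'   `singular_values` (nonincreasing), `d`, `dimension_selection`
#'   (profile-likelihood details when `d` was selected automatically).
#' @export
ase_embed <- function(A, d = NULL, method = c("auto", "exact", "randomized"),
                      n_sv = 80L, seed = NULL) {
  method <- match.arg(method)
  n <- nrow(A)
  if (n != ncol(A)) stopf("`A` must be square")
  if (method == "auto") method <- if (n <= 800) "exact" else "randomized"
  dec <- if (method == "exact") svd_exact(A)
         else svd_randomized(A, k = min(n_sv, n - 1L), seed = seed)
  sv <- dec$d
  sel <- NULL
  if (is.null(d)) {
    # the elbow is read off the leading (scree-plot) part of the spectrum;
    # including the full bulk lets the two-group likelihood split the bulk
    # itself instead of isolating the signal dimensions
    sel <- select_dimension(sv, max_rank = min(n_sv, length(sv)))
    d <- sel$d
  }
  check_scalar(d, "d", lower = 1, upper = length(sv), integer = TRUE)
  if (sv[d] <= 1e-12 * max(sv[1], 1e-300))
    stopf("`d` = %d exceeds the numerical rank of `A`", d)
  sq <- sqrt(sv[seq_len(d)])
  X <- dec$u[, seq_len(d), drop = FALSE] * rep(sq, each = n)
  Y <- dec$v[, seq_len(d), drop = FALSE] * rep(sq, each = n)
  structure(list(latent = cbind(X, Y), singular_values = sv, d = d,
                 method = method, dimension_selection = sel),
            class = "ase_embedding")
}

#' @export
print.ase_embedding <- function(x, ...) {
  cat(sprintf("ASE embedding: %d neurons in %d dimensions (d = %d, %s SVD)\n",
              nrow(x$latent), ncol(x$latent), x$d, x$method))
  invisible(x)
}

# Two-group Gaussian profile log-likelihood of sorted values split after
# position q, with a common (pooled MLE) variance and a variance floor.
profile_loglik <- function(values, q, var_floor = 1e-12) {
  g1 <- values[seq_len(q)]
  g2 <- values[-seq_len(q)]
  mu1 <- mean(g1)
  mu2 <- if (length(g2)) mean(g2) else 0
  pooled <- (sum((g1 - mu1)^2) + sum((g2 - mu2)^2)) / length(values)
  s <- sqrt(max(pooled, var_floor))
  sum(dnorm(g1, mu1, s, log = TRUE)) +
    (if (length(g2)) sum(dnorm(g2, mu2, s, log = TRUE)) else 0)
}

#' Select the embedding dimension by the profile-likelihood elbow
#'
#' Sorts the singular values in nonincreasing order and finds the cut
#' point `q` maximizing the two-group Gaussian profile likelihood (both
#' groups share a pooled variance, floored at `var_floor` to avoid
#' degenerate zero-variance groups). The first elbow is the selected
#' dimension; a second elbow, obtained by reapplying the rule to the tail
#' beyond the first cut, is also reported since spectra of real
#' connectomes often show two plateaus. When all values are equal the
#' convention is `d = 1`.
#'
#' @param singular_values At least 3 nonnegative values.
#' @param max_rank Consider only the leading `max_rank` values.
#' @param var_floor Variance floor of the profile likelihood.
#' @return List with `d` (first elbow), `second_elbow` (or `NA`), and
#'   `profile` (log-likelihood per candidate cut).
#' @export
select_dimension <- function(singular_values, max_rank = length(singular_values),
                             var_floor = 1e-12) {
  v <- sort(singular_values, decreasing = TRUE)
  v <- v[seq_len(min(max_rank, length(v)))]
  if (length(v) < 3) stopf("need at least 3 singular values")
  cuts <- seq_len(length(v) - 1L)
  prof <- vapply(cuts, function(q) profile_loglik(v, q, var_floor), numeric(1))
  d <- cuts[which.max(prof)]
  second <- NA_integer_
  tail_v <- v[-seq_len(d)]
  if (length(tail_v) >= 3) {
    prof2 <- vapply(seq_len(length(tail_v) - 1L),
                    function(q) profile_loglik(tail_v, q, var_floor),
                    numeric(1))
    second <- d + which.max(prof2)
  }
  list(d = d, second_elbow = second, profile = prof)
}
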