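# Gaussian mixture modelling of latent vectors: EM with model-based
# agglomerative (Ward) initialisation and BIC model selection. Implemented
# in-package (no external mixture-modelling engine is assumed available).

# Per-component Gaussian log-density, via Cholesky with a ridge fallback.
# (X - mu is formed by column-major recycling, cheaper than sweep().)
gauss_logdens <- function(X, mu, Sigma, ridge_scale) {
  p <- ncol(X)
  L <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(L)) {
    Sigma <- Sigma + diag(ridge_scale, p)
    L <- tryCatch(chol(Sigma), error = function(e) NULL)
    if (is.null(L)) return(NULL)
  }
  Z <- (X - rep(mu, each = nrow(X))) %*% backsolve(L, diag(p))
  -0.5 * (p * log(2 * pi) + 2 * sum(log(diag(L))) + rowSums(Z * Z))
}

# Ward-linkage agglomerative initial partition shared across candidate k.
# For large n the tree is built on a deterministic subsample and remaining
# points join the nearest subsample group centroid.
ward_init <- function(X, max_tree = 1000L) {
  n <- nrow(X)
  if (n <= max_tree) {
    hc <- hclust(dist(X), method = "ward.D2")
    list(hc = hc, sub = seq_len(n), assign_rest = NULL)
  } else {
    sub <- unique(round(seq(1, n, length.out = max_tree)))
    hc <- hclust(dist(X[sub, , drop = FALSE]), method = "ward.D2")
    list(hc = hc, sub = sub, assign_rest = setdiff(seq_len(n), sub))
  }
}

ward_partition <- function(init, X, k) {
  lab_sub <- cutree(init$hc, k = k)
  lab <- integer(nrow(X))
  lab[init$sub] <- lab_sub
  if (length(init$assign_rest)) {
    centers <- t(vapply(seq_len(k), function(g) {
      colMeans(X[init$sub[lab_sub == g], , drop = FALSE])
    }, numeric(ncol(X))))
    rest <- X[init$assign_rest, , drop = FALSE]
    d2 <- outer(rowSums(rest^2), rowSums(centers^2), "+") -
      2 * rest %*% t(centers)
    lab[init$assign_rest] <- max.col(-d2, ties.method = "first")
  }
  lab
}

# EM for a k-component full-covariance GMM from a hard initial partition.
# Returns NULL when the fit degenerates (empty component, singular
# covariance beyond repair).
em_gmm <- function(X, lab0, k, tol = 1e-6, max_iter = 500L) {
  n <- nrow(X); p <- ncol(X)
  ridge_scale <- 1e-6 * mean(apply(X, 2L, var)) + 1e-12
  pooled <- cov(X) + diag(ridge_scale, p)
  w <- mu <- Sigma <- vector("list", k)
  for (g in seq_len(k)) {
    idx <- which(lab0 == g)
    w[[g]] <- max(length(idx), 1) / n
    mu[[g]] <- if (length(idx)) colMeans(X[idx, , drop = FALSE]) else colMeans(X)
    Sigma[[g]] <- if (length(idx) > p) {
      cov(X[idx, , drop = FALSE]) + diag(ridge_scale, p)
    } else pooled
  }
  w <- unlist(w) / sum(unlist(w))
  loglik <- -Inf; converged <- FALSE
  R <- matrix(0, n, k)
  for (iter in seq_len(max_iter)) {
    LD <- matrix(0, n, k)
    for (g in seq_len(k)) {
      ld <- gauss_logdens(X, mu[[g]], Sigma[[g]], ridge_scale)
      if (is.null(ld)) return(NULL)
      LD[, g] <- log(w[g]) + ld
    }
    mx <- LD[, 1L]
    if (k > 1L) for (g in 2:k) mx <- pmax(mx, LD[, g])
    lse <- mx + log(rowSums(exp(LD - mx)))
    new_loglik <- sum(lse)
    R <- exp(LD - lse)
    if (is.finite(loglik) &&
        abs(new_loglik - loglik) <= tol * (abs(new_loglik) + 1e-10)) {
      loglik <- new_loglik; converged <- TRUE; break
    }
    loglik <- new_loglik
    Nk <- colSums(R)
    if (any(Nk < 1e-8)) return(NULL)
    w <- Nk / n
    MU <- crossprod(R, X) / Nk
    for (g in seq_len(k)) {
      mu[[g]] <- MU[g, ]
      Xc <- X - rep(MU[g, ], each = n)
      Sigma[[g]] <- crossprod(sqrt(R[, g]) * Xc) / Nk[g] +
        diag(ridge_scale, p)
    }
  }
  list(loglik = loglik, converged = converged, labels = max.col(R),
       weights = w, means = mu, covariances = Sigma,
       iterations = if (converged) iter else max_iter)
}

#' Fit a Gaussian mixture to latent vectors with BIC model selection
#'
#' For each candidate number of components `k = 1..k_max`, fits a
#' full-covariance GMM by EM initialised from a Ward-linkage agglomerative
#' partition of the latent vectors, then selects the `k` maximizing
#' `BIC = 2 log L - npar log n`. The fit is deterministic given the data
#' (the initialisation involves no randomness).
#'
#' @param embedding An `ase_embedding` or a plain numeric matrix of latent
#'   vectors (rows = neurons).
#' @param k_max Largest number of mixture components considered.
#' @param seed Unused placeholder for API symmetry (the fit is
#'   deterministic); kept so callers can thread a seed uniformly.
#' @param tol Relative log-likelihood convergence tolerance of EM.
#' @param max_iter EM iteration cap; non-convergence is flagged, not
#'   silent.
#' @param patience Stop scanning `k` after the BIC has decreased for this
#'   many consecutive candidates past the incumbent maximum; `Inf`
#'   (default) scans `1..k_max` exhaustively. A finite patience is a
#'   runtime optimisation for unimodal BIC landscapes.
#' @return Object of class `gmm_clustering`: `labels`, selected `k`,
#'   `bic_trace` (NA where a candidate fit degenerated or was skipped),
#'   `loglik`, `converged` (flag of the selected fit) and the fitted
#'   `model`.
#' @export
fit_gmm_bic <- function(embedding, k_max = 20L, seed = NULL, tol = 1e-6,
                        max_iter = 500L, patience = Inf) {
  X <- if (inherits(embedding, "ase_embedding")) embedding$latent
       else as.matrix(embedding)
  check_scalar(k_max, "k_max", lower = 1, integer = TRUE)
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stopf("need more observations (%d) than dimensions (%d)", n, p)
  init <- ward_init(X)
  k_max <- min(k_max, n - 1L)
  fits <- vector("list", k_max)
  bic <- rep(NA_real_, k_max)
  since_best <- 0L
  for (k in seq_len(k_max)) {
    lab0 <- if (k == 1L) rep(1L, n) else ward_partition(init, X, k)
    fit <- em_gmm(X, lab0, k, tol = tol, max_iter = max_iter)
    if (!is.null(fit)) {
      npar <- (k - 1) + k * p + k * p * (p + 1) / 2
      bic[k] <- 2 * fit$loglik - npar * log(n)
      fits[[k]] <- fit
    }
    if (any(is.finite(bic))) {
      since_best <- k - which.max(bic)
      if (since_best >= patience) break
    }
  }
  if (all(is.na(bic))) stopf("all GMM fits degenerated; check the embedding")
  k_best <- which.max(bic)
  best <- fits[[k_best]]
  labels <- best$labels
  # renumber so labels are 1..k with every label present
  labels <- match(labels, sort(unique(labels)))
  structure(list(labels = labels, k = length(unique(labels)),
                 bic_trace = bic, loglik = best$loglik,
                 converged = best$converged,
                 iterations = best$iterations,
                 model = best[c("weights", "means", "covariances")]),
            class = "gmm_clustering")
}

#' @export
print.gmm_clustering <- function(x, ...) {
  cat(sprintf("GMM clustering: k = %d (BIC-selected of %d), loglik = %.2f%s\n",
              x$k, length(x$bic_trace), x$loglik,
              if (x$converged) "" else " [EM did not converge]"))
  invisible(x)
}

#' Cluster one binary connectome by spectral embedding plus GMM
#'
#' Composition of [ase_embed()] (with automatic profile-likelihood
#' dimension selection unless `d` is pinned) and [fit_gmm_bic()]. This is
#' the per-graph clustering applied to every member of the binary
#' ensemble.
#'
#' @param A Trimmed binary adjacency matrix.
#' @param d Optional embedding-rank override.
#' @param k_max Largest candidate component count for BIC.
#' @param seed Seed for the randomized decomposition on large graphs.
#' @param patience BIC early-stop patience (see [fit_gmm_bic()]).
#' @param ... Passed to [ase_embed()].
#' @return A `gmm_clustering` with attribute `embedding`.
#' @export
cluster_single_graph <- function(A, d = NULL, k_max = 20L, seed = NULL,
                                 patience = Inf, ...) {
  emb <- ase_embed(A, d = d, seed = seed, ...)
  fit <- fit_gmm_bic(emb, k_max = k_max, seed = seed, patience = patience)
  attr(fit, "embedding") <- emb
  fit
}

#' Cluster every graph of a binary ensemble
#'
#' @param ensemble A `binary_ensemble`.
#' @param d,k_max,... Passed to [cluster_single_graph()].
#' @param seed Master seed spawning one substream per graph.
#' @return Object of class `clustering_ensemble`: an `n_total x G` integer
#'   matrix of cluster labels, `NA` where a neuron was trimmed out of a
#'   given graph, with attribute `kappas` (clusters per graph).
#' @export
cluster_ensemble <- function(ensemble, d = NULL, k_max = 20L, seed = NULL,
                             patience = Inf, ...) {
  if (!inherits(ensemble, "binary_ensemble"))
    stopf("`ensemble` must be a `binary_ensemble`")
  n <- attr(ensemble, "n_total")
  G <- length(ensemble)
  seeds <- spawn_seeds(seed, G)
  labels <- matrix(NA_integer_, n, G)
  for (l in seq_len(G)) {
    g <- ensemble[[l]]
    if (!length(g$index)) next
    fit <- cluster_single_graph(g$matrix, d = d, k_max = k_max,
                                seed = seeds[[l]], patience = patience, ...)
    labels[g$index, l] <- fit$labels
  }
  structure(labels, class = "clustering_ensemble",
            kappas = apply(labels, 2L, function(x)
              length(unique(x[!is.na(x)]))))
}
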