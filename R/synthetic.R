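#' Specify a stochastic block model for synthetic connectome generation
#'
#' An SBM is parameterised by a block membership probability vector `rho`
#' (length `kappa`, summing to one) and a `kappa x kappa` block connection
#' probability matrix `P`: a directed edge from a neuron in block `a` to a
#' neuron in block `b` is present independently with probability `P[a, b]`.
#' Present edges additionally carry an integer connection strength drawn
#' from a shifted geometric distribution with mean `strength_mean`,
#' emulating the long-tailed overlap counts of potential connectomes.
#'
#' @param n Number of neurons (`n >= kappa`).
#' @param kappa Number of blocks.
#' @param rho Block membership probabilities; length `kappa`, sums to 1.
#' @param P `kappa x kappa` matrix of block connection probabilities in
#'   `[0, 1]`.
#' @param strength_mean Target mean of nonzero strengths (>= 1). The
#'   default mirrors the mean nonzero strength typical of fly potential
#'   connectomes.
#' @param seed Integer seed used by [simulate_connectome()].
#' @return An object of class `sbm_spec`.
#' @seealso [simulate_connectome()]
#' @export
sbm_spec <- function(n, kappa, rho, P, strength_mean = 7.8, seed = NULL) {
  check_scalar(n, "n", lower = 1, integer = TRUE)
  check_scalar(kappa, "kappa", lower = 1, integer = TRUE)
  if (n < kappa) stopf("`n` (%d) must be at least `kappa` (%d)", n, kappa)
  if (length(rho) != kappa) stopf("`rho` must have length kappa = %d", kappa)
  if (any(rho < 0)) stopf("`rho` must be nonnegative")
  if (abs(sum(rho) - 1) > 1e-12)
    stopf("`rho` must sum to 1 (got %.15f)", sum(rho))
  P <- as.matrix(P)
  if (!all(dim(P) == kappa)) stopf("`P` must be %d x %d", kappa, kappa)
  if (any(P < 0) || any(P > 1)) stopf("`P` entries must lie in [0, 1]")
  check_scalar(strength_mean, "strength_mean", lower = 1)
  if (!is.null(seed)) check_scalar(seed, "seed", integer = TRUE)
  structure(list(n = as.integer(n), kappa = as.integer(kappa),
                 rho = as.numeric(rho), P = P,
                 strength_mean = strength_mean, seed = seed),
            class = "sbm_spec")
}

#' @export
print.sbm_spec <- function(x, ...) {
  cat(sprintf("SBM spec: n = %d, kappa = %d, mean strength = %g\n",
              x$n, x$kappa, x$strength_mean))
  invisible(x)
}

# Sample `m` distinct ordered pairs (i, j), i != j when a == b, from the
# block-pair index space, returning a 2-column matrix of neuron indices.
sample_block_pairs <- function(ia, ib, same_block, m) {
  na <- length(ia); nb <- length(ib)
  if (same_block) {
    npairs <- na * (na - 1)
    idx <- sample.int(npairs, m)
    r <- (idx - 1L) %/% (na - 1L) + 1L
    c0 <- (idx - 1L) %% (na - 1L) + 1L
    c <- ifelse(c0 >= r, c0 + 1L, c0)
    cbind(ia[r], ia[c])
  } else {
    idx <- sample.int(na * nb, m)
    cbind(ia[(idx - 1L) %% na + 1L], ib[(idx - 1L) %/% na + 1L])
  }
}

#' Generate a synthetic weighted SBM connectome
#'
#' Draws block labels from `rho`, places each directed edge `i -> j`
#' independently with probability `P[b(i), b(j)]` (no self-connections),
#' and assigns every present edge a strength `1 + Geometric(1/mu)` so that
#' nonzero strengths have mean `mu = strength_mean` on the positive
#' integers. With `strength_mean = 1` the strength distribution is
#' degenerate at 1.
#'
#' @param spec An [sbm_spec()].
#' @return An object of class `synthetic_connectome`: a list with
#'   `strengths` (a sparse integer-valued `dgCMatrix`), `labels` (true
#'   block of each neuron, in `1..kappa`) and the originating `spec`.
#' @export
simulate_connectome <- function(spec) {
  if (!inherits(spec, "sbm_spec")) stopf("`spec` must be an `sbm_spec`")
  with_seed(spec$seed, {
    n <- spec$n; kappa <- spec$kappa
    labels <- sample.int(kappa, n, replace = TRUE, prob = spec$rho)
    members <- split(seq_len(n), factor(labels, levels = seq_len(kappa)))
    ii <- integer(0); jj <- integer(0)
    for (a in seq_len(kappa)) {
      for (b in seq_len(kappa)) {
        p <- spec$P[a, b]
        if (p == 0) next
        ia <- members[[a]]; ib <- members[[b]]
        npairs <- if (a == b) length(ia) * (length(ia) - 1L)
                  else length(ia) * length(ib)
        if (npairs == 0L) next
        m <- rbinom(1L, npairs, p)
        if (m == 0L) next
        pr <- sample_block_pairs(ia, ib, a == b, m)
        ii <- c(ii, pr[, 1L]); jj <- c(jj, pr[, 2L])
      }
    }
    w <- if (spec$strength_mean == 1) rep(1, length(ii))
         else rgeom(length(ii), prob = 1 / spec$strength_mean) + 1
    strengths <- Matrix::sparseMatrix(i = ii, j = jj, x = as.numeric(w),
                                      dims = c(n, n))
    structure(list(strengths = strengths, labels = labels, spec = spec),
              class = "synthetic_connectome")
  })
}

#' @export
print.synthetic_connectome <- function(x, ...) {
  nnz <- Matrix::nnzero(x$strengths)
  cat(sprintf(
    "Synthetic connectome: %d neurons, %d blocks, %d edges (density %.3f%%)\n",
    x$spec$n, x$spec$kappa, nnz, 100 * nnz / x$spec$n^2))
  invisible(x)
}

#' Generate a categorical biomarker with tunable block association
#'
#' With probability `concordance` a neuron's category is a fixed function
#' of its block (block `k` maps to `categories[((k - 1) %% length) + 1]`);
#' otherwise the category is drawn uniformly at random. `concordance = 1`
#' therefore yields a deterministic block-to-category mapping and
#' `concordance = 0` yields independence.
#'
#' @param true_labels Integer block labels in `1..kappa`.
#' @param concordance Probability in `[0, 1]` of the deterministic mapping.
#' @param categories Nonempty character vector of category names. When
#'   `concordance = 1` there must be at least as many categories as blocks
#'   so that the mapping is injective.
#' @param seed Optional integer seed.
#' @return Character vector of categories, one per neuron.
#' @export
generate_metadata <- function(true_labels, concordance, categories,
                              seed = NULL) {
  check_scalar(concordance, "concordance", lower = 0, upper = 1)
  if (length(categories) == 0L) stopf("`categories` must be nonempty")
  kappa <- max(true_labels)
  if (concordance == 1 && length(categories) < kappa)
    stopf("need at least %d categories for concordance = 1", kappa)
  mapping <- categories[((seq_len(kappa) - 1L) %% length(categories)) + 1L]
  with_seed(seed, {
    n <- length(true_labels)
    use_map <- runif(n) < concordance
    out <- sample(categories, n, replace = TRUE)
    out[use_map] <- mapping[true_labels[use_map]]
    out
  })
}

#' Developmental birthtime levels, embryo (day 0) through day 9
#' @export
birthtime_levels <- function() c("embryo", paste0("day", 1:9))

#' Generate per-neuron developmental birthtimes from block-specific
#' day profiles
#'
#' @param true_labels Integer block labels in `1..kappa`.
#' @param day_profiles `kappa x 10` matrix; row `k` is the probability
#'   distribution of block `k` neurons over
#'   `embryo, day1, ..., day9` (rows sum to 1).
#' @param seed Optional integer seed.
#' @return Factor of birthtimes with levels [birthtime_levels()].
#' @export
generate_birthtimes <- function(true_labels, day_profiles, seed = NULL) {
  day_profiles <- as.matrix(day_profiles)
  kappa <- max(true_labels)
  if (nrow(day_profiles) < kappa || ncol(day_profiles) != 10L)
    stopf("`day_profiles` must be at least %d x 10", kappa)
  if (any(abs(rowSums(day_profiles) - 1) > 1e-8))
    stopf("`day_profiles` rows must sum to 1")
  lv <- birthtime_levels()
  with_seed(seed, {
    out <- vapply(true_labels, function(k) {
      sample.int(10L, 1L, prob = day_profiles[k, ])
    }, integer(1))
    factor(lv[out], levels = lv)
  })
}

#' Generate a complete synthetic dataset: strengths plus metadata table
#'
#' Convenience wrapper bundling [simulate_connectome()],
#' [generate_metadata()] (neurotransmitter and functional community) and
#' [generate_birthtimes()] into the dataset layout expected by
#' [run_pipeline()].
#'
#' @param spec An [sbm_spec()].
#' @param nt_concordance,community_concordance Association strength of the
#'   neurotransmitter and community columns with the true blocks.
#' @param day_profiles Optional `kappa x 10` birthtime profile matrix;
#'   default is a common mildly embryo-weighted profile for all blocks.
#' @return A list of class `synthetic_dataset` with elements `strengths`,
#'   `labels` and `metadata` (data frame with columns `neuron_id`,
#'   `neurotransmitter`, `birthtime`, `community`).
#' @export
simulate_dataset <- function(spec, nt_concordance = 0.3,
                             community_concordance = 0.8,
                             day_profiles = NULL) {
  conn <- simulate_connectome(spec)
  seeds <- spawn_seeds(if (is.null(spec$seed)) NULL else spec$seed + 1L, 3L)
  nts <- c("ACh", "DA", "GABA", "Glu", "OA", "5-HT")
  communities <- paste0("community", seq_len(spec$kappa))
  if (is.null(day_profiles)) {
    prof <- c(0.4, 0.15, 0.1, 0.08, 0.07, 0.06, 0.05, 0.04, 0.03, 0.02)
    day_profiles <- matrix(prof, nrow = spec$kappa, ncol = 10L, byrow = TRUE)
  }
  metadata <- data.frame(
    neuron_id = sprintf("n%05d", seq_len(spec$n)),
    neurotransmitter = generate_metadata(conn$labels, nt_concordance, nts,
                                         seed = seeds[[1]]),
    birthtime = generate_birthtimes(conn$labels, day_profiles,
                                    seed = seeds[[2]]),
    community = generate_metadata(conn$labels, community_concordance,
                                  communities, seed = seeds[[3]]),
    stringsAsFactors = FALSE)
  structure(list(strengths = conn$strengths, labels = conn$labels,
                 metadata = metadata, spec = spec),
            class = "synthetic_dataset")
}
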