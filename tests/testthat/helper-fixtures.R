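# Shared fixtures, all generated in code.

sparse_from_dense <- function(M) {
  methods::as(methods::as(methods::as(Matrix::Matrix(M), "dMatrix"),
                          "generalMatrix"), "CsparseMatrix")
}

# A small planted two-block connectome with clean separation.
toy_spec <- function(n = 400, seed = 42, p_in = 0.25, p_out = 0.02) {
  sbm_spec(n = n, kappa = 2, rho = c(0.5, 0.5),
           P = matrix(c(p_in, p_out, p_out, p_in), 2), seed = seed)
}

# Planted kappa-block spec with uniform membership.
planted_spec <- function(n, kappa, p_in, p_out, seed,
                         strength_mean = 7.8) {
  sbm_spec(n = n, kappa = kappa, rho = rep(1 / kappa, kappa),
           P = matrix(p_out, kappa, kappa) + diag(p_in - p_out, kappa),
           strength_mean = strength_mean, seed = seed)
}

# Binary SBM ensemble drawn directly from a block probability matrix
# (bypasses strengths), plus the matching consensus_partition built from
# the true labels. Used wherever the generating P must be recovered.
planted_binary_ensemble <- function(n, P, G, seed, sizes = NULL) {
  kappa <- nrow(P)
  if (is.null(sizes)) sizes <- rep(n %/% kappa, kappa)
  labels <- rep(seq_len(kappa), sizes)
  probs <- P[labels, labels]
  diag(probs) <- 0
  ens <- sample_binary_ensemble(sparse_from_dense(probs), G, seed = seed)
  part <- size_filter(labels, c_size = 1L)
  list(ensemble = ens, partition = part, labels = labels,
       true_P = P[order(-sizes), order(-sizes)])
}

# Random walkable circuit: directed edges present with prob `density`,
# weights uniform, every node guaranteed one incident edge.
random_circuit <- function(kappa, seed, density = 0.6) {
  set.seed(seed)
  repeat {
    p <- matrix(0, kappa, kappa)
    on <- matrix(runif(kappa^2) < density, kappa, kappa)
    diag(on) <- FALSE
    p[on] <- runif(sum(on), 0.05, 1)
    if (all(rowSums(p > 0) + colSums(p > 0) > 0)) break
  }
  list(p = p, class_sizes = sample(1:5, kappa, replace = TRUE), kappa = kappa)
}

# Circuit built from explicit edges; sizes default to 1 so step costs are
# simply 1 / p.
edge_circuit <- function(kappa, edges, sizes = rep(1L, kappa)) {
  p <- matrix(0, kappa, kappa)
  for (e in edges) p[e[[1]], e[[2]]] <- e[[3]]
  list(p = p, class_sizes = sizes, kappa = kappa)
}

# Independent oracle for absorption: igraph simple-path enumeration.
igraph_absorption <- function(circuit, s, t) {
  wc <- walk_circuit(circuit)
  fin <- which(is.finite(wc$cost), arr.ind = TRUE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = fin[, 1], to = fin[, 2]), directed = TRUE,
    vertices = data.frame(name = seq_len(wc$kappa)))
  paths <- igraph::all_simple_paths(g, from = as.character(s),
                                    to = as.character(t), mode = "out")
  if (!length(paths)) return(list(absorption = NA_real_, n_paths = 0L))
  costs <- vapply(paths, function(pth) {
    v <- as.integer(igraph::as_ids(pth))
    sum(wc$cost[cbind(v[-length(v)], v[-1])])
  }, numeric(1))
  list(absorption = mean(costs), n_paths = length(costs), costs = costs)
}

# Independent profile-likelihood oracle for dimension selection.
zg_oracle <- function(values, floor = 1e-12) {
  v <- sort(values, decreasing = TRUE)
  ll <- vapply(seq_len(length(v) - 1L), function(q) {
    g1 <- v[1:q]; g2 <- v[-(1:q)]
    s2 <- max((sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2)) / length(v),
              floor)
    sum(dnorm(g1, mean(g1), sqrt(s2), log = TRUE)) +
      sum(dnorm(g2, mean(g2), sqrt(s2), log = TRUE))
  }, numeric(1))
  which.max(ll)
}
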