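test_that("weighted degree follows the size-weighted probability sums", {
  circ <- edge_circuit(3, list(list(1, 2, 0.3), list(2, 1, 0.1),
                               list(2, 3, 0.2), list(3, 1, 0.4)),
                       sizes = c(100L, 10L, 1L))
  wd <- weighted_degree(circ)
  expect_equal(wd[1], (0.3 + 0.1 + 0.4) * 100)
  expect_equal(wd[2], (0.1 + 0.2 + 0.3) * 10)
  # class with in+out sum 0.4 and 100 neurons -> 40
  c2 <- edge_circuit(2, list(list(1, 2, 0.4)), sizes = c(100L, 100L))
  expect_equal(weighted_degree(c2), c(40, 40))
  # doubling size doubles the degree
  c3 <- c2; c3$class_sizes <- c(200L, 100L)
  expect_equal(weighted_degree(c3)[1], 80)
})

test_that("betweenness matches hand enumeration on line, star, complete", {
  line <- edge_circuit(3, list(list(1, 2, 0.5), list(2, 3, 0.5)))
  b <- betweenness_unweighted(line)
  expect_equal(unname(b), c(0, 1 / 2, 0))   # 1 of (k-1)(k-2)=2 pair paths

  full <- edge_circuit(3, lapply(1:6, function(i) {
    e <- rbind(c(1, 2), c(2, 1), c(1, 3), c(3, 1), c(2, 3), c(3, 2))[i, ]
    list(e[1], e[2], 0.5)
  }))
  expect_equal(unname(betweenness_unweighted(full)), c(0, 0, 0))

  star <- edge_circuit(4, list(list(2, 1, 0.5), list(1, 2, 0.5),
                               list(3, 1, 0.5), list(1, 3, 0.5),
                               list(4, 1, 0.5), list(1, 4, 0.5)))
  bs <- betweenness_unweighted(star)
  expect_equal(unname(bs), c(1, 0, 0, 0))   # center carries all 6 leaf pairs
  expect_error(betweenness_unweighted(edge_circuit(2, list(list(1, 2, 1)))),
               "at least 3")
})

test_that("hub identification requires both measures to be high", {
  # class 1 wired to everyone with high probability dominates both
  edges <- list()
  for (j in 2:5) edges <- c(edges, list(list(1, j, 0.9), list(j, 1, 0.9)))
  edges <- c(edges, list(list(2, 3, 0.05)))
  hub <- edge_circuit(5, edges, sizes = c(50L, rep(10L, 4)))
  rep_ <- hub_report(hub, quantile = 0.75)
  expect_equal(rep_$hubs, 1L)

  # anti-correlated measures can leave the hub set empty
  wd <- c(10, 1, 1); btw <- c(0, 0.5, 0.4)
  expect_length(identify_hubs(wd, btw, 0.5), 0)
})

test_that("relabeling classes permutes degree and betweenness", {
  circ <- random_circuit(5, seed = 3)
  perm <- c(3, 1, 4, 5, 2)
  circ2 <- list(p = circ$p[perm, perm], class_sizes = circ$class_sizes[perm],
                kappa = 5L)
  expect_equal(weighted_degree(circ2), weighted_degree(circ)[perm])
  expect_equal(unname(betweenness_unweighted(circ2)),
               unname(betweenness_unweighted(circ))[perm])
})

test_that("binomial fit fraction is ~1 on exact SBM data, lower when mixed", {
  P <- rbind(c(0.3, 0.08), c(0.05, 0.25))
  pl <- planted_binary_ensemble(200, P, G = 10, seed = 61)
  fit <- binomial_fit_fraction(pl$partition, pl$ensemble)
  expect_true(all(fit$fraction > 0.89))
  expect_false(any(fit$degenerate))

  # deterministic all-or-nothing data: zero variance, fraction 1, flagged
  n <- 40L
  full <- matrix(1, n, n) - diag(n)
  ens <- structure(list(list(matrix = sparse_from_dense(full), index = 1:n,
                             seed = NA)),
                   class = "binary_ensemble", n_total = n, degenerate = FALSE)
  part <- size_filter(rep(1:2, each = n / 2), c_size = 1L)
  f2 <- binomial_fit_fraction(part, ens)
  expect_true(all(f2$fraction[!f2$degenerate] == 1))

  # overdispersed mixture of two edge rates breaks the binomial fit
  set.seed(62)
  nA <- 200L
  rate <- rep(c(0.05, 0.55), each = nA / 2)     # mean 0.3 as above
  probs <- matrix(rate, nA, nA)                 # row-wise neuron rate
  diag(probs) <- 0
  ensM <- sample_binary_ensemble(sparse_from_dense(probs), 10, seed = 63)
  partM <- size_filter(rep(1L, nA), c_size = 1L)
  fM <- binomial_fit_fraction(partM, ensM)
  expect_lt(fM$fraction[1, 1], min(fit$fraction))
})

test_that("histogram intersection obeys its identities", {
  set.seed(70)
  x <- rnorm(500)
  expect_equal(histogram_intersection(x, x), 1)
  expect_equal(histogram_intersection(1:100, 201:300), 0)
  u1 <- runif(20000, 0, 1); u2 <- runif(20000, 0.5, 1.5)
  bins <- seq(0, 1.5, by = 0.05)
  expect_equal(histogram_intersection(u1, u2, bins), 0.5, tolerance = 0.03)
  # symmetry and bounds
  a <- rpois(300, 4); b <- rpois(300, 7)
  expect_equal(histogram_intersection(a, b), histogram_intersection(b, a))
  expect_gte(histogram_intersection(a, b), 0)
  expect_lte(histogram_intersection(a, b), 1)
  expect_error(histogram_intersection(numeric(0), 1:3), "nonempty")
})

test_that("connectome summary matches closed forms", {
  M <- matrix(0, 3, 3); M[1, 2] <- 2; M[2, 3] <- 4
  s <- connectome_summary(sparse_from_dense(M))
  expect_equal(s$sparsity, 2 / 9)
  expect_equal(s$avg_strength, 3)
  expect_equal(s$avg_degree, 2 * 2 / 3)

  n <- 5
  K <- matrix(1, n, n) - diag(n)
  sk <- connectome_summary(sparse_from_dense(K))
  expect_equal(sk$sparsity, (n^2 - n) / n^2)
  expect_equal(sk$avg_degree, 2 * (n - 1))

  s0 <- connectome_summary(sparse_from_dense(matrix(0, 3, 3)))
  expect_equal(s0$sparsity, 0)
  expect_true(is.na(s0$avg_strength))

  ens <- sample_binary_ensemble(sparse_from_dense(
    matrix(0.5, 4, 4) - diag(0.5, 4)), 5, seed = 8)
  se <- connectome_summary(ens)
  expect_named(se$sparsity, c("mean", "sd"))
})

test_that("subsample robustness reruns the pipeline and reports ARI", {
  spec <- planted_spec(300, 3, p_in = 0.35, p_out = 0.04, seed = 80)
  ds <- simulate_connectome(spec)
  cfg <- pipeline_config(p_conn = 0.15, G = 3, tau = 0.95, c_size = 5,
                         k_max = 5, patience = 2, seed = 81)
  rob <- subsample_robustness(ds$strengths, c(1, 0.9), cfg, seed = 82)
  expect_equal(dim(rob$ari), c(2, 2))
  expect_equal(rob$ari[1, 1], 1)            # same run vs itself
  expect_gte(rob$ari[1, 2], 0.9)            # clean SBM is robust at 90%
  expect_true(all(rob$pct_both <= 100, na.rm = TRUE))

  expect_error(subsample_robustness(ds$strengths, 0.05, cfg, seed = 1),
               "too small")
})
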