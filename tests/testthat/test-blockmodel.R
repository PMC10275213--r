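# A tiny hand-built ensemble: 4 neurons, classes {1,2} and {3,4}, one
# graph with 2 of the 4 possible class-1 -> class-2 edges present.
hand_ensemble <- function() {
  A <- sparse_from_dense(rbind(c(0, 1, 1, 0),
                               c(1, 0, 0, 1),
                               c(1, 0, 0, 1),
                               c(0, 1, 1, 0)))
  graphs <- list(list(matrix = A, index = 1:4, seed = NA))
  ens <- structure(graphs, class = "binary_ensemble", n_total = 4L,
                   degenerate = FALSE)
  part <- size_filter(c(1L, 1L, 2L, 2L), c_size = 1L)
  list(ens = ens, part = part)
}

test_that("block probabilities match the hand-computed proportions", {
  h <- hand_ensemble()
  bp <- estimate_block_probabilities(h$part, h$ens)
  # 2 of 4 ordered cross pairs in each direction; within-class: both
  # ordered self-pair-free pairs connected
  expect_equal(bp$p_hat, rbind(c(1, 0.5), c(0.5, 1)), ignore_attr = TRUE)
  expect_true(all(bp$p_hat >= 0 & bp$p_hat <= 1))
})

test_that("no edges between classes gives exactly zero", {
  A <- sparse_from_dense(rbind(c(0, 1, 0, 0),
                               c(1, 0, 0, 0),
                               c(0, 0, 0, 1),
                               c(0, 0, 1, 0)))
  ens <- structure(list(list(matrix = A, index = 1:4, seed = NA)),
                   class = "binary_ensemble", n_total = 4L,
                   degenerate = FALSE)
  part <- size_filter(c(1L, 1L, 2L, 2L), c_size = 1L)
  bp <- estimate_block_probabilities(part, ens)
  expect_equal(bp$p_hat[1, 2], 0)
  expect_equal(bp$p_hat[2, 1], 0)
})

test_that("planted block probabilities are recovered within 3 SE", {
  P <- rbind(c(0.30, 0.05, 0.10),
             c(0.02, 0.25, 0.08),
             c(0.12, 0.04, 0.20))
  pl <- planted_binary_ensemble(600, P, G = 20, seed = 44)
  bp <- estimate_block_probabilities(pl$partition, pl$ensemble)
  sizes <- pl$partition$class_sizes
  # class labels were renumbered by size; sizes equal here so order kept
  for (i in 1:3) for (j in 1:3) {
    npairs <- if (i == j) sizes[i] * (sizes[i] - 1) else sizes[i] * sizes[j]
    se <- sqrt(P[i, j] * (1 - P[i, j]) / (20 * npairs))
    expect_lt(abs(bp$p_hat[i, j] - P[i, j]), 3 * se + 1e-3)
  }
})

test_that("flooring removes the stray edge and records the threshold", {
  p <- matrix(0, 3, 3)
  p[1, 2] <- 0.5; p[2, 3] <- 0.5; p[1, 3] <- 0.001
  P_hat <- structure(list(p_hat = p, class_sizes = c(10L, 10L, 10L),
                          kappa = 3L, restricted = FALSE),
                     class = "block_probability")
  circ <- floor_to_circuit(P_hat)
  expect_equal(circ$floor_threshold, 0.001)
  expect_equal(nrow(circ$edges), 2)
  expect_true(all(circ$p[1, 2] == 0.5, circ$p[2, 3] == 0.5, circ$p[1, 3] == 0))
  # rebuilding with the returned threshold reproduces the edge set
  expect_identical(circ$p > 0, p > circ$floor_threshold)
})

test_that("coverage protects single-edge classes; uniform weights stay", {
  p <- matrix(0, 3, 3)
  p[1, 2] <- 0.9; p[2, 3] <- 0.8; p[3, 1] <- 1e-6
  P_hat <- structure(list(p_hat = p, class_sizes = rep(5L, 3), kappa = 3L,
                          restricted = FALSE), class = "block_probability")
  # removing 1e-6 keeps class 3 covered via 2->3; removing 0.8 as well
  # would isolate class 3, so the threshold stops at 1e-6
  circ <- floor_to_circuit(P_hat)
  expect_equal(circ$floor_threshold, 1e-6)
  expect_equal(nrow(circ$edges), 2)

  u <- matrix(0, 3, 3)
  u[1, 2] <- u[2, 3] <- u[3, 1] <- 0.4
  U_hat <- structure(list(p_hat = u, class_sizes = rep(5L, 3), kappa = 3L,
                          restricted = FALSE), class = "block_probability")
  uc <- floor_to_circuit(U_hat)
  expect_equal(uc$floor_threshold, 0)        # removing the common weight
  expect_equal(nrow(uc$edges), 3)            # would empty the circuit
  expect_true(all(rowSums(uc$p > 0) + colSums(uc$p > 0) > 0))
})

test_that("restriction to the full mask is the identity", {
  pl <- planted_binary_ensemble(120, rbind(c(0.4, 0.1), c(0.05, 0.3)),
                                G = 3, seed = 9)
  full <- estimate_block_probabilities(pl$partition, pl$ensemble)
  masked <- restricted_block_probabilities(pl$partition, pl$ensemble,
                                           rep(TRUE, 120))
  expect_equal(masked$p_hat, full$p_hat)
})

test_that("masking one class out zeroes its row and column", {
  pl <- planted_binary_ensemble(120, rbind(c(0.4, 0.1), c(0.05, 0.3)),
                                G = 3, seed = 10)
  mask <- pl$partition$labels != 2
  bp <- restricted_block_probabilities(pl$partition, pl$ensemble, mask)
  expect_true(all(bp$p_hat[2, ] == 0))
  expect_true(all(bp$p_hat[, 2] == 0))
  expect_warning(
    restricted_block_probabilities(pl$partition, pl$ensemble,
                                   rep(FALSE, 120)), "no classified")
})

test_that("restricted estimates recover a planted subpopulation", {
  # population A neurons (first half of each class) carry cross-block
  # edges with probability 0.3; population B carries none
  n <- 400L
  labels <- rep(1:2, each = n / 2)
  popA <- rep(c(TRUE, FALSE), times = c(n / 4, n / 4))[
    c(seq_len(n / 2), seq_len(n / 2))]
  probs <- matrix(0, n, n)
  across <- outer(labels, labels, "!=") & outer(popA, popA, "&")
  probs[across] <- 0.3
  within <- outer(labels, labels, "==")
  probs[within] <- 0.1
  diag(probs) <- 0
  ens <- sample_binary_ensemble(sparse_from_dense(probs), 5, seed = 12)
  part <- size_filter(labels, c_size = 1L)
  bp <- restricted_block_probabilities(part, ens, popA)
  npairs <- (n / 4)^2 * 5
  se <- sqrt(0.3 * 0.7 / npairs)
  expect_lt(abs(bp$p_hat[1, 2] - 0.3), 3 * se)
  expect_lt(abs(bp$p_hat[2, 1] - 0.3), 3 * se)
})

test_that("top-fraction filtering keeps heavy edges and ties", {
  p <- matrix(0, 4, 4)
  w <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10) / 10
  p[cbind(c(1, 1, 1, 2, 2, 3, 3, 4, 4, 2),
          c(2, 3, 4, 1, 3, 1, 4, 2, 3, 4))] <- w
  circ <- structure(list(p = p, class_sizes = rep(1L, 4), kappa = 4L,
                         floor_threshold = 0,
                         edges = data.frame(from = 1, to = 2, p = w)),
                    class = "circuit")
  circ$edges <- mesocircuit:::circuit_edges(p)
  kept <- top_fraction_edges(circ, 0.2)
  expect_equal(nrow(kept$edges), 2)
  expect_equal(sort(kept$edges$p), c(0.9, 1.0))
  expect_equal(top_fraction_edges(circ, 1)$p, circ$p)

  # ties straddling the cutoff are all kept
  p2 <- matrix(0, 3, 3)
  p2[1, 2] <- p2[2, 3] <- p2[3, 1] <- 0.5
  c2 <- structure(list(p = p2, class_sizes = rep(1L, 3), kappa = 3L,
                       floor_threshold = 0,
                       edges = mesocircuit:::circuit_edges(p2)),
                  class = "circuit")
  expect_equal(nrow(top_fraction_edges(c2, 1 / 3)$edges), 3)
})
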