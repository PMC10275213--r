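# Triangle toy: direct edge s(1) -> t(3) of cost 3, and a detour via
# a(2) with two cost-1 steps. Unit class sizes make cost = 1/p.
triangle <- function() {
  edge_circuit(3, list(list(1, 3, 1 / 3), list(1, 2, 1), list(2, 3, 1)))
}

test_that("step costs follow 1 / (P * scaled sizes)", {
  c1 <- edge_circuit(2, list(list(1, 2, 1)))
  expect_equal(step_cost(c1, 1, 2), 1)
  c2 <- edge_circuit(2, list(list(1, 2, 0.5)), sizes = c(2L, 1L))
  expect_equal(step_cost(c2, 1, 2), 1 / (0.5 * 2 * 1))
  expect_identical(step_cost(c2, 2, 1), Inf)       # absent edge
  wc <- walk_circuit(c2)
  expect_equal(min(wc$scaled_sizes), 1)
})

test_that("enumeration reproduces the triangle by hand", {
  r <- enumerate_absorption(triangle(), 1, 3)
  expect_equal(r$n_paths, 2L)
  expect_equal(r$absorption, 2.5)                   # paths cost 3 and 2
  expect_equal(shortest_path_cost(triangle(), 1, 3), 2)
  expect_equal(shortest_path_cost(triangle(), 1, 1), 0)

  # single-edge circuit: one path, absorption = its cost
  single <- edge_circuit(2, list(list(1, 2, 0.25)))
  r1 <- enumerate_absorption(single, 1, 2)
  expect_equal(r1$absorption, 4)
  expect_equal(r1$n_paths, 1L)

  # unreachable target is flagged
  r0 <- enumerate_absorption(edge_circuit(2, list(list(2, 1, 1))), 1, 2)
  expect_false(r0$defined)
})

test_that("the target is terminal: edges out of t are irrelevant", {
  tri <- triangle()
  tri$p[3, 1] <- 0.9                               # add t -> s
  r <- enumerate_absorption(tri, 1, 3)
  expect_equal(r$absorption, 2.5)
  expect_equal(r$n_paths, 2L)
})

test_that("enumeration agrees with the igraph oracle on random circuits", {
  for (seed in 1:10) {
    circ <- random_circuit(sample(3:6, 1), seed = seed)
    s <- 1; t <- circ$kappa
    mine <- enumerate_absorption(circ, s, t)
    oracle <- igraph_absorption(circ, s, t)
    expect_equal(mine$n_paths, oracle$n_paths)
    if (oracle$n_paths > 0)
      expect_equal(mine$absorption, oracle$absorption, tolerance = 1e-12)
    else expect_false(mine$defined)
  }
})

test_that("weighted sampling converges to the enumerated mean", {
  r_exact <- enumerate_absorption(triangle(), 1, 3)
  r_mc <- sample_absorption(triangle(), 1, 3, m = 1e5, seed = 7)
  expect_lt(abs(r_mc$absorption - r_exact$absorption),
            max(3 * r_mc$se, 0.02 * r_exact$absorption))

  # single-path circuits are exact for any m
  single <- edge_circuit(2, list(list(1, 2, 0.5)))
  expect_equal(sample_absorption(single, 1, 2, m = 10, seed = 1)$absorption,
               2)

  # determinism under a fixed seed
  a <- sample_absorption(triangle(), 1, 3, m = 500, seed = 5)
  b <- sample_absorption(triangle(), 1, 3, m = 500, seed = 5)
  expect_identical(a$absorption, b$absorption)

  # a circuit where path sampling probabilities are unequal: direct
  # 1->4 (cost 3, prob 1/2), 1->2->4 (cost 2, prob 1/4), 1->2->3->4
  # (cost 3, prob 1/4). Uniform-over-paths mean = 8/3; the naive
  # estimator targets 2.75 instead, the weighted one corrects it.
  skew <- edge_circuit(4, list(list(1, 4, 1 / 3), list(1, 2, 1),
                               list(2, 4, 1), list(2, 3, 1),
                               list(3, 4, 1)))
  expect_equal(enumerate_absorption(skew, 1, 4)$absorption, 8 / 3)
  w <- sample_absorption(skew, 1, 4, m = 1e5, seed = 9)
  expect_lt(abs(w$absorption - 8 / 3), 3 * w$se + 1e-9)
  naive <- sample_absorption(skew, 1, 4, m = 1e5, seed = 9,
                             weighted = FALSE)
  expect_gt(naive$absorption, 2.72)          # biased toward 2.75
})

test_that("walk_stats assembles matrices, averages and driftiness", {
  ws <- walk_stats(triangle(), seed = 1)
  expect_equal(ws$absorption[1, 3], 2.5)
  expect_equal(ws$shortest[1, 3], 2)
  expect_equal(ws$driftiness[1, 3], 1.25)
  expect_equal(diag(ws$absorption), rep(0, 3))
  expect_true(all(is.na(diag(ws$driftiness))))

  # kappa = 2 with single edges each way: unique paths, D = 1
  two <- edge_circuit(2, list(list(1, 2, 0.5), list(2, 1, 0.25)))
  ws2 <- walk_stats(two)
  expect_equal(ws2$driftiness[1, 2], 1)
  expect_equal(ws2$driftiness[2, 1], 1)
  expect_equal(ws2$A_o[1], ws2$absorption[1, 2])
  expect_error(walk_stats(edge_circuit(1, list())), "at least 2")
})

test_that("driftiness >= 1 wherever defined (100 random circuits)", {
  for (seed in 1:100) {
    circ <- random_circuit(sample(3:7, 1), seed = 1000 + seed)
    ws <- walk_stats(circ)
    d <- ws$driftiness[!is.na(ws$driftiness)]
    expect_true(all(d >= 1 - 1e-9))
  }
})

test_that("uniform cost scaling scales A and delta, leaves D invariant", {
  wc <- walk_circuit(random_circuit(5, seed = 77))
  lambda <- 3.7
  wc2 <- wc
  wc2$cost <- wc$cost * lambda
  s1 <- walk_stats(wc); s2 <- walk_stats(wc2)
  expect_equal(s2$absorption, s1$absorption * lambda)
  expect_equal(s2$shortest, s1$shortest * lambda)
  expect_equal(s2$driftiness, s1$driftiness)
})

test_that("removing an edge never decreases shortest-path costs", {
  circ <- random_circuit(6, seed = 55, density = 0.8)
  wc <- walk_circuit(circ)
  base <- walk_stats(wc)$shortest
  edges <- which(is.finite(wc$cost), arr.ind = TRUE)
  e <- edges[1, ]
  wc2 <- wc
  wc2$cost[e[1], e[2]] <- Inf
  after <- walk_stats(wc2)$shortest
  expect_true(all(after - base >= -1e-12))
})

test_that("percentile flags pick out the planted bottleneck pair", {
  # pair (1, 4): cheap direct edge is the shortest path, the two detours
  # are 200x more expensive; every other pair has a unique path
  circ <- edge_circuit(4, list(list(1, 4, 1),
                               list(1, 2, 0.01), list(2, 4, 0.01),
                               list(1, 3, 0.01), list(3, 4, 0.01)))
  ws <- walk_stats(circ)
  fl <- percentile_flags(ws, low_pct = 20, high_pct = 10)
  idx <- which(ws$driftiness == max(ws$driftiness, na.rm = TRUE),
               arr.ind = TRUE)
  expect_equal(unname(idx[1, ]), c(1, 4))
  expect_true(fl$critical_link[1, 4])
  expect_lte(sum(fl$critical_link, na.rm = TRUE),
             ceiling(0.1 * sum(!is.na(ws$driftiness))) )

  # class flags: the symmetric detour classes 2 and 3 tie for lowest
  # in-absorption, and ties share rank
  expect_true(all(which(fl$accessible) %in% c(2, 3)))
})
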