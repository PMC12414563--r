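test_that("complete uniform digraphs have GE = LE = w", {
  for (w in c(0.2, 1.5)) {
    for (n in c(3, 5)) {
      A <- matrix(w, n, n)
      diag(A) <- 0
      expect_equal(global_efficiency(A), w, tolerance = 1e-12)
      expect_equal(local_efficiency(A), w, tolerance = 1e-12)
    }
  }
})

test_that("edgeless and star graphs hit the degenerate closed forms", {
  Z <- matrix(0, 4, 4)
  expect_equal(global_efficiency(Z), 0)
  expect_equal(local_efficiency(Z), 0)
  # star digraph hub <-> leaves: leaves have 1 neighbour, the hub's
  # neighbours share no edges
  S <- matrix(0, 4, 4)
  S[1, 2:4] <- 0.8
  S[2:4, 1] <- 0.4
  expect_equal(local_efficiency(S), 0)
  expect_gt(global_efficiency(S), 0)
})

test_that("efficiencies equal the exhaustive path-enumeration oracle", {
  set.seed(41)
  for (rep in 1:50) {
    n <- sample(6:8, 1)
    A <- random_digraph(n, p_edge = stats::runif(1, 0.2, 0.6))
    expect_equal(global_efficiency(A), brute_global_efficiency(A),
                 tolerance = 1e-12)
    expect_equal(local_efficiency(A), brute_local_efficiency(A),
                 tolerance = 1e-12)
  }
})

test_that("efficiencies scale linearly with the weights", {
  set.seed(42)
  A <- random_digraph(7, 0.5)
  for (c in c(0.1, 3)) {
    expect_equal(global_efficiency(c * A), c * global_efficiency(A),
                 tolerance = 1e-12)
    expect_equal(local_efficiency(c * A), c * local_efficiency(A),
                 tolerance = 1e-12)
  }
})

test_that("adding an edge never decreases global efficiency", {
  set.seed(43)
  for (rep in 1:10) {
    A <- random_digraph(6, 0.3)
    ge0 <- global_efficiency(A)
    empty <- which(A == 0 & row(A) != col(A))
    pick <- sample(empty, 1)
    A[pick] <- stats::runif(1, 0.1, 2)
    expect_gte(global_efficiency(A), ge0 - 1e-14)
  }
})

test_that("adjacency validation rejects malformed inputs", {
  A <- matrix(0.5, 3, 3); diag(A) <- 0
  B <- A; B[1, 2] <- -0.1
  expect_error(global_efficiency(B), "negative")
  D <- A; diag(D) <- 1
  expect_error(local_efficiency(D), "diagonal")
})

test_that("degree centralities are row/column sums with matched totals", {
  A <- matrix(0, 2, 2)
  A[1, 2] <- 0.7
  ct <- degree_centralities(A)
  expect_equal(unname(ct$outdegree), c(0.7, 0))
  expect_equal(unname(ct$indegree), c(0, 0.7))
  # printed-style 4-node fixture checked against direct summation
  W <- matrix(c(0, 0.012, 0, 0.031,
                0.008, 0, 0.022, 0,
                0, 0.017, 0, 0.009,
                0.005, 0, 0.014, 0), 4, 4, byrow = TRUE)
  ct2 <- degree_centralities(W)
  expect_equal(unname(ct2$outdegree), c(0.043, 0.030, 0.026, 0.019))
  expect_equal(unname(ct2$indegree), c(0.013, 0.029, 0.036, 0.040))
  expect_equal(sum(ct2$outdegree), sum(ct2$indegree))
  expect_equal(sum(ct2$outdegree), sum(W))
})

test_that("node significance flags only truly separated nodes", {
  set.seed(44)
  n <- 25; nodes <- 12
  low <- lapply(1:n, function(s) stats::setNames(rnorm(nodes), letters[1:nodes]))
  high <- lapply(1:n, function(s) {
    v <- stats::setNames(rnorm(nodes), letters[1:nodes])
    v["c"] <- v["c"] - 3  # 3 SD separation at node c
    v
  })
  ns <- node_significance(low, high, metric = "outdegree",
                          n_perm = 2000, seed = 4)
  expect_true("c" %in% ns$significant_nodes)
  expect_lt(length(ns$significant_nodes), 3)
  # Bonferroni monotonicity: corrected set within uncorrected set
  uncorrected <- names(ns$p_raw)[ns$p_raw < ns$alpha]
  expect_true(all(ns$significant_nodes %in% uncorrected))
  # identical groups: nothing significant
  ns0 <- node_significance(low, low, metric = "outdegree",
                           n_perm = 500, seed = 5)
  expect_length(ns0$significant_nodes, 0)
})

test_that("nodewise type-I error calibrates under the null", {
  set.seed(45)
  rates <- vapply(1:20, function(s) {
    low <- lapply(1:20, function(k) rnorm(30))
    high <- lapply(1:20, function(k) rnorm(30))
    ns <- node_significance(low, high, n_perm = 1000, seed = s)
    mean(ns$p_raw < 0.05)  # uncorrected rate against nominal alpha
  }, numeric(1))
  expect_gt(mean(rates), 0.03)
  expect_lt(mean(rates), 0.07)
})
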