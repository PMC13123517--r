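test_that("basis identity maps variation to correlation as expected", {
  # T built from unit basis variances: t = 2 - 2r, so t = 2 -> r = 0.
  # With every off-diagonal at 2 the system solution is exactly w^2 = 1.
  T0 <- matrix(2, 6, 6); diag(T0) <- 0
  out0 <- sparcc_basis_correlation(T0)
  expect_equal(out0$omega2, rep(1, 6), tolerance = 1e-9)
  expect_true(all(abs(out0$r[upper.tri(out0$r)]) < 1e-9))
  # planting t = 0 (r = 1) and t = 4 (r = -1) pairs: the exclusion loop
  # removes them from the variance system, restoring w^2 = 1, and the
  # pairwise identity maps them to +/-1
  Tv <- T0
  Tv[1, 2] <- Tv[2, 1] <- 0
  Tv[3, 4] <- Tv[4, 3] <- 4
  out <- sparcc_basis_correlation(Tv, exclusion_threshold = 0.1)
  expect_equal(out$omega2, rep(1, 6), tolerance = 1e-9)
  expect_equal(out$r[1, 2], 1, tolerance = 1e-9)
  expect_equal(out$r[3, 4], -1, tolerance = 1e-9)
  expect_equal(out$r[1, 5], 0, tolerance = 1e-9)
})

test_that("basis solve matches the dense oracle on random instances", {
  set.seed(101)
  for (i in 1:10) {
    logf <- matrix(rnorm(60 * 6), 60, 6)
    Tv <- sagnet:::.sparcc_variation_cpp(logf)
    out <- sparcc_basis_correlation(Tv, exclusion_threshold = Inf)
    expect_equal(out$r, sparcc_dense_oracle(Tv), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("estimates are reproducible and structurally valid", {
  set.seed(5)
  counts <- matrix(rpois(15 * 8, 60), 15, 8,
                   dimnames = list(NULL, paste0("t", 1:8)))
  e1 <- sparcc_infer(counts, n_permutations = 49, seed = 9)
  e2 <- sparcc_infer(counts, n_permutations = 49, seed = 9)
  expect_identical(e1$r, e2$r)
  expect_identical(e1$p, e2$p)
  expect_true(isSymmetric(e1$r))
  expect_true(all(abs(e1$r) <= 1))
  expect_equal(unname(diag(e1$r)), rep(1, 8))
  expect_true(all(e1$p >= 0 & e1$p <= 1))
  expect_true(isSymmetric(e1$variation))
  expect_equal(unname(diag(e1$variation)), rep(0, 8))
})

test_that("all-zero taxa are dropped and small tables rejected", {
  counts <- cbind(matrix(rpois(40, 30), 10, 4), 0)
  colnames(counts) <- paste0("t", 1:5)
  expect_message(est <- sparcc_infer(counts, n_permutations = 0, seed = 1),
                 "all-zero")
  expect_equal(est$taxa, paste0("t", 1:4))
  expect_error(
    suppressMessages(sparcc_infer(counts[, c(1:3, 5)], n_permutations = 0)),
    class = "sagnet_input_error")
  expect_error(sparcc_infer(counts[1:2, 1:4], n_permutations = 0),
               class = "sagnet_input_error")
})

test_that("independent taxa yield no strong correlations", {
  set.seed(303)
  basis <- matrix(exp(rnorm(50 * 20, 0, 1)), 50, 20)
  frac <- basis / rowSums(basis)
  counts <- t(apply(frac, 1, function(f) rmultinom(1, 1e5, f)[, 1]))
  colnames(counts) <- paste0("t", 1:20)
  est <- sparcc_infer(counts, n_permutations = 0, seed = 7)
  offdiag <- est$r[upper.tri(est$r)]
  # estimates stay within correlation sampling noise at 50 samples:
  # no systematic compositional bias and nothing near the edge threshold
  expect_lt(mean(abs(offdiag)), 0.12)
  expect_lt(max(abs(offdiag)), 0.5)
  expect_lt(abs(mean(offdiag)), 0.06)
})

test_that("network thresholding follows the |r| and p rules", {
  taxa <- paste0("t", 1:4)
  r <- diag(4); p <- matrix(1, 4, 4); diag(p) <- 0
  dimnames(r) <- dimnames(p) <- list(taxa, taxa)
  r[1, 2] <- r[2, 1] <- 0.7;  p[1, 2] <- p[2, 1] <- 0.01  # edge
  r[1, 3] <- r[3, 1] <- 0.7;  p[1, 3] <- p[3, 1] <- 0.2   # p too high
  r[2, 3] <- r[3, 2] <- 0.5;  p[2, 3] <- p[3, 2] <- 0.001 # |r| too low
  r[2, 4] <- r[4, 2] <- -0.65; p[2, 4] <- p[4, 2] <- 0.01 # negative edge
  net <- build_network(list(r = r, p = p))
  keys <- network_edge_keys(net)
  expect_setequal(keys, c("t1|t2", "t2|t4"))
  expect_equal(sort(igraph::E(net)$r), c(-0.65, 0.7))
  # boundary values are exclusive
  r[1, 2] <- r[2, 1] <- 0.6; p[2, 4] <- p[4, 2] <- 0.05
  expect_equal(igraph::ecount(build_network(list(r = r, p = p))), 0)
})

test_that("metrics handle empty and complete graphs", {
  empty <- build_network(list(r = diag(3), p = matrix(1, 3, 3)))
  met0 <- partition_and_metrics(empty)
  expect_equal(met0$n_nodes, 0)
  expect_equal(met0$density, 0)
  expect_equal(met0$n_modules, 0L)
  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- paste0("t", 1:4)
  igraph::E(k4)$weight <- 1
  expect_equal(partition_and_metrics(k4)$density, 1)
})

test_that("two disjoint triangles partition into themselves with Q = 0.5", {
  g <- igraph::make_full_graph(3) + igraph::make_full_graph(3)
  igraph::V(g)$name <- paste0("t", 1:6)
  igraph::E(g)$weight <- 1
  met <- partition_and_metrics(g)
  expect_equal(met$n_modules, 2L)
  expect_equal(sort(met$module_sizes), c(3L, 3L))
  expect_equal(met$modularity, 0.5, tolerance = 1e-12)
  expect_equal(length(unique(met$membership[paste0("t", 1:3)])), 1L)
})

test_that("density and modularity match definition oracles on random
          graphs", {
  set.seed(55)
  for (i in 1:25) {
    n <- sample(6:14, 1)
    g <- igraph::sample_gnp(n, 0.4)
    if (igraph::ecount(g) == 0) next
    igraph::V(g)$name <- paste0("t", seq_len(n))
    igraph::E(g)$weight <- 1
    met <- partition_and_metrics(g)
    expect_equal(met$density, igraph::edge_density(g), tolerance = 1e-12)
    adj <- as.matrix(igraph::as_adjacency_matrix(g))
    expect_equal(met$modularity,
                 modularity_oracle(adj, met$membership[rownames(adj)]),
                 tolerance = 1e-12)
  }
})

test_that("SES arithmetic and degeneracy flags are correct", {
  g <- igraph::make_full_graph(3) + igraph::make_full_graph(3)
  igraph::E(g)$weight <- 1
  ses <- modularity_ses(g, n_null = 200, seed = 3)
  expect_equal(ses$ses, (ses$observed_q - ses$null_mean) / ses$null_sd,
               tolerance = 1e-12)
  expect_false(ses$degenerate)
  expect_error(modularity_ses(igraph::make_empty_graph(3, directed = FALSE)),
               class = "sagnet_input_error")
})

test_that("rarefaction output has the declared shape and is seeded", {
  set.seed(77)
  counts <- matrix(rpois(30 * 16, 50), 30, 16,
                   dimnames = list(NULL, paste0("t", 1:16)))
  groups <- setNames(rep(c("A", "B"), each = 8), paste0("t", 1:16))
  ctl <- list(n_resamples = 3, n_permutations = 19, r_min = 0.4)
  r1 <- rarefaction_density_test(counts, groups, k = 6, n_iter = 10,
                                 seed = 4, n_label_perm = 99,
                                 sparcc_control = ctl)
  r2 <- rarefaction_density_test(counts, groups, k = 6, n_iter = 10,
                                 seed = 4, n_label_perm = 99,
                                 sparcc_control = ctl)
  expect_equal(lengths(r1$density), c(A = 10L, B = 10L))
  expect_identical(r1$density, r2$density)
  expect_identical(r1$p, r2$p)
  expect_true(all(unlist(r1$density) >= 0 & unlist(r1$density) <= 1))
  expect_error(rarefaction_density_test(counts, groups, k = 9, n_iter = 2),
               class = "sagnet_input_error")
})
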