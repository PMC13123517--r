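test_that("Jaccard distances follow set arithmetic and conventions", {
  ann <- data.frame(genome_id = c("g1", "g1", "g2", "g2", "g3", "g3"),
                    family = c("GH1", "GT2", "GT2", "CE7", "PL9", "AA4"))
  out <- jaccard_distances(ann, genomes = c("g1", "g2", "g3", "g4", "g5"))
  d <- out$distance
  expect_equal(d["g1", "g2"], 1 - 1 / 3, tolerance = 1e-12)
  expect_equal(d["g1", "g3"], 1)            # disjoint non-empty
  expect_equal(d["g4", "g5"], 0)            # two empty profiles
  expect_equal(d["g1", "g4"], 1)            # empty vs non-empty
  expect_equal(diag(d), setNames(rep(0, 5), rownames(d)))
  expect_true(isSymmetric(d))
  # duplicates collapse to a single presence
  ann2 <- rbind(ann, data.frame(genome_id = "g1", family = "GH1"))
  expect_equal(jaccard_distances(ann2, genomes = rownames(d))$presence,
               out$presence)
})

test_that("Jaccard matches the set oracle and obeys the triangle
          inequality on random profiles", {
  set.seed(42)
  fams <- paste0("GH", 1:15)
  for (rep_ in 1:4) {
    sets <- lapply(1:8, function(i) sample(fams, sample(0:10, 1)))
    names(sets) <- paste0("g", 1:8)
    ann <- do.call(rbind, lapply(names(sets), function(g)
      if (length(sets[[g]])) data.frame(genome_id = g, family = sets[[g]])))
    d <- jaccard_distances(ann, genomes = names(sets))$distance
    for (i in 1:7) for (j in (i + 1):8)
      expect_equal(d[i, j], jaccard_set_oracle(sets[[i]], sets[[j]]),
                   tolerance = 1e-12)
    for (i in 1:8) for (j in 1:8) for (k in 1:8)
      expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
  }
})

test_that("patristic distances are branch-length path sums", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  d <- patristic_distances(tr)
  expect_equal(d["A", "B"], 2)
  expect_equal(d["A", "C"], 4)
  expect_equal(d["B", "C"], 4)
  star <- ape::read.tree(text = "(A:1.5,B:1.5,C:1.5,D:1.5);")
  ds <- patristic_distances(star)
  expect_true(all(ds[upper.tri(ds)] == 3))
  no_bl <- ape::read.tree(text = "((A,B),C);")
  expect_error(patristic_distances(no_bl), class = "sagnet_input_error")
})

test_that("patristic distances match the root-path LCA oracle", {
  set.seed(7)
  tr <- ape::rphylo(25, 1, 0)
  expect_equal(patristic_distances(tr),
               patristic_oracle(tr)[tr$tip.label, tr$tip.label],
               tolerance = 1e-10)
})

test_that("identical matrices give a perfect phylogeny-function
          association", {
  set.seed(11)
  tr <- ape::rphylo(12, 1, 0)
  d <- patristic_distances(tr)
  groups <- setNames(rep(c("C-depleted", "C-enriched"), each = 6),
                     tr$tip.label)
  res <- phylo_function_association(d, d, groups, n_perm = 99, seed = 1)
  expect_equal(res$slope, c(1, 1), tolerance = 1e-9)
  expect_equal(res$r2, c(1, 1), tolerance = 1e-9)
  expect_equal(res$mantel_r, c(1, 1), tolerance = 1e-9)
  expect_true(all(res$mantel_p <= 0.05))
})

test_that("Mantel p is invariant to joint monotone relabeling", {
  set.seed(13)
  tr <- ape::rphylo(10, 1, 0)
  dp <- patristic_distances(tr)
  df <- as.matrix(dist(matrix(rnorm(20), 10)))
  dimnames(df) <- dimnames(dp)
  groups <- setNames(rep("C-depleted", 10), rownames(dp))
  r1 <- phylo_function_association(dp, df, groups, n_perm = 199, seed = 5)
  perm <- sample(rownames(dp))
  r2 <- phylo_function_association(dp[perm, perm], df[perm, perm],
                                   setNames(groups[perm], perm),
                                   n_perm = 199, seed = 5)
  expect_equal(r1$mantel_r, r2$mantel_r, tolerance = 1e-12)
})

test_that("degenerate within-group distances are flagged", {
  d0 <- matrix(0, 5, 5, dimnames = list(paste0("g", 1:5), paste0("g", 1:5)))
  dr <- as.matrix(dist(matrix(rnorm(10), 5)))
  dimnames(dr) <- dimnames(d0)
  res <- phylo_function_association(
    d0, dr, setNames(rep("C-depleted", 5), rownames(d0)), n_perm = 99)
  expect_true(res$degenerate)
  expect_true(is.na(res$mantel_r))
})

test_that("family enrichment scores a fully separated family correctly", {
  pm <- matrix(0L, 20, 2, dimnames = list(paste0("g", 1:20), c("GH1", "GH2")))
  pm[1:10, "GH1"] <- 1L       # all of group 1, none of group 2
  pm[, "GH2"] <- rep(c(1L, 0L), 10)  # equal prevalence
  groups <- setNames(rep(c("C-enriched", "C-depleted"), each = 10),
                     rownames(pm))
  res <- family_enrichment(pm, groups)
  gh1 <- res[res$family == "GH1", ]
  expect_lt(gh1$p, 1e-4)
  expect_equal(gh1$log2fc, log2(21), tolerance = 1e-9)
  expect_equal(gh1$direction, "C-enriched")
  expect_equal(res$log2fc[res$family == "GH2"], 0, tolerance = 1e-9)
})

test_that("enrichment is antisymmetric under group-label exchange", {
  set.seed(17)
  pm <- matrix(rbinom(120, 1, 0.4), 12, 10,
               dimnames = list(paste0("g", 1:12), paste0("F", 1:10)))
  pm[, 1] <- 1L  # keep one family from being dropped as all-absent
  g1 <- setNames(rep(c("C-enriched", "C-depleted"), each = 6), rownames(pm))
  g2 <- setNames(rep(c("C-depleted", "C-enriched"), each = 6), rownames(pm))
  r1 <- suppressMessages(family_enrichment(pm, g1))
  r2 <- suppressMessages(family_enrichment(pm, g2))
  keep <- intersect(r1$family, r2$family)
  expect_equal(r1$p[match(keep, r1$family)], r2$p[match(keep, r2$family)],
               tolerance = 1e-12)
  expect_equal(r1$log2fc[match(keep, r1$family)],
               -r2$log2fc[match(keep, r2$family)], tolerance = 1e-12)
})

test_that("volcano flags require both q <= 0.05 and |log2fc| >= 1", {
  # near-boundary family: modest effect, significant q
  pm <- matrix(0L, 40, 3, dimnames = list(paste0("g", 1:40),
                                          c("F1", "F2", "F3")))
  pm[1:20, "F1"] <- 1L
  pm[c(1:14, 21:26), "F2"] <- 1L   # prevalence 14/20 vs 6/20: |lfc| < 1.3
  pm[c(1:12, 21:30), "F3"] <- 1L   # small effect, not significant
  groups <- setNames(rep(c("C-enriched", "C-depleted"), each = 20),
                     rownames(pm))
  res <- family_enrichment(pm, groups)
  expect_true(all(res$significant == (res$q <= 0.05 & abs(res$log2fc) >= 1)))
  expect_true(res$significant[res$family == "F1"])
  expect_false(res$significant[res$family == "F3"])
})

test_that("planted group-enriched families are detected end to end", {
  cfg <- sim_config(n_per_group = 60, n_families = 30,
                    enriched_families = data.frame(
                      family = 5, group = "C-enriched",
                      odds_multiplier = 20),
                    seed = 19)
  out <- simulate_sag_catalog(cfg)
  groups <- setNames(out$sags$group, out$sags$sag_id)
  pm <- simulate_cazyme_matrix(out$tree, cfg, groups = groups)
  res <- suppressMessages(family_enrichment(pm, groups))
  hit <- res[res$family == colnames(pm)[5], ]
  expect_lt(hit$q, 0.05)
  expect_equal(hit$direction, "C-enriched")
})

test_that("moderate-rate simulated profiles carry phylogenetic signal", {
  cfg <- sim_config(n_per_group = 25, n_families = 60, seed = 23)
  out <- simulate_sag_catalog(cfg)
  pm <- simulate_cazyme_matrix(out$tree, cfg)
  dp <- patristic_distances(out$tree)
  df <- jaccard_distances(pm)$distance
  groups <- setNames(out$sags$group, out$sags$sag_id)
  res <- phylo_function_association(dp, df[rownames(dp), rownames(dp)],
                                    groups, n_perm = 499, seed = 3)
  expect_true(any(res$mantel_p < 0.05))
})
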