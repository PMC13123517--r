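# Independent brute-force oracles used across the suite. These stay free of
# any package internals so they can disagree with the implementation.

# Benjamini-Hochberg step-up, straight from the definition:
# q_(i) = min_{j >= i} p_(j) * n / j on the sorted p-values.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- ps * n / seq_len(n)
  for (i in (n - 1):1) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# Jaccard distance between two family sets, by explicit set arithmetic
jaccard_set_oracle <- function(f1, f2) {
  u <- length(union(f1, f2))
  if (u == 0) return(0)
  1 - length(intersect(f1, f2)) / u
}

# patristic distance via root paths: d(i,j) = depth(i) + depth(j) -
# 2 depth(LCA), with depths summed branch lengths from the root
patristic_oracle <- function(tree) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  parent <- integer(n_tip + tree$Nnode)
  elen <- numeric(n_tip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  path_to_root <- function(v) {
    p <- v
    while (v != root) { v <- parent[v]; p <- c(p, v) }
    p
  }
  depth <- function(v) { d <- 0; while (v != root) { d <- d + elen[v]; v <- parent[v] }; d }
  d <- matrix(0, n_tip, n_tip, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n_tip - 1)) for (j in (i + 1):n_tip) {
    lca <- intersect(path_to_root(i), path_to_root(j))
    lca <- lca[which.max(vapply(lca, depth, 0))]
    d[i, j] <- d[j, i] <- depth(i) + depth(j) - 2 * depth(lca)
  }
  d
}

# unweighted modularity straight from the definition:
# Q = (1/2m) sum_ij (A_ij - k_i k_j / 2m) delta(c_i, c_j)
modularity_oracle <- function(adj, membership) {
  m <- sum(adj) / 2
  k <- rowSums(adj)
  delta <- outer(membership, membership, "==")
  sum((adj - outer(k, k) / (2 * m)) * delta) / (2 * m)
}

# dense solve of the sparse-basis variance system (no exclusions)
sparcc_dense_oracle <- function(Tv) {
  p <- nrow(Tv)
  M <- matrix(1, p, p); diag(M) <- p - 1
  w2 <- solve(M, rowSums(Tv))
  w <- sqrt(pmax(w2, 1e-12))
  r <- (outer(w2, w2, "+") - Tv) / (2 * outer(w, w))
  r <- pmin(pmax(r, -1), 1)
  diag(r) <- 1
  r
}

# edge sets as canonical "a|b" strings for recovery comparisons
edge_keys <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")

network_edge_keys <- function(net) {
  if (igraph::ecount(net) == 0) return(character(0))
  el <- igraph::as_data_frame(net, what = "edges")
  edge_keys(el$from, el$to)
}

# small valid exchange table with exact component products
random_exchange_fixture <- function(n_comm = 4, n_genomes = 4, n_rows = 30) {
  comm <- sprintf("c%d", seq_len(n_comm))
  mem <- data.frame(
    community_id = rep(comm, each = n_genomes),
    genome_id = sprintf("g%d_%d", rep(seq_len(n_comm), each = n_genomes),
                        seq_len(n_genomes)),
    group = rep(rep(c("C-depleted", "C-enriched"), length.out = n_comm),
                each = n_genomes),
    stringsAsFactors = FALSE)
  cid <- sample(comm, n_rows, replace = TRUE)
  pick <- function(cids) t(vapply(cids, function(cc) {
    sample(mem$genome_id[mem$community_id == cc], 2)
  }, character(2)))
  rd <- pick(cid)
  sm <- runif(n_rows, 0.01, 0.99)
  a <- matrix(rgamma(3 * n_rows, 1, 1), ncol = 3)
  a <- a / rowSums(a)
  recs <- data.frame(community = cid, medium = "minimal",
                     receiver = rd[, 1], donor = rd[, 2],
                     compound = sample(default_category_map()$metabolite_id,
                                       n_rows, replace = TRUE),
                     scs = sm^a[, 1], mus = sm^a[, 2], mps = sm^a[, 3],
                     smetana = sm, stringsAsFactors = FALSE)
  list(records = recs, membership = mem)
}
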