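#' Compositionally aware correlation inference (SparCC-type)
#'
#' Estimates correlations between the unobserved basis abundances underlying
#' a compositional count table. Per resample, fractions are drawn from a
#' Dirichlet posterior with a +1 pseudocount; the log-ratio variation matrix
#' `t_ij = var(log(x_i / x_j))` is formed; basis variances are solved from
#' the sparse-correlation linear system over the row sums of T; and
#' `r_ij = (w_i^2 + w_j^2 - t_ij) / (2 w_i w_j)`. The strongest-correlated
#' pair is iteratively excluded from the variance system while
#' `max |r| > exclusion_threshold`, up to `max_exclusions` rounds. The final
#' estimate is the element-wise median over resamples, clipped to \[-1, 1\].
#' P-values come from permuting each taxon's counts independently across
#' samples and re-estimating; two-sided pseudo p = `(b + 1) / (B + 1)`.
#'
#' @param table samples x taxa matrix (or data.frame) of non-negative
#'   counts. All-zero taxa are dropped with a message.
#' @param n_resamples Dirichlet resamples per estimate (default 20).
#' @param exclusion_threshold stop excluding pairs once max |r| falls to or
#'   below this value (default 0.1).
#' @param max_exclusions maximum pair-exclusion rounds (default 10).
#' @param n_permutations permutations for p-values; 0 skips them.
#' @param seed RNG seed; the whole estimate is reproducible given it.
#' @return object of class `sparcc_estimate`: list with `r` (correlations),
#'   `p` (permutation p-values, NA when skipped), `variation` (T from the
#'   pseudocounted observed fractions), `omega` (basis standard deviations
#'   from the same), `taxa`, `n_samples`.
#' @examples
#' set.seed(1)
#' x <- matrix(rpois(200, 50), 10, 20)
#' est <- sparcc_infer(x, n_permutations = 0, seed = 1)
#' range(est$r)
#' @export
sparcc_infer <- function(table, n_resamples = 20, exclusion_threshold = 0.1,
                         max_exclusions = 10, n_permutations = 999,
                         seed = NULL) {
  m <- as.matrix(table)
  if (any(m < 0)) stop_sagnet("sagnet_input_error", "negative counts")
  zero <- colSums(m) == 0
  if (any(zero)) {
    message("sparcc_infer: dropping ", sum(zero), " all-zero taxon(a)")
    m <- m[, !zero, drop = FALSE]
  }
  if (ncol(m) < 4)
    stop_sagnet("sagnet_input_error",
                "need >= 4 taxa for the basis-variance system")
  if (nrow(m) < 3)
    stop_sagnet("sagnet_input_error", "need >= 3 samples")
  taxa <- colnames(m) %||% sprintf("t%d", seq_len(ncol(m)))
  if (!is.null(seed)) set.seed(seed)
  r <- .sparcc_estimate_cpp(m, n_resamples, exclusion_threshold,
                            max_exclusions)
  dimnames(r) <- list(taxa, taxa)
  p <- matrix(NA_real_, ncol(m), ncol(m), dimnames = dimnames(r))
  if (n_permutations > 0) {
    exceed <- .sparcc_perm_counts_cpp(m, r, n_permutations, n_resamples,
                                      exclusion_threshold, max_exclusions)
    p <- (exceed + 1) / (n_permutations + 1)
    diag(p) <- 0
    dimnames(p) <- dimnames(r)
  }
  # deterministic variation matrix / basis sds from pseudocounted fractions
  f <- (m + 1) / rowSums(m + 1)
  Tv <- .sparcc_variation_cpp(log(f))
  bas <- .sparcc_basis_cpp(Tv, exclusion_threshold, max_exclusions)
  dimnames(Tv) <- dimnames(r)
  structure(list(r = r, p = p, variation = Tv,
                 omega = sqrt(pmax(drop(bas$omega2), 0)),
                 taxa = taxa, n_samples = nrow(m)),
            class = "sparcc_estimate")
}

#' Basis correlations from a variation matrix
#'
#' The deterministic core of [sparcc_infer()]: solves the sparse-basis
#' linear system for component variances from a log-ratio variation matrix
#' and returns the implied correlation matrix, applying the iterative
#' strong-pair exclusion. Mainly useful for testing and for inspecting the
#' estimator without resampling.
#'
#' @param variation square symmetric variation matrix (zero diagonal).
#' @param exclusion_threshold,max_exclusions as in [sparcc_infer()]; set
#'   `exclusion_threshold = Inf` to disable exclusions.
#' @return list with `r` (correlation matrix) and `omega2` (basis
#'   variances).
#' @export
sparcc_basis_correlation <- function(variation, exclusion_threshold = 0.1,
                                     max_exclusions = 10) {
  thr <- if (is.infinite(exclusion_threshold)) 2 else exclusion_threshold
  out <- .sparcc_basis_cpp(as.matrix(variation), thr, max_exclusions)
  dimnames(out$r) <- dimnames(variation)
  out$omega2 <- drop(out$omega2)
  out
}

#' Build the thresholded co-occurrence network
#'
#' Retains an undirected edge (i, j) iff `|r_ij| > r_min` and
#' `p_ij < p_max`; edges carry the signed correlation as weight. The node
#' set is the taxa incident to at least one retained edge.
#'
#' @param est a [sparcc_infer()] result (or any list with `r` and `p`
#'   matrices).
#' @param r_min minimum absolute correlation (default 0.6, exclusive).
#' @param p_max maximum p-value (default 0.05, exclusive).
#' @return an [igraph::graph_from_data_frame()] undirected graph with edge
#'   attributes `r` (signed), `p` and `weight = |r|`.
#' @export
build_network <- function(est, r_min = 0.6, p_max = 0.05) {
  r <- est$r; p <- est$p
  if (!all(dim(r) == dim(p)))
    stop_sagnet("sagnet_input_error", "r and p shapes differ")
  sel <- which(upper.tri(r) & abs(r) > r_min & p < p_max, arr.ind = TRUE)
  taxa <- rownames(r)
  if (!nrow(sel))
    return(igraph::make_empty_graph(0, directed = FALSE))
  edges <- data.frame(from = taxa[sel[, 1]], to = taxa[sel[, 2]],
                      r = r[sel], p = p[sel], weight = abs(r[sel]),
                      stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edges, directed = FALSE)
}

#' Network density from node and edge counts
#'
#' `2 m / (n (n - 1))` for an undirected simple graph; defined as 0 for
#' n < 2.
#'
#' @param n_nodes,n_edges node and edge counts.
#' @return density in \[0, 1\].
#' @examples
#' network_density(21, 55)  # ~0.262
#' network_density(16, 69)  # 0.575
#' @export
network_density <- function(n_nodes, n_edges) {
  ifelse(n_nodes < 2, 0, 2 * n_edges / (n_nodes * (n_nodes - 1)))
}

#' Partition a network into sub-communities and compute metrics
#'
#' Modules come from deterministic greedy modularity maximization
#' (agglomerative, on `|r|` edge weights); each module of the co-occurrence
#' network is a sub-community whose size is its node count. Modularity Q is
#' computed on the same weights.
#'
#' @param net igraph graph as returned by [build_network()].
#' @param seed RNG seed (the greedy algorithm is deterministic; the seed is
#'   accepted for interface symmetry with the null-model machinery).
#' @return object of class `network_metrics`: list with `n_nodes`,
#'   `n_edges`, `density`, `modularity`, `n_modules`, `module_sizes`, and
#'   `membership` (named node -> module id).
#' @export
partition_and_metrics <- function(net, seed = NULL) {
  n <- igraph::vcount(net); m <- igraph::ecount(net)
  if (n == 0 || m == 0)
    return(structure(list(n_nodes = n, n_edges = m,
                          density = network_density(n, m),
                          modularity = NA_real_, n_modules = 0L,
                          module_sizes = integer(0),
                          membership = setNames(integer(0), character(0))),
                     class = "network_metrics"))
  if (!is.null(seed)) set.seed(seed)
  w <- igraph::E(net)$weight %||% rep(1, m)
  cl <- igraph::cluster_fast_greedy(net, weights = w)
  memb <- igraph::membership(cl)
  q <- igraph::modularity(net, memb, weights = w)
  structure(list(n_nodes = n, n_edges = m, density = network_density(n, m),
                 modularity = q, n_modules = length(unique(memb)),
                 module_sizes = as.integer(table(memb)),
                 membership = setNames(as.integer(memb),
                                       igraph::V(net)$name)),
            class = "network_metrics")
}

#' Null-model standardized effect size for modularity
#'
#' Compares the observed modularity against `n_null` Erdos-Renyi G(n, m)
#' random graphs matched on both node and edge counts (modularity is
#' density-dependent, so matching only nodes would make the effect size
#' meaningless). Each null graph is partitioned by the same greedy
#' algorithm. `SES = (Q_obs - mean_null) / sd_null`; the empirical p-value
#' is `(#{Q_null >= Q_obs} + 1) / (n_null + 1)`.
#'
#' @param net igraph graph with >= 1 edge.
#' @param n_null number of null replicates (default 1000; >= 100 advised
#'   for a stable SES).
#' @param seed RNG seed for the null ensemble.
#' @return object of class `null_model_result`: list with `observed_q`,
#'   `null_mean`, `null_sd`, `ses`, `p`, `n_null`, `degenerate` (TRUE with
#'   `ses = NA` when the null sd is 0).
#' @export
modularity_ses <- function(net, n_null = 1000, seed = NULL) {
  if (igraph::ecount(net) < 1)
    stop_sagnet("sagnet_input_error", "network has no edges")
  if (!is.null(seed)) set.seed(seed)
  n <- igraph::vcount(net); m <- igraph::ecount(net)
  obs <- partition_and_metrics(net)$modularity
  qn <- vapply(seq_len(n_null), function(i) {
    g <- igraph::sample_gnm(n, m)
    igraph::modularity(g, igraph::membership(
      igraph::cluster_fast_greedy(g)))
  }, numeric(1))
  s <- sd(qn)
  degen <- !is.finite(s) || s == 0
  structure(list(observed_q = obs, null_mean = mean(qn), null_sd = s,
                 ses = if (degen) NA_real_ else (obs - mean(qn)) / s,
                 p = (sum(qn >= obs) + 1) / (n_null + 1),
                 n_null = n_null, degenerate = degen),
            class = "null_model_result")
}

#' Rarefaction-based comparison of network density between groups
#'
#' Per iteration, `k` taxa are sampled without replacement from each group,
#' the correlation network is re-inferred on each subset with identical
#' parameters, and its density recorded over the `k` rarefied taxa
#' (`2 m / (k (k - 1))`, 0 for empty networks), so per-iteration networks of
#' equal size are compared on a common denominator. The
#' two-sided permutation p-value for the mean density difference permutes
#' group labels over the pooled per-iteration densities.
#'
#' @param table samples x taxa count matrix covering both groups' taxa.
#' @param groups named character vector taxon -> group label (two labels).
#' @param k taxa drawn per group per iteration (default 18).
#' @param n_iter rarefaction iterations (default 1000).
#' @param seed RNG seed.
#' @param n_label_perm label permutations for the density-difference test.
#' @param sparcc_control list overriding the network-reconstruction
#'   parameters: n_resamples, exclusion_threshold, max_exclusions,
#'   n_permutations, r_min, p_max.
#' @return object of class `rarefaction_result`: list with `density` (named
#'   list of per-iteration density vectors per group), `mean_diff` (first
#'   group minus second), `p`, `n_iter`, `k`.
#' @export
rarefaction_density_test <- function(table, groups, k = 18, n_iter = 1000,
                                     seed = NULL, n_label_perm = 999,
                                     sparcc_control = list()) {
  ctl <- modifyList(list(n_resamples = 20, exclusion_threshold = 0.1,
                         max_exclusions = 10, n_permutations = 99,
                         r_min = 0.6, p_max = 0.05), sparcc_control)
  m <- as.matrix(table)
  lv <- unique(groups)
  if (length(lv) != 2)
    stop_sagnet("sagnet_input_error", "need exactly two groups")
  gtaxa <- lapply(lv, function(g) intersect(colnames(m),
                                            names(groups)[groups == g]))
  names(gtaxa) <- lv
  if (any(vapply(gtaxa, length, 1L) < k))
    stop_sagnet("sagnet_input_error",
                paste("k =", k, "exceeds the taxon count of a group"))
  if (!is.null(seed)) set.seed(seed)
  dens <- lapply(lv, function(g) numeric(n_iter))
  names(dens) <- lv
  for (i in seq_len(n_iter)) {
    for (g in lv) {
      sub <- m[, sample(gtaxa[[g]], k), drop = FALSE]
      est <- sparcc_infer(sub, n_resamples = ctl$n_resamples,
                          exclusion_threshold = ctl$exclusion_threshold,
                          max_exclusions = ctl$max_exclusions,
                          n_permutations = ctl$n_permutations)
      net <- build_network(est, r_min = ctl$r_min, p_max = ctl$p_max)
      dens[[g]][i] <- network_density(k, igraph::ecount(net))
    }
  }
  pooled <- c(dens[[1]], dens[[2]])
  lab <- rep(c(TRUE, FALSE), each = n_iter)
  obs <- mean(dens[[1]]) - mean(dens[[2]])
  b <- 0L
  for (j in seq_len(n_label_perm)) {
    pl <- sample(lab)
    d <- mean(pooled[pl]) - mean(pooled[!pl])
    if (abs(d) >= abs(obs) - 1e-15) b <- b + 1L
  }
  structure(list(density = dens, mean_diff = obs,
                 p = (b + 1) / (n_label_perm + 1),
                 n_iter = n_iter, k = k),
            class = "rarefaction_result")
}
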