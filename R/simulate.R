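#' Simulation configuration for synthetic pipeline inputs
#'
#' Bundles every parameter of the synthetic-data generators: group-structured
#' genome features following a power-law CDS-size relationship,
#' phylogenetically autocorrelated binary CAZyme profiles with group-enriched
#' families, compositional count tables with planted block correlation, and
#' metabolite exchange tables with planted per-category group effects.
#' Identical configuration and seed give byte-identical outputs.
#'
#' @param n_per_group genomes per treatment group (positive integer).
#' @param base_size mean genome size (bp) of the C-depleted group.
#' @param size_sd_log log-scale standard deviation of genome size.
#' @param size_group_multiplier ratio of mean genome size,
#'   C-enriched / C-depleted. Default 1.18 (an 18% difference).
#' @param scaling_slope exponent of the CDS-size power law (log10-log10
#'   slope).
#' @param scaling_intercept log10-scale offset of the power law.
#' @param scaling_noise_sd standard deviation of the log10 residual noise.
#' @param gc_means named per-group mean GC fraction, each in (0, 1).
#' @param gc_sd standard deviation of GC around the group mean.
#' @param n_families number of CAZyme families to simulate.
#' @param gain_rate,loss_rate gain (0 to 1) and loss (1 to 0) rates of the
#'   two-state Markov process by which each family evolves along the tree.
#' @param enriched_families `NULL` or a data.frame with columns `family`
#'   (index or name), `group`, `odds_multiplier`: presence odds of that
#'   family are multiplied in the designated group.
#' @param n_taxa number of taxa in the abundance table.
#' @param n_samples number of samples in the abundance table.
#' @param depth multinomial sequencing depth per sample (>= 100).
#' @param sigma_log log-scale standard deviation of basis abundances.
#' @param block_spec list of `list(members =, rho =)` entries: taxa indices
#'   (or names) forming a correlated block and the within-block basis
#'   correlation in \[-1, 1\]. Blocks must be disjoint.
#' @param category_effects named numeric vector: planted log2 fold change
#'   (C-enriched over C-depleted) of the mean exchange score per metabolite
#'   category.
#' @param exclusive_categories categories emitted only in C-enriched
#'   sub-communities.
#' @param base_mean baseline mean exchange score (C-depleted) in (0, 1).
#' @param beta_concentration concentration of the Beta score distribution.
#' @param exchange_prob probability that a given (receiver, donor,
#'   metabolite) triple is emitted.
#' @param seed integer seed governing all generators.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_per_group = 10, seed = 1)
#' cat_out <- simulate_sag_catalog(cfg)
#' head(cat_out$sags)
#' @export
sim_config <- function(n_per_group = 30,
                       base_size = 3.5e6,
                       size_sd_log = 0.35,
                       size_group_multiplier = 1.18,
                       scaling_slope = 0.9,
                       scaling_intercept = -2.38,
                       scaling_noise_sd = 0.05,
                       gc_means = c("C-depleted" = 0.62, "C-enriched" = 0.57),
                       gc_sd = 0.02,
                       n_families = 60,
                       gain_rate = 0.3,
                       loss_rate = 0.7,
                       enriched_families = NULL,
                       n_taxa = 30,
                       n_samples = 40,
                       depth = 50000,
                       sigma_log = 1,
                       block_spec = list(list(members = 1:6, rho = 0.8),
                                         list(members = 7:12, rho = 0.8),
                                         list(members = 13:18, rho = 0.8)),
                       category_effects = c("amino acids" = 1.42,
                                            "aromatic compounds" = 0.76),
                       exclusive_categories = "B-vitamins",
                       base_mean = 0.12,
                       beta_concentration = 10,
                       exchange_prob = 0.25,
                       seed = 1L) {
  cfg <- list(n_per_group = n_per_group, base_size = base_size,
              size_sd_log = size_sd_log,
              size_group_multiplier = size_group_multiplier,
              scaling_slope = scaling_slope,
              scaling_intercept = scaling_intercept,
              scaling_noise_sd = scaling_noise_sd,
              gc_means = gc_means, gc_sd = gc_sd,
              n_families = n_families,
              gain_rate = gain_rate, loss_rate = loss_rate,
              enriched_families = enriched_families,
              n_taxa = n_taxa, n_samples = n_samples, depth = depth,
              sigma_log = sigma_log, block_spec = block_spec,
              category_effects = category_effects,
              exclusive_categories = exclusive_categories,
              base_mean = base_mean,
              beta_concentration = beta_concentration,
              exchange_prob = exchange_prob,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop_sagnet("sagnet_config_error", msg)
  counts <- c(n_per_group = cfg$n_per_group, n_families = cfg$n_families,
              n_taxa = cfg$n_taxa, n_samples = cfg$n_samples)
  chk(all(counts > 0), paste("all counts must be positive; got",
                             paste(names(counts)[counts <= 0], collapse = ", ")))
  chk(cfg$depth >= 100, "depth must be >= 100")
  chk(all(cfg$gc_means > 0 & cfg$gc_means < 1), "gc_means must lie in (0,1)")
  chk(setequal(names(cfg$gc_means), sag_groups()),
      "gc_means must be named with both group labels")
  chk(cfg$scaling_noise_sd >= 0, "scaling_noise_sd must be >= 0")
  chk(cfg$gain_rate >= 0 && cfg$loss_rate >= 0, "Markov rates must be >= 0")
  chk(cfg$base_mean > 0 && cfg$base_mean < 1, "base_mean must lie in (0,1)")
  if (length(cfg$block_spec)) {
    rhos <- vapply(cfg$block_spec, function(b) b$rho, numeric(1))
    chk(all(rhos >= -1 & rhos <= 1), "block correlations must lie in [-1,1]")
    members <- unlist(lapply(cfg$block_spec, function(b) b$members))
    chk(!anyDuplicated(members), "block members must be disjoint")
    if (is.numeric(members))
      chk(all(members >= 1 & members <= cfg$n_taxa),
          "block member indices must lie within 1..n_taxa")
  }
  invisible(cfg)
}

# deterministic sub-seeds so successive generators do not share RNG streams
sim_seed <- function(cfg, offset) set.seed(cfg$seed + offset)

#' Simulate a SAG catalog and companion phylogeny
#'
#' Generates `2 * n_per_group` single-amplified-genome records across the two
#' carbon-availability groups. True genome sizes are log-normal with a
#' group-specific mean; CDS counts follow the power law
#' `CDS = round(10^(a + b * log10(size) + e))` with Gaussian log10 noise `e`;
#' completeness is uniform on \[40, 100\]% and contamination on \[0, 15\]% so
#' the quality filter is exercised; `assembly_length = size * completeness /
#' 100`. A random ultrametric (pure-birth) tree is simulated over all
#' genome ids.
#'
#' @param config a [sim_config()].
#' @return list with `sags` (data.frame: sag_id, group, site,
#'   assembly_length, completeness, contamination, gc, cds_count, true_size)
#'   and `tree` (an [ape::rphylo()] phylo object with tips = sag ids).
#' @export
simulate_sag_catalog <- function(config) {
  validate_sim_config(config)
  sim_seed(config, 0L)
  n <- 2L * config$n_per_group
  grp <- rep(sag_groups(), each = config$n_per_group)
  ids <- sprintf("SAG%03d", seq_len(n))
  mean_size <- ifelse(grp == "C-enriched",
                      config$base_size * config$size_group_multiplier,
                      config$base_size)
  size <- rlnorm(n, meanlog = log(mean_size) - config$size_sd_log^2 / 2,
                 sdlog = config$size_sd_log)
  eps <- if (config$scaling_noise_sd > 0)
    rnorm(n, 0, config$scaling_noise_sd) else numeric(n)
  cds <- round(10^(config$scaling_intercept +
                     config$scaling_slope * log10(size) + eps))
  completeness <- runif(n, 40, 100)
  contamination <- runif(n, 0, 15)
  gc <- pmin(pmax(rnorm(n, config$gc_means[grp], config$gc_sd), 0.01), 0.99)
  sags <- data.frame(
    sag_id = ids, group = grp,
    site = sample(c("AH", "HLJ", "JX", "SD"), n, replace = TRUE),
    assembly_length = round(size * completeness / 100),
    completeness = completeness, contamination = contamination,
    gc = gc, cds_count = as.integer(cds), true_size = size,
    stringsAsFactors = FALSE)
  tree <- ape::rphylo(n, birth = 1, death = 0)
  tree$tip.label <- sample(ids)
  list(sags = sags, tree = tree)
}

#' Simulate phylogenetically autocorrelated CAZyme presence/absence profiles
#'
#' Each family evolves independently along the tree as a two-state (absent /
#' present) Markov process with the configured gain and loss rates, so
#' closely related tips share profiles. Families listed in
#' `config$enriched_families` then have their tip presence odds multiplied in
#' the designated group (those tips are redrawn independently, which is what
#' makes the enrichment detectable over the phylogenetic background).
#'
#' @param tree phylo object whose tips are genome ids.
#' @param config a [sim_config()].
#' @param groups named character vector genome id -> group label; required
#'   only when `enriched_families` is set.
#' @return binary matrix, genomes x families.
#' @export
simulate_cazyme_matrix <- function(tree, config, groups = NULL) {
  validate_sim_config(config)
  if (!inherits(tree, "phylo"))
    stop_sagnet("sagnet_input_error", "tree must be a phylo object")
  tips <- tree$tip.label
  if (!is.null(groups) && !setequal(names(groups), tips))
    stop_sagnet("sagnet_input_error",
                "tree tip labels do not match the genome ids in `groups`")
  sim_seed(config, 1L)
  nf <- config$n_families
  prefixes <- c("GH", "GT", "CE", "PL", "AA", "CBM")
  fam_names <- paste0(rep_len(prefixes, nf), seq_len(nf))
  g <- config$gain_rate; l <- config$loss_rate
  q <- g + l
  pi1 <- if (q > 0) g / q else 0
  m <- matrix(0L, length(tips), nf, dimnames = list(tips, fam_names))
  for (f in seq_len(nf))
    m[, f] <- evolve_binary_trait(tree, pi1, q)
  ef <- config$enriched_families
  if (!is.null(ef) && nrow(ef)) {
    if (is.null(groups))
      stop_sagnet("sagnet_input_error",
                  "`groups` is required when enriched_families is set")
    for (k in seq_len(nrow(ef))) {
      fam <- ef$family[k]
      col <- if (is.numeric(fam)) fam else match(fam, fam_names)
      target <- tips[groups[tips] == ef$group[k]]
      odds <- ef$odds_multiplier[k] * pi1 / (1 - pi1)
      p_boost <- odds / (1 + odds)
      m[target, col] <- rbinom(length(target), 1L, p_boost)
    }
  }
  m
}

# simulate one two-state trait down the tree; returns 0/1 per tip in
# tree$tip.label order. pi1 = stationary presence probability, q = total
# switching rate; P(state flips toward stationary) = 1 - exp(-q t).
evolve_binary_trait <- function(tree, pi1, q) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  state <- integer(n_node)
  root <- n_tip + 1L
  state[root] <- rbinom(1L, 1L, pi1)
  edge <- tree$edge
  el <- tree$edge.length
  ord <- order(edge[, 1])  # parents precede children for cladewise trees
  for (e in ord) {
    par <- edge[e, 1]; child <- edge[e, 2]
    w <- 1 - exp(-q * el[e])
    p1 <- if (state[par] == 1L) (1 - w) + w * pi1 else w * pi1
    state[child] <- rbinom(1L, 1L, p1)
  }
  state[seq_len(n_tip)]
}

#' Simulate a compositional abundance table with planted block correlation
#'
#' Basis (absolute) abundances are multivariate log-normal with a
#' block-diagonal correlation structure given by `config$block_spec`; per
#' sample they are converted to fractions and multinomially sampled at the
#' configured depth. The within-block pairs with non-zero correlation are
#' returned as the planted true edge set for network-recovery tests.
#'
#' @param config a [sim_config()].
#' @param taxa optional taxon names (default `SAG001 ...`).
#' @return list with `table` (samples x taxa count matrix) and
#'   `planted_edges` (data.frame `a`, `b` of taxon-name pairs).
#' @export
simulate_abundance_table <- function(config, taxa = NULL) {
  validate_sim_config(config)
  sim_seed(config, 2L)
  p <- config$n_taxa
  taxa <- taxa %||% sprintf("SAG%03d", seq_len(p))
  if (length(taxa) != p)
    stop_sagnet("sagnet_input_error", "length(taxa) must equal n_taxa")
  if (config$depth < p)
    warning("depth is smaller than the number of taxa; ",
            "counts will be extremely sparse")
  R <- diag(p)
  edges <- list()
  for (b in config$block_spec) {
    idx <- if (is.numeric(b$members)) b$members else match(b$members, taxa)
    if (anyNA(idx) || any(idx < 1 | idx > p))
      stop_sagnet("sagnet_input_error", "block members outside taxon set")
    R[idx, idx] <- b$rho
    diag(R)[idx] <- 1
    if (b$rho != 0) {
      prs <- t(utils::combn(sort(idx), 2))
      edges[[length(edges) + 1L]] <-
        data.frame(a = taxa[prs[, 1]], b = taxa[prs[, 2]])
    }
  }
  planted <- if (length(edges)) do.call(rbind, edges) else
    data.frame(a = character(), b = character())
  mu <- rnorm(p, 0, 1)  # heterogeneous baseline log-abundance per taxon
  L <- chol(R)
  Z <- matrix(rnorm(config$n_samples * p), config$n_samples, p) %*% L
  logbasis <- sweep(Z * config$sigma_log, 2, mu, "+")
  frac <- exp(logbasis)
  frac <- frac / rowSums(frac)
  counts <- t(apply(frac, 1, function(f) rmultinom(1, config$depth, f)[, 1]))
  dimnames(counts) <- list(sprintf("S%02d", seq_len(config$n_samples)), taxa)
  list(table = counts, planted_edges = planted)
}

#' Simulate a SMETANA-detailed-style metabolite exchange table
#'
#' For every ordered (receiver, donor) pair within each sub-community and
#' every metabolite in the category vocabulary, a row is emitted with
#' probability `exchange_prob`. Exchange scores are Beta-distributed on
#' \[0, 1\] with mean `base_mean` in C-depleted sub-communities, shifted by
#' the planted per-category log2 fold changes in C-enriched ones. The
#' component scores scs, mus, mps are emitted so that their product equals
#' the smetana score exactly. Categories in `exclusive_categories` appear
#' only in C-enriched sub-communities.
#'
#' @param membership data.frame with columns `community_id`, `genome_id`,
#'   `group` (one row per member genome).
#' @param config a [sim_config()].
#' @param category_map data.frame `metabolite_id`, `category`; defaults to
#'   the vocabulary shipped with the package.
#' @return data.frame in the detailed-exchange dialect: community, medium,
#'   receiver, donor, compound, scs, mus, mps, smetana.
#' @export
simulate_exchange_table <- function(membership, config,
                                    category_map = default_category_map()) {
  validate_sim_config(config)
  if (!nrow(membership))
    stop_sagnet("sagnet_input_error", "membership is empty")
  if (!all(c("community_id", "genome_id", "group") %in% names(membership)))
    stop_sagnet("sagnet_input_error",
                "membership needs community_id, genome_id, group columns")
  sim_seed(config, 3L)
  phi <- config$beta_concentration
  eff <- config$category_effects
  rows <- vector("list", 0L)
  for (comm in unique(membership$community_id)) {
    mem <- membership[membership$community_id == comm, ]
    grp <- mem$group[1]
    ids <- mem$genome_id
    if (length(ids) < 2) next
    pairs <- expand.grid(receiver = ids, donor = ids,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$receiver != pairs$donor, ]
    cm <- category_map
    if (grp != "C-enriched")
      cm <- cm[!(cm$category %in% config$exclusive_categories), ]
    np <- nrow(pairs); nm <- nrow(cm)
    keep <- which(runif(np * nm) < config$exchange_prob)
    if (!length(keep)) next
    pi_idx <- ((keep - 1L) %% np) + 1L
    mi_idx <- ((keep - 1L) %/% np) + 1L
    cat_k <- cm$category[mi_idx]
    lfc <- ifelse(grp == "C-enriched" & cat_k %in% names(eff),
                  eff[cat_k], 0)
    mu <- pmin(config$base_mean * 2^lfc, 0.95)
    sm <- rbeta(length(keep), mu * phi, (1 - mu) * phi)
    sm <- pmin(pmax(sm, 1e-6), 1 - 1e-6)
    # split log(smetana) three ways so scs * mus * mps == smetana exactly
    a <- matrix(rgamma(3 * length(keep), 1, 1), ncol = 3)
    a <- a / rowSums(a)
    rows[[length(rows) + 1L]] <- data.frame(
      community = comm, medium = "minimal",
      receiver = pairs$receiver[pi_idx], donor = pairs$donor[pi_idx],
      compound = cm$metabolite_id[mi_idx],
      scs = sm^a[, 1], mus = sm^a[, 2], mps = sm^a[, 3],
      smetana = sm, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(community = character(), medium = character(),
                      receiver = character(), donor = character(),
                      compound = character(), scs = numeric(),
                      mus = numeric(), mps = numeric(), smetana = numeric()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Metabolite-to-category vocabulary shipped with the package
#'
#' BiGG-style extracellular metabolite identifiers mapped to exchange
#' categories (amino acids, aromatic compounds, B-vitamins, oligopeptides,
#' sugars/phosphosugars, nucleobases, other). Editable: any table with
#' columns `metabolite_id`, `category` can replace it.
#'
#' @return data.frame with columns `metabolite_id`, `category`.
#' @export
default_category_map <- function() {
  path <- system.file("extdata", "metabolite_categories.tsv",
                      package = "sagnet", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}
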