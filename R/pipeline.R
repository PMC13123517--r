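#' Read and validate a pipeline configuration
#'
#' The configuration is a YAML (or R list) with either a `simulation` block
#' (arguments to [sim_config()]) or an `inputs` block (paths: `sag_table`,
#' `annotations`, `abundance`, `tree`, and optionally `exchange` +
#' `membership`), plus optional `qc` (min_completeness, max_contamination),
#' `network` (r_min, p_max, n_resamples, n_permutations, n_null,
#' rarefaction_k, rarefaction_iter), `category_map` path, `seed`, and
#' `outdir`.
#'
#' @param config path to a YAML file or an R list with the same structure.
#' @return validated configuration list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (is.null(cfg$simulation) && is.null(cfg$inputs))
    stop_sagnet("sagnet_config_error",
                "config needs a `simulation` block or an `inputs` block")
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$qc <- modifyList(list(min_completeness = 50, max_contamination = 10),
                       cfg$qc %||% list())
  cfg$network <- modifyList(
    list(r_min = 0.6, p_max = 0.05, n_resamples = 20, n_permutations = 999,
         exclusion_threshold = 0.1, max_exclusions = 10, n_null = 1000,
         rarefaction_k = 18, rarefaction_iter = 1000,
         rarefaction_permutations = 99, rarefaction_resamples = 5),
    cfg$network %||% list())
  if (cfg$network$r_min < 0 || cfg$network$r_min > 1 ||
      cfg$network$p_max <= 0 || cfg$network$p_max > 1)
    stop_sagnet("sagnet_config_error", "network thresholds out of range")
  if (cfg$qc$min_completeness < 0 || cfg$qc$min_completeness > 100 ||
      cfg$qc$max_contamination < 0)
    stop_sagnet("sagnet_config_error", "QC thresholds out of range")
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Orchestrates, with a single global seed: input generation (or loading),
#' quality filtering, genome-feature comparisons with the log-log scaling
#' fit, CAZyme distance and enrichment analyses, per-group co-occurrence
#' network inference with null-model and rarefaction validation, and
#' cross-feeding score aggregation with category profiling. Every
#' intermediate table is written to `outdir` with a stage header, plus a
#' machine-readable `summary.json` and a `run_log.txt` recording the
#' package version, seed and parameters. On failure a `FAILED` marker file
#' is left in `outdir` and the (classed) error is re-thrown.
#'
#' @param config a [read_pipeline_config()] input (path or list).
#' @param outdir output directory (overrides the config entry).
#' @return invisibly, the summary list.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  cfg <- read_pipeline_config(config)
  outdir <- outdir %||% cfg$outdir %||% stop_sagnet(
    "sagnet_config_error", "no output directory configured")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  unlink(file.path(outdir, "FAILED"))
  tryCatch(
    run_pipeline_stages(cfg, outdir),
    error = function(e) {
      file.create(file.path(outdir, "FAILED"))
      stop(e)
    })
}

run_pipeline_stages <- function(cfg, outdir) {
  log_path <- file.path(outdir, "run_log.txt")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)
  logf("sagnet %s | seed %d | %s",
       as.character(utils::packageVersion("sagnet")), cfg$seed,
       format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  summary <- list(seed = cfg$seed)

  ## ---- inputs -------------------------------------------------------
  if (!is.null(cfg$simulation)) {
    sim_args <- cfg$simulation
    sim_args$seed <- cfg$seed
    if (!is.null(sim_args$block_spec))
      sim_args$block_spec <- lapply(sim_args$block_spec, function(b)
        list(members = unlist(b$members), rho = b$rho))
    # YAML mappings arrive as lists; the generators expect named vectors
    for (nm in c("gc_means", "category_effects"))
      if (!is.null(sim_args[[nm]])) sim_args[[nm]] <- unlist(sim_args[[nm]])
    scfg <- do.call(sim_config, sim_args)
    cat_out <- simulate_sag_catalog(scfg)
    sags <- cat_out$sags
    tree <- cat_out$tree
    groups_all <- setNames(sags$group, sags$sag_id)
    pm <- simulate_cazyme_matrix(tree, scfg, groups = groups_all)
    ab <- simulate_abundance_table(
      scfg, taxa = abundance_taxa(sags, scfg$n_taxa))
    abundance <- ab$table
    jsonlite::write_json(
      list(planted_edges = ab$planted_edges,
           config = scfg[setdiff(names(scfg), "enriched_families")]),
      file.path(outdir, "planted_truth.json"), auto_unbox = TRUE,
      digits = NA)
    exchange <- NULL  # simulated later, from the inferred sub-communities
    logf("simulated inputs: %d SAGs, %d families, %d x %d abundance table",
         nrow(sags), ncol(pm), nrow(abundance), ncol(abundance))
  } else {
    sags <- read_sag_table(cfg$inputs$sag_table)
    tree <- ape::read.tree(cfg$inputs$tree)
    ann <- read_annotation_table(cfg$inputs$annotations)
    pm <- jaccard_distances(ann, genomes = sags$sag_id)$presence
    abundance <- read_abundance_table(cfg$inputs$abundance)
    groups_all <- setNames(sags$group, sags$sag_id)
    exchange <- if (!is.null(cfg$inputs$exchange))
      read_exchange_table(cfg$inputs$exchange) else NULL
    scfg <- NULL
  }

  ## ---- genome features ----------------------------------------------
  sags$estimated_size <- estimate_genome_size(sags$assembly_length,
                                              sags$completeness)
  kept <- qc_filter(sags, cfg$qc$min_completeness, cfg$qc$max_contamination)
  kept <- flag_large_genomes(kept)
  logf("QC: retained %d of %d SAGs; %d flagged as unusually large",
       nrow(kept), nrow(sags), sum(kept$size_outlier))
  fit <- fit_scaling_residuals(kept)
  feat <- compare_genome_features(kept, fit)
  write_stage_tsv(kept, file.path(outdir, "sags_filtered.tsv"),
                  "genome_features", cfg$qc)
  write_stage_tsv(feat, file.path(outdir, "feature_tests.tsv"),
                  "genome_features", cfg$qc)
  summary$genome_features <- list(
    n_input = nrow(sags), n_retained = nrow(kept),
    scaling_slope = fit$slope, scaling_r2 = fit$r2,
    feature_tests = feat[c("feature", "statistic", "p", "q",
                           "percent_diff")])

  ## ---- CAZyme function ----------------------------------------------
  jd <- jaccard_distances(pm)
  dp <- patristic_distances(tree)
  groups_tree <- groups_all[rownames(jd$distance)]
  assoc <- phylo_function_association(dp[rownames(jd$distance),
                                         rownames(jd$distance)],
                                      jd$distance, groups_tree,
                                      seed = cfg$seed + 11L)
  enr <- family_enrichment(jd$presence, groups_tree)
  write_stage_tsv(jd$distance, file.path(outdir, "jaccard_distance.tsv"),
                  "cazyme_function")
  write_stage_tsv(enr, file.path(outdir, "family_enrichment.tsv"),
                  "cazyme_function")
  write_stage_tsv(assoc, file.path(outdir, "phylo_function.tsv"),
                  "cazyme_function")
  summary$cazyme <- list(
    n_families = ncol(jd$presence),
    n_enriched = sum(enr$significant),
    association = assoc[c("group", "slope", "r2", "mantel_r", "mantel_p")])

  ## ---- network inference, per group ---------------------------------
  np <- cfg$network
  summary$network <- list()
  memberships <- list()
  for (g in unique(groups_all)) {
    taxa_g <- intersect(colnames(abundance),
                        names(groups_all)[groups_all == g])
    if (length(taxa_g) < 4) {
      logf("network[%s]: skipped (%d taxa)", g, length(taxa_g))
      next
    }
    est <- sparcc_infer(abundance[, taxa_g, drop = FALSE],
                        n_resamples = np$n_resamples,
                        exclusion_threshold = np$exclusion_threshold,
                        max_exclusions = np$max_exclusions,
                        n_permutations = np$n_permutations,
                        seed = cfg$seed + 20L + match(g, sag_groups()))
    net <- build_network(est, r_min = np$r_min, p_max = np$p_max)
    met <- partition_and_metrics(net)
    slug <- gsub("[^A-Za-z0-9]+", "_", g)
    write_network(net, file.path(outdir, paste0("network_", slug, ".tsv")),
                  file.path(outdir, paste0("network_", slug, ".graphml")),
                  params = np)
    ses <- if (met$n_edges >= 1)
      modularity_ses(net, n_null = np$n_null,
                     seed = cfg$seed + 30L + match(g, sag_groups()))
    else NULL
    summary$network[[g]] <- list(
      n_nodes = met$n_nodes, n_edges = met$n_edges,
      density = met$density, modularity = met$modularity,
      n_subcommunities = met$n_modules,
      ses = if (!is.null(ses)) ses$ses else NA,
      ses_p = if (!is.null(ses)) ses$p else NA)
    logf("network[%s]: %d nodes, %d edges, %d sub-communities, SES %.3f",
         g, met$n_nodes, met$n_edges, met$n_modules,
         if (!is.null(ses)) ses$ses else NA_real_)
    if (met$n_modules > 0) {
      mods <- split(names(met$membership), met$membership)
      mods <- mods[lengths(mods) >= 2]
      if (length(mods))
        memberships[[g]] <- data.frame(
          community_id = paste0(slug, "_m", rep(seq_along(mods),
                                                lengths(mods))),
          genome_id = unlist(mods, use.names = FALSE),
          group = g, stringsAsFactors = FALSE)
    }
  }

  ## rarefaction density comparison across groups
  gt <- groups_all[intersect(colnames(abundance), names(groups_all))]
  k <- min(np$rarefaction_k, min(table(gt)))
  if (length(unique(gt)) == 2 && k >= 4) {
    rar <- rarefaction_density_test(
      abundance, gt, k = k, n_iter = np$rarefaction_iter,
      seed = cfg$seed + 40L,
      sparcc_control = list(n_resamples = np$rarefaction_resamples,
                            n_permutations = np$rarefaction_permutations,
                            r_min = np$r_min, p_max = np$p_max))
    summary$rarefaction <- list(
      k = rar$k, n_iter = rar$n_iter,
      mean_density = lapply(rar$density, mean),
      mean_diff = rar$mean_diff, p = rar$p)
    logf("rarefaction: k=%d, mean density diff %.4f, p=%.4f",
         rar$k, rar$mean_diff, rar$p)
  }

  ## ---- cross-feeding -------------------------------------------------
  membership <- do.call(rbind, memberships)
  if (!is.null(cfg$inputs$membership))
    membership <- read.delim(cfg$inputs$membership,
                             stringsAsFactors = FALSE)
  if (!is.null(membership) && nrow(membership)) {
    cmap <- if (!is.null(cfg$category_map))
      read.delim(cfg$category_map, stringsAsFactors = FALSE)
    else default_category_map()
    if (is.null(exchange)) {
      if (is.null(scfg))
        stop_sagnet("sagnet_config_error",
                    "file-driven runs need an `exchange` input")
      exchange <- simulate_exchange_table(membership, scfg,
                                          category_map = cmap)
    }
    exchange <- validate_exchange_table(exchange)
    scores <- score_subcommunities(exchange, membership)
    write_stage_tsv(scores, file.path(outdir, "subcommunity_scores.tsv"),
                    "crossfeeding")
    score_test <- if (length(unique(scores$group)) == 2 &&
                      all(table(scores$group) >= 2))
      compare_groups_bh(list(normalized_score = list(
        values = scores$normalized_score, groups = scores$group)))
    else NULL
    prof <- if (length(unique(membership$community_id)) >= 3)
      category_profiles_pca(exchange, membership, cmap)
    else NULL
    if (is.null(prof))
      logf("crossfeeding: < 3 sub-communities, category PCA skipped")
    else
      write_stage_tsv(prof$profile,
                      file.path(outdir, "category_profile.tsv"),
                      "crossfeeding")
    cat_test <- if (!is.null(prof) && !is.null(prof$groups) &&
                    length(unique(prof$groups)) == 2 &&
                    all(table(prof$groups) >= 2))
      category_group_test(prof$profile, prof$groups)
    else NULL
    if (!is.null(cat_test))
      write_stage_tsv(cat_test, file.path(outdir, "category_tests.tsv"),
                      "crossfeeding")
    summary$crossfeeding <- list(
      n_subcommunities = nrow(scores),
      normalized_score_test = if (!is.null(score_test))
        score_test[c("feature", "statistic", "p", "percent_diff")],
      dim1_variance = if (!is.null(prof))
        prof$pca$explained_variance_ratio[1],
      top_dim1_category = if (!is.null(prof))
        rownames(prof$pca$contributions)[
          which.max(prof$pca$contributions[, 1])],
      category_tests = if (!is.null(cat_test)) cat_test)
    logf("crossfeeding: %d sub-communities scored", nrow(scores))
  }

  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, na = "null",
                       pretty = TRUE)
  logf("pipeline complete")
  invisible(summary)
}

# abundance-table taxa interleaved across groups so both per-group networks
# have planted structure when the block spec spans the low indices
abundance_taxa <- function(sags, n_taxa) {
  byg <- split(sags$sag_id, sags$group)
  half <- ceiling(n_taxa / 2)
  d <- byg[["C-depleted"]]; e <- byg[["C-enriched"]]
  if (length(d) < half || length(e) < n_taxa - half)
    stop_sagnet("sagnet_config_error",
                "n_taxa exceeds the available SAGs per group")
  c(d[seq_len(half)], e[seq_len(n_taxa - half)])
}
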