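#' Quality-filter a SAG catalog
#'
#' Retains genomes with completeness at or above `min_completeness` and
#' contamination at or below `max_contamination` (both boundaries
#' inclusive). Counts retained and removed per group are reported via
#' `message()`.
#'
#' @param records data.frame of SAG records with `completeness` and
#'   `contamination` columns (percent scales).
#' @param min_completeness minimum completeness, percent. Default 50.
#' @param max_contamination maximum contamination, percent. Default 10.
#' @return the filtered data.frame (possibly zero rows, with a warning).
#' @examples
#' sags <- simulate_sag_catalog(sim_config(n_per_group = 10, seed = 1))$sags
#' nrow(qc_filter(sags))
#' @export
qc_filter <- function(records, min_completeness = 50, max_contamination = 10) {
  if (!nrow(records))
    stop_sagnet("sagnet_input_error", "empty SAG table")
  keep <- records$completeness >= min_completeness &
    records$contamination <= max_contamination
  if ("group" %in% names(records)) {
    tab <- table(records$group, factor(keep, levels = c(TRUE, FALSE)))
    for (g in rownames(tab))
      message(sprintf("qc_filter: %s: retained %d, removed %d",
                      g, tab[g, "TRUE"], tab[g, "FALSE"]))
  }
  out <- records[keep, , drop = FALSE]
  if (!nrow(out)) warning("qc_filter: no genomes pass the quality filter")
  out
}

#' Completeness-corrected genome size
#'
#' `estimated size = assembly_length / (completeness / 100)`, so a genome
#' assembled to 3 Mb at 75% completeness is estimated at 4 Mb. Vectorized.
#'
#' @param assembly_length assembly length in bp (> 0).
#' @param completeness completeness percent in (0, 100].
#' @return estimated genome size in bp; always >= `assembly_length`.
#' @export
estimate_genome_size <- function(assembly_length, completeness) {
  if (any(completeness <= 0) || any(completeness > 100))
    stop_sagnet("sagnet_domain_error", "completeness must lie in (0, 100]")
  assembly_length / (completeness / 100)
}

#' Flag unusually large genomes
#'
#' Marks genomes whose estimated size exceeds `Q3 + 3 * IQR` of the pooled
#' size distribution. Flagged genomes are retained by default; removal is
#' behind the explicit `remove` flag.
#'
#' @param records SAG data.frame with an `estimated_size` column.
#' @param remove drop flagged genomes instead of only flagging them.
#' @return `records` with a logical `size_outlier` column (or with flagged
#'   rows removed when `remove = TRUE`).
#' @export
flag_large_genomes <- function(records, remove = FALSE) {
  qs <- quantile(records$estimated_size, c(0.25, 0.75), names = FALSE)
  cut <- qs[2] + 3 * (qs[2] - qs[1])
  records$size_outlier <- records$estimated_size > cut
  if (remove) records[!records$size_outlier, , drop = FALSE] else records
}

#' Fit the log-log CDS-size scaling law and attribute residuals
#'
#' Ordinary least squares of `log10(cds_count)` on `log10(estimated_size)`
#' over all retained genomes pooled (one common line for both groups, so the
#' per-group residual distributions are directly comparable). Residuals are
#' observed minus fitted log10 CDS per genome.
#'
#' @param records SAG data.frame with positive `estimated_size` and
#'   `cds_count`.
#' @return object of class `scaling_fit`: list with `slope`, `intercept`,
#'   `r2`, and named `residuals`.
#' @export
fit_scaling_residuals <- function(records) {
  bad <- which(records$estimated_size <= 0 | records$cds_count <= 0)
  if (length(bad))
    stop_sagnet("sagnet_domain_error",
                paste("non-positive size or CDS count for record(s):",
                      paste(records$sag_id[bad], collapse = ", ")))
  if (nrow(records) < 2)
    stop_sagnet("sagnet_input_error", "need at least 2 genomes to fit")
  x <- log10(records$estimated_size)
  y <- log10(records$cds_count)
  fit <- stats::lm(y ~ x)
  res <- stats::residuals(fit)
  names(res) <- records$sag_id
  r2 <- if (var(y) > 0) summary(fit)$r.squared else 1
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = r2, residuals = res),
            class = "scaling_fit")
}

#' Kruskal-Wallis group comparisons with BH correction
#'
#' Runs a tie-corrected Kruskal-Wallis test (chi-squared approximation) per
#' feature and adjusts the resulting p-values with Benjamini-Hochberg across
#' the submitted feature family. Also reports per-group medians and means
#' and the percent difference of group means,
#' `(mean_enriched - mean_depleted) / mean_depleted * 100` when the groups
#' are the two canonical labels (otherwise second group vs first).
#'
#' @param features named list; each element is `list(values =, groups =)`
#'   with parallel vectors.
#' @return data.frame: feature, statistic (H), df, p, q, percent_diff, plus
#'   per-group median/mean columns.
#' @examples
#' compare_groups_bh(list(size = list(values = c(1, 2, 3, 4, 5, 6),
#'   groups = rep(c("A", "B"), each = 3))))
#' @export
compare_groups_bh <- function(features) {
  if (!length(features))
    stop_sagnet("sagnet_input_error", "no features submitted")
  rows <- lapply(names(features), function(f) {
    v <- features[[f]]$values
    g <- factor(features[[f]]$groups)
    if (nlevels(g) < 2 || any(table(g) < 1))
      stop_sagnet("sagnet_input_error",
                  paste0("feature '", f, "': need >= 2 non-empty groups"))
    kw <- kruskal.test(v, g)
    med <- tapply(v, g, median)
    mn <- tapply(v, g, mean)
    lv <- levels(g)
    ref <- if (all(sag_groups() %in% lv))
      c("C-depleted", "C-enriched") else lv[1:2]
    pd <- (mn[ref[2]] - mn[ref[1]]) / mn[ref[1]] * 100
    out <- data.frame(feature = f, statistic = unname(kw$statistic),
                      df = unname(kw$parameter), p = kw$p.value,
                      percent_diff = unname(pd), stringsAsFactors = FALSE)
    for (l in lv) {
      out[[paste0("median_", l)]] <- unname(med[l])
      out[[paste0("mean_", l)]] <- unname(mn[l])
    }
    out
  })
  res <- do.call(rbind, rows)
  res$q <- p.adjust(res$p, method = "BH")
  res[, c(setdiff(names(res), "q")[1:4], "q",
          setdiff(names(res), c("feature", "statistic", "df", "p", "q")))]
}

#' Group comparison of genome features
#'
#' Convenience wrapper: compares estimated genome size, CDS count and GC
#' content (and scaling residuals when a fit is supplied) between groups
#' with [compare_groups_bh()].
#'
#' @param records QC-filtered SAG data.frame with an `estimated_size`
#'   column.
#' @param fit optional [fit_scaling_residuals()] result whose residuals are
#'   compared as an extra feature.
#' @return data.frame as returned by [compare_groups_bh()].
#' @export
compare_genome_features <- function(records, fit = NULL) {
  g <- records$group
  feats <- list(
    genome_size = list(values = records$estimated_size, groups = g),
    cds_count = list(values = records$cds_count, groups = g),
    gc = list(values = records$gc, groups = g))
  if (!is.null(fit))
    feats$scaling_residual <- list(
      values = unname(fit$residuals[records$sag_id]), groups = g)
  compare_groups_bh(feats)
}
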