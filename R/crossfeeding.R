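#' Read a detailed metabolite-exchange table
#'
#' Parses the detailed per-interaction output dialect: one row per
#' (community, receiver, donor, metabolite) with an exchange score
#' `smetana` in \[0, 1\] and optional component scores `scs`, `mus`, `mps`
#' whose product equals `smetana`.
#'
#' @param path TSV file with header columns at least `community`,
#'   `receiver`, `donor`, `compound`, `smetana`.
#' @param tol tolerance for the component-product identity check.
#' @return data.frame of validated exchange records.
#' @export
read_exchange_table <- function(path, tol = 1e-6) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  validate_exchange_table(df, tol = tol)
}

#' Validate an in-memory exchange table
#'
#' Checks required columns, the \[0, 1\] score range, receiver != donor,
#' and (when all three component columns are present) the identity
#' `scs * mus * mps == smetana` within `tol`. Violations raise errors
#' naming the offending row numbers.
#'
#' @param df exchange data.frame.
#' @param tol component-product tolerance.
#' @return the validated data.frame, invisibly unchanged.
#' @export
validate_exchange_table <- function(df, tol = 1e-6) {
  req <- c("community", "receiver", "donor", "compound", "smetana")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop_sagnet("sagnet_format_error",
                paste("missing required column(s):",
                      paste(missing_cols, collapse = ", ")))
  if (!nrow(df))
    stop_sagnet("sagnet_input_error", "empty exchange table")
  bad <- which(!is.finite(df$smetana) | df$smetana < 0 | df$smetana > 1)
  if (length(bad))
    stop_sagnet("sagnet_format_error",
                paste("smetana outside [0, 1] at row(s):",
                      paste(head(bad, 10), collapse = ", ")))
  self <- which(df$receiver == df$donor)
  if (length(self))
    stop_sagnet("sagnet_format_error",
                paste("receiver equals donor at row(s):",
                      paste(head(self, 10), collapse = ", ")))
  comp <- c("scs", "mus", "mps")
  if (all(comp %in% names(df))) {
    have <- stats::complete.cases(df[comp])
    prod_ <- df$scs * df$mus * df$mps
    off <- which(have & abs(prod_ - df$smetana) > tol)
    if (length(off))
      stop_sagnet("sagnet_format_error",
                  paste("scs*mus*mps != smetana at row(s):",
                        paste(head(off, 10), collapse = ", ")))
  }
  df
}

#' Aggregate exchange scores into sub-community sum and normalized scores
#'
#' The sum score of a sub-community is the sum of the exchange scores over
#' all of its detailed rows (every receiver-donor-metabolite triple); the
#' size-normalized score divides it by the number of member genomes. A
#' community with no records scores 0 on both.
#'
#' @param records validated exchange data.frame.
#' @param membership data.frame `community_id`, `genome_id` and optionally
#'   `group`.
#' @return data.frame: community_id, group (if supplied), size, sum_score,
#'   normalized_score.
#' @examples
#' recs <- data.frame(community = "c1", receiver = c("a", "b", "c"),
#'   donor = c("b", "c", "a"), compound = "M_ala__L_e",
#'   smetana = c(0.5, 0.25, 0.25))
#' mem <- data.frame(community_id = "c1", genome_id = c("a", "b", "c", "d"))
#' score_subcommunities(recs, mem)  # sum 1, normalized 0.25
#' @export
score_subcommunities <- function(records, membership) {
  sizes <- table(membership$community_id)
  if (any(sizes == 0))
    stop_sagnet("sagnet_input_error", "community with zero members")
  unknown <- setdiff(unique(records$community), names(sizes))
  if (length(unknown))
    stop_sagnet("sagnet_input_error",
                paste("records reference unknown community(ies):",
                      paste(unknown, collapse = ", ")))
  comms <- names(sizes)
  sums <- vapply(comms, function(cid)
    sum(records$smetana[records$community == cid]), numeric(1))
  out <- data.frame(community_id = comms, size = as.integer(sizes[comms]),
                    sum_score = unname(sums),
                    stringsAsFactors = FALSE)
  out$normalized_score <- out$sum_score / out$size
  if ("group" %in% names(membership)) {
    gmap <- unique(membership[c("community_id", "group")])
    out$group <- gmap$group[match(out$community_id, gmap$community_id)]
    out <- out[, c("community_id", "group", "size", "sum_score",
                   "normalized_score")]
  }
  rownames(out) <- NULL
  out
}

#' Metabolite-category exchange profiles and PCA
#'
#' Sums exchange scores per sub-community and metabolite category
#' (unmapped metabolites fall into `other`, with a message), so each row sum
#' equals the sub-community's sum score. The profile matrix is
#' column-standardized (zero mean, unit variance; zero-variance categories
#' are dropped with a message) and decomposed by singular-value PCA. The
#' contribution of category j to dimension d is
#' `100 * loading_jd^2 / sum_j loading_jd^2`.
#'
#' @param records validated exchange data.frame.
#' @param membership data.frame `community_id`, `genome_id`, optional
#'   `group`.
#' @param category_map data.frame `metabolite_id`, `category`.
#' @return list with `profile` (sub-communities x categories matrix),
#'   `groups` (named vector, when supplied), and `pca` (list: scores,
#'   loadings, explained_variance_ratio, contributions).
#' @export
category_profiles_pca <- function(records, membership,
                                  category_map = default_category_map()) {
  cat_of <- category_map$category[match(records$compound,
                                        category_map$metabolite_id)]
  n_un <- sum(is.na(cat_of))
  if (n_un)
    message("category_profiles_pca: ", n_un,
            " record(s) with unmapped metabolites assigned to 'other'")
  cat_of[is.na(cat_of)] <- "other"
  comms <- unique(membership$community_id)
  cats <- union(unique(category_map$category), "other")
  prof <- matrix(0, length(comms), length(cats),
                 dimnames = list(comms, cats))
  agg <- tapply(records$smetana,
                list(factor(records$community, levels = comms),
                     factor(cat_of, levels = cats)), sum)
  agg[is.na(agg)] <- 0
  prof[] <- agg
  if (all(prof == 0))
    stop_sagnet("sagnet_degenerate_error", "all-zero profile matrix")
  if (nrow(prof) < 3)
    stop_sagnet("sagnet_input_error", "need >= 3 sub-communities for PCA")
  keep <- apply(prof, 2, sd) > 0
  if (any(!keep))
    message("category_profiles_pca: dropping ", sum(!keep),
            " zero-variance category column(s)")
  z <- scale(prof[, keep, drop = FALSE])
  pc <- prcomp(z, center = FALSE, scale. = FALSE)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  contrib <- 100 * sweep(pc$rotation^2, 2,
                         colSums(pc$rotation^2), "/")
  groups <- NULL
  if ("group" %in% names(membership)) {
    gmap <- unique(membership[c("community_id", "group")])
    groups <- setNames(gmap$group, gmap$community_id)[comms]
  }
  list(profile = prof, groups = groups,
       pca = list(scores = pc$x, loadings = pc$rotation,
                  explained_variance_ratio = evr,
                  contributions = contrib))
}

#' Per-category group comparison of exchange potential
#'
#' For each metabolite category, compares the per-sub-community category
#' scores between the two groups with a Kruskal-Wallis test and reports the
#' fold change `log2fc = log2((mean_E + eps) / (mean_D + eps))` with
#' `eps = 0.5 * min positive score`. Categories observed in only one group
#' are flagged `exclusive` (not tested); categories absent everywhere are
#' dropped. BH correction across tested categories.
#'
#' @param profile sub-communities x categories matrix from
#'   [category_profiles_pca()].
#' @param groups named vector sub-community -> group label (two labels,
#'   each with >= 2 sub-communities).
#' @return data.frame: category, log2fc, p, q, exclusive, exclusive_group.
#' @export
category_group_test <- function(profile, groups) {
  g <- groups[rownames(profile)]
  lv <- sort(unique(g))  # deterministic label order: fc is lv[2] over lv[1]
  if (length(lv) != 2 || any(table(g) < 2))
    stop_sagnet("sagnet_input_error",
                "need two groups with >= 2 sub-communities each")
  if (all(sag_groups() %in% lv)) lv <- sag_groups()
  pos <- profile[profile > 0]
  eps <- if (length(pos)) 0.5 * min(pos) else 0.5
  rows <- lapply(colnames(profile), function(cat_) {
    v <- profile[, cat_]
    if (all(v == 0)) return(NULL)  # absent everywhere: dropped
    seen <- vapply(lv, function(l) any(v[g == l] > 0), logical(1))
    if (sum(seen) == 1)
      return(data.frame(category = cat_, log2fc = NA_real_, p = NA_real_,
                        exclusive = TRUE, exclusive_group = lv[seen],
                        stringsAsFactors = FALSE))
    mE <- mean(v[g == lv[2]]); mD <- mean(v[g == lv[1]])
    kw <- kruskal.test(v, factor(g))
    data.frame(category = cat_, log2fc = log2((mE + eps) / (mD + eps)),
               p = kw$p.value, exclusive = FALSE,
               exclusive_group = NA_character_, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res))
    stop_sagnet("sagnet_degenerate_error", "no category with any signal")
  res$q <- NA_real_
  res$q[!res$exclusive] <- p.adjust(res$p[!res$exclusive], method = "BH")
  rownames(res) <- NULL
  res[, c("category", "log2fc", "p", "q", "exclusive", "exclusive_group")]
}
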