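#' CAZyme presence/absence matrix and Jaccard functional distances
#'
#' Collapses an annotation table (one row per CAZyme hit; duplicates allowed)
#' into a binary genomes x families matrix and computes the pairwise Jaccard
#' distance `d(i, j) = 1 - |F_i intersect F_j| / |F_i union F_j|` between
#' genome family sets. A genome with no annotations is retained with an
#' empty set; two empty sets are at distance 0 (identical emptiness), an
#' empty vs a non-empty set at distance 1.
#'
#' @param annotations data.frame with columns `genome_id` and `family`, or a
#'   binary matrix already in genomes x families form.
#' @param genomes optional character vector forcing the genome universe
#'   (genomes without annotations get all-zero rows).
#' @return list with `presence` (binary matrix) and `distance` (square
#'   symmetric matrix, zero diagonal, entries in \[0, 1\]).
#' @examples
#' ann <- data.frame(genome_id = c("g1", "g1", "g2", "g2"),
#'                   family = c("GH1", "GT2", "GT2", "CE7"))
#' jaccard_distances(ann)$distance["g1", "g2"]  # 1 - 1/3
#' @export
jaccard_distances <- function(annotations, genomes = NULL) {
  if (is.matrix(annotations)) {
    pm <- (annotations != 0) * 1L
  } else {
    if (!all(c("genome_id", "family") %in% names(annotations)))
      stop_sagnet("sagnet_input_error",
                  "annotations need genome_id and family columns")
    gl <- genomes %||% unique(annotations$genome_id)
    fl <- unique(annotations$family)
    pm <- matrix(0L, length(gl), length(fl), dimnames = list(gl, fl))
    pm[cbind(match(annotations$genome_id, gl),
             match(annotations$family, fl))] <- 1L
  }
  if (anyDuplicated(rownames(pm)) || anyDuplicated(colnames(pm)))
    stop_sagnet("sagnet_input_error", "duplicate genome or family labels")
  if (nrow(pm) < 2)
    stop_sagnet("sagnet_input_error", "need >= 2 genomes")
  inter <- tcrossprod(pm)                       # |F_i intersect F_j|
  sizes <- rowSums(pm)
  uni <- outer(sizes, sizes, "+") - inter       # |F_i union F_j|
  d <- ifelse(uni > 0, 1 - inter / uni, 0)      # two empty sets -> 0
  diag(d) <- 0
  list(presence = pm, distance = d)
}

#' Patristic distances between tree tips
#'
#' Sum of branch lengths along the path between every pair of tips.
#'
#' @param tree phylo object with branch lengths.
#' @return square symmetric matrix of patristic distances, tips as labels.
#' @export
patristic_distances <- function(tree) {
  if (!inherits(tree, "phylo"))
    stop_sagnet("sagnet_input_error", "tree must be a phylo object")
  if (is.null(tree$edge.length))
    stop_sagnet("sagnet_input_error", "tree has no branch lengths")
  if (anyDuplicated(tree$tip.label))
    stop_sagnet("sagnet_input_error", "duplicated tip labels")
  if (length(tree$tip.label) < 2)
    stop_sagnet("sagnet_input_error", "need >= 2 tips")
  ape::cophenetic.phylo(tree)
}

#' Per-group association between functional and phylogenetic distance
#'
#' Within each group, regresses functional distance on phylogenetic distance
#' over the upper-triangle genome pairs (least-squares slope and r
#' squared) and assesses significance with a Mantel permutation test:
#' genome labels of one matrix are permuted `n_perm` times and the two-sided
#' pseudo p-value is `(b + 1) / (B + 1)` where `b` counts permuted |r| at or
#' above the observed.
#'
#' @param dphylo,dfunc square distance matrices with identical label sets.
#' @param groups named character vector genome id -> group label.
#' @param n_perm Mantel permutations (default 999).
#' @param seed RNG seed for the permutations.
#' @return data.frame per group: slope, r2, mantel_r, mantel_p, n_genomes,
#'   and `degenerate` (TRUE when either matrix is constant within the group,
#'   in which case the association is undefined and statistics are NA).
#' @export
phylo_function_association <- function(dphylo, dfunc, groups,
                                       n_perm = 999, seed = NULL) {
  ids <- rownames(dphylo)
  if (!setequal(ids, rownames(dfunc)) || !setequal(ids, names(groups)))
    stop_sagnet("sagnet_input_error", "label sets of inputs do not match")
  dfunc <- dfunc[ids, ids]
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(unique(groups), function(g) {
    sel <- ids[groups[ids] == g]
    if (length(sel) < 4)
      stop_sagnet("sagnet_input_error",
                  paste0("group '", g, "': need >= 4 genomes"))
    dp <- dphylo[sel, sel]; df <- dfunc[sel, sel]
    ut <- upper.tri(dp)
    x <- dp[ut]; y <- df[ut]
    if (sd(x) == 0 || sd(y) == 0)
      return(data.frame(group = g, slope = NA_real_, r2 = NA_real_,
                        mantel_r = NA_real_, mantel_p = NA_real_,
                        n_genomes = length(sel), degenerate = TRUE))
    fit <- stats::lm(y ~ x)
    robs <- cor(x, y)
    b <- 0L
    for (i in seq_len(n_perm)) {
      pidx <- sample(length(sel))
      rp <- cor(dp[pidx, pidx][ut], y)
      if (abs(rp) >= abs(robs) - 1e-12) b <- b + 1L
    }
    data.frame(group = g, slope = unname(stats::coef(fit)[2]),
               r2 = summary(fit)$r.squared, mantel_r = robs,
               mantel_p = (b + 1) / (n_perm + 1),
               n_genomes = length(sel), degenerate = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-family presence/absence enrichment between two groups
#'
#' For each CAZyme family, builds the 2x2 present/absent by group table and
#' tests it with a two-sided Fisher exact test. The effect size is a
#' Haldane-corrected prevalence log-ratio,
#' `log2fc = log2(((a + 0.5) / (n1 + 1)) / ((c + 0.5) / (n2 + 1)))` with `a`,
#' `c` the presence counts and `n1`, `n2` the group sizes (group 1 =
#' C-enriched when present, otherwise the first label). BH correction is
#' applied across families; a family is flagged significant at `q <= 0.05`
#' and `|log2fc| >= 1`. Families absent from every genome are dropped with
#' a message.
#'
#' @param pm binary presence matrix, genomes x families.
#' @param groups named character vector genome id -> group label (exactly
#'   two labels, each with >= 2 genomes).
#' @return data.frame: family, present_1, present_2, n_1, n_2, log2fc, p,
#'   q, direction, significant.
#' @export
family_enrichment <- function(pm, groups) {
  ids <- rownames(pm)
  if (!setequal(ids, names(groups)))
    stop_sagnet("sagnet_input_error", "matrix rows do not match groups")
  g <- groups[ids]
  lv <- unique(g)
  if (length(lv) != 2 || any(table(g) < 2))
    stop_sagnet("sagnet_input_error",
                "need exactly two groups with >= 2 genomes each")
  if ("C-enriched" %in% lv) lv <- c("C-enriched", setdiff(lv, "C-enriched"))
  n1 <- sum(g == lv[1]); n2 <- sum(g == lv[2])
  empty <- colSums(pm) == 0
  if (any(empty))
    message("family_enrichment: dropping ", sum(empty),
            " family(ies) absent from all genomes")
  pm <- pm[, !empty, drop = FALSE]
  a <- colSums(pm[g == lv[1], , drop = FALSE])
  c_ <- colSums(pm[g == lv[2], , drop = FALSE])
  p <- vapply(seq_along(a), function(k)
    fisher.test(matrix(c(a[k], n1 - a[k], c_[k], n2 - c_[k]), 2))$p.value,
    numeric(1))
  log2fc <- log2(((a + 0.5) / (n1 + 1)) / ((c_ + 0.5) / (n2 + 1)))
  q <- p.adjust(p, method = "BH")
  data.frame(family = colnames(pm), present_1 = unname(a),
             present_2 = unname(c_), n_1 = n1, n_2 = n2,
             log2fc = unname(log2fc), p = unname(p), q = unname(q),
             direction = ifelse(log2fc >= 0, lv[1], lv[2]),
             significant = unname(q <= 0.05 & abs(log2fc) >= 1),
             stringsAsFactors = FALSE)
}
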