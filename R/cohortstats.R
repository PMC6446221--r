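# Cohort-level comparative statistics: strain binning, rank-based two-group
# and multi-group tests, BH FDR, Bonferroni-adjusted Spearman correlation
# matrices, and metabolome group scores/rankings.

#' Collapse binned strains to single pseudo-observations
#'
#' Strains sharing a `bin_group` (e.g. the related Brazilian bioethanol
#' strains) are replaced by one pseudo-observation whose value is the group
#' median (or mean), avoiding pseudo-replication in group tests. Other
#' strains are untouched.
#'
#' @param values named numeric vector (strain -> value).
#' @param metadata strain table with `strain_id`, `bin_group` and a grouping
#'   column.
#' @param group_col metadata column used as group label (default
#'   `"category"`).
#' @param collapse `"median"` (default) or `"mean"`.
#' @return data.frame `strain`, `value`, `group`, `binned`.
#' @export
bin_strains <- function(values, metadata, group_col = "category",
                        collapse = c("median", "mean")) {
  collapse <- match.arg(collapse)
  fun <- if (collapse == "median") stats::median else mean
  md <- metadata[match(names(values), metadata$strain_id), , drop = FALSE]
  out <- data.frame(strain = names(values), value = as.numeric(values),
                    group = md[[group_col]],
                    bin_group = md$bin_group, binned = FALSE,
                    stringsAsFactors = FALSE)
  bins <- unique(out$bin_group[!is.na(out$bin_group)])
  for (bg in bins) {
    idx <- which(out$bin_group %in% bg)
    if (length(idx) < 2) next
    pseudo <- out[idx[1], , drop = FALSE]
    pseudo$strain <- bg
    pseudo$value <- fun(out$value[idx])
    pseudo$binned <- TRUE
    out <- rbind(out[-idx, , drop = FALSE], pseudo)
  }
  rownames(out) <- NULL
  out[, c("strain", "value", "group", "binned")]
}

#' Two-group Wilcoxon rank-sum comparison
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test; exact null distribution
#' for small untied samples, normal approximation with tie correction
#' otherwise (the default behaviour of [stats::wilcox.test()]).
#'
#' @param grouped data.frame `value`, `group` (from [bin_strains()] or
#'   equivalent).
#' @param groups the two group labels to compare.
#' @return list `statistic` (W), `p`, `n` (per-group sizes).
#' @export
compare_two <- function(grouped, groups) {
  assert_that(length(groups) == 2, "exactly two groups required")
  x <- grouped$value[grouped$group == groups[1]]
  y <- grouped$value[grouped$group == groups[2]]
  assert_that(length(x) >= 2 && length(y) >= 2,
              "need >= 2 observations per group")
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = NULL))
  list(statistic = unname(wt$statistic), p = wt$p.value,
       n = stats::setNames(c(length(x), length(y)), groups))
}

#' Kruskal-Wallis comparison across several groups
#'
#' @param grouped data.frame `value`, `group`.
#' @return list `statistic` (H), `p`, `df`, `n`.
#' @export
compare_many <- function(grouped, groups = NULL) {
  if (!is.null(groups)) {
    grouped <- grouped[grouped$group %in% groups, , drop = FALSE]
  }
  g <- factor(grouped$group)
  assert_that(nlevels(g) >= 2, "need at least two groups")
  if (stats::var(grouped$value) == 0) {
    return(list(statistic = 0, p = 1, df = nlevels(g) - 1L,
                n = table(g)))
  }
  kt <- stats::kruskal.test(grouped$value, g)
  list(statistic = unname(kt$statistic), p = kt$p.value,
       df = unname(kt$parameter), n = table(g))
}

#' Benjamini-Hochberg adjusted q-values
#'
#' @param pvals numeric vector of P values in (0, 1].
#' @return numeric vector of step-up adjusted values.
#' @export
bh_fdr <- function(pvals) {
  assert_that(all(pvals > 0 & pvals <= 1), "p-values must lie in (0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Pairwise Spearman correlation matrix with Bonferroni adjustment
#'
#' @param features data.frame or matrix, observations x features; at least 3
#'   complete observations per pair.
#' @return list with matrices `rho` and `p_adj` (Bonferroni over the tested
#'   pairs; constant features give NA entries).
#' @export
spearman_matrix <- function(features) {
  X <- as.matrix(features)
  k <- ncol(X)
  rho <- matrix(NA_real_, k, k, dimnames = list(colnames(X), colnames(X)))
  praw <- rho
  n_pairs <- k * (k - 1) / 2
  for (i in seq_len(k)) {
    rho[i, i] <- 1
    praw[i, i] <- 0
    for (j in seq_len(k)) {
      if (j <= i) next
      ok <- stats::complete.cases(X[, i], X[, j])
      if (sum(ok) < 3 || stats::sd(X[ok, i]) == 0 ||
          stats::sd(X[ok, j]) == 0) next
      ct <- suppressWarnings(
        stats::cor.test(X[ok, i], X[ok, j], method = "spearman"))
      rho[i, j] <- rho[j, i] <- unname(ct$estimate)
      praw[i, j] <- praw[j, i] <- ct$p.value
    }
  }
  list(rho = rho, p_adj = pmin(praw * n_pairs, 1))
}

#' Metabolome group scores and per-group strain rankings
#'
#' Each metabolite's log abundance is centered and scaled across strains;
#' the group score of a strain is the mean z-score over the group's
#' metabolites (the extent to which the group's metabolites sit above or
#' below the across-strain mean). A per-group strain ranking is derived
#' from the scores. For extracellular data a sign of -1 flips scores so that
#' net production ranks above consumption.
#'
#' @param abundance metabolites x strains positive matrix.
#' @param group_map data.frame `metabolite`, `group`.
#' @param sign +1 (default) or -1.
#' @param log_transform take logs before scaling (default TRUE).
#' @return list with `scores` (strains x groups matrix) and `rankings`
#'   (long data.frame from [rank_condition()] per group).
#' @export
metabolome_group_scores <- function(abundance, group_map, sign = 1,
                                    log_transform = TRUE) {
  assert_that(all(abundance > 0), "abundances must be positive")
  M <- if (log_transform) log(abundance) else abundance
  z <- t(scale(t(M)))  # per metabolite across strains
  z[is.nan(z)] <- 0    # constant metabolite -> no contribution
  groups <- unique(group_map$group)
  scores <- matrix(NA_real_, ncol(abundance), length(groups),
                   dimnames = list(colnames(abundance), groups))
  for (g in groups) {
    members <- intersect(group_map$metabolite[group_map$group == g],
                         rownames(abundance))
    if (length(members) == 0) next
    scores[, g] <- sign * colMeans(z[members, , drop = FALSE])
  }
  rankings <- do.call(rbind, lapply(groups, function(g) {
    if (all(is.na(scores[, g]))) return(NULL)
    rank_condition(scores[, g], condition = g, score_type = "metabolome")
  }))
  rownames(rankings) <- NULL
  list(scores = scores, rankings = rankings)
}
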