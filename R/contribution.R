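# Decomposition of gene-level association evidence into the relative
# contributions of the three variant sources (SNP/indel, CNV gain, CNV
# loss), summarized per gene category as barycentric coordinates.

#' Gene x source evidence matrix on the -log10 P scale
#'
#' @param gene_p data.frame from [gene_pvalues()] (columns `gene_id`,
#'   `source`, `p`), restricted to one ranking.
#' @param genes gene ids defining the rows (default: all in `gene_p`).
#' @return matrix genes x 3 (`snp`, `gain`, `loss`) of `-log10(p)`; missing
#'   source evidence is 0.
#' @export
source_matrix <- function(gene_p, genes = NULL) {
  sources <- c("snp", "gain", "loss")
  if (is.null(genes)) genes <- sort(unique(gene_p$gene_id))
  out <- matrix(0, length(genes), 3, dimnames = list(genes, sources))
  gp <- gene_p[gene_p$source %in% sources, , drop = FALSE]
  if (any(gp$p <= 0)) {
    warnf("p = 0 capped at the smallest representable double")
    gp$p <- pmax(gp$p, .Machine$double.xmin)
  }
  ri <- match(gp$gene_id, genes)
  ok <- !is.na(ri)
  out[cbind(ri[ok], match(gp$source[ok], sources))] <- -log10(gp$p[ok])
  out
}

#' Relative source contribution for a gene category
#'
#' Takes the `q` quantile (default the 75% quantile of the genes sorted by P
#' value, i.e. of the `-log10 p` column) of each source's evidence over the
#' category's genes and normalizes the three quantiles to sum to 1.
#'
#' @param mat rows of a [source_matrix()] for one category (>= 4 genes).
#' @param q quantile level.
#' @param category,ranking labels carried into the output.
#' @return one-row data.frame `category`, `ranking`, `q`, `w_snp`, `w_gain`,
#'   `w_loss`, `no_evidence`.
#' @export
category_contribution <- function(mat, q = 0.75, category = NA_character_,
                                  ranking = NA_character_) {
  assert_that(nrow(mat) >= 4, "need at least 4 genes in the category")
  qs <- apply(mat[, c("snp", "gain", "loss"), drop = FALSE], 2,
              stats::quantile, probs = q, names = FALSE)
  tot <- sum(qs)
  if (tot <= 0) {
    w <- c(0, 0, 0)
    no_evidence <- TRUE
  } else {
    w <- qs / tot
    no_evidence <- FALSE
  }
  data.frame(category = category, ranking = ranking, q = q,
             w_snp = w[1], w_gain = w[2], w_loss = w[3],
             no_evidence = no_evidence, stringsAsFactors = FALSE)
}

#' Contribution points for every gene category and ranking
#'
#' @param gene_p data.frame from [gene_pvalues()] including a `ranking`
#'   column.
#' @param gene_categories data.frame `gene_id`, `category` (a gene may
#'   appear under several categories).
#' @param q quantile level (default 0.75).
#' @return data.frame of [category_contribution()] rows.
#' @export
contribution_table <- function(gene_p, gene_categories, q = 0.75) {
  out <- list()
  for (rk in unique(gene_p$ranking)) {
    gp <- gene_p[gene_p$ranking == rk, , drop = FALSE]
    for (cat in unique(gene_categories$category)) {
      ids <- gene_categories$gene_id[gene_categories$category == cat]
      if (length(ids) < 4) next
      mat <- source_matrix(gp, genes = ids)
      out[[length(out) + 1L]] <- category_contribution(mat, q, cat, rk)
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
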