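# EMMA-style linear mixed-model association: spectral REML fit of the
# variance components, P3D/EMMAX-style generalized-least-squares marker
# scan, QQ-departure significance cutoffs, gene-level P assignment and
# genomic window counts.

#' Turn a condition ranking into a phenotype vector
#'
#' Strain rankings serve as phenotypic values; by default they are passed
#' through a rank-based inverse-normal transform (INT) so the LMM normality
#' assumption is reasonable. With `int = FALSE` the raw rank numbers are
#' returned.
#'
#' @param ranking data.frame from [rank_condition()] (columns `strain`,
#'   `rank`).
#' @param int apply the inverse-normal transform (default TRUE).
#' @return named numeric vector (strain -> phenotype).
#' @export
transform_phenotype <- function(ranking, int = TRUE) {
  y <- stats::setNames(ranking$rank, ranking$strain)
  if (!int) return(y)
  n <- length(y)
  stats::setNames(stats::qnorm((y - 0.5) / n), names(y))
}

#' REML fit of the null mixed model by spectral decomposition
#'
#' Fits `y = X0 b + g + e` with `g ~ N(0, sigma_g^2 K)` and
#' `e ~ N(0, sigma_e^2 I)`. After one eigendecomposition of the projected
#' kinship the restricted likelihood is a one-dimensional function of
#' `delta = sigma_e^2 / sigma_g^2`, maximized over a dense grid in
#' `log10(delta)` followed by local refinement.
#'
#' @param y named phenotype vector.
#' @param K kinship matrix (PSD, matching `y` order).
#' @param X0 covariate matrix (default: intercept only).
#' @param delta_grid log10(delta) grid bounds and size.
#' @return object of class `reml_fit` with `delta`, `sigma_g2`, `sigma_e2`,
#'   `reml_loglik`, plus the cached eigendecomposition of `K` for scans.
#' @export
reml_null <- function(y, K, X0 = NULL, delta_grid = c(-5, 5, 100)) {
  n <- length(y)
  assert_that(n >= 5, "need at least 5 observations")
  assert_that(all(dim(K) == c(n, n)), "K dimensions must match y")
  eK <- eigen((K + t(K)) / 2, symmetric = TRUE)
  assert_that(min(eK$values) > -1e-6 * max(abs(eK$values)) - 1e-12,
              "K must be positive semi-definite")
  if (is.null(X0)) X0 <- matrix(1, n, 1)
  q <- ncol(X0)
  S <- diag(n) - X0 %*% solve(crossprod(X0), t(X0))
  eS <- eigen(S %*% ((K + t(K)) / 2) %*% S, symmetric = TRUE)
  xi <- eS$values[seq_len(n - q)]
  eta <- drop(crossprod(eS$vectors[, seq_len(n - q), drop = FALSE], y))
  ll <- function(log10d) {
    d <- 10^log10d
    denom <- xi + d
    0.5 * ((n - q) * (log((n - q) / (2 * pi)) - 1 -
                        log(sum(eta^2 / denom))) - sum(log(denom)))
  }
  grid <- seq(delta_grid[1], delta_grid[2], length.out = delta_grid[3])
  vals <- vapply(grid, ll, numeric(1))
  i <- which.max(vals)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(ll, c(lo, hi), maximum = TRUE, tol = 1e-8)
  if (i == 1L || i == length(grid)) {
    warnf("REML likelihood maximized at the delta grid boundary (flat or unidentifiable ridge)")
  }
  delta <- 10^opt$maximum
  sigma_g2 <- sum(eta^2 / (xi + delta)) / (n - q)
  sigma_e2 <- delta * sigma_g2
  structure(list(delta = delta, sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
                 reml_loglik = opt$objective, y = y, K = K, X0 = X0,
                 eigK = eK, n = n, q = q, loglik_fn = ll),
            class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat(sprintf("reml_fit: delta = %.4g (sigma_g2 = %.4g, sigma_e2 = %.4g), REML logLik = %.4f\n",
              x$delta, x$sigma_g2, x$sigma_e2, x$reml_loglik))
  invisible(x)
}

# Whitening matrix V^{-1/2} for V = sigma_g2 K + sigma_e2 I from a cached
# eigendecomposition of K.
whitener <- function(fit) {
  v <- fit$sigma_g2 * pmax(fit$eigK$values, 0) + fit$sigma_e2
  v <- pmax(v, 1e-10 * max(v))
  fit$eigK$vectors %*% (t(fit$eigK$vectors) / sqrt(v))
}

#' Mixed-model association scan
#'
#' Tests each marker by generalized least squares of the phenotype on
#' `[X0, x]` under the null variance components (P3D/EMMAX-style reuse,
#' `mode = "p3d"`, the default) or with `delta` re-estimated per marker
#' (`mode = "exact"`). Wald t-test P values. Constant markers are skipped;
#' the count is reported in the `n_skipped` attribute.
#'
#' @param y named phenotype vector.
#' @param markers markers x strains numeric matrix (dosages or 0/1 presence),
#'   rownames = unit ids, columns matching `y` order.
#' @param fit `reml_fit` from [reml_null()] (fitted on the same `y`, `K`).
#' @param source label recorded per result row (e.g. "snp", "gain", "loss").
#' @param ranking label of the tested ranking.
#' @param mode `"p3d"` or `"exact"`.
#' @return data.frame `unit`, `source`, `ranking`, `beta`, `se`, `p`.
#' @export
assoc_scan <- function(y, markers, fit, source = "snp",
                       ranking = NA_character_, mode = c("p3d", "exact")) {
  mode <- match.arg(mode)
  assert_that(inherits(fit, "reml_fit"), "fit must come from reml_null()")
  assert_that(ncol(markers) == length(y), "markers/strains mismatch")
  keep <- apply(markers, 1, function(x) stats::sd(x) > 0)
  n_skipped <- sum(!keep)
  markers <- markers[keep, , drop = FALSE]
  n <- length(y)
  q <- ncol(fit$X0)
  res <- vector("list", nrow(markers))
  if (mode == "p3d") {
    W <- whitener(fit)
    yt <- drop(W %*% y)
    X0t <- W %*% fit$X0
    for (i in seq_len(nrow(markers))) {
      xt <- drop(W %*% markers[i, ])
      res[[i]] <- gls_wald(yt, cbind(X0t, xt), n, q)
    }
  } else {
    for (i in seq_len(nrow(markers))) {
      fi <- reml_null(y, fit$K, X0 = cbind(fit$X0, markers[i, ]))
      W <- whitener(fi)
      res[[i]] <- gls_wald(drop(W %*% y), W %*% cbind(fit$X0, markers[i, ]),
                           n, q)
    }
  }
  out <- do.call(rbind, res)
  out <- data.frame(unit = rownames(markers), source = source,
                    ranking = ranking, beta = out[, 1], se = out[, 2],
                    p = out[, 3], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}

# Wald test of the last column's coefficient in an OLS fit (whitened data).
gls_wald <- function(yt, Xt, n, q) {
  XtX <- crossprod(Xt)
  b <- solve(XtX, crossprod(Xt, yt))
  r <- yt - Xt %*% b
  df <- n - ncol(Xt)
  s2 <- sum(r^2) / df
  se <- sqrt(s2 * solve(XtX)[ncol(Xt), ncol(Xt)])
  beta <- b[length(b)]
  tval <- beta / se
  c(beta, se, 2 * stats::pt(-abs(tval), df))
}

#' Assign block-representative P values to all member markers
#'
#' @param assoc result of [assoc_scan()] on block representatives.
#' @param blocks block table from [ld_blocks()].
#' @param assignment marker id -> block id map from [ld_blocks()].
#' @return data.frame with one row per member marker carrying its block's
#'   statistics plus `block_id`.
#' @export
expand_block_pvalues <- function(assoc, blocks, assignment) {
  bi <- match(blocks$block_id[match(assignment, blocks$block_id)],
              blocks$block_id)
  rep_of <- blocks$representative[bi]
  idx <- match(rep_of, assoc$unit)
  out <- assoc[idx, , drop = FALSE]
  out$block_id <- blocks$block_id[bi]
  out$unit <- names(assignment)
  rownames(out) <- NULL
  out[!is.na(idx), , drop = FALSE]
}

#' Significance cutoff from the departure of observed from expected P values
#'
#' Walks from the most significant P value and accepts points while the
#' observed value departs from its expected uniform quantile by at least
#' `eps_log10` on the -log10 scale. The expected value for each step is the
#' rank-1 quantile of the points not yet accepted, `1 / (m - j + 1)` at step
#' `j + 1` of `m` points (so the first comparison is against `1 / (m + 1)`):
#' once a point is accepted it no longer counts toward the null distribution
#' the remaining points are compared with. The threshold is the largest
#' accepted P value; when nothing is accepted the threshold is the 0
#' sentinel (no significant calls).
#'
#' @param pvals numeric vector of P values (>= 20 of them).
#' @param source label stored in the result.
#' @param eps_log10 departure band on the -log10 scale (default 0.5).
#' @return list `source`, `threshold`, `eps_log10`, `n_significant`.
#' @export
qq_cutoff <- function(pvals, source = "snp", eps_log10 = 0.5) {
  assert_that(length(pvals) >= 20, "need at least 20 p-values")
  p <- sort(pvals)
  m <- length(p)
  j <- 0L
  while (j < m) {
    expected <- 1 / (m - j + 1)
    if (-log10(p[j + 1L]) >= -log10(expected) + eps_log10) {
      j <- j + 1L
    } else {
      break
    }
  }
  list(source = source,
       threshold = if (j > 0L) p[j] else 0,
       eps_log10 = eps_log10,
       n_significant = j)
}

#' Gene-level P values from overlapping association units
#'
#' A gene's P value per source is the minimum P over all tested units
#' (markers, LD blocks, CNV markers) overlapping the gene span extended by a
#' strand-aware upstream regulatory window (default 800 bp). Genes with no
#' overlapping unit are missing for that source.
#'
#' @param units data.frame `unit`, `chrom`, `start`, `end` (0-based
#'   half-open; point markers as `[pos, pos + 1)`), `source`, `p`, and
#'   optionally `ranking`.
#' @param genes gene table (`gene_id`, `chrom`, `start`, `end`, `strand`).
#' @param upstream_bp upstream window length.
#' @return data.frame `gene_id`, `source` (and `ranking` if present in
#'   `units`), `p`, `n_units`.
#' @export
gene_pvalues <- function(units, genes, upstream_bp = 800) {
  up <- ifelse(genes$strand == "+", pmax(0, genes$start - upstream_bp),
               genes$start)
  dn <- ifelse(genes$strand == "+", genes$end, genes$end + upstream_bp)
  gr_genes <- GenomicRanges::GRanges(genes$chrom,
                                     IRanges::IRanges(up + 1L, dn))
  gr_units <- GenomicRanges::GRanges(units$chrom,
                                     IRanges::IRanges(units$start + 1L,
                                                      units$end))
  hits <- GenomicRanges::findOverlaps(gr_genes, gr_units)
  if (length(hits) == 0L) {
    return(data.frame(gene_id = character(), source = character(),
                      p = numeric(), n_units = integer(),
                      stringsAsFactors = FALSE))
  }
  d <- data.frame(gene_id = genes$gene_id[S4Vectors::queryHits(hits)],
                  source = units$source[S4Vectors::subjectHits(hits)],
                  p = units$p[S4Vectors::subjectHits(hits)],
                  stringsAsFactors = FALSE)
  keys <- c("gene_id", "source")
  if ("ranking" %in% names(units)) {
    d$ranking <- units$ranking[S4Vectors::subjectHits(hits)]
    keys <- c(keys, "ranking")
  }
  key <- do.call(paste, c(d[keys], sep = "\r"))
  out <- do.call(rbind, lapply(split(d, key), function(x) {
    r <- x[which.min(x$p), , drop = FALSE]
    r$n_units <- nrow(x)
    r
  }))
  rownames(out) <- NULL
  out
}

#' Count significant units per genomic window
#'
#' @param units data.frame `chrom`, `start`, `p`, `source` (and optionally
#'   `ranking`).
#' @param cutoffs list of [qq_cutoff()] results, one per source present.
#' @param window window size in bp (default 50 kb).
#' @return data.frame `chrom`, `window_start`, `window_end`,
#'   `n_significant`, sorted descending by count (hot spots first).
#' @export
genomic_windows <- function(units, cutoffs, window = 50000) {
  thr <- stats::setNames(vapply(cutoffs, `[[`, numeric(1), "threshold"),
                         vapply(cutoffs, `[[`, character(1), "source"))
  sig <- units[units$p <= thr[units$source] & thr[units$source] > 0, ,
               drop = FALSE]
  if (nrow(sig) == 0L) {
    return(data.frame(chrom = character(), window_start = integer(),
                      window_end = integer(), n_significant = integer(),
                      stringsAsFactors = FALSE))
  }
  ws <- floor(sig$start / window) * window
  key <- paste(sig$chrom, ws)
  tab <- table(key)
  parts <- strsplit(names(tab), " ", fixed = TRUE)
  out <- data.frame(chrom = vapply(parts, `[`, "", 1),
                    window_start = as.integer(vapply(parts, `[`, "", 2)),
                    stringsAsFactors = FALSE)
  out$window_end <- out$window_start + as.integer(window)
  out$n_significant <- as.integer(tab)
  out <- out[order(-out$n_significant, out$chrom, out$window_start), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
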