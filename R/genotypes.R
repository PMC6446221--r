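# Variant and CNV handling: genotype matrix container, core-genome/MAF
# filtering, LD-block construction, kinship, CNV interval markers from
# overlap relationships, and CNV-to-gene event assignment.

#' Construct a genotype matrix container
#'
#' Markers x strains dosage codes in {0, 1, 2, NA} with a marker map.
#' Positions in the map are 0-based (VCF positions are converted on read).
#'
#' @param G integer matrix (markers x strains), dosages 0/1/2 or NA.
#' @param map data.frame `id`, `chrom`, `pos`, `ref`, `alt`, `kind`.
#' @param strain_ids strain (column) names.
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(G, map, strain_ids) {
  assert_that(nrow(G) == nrow(map), "G and map row counts differ")
  assert_that(ncol(G) == length(strain_ids), "G columns != strain ids")
  assert_that(all(G %in% c(0L, 1L, 2L, NA)), "dosages must be 0/1/2/NA")
  dimnames(G) <- list(map$id, strain_ids)
  structure(list(G = G, map = map, strains = strain_ids),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d markers x %d strains (%d snp, %d indel)\n",
              nrow(x$G), ncol(x$G), sum(x$map$kind == "snp"),
              sum(x$map$kind == "indel")))
  invisible(x)
}

#' Minor-allele frequencies of a genotype matrix
#' @param gm a [genotype_matrix()].
#' @return numeric vector in \[0, 0.5\], one per marker.
#' @export
marker_maf <- function(gm) {
  af <- rowMeans(gm$G, na.rm = TRUE) / 2
  pmin(af, 1 - af)
}

#' Per-strain heterozygosity fraction
#'
#' Fraction of a strain's non-reference genotype calls that are heterozygous.
#' @param gm a [genotype_matrix()].
#' @return named numeric vector in \[0, 1\].
#' @export
strain_heterozygosity <- function(gm) {
  apply(gm$G, 2, function(g) {
    nv <- sum(g > 0, na.rm = TRUE)
    if (nv == 0) return(0)
    sum(g == 1, na.rm = TRUE) / nv
  })
}

#' Write a genotype matrix as a minimal VCF
#'
#' Biallelic records with GT-only FORMAT; internal 0-based positions are
#' written 1-based as VCF requires.
#'
#' @param gm a [genotype_matrix()].
#' @param path output path.
#' @export
write_vcf <- function(gm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", gm$strains), collapse = "\t")), con)
  gt <- c("0/0", "0/1", "1/1")
  for (i in seq_len(nrow(gm$G))) {
    calls <- ifelse(is.na(gm$G[i, ]), "./.", gt[gm$G[i, ] + 1L])
    writeLines(paste(c(gm$map$chrom[i], gm$map$pos[i] + 1L, gm$map$id[i],
                       gm$map$ref[i], gm$map$alt[i], ".", "PASS", ".", "GT",
                       calls), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a VCF into a genotype matrix
#'
#' Biallelic SNP/indel records only; multiallelic records are skipped with a
#' warning. Dosage is taken from the GT field (0/0 = 0, 0/1 or 1/0 = 1,
#' 1/1 = 2, missing = NA); phased separators are accepted.
#'
#' @param path VCF path.
#' @return a [genotype_matrix()] with 0-based positions.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt_raw <- v@gt
  assert_that(!is.null(gt_raw) && "FORMAT" %in% colnames(gt_raw),
              "VCF has no genotype (FORMAT) field")
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    warnf("skipping %d multiallelic record(s)", sum(multi))
  }
  keep <- which(!multi)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1,
                                     dimnames = list(NULL, names(gt)))
  to_dosage <- function(x) {
    x <- gsub("|", "/", x, fixed = TRUE)
    d <- rep(NA_integer_, length(x))
    d[x %in% "0/0"] <- 0L
    d[x %in% c("0/1", "1/0")] <- 1L
    d[x %in% "1/1"] <- 2L
    d
  }
  G <- apply(gt[keep, , drop = FALSE], 2, to_dosage)
  if (is.null(dim(G))) G <- matrix(G, nrow = length(keep))
  ref <- fix[keep, "REF"]
  alt <- fix[keep, "ALT"]
  map <- data.frame(
    id = ifelse(is.na(fix[keep, "ID"]) | fix[keep, "ID"] == ".",
                sprintf("m%05d", seq_along(keep)), fix[keep, "ID"]),
    chrom = fix[keep, "CHROM"],
    pos = as.integer(fix[keep, "POS"]) - 1L,
    ref = ref, alt = alt,
    kind = ifelse(nchar(ref) == 1 & nchar(alt) == 1, "snp", "indel"),
    stringsAsFactors = FALSE
  )
  genotype_matrix(G, map, colnames(gt))
}

#' Restrict markers to core-genome regions and filter by MAF
#'
#' Keeps markers whose position falls inside the (normalized) core mask and
#' whose minor-allele frequency is strictly greater than `maf_min`; marker
#' order is preserved.
#'
#' @param gm a [genotype_matrix()].
#' @param mask data.frame `chrom`, `start`, `end` (0-based half-open), or
#'   NULL to skip the mask.
#' @param maf_min MAF threshold (strict `>`), default 0.05.
#' @return filtered [genotype_matrix()].
#' @export
filter_core_maf <- function(gm, mask = NULL, maf_min = 0.05) {
  keep <- marker_maf(gm) > maf_min
  if (!is.null(mask)) {
    mask <- normalize_intervals(mask)
    keep <- keep & points_in_intervals(gm$map$chrom, gm$map$pos, mask)
  }
  if (!any(keep)) warnf("no markers survive the core/MAF filter")
  genotype_matrix(gm$G[keep, , drop = FALSE],
                  gm$map[keep, , drop = FALSE], gm$strains)
}

# r^2 between two dosage vectors over complete pairs.
dosage_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(0)
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(0)
  stats::cor(x[ok], y[ok])^2
}

#' Build LD blocks by greedy left-to-right chaining
#'
#' Walking along each chromosome in position order, the current block is
#' extended while the next marker lies within `max_gap_bp` of the block's
#' last member and has `r^2 >= r2_min` with the block's representative
#' marker. The representative is the highest-MAF member so far (ties go to
#' the leftmost). Singletons are blocks of one.
#'
#' @param gm a [genotype_matrix()] (markers sorted by position per chrom).
#' @param r2_min r-squared threshold (default 0.8).
#' @param max_gap_bp maximum gap between consecutive members (default 20 kb).
#' @return list with `blocks` (data.frame `block_id`, `chrom`, `start`,
#'   `end`, `n_members`, `representative`), `assignment` (marker id ->
#'   block_id) and `representatives` (a [genotype_matrix()] of block
#'   representatives).
#' @export
ld_blocks <- function(gm, r2_min = 0.8, max_gap_bp = 20000) {
  maf <- marker_maf(gm)
  blocks <- list()
  assignment <- stats::setNames(character(nrow(gm$map)), gm$map$id)
  for (cc in unique(gm$map$chrom)) {
    idx <- which(gm$map$chrom == cc)
    idx <- idx[order(gm$map$pos[idx])]
    cur <- idx[1]
    rep_i <- idx[1]
    flush <- function(members, rep_i) {
      bid <- sprintf("blk%04d", length(blocks) + 1L)
      blocks[[length(blocks) + 1L]] <<- data.frame(
        block_id = bid, chrom = cc,
        start = min(gm$map$pos[members]), end = max(gm$map$pos[members]) + 1L,
        n_members = length(members),
        representative = gm$map$id[rep_i], stringsAsFactors = FALSE)
      assignment[gm$map$id[members]] <<- bid
    }
    members <- idx[1]
    for (i in idx[-1]) {
      gap_ok <- gm$map$pos[i] - gm$map$pos[members[length(members)]] <= max_gap_bp
      if (gap_ok && dosage_r2(gm$G[rep_i, ], gm$G[i, ]) >= r2_min) {
        members <- c(members, i)
        if (maf[i] > maf[rep_i]) rep_i <- i
      } else {
        flush(members, rep_i)
        members <- i
        rep_i <- i
      }
    }
    flush(members, rep_i)
  }
  blocks <- do.call(rbind, blocks)
  rownames(blocks) <- NULL
  rep_idx <- match(blocks$representative, gm$map$id)
  reps <- genotype_matrix(gm$G[rep_idx, , drop = FALSE],
                          gm$map[rep_idx, , drop = FALSE], gm$strains)
  list(blocks = blocks, assignment = assignment, representatives = reps)
}

#' Kinship matrix (VanRaden-style genomic relationship matrix)
#'
#' Centered and scaled genotype cross-product over non-constant markers,
#' normalized so the mean diagonal is 1; positive semi-definiteness is
#' enforced by clipping tiny negative eigenvalues.
#'
#' @param gm a [genotype_matrix()] with at least 2 strains.
#' @param method `"vanraden"` (default) or `"ibs"` (allele-sharing).
#' @return list with `K` (strain x strain matrix) and `n_markers` used.
#' @export
kinship <- function(gm, method = c("vanraden", "ibs")) {
  method <- match.arg(method)
  assert_that(ncol(gm$G) >= 2, "need at least 2 strains")
  G <- gm$G
  G[is.na(G)] <- matrix(rowMeans(G, na.rm = TRUE),
                        nrow(G), ncol(G))[is.na(G)]
  p <- rowMeans(G) / 2
  keep <- p > 0 & p < 1
  G <- G[keep, , drop = FALSE]
  p <- p[keep]
  assert_that(nrow(G) >= 1, "no polymorphic markers for kinship")
  if (method == "vanraden") {
    Z <- (G - 2 * p) / sqrt(2 * p * (1 - p))
    K <- crossprod(Z) / nrow(Z)
  } else {
    # mean identity-by-state similarity, rescaled to [0, 1]
    n <- ncol(G)
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      K[i, ] <- 1 - colMeans(abs(G - G[, i])) / 2
    }
  }
  K <- K / mean(diag(K))
  eg <- eigen((K + t(K)) / 2, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  K <- eg$vectors %*% (vals * t(eg$vectors))
  dimnames(K) <- list(gm$strains, gm$strains)
  list(K = (K + t(K)) / 2, n_markers = nrow(G))
}

#' Build CNV markers from overlap relationships of per-strain segments
#'
#' All strains' intervals of one event type are pooled, the genome is cut at
#' the union of their breakpoints into atomic segments, each atomic segment
#' gets the presence vector of the strains whose interval covers it, and
#' adjacent atomic segments with identical presence vectors are merged.
#' Constant markers and markers whose minor presence class is rarer than
#' `min_class_frac` are dropped. Gain and loss events are handled in
#' separate calls.
#'
#' @param segments CNV segment data.frame (`chrom`, `start`, `end`,
#'   `strain`, `event`); deletion segments count as losses.
#' @param strains character vector of all strain ids (defines the marker
#'   presence columns).
#' @param event `"gain"` or `"loss"`.
#' @param min_class_frac minimum minor presence-class frequency.
#' @return list with `markers` (data.frame `marker_id`, `chrom`, `start`,
#'   `end`, `event`, `n_present`) and `presence` (markers x strains 0/1
#'   matrix).
#' @export
cnv_markers <- function(segments, strains, event = c("gain", "loss"),
                        min_class_frac = 0.05) {
  event <- match.arg(event)
  want <- if (event == "loss") c("loss", "deletion") else "gain"
  seg <- segments[segments$event %in% want, , drop = FALSE]
  empty <- list(
    markers = data.frame(marker_id = character(), chrom = character(),
                         start = integer(), end = integer(),
                         event = character(), n_present = integer(),
                         stringsAsFactors = FALSE),
    presence = matrix(0L, 0, length(strains),
                      dimnames = list(NULL, strains)))
  if (nrow(seg) == 0L) return(empty)
  rows <- list()
  pres <- list()
  for (cc in unique(seg$chrom)) {
    d <- seg[seg$chrom == cc, , drop = FALSE]
    bp <- sort(unique(c(d$start, d$end)))
    if (length(bp) < 2L) next
    starts <- bp[-length(bp)]
    ends <- bp[-1]
    # presence: a strain covers an atomic segment iff one of its intervals
    # contains it (any overlap is full cover, by construction of the cuts)
    P <- matrix(0L, length(starts), length(strains),
                dimnames = list(NULL, strains))
    for (k in seq_len(nrow(d))) {
      hit <- which(starts >= d$start[k] & ends <= d$end[k])
      P[hit, d$strain[k]] <- 1L
    }
    # drop atomic segments covered by nobody, then merge adjacent identical
    occ <- rowSums(P) > 0
    runs <- list()
    i <- 1L
    while (i <= length(starts)) {
      if (!occ[i]) { i <- i + 1L; next }
      j <- i
      while (j + 1L <= length(starts) && occ[j + 1L] &&
             ends[j] == starts[j + 1L] &&
             all(P[j + 1L, ] == P[i, ])) {
        j <- j + 1L
      }
      runs[[length(runs) + 1L]] <- c(i, j)
      i <- j + 1L
    }
    for (r in runs) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = cc, start = starts[r[1]], end = ends[r[2]], event = event,
        stringsAsFactors = FALSE)
      pres[[length(pres) + 1L]] <- P[r[1], ]
    }
  }
  if (length(rows) == 0L) return(empty)
  markers <- do.call(rbind, rows)
  presence <- do.call(rbind, pres)
  n <- length(strains)
  minor <- pmin(rowSums(presence), n - rowSums(presence))
  keep <- minor > 0 & (minor / n) >= min_class_frac
  markers <- markers[keep, , drop = FALSE]
  presence <- presence[keep, , drop = FALSE]
  if (nrow(markers) == 0L) return(empty)
  markers$marker_id <- sprintf("cnv_%s_%04d", event, seq_len(nrow(markers)))
  markers$n_present <- rowSums(presence)
  rownames(markers) <- NULL
  rownames(presence) <- markers$marker_id
  list(markers = markers[, c("marker_id", "chrom", "start", "end", "event",
                             "n_present")],
       presence = presence)
}

#' Assign CNV events to genes
#'
#' A gene fully covered by a gain region is labeled `gain`; a gene only
#' partially overlapped by a gain region gets no gain label (the extra copy
#' is incomplete). Loss and deletion regions label a gene on full cover or
#' partial overlap alike (at least one copy of the gene is truncated);
#' deletion means zero copies. Precedence when several events touch the same
#' gene: deletion > loss > gain.
#'
#' @param genes data.frame `gene_id`, `chrom`, `start`, `end` (0-based
#'   half-open), plus optional annotation columns.
#' @param segments CNV segment data.frame (`chrom`, `start`, `end`,
#'   `strain`, `event`).
#' @param strains character vector of all strain ids.
#' @return gene x strain character matrix with entries in
#'   {"gain", "loss", "deletion", "none"}.
#' @export
gene_cnv_events <- function(genes, segments, strains) {
  out <- matrix("none", nrow(genes), length(strains),
                dimnames = list(genes$gene_id, strains))
  if (nrow(segments) == 0L) return(out)
  gr_genes <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start + 1L, genes$end))
  gr_seg <- GenomicRanges::GRanges(
    segments$chrom, IRanges::IRanges(segments$start + 1L, segments$end))
  hits <- GenomicRanges::findOverlaps(gr_genes, gr_seg)
  if (length(hits) == 0L) return(out)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  full <- segments$start[si] <= genes$start[qi] &
    segments$end[si] >= genes$end[qi]
  ev <- segments$event[si]
  label <- ifelse(ev == "gain", ifelse(full, "gain", "none"), ev)
  prec <- c(none = 0L, gain = 1L, loss = 2L, deletion = 3L)
  for (h in seq_along(qi)) {
    if (label[h] == "none") next
    g <- qi[h]
    s <- segments$strain[si[h]]
    if (prec[[label[h]]] > prec[[out[g, s]]]) out[g, s] <- label[h]
  }
  out
}

#' Generate a synthetic gene catalogue
#'
#' Non-overlapping gene spans tiled over the chromosomes with strand, ORF
#' class and transcription-factor superfamily labels, matching the
#' annotation columns the analysis consumes.
#'
#' @param chrom_lengths named vector of chromosome lengths.
#' @param n_genes number of genes.
#' @param seed integer seed.
#' @return data.frame `gene_id`, `symbol`, `chrom`, `start`, `end`,
#'   `strand`, `orf_class`, `tf_superfamily`.
#' @export
gen_genes <- function(chrom_lengths, n_genes = 200, seed = 1) {
  set.seed(seed)
  per_chrom <- round(n_genes * chrom_lengths / sum(chrom_lengths))
  per_chrom[1] <- per_chrom[1] + n_genes - sum(per_chrom)
  rows <- list()
  for (cc in names(chrom_lengths)) {
    k <- per_chrom[[cc]]
    if (k <= 0) next
    slot <- floor(chrom_lengths[[cc]] / k)
    glen <- pmin(pmax(round(stats::rlnorm(k, log(1500), 0.4)), 300),
                 slot - 100)
    start <- (seq_len(k) - 1L) * slot + floor(runif(k) * (slot - glen - 50))
    rows[[cc]] <- data.frame(
      chrom = cc, start = as.integer(start),
      end = as.integer(start + glen),
      strand = sample(c("+", "-"), k, replace = TRUE),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  n <- nrow(out)
  out$gene_id <- sprintf("Y%04d", seq_len(n))
  out$symbol <- sprintf("GEN%d", seq_len(n))
  out$orf_class <- sample(c("verified", "uncharacterized", "dubious"), n,
                          replace = TRUE, prob = c(0.7, 0.2, 0.1))
  tf <- sample(c("none", "zipper", "HTH", "zinc finger", "other"), n,
               replace = TRUE, prob = c(0.8, 0.05, 0.05, 0.05, 0.05))
  out$tf_superfamily <- tf
  rownames(out) <- NULL
  out[, c("gene_id", "symbol", "chrom", "start", "end", "strand",
          "orf_class", "tf_superfamily")]
}
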