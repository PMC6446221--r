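# Variant I/O, marker filtering, LD blocks, kinship, CNV markers and
# gene-event assignment.

make_gm <- function(G, chrom = NULL, pos = NULL) {
  m <- nrow(G)
  map <- data.frame(id = sprintf("m%03d", seq_len(m)),
                    chrom = chrom %||% rep("chrI", m),
                    pos = pos %||% (seq_len(m) * 100L),
                    ref = "A", alt = "T", kind = "snp",
                    stringsAsFactors = FALSE)
  genotype_matrix(G, map, colnames(G) %||% sprintf("S%02d", seq_len(ncol(G))))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("VCF writing and reading round-trip the genotype matrix", {
  st <- gen_strains(8, seed = 1)
  gt <- gen_genotypes(st, n_markers = 60, seed = 2)
  path <- tempfile(fileext = ".vcf")
  write_vcf(gt$genotypes, path)
  back <- read_vcf(path)
  expect_equal(back$G, gt$genotypes$G)
  expect_equal(back$map$pos, gt$genotypes$map$pos)
  expect_equal(back$strains, gt$genotypes$strains)
  # dosage semantics: 0/1 -> 1; all-homozygous strain -> heterozygosity 0
  G <- matrix(c(0L, 1L, 2L, 0L, 0L, 2L), 3, 2)
  gm <- make_gm(G)
  write_vcf(gm, path)
  b2 <- read_vcf(path)
  expect_equal(unname(b2$G[2, 1]), 1L)
  het <- strain_heterozygosity(b2)
  expect_equal(unname(het[2]), 0)
  expect_equal(unname(het[1]), 0.5)
})

test_that("core/MAF filtering is strict, boundary-exact and idempotent", {
  # 10 strains: MAF exactly 0.05 means 1 alt allele in 20
  G <- rbind(c(1L, rep(0L, 9)),            # MAF 0.05 -> removed (strict >)
             c(1L, 1L, rep(0L, 8)),        # MAF 0.10 -> kept
             rep(1L, 10))                  # MAF 0.50 -> kept
  gm <- make_gm(G, pos = c(100L, 200L, 300L))
  f <- filter_core_maf(gm, mask = NULL, maf_min = 0.05)
  expect_equal(rownames(f$G), c("m002", "m003"))
  # mask boundaries are half-open: pos 200 inside [200, 300), 300 outside
  mask <- data.frame(chrom = "chrI", start = 200L, end = 300L)
  fm <- filter_core_maf(gm, mask = mask, maf_min = 0)
  expect_equal(rownames(fm$G), "m002")
  # idempotence
  f2 <- filter_core_maf(f, mask = NULL, maf_min = 0.05)
  expect_equal(f2$G, f$G)
  # whole-genome mask and maf 0 are the identity
  all_mask <- data.frame(chrom = "chrI", start = 0L, end = 10000L)
  expect_equal(filter_core_maf(gm, all_mask, maf_min = 0)$G, gm$G)
})

test_that("LD blocks chain by r2 with the representative and respect gaps", {
  x <- c(0L, 0L, 1L, 1L, 2L, 2L, 0L, 1L)
  y <- c(2L, 0L, 1L, 0L, 1L, 2L, 0L, 2L)  # nearly uncorrelated with x
  G <- rbind(x, x, y)
  gm <- make_gm(G, pos = c(100L, 200L, 300L))
  bl <- ld_blocks(gm, r2_min = 0.8, max_gap_bp = 1000)
  expect_equal(nrow(bl$blocks), 2)
  expect_equal(bl$blocks$n_members, c(2L, 1L))
  # independent markers -> all singletons
  set.seed(3)
  Gi <- matrix(sample(0:2, 8 * 30, replace = TRUE), 8, 30)
  bli <- ld_blocks(make_gm(Gi, pos = seq_len(8) * 50L), r2_min = 0.8,
                   max_gap_bp = 1e6)
  expect_equal(nrow(bli$blocks), 8)
  # a gap beyond max_gap_bp splits identical markers
  gm_gap <- make_gm(rbind(x, x), pos = c(100L, 50000L))
  bl_gap <- ld_blocks(gm_gap, r2_min = 0.8, max_gap_bp = 20000)
  expect_equal(nrow(bl_gap$blocks), 2)
})

test_that("LD chaining matches a direct re-evaluation on random inputs", {
  # independent oracle: literal transcription of the chaining definition
  oracle_blocks <- function(G, pos, maf, r2_min, max_gap) {
    out <- list(); members <- 1L; rep_i <- 1L
    for (i in seq_len(nrow(G))[-1]) {
      ok <- !is.na(G[rep_i, ]) & !is.na(G[i, ])
      r2 <- if (sd(G[rep_i, ok]) == 0 || sd(G[i, ok]) == 0) 0 else
        cor(G[rep_i, ok], G[i, ok])^2
      if (pos[i] - pos[members[length(members)]] <= max_gap && r2 >= r2_min) {
        members <- c(members, i)
        if (maf[i] > maf[rep_i]) rep_i <- i
      } else {
        out[[length(out) + 1L]] <- list(members = members, rep = rep_i)
        members <- i; rep_i <- i
      }
    }
    out[[length(out) + 1L]] <- list(members = members, rep = rep_i)
    out
  }
  set.seed(4)
  for (trial in 1:10) {
    m <- sample(10:40, 1)
    base <- matrix(sample(0:2, m * 12, replace = TRUE,
                          prob = c(0.5, 0.2, 0.3)), m, 12)
    # plant stretches of correlated markers
    for (k in seq_len(m - 1)) {
      if (runif(1) < 0.4) base[k + 1, ] <- base[k, ]
    }
    pos <- sort(sample.int(5000, m)) * 10L
    gm <- make_gm(base, pos = pos)
    got <- ld_blocks(gm, r2_min = 0.8, max_gap_bp = 10000)
    want <- oracle_blocks(base, pos, marker_maf(gm), 0.8, 10000)
    expect_equal(nrow(got$blocks), length(want))
    expect_equal(got$blocks$n_members,
                 vapply(want, function(b) length(b$members), integer(1)))
    expect_equal(got$blocks$representative,
                 gm$map$id[vapply(want, `[[`, integer(1), "rep")])
  }
})

test_that("kinship behaves like a genomic relationship matrix", {
  set.seed(5)
  G <- matrix(sample(0:2, 400 * 10, replace = TRUE), 400, 10)
  G[, 10] <- G[, 9]  # duplicated strain
  gm <- make_gm(G, pos = seq_len(400) * 10L)
  K <- kinship(gm)$K
  expect_equal(K, t(K), tolerance = 1e-12)
  expect_equal(mean(diag(K)), 1, tolerance = 1e-12)
  expect_equal(K[9, 10], K[9, 9], tolerance = 1e-9)
  expect_gte(min(eigen(K, only.values = TRUE)$values), -1e-8)
  # many independent equifrequent markers -> K close to identity (sample
  # centering biases off-diagonals by about -1/(n-1), so use a larger n)
  set.seed(6)
  Gi <- matrix(rbinom(5000 * 50, 2, 0.5), 5000, 50)
  Ki <- kinship(make_gm(Gi, pos = seq_len(5000) * 10L))$K
  expect_lt(max(abs(Ki - diag(50))), 0.15)
  expect_lt(mean(abs(Ki[upper.tri(Ki)])), 0.05)
  # invariant under marker permutation
  perm <- sample(nrow(G))
  K2 <- kinship(make_gm(G[perm, ], pos = seq_len(400) * 10L))$K
  expect_equal(unname(K), unname(K2), tolerance = 1e-10)
  # constant markers are ignored
  Gc <- rbind(G, matrix(1L, 5, 10))
  K3 <- kinship(make_gm(Gc, pos = seq_len(405) * 10L))$K
  expect_equal(unname(K), unname(K3), tolerance = 1e-10)
})

test_that("CNV markers reproduce the staircase and identical-interval cases", {
  strains <- c("A", "B", "C")
  seg <- data.frame(chrom = "chrI",
                    start = c(0L, 50L), end = c(100L, 150L),
                    strain = c("A", "B"),
                    event = "gain", stringsAsFactors = FALSE)
  mk <- cnv_markers(seg, strains, "gain", min_class_frac = 0)
  expect_equal(nrow(mk$markers), 3)
  expect_equal(mk$markers$start, c(0L, 50L, 100L))
  expect_equal(mk$markers$end, c(50L, 100L, 150L))
  expect_equal(unname(mk$presence[, "A"]), c(1L, 1L, 0L))
  expect_equal(unname(mk$presence[, "B"]), c(0L, 1L, 1L))
  # literally identical interval in two strains -> one marker holding both
  seg2 <- data.frame(chrom = "chrI", start = c(10L, 10L), end = c(60L, 60L),
                     strain = c("A", "B"), event = "gain",
                     stringsAsFactors = FALSE)
  mk2 <- cnv_markers(seg2, strains, "gain", min_class_frac = 0)
  expect_equal(nrow(mk2$markers), 1)
  expect_equal(unname(mk2$presence[1, ]), c(1L, 1L, 0L))
  # a presence pattern shared by everyone is constant -> dropped
  seg3 <- data.frame(chrom = "chrI", start = 10L, end = 60L,
                     strain = strains, event = "gain",
                     stringsAsFactors = FALSE)
  expect_equal(nrow(cnv_markers(seg3, strains, "gain")$markers), 0)
  # frequency filter: minor class below the threshold is dropped
  mk4 <- cnv_markers(seg2, strains, "gain", min_class_frac = 0.99)
  expect_equal(nrow(mk4$markers), 0)
})

test_that("CNV markers equal the per-base brute force on random toys", {
  set.seed(7)
  strains <- sprintf("S%d", 1:5)
  for (trial in 1:25) {
    n_seg <- sample(1:8, 1)
    seg <- data.frame(
      chrom = sample(c("c1", "c2"), n_seg, replace = TRUE),
      start = sample(0:180, n_seg, replace = TRUE),
      strain = sample(strains, n_seg, replace = TRUE),
      event = sample(c("gain", "loss", "deletion"), n_seg, replace = TRUE),
      stringsAsFactors = FALSE)
    seg$end <- seg$start + sample(5:60, n_seg, replace = TRUE)
    for (ev in c("gain", "loss")) {
      got <- cnv_markers(seg, strains, ev, min_class_frac = 0.05)
      want <- cnv_oracle(seg, strains, ev, min_class_frac = 0.05)
      expect_equal(nrow(got$markers), length(want))
      if (length(want) > 0) {
        ord <- order(vapply(want, `[[`, "", "chrom"),
                     vapply(want, function(x) x$start, integer(1)))
        want <- want[ord]
        gord <- order(got$markers$chrom, got$markers$start)
        expect_equal(got$markers$start[gord],
                     vapply(want, function(x) x$start, integer(1)))
        expect_equal(got$markers$end[gord],
                     vapply(want, function(x) x$end, integer(1)))
        for (k in seq_along(want)) {
          expect_equal(unname(got$presence[gord[k], ]), want[[k]]$presence)
        }
      }
    }
  }
})

test_that("gene event assignment follows the coverage rules", {
  genes <- data.frame(gene_id = c("g1", "g2", "g3"), chrom = "chrI",
                      start = c(100L, 300L, 500L), end = c(200L, 400L, 600L),
                      strand = "+", stringsAsFactors = FALSE)
  seg <- data.frame(
    chrom = "chrI",
    start = c(50L, 350L, 550L),
    end = c(250L, 380L, 650L),
    strain = c("A", "A", "A"),
    event = c("gain", "gain", "deletion"),
    stringsAsFactors = FALSE)
  ev <- gene_cnv_events(genes, seg, c("A", "B"))
  expect_equal(unname(ev["g1", "A"]), "gain")      # fully covered gain
  expect_equal(unname(ev["g2", "A"]), "none")      # partial gain not assigned
  expect_equal(unname(ev["g3", "A"]), "deletion")  # partial deletion assigned
  expect_true(all(ev[, "B"] == "none"))
  # partial loss assigned; full-cover loss too; deletion beats loss
  seg2 <- data.frame(chrom = "chrI", start = c(150L, 250L),
                     end = c(420L, 420L), strain = "A",
                     event = c("loss", "deletion"), stringsAsFactors = FALSE)
  ev2 <- gene_cnv_events(genes, seg2, "A")
  expect_equal(unname(ev2["g2", "A"]), "deletion")
  expect_equal(unname(ev2["g1", "A"]), "loss")
  # whole-chromosome gain labels every gene on the chromosome
  seg3 <- data.frame(chrom = "chrI", start = 0L, end = 10000L, strain = "A",
                     event = "gain", stringsAsFactors = FALSE)
  ev3 <- gene_cnv_events(genes, seg3, "A")
  expect_true(all(ev3[, "A"] == "gain"))
})

test_that("interval normalization merges and validates", {
  iv <- data.frame(chrom = c("c1", "c1", "c2"),
                   start = c(10L, 50L, 5L), end = c(60L, 100L, 20L))
  nm <- normalize_intervals(iv)
  expect_equal(nrow(nm), 2)
  expect_equal(nm$end[nm$chrom == "c1"], 100L)
  expect_error(normalize_intervals(data.frame(chrom = "c", start = 5L,
                                              end = 5L)),
               "start < end")
})
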