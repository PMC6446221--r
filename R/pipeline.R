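# End-to-end orchestration from a single configuration: simulate inputs,
# extract parameters, score and rank, run both GWAS branches, decompose
# contributions, discover network modules, and compute cohort statistics,
# with every tunable named in the config and every artifact written as
# diffable plain text.

#' Default pipeline configuration
#'
#' Every tunable of every stage lives here; nothing is hard-coded in
#' [run_all()]. The default sizes keep a full run small enough for tests
#' while exercising every stage.
#'
#' @param seed master seed; all stage seeds derive from it.
#' @return nested configuration list.
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    synthio = list(
      n_strains = 12, n_conditions = 3, levels_per_condition = 4,
      n_replicates = 2, noise_sd = 0.005, t_max = 66, dt = 1,
      blank = 0.1, blank_threshold = 0.05, family = "logistic",
      n_markers = 300, n_populations = 2, fst_like = 0.2,
      chrom_lengths = c(chrI = 2e5, chrII = 8e5, chrIII = 3e5),
      cnv_mean_events = 3, cnv_shared = 2, n_genes = 120,
      network_nodes = 60, network_edge_prob = 0.06,
      planted_clique_size = 8, n_metabolites = 79
    ),
    growthio = list(min_amplitude = 0.05, smooth_window = 1, reg_window = 5),
    scoring = list(weights = rep(1, 5), rva_samples = 50, pi_bump = 0.2),
    gwas = list(maf_min = 0.05, r2_min = 0.8, max_gap_bp = 20000,
                eps_log10 = 0.5, upstream_bp = 800, int = TRUE,
                mode = "p3d", min_class_frac = 0.05, window = 50000,
                max_rankings = 2),
    contribution = list(q = 0.75),
    modules = list(score_min = 0, clique_min_size = 3, alpha = 0.05,
                   n_random = 5),
    cohort = list(collapse = "median")
  )
}

#' Validate a pipeline configuration
#'
#' Schema and cross-field checks; returns the violations rather than
#' stopping, so callers can report them all at once.
#'
#' @param config configuration list (see [default_config()]).
#' @return character vector of violations (empty when valid).
#' @export
validate_config <- function(config) {
  v <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)
  chk(is.numeric(config$seed) && length(config$seed) == 1,
      "seed must be a single number")
  sy <- config$synthio
  chk(!is.null(sy$n_strains) && sy$n_strains >= 4,
      "synthio$n_strains must be >= 4")
  chk(all(sy$levels_per_condition >= 4 & sy$levels_per_condition <= 7),
      "synthio$levels_per_condition must lie in 4..7")
  chk(sy$noise_sd >= 0, "synthio$noise_sd must be >= 0")
  sc <- config$scoring
  chk(length(sc$weights) == 5, "scoring$weights must have length 5")
  chk(all(sc$weights >= 0), "scoring$weights must be non-negative")
  chk(sum(sc$weights) > 0, "scoring$weights must not sum to 0")
  chk(sc$pi_bump > 0, "scoring$pi_bump must be > 0")
  gw <- config$gwas
  chk(gw$maf_min >= 0 && gw$maf_min < 0.5,
      "gwas$maf_min must lie in [0, 0.5)")
  chk(gw$r2_min > 0 && gw$r2_min <= 1, "gwas$r2_min must lie in (0, 1]")
  chk(gw$eps_log10 > 0, "gwas$eps_log10 must be > 0")
  chk(gw$upstream_bp >= 0, "gwas$upstream_bp must be >= 0")
  chk(gw$mode %in% c("p3d", "exact"), "gwas$mode must be 'p3d' or 'exact'")
  co <- config$contribution
  chk(co$q > 0 && co$q < 1, "contribution$q must lie in (0, 1)")
  mo <- config$modules
  chk(mo$alpha > 0 && mo$alpha < 1, "modules$alpha must lie in (0, 1)")
  chk(mo$n_random >= 1, "modules$n_random must be >= 1")
  v
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline
#'
#' Executes the stages in dependency order (curves -> parameters ->
#' scores/rankings -> GWAS inputs -> scans -> cutoffs -> gene P ->
#' contributions -> modules -> cohort statistics) into `outdir`. All outputs
#' are plain-text TSV/JSON; `run_log.json` records the seeds, package
#' version and the MD5 hash of the serialized config. A stage failure halts
#' the run naming the stage.
#'
#' @param config configuration list (see [default_config()]).
#' @param outdir output directory (created if needed).
#' @return invisibly, the output directory path.
#' @export
run_all <- function(config = default_config(), outdir = tempfile("sgrun")) {
  violations <- validate_config(config)
  if (length(violations) > 0) {
    stopf("invalid config: %s", paste(violations, collapse = "; "))
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("pipeline halted in stage '%s' (outputs in %s): %s",
            name, outdir, conditionMessage(e))
    })
  }
  sy <- config$synthio
  seed <- config$seed

  sim <- stage("simulate", {
    strains <- gen_strains(sy$n_strains, seed = seed)
    gc <- gen_growth_curves(strains, n_conditions = sy$n_conditions,
                            levels_per_condition = sy$levels_per_condition,
                            n_replicates = sy$n_replicates,
                            noise_sd = sy$noise_sd, seed = seed + 1,
                            t_max = sy$t_max, dt = sy$dt, blank = sy$blank,
                            blank_threshold = sy$blank_threshold,
                            family = sy$family)
    gt <- gen_genotypes(strains, n_markers = sy$n_markers,
                        n_populations = sy$n_populations,
                        fst_like = sy$fst_like,
                        chrom_lengths = sy$chrom_lengths, seed = seed + 2)
    cnv <- gen_cnv(strains, chrom_lengths = sy$chrom_lengths,
                   mean_events = sy$cnv_mean_events,
                   n_shared = sy$cnv_shared, seed = seed + 3)
    genes <- gen_genes(sy$chrom_lengths, n_genes = sy$n_genes,
                       seed = seed + 4)
    net <- gen_network(n_nodes = sy$network_nodes,
                       edge_prob = sy$network_edge_prob,
                       planted_cliques = list(
                         list(size = sy$planted_clique_size, fg_frac = 1)),
                       seed = seed + 5)
    met <- gen_metabolome(strains, n_metabolites = sy$n_metabolites,
                          seed = seed + 6)
    write_curves(gc$curves, file.path(outdir, "curves.tsv"))
    write_vcf(gt$genotypes, file.path(outdir, "genotypes.vcf"))
    write_cnv_bed(cnv, file.path(outdir, "cnv_segments.bed"))
    write_network_tsv(net$edges, file.path(outdir, "network.tsv"))
    write_tsv(strains, file.path(outdir, "strains.tsv"))
    write_tsv(genes, file.path(outdir, "genes.tsv"))
    list(strains = strains, gc = gc, gt = gt, cnv = cnv, genes = genes,
         net = net, met = met)
  })

  params <- stage("growth_params", {
    curves <- read_curves(file.path(outdir, "curves.tsv"))
    p <- extract_params_table(curves, blank = sy$blank,
                              min_amplitude = config$growthio$min_amplitude,
                              reg_window = config$growthio$reg_window,
                              smooth_window = config$growthio$smooth_window)
    write_params(p, file.path(outdir, "growth_params.tsv"))
    p
  })

  scores <- stage("scoring", {
    w <- weight_vector(config$scoring$weights)
    rankings <- rank_all(params, w)
    write_tsv(rankings, file.path(outdir, "rankings.tsv"))
    write_tsv(top_frequency(rankings), file.path(outdir, "top_frequency.tsv"))
    rva <- rank_variability(params, config$scoring$rva_samples,
                            seed = seed + 7)
    write_tsv(rva$summary, file.path(outdir, "rva_summary.tsv"))
    pi_scores <- parameter_influence(params, bump = config$scoring$pi_bump)
    write_tsv(pi_scores, file.path(outdir, "pi_scores.tsv"))
    list(rankings = rankings, rva = rva, pi = pi_scores)
  })

  gwas <- stage("gwas", {
    gw <- config$gwas
    gm <- read_vcf(file.path(outdir, "genotypes.vcf"))
    gm <- filter_core_maf(gm, mask = NULL, maf_min = gw$maf_min)
    blocks <- ld_blocks(gm, r2_min = gw$r2_min, max_gap_bp = gw$max_gap_bp)
    K <- kinship(gm)$K
    gain <- cnv_markers(sim$cnv, sim$strains$strain_id, "gain",
                        gw$min_class_frac)
    loss <- cnv_markers(sim$cnv, sim$strains$strain_id, "loss",
                        gw$min_class_frac)
    rk <- scores$rankings
    rk_keys <- unique(rk[, c("condition", "score_type")])
    rk_keys <- utils::head(rk_keys, gw$max_rankings)
    all_units <- list()
    for (i in seq_len(nrow(rk_keys))) {
      cc <- rk_keys$condition[i]
      st <- rk_keys$score_type[i]
      label <- paste(cc, st, sep = ":")
      rk1 <- rk[rk$condition == cc & rk$score_type == st, ]
      rk1 <- rk1[match(gm$strains, rk1$strain), ]
      y <- transform_phenotype(rk1, int = gw$int)
      fit <- suppressWarnings(reml_null(y, K))
      snp_assoc <- assoc_scan(y, blocks$representatives$G, fit,
                              source = "snp", ranking = label,
                              mode = gw$mode)
      bi <- match(snp_assoc$unit, blocks$blocks$representative)
      all_units[[paste(label, "snp")]] <- data.frame(
        unit = blocks$blocks$block_id[bi],
        chrom = blocks$blocks$chrom[bi],
        start = blocks$blocks$start[bi],
        end = blocks$blocks$end[bi],
        source = "snp", ranking = label, p = snp_assoc$p,
        beta = snp_assoc$beta, stringsAsFactors = FALSE)
      for (ev in c("gain", "loss")) {
        mk <- if (ev == "gain") gain else loss
        if (nrow(mk$markers) == 0) next
        pres <- mk$presence[, gm$strains, drop = FALSE]
        ca <- assoc_scan(y, pres, fit, source = ev, ranking = label,
                         mode = gw$mode)
        mi <- match(ca$unit, mk$markers$marker_id)
        all_units[[paste(label, ev)]] <- data.frame(
          unit = ca$unit, chrom = mk$markers$chrom[mi],
          start = mk$markers$start[mi], end = mk$markers$end[mi],
          source = ev, ranking = label, p = ca$p, beta = ca$beta,
          stringsAsFactors = FALSE)
      }
    }
    units <- do.call(rbind, all_units)
    rownames(units) <- NULL
    cutoffs <- lapply(unique(units$source), function(src) {
      ps <- units$p[units$source == src]
      if (length(ps) >= 20) qq_cutoff(ps, src, gw$eps_log10)
      else list(source = src, threshold = 0, eps_log10 = gw$eps_log10,
                n_significant = 0L)
    })
    units$significant <- FALSE
    for (co in cutoffs) {
      units$significant[units$source == co$source &
                          units$p <= co$threshold & co$threshold > 0] <- TRUE
    }
    gene_p <- gene_pvalues(units, sim$genes, upstream_bp = gw$upstream_bp)
    windows <- genomic_windows(units, cutoffs, window = gw$window)
    write_tsv(units, file.path(outdir, "assoc_units.tsv"))
    write_tsv(gene_p, file.path(outdir, "gene_pvalues.tsv"))
    write_tsv(windows, file.path(outdir, "window_counts.tsv"))
    jsonlite::write_json(cutoffs, file.path(outdir, "cutoffs.json"),
                         auto_unbox = TRUE, digits = NA)
    list(units = units, cutoffs = cutoffs, gene_p = gene_p,
         windows = windows, kinship = K)
  })

  stage("contribution", {
    cats <- rbind(
      data.frame(gene_id = sim$genes$gene_id, category = "all",
                 stringsAsFactors = FALSE),
      data.frame(gene_id = sim$genes$gene_id,
                 category = sim$genes$orf_class, stringsAsFactors = FALSE),
      data.frame(gene_id = sim$genes$gene_id[sim$genes$tf_superfamily != "none"],
                 category = paste0("TF:", sim$genes$tf_superfamily[
                   sim$genes$tf_superfamily != "none"]),
                 stringsAsFactors = FALSE)
    )
    ct <- contribution_table(gwas$gene_p, cats, q = config$contribution$q)
    write_tsv(ct, file.path(outdir, "contributions.tsv"))
    ct
  })

  stage("modules", {
    mo <- config$modules
    g <- network_from_edges(sim$net$edges, mo$score_min,
                            nodes = sim$net$nodes)
    mods <- find_modules(g, sim$net$foreground, mo$clique_min_size, mo$alpha)
    stats_row <- module_stats(mods, g, sim$net$foreground)
    nc <- null_comparison(g, sim$net$foreground, n_random = mo$n_random,
                          seed = seed + 8, clique_min_size = mo$clique_min_size,
                          alpha = mo$alpha)
    membership <- if (length(mods) > 0) {
      do.call(rbind, lapply(seq_along(mods), function(i) {
        data.frame(module = i, node = mods[[i]]$nodes,
                   stringsAsFactors = FALSE)
      }))
    } else data.frame(module = integer(), node = character())
    write_tsv(membership, file.path(outdir, "module_membership.tsv"))
    write_tsv(stats_row, file.path(outdir, "module_stats.tsv"))
    jsonlite::write_json(list(real = nc$real, tests = as.list(nc$tests)),
                         file.path(outdir, "module_null_comparison.json"),
                         auto_unbox = TRUE, digits = NA)
    mods
  })

  stage("cohort_stats", {
    rk <- scores$rankings
    first <- rk[rk$condition == rk$condition[1] &
                  rk$score_type == "performance", ]
    vals <- stats::setNames(first$rank, first$strain)
    grouped <- bin_strains(vals, sim$strains,
                           collapse = config$cohort$collapse)
    have <- table(grouped$group)
    report <- list()
    if (all(c("industrial", "environmental") %in% names(have)) &&
        all(have[c("industrial", "environmental")] >= 2)) {
      ct <- compare_two(grouped, c("industrial", "environmental"))
      report$industrial_vs_environmental <- list(
        statistic = ct$statistic, p = ct$p, n = as.list(ct$n))
    }
    if (length(have[have >= 2]) >= 3) {
      km <- compare_many(grouped[grouped$group %in%
                                   names(have[have >= 2]), ])
      report$subcategories_kruskal <- list(statistic = km$statistic,
                                           p = km$p, df = km$df)
    }
    mg <- metabolome_group_scores(sim$met$intra, sim$met$groups)
    write_tsv(mg$rankings, file.path(outdir, "metabolome_rankings.tsv"))
    jsonlite::write_json(report, file.path(outdir, "cohort_tests.json"),
                         auto_unbox = TRUE, digits = NA)
    report
  })

  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  cfg_file <- file.path(outdir, "config.json")
  writeLines(cfg_json, cfg_file)
  log <- list(
    package = "stressgwas",
    version = as.character(utils::packageVersion("stressgwas")),
    seed = seed,
    config_md5 = unname(tools::md5sum(cfg_file))
  )
  jsonlite::write_json(log, file.path(outdir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
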