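# Synthetic-data generators emulating the structure of a yeast strain-
# collection phenomics + genomics study: growth curves under increasing
# inhibitory levels, structured genotypes, CNV segment sets, a scored
# interaction network and a two-compartment metabolome. Every generator is
# deterministic under a fixed seed and returns the ground truth it used, so
# downstream modules can be tested by parameter recovery.

#' Generate a synthetic strain collection
#'
#' Strains are assigned to the four isolation categories (industrial,
#' environmental, laboratory, clinical) in proportions approximating a
#' 36-strain collection with 17/13/4/2 members, with consistent
#' subcategories (e.g. plant implies environmental). When `n >= 10` a group
#' of related bioethanol strains shares a `bin_group`, which group-level
#' tests collapse to a single pseudo-observation.
#'
#' @param n number of strains (>= 4 so all categories can be present).
#' @param seed integer seed.
#' @return data.frame with columns `strain_id`, `category`, `subcategory`,
#'   `geography`, `ploidy`, `bin_group` (NA when unbinned).
#' @export
gen_strains <- function(n, seed = 1) {
  assert_that(n >= 4, "n must be >= 4 (one strain per category)")
  set.seed(seed)
  cats <- c("industrial", "environmental", "laboratory", "clinical")
  prop <- c(17, 13, 4, 2) / 36
  counts <- pmax(1L, floor(n * prop))
  # settle rounding so counts sum to n, favouring the largest remainders
  while (sum(counts) < n) {
    rem <- n * prop - counts
    i <- which.max(rem)
    counts[i] <- counts[i] + 1L
  }
  while (sum(counts) > n) {
    i <- which.max(counts - pmax(1, n * prop))
    counts[i] <- counts[i] - 1L
  }
  category <- rep(cats, counts)
  subcat_pool <- list(
    industrial = c("bioethanol", "brewing", "food"),
    environmental = c("soil", "plant", "animal"),
    laboratory = "lab",
    clinical = "clinical"
  )
  subcategory <- unlist(lapply(cats, function(cc) {
    k <- counts[match(cc, cats)]
    pool <- subcat_pool[[cc]]
    if (length(pool) == 1L) rep(pool, k) else
      pool[1 + (sample.int(length(pool), k, replace = TRUE) - 1)]
  }))
  # guarantee enough bioethanol strains to form the binned group
  if (n >= 10) {
    ind <- which(category == "industrial")
    need <- 2L - sum(subcategory[ind] == "bioethanol")
    if (need > 0 && length(ind) >= 2) {
      subcategory[ind[seq_len(min(need + sum(subcategory[ind] == "bioethanol"), length(ind)))[1:2]]] <- "bioethanol"
    }
  }
  geos <- c("Brazil", "Europe", "North America", "Asia", "Africa", "Oceania")
  geography <- geos[sample.int(length(geos), n, replace = TRUE)]
  bin_group <- rep(NA_character_, n)
  if (n >= 10) {
    bio <- which(subcategory == "bioethanol")
    nb <- max(2L, ceiling(length(bio) / 2))
    bio <- bio[seq_len(min(nb, length(bio)))]
    bin_group[bio] <- "brazil_bioethanol"
    geography[bio] <- "Brazil"
  }
  ploidy <- sample(c(1L, 2L, 3L, 4L), n, replace = TRUE,
                   prob = c(0.25, 0.55, 0.12, 0.08))
  data.frame(
    strain_id = sprintf("S%03d", seq_len(n)),
    category = category,
    subcategory = subcategory,
    geography = geography,
    ploidy = ploidy,
    bin_group = bin_group,
    stringsAsFactors = FALSE
  )
}

# Hill dose-response factor in (0, 1]; exactly 1 at dose 0.
hill_factor <- function(dose, ic50, hill) {
  ifelse(dose <= 0, 1, 1 / (1 + (dose / ic50)^hill))
}

#' Generate dose-response growth curves and their ground truth
#'
#' Each curve is a logistic trajectory
#' `signal(t) = blank + A / (1 + exp(-mu * (t - t_mid)))` with
#' `t_mid = lag + 2/mu` (so `lag` is the Zwietering tangent lag), observed on
#' a regular time grid spanning about 66 h. Amplitude and growth rate scale
#' down, and lag scales up, with the inhibitory level through a strain- and
#' condition-specific Hill dose-response (dose = level index). When the
#' dosed amplitude drops below `blank_threshold` the strain no longer grows
#' at that level and the curve is flat at the blank, which reproduces the
#' varying number of growing strains per experimental setting.
#'
#' @param strains data.frame from [gen_strains()].
#' @param n_conditions number of stress conditions.
#' @param levels_per_condition scalar or per-condition vector, each in 4..7.
#' @param n_replicates replicates per curve.
#' @param noise_sd additive Gaussian noise standard deviation (>= 0).
#' @param seed integer seed.
#' @param t_max,dt time grid: `seq(0, t_max, by = dt)` hours.
#' @param blank blank (background) signal level.
#' @param blank_threshold amplitude below which a well is scored "no growth".
#' @param family `"logistic"` (default) or `"gompertz"`; the extraction
#'   module makes no assumption about the family.
#' @return list with `curves` (long data.frame: strain, condition, level,
#'   replicate, time_h, signal) and `truth` (per-strain baseline parameters,
#'   per-strain-condition IC50/Hill, and the per-level dosed parameters).
#' @export
gen_growth_curves <- function(strains, n_conditions = 13,
                              levels_per_condition = 5, n_replicates = 3,
                              noise_sd = 0.01, seed = 1,
                              t_max = 66, dt = 0.5,
                              blank = 0.1, blank_threshold = 0.05,
                              family = c("logistic", "gompertz")) {
  family <- match.arg(family)
  assert_that(noise_sd >= 0, "noise_sd must be >= 0")
  levels_per_condition <- rep_len(levels_per_condition, n_conditions)
  assert_that(all(levels_per_condition >= 4 & levels_per_condition <= 7),
              "levels_per_condition must lie in 4..7")
  set.seed(seed)
  n <- nrow(strains)
  conditions <- sprintf("C%02d", seq_len(n_conditions))
  strain_params <- data.frame(
    strain_id = strains$strain_id,
    baseline_mu = runif(n, 0.25, 0.55),
    lag_h = runif(n, 2, 6),
    amplitude = runif(n, 0.8, 1.3),
    stringsAsFactors = FALSE
  )
  dose_response <- expand.grid(strain_id = strains$strain_id,
                               condition = conditions,
                               KEEP.OUT.ATTRS = FALSE,
                               stringsAsFactors = FALSE)
  dose_response$ic50 <- runif(nrow(dose_response), 1.2,
                              max(levels_per_condition) + 1)
  dose_response$hill <- runif(nrow(dose_response), 1.5, 4)
  times <- seq(0, t_max, by = dt)
  rows <- vector("list", n_conditions)
  level_truth <- vector("list", n_conditions)
  for (ci in seq_len(n_conditions)) {
    nl <- levels_per_condition[ci]
    dr <- dose_response[dose_response$condition == conditions[ci], ]
    dr <- dr[match(strains$strain_id, dr$strain_id), ]
    lt <- expand.grid(strain_id = strains$strain_id, level = 0:(nl - 1),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    f <- hill_factor(lt$level,
                     dr$ic50[match(lt$strain_id, dr$strain_id)],
                     dr$hill[match(lt$strain_id, dr$strain_id)])
    lt$condition <- conditions[ci]
    lt$mu <- strain_params$baseline_mu[match(lt$strain_id, strain_params$strain_id)] * f
    lt$amplitude <- strain_params$amplitude[match(lt$strain_id, strain_params$strain_id)] * f
    lt$lag_h <- strain_params$lag_h[match(lt$strain_id, strain_params$strain_id)] / f
    lt$grew <- lt$amplitude >= blank_threshold
    level_truth[[ci]] <- lt
    per_curve <- lt[rep(seq_len(nrow(lt)), each = n_replicates), ]
    per_curve$replicate <- rep(seq_len(n_replicates), nrow(lt))
    sig <- lapply(seq_len(nrow(per_curve)), function(i) {
      p <- per_curve[i, ]
      y <- if (!p$grew) rep(0, length(times)) else
        growth_trajectory(times, p$mu, p$amplitude, p$lag_h, family)
      y <- blank + y
      if (noise_sd > 0) y <- pmax(0, y + rnorm(length(times), 0, noise_sd))
      y
    })
    rows[[ci]] <- data.frame(
      strain = rep(per_curve$strain_id, each = length(times)),
      condition = conditions[ci],
      level = rep(per_curve$level, each = length(times)),
      replicate = rep(per_curve$replicate, each = length(times)),
      time_h = rep(times, nrow(per_curve)),
      signal = unlist(sig),
      stringsAsFactors = FALSE
    )
  }
  curves <- do.call(rbind, rows)
  rownames(curves) <- NULL
  truth <- list(strain_params = strain_params, dose_response = dose_response,
                level_truth = do.call(rbind, level_truth),
                blank = blank, blank_threshold = blank_threshold,
                family = family, levels_per_condition = levels_per_condition,
                conditions = conditions)
  list(curves = curves, truth = truth)
}

#' Closed-form growth trajectory above the blank
#'
#' @param times time grid (hours).
#' @param mu maximum specific growth rate (1/h).
#' @param amplitude final signal amplitude above blank.
#' @param lag_h Zwietering tangent lag (h).
#' @param family "logistic" or "gompertz".
#' @return numeric vector of signal-above-blank values.
#' @export
growth_trajectory <- function(times, mu, amplitude, lag_h,
                              family = c("logistic", "gompertz")) {
  family <- match.arg(family)
  if (family == "logistic") {
    t_mid <- lag_h + 2 / mu
    amplitude / (1 + exp(-mu * (times - t_mid)))
  } else {
    # Zwietering reparameterized Gompertz with the same (mu, A, lag) meaning
    amplitude * exp(-exp(mu * exp(1) / amplitude * (lag_h - times) + 1))
  }
}

#' Generate structured genotypes and a matching phenotype
#'
#' Genotypes follow a Balding-Nichols construction: each marker has an
#' ancestral allele frequency, population-specific frequencies are drawn from
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` with `F = fst_like`, and strains carry
#' binomial(2) dosages at their population's frequency, which induces a
#' non-trivial kinship. The phenotype is the sum of planted marker effects
#' (on standardized dosages), a polygenic term with covariance proportional
#' to the realized kinship, and independent noise.
#'
#' @param strains data.frame from [gen_strains()].
#' @param n_markers number of biallelic markers.
#' @param n_populations number of populations.
#' @param fst_like Balding-Nichols F, in (0, 1).
#' @param causal data.frame with columns `marker` (index) and `effect`
#'   (per-SD effect), or NULL for a null scan input.
#' @param sigma_g2,sigma_e2 polygenic and residual variances.
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param seed integer seed.
#' @return list with `genotypes` (a [genotype_matrix()]), `phenotype` (named
#'   vector), `kinship` (the realized kinship used for the polygenic draw),
#'   `populations` and `causal`.
#' @export
gen_genotypes <- function(strains, n_markers = 500, n_populations = 2,
                          fst_like = 0.2, causal = NULL,
                          sigma_g2 = 1, sigma_e2 = 0.25,
                          chrom_lengths = c(chrI = 2e5, chrII = 8e5,
                                            chrIII = 3e5, chrIV = 1.5e6),
                          seed = 1) {
  assert_that(fst_like > 0 && fst_like < 1, "fst_like must be in (0,1)")
  if (!is.null(causal)) {
    assert_that(all(causal$marker >= 1 & causal$marker <= n_markers),
                "causal markers must index existing markers")
    assert_that(nrow(causal) < n_markers, "need fewer causal markers than markers")
  }
  set.seed(seed)
  n <- nrow(strains)
  pops <- rep_len(seq_len(n_populations), n)
  p_anc <- runif(n_markers, 0.05, 0.95)
  shape_scale <- (1 - fst_like) / fst_like
  p_pop <- matrix(rbeta(n_markers * n_populations,
                        rep(p_anc, n_populations) * shape_scale,
                        rep(1 - p_anc, n_populations) * shape_scale),
                  nrow = n_markers)
  G <- matrix(0L, n_markers, n)
  for (s in seq_len(n)) {
    G[, s] <- rbinom(n_markers, 2L, p_pop[, pops[s]])
  }
  # marker map: positions spread over the chromosomes, sorted
  chrom <- sample(names(chrom_lengths), n_markers, replace = TRUE,
                  prob = chrom_lengths / sum(chrom_lengths))
  pos <- floor(runif(n_markers) * chrom_lengths[chrom])
  ord <- order(match(chrom, names(chrom_lengths)), pos)
  chrom <- chrom[ord]; pos <- pos[ord]; G <- G[ord, , drop = FALSE]
  if (!is.null(causal)) causal$marker <- match(causal$marker, ord)
  kinds <- sample(c("snp", "indel"), n_markers, replace = TRUE,
                  prob = c(0.9, 0.1))
  map <- data.frame(
    id = sprintf("m%05d", seq_len(n_markers)),
    chrom = chrom, pos = pos,
    ref = sample(c("A", "C", "G", "T"), n_markers, replace = TRUE),
    alt = sample(c("A", "C", "G", "T"), n_markers, replace = TRUE),
    kind = kinds, stringsAsFactors = FALSE
  )
  map$alt <- ifelse(map$alt == map$ref, paste0(map$ref, "T"), map$alt)
  map$kind[nchar(map$alt) > 1] <- "indel"
  gm <- genotype_matrix(G, map, strains$strain_id)
  K <- kinship(gm)$K
  # polygenic + residual phenotype
  eg <- eigen(K, symmetric = TRUE)
  L <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), nrow(K))
  g <- sqrt(sigma_g2) * as.vector(L %*% rnorm(n))
  y <- g + rnorm(n, 0, sqrt(sigma_e2))
  if (!is.null(causal)) {
    for (i in seq_len(nrow(causal))) {
      x <- G[causal$marker[i], ]
      sdx <- stats::sd(x)
      if (sdx > 0) y <- y + causal$effect[i] * (x - mean(x)) / sdx
    }
  }
  names(y) <- strains$strain_id
  list(genotypes = gm, phenotype = y, kinship = K, populations = pops,
       causal = causal,
       allele_freqs = list(ancestral = p_anc[ord],
                           population = p_pop[ord, , drop = FALSE]))
}

#' Generate per-strain CNV segment sets
#'
#' Events are biased toward chromosome ends (subtelomeric placement via a
#' Beta(0.5, 0.5) position draw) and a configurable number of events is
#' shared by random strain subsets, creating the overlap structure that CNV
#' marker construction exploits. Copy numbers are drawn relative to each
#' strain's ploidy: gain = above ploidy, loss = below ploidy but above zero,
#' deletion = zero copies.
#'
#' @param strains data.frame from [gen_strains()].
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param mean_events Poisson mean of private events per strain (may be 0).
#' @param n_shared number of events shared across random strain subsets.
#' @param seed integer seed.
#' @return data.frame with columns `chrom`, `start`, `end` (0-based,
#'   half-open), `copy_number`, `strain`, `event`.
#' @export
gen_cnv <- function(strains, chrom_lengths = c(chrI = 2e5, chrII = 8e5,
                                               chrIII = 3e5, chrIV = 1.5e6),
                    mean_events = 3, n_shared = 2, seed = 1) {
  assert_that(all(chrom_lengths > 0), "chromosome lengths must be positive")
  set.seed(seed)
  n <- nrow(strains)
  draw_event <- function() {
    cc <- sample(names(chrom_lengths), 1,
                 prob = chrom_lengths / sum(chrom_lengths))
    len <- min(max(1000, round(stats::rlnorm(1, log(2e4), 0.7))),
               floor(chrom_lengths[[cc]] / 2))
    start <- floor(rbeta(1, 0.5, 0.5) * (chrom_lengths[[cc]] - len))
    list(chrom = cc, start = start, end = start + len)
  }
  copy_for <- function(type, ploidy) {
    switch(type,
           gain = ploidy + sample.int(2L, 1L),
           loss = if (ploidy >= 2) sample.int(ploidy - 1L, 1L) else 0L,
           deletion = 0L)
  }
  out <- list()
  for (s in seq_len(n)) {
    k <- stats::rpois(1, mean_events)
    if (k == 0) next
    for (i in seq_len(k)) {
      ev <- draw_event()
      type <- sample(c("gain", "loss", "deletion"), 1, prob = c(0.5, 0.3, 0.2))
      cn <- copy_for(type, strains$ploidy[s])
      out[[length(out) + 1L]] <- data.frame(
        chrom = ev$chrom, start = ev$start, end = ev$end,
        copy_number = cn, strain = strains$strain_id[s],
        stringsAsFactors = FALSE)
    }
  }
  if (n_shared > 0 && n >= 2) {
    for (i in seq_len(n_shared)) {
      ev <- draw_event()
      type <- sample(c("gain", "loss"), 1)
      members <- sample(seq_len(n), max(2, min(n, stats::rpois(1, 3) + 2)))
      for (s in members) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = ev$chrom, start = ev$start, end = ev$end,
          copy_number = copy_for(type, strains$ploidy[s]),
          strain = strains$strain_id[s], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), copy_number = integer(),
                      strain = character(), event = character(),
                      stringsAsFactors = FALSE))
  }
  seg <- do.call(rbind, out)
  rownames(seg) <- NULL
  seg$event <- classify_cnv_event(
    seg$copy_number, strains$ploidy[match(seg$strain, strains$strain_id)])
  seg
}

#' Classify a copy number relative to ploidy
#' @param copy_number observed copies; @param ploidy strain ploidy.
#' @return "gain", "loss" or "deletion".
#' @export
classify_cnv_event <- function(copy_number, ploidy) {
  ifelse(copy_number == 0, "deletion",
         ifelse(copy_number > ploidy, "gain", "loss"))
}

#' Generate a scored interaction network with planted cliques
#'
#' An Erdos-Renyi background graph plus fully connected planted cliques on
#' disjoint node sets; the foreground gene list contains the requested
#' fraction of each clique plus random background nodes, providing a
#' power/null scaffold for module discovery.
#'
#' @param n_nodes number of nodes.
#' @param edge_prob background edge probability.
#' @param planted_cliques list of `list(size =, fg_frac =)` entries.
#' @param n_background_fg random non-clique foreground nodes to add.
#' @param seed integer seed.
#' @return list with `edges` (data.frame node_a, node_b, score),
#'   `foreground` (character) and `cliques` (list of node-id vectors).
#' @export
gen_network <- function(n_nodes = 100, edge_prob = 0.05,
                        planted_cliques = list(list(size = 8, fg_frac = 1)),
                        n_background_fg = 5, seed = 1) {
  sizes <- vapply(planted_cliques, function(x) x$size, numeric(1))
  assert_that(sum(sizes) <= n_nodes, "planted cliques exceed node count")
  set.seed(seed)
  nodes <- sprintf("g%04d", seq_len(n_nodes))
  g <- igraph::sample_gnp(n_nodes, edge_prob)
  el <- igraph::as_edgelist(g, names = FALSE)
  edges <- if (nrow(el) > 0) {
    data.frame(node_a = nodes[el[, 1]], node_b = nodes[el[, 2]],
               score = round(runif(nrow(el), 400, 900)),
               stringsAsFactors = FALSE)
  } else {
    data.frame(node_a = character(), node_b = character(), score = numeric(),
               stringsAsFactors = FALSE)
  }
  cliques <- list()
  cursor <- 0L
  for (pc in planted_cliques) {
    members <- nodes[cursor + seq_len(pc$size)]
    cursor <- cursor + pc$size
    cliques[[length(cliques) + 1L]] <- members
    prs <- utils::combn(members, 2)
    edges <- rbind(edges, data.frame(node_a = prs[1, ], node_b = prs[2, ],
                                     score = 950, stringsAsFactors = FALSE))
  }
  # dedupe undirected edges, keep max score, drop self-loops
  if (nrow(edges) > 0) {
    a <- pmin(edges$node_a, edges$node_b)
    b <- pmax(edges$node_a, edges$node_b)
    keep <- a != b
    key <- paste(a, b)[keep]
    agg <- tapply(edges$score[keep], key, max)
    parts <- strsplit(names(agg), " ", fixed = TRUE)
    edges <- data.frame(node_a = vapply(parts, `[`, "", 1),
                        node_b = vapply(parts, `[`, "", 2),
                        score = as.numeric(agg), stringsAsFactors = FALSE)
    rownames(edges) <- NULL
  }
  foreground <- character()
  for (i in seq_along(cliques)) {
    k <- round(planted_cliques[[i]]$fg_frac * length(cliques[[i]]))
    if (k > 0) foreground <- c(foreground, sample(cliques[[i]], k))
  }
  pool <- setdiff(nodes, unlist(cliques))
  if (n_background_fg > 0 && length(pool) > 0) {
    foreground <- c(foreground,
                    sample(pool, min(n_background_fg, length(pool))))
  }
  list(edges = edges, foreground = unique(foreground), cliques = cliques,
       nodes = nodes)
}

#' Generate a two-compartment metabolome table
#'
#' Log-normal abundances for intra- and extracellular compartments with a
#' configurable coupling between the compartments' strain-varying component
#' (`coupling = -1` with `noise_sd = 0` makes the two compartments perfectly
#' anti-correlated). Group effects shift whole metabolite groups for chosen
#' strain subcategories, e.g. raising fatty-acid biosynthesis intermediates
#' in plant strains.
#'
#' @param strains data.frame from [gen_strains()].
#' @param n_metabolites number of metabolites (79 emulates a GC-MS panel).
#' @param group_map data.frame `metabolite`, `group` (every metabolite in at
#'   least one group); NULL for a default eight-group assignment.
#' @param group_effects list of `list(group =, subcategory =, shift =)`.
#' @param coupling intra/extra coupling in \[-1, 1\].
#' @param noise_sd residual log-scale noise of the extracellular compartment.
#' @param seed integer seed.
#' @return list with matrices `intra`, `extra` (metabolites x strains) and
#'   `groups` (the group map used).
#' @export
gen_metabolome <- function(strains, n_metabolites = 79, group_map = NULL,
                           group_effects = list(), coupling = -0.5,
                           noise_sd = 0.3, seed = 1) {
  set.seed(seed)
  n <- nrow(strains)
  mets <- sprintf("met%03d", seq_len(n_metabolites))
  if (is.null(group_map)) {
    groups <- c("proteinogenic amino acids", "fatty acid biosynthesis",
                "TCA cycle", "carboxylic acids", "aromatic compounds",
                "sugars and polyols", "nucleotides", "other")
    group_map <- data.frame(metabolite = mets,
                            group = rep_len(groups, n_metabolites),
                            stringsAsFactors = FALSE)
  }
  assert_that(all(mets %in% group_map$metabolite),
              "every metabolite needs at least one group")
  mu_m <- rnorm(n_metabolites, 0, 1)
  nu_m <- rnorm(n_metabolites, 0, 1)
  sig <- matrix(rnorm(n_metabolites * n), n_metabolites, n)
  eps <- matrix(rnorm(n_metabolites * n), n_metabolites, n)
  intra_log <- mu_m + sig
  extra_log <- nu_m + coupling * sig + noise_sd * eps
  for (ge in group_effects) {
    rows <- group_map$metabolite[group_map$group == ge$group]
    cols <- which(strains$subcategory == ge$subcategory)
    ri <- match(rows, mets)
    intra_log[ri, cols] <- intra_log[ri, cols] + ge$shift
  }
  dimnames(intra_log) <- dimnames(extra_log) <- list(mets, strains$strain_id)
  list(intra = exp(intra_log), extra = exp(extra_log), groups = group_map)
}

#' Write a curve table as delimited text
#' @param curves long curve data.frame; @param path output TSV path.
#' @export
write_curves <- function(curves, path) {
  utils::write.table(curves, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write CNV segments as BED-like text (chrom, start, end, copy_number, strain)
#' @param segments CNV segment data.frame; @param path output path.
#' @export
write_cnv_bed <- function(segments, path) {
  cols <- c("chrom", "start", "end", "copy_number", "strain")
  utils::write.table(segments[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a network as a 3-column TSV (node_a, node_b, score)
#' @param edges edge data.frame; @param path output path.
#' @export
write_network_tsv <- function(edges, path) {
  utils::write.table(edges[, c("node_a", "node_b", "score")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
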