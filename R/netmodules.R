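# Protein-interaction module discovery: maximal-clique enumeration,
# hypergeometric enrichment of a foreground gene list with BH correction,
# union of significant cliques into connected modules, modularity
# statistics, and a random-gene-list null comparison.

#' Read a scored interaction network
#'
#' Three-column TSV (`node_a`, `node_b`, `score`); edges below `score_min`
#' are dropped, duplicate undirected edges keep the maximum score, and
#' self-loops are removed.
#'
#' @param path TSV path (header expected).
#' @param score_min minimum edge confidence score.
#' @return an undirected `igraph` graph with a `score` edge attribute.
#' @export
read_network <- function(path, score_min = 0) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  assert_that(ncol(df) >= 3, "network file needs 3 columns")
  names(df)[1:3] <- c("node_a", "node_b", "score")
  assert_that(!any(is.na(df$score)), "malformed network line: bad score")
  network_from_edges(df, score_min)
}

#' Build the network graph from an edge data.frame
#' @param edges data.frame `node_a`, `node_b`, `score`.
#' @param score_min minimum edge score kept.
#' @param nodes optional node universe (keeps isolated nodes in the
#'   enrichment background; defaults to the nodes appearing in edges).
#' @return an undirected `igraph` graph.
#' @export
network_from_edges <- function(edges, score_min = 0, nodes = NULL) {
  edges <- edges[edges$score >= score_min & edges$node_a != edges$node_b, ,
                 drop = FALSE]
  a <- pmin(edges$node_a, edges$node_b)
  b <- pmax(edges$node_a, edges$node_b)
  key <- paste(a, b, sep = "\r")
  if (any(duplicated(key))) {
    sc <- tapply(edges$score, key, max)
    parts <- strsplit(names(sc), "\r", fixed = TRUE)
    edges <- data.frame(node_a = vapply(parts, `[`, "", 1),
                        node_b = vapply(parts, `[`, "", 2),
                        score = as.numeric(sc), stringsAsFactors = FALSE)
  }
  if (!is.null(nodes)) {
    nodes <- union(nodes, c(edges$node_a, edges$node_b))
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  igraph::E(g)$score <- edges$score
  g
}

#' Discover foreground-enriched network modules
#'
#' Enumerates maximal cliques of at least `clique_min_size` nodes, tests
#' each for foreground enrichment with a hypergeometric test against the
#' network-node background, adjusts across cliques by Benjamini-Hochberg,
#' and unions the significant cliques; the connected components of the union
#' are the modules.
#'
#' @param g `igraph` network.
#' @param foreground character vector of foreground gene ids (members not in
#'   the network are dropped with a warning).
#' @param clique_min_size minimum clique size (default 3).
#' @param alpha BH-adjusted significance level (default 0.05).
#' @return list of modules, each `list(nodes, cliques, q_min)`; empty list
#'   when no clique is enriched.
#' @export
find_modules <- function(g, foreground, clique_min_size = 3, alpha = 0.05) {
  assert_that(length(foreground) > 0, "foreground gene list is empty")
  nodes <- igraph::V(g)$name
  missing <- setdiff(foreground, nodes)
  if (length(missing) > 0) {
    warnf("%d foreground gene(s) absent from the network; dropped",
          length(missing))
  }
  fg <- intersect(foreground, nodes)
  if (length(fg) == 0) return(list())
  cl <- igraph::max_cliques(g, min = clique_min_size)
  if (length(cl) == 0) return(list())
  cl <- lapply(cl, function(x) nodes[as.integer(x)])
  N <- length(nodes)
  Kfg <- length(fg)
  pvals <- vapply(cl, function(members) {
    k <- sum(members %in% fg)
    # P(X >= k) for X ~ Hypergeom(N, Kfg, |clique|)
    stats::phyper(k - 1, Kfg, N - Kfg, length(members), lower.tail = FALSE)
  }, numeric(1))
  qvals <- stats::p.adjust(pvals, method = "BH")
  sig <- which(qvals <= alpha)
  if (length(sig) == 0) return(list())
  # union graph of significant cliques; components = modules
  edges <- do.call(rbind, lapply(sig, function(i) {
    prs <- utils::combn(cl[[i]], 2)
    data.frame(a = prs[1, ], b = prs[2, ], stringsAsFactors = FALSE)
  }))
  ug <- igraph::graph_from_data_frame(edges, directed = FALSE)
  comp <- igraph::components(ug)
  lapply(seq_len(comp$no), function(ci) {
    mnodes <- names(comp$membership)[comp$membership == ci]
    member_cl <- sig[vapply(sig, function(i) all(cl[[i]] %in% mnodes),
                            logical(1))]
    list(nodes = sort(mnodes),
         cliques = cl[member_cl],
         q_min = min(qvals[member_cl]))
  })
}

#' Modularity statistics of a module set
#'
#' @param modules list from [find_modules()].
#' @param g the network graph.
#' @param foreground foreground gene ids.
#' @param reference curated reference gene ids (e.g. database phenotype
#'   entries) used for the overlap statistics.
#' @return one-row data.frame: `nodes_in_modules`, `nodes_in_cliques`,
#'   `internal_edges`, `foreground_proportion`, `edges_to_reference_nodes`,
#'   `overlap_rate`, `foreground_overlap_rate`.
#' @export
module_stats <- function(modules, g, foreground, reference = character()) {
  zero <- data.frame(nodes_in_modules = 0L, nodes_in_cliques = 0L,
                     internal_edges = 0L, foreground_proportion = 0,
                     edges_to_reference_nodes = 0L, overlap_rate = 0,
                     foreground_overlap_rate = 0)
  if (length(modules) == 0) return(zero)
  mnodes <- sort(unique(unlist(lapply(modules, `[[`, "nodes"))))
  cnodes <- sort(unique(unlist(lapply(modules, function(m) unlist(m$cliques)))))
  sub <- igraph::induced_subgraph(g, mnodes)
  fg_in <- intersect(mnodes, foreground)
  ref_in <- intersect(mnodes, reference)
  # edges from module nodes to reference nodes anywhere in the network
  ends <- igraph::as_edgelist(g)
  e2ref <- sum((ends[, 1] %in% mnodes & ends[, 2] %in% reference) |
                 (ends[, 2] %in% mnodes & ends[, 1] %in% reference))
  data.frame(
    nodes_in_modules = length(mnodes),
    nodes_in_cliques = length(cnodes),
    internal_edges = igraph::ecount(sub),
    foreground_proportion = length(fg_in) / length(mnodes),
    edges_to_reference_nodes = e2ref,
    overlap_rate = if (length(mnodes) > 0) length(ref_in) / length(mnodes) else 0,
    foreground_overlap_rate = if (length(fg_in) > 0)
      length(intersect(fg_in, reference)) / length(fg_in) else 0
  )
}

#' Compare real-foreground modules against random-gene-list nulls
#'
#' Runs the full module discovery for `n_random` random node lists and
#' compares each modularity statistic between the real list and the nulls
#' with a paired one-sided Wilcoxon signed-rank test (real exceeds null).
#'
#' Two pairing schemes are available. The default, `pairing = "subsample"`,
#' draws per replicate a random subsample of the foreground (fraction
#' `subsample_frac`) and an independent random node list of the same length,
#' and pairs the two runs; under a random foreground the two lists are
#' exchangeable, so the reported P values are calibrated. The alternative
#' `pairing = "vs_real"` pairs the full real list's (constant) statistics
#' against each null run; it uses the whole foreground but its P values are
#' only descriptive because the pairs share the single real value.
#'
#' @param g network graph.
#' @param foreground foreground gene ids.
#' @param reference reference gene ids for the overlap statistics.
#' @param n_random number of replicates (>= 1; 5 mirrors the study design).
#' @param seed integer seed.
#' @param clique_min_size,alpha passed to [find_modules()].
#' @param pairing `"subsample"` (default) or `"vs_real"`.
#' @param subsample_frac foreground fraction per subsample replicate.
#' @return list with `real` (full-list stats row), `real_reps` and `null`
#'   (per-replicate stats) and `tests` (per-statistic signed-rank P values).
#' @export
null_comparison <- function(g, foreground, reference = character(),
                            n_random = 5, seed = 1, clique_min_size = 3,
                            alpha = 0.05,
                            pairing = c("subsample", "vs_real"),
                            subsample_frac = 0.9) {
  pairing <- match.arg(pairing)
  assert_that(n_random >= 1, "n_random must be >= 1")
  assert_that(length(foreground) > 0, "foreground gene list is empty")
  set.seed(seed)
  nodes <- igraph::V(g)$name
  fg <- intersect(foreground, nodes)
  run_stats <- function(list_i) {
    module_stats(suppressWarnings(
      find_modules(g, list_i, clique_min_size, alpha)), g, list_i, reference)
  }
  real <- run_stats(fg)
  if (pairing == "subsample") {
    k <- max(1L, round(subsample_frac * length(fg)))
    real_reps <- do.call(rbind, lapply(seq_len(n_random), function(i) {
      run_stats(sample(fg, k))
    }))
    null_df <- do.call(rbind, lapply(seq_len(n_random), function(i) {
      run_stats(sample(nodes, k))
    }))
  } else {
    real_reps <- real[rep(1L, n_random), , drop = FALSE]
    null_df <- do.call(rbind, lapply(seq_len(n_random), function(i) {
      run_stats(sample(nodes, length(fg)))
    }))
  }
  tests <- vapply(names(real), function(st) {
    d <- real_reps[[st]] - null_df[[st]]
    if (all(d == 0)) return(1)
    suppressWarnings(stats::wilcox.test(d, mu = 0,
                                        alternative = "greater")$p.value)
  }, numeric(1))
  list(real = real, real_reps = real_reps, null = null_df, tests = tests)
}

#' Cross-phenotype module overlap
#'
#' Jaccard similarity of module node sets across phenotypes; pairs at or
#' above `jaccard_min` are flagged as shared modules.
#'
#' @param module_sets named list (phenotype -> [find_modules()] result).
#' @param jaccard_min sharing threshold (default 0.5).
#' @return data.frame `phenotype_a`, `module_a`, `phenotype_b`, `module_b`,
#'   `jaccard`, `shared`.
#' @export
shared_modules <- function(module_sets, jaccard_min = 0.5) {
  assert_that(length(module_sets) >= 2, "need at least 2 module sets")
  phen <- names(module_sets)
  out <- list()
  for (i in seq_along(phen)[-length(phen)]) {
    for (j in (i + 1):length(phen)) {
      ma <- module_sets[[i]]
      mb <- module_sets[[j]]
      for (a in seq_along(ma)) {
        for (b in seq_along(mb)) {
          na <- ma[[a]]$nodes
          nb <- mb[[b]]$nodes
          jac <- length(intersect(na, nb)) / length(union(na, nb))
          out[[length(out) + 1L]] <- data.frame(
            phenotype_a = phen[i], module_a = a,
            phenotype_b = phen[j], module_b = b,
            jaccard = jac, shared = jac >= jaccard_min,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(phenotype_a = character(), module_a = integer(),
                      phenotype_b = character(), module_b = integer(),
                      jaccard = numeric(), shared = logical(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
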