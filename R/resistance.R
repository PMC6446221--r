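# Performance and robustness scoring of strains from growth parameters,
# integration across inhibitory levels into per-condition rankings, and
# sensitivity of the rankings to the parameter weights (rank variability
# analysis and parameter-influence scores).

#' The five growth parameters used by the scoring layer
#' @export
growth_param_fields <- c("lag_h", "mu_max", "amplitude", "t_half", "auc")

# Parameters for which smaller is better (inverted before scoring).
time_like_fields <- c("lag_h", "t_half")

#' Construct a normalized weight vector over the five growth parameters
#'
#' @param w five non-negative reals; normalized to sum 1.
#' @return named numeric vector of length 5.
#' @export
weight_vector <- function(w = rep(1, 5)) {
  assert_that(length(w) == 5, "need exactly 5 weights")
  assert_that(all(w >= 0), "weights must be non-negative")
  assert_that(sum(w) > 0, "weights must not all be zero")
  w <- w / sum(w)
  names(w) <- growth_param_fields
  w
}

#' Orient and min-max normalize a parameter table at one condition and level
#'
#' Time-like parameters (lag, t_half) are inverted so that larger always
#' means better, then every parameter is min-max scaled across the growing
#' strains at that level (degenerate range maps to 0.5; a single grower gets
#' 1). Non-growing strains are pinned to 0 on all parameters.
#'
#' @param level_params parameter-table rows of one condition + level
#'   (columns `strain`, the five parameters, `grew`).
#' @return strains x 5 matrix in \[0, 1\] with strain rownames, or `NULL`
#'   (level unusable) when no strain grew.
#' @export
orient_and_normalize <- function(level_params) {
  growers <- which(level_params$grew)
  if (length(growers) == 0L) return(NULL)
  n <- nrow(level_params)
  out <- matrix(0, n, length(growth_param_fields),
                dimnames = list(level_params$strain, growth_param_fields))
  for (f in growth_param_fields) {
    x <- level_params[[f]][growers]
    if (f %in% time_like_fields) x <- -x
    out[growers, f] <- if (length(growers) == 1L) 1 else minmax01(x)
  }
  out
}

#' Per-strain performance at one level
#'
#' Weighted sum of the oriented, normalized parameters: how well each strain
#' compares with the other strains at this condition and inhibitory level.
#'
#' @param oriented matrix from [orient_and_normalize()].
#' @param w weight vector (see [weight_vector()]).
#' @return named numeric vector in \[0, 1\].
#' @export
performance_level <- function(oriented, w = weight_vector()) {
  w <- weight_vector(w)
  drop(oriented[, growth_param_fields, drop = FALSE] %*% w)
}

#' Per-strain robustness across the inhibitory levels of one condition
#'
#' Robustness measures how well a strain maintains its own growth parameters
#' as the inhibitory level increases: for each parameter the retention at a
#' level is the ratio to the strain's value at the least inhibitory
#' (reference) level, clamped to \[0, 1\], with time-like parameters inverted
#' before the ratio; levels at which the strain did not grow retain 0. The
#' score is the weighted mean retention over parameters, averaged over all
#' non-reference levels.
#'
#' @param cond_params parameter-table rows of one condition (all levels).
#' @param w weight vector.
#' @return named numeric vector in \[0, 1\]; `NA` for strains absent or
#'   non-growing at the reference level (ranked last downstream).
#' @export
robustness_strain <- function(cond_params, w = weight_vector()) {
  w <- weight_vector(w)
  levels_present <- sort(unique(cond_params$level))
  assert_that(length(levels_present) >= 2, "need at least 2 levels")
  ref_level <- levels_present[1]
  higher <- levels_present[-1]
  strains <- unique(cond_params$strain)
  ref <- cond_params[cond_params$level == ref_level, , drop = FALSE]
  out <- stats::setNames(rep(NA_real_, length(strains)), strains)
  for (s in strains) {
    r <- ref[ref$strain == s, , drop = FALSE]
    if (nrow(r) == 0L || !r$grew[1]) next
    ret <- stats::setNames(numeric(length(growth_param_fields)),
                           growth_param_fields)
    for (f in growth_param_fields) {
      vals <- vapply(higher, function(l) {
        d <- cond_params[cond_params$strain == s & cond_params$level == l, ,
                         drop = FALSE]
        if (nrow(d) == 0L || !d$grew[1]) return(0)
        if (f %in% time_like_fields) {
          if (d[[f]][1] <= 0) return(0)
          min(1, max(0, r[[f]][1] / d[[f]][1]))
        } else {
          if (r[[f]][1] <= 0) return(0)
          min(1, max(0, d[[f]][1] / r[[f]][1]))
        }
      }, numeric(1))
      ret[f] <- mean(vals)
    }
    out[s] <- sum(w * ret)
  }
  out
}

#' Integrate per-level scores into one per-strain condition score
#'
#' Unweighted mean over usable levels by default; optional level weights.
#'
#' @param level_scores matrix strains x levels (NA for unusable levels).
#' @param level_weights optional non-negative weights per level column.
#' @return named numeric vector.
#' @export
integrate_levels <- function(level_scores, level_weights = NULL) {
  level_scores <- as.matrix(level_scores)
  if (is.null(level_weights)) {
    return(rowMeans(level_scores, na.rm = TRUE))
  }
  assert_that(length(level_weights) == ncol(level_scores),
              "one weight per level required")
  apply(level_scores, 1, function(x) {
    ok <- !is.na(x)
    if (!any(ok)) return(NA_real_)
    sum(x[ok] * level_weights[ok]) / sum(level_weights[ok])
  })
}

#' Score one condition: integrated performance and robustness per strain
#'
#' @param cond_params parameter-table rows of one condition.
#' @param w weight vector.
#' @param level_weights optional level-integration weights for performance.
#' @return data.frame `strain`, `performance`, `robustness`.
#' @export
score_condition <- function(cond_params, w = weight_vector(),
                            level_weights = NULL) {
  w <- weight_vector(w)
  strains <- sort(unique(cond_params$strain))
  levels_present <- sort(unique(cond_params$level))
  perf <- matrix(NA_real_, length(strains), length(levels_present),
                 dimnames = list(strains, levels_present))
  for (j in seq_along(levels_present)) {
    lp <- cond_params[cond_params$level == levels_present[j], , drop = FALSE]
    om <- orient_and_normalize(lp)
    if (is.null(om)) next
    p <- performance_level(om, w)
    perf[names(p), j] <- p
  }
  performance <- integrate_levels(perf, level_weights)
  robustness <- if (length(levels_present) >= 2) {
    robustness_strain(cond_params, w)[strains]
  } else {
    stats::setNames(rep(NA_real_, length(strains)), strains)
  }
  data.frame(strain = strains,
             performance = as.numeric(performance[strains]),
             robustness = as.numeric(robustness),
             stringsAsFactors = FALSE)
}

#' Rank strains within a condition
#'
#' Descending scores give rank 1 to the best strain, ties receive average
#' ranks and missing scores are ranked last. The decile ranking value is
#' `ceiling(10 * rank / n_strains)` (1 = top decile, 10 = bottom).
#'
#' @param scores named numeric vector (strain -> score), NAs allowed.
#' @param condition,score_type identifiers carried into the output.
#' @return data.frame `condition`, `score_type`, `strain`, `score`, `rank`,
#'   `ranking_value`.
#' @export
rank_condition <- function(scores, condition = NA_character_,
                           score_type = NA_character_) {
  r <- rank_desc_na_last(scores)
  data.frame(condition = condition, score_type = score_type,
             strain = names(scores), score = as.numeric(scores),
             rank = r, ranking_value = as.integer(ceiling(10 * r / length(r))),
             stringsAsFactors = FALSE)
}

#' Rank all conditions for both score types
#'
#' @param params full parameter table (all conditions).
#' @param w weight vector.
#' @return long data.frame of [rank_condition()] rows for every condition
#'   and score type.
#' @export
rank_all <- function(params, w = weight_vector()) {
  out <- lapply(sort(unique(params$condition)), function(cc) {
    sc <- score_condition(params[params$condition == cc, , drop = FALSE], w)
    rbind(
      rank_condition(stats::setNames(sc$performance, sc$strain), cc,
                     "performance"),
      rank_condition(stats::setNames(sc$robustness, sc$strain), cc,
                     "robustness")
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Frequency of top-k appearances across all rankings
#'
#' @param rankings long ranking data.frame from [rank_all()].
#' @param k rank cutoff (default top 10).
#' @return data.frame `strain`, `top_k_count`, sorted descending.
#' @export
top_frequency <- function(rankings, k = 10) {
  strains <- sort(unique(rankings$strain))
  cnt <- vapply(strains, function(s) {
    sum(rankings$rank[rankings$strain == s] <= k)
  }, numeric(1))
  out <- data.frame(strain = strains, top_k_count = as.integer(cnt),
                    stringsAsFactors = FALSE)
  out[order(-out$top_k_count, out$strain), , drop = FALSE]
}

# Uniform sample from the 4-simplex: Dirichlet(1,1,1,1,1).
rdirichlet5 <- function(n) {
  g <- matrix(stats::rgamma(5 * n, 1), n, 5)
  g / rowSums(g)
}

#' Rank variability analysis (RVA)
#'
#' Re-scores and re-ranks all strains under `n_weight_samples` weight vectors
#' drawn uniformly from the simplex, quantifying how stable each strain's
#' ranking is to the choice of parameter weights.
#'
#' @param params full parameter table.
#' @param n_weight_samples number of Dirichlet(1,...,1) weight draws.
#' @param seed integer seed.
#' @param probs rank quantiles to report.
#' @return list with `ranks` (strain x condition x score_type x sample rank
#'   array flattened to a long data.frame), `summary` (per strain/condition/
#'   score_type rank quantiles) and `bin_probs` (probability of each decile
#'   ranking value).
#' @export
rank_variability <- function(params, n_weight_samples = 100, seed = 1,
                             probs = c(0.05, 0.25, 0.5, 0.75, 0.95)) {
  assert_that(n_weight_samples >= 1, "n_weight_samples must be >= 1")
  set.seed(seed)
  W <- rdirichlet5(n_weight_samples)
  draws <- lapply(seq_len(n_weight_samples), function(i) {
    rk <- rank_all(params, weight_vector(W[i, ]))
    rk$sample <- i
    rk
  })
  long <- do.call(rbind, draws)
  key <- paste(long$strain, long$condition, long$score_type, sep = "\r")
  summ <- do.call(rbind, lapply(split(long, key), function(d) {
    q <- stats::quantile(d$rank, probs = probs, names = FALSE)
    out <- data.frame(strain = d$strain[1], condition = d$condition[1],
                      score_type = d$score_type[1], stringsAsFactors = FALSE)
    for (i in seq_along(probs)) out[[sprintf("q%02d", round(100 * probs[i]))]] <- q[i]
    out
  }))
  bins <- do.call(rbind, lapply(split(long, key), function(d) {
    p <- tabulate(d$ranking_value, nbins = 10) / nrow(d)
    out <- data.frame(strain = d$strain[1], condition = d$condition[1],
                      score_type = d$score_type[1], stringsAsFactors = FALSE)
    for (b in 1:10) out[[paste0("bin", b)]] <- p[b]
    out
  }))
  rownames(summ) <- rownames(bins) <- NULL
  list(ranks = long, summary = summ, bin_probs = bins)
}

#' Parameter-influence (PI) scores
#'
#' For every growth parameter, the baseline equal-weight ranking is compared
#' with the ranking obtained after giving that parameter extra weight
#' (`bump`, renormalized). The raw PI of a strain is the improvement in rank
#' position (baseline rank minus bumped rank; positive = moved up). All raw
#' scores are normalized by the global maximum absolute value over all
#' parameters and conditions, so PI lies in \[-1, 1\] with at least one entry
#' at +/-1 unless all are zero.
#'
#' @param params full parameter table.
#' @param bump positive weight increment.
#' @return long data.frame `strain`, `condition`, `score_type`, `parameter`,
#'   `pi_raw`, `pi`.
#' @export
parameter_influence <- function(params, bump = 0.2) {
  assert_that(bump > 0, "bump must be > 0")
  base <- rank_all(params, weight_vector())
  out <- list()
  for (k in seq_along(growth_param_fields)) {
    w <- rep(0.2, 5)
    w[k] <- w[k] + bump
    bumped <- rank_all(params, weight_vector(w))
    m <- merge(base, bumped,
               by = c("condition", "score_type", "strain"),
               suffixes = c("_base", "_bump"))
    out[[k]] <- data.frame(strain = m$strain, condition = m$condition,
                           score_type = m$score_type,
                           parameter = growth_param_fields[k],
                           pi_raw = m$rank_base - m$rank_bump,
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  mx <- max(abs(out$pi_raw))
  out$pi <- if (mx > 0) out$pi_raw / mx else 0
  rownames(out) <- NULL
  out
}

#' Spearman correlation of two strains' PI profiles
#'
#' Correlates the flattened (parameter x condition x score type) PI vectors
#' of two strains.
#'
#' @param pi_scores long data.frame from [parameter_influence()].
#' @param strain_a,strain_b strain ids.
#' @return list `rho`, `p` (both NA when a profile is constant).
#' @export
pi_correlation <- function(pi_scores, strain_a, strain_b) {
  a <- pi_scores[pi_scores$strain == strain_a, ]
  b <- pi_scores[pi_scores$strain == strain_b, ]
  m <- merge(a, b, by = c("condition", "score_type", "parameter"),
             suffixes = c("_a", "_b"))
  assert_that(nrow(m) >= 3, "need at least 3 paired PI entries")
  if (stats::sd(m$pi_a) == 0 || stats::sd(m$pi_b) == 0) {
    return(list(rho = NA_real_, p = NA_real_))
  }
  ct <- suppressWarnings(stats::cor.test(m$pi_a, m$pi_b, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value)
}
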