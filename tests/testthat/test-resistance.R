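# Scoring, ranking, rank variability and parameter influence.

test_that("orientation and min-max normalization follow the level rules", {
  # lag (2h, 4h): inverted then scaled -> (1, 0)
  lp <- rbind(param_row("A", "C1", 0, 2, 0.4, 1, 10, 50),
              param_row("B", "C1", 0, 4, 0.4, 1, 10, 50))
  om <- orient_and_normalize(lp)
  expect_equal(unname(om[, "lag_h"]), c(1, 0))
  # degenerate fields all 0.5
  expect_equal(unname(om[, "mu_max"]), c(0.5, 0.5))

  # a single grower gets 1 everywhere, the non-grower 0
  lp2 <- rbind(param_row("A", "C1", 0, 2, 0.4, 1, 10, 50),
               param_row("B", "C1", 0, 66, 0, 0, 66, 0, grew = FALSE))
  om2 <- orient_and_normalize(lp2)
  expect_equal(unname(om2["A", ]), rep(1, 5))
  expect_equal(unname(om2["B", ]), rep(0, 5))

  # all identical growers -> 0.5 across the board
  lp3 <- rbind(param_row("A", "C1", 0, 3, 0.4, 1, 10, 50),
               param_row("B", "C1", 0, 3, 0.4, 1, 10, 50))
  expect_true(all(orient_and_normalize(lp3) == 0.5))

  # all non-growers -> unusable level
  lp4 <- param_row("A", "C1", 0, 66, 0, 0, 66, 0, grew = FALSE)
  expect_null(orient_and_normalize(lp4))
})

test_that("performance is a weighted sum with the expected special cases", {
  lp <- rbind(param_row("A", "C1", 0, 2, 0.5, 1.2, 8, 60),
              param_row("B", "C1", 0, 4, 0.3, 0.8, 12, 40),
              param_row("C", "C1", 0, 3, 0.4, 1.0, 10, 50))
  om <- orient_and_normalize(lp)
  # A dominates every parameter -> unique maximum under any weights
  p_eq <- performance_level(om, weight_vector())
  expect_equal(names(which.max(p_eq)), "A")
  expect_equal(unname(p_eq["A"]), 1)
  # degenerate weights reduce to a single parameter's ordering
  p_mu <- performance_level(om, weight_vector(c(0, 1, 0, 0, 0)))
  expect_equal(order(-p_mu), order(-lp$mu_max))
  # swapped profiles with symmetric weights give equal scores
  lp_sym <- rbind(param_row("X", "C1", 0, 2, 0.3, 1, 10, 50),
                  param_row("Y", "C1", 0, 4, 0.5, 1, 10, 50))
  om_sym <- orient_and_normalize(lp_sym)
  p_sym <- performance_level(om_sym, weight_vector(c(1, 1, 0, 0, 0)))
  expect_equal(unname(p_sym["X"]), unname(p_sym["Y"]))
})

test_that("robustness rewards retention and zeroes reference-only growers", {
  # stable strain: identical parameters at every level -> robustness 1
  # fragile strain: grows only at the reference level -> robustness 0
  rows <- list()
  for (l in 0:3) {
    rows[[length(rows) + 1L]] <- param_row("stable", "C1", l, 3, 0.4, 1, 10, 50)
    rows[[length(rows) + 1L]] <-
      if (l == 0) param_row("fragile", "C1", l, 2, 0.5, 1.2, 8, 60)
      else param_row("fragile", "C1", l, 66, 0, 0, 66, 0, grew = FALSE)
  }
  cp <- do.call(rbind, rows)
  rb <- robustness_strain(cp)
  expect_equal(unname(rb["stable"]), 1)
  expect_equal(unname(rb["fragile"]), 0)
  # absent at reference -> NA
  cp2 <- cp[!(cp$strain == "fragile" & cp$level == 0), ]
  rb2 <- robustness_strain(cp2)
  expect_true(is.na(rb2["fragile"]))
})

test_that("high-performance/low-robustness and the reverse pattern emerge", {
  # strain P: excellent at low levels, collapses at high levels;
  # strain D: modest but perfectly stable; strain M: middling throughout.
  rows <- list()
  for (l in 0:3) {
    f <- c(1, 0.9, 0.2, 0.05)[l + 1]
    rows[[length(rows) + 1L]] <- param_row("P", "C1", l, 2 / f, 0.6 * f,
                                           1.4 * f, 6 / f, 80 * f,
                                           grew = f > 0.1)
    rows[[length(rows) + 1L]] <- param_row("D", "C1", l, 4, 0.3, 0.8, 12, 40)
    rows[[length(rows) + 1L]] <- param_row("M", "C1", l, 3, 0.4, 1, 10, 50)
  }
  cp <- do.call(rbind, rows)
  cp[!cp$grew, c("lag_h", "t_half")] <- 66
  cp[!cp$grew, c("mu_max", "amplitude", "auc")] <- 0
  sc <- score_condition(cp)
  perf <- setNames(sc$performance, sc$strain)
  rob <- setNames(sc$robustness, sc$strain)
  expect_gt(perf["P"], perf["D"])   # P outperforms cross-sectionally
  expect_lt(rob["P"], rob["D"])     # but D withstands the levels
  expect_equal(unname(rob["D"]), 1)
})

test_that("ranking uses average ties, NA-last, and decile values", {
  r <- rank_condition(c(A = 0.9, B = 0.5, C = 0.5, D = 0.1), "C1", "performance")
  expect_equal(r$rank, c(1, 2.5, 2.5, 4))
  # decile: rank 22 of 36 -> ceiling(220/36) = 7 (a "low" value > 6)
  scores36 <- setNames(seq(36, 1), sprintf("S%02d", 1:36))
  r36 <- rank_condition(scores36)
  expect_equal(r36$ranking_value[r36$rank == 22], 7L)
  expect_true(all(r36$ranking_value >= 1 & r36$ranking_value <= 10))
  # all equal scores share one ranking value
  re <- rank_condition(c(A = 1, B = 1, C = 1))
  expect_equal(length(unique(re$ranking_value)), 1L)
  # missing ranked last
  rna <- rank_condition(c(A = 0.2, B = NA, C = 0.5))
  expect_equal(rna$rank[rna$strain == "B"], 3)
})

test_that("top-k frequency counts both score types over all conditions", {
  # A is best at every level AND retains fully; the others decay
  vals <- rbind(A = c(0.50, 0.50, 0.50),
                B = c(0.45, 0.30, 0.20),
                C = c(0.40, 0.25, 0.15),
                D = c(0.35, 0.20, 0.10))
  pt <- rbind(single_param_table(vals, condition = "C1"),
              single_param_table(vals, condition = "C2"))
  rk <- rank_all(pt)
  tf <- top_frequency(rk, k = 1)
  expect_equal(tf$top_k_count[tf$strain == "A"], 4L)  # 2 conditions x 2 types
  # k = n keeps everyone in every ranking
  tf_all <- top_frequency(rk, k = 4)
  expect_true(all(tf_all$top_k_count == 4L))
})

test_that("a dominant strain is rank 1 under every sampled weight vector", {
  vals <- matrix(c(0.5, 0.4, 0.3, 0.2), 4, 3,
                 dimnames = list(c("A", "B", "C", "D"), NULL))
  pt <- single_param_table(vals)
  # A dominates the one informative parameter; the rest are level ties
  rva <- rank_variability(pt, n_weight_samples = 25, seed = 3)
  a_perf <- rva$ranks[rva$ranks$strain == "A" &
                        rva$ranks$score_type == "performance", ]
  expect_true(all(a_perf$rank == 1))
  # identical strains have identical rank distributions
  vals2 <- matrix(c(0.5, 0.5, 0.2), 3, 2,
                  dimnames = list(c("A", "B", "C"), NULL))
  rva2 <- rank_variability(single_param_table(vals2), 25, seed = 4)
  sa <- rva2$summary[rva2$summary$strain == "A", -1]
  sb <- rva2$summary[rva2$summary$strain == "B", -1]
  rownames(sa) <- rownames(sb) <- NULL
  expect_equal(sa, sb)
  # determinism
  rva3 <- rank_variability(pt, 25, seed = 3)
  expect_equal(rva$ranks, rva3$ranks)
})

test_that("PI scores are normalized to [-1, 1] with the right signs", {
  # A leads on mu_max only; B leads on amplitude only; C trails both
  rows <- list()
  for (l in 0:1) {
    rows[[length(rows) + 1L]] <- param_row("A", "C1", l, 3, 0.6, 0.9, 10, 50)
    rows[[length(rows) + 1L]] <- param_row("B", "C1", l, 3, 0.35, 1.3, 10, 50)
    rows[[length(rows) + 1L]] <- param_row("C", "C1", l, 3, 0.4, 1.0, 10, 50)
  }
  pt <- do.call(rbind, rows)
  pi_scores <- parameter_influence(pt, bump = 0.4)
  expect_true(all(pi_scores$pi >= -1 & pi_scores$pi <= 1))
  expect_equal(max(abs(pi_scores$pi)), 1)
  a_mu <- pi_scores[pi_scores$strain == "A" &
                      pi_scores$parameter == "mu_max" &
                      pi_scores$score_type == "performance", ]
  expect_gt(a_mu$pi, 0)  # up-weighting its best parameter moves A up
  expect_error(parameter_influence(pt, bump = 0), "> 0")
  # identical strains -> all-zero PI
  vals_id <- matrix(0.4, 3, 2, dimnames = list(c("A", "B", "C"), NULL))
  pi0 <- parameter_influence(single_param_table(vals_id))
  expect_true(all(pi0$pi == 0))
})

test_that("PI correlations hit the trivial anchors", {
  # two conflicting informative parameters so rank changes under bumps
  mk_cond <- function(cc, mu, amp) {
    do.call(rbind, lapply(0:1, function(l) {
      do.call(rbind, lapply(seq_along(mu), function(i) {
        param_row(c("A", "B", "C", "D")[i], cc, l, 3, mu[i], amp[i], 10, 50)
      }))
    }))
  }
  pt <- rbind(mk_cond("C1", c(0.6, 0.5, 0.4, 0.3), c(0.8, 1.0, 1.2, 1.4)),
              mk_cond("C2", c(0.3, 0.6, 0.5, 0.4), c(1.4, 0.8, 1.2, 1.0)))
  pi_scores <- parameter_influence(pt, bump = 0.5)
  expect_gt(sd(pi_scores$pi[pi_scores$strain == "A"]), 0)
  self <- pi_correlation(pi_scores, "A", "A")
  expect_equal(self$rho, 1)
  # mirrored profiles correlate at -1
  mirrored <- pi_scores
  mirrored$pi[mirrored$strain == "B"] <- -pi_scores$pi[pi_scores$strain == "A"]
  mir <- pi_correlation(mirrored, "A", "B")
  expect_equal(mir$rho, -1)
})

test_that("final rankings are invariant to a common monotone signal rescale", {
  st <- gen_strains(6, seed = 10)
  gc <- gen_growth_curves(st, n_conditions = 1, levels_per_condition = 4,
                          n_replicates = 1, noise_sd = 0, seed = 11, dt = 1)
  p1 <- extract_params_table(gc$curves, blank = gc$truth$blank)
  scaled <- gc$curves
  scaled$signal <- (scaled$signal - gc$truth$blank) * 3 + gc$truth$blank
  p2 <- extract_params_table(scaled, blank = gc$truth$blank)
  r1 <- rank_all(p1)
  r2 <- rank_all(p2)
  expect_equal(r1$rank, r2$rank)
})

test_that("with one informative parameter the ranking matches the truth", {
  # shared dose-response factor keeps the strain order fixed across levels,
  # so the true ordering is the baseline ordering of the informative field
  set.seed(12)
  for (rep in 1:3) {
    mu0 <- sort(runif(5, 0.2, 0.6), decreasing = TRUE)
    names(mu0) <- sprintf("S%d", 1:5)
    f <- c(1, 0.8, 0.5, 0.3)
    vals <- outer(mu0, f)
    pt <- single_param_table(vals)
    rk <- rank_all(pt)
    perf <- rk[rk$score_type == "performance", ]
    expect_equal(perf$strain[order(perf$rank)], names(mu0))
  }
})
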