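# Shared fixtures built in code: closed-form curves, tiny hand-made
# parameter tables, and small interval/genotype toys.

# Independent closed form of the logistic trajectory used as extraction
# oracle (written out here so the test does not lean on the generator).
oracle_logistic <- function(times, mu, A, lag, blank = 0) {
  t_mid <- lag + 2 / mu
  blank + A / (1 + exp(-mu * (times - t_mid)))
}

# A minimal parameter-table row.
param_row <- function(strain, condition, level, lag_h, mu_max, amplitude,
                      t_half, auc, grew = TRUE) {
  data.frame(strain = strain, condition = condition, level = level,
             lag_h = lag_h, mu_max = mu_max, amplitude = amplitude,
             t_half = t_half, auc = auc, grew = grew,
             stringsAsFactors = FALSE)
}

# Parameter table where a single field varies across strains and levels;
# all other fields are constant (uninformative).
single_param_table <- function(values, field = "mu_max",
                               condition = "C1") {
  # values: strains x levels matrix (NA = no growth)
  strains <- rownames(values)
  rows <- list()
  const <- list(lag_h = 3, mu_max = 0.4, amplitude = 1, t_half = 10,
                auc = 50)
  for (s in strains) {
    for (l in seq_len(ncol(values))) {
      v <- values[s, l]
      r <- param_row(s, condition, l - 1L, const$lag_h, const$mu_max,
                     const$amplitude, const$t_half, const$auc,
                     grew = !is.na(v))
      if (!is.na(v)) r[[field]] <- v else {
        r$lag_h <- r$t_half <- 66
        r$mu_max <- r$amplitude <- r$auc <- 0
      }
      rows[[length(rows) + 1L]] <- r
    }
  }
  do.call(rbind, rows)
}

# Brute-force per-base oracle for CNV marker construction (independent of
# the breakpoint algorithm): walks every base, groups identical non-empty
# presence columns into maximal runs, applies the same frequency filter.
cnv_oracle <- function(segments, strains, event, min_class_frac = 0.05) {
  want <- if (event == "loss") c("loss", "deletion") else "gain"
  seg <- segments[segments$event %in% want, , drop = FALSE]
  out <- list()
  for (cc in unique(seg$chrom)) {
    d <- seg[seg$chrom == cc, , drop = FALSE]
    lo <- min(d$start); hi <- max(d$end)
    bases <- lo:(hi - 1)
    P <- sapply(strains, function(s) {
      ds <- d[d$strain == s, , drop = FALSE]
      cov <- rep(FALSE, length(bases))
      for (k in seq_len(nrow(ds))) {
        cov <- cov | (bases >= ds$start[k] & bases < ds$end[k])
      }
      cov
    })
    if (is.null(dim(P))) P <- matrix(P, nrow = length(bases))
    key <- apply(P, 1, paste, collapse = "")
    occupied <- rowSums(P) > 0
    i <- 1L
    while (i <= length(bases)) {
      if (!occupied[i]) { i <- i + 1L; next }
      j <- i
      while (j + 1L <= length(bases) && key[j + 1L] == key[i]) j <- j + 1L
      out[[length(out) + 1L]] <- list(chrom = cc, start = bases[i],
                                      end = bases[j] + 1L,
                                      presence = as.integer(P[i, ]))
      i <- j + 1L
    }
  }
  n <- length(strains)
  keep <- vapply(out, function(m) {
    minor <- min(sum(m$presence), n - sum(m$presence))
    minor > 0 && minor / n >= min_class_frac
  }, logical(1))
  out[keep]
}

# Random PSD kinship-like matrix with unit mean diagonal.
random_psd <- function(n, seed = 1) {
  set.seed(seed)
  Z <- matrix(rnorm(n * 3 * n), 3 * n, n)
  K <- crossprod(Z) / (3 * n)
  K / mean(diag(K))
}

# Direct (explicit-inverse) restricted log-likelihood at a given delta,
# profiling sigma_g2; the independent oracle for the spectral REML fit.
direct_reml_loglik <- function(y, K, X, delta) {
  n <- length(y)
  q <- ncol(X)
  V1 <- K + delta * diag(n)
  V1i <- solve(V1)
  XtV1iX <- t(X) %*% V1i %*% X
  P1 <- V1i - V1i %*% X %*% solve(XtV1iX) %*% t(X) %*% V1i
  sg2 <- drop(t(y) %*% P1 %*% y) / (n - q)
  ld <- function(M) as.numeric(determinant(M, logarithm = TRUE)$modulus)
  -0.5 * ((n - q) * log(2 * pi * sg2) + ld(V1) + ld(XtV1iX) -
            ld(crossprod(X)) + (n - q))
}
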