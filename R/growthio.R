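# Reading growth-curve tables and extracting the five per-curve growth
# parameters (lag, mu_max, amplitude, t_half, AUC) that feed the resistance
# scores.

#' Read a growth-curve table
#'
#' Expects a delimited text file with columns `strain`, `condition`, `level`,
#' `replicate`, `time_h`, `signal` (the format written by [write_curves()]).
#' Rows are validated; within each curve the rows are sorted by time (with a
#' warning if they arrived shuffled).
#'
#' @param path file path.
#' @return long data.frame of curves, one row per observation.
#' @export
read_curves <- function(path) {
  assert_that(file.exists(path), "file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("strain", "condition", "level", "replicate", "time_h", "signal")
  assert_that(all(need %in% names(df)),
              "curve table must have columns: %s", paste(need, collapse = ", "))
  bad <- which(!is.finite(df$signal) | !is.finite(df$time_h))
  if (length(bad) > 0) {
    stopf("malformed curve row(s) at line(s) %s: missing/non-numeric values",
          paste(utils::head(bad + 1L, 5), collapse = ", "))
  }
  key <- paste(df$strain, df$condition, df$level, df$replicate)
  shuffled <- FALSE
  reord <- seq_len(nrow(df))
  for (idx in split(seq_len(nrow(df)), key)) {
    tt <- df$time_h[idx]
    if (any(duplicated(tt))) {
      stopf("curve %s has non-increasing (duplicated) time points",
            key[idx[1]])
    }
    if (is.unsorted(tt, strictly = TRUE)) {
      shuffled <- TRUE
      reord[idx] <- idx[order(tt)]  # sort within the curve, keep row blocks
    }
  }
  if (shuffled) warnf("time rows arrived unsorted; sorted by time per curve")
  df <- df[reord, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Split a long curve table into per-curve lists
#'
#' @param curves long curve data.frame.
#' @return list of curves, each a list with ids, `time_h` and `signal`.
#' @export
curve_list <- function(curves) {
  key <- paste(curves$strain, curves$condition, curves$level,
               curves$replicate, sep = "\r")
  lapply(split(curves, key), function(d) {
    d <- d[order(d$time_h), ]
    list(strain = d$strain[1], condition = d$condition[1],
         level = d$level[1], replicate = d$replicate[1],
         time_h = d$time_h, signal = d$signal)
  })
}

#' Smooth a signal with a centered moving median
#'
#' Endpoints are handled by shrinking the window; `window = 1` is the
#' identity. A centered median removes single-point spikes without displacing
#' monotone stretches of the curve.
#'
#' @param signal numeric vector.
#' @param window odd window size, at most `length(signal)`.
#' @return smoothed numeric vector.
#' @export
smooth_signal <- function(signal, window = 5) {
  assert_that(window %% 2 == 1, "window must be odd")
  assert_that(window <= length(signal), "window exceeds number of points")
  if (window == 1L) return(signal)
  h <- (window - 1L) %/% 2L
  n <- length(signal)
  vapply(seq_len(n), function(i) {
    hh <- min(h, i - 1L, n - i)  # shrink symmetrically at the ends
    stats::median(signal[(i - hh):(i + hh)])
  }, numeric(1))
}

#' Extract the five growth parameters from one curve
#'
#' Works on any sigmoid-like trajectory (no curve-family assumption):
#' * `mu_max`: maximum slope of the natural log of the blank-subtracted
#'   (optionally smoothed) signal over a sliding linear-regression window;
#' * `amplitude`: maximum blank-subtracted signal;
#' * `t_half`: first time the blank-subtracted signal reaches half the
#'   amplitude (linear interpolation);
#' * `lag_h`: Zwietering tangent construction - the tangent through the
#'   half-amplitude point with the inflection slope `mu_max * A / 4`
#'   intersected with the baseline, i.e. `t_half - 2 / mu_max` (clamped at 0);
#' * `auc`: trapezoidal area of the blank-subtracted signal over the full
#'   observation window.
#'
#' A curve whose amplitude stays below `min_amplitude` is scored "no growth"
#' and receives defined worst-case sentinels (lag and t_half at the end of
#' observation, mu_max = amplitude = auc = 0) so downstream ranking is total.
#'
#' @param time_h,signal the curve.
#' @param blank background signal level to subtract.
#' @param min_amplitude growth/no-growth amplitude threshold.
#' @param reg_window sliding log-linear regression width (points).
#' @param smooth_window odd moving-median window (1 = no smoothing).
#' @return one-row data.frame: lag_h, mu_max, amplitude, t_half, auc, grew.
#' @export
extract_params <- function(time_h, signal, blank = 0, min_amplitude = 0.05,
                           reg_window = 5, smooth_window = 1) {
  assert_that(length(time_h) >= 5, "need at least 5 time points")
  assert_that(length(time_h) == length(signal), "time/signal length mismatch")
  assert_that(!is.unsorted(time_h, strictly = TRUE),
              "time must be strictly increasing")
  s <- smooth_signal(signal, smooth_window) - blank
  A <- max(s)
  t_end <- time_h[length(time_h)]
  if (!is.finite(A) || A < min_amplitude) {
    return(data.frame(lag_h = t_end, mu_max = 0, amplitude = 0,
                      t_half = t_end, auc = 0, grew = FALSE))
  }
  n <- length(s)
  w <- min(reg_window, n)
  ls <- suppressWarnings(log(s))
  best <- 0
  for (i in seq_len(n - w + 1L)) {
    idx <- i:(i + w - 1L)
    y <- ls[idx]
    if (any(!is.finite(y))) next
    x <- time_h[idx]
    slope <- stats::cov(x, y) / stats::var(x)
    if (is.finite(slope) && slope > best) best <- slope
  }
  mu <- max(0, best)
  # first upward crossing of A/2, linearly interpolated
  half <- A / 2
  cross <- which(s >= half)[1]
  t_half <- if (cross == 1L) time_h[1] else {
    t0 <- time_h[cross - 1L]; t1 <- time_h[cross]
    s0 <- s[cross - 1L]; s1 <- s[cross]
    if (s1 > s0) t0 + (half - s0) / (s1 - s0) * (t1 - t0) else t1
  }
  lag <- if (mu > 0) max(0, t_half - 2 / mu) else t_half
  data.frame(lag_h = lag, mu_max = mu, amplitude = A, t_half = t_half,
             auc = trapz(time_h, pmax(s, 0)), grew = TRUE)
}

#' Aggregate replicate growth parameters
#'
#' Per-field median across replicates of the same (strain, condition, level);
#' `grew` by majority vote with ties counted as growth; dispersion as the
#' median absolute deviation.
#'
#' @param params data.frame of per-replicate rows (columns lag_h, mu_max,
#'   amplitude, t_half, auc, grew), all from one (strain, condition, level).
#' @return one-row data.frame of medians, `grew`, and `<field>_mad` columns.
#' @export
aggregate_replicates <- function(params) {
  assert_that(nrow(params) >= 1, "need at least one replicate")
  for (col in c("strain", "condition", "level")) {
    if (col %in% names(params) && length(unique(params[[col]])) > 1) {
      stopf("replicates mix different values of '%s'", col)
    }
  }
  fields <- c("lag_h", "mu_max", "amplitude", "t_half", "auc")
  med <- vapply(fields, function(f) stats::median(params[[f]]), numeric(1))
  mads <- vapply(fields, function(f) stats::mad(params[[f]], constant = 1),
                 numeric(1))
  out <- as.data.frame(as.list(med))
  out$grew <- mean(params$grew) >= 0.5
  for (f in fields) out[[paste0(f, "_mad")]] <- mads[[f]]
  out
}

#' Extract and aggregate growth parameters for a whole curve table
#'
#' Applies [extract_params()] per curve and [aggregate_replicates()] per
#' (strain, condition, level).
#'
#' @param curves long curve data.frame (see [read_curves()]).
#' @inheritParams extract_params
#' @return parameter table: one row per strain/condition/level with the five
#'   parameters, `grew`, and per-field MAD dispersions.
#' @export
extract_params_table <- function(curves, blank = 0, min_amplitude = 0.05,
                                 reg_window = 5, smooth_window = 1) {
  cl <- curve_list(curves)
  per_rep <- do.call(rbind, lapply(cl, function(cv) {
    p <- extract_params(cv$time_h, cv$signal, blank = blank,
                        min_amplitude = min_amplitude,
                        reg_window = reg_window,
                        smooth_window = smooth_window)
    cbind(data.frame(strain = cv$strain, condition = cv$condition,
                     level = cv$level, replicate = cv$replicate,
                     stringsAsFactors = FALSE), p)
  }))
  key <- paste(per_rep$strain, per_rep$condition, per_rep$level, sep = "\r")
  out <- do.call(rbind, lapply(split(per_rep, key), function(d) {
    cbind(d[1, c("strain", "condition", "level")],
          aggregate_replicates(d))
  }))
  rownames(out) <- NULL
  out[order(out$condition, out$level, out$strain), , drop = FALSE]
}

#' Write a growth-parameter table as TSV
#' @param params parameter table; @param path output path.
#' @export
write_params <- function(params, path) {
  utils::write.table(params, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
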