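# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @keywords internal
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stopf(fmt, ...)
  invisible(TRUE)
}

#' Min-max scale a vector to \[0, 1\]
#'
#' Degenerate ranges (all values equal) map to 0.5 so that downstream weighted
#' sums remain defined when a parameter carries no information at a level.
#' @keywords internal
minmax01 <- function(x) {
  r <- range(x, na.rm = TRUE)
  if (!is.finite(r[1]) || r[2] - r[1] <= 0) {
    return(rep(0.5, length(x)))
  }
  (x - r[1]) / (r[2] - r[1])
}

# Trapezoidal integral of y over x.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n]) / 2)
}

#' Normalize genomic intervals: sort and merge overlapping/adjacent ones
#'
#' Intervals are 0-based half-open `[start, end)` on named chromosomes.
#' @param intervals data.frame with columns `chrom`, `start`, `end`.
#' @return data.frame with non-overlapping intervals sorted by (chrom, start).
#' @export
normalize_intervals <- function(intervals) {
  assert_that(all(c("chrom", "start", "end") %in% names(intervals)),
              "intervals need columns chrom, start, end")
  assert_that(all(intervals$end > intervals$start),
              "intervals must satisfy start < end")
  out <- lapply(split(intervals, intervals$chrom), function(d) {
    d <- d[order(d$start, d$end), , drop = FALSE]
    starts <- d$start[1]
    ends <- d$end[1]
    if (nrow(d) > 1L) {
      for (i in 2:nrow(d)) {
        j <- length(ends)
        if (d$start[i] <= ends[j]) {
          ends[j] <- max(ends[j], d$end[i])
        } else {
          starts <- c(starts, d$start[i])
          ends <- c(ends, d$end[i])
        }
      }
    }
    data.frame(chrom = d$chrom[1], start = starts, end = ends,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

# Membership of 0-based points in a normalized interval set (same chromosome
# naming); returns logical vector.
points_in_intervals <- function(chrom, pos, intervals) {
  if (nrow(intervals) == 0L) return(rep(FALSE, length(pos)))
  hit <- rep(FALSE, length(pos))
  for (cc in unique(chrom)) {
    iv <- intervals[intervals$chrom == cc, , drop = FALSE]
    if (nrow(iv) == 0L) next
    sel <- which(chrom == cc)
    for (k in seq_len(nrow(iv))) {
      hit[sel] <- hit[sel] | (pos[sel] >= iv$start[k] & pos[sel] < iv$end[k])
    }
  }
  hit
}

# Average ranks for descending scores with NAs forced to the bottom
# (NAs share the average of the trailing positions).
rank_desc_na_last <- function(score) {
  n <- length(score)
  r <- rep(NA_real_, n)
  ok <- !is.na(score)
  r[ok] <- rank(-score[ok], ties.method = "average")
  if (any(!ok)) {
    tail_ranks <- seq(sum(ok) + 1L, n)
    r[!ok] <- mean(tail_ranks)
  }
  r
}
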