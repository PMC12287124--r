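#' Half-open interval algebra
#'
#' Activity spans and step windows are half-open intervals `[start, end)` on
#' the case clock (seconds). Working with half-open spans makes union and
#' total-duration arithmetic exact: abutting intervals share no time, so
#' durations add without double counting.
#'
#' An interval set is a two-column numeric matrix (`start`, `end`).
#' `iv_normalize()` sorts and merges overlapping or abutting intervals, after
#' which the set is disjoint and ordered; the other operations require
#' normalized input.
#'
#' @param start,end numeric vectors of interval endpoints, `start < end`.
#' @param a,b normalized interval sets (matrices from [iv_normalize()]).
#' @param times numeric vector of timestamps.
#' @return `iv_normalize()`, `iv_intersect()`: a normalized interval matrix.
#'   `iv_length()`: total covered duration in seconds. `iv_locate()`: for each
#'   time, the 1-based index of the covering interval, or `NA` if uncovered.
#' @examples
#' iv <- iv_normalize(c(0, 5, 20), c(6, 10, 30))
#' iv_length(iv)                       # 20
#' iv_length(iv_intersect(iv, iv_normalize(8, 25)))  # 7
#' @name intervals
NULL

#' @rdname intervals
#' @export
iv_normalize <- function(start, end) {
  if (length(start) != length(end))
    abort_usage("interval start/end lengths differ (%d vs %d)",
                length(start), length(end))
  keep <- !(is.na(start) | is.na(end))
  start <- start[keep]; end <- end[keep]
  if (any(start >= end))
    abort_validation("interval with start >= end (first offender: [%g, %g))",
                     start[which(start >= end)[1]], end[which(start >= end)[1]])
  if (length(start) == 0L) return(iv_empty())
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- numeric(0); out_e <- numeric(0)
  if (length(start) > 1L) {
    for (i in 2:length(start)) {
      if (start[i] <= me) {
        me <- max(me, end[i])
      } else {
        out_s <- c(out_s, ms); out_e <- c(out_e, me)
        ms <- start[i]; me <- end[i]
      }
    }
  }
  out_s <- c(out_s, ms); out_e <- c(out_e, me)
  cbind(start = out_s, end = out_e)
}

iv_empty <- function() {
  cbind(start = numeric(0), end = numeric(0))
}

#' @rdname intervals
#' @export
iv_length <- function(a) {
  if (nrow(a) == 0L) return(0)
  sum(a[, "end"] - a[, "start"])
}

#' @rdname intervals
#' @export
iv_intersect <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(iv_empty())
  out_s <- numeric(0); out_e <- numeric(0)
  j <- 1L
  for (i in seq_len(nrow(a))) {
    while (j <= nrow(b) && b[j, "end"] <= a[i, "start"]) j <- j + 1L
    k <- j
    while (k <= nrow(b) && b[k, "start"] < a[i, "end"]) {
      s <- max(a[i, "start"], b[k, "start"])
      e <- min(a[i, "end"], b[k, "end"])
      if (s < e) { out_s <- c(out_s, s); out_e <- c(out_e, e) }
      k <- k + 1L
    }
  }
  cbind(start = out_s, end = out_e)
}

#' @rdname intervals
#' @export
iv_locate <- function(times, a) {
  if (nrow(a) == 0L || length(times) == 0L)
    return(rep(NA_integer_, length(times)))
  # half-open membership: start <= t < end
  idx <- findInterval(times, a[, "start"])
  inside <- idx >= 1L & times < a[cbind(pmax(idx, 1L), 2L)]
  ifelse(inside, idx, NA_integer_)
}
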