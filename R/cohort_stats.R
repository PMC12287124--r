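#' Normality gate for the two-group comparison
#'
#' The comparison procedure is normality-gated: a metric is compared
#' parametrically only when a Shapiro-Wilk test fails to reject normality
#' (p >= `alpha`) in *both* groups; otherwise the nonparametric path is
#' taken. Shapiro-Wilk is the conventional choice at the small per-step case
#' counts involved here. A zero-variance (constant) group is treated as
#' non-normal. The gate is deterministic for fixed input.
#'
#' @param values_a,values_b per-case metric values (NAs dropped).
#' @param alpha gate level.
#' @return `TRUE` (parametric) or `FALSE`; `NA` when either group has fewer
#'   than 3 non-missing values, in which case the comparison is skipped.
#' @export
normality_gate <- function(values_a, values_b, alpha = 0.05) {
  a <- values_a[!is.na(values_a)]
  b <- values_b[!is.na(values_b)]
  if (length(a) < 3L || length(b) < 3L) return(NA)
  ok <- vapply(list(a, b), function(x) {
    if (sd(x) == 0) return(FALSE)
    p <- tryCatch(shapiro.test(x)$p.value, error = function(e) 0)
    p >= alpha
  }, logical(1))
  all(ok)
}

#' Summarize one group of per-case values
#'
#' Both summary conventions are computed: marginal mean with a t-based 95%
#' confidence interval (reported when the comparison is parametric) and
#' median with interquartile range (reported otherwise).
#'
#' @param x per-case values (NAs dropped).
#' @param label group label.
#' @return a one-row data.frame: `label`, `n`, `mean`, `ci_low`, `ci_high`,
#'   `median`, `q1`, `q3`.
#' @export
group_summary <- function(x, label = "group") {
  x <- x[!is.na(x)]
  n <- length(x)
  m <- if (n > 0) mean(x) else NA_real_
  half <- if (n > 1 && sd(x) > 0) qt(0.975, n - 1) * sd(x) / sqrt(n) else 0
  q <- if (n > 0) unname(quantile(x, c(0.25, 0.5, 0.75))) else rep(NA_real_, 3)
  data.frame(label = label, n = n, mean = m,
             ci_low = m - half, ci_high = m + half,
             median = q[2], q1 = q[1], q3 = q[3],
             stringsAsFactors = FALSE)
}

#' Compare two groups of per-case metric values
#'
#' Applies the normality-gated procedure: a two-sided independent Student
#' t-test (equal variances; set `welch = TRUE` for the Welch variant) when
#' [normality_gate()] passes, otherwise a two-sided Mann-Whitney U test —
#' exact when both groups have at most 8 cases and the data are tie-free,
#' else the normal approximation with continuity and tie correction.
#' p < 0.05 is flagged significant. When every value in both groups is
#' identical the comparison is degenerate and p = 1 by convention.
#'
#' @param values_a,values_b per-case values.
#' @param labels length-2 character: group labels.
#' @param test `"auto"` (gate decides), or force `"t_test"`/`"mann_whitney"`.
#' @param welch use Welch's t-test instead of Student's.
#' @param alpha significance level.
#' @return a one-row `comparison_row` data.frame with group summaries
#'   (suffixes `_a`, `_b`), `test_used`, `p_value`, `significant`, or `NULL`
#'   (with a warning) when a group has fewer than 3 values.
#' @export
compare_groups <- function(values_a, values_b, labels = c("A", "B"),
                           test = c("auto", "t_test", "mann_whitney"),
                           welch = FALSE, alpha = 0.05) {
  test <- match.arg(test)
  a <- values_a[!is.na(values_a)]
  b <- values_b[!is.na(values_b)]
  if (length(a) < 3L || length(b) < 3L) {
    warn_opikin("comparison skipped: a group has < 3 non-missing values (%d vs %d)",
                length(a), length(b))
    return(NULL)
  }
  parametric <- switch(test,
                       auto = isTRUE(normality_gate(a, b)),
                       t_test = TRUE,
                       mann_whitney = FALSE)
  degenerate <- sd(c(a, b)) == 0
  if (degenerate) {
    warn_opikin("all values identical in both groups; p = 1 by convention")
    p <- 1
    used <- if (parametric) "t_test" else "mann_whitney"
  } else if (parametric) {
    p <- t.test(a, b, var.equal = !welch)$p.value
    used <- "t_test"
  } else {
    exact <- length(a) <= 8L && length(b) <= 8L && !anyDuplicated(c(a, b))
    p <- suppressWarnings(
      wilcox.test(a, b, exact = exact, correct = TRUE)$p.value)
    used <- "mann_whitney"
  }
  sa <- group_summary(a, labels[1])
  sb <- group_summary(b, labels[2])
  names(sa) <- paste0(names(sa), "_a")
  names(sb) <- paste0(names(sb), "_b")
  out <- cbind(sa, sb,
               data.frame(test_used = used, p_value = p,
                          significant = p < alpha,
                          degenerate = degenerate,
                          stringsAsFactors = FALSE))
  class(out) <- c("comparison_row", "data.frame")
  out
}

#' Build the step-by-metric cohort comparison table
#'
#' Reproduces the shape of the reported comparison tables: one row per
#' (step, metric) with both cohorts summarized and compared via
#' [compare_groups()]. The unit of analysis is the *case*: for each case and
#' step, the per-case value of a metric is the (usually single) value of the
#' operators whose role falls in the group; when several same-group operators
#' share a step in one case their values are averaged. Rows are ordered by
#' ontology step index, then metric. No multiple-testing correction is
#' applied by default — the source analysis reports raw p-values across the
#' step-by-metric grid — but `p_adjust = "BH"` enables a Benjamini-Hochberg
#' mode.
#'
#' @param opis a `step_opi` table pooled over cases
#'   (e.g. `do.call(rbind, lapply(cases, case_opis))`).
#' @param group_a,group_b character vectors of roles forming the two-set
#'   partition, e.g. `"attending"` vs `c("resident", "fellow")`.
#' @param metrics metric columns to compare (default [opi_metrics()]).
#' @param labels group labels for the output.
#' @param p_adjust `"none"` (default) or any [stats::p.adjust()] method.
#' @param ... passed to [compare_groups()].
#' @return a `comparison_table` data.frame: `step`, `metric`, the summary
#'   columns of [compare_groups()], `test_used`, `p_value`, `significant`.
#' @export
build_comparison_table <- function(opis, group_a, group_b,
                                   metrics = opi_metrics(),
                                   labels = NULL, p_adjust = "none", ...) {
  if (length(group_a) == 0L || length(group_b) == 0L)
    abort_usage("both sides of the role partition must be non-empty")
  if (length(intersect(group_a, group_b)))
    abort_usage("role groups overlap: %s",
                paste(intersect(group_a, group_b), collapse = ", "))
  labels <- labels %||% c(paste(group_a, collapse = "+"),
                          paste(group_b, collapse = "+"))
  have <- intersect(metrics, names(opis))
  if (length(have) < length(metrics))
    warn_opikin("metric(s) absent from OPI table: %s",
                paste(setdiff(metrics, have), collapse = ", "))
  rows <- list()
  steps <- ryg_steps()
  for (s in steps[steps %in% unique(opis$step)]) {
    sub <- opis[opis$step == s, , drop = FALSE]
    for (m in have) {
      va <- per_case_values(sub, group_a, m)
      vb <- per_case_values(sub, group_b, m)
      if (length(va) == 0L || length(vb) == 0L) next
      cmp <- withCallingHandlers(
        compare_groups(va, vb, labels = labels, ...),
        opikin_warning = function(w) invokeRestart("muffleWarning"))
      if (is.null(cmp)) next
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(step = s, metric = m, stringsAsFactors = FALSE), cmp)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(step = character(), metric = character())
  if (nrow(out) && p_adjust != "none") {
    out$p_value <- p.adjust(out$p_value, method = p_adjust)
    out$significant <- out$p_value < 0.05
  }
  rownames(out) <- NULL
  class(out) <- c("comparison_table", "data.frame")
  out
}

# one value per case: average over same-group operators within the case
per_case_values <- function(opis, roles, metric) {
  sel <- opis$role %in% roles & !is.na(opis[[metric]])
  if (!any(sel)) return(numeric(0))
  tapply(opis[[metric]][sel], opis$case_id[sel], mean)
}
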