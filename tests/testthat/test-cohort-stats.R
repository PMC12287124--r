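test_that("normality gate passes Gaussian and rejects heavy-tailed samples", {
  set.seed(105)
  a <- rnorm(20); b <- rnorm(20)
  expect_true(normality_gate(a, b))
  set.seed(102)
  la <- rlnorm(20, sdlog = 1.5); lb <- rlnorm(20, sdlog = 1.5)
  expect_false(normality_gate(la, lb))
  expect_false(normality_gate(rep(3, 10), rnorm(10)))  # constant group
  expect_true(is.na(normality_gate(c(1, 2), rnorm(10))))  # too few
})

test_that("identical groups give p = 1 and no significance", {
  x <- c(1, 2, 3, 4, 5)
  cmp <- suppressWarnings(compare_groups(x, x))
  expect_equal(cmp$p_value, 1)
  expect_false(cmp$significant)
  # all-constant input is degenerate by convention
  cmp2 <- suppressWarnings(compare_groups(rep(2, 5), rep(2, 6)))
  expect_equal(cmp2$p_value, 1)
  expect_true(cmp2$degenerate)
})

test_that("exact Mann-Whitney matches full enumeration at 5 vs 5", {
  a <- 1:5; b <- 6:10
  # oracle: enumerate all C(10,5) = 252 rank assignments of the pooled
  # sample, compute U for each, two-sided p = P(U <= min(U_obs, U'_obs)) * 2
  pooled <- c(a, b)
  combs <- combn(10, 5)
  u_of <- function(idx) sum(rank(pooled)[idx]) - 5 * 6 / 2
  us <- apply(combs, 2, u_of)
  u_obs <- u_of(1:5)
  p_oracle <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  expect_equal(p_oracle, 2 / 252)  # complete separation

  cmp <- compare_groups(a, b, test = "mann_whitney")
  expect_equal(cmp$p_value, p_oracle, tolerance = 1e-12)
  expect_equal(round(cmp$p_value, 4), 0.0079)
  expect_equal(cmp$test_used, "mann_whitney")
})

test_that("summaries satisfy their ordering invariants", {
  set.seed(5)
  x <- rlnorm(40)
  s <- group_summary(x, "g")
  expect_lte(s$ci_low, s$mean); expect_gte(s$ci_high, s$mean)
  expect_lte(s$q1, s$median); expect_gte(s$q3, s$median)
  expect_equal(s$n, 40)
})

test_that("label swap keeps the p-value and swaps the summaries", {
  set.seed(7)
  a <- rnorm(12, 1); b <- rnorm(15, 2)
  ab <- compare_groups(a, b, labels = c("A", "B"))
  ba <- compare_groups(b, a, labels = c("B", "A"))
  expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)
  expect_equal(ab$mean_a, ba$mean_b)
  expect_equal(ab$median_b, ba$median_a)
})

test_that("nonparametric rejection rate is monotone in the location shift", {
  set.seed(11)
  shifts <- c(0.3, 0.8, 1.4)
  rej <- vapply(shifts, function(d) {
    mean(vapply(1:200, function(i) {
      a <- rnorm(15); b <- rnorm(15) + d
      compare_groups(a, b, test = "mann_whitney")$p_value < 0.05
    }, logical(1)))
  }, numeric(1))
  expect_true(all(diff(rej) >= 0))
  expect_gt(rej[3], 0.9)
})

test_that("comparison tables have the step-by-metric structure", {
  cfg <- make_small_config(seed = 13, n_cases = 6)
  sim <- suppressWarnings(simulate_cohorts(cfg))
  opis <- do.call(rbind, lapply(sim$cases, case_opis))
  class(opis) <- c("step_opi", "data.frame")

  tab <- build_comparison_table(opis, "attending", c("resident", "fellow"))
  expect_s3_class(tab, "comparison_table")
  expect_equal(unique(tab$step),
               c("dissection", "creation_of_gastric_pouch"))
  expect_true(all(tab$metric %in% opi_metrics()))
  # rows ordered by ontology index then metric
  idx <- match(tab$step, ryg_steps())
  expect_false(is.unsorted(idx))
  expect_true(all(tab$n_a == 6 & tab$n_b == 6))
  expect_equal(tab$significant, tab$p_value < 0.05)

  # attending vs resident alone is a valid sub-partition
  tab2 <- build_comparison_table(opis, "attending", "resident")
  expect_equal(nrow(tab2), nrow(tab))

  expect_error(build_comparison_table(opis, character(0), "resident"),
               class = "opikin_usage_error")
  expect_error(build_comparison_table(opis, "attending",
                                      c("attending", "resident")),
               class = "opikin_usage_error")

  # absent metric -> warning, no rows for it
  expect_warning(
    tab3 <- build_comparison_table(opis, "attending", "resident",
                                   metrics = c("bimanual_dexterity",
                                               "no_such_metric")),
    "absent")
  expect_equal(unique(tab3$metric), "bimanual_dexterity")
})

test_that("BH adjustment only relabels significance, never reorders rows", {
  cfg <- make_small_config(seed = 17, n_cases = 5)
  sim <- suppressWarnings(simulate_cohorts(cfg))
  opis <- do.call(rbind, lapply(sim$cases, case_opis))
  class(opis) <- c("step_opi", "data.frame")
  raw <- build_comparison_table(opis, "attending", "resident")
  adj <- build_comparison_table(opis, "attending", "resident",
                                p_adjust = "BH")
  expect_equal(adj[, c("step", "metric")], raw[, c("step", "metric")])
  expect_true(all(adj$p_value >= raw$p_value - 1e-12))
})
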