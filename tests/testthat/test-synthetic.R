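test_that("generation is deterministic under a fixed master seed", {
  cfg <- make_small_config(seed = 31)
  a <- suppressWarnings(simulate_case(cfg, "attending", 2))
  b <- suppressWarnings(simulate_case(cfg, "attending", 2))
  expect_identical(a$kinematics, b$kinematics)
  expect_identical(a$activity, b$activity)
  expect_identical(attr(a, "ground_truth"), attr(b, "ground_truth"))
  # different seed -> different data, same schema
  cfg2 <- make_small_config(seed = 32)
  c2 <- suppressWarnings(simulate_case(cfg2, "attending", 2))
  expect_false(identical(a$kinematics$x_cm, c2$kinematics$x_cm))
  expect_identical(names(a$kinematics), names(c2$kinematics))
})

test_that("adding cases never perturbs existing ones", {
  cfg <- make_small_config(seed = 31, n_cases = 2)
  cfg5 <- make_small_config(seed = 31, n_cases = 5)
  a <- suppressWarnings(simulate_case(cfg, "trainee", 1))
  b <- suppressWarnings(simulate_case(cfg5, "trainee", 1))
  expect_identical(a$kinematics, b$kinematics)
})

test_that("realized active speed hits the programmed target", {
  pr <- step_profile(speed_dom_cm_s = 4, duty_cycle_dom = 1,
                     duty_cycle_nondom = 1)
  for (seed in 1:20) {
    set.seed(seed)
    tr <- simulate_trajectory(pr, "dominant", 60, cbind(start = 0, end = 60),
                              sample_rate_hz = 50)
    pl <- path_length(data.frame(time_s = tr$time_s, x_cm = tr$tip[, 1],
                                 y_cm = tr$tip[, 2], z_cm = tr$tip[, 3]))
    v <- pl / 60
    expect_gt(v, 3.8); expect_lt(v, 4.2)
  }
})

test_that("idle hands are frozen: no activity means no path", {
  pr <- step_profile()
  set.seed(3)
  tr <- simulate_trajectory(pr, "dominant", 30, iv_normalize(0, 0.01),
                            sample_rate_hz = 20)
  d <- diff(tr$tip[tr$time_s >= 0.1, , drop = FALSE])
  expect_equal(max(abs(d)), 0)
})

test_that("wrist streams are tip streams contracted by the motion scale", {
  pr <- step_profile(motion_scale = 2.5)
  set.seed(4)
  tr <- simulate_trajectory(pr, "nondominant", 20, cbind(0, 20), 25)
  as_df <- function(m, t) data.frame(time_s = t, x_cm = m[, 1],
                                     y_cm = m[, 2], z_cm = m[, 3])
  expect_equal(path_length(as_df(tr$tip, tr$time_s)) /
                 path_length(as_df(tr$wrist, tr$time_s)), 2.5,
               tolerance = 1e-9)
})

test_that("a one-step config yields a bundle with exactly that step", {
  cfg <- make_small_config(seed = 41, steps = "measurement")
  case <- suppressWarnings(simulate_case(cfg, "attending", 1))
  win <- build_step_windows(case)
  expect_equal(unique(win$step), "measurement")
  expect_equal(unique(map_subtask(case$segments$raw_label)), "measurement")
})

test_that("the study preset has the roster shape of the source cohort", {
  cfg <- preset_study_effects(n_cases_per_cohort = 8, seed = 1)
  ops <- do.call(rbind, lapply(cfg$cohorts, function(co) co$operators))
  expect_equal(sum(ops$role == "attending"), 2)
  expect_equal(sum(ops$role %in% c("resident", "fellow")), 6)
  expect_equal(sum(ops$role == "fellow"), 2)
  # cohort sizes and operator cycling
  sim <- suppressWarnings(simulate_cohorts(
    preset_null(n_per_cohort = 3, seed = 2)))
  expect_equal(length(sim$cases), 6)
  roles <- vapply(sim$cases, function(cs) cs$roster$role, "")
  expect_equal(sort(unique(roles)), c("attending", "resident"))
})

test_that("preset profiles encode the six programmed effect directions", {
  cfg <- preset_study_effects()
  att <- cfg$cohorts[[1]]$profiles; trn <- cfg$cohorts[[2]]$profiles
  expect_gt(att$dissection$dominance_scale, trn$dissection$dominance_scale)
  expect_gt(att$dissection$speed_nondom_cm_s,
            trn$dissection$speed_nondom_cm_s)
  expect_lt(att$creation_of_gastric_pouch$speed_nondom_cm_s,
            trn$creation_of_gastric_pouch$speed_nondom_cm_s)
  expect_gt(att$creation_of_gastric_pouch$duty_cycle_dom,
            trn$creation_of_gastric_pouch$duty_cycle_dom)
  expect_gt(att$hand_sewn_anastomosis$duty_cycle_dom,
            trn$hand_sewn_anastomosis$duty_cycle_dom)
  expect_lt(att$hand_sewn_anastomosis$workspace_sigma_cm,
            trn$hand_sewn_anastomosis$workspace_sigma_cm)
  # null steps identical between cohorts
  for (s in setdiff(ryg_steps(), unique(preset_effect_directions()$step)))
    expect_identical(att[[s]], trn[[s]])
})

test_that("cohort simulation writes bundles plus a ground-truth manifest", {
  cfg <- make_small_config(seed = 51, n_cases = 2)
  dir <- tempfile("cohorts")
  sim <- suppressWarnings(simulate_cohorts(cfg, path = dir))
  expect_true(file.exists(file.path(dir, "manifest.yaml")))
  expect_equal(length(list.dirs(dir, recursive = FALSE)), 4)
  back <- read_case_bundle(file.path(dir, "attending_case001"))
  expect_equal(back$kinematics, sim$cases[["attending_case001"]]$kinematics)
  # refuses to clobber without overwrite
  expect_error(suppressWarnings(simulate_cohorts(cfg, path = dir)),
               class = "opikin_usage_error")
  unlink(dir, recursive = TRUE)
})

test_that("pipeline estimates converge to programmed parameters", {
  short <- recover_parameters(duration_s = 60, n_reps = 60, seed = 1,
                              sample_rate_hz = 25)
  long <- recover_parameters(duration_s = 600, n_reps = 60, seed = 1,
                             sample_rate_hz = 25)
  # longer steps estimate better (averaged across parameters)
  expect_lt(mean(long$rel_error_pct), mean(short$rel_error_pct))
  # at 600 s: speeds and scaling within 5%, duty cycle within 3 points
  spd <- long[long$parameter %in% c("speed_dom_cm_s", "speed_nondom_cm_s",
                                    "sensitivity_ratio_dom",
                                    "sensitivity_ratio_nondom",
                                    "bimanual_dexterity"), ]
  expect_true(all(spd$rel_error_pct < 5))
  duty <- long[grepl("pct_active", long$parameter), ]
  expect_true(all(duty$abs_error < 3))
})

test_that("programmed dexterity dominance shows up in computed OPIs", {
  hits <- 0
  for (seed in 1:12) {
    cfg <- generator_config(
      cohorts = list(cohort_spec(
        "solo",
        list(dissection = step_profile(median_duration_s = 40,
                                       dominance_scale = 1.5)),
        n_cases = 1)),
      sample_rate_hz = 20, seed = seed)
    cs <- suppressWarnings(simulate_case(cfg, "solo", 1))
    opis <- case_opis(cs)
    hits <- hits + (opis$bimanual_dexterity > 1)
  }
  expect_gte(hits, 11)
})
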