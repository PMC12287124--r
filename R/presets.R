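#' Study-effects preset
#'
#' A two-cohort generator configuration (attending vs trainee) encoding the
#' six step-by-metric effect *directions* observed in the study population —
#' signs, not magnitudes, with moderate scaled-down effect sizes and step
#' durations suitable for repeated desk-scale replication:
#'
#' * dissection: higher attending bimanual dexterity (dominant-hand travel
#'   multiplier 1.4 vs 0.65) and faster attending non-dominant speed
#'   (3.7 vs 3.0 cm/s);
#' * gastric pouch creation: slower attending non-dominant speed
#'   (3.9 vs 4.8 cm/s) and higher attending active console time
#'   (duty cycles 0.78/0.66 vs 0.52/0.47);
#' * hand-sewn anastomosis: higher attending active console time
#'   (0.72/0.62 vs 0.40/0.35) and lower attending workspace rate
#'   (spread 1.5 vs 2.4 cm, compounded by the longer attending active time).
#'
#' The remaining five steps (measurement, mesenteric division, stapled
#' anastomosis, enterotomy closure, defect closure) have identical profiles
#' in both cohorts and act as built-in negative controls. Trainee cases
#' alternate between resident and fellow operators so role-partition
#' groupings such as attending vs resident remain possible.
#'
#' @param n_cases_per_cohort cases per cohort.
#' @param sample_rate_hz kinematic sampling rate; the preset default (20 Hz)
#'   keeps repeated replication cheap while leaving dozens of samples per
#'   active bout.
#' @param seed master seed.
#' @return a [generator_config()].
#' @export
preset_study_effects <- function(n_cases_per_cohort = 20,
                                 sample_rate_hz = 20, seed = 1) {
  base <- list(
    dissection = step_profile(median_duration_s = 90),
    creation_of_gastric_pouch = step_profile(median_duration_s = 50),
    measurement = step_profile(median_duration_s = 25,
                               speed_nondom_cm_s = 4.5),
    division_of_mesentery = step_profile(median_duration_s = 20),
    staple_anastomosis = step_profile(median_duration_s = 35),
    enterotomy_closure = step_profile(median_duration_s = 45),
    defect_closure = step_profile(median_duration_s = 45),
    hand_sewn_anastomosis = step_profile(median_duration_s = 60))

  att <- base; trn <- base
  set <- function(p, ...) { p[names(list(...))] <- list(...); p }
  att$dissection <- set(att$dissection, dominance_scale = 1.4,
                        speed_nondom_cm_s = 3.7)
  trn$dissection <- set(trn$dissection, dominance_scale = 0.65,
                        speed_nondom_cm_s = 3.0)
  att$creation_of_gastric_pouch <- set(att$creation_of_gastric_pouch,
                                       speed_nondom_cm_s = 3.9,
                                       duty_cycle_dom = 0.78,
                                       duty_cycle_nondom = 0.66)
  trn$creation_of_gastric_pouch <- set(trn$creation_of_gastric_pouch,
                                       speed_nondom_cm_s = 4.8,
                                       duty_cycle_dom = 0.52,
                                       duty_cycle_nondom = 0.47)
  att$hand_sewn_anastomosis <- set(att$hand_sewn_anastomosis,
                                   duty_cycle_dom = 0.72,
                                   duty_cycle_nondom = 0.62,
                                   workspace_sigma_cm = 1.5)
  trn$hand_sewn_anastomosis <- set(trn$hand_sewn_anastomosis,
                                   duty_cycle_dom = 0.40,
                                   duty_cycle_nondom = 0.35,
                                   workspace_sigma_cm = 2.4)

  attending_ops <- data.frame(
    operator_id = c("att_op1", "att_op2"), role = "attending",
    prior_robotic_cases = c(500, 1300), stringsAsFactors = FALSE)
  trainee_ops <- data.frame(
    operator_id = sprintf("trn_op%d", 1:6),
    role = c("resident", "fellow", "resident", "resident", "fellow",
             "resident"),
    prior_robotic_cases = c(3, 125, 10, 17, 60, 25),
    stringsAsFactors = FALSE)

  generator_config(
    cohorts = list(
      cohort_spec("attending", att, n_cases_per_cohort, attending_ops),
      cohort_spec("trainee", trn, n_cases_per_cohort, trainee_ops)),
    sample_rate_hz = sample_rate_hz, seed = seed)
}

#' Programmed effect directions of the study preset
#'
#' @return data.frame `step`, `metric`, `sign`: the sign of
#'   (attending - trainee) for each of the six programmed cells of
#'   [preset_study_effects()].
#' @export
preset_effect_directions <- function() {
  data.frame(
    step = c("dissection", "dissection", "creation_of_gastric_pouch",
             "creation_of_gastric_pouch", "hand_sewn_anastomosis",
             "hand_sewn_anastomosis"),
    metric = c("bimanual_dexterity", "speed_nondom_cm_s", "speed_nondom_cm_s",
               "pct_active_console", "pct_active_console",
               "workspace_rate_cm3_s"),
    sign = c(1, 1, -1, 1, 1, -1),
    stringsAsFactors = FALSE)
}

#' Null-calibration preset
#'
#' Two cohorts with *identical* profiles, used to check that the comparison
#' procedure's false-positive rate sits at its nominal level. A single step
#' with a short duration keeps one replicate cheap enough to run by the
#' thousand.
#'
#' @param n_per_cohort cases per cohort.
#' @param steps canonical step(s) to simulate.
#' @param median_duration_s step duration median.
#' @param sample_rate_hz sampling rate.
#' @param seed master seed.
#' @return a [generator_config()].
#' @export
preset_null <- function(n_per_cohort = 15, steps = "dissection",
                        median_duration_s = 18, sample_rate_hz = 15,
                        seed = 1) {
  profiles <- setNames(
    lapply(steps, function(s) step_profile(median_duration_s =
                                             median_duration_s)),
    steps)
  ops_a <- data.frame(operator_id = c("a_op1", "a_op2"), role = "attending",
                      prior_robotic_cases = c(500, 1300),
                      stringsAsFactors = FALSE)
  ops_b <- data.frame(operator_id = sprintf("b_op%d", 1:3), role = "resident",
                      prior_robotic_cases = c(5, 20, 60),
                      stringsAsFactors = FALSE)
  generator_config(
    cohorts = list(cohort_spec("groupA", profiles, n_per_cohort, ops_a),
                   cohort_spec("groupB", profiles, n_per_cohort, ops_b)),
    sample_rate_hz = sample_rate_hz, seed = seed)
}
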