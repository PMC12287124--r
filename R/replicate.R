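#' Run the full pipeline on one simulated dataset
#'
#' Simulates every case of a configuration, computes the per-step OPI table
#' for each, pools them, and builds the two-group comparison table.
#'
#' @param config a [generator_config()].
#' @param group_a,group_b role partitions for [build_comparison_table()].
#' @param metrics metric columns to compare.
#' @param lexicon step lexicon.
#' @return list: `opis` (pooled `step_opi`), `table` (`comparison_table`),
#'   `truth` (generator ground truth).
#' @export
run_cohort_comparison <- function(config, group_a = "attending",
                                  group_b = c("resident", "fellow"),
                                  metrics = opi_metrics(),
                                  lexicon = default_ontology()) {
  sim <- suppressWarnings(simulate_cohorts(config))
  opis <- do.call(rbind, lapply(sim$cases, case_opis, lexicon = lexicon))
  rownames(opis) <- NULL
  class(opis) <- c("step_opi", "data.frame")
  tab <- build_comparison_table(opis, group_a, group_b, metrics = metrics)
  # signed direction: attending-side minus trainee-side location
  tab$direction <- sign(ifelse(tab$test_used == "t_test",
                               tab$mean_a - tab$mean_b,
                               tab$median_a - tab$median_b))
  list(opis = opis, table = tab, truth = sim$truth)
}

#' Null calibration of the comparison procedure
#'
#' Repeatedly simulates a null configuration (identical cohort profiles),
#' runs the whole pipeline, and tallies the per-metric rejection rate at
#' `alpha`. Under a faithful procedure the rate should sit inside the
#' binomial sampling envelope around `alpha`.
#'
#' @param config a null [generator_config()], e.g. [preset_null()].
#' @param reps number of replicates.
#' @param alpha nominal level.
#' @param seed base seed; replicate r uses a substream seed derived from it.
#' @return list: `per_metric` (named rejection-rate vector), `overall`
#'   (pooled rate), `reps`, `n_tests`.
#' @export
calibrate_null <- function(config, reps = 1000, alpha = 0.05, seed = 1) {
  hits <- list(); tot <- list()
  for (r in seq_len(reps)) {
    config$seed <- derive_seed(seed, "null-rep", r)
    tab <- run_cohort_comparison(config)$table
    for (i in seq_len(nrow(tab))) {
      m <- tab$metric[i]
      hits[[m]] <- (hits[[m]] %||% 0) + (tab$p_value[i] < alpha)
      tot[[m]] <- (tot[[m]] %||% 0) + 1
    }
  }
  per_metric <- unlist(hits) / unlist(tot)[names(hits)]
  list(per_metric = per_metric,
       overall = sum(unlist(hits)) / sum(unlist(tot)),
       reps = reps, n_tests = sum(unlist(tot)))
}

#' Direction recovery on the study-effects preset
#'
#' Repeatedly simulates the [preset_study_effects()] configuration and, per
#' replicate, asks (a) whether each of the six programmed step-by-metric
#' effects is flagged significant with the programmed sign, (b) how often
#' cells in the five null steps are flagged (false positives), and (c)
#' whether the two workspace normalizations reach the same significance
#' decision for the hand-sewn-anastomosis workspace effect.
#'
#' @param reps replicates.
#' @param n_cases_per_cohort cases per cohort per replicate.
#' @param seed base seed.
#' @param sample_rate_hz passed to the preset.
#' @return list: `effects` (data.frame step, metric, sign,
#'   `prop_detected` — significant with correct sign), `null_fp` (data.frame
#'   step, metric, `prop_flagged` over null-step cells), `concordance`
#'   (proportion of replicates where the two workspace normalizations agree
#'   on the hand-sewn effect), `reps`.
#' @export
recover_directions <- function(reps = 100, n_cases_per_cohort = 20, seed = 1,
                               sample_rate_hz = 20) {
  dirs <- preset_effect_directions()
  null_steps <- setdiff(ryg_steps(), unique(dirs$step))
  det <- matrix(0, nrow(dirs), 1)
  fp <- list(); fp_tot <- list()
  concord <- 0; concord_tot <- 0
  for (r in seq_len(reps)) {
    cfg <- preset_study_effects(n_cases_per_cohort,
                                sample_rate_hz = sample_rate_hz,
                                seed = derive_seed(seed, "dir-rep", r))
    tab <- run_cohort_comparison(cfg)$table
    key <- paste(tab$step, tab$metric)
    for (i in seq_len(nrow(dirs))) {
      row <- match(paste(dirs$step[i], dirs$metric[i]), key)
      if (!is.na(row) && tab$significant[row] &&
          tab$direction[row] == dirs$sign[i])
        det[i] <- det[i] + 1
    }
    for (row in which(tab$step %in% null_steps)) {
      k <- key[row]
      fp[[k]] <- (fp[[k]] %||% 0) + tab$significant[row]
      fp_tot[[k]] <- (fp_tot[[k]] %||% 0) + 1
    }
    hs <- tab[tab$step == "hand_sewn_anastomosis" &
                tab$metric %in% c("workspace_rate_cm3_s",
                                  "workspace_per_pathlength_cm2"), ]
    if (nrow(hs) == 2L) {
      concord <- concord + (hs$significant[1] == hs$significant[2])
      concord_tot <- concord_tot + 1
    }
  }
  keys <- names(fp)
  parts <- do.call(rbind, strsplit(keys, " "))
  list(effects = cbind(dirs, prop_detected = det[, 1] / reps),
       null_fp = data.frame(step = parts[, 1], metric = parts[, 2],
                            prop_flagged = unlist(fp)[keys] /
                              unlist(fp_tot)[keys],
                            row.names = NULL, stringsAsFactors = FALSE),
       concordance = concord / max(concord_tot, 1),
       reps = reps)
}

#' Generator-parameter recovery through the OPI pipeline
#'
#' Simulates single-operator cases with a long step of known (unjittered)
#' profile and measures how well the pipeline's OPI estimates recover the
#' programmed generator parameters: per-hand speed, duty cycle (-> percent
#' active time), dominance scale (-> bimanual dexterity) and motion scale
#' (-> sensitivity ratio). Estimates are pooled over replicate cases as
#' ratios of totals (total path length over total active time, and so on):
#' pooling damps the bout-sampling noise of the duty-cycle realization and,
#' unlike a mean of per-case ratios, carries no Jensen bias from the random
#' denominator.
#'
#' @param duration_s simulated step duration.
#' @param n_reps replicate cases pooled.
#' @param sample_rate_hz sampling rate.
#' @param seed master seed.
#' @param profile the [step_profile()] to recover.
#' @return data.frame: `parameter`, `programmed`, `estimated`, `abs_error`,
#'   `rel_error_pct`; duty-cycle rows are in percentage points.
#' @export
recover_parameters <- function(duration_s = 600, n_reps = 60,
                               sample_rate_hz = 50, seed = 1,
                               profile = step_profile(
                                 median_duration_s = duration_s,
                                 duration_log_sd = 1e-6,
                                 duty_cycle_dom = 0.6,
                                 duty_cycle_nondom = 0.45,
                                 speed_dom_cm_s = 4,
                                 speed_nondom_cm_s = 3.2,
                                 dominance_scale = 1.3,
                                 motion_scale = 1.8)) {
  cfg <- generator_config(
    cohorts = list(cohort_spec("solo", list(dissection = profile),
                               n_cases = n_reps)),
    sample_rate_hz = sample_rate_hz, seed = seed, case_jitter_sd = 1e-9)
  sim <- suppressWarnings(simulate_cohorts(cfg))
  opis <- do.call(rbind, lapply(sim$cases, case_opis))
  est <- c(
    speed_dom_cm_s = sum(opis$pathlength_dom_cm) /
      sum(opis$active_time_dom_s),
    speed_nondom_cm_s = sum(opis$pathlength_nondom_cm) /
      sum(opis$active_time_nondom_s),
    pct_active_dom = 100 * sum(opis$active_time_dom_s) /
      sum(opis$total_task_duration_s),
    pct_active_nondom = 100 * sum(opis$active_time_nondom_s) /
      sum(opis$total_task_duration_s),
    bimanual_dexterity = sum(opis$pathlength_dom_cm) /
      sum(opis$pathlength_nondom_cm),
    sensitivity_ratio_dom = sum(opis$pathlength_dom_cm) /
      sum(opis$pathlength_dom_cm / opis$sensitivity_ratio_dom),
    sensitivity_ratio_nondom = sum(opis$pathlength_nondom_cm) /
      sum(opis$pathlength_nondom_cm / opis$sensitivity_ratio_nondom))
  prog <- c(
    speed_dom_cm_s = profile$speed_dom_cm_s * profile$dominance_scale,
    speed_nondom_cm_s = profile$speed_nondom_cm_s,
    pct_active_dom = 100 * profile$duty_cycle_dom,
    pct_active_nondom = 100 * profile$duty_cycle_nondom,
    bimanual_dexterity = profile$speed_dom_cm_s * profile$dominance_scale *
      profile$duty_cycle_dom /
      (profile$speed_nondom_cm_s * profile$duty_cycle_nondom),
    sensitivity_ratio_dom = profile$motion_scale,
    sensitivity_ratio_nondom = profile$motion_scale)
  data.frame(parameter = names(prog), programmed = unname(prog),
             estimated = unname(est[names(prog)]),
             abs_error = unname(abs(est[names(prog)] - prog)),
             rel_error_pct = unname(100 * abs(est[names(prog)] - prog) /
                                      prog),
             row.names = NULL, stringsAsFactors = FALSE)
}
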