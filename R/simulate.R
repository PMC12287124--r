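#' Per-step generator profile
#'
#' Parameterizes exactly the structures the step OPIs measure: step duration
#' (lognormal), per-hand duty cycle (fraction of the step each hand is
#' actively driving -> percent active time), per-hand target tip speed
#' (cm/s), spatial spread of the mean-reverting motion (-> workspace volume),
#' a dominant-hand travel multiplier (-> bimanual dexterity), and the
#' instrument:wrist motion scale (-> console sensitivity ratio).
#'
#' @param median_duration_s,duration_log_sd lognormal duration parameters.
#' @param duty_cycle_dom,duty_cycle_nondom per-hand active fraction in (0, 1].
#' @param speed_dom_cm_s,speed_nondom_cm_s target mean tip speed during
#'   active time.
#' @param workspace_sigma_cm stationary positional spread of the motion.
#' @param dominance_scale multiplier on dominant-hand travel (> 1 means the
#'   dominant hand travels farther; the effective dominant speed is
#'   `speed_dom_cm_s * dominance_scale`).
#' @param motion_scale instrument-tip : console-wrist path-length ratio.
#' @return a `step_profile` list.
#' @export
step_profile <- function(median_duration_s = 45, duration_log_sd = 0.25,
                         duty_cycle_dom = 0.55, duty_cycle_nondom = 0.5,
                         speed_dom_cm_s = 4, speed_nondom_cm_s = 3.5,
                         workspace_sigma_cm = 2, dominance_scale = 1,
                         motion_scale = 1.8) {
  p <- list(median_duration_s = median_duration_s,
            duration_log_sd = duration_log_sd,
            duty_cycle_dom = duty_cycle_dom,
            duty_cycle_nondom = duty_cycle_nondom,
            speed_dom_cm_s = speed_dom_cm_s,
            speed_nondom_cm_s = speed_nondom_cm_s,
            workspace_sigma_cm = workspace_sigma_cm,
            dominance_scale = dominance_scale,
            motion_scale = motion_scale)
  stopifnot(all(unlist(p) > 0), duty_cycle_dom <= 1, duty_cycle_nondom <= 1)
  structure(p, class = "step_profile")
}

#' Cohort specification
#'
#' @param label cohort label (e.g. `"attending"`, `"trainee"`).
#' @param profiles named list of [step_profile()]s keyed by canonical step
#'   name; steps absent from the list are absent from the cohort's cases.
#' @param n_cases cases to simulate.
#' @param operators data.frame `operator_id`, `role`, `prior_robotic_cases`;
#'   cases are assigned operators cyclically, so several cases can share a
#'   surgeon as in a real service.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(label, profiles, n_cases,
                        operators = data.frame(
                          operator_id = paste0(label, "_op1"),
                          role = "attending", prior_robotic_cases = 500,
                          stringsAsFactors = FALSE)) {
  bad <- setdiff(names(profiles), ryg_steps())
  if (length(bad))
    abort_usage("profiles for unknown step(s): %s", paste(bad, collapse = ", "))
  structure(list(label = label, profiles = profiles, n_cases = n_cases,
                 operators = operators),
            class = "cohort_spec")
}

#' Generator configuration
#'
#' @param cohorts list of [cohort_spec()]s.
#' @param sample_rate_hz nominal kinematic sampling rate (Hz).
#' @param seed master seed. Every stream derives its own substream seed from
#'   (master, cohort, case index, step, hand), so adding cases or cohorts
#'   never perturbs existing ones, and a fixed master seed yields
#'   byte-identical bundles.
#' @param mean_active_bout_s mean length of an active bout; activity is an
#'   alternating renewal process of exponential active/idle bouts with the
#'   idle mean chosen to match the profile's duty cycle, so the interval
#'   algebra is exercised on fragmented activity rather than one block.
#' @param case_jitter_sd between-case lognormal jitter (sd on the log scale)
#'   applied per case and step to speeds, duty cycles and workspace spread —
#'   the case-to-case variability that the cohort statistics operate on.
#' @return a `generator_config` list.
#' @export
generator_config <- function(cohorts, sample_rate_hz = 50, seed = 1,
                             mean_active_bout_s = 8, case_jitter_sd = 0.08) {
  structure(list(cohorts = cohorts, sample_rate_hz = sample_rate_hz,
                 seed = as.integer(seed),
                 mean_active_bout_s = mean_active_bout_s,
                 case_jitter_sd = case_jitter_sd),
            class = "generator_config")
}

# deterministic substream seed: FNV-1a over the key string, folded into
# [0, 2^31 - 2] (R's set.seed accepts any 32-bit integer; keep it positive)
derive_seed <- function(master, ...) {
  key <- paste(c(master, ...), collapse = "\r")
  h <- 5381
  # polynomial rolling hash mod (2^31 - 1); multiplier small enough that the
  # product stays exactly representable in a double
  for (b in utf8ToInt(key)) h <- (h * 131 + b) %% 2147483647
  as.integer(h %% 2147483646) + 1L
}

# alternating exponential active/idle bouts over [0, duration) matching the
# duty cycle; returns a normalized interval matrix of the active spans
simulate_bouts <- function(duration_s, duty_cycle, mean_active_bout_s = 8) {
  if (duty_cycle >= 1) return(cbind(start = 0, end = duration_s))
  mean_idle <- mean_active_bout_s * (1 / duty_cycle - 1)
  t <- 0
  active <- runif(1) < duty_cycle
  starts <- numeric(0); ends <- numeric(0)
  while (t < duration_s) {
    len <- rexp(1, 1 / if (active) mean_active_bout_s else mean_idle)
    if (active) {
      starts <- c(starts, t)
      ends <- c(ends, min(t + len, duration_s))
    }
    t <- t + len
    active <- !active
  }
  if (length(starts) == 0L)
    return(cbind(start = 0, end = min(mean_active_bout_s, duration_s)))
  iv_normalize(starts, ends)
}

#' Simulate one hand's tip and wrist streams for a step
#'
#' Motion model: a stationary damped Langevin process (a stochastic harmonic
#' oscillator with reversion time-constant `tau = 1` s) around the step
#' center — the simplest stationary smooth process with separately
#' controllable spatial spread (`workspace_sigma_cm`) and speed. The process
#' advances only while the hand is active; during idle spans the tip is
#' frozen. Increments are rescaled once so the realized path length during
#' active time equals `target speed x active time` (the raw realized speed is
#' already within a few percent, so the rescale barely perturbs the spread).
#' The wrist stream is the tip stream contracted about its centroid by
#' `1 / motion_scale`.
#'
#' @param profile a [step_profile()].
#' @param hand `"dominant"` or `"nondominant"`.
#' @param duration_s step duration.
#' @param active_intervals normalized active spans within `[0, duration_s)`.
#' @param sample_rate_hz sampling rate.
#' @param center length-3 numeric, step workspace center (cm).
#' @return list with `time_s` (shared sample times, starting at 0; the
#'   caller offsets to the case clock) and two n-by-3 position matrices
#'   `tip`, `wrist`.
#' @export
simulate_trajectory <- function(profile, hand, duration_s, active_intervals,
                                sample_rate_hz = 50, center = c(0, 0, 0)) {
  active_intervals <- as_windows(active_intervals)
  dt <- 1 / sample_rate_hz
  n <- max(2L, floor(duration_s * sample_rate_hz))
  t <- (seq_len(n) - 1L) * dt
  active <- !is.na(iv_locate(t, active_intervals))
  n_act <- sum(active)
  target <- profile$speed_dom_cm_s * profile$dominance_scale
  if (hand == "nondominant") target <- profile$speed_nondom_cm_s
  sigma_v <- target / (2 * sqrt(2 / pi))  # E|v| = sigma_v * 2 * sqrt(2/pi)

  if (n_act >= 2L) {
    motion <- .sim_motion(n_act, dt, profile$workspace_sigma_cm, sigma_v, 1)
    arc0 <- sum(sqrt(rowSums(diff(motion)^2)))
    at <- iv_length(iv_intersect(active_intervals,
                                 cbind(start = 0, end = duration_s)))
    scl <- if (arc0 > 0) target * at / arc0 else 1
    motion <- sweep(sweep(motion, 2, motion[1, ]) * scl, 2, -motion[1, ])
  } else {
    motion <- matrix(rnorm(3, 0, profile$workspace_sigma_cm), 1, 3)
  }
  j <- pmax(cumsum(active), 1L)
  tip <- sweep(motion[j, , drop = FALSE], 2, -center)
  ctr <- colMeans(tip)
  wrist <- sweep(sweep(tip, 2, ctr) / profile$motion_scale, 2, -ctr)
  list(time_s = t, tip = tip, wrist = wrist)
}

# one raw annotation label (or several subtask labels) per canonical step,
# exercising the synonym lexicon and segment-union logic
.RAW_LABELS <- list(
  dissection = c("Dissection of Angle of His", "Retrogastric dissection"),
  creation_of_gastric_pouch = "Gastric Pouch Creation",
  measurement = "Limb measurement",
  division_of_mesentery = "Mesenteric division",
  staple_anastomosis = "Stapled anastomosis",
  enterotomy_closure = c("Common channel enterotomy closure"),
  defect_closure = c("Mesenteric defect closure", "Petersen defect closure"),
  hand_sewn_anastomosis = "Hand sewn anastomosis")

#' Simulate a complete case bundle
#'
#' Draws per-step durations from the cohort's profiles, lays the steps out
#' sequentially, simulates alternating active/idle bouts and both hands' tip
#' and wrist streams, labels segments with raw subtask names that map onto
#' the canonical ontology (some steps are annotated as two subtasks to
#' exercise the merge logic), and builds the roster. Per-case lognormal
#' jitter (`case_jitter_sd`) perturbs speeds, duty cycles and workspace
#' spread, giving the case-to-case variability the statistics see. The
#' realized (jittered) per-step parameters are attached as
#' `attr(case, "ground_truth")`.
#'
#' @param config a [generator_config()].
#' @param cohort_label which cohort to draw the case from.
#' @param case_index 1-based case index within the cohort.
#' @return a validated [case_record()] with a `ground_truth` attribute.
#' @export
simulate_case <- function(config, cohort_label, case_index) {
  co <- NULL
  for (c_ in config$cohorts) if (c_$label == cohort_label) co <- c_
  if (is.null(co)) abort_usage("unknown cohort: %s", cohort_label)
  op <- co$operators[1L + (case_index - 1L) %% nrow(co$operators), ]
  case_id <- sprintf("%s_case%03d", co$label, case_index)
  rate <- config$sample_rate_hz

  kin <- list(); act <- list(); seg <- list(); truth <- list()
  t0 <- 0
  steps <- ryg_steps()
  for (s in steps[steps %in% names(co$profiles)]) {
    set.seed(derive_seed(config$seed, co$label, case_index, s, "layout"))
    pr <- co$profiles[[s]]
    jit <- function(x) x * rlnorm(1, 0, config$case_jitter_sd)
    pr$speed_dom_cm_s <- jit(pr$speed_dom_cm_s)
    pr$speed_nondom_cm_s <- jit(pr$speed_nondom_cm_s)
    pr$duty_cycle_dom <- min(jit(pr$duty_cycle_dom), 1)
    pr$duty_cycle_nondom <- min(jit(pr$duty_cycle_nondom), 1)
    pr$workspace_sigma_cm <- jit(pr$workspace_sigma_cm)
    dur <- rlnorm(1, log(pr$median_duration_s), pr$duration_log_sd)
    dur <- max(dur, 4 / rate * 10)
    center <- runif(3, -8, 8)
    bouts <- list(
      dominant = simulate_bouts(dur, pr$duty_cycle_dom,
                                config$mean_active_bout_s),
      nondominant = simulate_bouts(dur, pr$duty_cycle_nondom,
                                   config$mean_active_bout_s))

    for (h in .HANDS) {
      set.seed(derive_seed(config$seed, co$label, case_index, s, h))
      tr <- simulate_trajectory(pr, h, dur, bouts[[h]], rate, center)
      for (src in c("instrument_tip", "controller_wrist")) {
        kin[[length(kin) + 1L]] <- list(
          time_s = tr$time_s + t0, hand = h, source = src,
          xyz = tr[[if (src == "instrument_tip") "tip" else "wrist"]])
      }
      scope <- if (h == "dominant") "dominant_hand" else "nondominant_hand"
      act[[length(act) + 1L]] <- data.frame(
        operator_id = op$operator_id, scope = scope,
        start_s = bouts[[h]][, "start"] + t0,
        end_s = bouts[[h]][, "end"] + t0, stringsAsFactors = FALSE)
    }
    console <- iv_normalize(c(bouts$dominant[, 1], bouts$nondominant[, 1]),
                            c(bouts$dominant[, 2], bouts$nondominant[, 2]))
    act[[length(act) + 1L]] <- data.frame(
      operator_id = op$operator_id, scope = "console",
      start_s = console[, "start"] + t0, end_s = console[, "end"] + t0,
      stringsAsFactors = FALSE)

    labels <- .RAW_LABELS[[s]]
    cuts <- seq(t0, t0 + dur, length.out = length(labels) + 1L)
    seg[[length(seg) + 1L]] <- data.frame(
      raw_label = labels, operator_id = op$operator_id,
      start_s = cuts[-length(cuts)], end_s = cuts[-1L],
      stringsAsFactors = FALSE)

    truth[[length(truth) + 1L]] <- data.frame(
      case_id = case_id, step = s, operator_id = op$operator_id,
      duration_s = dur,
      duty_cycle_dom = pr$duty_cycle_dom,
      duty_cycle_nondom = pr$duty_cycle_nondom,
      speed_dom_cm_s = pr$speed_dom_cm_s * pr$dominance_scale,
      speed_nondom_cm_s = pr$speed_nondom_cm_s,
      workspace_sigma_cm = pr$workspace_sigma_cm,
      dominance_scale = pr$dominance_scale,
      motion_scale = pr$motion_scale,
      realized_duty_dom = iv_length(bouts$dominant) / dur,
      realized_duty_nondom = iv_length(bouts$nondominant) / dur,
      stringsAsFactors = FALSE)
    t0 <- t0 + dur
  }

  lens <- vapply(kin, function(b) length(b$time_s), integer(1))
  xyz <- do.call(rbind, lapply(kin, `[[`, "xyz"))
  kin_df <- data.frame(
    time_s = unlist(lapply(kin, `[[`, "time_s"), use.names = FALSE),
    operator_id = op$operator_id,
    hand = rep(vapply(kin, `[[`, "", "hand"), lens),
    source = rep(vapply(kin, `[[`, "", "source"), lens),
    x_cm = xyz[, 1], y_cm = xyz[, 2], z_cm = xyz[, 3],
    stringsAsFactors = FALSE)
  case <- case_record(
    case_id = case_id,
    kinematics = kin_df,
    activity = do.call(rbind, act),
    segments = do.call(rbind, seg),
    roster = data.frame(operator_id = op$operator_id, role = op$role,
                        prior_robotic_cases = op$prior_robotic_cases,
                        handedness = "right", stringsAsFactors = FALSE),
    metadata = list(procedure = "initial", cohort = co$label),
    sample_rate_hz = rate)
  attr(case, "ground_truth") <- do.call(rbind, truth)
  case
}

#' Simulate all cohorts of a configuration
#'
#' @param config a [generator_config()].
#' @param path optional output directory; when given, one bundle per case is
#'   written under `path/<case_id>/` together with `manifest.yaml` recording
#'   the ground-truth per-step parameters of every case.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return invisibly, a list with `cases` (list of `case_record`s) and
#'   `truth` (the pooled ground-truth data.frame).
#' @export
simulate_cohorts <- function(config, path = NULL, overwrite = FALSE) {
  cases <- list(); truth <- list()
  for (co in config$cohorts) {
    for (i in seq_len(co$n_cases)) {
      cs <- simulate_case(config, co$label, i)
      cases[[cs$case_id]] <- cs
      truth[[cs$case_id]] <- cbind(cohort = co$label,
                                   attr(cs, "ground_truth"))
    }
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  if (!is.null(path)) {
    if (dir.exists(path) && length(list.files(path)) > 0L && !overwrite)
      abort_usage("output directory %s exists and is non-empty", path)
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    for (cs in cases)
      write_case_bundle(cs, file.path(path, cs$case_id), overwrite = overwrite)
    yaml::write_yaml(list(seed = config$seed,
                          sample_rate_hz = config$sample_rate_hz,
                          n_cases = length(cases),
                          truth = lapply(split(truth, truth$case_id),
                                         function(d) as.list(d))),
                     file.path(path, "manifest.yaml"))
  }
  invisible(list(cases = cases, truth = truth))
}
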