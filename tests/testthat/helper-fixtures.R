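# Small hand-built case fixtures, constructed in code (no stored data).

# regular samples along a straight line, one operator, both hands + wrists
make_line_stream <- function(t, slope = c(1, 0, 0), origin = c(0, 0, 0)) {
  data.frame(time_s = t,
             x_cm = origin[1] + slope[1] * t,
             y_cm = origin[2] + slope[2] * t,
             z_cm = origin[3] + slope[3] * t)
}

make_test_case <- function(case_id = "fixture01", duration = 10, rate = 10,
                           n_ops = 1) {
  t <- seq(0, duration - 1 / rate, by = 1 / rate)
  ops <- paste0("op", seq_len(n_ops))
  kin <- do.call(rbind, lapply(ops, function(op) {
    do.call(rbind, lapply(c("dominant", "nondominant"), function(h) {
      do.call(rbind, lapply(c("instrument_tip", "controller_wrist"),
                            function(src) {
        sl <- if (h == "dominant") c(2, 0, 0) else c(0, 1, 0)
        if (src == "controller_wrist") sl <- sl / 2
        cbind(make_line_stream(t, sl), operator_id = op, hand = h,
              source = src, stringsAsFactors = FALSE)
      }))
    }))
  }))
  activity <- do.call(rbind, lapply(ops, function(op) {
    data.frame(operator_id = op,
               scope = c("console", "dominant_hand", "nondominant_hand"),
               start_s = 0, end_s = duration, stringsAsFactors = FALSE)
  }))
  segments <- do.call(rbind, lapply(seq_along(ops), function(i) {
    data.frame(raw_label = c("Dissection of Angle of His",
                             "Gastric Pouch Creation"),
               operator_id = ops[i],
               start_s = c(0, duration / 2),
               end_s = c(duration / 2, duration),
               stringsAsFactors = FALSE)
  }))
  roster <- data.frame(operator_id = ops,
                       role = rep(c("attending", "resident"),
                                  length.out = n_ops),
                       prior_robotic_cases = 100,
                       handedness = "right", stringsAsFactors = FALSE)
  case_record(case_id, kin, activity, segments, roster,
              metadata = list(procedure = "initial"), sample_rate_hz = rate)
}

# tiny two-cohort config for fast end-to-end tests
make_small_config <- function(seed = 1, n_cases = 4,
                              steps = c("dissection",
                                        "creation_of_gastric_pouch")) {
  profiles <- setNames(lapply(steps, function(s)
    step_profile(median_duration_s = 15)), steps)
  generator_config(
    cohorts = list(
      cohort_spec("attending", profiles, n_cases,
                  data.frame(operator_id = "a1", role = "attending",
                             prior_robotic_cases = 800,
                             stringsAsFactors = FALSE)),
      cohort_spec("trainee", profiles, n_cases,
                  data.frame(operator_id = "t1", role = "resident",
                             prior_robotic_cases = 20,
                             stringsAsFactors = FALSE))),
    sample_rate_hz = 20, seed = seed)
}

# rigid rotation matrix from an axis-angle (unit quaternion free)
rotation_matrix <- function(axis = c(1, 1, 1), angle = 0.7) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

apply_rigid <- function(case, R = rotation_matrix(), shift = c(5, -3, 2)) {
  p <- as.matrix(case$kinematics[, c("x_cm", "y_cm", "z_cm")]) %*% t(R)
  case$kinematics$x_cm <- p[, 1] + shift[1]
  case$kinematics$y_cm <- p[, 2] + shift[2]
  case$kinematics$z_cm <- p[, 3] + shift[3]
  case
}

scale_case <- function(case, k) {
  case$kinematics$x_cm <- case$kinematics$x_cm * k
  case$kinematics$y_cm <- case$kinematics$y_cm * k
  case$kinematics$z_cm <- case$kinematics$z_cm * k
  case
}

swap_hands <- function(case) {
  h <- case$kinematics$hand
  case$kinematics$hand <- ifelse(h == "dominant", "nondominant", "dominant")
  sc <- case$activity$scope
  case$activity$scope <- ifelse(sc == "dominant_hand", "nondominant_hand",
                                ifelse(sc == "nondominant_hand",
                                       "dominant_hand", sc))
  case
}
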