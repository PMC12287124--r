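#' Assemble a case record
#'
#' A case record holds everything recorded for one operation: the kinematic
#' streams (instrument-tip and console-wrist positions for each hand of each
#' operator), the activity events (spans during which a console or hand was
#' actively driving), the annotated step segments, and the operator roster.
#' All tables share one clock: seconds from case start. Coordinates are
#' centimeters in an arbitrary fixed right-handed frame; every metric computed
#' downstream is invariant to translation and rotation of that frame, so no
#' registration between cases is attempted.
#'
#' @param case_id character scalar.
#' @param kinematics data.frame with columns `time_s`, `operator_id`, `hand`
#'   (`"dominant"`/`"nondominant"`), `source` (`"instrument_tip"`/
#'   `"controller_wrist"`), `x_cm`, `y_cm`, `z_cm`. Within one
#'   (operator, hand, source) stream timestamps must be strictly increasing.
#' @param activity data.frame with columns `operator_id`, `scope`
#'   (`"console"`, `"dominant_hand"`, `"nondominant_hand"`), `start_s`,
#'   `end_s`; spans are half-open `[start_s, end_s)`.
#' @param segments data.frame with columns `raw_label`, `operator_id`,
#'   `start_s`, `end_s`.
#' @param roster data.frame with columns `operator_id`, `role`
#'   (`"attending"`, `"fellow"`, `"resident"`), `prior_robotic_cases`,
#'   `handedness` (`"right"`/`"left"`).
#' @param metadata named list of free-form case metadata.
#' @param sample_rate_hz nominal kinematic sampling rate (Hz); sample gaps
#'   longer than 5 nominal periods are reported as warnings, not errors,
#'   because clinical recorders drop samples.
#' @return A validated object of class `case_record`.
#' @seealso [read_case_bundle()], [write_case_bundle()], [simulate_case()]
#' @export
case_record <- function(case_id, kinematics, activity, segments, roster,
                        metadata = list(), sample_rate_hz = 50) {
  plain <- function(df) {
    df <- as.data.frame(df)
    rownames(df) <- NULL
    df
  }
  x <- structure(
    list(case_id = as.character(case_id),
         kinematics = plain(kinematics),
         activity = plain(activity),
         segments = plain(segments),
         roster = plain(roster),
         metadata = metadata,
         sample_rate_hz = as.numeric(sample_rate_hz)),
    class = "case_record")
  validate_case_record(x)
}

.HANDS <- c("dominant", "nondominant")
.SOURCES <- c("instrument_tip", "controller_wrist")
.SCOPES <- c("console", "dominant_hand", "nondominant_hand")
.ROLES <- c("attending", "fellow", "resident")

require_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    abort_validation("%s is missing column(s): %s", what,
                     paste(miss, collapse = ", "))
}

#' Validate a case record
#'
#' Enforces the structural invariants of a [case_record()]: finite
#' coordinates, non-negative strictly increasing timestamps per stream,
#' well-formed half-open activity and segment spans, and referential
#' integrity of `operator_id` against the roster. Sampling gaps larger than
#' five nominal periods raise an `opikin_gap_warning` (recorder dropouts are
#' tolerated); genuine invariant violations raise an
#' `opikin_validation_error` naming the offending stream.
#'
#' @param x a `case_record`.
#' @return `x`, invisibly, when valid.
#' @export
validate_case_record <- function(x) {
  if (!inherits(x, "case_record")) abort_usage("not a case_record")
  kin <- x$kinematics
  require_cols(kin, c("time_s", "operator_id", "hand", "source",
                      "x_cm", "y_cm", "z_cm"), "kinematics")
  require_cols(x$activity, c("operator_id", "scope", "start_s", "end_s"),
               "activity")
  require_cols(x$segments, c("raw_label", "operator_id", "start_s", "end_s"),
               "segments")
  require_cols(x$roster, c("operator_id", "role", "prior_robotic_cases",
                           "handedness"), "roster")
  if (nrow(kin) == 0L) abort_validation("case has no kinematic samples")

  coords <- as.matrix(kin[, c("x_cm", "y_cm", "z_cm")])
  if (!all(is.finite(coords)))
    abort_validation("non-finite coordinates in kinematics")
  if (!all(is.finite(kin$time_s)) || any(kin$time_s < 0))
    abort_validation("kinematic time_s must be finite and >= 0")
  if (!all(kin$hand %in% .HANDS))
    abort_validation("kinematics hand must be one of: %s",
                     paste(.HANDS, collapse = ", "))
  if (!all(kin$source %in% .SOURCES))
    abort_validation("kinematics source must be one of: %s",
                     paste(.SOURCES, collapse = ", "))

  key <- paste(kin$operator_id, kin$hand, kin$source, sep = ", ")
  period <- 1 / x$sample_rate_hz
  for (idx in split(seq_len(nrow(kin)), key)) {
    tt <- kin$time_s[idx]
    dt <- diff(tt)
    if (any(dt <= 0))
      abort_validation("non-increasing timestamps in stream (%s) at t=%g s",
                       key[idx[1]], tt[which(dt <= 0)[1] + 1L])
    ngap <- sum(dt > 5 * period)
    if (ngap > 0)
      warn_opikin("stream (%s) has %d sampling gap(s) > 5 nominal periods",
                  key[idx[1]], ngap, class = "opikin_gap_warning")
  }

  if (nrow(x$activity)) {
    if (!all(x$activity$scope %in% .SCOPES))
      abort_validation("activity scope must be one of: %s",
                       paste(.SCOPES, collapse = ", "))
    if (any(x$activity$start_s >= x$activity$end_s))
      abort_validation("activity interval with start_s >= end_s")
  }
  if (nrow(x$segments) && any(x$segments$start_s >= x$segments$end_s))
    abort_validation("segment with start_s >= end_s")

  if (!all(x$roster$role %in% .ROLES))
    abort_validation("roster role must be one of: %s",
                     paste(.ROLES, collapse = ", "))
  if (any(is.na(x$roster$handedness)) ||
      !all(x$roster$handedness %in% c("right", "left")))
    abort_validation("handedness must be recorded (right/left) for every operator")
  if (anyDuplicated(x$roster$operator_id))
    abort_validation("duplicate operator_id in roster")

  known <- x$roster$operator_id
  for (tab in c("kinematics", "activity", "segments")) {
    unk <- setdiff(unique(x[[tab]]$operator_id), known)
    if (length(unk))
      abort_validation("%s references operator_id not in roster: %s",
                       tab, paste(unk, collapse = ", "))
  }
  invisible(x)
}

#' @export
print.case_record <- function(x, ...) {
  cat(sprintf("<case_record %s>\n", x$case_id))
  cat(sprintf("  %d kinematic samples in %d stream(s) @ %g Hz nominal\n",
              nrow(x$kinematics),
              nrow(unique(x$kinematics[, c("operator_id", "hand", "source")])),
              x$sample_rate_hz))
  cat(sprintf("  %d activity interval(s), %d segment(s), %d operator(s)\n",
              nrow(x$activity), nrow(x$segments), nrow(x$roster)))
  invisible(x)
}

#' Extract one kinematic stream from a case
#'
#' @param case a `case_record`.
#' @param operator_id,hand,source stream key.
#' @return data.frame (`time_s`, `x_cm`, `y_cm`, `z_cm`), possibly empty.
#' @export
get_stream <- function(case, operator_id, hand, source = "instrument_tip") {
  kin <- case$kinematics
  sel <- kin$operator_id == operator_id & kin$hand == hand &
    kin$source == source
  out <- kin[sel, c("time_s", "x_cm", "y_cm", "z_cm")]
  rownames(out) <- NULL
  out
}

# activity intervals for one operator/scope as a normalized interval matrix
activity_intervals <- function(case, operator_id, scope) {
  act <- case$activity
  sel <- act$operator_id == operator_id & act$scope == scope
  if (!any(sel)) return(iv_empty())
  iv_normalize(act$start_s[sel], act$end_s[sel])
}
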