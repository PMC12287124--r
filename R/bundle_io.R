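#' Read and write case bundles
#'
#' A case bundle is a directory of plain comma-delimited text files plus a
#' small YAML header — a clean-room stand-in for the proprietary console
#' recorder format, which is undocumented:
#'
#' * `kinematics.csv`: `time_s, operator_id, hand, source, x_cm, y_cm, z_cm`
#' * `activity.csv`:   `operator_id, scope, start_s, end_s`
#' * `segments.csv`:   `raw_label, operator_id, start_s, end_s`
#' * `roster.csv`:     `operator_id, role, prior_robotic_cases, handedness`
#' * `meta.yaml`:      `case_id`, `sample_rate_hz`, free-form `metadata`
#'
#' Numeric values are serialized with 17 significant digits so that
#' `read_case_bundle(write_case_bundle(x))` reproduces `x` exactly.
#'
#' @param path bundle directory.
#' @return `read_case_bundle()`: a validated [case_record()].
#' @export
read_case_bundle <- function(path) {
  files <- c(kinematics = "kinematics.csv", activity = "activity.csv",
             segments = "segments.csv", roster = "roster.csv",
             meta = "meta.yaml")
  paths <- file.path(path, files)
  names(paths) <- names(files)
  missing <- !file.exists(paths)
  if (any(missing))
    abort_validation("bundle %s is missing file(s): %s", path,
                     paste(files[missing], collapse = ", "))
  kin <- read.csv(paths["kinematics"], stringsAsFactors = FALSE)
  act <- read.csv(paths["activity"], stringsAsFactors = FALSE)
  seg <- read.csv(paths["segments"], stringsAsFactors = FALSE)
  ros <- read.csv(paths["roster"], stringsAsFactors = FALSE)
  meta <- yaml::read_yaml(paths["meta"])
  case_record(case_id = meta$case_id %||% basename(path),
              kinematics = kin, activity = act, segments = seg, roster = ros,
              metadata = meta$metadata %||% list(),
              sample_rate_hz = meta$sample_rate_hz %||% 50)
}

# write numerics at full double precision so the text round-trip is exact
format_full <- function(df) {
  for (nm in names(df))
    if (is.numeric(df[[nm]]) && !is.integer(df[[nm]]))
      df[[nm]] <- sprintf("%.17g", df[[nm]])
  df
}

#' @param case a valid [case_record()].
#' @param overwrite overwrite an existing bundle directory?
#' @rdname read_case_bundle
#' @export
write_case_bundle <- function(case, path, overwrite = FALSE) {
  validate_case_record(case)
  if (nrow(case$kinematics) == 0L)
    abort_validation("refusing to write a bundle with no kinematics")
  if (dir.exists(path) && !overwrite &&
      length(list.files(path)) > 0L)
    abort_usage("output directory %s exists and is non-empty (use overwrite)", path)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, file) {
    write.csv(format_full(df), file.path(path, file), row.names = FALSE,
              quote = FALSE)
  }
  wr(case$kinematics, "kinematics.csv")
  wr(case$activity, "activity.csv")
  wr(case$segments, "segments.csv")
  wr(case$roster, "roster.csv")
  yaml::write_yaml(list(case_id = case$case_id,
                        sample_rate_hz = case$sample_rate_hz,
                        metadata = case$metadata),
                   file.path(path, "meta.yaml"))
  invisible(path)
}

#' Render a p-value the way the comparison tables print it
#'
#' Three decimals, with values below 0.001 rendered as `"<0.001"`.
#'
#' @param p numeric vector of p-values.
#' @return character vector.
#' @export
format_p <- function(p) {
  ifelse(is.na(p), "NA",
         ifelse(p < 0.001, "<0.001", sprintf("%.3f", p)))
}

#' Write an OPI or comparison table to delimited text
#'
#' Serializes either per-(case, step, operator) OPI rows
#' ([compute_step_opis()]) or two-group comparison rows
#' ([build_comparison_table()]) as CSV with a fixed column order. OPI rows
#' are sorted by (`case_id`, step-ontology index, `operator_id`); comparison
#' rows keep their (step index, metric) order. A `p_value` column, when
#' present, is rendered to three decimals with `"<0.001"` below that
#' threshold; the numeric value is preserved alongside as `p_value_numeric`.
#'
#' @param rows a `step_opi` or `comparison_table` data.frame (not a mixture).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_opi_table <- function(rows, path) {
  if (!is.data.frame(rows))
    abort_usage("rows must be a data.frame of one row type")
  if (inherits(rows, "step_opi")) {
    if (nrow(rows)) {
      idx <- match(rows$step, ryg_steps())
      rows <- rows[order(rows$case_id, idx, rows$operator_id), , drop = FALSE]
    }
  } else if (inherits(rows, "comparison_table")) {
    if ("p_value" %in% names(rows)) {
      rows$p_value_numeric <- rows$p_value
      rows$p_value <- format_p(rows$p_value_numeric)
    }
  } else if ("p_value" %in% names(rows) &&
             any(c("case_id", "operator_id") %in% names(rows))) {
    abort_usage("mixed row types: table has both per-case and comparison columns")
  }
  df <- as.data.frame(rows)
  for (nm in names(df))
    if (is.numeric(df[[nm]]) && !is.integer(df[[nm]]))
      df[[nm]] <- signif(df[[nm]], 12)
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
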