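#' The eight-step r-RYGB ontology
#'
#' Robotic Roux-en-Y gastric bypass is analyzed over eight canonical steps,
#' ordered as they occur in the procedure. Raw annotation subtasks are mapped
#' onto these steps (merging smaller segmented tasks), and rare side tasks
#' such as the leak test or a concurrent hiatal hernia repair are excluded so
#' that comparisons concentrate on steps with adequate sample sizes.
#'
#' @return `ryg_steps()`: character vector of the eight canonical step names
#'   in procedure order.
#' @export
ryg_steps <- function() {
  c("dissection", "creation_of_gastric_pouch", "measurement",
    "division_of_mesentery", "staple_anastomosis", "enterotomy_closure",
    "defect_closure", "hand_sewn_anastomosis")
}

#' Load or build a step lexicon
#'
#' The lexicon maps raw annotation labels to canonical steps. It ships as an
#' editable YAML file (the raw labels used by any given annotation team are
#' not standardized, so the mapping must be user-extensible) with three keys:
#' `steps` (the canonical names, in order), `synonyms` (raw label ->
#' canonical step) and `exclusions` (labels excluded from analysis). Matching
#' is case-insensitive on a whitespace/punctuation-normalized label.
#'
#' @param path YAML lexicon; default is the packaged one.
#' @return a `step_lexicon` list with elements `steps`, `synonyms`,
#'   `exclusions`.
#' @export
read_ontology <- function(path = system.file("extdata", "ontology.yaml",
                                             package = "opikin")) {
  raw <- yaml::read_yaml(path)
  steps <- unlist(raw$steps)
  if (!identical(sort(steps), sort(ryg_steps())))
    abort_validation("ontology steps must be exactly the eight canonical steps")
  syn <- lapply(raw$synonyms, as.character)
  bad <- !unlist(syn) %in% steps
  if (any(bad))
    abort_validation("synonym targets not canonical steps: %s",
                     paste(unlist(syn)[bad], collapse = ", "))
  structure(list(steps = steps,
                 synonyms = setNames(as.character(unlist(syn)),
                                     normalize_label(names(syn))),
                 exclusions = normalize_label(unlist(raw$exclusions))),
            class = "step_lexicon")
}

#' @rdname read_ontology
#' @export
default_ontology <- function() read_ontology()

normalize_label <- function(x) {
  x <- tolower(trimws(x))
  gsub("[^a-z0-9]+", "_", x)
}

#' Map raw annotation labels to canonical steps
#'
#' @param raw_label character vector of raw annotation labels.
#' @param lexicon a `step_lexicon` from [read_ontology()].
#' @return character vector: a canonical step name, `"EXCLUDED"` for labels
#'   on the exclusion list, or `"UNKNOWN"` for unmapped labels. `UNKNOWN` is
#'   a value, not an error; downstream policy decides what to do with it.
#' @examples
#' lex <- default_ontology()
#' map_subtask("Creation of Gastric Pouch", lex)  # canonical step
#' map_subtask("leak test", lex)                  # "EXCLUDED"
#' @export
map_subtask <- function(raw_label, lexicon = default_ontology()) {
  norm <- normalize_label(raw_label)
  out <- rep("UNKNOWN", length(norm))
  out[norm %in% lexicon$exclusions] <- "EXCLUDED"
  is_canon <- norm %in% lexicon$steps
  out[is_canon] <- norm[is_canon]
  hit <- match(norm, names(lexicon$synonyms))
  use <- !is.na(hit) & out == "UNKNOWN"
  out[use] <- unname(lexicon$synonyms[hit[use]])
  out
}

#' Build per-step analysis windows for a case
#'
#' Maps every annotated segment onto the ontology, drops excluded and
#' unmapped labels (the latter with a warning), resolves overlaps between
#' segments of *different* steps by truncating the later-starting segment at
#' the earlier one's end (the ontology is linear), and unions overlapping
#' windows *within* one (step, operator). Segments from different operators
#' are never merged, so per-operator OPIs stay computable. Steps revisited
#' after an interruption are analyzed as one unit (all windows of a step in a
#' case pooled); steps with instrument-tip kinematics for only one hand (or
#' neither) inside their windows are omitted, mirroring the exclusion of
#' steps without both console streams.
#'
#' @param case a validated [case_record()].
#' @param lexicon a `step_lexicon`.
#' @return a `step_windows` data.frame: `case_id`, `step`, `step_index`,
#'   `operator_id`, `role`, `start_s`, `end_s`, ordered by ontology index.
#' @export
build_step_windows <- function(case, lexicon = default_ontology()) {
  seg <- case$segments
  if (nrow(seg) == 0L) {
    warn_opikin("case %s has no segments", case$case_id)
    return(empty_step_windows())
  }
  seg$step <- map_subtask(seg$raw_label, lexicon)
  n_unknown <- sum(seg$step == "UNKNOWN")
  if (n_unknown > 0)
    warn_opikin("case %s: dropping %d segment(s) with unmapped label(s): %s",
                case$case_id, n_unknown,
                paste(unique(seg$raw_label[seg$step == "UNKNOWN"]),
                      collapse = ", "))
  seg <- seg[!seg$step %in% c("UNKNOWN", "EXCLUDED"), , drop = FALSE]
  if (nrow(seg) == 0L) {
    warn_opikin("case %s has no mappable segments", case$case_id)
    return(empty_step_windows())
  }
  seg$step_index <- match(seg$step, lexicon$steps)

  # linear ontology: truncate a segment that starts inside an
  # earlier-starting segment of a *different* step
  seg <- seg[order(seg$start_s, seg$end_s), , drop = FALSE]
  for (i in seq_len(nrow(seg))) {
    if (i == 1L) next
    for (j in seq_len(i - 1L)) {
      if (seg$step[j] != seg$step[i] && seg$end_s[j] > seg$start_s[i] &&
          seg$start_s[j] <= seg$start_s[i]) {
        warn_opikin("case %s: segment '%s' overlaps '%s'; truncating at %g s",
                    case$case_id, seg$raw_label[i], seg$raw_label[j],
                    seg$end_s[j])
        seg$start_s[i] <- seg$end_s[j]
      }
    }
  }
  seg <- seg[seg$start_s < seg$end_s, , drop = FALSE]

  role_of <- setNames(case$roster$role, case$roster$operator_id)
  out <- list()
  for (grp in split(seg, list(seg$step, seg$operator_id), drop = TRUE)) {
    iv <- iv_normalize(grp$start_s, grp$end_s)
    out[[length(out) + 1L]] <- data.frame(
      case_id = case$case_id,
      step = grp$step[1],
      step_index = grp$step_index[1],
      operator_id = grp$operator_id[1],
      role = unname(role_of[grp$operator_id[1]]),
      start_s = iv[, "start"], end_s = iv[, "end"],
      stringsAsFactors = FALSE)
  }
  win <- do.call(rbind, out)
  win <- win[order(win$step_index, win$operator_id, win$start_s), ,
             drop = FALSE]

  # omit steps lacking tip kinematics for both hands inside their windows
  kin <- case$kinematics
  is_tip <- kin$source == "instrument_tip"
  tip_t <- lapply(setNames(.HANDS, .HANDS), function(h)
    list(t = kin$time_s[is_tip & kin$hand == h],
         op = kin$operator_id[is_tip & kin$hand == h]))
  keep_step <- vapply(unique(win$step), function(s) {
    wv <- win[win$step == s, , drop = FALSE]
    iv <- iv_normalize(wv$start_s, wv$end_s)
    all(vapply(.HANDS, function(h) {
      sel <- tip_t[[h]]$op %in% wv$operator_id
      any(!is.na(iv_locate(tip_t[[h]]$t[sel], iv)))
    }, logical(1)))
  }, logical(1))
  dropped <- unique(win$step)[!keep_step]
  if (length(dropped))
    warn_opikin("case %s: omitting step(s) without both hands' kinematics: %s",
                case$case_id, paste(dropped, collapse = ", "))
  win <- win[win$step %in% unique(win$step)[keep_step], , drop = FALSE]
  rownames(win) <- NULL
  class(win) <- c("step_windows", "data.frame")
  win
}

empty_step_windows <- function() {
  structure(data.frame(case_id = character(), step = character(),
                       step_index = integer(), operator_id = character(),
                       role = character(), start_s = numeric(),
                       end_s = numeric(), stringsAsFactors = FALSE),
            class = c("step_windows", "data.frame"))
}
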