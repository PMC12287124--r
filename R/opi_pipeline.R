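#' Pipeline configuration
#'
#' @param hand_speed_threshold_cm_s controller-wrist speed (over
#'   `hand_speed_window_s`) above which a hand counts as moving, used only
#'   when per-hand activity scopes are absent and must be derived from
#'   console-scope activity.
#' @param hand_speed_window_s smoothing window for the derived-hand-activity
#'   speed estimate.
#' @param restrict_path_to_active restrict path length to samples inside
#'   active intervals (the default): speed is defined during active console
#'   time, and `speed * active_time = path_length` must hold exactly. The
#'   full-window path length is always reported alongside as a secondary
#'   field (`pathlength_window_*`).
#' @param pool_hands_workspace pool both hands' tip positions for the
#'   workspace hull (the default) or use the dominant hand only.
#' @return a list of settings for [compute_step_opis()].
#' @export
opi_config <- function(hand_speed_threshold_cm_s = 0.05,
                       hand_speed_window_s = 0.1,
                       restrict_path_to_active = TRUE,
                       pool_hands_workspace = TRUE) {
  list(hand_speed_threshold_cm_s = hand_speed_threshold_cm_s,
       hand_speed_window_s = hand_speed_window_s,
       restrict_path_to_active = restrict_path_to_active,
       pool_hands_workspace = pool_hands_workspace)
}

# per-hand activity: recorded hand-scope intervals when available, otherwise
# spans where the controller wrist moves faster than the threshold,
# intersected with console-active time
hand_activity <- function(case, operator_id, hand, console_iv, config) {
  scope <- if (hand == "dominant") "dominant_hand" else "nondominant_hand"
  rec <- activity_intervals(case, operator_id, scope)
  if (nrow(rec) > 0L) return(rec)
  wrist <- get_stream(case, operator_id, hand, "controller_wrist")
  if (nrow(wrist) < 2L) return(console_iv)
  w <- config$hand_speed_window_s
  t <- wrist$time_s
  dpos <- sqrt(diff(wrist$x_cm)^2 + diff(wrist$y_cm)^2 + diff(wrist$z_cm)^2)
  # centered moving displacement over ~w seconds
  dt <- diff(t)
  k <- max(1L, round(w / stats::median(dt)))
  sp <- stats::filter(dpos / dt, rep(1 / k, k), sides = 2)
  sp[is.na(sp)] <- dpos[is.na(sp)] / dt[is.na(sp)]
  moving <- sp > config$hand_speed_threshold_cm_s
  if (!any(moving)) return(iv_empty())
  r <- rle(as.vector(moving))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  act <- which(r$values)
  iv <- iv_normalize(t[starts[act]], t[pmin(ends[act] + 1L, length(t))])
  iv_intersect(iv, console_iv)
}

#' Compute the per-step OPI table for one case
#'
#' For every (step, operator) pair in the step windows, computes the full
#' objective-performance-indicator vector:
#'
#' * `total_task_duration_s` — summed window length of the step;
#' * `active_console_time_s`, `pct_active_console` — time the console was
#'   actively driven inside the step, and as a percentage of duration;
#' * per-hand `active_time_{dom,nondom}_s` and `pct_active_{dom,nondom}`;
#' * `pathlength_{dom,nondom}_cm` — instrument-tip distance traveled during
#'   that hand's active time (plus `pathlength_window_*_cm`, the unrestricted
#'   full-window distances, as a sensitivity field);
#' * `speed_{dom,nondom}_cm_s` — path length over active time, so
#'   `speed * active_time = pathlength` holds exactly per hand;
#' * `bimanual_dexterity` — dominant over non-dominant path length;
#' * `workspace_volume_cm3` — convex hull of pooled both-hand tip positions
#'   during console-active time — with `workspace_rate_cm3_s` (per second of
#'   active console time) and `workspace_per_pathlength_cm2` (per cm of
#'   summed path length);
#' * `sensitivity_ratio_{dom,nondom}` — tip over wrist path length, the
#'   motion-scaling diagnostic.
#'
#' Undefined metrics (zero denominators) are `NA`, never 0 or infinity.
#' Steps whose windows contain no tip kinematics for one of the hands are
#' omitted upstream by [build_step_windows()].
#'
#' @param case a validated [case_record()].
#' @param windows a `step_windows` table from [build_step_windows()].
#' @param config a list from [opi_config()].
#' @return a `step_opi` data.frame, one row per (step, operator), ordered by
#'   ontology step index.
#' @export
compute_step_opis <- function(case, windows, config = opi_config()) {
  if (nrow(windows) == 0L) return(empty_step_opi())
  kin <- case$kinematics
  uops <- unique(kin$operator_id)
  code <- (match(kin$operator_id, uops) - 1L) * 4L +
    (kin$hand == "dominant") * 2L + (kin$source == "instrument_tip") + 1L
  sidx <- split(seq_len(nrow(kin)), code)
  xyz <- cbind(kin$x_cm, kin$y_cm, kin$z_cm)
  # stream restricted to [lo, hi) via binary search on the sorted times
  stream_m <- function(op, h, src, lo = -Inf, hi = Inf) {
    k <- (match(op, uops) - 1L) * 4L + (h == "dominant") * 2L +
      (src == "instrument_tip") + 1L
    i <- sidx[[as.character(k)]]
    if (is.null(i)) return(list(t = numeric(0), p = xyz[0, , drop = FALSE]))
    tt <- kin$time_s[i]
    if (is.finite(lo) || is.finite(hi)) {
      rng <- findInterval(c(lo, hi), tt, left.open = TRUE)
      keep <- if (rng[2] > rng[1]) (rng[1] + 1L):rng[2] else integer(0)
      i <- i[keep]
      tt <- tt[keep]
    }
    list(t = tt, p = xyz[i, , drop = FALSE])
  }
  # path length of the samples inside iv, with no accumulation across
  # interval boundaries (same contract as clip_stream + path_length)
  path_len_m <- function(s, iv) {
    id <- iv_locate(s$t, iv)
    keep <- which(!is.na(id))
    if (length(keep) < 2L) return(0)
    pp <- s$p[keep, , drop = FALSE]
    d <- sqrt(rowSums(diff(pp)^2))
    d[diff(id[keep]) != 0] <- 0
    sum(d)
  }
  clip_m <- function(s, iv) {
    keep <- !is.na(iv_locate(s$t, iv))
    s$p[keep, , drop = FALSE]
  }

  groups <- split(windows, list(windows$step, windows$operator_id),
                  drop = TRUE)
  acc <- vector("list", length(groups))
  gi <- 0L
  for (grp in groups) {
    op <- grp$operator_id[1]
    win <- iv_normalize(grp$start_s, grp$end_s)
    total_s <- iv_length(win)

    console_iv <- activity_intervals(case, op, "console")
    if (nrow(console_iv) == 0L) {
      # fall back to the union of recorded hand scopes
      console_iv <- iv_normalize(
        c(activity_intervals(case, op, "dominant_hand")[, 1],
          activity_intervals(case, op, "nondominant_hand")[, 1]),
        c(activity_intervals(case, op, "dominant_hand")[, 2],
          activity_intervals(case, op, "nondominant_hand")[, 2]))
    }
    console_in <- iv_intersect(console_iv, win)
    active_console_s <- iv_length(console_in)

    lo <- min(win[, "start"]); hi <- max(win[, "end"])
    hand_vals <- lapply(c(dominant = "dominant", nondominant = "nondominant"),
                        function(h) {
      tip <- stream_m(op, h, "instrument_tip", lo, hi)
      wrist <- stream_m(op, h, "controller_wrist", lo, hi)
      act_iv <- iv_intersect(hand_activity(case, op, h, console_iv, config),
                             win)
      at <- iv_length(act_iv)
      clip_iv <- if (config$restrict_path_to_active) act_iv else win
      pl <- path_len_m(tip, clip_iv)
      pl_window <- path_len_m(tip, win)
      wrist_pl <- path_len_m(wrist, clip_iv)
      list(active_s = at, pl = pl, pl_window = pl_window,
           speed = instrument_speed(pl, at),
           sens = console_sensitivity(pl, wrist_pl),
           tip_active = clip_m(tip, console_in))
    })
    dom <- hand_vals$dominant; nond <- hand_vals$nondominant

    ws_pts <- if (config$pool_hands_workspace)
      rbind(dom$tip_active, nond$tip_active) else dom$tip_active
    vol <- if (nrow(ws_pts) >= 4L) .hull3d_volume(ws_pts) else 0
    norm <- normalize_workspace(vol, active_console_s, dom$pl + nond$pl)

    gi <- gi + 1L
    acc[[gi]] <- list(
      step = grp$step[1], step_index = grp$step_index[1], operator_id = op,
      role = grp$role[1],
      num = c(total_task_duration_s = total_s,
              active_console_time_s = active_console_s,
              pct_active_console = if (total_s > 0)
                100 * active_console_s / total_s else NA_real_,
              active_time_dom_s = dom$active_s,
              pct_active_dom = if (total_s > 0)
                100 * dom$active_s / total_s else NA_real_,
              active_time_nondom_s = nond$active_s,
              pct_active_nondom = if (total_s > 0)
                100 * nond$active_s / total_s else NA_real_,
              pathlength_dom_cm = dom$pl,
              pathlength_nondom_cm = nond$pl,
              pathlength_window_dom_cm = dom$pl_window,
              pathlength_window_nondom_cm = nond$pl_window,
              speed_dom_cm_s = dom$speed,
              speed_nondom_cm_s = nond$speed,
              bimanual_dexterity = bimanual_dexterity(dom$pl, nond$pl),
              workspace_volume_cm3 = vol,
              workspace_rate_cm3_s = norm$rate_cm3_s,
              workspace_per_pathlength_cm2 = norm$per_pathlength_cm2,
              sensitivity_ratio_dom = dom$sens,
              sensitivity_ratio_nondom = nond$sens))
  }
  num <- do.call(rbind, lapply(acc, `[[`, "num"))
  out <- data.frame(
    case_id = case$case_id,
    step = vapply(acc, `[[`, "", "step"),
    step_index = vapply(acc, function(a) as.integer(a$step_index),
                        integer(1)),
    operator_id = vapply(acc, `[[`, "", "operator_id"),
    role = vapply(acc, `[[`, "", "role"),
    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(num))
  out <- out[order(out$step_index, out$operator_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("step_opi", "data.frame")
  out
}

empty_step_opi <- function() {
  structure(data.frame(), class = c("step_opi", "data.frame"))
}

#' Run the whole OPI pipeline for one case
#'
#' Convenience wrapper: [build_step_windows()] then [compute_step_opis()].
#'
#' @inheritParams compute_step_opis
#' @param lexicon a `step_lexicon`.
#' @return a `step_opi` data.frame.
#' @export
case_opis <- function(case, lexicon = default_ontology(),
                      config = opi_config()) {
  compute_step_opis(case, build_step_windows(case, lexicon), config)
}

#' OPI metric names usable in cohort comparisons
#'
#' The default metric set mirrors the reported comparison tables: duration,
#' console/hand active-time percentages, per-hand speeds, bimanual dexterity
#' and the two workspace normalizations.
#'
#' @return character vector of column names of a `step_opi` table.
#' @export
opi_metrics <- function() {
  c("total_task_duration_s", "pct_active_console", "pct_active_dom",
    "pct_active_nondom", "speed_dom_cm_s", "speed_nondom_cm_s",
    "bimanual_dexterity", "workspace_rate_cm3_s",
    "workspace_per_pathlength_cm2")
}
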