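#' Trial-level exclusion rules
#'
#' Removes trials according to the pre-registered rules, in a fixed order so
#' each rejected trial carries exactly one (the first triggered) reason:
#'
#' 1. `probe_rt_gt_5000` — probe RT above 5000 ms;
#' 2. `probe_rt_gt_2p5sd` — probe RT more than 2.5 SD above that
#'    participant's mean probe RT, mean and SD computed across all of the
#'    participant's trials surviving the absolute 5000-ms cut (one-sided);
#' 3. `dial_timeout` — report not completed within 4000 ms of dial onset;
#' 4. `distractor_keypress` — a response to the distractor in a distraction
#'    block;
#' 5. `interrupter_no_response` — no response to the interrupter;
#' 6. `interrupter_wrong_key` — response key inconsistent with the
#'    interrupter's tilt direction;
#' 7. `interrupter_rt_gt_1000` — interrupter response slower than 1000 ms.
#'
#' The per-participant RT threshold is frozen into the returned log
#' (`attr(log, "rt_thresholds")`); passing that log back via `frozen`
#' makes filtering idempotent on already-filtered records.
#'
#' @param records trial data.frame (trial CSV dialect).
#' @param thresholds named list overriding the defaults
#'   `probe_rt_ms = 5000`, `rt_sd = 2.5`, `dial_ms = 4000`,
#'   `interrupter_ms = 1000`.
#' @param frozen optional rejection log from a previous pass whose frozen RT
#'   thresholds should be reused.
#' @return list with `kept` (surviving records) and `log` (class
#'   `wm_rejection_log`: one row per rejected trial with its reason, plus a
#'   per-participant summary in `attr(, "participants")`).
#' @export
filter_trials <- function(records, thresholds = list(), frozen = NULL) {
  th <- utils::modifyList(list(probe_rt_ms = 5000, rt_sd = 2.5,
                               dial_ms = 4000, interrupter_ms = 1000),
                          thresholds)
  need <- c("participant_id", "trial_index", "interference_type",
            "interference_present", "interference_angle", "probe_rt_ms",
            "dial_time_ms", "interrupter_response", "interrupter_rt_ms",
            "distractor_keypress")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols))
    stop_schema(paste("filter_trials: missing column(s):",
                      paste(missing_cols, collapse = ", ")))

  reason <- rep(NA_character_, nrow(records))
  hit <- function(cond, label) {
    sel <- is.na(reason) & !is.na(cond) & cond
    reason[sel] <<- label
  }

  hit(records$probe_rt_ms > th$probe_rt_ms, "probe_rt_gt_5000")

  # per-participant 2.5-SD threshold over trials surviving the absolute cut
  if (is.null(frozen)) {
    ok <- is.na(reason) & !is.na(records$probe_rt_ms)
    rts <- split(records$probe_rt_ms[ok], records$participant_id[ok])
    thr <- vapply(rts, function(x) mean(x) + th$rt_sd * stats::sd(x), numeric(1))
  } else {
    thr <- attr(frozen, "rt_thresholds")
    if (is.null(thr)) stop_invalid_input("filter_trials: frozen log lacks rt_thresholds")
  }
  trial_thr <- thr[as.character(records$participant_id)]
  hit(records$probe_rt_ms > trial_thr, "probe_rt_gt_2p5sd")

  hit(records$dial_time_ms > th$dial_ms, "dial_timeout")
  hit(records$interference_type == "distraction" & records$distractor_keypress,
      "distractor_keypress")

  int_trial <- records$interference_type == "interruption" & records$interference_present
  hit(int_trial & (is.na(records$interrupter_response) |
                     records$interrupter_response == "none"),
      "interrupter_no_response")
  resp_sign <- ifelse(records$interrupter_response == "right", 1,
                      ifelse(records$interrupter_response == "left", -1, NA))
  hit(int_trial & !is.na(resp_sign) &
        resp_sign != sign(records$interference_angle),
      "interrupter_wrong_key")
  hit(int_trial & records$interrupter_rt_ms > th$interrupter_ms,
      "interrupter_rt_gt_1000")

  rejected <- !is.na(reason)
  log <- data.frame(participant_id = records$participant_id[rejected],
                    trial_index = records$trial_index[rejected],
                    reason = reason[rejected],
                    stringsAsFactors = FALSE)
  pid <- unique(records$participant_id)
  n_tot <- tapply(rep(1L, nrow(records)), records$participant_id, sum)[as.character(pid)]
  n_rej <- vapply(pid, function(p) sum(log$participant_id == p), integer(1))
  participants <- data.frame(participant_id = pid,
                             n_trials = as.integer(n_tot),
                             n_rejected = n_rej,
                             fraction_rejected = n_rej / as.integer(n_tot),
                             stringsAsFactors = FALSE)
  attr(log, "participants") <- participants
  attr(log, "rt_thresholds") <- thr
  class(log) <- c("wm_rejection_log", "data.frame")
  list(kept = records[!rejected, , drop = FALSE], log = log)
}

#' Participant-level exclusion
#'
#' Excludes participants whose fraction of rejected trials exceeds the
#' threshold (strictly greater than, default 10%).
#'
#' @param log a rejection log from [filter_trials()].
#' @param threshold maximum tolerated rejected fraction.
#' @return data.frame of per-participant summaries with an `excluded` flag;
#'   kept ids in `attr(, "kept_ids")`.
#' @export
exclude_participants <- function(log, threshold = 0.10) {
  p <- attr(log, "participants")
  if (is.null(p)) stop_invalid_input("exclude_participants: log lacks participant summary")
  p$excluded <- p$fraction_rejected > threshold
  attr(p, "kept_ids") <- p$participant_id[!p$excluded]
  p
}

#' Serialize a rejection log
#'
#' Writes the per-trial rejections as CSV and the per-participant summary as
#' JSON next to it.
#'
#' @param log rejection log from [filter_trials()].
#' @param csv_path output CSV path; the JSON summary goes to the same path
#'   with extension `.json`.
#' @return invisibly, the two paths.
#' @export
write_rejection_log <- function(log, csv_path) {
  utils::write.csv(as.data.frame(log), csv_path, row.names = FALSE, quote = FALSE)
  json_path <- sub("\\.csv$", ".json", csv_path)
  jsonlite::write_json(attr(log, "participants"), json_path,
                       dataframe = "rows", digits = NA)
  invisible(c(csv = csv_path, json = json_path))
}
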