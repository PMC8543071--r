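#' Per-trial reproduction error
#'
#' Absolute wrapped deviation between the reported orientation and the probed
#' (target) orientation, in degrees, bounded by 90.
#'
#' @param records trial data.frame with `report_angle` and `target_angle`.
#' @return numeric vector in \[0, 90\].
#' @export
reproduction_error <- function(records) {
  if (anyNA(records$report_angle))
    stop_missing_response("reproduction_error: report_angle absent on some trials")
  abs_dev(records$report_angle, records$target_angle)
}

#' Feedback score from a reproduction error
#'
#' Linear mapping of the error onto 0..100 feedback points: 100 for a perfect
#' report, 0 for a perpendicular one, rounded to the nearest integer.
#'
#' @param error reproduction error in degrees, in \[0, 90\].
#' @return integer score in \[0, 100\].
#' @export
feedback_score <- function(error) {
  if (!is.numeric(error) || anyNA(error) || any(error < 0 | error > 90))
    stop_invalid_input("feedback_score: error must lie in [0, 90]")
  as.integer(round(100 * (1 - error / 90)))
}

#' Per-participant condition means
#'
#' Aggregates reproduction error (and interrupter RT, where defined) into
#' per-participant cell means over the requested condition cells. Cells with
#' zero trials are absent from the output, never reported as zero.
#'
#' @param records filtered trial records with reports.
#' @param cells character vector of grouping columns, e.g.
#'   `c("interference_type", "predictability")`; `"onset_ms"` restricts
#'   implicitly to interference-present trials (onset is undefined otherwise).
#' @return data.frame: participant_id, cell columns, `mean_abs_error`,
#'   `n_trials`, and `mean_interrupter_rt` (NA where undefined).
#' @export
condition_means <- function(records, cells) {
  bad <- setdiff(cells, names(records))
  if (length(bad))
    stop_schema(paste("condition_means: unknown cell column(s):",
                      paste(bad, collapse = ", ")))
  r <- records
  if ("onset_ms" %in% cells) r <- r[r$interference_present, , drop = FALSE]
  r$err <- reproduction_error(r)
  key <- interaction(r[c("participant_id", cells)], drop = TRUE, lex.order = TRUE)
  first <- !duplicated(key)
  out <- r[first, c("participant_id", cells), drop = FALSE]
  out$mean_abs_error <- as.numeric(tapply(r$err, key, mean)[as.character(key[first])])
  out$n_trials <- as.integer(tapply(rep(1L, nrow(r)), key, sum)[as.character(key[first])])
  irt <- tapply(r$interrupter_rt_ms, key, function(x)
    if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE))
  out$mean_interrupter_rt <- as.numeric(irt[as.character(key[first])])
  out <- out[do.call(order, out[c("participant_id", cells)]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Paired per-participant contrast between two condition cells
#'
#' Computes value(a) - value(b) per participant, in exactly that order (e.g.
#' Interference - No Interference gives a positive interference cost;
#' Fixed - Variable gives a negative value when prediction helps).
#'
#' @param summaries output of [condition_means()].
#' @param cell column name defining the contrast (e.g. `"predictability"`).
#' @param a,b the two levels, contrast taken as a minus b.
#' @param value column to contrast (default `"mean_abs_error"`).
#' @return data.frame: participant_id, difference.
#' @export
paired_contrast <- function(summaries, cell, a, b, value = "mean_abs_error") {
  sa <- summaries[summaries[[cell]] == a, ]
  sb <- summaries[summaries[[cell]] == b, ]
  ids <- sort(unique(summaries$participant_id))
  va <- sa[[value]][match(ids, sa$participant_id)]
  vb <- sb[[value]][match(ids, sb$participant_id)]
  if (anyNA(va) || anyNA(vb))
    stop_incomplete_design("paired_contrast: some participants lack a cell")
  data.frame(participant_id = ids, difference = va - vb)
}

#' Within-subject standard error of the mean (Cousineau-Morey)
#'
#' Removes per-participant offsets before computing the per-cell SEM: each
#' participant's cell values are recentred by subtracting the participant
#' mean and adding the grand mean; the SEM of the recentred values in each
#' cell is then inflated by `sqrt(M / (M - 1))`, the small-sample correction
#' for M cells.
#'
#' @param mat numeric matrix, participants in rows, condition cells in
#'   columns; must be complete.
#' @return numeric vector of per-cell SEMs.
#' @export
within_subject_sem <- function(mat) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop_incomplete_design("within_subject_sem: matrix has missing cells")
  m <- ncol(mat)
  if (m < 2) stop_invalid_input("within_subject_sem: need at least 2 cells (Morey correction undefined for M = 1)")
  centred <- mat - rowMeans(mat) + mean(mat)
  sems <- apply(centred, 2, stats::sd) / sqrt(nrow(mat))
  sems * sqrt(m / (m - 1))
}
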