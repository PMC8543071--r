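# Moving-window response-bias analysis: demeaned signed errors binned by the
# target-interference angular difference, signed AUC integration, and a
# per-condition equated bias. Sign convention: delta = signed interference
# minus target difference, bias = demeaned signed report minus target error;
# attraction <=> matching signs.

#' Demeaned signed reproduction errors
#'
#' Signed error `signed_diff(report, target)` minus the participant's mean
#' signed error across all analyzable trials of all conditions, removing
#' general (stimulus-independent) response biases.
#'
#' @param records filtered trial records with reports.
#' @return numeric vector aligned with `records` rows.
#' @export
demean_signed_errors <- function(records) {
  e <- signed_diff(records$report_angle, records$target_angle)
  mu <- tapply(e, records$participant_id, mean)
  e - as.numeric(mu[as.character(records$participant_id)])
}

#' Moving-window bias curve
#'
#' For each window center c on the 5-degree grid spanning the 180-degree
#' periodic difference axis (centers -90, -85, ..., +85), the value is the
#' mean demeaned error over trials whose target-interference difference lies
#' within +/- width/2 of c, with circular wrap-around on the 180-degree
#' period. Adjacent windows overlap (default step 5, width 45), yielding a
#' smoothed curve. Empty windows are dropped.
#'
#' @param errors demeaned signed errors (degrees).
#' @param deltas signed interference-minus-target differences (degrees).
#' @param step grid step between window centers.
#' @param width full window width.
#' @return object of class `wm_bias_curve`: data.frame with `center`,
#'   `value`, `count`.
#' @export
compute_bias_curve <- function(errors, deltas, step = 5, width = 45) {
  keep <- !is.na(errors) & !is.na(deltas)
  errors <- errors[keep]; deltas <- deltas[keep]
  if (!length(errors)) stop_insufficient_data("compute_bias_curve: no usable trials")
  centers <- seq(-90, 90 - step, by = step)
  half <- width / 2
  vals <- counts <- numeric(length(centers))
  for (i in seq_along(centers)) {
    d <- abs_dev(deltas, centers[i])  # circular distance on the 180 period
    sel <- d <= half
    counts[i] <- sum(sel)
    vals[i] <- if (counts[i]) mean(errors[sel]) else NA_real_
  }
  out <- data.frame(center = centers, value = vals, count = counts)
  out <- out[out$count > 0, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("wm_bias_curve", "data.frame"))
}

#' Signed areas under the bias curve
#'
#' Trapezoidal integration of the bias curve separately over negative and
#' positive window centers (the 0 center, if present, contributes to
#' neither). The attraction statistic `(auc_pos - auc_neg) / 2` is positive
#' when reports are pulled toward the interfering item.
#'
#' @param curve a [compute_bias_curve()] result.
#' @return list with `auc_neg`, `auc_pos` (degree^2) and `attraction_stat`.
#' @export
integrate_auc <- function(curve) {
  trap <- function(x, y) {
    if (length(x) < 2) return(NA_real_)
    sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  }
  neg <- curve[curve$center < 0, ]
  pos <- curve[curve$center > 0, ]
  if (nrow(neg) < 2 || nrow(pos) < 2)
    stop_insufficient_data("integrate_auc: need populated bins on both sides of 0")
  auc_neg <- trap(neg$center, neg$value)
  auc_pos <- trap(pos$center, pos$value)
  list(auc_neg = auc_neg, auc_pos = auc_pos,
       attraction_stat = (auc_pos - auc_neg) / 2)
}

#' Equated per-condition response bias
#'
#' Per participant and condition: half the difference between the mean
#' demeaned error over trials with positive target-interference difference
#' and the mean over trials with negative difference. Positive values denote
#' attraction toward the interfering item. This single scalar per
#' participant x condition feeds the 2 x 2 repeated-measures ANOVA on the
#' bias magnitude.
#'
#' @param records filtered interference-present trial records.
#' @param cells condition columns (default interference type x
#'   predictability); use `character(0)` for one value per participant.
#' @return data.frame: participant_id, cells, `equated_bias`, trial counts
#'   per side.
#' @export
equated_bias <- function(records,
                         cells = c("interference_type", "predictability")) {
  usable <- !is.na(records$report_angle)
  records <- records[usable, , drop = FALSE]
  # demeaning pool: all analyzable trials of all conditions
  err_all <- demean_signed_errors(records)
  keep <- records$interference_present
  r <- records[keep, , drop = FALSE]
  err <- err_all[keep]
  delta <- signed_diff(r$interference_angle, r$target_angle)
  key <- interaction(r[c("participant_id", cells)], drop = TRUE, lex.order = TRUE)
  pieces <- split(seq_len(nrow(r)), key)
  rows <- lapply(pieces, function(idx) {
    d <- delta[idx]; e <- err[idx]
    n_pos <- sum(d > 0); n_neg <- sum(d < 0)
    if (n_pos == 0 || n_neg == 0)
      stop_insufficient_data("equated_bias: a condition cell has trials on only one side")
    cbind(r[idx[1], c("participant_id", cells), drop = FALSE],
          data.frame(equated_bias = (mean(e[d > 0]) - mean(e[d < 0])) / 2,
                     n_pos = n_pos, n_neg = n_neg))
  })
  out <- do.call(rbind, rows)
  out <- out[do.call(order, out[c("participant_id", cells)]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' One-sample attraction test
#'
#' Tests the per-participant attraction statistics against zero with a
#' two-tailed one-sample t test and reports Cohen's d (mean / SD).
#'
#' @param x one attraction statistic per participant.
#' @return list of class `wm_ttest`: t, df, p_raw, p_bonferroni (= p_raw,
#'   family of one), cohen_d.
#' @export
attraction_test <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2) stop_insufficient_data("attraction_test: need at least 2 participants")
  s <- stats::sd(x)
  if (s == 0) stop_degenerate("attraction_test: zero variance")
  t <- mean(x) / (s / sqrt(n))
  p <- 2 * stats::pt(abs(t), n - 1, lower.tail = FALSE)
  structure(list(t = t, df = n - 1, p_raw = p, p_bonferroni = p,
                 cohen_d = mean(x) / s),
            class = "wm_ttest")
}
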