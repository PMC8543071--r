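# Repeated-measures inference: fully within-subjects ANOVA with generalized
# eta squared, paired t with Cohen's d (d_z), Bonferroni adjustment, and
# exact noncentral-t power analysis for paired designs.

# Inclusion-exclusion (Yates) effect decomposition over factor subsets,
# carried per observation: the effect value of subset U at an observation is
# its U-marginal mean minus the grand mean and all lower-order effect values.
# On a balanced fully-crossed design, sum of squared per-observation effect
# values equals the classical SS for that term.
ss_decompose <- function(dv, factors) {
  stopifnot(length(dv) == nrow(factors))
  grand <- mean(dv)
  fnames <- names(factors)
  subsets <- unlist(lapply(seq_along(fnames), function(k)
    utils::combn(fnames, k, simplify = FALSE)), recursive = FALSE)
  keyof <- function(u) paste(sort(u), collapse = ":")
  eff <- list()  # per-observation effect values per subset
  ss <- stats::setNames(numeric(length(subsets)),
                        vapply(subsets, keyof, ""))
  df <- ss
  for (u in subsets) {
    key <- keyof(u)
    ik <- interaction(factors[u], drop = TRUE)
    e <- stats::ave(dv, ik) - grand
    if (length(u) > 1) {
      for (k in seq_len(length(u) - 1)) {
        for (tt in utils::combn(u, k, simplify = FALSE))
          e <- e - eff[[keyof(tt)]]
      }
    }
    eff[[key]] <- e
    ss[key] <- sum(e^2)
    df[key] <- prod(vapply(u, function(f) nlevels(factors[[f]]) - 1L, 1L))
  }
  list(ss = ss, df = df)
}

#' Fully within-subjects repeated-measures ANOVA with generalized eta squared
#'
#' Classical sums-of-squares decomposition for a balanced design with one
#' observation (a cell mean) per subject and cell, one to three within
#' factors. Each effect is tested against its own effect-by-subject
#' interaction. Generalized eta squared for a fully within design is
#' `SS_effect / (SS_effect + SS_subject + sum of all effect-by-subject SS)`.
#' No sphericity correction is applied.
#'
#' @param data long-format data.frame of per-subject cell means.
#' @param dv name of the dependent-variable column.
#' @param within character vector (length 1-3) of within-factor columns.
#' @param subject name of the subject-id column.
#' @return data.frame of class `wm_anova_table`: effect, df_num, df_den, F,
#'   p, ges.
#' @export
rm_anova <- function(data, dv, within, subject) {
  cols <- c(dv, within, subject)
  miss <- setdiff(cols, names(data))
  if (length(miss))
    stop_schema(paste("rm_anova: missing column(s):", paste(miss, collapse = ", ")))
  if (length(within) < 1 || length(within) > 3)
    stop_invalid_input("rm_anova: need 1 to 3 within factors")
  if (anyNA(data[[dv]]))
    stop_incomplete_design("rm_anova: missing DV values")
  fac <- data.frame(lapply(data[c(within, subject)], factor))
  names(fac) <- c(within, subject)
  n_subj <- nlevels(fac[[subject]])
  if (n_subj < 2) stop_insufficient_data("rm_anova: need at least 2 subjects")
  n_cells <- prod(vapply(within, function(f) nlevels(fac[[f]]), 1L))
  cnt <- table(interaction(fac, drop = FALSE))
  if (any(cnt != 1) || nrow(data) != n_subj * n_cells)
    stop_incomplete_design("rm_anova: design must be complete and balanced with one value per subject x cell")

  dec <- ss_decompose(data[[dv]], fac)
  keyof <- function(u) paste(sort(u), collapse = ":")
  effects <- unlist(lapply(seq_along(within), function(k)
    utils::combn(within, k, simplify = FALSE)), recursive = FALSE)
  ss_subj_related <- dec$ss[keyof(subject)] +
    sum(vapply(effects, function(e) dec$ss[keyof(c(e, subject))], 1))
  rows <- lapply(effects, function(e) {
    k <- keyof(e); ke <- keyof(c(e, subject))
    Fval <- (dec$ss[k] / dec$df[k]) / (dec$ss[ke] / dec$df[ke])
    data.frame(effect = paste(e, collapse = ":"),
               df_num = as.integer(dec$df[k]), df_den = as.integer(dec$df[ke]),
               F = Fval,
               p = stats::pf(Fval, dec$df[k], dec$df[ke], lower.tail = FALSE),
               ges = dec$ss[k] / (dec$ss[k] + ss_subj_related),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("wm_anova_table", "data.frame")
  out
}

#' Paired-samples t test with Cohen's d
#'
#' Two-tailed t test on paired differences; Cohen's d is the standardized
#' mean difference d_z = mean(diff) / sd(diff).
#'
#' @param x,y paired numeric vectors of equal length.
#' @param m Bonferroni family size for the adjusted p value.
#' @return list of class `wm_ttest`: t, df, p_raw, p_bonferroni, cohen_d.
#' @export
paired_t <- function(x, y, m = 1L) {
  if (length(x) != length(y))
    stop_invalid_input("paired_t: x and y must have equal length")
  d <- x - y
  n <- length(d)
  if (n < 2) stop_insufficient_data("paired_t: need at least 2 pairs")
  s <- stats::sd(d)
  if (s == 0) stop_degenerate("paired_t: zero-variance differences")
  t <- mean(d) / (s / sqrt(n))
  p <- 2 * stats::pt(abs(t), n - 1, lower.tail = FALSE)
  structure(list(t = t, df = n - 1, p_raw = p,
                 p_bonferroni = bonferroni(p, m), cohen_d = mean(d) / s),
            class = "wm_ttest")
}

#' @export
print.wm_ttest <- function(x, ...) {
  cat(sprintf("t(%d) = %.3f, p = %.4g (Bonferroni: %.4g), d = %.3f\n",
              x$df, x$t, x$p_raw, x$p_bonferroni, x$cohen_d))
  invisible(x)
}

#' Bonferroni adjustment
#'
#' @param p p values in \[0, 1\].
#' @param m family size (>= 1).
#' @return `pmin(1, p * m)`.
#' @export
bonferroni <- function(p, m) {
  if (any(p < 0 | p > 1) || m < 1)
    stop_invalid_input("bonferroni: need p in [0,1] and m >= 1")
  pmin(1, p * m)
}

#' Exact power of a paired-samples t test
#'
#' Noncentral-t power: noncentrality `d * sqrt(n)`, `n - 1` degrees of
#' freedom, rejection region from the central t at level alpha.
#'
#' @param n number of pairs (>= 2).
#' @param d standardized effect size (d_z).
#' @param alpha significance level.
#' @param tails 1 or 2.
#' @return power in \[0, 1\].
#' @export
power_paired_t <- function(n, d, alpha = 0.05, tails = 2) {
  if (n < 2 || alpha <= 0 || alpha >= 1 || !tails %in% c(1, 2))
    stop_invalid_input("power_paired_t: invalid inputs")
  df <- n - 1
  ncp <- d * sqrt(n)
  if (tails == 2) {
    crit <- stats::qt(1 - alpha / 2, df)
    stats::pt(crit, df, ncp, lower.tail = FALSE) + stats::pt(-crit, df, ncp)
  } else {
    crit <- stats::qt(1 - alpha, df)
    stats::pt(crit, df, ncp, lower.tail = FALSE)
  }
}

#' A-priori sample size for a paired-samples t test
#'
#' Smallest n whose exact noncentral-t power reaches the target.
#'
#' @param d standardized effect size (> 0).
#' @param alpha significance level.
#' @param power target power in (0, 1).
#' @param tails 1 or 2.
#' @param n_max search ceiling.
#' @return integer sample size.
#' @export
required_sample_size <- function(d, alpha = 0.05, power = 0.95, tails = 2,
                                 n_max = 1e6) {
  if (d <= 0 || power <= 0 || power >= 1)
    stop_invalid_input("required_sample_size: need d > 0 and power in (0, 1)")
  for (n in 2:n_max) {
    if (power_paired_t(n, d, alpha, tails) >= power) return(as.integer(n))
  }
  stop_invalid_input("required_sample_size: target power unattainable within n_max")
}
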