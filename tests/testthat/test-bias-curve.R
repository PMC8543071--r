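test_that("demeaning removes constant per-participant report shifts", {
  tr <- rbind(toy_trials(20, participant = 1), toy_trials(20, participant = 2))
  set.seed(81)
  tr$target_angle <- runif(40, -80, 80)
  tr$report_angle <- wrap_orientation(tr$target_angle +
                                        ifelse(tr$participant_id == 1, 3, -7))
  e <- demean_signed_errors(tr)
  expect_equal(e, rep(0, 40), tolerance = 1e-12)
  # demeaned errors sum to zero within participant by construction
  tr$report_angle <- wrap_orientation(tr$target_angle + rnorm(40, 2, 5))
  e2 <- demean_signed_errors(tr)
  expect_equal(as.numeric(tapply(e2, tr$participant_id, sum)), c(0, 0),
               tolerance = 1e-9)
})

test_that("bias curve windows span +/-22.5 degrees with circular wrap", {
  set.seed(82)
  deltas <- sample(seq(-85, 90, 5), 3000, replace = TRUE)
  # constant error: every window must average to that constant
  c1 <- compute_bias_curve(rep(4, 3000), deltas)
  expect_equal(c1$value, rep(4, nrow(c1)))
  expect_equal(c1$center, seq(-90, 85, 5))
  # adjacent windows share 8 of 9 grid offsets: counts differ by small steps
  expect_true(all(c1$count > 0))
  # wrap: a trial at delta = 90 falls in the -90-centred window
  c2 <- compute_bias_curve(c(1, 1), c(90, -88), width = 45)
  expect_true(2 %in% c2$count[c2$center == -90])
})

test_that("with a degenerate 5-degree window the curve equals raw binned means", {
  set.seed(83)
  deltas <- sample(seq(-85, 90, 5), 2000, replace = TRUE)
  errs <- rnorm(2000)
  cv <- compute_bias_curve(errs, deltas, step = 5, width = 5)
  # independent oracle: raw means per grid value, with 90 folded onto -90
  folded <- ifelse(deltas == 90, -90, deltas)
  raw <- tapply(errs, folded, mean)
  expect_equal(cv$value, as.numeric(raw[as.character(cv$center)]))
})

test_that("moving-window curve tracks the window-smoothed sinusoidal bias", {
  A <- 3
  set.seed(84)
  grid5 <- seq(-85, 90, 5)
  deltas <- sample(grid5, 40000, replace = TRUE)
  errs <- A * sin(2 * deltas * pi / 180) + rnorm(40000, 0, 6)
  cv <- compute_bias_curve(errs, deltas)
  # oracle: average the true sine over the grid deltas inside each window
  oracle <- vapply(cv$center, function(ct) {
    inside <- grid5[abs_dev(grid5, ct) <= 22.5]
    mean(A * sin(2 * inside * pi / 180))
  }, numeric(1))
  expect_gt(cor(cv$value, oracle), 0.95)
  auc <- integrate_auc(cv)
  oracle_curve <- data.frame(center = cv$center, value = oracle)
  auc_o <- integrate_auc(oracle_curve)
  expect_equal(auc$attraction_stat, auc_o$attraction_stat,
               tolerance = 0.1 * abs(auc_o$attraction_stat))
  expect_gt(auc$attraction_stat, 0)
})

test_that("AUC integration is trapezoidal, side-split, and signed as attraction", {
  centers <- seq(-90, 85, 5)
  k <- 0.05
  lin <- data.frame(center = centers, value = k * centers,
                    count = rep(10, length(centers)))
  auc <- integrate_auc(lin)
  # independent trapezoid on each side of an odd function
  trap <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  expect_equal(auc$auc_pos, trap(centers[centers > 0], k * centers[centers > 0]))
  expect_equal(auc$auc_neg, trap(centers[centers < 0], k * centers[centers < 0]))
  expect_gt(auc$auc_pos, 0)
  expect_equal(auc$auc_pos + auc$auc_neg,
               (auc$auc_pos - auc$auc_neg) - 2 * abs(auc$auc_neg),
               tolerance = 1e-9)
  expect_gt(auc$attraction_stat, 0)

  flat0 <- data.frame(center = centers, value = rep(0, length(centers)),
                      count = rep(10, length(centers)))
  a0 <- integrate_auc(flat0)
  expect_equal(c(a0$auc_neg, a0$auc_pos, a0$attraction_stat), c(0, 0, 0))
  one_sided <- lin[lin$center > 0, ]
  expect_error(integrate_auc(one_sided), class = "wm_insufficient_data")
})

test_that("equated bias is null at A = 0, positive at A > 0, and mirror-consistent", {
  coh0 <- small_cohort(n_participants = 6, seed = 85,
                       params = clean_params(bias_amplitude_A = 0, p_swap = 0))
  eq0 <- equated_bias(coh0, cells = character(0))
  expect_equal(mean(eq0$equated_bias), 0, tolerance = 0.6)

  cohA <- small_cohort(n_participants = 6, seed = 86,
                       params = clean_params(bias_amplitude_A = 2, p_swap = 0,
                                             p_guess = 0))
  eqA <- equated_bias(cohA, cells = character(0))
  # closed-form grid average of A sin(2 delta) over the positive deltas
  delta <- signed_diff(cohA$interference_angle[cohA$interference_present],
                       cohA$target_angle[cohA$interference_present])
  truth <- (mean(2 * sin(2 * delta[delta > 0] * pi / 180)) -
              mean(2 * sin(2 * delta[delta < 0] * pi / 180))) / 2
  expect_equal(mean(eqA$equated_bias), truth, tolerance = 0.35)

  # a full mirror of the world (all angles negated) leaves the bias unchanged;
  # trials at the self-conjugate boundary delta = 90 are dropped first, since
  # +90 and -90 are the same orientation but wrap to the same signed value
  d_all <- rep(0, nrow(cohA))
  pres <- cohA$interference_present
  d_all[pres] <- signed_diff(cohA$interference_angle[pres],
                             cohA$target_angle[pres])
  cohB <- cohA[!(pres & abs(d_all) == 90), ]
  eqB <- equated_bias(cohB, cells = character(0))
  mirrored <- cohB
  for (cl in c("report_angle", "target_angle", "nonprobed_angle",
               "interference_angle")) {
    v <- mirrored[[cl]]; ok <- !is.na(v)
    v[ok] <- wrap_orientation(-v[ok])
    mirrored[[cl]] <- v
  }
  eqM <- equated_bias(mirrored, cells = character(0))
  expect_equal(eqM$equated_bias, eqB$equated_bias, tolerance = 1e-9)
  # reflecting each report about its target negates every signed error
  reflected <- cohA
  reflected$report_angle <- wrap_orientation(2 * reflected$target_angle -
                                               reflected$report_angle)
  eqR <- equated_bias(reflected, cells = character(0))
  expect_equal(eqR$equated_bias, -eqA$equated_bias, tolerance = 1e-9)
  expect_gt(mean(eqA$equated_bias), 0)
})

test_that("the attraction t test behaves at the corners", {
  expect_error(attraction_test(c(1, 1, 1, 1)), class = "wm_degenerate_variance")
  expect_error(attraction_test(2), class = "wm_insufficient_data")
  t0 <- attraction_test(c(-1, 1, -2, 2))
  expect_equal(t0$t, 0)
  expect_equal(t0$p_raw, 1)
  set.seed(87)
  x <- rnorm(20, 1, 1)
  tt <- attraction_test(x)
  ref <- t.test(x)                         # base-R oracle
  expect_equal(tt$t, unname(ref$statistic))
  expect_equal(tt$p_raw, ref$p.value)
  expect_equal(tt$cohen_d, mean(x) / sd(x))
})

test_that("cohort bias curve is invariant to per-participant constant report shifts", {
  # p_guess = 0 keeps every signed error small, so adding a small constant
  # never wraps past +/-90 and the shift is exactly constant in signed-error
  # space (wrapping would break constancy for near-perpendicular errors)
  coh <- small_cohort(n_participants = 4, seed = 88,
                      params = clean_params(bias_amplitude_A = 2, p_swap = 0,
                                            p_guess = 0))
  shift <- c(0, 4, -3, 7)[match(coh$participant_id, 1:4)]
  shifted <- coh
  shifted$report_angle <- wrap_orientation(coh$report_angle + shift)
  curve_of <- function(x) {
    e <- demean_signed_errors(x)[x$interference_present]
    d <- signed_diff(x$interference_angle[x$interference_present],
                     x$target_angle[x$interference_present])
    compute_bias_curve(e, d)
  }
  expect_equal(curve_of(shifted)$value, curve_of(coh)$value, tolerance = 1e-9)
})
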