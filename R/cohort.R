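#' Design specification for a synthetic cohort
#'
#' Encodes the factorial block design of the task: 12 blocks of 32 trials per
#' participant; within each block 75% of trials carry an interfering item
#' presented 500, 1250 or 2000 ms after encoding onset; blocks cross
#' interference type (distraction vs. interruption, 6 blocks each) with
#' temporal predictability (fixed vs. variable onset, 6 blocks each);
#' orientations are drawn from a 5-degree grid spanning +/-5 to +/-85 so that
#' no bar is ever vertical or horizontal.
#'
#' @param n_participants number of simulated participants.
#' @param n_blocks blocks per participant; must equal `4 * length(onsets_ms)`
#'   so that each interference type has one fixed-onset block per onset plus
#'   an equal number of variable-onset blocks.
#' @param trials_per_block trials in each block.
#' @param interference_proportion fraction of trials per block carrying an
#'   interfering item; `trials_per_block * interference_proportion` must be an
#'   integer divisible by `length(onsets_ms)` and even (tilt counterbalancing).
#' @param onsets_ms possible interference onsets (ms after encoding onset).
#' @param angle_grid permitted orientations in degrees.
#' @param delay_ms retention delay (metadata only).
#' @param interference_duration_ms interfering-item duration (metadata only).
#' @param rng_seed master seed; per-participant streams are derived from it.
#' @return object of class `wm_design_spec`.
#' @export
design_spec <- function(n_participants = 54L,
                        n_blocks = 12L,
                        trials_per_block = 32L,
                        interference_proportion = 0.75,
                        onsets_ms = c(500L, 1250L, 2000L),
                        angle_grid = c(-seq(85, 5, by = -5), seq(5, 85, by = 5)),
                        delay_ms = 2750L,
                        interference_duration_ms = 250L,
                        rng_seed = 1L) {
  spec <- structure(list(
    n_participants = as.integer(n_participants),
    n_blocks = as.integer(n_blocks),
    trials_per_block = as.integer(trials_per_block),
    interference_proportion = interference_proportion,
    onsets_ms = as.integer(onsets_ms),
    angle_grid = as.numeric(angle_grid),
    delay_ms = as.integer(delay_ms),
    interference_duration_ms = as.integer(interference_duration_ms),
    rng_seed = as.integer(rng_seed)
  ), class = "wm_design_spec")
  validate_design_spec(spec)
  spec
}

validate_design_spec <- function(spec) {
  n_int <- spec$trials_per_block * spec$interference_proportion
  if (spec$n_participants < 1L)
    stop_configuration("design_spec: need at least one participant")
  if (abs(n_int - round(n_int)) > 1e-9)
    stop_configuration("design_spec: trials_per_block * interference_proportion must be an integer")
  n_int <- as.integer(round(n_int))
  k <- length(spec$onsets_ms)
  if (k < 1L) stop_configuration("design_spec: need at least one onset")
  if (spec$n_blocks != 4L * k)
    stop_configuration(sprintf(
      "design_spec: n_blocks must be 4 * length(onsets_ms) = %d", 4L * k))
  if (n_int %% k != 0L)
    stop_configuration("design_spec: interference trials per block must divide evenly across onsets")
  if (n_int %% 2L != 0L)
    stop_configuration("design_spec: interference trials per block must be even (tilt counterbalancing)")
  if (any(spec$angle_grid == 0) || any(abs(spec$angle_grid) > 90))
    stop_configuration("design_spec: angle grid must avoid 0 and stay within +/-90")
  if (!any(spec$angle_grid > 0) || !any(spec$angle_grid < 0))
    stop_configuration("design_spec: angle grid needs both tilt directions")
  invisible(spec)
}

#' Generative parameters for simulated responses
#'
#' The response model mirrors the analysis model: with probability `p_guess`
#' the report is uniform on the orientation space; otherwise, on interference
#' trials, with probability `p_swap` it is centred on the interfering item's
#' orientation (a swap); otherwise it is centred on the target orientation
#' shifted by the attraction bias `A * sin(2 * delta * pi / 180)` where
#' `delta` is the signed interference-minus-target difference. Angular noise
#' is von Mises on the doubled circle with concentration `kappa_base`,
#' deflated multiplicatively in interruption and variable-onset blocks
#' (concentration deflation raises mean absolute error monotonically, which
#' reproduces the qualitative condition effects without committing to a
#' mechanism).
#'
#' Reaction times are shifted lognormal. Interrupter RTs receive additive
#' offsets on the lognormal location: a speed-up in fixed-onset blocks (the
#' onset is known) and a foreperiod effect in variable-onset blocks (faster
#' at later onsets as hazard accumulates).
#'
#' Contamination rates inject trials that each violate exactly one exclusion
#' rule, exercising the preprocessing module. Defaults are chosen to retain
#' roughly 94% of trials after filtering, matching a realistic online cohort.
#'
#' @param kappa_base concentration of report noise on the doubled circle.
#' @param p_swap probability of reporting the interfering item (conditional
#'   on not guessing; interference trials only).
#' @param p_guess probability of a uniform guess.
#' @param bias_amplitude_A attraction amplitude in degrees (peak of the
#'   sinusoidal pull at a 45-degree target-interference difference).
#' @param kappa_factor_interruption,kappa_factor_variable multiplicative
#'   concentration deflation (< 1 worsens performance) applied in
#'   interruption and variable-onset blocks respectively.
#' @param rt_probe_params,rt_dial_params,rt_interrupter_params shifted
#'   lognormal parameters `list(shift, meanlog, sdlog)`; the interrupter set
#'   additionally takes `fixed_advantage` (meanlog offset in fixed-onset
#'   blocks) and `onset_slope` (meanlog offset per step of onset position
#'   under variable onset; negative = foreperiod speed-up).
#' @param contamination_rates named list of per-trial contamination
#'   probabilities: `slow_probe_rt`, `slow_dial`, `distractor_keypress`,
#'   `interrupter_miss`, `interrupter_wrong_key`, `interrupter_slow`.
#' @return object of class `wm_generative_params`.
#' @export
generative_params <- function(kappa_base = 12,
                              p_swap = 0.05,
                              p_guess = 0.10,
                              bias_amplitude_A = 2,
                              kappa_factor_interruption = 0.75,
                              kappa_factor_variable = 0.90,
                              rt_probe_params = list(shift = 300, meanlog = log(600), sdlog = 0.45),
                              rt_dial_params = list(shift = 500, meanlog = log(1400), sdlog = 0.30),
                              rt_interrupter_params = list(shift = 150, meanlog = log(350),
                                                           sdlog = 0.25, fixed_advantage = -0.08,
                                                           onset_slope = -0.06),
                              contamination_rates = list(slow_probe_rt = 0.010,
                                                         slow_dial = 0.010,
                                                         distractor_keypress = 0.020,
                                                         interrupter_miss = 0.010,
                                                         interrupter_wrong_key = 0.020,
                                                         interrupter_slow = 0.010)) {
  p <- structure(list(
    kappa_base = kappa_base, p_swap = p_swap, p_guess = p_guess,
    bias_amplitude_A = bias_amplitude_A,
    kappa_factor_interruption = kappa_factor_interruption,
    kappa_factor_variable = kappa_factor_variable,
    rt_probe_params = rt_probe_params,
    rt_dial_params = rt_dial_params,
    rt_interrupter_params = rt_interrupter_params,
    contamination_rates = contamination_rates
  ), class = "wm_generative_params")
  validate_generative_params(p)
  p
}

validate_generative_params <- function(p) {
  rates <- unlist(p$contamination_rates)
  if (p$kappa_base <= 0) stop_configuration("generative_params: kappa_base must be > 0")
  if (p$p_swap < 0 || p$p_guess < 0 || p$p_swap + p$p_guess > 1)
    stop_configuration("generative_params: need p_swap, p_guess >= 0 and p_swap + p_guess <= 1")
  if (any(rates < 0) || any(rates > 1))
    stop_configuration("generative_params: contamination rates must lie in [0, 1]")
  if (!is.finite(p$bias_amplitude_A))
    stop_configuration("generative_params: bias amplitude must be finite")
  invisible(p)
}

# Deterministic per-participant seed stream. Double-precision arithmetic with
# an intermediate modulus keeps every product below 2^53, so the derivation is
# exact and stable across platforms.
participant_seed <- function(master_seed, participant_id) {
  m <- 2147483647  # 2^31 - 1
  s <- (as.numeric(master_seed) %% m) * 40503 %% m
  as.integer((s + as.numeric(participant_id) * 65537 + 11) %% m)
}

trial_columns <- c("participant_id", "block_index", "trial_index",
                   "interference_type", "predictability", "interference_present",
                   "onset_ms", "target_angle", "nonprobed_angle",
                   "interference_angle", "probed_side", "report_angle",
                   "probe_rt_ms", "dial_time_ms", "interrupter_response",
                   "interrupter_rt_ms", "distractor_keypress")

#' Build the trial schedule (stimulus fields) for one participant
#'
#' Produces the pseudo-randomised block order and per-trial stimulus layout:
#' blocks come in pairs sharing temporal predictability, with both
#' interference types inside each pair in random order and fixed/variable
#' pairs alternating (which kind leads alternates across participants via the
#' participant's random stream). Each interference type receives one
#' fixed-onset block per onset, in random order. Within a block, interference
#' trials split equally across onsets when variable, interfering-item tilt
#' direction is counterbalanced, and every encoding display carries one
#' leftward- and one rightward-tilted bar. The probed screen side is
#' counterbalanced within participant.
#'
#' @param spec a [design_spec()].
#' @param participant_id integer id; also seeds this participant's stream.
#' @return data.frame of trial records with stimulus fields populated and all
#'   response fields `NA`.
#' @export
build_schedule <- function(spec, participant_id) {
  validate_design_spec(spec)
  seed <- participant_seed(spec$rng_seed, participant_id)
  withr_seed(seed, build_schedule_impl(spec, participant_id))
}

# run expr under a local RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

build_schedule_impl <- function(spec, participant_id) {
  k <- length(spec$onsets_ms)
  n_pairs <- spec$n_blocks / 2L
  # alternating predictability pairs; leading kind randomized per participant
  lead_fixed <- stats::runif(1) < 0.5
  pair_pred <- rep(if (lead_fixed) c("fixed", "variable") else c("variable", "fixed"),
                   length.out = n_pairs)
  # one fixed-onset block per onset per interference type, order randomized
  fixed_onsets <- list(distraction = sample(spec$onsets_ms),
                       interruption = sample(spec$onsets_ms))
  fixed_count <- c(distraction = 0L, interruption = 0L)

  n_trials <- spec$n_blocks * spec$trials_per_block
  n_int_per_block <- as.integer(round(spec$trials_per_block * spec$interference_proportion))

  # probed screen side counterbalanced within participant
  side_pool <- sample(rep(c("left", "right"), length.out = n_trials))

  rows <- vector("list", spec$n_blocks)
  block_i <- 0L
  for (pair in seq_len(n_pairs)) {
    types <- sample(c("distraction", "interruption"))
    for (ty in types) {
      block_i <- block_i + 1L
      pred <- pair_pred[pair]
      if (pred == "fixed") {
        fixed_count[[ty]] <- fixed_count[[ty]] + 1L
        block_onset <- fixed_onsets[[ty]][fixed_count[[ty]]]
      } else block_onset <- NA_integer_

      present <- sample(rep(c(TRUE, FALSE),
                            c(n_int_per_block, spec$trials_per_block - n_int_per_block)))
      onset <- rep(NA_integer_, spec$trials_per_block)
      if (pred == "fixed") {
        onset[present] <- block_onset
      } else {
        onset[present] <- sample(rep(spec$onsets_ms, each = n_int_per_block %/% k))
      }
      # one leftward + one rightward bar per display; probed one is 'target'
      pos_grid <- spec$angle_grid[spec$angle_grid > 0]
      neg_grid <- spec$angle_grid[spec$angle_grid < 0]
      target_sign <- sample(c(-1, 1), spec$trials_per_block, replace = TRUE)
      target <- ifelse(target_sign > 0,
                       sample(pos_grid, spec$trials_per_block, replace = TRUE),
                       sample(neg_grid, spec$trials_per_block, replace = TRUE))
      nonprobed <- ifelse(target_sign > 0,
                          sample(neg_grid, spec$trials_per_block, replace = TRUE),
                          sample(pos_grid, spec$trials_per_block, replace = TRUE))
      # interfering tilt counterbalanced within block
      int_sign <- sample(rep(c(-1, 1), length.out = n_int_per_block))
      interference <- rep(NA_real_, spec$trials_per_block)
      interference[present] <- ifelse(int_sign > 0,
                                      sample(pos_grid, n_int_per_block, replace = TRUE),
                                      sample(neg_grid, n_int_per_block, replace = TRUE))
      idx0 <- (block_i - 1L) * spec$trials_per_block
      rows[[block_i]] <- data.frame(
        participant_id = participant_id,
        block_index = block_i,
        trial_index = idx0 + seq_len(spec$trials_per_block),
        interference_type = ty,
        predictability = pred,
        interference_present = present,
        onset_ms = onset,
        target_angle = target,
        nonprobed_angle = nonprobed,
        interference_angle = interference,
        probed_side = side_pool[idx0 + seq_len(spec$trials_per_block)],
        report_angle = NA_real_,
        probe_rt_ms = NA_real_,
        dial_time_ms = NA_real_,
        interrupter_response = NA_character_,
        interrupter_rt_ms = NA_real_,
        distractor_keypress = NA,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Sample from a von Mises distribution (Best-Fisher rejection algorithm)
#'
#' @param n number of draws.
#' @param mu mean direction in radians.
#' @param kappa concentration (>= 0); `kappa ~ 0` degenerates to uniform.
#' @return radians in \[-pi, pi).
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (n == 0L) return(numeric(0))
  if (kappa < 1e-8) return(((stats::runif(n, -pi, pi) + mu + pi) %% (2 * pi)) - pi)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  filled <- 0L
  while (filled < n) {
    m <- n - filled
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    if (any(ok)) {
      theta <- sign(u3[ok] - 0.5) * acos(pmin(1, pmax(-1, f[ok])))
      take <- length(theta)
      out[(filled + 1L):(filled + take)] <- theta
      filled <- filled + take
    }
  }
  ((out + mu + pi) %% (2 * pi)) - pi
}

# Draw orientation reports for vectors of targets/non-targets under the
# mixture + bias generative model. kappa may be scalar or per-trial.
# Used both by simulate_responses() and directly by the recovery harness.
simulate_reports <- function(targets, nontargets, params, kappa = params$kappa_base) {
  n <- length(targets)
  kappa <- rep(kappa, length.out = n)
  has_nt <- !is.na(nontargets)
  u <- stats::runif(n)
  guess <- u < params$p_guess
  u2 <- stats::runif(n)
  swap <- !guess & has_nt & u2 < params$p_swap
  delta <- rep(0, n)
  delta[has_nt] <- signed_diff(nontargets[has_nt], targets[has_nt])
  bias <- params$bias_amplitude_A * sin(2 * delta * pi / 180)
  centre <- ifelse(swap, nontargets, targets + ifelse(has_nt, bias, 0))
  report <- numeric(n)
  for (kv in unique(kappa)) {
    sel <- which(kappa == kv & !guess)
    if (length(sel))
      report[sel] <- centre[sel] + rvonmises(length(sel), 0, kv) * 90 / pi
  }
  report[guess] <- stats::runif(sum(guess), -90, 90)
  wrap_orientation(report)
}

rshifted_lnorm <- function(n, p, meanlog_offset = 0) {
  p$shift + stats::rlnorm(n, p$meanlog + meanlog_offset, p$sdlog)
}

#' Simulate behavioral responses for a trial schedule
#'
#' Fills in report angles, reaction times, interrupter responses and
#' contaminant trials for a schedule produced by [build_schedule()], under
#' the generative model described in [generative_params()]. Each contaminant
#' type violates exactly one preprocessing exclusion rule. Deterministic
#' given (schedule, params, seed).
#'
#' @param schedule data.frame from [build_schedule()] (one participant or a
#'   whole cohort; rows are processed as given).
#' @param params a [generative_params()].
#' @param seed integer seed for the response stream.
#' @return the schedule with all response fields populated.
#' @export
simulate_responses <- function(schedule, params, seed = 1L) {
  validate_generative_params(params)
  if (params$p_swap > 0 && !any(schedule$interference_present))
    stop_configuration("simulate_responses: p_swap > 0 but schedule has no interference trials")
  withr_seed(seed, simulate_responses_impl(schedule, params))
}

simulate_responses_impl <- function(schedule, params) {
  n <- nrow(schedule)
  s <- schedule
  interruption <- s$interference_type == "interruption"
  variable <- s$predictability == "variable"
  kappa <- params$kappa_base *
    ifelse(interruption, params$kappa_factor_interruption, 1) *
    ifelse(variable, params$kappa_factor_variable, 1)

  nts <- ifelse(s$interference_present, s$interference_angle, NA_real_)
  s$report_angle <- simulate_reports(s$target_angle, nts, params, kappa)

  s$probe_rt_ms <- rshifted_lnorm(n, params$rt_probe_params)
  s$dial_time_ms <- rshifted_lnorm(n, params$rt_dial_params)

  # interrupter response: correct key at the interfering item's tilt sign
  int_trial <- interruption & s$interference_present
  rtp <- params$rt_interrupter_params
  onset_pos <- match(s$onset_ms, sort(unique(s$onset_ms[!is.na(s$onset_ms)])))
  offs <- ifelse(variable, rtp$onset_slope * (onset_pos - 1),
                 rtp$fixed_advantage)
  offs[is.na(offs)] <- 0
  irt <- rshifted_lnorm(n, rtp, meanlog_offset = offs)
  s$interrupter_rt_ms[int_trial] <- pmin(irt[int_trial], 995)
  s$interrupter_response[int_trial] <-
    ifelse(s$interference_angle[int_trial] > 0, "right", "left")
  s$distractor_keypress[s$interference_type == "distraction"] <- FALSE

  # contaminants: at most one per trial, first applicable type wins
  cr <- params$contamination_rates
  u <- stats::runif(n)
  assign_contaminant <- function(u, eligible_rates) {
    cum <- cumsum(unlist(eligible_rates))
    idx <- findInterval(u, c(0, cum), left.open = TRUE)
    out <- rep(NA_character_, length(u))
    hit <- idx >= 1 & idx <= length(eligible_rates)
    out[hit] <- names(eligible_rates)[idx[hit]]
    out
  }
  distr_int <- s$interference_type == "distraction" & s$interference_present
  kinds <- rep(NA_character_, n)
  common <- c(slow_probe_rt = cr$slow_probe_rt, slow_dial = cr$slow_dial)
  kinds[!int_trial & !distr_int] <- assign_contaminant(u[!int_trial & !distr_int], common)
  kinds[distr_int] <- assign_contaminant(
    u[distr_int], c(common, distractor_keypress = cr$distractor_keypress))
  kinds[int_trial] <- assign_contaminant(
    u[int_trial], c(common,
                    interrupter_miss = cr$interrupter_miss,
                    interrupter_wrong_key = cr$interrupter_wrong_key,
                    interrupter_slow = cr$interrupter_slow))

  slow_p <- which(kinds == "slow_probe_rt")
  s$probe_rt_ms[slow_p] <- 5001 + stats::rexp(length(slow_p), 1 / 800)
  slow_d <- which(kinds == "slow_dial")
  s$dial_time_ms[slow_d] <- 4001 + stats::rexp(length(slow_d), 1 / 500)
  s$distractor_keypress[which(kinds == "distractor_keypress")] <- TRUE
  miss <- which(kinds == "interrupter_miss")
  s$interrupter_response[miss] <- "none"
  s$interrupter_rt_ms[miss] <- NA_real_
  wrong <- which(kinds == "interrupter_wrong_key")
  s$interrupter_response[wrong] <-
    ifelse(s$interference_angle[wrong] > 0, "left", "right")
  slow_i <- which(kinds == "interrupter_slow")
  s$interrupter_rt_ms[slow_i] <- 1001 + stats::runif(length(slow_i), 0, 400)
  s
}

#' Simulate a full cohort
#'
#' Builds the schedule and simulates responses for every participant, using
#' per-participant seed streams derived from the master seed so the cohort is
#' reproducible piecewise.
#'
#' @param spec a [design_spec()].
#' @param params a [generative_params()].
#' @return data.frame of complete trial records for all participants.
#' @export
simulate_cohort <- function(spec, params = generative_params()) {
  recs <- lapply(seq_len(spec$n_participants), function(p) {
    sched <- build_schedule(spec, p)
    simulate_responses(sched, params,
                       seed = participant_seed(spec$rng_seed + 104729, p))
  })
  do.call(rbind, recs)
}

#' Write / read a cohort in the trial CSV dialect
#'
#' UTF-8 comma-separated, header row, one trial per row, with the columns
#' `participant_id, block_index, trial_index, interference_type,
#' predictability, interference_present, onset_ms, target_angle,
#' nonprobed_angle, interference_angle, probed_side, report_angle,
#' probe_rt_ms, dial_time_ms, interrupter_response, interrupter_rt_ms,
#' distractor_keypress`. Empty cells denote absent values; the round trip is
#' lossless.
#'
#' @param records trial data.frame.
#' @param path file path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns the
#'   records.
#' @export
write_cohort <- function(records, path) {
  missing_cols <- setdiff(trial_columns, names(records))
  if (length(missing_cols))
    stop_schema(paste("write_cohort: missing columns:",
                      paste(missing_cols, collapse = ", ")))
  out <- records[, trial_columns]
  out$interference_present <- ifelse(out$interference_present, "true", "false")
  out$distractor_keypress <- ifelse(is.na(out$distractor_keypress), "",
                                    ifelse(out$distractor_keypress, "true", "false"))
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop_io(paste("read_cohort: no such file:", path))
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                    fileEncoding = "UTF-8"),
    error = function(e) stop_parse(paste("read_cohort:", conditionMessage(e))))
  missing_cols <- setdiff(trial_columns, names(df))
  if (length(missing_cols))
    stop_parse(paste("read_cohort: missing required column(s):",
                     paste(missing_cols, collapse = ", ")))
  df <- df[, trial_columns]
  to_logical <- function(x, col) {
    out <- rep(NA, length(x))
    out[x %in% "true"] <- TRUE
    out[x %in% "false"] <- FALSE
    bad <- which(!is.na(x) & !x %in% c("true", "false"))
    if (length(bad))
      stop_parse(sprintf("read_cohort: row %d: bad logical value '%s' in %s",
                         bad[1], x[bad[1]], col))
    out
  }
  df$interference_present <- to_logical(as.character(df$interference_present),
                                        "interference_present")
  if (anyNA(df$interference_present))
    stop_parse(sprintf("read_cohort: row %d: interference_present must be true/false",
                       which(is.na(df$interference_present))[1]))
  df$distractor_keypress <- to_logical(as.character(df$distractor_keypress),
                                       "distractor_keypress")
  num_cols <- c("block_index", "trial_index", "onset_ms", "target_angle",
                "nonprobed_angle", "interference_angle", "report_angle",
                "probe_rt_ms", "dial_time_ms", "interrupter_rt_ms")
  for (cl in num_cols) {
    x <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(!is.na(df[[cl]]) & is.na(x))
    if (length(bad))
      stop_parse(sprintf("read_cohort: row %d: non-numeric value in %s", bad[1], cl))
    df[[cl]] <- x
  }
  df$interrupter_response <- as.character(df$interrupter_response)
  df
}
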