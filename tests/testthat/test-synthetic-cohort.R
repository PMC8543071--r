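test_that("default schedule reproduces the factorial design counts", {
  spec <- design_spec(n_participants = 1, rng_seed = 3)
  s <- build_schedule(spec, 1)
  expect_equal(nrow(s), 384)
  expect_equal(sum(s$interference_present), 288)
  expect_equal(unname(table(s$block_index)), rep(32L, 12), ignore_attr = TRUE)
  # 75% interference within every block
  per_block <- tapply(s$interference_present, s$block_index, sum)
  expect_true(all(per_block == 24))
  # 6 blocks per interference type, 6 per predictability, crossed 3/3
  expect_equal(unname(table(s$interference_type[!duplicated(s$block_index)])),
               c(6L, 6L), ignore_attr = TRUE)
  blk <- s[!duplicated(s$block_index), ]
  expect_equal(unname(table(blk$interference_type, blk$predictability)),
               matrix(3L, 2, 2), ignore_attr = TRUE)
})

test_that("per-onset interference counts are equal between fixed and pooled variable blocks", {
  s <- build_schedule(design_spec(n_participants = 1, rng_seed = 8), 1)
  for (ty in c("distraction", "interruption")) {
    f <- s[s$interference_type == ty & s$predictability == "fixed" &
             s$interference_present, ]
    v <- s[s$interference_type == ty & s$predictability == "variable" &
             s$interference_present, ]
    expect_equal(unname(table(f$onset_ms)), rep(24L, 3), ignore_attr = TRUE)
    expect_equal(unname(table(v$onset_ms)), rep(24L, 3), ignore_attr = TRUE)
    # each fixed-onset block uses exactly one onset, each onset once
    expect_equal(sort(as.numeric(unique(tapply(f$onset_ms, f$block_index, unique)))),
                 c(500, 1250, 2000))
  }
})

test_that("block ordering nests interference types within same-predictability pairs", {
  for (p in 1:5) {
    s <- build_schedule(design_spec(n_participants = 5, rng_seed = 21), p)
    blk <- s[!duplicated(s$block_index), ]
    pair <- (blk$block_index + 1) %/% 2
    for (pr in split(blk, pair)) {
      expect_equal(length(unique(pr$predictability)), 1L)
      expect_setequal(pr$interference_type, c("distraction", "interruption"))
    }
  }
})

test_that("displays carry one leftward and one rightward bar; tilt and side counterbalanced", {
  s <- build_schedule(design_spec(n_participants = 1, rng_seed = 5), 1)
  expect_true(all(sign(s$target_angle) != sign(s$nonprobed_angle)))
  expect_true(all(s$target_angle %in% c(-seq(5, 85, 5), seq(5, 85, 5))))
  # interfering tilt counterbalanced within block
  int_sign <- tapply(sign(s$interference_angle[s$interference_present]),
                     s$block_index[s$interference_present], sum)
  expect_true(all(int_sign == 0))
  # probed side counterbalanced within participant
  expect_equal(sum(s$probed_side == "left"), 192)
})

test_that("schedules are deterministic per (spec, participant) and differ across participants", {
  spec <- design_spec(n_participants = 3, rng_seed = 13)
  a <- build_schedule(spec, 1)
  b <- build_schedule(spec, 1)
  c <- build_schedule(spec, 2)
  expect_identical(a, b)
  expect_false(identical(a$target_angle, c$target_angle))
})

test_that("invalid design specs are rejected", {
  expect_error(design_spec(interference_proportion = 0.7),
               class = "wm_configuration_error")
  expect_error(design_spec(n_blocks = 10), class = "wm_configuration_error")
  expect_error(design_spec(angle_grid = c(-10, 0, 10)),
               class = "wm_configuration_error")
})

test_that("noise-free limit reproduces the target on every trial", {
  s <- build_schedule(design_spec(n_participants = 1, rng_seed = 2), 1)
  r <- simulate_responses(s, clean_params(kappa_base = 1e6, p_swap = 0,
                                          p_guess = 0, bias_amplitude_A = 0),
                          seed = 4)
  expect_true(all(abs_dev(r$report_angle, r$target_angle) < 0.5))
})

test_that("pure guessing drives mean absolute error to 45 degrees", {
  spec <- design_spec(n_participants = 5, rng_seed = 6)
  coh <- simulate_cohort(spec, clean_params(p_guess = 1, p_swap = 0))
  err <- abs_dev(coh$report_angle, coh$target_angle)
  expect_equal(mean(err), 45, tolerance = 2.5)  # n = 1920, SE ~ 0.6
})

test_that("attraction bias is absent at A = 0 and signed correctly at A > 0", {
  s <- do.call(rbind, lapply(1:6, function(p)
    build_schedule(design_spec(n_participants = 6, rng_seed = 31), p)))
  pres <- s$interference_present
  delta <- rep(NA_real_, nrow(s))
  delta[pres] <- signed_diff(s$interference_angle[pres], s$target_angle[pres])
  r0 <- simulate_responses(s, clean_params(bias_amplitude_A = 0, p_swap = 0,
                                           p_guess = 0), seed = 41)
  e0 <- signed_diff(r0$report_angle, r0$target_angle)
  expect_equal(mean(e0[pres & delta > 0]), 0, tolerance = 0.5)
  expect_equal(mean(e0[pres & delta < 0]), 0, tolerance = 0.5)
  rA <- simulate_responses(s, clean_params(bias_amplitude_A = 3, p_swap = 0,
                                           p_guess = 0), seed = 41)
  eA <- signed_diff(rA$report_angle, rA$target_angle)
  expect_gt(mean(eA[pres & delta > 0]), 0.5)
  expect_lt(mean(eA[pres & delta < 0]), -0.5)
})

test_that("contaminant injection hits the configured overall rate", {
  rates <- list(slow_probe_rt = 0.02, slow_dial = 0.02,
                distractor_keypress = 0.04, interrupter_miss = 0.02,
                interrupter_wrong_key = 0.02, interrupter_slow = 0.02)
  coh <- simulate_cohort(design_spec(n_participants = 6, rng_seed = 17),
                         generative_params(contamination_rates = rates))
  flt <- filter_trials(coh)
  # expected: common 4% everywhere; distraction-interference +4%; interruption
  # interference +6%; plus the 2.5-SD RT rule catching honest slow tails.
  frac <- nrow(flt$log) / nrow(coh)
  expect_gt(frac, 0.05)
  expect_lt(frac, 0.10)
  kp <- table(flt$log$reason)[["distractor_keypress"]]
  n_elig <- sum(coh$interference_type == "distraction" & coh$interference_present)
  expect_equal(kp / n_elig, 0.04,
               tolerance = 3 * sqrt(0.04 * 0.96 / n_elig) / 0.04)
})

test_that("simulation flags a swap request on a schedule without interference", {
  spec <- design_spec(n_participants = 1, interference_proportion = 0,
                      rng_seed = 2)
  s <- build_schedule(spec, 1)
  expect_error(simulate_responses(s, generative_params(p_swap = 0.1)),
               class = "wm_configuration_error")
  expect_silent(r <- simulate_responses(s, clean_params(p_swap = 0), seed = 1))
})

test_that("cohort CSV round-trips losslessly and validates its schema", {
  coh <- small_cohort(n_participants = 2, seed = 23,
                      params = generative_params())  # includes contaminants/NAs
  path <- tempfile(fileext = ".csv")
  write_cohort(coh, path)
  back <- read_cohort(path)
  rownames(coh) <- rownames(back) <- NULL
  expect_equal(back, coh, tolerance = 1e-12)

  # absent fields serialized as empty cells and read back as absent
  expect_true(anyNA(back$interference_angle))
  expect_identical(is.na(back$interference_angle), is.na(coh$interference_angle))

  txt <- readLines(path)
  bad <- tempfile(fileext = ".csv")
  writeLines(sub("interference_angle", "wrong_name", txt), bad)
  err <- tryCatch(read_cohort(bad), condition = function(c) c)
  expect_s3_class(err, "wm_parse_error")
  expect_match(conditionMessage(err), "interference_angle")
})
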