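# Shared fixtures, built in code.

no_contamination <- function() {
  list(slow_probe_rt = 0, slow_dial = 0, distractor_keypress = 0,
       interrupter_miss = 0, interrupter_wrong_key = 0, interrupter_slow = 0)
}

clean_params <- function(...) {
  generative_params(..., contamination_rates = no_contamination())
}

# minimal hand-built trial records; defaults are a clean distraction trial
toy_trials <- function(n, probe_rt = 500, dial = 1000, type = "distraction",
                       present = TRUE, participant = 1L) {
  data.frame(
    participant_id = participant,
    block_index = 1L,
    trial_index = seq_len(n),
    interference_type = type,
    predictability = "fixed",
    interference_present = present,
    onset_ms = ifelse(present, 500, NA_real_),
    target_angle = 30, nonprobed_angle = -30,
    interference_angle = ifelse(present, 45, NA_real_),
    probed_side = "left",
    report_angle = 30,
    probe_rt_ms = rep_len(probe_rt, n),
    dial_time_ms = rep_len(dial, n),
    interrupter_response = if (type == "interruption") "right" else NA_character_,
    interrupter_rt_ms = if (type == "interruption") 400 else NA_real_,
    distractor_keypress = if (type == "distraction") FALSE else NA,
    stringsAsFactors = FALSE
  )
}

# small simulated cohort used by several suites
small_cohort <- function(n_participants = 4, seed = 11, params = clean_params()) {
  simulate_cohort(design_spec(n_participants = n_participants, rng_seed = seed),
                  params)
}
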