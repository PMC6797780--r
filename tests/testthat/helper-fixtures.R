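# Shared fixtures: cheap observers (no calibration solve) and hand-built
# trial tables.

test_grid <- function(d = 1.5) {
  matrix(d, 3, 3, dimnames = list(snr = c(2, 3, 4), contrast = c(40, 60, 80)))
}

test_observer <- function(...) {
  observer_params(sensitivity_grid = default_sensitivity_grid(), ...)
}

# An observer whose confidence readout and wagering are noiseless, with no
# reward (so every trial is a wager trial): the ideal metacognitive wagerer.
ideal_observer <- function(d = 1.5) {
  observer_params(sensitivity_grid = test_grid(d),
                  confidence_noise_sd = 0, wait_noise_sd = 0,
                  wait_intercept_a = 6, wait_slope_b = 9,
                  rt_lapse_prob = 0, reinit_prob = 1)
}

no_reward <- function() reward_schedule_params(p_reward_given_correct = 0)

# Minimal valid trial row(s); override any column.
make_trials <- function(n = 1, ...) {
  out <- tibble::tibble(
    rat_id = rep("r1", n), session_id = "s1", trial_index = seq_len(n) - 1L,
    phase = "discrimination", region = "none", virus = "none", drug = "none",
    confidence_group = "none", snr = 3L, contrast = 60L,
    stimulus = rep(c("H", "V"), length.out = n),
    choice = rep(c("left", "right"), length.out = n),
    correct = TRUE, reward_scheduled = FALSE, reward_delay_s = NA_real_,
    rewarded = FALSE, reaction_time_s = 1.0, waiting_time_s = 10,
    reinitiated = TRUE
  )
  over <- list(...)
  for (nm in names(over)) out[[nm]] <- over[[nm]]
  out
}

# Hand-built reversal session from a sequence of applied rules (TRUE =
# correct rule) and rewards; stimulus fixed H so choice encodes the rule.
rule_sequence_trials <- function(rule_correct, rewarded = rep(FALSE, length(rule_correct)),
                                 session_id = "s1") {
  rule <- rule_for_phase("reversal")
  n <- length(rule_correct)
  make_trials(n,
              phase = "reversal", session_id = session_id,
              stimulus = rep("H", n),
              choice = ifelse(rule_correct, rule[["H"]],
                              rule_for_phase("discrimination")[["H"]]),
              correct = rule_correct,
              reward_scheduled = rewarded, rewarded = rewarded,
              reward_delay_s = ifelse(rewarded, 5, NA_real_),
              waiting_time_s = NA_real_, reinitiated = FALSE)
}
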