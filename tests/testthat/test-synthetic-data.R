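test_that("identical seeds give identical sessions; all records valid", {
  obs <- test_observer()
  a <- simulate_discrimination_session(obs, n_trials = 500, seed = 7)
  b <- simulate_discrimination_session(obs, n_trials = 500, seed = 7)
  expect_identical(a, b)
  expect_silent(validate_trials(a))

  r1 <- simulate_reversal_session(obs, learner_params(), seed = 9, n_trials = 200)
  r2 <- simulate_reversal_session(obs, learner_params(), seed = 9, n_trials = 200)
  expect_identical(r1, r2)
  expect_silent(validate_trials(r1))
})

test_that("reward schedule hits its probability and delay distribution", {
  sched <- draw_reward_schedule(rep(TRUE, 1e5), seed = 3)
  p <- reward_schedule_params()
  se_p <- sqrt(0.7 * 0.3 / 1e5)
  expect_lt(abs(mean(sched$reward_scheduled) - p$p_reward_given_correct), 3 * se_p)
  delays <- sched$reward_delay_s[sched$reward_scheduled]
  se_d <- p$mean_delay_s / sqrt(length(delays))
  expect_lt(abs(mean(delays) - p$mean_delay_s), 3 * se_d)

  # incorrect choices are never rewarded
  none <- draw_reward_schedule(rep(FALSE, 100), seed = 4)
  expect_false(any(none$reward_scheduled))
  expect_true(all(is.na(none$reward_delay_s)))
})

test_that("default sensitivity grid encodes the accuracy targets", {
  # with no contrast spread, d' at SNR 4 is exactly 2 * qnorm(0.80)
  g0 <- default_sensitivity_grid(contrast_spread = 0)
  expect_equal(unname(g0["4", ]), rep(2 * qnorm(0.80), 3), tolerance = 1e-12)
  expect_equal(unname(g0["2", 1]), 2 * qnorm(0.69), tolerance = 1e-12)
  # chance targets give d' = 0
  expect_equal(unname(default_sensitivity_grid(c(0.5, 0.5, 0.5), 0)),
               matrix(0, 3, 3), tolerance = 1e-12)

  # a zero-sensitivity observer performs at chance
  obs0 <- observer_params(sensitivity_grid = matrix(0, 3, 3))
  tr <- simulate_discrimination_session(obs0, n_trials = 2e4, seed = 1)
  expect_lt(abs(mean(tr$correct) - 0.5), 3 * sqrt(0.25 / 2e4))
})

test_that("waiting increases and reaction time decreases with SNR", {
  obs <- test_observer()
  tr <- simulate_discrimination_session(obs, n_trials = 1e5, seed = 21)
  w <- select_wager_trials(tr)
  wait_by_snr <- tapply(w$waiting_time_s, w$snr, mean)
  expect_true(all(diff(wait_by_snr) > 0))
  rt_by_snr <- tapply(tr$reaction_time_s, tr$snr, mean)
  expect_true(all(diff(rt_by_snr) < 0))
})

test_that("manipulations change only what they should", {
  obs <- test_observer()
  lrn <- learner_params()

  same <- apply_manipulation(obs, lrn, manipulation_spec("none"))
  expect_identical(same$observer, obs)
  expect_identical(same$learner, lrn)

  acc <- apply_manipulation(obs, lrn, manipulation_spec("ACC"))
  expect_equal(acc$observer$wait_slope_b, 0)
  bla <- apply_manipulation(obs, lrn, manipulation_spec("BLA"))
  expect_equal(bla$observer$wait_slope_b, obs$wait_slope_b)
  expect_lt(bla$observer$wait_intercept_a, obs$wait_intercept_a)

  # reaction-time parameters untouched under any manipulation
  for (m in list(acc$observer, bla$observer)) {
    expect_equal(m$rt_intercept_r0, obs$rt_intercept_r0)
    expect_equal(m$rt_slope_r1, obs$rt_slope_r1)
    expect_equal(m$rt_noise_sd, obs$rt_noise_sd)
  }
  # inhibition removes the learner's confidence benefit
  expect_equal(unname(acc$learner$confidence_deltas),
               c(0, 0, 0))
  expect_error(manipulation_spec("OFC"))
})

test_that("deterministic learner reaches the absorbing correct state", {
  lrn <- learner_params(p_win_stay = 1, p_lose_switch_after_correct = 0,
                        p_lose_switch_after_incorrect = 1,
                        p_start_old_rule = 1, perceptual_lapse = 0,
                        confidence_deltas = c(win_stay = 0,
                                              lose_switch_after_correct = 0,
                                              lose_switch_after_incorrect = 0))
  tr <- simulate_reversal_session(test_observer(), lrn, n_trials = 50, seed = 2)
  expect_false(tr$correct[1])      # starts on the old rule
  expect_true(all(tr$correct[-1])) # switches once and never leaves
})

test_that("symmetric learner hovers at chance", {
  lrn <- learner_params(p_win_stay = 0.5, p_lose_switch_after_correct = 0.5,
                        p_lose_switch_after_incorrect = 0.5,
                        p_start_old_rule = 0.5)
  tr <- simulate_reversal_session(test_observer(), lrn, n_trials = 2e4, seed = 6)
  expect_lt(abs(mean(tr$correct) - 0.5), 0.02)
})

test_that("learner long-run accuracy matches the two-state chain closed form", {
  ws <- 0.8; lsc <- 0.3; lsi <- 0.4; pr <- 0.7
  lrn <- learner_params(p_win_stay = ws, p_lose_switch_after_correct = lsc,
                        p_lose_switch_after_incorrect = lsi,
                        p_start_old_rule = 0.5)
  u_c <- pr * (1 - ws) + (1 - pr) * lsc
  s_i <- lsi
  p_star <- s_i / (s_i + u_c)
  tr <- simulate_reversal_session(test_observer(), lrn, n_trials = 2e4, seed = 8)
  acc <- tr$correct[-(1:100)]                 # drop burn-in
  lambda <- 1 - u_c - s_i                     # chain autocorrelation
  se <- sqrt(p_star * (1 - p_star) / length(acc)) *
    sqrt((1 + lambda) / (1 - lambda))
  expect_lt(abs(mean(acc) - p_star), 3 * se)
})

test_that("unrewarded non-reinitiated trials terminate at the 40 s cap", {
  obs <- test_observer(reinit_prob = 0.2)
  tr <- simulate_discrimination_session(obs, n_trials = 2e4, seed = 12)
  timeouts <- !tr$rewarded & !tr$reinitiated
  expect_gt(sum(timeouts), 0)
  # a timeout happens iff no scheduled reward arrived within the cap
  expect_true(all(is.na(tr$waiting_time_s[timeouts])))
  got_delay <- timeouts & tr$reward_scheduled
  expect_true(all(tr$reward_delay_s[got_delay] > reward_schedule_params()$cap_s))
  # and every recorded wait respects the cap
  expect_true(all(tr$waiting_time_s <= 40, na.rm = TRUE))
})
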