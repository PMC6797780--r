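# Task simulator: SDT observer + wagering policy + probabilistic delayed
# reward + two-state reversal learner + regional-inhibition parameter shifts.

SNR_LEVELS <- c(2L, 3L, 4L)
CONTRAST_LEVELS <- c(40L, 60L, 80L)

# Stimulus-response rules. Discrimination phase uses H->left, V->right; the
# reversal phase inverts the mapping.
#' Stimulus-response rule in force for a task phase
#'
#' @param phase `"discrimination"` or `"reversal"`.
#' @return Named character vector mapping stimulus (`H`, `V`) to response side.
#' @export
rule_for_phase <- function(phase) {
  phase <- match.arg(phase, c("discrimination", "reversal"))
  if (phase == "discrimination") c(H = "left", V = "right")
  else c(H = "right", V = "left")
}

restore_seed <- function(seed) {
  if (is.null(seed)) return(invisible(NULL))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed) %% .Machine$integer.max)
  old
}

unrestore_seed <- function(old, seed) {
  if (is.null(seed)) return(invisible(NULL))
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Observer / wagerer parameters
#'
#' Generative parameters of the simulated perceiver-wagerer. Perception is an
#' equal-variance Gaussian signal-detection observer: on each trial the
#' evidence is `x ~ Normal(+/- d'/2, 1)` (positive mean for a vertical
#' stimulus) and the choice is the V-mapped side iff `x > criterion_c`.
#' Confidence is the balance of evidence `|x - criterion_c|` corrupted by
#' `confidence_noise_sd`; the intended wait is linear in confidence, clamped
#' to `[min_wait_s, max_wait_s]`; reaction time decreases with evidence
#' strength and carries a rare slow "lapse" component (disengaged trials)
#' that motivates the session-level reaction-time outlier filter.
#'
#' @param sensitivity_grid 3x3 numeric matrix of generating d' values,
#'   rows = SNR (2,3,4), columns = contrast (40,60,80); nonnegative and
#'   nondecreasing in SNR at fixed contrast.
#' @param criterion_c Decision criterion (response bias), evidence units.
#' @param wait_intercept_a,wait_slope_b Intercept (s) and slope (s per unit
#'   confidence) of the wagering policy.
#' @param wait_noise_sd SD (s) of Gaussian noise on the intended wait.
#' @param rt_intercept_r0,rt_slope_r1,rt_noise_sd Reaction-time model:
#'   `rt = max(0.05, r0 - r1 * |x| + Normal(0, rt_noise_sd))`.
#' @param rt_lapse_prob,rt_lapse_mean_s Probability of a slow lapse trial and
#'   mean (s) of its additional exponential delay.
#' @param confidence_noise_sd SD of Gaussian corruption of the confidence
#'   readout (evidence units).
#' @param min_wait_s Minimum wait before reinitiation is possible (s).
#' @param max_wait_s Trial cap (s).
#' @param reinit_prob Probability that the animal elects to reinitiate at all
#'   on an unrewarded trial (otherwise the trial times out at the cap).
#' @return An object of class `observer_params`.
#' @export
observer_params <- function(sensitivity_grid,
                            criterion_c = 0,
                            wait_intercept_a = 6,
                            wait_slope_b = 9,
                            wait_noise_sd = 2.5,
                            rt_intercept_r0 = 3.0,
                            rt_slope_r1 = 0.5,
                            rt_noise_sd = 0.6,
                            rt_lapse_prob = 0.01,
                            rt_lapse_mean_s = 8,
                            confidence_noise_sd = 0.2,
                            min_wait_s = 2,
                            max_wait_s = WAIT_CAP_S,
                            reinit_prob = 0.3) {
  sensitivity_grid <- as.matrix(sensitivity_grid)
  stopifnot(
    identical(dim(sensitivity_grid), c(3L, 3L)),
    all(sensitivity_grid >= 0),
    wait_noise_sd >= 0, rt_noise_sd >= 0, confidence_noise_sd >= 0,
    min_wait_s < max_wait_s,
    rt_lapse_prob >= 0, rt_lapse_prob <= 1,
    reinit_prob >= 0, reinit_prob <= 1
  )
  if (any(apply(sensitivity_grid, 2, diff) < -1e-12)) {
    stop("sensitivity_grid must be nondecreasing in snr at fixed contrast",
         call. = FALSE)
  }
  dimnames(sensitivity_grid) <- list(snr = SNR_LEVELS, contrast = CONTRAST_LEVELS)
  structure(
    list(sensitivity_grid = sensitivity_grid, criterion_c = criterion_c,
         wait_intercept_a = wait_intercept_a, wait_slope_b = wait_slope_b,
         wait_noise_sd = wait_noise_sd, rt_intercept_r0 = rt_intercept_r0,
         rt_slope_r1 = rt_slope_r1, rt_noise_sd = rt_noise_sd,
         rt_lapse_prob = rt_lapse_prob, rt_lapse_mean_s = rt_lapse_mean_s,
         confidence_noise_sd = confidence_noise_sd,
         min_wait_s = min_wait_s, max_wait_s = max_wait_s,
         reinit_prob = reinit_prob),
    class = "observer_params"
  )
}

#' Reward-schedule parameters
#'
#' Correct choices are reinforced probabilistically after a random delay:
#' with probability `p_reward_given_correct` a reward is scheduled, its delay
#' drawn from an exponential distribution with mean `mean_delay_s` (not
#' truncated; a delay longer than the wait or the cap simply goes
#' undelivered). Incorrect choices are never rewarded.
#'
#' @param p_reward_given_correct Probability of scheduling (default 0.70).
#' @param mean_delay_s Mean reward delay in seconds (default 8).
#' @param cap_s Trial cap in seconds (default 40).
#' @return An object of class `reward_schedule_params`.
#' @export
reward_schedule_params <- function(p_reward_given_correct = 0.70,
                                   mean_delay_s = 8,
                                   cap_s = WAIT_CAP_S) {
  stopifnot(p_reward_given_correct >= 0, p_reward_given_correct <= 1,
            mean_delay_s > 0, cap_s > 0)
  structure(list(p_reward_given_correct = p_reward_given_correct,
                 mean_delay_s = mean_delay_s, cap_s = cap_s),
            class = "reward_schedule_params")
}

#' Draw reward schedules for a vector of trials
#'
#' @param correct Logical vector: was the choice correct?
#' @param params A [reward_schedule_params()] object.
#' @param seed Optional integer seed.
#' @return A tibble with `reward_scheduled` (logical) and `reward_delay_s`
#'   (seconds, `NA` when no reward is scheduled).
#' @export
draw_reward_schedule <- function(correct, params = reward_schedule_params(),
                                 seed = NULL) {
  old <- restore_seed(seed)
  on.exit(unrestore_seed(old, seed), add = TRUE)
  n <- length(correct)
  scheduled <- correct & stats::runif(n) < params$p_reward_given_correct
  delay <- rep(NA_real_, n)
  delay[scheduled] <- stats::rexp(sum(scheduled), rate = 1 / params$mean_delay_s)
  tibble::tibble(reward_scheduled = scheduled, reward_delay_s = delay)
}

#' Reversal-learner parameters
#'
#' A two-state Markov agent over the intended stimulus-response rule
#' (correct/new vs. incorrect/old). Transitions are contingent on the last
#' trial's intended rule and reward: after a rewarded correct-rule trial the
#' agent stays with probability `p_win_stay`; after an unrewarded correct-rule
#' trial it switches with probability `p_lose_switch_after_correct`; after an
#' incorrect-rule trial (never rewarded) it switches to the correct rule with
#' probability `p_lose_switch_after_incorrect`. In the high-confidence (HC)
#' condition `confidence_deltas` is added to the three probabilities.
#'
#' @param p_win_stay,p_lose_switch_after_correct,p_lose_switch_after_incorrect
#'   Transition probabilities.
#' @param p_start_old_rule Probability of perseverating on the pre-reversal
#'   rule on trial 0.
#' @param perceptual_lapse Probability the executed choice contradicts the
#'   intended rule.
#' @param confidence_deltas Named numeric additive shifts
#'   (`win_stay`, `lose_switch_after_correct`, `lose_switch_after_incorrect`)
#'   applied in the HC condition.
#' @return An object of class `learner_params`.
#' @export
learner_params <- function(p_win_stay = 0.994,
                           p_lose_switch_after_correct = 0.006,
                           p_lose_switch_after_incorrect = 0.012,
                           p_start_old_rule = 0.9,
                           perceptual_lapse = 0,
                           confidence_deltas = c(win_stay = 0.004,
                                                 lose_switch_after_correct = -0.004,
                                                 lose_switch_after_incorrect = 0.020)) {
  probs <- c(p_win_stay, p_lose_switch_after_correct,
             p_lose_switch_after_incorrect, p_start_old_rule, perceptual_lapse)
  stopifnot(all(probs >= 0), all(probs <= 1),
            all(c("win_stay", "lose_switch_after_correct",
                  "lose_switch_after_incorrect") %in% names(confidence_deltas)))
  shifted <- c(p_win_stay + confidence_deltas[["win_stay"]],
               p_lose_switch_after_correct +
                 confidence_deltas[["lose_switch_after_correct"]],
               p_lose_switch_after_incorrect +
                 confidence_deltas[["lose_switch_after_incorrect"]])
  if (any(shifted < 0) || any(shifted > 1)) {
    stop("confidence_deltas push a transition probability outside [0, 1]",
         call. = FALSE)
  }
  structure(list(p_win_stay = p_win_stay,
                 p_lose_switch_after_correct = p_lose_switch_after_correct,
                 p_lose_switch_after_incorrect = p_lose_switch_after_incorrect,
                 p_start_old_rule = p_start_old_rule,
                 perceptual_lapse = perceptual_lapse,
                 confidence_deltas = confidence_deltas),
            class = "learner_params")
}

#' Regional-inhibition manipulation
#'
#' Chemogenetic inhibition is modeled as a shift of the wagering policy:
#' ACC inhibition flattens the confidence slope (`wait_slope_multiplier = 0`,
#' waiting becomes insensitive to stimulus strength) and shifts the mean wait
#' upward; BLA inhibition preserves the slope and shifts the mean wait
#' downward (delay aversion). `wait_intercept_shift_s` is the target change in
#' mean waiting time on wager trials relative to the unmanipulated observer;
#' [apply_manipulation()] solves the raw policy intercept so that the realized
#' wager-trial mean difference equals this target. Reaction-time parameters
#' are never touched. Under either inhibition the learner's confidence deltas
#' are scaled by `learner_delta_scaling` (default 0: the confidence benefit on
#' reversal learning is removed).
#'
#' @param region `"ACC"`, `"BLA"`, or `"none"`.
#' @param wait_slope_multiplier Multiplier on the wagering slope
#'   (default: 0 for ACC, 1 for BLA).
#' @param wait_intercept_shift_s Target mean wager-wait difference, seconds
#'   (default: +3.45 for ACC, -4.59 for BLA).
#' @param confidence_noise_add Additional SD added (in quadrature) to the
#'   confidence readout noise (default: 1 for ACC, 0 otherwise).
#' @param learner_delta_scaling Multiplier on the learner's confidence deltas
#'   (default: 0 under either inhibition, 1 for `"none"`).
#' @return An object of class `manipulation_spec`.
#' @export
manipulation_spec <- function(region = c("none", "ACC", "BLA"),
                              wait_slope_multiplier = NULL,
                              wait_intercept_shift_s = NULL,
                              confidence_noise_add = NULL,
                              learner_delta_scaling = NULL) {
  region <- match.arg(region)
  defaults <- switch(region,
    none = list(mult = 1, shift = 0, noise = 0, scale = 1),
    ACC = list(mult = 0, shift = 3.45, noise = 1, scale = 0),
    BLA = list(mult = 1, shift = -4.59, noise = 0, scale = 0)
  )
  mult <- if (is.null(wait_slope_multiplier)) defaults$mult else wait_slope_multiplier
  shift <- if (is.null(wait_intercept_shift_s)) defaults$shift else wait_intercept_shift_s
  noise <- if (is.null(confidence_noise_add)) defaults$noise else confidence_noise_add
  scale <- if (is.null(learner_delta_scaling)) defaults$scale else learner_delta_scaling
  stopifnot(mult >= 0, noise >= 0, scale >= 0)
  structure(list(region = region, wait_slope_multiplier = mult,
                 wait_intercept_shift_s = shift,
                 confidence_noise_add = noise,
                 learner_delta_scaling = scale),
            class = "manipulation_spec")
}

# ---- quadrature over the generative wagering model ----------------------

# Expected waiting time on wager (reinitiated, unrewarded) trials, by exact
# numerical integration of the generative model: evidence -> confidence ->
# clamped linear wait, with the reward race censoring long waits on correct
# trials. Returns overall/correct/incorrect means and per-SNR means.
wager_wait_moments <- function(obs, rew = reward_schedule_params(),
                               snr_levels = SNR_LEVELS) {
  grid <- obs$sensitivity_grid
  b <- obs$wait_slope_b
  s_eff <- sqrt(b^2 * obs$confidence_noise_sd^2 + obs$wait_noise_sd^2)
  tg <- seq(0.01, 9, by = 0.02)          # balance-of-evidence bin midpoints
  if (s_eff > 0) {
    eg <- seq(-8, 8, length.out = 601) * s_eff
    ew <- stats::dnorm(eg, sd = s_eff); ew <- ew / sum(ew)
  } else {
    eg <- 0; ew <- 1
  }
  p0 <- 1 - rew$p_reward_given_correct
  p1 <- rew$p_reward_given_correct
  acc_fun <- function(mu) stats::pnorm(mu)          # P(correct | d'), c = 0 offsets cancel
  num <- den <- matrix(0, length(snr_levels), 2,
                       dimnames = list(snr_levels, c("correct", "incorrect")))
  for (si in seq_along(snr_levels)) {
    for (ci in seq_along(CONTRAST_LEVELS)) {
      mu <- grid[as.character(snr_levels[si]), ci] / 2
      for (corr in c(TRUE, FALSE)) {
        dens <- if (corr) stats::dnorm(tg - mu) else stats::dnorm(tg + mu)
        if (sum(dens) == 0) next
        dens <- dens / sum(dens)
        w <- pmin(obs$max_wait_s,
                  pmax(obs$min_wait_s,
                       outer(obs$wait_intercept_a + b * tg, eg, `+`)))
        keepw <- if (corr) p0 + p1 * exp(-w / rew$mean_delay_s) else 1
        wt <- outer(dens, ew)                        # joint quadrature weight
        pcell <- (1 / 9) * if (corr) acc_fun(mu) else 1 - acc_fun(mu)
        num[si, 2 - corr] <- num[si, 2 - corr] + pcell * sum(wt * keepw * w)
        den[si, 2 - corr] <- den[si, 2 - corr] + pcell * sum(wt * keepw)
      }
    }
  }
  list(mean_overall = sum(num) / sum(den),
       mean_correct = sum(num[, "correct"]) / sum(den[, "correct"]),
       mean_incorrect = sum(num[, "incorrect"]) / sum(den[, "incorrect"]),
       mean_by_snr = rowSums(num) / rowSums(den))
}

default_sensitivity_grid <- function(accuracy_by_snr = c(0.69, 0.74, 0.80),
                                     contrast_spread = 0.04) {
  acc <- outer(accuracy_by_snr, c(-1, 0, 1) * contrast_spread, `+`)
  grid <- 2 * stats::qnorm(acc)
  dimnames(grid) <- list(snr = SNR_LEVELS, contrast = CONTRAST_LEVELS)
  grid
}

.mw_cache <- new.env(parent = emptyenv())

#' Build the default-calibrated observer
#'
#' Constructs the observer whose defaults encode the task's printed summary
#' behavior: the sensitivity grid is chosen so that simulated accuracy pooled
#' over contrast equals `accuracy_by_snr` (0.69 / 0.74 / 0.80 at SNR 2-4)
#' under the equal-variance model (accuracy = Phi(d'/2) at zero bias), with a
#' +/- `contrast_spread` accuracy spread across contrast levels; the wagering
#' intercept and slope are solved by quadrature over the generative model so
#' that the mean waiting time on wager trials equals `target_mean_wait_s` and
#' the correct-minus-incorrect mean waiting gap equals `target_wait_gap_s`.
#'
#' @param accuracy_by_snr Pooled accuracy targets for SNR 2, 3, 4.
#' @param contrast_spread Accuracy offset across contrast 40/60/80.
#' @param target_wait_gap_s Correct-incorrect mean wager-wait gap (s).
#' @param target_mean_wait_s Overall mean wager-wait (s).
#' @param reward Reward schedule assumed for the censoring race.
#' @param ... Passed on to [observer_params()] (noise SDs, RT model, ...).
#' @return An `observer_params` object.
#' @export
build_default_observer <- function(accuracy_by_snr = c(0.69, 0.74, 0.80),
                                   contrast_spread = 0.04,
                                   target_wait_gap_s = 4.74,
                                   target_mean_wait_s = 19,
                                   reward = reward_schedule_params(),
                                   ...) {
  key <- paste(c(accuracy_by_snr, contrast_spread, target_wait_gap_s,
                 target_mean_wait_s, reward$p_reward_given_correct,
                 reward$mean_delay_s,
                 vapply(list(...), paste, "", collapse = ",")),
               collapse = "|")
  if (!is.null(.mw_cache[[key]])) return(.mw_cache[[key]])
  grid <- default_sensitivity_grid(accuracy_by_snr, contrast_spread)
  base <- observer_params(sensitivity_grid = grid, ...)
  solve_a <- function(b) {
    f <- function(a) {
      o <- base; o$wait_intercept_a <- a; o$wait_slope_b <- b
      wager_wait_moments(o, reward)$mean_overall - target_mean_wait_s
    }
    stats::uniroot(f, c(-30, 39), tol = 1e-5)$root
  }
  gap_at <- function(b) {
    a <- solve_a(b)
    o <- base; o$wait_intercept_a <- a; o$wait_slope_b <- b
    m <- wager_wait_moments(o, reward)
    c(gap = m$mean_correct - m$mean_incorrect, a = a)
  }
  f_gap <- function(b) gap_at(b)[["gap"]] - target_wait_gap_s
  b_star <- stats::uniroot(f_gap, c(1, 20), tol = 1e-5)$root
  a_star <- solve_a(b_star)
  obs <- base
  obs$wait_intercept_a <- a_star
  obs$wait_slope_b <- b_star
  .mw_cache[[key]] <- obs
  obs
}

#' Apply a regional-inhibition manipulation to observer and learner
#'
#' Returns modified copies. Reaction-time parameters are untouched under any
#' manipulation. The wagering slope is multiplied by
#' `spec$wait_slope_multiplier` (0 under the ACC default: waiting becomes
#' insensitive to the stimulus) and the raw intercept is solved by quadrature
#' so that the mean wager-trial waiting time changes by exactly
#' `spec$wait_intercept_shift_s` relative to the unmanipulated observer.
#' Confidence-readout noise increases by `confidence_noise_add` (in
#' quadrature) and the learner's confidence deltas are scaled by
#' `learner_delta_scaling`.
#'
#' @param obs An [observer_params()] object.
#' @param lrn A [learner_params()] object.
#' @param spec A [manipulation_spec()] object.
#' @param reward Reward schedule assumed for the censoring race.
#' @return A list with elements `observer` and `learner`.
#' @export
apply_manipulation <- function(obs, lrn, spec,
                               reward = reward_schedule_params()) {
  if (!inherits(spec, "manipulation_spec")) {
    stop("spec must be a manipulation_spec object", call. = FALSE)
  }
  if (spec$region == "none") return(list(observer = obs, learner = lrn))
  base_mean <- wager_wait_moments(obs, reward)$mean_overall
  target <- base_mean + spec$wait_intercept_shift_s
  mod <- obs
  mod$wait_slope_b <- obs$wait_slope_b * spec$wait_slope_multiplier
  mod$confidence_noise_sd <- sqrt(obs$confidence_noise_sd^2 +
                                    spec$confidence_noise_add^2)
  f <- function(a) {
    m <- mod; m$wait_intercept_a <- a
    wager_wait_moments(m, reward)$mean_overall - target
  }
  mod$wait_intercept_a <- stats::uniroot(f, c(-40, 39.9), tol = 1e-5)$root
  lrn2 <- lrn
  lrn2$confidence_deltas <- lrn$confidence_deltas * spec$learner_delta_scaling
  list(observer = mod, learner = lrn2)
}

# ---- session simulators -------------------------------------------------

#' Simulate one discrimination (time-wagering) session
#'
#' Per trial: stimulus H/V equiprobable; (SNR, contrast) uniform over the
#' requested grid; evidence `x ~ Normal(+/- d'/2, 1)`; choice by criterion;
#' confidence = `|x - c|` + readout noise; intended wait = clamped linear
#' policy; reaction time decreasing in `|x|` with a rare slow lapse. Rewards
#' are scheduled on 70% of correct choices with exponential delays; a trial
#' is rewarded iff the delay beats the (intended) wait, else the animal
#' either reinitiates at its intended wait or times out at the 40 s cap.
#'
#' @param obs An [observer_params()] object.
#' @param rew A [reward_schedule_params()] object.
#' @param n_trials Number of trials (>= 1).
#' @param seed Optional integer seed (reproducible sessions).
#' @param snr_levels,contrast_levels Stimulus levels sampled uniformly.
#' @param rat_id,session_id,region,virus,drug,confidence_group Condition labels.
#' @return A validated trial tibble.
#' @export
simulate_discrimination_session <- function(obs,
                                            rew = reward_schedule_params(),
                                            n_trials = 300,
                                            seed = NULL,
                                            snr_levels = SNR_LEVELS,
                                            contrast_levels = CONTRAST_LEVELS,
                                            rat_id = "rat01",
                                            session_id = "s01",
                                            region = "none",
                                            virus = "none",
                                            drug = "none",
                                            confidence_group = "none") {
  stopifnot(n_trials >= 1)
  old <- restore_seed(seed)
  on.exit(unrestore_seed(old, seed), add = TRUE)

  n <- n_trials
  snr <- snr_levels[sample.int(length(snr_levels), n, replace = TRUE)]
  contrast <- contrast_levels[sample.int(length(contrast_levels), n, replace = TRUE)]
  stimulus <- sample(c("H", "V"), n, replace = TRUE)
  dp <- obs$sensitivity_grid[cbind(match(snr, SNR_LEVELS),
                                   match(contrast, CONTRAST_LEVELS))]
  x <- stats::rnorm(n, mean = ifelse(stimulus == "V", dp / 2, -dp / 2), sd = 1)
  rule <- rule_for_phase("discrimination")
  choice <- ifelse(x > obs$criterion_c, rule[["V"]], rule[["H"]])
  correct <- choice == rule[stimulus]

  conf <- abs(x - obs$criterion_c)
  if (obs$confidence_noise_sd > 0) {
    conf <- conf + stats::rnorm(n, sd = obs$confidence_noise_sd)
  }
  w_int <- obs$wait_intercept_a + obs$wait_slope_b * conf
  if (obs$wait_noise_sd > 0) w_int <- w_int + stats::rnorm(n, sd = obs$wait_noise_sd)
  w_int <- pmin(obs$max_wait_s, pmax(obs$min_wait_s, w_int))

  rt <- obs$rt_intercept_r0 - obs$rt_slope_r1 * abs(x)
  if (obs$rt_noise_sd > 0) rt <- rt + stats::rnorm(n, sd = obs$rt_noise_sd)
  lapse <- stats::runif(n) < obs$rt_lapse_prob
  rt[lapse] <- rt[lapse] + stats::rexp(sum(lapse), rate = 1 / obs$rt_lapse_mean_s)
  rt <- pmax(0.05, rt)

  sched <- draw_reward_schedule(correct, rew)
  reinit_choice <- stats::runif(n) < obs$reinit_prob
  horizon <- ifelse(reinit_choice, w_int, rew$cap_s)
  rewarded <- sched$reward_scheduled & !is.na(sched$reward_delay_s) &
    sched$reward_delay_s <= horizon
  reinitiated <- reinit_choice & !rewarded
  waiting <- ifelse(reinitiated, w_int, NA_real_)

  trials <- tibble::tibble(
    rat_id = rat_id, session_id = session_id, trial_index = 0:(n - 1),
    phase = "discrimination", region = region, virus = virus, drug = drug,
    confidence_group = confidence_group,
    snr = as.integer(snr), contrast = as.integer(contrast),
    stimulus = stimulus, choice = unname(choice), correct = unname(correct),
    reward_scheduled = sched$reward_scheduled,
    reward_delay_s = sched$reward_delay_s,
    rewarded = rewarded, reaction_time_s = rt,
    waiting_time_s = waiting, reinitiated = reinitiated
  )
  validate_trials(trials)
  trials
}

#' Simulate one reversal-learning session
#'
#' The agent holds an intended stimulus-response rule each trial (the new,
#' correct rule or the old, pre-reversal rule) and transitions according to
#' [learner_params()], contingent on the previous trial's intended rule and
#' reward. In the HC condition the confidence deltas are added to the
#' transition probabilities. The reinitiation option is removed: rewards are
#' delivered after their scheduled delay (no wagering race) and trials carry
#' no waiting time. One fixed (SNR, contrast) stimulus pair is used, matching
#' the task design in which a single discrimination-matched stimulus is
#' assigned per animal for the reversal.
#'
#' @param obs An [observer_params()] object (used for the reaction-time model).
#' @param lrn A [learner_params()] object.
#' @param rew A [reward_schedule_params()] object.
#' @param confidence_group `"HC"` or `"LC"` (HC applies the confidence deltas).
#' @param n_trials Number of trials (default 160).
#' @param seed Optional integer seed.
#' @param snr,contrast The assigned stimulus cell.
#' @param rat_id,session_id,region,virus,drug Condition labels.
#' @return A validated trial tibble (phase `"reversal"`).
#' @export
simulate_reversal_session <- function(obs, lrn,
                                      rew = reward_schedule_params(),
                                      confidence_group = c("LC", "HC"),
                                      n_trials = 160,
                                      seed = NULL,
                                      snr = 3L, contrast = 60L,
                                      rat_id = "rat01", session_id = "s01",
                                      region = "none", virus = "none",
                                      drug = "none") {
  stopifnot(n_trials >= 1)
  confidence_group <- match.arg(confidence_group)
  old <- restore_seed(seed)
  on.exit(unrestore_seed(old, seed), add = TRUE)

  d <- lrn$confidence_deltas
  if (confidence_group == "HC") {
    p_ws <- lrn$p_win_stay + d[["win_stay"]]
    p_lsc <- lrn$p_lose_switch_after_correct + d[["lose_switch_after_correct"]]
    p_lsi <- lrn$p_lose_switch_after_incorrect + d[["lose_switch_after_incorrect"]]
  } else {
    p_ws <- lrn$p_win_stay
    p_lsc <- lrn$p_lose_switch_after_correct
    p_lsi <- lrn$p_lose_switch_after_incorrect
  }
  stopifnot(p_ws >= 0, p_ws <= 1, p_lsc >= 0, p_lsc <= 1,
            p_lsi >= 0, p_lsi <= 1)

  n <- n_trials
  intended_correct <- logical(n)
  intended_correct[1] <- stats::runif(1) >= lrn$p_start_old_rule
  sched_p <- rew$p_reward_given_correct
  executed_flip <- stats::runif(n) < lrn$perceptual_lapse
  stimulus <- sample(c("H", "V"), n, replace = TRUE)
  rule_new <- rule_for_phase("reversal")
  rule_old <- rule_for_phase("discrimination")

  scheduled <- logical(n); rewarded <- logical(n)
  u <- stats::runif(n)          # reward draw
  v <- stats::runif(n)          # transition draw
  for (t in seq_len(n)) {
    correct_t <- xor(intended_correct[t], executed_flip[t])
    scheduled[t] <- correct_t && u[t] < sched_p
    rewarded[t] <- scheduled[t]  # delay always delivered: no wagering race
    if (t < n) {
      if (intended_correct[t]) {
        p_leave <- if (rewarded[t]) 1 - p_ws else p_lsc
      } else {
        p_leave <- p_lsi
      }
      intended_correct[t + 1] <- if (v[t] < p_leave) !intended_correct[t]
                                 else intended_correct[t]
    }
  }
  executed_correct <- xor(intended_correct, executed_flip)
  intended_rule_map <- ifelse(intended_correct,
                              rule_new[stimulus], rule_old[stimulus])
  choice <- ifelse(executed_flip,
                   ifelse(intended_rule_map == "left", "right", "left"),
                   intended_rule_map)
  delay <- rep(NA_real_, n)
  delay[scheduled] <- stats::rexp(sum(scheduled), rate = 1 / rew$mean_delay_s)

  dp <- obs$sensitivity_grid[as.character(snr), as.character(contrast)]
  xev <- stats::rnorm(n, mean = dp / 2)  # evidence strength for the RT model
  rt <- obs$rt_intercept_r0 - obs$rt_slope_r1 * abs(xev)
  if (obs$rt_noise_sd > 0) rt <- rt + stats::rnorm(n, sd = obs$rt_noise_sd)
  rt <- pmax(0.05, rt)

  trials <- tibble::tibble(
    rat_id = rat_id, session_id = session_id, trial_index = 0:(n - 1),
    phase = "reversal", region = region, virus = virus, drug = drug,
    confidence_group = confidence_group,
    snr = as.integer(snr), contrast = as.integer(contrast),
    stimulus = stimulus, choice = unname(choice),
    correct = unname(executed_correct),
    reward_scheduled = scheduled, reward_delay_s = delay,
    rewarded = rewarded, reaction_time_s = rt,
    waiting_time_s = NA_real_, reinitiated = FALSE
  )
  validate_trials(trials)
  trials
}

#' Simulate a multi-rat, multi-session experiment
#'
#' Convenience wrapper generating a cohort. Per-session random streams are
#' derived deterministically from the single global `seed` and the session
#' counter, so the full table is reproducible and individual sessions are
#' independent.
#'
#' @param n_rats,sessions_per_rat,n_trials Cohort dimensions.
#' @param phase `"discrimination"` or `"reversal"`.
#' @param obs,lrn,rew Parameter objects (defaults: calibrated observer,
#'   default learner, default reward schedule).
#' @param spec A [manipulation_spec()] applied to all sessions.
#' @param confidence_group For reversal sessions.
#' @param drug,virus Labels recorded on every trial.
#' @param seed Integer seed for the whole cohort.
#' @param ... Passed to the per-session simulator.
#' @return A trial tibble covering all rats and sessions.
#' @export
simulate_experiment <- function(n_rats = 3, sessions_per_rat = 4,
                                n_trials = 300,
                                phase = c("discrimination", "reversal"),
                                obs = build_default_observer(),
                                lrn = learner_params(),
                                rew = reward_schedule_params(),
                                spec = manipulation_spec("none"),
                                confidence_group = "LC",
                                drug = "none", virus = "none",
                                seed = 1, ...) {
  phase <- match.arg(phase)
  applied <- apply_manipulation(obs, lrn, spec, rew)
  out <- vector("list", n_rats * sessions_per_rat)
  k <- 0
  for (r in seq_len(n_rats)) {
    for (s in seq_len(sessions_per_rat)) {
      k <- k + 1
      sseed <- (as.integer(seed) %% 100000L) * 20011L + k * 7919L
      args <- list(obs = applied$observer, rew = rew, n_trials = n_trials,
                   seed = sseed %% .Machine$integer.max,
                   rat_id = sprintf("rat%02d", r),
                   session_id = sprintf("s%02d", s),
                   region = spec$region,
                   virus = virus, drug = drug, ...)
      out[[k]] <- if (phase == "discrimination") {
        do.call(simulate_discrimination_session,
                c(args, list(confidence_group = confidence_group)))
      } else {
        do.call(simulate_reversal_session,
                c(args, list(lrn = applied$learner,
                             confidence_group = confidence_group)))
      }
    }
  }
  dplyr::bind_rows(out)
}
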