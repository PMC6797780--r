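# Win-Stay / Lose-Switch scoring and the rule-based repetition index over
# reversal-phase trial blocks.

#' Infer the applied stimulus-response rule on a trial
#'
#' A trial applied the `correct_rule` iff the executed choice equals the
#' response the rule in force maps the stimulus to; otherwise it applied the
#' (complementary) `incorrect_rule`.
#'
#' @param stimulus Character vector of `"H"`/`"V"`.
#' @param choice Character vector of `"left"`/`"right"`.
#' @param rule_in_force Named character vector mapping `H` and `V` to
#'   distinct sides (e.g. `rule_for_phase("reversal")`).
#' @return Character vector: `"correct_rule"` or `"incorrect_rule"`.
#' @export
infer_applied_rule <- function(stimulus, choice, rule_in_force) {
  if (!all(c("H", "V") %in% names(rule_in_force)) ||
      rule_in_force[["H"]] == rule_in_force[["V"]]) {
    stop("rule_in_force must map H and V to distinct sides", call. = FALSE)
  }
  unname(ifelse(choice == rule_in_force[stimulus],
                "correct_rule", "incorrect_rule"))
}

#' Rule-based repetition index
#'
#' `RRI = p(StayRule) - p(C)^2 - (1 - p(C))^2`: the probability of using the
#' same rule on two consecutive trials minus the chance rate of repetition
#' implied by the block-level probability `p(C)` of choosing the correct
#' rule. Ranges over `[-0.5, 1]` for valid inputs; 0 for an agent selecting
#' rules independently across trials.
#'
#' @param p_stay_rule Probability the same rule was used on consecutive trials.
#' @param p_correct_rule Block-level probability of the correct rule.
#' @return The repetition index.
#' @export
compute_rri <- function(p_stay_rule, p_correct_rule) {
  stopifnot(all(p_stay_rule >= 0 & p_stay_rule <= 1, na.rm = TRUE),
            all(p_correct_rule >= 0 & p_correct_rule <= 1, na.rm = TRUE))
  p_stay_rule - p_correct_rule^2 - (1 - p_correct_rule)^2
}

#' Score Win-Stay / Lose-Switch strategies and the repetition index
#'
#' Over consecutive within-session trial pairs (t, t+1) inside the block,
#' computes:
#' * `p_win_stay`: P(correct rule at t+1 | correct rule and rewarded at t)
#' * `p_lose_switch_after_correct`: P(incorrect rule at t+1 | correct rule,
#'   unrewarded at t) — correct responses go unrewarded 30% of the time by
#'   design, so this conditions on genuine negative feedback after a correct
#'   choice
#' * `p_lose_switch_after_incorrect`: P(correct rule at t+1 | incorrect rule
#'   at t; incorrect trials are never rewarded)
#' * `p_stay_rule`, `p_correct_rule`, and the repetition index
#'   ([compute_rri()]).
#'
#' Pairs never span session boundaries, and pairs containing a trial removed
#' upstream (non-consecutive `trial_index`) are dropped. Probabilities with
#' an empty conditioning set are `NA` with denominator 0 recorded in
#' `n_pairs_by_type`.
#'
#' @param trials Reversal-phase trial table (one or more sessions).
#' @param block `"first_half"` (default; the first half of each session's
#'   trials) or `"full"`.
#' @param rule_in_force Rule defining the correct mapping (default: the
#'   reversal-phase rule).
#' @return An object of class `strategy_profile` (also a one-row tibble with
#'   the probabilities, `rri`, denominators and block descriptor).
#' @export
compute_strategy_profile <- function(trials,
                                     block = c("first_half", "full"),
                                     rule_in_force = rule_for_phase("reversal")) {
  block <- match.arg(block)
  sess <- interaction(trials$rat_id, trials$session_id, drop = TRUE)
  num <- c(ws = 0, lsc = 0, lsi = 0, stay = 0)
  den <- c(ws = 0, lsc = 0, lsi = 0, stay = 0)
  n_correct_rule <- 0L; n_block <- 0L
  for (s in levels(sess)) {
    sub <- trials[sess == s, , drop = FALSE]
    sub <- sub[order(sub$trial_index), , drop = FALSE]
    n <- max(sub$trial_index) + 1L   # session length, robust to removed trials
    if (block == "first_half") sub <- sub[sub$trial_index < floor(n / 2), , drop = FALSE]
    if (nrow(sub) < 2) next
    applied <- infer_applied_rule(sub$stimulus, sub$choice, rule_in_force)
    corr_rule <- applied == "correct_rule"
    n_correct_rule <- n_correct_rule + sum(corr_rule)
    n_block <- n_block + nrow(sub)
    adjacent <- diff(sub$trial_index) == 1L   # removed trials break pairs
    a <- corr_rule[-nrow(sub)][adjacent]
    b <- corr_rule[-1][adjacent]
    rew <- isTRUE_vec(sub$rewarded)[-nrow(sub)][adjacent]
    den["ws"] <- den["ws"] + sum(a & rew)
    num["ws"] <- num["ws"] + sum(a & rew & b)
    den["lsc"] <- den["lsc"] + sum(a & !rew)
    num["lsc"] <- num["lsc"] + sum(a & !rew & !b)
    den["lsi"] <- den["lsi"] + sum(!a)
    num["lsi"] <- num["lsi"] + sum(!a & b)
    den["stay"] <- den["stay"] + length(a)
    num["stay"] <- num["stay"] + sum(a == b)
  }
  if (n_block < 2) stop("block has fewer than 2 trials", call. = FALSE)
  ratio <- function(k) if (den[[k]] > 0) num[[k]] / den[[k]] else NA_real_
  p_stay <- ratio("stay")
  p_c <- n_correct_rule / n_block
  out <- tibble::tibble(
    p_win_stay = ratio("ws"),
    p_lose_switch_after_correct = ratio("lsc"),
    p_lose_switch_after_incorrect = ratio("lsi"),
    p_stay_rule = p_stay,
    p_correct_rule = p_c,
    rri = if (is.na(p_stay)) NA_real_ else compute_rri(p_stay, p_c),
    n_win_stay = den[["ws"]],
    n_lose_after_correct = den[["lsc"]],
    n_lose_after_incorrect = den[["lsi"]],
    n_pairs = den[["stay"]],
    n_trials = n_block,
    block = block
  )
  class(out) <- c("strategy_profile", class(out))
  out
}

#' Per-session strategy profiles for grouped analysis
#'
#' Applies [compute_strategy_profile()] to each (rat, session) and returns
#' one row per session with the session's condition labels, suitable for
#' session-level permutation tests.
#'
#' @inheritParams compute_strategy_profile
#' @return A tibble, one row per session.
#' @export
strategy_profiles_by_session <- function(trials,
                                         block = c("first_half", "full"),
                                         rule_in_force = rule_for_phase("reversal")) {
  block <- match.arg(block)
  labels <- c("rat_id", "session_id", "region", "virus", "drug",
              "confidence_group")
  dplyr::group_by(trials, dplyr::across(dplyr::all_of(labels))) |>
    dplyr::group_modify(function(d, key) {
      d$rat_id <- key$rat_id; d$session_id <- key$session_id
      prof <- compute_strategy_profile(d, block = block,
                                       rule_in_force = rule_in_force)
      tibble::as_tibble(prof)
    }) |>
    dplyr::ungroup()
}
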