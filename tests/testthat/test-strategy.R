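test_that("applied-rule inference follows the rule in force", {
  rule <- c(H = "left", V = "right")
  expect_equal(infer_applied_rule("H", "left", rule), "correct_rule")
  expect_equal(infer_applied_rule("H", "right", rule), "incorrect_rule")
  # flipping the rule mapping flips every label
  flipped <- c(H = "right", V = "left")
  stim <- sample(c("H", "V"), 50, replace = TRUE)
  ch <- sample(c("left", "right"), 50, replace = TRUE)
  a <- infer_applied_rule(stim, ch, rule)
  b <- infer_applied_rule(stim, ch, flipped)
  expect_true(all(a != b))
  expect_error(infer_applied_rule("H", "left", c(H = "left", V = "left")),
               "distinct")
})

test_that("the repetition index evaluates its defining arithmetic", {
  expect_equal(compute_rri(0.5, 0.5), 0)
  expect_equal(compute_rri(1.0, 0.7), 0.42)
  # 0.58 is the chance stay rate at p(C) = 0.7
  expect_equal(compute_rri(0.58, 0.7), 0, tolerance = 1e-12)
  expect_error(compute_rri(1.2, 0.5))
  # over actual rule sequences the index stays in [-0.5, 1]: a strict
  # alternator pins p(C) near 0.5, so the chance term cannot exceed
  # p_stay_rule by more than 0.5
  for (len in c(4, 7, 10)) {
    seqs <- expand.grid(rep(list(c(FALSE, TRUE)), len))
    for (i in seq_len(nrow(seqs))) {
      sq <- as.logical(seqs[i, ])
      ps <- mean(sq[-len] == sq[-1]); pc <- mean(sq)
      val <- compute_rri(ps, pc)
      # odd-length alternators overshoot -0.5 by exactly 1/(2 N^2)
      expect_gte(val, -0.5 - 1 / (2 * len^2) - 1e-12)
      expect_lte(val, 1)
    }
  }
  # the alternating sequence attains the lower bound in the limit
  expect_equal(compute_rri(0, 0.5), -0.5)
})

test_that("a deterministic stay agent has p_stay_rule 1 and nonnegative rri", {
  tr <- rule_sequence_trials(rep(TRUE, 20))
  prof <- compute_strategy_profile(tr, block = "full")
  expect_equal(prof$p_stay_rule, 1)
  expect_gte(prof$rri, 0)
  expect_equal(prof$p_correct_rule, 1)
})

test_that("strategy profile matches a brute-force pair scan on every short sequence", {
  # independent oracle: direct pair counting on the logical sequence
  oracle <- function(sq, rew) {
    a <- sq[-length(sq)]; b <- sq[-1]; ra <- rew[-length(sq)]
    safe <- function(num, den) if (den > 0) num / den else NA_real_
    pc <- mean(sq)
    ps <- safe(sum(a == b), length(a))
    list(ws = safe(sum(a & ra & b), sum(a & ra)),
         lsc = safe(sum(a & !ra & !b), sum(a & !ra)),
         lsi = safe(sum(!a & b), sum(!a)),
         stay = ps, pc = pc,
         rri = if (is.na(ps)) NA_real_ else ps - pc^2 - (1 - pc)^2)
  }
  set.seed(10)
  for (len in c(2, 5, 10)) {
    seqs <- expand.grid(rep(list(c(FALSE, TRUE)), len))
    for (i in seq_len(nrow(seqs))) {
      sq <- as.logical(seqs[i, ])
      rew <- sq & (runif(len) < 0.7)       # only correct trials can be rewarded
      prof <- compute_strategy_profile(rule_sequence_trials(sq, rew),
                                       block = "full")
      ex <- oracle(sq, rew)
      expect_equal(prof$p_win_stay, ex$ws)
      expect_equal(prof$p_lose_switch_after_correct, ex$lsc)
      expect_equal(prof$p_lose_switch_after_incorrect, ex$lsi)
      expect_equal(prof$p_stay_rule, ex$stay)
      expect_equal(prof$p_correct_rule, ex$pc)
      expect_equal(prof$rri, ex$rri)
    }
  }
})

test_that("i.i.d. rule agents have mean RRI near zero", {
  set.seed(99)
  n_trials <- 1000
  for (p in c(0.3, 0.5, 0.7)) {
    rri <- replicate(1000, {
      sq <- runif(n_trials) < p
      a <- sq[-n_trials]; b <- sq[-1]
      mean(a == b) - mean(sq)^2 - (1 - mean(sq))^2
    })
    expect_lt(abs(mean(rri)), 3 * sd(rri) / sqrt(length(rri)))
  }
})

test_that("pairs never span session boundaries and filtered trials break pairs", {
  # two sessions, each a run; a cross-session pair would be a switch
  s1 <- rule_sequence_trials(rep(TRUE, 6), session_id = "s1")
  s2 <- rule_sequence_trials(rep(FALSE, 6), session_id = "s2")
  prof <- compute_strategy_profile(dplyr::bind_rows(s1, s2), block = "full")
  expect_equal(prof$p_stay_rule, 1)   # 10 within-session pairs, all stays

  # removing a middle trial must drop both pairs that contained it
  s3 <- rule_sequence_trials(c(TRUE, TRUE, FALSE, TRUE, TRUE))
  s3 <- s3[-3, ]
  prof3 <- compute_strategy_profile(s3, block = "full")
  expect_equal(prof3$n_pairs, 2)      # (0,1) and (3,4) only
  expect_equal(prof3$p_stay_rule, 1)
})

test_that("Markov learner parameters are recovered from 1e4 trials", {
  ws <- 0.8; lsc <- 0.3; lsi <- 0.4
  lrn <- learner_params(p_win_stay = ws, p_lose_switch_after_correct = lsc,
                        p_lose_switch_after_incorrect = lsi,
                        p_start_old_rule = 0.5)
  tr <- simulate_reversal_session(test_observer(), lrn, n_trials = 1e4, seed = 15)
  prof <- compute_strategy_profile(tr, block = "full")
  expect_lt(abs(prof$p_win_stay - ws), 0.03)
  expect_lt(abs(prof$p_lose_switch_after_correct - lsc), 0.03)
  expect_lt(abs(prof$p_lose_switch_after_incorrect - lsi), 0.03)
})

test_that("HC deltas shift all four strategy measures in the task's directions", {
  lrn <- learner_params()
  sim_group <- function(grp, seed0) {
    profs <- lapply(1:500, function(i) {
      tr <- simulate_reversal_session(test_observer(), lrn,
                                      confidence_group = grp,
                                      n_trials = 160, seed = seed0 + i)
      compute_strategy_profile(tr, block = "first_half")
    })
    dplyr::bind_rows(profs)
  }
  hc <- sim_group("HC", 4000)
  lc <- sim_group("LC", 8000)
  expect_gt(mean(hc$p_win_stay, na.rm = TRUE) -
              mean(lc$p_win_stay, na.rm = TRUE), 0)
  expect_lt(mean(hc$p_lose_switch_after_correct, na.rm = TRUE) -
              mean(lc$p_lose_switch_after_correct, na.rm = TRUE), 0)
  expect_gt(mean(hc$p_lose_switch_after_incorrect, na.rm = TRUE) -
              mean(lc$p_lose_switch_after_incorrect, na.rm = TRUE), 0)
  expect_gt(mean(hc$rri, na.rm = TRUE) - mean(lc$rri, na.rm = TRUE), 0)
})
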