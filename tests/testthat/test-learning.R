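test_that("sliding-window curve handles degenerate inputs exactly", {
  tr <- make_trials(50, phase = "reversal", correct = TRUE,
                    waiting_time_s = NA_real_, reinitiated = FALSE)
  cv <- sliding_window_accuracy(tr, window = 10)
  expect_equal(nrow(cv), 41)
  expect_true(all(cv$accuracy == 1))

  alt <- make_trials(40, phase = "reversal",
                     correct = rep(c(TRUE, FALSE), 20),
                     waiting_time_s = NA_real_, reinitiated = FALSE)
  cv2 <- sliding_window_accuracy(alt, window = 2)
  expect_true(all(cv2$accuracy == 0.5))

  expect_error(sliding_window_accuracy(alt, window = 100), "window")
})

test_that("sliding-window curve tracks the Markov chain's analytic trajectory", {
  ws <- 0.97; lsc <- 0.05; lsi <- 0.06; pr <- 0.7; p0 <- 0.1
  lrn <- learner_params(p_win_stay = ws, p_lose_switch_after_correct = lsc,
                        p_lose_switch_after_incorrect = lsi,
                        p_start_old_rule = 1 - p0)
  n_sess <- 200; n_tr <- 300
  trs <- lapply(1:n_sess, function(i) {
    simulate_reversal_session(test_observer(), lrn, n_trials = n_tr,
                              seed = 3000 + i, session_id = sprintf("s%03d", i))
  })
  cv <- sliding_window_accuracy(dplyr::bind_rows(trs), window = 50)
  u <- pr * (1 - ws) + (1 - pr) * lsc
  s <- lsi
  p_star <- s / (s + u)
  lam <- 1 - s - u
  p_t <- p_star + (p0 - p_star) * lam^(0:(n_tr - 1))
  smooth <- stats::filter(p_t, rep(1 / 50, 50), sides = 1)[50:n_tr]
  se <- sqrt(smooth * (1 - smooth) / (n_sess * 50)) *
    sqrt((1 + lam) / (1 - lam))          # autocorrelation-adjusted
  expect_true(all(abs(cv$accuracy - smooth) < 4 * se))
})

test_that("early/late split uses floor(N/2) and ceiling(3N/4) boundaries", {
  tr <- make_trials(100, phase = "reversal", waiting_time_s = NA_real_,
                    reinitiated = FALSE)
  sp <- split_early_late(tr)
  expect_equal(range(sp$early$trial_index), c(0, 49))
  expect_equal(range(sp$late$trial_index), c(75, 99))

  tr7 <- make_trials(7, phase = "reversal", waiting_time_s = NA_real_,
                     reinitiated = FALSE)
  sp7 <- split_early_late(tr7)
  expect_equal(sp7$early$trial_index, 0:2)
  expect_equal(sp7$late$trial_index, 5:6)
  expect_length(intersect(sp7$early$trial_index, sp7$late$trial_index), 0)
  expect_error(split_early_late(make_trials(3)), "at least 4")
})

test_that("chi-square proportion comparison matches the hand formula", {
  same <- compare_proportions(c(50, 50), c(50, 50))
  expect_equal(same$chi2, 0)
  expect_equal(same$p_value, 1)

  # Pearson 2x2 by n(ad - bc)^2 / (r1 r2 c1 c2)
  r <- compare_proportions(c(90, 10), c(50, 50))
  expect_equal(r$chi2, 200 * (90 * 50 - 10 * 50)^2 / (100 * 100 * 140 * 60),
               tolerance = 1e-9)
  expect_equal(r$chi2, 38.0952381, tolerance = 1e-6)

  r2 <- compare_proportions(c(180, 20), c(100, 100))
  expect_equal(r2$chi2, 2 * r$chi2, tolerance = 1e-9)

  expect_error(compare_proportions(c(0, 0), c(5, 5)), "margin")
})

test_that("alpha is recovered within 15% from curve-generated cohorts", {
  gen <- function(alpha, n_sess = 20, n_tr = 800, seed = 1) {
    set.seed(seed)
    dplyr::bind_rows(lapply(1:n_sess, function(i) {
      t <- 0:(n_tr - 1)
      p <- 0.85 - (0.85 - 0.5) * exp(-t / alpha)
      make_trials(n_tr, phase = "reversal", session_id = sprintf("s%02d", i),
                  correct = runif(n_tr) < p,
                  waiting_time_s = NA_real_, reinitiated = FALSE)
    }))
  }
  # the per-cohort MLE sits at the information limit (sampling SD 9-18% at
  # this problem size), so recovery is assessed on the mean estimate over
  # replicate cohorts
  for (alpha in c(100, 200, 400)) {
    ests <- vapply(1:12, function(r) {
      fit <- fit_learning_curve(gen(alpha, seed = alpha * 37 + r),
                                n_bootstrap = 0)
      expect_true(fit$converged)
      fit$alpha
    }, numeric(1))
    expect_lt(abs(mean(ests) - alpha) / alpha, 0.15)
  }

  # halving alpha halves the fitted time constant (trials-to-half-asymptote
  # is alpha * log 2, so the ratio of fitted alphas is the quantity checked)
  a300 <- mean(vapply(1:6, function(r)
    fit_learning_curve(gen(300, seed = 7000 + r), n_bootstrap = 0)$alpha,
    numeric(1)))
  a150 <- mean(vapply(1:6, function(r)
    fit_learning_curve(gen(150, seed = 8000 + r), n_bootstrap = 0)$alpha,
    numeric(1)))
  expect_equal(a150 / a300, 0.5, tolerance = 0.15)
})

test_that("a flat curve leaves alpha unidentifiable, with diagnostic", {
  set.seed(3)
  tr <- make_trials(2000, phase = "reversal", correct = runif(2000) < 0.75,
                    waiting_time_s = NA_real_, reinitiated = FALSE)
  fit <- fit_learning_curve(tr, n_bootstrap = 0)
  expect_true(is.na(fit$alpha))
  expect_true(fit$flat)
  expect_match(fit$diagnostic, "unidentifiable")
})

test_that("bootstrap CI brackets the point estimate", {
  set.seed(11)
  trs <- dplyr::bind_rows(lapply(1:10, function(i) {
    t <- 0:399
    p <- 0.85 - 0.35 * exp(-t / 80)
    make_trials(400, phase = "reversal", session_id = sprintf("s%02d", i),
                correct = runif(400) < p,
                waiting_time_s = NA_real_, reinitiated = FALSE)
  }))
  fit <- fit_learning_curve(trs, n_bootstrap = 60, seed = 5)
  expect_false(is.na(fit$ci_alpha[1]))
  expect_lte(fit$ci_alpha[1], fit$alpha)
  expect_gte(fit$ci_alpha[2], fit$alpha)
})

test_that("HC simulations fit a smaller alpha than LC (faster learning)", {
  lrn <- learner_params()
  sim <- function(grp, seed0) {
    dplyr::bind_rows(lapply(1:60, function(i) {
      simulate_reversal_session(test_observer(), lrn, confidence_group = grp,
                                n_trials = 160, seed = seed0 + i,
                                session_id = sprintf("s%03d", i))
    }))
  }
  f_hc <- fit_learning_curve(sim("HC", 60000), n_bootstrap = 0)
  f_lc <- fit_learning_curve(sim("LC", 70000), n_bootstrap = 0)
  expect_lt(f_hc$alpha, f_lc$alpha)
})

test_that("matched-pair selection finds equal-d' cells with maximal wait gap", {
  # two cells tie exactly on d', differ by 5 s in wait: must be returned
  mk_cell <- function(snr, contrast, hr, wait, n = 120) {
    sig <- rep(c(TRUE, FALSE), each = n / 2)
    k <- round(hr * n / 2)   # deterministic counts: exact d' ties
    said <- c(rep(c(TRUE, FALSE), c(k, n / 2 - k)),
              rep(c(TRUE, FALSE), c(n / 2 - k, k)))
    rule <- rule_for_phase("discrimination")
    make_trials(n, snr = snr, contrast = contrast,
                stimulus = ifelse(sig, "V", "H"),
                choice = ifelse(said, rule[["V"]], rule[["H"]]),
                correct = sig == said,
                waiting_time_s = pmin(40, pmax(0, rnorm(n, wait, 0.1))))
  }
  set.seed(21)
  tr <- dplyr::bind_rows(
    mk_cell(2L, 40L, 0.78, wait = 12),
    mk_cell(3L, 60L, 0.78, wait = 17),
    mk_cell(4L, 80L, 0.95, wait = 25)
  )
  tr$trial_index <- 0:(nrow(tr) - 1)
  sel <- select_matched_stimulus_pairs(tr, tolerance_dprime = 0.2)
  expect_setequal(sel$snr, c(2L, 3L))
  expect_equal(sel$label[which.max(sel$mean_wait)], "HC")
  expect_gt(abs(diff(sel$mean_wait)), 3)

  # all-distinct d' grid with zero tolerance: explicit failure naming the
  # nearest candidates
  tr2 <- dplyr::bind_rows(
    mk_cell(2L, 40L, 0.70, wait = 12),
    mk_cell(3L, 60L, 0.80, wait = 17),
    mk_cell(4L, 80L, 0.95, wait = 25)
  )
  tr2$trial_index <- 0:(nrow(tr2) - 1)
  expect_error(select_matched_stimulus_pairs(tr2, tolerance_dprime = 0),
               "nearest candidates")
})

test_that("selection on simulated rats respects the tolerance by construction", {
  obs <- test_observer()
  tr <- simulate_discrimination_session(obs, n_trials = 2e4, seed = 31)
  sel <- select_matched_stimulus_pairs(tr, tolerance_dprime = 0.1)
  expect_lte(abs(diff(sel$d_prime)), 0.1)
  expect_gte(sel$mean_wait[sel$label == "HC"], sel$mean_wait[sel$label == "LC"])
})
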