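# Learning curves, early/late comparison, exponential learning-curve fit,
# and selection of discrimination-matched HC/LC stimulus pairs.

#' Sliding-window learning curve
#'
#' Accuracy after the reversal, averaged over a sliding window of `window`
#' trials: sessions are aligned by post-reversal trial index, per-index
#' accuracy is pooled across sessions, and a centered running mean over the
#' window is taken. The curve has `n_trials - window + 1` points.
#'
#' @param trials Reversal-phase trial table.
#' @param window Window width in trials (default 100).
#' @return An object of class `learning_curve`: tibble with `trial_center`
#'   (0-based index of the window center) and `accuracy`; attributes
#'   `window`, `n_sessions`.
#' @export
sliding_window_accuracy <- function(trials, window = 100) {
  stopifnot(window >= 1)
  idx <- trials$trial_index
  n_trials <- max(idx) + 1L
  if (window > n_trials) {
    stop("window (", window, ") exceeds trial count (", n_trials, ")",
         call. = FALSE)
  }
  num <- tapply(as.numeric(trials$correct), factor(idx, 0:(n_trials - 1)),
                sum, default = 0)
  den <- tapply(rep(1, nrow(trials)), factor(idx, 0:(n_trials - 1)),
                sum, default = 0)
  ksum <- function(v) stats::filter(v, rep(1, window), sides = 1)
  acc <- as.numeric(ksum(num) / ksum(den))
  keep <- window:n_trials
  out <- tibble::tibble(
    trial_center = keep - 1 - (window - 1) / 2,
    accuracy = acc[keep]
  )
  attr(out, "window") <- window
  attr(out, "n_sessions") <- length(unique(interaction(trials$rat_id,
                                                       trials$session_id)))
  class(out) <- c("learning_curve", class(out))
  out
}

#' Split a session into early and late blocks
#'
#' Early = the first half of the trials (index < floor(N/2)); late = the
#' last quarter (index >= floor(3N/4)). The blocks are always disjoint.
#'
#' @param trials A trial table (one alignment; uses `trial_index`).
#' @return A list with elements `early` and `late` (trial tibbles).
#' @export
split_early_late <- function(trials) {
  n <- max(trials$trial_index) + 1L
  if (n < 4) stop("need at least 4 trials to split early/late", call. = FALSE)
  early <- trials[trials$trial_index < floor(n / 2), , drop = FALSE]
  late <- trials[trials$trial_index >= floor(3 * n / 4), , drop = FALSE]
  list(early = early, late = late)
}

#' Chi-square comparison of two correct/incorrect ratios
#'
#' Pearson chi-square on the 2x2 table (1 df, no continuity correction), the
#' test used to compare early/late performance ratios between conditions.
#'
#' @param counts_a,counts_b Length-2 vectors `(correct, incorrect)`.
#' @return A list with `chi2` and `p_value`.
#' @export
compare_proportions <- function(counts_a, counts_b) {
  stopifnot(length(counts_a) == 2, length(counts_b) == 2,
            all(c(counts_a, counts_b) >= 0))
  tab <- rbind(counts_a, counts_b)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero margin in 2x2 table", call. = FALSE)
  }
  if (identical(prop.table(tab, 1)[1, 1], prop.table(tab, 1)[2, 1])) {
    return(list(chi2 = 0, p_value = 1))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi2 = unname(ct$statistic), p_value = unname(ct$p.value))
}

# Saturating-exponential learning model:
#   P(C)_t = p_asymptote - (p_asymptote - p_start) * exp(-t / alpha).
# Bernoulli negative log-likelihood over raw trials.
learning_nll <- function(theta, t, y) {
  ps <- stats::plogis(theta[1])
  pa <- stats::plogis(theta[2])
  alpha <- exp(theta[3])
  p <- pa - (pa - ps) * exp(-t / alpha)
  p <- pmin(1 - 1e-9, pmax(1e-9, p))
  -sum(y * log(p) + (1 - y) * log(1 - p))
}

fit_learning_once <- function(t, y) {
  early_p <- mean(y[t <= stats::quantile(t, 0.1)])
  late_p <- mean(y[t >= stats::quantile(t, 0.75)])
  th1 <- stats::qlogis(pmin(0.95, pmax(0.05, early_p)))
  th2 <- stats::qlogis(pmin(0.95, pmax(0.05, late_p)))
  # multi-start over the time constant: the likelihood can be flat in alpha
  # when the asymptote is only weakly identified
  best <- NULL
  for (alpha0 in pmax(2, max(t)) / c(2, 5, 10, 20, 50)) {
    fit <- stats::optim(c(th1, th2, log(alpha0)), learning_nll, t = t, y = y,
                        method = "Nelder-Mead",
                        control = list(reltol = 1e-10, maxit = 5000))
    fit <- stats::optim(fit$par, learning_nll, t = t, y = y,
                        method = "Nelder-Mead",
                        control = list(reltol = 1e-10, maxit = 5000))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  # constant-model likelihood for the flatness diagnostic
  p_hat <- mean(y)
  nll0 <- -sum(y * log(p_hat) + (1 - y) * log(1 - p_hat))
  list(p_start = stats::plogis(best$par[1]),
       p_asymptote = stats::plogis(best$par[2]),
       alpha = exp(best$par[3]),
       nll = best$value,
       nll_constant = nll0,
       converged = best$convergence == 0)
}

#' Fit an exponential learning curve
#'
#' Fits `P(C)_t = p_asymptote - (p_asymptote - p_start) exp(-t / alpha)` to
#' raw per-trial correctness by maximizing the Bernoulli likelihood, pooling
#' all supplied sessions aligned on post-reversal trial index. `alpha` (in
#' trials) is the learning parameter: the rate constant of relearning. A 95%
#' percentile bootstrap CI for `alpha` is taken over sessions.
#'
#' When the data carry no evidence of a time course — the exponential model
#' improves on a constant-accuracy model by less than a 2-df likelihood-ratio
#' criterion, or the fitted start and asymptote coincide — `alpha` is
#' unidentifiable and reported `NA` with a diagnostic.
#'
#' @param trials Reversal-phase trial table (>= 1 session).
#' @param n_bootstrap Bootstrap replicates over sessions (default 1000; 0
#'   skips the CI).
#' @param seed Seed for the bootstrap resampling.
#' @return An object of class `learning_fit`: `alpha`, `p_start`,
#'   `p_asymptote`, `ci_alpha`, `fit_form`, `n_bootstrap`, `seed`,
#'   `converged`, `flat`.
#' @export
fit_learning_curve <- function(trials, n_bootstrap = 1000, seed = 1) {
  sess <- interaction(trials$rat_id, trials$session_id, drop = TRUE)
  t <- as.numeric(trials$trial_index)
  y <- as.numeric(trials$correct)
  fit <- fit_learning_once(t, y)
  lr_crit <- stats::qchisq(0.95, df = 2) / 2
  flat <- abs(fit$p_asymptote - fit$p_start) < 0.01 ||
    (fit$nll_constant - fit$nll) < lr_crit
  ci <- c(NA_real_, NA_real_)
  if (!flat && n_bootstrap > 0 && nlevels(sess) > 1) {
    old <- restore_seed(seed)
    on.exit(unrestore_seed(old, seed), add = TRUE)
    lv <- levels(sess)
    alphas <- rep(NA_real_, n_bootstrap)
    sess_idx <- split(seq_along(t), sess)
    for (b in seq_len(n_bootstrap)) {
      take <- sample(lv, length(lv), replace = TRUE)
      rows <- unlist(sess_idx[take], use.names = FALSE)
      fb <- fit_learning_once(t[rows], y[rows])
      if (abs(fb$p_asymptote - fb$p_start) >= 0.01 &&
          (fb$nll_constant - fb$nll) >= lr_crit) alphas[b] <- fb$alpha
    }
    ci <- unname(stats::quantile(alphas, c(0.025, 0.975), na.rm = TRUE))
  }
  structure(list(
    alpha = if (flat) NA_real_ else fit$alpha,
    p_start = fit$p_start,
    p_asymptote = fit$p_asymptote,
    ci_alpha = ci,
    fit_form = "p_asym - (p_asym - p_start) * exp(-trial / alpha)",
    n_bootstrap = n_bootstrap,
    seed = seed,
    converged = fit$converged,
    flat = flat,
    diagnostic = if (flat) "flat curve: alpha unidentifiable" else NA_character_
  ), class = "learning_fit")
}

#' Select discrimination-matched HC/LC stimulus pairs
#'
#' Among all pairs of (SNR, contrast) cells whose per-cell d' estimates agree
#' within `tolerance_dprime`, returns the pair maximizing the absolute
#' difference in mean wager-trial waiting time; the higher-wait cell is
#' labeled HC. This reproduces the selection of stimuli with matched
#' perceptual performance but different confidence used to assign reversal
#' conditions.
#'
#' @param trials Discrimination-phase trials of one rat (no-injection
#'   sessions).
#' @param tolerance_dprime Maximum |d' difference| for a matched pair
#'   (default 0.1).
#' @param min_trials_per_cell Cells with fewer trials are ignored (default 20).
#' @return A tibble with two rows (HC and LC cells: snr, contrast, d_prime,
#'   mean_wait, label).
#' @export
select_matched_stimulus_pairs <- function(trials, tolerance_dprime = 0.1,
                                          min_trials_per_cell = 20) {
  cells <- expand.grid(snr = SNR_LEVELS, contrast = CONTRAST_LEVELS)
  stats_list <- list()
  wager <- select_wager_trials(trials)
  for (i in seq_len(nrow(cells))) {
    sub <- trials[trials$snr == cells$snr[i] & trials$contrast == cells$contrast[i], ]
    wsub <- wager[wager$snr == cells$snr[i] & wager$contrast == cells$contrast[i], ]
    if (nrow(sub) < min_trials_per_cell || nrow(wsub) == 0) next
    if (length(unique(sub$stimulus)) < 2) next
    sdt <- compute_sdt(sub)
    stats_list[[length(stats_list) + 1]] <- tibble::tibble(
      snr = cells$snr[i], contrast = cells$contrast[i],
      d_prime = sdt$d_prime, mean_wait = mean(wsub$waiting_time_s),
      n = nrow(sub)
    )
  }
  cs <- dplyr::bind_rows(stats_list)
  if (nrow(cs) < 2) stop("fewer than two usable stimulus cells", call. = FALSE)
  pairs <- utils::combn(nrow(cs), 2)
  dd <- abs(cs$d_prime[pairs[1, ]] - cs$d_prime[pairs[2, ]])
  dw <- abs(cs$mean_wait[pairs[1, ]] - cs$mean_wait[pairs[2, ]])
  ok <- dd <= tolerance_dprime
  if (!any(ok)) {
    nearest <- order(dd)[seq_len(min(3, length(dd)))]
    msg <- paste(sprintf("(snr %d, contrast %d) vs (snr %d, contrast %d): |d' diff| = %.3f",
                         cs$snr[pairs[1, nearest]], cs$contrast[pairs[1, nearest]],
                         cs$snr[pairs[2, nearest]], cs$contrast[pairs[2, nearest]],
                         dd[nearest]), collapse = "; ")
    stop("no stimulus pair within d' tolerance ", tolerance_dprime,
         "; nearest candidates: ", msg, call. = FALSE)
  }
  best <- which(ok)[which.max(dw[ok])]
  i <- pairs[1, best]; j <- pairs[2, best]
  hc <- if (cs$mean_wait[i] >= cs$mean_wait[j]) i else j
  lc <- if (hc == i) j else i
  out <- cs[c(hc, lc), ]
  out$label <- c("HC", "LC")
  out
}
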