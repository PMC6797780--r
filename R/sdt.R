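# Type-1 signal detection and type-2 (metacognitive) estimation.
# Signal convention: a vertical (V) stimulus is "signal"; a V response to V
# is a hit, a V response to H is a false alarm. d' is symmetric under the
# convention; the criterion flips sign.

#' Type-1 signal detection estimates
#'
#' Computes d' and the decision criterion from a trial table under the
#' equal-variance Gaussian model, with the log-linear correction (0.5 added
#' to every cell, 1 to every denominator) applied always so that rates are
#' strictly inside (0, 1).
#'
#' `d' = qnorm(HR) - qnorm(FAR)`; `c = -0.5 (qnorm(HR) + qnorm(FAR))`.
#'
#' @param trials A trial table with `stimulus` and `choice` columns, or a
#'   data frame with logical columns `is_signal` and `said_signal`.
#' @param phase Phase whose stimulus-response rule defines which choice
#'   "says V". Defaults to the phase of the first trial.
#' @return An object of class `sdt_result`: list with `d_prime`,
#'   `criterion_c`, `hit_rate`, `fa_rate`, `n_signal`, `n_noise`,
#'   `correction_applied`.
#' @export
compute_sdt <- function(trials, phase = NULL) {
  if (all(c("is_signal", "said_signal") %in% names(trials))) {
    is_signal <- trials$is_signal
    said_signal <- trials$said_signal
  } else {
    if (is.null(phase)) phase <- trials$phase[1]
    rule <- rule_for_phase(phase)
    is_signal <- trials$stimulus == "V"
    said_signal <- trials$choice == rule[["V"]]
  }
  n_signal <- sum(is_signal)
  n_noise <- sum(!is_signal)
  if (n_signal == 0 || n_noise == 0) {
    stop("both stimulus classes must be present to estimate d'", call. = FALSE)
  }
  hits <- sum(is_signal & said_signal)
  fas <- sum(!is_signal & said_signal)
  hr <- (hits + 0.5) / (n_signal + 1)
  far <- (fas + 0.5) / (n_noise + 1)
  structure(list(
    d_prime = stats::qnorm(hr) - stats::qnorm(far),
    criterion_c = -0.5 * (stats::qnorm(hr) + stats::qnorm(far)),
    hit_rate = hr, fa_rate = far,
    n_signal = n_signal, n_noise = n_noise,
    correction_applied = TRUE
  ), class = "sdt_result")
}

#' Bin a continuous confidence proxy into ratings
#'
#' Converts per-trial waiting times (or any graded confidence proxy) into
#' `1..K` ratings by empirical quantile cut-points computed on the supplied
#' values. Ties at a cut-point go to the lower bin. If fewer than `K`
#' distinct values exist, `K` is reduced with a warning; the effective K is
#' returned as an attribute.
#'
#' @param values Numeric vector (already wager-filtered waiting times).
#' @param K Number of rating bins (default 4).
#' @return Integer ratings in `1..K_effective`, with attribute `K`.
#' @export
bin_confidence <- function(values, K = 4) {
  stopifnot(K >= 2, all(is.finite(values)))
  n_distinct <- length(unique(values))
  if (n_distinct < K) {
    warning(sprintf("only %d distinct values; reducing K from %d to %d",
                    n_distinct, K, max(2L, n_distinct)), call. = FALSE)
    K <- max(2L, n_distinct)
  }
  repeat {
    cuts <- unique(stats::quantile(values, probs = seq_len(K - 1) / K,
                                   type = 7, names = FALSE))
    ratings <- findInterval(values, cuts, left.open = TRUE) + 1L
    if (length(unique(ratings)) == K || K == 2L) break
    K <- K - 1L   # duplicated cut-points collapse bins; shrink and retry
  }
  attr(ratings, "K") <- max(ratings)
  ratings
}

#' Build a stimulus x response x rating count array
#'
#' @param is_signal,said_signal Logical per-trial vectors.
#' @param ratings Integer ratings `1..K`.
#' @param K Number of rating bins.
#' @return A 2 x 2 x K array with dimnames stimulus (noise, signal) x
#'   response (noise, signal) x rating.
#' @export
rating_counts <- function(is_signal, said_signal, ratings, K = max(ratings)) {
  counts <- array(
    0L, dim = c(2, 2, K),
    dimnames = list(stimulus = c("noise", "signal"),
                    response = c("noise", "signal"),
                    rating = seq_len(K))
  )
  tab <- table(factor(is_signal, c(FALSE, TRUE)),
               factor(said_signal, c(FALSE, TRUE)),
               factor(ratings, seq_len(K)))
  counts[] <- as.integer(tab)
  counts
}

# Type-2 (response-conditional) rating probabilities under the meta-d' model.
# For stimulus mean mu = +/- meta_d / 2 and meta criterion mc = c' * meta_d,
# response-specific type-2 criteria fan out from mc on each side.
meta_d_cell_probs <- function(meta_d, mc, crit_lo, crit_hi, K) {
  # crit_lo: K-1 descending criteria below mc (for "noise" responses)
  # crit_hi: K-1 ascending criteria above mc (for "signal" responses)
  bounds_hi <- c(mc, crit_hi, Inf)
  bounds_lo <- c(mc, crit_lo, -Inf)
  out <- array(NA_real_, dim = c(2, 2, K))
  for (s in 1:2) {
    mu <- if (s == 2) meta_d / 2 else -meta_d / 2
    p_hi <- stats::pnorm(bounds_hi - mu)
    p_sig <- diff(p_hi)                       # rating 1..K for "signal" resp.
    p_lo <- stats::pnorm(bounds_lo - mu)
    p_noi <- -diff(p_lo)                      # rating 1..K for "noise" resp.
    denom_sig <- 1 - stats::pnorm(mc - mu)
    denom_noi <- stats::pnorm(mc - mu)
    out[s, 2, ] <- p_sig / denom_sig
    out[s, 1, ] <- p_noi / denom_noi
  }
  out
}

#' Fit meta-d' by maximum likelihood
#'
#' Fits the equal-variance Gaussian type-2 model of metacognitive
#' sensitivity: holding the type-1 relative criterion `c' = c/d'` fixed, the
#' meta-level sensitivity `meta-d'` and the ordered response-conditional
#' type-2 criteria are estimated by maximizing the multinomial likelihood of
#' the rating counts conditional on (stimulus, response). Every cell of the
#' type-2 tables is padded by `1/(2K)` before fitting so zero cells cannot
#' produce infinite log-likelihoods.
#'
#' @param counts A 2 x 2 x K array from [rating_counts()].
#' @param sdt An [compute_sdt()] result supplying d' and c (type-1 stage,
#'   computed on all trials).
#' @param reltol Optimizer relative tolerance (default 1e-6).
#' @param maxit Maximum function evaluations (default 1e4).
#' @return An object of class `meta_d_result`: `meta_d_prime`, `efficiency`
#'   (meta-d'/d', `NA` with `unstable = TRUE` when `d' <= 0.2`),
#'   `n_rating_bins`, `type2_criteria` (2(K-1) values, noise-side then
#'   signal-side), `log_likelihood`, `converged`.
#' @export
fit_meta_d <- function(counts, sdt, reltol = 1e-6, maxit = 1e4) {
  K <- dim(counts)[3]
  stopifnot(K >= 2, all(counts >= 0))
  d <- sdt$d_prime
  c1 <- sdt$criterion_c
  c_rel <- if (abs(d) > 1e-8) c1 / d else 0
  padded <- counts + 1 / (2 * K)

  nll <- function(theta) {
    meta_d <- theta[1]
    mc <- c_rel * meta_d
    gaps_lo <- exp(theta[2:K])
    gaps_hi <- exp(theta[(K + 1):(2 * K - 1)])
    crit_lo <- mc - cumsum(gaps_lo)
    crit_hi <- mc + cumsum(gaps_hi)
    pr <- meta_d_cell_probs(meta_d, mc, crit_lo, crit_hi, K)
    pr <- pmax(pr, 1e-12)
    -sum(padded * log(pr))
  }

  init <- c(if (abs(d) > 0.1) d else 0.1, rep(log(0.5), 2 * (K - 1)))
  fit <- stats::optim(init, nll, method = "Nelder-Mead",
                      control = list(reltol = reltol, maxit = maxit))
  # polish from a second start if the first failed to converge
  if (fit$convergence != 0) {
    fit2 <- stats::optim(fit$par, nll, method = "Nelder-Mead",
                         control = list(reltol = reltol, maxit = maxit))
    if (fit2$value <= fit$value) fit <- fit2
  }
  meta_d <- fit$par[1]
  mc <- c_rel * meta_d
  crit <- c(rev(mc - cumsum(exp(fit$par[2:K]))),
            mc + cumsum(exp(fit$par[(K + 1):(2 * K - 1)])))
  unstable <- !is.finite(d) || d <= 0.2
  structure(list(
    meta_d_prime = meta_d,
    efficiency = if (unstable) NA_real_ else meta_d / d,
    unstable = unstable,
    n_rating_bins = K,
    type2_criteria = crit,
    log_likelihood = -fit$value,
    converged = fit$convergence == 0,
    d_prime = d, criterion_c = c1
  ), class = "meta_d_result")
}

#' Metacognitive efficiency from a trial table
#'
#' Convenience composition of the full type-2 pipeline: the type-1 stage
#' (d', c) is computed on *all* supplied trials, ratings exist only on wager
#' trials (unrewarded, reinitiated), so both tables enter the fit: waiting
#' times of the wager subset are quantile-binned into `K` ratings and the
#' meta-d' model is fit on their (stimulus, response, rating) counts.
#'
#' @param trials A trial table (all trials of one analysis unit).
#' @param K Number of rating bins (default 4).
#' @param phase Phase for the stimulus-response rule (default: first trial's).
#' @param ... Passed to [fit_meta_d()].
#' @return A `meta_d_result` (see [fit_meta_d()]).
#' @export
metacognitive_efficiency <- function(trials, K = 4, phase = NULL, ...) {
  if (is.null(phase)) phase <- trials$phase[1]
  sdt <- compute_sdt(trials, phase = phase)
  wager <- select_wager_trials(trials)
  if (nrow(wager) < 2 * K) {
    stop("too few wager trials to bin confidence", call. = FALSE)
  }
  ratings <- bin_confidence(wager$waiting_time_s, K = K)
  rule <- rule_for_phase(phase)
  counts <- rating_counts(wager$stimulus == "V",
                          wager$choice == rule[["V"]],
                          ratings, K = attr(ratings, "K"))
  fit_meta_d(counts, sdt, ...)
}
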