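# Permutation inference for two-group contrasts on session-level measures,
# with Bonferroni correction.

#' Two-group permutation test
#'
#' Tests a two-group contrast by permuting group labels at the exchange-unit
#' level (sessions by default: condition labels such as drug or confidence
#' group attach to whole sessions). The statistic is the difference of group
#' means (A - B, first level minus second). Two-sided p value with the +1
#' smoothing convention: `p = (1 + #\{|T*| >= |T|\}) / (n_permutations + 1)`;
#' ties count as exceedances. When the number of units is at most 12 and the
#' number of distinct reassignments does not exceed `n_permutations`, the
#' null is enumerated exactly (with a notice) and `p = #\{|T*| >= |T|\} / M`.
#'
#' @param values Numeric per-unit measurements (e.g. one per session).
#' @param labels Two-level factor/character of group labels, same length.
#' @param n_permutations Number of label permutations (default 10000).
#' @param m_comparisons Bonferroni family size recorded in the result
#'   (default 4: the four strategy measures); correction via [bonferroni()].
#' @param seed Seed for reproducible permutations.
#' @return An object of class `permutation_result`: `stat_observed`, `p_raw`,
#'   `p_corrected`, `m_comparisons`, `n_permutations`, `exact`, `null_mean`,
#'   `null_sd`, `exchange_unit`, `seed`.
#' @export
permutation_test <- function(values, labels, n_permutations = 10000,
                             m_comparisons = 4, seed = 1) {
  ok <- !is.na(values) & !is.na(labels)
  values <- values[ok]; labels <- as.character(labels[ok])
  lv <- unique(labels)
  if (length(lv) != 2) stop("labels must have exactly two levels", call. = FALSE)
  n_a <- sum(labels == lv[1]); n_b <- sum(labels == lv[2])
  if (n_a == 0 || n_b == 0) stop("both groups must be nonempty", call. = FALSE)
  n <- length(values)
  obs <- mean(values[labels == lv[1]]) - mean(values[labels == lv[2]])

  n_distinct <- choose(n, n_a)
  exact <- n <= 12 && n_distinct <= n_permutations
  if (exact) {
    message("exact enumeration over ", n_distinct, " label assignments")
    combos <- utils::combn(n, n_a)
    tot <- sum(values)
    stat <- apply(combos, 2, function(ix) {
      sum(values[ix]) / n_a - (tot - sum(values[ix])) / n_b
    })
    p_raw <- sum(abs(stat) >= abs(obs) - 1e-12) / n_distinct
    n_used <- n_distinct
  } else {
    old <- restore_seed(seed)
    on.exit(unrestore_seed(old, seed), add = TRUE)
    tot <- sum(values)
    stat <- replicate(n_permutations, {
      ix <- sample.int(n, n_a)
      sum(values[ix]) / n_a - (tot - sum(values[ix])) / n_b
    })
    p_raw <- (1 + sum(abs(stat) >= abs(obs) - 1e-12)) / (n_permutations + 1)
    n_used <- n_permutations
  }
  structure(list(
    stat_observed = obs,
    n_permutations = n_used,
    exact = exact,
    p_raw = p_raw,
    p_corrected = min(1, m_comparisons * p_raw),
    m_comparisons = m_comparisons,
    exchange_unit = "session",
    seed = seed,
    null_mean = mean(stat),
    null_sd = stats::sd(stat)
  ), class = "permutation_result")
}

#' Bonferroni correction
#'
#' Multiplies each p value by the family size `m` (default: the number of p
#' values supplied, matching the four strategy measures tested together) and
#' caps at 1.
#'
#' @param p_values Numeric p values in (0, 1].
#' @param m Family size; defaults to `length(p_values)`.
#' @return Corrected p values.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (any(p_values <= 0 | p_values > 1, na.rm = TRUE)) {
    stop("p values must be in (0, 1]", call. = FALSE)
  }
  pmin(1, p_values * m)
}
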