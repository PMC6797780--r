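# Column contract for long-format trial tables. One row per behavioral trial.
TRIAL_COLUMNS <- c(
  "rat_id", "session_id", "trial_index", "phase", "region", "virus", "drug",
  "confidence_group", "snr", "contrast", "stimulus", "choice", "correct",
  "reward_scheduled", "reward_delay_s", "rewarded", "reaction_time_s",
  "waiting_time_s", "reinitiated"
)

TRIAL_ENUMS <- list(
  phase = c("discrimination", "reversal"),
  region = c("ACC", "BLA", "none"),
  virus = c("DREADD", "EGFP", "none"),
  drug = c("CNO", "vehicle", "none"),
  confidence_group = c("HC", "LC", "none"),
  stimulus = c("H", "V"),
  choice = c("left", "right")
)

WAIT_CAP_S <- 40

#' Column names of the trial-table contract
#'
#' @return Character vector of the 19 mandatory columns, in contract order.
#' @export
trial_columns <- function() TRIAL_COLUMNS

#' Validate a trial table
#'
#' Checks a long-format trial table against the data contract: mandatory
#' columns, enum levels, the waiting-time cap (`[0, 40]` s), positive reaction
#' times, and the outcome logic (a rewarded trial must be correct and
#' reward-scheduled and carries no waiting time; a reinitiated trial must carry
#' one; rewarded and reinitiated are mutually exclusive — a trial that is
#' neither timed out at the cap).
#'
#' @param trials A data frame of trials.
#' @return `trials`, invisibly, as a tibble with `trial_index` as integer.
#' @export
validate_trials <- function(trials) {
  missing_cols <- setdiff(TRIAL_COLUMNS, names(trials))
  if (length(missing_cols) > 0) {
    stop("trial table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  trials <- tibble::as_tibble(trials)

  for (col in names(TRIAL_ENUMS)) {
    vals <- trials[[col]]
    bad <- which(!is.na(vals) & !(vals %in% TRIAL_ENUMS[[col]]))
    if (length(bad) > 0) {
      stop(sprintf("invalid value '%s' for column '%s' at row %d",
                   vals[bad[1]], col, bad[1]), call. = FALSE)
    }
  }
  bad_snr <- which(!is.na(trials$snr) & !(trials$snr %in% c(2L, 3L, 4L)))
  if (length(bad_snr) > 0) {
    stop(sprintf("invalid snr '%s' at row %d (levels are 2, 3, 4)",
                 trials$snr[bad_snr[1]], bad_snr[1]), call. = FALSE)
  }
  bad_con <- which(!is.na(trials$contrast) &
                     !(trials$contrast %in% c(40L, 60L, 80L)))
  if (length(bad_con) > 0) {
    stop(sprintf("invalid contrast '%s' at row %d (levels are 40, 60, 80)",
                 trials$contrast[bad_con[1]], bad_con[1]), call. = FALSE)
  }

  wt <- trials$waiting_time_s
  bad_wt <- which(!is.na(wt) & (wt < 0 | wt > WAIT_CAP_S))
  if (length(bad_wt) > 0) {
    stop(sprintf("waiting_time_s = %s at row %d outside [0, %d] (trial cap)",
                 format(wt[bad_wt[1]]), bad_wt[1], WAIT_CAP_S), call. = FALSE)
  }
  rt <- trials$reaction_time_s
  bad_rt <- which(!is.na(rt) & rt <= 0)
  if (length(bad_rt) > 0) {
    stop(sprintf("reaction_time_s must be positive (row %d)", bad_rt[1]),
         call. = FALSE)
  }

  rewarded <- isTRUE_vec(trials$rewarded)
  reinit <- isTRUE_vec(trials$reinitiated)
  bad <- which(rewarded & !(isTRUE_vec(trials$correct) &
                              isTRUE_vec(trials$reward_scheduled)))
  if (length(bad) > 0) {
    stop(sprintf("row %d: rewarded trial must be correct and reward-scheduled",
                 bad[1]), call. = FALSE)
  }
  bad <- which(rewarded & !is.na(wt))
  if (length(bad) > 0) {
    stop(sprintf("row %d: rewarded trial cannot carry a waiting time (wait is censored by reward delivery)",
                 bad[1]), call. = FALSE)
  }
  bad <- which(reinit & is.na(wt))
  if (length(bad) > 0) {
    stop(sprintf("row %d: reinitiated trial must carry a waiting time", bad[1]),
         call. = FALSE)
  }
  bad <- which(rewarded & reinit)
  if (length(bad) > 0) {
    stop(sprintf("row %d: a trial cannot be both rewarded and reinitiated",
                 bad[1]), call. = FALSE)
  }

  trials$trial_index <- as.integer(trials$trial_index)
  invisible(trials)
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Read a trial table from CSV
#'
#' Reads a UTF-8, comma-separated trial table with the exact header of
#' [trial_columns()]. Empty cells are parsed as absent (`NA`). Records are
#' returned grouped by session and sorted chronologically by `trial_index`.
#'
#' @param path Path to a CSV file.
#' @return A tibble of validated trials, ordered by `rat_id`, `session_id`,
#'   `trial_index`.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols(),
                                  progress = FALSE, show_col_types = FALSE))
  missing_cols <- setdiff(TRIAL_COLUMNS, header)
  if (length(missing_cols) > 0) {
    stop("CSV is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  trials <- readr::read_csv(
    path,
    col_types = readr::cols(
      rat_id = readr::col_character(),
      session_id = readr::col_character(),
      trial_index = readr::col_integer(),
      phase = readr::col_character(),
      region = readr::col_character(),
      virus = readr::col_character(),
      drug = readr::col_character(),
      confidence_group = readr::col_character(),
      snr = readr::col_integer(),
      contrast = readr::col_integer(),
      stimulus = readr::col_character(),
      choice = readr::col_character(),
      correct = readr::col_logical(),
      reward_scheduled = readr::col_logical(),
      reward_delay_s = readr::col_double(),
      rewarded = readr::col_logical(),
      reaction_time_s = readr::col_double(),
      waiting_time_s = readr::col_double(),
      reinitiated = readr::col_logical()
    ),
    progress = FALSE, show_col_types = FALSE
  )
  missing_cols <- setdiff(TRIAL_COLUMNS, names(trials))
  if (length(missing_cols) > 0) {
    stop("CSV is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  trials <- validate_trials(trials)
  dplyr::arrange(trials, .data$rat_id, .data$session_id, .data$trial_index)
}

#' Write a trial table to CSV
#'
#' Writes the exact column contract (see [trial_columns()]); absent values
#' become empty cells, booleans are written as `true`/`false`.
#'
#' @param trials A validated trial table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  if (nrow(trials) > 0) trials <- validate_trials(trials)
  out <- tibble::as_tibble(trials)[, TRIAL_COLUMNS, drop = FALSE]
  for (col in c("correct", "reward_scheduled", "rewarded", "reinitiated")) {
    out[[col]] <- ifelse(is.na(out[[col]]), NA_character_,
                         ifelse(out[[col]], "true", "false"))
  }
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Remove reaction-time outlier trials
#'
#' Removes, within each session, trials whose reaction time deviates from the
#' session mean by more than `k` session standard deviations. Mean and SD are
#' computed once on the unfiltered session (single pass; the filter is not
#' re-iterated). Sessions with fewer than two reaction times are returned
#' unchanged.
#'
#' @param trials A trial table.
#' @param k Deviation multiplier (default 3 standard deviations).
#' @return The filtered trial table, with attribute `n_removed`.
#' @export
filter_rt_outliers <- function(trials, k = 3) {
  keep <- rep(TRUE, nrow(trials))
  sess <- interaction(trials$rat_id, trials$session_id, drop = TRUE)
  for (s in levels(sess)) {
    idx <- which(sess == s)
    rt <- trials$reaction_time_s[idx]
    ok <- !is.na(rt)
    if (sum(ok) < 2) next
    m <- mean(rt[ok])
    sd_rt <- stats::sd(rt[ok])
    if (!is.finite(sd_rt) || sd_rt == 0) next
    keep[idx[ok]] <- abs(rt[ok] - m) <= k * sd_rt
  }
  out <- trials[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Select wager trials
#'
#' Keeps only trials informative about time wagering: unrewarded trials that
#' carry a waiting time (i.e. the animal reinitiated). Rewarded trials are
#' excluded because reward delivery censors the intended wait; timeout trials
#' carry no waiting time.
#'
#' @param trials A trial table.
#' @return The subset of wager trials.
#' @export
select_wager_trials <- function(trials) {
  keep <- !isTRUE_vec(trials$rewarded) & !is.na(trials$waiting_time_s)
  trials[keep, , drop = FALSE]
}

#' Z-score a per-trial measure within sessions
#'
#' Standardizes `values` within each session to mean 0 using the population
#' (1/n) standard deviation, so that e.g. `{1, 2, 3}` maps to
#' `{-1.2247, 0, 1.2247}`. Sessions with zero variance yield all zeros with a
#' warning. `NA` values are left `NA` and ignored in the session moments.
#'
#' @param values Numeric per-trial measure.
#' @param sessions Session identifier per trial (any vector; grouping unit).
#' @return Numeric vector of standardized values, same length as `values`.
#' @export
zscore_within_session <- function(values, sessions) {
  stopifnot(length(values) == length(sessions))
  out <- rep(NA_real_, length(values))
  sess <- interaction(sessions, drop = TRUE)
  for (s in levels(sess)) {
    idx <- which(sess == s)
    v <- values[idx]
    ok <- is.finite(v)
    if (sum(ok) < 2) {
      stop("session '", s, "' has fewer than 2 finite values", call. = FALSE)
    }
    m <- mean(v[ok])
    sd_pop <- sqrt(mean((v[ok] - m)^2))
    if (sd_pop == 0) {
      warning("session '", s, "' has zero variance; returning zeros",
              call. = FALSE)
      out[idx][ok] <- 0
    } else {
      out[idx][ok] <- (v[ok] - m) / sd_pop
    }
  }
  out
}
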