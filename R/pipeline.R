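# End-to-end orchestration: configuration, the full analysis pipeline, and a
# plain-text + figure report over its outputs.

#' Analysis configuration
#'
#' A single flat configuration for [run_pipeline()]. Every analysis constant
#' of the task is surfaced here with its canonical default: the 3 SD
#' reaction-time filter, K = 4 confidence bins, the 100-trial learning
#' window, 10,000 permutations with a Bonferroni family of 4, the 70%
#' reward schedule with 8 s mean delay and 40 s cap, and the 2 s minimum
#' wait.
#'
#' @param seed Global seed for simulation and resampling.
#' @param input_trials Optional path to a trial CSV; when `NULL`, a cohort is
#'   simulated.
#' @param out_dir Output directory for result CSVs and the run log.
#' @param rt_filter_k RT outlier multiplier (default 3).
#' @param confidence_bins Rating bins K for meta-d' (default 4).
#' @param window Learning-curve window (default 100).
#' @param n_permutations Permutations per contrast (default 10000).
#' @param bonferroni_m Bonferroni family size (default 4).
#' @param n_bootstrap Bootstrap replicates for the learning-fit CI.
#' @param group_by Grouping keys for the metacognition table.
#' @param n_rats,sessions_per_rat,n_trials_discrimination,n_trials_reversal
#'   Simulated cohort dimensions (used when `input_trials` is `NULL`).
#' @param simulate_regions Manipulation arms to simulate alongside vehicle.
#' @param observer,learner,reward Optional parameter objects overriding the
#'   calibrated defaults.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(seed = 1,
                            input_trials = NULL,
                            out_dir = tempfile("metawager-run-"),
                            rt_filter_k = 3,
                            confidence_bins = 4,
                            window = 100,
                            n_permutations = 10000,
                            bonferroni_m = 4,
                            n_bootstrap = 200,
                            group_by = c("rat_id", "drug", "region"),
                            n_rats = 3,
                            sessions_per_rat = 4,
                            n_trials_discrimination = 300,
                            n_trials_reversal = 160,
                            simulate_regions = "none",
                            observer = NULL,
                            learner = NULL,
                            reward = NULL) {
  stopifnot(rt_filter_k > 0, confidence_bins >= 2, window >= 1,
            n_permutations >= 1, bonferroni_m >= 1)
  structure(as.list(environment()), class = "analysis_config")
}

#' Read an analysis configuration from a YAML file
#'
#' Flat key-value YAML whose keys are [analysis_config()] argument names.
#'
#' @param path YAML file path.
#' @return An `analysis_config` object.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(analysis_config, vals)
}

simulate_cohort <- function(config) {
  obs <- if (is.null(config$observer)) build_default_observer() else config$observer
  lrn <- if (is.null(config$learner)) learner_params() else config$learner
  rew <- if (is.null(config$reward)) reward_schedule_params() else config$reward
  parts <- list()
  for (region in config$simulate_regions) {
    spec <- manipulation_spec(region)
    drug <- if (region == "none") "vehicle" else "CNO"
    virus <- if (region == "none") "none" else "DREADD"
    parts[[paste0("disc-", region)]] <- simulate_experiment(
      n_rats = config$n_rats, sessions_per_rat = config$sessions_per_rat,
      n_trials = config$n_trials_discrimination, phase = "discrimination",
      obs = obs, lrn = lrn, rew = rew, spec = spec,
      confidence_group = "none", drug = drug, virus = virus,
      seed = config$seed + match(region, config$simulate_regions)
    )
    for (grp in c("HC", "LC")) {
      parts[[paste0("rev-", region, "-", grp)]] <- simulate_experiment(
        n_rats = config$n_rats, sessions_per_rat = config$sessions_per_rat,
        n_trials = config$n_trials_reversal, phase = "reversal",
        obs = obs, lrn = lrn, rew = rew, spec = spec,
        confidence_group = grp, drug = drug, virus = virus,
        seed = config$seed + 100 * match(region, config$simulate_regions) +
          1000 * (grp == "HC")
      )
    }
  }
  dplyr::bind_rows(parts)
}

#' Run the full analysis pipeline
#'
#' Reads (or simulates) trials, applies the reaction-time filter, and
#' produces the four result tables plus a structured run log: `metad.csv`
#' (d', criterion, meta-d', efficiency per group), `strategies.csv`
#' (per-session Win-Stay / Lose-Switch / repetition-index profiles),
#' `learning.csv` (exponential learning fits per condition),
#' `permtests.csv` (HC-vs-LC permutation contrasts on the four strategy
#' measures, Bonferroni-corrected). Deterministic given `config$seed`; every
#' output row carries its grouping keys and denominators; the log records
#' all filter counts.
#'
#' @param config An [analysis_config()].
#' @return Invisibly, a list with the four tibbles, the filtered trials, the
#'   log lines, and `out_dir`; the CSVs and `run-log.txt` are written to
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("metawager pipeline; seed = %d", config$seed))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  trials <- stage("input", {
    if (!is.null(config$input_trials)) read_trials(config$input_trials)
    else simulate_cohort(config)
  })
  log_lines <- c(log_lines, sprintf("trials in: %d", nrow(trials)))

  filtered <- stage("rt_filter", filter_rt_outliers(trials, k = config$rt_filter_k))
  n_removed <- attr(filtered, "n_removed")
  log_lines <- c(log_lines,
                 sprintf("rt filter (k = %g): removed %d of %d trials (%.2f%%)",
                         config$rt_filter_k, n_removed, nrow(trials),
                         100 * n_removed / nrow(trials)))

  disc <- filtered[filtered$phase == "discrimination", ]
  rev <- filtered[filtered$phase == "reversal", ]
  log_lines <- c(log_lines,
                 sprintf("wager trials (discrimination): %d of %d",
                         nrow(select_wager_trials(disc)), nrow(disc)))

  metad <- stage("metad", {
    if (nrow(disc) == 0) tibble::tibble() else
      dplyr::group_by(disc, dplyr::across(dplyr::all_of(config$group_by))) |>
        dplyr::group_modify(function(d, key) {
          fit <- tryCatch(metacognitive_efficiency(d, K = config$confidence_bins),
                          error = function(e) NULL)
          if (is.null(fit)) return(tibble::tibble())
          tibble::tibble(d_prime = fit$d_prime, criterion_c = fit$criterion_c,
                         meta_d_prime = fit$meta_d_prime,
                         efficiency = fit$efficiency,
                         K = fit$n_rating_bins, converged = fit$converged,
                         n_trials = nrow(d))
        }) |>
        dplyr::ungroup()
  })

  strategies <- stage("strategies", {
    if (nrow(rev) == 0) tibble::tibble() else
      strategy_profiles_by_session(rev, block = "first_half")
  })

  learning <- stage("learning", {
    if (nrow(rev) == 0) tibble::tibble() else {
      groups <- dplyr::distinct(rev, .data$region, .data$drug,
                                .data$confidence_group)
      out <- list()
      for (i in seq_len(nrow(groups))) {
        sub <- dplyr::semi_join(rev, groups[i, ],
                                by = c("region", "drug", "confidence_group"))
        fit <- fit_learning_curve(sub, n_bootstrap = config$n_bootstrap,
                                  seed = config$seed + i)
        out[[i]] <- tibble::tibble(
          region = groups$region[i], drug = groups$drug[i],
          confidence_group = groups$confidence_group[i],
          alpha = fit$alpha, p_start = fit$p_start,
          p_asymptote = fit$p_asymptote,
          ci_alpha_low = fit$ci_alpha[1], ci_alpha_high = fit$ci_alpha[2],
          n_sessions = length(unique(paste(sub$rat_id, sub$session_id))),
          n_trials = nrow(sub), converged = fit$converged
        )
      }
      dplyr::bind_rows(out)
    }
  })

  permtests <- stage("permtests", {
    measures <- c("p_win_stay", "p_lose_switch_after_correct",
                  "p_lose_switch_after_incorrect", "rri")
    if (nrow(strategies) == 0 ||
        length(unique(strategies$confidence_group)) < 2) {
      tibble::tibble()
    } else {
      out <- list()
      for (region in unique(strategies$region)) {
        sub <- strategies[strategies$region == region, ]
        if (length(unique(sub$confidence_group)) < 2) next
        for (ms in measures) {
          pt <- permutation_test(sub[[ms]], sub$confidence_group,
                                 n_permutations = config$n_permutations,
                                 m_comparisons = config$bonferroni_m,
                                 seed = config$seed)
          out[[paste(region, ms)]] <- tibble::tibble(
            region = region, measure = ms, stat_observed = pt$stat_observed,
            p_raw = pt$p_raw, p_corrected = pt$p_corrected,
            n_permutations = pt$n_permutations, exact = pt$exact,
            n_sessions = sum(!is.na(sub[[ms]]))
          )
        }
      }
      dplyr::bind_rows(out)
    }
  })

  bundle <- list(metad = metad, strategies = strategies, learning = learning,
                 permtests = permtests, trials = filtered,
                 log = log_lines, out_dir = config$out_dir)
  readr::write_csv(metad, file.path(config$out_dir, "metad.csv"))
  readr::write_csv(strategies, file.path(config$out_dir, "strategies.csv"))
  readr::write_csv(learning, file.path(config$out_dir, "learning.csv"))
  readr::write_csv(permtests, file.path(config$out_dir, "permtests.csv"))
  writeLines(log_lines, file.path(config$out_dir, "run-log.txt"))
  invisible(bundle)
}

report_section <- function(title, df, digits = 3) {
  if (is.null(df) || nrow(df) == 0) {
    return(c(paste("##", title), "", "no data", ""))
  }
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], round, digits)
  c(paste("##", title), "",
    paste(utils::capture.output(print.data.frame(as.data.frame(df))),
          collapse = "\n"), "")
}

#' Generate a static report from a pipeline result bundle
#'
#' Writes a plain-markdown report summarizing the analysis surfaces (waiting
#' time and reaction time against SNR, metacognition table, learning fits,
#' strategy contrasts) plus ggplot figures saved alongside. Sections without
#' data are marked "no data". No network access is used.
#'
#' @param bundle Result of [run_pipeline()].
#' @param path Output file (default `report.md` inside the bundle's out_dir).
#' @return `path`, invisibly.
#' @export
generate_report <- function(bundle, path = file.path(bundle$out_dir, "report.md")) {
  needed <- c("metad", "strategies", "learning", "permtests", "trials")
  missing <- setdiff(needed, names(bundle))
  if (length(missing) > 0) {
    stop("bundle is missing member(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  lines <- c("# Time-wagering analysis report", "")

  disc <- bundle$trials[bundle$trials$phase == "discrimination", ]
  if (nrow(disc) > 0) {
    wager <- select_wager_trials(disc)
    by_snr <- dplyr::group_by(wager, .data$region, .data$drug, .data$snr) |>
      dplyr::summarise(mean_wait_s = mean(.data$waiting_time_s),
                       n_wager = dplyr::n(), .groups = "drop")
    rt_snr <- dplyr::group_by(disc, .data$region, .data$drug, .data$snr) |>
      dplyr::summarise(mean_rt_s = mean(.data$reaction_time_s),
                       accuracy = mean(.data$correct),
                       n = dplyr::n(), .groups = "drop")
    lines <- c(lines, report_section("Waiting time by SNR (wager trials)", by_snr),
               report_section("Reaction time and accuracy by SNR", rt_snr))
    fig <- file.path(dirname(path), "waiting-by-snr.png")
    p <- ggplot2::ggplot(by_snr, ggplot2::aes(x = .data$snr, y = .data$mean_wait_s,
                                              color = .data$region)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "SNR", y = "mean waiting time (s)")
    try(suppressMessages(ggplot2::ggsave(fig, p, width = 5, height = 4, dpi = 120)),
        silent = TRUE)
  } else {
    lines <- c(lines, report_section("Waiting time by SNR (wager trials)", NULL),
               report_section("Reaction time and accuracy by SNR", NULL))
  }

  rev <- bundle$trials[bundle$trials$phase == "reversal", ]
  if (nrow(rev) > 0 && max(rev$trial_index) + 1 >= 100) {
    curves <- list()
    for (grp in unique(rev$confidence_group)) {
      cv <- sliding_window_accuracy(rev[rev$confidence_group == grp, ],
                                    window = min(100, max(rev$trial_index)))
      cv$confidence_group <- grp
      curves[[grp]] <- cv
    }
    curves <- dplyr::bind_rows(curves)
    fig2 <- file.path(dirname(path), "learning-curves.png")
    p2 <- ggplot2::ggplot(curves,
                          ggplot2::aes(x = .data$trial_center, y = .data$accuracy,
                                       color = .data$confidence_group)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "trial after reversal", y = "p(correct)")
    try(suppressMessages(ggplot2::ggsave(fig2, p2, width = 5, height = 4, dpi = 120)),
        silent = TRUE)
  }

  lines <- c(lines,
             report_section("Metacognition (d', meta-d', efficiency)", bundle$metad),
             report_section("Learning fits", bundle$learning),
             report_section("Strategy contrasts (permutation tests)", bundle$permtests),
             "", paste("log:", paste(bundle$log, collapse = " | ")))
  writeLines(lines, path)
  invisible(path)
}
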