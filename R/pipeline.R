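#' Simulate a complete neurofeedback experiment
#'
#' Builds the lexicon, balanced word sets and per-session trial schedules,
#' synthesizes the continuous session recordings with ground truth, and
#' simulates the learner's keystroke responses. Defaults mirror the study
#' design the toolkit emulates: six 20-trial sessions, four contacts at
#' 512 Hz, 10 old / 10 new probes per session.
#'
#' @param n_sessions number of sessions (must match the learner's gain
#'   trajectory length).
#' @param n_trials trials per session, or a vector of per-session counts
#'   (truncated sessions are allowed).
#' @param learner a [learner_model()]; `NULL` gives unit gains and no
#'   behavior coupling.
#' @param noise,osc,spikes component models for the signal generator.
#' @param seed master integer seed; every sub-seed derives from it.
#' @return an `nf_experiment` list: `lexicon`, per-session `plans`,
#'   `recordings`, `truths`, `responses`, the models and the seed.
#' @export
simulate_experiment <- function(n_sessions = 6, n_trials = 20,
                                learner = NULL,
                                noise = noise_model(),
                                osc = oscillation_spec(),
                                spikes = spike_model(),
                                seed = 1) {
  if (is.null(learner)) {
    learner <- learner_model(theta_gain_by_session = rep(1, n_sessions))
  }
  if (length(learner$theta_gain_by_session) != n_sessions) {
    stop("learner gain trajectory length must equal n_sessions",
         call. = FALSE)
  }
  counts <- rep_len(n_trials, n_sessions)
  full <- max(counts)
  with_seed(seed, {
    sub <- sample.int(.Machine$integer.max - 1, 4 + 4 * n_sessions)
    lexicon <- build_lexicon(6 * full * n_sessions, seed = sub[1])
    plans <- recordings <- truths <- responses <- vector("list", n_sessions)
    for (s in seq_len(n_sessions)) {
      rows <- ((s - 1) * 6 * full + 1):(s * 6 * full)
      ws <- make_word_sets(structure(lexicon[rows, ],
                                     class = c("lexicon", "data.frame")),
                           n_sets = full, seed = sub[4 + 4 * (s - 1) + 1])
      plan <- schedule_session(ws, n_old = full %/% 2,
                               n_new = full - full %/% 2,
                               seed = sub[4 + 4 * (s - 1) + 2])
      if (counts[s] < full) plan <- truncate_session(plan, counts[s])
      gs <- generate_session(plan, learner, noise, osc, spikes,
                             session = s, seed = sub[4 + 4 * (s - 1) + 3])
      plans[[s]] <- plan
      recordings[[s]] <- gs$recording
      truths[[s]] <- gs$truth
      responses[[s]] <- simulate_responses(plan, gs$truth,
                                           seed = sub[4 + 4 * (s - 1) + 4])
    }
    structure(list(lexicon = lexicon, plans = plans,
                   recordings = recordings, truths = truths,
                   responses = responses, learner = learner,
                   noise = noise, osc = osc, spikes = spikes, seed = seed),
              class = "nf_experiment")
  })
}

#' @export
print.nf_experiment <- function(x, ...) {
  cat(sprintf("<nf_experiment> %d sessions (%s trials), seed %d\n",
              length(x$plans),
              paste(vapply(x$plans, function(p) length(p$trials), 0L),
                    collapse = "/"),
              x$seed))
  invisible(x)
}

#' Run the offline analysis battery over an experiment
#'
#' Per-trial adaptive-ASR spectra for every session, then the four
#' analyses: binwise correct-versus-error comparison (Task 1 grouping,
#' falling back to Task 2 when too few sessions have error trials, as when
#' accuracy is near ceiling), binwise first-versus-final session
#' comparison, one-way session ANOVA with Tukey post-hoc on log theta
#' power, and the three subset-ruled Spearman correlations.
#'
#' @param experiment an [simulate_experiment()] result, or a list with
#'   `plans`, `recordings`, `responses`.
#' @param config an [nf_config()].
#' @param asr_policy offline ASR policy (default `"adaptive"`).
#' @param alpha familywise level.
#' @param freq_range binwise test range, Hz.
#' @return a `stats_report` list: `spectra` (combined `trial_spectra`),
#'   `correct_error` (+ `correct_error_grouping`), `first_final`, `anova`,
#'   `correlations`, `alpha`.
#' @export
analyze_experiment <- function(experiment, config = nf_config(),
                               asr_policy = "adaptive", alpha = 0.05,
                               freq_range = c(1, 100)) {
  n_sessions <- length(experiment$plans)
  sp <- vector("list", n_sessions)
  for (s in seq_len(n_sessions)) {
    sp[[s]] <- psd_per_trial(experiment$recordings[[s]],
                             experiment$plans[[s]],
                             responses = experiment$responses[[s]],
                             session = s, asr_policy = asr_policy,
                             config = config)
  }
  spectra <- bind_spectra(sp)
  ce <- NULL
  grouping <- NA_character_
  for (g in c("task1", "task2")) {
    ce <- tryCatch(compare_correct_error(spectra, g, alpha, freq_range),
                   thetanf_insufficient_data = function(e) NULL)
    if (!is.null(ce)) { grouping <- g; break }
  }
  ff <- compare_first_final(spectra, alpha, freq_range)
  an <- session_anova(spectra$meta$log_theta, spectra$meta$session,
                      alpha = alpha)
  co <- theta_behavior_correlation(spectra$meta, alpha = alpha)
  structure(list(spectra = spectra, correct_error = ce,
                 correct_error_grouping = grouping, first_final = ff,
                 anova = an, correlations = co, alpha = alpha),
            class = "stats_report")
}

#' @export
print.stats_report <- function(x, ...) {
  cat("== Offline analysis battery ==\n")
  if (is.null(x$correct_error)) {
    cat("Correct vs error: insufficient error trials under both groupings\n")
  } else {
    cat(sprintf("Correct vs error (%s, %d sessions): %d/%d bins significant\n",
                x$correct_error_grouping, attr(x$correct_error, "n_units"),
                sum(x$correct_error$significant), nrow(x$correct_error)))
  }
  sig <- x$first_final$significant
  cat(sprintf("First vs final session: %d/%d bins significant%s\n",
              sum(sig), length(sig),
              if (any(sig)) sprintf(" (at %s Hz)", paste(
                x$first_final$freq[sig], collapse = ", ")) else ""))
  print(x$anova)
  cat("Theta-behavior correlations (Holm over the defined analyses):\n")
  for (i in seq_len(nrow(x$correlations))) {
    r <- x$correlations[i, ]
    if (r$defined) {
      cat(sprintf("  %s: rho = %+.2f, p = %.3f (Holm %.3f)\n",
                  r$analysis, r$rho, r$p_raw, r$p_holm))
    } else {
      cat(sprintf("  %s: undefined (constant scores)\n", r$analysis))
    }
  }
  invisible(x)
}

#' Write a stats report (and per-trial metrics) to disk
#'
#' The JSON report carries all four analyses with raw and Holm-adjusted
#' p-values; the binwise tables can also be written as CSV.
#'
#' @param report a [analyze_experiment()] result.
#' @param path JSON output path.
#' @param seed optional seed to embed for reproducibility.
#' @export
write_stats_report <- function(report, path, seed = NULL) {
  out <- list(
    seed = seed,
    alpha = report$alpha,
    correct_error = if (!is.null(report$correct_error)) c(
      list(grouping = report$correct_error_grouping,
           n_sessions = attr(report$correct_error, "n_units")),
      as.list(as.data.frame(report$correct_error))) else NULL,
    first_final = as.list(as.data.frame(report$first_final)),
    anova = report$anova[c("F", "df_between", "df_within", "p",
                           "eta_squared")],
    tukey = report$anova$tukey,
    correlations = as.data.frame(report$correlations),
    per_trial = report$spectra$meta
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null")
  invisible(path)
}

#' @rdname write_stats_report
#' @param binwise a `binwise_test` data frame.
#' @export
write_binwise_csv <- function(binwise, path) {
  utils::write.csv(as.data.frame(binwise), path, row.names = FALSE)
  invisible(path)
}

# Bernoulli success draws with logit linear in standardized log theta.
learner_success <- function(learner, theta_factor) {
  z <- log(theta_factor)
  z <- if (stats::sd(z) > 0) (z - mean(z)) / stats::sd(z) else 0 * z
  p <- stats::plogis(stats::qlogis(learner$base_success_prob) +
                       2 * learner$behavior_coupling * z)
  list(task1 = stats::runif(length(z)) < p,
       task2 = stats::runif(length(z)) < p)
}

#' Simulate per-trial spectra for one session without the full recording
#'
#' Monte-Carlo studies of the statistics battery need many replicates;
#' synthesizing only the 13 s encoding epochs (skipping rest and
#' inter-trial intervals) runs the identical spectral pipeline at a
#' fraction of the cost. Probe assignment and recognition outcomes follow
#' the same learner model as [generate_session()].
#'
#' @param session session index into the learner's gain trajectory.
#' @param learner,noise,osc,spikes component models (`spikes = NULL` for
#'   clean epochs).
#' @param n_trials,n_old trial count and number of old probes.
#' @param asr_policy `"none"`, `"adaptive"` or `"fixed"`; non-none
#'   policies calibrate on a freshly generated rest-length background.
#' @param config an [nf_config()].
#' @param seed integer seed.
#' @return a `trial_spectra` object (see [psd_per_trial()]).
#' @export
simulate_session_spectra <- function(session, learner = learner_model(),
                                     noise = noise_model(),
                                     osc = oscillation_spec(),
                                     spikes = NULL,
                                     n_trials = 20, n_old = n_trials %/% 2,
                                     asr_policy = "none",
                                     config = nf_config(), seed = NULL) {
  gain <- learner$theta_gain_by_session[session]
  with_seed(seed, {
    jitter <- stats::rlnorm(n_trials, 0, learner$jitter_sd)
    theta_factor <- gain * jitter
    succ <- learner_success(learner, theta_factor)
    probe_is_old <- sample(rep(c(TRUE, FALSE), c(n_old, n_trials - n_old)))
    calib <- NULL
    if (asr_policy != "none") {
      rest <- generate_background(20, 512, noise)
      calib <- asr_calibrate(rest, asr_params(window = config$asr_window))
    }
    db <- pw <- NULL
    exc <- kk <- theta <- numeric(n_trials)
    for (tr in seq_len(n_trials)) {
      ge <- generate_trial_epoch(13, 512, noise, osc, spikes,
                                 theta_factor = theta_factor[tr])
      full13 <- ge$epoch
      exc[tr] <- compute_exceedance(full13)$fraction
      k <- switch(asr_policy, adaptive = select_k(exc[tr]),
                  fixed = config$asr_k, none = NA_real_)
      kk[tr] <- k
      if (!is.na(k)) full13 <- asr_clean(full13, calib, k = k)$epoch
      win <- full13
      win$samples <- win$samples[, -(seq_len(round(512))), drop = FALSE]
      psd <- welch_psd(win, config$welch_window_s, config$welch_overlap)
      avg <- colMeans(psd$psd)
      theta[tr] <- band_power(psd, config$theta_band[1],
                              config$theta_band[2])$mean
      if (is.null(db)) {
        db <- pw <- matrix(0, n_trials, length(psd$freqs))
        freqs <- psd$freqs
      }
      pw[tr, ] <- avg
      db[tr, ] <- 10 * log10(pmax(avg, 1e-12))
    }
    hit <- probe_is_old & succ$task1
    meta <- data.frame(session = session, trial = seq_len(n_trials),
                       exceedance = exc, k_used = kk, theta_power = theta,
                       log_theta = log10(theta),
                       probe_is_old = probe_is_old,
                       task1_correct = succ$task1, hit = hit,
                       task2_correct = hit & succ$task2)
    structure(list(freqs = freqs, db = db, power = pw, meta = meta),
              class = "trial_spectra")
  })
}
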