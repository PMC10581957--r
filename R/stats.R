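#' Holm-Bonferroni step-down correction
#'
#' Step-down familywise error control: the sorted p-values are multiplied
#' by `m, m-1, ...`, made monotone non-decreasing and capped at 1;
#' hypotheses with adjusted p below `alpha` are rejected.
#'
#' @param pvalues numeric vector of raw p-values in `[0, 1]`.
#' @param alpha familywise significance level.
#' @return a list with `adjusted` p-values (same order as the input) and
#'   logical `reject`.
#' @examples
#' holm_bonferroni(c(0.01, 0.04, 0.03))$adjusted  # 0.03 0.06 0.06
#' @export
holm_bonferroni <- function(pvalues, alpha = 0.05) {
  if (length(pvalues) == 0) {
    return(list(adjusted = numeric(0), reject = logical(0)))
  }
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  adjusted <- stats::p.adjust(pvalues, method = "holm")
  list(adjusted = adjusted, reject = adjusted < alpha)
}

# Per-trial correctness flags derived from responses + plan; the same
# denominators score_recognition uses.
response_flags <- function(responses, plan) {
  is_old <- vapply(plan$trials, `[[`, logical(1), "probe_is_old")
  a1 <- as.character(responses$task1_answer)
  truth1 <- ifelse(is_old, "old", "new")
  correct1 <- !is.na(a1) & a1 == truth1
  hit <- is_old & !is.na(a1) & a1 == "old"
  pos_true <- vapply(plan$trials, function(t)
    if (t$probe_is_old) t$correct_position else NA_integer_, integer(1))
  correct2 <- hit & !is.na(responses$task2_answer) &
    responses$task2_answer == pos_true
  data.frame(trial = seq_along(plan$trials), probe_is_old = is_old,
             task1_correct = correct1, hit = hit, task2_correct = correct2)
}

#' Per-trial electrode-averaged spectra for one session
#'
#' The offline spectral pipeline: filter the recording, then per trial
#' extract the 13 s encoding epoch, measure its exceedance fraction,
#' choose the ASR cutoff (adaptive rule, fixed `k`, or no cleaning),
#' clean, drop the 1 s lead, estimate the Welch PSD and average it across
#' electrodes. The dB transform is `10 * log10(uV^2/Hz)` with a `1e-12`
#' floor.
#'
#' @param recording continuous [signal_epoch()] for the session.
#' @param plan the session's plan.
#' @param responses optional responses for correctness flags.
#' @param session session index recorded in the output.
#' @param asr_policy `"adaptive"` (exceedance-driven `k`), `"fixed"`, or
#'   `"none"`.
#' @param config an [nf_config()] (filter/Welch/ASR settings; `asr_k` is
#'   the fixed-policy cutoff).
#' @param preprocessed set to `TRUE` if `recording` is already filtered.
#' @return a `trial_spectra` object: `freqs`, `db` (trials x frequencies,
#'   electrode-averaged dB), `power` (linear electrode-averaged PSD), and
#'   `meta` (session, trial, exceedance, `k_used`, theta power and
#'   correctness flags).
#' @export
psd_per_trial <- function(recording, plan, responses = NULL, session = 1,
                          asr_policy = c("adaptive", "fixed", "none"),
                          config = nf_config(), preprocessed = FALSE) {
  asr_policy <- match.arg(asr_policy)
  rec <- if (preprocessed) recording else preprocess(recording, config$filter)
  calib <- NULL
  if (asr_policy != "none") {
    rest <- epoch_slice(rec, 0, plan$timeline$rest)
    calib <- asr_calibrate(rest, asr_params(window = config$asr_window))
  }
  n_trials <- length(plan$trials)
  db <- pw <- NULL
  exc <- kk <- theta <- numeric(n_trials)
  for (tr in seq_len(n_trials)) {
    ep <- tryCatch(
      extract_encoding_epoch(rec, trial_onset(plan, tr)),
      error = function(e) stop(sprintf("trial %d: %s", tr,
                                       conditionMessage(e)), call. = FALSE))
    full13 <- ep$full13
    exc[tr] <- compute_exceedance(full13)$fraction
    k <- switch(asr_policy,
                adaptive = select_k(exc[tr]),
                fixed = config$asr_k,
                none = NA_real_)
    kk[tr] <- k
    if (!is.na(k)) full13 <- asr_clean(full13, calib, k = k)$epoch
    n_lead <- round(1 * rec$fs)
    win <- full13
    win$samples <- full13$samples[, -(seq_len(n_lead)), drop = FALSE]
    psd <- welch_psd(win, config$welch_window_s, config$welch_overlap)
    avg <- colMeans(psd$psd)
    theta[tr] <- band_power(psd, config$theta_band[1],
                            config$theta_band[2])$mean
    if (is.null(db)) {
      db <- matrix(0, n_trials, length(psd$freqs))
      pw <- matrix(0, n_trials, length(psd$freqs))
      freqs <- psd$freqs
    }
    pw[tr, ] <- avg
    db[tr, ] <- 10 * log10(pmax(avg, 1e-12))
  }
  flags <- if (!is.null(responses)) response_flags(responses, plan) else
    data.frame(trial = seq_len(n_trials), probe_is_old = NA,
               task1_correct = NA, hit = NA, task2_correct = NA)
  meta <- cbind(data.frame(session = session, trial = seq_len(n_trials),
                           exceedance = exc, k_used = kk,
                           theta_power = theta,
                           log_theta = log10(theta)),
                flags[, -1, drop = FALSE])
  structure(list(freqs = freqs, db = db, power = pw, meta = meta),
            class = "trial_spectra")
}

#' Combine per-session trial spectra
#'
#' @param ... `trial_spectra` objects (or a single list of them) sharing
#'   one frequency grid.
#' @return a combined `trial_spectra`.
#' @export
bind_spectra <- function(...) {
  xs <- list(...)
  if (length(xs) == 1 && !inherits(xs[[1]], "trial_spectra")) xs <- xs[[1]]
  f0 <- xs[[1]]$freqs
  for (x in xs) stopifnot(identical(x$freqs, f0))
  structure(list(freqs = f0,
                 db = do.call(rbind, lapply(xs, `[[`, "db")),
                 power = do.call(rbind, lapply(xs, `[[`, "power")),
                 meta = do.call(rbind, lapply(xs, `[[`, "meta"))),
            class = "trial_spectra")
}

insufficient_data <- function(msg) {
  cond <- simpleError(msg)
  class(cond) <- c("thetanf_insufficient_data", class(cond))
  stop(cond)
}

binwise_result <- function(freqs, stat, p_raw, direction, alpha, test,
                           n_units) {
  hb <- holm_bonferroni(p_raw, alpha)
  structure(data.frame(freq = freqs, stat = stat, p_raw = p_raw,
                       p_holm = hb$adjusted, significant = hb$reject,
                       direction = direction),
            test = test, alpha = alpha, n_units = n_units,
            class = c("binwise_test", "data.frame"))
}

#' Binwise correct-versus-error spectral comparison
#'
#' For each session the mean dB spectrum of correct trials and of error
#' trials is formed (sessions in which every trial was answered correctly,
#' or none was, are excluded); each frequency bin is then compared with a
#' paired t-test across sessions, Holm-corrected over bins.
#'
#' @param spectra a (combined) `trial_spectra` with correctness flags.
#' @param grouping `"task1"` (old/new answer, all trials) or `"task2"`
#'   (position answer, restricted to old probes answered "old").
#' @param alpha familywise level.
#' @param freq_range bins entering the test, Hz.
#' @return a `binwise_test` data frame (`freq`, `stat`, `p_raw`, `p_holm`,
#'   `significant`, `direction` = mean correct minus error dB); the number
#'   of contributing sessions is in `attr(, "n_units")`.
#' @export
compare_correct_error <- function(spectra, grouping = c("task1", "task2"),
                                  alpha = 0.05, freq_range = c(1, 100)) {
  grouping <- match.arg(grouping)
  meta <- spectra$meta
  use <- if (grouping == "task1") rep(TRUE, nrow(meta)) else meta$hit
  flag <- if (grouping == "task1") meta$task1_correct else meta$task2_correct
  if (any(is.na(flag[use]))) {
    stop("spectra carry no correctness flags; supply responses to psd_per_trial",
         call. = FALSE)
  }
  sel <- which(spectra$freqs >= freq_range[1] & spectra$freqs <= freq_range[2])
  sessions <- sort(unique(meta$session))
  cs <- es <- NULL
  used <- integer(0)
  for (s in sessions) {
    i_c <- which(meta$session == s & use & flag)
    i_e <- which(meta$session == s & use & !flag)
    if (length(i_c) == 0 || length(i_e) == 0) next
    cs <- rbind(cs, colMeans(spectra$db[i_c, sel, drop = FALSE]))
    es <- rbind(es, colMeans(spectra$db[i_e, sel, drop = FALSE]))
    used <- c(used, s)
  }
  if (length(used) < 2) {
    insufficient_data(sprintf(
      "only %d session(s) have both correct and error trials under %s grouping",
      length(used), grouping))
  }
  d <- cs - es
  stat <- p <- numeric(ncol(d))
  for (j in seq_len(ncol(d))) {
    if (stats::sd(d[, j]) == 0) {
      stat[j] <- 0; p[j] <- 1
    } else {
      tt <- stats::t.test(d[, j])
      stat[j] <- unname(tt$statistic); p[j] <- tt$p.value
    }
  }
  binwise_result(spectra$freqs[sel], stat, p, colMeans(d), alpha,
                 test = paste0("paired t (correct - error, ", grouping, ")"),
                 n_units = length(used))
}

#' Binwise first-versus-final session comparison
#'
#' Compares the trial-level dB values of the final session against the
#' first session per frequency bin with a two-sample Wilcoxon rank-sum
#' test, Holm-corrected over bins. Unequal trial counts (truncated
#' sessions) are handled by the rank-sum test itself.
#'
#' @inheritParams compare_correct_error
#' @return a `binwise_test` data frame; `direction` is the median dB
#'   difference (final minus first).
#' @export
compare_first_final <- function(spectra, alpha = 0.05,
                                freq_range = c(1, 100)) {
  meta <- spectra$meta
  sessions <- sort(unique(meta$session))
  if (length(sessions) < 2) insufficient_data("need at least 2 sessions")
  i1 <- which(meta$session == sessions[1])
  i2 <- which(meta$session == sessions[length(sessions)])
  if (length(i1) < 2 || length(i2) < 2) {
    stop("first and final sessions need at least 2 trials each",
         call. = FALSE)
  }
  sel <- which(spectra$freqs >= freq_range[1] & spectra$freqs <= freq_range[2])
  stat <- p <- dir <- numeric(length(sel))
  for (j in seq_along(sel)) {
    a <- spectra$db[i2, sel[j]]; b <- spectra$db[i1, sel[j]]
    wt <- suppressWarnings(stats::wilcox.test(a, b))
    stat[j] <- unname(wt$statistic); p[j] <- wt$p.value
    dir[j] <- stats::median(a) - stats::median(b)
  }
  binwise_result(spectra$freqs[sel], stat, p, dir, alpha,
                 test = "Wilcoxon rank sum (final - first)",
                 n_units = length(i1) + length(i2))
}

#' One-way session ANOVA with Tukey post-hoc on log theta power
#'
#' Classical one-way ANOVA of per-trial log10 theta power across sessions
#' (`eta^2 = SS_between / SS_total`), followed by Tukey's HSD on all
#' session pairs (Tukey-Kramer for unequal trial counts).
#'
#' @param log_theta per-trial log10 theta power values.
#' @param session parallel vector of session indices.
#' @param alpha familywise level for the Tukey intervals.
#' @return a `session_anova` list: `F`, `df_between`, `df_within`, `p`,
#'   `eta_squared`, and `tukey` (data frame of pairwise differences with
#'   adjusted p-values).
#' @export
session_anova <- function(log_theta, session, alpha = 0.05) {
  stopifnot(length(log_theta) == length(session))
  g <- factor(session)
  if (nlevels(g) < 2) stop("need at least 2 sessions", call. = FALSE)
  if (any(table(g) < 2)) stop("each session needs at least 2 trials",
                              call. = FALSE)
  if (stats::var(log_theta) == 0) {
    stop("degenerate input: all theta power values identical",
         call. = FALSE)
  }
  fit <- stats::aov(log_theta ~ g)
  tab <- summary(fit)[[1]]
  ssb <- tab["g", "Sum Sq"]
  ssw <- tab["Residuals", "Sum Sq"]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
  tukey <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], row.names = NULL)
  structure(list(F = tab["g", "F value"],
                 df_between = tab["g", "Df"],
                 df_within = tab["Residuals", "Df"],
                 p = tab["g", "Pr(>F)"],
                 eta_squared = ssb / (ssb + ssw),
                 tukey = tukey), class = "session_anova")
}

#' @export
print.session_anova <- function(x, ...) {
  cat(sprintf("One-way session ANOVA: F(%d, %d) = %.3f, eta^2 = %.3f, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$eta_squared, x$p))
  sig <- x$tukey[x$tukey$p_adj < 0.05, , drop = FALSE]
  if (nrow(sig)) {
    cat("Tukey pairs with adjusted p < 0.05:\n")
    for (i in seq_len(nrow(sig))) {
      cat(sprintf("  %s: diff = %+.3f, p = %.4g\n", sig$pair[i],
                  sig$diff[i], sig$p_adj[i]))
    }
  } else cat("No Tukey pair significant at 0.05\n")
  invisible(x)
}

# All permutations of 1..n as an (n! x n) matrix.
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  p <- all_permutations(n - 1)
  out <- matrix(0L, n * nrow(p), n)
  for (i in seq_len(n)) {
    rows <- (i - 1) * nrow(p) + seq_len(nrow(p))
    out[rows, 1] <- i
    rest <- seq_len(n)[-i]
    out[rows, -1] <- matrix(rest[p], nrow(p))
  }
  out
}

spearman_rho <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(NA_real_)
  stats::cor(rx, ry)
}

# Two-sided Spearman p: exact permutation enumeration for n <= 8 (ties via
# average ranks), t approximation otherwise.
spearman_pvalue <- function(x, y, exact_max_n = 8) {
  n <- length(x)
  rho <- spearman_rho(x, y)
  if (is.na(rho)) return(list(rho = NA_real_, p = NA_real_))
  if (n <= exact_max_n) {
    rx <- rank(x); ry <- rank(y)
    P <- all_permutations(n)
    rxp <- matrix(rx[P], nrow(P))
    rxp <- rxp - rowMeans(rxp)
    ryc <- ry - mean(ry)
    denom <- sqrt(rowSums(rxp^2) * sum(ryc^2))
    rho_all <- as.vector(rxp %*% ryc) / denom
    p <- mean(abs(rho_all) >= abs(rho) - 1e-12)
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-300))
    p <- 2 * stats::pt(-abs(tt), n - 2)
  }
  list(rho = rho, p = min(p, 1))
}

#' Session-level correlations between theta power and recognition scores
#'
#' The three correlational analyses, each a Spearman rank correlation over
#' sessions with its own subset rule for the theta summary:
#' (a) mean theta power of all trials against Task 1 accuracy;
#' (b) mean theta power of old-probe trials against Task 1 recall;
#' (c) mean theta power of old probes correctly answered "old" against
#' Task 2 accuracy. P-values are exact-permutation for up to 8 sessions
#' and Holm-corrected across the (defined) analyses; an analysis whose
#' score series has zero variance is flagged undefined and leaves the
#' Holm family.
#'
#' @param trials trial-level data frame with columns `session`,
#'   `theta_power`, `probe_is_old`, `task1_correct`, `hit` (old probe
#'   answered "old") and `task2_correct` — the `meta` component of a
#'   combined [psd_per_trial()] result has exactly these.
#' @param alpha familywise level.
#' @return a `theta_correlations` data frame: `analysis`, `rho`, `p_raw`,
#'   `p_holm`, `significant`, `n_sessions`, `defined`; per-session paired
#'   values are in `attr(, "pairs")`.
#' @export
theta_behavior_correlation <- function(trials, alpha = 0.05) {
  sessions <- sort(unique(trials$session))
  if (length(sessions) < 4) {
    insufficient_data("need at least 4 sessions for rank correlation")
  }
  per <- lapply(sessions, function(s) {
    d <- trials[trials$session == s, ]
    n_old <- sum(d$probe_is_old)
    n_hit <- sum(d$hit)
    data.frame(
      session = s,
      theta_all = mean(d$theta_power),
      theta_old = if (n_old) mean(d$theta_power[d$probe_is_old]) else NA,
      theta_hit = if (n_hit) mean(d$theta_power[d$hit]) else NA,
      task1_accuracy = 100 * mean(d$task1_correct),
      task1_recall = if (n_old) 100 * n_hit / n_old else NA,
      task2_accuracy = if (n_hit) 100 * sum(d$task2_correct) / n_hit else NA)
  })
  per <- do.call(rbind, per)
  specs <- list(
    task1_accuracy = c("theta_all", "task1_accuracy"),
    task1_recall = c("theta_old", "task1_recall"),
    task2_accuracy = c("theta_hit", "task2_accuracy"))
  res <- lapply(names(specs), function(id) {
    x <- per[[specs[[id]][1]]]; y <- per[[specs[[id]][2]]]
    ok <- stats::complete.cases(x, y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 4 || stats::sd(y) == 0 || stats::sd(x) == 0) {
      return(data.frame(analysis = id, rho = NA_real_, p_raw = NA_real_,
                        n_sessions = length(x), defined = FALSE))
    }
    sp <- spearman_pvalue(x, y)
    data.frame(analysis = id, rho = sp$rho, p_raw = sp$p,
               n_sessions = length(x), defined = TRUE)
  })
  res <- do.call(rbind, res)
  res$p_holm <- NA_real_
  res$significant <- NA
  if (any(res$defined)) {
    hb <- holm_bonferroni(res$p_raw[res$defined], alpha)
    res$p_holm[res$defined] <- hb$adjusted
    res$significant[res$defined] <- hb$reject
  }
  structure(res[, c("analysis", "rho", "p_raw", "p_holm", "significant",
                    "n_sessions", "defined")],
            pairs = per, alpha = alpha,
            class = c("theta_correlations", "data.frame"))
}
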