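#' Trial timeline constants
#'
#' One trial is: encoding (five words, each shown for 1.6 s after a 1.0 s
#' blank, i.e. a 2.6 s cycle, 13 s in total), an 8 s old/new recognition
#' question (Task 1), an 8 s presentation-order question (Task 2), and a
#' 10 s intermittent feedback period. Each session opens with a 20 s rest.
#' The 12 s analysis window drops the first cycle's 1 s blank.
#'
#' @param rest rest duration at session start, seconds.
#' @param word_gap blank before each word, seconds.
#' @param word_duration word presentation time, seconds.
#' @param words_per_trial number of words encoded per trial.
#' @param task1,task2 recognition question durations, seconds.
#' @param feedback feedback bar display duration, seconds.
#' @return a named list of timeline constants.
#' @export
nf_timeline <- function(rest = 20, word_gap = 1.0, word_duration = 1.6,
                        words_per_trial = 5, task1 = 8, task2 = 8,
                        feedback = 10) {
  list(rest = rest, word_gap = word_gap, word_duration = word_duration,
       words_per_trial = words_per_trial, task1 = task1, task2 = task2,
       feedback = feedback)
}

#' @rdname nf_timeline
#' @param timeline a timeline list from `nf_timeline()`.
#' @export
encoding_duration <- function(timeline = nf_timeline()) {
  timeline$words_per_trial * (timeline$word_gap + timeline$word_duration)
}

#' @rdname nf_timeline
#' @export
analysis_duration <- function(timeline = nf_timeline()) {
  encoding_duration(timeline) - timeline$word_gap
}

#' @rdname nf_timeline
#' @export
trial_duration <- function(timeline = nf_timeline()) {
  encoding_duration(timeline) + timeline$task1 + timeline$task2 +
    timeline$feedback
}

#' Build a synthetic word lexicon with familiarity scores
#'
#' Stand-in for a large familiarity-rated word database: opaque tokens with
#' Gaussian familiarity scores.
#'
#' @param n_words number of words (>= 6).
#' @param familiarity_mean,familiarity_sd Gaussian parameters of the
#'   familiarity scores.
#' @param seed integer seed.
#' @return a data frame with columns `token` and `familiarity`, class
#'   `lexicon`.
#' @export
build_lexicon <- function(n_words, familiarity_mean = 5,
                          familiarity_sd = 1, seed = NULL) {
  if (!is.numeric(n_words) || n_words < 6) {
    stop("'n_words' must be at least 6", call. = FALSE)
  }
  n_words <- as.integer(n_words)
  with_seed(seed, {
    tokens <- sprintf("w%05d", seq_len(n_words))
    fam <- stats::rnorm(n_words, familiarity_mean, familiarity_sd)
    structure(data.frame(token = tokens, familiarity = fam,
                         stringsAsFactors = FALSE),
              class = c("lexicon", "data.frame"))
  })
}

set_means <- function(assign_idx, fam) {
  vapply(assign_idx, function(ix) mean(fam[ix]), numeric(1))
}

#' Partition a lexicon into familiarity-balanced six-word sets
#'
#' Draws `6 * n_sets` words and partitions them into disjoint six-word
#' sets whose mean familiarities all lie within `tolerance` of the grand
#' mean: a greedy snake assignment over familiarity-sorted words followed
#' by pairwise swap refinement between the extreme sets.
#'
#' @param lexicon a [build_lexicon()] data frame.
#' @param n_sets number of sets (one per trial; default 20).
#' @param tolerance maximum allowed deviation of any set mean from the
#'   grand mean; `NULL` uses 0.05 standard deviations of the lexicon's
#'   familiarity.
#' @param seed integer seed for the word draw.
#' @param max_iter swap-refinement iteration cap.
#' @return a list of `n_sets` word sets, each a list with `words`
#'   (6 tokens) and `mean_familiarity`.
#' @export
make_word_sets <- function(lexicon, n_sets = 20, tolerance = NULL,
                           seed = NULL, max_iter = 2000) {
  need <- 6L * n_sets
  if (nrow(lexicon) < need) {
    stop(sprintf("lexicon has %d words; %d needed for %d sets",
                 nrow(lexicon), need, n_sets), call. = FALSE)
  }
  if (is.null(tolerance)) {
    tolerance <- 0.05 * stats::sd(lexicon$familiarity)
    if (!is.finite(tolerance)) tolerance <- 0
  }
  with_seed(seed, {
    pick <- sample(nrow(lexicon), need)
    fam <- lexicon$familiarity[pick]
    tok <- lexicon$token[pick]
    ord <- order(fam, decreasing = TRUE)
    # snake deal: 1..k, k..1, ... keeps initial means close
    lanes <- rep(c(seq_len(n_sets), rev(seq_len(n_sets))), length.out = need)
    assign_idx <- split(ord, lanes)[as.character(seq_len(n_sets))]
    grand <- mean(fam)
    dev <- function(a) max(abs(set_means(a, fam) - grand))
    best <- dev(assign_idx)
    it <- 0
    while (best > tolerance && it < max_iter) {
      it <- it + 1
      m <- set_means(assign_idx, fam)
      hi <- which.max(m); lo <- which.min(m)
      # best single swap between the extreme sets
      improved <- FALSE
      gap_best <- best
      swap <- NULL
      for (a in assign_idx[[hi]]) for (b in assign_idx[[lo]]) {
        d <- (fam[a] - fam[b]) / 6
        new_hi <- m[hi] - d; new_lo <- m[lo] + d
        cand <- max(abs(c(m[-c(hi, lo)], new_hi, new_lo) - grand))
        if (cand < gap_best - 1e-12) {
          gap_best <- cand; swap <- c(a, b); improved <- TRUE
        }
      }
      if (!improved) break
      assign_idx[[hi]][assign_idx[[hi]] == swap[1]] <- swap[2]
      assign_idx[[lo]][assign_idx[[lo]] == swap[2]] <- swap[1]
      best <- dev(assign_idx)
    }
    if (best > tolerance) {
      cond <- simpleError(sprintf(
        "could not balance word sets to tolerance %.4g; best spread %.4g",
        tolerance, best))
      class(cond) <- c("thetanf_balancing_failure", class(cond))
      cond$best_spread <- best
      stop(cond)
    }
    lapply(assign_idx, function(ix) {
      list(words = tok[ix], mean_familiarity = mean(fam[ix]))
    })
  })
}

#' Schedule one neurofeedback session
#'
#' Assigns each word set to a trial, picks the held-out word, randomizes
#' the presentation order of the remaining five, and sets up the old/new
#' probe design: `n_old` trials probe one of the presented words (uniform
#' position), `n_new` trials probe the held-out word, in uniformly
#' shuffled order.
#'
#' @param word_sets list of six-word sets from [make_word_sets()].
#' @param n_old,n_new number of old-probe and new-probe trials (default
#'   10/10 for a 20-trial session).
#' @param timeline timeline constants, see [nf_timeline()].
#' @param seed integer seed.
#' @return a `session_plan`: list of `trials` (each with `word_set`,
#'   `presented`, `probe`, `probe_is_old`, `correct_position`) plus the
#'   `timeline`.
#' @export
schedule_session <- function(word_sets, n_old = 10, n_new = 10,
                             timeline = nf_timeline(), seed = NULL) {
  n_trials <- n_old + n_new
  if (length(word_sets) != n_trials) {
    stop(sprintf("%d word sets supplied for %d trials",
                 length(word_sets), n_trials), call. = FALSE)
  }
  with_seed(seed, {
    is_old <- sample(rep(c(TRUE, FALSE), c(n_old, n_new)))
    trials <- vector("list", n_trials)
    for (i in seq_len(n_trials)) {
      ws <- word_sets[[i]]
      held_ix <- sample(6, 1)
      presented <- sample(ws$words[-held_ix])
      if (is_old[i]) {
        pos <- sample(5, 1)
        trials[[i]] <- list(word_set = ws, presented = presented,
                            probe = presented[pos], probe_is_old = TRUE,
                            correct_position = pos)
      } else {
        trials[[i]] <- list(word_set = ws, presented = presented,
                            probe = ws$words[held_ix], probe_is_old = FALSE,
                            correct_position = NA_integer_)
      }
    }
    structure(list(trials = trials, timeline = timeline),
              class = "session_plan")
  })
}

#' @export
print.session_plan <- function(x, ...) {
  n_old <- sum(vapply(x$trials, `[[`, logical(1), "probe_is_old"))
  cat(sprintf("<session_plan> %d trials (%d old / %d new probes), %.0f s\n",
              length(x$trials), n_old, length(x$trials) - n_old,
              session_duration(x)))
  invisible(x)
}

#' Truncate a session plan after a given trial
#'
#' Sessions may end early (for example after a system error); downstream
#' statistics accept the resulting unequal trial counts.
#'
#' @param plan a `session_plan`.
#' @param n_trials number of trials to keep.
#' @return the truncated `session_plan`.
#' @export
truncate_session <- function(plan, n_trials) {
  stopifnot(n_trials >= 1, n_trials <= length(plan$trials))
  plan$trials <- plan$trials[seq_len(n_trials)]
  plan
}

#' Session geometry
#'
#' @param plan a `session_plan`.
#' @param trial_index 1-based trial number.
#' @return `trial_onset` gives the encoding-period start in seconds from
#'   session start; `session_duration` the total session length.
#' @export
trial_onset <- function(plan, trial_index) {
  tl <- plan$timeline
  if (trial_index < 1 || trial_index > length(plan$trials)) {
    stop(sprintf("trial index %d out of 1..%d", trial_index,
                 length(plan$trials)), call. = FALSE)
  }
  tl$rest + (trial_index - 1) * trial_duration(tl)
}

#' @rdname trial_onset
#' @export
session_duration <- function(plan) {
  plan$timeline$rest + length(plan$trials) * trial_duration(plan$timeline)
}

#' Event list for one trial
#'
#' @param plan a `session_plan`.
#' @param trial_index 1-based trial number.
#' @return a data frame of events `(onset, duration, trial_index,
#'   event_type)` in seconds from session start; the first trial is
#'   preceded by the session's rest event. Event types are `rest`, `word`,
#'   `probe_task1`, `probe_task2`, `feedback`.
#' @export
trial_events <- function(plan, trial_index) {
  tl <- plan$timeline
  enc0 <- trial_onset(plan, trial_index)
  cyc <- tl$word_gap + tl$word_duration
  ev <- data.frame(
    onset = c(enc0 + tl$word_gap + cyc * (seq_len(tl$words_per_trial) - 1),
              enc0 + encoding_duration(tl),
              enc0 + encoding_duration(tl) + tl$task1,
              enc0 + encoding_duration(tl) + tl$task1 + tl$task2),
    duration = c(rep(tl$word_duration, tl$words_per_trial),
                 tl$task1, tl$task2, tl$feedback),
    trial_index = trial_index,
    event_type = c(rep("word", tl$words_per_trial),
                   "probe_task1", "probe_task2", "feedback"),
    stringsAsFactors = FALSE
  )
  if (trial_index == 1) {
    ev <- rbind(data.frame(onset = 0, duration = tl$rest, trial_index = 0,
                           event_type = "rest", stringsAsFactors = FALSE),
                ev)
  }
  ev
}

#' @rdname trial_events
#' @export
session_events <- function(plan) {
  do.call(rbind, lapply(seq_along(plan$trials),
                        function(i) trial_events(plan, i)))
}

#' Score a session's recognition responses
#'
#' Task 1 accuracy is the proportion of trials whose old/new answer is
#' correct (missing answers count as incorrect and stay in the
#' denominator). Recall is the proportion of old probes answered "old".
#' Task 2 accuracy is the proportion of correct position answers among the
#' old probes that were correctly answered "old" in Task 1; with an empty
#' denominator the score is undefined (`NA`) and flagged, never 0.
#'
#' @param responses a data frame with one row per trial and columns
#'   `task1_answer` ("old"/"new"/`NA`) and `task2_answer` (integer or
#'   `NA`), as from [simulate_responses()].
#' @param plan the `session_plan` the responses belong to.
#' @return a `recognition_scores` list: `task1_accuracy`, `task1_recall`,
#'   `task2_accuracy` (percent), `task2_defined`, and the counts used.
#' @export
score_recognition <- function(responses, plan) {
  n_trials <- length(plan$trials)
  if (nrow(responses) != n_trials) {
    stop(sprintf("%d responses for %d trials", nrow(responses), n_trials),
         call. = FALSE)
  }
  is_old <- vapply(plan$trials, `[[`, logical(1), "probe_is_old")
  truth1 <- ifelse(is_old, "old", "new")
  a1 <- as.character(responses$task1_answer)
  correct1 <- !is.na(a1) & a1 == truth1
  said_old <- !is.na(a1) & a1 == "old"
  hits <- is_old & said_old
  n_old <- sum(is_old)
  pos_true <- vapply(plan$trials, function(t)
    if (t$probe_is_old) t$correct_position else NA_integer_, integer(1))
  correct2 <- hits & !is.na(responses$task2_answer) &
    responses$task2_answer == pos_true
  task2_defined <- sum(hits) > 0
  structure(list(
    task1_accuracy = 100 * sum(correct1) / n_trials,
    task1_recall = if (n_old > 0) 100 * sum(hits) / n_old else NA_real_,
    task2_accuracy = if (task2_defined) 100 * sum(correct2) / sum(hits)
                     else NA_real_,
    task2_defined = task2_defined,
    n_trials = n_trials, n_old = n_old, n_hits = sum(hits)
  ), class = "recognition_scores")
}

#' @export
print.recognition_scores <- function(x, ...) {
  cat(sprintf("Task 1 accuracy %.1f%%, recall %.1f%%; Task 2 accuracy %s\n",
              x$task1_accuracy, x$task1_recall,
              if (x$task2_defined) sprintf("%.1f%%", x$task2_accuracy)
              else "undefined (no correctly recognized old probes)"))
  invisible(x)
}
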