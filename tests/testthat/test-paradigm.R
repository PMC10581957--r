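test_that("lexicon construction is deterministic and validates its size", {
  a <- build_lexicon(1000, seed = 4)
  b <- build_lexicon(1000, seed = 4)
  expect_identical(a, b)
  expect_equal(nrow(a), 1000)
  expect_false(any(duplicated(a$token)))
  expect_error(build_lexicon(5), "at least 6")
})

test_that("word sets are disjoint, six-a-piece and familiarity balanced", {
  lex <- build_lexicon(120, familiarity_mean = 5, familiarity_sd = 1,
                       seed = 8)
  ws <- make_word_sets(lex, n_sets = 20, tolerance = 0.25, seed = 9)
  expect_length(ws, 20)
  words <- unlist(lapply(ws, `[[`, "words"))
  expect_length(words, 120)
  expect_false(any(duplicated(words)))
  # recompute the means independently from the lexicon
  fam <- setNames(lex$familiarity, lex$token)
  means <- vapply(ws, function(w) mean(fam[w$words]), numeric(1))
  expect_equal(means, vapply(ws, `[[`, numeric(1), "mean_familiarity"))
  expect_lte(diff(range(means)), 0.5)
})

test_that("zero-spread lexicons balance trivially and infeasible ones fail loudly", {
  flat <- build_lexicon(60, familiarity_sd = 0, seed = 1)
  ws <- make_word_sets(flat, 10, tolerance = 0, seed = 2)
  expect_length(ws, 10)
  wide <- build_lexicon(36, familiarity_sd = 10, seed = 3)
  expect_error(make_word_sets(wide, 6, tolerance = 1e-12, seed = 4,
                              max_iter = 5),
               class = "thetanf_balancing_failure")
  expect_error(make_word_sets(flat, 11), "needed")
})

test_that("the default schedule has 10 old and 10 new probes with valid trials", {
  plan <- small_plan(20, seed = 7)
  is_old <- vapply(plan$trials, `[[`, logical(1), "probe_is_old")
  expect_length(plan$trials, 20)
  expect_equal(sum(is_old), 10)
  for (t in plan$trials) {
    expect_length(t$presented, 5)
    expect_true(all(t$presented %in% t$word_set$words))
    if (t$probe_is_old) {
      expect_identical(t$probe, t$presented[t$correct_position])
    } else {
      expect_false(t$probe %in% t$presented)
      expect_true(is.na(t$correct_position))
    }
  }
  # schedule conservation: 6 distinct words per trial consumed
  words <- unlist(lapply(plan$trials, function(t) t$word_set$words))
  expect_length(unique(words), 120)
})

test_that("all-new schedules carry no correct positions", {
  lex <- build_lexicon(36, seed = 1)
  ws <- make_word_sets(lex, 6, seed = 2)
  plan <- schedule_session(ws, n_old = 0, n_new = 6, seed = 3)
  expect_true(all(is.na(vapply(plan$trials, `[[`, integer(1),
                               "correct_position"))))
  expect_error(schedule_session(ws, n_old = 4, n_new = 4), "word sets")
})

test_that("old-probe positions are uniform on 1..5 across seeds", {
  lex <- build_lexicon(36, seed = 10)
  ws <- make_word_sets(lex, 6, seed = 11)
  pos <- integer(0)
  for (s in 1:1000) {
    plan <- schedule_session(ws, n_old = 6, n_new = 0, seed = s)
    pos <- c(pos, vapply(plan$trials, `[[`, integer(1), "correct_position"))
  }
  expect_gt(chisq.test(table(factor(pos, levels = 1:5)))$p.value, 0.001)
})

test_that("the trial timeline yields 13 s encoding epochs and monotone events", {
  tl <- nf_timeline()
  expect_equal(encoding_duration(tl), 13)
  expect_equal(analysis_duration(tl), 12)
  plan <- small_plan(4, seed = 20)
  ev1 <- trial_events(plan, 1)
  # first trial preceded by the 20 s rest; words at 1.0 + 2.6k
  expect_equal(ev1$onset[1], 0)
  expect_equal(ev1$duration[1], 20)
  expect_equal(ev1$onset[2:6], 20 + 1.0 + 2.6 * (0:4))
  expect_true(all(ev1$duration[2:6] == 1.6))
  ev <- session_events(plan)
  expect_true(!is.unsorted(ev$onset))
  ends <- ev$onset + ev$duration
  expect_true(all(ev$onset[-1] - ends[-nrow(ev)] > -1e-9))
  # last event closes the session
  expect_equal(max(ends), session_duration(plan))
  expect_error(trial_events(plan, 5), "out of")
})

test_that("recognition scoring reproduces the hand-counted example", {
  plan <- small_plan(20, seed = 30)
  is_old <- vapply(plan$trials, `[[`, logical(1), "probe_is_old")
  old_ix <- which(is_old); new_ix <- which(!is_old)
  task1 <- ifelse(is_old, "old", "new")
  task2 <- rep(NA_integer_, 20)
  # 18/20 task-1 correct: one miss (old -> "new"), one false alarm
  task1[old_ix[1]] <- "new"
  task1[new_ix[1]] <- "old"
  # 9 hits; 6 of them with the correct position, 3 wrong
  hits <- old_ix[-1]
  for (i in seq_along(hits)) {
    cp <- plan$trials[[hits[i]]]$correct_position
    task2[hits[i]] <- if (i <= 6) cp else (cp %% 5) + 1
  }
  sc <- score_recognition(data.frame(trial = 1:20, task1_answer = task1,
                                     task2_answer = task2), plan)
  expect_equal(sc$task1_accuracy, 90)
  expect_equal(sc$task1_recall, 90)
  expect_equal(sc$task2_accuracy, 100 * 6 / 9, tolerance = 1e-12)
})

test_that("perfect answers score 100/100/100 and scoring is order invariant", {
  plan <- small_plan(10, seed = 31)
  resp <- data.frame(
    trial = 1:10,
    task1_answer = vapply(plan$trials, function(t)
      if (t$probe_is_old) "old" else "new", ""),
    task2_answer = vapply(plan$trials, `[[`, integer(1),
                          "correct_position"))
  sc <- score_recognition(resp, plan)
  expect_equal(c(sc$task1_accuracy, sc$task1_recall, sc$task2_accuracy),
               c(100, 100, 100))
  # permute trials and responses jointly
  perm <- sample(10)
  plan2 <- plan; plan2$trials <- plan$trials[perm]
  sc2 <- score_recognition(resp[perm, ], plan2)
  expect_equal(sc2$task1_accuracy, sc$task1_accuracy)
  expect_equal(sc2$task2_accuracy, sc$task2_accuracy)
})

test_that("missing answers count against accuracy and empty task-2 denominators flag", {
  plan <- small_plan(4, seed = 32)
  resp <- data.frame(trial = 1:4, task1_answer = NA_character_,
                     task2_answer = NA_integer_)
  sc <- score_recognition(resp, plan)
  expect_equal(sc$task1_accuracy, 0)
  expect_false(sc$task2_defined)
  expect_true(is.na(sc$task2_accuracy))
  expect_error(score_recognition(resp[1:3, ], plan), "responses")
})

test_that("truncated sessions keep a consistent timeline", {
  plan <- truncate_session(small_plan(20, seed = 33), 17)
  expect_length(plan$trials, 17)
  expect_equal(session_duration(plan), 20 + 17 * 39)
})
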