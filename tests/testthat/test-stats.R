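test_that("Holm step-down reproduces the hand-worked example and edge cases", {
  hb <- holm_bonferroni(c(0.01, 0.04, 0.03))
  expect_equal(hb$adjusted, c(0.03, 0.06, 0.06))
  expect_equal(holm_bonferroni(0.02)$adjusted, 0.02)
  expect_true(all(holm_bonferroni(rep(0, 5))$reject))
  expect_error(holm_bonferroni(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Holm matches a brute-force oracle and dominates Bonferroni", {
  set.seed(14)
  for (r in 1:25) {
    p <- runif(sample(2:40, 1))^2
    adj <- holm_bonferroni(p)$adjusted
    expect_equal(adj, holm_oracle(p), tolerance = 1e-12)
    expect_gte(min(adj - p), 0)                  # adjusted >= raw
    bonf <- pmin(1, p * length(p)) < 0.05
    expect_true(all(bonf <= (adj < 0.05)))       # rejections superset
  }
})

test_that("session ANOVA matches a sums-of-squares oracle on random data", {
  set.seed(15)
  for (r in 1:20) {
    sizes <- sample(3:10, sample(2:5, 1), replace = TRUE)
    g <- rep(seq_along(sizes), sizes)
    y <- rnorm(length(g)) + 0.5 * g
    fit <- session_anova(y, g)
    orc <- anova_oracle(y, g)
    expect_equal(fit$F, orc$F, tolerance = 1e-10)
    expect_equal(fit$df_between, orc$df_between)
    expect_equal(fit$df_within, orc$df_within)
    expect_equal(fit$eta_squared, orc$eta_squared, tolerance = 1e-10)
  }
})

test_that("ANOVA degrees of freedom follow the session design", {
  set.seed(16)
  y6 <- rnorm(120)
  fit6 <- session_anova(y6, rep(1:6, each = 20))
  expect_equal(c(fit6$df_between, fit6$df_within), c(5, 114))
  sizes <- c(20, 17, 20, 20, 20)
  fit5 <- session_anova(rnorm(sum(sizes)), rep(1:5, sizes))
  expect_equal(c(fit5$df_between, fit5$df_within), c(4, 92))
  expect_equal(nrow(fit5$tukey), choose(5, 2))
})

test_that("constant within-group data drives eta squared to one", {
  y <- rep(c(0, 1, 3), each = 4)
  fit <- session_anova(y, rep(1:3, each = 4))
  expect_equal(fit$eta_squared, 1)
  expect_error(session_anova(rep(1, 10), rep(1:2, each = 5)),
               "degenerate")
  expect_error(session_anova(rnorm(3), c(1, 1, 2)), "at least 2 trials")
})

test_that("Tukey flags the pairs with a real shift and only those", {
  set.seed(18)
  y <- c(rnorm(20, 0, 1), rnorm(20, 0, 1), rnorm(20, 3, 1))
  fit <- session_anova(y, rep(1:3, each = 20))
  tk <- setNames(fit$tukey$p_adj, fit$tukey$pair)
  expect_gt(tk[["2-1"]], 0.05)
  expect_lt(tk[["3-1"]], 0.01)
  expect_lt(tk[["3-2"]], 0.01)
})

test_that("Spearman rho and exact permutation p match independent references", {
  set.seed(18)
  # tie-free: compare against cor.test's exact distribution
  for (r in 1:10) {
    x <- sample(100, 7); y <- sample(100, 7)
    sp <- thetanf:::spearman_pvalue(x, y)
    ct <- cor.test(x, y, method = "spearman", exact = TRUE)
    expect_equal(sp$rho, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(sp$p, ct$p.value, tolerance = 1e-12)
  }
  # perfect monotone association
  expect_equal(thetanf:::spearman_pvalue(1:6, c(2, 5, 7, 8, 12, 20))$rho, 1)
  # large-n path uses the t approximation
  x <- rnorm(30); y <- x + rnorm(30)
  sp <- thetanf:::spearman_pvalue(x, y)
  expect_lt(sp$p, 0.01)
})

test_that("theta-behavior correlations apply the three subset rules", {
  # deterministic meta: theta and all three scores strictly increase with
  # session, so every Spearman rho must be exactly 1
  meta <- do.call(rbind, lapply(1:6, function(s) {
    n <- 12
    old <- seq_len(n) <= 6
    hit <- seq_len(n) <= s                  # recall = s/6
    correct <- hit | (seq_len(n) %in% (7:(6 + s)))  # accuracy = 2s/12
    t2 <- hit & seq_len(n) <= (s - 1)       # task2 accuracy = (s-1)/s
    data.frame(session = s, theta_power = s + (1:n) / 100,
               probe_is_old = old, task1_correct = correct, hit = hit,
               task2_correct = t2)
  }))
  co <- theta_behavior_correlation(meta)
  expect_equal(co$analysis,
               c("task1_accuracy", "task1_recall", "task2_accuracy"))
  expect_equal(co$rho[co$analysis == "task1_accuracy"], 1)
  expect_true(all(co$defined))
  pairs <- attr(co, "pairs")
  # subset rules recomputed by hand for session 1
  d1 <- meta[meta$session == 1, ]
  expect_equal(pairs$theta_all[1], mean(d1$theta_power))
  expect_equal(pairs$theta_old[1], mean(d1$theta_power[d1$probe_is_old]))
  expect_equal(pairs$theta_hit[1], mean(d1$theta_power[d1$hit]))
  expect_error(theta_behavior_correlation(meta[meta$session <= 3, ]),
               class = "thetanf_insufficient_data")
})

test_that("constant scores leave the Holm family as undefined correlations", {
  meta <- do.call(rbind, lapply(1:6, function(s) {
    data.frame(session = s, theta_power = rlnorm(10, 0, 0.1),
               probe_is_old = rep(c(TRUE, FALSE), 5),
               task1_correct = TRUE,
               hit = rep(c(TRUE, FALSE), 5), task2_correct = FALSE)
  }))
  co <- theta_behavior_correlation(meta)
  expect_false(any(co$defined[co$analysis != "task2_accuracy"]))
  expect_true(all(is.na(co$rho[!co$defined])))
})

test_that("under null coupling the correlation analyses are calibrated", {
  set.seed(99)
  nrep <- 200
  rej <- 0; rhos <- numeric(0)
  for (r in 1:nrep) {
    meta <- do.call(rbind, lapply(1:6, function(s) {
      n <- 20
      succ <- runif(n) < 0.9
      old <- sample(rep(c(TRUE, FALSE), each = 10))
      hit <- old & succ
      data.frame(session = s, theta_power = rlnorm(n, 0, 0.1),
                 probe_is_old = old, task1_correct = succ, hit = hit,
                 task2_correct = hit & (runif(n) < 0.9))
    }))
    a <- theta_behavior_correlation(meta)
    a <- a[a$analysis == "task1_accuracy", ]
    if (a$defined) {
      rhos <- c(rhos, a$rho)
      rej <- rej + (a$p_raw < 0.05)
    }
  }
  expect_lt(abs(mean(rhos)), 0.15)
  rate <- rej / length(rhos)
  expect_gt(rate, 0.01)
  expect_lt(rate, 0.12)
})

test_that("identical correct and error spectra give flat p-values", {
  meta <- data.frame(session = rep(1:3, each = 4), trial = 1:12,
                     probe_is_old = TRUE,
                     task1_correct = rep(c(TRUE, TRUE, FALSE, FALSE), 3),
                     hit = TRUE, task2_correct = TRUE,
                     theta_power = 1, log_theta = 0)
  db <- lapply(1:12, function(i) matrix(5, 1, 100))
  sp <- synthetic_spectra(db, meta)
  res <- compare_correct_error(sp, "task1")
  expect_true(all(res$p_raw == 1))
  expect_false(any(res$significant))
})

test_that("all-correct sessions are excluded from the correct/error comparison", {
  set.seed(20)
  meta <- data.frame(session = rep(1:6, each = 6), trial = 1:36,
                     probe_is_old = TRUE, hit = TRUE, task2_correct = TRUE,
                     task1_correct = rep(c(TRUE, TRUE, TRUE, TRUE, FALSE,
                                           FALSE), 6),
                     theta_power = 1, log_theta = 0)
  meta$task1_correct[meta$session == 6] <- TRUE   # session 6 at ceiling
  db <- lapply(1:36, function(i) matrix(rnorm(100), 1))
  sp <- synthetic_spectra(db, meta)
  res <- compare_correct_error(sp, "task1")
  expect_equal(attr(res, "n_units"), 5)
  # only one usable session -> insufficient data
  meta2 <- meta; meta2$task1_correct[meta2$session > 1] <- TRUE
  expect_error(compare_correct_error(synthetic_spectra(db, meta2), "task1"),
               class = "thetanf_insufficient_data")
})

test_that("a theta-confined dB effect is detected in the theta bins and only there", {
  set.seed(21)
  found <- confined <- 0
  nrep <- 50
  for (r in 1:nrep) {
    meta <- data.frame(session = rep(1:6, each = 10), trial = 1:60,
                       probe_is_old = TRUE, hit = TRUE,
                       task2_correct = TRUE,
                       task1_correct = rep(rep(c(TRUE, FALSE), c(6, 4)), 6),
                       theta_power = 1, log_theta = 0)
    db <- lapply(seq_len(60), function(i) {
      row <- matrix(rnorm(100, 0, 1), 1)
      if (meta$task1_correct[i]) row[1, 4:8] <- row[1, 4:8] - 3
      row
    })
    res <- compare_correct_error(synthetic_spectra(db, meta), "task1")
    sig <- res$freq[res$significant]
    if (length(sig) > 0 && all(sig >= 4 & sig <= 8)) confined <- confined + 1
    if (any(res$significant[res$freq >= 4 & res$freq <= 8]))
      found <- found + 1
  }
  expect_gte(found / nrep, 0.9)
  expect_gte(confined / nrep, 0.9)
})

test_that("first/final comparison handles identical and unequal-count sessions", {
  set.seed(22)
  db <- lapply(1:40, function(i) matrix(rnorm(100), 1))
  meta <- data.frame(session = rep(c(1, 6), each = 20), trial = 1:40,
                     probe_is_old = TRUE, task1_correct = TRUE, hit = TRUE,
                     task2_correct = TRUE, theta_power = 1, log_theta = 0)
  res <- compare_first_final(synthetic_spectra(db, meta))
  expect_false(any(res$significant))
  # truncated final session (17 trials) is accepted
  sp17 <- synthetic_spectra(db[1:37], meta[1:37, ])
  expect_s3_class(compare_first_final(sp17), "binwise_test")
  # a genuine shift is flagged with the right sign
  db2 <- db
  for (i in 21:40) db2[[i]][1, 4:8] <- db2[[i]][1, 4:8] + 6
  res2 <- compare_first_final(synthetic_spectra(db2, meta))
  expect_true(all(res2$significant[4:8]))
  expect_true(all(res2$direction[4:8] > 0))
  expect_false(any(res2$significant[-(4:8)]))
})
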