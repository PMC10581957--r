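# Shared fixtures, built in code at test time.

# A 13 s, 4-channel Gaussian epoch at 512 Hz.
gaussian_epoch <- function(seed = 1, duration = 13, n_channels = 4,
                           fs = 512, sd = 1) {
  set.seed(seed)
  signal_epoch(matrix(rnorm(n_channels * duration * fs, sd = sd),
                      n_channels), fs = fs)
}

# Epoch with an exactly known exceedance fraction: a uniform base (whose
# deviations never reach 3 SD even after pulse inflation) plus signed
# 10-sigma pulses at a chosen fraction of samples.
exceedance_epoch <- function(fraction, seed = 1, duration = 13,
                             n_channels = 4, fs = 512) {
  set.seed(seed)
  n <- duration * fs
  x <- matrix(runif(n_channels * n, -1, 1) * sqrt(3), n_channels)
  n_pulse <- round(fraction * n)
  for (ch in seq_len(n_channels)) {
    idx <- sample(n, n_pulse)
    x[ch, idx] <- 10 * sample(c(-1, 1), n_pulse, replace = TRUE)
  }
  signal_epoch(x, fs = fs)
}

# Small balanced session plan over a fresh lexicon.
small_plan <- function(n_trials = 20, seed = 42) {
  lex <- build_lexicon(6 * n_trials, seed = seed)
  ws <- make_word_sets(lex, n_trials, seed = seed + 1)
  schedule_session(ws, n_old = n_trials %/% 2,
                   n_new = n_trials - n_trials %/% 2, seed = seed + 2)
}

# Trial spectra built directly from dB values (no signal synthesis), for
# statistics tests with a known spectral effect.
synthetic_spectra <- function(db_list, meta) {
  db <- do.call(rbind, db_list)
  structure(list(freqs = 1:100, db = db, power = 10^(db / 10),
                 meta = meta), class = "trial_spectra")
}

# Independent brute-force Holm step-down used as an oracle.
holm_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    running <- max(running, (m - i + 1) * p[o[i]])
    adj[o[i]] <- min(1, running)
  }
  adj
}

# Independent sums-of-squares one-way ANOVA oracle.
anova_oracle <- function(y, g) {
  g <- factor(g)
  grand <- mean(y)
  ssb <- sum(tapply(y, g, function(v) length(v) * (mean(v) - grand)^2))
  ssw <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
  dfb <- nlevels(g) - 1
  dfw <- length(y) - nlevels(g)
  list(F = (ssb / dfb) / (ssw / dfw), df_between = dfb, df_within = dfw,
       eta_squared = ssb / (ssb + ssw))
}
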