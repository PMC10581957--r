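#' Acquisition filter specification
#'
#' @param bandpass two-element band edges in Hz (default 0.5-200, the
#'   acquisition band).
#' @param notch power-line notch frequency in Hz (50; `NA` disables).
#' @param order Butterworth band-pass order (applied forward-backward, so
#'   the effective attenuation is doubled and the phase is zero).
#' @param notch_q notch quality factor (bandwidth = notch / Q).
#' @return a `filter_spec` list.
#' @export
filter_spec <- function(bandpass = c(0.5, 200), notch = 50, order = 4,
                        notch_q = 30) {
  stopifnot(length(bandpass) == 2, bandpass[1] > 0,
            bandpass[2] > bandpass[1])
  structure(list(bandpass = bandpass, notch = notch, order = order,
                 notch_q = notch_q), class = "filter_spec")
}

#' Band-pass and notch filter an epoch
#'
#' Zero-phase (forward-backward Butterworth) band-pass followed by a
#' band-stop notch at the power-line frequency.
#'
#' @param epoch a [signal_epoch()].
#' @param spec a [filter_spec()].
#' @return the filtered [signal_epoch()], same shape.
#' @export
preprocess <- function(epoch, spec = filter_spec()) {
  ny <- epoch$fs / 2
  if (spec$bandpass[2] >= ny) {
    stop(sprintf("band edge %g Hz at or above Nyquist (%g Hz)",
                 spec$bandpass[2], ny), call. = FALSE)
  }
  bp <- signal::butter(spec$order, spec$bandpass / ny, type = "pass")
  use_notch <- !is.na(spec$notch) && spec$notch > 0
  if (use_notch) {
    bw <- spec$notch / spec$notch_q
    ns <- signal::butter(2, c(spec$notch - bw / 2, spec$notch + bw / 2) / ny,
                         type = "stop")
  }
  out <- epoch
  for (ch in seq_len(n_channels(epoch))) {
    y <- signal::filtfilt(bp, epoch$samples[ch, ])
    if (use_notch) y <- signal::filtfilt(ns, y)
    out$samples[ch, ] <- y
  }
  out
}

#' Extract the encoding epoch of a trial
#'
#' Cuts the 13 s encoding period (five 2.6 s word cycles) starting at the
#' trial onset, and the 12 s analysis window that drops the first second
#' (the blank before the first word).
#'
#' @param recording a continuous [signal_epoch()] covering the trial.
#' @param trial_onset encoding-period start in seconds from the start of
#'   the recording's time axis.
#' @param encoding_s,lead_s encoding length and dropped lead, seconds.
#' @return a list with `full13` (13 s epoch) and `analysis12` (12 s
#'   epoch); at 512 Hz these hold 6656 and 6144 samples.
#' @export
extract_encoding_epoch <- function(recording, trial_onset,
                                   encoding_s = 13, lead_s = 1) {
  rel <- trial_onset - recording$start_time
  if (rel < 0 || rel + encoding_s > epoch_duration(recording) + 1e-9) {
    stop(sprintf("encoding window [%g, %g] s outside recording",
                 trial_onset, trial_onset + encoding_s), call. = FALSE)
  }
  full13 <- epoch_slice(recording, rel, rel + encoding_s)
  n_lead <- round(lead_s * recording$fs)
  analysis12 <- full13
  analysis12$samples <- full13$samples[, -(seq_len(n_lead)), drop = FALSE]
  analysis12$start_time <- full13$start_time + lead_s
  list(full13 = full13, analysis12 = analysis12)
}

#' Welch power spectral density
#'
#' Averaged periodogram with Hann windows and 50% overlap; the default
#' 1 s window gives a 1 Hz frequency resolution (23 segments for the 12 s
#' analysis window). Density scaling, so units are microvolt^2 per Hz.
#'
#' @param epoch a [signal_epoch()] of at least one window length.
#' @param window_s segment length in seconds.
#' @param overlap fractional overlap between segments.
#' @return a `spectral_estimate`: `freqs` (Hz), `psd` (channels x
#'   frequencies matrix), `fs`, `window_s`, `overlap`, `n_segments`.
#' @export
welch_psd <- function(epoch, window_s = 1, overlap = 0.5) {
  fs <- epoch$fs
  L <- round(window_s * fs)
  n <- n_samples(epoch)
  if (n < L) stop("epoch shorter than one Welch window", call. = FALSE)
  step <- max(1, round(L * (1 - overlap)))
  starts <- seq(1, n - L + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(L) - 1) / L)   # periodic Hann
  norm <- fs * sum(w^2)
  nfreq <- L %/% 2 + 1
  nch <- n_channels(epoch)
  acc <- matrix(0, nch, nfreq)
  for (s in starts) {
    seg <- epoch$samples[, s:(s + L - 1), drop = FALSE] *
      rep(w, each = nch)
    spec <- Mod(t(stats::mvfft(t(seg))))^2 / norm
    half <- spec[, seq_len(nfreq), drop = FALSE]
    half[, 2:(nfreq - 1)] <- 2 * half[, 2:(nfreq - 1)]
    acc <- acc + half
  }
  psd <- acc / length(starts)
  structure(list(freqs = (seq_len(nfreq) - 1) * fs / L, psd = psd,
                 fs = fs, window_s = window_s, overlap = overlap,
                 n_segments = length(starts),
                 channel_labels = epoch$channel_labels),
            class = "spectral_estimate")
}

#' @export
print.spectral_estimate <- function(x, ...) {
  cat(sprintf("<spectral_estimate> %d channel(s), %g-%g Hz at %g Hz bins (%d segments)\n",
              nrow(x$psd), min(x$freqs), max(x$freqs),
              x$freqs[2] - x$freqs[1], x$n_segments))
  invisible(x)
}

#' Integrated band power
#'
#' Trapezoidal integration of the PSD from `lo` to `hi` Hz (inclusive) per
#' channel, averaged across channels — the feedback signal when applied to
#' the theta band.
#'
#' @param psd a [welch_psd()] estimate.
#' @param lo,hi band edges in Hz (defaults 4 and 8, the theta band).
#' @return a `band_power` list: `per_channel` (microvolt^2), `mean`,
#'   `log_mean` (log10 of the mean) and the band.
#' @export
band_power <- function(psd, lo = 4, hi = 8) {
  if (hi <= lo) stop("'hi' must exceed 'lo'", call. = FALSE)
  if (lo < min(psd$freqs) || hi > max(psd$freqs)) {
    stop("band outside the estimated frequency range", call. = FALSE)
  }
  sel <- which(psd$freqs >= lo - 1e-9 & psd$freqs <= hi + 1e-9)
  f <- psd$freqs[sel]
  per_channel <- apply(psd$psd[, sel, drop = FALSE], 1, function(p) {
    sum(diff(f) * (p[-1] + p[-length(p)]) / 2)
  })
  m <- mean(per_channel)
  structure(list(per_channel = per_channel, mean = m,
                 log_mean = log10(max(m, 1e-300)), band = c(lo, hi)),
            class = "band_power")
}

#' Feedback bar history
#'
#' The intermittent feedback protocol shows, after each trial, the trial's
#' theta power as the height of a new bar next to the bars of all previous
#' trials. The state is an append-only history of raw power values;
#' [bar_heights()] gives the displayed heights rescaled to the running
#' maximum.
#'
#' @return `feedback_state()` returns an empty state.
#' @export
feedback_state <- function() {
  structure(list(history = numeric(0)), class = "feedback_state")
}

#' @rdname feedback_state
#' @param state a `feedback_state`.
#' @param power a [band_power()] (or a single numeric power value).
#' @export
update_feedback <- function(state, power) {
  v <- if (inherits(power, "band_power")) power$mean else as.numeric(power)
  state$history <- c(state$history, v)
  state
}

#' @rdname feedback_state
#' @export
bar_heights <- function(state) {
  if (length(state$history) == 0) return(numeric(0))
  state$history / max(state$history)
}

#' Closed-loop session configuration
#'
#' @param mode `"p01"` (no real-time artifact correction) or `"p02"`
#'   (real-time ASR with fixed `k = 4`).
#' @param use_full_13s compute the feedback power on the full 13 s
#'   encoding epoch instead of the 12 s analysis window.
#' @param theta_band feedback band in Hz.
#' @param filter a [filter_spec()].
#' @param welch_window_s,welch_overlap Welch settings.
#' @param asr_k real-time ASR cutoff for `"p02"` mode.
#' @param asr_window ASR window length in seconds.
#' @return an `nf_config` list.
#' @export
nf_config <- function(mode = c("p01", "p02"), use_full_13s = FALSE,
                      theta_band = c(4, 8), filter = filter_spec(),
                      welch_window_s = 1, welch_overlap = 0.5,
                      asr_k = 4, asr_window = 0.5) {
  mode <- match.arg(mode)
  structure(list(mode = mode, use_full_13s = use_full_13s,
                 theta_band = theta_band, filter = filter,
                 welch_window_s = welch_window_s,
                 welch_overlap = welch_overlap,
                 asr_k = asr_k, asr_window = asr_window),
            class = "nf_config")
}

#' Run the closed neurofeedback loop over a session
#'
#' Replays a continuous recording (in memory or from an EDF file) through
#' the real-time chain: filtering, per-trial encoding-epoch extraction,
#' optional real-time ASR (fixed `k = 4` in `"p02"` mode, none in
#' `"p01"`), Welch PSD, theta band power averaged across contacts, and the
#' intermittent feedback update. Deterministic given the recording.
#'
#' @param plan a [schedule_session()] plan.
#' @param source a continuous [signal_epoch()] or the path to an EDF file.
#' @param config an [nf_config()].
#' @param responses optional per-trial responses (see
#'   [simulate_responses()]) to score.
#' @return an `nf_session_record`: per-trial data frame (`trial`,
#'   `theta_power`, `log_theta`, `k_used`, `feedback` raw value),
#'   the final `feedback_state`, `scores` (or `NULL`), the ASR
#'   `cleaning_log` (empty in `"p01"` mode) and the `config`.
#' @export
run_closed_loop <- function(plan, source, config = nf_config(),
                            responses = NULL) {
  rec <- if (is.character(source)) read_edf(source) else source
  stopifnot(inherits(rec, "signal_epoch"))
  n_trials <- length(plan$trials)
  need <- session_duration(plan)
  if (epoch_duration(rec) + 1e-9 < need) {
    stop(sprintf("recording (%.1f s) shorter than the %d-trial plan (%.1f s)",
                 epoch_duration(rec), n_trials, need), call. = FALSE)
  }
  rec <- preprocess(rec, config$filter)
  calib <- NULL
  if (config$mode == "p02") {
    rest <- epoch_slice(rec, 0, plan$timeline$rest)
    calib <- asr_calibrate(rest, asr_params(k = config$asr_k,
                                            window = config$asr_window))
  }
  state <- feedback_state()
  theta <- k_used <- numeric(n_trials)
  logs <- list()
  for (tr in seq_len(n_trials)) {
    ep <- extract_encoding_epoch(rec, trial_onset(plan, tr))
    target <- if (config$use_full_13s) ep$full13 else ep$analysis12
    if (config$mode == "p02") {
      cl <- asr_clean(target, calib, k = config$asr_k)
      target <- cl$epoch
      lg <- cl$log
      lg$trial <- tr
      logs[[length(logs) + 1]] <- lg[lg$n_rejected > 0, , drop = FALSE]
      k_used[tr] <- config$asr_k
    } else {
      k_used[tr] <- NA_real_
    }
    psd <- welch_psd(target, config$welch_window_s, config$welch_overlap)
    bp <- band_power(psd, config$theta_band[1], config$theta_band[2])
    theta[tr] <- bp$mean
    state <- update_feedback(state, bp)
  }
  scores <- if (!is.null(responses)) score_recognition(responses, plan)
            else NULL
  structure(list(
    trials = data.frame(trial = seq_len(n_trials), theta_power = theta,
                        log_theta = log10(theta), k_used = k_used,
                        feedback = state$history),
    feedback = state,
    scores = scores,
    cleaning_log = if (length(logs)) do.call(rbind, logs)
                   else data.frame(window_start = numeric(0),
                                   n_rejected = integer(0),
                                   energy_removed = numeric(0),
                                   trial = integer(0)),
    config = config
  ), class = "nf_session_record")
}

#' @export
print.nf_session_record <- function(x, ...) {
  cat(sprintf("<nf_session_record> %d trials, mode %s; mean theta power %.3g uV^2\n",
              nrow(x$trials), x$config$mode, mean(x$trials$theta_power)))
  if (!is.null(x$scores)) print(x$scores)
  invisible(x)
}
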