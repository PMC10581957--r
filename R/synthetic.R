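#' Component models for the synthetic iEEG generator
#'
#' The generator builds intracranial EEG as the sum of three independent
#' parts: a `1/f^beta` background, a narrowband theta oscillation whose
#' amplitude tracks the task, and sharp spike transients mimicking
#' interictal epileptiform discharges. Each part has its own small model
#' object so study conditions are stated once and passed around.
#'
#' @param exponent spectral slope `beta` of the `1/f^beta` background
#'   (unitless, >= 0; 1 is a typical broadband iEEG slope).
#' @param scale RMS amplitude of the background in microvolts.
#' @return `noise_model` returns a `noise_model` object.
#' @export
noise_model <- function(exponent = 1, scale = 10) {
  stopifnot(is.numeric(exponent), length(exponent) == 1, exponent >= 0)
  if (!is.numeric(scale) || length(scale) != 1 || scale < 0) {
    stop("'scale' must be a single non-negative RMS in microvolts",
         call. = FALSE)
  }
  structure(list(exponent = exponent, scale = scale), class = "noise_model")
}

#' @rdname noise_model
#' @param center_freq oscillation centre frequency in Hz (default 6, the
#'   middle of the 4-8 Hz theta band).
#' @param bandwidth full bandwidth in Hz; 0 gives a pure sinusoid,
#'   positive values give narrowband Gaussian noise of that width.
#' @param amplitude peak amplitude in microvolts (a sinusoid of peak `A`
#'   carries band power `A^2/2`).
#' @export
oscillation_spec <- function(center_freq = 6, bandwidth = 1, amplitude = 5) {
  stopifnot(is.numeric(center_freq), center_freq > 0,
            is.numeric(bandwidth), bandwidth >= 0,
            is.numeric(amplitude), amplitude >= 0)
  structure(list(center_freq = center_freq, bandwidth = bandwidth,
                 amplitude = amplitude), class = "oscillation_spec")
}

#' @rdname noise_model
#' @param rate spike rate in events per second (Poisson process).
#' @param amplitude spike peak amplitude in microvolts on the strongest
#'   contact.
#' @param width half-duration of the transient in seconds.
#' @param waveform `"biphasic_sharp"` (derivative-of-Gaussian, one positive
#'   and one negative lobe) or `"gaussian_pulse"`.
#' @param channel_profile per-channel amplitude scaling of the synchronous
#'   spike; `NULL` uses a geometric falloff `0.8^(i-1)` across contacts,
#'   mimicking a focal generator seen by a 4-contact strip.
#' @export
spike_model <- function(rate = 0.2, amplitude = 150, width = 0.05,
                        waveform = c("biphasic_sharp", "gaussian_pulse"),
                        channel_profile = NULL) {
  waveform <- match.arg(waveform)
  stopifnot(is.numeric(rate), rate >= 0, is.numeric(width), width > 0,
            is.numeric(amplitude), amplitude >= 0)
  structure(list(rate = rate, amplitude = amplitude, width = width,
                 waveform = waveform, channel_profile = channel_profile),
            class = "spike_model")
}

#' @rdname noise_model
#' @param theta_gain_by_session multiplicative theta-amplitude factor per
#'   session; its length fixes the number of sessions the learner supports.
#' @param behavior_coupling number in `[-1, 1]` linking per-trial theta
#'   power to recognition success probability (0 = no link); success
#'   probability is Bernoulli with logit linear in the standardized
#'   log theta factor times `2 * behavior_coupling`.
#' @param base_success_prob recognition success probability at average
#'   theta power.
#' @param jitter_sd standard deviation of the lognormal per-trial theta
#'   amplitude jitter (log scale; default 0.1 keeps power positive with
#'   ~10% trial-to-trial variation).
#' @export
learner_model <- function(theta_gain_by_session = rep(1, 6),
                          behavior_coupling = 0,
                          base_success_prob = 0.9,
                          jitter_sd = 0.1) {
  stopifnot(all(theta_gain_by_session >= 0),
            abs(behavior_coupling) <= 1,
            base_success_prob > 0, base_success_prob <= 1,
            jitter_sd >= 0)
  structure(list(theta_gain_by_session = as.numeric(theta_gain_by_session),
                 behavior_coupling = behavior_coupling,
                 base_success_prob = base_success_prob,
                 jitter_sd = jitter_sd), class = "learner_model")
}

# 1/f^(beta/2) amplitude gain on the FFT grid; flat below f_lo so the
# integrated power stays finite for beta > 0. DC removed.
shape_gain <- function(n, fs, exponent, f_lo = 0.5) {
  f <- c(0, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f)           # two-sided grid folded to [0, fs/2]
  g <- rep(0, n)
  pos <- f > 0
  g[pos] <- pmax(f[pos], f_lo)^(-exponent / 2)
  g
}

#' Generate 1/f background iEEG
#'
#' Synthesizes per-channel independent Gaussian noise whose power spectrum
#' follows `1/f^beta` over the acquisition band, by spectral shaping of
#' white noise in the frequency domain. Each channel is rescaled to exactly
#' the requested RMS.
#'
#' @param duration epoch length in seconds (> 0).
#' @param fs sampling rate in Hz.
#' @param noise a [noise_model()].
#' @param n_channels number of contacts (default 4).
#' @param seed integer seed; identical seeds give bit-identical epochs.
#' @return a [signal_epoch()].
#' @examples
#' bg <- generate_background(13, 512, noise_model(exponent = 1, scale = 10),
#'                           seed = 1)
#' sd(as.vector(bg$samples))  # ~10 uV
#' @export
generate_background <- function(duration, fs = 512, noise = noise_model(),
                                n_channels = 4, seed = NULL) {
  if (!is.numeric(duration) || duration <= 0) {
    stop("'duration' must be positive", call. = FALSE)
  }
  if (!is.numeric(fs) || fs <= 0) stop("'fs' must be positive", call. = FALSE)
  n <- round(duration * fs)
  with_seed(seed, {
    samples <- matrix(0, n_channels, n)
    if (noise$scale > 0) {
      gain <- shape_gain(n, fs, noise$exponent)
      for (ch in seq_len(n_channels)) {
        w <- stats::rnorm(n)
        y <- Re(stats::fft(stats::fft(w) * gain, inverse = TRUE)) / n
        rms <- sqrt(mean(y^2))
        samples[ch, ] <- y * (noise$scale / rms)
      }
    } else {
      # burn the same RNG draws so the seed stream is scale-invariant
      for (ch in seq_len(n_channels)) stats::rnorm(n)
    }
    signal_epoch(samples, fs = fs)
  })
}

# Realize the oscillation waveform on its own: one row per channel.
oscillation_waveform <- function(spec, n, fs, n_channels, seed = NULL) {
  with_seed(seed, {
    t <- (seq_len(n) - 1) / fs
    out <- matrix(0, n_channels, n)
    if (spec$amplitude == 0) return(out)
    if (spec$bandwidth == 0) {
      phase <- stats::runif(n_channels, 0, 2 * pi)
      for (ch in seq_len(n_channels)) {
        out[ch, ] <- spec$amplitude *
          sin(2 * pi * spec$center_freq * t + phase[ch])
      }
    } else {
      # narrowband Gaussian noise: white noise shaped by a Gaussian band
      # around f0; RMS set to A/sqrt(2) so band power matches A^2/2
      f <- c(0, seq_len(n - 1)) * fs / n
      f <- pmin(f, fs - f)
      bw_sd <- spec$bandwidth / 2
      g <- exp(-0.5 * ((f - spec$center_freq) / bw_sd)^2)
      for (ch in seq_len(n_channels)) {
        w <- stats::rnorm(n)
        y <- Re(stats::fft(stats::fft(w) * g, inverse = TRUE)) / n
        out[ch, ] <- y * (spec$amplitude / sqrt(2)) / sqrt(mean(y^2))
      }
    }
    out
  })
}

#' Add a narrowband oscillation to an epoch
#'
#' Additive: the input epoch is left unchanged and the returned epoch is
#' input plus oscillation. With a fixed seed the realized waveform is
#' reproducible, so it can be subtracted again exactly.
#'
#' @param epoch a [signal_epoch()].
#' @param spec an [oscillation_spec()].
#' @param seed integer seed controlling phases (sinusoid) or the noise
#'   realization (narrowband).
#' @return a [signal_epoch()] of the same shape.
#' @export
add_oscillation <- function(epoch, spec, seed = NULL) {
  ny <- epoch$fs / 2
  if (spec$center_freq - spec$bandwidth / 2 <= 0 ||
      spec$center_freq + spec$bandwidth / 2 >= ny) {
    stop(sprintf("oscillation band must lie inside (0, %g) Hz", ny),
         call. = FALSE)
  }
  osc <- oscillation_waveform(spec, n_samples(epoch), epoch$fs,
                              n_channels(epoch), seed = seed)
  out <- epoch
  out$samples <- epoch$samples + osc
  out
}

# Spike kernel sampled at fs; peak normalized to 1.
spike_kernel <- function(width, fs, waveform) {
  sigma <- width / 2
  t <- seq(-3 * sigma, 3 * sigma, by = 1 / fs)
  k <- switch(waveform,
    gaussian_pulse = exp(-0.5 * (t / sigma)^2),
    biphasic_sharp = -(t / sigma) * exp(0.5 - 0.5 * (t / sigma)^2)
  )
  k / max(abs(k))
}

#' Inject epileptiform spike transients
#'
#' Onsets follow a homogeneous Poisson process at `model$rate`; each spike
#' is a sharp transient added synchronously to all channels, scaled by the
#' model's per-channel amplitude profile.
#'
#' @param epoch a [signal_epoch()].
#' @param model a [spike_model()].
#' @param seed integer seed for onset times.
#' @return a list with elements `epoch` (contaminated signal) and `onsets`
#'   (spike peak times in seconds, on the epoch's own time axis starting
#'   at 0).
#' @export
inject_spikes <- function(epoch, model, seed = NULL) {
  dur <- epoch_duration(epoch)
  with_seed(seed, {
    n_spk <- stats::rpois(1, model$rate * dur)
    onsets <- sort(stats::runif(n_spk, 0, dur))
    out <- epoch
    if (n_spk > 0 && model$amplitude > 0) {
      nch <- n_channels(epoch)
      profile <- model$channel_profile
      if (is.null(profile)) profile <- 0.8^(seq_len(nch) - 1)
      stopifnot(length(profile) == nch)
      kern <- spike_kernel(model$width, epoch$fs, model$waveform)
      half <- (length(kern) - 1) %/% 2
      n <- n_samples(epoch)
      for (on in onsets) {
        centre <- round(on * epoch$fs) + 1
        idx <- (centre - half):(centre - half + length(kern) - 1)
        keep <- idx >= 1 & idx <= n
        if (!any(keep)) next
        add <- model$amplitude * kern[keep]
        out$samples[, idx[keep]] <- out$samples[, idx[keep]] +
          outer(profile, add)
      }
    }
    list(epoch = out, onsets = onsets)
  })
}

#' Synthesize one encoding-period epoch
#'
#' Convenience composition used by the session generator and by
#' simulation studies that only need trial epochs (skipping the inter-trial
#' intervals): background + theta oscillation at `theta_factor` times the
#' spec amplitude + optional spikes.
#'
#' @param duration epoch length in seconds (default 13, one encoding
#'   period).
#' @param fs sampling rate in Hz.
#' @param noise,osc,spikes component models; `spikes = NULL` omits
#'   transients.
#' @param theta_factor multiplicative theta amplitude factor for this trial.
#' @param n_channels number of contacts.
#' @param seed integer seed.
#' @return a list with `epoch` and `spike_onsets`.
#' @export
generate_trial_epoch <- function(duration = 13, fs = 512,
                                 noise = noise_model(),
                                 osc = oscillation_spec(),
                                 spikes = NULL,
                                 theta_factor = 1, n_channels = 4,
                                 seed = NULL) {
  with_seed(seed, {
    ep <- generate_background(duration, fs, noise, n_channels)
    sp <- osc
    sp$amplitude <- osc$amplitude * theta_factor
    ep <- add_oscillation(ep, sp)
    onsets <- numeric(0)
    if (!is.null(spikes) && spikes$rate > 0) {
      res <- inject_spikes(ep, spikes)
      ep <- res$epoch
      onsets <- res$onsets
    }
    list(epoch = ep, spike_onsets = onsets)
  })
}

#' Generate a full neurofeedback session recording with ground truth
#'
#' Builds the continuous 4-contact recording spanning the whole session
#' timeline (rest, then per trial: encoding, two recognition windows,
#' feedback). The theta oscillation is present only during encoding
#' periods, with amplitude `osc$amplitude * session_gain * jitter` where
#' the per-trial jitter is lognormal. Recognition success indicators are
#' drawn from a Bernoulli model whose logit is linear in the standardized
#' log theta factor scaled by the learner's behavior coupling. Spikes are
#' injected over the entire session.
#'
#' @param plan a [schedule_session()] plan.
#' @param learner a [learner_model()].
#' @param noise,osc,spikes component models (`spikes = NULL` for a clean
#'   session).
#' @param session session index selecting the learner's theta gain.
#' @param n_channels number of contacts.
#' @param seed integer seed; the whole session is deterministic given it.
#' @return a list with `recording` (continuous [signal_epoch()]) and
#'   `truth` (ground truth: per-trial data frame with `trial`,
#'   `theta_factor`, `task1_success`, `task2_success`, plus `spike_onsets`
#'   in session seconds and the `session` index).
#' @export
generate_session <- function(plan, learner = learner_model(),
                             noise = noise_model(),
                             osc = oscillation_spec(),
                             spikes = spike_model(),
                             session = 1, n_channels = 4, seed = NULL) {
  if (session < 1 || session > length(learner$theta_gain_by_session)) {
    stop(sprintf("session %d outside the learner's %d-session gain trajectory",
                 session, length(learner$theta_gain_by_session)),
         call. = FALSE)
  }
  tl <- plan$timeline
  n_trials <- length(plan$trials)
  fs <- 512
  total_dur <- session_duration(plan)
  gain <- learner$theta_gain_by_session[session]

  with_seed(seed, {
    rec <- generate_background(total_dur, fs, noise, n_channels)
    jitter <- stats::rlnorm(n_trials, meanlog = 0, sdlog = learner$jitter_sd)
    theta_factor <- gain * jitter
    enc_len <- encoding_duration(tl)
    n_enc <- round(enc_len * fs)
    for (tr in seq_len(n_trials)) {
      onset <- trial_onset(plan, tr)
      sp <- osc
      sp$amplitude <- osc$amplitude * theta_factor[tr]
      osc_wave <- oscillation_waveform(sp, n_enc, fs, n_channels)
      i0 <- round(onset * fs)
      rec$samples[, (i0 + 1):(i0 + n_enc)] <-
        rec$samples[, (i0 + 1):(i0 + n_enc)] + osc_wave
    }
    spike_onsets <- numeric(0)
    if (!is.null(spikes) && spikes$rate > 0) {
      res <- inject_spikes(rec, spikes)
      rec <- res$epoch
      spike_onsets <- res$onsets
    }
    # success model: logit linear in standardized log theta factor
    z <- log(theta_factor)
    z <- if (stats::sd(z) > 0) (z - mean(z)) / stats::sd(z) else rep(0, n_trials)
    eta <- stats::qlogis(learner$base_success_prob) +
      2 * learner$behavior_coupling * z
    p <- stats::plogis(eta)
    task1_success <- stats::runif(n_trials) < p
    task2_success <- stats::runif(n_trials) < p
    truth <- list(
      trials = data.frame(trial = seq_len(n_trials),
                          theta_factor = theta_factor,
                          task1_success = task1_success,
                          task2_success = task2_success),
      spike_onsets = spike_onsets,
      session = session
    )
    list(recording = rec, truth = truth)
  })
}

#' Convert ground-truth success indicators into keystroke responses
#'
#' A successful Task 1 trial answers the old/new probe correctly; a failed
#' one gives the opposite answer. Task 2 (the probe's presentation
#' position) is answered only when the probe was called "old": success
#' yields the correct position, failure a uniformly random wrong position.
#'
#' @param plan a [schedule_session()] plan.
#' @param truth ground truth from [generate_session()].
#' @param seed integer seed for the wrong-position draws.
#' @return a data frame with columns `trial`, `task1_answer` ("old"/"new")
#'   and `task2_answer` (integer position or `NA`).
#' @export
simulate_responses <- function(plan, truth, seed = NULL) {
  n_trials <- length(plan$trials)
  tt <- truth$trials
  stopifnot(nrow(tt) == n_trials)
  with_seed(seed, {
    task1 <- character(n_trials)
    task2 <- rep(NA_integer_, n_trials)
    for (i in seq_len(n_trials)) {
      tp <- plan$trials[[i]]
      correct1 <- if (tp$probe_is_old) "old" else "new"
      wrong1 <- if (tp$probe_is_old) "new" else "old"
      task1[i] <- if (tt$task1_success[i]) correct1 else wrong1
      if (task1[i] == "old" && tp$probe_is_old) {
        if (tt$task2_success[i]) {
          task2[i] <- tp$correct_position
        } else {
          task2[i] <- sample(setdiff(1:5, tp$correct_position), 1)
        }
      } else if (task1[i] == "old" && !tp$probe_is_old) {
        task2[i] <- sample(1:5, 1)  # false alarm still gets a position probe
      }
    }
    data.frame(trial = seq_len(n_trials), task1_answer = task1,
               task2_answer = task2, stringsAsFactors = FALSE)
  })
}
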