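#' Exceedance fraction of an epoch
#'
#' Fraction of samples whose deviation from the channel mean exceeds three
#' channel standard deviations, computed over the whole epoch. The pooled
#' fraction (total exceeding samples over total samples, channel means/SDs
#' applied per channel) drives the adaptive choice of the ASR cutoff
#' parameter; per-channel fractions are reported alongside.
#'
#' @param epoch a [signal_epoch()] (typically one 13 s encoding epoch).
#' @param n_sd deviation threshold in standard deviations (default 3).
#' @return a list with `fraction` (pooled) and `per_channel`.
#' @export
compute_exceedance <- function(epoch, n_sd = 3) {
  x <- epoch$samples
  if (length(x) == 0) stop("empty epoch", call. = FALSE)
  mu <- rowMeans(x)
  sdv <- apply(x, 1, stats::sd)
  exceed <- abs(x - mu) > n_sd * sdv
  exceed[sdv == 0, ] <- FALSE   # constant channel: nothing exceeds
  per_channel <- rowMeans(exceed)
  list(fraction = mean(exceed), per_channel = per_channel)
}

#' Adaptive ASR cutoff selection
#'
#' Piecewise-constant rule mapping the epoch's exceedance fraction to the
#' ASR rejection cutoff `k`: below 1% contamination a permissive `k = 10`,
#' in the closed band 1-1.5% `k = 6`, above 1.5% an aggressive `k = 4`.
#'
#' @param fraction exceedance fraction in `[0, 1]`.
#' @return integer `k` (10, 6 or 4).
#' @examples
#' select_k(0.005)  # 10
#' select_k(0.012)  # 6
#' select_k(0.02)   # 4
#' @export
select_k <- function(fraction) {
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      is.na(fraction) || fraction < 0 || fraction > 1) {
    stop("'fraction' must be a single value in [0, 1]", call. = FALSE)
  }
  if (fraction < 0.01) 10L else if (fraction <= 0.015) 6L else 4L
}

#' ASR parameters
#'
#' @param k rejection cutoff in robust standard deviations (> 0).
#' @param window sliding-window length in seconds (default 0.5; windows
#'   overlap by 50% and are re-blended with raised-cosine weights).
#' @return an `asr_params` list.
#' @export
asr_params <- function(k = 4, window = 0.5) {
  stopifnot(k > 0, window > 0)
  structure(list(k = k, window = window), class = "asr_params")
}

# Sliding window start indices (50% overlap), covering the whole signal.
asr_windows <- function(n, wlen) {
  step <- max(1, wlen %/% 2)
  starts <- seq(1, max(1, n - wlen + 1), by = step)
  if (starts[length(starts)] + wlen - 1 < n) {
    starts <- c(starts, n - wlen + 1)
  }
  starts
}

#' Calibrate artifact subspace reconstruction on clean reference data
#'
#' Eigendecomposes the reference covariance to obtain the component basis,
#' then summarizes the distribution of per-component sliding-window RMS by
#' robust location and scale (median and scaled MAD). Cleaning later
#' rejects window components whose RMS exceeds `mu_c + k * sigma_c`.
#'
#' @param reference a low-artifact [signal_epoch()] (the session's opening
#'   rest period is the natural choice); must span at least 10 windows.
#' @param params an [asr_params()].
#' @return an `asr_calibration`: orthonormal `basis` (columns are
#'   components), reference eigenvalues `variances`, robust RMS location
#'   `mu` and scale `sigma` per component, window length, `fs` and channel
#'   count.
#' @export
asr_calibrate <- function(reference, params = asr_params()) {
  fs <- reference$fs
  wlen <- round(params$window * fs)
  if (n_samples(reference) < 10 * wlen) {
    stop("reference must span at least 10 ASR windows", call. = FALSE)
  }
  x <- reference$samples
  x <- x - rowMeans(x)
  C <- tcrossprod(x) / ncol(x)
  eg <- eigen(C, symmetric = TRUE)
  if (min(eg$values) <= 1e-12 * max(eg$values)) {
    bad <- reference$channel_labels[
      apply(abs(eg$vectors[, eg$values <= 1e-12 * max(eg$values),
                           drop = FALSE]), 1, max) > 0.5]
    stop(sprintf("rank-deficient reference covariance (channels: %s)",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  V <- eg$vectors
  comps <- crossprod(V, x)                       # components x samples
  starts <- asr_windows(ncol(x), wlen)
  rms <- sapply(starts, function(s) {
    sqrt(rowMeans(comps[, s:(s + wlen - 1), drop = FALSE]^2))
  })
  if (is.null(dim(rms))) rms <- matrix(rms, nrow = 1)
  mu <- apply(rms, 1, stats::median)
  sigma <- apply(rms, 1, stats::mad)             # scaled MAD (x1.4826)
  sigma <- pmax(sigma, 1e-12 * mu)
  structure(list(basis = V, variances = eg$values, mu = mu, sigma = sigma,
                 window = params$window, fs = fs, n_channels = nrow(x)),
            class = "asr_calibration")
}

#' Clean an epoch by artifact subspace reconstruction
#'
#' Slides half-overlapping windows over the epoch; in each window the
#' window covariance is eigendecomposed, and window components whose
#' variance exceeds the calibration threshold (the reference RMS
#' thresholds `mu_c + k * sigma_c` mapped into the window basis) are
#' flagged as artifact. Flagged components are re-imputed from the
#' retained ones using the reference covariance (conditional expectation),
#' so the reconstruction stays inside the calibration subspace. Windows
#' are re-blended with raised-cosine weights.
#'
#' @param epoch a [signal_epoch()] with the calibration's channel count.
#' @param calib an [asr_calibrate()] result.
#' @param k rejection cutoff (> 0); smaller values reject more.
#' @return a list with `epoch` (cleaned, same shape) and `log` (per-window
#'   data frame: window start time, components rejected, energy removed).
#' @export
asr_clean <- function(epoch, calib, k = 4) {
  if (k <= 0) stop("'k' must be positive", call. = FALSE)
  if (n_channels(epoch) != calib$n_channels) {
    stop("channel count does not match calibration", call. = FALSE)
  }
  x <- epoch$samples
  n <- ncol(x)
  nch <- nrow(x)
  wlen <- round(calib$window * epoch$fs)
  starts <- asr_windows(n, wlen)
  V <- calib$basis
  thr <- calib$mu + k * calib$sigma              # RMS thresholds, calib basis
  Tmat <- V %*% diag(thr, nch)                   # threshold operator
  Cref <- V %*% diag(calib$variances, nch) %*% t(V)
  out <- matrix(0, nch, n)
  wsum <- numeric(n)
  taper <- 0.5 - 0.5 * cos(2 * pi * (seq_len(wlen) - 0.5) / wlen)
  nrej <- integer(length(starts))
  erem <- numeric(length(starts))
  for (w in seq_along(starts)) {
    idx <- starts[w]:(starts[w] + wlen - 1)
    seg <- x[, idx, drop = FALSE]
    Cw <- tcrossprod(seg) / wlen
    eg <- eigen(Cw, symmetric = TRUE)
    U <- eg$vectors
    d <- pmax(eg$values, 0)
    # artifact if window component RMS^2 exceeds the threshold operator
    # projected onto that direction
    lim <- colSums((t(Tmat) %*% U)^2)
    keep <- d <= lim
    if (all(keep)) {
      clean <- seg
    } else {
      y <- crossprod(U, seg)                     # window components
      Sig <- t(U) %*% Cref %*% U                 # reference cov, window basis
      f <- which(!keep); r <- which(keep)
      if (length(r) == 0) {
        y[] <- 0
      } else {
        B <- Sig[f, r, drop = FALSE] %*%
          solve(Sig[r, r, drop = FALSE] +
                  diag(1e-9 * mean(diag(Sig)), length(r)))
        y[f, ] <- B %*% y[r, , drop = FALSE]
      }
      clean <- U %*% y
      nrej[w] <- length(f)
      erem[w] <- sum((seg - clean)^2)
    }
    out[, idx] <- out[, idx] + clean * rep(taper, each = nch)
    wsum[idx] <- wsum[idx] + taper
  }
  out <- out / rep(pmax(wsum, 1e-12), each = nch)
  cleaned <- epoch
  cleaned$samples <- out
  list(epoch = cleaned,
       log = data.frame(window_start = (starts - 1) / epoch$fs,
                        n_rejected = nrej, energy_removed = erem))
}
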