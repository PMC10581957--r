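#' Multichannel signal epoch
#'
#' The basic container every DSP stage in the package consumes and produces:
#' a channels-by-samples matrix of potentials in microvolts together with the
#' sampling rate, contact labels and the epoch start time relative to the
#' session origin.
#'
#' @param samples numeric matrix, `n_channels x n_samples`, in microvolts.
#'   A plain numeric vector is treated as a single channel.
#' @param fs sampling rate in Hz (default 512, the acquisition rate of the
#'   4-contact mesial temporal montage the toolkit emulates).
#' @param channel_labels character vector of contact names; defaults to
#'   `MTL1..MTLn`.
#' @param start_time epoch onset in seconds from session start.
#' @return An object of class `signal_epoch`.
#' @examples
#' ep <- signal_epoch(matrix(rnorm(2 * 512), 2), fs = 512)
#' epoch_duration(ep)
#' @export
signal_epoch <- function(samples, fs = 512, channel_labels = NULL,
                         start_time = 0) {
  if (is.vector(samples) && is.numeric(samples)) {
    samples <- matrix(samples, nrow = 1)
  }
  stopifnot(is.matrix(samples), is.numeric(samples))
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    stop("'fs' must be a single positive number", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("all samples must be finite", call. = FALSE)
  }
  nch <- nrow(samples)
  if (is.null(channel_labels)) {
    channel_labels <- paste0("MTL", seq_len(nch))
  }
  if (length(channel_labels) != nch) {
    stop("'channel_labels' length must equal the number of channels",
         call. = FALSE)
  }
  structure(
    list(samples = samples, fs = fs,
         channel_labels = as.character(channel_labels),
         start_time = as.numeric(start_time)),
    class = "signal_epoch"
  )
}

#' @export
print.signal_epoch <- function(x, ...) {
  cat(sprintf("<signal_epoch> %d channel(s) x %d samples @ %g Hz (%.3f s), t0 = %.3f s\n",
              n_channels(x), n_samples(x), x$fs, epoch_duration(x),
              x$start_time))
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  invisible(x)
}

#' Epoch geometry helpers
#'
#' @param epoch a [signal_epoch()].
#' @return `n_channels`/`n_samples` return integers, `epoch_duration` the
#'   duration in seconds, `epoch_times` the per-sample time axis in seconds
#'   from session start.
#' @export
n_channels <- function(epoch) nrow(epoch$samples)

#' @rdname n_channels
#' @export
n_samples <- function(epoch) ncol(epoch$samples)

#' @rdname n_channels
#' @export
epoch_duration <- function(epoch) n_samples(epoch) / epoch$fs

#' @rdname n_channels
#' @export
epoch_times <- function(epoch) {
  epoch$start_time + (seq_len(n_samples(epoch)) - 1) / epoch$fs
}

#' Extract a time slice from an epoch
#'
#' @param epoch a [signal_epoch()].
#' @param from,to slice bounds in seconds relative to the epoch's own start
#'   (`from` inclusive, `to` exclusive); the slice covers
#'   `round(from * fs) + 1 .. round(to * fs)` samples.
#' @return a [signal_epoch()] with `start_time` shifted accordingly.
#' @export
epoch_slice <- function(epoch, from, to) {
  i0 <- round(from * epoch$fs)
  i1 <- round(to * epoch$fs)
  if (i0 < 0 || i1 > n_samples(epoch) || i1 <= i0) {
    stop(sprintf("slice [%g, %g) s outside epoch of %g s", from, to,
                 epoch_duration(epoch)), call. = FALSE)
  }
  signal_epoch(epoch$samples[, (i0 + 1):i1, drop = FALSE], fs = epoch$fs,
               channel_labels = epoch$channel_labels,
               start_time = epoch$start_time + i0 / epoch$fs)
}

# Run code with a private RNG stream: seeds the global RNG, restores the
# caller's .Random.seed on exit so generators do not perturb user code.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}
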