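# Fixed-width ASCII field, space padded, as the EDF header requires.
edf_field <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) stop(sprintf("EDF field '%s' exceeds %d chars", s,
                                     width), call. = FALSE)
  formatC(s, width = -width)
}

# Numeric EDF field that must fit 8 chars.
edf_num8 <- function(x) {
  for (d in 7:2) {
    s <- formatC(x, digits = d, format = "g", width = 0)
    if (nchar(s) <= 8) return(edf_field(s, 8))
  }
  stop("cannot format number in 8 chars", call. = FALSE)
}

#' Write / read a continuous recording as EDF
#'
#' Plain European Data Format: 16-bit samples, one-second data records,
#' physical dimension microvolts, symmetric physical range per channel.
#' Recordings are padded with zeros to a whole number of records, so
#' round-trips preserve the sampling rate and channel labels exactly and
#' the samples to within the 16-bit quantization step of the physical
#' range.
#'
#' @param epoch a [signal_epoch()]; `fs` must be a whole number.
#' @param path output file path.
#' @param recording_id free-text recording identifier (80 chars max).
#' @return `write_edf` returns `path` invisibly; `read_edf` returns a
#'   [signal_epoch()].
#' @export
write_edf <- function(epoch, path, recording_id = "thetanf synthetic iEEG") {
  fs <- epoch$fs
  if (abs(fs - round(fs)) > 1e-9) stop("EDF export needs integer fs",
                                       call. = FALSE)
  fs <- as.integer(round(fs))
  x <- epoch$samples
  nch <- nrow(x)
  n_rec <- ceiling(ncol(x) / fs)
  if (ncol(x) < n_rec * fs) {
    x <- cbind(x, matrix(0, nch, n_rec * fs - ncol(x)))
  }
  pmax_v <- pmax(apply(abs(x), 1, max), 1e-6)
  pmax_v <- vapply(pmax_v, function(v) as.numeric(formatC(v * 1.001,
                   digits = 6, format = "g")), numeric(1))
  pmin_v <- -pmax_v
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  put <- function(s) writeChar(s, con, eos = NULL)
  put(edf_field("0", 8))
  put(edf_field("X X X X", 80))
  put(edf_field(recording_id, 80))
  put(edf_field("01.01.00", 8))
  put(edf_field("00.00.00", 8))
  put(edf_field(256 * (nch + 1), 8))
  put(edf_field("", 44))
  put(edf_field(n_rec, 8))
  put(edf_field("1", 8))
  put(edf_field(nch, 4))
  for (lab in epoch$channel_labels) put(edf_field(lab, 16))
  for (i in seq_len(nch)) put(edf_field("", 80))
  for (i in seq_len(nch)) put(edf_field("uV", 8))
  for (i in seq_len(nch)) put(edf_num8(pmin_v[i]))
  for (i in seq_len(nch)) put(edf_num8(pmax_v[i]))
  for (i in seq_len(nch)) put(edf_field(dmin, 8))
  for (i in seq_len(nch)) put(edf_field(dmax, 8))
  for (i in seq_len(nch)) put(edf_field("", 80))
  for (i in seq_len(nch)) put(edf_field(fs, 8))
  for (i in seq_len(nch)) put(edf_field("", 32))
  gain <- (pmax_v - pmin_v) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (ch in seq_len(nch)) {
      d <- round((x[ch, idx] - pmin_v[ch]) / gain[ch] + dmin)
      d <- pmin(pmax(d, dmin), dmax)
      writeBin(as.integer(d), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' @rdname write_edf
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  grab <- function(width) {
    s <- readChar(con, width, useBytes = TRUE)
    if (nchar(s) < width) stop(sprintf(
      "malformed EDF header in '%s' at byte offset %d", path,
      seek(con, NA)), call. = FALSE)
    trimws(s)
  }
  grab(8); grab(80); grab(80); grab(8); grab(8)
  header_bytes <- as.integer(grab(8))
  grab(44)
  n_rec <- as.integer(grab(8))
  rec_dur <- as.numeric(grab(8))
  nch <- as.integer(grab(4))
  if (is.na(nch) || nch < 1 || is.na(n_rec) ||
      header_bytes != 256 * (nch + 1)) {
    stop(sprintf("malformed EDF header in '%s' at byte offset 256", path),
         call. = FALSE)
  }
  labels <- vapply(seq_len(nch), function(i) grab(16), "")
  for (i in seq_len(nch)) grab(80)
  for (i in seq_len(nch)) grab(8)            # physical dimension
  pmin_v <- vapply(seq_len(nch), function(i) as.numeric(grab(8)), 0)
  pmax_v <- vapply(seq_len(nch), function(i) as.numeric(grab(8)), 0)
  dmin_v <- vapply(seq_len(nch), function(i) as.numeric(grab(8)), 0)
  dmax_v <- vapply(seq_len(nch), function(i) as.numeric(grab(8)), 0)
  for (i in seq_len(nch)) grab(80)
  spr <- vapply(seq_len(nch), function(i) as.integer(grab(8)), 0L)
  for (i in seq_len(nch)) grab(32)
  fs <- spr[1] / rec_dur
  samples <- matrix(0, nch, n_rec * spr[1])
  gain <- (pmax_v - pmin_v) / (dmax_v - dmin_v)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(nch)) {
      d <- readBin(con, integer(), n = spr[ch], size = 2, signed = TRUE,
                   endian = "little")
      if (length(d) < spr[ch]) stop(sprintf(
        "truncated EDF data in '%s' (record %d)", path, r), call. = FALSE)
      idx <- ((r - 1) * spr[ch] + 1):(r * spr[ch])
      samples[ch, idx] <- (d - dmin_v[ch]) * gain[ch] + pmin_v[ch]
    }
  }
  signal_epoch(samples, fs = fs, channel_labels = labels)
}

EVENT_TYPES <- c("rest", "word", "probe_task1", "probe_task2", "feedback")

#' Write / read an events table as TSV
#'
#' Tab-separated file with the fixed header `onset`, `duration`,
#' `trial_index`, `event_type` (onset and duration in seconds). The event
#' vocabulary is closed: rest, word, probe_task1, probe_task2, feedback.
#'
#' @param events a data frame as produced by [session_events()].
#' @param path file path.
#' @return `write_events` returns `path` invisibly; `read_events` the
#'   validated data frame.
#' @export
write_events <- function(events, path) {
  stopifnot(all(c("onset", "duration", "trial_index", "event_type")
                %in% names(events)))
  bad <- setdiff(unique(events$event_type), EVENT_TYPES)
  if (length(bad)) stop(sprintf("unknown event type(s): %s",
                                paste(bad, collapse = ", ")), call. = FALSE)
  utils::write.table(events[, c("onset", "duration", "trial_index",
                                "event_type")],
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(identical(names(ev), c("onset", "duration", "trial_index",
                                   "event_type")))
  bad <- setdiff(unique(ev$event_type), EVENT_TYPES)
  if (length(bad)) stop(sprintf("unknown event type(s): %s",
                                paste(bad, collapse = ", ")), call. = FALSE)
  if (is.unsorted(ev$onset)) stop("event onsets must be non-decreasing",
                                  call. = FALSE)
  ev
}

#' Write / read a lexicon as CSV
#'
#' @param lexicon a [build_lexicon()] data frame.
#' @param path file path.
#' @export
write_lexicon <- function(lexicon, path) {
  utils::write.csv(lexicon[, c("token", "familiarity")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_lexicon
#' @export
read_lexicon <- function(path) {
  lx <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(identical(names(lx), c("token", "familiarity")))
  structure(lx, class = c("lexicon", "data.frame"))
}

#' Serialize / restore a session plan as JSON
#'
#' @param plan a `session_plan`.
#' @param path file path.
#' @export
write_plan <- function(plan, path) {
  jsonlite::write_json(unclass(plan), path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_plan
#' @export
read_plan <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  trials <- lapply(raw$trials, function(t) {
    list(word_set = list(words = unlist(t$word_set$words),
                         mean_familiarity = t$word_set$mean_familiarity),
         presented = unlist(t$presented),
         probe = t$probe,
         probe_is_old = isTRUE(t$probe_is_old),
         correct_position = if (is.null(t$correct_position) ||
                                !is.numeric(t$correct_position))
                              NA_integer_
                            else as.integer(t$correct_position))
  })
  structure(list(trials = trials, timeline = lapply(raw$timeline, as.numeric)),
            class = "session_plan")
}

#' Write ground truth as a JSON sidecar
#'
#' @param truth ground truth from [generate_session()].
#' @param path file path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  raw <- jsonlite::fromJSON(path)
  list(trials = as.data.frame(raw$trials),
       spike_onsets = as.numeric(unlist(raw$spike_onsets)),
       session = as.integer(raw$session))
}
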