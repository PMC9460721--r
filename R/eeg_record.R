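#' Multichannel EEG recording
#'
#' Container for one continuous multichannel recording: a channels x samples
#' matrix of physical amplitudes (microvolts), the sampling rate, ordered
#' channel names and an optional absolute start offset used when several
#' records of one patient must be placed on a common time axis (the
#' interictal margin rule spans record boundaries).
#'
#' @param data numeric matrix, channels in rows, samples in columns.
#' @param fs sampling rate in Hz (> 0).
#' @param channel_names character vector, one name per row of `data`.
#'   Names are canonicalized (see [canonical_channel_names()]) and must be
#'   unique afterwards.
#' @param record_id identifier string.
#' @param start_offset start time of this record in seconds on the patient's
#'   absolute time axis (default 0).
#' @return An object of class `eeg_record`.
#' @export
eeg_record <- function(data, fs, channel_names,
                       record_id = "record", start_offset = 0) {
  if (!is.matrix(data) || !is.numeric(data))
    stop("`data` must be a numeric matrix (channels x samples)")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a single positive number")
  if (ncol(data) < 1L) stop("record must contain at least one sample")
  channel_names <- canonical_channel_names(channel_names)
  if (length(channel_names) != nrow(data))
    stop("length(channel_names) must equal nrow(data)")
  if (anyDuplicated(channel_names))
    stop("duplicate channel names after canonicalization: ",
         paste(unique(channel_names[duplicated(channel_names)]), collapse = ", "))
  rownames(data) <- channel_names
  structure(
    list(record_id = as.character(record_id), data = data, fs = fs,
         channel_names = channel_names, start_offset = as.numeric(start_offset)),
    class = "eeg_record")
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("<eeg_record> %s: %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$record_id, nrow(x$data), ncol(x$data), x$fs,
              ncol(x$data) / x$fs))
  invisible(x)
}

#' Record duration in seconds
#' @param record an [eeg_record()].
#' @return duration in seconds.
#' @export
record_duration <- function(record) ncol(record$data) / record$fs

#' Canonicalize EEG channel labels
#'
#' Uppercases, trims and squeezes whitespace, and strips trailing `-0` /
#' `-REF` suffix variants so that label variations between files (and between
#' bipolar and referential naming) compare equal.
#'
#' @param x character vector of raw labels.
#' @return character vector of canonical labels.
#' @export
canonical_channel_names <- function(x) {
  x <- toupper(trimws(as.character(x)))
  x <- gsub("[[:space:]]+", " ", x)
  sub("-(0|REF)$", "", x)
}
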