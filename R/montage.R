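#' Channel montages
#'
#' A montage is the ordered set of channels fed to the classifier. Two
#' standard montages ship with the package: the 18-channel longitudinal
#' bipolar montage shared across the CHB-MIT corpus and a 16-channel
#' referential montage (10-20 electrodes against a common reference,
#' `-Ref` suffixes stripped by canonicalization).
#'
#' @param name montage name.
#' @param channels ordered character vector of channel names.
#' @return object of class `montage_spec` with fields `name`, `channels`,
#'   `expected_count`.
#' @export
montage_spec <- function(name, channels) {
  channels <- canonical_channel_names(channels)
  if (anyDuplicated(channels))
    stop("montage has duplicate channels after canonicalization")
  structure(list(name = as.character(name), channels = channels,
                 expected_count = length(channels)),
            class = "montage_spec")
}

#' @rdname montage_spec
#' @export
montage_chbmit <- function() {
  montage_spec("chbmit18", c(
    "FP1-F7", "F7-T7", "T7-P7", "P7-O1",
    "FP1-F3", "F3-C3", "C3-P3", "P3-O1",
    "FP2-F4", "F4-C4", "C4-P4", "P4-O2",
    "FP2-F8", "F8-T8", "T8-P8", "P8-O2",
    "FZ-CZ", "CZ-PZ"))
}

#' @rdname montage_spec
#' @export
montage_zju4h <- function() {
  montage_spec("zju4h16", c(
    "FP1-REF", "FP2-REF", "F3-REF", "F4-REF", "C3-REF", "C4-REF",
    "P3-REF", "P4-REF", "O1-REF", "O2-REF", "F7-REF", "F8-REF",
    "T3-REF", "T4-REF", "T5-REF", "T6-REF"))
}

#' @rdname montage_spec
#' @param path JSON file with fields `name` and `channels`.
#' @export
read_montage <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$name) || is.null(cfg$channels))
    stop("montage config needs fields `name` and `channels`: ", path)
  montage_spec(cfg$name, cfg$channels)
}

#' @rdname montage_spec
#' @param montage a `montage_spec`.
#' @export
write_montage <- function(montage, path) {
  jsonlite::write_json(list(name = montage$name, channels = montage$channels),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Select and order the montage channels of a record
#'
#' Returns the record restricted to exactly the montage channels, in
#' montage order. Missing channels are an error (records with missing
#' montage channels are skipped upstream in the pipeline).
#'
#' @param record an [eeg_record()].
#' @param montage a [montage_spec()].
#' @return an [eeg_record()] with `expected_count` channels.
#' @export
select_montage <- function(record, montage) {
  missing <- setdiff(montage$channels, record$channel_names)
  if (length(missing))
    stop("record ", record$record_id, " is missing montage channels: ",
         paste(missing, collapse = ", "))
  idx <- match(montage$channels, record$channel_names)
  eeg_record(record$data[idx, , drop = FALSE], fs = record$fs,
             channel_names = montage$channels, record_id = record$record_id,
             start_offset = record$start_offset)
}
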