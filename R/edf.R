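# Minimal EDF/EDF+ continuous-recording I/O.
#
# EDF stores fixed-width ASCII headers followed by 16-bit little-endian
# integer data records; physical values are recovered by the per-signal
# linear map (digital range -> physical range). Only what the pipeline
# needs is implemented: equal sampling rate across kept signals, one
# contiguous recording per file. Annotation signals ("EDF Annotations")
# are dropped on read.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = width, flag = "-")
}

edf_num <- function(x, width) {
  s <- formatC(x, width = width, format = "g", digits = max(1L, width - 2L))
  s <- trimws(s)
  if (nchar(s) > width) s <- substr(s, 1L, width)
  edf_pad(s, width)
}

# seconds since 2000-01-01 00:00:00 UTC <-> EDF date/time fields
edf_epoch <- function() ISOdatetime(2000, 1, 1, 0, 0, 0, tz = "UTC")

#' Read an EDF/EDF+ recording
#'
#' Reads all ordinary signal channels of a European Data Format file at the
#' file's native sampling rate. Channel labels are canonicalized
#' ([canonical_channel_names()]); when canonicalization produces duplicate
#' labels (CHB-MIT files repeat e.g. `T8-P8`), the first occurrence is kept
#' and later ones are dropped with a warning.
#'
#' @param path path to an `.edf` file.
#' @return An [eeg_record()]. `start_offset` is the recording start time in
#'   seconds relative to 2000-01-01 00:00:00 (only differences between
#'   records of one patient are ever used).
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("cannot read EDF file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) {
    raw <- readBin(con, "raw", n = n)
    if (length(raw) < n) stop("truncated EDF header in ", path)
    rawToChar(raw)
  }
  rd(8)                                   # version
  rd(80); rd(80)                          # patient / recording id
  startdate <- trimws(rd(8))
  starttime <- trimws(rd(8))
  header_bytes <- as.integer(rd(8))
  rd(44)
  n_records <- as.integer(rd(8))
  record_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1L)
    stop("unsupported EDF file (no signal channels): ", path)

  labels   <- vapply(seq_len(ns), function(i) trimws(rd(16)), "")
  for (i in seq_len(ns)) rd(80)           # transducer
  for (i in seq_len(ns)) rd(8)            # physical dimension
  phys_min <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  phys_max <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dig_min  <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dig_max  <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)           # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)           # reserved
  stopifnot(header_bytes == 256L + 256L * ns)

  keep <- toupper(labels) != "EDF ANNOTATIONS"
  if (!any(keep))
    stop("unsupported EDF file (annotation-only, no signal channels): ", path)
  if (length(unique(spr[keep])) != 1L)
    stop("unsupported EDF file (channels with differing sampling rates): ",
         path)
  fs <- spr[keep][1L] / record_dur

  raw <- readBin(con, "integer", n = n_records * sum(spr), size = 2L,
                 signed = TRUE, endian = "little")
  if (length(raw) < n_records * sum(spr))
    stop("truncated EDF data records in ", path)

  # de-interleave: each record holds spr[i] samples of signal i in turn
  offsets <- c(0L, cumsum(spr))
  rec_len <- sum(spr)
  n_keep <- sum(keep)
  data <- matrix(0, nrow = n_keep, ncol = n_records * spr[keep][1L])
  row <- 0L
  for (i in seq_len(ns)) {
    if (!keep[i]) next
    row <- row + 1L
    idx <- as.vector(outer(seq_len(spr[i]) + offsets[i],
                           (seq_len(n_records) - 1L) * rec_len, `+`))
    dig <- raw[idx]
    scale <- (phys_max[i] - phys_min[i]) / (dig_max[i] - dig_min[i])
    data[row, ] <- (dig - dig_min[i]) * scale + phys_min[i]
  }

  can <- canonical_channel_names(labels[keep])
  if (anyDuplicated(can)) {
    warning("duplicate channel labels after canonicalization in ", path,
            "; keeping first occurrence of: ",
            paste(unique(can[duplicated(can)]), collapse = ", "))
    first <- !duplicated(can)
    data <- data[first, , drop = FALSE]
    can <- can[first]
  }

  start_offset <- tryCatch({
    d <- as.integer(strsplit(startdate, ".", fixed = TRUE)[[1]])
    t <- as.integer(strsplit(starttime, ".", fixed = TRUE)[[1]])
    year <- if (d[3] >= 85L) 1900L + d[3] else 2000L + d[3]
    as.numeric(difftime(ISOdatetime(year, d[2], d[1], t[1], t[2], t[3],
                                    tz = "UTC"),
                        edf_epoch(), units = "secs"))
  }, error = function(e) 0)

  eeg_record(data, fs = fs, channel_names = can,
             record_id = sub("\\.edf$", "", basename(path),
                             ignore.case = TRUE),
             start_offset = start_offset)
}

#' Write an EEG record to EDF
#'
#' Writes 16-bit EDF with one-second data records; each channel is scaled
#' to a symmetric physical range covering its data. Amplitudes therefore
#' round-trip within one 16-bit quantization step of that range. The sample
#' count must be a whole number of data records (whole seconds at integer
#' `fs`).
#'
#' @param record an [eeg_record()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(record, path) {
  data <- record$data
  fs <- record$fs
  if (abs(fs - round(fs)) > 1e-9)
    stop("write_edf requires an integer sampling rate")
  fs <- as.integer(round(fs))
  n <- ncol(data)
  if (n %% fs != 0L)
    stop("write_edf requires a whole number of 1-second data records")
  n_records <- n %/% fs
  ns <- nrow(data)

  phys_max <- apply(abs(data), 1L, max)
  phys_max[phys_max == 0] <- 1
  dig <- matrix(0L, nrow = ns, ncol = n)
  for (i in seq_len(ns))
    dig[i, ] <- as.integer(round(data[i, ] / phys_max[i] * 32767))

  start <- edf_epoch() + record$start_offset
  lt <- as.POSIXlt(start, tz = "UTC")

  con <- file(path, "wb")
  on.exit(close(con))
  w <- function(x, width) writeBin(charToRaw(edf_pad(x, width)), con)
  w("0", 8)
  w(paste0("X X X ", record$record_id), 80)
  w(paste0("Startdate X X X X ", record$record_id), 80)
  w(sprintf("%02d.%02d.%02d", lt$mday, lt$mon + 1L, lt$year %% 100L), 8)
  w(sprintf("%02d.%02d.%02d", lt$hour, lt$min, as.integer(lt$sec)), 8)
  w(as.character(256L + 256L * ns), 8)
  w("", 44)
  w(as.character(n_records), 8)
  w("1", 8)
  w(as.character(ns), 4)
  for (i in seq_len(ns)) w(record$channel_names[i], 16)
  for (i in seq_len(ns)) w("", 80)
  for (i in seq_len(ns)) w("uV", 8)
  for (i in seq_len(ns)) w(edf_num(-phys_max[i], 8), 8)
  for (i in seq_len(ns)) w(edf_num(phys_max[i], 8), 8)
  for (i in seq_len(ns)) w("-32767", 8)
  for (i in seq_len(ns)) w("32767", 8)
  for (i in seq_len(ns)) w("", 80)
  for (i in seq_len(ns)) w(as.character(fs), 8)
  for (i in seq_len(ns)) w("", 32)

  # interleave records: record r = fs samples of ch1, then ch2, ...
  idx <- matrix(seq_len(n), nrow = fs)          # samples per record
  for (r in seq_len(n_records))
    writeBin(as.integer(t(dig[, idx[, r], drop = FALSE])), con,
             size = 2L, endian = "little")
  invisible(path)
}
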