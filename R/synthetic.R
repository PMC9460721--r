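# Synthetic multichannel EEG with annotated seizures.
#
# The generator states a simple world the pipeline must detect: a 1/f^beta
# Gaussian background per channel, a band-limited (< 50 Hz) low-frequency
# rhythm added during the 15 min before each seizure onset at
# `amplitude_ratio` times the background RMS, and a high-amplitude 4-12 Hz
# burst during the seizure itself. Everything is deterministic given the
# seed. It emulates sampling-rate/channel-count conventions of scalp EEG
# corpora, not EEG physiology.

#' Specification of a synthetic EEG record
#'
#' @param n_channels number of channels (default 4).
#' @param fs sampling rate in Hz (default 256, the common scalp-EEG rate).
#' @param duration record length in seconds.
#' @param seizure_times data.frame with columns `onset`, `offset`
#'   (seconds, disjoint, inside the record) or `NULL`.
#' @param beta spectral slope of the 1/f^beta background (default 1).
#' @param sigma_bg background RMS amplitude in microvolts (default 30).
#' @param rhythm_hz preictal rhythm frequency (default 3 Hz; must be
#'   < 50 Hz so the band limit retains it).
#' @param amplitude_ratio preictal rhythm amplitude as a multiple of
#'   `sigma_bg` (default 4, >= 1).
#' @param chirp optional `c(f_start, f_end)`: sweep the preictal rhythm
#'   linearly instead of a fixed tone.
#' @param seed integer seed.
#' @param record_id,start_offset passed through to the record.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_channels = 4, fs = 256, duration = 600,
                           seizure_times = NULL, beta = 1,
                           sigma_bg = 30, rhythm_hz = 3,
                           amplitude_ratio = 4, chirp = NULL,
                           seed = 1L, record_id = "synthetic",
                           start_offset = 0) {
  if (rhythm_hz >= 50) stop("rhythm_hz must be below 50 Hz")
  if (amplitude_ratio < 1) stop("amplitude_ratio must be >= 1")
  if (beta < 0.5 - 1e-9 || beta > 1.5 + 1e-9)
    stop("beta must lie in [0.5, 1.5]")
  if (!is.null(seizure_times) && nrow(seizure_times)) {
    st <- seizure_times[order(seizure_times$onset), , drop = FALSE]
    if (any(st$onset < 0) || any(st$offset > duration) ||
        any(st$offset <= st$onset))
      stop("seizure intervals must be disjoint and inside the record")
    if (nrow(st) > 1 && any(st$onset[-1] < st$offset[-nrow(st)]))
      stop("seizure intervals must be disjoint")
    seizure_times <- st
    rm(st)
  }
  structure(as.list(environment()), class = "synthetic_spec")
}

# 1/f^beta Gaussian noise, unit variance
pink_noise <- function(n, beta) {
  X <- fft(rnorm(n))
  k <- seq_len(n) - 1L
  f <- pmin(k, n - k) / n
  shape <- c(0, f[-1]^(-beta / 2))
  x <- Re(fft(X * shape, inverse = TRUE)) / n
  x / sd(x)
}

#' Generate one synthetic annotated EEG record
#'
#' @param spec a [synthetic_spec()].
#' @return list with `record` (an [eeg_record()]) and `annotations`
#'   (a `seizure_annotation` data.frame, possibly empty).
#' @export
generate_record <- function(spec) {
  n <- as.integer(round(spec$duration * spec$fs))
  t <- (seq_len(n) - 1L) / spec$fs
  st <- spec$seizure_times
  pre_windows <- NULL
  if (!is.null(st) && nrow(st)) {
    for (i in seq_len(nrow(st))) {
      lo <- max(st$onset[i] - 900, 0)
      earlier <- st$offset[st$offset <= st$onset[i]]
      if (length(earlier) && max(earlier) > lo) {
        lo <- max(earlier)
        warning("preictal window of seizure ", i,
                " truncated by a prior seizure")
      }
      pre_windows <- rbind(pre_windows, c(lo, st$onset[i]))
    }
  }
  data <- with_seed(spec$seed, {
    out <- matrix(0, nrow = spec$n_channels, ncol = n)
    for (ch in seq_len(spec$n_channels)) {
      x <- spec$sigma_bg * pink_noise(n, spec$beta)
      if (!is.null(pre_windows)) {
        phase <- runif(1, 0, 2 * pi)
        for (i in seq_len(nrow(pre_windows))) {
          w <- t >= pre_windows[i, 1] & t < pre_windows[i, 2]
          if (!any(w)) next
          tw <- t[w] - pre_windows[i, 1]
          freq <- if (is.null(spec$chirp)) spec$rhythm_hz
          else spec$chirp[1] + (spec$chirp[2] - spec$chirp[1]) * tw /
            max(tw[length(tw)], 1e-9) / 2   # phase of a linear chirp
          x[w] <- x[w] + spec$amplitude_ratio * spec$sigma_bg *
            sin(2 * pi * freq * tw + phase)
        }
      }
      if (!is.null(st) && nrow(st)) {
        phase <- runif(1, 0, 2 * pi)
        for (i in seq_len(nrow(st))) {
          w <- t >= st$onset[i] & t < st$offset[i]
          if (!any(w)) next
          tw <- t[w] - st$onset[i]
          dur <- max(st$offset[i] - st$onset[i], 1e-9)
          # burst sweeping 12 -> 4 Hz across the ictal window
          ph <- 2 * pi * (12 * tw - 4 * tw^2 / dur)
          x[w] <- x[w] + 5 * spec$sigma_bg * sin(ph + phase)
        }
      }
      out[ch, ] <- x
    }
    out
  })
  record <- eeg_record(data, fs = spec$fs,
                       channel_names = sprintf("SYN%d",
                                               seq_len(spec$n_channels)),
                       record_id = spec$record_id,
                       start_offset = spec$start_offset)
  ann <- if (!is.null(st) && nrow(st))
    validate_annotations(data.frame(record_id = spec$record_id,
                                    onset = st$onset, offset = st$offset))
  else validate_annotations(data.frame(record_id = character(),
                                       onset = numeric(),
                                       offset = numeric()))
  list(record = record, annotations = ann)
}

#' Generate an on-disk multi-patient fixture tree
#'
#' Per patient, two EDF records: an interictal-only record at the start of
#' the (virtual) monitoring day and, six hours later, a record holding one
#' seizure preceded by its preictal window. All records are written as EDF
#' and indexed by one annotation CSV and a montage JSON, so the standard
#' readers consume them without special-casing. Per-patient seeds derive
#' from `seed`.
#'
#' @param out_dir writable output directory.
#' @param n_patients number of patients (default 3).
#' @param seed master seed.
#' @param n_channels,fs,beta,sigma_bg,rhythm_hz,amplitude_ratio,chirp
#'   forwarded to [synthetic_spec()].
#' @param interictal_seconds duration of the seizure-free record (360).
#' @param preictal_seconds preictal data before onset in the seizure
#'   record (300; the onset sits that far into the record, so the full
#'   15-min horizon is clipped at the record start).
#' @param ictal_seconds seizure duration (20).
#' @return list with `patients`, per-patient `edf` paths, `annotations`
#'   CSV path and `montage` JSON path.
#' @export
generate_dataset <- function(out_dir, n_patients = 3, seed = 1L,
                             n_channels = 4, fs = 256, beta = 1,
                             sigma_bg = 30, rhythm_hz = 3,
                             amplitude_ratio = 4, chirp = NULL,
                             interictal_seconds = 360,
                             preictal_seconds = 300,
                             ictal_seconds = 20) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  ann_all <- NULL
  edf <- list()
  patients <- sprintf("pat%02d", seq_len(n_patients))
  for (p in seq_len(n_patients)) {
    pdir <- file.path(out_dir, patients[p])
    dir.create(pdir, showWarnings = FALSE)
    base <- seed * 1000L + p * 10L
    # record 1: far (> 4 h) before the seizure, purely interictal
    s1 <- synthetic_spec(n_channels = n_channels, fs = fs,
                         duration = interictal_seconds, beta = beta,
                         sigma_bg = sigma_bg, rhythm_hz = rhythm_hz,
                         amplitude_ratio = amplitude_ratio, chirp = chirp,
                         seed = base + 1L,
                         record_id = paste0(patients[p], "_rec1"),
                         start_offset = 0)
    # record 2: preictal run-up, seizure, short tail
    dur2 <- preictal_seconds + ictal_seconds + 10
    s2 <- synthetic_spec(n_channels = n_channels, fs = fs,
                         duration = dur2,
                         seizure_times = data.frame(
                           onset = preictal_seconds,
                           offset = preictal_seconds + ictal_seconds),
                         beta = beta, sigma_bg = sigma_bg,
                         rhythm_hz = rhythm_hz,
                         amplitude_ratio = amplitude_ratio, chirp = chirp,
                         seed = base + 2L,
                         record_id = paste0(patients[p], "_rec2"),
                         start_offset = 6 * 3600)
    paths <- character()
    for (s in list(s1, s2)) {
      g <- generate_record(s)
      path <- file.path(pdir, paste0(s$record_id, ".edf"))
      write_edf(g$record, path)
      paths <- c(paths, path)
      if (nrow(g$annotations)) ann_all <- rbind(ann_all, g$annotations)
    }
    edf[[patients[p]]] <- paths
  }
  ann_path <- file.path(out_dir, "annotations.csv")
  write_annotations(validate_annotations(ann_all), ann_path)
  mont <- montage_spec("synthetic", sprintf("SYN%d", seq_len(n_channels)))
  mont_path <- file.path(out_dir, "montage.json")
  write_montage(mont, mont_path)
  list(patients = patients, edf = edf, annotations = ann_path,
       montage = mont_path)
}
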