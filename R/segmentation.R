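# Preictal/interictal period labeling and fixed-length segment extraction.
#
# Conventions: seconds from record start, half-open intervals [start, end),
# 0-based sample indexing. The preictal horizon (default 15 min) ends
# exactly at seizure onset; interictal requires a margin (default 4 h)
# from every onset and offset; everything else -- ictal neighbourhoods,
# postictal -- is excluded from classification.

# -- small interval algebra on sorted disjoint [start, end) sets ----------
iv_normalize <- function(iv) {
  iv <- iv[iv[, 2] > iv[, 1], , drop = FALSE]
  if (!nrow(iv)) return(iv)
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv[i, 1] <= out[nrow(out), 2])
      out[nrow(out), 2] <- max(out[nrow(out), 2], iv[i, 2])
    else out <- rbind(out, iv[i, ])
  }
  out
}

iv_complement <- function(iv, lo, hi) {
  iv <- iv_normalize(iv)
  starts <- c(lo, iv[, 2])
  ends <- c(iv[, 1], hi)
  cbind(pmax(starts, lo), pmin(ends, hi))[ends > starts &
                                             pmin(ends, hi) > pmax(starts, lo),
                                           , drop = FALSE]
}

iv_intersect_span <- function(iv, lo, hi) {
  out <- cbind(pmax(iv[, 1], lo), pmin(iv[, 2], hi))
  out[out[, 2] > out[, 1], , drop = FALSE]
}

#' Label preictal/interictal/ictal periods of a record
#'
#' Applies the staging rules to one record: for each seizure with onset
#' \eqn{t_0} and offset \eqn{t_1}, preictal is \eqn{[t_0 - 900, t_0)}
#' (15 min by default) clipped at time zero and truncated at any earlier
#' seizure's offset; ictal is \eqn{[t_0, t_1)}; interictal is every time
#' at least `interictal_margin_hours` before every onset and after every
#' offset; the remainder (including postictal) is `excluded`.
#'
#' Multi-record patients: pass `t0 = ` the record's start on the patient's
#' absolute time axis and `annotations` with absolute onsets/offsets from
#' all records, so the interictal margin spans record boundaries.
#'
#' @param record_duration duration of the record in seconds.
#' @param annotations data.frame with columns `onset`, `offset` (seconds,
#'   absolute when `t0` is used), sorted and non-overlapping.
#' @param preictal_minutes preictal horizon before onset (default 15).
#' @param interictal_margin_hours margin separating interictal data from
#'   any seizure (default 4).
#' @param t0 start of this record on the absolute time axis (default 0).
#' @return data.frame of class `period_interval` with columns `start`,
#'   `end` (seconds from record start) and `label` in
#'   `preictal, interictal, ictal, excluded`; intervals are disjoint.
#' @export
label_periods <- function(record_duration, annotations,
                          preictal_minutes = 15,
                          interictal_margin_hours = 4, t0 = 0) {
  if (!is.numeric(record_duration) || record_duration < 0)
    stop("record_duration must be non-negative")
  lo <- t0
  hi <- t0 + record_duration
  ann <- if (is.null(annotations) || NROW(annotations) == 0)
    data.frame(onset = numeric(), offset = numeric())
  else annotations[order(annotations$onset), , drop = FALSE]
  pre_s <- preictal_minutes * 60
  margin <- interictal_margin_hours * 3600

  ictal <- cbind(ann$onset, ann$offset)
  pre <- matrix(numeric(), ncol = 2)
  for (i in seq_len(nrow(ann))) {
    start <- max(ann$onset[i] - pre_s, 0)
    earlier <- ann$offset[ann$offset <= ann$onset[i]]
    if (length(earlier)) start <- max(start, max(earlier))
    pre <- rbind(pre, c(start, ann$onset[i]))
  }
  guarded <- cbind(ann$onset - margin, ann$offset + margin)
  inter <- iv_complement(guarded, lo, hi)

  pieces <- list(
    preictal = iv_intersect_span(pre, lo, hi),
    ictal = iv_intersect_span(ictal, lo, hi),
    interictal = inter)
  used <- do.call(rbind, pieces)
  excluded <- if (length(used)) iv_complement(used, lo, hi)
  else cbind(lo, hi)[record_duration > 0, , drop = FALSE]
  pieces$excluded <- excluded

  out <- do.call(rbind, lapply(names(pieces), function(lbl) {
    m <- pieces[[lbl]]
    if (!nrow(m)) return(NULL)
    data.frame(start = m[, 1] - t0, end = m[, 2] - t0, label = lbl)
  }))
  if (is.null(out))
    out <- data.frame(start = numeric(), end = numeric(),
                      label = character())
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out$label <- factor(out$label,
                      levels = c("preictal", "interictal", "ictal",
                                 "excluded"))
  class(out) <- c("period_interval", "data.frame")
  out
}

#' Cut fixed-length labeled segments from a record
#'
#' Tiles every preictal/interictal interval from its start with windows of
#' `segment_seconds`, stepping by `segment_seconds - overlap_seconds`;
#' partial trailing windows are discarded. Ictal and excluded intervals
#' yield no segments.
#'
#' @param record an [eeg_record()].
#' @param intervals output of [label_periods()] for this record
#'   (record-relative times).
#' @param segment_seconds window length in seconds (1 or 3 in the standard
#'   configurations; any positive value dividing into whole samples works).
#' @param overlap_seconds overlap between consecutive windows (default 0,
#'   must be < `segment_seconds`).
#' @return list of `labeled_segment` objects, each with fields
#'   `record_id`, `start` (s), `duration` (s), `label`, `data`
#'   (channels x samples).
#' @export
extract_segments <- function(record, intervals, segment_seconds,
                             overlap_seconds = 0) {
  if (segment_seconds <= 0) stop("segment_seconds must be positive")
  if (overlap_seconds < 0 || overlap_seconds >= segment_seconds)
    stop("overlap_seconds must lie in [0, segment_seconds)")
  w_samp <- segment_seconds * record$fs
  if (abs(w_samp - round(w_samp)) > 1e-9)
    stop("segment_seconds * fs must be an integer sample count")
  w_samp <- as.integer(round(w_samp))
  step <- segment_seconds - overlap_seconds

  keep <- intervals[intervals$label %in% c("preictal", "interictal"), ,
                    drop = FALSE]
  segs <- list()
  for (i in seq_len(nrow(keep))) {
    if (keep$end[i] - keep$start[i] < segment_seconds - 1e-9) next
    starts <- seq(keep$start[i], keep$end[i] - segment_seconds + 1e-9,
                  by = step)
    starts <- starts[starts + segment_seconds <= keep$end[i] + 1e-9]
    for (s in starts) {
      i0 <- as.integer(round(s * record$fs))          # 0-based
      if (i0 + w_samp > ncol(record$data)) next
      segs[[length(segs) + 1L]] <- structure(list(
        record_id = record$record_id, start = s,
        duration = segment_seconds,
        label = as.character(keep$label[i]),
        data = record$data[, (i0 + 1L):(i0 + w_samp), drop = FALSE]),
        class = "labeled_segment")
    }
  }
  if (!length(segs))
    warning("no interval long enough for a ", segment_seconds,
            " s segment in record ", record$record_id)
  segs
}

#' Balance preictal/interictal segment counts 1:1
#'
#' Keeps every preictal segment and subsamples the interictal segments
#' uniformly without replacement down to the preictal count. If there are
#' fewer interictal than preictal segments all are kept and the imbalance
#' is reported as a warning (no upsampling). Deterministic given `seed`.
#'
#' @param segments list of `labeled_segment`s containing both classes.
#' @param seed integer seed for the subsampling draw.
#' @return list of `labeled_segment`s (preictal first, then the selected
#'   interictal segments in original order).
#' @export
balance_classes <- function(segments, seed) {
  labels <- vapply(segments, `[[`, "", "label")
  pre <- which(labels == "preictal")
  inter <- which(labels == "interictal")
  if (!length(pre)) stop("no preictal segments to balance")
  if (!length(inter)) stop("no interictal segments to balance")
  if (length(inter) < length(pre)) {
    warning("only ", length(inter), " interictal segments for ",
            length(pre), " preictal; keeping all (imbalanced)")
    sel <- inter
  } else {
    sel <- sort(with_seed(seed, sample(inter, length(pre))))
  }
  segments[c(pre, sel)]
}

# evaluate `expr` under a temporary RNG state seeded by `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Write / read a segment manifest CSV
#'
#' The manifest records provenance only (`record_id,start_s,duration_s,label`),
#' not waveform data.
#' @param segments list of `labeled_segment`s.
#' @param path output CSV path.
#' @export
write_segment_manifest <- function(segments, path) {
  df <- data.frame(
    record_id = vapply(segments, `[[`, "", "record_id"),
    start_s = vapply(segments, `[[`, 0, "start"),
    duration_s = vapply(segments, `[[`, 0, "duration"),
    label = vapply(segments, `[[`, "", "label"))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
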