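#' Seizure annotations
#'
#' Seizure onset/offset times are exchanged as a plain CSV with header
#' `record_id,onset_s,offset_s`, times in seconds from the start of the
#' named record. Annotations are validated (0 <= onset < offset, no
#' overlap within a record) and returned sorted by record then onset.
#'
#' @param path path to the annotation CSV.
#' @return data.frame of class `seizure_annotation` with columns
#'   `record_id`, `onset`, `offset`.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("cannot read annotation file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("record_id", "onset_s", "offset_s")
  if (!all(need %in% names(df)))
    stop("annotation file must have columns record_id,onset_s,offset_s")
  ann <- data.frame(record_id = as.character(df$record_id),
                    onset = as.numeric(df$onset_s),
                    offset = as.numeric(df$offset_s),
                    stringsAsFactors = FALSE)
  validate_annotations(ann, line = seq_len(nrow(ann)) + 1L)
}

#' @rdname read_annotations
#' @param ann annotation data.frame with columns `record_id`, `onset`,
#'   `offset`.
#' @param line optional source line numbers used in error messages.
#' @export
validate_annotations <- function(ann, line = NULL) {
  if (is.null(line)) line <- seq_len(nrow(ann))
  bad <- which(!(ann$onset >= 0 & ann$onset < ann$offset))
  if (length(bad))
    stop("invalid annotation (need 0 <= onset < offset) at line ",
         paste(line[bad], collapse = ", "))
  ord <- order(ann$record_id, ann$onset)
  ann <- ann[ord, , drop = FALSE]
  line <- line[ord]
  for (rid in unique(ann$record_id)) {
    i <- which(ann$record_id == rid)
    if (length(i) > 1L) {
      prev_off <- ann$offset[i][-length(i)]
      nxt_on <- ann$onset[i][-1L]
      ov <- which(nxt_on < prev_off)
      if (length(ov))
        stop("overlapping annotations in record ", rid, " at line ",
             paste(line[i][ov + 1L], collapse = ", "))
    }
  }
  rownames(ann) <- NULL
  class(ann) <- c("seizure_annotation", "data.frame")
  ann
}

#' @rdname read_annotations
#' @export
write_annotations <- function(ann, path) {
  out <- data.frame(record_id = ann$record_id, onset_s = ann$onset,
                    offset_s = ann$offset)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
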