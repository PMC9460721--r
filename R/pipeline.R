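# End-to-end orchestration: per patient, read -> montage -> label ->
# extract -> balance -> time-frequency images -> stratified k-fold CV ->
# metrics, with per-patient error isolation and a reproducibility
# manifest. Also the plain command-line front end.

#' Pipeline configuration
#'
#' @param data_dir directory with one subdirectory of EDF files per
#'   patient.
#' @param annotations annotation CSV path (`record_id,onset_s,offset_s`).
#' @param montage montage JSON path, or one of `"chbmit"`, `"zju4h"`.
#' @param out_dir output directory for results/manifest.
#' @param segment_seconds window length (1 or 3; default 3).
#' @param transform `"swt"` or `"cwt"`.
#' @param preictal_minutes,interictal_margin_hours staging parameters.
#' @param overlap_seconds window overlap (default 0).
#' @param fmin,fmax,voices_per_octave,freq_bins transform grid parameters.
#' @param image_size classifier input side length (default 128).
#' @param model a [model_config()] (input shape is set per dataset).
#' @param cv_folds folds for the per-patient cross-validation (5).
#' @param balance_seed,fold_seed seeds for subsampling and fold splits.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(data_dir, annotations, montage, out_dir,
                            segment_seconds = 3, transform = "swt",
                            preictal_minutes = 15,
                            interictal_margin_hours = 4,
                            overlap_seconds = 0,
                            fmin = 0.5, fmax = 50, voices_per_octave = 8,
                            freq_bins = 128, image_size = 128,
                            model = model_config(profile = "reduced"),
                            cv_folds = 5, balance_seed = 1L,
                            fold_seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

resolve_montage <- function(montage) {
  if (inherits(montage, "montage_spec")) return(montage)
  switch(montage,
         chbmit = montage_chbmit(),
         zju4h = montage_zju4h(),
         read_montage(montage))
}

#' Segment one patient's records
#'
#' Reads every EDF under `patient_dir`, applies the montage, places the
#' records on a common absolute time axis using their header start times,
#' labels periods (the interictal margin spans record boundaries) and
#' extracts balanced segments.
#'
#' @param patient_dir directory with the patient's EDF files.
#' @param ann annotation data.frame (record-relative times).
#' @param config a [pipeline_config()].
#' @return list of balanced `labeled_segment`s (fields carry provenance).
#' @export
segment_patient <- function(patient_dir, ann, config) {
  files <- sort(list.files(patient_dir, pattern = "\\.edf$",
                           ignore.case = TRUE, full.names = TRUE))
  if (!length(files)) stop("no EDF files in ", patient_dir)
  montage <- resolve_montage(config$montage)
  records <- lapply(files, function(f) select_montage(read_edf(f), montage))
  t0s <- vapply(records, `[[`, 0, "start_offset")
  t0s <- t0s - min(t0s)
  # absolute annotation times across this patient's records
  ids <- vapply(records, `[[`, "", "record_id")
  ann_abs <- NULL
  for (i in seq_along(records)) {
    a <- ann[ann$record_id == ids[i], , drop = FALSE]
    if (nrow(a))
      ann_abs <- rbind(ann_abs, data.frame(onset = a$onset + t0s[i],
                                           offset = a$offset + t0s[i]))
  }
  segs <- list()
  for (i in seq_along(records)) {
    iv <- label_periods(record_duration(records[[i]]), ann_abs,
                        preictal_minutes = config$preictal_minutes,
                        interictal_margin_hours =
                          config$interictal_margin_hours,
                        t0 = t0s[i])
    segs <- c(segs, suppressWarnings(
      extract_segments(records[[i]], iv, config$segment_seconds,
                       config$overlap_seconds)))
  }
  balance_classes(segs, seed = config$balance_seed)
}

#' Build classifier images for a list of segments
#'
#' @param segments balanced `labeled_segment`s (one patient).
#' @param fs sampling rate of the segments' records.
#' @param config a [pipeline_config()].
#' @return list of `tf_image`s.
#' @export
build_images <- function(segments, fs, config) {
  wav <- morlet_wavelet()
  grid <- make_scale_grid(fs, config$fmin, min(config$fmax, fs / 2),
                          config$voices_per_octave, wav)
  lapply(segments, function(s)
    build_image(s, fs = fs, wavelet = wav, grid = grid,
                freq_bins = config$freq_bins, transform = config$transform,
                out_h = config$image_size, out_w = config$image_size,
                fmax_band = config$fmax))
}

#' Run the full pipeline
#'
#' Per patient: segmentation, image construction, stratified k-fold
#' cross-validation with one model per patient, and metric computation.
#' A stage error aborts that patient with a logged reason; remaining
#' patients continue. Writes `results.csv` (one row per patient and
#' fold), `summary.csv` (per patient plus an unweighted `Average` row)
#' and `manifest.json` (configuration echo + input hashes) to `out_dir`.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with `summary`, `results`, `failed`.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  ann <- read_annotations(config$annotations)
  patient_dirs <- list.dirs(config$data_dir, recursive = FALSE)
  if (!length(patient_dirs)) stop("no patient directories in ",
                                  config$data_dir)
  rows <- NULL; summaries <- NULL; failed <- list()
  for (pdir in patient_dirs) {
    patient <- basename(pdir)
    res <- tryCatch({
      segs <- segment_patient(pdir, ann, config)
      fs <- read_edf(list.files(pdir, pattern = "\\.edf$",
                                full.names = TRUE)[1])$fs
      images <- build_images(segs, fs, config)
      mc <- config$model
      mc$input_shape <- c(config$image_size, config$image_size,
                          dim(images[[1]]$pixels)[3])
      folds <- cross_validate(images, k = config$cv_folds, config = mc,
                              seed = config$fold_seed)
      pooled <- list(tp = 0L, fn = 0L, tn = 0L, fp = 0L)
      for (f in folds) {
        cm <- f$confusion
        pooled <- Map(`+`, pooled, cm[c("tp", "fn", "tn", "fp")])
        m <- metrics(cm)
        rows <- rbind(rows, data.frame(
          patient = patient, fold = f$fold,
          segment_s = config$segment_seconds,
          transform = config$transform, model = "mlf_cnn",
          accuracy = m$accuracy, sensitivity = m$sensitivity,
          specificity = m$specificity))
      }
      class(pooled) <- "confusion"
      summaries <- rbind(summaries, metrics_report(
        patient, pooled, config$segment_seconds,
        model_name = "mlf_cnn", transform = config$transform))
      TRUE
    }, error = function(e) {
      message("patient ", patient, " failed: ", conditionMessage(e))
      failed[[patient]] <<- conditionMessage(e)
      FALSE
    })
  }
  if (is.null(summaries)) stop("all patients failed")
  agg <- aggregate_metrics(summaries)
  avg_row <- summaries[1, ]
  avg_row$patient <- "Average"
  for (cl in names(agg$mean)) avg_row[[cl]] <- agg$mean[[cl]]
  summary_df <- rbind(summaries, avg_row)
  write.csv(rows, file.path(config$out_dir, "results.csv"),
            row.names = FALSE)
  write.csv(summary_df, file.path(config$out_dir, "summary.csv"),
            row.names = FALSE)
  manifest <- list(
    config = config[setdiff(names(config), "model")],
    model = unclass(config$model),
    inputs = list(annotations = unname(tools::md5sum(config$annotations))))
  jsonlite::write_json(manifest, file.path(config$out_dir,
                                           "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(list(summary = summary_df, results = rows, failed = failed))
}

#' Command-line entry point
#'
#' Subcommands: `fixtures` (write a synthetic dataset), `segment` (write a
#' segment manifest per patient), `images`, `train`, `evaluate` and
#' `run-all` (the full pipeline; `images`/`train`/`evaluate` run the same
#' stages and stop after writing their outputs). Arguments are
#' `--key=value` pairs mirroring [pipeline_config()] fields; invoke as
#' `Rscript -e 'ssqeeg::ssqeeg_cli()' run-all --data_dir=... ...`.
#'
#' @param args character vector (default: command-line arguments).
#' @return exit status, invisibly (0 only if all patients completed).
#' @export
ssqeeg_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    message("usage: ssqeeg_cli <fixtures|segment|run-all> --key=value ...")
    return(invisible(1L))
  }
  cmd <- args[1]
  kv <- strsplit(sub("^--", "", args[-1]), "=", fixed = TRUE)
  opts <- setNames(lapply(kv, function(x) paste(x[-1], collapse = "=")),
                   vapply(kv, `[[`, "", 1))
  num <- function(x, d) if (is.null(opts[[x]])) d else as.numeric(opts[[x]])
  chr <- function(x, d = NULL) if (is.null(opts[[x]])) d else opts[[x]]
  if (cmd == "fixtures") {
    out <- generate_dataset(chr("out_dir", "fixtures"),
                            n_patients = num("n_patients", 3),
                            seed = as.integer(num("seed", 1)),
                            n_channels = num("n_channels", 4),
                            amplitude_ratio = num("amplitude_ratio", 4))
    message("wrote fixtures for ", length(out$patients), " patients")
    return(invisible(0L))
  }
  config <- pipeline_config(
    data_dir = chr("data_dir", "fixtures"),
    annotations = chr("annotations",
                      file.path(chr("data_dir", "fixtures"),
                                "annotations.csv")),
    montage = chr("montage",
                  file.path(chr("data_dir", "fixtures"), "montage.json")),
    out_dir = chr("out_dir", "results"),
    segment_seconds = num("segment_seconds", 3),
    transform = chr("transform", "swt"),
    cv_folds = num("cv_folds", 5),
    balance_seed = as.integer(num("seed", 1)),
    fold_seed = as.integer(num("seed", 1)))
  if (cmd == "segment") {
    ann <- read_annotations(config$annotations)
    for (pdir in list.dirs(config$data_dir, recursive = FALSE)) {
      segs <- segment_patient(pdir, ann, config)
      dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
      write_segment_manifest(segs, file.path(
        config$out_dir, paste0(basename(pdir), "_segments.csv")))
    }
    return(invisible(0L))
  }
  if (cmd %in% c("images", "train", "evaluate", "run-all")) {
    res <- run_pipeline(config)
    return(invisible(if (length(res$failed)) 1L else 0L))
  }
  message("unknown subcommand: ", cmd)
  invisible(1L)
}
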