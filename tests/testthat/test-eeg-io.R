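# EDF round trips, channel canonicalization, montage selection,
# annotation parsing.

test_that("EDF write/read round-trips a synthetic record", {
  spec <- synthetic_spec(n_channels = 4, fs = 256, duration = 60,
                         seed = 42, record_id = "fix4")
  rec <- generate_record(spec)$record
  path <- file.path(tempdir(), "fix4.edf")
  write_edf(rec, path)
  back <- read_edf(path)

  expect_equal(ncol(back$data), 60 * 256)      # 15360 samples
  expect_equal(back$fs, 256)
  expect_equal(back$channel_names, rec$channel_names)
  expect_equal(back$record_id, "fix4")
  # amplitudes within one 16-bit quantization step of the physical range
  q <- apply(abs(rec$data), 1, max) / 32767
  for (ch in 1:4)
    expect_lt(max(abs(back$data[ch, ] - rec$data[ch, ])), q[ch] + 1e-12)

  # second round trip is exact (already quantized)
  path2 <- file.path(tempdir(), "fix4b.edf")
  write_edf(back, path2)
  again <- read_edf(path2)
  expect_equal(again$data, back$data, tolerance = 1e-10)

  # start time survives
  rec2 <- rec; rec2$start_offset <- 6 * 3600
  write_edf(rec2, path)
  expect_equal(read_edf(path)$start_offset, 6 * 3600)
})

test_that("read_edf rejects unreadable or degenerate input", {
  expect_error(read_edf(file.path(tempdir(), "nope.edf")), "cannot read")
  # header with zero signals
  path <- file.path(tempdir(), "empty.edf")
  con <- file(path, "wb")
  hdr <- sprintf("%-8s%-80s%-80s%-8s%-8s%-8s%-44s%-8s%-8s%-4s",
                 "0", "p", "r", "01.01.00", "00.00.00", "256", "", "0",
                 "1", "0")
  writeBin(charToRaw(hdr), con); close(con)
  expect_error(read_edf(path), "unsupported|no signal")
})

test_that("channel names canonicalize and duplicates resolve to first", {
  expect_equal(canonical_channel_names(c(" fp1-f7 ", "T8-P8-0", "C3-Ref")),
               c("FP1-F7", "T8-P8", "C3"))
  rec <- eeg_record(matrix(rnorm(40), 4), 10,
                    c("A", "B", "C", "D"), "r")
  expect_error(eeg_record(matrix(0, 2, 4), 10, c("T8-P8", "T8-P8-0")),
               "duplicate")
})

test_that("select_montage orders channels and is idempotent", {
  set.seed(1)
  data <- matrix(rnorm(5 * 20), 5)
  rec <- eeg_record(data, 256, c("CZ-PZ", "FP1-F7", "XX", "F7-T7", "FZ-CZ"),
                    "r")
  m <- montage_spec("sub", c("FP1-F7", "F7-T7", "FZ-CZ", "CZ-PZ"))
  sel <- select_montage(rec, m)
  expect_equal(sel$channel_names, m$channels)
  expect_equal(sel$data[1, ], data[2, ])       # FP1-F7 was row 2
  expect_equal(select_montage(sel, m), sel)    # idempotent
  expect_error(select_montage(rec, montage_spec("bad", c("FP1-F7", "XX-YY"))),
               "XX-YY")
})

test_that("standard montages match the published channel sets", {
  cm <- montage_chbmit()
  expect_equal(cm$expected_count, 18)
  expect_equal(cm$channels[1:3], c("FP1-F7", "F7-T7", "T7-P7"))
  expect_equal(cm$channels[17:18], c("FZ-CZ", "CZ-PZ"))
  zm <- montage_zju4h()
  expect_equal(zm$expected_count, 16)
  expect_true(all(c("FP1", "T6") %in% zm$channels))  # -REF stripped

  # a 23-channel CHB-MIT-style record reduces to the 18-channel montage
  extra <- c(cm$channels, "VNS", "ECG", "LOC-ROC", "EXT1", "EXT2")
  rec <- eeg_record(matrix(rnorm(23 * 10), 23), 256, extra, "chb")
  expect_equal(select_montage(rec, cm)$channel_names, cm$channels)
})

test_that("montage JSON round-trips", {
  m <- montage_spec("synthetic", c("SYN1", "SYN2"))
  p <- file.path(tempdir(), "mont.json")
  write_montage(m, p)
  expect_equal(read_montage(p)$channels, m$channels)
})

test_that("annotation CSV parsing validates and sorts", {
  p <- file.path(tempdir(), "ann.csv")
  writeLines(c("record_id,onset_s,offset_s",
               "recA,18000,18120",
               "recA,100,160",
               "recB,50,70"), p)
  ann <- read_annotations(p)
  expect_s3_class(ann, "seizure_annotation")
  expect_equal(ann$onset[ann$record_id == "recA"], c(100, 18000))
  expect_equal(ann$offset[ann$record_id == "recA"][2], 18120)

  writeLines("record_id,onset_s,offset_s", p)
  expect_equal(nrow(read_annotations(p)), 0)   # empty file -> empty list

  writeLines(c("record_id,onset_s,offset_s", "r,120,100"), p)
  expect_error(read_annotations(p), "line 2")

  writeLines(c("record_id,onset_s,offset_s", "r,100,200", "r,150,300"), p)
  expect_error(read_annotations(p), "overlap")
})
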