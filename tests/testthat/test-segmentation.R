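# Period labeling, segment extraction, class balancing.

ann_df <- function(onset, offset) data.frame(onset = onset, offset = offset)

test_that("single seizure in a 10 h record labels all four period types", {
  iv <- label_periods(36000, ann_df(18000, 18120))
  get <- function(lbl) iv[iv$label == lbl, c("start", "end")]
  expect_equal(unlist(get("preictal"), use.names = FALSE), c(17100, 18000))
  expect_equal(unlist(get("ictal"), use.names = FALSE), c(18000, 18120))
  inter <- get("interictal")
  expect_equal(inter$start, c(0, 32520))       # onset-4h / offset+4h
  expect_equal(inter$end, c(3600, 36000))
  # disjoint cover of the record
  expect_equal(sum(iv$end - iv$start), 36000)
  o <- order(iv$start)
  expect_true(all(iv$start[o][-1] >= iv$end[o][-nrow(iv)]))
})

test_that("preictal clips at record start and truncates at prior offsets", {
  iv <- label_periods(7200, ann_df(600, 660))
  pre <- iv[iv$label == "preictal", ]
  expect_equal(c(pre$start, pre$end), c(0, 600))

  # second onset 500 s after the first: preictal truncated at the first
  # seizure's offset (enumerated from the stated truncation rule)
  iv2 <- label_periods(40000, ann_df(c(18000, 18500), c(18060, 18560)))
  pre2 <- iv2[iv2$label == "preictal", ]
  expect_equal(pre2$start, c(17100, 18060))
  expect_equal(pre2$end, c(18000, 18500))
  expect_equal(pre2$end[2] - pre2$start[2], 500 - 60)
  # brute-force disjointness at 1 s resolution
  grid <- seq(0.5, 39999.5, by = 7)
  hits <- sapply(grid, function(t) sum(t >= iv2$start & t < iv2$end))
  expect_true(all(hits == 1))
})

test_that("interictal margin spans record boundaries via t0", {
  # record at t0 = 6 h, seizure at 300 s into it; an earlier record
  # [0, 360) is fully interictal, the later one has none
  ann <- ann_df(6 * 3600 + 300, 6 * 3600 + 320)
  iv1 <- label_periods(360, ann, t0 = 0)
  expect_equal(as.character(unique(iv1$label)), "interictal")
  iv2 <- label_periods(330, ann, t0 = 6 * 3600)
  expect_false("interictal" %in% iv2$label)
  expect_equal(unlist(iv2[iv2$label == "preictal", c("start", "end")],
                      use.names = FALSE), c(0, 300))
})

test_that("no annotations means all interictal; negative duration errors", {
  iv <- label_periods(100, NULL)
  expect_equal(as.character(iv$label), "interictal")
  expect_error(label_periods(-5, NULL), "non-negative")
})

test_that("segment counts follow floor(L/w) and skip non-usable periods", {
  rec <- eeg_record(matrix(seq_len(2 * 920 * 8), nrow = 2), 8,
                    c("A", "B"), "r")
  iv <- data.frame(start = c(0, 900), end = c(900, 910),
                   label = c("preictal", "ictal"))
  segs <- extract_segments(rec, iv, 3)
  expect_length(segs, 300)
  expect_length(extract_segments(rec, iv, 1), 900)
  expect_true(all(vapply(segs, function(s) ncol(s$data), 0) == 24))
  # 10 s interval, 3 s windows -> 3 segments, trailing 1 s discarded
  iv10 <- data.frame(start = 0, end = 10, label = "interictal")
  expect_length(extract_segments(rec, iv10, 3), 3)
  # sample alignment: segment at start s covers samples [s*fs, s*fs + w*fs)
  s2 <- extract_segments(rec, iv10, 3)[[2]]
  expect_equal(s2$data[1, 1], rec$data[1, 3 * 8 + 1])
  # overlap
  expect_length(extract_segments(rec, iv10, 3, overlap_seconds = 2), 8)
  expect_error(extract_segments(rec, iv10, 3, overlap_seconds = 3),
               "overlap")
  # window longer than every interval -> empty with warning
  expect_warning(out <- extract_segments(rec, iv10, 60), "no interval")
  expect_length(out, 0)
})

test_that("balancing keeps all preictal and subsamples interictal 1:1", {
  d <- matrix(0, 1, 8)
  segs <- c(lapply(1:30, function(i) make_segment(d, "preictal", start = i)),
            lapply(1:200, function(i) make_segment(d, "interictal",
                                                   start = 1000 + i)))
  bal <- balance_classes(segs, seed = 9)
  lab <- vapply(bal, `[[`, "", "label")
  expect_equal(sum(lab == "preictal"), 30)
  expect_equal(sum(lab == "interictal"), 30)
  # deterministic given seed, different for another seed
  bal2 <- balance_classes(segs, seed = 9)
  expect_identical(vapply(bal2, `[[`, 0, "start"),
                   vapply(bal, `[[`, 0, "start"))
  bal3 <- balance_classes(segs, seed = 10)
  expect_false(identical(vapply(bal3, `[[`, 0, "start"),
                         vapply(bal, `[[`, 0, "start")))
  # cannot upsample: all interictal kept with a warning
  few <- c(segs[1:30], segs[31:50])
  expect_warning(bal4 <- balance_classes(few, seed = 1), "imbalanced")
  expect_length(bal4, 50)
  expect_error(balance_classes(segs[1:30], 1), "interictal")
})

test_that("preictal bookkeeping: 7 untruncated seizures give 105 min", {
  onsets <- (1:7) * 3 * 3600
  iv <- label_periods(24 * 3600, ann_df(onsets, onsets + 60))
  pre <- iv[iv$label == "preictal", ]
  expect_equal(sum(pre$end - pre$start) / 60, 7 * 15)   # 105 min
})
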