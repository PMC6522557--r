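test_that("call tables parse, reject bad rows individually, and handle empty files", {
  calls <- make_calls(make_call(caller = "defuse"),
                      make_call(caller = "tophatfusion"),
                      make_call(caller = "starfusion", gene5 = "C", gene3 = "D"))
  got <- read_fusion_calls(write_calls(calls))
  expect_equal(nrow(got), 3)
  expect_equal(nrow(attr(got, "rejected")), 0)

  bad <- calls
  bad$strand5[2] <- "."
  got <- read_fusion_calls(write_calls(bad))
  expect_equal(nrow(got), 2)
  expect_equal(attr(got, "rejected")$line, 2)
  expect_match(attr(got, "rejected")$reason, "strand")

  empty <- read_fusion_calls(write_calls(calls[0, ]))
  expect_equal(nrow(empty), 0)

  expect_error(read_fusion_calls(write_calls(calls[, -2])), "missing required")
  expect_error(read_fusion_calls(tempfile()), "not found")
})

test_that("schema mapping renames columns before validation", {
  calls <- make_call()
  names(calls)[1] <- "Sample"
  got <- read_fusion_calls(write_calls(calls), schema = c(sample_id = "Sample"))
  expect_equal(got$sample_id, "S1")
})

test_that("calls merge into transcripts by breakpoint tolerance", {
  two <- make_calls(
    make_call(caller = "defuse", breakpoint5 = 1000, junction_reads = 5),
    make_call(caller = "tophatfusion", breakpoint5 = 1003, junction_reads = 9))
  m <- merge_calls(two, breakpoint_tolerance_bp = 5)
  expect_equal(nrow(m), 1)
  expect_equal(m$n_callers, 2)
  expect_equal(m$max_junction_reads, 9)
  # representative breakpoint from the best-supported call
  expect_equal(m$breakpoint5, 1003)

  apart <- make_calls(
    make_call(caller = "defuse", breakpoint5 = 1000),
    make_call(caller = "tophatfusion", breakpoint5 = 1050))
  expect_equal(nrow(merge_calls(apart, 5)), 2)

  single <- merge_calls(make_call(), 5)
  expect_equal(single$n_callers, 1)
  expect_equal(nrow(merge_calls(make_call()[0, ], 5)), 0)
})

test_that("consensus frame prefers in-frame evidence", {
  m <- merge_calls(make_calls(
    make_call(caller = "defuse", frame = "unknown"),
    make_call(caller = "starfusion", frame = "in_frame")), 5)
  expect_equal(m$frame, "in_frame")
})

test_that("filtering applies read, caller and blacklist criteria with reasons", {
  tx <- merge_calls(make_calls(
    make_call(caller = "defuse", junction_reads = 5),
    make_call(caller = "starfusion", junction_reads = 2),
    make_call(caller = "defuse", gene5 = "C", gene3 = "D", junction_reads = 10),
    make_call(caller = "defuse", gene5 = "E", gene3 = "F", junction_reads = 3),
    make_call(caller = "starfusion", gene5 = "E", gene3 = "F",
              junction_reads = 3),
    make_call(caller = "defuse", gene5 = "X", gene3 = "Y", junction_reads = 8),
    make_call(caller = "starfusion", gene5 = "X", gene3 = "Y",
              junction_reads = 8)), 5)
  bl <- data.frame(gene5 = "X", gene3 = "Y")
  kept <- filter_transcripts(tx, blacklist = bl)
  expect_equal(sort(paste0(kept$gene5, kept$gene3)), "AB")
  removed <- attr(kept, "removed")
  expect_setequal(removed$reason[removed$gene5 == "C"], "below caller threshold")
  expect_setequal(removed$reason[removed$gene5 == "E"],
                  "below junction-read threshold")
  expect_setequal(removed$reason[removed$gene5 == "X"],
                  "normal-tissue blacklist")
})

test_that("filtering is monotone in both thresholds and matches a row-wise rescan", {
  set.seed(42)
  calls <- do.call(rbind, lapply(1:120, function(i) {
    make_call(sample_id = sample(c("S1", "S2"), 1),
              caller = sample(c("a", "b", "c"), 1),
              gene5 = sample(LETTERS[1:6], 1), gene3 = sample(letters[1:6], 1),
              breakpoint5 = sample(c(1000, 2000), 1),
              breakpoint3 = sample(c(5000, 6000), 1),
              junction_reads = sample(1:10, 1))
  }))
  tx <- merge_calls(calls, 5)
  prev <- NULL
  for (mr in 1:6) {
    kept <- filter_transcripts(tx, min_junction_reads = mr, min_callers = 2)
    brute <- tx[tx$max_junction_reads >= mr & tx$n_callers >= 2, ]
    expect_equal(nrow(kept), nrow(brute))
    if (!is.null(prev)) expect_lte(nrow(kept), prev)
    prev <- nrow(kept)
  }
  k1 <- filter_transcripts(tx, min_callers = 1)
  k2 <- filter_transcripts(tx, min_callers = 2)
  k3 <- filter_transcripts(tx, min_callers = 3)
  expect_true(nrow(k1) >= nrow(k2) && nrow(k2) >= nrow(k3))
})

test_that("source deduplication keeps the highest-precedence source per line", {
  ann <- data.frame(sample_id = c("L1_s", "L1_a", "L2_s"),
                    cell_line = c("L1", "L1", "L2"),
                    source = c("sanger", "archive", "sanger"))
  tx <- merge_calls(make_calls(
    make_call(sample_id = "L1_s"),
    make_call(sample_id = "L1_a", gene5 = "C", gene3 = "D"),
    make_call(sample_id = "L2_s", gene5 = "E", gene3 = "F")), 5)
  out <- deduplicate_samples(tx, ann, c("sanger", "archive"))
  expect_setequal(out$sample_id, c("L1_s", "L2_s"))
  expect_error(deduplicate_samples(tx, ann, character(0)), "non-empty")
  expect_error(deduplicate_samples(tx, ann[-1, ], c("sanger", "archive")),
               "without source annotation")
})

test_that("events collapse transcripts per (cell line, ordered gene pair)", {
  tx <- merge_calls(make_calls(
    make_call(breakpoint5 = 1000),
    make_call(breakpoint5 = 9000, frame = "out_of_frame"),
    make_call(sample_id = "S2")), 5)
  ev <- aggregate_events(tx)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$transcript_count[ev$cell_line == "S1"], 2)
  expect_true(all(ev$any_in_frame))
  expect_equal(nrow(aggregate_events(tx[0, ])), 0)
  # idempotent under re-application of filter + aggregation
  ev2 <- aggregate_events(filter_transcripts(tx, min_callers = 1))
  expect_identical(ev, ev2)
})

test_that("catalog summary counts unique and recurrent fusions", {
  ev <- make_events(c("A--B", "A--B", "C--D"), c("L1", "L2", "L1"))
  ann <- data.frame(cell_line = c("L1", "L2", "L3"),
                    cancer_type = c("t1", "t1", "t2"))
  s <- summarize_catalog(ev, ann)
  expect_equal(s$n_events, 3)
  expect_equal(s$n_unique_fusions, 2)
  expect_equal(s$n_recurrent_fusions, 1)
  expect_equal(s$recurrent_percent, 50)
  # annotated line with no events contributes a zero to its type median
  expect_equal(unname(s$events_per_type_median[["t2"]]), 0)
  expect_true(s$n_recurrent_fusions <= s$n_unique_fusions)
  expect_true(s$n_unique_fusions <= s$n_events)
  expect_error(summarize_catalog(ev, ann[1, ]), "without cancer-type")
  expect_output(print(s), "unique fusions")
})

test_that("percentage rounding is nearest-integer, half away from zero", {
  expect_equal(pct_round(1, 8), 13)     # 12.5 -> 13
  expect_equal(pct_round(1, 40), 3)     # 2.5 -> 3
  expect_equal(pct_round(0, 10), 0)
  expect_error(pct_round(1, 0))
})
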