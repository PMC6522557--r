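test_that("scale-to-essentials anchors medians at 0 and -1", {
  guides <- c(e1 = "ge", e2 = "ge", n1 = "gn", n2 = "gn", x1 = "gx")
  fc <- matrix(c(-2, -2, 0, 0, -1,
                 -4, -4, 2, 2, 0), 5, 2,
               dimnames = list(names(guides), c("L1", "L2")))
  sc <- scale_to_essentials(fc, guides, "ge", "gn")
  expect_equal(unname(sc[, "L1"]), c(-1, -1, 0, 0, -0.5))
  expect_equal(unname(sc["x1", "L2"]), (0 - 2) / (2 - -4))
  anchors <- attr(sc, "anchors")
  expect_equal(anchors$median_essential, c(-2, -4))

  # idempotent once anchored at 0 / -1
  sc2 <- scale_to_essentials(sc, guides, "ge", "gn")
  expect_equal(unclass(sc2)[, ], unclass(sc)[, ], tolerance = 1e-12,
               ignore_attr = TRUE)

  inverted <- fc
  inverted[1:2, ] <- 5                   # essentials above non-essentials
  expect_error(scale_to_essentials(inverted, guides, "ge", "gn"),
               "median")
})

test_that("guide mapping follows the strand and breakpoint-side rules", {
  guides <- data.frame(
    guide = paste0("sg", 1:6),
    gene = c("A", "A", "A", "B", "B", "B"),
    chrom = c(rep("chr1", 3), rep("chr2", 3)),
    cut_position = c(1000, 2000, 2500, 1000, 2000, 2500),
    gene_strand = "+", stringsAsFactors = FALSE)
  tr <- data.frame(gene5 = "A", gene3 = "B", chrom5 = "chr1", chrom3 = "chr2",
                   breakpoint5 = 2000, breakpoint3 = 2000,
                   strand5 = "+", strand3 = "+", stringsAsFactors = FALSE)
  p <- map_guides_to_transcript(guides, tr)
  expect_setequal(p$mapping5, c("sg1", "sg2"))   # before bp, tie included
  expect_setequal(p$nonmapping5, "sg3")
  expect_setequal(p$mapping3, c("sg5", "sg6"))   # at/after bp on +
  expect_setequal(p$nonmapping3, "sg4")

  # minus-strand 5' gene: mapping side flips
  tr$strand5 <- "-"
  p2 <- map_guides_to_transcript(guides, tr)
  expect_setequal(p2$mapping5, c("sg2", "sg3"))

  # chromosome mismatch excludes the guide with a warning
  guides$chrom[1] <- "chr9"
  expect_warning(p3 <- map_guides_to_transcript(guides, tr),
                 "wrong chromosome")
  expect_equal(p3$excluded, "sg1")
})

test_that("guide mapping equals a brute-force rule-by-rule rederivation", {
  set.seed(51)
  for (rep in 1:1000) {
    bp5 <- sample(100:200, 1); bp3 <- sample(100:200, 1)
    s5 <- sample(c("+", "-"), 1); s3 <- sample(c("+", "-"), 1)
    guides <- data.frame(
      guide = paste0("sg", 1:8),
      gene = rep(c("A", "B"), each = 4), chrom = "chr1",
      cut_position = sample(90:210, 8, replace = TRUE),
      gene_strand = rep(c(s5, s3), each = 4), stringsAsFactors = FALSE)
    tr <- data.frame(gene5 = "A", gene3 = "B", chrom5 = "chr1",
                     chrom3 = "chr1", breakpoint5 = bp5, breakpoint3 = bp3,
                     strand5 = s5, strand3 = s3, stringsAsFactors = FALSE)
    p <- map_guides_to_transcript(guides, tr)
    for (i in 1:8) {
      g <- guides[i, ]
      expected <- if (g$gene == "A") {
        if (s5 == "+") g$cut_position <= bp5 else g$cut_position >= bp5
      } else {
        if (s3 == "+") g$cut_position >= bp3 else g$cut_position <= bp3
      }
      in_map <- g$guide %in% c(p$mapping5, p$mapping3)
      expect_identical(in_map, expected)
    }
  }
})

test_that("per-guide Z-normalization handles standard and degenerate rows", {
  m <- rbind(a = c(-1, 0, 1), b = c(2, 2, 2), c = c(0, 5, 10))
  z <- zscore_per_guide(m)
  expect_equal(unname(z["a", ]), c(-1, 0, 1))
  expect_equal(unname(z["b", ]), c(0, 0, 0))
  expect_equal(unname(z["c", ]), c(-1, 0, 1))
  one_col <- matrix(c(1, 2), 2, 1, dimnames = list(c("a", "b"), "L1"))
  expect_true(all(zscore_per_guide(one_col) == 0))
})

test_that("the FES averages per-gene mapping/non-mapping Z differences", {
  set.seed(52)
  sc <- matrix(rnorm(8 * 6), 8, 6,
               dimnames = list(paste0("sg", 1:8), paste0("L", 1:6)))
  part <- list(mapping5 = c("sg1", "sg2"), nonmapping5 = c("sg3", "sg4"),
               mapping3 = c("sg5"), nonmapping3 = character(0))
  got <- fes_score(part, sc, "L2")
  z <- zscore_per_guide(sc)
  want_fes <- mean(c(mean(z[part$mapping5, "L2"]) - mean(z[part$nonmapping5, "L2"]),
                     mean(z[part$mapping3, "L2"]) - 0))
  want_raw <- mean(sc[c("sg1", "sg2", "sg5"), "L2"]) -
    mean(sc[c("sg3", "sg4"), "L2"])
  expect_equal(got[["fes"]], want_fes)
  expect_equal(got[["raw_diff"]], want_raw)

  # constant rows give all-zero Z -> FES 0
  flat <- matrix(5, 8, 3, dimnames = list(paste0("sg", 1:8), paste0("L", 1:3)))
  expect_equal(fes_score(part, flat, "L1")[["fes"]], 0)

  # only the 3' gene has mapping guides and no non-mapping guide
  p3 <- list(mapping5 = character(0), nonmapping5 = character(0),
             mapping3 = c("sg5", "sg6"), nonmapping3 = character(0))
  got3 <- fes_score(p3, sc, "L3")
  expect_equal(got3[["fes"]], mean(z[c("sg5", "sg6"), "L3"]))

  # no mapping guides at all -> untestable
  none <- list(mapping5 = character(0), nonmapping5 = "sg1",
               mapping3 = character(0), nonmapping3 = "sg5")
  expect_true(is.na(fes_score(none, sc, "L1")[["fes"]]))
})

test_that("FES is invariant to guide relabeling and cell-line order", {
  set.seed(53)
  scr <- make_screen(8, 4)
  tr <- make_screen_transcripts(scr, "g001--g002", "L03")
  part <- map_guides_to_transcript(scr$guides, tr[1, ])
  a <- fes_score(part, scr$fold_changes, "L03")
  shuffled <- scr$fold_changes[sample(nrow(scr$fold_changes)),
                               sample(ncol(scr$fold_changes))]
  b <- fes_score(part, shuffled, "L03")
  expect_equal(a, b)
})

test_that("FES significance is reproducible, plus-one bounded and filtered on raw_diff", {
  set.seed(54)
  scr <- make_screen(12, 6)
  tr <- make_screen_transcripts(scr, c("g001--g002", "g003--g004"),
                                c("L01", "L02"))
  scr$fold_changes[, "L01"][
    c(map_guides_to_transcript(scr$guides, tr[1, ])$mapping5,
      map_guides_to_transcript(scr$guides, tr[1, ])$mapping3)] <- -2
  r1 <- fes_significance(tr, scr$guides, scr$fold_changes, n_perm = 100,
                         seed = 9)
  r2 <- fes_significance(tr, scr$guides, scr$fold_changes, n_perm = 100,
                         seed = 9)
  expect_identical(r1, r2)
  expect_true(all(r1$p_value > 0 & r1$p_value <= 1))
  expect_gte(min(r1$p_value), 1 / 101)
  expect_true(r1$passes_min_diff[1])
  expect_output(print(r1), "FES results")

  # a strong hit that fails the -0.45 raw-difference rule is not significant
  weak <- r1
  weak$raw_diff[1] <- -0.3
  weak$passes_min_diff[1] <- weak$raw_diff[1] <= -0.45
  expect_false(weak$passes_min_diff[1])
  expect_true(r1$raw_diff[1] <= -0.45 && r1$passes_min_diff[1])
})

test_that("event-level aggregation uses the any-transcript, any-dataset rule", {
  base <- data.frame(transcript = c("t1", "t1", "t2"),
                     gene5 = "A", gene3 = "B",
                     cell_line = c("L1", "L2", "L3"), dataset = "d1",
                     significant = c(TRUE, TRUE, FALSE),
                     stringsAsFactors = FALSE)
  ev <- aggregate_events_fes(base)
  expect_equal(sum(ev$significant), 2)   # one transcript, two screened lines
  other <- transform(base[3, ], dataset = "d2", significant = TRUE)
  ev2 <- aggregate_events_fes(list(base, other))
  expect_true(ev2$significant[ev2$cell_line == "L3"])
  none <- transform(base, significant = FALSE)
  expect_equal(sum(aggregate_events_fes(none)$significant), 0)
})
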