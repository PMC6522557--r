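test_that("Glass Deltas match the closed form and flag degenerate groups", {
  gd <- glass_deltas(c(-1, 1), c(3, 5))
  expect_equal(unname(gd), rep(4 / sqrt(2), 2))
  expect_equal(unname(glass_deltas(c(1, 2, 3), c(2, 1, 3))), c(0, 0))
  gd2 <- glass_deltas(c(2, 2), c(0, 1))
  expect_true(is.na(gd2[["delta_pos"]]))
  expect_false(is.na(gd2[["delta_neg"]]))
  expect_true(is.na(glass_deltas(5, c(0, 1))[["delta_pos"]]))  # group of 1
  expect_error(glass_deltas(numeric(0), 1), "non-empty")
})

test_that("Glass Deltas shift-invariant and inversely scale-covariant", {
  set.seed(41)
  pos <- rnorm(6); neg <- rnorm(9, 2)
  base <- glass_deltas(pos, neg)
  expect_equal(glass_deltas(pos + 7, neg + 7), base)
  expect_equal(glass_deltas(3 * pos, 3 * neg), base)   # |.|/sd both scale by 3
  expect_equal(glass_deltas(pos * 2, neg * 2), base)
})

test_that("feature-drug ANOVA handles degenerate fixtures", {
  y <- setNames(c(0, 0, 0, 2, 2, 2, 2), paste0("L", 1:7))
  f <- setNames(c(rep(TRUE, 3), rep(FALSE, 4)), names(y))
  r <- fit_feature_drug_anova(f, y)
  expect_equal(r$effect_size, -2)
  expect_true(is.na(r$glass_delta_pos) && is.na(r$glass_delta_neg))

  const <- setNames(rep(FALSE, 7), names(y))
  expect_false(fit_feature_drug_anova(const, y)$testable)
  small <- setNames(c(TRUE, rep(FALSE, 6)), names(y))
  expect_match(fit_feature_drug_anova(small, y)$reason, "group size")
})

test_that("feature p-value equals the nested F oracle with a tissue covariate", {
  set.seed(42)
  for (i in 1:30) {
    n <- 60
    lines <- paste0("L", 1:n)
    tissue <- factor(sample(c("lung", "colon", "breast"), n, replace = TRUE))
    f <- setNames(sample(c(TRUE, FALSE), n, replace = TRUE), lines)
    if (sum(f) < 2 || sum(!f) < 2) next
    y <- setNames(rnorm(n) + as.numeric(tissue) - 0.8 * f, lines)
    cov <- data.frame(tissue = tissue, row.names = lines)
    r <- fit_feature_drug_anova(f, y, cov)
    expect_equal(r$p_value, nested_f_pvalue(y, unname(f), data.frame(tissue)),
                 tolerance = 1e-10)
  }
})

test_that("collinear fusion features are reported as not testable", {
  n <- 12
  lines <- paste0("L", 1:n)
  f <- setNames(rep(c(TRUE, FALSE), c(3, 9)), lines)
  cov <- data.frame(cfe_X = unname(f), row.names = lines)
  y <- setNames(rnorm(n), lines)
  r <- fit_feature_drug_anova(f, y, cov)
  expect_false(r$testable)
  expect_match(r$reason, "collinear")
})

test_that("stage-1 covariate selection enforces all three cutoffs", {
  s1 <- data.frame(
    feature = c("A", "B", "C"), drug = "D1",
    p_value = c(1e-5, 1e-5, 0.5), fdr = c(0.1, 0.1, 0.9),
    glass_delta_pos = c(1.5, 0.8, 2), glass_delta_neg = c(2, 2, 2),
    testable = TRUE)
  sel <- select_cfe_covariates(s1)
  expect_equal(sel, list(D1 = "A"))
  expect_equal(length(select_cfe_covariates(s1[0, ])), 0)
})

test_that("stage-2 p-values are uniform under a null with tissue effects", {
  set.seed(43)
  n <- 50
  lines <- paste0("L", 1:n)
  tissue <- rep(c("a", "b"), each = n / 2)
  ann <- data.frame(cell_line = lines, tissue = tissue, msi_status = "MSS")
  feats <- matrix(0L, 40, n, dimnames = list(paste0("F", 1:40), lines))
  for (i in 1:40) feats[i, sample(n, sample(3:8, 1))] <- 1L
  drug <- do.call(rbind, lapply(c("D1", "D2", "D3"), function(d) {
    data.frame(drug = d, cell_line = lines,
               ic50 = rnorm(n) + ifelse(tissue == "a", 1, -1))
  }))
  res <- run_fusion_drug_screen(feats, drug, ann)
  p <- res$p_value[res$testable]
  ks <- ks.test(p, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("a confounding CFE covariate explains away a spurious fusion hit", {
  set.seed(44)
  n <- 40
  lines <- paste0("L", 1:n)
  ann <- data.frame(cell_line = lines, tissue = "pan", msi_status = "MSS")
  cfe <- matrix(0L, 1, n, dimnames = list("BRAFmut", lines))
  cfe[1, 1:4] <- 1L
  # the confounded fusion's carriers coincide with the CFE; nine unrelated
  # fusions keep the stage-2 BH correction honest
  fus <- matrix(0L, 10, n,
                dimnames = list(c("NKD1--ADCY7", paste0("null", 1:9)), lines))
  fus[1, 1:2] <- 1L
  for (i in 2:10) fus[i, sample(n, 4)] <- 1L
  drug <- do.call(rbind, lapply(c("dab", "noiseA", "noiseB"), function(d) {
    y <- rnorm(n, 0, 0.3)
    if (d == "dab") y <- y - 4 * cfe[1, ]   # the CFE carries the real effect
    data.frame(drug = d, cell_line = lines, ic50 = y)
  }))

  naive <- run_fusion_drug_screen(fus, drug, ann)
  expect_true(naive$significant[naive$feature == "NKD1--ADCY7" &
                                  naive$drug == "dab"])

  s1 <- run_cfe_drug_screen(cfe, drug, ann)
  sel <- select_cfe_covariates(s1)
  expect_equal(sel$dab, "BRAFmut")
  adjusted <- run_fusion_drug_screen(fus, drug, ann, cfe_matrix = cfe,
                                     cfe_covariates = sel)
  expect_false(adjusted$significant[adjusted$feature == "NKD1--ADCY7" &
                                      adjusted$drug == "dab"])
})

test_that("a planted sensitizing fusion is recovered as significant", {
  set.seed(45)
  n <- 50
  lines <- paste0("L", 1:n)
  ann <- data.frame(cell_line = lines, tissue = rep(c("a", "b"), each = 25),
                    msi_status = "MSS")
  fus <- matrix(0L, 5, n, dimnames = list(paste0("F", 1:5), lines))
  for (i in 1:5) fus[i, sample(n, 4)] <- 1L
  y <- rnorm(n) + ifelse(ann$tissue == "a", 0.5, -0.5)
  y[fus[1, ] == 1] <- y[fus[1, ] == 1] - 3
  drug <- data.frame(drug = "D1", cell_line = lines, ic50 = y)
  res <- run_fusion_drug_screen(fus, drug, ann)
  expect_true(res$significant[res$feature == "F1"])
  expect_lt(res$effect_size[res$feature == "F1"], 0)   # sensitizing
})
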