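#' @title Fusion / drug-sensitivity association
#' @description Two-stage covariate-adjusted ANOVA on log IC50 drug
#'   response. Stage 1 associates established cancer functional events
#'   (CFEs: driver mutations, copy-number segments, methylation states)
#'   with each drug, adjusting for tissue and MSI status; CFEs passing the
#'   large-effect cutoffs (FDR < 25%, p < 0.001, both Glass Deltas > 1)
#'   become per-drug confounder covariates. Stage 2 tests recurrent fusion
#'   events for drug association with those confounders included, gating
#'   hits on FDR and dual Glass Deltas.
#' @name drug-assoc
NULL

#' Glass Delta effect sizes for a two-group comparison
#'
#' `delta_pos = |mean_pos - mean_neg| / sd_pos` and likewise with the
#' negative group's standard deviation (sample sd, n - 1 denominator).
#' A group of size one or with zero spread yields `NA` for its delta,
#' which fails the effect-size gate downstream.
#'
#' @param pos,neg Numeric vectors of raw (unadjusted) log IC50 values for
#'   feature-positive and feature-negative cell lines. Both non-empty.
#' @return Named numeric vector `c(delta_pos, delta_neg)`.
#' @export
glass_deltas <- function(pos, neg) {
  if (!length(pos) || !length(neg)) stop("both groups must be non-empty")
  d <- abs(mean(pos) - mean(neg))
  one <- function(g) {
    if (length(g) < 2) return(NA_real_)
    s <- stats::sd(g)
    if (!is.finite(s) || s == 0) return(NA_real_)
    d / s
  }
  c(delta_pos = one(pos), delta_neg = one(neg))
}

#' Covariate-adjusted ANOVA of one feature against one drug
#'
#' Ordinary least squares of log IC50 on covariates plus the binary
#' feature; the feature p-value is the type-II F-test (equivalently the
#' nested-model F-test, there being no interactions). The effect size is
#' the feature coefficient (negative = sensitizing); Glass Deltas are
#' computed on the raw group values.
#'
#' @param feature Logical/0-1 vector named by cell line.
#' @param ic50 Numeric log IC50 vector named by cell line.
#' @param covariates Optional `data.frame` of covariates with rownames (or
#'   a `cell_line` column) identifying lines. Constant columns are dropped
#'   (e.g. tissue for a drug screened in a single tissue).
#' @param min_group Minimum positive and negative group size (default 2).
#' @return One-row `data.frame` with `n_pos, n_neg, effect_size, p_value,
#'   glass_delta_pos, glass_delta_neg, testable, reason`.
#' @export
fit_feature_drug_anova <- function(feature, ic50, covariates = NULL,
                                   min_group = 2) {
  lines <- intersect(names(feature), names(ic50)[is.finite(ic50)])
  f <- as.logical(feature[lines])
  y <- ic50[lines]
  res <- data.frame(n_pos = sum(f), n_neg = sum(!f), effect_size = NA_real_,
                    p_value = NA_real_, glass_delta_pos = NA_real_,
                    glass_delta_neg = NA_real_, testable = FALSE,
                    reason = "", stringsAsFactors = FALSE)
  if (sum(f) < min_group || sum(!f) < min_group) {
    res$reason <- "insufficient group size"
    return(res)
  }
  dat <- data.frame(.y = y)
  if (!is.null(covariates)) {
    cov <- as.data.frame(covariates)
    if ("cell_line" %in% names(cov)) {
      rownames(cov) <- cov$cell_line
      cov$cell_line <- NULL
    }
    cov <- droplevels(cov[lines, , drop = FALSE])
    keep <- vapply(cov, function(v) length(unique(v)) > 1, logical(1))
    dat <- cbind(dat, cov[, keep, drop = FALSE])
  }
  # the feature enters last so that, when it is a linear combination of the
  # covariates, it (not a covariate) is the aliased term
  dat$.feature <- f
  fit <- stats::lm(.y ~ ., data = dat)
  al <- stats::alias(fit)$Complete
  if (!is.null(al)) {
    if (".featureTRUE" %in% rownames(al)) {
      res$reason <- "feature collinear with covariates"
      return(res)
    }
    drop <- unique(sub("TRUE$", "", rownames(al)))
    dat <- dat[, setdiff(names(dat), drop), drop = FALSE]
    fit <- stats::lm(.y ~ ., data = dat)
  }
  a2 <- tryCatch(car::Anova(fit, type = 2), error = function(e) NULL)
  # a saturated/zero-residual fit leaves no F-test; effect sizes and Glass
  # Deltas are still reported so the gate can judge the association
  res$p_value <- if (is.null(a2)) NA_real_ else a2[".feature", "Pr(>F)"]
  res$effect_size <- unname(stats::coef(fit)[".featureTRUE"])
  gd <- glass_deltas(y[f], y[!f])
  res$glass_delta_pos <- gd[["delta_pos"]]
  res$glass_delta_neg <- gd[["delta_neg"]]
  res$testable <- TRUE
  res
}

# Shared driver for stage 1 (CFEs) and stage 2 (fusions): tests every
# (feature, drug) pair meeting group-size preconditions, BH-corrects across
# all tests of the stage.
run_feature_drug_screen <- function(feature_matrix, drug_table,
                                    sample_annotation,
                                    extra_covariates = NULL, min_group = 2,
                                    test_features = rownames(feature_matrix)) {
  ann <- unique(sample_annotation[, intersect(
    c("cell_line", "tissue", "cancer_type", "msi_status"),
    names(sample_annotation))])
  tissue <- ann[["tissue"]] %||% ann[["cancer_type"]]
  base_cov <- data.frame(row.names = ann$cell_line,
                         tissue = factor(tissue))
  if ("msi_status" %in% names(ann)) {
    msi <- as.character(ann$msi_status)
    msi[is.na(msi)] <- "unknown"
    base_cov$msi_status <- factor(msi)
  }
  drugs <- unique(drug_table$drug)
  rows <- list()
  for (d in drugs) {
    dt <- drug_table[drug_table$drug == d, , drop = FALSE]
    y <- stats::setNames(dt$ic50, dt$cell_line)
    cov <- base_cov
    extra <- extra_covariates[[d]]
    if (length(extra)) {
      add <- as.data.frame(t(feature_matrix[extra, rownames(cov), drop = FALSE]))
      names(add) <- paste0("cfe_", extra)
      add[] <- lapply(add, function(v) as.logical(v))
      cov <- cbind(cov, add)
    }
    for (feat in test_features) {
      if (feat %in% extra) next
      fv <- stats::setNames(as.logical(feature_matrix[feat, ]),
                            colnames(feature_matrix))
      r <- fit_feature_drug_anova(fv, y, cov, min_group = min_group)
      r <- cbind(data.frame(feature = feat, drug = d,
                            covariates_used = paste(
                              c(names(cov)), collapse = ","),
                            stringsAsFactors = FALSE), r)
      rows[[length(rows) + 1L]] <- r
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$fdr <- NA_real_
  tested <- which(out$testable)
  out$fdr[tested] <- stats::p.adjust(out$p_value[tested], "BH")
  out
}

#' Stage 1: cancer-functional-event / drug associations
#'
#' Tests every CFE against every drug with tissue and MSI covariates;
#' BH FDR across all stage-1 tests.
#'
#' @param cfe_matrix Binary CFE x cell line matrix.
#' @param drug_table Long `data.frame` with `drug, cell_line, ic50`
#'   (log-scale IC50, at most one value per pair).
#' @param sample_annotation `data.frame` with `cell_line`, `tissue` (or
#'   `cancer_type`) and optionally `msi_status`.
#' @param min_group Minimum group size per side (default 2).
#' @return Association `data.frame` (one row per tested pair).
#' @export
run_cfe_drug_screen <- function(cfe_matrix, drug_table, sample_annotation,
                                min_group = 2) {
  run_feature_drug_screen(cfe_matrix, drug_table, sample_annotation,
                          min_group = min_group)
}

#' Select per-drug CFE confounder covariates from stage-1 results
#'
#' A CFE becomes a stage-2 covariate for a drug when its stage-1
#' association has FDR below `fdr_max`, p below `p_max` and both Glass
#' Deltas above `delta_min`.
#'
#' @param stage1 Output of [run_cfe_drug_screen()].
#' @param fdr_max,p_max,delta_min Cutoffs (defaults 0.25, 0.001, 1).
#' @return Named list, drug -> character vector of CFE ids.
#' @export
select_cfe_covariates <- function(stage1, fdr_max = 0.25, p_max = 0.001,
                                  delta_min = 1) {
  sel <- stage1$testable &
    !is.na(stage1$fdr) & stage1$fdr < fdr_max &
    !is.na(stage1$p_value) & stage1$p_value < p_max &
    !is.na(stage1$glass_delta_pos) & stage1$glass_delta_pos > delta_min &
    !is.na(stage1$glass_delta_neg) & stage1$glass_delta_neg > delta_min
  split(stage1$feature[sel], stage1$drug[sel])
}

#' Stage 2: fusion / drug associations with CFE confounders
#'
#' Tests every recurrent fusion feature against every drug, with tissue,
#' MSI and the drug's selected CFE confounders as covariates. BH FDR is
#' computed across all stage-2 tests; a hit is `significant` when FDR is
#' below `fdr_max` and both Glass Deltas exceed `delta_min`. Negative
#' effect sizes indicate sensitization.
#'
#' @param fusion_matrix Binary fusion-feature x cell line matrix (each
#'   feature positive in at least 2 screened lines to be testable).
#' @param drug_table,sample_annotation As in [run_cfe_drug_screen()].
#' @param cfe_matrix Binary CFE matrix (needed when `cfe_covariates` is
#'   non-empty).
#' @param cfe_covariates Named list from [select_cfe_covariates()].
#' @param fdr_max,delta_min Significance gate (defaults 0.25 and 1).
#' @param min_group Minimum group size per side (default 2).
#' @return Association `data.frame` with a logical `significant` column.
#' @export
run_fusion_drug_screen <- function(fusion_matrix, drug_table,
                                   sample_annotation, cfe_matrix = NULL,
                                   cfe_covariates = list(), fdr_max = 0.25,
                                   delta_min = 1, min_group = 2) {
  if (length(cfe_covariates) && is.null(cfe_matrix)) {
    stop("cfe_matrix required when cfe_covariates are supplied")
  }
  extra <- if (length(cfe_covariates)) cfe_covariates else NULL
  out <- if (is.null(extra)) {
    run_feature_drug_screen(fusion_matrix, drug_table, sample_annotation,
                            min_group = min_group)
  } else {
    # stack fusion features on the CFE matrix so confounder columns resolve
    all_lines <- colnames(fusion_matrix)
    fm <- rbind(fusion_matrix, cfe_matrix[, all_lines, drop = FALSE])
    run_feature_drug_screen(fm, drug_table, sample_annotation,
                            extra_covariates = extra,
                            min_group = min_group,
                            test_features = rownames(fusion_matrix))
  }
  out$significant <- out$testable &
    !is.na(out$fdr) & out$fdr < fdr_max &
    !is.na(out$glass_delta_pos) & out$glass_delta_pos > delta_min &
    !is.na(out$glass_delta_neg) & out$glass_delta_neg > delta_min
  rownames(out) <- NULL
  out
}
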