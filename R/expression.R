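#' @title Fusion / expression association
#' @description Links the fusion status of a partner gene to its own
#'   expression (log2 RPKM) with an ordinary least-squares model adjusting
#'   for cancer type, microsatellite instability and the gene's copy-number
#'   category; significance of the fusion term is a type-II F-test, which
#'   for a single term without interactions equals the nested-model F-test.
#'   Separately flags fusion events whose 3' gene is expressed above the
#'   95th percentile of non-carrier cell lines without amplification.
#' @name expression-assoc
NULL

#' Genes testable for fusion-linked differential expression
#'
#' Aggregates fusion events sharing a common partner gene at the 5' or the
#' 3' end; a gene is testable at an end when fused at that end in at least
#' `min_samples` cell lines.
#'
#' @param events Event table from [aggregate_events()].
#' @param min_samples Minimum carrier cell lines (default 3, i.e. recurrent
#'   with n > 2).
#' @return `data.frame` with columns `gene, end` (`"5p"`/`"3p"`) and a list
#'   column `cell_lines` of carrier cell lines.
#' @export
build_fused_gene_sets <- function(events, min_samples = 3) {
  one_end <- function(col, end) {
    sets <- lapply(split(events$cell_line, events[[col]]), unique)
    sets <- sets[lengths(sets) >= min_samples]
    if (!length(sets)) return(NULL)
    data.frame(gene = names(sets), end = end,
               cell_lines = I(unname(sets)), stringsAsFactors = FALSE)
  }
  out <- rbind(one_end("gene5", "5p"), one_end("gene3", "3p"))
  if (is.null(out)) {
    out <- data.frame(gene = character(), end = character(),
                      cell_lines = I(list()), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Fit the fusion / expression linear model for one gene
#'
#' Models log2 RPKM expression as covariate effects plus a fusion-status
#' term: `G = beta_cov * X_cov + beta_fusion * X_fusion + noise`, fitted by
#' ordinary least squares. The fusion-term p-value is the type-II F-test
#' (computed with [car::Anova]); with no interactions this equals the F-test
#' comparing the full model to the model without the fusion term.
#'
#' @param expression Numeric response vector (log2 RPKM across samples).
#' @param fused Logical (or 0/1) fusion indicator, same length.
#' @param covariates Optional `data.frame` of covariates (factors or
#'   numeric), same number of rows. Constant columns and empty factor
#'   levels are dropped.
#' @return Object of class `fusion_expr_fit` with elements `beta_fusion`,
#'   `beta_covariates`, `p_value`, `n_fused`, `n`, `testable`, `fit` (the
#'   underlying `lm`, when testable).
#' @export
fit_fusion_expression_model <- function(expression, fused, covariates = NULL) {
  fused <- as.logical(fused)
  stopifnot(length(fused) == length(expression))
  out <- list(beta_fusion = NA_real_, beta_covariates = NULL,
              p_value = NA_real_, n_fused = sum(fused), n = length(fused),
              testable = FALSE, fit = NULL)
  class(out) <- "fusion_expr_fit"
  if (all(fused) || !any(fused)) {
    out$reason <- "fusion indicator is constant"
    return(out)
  }
  dat <- data.frame(.y = expression)
  if (!is.null(covariates)) {
    covariates <- droplevels(as.data.frame(covariates))
    keep <- vapply(covariates, function(v) length(unique(v)) > 1, logical(1))
    dat <- cbind(dat, covariates[, keep, drop = FALSE])
  }
  dat$.fusion <- fused                   # last, so aliasing names the fusion
  fit <- stats::lm(.y ~ ., data = dat)
  al <- stats::alias(fit)$Complete
  if (!is.null(al)) {
    stop("rank-deficient design; aliased coefficients: ",
         paste(rownames(al), collapse = ", "))
  }
  a2 <- car::Anova(fit, type = 2)
  out$p_value <- a2[".fusion", "Pr(>F)"]
  cf <- stats::coef(fit)
  out$beta_fusion <- unname(cf[".fusionTRUE"])
  out$beta_covariates <- cf[setdiff(names(cf), c("(Intercept)", ".fusionTRUE"))]
  out$testable <- TRUE
  out$fit <- fit
  out
}

#' @export
print.fusion_expr_fit <- function(x, ...) {
  if (!x$testable) {
    cat("fusion-expression model: not testable (", x$reason, ")\n", sep = "")
  } else {
    cat(sprintf(
      "fusion-expression model: beta_fusion = %.3f (log2 units), p = %.3g, n_fused = %d/%d\n",
      x$beta_fusion, x$p_value, x$n_fused, x$n))
  }
  invisible(x)
}

#' Benjamini-Hochberg adjustment within strata
#'
#' Applies BH FDR to a vector of p-values independently within each stratum
#' (a pan-cancer analysis is a single stratum).
#'
#' @param p Numeric p-values.
#' @param stratum Stratum label per p-value; default one stratum.
#' @return Vector of adjusted values, same order as `p`.
#' @export
adjust_expression_fdr <- function(p, stratum = rep("all", length(p))) {
  stopifnot(length(stratum) == length(p))
  out <- rep(NA_real_, length(p))
  for (s in unique(stratum)) {
    i <- which(stratum == s & !is.na(p))
    out[i] <- stats::p.adjust(p[i], "BH")
  }
  out
}

#' Test all recurrently fused genes for differential expression
#'
#' Runs [fit_fusion_expression_model()] for every gene-end combination from
#' [build_fused_gene_sets()], with cancer type (when more than one),
#' MSI status and the gene's copy-number category as covariates, and
#' adjusts p-values by BH within the (single, pan-cancer) stratum.
#'
#' @param events Event table.
#' @param expression Gene x sample numeric matrix of log2 RPKM.
#' @param sample_annotation `data.frame` with `cell_line`, `cancer_type`
#'   and optionally `msi_status`.
#' @param cna Optional long `data.frame` (`gene`, `cell_line`, `category`
#'   in `loss/neutral/amplified`); genes/lines absent default to neutral.
#' @param min_samples Minimum carrier lines per gene end (default 3).
#' @return `data.frame`: `gene, end, n_fused, beta_fusion, p_value, fdr`.
#' @export
test_fusion_expression <- function(events, expression, sample_annotation,
                                   cna = NULL, min_samples = 3) {
  sets <- build_fused_gene_sets(events, min_samples = min_samples)
  lines <- colnames(expression)
  ann <- unique(sample_annotation[, intersect(
    c("cell_line", "cancer_type", "msi_status"), names(sample_annotation))])
  ann <- ann[match(lines, ann$cell_line), , drop = FALSE]
  rows <- lapply(seq_len(nrow(sets)), function(i) {
    gene <- sets$gene[i]
    if (!gene %in% rownames(expression)) return(NULL)
    fused <- lines %in% sets$cell_lines[[i]]
    cov <- data.frame(cancer_type = factor(ann$cancer_type))
    if ("msi_status" %in% names(ann)) {
      msi <- as.character(ann$msi_status)
      msi[is.na(msi)] <- "unknown"
      cov$msi_status <- factor(msi)
    }
    if (!is.null(cna)) {
      g <- cna[cna$gene == gene, , drop = FALSE]
      cat3 <- g$category[match(lines, g$cell_line)]
      cat3[is.na(cat3)] <- "neutral"
      cov$cna <- factor(cat3)
    }
    f <- fit_fusion_expression_model(expression[gene, ], fused, cov)
    data.frame(gene = gene, end = sets$end[i], n_fused = f$n_fused,
               beta_fusion = f$beta_fusion, p_value = f$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(gene = character(), end = character(),
                      n_fused = integer(), beta_fusion = numeric(),
                      p_value = numeric(), fdr = numeric(),
                      stringsAsFactors = FALSE))
  }
  out$fdr <- adjust_expression_fdr(out$p_value)
  rownames(out) <- NULL
  out
}

#' Flag outlier 3' gene overexpression in fusion carriers
#'
#' For each fusion event, ranks the carrier's expression of the 3' gene
#' against all other cell lines (strictly-lower count over the number of
#' other lines, carrier excluded from its own reference set). The event is
#' flagged when the rank reaches the 95th percentile and the carrier is not
#' amplified for the gene.
#'
#' @param events Event table.
#' @param expression Gene x sample log2 RPKM matrix.
#' @param cna Optional long CNA `data.frame` as in
#'   [test_fusion_expression()]; used to mark amplified carriers.
#' @param percentile Flagging threshold on the rank (default 0.95).
#' @return `data.frame`: `cell_line, gene5, gene3, carrier_expression,
#'   percentile_rank, amplified, testable, flagged`.
#' @export
flag_overexpression <- function(events, expression, cna = NULL,
                                percentile = 0.95) {
  amp_key <- if (!is.null(cna)) {
    paste(cna$gene, cna$cell_line, sep = "\r")[cna$category == "amplified"]
  } else character(0)
  rows <- lapply(seq_len(nrow(events)), function(i) {
    gene <- events$gene3[i]
    line <- events$cell_line[i]
    testable <- gene %in% rownames(expression) && line %in% colnames(expression)
    if (!testable) {
      return(data.frame(cell_line = line, gene5 = events$gene5[i], gene3 = gene,
                        carrier_expression = NA_real_, percentile_rank = NA_real_,
                        amplified = NA, testable = FALSE, flagged = NA,
                        stringsAsFactors = FALSE))
    }
    x <- expression[gene, ]
    carrier <- x[[line]]
    others <- x[setdiff(colnames(expression), line)]
    rank <- if (length(others)) sum(others < carrier) / length(others) else NA_real_
    amplified <- paste(gene, line, sep = "\r") %in% amp_key
    data.frame(cell_line = line, gene5 = events$gene5[i], gene3 = gene,
               carrier_expression = carrier, percentile_rank = rank,
               amplified = amplified, testable = TRUE,
               flagged = !is.na(rank) && rank >= percentile && !amplified,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
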