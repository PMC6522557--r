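#' @title End-to-end pipeline
#' @description Runs the full triage on a directory of input files (or a
#'   freshly simulated study): consensus catalog, recurrence permutation
#'   test, expression association, two-stage drug ANOVA, FES scoring and
#'   set enrichment, writing one tab-separated table per stage plus a
#'   machine-readable run manifest. Stage seeds are derived from the
#'   global seed by fixed offsets so each stage is independently
#'   reproducible.
#' @name pipeline
NULL

write_stage <- function(x, out_dir, name) {
  path <- file.path(out_dir, paste0(name, ".tsv"))
  df <- as.data.frame(x)
  df <- df[, !vapply(df, is.list, logical(1)), drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full fusion-prioritization pipeline
#'
#' Simulates a study from `config` (or uses a pre-built one), runs all
#' stages in dependency order and writes per-stage outputs and a manifest
#' to `out_dir`. The enrichment stage asks whether the planted functional
#' fusions rank among the most depleted FES values.
#'
#' @param out_dir Output directory (created if missing).
#' @param config A [sim_config()]; its seed drives every stage.
#' @param study Optional pre-built [simulate_study()] result (must match
#'   `config` if both are given).
#' @param n_perm_recurrence,n_perm_fes,n_perm_enrichment Permutation
#'   counts per stochastic stage.
#' @param params List of stage parameters:
#'   `min_junction_reads, min_callers, breakpoint_tolerance_bp,
#'   source_precedence, min_expr_samples, fes_min_diff, fes_fdr_max`.
#' @return Invisibly, a list with every stage result and the manifest.
#' @export
run_pipeline <- function(out_dir, config = sim_config(), study = NULL,
                         n_perm_recurrence = 1000, n_perm_fes = 1000,
                         n_perm_enrichment = 1000,
                         params = list()) {
  p <- utils::modifyList(list(min_junction_reads = 4, min_callers = 2,
                              breakpoint_tolerance_bp = 5,
                              source_precedence = c("sanger", "archive"),
                              min_expr_samples = 3,
                              fes_min_diff = 0.45, fes_fdr_max = 0.05),
                         params)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  study <- study %||% simulate_study(config)
  ann <- study$annotation

  # stage: catalog
  calls <- validate_fusion_calls(study$calls)
  transcripts <- merge_calls(calls, p$breakpoint_tolerance_bp)
  transcripts <- filter_transcripts(transcripts, p$min_junction_reads,
                                    p$min_callers, study$blacklist)
  transcripts <- deduplicate_samples(transcripts, ann, p$source_precedence)
  events <- aggregate_events(transcripts)
  summary <- summarize_catalog(events, ann, transcripts)
  write_stage(transcripts, out_dir, "transcripts")
  write_stage(events, out_dir, "events")
  write_stage(data.frame(metric = setdiff(names(unclass(summary)),
                                          "events_per_type_median"),
                         value = unlist(unclass(summary)[setdiff(
                           names(unclass(summary)), "events_per_type_median")])),
              out_dir, "catalog_summary")

  # stage: recurrence
  recurrence <- fusion_recurrence(events, ann, n_perm = n_perm_recurrence,
                                  seed = derive_seed(config$seed, 201))
  write_stage(recurrence, out_dir, "recurrence")

  # stage: expression association + overexpression flags
  expr_assoc <- test_fusion_expression(events, study$expression, ann,
                                       study$cna,
                                       min_samples = p$min_expr_samples)
  overexpr <- flag_overexpression(events, study$expression, study$cna)
  write_stage(expr_assoc, out_dir, "expression_assoc")
  write_stage(overexpr, out_dir, "overexpression")

  # stage: drug association (two-stage ANOVA)
  lines <- unique(ann$cell_line)
  fusion_matrix <- fusion_feature_matrix(events, lines)
  drug_ic50 <- stats::setNames(study$ic50, c("drug", "cell_line", "ic50"))
  stage1 <- run_cfe_drug_screen(study$cfe, drug_ic50, ann)
  cfe_cov <- select_cfe_covariates(stage1)
  stage2 <- run_fusion_drug_screen(fusion_matrix, drug_ic50, ann,
                                   cfe_matrix = study$cfe,
                                   cfe_covariates = cfe_cov)
  write_stage(stage1, out_dir, "drug_stage1")
  write_stage(stage2, out_dir, "drug_stage2")

  # stage: FES
  cr <- study$crispr
  guide_genes <- stats::setNames(cr$guides$gene, cr$guides$guide)
  scaled <- cr$fold_changes   # generated on the already-scaled convention
  fes_transcripts <- transcripts[transcripts$gene5 %in% cr$guides$gene &
                                   transcripts$gene3 %in% cr$guides$gene, ]
  fes <- fes_significance(fes_transcripts, cr$guides, scaled,
                          n_perm = n_perm_fes, min_diff = p$fes_min_diff,
                          fdr_max = p$fes_fdr_max,
                          seed = derive_seed(config$seed, 202))
  fes_events <- aggregate_events_fes(fes)
  write_stage(fes, out_dir, "fes")
  write_stage(fes_events, out_dir, "fes_events")

  # stage: enrichment of planted functional fusions among depleted FES
  enrichment <- NULL
  ok <- !is.na(fes$fes)
  if (any(ok)) {
    scores <- stats::setNames(-fes$fes[ok],
                              paste0(fes$transcript[ok], "@", fes$cell_line[ok]))
    truth_pairs <- with(study$truth$fusions[study$truth$fusions$functional, ],
                        paste0(gene5, "--", gene3))
    in_set <- sub(":.*$", "", names(scores)) %in% truth_pairs
    if (any(in_set) && !all(in_set)) {
      enrichment <- enrichment_pvalue(scores, names(scores)[in_set],
                                      n_perm = n_perm_enrichment,
                                      seed = derive_seed(config$seed, 203))
      write_stage(data.frame(set = "planted_functional",
                             es = enrichment$es, p_value = enrichment$p_value,
                             n_set = enrichment$n_set,
                             n_total = enrichment$n_total), out_dir,
                  "enrichment")
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("fusionscreen")),
    seed = config$seed,
    stage_seeds = list(recurrence = derive_seed(config$seed, 201),
                       fes = derive_seed(config$seed, 202),
                       enrichment = derive_seed(config$seed, 203)),
    parameters = p,
    n_perm = list(recurrence = n_perm_recurrence, fes = n_perm_fes,
                  enrichment = n_perm_enrichment),
    config = unclass(config)[!vapply(unclass(config), is.function, logical(1))],
    outputs = sort(list.files(out_dir, pattern = "\\.tsv$"))
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  manifest$file_digests <- as.list(tools::md5sum(
    file.path(out_dir, manifest$outputs)))

  invisible(list(transcripts = transcripts, events = events,
                 summary = summary, recurrence = recurrence,
                 expression = expr_assoc, overexpression = overexpr,
                 drug_stage1 = stage1, drug_stage2 = stage2,
                 fes = fes, fes_events = fes_events,
                 enrichment = enrichment, manifest = manifest))
}

#' Binary fusion-event feature matrix
#'
#' One row per recurrent ordered gene pair (present in at least
#' `min_lines` cell lines), one column per cell line; entry 1 when the
#' line carries the fusion event.
#'
#' @param events Event table from [aggregate_events()].
#' @param cell_lines Column universe.
#' @param min_lines Minimum positive lines per feature (default 2).
#' @return Binary matrix with `gene5--gene3` rownames.
#' @export
fusion_feature_matrix <- function(events, cell_lines, min_lines = 2) {
  pair <- paste0(events$gene5, "--", events$gene3)
  keep <- names(which(table(pair) >= min_lines))
  m <- matrix(0L, length(keep), length(cell_lines),
              dimnames = list(keep, cell_lines))
  sel <- pair %in% keep
  m[cbind(match(pair[sel], keep), match(events$cell_line[sel], cell_lines))] <- 1L
  m
}
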