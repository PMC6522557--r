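#' @title Synthetic study generator with planted ground truth
#' @description Generates every input the pipeline consumes — per-caller
#'   fusion call tables, a normal-tissue blacklist, a log2 RPKM expression
#'   matrix, copy-number categories, sample annotation, a drug-response
#'   table with a CFE matrix, and a pooled CRISPR screen (guide library +
#'   fold-change matrix + reference gene lists) — together with a truth
#'   manifest recording which fusions were planted, which are functional,
#'   which drive expression and which sensitize to which drug. All
#'   generators are deterministic given the config seed.
#' @name synthetic-data
NULL

#' Simulation configuration
#'
#' Collects every tunable of the synthetic study. Defaults define the
#' reference conditions used throughout the test-suite: 60 cell lines in 4
#' cancer types, 120 genes, 20 planted fusion pairs (recurrent and
#' singleton), 5 CRISPR-functional fusions with a -1 mapping-guide
#' depletion at noise sd 0.25, expression effects of +3 (oncogene-like 3'
#' partner) and -2 (TSG-like 5' partner) log2 units at residual sd 1, and
#' a -3 log IC50 drug-sensitizing fusion in 4 carrier lines.
#'
#' @param seed Integer master seed; stage seeds are derived by fixed
#'   offsets.
#' @param n_cell_lines,n_cancer_types,n_genes,n_chromosomes Study sizes.
#' @param gene_length,gene_gap Gene model geometry in bp.
#' @param n_replicated_lines Cell lines sequenced by both data sources.
#' @param n_fusion_pairs Planted unique fusion gene pairs.
#' @param n_functional_fusions Pairs whose mapping guides are depleted.
#' @param n_expression_drivers Pairs with a planted expression shift.
#' @param beta_oncogene,beta_tsg Planted log2 expression shifts.
#' @param caller_names,caller_fn_rate Caller set and per-caller dropout.
#' @param n_noise_calls,n_lowread_calls,n_blacklist_pairs Noise structure.
#' @param true_reads_lambda,noise_reads_lambda Junction-read Poisson means
#'   (true calls are 4 + Pois, noise 1 + Pois).
#' @param breakpoint_jitter Max per-caller breakpoint jitter in bp.
#' @param expr_baseline_mean,expr_baseline_sd,expr_type_sd,expr_residual_sd
#'   Expression model (log2 RPKM scale).
#' @param cna_amp_rate,cna_loss_rate,cna_effect Copy-number confounding.
#' @param msi_rate Fraction of MSI cell lines.
#' @param n_drugs,drug_tissue_sd,drug_noise_sd,drug_fusion_shift,
#'   drug_carriers Drug screen (log IC50 scale).
#' @param n_cfes,cfe_rate,cfe_drug_shift Cancer-functional-event matrix and
#'   the confounder's effect.
#' @param guides_per_gene,crispr_depletion,crispr_noise_sd CRISPR screen.
#' @param n_essential,n_nonessential Reference gene list sizes.
#' @return Object of class `sim_config` (a named list).
#' @export
sim_config <- function(seed = 1,
                       n_cell_lines = 60, n_cancer_types = 4,
                       n_genes = 120, n_chromosomes = 4,
                       gene_length = 20000, gene_gap = 10000,
                       n_replicated_lines = 3,
                       n_fusion_pairs = 20, n_functional_fusions = 5,
                       n_expression_drivers = 6,
                       beta_oncogene = 3, beta_tsg = -2,
                       caller_names = c("defuse", "tophatfusion", "starfusion"),
                       caller_fn_rate = 0.1,
                       n_noise_calls = 40, n_lowread_calls = 10,
                       n_blacklist_pairs = 5,
                       true_reads_lambda = 6, noise_reads_lambda = 2,
                       breakpoint_jitter = 2,
                       expr_baseline_mean = 5, expr_baseline_sd = 1,
                       expr_type_sd = 0.5, expr_residual_sd = 1,
                       cna_amp_rate = 0.05, cna_loss_rate = 0.05,
                       cna_effect = 1, msi_rate = 0.1,
                       n_drugs = 8, drug_tissue_sd = 1, drug_noise_sd = 1,
                       drug_fusion_shift = -3, drug_carriers = 4,
                       n_cfes = 10, cfe_rate = 0.15, cfe_drug_shift = -3,
                       guides_per_gene = 5, crispr_depletion = -1,
                       crispr_noise_sd = 0.25,
                       n_essential = 15, n_nonessential = 15) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_genes >= 2 * cfg$n_fusion_pairs +
              cfg$n_essential + cfg$n_nonessential,
            cfg$caller_fn_rate >= 0, cfg$caller_fn_rate <= 1,
            cfg$msi_rate >= 0, cfg$msi_rate <= 1)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate non-overlapping gene models
#'
#' Lays `n_genes` genes of fixed length end to end (with gaps) across
#' `n_chromosomes` chromosomes, assigning each a random genomic strand.
#'
#' @param config A [sim_config()].
#' @return `data.frame`: `gene, chrom, start, end, strand`.
#' @export
simulate_genome <- function(config) {
  stopifnot(config$n_genes >= 2)
  set.seed(derive_seed(config$seed, 101))
  n <- config$n_genes
  chrom <- paste0("chr", rep_len(seq_len(config$n_chromosomes), n))
  idx <- stats::ave(seq_len(n), chrom, FUN = seq_along)
  start <- 1 + (idx - 1) * (config$gene_length + config$gene_gap)
  data.frame(gene = sprintf("G%03d", seq_len(n)),
             chrom = chrom, start = start,
             end = start + config$gene_length - 1,
             strand = sample(c("+", "-"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

#' Simulate the sample annotation
#'
#' Cell lines are assigned evenly to cancer types (tissue = cancer type),
#' with an MSI flag at the configured rate. Every line has a Sanger-like
#' sequencing sample; the first `n_replicated_lines` also have an
#' archive-source sample, exercising source deduplication.
#'
#' @param config A [sim_config()].
#' @return `data.frame`: `sample_id, cell_line, cancer_type, tissue,
#'   msi_status, source`.
#' @export
simulate_annotation <- function(config) {
  set.seed(derive_seed(config$seed, 102))
  lines <- sprintf("CL%02d", seq_len(config$n_cell_lines))
  type <- paste0("type", rep_len(seq_len(config$n_cancer_types),
                                 config$n_cell_lines))
  msi <- ifelse(stats::runif(config$n_cell_lines) < config$msi_rate,
                "MSI", "MSS")
  ann <- data.frame(sample_id = paste0(lines, "_sanger"), cell_line = lines,
                    cancer_type = type, tissue = type, msi_status = msi,
                    source = "sanger", stringsAsFactors = FALSE)
  if (config$n_replicated_lines > 0) {
    i <- seq_len(config$n_replicated_lines)
    dup <- ann[i, ]
    dup$sample_id <- paste0(dup$cell_line, "_archive")
    dup$source <- "archive"
    ann <- rbind(ann, dup)
  }
  rownames(ann) <- NULL
  ann
}

#' Plant the ground-truth fusions
#'
#' Draws fusion gene pairs (disjoint from the essential/non-essential
#' reference genes), assigns carrier cell lines — the first pairs are
#' recurrent within a single cancer type, a middle block is recurrent
#' across types, the rest are singletons — breakpoints inside each gene,
#' and designates which pairs are CRISPR-functional, which drive partner
#' expression (and in which direction), which sensitize to a drug, and
#' which is confounded with a CFE.
#'
#' @param config A [sim_config()].
#' @param genome Output of [simulate_genome()].
#' @param annotation Output of [simulate_annotation()].
#' @return A list of class `truth_manifest`: `fusions` (one row per pair
#'   with a `carriers` list column), `blacklist`, reference gene lists,
#'   and the confounded CFE id.
#' @export
simulate_truth <- function(config, genome, annotation) {
  set.seed(derive_seed(config$seed, 103))
  lines <- unique(annotation$cell_line)
  types <- annotation$cancer_type[match(lines, annotation$cell_line)]
  genes <- sample(genome$gene)
  n_pair <- config$n_fusion_pairs
  ess <- genes[seq_len(config$n_essential)]
  ness <- genes[config$n_essential + seq_len(config$n_nonessential)]
  pool <- genes[-seq_len(config$n_essential + config$n_nonessential)]
  g5 <- pool[seq_len(n_pair)]
  g3 <- pool[n_pair + seq_len(n_pair)]
  spare <- pool[-seq_len(2 * n_pair)]

  n_typed <- min(6L, n_pair)              # recurrent within one cancer type
  n_cross <- min(6L, max(0L, n_pair - n_typed))  # recurrent across types
  carriers <- vector("list", n_pair)
  for (i in seq_len(n_pair)) {
    if (i <= n_typed) {
      t <- sample(unique(types), 1)
      carriers[[i]] <- sample(lines[types == t],
                              min(config$drug_carriers, sum(types == t)))
    } else if (i <= n_typed + n_cross) {
      carriers[[i]] <- sample(lines, 3)
    } else {
      carriers[[i]] <- sample(lines, 1)
    }
  }
  gm <- function(g) genome[match(g, genome$gene), ]
  m5 <- gm(g5); m3 <- gm(g3)
  frac5 <- stats::runif(n_pair, 0.3, 0.7)
  frac3 <- stats::runif(n_pair, 0.3, 0.7)
  fus <- data.frame(
    pair_id = sprintf("F%02d", seq_len(n_pair)),
    gene5 = g5, gene3 = g3,
    chrom5 = m5$chrom, chrom3 = m3$chrom,
    breakpoint5 = round(m5$start + frac5 * (m5$end - m5$start)),
    breakpoint3 = round(m3$start + frac3 * (m3$end - m3$start)),
    strand5 = m5$strand, strand3 = m3$strand,
    in_frame = stats::runif(n_pair) < 0.3,
    stringsAsFactors = FALSE)
  fus$carriers <- carriers

  fus$functional <- FALSE
  fus$functional[1 + seq_len(min(config$n_functional_fusions, n_pair - 1))] <- TRUE

  # expression drivers need >= 3 carriers; alternate oncogene-like (3' end,
  # positive shift) and TSG-like (5' end, negative shift)
  eligible <- which(lengths(carriers) >= 3)
  drv <- utils::head(eligible, config$n_expression_drivers)
  fus$expr_driver_end <- NA_character_
  fus$expr_beta <- NA_real_
  for (k in seq_along(drv)) {
    i <- drv[k]
    if (k %% 2 == 1) {
      fus$expr_driver_end[i] <- "3p"; fus$expr_beta[i] <- config$beta_oncogene
    } else {
      fus$expr_driver_end[i] <- "5p"; fus$expr_beta[i] <- config$beta_tsg
    }
  }

  fus$drug <- NA_character_
  fus$drug_shift <- NA_real_
  fus$drug[1] <- "D01"
  fus$drug_shift[1] <- config$drug_fusion_shift
  # confounded pair: carriers coincide with a CFE that carries the real
  # effect on another drug; the fusion itself gets no planted effect
  conf <- which(!fus$functional & is.na(fus$drug) & lengths(carriers) >= 2)[1]
  fus$confounded <- seq_len(n_pair) == conf

  n_bl <- config$n_blacklist_pairs
  blacklist <- data.frame(gene5 = spare[seq_len(n_bl)],
                          gene3 = spare[n_bl + seq_len(n_bl)],
                          stringsAsFactors = FALSE)
  out <- list(fusions = fus, blacklist = blacklist,
              essential = ess, nonessential = ness,
              confounder_cfe = "CFE01", confounder_drug = "D02")
  class(out) <- "truth_manifest"
  out
}

#' Simulate per-caller fusion call tables and the blacklist
#'
#' True fusions are emitted in every carrier sample by two guaranteed
#' callers plus the third at one minus the dropout rate, with at least
#' four junction reads and small per-caller breakpoint jitter. Noise comes
#' as single-caller calls, two-caller calls below the read threshold, and
#' blacklisted pairs called convincingly but listed in the normal-tissue
#' blacklist.
#'
#' @param config A [sim_config()].
#' @param truth Output of [simulate_truth()].
#' @param annotation Output of [simulate_annotation()].
#' @param genome Output of [simulate_genome()].
#' @return List: `calls` (combined table with a `caller` column, valid
#'   per [validate_fusion_calls()]) and `blacklist`.
#' @export
simulate_fusion_calls <- function(config, truth, annotation, genome) {
  set.seed(derive_seed(config$seed, 104))
  callers <- config$caller_names
  fus <- truth$fusions
  rows <- list()
  emit <- function(sample_id, f, caller, reads, frame) {
    j <- config$breakpoint_jitter
    data.frame(sample_id = sample_id, caller = caller,
               gene5 = f$gene5, gene3 = f$gene3,
               chrom5 = f$chrom5, chrom3 = f$chrom3,
               breakpoint5 = f$breakpoint5 + sample(-j:j, 1),
               breakpoint3 = f$breakpoint3 + sample(-j:j, 1),
               strand5 = f$strand5, strand3 = f$strand3,
               junction_reads = reads, frame = frame,
               stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(fus))) {
    f <- fus[i, ]
    frame <- if (f$in_frame) "in_frame" else "out_of_frame"
    for (line in f$carriers[[1]]) {
      for (sid in annotation$sample_id[annotation$cell_line == line]) {
        use <- sample(callers, 2)
        third <- setdiff(callers, use)
        if (stats::runif(1) >= config$caller_fn_rate) use <- c(use, third)
        for (cl in use) {
          rows[[length(rows) + 1L]] <-
            emit(sid, f, cl, 4 + stats::rpois(1, config$true_reads_lambda),
                 frame)
        }
      }
    }
  }
  rand_pair <- function() {
    repeat {
      g <- sample(genome$gene, 2)
      if (!any(g[1] == fus$gene5 & g[2] == fus$gene3)) return(g)
    }
  }
  noise_row <- function(n_callers, reads) {
    g <- rand_pair()
    m <- genome[match(g, genome$gene), ]
    f <- data.frame(gene5 = g[1], gene3 = g[2],
                    chrom5 = m$chrom[1], chrom3 = m$chrom[2],
                    breakpoint5 = round(mean(c(m$start[1], m$end[1]))),
                    breakpoint3 = round(mean(c(m$start[2], m$end[2]))),
                    strand5 = m$strand[1], strand3 = m$strand[2],
                    stringsAsFactors = FALSE)
    sid <- sample(annotation$sample_id, 1)
    lapply(sample(callers, n_callers), function(cl) {
      emit(sid, f, cl, reads, "unknown")
    })
  }
  for (k in seq_len(config$n_noise_calls)) {
    rows <- c(rows, noise_row(1, 1 + stats::rpois(1, config$noise_reads_lambda)))
  }
  for (k in seq_len(config$n_lowread_calls)) {
    rows <- c(rows, noise_row(2, sample(1:3, 1)))
  }
  bl <- truth$blacklist
  for (i in seq_len(nrow(bl))) {
    m <- genome[match(c(bl$gene5[i], bl$gene3[i]), genome$gene), ]
    f <- data.frame(gene5 = bl$gene5[i], gene3 = bl$gene3[i],
                    chrom5 = m$chrom[1], chrom3 = m$chrom[2],
                    breakpoint5 = round(mean(c(m$start[1], m$end[1]))),
                    breakpoint3 = round(mean(c(m$start[2], m$end[2]))),
                    strand5 = m$strand[1], strand3 = m$strand[2],
                    stringsAsFactors = FALSE)
    sid <- sample(annotation$sample_id, 1)
    for (cl in sample(callers, 2)) {
      rows[[length(rows) + 1L]] <-
        emit(sid, f, cl, 4 + stats::rpois(1, config$true_reads_lambda),
             "unknown")
    }
  }
  calls <- do.call(rbind, rows)
  rownames(calls) <- NULL
  list(calls = calls, blacklist = bl)
}

#' Simulate expression and copy-number data
#'
#' Gene x cell line log2 RPKM values: per-gene baseline, per-(gene, cancer
#' type) shifts, additive copy-number effects (amplified +, loss -),
#' planted fusion-driver shifts in carrier lines at the designated partner
#' end, and Gaussian residual noise.
#'
#' @inheritParams simulate_fusion_calls
#' @return List: `expression` (matrix), `cna` (long `data.frame` of
#'   non-neutral categories: `gene, cell_line, category`).
#' @export
simulate_expression_cna <- function(config, truth, annotation, genome) {
  set.seed(derive_seed(config$seed, 105))
  lines <- unique(annotation$cell_line)
  types <- annotation$cancer_type[match(lines, annotation$cell_line)]
  genes <- genome$gene
  ng <- length(genes); nl <- length(lines)
  base <- stats::rnorm(ng, config$expr_baseline_mean, config$expr_baseline_sd)
  tlev <- unique(types)
  teff <- matrix(stats::rnorm(ng * length(tlev), 0, config$expr_type_sd),
                 ng, length(tlev), dimnames = list(genes, tlev))
  u <- stats::runif(ng * nl)
  cat <- ifelse(u < config$cna_amp_rate, "amplified",
                ifelse(u < config$cna_amp_rate + config$cna_loss_rate,
                       "loss", "neutral"))
  cna_m <- matrix(cat, ng, nl, dimnames = list(genes, lines))
  cna_eff <- (cna_m == "amplified") * config$cna_effect -
    (cna_m == "loss") * config$cna_effect
  expr <- base + teff[, types] + cna_eff +
    matrix(stats::rnorm(ng * nl, 0, config$expr_residual_sd), ng, nl)
  dimnames(expr) <- list(genes, lines)
  fus <- truth$fusions
  for (i in which(!is.na(fus$expr_driver_end))) {
    g <- if (fus$expr_driver_end[i] == "5p") fus$gene5[i] else fus$gene3[i]
    expr[g, fus$carriers[[i]]] <- expr[g, fus$carriers[[i]]] + fus$expr_beta[i]
  }
  idx <- which(cna_m != "neutral", arr.ind = TRUE)
  cna <- data.frame(gene = genes[idx[, 1]], cell_line = lines[idx[, 2]],
                    category = cna_m[idx], stringsAsFactors = FALSE)
  list(expression = expr, cna = cna)
}

#' Simulate drug response and the CFE matrix
#'
#' Log IC50 values per (drug, cell line): per-(drug, tissue) baseline
#' shifts, Gaussian noise, the planted fusion-drug sensitization in the
#' fusion's carriers, and a CFE (default `CFE01`) that carries a real
#' effect on a second drug while coinciding with the confounded fusion's
#' carriers — reproducing the situation where a fusion-drug association is
#' explained by a co-occurring driver event.
#'
#' @inheritParams simulate_fusion_calls
#' @return List: `ic50` (long `data.frame` `drug, cell_line, ic50`),
#'   `cfe` (binary CFE x cell line matrix).
#' @export
simulate_drug_response <- function(config, truth, annotation) {
  set.seed(derive_seed(config$seed, 106))
  lines <- unique(annotation$cell_line)
  types <- annotation$cancer_type[match(lines, annotation$cell_line)]
  drugs <- sprintf("D%02d", seq_len(config$n_drugs))
  tlev <- unique(types)
  teff <- matrix(stats::rnorm(length(drugs) * length(tlev), 0,
                              config$drug_tissue_sd),
                 length(drugs), length(tlev), dimnames = list(drugs, tlev))
  ic50 <- teff[, types] +
    matrix(stats::rnorm(length(drugs) * length(lines), 0,
                        config$drug_noise_sd),
           length(drugs), length(lines))
  dimnames(ic50) <- list(drugs, lines)

  cfe <- matrix(stats::runif(config$n_cfes * length(lines)) < config$cfe_rate,
                config$n_cfes, length(lines),
                dimnames = list(sprintf("CFE%02d", seq_len(config$n_cfes)),
                                lines)) + 0L
  fus <- truth$fusions
  planted <- which(!is.na(fus$drug))
  for (i in planted) {
    ic50[fus$drug[i], fus$carriers[[i]]] <-
      ic50[fus$drug[i], fus$carriers[[i]]] + fus$drug_shift[i]
  }
  conf <- which(fus$confounded)
  if (length(conf)) {
    # the CFE's positives are the confounded fusion's carriers plus a couple
    # of other lines: coincident enough that the fusion picks up the CFE's
    # effect, distinct enough that the adjusted model can separate them
    carriers <- fus$carriers[[conf]]
    pos <- union(carriers, sample(setdiff(lines, carriers), 2))
    cfe[truth$confounder_cfe, ] <- 0L
    cfe[truth$confounder_cfe, pos] <- 1L
    ic50[truth$confounder_drug, pos] <-
      ic50[truth$confounder_drug, pos] + config$cfe_drug_shift
  }
  long <- data.frame(drug = rep(drugs, length(lines)),
                     cell_line = rep(lines, each = length(drugs)),
                     ic50 = as.vector(ic50), stringsAsFactors = FALSE)
  list(ic50 = long, cfe = cfe)
}

#' Simulate a pooled CRISPR screen
#'
#' Places `guides_per_gene` sgRNAs uniformly across each gene and emits a
#' guide x cell line fold-change matrix on the already-scaled convention:
#' guides of non-essential reference genes centre at 0, essential
#' reference guides at -1, and mapping guides of functional fusions gain
#' the configured depletion in carrier lines only.
#'
#' @inheritParams simulate_fusion_calls
#' @return List: `guides` (library table `guide, gene, chrom,
#'   cut_position, gene_strand`), `fold_changes` (matrix), `essential`,
#'   `nonessential` (gene lists), `guide_mapping` (per functional pair,
#'   the mapping guide ids).
#' @export
simulate_crispr_screen <- function(config, truth, annotation, genome) {
  set.seed(derive_seed(config$seed, 107))
  lines <- unique(annotation$cell_line)
  k <- config$guides_per_gene
  guides <- do.call(rbind, lapply(seq_len(nrow(genome)), function(i) {
    g <- genome[i, ]
    pos <- round(seq(g$start, g$end, length.out = k + 2))[2:(k + 1)]
    data.frame(guide = sprintf("%s_sg%d", g$gene, seq_len(k)),
               gene = g$gene, chrom = g$chrom, cut_position = pos,
               gene_strand = g$strand, stringsAsFactors = FALSE)
  }))
  fc <- matrix(stats::rnorm(nrow(guides) * length(lines), 0,
                            config$crispr_noise_sd),
               nrow(guides), length(lines),
               dimnames = list(guides$guide, lines))
  ess_rows <- guides$gene %in% truth$essential
  fc[ess_rows, ] <- fc[ess_rows, ] - 1
  fus <- truth$fusions
  mapping <- list()
  for (i in which(fus$functional)) {
    part <- map_guides_to_transcript(
      guides[guides$gene %in% c(fus$gene5[i], fus$gene3[i]), ], fus[i, ])
    ids <- c(part$mapping5, part$mapping3)
    mapping[[fus$pair_id[i]]] <- ids
    fc[ids, fus$carriers[[i]]] <- fc[ids, fus$carriers[[i]]] +
      config$crispr_depletion
  }
  list(guides = guides, fold_changes = fc,
       essential = truth$essential, nonessential = truth$nonessential,
       guide_mapping = mapping)
}

#' Simulate a complete study
#'
#' Runs every generator with seeds derived from the config seed and
#' returns all pipeline inputs plus the truth manifest.
#'
#' @param config A [sim_config()].
#' @return Named list: `config, genome, annotation, truth, calls,
#'   blacklist, expression, cna, ic50, cfe, crispr`.
#' @export
simulate_study <- function(config = sim_config()) {
  genome <- simulate_genome(config)
  annotation <- simulate_annotation(config)
  truth <- simulate_truth(config, genome, annotation)
  fc <- simulate_fusion_calls(config, truth, annotation, genome)
  ec <- simulate_expression_cna(config, truth, annotation, genome)
  dr <- simulate_drug_response(config, truth, annotation)
  cr <- simulate_crispr_screen(config, truth, annotation, genome)
  list(config = config, genome = genome, annotation = annotation,
       truth = truth, calls = fc$calls, blacklist = fc$blacklist,
       expression = ec$expression, cna = ec$cna,
       ic50 = dr$ic50, cfe = dr$cfe, crispr = cr)
}
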