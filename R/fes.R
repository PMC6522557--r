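#' @title Fusion essentiality score (FES) from pooled CRISPR screens
#' @description Rather than averaging sgRNA fold changes to gene level, the
#'   FES exploits individual guide positions: guides targeting the portion
#'   of either partner gene retained in a fusion transcript ("mapping"
#'   guides) are compared with the remaining guides for the same genes
#'   ("non-mapping"). A strongly negative FES in the fusion-carrying cell
#'   line indicates fusion-specific loss of fitness. Significance is
#'   assessed by randomizing fold changes within cell lines.
#' @name fes-crispr
NULL

#' Scale fold changes to essential / non-essential reference medians
#'
#' Per cell line, linearly rescales corrected log fold changes so the
#' median over guides targeting non-essential reference genes is 0 and the
#' median over guides targeting essential reference genes is -1:
#' `scaled(x) = (x - m_ne) / (m_ne - m_e)`.
#'
#' @param fold_changes Guide x cell line numeric matrix (corrected log
#'   fold changes), rownames = guide ids.
#' @param guide_genes Named character vector, guide id -> target gene.
#' @param essential,nonessential Character vectors of reference gene
#'   symbols; every cell line must have guides for both lists.
#' @return Scaled matrix with attribute `anchors` (per-line `m_e`, `m_ne`).
#'   Errors if any cell line has `m_e >= m_ne` (failed screen).
#' @export
scale_to_essentials <- function(fold_changes, guide_genes, essential,
                                nonessential) {
  genes <- guide_genes[rownames(fold_changes)]
  e_idx <- which(genes %in% essential)
  ne_idx <- which(genes %in% nonessential)
  if (!length(e_idx) || !length(ne_idx)) {
    stop("no guides targeting one of the reference gene lists")
  }
  m_e <- apply(fold_changes[e_idx, , drop = FALSE], 2, stats::median)
  m_ne <- apply(fold_changes[ne_idx, , drop = FALSE], 2, stats::median)
  bad <- m_e >= m_ne
  if (any(bad)) {
    stop("essential-guide median not below non-essential median in: ",
         paste(colnames(fold_changes)[bad], collapse = ", "))
  }
  scaled <- sweep(fold_changes, 2, m_ne, "-")
  scaled <- sweep(scaled, 2, m_ne - m_e, "/")
  attr(scaled, "anchors") <- data.frame(cell_line = colnames(fold_changes),
                                        median_essential = m_e,
                                        median_nonessential = m_ne,
                                        row.names = NULL)
  scaled
}

#' Partition a fusion's guides into mapping and non-mapping sets
#'
#' A guide maps onto the 5' gene when the gene is on the plus strand and
#' its cut site is at or before the 5' breakpoint, or the gene is on the
#' minus strand and the cut site is at or after the breakpoint; the 3' gene
#' rule is the mirror image (cut at or after the breakpoint on plus, at or
#' before on minus). A cut site exactly at the breakpoint counts as
#' mapping. Guides on the wrong chromosome are excluded with a warning.
#'
#' @param guides `data.frame` with columns `guide, gene, chrom,
#'   cut_position, gene_strand`, restricted or not to the partner genes.
#' @param transcript One-row `data.frame` (or list) with `gene5, gene3,
#'   chrom5, chrom3, breakpoint5, breakpoint3, strand5, strand3`, where the
#'   strands are the partner genes' genomic strands.
#' @return List with character vectors `mapping5, nonmapping5, mapping3,
#'   nonmapping3, excluded` of guide ids.
#' @export
map_guides_to_transcript <- function(guides, transcript) {
  t <- as.list(transcript)
  out <- list(mapping5 = character(), nonmapping5 = character(),
              mapping3 = character(), nonmapping3 = character(),
              excluded = character())
  side <- function(gene, chrom, bp, strand, five_prime) {
    g <- guides[guides$gene == gene, , drop = FALSE]
    if (!nrow(g)) return(list(map = character(), non = character(),
                              excl = character()))
    ok <- g$chrom == chrom
    if (any(!ok)) warning("guide(s) on wrong chromosome for ", gene,
                          ": ", paste(g$guide[!ok], collapse = ", "))
    g <- g[ok, , drop = FALSE]
    before <- g$cut_position <= bp
    after <- g$cut_position >= bp
    mapping <- if (five_prime) {
      if (strand == "+") before else after
    } else {
      if (strand == "+") after else before
    }
    list(map = g$guide[mapping], non = g$guide[!mapping],
         excl = guides$guide[guides$gene == gene][!ok])
  }
  s5 <- side(t$gene5, t$chrom5, t$breakpoint5, t$strand5, TRUE)
  s3 <- side(t$gene3, t$chrom3, t$breakpoint3, t$strand3, FALSE)
  out$mapping5 <- s5$map; out$nonmapping5 <- s5$non
  out$mapping3 <- s3$map; out$nonmapping3 <- s3$non
  out$excluded <- c(s5$excl, s3$excl)
  out
}

#' Z-normalize fold changes per guide across cell lines
#'
#' Each guide row is centered and scaled by its sample standard deviation
#' across the cell lines of one screening dataset. Rows with fewer than two
#' values or zero spread are set to zero.
#'
#' @param scaled Guide x cell line matrix (output of
#'   [scale_to_essentials()], or pre-scaled data).
#' @return Z matrix of the same shape.
#' @export
zscore_per_guide <- function(scaled) {
  m <- rowMeans(scaled)
  s <- row_sds(scaled)
  z <- (scaled - m) / ifelse(s == 0, Inf, s)
  z[s == 0, ] <- 0
  z
}

# Mean Z of a guide index set at one cell line, from precomputed row
# means/sds of the scaled matrix; zero-sd guides contribute z = 0.
.mean_z <- function(scaled, col, idx, rm, rs) {
  if (!length(idx)) return(NA_real_)
  z <- (scaled[idx, col] - rm[idx]) / ifelse(rs[idx] == 0, Inf, rs[idx])
  mean(z)
}

# FES and raw mapping/non-mapping difference for one transcript at its
# carrier cell line. partition holds integer row indices into `scaled`.
.fes_one <- function(scaled, col, partition, rm, rs) {
  diffs <- numeric(0)
  for (g in c("5", "3")) {
    map <- partition[[paste0("mapping", g)]]
    non <- partition[[paste0("nonmapping", g)]]
    if (!length(map)) next
    mz <- .mean_z(scaled, col, map, rm, rs)
    nz <- if (length(non)) .mean_z(scaled, col, non, rm, rs) else 0
    diffs <- c(diffs, mz - nz)
  }
  if (!length(diffs)) return(c(fes = NA_real_, raw_diff = NA_real_))
  all_map <- c(partition$mapping5, partition$mapping3)
  all_non <- c(partition$nonmapping5, partition$nonmapping3)
  raw <- mean(scaled[all_map, col]) -
    if (length(all_non)) mean(scaled[all_non, col]) else 0
  c(fes = mean(diffs), raw_diff = raw)
}

#' Fusion essentiality score for one transcript
#'
#' Per partner gene with at least one mapping guide, the mean Z-score of
#' mapping guides minus that of non-mapping guides (taken as zero when the
#' gene has no non-mapping guide); the FES is the average of the per-gene
#' differences. The raw difference (`raw_diff`) applies the same pooling to
#' the scaled, un-normalized fold changes across both genes and feeds the
#' minimum-difference filter.
#'
#' @param partition Output of [map_guides_to_transcript()].
#' @param scaled Guide x cell line scaled fold-change matrix.
#' @param cell_line Carrier cell line (column name).
#' @return Named numeric vector `c(fes, raw_diff)`; `NA`s when no mapping
#'   guide exists on either gene (untestable transcript).
#' @export
fes_score <- function(partition, scaled, cell_line) {
  idx <- lapply(partition[c("mapping5", "nonmapping5",
                            "mapping3", "nonmapping3")],
                function(g) match(g, rownames(scaled)))
  idx <- lapply(idx, function(i) i[!is.na(i)])
  rm <- rowMeans(scaled)
  rs <- row_sds(scaled)
  .fes_one(scaled, match(cell_line, colnames(scaled)), idx, rm, rs)
}

#' FES significance by within-cell-line randomization
#'
#' Computes the observed FES for every transcript in its carrier cell
#' line, then repeatedly permutes the scaled fold changes independently
#' within every cell line, re-deriving per-guide Z-scores and every
#' transcript's FES on each randomized matrix. The depletion-sided p-value
#' is `(1 + #\{null FES <= observed\}) / (1 + n_perm)`; BH FDR is computed
#' across the transcripts of the dataset, and hits must additionally pass
#' the minimum raw mapping/non-mapping difference (`raw_diff <= -min_diff`).
#'
#' @param transcripts `data.frame` with one row per (transcript, carrier
#'   cell line): columns `gene5, gene3, chrom5, chrom3, breakpoint5,
#'   breakpoint3, strand5, strand3, cell_line`.
#' @param guides Guide library (see [map_guides_to_transcript()]).
#' @param scaled Scaled guide x cell line fold-change matrix for one
#'   screening dataset.
#' @param n_perm Number of randomizations (default 10000).
#' @param min_diff Minimum depletion difference (default 0.45; the filter
#'   keeps `raw_diff <= -min_diff`).
#' @param fdr_max FDR cutoff for the `significant` flag (default 0.05).
#' @param seed Optional integer seed; results are bit-reproducible given it.
#' @param dataset Label recorded in the output (default `"screen"`).
#' @return `data.frame` of class `fes_result`: one row per testable
#'   transcript with `fes, raw_diff, n_mapping, n_nonmapping, p_value,
#'   fdr, passes_min_diff, significant`.
#' @export
fes_significance <- function(transcripts, guides, scaled, n_perm = 10000,
                             min_diff = 0.45, fdr_max = 0.05, seed = NULL,
                             dataset = "screen") {
  stopifnot(n_perm >= 1)
  if (!is.null(seed)) set.seed(seed)
  parts <- lapply(seq_len(nrow(transcripts)), function(i) {
    p <- map_guides_to_transcript(guides, transcripts[i, ])
    lapply(p[c("mapping5", "nonmapping5", "mapping3", "nonmapping3")],
           function(g) {
             j <- match(g, rownames(scaled))
             j[!is.na(j)]
           })
  })
  cols <- match(transcripts$cell_line, colnames(scaled))
  testable <- vapply(parts, function(p) {
    length(p$mapping5) + length(p$mapping3) > 0
  }, logical(1)) & !is.na(cols)

  rm0 <- rowMeans(scaled)
  rs0 <- row_sds(scaled)
  obs <- t(vapply(seq_along(parts), function(i) {
    if (!testable[i]) return(c(fes = NA_real_, raw_diff = NA_real_))
    .fes_one(scaled, cols[i], parts[[i]], rm0, rs0)
  }, c(fes = 0, raw_diff = 0)))

  n_guides <- nrow(scaled)
  exceed <- integer(nrow(transcripts))
  for (b in seq_len(n_perm)) {
    perm <- scaled
    for (j in seq_len(ncol(scaled))) {
      perm[, j] <- scaled[sample.int(n_guides), j]
    }
    rmp <- rowMeans(perm)
    rsp <- row_sds(perm)
    for (i in which(testable)) {
      null_fes <- .fes_one(perm, cols[i], parts[[i]], rmp, rsp)[["fes"]]
      if (null_fes <= obs[i, "fes"]) exceed[i] <- exceed[i] + 1L
    }
  }
  p <- ifelse(testable, empirical_p(exceed, n_perm), NA_real_)
  fdr <- rep(NA_real_, length(p))
  fdr[testable] <- stats::p.adjust(p[testable], "BH")
  passes <- obs[, "raw_diff"] <= -min_diff
  out <- data.frame(
    transcript = paste0(transcripts$gene5, "--", transcripts$gene3, ":",
                        transcripts$breakpoint5, "-", transcripts$breakpoint3),
    gene5 = transcripts$gene5, gene3 = transcripts$gene3,
    cell_line = transcripts$cell_line, dataset = dataset,
    n_mapping = vapply(parts, function(p) length(p$mapping5) + length(p$mapping3),
                       integer(1)),
    n_nonmapping = vapply(parts, function(p) {
      length(p$nonmapping5) + length(p$nonmapping3)
    }, integer(1)),
    fes = obs[, "fes"], raw_diff = obs[, "raw_diff"],
    p_value = p, fdr = fdr,
    passes_min_diff = passes,
    significant = testable & !is.na(fdr) & fdr < fdr_max & passes,
    stringsAsFactors = FALSE)
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  class(out) <- c("fes_result", class(out))
  out
}

#' @export
print.fes_result <- function(x, ...) {
  cat(sprintf("FES results: %d transcripts (%d testable), %d significant\n",
              nrow(x), sum(!is.na(x$fes)), sum(x$significant, na.rm = TRUE)))
  NextMethod()
}

#' Event-level FES significance
#'
#' A fusion event (an ordered gene pair in a cell line) is significant when
#' any of its transcripts is significant in at least one screening dataset
#' for that cell line.
#'
#' @param fes_results One or more `fes_result` tables (a `data.frame` or a
#'   list of them, e.g. one per dataset).
#' @return `data.frame`: `cell_line, gene5, gene3, n_transcripts,
#'   significant`.
#' @export
aggregate_events_fes <- function(fes_results) {
  if (is.data.frame(fes_results)) fes_results <- list(fes_results)
  x <- do.call(rbind, lapply(fes_results, as.data.frame))
  if (!nrow(x)) {
    return(data.frame(cell_line = character(), gene5 = character(),
                      gene3 = character(), n_transcripts = integer(),
                      significant = logical(), stringsAsFactors = FALSE))
  }
  key <- paste(x$cell_line, x$gene5, x$gene3, sep = "\r")
  idx <- split(seq_len(nrow(x)), key)
  out <- do.call(rbind, lapply(idx, function(i) {
    data.frame(cell_line = x$cell_line[i[1]], gene5 = x$gene5[i[1]],
               gene3 = x$gene3[i[1]],
               n_transcripts = length(unique(x$transcript[i])),
               significant = any(x$significant[i], na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
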