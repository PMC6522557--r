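#' @title Consensus fusion catalog
#' @description Functions that read per-caller fusion call tables, merge
#'   calls into breakpoint-level fusion transcripts, apply consensus
#'   filtering (junction-read support, multi-caller support, normal-tissue
#'   blacklist), collapse transcripts into per-cell-line fusion events and
#'   summarize the catalog.
#' @name fusion-catalog
NULL

.call_columns <- c("sample_id", "caller", "gene5", "gene3", "chrom5", "chrom3",
                   "breakpoint5", "breakpoint3", "strand5", "strand3",
                   "junction_reads", "frame")

.frame_levels <- c("in_frame", "out_of_frame", "unknown")

#' Read a table of raw fusion calls
#'
#' Reads a tab-separated table of caller-specific fusion calls, one row per
#' call. Rows failing validation (bad strand, non-positive coordinate,
#' negative junction reads, unknown frame label, identical partner genes)
#' are rejected individually; the valid rows are returned and the rejects
#' are reported, with line numbers, in the `"rejected"` attribute.
#'
#' @param path Path to a tab-separated file with header. Required columns:
#'   `sample_id, caller, gene5, gene3, chrom5, chrom3, breakpoint5,
#'   breakpoint3, strand5, strand3, junction_reads, frame`. Extra columns
#'   are kept. Coordinates are 1-based: `breakpoint5` is the last included
#'   base of the 5' segment, `breakpoint3` the first included base of the
#'   3' segment.
#' @param schema Optional named character vector mapping required column
#'   names to the names actually used in the file, e.g.
#'   `c(sample_id = "Sample")`.
#' @return A `data.frame` of valid calls with attribute `"rejected"`, a
#'   `data.frame` with columns `line` (1-based data row) and `reason`.
#' @export
read_fusion_calls <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(schema)) {
    for (std in names(schema)) {
      i <- match(schema[[std]], names(raw))
      if (is.na(i)) stop("schema column not in file: ", schema[[std]])
      names(raw)[i] <- std
    }
  }
  missing <- setdiff(.call_columns, names(raw))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  validate_fusion_calls(raw)
}

#' Validate raw fusion call rows
#'
#' Row-level validation used by [read_fusion_calls()]; exported so calls
#' assembled in memory can be checked the same way.
#'
#' @param calls `data.frame` with the columns listed in
#'   [read_fusion_calls()].
#' @return Valid rows, with rejected rows in the `"rejected"` attribute.
#' @export
validate_fusion_calls <- function(calls) {
  n <- nrow(calls)
  reasons <- character(n)
  calls$breakpoint5 <- suppressWarnings(as.numeric(calls$breakpoint5))
  calls$breakpoint3 <- suppressWarnings(as.numeric(calls$breakpoint3))
  calls$junction_reads <- suppressWarnings(as.numeric(calls$junction_reads))
  bad <- function(cond, why) {
    cond[is.na(cond)] <- TRUE
    reasons[cond & !nzchar(reasons)] <<- why
  }
  if (n) {
    bad(!(calls$strand5 %in% c("+", "-")) | !(calls$strand3 %in% c("+", "-")),
        "invalid strand")
    bad(is.na(calls$breakpoint5) | is.na(calls$breakpoint3) |
          calls$breakpoint5 < 1 | calls$breakpoint3 < 1,
        "invalid breakpoint coordinate")
    bad(is.na(calls$junction_reads) | calls$junction_reads < 0,
        "negative or unparseable junction_reads")
    bad(!(calls$frame %in% .frame_levels), "unknown frame label")
    bad(calls$gene5 == calls$gene3, "identical partner genes")
  }
  keep <- !nzchar(reasons)
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- data.frame(line = which(!keep),
                                      reason = reasons[!keep],
                                      stringsAsFactors = FALSE)
  out
}

#' Merge caller-specific calls into fusion transcripts
#'
#' Calls from the same sample with the same ordered gene pair and both
#' breakpoints within `breakpoint_tolerance_bp` of a cluster representative
#' are treated as one fusion transcript called by several algorithms.
#' The representative breakpoints are taken from the supporting call with
#' the most junction reads; supporting callers are the union and
#' `max_junction_reads` the maximum over the cluster. The consensus frame
#' is `in_frame` if any supporting call is in frame, else `out_of_frame`
#' if any call says so, else `unknown`.
#'
#' @param calls Validated calls (see [read_fusion_calls()]).
#' @param breakpoint_tolerance_bp Non-negative integer; maximum distance, on
#'   each breakpoint, for two calls to be the same transcript. Default 5.
#' @return `data.frame` of transcripts with columns `sample_id, gene5,
#'   gene3, chrom5, chrom3, breakpoint5, breakpoint3, strand5, strand3,
#'   n_callers, callers, max_junction_reads, frame`.
#' @export
merge_calls <- function(calls, breakpoint_tolerance_bp = 5) {
  stopifnot(breakpoint_tolerance_bp >= 0)
  if (!nrow(calls)) return(.empty_transcripts())
  key <- paste(calls$sample_id, calls$gene5, calls$gene3, sep = "\r")
  groups <- split(seq_len(nrow(calls)), key)
  out <- lapply(groups, function(idx) {
    g <- calls[idx[order(-calls$junction_reads[idx])], , drop = FALSE]
    reps <- integer(0)                 # row indices (within g) of cluster reps
    members <- list()
    for (r in seq_len(nrow(g))) {
      hit <- 0L
      for (ci in seq_along(reps)) {
        p <- reps[ci]
        if (abs(g$breakpoint5[r] - g$breakpoint5[p]) <= breakpoint_tolerance_bp &&
            abs(g$breakpoint3[r] - g$breakpoint3[p]) <= breakpoint_tolerance_bp) {
          hit <- ci
          break
        }
      }
      if (hit) {
        members[[hit]] <- c(members[[hit]], r)
      } else {
        reps <- c(reps, r)
        members[[length(reps)]] <- r
      }
    }
    do.call(rbind, lapply(seq_along(reps), function(ci) {
      m <- g[members[[ci]], , drop = FALSE]
      p <- g[reps[ci], , drop = FALSE]
      frame <- if (any(m$frame == "in_frame")) "in_frame"
               else if (any(m$frame == "out_of_frame")) "out_of_frame"
               else "unknown"
      data.frame(sample_id = p$sample_id, gene5 = p$gene5, gene3 = p$gene3,
                 chrom5 = p$chrom5, chrom3 = p$chrom3,
                 breakpoint5 = p$breakpoint5, breakpoint3 = p$breakpoint3,
                 strand5 = p$strand5, strand3 = p$strand3,
                 n_callers = length(unique(m$caller)),
                 callers = paste(sort(unique(m$caller)), collapse = ","),
                 max_junction_reads = max(m$junction_reads),
                 frame = frame, stringsAsFactors = FALSE)
    }))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.empty_transcripts <- function() {
  data.frame(sample_id = character(), gene5 = character(), gene3 = character(),
             chrom5 = character(), chrom3 = character(),
             breakpoint5 = numeric(), breakpoint3 = numeric(),
             strand5 = character(), strand3 = character(),
             n_callers = integer(), callers = character(),
             max_junction_reads = numeric(), frame = character(),
             stringsAsFactors = FALSE)
}

#' Filter fusion transcripts by consensus criteria
#'
#' Retains transcripts called by at least `min_callers` algorithms, with at
#' least `min_junction_reads` reads aligning directly across the breakpoint
#' in the best-supported call, and whose ordered gene pair is not on the
#' normal-tissue blacklist.
#'
#' @param transcripts Output of [merge_calls()].
#' @param min_junction_reads Minimum junction reads (default 4).
#' @param min_callers Minimum distinct supporting callers (default 2).
#' @param blacklist Optional two-column `data.frame` (`gene5`, `gene3`) of
#'   ordered gene pairs seen in non-neoplastic samples.
#' @return Retained transcripts; removed rows, with a `reason` column, in
#'   the `"removed"` attribute.
#' @export
filter_transcripts <- function(transcripts, min_junction_reads = 4,
                               min_callers = 2, blacklist = NULL) {
  stopifnot(min_junction_reads >= 1, min_callers >= 1)
  reason <- character(nrow(transcripts))
  few_callers <- transcripts$n_callers < min_callers
  few_reads <- transcripts$max_junction_reads < min_junction_reads
  reason[few_reads] <- "below junction-read threshold"
  reason[few_callers] <- "below caller threshold"
  if (!is.null(blacklist) && nrow(blacklist)) {
    bl <- paste(blacklist$gene5, blacklist$gene3, sep = "\r")
    listed <- paste(transcripts$gene5, transcripts$gene3, sep = "\r") %in% bl
    reason[listed] <- "normal-tissue blacklist"
  }
  keep <- !nzchar(reason)
  out <- transcripts[keep, , drop = FALSE]
  rownames(out) <- NULL
  removed <- transcripts[!keep, , drop = FALSE]
  removed$reason <- reason[!keep]
  rownames(removed) <- NULL
  attr(out, "removed") <- removed
  out
}

#' Resolve cell lines sequenced by more than one source
#'
#' When a cell line has RNA-seq (and therefore fusion calls) from several
#' data sources, only transcripts from the highest-precedence source are
#' kept. Adds a `cell_line` and `source` column from the annotation.
#'
#' @param transcripts Transcript table with a `sample_id` column.
#' @param sample_annotation `data.frame` with columns `sample_id`,
#'   `cell_line`, `source`.
#' @param source_precedence Character vector of sources, highest precedence
#'   first. Must be non-empty and cover every source in use.
#' @return Transcripts restricted to the chosen source per cell line.
#' @export
deduplicate_samples <- function(transcripts, sample_annotation,
                                source_precedence) {
  if (length(source_precedence) == 0) stop("source_precedence must be non-empty")
  i <- match(transcripts$sample_id, sample_annotation$sample_id)
  if (anyNA(i)) {
    stop("sample(s) without source annotation: ",
         paste(unique(transcripts$sample_id[is.na(i)]), collapse = ", "))
  }
  transcripts$cell_line <- sample_annotation$cell_line[i]
  transcripts$source <- sample_annotation$source[i]
  rank <- match(transcripts$source, source_precedence)
  if (anyNA(rank)) {
    stop("source(s) missing from precedence list: ",
         paste(unique(transcripts$source[is.na(rank)]), collapse = ", "))
  }
  best <- tapply(rank, transcripts$cell_line, min)
  keep <- rank == best[transcripts$cell_line]
  out <- transcripts[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Collapse fusion transcripts into fusion events
#'
#' The presence of any fusion between an ordered gene pair in a cell line is
#' one fusion event, regardless of how many breakpoint-level transcripts
#' support it.
#'
#' @param transcripts Filtered transcript table. A `cell_line` column is
#'   used if present (after [deduplicate_samples()]), else `sample_id`.
#' @return `data.frame` with columns `cell_line, gene5, gene3,
#'   transcript_count, any_in_frame`.
#' @export
aggregate_events <- function(transcripts) {
  line <- transcripts$cell_line %||% transcripts$sample_id
  if (!nrow(transcripts)) {
    return(data.frame(cell_line = character(), gene5 = character(),
                      gene3 = character(), transcript_count = integer(),
                      any_in_frame = logical(), stringsAsFactors = FALSE))
  }
  key <- paste(line, transcripts$gene5, transcripts$gene3, sep = "\r")
  idx <- split(seq_len(nrow(transcripts)), key)
  out <- do.call(rbind, lapply(idx, function(i) {
    data.frame(cell_line = line[i[1]], gene5 = transcripts$gene5[i[1]],
               gene3 = transcripts$gene3[i[1]],
               transcript_count = length(i),
               any_in_frame = any(transcripts$frame[i] == "in_frame"),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$cell_line, out$gene5, out$gene3), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize a fusion catalog
#'
#' Counts transcripts, events, unique fusions (distinct ordered gene pairs)
#' and recurrent fusions (pairs with events in two or more cell lines),
#' the in-frame event fraction, and per-cancer-type medians of events per
#' cell line (cell lines with zero events included).
#'
#' @param events Output of [aggregate_events()].
#' @param sample_annotation `data.frame` with columns `cell_line` and
#'   `cancer_type` covering every cell line in `events`.
#' @param transcripts Optional transcript table, to report `n_transcripts`.
#' @return Object of class `catalog_summary`.
#' @export
summarize_catalog <- function(events, sample_annotation, transcripts = NULL) {
  ann <- unique(sample_annotation[, c("cell_line", "cancer_type")])
  unknown <- setdiff(events$cell_line, ann$cell_line)
  if (length(unknown)) {
    stop("cell line(s) without cancer-type annotation: ",
         paste(unknown, collapse = ", "))
  }
  pair <- paste(events$gene5, events$gene3, sep = "\r")
  n_events <- nrow(events)
  n_unique <- length(unique(pair))
  rec <- table(pair)
  n_recurrent <- sum(rec >= 2)
  counts <- table(factor(events$cell_line, levels = ann$cell_line))
  per_type <- tapply(as.numeric(counts), ann$cancer_type, stats::median)
  out <- list(
    n_transcripts = if (is.null(transcripts)) NA_integer_ else nrow(transcripts),
    n_events = n_events,
    n_unique_fusions = n_unique,
    n_recurrent_fusions = n_recurrent,
    recurrent_percent = if (n_unique > 0) pct_round(n_recurrent, n_unique) else NA_integer_,
    fraction_in_frame = if (n_events > 0) mean(events$any_in_frame) else NA_real_,
    median_events_per_line = stats::median(as.numeric(counts)),
    events_per_type_median = per_type
  )
  class(out) <- "catalog_summary"
  out
}

#' @export
print.catalog_summary <- function(x, ...) {
  cat("Fusion catalog summary\n")
  if (!is.na(x$n_transcripts)) cat("  transcripts:      ", x$n_transcripts, "\n")
  cat("  fusion events:    ", x$n_events, "\n")
  cat("  unique fusions:   ", x$n_unique_fusions, "\n")
  cat(sprintf("  recurrent fusions: %d (%s%%)\n", x$n_recurrent_fusions,
              ifelse(is.na(x$recurrent_percent), "NA", x$recurrent_percent)))
  if (!is.na(x$fraction_in_frame)) {
    cat(sprintf("  in-frame events:   %.1f%%\n", 100 * x$fraction_in_frame))
  }
  cat("  median events per cell line:", x$median_events_per_line, "\n")
  invisible(x)
}
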