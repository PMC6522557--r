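# Fixture builders shared across test files. Everything is generated in
# code; no data files.

make_call <- function(sample_id = "S1", caller = "defuse", gene5 = "A",
                      gene3 = "B", chrom5 = "chr1", chrom3 = "chr2",
                      breakpoint5 = 1000, breakpoint3 = 5000,
                      strand5 = "+", strand3 = "+", junction_reads = 10,
                      frame = "in_frame") {
  data.frame(sample_id = sample_id, caller = caller, gene5 = gene5,
             gene3 = gene3, chrom5 = chrom5, chrom3 = chrom3,
             breakpoint5 = breakpoint5, breakpoint3 = breakpoint3,
             strand5 = strand5, strand3 = strand3,
             junction_reads = junction_reads, frame = frame,
             stringsAsFactors = FALSE)
}

make_calls <- function(...) do.call(rbind, list(...))

write_calls <- function(calls, path = tempfile(fileext = ".tsv")) {
  write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

make_events <- function(pairs, lines, in_frame = TRUE) {
  data.frame(cell_line = lines,
             gene5 = vapply(strsplit(pairs, "--"), `[`, character(1), 1),
             gene3 = vapply(strsplit(pairs, "--"), `[`, character(1), 2),
             transcript_count = rep(1L, length(lines)),
             any_in_frame = rep_len(in_frame, length(lines)),
             stringsAsFactors = FALSE)
}

# Random binary matrix with at least one 1, for rewiring properties.
random_binary_matrix <- function(nr, nc, p = 0.3) {
  repeat {
    m <- matrix(as.integer(runif(nr * nc) < p), nr, nc)
    if (sum(m) >= 2) return(m)
  }
}

# All binary matrices with the given margins, as collapse-keys (exhaustive
# oracle for rewiring uniformity).
enumerate_margin_matrices <- function(row_sums, col_sums) {
  nr <- length(row_sums); nc <- length(col_sums)
  out <- character(0)
  for (bits in 0:(2^(nr * nc) - 1)) {
    m <- matrix(bitwAnd(bits %/% 2^(seq_len(nr * nc) - 1), 1), nr, nc)
    if (all(rowSums(m) == row_sums) && all(colSums(m) == col_sums)) {
      out <- c(out, paste(m, collapse = ""))
    }
  }
  out
}

# Independently coded nested-model F-test for a single added term: the
# oracle for the type-II ANOVA p-values.
nested_f_pvalue <- function(y, term, covariates = NULL) {
  dat <- data.frame(.y = y, .t = term)
  if (!is.null(covariates)) dat <- cbind(dat, covariates)
  full <- lm(.y ~ ., data = dat)
  red <- lm(.y ~ ., data = dat[, setdiff(names(dat), ".t"), drop = FALSE])
  rss1 <- sum(residuals(full)^2)
  rss0 <- sum(residuals(red)^2)
  df1 <- full$df.residual
  q <- red$df.residual - df1
  f <- ((rss0 - rss1) / q) / (rss1 / df1)
  pf(f, q, df1, lower.tail = FALSE)
}

# Step-by-step running-sum walk (enumeration oracle for the enrichment
# score): explicit loop, no shared code with the implementation.
brute_force_es <- function(scores, item_set, weight = 1) {
  ord <- order(-scores, names(scores), method = "radix")
  s <- scores[ord]
  hit <- names(s) %in% item_set
  denom_hit <- sum(abs(s[hit])^weight)
  best <- 0; cur <- 0
  for (i in seq_along(s)) {
    if (hit[i]) {
      cur <- cur + if (denom_hit > 0) abs(s[[i]])^weight / denom_hit else 1 / sum(hit)
    } else {
      cur <- cur - 1 / (length(s) - sum(hit))
    }
    if (abs(cur) > abs(best) + 1e-9) best <- cur
  }
  unname(best)
}

# Small CRISPR screen with an optional planted fusion: genes laid on one
# chromosome, k guides per gene, fold changes N(0, noise_sd); mapping
# guides of `planted` transcripts shifted in their carrier line.
make_screen <- function(n_lines, n_genes, guides_per_gene = 5,
                        noise_sd = 0.25, transcripts = NULL,
                        planted = integer(0), shift = -1) {
  genes <- sprintf("g%03d", seq_len(n_genes))
  glen <- 1000
  guides <- do.call(rbind, lapply(seq_along(genes), function(i) {
    start <- (i - 1) * 2000 + 1
    pos <- round(seq(start, start + glen, length.out = guides_per_gene + 2))
    data.frame(guide = sprintf("%s_sg%d", genes[i], seq_len(guides_per_gene)),
               gene = genes[i], chrom = "chr1",
               cut_position = pos[2:(guides_per_gene + 1)],
               gene_strand = "+", stringsAsFactors = FALSE)
  }))
  lines <- sprintf("L%02d", seq_len(n_lines))
  fc <- matrix(rnorm(nrow(guides) * n_lines, 0, noise_sd), nrow(guides),
               n_lines, dimnames = list(guides$guide, lines))
  if (!is.null(transcripts)) {
    for (i in planted) {
      part <- map_guides_to_transcript(guides, transcripts[i, ])
      ids <- c(part$mapping5, part$mapping3)
      fc[ids, transcripts$cell_line[i]] <- fc[ids, transcripts$cell_line[i]] + shift
    }
  }
  list(guides = guides, fold_changes = fc, lines = lines, genes = genes)
}

# Transcripts over a make_screen() gene layout; breakpoints mid-gene so
# both mapping and non-mapping guides exist.
make_screen_transcripts <- function(screen, pairs, lines) {
  g <- screen$guides
  one <- function(gene) {
    i <- which(g$gene == gene)
    c(chrom = g$chrom[i[1]],
      bp = round(mean(range(g$cut_position[i]))), strand = g$gene_strand[i[1]])
  }
  do.call(rbind, lapply(seq_along(lines), function(k) {
    p <- strsplit(pairs[k], "--")[[1]]
    a <- one(p[1]); b <- one(p[2])
    data.frame(gene5 = p[1], gene3 = p[2], chrom5 = a[["chrom"]],
               chrom3 = b[["chrom"]],
               breakpoint5 = as.numeric(a[["bp"]]),
               breakpoint3 = as.numeric(b[["bp"]]),
               strand5 = a[["strand"]], strand3 = b[["strand"]],
               cell_line = lines[k], stringsAsFactors = FALSE)
  }))
}
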