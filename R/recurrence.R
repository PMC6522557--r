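#' @title Fusion recurrence permutation test
#' @description A gene is recurrently fused in a cancer type if it is fused
#'   in more cell lines of that type than expected under a null in which
#'   fusion burden is held fixed per gene and per sample but assignment is
#'   otherwise random. The null is generated by degree-preserving rewiring
#'   (checkerboard switches) of the binary gene x sample occurrence matrix.
#' @name recurrence
NULL

#' Build the binary gene x sample fusion occurrence matrix
#'
#' Entry (G, S) is 1 if sample S carries at least one fusion event with G as
#' 5' or 3' partner, else 0 (binary, not a count).
#'
#' @param events Event table from [aggregate_events()].
#' @param genes Optional gene universe (rows); defaults to genes observed in
#'   `events`. Every event gene must be included.
#' @param samples Optional sample universe (columns); defaults to cell lines
#'   observed in `events`.
#' @return Integer 0/1 matrix with gene rownames and sample colnames.
#' @export
build_occurrence_matrix <- function(events, genes = NULL, samples = NULL) {
  seen <- unique(c(events$gene5, events$gene3))
  genes <- genes %||% sort(seen)
  if (length(setdiff(seen, genes))) {
    stop("event gene(s) missing from gene universe")
  }
  samples <- samples %||% sort(unique(events$cell_line))
  m <- matrix(0L, length(genes), length(samples),
              dimnames = list(genes, samples))
  if (nrow(events)) {
    for (end in c("gene5", "gene3")) {
      m[cbind(match(events[[end]], genes),
              match(events$cell_line, samples))] <- 1L
    }
  }
  m
}

#' Randomize a binary matrix preserving row and column sums
#'
#' Runs a checkerboard-switch Markov chain: each step proposes two 1-cells
#' (g1, s1), (g2, s2) uniformly at random; if g1 != g2, s1 != s2 and the
#' complementary cells (g1, s2), (g2, s1) are 0, the 2x2 checkerboard is
#' swapped, otherwise the state is unchanged. Counting proposals (rather
#' than accepted swaps) as steps makes the chain's stationary distribution
#' exactly uniform over all margin-compatible binary matrices, since the
#' proposal is symmetric and constant across states.
#'
#' @param matrix Binary 0/1 matrix.
#' @param n_switches Number of proposal steps. Defaults to 10 times the
#'   number of 1-entries, a mixing heuristic.
#' @param seed Optional integer seed.
#' @return Rewired matrix with identical row and column sums. Attributes:
#'   `n_accepted` (successful swaps) and `degenerate` (`TRUE` when no swap
#'   was ever possible, e.g. an all-ones matrix, in which case a warning is
#'   raised and the input is returned unchanged).
#' @export
rewire <- function(matrix, n_switches = NULL, seed = NULL) {
  stopifnot(all(matrix %in% c(0L, 1L)))
  if (!is.null(seed)) set.seed(seed)
  ones <- which(matrix == 1L)
  k <- length(ones)
  n_switches <- n_switches %||% (10L * k)
  nr <- nrow(matrix)
  ri <- (ones - 1L) %% nr + 1L
  ci <- (ones - 1L) %/% nr + 1L
  accepted <- 0L
  if (k >= 2L && n_switches > 0L) {
    a <- sample.int(k, n_switches, replace = TRUE)
    b <- sample.int(k - 1L, n_switches, replace = TRUE)
    b <- b + (b >= a)                   # uniform over distinct pairs
    for (s in seq_len(n_switches)) {
      i <- a[s]; j <- b[s]
      r1 <- ri[i]; c1 <- ci[i]; r2 <- ri[j]; c2 <- ci[j]
      if (r1 == r2 || c1 == c2) next
      if (matrix[r1, c2] != 0L || matrix[r2, c1] != 0L) next
      matrix[r1, c1] <- 0L; matrix[r2, c2] <- 0L
      matrix[r1, c2] <- 1L; matrix[r2, c1] <- 1L
      ci[i] <- c2; ci[j] <- c1
      accepted <- accepted + 1L
    }
  }
  degenerate <- k >= 2L && n_switches > 0L && accepted == 0L &&
    !any_valid_switch(matrix)
  if (degenerate) warning("matrix admits no checkerboard switch; returned unchanged")
  structure(matrix, n_accepted = accepted, degenerate = degenerate)
}

# Exhaustive check used only to distinguish "unlucky chain" from "no switch
# exists" when zero proposals were accepted; matrices there are tiny.
any_valid_switch <- function(m) {
  ones <- which(m == 1L, arr.ind = TRUE)
  k <- nrow(ones)
  if (k < 2L) return(FALSE)
  for (x in seq_len(k - 1L)) {
    for (y in seq(x + 1L, k)) {
      if (ones[x, 1L] != ones[y, 1L] && ones[x, 2L] != ones[y, 2L] &&
          m[ones[x, 1L], ones[y, 2L]] == 0L && m[ones[y, 1L], ones[x, 2L]] == 0L) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Null distribution of per-type fused-sample counts
#'
#' For each of `n_perm` independent rewirings of the occurrence matrix
#' (each a fresh chain of `n_switches` steps from the observed matrix),
#' records, for every gene and cancer type, how many samples of that type
#' have the gene fused.
#'
#' @param matrix Occurrence matrix from [build_occurrence_matrix()].
#' @param cancer_type Character vector of cancer-type labels, one per
#'   column of `matrix`.
#' @param n_perm Number of permutations (default 10000).
#' @param n_switches Chain length per permutation; see [rewire()].
#' @param seed Optional integer seed; results are reproducible given it.
#' @return List with `null` (array gene x type x permutation of counts),
#'   `observed` (gene x type matrix), `n_perm`, `seed`.
#' @export
permutation_null <- function(matrix, cancer_type, n_perm = 10000,
                             n_switches = NULL, seed = NULL) {
  stopifnot(n_perm >= 1, length(cancer_type) == ncol(matrix))
  if (!is.null(seed)) set.seed(seed)
  types <- sort(unique(cancer_type))
  ind <- outer(cancer_type, types, "==") + 0   # samples x types
  observed <- matrix %*% ind
  dimnames(observed) <- list(rownames(matrix), types)
  null <- array(0L, dim = c(nrow(matrix), length(types), n_perm),
                dimnames = list(rownames(matrix), types, NULL))
  for (p in seq_len(n_perm)) {
    null[, , p] <- rewire(matrix, n_switches = n_switches) %*% ind
  }
  list(null = null, observed = observed, n_perm = n_perm, seed = seed)
}

#' Empirical p-values for per-type fusion recurrence
#'
#' For every (gene, cancer type) pair with at least one observed fused
#' sample, p is the plus-one-smoothed fraction of permutations whose null
#' count reaches the observed count:
#' `p = (1 + #\{null >= N\}) / (1 + n_perm)`. Benjamini-Hochberg FDR is
#' computed over all tested pairs.
#'
#' @param null_table Output of [permutation_null()].
#' @return `data.frame` with columns `gene, cancer_type, observed_n,
#'   p_value, fdr`, sorted by p.
#' @export
empirical_pvalues <- function(null_table) {
  obs <- null_table$observed
  tested <- which(obs >= 1, arr.ind = TRUE)
  if (!nrow(tested)) {
    return(data.frame(gene = character(), cancer_type = character(),
                      observed_n = integer(), p_value = numeric(),
                      fdr = numeric(), stringsAsFactors = FALSE))
  }
  n_perm <- null_table$n_perm
  p <- vapply(seq_len(nrow(tested)), function(i) {
    g <- tested[i, 1]; t <- tested[i, 2]
    empirical_p(sum(null_table$null[g, t, ] >= obs[g, t]), n_perm)
  }, numeric(1))
  out <- data.frame(gene = rownames(obs)[tested[, 1]],
                    cancer_type = colnames(obs)[tested[, 2]],
                    observed_n = obs[tested],
                    p_value = p,
                    fdr = stats::p.adjust(p, "BH"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fusion recurrence test, end to end
#'
#' Convenience wrapper: builds the occurrence matrix from events, generates
#' the rewiring null and returns empirical per-(gene, cancer type)
#' recurrence p-values with BH FDR.
#'
#' @inheritParams build_occurrence_matrix
#' @param sample_annotation `data.frame` with `cell_line` and `cancer_type`.
#' @inheritParams permutation_null
#' @return See [empirical_pvalues()].
#' @export
fusion_recurrence <- function(events, sample_annotation, n_perm = 10000,
                              n_switches = NULL, seed = NULL) {
  m <- build_occurrence_matrix(events)
  ann <- unique(sample_annotation[, c("cell_line", "cancer_type")])
  type <- ann$cancer_type[match(colnames(m), ann$cell_line)]
  if (anyNA(type)) stop("cell line(s) without cancer-type annotation")
  nt <- permutation_null(m, type, n_perm = n_perm, n_switches = n_switches,
                         seed = seed)
  empirical_pvalues(nt)
}
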