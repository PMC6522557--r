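#' @title Pre-ranked running-sum set enrichment
#' @description Tests whether a set of items (e.g. known oncogenic fusion
#'   transcripts) concentrates at one end of a ranked list (e.g. transcripts
#'   ranked by FES). The statistic is the classic weighted running sum: the
#'   walk goes up by a (score-weighted) increment at set members and down by
#'   a constant at non-members; the enrichment score is the signed maximum
#'   deviation from zero. Significance is from random sets of the same size.
#' @name set-enrichment
NULL

# Deterministic ranking: decreasing score, ties broken by item id.
.rank_items <- function(scores) {
  stopifnot(!is.null(names(scores)), !anyDuplicated(names(scores)))
  scores[order(-scores, names(scores), method = "radix")]
}

#' Weighted running-sum enrichment score
#'
#' Items are sorted by decreasing score (ties broken by id). The running
#' sum increments by `|score|^weight_exponent / sum(|set scores|^weight_exponent)`
#' at set members and decrements by `1 / (n_total - n_set)` elsewhere; the
#' enrichment score (ES) is the running-sum value of largest magnitude.
#'
#' @param scores Named numeric vector of ranking scores (unique names).
#' @param item_set Character vector of item ids; its intersection with
#'   `scores` must be non-empty and must not cover all items.
#' @param weight_exponent Non-negative weighting exponent; 0 gives the
#'   unweighted (Kolmogorov-Smirnov-like) form. Default 1.
#' @return ES in `[-1, 1]`, with attributes `n_set` and `n_total`.
#' @export
enrichment_score <- function(scores, item_set, weight_exponent = 1) {
  ranked <- .rank_items(scores)
  hit <- names(ranked) %in% item_set
  n <- length(ranked)
  m <- sum(hit)
  if (m == 0) stop("item_set does not intersect the ranked list")
  if (m == n) stop("item_set covers the whole ranked list")
  w <- abs(ranked)^weight_exponent
  wh <- sum(w[hit])
  inc <- if (wh > 0) w * hit / wh else hit / m
  dec <- (!hit) / (n - m)
  walk <- cumsum(inc - dec)
  # earliest step attaining the maximum |deviation| (within numerical
  # tolerance, so exactly symmetric +/- extremes resolve deterministically)
  dev <- abs(walk)
  es <- walk[which(dev >= max(dev) - 1e-9)[1]]
  structure(es, n_set = m, n_total = n)
}

#' Permutation p-value for a running-sum enrichment score
#'
#' Null enrichment scores come from random item sets of the same size
#' drawn without replacement from the ranked list; the one-sided,
#' sign-matched p-value is
#' `(1 + #\{|null| >= |observed| and sign matches\}) / (1 + n_perm)`.
#'
#' @inheritParams enrichment_score
#' @param n_perm Number of random sets (default 1000).
#' @param seed Optional integer seed.
#' @return List of class `enrichment_result`: `es, p_value, n_set,
#'   n_total, n_perm, weight_exponent`.
#' @export
enrichment_pvalue <- function(scores, item_set, n_perm = 1000,
                              weight_exponent = 1, seed = NULL) {
  stopifnot(n_perm >= 1)
  if (!is.null(seed)) set.seed(seed)
  es <- enrichment_score(scores, item_set, weight_exponent)
  m <- attr(es, "n_set")
  ids <- names(scores)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    null_es <- enrichment_score(scores, sample(ids, m), weight_exponent)
    if (sign(null_es) == sign(es) && abs(null_es) >= abs(es)) hits <- hits + 1L
  }
  out <- list(es = as.numeric(es), p_value = empirical_p(hits, n_perm),
              n_set = m, n_total = attr(es, "n_total"), n_perm = n_perm,
              weight_exponent = weight_exponent)
  class(out) <- "enrichment_result"
  out
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("running-sum enrichment: ES = %.3f (set %d of %d), p = %.4g (%d permutations)\n",
              x$es, x$n_set, x$n_total, x$p_value, x$n_perm))
  invisible(x)
}

#' Read gene sets in GMT format
#'
#' Uses [fgsea::gmtPathways()] when fgsea is installed; otherwise falls
#' back to a minimal reader of the same tab-separated layout
#' (set name, description, members...).
#'
#' @param path Path to a `.gmt` file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (requireNamespace("fgsea", quietly = TRUE)) {
    return(fgsea::gmtPathways(path))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(strsplit(lines, "\t"), function(x) x[-(1:2)])
  names(out) <- vapply(strsplit(lines, "\t"), `[`, character(1), 1)
  out
}
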