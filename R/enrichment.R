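#' Enrichment test configuration
#'
#' @param test Over-representation test: `"hypergeometric"` (default),
#'   `"fisher"` (one-sided exact, identical to hypergeometric), `"binomial"`,
#'   or `"chisq"` (Pearson, no continuity correction).
#' @param min_set_size Terms with fewer annotated genes (counted within the
#'   background) are skipped; default 5.
#' @param padj_method Multiple-testing correction: `"BH"` (default),
#'   `"bonferroni"`, or `"none"`.
#' @param background Optional explicit background gene universe; by default
#'   the union of all genes across the collection's terms.
#' @return An object of class `EnrichConfig`.
#' @export
enrich_config <- function(test = c("hypergeometric", "fisher", "binomial", "chisq"),
                          min_set_size = 5,
                          padj_method = c("BH", "bonferroni", "none"),
                          background = NULL) {
  test <- match.arg(test)
  padj_method <- match.arg(padj_method)
  if (min_set_size < 1) stopf("min_set_size must be >= 1")
  structure(list(test = test, min_set_size = as.integer(min_set_size),
                 padj_method = padj_method, background = background),
            class = "EnrichConfig")
}

# validate the (k, n, K, N) overlap counts behind every test
validate_counts <- function(k, n, K, N) {
  vals <- c(k = k, n = n, K = K, N = N)
  if (anyNA(vals) || any(vals < 0) || any(vals != floor(vals))) {
    stopf("counts must be non-negative integers (got k=%s n=%s K=%s N=%s)",
          k, n, K, N)
  }
  if (k > min(n, K) || n > N || K > N) {
    stopf("invalid contingency counts: need k <= min(n, K), n <= N, K <= N (got k=%s n=%s K=%s N=%s)",
          k, n, K, N)
  }
  invisible(TRUE)
}

#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability P(X >= k) where X ~ Hypergeometric(N, K, n): the
#' chance of drawing at least `k` term genes when sampling `n` genes without
#' replacement from a background of `N` genes of which `K` belong to the term.
#'
#' @param k Overlap size (query genes in the term).
#' @param n Effective query size.
#' @param K Term size within the background.
#' @param N Background size.
#' @return p-value in (0, 1].
#' @export
hypergeom_pvalue <- function(k, n, K, N) {
  validate_counts(k, n, K, N)
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' One-sided Fisher exact test on the 2x2 overlap table
#'
#' Tests the table `(k, n-k; K-k, N-K-n+k)` with alternative "greater";
#' mathematically identical to [hypergeom_pvalue()].
#'
#' @inheritParams hypergeom_pvalue
#' @return p-value in (0, 1].
#' @export
fisher_pvalue <- function(k, n, K, N) {
  validate_counts(k, n, K, N)
  tab <- matrix(c(k, K - k, n - k, N - K - n + k), nrow = 2)
  if (any(tab < 0)) stopf("derived 2x2 cell is negative")
  stats::fisher.test(tab, alternative = "greater")$p.value
}

#' Binomial over-representation p-value
#'
#' Upper-tail P(X >= k) for X ~ Binomial(n, K/N): the sampling-with-
#' replacement approximation to the hypergeometric test.
#'
#' @inheritParams hypergeom_pvalue
#' @return p-value in (0, 1].
#' @export
binomial_pvalue <- function(k, n, K, N) {
  validate_counts(k, n, K, N)
  if (N == 0) stopf("background size N must be positive")
  if (k == 0) return(1)
  stats::pbinom(k - 1, n, K / N, lower.tail = FALSE)
}

#' Pearson chi-square p-value on the 2x2 overlap table
#'
#' Classical Pearson statistic without continuity correction, df = 1,
#' upper-tail p. All four expected cell counts must be positive; otherwise an
#' exact test is advised.
#'
#' @inheritParams hypergeom_pvalue
#' @return p-value in [0, 1].
#' @export
chisq_pvalue <- function(k, n, K, N) {
  validate_counts(k, n, K, N)
  tab <- matrix(c(k, K - k, n - k, N - K - n + k), nrow = 2)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected <= 0)) {
    stopf("a zero expected cell makes the chi-square test undefined; use an exact test (hypergeometric/fisher)")
  }
  suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
}

#' Adjust p-values for multiple testing
#'
#' `"BH"` is the Benjamini-Hochberg step-up procedure; `"bonferroni"` is
#' `min(1, p * m)`; `"none"` returns the input.
#'
#' @param pvals Numeric vector of p-values in [0, 1].
#' @param method `"BH"`, `"bonferroni"`, or `"none"`.
#' @return Adjusted p-values in input order.
#' @export
adjust_pvalues <- function(pvals, method = c("BH", "bonferroni", "none")) {
  method <- match.arg(method)
  if (anyNA(pvals) || any(pvals < 0) || any(pvals > 1)) {
    stopf("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = c(BH = "BH", bonferroni = "bonferroni",
                                    none = "none")[[method]])
}

#' Test the pooled coding genes for term over-representation
#'
#' The background B is `cfg$background` if given, else the union of all genes
#' across the collection's terms. The effective query is Q = pool genes
#' present in B (genes outside the background are dropped from `n` and
#' logged). Terms with fewer than `cfg$min_set_size` genes inside B are
#' skipped; rows are produced only for terms with at least one overlapping
#' query gene, and the multiple-testing family is exactly that set of
#' reported terms. Each row records the overlap counts, the overlapping
#' genes, and the contributing ncRNAs (those whose neighbor set meets the
#' overlap).
#'
#' @param nm A `NeighborMap` (its `union_pool` is the query).
#' @param collection A `GeneSetCollection`.
#' @param cfg An [enrich_config()].
#' @return data.frame with columns `term_id`, `term_name`, `p_value`,
#'   `p_adjusted`, `k`, `n`, `K`, `N`, `overlap_genes`,
#'   `contributing_ncrnas` (the last two semicolon-joined, sorted), one row
#'   per reported term, in collection order.
#' @export
enrich <- function(nm, collection, cfg = enrich_config()) {
  stopifnot(inherits(nm, "NeighborMap"), inherits(collection, "GeneSetCollection"),
            inherits(cfg, "EnrichConfig"))
  if (!length(nm$union_pool)) stopf("the pooled coding gene set is empty")
  if (!length(collection$terms)) stopf("the gene-set collection is empty")
  B <- if (!is.null(cfg$background)) unique(as.character(cfg$background))
       else unique(unlist(collection$terms, use.names = FALSE))
  Q <- intersect(nm$union_pool, B)
  dropped <- length(nm$union_pool) - length(Q)
  if (!length(Q)) {
    stopf("none of the %d pooled genes occur in the background of %d genes; check that gene identifiers match the collection",
          length(nm$union_pool), length(B))
  }
  if (dropped) {
    ce_log("INFO", dropped, " pooled gene(s) absent from the background were dropped from the query")
  }
  n <- length(Q)
  N <- length(B)
  pfun <- switch(cfg$test,
    hypergeometric = hypergeom_pvalue,
    fisher = fisher_pvalue,
    binomial = binomial_pvalue,
    chisq = chisq_pvalue)
  real <- names(nm$per_ncrna)[!startsWith(names(nm$per_ncrna), ".")]

  skipped_small <- 0L
  rows <- list()
  for (tid in names(collection$terms)) {
    tg <- intersect(collection$terms[[tid]], B)
    K <- length(tg)
    if (K < cfg$min_set_size) { skipped_small <- skipped_small + 1L; next }
    ov <- intersect(Q, tg)
    k <- length(ov)
    if (k == 0L) next
    contrib <- real[vapply(nm$per_ncrna[real],
                           function(ci) length(intersect(ci, ov)) > 0L,
                           logical(1))]
    rows[[tid]] <- data.frame(
      term_id = tid,
      term_name = unname(collection$term_names[[tid]]),
      p_value = pfun(k, n, K, N),
      k = k, n = n, K = K, N = N,
      overlap_genes = paste(sort_c(ov), collapse = ";"),
      contributing_ncrnas = paste(sort_c(contrib), collapse = ";"),
      stringsAsFactors = FALSE)
  }
  if (skipped_small) {
    ce_log("DEBUG", skipped_small, " term(s) below min_set_size ",
           cfg$min_set_size, " were skipped")
  }
  if (!length(rows)) {
    warning("no term overlaps the query; returning zero rows", call. = FALSE)
    return(data.frame(term_id = character(), term_name = character(),
                      p_value = numeric(), p_adjusted = numeric(),
                      k = integer(), n = integer(), K = integer(), N = integer(),
                      overlap_genes = character(),
                      contributing_ncrnas = character()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  ce_log("DEBUG", "multiple-testing family size: ", nrow(out))
  out$p_adjusted <- adjust_pvalues(out$p_value, cfg$padj_method)
  out[, c("term_id", "term_name", "p_value", "p_adjusted", "k", "n", "K", "N",
          "overlap_genes", "contributing_ncrnas")]
}
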