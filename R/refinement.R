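#' Co-expression configuration
#'
#' Defaults follow the package's standard analysis settings: correlation
#' coefficient cutoff 0.3, significance p-value 0.05, confidence level 0.95,
#' and expression-variance pre-filter 0.0025. The optional low-expression /
#' log2 / MAD fields reproduce a common RNA-seq preprocessing preset (drop
#' genes below an expression floor in too many samples, log2(x+1) transform,
#' keep high-MAD genes).
#'
#' @param method Correlation measure: `"pearson"`, `"spearman"`, `"kendall"`.
#' @param variance_cutoff Genes with sample variance below this are dropped
#'   before correlation (default 0.0025).
#' @param coefficient_cutoff Minimum correlation magnitude to retain an edge
#'   (default 0.3), interpreted under `coefficient_rule`.
#' @param coefficient_rule `"absolute"` (|r| >= cutoff), `"positive"`
#'   (r >= cutoff) or `"negative"` (r <= -cutoff).
#' @param p_cutoff Maximum two-sided p-value to retain an edge (default 0.05).
#' @param confidence_level Confidence level for the Pearson Fisher-z interval
#'   (default 0.95; reporting only — retention is gated by the p-value).
#' @param low_expr_value,low_expr_fraction If both set, drop genes whose raw
#'   value is `< low_expr_value` in more than `low_expr_fraction` of samples.
#' @param log2_transform Apply `log2(x + 1)` after the low-expression filter.
#' @param mad_cutoff If set, drop genes with median absolute deviation
#'   `<= mad_cutoff` (applied last).
#' @return An object of class `CoexpressionConfig`.
#' @export
coexpression_config <- function(method = c("pearson", "spearman", "kendall"),
                                variance_cutoff = 0.0025,
                                coefficient_cutoff = 0.3,
                                coefficient_rule = c("absolute", "positive", "negative"),
                                p_cutoff = 0.05,
                                confidence_level = 0.95,
                                low_expr_value = NULL,
                                low_expr_fraction = NULL,
                                log2_transform = FALSE,
                                mad_cutoff = NULL) {
  method <- match.arg(method)
  coefficient_rule <- match.arg(coefficient_rule)
  if (variance_cutoff < 0) stopf("variance_cutoff must be >= 0")
  if (p_cutoff < 0 || p_cutoff > 1) stopf("p_cutoff must be in [0, 1]")
  if (confidence_level <= 0 || confidence_level >= 1) {
    stopf("confidence_level must be in (0, 1)")
  }
  if (xor(is.null(low_expr_value), is.null(low_expr_fraction))) {
    stopf("low_expr_value and low_expr_fraction must be set together")
  }
  structure(list(method = method,
                 variance_cutoff = variance_cutoff,
                 coefficient_cutoff = coefficient_cutoff,
                 coefficient_rule = coefficient_rule,
                 p_cutoff = p_cutoff,
                 confidence_level = confidence_level,
                 low_expr_value = low_expr_value,
                 low_expr_fraction = low_expr_fraction,
                 log2_transform = isTRUE(log2_transform),
                 mad_cutoff = mad_cutoff),
            class = "CoexpressionConfig")
}

#' Pre-filter an expression matrix before correlation analysis
#'
#' Steps are applied in a fixed order: (1) low-expression filter (if
#' configured), (2) log2(x+1) transform (if configured), (3) variance filter,
#' (4) MAD filter (if configured).
#'
#' @param mat Numeric genes-by-samples matrix (rownames = gene ids).
#' @param cfg A [coexpression_config()].
#' @return The filtered (and possibly transformed) matrix.
#' @export
prefilter_expression <- function(mat, cfg = coexpression_config()) {
  stopifnot(is.matrix(mat), is.numeric(mat), !is.null(rownames(mat)))
  if (!nrow(mat)) stopf("expression matrix is empty")
  n0 <- nrow(mat)
  if (!is.null(cfg$low_expr_value)) {
    frac_low <- rowMeans(mat < cfg$low_expr_value)
    mat <- mat[frac_low <= cfg$low_expr_fraction, , drop = FALSE]
  }
  if (cfg$log2_transform) mat <- log2(mat + 1)
  if (nrow(mat)) {
    v <- apply(mat, 1L, stats::var)
    mat <- mat[v >= cfg$variance_cutoff, , drop = FALSE]
  }
  if (!is.null(cfg$mad_cutoff) && nrow(mat)) {
    m <- apply(mat, 1L, stats::mad)
    mat <- mat[m > cfg$mad_cutoff, , drop = FALSE]
  }
  if (!nrow(mat)) {
    stopf("expression pre-filtering removed all %d genes; relax the cutoffs", n0)
  }
  ce_log("DEBUG", "expression pre-filter kept ", nrow(mat), " of ", n0, " genes")
  mat
}

#' Compute filtered co-expression edges between two gene sets
#'
#' One edge per (left, right) pair. Coefficients and two-sided p-values:
#' Pearson and Spearman use the t statistic with n-2 degrees of freedom (on
#' raw values and rank correlations, respectively); Kendall uses the normal
#' approximation of tau-b. Pearson edges also carry the Fisher-z confidence
#' interval at `cfg$confidence_level`. Only edges passing both the
#' coefficient rule/cutoff and the p-value cutoff are returned.
#'
#' @param mat Numeric genes-by-samples matrix (typically pre-filtered with
#'   [prefilter_expression()]).
#' @param left_ids,right_ids Gene ids present in `mat` (left is typically the
#'   ncRNAs, right the coding candidates).
#' @param cfg A [coexpression_config()].
#' @return data.frame with columns `gene_a`, `gene_b`, `coefficient`,
#'   `p_value`, `ci_low`, `ci_high`, `n_samples`; one row per retained edge.
#' @export
compute_coexpression <- function(mat, left_ids, right_ids,
                                 cfg = coexpression_config()) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)))
  left_ids <- intersect(unique(left_ids), rownames(mat))
  right_ids <- intersect(unique(right_ids), rownames(mat))
  n <- ncol(mat)
  if (n < 3L) stopf("correlation requires >= 3 samples, got %d", n)
  empty <- data.frame(gene_a = character(), gene_b = character(),
                      coefficient = numeric(), p_value = numeric(),
                      ci_low = numeric(), ci_high = numeric(),
                      n_samples = integer())
  if (!length(left_ids) || !length(right_ids)) return(empty)

  rows <- vector("list", length(left_ids) * length(right_ids))
  idx <- 0L
  for (a in left_ids) {
    xa <- mat[a, ]
    for (b in right_ids) {
      if (a == b) next
      ct <- tryCatch(
        stats::cor.test(xa, mat[b, ], method = cfg$method, exact = FALSE,
                        conf.level = cfg$confidence_level),
        error = function(e) NULL)
      if (is.null(ct) || is.na(ct$estimate)) next
      r <- unname(ct$estimate)
      p <- ct$p.value
      keep <- switch(cfg$coefficient_rule,
        absolute = abs(r) >= cfg$coefficient_cutoff,
        positive = r >= cfg$coefficient_cutoff,
        negative = r <= -abs(cfg$coefficient_cutoff))
      if (!keep || is.na(p) || p > cfg$p_cutoff) next
      ci <- if (!is.null(ct$conf.int)) ct$conf.int else c(NA_real_, NA_real_)
      idx <- idx + 1L
      rows[[idx]] <- data.frame(gene_a = a, gene_b = b, coefficient = r,
                                p_value = p, ci_low = ci[1], ci_high = ci[2],
                                n_samples = n)
    }
  }
  if (!idx) return(empty)
  do.call(rbind, rows[seq_len(idx)])
}

#' Filter or expand a neighbor map by co-expression evidence
#'
#' In `"filter"` mode each C_i is intersected with the coding genes that have
#' a retained edge to r_i. In `"expand"` mode the per-ncRNA sets are left
#' unchanged and every coding gene with a retained edge to any r_i is added
#' to the pool; the added genes are recorded in the `".coexpression"`
#' pseudo-entry so the union invariant (pool = union of the per-ncRNA sets)
#' remains exact.
#'
#' @param nm A `NeighborMap`.
#' @param edges Edge table from [compute_coexpression()] with `gene_a` =
#'   ncRNA ids and `gene_b` = coding gene ids.
#' @param mode `"filter"` or `"expand"`.
#' @return A `NeighborMap`.
#' @export
apply_coexpression <- function(nm, edges, mode = c("filter", "expand")) {
  mode <- match.arg(mode)
  stopifnot(inherits(nm, "NeighborMap"))
  per <- nm$per_ncrna
  real <- names(per)[!startsWith(names(per), ".")]
  partners <- split(edges$gene_b, edges$gene_a)
  if (mode == "filter") {
    for (id in real) per[[id]] <- intersect(per[[id]], partners[[id]] %||% character())
  } else {
    gained <- unique(unlist(partners[intersect(names(partners), real)],
                            use.names = FALSE))
    if (length(gained)) per[[".coexpression"]] <- gained
  }
  neighbor_map(per, params = nm$params)
}

#' Restrict neighbor sets to TAD co-membership
#'
#' Every gene is assigned to each TAD region its span overlaps by at least
#' 1 bp (genes straddling a boundary belong to both sides). C_i keeps only
#' the coding genes sharing at least one assigned TAD with r_i; an ncRNA
#' overlapping no TAD loses all its neighbors (logged).
#'
#' @param nm A `NeighborMap`.
#' @param annotation The `GeneAnnotation` the map was built from.
#' @param tads A `GRanges` of TAD regions from [read_bed()] or [make_tads()].
#' @return A `NeighborMap`.
#' @export
filter_by_tad <- function(nm, annotation, tads) {
  stopifnot(inherits(nm, "NeighborMap"), inherits(annotation, "GeneAnnotation"),
            methods::is(tads, "GRanges"))
  if (!length(tads)) stopf("TAD set is empty")
  per <- nm$per_ncrna
  real <- names(per)[!startsWith(names(per), ".")]
  involved <- unique(c(real, unlist(per, use.names = FALSE)))
  involved <- intersect(involved, annotation$genes$gene_id)
  hits <- GenomicRanges::findOverlaps(annotation$genes[involved], tads,
                                      ignore.strand = TRUE, minoverlap = 1L)
  tad_of <- split(S4Vectors::subjectHits(hits),
                  involved[S4Vectors::queryHits(hits)])
  for (id in real) {
    mine <- tad_of[[id]]
    if (is.null(mine)) {
      if (length(per[[id]])) {
        ce_log("INFO", "ncRNA ", id, " overlaps no TAD region; neighbor set emptied")
      }
      per[[id]] <- character()
      next
    }
    keep <- vapply(per[[id]], function(g) {
      theirs <- tad_of[[g]]
      !is.null(theirs) && length(intersect(mine, theirs)) > 0L
    }, logical(1))
    per[[id]] <- per[[id]][keep]
  }
  neighbor_map(per, params = nm$params)
}

#' Restrict neighbor sets to miRNA targets
#'
#' Intended for miRNA input sets: each C_i is intersected with the target
#' genes recorded for r_i in the target table. Keys are matched
#' case-insensitively against the ncRNA's gene id (and its symbol when the
#' annotation is supplied); `strip_species_prefix` additionally drops a
#' leading miRBase species code (e.g. `hsa-`) on both sides. An r_i with no
#' table entry keeps no neighbors (warned).
#'
#' @param nm A `NeighborMap`.
#' @param targets Named list from [read_target_table()].
#' @param annotation Optional `GeneAnnotation` enabling symbol-keyed matches.
#' @param strip_species_prefix Drop a `xxx-` species prefix before matching
#'   (default `FALSE`).
#' @return A `NeighborMap`.
#' @export
filter_by_targets <- function(nm, targets, annotation = NULL,
                              strip_species_prefix = FALSE) {
  stopifnot(inherits(nm, "NeighborMap"), is.list(targets))
  norm <- function(x) {
    x <- tolower(x)
    # drop a miRBase species code (hsa-, mmu-, ...) but never the mir-/let- stem
    if (strip_species_prefix) x <- sub("^[a-z]{3,4}-(?=mir|let)", "", x, perl = TRUE)
    x
  }
  tab <- stats::setNames(targets, norm(names(targets)))
  per <- nm$per_ncrna
  real <- names(per)[!startsWith(names(per), ".")]
  sym_of <- if (!is.null(annotation)) {
    stats::setNames(annotation$genes$symbol, annotation$genes$gene_id)
  } else character()
  misses <- character()
  for (id in real) {
    keys <- norm(unique(c(id, unname(sym_of[id]))))
    entry <- NULL
    for (k in keys) {
      if (!is.na(k) && !is.null(tab[[k]])) { entry <- tab[[k]]; break }
    }
    if (is.null(entry)) {
      misses <- c(misses, id)
      per[[id]] <- character()
    } else {
      per[[id]] <- intersect(per[[id]], entry)
    }
  }
  if (length(misses)) {
    warning(sprintf("%d input gene(s) absent from the target table; their neighbor sets were emptied (e.g. %s)",
                    length(misses), paste(utils::head(misses, 3), collapse = ", ")),
            call. = FALSE)
  }
  neighbor_map(per, params = nm$params)
}

#' Subset an ncRNA input set by biotype
#'
#' @param ncrnas An `NcrnaSet`.
#' @param annotation A `GeneAnnotation`.
#' @param biotypes Character vector of biotype labels.
#' @param mode `"keep"` retains genes whose biotype is listed; `"exclude"`
#'   retains the complement.
#' @return An `NcrnaSet`; an empty result is an error.
#' @export
filter_biotype <- function(ncrnas, annotation, biotypes,
                           mode = c("keep", "exclude")) {
  mode <- match.arg(mode)
  stopifnot(inherits(ncrnas, "NcrnaSet"), inherits(annotation, "GeneAnnotation"))
  if (!length(biotypes)) stopf("biotypes must be non-empty")
  bt <- stats::setNames(annotation$genes$biotype, annotation$genes$gene_id)
  hit <- bt[ncrnas$resolved] %in% biotypes
  keep <- if (mode == "keep") hit else !hit
  out <- ncrnas$resolved[keep]
  if (!length(out)) {
    stopf("biotype filter (%s: %s) removed every input gene", mode,
          paste(biotypes, collapse = ","))
  }
  structure(list(resolved = out, unresolved = ncrnas$unresolved),
            class = "NcrnaSet")
}
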