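#' Search configuration for the cis neighborhood scan
#'
#' The window placed around each ncRNA spans its full gene body extended by
#' `upstream` bp before the start and `downstream` bp after the end (genomic
#' left/right). With `strand_aware = TRUE` the two extensions swap roles on
#' minus-strand ncRNAs so that "upstream" follows transcription. Proximity is
#' any overlap of at least 1 bp between the window and the coding gene's
#' region; `region_mode` selects whether that region is the coding gene's
#' full span, its merged exons, or its introns.
#'
#' @param upstream,downstream Non-negative window extensions in bp
#'   (default 10000 each).
#' @param strand_aware Swap extensions on minus-strand ncRNAs
#'   (default `FALSE`).
#' @param region_mode `"gene"`, `"exon"` or `"intron"` — the part of each
#'   coding gene tested for overlap.
#' @param coding_biotypes Biotypes counted as protein-coding.
#' @return An object of class `SearchConfig`.
#' @export
search_config <- function(upstream = 10000, downstream = 10000,
                          strand_aware = FALSE,
                          region_mode = c("gene", "exon", "intron"),
                          coding_biotypes = "protein_coding") {
  region_mode <- match.arg(region_mode)
  if (upstream < 0 || downstream < 0) stopf("window extensions must be >= 0")
  structure(list(upstream = as.numeric(upstream),
                 downstream = as.numeric(downstream),
                 strand_aware = isTRUE(strand_aware),
                 region_mode = region_mode,
                 coding_biotypes = coding_biotypes),
            class = "SearchConfig")
}

#' Derive the genomic regions of genes under a region mode
#'
#' `"gene"` returns the full span, `"exon"` the merged exon union, and
#' `"intron"` the gaps between consecutive merged exons within the span
#' (empty for single-exon genes; not an error).
#'
#' @param annotation A `GeneAnnotation`.
#' @param mode `"gene"`, `"exon"` or `"intron"`.
#' @param gene_ids Genes to derive regions for (default: all).
#' @return A named `GRangesList`, one element per gene.
#' @export
derive_regions <- function(annotation, mode = c("gene", "exon", "intron"),
                           gene_ids = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(annotation, "GeneAnnotation"))
  if (is.null(gene_ids)) gene_ids <- annotation$genes$gene_id
  genes <- annotation$genes[gene_ids]
  switch(mode,
    gene = {
      grl <- methods::as(genes, "GRangesList")
      names(grl) <- gene_ids
      grl
    },
    exon = annotation$exons[gene_ids],
    intron = {
      ex <- annotation$exons[gene_ids]
      GenomicRanges::psetdiff(GenomicRanges::granges(genes), ex)
    }
  )
}

#' Expand an interval into its neighborhood search window
#'
#' @param gr A `GRanges` of ncRNA spans.
#' @param cfg A [search_config()].
#' @return A `GRanges` of windows, start clamped to position 1.
#' @export
search_window <- function(gr, cfg) {
  stopifnot(inherits(cfg, "SearchConfig"))
  up <- rep(cfg$upstream, length(gr))
  dn <- rep(cfg$downstream, length(gr))
  if (cfg$strand_aware) {
    minus <- as.logical(GenomicRanges::strand(gr) == "-")
    tmp <- up[minus]; up[minus] <- dn[minus]; dn[minus] <- tmp
  }
  new_start <- pmax(1, GenomicRanges::start(gr) - up)
  new_end <- GenomicRanges::end(gr) + dn
  out <- gr
  IRanges::ranges(out) <- IRanges::IRanges(new_start, new_end)
  out
}

#' Construct a neighbor map
#'
#' @param per_ncrna Named list: ncRNA gene id -> character vector of coding
#'   gene ids. Names beginning with `"."` are pseudo-entries (used to record
#'   co-expression expansion genes) and are not treated as input ncRNAs.
#' @param params The `SearchConfig` used, or `NULL`.
#' @return An object of class `NeighborMap` with the per-ncRNA sets and their
#'   union `union_pool`.
#' @export
neighbor_map <- function(per_ncrna, params = NULL) {
  stopifnot(is.list(per_ncrna))
  if (length(per_ncrna) && is.null(names(per_ncrna))) {
    stopf("per_ncrna must be named by ncRNA gene id")
  }
  per_ncrna <- lapply(per_ncrna, function(g) sort_c(unique(as.character(g))))
  structure(list(per_ncrna = per_ncrna,
                 union_pool = sort_c(unique(unlist(per_ncrna, use.names = FALSE))),
                 params = params),
            class = "NeighborMap")
}

#' @export
print.NeighborMap <- function(x, ...) {
  real <- !startsWith(names(x$per_ncrna), ".")
  cat(sprintf("NeighborMap: %d ncRNAs, pooled coding genes |C| = %d (median |C_i| = %g)\n",
              sum(real), length(x$union_pool),
              stats::median(lengths(x$per_ncrna[real]))))
  invisible(x)
}

#' Find proximal protein-coding genes for each ncRNA
#'
#' For each resolved ncRNA r_i the window from [search_window()] is
#' intersected (strand-blind, same chromosome, >= 1 bp overlap) with the
#' coding genes' regions under `cfg$region_mode`, yielding the per-ncRNA
#' neighbor set C_i; the pooled candidate set is the union C of all C_i. An
#' ncRNA never appears in its own neighbor set, and an input gene annotated
#' with a coding biotype is excluded from its own set with a warning.
#'
#' @param ncrnas An `NcrnaSet` from [resolve_ids()].
#' @param annotation A `GeneAnnotation`.
#' @param cfg A [search_config()].
#' @return A `NeighborMap`.
#' @export
find_cis_neighbors <- function(ncrnas, annotation, cfg = search_config()) {
  stopifnot(inherits(ncrnas, "NcrnaSet"), inherits(annotation, "GeneAnnotation"),
            inherits(cfg, "SearchConfig"))
  if (!length(ncrnas$resolved)) stopf("no resolved ncRNA identifiers")
  ids <- ncrnas$resolved
  missing <- setdiff(ids, annotation$genes$gene_id)
  if (length(missing)) {
    stopf("resolved ids absent from annotation: %s",
          paste(utils::head(missing, 5), collapse = ", "))
  }
  coding_ids <- annotation$genes$gene_id[
    annotation$genes$biotype %in% cfg$coding_biotypes]
  if (any(ids %in% coding_ids)) {
    warning(sprintf("%d input gene(s) carry a coding biotype; each is excluded from its own neighbor set",
                    sum(ids %in% coding_ids)), call. = FALSE)
  }
  windows <- search_window(annotation$genes[ids], cfg)
  regions <- derive_regions(annotation, cfg$region_mode, coding_ids)
  flat <- unlist(regions, use.names = FALSE)
  flat_gene <- rep(names(regions), S4Vectors::elementNROWS(regions))
  hits <- GenomicRanges::findOverlaps(windows, flat, ignore.strand = TRUE,
                                      minoverlap = 1L)
  per <- stats::setNames(vector("list", length(ids)), ids)
  hit_by_q <- split(flat_gene[S4Vectors::subjectHits(hits)],
                    S4Vectors::queryHits(hits))
  for (i in seq_along(ids)) {
    nb <- hit_by_q[[as.character(i)]] %||% character()
    per[[i]] <- setdiff(unique(nb), ids[[i]])
  }
  nm <- neighbor_map(per, params = cfg)
  if (!length(nm$union_pool)) {
    warning("no coding neighbors found for any input ncRNA", call. = FALSE)
  }
  nm
}

#' Tabulate neighbor pairs with genomic distances
#'
#' Distance is the gap in bp between the ncRNA span and the neighbor's span
#' (0 when they overlap or are adjacent), ignoring strand.
#'
#' @param nm A `NeighborMap` from [find_cis_neighbors()].
#' @param annotation The `GeneAnnotation` used to build it.
#' @return data.frame with columns `ncRNA_id`, `neighbor_gene_id`,
#'   `distance_bp`.
#' @export
neighbor_table <- function(nm, annotation) {
  stopifnot(inherits(nm, "NeighborMap"), inherits(annotation, "GeneAnnotation"))
  real <- nm$per_ncrna[!startsWith(names(nm$per_ncrna), ".")]
  nc <- rep(names(real), lengths(real))
  nb <- unlist(real, use.names = FALSE)
  if (!length(nc)) {
    return(data.frame(ncRNA_id = character(), neighbor_gene_id = character(),
                      distance_bp = integer()))
  }
  d <- GenomicRanges::distance(annotation$genes[nc], annotation$genes[nb],
                               ignore.strand = TRUE)
  data.frame(ncRNA_id = nc, neighbor_gene_id = nb,
             distance_bp = as.integer(d), row.names = NULL)
}
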