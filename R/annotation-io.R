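#' Construct a gene annotation object
#'
#' The central coordinate container of the package. Gene spans are held as a
#' [GenomicRanges::GRanges] (1-based, closed intervals, the Bioconductor
#' convention; GTF is native, BED input is shifted on read) with metadata
#' columns `gene_id`, `symbol` and `biotype`; per-gene exons are a
#' [GenomicRanges::GRangesList] of merged (reduced) exon unions across all
#' transcripts.
#'
#' @param genes `GRanges` with metadata columns `gene_id`, `symbol`,
#'   `biotype`; one range per gene.
#' @param exons Named `GRangesList` (names = gene ids) of merged exons, or
#'   `NULL` to use each gene's span as its single exon.
#' @param assembly Free-text assembly label.
#' @param coding_biotypes Biotypes regarded as protein-coding downstream.
#' @return An object of class `GeneAnnotation`.
#' @export
gene_annotation <- function(genes, exons = NULL, assembly = "unknown",
                            coding_biotypes = "protein_coding") {
  stopifnot(methods::is(genes, "GRanges"))
  mc <- S4Vectors::mcols(genes)
  for (col in c("gene_id", "symbol", "biotype")) {
    if (!col %in% colnames(mc)) stopf("genes is missing metadata column '%s'", col)
  }
  ids <- as.character(mc$gene_id)
  if (anyDuplicated(ids)) {
    stopf("duplicate gene_id in annotation: %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (any(is.na(mc$biotype) | mc$biotype == "")) {
    stopf("every gene must carry a non-empty biotype")
  }
  names(genes) <- ids
  if (is.null(exons)) {
    exons <- methods::as(genes, "GRangesList")
    names(exons) <- ids
  } else {
    stopifnot(methods::is(exons, "GRangesList"))
    missing <- setdiff(ids, names(exons))
    if (length(missing)) {
      extra <- methods::as(genes[missing], "GRangesList")
      names(extra) <- missing
      exons <- c(exons, extra)
    }
    exons <- exons[ids]
    # exons must lie within the gene span on the same chromosome
    nex <- S4Vectors::elementNROWS(exons)
    fl <- unlist(exons, use.names = FALSE)
    grp <- rep(seq_along(exons), nex)
    span_ok <- rep(TRUE, length(exons))
    if (length(fl)) {
      lo <- tapply(GenomicRanges::start(fl), grp, min)
      hi <- tapply(GenomicRanges::end(fl), grp, max)
      g <- as.integer(names(lo))
      span_ok[g] <- lo >= GenomicRanges::start(genes)[g] &
        hi <= GenomicRanges::end(genes)[g]
    }
    if (!all(span_ok)) {
      stopf("exons extend beyond the gene span for: %s",
            paste(utils::head(ids[!span_ok], 5), collapse = ", "))
    }
  }
  exons <- methods::as(exons, "CompressedGRangesList")
  structure(
    list(genes = genes, exons = exons, assembly = assembly,
         coding_biotypes = coding_biotypes),
    class = "GeneAnnotation"
  )
}

#' @export
print.GeneAnnotation <- function(x, ...) {
  bt <- table(x$genes$biotype)
  cat(sprintf("GeneAnnotation: %d genes on %d sequence(s) [%s]\n",
              length(x$genes),
              length(GenomeInfoDb::seqlevels(x$genes)), x$assembly))
  cat("  biotypes:", paste(sprintf("%s=%d", names(bt), bt), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
length.GeneAnnotation <- function(x) length(x$genes)

#' Read a GENCODE-style GTF annotation
#'
#' Parses gene/transcript/exon features via [rtracklayer::import()], merges
#' exons per gene across all transcripts into a non-overlapping union, and
#' returns a [gene_annotation()]. Both `gene_type` and `gene_biotype`
#' attribute spellings are accepted; gzip-compressed files are handled
#' transparently. Genes lacking exon features get their span as a single
#' exon; gene records absent entirely are reconstructed as the range of
#' their exons.
#'
#' @param path Path to a GTF (optionally `.gz`).
#' @param coding_biotypes Biotypes regarded as protein-coding downstream.
#' @return A `GeneAnnotation`.
#' @export
read_gtf <- function(path, coding_biotypes = "protein_coding") {
  lines <- read_text_lines(path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  if (!any(body)) {
    ce_log("WARN", "GTF '", path, "' contains no feature lines; annotation is empty")
    empty <- GenomicRanges::GRanges()
    S4Vectors::mcols(empty) <- S4Vectors::DataFrame(
      gene_id = character(), symbol = character(), biotype = character())
    return(gene_annotation(empty, assembly = basename(path),
                           coding_biotypes = coding_biotypes))
  }
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nfield != 9L)) {
    bad <- which(body)[which(nfield != 9L)[1]]
    stopf("malformed GTF line %d in '%s': expected 9 tab-separated fields, found %d",
          bad, path, nfield[which(nfield != 9L)[1]])
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = "gtf"),
    error = function(e) stopf("failed to parse GTF '%s': %s", path, conditionMessage(e))
  )
  mc <- S4Vectors::mcols(gr)
  biotype <- if ("gene_type" %in% colnames(mc)) mc$gene_type
             else if ("gene_biotype" %in% colnames(mc)) mc$gene_biotype
             else rep(NA_character_, length(gr))
  symbol <- if ("gene_name" %in% colnames(mc)) mc$gene_name
            else rep(NA_character_, length(gr))
  gene_id <- as.character(mc$gene_id)
  if (anyNA(gene_id)) stopf("GTF '%s' has features without a gene_id attribute", path)

  is_gene <- mc$type == "gene"
  is_exon <- mc$type == "exon"

  # merged exon union per gene across transcripts
  exons <- GenomicRanges::reduce(
    GenomicRanges::split(gr[is_exon], gene_id[is_exon]))

  gids <- unique(gene_id)
  gene_rows <- which(is_gene)
  gid_g <- gene_id[gene_rows]
  if (anyDuplicated(gid_g)) {
    key <- paste(as.character(GenomeInfoDb::seqnames(gr))[gene_rows],
                 GenomicRanges::start(gr)[gene_rows],
                 GenomicRanges::end(gr)[gene_rows])
    n_coord <- tapply(key, gid_g, function(x) length(unique(x)))
    if (any(n_coord > 1L)) {
      stopf("duplicate gene_id '%s' with conflicting coordinates in '%s'",
            names(n_coord)[n_coord > 1L][1], path)
    }
    gene_rows <- gene_rows[!duplicated(gid_g)]
    gid_g <- gid_g[!duplicated(gid_g)]
  }
  genes <- gr[gene_rows]
  # genes with no gene feature: span = extent of their other features
  orphan <- setdiff(gids, gid_g)
  if (length(orphan)) {
    sel <- which(gene_id %in% orphan)
    og <- factor(gene_id[sel], levels = orphan)
    first <- sel[!duplicated(gene_id[sel])]
    extra <- GenomicRanges::GRanges(
      as.character(GenomeInfoDb::seqnames(gr))[first],
      IRanges::IRanges(
        as.numeric(tapply(GenomicRanges::start(gr)[sel], og, min)),
        as.numeric(tapply(GenomicRanges::end(gr)[sel], og, max))),
      strand = as.character(GenomicRanges::strand(gr))[first])
    S4Vectors::mcols(extra) <- S4Vectors::mcols(gr)[first, , drop = FALSE]
    suppressWarnings(genes <- c(genes, extra))
  }
  genes <- genes[match(gids, S4Vectors::mcols(genes)$gene_id)]
  gmc <- S4Vectors::mcols(genes)
  gbio <- if ("gene_type" %in% colnames(gmc)) gmc$gene_type
          else if ("gene_biotype" %in% colnames(gmc)) gmc$gene_biotype
          else rep("unknown", length(genes))
  gsym <- if ("gene_name" %in% colnames(gmc)) gmc$gene_name else gmc$gene_id
  S4Vectors::mcols(genes) <- S4Vectors::DataFrame(
    gene_id = as.character(gmc$gene_id),
    symbol = ifelse(is.na(gsym), as.character(gmc$gene_id), as.character(gsym)),
    biotype = ifelse(is.na(gbio), "unknown", as.character(gbio))
  )
  gene_annotation(genes, exons = exons, assembly = basename(path),
                  coding_biotypes = coding_biotypes)
}

#' Read TAD regions from a BED3/BED4 file
#'
#' Native BED coordinates (0-based, half-open) are converted to the package's
#' 1-based closed convention on read. Unnamed regions are auto-named
#' `region_<i>` by file order. Overlapping or nested regions are permitted.
#'
#' @param path Path to a BED file (optionally `.gz`).
#' @return A `GRanges` with a `name` metadata column.
#' @export
read_bed <- function(path) {
  lines <- read_text_lines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#") &
    !startsWith(lines, "track") & !startsWith(lines, "browser")
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  if (length(fields) == 0L) {
    return(GenomicRanges::GRanges(name = character()))
  }
  if (any(lengths(fields) < 3L)) {
    bad <- lineno[which(lengths(fields) < 3L)[1]]
    stopf("malformed BED line %d in '%s': fewer than 3 fields", bad, path)
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  if (anyNA(start0) || anyNA(end0)) {
    bad <- lineno[which(is.na(start0) | is.na(end0))[1]]
    stopf("malformed BED line %d in '%s': non-numeric coordinates", bad, path)
  }
  if (any(start0 >= end0)) {
    bad <- lineno[which(start0 >= end0)[1]]
    stopf("invalid BED line %d in '%s': chromStart >= chromEnd", bad, path)
  }
  name <- vapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    if (length(f) >= 4L && nzchar(f[[4L]])) f[[4L]] else sprintf("region_%d", i)
  }, "")
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1, end0), name = name)
}

#' Construct a gene-set collection
#'
#' @param terms Named list (term_id -> character vector of gene ids).
#' @param term_names Named character vector of display names (defaults to the
#'   term ids).
#' @param source_label Free-text provenance label.
#' @return An object of class `GeneSetCollection`.
#' @export
gene_set_collection <- function(terms, term_names = NULL, source_label = "custom") {
  stopifnot(is.list(terms))
  if (length(terms) && is.null(names(terms))) stopf("terms must be named by term_id")
  if (anyDuplicated(names(terms))) {
    stopf("duplicate term_id: %s",
          paste(unique(names(terms)[duplicated(names(terms))]), collapse = ", "))
  }
  if (any(lengths(terms) == 0L)) {
    stopf("empty gene set for term(s): %s",
          paste(names(terms)[lengths(terms) == 0L], collapse = ", "))
  }
  terms <- lapply(terms, function(g) unique(as.character(g)))
  if (is.null(term_names)) term_names <- stats::setNames(names(terms), names(terms))
  term_names <- term_names[names(terms)]
  term_names[is.na(term_names)] <- names(terms)[is.na(term_names)]
  names(term_names) <- names(terms)
  structure(list(terms = terms, term_names = term_names,
                 source_label = source_label),
            class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat(sprintf("GeneSetCollection '%s': %d terms, %d distinct genes\n",
              x$source_label, length(x$terms),
              length(unique(unlist(x$terms, use.names = FALSE)))))
  invisible(x)
}

#' @export
length.GeneSetCollection <- function(x) length(x$terms)

#' Read a GMT gene-set file
#'
#' One set per line: `term_id<TAB>description<TAB>gene1<TAB>gene2...`.
#' Duplicate genes within a line are collapsed; duplicate term ids across
#' lines are an error.
#'
#' @param path Path to a GMT file (optionally `.gz`).
#' @return A `GeneSetCollection`.
#' @export
read_gmt <- function(path) {
  lines <- read_text_lines(path)
  keep <- nzchar(lines)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  lineno <- which(keep)
  if (any(lengths(fields) < 3L)) {
    bad <- lineno[which(lengths(fields) < 3L)[1]]
    stopf("malformed GMT line %d in '%s': need term, description and >=1 gene",
          bad, path)
  }
  ids <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(ids)) {
    stopf("duplicate term_id in GMT '%s': %s", path,
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  terms <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(terms) <- ids
  term_names <- stats::setNames(vapply(fields, `[[`, "", 2L), ids)
  term_names[!nzchar(term_names)] <- ids[!nzchar(term_names)]
  gene_set_collection(terms, term_names, source_label = basename(path))
}

#' Read a term-to-gene table as a gene-set collection
#'
#' A two- or three-column headerless TSV: `term_id`, `gene_id` and an
#' optional `term_name`. Rows are grouped by term. This is a local stand-in
#' for database-backed annotation tables (GO/KEGG/Reactome exports).
#'
#' @param path Path to a TSV file (optionally `.gz`).
#' @return A `GeneSetCollection`.
#' @export
read_term_gene_table <- function(path) {
  lines <- read_text_lines(path)
  keep <- nzchar(lines)
  if (!any(keep)) return(gene_set_collection(list(), source_label = basename(path)))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  if (any(lengths(fields) < 2L)) {
    bad <- which(keep)[which(lengths(fields) < 2L)[1]]
    stopf("malformed term-gene line %d in '%s': need term_id and gene_id", bad, path)
  }
  term <- vapply(fields, `[[`, "", 1L)
  gene <- vapply(fields, `[[`, "", 2L)
  tname <- vapply(fields, function(f) if (length(f) >= 3L) f[[3L]] else NA_character_, "")
  terms <- lapply(split(gene, term), unique)
  nm <- vapply(split(tname, term), function(v) {
    v <- v[!is.na(v)]
    if (length(v)) v[[1L]] else NA_character_
  }, "")
  nm[is.na(nm)] <- names(terms)[is.na(nm)]
  gene_set_collection(terms, nm, source_label = basename(path))
}

#' Read a gene-by-sample expression matrix
#'
#' Expects a header row of sample ids and a first column of gene ids; all
#' remaining cells must parse as finite numbers. Missing values are an error
#' rather than silently imputed.
#'
#' @param path Path to a TSV/TXT file (optionally `.gz`).
#' @return Numeric matrix, genes in rows (rownames) x samples in columns
#'   (colnames).
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(gzfile(path), header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  if (ncol(df) < 2L) stopf("expression file '%s' needs a gene-id column and >=1 sample", path)
  gene_ids <- df[[1L]]
  if (anyDuplicated(gene_ids)) {
    stopf("duplicate gene id(s) in expression file '%s': %s", path,
          paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  }
  sample_ids <- colnames(df)[-1L]
  if (anyDuplicated(sample_ids)) {
    stopf("duplicate sample id(s) in expression file '%s'", path)
  }
  body <- as.matrix(df[, -1L, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  bad <- which(!is.finite(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    stopf("non-numeric or missing expression value at gene '%s', sample '%s' in '%s'",
          gene_ids[bad[1, 1]], sample_ids[bad[1, 2]], path)
  }
  dimnames(vals) <- list(gene_ids, sample_ids)
  vals
}

#' Read a miRNA-to-target table
#'
#' A headerless two-column TSV (`mirna_id`, `target_gene_id`); duplicated
#' rows collapse under set semantics.
#'
#' @param path Path to a TSV file (optionally `.gz`).
#' @return Named list: miRNA id -> character vector of target gene ids.
#' @export
read_target_table <- function(path) {
  lines <- read_text_lines(path)
  keep <- nzchar(lines)
  if (!any(keep)) return(stats::setNames(list(), character()))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  if (any(lengths(fields) < 2L)) {
    bad <- which(keep)[which(lengths(fields) < 2L)[1]]
    stopf("malformed target-table line %d in '%s': need miRNA and target columns",
          bad, path)
  }
  mir <- vapply(fields, `[[`, "", 1L)
  tgt <- vapply(fields, `[[`, "", 2L)
  lapply(split(tgt, mir), unique)
}

#' Read an alias table mapping alternative identifiers to gene ids
#'
#' A TSV with header columns `alias` and `gene_id`. Used by [resolve_ids()]
#' to map Ensembl transcript ids, Entrez ids, miRBase ids or historical
#' symbols onto the annotation's gene-id space.
#'
#' @param path Path to a TSV file (optionally `.gz`).
#' @return data.frame with columns `alias`, `gene_id`.
#' @export
read_alias_table <- function(path) {
  df <- utils::read.delim(gzfile(path), header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  if (!all(c("alias", "gene_id") %in% colnames(df))) {
    stopf("alias table '%s' must have header columns 'alias' and 'gene_id'", path)
  }
  df[, c("alias", "gene_id")]
}

#' Resolve heterogeneous input identifiers to annotation gene ids
#'
#' Tokens are matched case-insensitively against, in order: the annotation's
#' `gene_id`, its `symbol`, then the optional alias table. A symbol mapping
#' to several gene ids resolves to all of them with a warning. Duplicate
#' tokens (after case folding) collapse.
#'
#' @param tokens Character vector of input identifiers.
#' @param annotation A `GeneAnnotation`.
#' @param alias Optional alias data.frame from [read_alias_table()].
#' @return An object of class `NcrnaSet` with elements `resolved` (gene ids
#'   present in the annotation, input order preserved) and `unresolved`
#'   (tokens that could not be mapped).
#' @export
resolve_ids <- function(tokens, annotation, alias = NULL) {
  stopifnot(inherits(annotation, "GeneAnnotation"))
  tokens <- tokens[nzchar(tokens)]
  if (!length(tokens)) stopf("no input identifiers supplied")
  ids <- annotation$genes$gene_id
  by_id <- split(ids, tolower(ids))
  by_sym <- split(ids, tolower(annotation$genes$symbol))
  by_alias <- if (!is.null(alias)) {
    keep <- tolower(alias$gene_id) %in% tolower(ids)
    id_of <- stats::setNames(ids, tolower(ids))
    split(unname(id_of[tolower(alias$gene_id[keep])]), tolower(alias$alias[keep]))
  } else list()

  resolved <- character()
  unresolved <- character()
  for (tok in tokens) {
    key <- tolower(tok)
    hit <- by_id[[key]] %||% by_sym[[key]] %||% by_alias[[key]]
    if (is.null(hit)) {
      unresolved <- c(unresolved, tok)
    } else {
      hit <- unique(hit)
      if (length(hit) > 1L) {
        warning(sprintf("identifier '%s' is ambiguous; resolving to %d genes",
                        tok, length(hit)), call. = FALSE)
      }
      resolved <- c(resolved, hit)
    }
  }
  resolved <- unique(resolved)
  if (!length(resolved)) {
    stopf("none of the %d input identifiers could be resolved (first few: %s)",
          length(tokens), paste(utils::head(unresolved, 5), collapse = ", "))
  }
  if (length(unresolved)) {
    ce_log("WARN", length(unresolved), " input identifier(s) unresolved: ",
           paste(utils::head(unresolved, 10), collapse = ", "))
  }
  structure(list(resolved = resolved, unresolved = unique(unresolved)),
            class = "NcrnaSet")
}

#' @export
print.NcrnaSet <- function(x, ...) {
  cat(sprintf("NcrnaSet: %d resolved, %d unresolved\n",
              length(x$resolved), length(x$unresolved)))
  invisible(x)
}
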