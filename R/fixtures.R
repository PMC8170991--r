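#' Specification for a synthetic fixture bundle
#'
#' Defines a deterministic synthetic study: a multi-chromosome gene
#' annotation with coding and non-coding genes, contiguous TAD tiles, a
#' genes-by-samples expression matrix with planted correlated pairs, a
#' miRNA-style target table, and a gene-set collection with one term planted
#' to overlap the cis-neighborhood pool. The defaults describe a compact
#' genome (2 chromosomes of 1 Mb, 150 coding and 30 non-coding genes) on
#' which the default 10 kb search window yields a pooled neighborhood of a
#' few dozen coding genes, 100 expression samples, planted co-expression at
#' rho = 0.8, a planted term sharing 8 genes with the pool, and 40 decoy
#' terms of matched size.
#'
#' @param seed Integer seed; every generated artifact is a pure function of
#'   the spec.
#' @param n_chrom,chrom_length_bp Number and length of chromosomes.
#' @param n_coding,n_ncrna Gene counts by class.
#' @param n_tads_per_chrom Contiguous TAD tiles per chromosome.
#' @param n_samples Expression samples.
#' @param planted_pairs data.frame with columns `ncrna`, `coding` (1-based
#'   indices into the respective gene classes) and `rho` (target Pearson
#'   correlation in (-1, 1)).
#' @param planted_term_overlap Genes the planted term shares with the pool.
#' @param n_decoy_terms Decoy terms of matched size.
#' @return An object of class `FixtureSpec`.
#' @export
fixture_spec <- function(seed = 1L, n_chrom = 2L, chrom_length_bp = 1e6,
                         n_coding = 150L, n_ncrna = 30L,
                         n_tads_per_chrom = 8L, n_samples = 100L,
                         planted_pairs = data.frame(ncrna = 1:3, coding = 1:3,
                                                    rho = 0.8),
                         planted_term_overlap = 8L, n_decoy_terms = 40L) {
  counts <- c(n_chrom, chrom_length_bp, n_coding, n_ncrna, n_tads_per_chrom,
              n_samples, planted_term_overlap, n_decoy_terms)
  if (any(counts <= 0)) stopf("all fixture counts must be positive")
  if (planted_term_overlap > n_coding) {
    stopf("planted_term_overlap cannot exceed n_coding")
  }
  if (!is.null(planted_pairs) && nrow(planted_pairs)) {
    stopifnot(all(c("ncrna", "coding", "rho") %in% colnames(planted_pairs)))
    if (any(abs(planted_pairs$rho) >= 1)) stopf("rho targets must be in (-1, 1)")
    if (any(planted_pairs$ncrna > n_ncrna) || any(planted_pairs$coding > n_coding)) {
      stopf("planted pair indices exceed gene counts")
    }
  }
  structure(list(seed = as.integer(seed), n_chrom = as.integer(n_chrom),
                 chrom_length_bp = as.numeric(chrom_length_bp),
                 n_coding = as.integer(n_coding), n_ncrna = as.integer(n_ncrna),
                 n_tads_per_chrom = as.integer(n_tads_per_chrom),
                 n_samples = as.integer(n_samples),
                 planted_pairs = planted_pairs,
                 planted_term_overlap = as.integer(planted_term_overlap),
                 n_decoy_terms = as.integer(n_decoy_terms)),
            class = "FixtureSpec")
}

# split `extra` bp across n slots with random positive weights
split_extra <- function(extra, n) {
  w <- stats::runif(n) + 0.1
  floor(extra * w / sum(w))
}

#' Generate a synthetic gene annotation
#'
#' Genes are shuffled across chromosomes and placed left to right with at
#' least 1 kb between consecutive spans; remaining room is distributed as
#' random extra gap. Coding genes get 1-4 exons tiling their span with
#' intervening introns; non-coding genes are single-exon and rotate through
#' the biotypes lincRNA, antisense and miRNA (miRNA genes receive
#' miRBase-style symbols). Identical specs yield identical annotations.
#'
#' @param spec A [fixture_spec()].
#' @return A `GeneAnnotation`.
#' @export
make_annotation <- function(spec) {
  stopifnot(inherits(spec, "FixtureSpec"))
  with_seed(spec$seed, {
    nc_bio <- rep(c("lincRNA", "antisense", "miRNA"), length.out = spec$n_ncrna)
    gene_tab <- data.frame(
      gene_id = c(sprintf("PCG%04d", seq_len(spec$n_coding)),
                  sprintf("NCG%04d", seq_len(spec$n_ncrna))),
      symbol = c(sprintf("CODG%d", seq_len(spec$n_coding)),
                 ifelse(nc_bio == "miRNA",
                        sprintf("hsa-mir-%d", seq_len(spec$n_ncrna)),
                        sprintf("LNCG%d", seq_len(spec$n_ncrna)))),
      biotype = c(rep("protein_coding", spec$n_coding), nc_bio),
      stringsAsFactors = FALSE)
    n <- nrow(gene_tab)
    ord <- sample.int(n)
    gene_tab <- gene_tab[ord, , drop = FALSE]
    gene_tab$chrom <- sprintf("chr%d", rep(seq_len(spec$n_chrom), length.out = n))
    gene_tab$length <- ifelse(gene_tab$biotype == "protein_coding",
                              sample(2000:8000, n, replace = TRUE),
                              sample(500:3000, n, replace = TRUE))
    gene_tab$strand <- sample(c("+", "-"), n, replace = TRUE)
    gene_tab$start <- NA_real_
    for (chr in unique(gene_tab$chrom)) {
      sel <- which(gene_tab$chrom == chr)
      m <- length(sel)
      total_min <- sum(gene_tab$length[sel]) + 1000 * (m + 1)
      if (total_min > spec$chrom_length_bp) {
        stopf("genes do not fit on %s: need >= %d bp but chrom_length_bp = %g; reduce gene counts or lengths, or enlarge the chromosome",
              chr, total_min, spec$chrom_length_bp)
      }
      gaps <- 1000 + split_extra(spec$chrom_length_bp - total_min, m + 1)
      starts <- cumsum(gaps[seq_len(m)] +
                         c(0, gene_tab$length[sel][-m])) + 1
      gene_tab$start[sel] <- starts
    }
    gene_tab$end <- gene_tab$start + gene_tab$length - 1

    genes <- GenomicRanges::GRanges(
      gene_tab$chrom,
      IRanges::IRanges(gene_tab$start, gene_tab$end),
      strand = gene_tab$strand,
      gene_id = gene_tab$gene_id, symbol = gene_tab$symbol,
      biotype = gene_tab$biotype)

    exon_list <- lapply(seq_len(n), function(i) {
      if (gene_tab$biotype[i] != "protein_coding") {
        return(IRanges::IRanges(gene_tab$start[i], gene_tab$end[i]))
      }
      n_ex <- sample(1:4, 1L)
      if (n_ex == 1L) {
        return(IRanges::IRanges(gene_tab$start[i], gene_tab$end[i]))
      }
      n_seg <- 2L * n_ex - 1L
      L <- gene_tab$length[i]
      w <- stats::runif(n_seg) + 0.2
      bounds <- round(cumsum(w) / sum(w) * L)
      lens <- diff(c(0, bounds))
      if (any(lens < 1)) {
        return(IRanges::IRanges(gene_tab$start[i], gene_tab$end[i]))
      }
      offs <- cumsum(c(0, lens[-n_seg]))
      ex <- seq(1, n_seg, by = 2)
      IRanges::IRanges(gene_tab$start[i] + offs[ex],
                       gene_tab$start[i] + offs[ex] + lens[ex] - 1)
    })
    nex <- lengths(exon_list)
    flat <- GenomicRanges::GRanges(
      rep(gene_tab$chrom, nex),
      unlist(methods::as(exon_list, "IRangesList"), use.names = FALSE),
      strand = rep(gene_tab$strand, nex))
    exons <- GenomicRanges::split(
      flat, factor(rep(gene_tab$gene_id, nex), levels = gene_tab$gene_id))
    gene_annotation(genes, exons = exons,
                    assembly = sprintf("synthetic-seed%d", spec$seed))
  })
}

#' Generate contiguous TAD tiles
#'
#' Each chromosome is cut into `n_tads_per_chrom` contiguous, non-overlapping
#' tiles covering the whole sequence; cut points start from an equal tiling
#' and snap to the midpoint of the nearest inter-gene gap so that genes do
#' not straddle boundaries unless the gene layout forces it.
#'
#' @param spec A [fixture_spec()].
#' @param annotation The matching [make_annotation()] output.
#' @return A `GRanges` of TAD regions with a `name` column.
#' @export
make_tads <- function(spec, annotation) {
  stopifnot(inherits(spec, "FixtureSpec"), inherits(annotation, "GeneAnnotation"))
  with_seed(spec$seed + 1L, {
    chrom <- character(); starts <- numeric(); ends <- numeric(); nms <- character()
    for (ci in seq_len(spec$n_chrom)) {
      chr <- sprintf("chr%d", ci)
      L <- spec$chrom_length_bp
      k <- spec$n_tads_per_chrom
      g <- annotation$genes[as.character(GenomeInfoDb::seqnames(annotation$genes)) == chr]
      g <- g[order(GenomicRanges::start(g))]
      gap_mid <- if (length(g) > 1) {
        s <- GenomicRanges::start(g); e <- GenomicRanges::end(g)
        mids <- floor((e[-length(e)] + s[-1]) / 2)
        mids[s[-1] - e[-length(e)] > 1]
      } else numeric()
      cuts <- round(L * seq_len(k - 1) / k)
      if (length(gap_mid)) {
        cuts <- vapply(cuts, function(x) gap_mid[which.min(abs(gap_mid - x))], 0)
      }
      cuts <- sort(unique(cuts))
      bounds <- c(1, cuts + 1)
      chrom <- c(chrom, rep(chr, length(bounds)))
      starts <- c(starts, bounds)
      ends <- c(ends, c(cuts, L))
      nms <- c(nms, sprintf("TAD_%s_%d", chr, seq_along(bounds)))
    }
    GenomicRanges::GRanges(chrom, IRanges::IRanges(starts, ends), name = nms)
  })
}

#' Generate an expression matrix with planted correlated pairs
#'
#' Background genes draw independent standard-normal profiles (log-scale
#' expression). For each planted pair the coding partner's profile is
#' `rho * standardize(ncRNA profile) + sqrt(1 - rho^2) * noise`, so its
#' expected Pearson correlation with the ncRNA equals `rho`.
#'
#' @param spec A [fixture_spec()].
#' @param annotation The matching [make_annotation()] output.
#' @return Numeric matrix, all genes x samples.
#' @export
make_expression <- function(spec, annotation) {
  stopifnot(inherits(spec, "FixtureSpec"), inherits(annotation, "GeneAnnotation"))
  with_seed(spec$seed + 2L, {
    ids <- annotation$genes$gene_id
    mat <- matrix(stats::rnorm(length(ids) * spec$n_samples),
                  nrow = length(ids),
                  dimnames = list(ids, sprintf("S%03d", seq_len(spec$n_samples))))
    pp <- spec$planted_pairs
    if (!is.null(pp) && nrow(pp)) {
      for (i in seq_len(nrow(pp))) {
        a <- sprintf("NCG%04d", pp$ncrna[i])
        b <- sprintf("PCG%04d", pp$coding[i])
        za <- as.numeric(scale(mat[a, ]))
        mat[b, ] <- pp$rho[i] * za +
          sqrt(1 - pp$rho[i]^2) * stats::rnorm(spec$n_samples)
      }
    }
    mat
  })
}

#' Generate a miRNA-style target table
#'
#' Every non-coding gene receives a random set of 10-30 coding targets that
#' always includes the coding partners of its planted co-expression pairs,
#' keyed by gene id.
#'
#' @param spec A [fixture_spec()].
#' @param annotation The matching [make_annotation()] output.
#' @return Named list: ncRNA gene id -> character vector of coding gene ids.
#' @export
make_targets <- function(spec, annotation) {
  stopifnot(inherits(spec, "FixtureSpec"), inherits(annotation, "GeneAnnotation"))
  with_seed(spec$seed + 3L, {
    coding <- sprintf("PCG%04d", seq_len(spec$n_coding))
    pp <- spec$planted_pairs
    out <- lapply(seq_len(spec$n_ncrna), function(i) {
      tg <- sample(coding, sample(10:30, 1L))
      if (!is.null(pp) && nrow(pp)) {
        tg <- union(tg, sprintf("PCG%04d", pp$coding[pp$ncrna == i]))
      }
      sort_c(tg)
    })
    stats::setNames(out, sprintf("NCG%04d", seq_len(spec$n_ncrna)))
  })
}

#' Generate a gene-set collection with one planted term
#'
#' The planted term (`TERM_PLANTED`) contains `planted_term_overlap` genes
#' drawn from the supplied neighborhood pool plus coding fillers from outside
#' the pool; decoy terms of matched size are drawn uniformly from the
#' non-pool coding genes, so only the planted term overlaps the pool by
#' construction.
#'
#' @param spec A [fixture_spec()].
#' @param annotation The matching [make_annotation()] output.
#' @param pool Character vector of pooled coding gene ids (a `NeighborMap`'s
#'   `union_pool`).
#' @return A `GeneSetCollection`.
#' @export
make_genesets <- function(spec, annotation, pool) {
  stopifnot(inherits(spec, "FixtureSpec"), inherits(annotation, "GeneAnnotation"))
  coding <- sprintf("PCG%04d", seq_len(spec$n_coding))
  pool <- intersect(pool, coding)
  if (length(pool) < spec$planted_term_overlap) {
    stopf("pool has %d coding genes but planted_term_overlap = %d; enlarge the window or the genome",
          length(pool), spec$planted_term_overlap)
  }
  with_seed(spec$seed + 4L, {
    n_fill <- max(2L, 5L - spec$planted_term_overlap)
    size <- spec$planted_term_overlap + n_fill
    nonpool <- setdiff(coding, pool)
    if (length(nonpool) < size) {
      stopf("only %d coding genes lie outside the pool but terms need %d; enlarge n_coding",
            length(nonpool), size)
    }
    planted <- c(sample(pool, spec$planted_term_overlap),
                 sample(nonpool, n_fill))
    decoys <- lapply(seq_len(spec$n_decoy_terms), function(i) sample(nonpool, size))
    terms <- c(list(TERM_PLANTED = sort_c(planted)),
               stats::setNames(lapply(decoys, sort_c),
                               sprintf("DECOY_%02d", seq_len(spec$n_decoy_terms))))
    nms <- stats::setNames(c("planted signal term",
                             sprintf("decoy term %d", seq_len(spec$n_decoy_terms))),
                           names(terms))
    gene_set_collection(terms, nms, source_label = sprintf("synthetic-seed%d", spec$seed))
  })
}

# ---- plain-text writers for the fixture bundle -------------------------------

#' Write a GeneAnnotation as a GENCODE-dialect GTF
#'
#' Emits one `gene` feature per gene and one `exon` feature per merged exon,
#' with `gene_id`, `gene_name`, `gene_type` (and `transcript_id` on exons)
#' attributes; 1-based inclusive coordinates.
#'
#' @param annotation A `GeneAnnotation`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gtf <- function(annotation, path) {
  g <- annotation$genes
  attr_of <- function(i) {
    sprintf('gene_id "%s"; gene_name "%s"; gene_type "%s";',
            g$gene_id[i], g$symbol[i], g$biotype[i])
  }
  lines <- character()
  for (i in seq_along(g)) {
    chrom <- as.character(GenomeInfoDb::seqnames(g))[i]
    strand <- as.character(GenomicRanges::strand(g))[i]
    if (strand == "*") strand <- "."
    lines <- c(lines, paste(chrom, "cisenrich", "gene",
                            GenomicRanges::start(g)[i], GenomicRanges::end(g)[i],
                            ".", strand, ".", attr_of(i), sep = "\t"))
    ex <- annotation$exons[[g$gene_id[i]]]
    for (j in seq_along(ex)) {
      lines <- c(lines, paste(chrom, "cisenrich", "exon",
                              GenomicRanges::start(ex)[j], GenomicRanges::end(ex)[j],
                              ".", strand, ".",
                              paste0(attr_of(i), sprintf(' transcript_id "%s.t1";',
                                                         g$gene_id[i])),
                              sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write TAD regions as BED4
#'
#' Converts the internal 1-based closed coordinates back to native BED
#' 0-based half-open.
#'
#' @param tads `GRanges` with a `name` column.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(tads, path) {
  lines <- paste(as.character(GenomeInfoDb::seqnames(tads)),
                 GenomicRanges::start(tads) - 1,
                 GenomicRanges::end(tads),
                 tads$name, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Write an expression matrix as TSV
#' @param mat Numeric matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_expression <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat),
                   apply(mat, 2, fmt_num), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a target table as two-column TSV
#' @param targets Named list: miRNA id -> target gene ids.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_target_table <- function(targets, path) {
  lines <- unlist(lapply(names(targets), function(m) {
    paste(m, targets[[m]], sep = "\t")
  }), use.names = FALSE)
  writeLines(lines %||% character(), path)
  invisible(path)
}

#' Write a gene-set collection as GMT
#' @param collection A `GeneSetCollection`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$terms), function(tid) {
    paste(c(tid, collection$term_names[[tid]], collection$terms[[tid]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Generate and write a complete fixture bundle
#'
#' Writes `genome.gtf`, `tads.bed`, `expression.tsv`, `targets.tsv`,
#' `genesets.gmt`, `ncrna_input.txt` (the non-coding gene ids),
#' `background.txt` (all coding gene ids, a ready-made enrichment universe)
#' and `truth.json` (the planted-signal manifest) into `dir`. The gene-set
#' collection is planted against the pool obtained with the default
#' [search_config()], and planted co-expression pairs are anchored to actual
#' cis-neighbor pairs (the i-th pair becomes the i-th ncRNA with coding
#' neighbors and its nearest neighbor, keeping the requested rho), emulating
#' an ncRNA co-expressed with a nearby coding gene; the pairs used are
#' recorded in `truth.json`.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, a list with the in-memory objects and the `truth`
#'   manifest.
#' @export
simulate_fixtures <- function(spec, dir) {
  stopifnot(inherits(spec, "FixtureSpec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ann <- make_annotation(spec)
  tads <- make_tads(spec, ann)
  nc_ids <- sprintf("NCG%04d", seq_len(spec$n_ncrna))
  ncrnas <- structure(list(resolved = nc_ids, unresolved = character()),
                      class = "NcrnaSet")
  nm <- find_cis_neighbors(ncrnas, ann, search_config())
  pp <- spec$planted_pairs
  if (!is.null(pp) && nrow(pp)) {
    with_nb <- which(lengths(nm$per_ncrna[nc_ids]) > 0L)
    n_pairs <- min(nrow(pp), length(with_nb))
    pp <- pp[seq_len(n_pairs), , drop = FALSE]
    pp$ncrna <- with_nb[seq_len(n_pairs)]
    pp$coding <- vapply(pp$ncrna, function(i) {
      as.integer(sub("PCG", "", nm$per_ncrna[[nc_ids[i]]][1]))
    }, 0L)
    spec$planted_pairs <- pp
  }
  expr <- make_expression(spec, ann)
  targets <- make_targets(spec, ann)
  gs <- make_genesets(spec, ann, nm$union_pool)
  write_gtf(ann, file.path(dir, "genome.gtf"))
  write_bed(tads, file.path(dir, "tads.bed"))
  write_expression(expr, file.path(dir, "expression.tsv"))
  write_target_table(targets, file.path(dir, "targets.tsv"))
  write_gmt(gs, file.path(dir, "genesets.gmt"))
  writeLines(nc_ids, file.path(dir, "ncrna_input.txt"))
  writeLines(sprintf("PCG%04d", seq_len(spec$n_coding)),
             file.path(dir, "background.txt"))
  truth <- list(
    seed = spec$seed,
    planted_term = "TERM_PLANTED",
    planted_term_genes = gs$terms$TERM_PLANTED,
    pool_size = length(nm$union_pool),
    planted_pairs = if (!is.null(pp) && nrow(pp)) {
      data.frame(ncrna = sprintf("NCG%04d", pp$ncrna),
                 coding = sprintf("PCG%04d", pp$coding), rho = pp$rho)
    } else NULL)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(annotation = ann, tads = tads, expression = expr,
                 targets = targets, genesets = gs, neighbor_map = nm,
                 truth = truth))
}
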