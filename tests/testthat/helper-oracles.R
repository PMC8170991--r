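# Independent oracles used across the suite. These deliberately avoid the
# code paths (and where possible the library calls) they are checking.

# upper-tail hypergeometric probability by counting draw classes with choose()
enum_hyper <- function(k, n, K, N) {
  if (k == 0) return(1)
  x <- k:min(n, K)
  sum(choose(K, x) * choose(N - K, n - x)) / choose(N, n)
}

# upper-tail hypergeometric probability by literal enumeration of all C(N, n)
# subsets of the background (feasible only for small N)
subset_enum_hyper <- function(k, n, K, N) {
  if (k == 0) return(1)
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)  # genes 1..K are "in the term"
}

# textbook Pearson correlation from the definition
manual_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# two-sided t-test p-value for a correlation coefficient
manual_cor_pvalue <- function(r, n) {
  tt <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(tt), df = n - 2)
}

# Benjamini-Hochberg step-up from the definition
manual_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Newman modularity of a partition from the definition
manual_modularity <- function(edges, membership) {
  m <- nrow(edges)
  deg <- table(c(edges$source, edges$target))
  q <- 0
  for (cl in unique(membership)) {
    nodes <- names(membership)[membership == cl]
    e_c <- sum(edges$source %in% nodes & edges$target %in% nodes)
    d_c <- sum(deg[names(deg) %in% nodes])
    q <- q + e_c / m - (d_c / (2 * m))^2
  }
  q
}

# all-pairs brute-force cis neighborhood, independent of the GRanges index
brute_force_neighbors <- function(ann, ncrna_ids, upstream, downstream,
                                  strand_aware = FALSE,
                                  region_mode = "gene",
                                  coding_biotypes = "protein_coding") {
  g <- ann$genes
  gene_df <- data.frame(
    id = g$gene_id,
    chrom = as.character(GenomeInfoDb::seqnames(g)),
    start = GenomicRanges::start(g),
    end = GenomicRanges::end(g),
    strand = as.character(GenomicRanges::strand(g)),
    biotype = g$biotype, stringsAsFactors = FALSE)
  coding <- gene_df[gene_df$biotype %in% coding_biotypes, , drop = FALSE]

  # region rows for the coding genes, with introns recomputed by hand
  reg <- do.call(rbind, lapply(seq_len(nrow(coding)), function(i) {
    id <- coding$id[i]
    if (region_mode == "gene") {
      return(data.frame(id = id, chrom = coding$chrom[i],
                        start = coding$start[i], end = coding$end[i]))
    }
    ex <- ann$exons[[id]]
    es <- GenomicRanges::start(ex); ee <- GenomicRanges::end(ex)
    o <- order(es); es <- es[o]; ee <- ee[o]
    if (region_mode == "exon") {
      return(data.frame(id = id, chrom = coding$chrom[i], start = es, end = ee))
    }
    if (length(es) < 2L) return(NULL)
    data.frame(id = id, chrom = coding$chrom[i],
               start = ee[-length(ee)] + 1, end = es[-1] - 1)
  }))

  out <- list()
  for (r in ncrna_ids) {
    row <- gene_df[gene_df$id == r, ]
    up <- upstream; dn <- downstream
    if (strand_aware && row$strand == "-") { tmp <- up; up <- dn; dn <- tmp }
    ws <- max(1, row$start - up)
    we <- row$end + dn
    hit <- reg$chrom == row$chrom & reg$start <= we & reg$end >= ws
    out[[r]] <- setdiff(sort(unique(reg$id[hit])), r)
  }
  out
}
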