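test_that("GTF genes round-trip through write and read unchanged", {
  ann <- make_annotation(fixture_spec(seed = 7, n_coding = 40, n_ncrna = 10))
  f <- write_lines_tmp(character(), ".gtf")
  write_gtf(ann, f)
  back <- read_gtf(f)
  ids <- ann$genes$gene_id
  expect_setequal(back$genes$gene_id, ids)
  b <- back$genes[ids]
  expect_identical(GenomicRanges::start(b), GenomicRanges::start(ann$genes))
  expect_identical(GenomicRanges::end(b), GenomicRanges::end(ann$genes))
  expect_identical(as.character(GenomicRanges::strand(b)),
                   as.character(GenomicRanges::strand(ann$genes)))
  expect_identical(b$biotype, ann$genes$biotype)
  expect_identical(b$symbol, ann$genes$symbol)
  for (gid in sample(ids, 10)) {
    expect_identical(GenomicRanges::start(back$exons[[gid]]),
                     GenomicRanges::start(ann$exons[[gid]]), info = gid)
    expect_identical(GenomicRanges::end(back$exons[[gid]]),
                     GenomicRanges::end(ann$exons[[gid]]), info = gid)
  }
})

test_that("exons from multiple transcripts are merged into a disjoint union", {
  gtf <- c(
    'chr1\tsrc\tgene\t1001\t2000\t.\t+\t.\tgene_id "G1"; gene_name "g1"; gene_type "protein_coding";',
    'chr1\tsrc\texon\t1001\t1200\t.\t+\t.\tgene_id "G1"; transcript_id "G1.t1"; gene_type "protein_coding";',
    'chr1\tsrc\texon\t1101\t1300\t.\t+\t.\tgene_id "G1"; transcript_id "G1.t2"; gene_type "protein_coding";')
  ann <- read_gtf(write_lines_tmp(gtf, ".gtf"))
  ex <- ann$exons[["G1"]]
  expect_length(ex, 1L)
  expect_equal(GenomicRanges::start(ex), 1001)
  expect_equal(GenomicRanges::end(ex), 1300)
  # merged total length equals base-by-base union of the input exons
  bases <- union(1001:1200, 1101:1300)
  expect_equal(sum(GenomicRanges::width(ex)), length(bases))
  # gene span preserved as written (1-based inclusive)
  expect_equal(GenomicRanges::start(ann$genes["G1"]), 1001)
  expect_equal(GenomicRanges::end(ann$genes["G1"]), 2000)
})

test_that("merged exon length equals the brute-force base union on random transcript sets", {
  set.seed(41)
  for (rep in 1:20) {
    n_tx <- sample(2:4, 1)
    exon_rows <- do.call(rbind, lapply(seq_len(n_tx), function(t) {
      s <- sort(sample(1001:4800, sample(1:3, 1)))
      data.frame(start = s, end = pmin(s + sample(50:400, length(s),
                                                  replace = TRUE), 5000))
    }))
    gtf <- c(
      'chr1\tsrc\tgene\t1001\t5000\t.\t+\t.\tgene_id "G"; gene_type "protein_coding";',
      sprintf('chr1\tsrc\texon\t%d\t%d\t.\t+\t.\tgene_id "G"; transcript_id "G.t";',
              exon_rows$start, exon_rows$end))
    ann <- read_gtf(write_lines_tmp(gtf, ".gtf"))
    ex <- ann$exons[["G"]]
    truth <- unique(unlist(Map(seq, exon_rows$start, exon_rows$end)))
    expect_equal(sum(GenomicRanges::width(ex)), length(truth))
    # pairwise disjoint and sorted
    s <- GenomicRanges::start(ex); e <- GenomicRanges::end(ex)
    expect_true(all(diff(s) > 0))
    if (length(s) > 1) expect_true(all(s[-1] > e[-length(e)] + 1))
  }
})

test_that("GTF edge cases: empty file, malformed line, conflicting duplicates, missing gene feature", {
  empty <- write_lines_tmp("# just a comment", ".gtf")
  expect_message(ann <- read_gtf(empty), "empty")
  expect_length(ann$genes, 0L)

  bad <- write_lines_tmp(c(
    'chr1\tsrc\tgene\t1\t100\t.\t+\t.\tgene_id "G1";',
    "chr1\tonly\tthree"), ".gtf")
  expect_error(read_gtf(bad), "line 2")

  dup <- write_lines_tmp(c(
    'chr1\tsrc\tgene\t1\t100\t.\t+\t.\tgene_id "G1"; gene_type "lincRNA";',
    'chr1\tsrc\tgene\t500\t900\t.\t+\t.\tgene_id "G1"; gene_type "lincRNA";'),
    ".gtf")
  expect_error(read_gtf(dup), "conflicting coordinates")

  # exon-only gene: span reconstructed as the feature extent
  orphan <- write_lines_tmp(c(
    'chr1\tsrc\texon\t1001\t1200\t.\t-\t.\tgene_id "GX"; gene_type "miRNA";',
    'chr1\tsrc\texon\t1500\t1800\t.\t-\t.\tgene_id "GX"; gene_type "miRNA";'),
    ".gtf")
  ann <- read_gtf(orphan)
  expect_equal(GenomicRanges::start(ann$genes["GX"]), 1001)
  expect_equal(GenomicRanges::end(ann$genes["GX"]), 1800)
  expect_equal(ann$genes["GX"]$biotype, "miRNA")
})

test_that("BED reader converts to 1-based closed, names unnamed regions, rejects inverted intervals", {
  f <- write_lines_tmp(c("chr1\t0\t500000\tTAD_A", "chr1\t500000\t900000"),
                       ".bed")
  tads <- read_bed(f)
  expect_equal(GenomicRanges::start(tads), c(1, 500001))
  expect_equal(GenomicRanges::end(tads), c(500000, 900000))
  expect_equal(tads$name, c("TAD_A", "region_2"))

  inv <- write_lines_tmp("chr1\t100\t50", ".bed")
  expect_error(read_bed(inv), "line 1")
})

test_that("GMT reader de-duplicates genes and enforces term uniqueness", {
  f <- write_lines_tmp(c("T1\tdesc one\tG1\tG2\tG2", "T2\tdesc two\tG3"),
                       ".gmt")
  gs <- read_gmt(f)
  expect_equal(gs$terms$T1, c("G1", "G2"))
  expect_equal(unname(gs$term_names["T1"]), "desc one")
  expect_length(gs, 2L)

  expect_error(read_gmt(write_lines_tmp("T1\tdesc", ".gmt")), "line 1")
  expect_error(read_gmt(write_lines_tmp(c("T1\td\tG1", "T1\td\tG2"), ".gmt")),
               "T1")
})

test_that("GMT reader agrees with fgsea's reference parser", {
  skip_if_not_installed("fgsea")
  spec <- fixture_spec(seed = 5)
  ann <- make_annotation(spec)
  gs <- make_genesets(spec, ann, sprintf("PCG%04d", 1:20))
  f <- write_lines_tmp(character(), ".gmt")
  write_gmt(gs, f)
  ref <- fgsea::gmtPathways(f)
  expect_setequal(names(ref), names(gs$terms))
  for (tid in names(ref)) expect_setequal(ref[[tid]], gs$terms[[tid]])
})

test_that("term-gene table groups rows into sets and keeps optional names", {
  f <- write_lines_tmp(c("T1\tG1", "T1\tG2", "T2\tG3\tsecond term"), ".tsv")
  gs <- read_term_gene_table(f)
  expect_equal(lengths(gs$terms), c(T1 = 2L, T2 = 1L))
  expect_equal(unname(gs$term_names["T2"]), "second term")
  expect_equal(unname(gs$term_names["T1"]), "T1")

  empty <- read_term_gene_table(write_lines_tmp(character(), ".tsv"))
  expect_length(empty, 0L)
  expect_error(read_term_gene_table(write_lines_tmp("only_one_column", ".tsv")),
               "line 1")
})

test_that("expression reader returns a numeric matrix and rejects duplicates and missing cells", {
  f <- write_lines_tmp(c("gene\tS1\tS2\tS3\tS4",
                         "G1\t1\t2\t3\t4",
                         "G2\t0.5\t0.5\t0.5\t0.5",
                         "G3\t-1\t0\t1\t2"), ".tsv")
  m <- read_expression(f)
  expect_identical(dim(m), c(3L, 4L))
  expect_identical(rownames(m), c("G1", "G2", "G3"))
  expect_equal(m["G3", "S1"], -1)

  dup <- write_lines_tmp(c("gene\tS1", "G1\t1", "G1\t2"), ".tsv")
  expect_error(read_expression(dup), "duplicate")

  nas <- write_lines_tmp(c("gene\tS1\tS2", "G1\t1\tNA"), ".tsv")
  expect_error(read_expression(nas), "gene 'G1', sample 'S2'")
})

test_that("target table groups with set semantics", {
  f <- write_lines_tmp(c("miR-1\tG1", "miR-1\tG2", "miR-1\tG2", "miR-2\tG3"),
                       ".tsv")
  tt <- read_target_table(f)
  expect_equal(tt[["miR-1"]], c("G1", "G2"))
  expect_equal(tt[["miR-2"]], "G3")
  expect_length(read_target_table(write_lines_tmp(character(), ".tsv")), 0L)
})

test_that("gzip-compressed inputs are read transparently", {
  lines <- c("T1\tdesc\tG1\tG2")
  f <- tempfile(fileext = ".gmt.gz")
  con <- gzfile(f, "wt"); writeLines(lines, con); close(con)
  expect_equal(read_gmt(f)$terms$T1, c("G1", "G2"))
})

test_that("resolve_ids matches gene_id, then symbol, then alias, case-insensitively", {
  ann <- tiny_annotation()
  r <- resolve_ids(c("ncg01", "CODA"), ann)
  expect_setequal(r$resolved, c("NCG01", "PCG01"))

  # duplicates after case folding collapse
  r2 <- resolve_ids(c("LNC1", "lnc1"), ann)
  expect_identical(r2$resolved, "NCG01")

  # alias table
  alias <- data.frame(alias = "ENST000001", gene_id = "NCG02")
  r3 <- resolve_ids("enst000001", ann, alias)
  expect_identical(r3$resolved, "NCG02")

  # nothing resolvable is a hard error
  expect_error(resolve_ids("nosuchgene", ann), "resolved")

  # unresolved tokens are reported alongside the resolved ones
  suppressMessages(r4 <- resolve_ids(c("NCG01", "nosuchgene"), ann))
  expect_identical(r4$unresolved, "nosuchgene")
})

test_that("an ambiguous symbol resolves to all matching genes with a warning", {
  genes <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1, 1000), c(500, 1500)), strand = "+",
    gene_id = c("A1", "A2"), symbol = c("SHARED", "SHARED"),
    biotype = c("lincRNA", "lincRNA"))
  ann <- gene_annotation(genes)
  expect_warning(r <- resolve_ids("shared", ann), "ambiguous")
  expect_setequal(r$resolved, c("A1", "A2"))
})

test_that("resolve_ids is idempotent on its own output", {
  ann <- make_annotation(fixture_spec(seed = 3))
  tokens <- c(sprintf("NCG%04d", 1:10), "LNCG1")
  r1 <- resolve_ids(tokens, ann)
  r2 <- resolve_ids(r1$resolved, ann)
  expect_identical(r2$resolved, r1$resolved)
  expect_length(r2$unresolved, 0L)
})
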