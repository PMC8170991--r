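# A small hand-built annotation exercising every geometric edge case:
#   NCG01  lincRNA        chr1 100001-101000 (+)
#   PCG01  protein_coding chr1 105001-106000 (+)   4 kb downstream of NCG01
#   PCG02  protein_coding chr1 120001-121000 (+)  19 kb downstream of NCG01
#   PCG03  protein_coding chr2 105001-106000 (+)   other chromosome
#   PCG04  protein_coding chr1 200001-201000 (+)   two exons, one intron
#   NCG02  miRNA          chr1 300001-300500 (-)   symbol hsa-mir-21
tiny_annotation <- function() {
  genes <- GenomicRanges::GRanges(
    c("chr1", "chr1", "chr1", "chr2", "chr1", "chr1"),
    IRanges::IRanges(c(100001, 105001, 120001, 105001, 200001, 300001),
                     c(101000, 106000, 121000, 106000, 201000, 300500)),
    strand = c("+", "+", "+", "+", "+", "-"),
    gene_id = c("NCG01", "PCG01", "PCG02", "PCG03", "PCG04", "NCG02"),
    symbol = c("LNC1", "CODA", "CODB", "CODC", "CODD", "hsa-mir-21"),
    biotype = c("lincRNA", rep("protein_coding", 4), "miRNA"))
  exons <- methods::as(stats::setNames(list(
    GenomicRanges::GRanges("chr1", IRanges::IRanges(100001, 101000), strand = "+"),
    GenomicRanges::GRanges("chr1", IRanges::IRanges(105001, 106000), strand = "+"),
    GenomicRanges::GRanges("chr1", IRanges::IRanges(120001, 121000), strand = "+"),
    GenomicRanges::GRanges("chr2", IRanges::IRanges(105001, 106000), strand = "+"),
    GenomicRanges::GRanges("chr1", IRanges::IRanges(c(200001, 200801),
                                                    c(200200, 201000)),
                           strand = "+"),
    GenomicRanges::GRanges("chr1", IRanges::IRanges(300001, 300500), strand = "-")),
    c("NCG01", "PCG01", "PCG02", "PCG03", "PCG04", "NCG02")), "GRangesList")
  suppressWarnings(cisenrich::gene_annotation(genes, exons, assembly = "tiny"))
}

tiny_ncrnas <- function(ids = c("NCG01", "NCG02")) {
  structure(list(resolved = ids, unresolved = character()), class = "NcrnaSet")
}

# a neighbor map with known structure for filter tests
tiny_neighbor_map <- function() {
  cisenrich::neighbor_map(list(
    NCG01 = c("PCG01", "PCG02"),
    NCG02 = c("PCG04")))
}

write_lines_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
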