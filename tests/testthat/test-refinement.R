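test_that("expression pre-filter applies low-expression, log2, variance and MAD steps in order", {
  cfg <- coexpression_config()
  m <- rbind(constant = rep(5, 10),
             alternating = rep(c(0, 1), 5),
             noisy = seq(0.1, 1, length.out = 10))
  colnames(m) <- sprintf("S%d", 1:10)
  out <- prefilter_expression(m, cfg)
  expect_false("constant" %in% rownames(out))   # variance 0 < 0.0025
  expect_true("alternating" %in% rownames(out)) # variance ~0.26

  # low-expression rule: below 0.05 in more than 20% of samples is dropped
  m2 <- rbind(low = c(rep(0.01, 9), 1), high = 10 * (1:10))
  colnames(m2) <- sprintf("S%d", 1:10)
  cfg2 <- coexpression_config(low_expr_value = 0.05, low_expr_fraction = 0.2)
  out2 <- prefilter_expression(m2, cfg2)
  expect_identical(rownames(out2), "high")

  # log2 transform precedes the MAD filter
  m3 <- rbind(keep = 2^(1:10) - 1, flat = rep(1000, 10))
  colnames(m3) <- sprintf("S%d", 1:10)
  cfg3 <- coexpression_config(log2_transform = TRUE, mad_cutoff = 0.5,
                              variance_cutoff = 0)
  out3 <- prefilter_expression(m3, cfg3)
  expect_identical(rownames(out3), "keep")
  expect_equal(out3["keep", 1], 1)  # log2(1 + 1)

  # removing every gene is a hard error
  expect_error(prefilter_expression(m[1, , drop = FALSE], cfg), "removed all")
})

test_that("Pearson edges match the textbook formula and its t-test p-value", {
  set.seed(10)
  x <- c(0.3, -1.2, 0.5, 2.1, -0.7, 1.4, 0.0, -0.3, 0.9, -1.8)
  y <- c(0.1, -0.9, 0.8, 1.7, -1.1, 1.0, 0.4, -0.2, 1.2, -1.5)
  m <- rbind(A = x, B = y)
  colnames(m) <- sprintf("S%d", 1:10)
  cfg <- coexpression_config(coefficient_cutoff = 0, p_cutoff = 1)
  e <- compute_coexpression(m, "A", "B", cfg)
  expect_equal(nrow(e), 1L)
  expect_equal(e$coefficient, manual_pearson(x, y), tolerance = 1e-12)
  expect_equal(e$p_value, manual_cor_pvalue(manual_pearson(x, y), 10),
               tolerance = 1e-12)
  expect_true(e$ci_low <= e$coefficient && e$coefficient <= e$ci_high)
  expect_equal(e$n_samples, 10L)
})

test_that("Spearman works on ranks; Kendall uses the tau-b normal approximation", {
  x <- c(3, 1, 4, 1.5, 5, 9, 2.6, 5.3, 5.8, 9.7)
  y <- x^2 + c(0.1, -0.2, 0.3, 0, -0.1, 0.2, -0.3, 0.1, 0, -0.2)
  m <- rbind(A = x, B = y); colnames(m) <- sprintf("S%d", 1:10)
  sp <- compute_coexpression(m, "A", "B",
                             coexpression_config(method = "spearman",
                                                 coefficient_cutoff = 0,
                                                 p_cutoff = 1))
  expect_equal(sp$coefficient, manual_pearson(rank(x), rank(y)),
               tolerance = 1e-12)
  kd <- compute_coexpression(m, "A", "B",
                             coexpression_config(method = "kendall",
                                                 coefficient_cutoff = 0,
                                                 p_cutoff = 1))
  # monotone-increasing relation: tau = 1, p from the normal approximation
  expect_equal(kd$coefficient, 1)
  expect_true(kd$p_value > 0 && kd$p_value < 0.01)
})

test_that("coefficient sign rules gate retention", {
  m <- rbind(A = 1:10 + 0.001 * rnorm(10), B = -(1:10), C = 1:10 + 0.5)
  colnames(m) <- sprintf("S%d", 1:10)
  # perfect positive correlation retained everywhere it should be
  pos <- compute_coexpression(m, "A", "C", coexpression_config())
  expect_equal(nrow(pos), 1L)
  expect_gt(pos$coefficient, 0.99)
  # negative pair: retained under absolute, dropped under positive
  neg_abs <- compute_coexpression(m, "A", "B", coexpression_config())
  expect_equal(nrow(neg_abs), 1L)
  expect_lt(neg_abs$coefficient, -0.99)
  neg_pos <- compute_coexpression(
    m, "A", "B", coexpression_config(coefficient_rule = "positive"))
  expect_equal(nrow(neg_pos), 0L)
  neg_neg <- compute_coexpression(
    m, "A", "B", coexpression_config(coefficient_rule = "negative"))
  expect_equal(nrow(neg_neg), 1L)
  # fewer than 3 samples is degenerate
  expect_error(compute_coexpression(m[, 1:2], "A", "B", coexpression_config()),
               ">= 3 samples")
})

test_that("Fisher-z confidence interval covers the planted correlation at the nominal rate", {
  n <- 100; rho <- 0.6; reps <- 200
  covered <- 0
  cfg <- coexpression_config(coefficient_cutoff = 0, p_cutoff = 1)
  set.seed(99)
  for (i in seq_len(reps)) {
    a <- rnorm(n)
    b <- rho * a + sqrt(1 - rho^2) * rnorm(n)
    m <- rbind(A = a, B = b); colnames(m) <- sprintf("S%d", 1:n)
    e <- compute_coexpression(m, "A", "B", cfg)
    if (e$ci_low <= rho && rho <= e$ci_high) covered <- covered + 1
  }
  # 95% nominal; allow Monte-Carlo error (binomial sd ~1.5% at 200 reps)
  expect_gt(covered / reps, 0.90)
})

test_that("co-expression filter intersects per-ncRNA sets; expand grows the pool", {
  nm <- tiny_neighbor_map()
  edges <- data.frame(gene_a = c("NCG01", "NCG02"),
                      gene_b = c("PCG01", "PCG09"),
                      coefficient = c(0.9, 0.8), p_value = c(1e-5, 1e-4),
                      ci_low = NA_real_, ci_high = NA_real_, n_samples = 50L)
  filt <- apply_coexpression(nm, edges, "filter")
  expect_identical(filt$per_ncrna$NCG01, "PCG01")
  expect_identical(filt$per_ncrna$NCG02, character())  # PCG09 not a neighbor

  exp_ <- apply_coexpression(nm, edges, "expand")
  expect_identical(exp_$per_ncrna$NCG01, nm$per_ncrna$NCG01)  # sets unchanged
  expect_true(all(c("PCG09", nm$union_pool) %in% exp_$union_pool))
  # union invariant holds with the expansion pseudo-entry
  expect_identical(exp_$union_pool,
                   sort(unique(unlist(exp_$per_ncrna, use.names = FALSE)),
                        method = "radix"))

  # filtering with no edges empties everything
  none <- apply_coexpression(nm, edges[0, ], "filter")
  expect_length(none$union_pool, 0L)
})

test_that("expand mode always yields a superset of filter mode's pool", {
  set.seed(31)
  for (rep in 1:10) {
    ids_nc <- sprintf("N%d", 1:5)
    ids_pc <- sprintf("P%d", 1:20)
    nm <- neighbor_map(stats::setNames(
      lapply(1:5, function(i) sample(ids_pc, sample(0:8, 1))), ids_nc))
    k <- sample(1:15, 1)
    edges <- data.frame(gene_a = sample(ids_nc, k, replace = TRUE),
                        gene_b = sample(ids_pc, k, replace = TRUE),
                        coefficient = 0.9, p_value = 1e-4,
                        ci_low = NA_real_, ci_high = NA_real_, n_samples = 50L)
    f <- apply_coexpression(nm, edges, "filter")
    e <- apply_coexpression(nm, edges, "expand")
    expect_true(all(f$union_pool %in% e$union_pool))
    for (id in ids_nc) {
      expect_true(all(f$per_ncrna[[id]] %in% nm$per_ncrna[[id]]))
    }
  }
})

test_that("TAD filter keeps co-members, empties unassigned ncRNAs, and assigns straddlers to both sides", {
  ann <- tiny_annotation()
  nm <- neighbor_map(list(NCG01 = c("PCG01", "PCG02")))
  # one TAD containing NCG01 and PCG01 but not PCG02
  tads <- GenomicRanges::GRanges("chr1", IRanges::IRanges(90001, 110000),
                                 name = "TAD_A")
  out <- filter_by_tad(nm, ann, tads)
  expect_identical(out$per_ncrna$NCG01, "PCG01")

  # ncRNA overlapping no TAD loses all neighbors
  tads2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(500000, 600000),
                                  name = "TAD_B")
  suppressMessages(out2 <- filter_by_tad(nm, ann, tads2))
  expect_length(out2$per_ncrna$NCG01, 0L)

  # a gene straddling the boundary belongs to both TADs (any-overlap rule)
  tads3 <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(90001, 105501), c(105500, 130000)),
    name = c("TAD_L", "TAD_R"))
  # PCG01 (105001-106000) straddles; NCG01 lies in TAD_L only
  out3 <- filter_by_tad(nm, ann, tads3)
  expect_true("PCG01" %in% out3$per_ncrna$NCG01)   # shares TAD_L via overlap
  expect_false("PCG02" %in% out3$per_ncrna$NCG01)  # TAD_R only
  expect_error(filter_by_tad(nm, ann, tads3[0]), "empty")
})

test_that("TAD any-overlap assignment matches brute-force enumeration on fixtures", {
  for (s in c(12, 13)) {
    spec <- fixture_spec(seed = s)
    ann <- make_annotation(spec)
    tads <- make_tads(spec, ann)
    nm <- find_cis_neighbors(tiny_ncrnas(sprintf("NCG%04d", 1:30)), ann,
                             search_config())
    out <- filter_by_tad(nm, ann, tads)
    # brute-force: gene -> TADs by interval arithmetic
    g <- ann$genes
    gdf <- data.frame(id = g$gene_id,
                      chrom = as.character(GenomeInfoDb::seqnames(g)),
                      start = GenomicRanges::start(g),
                      end = GenomicRanges::end(g))
    tdf <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(tads)),
                      start = GenomicRanges::start(tads),
                      end = GenomicRanges::end(tads))
    tad_of <- function(id) {
      r <- gdf[gdf$id == id, ]
      which(tdf$chrom == r$chrom & tdf$start <= r$end & tdf$end >= r$start)
    }
    for (r in names(nm$per_ncrna)) {
      mine <- tad_of(r)
      want <- Filter(function(x) length(intersect(tad_of(x), mine)) > 0,
                     nm$per_ncrna[[r]])
      expect_identical(out$per_ncrna[[r]],
                       sort(as.character(want), method = "radix"),
                       info = sprintf("seed %d id %s", s, r))
    }
  }
})

test_that("target filter intersects with the miRNA's targets and warns on missing keys", {
  nm <- tiny_neighbor_map()
  targets <- list(NCG01 = c("PCG02", "PCG03"))
  expect_warning(out <- filter_by_targets(nm, targets), "absent")
  expect_identical(out$per_ncrna$NCG01, "PCG02")
  expect_length(out$per_ncrna$NCG02, 0L)  # no table entry

  # empty table empties everything
  expect_warning(out2 <- filter_by_targets(nm, list()), "absent")
  expect_length(out2$union_pool, 0L)

  # case-insensitive symbol matching with species-prefix stripping
  ann <- tiny_annotation()
  nm2 <- neighbor_map(list(NCG02 = c("PCG01", "PCG04")))
  tt <- list(`MIR-21` = "PCG04")  # matches symbol hsa-mir-21 after stripping
  out3 <- filter_by_targets(nm2, tt, annotation = ann,
                            strip_species_prefix = TRUE)
  expect_identical(out3$per_ncrna$NCG02, "PCG04")
})

test_that("biotype filter keeps or excludes and rejects an empty result", {
  ann <- tiny_annotation()
  ncr <- tiny_ncrnas(c("NCG01", "NCG02"))
  keep <- filter_biotype(ncr, ann, "lincRNA", "keep")
  expect_identical(keep$resolved, "NCG01")
  excl <- filter_biotype(ncr, ann, "lincRNA", "exclude")
  expect_identical(excl$resolved, "NCG02")
  expect_error(filter_biotype(keep, ann, "lincRNA", "exclude"), "removed every")
})

test_that("TAD and target filters commute and all filters shrink their inputs", {
  for (s in c(21, 22)) {
    spec <- fixture_spec(seed = s)
    ann <- make_annotation(spec)
    tads <- make_tads(spec, ann)
    targets <- make_targets(spec, ann)
    nm <- find_cis_neighbors(tiny_ncrnas(sprintf("NCG%04d", 1:30)), ann,
                             search_config())
    a <- suppressWarnings(filter_by_targets(filter_by_tad(nm, ann, tads), targets))
    b <- suppressWarnings(filter_by_tad(filter_by_targets(nm, targets), ann, tads))
    expect_identical(a$per_ncrna, b$per_ncrna)
    for (r in names(nm$per_ncrna)) {
      expect_true(all(a$per_ncrna[[r]] %in% nm$per_ncrna[[r]]))
    }
  }
})
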