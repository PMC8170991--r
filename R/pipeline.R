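#' Known pipeline configuration keys and their defaults
#' @keywords internal
.config_defaults <- function() list(
  # required paths (no defaults)
  input = NULL, gtf = NULL, output_dir = NULL,
  genesets = NULL, term_gene_table = NULL,
  # neighborhood
  upstream = 10000, downstream = 10000, strand_aware = FALSE,
  region_mode = "gene", coding_biotypes = "protein_coding",
  alias_table = NULL,
  # refinement (all optional stages)
  tad_bed = NULL,
  expression = NULL, coexpression_mode = NULL,
  corr_method = "pearson", corr_cutoff = 0.3, corr_rule = "absolute",
  corr_p = 0.05, variance_cutoff = 0.0025, confidence_level = 0.95,
  low_expr_value = NULL, low_expr_fraction = NULL,
  log2_transform = FALSE, mad_cutoff = NULL,
  targets = NULL, strip_species_prefix = FALSE,
  biotype = NULL, biotype_mode = "keep",
  # enrichment
  test = "hypergeometric", min_set_size = 5, padj_method = "BH",
  background = NULL,
  # reporting / reproducibility
  rank_by = "padj", top_n = NULL, graphml = FALSE,
  seed = 1, log_level = "INFO")

#' Validate a pipeline configuration
#'
#' Accepts a YAML file path or a named list. Unknown keys are an error
#' (silent typos are the main practical failure mode of enrichment
#' configuration); missing keys take the package defaults (window 10 kb both
#' sides, variance cutoff 0.0025, correlation cutoff 0.3, p 0.05, confidence
#' level 0.95, minimum term size 5, BH correction).
#'
#' @param raw Path to a YAML file, or a named list of settings.
#' @return A validated `PipelineConfig` list.
#' @export
validate_config <- function(raw) {
  if (is.character(raw) && length(raw) == 1L) {
    raw <- yaml::read_yaml(raw)
  }
  if (!is.list(raw)) stopf("config must be a YAML file path or a named list")
  defaults <- .config_defaults()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown)) {
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, raw, keep.null = TRUE)
  for (key in c("input", "gtf", "output_dir")) {
    if (is.null(cfg[[key]])) stopf("config key '%s' is required", key)
  }
  if (is.null(cfg$genesets) && is.null(cfg$term_gene_table)) {
    stopf("one of 'genesets' (GMT) or 'term_gene_table' (TSV) is required")
  }
  if (cfg$upstream < 0 || cfg$downstream < 0) {
    stopf("'upstream' and 'downstream' must be >= 0")
  }
  if (!cfg$region_mode %in% c("gene", "exon", "intron")) {
    stopf("'region_mode' must be one of gene/exon/intron")
  }
  if (!is.null(cfg$coexpression_mode) &&
      !cfg$coexpression_mode %in% c("filter", "expand")) {
    stopf("'coexpression_mode' must be filter or expand")
  }
  if (!is.null(cfg$coexpression_mode) && is.null(cfg$expression)) {
    stopf("'coexpression_mode' requires 'expression'")
  }
  if (!cfg$test %in% c("hypergeometric", "fisher", "binomial", "chisq")) {
    stopf("'test' must be one of hypergeometric/fisher/binomial/chisq")
  }
  if (!cfg$padj_method %in% c("BH", "bonferroni", "none")) {
    stopf("'padj_method' must be BH, bonferroni or none")
  }
  if (!cfg$biotype_mode %in% c("keep", "exclude")) {
    stopf("'biotype_mode' must be keep or exclude")
  }
  if (!cfg$rank_by %in% c("pval", "padj")) stopf("'rank_by' must be pval or padj")
  if (cfg$min_set_size < 1) stopf("'min_set_size' must be >= 1")
  if (!cfg$log_level %in% names(.log_levels)) {
    stopf("'log_level' must be one of %s", paste(names(.log_levels), collapse = "/"))
  }
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "PipelineConfig")
}

#' Run the full cis-enrichment pipeline
#'
#' Stage order: resolve identifiers, biotype filter (if configured), cis
#' neighborhood search, TAD filter (if configured), co-expression
#' filter/expansion (if configured), miRNA-target filter (if configured),
#' enrichment, reporting. Disabled stages are true no-ops. Outputs written to
#' `cfg$output_dir`: `neighbors.tsv`, `enrichment.tsv`, `dotplot.tsv`,
#' `network_edges.tsv`, `network_nodes.tsv` and `manifest.json` (config,
#' seed, stage-by-stage gene counts, package version — no timestamps, so
#' identical config + seed reproduce byte-identical directories). A stage
#' failure aborts with a stage-labelled error and removes partial outputs.
#'
#' @param cfg A `PipelineConfig` from [validate_config()].
#' @return Invisibly, a list with the enrichment rows, the network, the
#'   neighbor map and the manifest.
#' @export
run_pipeline <- function(cfg) {
  if (!inherits(cfg, "PipelineConfig")) cfg <- validate_config(cfg)
  old_opt <- options(cisenrich.log_level = cfg$log_level)
  on.exit(options(old_opt), add = TRUE)
  set.seed(cfg$seed)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  cleanup_on_error <- function(expr, stage) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stopf("stage %s: %s", stage, conditionMessage(e))
    })
  }
  counts <- list()

  ann <- cleanup_on_error(read_gtf(cfg$gtf, cfg$coding_biotypes), "annotation")
  tokens <- cleanup_on_error(read_text_lines(cfg$input), "input")
  alias <- if (!is.null(cfg$alias_table)) {
    cleanup_on_error(read_alias_table(cfg$alias_table), "input")
  } else NULL
  ncrnas <- cleanup_on_error(resolve_ids(tokens, ann, alias), "resolve")
  counts$resolved <- length(ncrnas$resolved)
  counts$unresolved <- length(ncrnas$unresolved)
  ce_log("INFO", "resolved ", counts$resolved, " of ",
         counts$resolved + counts$unresolved, " input identifiers")

  if (!is.null(cfg$biotype)) {
    ncrnas <- cleanup_on_error(
      filter_biotype(ncrnas, ann, cfg$biotype, cfg$biotype_mode), "biotype")
    counts$after_biotype <- length(ncrnas$resolved)
  }

  scfg <- search_config(cfg$upstream, cfg$downstream, cfg$strand_aware,
                        cfg$region_mode, cfg$coding_biotypes)
  nm <- cleanup_on_error(find_cis_neighbors(ncrnas, ann, scfg), "neighbors")
  counts$pool_after_neighbors <- length(nm$union_pool)
  ce_log("INFO", "cis neighborhood pool: ", length(nm$union_pool), " coding genes")

  if (!is.null(cfg$tad_bed)) {
    tads <- cleanup_on_error(read_bed(cfg$tad_bed), "tad")
    nm <- cleanup_on_error(filter_by_tad(nm, ann, tads), "tad")
    counts$pool_after_tad <- length(nm$union_pool)
  }

  if (!is.null(cfg$coexpression_mode)) {
    ccfg <- coexpression_config(
      method = cfg$corr_method, variance_cutoff = cfg$variance_cutoff,
      coefficient_cutoff = cfg$corr_cutoff, coefficient_rule = cfg$corr_rule,
      p_cutoff = cfg$corr_p, confidence_level = cfg$confidence_level,
      low_expr_value = cfg$low_expr_value,
      low_expr_fraction = cfg$low_expr_fraction,
      log2_transform = cfg$log2_transform, mad_cutoff = cfg$mad_cutoff)
    nm <- cleanup_on_error({
      mat <- prefilter_expression(read_expression(cfg$expression), ccfg)
      real <- names(nm$per_ncrna)[!startsWith(names(nm$per_ncrna), ".")]
      right <- if (cfg$coexpression_mode == "filter") nm$union_pool
               else intersect(rownames(mat),
                              ann$genes$gene_id[ann$genes$biotype %in% cfg$coding_biotypes])
      edges <- compute_coexpression(mat, real, right, ccfg)
      apply_coexpression(nm, edges, cfg$coexpression_mode)
    }, "coexpression")
    counts$pool_after_coexpression <- length(nm$union_pool)
  }

  if (!is.null(cfg$targets)) {
    nm <- cleanup_on_error(
      filter_by_targets(nm, read_target_table(cfg$targets), ann,
                        cfg$strip_species_prefix), "targets")
    counts$pool_after_targets <- length(nm$union_pool)
  }

  collection <- cleanup_on_error(
    if (!is.null(cfg$genesets)) read_gmt(cfg$genesets)
    else read_term_gene_table(cfg$term_gene_table), "genesets")
  background <- if (!is.null(cfg$background)) {
    cleanup_on_error(read_text_lines(cfg$background), "genesets")
  } else NULL
  ecfg <- enrich_config(cfg$test, cfg$min_set_size, cfg$padj_method, background)
  rows <- cleanup_on_error(enrich(nm, collection, ecfg), "enrich")
  counts$terms_reported <- nrow(rows)

  top_n <- cfg$top_n %||% nrow(rows)
  ranked <- if (nrow(rows)) rank_and_select(rows, cfg$rank_by, max(1L, top_n))
            else rows
  network <- build_term_network(ranked, nm)
  cleanup_on_error({
    written <- c(written, write_outputs(ranked, network, cfg$output_dir,
                                         graphml = isTRUE(cfg$graphml)))
    nt <- neighbor_table(nm, ann)
    np <- file.path(cfg$output_dir, "neighbors.tsv")
    utils::write.table(nt, np, sep = "\t", quote = FALSE, row.names = FALSE)
    dd <- dotplot_data(ranked, cfg$rank_by)
    dd$p <- vapply(dd$p, fmt_num, "")
    dp <- file.path(cfg$output_dir, "dotplot.tsv")
    utils::write.table(dd, dp, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <- list(
      package_version = as.character(utils::packageVersion("cisenrich")),
      config = unclass(cfg), seed = cfg$seed, stage_counts = counts)
    mp <- file.path(cfg$output_dir, "manifest.json")
    jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA, null = "null")
    written <- c(written, np, dp, mp)
    manifest
  }, "report") -> manifest

  ce_log("INFO", "wrote ", length(written), " file(s) to ", cfg$output_dir)
  invisible(list(rows = rows, ranked = ranked, network = network,
                 neighbor_map = nm, manifest = manifest))
}
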