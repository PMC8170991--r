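#' Rank enrichment rows and keep the top N
#'
#' Stable ascending sort by the chosen p metric, ties broken by overlap size
#' `k` (descending) then `term_id` (ascending, C locale).
#'
#' @param rows data.frame from [enrich()].
#' @param by `"pval"` or `"padj"`.
#' @param top_n Number of rows to keep (all rows if fewer).
#' @return The selected rows, ranked.
#' @export
rank_and_select <- function(rows, by = c("pval", "padj"), top_n = 10L) {
  by <- match.arg(by)
  if (top_n < 1) stopf("top_n must be >= 1")
  if (!nrow(rows)) return(rows)
  key <- if (by == "pval") rows$p_value else rows$p_adjusted
  ord <- order(key, -rows$k, xtfrm(rows$term_id), method = "radix")
  out <- rows[utils::head(ord, top_n), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Dot-plot table for enrichment results
#'
#' One record per term with the chosen p metric and the overlap size `k`
#' (the dot size), in [rank_and_select()] order.
#'
#' @param rows data.frame from [enrich()].
#' @param by `"pval"` or `"padj"`.
#' @param top_n Number of terms to include (default: all).
#' @return data.frame with columns `term_name`, `p`, `k`.
#' @export
dotplot_data <- function(rows, by = c("pval", "padj"), top_n = nrow(rows)) {
  by <- match.arg(by)
  if (!nrow(rows)) {
    return(data.frame(term_name = character(), p = numeric(), k = integer()))
  }
  sel <- rank_and_select(rows, by, top_n)
  data.frame(term_name = sel$term_name,
             p = if (by == "pval") sel$p_value else sel$p_adjusted,
             k = sel$k)
}

#' Render the dot plot
#'
#' A thin ggplot2 layer over [dotplot_data()]: terms on the y axis, -log10 p
#' on x, dot size = overlap count.
#'
#' @inheritParams dotplot_data
#' @return A ggplot object.
#' @export
plot_enrichment_dotplot <- function(rows, by = c("pval", "padj"),
                                    top_n = min(20L, nrow(rows))) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stopf("ggplot2 is required for plotting")
  }
  dd <- dotplot_data(rows, by, top_n)
  dd$term_name <- factor(dd$term_name, levels = rev(dd$term_name))
  ggplot2::ggplot(dd, ggplot2::aes(x = -log10(p), y = term_name, size = k)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(-log[10](p)), y = NULL, size = "genes") +
    ggplot2::theme_bw()
}

#' Build the clustered term-gene-ncRNA network
#'
#' A bipartite term-gene graph from each row's overlap genes, extended by
#' gene-ncRNA edges for every ncRNA whose neighbor set contains an overlap
#' gene. Nodes are clustered by greedy modularity maximization
#' ([igraph::cluster_fast_greedy()], deterministic).
#'
#' @param rows data.frame from [enrich()].
#' @param nm The `NeighborMap` behind the rows.
#' @return An object of class `TermNetwork`: list with `graph` (igraph),
#'   `nodes` (data.frame: node, type, degree, cluster) and `edges`
#'   (data.frame: source, target, edge_type).
#' @export
build_term_network <- function(rows, nm) {
  stopifnot(inherits(nm, "NeighborMap"))
  real <- names(nm$per_ncrna)[!startsWith(names(nm$per_ncrna), ".")]
  edges <- data.frame(source = character(), target = character(),
                      edge_type = character())
  genes <- character()
  if (nrow(rows)) {
    for (i in seq_len(nrow(rows))) {
      ov <- strsplit(rows$overlap_genes[i], ";", fixed = TRUE)[[1]]
      ov <- ov[nzchar(ov)]
      genes <- union(genes, ov)
      if (length(ov)) {
        edges <- rbind(edges, data.frame(source = rows$term_id[i], target = ov,
                                         edge_type = "term-gene"))
      }
    }
    for (r in sort_c(real)) {
      shared <- intersect(nm$per_ncrna[[r]], genes)
      if (length(shared)) {
        edges <- rbind(edges, data.frame(source = sort_c(shared), target = r,
                                         edge_type = "gene-ncRNA"))
      }
    }
  }
  edges <- unique(edges)
  node_type <- c(
    stats::setNames(rep("term", nrow(rows)), rows$term_id),
    stats::setNames(rep("gene", length(genes)), genes),
    stats::setNames(rep("ncRNA", length(unique(edges$target[edges$edge_type == "gene-ncRNA"]))),
                    unique(edges$target[edges$edge_type == "gene-ncRNA"])))
  if (!nrow(edges)) {
    nodes <- data.frame(node = character(), type = character(),
                        degree = integer(), cluster = integer())
    g <- igraph::make_empty_graph(directed = FALSE)
    return(structure(list(graph = g, nodes = nodes, edges = edges),
                     class = "TermNetwork"))
  }
  g <- igraph::graph_from_data_frame(edges[, c("source", "target")],
                                     directed = FALSE)
  cl <- igraph::cluster_fast_greedy(g)
  memb <- igraph::membership(cl)
  deg <- igraph::degree(g)
  vn <- igraph::V(g)$name
  nodes <- data.frame(node = vn,
                      type = unname(node_type[vn]),
                      degree = as.integer(deg[vn]),
                      cluster = as.integer(memb[vn]))
  nodes <- nodes[order(xtfrm(nodes$node), method = "radix"), , drop = FALSE]
  rownames(nodes) <- NULL
  igraph::V(g)$type_label <- unname(node_type[vn])
  igraph::V(g)$cluster <- as.integer(memb[vn])
  structure(list(graph = g, nodes = nodes, edges = edges),
            class = "TermNetwork")
}

#' @export
print.TermNetwork <- function(x, ...) {
  cat(sprintf("TermNetwork: %d nodes, %d edges, %d cluster(s)\n",
              nrow(x$nodes), nrow(x$edges),
              length(unique(x$nodes$cluster))))
  invisible(x)
}

# format a double so that parsing the string recovers the identical value
fmt_num <- function(x) sprintf("%.17g", x)

#' Write enrichment and network outputs
#'
#' The enrichment table is written with the fixed column order `term_id`,
#' `term_name`, `p_value`, `p_adjusted`, `GeneRatio` (the string `"k/n"`),
#' `BGRatio` (`"K/N"`), `EGNo` (= k), `overlap_genes`, `ncGeneList`
#' (semicolon-joined, sorted). The network is written as an edge list
#' (`source`, `target`, `edge_type`) plus node attributes (`node`, `type`,
#' `degree`, `cluster`), and optionally as GraphML.
#'
#' @param rows data.frame from [enrich()].
#' @param network Optional `TermNetwork` from [build_term_network()].
#' @param dir Output directory (created if absent).
#' @param graphml Also write `network.graphml` (default `FALSE`).
#' @return Invisibly, the paths written.
#' @export
write_outputs <- function(rows, network = NULL, dir, graphml = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  ep <- file.path(dir, "enrichment.tsv")
  tab <- data.frame(
    term_id = rows$term_id,
    term_name = rows$term_name,
    p_value = vapply(rows$p_value, fmt_num, ""),
    p_adjusted = vapply(rows$p_adjusted, fmt_num, ""),
    GeneRatio = sprintf("%d/%d", rows$k, rows$n),
    BGRatio = sprintf("%d/%d", rows$K, rows$N),
    EGNo = rows$k,
    overlap_genes = rows$overlap_genes,
    ncGeneList = rows$contributing_ncrnas,
    check.names = FALSE)
  utils::write.table(tab, ep, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, ep)
  if (!is.null(network)) {
    stopifnot(inherits(network, "TermNetwork"))
    np <- file.path(dir, "network_edges.tsv")
    utils::write.table(network$edges, np, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    ap <- file.path(dir, "network_nodes.tsv")
    utils::write.table(network$nodes, ap, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, np, ap)
    if (graphml && igraph::gorder(network$graph) > 0) {
      gp <- file.path(dir, "network.graphml")
      igraph::write_graph(network$graph, gp, format = "graphml")
      paths <- c(paths, gp)
    }
  }
  invisible(paths)
}

#' Re-read an enrichment table written by [write_outputs()]
#'
#' Inverse of the serialization: reconstructs the numeric counts from the
#' GeneRatio/BGRatio strings.
#'
#' @param path Path to `enrichment.tsv`.
#' @return data.frame in the same shape as [enrich()] output.
#' @export
read_enrichment_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  ratio <- function(s, part) as.integer(vapply(strsplit(s, "/", fixed = TRUE),
                                               `[[`, "", part))
  out <- data.frame(
    term_id = df$term_id,
    term_name = df$term_name,
    p_value = as.numeric(df$p_value),
    p_adjusted = as.numeric(df$p_adjusted),
    k = if (nrow(df)) ratio(df$GeneRatio, 1L) else integer(),
    n = if (nrow(df)) ratio(df$GeneRatio, 2L) else integer(),
    K = if (nrow(df)) ratio(df$BGRatio, 1L) else integer(),
    N = if (nrow(df)) ratio(df$BGRatio, 2L) else integer(),
    overlap_genes = df$overlap_genes,
    contributing_ncrnas = df$ncGeneList,
    stringsAsFactors = FALSE)
  out
}
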