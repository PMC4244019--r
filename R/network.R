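# Interaction-network overlay: induced subgraphs of a user-supplied gene
# interaction edge list over selected gene sets. Remote database lookups are
# deliberately out of scope; any locally supplied edge table works.

#' Read a gene-interaction edge list
#'
#' TSV columns `gene_a`, `gene_b` and optional `score` in \[0, 1\]. Edges are
#' undirected: duplicate unordered pairs are collapsed keeping the maximum
#' score, and self-loop rows are dropped with a warning.
#'
#' @param path edge-list file.
#' @param score_threshold optional minimum score; edges below it are dropped.
#' @return an undirected [igraph::igraph] with a `score` edge attribute when
#'   scores are supplied.
#' @export
read_edge_list <- function(path, score_threshold = NULL) {
  if (!file.exists(path)) .stop2("edge list not found: %s", path)
  d <- read.delim(path, check.names = FALSE, colClasses = "character")
  need <- c("gene_a", "gene_b")
  if (!all(need %in% names(d)))
    .stop2("edge list needs columns gene_a, gene_b (optional score)")
  has_score <- "score" %in% names(d)
  if (has_score) {
    d$score <- as.numeric(d$score)
    if (anyNA(d$score) || any(d$score < 0 | d$score > 1))
      .stop2("edge scores must be numeric in [0, 1]")
  }
  loops <- d$gene_a == d$gene_b
  if (any(loops)) {
    warning(sprintf("dropping %d self-loop edge(s)", sum(loops)))
    d <- d[!loops, , drop = FALSE]
  }
  if (nrow(d) == 0L)
    return(igraph::make_empty_graph(0, directed = FALSE))
  # normalize unordered pairs, collapse duplicates keeping max score
  a <- pmin(d$gene_a, d$gene_b); b <- pmax(d$gene_a, d$gene_b)
  key <- paste(a, b, sep = "\r")
  if (has_score) {
    sc <- tapply(d$score, key, max)
    keys <- names(sc)
  } else {
    keys <- unique(key)
  }
  parts <- strsplit(keys, "\r", fixed = TRUE)
  edges <- cbind(vapply(parts, `[[`, "", 1L), vapply(parts, `[[`, "", 2L))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  if (has_score) igraph::E(g)$score <- as.numeric(sc)
  if (!is.null(score_threshold) && has_score)
    g <- igraph::delete_edges(g, igraph::E(g)[igraph::E(g)$score < score_threshold])
  g
}

#' Induced subgraph over a gene set
#'
#' Returns the graph whose nodes are exactly `genes` (genes absent from the
#' parent graph become isolated nodes) and whose edges are the parent's edges
#' with both ends in `genes`. Idempotent.
#'
#' @param g an undirected [igraph::igraph] with gene-symbol vertex names.
#' @param genes character vector of gene symbols.
#' @return an [igraph::igraph].
#' @export
induced_gene_subgraph <- function(g, genes) {
  stopifnot(igraph::is_igraph(g))
  genes <- unique(as.character(genes))
  present <- intersect(genes, igraph::V(g)$name)
  sub <- igraph::induced_subgraph(g, present)
  missing_g <- setdiff(genes, present)
  if (length(missing_g)) sub <- igraph::add_vertices(sub, length(missing_g), name = missing_g)
  sub
}

#' Number of genes with at least one interaction
#'
#' @param g an [igraph::igraph], typically from [induced_gene_subgraph()].
#' @return count of nodes with degree >= 1.
#' @export
count_interacting_genes <- function(g) {
  stopifnot(igraph::is_igraph(g))
  sum(igraph::degree(g) >= 1)
}

#' Write a graph back to the edge-list dialect
#'
#' @param g an [igraph::igraph].
#' @param path output TSV.
#' @return the path, invisibly.
#' @export
write_edge_list <- function(g, path) {
  stopifnot(igraph::is_igraph(g))
  el <- igraph::as_edgelist(g)
  d <- data.frame(gene_a = el[, 1], gene_b = el[, 2], stringsAsFactors = FALSE)
  if ("score" %in% igraph::edge_attr_names(g)) d$score <- igraph::E(g)$score
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
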