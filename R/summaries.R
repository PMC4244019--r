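# Top-N gene selection, hierarchical clustering of cell-type profiles, and
# publication-style table exports.

#' Top-N up- or down-regulated genes for a telocyte condition
#'
#' Ranks genes by their aggregated fold across the comparisons of the
#' selected design (descending), with ties broken lexicographically by gene
#' symbol, and returns the first `n`. The default aggregate, `min`, is the
#' same statistic the consistency classifier bins, so a gene's rank reflects
#' its weakest comparison; `mean` is offered as an alternative (infinite
#' sentinel folds are excluded from the mean when finite values exist).
#'
#' @param rt a `ratio_table`.
#' @param mode `"TC5"`, `"TC10"` or `"combined"` — which comparisons to
#'   aggregate over.
#' @param direction `"up"` or `"down"`.
#' @param n number of genes to return (clamped to the number available).
#' @param aggregate `"min"` or `"mean"`.
#' @return character vector of gene symbols, ranked.
#' @export
top_n_genes <- function(rt, mode = c("combined", "TC5", "TC10"),
                        direction = c("up", "down"), n = 50L,
                        aggregate = c("min", "mean")) {
  mode <- match.arg(mode); direction <- match.arg(direction)
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(rt, "ratio_table"), n >= 1L)
  cols <- .mode_columns(rt, mode)
  m <- rt$ratios[, cols, drop = FALSE]
  if (nrow(m) == 0L) return(character(0))
  score_mat <- if (direction == "up") {
    ifelse(m <= -1, Inf, -m / (1 + m))  # signed up-fold; negative when r > 0
  } else {
    m
  }
  agg_fun <- if (aggregate == "min") {
    function(v) min(v)
  } else {
    function(v) if (any(is.finite(v))) mean(v[is.finite(v)]) else Inf
  }
  score <- apply(score_mat, 1L, agg_fun)
  ord <- order(-score, rownames(m))
  head(rownames(m)[ord], n)
}

#' Hierarchically cluster cell-type conditions
#'
#' Computes a condition dendrogram on `log2(mean + 1)`-transformed profile
#' values over a gene subset, with correlation distance (1 - Pearson) and
#' average linkage — the standard recipe for expression-profile dendrograms.
#' Deterministic given input order; identical condition columns merge at
#' height 0.
#'
#' @param profile a [cell_profile()] with at least two conditions.
#' @param genes optional character vector of genes to cluster on (default:
#'   all genes in the profile).
#' @param distance only `"one_minus_pearson"` is implemented.
#' @param linkage only `"average"` is implemented.
#' @return an object of class `hclust` over the condition labels.
#' @export
cluster_conditions <- function(profile, genes = NULL,
                               distance = c("one_minus_pearson"),
                               linkage = c("average")) {
  distance <- match.arg(distance); linkage <- match.arg(linkage)
  stopifnot(inherits(profile, "cell_profile"))
  m <- profile$means
  if (!is.null(genes)) {
    missing_g <- setdiff(genes, rownames(m))
    if (length(missing_g))
      .stop2("gene(s) absent from profile: %s", paste(head(missing_g, 5L), collapse = ", "))
    m <- m[genes, , drop = FALSE]
  }
  if (nrow(m) == 0L) .stop2("gene subset is empty")
  if (ncol(m) < 2L) .stop2("need at least two conditions to cluster")
  lm2 <- log2(m + 1)
  sds <- apply(lm2, 2L, stats::sd)
  if (any(sds == 0))
    .stop2("condition(s) with zero variance (degenerate correlation): %s",
           paste(colnames(m)[sds == 0], collapse = ", "))
  d <- as.dist(1 - cor(lm2))
  hclust(d, method = "average")
}

#' Export a condition dendrogram as Newick
#'
#' Branch lengths are merge-height differences (the `ape` phylo conversion
#' of an `hclust` tree).
#'
#' @param hc an `hclust` object from [cluster_conditions()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_dendrogram_newick <- function(hc, path) {
  stopifnot(inherits(hc, "hclust"))
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Export screen results as publication-style summary tables
#'
#' Writes, into `out_dir`:
#' \itemize{
#'   \item `classifications.tsv` — gene, direction, min_fold, bin, mode;
#'   \item `counts_up.tsv`, `counts_down.tsv` — cumulative >0/>1/>4 and
#'     per-bin counts;
#'   \item `genes_<direction>_<bin>.tsv` — per-bin gene fold tables in the
#'     published `a/b` pair dialect (round-trippable with
#'     [read_ratio_table()] at the declared precision);
#'   \item `heatmap_top_<direction>.tsv` — genes-by-comparisons signed
#'     `log2(mean_comparator/mean_TC)` matrices for the top-`top_n` gene
#'     sets of each direction (sentinel ratios floored).
#' }
#'
#' @param screen a [fold_screen()].
#' @param rt the `ratio_table` the screen was computed from (full design).
#' @param out_dir output directory, created if needed.
#' @param top_n size of the top gene sets exported for heatmaps.
#' @return character vector of the files written, invisibly.
#' @export
export_summary_tables <- function(screen, rt, out_dir, top_n = 50L) {
  stopifnot(inherits(screen, "fold_screen"), inherits(rt, "ratio_table"))
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    .stop2("cannot create output directory %s", out_dir)
  files <- character(0)
  w <- function(name) { f <- file.path(out_dir, name); files <<- c(files, f); f }

  cls <- screen$classifications
  cls_out <- cls[c("gene", "direction", "min_fold", "bin")]
  cls_out$mode <- rep(screen$mode, nrow(cls_out))
  write.table(cls_out, w("classifications.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  for (dir in c("up", "down")) {
    tc <- screen$counts[[dir]]
    cnt <- data.frame(threshold = c(">0", ">1", ">4"),
                      cumulative = unlist(tc$cumulative),
                      bin = .bin_levels, bin_count = unlist(tc$bins))
    write.table(cnt, w(sprintf("counts_%s.tsv", dir)), sep = "\t",
                quote = FALSE, row.names = FALSE)
    for (b in .bin_levels) {
      genes_b <- cls$gene[cls$direction == dir & !is.na(cls$bin) & cls$bin == b]
      sub <- ratio_table_new(rt$ratios[genes_b, , drop = FALSE],
                             rt$comparisons, precision = min(rt$precision, 2L))
      tag <- c("(0,1]" = "0_1", "(1,4]" = "1_4", "(4,Inf)" = "4_inf")[[b]]
      write_ratio_table(sub, w(sprintf("genes_%s_%s.tsv", dir, tag)))
    }
    top <- top_n_genes(rt, mode = screen$mode, direction = dir, n = top_n)
    m <- rt$ratios[top, , drop = FALSE]
    # signed log2 expression ratio comparator/TC; sentinel -1 floored
    hm <- log2(pmax(1 + m, 2^-20))
    hm_out <- data.frame(gene = rownames(hm), hm, check.names = FALSE)
    write.table(hm_out, w(sprintf("heatmap_top_%s.tsv", dir)), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(files)
}
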