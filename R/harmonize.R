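# Cross-study harmonization: normalization, replicate averaging into
# per-cell-type mean profiles, symbol-intersection merging, chromosome
# restriction.

#' Construct a cell-type mean-intensity profile
#'
#' A `cell_profile` is a genes-by-conditions matrix of non-negative mean
#' intensities with an optional per-gene chromosome label.
#'
#' @param means numeric matrix, genes in rows (named), conditions in columns
#'   (named, drawn from [tc_conditions()]).
#' @param chromosome optional named character vector of chromosome labels.
#' @return object of class `cell_profile`.
#' @export
cell_profile <- function(means, chromosome = NULL) {
  stopifnot(is.matrix(means), is.numeric(means))
  if (nrow(means) > 0L && is.null(rownames(means)))
    .stop2("cell profile requires gene row names")
  if (is.null(rownames(means))) rownames(means) <- character(0)
  if (is.null(colnames(means)))
    .stop2("cell profile requires condition column names")
  if (anyDuplicated(colnames(means))) .stop2("duplicate condition in cell profile")
  bad <- setdiff(colnames(means), tc_conditions())
  if (length(bad)) .stop2("unknown condition(s): %s", paste(bad, collapse = ", "))
  if (any(means < 0)) .stop2("cell profile means must be >= 0")
  if (!is.null(chromosome)) chromosome <- chromosome[rownames(means)]
  structure(list(means = means, chromosome = chromosome), class = "cell_profile")
}

#' @export
print.cell_profile <- function(x, ...) {
  cat(sprintf("cell_profile: %d genes x %d conditions (%s)\n",
              nrow(x$means), ncol(x$means), paste(colnames(x$means), collapse = ", ")))
  invisible(x)
}

#' @export
dim.cell_profile <- function(x) dim(x$means)

#' Normalize samples of a gene matrix
#'
#' `"none"` is the identity. `"median_scale"` multiplies each sample so its
#' median equals the global median of the input per-sample medians — a pure
#' per-sample scale transform that leaves within-sample value ratios
#' unchanged. `"quantile"` replaces each sample's sorted values by the mean
#' of the order statistics across samples, so all samples share one value
#' distribution (ties receive the mean of their reference values).
#'
#' @param gm a `gene_matrix` (see [aggregate_probes_to_genes()]) or any
#'   non-negative numeric matrix with genes in rows and samples in columns.
#' @param method one of `"none"`, `"median_scale"`, `"quantile"`.
#' @return matrix of the same shape and attributes.
#' @export
normalize_samples <- function(gm, method = c("none", "median_scale", "quantile")) {
  method <- match.arg(method)
  stopifnot(is.matrix(gm), is.numeric(gm), ncol(gm) >= 1L)
  if (any(gm < 0)) .stop2("normalize_samples expects non-negative values")
  if (method == "none") return(gm)
  out <- gm
  if (method == "median_scale") {
    med <- apply(gm, 2L, median)
    if (any(med == 0))
      .stop2("degenerate sample(s) with zero median under median_scale: %s",
             paste(colnames(gm)[med == 0], collapse = ", "))
    target <- median(med)
    out[] <- sweep(gm, 2L, target / med, `*`)
  } else {  # quantile
    n <- nrow(gm)
    sorted <- apply(gm, 2L, sort)
    ref <- rowMeans(sorted)
    for (j in seq_len(ncol(gm))) {
      rk <- rank(gm[, j], ties.method = "average")
      # interpolate reference at fractional ranks so ties share one value
      out[, j] <- approx(seq_len(n), ref, xout = rk, rule = 2)$y
    }
  }
  out
}

#' Average replicate samples into per-condition mean profiles
#'
#' For each cell-type condition, takes the arithmetic mean across all of its
#' samples (pooled with equal weight across studies). Conditions with no
#' samples in `gm` are absent from the output.
#'
#' @param gm a `gene_matrix` (genes x samples).
#' @param sheet a [read_sample_sheet()] covering every sample in `gm`.
#' @return a [cell_profile()].
#' @export
average_by_cell_type <- function(gm, sheet) {
  stopifnot(is.matrix(gm))
  sheet <- as_sample_sheet(as.data.frame(sheet))
  idx <- match(colnames(gm), sheet$sample_id)
  if (anyNA(idx))
    .stop2("sample(s) missing from sample sheet: %s",
           paste(colnames(gm)[is.na(idx)], collapse = ", "))
  cond <- sheet$condition[idx]
  levels_present <- tc_conditions()[tc_conditions() %in% cond]
  means <- vapply(levels_present, function(cc)
    rowMeans(gm[, cond == cc, drop = FALSE]), numeric(nrow(gm)))
  if (nrow(gm) == 1L) means <- matrix(means, nrow = 1L,
                                      dimnames = list(rownames(gm), levels_present))
  cell_profile(means, chromosome = attr(gm, "chromosome"))
}

#' Merge cell-type profiles from different studies on shared gene symbols
#'
#' Restricts every profile to the intersection of their gene symbol sets and
#' binds the (disjoint) condition sets together. The number of genes dropped
#' from each input is reported as a message; an empty intersection yields an
#' empty profile with a warning, not an error.
#'
#' @param profiles list of two or more [cell_profile()] objects with disjoint
#'   condition sets.
#' @return a merged [cell_profile()].
#' @export
merge_on_shared_genes <- function(profiles) {
  stopifnot(is.list(profiles), length(profiles) >= 2L)
  lapply(profiles, function(p) stopifnot(inherits(p, "cell_profile")))
  conds <- unlist(lapply(profiles, function(p) colnames(p$means)))
  if (anyDuplicated(conds))
    .stop2("condition(s) present in more than one profile: %s",
           paste(unique(conds[duplicated(conds)]), collapse = ", "))
  gene_sets <- lapply(profiles, function(p) rownames(p$means))
  shared <- Reduce(intersect, gene_sets)
  for (k in seq_along(profiles))
    message(sprintf("merge_on_shared_genes: input %d drops %d of %d genes",
                    k, length(gene_sets[[k]]) - length(shared), length(gene_sets[[k]])))
  if (length(shared) == 0L) {
    warning("merge_on_shared_genes: no shared gene symbols; returning empty profile")
    means <- matrix(numeric(0), nrow = 0L, ncol = length(conds),
                    dimnames = list(character(0), conds))
    return(cell_profile(means))
  }
  means <- do.call(cbind, lapply(profiles, function(p) p$means[shared, , drop = FALSE]))
  chrom <- NULL
  for (p in profiles) {
    if (!is.null(p$chromosome)) { chrom <- p$chromosome[shared]; break }
  }
  cell_profile(means, chromosome = chrom)
}

#' Restrict a profile to one chromosome
#'
#' Keeps only the genes annotated to `chrom`, preserving order. In the
#' original telocyte study this step reduced 11,545 genes to 917 on
#' chromosome 2 and 567 on chromosome 3.
#'
#' @param profile a [cell_profile()] whose genes all carry chromosome labels.
#' @param chrom chromosome label, e.g. `"2"`.
#' @return a [cell_profile()].
#' @export
restrict_to_chromosome <- function(profile, chrom) {
  stopifnot(inherits(profile, "cell_profile"))
  ch <- profile$chromosome
  if (is.null(ch)) .stop2("profile carries no chromosome labels")
  nolabel <- rownames(profile$means)[is.na(ch) | !nzchar(ch)]
  if (length(nolabel))
    .stop2("gene(s) lacking a chromosome label: %s", paste(head(nolabel, 5L), collapse = ", "))
  keep <- ch == chrom
  if (!any(keep))
    warning(sprintf("restrict_to_chromosome: no genes on chromosome %s", chrom))
  cell_profile(profile$means[keep, , drop = FALSE], chromosome = ch[keep])
}
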