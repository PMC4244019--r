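# The core computation: relative-ratio folds against every comparator,
# the all-comparisons consistency rule, threshold binning at >0/>1/>4, and
# the count tables.
#
# Sign convention (decoded from the published tables): the stored ratio is
#   r = mean_comparator / mean_TC - 1,
# so genes up-regulated in telocytes carry NEGATIVE ratios. The up-fold the
# bin labels refer to is u = -r/(1+r) = mean_TC/mean_comparator - 1, with
# exact bin boundaries u(-0.5) = 1 and u(-0.8) = 4. Down-folds are the
# positive ratios themselves. A ratio of exactly -1 is the comparator-
# near-zero sentinel (u = +Inf).

#' Relative ratios of comparator cell types against a telocyte condition
#'
#' For each gene g and comparator c computes
#' `r = mean_c(g) / max(mean_tc(g), eps) - 1`. The ratio is negative exactly
#' when the telocyte mean exceeds the comparator mean. A comparator mean of 0
#' gives the sentinel value -1.
#'
#' @param profile a [cell_profile()] containing `tc_condition` and all
#'   comparators.
#' @param tc_condition `"TC_D5"` or `"TC_D10"`.
#' @param comparators character vector of comparator conditions (default: the
#'   seven non-telocyte conditions present in the profile).
#' @param eps positive floor for the telocyte mean, guarding division by
#'   zero. Default: `1e-8` times the global median intensity (or `1e-8` if
#'   that median is 0).
#' @return a [ratio_table_new()] with one comparison per comparator.
#' @export
compute_ratios <- function(profile, tc_condition = c("TC_D5", "TC_D10"),
                           comparators = NULL, eps = NULL) {
  stopifnot(inherits(profile, "cell_profile"))
  tc_condition <- match.arg(tc_condition)
  if (is.null(comparators))
    comparators <- intersect(tc_comparator_conditions(), colnames(profile$means))
  if (length(comparators) == 0L) .stop2("comparator list is empty")
  if (any(comparators %in% tc_reference_conditions()))
    .stop2("telocyte conditions cannot serve as comparators")
  missing_cond <- setdiff(c(tc_condition, comparators), colnames(profile$means))
  if (length(missing_cond))
    .stop2("condition(s) absent from profile: %s", paste(missing_cond, collapse = ", "))
  if (is.null(eps)) {
    gm <- median(profile$means)
    eps <- if (is.na(gm) || gm <= 0) 1e-8 else 1e-8 * gm
  }
  stopifnot(eps > 0)
  tc <- pmax(profile$means[, tc_condition], eps)
  ratios <- profile$means[, comparators, drop = FALSE] / tc - 1
  rownames(ratios) <- rownames(profile$means)
  ratio_table_new(ratios,
                  data.frame(tc = tc_condition, other = comparators,
                             stringsAsFactors = FALSE),
                  precision = 15L)
}

#' Full 14-comparison ratio table for the combined telocyte design
#'
#' Convenience wrapper around [compute_ratios()] producing the full design:
#' both telocyte conditions against each of the comparators.
#'
#' @inheritParams compute_ratios
#' @return a `ratio_table` with `2 * length(comparators)` comparisons.
#' @export
ratio_table <- function(profile, comparators = NULL, eps = NULL) {
  r5 <- compute_ratios(profile, "TC_D5", comparators, eps)
  r10 <- compute_ratios(profile, "TC_D10", comparators, eps)
  comps <- rbind(r5$comparisons, r10$comparisons)
  ord <- order(match(comps$other, tc_comparator_conditions()),
               match(comps$tc, tc_reference_conditions()))
  ratios <- cbind(r5$ratios, r10$ratios)[, ord, drop = FALSE]
  ratio_table_new(ratios, comps[ord, ], precision = 15L)
}

#' Up- and down-regulation folds from a relative ratio
#'
#' `up_fold()` maps a non-positive ratio to the telocyte-side fold
#' `u = -r/(1+r) = mean_TC/mean_comparator - 1`; the sentinel `r = -1`
#' (comparator mean near zero) maps to `+Inf`. `down_fold()` is the identity
#' on non-negative ratios, matching the published down-regulation folds.
#' Ratios on the wrong side of zero by more than `tol` are domain errors;
#' ratios within `tol` of zero are clamped to the boundary (fold 0).
#'
#' @param r numeric vector of relative ratios.
#' @param tol boundary tolerance (default 0.005, half a unit in the last
#'   printed decimal of 2-decimal sources).
#' @return numeric vector of non-negative folds (possibly `Inf` for
#'   `up_fold`).
#' @export
#' @examples
#' up_fold(c(-0.5, -0.8))  # the bin boundaries: 1 and 4
up_fold <- function(r, tol = 0.005) {
  if (any(r > tol)) .stop2("up_fold: ratio %.4g exceeds tolerance; gene is not up-regulated in this comparison", max(r))
  rc <- pmin(r, 0)
  u <- ifelse(rc <= -1, Inf, -rc / (1 + rc))
  u
}

#' @rdname up_fold
#' @export
down_fold <- function(r, tol = 0.005) {
  if (any(r < -tol)) .stop2("down_fold: ratio %.4g below -tolerance; gene is not down-regulated in this comparison", min(r))
  pmax(r, 0)
}

.bin_levels <- c("(0,1]", "(1,4]", "(4,Inf)")

.bin_from_fold <- function(min_fold, tol) {
  ifelse(min_fold >= 4 - tol, "(4,Inf)",
         ifelse(min_fold >= 1 - tol, "(1,4]", "(0,1]"))
}

.mode_columns <- function(rt, mode) {
  comps <- rt$comparisons
  sel <- switch(mode,
                TC5 = comps$tc == "TC_D5",
                TC10 = comps$tc == "TC_D10",
                combined = rep(TRUE, nrow(comps)))
  n_needed <- switch(mode, TC5 = , TC10 = length(tc_comparator_conditions()),
                     combined = 2L * length(tc_comparator_conditions()))
  have <- comps[sel, , drop = FALSE]
  full <- expand.grid(tc = switch(mode, TC5 = "TC_D5", TC10 = "TC_D10",
                                  combined = tc_reference_conditions()),
                      other = tc_comparator_conditions(),
                      stringsAsFactors = FALSE)
  missing_cmp <- setdiff(paste(full$tc, full$other), paste(have$tc, have$other))
  if (length(missing_cmp))
    .stop2("incomplete design for mode '%s': missing comparison(s) %s",
           mode, paste(missing_cmp, collapse = ", "))
  which(sel)
}

#' Classify one gene by the all-comparisons consistency rule
#'
#' A gene is telocyte-up only if every selected ratio is `<= tol`, and
#' telocyte-down only if every selected ratio is `>= -tol`; anything else is
#' unclassified, as is a gene whose ratios all sit within `tol` of zero
#' (it satisfies both conditions and carries no direction evidence).
#' The minimum fold across the selected comparisons (ratios
#' within `tol` of zero clamped to the boundary) determines the bin: the
#' largest threshold `t` in \{0, 1, 4\} with `min_fold >= t - tol`, reported
#' as `(0,1]`, `(1,4]` or `(4,Inf)`.
#'
#' @param ratios named numeric vector: one gene's row of a `ratio_table`.
#' @param comparisons the ratio table's comparison data frame (columns `tc`,
#'   `other`), aligned with `ratios`.
#' @param mode `"TC5"`, `"TC10"` (7 comparisons) or `"combined"` (14).
#' @param tol boundary tolerance; default 0.005 matches 2-decimal printed
#'   sources.
#' @return one-row data frame: `gene`, `direction`, `min_fold`, `bin`,
#'   `comparisons_used`.
#' @export
classify_gene <- function(ratios, comparisons, mode = c("combined", "TC5", "TC10"),
                          tol = 0.005) {
  mode <- match.arg(mode)
  rt <- ratio_table_new(matrix(ratios, nrow = 1L,
                               dimnames = list("gene", NULL)),
                        comparisons, precision = 15L)
  cols <- .mode_columns(rt, mode)
  r <- ratios[cols]
  up_ok <- all(r <= tol); down_ok <- all(r >= -tol)
  if (up_ok && down_ok) {
    # every ratio within tolerance of zero: no direction evidence
    direction <- "unclassified"
    min_fold <- NA_real_
  } else if (up_ok) {
    direction <- "up"
    min_fold <- min(up_fold(r, tol))
  } else if (down_ok) {
    direction <- "down"
    min_fold <- min(down_fold(r, tol))
  } else {
    direction <- "unclassified"
    min_fold <- NA_real_
  }
  data.frame(direction = direction, min_fold = min_fold,
             bin = if (direction == "unclassified") NA_character_ else .bin_from_fold(min_fold, tol),
             comparisons_used = length(cols), stringsAsFactors = FALSE)
}

#' Consistency-classify every gene of a ratio table
#'
#' Vectorized over genes; equivalent to applying [classify_gene()] row by
#' row. The combined-mode up (down) set is exactly the intersection of the
#' TC5- and TC10-mode up (down) sets.
#'
#' @param rt a `ratio_table` complete for the requested mode.
#' @inheritParams classify_gene
#' @return data frame with one row per gene: `gene`, `direction`,
#'   `min_fold`, `bin`, `comparisons_used`.
#' @export
classify_all <- function(rt, mode = c("combined", "TC5", "TC10"), tol = 0.005) {
  mode <- match.arg(mode)
  stopifnot(inherits(rt, "ratio_table"))
  cols <- .mode_columns(rt, mode)
  m <- rt$ratios[, cols, drop = FALSE]
  n <- nrow(m)
  if (n == 0L)
    return(data.frame(gene = character(0), direction = character(0),
                      min_fold = numeric(0), bin = character(0),
                      comparisons_used = integer(0), stringsAsFactors = FALSE))
  up_ok <- rowSums(m > tol) == 0L
  down_ok <- rowSums(m < -tol) == 0L
  is_up <- up_ok & !down_ok
  is_down <- down_ok & !up_ok  # all-ties genes carry no direction evidence
  direction <- ifelse(is_up, "up", ifelse(is_down, "down", "unclassified"))
  # up-folds with clamped boundary; sentinel -1 -> Inf
  rc <- pmin(m, 0)
  u <- ifelse(rc <= -1, Inf, -rc / (1 + rc))
  d <- pmax(m, 0)
  min_fold <- rep(NA_real_, n)
  min_fold[is_up] <- apply(u[is_up, , drop = FALSE], 1L, min)
  min_fold[is_down] <- apply(d[is_down, , drop = FALSE], 1L, min)
  bin <- rep(NA_character_, n)
  cls <- direction != "unclassified"
  bin[cls] <- .bin_from_fold(min_fold[cls], tol)
  data.frame(gene = rownames(m), direction = direction, min_fold = min_fold,
             bin = bin, comparisons_used = length(cols),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Screen a ratio table or cell-type profile for telocyte-specific genes
#'
#' The package's main entry point. Applies the all-comparisons consistency
#' classifier ([classify_all()]) and tabulates the up- and down-regulated
#' gene counts at the >0, >1 and >4 thresholds.
#'
#' @param x a `ratio_table`, or a [cell_profile()] (ratios are then computed
#'   with [ratio_table()] first).
#' @inheritParams classify_gene
#' @param eps telocyte-mean floor, passed to [compute_ratios()] when `x` is a
#'   profile.
#' @return object of class `fold_screen`: list with elements
#'   `classifications` (the [classify_all()] data frame), `counts` (list of
#'   up/down [threshold_counts()]), `mode`, `tol` and `n_genes`. Methods:
#'   `print`, `summary`, `as.data.frame`.
#' @export
#' @examples
#' path <- system.file("extdata", "chr2_up_folds.tsv", package = "telofold")
#' scr <- fold_screen(read_ratio_table(path))
#' summary(scr)
fold_screen <- function(x, mode = c("combined", "TC5", "TC10"), tol = 0.005,
                        eps = NULL) {
  mode <- match.arg(mode)
  if (inherits(x, "cell_profile")) x <- ratio_table(x, eps = eps)
  stopifnot(inherits(x, "ratio_table"))
  cls <- classify_all(x, mode = mode, tol = tol)
  counts <- list(up = threshold_counts(cls, "up", tol = tol),
                 down = threshold_counts(cls, "down", tol = tol))
  structure(list(classifications = cls, counts = counts, mode = mode,
                 tol = tol, n_genes = nrow(cls)),
            class = "fold_screen")
}

#' @export
print.fold_screen <- function(x, ...) {
  cat(sprintf("fold_screen (mode %s, tol %g): %d genes\n", x$mode, x$tol, x$n_genes))
  tab <- table(factor(x$classifications$direction, c("up", "down", "unclassified")))
  cat(sprintf("  up %d | down %d | unclassified %d\n", tab["up"], tab["down"],
              tab["unclassified"]))
  invisible(x)
}

#' @export
summary.fold_screen <- function(object, ...) {
  up <- object$counts$up; down <- object$counts$down
  out <- data.frame(
    direction = c("up", "down"),
    `>0` = c(up$cumulative[[">0"]], down$cumulative[[">0"]]),
    `>1` = c(up$cumulative[[">1"]], down$cumulative[[">1"]]),
    `>4` = c(up$cumulative[[">4"]], down$cumulative[[">4"]]),
    check.names = FALSE)
  structure(list(mode = object$mode, tol = object$tol, n_genes = object$n_genes,
                 table = out, counts = object$counts),
            class = "summary.fold_screen")
}

#' @export
print.summary.fold_screen <- function(x, ...) {
  cat(sprintf("Fold-consistency screen: %d genes, mode %s, tolerance %g\n",
              x$n_genes, x$mode, x$tol))
  cat(sprintf("Compared pairs/fold regulated (mode %s)\n", x$mode))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.fold_screen <- function(x, ...) x$classifications

#' Cumulative and per-bin gene counts at the fold thresholds
#'
#' Counts classified genes of one direction cumulatively at the >0, >1 and
#' >4 thresholds (applied boundary-inclusively as `min_fold >= t - tol`) and
#' per bin. The invariants `count(>0) >= count(>1) >= count(>4)`,
#' `sum(bins) = count(>0)` and `count(>1) = bin(1,4] + bin(4,Inf)` hold by
#' construction.
#'
#' @param cls a classification data frame from [classify_all()], or a
#'   `fold_screen`.
#' @param direction `"up"` or `"down"`.
#' @param tol boundary tolerance used for the cumulative thresholds.
#' @return list with elements `direction`, `mode` (comparisons used),
#'   `cumulative` (named counts at `>0`, `>1`, `>4`) and `bins` (named counts
#'   for the three bins).
#' @export
threshold_counts <- function(cls, direction = c("up", "down"), tol = 0.005) {
  direction <- match.arg(direction)
  if (inherits(cls, "fold_screen")) cls <- cls$classifications
  if (nrow(cls) && length(unique(cls$comparisons_used)) > 1L)
    .stop2("threshold_counts: classifications mix modes (comparisons_used differs)")
  sel <- cls[cls$direction == direction, , drop = FALSE]
  mf <- sel$min_fold
  cum <- c(">0" = nrow(sel),
           ">1" = sum(mf >= 1 - tol),
           ">4" = sum(mf >= 4 - tol))
  bins <- table(factor(sel$bin, levels = .bin_levels))
  list(direction = direction,
       comparisons_used = if (nrow(cls)) cls$comparisons_used[1] else NA_integer_,
       cumulative = as.list(cum),
       bins = as.list(setNames(as.integer(bins), .bin_levels)))
}

#' Single-comparison up/down gene counts
#'
#' For one (telocyte condition, comparator) column, counts genes up- and
#' down-regulated at each threshold: a gene is up at `>t` iff its ratio is
#' below `-tol` and its up-fold is `>= t - tol` (symmetrically for down).
#' Ties (`|r| <= tol`) count toward neither direction.
#'
#' @param rt a `ratio_table`.
#' @param tc_condition `"TC_D5"` or `"TC_D10"`.
#' @param comparator one of [tc_comparator_conditions()].
#' @param tol boundary tolerance.
#' @return list with `up` and `down` (each named counts at `>0`, `>1`,
#'   `>4`) and `ties`.
#' @export
pairwise_direction_counts <- function(rt, tc_condition, comparator, tol = 0.005) {
  stopifnot(inherits(rt, "ratio_table"))
  key <- paste0(tc_condition, "_vs_", comparator)
  if (!key %in% colnames(rt$ratios))
    .stop2("comparison %s not present in ratio table", key)
  r <- rt$ratios[, key]
  is_up <- r < -tol
  is_down <- r > tol
  u <- ifelse(r <= -1, Inf, -r / (1 + r))
  up <- c(">0" = sum(is_up),
          ">1" = sum(is_up & u >= 1 - tol),
          ">4" = sum(is_up & u >= 4 - tol))
  down <- c(">0" = sum(is_down),
            ">1" = sum(is_down & r >= 1 - tol),
            ">4" = sum(is_down & r >= 4 - tol))
  list(up = as.list(up), down = as.list(down), ties = sum(!is_up & !is_down))
}
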