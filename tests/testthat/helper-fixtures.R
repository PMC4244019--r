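# In-code fixture builders shared across the suite.

toy_probe_matrix <- function() {
  m <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 3, byrow = TRUE,
              dimnames = list(c("p1", "p2", "p3"), c("s1", "s2")))
  probe_matrix(m, study_id = "toy")
}

write_tsv_lines <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

toy_annotation <- function() {
  as_probe_annotation(data.frame(
    probe_id = c("p1", "p2", "p3", "p4", "p5"),
    symbol = c("GA", "GA", "GB", "", ""),
    chromosome = c("2", "2", "3", "", ""),
    stringsAsFactors = FALSE))
}

# a full 9-condition profile with controllable per-gene means
toy_profile <- function(means_by_gene) {
  m <- do.call(rbind, means_by_gene)
  rownames(m) <- names(means_by_gene)
  colnames(m) <- tc_conditions()
  cell_profile(m, chromosome = setNames(rep("2", nrow(m)), rownames(m)))
}

full_comparisons <- function() {
  data.frame(
    tc = rep(tc_reference_conditions(), times = 7),
    other = rep(tc_comparator_conditions(), each = 2),
    stringsAsFactors = FALSE)
}

# random full-design ratio table with sentinels and near-boundary values mixed in
random_ratio_table <- function(n_genes, seed) {
  set.seed(seed)
  comps <- full_comparisons()
  r <- matrix(exp(rnorm(n_genes * 14, sd = 1.2)) - 1, nrow = n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)), NULL))
  # sprinkle sentinels, exact zeros and within-tolerance values
  n_special <- max(1L, round(0.05 * length(r)))
  idx <- sample(length(r), n_special)
  r[idx] <- sample(c(-1, 0, 0.004, -0.004, -0.5, -0.8, 1), n_special, replace = TRUE)
  # force a few all-negative and all-positive rows so both directions occur
  k <- max(1L, n_genes %/% 10)
  r[seq_len(k), ] <- -abs(r[seq_len(k), , drop = FALSE]) / (1 + abs(r[seq_len(k), , drop = FALSE]))
  r[k + seq_len(k), ] <- abs(r[k + seq_len(k), , drop = FALSE])
  ratio_table_new(r, comps, precision = 15L)
}

# full harmonization + screen on simulator output (the standard route
# through the package used by several test files)
screen_sim <- function(sim, normalization = "median_scale", mode = "combined") {
  gms <- lapply(sim$probe_matrices, function(pm) {
    aggregate_probes_to_genes(
      suppressMessages(filter_annotated_probes(pm, sim$annotation)),
      sim$annotation)
  })
  shared <- Reduce(intersect, lapply(gms, rownames))
  pooled <- do.call(cbind, lapply(gms, function(g) g[shared, , drop = FALSE]))
  pooled <- normalize_samples(pooled, normalization)
  prof <- average_by_cell_type(pooled, sim$sample_sheet)
  fold_screen(ratio_table(prof), mode = mode)
}

fixture_path <- function(name) {
  p <- system.file("extdata", name, package = "telofold")
  stopifnot(nzchar(p))
  p
}
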