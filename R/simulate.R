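# Synthetic multi-study expression data with planted telocyte-specific
# genes, and recovery scoring. The generator emulates the study design the
# screen was built for: several studies/platforms carrying different
# cell-type conditions, replicate arrays with multiplicative log-normal
# noise, per-study scale factors, multi-probe genes and unannotated decoy
# probes.

#' Configuration for the multi-study simulator
#'
#' Defaults describe the reference simulation conditions used throughout the
#' package's tests: 1000 genes on chromosomes 2 and 3, four studies jointly
#' covering the nine cell-type conditions, 3 replicate arrays per condition,
#' 5% of genes planted telocyte-up and 5% telocyte-down at fold 5,
#' 5% multiplicative replicate noise, and per-study scale factors in
#' \[0.8, 1.25\].
#'
#' @param n_genes number of simulated genes.
#' @param chromosomes named numeric vector of per-gene chromosome assignment
#'   probabilities (must sum to 1).
#' @param studies named list: conditions carried by each study. Together they
#'   must cover each condition exactly once.
#' @param replicates replicate arrays per condition.
#' @param probes_per_gene numeric vector of probabilities for 1, 2, ...
#'   probes per gene.
#' @param fraction_unannotated fraction of all probes that are decoys without
#'   an official symbol.
#' @param baseline_log_mean,baseline_log_sd log-normal baseline intensity
#'   parameters (natural-log scale).
#' @param effect_fold_up,effect_fold_down planted fold sizes; a planted up
#'   gene's telocyte mean is `(effect_fold_up + 1)` times its baseline, a
#'   planted down gene's comparator means are `(effect_fold_down + 1)` times
#'   baseline (so telocyte means stay comparable across classes).
#' @param frac_up,frac_down fractions of genes planted up / down
#'   (telocyte-specific: applied to both `TC_D5` and `TC_D10`).
#' @param noise_cv coefficient of variation of the multiplicative
#'   (log-normal, mean 1) replicate noise.
#' @param study_scale length-2 range of the per-study multiplicative scale
#'   factor.
#' @param seed integer seed governing all draws.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 1000L,
                       chromosomes = c("2" = 0.6, "3" = 0.4),
                       studies = list(study1 = c("TC_D5", "TC_D10", "Fb", "MSC"),
                                      study2 = "ATII",
                                      study3 = c("T_BL", "T_LL"),
                                      study4 = c("ABC", "PAC")),
                       replicates = 3L,
                       probes_per_gene = c(0.6, 0.3, 0.1),
                       fraction_unannotated = 0.126,
                       baseline_log_mean = 6, baseline_log_sd = 1,
                       effect_fold_up = 5, effect_fold_down = 5,
                       frac_up = 0.05, frac_down = 0.05,
                       noise_cv = 0.05,
                       study_scale = c(0.8, 1.25),
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), chromosomes = chromosomes,
              studies = studies, replicates = as.integer(replicates),
              probes_per_gene = probes_per_gene,
              fraction_unannotated = fraction_unannotated,
              baseline_log_mean = baseline_log_mean,
              baseline_log_sd = baseline_log_sd,
              effect_fold_up = effect_fold_up, effect_fold_down = effect_fold_down,
              frac_up = frac_up, frac_down = frac_down, noise_cv = noise_cv,
              study_scale = study_scale, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_genes < 1L) .stop2("n_genes must be >= 1")
    if (is.null(names(chromosomes)) || any(chromosomes < 0) ||
        abs(sum(chromosomes) - 1) > 1e-8)
      .stop2("chromosomes must be a named probability vector summing to 1")
    conds <- unlist(studies)
    if (anyDuplicated(conds))
      .stop2("each condition may be carried by exactly one study")
    bad <- setdiff(conds, tc_conditions())
    if (length(bad)) .stop2("unknown condition(s) in studies: %s", paste(bad, collapse = ", "))
    if (!all(tc_reference_conditions() %in% conds))
      .stop2("studies must cover both telocyte conditions")
    if (replicates < 1L) .stop2("replicates must be >= 1")
    if (any(probes_per_gene < 0) || sum(probes_per_gene) <= 0)
      .stop2("probes_per_gene must be non-negative probabilities")
    if (fraction_unannotated < 0 || fraction_unannotated >= 1)
      .stop2("fraction_unannotated must be in [0, 1)")
    if (effect_fold_up <= 0 || effect_fold_down <= 0)
      .stop2("effect folds must be > 0")
    if (frac_up < 0 || frac_down < 0 || frac_up + frac_down > 1)
      .stop2("planted fractions must be in [0,1] and sum to <= 1")
    if (noise_cv < 0) .stop2("noise_cv must be >= 0")
    if (length(study_scale) != 2L || any(study_scale <= 0) ||
        study_scale[1] > study_scale[2])
      .stop2("study_scale must be a positive (lo, hi) range")
  })
  invisible(cfg)
}

# mean-1 multiplicative log-normal noise with coefficient of variation cv
.noise_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

#' Simulate probe-level data for several studies with planted marker genes
#'
#' Every draw is governed by `cfg$seed`; the same configuration yields
#' bit-identical output. Each gene's baseline intensity is log-normal;
#' planted up genes are multiplied by `effect_fold_up + 1` in the two
#' telocyte conditions only, planted down genes have their comparator-side
#' means multiplied by `effect_fold_down + 1`; every probe of a gene
#' replicates the gene value with independent noise; each sample is further
#' multiplied by its study's scale factor. Decoy probes carry no symbol.
#'
#' @param cfg a [sim_config()].
#' @return list with elements `probe_matrices` (named list of
#'   [probe_matrix()], one per study), `sample_sheet`, `annotation` and
#'   `truth` (data frame `gene`, `label` in up/down/null, `true_fold`).
#' @export
simulate_multistudy <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  n <- cfg$n_genes
  genes <- sprintf("G%05d", seq_len(n))
  chrom <- sample(names(cfg$chromosomes), n, replace = TRUE, prob = cfg$chromosomes)
  baseline <- rlnorm(n, cfg$baseline_log_mean, cfg$baseline_log_sd)

  n_up <- round(cfg$frac_up * n)
  n_down <- round(cfg$frac_down * n)
  planted <- sample.int(n, n_up + n_down)
  label <- rep("null", n)
  label[planted[seq_len(n_up)]] <- "up"
  label[planted[n_up + seq_len(n_down)]] <- "down"
  truth <- data.frame(gene = genes, label = label,
                      true_fold = ifelse(label == "up", cfg$effect_fold_up,
                                         ifelse(label == "down", cfg$effect_fold_down,
                                                NA_real_)),
                      stringsAsFactors = FALSE)

  # shared probe universe: k probes per gene plus unannotated decoys
  k <- sample.int(length(cfg$probes_per_gene), n, replace = TRUE,
                  prob = cfg$probes_per_gene)
  probe_gene_idx <- rep(seq_len(n), k)
  probe_ids <- sprintf("p_%s_%d", genes[probe_gene_idx],
                       sequence(k))
  n_annot <- length(probe_ids)
  n_decoy <- round(n_annot * cfg$fraction_unannotated / (1 - cfg$fraction_unannotated))
  decoy_ids <- sprintf("p_decoy_%05d", seq_len(n_decoy))
  decoy_baseline <- rlnorm(n_decoy, cfg$baseline_log_mean, cfg$baseline_log_sd)
  annotation <- as_probe_annotation(data.frame(
    probe_id = c(probe_ids, decoy_ids),
    symbol = c(genes[probe_gene_idx], rep("", n_decoy)),
    chromosome = c(chrom[probe_gene_idx], rep("", n_decoy)),
    stringsAsFactors = FALSE))

  study_ids <- names(cfg$studies)
  scale_s <- setNames(runif(length(study_ids), cfg$study_scale[1], cfg$study_scale[2]),
                      study_ids)

  sheet_rows <- list()
  probe_matrices <- list()
  up_mult <- cfg$effect_fold_up + 1
  down_mult <- cfg$effect_fold_down + 1
  for (s in study_ids) {
    conds <- cfg$studies[[s]]
    samp_ids <- as.vector(t(outer(conds, seq_len(cfg$replicates),
                                  function(cc, rr) sprintf("%s_%s_r%d", s, cc, rr))))
    samp_cond <- rep(conds, each = cfg$replicates)
    sheet_rows[[s]] <- data.frame(sample_id = samp_ids, condition = samp_cond,
                                  study_id = s,
                                  replicate = rep(seq_len(cfg$replicates), length(conds)),
                                  stringsAsFactors = FALSE)
    m <- matrix(0, nrow = n_annot + n_decoy, ncol = length(samp_ids),
                dimnames = list(c(probe_ids, decoy_ids), samp_ids))
    for (j in seq_along(samp_ids)) {
      cond <- samp_cond[j]
      eff <- rep(1, n)
      if (cond %in% tc_reference_conditions()) {
        eff[label == "up"] <- up_mult
      } else {
        eff[label == "down"] <- down_mult
      }
      gene_val <- baseline * eff
      vals <- c(gene_val[probe_gene_idx], decoy_baseline) * scale_s[[s]]
      m[, j] <- vals * .noise_factor(length(vals), cfg$noise_cv)
    }
    probe_matrices[[s]] <- probe_matrix(m, study_id = s)
  }
  sheet <- as_sample_sheet(do.call(rbind, c(sheet_rows, make.row.names = FALSE)))
  list(probe_matrices = probe_matrices, sample_sheet = sheet,
       annotation = annotation, truth = truth)
}

#' Score classifier recovery of planted genes
#'
#' @param cls classification data frame from [classify_all()] or a
#'   [fold_screen()].
#' @param truth the `truth` table from [simulate_multistudy()].
#' @param tol boundary tolerance used to bin the true folds for the bin
#'   accuracy.
#' @return list with `sensitivity` (direction-matched recovered planted /
#'   planted), `specificity` (nulls left unclassified / nulls), `fdp`
#'   (classified genes not direction-matched planted / classified; 0 when
#'   nothing is classified) and `bin_accuracy` (recovered planted genes whose
#'   assigned bin matches the true-fold bin).
#' @export
evaluate_recovery <- function(cls, truth, tol = 0.005) {
  if (inherits(cls, "fold_screen")) cls <- cls$classifications
  if (!setequal(cls$gene, truth$gene))
    .stop2("gene universes of classifications and truth differ")
  idx <- match(truth$gene, cls$gene)
  pred <- cls$direction[idx]
  bins <- cls$bin[idx]
  planted <- truth$label %in% c("up", "down")
  matched <- planted & pred == truth$label
  n_planted <- sum(planted)
  n_null <- sum(!planted)
  n_classified <- sum(pred != "unclassified")
  sens <- if (n_planted) sum(matched) / n_planted else NA_real_
  spec <- if (n_null) sum(pred[!planted] == "unclassified") / n_null else NA_real_
  fdp <- if (n_classified) sum(pred != "unclassified" & !matched) / n_classified else 0
  bin_acc <- if (sum(matched)) {
    true_bin <- .bin_from_fold(truth$true_fold[matched], tol)
    mean(bins[matched] == true_bin)
  } else NA_real_
  list(sensitivity = sens, specificity = spec, fdp = fdp, bin_accuracy = bin_acc)
}
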