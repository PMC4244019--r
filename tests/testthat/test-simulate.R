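small_cfg <- function(...) {
  sim_config(n_genes = 60, replicates = 2, probes_per_gene = c(0.7, 0.3),
             fraction_unannotated = 0.1, seed = 101, ...)
}

test_that("the simulator is reproducible and validates its configuration", {
  s1 <- simulate_multistudy(small_cfg())
  s2 <- simulate_multistudy(small_cfg())
  expect_identical(s1, s2)
  # a different seed changes the data
  s3 <- simulate_multistudy(sim_config(n_genes = 60, replicates = 2,
                                       probes_per_gene = c(0.7, 0.3),
                                       fraction_unannotated = 0.1, seed = 102))
  expect_false(identical(s1$probe_matrices, s3$probe_matrices))

  # structure: decoys unannotated, truth covers every gene once
  expect_true(any(!nzchar(s1$annotation$symbol)))
  expect_identical(sort(s1$truth$gene),
                   sort(unique(s1$annotation$symbol[nzchar(s1$annotation$symbol)])))
  expect_true(all(s1$truth$label %in% c("up", "down", "null")))

  expect_error(sim_config(frac_up = 0.7, frac_down = 0.5), "fractions")
  expect_error(sim_config(noise_cv = -1), "noise_cv")
  expect_error(sim_config(study_scale = c(2, 1)), "study_scale")
  expect_error(sim_config(studies = list(a = "TC_D5", b = "TC_D5")), "exactly one study")
})

test_that("noise-free planted folds hit the closed-form ratio exactly", {
  cfg <- sim_config(n_genes = 50, replicates = 2, noise_cv = 0,
                    study_scale = c(1, 1), effect_fold_up = 4,
                    effect_fold_down = 4, seed = 5)
  sim <- simulate_multistudy(cfg)
  scr <- screen_sim(sim, normalization = "none")
  rt_genes <- scr$classifications
  up <- sim$truth$gene[sim$truth$label == "up"]
  # every planted up gene's 14 ratios equal 1/5 - 1 = -0.8, the u = 4 boundary
  gms <- lapply(sim$probe_matrices, function(pm) {
    aggregate_probes_to_genes(
      suppressMessages(filter_annotated_probes(pm, sim$annotation)),
      sim$annotation)
  })
  shared <- Reduce(intersect, lapply(gms, rownames))
  pooled <- do.call(cbind, lapply(gms, function(g) g[shared, , drop = FALSE]))
  prof <- average_by_cell_type(pooled, sim$sample_sheet)
  rt <- ratio_table(prof)
  expect_true(all(abs(rt$ratios[up, ] - (-0.8)) < 1e-12))
  expect_true(all(rt_genes$direction[rt_genes$gene %in% up] == "up"))
  expect_true(all(abs(rt_genes$min_fold[rt_genes$gene %in% up] - 4) < 1e-9))
})

test_that("with nothing planted and no noise the screen finds nothing", {
  cfg <- sim_config(n_genes = 40, replicates = 2, noise_cv = 0,
                    study_scale = c(1, 1), frac_up = 0, frac_down = 0, seed = 6)
  scr <- screen_sim(simulate_multistudy(cfg), normalization = "none")
  expect_identical(scr$counts$up$cumulative[[">0"]], 0L)
  expect_identical(scr$counts$down$cumulative[[">0"]], 0L)
})

test_that("noise-free min_fold recovers the planted fold under scale correction", {
  # flat baseline so per-sample medians are unaffected by the planted genes
  # and median scaling recovers the per-study factor exactly
  cfg <- sim_config(n_genes = 200, replicates = 3, noise_cv = 0,
                    baseline_log_sd = 0, study_scale = c(0.8, 1.25),
                    effect_fold_up = 5, effect_fold_down = 5, seed = 8)
  sim <- simulate_multistudy(cfg)
  scr <- screen_sim(sim, normalization = "median_scale")
  cls <- scr$classifications
  for (lab in c("up", "down")) {
    planted <- sim$truth$gene[sim$truth$label == lab]
    got <- cls[cls$gene %in% planted, ]
    expect_true(all(got$direction == lab))
    expect_true(all(abs(got$min_fold - 5) / 5 <= 1e-9))
    expect_true(all(got$bin == "(4,Inf)"))
  }
})

test_that("recovery scoring matches hand-counted confusion tallies", {
  truth <- data.frame(gene = sprintf("g%02d", 1:10),
                      label = c("up", "up", "down", rep("null", 7)),
                      true_fold = c(5, 5, 5, rep(NA, 7)),
                      stringsAsFactors = FALSE)
  cls <- data.frame(gene = truth$gene,
                    direction = c("up", "unclassified", "down", "up",
                                  rep("unclassified", 6)),
                    min_fold = c(4.8, NA, 5.2, 0.3, rep(NA, 6)),
                    bin = c("(4,Inf)", NA, "(4,Inf)", "(0,1]", rep(NA, 6)),
                    comparisons_used = 14L, stringsAsFactors = FALSE)
  r <- evaluate_recovery(cls, truth)
  expect_equal(r$sensitivity, 2 / 3)
  expect_equal(r$specificity, 6 / 7)
  expect_equal(r$fdp, 1 / 3)
  expect_equal(r$bin_accuracy, 1)

  # perfect predictions
  perfect <- cls
  perfect$direction <- truth$label
  perfect$direction[perfect$direction == "null"] <- "unclassified"
  perfect$min_fold <- ifelse(is.na(truth$true_fold), NA, 5)
  perfect$bin <- ifelse(is.na(truth$true_fold), NA, "(4,Inf)")
  rp <- evaluate_recovery(perfect, truth)
  expect_equal(unlist(rp[c("sensitivity", "specificity", "fdp")]),
               c(sensitivity = 1, specificity = 1, fdp = 0))

  # nothing predicted
  none <- cls; none$direction <- "unclassified"
  expect_equal(evaluate_recovery(none, truth)$sensitivity, 0)

  # random instance vs loop oracle
  set.seed(31)
  rnd_truth <- data.frame(gene = sprintf("g%02d", 1:50),
                          label = sample(c("up", "down", "null"), 50, TRUE,
                                         prob = c(0.2, 0.2, 0.6)),
                          true_fold = 5, stringsAsFactors = FALSE)
  rnd_truth$true_fold[rnd_truth$label == "null"] <- NA
  rnd_cls <- data.frame(gene = rnd_truth$gene,
                        direction = sample(c("up", "down", "unclassified"), 50, TRUE),
                        min_fold = runif(50, 0, 6), bin = "(4,Inf)",
                        comparisons_used = 14L, stringsAsFactors = FALSE)
  rnd_cls$min_fold[rnd_cls$direction == "unclassified"] <- NA
  got <- evaluate_recovery(rnd_cls, rnd_truth)
  want <- oracle_recovery(rnd_cls, rnd_truth)
  expect_equal(got[c("sensitivity", "specificity", "fdp")], want)

  expect_error(evaluate_recovery(cls[-1, ], truth), "universes")
})

test_that("sensitivity degrades monotonically as replicate noise grows", {
  sens_at <- function(cv) {
    vals <- vapply(c(301, 302, 303), function(seed) {
      cfg <- sim_config(n_genes = 150, replicates = 2, noise_cv = cv,
                        effect_fold_up = 1.5, effect_fold_down = 1.5,
                        seed = seed)
      sim <- simulate_multistudy(cfg)
      evaluate_recovery(screen_sim(sim), sim$truth)$sensitivity
    }, numeric(1))
    mean(vals)
  }
  s <- c(sens_at(0.02), sens_at(0.3), sens_at(0.8))
  expect_true(s[1] >= s[2] && s[2] >= s[3])
})
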