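test_that("relative ratios follow the comparator-over-TC sign convention", {
  prof <- toy_profile(list(
    G1 = c(5, 5, rep(4.1, 7)),     # TC higher -> negative ratio
    G2 = c(3, 3, rep(3, 7)),       # equal -> zero
    G3 = c(2, 2, rep(0, 7))))      # comparator zero -> sentinel -1
  rt <- compute_ratios(prof, "TC_D5")
  expect_equal(unname(rt$ratios["G1", "TC_D5_vs_Fb"]), 4.1 / 5 - 1)
  expect_equal(unname(rt$ratios["G2", "TC_D5_vs_Fb"]), 0)
  expect_equal(unname(rt$ratios["G3", "TC_D5_vs_ATII"]), -1)
  expect_error(compute_ratios(prof, "TC_D5", comparators = character(0)), "empty")
  expect_error(compute_ratios(prof, "TC_D5", comparators = "TC_D10"), "comparators")

  # swapping roles gives the algebraic dual (1+r)(1+r') = 1
  set.seed(3)
  for (i in 1:25) {
    a <- runif(1, 0.1, 10); b <- runif(1, 0.1, 10)
    r <- b / a - 1; rp <- a / b - 1
    expect_equal((1 + r) * (1 + rp), 1, tolerance = 1e-12)
  }
})

test_that("up- and down-folds map ratios onto the printed fold scale", {
  expect_equal(up_fold(-0.5), 1)   # bin boundary
  expect_equal(up_fold(-0.8), 4)   # bin boundary
  expect_equal(up_fold(-0.88), 0.88 / 0.12, tolerance = 1e-12)
  expect_identical(up_fold(-1), Inf)
  expect_equal(up_fold(0.004), 0)  # clamped inside tolerance
  expect_error(up_fold(0.3), "not up-regulated")

  expect_equal(down_fold(2.17), 2.17)
  expect_equal(down_fold(0), 0)
  expect_equal(down_fold(-0.004), 0)
  expect_error(down_fold(-0.3), "not down-regulated")

  # duality round trip: r = -u/(1+u) recovers the ratio
  u <- c(0, 0.25, 1, 4, 7.33)
  r <- -u / (1 + u)
  expect_equal(up_fold(r), u, tolerance = 1e-12)
  # strictly decreasing on (-1, 0]
  rr <- seq(-0.99, 0, by = 0.01)
  expect_true(all(diff(up_fold(rr)) < 0))
})

test_that("single genes classify by the all-comparisons consistency rule", {
  rt <- read_ratio_table(fixture_path("chr2_up_folds.tsv"))
  comps <- rt$comparisons

  myl9 <- classify_gene(rt$ratios["Myl9", ], comps)
  expect_identical(myl9$direction, "up")
  expect_equal(myl9$min_fold, 0.88 / 0.12, tolerance = 1e-9)
  expect_identical(myl9$bin, "(4,Inf)")
  expect_identical(myl9$comparisons_used, 14L)

  rtd <- read_ratio_table(fixture_path("chr2_down_folds.tsv"))
  gzf1 <- classify_gene(rtd$ratios["Gzf1", ], comps)
  expect_identical(gzf1$direction, "down")
  expect_equal(gzf1$min_fold, 1)
  expect_identical(gzf1$bin, "(1,4]")  # boundary-inclusive at printed precision

  mixed <- classify_gene(c(rep(-0.5, 7), rep(0.5, 7)), comps)
  expect_identical(mixed$direction, "unclassified")
  expect_true(is.na(mixed$bin))

  ties <- classify_gene(rep(0, 14), comps)
  expect_identical(ties$direction, "unclassified")
})

test_that("vectorized classification matches the per-gene rule and oracle", {
  rt <- read_ratio_table(fixture_path("chr2_up_folds.tsv"))
  cls <- classify_all(rt)
  expect_identical(nrow(cls), 25L)
  expect_true(all(cls$direction == "up"))

  empty <- ratio_table_new(matrix(numeric(0), 0, 14,
                                  dimnames = list(NULL, NULL)),
                           full_comparisons())
  expect_identical(nrow(classify_all(empty)), 0L)

  for (seed in c(11, 12, 13)) {
    rnd <- random_ratio_table(50, seed)
    for (mode in c("combined", "TC5", "TC10")) {
      got <- classify_all(rnd, mode = mode)
      want <- oracle_classify(rnd, mode, 0.005)
      expect_identical(got$direction, want$direction)
      expect_equal(got$min_fold, want$min_fold)
      expect_identical(got$bin, want$bin)
    }
  }
})

test_that("combined-mode sets are the intersection of the single-day sets", {
  for (seed in c(21, 22)) {
    rnd <- random_ratio_table(80, seed)
    c5 <- classify_all(rnd, "TC5"); c10 <- classify_all(rnd, "TC10")
    cc <- classify_all(rnd, "combined")
    for (dir in c("up", "down")) {
      expect_setequal(cc$gene[cc$direction == dir],
                      intersect(c5$gene[c5$direction == dir],
                                c10$gene[c10$direction == dir]))
    }
    # combined min_fold never exceeds either single-mode min_fold
    both <- cc$gene[cc$direction != "unclassified"]
    for (g in both) {
      expect_lte(cc$min_fold[cc$gene == g],
                 min(c5$min_fold[c5$gene == g], c10$min_fold[c10$gene == g]))
    }
    # up and down sets disjoint
    expect_length(intersect(cc$gene[cc$direction == "up"],
                            cc$gene[cc$direction == "down"]), 0)
  }
})

test_that("classification is invariant to per-gene rescaling of means", {
  set.seed(5)
  base <- lapply(setNames(1:6, paste0("G", 1:6)),
                 function(i) runif(9, 0.5, 20))
  prof <- toy_profile(base)
  cls1 <- classify_all(ratio_table(prof))
  scaled <- toy_profile(lapply(base, function(v) v * runif(1, 0.01, 100)))
  cls2 <- classify_all(ratio_table(scaled))
  expect_identical(cls1$direction, cls2$direction)
  expect_equal(cls1$min_fold, cls2$min_fold, tolerance = 1e-9)
})

test_that("threshold counts reproduce the published tallies and invariants", {
  scr <- fold_screen(read_ratio_table(fixture_path("chr2_up_folds.tsv")))
  up <- scr$counts$up
  expect_identical(unlist(up$bins),
                   c("(0,1]" = 20L, "(1,4]" = 4L, "(4,Inf)" = 1L))
  expect_identical(unlist(up$cumulative), c(">0" = 25L, ">1" = 5L, ">4" = 1L))

  none <- threshold_counts(classify_all(ratio_table_new(
    matrix(numeric(0), 0, 14), full_comparisons())), "up")
  expect_true(all(unlist(none$cumulative) == 0) && all(unlist(none$bins) == 0))

  for (seed in c(31, 32)) {
    rnd <- random_ratio_table(60, seed)
    cls <- classify_all(rnd)
    for (dir in c("up", "down")) {
      tc <- threshold_counts(cls, dir)
      cum <- unlist(tc$cumulative); bins <- unlist(tc$bins)
      expect_equal(unname(cum), oracle_threshold_counts(cls, dir, 0.005))
      # monotone, bins sum to >0, and >1 = (1,4] + (4,Inf)
      expect_true(cum[">0"] >= cum[">1"] && cum[">1"] >= cum[">4"])
      expect_identical(sum(bins), as.integer(cum[">0"]))
      expect_identical(bins[["(1,4]"]] + bins[["(4,Inf)"]], as.integer(cum[">1"]))
    }
  }
})

test_that("pairwise counts split one comparison into up, down and ties", {
  rt <- ratio_table_new(
    matrix(c(-0.6, 0.5, 0), 3, 1, dimnames = list(c("a", "b", "c"), NULL)),
    data.frame(tc = "TC_D5", other = "Fb", stringsAsFactors = FALSE))
  pc <- pairwise_direction_counts(rt, "TC_D5", "Fb")
  expect_identical(pc$up[[">0"]], 1L)
  expect_identical(pc$down[[">0"]], 1L)
  expect_identical(pc$ties, 1L)

  zeros <- ratio_table_new(
    matrix(0, 4, 1, dimnames = list(paste0("g", 1:4), NULL)),
    data.frame(tc = "TC_D5", other = "Fb", stringsAsFactors = FALSE))
  pz <- pairwise_direction_counts(zeros, "TC_D5", "Fb")
  expect_true(all(unlist(pz$up) == 0) && all(unlist(pz$down) == 0))
  expect_identical(pz$ties, 4L)

  # random column vs direct enumeration at all six thresholds
  set.seed(44)
  r <- exp(rnorm(100)) - 1
  rt2 <- ratio_table_new(matrix(r, 100, 1,
                                dimnames = list(sprintf("g%03d", 1:100), NULL)),
                         data.frame(tc = "TC_D10", other = "ABC",
                                    stringsAsFactors = FALSE))
  pc2 <- pairwise_direction_counts(rt2, "TC_D10", "ABC")
  tol <- 0.005
  u <- ifelse(r <= -1, Inf, -r / (1 + r))
  expect_identical(pc2$up[[">0"]], sum(r < -tol))
  expect_identical(pc2$up[[">1"]], sum(r < -tol & u >= 1 - tol))
  expect_identical(pc2$up[[">4"]], sum(r < -tol & u >= 4 - tol))
  expect_identical(pc2$down[[">0"]], sum(r > tol))
  expect_identical(pc2$down[[">1"]], sum(r > tol & r >= 1 - tol))
  expect_identical(pc2$down[[">4"]], sum(r > tol & r >= 4 - tol))
  expect_error(pairwise_direction_counts(rt2, "TC_D5", "Fb"), "not present")
})
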