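# Independent naive reimplementations used as oracles. Deliberately written
# as plain loops, sharing no code with the package internals.

oracle_gene_means <- function(pm, ann) {
  syms <- ann$symbol[match(rownames(pm), ann$probe_id)]
  genes <- unique(syms)
  out <- matrix(NA_real_, length(genes), ncol(pm),
                dimnames = list(genes, colnames(pm)))
  for (g in genes) {
    rows <- which(syms == g)
    for (j in seq_len(ncol(pm))) {
      s <- 0
      for (i in rows) s <- s + pm[i, j]
      out[g, j] <- s / length(rows)
    }
  }
  out
}

oracle_group_means <- function(gm, sheet) {
  conds <- unique(sheet$condition[match(colnames(gm), sheet$sample_id)])
  out <- matrix(NA_real_, nrow(gm), length(conds),
                dimnames = list(rownames(gm), conds))
  for (cc in conds) {
    samp <- sheet$sample_id[sheet$condition == cc]
    samp <- samp[samp %in% colnames(gm)]
    for (i in seq_len(nrow(gm))) out[i, cc] <- mean(unlist(gm[i, samp]))
  }
  out
}

# per-gene loop classifier: the independent check on classify_all
oracle_classify <- function(rt, mode, tol) {
  comps <- rt$comparisons
  sel <- switch(mode,
                TC5 = which(comps$tc == "TC_D5"),
                TC10 = which(comps$tc == "TC_D10"),
                combined = seq_len(nrow(comps)))
  res <- list()
  for (i in seq_len(nrow(rt$ratios))) {
    r <- rt$ratios[i, sel]
    up_ok <- TRUE; down_ok <- TRUE
    for (v in r) {
      if (v > tol) up_ok <- FALSE
      if (v < -tol) down_ok <- FALSE
    }
    if (up_ok && !down_ok) {
      folds <- numeric(0)
      for (v in r) {
        v2 <- if (v > 0) 0 else v
        folds <- c(folds, if (v2 <= -1) Inf else -v2 / (1 + v2))
      }
      mf <- min(folds); dir <- "up"
    } else if (down_ok && !up_ok) {
      folds <- numeric(0)
      for (v in r) folds <- c(folds, if (v < 0) 0 else v)
      mf <- min(folds); dir <- "down"
    } else {
      mf <- NA_real_; dir <- "unclassified"
    }
    b <- if (is.na(mf)) NA_character_
         else if (mf >= 4 - tol) "(4,Inf)"
         else if (mf >= 1 - tol) "(1,4]"
         else "(0,1]"
    res[[i]] <- data.frame(gene = rownames(rt$ratios)[i], direction = dir,
                           min_fold = mf, bin = b, stringsAsFactors = FALSE)
  }
  do.call(rbind, res)
}

oracle_threshold_counts <- function(cls_df, direction, tol) {
  c0 <- c1 <- c4 <- 0
  for (i in seq_len(nrow(cls_df))) {
    if (cls_df$direction[i] != direction) next
    c0 <- c0 + 1
    if (cls_df$min_fold[i] >= 1 - tol) c1 <- c1 + 1
    if (cls_df$min_fold[i] >= 4 - tol) c4 <- c4 + 1
  }
  c(c0, c1, c4)
}

# naive O(k^3) UPGMA returning the cophenetic distance matrix
oracle_upgma_cophenetic <- function(d) {
  d <- as.matrix(d)
  k <- nrow(d)
  labels <- rownames(d)
  clusters <- as.list(seq_len(k))
  active <- rep(TRUE, k + (k - 1))
  dm <- matrix(Inf, k + (k - 1), k + (k - 1))
  dm[seq_len(k), seq_len(k)] <- d
  diag(dm) <- Inf
  coph <- matrix(0, k, k, dimnames = list(labels, labels))
  nxt <- k
  for (step in seq_len(k - 1)) {
    best <- c(NA, NA); bestd <- Inf
    ids <- which(active[seq_len(nxt)])
    for (a in ids) for (b in ids) if (a < b && dm[a, b] < bestd) {
      bestd <- dm[a, b]; best <- c(a, b)
    }
    a <- best[1]; b <- best[2]
    for (i in clusters[[a]]) for (j in clusters[[b]]) {
      coph[i, j] <- bestd; coph[j, i] <- bestd
    }
    nxt <- nxt + 1
    clusters[[nxt]] <- c(clusters[[a]], clusters[[b]])
    na <- length(clusters[[a]]); nb <- length(clusters[[b]])
    for (o in ids) {
      if (o == a || o == b) next
      dm[nxt, o] <- dm[o, nxt] <- (na * dm[a, o] + nb * dm[b, o]) / (na + nb)
    }
    active[c(a, b)] <- FALSE
    active[nxt] <- TRUE
  }
  coph
}

oracle_recovery <- function(cls_df, truth) {
  tp <- fp <- 0; n_planted <- 0; n_null <- 0; null_neg <- 0; n_cls <- 0
  for (i in seq_len(nrow(truth))) {
    g <- truth$gene[i]
    pred <- cls_df$direction[cls_df$gene == g]
    planted <- truth$label[i] != "null"
    if (planted) n_planted <- n_planted + 1 else n_null <- n_null + 1
    if (pred != "unclassified") {
      n_cls <- n_cls + 1
      if (planted && pred == truth$label[i]) tp <- tp + 1 else fp <- fp + 1
    } else if (!planted) null_neg <- null_neg + 1
  }
  list(sensitivity = if (n_planted) tp / n_planted else NA_real_,
       specificity = if (n_null) null_neg / n_null else NA_real_,
       fdp = if (n_cls) fp / n_cls else 0)
}
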