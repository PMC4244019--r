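# End-to-end orchestration: configuration validation and the
# simulate/ingest -> harmonize -> classify -> summarize -> overlay pipeline,
# with a per-stage log and a checksum manifest.

#' Load a pipeline run configuration
#'
#' A run configuration is a YAML file (or an equivalent list) with exactly
#' one of the keys `input` (paths: `probe_matrices` as a named
#' study-to-path map, `sample_sheet`, `annotation`) or `simulate`
#' (arguments for [sim_config()]), plus the analysis settings
#' `normalization` (`none`/`median_scale`/`quantile`), `tolerance`, `eps`
#' (optional), `mode` (`combined`/`TC5`/`TC10`), `chromosomes` (list of
#' labels), `top_n`, `cluster` (logical), optional `edge_list` path, and
#' `seed`.
#'
#' @param x path to a YAML file, or a list.
#' @return list of class `run_config` (not yet validated; see
#'   [validate_config()]).
#' @export
read_run_config <- function(x) {
  cfg <- if (is.character(x)) yaml::read_yaml(x) else x
  defaults <- list(normalization = "median_scale", tolerance = 0.005,
                   eps = NULL, mode = "combined", chromosomes = list("2", "3"),
                   top_n = 50L, cluster = TRUE, edge_list = NULL, seed = 1L)
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  class(cfg) <- "run_config"
  cfg
}

#' Validate a run configuration
#'
#' Returns findings instead of throwing, so configurations can be checked
#' before any computation.
#'
#' @param cfg a [read_run_config()] list.
#' @return character vector of findings; empty when the configuration is
#'   valid.
#' @export
validate_config <- function(cfg) {
  findings <- character(0)
  add <- function(msg) findings <<- c(findings, msg)
  has_input <- !is.null(cfg$input); has_sim <- !is.null(cfg$simulate)
  if (has_input == has_sim)
    add("exactly one of 'input' and 'simulate' must be present")
  if (has_input) {
    for (k in c("probe_matrices", "sample_sheet", "annotation"))
      if (is.null(cfg$input[[k]])) add(sprintf("input lacks '%s'", k))
    paths <- c(unlist(cfg$input$probe_matrices), cfg$input$sample_sheet,
               cfg$input$annotation)
    for (p in paths) if (!is.null(p) && !file.exists(p))
      add(sprintf("input file not found: %s", p))
  }
  if (has_sim) {
    ok <- tryCatch({ do.call(sim_config, cfg$simulate); TRUE },
                   error = function(e) { add(conditionMessage(e)); FALSE })
  }
  if (!is.numeric(cfg$tolerance) || cfg$tolerance < 0)
    add("tolerance must be a non-negative number")
  if (!cfg$mode %in% c("combined", "TC5", "TC10"))
    add("mode must be one of combined, TC5, TC10")
  if (!cfg$normalization %in% c("none", "median_scale", "quantile"))
    add("normalization must be one of none, median_scale, quantile")
  if (!is.null(cfg$edge_list) && !file.exists(cfg$edge_list))
    add(sprintf("edge list not found: %s", cfg$edge_list))
  if (length(cfg$chromosomes) < 1L) add("at least one chromosome required")
  findings
}

#' Run the full screening pipeline
#'
#' Stages: simulate or ingest probe-level data; filter unannotated probes
#' and aggregate to genes per study; restrict to shared genes and pool the
#' samples; normalize; average replicates into the cell-type profile; then,
#' per chromosome: restrict, compute the 14-comparison ratio table, run the
#' consistency screen, export summary tables, cluster conditions on the
#' classified gene set, and (if an edge list is configured) overlay the
#' up-regulated genes on the interaction network. Every output file is
#' recorded in `manifest.tsv` with its MD5 checksum; the run is
#' deterministic given the configuration (including its seed), so identical
#' configurations give identical manifests. A per-stage log is written to
#' `run_log.txt`. Any stage error aborts with the stage name.
#'
#' @param cfg a [read_run_config()] configuration (or path to one).
#' @param out_dir output directory.
#' @return invisibly, the manifest data frame (`file`, `md5`).
#' @export
run_pipeline <- function(cfg, out_dir) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  findings <- validate_config(cfg)
  if (length(findings))
    .stop2("invalid run configuration:\n- %s", paste(findings, collapse = "\n- "))
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    .stop2("cannot create output directory %s", out_dir)

  log_lines <- character(0)
  note <- function(fmt, ...) log_lines <<- c(log_lines, sprintf(fmt, ...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      .stop2("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  outputs <- character(0)
  keep <- function(f) { outputs <<- c(outputs, f); f }

  # --- acquire probe-level data
  if (!is.null(cfg$simulate)) {
    sim <- stage("simulate", {
      args <- cfg$simulate; args$seed <- cfg$seed
      simulate_multistudy(do.call(sim_config, args))
    })
    pms <- sim$probe_matrices; sheet <- sim$sample_sheet; ann <- sim$annotation
    truth_path <- file.path(out_dir, "truth.tsv")
    write.table(sim$truth, keep(truth_path), sep = "\t", quote = FALSE, row.names = FALSE)
    note("simulate: %d studies, %d genes", length(pms), nrow(sim$truth))
  } else {
    pms <- stage("ingest", {
      paths <- cfg$input$probe_matrices
      ids <- if (is.null(names(paths))) sprintf("study%d", seq_along(paths)) else names(paths)
      setNames(lapply(seq_along(paths),
                      function(i) read_probe_matrix(paths[[i]], study_id = ids[i])), ids)
    })
    sheet <- stage("ingest", read_sample_sheet(cfg$input$sample_sheet))
    ann <- stage("ingest", read_probe_annotation(cfg$input$annotation))
    note("ingest: %d studies", length(pms))
  }

  # --- harmonize
  gms <- stage("aggregate", lapply(pms, function(pm) {
    fm <- suppressMessages(filter_annotated_probes(pm, ann))
    note("filter [%s]: removed %d unannotated probes of %d",
         attr(pm, "study_id"), attr(fm, "n_removed"), nrow(pm))
    aggregate_probes_to_genes(fm, ann)
  }))
  profile <- stage("harmonize", {
    shared <- Reduce(intersect, lapply(gms, rownames))
    if (length(shared) == 0L) .stop2("no genes shared across studies")
    for (s in names(gms))
      note("harmonize [%s]: %d of %d genes shared", s, length(shared), nrow(gms[[s]]))
    chrom <- attr(gms[[1]], "chromosome")[shared]
    pooled <- do.call(cbind, lapply(gms, function(g) g[shared, , drop = FALSE]))
    pooled <- normalize_samples(pooled, cfg$normalization)
    attr(pooled, "chromosome") <- chrom
    average_by_cell_type(pooled, sheet)
  })
  note("profile: %d genes x %d conditions", nrow(profile$means), ncol(profile$means))

  graph <- if (!is.null(cfg$edge_list)) stage("network", read_edge_list(cfg$edge_list))

  # --- per-chromosome screens
  for (ch in unlist(cfg$chromosomes)) {
    chdir <- file.path(out_dir, paste0("chr", ch))
    prof_ch <- stage(paste0("restrict chr", ch), restrict_to_chromosome(profile, ch))
    if (nrow(prof_ch$means) == 0L) { note("chr%s: no genes; skipped", ch); next }
    rt <- stage(paste0("ratios chr", ch), ratio_table(prof_ch, eps = cfg$eps))
    scr <- stage(paste0("classify chr", ch),
                 fold_screen(rt, mode = cfg$mode, tol = cfg$tolerance))
    note("chr%s: %d genes; up %d / down %d at >0", ch, scr$n_genes,
         scr$counts$up$cumulative[[">0"]], scr$counts$down$cumulative[[">0"]])
    files <- stage(paste0("summarize chr", ch),
                   export_summary_tables(scr, rt, chdir, top_n = cfg$top_n))
    for (f in files) keep(f)
    cls <- scr$classifications
    de_genes <- cls$gene[cls$direction != "unclassified"]
    if (isTRUE(cfg$cluster)) {
      if (length(de_genes) >= 2L) {
        hc <- stage(paste0("cluster chr", ch), cluster_conditions(prof_ch, de_genes))
        keep(write_dendrogram_newick(hc, file.path(chdir, "dendrogram.nwk")))
      } else note("chr%s: <2 classified genes, clustering skipped", ch)
    }
    if (!is.null(graph)) {
      up_genes <- cls$gene[cls$direction == "up"]
      sub <- stage(paste0("network chr", ch), induced_gene_subgraph(graph, up_genes))
      keep(write_edge_list(sub, file.path(chdir, "up_gene_network.tsv")))
      note("chr%s: %d of %d up genes have interactions", ch,
           count_interacting_genes(sub), length(up_genes))
    }
  }

  log_path <- file.path(out_dir, "run_log.txt")
  writeLines(log_lines, keep(log_path))
  rel <- sub("^/", "", sub(out_dir, "", outputs, fixed = TRUE))
  manifest <- data.frame(file = rel, md5 = unname(tools::md5sum(outputs)),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), , drop = FALSE]
  write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
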