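#' Default pipeline configuration
#'
#' Assembles the full set of analysis parameters with the package
#' defaults: 1-cM walking step, permutation-derived LOD thresholds for IM
#' and ICIM (95th percentile of pooled null maxima), a fixed GCIM LOD
#' threshold of 7.5 for F2 and 4.0 for RIL populations, a 1-Mbp cis
#' window, 500-kbp padding for the consensus overlap test, and the
#' 95/99/80 hotspot percentile rule.
#'
#' @param population `"F2"` or `"RIL"`.
#' @param seed root seed; every stage derives its own substream from it.
#' @param sim list of overrides for [sim_config()] (used when the
#'   pipeline simulates its input).
#' @param ... further overrides of the defaults (see the returned list).
#' @return a named configuration list.
#' @export
pipeline_config <- function(population = c("F2", "RIL"), seed = 1L,
                            sim = list(), ...) {
  population <- match.arg(population)
  cfg <- list(
    population = population, seed = as.integer(seed), sim = sim,
    step_cM = 1, split_gap_cM = 30,
    min_count = 2, min_fraction = 0.25,
    lod_thresholds = list(
      IM = "permutation", ICIM = "permutation",
      GCIM = if (population == "F2") 7.5 else 4.0
    ),
    gcim_model = if (population == "F2") "fixed_REML" else "fixed",
    perm = list(n_sample_genes = 100, n_perm = 1000, alpha = 0.05),
    cis_window_bp = 1e6, pad_bp = 5e5,
    hotspot_pct = list(count_minor = 95, count_major = 99, density = 80),
    pcc_pos = 0.85, pcc_neg = -0.85
  )
  dots <- list(...)
  cfg[names(dots)] <- dots
  cfg
}

#' Run the combinatorial eQTL pipeline end to end
#'
#' Executes simulate (or load) -> linkage map -> expression filtering and
#' normalization -> three scan engines with their LOD thresholds ->
#' cis/trans classification -> two-of-three consensus merge -> hotspot
#' detection and adjacent-hotspot merging, writing each stage's table
#' under `out_dir` together with a machine-readable `summary.json`
#' recording seeds, thresholds and the per-stage counts (interactions per
#' method, consensus regions with and without duplicates, hotspot
#' classes). A stage failure aborts with a stage-named error; artifacts
#' of completed stages are retained.
#'
#' @param config a [pipeline_config()] list, or a path to a YAML file of
#'   the same shape.
#' @param out_dir output directory.
#' @return invisibly, a list with the summary, the consensus table, the
#'   classified (merged) hotspots and the ground truth when simulated.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  sim_args <- config$sim %||% list()
  sim_args$population_type <- config$population
  sim_args$seed <- config$seed
  scfg <- stage("simulate", do.call(sim_config, sim_args))
  sim <- stage("simulate", simulate_genotypes(scfg))
  expr_sim <- stage("simulate", simulate_expression(sim, scfg))
  write_simulation(sim, expr_sim, file.path(out_dir, "input"))

  map <- stage("map", build_map(sim$genotypes, sim$markers,
                                config$population, config$split_gap_cM))
  utils::write.table(map, file.path(out_dir, "map.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  expressed <- stage("expression", filter_expressed(
    expr_sim$counts, config$min_count, config$min_fraction))
  norm <- stage("expression", median_ratio_normalize(
    expr_sim$counts[expressed, , drop = FALSE]))
  phenos <- log2(norm$normalized + 1)

  designs <- stage("scan", scan_designs(map, sim$genotypes,
                                        config$population, config$step_cM))
  thr <- stage("threshold", resolve_thresholds(
    config, phenos, map, sim$genotypes, designs))
  interactions <- stage("scan", scan_all_genes(
    phenos, map, sim$genotypes, config, designs, thr))
  utils::write.table(interactions, file.path(out_dir, "peaks.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  interactions <- stage("consensus", classify_cis_trans(
    interactions, expr_sim$genes, config$cis_window_bp))
  consensus <- stage("consensus", merge_methods(interactions,
                                                config$pad_bp))
  utils::write.table(consensus, file.path(out_dir, "consensus.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(codify_interaction(consensus$class, consensus$gene_id,
                                consensus$chrom, consensus$start_bp,
                                consensus$end_bp),
             file.path(out_dir, "consensus_codified.txt"))

  trans_regions <- stage("hotspots", count_by_marker_pair(
    consensus[consensus$class == "trans", , drop = FALSE]))
  hotspots <- NULL
  merged_hotspots <- NULL
  if (nrow(trans_regions) >= 2) {
    hotspots <- stage("hotspots", classify_hotspots(
      trans_regions, config$population,
      config$hotspot_pct$count_minor, config$hotspot_pct$count_major,
      config$hotspot_pct$density))
    utils::write.table(hotspots, file.path(out_dir, "hotspots.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    called <- hotspots[hotspots$class != "none", , drop = FALSE]
    attr(called, "population") <- config$population
    merged_hotspots <- stage("hotspots", merge_adjacent(called))
    utils::write.table(merged_hotspots,
                       file.path(out_dir, "hotspots_merged.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  summary <- list(
    population = config$population, seed = config$seed,
    n_lines = scfg$n_lines, n_markers = nrow(sim$markers),
    n_genes_simulated = scfg$n_genes, n_genes_expressed = length(expressed),
    lod_thresholds = thr,
    interactions_per_method = method_counts(interactions),
    consensus = consensus_counts(interactions, consensus, config$pad_bp),
    hotspots = if (is.null(hotspots)) NULL else
      as.list(table(hotspots$class)),
    merged_hotspot_names = merged_hotspots$name
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(summary = summary, consensus = consensus,
                 hotspots = hotspots, merged_hotspots = merged_hotspots,
                 map = map, truth = expr_sim$truth,
                 expression = phenos, genes = expr_sim$genes))
}

resolve_thresholds <- function(config, phenos, map, genotypes, designs) {
  thr <- config$lod_thresholds
  for (m in c("IM", "ICIM")) {
    if (identical(thr[[m]], "permutation")) {
      pt <- permutation_threshold(
        phenos, map, genotypes, method = "IM",
        n_sample_genes = min(config$perm$n_sample_genes, nrow(phenos)),
        n_perm = config$perm$n_perm, alpha = config$perm$alpha,
        seed = substream_seed(config$seed, paste0("perm_", m)),
        designs = designs)
      thr[[m]] <- pt$threshold
    }
  }
  thr
}

scan_all_genes <- function(phenos, map, genotypes, config, designs, thr) {
  genes <- rownames(phenos)
  Y <- t(phenos)
  lods_im <- lod_profile_matrix(designs, Y)
  rows <- list()
  for (gi in seq_along(genes)) {
    y <- Y[, gi]
    pk_im <- peak_table(designs, lods_im[, gi], y, thr$IM, "IM")
    pk_icim <- icim_scan(y, map, genotypes, designs = designs,
                         threshold = thr$ICIM)$peaks
    pk_gcim <- gcim_scan(y, map, genotypes, model = config$gcim_model,
                         designs = designs, threshold = thr$GCIM)$peaks
    pk <- rbind(pk_im, pk_icim, pk_gcim)
    if (nrow(pk) > 0) {
      pk <- cbind(gene_id = genes[gi], pk, stringsAsFactors = FALSE)
      rows[[length(rows) + 1]] <- pk
    }
  }
  if (length(rows) == 0) {
    return(data.frame(gene_id = character(0), method = character(0),
                      linkage_group = character(0), chrom = character(0),
                      pos_cM = numeric(0), left_bp = numeric(0),
                      right_bp = numeric(0), lod = numeric(0),
                      pve = numeric(0), additive = numeric(0),
                      dominance = numeric(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  names(out)[names(out) == "left_bp"] <- "start_bp"
  names(out)[names(out) == "right_bp"] <- "end_bp"
  rownames(out) <- NULL
  out
}

method_counts <- function(interactions) {
  out <- list()
  for (m in unique(interactions$method)) {
    sub <- interactions[interactions$method == m, , drop = FALSE]
    out[[m]] <- list(trans = sum(sub$class == "trans"),
                     cis = sum(sub$class == "cis"))
  }
  out
}

# Table-1-shaped accounting: per pairwise comparison the number of
# co-validated regions ("with duplicates"), and the unique count from
# the full three-method merge.
consensus_counts <- function(interactions, consensus, pad_bp) {
  pairs <- list(c("ICIM", "IM"), c("ICIM", "GCIM"), c("IM", "GCIM"))
  with_dup <- list()
  for (p in pairs) {
    sub <- interactions[interactions$method %in% p, , drop = FALSE]
    nm <- paste(p, collapse = "_vs_")
    if (length(unique(sub$method)) < 2) {
      with_dup[[nm]] <- list(trans = 0L, cis = 0L)
      next
    }
    cc <- merge_methods(sub, pad_bp)
    with_dup[[nm]] <- list(trans = sum(cc$class == "trans"),
                           cis = sum(cc$class == "cis"))
  }
  tot_dup <- list(
    trans = sum(vapply(with_dup, function(x) x$trans, 0)),
    cis = sum(vapply(with_dup, function(x) x$cis, 0))
  )
  list(
    with_duplicates = with_dup, total_with_duplicates = tot_dup,
    unique = list(trans = sum(consensus$class == "trans"),
                  cis = sum(consensus$class == "cis"))
  )
}

#' List the consensus regions interacting with one gene
#'
#' @param consensus consensus data frame from [merge_methods()] or
#'   [run_pipeline()].
#' @param gene_id gene of interest; an unknown gene returns an empty
#'   table with a warning.
#' @return the consensus rows targeting the gene.
#' @export
interactions_for_gene <- function(consensus, gene_id) {
  out <- consensus[consensus$gene_id == gene_id, , drop = FALSE]
  if (nrow(out) == 0) {
    warning("no interactions recorded for gene ", gene_id, call. = FALSE)
  }
  rownames(out) <- NULL
  out
}
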