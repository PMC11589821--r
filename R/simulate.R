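#' Configuration for the biparental-cross simulator
#'
#' Bundles and validates every knob of the synthetic cross generator. The
#' defaults emulate the scale of an early-maturing soybean F2 mapping
#' population: 176 lines, 20 chromosomes carrying ~1,600 GBS-style markers,
#' tens of thousands of expressed genes, a modest fraction of genes with a
#' local (cis) regulatory variant, and planted trans-regulatory hotspots
#' each driving tens to hundreds of target genes.
#'
#' @param population_type `"F2"` (segregating, heterozygotes present) or
#'   `"RIL"` (selfed recombinant inbred lines, fully homozygous).
#' @param n_lines number of offspring lines (F2 default 176; a RIL study
#'   of this kind would typically use ~162).
#' @param n_chromosomes number of chromosomes.
#' @param markers_per_chromosome markers placed evenly along each chromosome.
#' @param chromosome_length_bp physical length of each chromosome.
#' @param chromosome_length_cM genetic length of each chromosome; adjacent
#'   marker recombination fractions derive from it via the inverse Kosambi
#'   function.
#' @param n_genes number of expressed genes to simulate.
#' @param cis_fraction proportion of genes given a cis eQTL at the marker
#'   nearest their transcription start site.
#' @param cis_effect additive allele-substitution effect of cis eQTLs on the
#'   log2 expression scale, in units of the residual SD (`residual_sd`).
#' @param dominance_effect heterozygote deviation (F2 only), same units.
#' @param hotspot_specs list of planted trans hotspots; each element is a
#'   list with `marker` (global marker index of the regulator), `n_targets`
#'   and `effect` (additive effect in residual-SD units). The default plants
#'   one large hotspot (200 targets, 1.5 SD) and one smaller one
#'   (40 targets, 1 SD).
#' @param dispersion negative-binomial dispersion of the counts
#'   (`variance = mu + dispersion * mu^2`); 0 gives Poisson counts.
#' @param residual_sd SD of the per-line log2-scale biological noise that
#'   defines the unit of the effect sizes.
#' @param library_size_range range of per-line relative library-size
#'   factors, drawn log-uniformly.
#' @param seed integer seed; together with the config it fully determines
#'   every simulated artifact.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(population_type = c("F2", "RIL"),
                       n_lines = 176,
                       n_chromosomes = 20,
                       markers_per_chromosome = 80,
                       chromosome_length_bp = 5e7,
                       chromosome_length_cM = 100,
                       n_genes = 20000,
                       cis_fraction = 0.05,
                       cis_effect = 1,
                       dominance_effect = 0,
                       hotspot_specs = list(
                         list(marker = 290L, n_targets = 200L, effect = 1.5),
                         list(marker = 1210L, n_targets = 40L, effect = 1)
                       ),
                       dispersion = 0.05,
                       residual_sd = 1,
                       library_size_range = c(0.7, 1.4),
                       seed = 1L) {
  population_type <- match.arg(population_type)
  if (n_lines < 2 || n_chromosomes < 1 || markers_per_chromosome < 1 ||
      n_genes < 1) {
    stop("counts (lines, chromosomes, markers, genes) must be positive ",
         "(n_lines >= 2)", call. = FALSE)
  }
  if (cis_fraction < 0 || cis_fraction > 1) {
    stop("cis_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (!all(vapply(hotspot_specs, function(h) {
    is.finite(h$effect) && h$n_targets >= 0 && h$marker >= 1
  }, logical(1)))) {
    stop("hotspot specs need a valid marker index, target count and a ",
         "finite effect size", call. = FALSE)
  }
  if (dispersion < 0 || residual_sd < 0) {
    stop("dispersion and residual_sd must be non-negative", call. = FALSE)
  }
  if (length(library_size_range) != 2 || any(library_size_range <= 0)) {
    stop("library_size_range must be two positive numbers", call. = FALSE)
  }
  n_targets_total <- sum(vapply(hotspot_specs, function(h) h$n_targets, 0))
  if (n_targets_total + ceiling(cis_fraction * n_genes) > n_genes) {
    stop("hotspot target counts plus cis genes exceed n_genes", call. = FALSE)
  }
  cfg <- list(
    population_type = population_type, n_lines = as.integer(n_lines),
    n_chromosomes = as.integer(n_chromosomes),
    markers_per_chromosome = as.integer(markers_per_chromosome),
    chromosome_length_bp = chromosome_length_bp,
    chromosome_length_cM = chromosome_length_cM,
    n_genes = as.integer(n_genes), cis_fraction = cis_fraction,
    cis_effect = cis_effect, dominance_effect = dominance_effect,
    hotspot_specs = hotspot_specs, dispersion = dispersion,
    residual_sd = residual_sd, library_size_range = library_size_range,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate genotypes for a biparental cross
#'
#' Places markers evenly along each chromosome (in bp and cM), converts
#' adjacent-marker map distances to recombination fractions through the
#' inverse Kosambi function, and draws line genotypes chromosome by
#' chromosome. F2 lines are built from two independent gametes, each a
#' Markov chain of crossovers (no interference); genotypes are coded
#' A/H/B with the expected 1:2:1 segregation. RIL lines are single
#' homozygous genomes coded A/B whose adjacent-marker recombination uses
#' the selfed-RIL map expansion `r* = 2r / (1 + 2r)`.
#'
#' @param config a [sim_config()].
#' @return a list with `genotypes` (lines x markers character matrix),
#'   `markers` (data frame: `marker_id`, `chrom`, `pos_bp`, `pos_cM`) and
#'   `population`.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(substream_seed(config$seed, "genotypes"))
  n <- config$n_lines
  m <- config$markers_per_chromosome
  chroms <- sprintf("GM%02d", seq_len(config$n_chromosomes))
  marker_list <- vector("list", config$n_chromosomes)
  geno_list <- vector("list", config$n_chromosomes)
  for (ci in seq_len(config$n_chromosomes)) {
    pos_bp <- round(seq(1, config$chromosome_length_bp, length.out = m))
    pos_cM <- seq(0, config$chromosome_length_cM, length.out = m)
    r_adj <- if (m > 1) kosambi_r(diff(pos_cM)) else numeric(0)
    marker_list[[ci]] <- data.frame(
      marker_id = sprintf("%s_%09d", chroms[ci], pos_bp),
      chrom = chroms[ci], pos_bp = pos_bp, pos_cM = pos_cM,
      stringsAsFactors = FALSE
    )
    if (config$population_type == "F2") {
      g1 <- sim_gametes(n, m, r_adj)
      g2 <- sim_gametes(n, m, r_adj)
      geno_list[[ci]] <- g1 + g2
    } else {
      r_star <- if (m > 1) 2 * r_adj / (1 + 2 * r_adj) else numeric(0)
      geno_list[[ci]] <- 2 * sim_gametes(n, m, r_star)
    }
  }
  markers <- do.call(rbind, marker_list)
  num <- do.call(cbind, geno_list)
  geno <- matrix(c("A", "H", "B")[num + 1], nrow = n,
                 dimnames = list(sprintf("L%04d", seq_len(n)),
                                 markers$marker_id))
  list(genotypes = geno, markers = markers,
       population = config$population_type)
}

# One haploid genome per line: allele 0/1 at the first marker, then a
# crossover (allele switch) between adjacent markers with probability r.
sim_gametes <- function(n_lines, n_markers, r_adj) {
  g <- matrix(0L, n_lines, n_markers)
  g[, 1] <- stats::rbinom(n_lines, 1, 0.5)
  if (n_markers > 1) {
    for (j in 2:n_markers) {
      sw <- stats::rbinom(n_lines, 1, r_adj[j - 1])
      g[, j] <- ifelse(sw == 1L, 1L - g[, j - 1], g[, j - 1])
    }
  }
  g
}

#' Simulate expression counts with planted cis eQTLs and trans hotspots
#'
#' Genes receive a shared log-normal baseline; a configured fraction get a
#' cis effect at the marker nearest their TSS, and each planted hotspot
#' regulator drives its target genes in trans. Effects act additively on
#' the log2 scale (allele coding -1/0/+1; F2 heterozygotes may get a
#' dominance deviation). Counts are negative binomial around the per-line
#' mean after applying library-size factors.
#'
#' @param sim output of [simulate_genotypes()].
#' @param config the same [sim_config()].
#' @return list with `counts` (genes x lines integer matrix), `genes`
#'   (annotation data frame: `gene_id`, `chrom`, `tss_bp`, `strand`),
#'   `lib_factors`, and `truth` (a `ground_truth` list: `cis_gene_to_marker`,
#'   `hotspots` with regulator marker/position and target genes, and the
#'   true effect sizes).
#' @export
simulate_expression <- function(sim, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(substream_seed(config$seed, "expression"))
  markers <- sim$markers
  n_mark <- nrow(markers)
  for (h in config$hotspot_specs) {
    if (h$marker > n_mark) {
      stop("hotspot regulator marker index exceeds the marker count",
           call. = FALSE)
    }
    if (h$n_targets > config$n_genes) {
      stop("hotspot target count exceeds n_genes", call. = FALSE)
    }
  }
  ng <- config$n_genes
  n <- config$n_lines
  chroms <- unique(markers$chrom)
  gene_chrom <- chroms[(seq_len(ng) - 1) %% length(chroms) + 1]
  tss <- round(stats::runif(ng, 1, config$chromosome_length_bp))
  genes <- data.frame(
    gene_id = sprintf("Gene.%05d", seq_len(ng)), chrom = gene_chrom,
    tss_bp = tss, strand = sample(c("+", "-"), ng, replace = TRUE),
    stringsAsFactors = FALSE
  )
  num <- geno_to_numeric(sim$genotypes) # lines x markers
  x_add <- num - 1
  is_het <- (num == 1) * 1

  # planted structure: hotspot targets first, then cis genes from the rest
  assigned <- logical(ng)
  hot_truth <- list()
  signal <- matrix(0, ng, n) # log2-scale genetic signal, genes x lines
  for (hi in seq_along(config$hotspot_specs)) {
    h <- config$hotspot_specs[[hi]]
    if (h$n_targets == 0) next
    targets <- sample(which(!assigned), h$n_targets)
    assigned[targets] <- TRUE
    xa <- x_add[, h$marker]
    signal[targets, ] <- signal[targets, , drop = FALSE] +
      rep(h$effect * config$residual_sd * xa, each = length(targets))
    hot_truth[[hi]] <- list(
      marker_id = markers$marker_id[h$marker], chrom = markers$chrom[h$marker],
      pos_bp = markers$pos_bp[h$marker], effect = h$effect,
      targets = genes$gene_id[sort(targets)]
    )
  }
  n_cis <- round(config$cis_fraction * ng)
  cis_genes <- if (n_cis > 0) sort(sample(which(!assigned), n_cis)) else integer(0)
  cis_marker <- integer(0)
  for (gi in cis_genes) {
    on_chr <- which(markers$chrom == genes$chrom[gi])
    mk <- on_chr[which.min(abs(markers$pos_bp[on_chr] - genes$tss_bp[gi]))]
    cis_marker <- c(cis_marker, mk)
    xa <- x_add[, mk]
    add <- config$cis_effect * config$residual_sd * xa
    if (sim$population == "F2" && config$dominance_effect != 0) {
      add <- add + config$dominance_effect * config$residual_sd * is_het[, mk]
    }
    signal[gi, ] <- signal[gi, ] + add
  }

  baseline <- stats::rlnorm(ng, meanlog = log(100), sdlog = 1)
  lsr <- log(config$library_size_range)
  lib <- exp(stats::runif(n, lsr[1], lsr[2]))
  noise <- matrix(stats::rnorm(ng * n, 0, config$residual_sd), ng, n)
  mu <- baseline * 2^(signal + noise) * rep(lib, each = ng)
  size <- if (config$dispersion == 0) Inf else 1 / config$dispersion
  counts <- matrix(stats::rnbinom(ng * n, mu = mu, size = size), ng, n,
                   dimnames = list(genes$gene_id, rownames(sim$genotypes)))
  truth <- list(
    cis_gene_to_marker = stats::setNames(
      as.list(markers$marker_id[cis_marker]), genes$gene_id[cis_genes]),
    cis_effect = config$cis_effect,
    hotspots = hot_truth
  )
  class(truth) <- "ground_truth"
  list(counts = counts, genes = genes, lib_factors = lib, truth = truth)
}

#' Simulate annotated variants for candidate genes
#'
#' Emits a small synthetic variant set (VCF 4.2 body plus a companion
#' annotation table) for a list of candidate genes, with consequence
#' classes, UTR location flags, SIFT scores and per-parent alleles. The
#' first candidate gene is guaranteed a deleterious missense variant whose
#' alternate allele is carried by exactly one parent (it survives the full
#' prioritization cascade) and a LOW-consequence variant that does not.
#'
#' @param candidate_genes character vector of gene ids (non-empty unless
#'   `n_per_gene = 0`).
#' @param gene_annotation data frame with `gene_id`, `chrom`, `tss_bp`.
#' @param n_per_gene random variants drawn per gene (besides the planted
#'   pair); 0 with no genes gives a valid empty set.
#' @param seed integer seed.
#' @return data frame of variant candidates (see [filter_candidates()] for
#'   the column contract).
#' @export
simulate_variants <- function(candidate_genes, gene_annotation,
                              n_per_gene = 3, seed = 1L) {
  if (length(candidate_genes) == 0) {
    return(empty_variant_table())
  }
  set.seed(substream_seed(seed, "variants"))
  bases <- c("A", "C", "G", "T")
  rows <- list()
  for (g in candidate_genes) {
    ann <- gene_annotation[gene_annotation$gene_id == g, ]
    if (nrow(ann) == 0) stop("candidate gene not annotated: ", g, call. = FALSE)
    for (k in seq_len(n_per_gene)) {
      ref <- sample(bases, 1)
      alt <- sample(setdiff(bases, ref), 1)
      cons <- sample(c("HIGH", "MODERATE", "LOW", "MODIFIER"), 1,
                     prob = c(.05, .35, .3, .3))
      loc <- sample(c("CDS", "3'UTR", "5'UTR", "other"), 1,
                    prob = c(.4, .2, .2, .2))
      sift <- if (cons == "MODERATE" && loc == "CDS") round(stats::runif(1), 3) else NA_real_
      carrier <- sample(c("p1", "p2", "both", "none"), 1,
                        prob = c(.35, .35, .15, .15))
      rows[[length(rows) + 1]] <- variant_row(
        g, ann$chrom, ann$tss_bp + sample.int(5000, 1), ref, alt, cons, loc,
        sift,
        parent1 = if (carrier %in% c("p1", "both")) alt else ref,
        parent2 = if (carrier %in% c("p2", "both")) alt else ref,
        reference = ref
      )
    }
  }
  # planted pair in the first candidate gene
  ann1 <- gene_annotation[gene_annotation$gene_id == candidate_genes[1], ]
  rows[[length(rows) + 1]] <- variant_row(
    candidate_genes[1], ann1$chrom, ann1$tss_bp + 101, "A", "G",
    "MODERATE", "CDS", 0.01, parent1 = "G", parent2 = "A", reference = "A"
  )
  rows[[length(rows) + 1]] <- variant_row(
    candidate_genes[1], ann1$chrom, ann1$tss_bp + 202, "C", "T",
    "LOW", "CDS", NA_real_, parent1 = "T", parent2 = "C", reference = "C"
  )
  out <- do.call(rbind, rows)
  out[order(out$chrom, out$pos_bp), , drop = FALSE]
}

variant_row <- function(gene, chrom, pos, ref, alt, cons, loc, sift,
                        parent1, parent2, reference) {
  data.frame(gene_id = gene, chrom = chrom, pos_bp = pos, ref = ref,
             alt = alt, consequence = cons, location = loc,
             sift_score = sift, parent1 = parent1, parent2 = parent2,
             reference_allele = reference, stringsAsFactors = FALSE)
}

empty_variant_table <- function() {
  variant_row(character(0), character(0), numeric(0), character(0),
              character(0), character(0), character(0), numeric(0),
              character(0), character(0), character(0))
}

#' Write simulated artifacts as plain-text files
#'
#' Writes the genotype matrix, marker table, count matrix, gene annotation
#' and ground-truth record (JSON) into a directory, in the TSV layouts the
#' analysis functions read back.
#'
#' @param sim output of [simulate_genotypes()].
#' @param expr output of [simulate_expression()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, expr, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_mat(sim$genotypes, file.path(dir, "genotypes.tsv"), "line")
  utils::write.table(sim$markers, file.path(dir, "markers.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_tsv_mat(expr$counts, file.path(dir, "counts.tsv"), "gene_id")
  utils::write.table(expr$genes, file.path(dir, "genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_ground_truth(expr$truth, file.path(dir, "ground_truth.json"))
  invisible(dir)
}

write_tsv_mat <- function(m, path, id_col) {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Serialize / read back a ground-truth record
#'
#' @param truth a `ground_truth` object from [simulate_expression()].
#' @param path JSON file path.
#' @return `read_ground_truth()` returns the `ground_truth` object.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  truth <- jsonlite::read_json(path, simplifyVector = TRUE)
  truth$cis_gene_to_marker <- as.list(truth$cis_gene_to_marker)
  if (is.data.frame(truth$hotspots)) {
    truth$hotspots <- lapply(seq_len(nrow(truth$hotspots)), function(i) {
      h <- as.list(truth$hotspots[i, ])
      h$targets <- h$targets[[1]]
      h
    })
  }
  class(truth) <- "ground_truth"
  truth
}
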