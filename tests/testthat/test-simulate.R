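test_that("the same seed reproduces genotypes and counts exactly", {
  cfg <- sim_config(n_lines = 30, n_chromosomes = 2,
                    markers_per_chromosome = 10, n_genes = 50,
                    cis_fraction = 0.1,
                    hotspot_specs = list(list(marker = 5L, n_targets = 10L,
                                              effect = 1)),
                    seed = 11)
  a <- simulate_genotypes(cfg)
  b <- simulate_genotypes(cfg)
  expect_identical(a, b)
  ea <- simulate_expression(a, cfg)
  eb <- simulate_expression(b, cfg)
  expect_identical(ea$counts, eb$counts)
  expect_identical(ea$truth, eb$truth)
})

test_that("zero map length means no recombination within a chromosome", {
  cfg <- sim_config(n_lines = 40, n_chromosomes = 2,
                    markers_per_chromosome = 8, chromosome_length_cM = 0,
                    n_genes = 10, cis_fraction = 0, hotspot_specs = list(),
                    seed = 3)
  sim <- simulate_genotypes(cfg)
  for (chr in unique(sim$markers$chrom)) {
    cols <- sim$markers$marker_id[sim$markers$chrom == chr]
    g <- sim$genotypes[, cols, drop = FALSE]
    expect_true(all(g == g[, 1]))
  }
})

test_that("F2 single-marker segregation is 1:2:1 within sampling error", {
  cfg <- sim_config(n_lines = 10000, n_chromosomes = 1,
                    markers_per_chromosome = 1, n_genes = 1,
                    cis_fraction = 0, hotspot_specs = list(), seed = 5)
  sim <- simulate_genotypes(cfg)
  tab <- table(factor(sim$genotypes[, 1], c("A", "H", "B")))
  p_hat <- as.numeric(tab) / 10000
  p_exp <- c(0.25, 0.5, 0.25)
  se <- sqrt(p_exp * (1 - p_exp) / 10000)
  expect_true(all(abs(p_hat - p_exp) < 3 * se))
  gof <- stats::chisq.test(as.numeric(tab), p = p_exp)
  expect_gt(gof$p.value, 0.001)
})

test_that("RIL recombination follows the selfed expansion 2r/(1+2r)", {
  # adjacent markers at map distance corresponding to r = 0.1
  cfg <- sim_config("RIL", n_lines = 10000, n_chromosomes = 1,
                    markers_per_chromosome = 2,
                    chromosome_length_cM = kosambi_cm(0.1), n_genes = 1,
                    cis_fraction = 0, hotspot_specs = list(), seed = 9)
  sim <- simulate_genotypes(cfg)
  expect_true(all(sim$genotypes %in% c("A", "B")))
  r_star <- 2 * 0.1 / (1 + 2 * 0.1)
  obs <- mean(sim$genotypes[, 1] != sim$genotypes[, 2])
  se <- sqrt(r_star * (1 - r_star) / 10000)
  expect_lt(abs(obs - r_star), 3 * se)
})

test_that("null genes show no genotype dependence", {
  cfg <- sim_config(n_lines = 2000, n_chromosomes = 1,
                    markers_per_chromosome = 4, n_genes = 20,
                    cis_fraction = 0, hotspot_specs = list(), seed = 21)
  sim <- simulate_genotypes(cfg)
  expr <- simulate_expression(sim, cfg)
  x <- eqtlhot:::geno_to_numeric(sim$genotypes)[, 1] - 1
  slopes <- apply(log2(expr$counts + 1), 1, function(y) {
    stats::coef(stats::lm(y ~ x))[2]
  })
  expect_lt(max(abs(slopes)), 0.15)
})

test_that("hotspot targets are strongly co-expressed at 2 SD effects", {
  cfg <- sim_config("RIL", n_lines = 162, n_chromosomes = 2,
                    markers_per_chromosome = 10, n_genes = 120,
                    cis_fraction = 0,
                    hotspot_specs = list(list(marker = 5L, n_targets = 100L,
                                              effect = 2)),
                    seed = 13)
  sim <- simulate_genotypes(cfg)
  expr <- simulate_expression(sim, cfg)
  targets <- expr$truth$hotspots[[1]]$targets
  # independent correlation computation on the log scale
  cc <- stats::cor(t(log2(expr$counts[targets, ] + 1)))
  expect_gt(mean(cc[upper.tri(cc)]), 0.5)
})

test_that("counts approach the Poisson limit as dispersion vanishes", {
  cfg <- sim_config(n_lines = 500, n_chromosomes = 1,
                    markers_per_chromosome = 2, n_genes = 200,
                    cis_fraction = 0, hotspot_specs = list(),
                    dispersion = 1e-9, residual_sd = 0,
                    library_size_range = c(1, 1), seed = 17)
  sim <- simulate_genotypes(cfg)
  expr <- simulate_expression(sim, cfg)
  ratio <- apply(expr$counts, 1, stats::var) / rowMeans(expr$counts)
  expect_lt(abs(mean(ratio) - 1), 0.1)
})

test_that("ground truth round-trips through JSON serialization", {
  cfg <- sim_config(n_lines = 30, n_chromosomes = 2,
                    markers_per_chromosome = 10, n_genes = 40,
                    cis_fraction = 0.2,
                    hotspot_specs = list(list(marker = 3L, n_targets = 8L,
                                              effect = 1.5)),
                    seed = 31)
  sim <- simulate_genotypes(cfg)
  expr <- simulate_expression(sim, cfg)
  path <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(expr$truth, path)
  back <- read_ground_truth(path)
  expect_identical(back$cis_gene_to_marker, expr$truth$cis_gene_to_marker)
  expect_identical(back$hotspots[[1]]$targets,
                   expr$truth$hotspots[[1]]$targets)
  expect_equal(back$hotspots[[1]]$pos_bp, expr$truth$hotspots[[1]]$pos_bp)
  # every target exists in the count matrix, regulators on the map
  expect_true(all(expr$truth$hotspots[[1]]$targets %in%
                    rownames(expr$counts)))
  expect_true(expr$truth$hotspots[[1]]$marker_id %in% sim$markers$marker_id)
})

test_that("invalid simulator configurations are rejected", {
  expect_error(sim_config(n_lines = 1), "n_lines >= 2")
  expect_error(sim_config(cis_fraction = 1.2), "cis_fraction")
  expect_error(sim_config(n_genes = 50,
                          hotspot_specs = list(list(marker = 1L,
                                                    n_targets = 60L,
                                                    effect = 1))),
               "exceed")
  cfg <- sim_config(n_lines = 10, n_chromosomes = 1,
                    markers_per_chromosome = 5, n_genes = 100,
                    cis_fraction = 0,
                    hotspot_specs = list(list(marker = 50L, n_targets = 5L,
                                              effect = 1)), seed = 1)
  sim <- simulate_genotypes(cfg)
  expect_error(simulate_expression(sim, cfg), "marker index")
})

test_that("simulated variants include a planted cascade survivor", {
  genes <- data.frame(gene_id = c("GeneA", "GeneB"), chrom = "GM01",
                      tss_bp = c(1e6, 2e6), strand = "+",
                      stringsAsFactors = FALSE)
  v <- simulate_variants(c("GeneA", "GeneB"), genes, n_per_gene = 2,
                         seed = 4)
  kept <- filter_candidates(v, c("GeneA", "GeneB"))
  planted <- kept[kept$gene_id == "GeneA" & kept$sift_score %in% 0.01, ]
  expect_equal(nrow(planted), 1)
  expect_identical(planted$sift_verdict, "deleterious")
  # the planted LOW-consequence CDS variant is removed
  ann1 <- genes[genes$gene_id == "GeneA", ]
  expect_false((ann1$tss_bp + 202) %in% kept$pos_bp)
  expect_true((ann1$tss_bp + 202) %in% v$pos_bp)
  # zero variants requested -> structurally valid empty table and VCF
  v0 <- simulate_variants(character(0), genes)
  expect_equal(nrow(v0), 0)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_variants_vcf(v0, path)
  lines <- readLines(path)
  expect_true(startsWith(lines[1], "##fileformat=VCFv4.2"))
  expect_true(any(startsWith(lines, "#CHROM")))
})
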