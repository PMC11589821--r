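# Shared small cross for the scan tests.
scan_fixture <- function(population = "F2", seed = 1, n_lines = 176,
                         n_chr = 2, m_per_chr = 15, len_cM = 60) {
  cfg <- sim_config(population, n_lines = n_lines, n_chromosomes = n_chr,
                    markers_per_chromosome = m_per_chr,
                    chromosome_length_cM = len_cM, n_genes = 5,
                    cis_fraction = 0, hotspot_specs = list(), seed = seed)
  sim <- simulate_genotypes(cfg)
  map <- build_map(sim$genotypes, sim$markers, population)
  designs <- scan_designs(map, sim$genotypes, population)
  list(cfg = cfg, sim = sim, map = map, designs = designs)
}

test_that("a constant phenotype gives an all-zero LOD profile", {
  fx <- scan_fixture(seed = 101)
  res <- im_scan(rep(2, 176), designs = fx$designs)
  expect_true(all(res$profile$lod == 0))
  expect_equal(nrow(res$peaks), 0)
})

test_that("IM LOD at marker positions equals the regression oracle", {
  fx <- scan_fixture(seed = 102)
  set.seed(1)
  num <- eqtlhot:::geno_to_numeric(fx$sim$genotypes)
  y <- (num[, 8] - 1) * 0.8 + rnorm(176)
  res <- im_scan(y, designs = fx$designs)
  # at a marker the expected QTL genotype is the observed genotype
  for (mk in fx$map$marker_id[c(3, 8, 20)]) {
    i <- match(mk, fx$map$marker_id)
    at <- which(res$profile$pos_cM == fx$map$pos_cM[i] &
                  res$profile$linkage_group == fx$map$linkage_group[i])
    xa <- num[, mk] - 1
    xd <- as.numeric(num[, mk] == 1)
    expect_lt(abs(res$profile$lod[at[1]] -
                    lod_lm_oracle(y, cbind(xa, xd))), 1e-8)
  }
})

test_that("IM localizes a planted effect and reports sensible effects", {
  fx <- scan_fixture(seed = 103)
  set.seed(2)
  num <- eqtlhot:::geno_to_numeric(fx$sim$genotypes)
  true_marker <- 12
  y <- (num[, true_marker] - 1) * 1 + rnorm(176)
  res <- im_scan(y, designs = fx$designs, threshold = 3)
  lg <- fx$map$linkage_group[true_marker]
  pk <- res$peaks[res$peaks$linkage_group == lg, ]
  expect_equal(nrow(pk), 1)
  expect_lt(abs(pk$pos_cM - fx$map$pos_cM[true_marker]), 10)
  expect_lt(abs(pk$additive - 1), 0.35)
  expect_true(pk$pve > 5 && pk$pve < 100)
  expect_true(all(res$peaks$lod >= 0))
})

test_that("scans are invariant to line reordering", {
  fx <- scan_fixture(seed = 104, n_lines = 100)
  set.seed(3)
  num <- eqtlhot:::geno_to_numeric(fx$sim$genotypes)
  y <- (num[, 5] - 1) + rnorm(100)
  res1 <- im_scan(y, designs = fx$designs, threshold = 3)
  perm <- sample(100)
  g2 <- fx$sim$genotypes[perm, ]
  d2 <- scan_designs(fx$map, g2, "F2")
  res2 <- im_scan(y[perm], designs = d2, threshold = 3)
  expect_equal(res1$profile$lod, res2$profile$lod, tolerance = 1e-9)
  expect_equal(res1$peaks, res2$peaks, tolerance = 1e-9)
})

test_that("ICIM reduces to IM when no cofactor is selected", {
  fx <- scan_fixture(seed = 105, n_lines = 120)
  set.seed(4)
  y <- rnorm(120) # pure noise; a tiny p_in guarantees no cofactor enters
  im <- im_scan(y, designs = fx$designs, threshold = Inf)
  icim <- icim_scan(y, fx$map, fx$sim$genotypes, designs = fx$designs,
                    threshold = Inf, p_in = 1e-8)
  expect_equal(icim$profile$lod, im$profile$lod, tolerance = 1e-12)
})

test_that("ICIM cofactor adjustment matches an explicit residual oracle", {
  set.seed(5)
  n <- 150
  g <- matrix(sample(c("A", "B"), n * 5, replace = TRUE), n, 5,
              dimnames = list(paste0("L", 1:n), paste0("m", 1:5)))
  pos <- data.frame(marker_id = paste0("m", 1:5), chrom = "GM01",
                    pos_bp = (1:5) * 1e6, stringsAsFactors = FALSE)
  map <- build_map(g, pos, "RIL", split_gap_cM = 1e9)
  designs <- scan_designs(map, g, "RIL")
  num <- eqtlhot:::geno_to_numeric(g) - 1
  y <- num[, 1] * 1.5 + num[, 4] * 1.5 + rnorm(n, 0, 0.5)
  sel <- eqtlhot:::stepwise_select(y, num, 0.001, 0.002)
  expect_setequal(colnames(num)[sel], c("m1", "m4"))
  icim <- icim_scan(y, map, g, designs = designs, threshold = Inf)
  # oracle: for the interval m1-m2, subtract the fitted contribution of
  # every selected cofactor except the flanking markers m1, m2
  beta <- stats::coef(stats::lm(y ~ num[, sel]))[-1]
  keep <- !(colnames(num)[sel] %in% c("m1", "m2"))
  y_adj <- y - num[, sel, drop = FALSE][, keep, drop = FALSE] %*%
    cbind(beta[keep])
  at <- which(icim$profile$left_marker == "m1" &
                icim$profile$right_marker == "m2")
  sub <- designs
  sub$designs <- designs$designs[at]
  oracle <- eqtlhot:::lod_profile_matrix(sub, matrix(y_adj))[, 1]
  expect_equal(icim$profile$lod[at], oracle, tolerance = 1e-10)
})

test_that("ICIM recovers two planted QTL on different chromosomes", {
  hits <- 0
  for (seed in 1:3) {
    fx <- scan_fixture(seed = 200 + seed, n_lines = 200)
    set.seed(seed)
    num <- eqtlhot:::geno_to_numeric(fx$sim$genotypes)
    q1 <- 5
    q2 <- 22 # second chromosome
    y <- (num[, q1] - 1) * 1.2 + (num[, q2] - 1) * 1.2 + rnorm(200)
    res <- icim_scan(y, fx$map, fx$sim$genotypes, designs = fx$designs,
                     threshold = 3)
    found <- vapply(c(q1, q2), function(q) {
      any(res$peaks$linkage_group == fx$map$linkage_group[q] &
            abs(res$peaks$pos_cM - fx$map$pos_cM[q]) < 15)
    }, logical(1))
    hits <- hits + sum(found)
  }
  expect_gte(hits, 5) # 5 of 6 planted QTL across three seeds
})

test_that("GCIM with k = 0 reduces to a plain marker-regression scan", {
  fx <- scan_fixture(seed = 106, n_lines = 120)
  set.seed(6)
  num <- eqtlhot:::geno_to_numeric(fx$sim$genotypes)
  y <- (num[, 10] - 1) * 0.8 + rnorm(120)
  res <- gcim_scan(y, fx$map, fx$sim$genotypes, model = "fixed", k = 0,
                   designs = fx$designs)
  oracle <- vapply(fx$map$marker_id, function(mk) {
    lod_lm_oracle(y, cbind(num[, mk] - 1,
                           as.numeric(num[, mk] == 1)))
  }, numeric(1))
  # the scan regresses on the additive coding only
  oracle_add <- vapply(fx$map$marker_id, function(mk) {
    lod_lm_oracle(y, cbind(num[, mk] - 1))
  }, numeric(1))
  expect_equal(res$profile$lod, unname(oracle_add), tolerance = 1e-8)
  expect_false(isTRUE(all.equal(res$profile$lod, unname(oracle))))
})

test_that("GCIM recovers a strong planted QTL under both models", {
  for (model in c("fixed", "fixed_REML")) {
    fx <- scan_fixture(seed = 107, n_lines = 176)
    set.seed(7)
    num <- eqtlhot:::geno_to_numeric(fx$sim$genotypes)
    y <- (num[, 20] - 1) * 1.2 + rnorm(176)
    res <- gcim_scan(y, fx$map, fx$sim$genotypes, model = model,
                     designs = fx$designs, threshold = 4)
    expect_true(any(res$peaks$linkage_group == fx$map$linkage_group[20] &
                      abs(res$peaks$pos_cM - fx$map$pos_cM[20]) < 15),
                info = model)
  }
})

test_that("GCIM keeps a low false-positive rate on null phenotypes", {
  fx <- scan_fixture(seed = 108, n_lines = 120, m_per_chr = 10)
  set.seed(8)
  calls <- vapply(1:100, function(i) {
    y <- rnorm(120)
    nrow(gcim_scan(y, fx$map, fx$sim$genotypes, model = "fixed",
                   designs = fx$designs, threshold = 4)$peaks) > 0
  }, logical(1))
  expect_lt(mean(calls), 0.10)
})

test_that("permutation thresholds are reproducible and well-bookkept", {
  fx <- scan_fixture("RIL", seed = 109, n_lines = 80, n_chr = 2,
                     m_per_chr = 8, len_cM = 50)
  set.seed(9)
  expr <- matrix(rnorm(20 * 80), 20, 80,
                 dimnames = list(paste0("g", 1:20), NULL))
  expect_warning(
    pt1 <- permutation_threshold(expr, n_sample_genes = 5, n_perm = 50,
                                 seed = 42, designs = fx$designs),
    "unstable")
  expect_warning(
    pt2 <- permutation_threshold(expr, n_sample_genes = 5, n_perm = 50,
                                 seed = 42, designs = fx$designs),
    "unstable")
  expect_identical(pt1$threshold, pt2$threshold)
  expect_equal(pt1$n_pooled, 5 * 50)
  # degenerate null: all pooled maxima identical -> threshold equals it
  expect_equal(percentile(rep(3.3, 1000), 95), 3.3)
  expect_error(permutation_threshold(expr, n_sample_genes = 50,
                                     n_perm = 100, designs = fx$designs),
               "fewer than")
})
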