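# The worked rows from the two parental-variant tables, as a fixture.
table_variants <- function() {
  data.frame(
    gene_id = c("Glyma.15G261300", "Glyma.15G263700", "Glyma.15G263700",
                "Glyma.18G025600", "Glyma.18G025600",
                "Glyma.04G135400", "Glyma.13G285400", "Glyma.13G285400",
                "Glyma.13G285400", "Glyma.13G285400"),
    chrom = c("GM15", "GM15", "GM15", "GM18", "GM18",
              "GM04", "GM13", "GM13", "GM13", "GM13"),
    pos_bp = c(49385259, 49734668, 49736375, 1893844, 1894078,
               19964773, 38627139, 38627196, 38627262, 38627374),
    ref = c("A", "A", "T", "A", "C", "A", "C", "A", "T", "T"),
    alt = c("C", "G", "G", "G", "A", "T", "G", "T", "A", "A"),
    consequence = c("MODIFIER", "MODERATE", "MODIFIER", "MODIFIER",
                    "MODIFIER", "MODERATE", "MODIFIER", "MODIFIER",
                    "MODIFIER", "MODIFIER"),
    location = c("3'UTR", "CDS", "5'UTR", "3'UTR", "3'UTR",
                 "CDS", "5'UTR", "5'UTR", "5'UTR", "5'UTR"),
    sift_score = c(NA, 0.01, NA, NA, NA, 0.02, NA, NA, NA, NA),
    parent1 = c("C", "G", "G", "G", "A", "T", "C", "A", "T/A", "T"),
    parent2 = c("A", "A", "T", "A", "C", "A", "G", "T", "A", "A"),
    reference_allele = c("A", "A", "T", "A", "C", "A", "C", "A", "T", "T"),
    stringsAsFactors = FALSE
  )
}

tf_list <- c("Glyma.15G261300", "Glyma.15G263700", "Glyma.18G025600",
             "Glyma.04G135400", "Glyma.13G285400")

test_that("the deleterious missense single-parent variant is retained", {
  kept <- filter_candidates(table_variants(), tf_list)
  hit <- kept[kept$pos_bp == 49734668, ]
  expect_equal(nrow(hit), 1)
  expect_identical(hit$sift_verdict, "deleterious")
  expect_identical(hit$carrier, "parent1")
  # all ten curated rows pass the cascade by construction
  expect_equal(nrow(kept), 10)
})

test_that("consequence/UTR and parental rules remove failing variants", {
  v <- table_variants()
  low <- v[1, ]
  low$consequence <- "LOW"
  low$location <- "CDS"
  both <- v[2, ]
  both$parent1 <- both$alt
  both$parent2 <- both$alt
  neither <- v[2, ]
  neither$parent1 <- neither$ref
  neither$parent2 <- neither$ref
  het_vs_ref <- v[2, ]
  het_vs_ref$parent1 <- paste0(het_vs_ref$ref, "/", het_vs_ref$alt)
  het_vs_ref$parent2 <- het_vs_ref$ref
  vv <- rbind(low, both, neither, het_vs_ref)
  vv$pos_bp <- 1:4
  kept <- filter_candidates(vv, tf_list)
  # only the lone het carrier against a reference parent survives
  expect_equal(kept$pos_bp, 4)
  expect_identical(kept$het_parent, "parent1")
})

test_that("het non-blocking rule keeps a hom-alt carrier beside a het", {
  v <- table_variants()[9, ] # T/*/A style: parent1 het, parent2 hom alt
  kept <- filter_candidates(v, tf_list)
  expect_equal(nrow(kept), 1)
  expect_identical(kept$carrier, "parent2")
  expect_identical(kept$het_parent, "parent1")
})

test_that("unlisted genes are silent, missing parents warn", {
  v <- table_variants()
  expect_equal(nrow(filter_candidates(v, "Glyma.99G000000")), 0)
  v$parent1[3] <- NA
  expect_warning(kept <- filter_candidates(v, tf_list), "missing parental")
  expect_false(49736375 %in% kept$pos_bp)
})

test_that("the filter is idempotent, order-free, and contract-clean", {
  v <- table_variants()
  genes <- data.frame(gene_id = tf_list,
                      chrom = c("GM15", "GM15", "GM18", "GM04", "GM13"),
                      tss_bp = c(49385000, 49734000, 1893000, 19960000,
                                 38627000),
                      stringsAsFactors = FALSE)
  extra <- simulate_variants(tf_list, genes, n_per_gene = 6, seed = 33)
  vv <- rbind(v, extra)
  kept1 <- filter_candidates(vv, tf_list)
  kept2 <- filter_candidates(vv[rev(seq_len(nrow(vv))), ], tf_list)
  expect_setequal(paste(kept1$chrom, kept1$pos_bp),
                  paste(kept2$chrom, kept2$pos_bp))
  again <- filter_candidates(kept1[, names(vv)], tf_list)
  expect_equal(nrow(again), nrow(kept1))
  # every retained row satisfies the disjunction and the parental rule
  expect_true(all(kept1$consequence %in% c("MODERATE", "HIGH") |
                    kept1$location %in% c("3'UTR", "5'UTR")))
  hom_alt <- function(p, alt) !grepl("/", p, fixed = TRUE) & p == alt
  n_hom <- hom_alt(kept1$parent1, kept1$alt) +
    hom_alt(kept1$parent2, kept1$alt)
  expect_true(all(n_hom <= 1))
})

test_that("candidate tables reproduce from a fixture VCF round-trip", {
  v <- table_variants()
  vcf <- withr::local_tempfile(fileext = ".vcf")
  ann <- withr::local_tempfile(fileext = ".tsv")
  write_variants_vcf(v, vcf, ann)
  back <- read_variant_table(vcf, ann)
  expect_equal(nrow(back), nrow(v))
  kept <- filter_candidates(back, tf_list)
  genes <- data.frame(gene_id = tf_list,
                      chrom = c("GM15", "GM15", "GM18", "GM04", "GM13"),
                      tss_bp = c(49385259, 49734668, 1893844, 19964773,
                                 38627139),
                      stringsAsFactors = FALSE)
  regions <- data.frame(
    chrom = c("GM15", "GM18", "GM04", "GM13"),
    start_bp = c(49385092, 1434182, 17227512, 37790482),
    end_bp = c(49442237, 1935386, 20251662, 38620690),
    stringsAsFactors = FALSE
  )
  regions$name <- region_name(c("F2", "F2", "RIL", "RIL"), regions$chrom,
                              regions$start_bp, regions$end_bp)
  tab <- summarize_candidates(kept, regions, genes)
  # the five RIL-table rows resolve to their regions with paper-style
  # genotype strings, including the asterisked heterozygote
  ril <- tab[startsWith(tab$region, "RIL"), ]
  expect_equal(nrow(ril), 5)
  het_row <- tab[tab$snp == "GM13:38,627,262", ]
  expect_identical(het_row$genotypes, "T/A*/A")
  expect_identical(tab[tab$snp == "GM04:19,964,773", ]$sift_consequence,
                   "Missense (Deleterious)")
  expect_identical(tab[tab$snp == "GM13:38,627,139", ]$sift_consequence,
                   "N/A")
  # region assignment equals a brute-force distance scan
  for (i in seq_len(nrow(tab))) {
    g <- genes[genes$gene_id == tab$gene_id[i], ]
    r <- regions[regions$name == tab$region[i], ]
    d <- max(r$start_bp - g$tss_bp, g$tss_bp - r$end_bp, 0)
    expect_true(g$chrom == r$chrom && d <= 3e5)
  }
  # empty candidate set -> header-only table
  empty <- summarize_candidates(kept[0, ], regions, genes)
  expect_equal(nrow(empty), 0)
  expect_true(all(c("region", "snp", "genotypes") %in% names(empty)))
})
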