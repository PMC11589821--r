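# Independent reference implementations used to cross-check the package.
# These deliberately use the most literal formulation of each computation
# (double loops, explicit sums) rather than the package's code paths.

# Benjamini-Hochberg by explicit sort-and-cummin.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Median-of-ratios size factors by explicit per-line loops, rescaled to
# a unit geometric mean.
size_factor_oracle <- function(counts) {
  use <- apply(counts, 1, function(r) all(r > 0))
  geo <- exp(rowMeans(log(counts[use, , drop = FALSE])))
  sf <- sapply(seq_len(ncol(counts)), function(j) {
    stats::median(counts[use, j] / geo)
  })
  sf / exp(mean(log(sf)))
}

# Upper hypergeometric tail P(X >= k) by summing point masses from the
# combinatorial definition.
hyper_upper_oracle <- function(k, K, N, n) {
  ks <- k:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# Lower tail P(X <= k).
hyper_lower_oracle <- function(k, K, N, n) {
  ks <- max(0, n - (N - K)):k
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# Regression LOD at a marker from an explicit lm fit.
lod_lm_oracle <- function(y, X) {
  fit1 <- stats::lm(y ~ X)
  fit0 <- stats::lm(y ~ 1)
  rss1 <- sum(stats::residuals(fit1)^2)
  rss0 <- sum(stats::residuals(fit0)^2)
  (length(y) / 2) * log10(rss0 / rss1)
}

# Expression filter by explicit double loop.
filter_expressed_oracle <- function(counts, min_count, min_fraction) {
  need <- ceiling(min_fraction * ncol(counts))
  kept <- character(0)
  for (g in rownames(counts)) {
    n_active <- 0
    for (j in seq_len(ncol(counts))) {
      if (counts[g, j] >= min_count) n_active <- n_active + 1
    }
    if (n_active >= need) kept <- c(kept, g)
  }
  kept
}

# All-pairs brute-force consensus: repeatedly sweep over interaction
# pairs of the same gene/class/chromosome from different methods whose
# +/- pad intervals intersect, pooling them into groups until stable.
consensus_bruteforce <- function(interactions, pad_bp = 5e5) {
  n <- nrow(interactions)
  group <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      a <- interactions[i, ]
      b <- interactions[j, ]
      if (a$gene_id != b$gene_id || a$class != b$class ||
          a$chrom != b$chrom || a$method == b$method) next
      if (a$start_bp - pad_bp <= b$end_bp + pad_bp &&
          b$start_bp - pad_bp <= a$end_bp + pad_bp &&
          group[i] != group[j]) {
        group[group == group[j]] <- group[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  out <- list()
  for (g in unique(group)) {
    mem <- interactions[group == g, , drop = FALSE]
    if (length(unique(mem$method)) < 2) next
    out[[length(out) + 1]] <- data.frame(
      gene_id = mem$gene_id[1], chrom = mem$chrom[1],
      start_bp = min(mem$start_bp), end_bp = max(mem$end_bp),
      class = mem$class[1], n_methods = length(unique(mem$method)),
      stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0) {
    return(data.frame(gene_id = character(0), chrom = character(0),
                      start_bp = numeric(0), end_bp = numeric(0),
                      class = character(0), n_methods = integer(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$gene_id, res$class, res$chrom, res$start_bp), ,
      drop = FALSE]
}

# Percentile-and-filter hotspot classifier oracle.
hotspot_class_oracle <- function(count, density, pmin = 95, pmaj = 99,
                                 pden = 80) {
  cmin <- stats::quantile(count, pmin / 100, type = 7, names = FALSE)
  cmaj <- stats::quantile(count, pmaj / 100, type = 7, names = FALSE)
  dmin <- stats::quantile(density[!is.na(density)], pden / 100, type = 7,
                          names = FALSE)
  sapply(seq_along(count), function(i) {
    if (is.na(density[i]) || density[i] < dmin) return("none")
    if (count[i] >= cmaj) return("major")
    if (count[i] >= cmin) return("minor")
    "none"
  })
}

# Random interaction toy sets for consensus tests.
random_interactions <- function(n, seed) {
  set.seed(seed)
  start <- sample(1e6, n) * 10
  data.frame(
    gene_id = sample(paste0("G", 1:3), n, replace = TRUE),
    method = sample(c("ICIM", "IM", "GCIM"), n, replace = TRUE),
    chrom = sample(c("GM01", "GM02"), n, replace = TRUE),
    start_bp = start, end_bp = start + sample(2e5, n),
    class = sample(c("cis", "trans"), n, replace = TRUE),
    lod = round(stats::runif(n, 3, 12), 2),
    stringsAsFactors = FALSE
  )
}
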