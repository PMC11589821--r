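#' Filter genes by minimum expression across the population
#'
#' A gene is retained when its raw count reaches `min_count` in at least
#' `ceiling(min_fraction * n_lines)` lines (boundary inclusive).
#'
#' @param counts genes x lines integer matrix (raw counts).
#' @param min_count per-line count needed to call a gene active (default 2).
#' @param min_fraction fraction of the population that must be active
#'   (default 0.25).
#' @return character vector of retained gene ids.
#' @export
filter_expressed <- function(counts, min_count = 2, min_fraction = 0.25) {
  if (is.null(dim(counts)) || nrow(counts) == 0 || ncol(counts) == 0) {
    stop("count matrix is empty", call. = FALSE)
  }
  need <- ceiling(min_fraction * ncol(counts))
  rownames(counts)[rowSums(counts >= min_count) >= need]
}

#' Median-of-ratios normalization
#'
#' The size-factor method used for RNA-seq count normalization: each
#' line's size factor is the median, over genes expressed in every line,
#' of the ratio of its count to the gene's geometric mean; normalized
#' values are counts divided by the size factor. Size factors are
#' rescaled to a unit geometric mean, which leaves relative library
#' sizes untouched and makes normalization idempotent.
#'
#' @param counts genes x lines matrix of raw counts.
#' @return list with `normalized` (matrix) and `size_factors` (named
#'   vector, one per line).
#' @export
median_ratio_normalize <- function(counts) {
  if (ncol(counts) < 2) stop("need at least 2 lines", call. = FALSE)
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(all_pos)) {
    stop("no gene has nonzero counts in every line; relax the expression ",
         "filter or pool more genes before normalizing", call. = FALSE)
  }
  pos <- counts[all_pos, , drop = FALSE]
  geo <- exp(rowMeans(log(pos)))
  sf <- apply(pos / geo, 2, stats::median)
  sf <- sf / exp(mean(log(sf)))
  list(normalized = sweep(counts, 2, sf, "/"), size_factors = sf)
}

#' Two-group parental differential-expression test
#'
#' A light-weight stand-in for a full count-model DE analysis that keeps
#' the downstream gating logic: counts of both parents are normalized
#' together by [median_ratio_normalize()], a Welch t-test is run per gene
#' on `log2(normalized + 1)`, p-values are Benjamini-Hochberg adjusted
#' across tested genes, and a gene is a DEG iff adjusted p <= `fdr` AND
#' linear fold change >= `fc_threshold` in either direction. Group A is
#' the reference: fold changes are mean(B)/mean(A) on the normalized
#' linear scale.
#'
#' @param counts_group_a,counts_group_b genes x replicates raw count
#'   matrices (same genes, >= 2 replicates each).
#' @param fc_threshold minimum linear fold change (default 2.0).
#' @param fdr adjusted p-value cutoff (default 0.05).
#' @return data frame: `gene_id`, `fold_change` (linear), `direction`
#'   (`up`/`down` in B relative to reference A), `p_value`, `fdr_p`, `deg`.
#' @export
parental_de <- function(counts_group_a, counts_group_b,
                        fc_threshold = 2.0, fdr = 0.05) {
  if (ncol(counts_group_a) < 2 || ncol(counts_group_b) < 2) {
    stop("need at least 2 replicates per group", call. = FALSE)
  }
  if (!identical(rownames(counts_group_a), rownames(counts_group_b))) {
    stop("the two groups must share the same gene rows", call. = FALSE)
  }
  na <- ncol(counts_group_a)
  norm <- median_ratio_normalize(cbind(counts_group_a, counts_group_b))$normalized
  a <- norm[, seq_len(na), drop = FALSE]
  b <- norm[, -seq_len(na), drop = FALSE]
  la <- log2(a + 1)
  lb <- log2(b + 1)
  p <- vapply(seq_len(nrow(norm)), function(i) {
    if (stats::sd(la[i, ]) == 0 && stats::sd(lb[i, ]) == 0) {
      return(if (mean(la[i, ]) == mean(lb[i, ])) 1 else 0)
    }
    stats::t.test(lb[i, ], la[i, ])$p.value
  }, numeric(1))
  padj <- stats::p.adjust(p, method = "BH")
  ma <- rowMeans(a)
  mb <- rowMeans(b)
  fc <- mb / ma
  res <- data.frame(
    gene_id = rownames(norm),
    fold_change = ifelse(fc >= 1 | is.na(fc), fc, 1 / fc),
    direction = ifelse(mb >= ma, "up", "down"),
    p_value = p, fdr_p = padj, stringsAsFactors = FALSE
  )
  res$deg <- !is.na(res$fold_change) & res$fdr_p <= fdr &
    res$fold_change >= fc_threshold
  rownames(res) <- NULL
  res
}
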