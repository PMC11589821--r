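#' Fisher-test term enrichment with multiply-by-genes Bonferroni
#'
#' For every annotation term, counts annotated genes in the query set
#' (`k`) and in the background (`K`) and assesses over- or
#' under-representation by the one-sided hypergeometric tail in the
#' direction of the observed deviation from expectation. Raw p-values are
#' corrected by plain multiplication with `multiplier` and are not
#' clipped at 1, following the convention of multiplying by the number of
#' scanned genes (so a raw p of 0.003 scanned over 4,000 genes becomes a
#' corrected value of 12). A term is significant when its corrected value
#' is at most `alpha`.
#'
#' @param query_genes character vector, a subset of `background_genes`.
#' @param background_genes the scanned gene universe.
#' @param annotation data frame with `gene_id`, `term_id`, `term_name`,
#'   `category`.
#' @param multiplier Bonferroni multiplier; defaults to the number of
#'   query genes scanned. Pass the number of tested terms for the
#'   conventional term-count Bonferroni.
#' @param alpha corrected-value significance cutoff (default 0.01).
#' @return data frame sorted by corrected p: `term_id`, `term_name`,
#'   `category`, `k`, `K`, `n`, `N`, `direction` (`over`/`under`),
#'   `p_value`, `p_corrected`, `significant`.
#' @export
fisher_enrichment <- function(query_genes, background_genes, annotation,
                              multiplier = NULL, alpha = 0.01) {
  query_genes <- unique(query_genes)
  background_genes <- unique(background_genes)
  if (length(query_genes) == 0) stop("empty query set", call. = FALSE)
  if (!all(query_genes %in% background_genes)) {
    stop("query genes must be a subset of the background", call. = FALSE)
  }
  multiplier <- multiplier %||% length(query_genes)
  ann <- annotation[annotation$gene_id %in% background_genes, , drop = FALSE]
  ann <- unique(ann[, c("gene_id", "term_id", "term_name", "category")])
  N <- length(background_genes)
  n <- length(query_genes)
  terms <- unique(ann[, c("term_id", "term_name", "category")])
  rows <- lapply(seq_len(nrow(terms)), function(i) {
    genes_t <- ann$gene_id[ann$term_id == terms$term_id[i]]
    K <- length(genes_t)
    k <- sum(query_genes %in% genes_t)
    expected <- n * K / N
    if (k >= expected) {
      direction <- "over"
      p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    } else {
      direction <- "under"
      p <- stats::phyper(k, K, N - K, n)
    }
    data.frame(term_id = terms$term_id[i], term_name = terms$term_name[i],
               category = terms$category[i], k = k, K = K, n = n, N = N,
               direction = direction, p_value = p,
               p_corrected = p * multiplier, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$significant <- res$p_corrected <= alpha
  res <- res[order(res$p_corrected), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Bonferroni correction by multiplication with the scanned-gene count
#'
#' @param p raw Fisher-test p-value(s).
#' @param n_scanned number of scanned genes.
#' @return corrected value(s), possibly above 1 (not clipped).
#' @export
soybase_bonferroni <- function(p, n_scanned) {
  stopifnot(all(p >= 0 & p <= 1), n_scanned >= 1)
  p * n_scanned
}

#' Restrict enrichment results to a curated biological-process term list
#'
#' Keeps only results whose term appears on the curated list with a
#' biological-process category; molecular-function and
#' cellular-component terms are removed.
#'
#' @param results output of [fisher_enrichment()].
#' @param frspd_terms data frame with `term_id` and `category` (the
#'   curated flowering/reproduction/senescence/photosynthesis/development
#'   list).
#' @return the filtered results.
#' @export
filter_frspd <- function(results, frspd_terms) {
  is_bp <- tolower(frspd_terms$category) %in%
    c("bp", "biological_process", "biological process")
  keep_terms <- frspd_terms$term_id[is_bp]
  out <- results[results$term_id %in% keep_terms, , drop = FALSE]
  rownames(out) <- NULL
  out
}
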