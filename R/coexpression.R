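#' Build a co-expression network around a gene set
#'
#' Computes pairwise Pearson correlation coefficients (PCC) across lines
#' for a set of target genes plus candidate transcription factors, then
#' clusters the genes by average-linkage hierarchical clustering on the
#' distance `1 - PCC`. The number of clusters defaults to cutting the
#' dendrogram at the largest gap between successive merge heights;
#' pass `k` to fix it. Clusters are labeled `C1`, `C2`, ... by
#' descending size. Constant-expression genes are dropped with a warning
#' (their PCC is undefined).
#'
#' @param gene_set character vector of member gene ids.
#' @param candidate_tfs additional gene ids (e.g. candidate regulators)
#'   included in the network.
#' @param expression genes x lines matrix of normalized expression.
#' @param k optional fixed number of clusters.
#' @return list of class `coexpression_network`: `members`, `pcc`
#'   (symmetric matrix with unit diagonal), `cluster` (named `C*` labels),
#'   `k`, `hclust`, `kind = "CEN"`.
#' @export
build_cen <- function(gene_set, candidate_tfs = character(0), expression,
                      k = NULL) {
  members <- unique(c(gene_set, candidate_tfs))
  missing <- setdiff(members, rownames(expression))
  if (length(missing) > 0) {
    stop("genes absent from the expression matrix: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  expr <- expression[members, , drop = FALSE]
  sds <- apply(expr, 1, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant-expression gene(s): ",
            paste(members[sds == 0], collapse = ", "), call. = FALSE)
    members <- members[sds > 0]
    expr <- expr[members, , drop = FALSE]
  }
  if (length(members) < 3) {
    stop("need at least 3 non-constant genes", call. = FALSE)
  }
  pcc <- stats::cor(t(expr))
  hc <- stats::hclust(stats::as.dist(1 - pcc), method = "average")
  if (is.null(k)) {
    h <- hc$height
    k <- if (length(h) >= 2) {
      length(members) - which.max(diff(h))
    } else {
      2L
    }
  }
  k <- max(2L, min(as.integer(k), length(members)))
  cl <- stats::cutree(hc, k = k)
  sizes <- sort(table(cl), decreasing = TRUE)
  relabel <- stats::setNames(paste0("C", seq_along(sizes)), names(sizes))
  cluster <- stats::setNames(unname(relabel[as.character(cl)]), members)
  structure(list(members = members, pcc = pcc, cluster = cluster, k = k,
                 hclust = hc, kind = "CEN"),
            class = "coexpression_network")
}

#' Transcriptome-wide co-expression network for one query gene
#'
#' Correlates the query gene with every other gene in the expression
#' matrix and returns the positive network (PCC at or above
#' `pos_threshold`) and negative network (PCC at or below
#' `neg_threshold`); the query itself is excluded and the two sets are
#' disjoint. Constant genes are skipped with a warning.
#'
#' @param query_gene gene id present in `expression`.
#' @param expression genes x lines matrix of normalized expression.
#' @param pos_threshold positive PCC cutoff, boundary included
#'   (default 0.85).
#' @param neg_threshold negative PCC cutoff, boundary included
#'   (default -0.85).
#' @return list with `pos` and `neg` data frames (`gene_id`, `pcc`,
#'   sorted by |PCC| descending), `query_gene`, and the thresholds.
#' @export
build_twcen <- function(query_gene, expression, pos_threshold = 0.85,
                        neg_threshold = -0.85) {
  if (!query_gene %in% rownames(expression)) {
    stop("query gene not found in the expression matrix", call. = FALSE)
  }
  q <- as.numeric(expression[query_gene, ])
  if (stats::sd(q) == 0) {
    stop("query gene has constant expression; PCC undefined", call. = FALSE)
  }
  others <- setdiff(rownames(expression), query_gene)
  mat <- expression[others, , drop = FALSE]
  sds <- apply(mat, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant-expression gene(s) skipped",
            call. = FALSE)
  }
  ok <- sds > 0
  pcc <- as.numeric(stats::cor(t(mat[ok, , drop = FALSE]), q))
  res <- data.frame(gene_id = others[ok], pcc = pcc,
                    stringsAsFactors = FALSE)
  pos <- res[res$pcc >= pos_threshold, , drop = FALSE]
  neg <- res[res$pcc <= neg_threshold, , drop = FALSE]
  pos <- pos[order(-pos$pcc), , drop = FALSE]
  neg <- neg[order(neg$pcc), , drop = FALSE]
  rownames(pos) <- rownames(neg) <- NULL
  list(pos = pos, neg = neg, query_gene = query_gene,
       pos_threshold = pos_threshold, neg_threshold = neg_threshold)
}

#' Mean Pearson correlation between a query gene and a gene list
#'
#' Summary helper, e.g. the mean co-expression of a candidate regulator
#' with a family of homologs.
#'
#' @param expression genes x lines matrix.
#' @param query_gene gene id.
#' @param genes gene ids to average over (the query is excluded if
#'   present).
#' @return mean PCC.
#' @export
mean_pcc <- function(expression, query_gene, genes) {
  genes <- setdiff(genes, query_gene)
  stopifnot(length(genes) > 0)
  q <- as.numeric(expression[query_gene, ])
  mean(as.numeric(stats::cor(t(expression[genes, , drop = FALSE]), q)))
}
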