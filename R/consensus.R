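#' Classify eQTL interactions as cis or trans
#'
#' An interaction is cis when its region lies on the gene's own
#' chromosome and the minimum distance from the transcription start site
#' to the `[start, end]` interval is at most `window_bp` (zero when the
#' TSS falls inside the region; a distance of exactly `window_bp` is
#' still cis). Everything else is trans.
#'
#' @param interactions data frame with `gene_id`, `chrom`, `start_bp`,
#'   `end_bp` (one row per mapped interaction).
#' @param gene_annotation data frame with `gene_id`, `chrom`, `tss_bp`.
#' @param window_bp cis window from the TSS (default 1,000,000).
#' @return `interactions` with a `class` column (`"cis"`/`"trans"`).
#' @export
classify_cis_trans <- function(interactions, gene_annotation,
                               window_bp = 1e6) {
  idx <- match(interactions$gene_id, gene_annotation$gene_id)
  if (anyNA(idx)) {
    stop("unannotated gene(s): ",
         paste(unique(interactions$gene_id[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  tss <- gene_annotation$tss_bp[idx]
  same <- interactions$chrom == gene_annotation$chrom[idx]
  dist <- pmax(interactions$start_bp - tss, tss - interactions$end_bp, 0)
  interactions$class <- ifelse(same & dist <= window_bp, "cis", "trans")
  interactions
}

#' Pad a region symmetrically, clamped to the chromosome
#'
#' @param start_bp,end_bp region bounds.
#' @param pad_bp padding added on both sides (default 500,000).
#' @param chrom_length_bp chromosome length for the right clamp
#'   (default `Inf`).
#' @return a two-column matrix `start`, `end`.
#' @export
expand_region <- function(start_bp, end_bp, pad_bp = 5e5,
                          chrom_length_bp = Inf) {
  cbind(start = pmax(1, start_bp - pad_bp),
        end = pmin(chrom_length_bp, end_bp + pad_bp))
}

#' Merge interactions found by at least two methods
#'
#' Per gene and per cis/trans class, interactions from the three scan
#' methods are compared pairwise (ICIM vs IM, ICIM vs GCIM, IM vs GCIM).
#' Two interactions co-validate when they target the same gene, lie on
#' the same chromosome, and their `pad_bp`-padded intervals intersect
#' (equivalent to an edge-to-edge distance of at most `2 * pad_bp`,
#' i.e. "within 1 Mbp of each other" at the default). Co-validated pairs
#' are union-merged into consensus regions; a region appearing in more
#' than one pairwise comparison is collapsed to a single record. Finally,
#' any trans consensus region whose padded interval intersects a cis
#' consensus region of the same gene is reclassified as cis.
#'
#' Consensus coordinates are the un-padded union of the contributing
#' regions; padding is only the overlap test.
#'
#' @param interactions data frame with `gene_id`, `method`, `chrom`,
#'   `start_bp`, `end_bp`, `class`, and optionally `lod`, `pve`; at least
#'   two distinct methods must be present.
#' @param pad_bp padding used for the overlap test (default 500,000).
#' @return data frame of consensus regions: `gene_id`, `chrom`,
#'   `start_bp`, `end_bp`, `class`, `methods` (comma-joined, sorted),
#'   `n_methods`, `n_interactions`, `max_lod`.
#' @export
merge_methods <- function(interactions, pad_bp = 5e5) {
  if (length(unique(interactions$method)) < 2) {
    stop("interactions from at least two methods are required",
         call. = FALSE)
  }
  if (is.null(interactions$class)) {
    stop("interactions must carry a cis/trans class; run ",
         "classify_cis_trans() first", call. = FALSE)
  }
  if (is.null(interactions$lod)) interactions$lod <- NA_real_
  out <- list()
  split_key <- paste(interactions$gene_id, interactions$class)
  for (kk in unique(split_key)) {
    sub <- interactions[split_key == kk, , drop = FALSE]
    n <- nrow(sub)
    pad <- expand_region(sub$start_bp, sub$end_bp, pad_bp)
    parent <- seq_len(n)
    find <- function(i) {
      while (parent[i] != i) i <- parent[i]
      i
    }
    linked <- rep(FALSE, n)
    if (n >= 2) {
      for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        if (sub$method[i] == sub$method[j]) next
        if (sub$chrom[i] != sub$chrom[j]) next
        if (pad[i, 1] <= pad[j, 2] && pad[j, 1] <= pad[i, 2]) {
          parent[find(i)] <- find(j)
          linked[i] <- linked[j] <- TRUE
        }
      }
    }
    comp <- vapply(seq_len(n), find, integer(1))
    for (cc in unique(comp[linked])) {
      mem <- sub[comp == cc, , drop = FALSE]
      if (length(unique(mem$method)) < 2) next
      out[[length(out) + 1]] <- data.frame(
        gene_id = mem$gene_id[1], chrom = mem$chrom[1],
        start_bp = min(mem$start_bp), end_bp = max(mem$end_bp),
        class = mem$class[1],
        methods = paste(sort(unique(mem$method)), collapse = ","),
        n_methods = length(unique(mem$method)), n_interactions = nrow(mem),
        max_lod = suppressWarnings(max(mem$lod, na.rm = TRUE)),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0) {
    return(data.frame(gene_id = character(0), chrom = character(0),
                      start_bp = numeric(0), end_bp = numeric(0),
                      class = character(0), methods = character(0),
                      n_methods = integer(0), n_interactions = integer(0),
                      max_lod = numeric(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res$max_lod[!is.finite(res$max_lod)] <- NA_real_
  # trans regions overlapping a cis region of the same gene become cis
  for (i in which(res$class == "trans")) {
    cis <- res[res$gene_id == res$gene_id[i] & res$class == "cis" &
                 res$chrom == res$chrom[i], , drop = FALSE]
    if (nrow(cis) == 0) next
    pi <- expand_region(res$start_bp[i], res$end_bp[i], pad_bp)
    if (any(pi[1, 1] <= cis$end_bp & cis$start_bp <= pi[1, 2])) {
      res$class[i] <- "cis"
    }
  }
  res <- res[order(res$gene_id, res$class, res$chrom, res$start_bp), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Codification strings for interactions
#'
#' One-line text encoding of an interaction,
#' `"<class>_<gene>_<chrom> <start> <end>"`; for example
#' `"trans_Glyma.01G123600_GM05 40000 200000"` is the region
#' 40,000-200,000 on chromosome GM05 interacting in trans with the gene.
#'
#' @param class `"cis"` or `"trans"`.
#' @param gene_id gene identifier.
#' @param chrom chromosome of the interacting region.
#' @param start_bp,end_bp region bounds.
#' @return `codify_interaction()` returns the string;
#'   `parse_codification()` returns a data frame with the five fields.
#' @export
codify_interaction <- function(class, gene_id, chrom, start_bp, end_bp) {
  stopifnot(all(class %in% c("cis", "trans")))
  sprintf("%s_%s_%s %d %d", class, gene_id, chrom,
          as.integer(start_bp), as.integer(end_bp))
}

#' @rdname codify_interaction
#' @param x codification string(s).
#' @export
parse_codification <- function(x) {
  parts <- strsplit(x, " ", fixed = TRUE)
  bad <- vapply(parts, length, 0L) != 3
  if (any(bad)) stop("malformed codification string", call. = FALSE)
  head <- vapply(parts, `[[`, "", 1)
  m <- regmatches(head, regexec("^(cis|trans)_(.+)_([^_]+)$", head))
  if (any(vapply(m, length, 0L) != 4)) {
    stop("malformed codification string", call. = FALSE)
  }
  data.frame(
    class = vapply(m, `[[`, "", 2),
    gene_id = vapply(m, `[[`, "", 3),
    chrom = vapply(m, `[[`, "", 4),
    start_bp = as.numeric(vapply(parts, `[[`, "", 2)),
    end_bp = as.numeric(vapply(parts, `[[`, "", 3)),
    stringsAsFactors = FALSE
  )
}
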