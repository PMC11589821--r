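#' Estimate the recombination fraction between two adjacent markers
#'
#' For RIL populations the observed recombinant fraction between
#' homozygous calls is mapped back through the selfed-RIL expansion
#' `r_obs = 2r / (1 + 2r)`, i.e. `r = r_obs / (2 - 2 r_obs)`. For F2
#' populations a maximum-likelihood estimate is obtained by
#' expectation-maximization over the nine unordered genotype-pair classes
#' (the double-heterozygote class carries the phase ambiguity). Missing
#' calls are excluded pairwise.
#'
#' @param genotypes lines x markers character matrix (`A`/`H`/`B`, `NA`).
#' @param marker_a,marker_b marker ids (column names).
#' @param population `"F2"` or `"RIL"`.
#' @param min_lines minimum shared non-missing lines (default 10).
#' @return estimated recombination fraction, clamped to `[0, 0.4999]`.
#' @export
estimate_adjacent_r <- function(genotypes, marker_a, marker_b,
                                population = c("F2", "RIL"),
                                min_lines = 10) {
  population <- match.arg(population)
  if (!all(c(marker_a, marker_b) %in% colnames(genotypes))) {
    stop("both markers must be present in the genotype matrix", call. = FALSE)
  }
  num <- geno_to_numeric(genotypes[, c(marker_a, marker_b), drop = FALSE])
  a <- num[, 1]
  b <- num[, 2]
  if (population == "RIL") {
    keep <- !is.na(a) & !is.na(b) & a != 1 & b != 1
    if (sum(keep) < min_lines) {
      stop("fewer than ", min_lines, " shared non-missing lines", call. = FALSE)
    }
    r_obs <- mean(a[keep] != b[keep])
    r <- if (r_obs >= 1) 0.4999 else r_obs / (2 - 2 * r_obs)
  } else {
    keep <- !is.na(a) & !is.na(b)
    if (sum(keep) < min_lines) {
      stop("fewer than ", min_lines, " shared non-missing lines", call. = FALSE)
    }
    r <- f2_em_r(a[keep], b[keep])
  }
  min(max(r, 0), 0.4999)
}

# EM for the F2 recombination fraction from unordered genotype pairs.
# Every class except the double heterozygote has a known recombinant-gamete
# count; the double het is a mixture of 0 (parental x parental) and 2
# (recombinant x recombinant) recombinant gametes.
f2_em_r <- function(a, b) {
  n <- length(a)
  tab <- table(factor(a, 0:2), factor(b, 0:2))
  # recombinant gametes contributed by each (a, b) class
  rec <- matrix(c(0, 1, 2,
                  1, NA, 1,
                  2, 1, 0), 3, 3, byrow = TRUE)
  fixed_rec <- sum(tab * ifelse(is.na(rec), 0, rec))
  n_dh <- tab[2, 2]
  r <- 0.25
  for (it in 1:100) {
    e_dh <- if (n_dh > 0) 2 * r^2 / (r^2 + (1 - r)^2) else 0
    r_new <- (fixed_rec + n_dh * e_dh) / (2 * n)
    if (abs(r_new - r) < 1e-12) break
    r <- r_new
  }
  r
}

#' Build a physically anchored linkage map
#'
#' Orders markers by chromosome and physical position, estimates adjacent
#' recombination fractions from the genotype matrix, converts them to
#' Kosambi centiMorgans, and accumulates positions. Wherever an adjacent
#' gap strictly exceeds `split_gap_cM`, a new linkage group starts; split
#' chromosomes get letter suffixes (`GM13a`, `GM13b`, ...). Duplicate
#' physical positions on a chromosome are tie-broken by marker id with a
#' warning.
#'
#' @param genotypes lines x markers character matrix.
#' @param marker_positions data frame with `marker_id`, `chrom`, `pos_bp`.
#' @param population `"F2"` or `"RIL"`.
#' @param split_gap_cM gap threshold; exactly 30.0 cM stays joined.
#' @return a `genetic_map` data frame: `linkage_group`, `marker_id`,
#'   `chrom`, `pos_bp`, `pos_cM` (cumulative within group, restarting at 0).
#' @export
build_map <- function(genotypes, marker_positions,
                      population = c("F2", "RIL"), split_gap_cM = 30) {
  population <- match.arg(population)
  if (!all(marker_positions$marker_id %in% colnames(genotypes))) {
    stop("every marker needs a genotype column", call. = FALSE)
  }
  out <- list()
  for (chr in unique(marker_positions$chrom)) {
    mp <- marker_positions[marker_positions$chrom == chr, , drop = FALSE]
    if (anyDuplicated(mp$pos_bp)) {
      warning("duplicate physical positions on ", chr,
              "; tie-broken by marker id", call. = FALSE)
    }
    mp <- mp[order(mp$pos_bp, mp$marker_id), , drop = FALSE]
    m <- nrow(mp)
    d <- numeric(0)
    if (m > 1) {
      d <- vapply(seq_len(m - 1), function(i) {
        kosambi_cm(estimate_adjacent_r(genotypes, mp$marker_id[i],
                                       mp$marker_id[i + 1], population))
      }, numeric(1))
    }
    grp <- cumsum(c(0, d > split_gap_cM))
    n_grp <- max(grp) + 1
    for (g in seq_len(n_grp) - 1) {
      idx <- which(grp == g)
      lg <- if (n_grp == 1) chr else paste0(chr, letters[g + 1])
      within_d <- if (length(idx) > 1) d[idx[-length(idx)]] else numeric(0)
      out[[length(out) + 1]] <- data.frame(
        linkage_group = lg, marker_id = mp$marker_id[idx], chrom = chr,
        pos_bp = mp$pos_bp[idx], pos_cM = cumsum(c(0, within_d)),
        stringsAsFactors = FALSE
      )
    }
  }
  map <- do.call(rbind, out)
  rownames(map) <- NULL
  class(map) <- c("genetic_map", "data.frame")
  map
}
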