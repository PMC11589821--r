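#' Count trans interactions per regulating marker-pair region
#'
#' Tallies how many trans interactions each distinct regulating region
#' (chromosome, left bound, right bound) controls, and attaches the
#' per-kbp interaction density.
#'
#' @param consensus_trans data frame of consensus trans regions
#'   (`gene_id`, `chrom`, `start_bp`, `end_bp`), one row per interaction.
#' @return data frame: `chrom`, `start_bp`, `end_bp`, `size_bp`, `count`,
#'   `density` (interactions/kbp; `NA` for zero-width regions, which are
#'   flagged and excluded from the density percentile pool).
#' @export
count_by_marker_pair <- function(consensus_trans) {
  if (nrow(consensus_trans) == 0) {
    return(data.frame(chrom = character(0), start_bp = numeric(0),
                      end_bp = numeric(0), size_bp = numeric(0),
                      count = integer(0), density = numeric(0),
                      stringsAsFactors = FALSE))
  }
  key <- paste(consensus_trans$chrom, consensus_trans$start_bp,
               consensus_trans$end_bp)
  tab <- table(key)
  first <- consensus_trans[!duplicated(key), , drop = FALSE]
  first <- first[order(first$chrom, first$start_bp, first$end_bp), ,
                 drop = FALSE]
  count <- as.integer(tab[paste(first$chrom, first$start_bp,
                                first$end_bp)])
  out <- data.frame(
    chrom = first$chrom, start_bp = first$start_bp, end_bp = first$end_bp,
    size_bp = first$end_bp - first$start_bp, count = count,
    stringsAsFactors = FALSE
  )
  out$density <- ifelse(out$size_bp > 0,
                        interaction_density(out$count, out$start_bp,
                                            out$end_bp),
                        NA_real_)
  rownames(out) <- NULL
  out
}

#' Trans-interaction density of a region
#'
#' Average number of trans interactions per kilobase spanned by a pair of
#' flanking markers: `count / ((right - left) / 1000)`. Outputs are
#' conventionally reported to two decimals; the value returned here is
#' unrounded.
#'
#' @param count number of trans interactions in the region.
#' @param left_bp,right_bp flanking marker positions, `right > left`.
#' @return density in interactions/kbp.
#' @export
interaction_density <- function(count, left_bp, right_bp) {
  if (any(right_bp <= left_bp)) {
    stop("right_bp must exceed left_bp (zero-width regions have ",
         "undefined density)", call. = FALSE)
  }
  count / ((right_bp - left_bp) / 1000)
}

#' Classify marker-pair regions into major/minor hotspots
#'
#' A region is a hotspot only when it passes both criteria: its
#' trans-interaction count reaches the population count percentile
#' (99th for major, 95th for minor) AND its density reaches the 80th
#' density percentile. Counts at or above the 99th percentile are major;
#' counts in `[95th, 99th)` are minor; everything else (including
#' high-count regions below the density cutoff) is `"none"`. Percentiles
#' use linear interpolation and boundary values are included, computed
#' over all supplied regions of the population (zero-width regions are
#' excluded from the density pool but remain count-eligible, with their
#' density criterion treated as not met).
#'
#' @param regions output of [count_by_marker_pair()] (>= 2 regions).
#' @param population `"F2"` or `"RIL"` tag used in region names.
#' @param count_pct_minor,count_pct_major,density_pct percentile settings
#'   (defaults 95/99/80).
#' @return `regions` with `class` (`major`/`minor`/`none`) and `name`
#'   columns, plus the thresholds as attributes `count_minor`,
#'   `count_major`, `density_min`.
#' @export
classify_hotspots <- function(regions, population = c("F2", "RIL"),
                              count_pct_minor = 95, count_pct_major = 99,
                              density_pct = 80) {
  population <- match.arg(population)
  if (nrow(regions) < 2) {
    stop("need at least 2 regions to form percentile thresholds",
         call. = FALSE)
  }
  cmin <- percentile(regions$count, count_pct_minor)
  cmaj <- percentile(regions$count, count_pct_major)
  dpool <- regions$density[!is.na(regions$density)]
  dmin <- if (length(dpool) > 0) percentile(dpool, density_pct) else Inf
  dense_ok <- !is.na(regions$density) & regions$density >= dmin
  regions$class <- ifelse(
    regions$count >= cmaj & dense_ok, "major",
    ifelse(regions$count >= cmin & regions$count < cmaj & dense_ok,
           "minor", "none")
  )
  regions$name <- region_name(population, regions$chrom, regions$start_bp,
                              regions$end_bp)
  attr(regions, "count_minor") <- cmin
  attr(regions, "count_major") <- cmaj
  attr(regions, "density_min") <- dmin
  attr(regions, "population") <- population
  regions
}

#' Merge hotspots that share a boundary marker
#'
#' Hotspot regions on the same chromosome whose bounds touch (the right
#' marker of one is the left marker of the next) are merged into a single
#' region spanning `min(left)`-`max(right)`; counts are summed, density
#' recomputed, the class is the stronger of the two
#' (major > minor > none), and the region is renamed.
#'
#' @param hotspots classified hotspot data frame from
#'   [classify_hotspots()] (or any subset of it).
#' @return merged hotspot data frame.
#' @export
merge_adjacent <- function(hotspots) {
  if (nrow(hotspots) <= 1) return(hotspots)
  population <- attr(hotspots, "population") %||% "F2"
  h <- hotspots[order(hotspots$chrom, hotspots$start_bp), , drop = FALSE]
  rank <- c(none = 0, minor = 1, major = 2)
  out <- h[1, , drop = FALSE]
  for (i in 2:nrow(h)) {
    last <- nrow(out)
    if (h$chrom[i] == out$chrom[last] &&
        h$start_bp[i] == out$end_bp[last]) {
      out$end_bp[last] <- h$end_bp[i]
      out$count[last] <- out$count[last] + h$count[i]
      out$size_bp[last] <- out$end_bp[last] - out$start_bp[last]
      out$density[last] <- interaction_density(out$count[last],
                                               out$start_bp[last],
                                               out$end_bp[last])
      if (!is.null(h$class)) {
        out$class[last] <- names(rank)[
          max(rank[out$class[last]], rank[h$class[i]]) + 1]
      }
    } else {
      out <- rbind(out, h[i, , drop = FALSE])
    }
  }
  if (!is.null(out$name)) {
    out$name <- region_name(population, out$chrom, out$start_bp, out$end_bp)
  }
  rownames(out) <- NULL
  out
}

#' Canonical hotspot region name
#'
#' `"<TAG>_<CHROM>:<start>-<end>"` with thousands-separated coordinates,
#' e.g. `F2_GM18:1,434,182-1,935,386`.
#'
#' @param population_tag `"F2"` or `"RIL"`.
#' @param chrom chromosome label.
#' @param start_bp,end_bp region bounds.
#' @return character vector of names.
#' @export
region_name <- function(population_tag, chrom, start_bp, end_bp) {
  sprintf("%s_%s:%s-%s", population_tag, chrom, format_bp(start_bp),
          format_bp(end_bp))
}

#' @rdname region_name
#' @param name region name string(s) to parse back.
#' @export
parse_region_name <- function(name) {
  m <- regmatches(name, regexec("^([^_]+)_([^:]+):([0-9,]+)-([0-9,]+)$",
                                name))
  if (any(vapply(m, length, 0L) != 5)) {
    stop("malformed region name", call. = FALSE)
  }
  data.frame(
    population_tag = vapply(m, `[[`, "", 2),
    chrom = vapply(m, `[[`, "", 3),
    start_bp = as.numeric(gsub(",", "", vapply(m, `[[`, "", 4))),
    end_bp = as.numeric(gsub(",", "", vapply(m, `[[`, "", 5))),
    stringsAsFactors = FALSE
  )
}
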