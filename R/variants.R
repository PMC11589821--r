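#' SIFT verdict from a score
#'
#' Scores below 0.05 are deleterious; scores at or above 0.05 are
#' tolerated; missing scores give `"N/A"`.
#'
#' @param score numeric SIFT score(s) in `[0, 1]` or `NA`.
#' @return character vector of verdicts.
#' @export
sift_verdict <- function(score) {
  ifelse(is.na(score), "N/A",
         ifelse(score < 0.05, "deleterious", "tolerated"))
}

#' Candidate-variant prioritization cascade
#'
#' Keeps variants located in listed transcription-factor genes that
#' satisfy, in order: (1) consequence class MODERATE or HIGH, OR location
#' in the 3'UTR / 5'UTR; (2) the alternate allele is present in a single
#' parental line: exactly one parent is a homozygous carrier (a
#' heterozygous call in the other parent, encoded `"ref/alt"`, is flagged
#' with an asterisk in rendered tables but does not block the variant),
#' or a lone heterozygous carrier faces a parent matching the reference
#' allele. Variants in unlisted genes are silently excluded;
#' variants missing a parental genotype are dropped with a warning. A
#' SIFT verdict is attached (scores below 0.05 deleterious, at or above
#' 0.05 tolerated).
#'
#' @param variants data frame with `gene_id`, `chrom`, `pos_bp`, `ref`,
#'   `alt`, `consequence` (`HIGH`/`MODERATE`/`LOW`/`MODIFIER`),
#'   `location` (`CDS`/`3'UTR`/`5'UTR`/`other`), `sift_score`, `parent1`,
#'   `parent2`, `reference_allele`; parent columns hold the carried
#'   allele, `"ref/alt"` for heterozygotes.
#' @param tf_gene_list character vector of candidate TF gene ids.
#' @return the retained rows with added `sift_verdict`, `het_parent`
#'   (which parent is heterozygous, if any) and `carrier` columns.
#' @export
filter_candidates <- function(variants, tf_gene_list) {
  v <- variants[variants$gene_id %in% tf_gene_list, , drop = FALSE]
  if (nrow(v) == 0) return(annotate_candidates(v))
  miss <- is.na(v$parent1) | is.na(v$parent2)
  if (any(miss)) {
    warning(sum(miss), " variant(s) dropped for missing parental genotype",
            call. = FALSE)
    v <- v[!miss, , drop = FALSE]
  }
  effect_ok <- v$consequence %in% c("MODERATE", "HIGH") |
    v$location %in% c("3'UTR", "5'UTR")
  v <- v[effect_ok, , drop = FALSE]
  het1 <- grepl("/", v$parent1, fixed = TRUE)
  het2 <- grepl("/", v$parent2, fixed = TRUE)
  hom_alt1 <- !het1 & v$parent1 == v$alt
  hom_alt2 <- !het2 & v$parent2 == v$alt
  hom_ref1 <- !het1 & v$parent1 == v$ref
  hom_ref2 <- !het2 & v$parent2 == v$ref
  het_carries1 <- het1 & carries_alt(v$parent1, v$alt)
  het_carries2 <- het2 & carries_alt(v$parent2, v$alt)
  # "present in a single parental line": exactly one homozygous carrier
  # (a heterozygous other parent is flagged but does not block), or a
  # lone heterozygous carrier against a reference-matching parent
  single <- (hom_alt1 + hom_alt2 == 1) |
    (hom_alt1 + hom_alt2 == 0 &
       ((het_carries1 & hom_ref2) | (het_carries2 & hom_ref1)))
  v <- annotate_candidates(v[single, , drop = FALSE])
  rownames(v) <- NULL
  v
}

carries_alt <- function(geno, alt) {
  if (length(geno) == 0) return(logical(0))
  het <- grepl("/", geno, fixed = TRUE)
  mapply(function(g, a, h) {
    if (h) a %in% strsplit(g, "/", fixed = TRUE)[[1]] else g == a
  }, geno, alt, het, USE.NAMES = FALSE)
}

annotate_candidates <- function(v) {
  v$sift_verdict <- sift_verdict(v$sift_score)
  if (nrow(v) == 0) {
    v$het_parent <- character(0)
    v$carrier <- character(0)
    return(v)
  }
  het1 <- grepl("/", v$parent1, fixed = TRUE)
  het2 <- grepl("/", v$parent2, fixed = TRUE)
  v$het_parent <- ifelse(het1 & het2, "both",
                         ifelse(het1, "parent1",
                                ifelse(het2, "parent2", "none")))
  hom_alt1 <- !het1 & v$parent1 == v$alt
  hom_alt2 <- !het2 & v$parent2 == v$alt
  v$carrier <- ifelse(hom_alt1, "parent1",
                      ifelse(hom_alt2, "parent2",
                             ifelse(carries_alt(v$parent1, v$alt),
                                    "parent1", "parent2")))
  v
}

#' Tabulate retained candidate variants per region
#'
#' Assigns each retained variant's gene to the regions whose interval
#' lies within `window_bp` of the gene's TSS on the same chromosome (a
#' candidate just outside a hotspot, within the default 300 kbp, is still
#' reported), and renders one row per variant in the conventional layout:
#' region name, gene, SNP coordinate, REF/ALT alleles, a
#' `reference/parent1/parent2` genotype string (heterozygotes marked with
#' an asterisk), location, and SIFT/consequence annotation.
#'
#' @param candidates output of [filter_candidates()].
#' @param regions data frame with `chrom`, `start_bp`, `end_bp`, `name`.
#' @param gene_annotation data frame with `gene_id`, `chrom`, `tss_bp`.
#' @param window_bp proximity window for region assignment
#'   (default 300,000).
#' @return data frame: `region`, `gene_id`, `snp`, `ref`, `alt`,
#'   `genotypes`, `location`, `sift_consequence`.
#' @export
summarize_candidates <- function(candidates, regions, gene_annotation,
                                 window_bp = 3e5) {
  out <- list()
  for (i in seq_len(nrow(candidates))) {
    v <- candidates[i, , drop = FALSE]
    ann <- gene_annotation[gene_annotation$gene_id == v$gene_id, ]
    if (nrow(ann) == 0) next
    hit <- regions$chrom == ann$chrom &
      pmax(regions$start_bp - ann$tss_bp, ann$tss_bp - regions$end_bp, 0) <=
        window_bp
    for (r in which(hit)) {
      g1 <- if (grepl("/", v$parent1)) paste0(sub(".*/", "", v$parent1), "*")
        else v$parent1
      g2 <- if (grepl("/", v$parent2)) paste0(sub(".*/", "", v$parent2), "*")
        else v$parent2
      sc <- if (v$location == "CDS" && v$consequence == "MODERATE") {
        paste0("Missense (",
               if (v$sift_verdict == "deleterious") "Deleterious"
               else "Tolerated", ")")
      } else {
        "N/A"
      }
      out[[length(out) + 1]] <- data.frame(
        region = regions$name[r], gene_id = v$gene_id,
        snp = paste0(v$chrom, ":", format_bp(v$pos_bp)), ref = v$ref,
        alt = v$alt,
        genotypes = paste(v$reference_allele, g1, g2, sep = "/"),
        location = v$location, sift_consequence = sc,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0) {
    return(data.frame(region = character(0), gene_id = character(0),
                      snp = character(0), ref = character(0),
                      alt = character(0), genotypes = character(0),
                      location = character(0),
                      sift_consequence = character(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write variants as a minimal VCF 4.2 file
#'
#' Emits a valid VCF body (CHROM/POS/ID/REF/ALT/QUAL/FILTER/INFO) for a
#' variant table; companion annotations (consequence, location, SIFT,
#' parental alleles) belong in a side TSV, mirroring how effect-predictor
#' output is shipped alongside a call set.
#'
#' @param variants variant data frame (see [filter_candidates()]).
#' @param vcf_path output VCF path.
#' @param annotation_path optional output path for the annotation TSV.
#' @return `vcf_path`, invisibly.
#' @export
write_variants_vcf <- function(variants, vcf_path, annotation_path = NULL) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=eqtlhot-simulated",
    paste0("##INFO=<ID=GENE,Number=1,Type=String,",
           "Description=\"Gene identifier\">"),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- if (nrow(variants) == 0) character(0) else sprintf(
    "%s\t%d\t%s\t%s\t%s\t.\tPASS\tGENE=%s",
    variants$chrom, as.integer(variants$pos_bp),
    paste0(variants$chrom, "_", as.integer(variants$pos_bp)),
    variants$ref, variants$alt, variants$gene_id
  )
  writeLines(c(header, body), vcf_path)
  if (!is.null(annotation_path)) {
    utils::write.table(variants, annotation_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(vcf_path)
}

#' Read a VCF plus companion annotation TSV into a variant table
#'
#' Uses the `vcfR` package when available to parse the VCF body and joins
#' the companion annotation by chromosome and position; falls back to a
#' plain-text parse of the fixed VCF columns otherwise.
#'
#' @param vcf_path VCF 4.2 file.
#' @param annotation_path companion TSV with the [filter_candidates()]
#'   columns.
#' @return variant data frame.
#' @export
read_variant_table <- function(vcf_path, annotation_path) {
  ann <- utils::read.table(annotation_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "")
  fixed <- if (requireNamespace("vcfR", quietly = TRUE)) {
    v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
    data.frame(chrom = vcfR::getCHROM(v), pos_bp = vcfR::getPOS(v),
               ref = vcfR::getREF(v), alt = vcfR::getALT(v),
               stringsAsFactors = FALSE)
  } else {
    lines <- readLines(vcf_path)
    lines <- lines[!startsWith(lines, "#")]
    if (length(lines) == 0) {
      data.frame(chrom = character(0), pos_bp = numeric(0),
                 ref = character(0), alt = character(0),
                 stringsAsFactors = FALSE)
    } else {
      f <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
      data.frame(chrom = f[, 1], pos_bp = as.numeric(f[, 2]), ref = f[, 4],
                 alt = f[, 5], stringsAsFactors = FALSE)
    }
  }
  key_v <- paste(fixed$chrom, fixed$pos_bp)
  key_a <- paste(ann$chrom, ann$pos_bp)
  ann[match(key_v, key_a), , drop = FALSE]
}
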