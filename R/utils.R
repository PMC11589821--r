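#' Empirical percentile with linear interpolation
#'
#' Percentiles throughout the package (permutation thresholds, hotspot
#' count/density cutoffs) use the linear-interpolation definition between
#' order statistics (type 7 in [stats::quantile()]).
#'
#' @param x numeric vector.
#' @param p percentile in `[0, 100]`.
#' @return the interpolated percentile value.
#' @export
percentile <- function(x, p) {
  stopifnot(is.numeric(x), length(x) >= 1, p >= 0, p <= 100)
  stats::quantile(x, probs = p / 100, type = 7, names = FALSE, na.rm = FALSE)
}

#' Format a base-pair coordinate with thousands separators
#' @param x integer-valued coordinate(s).
#' @return character vector like `"1,434,182"`.
#' @export
format_bp <- function(x) {
  formatC(round(x), big.mark = ",", format = "d")
}

# Derive a deterministic 32-bit substream seed from a root seed and a stage
# name, so each pipeline stage has its own reproducible stream.
substream_seed <- function(root_seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(root_seed) * 7919 + h) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Convert A/H/B character genotype calls to B-allele counts 0/1/2 (NA kept).
geno_to_numeric <- function(g) {
  out <- matrix(NA_real_, nrow(g), ncol(g), dimnames = dimnames(g))
  out[g == "A"] <- 0
  out[g == "H"] <- 1
  out[g == "B"] <- 2
  out
}
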