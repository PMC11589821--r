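#' Kosambi map distance
#'
#' Converts a recombination fraction into centiMorgans using the Kosambi
#' mapping function, `m = 25 * ln((1 + 2r) / (1 - 2r))`, which accounts for
#' crossover interference between nearby exchanges.
#'
#' @param r recombination fraction(s), `0 <= r < 0.5`.
#' @return map distance in centiMorgans.
#' @seealso [kosambi_r()] for the inverse.
#' @examples
#' kosambi_cm(0.25) # 25 * log(3) = 27.47 cM
#' @export
kosambi_cm <- function(r) {
  if (any(!is.finite(r)) || any(r < 0) || any(r >= 0.5)) {
    stop("recombination fraction must satisfy 0 <= r < 0.5", call. = FALSE)
  }
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' Inverse Kosambi function
#'
#' Converts a Kosambi map distance back to a recombination fraction,
#' `r = tanh(m / 50) / 2`.
#'
#' @param cm map distance(s) in centiMorgans, `cm >= 0`.
#' @return recombination fraction in `[0, 0.5)`.
#' @export
kosambi_r <- function(cm) {
  if (any(!is.finite(cm)) || any(cm < 0)) {
    stop("map distance must be a finite non-negative number", call. = FALSE)
  }
  tanh(cm / 50) / 2
}
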