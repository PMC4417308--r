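#' Kosambi mapping function and its inverse
#'
#' Converts a recombination fraction r into map distance
#' d = 25 * ln((1 + 2r) / (1 - 2r)) centiMorgans, which accounts for partial
#' crossover interference, and back via r = tanh(d / 50) / 2.
#'
#' @param r Recombination fraction(s) in \[0, 0.5).
#' @param d Map distance(s) in centiMorgans, >= 0.
#' @return `kosambi()`: distance in cM; `kosambi_inv()`: recombination
#'   fraction. Round-trip `kosambi_inv(kosambi(r))` recovers `r` to 1e-12.
#' @examples
#' kosambi(0.2)       # 21.18 cM
#' kosambi_inv(50)    # r for a 50 cM interval
#' @export
kosambi <- function(r) {
  if (any(r < 0 | r >= 0.5)) stop("r must lie in [0, 0.5)", call. = FALSE)
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' @rdname kosambi
#' @export
kosambi_inv <- function(d) {
  if (any(d < 0)) stop("d must be >= 0", call. = FALSE)
  0.5 * tanh(d / 50)
}

#' Haldane mapping function and its inverse
#'
#' d = -50 * ln(1 - 2r) centiMorgans, the map function under which
#' recombination fractions compose without crossover interference
#' (r13 = r12 + r23 - 2 r12 r23). Used internally where two-point
#' recombination fractions spanning many intervals must be combined
#' additively; reported map intervals use [kosambi()].
#'
#' @inheritParams kosambi
#' @return `haldane()`: distance in cM; `haldane_inv()`: recombination
#'   fraction.
#' @export
haldane <- function(r) {
  if (any(r < 0 | r >= 0.5)) stop("r must lie in [0, 0.5)", call. = FALSE)
  -50 * log(1 - 2 * r)
}

#' @rdname haldane
#' @export
haldane_inv <- function(d) {
  if (any(d < 0)) stop("d must be >= 0", call. = FALSE)
  0.5 * (1 - exp(-d / 50))
}
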