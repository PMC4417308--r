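#' @useDynLib cpmap, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Genotype codes used throughout: "AA", "AB", "BB" on the ref/alt axis
# (A = ref allele, B = alt allele); NA = missing call.
GT_LEVELS <- c("AA", "AB", "BB")

#' Rand index between two partitions
#'
#' Plain (unadjusted) Rand index: the fraction of object pairs on which two
#' partitions agree (both together or both apart).
#'
#' @param a,b Vectors of group labels over the same objects.
#' @return A number in \[0, 1\].
#' @export
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  n <- length(a)
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_i <- sum(choose(rowSums(tab), 2))
  sum_j <- sum(choose(colSums(tab), 2))
  total <- choose(n, 2)
  (total + 2 * sum_ij - sum_i - sum_j) / total
}

#' Kendall rank correlation of an inferred order against a true order
#'
#' Reported as the maximum of |tau| over the order and its reversal, because a
#' linkage group has no intrinsic left/right end.
#'
#' @param inferred,truth Vectors giving positions (ranks) of the same markers.
#' @return |tau| in \[0, 1\].
#' @export
order_agreement <- function(inferred, truth) {
  stopifnot(length(inferred) == length(truth))
  if (length(inferred) < 2) return(1)
  abs(stats::cor(inferred, truth, method = "kendall"))
}

# internal: stop with a field-named validation message
check_that <- function(ok, field, msg) {
  if (!isTRUE(ok)) stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

# internal: proportions summing to 1 within tolerance
check_props <- function(p, field) {
  check_that(all(p >= 0), field, "proportions must be non-negative")
  check_that(abs(sum(p) - 1) <= 1e-9, field, "proportions must sum to 1")
}
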