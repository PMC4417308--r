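# Two-point linkage analysis for a CP (outbred full-sib) family.
#
# Each parent may be heterozygous at either marker independently, so phase
# (which alleles sit on the same parental haplotype) is unknown and is
# enumerated explicitly: at most two configurations per parent, four per pair.

# internal: allele pair (0 = ref "A", 1 = alt "B") for a genotype string
.gt_alleles <- function(gt) {
  switch(gt, AA = c(0L, 0L), AB = c(0L, 1L), BB = c(1L, 1L),
         stop("unknown genotype: ", gt, call. = FALSE))
}

# internal: 3x3 two-locus genotype probability matrix (rows = genotype at
# locus i, cols = locus j; codes AA/AB/BB) for given r and per-parent phase.
# phase: 0 = coupling (first-listed alleles on one haplotype), 1 = repulsion.
.pair_prob_matrix <- function(mat_i, mat_j, pat_i, pat_j,
                              phase_mat, phase_pat, r) {
  gamete_probs <- function(phase) {
    # prob of transmitting allele-slot u at locus i with slot v at locus j
    p <- matrix(r / 2, 2, 2)
    if (phase == 0) diag(p) <- (1 - r) / 2 else p[cbind(1:2, 2:1)] <- (1 - r) / 2
    p
  }
  pm <- gamete_probs(phase_mat)
  pp <- gamete_probs(phase_pat)
  P <- matrix(0, 3, 3)
  for (u in 1:2) for (v in 1:2) for (s in 1:2) for (t in 1:2) {
    gi <- mat_i[u] + pat_i[s]  # 0/1/2 -> AA/AB/BB
    gj <- mat_j[v] + pat_j[t]
    P[gi + 1, gj + 1] <- P[gi + 1, gj + 1] + pm[u, v] * pp[s, t]
  }
  P
}

# internal: 3x3 table of jointly non-missing progeny genotype pairs
.pair_counts <- function(g_i, g_j) {
  keep <- !is.na(g_i) & !is.na(g_j)
  tab <- matrix(0, 3, 3, dimnames = list(GT_LEVELS, GT_LEVELS))
  if (any(keep)) {
    t0 <- table(factor(g_i[keep], GT_LEVELS), factor(g_j[keep], GT_LEVELS))
    tab[] <- as.numeric(t0)
  }
  tab
}

#' Two-locus log-likelihood for a CP marker pair
#'
#' Generative likelihood of the observed progeny genotypes at two markers:
#' each progeny genotype is the union of one maternal and one paternal
#' gamete, each parent transmitting a phase-defined two-locus haplotype with
#' per-meiosis recombination probability `r`. Missing genotypes contribute a
#' factor of 1.
#'
#' @param m_i,m_j Marker records: lists with `maternal_gt`, `paternal_gt`
#'   (genotype strings `"AA"`, `"AB"`, `"BB"`) and `progeny_gts` (character
#'   vector, `NA` = missing).
#' @param phase Length-2 character vector `c(mat, pat)`, each `"coupling"`,
#'   `"repulsion"` or `"na"` (ignored for a parent not doubly heterozygous).
#' @param r Recombination fraction in \[0, 0.5\].
#' @return Natural-log likelihood.
#' @export
pair_log_likelihood <- function(m_i, m_j, phase = c("coupling", "coupling"),
                                r) {
  if (length(r) != 1 || r < 0 || r > 0.5)
    stop("r must lie in [0, 0.5]", call. = FALSE)
  ph <- match(phase, c("coupling", "repulsion", "na")) - 1L
  ph[ph == 2L] <- 0L  # "na" treated as coupling; likelihood is unaffected
  P <- .pair_prob_matrix(.gt_alleles(m_i$maternal_gt), .gt_alleles(m_j$maternal_gt),
                         .gt_alleles(m_i$paternal_gt), .gt_alleles(m_j$paternal_gt),
                         ph[1], ph[2], r)
  cnt <- .pair_counts(m_i$progeny_gts, m_j$progeny_gts)
  sum(cnt[cnt > 0] * log(pmax(P[cnt > 0], 1e-300)))
}

# internal: phase labels a parent can take for a marker pair
.phase_options <- function(gt_i, gt_j) {
  if (gt_i == "AB" && gt_j == "AB") c("coupling", "repulsion") else "na"
}

#' Two-point recombination fraction, phase and LOD for a marker pair
#'
#' Maximises [pair_log_likelihood()] jointly over the (at most four) phase
#' configurations and r, by a coarse grid followed by golden-section
#' refinement. LOD is log10 of the likelihood ratio at the MLE versus
#' independence (r = 0.5) under the best phase.
#'
#' A pair with no parent heterozygous at both markers carries no information
#' on recombination (e.g. a maternal-only x paternal-only pair): it is
#' returned with `rf = 0.5`, `lod = 0`, `informative_meioses = 0` and
#' `uninformative = TRUE`.
#'
#' @inheritParams pair_log_likelihood
#' @return A list of class `"two_point"`: `rf`, `phase` (per-parent),
#'   `lod`, `informative_meioses`, `uninformative`.
#' @export
estimate_two_point <- function(m_i, m_j) {
  for (m in list(m_i, m_j)) {
    if (is.na(m$maternal_gt) || is.na(m$paternal_gt))
      stop("parental genotypes must be non-missing", call. = FALSE)
  }
  n_complete <- sum(!is.na(m_i$progeny_gts) & !is.na(m_j$progeny_gts))
  het_both <- c(mat = m_i$maternal_gt == "AB" && m_j$maternal_gt == "AB",
                pat = m_i$paternal_gt == "AB" && m_j$paternal_gt == "AB")
  nim <- n_complete * sum(het_both)

  res <- list(marker_i = m_i$id %||% NA_character_,
              marker_j = m_j$id %||% NA_character_,
              rf = 0.5, phase = c(mat = "n/a", pat = "n/a"), lod = 0,
              informative_meioses = nim, uninformative = nim == 0)
  class(res) <- "two_point"
  if (nim == 0) return(res)

  best <- list(ll = -Inf, r = 0.5, phase = c("n/a", "n/a"))
  for (ph_m in .phase_options(m_i$maternal_gt, m_j$maternal_gt)) {
    for (ph_p in .phase_options(m_i$paternal_gt, m_j$paternal_gt)) {
      f <- function(r) pair_log_likelihood(m_i, m_j, c(ph_m, ph_p), r)
      grid <- seq(0, 0.5, by = 0.01)
      ll_grid <- vapply(grid, f, numeric(1))
      k <- which.max(ll_grid)
      lo <- max(0, grid[k] - 0.01); hi <- min(0.5, grid[k] + 0.01)
      opt <- stats::optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-6)
      cand <- if (opt$objective >= ll_grid[k]) {
        list(ll = opt$objective, r = opt$maximum)
      } else list(ll = ll_grid[k], r = grid[k])
      if (cand$ll > best$ll + 1e-12) {
        best <- list(ll = cand$ll, r = cand$r, phase = c(ph_m, ph_p))
      }
    }
  }
  ll_half <- pair_log_likelihood(m_i, m_j, best$phase, 0.5)
  res$rf <- min(max(best$r, 0), 0.5)
  res$phase <- c(mat = best$phase[1], pat = best$phase[2])
  res$lod <- max(0, (best$ll - ll_half) / log(10))
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' All-pairs two-point table
#'
#' Computes rf, LOD, phase and informative-meiosis counts for every marker
#' pair, using the compiled engine (identical model to
#' [estimate_two_point()], vectorised over pairs).
#'
#' @param markers A marker data.frame as returned by [filter_markers()] /
#'   [simulate_population()]: columns `id`, `maternal_gt`, `paternal_gt`.
#' @param geno Progeny genotype matrix (markers x progeny, entries
#'   `"AA"/"AB"/"BB"` or `NA`) aligned with `markers` rows.
#' @return A list of matrices `rf`, `lod`, `n_informative`, `info` (observed
#'   information about rf at the MLE), plus character matrices `phase_mat`,
#'   `phase_pat` and the marker `ids`.
#' @export
two_point_table <- function(markers, geno) {
  stopifnot(nrow(markers) == nrow(geno))
  code <- function(g) {
    out <- match(g, GT_LEVELS) - 1L
    out[is.na(out)] <- -1L
    out
  }
  gm <- matrix(code(geno), nrow = nrow(geno))
  res <- cpp_two_point_all(gm, code(markers$maternal_gt),
                           code(markers$paternal_gt))
  phase_lab <- function(m) {
    out <- matrix("n/a", nrow(m), ncol(m),
                  dimnames = list(as.character(markers$id),
                                  as.character(markers$id)))
    out[m == 0L] <- "coupling"
    out[m == 1L] <- "repulsion"
    out
  }
  ids <- as.character(markers$id)
  dimnames(res$rf) <- dimnames(res$lod) <- dimnames(res$n_informative) <-
    dimnames(res$info) <- list(ids, ids)
  list(rf = res$rf, lod = res$lod, n_informative = res$n_informative,
       info = res$info, phase_mat = phase_lab(res$phase_mat),
       phase_pat = phase_lab(res$phase_pat), ids = ids)
}
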