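# Marker quality control for a CP full-sib family: segregation typing,
# goodness-of-fit filtering, co-segregation deduplication, genic-context
# annotation and summary statistics.

#' Classify marker segregation from the parental genotypes
#'
#' In a full-sib CP family a marker heterozygous in exactly one parent
#' segregates 1:1, one heterozygous in both parents segregates 1:2:1, and
#' identical homozygous parents give a monomorphic (uninformative) marker.
#'
#' @param maternal_gt,paternal_gt Genotype vectors (`"AA"/"AB"/"BB"`,
#'   `NA` = missing).
#' @return Character vector over `maternal_1to1`, `paternal_1to1`,
#'   `both_het_1to2to1`, `monomorphic`, `uninformative`.
#' @export
classify_segregation <- function(maternal_gt, paternal_gt) {
  out <- rep("uninformative", length(maternal_gt))
  known <- !is.na(maternal_gt) & !is.na(paternal_gt)
  m_het <- known & maternal_gt == "AB"
  p_het <- known & paternal_gt == "AB"
  out[m_het & !p_het] <- "maternal_1to1"
  out[!m_het & p_het] <- "paternal_1to1"
  out[m_het & p_het] <- "both_het_1to2to1"
  out[known & !m_het & !p_het & maternal_gt == paternal_gt] <- "monomorphic"
  # both parents homozygous for different alleles: all progeny AB, no
  # segregation to map
  out[known & !m_het & !p_het & maternal_gt != paternal_gt] <- "uninformative"
  out
}

#' Chi-square goodness of fit to a Mendelian segregation ratio
#'
#' Pearson chi-square with k - 1 degrees of freedom against an expected
#' ratio such as 1:1 or 1:2:1.
#'
#' @param observed_counts Non-negative counts, at least one positive.
#' @param ratio Expected ratio, e.g. `c(1, 1)` or `c(1, 2, 1)`.
#' @return List with `stat` and `p`.
#' @export
chi_square_gof <- function(observed_counts, ratio) {
  if (length(observed_counts) != length(ratio))
    stop("observed_counts and ratio lengths differ", call. = FALSE)
  if (any(observed_counts < 0) || sum(observed_counts) == 0)
    stop("counts must be non-negative with a positive total", call. = FALSE)
  ht <- suppressWarnings(
    stats::chisq.test(observed_counts, p = ratio / sum(ratio)))
  list(stat = unname(ht$statistic), p = unname(ht$p.value))
}

# internal: per-marker expected-class counts and chi-square, by seg class
.marker_chisq <- function(seg_class, maternal_gt, paternal_gt, geno_prog) {
  n <- length(seg_class)
  stat <- rep(NA_real_, n); p <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    g <- geno_prog[k, ]
    g <- g[!is.na(g)]
    if (!length(g)) next
    if (seg_class[k] %in% c("maternal_1to1", "paternal_1to1")) {
      hom <- if (seg_class[k] == "maternal_1to1") paternal_gt[k] else
        maternal_gt[k]
      counts <- c(sum(g == hom), sum(g == "AB"))
      if (sum(counts) == 0) next
      res <- chi_square_gof(counts, c(1, 1))
    } else if (seg_class[k] == "both_het_1to2to1") {
      counts <- c(sum(g == "AA"), sum(g == "AB"), sum(g == "BB"))
      res <- chi_square_gof(counts, c(1, 2, 1))
    } else next
    stat[k] <- res$stat; p[k] <- res$p
  }
  list(stat = stat, p = p)
}

#' Build the per-marker QC table
#'
#' Adds segregation class, missing fraction and chi-square goodness of fit
#' (1:1 or 1:2:1 according to class) to the marker table.
#'
#' @param gm A `"genotype_set"` (first two genotype columns are the parents).
#' @return Marker data.frame with `seg_class`, `missing_frac`, `chi2_stat`,
#'   `chi2_p` columns added.
#' @export
marker_qc_table <- function(gm) {
  m <- gm$markers
  prog <- gm$geno[, -(1:2), drop = FALSE]
  m$seg_class <- classify_segregation(m$maternal_gt, m$paternal_gt)
  m$missing_frac <- rowMeans(is.na(prog))
  cs <- .marker_chisq(m$seg_class, m$maternal_gt, m$paternal_gt, prog)
  m$chi2_stat <- cs$stat
  m$chi2_p <- cs$p
  m
}

#' Apply the marker filtering cascade
#'
#' Drops (in order) markers that are monomorphic or otherwise uninformative,
#' markers missing in more than `max_missing` of the progeny, and markers
#' whose segregation is distorted (chi-square p < `distortion_alpha`).
#'
#' @param markers QC table from [marker_qc_table()].
#' @param max_missing Maximum tolerated missing fraction (default 0.10).
#' @param distortion_alpha Chi-square significance level for segregation
#'   distortion (default 0.05).
#' @param abort_if_distorted_frac If not `NULL`, stop when more than this
#'   fraction of otherwise-retained markers is distorted.
#' @return List: `retained` (marker rows kept) and `report`, a
#'   `"filter_report"` with stage counts and per-reason discard lists.
#' @export
filter_markers <- function(markers, max_missing = 0.10,
                           distortion_alpha = 0.05,
                           abort_if_distorted_frac = NULL) {
  report <- list(total = nrow(markers))
  discarded <- list()
  if (nrow(markers) == 0) {
    report[c("polymorphic", "one_parent_het", "both_het", "after_missingness",
             "after_distortion")] <- 0
    report$discarded <- discarded
    class(report) <- "filter_report"
    return(list(retained = markers, report = report))
  }
  informative <- markers$seg_class %in%
    c("maternal_1to1", "paternal_1to1", "both_het_1to2to1")
  discarded$not_segregating <- markers$id[!informative]
  keep <- markers[informative, ]
  report$polymorphic <- nrow(keep)
  report$one_parent_het <- sum(keep$seg_class %in%
                                 c("maternal_1to1", "paternal_1to1"))
  report$both_het <- sum(keep$seg_class == "both_het_1to2to1")

  too_missing <- keep$missing_frac > max_missing
  discarded$missingness <- keep$id[too_missing]
  keep <- keep[!too_missing, ]
  report$after_missingness <- nrow(keep)

  distorted <- !is.na(keep$chi2_p) & keep$chi2_p < distortion_alpha
  discarded$distortion <- keep$id[distorted]
  keep <- keep[!distorted, ]
  report$after_distortion <- nrow(keep)

  if (!is.null(abort_if_distorted_frac) && report$after_missingness > 0) {
    frac <- length(discarded$distortion) / report$after_missingness
    if (frac > abort_if_distorted_frac)
      stop(sprintf("distorted-marker fraction %.3f exceeds %.3f", frac,
                   abort_if_distorted_frac), call. = FALSE)
  }
  report$distorted_fraction <-
    if (report$after_missingness > 0)
      length(discarded$distortion) / report$after_missingness else 0
  report$discarded <- discarded
  class(report) <- "filter_report"
  list(retained = keep, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("marker filter cascade:\n")
  for (f in c("total", "polymorphic", "after_missingness", "after_distortion",
              "after_dedup")) {
    if (!is.null(x[[f]])) cat(sprintf("  %-18s %d\n", f, x[[f]]))
  }
  invisible(x)
}

#' Deduplicate co-segregating markers
#'
#' Markers with effectively identical progeny genotype vectors are grouped
#' and one representative (smallest scaffold id, then smallest position) is
#' kept per group. Two vectors are merged only when they agree at every
#' jointly non-missing progeny and are jointly complete in at least
#' `min_joint_complete` of the progeny, so missingness cannot fabricate
#' identity.
#'
#' @param markers Filtered marker table.
#' @param geno Progeny genotype matrix with rownames = marker ids.
#' @param min_joint_complete Minimum fraction of progeny non-missing in both
#'   markers (default 0.9).
#' @return List: `representatives` (marker rows kept) and `groups`, a list
#'   mapping each representative id to the full co-segregation group.
#' @export
dedup_cosegregating <- function(markers, geno, min_joint_complete = 0.9) {
  ord <- order(markers$scaffold, markers$pos_bp, markers$id)
  markers <- markers[ord, ]
  g <- geno[markers$id, , drop = FALSE]
  n_prog <- ncol(g)
  reps <- integer()          # row indices of representatives
  groups <- list()
  assign_to <- rep(NA_integer_, nrow(markers))
  for (k in seq_len(nrow(markers))) {
    placed <- FALSE
    for (ri in seq_along(reps)) {
      r <- reps[ri]
      both <- !is.na(g[k, ]) & !is.na(g[r, ])
      if (sum(both) >= min_joint_complete * n_prog &&
          all(g[k, both] == g[r, both])) {
        assign_to[k] <- ri
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, k)
      assign_to[k] <- length(reps)
    }
  }
  groups <- split(markers$id, assign_to)
  names(groups) <- markers$id[reps]
  list(representatives = markers[reps, ], groups = groups)
}

#' Annotate a SNP by its genic context
#'
#' Assigns each marker to `CDS`, `UTR`, `intron`, `promoter` or `intergenic`
#' by interval overlap with the gene models, with precedence
#' CDS > UTR > intron > promoter. The promoter is the `promoter_len` bp
#' window upstream of the transcription start (strand-aware); explicit
#' `promoter` features in the model table are used when present.
#'
#' @param markers Marker table with `scaffold` and `pos_bp`.
#' @param gene_models Feature table (see [read_gene_models_gff3()]).
#' @param promoter_len Promoter window in bp, used only when the models carry
#'   no explicit promoter features (default 2000).
#' @return Character vector of categories, one per marker.
#' @export
annotate_snp <- function(markers, gene_models, promoter_len = 2000) {
  mk <- GenomicRanges::GRanges(markers$scaffold,
                               IRanges::IRanges(markers$pos_bp, width = 1))
  unknown <- !(markers$scaffold %in% gene_models$scaffold)
  if (any(unknown))
    warning(sum(unknown), " marker(s) on scaffolds absent from the annotation;",
            " set intergenic")
  feat_gr <- function(types) {
    gg <- gene_models[gene_models$type %in% types, , drop = FALSE]
    GenomicRanges::GRanges(gg$scaffold,
                           IRanges::IRanges(pmax(1L, gg$start), gg$end))
  }
  prom <- if (any(gene_models$type == "promoter")) {
    feat_gr("promoter")
  } else {
    gg <- gene_models[gene_models$type == "gene", , drop = FALSE]
    st <- ifelse(gg$strand == "+", pmax(1L, gg$start - promoter_len),
                 gg$end + 1L)
    en <- ifelse(gg$strand == "+", pmax(1L, gg$start - 1L),
                 gg$end + promoter_len)
    GenomicRanges::GRanges(gg$scaffold, IRanges::IRanges(st, en))
  }
  # seqlevel bookkeeping warnings from range merging are noise here: a
  # marker scaffold absent from the annotation is already reported above
  hits <- function(gr) suppressWarnings(IRanges::overlapsAny(mk, gr))
  out <- rep("intergenic", nrow(markers))
  out[hits(prom)] <- "promoter"
  out[hits(feat_gr("gene"))] <- "intron"  # inside a gene but no exon feature
  out[hits(feat_gr(c("five_prime_UTR", "three_prime_UTR")))] <- "UTR"
  out[hits(feat_gr("CDS"))] <- "CDS"
  out
}

#' Transition / transversion counts and ratio
#'
#' A<->G and C<->T substitutions are transitions; every other nucleotide pair
#' is a transversion.
#'
#' @param markers Marker table with single-nucleotide `ref` and `alt`.
#' @return List: `n_transitions`, `n_transversions`, `ratio` (NA with a flag
#'   `undefined = TRUE` when there are no transversions).
#' @export
ts_tv <- function(markers) {
  ok <- markers$ref %in% c("A", "C", "G", "T") &
    markers$alt %in% c("A", "C", "G", "T")
  if (any(!ok)) warning(sum(!ok), " marker(s) with non-ACGT alleles skipped")
  pair <- paste(pmin(markers$ref[ok], markers$alt[ok]),
                pmax(markers$ref[ok], markers$alt[ok]))
  n_ts <- sum(pair %in% c("A G", "C T"))
  n_tv <- sum(ok) - n_ts
  list(n_transitions = n_ts, n_transversions = n_tv,
       ratio = if (n_tv > 0) n_ts / n_tv else NA_real_,
       undefined = n_tv == 0)
}
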