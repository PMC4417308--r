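#' Simulation configuration for a full-sib mapping study
#'
#' Bundles every tunable of the synthetic-data generator: genome layout
#' (chromosomes, scaffolds, markers), population design (progeny count,
#' segregation-type mix), noise (missingness, genotyping error), and the gene
#' complement (density, immunity-class frequencies, cluster injection).
#'
#' Defaults emulate the study design the package targets: a cassava-like
#' genome of 18 chromosomes split into scaffolds, ~40 markers per chromosome
#' mixing one-parent-heterozygous (1:1) and both-parents-heterozygous (1:2:1)
#' segregation, 132 F1 progeny, 5% missing calls and no genotyping error.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_cM_lengths Map length of each chromosome in centiMorgans;
#'   recycled to `n_chromosomes`. The default is the published cassava
#'   linkage-group length profile (total 2,571 cM over 18 groups, from
#'   36.5 to 208.5 cM).
#' @param scaffolds_per_chrom Scaffolds tiling each chromosome.
#' @param scaffold_bp_lengths Physical length of each scaffold in bp;
#'   recycled across scaffolds.
#' @param markers_per_scaffold SNP markers placed on each scaffold.
#' @param seg_type_mix Named proportions over segregation types
#'   `maternal_1to1`, `paternal_1to1`, `both_het_1to2to1`, `monomorphic`.
#' @param n_progeny Number of F1 individuals.
#' @param missing_rate Per-call probability a progeny genotype is set missing.
#' @param genotyping_error_rate Per-call probability a progeny genotype is
#'   replaced by a different valid genotype.
#' @param gene_density Genes per megabase of scaffold sequence.
#' @param irp_class_freqs Named proportions over immunity-protein classes for
#'   genes that are IRPs (see [classify_irp()] for the classes).
#' @param irp_fraction Fraction of genes (outside injected clusters) that are
#'   immunity-related.
#' @param cluster_spec List with `n_clusters`, `genes_per_cluster`,
#'   `intra_gap_bp`: IRP clusters injected with known membership.
#' @param promoter_len Promoter window emitted upstream of each gene, bp.
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_chromosomes = 18,
                       chrom_cM_lengths = c(199.09, 108.24, 183.51, 142.84,
                                            129.03, 208.47, 132.22, 171.58,
                                            100.64, 36.47, 151.38, 137.08,
                                            148.08, 169.35, 149.15, 147.80,
                                            124.07, 132.17),
                       scaffolds_per_chrom = 8,
                       scaffold_bp_lengths = 1e6,
                       markers_per_scaffold = 5,
                       seg_type_mix = c(maternal_1to1 = 0.30,
                                        paternal_1to1 = 0.35,
                                        both_het_1to2to1 = 0.34,
                                        monomorphic = 0.01),
                       n_progeny = 132,
                       missing_rate = 0.05,
                       genotyping_error_rate = 0,
                       gene_density = 30,
                       irp_class_freqs = c(LRR = 425, `LRR-kinase` = 253,
                                           `NB-ARC-LRR` = 177, WRKY = 105,
                                           `NB-ARC` = 29, `TIR-NB-ARC-LRR` = 28,
                                           LysM = 17, TIR = 14,
                                           `LysM-kinase` = 11, `TIR-LRR` = 2) / 1061,
                       irp_fraction = 0.035,
                       cluster_spec = list(n_clusters = 10,
                                           genes_per_cluster = 3,
                                           intra_gap_bp = 50000),
                       promoter_len = 2000,
                       seed = 1L) {
  check_that(is.numeric(n_chromosomes) && n_chromosomes >= 1,
             "n_chromosomes", "need at least 1 chromosome")
  chrom_cM_lengths <- rep_len(chrom_cM_lengths, n_chromosomes)
  check_that(all(chrom_cM_lengths > 0), "chrom_cM_lengths", "lengths must be > 0")
  check_that(scaffolds_per_chrom >= 1, "scaffolds_per_chrom", "must be >= 1")
  scaffold_bp_lengths <- rep_len(scaffold_bp_lengths,
                                 n_chromosomes * scaffolds_per_chrom)
  check_that(all(scaffold_bp_lengths > 0), "scaffold_bp_lengths", "must be > 0")
  check_that(markers_per_scaffold >= 1, "markers_per_scaffold", "must be >= 1")
  seg_names <- c("maternal_1to1", "paternal_1to1", "both_het_1to2to1",
                 "monomorphic")
  check_that(setequal(names(seg_type_mix), seg_names),
             "seg_type_mix", paste("needs names", paste(seg_names, collapse = ", ")))
  check_props(seg_type_mix[seg_names], "seg_type_mix")
  check_that(n_progeny >= 2, "n_progeny", "need at least 2 progeny")
  check_that(missing_rate >= 0 && missing_rate <= 1, "missing_rate",
             "must lie in [0, 1]")
  check_that(genotyping_error_rate >= 0 && genotyping_error_rate <= 1,
             "genotyping_error_rate", "must lie in [0, 1]")
  check_that(gene_density > 0, "gene_density", "must be > 0")
  check_props(irp_class_freqs, "irp_class_freqs")
  check_that(irp_fraction >= 0 && irp_fraction <= 1, "irp_fraction",
             "must lie in [0, 1]")
  check_that(all(c("n_clusters", "genes_per_cluster", "intra_gap_bp") %in%
                   names(cluster_spec)),
             "cluster_spec", "needs n_clusters, genes_per_cluster, intra_gap_bp")
  check_that(cluster_spec$genes_per_cluster >= 2 || cluster_spec$n_clusters == 0,
             "cluster_spec", "clusters need at least 2 genes")
  check_that(promoter_len >= 0, "promoter_len", "must be >= 0")
  check_that(is.numeric(seed) && length(seed) == 1, "seed", "single integer")

  cfg <- list(n_chromosomes = as.integer(n_chromosomes),
              chrom_cM_lengths = as.numeric(chrom_cM_lengths),
              scaffolds_per_chrom = as.integer(scaffolds_per_chrom),
              scaffold_bp_lengths = as.numeric(scaffold_bp_lengths),
              markers_per_scaffold = as.integer(markers_per_scaffold),
              seg_type_mix = seg_type_mix[seg_names],
              n_progeny = as.integer(n_progeny),
              missing_rate = missing_rate,
              genotyping_error_rate = genotyping_error_rate,
              gene_density = gene_density,
              irp_class_freqs = irp_class_freqs,
              irp_fraction = irp_fraction,
              cluster_spec = cluster_spec,
              promoter_len = as.integer(promoter_len),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim_config: %d chromosomes x %d scaffolds x %d markers; %d progeny\n",
    x$n_chromosomes, x$scaffolds_per_chrom, x$markers_per_scaffold,
    x$n_progeny))
  cat(sprintf("  missing %.1f%%, error %.1f%%, seed %d\n",
              100 * x$missing_rate, 100 * x$genotyping_error_rate, x$seed))
  invisible(x)
}
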