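#!/usr/bin/env Rscript
# Stage 2 -- marker QC from the fixture files: segregation classification,
# chi-square goodness of fit, the filtering cascade (monomorphic /
# missingness / distortion), co-segregation deduplication, genic-context
# annotation and Ts/Tv.

library(cpmap)

fix <- file.path("results", "fixture")
gm <- read_genotypes_vcf(file.path(fix, "genotypes.vcf"))
genes <- read_gene_models_gff3(file.path(fix, "genes.gff3"))

tab <- marker_qc_table(gm)
tab$category <- annotate_snp(tab, genes)
flt <- filter_markers(tab, max_missing = 0.10, distortion_alpha = 0.05)
dd <- dedup_cosegregating(flt$retained, gm$geno[, -(1:2)])
flt$report$after_dedup <- nrow(dd$representatives)

print(flt$report)
cat("seg classes:", paste(names(table(tab$seg_class)), table(tab$seg_class),
                          collapse = ", "), "\n")
tv <- ts_tv(tab)
cat(sprintf("Ts/Tv: %d / %d = %.2f\n", tv$n_transitions, tv$n_transversions,
            tv$ratio))
cat("genic context:", paste(names(table(tab$category)), table(tab$category),
                            collapse = ", "), "\n")

dir.create("results", showWarnings = FALSE)
write_tsv(tab, file.path("results", "markers_qc.tsv"))
write_tsv(dd$representatives, file.path("results", "markers_retained.tsv"))
cat("wrote results/markers_qc.tsv and results/markers_retained.tsv\n")
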