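#!/usr/bin/env Rscript
# Stage 1 -- simulate the study: a cassava-like genome (18 chromosomes tiled
# by scaffolds), SNP markers with CP segregation types, a 132-individual
# full-sib F1 family with 5% missing calls, gene models and an
# immunity-related gene complement with injected physical clusters.
# Everything downstream runs from the files this stage writes.

library(cpmap)

out <- file.path("results", "fixture")
cfg <- sim_config(seed = 1L)
study <- simulate_study(cfg)
write_sim_fixture(study, out)

tm <- study$sim$truth$true_map
cat("simulated", nrow(tm), "markers on", length(unique(tm$chrom)),
    "chromosomes /", nrow(study$sim$scaffolds), "scaffolds\n")
cat("seg types:", paste(names(table(tm$seg_type)),
                        table(tm$seg_type), collapse = ", "), "\n")
cat("genes:", length(unique(study$sim$genes$gene_id)),
    "| IRP genes:", nrow(study$sim$truth$irp_truth),
    "| injected clusters:", length(study$sim$truth$cluster_truth), "\n")
cat("fixture written under", out, "\n")
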