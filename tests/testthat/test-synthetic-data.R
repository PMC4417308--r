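test_that("config validation names the offending field", {
  expect_error(sim_config(missing_rate = 1.5), "missing_rate")
  expect_error(sim_config(chrom_cM_lengths = -10), "chrom_cM_lengths")
  expect_error(sim_config(seg_type_mix = c(maternal_1to1 = 0.5,
                                           paternal_1to1 = 0.5,
                                           both_het_1to2to1 = 0.5,
                                           monomorphic = 0)), "seg_type_mix")
})

test_that("simulated genome satisfies its construction contract", {
  cfg <- sim_config(n_chromosomes = 1, scaffolds_per_chrom = 2,
                    markers_per_scaffold = 5, chrom_cM_lengths = 50,
                    seed = 11)
  sim <- simulate_genome(cfg)
  tm <- sim$truth$true_map
  expect_equal(nrow(tm), 10)
  expect_true(all(table(tm$scaffold) == 5))
  expect_true(all(diff(tm$cM) > 0))          # strictly increasing along chrom
  expect_true(all(tm$scaffold %in% sim$scaffolds$scaffold))
  # every scaffold placed once, with an orientation
  pl <- sim$truth$scaffold_placement
  expect_equal(sort(pl$scaffold), sort(sim$scaffolds$scaffold))
  expect_true(all(pl$orientation %in% c("+", "-")))
})

test_that("injected clusters obey the cluster rule by construction", {
  cfg <- sim_config(n_chromosomes = 1, scaffolds_per_chrom = 2,
                    markers_per_scaffold = 3, chrom_cM_lengths = 50,
                    cluster_spec = list(n_clusters = 1, genes_per_cluster = 3,
                                        intra_gap_bp = 50000),
                    seed = 12)
  sim <- simulate_genome(cfg)
  expect_equal(length(sim$truth$cluster_truth), 1)
  members <- sim$truth$cluster_truth[[1]]
  expect_equal(length(members), 3)
  gg <- sim$genes[sim$genes$type == "gene" & sim$genes$gene_id %in% members, ]
  gg <- gg[order(gg$start), ]
  gaps <- gg$start[-1] - gg$end[-nrow(gg)]
  expect_true(all(gaps <= 200000))
  expect_true(all(members %in% sim$truth$irp_truth$gene_id))
})

test_that("fixture generation is deterministic under a fixed seed", {
  cfg <- sim_config(n_chromosomes = 1, scaffolds_per_chrom = 2,
                    markers_per_scaffold = 4, chrom_cM_lengths = 60,
                    n_progeny = 30, seed = 13)
  d1 <- file.path(tempfile(), "a"); d2 <- file.path(tempfile(), "b")
  write_sim_fixture(simulate_study(cfg), d1)
  write_sim_fixture(simulate_study(cfg), d2)
  for (f in c("genotypes.vcf", "genes.gff3", "domains.domtblout",
              "scaffolds.tsv", file.path("truth", "true_map.tsv"))) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("meiosis respects the map: 0 cM never recombines, 21.18 cM gives r = 0.20", {
  cfg <- sim_config(n_chromosomes = 1, scaffolds_per_chrom = 1,
                    markers_per_scaffold = 2, chrom_cM_lengths = 50,
                    n_progeny = 10000, missing_rate = 0,
                    seg_type_mix = c(maternal_1to1 = 1, paternal_1to1 = 0,
                                     both_het_1to2to1 = 0, monomorphic = 0),
                    seed = 14)
  sim <- simulate_genome(cfg)

  # zero interval: force the two markers to the same cM
  sim0 <- sim
  sim0$truth$true_map$cM <- rep(sim0$truth$true_map$cM[1], 2)
  gm0 <- simulate_population(sim0, cfg)
  p <- list(mk_marker("a", gm0$markers$maternal_gt[1],
                      gm0$markers$paternal_gt[1], gm0$geno[1, -(1:2)]),
            mk_marker("b", gm0$markers$maternal_gt[2],
                      gm0$markers$paternal_gt[2], gm0$geno[2, -(1:2)]))
  expect_equal(estimate_two_point(p[[1]], p[[2]])$rf, 0, tolerance = 1e-6)

  # 21.18 cM interval: Kosambi inverse is r = 0.20
  sim1 <- sim
  sim1$truth$true_map$cM <- c(0, 21.18)
  gm1 <- simulate_population(sim1, cfg)
  p1 <- list(mk_marker("a", gm1$markers$maternal_gt[1],
                       gm1$markers$paternal_gt[1], gm1$geno[1, -(1:2)]),
             mk_marker("b", gm1$markers$maternal_gt[2],
                       gm1$markers$paternal_gt[2], gm1$geno[2, -(1:2)]))
  expect_equal(estimate_two_point(p1[[1]], p1[[2]])$rf, 0.20,
               tolerance = 0.02)
})

test_that("markers on different chromosomes are unlinked (rf ~ 0.5)", {
  cfg <- sim_config(n_chromosomes = 2, scaffolds_per_chrom = 1,
                    markers_per_scaffold = 1, chrom_cM_lengths = 50,
                    n_progeny = 10000, missing_rate = 0,
                    seg_type_mix = c(maternal_1to1 = 1, paternal_1to1 = 0,
                                     both_het_1to2to1 = 0, monomorphic = 0),
                    seed = 15)
  st <- simulate_study(cfg)
  p <- lapply(1:2, function(k) {
    mk_marker(st$gm$markers$id[k], st$gm$markers$maternal_gt[k],
              st$gm$markers$paternal_gt[k], st$gm$geno[k, -(1:2)])
  })
  expect_gt(estimate_two_point(p[[1]], p[[2]])$rf, 0.48)
})

test_that("every adjacent interval's empirical rf matches its Kosambi inverse", {
  cfg <- sim_config(n_chromosomes = 1, scaffolds_per_chrom = 1,
                    markers_per_scaffold = 6, chrom_cM_lengths = 80,
                    n_progeny = 10000, missing_rate = 0,
                    seg_type_mix = c(maternal_1to1 = 1, paternal_1to1 = 0,
                                     both_het_1to2to1 = 0, monomorphic = 0),
                    seed = 16)
  sim <- simulate_genome(cfg)
  gm <- simulate_population(sim, cfg)
  tm <- sim$truth$true_map
  for (k in 1:5) {
    true_r <- kosambi_inv(tm$cM[k + 1] - tm$cM[k])
    est <- estimate_two_point(
      mk_marker("a", gm$markers$maternal_gt[k], gm$markers$paternal_gt[k],
                gm$geno[k, -(1:2)]),
      mk_marker("b", gm$markers$maternal_gt[k + 1],
                gm$markers$paternal_gt[k + 1], gm$geno[k + 1, -(1:2)]))
    expect_lt(abs(est$rf - true_r), 0.02)
  }
})

test_that("a noiseless 1:1 marker segregates 1:1 over 10,000 progeny", {
  cfg <- sim_config(n_chromosomes = 1, scaffolds_per_chrom = 1,
                    markers_per_scaffold = 1, chrom_cM_lengths = 50,
                    n_progeny = 10000, missing_rate = 0,
                    seg_type_mix = c(maternal_1to1 = 1, paternal_1to1 = 0,
                                     both_het_1to2to1 = 0, monomorphic = 0),
                    seed = 17)
  st <- simulate_study(cfg)
  g <- st$gm$geno[1, -(1:2)]
  counts <- c(sum(g != "AB"), sum(g == "AB"))
  expect_gt(chi_square_gof(counts, c(1, 1))$p, 0.001)
})

test_that("apply_noise honours its rates and never touches parents", {
  z <- small_study(101)
  cfg0 <- z$cfg; cfg0$missing_rate <- 0; cfg0$genotyping_error_rate <- 0
  sim <- simulate_genome(cfg0)
  gm <- simulate_population(sim, cfg0)
  expect_identical(apply_noise(gm, cfg0)$geno, gm$geno)

  cfg1 <- cfg0; cfg1$missing_rate <- 0.1
  noised <- apply_noise(gm, cfg1)
  prog <- noised$geno[, -(1:2)]
  expect_gt(mean(is.na(prog)), 0.09 - 0.015)
  expect_lt(mean(is.na(prog)), 0.11 + 0.015)
  expect_false(anyNA(noised$geno[, 1:2]))

  cfg2 <- cfg0; cfg2$genotyping_error_rate <- 1
  err <- apply_noise(gm, cfg2)
  expect_true(all(err$geno[, -(1:2)] != gm$geno[, -(1:2)]))
})
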