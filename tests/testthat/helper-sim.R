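# Shared fixtures, built in code.

# a marker record in the form pair_log_likelihood()/estimate_two_point() take
mk_marker <- function(id, mat, pat, progeny) {
  list(id = id, maternal_gt = mat, paternal_gt = pat, progeny_gts = progeny)
}

# simulate a same-parent 1:1 marker pair at recombination fraction r
# (maternal AB x AA at both loci); fully informative for maternal meioses
sim_pair_1to1 <- function(r, n) {
  u <- stats::rbinom(n, 1, 0.5)
  v <- ifelse(stats::rbinom(n, 1, r) == 1, 1 - u, u)
  list(m1 = mk_marker("m1", "AB", "AA", c("AA", "AB")[u + 1]),
       m2 = mk_marker("m2", "AB", "AA", c("AA", "AB")[v + 1]))
}

# small complete study (genome + noised population), memoised per session
small_study <- local({
  cache <- new.env()
  function(seed = 101, ...) {
    key <- paste0("s", seed, "_", paste(c(...), collapse = "_"))
    if (is.null(cache[[key]])) {
      # density ~3.7 cM/marker, in the regime of the published map
      cfg <- sim_config(n_chromosomes = 2, scaffolds_per_chrom = 4,
                        markers_per_scaffold = 5, chrom_cM_lengths = 70,
                        n_progeny = 132, seed = seed, ...)
      cache[[key]] <- list(cfg = cfg, study = simulate_study(cfg))
    }
    cache[[key]]
  }
})

# two-point table for a genotype set after standard QC
tp_of <- function(study) {
  qc <- marker_qc_table(study$gm)
  flt <- filter_markers(qc)
  dd <- dedup_cosegregating(flt$retained, study$gm$geno[, -(1:2), drop = FALSE])
  keep <- dd$representatives
  list(markers = keep,
       tp = two_point_table(keep, study$gm$geno[keep$id, -(1:2), drop = FALSE]))
}

# hand-built two-point table over a few markers (for grouping/map unit tests)
mk_tp <- function(ids, rf, lod, n_informative = NULL, info = NULL) {
  n <- length(ids)
  dn <- list(ids, ids)
  fill <- function(m, default) {
    if (is.null(m)) m <- matrix(default, n, n)
    dimnames(m) <- dn
    diag(m) <- if (identical(default, 0.5)) 0 else diag(m)
    m
  }
  ph <- matrix("coupling", n, n, dimnames = dn)
  list(rf = fill(rf, 0.5), lod = fill(lod, 0),
       n_informative = fill(n_informative, 132L),
       info = fill(info, 1000),
       phase_mat = ph, phase_pat = ph, ids = ids)
}

# brute-force SARF minimum over all orders of <= 8 markers
brute_force_sarf <- function(ids, rf) {
  n <- length(ids)
  stopifnot(n <= 8)
  perms <- cpmap:::.permutations(n)
  best <- Inf
  for (k in seq_len(nrow(perms))) {
    ord <- ids[perms[k, ]]
    s <- sum(rf[cbind(ord[-n], ord[-1])])
    if (s < best) best <- s
  }
  best
}

# O(n^2) brute-force cluster detector: link every IRP pair satisfying the
# rule directly, then take maximal runs in bp order
brute_force_clusters <- function(genes_tbl, irp_ids, max_gap = 200000,
                                 max_intervening = 8) {
  out <- list()
  for (scf in unique(genes_tbl$scaffold[genes_tbl$gene_id %in% irp_ids])) {
    sg <- genes_tbl[genes_tbl$scaffold == scf, ]
    sg <- sg[order(sg$start), ]
    irp_rows <- which(sg$gene_id %in% irp_ids)
    if (length(irp_rows) < 2) next
    linked <- rep(FALSE, length(irp_rows) - 1)
    for (k in seq_len(length(irp_rows) - 1)) {
      a <- irp_rows[k]; b <- irp_rows[k + 1]
      gap <- sg$start[b] - sg$end[a]
      between <- sum(!(sg$gene_id[seq(a, b)] %in% irp_ids))
      linked[k] <- gap <= max_gap && between < max_intervening
    }
    run <- sg$gene_id[irp_rows[1]]
    for (k in seq_along(linked)) {
      if (linked[k]) {
        run <- c(run, sg$gene_id[irp_rows[k + 1]])
      } else {
        if (length(run) >= 2) out[[length(out) + 1]] <- run
        run <- sg$gene_id[irp_rows[k + 1]]
      }
    }
    if (length(run) >= 2) out[[length(out) + 1]] <- run
  }
  out
}

# random gene layout for cluster-oracle tests
random_gene_layout <- function(seed, n_genes = 40, irp_frac = 0.4) {
  set.seed(seed)
  n_scaf <- sample(1:3, 1)
  rows <- list()
  gid <- 0
  for (s in seq_len(n_scaf)) {
    pos <- 1
    for (g in seq_len(n_genes %/% n_scaf)) {
      gid <- gid + 1
      len <- sample(500:4000, 1)
      rows[[gid]] <- data.frame(
        gene_id = sprintf("g%03d", gid), type = "gene",
        scaffold = paste0("s", s), start = pos, end = pos + len,
        strand = "+", stringsAsFactors = FALSE)
      pos <- pos + len + sample(c(1000:80000, 150000:400000), 1,
                                prob = c(rep(1, 79001), rep(0.0004, 250001)))
    }
  }
  tbl <- do.call(rbind, rows)
  irp <- sample(tbl$gene_id, round(irp_frac * nrow(tbl)))
  list(genes = tbl, irp = irp)
}
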