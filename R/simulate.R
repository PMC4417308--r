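# Synthetic full-sib mapping study with fully known ground truth.
#
# The generator lays out chromosomes tiled by scaffolds, places SNP markers
# with CP segregation types on them, assigns parental phases, and emits gene
# models with an immunity-related subset placed both singly and in injected
# clusters.  Everything downstream (QC, mapping, anchoring, IRP cataloguing)
# can then be scored against the recorded truth.

IRP_CLASS_DOMAINS <- list(
  "LRR"            = "LRR",
  "LRR-kinase"     = c("LRR", "kinase"),
  "LysM"           = "LysM",
  "LysM-kinase"    = c("LysM", "kinase"),
  "NB-ARC"         = "NB-ARC",
  "NB-ARC-LRR"     = c("NB-ARC", "LRR"),
  "TIR"            = "TIR",
  "TIR-LRR"        = c("TIR", "LRR"),
  "TIR-NB-ARC-LRR" = c("TIR", "NB-ARC", "LRR"),
  "WRKY"           = "WRKY")

DOMAIN_PFAM <- c("LRR" = "PF00560", "kinase" = "PF00069", "LysM" = "PF01476",
                 "NB-ARC" = "PF00931", "TIR" = "PF01582", "WRKY" = "PF03106")

# transitions get weight such that Ts/Tv over many markers is ~1.06
.TS_PROB <- 1.06 / 2.06

#' Simulate a genome, gene complement and marker truth
#'
#' Builds the ground truth of a synthetic mapping study: scaffolds tiling
#' chromosomes, SNP markers with segregation types and parental phases, a
#' true genetic map, gene models with CDS/intron/UTR structure and an
#' explicit promoter window, and an immunity-related gene subset with domain
#' hits and injected physical clusters.
#'
#' @param config A [sim_config()].
#' @return A list of class `"sim_genome"` with elements `scaffolds` (scaffold,
#'   length_bp), `genes` (feature table: gene_id, type, scaffold, start, end,
#'   strand), `domains` (per-protein domain-hit table), and `truth` (true map,
#'   parental phases, adjacent-interval rf, scaffold placement, IRP classes,
#'   cluster membership).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)

  n_scaf <- config$n_chromosomes * config$scaffolds_per_chrom
  scaffolds <- data.frame(
    scaffold = sprintf("scf%05d", seq_len(n_scaf)),
    length_bp = config$scaffold_bp_lengths,
    stringsAsFactors = FALSE)

  ## --- scaffold placement and true marker map ------------------------------
  placement <- NULL
  markers <- NULL
  for (c_i in seq_len(config$n_chromosomes)) {
    chrom <- sprintf("chr%02d", c_i)
    L <- config$chrom_cM_lengths[c_i]
    span <- L / config$scaffolds_per_chrom
    for (s_i in seq_len(config$scaffolds_per_chrom)) {
      idx <- (c_i - 1) * config$scaffolds_per_chrom + s_i
      scf <- scaffolds$scaffold[idx]
      len <- scaffolds$length_bp[idx]
      ori <- sample(c("+", "-"), 1)
      start_cM <- (s_i - 1) * span
      placement <- rbind(placement, data.frame(
        scaffold = scf, chrom = chrom, start_cM = start_cM,
        end_cM = start_cM + span, orientation = ori,
        stringsAsFactors = FALSE))
      pos <- sort(sample.int(len, config$markers_per_scaffold))
      frac <- pos / len
      if (ori == "-") frac <- 1 - frac
      markers <- rbind(markers, data.frame(
        scaffold = scf, pos_bp = pos, chrom = chrom,
        cM = start_cM + frac * span, stringsAsFactors = FALSE))
    }
  }
  markers <- markers[order(markers$chrom, markers$cM), ]
  markers$id <- sprintf("S%s_%d", sub("scf", "", markers$scaffold),
                        markers$pos_bp)
  rownames(markers) <- NULL

  ## --- alleles, segregation types, parental phases -------------------------
  nm <- nrow(markers)
  markers$ref <- sample(c("A", "C", "G", "T"), nm, replace = TRUE)
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  is_ts <- stats::runif(nm) < .TS_PROB
  markers$alt <- ifelse(is_ts, transition[markers$ref], NA)
  for (k in which(!is_ts)) {
    markers$alt[k] <- sample(setdiff(c("A", "C", "G", "T"),
                                     c(markers$ref[k],
                                       transition[markers$ref[k]])), 1)
  }
  markers$seg_type <- sample(names(config$seg_type_mix), nm, replace = TRUE,
                             prob = config$seg_type_mix)

  hom_other <- function(n) sample(c("AA", "BB"), n, replace = TRUE)
  markers$maternal_gt <- markers$paternal_gt <- "AA"
  i <- markers$seg_type == "maternal_1to1"
  markers$maternal_gt[i] <- "AB"; markers$paternal_gt[i] <- hom_other(sum(i))
  i <- markers$seg_type == "paternal_1to1"
  markers$paternal_gt[i] <- "AB"; markers$maternal_gt[i] <- hom_other(sum(i))
  i <- markers$seg_type == "both_het_1to2to1"
  markers$maternal_gt[i] <- markers$paternal_gt[i] <- "AB"
  # monomorphic: both parents homozygous for the same allele (AA) -- filters
  # must discard these.

  # Phase: per parent, per marker, the alt-allele count on haplotype 1/2.
  # For a heterozygous parent, which haplotype carries the alt allele is
  # random; a homozygous parent has identical haplotypes.
  phase_for <- function(gt) {
    h <- matrix(0L, nm, 2)
    h[gt == "BB", ] <- 1L
    het <- which(gt == "AB")
    which_hap <- sample(1:2, length(het), replace = TRUE)
    h[cbind(het, which_hap)] <- 1L
    h
  }
  phases <- list(maternal = phase_for(markers$maternal_gt),
                 paternal = phase_for(markers$paternal_gt))

  true_rf <- do.call(rbind, lapply(split(markers, markers$chrom), function(mm) {
    if (nrow(mm) < 2) return(NULL)
    data.frame(marker_a = mm$id[-nrow(mm)], marker_b = mm$id[-1],
               chrom = mm$chrom[1], interval_cM = diff(mm$cM),
               rf = kosambi_inv(diff(mm$cM)), stringsAsFactors = FALSE)
  }))
  rownames(true_rf) <- NULL

  ## --- gene models ----------------------------------------------------------
  gene_rows <- list()
  irp_truth <- NULL
  cluster_truth <- list()
  gene_n <- 0L
  cluster_scafs <- if (config$cluster_spec$n_clusters > 0) {
    scaffolds$scaffold[sample.int(n_scaf,
                                  min(config$cluster_spec$n_clusters, n_scaf))]
  } else character()

  irp_classes <- names(config$irp_class_freqs)
  draw_class <- function(n) sample(irp_classes, n, replace = TRUE,
                                   prob = config$irp_class_freqs)

  emit_gene <- function(scf, start, strand, irp_class) {
    gene_n <<- gene_n + 1L
    gid <- sprintf("gene%05d", gene_n)
    n_cds <- sample(1:3, 1)
    cds_len <- sample(300:800, n_cds, replace = TRUE)
    intron_len <- if (n_cds > 1) sample(100:400, n_cds - 1, replace = TRUE) else integer()
    utr5 <- sample(100:300, 1); utr3 <- sample(100:300, 1)
    body <- rbind(cds_len, c(intron_len, NA_integer_))
    keep <- !is.na(body)
    segs <- c(utr5, body[keep], utr3)
    types <- c("five_prime_UTR",
               rep(c("CDS", "intron"), n_cds)[seq_len(2 * n_cds - 1)],
               "three_prime_UTR")
    if (strand == "-") { segs <- rev(segs); types <- rev(types) }
    ends <- start - 1 + cumsum(segs)
    starts <- c(start, head(ends, -1) + 1)
    gend <- ends[length(ends)]
    prom <- if (strand == "+") {
      c(max(1, start - config$promoter_len), max(1, start - 1))
    } else c(gend + 1, gend + config$promoter_len)
    rows <- data.frame(
      gene_id = gid,
      type = c("gene", types, "promoter"),
      scaffold = scf,
      start = c(start, starts, prom[1]),
      end = c(gend, ends, prom[2]),
      strand = strand, stringsAsFactors = FALSE)
    gene_rows[[length(gene_rows) + 1L]] <<- rows
    if (!is.na(irp_class)) {
      irp_truth <<- rbind(irp_truth, data.frame(
        gene_id = gid, irp_class = irp_class, stringsAsFactors = FALSE))
    }
    list(gene_id = gid, end = gend)
  }

  for (s in seq_len(n_scaf)) {
    scf <- scaffolds$scaffold[s]
    len <- scaffolds$length_bp[s]
    n_genes <- max(1L, round(config$gene_density * len / 1e6))
    is_cluster_scaf <- scf %in% cluster_scafs
    slot <- len / n_genes
    cluster_at <- if (is_cluster_scaf) sample.int(max(1L, n_genes %/% 2), 1) else -1L
    members <- character()
    g <- 1L
    while (g <= n_genes) {
      if (g == cluster_at) {
        # injected cluster: genes_per_cluster IRP genes with fixed small gaps;
        # the rest of this scaffold stays non-IRP so the injected member set
        # is exactly the maximal run.
        pos <- round((g - 1) * slot + slot / 4) + 1
        for (k in seq_len(config$cluster_spec$genes_per_cluster)) {
          res <- emit_gene(scf, pos, sample(c("+", "-"), 1), draw_class(1))
          members <- c(members, res$gene_id)
          pos <- res$end + config$cluster_spec$intra_gap_bp + 1
        }
        cluster_truth[[length(cluster_truth) + 1L]] <- members
        g <- g + 1L
        next
      }
      start <- round((g - 1) * slot + stats::runif(1, 0.05, 0.4) * slot) + 1
      cls <- if (!is_cluster_scaf && stats::runif(1) < config$irp_fraction)
        draw_class(1) else NA_character_
      emit_gene(scf, start, sample(c("+", "-"), 1), cls)
      g <- g + 1L
    }
  }
  genes <- do.call(rbind, gene_rows)
  # cluster injection can place genes past the next slot's start; keep the
  # table positionally sorted (per gene block) for downstream consumers
  gene_start <- stats::ave(genes$start, genes$gene_id, FUN = min)
  genes <- genes[order(genes$scaffold, gene_start, genes$gene_id,
                       genes$start), ]
  rownames(genes) <- NULL

  ## --- domain hits ----------------------------------------------------------
  domains <- .simulate_domain_hits(genes, irp_truth)

  truth <- list(true_map = markers[, c("id", "chrom", "cM", "scaffold",
                                       "pos_bp", "seg_type")],
                parental_phases = phases,
                true_rf = true_rf,
                scaffold_placement = placement,
                irp_truth = irp_truth,
                cluster_truth = cluster_truth)
  out <- list(scaffolds = scaffolds,
              genes = genes,
              domains = domains,
              markers = markers,
              truth = truth,
              config = config)
  class(out) <- "sim_genome"
  out
}

# internal: HMMER-style per-protein hit table; true hits at tiny e-values,
# plus decoys above the cutoff and hits with unmapped accessions
.simulate_domain_hits <- function(genes, irp_truth) {
  gene_ids <- unique(genes$gene_id)
  rows <- list()
  add_hit <- function(gene_id, domain, accession, evalue) {
    rows[[length(rows) + 1L]] <<- data.frame(
      target_name = domain, accession = accession,
      query_name = paste0(gene_id, ".1"), evalue = evalue,
      score = round(stats::runif(1, 20, 300), 1), stringsAsFactors = FALSE)
  }
  for (k in seq_len(NROW(irp_truth))) {
    for (dom in IRP_CLASS_DOMAINS[[irp_truth$irp_class[k]]]) {
      add_hit(irp_truth$gene_id[k], dom, DOMAIN_PFAM[[dom]],
              10^stats::runif(1, -60, -5))
    }
  }
  non_irp <- setdiff(gene_ids, irp_truth$gene_id)
  decoys <- sample(non_irp, max(0L, round(0.05 * length(non_irp))))
  for (g in decoys) {
    add_hit(g, "LRR", DOMAIN_PFAM[["LRR"]], 10^stats::runif(1, 1.01, 3))
  }
  others <- sample(setdiff(non_irp, decoys),
                   max(0L, round(0.05 * length(non_irp))))
  for (g in others) add_hit(g, "p450", "PF00067", 10^stats::runif(1, -30, -5))
  out <- do.call(rbind, rows)
  out[order(out$query_name), , drop = FALSE]
}

#' Simulate F1 progeny genotypes by meiosis along the true map
#'
#' Gametes are generated marker-to-marker as a Markov chain: the transmitted
#' parental haplotype switches between adjacent markers with probability equal
#' to the Kosambi inverse of the interval length in cM (no crossover
#' interference). Each progeny genotype is the union of one maternal and one
#' paternal gamete. Parents appear as the first two columns.
#'
#' @param sim A `"sim_genome"` from [simulate_genome()] (or a list with
#'   `markers` and `truth`).
#' @param config The same [sim_config()] used to build `sim`.
#' @return A list of class `"genotype_set"`: `markers` (id, scaffold, pos_bp,
#'   ref, alt, maternal_gt, paternal_gt) and `geno`, a markers x individuals
#'   character matrix (`"AA"/"AB"/"BB"`) whose first two columns are the
#'   parents `P1` (maternal) and `P2` (paternal).
#' @export
simulate_population <- function(sim, config) {
  stopifnot(inherits(config, "sim_config"))
  markers <- sim$markers
  truth <- sim$truth
  if (!all(markers$id %in% truth$true_map$id))
    stop("marker not present in truth map", call. = FALSE)
  set.seed(config$seed + 1L)

  n <- config$n_progeny
  gamete <- function(phase_hap, mm_idx, rf) {
    m <- length(mm_idx)
    h0 <- sample(0:1, n, replace = TRUE)
    if (m == 1) {
      hap <- matrix(h0, 1, n)
    } else {
      # switch indicators fill column-major, so the interval-wise rf vector
      # recycles correctly down each gamete
      sw <- matrix(stats::rbinom((m - 1) * n, 1, rf), m - 1, n)
      cum <- matrix(apply(sw, 2, cumsum), m - 1, n)
      hap <- rbind(h0, sweep(cum, 2, h0, `+`)) %% 2
    }
    # allele transmitted = allele on the chosen haplotype at each marker
    a1 <- phase_hap[mm_idx, 1]; a2 <- phase_hap[mm_idx, 2]
    matrix(ifelse(hap == 0, a1[row(hap)], a2[row(hap)]), nrow = m)
  }

  geno <- matrix(NA_character_, nrow(markers), n + 2)
  chroms <- split(seq_len(nrow(markers)), markers$chrom)
  for (mm_idx in chroms) {
    cm <- truth$true_map$cM[match(markers$id[mm_idx], truth$true_map$id)]
    rf <- if (length(mm_idx) > 1) kosambi_inv(diff(cm)) else numeric()
    mat_a <- gamete(truth$parental_phases$maternal, mm_idx, rf)
    pat_a <- gamete(truth$parental_phases$paternal, mm_idx, rf)
    geno[mm_idx, -(1:2)] <- GT_LEVELS[mat_a + pat_a + 1L]
  }
  geno[, 1] <- markers$maternal_gt
  geno[, 2] <- markers$paternal_gt
  colnames(geno) <- c("P1", "P2", sprintf("F1_%03d", seq_len(n)))
  rownames(geno) <- markers$id

  out <- list(markers = markers[, c("id", "scaffold", "pos_bp", "ref", "alt",
                                    "maternal_gt", "paternal_gt")],
              geno = geno)
  class(out) <- "genotype_set"
  out
}

#' Add genotyping noise to a simulated population
#'
#' Progeny calls are replaced by a different valid genotype with probability
#' `genotyping_error_rate` and then set missing with probability
#' `missing_rate`. Parent columns are never altered.
#'
#' @param gm A `"genotype_set"`.
#' @param config A [sim_config()] providing the two rates and the seed.
#' @return The `"genotype_set"` with noise applied.
#' @export
apply_noise <- function(gm, config) {
  stopifnot(inherits(gm, "genotype_set"), inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  prog <- gm$geno[, -(1:2), drop = FALSE]
  if (config$genotyping_error_rate > 0) {
    err <- which(stats::runif(length(prog)) < config$genotyping_error_rate)
    for (k in err) {
      prog[k] <- sample(setdiff(GT_LEVELS, prog[k]), 1)
    }
  }
  if (config$missing_rate > 0) {
    prog[stats::runif(length(prog)) < config$missing_rate] <- NA_character_
  }
  gm$geno[, -(1:2)] <- prog
  gm
}

#' One-call synthetic fixture
#'
#' Convenience wrapper: [simulate_genome()], [simulate_population()] and
#' [apply_noise()] under one config.
#'
#' @param config A [sim_config()].
#' @return List with `sim` (genome/truth) and `gm` (noised genotype set).
#' @export
simulate_study <- function(config = sim_config()) {
  sim <- simulate_genome(config)
  gm <- apply_noise(simulate_population(sim, config), config)
  list(sim = sim, gm = gm)
}
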