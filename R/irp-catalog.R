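# Immunity-related-protein repertoire: domain-hit parsing, architecture
# classification, physical and genetic placement, and cluster detection.

# Pfam accessions recognised for the six diagnostic domains. Several Pfam
# families describe LRR repeats; all are collapsed to the single LRR label.
DOMAIN_ACCESSIONS <- c(
  PF00560 = "LRR", PF07723 = "LRR", PF07725 = "LRR", PF12799 = "LRR",
  PF13306 = "LRR", PF13855 = "LRR", PF08263 = "LRR",
  PF00069 = "kinase", PF07714 = "kinase",
  PF01476 = "LysM",
  PF00931 = "NB-ARC",
  PF01582 = "TIR",
  PF03106 = "WRKY")

IRP_CLASSES <- c("LRR", "LRR-kinase", "LysM", "LysM-kinase", "NB-ARC",
                 "NB-ARC-LRR", "TIR", "TIR-LRR", "TIR-NB-ARC-LRR", "WRKY")

#' Parse a HMMER3 domain table
#'
#' Reads the whitespace-separated `--domtblout` layout (comment lines start
#' with `#`): target name, target accession, query name and the
#' full-sequence e-value are taken from columns 1, 2, 4 and 7. Hits with
#' e-value above `evalue_max` are dropped (the boundary is inclusive);
#' accessions not recognised as one of the diagnostic domains are ignored
#' with a warning.
#'
#' @param path Domain-table file.
#' @param evalue_max E-value cutoff, inclusive (default 10).
#' @return data.frame: `protein_id`, `domain`, `accession`, `evalue`.
#' @export
parse_domain_table <- function(path, evalue_max = 10) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  rows <- list()
  bad <- integer()
  for (k in seq_along(lines)) {
    f <- strsplit(trimws(lines[k]), "\\s+")[[1]]
    ev <- if (length(f) >= 7) suppressWarnings(as.numeric(f[7])) else NA
    if (length(f) < 7 || is.na(ev)) {
      bad <- c(bad, k)
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      protein_id = f[4], domain_raw = f[1], accession = f[2], evalue = ev,
      stringsAsFactors = FALSE)
  }
  if (length(bad))
    warning("skipped ", length(bad), " malformed line(s): ",
            paste(utils::head(bad, 5), collapse = ", "))
  hits <- do.call(rbind, rows)
  if (is.null(hits)) {
    return(data.frame(protein_id = character(), domain = character(),
                      accession = character(), evalue = numeric()))
  }
  hits <- hits[hits$evalue <= evalue_max, , drop = FALSE]
  acc <- sub("\\.\\d+$", "", hits$accession)
  hits$domain <- unname(DOMAIN_ACCESSIONS[acc])
  unknown <- is.na(hits$domain)
  if (any(unknown))
    warning(sum(unknown), " hit(s) with unrecognised domain accession ignored")
  hits <- hits[!unknown, c("protein_id", "domain", "accession", "evalue")]
  rownames(hits) <- NULL
  hits
}

#' Classify an immunity-related protein from its domain set
#'
#' Exact architecture mapping on domain presence/absence:
#' \{LRR\} = LRR (receptor-like protein); \{LRR, kinase\} = LRR-kinase
#' (receptor-like kinase); \{LysM\}; \{LysM, kinase\}; \{NB-ARC\};
#' \{NB-ARC, LRR\}; \{TIR\}; \{TIR, LRR\}; \{TIR, NB-ARC, LRR\}; \{WRKY\}
#' (only without any other domain). Any other non-empty combination is
#' `other`; an empty set is `not-IRP`.
#'
#' @param domain_set Character vector of domain labels (or a list of such
#'   vectors for vectorised use).
#' @return Class label(s).
#' @export
classify_irp <- function(domain_set) {
  if (is.list(domain_set))
    return(vapply(domain_set, classify_irp, character(1)))
  # radix sort = C collation, so the key is locale-independent
  key <- paste(sort(unique(domain_set), method = "radix"), collapse = "+")
  if (key == "") return("not-IRP")
  switch(key,
         "LRR" = "LRR",
         "LRR+kinase" = "LRR-kinase",
         "LysM" = "LysM",
         "LysM+kinase" = "LysM-kinase",
         "NB-ARC" = "NB-ARC",
         "LRR+NB-ARC" = "NB-ARC-LRR",
         "TIR" = "TIR",
         "LRR+TIR" = "TIR-LRR",
         "LRR+NB-ARC+TIR" = "TIR-NB-ARC-LRR",
         "WRKY" = "WRKY",
         "other")
}

#' Build the IRP catalog
#'
#' Joins per-protein domain hits to gene models, classifies every protein
#' with at least one diagnostic domain, and summarises the repertoire.
#'
#' @param hits Parsed hits from [parse_domain_table()].
#' @param gene_models Feature table (see [read_gene_models_gff3()]); the
#'   `gene` rows provide coordinates. Protein ids are matched to gene ids
#'   after stripping a trailing `.N` isoform suffix.
#' @return List of class `"irp_catalog"`: `genes` data.frame (`gene_id`,
#'   `protein_id`, `domains`, `irp_class`, `scaffold`, `start_bp`, `end_bp`,
#'   `lg`, `cM`), `class_counts`, `scaffold_counts`, `n_singleton`,
#'   `n_multi`.
#' @export
build_catalog <- function(hits, gene_models) {
  dom_sets <- split(hits$domain, hits$protein_id)
  cls <- classify_irp(lapply(dom_sets, identity))
  keep <- !(cls %in% c("not-IRP"))
  prot <- names(dom_sets)[keep]
  cls <- cls[keep]
  gene_id <- sub("\\.\\d+$", "", prot)
  gg <- gene_models[gene_models$type == "gene", , drop = FALSE]
  mi <- match(gene_id, gg$gene_id)
  if (anyNA(mi))
    warning(sum(is.na(mi)), " classified protein(s) without a gene model;",
            " catalogued unplaced")
  genes <- data.frame(
    gene_id = gene_id,
    protein_id = prot,
    domains = vapply(dom_sets[keep],
                     function(d) paste(sort(unique(d), method = "radix"),
                                       collapse = "+"),
                     character(1)),
    irp_class = cls,
    scaffold = gg$scaffold[mi],
    start_bp = gg$start[mi],
    end_bp = gg$end[mi],
    lg = NA_character_,
    cM = NA_real_,
    stringsAsFactors = FALSE)
  genes <- genes[order(genes$scaffold, genes$start_bp, genes$gene_id), ]
  rownames(genes) <- NULL
  scaffold_counts <- table(genes$scaffold)
  multi_scafs <- names(scaffold_counts)[scaffold_counts >= 2]
  out <- list(genes = genes,
              class_counts = table(factor(genes$irp_class,
                                          c(IRP_CLASSES, "other"))),
              scaffold_counts = scaffold_counts,
              n_singleton = sum(genes$scaffold %in%
                                  names(scaffold_counts)[scaffold_counts == 1]),
              n_multi = sum(genes$scaffold %in% multi_scafs))
  class(out) <- "irp_catalog"
  out
}

#' Place catalogued IRP genes on the genetic map
#'
#' Genes on anchored scaffolds receive a linkage group and an interpolated
#' cM position (at the gene midpoint) via [place_external_locus()]; genes on
#' unanchored scaffolds remain unplaced.
#'
#' @param catalog An `"irp_catalog"`.
#' @param anchors A `"scaffold_anchors"` table.
#' @param map The `"genetic_map"` behind `anchors`.
#' @return The catalog with `lg`/`cM` filled, plus `per_lg_counts` and
#'   `mean_per_lg`.
#' @export
map_irps <- function(catalog, anchors, map) {
  g <- catalog$genes
  for (k in seq_len(nrow(g))) {
    if (is.na(g$scaffold[k])) next
    mid <- floor((g$start_bp[k] + g$end_bp[k]) / 2)
    pl <- suppressWarnings(
      place_external_locus(g$scaffold[k], mid, anchors, map))
    if (pl$placed) {
      g$lg[k] <- pl$lg
      g$cM[k] <- pl$cM
    }
  }
  catalog$genes <- g
  mapped <- g[!is.na(g$lg), ]
  catalog$per_lg_counts <- table(mapped$lg)
  catalog$mean_per_lg <- if (length(catalog$per_lg_counts))
    mean(catalog$per_lg_counts) else NA_real_
  catalog$n_mapped <- nrow(mapped)
  catalog
}

#' Detect physical clusters of IRP genes
#'
#' Scans the IRP genes of each scaffold in bp order and links two
#' consecutive IRPs when the gap between their nearest boundaries (end of
#' the upstream gene to start of the downstream gene) is at most `max_gap`
#' bp AND the number of non-IRP genes strictly between them is less than
#' `max_intervening`. Clusters are maximal linked runs of two or more IRPs;
#' clusters never span scaffolds.
#'
#' @param catalog An `"irp_catalog"`.
#' @param gene_models Full feature table (all genes, IRP or not), used to
#'   count intervening genes.
#' @param max_gap Maximum boundary-to-boundary gap in bp (default 200000).
#' @param max_intervening Exclusive bound on intervening non-IRP genes
#'   (default 8: fewer than eight are allowed).
#' @return data.frame of clusters: `cluster_id`, `scaffold`, `lg`,
#'   `n_members`, `members` (comma-joined gene ids), `span_bp`.
#' @export
detect_clusters <- function(catalog, gene_models, max_gap = 200000,
                            max_intervening = 8) {
  irp <- catalog$genes
  gg <- gene_models[gene_models$type == "gene", , drop = FALSE]
  ord <- order(gg$scaffold, gg$start, gg$gene_id)
  if (!identical(ord, seq_len(nrow(gg)))) {
    warning("gene models not sorted; sorting internally")
    gg <- gg[ord, ]
  }
  gg$is_irp <- gg$gene_id %in% irp$gene_id
  clusters <- list()
  for (scf in unique(gg$scaffold[gg$is_irp])) {
    sg <- gg[gg$scaffold == scf, , drop = FALSE]
    irp_idx <- which(sg$is_irp)
    if (length(irp_idx) < 2) next
    run <- sg$gene_id[irp_idx[1]]
    run_start <- sg$start[irp_idx[1]]
    run_end <- sg$end[irp_idx[1]]
    flush <- function(run, run_start, run_end) {
      if (length(run) >= 2) {
        lg <- irp$lg[match(run[1], irp$gene_id)]
        clusters[[length(clusters) + 1L]] <<- data.frame(
          scaffold = scf, lg = if (is.na(lg)) NA_character_ else lg,
          n_members = length(run),
          members = paste(run, collapse = ","),
          span_bp = run_end - run_start + 1, stringsAsFactors = FALSE)
      }
    }
    for (j in seq_len(length(irp_idx) - 1)) {
      a <- irp_idx[j]; b <- irp_idx[j + 1]
      gap <- sg$start[b] - sg$end[a]
      n_between <- sum(!sg$is_irp[seq(a, b)])  # genes strictly between a, b
      if (gap <= max_gap && n_between < max_intervening) {
        run <- c(run, sg$gene_id[b])
        run_end <- max(run_end, sg$end[b])
      } else {
        flush(run, run_start, run_end)
        run <- sg$gene_id[b]
        run_start <- sg$start[b]
        run_end <- sg$end[b]
      }
    }
    flush(run, run_start, run_end)
  }
  if (!length(clusters)) {
    return(data.frame(cluster_id = integer(), scaffold = character(),
                      lg = character(), n_members = integer(),
                      members = character(), span_bp = numeric()))
  }
  out <- do.call(rbind, clusters)
  out <- cbind(cluster_id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}
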