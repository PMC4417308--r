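# File formats: VCF 4.2 subset (GT only) for genotypes, GFF3 for gene
# models, HMMER3 domain-table dialect for domain hits, TSV for scaffold
# lengths and truth tables.

.gt_to_vcf <- c(AA = "0/0", AB = "0/1", BB = "1/1")

#' Write a genotype set as a minimal VCF 4.2 file
#'
#' Emits CHROM/POS/ID/REF/ALT and GT-only sample columns; the first two
#' samples are the parents.
#'
#' @param gm A `"genotype_set"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(gm, path) {
  m <- gm$markers
  gt <- matrix(.gt_to_vcf[gm$geno], nrow = nrow(gm$geno))
  gt[is.na(gt)] <- "./."
  header <- c("##fileformat=VCFv4.2",
              "##source=cpmap-simulator",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", colnames(gm$geno)), collapse = "\t"))
  body <- paste(m$scaffold, m$pos_bp, m$id, m$ref, m$alt, ".", "PASS", ".",
                "GT", apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a genotype set from VCF
#'
#' Accepts any VCF 4.x with biallelic SNPs and a GT field. The first two
#' sample columns are taken as the maternal and paternal parents. Phased
#' separators are collapsed to unphased; genotypes are normalised to
#' AA/AB/BB on the ref/alt axis.
#'
#' @param path VCF file.
#' @return A `"genotype_set"`.
#' @export
read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix[, 1:5, drop = FALSE], stringsAsFactors = FALSE)
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt_raw))) {
    gt_raw <- matrix(gt_raw, nrow = 1,
                     dimnames = list(NULL, names(gt_raw)))
  }
  gt_raw[] <- gsub("|", "/", gt_raw, fixed = TRUE)
  code <- matrix(NA_character_, nrow(gt_raw), ncol(gt_raw),
                 dimnames = dimnames(gt_raw))
  code[gt_raw %in% c("0/0")] <- "AA"
  code[gt_raw %in% c("0/1", "1/0")] <- "AB"
  code[gt_raw %in% c("1/1")] <- "BB"
  if (ncol(code) < 3) stop("VCF must contain 2 parents plus progeny",
                           call. = FALSE)
  markers <- data.frame(id = fix$ID, scaffold = fix$CHROM,
                        pos_bp = as.integer(fix$POS),
                        ref = fix$REF, alt = fix$ALT,
                        maternal_gt = code[, 1], paternal_gt = code[, 2],
                        stringsAsFactors = FALSE)
  no_id <- is.na(markers$id) | markers$id == "."
  markers$id[no_id] <- paste0(markers$scaffold[no_id], "_",
                              markers$pos_bp[no_id])
  rownames(code) <- markers$id
  out <- list(markers = markers, geno = code)
  class(out) <- "genotype_set"
  out
}

#' Write / read gene models as GFF3
#'
#' The feature table uses one row per feature (`gene`, `CDS`, `intron`,
#' `five_prime_UTR`, `three_prime_UTR`, `promoter`) with a shared `gene_id`.
#'
#' @param genes Feature table (`gene_id`, `type`, `scaffold`, `start`, `end`,
#'   `strand`).
#' @param path GFF3 path.
#' @return `write_gene_models_gff3()`: `path` invisibly;
#'   `read_gene_models_gff3()`: the feature table.
#' @export
write_gene_models_gff3 <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$scaffold,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand)
  S4Vectors::mcols(gr)$type <- genes$type
  S4Vectors::mcols(gr)$phase <- ifelse(genes$type == "CDS", 0L, NA_integer_)
  S4Vectors::mcols(gr)$ID <- ifelse(genes$type == "gene", genes$gene_id,
                                    paste0(genes$gene_id, ":", genes$type,
                                           ":", genes$start))
  S4Vectors::mcols(gr)$Parent <- ifelse(genes$type == "gene", NA_character_,
                                        genes$gene_id)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_gene_models_gff3
#' @export
read_gene_models_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  parent <- as.character(S4Vectors::mcols(gr)$Parent)
  parent[parent == "character(0)"] <- NA
  id <- as.character(S4Vectors::mcols(gr)$ID)
  type <- as.character(S4Vectors::mcols(gr)$type)
  data.frame(
    gene_id = ifelse(type == "gene", id, parent),
    type = type,
    scaffold = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
}

#' Write a domain-hit table in HMMER3 domtblout dialect
#'
#' Whitespace-separated columns following the HMMER3 `--domtblout` layout
#' (target name, accession, query name, full-sequence e-value/score; unused
#' columns filled with `-`), plus the leading `#` header lines.
#'
#' @param domains Hit table (`target_name`, `accession`, `query_name`,
#'   `evalue`, `score`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_domain_table <- function(domains, path) {
  header <- c(
    "#                                                               --- full sequence ---",
    "# target name        accession   tlen query name           accession   qlen   E-value  score  bias",
    "#------------------- ----------      ----- -------------------- ---------- ----- --------- ------ -----")
  body <- sprintf("%-20s %-11s %5d %-20s %-10s %5d %9.3g %6.1f %5.1f",
                  domains$target_name, domains$accession, 200L,
                  domains$query_name, "-", 500L,
                  domains$evalue, domains$score, 0.1)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write scaffold lengths / truth tables as TSV
#'
#' @param x A data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write the complete synthetic fixture to a directory
#'
#' Emits `genotypes.vcf`, `genes.gff3`, `domains.domtblout`, `scaffolds.tsv`
#' and the `truth/` tables so every pipeline stage can run from files alone.
#'
#' @param study Output of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_fixture <- function(study, dir) {
  dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  write_genotypes_vcf(study$gm, file.path(dir, "genotypes.vcf"))
  write_gene_models_gff3(study$sim$genes, file.path(dir, "genes.gff3"))
  write_domain_table(study$sim$domains, file.path(dir, "domains.domtblout"))
  write_tsv(study$sim$scaffolds, file.path(dir, "scaffolds.tsv"))
  tr <- study$sim$truth
  write_tsv(tr$true_map, file.path(dir, "truth", "true_map.tsv"))
  write_tsv(tr$true_rf, file.path(dir, "truth", "true_rf.tsv"))
  write_tsv(tr$scaffold_placement,
            file.path(dir, "truth", "scaffold_placement.tsv"))
  write_tsv(tr$irp_truth, file.path(dir, "truth", "irp_truth.tsv"))
  write_tsv(data.frame(
    cluster = rep(seq_along(tr$cluster_truth),
                  lengths(tr$cluster_truth)),
    gene_id = unlist(tr$cluster_truth)),
    file.path(dir, "truth", "cluster_truth.tsv"))
  phase_df <- function(h) data.frame(marker = tr$true_map$id,
                                     hap1 = h[, 1], hap2 = h[, 2])
  write_tsv(phase_df(tr$parental_phases$maternal),
            file.path(dir, "truth", "phase_maternal.tsv"))
  write_tsv(phase_df(tr$parental_phases$paternal),
            file.path(dir, "truth", "phase_paternal.tsv"))
  invisible(dir)
}
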