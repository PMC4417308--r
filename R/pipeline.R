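# End-to-end orchestration: simulate (or read) -> marker QC -> linkage map ->
# scaffold anchoring -> IRP catalog, with persisted per-record tables and a
# summary report whose every number is re-derivable from those tables.

#' Run configuration for the full pipeline
#'
#' Exactly one of `sim` (a [sim_config()]) or `inputs` (paths to
#' `genotypes_vcf`, `genes_gff3`, `domains`, `scaffolds_tsv`) must be given.
#'
#' @param sim A [sim_config()], or `NULL` when reading files.
#' @param inputs Named list of input paths, or `NULL` when simulating.
#' @param max_missing,alpha,lod_min,rf_max,min_markers,promoter_len,max_gap,
#'   max_intervening,evalue_max Stage thresholds (documented on the stage
#'   functions).
#' @param seed Integer seed for any stage randomness.
#' @param out_dir Output directory for persisted tables.
#' @return A validated list of class `"run_config"`.
#' @export
run_config <- function(sim = sim_config(), inputs = NULL,
                       max_missing = 0.10, alpha = 0.05, lod_min = 3,
                       rf_max = 0.5, min_markers = 3, promoter_len = 2000,
                       max_gap = 200000, max_intervening = 8,
                       evalue_max = 10, seed = 1L, out_dir = tempfile("run")) {
  check_that(xor(is.null(sim), is.null(inputs)), "sim/inputs",
             "exactly one of a sim_config or input paths must be active")
  if (!is.null(inputs)) {
    need <- c("genotypes_vcf", "genes_gff3", "domains", "scaffolds_tsv")
    check_that(all(need %in% names(inputs)), "inputs",
               paste("needs", paste(need, collapse = ", ")))
    missing_files <- unlist(inputs[need])[!file.exists(unlist(inputs[need]))]
    if (length(missing_files))
      stop("missing input file(s): ", paste(missing_files, collapse = ", "),
           call. = FALSE)
  }
  check_that(max_missing >= 0 && max_missing <= 1, "max_missing", "in [0,1]")
  check_that(alpha >= 0 && alpha <= 1, "alpha", "in [0,1]")
  check_that(lod_min >= 0, "lod_min", ">= 0")
  check_that(rf_max > 0 && rf_max <= 0.5, "rf_max", "in (0, 0.5]")
  check_that(max_gap > 0, "max_gap", "> 0")
  check_that(max_intervening >= 1, "max_intervening", ">= 1")
  check_that(evalue_max > 0, "evalue_max", "> 0")
  cfg <- list(sim = sim, inputs = inputs, max_missing = max_missing,
              alpha = alpha, lod_min = lod_min, rf_max = rf_max,
              min_markers = min_markers, promoter_len = promoter_len,
              max_gap = max_gap, max_intervening = max_intervening,
              evalue_max = evalue_max, seed = as.integer(seed),
              out_dir = out_dir)
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from a YAML file
#'
#' Flat keys mirroring the [run_config()] arguments; `sim:` holds
#' [sim_config()] arguments.
#'
#' @param path YAML file.
#' @return A `"run_config"`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- if (!is.null(y$sim)) do.call(sim_config, y$sim) else NULL
  args <- y[setdiff(names(y), "sim")]
  do.call(run_config, c(list(sim = sim), args))
}

# internal: run one stage with logging; abort with stage name on failure
.stage <- function(name, quiet, expr) {
  t0 <- Sys.time()
  if (!quiet) message(sprintf("[%s] ...", name))
  res <- tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
  if (!quiet)
    message(sprintf("[%s] done in %.1fs", name,
                    as.numeric(Sys.time() - t0, units = "secs")))
  res
}

#' Run the full pipeline
#'
#' Executes simulate/read -> QC -> map -> anchor -> IRP in order, persisting
#' each stage's outputs under `config$out_dir` and returning a summary
#' report. Identical config and seed give an identical report.
#'
#' @param config A [run_config()].
#' @param quiet Suppress per-stage messages (default TRUE).
#' @return A list of class `"run_report"`; see [make_report_tables()].
#' @export
run_pipeline <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  dat <- .stage("input", quiet, {
    if (!is.null(config$sim)) {
      cfg <- config$sim
      cfg$seed <- config$seed
      study <- simulate_study(cfg)
      write_sim_fixture(study, file.path(config$out_dir, "fixture"))
      list(gm = study$gm, genes = study$sim$genes,
           domains_path = file.path(config$out_dir, "fixture",
                                    "domains.domtblout"),
           scaffolds = study$sim$scaffolds, truth = study$sim$truth)
    } else {
      list(gm = read_genotypes_vcf(config$inputs$genotypes_vcf),
           genes = read_gene_models_gff3(config$inputs$genes_gff3),
           domains_path = config$inputs$domains,
           scaffolds = read_tsv(config$inputs$scaffolds_tsv),
           truth = NULL)
    }
  })

  qc <- .stage("marker_qc", quiet, {
    tab <- marker_qc_table(dat$gm)
    tab$category <- annotate_snp(tab, dat$genes, config$promoter_len)
    flt <- filter_markers(tab, config$max_missing, config$alpha)
    dd <- dedup_cosegregating(flt$retained,
                              dat$gm$geno[, -(1:2), drop = FALSE])
    flt$report$after_dedup <- nrow(dd$representatives)
    write_tsv(tab[, setdiff(names(tab), "progeny_gts")],
              file.path(config$out_dir, "markers_qc.tsv"))
    list(table = tab, retained = dd$representatives, groups = dd$groups,
         report = flt$report, tstv = ts_tv(tab))
  })

  map <- .stage("linkage_map", quiet, {
    geno <- dat$gm$geno[qc$retained$id, -(1:2), drop = FALSE]
    tp <- two_point_table(qc$retained, geno)
    grp <- group_markers_robust(tp, config$lod_min, config$rf_max)
    orders <- lapply(grp$groups, order_group, tp = tp)
    gmap <- build_map(orders, tp, markers = qc$retained)
    write_tsv(gmap, file.path(config$out_dir, "map.tsv"))
    list(tp = tp, groups = grp, map = gmap, summary = map_summary(gmap))
  })

  anc <- .stage("scaffold_anchor", quiet, {
    anchors <- anchor_scaffolds(map$map, dat$scaffolds)
    write_tsv(anchors, file.path(config$out_dir, "anchors.tsv"))
    list(anchors = anchors,
         coverage = coverage(anchors, sum(dat$scaffolds$length_bp)),
         kbcm = kb_per_cm(map$map, anchors, config$min_markers))
  })

  irp <- .stage("irp_catalog", quiet, {
    hits <- suppressWarnings(
      parse_domain_table(dat$domains_path, config$evalue_max))
    catalog <- build_catalog(hits, dat$genes)
    catalog <- map_irps(catalog, anc$anchors, map$map)
    clusters <- detect_clusters(catalog, dat$genes, config$max_gap,
                                config$max_intervening)
    write_tsv(catalog$genes, file.path(config$out_dir, "irp_catalog.tsv"))
    write_tsv(clusters, file.path(config$out_dir, "irp_clusters.tsv"))
    list(catalog = catalog, clusters = clusters)
  })

  report <- list(filter = qc$report,
                 tstv = qc$tstv,
                 snp_categories = table(qc$table$category),
                 map_summary = map$summary,
                 n_unplaced_markers = length(map$groups$unplaced),
                 anchor = list(
                   n_scaffolds = nrow(anc$anchors),
                   n_conflicted = sum(anc$anchors$conflict),
                   n_oriented = sum(anc$anchors$orientation %in% c("+", "-")),
                   coverage = anc$coverage,
                   kb_per_cm_overall = anc$kbcm$overall_mean),
                 irp = list(
                   n_total = nrow(irp$catalog$genes),
                   class_counts = irp$catalog$class_counts,
                   n_mapped = irp$catalog$n_mapped %||% 0L,
                   n_singleton = irp$catalog$n_singleton,
                   n_multi = irp$catalog$n_multi,
                   n_clusters = nrow(irp$clusters),
                   n_clustered_genes = sum(irp$clusters$n_members)),
                 seed = config$seed,
                 out_dir = config$out_dir)
  class(report) <- "run_report"
  res <- list(report = report, qc = qc, map = map, anchors = anc, irp = irp,
              truth = dat$truth, config = config)
  class(res) <- "pipeline_result"
  res
}

#' Write the Table-1/2/3-style report bundle
#'
#' Emits the per-group map summary, the anchoring summary, the kbp/cM table
#' and the IRP summaries as TSVs, plus a JSON mirror of the whole report for
#' machine reading.
#'
#' @param result A `"pipeline_result"` from [run_pipeline()].
#' @param dir Output directory (default the run's `out_dir`).
#' @return `dir`, invisibly.
#' @export
make_report_tables <- function(result, dir = result$report$out_dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(result$map$summary$per_group,
            file.path(dir, "table_map_summary.tsv"))
  write_tsv(result$anchors$anchors, file.path(dir, "table_anchors.tsv"))
  if (nrow(result$anchors$kbcm$regions %||% data.frame()) > 0) {
    write_tsv(result$anchors$kbcm$per_group,
              file.path(dir, "table_kb_per_cm.tsv"))
  }
  cc <- result$irp$catalog$class_counts
  write_tsv(data.frame(irp_class = names(cc), n = as.integer(cc)),
            file.path(dir, "table_irp_classes.tsv"))
  write_tsv(result$irp$clusters, file.path(dir, "table_irp_clusters.tsv"))
  rep <- result$report
  rep$filter$discarded <- lapply(rep$filter$discarded, length)
  jsonlite::write_json(
    rapply(unclass(rep), function(x) {
      if (is.table(x)) as.list(stats::setNames(as.integer(x), names(x))) else x
    }, how = "replace"),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    force = TRUE)
  invisible(dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("pipeline run report\n")
  cat(sprintf("  markers: %d total -> %d after filters -> %d mapped in %d groups\n",
              x$filter$total, x$filter$after_dedup %||% x$filter$after_distortion,
              x$map_summary$overall$n_markers, x$map_summary$overall$n_groups))
  cat(sprintf("  map length %.1f cM, mean group density %.2f cM\n",
              x$map_summary$overall$total_length_cM,
              x$map_summary$overall$mean_group_density_cM))
  cat(sprintf("  scaffolds anchored: %d (%.1f%% coverage), %d conflicted, %d oriented\n",
              x$anchor$n_scaffolds, 100 * x$anchor$coverage,
              x$anchor$n_conflicted, x$anchor$n_oriented))
  cat(sprintf("  IRPs: %d catalogued, %d mapped, %d clusters (%d genes)\n",
              x$irp$n_total, x$irp$n_mapped, x$irp$n_clusters,
              x$irp$n_clustered_genes))
  invisible(x)
}
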