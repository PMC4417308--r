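# Anchoring assembly scaffolds onto the genetic map, orienting them,
# comparing maps through shared scaffolds and placing external loci.

#' Anchor scaffolds onto the genetic map
#'
#' Each scaffold is assigned to the linkage group(s) containing its mapped
#' markers. The primary group is the one with the most supporting markers
#' (ties broken by group name); a scaffold with markers in two or more
#' groups is flagged as a conflict but keeps all assignments.
#'
#' @param map A `"genetic_map"` with `scaffold` and `pos_bp` columns.
#' @param scaffold_lengths data.frame (`scaffold`, `length_bp`).
#' @return A `"scaffold_anchors"` data.frame: `scaffold`, `length_bp`, `lg`
#'   (primary), `all_lgs`, `orientation`, `n_markers`, `cm_min`, `cm_max`,
#'   `conflict`.
#' @export
anchor_scaffolds <- function(map, scaffold_lengths) {
  stopifnot(all(c("scaffold", "pos_bp") %in% names(map)))
  known <- map$scaffold %in% scaffold_lengths$scaffold
  if (any(!known))
    warning(length(unique(map$scaffold[!known])),
            " scaffold(s) without a known length; anchored with length 0")
  rows <- lapply(split(map, map$scaffold), function(sm) {
    tab <- sort(table(sm$group), decreasing = TRUE)
    primary <- names(tab)[tab == max(tab)]
    primary <- sort(primary)[1]
    sup <- sm[sm$group == primary, ]
    len <- scaffold_lengths$length_bp[match(sm$scaffold[1],
                                            scaffold_lengths$scaffold)]
    data.frame(
      scaffold = sm$scaffold[1],
      length_bp = if (is.na(len)) 0 else len,
      lg = primary,
      all_lgs = paste(sort(unique(sm$group)), collapse = ","),
      orientation = orient_scaffold(sup$pos_bp, sup$cM),
      n_markers = nrow(sm),
      cm_min = min(sup$cM), cm_max = max(sup$cM),
      conflict = length(unique(sm$group)) >= 2,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$scaffold), ]
  rownames(out) <- NULL
  class(out) <- c("scaffold_anchors", "data.frame")
  out
}

#' Orient a scaffold from its supporting markers
#'
#' The sign of the rank correlation between physical position (bp) and map
#' position (cM): positive is `+`, negative `-`; fewer than two markers,
#' degenerate coordinates or a zero correlation give `unknown`.
#'
#' @param pos_bp,cM Coordinates of the supporting markers.
#' @return `"+"`, `"-"` or `"unknown"`.
#' @export
orient_scaffold <- function(pos_bp, cM) {
  if (length(pos_bp) < 2 || length(unique(pos_bp)) < 2 ||
      length(unique(cM)) < 2) return("unknown")
  rho <- suppressWarnings(stats::cor(pos_bp, cM, method = "spearman"))
  if (is.na(rho) || rho == 0) return("unknown")
  if (rho > 0) "+" else "-"
}

#' Fraction of the genome covered by anchored scaffolds
#'
#' @param anchors A `"scaffold_anchors"` table; each scaffold counts once
#'   even when conflicted.
#' @param genome_size_bp Reference size to divide by; defaults to the sum of
#'   the anchored scaffold lengths' own assembly (pass the assembly total for
#'   a genome-wide figure).
#' @return Fraction in \[0, 1\].
#' @export
coverage <- function(anchors, genome_size_bp) {
  if (genome_size_bp <= 0) stop("genome_size_bp must be > 0", call. = FALSE)
  u <- !duplicated(anchors$scaffold)
  sum(anchors$length_bp[u]) / genome_size_bp
}

#' Compare two genetic maps through their scaffolds
#'
#' Anchor markers are markers tagging the same (scaffold, bp) position in
#' both maps; shared scaffolds are matched on scaffold id; scaffolds only in
#' map B are "new", with their summed length from the scaffold table.
#'
#' @param mapA,mapB `"genetic_map"` tables with `scaffold`, `pos_bp`.
#' @param scaffold_lengths data.frame (`scaffold`, `length_bp`).
#' @param bp_tol Coordinate tolerance in bp for anchor-marker identity
#'   (default 0 = exact).
#' @return List: `anchor_markers` (data.frame of matched positions),
#'   `shared_scaffolds`, `new_scaffolds`, `new_length_bp`, and `per_group`
#'   counts in map B.
#' @export
compare_maps <- function(mapA, mapB, scaffold_lengths, bp_tol = 0) {
  keyA <- paste(mapA$scaffold, mapA$pos_bp)
  if (bp_tol == 0) {
    hit <- mapB[paste(mapB$scaffold, mapB$pos_bp) %in% keyA, ]
  } else {
    hit <- mapB[vapply(seq_len(nrow(mapB)), function(k) {
      any(mapA$scaffold == mapB$scaffold[k] &
            abs(mapA$pos_bp - mapB$pos_bp[k]) <= bp_tol)
    }, logical(1)), ]
  }
  shared <- intersect(unique(mapA$scaffold), unique(mapB$scaffold))
  new_scafs <- setdiff(unique(mapB$scaffold), unique(mapA$scaffold))
  len <- scaffold_lengths$length_bp[match(new_scafs,
                                          scaffold_lengths$scaffold)]
  if (anyNA(len)) {
    warning(sum(is.na(len)), " new scaffold(s) without a known length;",
            " counted with length 0")
    len[is.na(len)] <- 0
  }
  per_group <- do.call(rbind, lapply(split(mapB, mapB$group), function(g) {
    data.frame(group = g$group[1],
               n_scaffolds_B = length(unique(g$scaffold)),
               n_shared = length(intersect(unique(g$scaffold), shared)),
               n_new = length(intersect(unique(g$scaffold), new_scafs)),
               n_anchor_markers = sum(hit$group == g$group[1]),
               stringsAsFactors = FALSE)
  }))
  rownames(per_group) <- NULL
  list(anchor_markers = hit,
       shared_scaffolds = shared,
       new_scaffolds = new_scafs,
       new_length_bp = sum(len),
       per_group = per_group)
}

#' Physical-to-genetic length ratios (kbp per cM)
#'
#' For every scaffold with at least `min_markers` supporting markers in its
#' primary group and a non-degenerate cM span, the ratio
#' (bp span / 1000) / (cM span). Per-group means and ranges and the overall
#' mean of per-region ratios are reported.
#'
#' @param map A `"genetic_map"` with `scaffold`, `pos_bp`.
#' @param anchors The matching `"scaffold_anchors"` table.
#' @param min_markers Minimum supporting markers per region (default 3).
#' @return List: `regions` data.frame (`scaffold`, `lg`, `kbp`, `cM`,
#'   `kbp_per_cM`), `per_group` (mean and range), `overall_mean`, `skipped`.
#' @export
kb_per_cm <- function(map, anchors, min_markers = 3) {
  regions <- NULL
  skipped <- character()
  for (scf in unique(anchors$scaffold)) {
    lg <- anchors$lg[anchors$scaffold == scf]
    sm <- map[map$scaffold == scf & map$group == lg, ]
    if (nrow(sm) < min_markers) next
    cm_span <- max(sm$cM) - min(sm$cM)
    if (cm_span <= 0) {
      skipped <- c(skipped, scf)
      next
    }
    kbp <- (max(sm$pos_bp) - min(sm$pos_bp)) / 1000
    regions <- rbind(regions, data.frame(
      scaffold = scf, lg = lg, kbp = kbp, cM = cm_span,
      kbp_per_cM = kbp / cm_span, stringsAsFactors = FALSE))
  }
  if (is.null(regions)) {
    return(list(regions = data.frame(), per_group = data.frame(),
                overall_mean = NA_real_, skipped = skipped))
  }
  per_group <- do.call(rbind, lapply(split(regions, regions$lg), function(g) {
    data.frame(group = g$lg[1], n_regions = nrow(g),
               mean_kbp_per_cM = mean(g$kbp_per_cM),
               min_kbp_per_cM = min(g$kbp_per_cM),
               max_kbp_per_cM = max(g$kbp_per_cM), stringsAsFactors = FALSE)
  }))
  rownames(per_group) <- NULL
  list(regions = regions, per_group = per_group,
       overall_mean = mean(regions$kbp_per_cM), skipped = skipped)
}

#' Place an external locus on the map through its scaffold
#'
#' The locus inherits its scaffold's primary linkage group; its cM position
#' is linearly interpolated between the flanking supporting markers in
#' scaffold bp order (which respects orientation automatically). Beyond the
#' outermost marker the nearest marker's cM is used and the placement is
#' flagged extrapolated. A locus on a conflicted scaffold is placed on the
#' majority group with a warning.
#'
#' @param scaffold,bp Locus coordinates.
#' @param anchors A `"scaffold_anchors"` table.
#' @param map The `"genetic_map"` used to build `anchors`.
#' @return List: `placed`, `lg`, `cM`, `extrapolated`, `reason` (when
#'   unplaced).
#' @export
place_external_locus <- function(scaffold, bp, anchors, map) {
  a <- anchors[anchors$scaffold == scaffold, ]
  if (nrow(a) == 0) {
    return(list(placed = FALSE, lg = NA_character_, cM = NA_real_,
                extrapolated = FALSE, reason = "scaffold not anchored"))
  }
  if (a$conflict[1])
    warning("scaffold ", scaffold,
            " is conflicted; placing on majority group ", a$lg[1])
  sup <- map[map$scaffold == scaffold & map$group == a$lg[1], ]
  sup <- sup[order(sup$pos_bp), ]
  cm <- if (bp <= sup$pos_bp[1]) {
    sup$cM[1]
  } else if (bp >= sup$pos_bp[nrow(sup)]) {
    sup$cM[nrow(sup)]
  } else {
    stats::approx(sup$pos_bp, sup$cM, xout = bp, ties = mean)$y
  }
  extrap <- bp < sup$pos_bp[1] || bp > sup$pos_bp[nrow(sup)]
  list(placed = TRUE, lg = a$lg[1], cM = cm, extrapolated = extrap,
       reason = NA_character_)
}
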