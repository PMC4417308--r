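mk_map_df <- function(group, marker, scaffold, pos_bp, cM) {
  m <- data.frame(group = group, marker = marker, scaffold = scaffold,
                  pos_bp = pos_bp, cM = cM, stringsAsFactors = FALSE)
  class(m) <- c("genetic_map", "data.frame")
  m
}

test_that("scaffolds are anchored, conflicted and oriented as specified", {
  map <- mk_map_df(
    group = c("LG1", "LG1", "LG1", "LG1", "LG2", "LG2"),
    marker = paste0("m", 1:6),
    scaffold = c("s1", "s1", "s1", "s2", "s2", "s2"),
    pos_bp = c(10000, 50000, 90000, 5000, 20000, 60000),
    cM = c(3, 5, 7, 10, 40, 38))
  lens <- data.frame(scaffold = c("s1", "s2"), length_bp = c(1e5, 8e4))
  a <- anchor_scaffolds(map, lens)
  s1 <- a[a$scaffold == "s1", ]
  expect_false(s1$conflict)
  expect_equal(s1$lg, "LG1")
  expect_equal(s1$orientation, "+")
  expect_equal(s1$n_markers, 3)
  s2 <- a[a$scaffold == "s2", ]
  expect_true(s2$conflict)            # markers in LG1 and LG2
  expect_equal(s2$lg, "LG2")          # majority group
  expect_equal(s2$all_lgs, "LG1,LG2")
  expect_equal(s2$orientation, "-")   # bp up, cM down in LG2

  # unknown scaffold length: warning, length 0
  map2 <- mk_map_df("LG1", "m9", "s9", 100, 1)
  expect_warning(a2 <- anchor_scaffolds(map2, lens), "length")
  expect_equal(a2$length_bp, 0)
})

test_that("orientation flips under bp reversal and needs two distinct markers", {
  expect_equal(orient_scaffold(c(10000, 50000), c(3, 7)), "+")
  expect_equal(orient_scaffold(c(10000, 50000), c(7, 3)), "-")
  expect_equal(orient_scaffold(c(10000), c(3)), "unknown")
  expect_equal(orient_scaffold(c(10000, 10000), c(3, 7)), "unknown")
  expect_equal(orient_scaffold(c(10000, 50000), c(3, 3)), "unknown")
  # reversal property on random supports
  set.seed(41)
  for (k in 1:20) {
    bp <- sort(sample(1:1e6, 5))
    cm <- sort(runif(5, 0, 20))
    o1 <- orient_scaffold(bp, cm)
    o2 <- orient_scaffold(max(bp) - bp + 1, cm)
    expect_true(o1 == "+" && o2 == "-")
  }
})

test_that("coverage divides unique anchored length by genome size", {
  a <- data.frame(scaffold = c("s1", "s2"), length_bp = c(242.6e6 - 1e6, 1e6))
  expect_equal(round(100 * coverage(a, 532.5e6), 1), 45.6)
  expect_equal(coverage(a[0, ], 532.5e6), 0)
  expect_equal(coverage(data.frame(scaffold = "s", length_bp = 100), 100), 1)
  # conflicted scaffolds (duplicated rows) count once
  dup <- rbind(a, a[1, ])
  expect_equal(coverage(dup, 532.5e6), coverage(a, 532.5e6))
  expect_error(coverage(a, 0), "> 0")
})

test_that("map comparison finds anchors, shared and new scaffolds", {
  A <- mk_map_df("LG1", c("a1", "a2"), c("s1", "s2"), c(100, 200), c(0, 5))
  B <- mk_map_df("LG1", c("b1", "b2", "b3"), c("s1", "s2", "s3"),
                 c(100, 999, 50), c(0, 4, 9))
  lens <- data.frame(scaffold = c("s1", "s2", "s3"),
                     length_bp = c(5e5, 4e5, 1e6))
  cmp <- compare_maps(A, B, lens)
  expect_equal(cmp$anchor_markers$marker, "b1")     # same (scaffold, bp)
  expect_setequal(cmp$shared_scaffolds, c("s1", "s2"))
  expect_equal(cmp$new_scaffolds, "s3")
  expect_equal(cmp$new_length_bp, 1e6)

  # identical maps: everything shared, all markers anchors, nothing new
  cmp2 <- compare_maps(A, A, lens)
  expect_equal(nrow(cmp2$anchor_markers), 2)
  expect_equal(length(cmp2$new_scaffolds), 0)
  expect_equal(cmp2$new_length_bp, 0)

  # missing length for a new scaffold
  expect_warning(cmp3 <- compare_maps(A, B, lens[1:2, ]), "length")
  expect_equal(cmp3$new_length_bp, 0)
})

test_that("map comparison equals a brute-force set-operation oracle", {
  set.seed(42)
  for (k in 1:20) {
    scafs <- paste0("s", 1:8)
    mkmap <- function() {
      n <- sample(5:15, 1)
      mk_map_df(sample(c("LG1", "LG2"), n, replace = TRUE),
                paste0("m", seq_len(n), "_", k),
                sample(scafs, n, replace = TRUE),
                sample(1:500, n), runif(n, 0, 50))
    }
    A <- mkmap(); B <- mkmap()
    lens <- data.frame(scaffold = scafs, length_bp = seq(1e5, 8e5, by = 1e5))
    cmp <- compare_maps(A, B, lens)
    expect_setequal(cmp$shared_scaffolds,
                    intersect(unique(A$scaffold), unique(B$scaffold)))
    new_oracle <- setdiff(unique(B$scaffold), unique(A$scaffold))
    expect_setequal(cmp$new_scaffolds, new_oracle)
    expect_equal(cmp$new_length_bp,
                 sum(lens$length_bp[lens$scaffold %in% new_oracle]))
    key <- paste(A$scaffold, A$pos_bp)
    expect_equal(nrow(cmp$anchor_markers),
                 sum(paste(B$scaffold, B$pos_bp) %in% key))
    # anti-symmetry of "new"
    cmp_rev <- compare_maps(B, A, lens)
    expect_equal(length(intersect(cmp$new_scaffolds, cmp_rev$new_scaffolds)),
                 0)
  }
})

test_that("kbp/cM regions respect the marker minimum and span rules", {
  map <- mk_map_df(
    group = rep("LG1", 5),
    marker = paste0("m", 1:5),
    scaffold = c("s1", "s1", "s1", "s2", "s2"),
    pos_bp = c(1, 500000, 1000001, 10, 20),
    cM = c(0, 5, 10, 12, 13))
  lens <- data.frame(scaffold = c("s1", "s2"), length_bp = c(1.1e6, 1e5))
  a <- anchor_scaffolds(map, lens)
  r <- kb_per_cm(map, a, min_markers = 3)
  expect_equal(nrow(r$regions), 1)              # s2 has only 2 markers
  expect_equal(r$regions$kbp_per_cM, 100)       # 1 Mb over 10 cM
  expect_equal(r$overall_mean, 100)
  # degenerate cM span is skipped with a reason
  map0 <- mk_map_df(rep("LG1", 3), paste0("z", 1:3), "s3",
                    c(1, 100, 200), c(2, 2, 2))
  a0 <- anchor_scaffolds(map0, data.frame(scaffold = "s3", length_bp = 1e4))
  r0 <- kb_per_cm(map0, a0)
  expect_equal(r0$skipped, "s3")
})

test_that("external loci interpolate within their scaffold's marker frame", {
  map <- mk_map_df(rep("LG1", 3), paste0("m", 1:3), "s1",
                   c(1000, 3000, 5000), c(4, 6, 10))
  lens <- data.frame(scaffold = "s1", length_bp = 1e4)
  a <- anchor_scaffolds(map, lens)
  expect_equal(place_external_locus("s1", 3000, a, map)$cM, 6)
  expect_equal(place_external_locus("s1", 2000, a, map)$cM, 5)
  ext <- place_external_locus("s1", 9000, a, map)
  expect_true(ext$extrapolated)
  expect_equal(ext$cM, 10)
  un <- place_external_locus("s9", 10, a, map)
  expect_false(un$placed)
  expect_match(un$reason, "not anchored")
  # conflicted scaffold: placed on the majority group with a warning
  map2 <- rbind(map, mk_map_df("LG2", "m4", "s1", 9000, 0))
  class(map2) <- c("genetic_map", "data.frame")
  a2 <- anchor_scaffolds(map2, lens)
  expect_warning(pl <- place_external_locus("s1", 2000, a2, map2),
                 "majority")
  expect_equal(pl$lg, "LG1")
})

test_that("synthetic scaffolds recover their true group and orientation", {
  z <- small_study(101)
  d <- tp_of(z$study)
  grp <- group_markers_robust(d$tp)
  orders <- lapply(grp$groups, order_group, tp = d$tp)
  map <- build_map(orders, d$tp, markers = d$markers)
  anchors <- anchor_scaffolds(map, z$study$sim$scaffolds)
  truth <- z$study$sim$truth
  # group assignment matches truth for every unconflicted scaffold
  group_chrom <- sapply(split(map, map$group), function(g) {
    names(which.max(table(truth$true_map$chrom[match(g$marker,
                                                     truth$true_map$id)])))
  })
  for (k in which(!anchors$conflict)) {
    want <- truth$scaffold_placement$chrom[
      truth$scaffold_placement$scaffold == anchors$scaffold[k]]
    expect_equal(unname(group_chrom[anchors$lg[k]]), want)
  }
  # orientation agrees with truth up to a per-group flip
  ok <- 0; tot <- 0
  for (gname in unique(anchors$lg)) {
    sel <- anchors$lg == gname & anchors$orientation %in% c("+", "-") &
      anchors$n_markers >= 3
    if (!any(sel)) next
    tori <- truth$scaffold_placement$orientation[
      match(anchors$scaffold[sel], truth$scaffold_placement$scaffold)]
    agree <- anchors$orientation[sel] == tori
    ok <- ok + max(sum(agree), sum(!agree))
    tot <- tot + length(agree)
  }
  expect_gte(ok / tot, 0.95)
})
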