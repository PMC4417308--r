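test_that("domain-table parsing enforces the inclusive e-value cutoff", {
  d <- data.frame(target_name = c("LRR", "LRR", "NB-ARC", "weird"),
                  accession = c("PF00560", "PF00560", "PF00931", "PF99999"),
                  query_name = c("p1.1", "p2.1", "p1.1", "p3.1"),
                  evalue = c(11, 10, 1e-40, 1e-10),
                  score = c(10, 20, 300, 5))
  f <- tempfile(fileext = ".domtblout")
  write_domain_table(d, f)
  expect_warning(hits <- parse_domain_table(f), "unrecognised")
  expect_false("p2.1" %in% hits$protein_id && 11 %in% hits$evalue)
  expect_true(any(hits$protein_id == "p2.1"))   # e-value 10 kept (inclusive)
  expect_false(any(hits$protein_id == "p3.1"))  # unknown accession dropped
  # p1.1's LRR hit sits above the cutoff (e-value 11): only NB-ARC survives
  expect_setequal(hits$domain[hits$protein_id == "p1.1"], "NB-ARC")

  # malformed line: skipped with a warning naming the line
  writeLines(c(readLines(f), "totally broken line"), f)
  w <- testthat::capture_warnings(parse_domain_table(f))
  expect_true(any(grepl("malformed", w)))

  # empty file -> empty catalog
  empty <- tempfile()
  writeLines("# nothing", empty)
  expect_equal(nrow(parse_domain_table(empty)), 0)
})

test_that("architecture classification is total and exact", {
  expect_equal(classify_irp("LRR"), "LRR")
  expect_equal(classify_irp(c("LRR", "kinase")), "LRR-kinase")
  expect_equal(classify_irp("LysM"), "LysM")
  expect_equal(classify_irp(c("LysM", "kinase")), "LysM-kinase")
  expect_equal(classify_irp("NB-ARC"), "NB-ARC")
  expect_equal(classify_irp(c("NB-ARC", "LRR")), "NB-ARC-LRR")
  expect_equal(classify_irp("TIR"), "TIR")
  expect_equal(classify_irp(c("TIR", "LRR")), "TIR-LRR")
  expect_equal(classify_irp(c("TIR", "NB-ARC", "LRR")), "TIR-NB-ARC-LRR")
  expect_equal(classify_irp("WRKY"), "WRKY")
  expect_equal(classify_irp(c("WRKY", "kinase")), "other")
  expect_equal(classify_irp(character()), "not-IRP")
  # order and duplication of domains are irrelevant
  expect_equal(classify_irp(c("LRR", "NB-ARC", "TIR", "LRR")),
               "TIR-NB-ARC-LRR")
  # vectorised over a list
  expect_equal(classify_irp(list("WRKY", c("kinase", "LRR"))),
               c("WRKY", "LRR-kinase"))
})

test_that("catalog counts equal the generator's truth exactly", {
  z <- small_study(101)
  sim <- z$study$sim
  hits <- suppressWarnings(parse_domain_table(
    write_domain_table(sim$domains, tempfile(fileext = ".domtblout"))))
  cat <- build_catalog(hits, sim$genes)
  truth <- sim$truth$irp_truth
  expect_setequal(cat$genes$gene_id, truth$gene_id)
  want <- table(truth$irp_class)
  for (cl in names(want)) {
    expect_equal(unname(cat$class_counts[cl]), unname(want[cl]), label = cl)
  }
  expect_equal(sum(cat$class_counts), nrow(cat$genes))
  expect_equal(cat$n_singleton + cat$n_multi, nrow(cat$genes))
})

test_that("singleton/multi scaffold split counts genes, not scaffolds", {
  genes <- data.frame(gene_id = paste0("g", 1:4), type = "gene",
                      scaffold = c("s1", "s1", "s1", "s2"),
                      start = c(1, 1000, 2000, 10), end = c(500, 1500, 2500, 400),
                      strand = "+", stringsAsFactors = FALSE)
  hits <- data.frame(protein_id = paste0("g", 1:4, ".1"), domain = "WRKY",
                     accession = "PF03106", evalue = 1e-10)
  cat <- build_catalog(hits, genes)
  expect_equal(cat$n_multi, 3)
  expect_equal(cat$n_singleton, 1)
})

test_that("genetic placement of IRPs matches a brute-force join", {
  z <- small_study(101)
  d <- tp_of(z$study)
  grp <- group_markers_robust(d$tp)
  orders <- lapply(grp$groups, order_group, tp = d$tp)
  map <- build_map(orders, d$tp, markers = d$markers)
  anchors <- anchor_scaffolds(map, z$study$sim$scaffolds)
  hits <- suppressWarnings(parse_domain_table(
    write_domain_table(z$study$sim$domains, tempfile())))
  cat <- build_catalog(hits, z$study$sim$genes)
  cat <- map_irps(cat, anchors, map)
  # mapped exactly the genes whose scaffold is anchored
  on_anchored <- cat$genes$scaffold %in% anchors$scaffold
  expect_equal(!is.na(cat$genes$lg), on_anchored)
  expect_equal(cat$n_mapped, sum(on_anchored))
  # a gene whose midpoint sits exactly on a supporting marker inherits its cM
  scf <- anchors$scaffold[which(!anchors$conflict)[1]]
  sup <- map[map$scaffold == scf & map$group ==
               anchors$lg[anchors$scaffold == scf], ]
  probe <- cat
  probe$genes <- probe$genes[1, ]
  probe$genes$scaffold <- scf
  probe$genes$start_bp <- sup$pos_bp[1] - 100
  probe$genes$end_bp <- sup$pos_bp[1] + 100
  probe <- map_irps(probe, anchors, map)
  expect_equal(probe$genes$cM, sup$cM[1])
})

test_that("cluster detection applies the 200 kb / fewer-than-8 rule", {
  mk_genes <- function(starts, irp) {
    data.frame(gene_id = sprintf("g%02d", seq_along(starts)), type = "gene",
               scaffold = "s1", start = starts, end = starts + 1000,
               strand = "+", stringsAsFactors = FALSE)
  }
  mk_cat <- function(genes, irp_ids) {
    g <- genes[genes$gene_id %in% irp_ids, ]
    structure(list(genes = data.frame(
      gene_id = g$gene_id, protein_id = paste0(g$gene_id, ".1"),
      domains = "LRR", irp_class = "LRR", scaffold = g$scaffold,
      start_bp = g$start, end_bp = g$end, lg = NA_character_, cM = NA_real_,
      stringsAsFactors = FALSE)), class = "irp_catalog")
  }
  # 150 kb apart with 3 intervening non-IRPs: one cluster of 2
  starts <- c(1, 30000, 60000, 90000, 152001)
  genes <- mk_genes(starts)
  cl <- detect_clusters(mk_cat(genes, c("g01", "g05")), genes)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$members, "g01,g05")
  expect_equal(cl$n_members, 2)

  # 250 kb apart, nothing between: no cluster
  genes2 <- mk_genes(c(1, 252001))
  expect_equal(nrow(detect_clusters(mk_cat(genes2, c("g01", "g02")), genes2)),
               0)

  # eight intervening non-IRPs break the chain even at a short gap
  starts3 <- c(1, seq(5000, 40000, length.out = 8), 50000)
  genes3 <- mk_genes(starts3)
  expect_equal(nrow(detect_clusters(mk_cat(genes3, c("g01", "g10")), genes3)),
               0)
  # seven intervening: linked
  starts4 <- c(1, seq(5000, 40000, length.out = 7), 50000)
  genes4 <- mk_genes(starts4)
  expect_equal(nrow(detect_clusters(mk_cat(genes4, c("g01", "g09")), genes4)),
               1)
})

test_that("cluster detection equals the quadratic brute-force oracle", {
  for (seed in 1:40) {
    lay <- random_gene_layout(seed)
    cat <- structure(list(genes = {
      g <- lay$genes[lay$genes$gene_id %in% lay$irp, ]
      data.frame(gene_id = g$gene_id, protein_id = paste0(g$gene_id, ".1"),
                 domains = "LRR", irp_class = "LRR", scaffold = g$scaffold,
                 start_bp = g$start, end_bp = g$end, lg = NA_character_,
                 cM = NA_real_, stringsAsFactors = FALSE)
    }), class = "irp_catalog")
    got <- detect_clusters(cat, lay$genes)
    want <- brute_force_clusters(lay$genes, lay$irp)
    got_sets <- sort(vapply(seq_len(nrow(got)), function(k) got$members[k],
                            character(1)))
    want_sets <- sort(vapply(want, paste, character(1), collapse = ","))
    expect_equal(got_sets, want_sets, label = paste("seed", seed))
  }
})

test_that("clusters are invariant under whole-scaffold translation", {
  lay <- random_gene_layout(99)
  cat_of <- function(tbl) structure(list(genes = {
    g <- tbl[tbl$gene_id %in% lay$irp, ]
    data.frame(gene_id = g$gene_id, protein_id = paste0(g$gene_id, ".1"),
               domains = "LRR", irp_class = "LRR", scaffold = g$scaffold,
               start_bp = g$start, end_bp = g$end, lg = NA_character_,
               cM = NA_real_, stringsAsFactors = FALSE)
  }), class = "irp_catalog")
  shifted <- lay$genes
  shifted$start <- shifted$start + 123456
  shifted$end <- shifted$end + 123456
  a <- detect_clusters(cat_of(lay$genes), lay$genes)
  b <- detect_clusters(cat_of(shifted), shifted)
  expect_equal(a$members, b$members)
})

test_that("injected truth clusters are recovered with identical membership", {
  z <- small_study(101)
  sim <- z$study$sim
  hits <- suppressWarnings(
    parse_domain_table(write_domain_table(sim$domains, tempfile())))
  cat <- build_catalog(hits, sim$genes)
  cl <- detect_clusters(cat, sim$genes)
  found_sets <- strsplit(cl$members, ",")
  for (truth_set in sim$truth$cluster_truth) {
    hit <- any(vapply(found_sets, function(s) setequal(s, truth_set),
                      logical(1)))
    expect_true(hit, label = paste("cluster", paste(truth_set, collapse = "+")))
  }
  # every reported cluster satisfies its defining predicates when re-checked
  gg <- sim$genes[sim$genes$type == "gene", ]
  gg <- gg[order(gg$scaffold, gg$start), ]
  for (k in seq_len(nrow(cl))) {
    mem <- strsplit(cl$members[k], ",")[[1]]
    rows <- gg[gg$gene_id %in% mem, ]
    rows <- rows[order(rows$start), ]
    sg <- gg[gg$scaffold == rows$scaffold[1], ]
    for (j in seq_len(nrow(rows) - 1)) {
      expect_lte(rows$start[j + 1] - rows$end[j], 200000)
      between <- sg$gene_id[sg$start > rows$start[j] &
                              sg$start < rows$start[j + 1]]
      expect_lt(sum(!(between %in% cat$genes$gene_id)), 8)
    }
  }
})
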