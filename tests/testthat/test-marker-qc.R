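test_that("segregation classes follow the CP rules", {
  expect_equal(classify_segregation("AB", "AA"), "maternal_1to1")
  expect_equal(classify_segregation("AB", "BB"), "maternal_1to1")
  expect_equal(classify_segregation("AA", "AB"), "paternal_1to1")
  expect_equal(classify_segregation("AB", "AB"), "both_het_1to2to1")
  expect_equal(classify_segregation("AA", "AA"), "monomorphic")
  expect_equal(classify_segregation("AA", "BB"), "uninformative")
  expect_equal(classify_segregation(NA, "AB"), "uninformative")
})

test_that("chi-square goodness of fit matches hand computations", {
  r <- chi_square_gof(c(66, 66), c(1, 1))
  expect_equal(r$stat, 0)
  expect_equal(r$p, 1)
  r2 <- chi_square_gof(c(70, 62), c(1, 1))
  expect_equal(r2$stat, (70 - 66)^2 / 66 + (62 - 66)^2 / 66, tolerance = 1e-10)
  expect_equal(round(r2$p, 3), 0.486)
  r3 <- chi_square_gof(c(33, 66, 33), c(1, 2, 1))
  expect_equal(r3$stat, 0)
  expect_error(chi_square_gof(c(0, 0), c(1, 1)), "positive")
  expect_error(chi_square_gof(c(1, 2, 3), c(1, 1)), "lengths")
})

test_that("filter cascade drops by reason and keeps an exact ledger", {
  n <- 132
  mk_row <- function(id, seg, miss, p) {
    data.frame(id = id, scaffold = "s1", pos_bp = nchar(id), seg_class = seg,
               missing_frac = miss, chi2_p = p, stringsAsFactors = FALSE)
  }
  markers <- rbind(
    mk_row("keep", "maternal_1to1", 0, 0.8),
    mk_row("mono", "monomorphic", 0, NA),
    mk_row("gappy", "paternal_1to1", 0.15, 0.9),
    mk_row("skewed", "both_het_1to2to1", 0.02, 1e-6))
  out <- filter_markers(markers, max_missing = 0.10, distortion_alpha = 0.05)
  expect_equal(out$retained$id, "keep")
  expect_equal(out$report$discarded$not_segregating, "mono")
  expect_equal(out$report$discarded$missingness, "gappy")
  expect_equal(out$report$discarded$distortion, "skewed")
  # cascade is monotone and counts reproduce the retained size
  expect_true(all(diff(c(out$report$total, out$report$polymorphic,
                         out$report$after_missingness,
                         out$report$after_distortion)) <= 0))
  expect_equal(out$report$after_distortion, nrow(out$retained))
  # alpha = 0 disables the distortion filter
  out0 <- filter_markers(markers, distortion_alpha = 0)
  expect_true("skewed" %in% out0$retained$id)
  # empty input
  e <- filter_markers(markers[0, ])
  expect_equal(nrow(e$retained), 0)
  expect_equal(e$report$total, 0)
})

test_that("a strongly distorted marker fails the chi-square filter", {
  p <- chi_square_gof(c(120, 12), c(1, 1))$p
  expect_lt(p, 1e-10)
})

test_that("dedup groups identical vectors and is honest about missingness", {
  g <- rep(c("AA", "AB"), 25)
  geno <- rbind(a = g, b = g, c = replace(g, 3, "AB"),
                d = replace(g, 1:45, NA))  # matches a where observed, but
                                           # too little joint coverage
  markers <- data.frame(id = c("a", "b", "c", "d"), scaffold = "s1",
                        pos_bp = 1:4, stringsAsFactors = FALSE)
  out <- dedup_cosegregating(markers, geno)
  expect_setequal(out$representatives$id, c("a", "c", "d"))
  expect_setequal(out$groups[["a"]], c("a", "b"))

  # 5 identical + 1 distinct -> 2 representatives (brute-force check)
  geno2 <- rbind(m1 = g, m2 = g, m3 = g, m4 = g, m5 = g,
                 m6 = rev(g))
  markers2 <- data.frame(id = paste0("m", 1:6), scaffold = "s1",
                         pos_bp = 1:6, stringsAsFactors = FALSE)
  out2 <- dedup_cosegregating(markers2, geno2)
  expect_equal(nrow(out2$representatives), 2)
  expect_equal(length(out2$groups[["m1"]]), 5)
})

test_that("SNP annotation follows CDS > UTR > intron > promoter precedence", {
  genes <- data.frame(
    gene_id = "g1",
    type = c("gene", "five_prime_UTR", "CDS", "intron", "CDS",
             "three_prime_UTR", "promoter"),
    scaffold = "s1",
    start = c(3000, 3000, 3200, 3500, 3800, 4200, 1000),
    end = c(4400, 3199, 3499, 3799, 4199, 4400, 2999),
    strand = "+", stringsAsFactors = FALSE)
  mk <- function(pos, scaffold = "s1") data.frame(scaffold = scaffold,
                                                  pos_bp = pos)
  expect_equal(annotate_snp(mk(3300), genes), "CDS")
  expect_equal(annotate_snp(mk(3600), genes), "intron")
  expect_equal(annotate_snp(mk(3100), genes), "UTR")
  expect_equal(annotate_snp(mk(2500), genes), "promoter")
  expect_equal(annotate_snp(mk(500), genes), "intergenic")
  expect_warning(cat_out <- annotate_snp(mk(100, "nowhere"), genes),
                 "absent")
  expect_equal(cat_out, "intergenic")
  # promoter derived from strand when no explicit feature is present
  genes2 <- genes[genes$type != "promoter", ]
  expect_equal(annotate_snp(mk(2500), genes2, promoter_len = 2000), "promoter")
  # categories partition a random marker set
  set.seed(21)
  pos <- sample(1:6000, 300, replace = TRUE)
  cats <- annotate_snp(mk(pos), genes)
  expect_equal(length(cats), 300)
  expect_true(all(cats %in% c("CDS", "UTR", "intron", "promoter",
                              "intergenic")))
})

test_that("Ts/Tv counting matches the published ratio arithmetic", {
  # 40,561 transitions vs 38,293 transversions print as 1.06
  expect_equal(round(40561 / 38293, 2), 1.06)
  m <- data.frame(ref = c("A", "C", "A", "G"), alt = c("G", "T", "C", "T"))
  r <- ts_tv(m)
  expect_equal(r$n_transitions, 2)
  expect_equal(r$n_transversions, 2)
  expect_equal(r$ratio, 1)
  one <- ts_tv(data.frame(ref = "A", alt = "G"))
  expect_true(one$undefined)
  expect_true(is.na(one$ratio))
  expect_warning(skip_bad <- ts_tv(data.frame(ref = c("A", "N"),
                                              alt = c("G", "C"))),
                 "non-ACGT")
  expect_equal(skip_bad$n_transitions, 1)
})

test_that("simulated marker set reproduces its constructed Ts/Tv exactly", {
  z <- small_study(101)
  m <- z$study$gm$markers
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  n_ts <- sum(transition[m$ref] == m$alt)
  r <- ts_tv(m)
  expect_equal(r$n_transitions, n_ts)
  expect_equal(r$n_transversions, nrow(m) - n_ts)
})
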