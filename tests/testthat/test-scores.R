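test_that("signed scores follow the mean-difference construction", {
  m <- matrix(c(2, 0, 1,
                0, 0, 0), 2, 3, byrow = TRUE,
              dimnames = list(NULL, c("p1", "p2", "p3")))
  s <- signed_set("demo", positive = c("p1", "p2"), negative = "p3")
  expect_equal(signed_score(m, s), c((2 + 0) / 2 - 1, 0))
  expect_error(signed_set("bad", character(), character()), "empty")
  expect_error(signed_set("bad", "a", c("a", "b")), "disjoint")
  expect_error(signed_score(m, signed_set("x", positive = "nope")),
               "missing")
})

test_that("signed scores match the loop oracle and are linear", {
  set.seed(70)
  m <- matrix(rexp(100 * 20), 100, 20,
              dimnames = list(NULL, sprintf("f%02d", 1:20)))
  pos <- sample(colnames(m), 7)
  neg <- sample(setdiff(colnames(m), pos), 5)
  s <- signed_set("r", pos, neg)
  got <- signed_score(m, s)
  expect_equal(got, oracle_signed_score(m, pos, neg), tolerance = 1e-12)
  expect_equal(signed_score(3 * m, s), 3 * got, tolerance = 1e-12)
  expect_equal(signed_score(Matrix::Matrix(m, sparse = TRUE), s), got,
               tolerance = 1e-12)
})

test_that("score group test matches exact enumeration on small samples", {
  sc <- c(3.1, 2.7, 4.0, 3.3, 0.2, 1.1, 0.9, 1.4)
  grp <- rep(c(TRUE, FALSE), each = 4)
  got <- score_group_test(sc, grp)
  expect_equal(got$p, oracle_ranksum_p(sc[grp], sc[!grp]), tolerance = 1e-12)
  one <- score_group_test(sc, grp, alternative = "greater")
  expect_lt(one$p, 0.05)
  expect_warning(flat <- score_group_test(rep(1, 8), grp), "constant")
  expect_equal(flat$p, 1)
  expect_error(score_group_test(sc, rep(TRUE, 8)), "non-empty")
})

test_that("marker-derived signed sets honor the threshold directions", {
  mt <- data.frame(
    feature = c("in_a", "low_auc", "in_b", "weak_fc"),
    group = c("A", "A", "B", "B"),
    logFC = c(0.3, 0.4, 0.5, 0.2),
    auc = c(0.65, 0.59, 0.7, 0.7),
    p = 0.001, fdr = c(0.05, 0.01, 0.02, 0.01))
  s <- build_signed_sets_from_markers(mt, fdr_max = 0.1, logfc_min = 0.25,
                                      auc_min = 0.6)
  expect_equal(s$positive, "in_a")   # auc 0.59 misses the strict > 0.6
  expect_equal(s$negative, "in_b")   # logFC 0.2 misses the strict > 0.25
  expect_error(build_signed_sets_from_markers(mt[0, ]), "empty")
})

test_that("class-specific peaks land in the right class only", {
  set.seed(71)
  n <- 240
  cls <- rep(c("A", "B", "C"), each = n / 3)
  m <- matrix(rnorm(n * 6, 1), n, 6,
              dimnames = list(NULL, sprintf("pk%d", 1:6)))
  m[cls == "A", 1] <- m[cls == "A", 1] + 2   # exclusive to A
  sets <- class_specific_peaks(m, cls)
  expect_true("pk1" %in% sets$A)
  expect_false("pk1" %in% c(sets$B, sets$C))
  expect_false("pk2" %in% unlist(sets))      # uniform peak in no set
  none <- class_specific_peaks(m, cls, fdr_max = 0, log2fc_min = Inf)
  expect_equal(sum(lengths(none)), 0L)
})

test_that("motif enrichment matches the exact hypergeometric tail", {
  set.seed(72)
  bg <- sprintf("pk%04d", 1:1000)
  motifs <- Matrix::Matrix(0, 1000, 2, sparse = TRUE,
                           dimnames = list(bg, c("hot", "flat")))
  cls_set <- bg[1:50]
  motifs[1:40, "hot"] <- 1                 # 40/50 in the class set
  motifs[sample(51:1000, 60), "hot"] <- 1  # 60 elsewhere -> 100 in 1000
  motifs[sample(1000, 200), "flat"] <- 1
  res <- motif_enrichment(list(myclass = cls_set), motifs, bg,
                          enrich_min = 5)
  hot <- res[res$motif == "hot", ]
  expect_equal(hot$p, oracle_hyper_upper(hot$k_set, hot$k_bg, 1000, 50),
               tolerance = 1e-12)
  expect_lt(hot$p, 1e-10)
  expect_true(hot$selected)
  flat <- res[res$motif == "flat", ]
  expect_false(flat$selected)
  expect_lt(flat$enrichment, 2)
})

test_that("the display filters require enrichment 5, 95% rule and expression", {
  bg <- sprintf("p%03d", 1:300)
  motifs <- Matrix::Matrix(0, 300, 2, sparse = TRUE,
                           dimnames = list(bg, c("m1", "m2")))
  motifs[1:25, "m1"] <- 1
  motifs[1:18, "m2"] <- 1
  motifs[200:260, "m2"] <- 1
  expr <- matrix(c(0.2, 0.01), 1, 2,
                 dimnames = list("cl", c("m1", "m2")))
  res <- motif_enrichment(list(cl = bg[1:30]), motifs, bg,
                          tf_expression = expr, enrich_min = 5,
                          expr_min = 0.05)
  m1 <- res[res$motif == "m1", ]; m2 <- res[res$motif == "m2", ]
  expect_true(m1$enrichment >= 5 && m1$selected)
  expect_false(m2$selected)   # TF expression below 0.05 blocks display
  expect_equal(max(res$pct_of_max), 100)
})

test_that("SNP overlap applies the strict PIP bound and half-open ends", {
  peaks <- data.frame(peak = "pk1", chrom = "chr1", start = 900L,
                      end = 1100L)
  snps <- data.frame(chrom = "chr1", pos = c(1000L, 1100L, 1000L),
                     id = c("in", "edge", "lowpip"),
                     pip = c(0.5, 0.5, 0.05))
  ov <- snp_peak_overlap(snps, peaks)
  expect_equal(ov$id, "in")
  expect_equal(ov$peak, "pk1")
  none <- snp_peak_overlap(snps[snps$pip < 0.1, ], peaks)
  expect_equal(nrow(none), 0L)
})

test_that("accessibility profiles z-score classes and call z > 1", {
  set.seed(73)
  n <- 240
  cls <- rep(sprintf("k%02d", 1:24), each = 10)
  m <- matrix(rnorm(n * 2, 1, 0.01), n, 2,
              dimnames = list(NULL, c("hotpk", "flatpk")))
  m[cls == "k01", 1] <- 10
  prof <- class_accessibility_profile(m, cls, c("hotpk", "flatpk"))
  expect_true(prof$accessible["hotpk", "k01"])
  expect_equal(sum(prof$accessible["hotpk", ]), 1L)
  expect_equal(mean(prof$z["hotpk", ]), 0, tolerance = 1e-12)
  expect_equal(sd(prof$z["hotpk", ]), 1, tolerance = 1e-12)
  # a constant peak is flagged, not called
  mconst <- cbind(m, constpk = 1)
  prof2 <- class_accessibility_profile(mconst, cls,
                                       c("hotpk", "constpk"))
  expect_true(prof2$flagged_zero_variance["constpk"])
})

test_that("cell-type specificity uses the exact rank test on class z values", {
  # 5 T classes ranked above 19 others: one-sided p = 1 / choose(24, 5)
  set.seed(74)
  cls <- sprintf("k%02d", 1:24)
  m <- matrix(rep(c(5, 5, 5, 5, 5, rep(1, 19)), each = 3) +
                rnorm(72, sd = 1e-3), 72, 1,
              dimnames = list(NULL, "pk"))
  labels <- rep(cls, each = 3)
  types <- setNames(rep(c("T", "other"), c(5, 19)), cls)
  prof <- class_accessibility_profile(m, labels, "pk", class_type = types)
  pT <- prof$type_tests$p[prof$type_tests$cell_type == "T"]
  expect_equal(pT, 1 / choose(24, 5), tolerance = 1e-12)
})

test_that("bedgraph export scales by reads-per-1e7 and is scale invariant", {
  fr <- data.frame(chrom = "chr1",
                   start = c(100L, 150L, 400L),
                   end = c(200L, 250L, 500L),
                   barcode = c("a", "a", "b"))
  region <- list(chrom = "chr1", start = 0L, end = 600L)
  tr <- export_class_bedgraph(fr, list(g1 = "a", g2 = "b"), region)
  # cell a: two overlapping fragments; total reads 2 -> scale 2/1e7
  g1 <- tr$g1
  expect_equal(g1$value[g1$start == 150], 2 / (2 / 1e7))
  expect_equal(g1$value[g1$start == 100], 1 / (2 / 1e7))
  doubled <- export_class_bedgraph(rbind(fr, fr), list(g1 = c("a")),
                                   region)$g1
  expect_equal(doubled$value, g1$value)
  far <- export_class_bedgraph(fr, list(g1 = "a"),
                               list(chrom = "chr9", start = 0L,
                                    end = 100L))$g1
  expect_equal(nrow(far), 0L)
  expect_error(export_class_bedgraph(fr, list(gx = "zz"), region),
               "zero total")
})
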