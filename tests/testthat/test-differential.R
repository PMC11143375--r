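test_that("lineage codes follow the CD4/CD8A open-closed table", {
  m <- Matrix::Matrix(matrix(c(1, 0,   # CD4 open, CD8A closed -> +1
                               0, 1,   # CD8A only -> -1
                               1, 1,   # both -> 0
                               0, 0),  # neither -> 0
                             4, 2, byrow = TRUE,
                             dimnames = list(NULL, c("cd4", "cd8a"))),
                     sparse = TRUE)
  expect_equal(derive_lineage(m, "cd4", "cd8a"), c(1L, -1L, 0L, 0L))
  expect_error(derive_lineage(m, "cd4", "missing"), "missing")
})

test_that("lineage LRT finds a planted association with a CD4-positive beta", {
  set.seed(60)
  n <- 2000
  lin <- sample(c(1, -1, 0), n, replace = TRUE, prob = c(0.45, 0.45, 0.1))
  smp <- sample(c("s1", "s2", "s3"), n, replace = TRUE)
  cls <- sample(c("c1", "c2"), n, replace = TRUE)
  p_open <- plogis(qlogis(0.5) + 0.7 * lin)
  y <- cbind(planted = rbinom(n, 1, p_open),
             null1 = rbinom(n, 1, 0.4), null2 = rbinom(n, 1, 0.2))
  res <- lineage_association(y, lin, cls, smp, rpois(n, 900))
  r <- res[res$feature == "planted", ]
  expect_true(r$significant)
  expect_gt(r$effect, 0)
  expect_equal(r$direction, "CD4")
  expect_false(any(res$significant[res$feature != "planted"] &
                     res$p[res$feature != "planted"] < 1e-4))
})

test_that("uniformly open or closed peaks are excluded before fitting", {
  n <- 200
  y <- cbind(allopen = rep(1, n), ok = rbinom(n, 1, 0.5))
  expect_message(
    res <- lineage_association(y, sample(c(-1, 1), n, TRUE),
                               rep("c1", n), rep(c("s1", "s2"), n / 2),
                               rpois(n, 500)),
    "uniformly")
  expect_false("allopen" %in% res$feature)
})

test_that("null lineage p-values are approximately uniform", {
  set.seed(61)
  n <- 800
  lin <- sample(c(1, -1, 0), n, replace = TRUE)
  y <- matrix(rbinom(n * 200, 1, 0.3), n, 200)
  res <- lineage_association(y, lin, rep("c1", n),
                             rep(c("s1", "s2"), n / 2), rpois(n, 500))
  frac <- mean(res$p < 0.05, na.rm = TRUE)
  expect_gt(frac, 0.02)
  expect_lt(frac, 0.09)
})

test_that("class logistic LRT detects exclusivity and survives confounding", {
  set.seed(62)
  n <- 1200
  cls <- rep(c(TRUE, FALSE), each = n / 2)
  smp <- rep(sprintf("s%d", 1:3), length.out = n)
  y <- cbind(excl = rbinom(n, 1, ifelse(cls, 0.7, 0.05)),
             unif = rbinom(n, 1, 0.4))
  res <- class_logistic_lrt(y, cls, smp, rpois(n, 700))
  expect_gt(res$effect[res$feature == "excl"], 2)
  expect_lt(res$p[res$feature == "excl"], 1e-10)
  expect_gt(res$p[res$feature == "unif"], 0.001)
  # a sample-confounded peak: open only in one sample, class balanced there
  hits <- vapply(1:10, function(s) {
    set.seed(100 + s)
    conf <- rbinom(n, 1, ifelse(smp == "s1", 0.6, 0.05))
    r <- class_logistic_lrt(cbind(conf = conf), cls, smp, rpois(n, 700))
    r$p[1] > 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("random-intercept sample effect agrees with the fixed default", {
  skip_if_not_installed("lme4")
  set.seed(63)
  n <- 600
  lin <- sample(c(1, -1), n, replace = TRUE)
  smp <- rep(c("s1", "s2", "s3"), each = n / 3)
  y <- cbind(pk = rbinom(n, 1, plogis(-0.5 + 0.8 * lin +
                                        0.3 * (smp == "s2"))))
  f <- lineage_association(y, lin, rep("c", n), smp, rpois(n, 500),
                           sample_effect = "fixed")
  r <- suppressMessages(
    lineage_association(y, lin, rep("c", n), smp, rpois(n, 500),
                        sample_effect = "random"))
  expect_equal(f$effect, r$effect, tolerance = 0.05)
  expect_lt(abs(log10(f$p) - log10(r$p)), 1)
})

test_that("pseudobulk sums and masks follow the 150/130/10 rules", {
  counts <- Matrix::Matrix(matrix(1:12, 6, 2,
                                  dimnames = list(sprintf("c%d", 1:6),
                                                  c("p1", "p2"))),
                           sparse = TRUE)
  smp <- c("a", "a", "a", "b", "b", "b")
  st <- c("x", "x", "y", "x", "y", "y")
  pb <- pseudobulk_counts(counts, smp, st, min_sample_cells = 2L,
                          min_state_cells = 2L, min_combo_cells = 1L)
  expect_equal(pb$counts["a.x", "p1"], 1 + 2)
  expect_equal(pb$counts["b.y", "p2"], 11 + 12)
  expect_equal(sum(pb$counts), sum(counts))
  # strict boundary: a combination with exactly the threshold count is masked
  pb2 <- pseudobulk_counts(counts, smp, st, min_sample_cells = 3L,
                           min_state_cells = 3L, min_combo_cells = 2L)
  expect_false(pb2$included[pb2$sample == "a" & pb2$state == "y"])
  pb3 <- pseudobulk_counts(counts, smp, st, min_sample_cells = 150L,
                           min_state_cells = 130L, min_combo_cells = 10L)
  expect_true(all(!pb3$included))
})

test_that("NB LRT excludes sparse peaks and reports the state effect", {
  sim <- simulate_pseudobulk(n_peaks = 60, planted = 1:5, fc = 4, seed = 9)
  sim$counts[, 60] <- c(rep(0, 8), c(1, 1, 1, 1))  # 4 reads in total
  res <- nb_lrt_differential(as_pb(sim))
  expect_false("peak00060" %in% res$feature)
  planted <- res[res$feature %in% sprintf("peak%05d", 1:5), ]
  expect_true(all(planted$effect > 0.7))
  expect_true(mean(planted$differential) >= 0.8)
})

test_that("NB LRT is invariant to relabeling the reference category", {
  sim <- simulate_pseudobulk(n_peaks = 30, planted = 1:3, fc = 3, seed = 10)
  pb1 <- as_pb(sim)
  pb2 <- as_pb(sim)
  pb2$state <- ifelse(pb2$state == "T1", "zz", "aa")  # swap factor order
  r1 <- nb_lrt_differential(pb1)
  r2 <- nb_lrt_differential(pb2)
  expect_equal(r1$lrt_stat, r2$lrt_stat, tolerance = 1e-6)
  expect_equal(abs(r1$effect), abs(r2$effect), tolerance = 1e-6)
})

test_that("NB LRT recovers planted log fold changes with small bias", {
  sims <- lapply(1:5, function(s)
    simulate_pseudobulk(n_peaks = 40, n_samples = 6, planted = 1:20,
                        fc = 4, seed = 200 + s))
  est <- unlist(lapply(sims, function(sim) {
    r <- nb_lrt_differential(as_pb(sim))
    r$effect[match(sprintf("peak%05d", 1:20), r$feature)]
  }))
  expect_lt(abs(mean(est, na.rm = TRUE) - log(4)) / log(4), 0.1)
})

test_that("rank-sum markers match exact enumeration and the AUC identity", {
  x <- c(1.2, 3.4, 0.5, 2.2, 5.1)
  y <- c(0.1, 0.3, 2.0, 0.7, 0.2)
  mat <- matrix(c(x, y), ncol = 1, dimnames = list(NULL, "f"))
  res <- wilcoxon_markers(mat, rep(c("A", "B"), each = 5))
  ra <- res[res$group == "A", ]
  wt <- wilcox.test(x, y)
  expect_equal(ra$p, wt$p.value, tolerance = 1e-12)
  expect_equal(ra$p, oracle_ranksum_p(x, y), tolerance = 1e-12)
  expect_equal(ra$auc, unname(wt$statistic) / 25, tolerance = 1e-12)
  # AUC equals the probability a random A value exceeds a random B value
  mc <- mean(outer(x, y, ">") + 0.5 * outer(x, y, "=="))
  expect_equal(ra$auc, mc, tolerance = 1e-12)
})

test_that("marker extremes: clean separation and identical groups", {
  g <- rep(c("A", "B"), each = 20)
  sep <- matrix(c(rnorm(20, 10), rnorm(20, 0)), ncol = 1,
                dimnames = list(NULL, "sep"))
  res <- wilcoxon_markers(sep, g)
  expect_equal(res$auc[res$group == "A"], 1)
  expect_lt(res$p[res$group == "A"], 1e-6)
  same <- matrix(rep(seq_len(20), 2), ncol = 1,
                 dimnames = list(NULL, "same"))
  res2 <- wilcoxon_markers(same, g)
  expect_equal(res2$auc[res2$group == "A"], 0.5)
})

test_that("concordance picks the strongest promoter peak and filters detection", {
  set.seed(64)
  n <- 120
  gene_mat <- Matrix::Matrix(matrix(rpois(n * 2, 2), n, 2,
                                    dimnames = list(NULL, c("g1", "g2"))),
                             sparse = TRUE)
  gene_mat[1:75, 2] <- 0   # g2 detected in at most 45 cells (<= 50 rule)
  peak_mat <- Matrix::Matrix(
    matrix(rpois(n * 3, c(1, 3, 2)), n, 3, byrow = TRUE,
           dimnames = list(NULL, c("pk_lo", "pk_hi", "pk_other"))),
    sparse = TRUE)
  map <- data.frame(peak = c("pk_lo", "pk_hi", "pk_other"),
                    gene = c("g1", "g1", "g2"))
  gene_de <- data.frame(feature = c("g1", "g2"), p = c(0.001, 0.5),
                        logFC = c(1, -0.2))
  peak_de <- data.frame(feature = c("pk_lo", "pk_hi", "pk_other"),
                        p = c(0.9, 0.2, 0.4), logFC = c(0.1, 0.3, -0.1))
  res <- promoter_gene_concordance(gene_de, peak_de, map, gene_mat, peak_mat)
  expect_equal(res$peak[res$gene == "g1"], "pk_hi")
  expect_false("g2" %in% res$gene)
  expect_true(res$direction_agree[res$gene == "g1"])
})
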