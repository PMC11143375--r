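test_that("within-cell duplicates collapse, cross-cell collisions survive", {
  reads <- data.table::data.table(
    chrom = "chr1",
    start = c(100L, 100L, 100L, 250L),
    mate_start = c(300L, 300L, 300L, 500L),
    cigar = "50M", mapq = 60L,
    barcode = c("A", "A", "B", "B"))
  out <- deduplicate_reads(reads)
  expect_equal(nrow(out), 3L)
  expect_equal(sort(out$barcode), c("A", "B", "B"))
  # dup pair in cell A plus one read in cell B at another locus
  expect_equal(attr(out, "drop_counts")[["duplicate"]], 1L)
})

test_that("dedup drops low-MAPQ, barcode-less and blacklisted records", {
  reads <- data.table::data.table(
    chrom = "chr1", start = c(10L, 20L, 30L, 40L),
    mate_start = 1000L, cigar = "50M",
    mapq = c(60L, 59L, 60L, 60L),
    barcode = c("A", "A", "", "A"))
  bl <- data.frame(chrom = "chr1", start = 35L, end = 45L)
  out <- deduplicate_reads(reads, blacklist = bl)
  expect_equal(out$start, 10L)
  dc <- attr(out, "drop_counts")
  expect_equal(dc[["mapq"]], 1L)
  expect_equal(dc[["no_barcode"]], 1L)
  expect_equal(dc[["blacklist"]], 1L)
})

test_that("dedup falls back to start-only keys without mate info", {
  reads <- data.table::data.table(chrom = "chr1",
                                  start = c(5L, 5L, 9L),
                                  barcode = "A")
  out <- deduplicate_reads(reads)
  expect_equal(sort(out$start), c(5L, 9L))
})

test_that("dedup is idempotent and never grows a barcode's records", {
  ds <- tiny_dataset()
  fr <- generate_fragments(ds$peak_counts[1:40, ], ds$peak_annot, seed = 2L)
  rd <- generate_reads(fr, dup_rate = 0.4, seed = 2L)
  d1 <- deduplicate_reads(rd)
  d2 <- deduplicate_reads(d1)
  expect_equal(nrow(d1), nrow(d2))
  per_bc_in <- table(rd$barcode)
  per_bc_out <- table(d1$barcode)
  expect_true(all(per_bc_out <= per_bc_in[names(per_bc_out)]))
})

test_that("summit trimming yields 200-bp peaks and greedy q de-overlap", {
  one <- trim_and_deduplicate_peaks(
    data.frame(chrom = "chr1", summit = 1000L, q = 1e-10))
  expect_equal(c(one$start, one$end), c(900L, 1100L))
  two <- trim_and_deduplicate_peaks(
    data.frame(chrom = "chr1", summit = c(1000L, 1100L), q = c(1e-10, 1e-5)))
  expect_equal(nrow(two), 1L)
  expect_equal(two$start, 900L)
  # chained overlaps: middle candidate has the best q and blocks both sides
  three <- trim_and_deduplicate_peaks(
    data.frame(chrom = "chr1", summit = c(100L, 180L, 260L),
               q = c(1e-8, 1e-9, 1e-7)))
  expect_equal(nrow(three), 1L)
  expect_equal(c(three$start, three$end), c(80L, 280L))
})

test_that("summits near the contig start clip to [0, 200) with a warning", {
  expect_warning(out <- trim_and_deduplicate_peaks(
    data.frame(chrom = "chr1", summit = 40L, q = 0.5)), "clip")
  expect_equal(c(out$start, out$end), c(0L, 200L))
  expect_true(out$clipped)
})

test_that("peak consolidation matches the brute-force oracle and is idempotent", {
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(5:50, 1)
    sp <- data.frame(chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
                     summit = sample(150:3000, n),
                     q = 10^runif(n, -12, -1))
    got <- trim_and_deduplicate_peaks(sp)
    ora <- oracle_trim_dedup(sp)
    expect_equal(got$start, ora$start)
    expect_equal(got$chrom, ora$chrom)
    expect_true(all(got$end - got$start == 200L))
    again <- trim_and_deduplicate_peaks(got)
    expect_equal(again$start, got$start)
  }
})

test_that("fragment counting honors half-open overlap and matches brute force", {
  peaks <- data.frame(chrom = "chr1", start = 900L, end = 1100L)
  inside <- data.frame(chrom = "chr1", start = 950L, end = 1050L,
                       barcode = "A")
  expect_equal(as.vector(count_fragments_in_peaks(inside, peaks)), 1)
  touching <- data.frame(chrom = "chr1", start = 1100L, end = 1200L,
                         barcode = "A")
  expect_equal(as.vector(count_fragments_in_peaks(touching, peaks)), 0)
  set.seed(21)
  n <- 400
  fr <- data.frame(chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
                   start = sample(1:5000, n, replace = TRUE),
                   barcode = sample(c("A", "B", "C"), n, replace = TRUE))
  fr$end <- fr$start + sample(50:300, n, replace = TRUE)
  pk <- data.frame(chrom = rep(c("chr1", "chr2"), each = 10),
                   start = rep(seq(100, 4600, by = 500), 2))
  pk$end <- pk$start + 200L
  got <- as.matrix(count_fragments_in_peaks(fr, pk,
                                            barcodes = c("A", "B", "C")))
  ora <- oracle_count_overlaps(fr, pk, c("A", "B", "C"))
  expect_equal(unname(got), unname(ora))
})

test_that("ATAC cell QC applies the literal boundary semantics", {
  th <- qc_thresholds()
  stats <- data.frame(
    reads = c(15000, 9000, 10000, 15000, 15000),
    reads_in_neighborhood = c(9000, 8500, 9000, 7000, 9000),
    reads_in_promoter = c(1800, 1500, 1500, 1800, 1800),
    reads_mito = c(750, 100, 100, 100, 1501),
    reads_blacklist = c(300, 10, 10, 10, 10))
  mask <- atac_cell_qc(stats, th)
  expect_true(mask[1])     # all thresholds met
  expect_false(mask[2])    # too few reads
  expect_false(mask[3])    # exactly 10,000 reads fails the strict bound
  expect_false(mask[4])    # neighborhood fraction below one half
  expect_false(mask[5])    # mitochondrial fraction above one tenth
  expect_error(atac_cell_qc(transform(stats, reads_mito = -1), th),
               "negative")
})

test_that("RNA cell QC needs 500 genes and under 20% mitochondrial reads", {
  stats <- data.frame(genes_detected = c(600, 499, 600, 500),
                      frac_mito = c(0.10, 0.00, 0.20, 0.199))
  expect_equal(rna_cell_qc(stats), c(TRUE, FALSE, FALSE, TRUE))
})

test_that("PMA selection keeps peaks at the 0.5% rule or min_cells override", {
  m <- Matrix::sparseMatrix(i = c(1:5, 1:4, 1:40),
                            j = c(rep(1, 5), rep(2, 4), rep(3, 40)),
                            x = 1, dims = c(1000, 3))
  expect_equal(select_pma_peaks(m), c(TRUE, FALSE, TRUE))
  expect_equal(select_pma_peaks(m, min_cells = 50), c(FALSE, FALSE, FALSE))
  expect_error(select_pma_peaks(m[0, , drop = FALSE]), "empty")
})

test_that("Tn5 shift applies the +4/-5 correction", {
  out <- tn5_shift(c(100L, 200L), c(150L, 260L))
  expect_equal(out$start, c(104L, 204L))
  expect_equal(out$end, c(145L, 255L))
})
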