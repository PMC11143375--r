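#' Log-normalize expression counts
#'
#' `log1p(1e4 * x_ij / rowSum_i)` — library-size normalization to 10,000
#' counts followed by log1p.
#'
#' @param counts cell x gene count matrix.
#' @param scale_factor target library size (default 1e4).
#' @return sparse normalized matrix.
#' @export
lognormalize_counts <- function(counts, scale_factor = 1e4) {
  x <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  rs <- Matrix::rowSums(x)
  out <- Matrix::Diagonal(x = ifelse(rs > 0, scale_factor / rs, 0)) %*% x
  out@x <- log1p(out@x)
  out <- methods::as(out, "CsparseMatrix")
  dimnames(out) <- dimnames(x)
  out
}

#' Run the full demonstration pipeline on synthetic data
#'
#' Chains every stage — simulate, read dedup, peak consolidation, fragment
#' counting, cell QC, chromatin clustering, cross-modal label transfer, the
#' class x state odds-ratio matrix, pairwise LDA AUC, lineage and pseudobulk
#' differential tests, signed scores, motif enrichment and SNP overlap —
#' writing per-stage TSV artifacts whose headers carry the seed, thresholds
#' and config hash. Identical configs yield byte-identical result tables.
#'
#' @param config a [synth_config()]; the demo default is a small
#'   reads-enabled dataset.
#' @param outdir output directory (created if needed).
#' @param qc optional [qc_thresholds()]; the default scales the read floor
#'   to the synthetic depth so that QC is exercised without emptying the
#'   demo dataset.
#' @return invisible list with the per-stage objects and file paths.
#' @export
run_pipeline <- function(config = synth_config(cells_per_sample = 250L,
                                               n_peaks = 600L,
                                               n_genes = 400L,
                                               with_reads = TRUE),
                         outdir = tempfile("superstate_run_"),
                         qc = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(outdir, "pipeline.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "",
                            file = log_path, append = TRUE)
  cat("", file = log_path)
  hash <- config_hash(config)
  meta <- list(seed = config$seed, config_hash = hash,
               qc_min_reads = NA, pma_frac = 0.005, knn_k = 5,
               knn_conf_votes = 3, fdr_or = 0.05, fdr_nb = 0.10,
               fdr_lineage = 0.20)
  write_run_config(config, file.path(outdir, "config.json"))

  logf("stage simulate: seed=%d", config$seed)
  ds <- generate_multiome(config)
  if (is.null(ds$fragments))
    stop("run_pipeline needs `with_reads = TRUE` in the config")

  logf("stage dedup: %d reads", nrow(ds$reads))
  dedup <- deduplicate_reads(ds$reads)

  logf("stage peaks: %d sub-peaks", nrow(ds$sub_peaks))
  peaks <- trim_and_deduplicate_peaks(ds$sub_peaks)
  write_bed(peaks, file.path(outdir, "peaks.bed"))

  logf("stage count")
  counts <- count_fragments_in_peaks(ds$fragments, peaks,
                                     barcodes = ds$cells$barcode)
  colnames(counts) <- peak_ids_by_position(peaks, ds$peak_annot)

  logf("stage qc")
  if (is.null(qc)) {
    qc <- qc_thresholds(
      min_reads = floor(quantile(ds$cells$n_fragments, 0.02)),
      rna_min_genes = floor(quantile(Matrix::rowSums(ds$gene_counts > 0),
                                     0.02)))
  }
  meta$qc_min_reads <- qc$min_reads
  prom_cols <- intersect(ds$peak_annot$peak[ds$peak_annot$is_promoter],
                         colnames(counts))
  stats <- data.frame(
    reads = Matrix::rowSums(counts),
    reads_in_neighborhood = Matrix::rowSums(counts),
    reads_in_promoter = Matrix::rowSums(counts[, prom_cols, drop = FALSE]),
    reads_mito = 0, reads_blacklist = 0)
  pass <- atac_cell_qc(stats, qc) &
    rna_cell_qc(data.frame(genes_detected =
                             Matrix::rowSums(ds$gene_counts > 0),
                           frac_mito = 0), qc)
  logf("qc: %d/%d cells pass", sum(pass), length(pass))
  cells <- ds$cells[pass, ]
  counts <- counts[pass, , drop = FALSE]
  genes <- ds$gene_counts[pass, , drop = FALSE]

  logf("stage cluster")
  clus <- cluster_chromatin(counts, cells$sample,
                            n_components = min(10L, ncol(counts) - 1L),
                            n_features = min(500L, ncol(counts)),
                            seed = config$seed)
  cells$chromatin_class <- sprintf("CC%d", clus$labels$label)
  write_results_tsv(cells, file.path(outdir, "cells.tsv"), meta)

  logf("stage transfer")
  rna <- lognormalize_counts(genes)
  rna_emb <- compute_embedding(
    rna[, select_variable_features(rna, min(300L, ncol(rna))), drop = FALSE],
    n_components = min(10L, ncol(rna) - 1L), seed = config$seed)
  half <- with_seed(config$seed, "transfer_split",
                    sample(c(TRUE, FALSE), nrow(cells), replace = TRUE))
  transfer <- knn_classify(rna_emb$coordinates[half, , drop = FALSE],
                           cells$state[half],
                           rna_emb$coordinates[!half, , drop = FALSE],
                           k = 5L)
  logf("transfer: %.1f%% high confidence",
       100 * mean(transfer$high_confidence))

  logf("stage superstate")
  or_tab <- class_state_or_matrix(cells$chromatin_class, cells$state)
  write_results_tsv(or_tab, file.path(outdir, "or_matrix.tsv"), meta)
  state_class <- vapply(split(cells$class, cells$state),
                        function(x) names(sort(table(x),
                                               decreasing = TRUE))[1], "")
  auc <- pairwise_lda_auc(clus$embedding, cells$state, cells$sample,
                          cells$n_fragments, seed = config$seed,
                          state_class = state_class)
  write_results_tsv(auc$pairs, file.path(outdir, "auc_pairs.tsv"), meta)

  logf("stage differential")
  bin <- binarize_counts(counts)
  prom_use <- intersect(prom_cols, colnames(bin))
  lineage <- derive_lineage(
    bin, ds$peak_annot$peak[which(ds$peak_annot$role == "CD4")],
    ds$peak_annot$peak[which(ds$peak_annot$role == "CD8A")])
  lin_res <- lineage_association(bin[, prom_use, drop = FALSE], lineage,
                                 cells$chromatin_class, cells$sample,
                                 cells$n_fragments)
  write_results_tsv(lin_res, file.path(outdir, "lineage.tsv"), meta)
  pbk <- pseudobulk_counts(counts, cells$sample, cells$state,
                           min_sample_cells = 20L, min_state_cells = 20L,
                           min_combo_cells = 3L)
  nb <- tryCatch(nb_lrt_differential(pbk),
                 error = function(e) { logf("pseudobulk skipped: %s",
                                            conditionMessage(e)); NULL })
  if (!is.null(nb))
    write_results_tsv(nb, file.path(outdir, "pseudobulk_differential.tsv"),
                      meta)
  markers <- wilcoxon_markers(rna, cells$state)
  write_results_tsv(markers, file.path(outdir, "gene_markers.tsv"), meta)

  logf("stage scores/enrich/variants")
  acc_norm <- tfidf_normalize(bin[, Matrix::colSums(bin) > 0, drop = FALSE])
  dmr <- ds$signed_sets$dmr_like
  dmr_use <- signed_set(dmr$name,
                        intersect(dmr$positive, colnames(acc_norm)),
                        intersect(dmr$negative, colnames(acc_norm)))
  scores <- signed_score(acc_norm, dmr_use)
  target <- attr(ds$signed_sets$dmr_like, "target_class")
  stest <- score_group_test(scores, cells$class == target, "greater")
  logf("dmr-like score test p=%.3g", stest$p)
  css <- class_specific_peaks(acc_norm, cells$chromatin_class)
  enr <- motif_enrichment(css, ds$motif_annot, colnames(acc_norm))
  write_results_tsv(enr, file.path(outdir, "motif_enrichment.tsv"), meta)
  snp_ov <- snp_peak_overlap(ds$snps, ds$peak_annot)
  write_results_tsv(snp_ov, file.path(outdir, "snp_overlap.tsv"), meta)
  region <- list(chrom = ds$peak_annot$chrom[1],
                 start = ds$peak_annot$start[1] - 200L,
                 end = ds$peak_annot$end[1] + 200L)
  tracks <- export_class_bedgraph(ds$fragments,
                                  split(cells$barcode,
                                        cells$chromatin_class),
                                  region)
  for (nm in names(tracks))
    write_bedgraph(tracks[[nm]],
                   file.path(outdir, sprintf("track_%s.bedgraph", nm)))
  logf("done")
  invisible(list(outdir = outdir, dataset = ds, cells = cells,
                 peaks = peaks, clusters = clus, transfer = transfer,
                 or_table = or_tab, auc = auc, lineage = lin_res,
                 pseudobulk = nb, markers = markers, scores = scores,
                 score_test = stest, motif_enrichment = enr,
                 snp_overlap = snp_ov))
}

# match consolidated peaks back to the generator's peak ids by coordinates
peak_ids_by_position <- function(peaks, peak_annot) {
  key <- paste(peaks$chrom, peaks$start)
  truth <- paste(peak_annot$chrom, peak_annot$start)
  ids <- peak_annot$peak[match(key, truth)]
  miss <- is.na(ids)
  ids[miss] <- sprintf("%s:%d-%d", peaks$chrom[miss], peaks$start[miss],
                       peaks$end[miss])
  ids
}
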