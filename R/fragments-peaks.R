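#' Cell-aware read deduplication
#'
#' Removes likely PCR duplicates within a cell while keeping reads from the
#' same positions in different cells. When mate information is available the
#' duplicate key is (start, mate_start, cigar); otherwise the start position
#' alone is used. Records with low mapping quality, a missing barcode, or
#' overlapping a blacklist are dropped.
#'
#' @param reads table with `chrom`, `start`, `barcode`, optionally
#'   `mate_start`, `cigar`, `mapq`.
#' @param blacklist optional data.frame of intervals (`chrom`, `start`,
#'   `end`, 0-based half-open) to exclude.
#' @param mapq_min minimum mapping quality retained (default 60).
#' @return `data.table` of retained records; attribute `"drop_counts"`
#'   reports how many records each filter removed.
#' @export
deduplicate_reads <- function(reads, blacklist = NULL, mapq_min = 60L) {
  rd <- data.table::as.data.table(reads)
  drops <- c(mapq = 0L, no_barcode = 0L, blacklist = 0L, duplicate = 0L,
             bad_key = 0L)
  if ("mapq" %in% names(rd)) {
    keep <- rd$mapq >= mapq_min
    drops["mapq"] <- sum(!keep)
    rd <- rd[keep]
  }
  keep <- !is.na(rd$barcode) & nzchar(rd$barcode)
  drops["no_barcode"] <- sum(!keep)
  rd <- rd[keep]
  if (!is.null(blacklist) && nrow(rd)) {
    gr <- GenomicRanges::GRanges(rd$chrom,
                                 IRanges::IRanges(rd$start + 1L, rd$start + 1L))
    bl <- GenomicRanges::GRanges(blacklist$chrom,
                                 IRanges::IRanges(blacklist$start + 1L,
                                                  blacklist$end))
    hit <- IRanges::overlapsAny(gr, bl)
    drops["blacklist"] <- sum(hit)
    rd <- rd[!hit]
  }
  paired <- all(c("mate_start", "cigar") %in% names(rd))
  if (paired) {
    bad <- is.na(rd$mate_start) | is.na(rd$cigar)
    if (any(bad)) {
      drops["bad_key"] <- sum(bad)
      warning(sum(bad), " paired records missing mate key fields; dropped")
      rd <- rd[!bad]
    }
    key <- c("barcode", "chrom", "start", "mate_start", "cigar")
  } else {
    key <- c("barcode", "chrom", "start")
  }
  n0 <- nrow(rd)
  rd <- unique(rd, by = key)
  drops["duplicate"] <- n0 - nrow(rd)
  data.table::setattr(rd, "drop_counts", drops)
  rd[]
}

#' Trim sub-peaks to 200 bp and remove overlaps greedily by q-value
#'
#' Each sub-peak becomes summit +/- 100 bp; candidates are then visited in
#' ascending q order (ties broken by chrom, start) and kept only if they do
#' not overlap an already-kept peak, yielding a sorted, pairwise
#' non-overlapping, fixed-width peak set.
#'
#' @param sub_peaks data.frame with `chrom`, `summit`, `q` (and optionally
#'   `start`, `end` bounding the summit).
#' @return data.frame of peaks (`chrom`, `start`, `end`, `summit`, `q`,
#'   `clipped`) sorted by coordinate; every width is 200.
#' @export
trim_and_deduplicate_peaks <- function(sub_peaks) {
  sp <- as.data.frame(sub_peaks)
  if (!nrow(sp))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), summit = integer(), q = numeric(),
                      clipped = logical()))
  if (any(sp$q <= 0 | sp$q > 1)) stop("q-values must lie in (0, 1]")
  if (all(c("start", "end") %in% names(sp)) &&
      any(sp$summit < sp$start | sp$summit >= sp$end))
    stop("summits must satisfy start <= summit < end")
  start <- sp$summit - 100L
  clipped <- start < 0L
  if (any(clipped)) {
    warning(sum(clipped), " summit(s) within 100 bp of the contig start; ",
            "clipped to [0, 200)")
    start[clipped] <- 0L
  }
  cand <- data.frame(chrom = sp$chrom, start = as.integer(start),
                     end = as.integer(start + 200L),
                     summit = as.integer(sp$summit), q = sp$q,
                     clipped = clipped, stringsAsFactors = FALSE)
  cand <- cand[order(cand$q, cand$chrom, cand$start), ]
  keep <- logical(nrow(cand))
  kept_starts <- split(numeric(0), character(0))
  for (i in seq_len(nrow(cand))) {
    ch <- cand$chrom[i]
    ks <- kept_starts[[ch]]
    s <- cand$start[i]
    # all peaks are width 200: overlap iff some kept start is within 199 bp
    if (is.null(ks) || !length(ks) || min(abs(ks - s)) >= 200) {
      keep[i] <- TRUE
      kept_starts[[ch]] <- c(ks, s)
    }
  }
  out <- cand[keep, ]
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}

#' Count fragments in peaks
#'
#' Overlap is any shared base pair under 0-based half-open coordinates
#' (as in `GenomicRanges::findOverlaps`, which performs the join).
#'
#' @param fragments table with `chrom`, `start`, `end`, `barcode`.
#' @param peaks peak table with `chrom`, `start`, `end` (and optionally
#'   `peak` ids).
#' @param barcodes optional character vector fixing the row universe/order;
#'   defaults to the barcodes observed.
#' @return sparse cell x peak count matrix.
#' @export
count_fragments_in_peaks <- function(fragments, peaks, barcodes = NULL) {
  fr <- as.data.frame(fragments)
  pk <- as.data.frame(peaks)
  if (is.null(barcodes)) barcodes <- sort(unique(fr$barcode))
  miss <- setdiff(unique(fr$chrom), unique(pk$chrom))
  if (length(miss))
    message("chromosomes with fragments but no peaks (counted as zero): ",
            paste(miss, collapse = ", "))
  frg <- GenomicRanges::GRanges(fr$chrom,
                                IRanges::IRanges(fr$start + 1L, fr$end))
  pkg <- GenomicRanges::GRanges(pk$chrom,
                                IRanges::IRanges(pk$start + 1L, pk$end))
  ov <- GenomicRanges::findOverlaps(frg, pkg)
  i <- match(fr$barcode[S4Vectors::queryHits(ov)], barcodes)
  j <- S4Vectors::subjectHits(ov)
  ok <- !is.na(i)
  pk_ids <- if ("peak" %in% names(pk)) pk$peak else
    sprintf("%s:%d-%d", pk$chrom, pk$start, pk$end)
  Matrix::sparseMatrix(i = i[ok], j = j[ok], x = 1,
                       dims = c(length(barcodes), nrow(pk)),
                       dimnames = list(barcodes, pk_ids))
}

#' Default quality-control thresholds
#'
#' ATAC cells must have more than `min_reads` reads, at least half of them in
#' peak neighborhoods (peaks widened `neighborhood_scale`-fold), at least 10%
#' in promoters, and not more than 10% mitochondrial or blacklisted. RNA
#' cells need at least 500 detected genes and under 20% mitochondrial reads.
#'
#' @param min_reads,min_frac_in_peak_neighborhood,neighborhood_scale,min_frac_promoter,max_frac_mito,max_frac_blacklist,rna_min_genes,rna_max_frac_mito
#'   thresholds; defaults follow the pipeline's standard settings.
#' @return list of class `"qc_thresholds"`.
#' @export
qc_thresholds <- function(min_reads = 10000L,
                          min_frac_in_peak_neighborhood = 0.5,
                          neighborhood_scale = 5L,
                          min_frac_promoter = 0.10,
                          max_frac_mito = 0.10,
                          max_frac_blacklist = 0.10,
                          rna_min_genes = 500L,
                          rna_max_frac_mito = 0.20) {
  th <- list(min_reads = min_reads,
             min_frac_in_peak_neighborhood = min_frac_in_peak_neighborhood,
             neighborhood_scale = neighborhood_scale,
             min_frac_promoter = min_frac_promoter,
             max_frac_mito = max_frac_mito,
             max_frac_blacklist = max_frac_blacklist,
             rna_min_genes = rna_min_genes,
             rna_max_frac_mito = rna_max_frac_mito)
  for (f in grep("frac", names(th), value = TRUE))
    stopifnot_fraction(th[[f]], f)
  structure(th, class = "qc_thresholds")
}

#' ATAC per-cell quality control
#'
#' Pass requires strictly more than `min_reads` reads, at least 50% of reads
#' in peak neighborhoods, at least 10% in promoters, and not more than 10%
#' mitochondrial / blacklisted reads (boundary semantics read literally:
#' "more than" strict, "at least"/"not more than" inclusive).
#'
#' @param cell_stats data.frame with `reads`, `reads_in_neighborhood`,
#'   `reads_in_promoter`, `reads_mito`, `reads_blacklist` (blacklist counts
#'   are pre-deduplication).
#' @param thresholds a [qc_thresholds()].
#' @return logical pass mask, one entry per row of `cell_stats`.
#' @export
atac_cell_qc <- function(cell_stats, thresholds = qc_thresholds()) {
  cs <- as.data.frame(cell_stats)
  need <- c("reads", "reads_in_neighborhood", "reads_in_promoter",
            "reads_mito", "reads_blacklist")
  if (!all(need %in% names(cs)))
    stop("cell_stats must contain: ", paste(need, collapse = ", "))
  if (any(as.matrix(cs[need]) < 0)) stop("negative counts in cell_stats")
  th <- thresholds
  cs$reads > th$min_reads &
    cs$reads_in_neighborhood / cs$reads >= th$min_frac_in_peak_neighborhood &
    cs$reads_in_promoter / cs$reads >= th$min_frac_promoter &
    cs$reads_mito / cs$reads <= th$max_frac_mito &
    cs$reads_blacklist / cs$reads <= th$max_frac_blacklist
}

#' RNA per-cell quality control
#'
#' Pass requires at least `rna_min_genes` detected genes and strictly less
#' than `rna_max_frac_mito` mitochondrial reads.
#'
#' @param cell_stats data.frame with `genes_detected` and `frac_mito`, or a
#'   cell x gene count matrix (then `mito_genes` names the mitochondrial
#'   columns).
#' @param thresholds a [qc_thresholds()].
#' @param mito_genes character vector of mitochondrial gene names (matrix
#'   input only).
#' @return logical pass mask.
#' @export
rna_cell_qc <- function(cell_stats, thresholds = qc_thresholds(),
                        mito_genes = NULL) {
  if (is.matrix(cell_stats) || inherits(cell_stats, "Matrix")) {
    m <- cell_stats
    mito <- if (is.null(mito_genes)) grep("^MT-", colnames(m), value = TRUE)
            else intersect(mito_genes, colnames(m))
    tot <- Matrix::rowSums(m)
    cell_stats <- data.frame(
      genes_detected = Matrix::rowSums(m > 0),
      frac_mito = if (length(mito))
        Matrix::rowSums(m[, mito, drop = FALSE]) / pmax(tot, 1) else 0)
  }
  cs <- as.data.frame(cell_stats)
  cs$genes_detected >= thresholds$rna_min_genes &
    cs$frac_mito < thresholds$rna_max_frac_mito
}

#' Select peaks with minimal accessibility (PMA)
#'
#' Keeps peaks with a fragment in at least `frac` of the cell type's cells;
#' `min_cells`, when given, overrides the fractional rule (used for rare
#' cell types).
#'
#' @param counts cell x peak count matrix restricted to one cell type.
#' @param frac minimum fraction of cells with a fragment (default 0.005).
#' @param min_cells optional absolute minimum overriding `frac`.
#' @return logical mask over peaks.
#' @export
select_pma_peaks <- function(counts, frac = 0.005, min_cells = NULL) {
  if (nrow(counts) == 0 || ncol(counts) == 0) stop("empty count matrix")
  n_with <- Matrix::colSums(counts > 0)
  thr <- if (!is.null(min_cells)) min_cells else ceiling(frac * nrow(counts))
  as.vector(n_with >= thr)
}

#' Tn5 insertion-site correction for raw read starts
#'
#' Shifts plus-strand starts by +4 and minus-strand ends by -5 to center on
#' the Tn5 insertion within its 9-bp binding site. The offsets are
#' configurable; fragment inputs elsewhere in the package are assumed to be
#' already corrected.
#'
#' @param start,end 0-based half-open fragment coordinates.
#' @param plus_shift,minus_shift offsets applied to `start` and `end`.
#' @return list with corrected `start` and `end`.
#' @export
tn5_shift <- function(start, end, plus_shift = 4L, minus_shift = -5L) {
  list(start = start + plus_shift, end = end + minus_shift)
}
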