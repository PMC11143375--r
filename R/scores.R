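#' Construct a signed feature set
#'
#' @param name set name.
#' @param positive,negative disjoint feature-id vectors (e.g. CD4-associated
#'   vs CD8A-associated peaks, hypermethylated vs hypomethylated loci,
#'   lining vs sublining genes); at most one may be empty.
#' @return list of class `"signed_set"`.
#' @export
signed_set <- function(name, positive = character(), negative = character()) {
  if (length(intersect(positive, negative)))
    stop("positive and negative sets must be disjoint")
  if (!length(positive) && !length(negative))
    stop("both sets empty")
  structure(list(name = name, positive = positive, negative = negative),
            class = "signed_set")
}

#' Signed per-cell score
#'
#' `score_i = mean_j in positive x_ij - mean_j in negative x_ij`: the mean
#' normalized value over the positive set minus the mean over the negative
#' set, so a positive score marks association with the positive set.
#'
#' @param norm_mat normalized cell x feature matrix.
#' @param set a [signed_set()].
#' @return numeric score per cell.
#' @export
signed_score <- function(norm_mat, set) {
  miss <- setdiff(c(set$positive, set$negative), colnames(norm_mat))
  if (length(miss))
    stop("feature(s) missing from the matrix: ",
         paste(head(miss, 5), collapse = ", "))
  pos <- if (length(set$positive))
    Matrix::rowSums(norm_mat[, set$positive, drop = FALSE]) /
      length(set$positive) else 0
  neg <- if (length(set$negative))
    Matrix::rowSums(norm_mat[, set$negative, drop = FALSE]) /
      length(set$negative) else 0
  as.vector(pos - neg)
}

#' Rank-sum test of scores between two cell groups
#'
#' @param scores per-cell scores.
#' @param group_mask logical: cells in the group of interest.
#' @param alternative `"two.sided"`, `"greater"` or `"less"` (group vs rest).
#' @return list with `p`, `statistic`, `alternative`, group sizes.
#' @export
score_group_test <- function(scores, group_mask,
                             alternative = c("two.sided", "greater",
                                             "less")) {
  alternative <- match.arg(alternative)
  if (!any(group_mask) || all(group_mask))
    stop("both groups must be non-empty")
  if (length(unique(scores)) == 1L) {
    warning("scores are constant; p = 1")
    return(list(p = 1, statistic = NA_real_, alternative = alternative,
                n1 = sum(group_mask), n2 = sum(!group_mask)))
  }
  wt <- wilcox.test(scores[group_mask], scores[!group_mask],
                    alternative = alternative)
  list(p = wt$p.value, statistic = unname(wt$statistic),
       alternative = alternative,
       n1 = sum(group_mask), n2 = sum(!group_mask))
}

#' Build a signed set from marker statistics
#'
#' Features passing `fdr < fdr_max`, `logFC > logfc_min`, `auc > auc_min`
#' for the first group become the positive set; those passing for the second
#' group the negative set. Standard cutoffs: genes 0.1 / 0.25 / 0.6, peaks
#' 0.1 / 0.1 / 0.58.
#'
#' @param marker_table output of [wilcoxon_markers()] for two groups.
#' @param fdr_max,logfc_min,auc_min thresholds (strict in the stated
#'   directions).
#' @param name set name.
#' @return a [signed_set()].
#' @export
build_signed_sets_from_markers <- function(marker_table, fdr_max = 0.1,
                                           logfc_min = 0.25, auc_min = 0.6,
                                           name = "markers") {
  mt <- as.data.frame(marker_table)
  if (!nrow(mt)) stop("empty marker table")
  groups <- sort(unique(mt$group))
  if (length(groups) != 2L) stop("marker table must contain two groups")
  pass <- mt$fdr < fdr_max & mt$logFC > logfc_min & mt$auc > auc_min
  signed_set(name,
             positive = mt$feature[pass & mt$group == groups[1]],
             negative = mt$feature[pass & mt$group == groups[2]])
}

#' Class-specific peaks by one-vs-rest rank-sum test
#'
#' Per class, peaks with `fdr <= fdr_max` and log2 fold change
#' `>= log2fc_min` in the one-vs-rest marker statistics (the rank-sum logFC
#' is computed on natural-log normalized values and converted to log2).
#'
#' @param norm_mat normalized cell x peak matrix.
#' @param class_labels per-cell classes (>= 2).
#' @param fdr_max,log2fc_min cutoffs (defaults 0.1 and 0.5).
#' @return named list of peak-id vectors, one per class; classes with fewer
#'   than 3 cells are skipped.
#' @export
class_specific_peaks <- function(norm_mat, class_labels, fdr_max = 0.1,
                                 log2fc_min = 0.5) {
  sizes <- table(class_labels)
  use <- names(sizes)[sizes >= 3L]
  if (length(use) < 2L) stop("need >= 2 classes with >= 3 cells")
  skipped <- setdiff(names(sizes), use)
  if (length(skipped))
    warning("class(es) with < 3 cells skipped: ",
            paste(skipped, collapse = ", "))
  keep <- class_labels %in% use
  mk <- wilcoxon_markers(norm_mat[keep, , drop = FALSE], class_labels[keep])
  mk$log2fc <- mk$logFC / log(2)
  sets <- lapply(use, function(cl) {
    sub <- mk[mk$group == cl, ]
    sub$feature[sub$fdr <= fdr_max & sub$log2fc >= log2fc_min]
  })
  names(sets) <- use
  sets
}

#' Hypergeometric motif enrichment in class-specific peaks
#'
#' Per (class, motif): upper-tail hypergeometric p of the motif count in the
#' class's peak set against the background peak universe, BH-adjusted within
#' the class; the enrichment value is `-log10(p_adj)`. A motif is selected
#' for display if its enrichment is at least `enrich_min`, is maximal or
#' within 95% of the class's maximum, and its TF has mean normalized
#' expression of at least `expr_min` in the class. For display, each motif's
#' enrichment is also scaled to the percentage of its cross-class maximum.
#'
#' @param class_peak_sets named list of peak-id vectors (subsets of the
#'   background).
#' @param motif_annot binary peak x motif matrix over the background.
#' @param background_peaks peak-id universe.
#' @param tf_expression optional class x motif matrix of mean normalized TF
#'   expression (`NULL` disables the expression filter).
#' @param enrich_min minimum enrichment for display (default 5).
#' @param expr_min minimum TF expression (default 0.05).
#' @return data.frame per (class, motif): `class`, `motif`, `k_set`,
#'   `n_set`, `k_bg`, `n_bg`, `p`, `p_adj`, `enrichment`, `pct_of_max`,
#'   `selected`.
#' @export
motif_enrichment <- function(class_peak_sets, motif_annot, background_peaks,
                             tf_expression = NULL, enrich_min = 5,
                             expr_min = 0.05) {
  motif_annot <- motif_annot[background_peaks, , drop = FALSE]
  motifs <- colnames(motif_annot)
  n_bg <- length(background_peaks)
  k_bg <- Matrix::colSums(motif_annot)
  drop <- k_bg == 0
  if (any(drop)) {
    motif_annot <- motif_annot[, !drop, drop = FALSE]
    motifs <- motifs[!drop]; k_bg <- k_bg[!drop]
  }
  res <- list()
  for (cl in names(class_peak_sets)) {
    set <- intersect(class_peak_sets[[cl]], background_peaks)
    n_set <- length(set)
    k_set <- if (n_set) Matrix::colSums(motif_annot[set, , drop = FALSE])
             else setNames(rep(0, length(motifs)), motifs)
    p <- phyper(k_set - 1, k_bg, n_bg - k_bg, n_set, lower.tail = FALSE)
    p_adj <- bh_fdr(p)
    enr <- -log10(pmax(p_adj, .Machine$double.xmin))
    cls_max <- max(enr)
    expr_ok <- if (is.null(tf_expression)) TRUE else {
      ex <- rep(0, length(motifs))
      hit <- intersect(motifs, colnames(tf_expression))
      if (cl %in% rownames(tf_expression))
        ex[match(hit, motifs)] <- tf_expression[cl, hit]
      ex >= expr_min
    }
    res[[cl]] <- data.frame(
      class = cl, motif = motifs, k_set = as.vector(k_set),
      n_set = n_set, k_bg = as.vector(k_bg), n_bg = n_bg,
      p = p, p_adj = p_adj, enrichment = enr,
      selected = enr >= enrich_min & enr >= 0.95 * cls_max & expr_ok,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  max_by_motif <- tapply(out$enrichment, out$motif, max)
  out$pct_of_max <- 100 * out$enrichment /
    pmax(max_by_motif[out$motif], .Machine$double.eps)
  out
}

#' Overlap fine-mapped SNPs with peaks
#'
#' SNPs with posterior inclusion probability strictly above `pip_min` are
#' joined to the peaks containing them (0-based half-open containment).
#'
#' @param snps data.frame with `chrom`, `pos` (0-based), `id`, `pip`.
#' @param peaks peak table with `chrom`, `start`, `end` (and optional
#'   `peak` ids).
#' @param pip_min PIP threshold (default 0.1, strict).
#' @return data.frame of overlaps: SNP columns plus `peak`, `peak_start`,
#'   `peak_end`.
#' @export
snp_peak_overlap <- function(snps, peaks, pip_min = 0.1) {
  sn <- snps[snps$pip > pip_min, , drop = FALSE]
  pk <- as.data.frame(peaks)
  pk_ids <- if ("peak" %in% names(pk)) pk$peak else
    sprintf("%s:%d-%d", pk$chrom, pk$start, pk$end)
  if (!nrow(sn))
    return(data.frame(chrom = character(), pos = integer(), id = character(),
                      pip = numeric(), peak = character(),
                      peak_start = integer(), peak_end = integer()))
  sg <- GenomicRanges::GRanges(sn$chrom,
                               IRanges::IRanges(sn$pos + 1L, sn$pos + 1L))
  pg <- GenomicRanges::GRanges(pk$chrom,
                               IRanges::IRanges(pk$start + 1L, pk$end))
  ov <- GenomicRanges::findOverlaps(sg, pg)
  qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
  data.frame(chrom = sn$chrom[qi], pos = sn$pos[qi], id = sn$id[qi],
             pip = sn$pip[qi], peak = pk_ids[si],
             peak_start = pk$start[si], peak_end = pk$end[si],
             stringsAsFactors = FALSE)
}

#' Class-level accessibility profile for peaks of interest
#'
#' Per peak: mean normalized accessibility by class, z-scored across classes
#' (mean 0, SD 1 per peak); classes with `z > 1` are called accessible. Per
#' broad cell type, a one-sided exact Wilcoxon test compares the z values of
#' the type's classes against the other classes (alternative "greater").
#'
#' @param norm_mat normalized cell x peak matrix.
#' @param class_labels per-cell classes (>= 2).
#' @param peaks_of_interest peak ids to profile.
#' @param class_type optional named map class -> broad cell type enabling
#'   the per-type test.
#' @param scale_domain `"per_peak"` (default) or `"joint"` (z over the whole
#'   class x peak grid).
#' @return list of class `"accessibility_profile"`: `means`, `z`
#'   (peak x class), `accessible` (logical), `flagged_zero_variance`,
#'   and `type_tests` when `class_type` is given.
#' @export
class_accessibility_profile <- function(norm_mat, class_labels,
                                        peaks_of_interest,
                                        class_type = NULL,
                                        scale_domain = c("per_peak",
                                                         "joint")) {
  scale_domain <- match.arg(scale_domain)
  classes <- sort(unique(as.character(class_labels)))
  if (length(classes) < 2L) stop("need >= 2 classes")
  peaks <- intersect(peaks_of_interest, colnames(norm_mat))
  if (!length(peaks)) stop("no peaks of interest found in the matrix")
  means <- sapply(classes, function(cl)
    Matrix::colMeans(norm_mat[class_labels == cl, peaks, drop = FALSE]))
  means <- matrix(means, nrow = length(peaks),
                  dimnames = list(peaks, classes))
  if (scale_domain == "per_peak") {
    sds <- apply(means, 1, sd)
    flagged <- sds == 0
    z <- (means - rowMeans(means)) / ifelse(sds == 0, NA_real_, sds)
  } else {
    flagged <- rep(FALSE, nrow(means))
    z <- (means - mean(means)) / sd(means)
  }
  out <- list(means = means, z = z, accessible = !is.na(z) & z > 1,
              flagged_zero_variance = flagged)
  if (!is.null(class_type)) {
    types <- unique(class_type[classes])
    out$type_tests <- do.call(rbind, lapply(peaks, function(pk) {
      zrow <- z[pk, ]
      do.call(rbind, lapply(types, function(ty) {
        in_ty <- class_type[classes] == ty
        p <- if (all(is.na(zrow))) NA_real_ else
          wilcox.test(zrow[in_ty], zrow[!in_ty], alternative = "greater",
                      exact = TRUE)$p.value
        data.frame(peak = pk, cell_type = ty, p = p,
                   stringsAsFactors = FALSE)
      }))
    }))
  }
  class(out) <- "accessibility_profile"
  out
}

#' Scaled per-group coverage tracks (bedgraph)
#'
#' Per cell group, base-pair coverage of its fragments within a region,
#' scaled by the group's total read count divided by 1e7, so tracks are
#' comparable across groups. Doubling a group's fragments everywhere leaves
#' its scaled track unchanged.
#'
#' @param fragments fragment table (`chrom`, `start`, `end`, `barcode`).
#' @param cell_groups named list of barcode vectors partitioning the cells.
#' @param region list/data.frame with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param scale_reads scaling denominator (default 1e7).
#' @return named list of data.frames (`chrom`, `start`, `end`, `value`),
#'   one per group, empty when the group has no fragments in the region.
#' @export
export_class_bedgraph <- function(fragments, cell_groups, region,
                                  scale_reads = 1e7) {
  fr <- as.data.frame(fragments)
  lapply(cell_groups, function(bcs) {
    sub_all <- fr[fr$barcode %in% bcs, , drop = FALSE]
    total <- nrow(sub_all)
    if (total == 0) stop("group with zero total reads")
    sub <- sub_all[sub_all$chrom == region$chrom &
                     sub_all$end > region$start &
                     sub_all$start < region$end, , drop = FALSE]
    if (!nrow(sub))
      return(data.frame(chrom = character(), start = integer(),
                        end = integer(), value = numeric()))
    cov <- IRanges::coverage(IRanges::IRanges(
      pmax(sub$start, region$start) + 1L, pmin(sub$end, region$end)))
    rl <- S4Vectors::runLength(cov); rv <- S4Vectors::runValue(cov)
    ends <- cumsum(rl)
    starts <- ends - rl
    keep <- rv > 0 & starts >= region$start
    data.frame(chrom = region$chrom,
               start = as.integer(starts[keep]),
               end = as.integer(pmin(ends[keep], region$end)),
               value = rv[keep] / (total / scale_reads))
  })
}
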