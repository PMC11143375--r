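#' Configuration for the synthetic multiome generator
#'
#' Defines a multi-sample paired ATAC/RNA dataset in which transcriptional
#' cell states are nested inside chromatin classes: all states of a class
#' share the same peak-openness profile (the superstate assumption) and are
#' told apart only by state-specific marker genes on the expression side.
#'
#' @param n_samples number of samples (batches/donors).
#' @param cells_per_sample cells drawn per sample.
#' @param n_classes number of chromatin classes `C`.
#' @param states_per_class integer vector of length `C`; states nested in
#'   each class.
#' @param n_peaks total number of 200-bp peaks `P`.
#' @param frac_class_specific fraction of peaks that are class-specific,
#'   split evenly across classes; these peaks are open at `p_open_high` in
#'   their class and `p_open_low` elsewhere.
#' @param p_open_high,p_open_low Bernoulli openness probabilities for
#'   class-specific peaks in/out of their class; background peaks sit at
#'   `p_open_low`.
#' @param depth_mu,depth_sigma log-mean and log-sd of the per-cell lognormal
#'   fragment depth.
#' @param batch_sigma standard deviation of the per-(sample, peak) logit
#'   shift emulating sample-level technical variation.
#' @param n_genes number of genes `G`.
#' @param markers_per_state marker genes planted per transcriptional state.
#' @param expr_fc fold change applied to a state's marker genes in cells of
#'   that state.
#' @param nb_dispersion negative-binomial size parameter for gene counts.
#' @param frac_promoter fraction of peaks flagged as promoter peaks (each
#'   promoter peak is paired with a gene).
#' @param n_lineage_peaks number of promoter peaks whose openness is coupled
#'   to the CD4/CD8 lineage code (besides the two dedicated CD4/CD8A peaks).
#' @param lineage_effect logit shift per unit of the ternary lineage code at
#'   lineage-coupled peaks.
#' @param lineage_closed_p openness of the dedicated CD4/CD8A promoter peaks
#'   in cells of the opposite lineage (kept very low so the accessibility-
#'   derived code disagrees with the truth only via sampling noise).
#' @param dup_rate within-cell read duplication probability used by
#'   [generate_reads()].
#' @param n_snps,n_motifs numbers of fine-mapped SNPs and motifs to plant.
#' @param frac_snp_in_class_peaks fraction of SNPs placed inside
#'   class-specific peaks (the rest are intergenic).
#' @param motif_fg_rate,motif_bg_rate planted motif frequency inside the
#'   matching class-specific peaks and in background peaks.
#' @param with_reads if `TRUE`, [generate_multiome()] also materializes
#'   fragment and read tables (only sensible at small scale).
#' @param seed single integer seed; all sub-generators derive child seeds
#'   from it deterministically.
#'
#' @return A validated list of class `"synth_config"`.
#' @export
synth_config <- function(n_samples = 3L, cells_per_sample = 1000L,
                         n_classes = 3L, states_per_class = c(2L, 2L, 1L),
                         n_peaks = 2000L, frac_class_specific = 0.15,
                         p_open_high = 0.45, p_open_low = 0.03,
                         depth_mu = log(800), depth_sigma = 0.35,
                         batch_sigma = 0.25,
                         n_genes = 1000L, markers_per_state = 20L,
                         expr_fc = 4, nb_dispersion = 2,
                         frac_promoter = 0.3,
                         n_lineage_peaks = 20L, lineage_effect = 1.5,
                         lineage_closed_p = 1e-4,
                         dup_rate = 0.3, n_snps = 100L, n_motifs = 10L,
                         frac_snp_in_class_peaks = 0.5,
                         motif_fg_rate = 0.8, motif_bg_rate = 0.1,
                         with_reads = FALSE, seed = 1L) {
  cfg <- list(
    n_samples = as.integer(n_samples),
    cells_per_sample = as.integer(cells_per_sample),
    n_classes = as.integer(n_classes),
    states_per_class = as.integer(states_per_class),
    n_peaks = as.integer(n_peaks),
    frac_class_specific = frac_class_specific,
    p_open_high = p_open_high, p_open_low = p_open_low,
    depth_mu = depth_mu, depth_sigma = depth_sigma,
    batch_sigma = batch_sigma,
    n_genes = as.integer(n_genes),
    markers_per_state = as.integer(markers_per_state),
    expr_fc = expr_fc, nb_dispersion = nb_dispersion,
    frac_promoter = frac_promoter,
    n_lineage_peaks = as.integer(n_lineage_peaks),
    lineage_effect = lineage_effect,
    lineage_closed_p = lineage_closed_p,
    dup_rate = dup_rate, n_snps = as.integer(n_snps),
    n_motifs = as.integer(n_motifs),
    frac_snp_in_class_peaks = frac_snp_in_class_peaks,
    motif_fg_rate = motif_fg_rate, motif_bg_rate = motif_bg_rate,
    with_reads = isTRUE(with_reads),
    seed = as.integer(seed))
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  if (length(cfg$states_per_class) != cfg$n_classes)
    stop("`states_per_class` must have length `n_classes`", call. = FALSE)
  if (sum(cfg$states_per_class) < 1L)
    stop("total number of states must be positive", call. = FALSE)
  for (f in c("frac_class_specific", "p_open_high", "p_open_low",
              "frac_promoter", "frac_snp_in_class_peaks",
              "motif_fg_rate", "motif_bg_rate", "lineage_closed_p"))
    stopifnot_fraction(cfg[[f]], f)
  if (cfg$dup_rate < 0 || cfg$dup_rate >= 1)
    stop("`dup_rate` must lie in [0, 1)", call. = FALSE)
  n_special <- round(cfg$frac_class_specific * cfg$n_peaks) +
    cfg$n_lineage_peaks + 2L
  if (cfg$n_peaks < n_special)
    stop("`n_peaks` smaller than the number of special peaks required",
         call. = FALSE)
  invisible(cfg)
}

# Lay P width-200 peaks out on a small artificial genome, 10 kb apart.
synth_peak_layout <- function(P, n_chrom = 5L) {
  per <- ceiling(P / n_chrom)
  chrom <- paste0("chr", rep(seq_len(n_chrom), each = per))[seq_len(P)]
  idx <- unlist(lapply(split(seq_len(P), chrom), seq_along), use.names = FALSE)
  idx <- idx[order(unlist(split(seq_len(P), chrom), use.names = FALSE))]
  start <- 10000L * idx
  data.frame(peak = sprintf("peak%05d", seq_len(P)),
             chrom = chrom, start = start, end = start + 200L,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic multi-sample multiome dataset
#'
#' Draws cells with a sample, chromatin class, nested transcriptional state,
#' and ternary CD4/CD8 lineage code; per-cell depths are lognormal; peak
#' openness is Bernoulli on the logit scale with per-(sample, peak) batch
#' shifts and lineage coupling; ATAC counts are Poisson on the per-cell
#' normalized openness simplex so that depth and composition are decoupled;
#' gene counts are negative binomial with state markers scaled by `expr_fc`.
#' All ground-truth labels are recorded.
#'
#' @param config a [synth_config()].
#' @return A list of class `"synthetic_multiome"` with elements
#'   `peak_counts` and `gene_counts` (sparse cell x feature matrices),
#'   `cells` (per-cell truth), `peak_annot`, `genes`, `sub_peaks`,
#'   `signed_sets`, `motif_annot`, `snps`, `config`, and — when
#'   `config$with_reads` — `fragments` and `reads`.
#' @export
generate_multiome <- function(config) {
  if (!inherits(config, "synth_config")) config <- do.call(synth_config, config)
  validate_synth_config(config)
  cfg <- config
  n <- cfg$n_samples * cfg$cells_per_sample
  P <- cfg$n_peaks
  C <- cfg$n_classes
  n_states <- sum(cfg$states_per_class)
  state_class <- rep(seq_len(C), cfg$states_per_class)

  cells <- with_seed(cfg$seed, "cells", {
    sample_id <- rep(sprintf("S%d", seq_len(cfg$n_samples)),
                     each = cfg$cells_per_sample)
    state <- sample(seq_len(n_states), n, replace = TRUE)
    class <- state_class[state]
    lineage <- sample(c(1L, -1L, 0L), n, replace = TRUE,
                      prob = c(0.45, 0.45, 0.10))
    depth <- rlnorm(n, cfg$depth_mu, cfg$depth_sigma)
    data.frame(barcode = sprintf("%s_BC%06d", sample_id, seq_len(n)),
               sample = sample_id,
               class = sprintf("C%d", class),
               state = sprintf("T%d", state),
               lineage = lineage, depth = depth,
               stringsAsFactors = FALSE)
  })

  annot <- with_seed(cfg$seed, "peaks", {
    a <- synth_peak_layout(P)
    n_cs <- round(cfg$frac_class_specific * P / C)
    a$class_specific <- NA_integer_
    cs_idx <- sample(seq_len(P), n_cs * C)
    a$class_specific[cs_idx] <- rep(seq_len(C), each = n_cs)
    bg <- which(is.na(a$class_specific))
    # promoter flags: dedicated lineage peaks must be promoters
    n_prom <- round(cfg$frac_promoter * P)
    special <- sample(bg, cfg$n_lineage_peaks + 2L)
    cd4 <- special[1L]; cd8a <- special[2L]
    lin_peaks <- special[-(1:2)]
    prom_pool <- setdiff(seq_len(P), special)
    prom <- c(special, sample(prom_pool, max(0L, n_prom - length(special))))
    a$is_promoter <- seq_len(P) %in% prom
    a$lineage_sign <- 0L
    # balanced CD4/CD8A association counts keep the total openness gain of
    # +1 and -1 cells identical, so the fragment-count covariate cannot
    # proxy the lineage for uncoupled peaks
    a$lineage_sign[lin_peaks] <- sample(rep(c(1L, -1L),
                                            length.out = length(lin_peaks)))
    a$role <- NA_character_
    a$role[cd4] <- "CD4"; a$role[cd8a] <- "CD8A"
    a
  })

  genes <- with_seed(cfg$seed, "genes", {
    g <- data.frame(gene = sprintf("G%05d", seq_len(cfg$n_genes)),
                    base = rlnorm(cfg$n_genes, log(0.5), 1),
                    marker_state = NA_integer_,
                    stringsAsFactors = FALSE)
    mk <- sample(seq_len(cfg$n_genes), cfg$markers_per_state * n_states)
    g$marker_state[mk] <- rep(seq_len(n_states), each = cfg$markers_per_state)
    g$gene[!is.na(g$marker_state)] <-
      sprintf("MK%02d_%03d", g$marker_state[mk], mk)
    g
  })

  # promoter peak -> gene pairing; marker genes paired first so that every
  # state marker has a promoter peak (needed for concordance analyses)
  annot$gene <- NA_character_
  annot <- with_seed(cfg$seed, "pairing", {
    prom_idx <- which(annot$is_promoter & is.na(annot$role))
    mk_genes <- which(!is.na(genes$marker_state))
    other <- setdiff(seq_len(cfg$n_genes), mk_genes)
    ord <- c(mk_genes[sample.int(length(mk_genes))],
             other[sample.int(length(other))])
    take <- head(ord, length(prom_idx))
    annot$gene[prom_idx[seq_along(take)]] <- genes$gene[take]
    annot$gene[which(annot$role == "CD4")] <- "CD4"
    annot$gene[which(annot$role == "CD8A")] <- "CD8A"
    annot
  })

  class_int <- as.integer(sub("^C", "", cells$class))
  sample_int <- as.integer(factor(cells$sample,
                                  levels = sprintf("S%d", seq_len(cfg$n_samples))))

  # openness logits: background at p_open_low; class-specific peaks high in
  # their class; batch shift per (sample, peak); lineage coupling
  L <- matrix(qlogis(cfg$p_open_low), n, P)
  for (c in seq_len(C)) {
    j <- which(annot$class_specific == c)
    if (length(j)) L[class_int == c, j] <- qlogis(cfg$p_open_high)
  }
  batch <- with_seed(cfg$seed, "batch",
                     matrix(rnorm(cfg$n_samples * P, 0, cfg$batch_sigma),
                            cfg$n_samples, P))
  L <- L + batch[sample_int, , drop = FALSE]
  cd4 <- which(annot$role == "CD4"); cd8a <- which(annot$role == "CD8A")
  L[, c(cd4, cd8a)] <- qlogis(cfg$lineage_closed_p) +
    batch[sample_int, c(cd4, cd8a), drop = FALSE]
  # the normalizing simplex uses the lineage-neutral openness (class + batch
  # only) so that peaks without planted coupling stay conditionally null for
  # lineage given class and sample; the cell's own sum would leak the lineage
  # perturbation into every background peak through the composition
  denom <- rowSums(plogis(L))
  lin <- which(annot$lineage_sign != 0L)
  if (length(lin))
    L[, lin] <- L[, lin] + cfg$lineage_effect *
      outer(cells$lineage, annot$lineage_sign[lin])
  L[cells$lineage == 1L, cd4] <- qlogis(cfg$p_open_high)
  L[cells$lineage == -1L, cd8a] <- qlogis(cfg$p_open_high)
  pi <- plogis(L)
  rm(L)
  mu <- pi / denom * cells$depth
  rm(pi)
  counts <- with_seed(cfg$seed, "atac_counts",
                      matrix(rpois(length(mu), mu), n, P))
  rm(mu)
  peak_counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  rm(counts)
  dimnames(peak_counts) <- list(cells$barcode, annot$peak)
  cells$n_fragments <- Matrix::rowSums(peak_counts)

  # RNA: NB counts, state markers multiplied by expr_fc
  gene_counts <- with_seed(cfg$seed, "rna_counts", {
    lib <- rlnorm(n, log(2000), 0.3)
    rel <- genes$base / sum(genes$base)
    mu_g <- outer(lib, rel)
    for (t in seq_len(n_states)) {
      gj <- which(genes$marker_state == t)
      ci <- which(cells$state == sprintf("T%d", t))
      if (length(gj) && length(ci)) mu_g[ci, gj] <- mu_g[ci, gj] * cfg$expr_fc
    }
    m <- matrix(rnbinom(length(mu_g), mu = mu_g, size = cfg$nb_dispersion),
                n, cfg$n_genes)
    methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
  })
  dimnames(gene_counts) <- list(cells$barcode, genes$gene)
  cells$n_umi <- Matrix::rowSums(gene_counts)

  sub_peaks <- generate_subpeaks(annot, seed = cfg$seed)
  signed_sets <- with_seed(cfg$seed, "signed_sets", {
    pos <- annot$peak[annot$lineage_sign == 1L]
    neg <- annot$peak[annot$lineage_sign == -1L]
    s1 <- annot$peak[which(annot$class_specific == 1L)]
    s2 <- annot$peak[which(annot$class_specific == min(2L, C))]
    list(
      lineage = signed_set("lineage", positive = pos, negative = neg),
      dmr_like = structure(
        signed_set("dmr_like",
                   positive = sample(s1, min(30L, length(s1))),
                   negative = sample(s2, min(30L, length(s2)))),
        target_class = "C1"))
  })
  motif_annot <- generate_motifs(annot,
                                 n_motifs = cfg$n_motifs, seed = cfg$seed,
                                 fg_rate = cfg$motif_fg_rate,
                                 bg_rate = cfg$motif_bg_rate)
  snps <- generate_snps(annot, n_snps = cfg$n_snps, seed = cfg$seed,
                        frac_in_class_peaks = cfg$frac_snp_in_class_peaks)

  out <- list(peak_counts = peak_counts, gene_counts = gene_counts,
              cells = cells, peak_annot = annot, genes = genes,
              sub_peaks = sub_peaks, signed_sets = signed_sets,
              motif_annot = motif_annot, snps = snps, config = cfg)
  if (cfg$with_reads) {
    out$fragments <- generate_fragments(peak_counts, annot, seed = cfg$seed)
    out$reads <- generate_reads(out$fragments, dup_rate = cfg$dup_rate,
                                seed = cfg$seed)
  }
  class(out) <- "synthetic_multiome"
  out
}

#' @export
print.synthetic_multiome <- function(x, ...) {
  cat(sprintf(
    "synthetic multiome: %d cells x %d peaks / %d genes; %d classes, %d states\n",
    nrow(x$cells), ncol(x$peak_counts), ncol(x$gene_counts),
    x$config$n_classes, sum(x$config$states_per_class)))
  invisible(x)
}

#' Overlapping sub-peak candidates around the true peaks
#'
#' Emits, per true 200-bp peak, a best candidate whose summit is the true
#' peak center plus 1-2 jittered, overlapping, worse-q candidates — a fixture
#' for summit trimming and greedy q-value de-overlap.
#'
#' @param peak_annot peak table with `chrom`, `start`, `end`.
#' @param seed integer seed.
#' @return data.frame with `chrom`, `start`, `end`, `summit`, `q`.
#' @export
generate_subpeaks <- function(peak_annot, seed = 1L) {
  with_seed(seed, "subpeaks", {
    center <- as.integer((peak_annot$start + peak_annot$end) %/% 2)
    n <- nrow(peak_annot)
    n_extra <- sample(1:2, n, replace = TRUE)
    best <- data.frame(chrom = peak_annot$chrom,
                       summit = center,
                       q = 10^runif(n, -12, -6))
    extra <- data.frame(
      chrom = rep(peak_annot$chrom, n_extra),
      summit = rep(center, n_extra) +
        sample(c(-80:-20, 20:80), sum(n_extra), replace = TRUE),
      q = rep(best$q, n_extra) * 10^runif(sum(n_extra), 1, 4))
    sp <- rbind(best, extra)
    sp$start <- pmax(0L, sp$summit - sample(100:400, nrow(sp), replace = TRUE))
    sp$end <- sp$summit + sample(100:400, nrow(sp), replace = TRUE)
    sp[order(sp$chrom, sp$start), c("chrom", "start", "end", "summit", "q")]
  })
}

#' Expand a cell x peak count matrix into a fragment table
#'
#' Each count becomes that many fragments placed uniformly so that every
#' fragment overlaps its source peak (0-based half-open coordinates).
#'
#' @param peak_counts sparse cell x peak matrix.
#' @param peak_annot peak table aligned with the columns.
#' @param seed integer seed.
#' @return `data.table` with `chrom`, `start`, `end`, `barcode`.
#' @export
generate_fragments <- function(peak_counts, peak_annot, seed = 1L) {
  tm <- methods::as(peak_counts, "TsparseMatrix")
  i <- rep(tm@i + 1L, tm@x)
  j <- rep(tm@j + 1L, tm@x)
  with_seed(seed, "fragments", {
    len <- sample(60:250, length(i), replace = TRUE)
    lo <- pmax(0L, peak_annot$start[j] - len + 1L)
    hi <- peak_annot$end[j] - 1L
    start <- lo + as.integer(floor(runif(length(i)) * (hi - lo + 1L)))
    fr <- data.table::data.table(chrom = peak_annot$chrom[j],
                                 start = start, end = start + len,
                                 barcode = rownames(peak_counts)[i])
    data.table::setorder(fr, chrom, start, end, barcode)
    fr[]
  })
}

#' Emit reads with within-cell PCR duplicates
#'
#' Each fragment is emitted once, plus `k` extra copies within the same cell
#' with `k ~ Geometric(dup_rate)`. The unique truth is recoverable from the
#' `is_duplicate` flag.
#'
#' @param fragments fragment table (`chrom`, `start`, `end`, `barcode`).
#' @param dup_rate duplication probability in `[0, 1)`.
#' @param seed integer seed.
#' @return `data.table` of read records: `chrom`, `start`, `mate_start`,
#'   `cigar`, `mapq`, `barcode`, `is_duplicate`.
#' @export
generate_reads <- function(fragments, dup_rate = 0.3, seed = 1L) {
  if (dup_rate < 0 || dup_rate >= 1)
    stop("`dup_rate` must lie in [0, 1)", call. = FALSE)
  fr <- data.table::as.data.table(fragments)
  k <- if (dup_rate == 0) rep(0L, nrow(fr)) else
    with_seed(seed, "reads", rgeom(nrow(fr), prob = 1 - dup_rate))
  idx <- rep(seq_len(nrow(fr)), k + 1L)
  dup <- unlist(lapply(k + 1L, function(m) c(FALSE, rep(TRUE, m - 1L))),
                use.names = FALSE)
  reads <- fr[idx]
  reads[, `:=`(mate_start = end, cigar = "50M", mapq = 60L,
               is_duplicate = dup)]
  reads[, end := NULL]
  reads[]
}

#' Plant fine-mapped SNPs in and around peaks
#'
#' A configurable fraction of SNPs is placed inside class-specific peaks,
#' the rest midway between peaks (intergenic); PIPs are Beta(0.5, 2).
#'
#' @param peak_annot peak table (`chrom`, `start`, `end`, `class_specific`).
#' @param n_snps number of SNPs.
#' @param seed integer seed.
#' @param frac_in_class_peaks fraction placed inside class-specific peaks.
#' @return data.frame with `chrom`, `pos` (0-based), `id`, `pip`,
#'   `in_class_peak`.
#' @export
generate_snps <- function(peak_annot, n_snps, seed = 1L,
                          frac_in_class_peaks = 0.5) {
  if (nrow(peak_annot) == 0) stop("`peak_annot` is empty", call. = FALSE)
  if (n_snps == 0)
    return(data.frame(chrom = character(), pos = integer(),
                      id = character(), pip = numeric(),
                      in_class_peak = logical()))
  with_seed(seed, "snps", {
    n_in <- round(frac_in_class_peaks * n_snps)
    cs <- which(!is.na(peak_annot$class_specific))
    if (!length(cs)) n_in <- 0L
    j_in <- if (n_in) sample(cs, n_in, replace = TRUE) else integer()
    pos_in <- peak_annot$start[j_in] +
      as.integer(floor(runif(n_in) * 200))
    j_out <- sample(seq_len(nrow(peak_annot)), n_snps - n_in, replace = TRUE)
    pos_out <- peak_annot$end[j_out] + 2000L +
      as.integer(floor(runif(n_snps - n_in) * 5000))
    df <- data.frame(
      chrom = c(peak_annot$chrom[j_in], peak_annot$chrom[j_out]),
      pos = c(pos_in, pos_out),
      id = sprintf("rs%06d", seq_len(n_snps)),
      pip = rbeta(n_snps, 0.5, 2),
      in_class_peak = rep(c(TRUE, FALSE), c(n_in, n_snps - n_in)),
      stringsAsFactors = FALSE)
    df[order(df$chrom, df$pos), ]
  })
}

#' Plant motif annotations over peaks
#'
#' One motif per class occurs at `fg_rate` in that class's specific peaks and
#' `bg_rate` elsewhere; remaining motifs occur uniformly at `bg_rate`.
#'
#' @param peak_annot peak table with `class_specific`.
#' @param n_motifs total motifs (must be at least the number of classes).
#' @param seed integer seed.
#' @param fg_rate,bg_rate planted and background occurrence rates.
#' @return sparse binary peak x motif matrix; planted motifs are named
#'   `MOTIF_C<k>`.
#' @export
generate_motifs <- function(peak_annot, n_motifs, seed = 1L,
                            fg_rate = 0.8, bg_rate = 0.1) {
  P <- nrow(peak_annot)
  if (P == 0) stop("`peak_annot` is empty", call. = FALSE)
  classes <- sort(unique(peak_annot$class_specific[!is.na(peak_annot$class_specific)]))
  n_motifs <- max(n_motifs, length(classes))
  with_seed(seed, "motifs", {
    m <- matrix(rbinom(P * n_motifs, 1L, bg_rate), P, n_motifs)
    for (k in seq_along(classes)) {
      j <- which(peak_annot$class_specific == classes[k])
      m[j, k] <- rbinom(length(j), 1L, fg_rate)
    }
    colnames(m) <- c(sprintf("MOTIF_C%d", classes),
                     sprintf("MOTIF_BG%d", seq_len(n_motifs - length(classes))))
    rownames(m) <- peak_annot$peak
    methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
  })
}

#' Simulate (sample, state) pseudobulk counts
#'
#' Negative-binomial counts over a samples-by-states grid with lognormal
#' sample size factors; a chosen subset of peaks carries a multiplicative
#' state effect. Used for calibration and power checks of the pseudobulk
#' likelihood-ratio test.
#'
#' @param n_peaks number of peaks.
#' @param n_samples,n_states grid dimensions.
#' @param planted indices of peaks with a state effect.
#' @param fc fold change applied in the last state for planted peaks.
#' @param base_mu mean count range (log-uniform) across peaks.
#' @param dispersion NB size parameter.
#' @param frac_of_library fraction of each pseudobulk's library represented
#'   by the simulated peaks; `n_fragments` is scaled up accordingly (with
#'   small lognormal jitter) so the fragment-count covariate reflects the
#'   whole library rather than the tested peaks alone.
#' @param seed integer seed.
#' @return list with `counts` ((sample x state) rows by peaks), `sample`,
#'   `state`, `n_fragments`, `planted`.
#' @export
simulate_pseudobulk <- function(n_peaks = 1000L, n_samples = 6L,
                                n_states = 2L, planted = integer(),
                                fc = 4, base_mu = c(20, 200),
                                dispersion = 10, frac_of_library = 0.02,
                                seed = 1L) {
  with_seed(seed, "pseudobulk", {
    grid <- expand.grid(sample = sprintf("S%d", seq_len(n_samples)),
                        state = sprintf("T%d", seq_len(n_states)),
                        stringsAsFactors = FALSE)
    sf <- rlnorm(n_samples, 0, 0.3)[as.integer(factor(grid$sample))]
    mu0 <- exp(runif(n_peaks, log(base_mu[1]), log(base_mu[2])))
    mu <- outer(sf, mu0)
    if (length(planted))
      mu[grid$state == sprintf("T%d", n_states), planted] <-
        mu[grid$state == sprintf("T%d", n_states), planted] * fc
    counts <- matrix(rnbinom(length(mu), mu = mu, size = dispersion),
                     nrow(grid), n_peaks,
                     dimnames = list(paste(grid$sample, grid$state, sep = "."),
                                     sprintf("peak%05d", seq_len(n_peaks))))
    lib <- round(sum(mu0) * sf / frac_of_library *
                   exp(rnorm(nrow(grid), 0, 0.05)))
    list(counts = counts, sample = grid$sample, state = grid$state,
         n_fragments = lib, planted = planted)
  })
}
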