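#' Ternary CD4/CD8 lineage code from promoter-peak accessibility
#'
#' `+1` when the CD4 promoter peak is open and CD8A closed, `-1` for the
#' reverse, `0` when both or neither are open.
#'
#' @param bin_mat binarized cell x peak matrix.
#' @param cd4_peak,cd8a_peak column ids of the two dedicated promoter peaks.
#' @return integer vector in `{-1, 0, 1}` per cell.
#' @export
derive_lineage <- function(bin_mat, cd4_peak, cd8a_peak) {
  if (!all(c(cd4_peak, cd8a_peak) %in% colnames(bin_mat)))
    stop("CD4/CD8A peak ids missing from the matrix")
  cd4 <- as.vector(bin_mat[, cd4_peak] > 0)
  cd8 <- as.vector(bin_mat[, cd8a_peak] > 0)
  ifelse(cd4 & !cd8, 1L, ifelse(cd8 & !cd4, -1L, 0L))
}

# Logistic likelihood-ratio engine shared by the lineage and class tests.
# X_full must contain X_null's columns plus the tested term(s); the default
# sample-effect strategy is fixed-effect one-hot dummies (present in both
# models, so the LRT df is the tested term's df); sample_effect = "random"
# fits a Laplace-approximated random intercept via lme4 instead.
logistic_lrt_engine <- function(y_mat, x_full, x_null, test_cols,
                                sample_labels = NULL,
                                sample_effect = c("fixed", "random")) {
  sample_effect <- match.arg(sample_effect)
  df_test <- length(test_cols)
  features <- colnames(y_mat) %||% sprintf("f%d", seq_len(ncol(y_mat)))
  res <- vector("list", ncol(y_mat))
  for (j in seq_len(ncol(y_mat))) {
    y <- as.vector(y_mat[, j])
    row <- data.frame(feature = features[j], effect = NA_real_,
                      lrt_stat = NA_real_, p = NA_real_,
                      converged = FALSE, stringsAsFactors = FALSE)
    if (sample_effect == "fixed") {
      fit_f <- tryCatch(suppressWarnings(
        glm.fit(x_full, y, family = binomial())), error = function(e) NULL)
      fit_n <- tryCatch(suppressWarnings(
        glm.fit(x_null, y, family = binomial())), error = function(e) NULL)
      if (!is.null(fit_f) && !is.null(fit_n) &&
          fit_f$converged && fit_n$converged &&
          all(abs(fit_f$coefficients[test_cols]) < 15)) {
        row$effect <- unname(fit_f$coefficients[test_cols[1]])
        row$lrt_stat <- max(0, fit_n$deviance - fit_f$deviance)
        row$p <- pchisq(row$lrt_stat, df_test, lower.tail = FALSE)
        row$converged <- TRUE
      }
    } else {
      if (!requireNamespace("lme4", quietly = TRUE))
        stop("sample_effect = 'random' requires the lme4 package")
      dat <- data.frame(y = y, x_full[, setdiff(colnames(x_full),
                                                "(Intercept)"),
                                      drop = FALSE],
                        .sample = sample_labels, check.names = FALSE)
      fixed <- setdiff(colnames(x_full), "(Intercept)")
      null_fixed <- setdiff(colnames(x_null), "(Intercept)")
      f_full <- stats::reformulate(c(sprintf("`%s`", fixed), "(1 | .sample)"),
                                   response = "y")
      f_null <- stats::reformulate(c(sprintf("`%s`", null_fixed),
                                     "(1 | .sample)"), response = "y")
      fit <- tryCatch({
        mf <- lme4::glmer(f_full, dat, family = binomial(),
                          control = lme4::glmerControl(calc.derivs = FALSE))
        mn <- lme4::glmer(f_null, dat, family = binomial(),
                          control = lme4::glmerControl(calc.derivs = FALSE))
        list(mf = mf, mn = mn)
      }, error = function(e) NULL)
      if (!is.null(fit)) {
        row$effect <- unname(lme4::fixef(fit$mf)[test_cols[1]])
        row$lrt_stat <- max(0, 2 * (as.numeric(logLik(fit$mf)) -
                                      as.numeric(logLik(fit$mn))))
        row$p <- pchisq(row$lrt_stat, df_test, lower.tail = FALSE)
        row$converged <- TRUE
      }
    }
    res[[j]] <- row
  }
  out <- do.call(rbind, res)
  out$fdr <- NA_real_
  ok <- out$converged
  out$fdr[ok] <- bh_fdr(out$p[ok])
  n_failed <- sum(!ok)
  if (n_failed)
    warning(n_failed, " feature(s) failed to converge (separation); ",
            "excluded from FDR")
  attr(out, "n_failed") <- n_failed
  out
}

drop_constant_cols <- function(x, keep_intercept = TRUE) {
  keep <- apply(x, 2, function(v) var(v) > 0)
  if (keep_intercept && "(Intercept)" %in% colnames(x))
    keep[colnames(x) == "(Intercept)"] <- TRUE
  x[, keep, drop = FALSE]
}

#' Lineage association of promoter peaks (mixed-logistic LRT)
#'
#' Per promoter peak, a logistic regression of binarized accessibility on the
#' ternary lineage code while accounting for chromatin class, sample, and
#' scaled log10 fragment counts; significance is the likelihood-ratio test
#' (df = 1) of the full model against one without the lineage term, with BH
#' FDR. A positive lineage beta means CD4-associated, negative CD8A. Peaks
#' that are uniformly open or closed are excluded before fitting.
#'
#' @param bin_prom binarized cell x promoter-peak matrix.
#' @param lineage ternary lineage code per cell (see [derive_lineage()]).
#' @param class_labels,sample_labels,n_fragments aligned covariates.
#' @param fdr_level selection level (default 0.20).
#' @param sample_effect `"fixed"` (one-hot dummies, default) or `"random"`
#'   (lme4 random intercept).
#' @return data.frame per peak: `feature`, `effect` (lineage log-odds),
#'   `lrt_stat`, `p`, `fdr`, `converged`, `significant`, `direction`
#'   (`"CD4"`/`"CD8A"`).
#' @export
lineage_association <- function(bin_prom, lineage, class_labels,
                                sample_labels, n_fragments,
                                fdr_level = 0.20,
                                sample_effect = c("fixed", "random")) {
  sample_effect <- match.arg(sample_effect)
  if (length(unique(sample_labels)) < 2L && sample_effect == "random")
    stop("need >= 2 samples for a sample effect")
  open_frac <- Matrix::colMeans(bin_prom > 0)
  usable <- open_frac > 0 & open_frac < 1
  if (!all(usable))
    message(sum(!usable), " uniformly open/closed peak(s) excluded")
  covs <- cbind(`(Intercept)` = 1,
                lineage = as.numeric(lineage),
                one_hot_named(class_labels, "class"),
                if (sample_effect == "fixed")
                  one_hot_named(sample_labels, "sample"),
                lognfrag = drop(scale(log10(pmax(n_fragments, 1)))))
  covs <- drop_constant_cols(covs)
  x_full <- covs
  x_null <- covs[, colnames(covs) != "lineage", drop = FALSE]
  res <- logistic_lrt_engine(bin_prom[, usable, drop = FALSE],
                             x_full, x_null, test_cols = "lineage",
                             sample_labels = sample_labels,
                             sample_effect = sample_effect)
  res$significant <- !is.na(res$fdr) & res$fdr < fdr_level
  res$direction <- ifelse(res$effect > 0, "CD4", "CD8A")
  attr(res, "fdr_level") <- fdr_level
  res
}

one_hot_named <- function(f, prefix) {
  m <- one_hot(f)
  if (ncol(m)) colnames(m) <- sub("^sample_", paste0(prefix, "_"),
                                  colnames(m))
  m
}

#' Single-cell differential accessibility by class (logistic LRT)
#'
#' One-vs-rest logistic regression per promoter peak: binarized accessibility
#' on a class indicator with sample and scaled log10 fragment-count
#' covariates; LRT (df = 1) against the class-free null. The reported effect
#' is the class beta (natural log-odds), labelled `log2FC` downstream by
#' convention of the display tables.
#'
#' @param bin_prom binarized cell x peak matrix.
#' @param class_indicator logical per cell (in the tested class).
#' @param sample_labels,n_fragments aligned covariates.
#' @param sample_effect see [lineage_association()].
#' @return data.frame per peak with `effect`, `lrt_stat`, `p`, `fdr`.
#' @export
class_logistic_lrt <- function(bin_prom, class_indicator, sample_labels,
                               n_fragments,
                               sample_effect = c("fixed", "random")) {
  sample_effect <- match.arg(sample_effect)
  open_frac <- Matrix::colMeans(bin_prom > 0)
  usable <- open_frac > 0 & open_frac < 1
  covs <- cbind(`(Intercept)` = 1,
                class = as.numeric(class_indicator),
                if (sample_effect == "fixed")
                  one_hot_named(sample_labels, "sample"),
                lognfrag = drop(scale(log10(pmax(n_fragments, 1)))))
  covs <- drop_constant_cols(covs)
  x_full <- covs
  x_null <- covs[, colnames(covs) != "class", drop = FALSE]
  logistic_lrt_engine(bin_prom[, usable, drop = FALSE], x_full, x_null,
                      test_cols = "class", sample_labels = sample_labels,
                      sample_effect = sample_effect)
}

#' Sum a cell matrix into (sample, state) pseudobulks
#'
#' Counts are summed over all cells sharing a (sample, state) combination.
#' The inclusion mask keeps combinations from samples with more than
#' `min_sample_cells` cells, states with more than `min_state_cells` cells,
#' and combinations with more than `min_combo_cells` cells (all strict).
#'
#' @param counts non-binary cell x peak matrix.
#' @param sample_labels,state_labels aligned per-cell labels.
#' @param min_sample_cells,min_state_cells,min_combo_cells thresholds
#'   (defaults 150 / 130 / 10).
#' @return list of class `"pseudobulk"`: `counts` (combination x peak),
#'   `sample`, `state`, `n_cells`, `n_fragments`, `included`.
#' @export
pseudobulk_counts <- function(counts, sample_labels, state_labels,
                              min_sample_cells = 150L,
                              min_state_cells = 130L,
                              min_combo_cells = 10L) {
  sample_labels <- as.character(sample_labels)
  state_labels <- as.character(state_labels)
  combo <- paste(sample_labels, state_labels, sep = ".")
  f <- factor(combo)
  ind <- Matrix::sparseMatrix(i = as.integer(f), j = seq_along(f), x = 1,
                              dims = c(nlevels(f), length(f)))
  pb <- as.matrix(ind %*% counts)
  rownames(pb) <- levels(f)
  lev_sample <- sub("\\..*$", "", levels(f))
  lev_state <- sub("^[^.]*\\.", "", levels(f))
  n_cells <- as.vector(table(f))
  sample_sizes <- table(sample_labels)
  state_sizes <- table(state_labels)
  included <- sample_sizes[lev_sample] > min_sample_cells &
    state_sizes[lev_state] > min_state_cells &
    n_cells > min_combo_cells
  structure(list(counts = pb, sample = lev_sample, state = lev_state,
                 n_cells = n_cells, n_fragments = rowSums(pb),
                 included = as.vector(included)),
            class = "pseudobulk")
}

#' Pseudobulk differential accessibility (negative-binomial LRT)
#'
#' Per peak, nested negative-binomial regressions of the (sample, state)
#' pseudobulk counts: full model with one-hot state, one-hot sample and
#' scaled log10 fragment totals versus a null without the state term; the
#' likelihood-ratio statistic has df = #states - 1 and BH FDR is applied
#' within the analysis.
#'
#' Pseudobulk designs leave very few residual degrees of freedom (a dozen
#' observations against sample + state + depth parameters), where a per-peak
#' dispersion MLE is unusable: it collapses toward Poisson and the
#' chi-square LRT rejects several-fold too often, while replacing the
#' reference with a per-peak deviance F kills all power at ~4 residual df.
#' The default therefore moderates across peaks: one common dispersion is
#' estimated from all tested peaks under the full design (Cox-Reid adjusted
#' profile likelihood via edgeR) and shared by every fit, with the usual
#' chi-square reference. `dispersion = "per_peak"` keeps the per-peak MLE
#' with the small-sample F reference for users with many pseudobulks. Peaks
#' (or analyses) where the dispersion fit fails fall back to Poisson and
#' are flagged.
#'
#' @param pb a [pseudobulk_counts()] result (masked rows are dropped).
#' @param states optional subset of states to compare (default: all included
#'   states).
#' @param min_reads peaks need at least this many reads across the retained
#'   pseudobulks (default 5).
#' @param fdr_level differential call level (default 0.10).
#' @param dispersion `"common"` (default, moderated across peaks) or
#'   `"per_peak"`.
#' @return data.frame per tested peak: `feature`, `effect` (largest state
#'   log fold change), `lrt_stat`, `p`, `fdr`, `differential`,
#'   `poisson_fallback`; attribute `n_fallback`.
#' @export
nb_lrt_differential <- function(pb, states = NULL, min_reads = 5L,
                                fdr_level = 0.10,
                                dispersion = c("common", "per_peak")) {
  dispersion <- match.arg(dispersion)
  keep <- pb$included
  if (!is.null(states)) keep <- keep & pb$state %in% states
  y_all <- pb$counts[keep, , drop = FALSE]
  st <- factor(pb$state[keep])
  sm <- factor(pb$sample[keep])
  if (nlevels(st) < 2L) stop("need >= 2 states after masking")
  lognf <- drop(scale(log10(pmax(pb$n_fragments[keep], 1))))
  tested <- which(colSums(y_all) >= min_reads)
  x_full <- drop_constant_cols(
    cbind(`(Intercept)` = 1, one_hot_named(st, "state"),
          one_hot_named(sm, "sample"), lognfrag = lognf))
  state_cols <- grep("^state_", colnames(x_full), value = TRUE)
  x_null <- x_full[, setdiff(colnames(x_full), state_cols), drop = FALSE]
  df_test <- length(state_cols)
  df_resid <- nrow(x_full) - ncol(x_full)
  theta_common <- NULL
  if (dispersion == "common" && length(tested)) {
    disp <- tryCatch(
      suppressWarnings(edgeR::estimateGLMCommonDisp(
        t(y_all[, tested, drop = FALSE]), design = x_full)),
      error = function(e) NULL)
    if (!is.null(disp) && is.finite(disp) && disp > 1e-8)
      theta_common <- 1 / disp
  }
  res <- vector("list", length(tested))
  n_fallback <- 0L
  for (k in seq_along(tested)) {
    j <- tested[k]
    y <- y_all[, j]
    theta <- if (dispersion == "common") theta_common else tryCatch(
      suppressWarnings(MASS::glm.nb(y ~ x_full - 1))$theta,
      error = function(e) NULL)
    fam <- if (!is.null(theta) && is.finite(theta) && theta > 0) {
      MASS::negative.binomial(theta)
    } else {
      n_fallback <- n_fallback + 1L
      poisson()
    }
    fit_f <- suppressWarnings(glm.fit(x_full, y, family = fam))
    fit_n <- suppressWarnings(glm.fit(x_null, y, family = fam))
    lrt <- max(0, fit_n$deviance - fit_f$deviance)
    p <- if (dispersion == "per_peak" && df_resid >= 1 &&
             fit_f$deviance > 0) {
      pf(lrt / df_test / (fit_f$deviance / df_resid), df_test, df_resid,
         lower.tail = FALSE)
    } else {
      pchisq(lrt, df_test, lower.tail = FALSE)
    }
    beta <- fit_f$coefficients[state_cols]
    res[[k]] <- data.frame(
      feature = colnames(y_all)[j],
      effect = beta[which.max(abs(beta))],
      lrt_stat = lrt,
      p = p,
      poisson_fallback = fam$family == "poisson",
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out$fdr <- bh_fdr(out$p)
  out$differential <- out$fdr < fdr_level
  if (n_fallback)
    message(n_fallback, " peak(s) used a Poisson fallback")
  attr(out, "n_fallback") <- n_fallback
  attr(out, "df_test") <- df_test
  out
}

#' @importFrom stats poisson pwilcox pf
NULL

#' Rank-sum marker statistics (one-vs-rest per group)
#'
#' Per feature and group: two-sided Wilcoxon rank-sum p (exact when both
#' groups are small and untied, normal approximation with tie and continuity
#' corrections otherwise), AUC = U / (n1 n2), and logFC = difference of group
#' means of the normalized values; BH FDR across features within each group.
#'
#' @param norm_mat normalized cell x feature matrix (log-normalized to 1e4
#'   for expression).
#' @param group_labels per-cell group labels (>= 2 groups).
#' @return data.frame with `feature`, `group`, `logFC`, `auc`, `p`, `fdr`.
#' @export
wilcoxon_markers <- function(norm_mat, group_labels) {
  groups <- sort(unique(as.character(group_labels)))
  if (length(groups) < 2L) stop("need >= 2 groups")
  x <- norm_mat
  n <- nrow(x)
  res <- list()
  for (g in groups) {
    in_g <- group_labels == g
    n1 <- sum(in_g); n0 <- n - n1
    if (n1 == 0) next
    stats_g <- apply_features(x, function(v) {
      r <- rank(v)
      u <- sum(r[in_g]) - n1 * (n1 + 1) / 2
      ties <- rle(sort(v))$lengths
      has_ties <- any(ties > 1)
      p <- if (!has_ties && min(n1, n0) > 0 && max(n1, n0) < 50) {
        if (u > n1 * n0 / 2)
          min(1, 2 * pwilcox(u - 1, n1, n0, lower.tail = FALSE))
        else min(1, 2 * pwilcox(u, n1, n0))
      } else {
        sigma2 <- n1 * n0 / 12 *
          ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
        if (sigma2 <= 0) 1 else {
          z <- u - n1 * n0 / 2
          z <- (z - sign(z) * 0.5) / sqrt(sigma2)
          min(1, 2 * pnorm(-abs(z)))
        }
      }
      c(u = u, p = p, lfc = mean(v[in_g]) - mean(v[!in_g]))
    })
    res[[g]] <- data.frame(
      feature = colnames(x) %||% sprintf("f%d", seq_len(ncol(x))),
      group = g,
      logFC = stats_g["lfc", ],
      auc = stats_g["u", ] / (n1 * n0),
      p = stats_g["p", ],
      fdr = bh_fdr(stats_g["p", ]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

apply_features <- function(x, fn) {
  dense <- as.matrix(x)
  vapply(seq_len(ncol(dense)), function(j) fn(dense[, j]),
         FUN.VALUE = fn(dense[, 1]))
}

#' Promoter/gene concordance between two states
#'
#' Pairs each retained gene with one promoter peak — the one with the maximum
#' normalized accessibility summed across the pair's cells when several map
#' to the gene — and reports both modalities' differential statistics, with
#' FDR corrected separately within modalities over the retained pairs.
#' Genes/peaks detected (>= 1 UMI/fragment) in no more than `min_cells` cells
#' are excluded, as are genes without any promoter peak.
#'
#' @param gene_de,peak_de data.frames with `feature`, `p`, and an effect
#'   column named `logFC`/`effect`, computed between the two states.
#' @param peak_gene_map data.frame with `peak`, `gene`.
#' @param gene_mat,peak_mat normalized matrices over the pair's cells (used
#'   for detection filters and peak choice).
#' @param min_cells strict detection threshold (default 50).
#' @return data.frame per retained gene: `gene`, `peak`, `gene_effect`,
#'   `gene_fdr`, `peak_effect`, `peak_fdr`, `direction_agree`; attribute
#'   `n_dropped_no_peak`.
#' @export
promoter_gene_concordance <- function(gene_de, peak_de, peak_gene_map,
                                      gene_mat, peak_mat, min_cells = 50L) {
  eff_col <- function(df) intersect(c("logFC", "effect"), names(df))[1]
  gd <- as.data.frame(gene_de); pd <- as.data.frame(peak_de)
  det_gene <- Matrix::colSums(gene_mat > 0)
  det_peak <- Matrix::colSums(peak_mat > 0)
  acc_sum <- Matrix::colSums(peak_mat)
  map <- peak_gene_map[!is.na(peak_gene_map$gene) &
                         peak_gene_map$peak %in% colnames(peak_mat), ]
  genes <- intersect(gd$feature, colnames(gene_mat))
  genes <- genes[det_gene[genes] > min_cells]
  n_no_peak <- 0L
  rows <- list()
  for (g in genes) {
    cand <- map$peak[map$gene == g]
    cand <- cand[det_peak[cand] > min_cells]
    cand <- intersect(cand, pd$feature)
    if (!length(cand)) { n_no_peak <- n_no_peak + 1L; next }
    pk <- cand[which.max(acc_sum[cand])]
    rows[[g]] <- data.frame(
      gene = g, peak = pk,
      gene_effect = gd[[eff_col(gd)]][match(g, gd$feature)],
      gene_p = gd$p[match(g, gd$feature)],
      peak_effect = pd[[eff_col(pd)]][match(pk, pd$feature)],
      peak_p = pd$p[match(pk, pd$feature)],
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(structure(data.frame(), n_dropped_no_peak = n_no_peak))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$gene_fdr <- bh_fdr(out$gene_p)
  out$peak_fdr <- bh_fdr(out$peak_p)
  out$direction_agree <- sign(out$gene_effect) == sign(out$peak_effect)
  attr(out, "n_dropped_no_peak") <- n_no_peak
  out
}
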