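#' Cross-modal k-nearest-neighbor classification
#'
#' Each query cell takes the most common label among its `k` nearest
#' reference neighbors (Euclidean distance in a shared embedding). Vote ties
#' are broken by the nearest neighbor's label. With `k = 5`, a mapping is
#' high-confidence when at least 3 of the 5 neighbors agree. The direction is
#' reversible: states can be transferred onto multiome cells or chromatin
#' classes onto reference cells by swapping the roles.
#'
#' @param reference_embedding,query_embedding coordinate matrices in the same
#'   space.
#' @param reference_labels labels of the reference cells.
#' @param k number of neighbors (default 5).
#' @param conf_votes votes required for high confidence (default 3 when
#'   `k = 5`, otherwise strict majority).
#' @return data.frame with `predicted`, `vote_count`, `high_confidence`.
#' @export
knn_classify <- function(reference_embedding, reference_labels,
                         query_embedding, k = 5L, conf_votes = NULL) {
  ref <- as_embedding(reference_embedding)$coordinates
  qry <- as_embedding(query_embedding)$coordinates
  if (k < 1L || k > nrow(ref)) stop("`k` must lie in [1, reference size]")
  if (length(reference_labels) != nrow(ref))
    stop("labels must align with the reference")
  if (is.null(conf_votes))
    conf_votes <- if (k == 5L) 3L else floor(k / 2) + 1L
  nn <- knn_indices(qry, ref, k)
  lab <- matrix(as.character(reference_labels)[nn], nrow(qry), k)
  res <- apply(lab, 1, function(r) {
    tab <- sort(table(r), decreasing = TRUE)
    winners <- names(tab)[tab == tab[1]]
    pick <- if (length(winners) == 1L) winners else
      r[match(TRUE, r %in% winners)]  # nearest neighbor among tied labels
    c(pick, tab[1])
  })
  data.frame(predicted = res[1, ],
             vote_count = as.integer(res[2, ]),
             high_confidence = as.integer(res[2, ]) >= conf_votes,
             row.names = rownames(qry) %||% NULL,
             stringsAsFactors = FALSE)
}

#' Fisher exact test with conditional-MLE odds ratio
#'
#' Exact two-sided p-value (minimum-likelihood rule, relative tolerance
#' `1 + 1e-7` for ties) and the conditional maximum-likelihood estimate of
#' the odds ratio under the noncentral hypergeometric model, solved to high
#' precision by matching the conditional expectation to the observed count.
#'
#' @param x 2x2 integer matrix (or vector `a, b, c, d` filled by row).
#' @return list with `or` (conditional MLE; may be 0 or `Inf`), `p`
#'   (two-sided), and the table margins.
#' @export
fisher_exact_or <- function(x) {
  x <- matrix(as.numeric(x), 2, 2, byrow = !is.matrix(x))
  if (any(x < 0) || any(x != round(x))) stop("table must hold counts")
  a <- x[1, 1]
  m1 <- x[1, 1] + x[1, 2]; m2 <- x[2, 1] + x[2, 2]
  n1 <- x[1, 1] + x[2, 1]
  lo <- max(0, n1 - m2); hi <- min(n1, m1)
  supp <- lo:hi
  d0 <- dhyper(supp, m1, m2, n1)
  p <- sum(d0[d0 <= d0[supp == a] * (1 + 1e-7)])
  p <- min(1, p)
  or <- if (lo == hi) NA_real_
  else if (a == lo) 0
  else if (a == hi) Inf
  else {
    lch <- lchoose(m1, supp) + lchoose(m2, n1 - supp)
    cond_mean <- function(t) {
      lw <- lch + supp * t
      w <- exp(lw - max(lw))
      sum(supp * w) / sum(w)
    }
    exp(uniroot(function(t) cond_mean(t) - a, c(-80, 80),
                tol = 1e-12)$root)
  }
  list(or = or, p = p, a = a, m1 = m1, m2 = m2, n1 = n1)
}

#' Class x state odds-ratio matrix (superstate test)
#'
#' For every chromatin class / transcriptional state pair, a 2x2 contingency
#' table of cells in/out of the class and in/out of the state yields a
#' conditional-MLE odds ratio and Fisher exact two-sided p-value; BH FDR is
#' applied across all computed pairs. States with `min_state_cells` cells or
#' fewer are excluded. For display, the natural-log OR of an infinite (or
#' zero) estimate is capped at plus (minus) `1 + ceiling(max finite |log
#' OR|)` in the table.
#'
#' @param class_labels,state_labels aligned per-cell labels.
#' @param min_state_cells states must exceed this cell count (default 10).
#' @param fdr_alpha significance level on the BH FDR (default 0.05).
#' @return data.frame of class `"or_table"`: `class`, `state`, `or`, `p`,
#'   `fdr`, `log_or_display`, `significant`, the 2x2 counts, and attributes
#'   `cap` and `fdr_alpha`.
#' @export
class_state_or_matrix <- function(class_labels, state_labels,
                                  min_state_cells = 10L, fdr_alpha = 0.05) {
  if (length(class_labels) != length(state_labels))
    stop("labels must be aligned per cell")
  class_labels <- as.character(class_labels)
  state_labels <- as.character(state_labels)
  st_sizes <- table(state_labels)
  states <- names(st_sizes)[st_sizes > min_state_cells]
  dropped <- setdiff(names(st_sizes), states)
  if (length(dropped))
    warning("state(s) with <= ", min_state_cells, " cells excluded: ",
            paste(dropped, collapse = ", "))
  classes <- sort(unique(class_labels))
  states <- sort(states)
  rows <- list()
  for (cl in classes) for (st in states) {
    a <- sum(class_labels == cl & state_labels == st)
    b <- sum(class_labels == cl & state_labels != st)
    c_ <- sum(class_labels != cl & state_labels == st)
    d <- sum(class_labels != cl & state_labels != st)
    ft <- fisher_exact_or(matrix(c(a, b, c_, d), 2, byrow = TRUE))
    rows[[paste(cl, st)]] <- data.frame(
      class = cl, state = st, or = ft$or, p = ft$p,
      n11 = a, n12 = b, n21 = c_, n22 = d, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res$fdr <- bh_fdr(res$p)
  lo <- log(res$or)
  finite <- is.finite(lo) & !is.na(lo)
  cap <- if (any(finite)) 1 + ceiling(max(abs(lo[finite]))) else 1
  res$log_or_display <- ifelse(is.na(lo), NA_real_,
                        ifelse(lo == Inf, cap,
                        ifelse(lo == -Inf, -cap, lo)))
  res$significant <- res$fdr < fdr_alpha
  attr(res, "cap") <- cap
  attr(res, "fdr_alpha") <- fdr_alpha
  class(res) <- c("or_table", "data.frame")
  res
}

# area under the ROC curve from scores (rank/U-statistic form, tie-aware)
auc_scores <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# two-class linear discriminant scores with a pooled-covariance ridge
ridge_lda_scores <- function(xtr, ytr, xte, ridge = 1e-6) {
  m1 <- colMeans(xtr[ytr, , drop = FALSE])
  m0 <- colMeans(xtr[!ytr, , drop = FALSE])
  s <- (crossprod(sweep(xtr[ytr, , drop = FALSE], 2, m1)) +
        crossprod(sweep(xtr[!ytr, , drop = FALSE], 2, m0))) /
    (nrow(xtr) - 2)
  s <- s + diag(ridge * mean(diag(s)), ncol(s))
  w <- solve(s, m1 - m0)
  drop(xte %*% w)
}

#' Pairwise LDA discriminability of transcriptional states in chromatin space
#'
#' For each unordered pair of states, a two-class LDA is trained on a
#' stratified 75% of cells predicting state from the chromatin embedding
#' (hPCs) plus one-hot sample and scaled log10 fragment-count covariates, and
#' scored by the AUC of posterior scores on the held-out 25%. Pairs in which
#' either state has fewer than `min_cells` cells are skipped, as are pairs
#' whose design degenerates even under a ridge fallback.
#'
#' @param embedding fine-grain chromatin embedding (10 hPCs) or matrix.
#' @param state_labels,sample_labels,n_fragments aligned per-cell data.
#' @param train_frac training fraction (default 0.75).
#' @param min_cells minimum cells per state (default 50).
#' @param seed integer seed for the splits.
#' @param state_class optional named map state -> class used to flag
#'   within-class pairs.
#' @return list of class `"auc_table"`: `pairs` data.frame (`state_a`,
#'   `state_b`, `auc`, `skipped`, `within_class`), symmetric `auc_matrix`
#'   with `NA` diagonal.
#' @export
pairwise_lda_auc <- function(embedding, state_labels, sample_labels,
                             n_fragments, train_frac = 0.75, min_cells = 50L,
                             seed = 1L, state_class = NULL) {
  co <- as_embedding(embedding)$coordinates
  state_labels <- as.character(state_labels)
  sample_labels <- as.character(sample_labels)
  states <- sort(unique(state_labels))
  sizes <- table(state_labels)
  pairs <- t(utils::combn(states, 2))
  out <- vector("list", nrow(pairs))
  for (ip in seq_len(nrow(pairs))) {
    s1 <- pairs[ip, 1]; s2 <- pairs[ip, 2]
    within <- if (!is.null(state_class))
      unname(state_class[s1] == state_class[s2]) else NA
    if (sizes[s1] < min_cells || sizes[s2] < min_cells) {
      out[[ip]] <- data.frame(state_a = s1, state_b = s2, auc = NA_real_,
                              skipped = TRUE, within_class = within)
      next
    }
    idx <- which(state_labels %in% c(s1, s2))
    y <- state_labels[idx] == s2
    xd <- cbind(co[idx, , drop = FALSE],
                one_hot(sample_labels[idx]),
                lognfrag = drop(scale(log10(pmax(n_fragments[idx], 1)))))
    keep <- apply(xd, 2, function(v) var(v) > 0 && all(is.finite(v)))
    xd <- xd[, keep, drop = FALSE]
    if (!ncol(xd)) {
      out[[ip]] <- data.frame(state_a = s1, state_b = s2, auc = NA_real_,
                              skipped = TRUE, within_class = within)
      next
    }
    split <- with_seed(seed, paste("lda", s1, s2), {
      tr <- logical(length(idx))
      for (g in list(which(y), which(!y)))
        tr[g[sample.int(length(g), max(1L, round(train_frac * length(g))))]] <- TRUE
      tr
    })
    auc <- tryCatch({
      fit <- MASS::lda(xd[split, , drop = FALSE],
                       grouping = factor(y[split]))
      post <- predict(fit, xd[!split, , drop = FALSE])$posterior[, "TRUE"]
      auc_scores(post, y[!split])
    }, error = function(e) {
      tryCatch(auc_scores(ridge_lda_scores(xd[split, , drop = FALSE],
                                           y[split],
                                           xd[!split, , drop = FALSE]),
                          y[!split]),
               error = function(e2) NA_real_)
    })
    out[[ip]] <- data.frame(state_a = s1, state_b = s2, auc = auc,
                            skipped = is.na(auc), within_class = within)
  }
  pairs_df <- do.call(rbind, out)
  m <- matrix(NA_real_, length(states), length(states),
              dimnames = list(states, states))
  for (i in seq_len(nrow(pairs_df))) {
    m[pairs_df$state_a[i], pairs_df$state_b[i]] <- pairs_df$auc[i]
    m[pairs_df$state_b[i], pairs_df$state_a[i]] <- pairs_df$auc[i]
  }
  structure(list(pairs = pairs_df, auc_matrix = m, seed = seed,
                 min_cells = min_cells, train_frac = train_frac),
            class = "auc_table")
}

one_hot <- function(f) {
  f <- factor(f)
  if (nlevels(f) < 2L)
    return(matrix(numeric(0), length(f), 0))
  m <- model.matrix(~f)[, -1, drop = FALSE]
  colnames(m) <- paste0("sample_", levels(f)[-1])
  m
}

#' Mean pairwise AUC within versus across chromatin classes
#'
#' Averages non-skipped pairwise AUCs partitioned by whether the two states
#' share a chromatin class. Under the superstate model the within-class mean
#' is expected to be markedly lower.
#'
#' @param auc an `"auc_table"` from [pairwise_lda_auc()] (or its `pairs`
#'   data.frame).
#' @param state_class named map state -> class (may be omitted if the pairs
#'   already carry `within_class`).
#' @return list with `mean_within`, `mean_across`, `n_within`, `n_across`;
#'   means are `NA` when a partition has no pairs.
#' @export
within_across_summary <- function(auc, state_class = NULL) {
  pairs <- if (inherits(auc, "auc_table")) auc$pairs else as.data.frame(auc)
  if (!is.null(state_class))
    pairs$within_class <- unname(state_class[pairs$state_a] ==
                                   state_class[pairs$state_b])
  ok <- !pairs$skipped & !is.na(pairs$auc)
  w <- ok & pairs$within_class
  a <- ok & !pairs$within_class
  list(mean_within = if (any(w)) mean(pairs$auc[w]) else NA_real_,
       mean_across = if (any(a)) mean(pairs$auc[a]) else NA_real_,
       n_within = sum(w), n_across = sum(a))
}

#' Per-class correlation of donor proportions between two sources
#'
#' Donors failing the minimum cell count in either source are dropped; the
#' remaining donors' per-class proportions are correlated (Pearson, two-sided
#' p).
#'
#' @param counts_a,counts_b donor x class cell-count matrices from the two
#'   sources with matching donors and classes.
#' @param min_cells minimum cells per donor in each source (default 200; 100
#'   is used for rare cell types such as endothelium).
#' @return data.frame per class: `class`, `r`, `p`, `n_donors`,
#'   `p_unreliable` (fewer than 3 donors).
#' @export
class_proportion_correlation <- function(counts_a, counts_b,
                                         min_cells = 200L) {
  counts_a <- as.matrix(counts_a); counts_b <- as.matrix(counts_b)
  stopifnot(all(rownames(counts_a) == rownames(counts_b)),
            all(colnames(counts_a) == colnames(counts_b)))
  keep <- rowSums(counts_a) >= min_cells & rowSums(counts_b) >= min_cells
  pa <- counts_a[keep, , drop = FALSE] / rowSums(counts_a[keep, , drop = FALSE])
  pb <- counts_b[keep, , drop = FALSE] / rowSums(counts_b[keep, , drop = FALSE])
  n <- sum(keep)
  res <- lapply(colnames(pa), function(cl) {
    if (n >= 3 && sd(pa[, cl]) > 0 && sd(pb[, cl]) > 0) {
      ct <- cor.test(pa[, cl], pb[, cl])
      data.frame(class = cl, r = unname(ct$estimate), p = ct$p.value,
                 n_donors = n, p_unreliable = FALSE)
    } else {
      r <- if (n >= 2) suppressWarnings(cor(pa[, cl], pb[, cl])) else NA_real_
      data.frame(class = cl, r = r, p = NA_real_, n_donors = n,
                 p_unreliable = TRUE)
    }
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
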