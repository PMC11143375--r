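#' log(TF x IDF) normalization of a binarized peak matrix
#'
#' `value_ij = log(1 + s * TF_ij * IDF_j)` with `TF_ij = x_ij / rowSum_i`,
#' `IDF_j = n_cells / colSum_j`, and scale `s = 1e4`. The dialect is recorded
#' as an attribute so alternative TF-IDF conventions can be compared.
#'
#' @param x binary (0/1) cell x peak matrix, dense or sparse.
#' @param scale_factor the `s` above.
#' @return sparse normalized matrix with attribute `"tfidf_dialect"`.
#' @export
tfidf_normalize <- function(x, scale_factor = 1e4) {
  x <- methods::as(Matrix::Matrix(x, sparse = TRUE), "CsparseMatrix")
  if (length(x@x) && (max(x@x) > 1 || min(x@x) < 0))
    stop("matrix must be binarized (0/1)")
  rs <- Matrix::rowSums(x)
  cs <- Matrix::colSums(x)
  if (any(cs == 0))
    stop("column(s) with zero total; filter features first")
  if (any(rs == 0)) warning("all-zero row(s) produce all-zero output")
  tf <- Matrix::Diagonal(x = ifelse(rs > 0, 1 / rs, 0)) %*% x
  tfidf <- tf %*% Matrix::Diagonal(x = nrow(x) / cs)
  tfidf@x <- log1p(scale_factor * tfidf@x)
  tfidf <- methods::as(tfidf, "CsparseMatrix")
  dimnames(tfidf) <- dimnames(x)
  attr(tfidf, "tfidf_dialect") <- sprintf("log1p(%g*TF*IDF)", scale_factor)
  tfidf
}

#' Variance-stabilized variable-feature selection
#'
#' Ranks features by the variance of clipped standardized values under a
#' mean-variance trend (VST style): a lowess fit of log10 variance on log10
#' mean gives each feature an expected standard deviation; values are
#' standardized with it, clipped at `sqrt(n_cells)`, and the variance of the
#' clipped values is the ranking statistic.
#'
#' @param x cell x feature matrix (counts or normalized values).
#' @param n_features number of features to select.
#' @return integer indices of the top features, highest standardized
#'   variance first.
#' @export
select_variable_features <- function(x, n_features) {
  if (n_features <= 0) stop("`n_features` must be positive")
  n_features <- min(n_features, ncol(x))
  n <- nrow(x)
  mu <- Matrix::colMeans(x)
  v <- col_vars(x, mu)
  use <- v > 0 & mu > 0
  std_var <- numeric(ncol(x))
  if (any(use)) {
    fit <- lowess(log10(mu[use]), log10(v[use]), f = 0.3)
    exp_sd <- sqrt(10^approx(fit$x, fit$y, xout = log10(mu[use]),
                             rule = 2, ties = "mean")$y)
    clip <- sqrt(n)
    xs <- as.matrix(x[, use, drop = FALSE])
    z <- sweep(sweep(xs, 2, mu[use]), 2, exp_sd, "/")
    z <- pmin(pmax(z, -clip), clip)
    std_var[use] <- apply(z, 2, var)
  }
  order(std_var, decreasing = TRUE)[seq_len(n_features)]
}

col_vars <- function(x, mu = Matrix::colMeans(x)) {
  n <- nrow(x)
  (Matrix::colSums(x^2) - n * mu^2) / (n - 1)
}

#' @importFrom stats lowess
NULL

#' PCA embedding of scaled features
#'
#' Features are centered and scaled to unit variance across cells, then a
#' truncated PCA is computed via the eigendecomposition of the feature
#' covariance. Component signs are fixed so that each loading's largest-
#' magnitude entry is positive, making the embedding deterministic.
#'
#' @param x cell x feature matrix (selected features).
#' @param n_components number of components (20 for broad cell type
#'   clustering, 10 for fine-grain chromatin classes).
#' @param seed integer seed (recorded; the decomposition itself is
#'   deterministic).
#' @return list of class `"superstate_embedding"`: `coordinates`
#'   (cells x components), `loadings`, `sdev`, `n_components`,
#'   `batch_adjusted`.
#' @export
compute_embedding <- function(x, n_components, seed = 1L) {
  if (n_components > min(dim(x)))
    stop("`n_components` exceeds matrix rank bound")
  xs <- as.matrix(x)
  mu <- colMeans(xs)
  sdv <- apply(xs, 2, sd)
  sdv[sdv == 0] <- 1
  xs <- sweep(sweep(xs, 2, mu), 2, sdv, "/")
  cv <- crossprod(xs) / (nrow(xs) - 1)
  eig <- eigen(cv, symmetric = TRUE)
  k <- seq_len(n_components)
  load <- eig$vectors[, k, drop = FALSE]
  flip <- apply(load, 2, function(v) sign(v[which.max(abs(v))]))
  load <- sweep(load, 2, flip, "*")
  coords <- xs %*% load
  colnames(coords) <- paste0("PC", k)
  rownames(coords) <- rownames(x)
  structure(list(coordinates = coords, loadings = load,
                 sdev = sqrt(pmax(eig$values[k], 0)),
                 n_components = n_components,
                 batch_adjusted = FALSE, seed = seed),
            class = "superstate_embedding")
}

#' Batch adjustment of an embedding
#'
#' Contract: after adjustment, the per-sample mean of every component equals
#' the global mean. The default method is per-sample centering — explicitly a
#' simple stand-in for mixture-model harmonization; an externally adjusted
#' embedding can be injected via `method = "external"`.
#'
#' @param embedding a [compute_embedding()] result or a bare coordinate
#'   matrix.
#' @param sample per-cell sample labels.
#' @param method `"center"` (default), `"none"`, or `"external"` with
#'   `external` supplying the adjusted coordinates.
#' @param external adjusted coordinate matrix for `method = "external"`.
#' @return the embedding with adjusted coordinates, `batch_adjusted = TRUE`.
#' @export
adjust_batch <- function(embedding, sample, method = c("center", "none",
                                                       "external"),
                         external = NULL) {
  method <- match.arg(method)
  emb <- as_embedding(embedding)
  co <- emb$coordinates
  if (length(sample) != nrow(co))
    stop("`sample` must label every cell")
  if (method == "none") return(emb)
  if (method == "external") {
    stopifnot(!is.null(external), all(dim(external) == dim(co)))
    emb$coordinates <- external
    emb$batch_adjusted <- TRUE
    return(emb)
  }
  sample <- as.character(sample)
  sizes <- table(sample)
  singletons <- names(sizes)[sizes == 1L]
  if (length(singletons))
    warning("sample(s) with one cell passed through unadjusted: ",
            paste(singletons, collapse = ", "))
  gmean <- colMeans(co)
  for (s in setdiff(names(sizes), singletons)) {
    i <- which(sample == s)
    co[i, ] <- sweep(co[i, , drop = FALSE], 2,
                     colMeans(co[i, , drop = FALSE]) - gmean)
  }
  emb$coordinates <- co
  emb$batch_adjusted <- TRUE
  emb
}

as_embedding <- function(x) {
  if (inherits(x, "superstate_embedding")) return(x)
  structure(list(coordinates = as.matrix(x),
                 n_components = ncol(x), batch_adjusted = FALSE),
            class = "superstate_embedding")
}

# k nearest neighbors by Euclidean distance (brute force, blockwise).
knn_indices <- function(query, ref, k, exclude_self = FALSE) {
  query <- as.matrix(query); ref <- as.matrix(ref)
  rn <- rowSums(ref^2)
  out <- matrix(0L, nrow(query), k)
  block <- max(1L, floor(2e7 / nrow(ref)))
  for (b in split(seq_len(nrow(query)), ceiling(seq_len(nrow(query)) / block))) {
    d2 <- outer(rowSums(query[b, , drop = FALSE]^2), rn, "+") -
      2 * tcrossprod(query[b, , drop = FALSE], ref)
    if (exclude_self) d2[cbind(seq_along(b), b)] <- Inf
    out[b, ] <- t(apply(d2, 1, function(r) order(r)[seq_len(k)]))
  }
  out
}

#' Shared-nearest-neighbor graph and Louvain clustering
#'
#' Builds a kNN graph, weights edges by the Jaccard similarity of neighbor
#' sets, prunes weights below `prune`, and optimizes modularity with Louvain
#' at the given resolution. Labels are contiguous integers ordered by
#' descending cluster size (largest cluster is 0).
#'
#' @param embedding embedding or coordinate matrix.
#' @param k_neighbors neighbors per cell (default 20).
#' @param resolution Louvain resolution.
#' @param prune minimum retained Jaccard weight (default 1/15).
#' @param seed integer seed fixing Louvain's tie-breaking.
#' @return list of class `"cluster_labels"`: `label` (integer per cell),
#'   `resolution`, `k_neighbors`, `prune`, `seed`.
#' @export
snn_louvain <- function(embedding, k_neighbors = 20L, resolution = 0.8,
                        prune = 1 / 15, seed = 1L) {
  co <- as_embedding(embedding)$coordinates
  n <- nrow(co)
  if (k_neighbors >= n) stop("`k_neighbors` must be below the cell count")
  nn <- knn_indices(co, co, k_neighbors, exclude_self = TRUE)
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), k_neighbors),
                              j = as.vector(nn), x = 1, dims = c(n, n))
  diag(adj) <- 1  # include self so Jaccard matches neighbor-set convention
  shared <- Matrix::tcrossprod(adj)
  ksz <- k_neighbors + 1L
  snn <- shared
  snn@x <- snn@x / (2 * ksz - snn@x)
  snn@x[snn@x < prune] <- 0
  snn <- Matrix::drop0(snn)
  diag(snn) <- 0
  snn <- Matrix::drop0(snn)
  g <- igraph::graph_from_adjacency_matrix(snn, mode = "max", weighted = TRUE)
  lab <- with_seed(seed, "louvain", {
    cl <- igraph::cluster_louvain(g, resolution = resolution)
    igraph::membership(cl)
  })
  deg <- igraph::degree(g)
  if (any(deg == 0) && length(unique(lab)) > 1L) {
    warning(sum(deg == 0), " disconnected cell(s) assigned to the nearest ",
            "cluster by centroid distance")
    cent <- do.call(rbind, lapply(split(seq_len(n), lab), function(i)
      colMeans(co[i, , drop = FALSE])))
    for (i in which(deg == 0)) {
      d2 <- rowSums(sweep(cent, 2, co[i, ])^2)
      lab[i] <- as.integer(rownames(cent)[which.min(d2)])
    }
  }
  sizes <- sort(table(lab), decreasing = TRUE)
  relab <- setNames(seq_along(sizes) - 1L, names(sizes))
  structure(list(label = unname(relab[as.character(lab)]),
                 resolution = resolution, k_neighbors = k_neighbors,
                 prune = prune, seed = seed),
            class = "cluster_labels")
}

#' Chromatin-class clustering pipeline
#'
#' The standard chain for one cell type: binarize, PMA filter, TF-IDF,
#' variable features, scale + PCA, batch adjustment, SNN + Louvain.
#'
#' @param counts cell x peak count matrix.
#' @param sample per-cell sample labels.
#' @param n_components PCs to keep (10 for fine-grain chromatin classes).
#' @param n_features variable features to keep.
#' @param pma_frac,pma_min_cells PMA filter parameters
#'   (see [select_pma_peaks()]).
#' @param k_neighbors,resolution,prune clustering parameters (see
#'   [snn_louvain()]); the fine-grain default resolution 0.1 targets
#'   class-level granularity, mirroring the marker-guided resolution choice
#'   used when classes carry finer substructure (e.g. the CD4/CD8 lineage
#'   axis).
#' @param batch_method passed to [adjust_batch()].
#' @param seed integer seed.
#' @return list with `labels` ([snn_louvain()] result), `embedding`,
#'   `pma_mask`, `variable_features`.
#' @export
cluster_chromatin <- function(counts, sample, n_components = 10L,
                              n_features = 1000L, pma_frac = 0.005,
                              pma_min_cells = NULL, k_neighbors = 20L,
                              resolution = 0.1, prune = 1 / 15,
                              batch_method = "center", seed = 1L) {
  bin <- binarize_counts(counts)
  pma <- select_pma_peaks(bin, frac = pma_frac, min_cells = pma_min_cells)
  norm <- tfidf_normalize(bin[, pma, drop = FALSE])
  vf <- select_variable_features(norm, n_features)
  emb <- compute_embedding(norm[, vf, drop = FALSE], n_components, seed = seed)
  emb <- adjust_batch(emb, sample, method = batch_method)
  labels <- snn_louvain(emb, k_neighbors = k_neighbors,
                        resolution = resolution, prune = prune, seed = seed)
  list(labels = labels, embedding = emb, pma_mask = pma,
       variable_features = vf)
}

#' Binarize a count matrix
#' @param x count matrix.
#' @return sparse 0/1 matrix of the same shape.
#' @export
binarize_counts <- function(x) {
  b <- methods::as(Matrix::Matrix(x, sparse = TRUE), "CsparseMatrix")
  b@x <- as.numeric(b@x > 0)
  Matrix::drop0(b)
}

#' Adjusted Rand index between two partitions
#'
#' Hubert-Arabie adjusted-for-chance agreement, used to compare recovered
#' chromatin classes with ground-truth labels.
#'
#' @param a,b two label vectors of equal length.
#' @return the adjusted Rand index (1 = identical partitions).
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  nn <- choose(sum(tab), 2)
  expected <- ai * bj / nn
  denom <- (ai + bj) / 2 - expected
  if (denom == 0) return(1)
  (nij - expected) / denom
}
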