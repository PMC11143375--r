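# Independent brute-force oracles used across tests. These deliberately take
# the slow, obvious route so they share no code path with the package.

# Greedy-by-q peak consolidation: trim, sort by (q, chrom, start), keep a
# candidate only if it overlaps no kept peak (full scan).
oracle_trim_dedup <- function(sub_peaks) {
  start <- pmax(0L, sub_peaks$summit - 100L)
  cand <- data.frame(chrom = sub_peaks$chrom, start = start,
                     end = start + 200L, q = sub_peaks$q,
                     stringsAsFactors = FALSE)
  cand <- cand[order(cand$q, cand$chrom, cand$start), ]
  kept <- cand[0, ]
  for (i in seq_len(nrow(cand))) {
    ov <- kept$chrom == cand$chrom[i] &
      kept$start < cand$end[i] & cand$start[i] < kept$end
    if (!any(ov)) kept <- rbind(kept, cand[i, ])
  }
  kept <- kept[order(kept$chrom, kept$start), ]
  rownames(kept) <- NULL
  kept
}

# all-pairs fragment x peak overlap count
oracle_count_overlaps <- function(fragments, peaks, barcodes) {
  m <- matrix(0, length(barcodes), nrow(peaks),
              dimnames = list(barcodes, NULL))
  for (i in seq_len(nrow(fragments))) for (j in seq_len(nrow(peaks))) {
    if (fragments$chrom[i] == peaks$chrom[j] &&
        fragments$start[i] < peaks$end[j] &&
        peaks$start[j] < fragments$end[i])
      m[fragments$barcode[i], j] <- m[fragments$barcode[i], j] + 1
  }
  m
}

# dense TF-IDF recomputation, entry by entry
oracle_tfidf <- function(x, s = 1e4) {
  x <- as.matrix(x)
  out <- matrix(0, nrow(x), ncol(x))
  for (i in seq_len(nrow(x))) for (j in seq_len(ncol(x))) {
    if (x[i, j] > 0) {
      tf <- x[i, j] / sum(x[i, ])
      idf <- nrow(x) / sum(x[, j])
      out[i, j] <- log(1 + s * tf * idf)
    }
  }
  out
}

# noncentral hypergeometric enumeration: exact two-sided p at psi = 1 and
# conditional MLE by direct likelihood maximization over log-psi
oracle_fisher <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; n1 <- a + c
  lo <- max(0, n1 - m2); hi <- min(n1, m1)
  supp <- lo:hi
  w <- exp(lchoose(m1, supp) + lchoose(m2, n1 - supp))
  d0 <- w / sum(w)
  p <- sum(d0[d0 <= d0[supp == a] * (1 + 1e-7)])
  or <- if (lo == hi) NA_real_
  else if (a == lo) 0 else if (a == hi) Inf
  else {
    # stationarity of the noncentral hypergeometric log-likelihood:
    # d/dt log L = a - E[X; e^t]; solve by plain bisection
    lch <- lchoose(m1, supp) + lchoose(m2, n1 - supp)
    score <- function(t) {
      lw <- lch + supp * t
      w <- exp(lw - max(lw))
      a - sum(supp * w) / sum(w)
    }
    tl <- -60; tu <- 60
    for (it in 1:90) {
      tm <- (tl + tu) / 2
      if (score(tm) > 0) tl <- tm else tu <- tm
    }
    exp((tl + tu) / 2)
  }
  list(or = or, p = min(1, p))
}

# exact upper-tail hypergeometric by summing binomial products
oracle_hyper_upper <- function(k, K, N, n) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# two-sided rank-sum p by full enumeration of group assignments
oracle_ranksum_p <- function(x, y) {
  v <- c(x, y); n1 <- length(x)
  r <- rank(v)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(v), n1)
  us <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * length(y) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# per-cell signed score by explicit loops
oracle_signed_score <- function(mat, pos, neg) {
  mat <- as.matrix(mat)
  out <- numeric(nrow(mat))
  for (i in seq_len(nrow(mat))) {
    sp <- 0; sn <- 0
    for (p in pos) sp <- sp + mat[i, p] / length(pos)
    for (q in neg) sn <- sn + mat[i, q] / length(neg)
    out[i] <- sp - sn
  }
  out
}
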