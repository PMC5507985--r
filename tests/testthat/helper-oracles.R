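# Independent brute-force oracles used to check the statistical kernels and
# the homology scan. These are deliberately naive re-derivations: they share
# no code path with the package implementations.

# exact two-sided WMW p by exhaustive enumeration of all group assignments
oracle_wmw_exact <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  u_of <- function(idx) {
    x <- pooled[idx]; y <- pooled[-idx]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  splits <- utils::combn(length(pooled), na)
  us <- apply(splits, 2, u_of)
  u_obs <- u_of(seq_len(na))
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# BH step-up: p_(i) * m / i with cumulative minimum from the largest rank
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(1, adj)[order(o)]
}

# Pearson r via the covariance/SD closed form and its t-transform p-value
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), n - 2))
}

# naive O(n^3) complete-linkage agglomeration; ties broken by the smallest
# (i, j) pair; returns merge heights (sorted) and the partition at every k
oracle_complete_linkage <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  partitions <- list()
  partitions[[n]] <- seq_len(n)
  while (length(clusters) > 1L) {
    m <- length(clusters)
    best <- c(Inf, NA, NA)
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      h <- max(d[clusters[[i]], clusters[[j]]])
      if (h < best[1] - 1e-12) best <- c(h, i, j)
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
    lab <- integer(n)
    for (k in seq_along(clusters)) lab[clusters[[k]]] <- k
    partitions[[length(clusters)]] <- lab
  }
  list(heights = heights, partitions = partitions)
}

# are two labelings the same partition (up to label names)?
same_partition <- function(a, b) {
  ca <- vapply(seq_along(a), function(i) min(which(a == a[i])), integer(1))
  cb <- vapply(seq_along(b), function(i) min(which(b == b[i])), integer(1))
  identical(ca, cb)
}

# exhaustive best-window oracle: for every relative alignment, every window
# is examined through cumulative mismatch sums (no two-pointer sweep)
oracle_best_window <- function(mir, tx, k) {
  p <- utf8ToInt(chartr("U", "T", toupper(mir)))
  s <- utf8ToInt(chartr("U", "T", toupper(tx)))
  L <- length(p); Ls <- length(s)
  best_len <- 0L
  for (d in (-(L - 1L)):(Ls - 1L)) {
    i_lo <- max(1L, 1L - d); i_hi <- min(L, Ls - d)
    if (i_hi < i_lo) next
    mism <- p[i_lo:i_hi] != s[(i_lo + d):(i_hi + d)]
    n <- length(mism)
    cs <- cumsum(c(0L, mism))
    for (len in n:1) {
      if (len <= best_len) break
      sums <- cs[(len + 1):(n + 1)] - cs[1:(n - len + 1)]
      if (any(sums <= k)) { best_len <- len; break }
    }
  }
  best_len
}

oracle_homology_flag <- function(mir, transcripts, min_frac, k) {
  w <- ceiling(min_frac * nchar(mir))
  any(vapply(transcripts, function(tx) oracle_best_window(mir, tx, k) >= w,
             logical(1)))
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# small annotation table around a set of sequences
toy_annotation <- function(seqs, versions = NULL) {
  data.frame(
    mirna_id = sprintf("toy-miR-%02d", seq_along(seqs)),
    mature_sequence = seqs,
    first_version = versions %||% rep(1L, length(seqs)),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
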