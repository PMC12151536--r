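# Independent brute-force oracles for the interval engine and the
# statistics, deliberately written against the definitions (per-base
# boolean masks, all-pairs scans, step-up enumeration) rather than the
# package's implementation.

# per-base boolean mask of a set restricted to one chromosome,
# positions 0..(len-1)
mask_of <- function(df, chrom, len) {
  m <- logical(len)
  df <- df[df$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(df))) {
    s <- max(0, df$start[i]); e <- min(len, df$end[i])
    if (e > s) m[(s + 1):e] <- TRUE
  }
  m
}

# covered runs of a mask as 0-based half-open intervals
runs_from_mask <- function(m, chrom = "chr1") {
  r <- rle(m)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  data.frame(chrom = rep(chrom, sum(keep)), start = starts[keep],
             end = ends[keep])
}

# definition oracle for merge with gap tolerance: union mask, then close
# every uncovered run of length <= gap lying between covered runs
oracle_merge <- function(df, gap, chrom = "chr1", len = 100000) {
  m <- mask_of(df, chrom, len)
  if (!any(m)) return(data.frame(chrom = character(), start = numeric(),
                                 end = numeric()))
  r <- rle(m)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths
  for (k in seq_along(r$values)) {
    if (!r$values[k] && k > 1 && k < length(r$values) &&
        r$lengths[k] <= gap)
      m[(starts[k] + 1):ends[k]] <- TRUE
  }
  runs_from_mask(m, chrom)
}

oracle_intersect <- function(a, b, chrom = "chr1", len = 100000) {
  runs_from_mask(mask_of(a, chrom, len) & mask_of(b, chrom, len), chrom)
}

# whole-interval filter: overlap bp of each query row against a subject
# table, all-pairs
oracle_filter <- function(query, subject, min_bp = 1) {
  keep <- vapply(seq_len(nrow(query)), function(i) {
    same <- subject$chrom == query$chrom[i]
    ov <- pmin(subject$end[same], query$end[i]) -
      pmax(subject$start[same], query$start[i])
    any(ov >= min_bp)
  }, logical(1))
  query[keep, , drop = FALSE]
}

# consensus oracle: merged-union runs, then per-run sample support
oracle_consensus <- function(dfs, min_samples, chrom = "chr1",
                             len = 100000) {
  pooled <- do.call(rbind, dfs)
  u <- runs_from_mask(mask_of(pooled, chrom, len), chrom)
  if (nrow(u) == 0) return(u)
  support <- rowSums(vapply(dfs, function(d) {
    vapply(seq_len(nrow(u)), function(i) {
      same <- d$chrom == u$chrom[i]
      any(pmin(d$end[same], u$end[i]) - pmax(d$start[same], u$start[i]) >= 1)
    }, logical(1))
  }, logical(nrow(u))))
  u[support >= min_samples, , drop = FALSE]
}

# random raw interval table on one chromosome
random_intervals <- function(n, len = 100000, max_w = 3000,
                             chrom = "chr1") {
  s <- sample.int(len - max_w, n, replace = TRUE) - 1
  w <- sample.int(max_w, n, replace = TRUE)
  data.frame(chrom = chrom, start = s, end = s + w,
             stringsAsFactors = FALSE)
}

# coordinate matrix in a fixed numeric storage mode, for exact
# comparisons between implementation and oracle outputs
coords <- function(df) {
  m <- unname(as.matrix(df[c("start", "end")]))
  storage.mode(m) <- "double"
  m
}

set_from_df <- function(df, canonical = FALSE) {
  interval_set(df$chrom, df$start, df$end, canonical = canonical)
}

# all-pairs window-association oracle
oracle_window_links <- function(enh_df, genes, window, anchor) {
  out <- list()
  for (i in seq_len(nrow(enh_df))) {
    for (j in seq_len(nrow(genes))) {
      if (enh_df$chrom[i] != genes$chrom[j]) next
      d <- if (anchor == "midpoint") {
        abs((enh_df$start[i] + enh_df$end[i]) / 2 - genes$tss[j])
      } else {
        if (genes$tss[j] >= enh_df$start[i] &&
            genes$tss[j] < enh_df$end[i]) 0
        else min(abs(enh_df$start[i] - genes$tss[j]),
                 abs(enh_df$end[i] - 1 - genes$tss[j]))
      }
      if (d <= window)
        out[[length(out) + 1]] <- data.frame(i = i,
                                             gene_id = genes$gene_id[j],
                                             distance = d)
    }
  }
  if (!length(out)) return(data.frame(i = integer(),
                                      gene_id = character(),
                                      distance = numeric()))
  do.call(rbind, out)
}

# reference Benjamini-Hochberg step-up, straight from the definition
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# hypergeometric enumeration for the 2x2 Fisher exact test (two-sided,
# summing all tables as or less probable than the observed one)
oracle_fisher <- function(tab) {
  m <- sum(tab[, 1]); n <- sum(tab[, 2]); k <- sum(tab[1, ])
  x <- tab[1, 1]
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p_obs <- stats::dhyper(x, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
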