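# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# window-by-window substring comparison motif scan (0-based positions)
naive_find_sites <- function(seq, motif) {
  L <- nchar(seq)
  k <- nchar(motif)
  if (L < k) return(integer())
  hits <- integer()
  for (i in seq_len(L - k + 1)) {
    if (substr(seq, i, i + k - 1) == motif) hits <- c(hits, i - 1L)
  }
  hits
}

# for each MspI cut, linear scan of all NlaIII cuts for nearest neighbors
naive_tags <- function(msp_cuts, nla_cuts) {
  out <- NULL
  for (mc in msp_cuts) {
    left <- nla_cuts[nla_cuts < mc]
    right <- nla_cuts[nla_cuts > mc]
    if (length(left))
      out <- rbind(out, c(max(left), mc))
    if (length(right))
      out <- rbind(out, c(mc, min(right)))
  }
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

# exhaustive-enumeration two-sided rank-sum P value (no ties assumed)
enum_wilcox_p <- function(a, b) {
  m <- length(a); n <- length(b)
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combos <- utils::combn(m + n, m)
  ws <- apply(combos, 2, function(ix) sum(rank(seq_len(m + n))[ix])) -
    m * (m + 1) / 2
  mu <- m * n / 2
  lo <- min(w_obs, 2 * mu - w_obs)
  hi <- max(w_obs, 2 * mu - w_obs)
  min(1, mean(ws <= lo) + mean(ws >= hi))
}

# direct Benjamini-Hochberg step-up
naive_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# straight-line re-implementation of the seed-and-extend region steps:
# (1) seed = first window of 5 consecutive sites (gaps <= 2000) with >= 4
# equal nonzero trends and pooled rank-sum P < 0.05; (2) extend downstream
# one same-trend site at a time, gap <= 2000, re-testing the incorporated
# region; (3) stop when P >= 0.05; (4) emit, resume after the region.
straightline_regions <- function(pos, case_mat, ctrl_mat, max_gap = 2000,
                                 alpha = 0.05) {
  n <- length(pos)
  trend <- numeric(n)
  for (i in seq_len(n))
    trend[i] <- sign(mean(case_mat[i, ]) - mean(ctrl_mat[i, ]))
  ptest <- function(ix) {
    suppressWarnings(stats::wilcox.test(as.vector(case_mat[ix, ]),
                                        as.vector(ctrl_mat[ix, ]),
                                        exact = FALSE,
                                        correct = TRUE)$p.value)
  }
  out <- NULL
  i <- 1
  while (i + 4 <= n) {
    ix <- i:(i + 4)
    gaps_ok <- all(diff(pos[ix]) <= max_gap)
    tr <- trend[ix]
    nup <- sum(tr == 1); ndn <- sum(tr == -1)
    if (!gaps_ok || max(nup, ndn) < 4) { i <- i + 1; next }
    maj <- if (nup >= ndn) 1 else -1
    if (ptest(ix) >= alpha) { i <- i + 1; next }
    last <- i + 4
    while (last + 1 <= n &&
           trend[last + 1] == maj &&
           pos[last + 1] - pos[last] <= max_gap &&
           ptest(i:(last + 1)) < alpha) {
      last <- last + 1
    }
    out <- rbind(out, c(start = pos[i], end = pos[last] + 4,
                        n_sites = last - i + 1, dir = maj))
    i <- last + 1
  }
  out
}

# random genome sequence with no CCGG/CATG unless stamped
random_clean_seq <- function(len) {
  repeat {
    s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
               collapse = "")
    if (!grepl("CCGG", s, fixed = TRUE) && !grepl("CATG", s, fixed = TRUE))
      return(s)
  }
}

# long-format count table from per-library matrices (sites x samples)
counts_from_matrices <- function(pos, L1, L2, L3, groups,
                                 chrom = "chr1") {
  samples <- colnames(L1)
  do.call(rbind, lapply(seq_along(samples), function(j) {
    data.frame(chrom = chrom, pos = pos, sample = samples[j],
               group = groups[j], L1 = L1[, j], L2 = L2[, j], L3 = L3[, j],
               stringsAsFactors = FALSE)
  }))
}
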