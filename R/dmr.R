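#' Wilcoxon rank-sum test P value
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum P value. Uses exact
#' enumeration when the pooled size is at most `exact_max` and there are
#' no ties, and the tie-corrected normal approximation (with continuity
#' correction) otherwise. Missing values are dropped.
#'
#' @param a,b numeric vectors (each with at least one non-missing value).
#' @param exact_max largest pooled sample size for the exact path.
#' @return two-sided P value.
#' @export
wilcoxon_rank_sum <- function(a, b, exact_max = 12) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) == 0 || length(b) == 0) stop("empty group")
  ex <- (length(a) + length(b)) <= exact_max && !anyDuplicated(c(a, b))
  suppressWarnings(
    stats::wilcox.test(a, b, exact = ex, correct = TRUE)$p.value)
}

#' Per-site change trend between groups
#'
#' Sign of the difference of group means of a site's modification level:
#' `+1` (case above control), `-1`, or `0` for an exact tie. A site with
#' no non-missing value in either group has no trend (`NA`).
#'
#' @param case,control per-sample levels of one site.
#' @return integer `-1`, `0`, `1`, or `NA`.
#' @export
site_trend <- function(case, control) {
  mc <- mean(case, na.rm = TRUE)
  mn <- mean(control, na.rm = TRUE)
  if (is.nan(mc) || is.nan(mn)) return(NA_integer_)
  as.integer(sign(mc - mn))
}

#' Detect differentially (hydroxy)methylated regions by seed-and-extend
#'
#' Scans each chromosome left to right over windows of `seed_size`
#' consecutive CCGG sites whose adjacent gaps are at most `max_gap` bp. A
#' window seeds a candidate region when at least `min_concordant` of its
#' sites share one nonzero change trend and the Wilcoxon rank-sum test on
#' the pooled member-site levels (all sites x all samples per group, or
#' per-site group means with `pool = "site_means"`) gives P below
#' `alpha`. The seed then extends one downstream site at a time while the
#' next site's trend matches the seed's majority trend, its gap to the
#' current last member is within `max_gap`, and the re-run pooled test on
#' the whole incorporated region keeps P below `alpha`. The first failing
#' site stops extension; the region is emitted and scanning resumes just
#' after it, so regions never overlap.
#'
#' @param levels long data.frame `chrom`, `pos`, `sample`, `group`
#'   (`"case"`/`"control"`), `level` (in `[0, 1]`, may be NA).
#' @param kind region label, `"DMR"` (5mC) or `"DhMR"` (5hmC).
#' @param max_gap maximum distance (bp) between adjacent member sites.
#' @param seed_size number of sites in the seed window.
#' @param min_concordant minimum seed sites sharing the majority trend.
#' @param alpha rank-sum significance threshold.
#' @param pool `"sites_by_samples"` pools every (site, sample) level per
#'   group into the test; `"site_means"` tests per-site group means.
#' @param min_presence a site observed in at most this fraction of either
#'   group's samples cannot be part of a seed.
#' @return data.frame of regions: `chrom`, `start`, `end` (half-open,
#'   spanning member CCGG motifs), `kind`, `direction`
#'   (`"hyper"`/`"hypo"` w.r.t. the case group), `n_sites`, `p_value`,
#'   and `member_sites` (list column of motif positions).
#' @export
find_regions <- function(levels, kind = c("DMR", "DhMR"), max_gap = 2000,
                         seed_size = 5, min_concordant = 4, alpha = 0.05,
                         pool = c("sites_by_samples", "site_means"),
                         min_presence = 0.5) {
  kind <- match.arg(kind)
  pool <- match.arg(pool)
  stopifnot(all(c("chrom", "pos", "sample", "group", "level") %in%
                  names(levels)),
            all(levels$group %in% c("case", "control")))
  grp <- unique(levels[, c("sample", "group")])
  if (length(unique(grp$group)) < 2) stop("both groups must be present")
  out <- lapply(split(levels, levels$chrom), function(lv) {
    .find_regions_chrom(lv, kind, max_gap, seed_size, min_concordant,
                        alpha, pool, min_presence)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), kind = character(),
                      direction = character(), n_sites = integer(),
                      p_value = numeric(),
                      member_sites = I(list()), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

.find_regions_chrom <- function(lv, kind, max_gap, seed_size,
                                min_concordant, alpha, pool, min_presence) {
  pos <- sort(unique(lv$pos))
  nS <- length(pos)
  if (nS < seed_size) return(NULL)
  samples <- unique(lv$sample)
  grp <- unname(setNames(lv$group, lv$sample)[samples])
  V <- matrix(NA_real_, nS, length(samples),
              dimnames = list(NULL, samples))
  V[cbind(match(lv$pos, pos), match(lv$sample, samples))] <- lv$level
  ic <- which(grp == "case")
  in_ <- which(grp == "control")

  trend <- vapply(seq_len(nS),
                  function(i) site_trend(V[i, ic], V[i, in_]),
                  integer(1))
  pres_ok <- rowMeans(!is.na(V[, ic, drop = FALSE])) > min_presence &
    rowMeans(!is.na(V[, in_, drop = FALSE])) > min_presence

  ptest <- function(idx) {
    if (pool == "sites_by_samples") {
      a <- as.vector(V[idx, ic, drop = FALSE])
      b <- as.vector(V[idx, in_, drop = FALSE])
    } else {
      a <- rowMeans(V[idx, ic, drop = FALSE], na.rm = TRUE)
      b <- rowMeans(V[idx, in_, drop = FALSE], na.rm = TRUE)
    }
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) == 0 || length(b) == 0) return(NA_real_)
    wilcoxon_rank_sum(a, b)
  }

  res <- list()
  i <- 1L
  while (i + seed_size - 1L <= nS) {
    idx <- i:(i + seed_size - 1L)
    if (any(diff(pos[idx]) > max_gap) || !all(pres_ok[idx])) {
      i <- i + 1L
      next
    }
    tr <- trend[idx]
    n_up <- sum(tr == 1L, na.rm = TRUE)
    n_dn <- sum(tr == -1L, na.rm = TRUE)
    if (max(n_up, n_dn) < min_concordant) {
      i <- i + 1L
      next
    }
    maj <- if (n_up >= n_dn) 1L else -1L
    p <- ptest(idx)
    if (is.na(p) || p >= alpha) {
      i <- i + 1L
      next
    }
    last <- i + seed_size - 1L
    while (last + 1L <= nS) {
      nxt <- last + 1L
      if (is.na(trend[nxt]) || trend[nxt] != maj) break
      if (pos[nxt] - pos[last] > max_gap) break
      p2 <- ptest(i:nxt)
      if (is.na(p2) || p2 >= alpha) break
      p <- p2
      last <- nxt
    }
    res[[length(res) + 1L]] <- data.frame(
      chrom = lv$chrom[1], start = pos[i], end = pos[last] + 4L,
      kind = kind, direction = if (maj == 1L) "hyper" else "hypo",
      n_sites = last - i + 1L, p_value = p,
      member_sites = I(list(pos[i:last])), stringsAsFactors = FALSE)
    i <- last + 1L
  }
  if (length(res) == 0) return(NULL)
  do.call(rbind, res)
}

#' Overlap between DhMRs and DMRs
#'
#' Counts DhMRs that intersect at least one DMR by one or more bp.
#'
#' @param dmrs,dhmrs region data.frames from [find_regions()].
#' @return list with `n_overlap` and `pct` (percentage of DhMRs, two
#'   decimals; `NA` when `dhmrs` is empty).
#' @export
overlap_stats <- function(dmrs, dhmrs) {
  if (nrow(dhmrs) == 0) return(list(n_overlap = 0L, pct = NA_real_))
  if (nrow(dmrs) == 0) return(list(n_overlap = 0L, pct = 0))
  gr_d <- GenomicRanges::GRanges(dmrs$chrom,
                                 IRanges::IRanges(dmrs$start + 1L, dmrs$end))
  gr_h <- GenomicRanges::GRanges(dhmrs$chrom,
                                 IRanges::IRanges(dhmrs$start + 1L, dhmrs$end))
  n <- sum(.ov_any(gr_h, gr_d))
  list(n_overlap = n, pct = round(100 * n / nrow(dhmrs), 2))
}

#' Write regions as BED6 plus a member-site table
#'
#' @param regions region data.frame from [find_regions()].
#' @param out_prefix path prefix; writes `<prefix>.bed` (name =
#'   `kind:direction`, score = `-log10(P)`) and `<prefix>_sites.tsv`.
#' @return invisibly, the paths written.
#' @export
write_regions <- function(regions, out_prefix) {
  bed <- paste0(out_prefix, ".bed")
  tsv <- paste0(out_prefix, "_sites.tsv")
  write.table(
    data.frame(regions$chrom, regions$start, regions$end,
               paste(regions$kind, regions$direction, sep = ":"),
               round(-log10(regions$p_value), 3), "."),
    bed, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  sites <- data.frame(
    region = rep(seq_len(nrow(regions)), lengths(regions$member_sites)),
    chrom = rep(regions$chrom, lengths(regions$member_sites)),
    pos = unlist(regions$member_sites))
  write.table(sites, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(bed, tsv))
}
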