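#' Estimate per-site modification fractions from three-library counts
#'
#' With `n1` = MspI/normal (C + mC + hmC), `n2` = MspI/glucosylated
#' (C + mC) and `n3` = HpaII/normal (C) tag counts at a CCGG site, the
#' unmodified fraction is `n3/n1`, the hydroxymethylated fraction is
#' `1 - n2/n1` and methylation takes the remainder. Each ratio is clipped
#' to `[0, 1]` and the triple renormalized to sum to one. Sites with
#' `n1 <= 0` are no-calls (all NA).
#'
#' @param n1,n2,n3 numeric vectors of (normalized) library counts.
#' @return data.frame with columns `u_hat`, `m_hat`, `h_hat`.
#' @examples
#' estimate_fractions(100, 50, 25)  # u 0.25, m 0.25, h 0.50
#' @export
estimate_fractions <- function(n1, n2, n3) {
  u <- clip(n3 / n1)
  h <- clip(1 - n2 / n1)
  m <- clip(1 - u - h)
  s <- u + m + h
  ok <- is.finite(n1) & n1 > 0 & s > 0
  out <- data.frame(u_hat = u / s, m_hat = m / s, h_hat = h / s)
  out[!ok, ] <- NA_real_
  out
}

#' Exact conditional Poisson rate-ratio test
#'
#' One-sided test that the rate underlying count `x` (library-size factor
#' `sx`) exceeds the rate underlying `y` (factor `sy`). Conditional on the
#' total, `x | x + y ~ Binomial(x + y, sx / (sx + sy))` under the null of
#' equal rates; the upper-tail probability is returned. All arguments are
#' vectorized.
#'
#' @param x,y non-negative counts.
#' @param sx,sy positive library-size factors (raw scale relative to the
#'   normalized scale).
#' @return upper-tail P values; `x + y == 0` gives 1 by convention.
#' @export
poisson_ratio_test <- function(x, y, sx = 1, sy = 1) {
  stopifnot(all(x >= 0, na.rm = TRUE), all(y >= 0, na.rm = TRUE),
            all(sx > 0), all(sy > 0))
  n <- x + y
  p0 <- sx / (sx + sy)
  p <- stats::pbinom(x - 1, n, p0, lower.tail = FALSE)
  p[n == 0] <- 1
  p
}

#' Call significantly methylated and hydroxymethylated CCGG sites
#'
#' Per site and sample, tests 5hmC presence by comparing L1 (C+mC+hmC)
#' against L2 (C+mC) and 5mC presence by comparing L2 against L3 (C) with
#' the exact conditional rate-ratio test on raw counts, using the
#' normalization's effective library-size factors. P values are
#' Benjamini-Hochberg adjusted per sample and per modification over all
#' testable sites. A site is called significant when the raw L1 depth
#' exceeds `depth_min`, the normalized library ratio exceeds 1 and the
#' adjusted value is below `fdr`.
#'
#' @param norm result of [grsn_normalize()].
#' @param raw the raw count data.frame that was normalized.
#' @param depth_min minimum raw L1 count (sequencing depth gate).
#' @param fdr FDR threshold on BH-adjusted P values.
#' @return data.frame with one row per (site, sample): the estimated
#'   fractions, depth, P/q values and significance flags.
#' @export
call_sites <- function(norm, raw, depth_min = 10, fdr = 0.001) {
  stopifnot(inherits(norm, "hmst_norm"))
  v <- norm$values
  key <- paste(v$chrom, v$pos, v$sample)
  rkey <- paste(raw$chrom, raw$pos, raw$sample)
  raw <- raw[match(key, rkey), ]
  sf <- norm$scale_factors
  sfm <- matrix(sf$scale_factor,
                nrow = length(unique(sf$sample)),
                dimnames = list(unique(sf$sample), c("L1", "L2", "L3")))
  s1 <- sfm[v$sample, "L1"]; s2 <- sfm[v$sample, "L2"]; s3 <- sfm[v$sample, "L3"]

  fr <- estimate_fractions(v$L1, v$L2, v$L3)
  p_hmC <- poisson_ratio_test(raw$L1, raw$L2, s1, s2)
  p_mC <- poisson_ratio_test(raw$L2, raw$L3, s2, s3)
  p_hmC[raw$L1 + raw$L2 == 0] <- NA
  p_mC[raw$L2 + raw$L3 == 0] <- NA

  out <- data.frame(chrom = v$chrom, pos = v$pos, sample = v$sample,
                    fr, depth = raw$L1,
                    p_mC = p_mC, p_hmC = p_hmC,
                    q_mC = NA_real_, q_hmC = NA_real_,
                    stringsAsFactors = FALSE)
  for (s in unique(out$sample)) {
    i <- out$sample == s
    out$q_mC[i] <- stats::p.adjust(out$p_mC[i], "BH")
    out$q_hmC[i] <- stats::p.adjust(out$p_hmC[i], "BH")
  }
  ratio_hmC <- v$L1 / v$L2
  ratio_mC <- v$L2 / v$L3
  out$sig_hmC <- !is.na(out$q_hmC) & out$depth > depth_min &
    is.finite(ratio_hmC) & ratio_hmC > 1 & out$q_hmC < fdr
  out$sig_mC <- !is.na(out$q_mC) & out$depth > depth_min &
    is.finite(ratio_mC) & ratio_mC > 1 & out$q_mC < fdr
  # L2 == 0 with L1 > 0 still indicates hmC; ratio is +Inf
  inf_h <- v$L2 == 0 & v$L1 > 0
  out$sig_hmC[inf_h] <- !is.na(out$q_hmC[inf_h]) &
    out$depth[inf_h] > depth_min & out$q_hmC[inf_h] < fdr
  inf_m <- v$L3 == 0 & v$L2 > 0
  out$sig_mC[inf_m] <- !is.na(out$q_mC[inf_m]) &
    out$depth[inf_m] > depth_min & out$q_mC[inf_m] < fdr
  out
}

#' Modification frequency of CCGG sites in an interval
#'
#' The fraction of CCGG sites within a genomic interval that are called
#' significantly modified for the requested modification.
#'
#' @param interval list or data.frame row with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param calls site calls for one sample (from [call_sites()]).
#' @param kind `"mC"` or `"hmC"`.
#' @return fraction in `[0, 1]`, or `NA` when the interval contains no
#'   CCGG site.
#' @export
modification_frequency <- function(interval, calls, kind = c("mC", "hmC")) {
  kind <- match.arg(kind)
  i <- calls$chrom == interval$chrom & calls$pos >= interval$start &
    calls$pos < interval$end
  if (!any(i)) return(NA_real_)
  mean(calls[[paste0("sig_", kind)]][i], na.rm = TRUE)
}

#' Per-sample site modification levels in long format
#'
#' Convenience extractor turning site calls into the long site-level table
#' consumed by [find_regions()].
#'
#' @param calls output of [call_sites()].
#' @param groups named vector mapping sample id to `"case"`/`"control"`.
#' @param kind `"mC"` (uses `m_hat`) or `"hmC"` (`h_hat`).
#' @return data.frame `chrom`, `pos`, `sample`, `group`, `level`.
#' @export
site_levels <- function(calls, groups, kind = c("mC", "hmC")) {
  kind <- match.arg(kind)
  data.frame(chrom = calls$chrom, pos = calls$pos, sample = calls$sample,
             group = unname(groups[calls$sample]),
             level = if (kind == "mC") calls$m_hat else calls$h_hat,
             stringsAsFactors = FALSE)
}
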