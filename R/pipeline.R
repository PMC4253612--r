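#' Run the site-level HMST-seq pipeline
#'
#' Convenience wrapper chaining normalization, site calling and
#' seed-and-extend region detection for both modifications.
#'
#' @param counts long count data.frame (`chrom`, `pos`, `sample`,
#'   `group`, `L1`, `L2`, `L3`), e.g. from [simulate_counts()] or read
#'   from a counts TSV.
#' @param depth_min,fdr site-calling gates (see [call_sites()]).
#' @param ... passed to [find_regions()] (`max_gap`, `alpha`, ...).
#' @return list with `norm`, `calls`, `dmrs`, `dhmrs`.
#' @export
hmst_pipeline <- function(counts, depth_min = 10, fdr = 0.001, ...) {
  stopifnot("group" %in% names(counts))
  groups <- setNames(counts$group, counts$sample)
  groups <- groups[!duplicated(names(groups))]
  norm <- grsn_normalize(counts)
  calls <- call_sites(norm, counts, depth_min = depth_min, fdr = fdr)
  dmrs <- find_regions(site_levels(calls, groups, "mC"), "DMR", ...)
  dhmrs <- find_regions(site_levels(calls, groups, "hmC"), "DhMR", ...)
  list(norm = norm, calls = calls, dmrs = dmrs, dhmrs = dhmrs)
}

#' Match recovered regions against planted truth
#'
#' A planted region counts as recovered when some emitted region of the
#' same kind shares at least `min_overlap` of its member sites in both
#' directions (reciprocal site overlap).
#'
#' @param found regions from [find_regions()].
#' @param planted truth regions (with `member_sites`).
#' @param min_overlap reciprocal member-site overlap fraction.
#' @return list with `recovered` (logical per planted region),
#'   `boundary_error` (sites missed or added at either end for the best
#'   match, NA when unrecovered) and `rate`.
#' @export
region_recovery <- function(found, planted, min_overlap = 0.8) {
  rec <- logical(nrow(planted))
  berr <- rep(NA_real_, nrow(planted))
  for (i in seq_len(nrow(planted))) {
    ps <- planted$member_sites[[i]]
    if (nrow(found) == 0) next
    cand <- which(found$chrom == planted$chrom[i])
    for (j in cand) {
      fs <- found$member_sites[[j]]
      ov <- length(intersect(ps, fs))
      if (ov / length(ps) >= min_overlap && ov / length(fs) >= min_overlap) {
        rec[i] <- TRUE
        be <- length(setdiff(ps, fs)) + length(setdiff(fs, ps))
        berr[i] <- min(berr[i], be, na.rm = TRUE)
      }
    }
  }
  list(recovered = rec, boundary_error = berr, rate = mean(rec))
}
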