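#' Gene model table
#'
#' Builds/validates the gene-model data.frame used across the package:
#' columns `gene_id`, `chrom`, `strand` (`+`/`-`), `tx_start`, `tx_end`
#' (0-based half-open) and optional comma-separated `exon_starts` /
#' `exon_ends`. The TSS is `tx_start` on `+` and `tx_end - 1` on `-`.
#'
#' @param df data.frame with at least the five required columns.
#' @return the validated data.frame with a `tss` column added.
#' @export
gene_models <- function(df) {
  need <- c("gene_id", "chrom", "strand", "tx_start", "tx_end")
  stopifnot(all(need %in% names(df)), all(df$strand %in% c("+", "-")),
            all(df$tx_start < df$tx_end), !anyDuplicated(df$gene_id))
  df$tss <- ifelse(df$strand == "+", df$tx_start, df$tx_end - 1L)
  df
}

#' Read gene models from BED12 or a plain TSV
#'
#' BED12 files are detected by column count; exon blocks become
#' `exon_starts`/`exon_ends`. Otherwise a header-carrying TSV with the
#' [gene_models()] columns is expected.
#'
#' @param path input file.
#' @return gene-model data.frame (see [gene_models()]).
#' @export
read_gene_models <- function(path) {
  first <- readLines(path, n = 1)
  nfld <- length(strsplit(first, "\t")[[1]])
  if (nfld == 12 && !grepl("gene_id", first)) {
    b <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    starts <- lapply(strsplit(sub(",$", "", b[[12]]), ","), as.integer)
    sizes <- lapply(strsplit(sub(",$", "", b[[11]]), ","), as.integer)
    df <- data.frame(gene_id = b[[4]], chrom = b[[1]], strand = b[[6]],
                     tx_start = b[[2]], tx_end = b[[3]],
                     stringsAsFactors = FALSE)
    df$exon_starts <- vapply(seq_len(nrow(b)), function(i)
      paste(b[[2]][i] + starts[[i]], collapse = ","), character(1))
    df$exon_ends <- vapply(seq_len(nrow(b)), function(i)
      paste(b[[2]][i] + starts[[i]] + sizes[[i]], collapse = ","),
      character(1))
    gene_models(df)
  } else {
    gene_models(read.delim(path, stringsAsFactors = FALSE))
  }
}

.parse_int_list <- function(x) lapply(strsplit(x, ","), as.integer)

# Feature GRanges (1-based closed, as GRanges requires) for each label.
.feature_ranges <- function(genes, enhancers, promoter_up, promoter_down) {
  tss <- genes$tss
  plus <- genes$strand == "+"
  p_start <- ifelse(plus, tss - promoter_up, tss - promoter_down + 1L)
  p_end <- ifelse(plus, tss + promoter_down - 1L, tss + promoter_up)
  prom <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(pmax(p_start, 0) + 1L,
                                                  pmax(p_end + 1L, 1L)))
  if (!is.null(genes$exon_starts)) {
    es <- .parse_int_list(genes$exon_starts)
    ee <- .parse_int_list(genes$exon_ends)
    exon <- GenomicRanges::GRanges(rep(genes$chrom, lengths(es)),
                                   IRanges::IRanges(unlist(es) + 1L,
                                                    unlist(ee)))
  } else {
    exon <- GenomicRanges::GRanges(genes$chrom,
                                   IRanges::IRanges(genes$tx_start + 1L,
                                                    genes$tx_end))
  }
  body <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(genes$tx_start + 1L,
                                                  genes$tx_end))
  intron <- GenomicRanges::setdiff(body, exon)
  enh <- if (is.null(enhancers) || nrow(enhancers) == 0) {
    GenomicRanges::GRanges()
  } else {
    GenomicRanges::GRanges(enhancers$chrom,
                           IRanges::IRanges(enhancers$start + 1L,
                                            enhancers$end))
  }
  list(promoter = GenomicRanges::reduce(prom), enhancer = GenomicRanges::reduce(enh),
       exon = GenomicRanges::reduce(exon), intron = GenomicRanges::reduce(intron))
}

#' Assign genomic features to sites or regions
#'
#' Every object receives exactly one label from promoter, enhancer, exon,
#' intron, intergenic. Point objects (width <= 1) are labeled by
#' precedence in that order. Wider objects take the label covering the
#' largest fraction of the object; exact ties fall back to the precedence
#' order. Promoters span `[TSS - promoter_up, TSS + promoter_down)` in a
#' strand-adjusted sense.
#'
#' @param objs data.frame with `chrom`, `start`, `end` (0-based half-open;
#'   for point sites use `start = pos`, `end = pos + 1`).
#' @param genes gene-model data.frame (see [gene_models()]).
#' @param enhancers optional data.frame `chrom`, `start`, `end`.
#' @param promoter_up,promoter_down promoter extent around the TSS, bp.
#' @return character vector of labels, one per row of `objs`.
#' @export
assign_feature <- function(objs, genes, enhancers = NULL,
                           promoter_up = 2000, promoter_down = 500) {
  labels <- c("promoter", "enhancer", "exon", "intron")
  feats <- .feature_ranges(genes, enhancers, promoter_up, promoter_down)
  gr <- GenomicRanges::GRanges(objs$chrom,
                               IRanges::IRanges(objs$start + 1L,
                                                pmax(objs$end, objs$start + 1L)))
  ow <- sapply(labels, function(l) {
    if (length(feats[[l]]) == 0) return(rep(0L, length(gr)))
    hits <- .find_ov(gr, feats[[l]])
    w <- IRanges::width(IRanges::pintersect(
      IRanges::ranges(gr)[S4Vectors::queryHits(hits)],
      IRanges::ranges(feats[[l]])[S4Vectors::subjectHits(hits)]))
    out <- rep(0L, length(gr))
    tw <- tapply(w, S4Vectors::queryHits(hits), sum)
    out[as.integer(names(tw))] <- as.integer(tw)
    out
  })
  ow <- matrix(ow, nrow = length(gr), dimnames = list(NULL, labels))
  width <- objs$end - objs$start
  vapply(seq_len(nrow(objs)), function(i) {
    w <- ow[i, ]
    if (all(w == 0)) return("intergenic")
    if (width[i] <= 1) return(labels[which(w > 0)[1]])
    labels[which(w == max(w))[1]]   # ties: first in precedence order
  }, character(1))
}

#' Signed distance to the nearest TSS
#'
#' Distance from the object midpoint to the nearest TSS, signed by the
#' gene's strand: negative means the object lies upstream of the gene.
#' Ties prefer the smallest absolute distance and then the
#' lexicographically first gene id.
#'
#' @param objs data.frame `chrom`, `start`, `end` (a point site may use
#'   `end = start + 1` or `end = start`).
#' @param genes gene-model data.frame.
#' @return data.frame with `distance` (signed bp) and `gene_id`; NA when
#'   the chromosome carries no gene.
#' @export
tss_distance <- function(objs, genes) {
  stopifnot(nrow(genes) >= 1)
  mid <- floor((objs$start + pmax(objs$end, objs$start + 1L)) / 2)
  out <- data.frame(distance = rep(NA_real_, nrow(objs)),
                    gene_id = NA_character_, stringsAsFactors = FALSE)
  for (ch in unique(objs$chrom)) {
    g <- genes[genes$chrom == ch, ]
    io <- which(objs$chrom == ch)
    if (nrow(g) == 0) next
    for (i in io) {
      d_abs <- abs(mid[i] - g$tss)
      best <- which(d_abs == min(d_abs))
      best <- best[order(g$gene_id[best])][1]
      signed <- if (g$strand[best] == "+") mid[i] - g$tss[best]
                else g$tss[best] - mid[i]
      out$distance[i] <- signed
      out$gene_id[i] <- g$gene_id[best]
    }
  }
  out
}

#' TSS-distance density profile of regions
#'
#' Bins the signed TSS distances of regions into equal-width bins over
#' `[-half_window, +half_window)` and normalizes by the number of regions
#' inside the window, so the profile sums to one.
#'
#' @param regions region data.frame (needs `chrom`, `start`, `end`).
#' @param genes gene-model data.frame.
#' @param half_window half-width of the profile, bp.
#' @param n_bins number of equal-width bins.
#' @return data.frame `bin_start`, `bin_end`, `count`, `density`.
#' @export
density_profile <- function(regions, genes, half_window = 40000,
                            n_bins = 80) {
  wb <- 2 * half_window / n_bins
  bs <- -half_window + wb * (seq_len(n_bins) - 1)
  out <- data.frame(bin_start = bs, bin_end = bs + wb, count = 0L,
                    density = NA_real_)
  if (nrow(regions) == 0) return(out)
  d <- tss_distance(regions, genes)$distance
  d <- d[!is.na(d) & d >= -half_window & d < half_window]
  if (length(d) == 0) return(out)
  bin <- floor((d + half_window) / wb) + 1
  tab <- table(factor(bin, levels = seq_len(n_bins)))
  out$count <- as.integer(tab)
  out$density <- out$count / length(d)
  out
}

#' Relative density of significant sites per genomic feature
#'
#' For each feature label, the ratio of significantly modified CCGG sites
#' to all inspected CCGG sites falling in that feature.
#'
#' @param calls site calls for one sample (from [call_sites()]).
#' @param all_sites data.frame `chrom`, `pos` of every inspected CCGG
#'   site.
#' @param genes gene-model data.frame.
#' @param enhancers optional enhancer intervals.
#' @param kind `"mC"` or `"hmC"`.
#' @param ... promoter extent arguments passed to [assign_feature()].
#' @return data.frame `feature`, `n_sites`, `n_sig`, `ratio` (NA for a
#'   feature with no inspected site).
#' @export
relative_density <- function(calls, all_sites, genes, enhancers = NULL,
                             kind = c("mC", "hmC"), ...) {
  kind <- match.arg(kind)
  objs <- data.frame(chrom = all_sites$chrom, start = all_sites$pos,
                     end = all_sites$pos + 1L)
  lab <- assign_feature(objs, genes, enhancers, ...)
  sig_key <- paste(calls$chrom, calls$pos)[calls[[paste0("sig_", kind)]] %in% TRUE]
  is_sig <- paste(all_sites$chrom, all_sites$pos) %in% sig_key
  feats <- c("promoter", "enhancer", "exon", "intron", "intergenic")
  n_all <- vapply(feats, function(f) sum(lab == f), integer(1))
  n_sig <- vapply(feats, function(f) sum(lab == f & is_sig), integer(1))
  data.frame(feature = feats, n_sites = n_all, n_sig = n_sig,
             ratio = ifelse(n_all == 0, NA_real_, n_sig / n_all),
             row.names = NULL, stringsAsFactors = FALSE)
}
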