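#' Differential expression on array-like intensities
#'
#' Per-gene two-sided Wilcoxon rank-sum test between case and control
#' columns of a continuous expression matrix, with BH adjustment across
#' genes. Direction is the sign of the case-minus-control mean.
#'
#' @param expr numeric matrix, genes x samples (rownames = gene ids).
#' @param case_ids,control_ids column names of the two groups (>= 2
#'   samples each).
#' @return data.frame `gene_id`, `p`, `fdr`, `direction` (+1 up in case,
#'   -1 down, 0 tie).
#' @export
deg_array <- function(expr, case_ids, control_ids) {
  stopifnot(length(case_ids) >= 2, length(control_ids) >= 2,
            all(c(case_ids, control_ids) %in% colnames(expr)))
  a <- expr[, case_ids, drop = FALSE]
  b <- expr[, control_ids, drop = FALSE]
  p <- vapply(seq_len(nrow(expr)), function(i) {
    x <- a[i, ]; y <- b[i, ]
    if (length(unique(c(x, y))) == 1) return(1)
    wilcoxon_rank_sum(x, y)
  }, numeric(1))
  dir <- as.integer(sign(rowMeans(a) - rowMeans(b)))
  data.frame(gene_id = rownames(expr), p = p,
             fdr = stats::p.adjust(p, "BH"), direction = dir,
             stringsAsFactors = FALSE)
}

# Two-sided exact conditional binomial P value: sum of the probabilities
# of outcomes no more likely than the observed one (the binom.test
# convention), computed directly.
.binom_two_sided <- function(x, n, p0) {
  if (n == 0) return(1)
  d <- stats::dbinom(x, n, p0)
  sum(stats::dbinom(0:n, n, p0)[stats::dbinom(0:n, n, p0) <= d * (1 + 1e-7)])
}

#' Differential expression on count data (two-library comparison)
#'
#' Exact conditional binomial test of a gene's count split between two
#' libraries given their total sizes: under equal expression,
#' `x | x + y ~ Binomial(x + y, N_x / (N_x + N_y))`. Two-sided P by the
#' minimum-likelihood convention; direction by the normalized ratio.
#'
#' @param x_gene,y_gene per-gene counts in the case and control library.
#' @param N_x,N_y the two library sizes (total counts).
#' @return data.frame `p`, `direction`, plus BH `fdr` across genes.
#' @export
deg_counts <- function(x_gene, y_gene, N_x, N_y) {
  stopifnot(N_x > 0, N_y > 0)
  p0 <- N_x / (N_x + N_y)
  p <- mapply(function(x, y) .binom_two_sided(x, x + y, p0),
              x_gene, y_gene)
  dir <- as.integer(sign(x_gene / N_x - y_gene / N_y))
  data.frame(p = p, fdr = stats::p.adjust(p, "BH"), direction = dir)
}

#' Combine per-group differential-expression results
#'
#' A gene is a DEG when its FDR is below `fdr` in at least one group and
#' its direction is the same nonzero sign in every group.
#'
#' @param per_group named list of data.frames with columns `gene_id`,
#'   `fdr`, `direction`.
#' @param fdr FDR threshold.
#' @return data.frame `gene_id`, `direction` (`"up"`/`"down"`/`NA`),
#'   `min_fdr`, `consistent`, `is_deg`.
#' @export
combine_degs <- function(per_group, fdr = 0.05) {
  stopifnot(length(per_group) >= 1)
  ids <- per_group[[1]]$gene_id
  fdrs <- sapply(per_group, function(g) g$fdr[match(ids, g$gene_id)])
  dirs <- sapply(per_group, function(g) g$direction[match(ids, g$gene_id)])
  fdrs <- matrix(fdrs, nrow = length(ids))
  dirs <- matrix(dirs, nrow = length(ids))
  min_fdr <- apply(fdrs, 1, min, na.rm = TRUE)
  consistent <- apply(dirs, 1, function(d) {
    d <- d[!is.na(d)]
    length(d) > 0 && all(d == d[1]) && d[1] != 0
  })
  is_deg <- min_fdr < fdr & consistent
  dir1 <- apply(dirs, 1, function(d) {
    d <- d[!is.na(d)]
    if (length(d)) d[1] else NA_integer_
  })
  direction <- ifelse(is_deg, ifelse(dir1 > 0, "up", "down"), NA)
  data.frame(gene_id = ids, direction = direction, min_fdr = min_fdr,
             consistent = consistent, is_deg = is_deg,
             stringsAsFactors = FALSE)
}

.gene_granges <- function(genes) {
  GenomicRanges::GRanges(genes$chrom,
                         IRanges::IRanges(genes$tx_start + 1L, genes$tx_end))
}

#' Filter DEGs whose direction is explained by copy number
#'
#' Removes upregulated DEGs whose gene body overlaps (>= 1 bp) an
#' amplification, and downregulated DEGs overlapping a deletion, in at
#' least one case sample.
#'
#' @param degs combined DEG table from [combine_degs()].
#' @param segments data.frame `sample_id`, `chrom`, `start`, `end`,
#'   `state` (`"amplification"`/`"deletion"`), somatic segments of the
#'   case samples.
#' @param genes gene-model data.frame.
#' @return `degs` with dosage-explained DEGs removed (non-DEG rows kept).
#' @export
cnv_filter <- function(degs, segments, genes) {
  if (nrow(segments) == 0) return(degs)
  g <- genes[match(degs$gene_id, genes$gene_id), ]
  gr_g <- .gene_granges(g)
  drop <- rep(FALSE, nrow(degs))
  for (st in c("amplification", "deletion")) {
    seg <- segments[segments$state == st, ]
    if (nrow(seg) == 0) next
    gr_s <- GenomicRanges::GRanges(seg$chrom,
                                   IRanges::IRanges(seg$start + 1L, seg$end))
    hit <- .ov_any(gr_g, gr_s)
    dir_tag <- if (st == "amplification") "up" else "down"
    drop <- drop | (hit & !is.na(degs$direction) & degs$direction == dir_tag)
  }
  degs[!drop, , drop = FALSE]
}

#' Screen tumor-suppressor candidates from promoter methylation changes
#'
#' Links each DEG to DMRs/DhMRs lying within `window` bp upstream of its
#' TSS (strand-adjusted, `[TSS - window, TSS)`). A gene passes the sign
#' rule when every linked DMR is anti-correlated with expression
#' (hyper-DMR with a down gene, hypo-DMR with an up gene), every linked
#' DhMR is positively correlated (hyper-DhMR with up, hypo-DhMR with
#' down), and, when both kinds are present, their directions are
#' opposite (hypermethylated promoters must be hypohydroxymethylated and
#' vice versa).
#'
#' @param degs combined DEG table (only `is_deg` rows are screened).
#' @param dmrs,dhmrs region data.frames from [find_regions()].
#' @param genes gene-model data.frame.
#' @param window upstream window, bp.
#' @return data.frame, one row per DEG with at least one linked region:
#'   gene, expression direction, linked-region summary and
#'   `passes_sign_rule`.
#' @export
screen_candidates <- function(degs, dmrs, dhmrs, genes, window = 5000) {
  degs <- degs[degs$is_deg %in% TRUE, , drop = FALSE]
  degs <- degs[order(degs$gene_id), , drop = FALSE]
  g <- gene_models(genes[, setdiff(names(genes), "tss")])
  g <- g[match(degs$gene_id, g$gene_id), ]
  plus <- g$strand == "+"
  win_start <- ifelse(plus, g$tss - window, g$tss + 1L)
  win_end <- ifelse(plus, g$tss, g$tss + window + 1L)  # half-open upstream
  gr_win <- GenomicRanges::GRanges(g$chrom,
                                   IRanges::IRanges(pmax(win_start, 0) + 1L,
                                                    pmax(win_end, 1L)))
  link <- function(regions) {
    if (is.null(regions) || nrow(regions) == 0)
      return(data.frame(gene = integer(), region = integer()))
    gr_r <- GenomicRanges::GRanges(regions$chrom,
                                   IRanges::IRanges(regions$start + 1L,
                                                    regions$end))
    h <- .find_ov(gr_win, gr_r)
    data.frame(gene = S4Vectors::queryHits(h),
               region = S4Vectors::subjectHits(h))
  }
  lm_ <- link(dmrs)
  lh_ <- link(dhmrs)
  rows <- sort(unique(c(lm_$gene, lh_$gene)))
  if (length(rows) == 0)
    return(data.frame(gene_id = character(), expr_direction = character(),
                      dmr_direction = character(),
                      dhmr_direction = character(), n_dmr = integer(),
                      n_dhmr = integer(), passes_sign_rule = logical(),
                      stringsAsFactors = FALSE))
  res <- lapply(rows, function(i) {
    dm <- dmrs[lm_$region[lm_$gene == i], , drop = FALSE]
    dh <- dhmrs[lh_$region[lh_$gene == i], , drop = FALSE]
    ed <- degs$direction[i]
    dmd <- unique(dm$direction)
    dhd <- unique(dh$direction)
    ok_dmr <- nrow(dm) == 0 ||
      (length(dmd) == 1 && ((dmd == "hyper" && ed == "down") ||
                            (dmd == "hypo" && ed == "up")))
    ok_dhmr <- nrow(dh) == 0 ||
      (length(dhd) == 1 && ((dhd == "hyper" && ed == "up") ||
                            (dhd == "hypo" && ed == "down")))
    ok_both <- nrow(dm) == 0 || nrow(dh) == 0 ||
      (length(dmd) == 1 && length(dhd) == 1 && dmd != dhd)
    data.frame(gene_id = degs$gene_id[i], expr_direction = ed,
               dmr_direction = if (length(dmd) == 1) dmd else
                 if (nrow(dm) == 0) NA_character_ else "mixed",
               dhmr_direction = if (length(dhd) == 1) dhd else
                 if (nrow(dh) == 0) NA_character_ else "mixed",
               n_dmr = nrow(dm), n_dhmr = nrow(dh),
               passes_sign_rule = ok_dmr && ok_dhmr && ok_both,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Hypergeometric pathway enrichment
#'
#' Upper-tail hypergeometric test of a gene set against each pathway,
#' with BH adjustment across pathways.
#'
#' @param gene_set character vector of genes (subset of `universe`).
#' @param pathway_map named list of pathway gene vectors.
#' @param universe character vector of all genes.
#' @return data.frame `pathway`, `n_pathway`, `n_overlap`, `p`, `q`.
#' @export
hypergeom_enrichment <- function(gene_set, pathway_map, universe) {
  gene_set <- intersect(gene_set, universe)
  pathway_map <- lapply(pathway_map, intersect, universe)
  pathway_map <- pathway_map[lengths(pathway_map) > 0]
  N <- length(universe)
  n <- length(gene_set)
  res <- lapply(names(pathway_map), function(pw) {
    K <- length(pathway_map[[pw]])
    k <- length(intersect(gene_set, pathway_map[[pw]]))
    data.frame(pathway = pw, n_pathway = K, n_overlap = k,
               p = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, "BH")
  rownames(out) <- NULL
  out
}

#' Enrichment rate of a gene set over its significant pathways
#'
#' The percentage of set genes that belong to at least one significantly
#' enriched pathway.
#'
#' @param gene_set character vector of genes.
#' @param enrichment result of [hypergeom_enrichment()].
#' @param pathway_map the pathway list used for the enrichment.
#' @param alpha significance threshold on the adjusted values.
#' @return list with `n_in_sig`, `n_set` and `rate_pct` (one decimal).
#' @export
enrichment_rate <- function(gene_set, enrichment, pathway_map,
                            alpha = 0.05) {
  sig <- enrichment$pathway[enrichment$q < alpha]
  in_sig <- unique(unlist(pathway_map[sig]))
  k <- sum(gene_set %in% in_sig)
  list(n_in_sig = k, n_set = length(gene_set),
       rate_pct = round(100 * k / length(gene_set), 1))
}

#' Read a GMT pathway file
#'
#' @param path GMT file (pathway, description, genes...).
#' @return named list of gene vectors.
#' @export
read_gmt <- function(path) {
  lines <- strsplit(readLines(path), "\t")
  setNames(lapply(lines, function(x) x[-(1:2)]),
           vapply(lines, `[`, character(1), 1))
}
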