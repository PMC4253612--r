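#' Simulation configuration
#'
#' Collects every knob of the synthetic HMST-seq study in one validated
#' list. Defaults emulate a desk-scale version of a matched tumor/normal
#' design: three matched pairs of samples measured with three libraries
#' each, CCGG sites at restriction-realistic density, mostly-methylated
#' baseline with a small 5hmC fraction, planted hyper-methylated DMRs and
#' hypo-hydroxymethylated DhMRs, library-size imbalance across the three
#' libraries, expression on two platforms (array intensities for five
#' pairs, counts for two pairs) with ~30% of genes differentially
#' expressed, and somatic CNV segments.
#'
#' @param n_chrom,chrom_length number and length (bp) of chromosomes.
#' @param ccgg_per_kb,catg_per_kb target motif densities (the CCGG
#'   default matches the genome-wide MspI-site rate in human).
#' @param island_sites,island_spacing CCGG sites per island cluster and
#'   their spacing (bp); islands hold `island_frac` of all CCGG sites,
#'   the rest are sparse bulk sites whose typical gaps exceed the
#'   region callers' 2,000-bp adjacency limit.
#' @param n_case,n_control methylation samples per group.
#' @param baseline_fractions mean (u, m, h) fractions of the methylated
#'   bulk component; must sum to 1.
#' @param island_fractions mean (u, m, h) of the island-like
#'   mostly-unmodified component.
#' @param island_frac fraction of CCGG sites in the island-like
#'   component.
#' @param fraction_concentration Dirichlet concentration of per-site
#'   baseline fractions around the component mean.
#' @param site_depth_sd log2-scale standard deviation of the per-site
#'   coverage factor shared across libraries and samples.
#' @param n_dmr,dmr_sites,dmr_delta,dmr_direction planted 5mC regions.
#' @param n_dhmr,dhmr_sites,dhmr_delta,dhmr_direction planted 5hmC
#'   regions.
#' @param buffer_sites unplanted CCGG sites kept between planted regions.
#' @param mean_depth mean per-library tag depth at a site.
#' @param lib_factors per-library size factors (L1, L2, L3).
#' @param depth_cv lognormal coefficient of variation of per-sample depth.
#' @param n_genes,gene_length gene models on the toy genome.
#' @param n_tsg,tsg_fold planted tumor-suppressor candidates: genes whose
#'   promoter carries a planted hyper-DMR and whose expression drops
#'   `tsg_fold`-fold in the case group (requires `n_tsg <= n_dmr` and
#'   `dmr_direction = "hyper"`).
#' @param tsg_min_expr_quantile planted TSG baselines are drawn above
#'   this quantile of the gene-expression baseline distribution: a
#'   silenced tumor suppressor must be expressed in the control tissue
#'   to be screenable at all.
#' @param deg_frac,deg_fold total fraction of differentially expressed
#'   genes (including TSGs) and the fold change of non-TSG DEGs.
#' @param n_array_pairs,array_sd,array_baseline_mean,array_baseline_sd
#'   array platform: matched pairs and log2-scale noise/baseline.
#' @param n_rnaseq_pairs,rnaseq_libsize,nb_dispersion count platform:
#'   matched pairs, per-library total count, negative-binomial
#'   dispersion (0 gives Poisson).
#' @param cnv_segs_per_sample,cnv_seg_length random somatic segments per
#'   case sample.
#' @param n_cnv_masked number of up-DEGs deliberately covered by an
#'   amplification and of non-TSG down-DEGs covered by a deletion (to
#'   exercise the dosage filter).
#' @param n_enhancers,enhancer_length decoy enhancer intervals.
#' @param screen_window upstream promoter window used when placing genes.
#' @param rng_seed integer seed; every generator output is a
#'   deterministic function of the configuration and this seed.
#' @return object of class `hmst_sim_config`.
#' @export
sim_config <- function(n_chrom = 2, chrom_length = 1000000,
                       ccgg_per_kb = 0.7, catg_per_kb = 4,
                       island_sites = 12, island_spacing = 250,
                       n_case = 3, n_control = 3,
                       baseline_fractions = c(u = 0.35, m = 0.50, h = 0.15),
                       island_fractions = c(u = 0.88, m = 0.08, h = 0.04),
                       island_frac = 0.5,
                       fraction_concentration = 30,
                       site_depth_sd = 0.6,
                       n_dmr = 20, dmr_sites = 10, dmr_delta = 0.4,
                       dmr_direction = "hyper",
                       n_dhmr = 10, dhmr_sites = 10, dhmr_delta = 0.3,
                       dhmr_direction = "hypo",
                       buffer_sites = 2,
                       mean_depth = 100, lib_factors = c(1.0, 0.8, 1.2),
                       depth_cv = 0.1,
                       n_genes = 500, gene_length = 1500,
                       n_tsg = 10, tsg_fold = 3,
                       tsg_min_expr_quantile = 0.5,
                       deg_frac = 0.3, deg_fold = 2,
                       n_array_pairs = 5, array_sd = 0.25,
                       array_baseline_mean = 7, array_baseline_sd = 1.5,
                       n_rnaseq_pairs = 2, rnaseq_libsize = 2e5,
                       nb_dispersion = 0,
                       cnv_segs_per_sample = 5, cnv_seg_length = 30000,
                       n_cnv_masked = 5,
                       n_enhancers = 50, enhancer_length = 1000,
                       screen_window = 5000,
                       rng_seed = 1) {
  cfg <- as.list(environment())
  stopifnot(abs(sum(cfg$baseline_fractions) - 1) < 1e-9,
            abs(sum(cfg$island_fractions) - 1) < 1e-9,
            cfg$island_frac >= 0, cfg$island_frac <= 1,
            all(cfg$baseline_fractions >= 0),
            cfg$dmr_delta > 0, cfg$dmr_delta < 1,
            cfg$n_tsg <= cfg$n_dmr,
            cfg$dmr_direction %in% c("hyper", "hypo"),
            cfg$dhmr_direction %in% c("hyper", "hypo"),
            length(cfg$lib_factors) == 3, all(cfg$lib_factors > 0),
            cfg$rng_seed == round(cfg$rng_seed))
  class(cfg) <- "hmst_sim_config"
  cfg
}

# sample() semantics change for length-1 vectors; avoid that
.shuffle <- function(x) x[sample.int(length(x))]
.pick <- function(x, k) x[sample.int(length(x), k)]

.ACGT <- c("A", "C", "G", "T")
.MOTIFS <- c("CCGG", "CATG")

#' Generate a toy genome with stamped CCGG/CATG sites
#'
#' Builds each chromosome as random background sequence, stamps CCGG and
#' CATG motifs on a jittered grid at the configured densities, and then
#' repairs any accidental motif created by the background or at stamp
#' junctions, so the motif positions are known exactly. Deterministic
#' under the configuration seed.
#'
#' @param cfg a [sim_config()].
#' @return list with `genome` (a `DNAStringSet`) and `sites` (data.frame
#'   `chrom`, `pos` (0-based motif start), `motif`).
#' @export
make_genome <- function(cfg) {
  set.seed(cfg$rng_seed)
  seqs <- character(cfg$n_chrom)
  names(seqs) <- sprintf("chr%d", seq_len(cfg$n_chrom))
  sites <- list()
  for (ci in seq_len(cfg$n_chrom)) {
    len <- cfg$chrom_length
    n_cc <- round(len / 1000 * cfg$ccgg_per_kb)
    n_ca <- round(len / 1000 * cfg$catg_per_kb)
    if (n_cc < 1 || (n_cc + n_ca) * 10 > len)
      stop("motif density unattainable at chromosome length ", len)
    # CCGG layout: dense island clusters (the CpG-island-like component)
    # interleaved with sparse bulk sites
    n_islands <- max(1L, round(cfg$island_frac * n_cc / cfg$island_sites))
    n_isl_sites <- n_islands * cfg$island_sites
    if (n_isl_sites > n_cc)
      stop("island_frac/island_sites exceed the CCGG budget")
    n_bulk <- n_cc - n_isl_sites
    isl_span <- n_islands * (cfg$island_sites - 1) * cfg$island_spacing
    gap <- (len - isl_span - 1000) / (n_bulk + n_islands + 1)
    if (gap < 10) stop("CCGG density unattainable at chromosome length ", len)
    events <- sample(rep(c("B", "I"), c(n_bulk, n_islands)))
    pos_cc <- numeric(n_cc)
    in_island <- logical(n_cc)
    p <- 0; k <- 0
    for (ev in events) {
      p <- p + gap * runif(1, 0.6, 1.4)
      if (ev == "B") {
        k <- k + 1; pos_cc[k] <- p
      } else {
        for (j in seq_len(cfg$island_sites)) {
          k <- k + 1; pos_cc[k] <- p; in_island[k] <- TRUE
          p <- p + cfg$island_spacing * runif(1, 0.7, 1.3)
        }
      }
    }
    if (max(pos_cc) > len - 10) {
      sc <- (len - 10) / max(pos_cc)
      pos_cc <- pos_cc * sc
    }
    pos_ca <- (seq_len(n_ca) - 0.5) * len / n_ca +
      runif(n_ca, -0.3, 0.3) * len / n_ca
    pos <- round(c(pos_cc, pos_ca))
    type <- rep(.MOTIFS, c(n_cc, n_ca))
    island_of <- c(in_island, rep(FALSE, n_ca))
    o <- order(pos)
    pos <- pos[o]; type <- type[o]; island_of <- island_of[o]
    pos <- pmin(pmax(pos, 1), len - 3)
    n <- length(pos)
    for (i in seq_len(n)[-1]) pos[i] <- max(pos[i], pos[i - 1] + 6L)
    for (i in rev(seq_len(n - 1))) pos[i] <- min(pos[i], pos[i + 1] - 6L)
    if (pos[1] < 1 || pos[n] > len - 3)
      stop("motif density unattainable after spacing fix")
    ch <- sample(.ACGT, len, replace = TRUE)
    mask <- rep(FALSE, len)
    for (i in seq_len(n)) {
      ch[pos[i]:(pos[i] + 3L)] <- strsplit(type[i], "")[[1]]
      mask[pos[i]:(pos[i] + 3L)] <- TRUE
    }
    intended <- paste(pos, type)
    for (iter in 1:50) {
      s <- paste(ch, collapse = "")
      acc <- NULL
      for (m in .MOTIFS) {
        q <- gregexpr(m, s, fixed = TRUE)[[1]]
        q <- q[q > 0]
        if (length(q)) q <- q[!(paste(q, m) %in% intended)]
        if (length(q)) acc <- rbind(acc, cbind(q, match(m, .MOTIFS)))
      }
      if (is.null(acc)) break
      for (r in seq_len(nrow(acc))) {
        w <- acc[r, 1]:(acc[r, 1] + 3L)
        free <- w[!mask[w]]
        if (length(free) == 0) next  # cannot happen with >=6 bp stamps gap
        o <- free[1]
        ch[o] <- sample(setdiff(.ACGT, ch[o]), 1)
      }
    }
    seqs[ci] <- paste(ch, collapse = "")
    sites[[ci]] <- data.frame(chrom = names(seqs)[ci],
                              pos = as.integer(pos) - 1L,
                              motif = type, island = island_of,
                              stringsAsFactors = FALSE)
  }
  sites <- do.call(rbind, sites)
  sites <- sites[order(sites$chrom, sites$pos), ]
  rownames(sites) <- NULL
  list(genome = Biostrings::DNAStringSet(seqs), sites = sites)
}

# Per-CCGG-site baseline (u, m, h): a two-component mixture of an
# island-like mostly-unmodified state and a methylated bulk state, each a
# Dirichlet around its mean, mimicking the bimodality of real
# methylomes. Also draws the per-site coverage factor shared by all
# libraries and samples. Identical for both groups until regions are
# planted.
make_site_truth <- function(sites, cfg) {
  ccgg <- sites[sites$motif == "CCGG", c("chrom", "pos", "island")]
  set.seed(cfg$rng_seed + 1L)
  n <- nrow(ccgg)
  island <- ccgg$island
  ccgg$island <- NULL
  f <- matrix(0, n, 3)
  for (st in c(TRUE, FALSE)) {
    i <- island == st
    mu <- if (st) cfg$island_fractions else cfg$baseline_fractions
    a <- cfg$fraction_concentration * mu
    g <- cbind(rgamma(sum(i), a[1]), rgamma(sum(i), a[2]),
               rgamma(sum(i), a[3]))
    f[i, ] <- g / rowSums(g)
  }
  cov <- 2^rnorm(n, 0, cfg$site_depth_sd)
  cov <- cov / mean(cov)
  truth <- data.frame(ccgg, cov = cov, island = island,
                      u_control = f[, 1], m_control = f[, 2], h_control = f[, 3],
                      u_case = f[, 1], m_case = f[, 2], h_case = f[, 3],
                      region = NA_integer_, stringsAsFactors = FALSE)
  truth[order(truth$chrom, truth$pos), ]
}

# Cap component `comp` at 1 - delta (minus margin) in both groups so the
# planted shift is exactly delta, then shift the target group.
.cap_and_shift <- function(truth, idx, comp, delta, shift_group) {
  comps <- c("u", "m", "h")
  other <- setdiff(comps, comp)
  for (grp in c("control", "case")) {
    v <- truth[idx, paste(comp, grp, sep = "_")]
    cap <- 1 - delta - 0.02
    over <- v > cap
    if (any(over)) {
      rest <- 1 - v[over]
      for (oc in other) {
        col <- paste(oc, grp, sep = "_")
        truth[idx[over], col] <- truth[idx[over], col] * (1 - cap) / rest
      }
      truth[idx[over], paste(comp, grp, sep = "_")] <- cap
    }
  }
  v <- truth[idx, paste(comp, shift_group, sep = "_")]
  scale <- (1 - v - delta) / (1 - v)
  for (oc in other) {
    col <- paste(oc, shift_group, sep = "_")
    truth[idx, col] <- truth[idx, col] * scale
  }
  truth[idx, paste(comp, shift_group, sep = "_")] <- v + delta
  truth
}

#' Plant differentially modified regions into the site truth
#'
#' Selects disjoint runs of consecutive CCGG sites (internal gaps at most
#' 2,000 bp, separated by `buffer_sites` unplanted sites) and shifts the
#' methylated (DMR) or hydroxymethylated (DhMR) fraction by exactly the
#' configured effect size between the groups: a `hyper` region raises the
#' case group, a `hypo` region lowers it (implemented as a raised control
#' baseline so the shift stays inside the simplex).
#'
#' @param truth baseline site truth from `make_site_truth`.
#' @param cfg a [sim_config()].
#' @return list with the modified `truth` and `regions` (data.frame with
#'   coordinates, kind, direction and member sites).
#' @export
plant_regions <- function(truth, cfg) {
  set.seed(cfg$rng_seed + 2L)
  used <- rep(FALSE, nrow(truth))
  regions <- list()
  specs <- list(
    list(kind = "DMR", comp = "m", n = cfg$n_dmr, n_sites = cfg$dmr_sites,
         delta = cfg$dmr_delta, direction = cfg$dmr_direction),
    list(kind = "DhMR", comp = "h", n = cfg$n_dhmr,
         n_sites = cfg$dhmr_sites, delta = cfg$dhmr_delta,
         direction = cfg$dhmr_direction))
  ord <- order(truth$chrom, truth$pos)
  stopifnot(identical(ord, seq_len(nrow(truth))))
  for (sp in specs) {
    if (sp$n == 0) next
    placed <- 0
    # eligible start index per chromosome: full run inside chrom, gaps ok
    elig <- unlist(lapply(split(seq_len(nrow(truth)), truth$chrom),
                          function(ix) {
      if (length(ix) < sp$n_sites) return(integer())
      d <- diff(truth$pos[ix])
      ok <- vapply(seq_len(length(ix) - sp$n_sites + 1), function(s)
        all(d[s:(s + sp$n_sites - 2)] <= 2000), logical(1))
      ix[which(ok)]
    }))
    elig <- .shuffle(elig)
    for (s in elig) {
      if (placed == sp$n) break
      span <- s:(s + sp$n_sites - 1)
      guard <- max(1, s - cfg$buffer_sites):
        min(nrow(truth), s + sp$n_sites - 1 + cfg$buffer_sites)
      if (any(used[guard])) next
      shift_group <- if (sp$direction == "hyper") "case" else "control"
      truth <- .cap_and_shift(truth, span, sp$comp, sp$delta, shift_group)
      used[guard] <- TRUE
      placed <- placed + 1
      regions[[length(regions) + 1]] <- data.frame(
        chrom = truth$chrom[s], start = truth$pos[s],
        end = truth$pos[span[sp$n_sites]] + 4L, kind = sp$kind,
        direction = sp$direction, n_sites = sp$n_sites,
        member_sites = I(list(truth$pos[span])), stringsAsFactors = FALSE)
      truth$region[span] <- length(regions)
    }
    if (placed < sp$n)
      stop("could not place ", sp$n, " ", sp$kind, " regions (placed ",
           placed, "); enlarge the genome or lower the density demands")
  }
  regions <- do.call(rbind, regions)
  regions <- regions[order(regions$chrom, regions$start), ]
  rownames(regions) <- NULL
  list(truth = truth, regions = regions)
}

#' Simulate three-library tag counts from the site truth
#'
#' For a site with true fractions (u, m, h) in a sample's group, library
#' factors (f1, f2, f3), sample depth factor s and mean depth d, counts
#' are `L1 ~ Poisson(f1 d s)`, `L2 ~ Poisson(f2 d s (1 - h))` and
#' `L3 ~ Poisson(f3 d s u)`, independent across sites and samples.
#'
#' @param truth (planted) site truth.
#' @param cfg a [sim_config()].
#' @param poisson if `FALSE`, returns the expected counts instead of
#'   Poisson draws (useful for exactness checks).
#' @return long data.frame `chrom`, `pos`, `sample`, `group`, `L1`,
#'   `L2`, `L3`.
#' @export
simulate_counts <- function(truth, cfg, poisson = TRUE) {
  set.seed(cfg$rng_seed + 3L)
  samples <- c(sprintf("case_%d", seq_len(cfg$n_case)),
               sprintf("control_%d", seq_len(cfg$n_control)))
  groups <- rep(c("case", "control"), c(cfg$n_case, cfg$n_control))
  depth_f <- if (cfg$depth_cv > 0)
    exp(rnorm(length(samples), 0, cfg$depth_cv) - cfg$depth_cv^2 / 2)
  else rep(1, length(samples))
  f <- cfg$lib_factors
  out <- lapply(seq_along(samples), function(si) {
    grp <- groups[si]
    u <- truth[[paste0("u_", grp)]]
    h <- truth[[paste0("h_", grp)]]
    cov <- if (is.null(truth$cov)) 1 else truth$cov
    d <- cfg$mean_depth * depth_f[si] * cov
    mu1 <- f[1] * d
    mu2 <- f[2] * d * (1 - h)
    mu3 <- f[3] * d * u
    n <- nrow(truth)
    data.frame(chrom = truth$chrom, pos = truth$pos, sample = samples[si],
               group = grp,
               L1 = if (poisson) rpois(n, mu1) else mu1,
               L2 = if (poisson) rpois(n, mu2) else mu2,
               L3 = if (poisson) rpois(n, mu3) else mu3,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Generate gene models anchored to the planted regions
#'
#' The first `n_tsg` planted DMRs each receive a gene whose
#' strand-adjusted upstream window contains the region (the planted
#' tumor-suppressor candidates); the remaining genes are placed on a
#' jittered grid across the genome. Two exons per gene.
#'
#' @param cfg a [sim_config()].
#' @param regions planted region table from [plant_regions()].
#' @return gene-model data.frame (see [gene_models()]).
#' @export
make_gene_models <- function(cfg, regions) {
  set.seed(cfg$rng_seed + 4L)
  gl <- cfg$gene_length
  dmr <- regions[regions$kind == "DMR" & regions$direction == "hyper", ]
  if (nrow(dmr) < cfg$n_tsg)
    stop("need at least n_tsg planted hyper-DMRs")
  res <- list()
  for (i in seq_len(cfg$n_tsg)) {
    r <- dmr[i, ]
    strand <- if (i %% 2 == 1) "+" else "-"
    if (strand == "+") {
      tss <- r$end + 500L
      tx_start <- tss; tx_end <- tss + gl
    } else {
      tss <- r$start - 500L
      tx_start <- tss - gl + 1L; tx_end <- tss + 1L
    }
    res[[i]] <- data.frame(gene_id = sprintf("TSG%04d", i),
                           chrom = r$chrom, strand = strand,
                           tx_start = tx_start, tx_end = tx_end,
                           stringsAsFactors = FALSE)
  }
  n_other <- cfg$n_genes - cfg$n_tsg
  per_chrom <- diff(round(seq(0, n_other, length.out = cfg$n_chrom + 1)))
  k <- cfg$n_tsg
  for (ci in seq_len(cfg$n_chrom)) {
    m <- per_chrom[ci]
    if (m == 0) next
    lo <- 5000; hi <- cfg$chrom_length - 5000 - gl
    spacing <- (hi - lo) / m
    tss <- round(lo + (seq_len(m) - 0.5) * spacing +
                   runif(m, -0.2, 0.2) * spacing)
    strand <- rep(c("+", "-"), length.out = m)
    res[[length(res) + 1]] <- data.frame(
      gene_id = sprintf("G%05d", k + seq_len(m)),
      chrom = sprintf("chr%d", ci), strand = strand,
      tx_start = ifelse(strand == "+", tss, tss - gl + 1L),
      tx_end = ifelse(strand == "+", tss + gl, tss + 1L),
      stringsAsFactors = FALSE)
    k <- k + m
  }
  g <- do.call(rbind, res)
  # two exons covering the first and last thirds of the body
  third <- round(gl / 3)
  g$exon_starts <- paste(g$tx_start, g$tx_end - third, sep = ",")
  g$exon_ends <- paste(g$tx_start + third, g$tx_end, sep = ",")
  gene_models(g)
}

#' Simulate expression matrices and CNV segments
#'
#' Assigns differential-expression truth (planted TSGs are
#' `tsg_fold`-fold down; additional genes are split between up and down
#' at `deg_fold`), draws array intensities (log-normal around a per-gene
#' baseline) for `n_array_pairs` matched pairs and negative-binomial
#' counts for `n_rnaseq_pairs` pairs, and places somatic CNV segments.
#' `n_cnv_masked` up-DEGs are deliberately covered by an amplification
#' and `n_cnv_masked` non-TSG down-DEGs by a deletion so the dosage
#' filter has work to do; random background segments avoid TSG bodies.
#' Non-TSG down-DEGs are chosen among genes whose upstream window is
#' free of planted regions, so the planted TSG set is exactly the set of
#' genes satisfying the screen's ground-truth definition.
#'
#' @param cfg a [sim_config()].
#' @param genes gene models from [make_gene_models()].
#' @param regions planted region table.
#' @return list with `expr_array` (matrix), `array_groups`,
#'   `expr_counts` (matrix, one column per library), `count_pairs`
#'   (data.frame pair/case/control column map), `lib_sizes`, `cnv`
#'   (segment data.frame) and `truth` (DEG/TSG/CNV assignments).
#' @export
simulate_expression_cnv <- function(cfg, genes, regions) {
  set.seed(cfg$rng_seed + 5L)
  ng <- nrow(genes)
  is_tsg <- grepl("^TSG", genes$gene_id)
  fold <- rep(1, ng)
  dir <- rep(0L, ng)
  fold[is_tsg] <- 1 / cfg$tsg_fold
  dir[is_tsg] <- -1L
  n_deg_other <- max(0, round(cfg$deg_frac * ng) - sum(is_tsg))
  # upstream windows free of planted regions -> eligible for down-DEG
  plus <- genes$strand == "+"
  win_start <- ifelse(plus, genes$tss - cfg$screen_window, genes$tss + 1L)
  win_end <- ifelse(plus, genes$tss, genes$tss + cfg$screen_window + 1L)
  gr_win <- GenomicRanges::GRanges(genes$chrom,
                                   IRanges::IRanges(pmax(win_start, 0) + 1L,
                                                    pmax(win_end, 1L)))
  gr_reg <- GenomicRanges::GRanges(regions$chrom,
                                   IRanges::IRanges(regions$start + 1L,
                                                    regions$end))
  clean_prom <- !.ov_any(gr_win, gr_reg)
  pool_down <- which(!is_tsg & dir == 0L & clean_prom)
  pool_up <- which(!is_tsg & dir == 0L)
  n_dn <- min(floor(n_deg_other / 2), length(pool_down))
  dn <- .pick(pool_down, n_dn)
  dir[dn] <- -1L; fold[dn] <- 1 / cfg$deg_fold
  pool_up <- setdiff(pool_up, dn)
  up <- .pick(pool_up, min(n_deg_other - n_dn, length(pool_up)))
  dir[up] <- 1L; fold[up] <- cfg$deg_fold

  base <- rnorm(ng, cfg$array_baseline_mean, cfg$array_baseline_sd)
  if (any(is_tsg)) {
    q <- stats::qnorm(runif(sum(is_tsg), cfg$tsg_min_expr_quantile, 1),
                      cfg$array_baseline_mean, cfg$array_baseline_sd)
    base[is_tsg] <- q
  }
  arr_case <- sprintf("arr_case_%d", seq_len(cfg$n_array_pairs))
  arr_ctrl <- sprintf("arr_ctrl_%d", seq_len(cfg$n_array_pairs))
  expr_array <- matrix(0, ng, 2 * cfg$n_array_pairs,
                       dimnames = list(genes$gene_id, c(arr_case, arr_ctrl)))
  for (j in seq_len(cfg$n_array_pairs)) {
    expr_array[, j] <- 2^(base + log2(fold) + rnorm(ng, 0, cfg$array_sd))
    expr_array[, cfg$n_array_pairs + j] <-
      2^(base + rnorm(ng, 0, cfg$array_sd))
  }

  w <- 2^base
  size <- if (cfg$nb_dispersion > 0) 1 / cfg$nb_dispersion else Inf
  cols <- as.vector(t(outer(seq_len(cfg$n_rnaseq_pairs), c("case", "ctrl"),
                            function(p, g) sprintf("rna_p%d_%s", p, g))))
  expr_counts <- matrix(0L, ng, length(cols),
                        dimnames = list(genes$gene_id, cols))
  lib_sizes <- setNames(rep(cfg$rnaseq_libsize, length(cols)), cols)
  for (j in seq_along(cols)) {
    fc <- if (grepl("case", cols[j])) fold else rep(1, ng)
    mu <- cfg$rnaseq_libsize * (w * fc) / sum(w * fc)
    expr_counts[, j] <- if (is.finite(size)) rnbinom(ng, mu = mu, size = size)
      else rpois(ng, mu)
  }

  # CNV: targeted dosage-masking segments plus random background
  segs <- list()
  gb <- function(i) genes[i, c("chrom", "tx_start", "tx_end")]
  mask_amp <- .pick(up, min(cfg$n_cnv_masked, length(up)))
  mask_del <- .pick(dn, min(cfg$n_cnv_masked, length(dn)))
  for (i in mask_amp)
    segs[[length(segs) + 1]] <- data.frame(
      sample_id = "case_1", chrom = genes$chrom[i],
      start = genes$tx_start[i] - 1000L, end = genes$tx_end[i] + 1000L,
      state = "amplification", stringsAsFactors = FALSE)
  for (i in mask_del)
    segs[[length(segs) + 1]] <- data.frame(
      sample_id = "case_1", chrom = genes$chrom[i],
      start = genes$tx_start[i] - 1000L, end = genes$tx_end[i] + 1000L,
      state = "deletion", stringsAsFactors = FALSE)
  gr_tsg <- .gene_granges(genes[is_tsg, , drop = FALSE])
  for (s in sprintf("case_%d", seq_len(cfg$n_case))) {
    placed <- 0
    tries <- 0
    while (placed < cfg$cnv_segs_per_sample && tries < 200) {
      tries <- tries + 1
      chrom <- sprintf("chr%d", sample.int(cfg$n_chrom, 1))
      start <- sample.int(cfg$chrom_length - cfg$cnv_seg_length, 1)
      seg <- GenomicRanges::GRanges(chrom,
        IRanges::IRanges(start + 1L, start + cfg$cnv_seg_length))
      if (any(.ov_any(seg, gr_tsg))) next
      segs[[length(segs) + 1]] <- data.frame(
        sample_id = s, chrom = chrom, start = start,
        end = start + cfg$cnv_seg_length,
        state = sample(c("amplification", "deletion"), 1),
        stringsAsFactors = FALSE)
      placed <- placed + 1
    }
  }
  cnv <- do.call(rbind, segs)
  rownames(cnv) <- NULL
  list(expr_array = expr_array,
       array_groups = list(case = arr_case, control = arr_ctrl),
       expr_counts = expr_counts,
       count_pairs = data.frame(pair = seq_len(cfg$n_rnaseq_pairs),
                                case = sprintf("rna_p%d_case",
                                               seq_len(cfg$n_rnaseq_pairs)),
                                control = sprintf("rna_p%d_ctrl",
                                                  seq_len(cfg$n_rnaseq_pairs)),
                                stringsAsFactors = FALSE),
       lib_sizes = lib_sizes, cnv = cnv,
       truth = list(
         deg = data.frame(gene_id = genes$gene_id, direction = dir,
                          fold = fold, stringsAsFactors = FALSE),
         tsg = genes$gene_id[is_tsg],
         masked_amp = genes$gene_id[mask_amp],
         masked_del = genes$gene_id[mask_del]))
}

#' Run the full synthetic-study generator
#'
#' Generates the genome, site truth, planted regions, tag counts, gene
#' models, expression and CNV data from one configuration, optionally
#' writing everything to plain-text files alongside a JSON truth table.
#' Byte-identical across runs with the same configuration.
#'
#' @param cfg a [sim_config()].
#' @param out_dir optional output directory.
#' @return list with all generated objects and the `truth` tables.
#' @export
simulate_hmst <- function(cfg = sim_config(), out_dir = NULL) {
  gen <- make_genome(cfg)
  truth0 <- make_site_truth(gen$sites, cfg)
  pl <- plant_regions(truth0, cfg)
  counts <- simulate_counts(pl$truth, cfg)
  genes <- make_gene_models(cfg, pl$regions)
  ec <- simulate_expression_cnv(cfg, genes, pl$regions)
  set.seed(cfg$rng_seed + 6L)
  enh <- data.frame(
    chrom = sprintf("chr%d", sample.int(cfg$n_chrom, cfg$n_enhancers,
                                        replace = TRUE)),
    start = sample.int(cfg$chrom_length - cfg$enhancer_length,
                       cfg$n_enhancers), stringsAsFactors = FALSE)
  enh$end <- enh$start + cfg$enhancer_length
  enh <- enh[order(enh$chrom, enh$start), ]
  rownames(enh) <- NULL
  sim <- list(config = cfg, genome = gen$genome, sites = gen$sites,
              truth = pl$truth, regions = pl$regions, counts = counts,
              genes = genes, enhancers = enh,
              expr_array = ec$expr_array, array_groups = ec$array_groups,
              expr_counts = ec$expr_counts, count_pairs = ec$count_pairs,
              lib_sizes = ec$lib_sizes, cnv = ec$cnv,
              expr_truth = ec$truth)
  if (!is.null(out_dir)) write_sim(sim, out_dir)
  sim
}

#' Write a simulated study to plain-text files
#'
#' @param sim result of [simulate_hmst()].
#' @param out_dir directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_sim <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  Biostrings::writeXStringSet(sim$genome, p("genome.fa"))
  write.table(sim$counts, p("counts.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  lv <- do.call(rbind, lapply(unique(sim$counts$sample), function(s) {
    grp <- sim$counts$group[match(s, sim$counts$sample)]
    data.frame(chrom = sim$truth$chrom, pos = sim$truth$pos, sample = s,
               group = grp, m = sim$truth[[paste0("m_", grp)]],
               h = sim$truth[[paste0("h_", grp)]])
  }))
  write.table(lv, p("levels.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$genes, p("genes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$enhancers, p("enhancers.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  for (nm in c("expr_array", "expr_counts")) {
    m <- data.frame(gene_id = rownames(sim[[nm]]), sim[[nm]],
                    check.names = FALSE)
    write.table(m, p(paste0(nm, ".tsv")), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  write.table(sim$cnv, p("cnv.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  truth <- list(site_truth = sim$truth,
                regions = within(sim$regions,
                                 member_sites <- I(lapply(member_sites, c))),
                expression = sim$expr_truth, lib_sizes = sim$lib_sizes)
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(out_dir)
}
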