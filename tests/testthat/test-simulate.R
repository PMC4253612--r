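small_cfg <- function(...) {
  args <- list(n_chrom = 1, chrom_length = 6e5, n_dmr = 6, n_dhmr = 3,
               n_tsg = 3, n_genes = 40, n_enhancers = 5)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

test_that("stamped motifs are recovered exactly by digestion", {
  cfg <- small_cfg()
  gen <- make_genome(cfg)
  for (motif in c("CCGG", "CATG")) {
    found <- find_sites(gen$genome, motif)
    truth <- gen$sites[gen$sites$motif == motif, ]
    expect_equal(found$motif_start, truth$pos)
  }
  expect_equal(sum(gen$sites$motif == "CCGG"),
               round(cfg$chrom_length / 1000 * cfg$ccgg_per_kb))
})

test_that("the generator is deterministic and seed-sensitive", {
  g1 <- make_genome(small_cfg())
  g2 <- make_genome(small_cfg())
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  g3 <- make_genome(small_cfg(rng_seed = 2))
  expect_false(identical(as.character(g1$genome), as.character(g3$genome)))

  s1 <- simulate_hmst(small_cfg())
  s2 <- simulate_hmst(small_cfg())
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$expr_array, s2$expr_array)
  expect_identical(s1$cnv, s2$cnv)
})

test_that("zero CATG density yields no virtual tags", {
  cfg <- small_cfg(catg_per_kb = 0)
  gen <- make_genome(cfg)
  tags <- build_virtual_library(find_sites(gen$genome, "CCGG"),
                                find_sites(gen$genome, "CATG"))
  expect_equal(nrow(tags), 0L)
})

test_that("count model means follow the three-library design", {
  cfg <- small_cfg(lib_factors = c(1, 1, 1), depth_cv = 0, site_depth_sd = 0)
  gen <- make_genome(cfg)
  truth <- hmstseq:::make_site_truth(gen$sites, cfg)
  # h = 1: expected L2 is zero
  truth$h_case <- 1; truth$u_case <- 0; truth$m_case <- 0
  cnt <- simulate_counts(truth, cfg)
  ca <- cnt[cnt$group == "case", ]
  expect_lt(mean(ca$L2), 0.01 * cfg$mean_depth)
  # u = 1: all three libraries share a mean (within 3 standard errors)
  truth$u_control <- 1; truth$m_control <- 0; truth$h_control <- 0
  cnt2 <- simulate_counts(truth, cfg)
  co <- cnt2[cnt2$group == "control", ]
  se <- sqrt(cfg$mean_depth / nrow(co))
  expect_lt(abs(mean(co$L1) - mean(co$L2)), 3 * sqrt(2) * se)
  expect_lt(abs(mean(co$L1) - mean(co$L3)), 3 * sqrt(2) * se)
  # zero depth gives zero counts
  cfg0 <- small_cfg(mean_depth = 0, depth_cv = 0)
  cnt0 <- simulate_counts(truth, cfg0)
  expect_true(all(cnt0[, c("L1", "L2", "L3")] == 0))
})

test_that("expected counts invert exactly through the fraction estimator", {
  cfg <- small_cfg(lib_factors = c(1, 1, 1), depth_cv = 0)
  gen <- make_genome(cfg)
  pl <- plant_regions(hmstseq:::make_site_truth(gen$sites, cfg), cfg)
  mu <- simulate_counts(pl$truth, cfg, poisson = FALSE)
  one <- mu[mu$sample == "case_1", ]
  fr <- estimate_fractions(one$L1, one$L2, one$L3)
  expect_equal(fr$u_hat, pl$truth$u_case, tolerance = 1e-12)
  expect_equal(fr$m_hat, pl$truth$m_case, tolerance = 1e-12)
  expect_equal(fr$h_hat, pl$truth$h_case, tolerance = 1e-12)
})

test_that("planted regions shift the truth by exactly the effect size", {
  cfg <- small_cfg()
  gen <- make_genome(cfg)
  pl <- plant_regions(hmstseq:::make_site_truth(gen$sites, cfg), cfg)
  reg <- pl$regions
  expect_equal(sum(reg$kind == "DMR"), cfg$n_dmr)
  expect_equal(sum(reg$kind == "DhMR"), cfg$n_dhmr)
  tr <- pl$truth
  for (i in seq_len(nrow(reg))) {
    k <- match(paste(reg$chrom[i], reg$member_sites[[i]]),
               paste(tr$chrom, tr$pos))
    expect_true(all(diff(tr$pos[k]) <= 2000))
    if (reg$kind[i] == "DMR") {
      d <- tr$m_case[k] - tr$m_control[k]
      expect_equal(d, rep(if (reg$direction[i] == "hyper") cfg$dmr_delta
                          else -cfg$dmr_delta, length(k)), tolerance = 1e-9)
    } else {
      d <- tr$h_case[k] - tr$h_control[k]
      expect_equal(d, rep(if (reg$direction[i] == "hyper") cfg$dhmr_delta
                          else -cfg$dhmr_delta, length(k)), tolerance = 1e-9)
    }
    # fractions remain a valid simplex point in both groups
    for (grp in c("case", "control")) {
      s <- tr[[paste0("u_", grp)]][k] + tr[[paste0("m_", grp)]][k] +
        tr[[paste0("h_", grp)]][k]
      expect_equal(s, rep(1, length(k)), tolerance = 1e-9)
    }
  }
  # asking for more regions than the genome can hold fails loudly
  expect_error(plant_regions(hmstseq:::make_site_truth(gen$sites, cfg),
                             small_cfg(n_dmr = 500)),
               "could not place")
})

test_that("expression truth behaves under null and planted folds", {
  # global null: no planted DEGs -> empty DEG set in expectation
  cfg <- small_cfg(n_tsg = 0, deg_frac = 0, n_cnv_masked = 0)
  gen <- make_genome(cfg)
  pl <- plant_regions(hmstseq:::make_site_truth(gen$sites, cfg), cfg)
  genes <- make_gene_models(cfg, pl$regions)
  ec <- simulate_expression_cnv(cfg, genes, pl$regions)
  dd <- list(arr = deg_array(ec$expr_array, ec$array_groups$case,
                             ec$array_groups$control))
  for (p in seq_len(nrow(ec$count_pairs))) {
    r <- deg_counts(ec$expr_counts[, ec$count_pairs$case[p]],
                    ec$expr_counts[, ec$count_pairs$control[p]],
                    ec$lib_sizes[ec$count_pairs$case[p]],
                    ec$lib_sizes[ec$count_pairs$control[p]])
    r$gene_id <- rownames(ec$expr_counts)
    dd[[p + 1]] <- r
  }
  degs <- combine_degs(dd)
  expect_lte(sum(degs$is_deg), 2)

  # a planted strong drop is found as a down-DEG across seeds
  found <- vapply(1:10, function(s) {
    cfg2 <- small_cfg(n_tsg = 3, tsg_fold = 8, deg_frac = 0.1, rng_seed = s)
    gen2 <- make_genome(cfg2)
    pl2 <- plant_regions(hmstseq:::make_site_truth(gen2$sites, cfg2), cfg2)
    genes2 <- make_gene_models(cfg2, pl2$regions)
    ec2 <- simulate_expression_cnv(cfg2, genes2, pl2$regions)
    r <- deg_counts(ec2$expr_counts[, "rna_p1_case"],
                    ec2$expr_counts[, "rna_p1_ctrl"],
                    ec2$lib_sizes["rna_p1_case"],
                    ec2$lib_sizes["rna_p1_ctrl"])
    r$gene_id <- rownames(ec2$expr_counts)
    tsg1 <- ec2$truth$tsg[1]
    i <- match(tsg1, r$gene_id)
    r$fdr[i] < 0.05 && r$direction[i] == -1L
  }, logical(1))
  expect_gte(mean(found), 0.9)

  # a planted up-DEG under an amplification is removed by the CNV filter
  cfg3 <- small_cfg(n_cnv_masked = 2)
  sim3 <- simulate_hmst(cfg3)
  degs3 <- data.frame(gene_id = sim3$expr_truth$deg$gene_id,
                      direction = c("down", NA, "up")[
                        match(sim3$expr_truth$deg$direction, c(-1, 0, 1))],
                      min_fdr = 0.01, consistent = TRUE,
                      is_deg = sim3$expr_truth$deg$direction != 0,
                      stringsAsFactors = FALSE)
  kept <- cnv_filter(degs3, sim3$cnv, sim3$genes)
  expect_false(any(sim3$expr_truth$masked_amp %in% kept$gene_id))
})

test_that("written study files are byte-identical across runs", {
  d1 <- file.path(tempdir(), "simA")
  d2 <- file.path(tempdir(), "simB")
  simulate_hmst(small_cfg(), out_dir = d1)
  simulate_hmst(small_cfg(), out_dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f), warn = FALSE),
                     readLines(file.path(d2, f), warn = FALSE), label = f)
  }
})
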