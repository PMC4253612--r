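test_that("array DEG test behaves under null and matches permutation", {
  set.seed(51)
  expr <- matrix(2^rnorm(100 * 6, 7, 1), 100, 6,
                 dimnames = list(sprintf("g%03d", 1:100),
                                 c("c1", "c2", "c3", "n1", "n2", "n3")))
  r <- deg_array(expr, c("c1", "c2", "c3"), c("n1", "n2", "n3"))
  expect_true(all(r$p >= 2 / 20))  # smallest attainable p at 3v3
  expect_lt(sum(r$fdr < 0.05), 2)

  # a fully separated gene reaches the enumeration-oracle value
  expr[1, ] <- c(100, 110, 120, 10, 11, 12)
  r2 <- deg_array(expr, c("c1", "c2", "c3"), c("n1", "n2", "n3"))
  expect_equal(r2$p[1], enum_wilcox_p(c(100, 110, 120), c(10, 11, 12)),
               tolerance = 1e-12)
  expect_equal(r2$direction[1], 1L)

  # constant genes get p = 1
  expr[2, ] <- 5
  r3 <- deg_array(expr, c("c1", "c2", "c3"), c("n1", "n2", "n3"))
  expect_equal(r3$p[2], 1)
})

test_that("planted array shifts are recovered with good sensitivity", {
  set.seed(52)
  ng <- 2000
  n <- 10
  de <- seq_len(ng) <= 200  # 10% of genes, 2-fold shift
  base <- rnorm(ng, 7, 1.5)
  mat <- matrix(0, ng, 2 * n,
                dimnames = list(sprintf("g%04d", seq_len(ng)),
                                c(sprintf("ca%d", 1:n), sprintf("co%d", 1:n))))
  for (j in 1:n) {
    mat[, j] <- 2^(base + ifelse(de, 1, 0) + rnorm(ng, 0, 0.25))
    mat[, n + j] <- 2^(base + rnorm(ng, 0, 0.25))
  }
  r <- deg_array(mat, sprintf("ca%d", 1:n), sprintf("co%d", 1:n))
  sens <- mean(r$fdr[de] < 0.05 & r$direction[de] == 1)
  expect_gte(sens, 0.8)
})

test_that("count DEG test equals direct binomial summation and is symmetric", {
  r <- deg_counts(100, 100, 1e5, 1e5)
  expect_gte(r$p, 0.5)
  # brute-force two-sided minimum-likelihood sum at x=100, y=10
  d <- stats::dbinom(0:110, 110, 0.5)
  want <- sum(d[d <= d[101] * (1 + 1e-7)])
  expect_equal(deg_counts(100, 10, 1e5, 1e5)$p, want, tolerance = 1e-9)
  a <- deg_counts(40, 90, 2e5, 3e5)
  b <- deg_counts(90, 40, 3e5, 2e5)
  expect_equal(a$p, b$p, tolerance = 1e-12)
  expect_equal(a$direction, -b$direction)
  expect_equal(deg_counts(0, 0, 1e5, 1e5)$p, 1)
})

test_that("per-group DEG combination applies the FDR and direction rules", {
  g1 <- data.frame(gene_id = c("a", "b", "c"), fdr = c(0.01, 0.01, 0.4),
                   direction = c(1L, 1L, 1L))
  g2 <- data.frame(gene_id = c("a", "b", "c"), fdr = c(0.2, 0.3, 0.3),
                   direction = c(1L, -1L, 1L))
  out <- combine_degs(list(g1, g2))
  expect_equal(out$is_deg, c(TRUE, FALSE, FALSE))
  expect_equal(out$direction[1], "up")
})

test_that("the CNV filter drops only dosage-concordant DEGs", {
  genes <- gene_models(data.frame(
    gene_id = c("up_amp", "dn_amp", "up_clear", "dn_del"),
    chrom = "chr1", strand = "+",
    tx_start = c(1000, 5000, 9000, 13000),
    tx_end = c(3000, 7000, 11000, 15000), stringsAsFactors = FALSE))
  degs <- data.frame(gene_id = genes$gene_id,
                     direction = c("up", "down", "up", "down"),
                     min_fdr = 0.01, consistent = TRUE, is_deg = TRUE,
                     stringsAsFactors = FALSE)
  segs <- data.frame(sample_id = "case_1", chrom = "chr1",
                     start = c(500, 4500, 12500), end = c(7500, 7600, 15500),
                     state = c("amplification", "amplification", "deletion"),
                     stringsAsFactors = FALSE)
  out <- cnv_filter(degs, segs, genes)
  expect_setequal(out$gene_id, c("dn_amp", "up_clear"))

  # random fixtures vs a brute-force interval check: a gene without any
  # overlapping segment is never removed
  set.seed(53)
  for (rep in 1:20) {
    ng <- 30
    gg <- gene_models(data.frame(
      gene_id = sprintf("g%02d", 1:ng), chrom = "chr1", strand = "+",
      tx_start = st <- sort(sample(1:2e5, ng)) * 10L,
      tx_end = st * 10L + 2000L, stringsAsFactors = FALSE))
    dd <- data.frame(gene_id = gg$gene_id,
                     direction = sample(c("up", "down"), ng, TRUE),
                     min_fdr = 0.01, consistent = TRUE, is_deg = TRUE,
                     stringsAsFactors = FALSE)
    ss <- data.frame(sample_id = "case_1", chrom = "chr1",
                     start = s0 <- sample(1:2e6, 8),
                     end = s0 + sample(1e4:1e5, 8),
                     state = sample(c("amplification", "deletion"), 8, TRUE),
                     stringsAsFactors = FALSE)
    out <- cnv_filter(dd, ss, gg)
    removed <- setdiff(dd$gene_id, out$gene_id)
    for (i in seq_len(ng)) {
      ovl <- ss[ss$start < gg$tx_end[i] & ss$end > gg$tx_start[i], ]
      concord <- (dd$direction[i] == "up" &
                    any(ovl$state == "amplification")) ||
        (dd$direction[i] == "down" & any(ovl$state == "deletion"))
      expect_equal(gg$gene_id[i] %in% removed, concord)
    }
  }
})

test_that("candidate screen matches hand enumeration on a toy fixture", {
  # 6 genes: strand-adjusted 5-kb upstream windows with hand-placed regions
  genes <- gene_models(data.frame(
    gene_id = sprintf("g%d", 1:6), chrom = "chr1",
    strand = c("+", "+", "-", "+", "+", "+"),
    tx_start = c(10000, 30000, 50000, 70000, 90000, 110000),
    tx_end = c(12000, 32000, 52000, 72000, 92000, 112000),
    stringsAsFactors = FALSE))
  degs <- data.frame(gene_id = genes$gene_id,
                     direction = c("down", "up", "down", "down", "down", "down"),
                     min_fdr = 0.01, consistent = TRUE,
                     is_deg = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
                     stringsAsFactors = FALSE)
  reg <- function(start, dir, kind)
    data.frame(chrom = "chr1", start = start, end = start + 1000,
               kind = kind, direction = dir, n_sites = 6, p_value = 0.01,
               stringsAsFactors = FALSE)
  dmrs <- rbind(reg(6000, "hyper", "DMR"),      # g1 window [5000,10000)
                reg(26000, "hyper", "DMR"),     # g2 (up) window
                reg(52100, "hyper", "DMR"),     # g3 minus strand upstream
                reg(66000, "hyper", "DMR"),     # g4
                reg(86000, "hyper", "DMR"),     # g5
                reg(106000, "hyper", "DMR"))    # g6 (not a DEG)
  dhmrs <- reg(86400, "hyper", "DhMR")          # g5: sign conflict
  out <- screen_candidates(degs, dmrs, dhmrs, genes)
  expect_setequal(out$gene_id, c("g1", "g2", "g3", "g4", "g5"))
  pass <- out$gene_id[out$passes_sign_rule]
  # g1: down + hyper-DMR -> pass; g2: up + hyper-DMR -> fail;
  # g3, g4: pass; g5: hyper-DMR + hyper-DhMR -> opposite-direction fail
  expect_setequal(pass, c("g1", "g3", "g4"))

  # invariance to input ordering
  out2 <- screen_candidates(degs[sample(6), ], dmrs[sample(6), ],
                            dhmrs, genes[sample(6), ])
  expect_equal(out2[order(out2$gene_id), ]$passes_sign_rule,
               out[order(out$gene_id), ]$passes_sign_rule)
})

test_that("hypergeometric enrichment matches the direct tail sum", {
  u <- sprintf("g%03d", 1:60)
  pw <- list(A = u[1:10], B = u[11:40])
  gs <- u[1:12]
  res <- hypergeom_enrichment(gs, pw, u)
  # brute-force upper-tail sum for pathway A: k=10, K=10, n=12, N=60
  want <- sum(sapply(10:10, function(k)
    choose(10, k) * choose(50, 12 - k) / choose(60, 12)))
  expect_equal(res$p[res$pathway == "A"], want, tolerance = 1e-12)
  expect_equal(res$q, stats::p.adjust(res$p, "BH"))
  # a set equal to a pathway's membership gives that pathway the smallest p
  res2 <- hypergeom_enrichment(u[11:40], pw, u)
  expect_equal(res2$pathway[which.min(res2$p)], "B")
})

test_that("enrichment rate reproduces the reported percentages", {
  u <- sprintf("g%05d", 1:20000)
  set_genes <- u[1:1373]
  pw <- list(sig = u[1:231], other = u[5000:5400])
  enr <- data.frame(pathway = c("sig", "other"), q = c(0.001, 0.9))
  er <- enrichment_rate(set_genes, enr, pw)
  expect_equal(er$n_in_sig, 231)
  expect_equal(er$rate_pct, 16.8)
  er2 <- enrichment_rate(u[1:218], data.frame(pathway = "sig", q = 0.001),
                         list(sig = u[1:19]))
  expect_equal(er2$rate_pct, 8.7)
})
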