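# Integration statistics: gene-level copy number, G/N grouping, the
# empirical-Bayes moderated t (cross-checked against limma and the
# ordinary covariate-adjusted t), BH adjustment, correlation and Welch.

test_that("gene copy number is the bp-weighted mean over the flanked span", {
  segs <- data.frame(chrom = "chr1", start = c(0, 50000), end = c(50000, 100000),
                     mean_cn = c(2, 4))
  # gene wholly inside one segment
  one <- data.frame(chrom = "chr1", start = 10000, end = 20000)
  expect_equal(gene_copy_number(segs, one, flank = 1e4),
               2)
  segs32 <- data.frame(chrom = "chr1", start = 0, end = 1e5, mean_cn = 3.2)
  expect_equal(gene_copy_number(segs32, one, flank = 1e4), 3.2)
  # equal bp in CN 2 and CN 4 after flanking: [30000, 70000) around 50000
  half <- data.frame(chrom = "chr1", start = 40000, end = 60000)
  expect_equal(gene_copy_number(segs, half, flank = 1e4), 3.0)
  # chromosome with no segments -> missing
  off <- data.frame(chrom = "chr9", start = 0, end = 1000)
  expect_true(is.na(gene_copy_number(segs, off)))
})

test_that("gene_cn_matrix agrees with scalar extraction per gene and sample", {
  set.seed(51)
  segs <- do.call(rbind, lapply(c("A", "B"), function(s) {
    bks <- sort(c(0, sample(1:99999, 4), 1e5))
    data.frame(sample = s, chrom = "chr1", start = bks[-6], end = bks[-1],
               mean_cn = runif(5, 1, 6))
  }))
  genes <- data.frame(gene = c("g1", "g2"), chrom = "chr1",
                      start = c(20000, 70000), end = c(30000, 71000))
  m <- gene_cn_matrix(segs, genes, flank = 1e4)
  for (g in 1:2) for (s in c("A", "B")) {
    expect_equal(m[genes$gene[g], s],
                 gene_copy_number(segs[segs$sample == s, ], genes[g, ],
                                  flank = 1e4))
  }
})

test_that("group assignment follows the >3 and 1.5-2.5 copy rules", {
  cn <- c(a = 3.4, b = 2.0, c = 2.7, d = 1.2, e = NA, f = 3.0)
  g <- assign_groups(cn)
  expect_equal(g$group[g$sample == "a"], "G")
  expect_equal(g$group[g$sample == "b"], "N")
  expect_equal(g$group[g$sample == "c"], "excluded")
  expect_equal(g$reason[g$sample == "c"], "intermediate")
  expect_equal(g$reason[g$sample == "d"], "loss")
  expect_equal(g$reason[g$sample == "e"], "missing")
  # exactly 3 copies is not strictly greater than the cutoff
  expect_equal(g$group[g$sample == "f"], "excluded")
  # the laxer "3 or more copies" reading is available via the cutoff
  g2 <- assign_groups(cn, gain_cutoff = 2.999)
  expect_equal(g2$group[g2$sample == "f"], "G")
})

make_de_data <- function(n_genes, nG = 8, nN = 10, beta = 0, sigma = 1,
                         seed = 1) {
  set.seed(seed)
  samples <- c(sprintf("G%02d", 1:nG), sprintf("N%02d", 1:nN))
  grp <- rep(c(1, 0), c(nG, nN))
  ht <- setNames(sample(c("serous", "endometrioid", "mucinous"),
                        nG + nN, replace = TRUE), samples)
  ht_eff <- c(serous = 0, endometrioid = 0.4, mucinous = -0.3)
  expr <- t(vapply(seq_len(n_genes), function(g) {
    5 + beta * grp + ht_eff[ht] + rnorm(nG + nN, 0, sigma)
  }, numeric(nG + nN)))
  rownames(expr) <- sprintf("p%04d", seq_len(n_genes))
  colnames(expr) <- samples
  list(expr = expr, groups = list(G = samples[grp == 1], N = samples[grp == 0]),
       ht = ht)
}

test_that("identical values in G and N give logFC 0 and p 1", {
  d <- make_de_data(5, seed = 2)
  d$expr[1, ] <- 7
  expect_warning(fit <- moderated_t_test(d$expr, d$groups, d$ht),
                 "zero/invalid residual variance")
  expect_equal(fit$table$logFC[1], 0)
  expect_equal(fit$table$p_raw[1], 1)
})

test_that("with d0 = 0 the moderated t equals the ordinary adjusted t", {
  d <- make_de_data(50, beta = 0.5, seed = 3)
  fit <- moderated_t_test(d$expr, d$groups, d$ht,
                          prior = list(d0 = 0, s0_sq = 1))
  grp <- factor(ifelse(colnames(d$expr) %in% d$groups$G, "G", "N"),
                levels = c("N", "G"))
  for (g in seq(1, 50, by = 7)) {
    lmfit <- lm(d$expr[g, ] ~ grp + factor(d$ht[colnames(d$expr)]))
    ct <- summary(lmfit)$coefficients["grpG", ]
    expect_equal(fit$table$logFC[g], unname(ct["Estimate"]), tolerance = 1e-10)
    expect_equal(fit$table$t[g], unname(ct["t value"]), tolerance = 1e-10)
    expect_equal(fit$table$p_raw[g], unname(ct["Pr(>|t|)"]), tolerance = 1e-10)
  }
})

test_that("as d0 grows all posterior variances shrink to s0^2", {
  d <- make_de_data(40, seed = 4)
  fit <- moderated_t_test(d$expr, d$groups, d$ht,
                          prior = list(d0 = Inf, s0_sq = 2))
  grp <- factor(ifelse(colnames(d$expr) %in% d$groups$G, "G", "N"),
                levels = c("N", "G"))
  X <- model.matrix(~ grp + factor(d$ht[colnames(d$expr)]))
  v <- solve(crossprod(X))["grpG", "grpG"]
  expect_equal(fit$table$t, fit$table$logFC / sqrt(2 * v), tolerance = 1e-12)
})

test_that("moderated statistics match limma's empirical-Bayes pipeline", {
  skip_if_not_installed("limma")
  d <- make_de_data(200, beta = 0.3, sigma = 0.8, seed = 5)
  fit <- moderated_t_test(d$expr, d$groups, d$ht)
  grp <- factor(ifelse(colnames(d$expr) %in% d$groups$G, "G", "N"),
                levels = c("N", "G"))
  design <- model.matrix(~ grp + factor(d$ht[colnames(d$expr)]))
  lfit <- limma::eBayes(limma::lmFit(d$expr, design))
  expect_equal(fit$table$logFC, unname(lfit$coefficients[, "grpG"]),
               tolerance = 1e-10)
  expect_equal(fit$prior$d0, lfit$df.prior, tolerance = 1e-6)
  expect_equal(fit$prior$s0_sq, lfit$s2.prior, tolerance = 1e-6)
  expect_equal(fit$table$t, unname(lfit$t[, "grpG"]), tolerance = 1e-8)
  expect_equal(fit$table$p_raw, unname(lfit$p.value[, "grpG"]),
               tolerance = 1e-8)
})

test_that("a planted logFC of 1 is recovered without bias", {
  d <- make_de_data(500, nG = 15, nN = 15, beta = 1.0, sigma = 0.5, seed = 6)
  fit <- moderated_t_test(d$expr, d$groups, d$ht)
  expect_lt(abs(mean(fit$table$logFC) - 1.0), 0.1)
})

test_that("group-size preconditions are enforced", {
  d <- make_de_data(5, nG = 1, nN = 10, seed = 7)
  expect_error(moderated_t_test(d$expr, d$groups, d$ht), "at least 2")
})

test_that("BH adjustment matches the closed-form step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(52)
  for (rep in 1:20) {
    p <- runif(sample(1:200, 1))
    if (rep %% 3 == 0) p[sample(length(p), 2, replace = TRUE)] <- NA
    expect_equal(bh_adjust(p), p.adjust(p, "BH"))
  }
})

test_that("BH is permutation-invariant and rank-monotone", {
  set.seed(53)
  p <- runif(50)
  adj <- bh_adjust(p)
  perm <- sample(50)
  expect_equal(bh_adjust(p[perm]), adj[perm])
  o <- order(p)
  expect_false(is.unsorted(adj[o]))
  expect_true(all(adj >= p))
})

test_that("correlation handles exact, inverse and degenerate cases", {
  cn <- c(2, 2, 3, 4, 4, 5)
  lin <- cn_expr_correlation(1 + 0.5 * cn, cn)
  expect_equal(lin$r, 1)
  expect_equal(lin$p_raw, 0)
  inv <- cn_expr_correlation(-cn, cn)
  expect_equal(inv$r, -1)
  expect_true(is.na(cn_expr_correlation(rep(1, 6), cn)$r))
  expect_true(is.na(cn_expr_correlation(c(1, 2), c(1, 2))$r))
  # p-value matches cor.test
  set.seed(54)
  x <- rnorm(30); y <- x + rnorm(30)
  ours <- cn_expr_correlation(x, y)
  ref <- cor.test(x, y)
  expect_equal(ours$r, unname(ref$estimate))
  expect_equal(ours$p_raw, ref$p.value, tolerance = 1e-12)
})

test_that("null correlations average to zero", {
  set.seed(55)
  r <- replicate(1000, cor(rnorm(68), rnorm(68)))
  expect_lt(abs(mean(r)), 0.02)
})

test_that("Welch test matches the closed form and stats::t.test", {
  same <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  a <- c(1, 2, 3); b <- c(1, 2, 3, 4, 5)
  w <- welch_t_test(a, b)
  se2 <- var(a) / 3 + var(b) / 5
  t_hand <- (mean(a) - mean(b)) / sqrt(se2)
  df_hand <- se2^2 / ((var(a) / 3)^2 / 2 + (var(b) / 5)^2 / 4)
  expect_equal(w$t, t_hand)
  expect_equal(w$df, df_hand)
  ref <- t.test(a, b)
  expect_equal(w$t, unname(ref$statistic))
  expect_equal(w$p, ref$p.value)

  big <- welch_t_test(rnorm(10, 0, 0.1), rnorm(10, 3, 0.1))
  expect_lt(big$p, 1e-6)
  # zero variance in both groups
  expect_equal(welch_t_test(c(2, 2), c(2, 2))$p, 1)
  expect_equal(welch_t_test(c(2, 2), c(3, 3))$p, 0)
})

test_that("per-region integration produces coherent tables", {
  cfg <- tiny_cohort_config(seed = 61)
  sim <- simulate_cohort(cfg)
  ex <- simulate_expression(sim, sim$truth, sigma_e = 0.3, seed = 3)
  segs <- call_state(segment_profiles(sim$tumour_markers, cbs_params(),
                                      seed = 4))
  regions <- data.frame(region_id = "1_1", chrom = "chr1",
                        start = 4e6, end = 8e6)
  it <- integrate_regions(regions, segs, ex$expr, ex$probe_map,
                          sim$truth$genes, histotype = sim$truth$histotype)
  res <- it$results
  expect_true(all(res$p_adj >= res$p_raw, na.rm = TRUE))
  expect_true(all(res$r >= -1 & res$r <= 1, na.rm = TRUE))
  expect_true(all(res$n_G >= 2 & res$n_N >= 2))
  # planted dosage genes inside the region must be strongly differential
  dosage <- sim$truth$genes$gene[sim$truth$genes$beta > 0]
  hits <- res[res$gene %in% dosage, ]
  expect_gt(nrow(hits), 0)
  expect_true(all(hits$logFC > 0))
})
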