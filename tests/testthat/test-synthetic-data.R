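# Synthetic cohort generator: determinism, planted-structure recovery and
# the expression dosage model.

test_that("identical config and seed give bit-identical cohorts", {
  cfg <- tiny_cohort_config(seed = 42)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$tumour_markers, b$tumour_markers)
  expect_identical(a$normal_markers, b$normal_markers)
  expect_identical(a$truth$events, b$truth$events)
  ea <- simulate_expression(a, a$truth, sigma_e = 0.3, seed = 5)
  eb <- simulate_expression(b, b$truth, sigma_e = 0.3, seed = 5)
  expect_identical(ea$expr, eb$expr)
})

test_that("amplicon carrier counts fall in the binomial 99% CI", {
  cfg <- cohort_config(
    n_tumours = 60, n_normals = 0, chrom_lengths = c(chr1 = 10e6),
    marker_spacing = 1e6, passenger_rate = 0, noise_sd_cn = 0, n_genes = 10,
    driver_amplicons = list(
      planted_amplicon("chr1", 2e6, 5e6, frequency = 0.5, cn = 4, beta = 0)),
    seed = 3)
  sim <- simulate_cohort(cfg)
  carriers <- sum(sim$truth$events$class == "driver")
  ci <- qbinom(c(0.005, 0.995), 60, 0.5)
  expect_gte(carriers, ci[1])
  expect_lte(carriers, ci[2])
})

test_that("a null config with zero noise yields exactly diploid markers", {
  cfg <- cohort_config(
    n_tumours = 4, n_normals = 2, chrom_lengths = c(chr1 = 5e6),
    marker_spacing = 5e5, passenger_rate = 0, noise_sd_cn = 0, n_genes = 5,
    seed = 1)
  sim <- simulate_cohort(cfg)
  expect_true(all(sim$tumour_markers$cn == 2))
  expect_true(all(sim$normal_markers$cn == 2))
})

test_that("a CNP carrier's matched normal shows the CNP", {
  cfg <- cohort_config(
    n_tumours = 20, n_normals = 20, chrom_lengths = c(chr1 = 10e6),
    marker_spacing = 5e5, passenger_rate = 0, noise_sd_cn = 0, n_genes = 5,
    cnp_spec = list(planted_cnp("chr1", 3e6, 6e6, 0.5)), seed = 9)
  sim <- simulate_cohort(cfg)
  ev <- sim$truth$events
  carriers <- ev$sample[ev$class == "cnp"]
  expect_gt(length(carriers), 0)
  for (tid in carriers) {
    nid <- sim$samples$matched_normal[sim$samples$sample == tid]
    nm <- sim$normal_markers
    inside <- nm$sample == nid & nm$pos > 3e6 & nm$pos <= 6e6
    expect_true(all(nm$cn[inside] != 2)) # one-copy gain or loss, no noise
    outside <- nm$sample == nid & !(nm$pos > 3e6 & nm$pos <= 6e6)
    expect_true(all(nm$cn[outside] == 2))
  }
})

test_that("empirical carrier frequency converges to the configured one", {
  cfg <- cohort_config(
    n_tumours = 500, n_normals = 0, chrom_lengths = c(chr1 = 10e6),
    marker_spacing = 2e6, passenger_rate = 0, noise_sd_cn = 0, n_genes = 4,
    driver_amplicons = list(
      planted_amplicon("chr1", 2e6, 6e6, frequency = 0.3, cn = 4, beta = 0)),
    seed = 17)
  sim <- simulate_cohort(cfg)
  freq <- sum(sim$truth$events$class == "driver") / 500
  expect_lt(abs(freq - 0.3), 3 * sqrt(0.3 * 0.7 / 500))
})

test_that("noiseless dosage genes correlate perfectly with copy number", {
  cfg <- tiny_cohort_config(seed = 21)
  cfg$histotype_gene_fraction <- 0 # no histotype offsets: pure dosage signal
  sim <- simulate_cohort(cfg)
  ex <- simulate_expression(sim, sim$truth, sigma_e = 0, seed = 2)
  genes <- sim$truth$genes
  dosage <- genes$gene[genes$beta > 0]
  expect_gt(length(dosage), 0)
  for (g in dosage) {
    cn <- sim$truth$gene_cn[g, ]
    if (sd(cn) == 0) next
    r <- cor(ex$expr[paste0(g, "_p1"), ], cn)
    expect_equal(r, 1, tolerance = 1e-12)
  }
})

test_that("null-gene correlations follow the null distribution at n = 60", {
  # beta = 0 genes paired with an unrelated copy-number covariate: the
  # fraction with |r| < 0.25 should match the t-transform prediction
  set.seed(33)
  n <- 60
  reps <- 500
  r <- replicate(reps, cor(rnorm(n), rnorm(n)))
  crit <- 0.25
  tcrit <- crit * sqrt((n - 2) / (1 - crit^2))
  expected <- 1 - 2 * pt(-tcrit, df = n - 2)
  emp <- mean(abs(r) < crit)
  ci <- qbinom(c(0.005, 0.995), reps, expected) / reps
  expect_gte(emp, ci[1])
  expect_lte(emp, ci[2])
})

test_that("histotype offsets shift group means by the planted amount", {
  cfg <- cohort_config(
    n_tumours = 40, n_normals = 0, chrom_lengths = c(chr1 = 10e6),
    marker_spacing = 1e6, passenger_rate = 0, noise_sd_cn = 0, n_genes = 10,
    histotypes = c(serous = 0.5, mucinous = 0.5),
    histotype_gene_fraction = 0, seed = 8)
  sim <- simulate_cohort(cfg)
  g <- sim$truth$genes$gene[1]
  sim$truth$histotype_offsets[g, "serous"] <- 1.0
  ex <- simulate_expression(sim, sim$truth, sigma_e = 0.05, seed = 4)
  ht <- sim$truth$histotype
  d <- mean(ex$expr[paste0(g, "_p1"), names(ht)[ht == "serous"]]) -
    mean(ex$expr[paste0(g, "_p1"), names(ht)[ht == "mucinous"]])
  expect_equal(d, 1.0, tolerance = 0.1)
})

test_that("invalid configurations and inputs are rejected", {
  expect_error(cohort_config(n_tumours = 2), "n_tumours")
  expect_error(cohort_config(histotypes = c(a = 0.5, b = 0.4)), "sum to 1")
  expect_error(cohort_config(marker_spacing = 0), "marker_spacing")
  expect_error(cohort_config(driver_amplicons = list(
    planted_amplicon("chr1", 5e6, 70e6, 0.5))), "exceeds")
  expect_error(planted_amplicon("chr1", 10, 5, 0.5), "start")
  expect_error(planted_cnp("chr1", 0, 10, 1.5), "population_frequency")
  sim <- simulate_cohort(tiny_cohort_config())
  expect_error(simulate_expression(sim, sim$truth, sigma_e = -1), "sigma_e")
})

test_that("overlapping planted events resolve by the max-CN rule", {
  cfg <- cohort_config(
    n_tumours = 4, n_normals = 0, chrom_lengths = c(chr1 = 10e6),
    marker_spacing = 1e6, passenger_rate = 0, noise_sd_cn = 0, n_genes = 4,
    driver_amplicons = list(
      planted_amplicon("chr1", 1e6, 6e6, frequency = 1, cn = 3, beta = 0),
      planted_amplicon("chr1", 4e6, 8e6, frequency = 1, cn = 6, beta = 0)),
    seed = 2)
  sim <- simulate_cohort(cfg)
  m <- sim$tumour_markers[sim$tumour_markers$sample == "T001", ]
  expect_true(all(m$cn[m$pos > 4e6 & m$pos <= 8e6] == 6))
  expect_true(all(m$cn[m$pos > 1e6 & m$pos <= 4e6] == 3))
})
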