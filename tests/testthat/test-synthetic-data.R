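test_that("the generator is deterministic given the master seed", {
  d1 <- generate_cohorts(small_config(seed = 42L))
  d2 <- generate_cohorts(small_config(seed = 42L))
  expect_identical(d1$beta, d2$beta)
  expect_identical(d1$samples, d2$samples)
  expect_identical(d1$genotypes$dosage, d2$genotypes$dosage)
  d3 <- generate_cohorts(small_config(seed = 43L))
  expect_false(identical(d1$beta, d3$beta))
})

test_that("changing the SNP count does not perturb the methylation stream", {
  d1 <- generate_cohorts(small_config(seed = 7L, n_snps = 10L))
  d2 <- generate_cohorts(small_config(seed = 7L, n_snps = 500L))
  expect_identical(d1$beta, d2$beta)
})

test_that("zero noise, no effects, one cell type gives identical samples", {
  cfg <- small_config(seed = 2L, planted_effects = NULL, noise_sd = 0,
                      cell_types = "whole", dirichlet_concentration = 1,
                      n_signature_probes = 0L)
  ds <- generate_cohorts(cfg)
  expect_true(all(ds$beta >= 0 & ds$beta <= 1))
  expect_true(all(apply(ds$beta, 1, function(x) diff(range(x)) == 0)))
})

test_that("planted group-mean differences converge to the planted delta", {
  ds <- generate_cohorts(simulation_config(n_background_probes = 50L,
                                           n_snps = 0L, seed = 3L))
  disc <- ds$samples$cohort == "discovery"
  tol <- 3 * 0.03 * sqrt(1 / 31 + 1 / 83)
  for (i in seq_len(nrow(ds$truth$planted_bulk))) {
    pb <- ds$truth$planted_bulk[i, ]
    es <- effect_size(ds$beta[pb$cpg_id, disc],
                      ds$samples$treated[disc] == 1)
    expect_lt(abs(es$delta_beta - pb$delta_beta), tol)
  }
})

test_that("cluster probes share the configured noise correlation", {
  pe <- data.frame(gene = "GENE1", cpg_id = "cgx0000001", delta_beta = -0.1,
                   baseline = 0.6, n_cpgs_in_cluster = 3L,
                   within_cluster_correlation = 0.9)
  ds <- generate_cohorts(small_config(seed = 5L, planted_effects = pe,
                                      noise_sd = 0.05, n_snps = 0L))
  unt <- ds$samples$sample_id[ds$samples$treated == 0]
  cc <- cor(t(ds$beta[c("cgx0000001", "cgx0000001_2", "cgx0000001_3"), unt]))
  expect_true(all(abs(cc[upper.tri(cc)] - 0.9) < 0.1))
  # all cluster members carry the same planted effect
  expect_equal(nrow(ds$truth$planted_bulk), 3L)
  expect_true(all(ds$truth$planted_bulk$delta_beta == -0.1))
})

test_that("a cell-specific effect shifts bulk beta by proportion x effect", {
  ce <- data.frame(cpg_id = "cgb000010", cell_type = "Treg",
                   cell_level_delta_beta = 0.25)
  cfg <- small_config(seed = 6L, planted_effects = NULL, noise_sd = 0.002,
                      target_cell_effects = ce, n_snps = 0L)
  ds <- generate_cohorts(cfg)
  tr <- ds$samples$treated == 1
  es <- effect_size(ds$beta["cgb000010", ], tr)
  expected <- mean(ds$truth$proportions[tr, "Treg"]) * 0.25
  expect_lt(abs(es$delta_beta - expected), 0.003)
})

test_that("invalid configurations are rejected with informative errors", {
  pe <- data.frame(gene = "BAD", cpg_id = "cgx1", delta_beta = 0.3,
                   baseline = 0.9)
  expect_error(small_config(planted_effects = pe), "BAD")
  pe2 <- data.frame(gene = c("A", "B"), cpg_id = c("cgx1", "cgx1"),
                    delta_beta = c(0.1, 0.1), baseline = c(0.5, 0.5))
  expect_error(small_config(planted_effects = pe2), "duplicated")
  expect_error(small_config(n_treated_disc = 0L), "cohort sizes")
  expect_error(small_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(small_config(dirichlet_concentration = rep(-1, 8)),
               "positive")
  pe3 <- data.frame(gene = "C", cpg_id = "cgb000001", delta_beta = 0.1,
                    baseline = 0.5)
  expect_error(generate_cohorts(small_config(planted_effects = pe3)),
               "collides")
})

test_that("genotypes follow Hardy-Weinberg at fixed MAF", {
  g <- generate_genotypes(4000L, 5L, maf_range = c(0.5, 0.5), seed = 1L)
  freqs <- t(apply(g$dosage, 1, function(x) tabulate(x + 1L, 3L) / length(x)))
  expect_true(all(abs(freqs - matrix(c(0.25, 0.5, 0.25), 5, 3,
                                     byrow = TRUE)) < 0.04))
})

test_that("HWE goodness-of-fit rejects at roughly the nominal rate", {
  g <- generate_genotypes(300L, 600L, maf_range = c(0.1, 0.4), seed = 2L)
  # oracle: exact HWE expected counts from the estimated allele frequency
  rej <- vapply(seq_len(600), function(i) {
    obs <- tabulate(g$dosage[i, ] + 1L, 3L)
    n <- sum(obs)
    p <- (2 * obs[3] + obs[2]) / (2 * n)
    exp_cnt <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
    stat <- sum((obs - exp_cnt)^2 / exp_cnt)
    stat > qchisq(0.95, df = 1)
  }, logical(1))
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)
})

test_that("zero SNPs yields an empty matrix with a valid header", {
  g <- generate_genotypes(10L, 0L, seed = 1L)
  expect_identical(dim(g$dosage), c(0L, 10L))
  expect_identical(colnames(g$dosage), sprintf("S%04d", 1:10))
  expect_identical(nrow(g$info), 0L)
  expect_error(generate_genotypes(0L, 5L), "positive")
})

test_that("truth record lists exactly the planted effects", {
  ds <- generate_cohorts(simulation_config(n_background_probes = 30L,
                                           n_snps = 0L, seed = 9L))
  expect_setequal(ds$truth$planted_bulk$cpg_id, ifnb_index_cpgs()$cpg_id)
  expect_equal(ds$truth$planted_bulk$delta_beta,
               ifnb_index_cpgs()$delta_beta_disc[
                 match(ds$truth$planted_bulk$gene, ifnb_index_cpgs()$gene)])
  expect_true(all(colnames(ds$beta) == ds$samples$sample_id))
})
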