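make_panel <- function(n_probes = 120L, k = 8L, seed = 1L) {
  set.seed(seed)
  m <- matrix(runif(n_probes * k, 0.05, 0.95), n_probes, k)
  dimnames(m) <- list(sprintf("p%04d", seq_len(n_probes)),
                      paste0("cell", seq_len(k)))
  m
}

test_that("a pure sample is assigned weight one on its cell type", {
  panel <- make_panel()
  w <- estimate_proportions(panel[, 3], panel)
  expect_equal(unname(w["cell3"]), 1, tolerance = 1e-8)
  expect_equal(sum(w), 1, tolerance = 1e-6)
})

test_that("a 50/50 noiseless mixture matches a simplex grid-search oracle", {
  panel <- make_panel(k = 2L, seed = 2L)
  y <- 0.5 * panel[, 1] + 0.5 * panel[, 2]
  w <- estimate_proportions(y, panel)
  # oracle: best weight on a 0.01-resolution grid over the 2-simplex
  grid <- seq(0, 1, 0.01)
  sse <- vapply(grid, function(a)
    sum((y - (a * panel[, 1] + (1 - a) * panel[, 2]))^2), numeric(1))
  expect_equal(unname(w["cell1"]), grid[which.min(sse)], tolerance = 0.005)
  expect_equal(unname(w["cell1"]), 0.5, tolerance = 1e-8)
})

test_that("noiseless mixtures of a well-conditioned panel are recovered", {
  panel <- make_panel(seed = 3L)
  set.seed(4)
  for (i in 1:10) {
    truth <- rdirichlet(1, rep(1, 8))[1, ]
    y <- as.numeric(panel %*% truth)
    names(y) <- rownames(panel)
    w <- estimate_proportions(y, panel)
    expect_lt(max(abs(w - truth)), 1e-6)
  }
})

test_that("estimates always lie on the simplex, noise or not", {
  panel <- make_panel(seed = 5L)
  set.seed(6)
  y <- as.numeric(panel %*% rdirichlet(1, rep(1, 8))[1, ]) + rnorm(120, 0, 0.05)
  names(y) <- rownames(panel)
  w <- estimate_proportions(y, panel)
  expect_true(all(w >= 0))
  expect_equal(sum(w), 1, tolerance = 1e-6)
})

test_that("permuting panel columns permutes the estimate identically", {
  panel <- make_panel(seed = 7L)
  set.seed(8)
  y <- as.numeric(panel %*% rdirichlet(1, rep(2, 8))[1, ]) + rnorm(120, 0, 0.01)
  names(y) <- rownames(panel)
  w1 <- estimate_proportions(y, panel)
  perm <- sample(8)
  w2 <- estimate_proportions(y, panel[, perm])
  expect_equal(w2, w1[perm], tolerance = 1e-6)
})

test_that("a rank-deficient panel is rejected naming collinear columns", {
  panel <- make_panel(k = 3L, seed = 9L)
  panel[, 2] <- panel[, 1]
  y <- panel[, 1]
  expect_error(estimate_proportions(y, panel), "cell1")
  expect_error(estimate_proportions(y, panel[, 1, drop = FALSE]), ">= 2")
  expect_error(estimate_proportions(y[1:2], panel), "shared probes")
})

test_that("matrix input deconvolves every sample", {
  panel <- make_panel(seed = 10L)
  set.seed(11)
  truth <- rdirichlet(5, rep(2, 8))
  b <- panel %*% t(truth)
  colnames(b) <- sprintf("s%d", 1:5)
  props <- estimate_proportions(b, panel)
  expect_identical(props$sample_id, colnames(b))
  expect_lt(max(abs(as.matrix(props[, -1]) - truth)), 1e-6)
})

test_that("the interaction scan localises a planted Treg-specific effect", {
  # The published interaction model carries no treatment main effect, so the
  # group-mean shift induced by a cell-specific effect is partially absorbed
  # by every low-abundance cell's interaction term; the affected cell is
  # identified as the one fitting best (smallest interaction p-value), and
  # it must pass the significance/effect-size filters.
  ce <- data.frame(cpg_id = "cgb000050", cell_type = "Treg",
                   cell_level_delta_beta = 0.25)
  hits_treg <- 0L; best_is_treg <- 0L
  for (seed in 1:10) {
    ds <- generate_cohorts(simulation_config(
      n_background_probes = 60L, planted_effects = NULL, noise_sd = 0.005,
      target_cell_effects = ce, n_snps = 0L, n_signature_probes = 0L,
      seed = 400L + seed))
    res <- cellwise_scan(ds$beta, ds$samples, ds$truth$proportions,
                         "cgb000050")
    if (any(res$passes_filters & res$cell_type == "Treg"))
      hits_treg <- hits_treg + 1L
    if (res$cell_type[which.min(res$p_value)] == "Treg")
      best_is_treg <- best_is_treg + 1L
  }
  expect_gte(hits_treg, 8L)
  expect_gte(best_is_treg, 8L)
})

test_that("the interaction scan is invariant to sample order", {
  ds <- generate_cohorts(small_config(seed = 13L, n_snps = 0L))
  ids <- ds$truth$planted_bulk$cpg_id[1:3]
  r1 <- cellwise_scan(ds$beta, ds$samples, ds$truth$proportions, ids)
  perm <- sample(nrow(ds$samples))
  r2 <- cellwise_scan(ds$beta[, perm], ds$samples[perm, ],
                      ds$truth$proportions[perm, ], ids)
  expect_equal(r1$coefficient, r2$coefficient, tolerance = 1e-9)
})

test_that("without planted cell effects nothing passes the filters", {
  for (seed in 1:5) {
    ds <- generate_cohorts(simulation_config(
      n_background_probes = 40L, planted_effects = NULL, n_snps = 0L,
      n_signature_probes = 0L, seed = 600L + seed))
    res <- cellwise_scan(ds$beta, ds$samples, ds$truth$proportions,
                         rownames(ds$beta)[1:20])
    expect_identical(sum(res$passes_filters), 0L)
  }
})

test_that("constant proportion columns are skipped with a warning", {
  ds <- generate_cohorts(small_config(seed = 14L, n_snps = 0L))
  pm <- ds$truth$proportions
  pm[, "DC"] <- 0.01
  expect_warning(res <- cellwise_scan(ds$beta, ds$samples, pm,
                                      rownames(ds$beta)[1]), "DC")
  expect_false("DC" %in% res$cell_type)
})

test_that("proportion comparison detects the reported NK shift", {
  # treated 0.010 vs untreated 0.016, sd 0.004, n = 64/285
  msg_seen <- FALSE
  sig <- 0L
  for (seed in 1:25) {
    set.seed(seed)
    pm <- cbind(NK = pmax(c(rnorm(64, 0.010, 0.004), rnorm(285, 0.016, 0.004)),
                          0))
    rownames(pm) <- sprintf("S%04d", 1:349)
    samples <- data.frame(sample_id = rownames(pm),
                          treated = rep(c(1L, 0L), c(64, 285)))
    res <- suppressMessages(compare_proportions(pm, samples))
    if (res$p_value[res$cell_type == "NK"] < 0.01) sig <- sig + 1L
  }
  expect_gte(sig, 23L)
})

test_that("identical groups give null proportion comparisons", {
  pm <- matrix(rep(c(0.2, 0.3, 0.5), each = 20), 20, 3,
               dimnames = list(sprintf("S%03d", 1:20), c("a", "b", "c")))
  pm <- pm + matrix(rep(seq(0, 0.01, length.out = 20), 3), 20, 3)
  samples <- data.frame(sample_id = rownames(pm),
                        treated = rep(c(1L, 0L), 10))
  expect_message(res <- compare_proportions(pm, samples), "compositional")
  expect_true(all(res$p_value > 0.2))
})
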