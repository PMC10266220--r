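mk_scores <- function(n, fn, treated = TRUE, seed = 1L) {
  set.seed(seed)
  days <- 10^runif(n, 1, 3.2)
  list(mts = data.frame(sample_id = sprintf("S%03d", 1:n), mts = fn(days)),
       samples = data.frame(sample_id = sprintf("S%03d", 1:n),
                            treated = as.integer(treated),
                            days_since_first_treatment = days))
}

test_that("an exactly log-linear score gives R squared one", {
  d <- mk_scores(30, function(days) -0.5 + 0.08 * log10(days))
  fit <- suppressWarnings(fit_time_model(d$mts, d$samples))
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$slope, 0.08, tolerance = 1e-10)
})

test_that("scores independent of time give a flat, insignificant fit", {
  d <- mk_scores(500, function(days) rnorm(length(days), -0.45, 0.1),
                 seed = 2L)
  fit <- fit_time_model(d$mts, d$samples)
  expect_lt(fit$r_squared, 0.02)
  expect_lt(abs(fit$slope), 0.02)
})

test_that("rescaling days changes the intercept but not the slope p-value", {
  d <- mk_scores(40, function(days) -0.5 + 0.05 * log10(days) +
                   rnorm(length(days), 0, 0.05), seed = 3L)
  f1 <- fit_time_model(d$mts, d$samples)
  d$samples$days_since_first_treatment <-
    d$samples$days_since_first_treatment * 7
  f2 <- fit_time_model(d$mts, d$samples)
  expect_equal(f1$p_value, f2$p_value, tolerance = 1e-10)
  expect_equal(f1$slope, f2$slope, tolerance = 1e-10)
  expect_false(isTRUE(all.equal(f1$intercept, f2$intercept)))
})

test_that("non-positive day counts are excluded and small n rejected", {
  d <- mk_scores(10, function(days) -0.5 + 0.08 * log10(days))
  d$samples$days_since_first_treatment[1:2] <- c(0, -5)
  expect_message(fit <- suppressWarnings(fit_time_model(d$mts, d$samples)),
                 "excluded")
  expect_equal(fit$n_used, 8)
  d2 <- mk_scores(3, function(days) days)
  d2$samples$days_since_first_treatment <- c(-1, 0, 5)
  expect_error(suppressMessages(fit_time_model(d2$mts, d2$samples)), ">= 3")
})

test_that("the day restriction limits the fitted subset", {
  d <- mk_scores(60, function(days) -0.5 + 0.08 * log10(days), seed = 4L)
  fit <- suppressWarnings(fit_time_model(d$mts, d$samples, max_days = 100))
  expect_equal(fit$n_used,
               sum(d$samples$days_since_first_treatment <= 100))
  expect_identical(fit$restricted_to_days, 100)
})

test_that("quartile split returns nearest-rank quartile groups", {
  mts <- data.frame(sample_id = sprintf("S%04d", 1:64), mts = rnorm(64))
  samples <- data.frame(sample_id = mts$sample_id, treated = 1L)
  q <- quartile_split(mts, samples)
  expect_length(q$bottom_ids, 16)
  expect_length(q$top_ids, 16)
  expect_true(max(mts$mts[mts$sample_id %in% q$bottom_ids]) <=
                min(mts$mts[mts$sample_id %in% q$top_ids]))
  # small worked case: scores 1..8
  mts8 <- data.frame(sample_id = letters[1:8], mts = 1:8)
  s8 <- data.frame(sample_id = letters[1:8], treated = 1L)
  q8 <- quartile_split(mts8, s8)
  expect_setequal(q8$bottom_ids, c("a", "b"))
  expect_setequal(q8$top_ids, c("g", "h"))
  expect_equal(unname(q8$cuts["lower"]), 2)
  expect_error(quartile_split(mts8[1:7, ], s8), ">= 8")
  mts8$mts <- 1
  expect_error(quartile_split(mts8, s8), "tied")
})

test_that("Freeman-Halton agrees with naive enumeration and fisher.test", {
  set.seed(5)
  for (i in 1:30) {
    g1 <- sample(0:2, 16, TRUE); g2 <- sample(0:2, 16, TRUE)
    tab <- rbind(tabulate(g1 + 1L, 3L), tabulate(g2 + 1L, 3L))
    p <- freeman_halton_test(tab)
    expect_equal(p, fh_naive(tab), tolerance = 1e-12)
    keep <- colSums(tab) > 0
    if (sum(keep) >= 2)
      expect_equal(p, fisher.test(tab[, keep, drop = FALSE])$p.value,
                   tolerance = 1e-9)
  }
})

test_that("the exact test is symmetric in groups and categories", {
  tab <- rbind(c(6, 7, 3), c(2, 9, 5))
  p <- freeman_halton_test(tab)
  expect_equal(freeman_halton_test(tab[2:1, ]), p)
  expect_equal(freeman_halton_test(tab[, c(3, 1, 2)]), p)
})

test_that("a no-heterozygote table reduces to the hypergeometric two-tail", {
  tab <- rbind(c(10, 0, 0), c(0, 0, 10))
  p <- freeman_halton_test(tab)
  # oracle: two-tail hypergeometric by direct mass summation
  dens <- dhyper(0:10, 10, 10, 10)
  expect_equal(p, sum(dens[dens <= dens[11] + 1e-12]), tolerance = 1e-12)
  expect_equal(freeman_halton_test(rbind(c(5, 0, 5), c(5, 0, 5))), 1)
})

test_that("the genotype scan handles null, monomorphic and missing SNPs", {
  g <- generate_genotypes(32L, 30L, seed = 6L)
  top <- colnames(g$dosage)[1:16]; bottom <- colnames(g$dosage)[17:32]
  g$dosage[1, ] <- 1L                       # monomorphic
  g$dosage[2, ] <- NA                       # all missing
  res <- genotype_scan(g, top, bottom)
  expect_identical(res$flag[1], "monomorphic")
  expect_equal(res$p_value[1], 1)
  expect_identical(res$flag[2], "all_missing")
  expect_true(is.na(res$p_value[2]))
  # identical genotype counts in both groups -> p = 1
  g$dosage[3, ] <- rep(c(0L, 1L, 2L, 1L), 8)
  res3 <- genotype_scan(g, top, bottom)
  expect_equal(res3$p_value[3], 1)
  expect_error(genotype_scan(g, top, top), "disjoint")
  expect_error(genotype_scan(g, character(0), bottom), "non-empty")
  expect_error(genotype_scan(g, c(top, "nope"), bottom), "nope")
})

test_that("ORA matches direct hypergeometric mass summation", {
  bg <- sprintf("g%05d", 1:26650)
  query <- bg[1:36]
  set5 <- c(bg[1:5], bg[20000:20004])            # k = 5 of K = 10
  coll <- gene_set_collection(list(S = set5), bg)
  res <- ora(query, coll)
  # oracle: direct summation of the hypergeometric pmf via lchoose
  k <- 5; K <- 10; n <- 36; N <- 26650
  oracle <- sum(vapply(k:min(K, n), function(i)
    exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)), numeric(1)))
  expect_equal(res$p_value, oracle, tolerance = 1e-12)
  expect_equal(res$overlap, 5)
})

test_that("ORA p-values are monotone in overlap and 1 for disjoint sets", {
  bg <- sprintf("g%05d", 1:26650)
  query <- bg[1:36]
  coll <- gene_set_collection(
    list(full = bg[1:36], minus1 = c(bg[2:36], bg[100:100]),
         disjoint = bg[1000:1035]), bg)
  res <- ora(query, coll)
  expect_equal(res$p_value[res$set == "disjoint"], 1)
  expect_lt(res$p_value[res$set == "full"],
            res$p_value[res$set == "minus1"])
  # maximal overlap attains the minimal achievable p
  expect_equal(res$p_value[res$set == "full"],
               exp(lchoose(36, 36) + lchoose(26650 - 36, 0) -
                     lchoose(26650, 36)), tolerance = 1e-12)
  expect_true(all(res$q_value >= res$p_value - 1e-15))
})

test_that("ORA drops out-of-background genes and rejects empty queries", {
  bg <- sprintf("g%03d", 1:500)
  coll <- gene_set_collection(list(S = bg[1:10]), bg)
  expect_message(res <- ora(c(bg[1:5], "alien"), coll), "alien")
  expect_equal(res$query_size, 5)
  expect_error(suppressMessages(ora("alien", coll)), "empty query")
  expect_error(gene_set_collection(list(S = "alien"), bg), "empty after")
})

test_that("the GMT fixture parses to the 36 published genes", {
  sets <- read_gmt(ifnb_treatment_gmt())
  expect_length(sets, 1)
  expect_length(sets[[1]], 36)
  expect_true(all(c("IFI44L", "OASL", "USP18", "ODF3B") %in% sets[[1]]))
})

test_that("sensitivity analysis picks the right test per covariate", {
  set.seed(7)
  n <- 60
  samples <- data.frame(sample_id = sprintf("S%03d", 1:n),
                        age = runif(n, 20, 70),
                        sex = sample(c("F", "M"), n, TRUE),
                        cohort = sample(c("discovery", "replication"), n, TRUE),
                        ms_subtype = sample(c("CIS", "RR", "SP", "PP"), n, TRUE),
                        armss = runif(n, 0, 10))
  mts <- data.frame(sample_id = samples$sample_id, mts = samples$age)
  r <- sensitivity_test(mts, samples, "age")
  expect_identical(r$type, "pearson")
  expect_equal(r$estimate, 1)
  expect_lt(r$p_value, 1e-10)
  r2 <- sensitivity_test(mts, samples, "sex")
  expect_identical(r2$type, "rank_sum")
  expect_message(r3 <- sensitivity_test(mts, samples, "ms_subtype"),
                 "k-group")
  expect_identical(r3$type, "kruskal_wallis")
  samples$armss <- 5
  expect_error(sensitivity_test(mts, samples, "armss"), "degenerate")
  expect_error(sensitivity_test(mts, samples, "shoe_size"), "unknown")
})
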