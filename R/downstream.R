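#' Time-since-treatment model for the MTS
#'
#' Ordinary least squares of the per-sample score on log10(days since first
#' treatment), over treated samples with positive day counts, optionally
#' restricted to samples within `max_days` of the first injection (the
#' published restricted fit uses 100 days).
#'
#' @param mts data.frame `sample_id, mts`.
#' @param samples sample sheet with `treated` and
#'   `days_since_first_treatment`.
#' @param max_days optional upper bound on days.
#' @return list of class `time_model_fit`: `slope` (per decade of days),
#'   `intercept`, `r_squared`, `p_value` (slope t-test), `n_used`,
#'   `restricted_to_days`, and `data` (the fitted points, for plotting).
#' @export
fit_time_model <- function(mts, samples, max_days = NULL) {
  d <- merge(mts, samples[, c("sample_id", "treated",
                              "days_since_first_treatment")], by = "sample_id")
  d <- d[d$treated == 1, , drop = FALSE]
  bad <- is.na(d$days_since_first_treatment) | d$days_since_first_treatment <= 0
  if (any(bad)) {
    message(sum(bad), " treated sample(s) without positive day count excluded")
    d <- d[!bad, , drop = FALSE]
  }
  if (!is.null(max_days)) d <- d[d$days_since_first_treatment <= max_days, ]
  if (nrow(d) < 3) abort("need >= 3 usable treated samples, have ", nrow(d))
  x <- log10(d$days_since_first_treatment)
  fit <- stats::lm(d$mts ~ x)
  sm <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 slope_se = sm$coefficients[2, 2],
                 r_squared = sm$r.squared,
                 p_value = sm$coefficients[2, 4],
                 n_used = nrow(d),
                 restricted_to_days = max_days,
                 data = data.frame(sample_id = d$sample_id,
                                   days = d$days_since_first_treatment,
                                   mts = d$mts)),
            class = "time_model_fit")
}

#' Top and bottom MTS quartiles of the treated samples
#'
#' Splits the treated samples into the lowest and highest 25% by score,
#' using the nearest-rank rule for the quartile boundaries: with n treated
#' samples each group has ceiling(n/4) members, and the reported cut values
#' are the type-1 (nearest-rank) quantiles.
#'
#' @param mts data.frame `sample_id, mts`.
#' @param samples sample sheet with `treated`.
#' @return list `bottom_ids`, `top_ids`, `cuts` (named `lower`, `upper`).
#' @export
quartile_split <- function(mts, samples) {
  tr <- samples$treated[match(mts$sample_id, samples$sample_id)]
  d <- mts[!is.na(tr) & tr == 1, , drop = FALSE]
  n <- nrow(d)
  if (n < 8) abort("need >= 8 treated samples for a quartile split, have ", n)
  if (diff(range(d$mts)) == 0)
    abort("all treated scores are tied (", d$mts[1], "); quartiles undefined")
  ord <- order(d$mts, d$sample_id)   # deterministic under ties
  k <- ceiling(n / 4)
  sorted <- d$mts[ord]
  list(bottom_ids = d$sample_id[ord][seq_len(k)],
       top_ids = d$sample_id[ord][seq(n - k + 1, n)],
       cuts = c(lower = unname(stats::quantile(d$mts, 0.25, type = 1)),
                upper = unname(stats::quantile(d$mts, 0.75, type = 1))))
}

#' Freeman-Halton exact test for a 2 x c contingency table
#'
#' Exact conditional test generalising Fisher's exact test: enumerates every
#' table with the observed margins and sums the (multivariate
#' hypergeometric) probabilities of tables no more probable than the
#' observed one. Intended for small tables such as 2 x 3 genotype counts.
#'
#' @param tab a 2 x c matrix of non-negative integer counts.
#' @return the two-sided exact p-value.
#' @export
freeman_halton_test <- function(tab) {
  if (!is.matrix(tab) || nrow(tab) != 2 || any(tab < 0) ||
      any(tab != round(tab)))
    abort("tab must be a 2 x c matrix of non-negative integer counts")
  r <- rowSums(tab); cs <- colSums(tab); N <- sum(tab)
  if (N == 0) abort("empty table")
  if (r[1] == 0 || r[2] == 0 || sum(cs > 0) < 2) return(1)
  ## enumerate the first row; the second row is fixed by the margins
  grid <- expand.grid(lapply(seq_along(cs),
                             function(j) 0:min(r[1], cs[j])))
  grid <- grid[rowSums(grid) == r[1], , drop = FALSE]
  g <- as.matrix(grid)
  h <- matrix(cs, nrow(g), ncol(g), byrow = TRUE) - g  # second row
  keep <- rowSums(h < 0) == 0
  g <- g[keep, , drop = FALSE]; h <- h[keep, , drop = FALSE]
  const <- sum(lgamma(r + 1)) + sum(lgamma(cs + 1)) - lgamma(N + 1)
  lp <- const - rowSums(lgamma(g + 1)) - rowSums(lgamma(h + 1))
  lobs <- const - sum(lgamma(tab + 1))
  min(sum(exp(lp[lp <= lobs + 1e-7])), 1)
}

#' Genotype association scan between MTS quartile groups
#'
#' For each SNP, builds the 2 x 3 table of genotype counts (dosage 0/1/2;
#' missing dropped) in the top- versus bottom-quartile groups and computes
#' the Freeman-Halton exact p-value. SNPs monomorphic across both groups get
#' p = 1 and are flagged; SNPs with no genotyped samples are flagged
#' `all_missing` with no p-value. Significance calls use the genome-wide
#' (7.69e-8) and suggestive (1e-5) thresholds.
#'
#' @param genotypes list with `dosage` (snps x samples, values 0/1/2/NA) and
#'   `info`, as from [generate_genotypes()] / [read_genotypes_tsv()]; a bare
#'   dosage matrix is also accepted.
#' @param top_ids,bottom_ids disjoint, non-empty sample id vectors.
#' @param gw_threshold,suggestive_threshold significance thresholds.
#' @return data.frame `snp_id, p_value, significant, suggestive, flag`.
#' @export
genotype_scan <- function(genotypes, top_ids, bottom_ids,
                          gw_threshold = 7.69e-8,
                          suggestive_threshold = 1e-5) {
  dosage <- if (is.list(genotypes)) genotypes$dosage else genotypes
  if (!length(top_ids) || !length(bottom_ids))
    abort("both quartile groups must be non-empty")
  if (length(intersect(top_ids, bottom_ids)))
    abort("quartile groups must be disjoint")
  missing <- setdiff(c(top_ids, bottom_ids), colnames(dosage))
  if (length(missing))
    abort("sample id(s) absent from genotypes: ",
          paste(missing, collapse = ", "))
  gt <- dosage[, top_ids, drop = FALSE]
  gb <- dosage[, bottom_ids, drop = FALSE]
  n_snps <- nrow(dosage)
  p <- rep(NA_real_, n_snps); flag <- rep("ok", n_snps)
  cache <- new.env(parent = emptyenv())
  count3 <- function(x) tabulate(x + 1L, nbins = 3L)
  for (i in seq_len(n_snps)) {
    t1 <- count3(gt[i, !is.na(gt[i, ])])
    t2 <- count3(gb[i, !is.na(gb[i, ])])
    if (sum(t1) + sum(t2) == 0) { flag[i] <- "all_missing"; next }
    if (sum((t1 + t2) > 0) < 2) { p[i] <- 1; flag[i] <- "monomorphic"; next }
    key <- paste(c(t1, t2), collapse = ",")
    hit <- cache[[key]]
    if (is.null(hit)) {
      hit <- freeman_halton_test(rbind(t1, t2))
      cache[[key]] <- hit
    }
    p[i] <- hit
  }
  data.frame(snp_id = rownames(dosage) %||% sprintf("snp%d", seq_len(n_snps)),
             p_value = p,
             significant = !is.na(p) & p < gw_threshold,
             suggestive = !is.na(p) & p < suggestive_threshold,
             flag = flag, stringsAsFactors = FALSE)
}

#' Assemble a gene-set collection over a fixed background
#'
#' @param sets named list of character vectors of gene symbols.
#' @param background character vector of background gene symbols (e.g. all
#'   genes annotated on the array; the published analysis used n = 26,650).
#' @return list of class `gene_set_collection` with `sets` (restricted to
#'   the background) and `background`.
#' @export
gene_set_collection <- function(sets, background) {
  if (!length(sets) || is.null(names(sets)) || any(names(sets) == ""))
    abort("sets must be a non-empty named list")
  background <- unique(background)
  sets <- lapply(sets, function(s) intersect(unique(s), background))
  if (any(lengths(sets) == 0))
    abort("set(s) empty after restriction to background: ",
          paste(names(sets)[lengths(sets) == 0], collapse = ", "))
  structure(list(sets = sets, background = background),
            class = "gene_set_collection")
}

#' Hypergeometric overrepresentation analysis
#'
#' One-sided hypergeometric upper-tail test of a query gene list against
#' each set in a collection, over the collection's fixed background, with
#' Benjamini-Hochberg adjustment across sets. Query genes outside the
#' background are dropped with a message.
#'
#' @param query_genes character vector of gene symbols.
#' @param collection a [gene_set_collection()].
#' @return data.frame `set, overlap (k), set_size (K), query_size (n),
#'   background_size (N), p_value, q_value`, ordered by p-value.
#' @export
ora <- function(query_genes, collection) {
  if (!inherits(collection, "gene_set_collection"))
    abort("collection must be a gene_set_collection")
  query <- unique(query_genes)
  out <- setdiff(query, collection$background)
  if (length(out)) {
    message(length(out), " query gene(s) outside the background dropped: ",
            paste(utils::head(out, 5), collapse = ", "))
    query <- intersect(query, collection$background)
  }
  if (!length(query)) abort("empty query after restriction to background")
  N <- length(collection$background); n <- length(query)
  res <- lapply(names(collection$sets), function(nm) {
    set <- collection$sets[[nm]]
    K <- length(set); k <- length(intersect(set, query))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = K, query_size = n,
               background_size = N, p_value = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  res[order(res$p_value, res$set), , drop = FALSE]
}

#' Sensitivity analysis of the MTS against a clinical covariate
#'
#' Tests whether the score is associated with a covariate: Pearson
#' correlation for continuous covariates (age, ARMSS severity, disease
#' duration, days since first treatment), a two-sided Wilcoxon rank-sum test
#' for binary categorical covariates (sex, cohort, IFN-beta subtype), and a
#' Kruskal-Wallis rank test for categorical covariates with more than two
#' levels (MS subtype), noted by message since the published analysis names
#' only a two-group rank test.
#'
#' @param mts data.frame `sample_id, mts`.
#' @param samples sample sheet.
#' @param covariate one of `age`, `armss`, `disease_duration`,
#'   `days_since_first_treatment`, `sex`, `cohort`, `ifnb_subtype`,
#'   `ms_subtype`.
#' @return list `covariate, type, estimate, p_value, n_used`.
#' @export
sensitivity_test <- function(mts, samples, covariate) {
  continuous <- c("age", "armss", "disease_duration",
                  "days_since_first_treatment")
  categorical <- c("sex", "cohort", "ifnb_subtype", "ms_subtype")
  known <- c(continuous, categorical)
  if (!covariate %in% known)
    abort("unknown covariate '", covariate, "'; known: ",
          paste(known, collapse = ", "))
  d <- merge(mts, samples[, c("sample_id", covariate)], by = "sample_id")
  d <- d[!is.na(d[[covariate]]), , drop = FALSE]
  if (nrow(d) < 3) abort("covariate present for fewer than 3 samples")
  v <- d[[covariate]]
  if (covariate %in% continuous) {
    if (stats::sd(v) == 0) abort("covariate '", covariate, "' is degenerate ",
                                 "(constant)")
    ct <- stats::cor.test(d$mts, v, method = "pearson")
    return(list(covariate = covariate, type = "pearson",
                estimate = unname(ct$estimate), p_value = ct$p.value,
                n_used = nrow(d)))
  }
  lev <- unique(v)
  if (length(lev) < 2) abort("covariate '", covariate, "' is degenerate ",
                             "(single level)")
  if (length(lev) == 2) {
    wt <- stats::wilcox.test(d$mts[v == lev[1]], d$mts[v == lev[2]],
                             exact = FALSE)
    return(list(covariate = covariate, type = "rank_sum",
                estimate = unname(wt$statistic), p_value = wt$p.value,
                n_used = nrow(d)))
  }
  message("covariate '", covariate, "' has ", length(lev),
          " levels; using a k-group rank test (Kruskal-Wallis)")
  kt <- stats::kruskal.test(d$mts, factor(v))
  list(covariate = covariate, type = "kruskal_wallis",
       estimate = unname(kt$statistic), p_value = kt$p.value,
       n_used = nrow(d))
}
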