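#' Group means and effect size (delta beta) for one probe
#'
#' The effect size of a differentially methylated position is the raw
#' difference of group mean beta values, treated minus untreated; it is
#' deliberately covariate-unadjusted (the regression supplies only the
#' p-value).
#'
#' @param beta_row numeric vector of per-sample beta values.
#' @param treated_mask logical or 0/1 vector, same length.
#' @return named list `mean_treated`, `mean_untreated`, `delta_beta`.
#' @export
effect_size <- function(beta_row, treated_mask) {
  treated_mask <- as.logical(treated_mask)
  if (length(beta_row) != length(treated_mask))
    abort("beta_row and treated_mask lengths differ")
  if (!any(treated_mask)) abort("treated group is empty")
  if (!any(!treated_mask)) abort("untreated group is empty")
  mt <- mean(beta_row[treated_mask])
  mu <- mean(beta_row[!treated_mask])
  list(mean_treated = mt, mean_untreated = mu, delta_beta = mt - mu)
}

# Build the logistic-model design matrix (CpG column left as a placeholder in
# position 2). Constant covariate columns -- e.g. sex in an all-female cohort
# -- are dropped rather than passed to the fitter.
build_ewas_design <- function(samples, cell_types, include_cohort_covariate) {
  n <- nrow(samples)
  covs <- list(age = samples$age, sexM = as.numeric(samples$sex == "M"))
  missing_cells <- setdiff(cell_types, names(samples))
  if (length(missing_cells))
    abort("cell fraction column(s) absent from sample sheet: ",
          paste(missing_cells, collapse = ", "))
  for (ct in cell_types) covs[[ct]] <- samples[[ct]]
  if (include_cohort_covariate)
    covs$cohort_repl <- as.numeric(samples$cohort == "replication")
  keep <- vapply(covs, function(v) stats::sd(v) > 0, logical(1))
  X <- cbind(`(Intercept)` = rep(1, n), cpg = NA_real_,
             do.call(cbind, covs[keep]))
  X
}

# Quantities of the covariate-only null model reused across a scan: its
# deviance (for the likelihood-ratio test) and fitted values / information
# (for the Rao score test used when the full fit is unreliable).
null_model_info <- function(X, y) {
  X0 <- X[, -2L, drop = FALSE]
  f0 <- suppressWarnings(stats::glm.fit(X0, y, family = stats::binomial()))
  mu <- f0$fitted.values
  w <- mu * (1 - mu)
  list(dev = f0$deviance, mu = mu, w = w, X0 = X0,
       R = chol(crossprod(X0, X0 * w)))
}

# Rao score test for adding one column x to the fitted null model: defined
# and powerful even under complete separation, where the ML fit of the full
# model diverges.
score_test_p <- function(ni, y, x) {
  u <- sum(x * (y - ni$mu))
  a <- crossprod(ni$X0, ni$w * x)
  z <- backsolve(ni$R, backsolve(ni$R, a, transpose = TRUE))
  v <- sum(ni$w * x^2) - crossprod(a, z)
  if (v <= 0) return(NA_real_)
  stats::pchisq(u^2 / as.numeric(v), 1, lower.tail = FALSE)
}

# Logistic fit of treatment status on one CpG plus covariates. The CpG-term
# p-value is the likelihood-ratio test against the covariate-only model,
# which stays calibrated and powerful when a strong CpG (quasi-)separates
# the classes and the Wald statistic collapses (Hauck-Donner effect). When
# the ML fit itself is unreliable -- it stopped at the boundary or failed to
# converge, where the iterations can terminate with an arbitrary deviance --
# the Rao score test under the null model is reported instead. Wald
# coefficient and SE are reported alongside whenever available.
fit_one_cpg <- function(X, y, beta_row, null_info) {
  es <- effect_size(beta_row, y)
  out <- c(es, list(coefficient = NA_real_, se = NA_real_,
                    p_value = NA_real_, n_used = length(y), flag = "ok"))
  if (stats::sd(beta_row) == 0) {
    out$flag <- "degenerate"
    return(out)
  }
  X[, 2L] <- beta_row
  fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
  r <- fit$rank
  cov <- tryCatch(chol2inv(fit$qr$qr[seq_len(r), seq_len(r), drop = FALSE]),
                  error = function(e) NULL)
  co <- fit$coefficients
  piv <- fit$qr$pivot[seq_len(r)]
  if (!is.null(cov)) {
    se <- rep(NA_real_, ncol(X))
    se[piv] <- sqrt(diag(cov))
    out$coefficient <- unname(co[2L])
    out$se <- se[2L]
  }
  boundary <- any(fit$fitted.values < 1e-8 | fit$fitted.values > 1 - 1e-8)
  if (!fit$converged) out$flag <- "nonconverged"
  else if (boundary) out$flag <- "separation"
  if (!(2L %in% piv)) {            # CpG aliased with covariates
    out$flag <- "degenerate"
    return(out)
  }
  if (out$flag == "ok") {
    lr <- max(null_info$dev - fit$deviance, 0)
    out$p_value <- stats::pchisq(lr, df = 1, lower.tail = FALSE)
  } else {
    out$p_value <- score_test_p(null_info, y, beta_row)
  }
  out
}

#' Per-CpG logistic treatment-association model
#'
#' Fits `glm(treated ~ CpG + age + sex + cell fractions (+ cohort))` with
#' binomial family: treatment status is the outcome (case-control EWAS
#' orientation) and the CpG beta value is a predictor. The reported p-value
#' for the CpG term is the likelihood-ratio test against the model without
#' the CpG; coefficient and SE are the Wald quantities. Effect size is the
#' raw group-mean difference from [effect_size()]. Fits at the boundary of
#' the parameter space (perfect or quasi-separation) or that fail to
#' converge are flagged `"separation"`/`"nonconverged"` and their p-value is
#' the Rao score test under the covariate-only null model, which remains
#' well-defined when the ML fit diverges; a constant CpG is flagged
#' `"degenerate"` with no p-value.
#'
#' @param beta_row numeric per-sample beta values (named or in sample-sheet
#'   order).
#' @param samples sample sheet data.frame with columns `treated`, `age`,
#'   `sex`, the cell-fraction columns, and `cohort`.
#' @param include_cohort_covariate add the cohort indicator (combined model).
#' @param cell_types names of the cell-fraction covariate columns.
#' @param cpg_id optional probe id attached to the record.
#' @return one-row data.frame (a DMP record) with columns `cpg_id`,
#'   `mean_treated`, `mean_untreated`, `delta_beta`, `coefficient`, `se`,
#'   `p_value`, `n_used`, `flag`.
#' @export
fit_cpg_model <- function(beta_row, samples, include_cohort_covariate = FALSE,
                          cell_types = c("NK", "Mono", "Bcell", "CD8T",
                                         "CD4T", "Neu"),
                          cpg_id = NA_character_) {
  y <- samples$treated
  if (min(sum(y == 1), sum(y == 0)) < 10)
    abort("need >= 10 samples in each outcome class")
  X <- build_ewas_design(samples, cell_types, include_cohort_covariate)
  rec <- fit_one_cpg(X, y, beta_row, null_model_info(X, y))
  data.frame(cpg_id = cpg_id, mean_treated = rec$mean_treated,
             mean_untreated = rec$mean_untreated,
             delta_beta = rec$delta_beta, coefficient = rec$coefficient,
             se = rec$se, p_value = rec$p_value, n_used = rec$n_used,
             flag = rec$flag, stringsAsFactors = FALSE)
}

#' Epigenome-wide treatment-association scan
#'
#' Applies the per-CpG logistic model to every probe for the requested
#' scope: `"discovery"` or `"replication"` fit within that cohort;
#' `"combined"` fits all samples with a cohort indicator covariate.
#' Results are ordered by (chrom, pos) when annotation is supplied.
#'
#' @param beta probes x samples matrix of beta values in \[0,1\], rownames =
#'   probe ids, colnames = sample ids.
#' @param samples sample sheet covering (at least) the scanned samples.
#' @param scope one of `"discovery"`, `"replication"`, `"combined"`.
#' @param annotation optional probe annotation (`cpg_id, chrom, pos, gene,
#'   feature`); merged into the result and used for ordering.
#' @param cell_types cell-fraction covariate columns.
#' @return data.frame of DMP records with columns `cpg_id, scope, chrom,
#'   pos, gene, feature, mean_treated, mean_untreated, delta_beta,
#'   coefficient, se, p_value, n_used, flag` (annotation columns NA when no
#'   annotation given).
#' @export
ewas_scan <- function(beta, samples, scope = c("discovery", "replication",
                                               "combined"),
                      annotation = NULL,
                      cell_types = c("NK", "Mono", "Bcell", "CD8T", "CD4T",
                                     "Neu")) {
  scope <- match.arg(scope)
  if (scope == "combined") {
    if (length(unique(samples$cohort)) < 2)
      abort("combined scan requires both cohorts in the sample sheet")
    sub <- samples
  } else {
    sub <- samples[samples$cohort == scope, , drop = FALSE]
    if (!nrow(sub)) abort("no samples with cohort == ", scope)
  }
  if (!all(sub$sample_id %in% colnames(beta)))
    abort("sample sheet ids missing from beta matrix")
  b <- beta[, sub$sample_id, drop = FALSE]
  if (nrow(b) == 0) {
    warning("empty probe set: returning no records")
    return(empty_dmp_frame())
  }
  y <- sub$treated
  if (min(sum(y == 1), sum(y == 0)) < 10)
    abort("need >= 10 samples in each outcome class")
  X <- build_ewas_design(sub, cell_types, scope == "combined")
  ni <- null_model_info(X, y)

  n_probes <- nrow(b)
  mean_treated <- mean_untreated <- coefficient <- se <- p_value <-
    rep(NA_real_, n_probes)
  flag <- character(n_probes)
  for (i in seq_len(n_probes)) {
    rec <- fit_one_cpg(X, y, b[i, ], ni)
    mean_treated[i] <- rec$mean_treated
    mean_untreated[i] <- rec$mean_untreated
    coefficient[i] <- rec$coefficient
    se[i] <- rec$se
    p_value[i] <- rec$p_value
    flag[i] <- rec$flag
  }
  res <- data.frame(cpg_id = rownames(b), scope = scope,
                    mean_treated = mean_treated,
                    mean_untreated = mean_untreated,
                    delta_beta = mean_treated - mean_untreated,
                    coefficient = coefficient, se = se, p_value = p_value,
                    n_used = nrow(sub), flag = flag, stringsAsFactors = FALSE)
  if (!is.null(annotation)) {
    ann <- annotation[match(res$cpg_id, annotation$cpg_id),
                      c("chrom", "pos", "gene", "feature")]
    res <- cbind(res[, "cpg_id", drop = FALSE], scope = scope, ann,
                 res[, c("mean_treated", "mean_untreated", "delta_beta",
                         "coefficient", "se", "p_value", "n_used", "flag")])
    res <- res[order(res$chrom, res$pos, res$cpg_id), ]
  } else {
    res$chrom <- NA_integer_; res$pos <- NA_integer_
    res$gene <- NA_character_; res$feature <- NA_character_
    res <- res[, c("cpg_id", "scope", "chrom", "pos", "gene", "feature",
                   "mean_treated", "mean_untreated", "delta_beta",
                   "coefficient", "se", "p_value", "n_used", "flag")]
  }
  rownames(res) <- NULL
  res
}

empty_dmp_frame <- function() {
  data.frame(cpg_id = character(0), scope = character(0),
             chrom = integer(0), pos = integer(0), gene = character(0),
             feature = character(0), mean_treated = numeric(0),
             mean_untreated = numeric(0), delta_beta = numeric(0),
             coefficient = numeric(0), se = numeric(0), p_value = numeric(0),
             n_used = integer(0), flag = character(0))
}

#' Cross-cohort replication filter
#'
#' A probe replicates when it meets the discovery threshold in the discovery
#' scan, the replication threshold in the replication scan, and has the same
#' (non-zero) sign of delta beta in both. Probes present in only one scope
#' are excluded with a message. Defaults use the genome-wide significance
#' threshold 9.8e-8 in both cohorts (strict preset); a documented lenient
#' replication preset is 1e-4.
#'
#' @param disc,repl DMP record data.frames from [ewas_scan()].
#' @param threshold_disc,threshold_repl p-value thresholds.
#' @return sorted character vector of replicated cpg_ids.
#' @export
replicate_dmps <- function(disc, repl, threshold_disc = 9.8e-8,
                           threshold_repl = 9.8e-8) {
  only <- c(setdiff(disc$cpg_id, repl$cpg_id),
            setdiff(repl$cpg_id, disc$cpg_id))
  if (length(only))
    message(length(only), " probe(s) present in one scope only; excluded")
  common <- intersect(disc$cpg_id, repl$cpg_id)
  d <- disc[match(common, disc$cpg_id), ]
  r <- repl[match(common, repl$cpg_id), ]
  ok <- !is.na(d$p_value) & !is.na(r$p_value) &
    d$p_value < threshold_disc & r$p_value < threshold_repl &
    sign(d$delta_beta) == sign(r$delta_beta) & d$delta_beta != 0
  sort(common[ok])
}
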