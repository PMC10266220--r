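#' Reduce replicated DMPs to one index CpG per gene
#'
#' Within each gene, replicated DMPs whose effect sizes share a sign are
#' represented by a single index CpG: the one with the smallest discovery
#' p-value (ties broken by largest absolute delta beta, then lexicographic
#' cpg_id). The index CpG's discovery delta beta becomes the gene's weight
#' in the methylation treatment score. Probes with no gene symbol are
#' excluded with a message; genes whose DMPs have mixed signs are skipped
#' with a warning.
#'
#' @param dmps discovery-scope DMP records (typically subset to the
#'   replicated probes), with `cpg_id`, `p_value`, `delta_beta`, and `gene`
#'   either as a column or resolvable through `annotation`.
#' @param annotation optional probe annotation supplying `gene`.
#' @return an MTS weight table: data.frame `cpg_id, gene, weight`, one row
#'   per gene, ordered by gene.
#' @export
select_index_dmps <- function(dmps, annotation = NULL) {
  if (!is.null(annotation))
    dmps$gene <- annotation$gene[match(dmps$cpg_id, annotation$cpg_id)]
  if (is.null(dmps$gene)) abort("no gene symbols: supply annotation")
  no_gene <- is.na(dmps$gene) | dmps$gene == ""
  if (any(no_gene)) {
    message(sum(no_gene), " probe(s) without gene symbol excluded: ",
            paste(utils::head(dmps$cpg_id[no_gene], 5), collapse = ", "))
    dmps <- dmps[!no_gene, , drop = FALSE]
  }
  if (!nrow(dmps)) abort("no gene-mapped probes to index")
  out <- lapply(split(dmps, dmps$gene), function(g) {
    if (length(unique(sign(g$delta_beta))) > 1) {
      warning("gene ", g$gene[1], " has mixed-sign delta beta; skipped")
      return(NULL)
    }
    g <- g[order(g$p_value, -abs(g$delta_beta), g$cpg_id), ]
    data.frame(cpg_id = g$cpg_id[1], gene = g$gene[1],
               weight = g$delta_beta[1], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) abort("every gene was skipped (mixed signs)")
  out <- out[order(out$gene), ]
  if (any(out$weight == 0)) {
    warning("gene(s) with zero weight dropped: ",
            paste(out$gene[out$weight == 0], collapse = ", "))
    out <- out[out$weight != 0, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Compute the methylation treatment score
#'
#' For each sample the MTS is the exact weighted sum of beta values at the
#' index CpGs, `MTS = sum_i beta(sample, CpG_i) * weight_i`, with the
#' discovery delta beta as weight. No normalisation, no intercept.
#'
#' @param beta probes x samples beta matrix.
#' @param weights weight table (`cpg_id, gene, weight`) from
#'   [select_index_dmps()] or [ifnb_index_weights()].
#' @return data.frame `sample_id, mts`.
#' @export
compute_mts <- function(beta, weights) {
  missing <- setdiff(weights$cpg_id, rownames(beta))
  if (length(missing))
    abort("weight CpG(s) absent from beta matrix: ",
          paste(missing, collapse = ", "))
  b <- beta[weights$cpg_id, , drop = FALSE]
  data.frame(sample_id = colnames(beta),
             mts = as.numeric(crossprod(b, weights$weight)),
             stringsAsFactors = FALSE)
}

#' Rank-based AUC (probability of correct ranking)
#'
#' The area under the ROC curve computed from midranks: the probability that
#' a randomly chosen positive (treated) score exceeds a randomly chosen
#' negative (untreated) score, ties counting one half. Identical to
#' exhaustive all-pairs counting.
#'
#' @param scores numeric scores.
#' @param labels binary labels (1/TRUE = positive class).
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) abort("both classes must be non-empty")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' One operating point per distinct threshold (classification rule:
#' score > threshold is called positive), including the two trivial corners.
#'
#' @inheritParams auc_rank
#' @return data.frame `threshold, fpr, tpr` ordered from (0,0) to (1,1).
#' @export
roc_points <- function(scores, labels) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) abort("both classes must be non-empty")
  th <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  tpr <- vapply(th, function(t) mean(scores[labels] > t), numeric(1))
  fpr <- vapply(th, function(t) mean(scores[!labels] > t), numeric(1))
  data.frame(threshold = th, fpr = fpr, tpr = tpr)
}

#' Group separation of the MTS
#'
#' Group means and SDs of the score by treatment status, with a two-sided
#' Wilcoxon rank-sum p-value.
#'
#' @param mts data.frame `sample_id, mts` from [compute_mts()].
#' @param samples sample sheet with `sample_id` and `treated`.
#' @return named list `mean_treated, sd_treated, mean_untreated,
#'   sd_untreated, rank_test_p`.
#' @export
group_separation <- function(mts, samples) {
  tr <- samples$treated[match(mts$sample_id, samples$sample_id)]
  if (anyNA(tr)) abort("sample_id mismatch between scores and sample sheet")
  s1 <- mts$mts[tr == 1]; s0 <- mts$mts[tr == 0]
  if (!length(s1) || !length(s0)) abort("both groups must be non-empty")
  p <- stats::wilcox.test(s1, s0, exact = FALSE)$p.value
  list(mean_treated = mean(s1), sd_treated = stats::sd(s1),
       mean_untreated = mean(s0), sd_untreated = stats::sd(s0),
       rank_test_p = p)
}
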