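#' Published index CpGs for interferon-beta treatment
#'
#' The eleven index differentially methylated positions (one per gene)
#' reported for IFN-beta treatment in multiple sclerosis, with the printed
#' discovery and replication group means, effect sizes (delta beta,
#' treated minus untreated) and p-values. These rounded values serve as
#' worked-example weights for the methylation treatment score and as the
#' default planted effects of the synthetic-data generator.
#'
#' Note that the printed means are rounded to two decimals independently of
#' the printed delta beta, so recomputing `mean_treated - mean_untreated`
#' can differ from the printed delta beta by one unit in the last digit.
#'
#' @return a data.frame with columns `cpg_id, chrom, pos, gene, feature`,
#'   and per-cohort `mean_treated_*`, `mean_untreated_*`, `delta_beta_*`,
#'   `p_*` for `disc` (discovery) and `repl` (replication), plus
#'   `p_combined`.
#' @export
ifnb_index_cpgs <- function() {
  path <- system.file("extdata", "ifnb_index_cpgs.csv", package = "methylMTS",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Published index-CpG weights as an MTS weight table
#'
#' Convenience wrapper returning the rounded discovery delta-beta weights in
#' the `cpg_id, gene, weight` layout used by [compute_mts()].
#'
#' @return a data.frame with columns `cpg_id`, `gene`, `weight`.
#' @export
ifnb_index_weights <- function() {
  tab <- ifnb_index_cpgs()
  data.frame(cpg_id = tab$cpg_id, gene = tab$gene,
             weight = tab$delta_beta_disc, stringsAsFactors = FALSE)
}

#' Path to the bundled IFN-beta treatment gene set (GMT)
#'
#' A single gene set of the 36 gene symbols carrying treatment-associated
#' DMPs in the combined-cohort scan, in standard GMT format; usable as a
#' query fixture or as a collection for [ora()].
#'
#' @return path to the installed GMT file.
#' @export
ifnb_treatment_gmt <- function() {
  system.file("extdata", "ifnb_treatment_genes.gmt", package = "methylMTS",
              mustWork = TRUE)
}
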