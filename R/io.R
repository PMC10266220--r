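## Readers/writers for the pipeline's plain-text formats. All files are
## UTF-8 with a mandatory header row, "NA" for missing values and Unix line
## endings; writing a freshly read canonical file reproduces it byte for
## byte. Genome coordinates are 1-based inclusive throughout.

fwrite_canon <- function(d, path, sep) {
  data.table::fwrite(d, path, sep = sep, quote = FALSE, na = "NA",
                     eol = "\n", scipen = 0)
}

fread_canon <- function(path, sep) {
  as.data.frame(data.table::fread(path, sep = sep, header = TRUE,
                                  na.strings = "NA", data.table = FALSE))
}

#' Write / read a beta matrix as TSV
#'
#' Probes as rows; first column `cpg_id`, one column per sample. On read,
#' duplicate probe ids and out-of-range values are rejected with the
#' offending coordinates.
#'
#' @param beta probes x samples numeric matrix.
#' @param path file path.
#' @return `read_beta_tsv` returns the matrix (rownames = probe ids).
#' @export
write_beta_tsv <- function(beta, path) {
  d <- data.frame(cpg_id = rownames(beta), beta, check.names = FALSE,
                  stringsAsFactors = FALSE)
  fwrite_canon(d, path, "\t")
  invisible(path)
}

#' @rdname write_beta_tsv
#' @export
read_beta_tsv <- function(path) {
  d <- fread_canon(path, "\t")
  if (names(d)[1] != "cpg_id") abort("beta TSV must start with a cpg_id column")
  if (anyDuplicated(d$cpg_id))
    abort("duplicate cpg_id: ", d$cpg_id[duplicated(d$cpg_id)][1])
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$cpg_id
  bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
  if (nrow(bad))
    abort("beta value out of [0,1] at probe ", rownames(m)[bad[1, 1]],
          ", sample ", colnames(m)[bad[1, 2]], ": ", m[bad[1, , drop = FALSE]])
  m
}

#' Write / read a sample sheet as CSV
#' @param samples sample sheet data.frame (unique `sample_id` required).
#' @param path file path.
#' @export
write_sample_sheet <- function(samples, path) {
  fwrite_canon(samples, path, ",")
  invisible(path)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  d <- fread_canon(path, ",")
  if (anyDuplicated(d$sample_id))
    abort("duplicate sample_id: ", d$sample_id[duplicated(d$sample_id)][1])
  d
}

#' Write / read probe annotation as CSV
#'
#' Columns `cpg_id, chrom, pos, gene, feature`; positions are 1-based;
#' `gene` empty for intergenic probes; `feature` drawn from the array
#' vocabulary (TSS1500, TSS200, 5'UTR, 1stExon, Body, 3'UTR, IGR),
#' optionally `;`-combined.
#'
#' @param annotation data.frame as above.
#' @param path file path.
#' @export
write_annotation_csv <- function(annotation, path) {
  fwrite_canon(annotation, path, ",")
  invisible(path)
}

#' @rdname write_annotation_csv
#' @export
read_annotation_csv <- function(path) {
  d <- fread_canon(path, ",")
  need <- c("cpg_id", "chrom", "pos", "gene", "feature")
  if (!all(need %in% names(d)))
    abort("annotation CSV needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(d$cpg_id))
    abort("duplicate cpg_id: ", d$cpg_id[duplicated(d$cpg_id)][1])
  d$gene[is.na(d$gene)] <- ""
  vocab <- c("TSS1500", "TSS200", "5'UTR", "1stExon", "Body", "3'UTR", "IGR")
  toks <- unique(unlist(strsplit(d$feature, ";", fixed = TRUE)))
  bad <- setdiff(toks, vocab)
  if (length(bad)) abort("unknown feature value(s): ", paste(bad, collapse = ", "))
  d
}

#' Write / read a cell-type reference panel as TSV
#' @param panel probes x cell-types matrix.
#' @param path file path.
#' @export
write_panel_tsv <- function(panel, path) {
  d <- data.frame(cpg_id = rownames(panel), panel, check.names = FALSE,
                  stringsAsFactors = FALSE)
  fwrite_canon(d, path, "\t")
  invisible(path)
}

#' @rdname write_panel_tsv
#' @export
read_panel_tsv <- function(path) {
  d <- fread_canon(path, "\t")
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$cpg_id
  m
}

#' Write / read a genotype matrix as TSV
#'
#' Columns `snp_id, chrom, pos` followed by one 0/1/2 dosage column per
#' sample; unknown codes are rejected with their coordinates.
#'
#' @param genotypes list with `dosage` and `info` (see
#'   [generate_genotypes()]).
#' @param path file path.
#' @export
write_genotypes_tsv <- function(genotypes, path) {
  d <- data.frame(snp_id = genotypes$info$snp_id,
                  chrom = genotypes$info$chrom, pos = genotypes$info$pos,
                  genotypes$dosage, check.names = FALSE,
                  stringsAsFactors = FALSE)
  fwrite_canon(d, path, "\t")
  invisible(path)
}

#' @rdname write_genotypes_tsv
#' @export
read_genotypes_tsv <- function(path) {
  d <- fread_canon(path, "\t")
  need <- c("snp_id", "chrom", "pos")
  if (!all(need %in% names(d)))
    abort("genotype TSV needs leading columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(d$snp_id))
    abort("duplicate snp_id: ", d$snp_id[duplicated(d$snp_id)][1])
  m <- as.matrix(d[, setdiff(names(d), need), drop = FALSE])
  rownames(m) <- d$snp_id
  bad <- which(!is.na(m) & !(m %in% c(0L, 1L, 2L)), arr.ind = TRUE)
  if (nrow(bad))
    abort("unknown genotype code at SNP ", rownames(m)[bad[1, 1]],
          ", sample ", colnames(m)[bad[1, 2]], ": ", m[bad[1, , drop = FALSE]])
  storage.mode(m) <- "integer"
  list(dosage = m, info = d[, need])
}

#' Write / read an MTS weight table as TSV (`cpg_id, gene, weight`)
#' @param weights weight table from [select_index_dmps()].
#' @param path file path.
#' @export
write_weights_tsv <- function(weights, path) {
  fwrite_canon(weights[, c("cpg_id", "gene", "weight")], path, "\t")
  invisible(path)
}

#' @rdname write_weights_tsv
#' @export
read_weights_tsv <- function(path) fread_canon(path, "\t")

#' Write / read DMP scan results as TSV (stable column order)
#' @param dmps data.frame from [ewas_scan()].
#' @param path file path.
#' @export
write_dmps_tsv <- function(dmps, path) {
  cols <- c("cpg_id", "scope", "chrom", "pos", "gene", "feature",
            "mean_treated", "mean_untreated", "delta_beta", "coefficient",
            "se", "p_value", "flag")
  fwrite_canon(dmps[, cols], path, "\t")
  invisible(path)
}

#' @rdname write_dmps_tsv
#' @export
read_dmps_tsv <- function(path) fread_canon(path, "\t")

#' Read a GMT gene-set file
#'
#' Standard tab-separated layout: set name, description, then member genes.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) fgsea::gmtPathways(path)

#' Write a named list of gene sets as GMT
#' @param sets named list of character vectors.
#' @param path file path.
#' @param descriptions optional per-set description column.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write / read the pipeline run manifest (JSON)
#' @param manifest named list.
#' @param path file path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)
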