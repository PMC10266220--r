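#' Configuration for the two-cohort synthetic methylation data generator
#'
#' Defaults emulate the study conditions of the dual-cohort IFN-beta EWAS:
#' a discovery cohort of 31 treated vs 83 untreated samples and a
#' replication cohort of 33 vs 202, planted per-gene treatment effects equal
#' to the published index-CpG effect sizes (with the published untreated
#' means as baselines), whole-blood-like cell mixtures, and Hardy-Weinberg
#' genotypes independent of all phenotypes.
#'
#' @param n_treated_disc,n_untreated_disc,n_treated_repl,n_untreated_repl
#'   cohort sizes (all > 0).
#' @param n_background_probes number of null background probes (>= 1).
#' @param planted_effects data.frame with columns `gene`, `cpg_id`,
#'   `delta_beta` (treated minus untreated, on the beta scale), `baseline`
#'   (untreated mean beta), and optionally `n_cpgs_in_cluster` (default 1)
#'   and `within_cluster_correlation` (default 0). Defaults to the published
#'   index-CpG set (discovery effect sizes and untreated means).
#' @param noise_sd additive Gaussian noise SD on the beta scale (default
#'   0.03); values are clipped to \[0.001, 0.999\] after noise.
#' @param cell_types character vector of cell-type names.
#' @param dirichlet_concentration positive Dirichlet concentrations, one per
#'   cell type; the default approximates whole-blood composition
#'   (neutrophils 0.55, CD4 0.15, CD8 0.08, B 0.06, NK 0.05, monocytes 0.08,
#'   dendritic cells 0.01, Tregs 0.02) at total concentration 40.
#' @param n_signature_probes number of background probes given independent
#'   per-cell-type methylation levels so the reference panel is well
#'   conditioned for deconvolution (the remaining probes share one baseline
#'   across cell types).
#' @param target_cell_effects data.frame with columns `cpg_id`, `cell_type`,
#'   `cell_level_delta_beta`: treatment effects confined to one cell type;
#'   the bulk shift in treated samples is proportion x cell-level effect.
#' @param n_snps,maf_range genotype simulation: number of SNPs and the
#'   uniform range minor-allele frequencies are drawn from
#'   (0 < low <= high <= 0.5).
#' @param female_prop_disc,female_prop_repl probability a sample is female,
#'   per cohort (defaults match the study demographics: all-female
#'   discovery, ~75% female replication).
#' @param age_mean,age_sd,age_shift_treated age model N(mean, sd) clipped to
#'   \[18, 80\]; `age_shift_treated` (default 0) is an opt-in confounding
#'   knob adding a constant to treated ages.
#' @param seed master seed; all stages draw from documented sub-streams via
#'   [substream_seed()].
#' @return a validated list of class `sim_config`.
#' @export
simulation_config <- function(n_treated_disc = 31L, n_untreated_disc = 83L,
                              n_treated_repl = 33L, n_untreated_repl = 202L,
                              n_background_probes = 5000L,
                              planted_effects = default_planted_effects(),
                              noise_sd = 0.03,
                              cell_types = c("Neu", "CD4T", "CD8T", "Bcell",
                                             "NK", "Mono", "DC", "Treg"),
                              dirichlet_concentration = 40 * c(0.55, 0.15,
                                0.08, 0.06, 0.05, 0.08, 0.01, 0.02),
                              n_signature_probes = 200L,
                              target_cell_effects = NULL,
                              n_snps = 1000L, maf_range = c(0.05, 0.49),
                              female_prop_disc = 1.0, female_prop_repl = 0.75,
                              age_mean = 45, age_sd = 10,
                              age_shift_treated = 0,
                              seed = 1L) {
  cfg <- list(n_treated_disc = as.integer(n_treated_disc),
              n_untreated_disc = as.integer(n_untreated_disc),
              n_treated_repl = as.integer(n_treated_repl),
              n_untreated_repl = as.integer(n_untreated_repl),
              n_background_probes = as.integer(n_background_probes),
              planted_effects = planted_effects, noise_sd = noise_sd,
              cell_types = cell_types,
              dirichlet_concentration = dirichlet_concentration,
              n_signature_probes = as.integer(n_signature_probes),
              target_cell_effects = target_cell_effects,
              n_snps = as.integer(n_snps), maf_range = maf_range,
              female_prop_disc = female_prop_disc,
              female_prop_repl = female_prop_repl,
              age_mean = age_mean, age_sd = age_sd,
              age_shift_treated = age_shift_treated,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

#' Default planted effects: the published index-CpG set
#'
#' One CpG per gene, planted at the discovery effect size on top of the
#' discovery untreated mean.
#' @return data.frame with columns `gene, cpg_id, delta_beta, baseline,
#'   n_cpgs_in_cluster, within_cluster_correlation`.
#' @export
default_planted_effects <- function() {
  tab <- ifnb_index_cpgs()
  data.frame(gene = tab$gene, cpg_id = tab$cpg_id,
             delta_beta = tab$delta_beta_disc,
             baseline = tab$mean_untreated_disc,
             n_cpgs_in_cluster = 1L, within_cluster_correlation = 0,
             chrom = tab$chrom, pos = tab$pos, feature = tab$feature,
             stringsAsFactors = FALSE)
}

validate_sim_config <- function(cfg) {
  sizes <- c(cfg$n_treated_disc, cfg$n_untreated_disc,
             cfg$n_treated_repl, cfg$n_untreated_repl)
  if (any(sizes <= 0)) abort("all cohort sizes must be > 0")
  if (cfg$n_background_probes < 1) abort("n_background_probes must be >= 1")
  if (length(cfg$cell_types) < 1) abort("cell_types must be non-empty")
  if (length(cfg$dirichlet_concentration) != length(cfg$cell_types))
    abort("dirichlet_concentration must have one entry per cell type")
  if (any(cfg$dirichlet_concentration <= 0))
    abort("dirichlet_concentration must be strictly positive")
  if (cfg$noise_sd < 0) abort("noise_sd must be >= 0")
  pe <- cfg$planted_effects
  if (!is.null(pe) && nrow(pe)) {
    need <- c("gene", "cpg_id", "delta_beta", "baseline")
    if (!all(need %in% names(pe)))
      abort("planted_effects needs columns: ", paste(need, collapse = ", "))
    if (anyDuplicated(pe$cpg_id))
      abort("duplicated planted cpg_id: ",
            paste(unique(pe$cpg_id[duplicated(pe$cpg_id)]), collapse = ", "))
    bad <- pe$baseline <= 0 | pe$baseline >= 1 |
      (pe$baseline + pe$delta_beta) <= 0 | (pe$baseline + pe$delta_beta) >= 1
    if (any(bad))
      abort("planted effect pushes group mean outside (0,1) for gene(s): ",
            paste(pe$gene[bad], collapse = ", "))
    if (any(abs(pe$delta_beta) > 1)) abort("delta_beta must lie in [-1, 1]")
  }
  mr <- cfg$maf_range
  if (length(mr) != 2 || mr[1] <= 0 || mr[1] > mr[2] || mr[2] > 0.5)
    abort("maf_range must satisfy 0 < low <= high <= 0.5")
  invisible(cfg)
}

#' Generate a two-cohort synthetic methylation dataset with planted effects
#'
#' Simulation model, per sample: cell proportions are drawn from a Dirichlet;
#' each probe has a baseline mean beta (background probes: Uniform(0.05,
#' 0.95); planted probes: their configured baseline) shared across cohorts;
#' per-cell-type reference profiles equal the baseline except at signature
#' probes (independent per-cell levels) and nowhere reflect treatment. Bulk
#' beta is the proportion-weighted mixture of the cell profiles, plus (for
#' treated samples) the planted bulk delta beta and any planted cell-specific
#' effect scaled by that sample's cell proportion, plus Gaussian noise,
#' clipped to \[0.001, 0.999\]. Probes of the same planted cluster share a
#' latent noise factor giving the configured within-cluster correlation.
#' Ages are N(age_mean, age_sd) clipped to \[18, 80\]; sex follows the
#' per-cohort female proportion; days since first treatment (treated samples
#' only) are 10^Uniform(1, 3.2). Genotypes are Hardy-Weinberg, independent
#' of everything else. Deterministic given `config$seed`.
#'
#' Sub-streams of the master seed (see [substream_seed()]): 1 probe
#' baselines/panel, 2 cell proportions, 3 noise, 4 phenotypes, 5 genotypes.
#'
#' @param config a [simulation_config()] object.
#' @return an object of class `synthetic_dataset`: list with elements
#'   `beta` (probes x samples matrix), `samples` (sample sheet data.frame
#'   including true cell-fraction columns), `annotation` (probe annotation),
#'   `reference` (probes x cell types panel matrix), `genotypes` (list with
#'   `dosage` and `info`), and `truth` (planted effect record).
#' @export
generate_cohorts <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(simulation_config, config)
  validate_sim_config(config)
  cfg <- config

  ## ---- probe table -------------------------------------------------------
  pe <- cfg$planted_effects
  planted <- NULL
  if (!is.null(pe) && nrow(pe)) {
    if (is.null(pe$n_cpgs_in_cluster)) pe$n_cpgs_in_cluster <- 1L
    if (is.null(pe$within_cluster_correlation)) pe$within_cluster_correlation <- 0
    if (is.null(pe$chrom)) pe$chrom <- rep(1L, nrow(pe))
    if (is.null(pe$pos)) pe$pos <- seq_len(nrow(pe)) * 1e6L
    if (is.null(pe$feature)) pe$feature <- "Body"
    rows <- lapply(seq_len(nrow(pe)), function(i) {
      k <- pe$n_cpgs_in_cluster[i]
      data.frame(cpg_id = if (k == 1) pe$cpg_id[i] else
                   c(pe$cpg_id[i], paste0(pe$cpg_id[i], "_", 2:k)),
                 gene = pe$gene[i], chrom = pe$chrom[i],
                 pos = pe$pos[i] + 50L * (seq_len(k) - 1L),
                 feature = pe$feature[i], delta_beta = pe$delta_beta[i],
                 baseline = pe$baseline[i], cluster = pe$gene[i],
                 rho = pe$within_cluster_correlation[i],
                 stringsAsFactors = FALSE)
    })
    planted <- do.call(rbind, rows)
  }
  bg_ids <- sprintf("cgb%06d", seq_len(cfg$n_background_probes))
  if (!is.null(planted) && any(planted$cpg_id %in% bg_ids))
    abort("planted cpg_id collides with a background probe id")

  set.seed(substream_seed(cfg$seed, 1L))
  bg <- data.frame(cpg_id = bg_ids,
                   gene = "", chrom = sample(1:22, cfg$n_background_probes, TRUE),
                   pos = sample.int(2e8L, cfg$n_background_probes, TRUE),
                   feature = "IGR",
                   delta_beta = 0,
                   baseline = stats::runif(cfg$n_background_probes, 0.05, 0.95),
                   cluster = NA_character_, rho = 0,
                   stringsAsFactors = FALSE)
  probes <- rbind(bg, planted)
  n_probes <- nrow(probes)

  ## reference panel: baseline everywhere; signature probes get independent
  ## per-cell-type levels so the panel has full column rank
  k_cells <- length(cfg$cell_types)
  panel <- matrix(probes$baseline, n_probes, k_cells)
  dimnames(panel) <- list(probes$cpg_id, cfg$cell_types)
  n_sig <- min(cfg$n_signature_probes, cfg$n_background_probes)
  sig_ids <- bg_ids[seq_len(n_sig)]
  if (n_sig > 0 && k_cells > 1)
    panel[seq_len(n_sig), ] <- stats::runif(n_sig * k_cells, 0.05, 0.95)

  ## ---- samples -----------------------------------------------------------
  n_disc <- cfg$n_treated_disc + cfg$n_untreated_disc
  n_repl <- cfg$n_treated_repl + cfg$n_untreated_repl
  n <- n_disc + n_repl
  sample_id <- sprintf("S%04d", seq_len(n))
  cohort <- rep(c("discovery", "replication"), c(n_disc, n_repl))
  treated <- c(rep(1L, cfg$n_treated_disc), rep(0L, cfg$n_untreated_disc),
               rep(1L, cfg$n_treated_repl), rep(0L, cfg$n_untreated_repl))

  set.seed(substream_seed(cfg$seed, 2L))
  props <- rdirichlet(n, stats::setNames(cfg$dirichlet_concentration,
                                         cfg$cell_types))
  rownames(props) <- sample_id

  set.seed(substream_seed(cfg$seed, 4L))
  age <- pmin(pmax(stats::rnorm(n, cfg$age_mean, cfg$age_sd), 18), 80) +
    cfg$age_shift_treated * treated
  pf <- ifelse(cohort == "discovery", cfg$female_prop_disc, cfg$female_prop_repl)
  sex <- ifelse(stats::runif(n) < pf, "F", "M")
  days <- ifelse(treated == 1L, 10^stats::runif(n, 1, 3.2), NA_real_)
  disease_duration <- round(abs(stats::rnorm(n, 8, 5)) + 0.5, 1)
  armss <- round(stats::runif(n, 0, 10), 2)
  ms_subtype <- sample(c("CIS", "RR", "SP", "PP"), n, TRUE,
                       prob = c(0.2, 0.5, 0.2, 0.1))
  ifnb_subtype <- ifelse(treated == 1L,
                         sample(c("1a", "1b"), n, TRUE), NA_character_)
  samples <- data.frame(sample_id = sample_id, cohort = cohort,
                        treated = treated, age = age, sex = sex,
                        days_since_first_treatment = days,
                        disease_duration = disease_duration, armss = armss,
                        ms_subtype = ms_subtype, ifnb_subtype = ifnb_subtype,
                        stringsAsFactors = FALSE)
  samples <- cbind(samples, as.data.frame(props))

  ## ---- bulk beta ---------------------------------------------------------
  beta <- panel %*% t(props)                       # probes x samples mixture
  trt <- which(treated == 1L)
  if (!is.null(planted)) {
    idx <- match(planted$cpg_id, probes$cpg_id)
    beta[idx, trt] <- beta[idx, trt] + planted$delta_beta
  }
  ce <- cfg$target_cell_effects
  if (!is.null(ce) && nrow(ce)) {
    if (!all(ce$cell_type %in% cfg$cell_types))
      abort("target_cell_effects cell_type not among configured cell types")
    if (!all(ce$cpg_id %in% probes$cpg_id))
      abort("target_cell_effects cpg_id not among simulated probes")
    for (i in seq_len(nrow(ce))) {
      p <- match(ce$cpg_id[i], probes$cpg_id)
      beta[p, trt] <- beta[p, trt] +
        props[trt, ce$cell_type[i]] * ce$cell_level_delta_beta[i]
    }
  }

  set.seed(substream_seed(cfg$seed, 3L))
  if (cfg$noise_sd > 0) {
    eps <- matrix(stats::rnorm(n_probes * n, 0, cfg$noise_sd), n_probes, n)
    clusters <- unique(probes$cluster[!is.na(probes$cluster) & probes$rho > 0])
    for (cl in clusters) {
      rows <- which(!is.na(probes$cluster) & probes$cluster == cl)
      if (length(rows) < 2) next
      rho <- probes$rho[rows[1]]
      z <- stats::rnorm(n, 0, cfg$noise_sd)
      eps[rows, ] <- sqrt(rho) * matrix(z, length(rows), n, byrow = TRUE) +
        sqrt(1 - rho) * eps[rows, ]
    }
    beta <- beta + eps
  }
  beta <- pmin(pmax(beta, 0.001), 0.999)
  dimnames(beta) <- list(probes$cpg_id, sample_id)

  genotypes <- generate_genotypes(n, cfg$n_snps, cfg$maf_range,
                                  seed = substream_seed(cfg$seed, 5L),
                                  sample_ids = sample_id)

  annotation <- probes[, c("cpg_id", "chrom", "pos", "gene", "feature")]
  rownames(annotation) <- NULL

  truth <- list(
    planted_bulk = if (is.null(planted)) planted else
      planted[, c("cpg_id", "gene", "delta_beta", "baseline", "cluster", "rho")],
    cell_effects = ce,
    proportions = props,
    signature_probes = sig_ids,
    cell_means = stats::setNames(
      cfg$dirichlet_concentration / sum(cfg$dirichlet_concentration),
      cfg$cell_types),
    seed = cfg$seed)

  structure(list(beta = beta, samples = samples, annotation = annotation,
                 reference = panel, genotypes = genotypes, truth = truth),
            class = "synthetic_dataset")
}

#' Simulate Hardy-Weinberg genotypes independent of phenotype
#'
#' Per SNP, a minor-allele frequency is drawn uniformly from `maf_range` and
#' dosages 0/1/2 are drawn with Hardy-Weinberg probabilities
#' ((1-m)^2, 2m(1-m), m^2), independently across samples and of all
#' phenotypes (a pure null model for the genotype scan).
#'
#' @param n_samples,n_snps dimensions (`n_samples` > 0, `n_snps` >= 0).
#' @param maf_range interval for the uniform MAF draw (0 < low <= high <= 0.5).
#' @param seed integer seed.
#' @param sample_ids optional column names.
#' @return list with `dosage` (n_snps x n_samples integer matrix, rownames
#'   snp ids) and `info` (data.frame `snp_id, chrom, pos, maf`).
#' @export
generate_genotypes <- function(n_samples, n_snps, maf_range = c(0.05, 0.49),
                               seed = 1L, sample_ids = NULL) {
  if (n_samples <= 0) abort("n_samples must be positive")
  if (n_snps < 0) abort("n_snps must be non-negative")
  if (maf_range[1] <= 0 || maf_range[1] > maf_range[2] || maf_range[2] > 0.5)
    abort("maf_range must satisfy 0 < low <= high <= 0.5")
  if (is.null(sample_ids)) sample_ids <- sprintf("S%04d", seq_len(n_samples))
  set.seed(seed)
  if (n_snps == 0) {
    return(list(dosage = matrix(integer(0), 0, n_samples,
                                dimnames = list(NULL, sample_ids)),
                info = data.frame(snp_id = character(0), chrom = integer(0),
                                  pos = integer(0), maf = numeric(0))))
  }
  maf <- stats::runif(n_snps, maf_range[1], maf_range[2])
  p0 <- (1 - maf)^2                  # P(dosage 0)
  p01 <- p0 + 2 * maf * (1 - maf)    # P(dosage 0 or 1)
  u <- matrix(stats::runif(n_snps * n_samples), n_snps, n_samples)
  dosage <- (u > p0) + (u > p01)
  storage.mode(dosage) <- "integer"
  info <- data.frame(snp_id = sprintf("rs%07d", seq_len(n_snps)),
                     chrom = sample(1:22, n_snps, TRUE),
                     pos = sample.int(2e8L, n_snps, TRUE), maf = maf)
  dimnames(dosage) <- list(info$snp_id, sample_ids)
  list(dosage = dosage, info = info)
}
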