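#' Pipeline configuration
#'
#' Bundles the thresholds, seed, stage toggles and file locations for
#' [run_pipeline()]. By default the pipeline simulates its inputs with
#' [generate_cohorts()]; set `simulate = FALSE` and supply paths to run on
#' existing files (paths are validated up front and a missing enabled input
#' is an error naming the path).
#'
#' @param out_dir output directory (created if absent).
#' @param seed master seed.
#' @param simulate generate inputs with [generate_cohorts()] (default) or
#'   read them from the `*_path` arguments.
#' @param sim a [simulation_config()]; defaults to the study conditions with
#'   this `seed`.
#' @param beta_path,samples_path,annotation_path,panel_path,genotypes_path,gmt_path
#'   input file paths when `simulate = FALSE` (`gmt_path` defaults to the
#'   bundled IFN-beta treatment gene set in either mode).
#' @param ewas_threshold genome-wide significance threshold (default 9.8e-8).
#' @param repl_threshold replication threshold (default strict 9.8e-8; a
#'   documented lenient preset is 1e-4).
#' @param gwas_threshold,suggestive_threshold genotype-scan thresholds
#'   (defaults 7.69e-8 and 1e-5).
#' @param interaction_coef_threshold cell-specific effect-size threshold on
#'   the percent scale (default 2).
#' @param time_restriction_days restricted time-model window (default 100).
#' @param run_gwas,run_cellscan stage toggles.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, simulate = TRUE, sim = NULL,
                            beta_path = NULL, samples_path = NULL,
                            annotation_path = NULL, panel_path = NULL,
                            genotypes_path = NULL,
                            gmt_path = ifnb_treatment_gmt(),
                            ewas_threshold = 9.8e-8, repl_threshold = 9.8e-8,
                            gwas_threshold = 7.69e-8,
                            suggestive_threshold = 1e-5,
                            interaction_coef_threshold = 2,
                            time_restriction_days = 100,
                            run_gwas = TRUE, run_cellscan = TRUE) {
  for (th in c(ewas_threshold, repl_threshold, gwas_threshold,
               suggestive_threshold))
    if (th <= 0 || th >= 1) abort("probability thresholds must lie in (0,1)")
  cfg <- list(out_dir = out_dir, seed = as.integer(seed), simulate = simulate,
              sim = sim %||% simulation_config(seed = seed),
              beta_path = beta_path, samples_path = samples_path,
              annotation_path = annotation_path, panel_path = panel_path,
              genotypes_path = genotypes_path, gmt_path = gmt_path,
              ewas_threshold = ewas_threshold, repl_threshold = repl_threshold,
              gwas_threshold = gwas_threshold,
              suggestive_threshold = suggestive_threshold,
              interaction_coef_threshold = interaction_coef_threshold,
              time_restriction_days = time_restriction_days,
              run_gwas = run_gwas, run_cellscan = run_cellscan)
  if (!simulate) {
    need <- c(beta = beta_path, samples = samples_path,
              annotation = annotation_path, panel = panel_path)
    if (run_gwas) need <- c(need, genotypes = genotypes_path)
    miss <- vapply(need, function(p) is.null(p) || !file.exists(p), logical(1))
    if (is.null(need) || length(need) < 4 || any(miss))
      abort("missing input file(s): ",
            paste(names(need)[miss], "=", unlist(need[miss]) %||% "<unset>",
                  collapse = "; "))
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes: simulate/load -> per-cohort and combined EWAS -> replication
#' filter -> index-CpG reduction and MTS -> discrimination (AUC, group
#' separation) -> time-since-treatment models (full and restricted) ->
#' deconvolution and proportion comparison -> cell-specific interaction scan
#' -> MTS-quartile genotype scan -> overrepresentation analysis ->
#' sensitivity analysis. Every intermediate table is written under
#' `config$out_dir` (files are written with a `.partial` suffix and renamed
#' when their stage completes, so an aborted run leaves only `.partial`
#' outputs for the failing stage), followed by a JSON manifest capturing
#' versions, seed, thresholds, and per-stage row counts. Any stage failure
#' aborts with the stage name.
#'
#' @param config a [pipeline_config()].
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    abort("config must be a pipeline_config")
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "methylMTS",
                   package_version = as.character(utils::packageVersion("methylMTS")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   seed = config$seed,
                   thresholds = config[c("ewas_threshold", "repl_threshold",
                                         "gwas_threshold",
                                         "suggestive_threshold",
                                         "interaction_coef_threshold",
                                         "time_restriction_days")],
                   stages = list(), outputs = character(0))
  pending <- character(0)
  emit <- function(writer, obj, name) {
    p <- file.path(out, paste0(name, ".partial"))
    writer(obj, p)
    pending <<- c(pending, p)
    manifest$outputs <<- c(manifest$outputs, file.path(out, name))
    invisible(p)
  }
  stage <- function(name, expr) {
    message("[", name, "] running")
    res <- tryCatch(force(expr), error = function(e)
      abort("stage '", name, "' failed: ", conditionMessage(e)))
    for (p in pending) file.rename(p, sub("\\.partial$", "", p))
    pending <<- character(0)
    res
  }

  ## ---- inputs ------------------------------------------------------------
  ds <- stage("simulate", {
    if (config$simulate) {
      d <- generate_cohorts(config$sim)
      emit(write_beta_tsv, d$beta, "beta.tsv")
      emit(write_sample_sheet, d$samples, "samples.csv")
      emit(write_annotation_csv, d$annotation, "annotation.csv")
      emit(write_panel_tsv, d$reference, "panel.tsv")
      emit(write_genotypes_tsv, d$genotypes, "genotypes.tsv")
      emit(write_manifest, list(planted_bulk = d$truth$planted_bulk,
                                cell_effects = d$truth$cell_effects,
                                cell_means = as.list(d$truth$cell_means),
                                seed = d$truth$seed), "truth.json")
      d
    } else {
      list(beta = read_beta_tsv(config$beta_path),
           samples = read_sample_sheet(config$samples_path),
           annotation = read_annotation_csv(config$annotation_path),
           reference = read_panel_tsv(config$panel_path),
           genotypes = if (config$run_gwas)
             read_genotypes_tsv(config$genotypes_path) else NULL)
    }
  })
  manifest$stages$simulate <- list(probes = nrow(ds$beta),
                                   samples = nrow(ds$samples))

  scans <- stage("ewas", {
    s <- lapply(c("discovery", "replication", "combined"), function(sc)
      ewas_scan(ds$beta, ds$samples, sc, ds$annotation))
    names(s) <- c("discovery", "replication", "combined")
    emit(write_dmps_tsv, s$discovery, "dmps_discovery.tsv")
    emit(write_dmps_tsv, s$replication, "dmps_replication.tsv")
    emit(write_dmps_tsv, s$combined, "dmps_combined.tsv")
    s
  })
  manifest$stages$ewas <- lapply(scans, function(s)
    sum(!is.na(s$p_value) & s$p_value < config$ewas_threshold))

  replicated <- stage("replicate", {
    r <- replicate_dmps(scans$discovery, scans$replication,
                        config$ewas_threshold, config$repl_threshold)
    emit(function(x, p) writeLines(x, p), r, "replicated_cpgs.txt")
    r
  })
  manifest$stages$replicate <- list(replicated_dmps = length(replicated))

  mts_res <- stage("mts", {
    disc_rep <- scans$discovery[scans$discovery$cpg_id %in% replicated, ]
    weights <- select_index_dmps(disc_rep, ds$annotation)
    scores <- compute_mts(ds$beta, weights)
    emit(write_weights_tsv, weights, "mts_weights.tsv")
    emit(function(x, p) fwrite_canon(x, p, "\t"), scores, "mts_scores.tsv")
    list(weights = weights, scores = scores)
  })
  manifest$stages$mts <- list(index_dmps = nrow(mts_res$weights),
                              samples_scored = nrow(mts_res$scores))

  disc <- stage("discrimination", {
    labels <- ds$samples$treated[match(mts_res$scores$sample_id,
                                       ds$samples$sample_id)]
    a <- auc_rank(mts_res$scores$mts, labels)
    gs <- group_separation(mts_res$scores, ds$samples)
    emit(function(x, p) fwrite_canon(x, p, ","),
         roc_points(mts_res$scores$mts, labels), "roc_points.csv")
    c(list(auc = a), gs)
  })
  manifest$stages$discrimination <- disc

  tm <- stage("timemodel", {
    full <- fit_time_model(mts_res$scores, ds$samples)
    restricted <- tryCatch(
      fit_time_model(mts_res$scores, ds$samples,
                     max_days = config$time_restriction_days),
      error = function(e) NULL)
    emit(function(x, p) fwrite_canon(x, p, "\t"), full$data, "time_model.tsv")
    list(full = full, restricted = restricted)
  })
  manifest$stages$timemodel <- list(
    slope = tm$full$slope, r_squared = tm$full$r_squared,
    p_value = tm$full$p_value, n_used = tm$full$n_used,
    restricted = if (is.null(tm$restricted)) NULL else
      list(slope = tm$restricted$slope, r_squared = tm$restricted$r_squared,
           p_value = tm$restricted$p_value, n_used = tm$restricted$n_used))

  props <- stage("deconv", {
    p <- estimate_proportions(ds$beta, ds$reference)
    cmp <- suppressMessages(compare_proportions(p, ds$samples))
    emit(function(x, pa) fwrite_canon(x, pa, ","), p, "proportions.csv")
    emit(function(x, pa) fwrite_canon(x, pa, "\t"), cmp,
         "proportion_tests.tsv")
    p
  })
  manifest$stages$deconv <- list(samples = nrow(props),
                                 cell_types = ncol(props) - 1L)

  if (config$run_cellscan) {
    cell <- stage("cellscan", {
      comb <- scans$combined
      ids <- comb$cpg_id[!is.na(comb$p_value) &
                           comb$p_value < config$ewas_threshold]
      if (!length(ids)) data.frame() else {
        cs <- cellwise_scan(ds$beta, ds$samples, props, ids,
                            p_threshold = config$ewas_threshold,
                            coef_threshold = config$interaction_coef_threshold)
        emit(function(x, p) fwrite_canon(x, p, "\t"), cs, "cell_specific.tsv")
        cs
      }
    })
    manifest$stages$cellscan <- list(records = nrow(cell),
                                     passing = sum(cell$passes_filters %||% 0))
  }

  if (config$run_gwas) {
    gwas <- stage("gwas", {
      q <- quartile_split(mts_res$scores, ds$samples)
      g <- genotype_scan(ds$genotypes, q$top_ids, q$bottom_ids,
                         config$gwas_threshold, config$suggestive_threshold)
      emit(function(x, p) fwrite_canon(x, p, "\t"), g, "gwas.tsv")
      list(q = q, g = g)
    })
    manifest$stages$gwas <- list(
      group_size = length(gwas$q$top_ids),
      cuts = as.list(gwas$q$cuts),
      snps = nrow(gwas$g), significant = sum(gwas$g$significant),
      suggestive = sum(gwas$g$suggestive))
  }

  ora_res <- stage("ora", {
    sets <- read_gmt(config$gmt_path)
    background <- unique(c(unlist(sets),
                           ds$annotation$gene[ds$annotation$gene != ""]))
    coll <- gene_set_collection(sets, background)
    r <- suppressMessages(ora(mts_res$weights$gene, coll))
    emit(function(x, p) fwrite_canon(x, p, "\t"), r, "ora.tsv")
    r
  })
  manifest$stages$ora <- list(sets = nrow(ora_res),
                              min_p = min(ora_res$p_value))

  sens <- stage("sensitivity", {
    covs <- c("age", "armss", "disease_duration", "sex", "cohort",
              "ifnb_subtype", "ms_subtype")
    covs <- intersect(covs, names(ds$samples))
    r <- lapply(covs, function(cv) tryCatch(
      as.data.frame(suppressMessages(
        sensitivity_test(mts_res$scores, ds$samples, cv))),
      error = function(e) NULL))
    r <- do.call(rbind, r)
    emit(function(x, p) fwrite_canon(x, p, "\t"), r, "sensitivity.tsv")
    r
  })
  manifest$stages$sensitivity <- list(covariates_tested = nrow(sens))

  manifest$timestamp <- format(Sys.time(), tz = "UTC")
  write_manifest(manifest, file.path(out, "manifest.json"))
  message("pipeline complete: ", out)
  invisible(manifest)
}
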