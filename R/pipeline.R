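#' End-to-end pipeline configuration
#'
#' One configuration object drives the whole analysis: simulate (or
#' load) a cohort, derive expression weights, QC/harmonize/annotate
#' variants, clump and score under both APOE modes, run the
#' association families, and quantify amyloid mediation.  The
#' configuration round-trips losslessly through YAML.
#'
#' @param sim Named list of [sim_config()] arguments.
#' @param clump Named list of [clump_config()] arguments.
#' @param qc Named list of [qc_thresholds()] arguments.
#' @param apoe_region,apoe_flank APOE mask window (see [apoe_mask()]).
#' @param weight_method Averaging semantics for [cell_weights()].
#' @param outcomes Character vector of outcome stages to run; any of
#'   `"abeta_status"`, `"ptau217"`, `"mmse"`, `"pacc"`.
#' @param longitudinal Run the mixed-model likelihood-ratio tests.
#' @param lrt_threshold Threshold index used for the longitudinal and
#'   mediation stages.
#' @param mediation_boot Bootstrap resamples for the mediation stage.
#' @param restricted Also compute the restricted (strictly
#'   cell-specific, unweighted) PRS.
#' @param tau Specificity threshold for the restricted PRS.
#' @param seed Pipeline seed (propagated to the simulator and the
#'   mediation bootstrap).
#' @param out_dir Output directory; `NULL` keeps results in memory
#'   only.
#' @return A list of class `cellprs_run_config`.
#' @export
run_config <- function(sim = list(), clump = list(), qc = list(),
                       apoe_region = "chr19:44905796-44909393",
                       apoe_flank = 1e6,
                       weight_method = "expm1_mean",
                       outcomes = c("abeta_status", "ptau217"),
                       longitudinal = FALSE,
                       lrt_threshold = 1,
                       mediation_boot = 1000,
                       restricted = FALSE, tau = 0.5,
                       seed = 1L, out_dir = NULL) {
  structure(list(sim = sim, clump = clump, qc = qc,
                 apoe_region = apoe_region, apoe_flank = apoe_flank,
                 weight_method = weight_method, outcomes = outcomes,
                 longitudinal = isTRUE(longitudinal),
                 lrt_threshold = lrt_threshold,
                 mediation_boot = mediation_boot,
                 restricted = isTRUE(restricted), tau = tau,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "cellprs_run_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @param config A [run_config()] object.
#' @return `read_run_config` returns the configuration;
#'   `write_run_config` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full cell-weighted PRS pipeline
#'
#' Executes all stages in dependency order on a synthetic cohort and
#' returns every intermediate product plus a manifest of per-stage
#' row counts (variants in/out of QC, harmonization, the APOE mask,
#' clumping and each threshold), so that `input = retained + dropped`
#' can be audited at every filter.
#'
#' @param config A [run_config()] object, or the path to its YAML
#'   serialization.
#' @param cohort Optional pre-built `cellprs_cohort`; simulated from
#'   `config` when missing.
#' @return A list of class `cellprs_run` with elements `cohort`,
#'   `weights`, `variants` (per APOE mode), `scores` (per mode),
#'   `associations`, `attenuation`, `mediation`, `longitudinal`,
#'   `restricted`, `manifest` and `config`.
#' @export
run_pipeline <- function(config = run_config(), cohort = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  manifest <- list()
  fail <- function(stage, e)
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)),
         call. = FALSE)

  ## -- simulate ------------------------------------------------------
  if (is.null(cohort)) {
    cohort <- tryCatch({
      sim_args <- config$sim
      if (is.null(sim_args$seed)) sim_args$seed <- config$seed
      simulate_cohort(do.call(sim_config, sim_args))
    }, error = function(e) fail("simulate", e))
  }
  manifest$simulate <- list(
    n_individuals = nrow(cohort$genotypes$dosage),
    n_variants = ncol(cohort$genotypes$dosage),
    n_genes = nrow(cohort$annotation),
    n_cells = nrow(cohort$expression$counts))

  ## -- weights -------------------------------------------------------
  weights <- tryCatch(
    cell_weights(cohort$expression$counts,
                 cohort$expression$cell_meta$cell_type,
                 method = config$weight_method),
    error = function(e) fail("weights", e))
  manifest$weights <- list(
    n_genes_emitted = nrow(weights),
    n_genes_absent = length(attr(weights, "absent_genes")),
    semantics = attr(weights, "semantics"))

  ## -- annotate ------------------------------------------------------
  ann_stage <- tryCatch({
    qc <- qc_filter(cohort$genotypes$dosage, cohort$genotypes$map,
                    do.call(qc_thresholds, config$qc))
    map_qc <- cohort$genotypes$map[qc$retained, , drop = FALSE]
    ss <- cohort$sumstats[
      cohort$sumstats$ID %in% map_qc$id, , drop = FALSE]
    harm <- harmonize_sumstats(ss, cohort$genotypes$map)
    harm <- map_nearest_gene(harm, cohort$annotation)
    masked <- apoe_mask(harm, config$apoe_region, config$apoe_flank)
    list(qc = qc, harm = harm, masked = masked)
  }, error = function(e) fail("annotate", e))
  harm <- ann_stage$harm
  masked <- ann_stage$masked
  manifest$qc <- list(
    n_in = ncol(cohort$genotypes$dosage),
    n_retained = sum(ann_stage$qc$retained),
    n_dropped = sum(!ann_stage$qc$retained),
    reasons = as.list(table(ann_stage$qc$report$reason)))
  manifest$harmonize <- list(
    n_in = manifest$qc$n_retained,
    n_retained = nrow(harm),
    n_dropped = manifest$qc$n_retained - nrow(harm))
  manifest$apoe_mask <- list(
    n_in = nrow(harm), n_retained = nrow(masked$retained),
    n_dropped = masked$n_dropped,
    region = config$apoe_region, flank = config$apoe_flank)

  ## -- clump + score per APOE mode ----------------------------------
  clump_cfg <- do.call(clump_config, config$clump)
  variant_sets <- list(include = harm, exclude = masked$retained)
  scores <- list(); score_manifest <- list()
  for (md in names(variant_sets)) {
    vt <- tryCatch(scale_weights(variant_sets[[md]], weights),
                   error = function(e) fail("scale_weights", e))
    res <- tryCatch({
      ret <- greedy_clump(vt, cohort$genotypes$dosage, clump_cfg)
      sets <- threshold_sets(vt, ret, clump_cfg)
      sm <- build_scores(cohort$genotypes$dosage, vt, clump_cfg,
                         retained = ret)
      list(retained = ret, sets = sets, scores = sm, variants = vt)
    }, error = function(e) fail("score", e))
    scores[[md]] <- res$scores
    variant_sets[[md]] <- res$variants
    score_manifest[[md]] <- list(
      n_in = nrow(res$variants),
      n_clump_retained = sum(res$retained),
      n_clump_removed = nrow(res$variants) - sum(res$retained),
      per_threshold = lapply(res$sets, length),
      n_score_columns = ncol(res$scores))
  }
  manifest$clump_score <- score_manifest

  ## -- associations --------------------------------------------------
  assoc <- list(); atten <- list()
  pheno <- cohort$phenotypes
  for (oc in config$outcomes) {
    fam <- if (oc == "abeta_status") "logistic" else "linear"
    res <- tryCatch(
      run_family(scores, pheno, outcome = oc, family = fam),
      error = function(e) fail(paste0("assoc_", oc), e))
    assoc[[oc]] <- res
    ## per-type attenuation: t-values across thresholds, include vs
    ## exclude
    at <- lapply(unique(res$score_type), function(ty) {
      ti <- res$statistic[res$score_type == ty &
                            res$apoe_mode == "include"]
      te <- res$statistic[res$score_type == ty &
                            res$apoe_mode == "exclude"]
      if (length(ti) >= 2 && stats::sd(ti - te) > 0)
        c(list(score_type = ty),
          attenuation_paired_t(ti, te)[c("statistic", "p_value")])
      else NULL
    })
    atten[[oc]] <- do.call(rbind, lapply(Filter(Negate(is.null), at),
                                         as.data.frame))
  }
  manifest$associations <- lapply(assoc, nrow)

  ## -- mediation -----------------------------------------------------
  med <- NULL
  if ("ptau217" %in% config$outcomes) {
    y <- inverse_normal_transform(pheno$ptau217)
    X <- as.matrix(pheno[, base_covariates(), drop = FALSE])
    med_rows <- list()
    for (ty in setdiff(unique(default_assoc_plan()$score_type), "full")) {
      col <- paste0(ty, "_PRS", config$lrt_threshold)
      if (!col %in% colnames(scores$include)) next
      m <- tryCatch(
        mediate_c_cprime(y, scores$include[, col], pheno$abeta_status,
                         X, n_boot = config$mediation_boot,
                         seed = config$seed + match(ty, default_cell_types())),
        error = function(e) fail("mediation", e))
      med_rows[[ty]] <- data.frame(
        score_type = ty, score_column = col, c = m$c,
        c_prime = m$c_prime, mediated = m$mediated,
        prop_mediated_pct = m$prop_mediated_pct,
        ci_low = m$ci_low, ci_high = m$ci_high,
        significant = m$significant, n_boot = m$n_boot,
        stringsAsFactors = FALSE)
    }
    med <- do.call(rbind, med_rows)
    manifest$mediation <- list(n_models = NROW(med),
                               n_boot = config$mediation_boot)
  }

  ## -- longitudinal --------------------------------------------------
  lrt <- NULL
  if (config$longitudinal) {
    long <- merge(cohort$longitudinal,
                  pheno[, c("id", base_covariates())], by = "id")
    lrt_rows <- list()
    for (ty in unique(default_assoc_plan()$score_type)) {
      col <- paste0(ty, "_PRS", config$lrt_threshold)
      if (!col %in% colnames(scores$include)) next
      long$score <- scores$include[match(long$id,
                                         rownames(scores$include)), col]
      for (oc in intersect(c("mmse", "pacc"), config$outcomes)) {
        long$.y <- inverse_normal_transform(long[[oc]])
        r <- tryCatch(
          longitudinal_lrt(long, outcome = ".y", score = "score"),
          error = function(e) fail("longitudinal", e))
        lrt_rows[[paste(ty, oc)]] <- data.frame(
          score_type = ty, outcome = oc, chisq = r$chisq, df = r$df,
          p_value = r$p_value, stringsAsFactors = FALSE)
      }
    }
    lrt <- do.call(rbind, lrt_rows)
  }

  ## -- restricted PRS ------------------------------------------------
  restr <- NULL
  if (config$restricted) {
    restr <- tryCatch(
      restricted_prs(cohort$genotypes$dosage, harm, weights,
                     cohort$annotation, clump_cfg, tau = config$tau),
      error = function(e) fail("restricted", e))
  }

  out <- structure(list(cohort = cohort, weights = weights,
                        variants = variant_sets, scores = scores,
                        associations = assoc, attenuation = atten,
                        mediation = med, longitudinal = lrt,
                        restricted = restr, manifest = manifest,
                        config = config),
                   class = "cellprs_run")

  ## -- write outputs -------------------------------------------------
  if (!is.null(config$out_dir)) {
    dir <- config$out_dir
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_run_config(config, file.path(dir, "config.yaml"))
    manifest$config_md5 <- unname(tools::md5sum(file.path(dir,
                                                          "config.yaml")))
    out$manifest <- manifest
    write_weights(weights, file.path(dir, "weights.tsv"))
    for (md in names(scores))
      utils::write.csv(
        data.frame(id = rownames(scores[[md]]),
                   as.data.frame(unclass(scores[[md]])),
                   check.names = FALSE),
        file.path(dir, sprintf("scores_%s.csv", md)), row.names = FALSE)
    for (oc in names(assoc))
      utils::write.csv(assoc[[oc]],
                       file.path(dir, sprintf("assoc_%s.csv", oc)),
                       row.names = FALSE)
    if (!is.null(med))
      utils::write.csv(med, file.path(dir, "mediation.csv"),
                       row.names = FALSE)
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  out
}

#' @export
print.cellprs_run <- function(x, ...) {
  cat("<cellprs_run>\n")
  cat(sprintf("  %d individuals, %d variants in, %d after QC+harmonization\n",
              x$manifest$simulate$n_individuals,
              x$manifest$simulate$n_variants,
              x$manifest$harmonize$n_retained))
  for (oc in names(x$associations))
    cat(sprintf("  %s: %d models, %d significant at FDR 5%%\n", oc,
                nrow(x$associations[[oc]]),
                sum(x$associations[[oc]]$p_fdr < 0.05)))
  if (!is.null(x$mediation))
    cat(sprintf("  mediation: %d cell scores, mean prop mediated %.1f%%\n",
                nrow(x$mediation), mean(x$mediation$prop_mediated_pct)))
  invisible(x)
}
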