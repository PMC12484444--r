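#' Default brain cell types
#'
#' The six analysis cell types used throughout the package: four
#' non-neuronal (astrocyte, microglia, OPC, oligodendrocyte) and two
#' neuronal (excitatory, inhibitory) classes.
#'
#' @return Character vector of length 6.
#' @export
default_cell_types <- function() {
  c("astrocyte", "excitatory", "inhibitory", "microglia",
    "OPC", "oligodendrocyte")
}

#' Mediation structure of the synthetic phenotypes
#'
#' Parameters of the generative path from genetics to amyloid to
#' phosphorylated tau.  A designated genetic score raises amyloid
#' liability (`gamma_amyloid`); amyloid raises pTau217 (`alpha_tau`);
#' each cell type's true score may additionally act on pTau217 directly
#' (`delta_direct`), bypassing amyloid.  With `delta_direct = 0` the
#' genetic effect on pTau217 is fully mediated by amyloid.
#'
#' @param gamma_amyloid Effect of the designated (standardized) genetic
#'   score on the amyloid liability scale.
#' @param alpha_tau Effect of amyloid (status indicator, or continuous
#'   liability when `mediator_type = "ratio"`) on pTau217.
#' @param delta_direct Named numeric vector of per-cell-type direct
#'   effects of the true cell scores on pTau217.  A single unnamed
#'   number is recycled over all cell types.
#' @param mediator_score Which true score drives amyloid liability:
#'   `"full"` (unweighted genetic score) or one of the cell types.
#' @return A list of class `cellprs_mediation_params`.
#' @export
mediation_params <- function(gamma_amyloid = 0.4, alpha_tau = 0.6,
                             delta_direct = 0.2,
                             mediator_score = "full") {
  stopifnot(is.numeric(gamma_amyloid), length(gamma_amyloid) == 1L,
            is.numeric(alpha_tau), length(alpha_tau) == 1L,
            is.numeric(delta_direct))
  structure(list(gamma_amyloid = gamma_amyloid, alpha_tau = alpha_tau,
                 delta_direct = delta_direct,
                 mediator_score = mediator_score),
            class = "cellprs_mediation_params")
}

#' Configuration of the synthetic cohort generator
#'
#' Bundles every tunable of the simulator: cohort and panel sizes, the
#' LD model (Gaussian-copula haplotypes with exchangeable within-block
#' correlation), the marker-gene structure of the single-cell counts,
#' the causal architecture of the discovery GWAS, and the
#' amyloid-mediated phenotype model.  The seed fully determines all
#' generated data.
#'
#' @param n_individuals Target-cohort size.
#' @param n_variants Number of variants in the panel.
#' @param n_genes Number of genes in the synthetic annotation.
#' @param cell_types Analysis cell-type labels.
#' @param markers_per_type Marker genes assigned to each cell type.
#' @param marker_fold Fold elevation of a marker gene's expression mean
#'   in its own cell type (default 20).  `marker_fold <= 1` is allowed
#'   but produces near-uniform weights (a warning is raised downstream).
#' @param cells_per_type Cells simulated per cell type.
#' @param frac_none Fraction of additional cells labelled `"None"`, to
#'   exercise the label filter (default 2%).
#' @param ld_block_size Maximum variants per LD block; blocks never
#'   span gene neighbourhoods.
#' @param ld_rho Within-block haplotype correlation, in `[0, 1)`.
#' @param maf_range Range from which per-variant minor allele
#'   frequencies are drawn; must lie in `(0, 0.5]`.
#' @param n_chromosomes Number of synthetic chromosomes.  When
#'   `apoe_locus = TRUE` the last one is labelled `chr19` and holds a
#'   gene centred in the APOE region so that the APOE mask has
#'   something to remove.
#' @param gene_spacing Distance in bp between adjacent gene centres;
#'   kept above 2 Mb so that the 1 Mb neighbourhoods of genes assigned
#'   to different cell types do not overlap.
#' @param gene_length Length in bp of each gene interval.
#' @param causal_gene_map Named list (cell type -> gene ids) of genes
#'   whose neighbourhoods carry causal GWAS effects.  Defaults to each
#'   type's marker genes.
#' @param effect_sd Standard deviation of per-causal-variant true
#'   effect sizes.  Zero gives a global null.
#' @param discovery_n Sample size of the internally simulated,
#'   independent discovery GWAS cohort.
#' @param mediation A [mediation_params()] object.
#' @param mediator_type `"status"` uses the dichotomized amyloid status
#'   in the pTau217 model; `"ratio"` uses the continuous liability
#'   (affine in the CSF ratio), giving an all-linear mediation path.
#' @param abeta_cutoff CSF ratio threshold below which amyloid status
#'   is positive (default 0.091).
#' @param abeta_prevalence Target marginal amyloid-positivity rate.
#' @param noise_sd Named residual standard deviations for the `abeta`
#'   liability, `ptau`, `mmse` and `pacc` phenotypes.
#' @param cog_time_effect Named per-cell-type effect of the true score
#'   on the annual cognitive slope (default all zero).
#' @param n_visits,visit_spacing Longitudinal design: number of visits
#'   and years between visits.
#' @param apoe_locus Place one gene at the APOE locus on chr19 (see
#'   `n_chromosomes`).
#' @param confounded_covariates If `TRUE`, PC1 is generated with a
#'   component of the designated genetic score (confounded mode);
#'   default generates all covariates independent of genotype.
#' @param seed Integer seed; identical configurations produce
#'   bit-identical cohorts.
#' @return A list of class `cellprs_sim_config`.
#' @export
sim_config <- function(n_individuals = 1000,
                       n_variants = 400,
                       n_genes = 120,
                       cell_types = default_cell_types(),
                       markers_per_type = 3,
                       marker_fold = 20,
                       cells_per_type = 80,
                       frac_none = 0.02,
                       ld_block_size = 8,
                       ld_rho = 0.7,
                       maf_range = c(0.05, 0.5),
                       n_chromosomes = 6,
                       gene_spacing = 2.5e6,
                       gene_length = 1e4,
                       causal_gene_map = NULL,
                       effect_sd = 0.15,
                       discovery_n = 5000,
                       mediation = mediation_params(),
                       mediator_type = c("status", "ratio"),
                       abeta_cutoff = 0.091,
                       abeta_prevalence = 0.35,
                       noise_sd = c(abeta = 1, ptau = 1, mmse = 1,
                                    pacc = 1),
                       cog_time_effect = NULL,
                       n_visits = 5,
                       visit_spacing = 2,
                       apoe_locus = TRUE,
                       confounded_covariates = FALSE,
                       seed = 1L) {
  mediator_type <- match.arg(mediator_type)
  if (length(maf_range) != 2L || any(maf_range <= 0) ||
      any(maf_range > 0.5) || maf_range[1] > maf_range[2])
    stop("`maf_range` must lie in (0, 0.5] with min <= max", call. = FALSE)
  if (ld_rho < 0 || ld_rho >= 1)
    stop("`ld_rho` must be in [0, 1)", call. = FALSE)
  if (frac_none < 0 || frac_none >= 1)
    stop("`frac_none` must be in [0, 1)", call. = FALSE)
  if (abeta_prevalence <= 0 || abeta_prevalence >= 1)
    stop("`abeta_prevalence` must be in (0, 1)", call. = FALSE)
  stopifnot(n_individuals >= 2, n_variants >= 1, n_genes >= 1,
            markers_per_type >= 1, effect_sd >= 0, discovery_n >= 10,
            gene_spacing > 2e6 + gene_length)
  cell_types <- as.character(cell_types)
  n_types <- length(cell_types)
  if (n_genes < n_types * markers_per_type)
    stop("need at least markers_per_type genes per cell type",
         call. = FALSE)
  gene_ids <- sprintf("G%03d", seq_len(n_genes))
  ## marker genes interleaved across types so neighbouring genes belong
  ## to different types but stay > 2 Mb apart
  marker_map <- lapply(seq_len(n_types), function(t)
    gene_ids[seq(t, by = n_types, length.out = markers_per_type)])
  names(marker_map) <- cell_types
  if (is.null(causal_gene_map)) causal_gene_map <- marker_map
  if (!all(unlist(causal_gene_map) %in% gene_ids))
    stop("causal_gene_map refers to genes not in the annotation",
         call. = FALSE)
  dd <- mediation$delta_direct
  if (is.null(names(dd))) {
    dd <- stats::setNames(rep_len(dd, n_types), cell_types)
  } else {
    full <- stats::setNames(rep(0, n_types), cell_types)
    full[names(dd)] <- dd
    dd <- full
  }
  mediation$delta_direct <- dd
  if (is.null(cog_time_effect)) {
    cog_time_effect <- stats::setNames(rep(0, n_types), cell_types)
  } else if (is.null(names(cog_time_effect))) {
    cog_time_effect <- stats::setNames(rep_len(cog_time_effect, n_types),
                                       cell_types)
  } else {
    full <- stats::setNames(rep(0, n_types), cell_types)
    full[names(cog_time_effect)] <- cog_time_effect
    cog_time_effect <- full
  }
  need <- c("abeta", "ptau", "mmse", "pacc")
  if (is.null(names(noise_sd)))
    noise_sd <- stats::setNames(rep_len(noise_sd, 4L), need)
  if (!all(need %in% names(noise_sd)))
    stop("noise_sd must name ", paste(need, collapse = ", "),
         call. = FALSE)
  structure(list(
    n_individuals = as.integer(n_individuals),
    n_variants = as.integer(n_variants),
    n_genes = as.integer(n_genes),
    cell_types = cell_types,
    markers_per_type = as.integer(markers_per_type),
    marker_fold = marker_fold,
    cells_per_type = as.integer(cells_per_type),
    frac_none = frac_none,
    ld_block_size = as.integer(ld_block_size),
    ld_rho = ld_rho,
    maf_range = maf_range,
    n_chromosomes = as.integer(n_chromosomes),
    gene_spacing = gene_spacing,
    gene_length = gene_length,
    gene_ids = gene_ids,
    marker_map = marker_map,
    causal_gene_map = causal_gene_map,
    effect_sd = effect_sd,
    discovery_n = as.integer(discovery_n),
    mediation = mediation,
    mediator_type = mediator_type,
    abeta_cutoff = abeta_cutoff,
    abeta_prevalence = abeta_prevalence,
    noise_sd = noise_sd[need],
    cog_time_effect = cog_time_effect,
    n_visits = as.integer(n_visits),
    visit_spacing = visit_spacing,
    apoe_locus = isTRUE(apoe_locus),
    confounded_covariates = isTRUE(confounded_covariates),
    seed = as.integer(seed)
  ), class = "cellprs_sim_config")
}

#' @export
print.cellprs_sim_config <- function(x, ...) {
  cat("<cellprs_sim_config>\n")
  cat(sprintf("  %d individuals, %d variants, %d genes, %d cell types\n",
              x$n_individuals, x$n_variants, x$n_genes,
              length(x$cell_types)))
  cat(sprintf("  LD: blocks of %d, rho = %.2f; MAF in [%.2f, %.2f]\n",
              x$ld_block_size, x$ld_rho, x$maf_range[1], x$maf_range[2]))
  cat(sprintf("  effect_sd = %.3g, discovery n = %d, seed = %d\n",
              x$effect_sd, x$discovery_n, x$seed))
  invisible(x)
}
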