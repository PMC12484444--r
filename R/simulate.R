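#' Synthetic gene annotation
#'
#' Lays `cfg$n_genes` gene intervals along the synthetic genome.  Genes
#' are spaced `cfg$gene_spacing` bp apart so that the 1 Mb variant
#' neighbourhood of each gene is disjoint from every other gene's.
#' When `cfg$apoe_locus` is set, the last chromosome is labelled chr19
#' and its first gene is centred inside the APOE region
#' (chr19:44905796-44909393) so that the APOE mask is exercised.
#'
#' @param cfg A [sim_config()] object.
#' @return A data.frame with columns `gene_id`, `chrom`, `start`,
#'   `end` (1-based inclusive) and `center`.
#' @export
simulate_annotation <- function(cfg) {
  n <- cfg$n_genes
  per_chrom <- ceiling(n / cfg$n_chromosomes)
  chrom_idx <- rep(seq_len(cfg$n_chromosomes), each = per_chrom)[seq_len(n)]
  labels <- paste0("chr", seq_len(cfg$n_chromosomes))
  if (cfg$apoe_locus) labels[cfg$n_chromosomes] <- "chr19"
  within <- stats::ave(seq_len(n), chrom_idx, FUN = seq_along)
  center <- 2e6 + (within - 1) * cfg$gene_spacing
  if (cfg$apoe_locus) {
    on19 <- chrom_idx == cfg$n_chromosomes
    ## centre the chr19 gene ladder on the APOE region midpoint
    center[on19] <- 44907594 + (within[on19] - 1) * cfg$gene_spacing
  }
  half <- cfg$gene_length / 2
  data.frame(gene_id = cfg$gene_ids,
             chrom = labels[chrom_idx],
             start = as.integer(round(center - half)),
             end = as.integer(round(center + half)),
             center = as.integer(round(center)),
             stringsAsFactors = FALSE)
}

## Variant map: each gene neighbourhood receives an equal share of the
## panel; variants sit within +/- 0.5 Mb of their gene centre, so every
## variant is within 1 Mb of its generating gene.
make_variant_map <- function(cfg, annotation) {
  m <- cfg$n_variants
  ## round-robin allocation so every gene neighbourhood is covered
  gene_of <- sort(rep_len(seq_len(cfg$n_genes), m))
  pos <- integer(m)
  for (g in unique(gene_of)) {
    idx <- which(gene_of == g)
    off <- sort(sample.int(1e6, length(idx))) - 5e5
    pos[idx] <- annotation$center[g] + off
  }
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
  maf <- stats::runif(m, cfg$maf_range[1], cfg$maf_range[2])
  ## LD blocks: chunks of consecutive variants within one gene
  ## neighbourhood, at most ld_block_size wide
  within <- stats::ave(seq_len(m), gene_of, FUN = seq_along)
  block <- paste0(gene_of, ".", (within - 1) %/% cfg$ld_block_size)
  block <- match(block, unique(block))
  data.frame(chrom = annotation$chrom[gene_of],
             pos = pos,
             id = sprintf("var%04d", seq_len(m)),
             ref = ref, alt = alt,
             maf = maf,
             block = block,
             source_gene = annotation$gene_id[gene_of],
             stringsAsFactors = FALSE)
}

## Gaussian-copula haplotypes: within each block, latent normals share
## a common factor with loading sqrt(rho); thresholding at the
## (1 - maf) quantile yields alleles with the requested frequency.
draw_dosages <- function(map, n, rho) {
  m <- nrow(map)
  n_hap <- 2L * n
  shared <- matrix(stats::rnorm(n_hap * max(map$block)), n_hap)
  z <- sqrt(rho) * shared[, map$block, drop = FALSE] +
    sqrt(1 - rho) * matrix(stats::rnorm(n_hap * m), n_hap)
  thr <- stats::qnorm(1 - map$maf)
  hap <- z > rep(thr, each = n_hap)
  storage.mode(hap) <- "integer"
  dos <- hap[seq_len(n), , drop = FALSE] +
    hap[n + seq_len(n), , drop = FALSE]
  colnames(dos) <- map$id
  dos
}

#' Simulate LD-blocked diploid genotypes
#'
#' Draws a dosage matrix (individuals x variants, values 0/1/2) from a
#' Gaussian-copula haplotype model with exchangeable within-block
#' correlation `cfg$ld_rho`, variant positions strictly increasing along
#' each chromosome, and minor allele frequencies uniform on
#' `cfg$maf_range`.  The counted (effect-allele) dosage is the ALT
#' allele count.
#'
#' @param cfg A [sim_config()] object.
#' @param annotation Gene annotation from [simulate_annotation()];
#'   simulated from `cfg` when missing.
#' @param seed Integer seed (defaults to `cfg$seed`).
#' @return A list of class `cellprs_genotypes` with elements `dosage`
#'   (matrix), `map` (variant data.frame with `chrom`, `pos`, `id`,
#'   `ref`, `alt`, `maf`, `block`, `source_gene`) and `n`.
#' @export
simulate_genotypes <- function(cfg, annotation = simulate_annotation(cfg),
                               seed = cfg$seed) {
  set.seed(seed)
  map <- make_variant_map(cfg, annotation)
  dos <- draw_dosages(map, cfg$n_individuals, cfg$ld_rho)
  rownames(dos) <- sprintf("S%04d", seq_len(cfg$n_individuals))
  structure(list(dosage = dos, map = map, n = cfg$n_individuals),
            class = "cellprs_genotypes")
}

#' @export
print.cellprs_genotypes <- function(x, ...) {
  cat(sprintf("<cellprs_genotypes> %d individuals x %d variants on %d chromosome(s)\n",
              nrow(x$dosage), ncol(x$dosage), length(unique(x$map$chrom))))
  invisible(x)
}

#' Simulate single-cell counts with marker-gene structure
#'
#' Counts are negative binomial with gene-level baseline means; each
#' cell type's marker genes (from `cfg$marker_map`) have their mean
#' multiplied by `cfg$marker_fold` in cells of that type.  A fraction
#' `cfg$frac_none` of extra cells carry the label `"None"` to exercise
#' the label filter.
#'
#' @inheritParams simulate_genotypes
#' @return A list with `counts` (cell x gene integer matrix) and
#'   `cell_meta` (data.frame with `barcode`, `cell_type`).
#' @export
simulate_expression <- function(cfg, annotation = simulate_annotation(cfg),
                                seed = cfg$seed + 1L) {
  if (!all(unlist(cfg$causal_gene_map) %in% annotation$gene_id))
    stop("causal genes missing from annotation", call. = FALSE)
  if (cfg$marker_fold <= 1)
    warning("marker_fold <= 1: cell-type weights will be near-uniform")
  set.seed(seed)
  types <- cfg$cell_types
  n_none <- round(cfg$frac_none * cfg$cells_per_type * length(types))
  labels <- c(rep(types, each = cfg$cells_per_type),
              rep("None", n_none))
  n_cells <- length(labels)
  base <- stats::rlnorm(cfg$n_genes, meanlog = log(2), sdlog = 0.5)
  mu <- matrix(base, n_cells, cfg$n_genes, byrow = TRUE)
  for (ty in types) {
    g <- match(cfg$marker_map[[ty]], cfg$gene_ids)
    mu[labels == ty, g] <- mu[labels == ty, g] * cfg$marker_fold
  }
  sizefac <- stats::rlnorm(n_cells, 0, 0.3)
  counts <- matrix(stats::rnbinom(n_cells * cfg$n_genes,
                                  mu = sizefac * mu, size = 2),
                   n_cells, cfg$n_genes)
  dimnames(counts) <- list(sprintf("cell%04d", seq_len(n_cells)),
                           cfg$gene_ids)
  list(counts = counts,
       cell_meta = data.frame(barcode = rownames(counts),
                              cell_type = labels,
                              stringsAsFactors = FALSE))
}

#' Expected cell-type weights implied by the generator
#'
#' Analytic percentage-expression fractions under the generator's
#' marker model: a marker gene has weight `fold / (fold + T - 1)` in
#' its own type and `1 / (fold + T - 1)` elsewhere; non-marker genes
#' are uniform at `1 / T`.  Used as the generator's own bookkeeping for
#' building true phenotype scores.
#'
#' @param cfg A [sim_config()] object.
#' @return A gene x cell-type matrix whose rows sum to 1.
#' @export
true_cell_weights <- function(cfg) {
  n_t <- length(cfg$cell_types)
  w <- matrix(1 / n_t, cfg$n_genes, n_t,
              dimnames = list(cfg$gene_ids, cfg$cell_types))
  for (ty in cfg$cell_types) {
    g <- match(cfg$marker_map[[ty]], cfg$gene_ids)
    w[g, ] <- 1 / (cfg$marker_fold + n_t - 1)
    w[g, ty] <- cfg$marker_fold / (cfg$marker_fold + n_t - 1)
  }
  w
}

#' Simulate discovery-GWAS summary statistics
#'
#' Simulates an independent discovery cohort of `cfg$discovery_n`
#' individuals from the same variant panel (same MAFs and LD blocks as
#' the target genotypes, new random draws), assigns true effects
#' `N(0, effect_sd^2)` to variants lying in the neighbourhood of causal
#' genes (`cfg$causal_gene_map`), generates a discovery phenotype, and
#' computes per-variant marginal regression estimates and p-values.
#'
#' @param cfg A [sim_config()] object.
#' @param genotypes Target genotypes from [simulate_genotypes()]; only
#'   the variant map (not the dosages) is reused, keeping discovery and
#'   target cohorts non-overlapping.
#' @param seed Integer seed.
#' @return A data.frame of class `cellprs_sumstats` with columns
#'   `CHR`, `POS`, `ID`, `EA`, `OA`, `BETA`, `P`; the true effects are
#'   attached as attribute `true_beta`.
#' @export
simulate_gwas <- function(cfg, genotypes, seed = cfg$seed + 2L) {
  set.seed(seed)
  map <- genotypes$map
  m <- nrow(map)
  causal_genes <- unique(unlist(cfg$causal_gene_map))
  causal <- map$source_gene %in% causal_genes
  beta_true <- numeric(m)
  beta_true[causal] <- stats::rnorm(sum(causal), 0, cfg$effect_sd)
  G <- draw_dosages(map, cfg$discovery_n, cfg$ld_rho)
  y <- as.numeric(G %*% beta_true) + stats::rnorm(cfg$discovery_n)
  Gc <- sweep(G, 2L, colMeans(G))
  yc <- y - mean(y)
  den <- colSums(Gc^2)
  den[den == 0] <- NA_real_
  bhat <- as.numeric(crossprod(Gc, yc)) / den
  n <- cfg$discovery_n
  rss <- sum(yc^2) - bhat^2 * den
  se <- sqrt(rss / (n - 2) / den)
  tstat <- bhat / se
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[is.na(p)] <- 1
  bhat[is.na(bhat)] <- 0
  out <- data.frame(CHR = map$chrom, POS = map$pos, ID = map$id,
                    EA = map$alt, OA = map$ref,
                    BETA = bhat, P = pmax(p, .Machine$double.xmin),
                    stringsAsFactors = FALSE)
  attr(out, "true_beta") <- beta_true
  class(out) <- c("cellprs_sumstats", "data.frame")
  out
}

#' Simulate amyloid-mediated phenotypes
#'
#' Builds the phenotype and longitudinal tables of the synthetic
#' cohort.  True per-cell-type genetic scores are formed from the
#' generator's own bookkeeping (true effects times true expression
#' weights); amyloid liability is
#' `gamma_amyloid * score + covariate effects + noise`; the CSF ratio
#' is an affine, decreasing function of liability calibrated so that
#' `abeta_status == (abeta_ratio < abeta_cutoff)` holds exactly with
#' marginal positivity near `cfg$abeta_prevalence`; pTau217 is driven
#' by amyloid (`alpha_tau`) plus per-cell-type direct effects
#' (`delta_direct`); cognition gets per-subject random intercepts and
#' slopes with an optional score-by-time term.
#'
#' @param cfg A [sim_config()] object.
#' @param genotypes Target genotypes from [simulate_genotypes()].
#' @param true_beta Per-variant true effects (attribute `true_beta` of
#'   [simulate_gwas()] output); defaults to all zero.
#' @param true_weights Gene x cell-type fraction matrix; defaults to
#'   [true_cell_weights()].
#' @param seed Integer seed.
#' @return A list with `phenotypes` (one row per individual: `id`,
#'   `age`, `sex`, `abeta_ratio`, `abeta_status`, `ptau217`, `mmse`,
#'   `pacc`, `apoe4_count`, `apoe2_count`, `PC1`..`PC10`),
#'   `longitudinal` (`id`, `visit`, `time`, `mmse`, `pacc`) and
#'   `true_scores` (individual x score matrix, cell types plus
#'   `full`).
#' @export
simulate_phenotypes <- function(cfg, genotypes, true_beta = NULL,
                                true_weights = true_cell_weights(cfg),
                                seed = cfg$seed + 3L) {
  set.seed(seed)
  G <- genotypes$dosage
  n <- nrow(G)
  map <- genotypes$map
  if (is.null(true_beta)) true_beta <- numeric(ncol(G))
  std0 <- function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }
  w_var <- true_weights[map$source_gene, , drop = FALSE]
  scores <- vapply(cfg$cell_types, function(ty)
    std0(as.numeric(G %*% (true_beta * w_var[, ty]))), numeric(n))
  scores <- cbind(scores, full = std0(as.numeric(G %*% true_beta)))

  age <- stats::rnorm(n, 71, 5.8)
  sex <- stats::rbinom(n, 1, 0.45)
  apoe4 <- sample(0:2, n, replace = TRUE, prob = c(0.65, 0.31, 0.04))
  apoe2 <- sample(0:2, n, replace = TRUE, prob = c(0.85, 0.14, 0.01))
  pcs <- matrix(stats::rnorm(n * 10), n,
                dimnames = list(NULL, paste0("PC", 1:10)))
  med <- cfg$mediation
  s_med <- if (med$mediator_score %in% colnames(scores))
    scores[, med$mediator_score] else rep(0, n)
  if (cfg$confounded_covariates) pcs[, 1] <- pcs[, 1] + 0.3 * s_med

  age_eff <- 0.02; sex_eff <- 0.1
  has_score <- as.integer(stats::sd(s_med) > 0)
  liab <- med$gamma_amyloid * s_med + age_eff * (age - 71) +
    sex_eff * sex + stats::rnorm(n, 0, cfg$noise_sd["abeta"])
  sd_liab <- sqrt(has_score * med$gamma_amyloid^2 +
                  (age_eff * 5.8)^2 + sex_eff^2 * 0.45 * 0.55 +
                  cfg$noise_sd["abeta"]^2)
  mu0 <- stats::qnorm(1 - cfg$abeta_prevalence, sd = sd_liab)
  status <- as.integer(liab > mu0)
  ratio <- cfg$abeta_cutoff + 0.01 * (mu0 - liab)

  amyloid_term <- if (cfg$mediator_type == "status") status else liab - mu0
  ptau_lin <- med$alpha_tau * amyloid_term +
    as.numeric(scores[, cfg$cell_types, drop = FALSE] %*%
                 med$delta_direct[cfg$cell_types]) +
    stats::rnorm(n, 0, cfg$noise_sd["ptau"])
  ptau217 <- exp(0.35 * ptau_lin + 2.5)

  s_full <- scores[, "full"]
  mmse0 <- 27.5 - 0.05 * (age - 71) - 0.3 * s_full +
    stats::rnorm(n, 0, cfg$noise_sd["mmse"])
  pacc0 <- -0.15 * s_full - 0.03 * (age - 71) +
    stats::rnorm(n, 0, cfg$noise_sd["pacc"])

  pheno <- data.frame(id = rownames(G), age = age, sex = sex,
                      abeta_ratio = ratio, abeta_status = status,
                      ptau217 = ptau217, mmse = mmse0, pacc = pacc0,
                      apoe4_count = apoe4, apoe2_count = apoe2,
                      stringsAsFactors = FALSE)
  pheno <- cbind(pheno, as.data.frame(pcs))

  times <- cfg$visit_spacing * (seq_len(cfg$n_visits) - 1)
  b0 <- stats::rnorm(n, 0, 1)
  b1 <- stats::rnorm(n, 0, 0.15)
  slope <- -0.15 + b1 +
    as.numeric(scores[, cfg$cell_types, drop = FALSE] %*%
                 cfg$cog_time_effect[cfg$cell_types])
  long <- data.frame(
    id = rep(pheno$id, each = cfg$n_visits),
    visit = rep(seq_len(cfg$n_visits), n),
    time = rep(times, n))
  long$mmse <- rep(mmse0 + b0, each = cfg$n_visits) +
    rep(slope, each = cfg$n_visits) * long$time +
    stats::rnorm(nrow(long), 0, 0.8)
  long$pacc <- rep(pacc0 + 0.2 * b0, each = cfg$n_visits) +
    0.3 * rep(slope, each = cfg$n_visits) * long$time +
    stats::rnorm(nrow(long), 0, 0.3)

  list(phenotypes = pheno, longitudinal = long, true_scores = scores)
}

#' Simulate a complete synthetic cohort
#'
#' Runs every generator stage in dependency order under sub-seeds
#' derived from `cfg$seed`: annotation, target genotypes, single-cell
#' counts, discovery-GWAS summary statistics and phenotypes.
#'
#' @param cfg A [sim_config()] object.
#' @return A list of class `cellprs_cohort` with elements
#'   `annotation`, `genotypes`, `expression`, `sumstats`, `phenotypes`,
#'   `longitudinal`, `truth` (true effects, weights and scores) and
#'   `cfg`.
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  annotation <- simulate_annotation(cfg)
  genotypes <- simulate_genotypes(cfg, annotation, seed = cfg$seed)
  expression <- simulate_expression(cfg, annotation, seed = cfg$seed + 1L)
  sumstats <- simulate_gwas(cfg, genotypes, seed = cfg$seed + 2L)
  tw <- true_cell_weights(cfg)
  ph <- simulate_phenotypes(cfg, genotypes,
                            true_beta = attr(sumstats, "true_beta"),
                            true_weights = tw, seed = cfg$seed + 3L)
  structure(list(annotation = annotation,
                 genotypes = genotypes,
                 expression = expression,
                 sumstats = sumstats,
                 phenotypes = ph$phenotypes,
                 longitudinal = ph$longitudinal,
                 truth = list(beta = attr(sumstats, "true_beta"),
                              weights = tw,
                              scores = ph$true_scores),
                 cfg = cfg),
            class = "cellprs_cohort")
}

#' @export
print.cellprs_cohort <- function(x, ...) {
  cat("<cellprs_cohort>\n")
  cat(sprintf("  %d individuals, %d variants, %d genes, %d cells\n",
              nrow(x$genotypes$dosage), ncol(x$genotypes$dosage),
              nrow(x$annotation), nrow(x$expression$counts)))
  cat(sprintf("  amyloid positive: %d (%.1f%%)\n",
              sum(x$phenotypes$abeta_status),
              100 * mean(x$phenotypes$abeta_status)))
  invisible(x)
}
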