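#' Clumping-and-thresholding configuration
#'
#' Defaults follow the standard clumping-and-thresholding workflow:
#' greedy clumping at r^2 < 0.1 over a 1000 kb window, and seven nested
#' strict P-value thresholds PRS1-PRS7 from 0.05 down to 5e-08.
#'
#' @param r2_threshold Squared-correlation threshold; variants with
#'   r^2 above it are absorbed by their index variant.
#' @param window_kb Clumping window half-width in kb.
#' @param p_thresholds Strictly decreasing vector of P-value cut-offs
#'   defining PRS1..PRSk.
#' @return A list of class `cellprs_clump_config`.
#' @export
clump_config <- function(r2_threshold = 0.1, window_kb = 1000,
                         p_thresholds = c(0.05, 5e-3, 5e-4, 5e-5,
                                          5e-6, 5e-7, 5e-8)) {
  if (r2_threshold <= 0 || r2_threshold > 1)
    stop("r2_threshold must be in (0, 1]", call. = FALSE)
  if (window_kb <= 0) stop("window_kb must be positive", call. = FALSE)
  if (any(diff(p_thresholds) >= 0))
    stop("p_thresholds must be strictly decreasing", call. = FALSE)
  structure(list(r2_threshold = r2_threshold, window_kb = window_kb,
                 p_thresholds = p_thresholds),
            class = "cellprs_clump_config")
}

#' Squared Pearson correlation between two dosage vectors
#'
#' Computed over pairwise-complete observations.  A zero-variance
#' vector yields r^2 = 0 with a warning (such a variant cannot clump
#' others).
#'
#' @param dosage_a,dosage_b Equal-length numeric vectors.
#' @return r^2 in `[0, 1]`.
#' @export
ld_r2 <- function(dosage_a, dosage_b) {
  if (length(dosage_a) != length(dosage_b) || length(dosage_a) < 2)
    stop("dosage vectors must have equal length >= 2", call. = FALSE)
  ok <- !is.na(dosage_a) & !is.na(dosage_b)
  a <- dosage_a[ok]; b <- dosage_b[ok]
  if (length(a) < 2 || stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("zero variance in dosage vector; r^2 defined as 0")
    return(0)
  }
  stats::cor(a, b)^2
}

#' Greedy LD clumping
#'
#' Iterates variants by ascending P-value (ties broken by chromosome
#' then position); each unassigned variant becomes an index variant and
#' removes all unassigned variants on the same chromosome within
#' `window_kb` kb having r^2 greater than `r2_threshold` with it.
#' Clumping is performed once on the unweighted P-values and the
#' retained index set is shared by all score types.
#'
#' @param variants Data.frame with `chrom`, `pos`, `pvalue` and
#'   `col_index` (column of each variant in `dosage`).
#' @param dosage Individuals x variants dosage matrix used for r^2.
#' @param cfg A [clump_config()] object.
#' @return Logical vector along `variants`: `TRUE` for retained index
#'   variants.
#' @export
greedy_clump <- function(variants, dosage, cfg = clump_config()) {
  m <- nrow(variants)
  if (m == 0L) return(logical(0))
  ord <- order(variants$pvalue, variants$chrom, variants$pos)
  window <- cfg$window_kb * 1000
  assigned <- logical(m)
  retained <- logical(m)
  X <- dosage[, variants$col_index, drop = FALSE]
  for (i in ord) {
    if (assigned[i]) next
    retained[i] <- TRUE
    assigned[i] <- TRUE
    cand <- which(!assigned & variants$chrom == variants$chrom[i] &
                    abs(variants$pos - variants$pos[i]) <= window)
    if (!length(cand)) next
    r2 <- suppressWarnings(
      stats::cor(X[, i], X[, cand, drop = FALSE],
                 use = "pairwise.complete.obs"))^2
    r2[is.na(r2)] <- 0
    assigned[cand[r2 > cfg$r2_threshold]] <- TRUE
  }
  retained
}

#' Scale variant effects by cell-type expression weights
#'
#' Multiplies each variant's effect size by its mapped gene's
#' percentage-expression weight (on the 0-100 percent scale) in every
#' cell type: `scaled_beta[c] = beta * 100 * weight[gene, c]`.  The
#' unweighted effect is carried unchanged in the `full` score column.
#' A variant whose gene is unmapped or absent from the weight matrix
#' gets `NA` cell-typed effects (it is excluded from cell-weighted
#' scores but kept in the full score).
#'
#' @param variants Harmonized variant table with `beta` and `gene_id`.
#' @param weights A `cell_weight_matrix` (genes x cell types).
#' @return `variants` with added columns `scaled_<type>` for each cell
#'   type and `scaled_full`; the number of variants without usable
#'   weights is reported via a message and the `n_unweighted`
#'   attribute.
#' @export
scale_weights <- function(variants, weights) {
  types <- colnames(weights)
  gi <- match(variants$gene_id, rownames(weights))
  for (ty in types) {
    variants[[paste0("scaled_", ty)]] <-
      variants$beta * 100 * weights[gi, ty]
  }
  variants$scaled_full <- variants$beta
  n_un <- sum(is.na(gi))
  if (n_un)
    message(sprintf(
      "%d variant(s) lack gene weights; kept in the full score only",
      n_un))
  attr(variants, "score_types") <- c(types, "full")
  attr(variants, "n_unweighted") <- n_un
  variants
}

#' Nested P-value threshold subsets (PRS1..PRSk)
#'
#' Subsets the clump-retained variants at each strict P-value
#' threshold.  Subsets are nested by construction: PRS(k+1) is a
#' subset of PRS(k).
#'
#' @param variants Variant table with `pvalue`.
#' @param retained Logical clump flags from [greedy_clump()].
#' @param cfg A [clump_config()] object.
#' @return Named list (`PRS1`..`PRSk`) of integer row indices into
#'   `variants`.
#' @export
threshold_sets <- function(variants, retained, cfg = clump_config()) {
  ths <- cfg$p_thresholds
  out <- lapply(ths, function(th) which(retained & variants$pvalue < th))
  names(out) <- paste0("PRS", seq_along(ths))
  out
}

#' Score individuals for one variant subset
#'
#' Weighted allele-dosage sum: `score_i = sum_v dosage_iv *
#' scaled_beta_v`.  Missing dosages are mean-imputed with twice the
#' effect-allele frequency among non-missing individuals.  Sum (not
#' average) semantics; standardization downstream removes the
#' distinction.
#'
#' @param dosage Individuals x variants dosage matrix.
#' @param variants Variant table with `col_index` and the requested
#'   effect column.
#' @param beta_col Name of the effect column (e.g. `"scaled_microglia"`
#'   or `"scaled_full"`).
#' @param subset Integer row indices into `variants` to score.
#' @return Numeric vector of raw scores, one per individual.
#' @export
score_individuals <- function(dosage, variants, beta_col,
                              subset = seq_len(nrow(variants))) {
  if (!length(subset)) stop("empty variant subset", call. = FALSE)
  beta <- variants[[beta_col]][subset]
  keep <- !is.na(beta)
  if (!any(keep)) stop("no usable effects in subset", call. = FALSE)
  beta <- beta[keep]
  G <- dosage[, variants$col_index[subset][keep], drop = FALSE]
  if (anyNA(G)) {
    eaf <- colMeans(G, na.rm = TRUE) / 2
    for (j in which(colSums(is.na(G)) > 0))
      G[is.na(G[, j]), j] <- 2 * eaf[j]
  }
  as.numeric(G %*% beta)
}

#' Standardize scores to mean 0, SD 1
#'
#' Uses the sample standard deviation (n - 1 denominator) computed over
#' the analysis sample.
#'
#' @param x Numeric vector (or matrix standardized column-wise).
#' @param name Label used in the zero-variance error message.
#' @return Standardized vector/matrix with attributes `center` and
#'   `scale`.
#' @export
standardize_scores <- function(x, name = deparse(substitute(x))) {
  if (is.matrix(x)) {
    out <- x
    for (j in seq_len(ncol(x)))
      out[, j] <- standardize_scores(x[, j], colnames(x)[j])
    return(out)
  }
  if (length(x) < 2) stop("need >= 2 individuals", call. = FALSE)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    stop(sprintf("score '%s' has zero variance; cannot standardize",
                 name), call. = FALSE)
  structure((x - mean(x)) / s, center = mean(x), scale = s)
}

#' Build the standardized score matrix
#'
#' Clumps once on unweighted P-values, then scores every
#' score type (six cell types plus `full`) at every threshold and
#' standardizes each column.  Empty subsets (or subsets with no
#' weighted variants for a cell type) are omitted with a warning
#' rather than emitted as zeros.
#'
#' @param dosage Individuals x variants dosage matrix.
#' @param variants Weighted variant table from [scale_weights()].
#' @param cfg A [clump_config()] object.
#' @param retained Optional precomputed clump flags; computed when
#'   missing.
#' @return A numeric matrix (individuals x score columns, named
#'   `<type>_PRS<k>`) of class `cellprs_scores` with attributes
#'   `n_variants` (named count per column), `thresholds` and
#'   `standardized = TRUE`.
#' @export
build_scores <- function(dosage, variants, cfg = clump_config(),
                         retained = NULL) {
  types <- attr(variants, "score_types")
  if (is.null(types))
    stop("variants must come from scale_weights()", call. = FALSE)
  if (is.null(retained)) retained <- greedy_clump(variants, dosage, cfg)
  sets <- threshold_sets(variants, retained, cfg)
  cols <- list(); nv <- integer(0)
  for (ty in types) {
    bc <- paste0("scaled_", ty)
    for (k in seq_along(sets)) {
      idx <- sets[[k]]
      idx <- idx[!is.na(variants[[bc]][idx])]
      nm <- paste0(ty, "_", names(sets)[k])
      if (!length(idx)) {
        warning(sprintf("score column %s is empty; omitted", nm))
        next
      }
      raw <- score_individuals(dosage, variants, bc, idx)
      if (stats::sd(raw) == 0) {
        warning(sprintf("score column %s has zero variance; omitted", nm))
        next
      }
      cols[[nm]] <- standardize_scores(raw, nm)
      nv[nm] <- length(idx)
    }
  }
  if (!length(cols)) stop("no non-empty score columns", call. = FALSE)
  out <- do.call(cbind, cols)
  rownames(out) <- rownames(dosage)
  structure(out, n_variants = nv, thresholds = cfg$p_thresholds,
            standardized = TRUE, class = c("cellprs_scores", "matrix",
                                           "array"))
}

#' Restricted PRS from strictly cell-specific genes
#'
#' Sensitivity analysis: per cell type, select the genes whose
#' expression weight in that type is at least `tau` (default 0.5),
#' keep the variants lying within 1 Mb of any selected gene's
#' interval, and run clumping and thresholding on that subset with the
#' unweighted effect sizes (no reweighting).
#'
#' @param dosage Individuals x variants dosage matrix.
#' @param variants Harmonized variant table (`chrom`, `pos`,
#'   `pvalue`, `beta`, `col_index`).
#' @param weights A `cell_weight_matrix`.
#' @param annotation Gene intervals (`gene_id`, `chrom`, `start`,
#'   `end`).
#' @param cfg A [clump_config()] object.
#' @param tau Specificity threshold on the weight fraction.
#' @param flank Neighbourhood half-width in bp (default 1 Mb).
#' @return A `cellprs_scores` matrix with columns `<type>_rPRS<k>`;
#'   cell types with no gene passing `tau` are absent with a warning.
#' @export
restricted_prs <- function(dosage, variants, weights, annotation,
                           cfg = clump_config(), tau = 0.5,
                           flank = 1e6) {
  cols <- list(); nv <- integer(0)
  variants$scaled_full <- variants$beta
  for (ty in colnames(weights)) {
    sel <- rownames(weights)[weights[, ty] >= tau]
    if (!length(sel)) {
      warning(sprintf("no genes pass tau = %g for %s; scores absent",
                      tau, ty))
      next
    }
    ann <- annotation[annotation$gene_id %in% sel, , drop = FALSE]
    near <- rep(FALSE, nrow(variants))
    for (g in seq_len(nrow(ann))) {
      near <- near | (variants$chrom == ann$chrom[g] &
                        variants$pos >= ann$start[g] - flank &
                        variants$pos <= ann$end[g] + flank)
    }
    if (!any(near)) {
      warning(sprintf("no variants within %g bp of %s-specific genes",
                      flank, ty))
      next
    }
    sub <- variants[near, , drop = FALSE]
    ret <- greedy_clump(sub, dosage, cfg)
    sets <- threshold_sets(sub, ret, cfg)
    for (k in seq_along(sets)) {
      idx <- sets[[k]]
      nm <- paste0(ty, "_r", names(sets)[k])
      if (!length(idx)) next
      raw <- score_individuals(dosage, sub, "scaled_full", idx)
      if (stats::sd(raw) == 0) next
      cols[[nm]] <- standardize_scores(raw, nm)
      nv[nm] <- length(idx)
    }
  }
  if (!length(cols)) {
    warning("restricted PRS: no score columns produced")
    return(NULL)
  }
  out <- do.call(cbind, cols)
  rownames(out) <- rownames(dosage)
  structure(out, n_variants = nv, thresholds = cfg$p_thresholds,
            standardized = TRUE, class = c("cellprs_scores", "matrix",
                                           "array"))
}

#' @export
print.cellprs_scores <- function(x, ...) {
  cat(sprintf("<cellprs_scores> %d individuals x %d standardized score columns\n",
              nrow(x), ncol(x)))
  nv <- attr(x, "n_variants")
  cat("  variants per column:", paste0(names(nv)[seq_len(min(4, length(nv)))],
                                       "=", nv[seq_len(min(4, length(nv)))],
                                       collapse = ", "),
      if (length(nv) > 4) "...", "\n")
  invisible(x)
}
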