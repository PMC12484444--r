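#' GWAS variant quality-control thresholds
#'
#' Standard array-QC defaults: Hardy-Weinberg equilibrium P > 5e-08,
#' minor allele frequency >= 5%, call rate > 99%, autosomal
#' bi-allelic SNVs only.
#'
#' @param hwe_p_min,maf_min,call_rate_min,autosomal_only,biallelic_only
#'   Threshold values; see Description.
#' @return A list of class `cellprs_qc_thresholds`.
#' @export
qc_thresholds <- function(hwe_p_min = 5e-8, maf_min = 0.05,
                          call_rate_min = 0.99, autosomal_only = TRUE,
                          biallelic_only = TRUE) {
  stopifnot(hwe_p_min >= 0, hwe_p_min <= 1, maf_min >= 0, maf_min <= 0.5,
            call_rate_min >= 0, call_rate_min <= 1)
  structure(list(hwe_p_min = hwe_p_min, maf_min = maf_min,
                 call_rate_min = call_rate_min,
                 autosomal_only = isTRUE(autosomal_only),
                 biallelic_only = isTRUE(biallelic_only)),
            class = "cellprs_qc_thresholds")
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom chi-square goodness-of-fit test of observed
#' genotype counts against Hardy-Weinberg expectations computed from
#' the sample allele frequency.  Monomorphic variants return p = 1 by
#' convention.  All arguments are vectorized.
#'
#' @param n_aa,n_ab,n_bb Counts of the three genotype classes
#'   (homozygous reference, heterozygous, homozygous alternate).
#' @return Vector of p-values in `(0, 1]`.
#' @export
hwe_test <- function(n_aa, n_ab, n_bb) {
  if (any(c(n_aa, n_ab, n_bb) < 0)) stop("counts must be >= 0",
                                         call. = FALSE)
  n <- n_aa + n_ab + n_bb
  if (any(n == 0)) stop("total genotype count must be positive",
                        call. = FALSE)
  p <- (2 * n_aa + n_ab) / (2 * n)
  q <- 1 - p
  e_aa <- n * p^2
  e_ab <- 2 * n * p * q
  e_bb <- n * q^2
  chisq <- ifelse(p == 0 | q == 0, 0,
                  (n_aa - e_aa)^2 / e_aa + (n_ab - e_ab)^2 / e_ab +
                    (n_bb - e_bb)^2 / e_bb)
  stats::pchisq(chisq, df = 1, lower.tail = FALSE)
}

strip_chr <- function(x) sub("^chr", "", x)

#' Quality-control filter for a variant panel
#'
#' Applies the [qc_thresholds()] criteria to a dosage matrix and its
#' variant map.  Allele frequency is `mean(dosage) / 2` over
#' non-missing entries, call rate the fraction non-missing, and the
#' Hardy-Weinberg test uses hard calls (`round(dosage)`).  Each dropped
#' variant is reported with the first criterion it failed, in the order
#' autosomal, biallelic, call_rate, maf, hwe.
#'
#' @param dosage Individuals x variants dosage matrix (values in
#'   `[0, 2]`, `NA` = missing).
#' @param variants Data.frame aligned to the columns of `dosage` with
#'   at least `chrom`, `id`, `ref`, `alt`.
#' @param thresholds A [qc_thresholds()] object.
#' @return A list with `retained` (logical vector) and `report`
#'   (data.frame `id`, `retained`, `reason`).
#' @export
qc_filter <- function(dosage, variants, thresholds = qc_thresholds()) {
  stopifnot(ncol(dosage) == nrow(variants))
  m <- ncol(dosage)
  call_rate <- colMeans(!is.na(dosage))
  af <- colMeans(dosage, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  hard <- round(dosage)
  n_bb <- colSums(hard == 2, na.rm = TRUE)
  n_ab <- colSums(hard == 1, na.rm = TRUE)
  n_aa <- colSums(hard == 0, na.rm = TRUE)
  hwe_p <- rep(1, m)
  ok_counts <- (n_aa + n_ab + n_bb) > 0
  hwe_p[ok_counts] <- hwe_test(n_aa[ok_counts], n_ab[ok_counts],
                               n_bb[ok_counts])
  autosomal <- strip_chr(variants$chrom) %in% as.character(1:22)
  bases <- c("A", "C", "G", "T")
  biallelic <- variants$ref %in% bases & variants$alt %in% bases &
    variants$ref != variants$alt
  reason <- rep(NA_character_, m)
  if (thresholds$autosomal_only) reason[!autosomal] <- "autosomal"
  if (thresholds$biallelic_only)
    reason[is.na(reason) & !biallelic] <- "biallelic"
  reason[is.na(reason) & call_rate <= thresholds$call_rate_min &
           call_rate < 1] <- "call_rate"
  reason[is.na(reason) & maf < thresholds$maf_min] <- "maf"
  reason[is.na(reason) & hwe_p <= thresholds$hwe_p_min] <- "hwe"
  retained <- is.na(reason)
  list(retained = retained,
       report = data.frame(id = variants$id, retained = retained,
                           reason = reason, stringsAsFactors = FALSE))
}

is_complement_pair <- function(a, b) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  !is.na(comp[a]) & comp[a] == b
}

#' Harmonize GWAS summary statistics against genotype alleles
#'
#' Matches summary-statistic records to genotyped variants on
#' `(chrom, pos)`.  When the effect allele equals the counted (ALT)
#' allele the record is kept as is; when effect and other alleles are
#' swapped relative to the genotype, the effect size's sign is flipped
#' and the alleles swapped.  Records whose alleles do not match the
#' genotype literally are dropped (no strand inference is attempted).
#' Strand-ambiguous (A/T, C/G) pairs are kept when they match
#' literally unless `drop_ambiguous = TRUE`.
#'
#' @param sumstats Data.frame with columns `CHR`, `POS`, `ID`, `EA`,
#'   `OA`, `BETA`, `P`.
#' @param variants Genotype variant map with `chrom`, `pos`, `id`,
#'   `ref`, `alt`; the ALT allele is the counted dosage allele.
#' @param drop_ambiguous Drop A/T and C/G allele pairs outright.
#' @return A data.frame (one row per matched variant) with columns
#'   `chrom`, `pos`, `id`, `ea`, `oa`, `beta`, `pvalue`, `col_index`
#'   (column in the dosage matrix) and `flipped`; dropped records are
#'   recorded in the `dropped` attribute with their reason.
#' @export
harmonize_sumstats <- function(sumstats, variants,
                               drop_ambiguous = FALSE) {
  key_s <- paste(strip_chr(sumstats$CHR), sumstats$POS)
  key_g <- paste(strip_chr(variants$chrom), variants$pos)
  if (anyDuplicated(key_s)) stop("duplicate (chrom, pos) in summary statistics",
                                 call. = FALSE)
  if (anyDuplicated(key_g)) stop("duplicate (chrom, pos) in genotype variants",
                                 call. = FALSE)
  gi <- match(key_s, key_g)
  matched <- !is.na(gi)
  out <- data.frame(chrom = variants$chrom[gi],
                    pos = variants$pos[gi],
                    id = variants$id[gi],
                    ea = sumstats$EA, oa = sumstats$OA,
                    beta = sumstats$BETA, pvalue = sumstats$P,
                    col_index = gi, flipped = FALSE,
                    stringsAsFactors = FALSE)
  ref <- variants$ref[gi]; alt <- variants$alt[gi]
  same <- matched & out$ea == alt & out$oa == ref
  swap <- matched & out$ea == ref & out$oa == alt
  ambiguous <- is_complement_pair(sumstats$EA, sumstats$OA)
  keep <- (same | swap) & !(drop_ambiguous & ambiguous)
  reason <- rep(NA_character_, nrow(sumstats))
  reason[!matched] <- "unmatched_position"
  reason[matched & !(same | swap)] <- "allele_mismatch"
  reason[drop_ambiguous & ambiguous & is.na(reason)] <-
    "strand_ambiguous"
  out$beta[swap] <- -out$beta[swap]
  out$ea[swap] <- alt[swap]
  out$oa[swap] <- ref[swap]
  out$flipped <- swap
  dropped <- data.frame(ID = sumstats$ID[!keep],
                        reason = reason[!keep],
                        stringsAsFactors = FALSE)
  if (nrow(dropped))
    message(sprintf("harmonization dropped %d of %d records",
                    nrow(dropped), nrow(sumstats)))
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Map each variant to its nearest gene
#'
#' Positional mapping: distance 0 when the position falls inside a
#' gene interval, otherwise the distance to the nearer interval end.
#' The same-chromosome gene minimizing the distance is returned, with
#' ties broken by smaller gene start and then lexicographic gene id.
#'
#' @param variants Data.frame with `chrom` and `pos`.
#' @param annotation Gene intervals with `gene_id`, `chrom`, `start`,
#'   `end` (1-based inclusive).
#' @param max_distance Optional cap in bp; variants farther than this
#'   from every gene are left unmapped.
#' @return `variants` with added columns `gene_id` and
#'   `gene_distance` (`NA` when unmapped).
#' @export
map_nearest_gene <- function(variants, annotation, max_distance = Inf) {
  gene_id <- rep(NA_character_, nrow(variants))
  gene_dist <- rep(NA_real_, nrow(variants))
  ann <- annotation[order(annotation$chrom, annotation$start,
                          annotation$gene_id), , drop = FALSE]
  for (ch in unique(variants$chrom)) {
    vi <- which(variants$chrom == ch)
    gs <- ann[ann$chrom == ch, , drop = FALSE]
    if (nrow(gs) == 0L) next
    pos <- variants$pos[vi]
    ## distance matrix variants x genes; 0 inside the interval
    d <- pmax(outer(gs$start, pos, function(s, p) s - p),
              outer(gs$end, pos, function(e, p) p - e), 0)
    best <- apply(d, 2L, which.min)   # first minimum = smallest start
    bd <- d[cbind(best, seq_along(vi))]
    ok <- bd <= max_distance
    gene_id[vi[ok]] <- gs$gene_id[best[ok]]
    gene_dist[vi[ok]] <- bd[ok]
  }
  n_un <- sum(is.na(gene_id))
  if (n_un)
    message(sprintf("%d variant(s) left unmapped (no gene in range)",
                    n_un))
  variants$gene_id <- gene_id
  variants$gene_distance <- gene_dist
  variants
}

#' Replace positional gene mapping with a supplied SNP-to-gene table
#'
#' Supports sensitivity analyses that map variants to genes from
#' external information (for example eQTL-based assignments).  The
#' table replaces any existing mapping; variants absent from the table
#' become unmapped.
#'
#' @param variants Data.frame with `id` (or `chrom` + `pos`).
#' @param table Data.frame with `gene_id` and either `id` or
#'   `chrom` + `pos` keys.
#' @return `variants` with `gene_id` replaced (`gene_distance` set to
#'   `NA`).
#' @export
apply_snp_gene_table <- function(variants, table) {
  if (!"gene_id" %in% names(table))
    stop("table must have a gene_id column", call. = FALSE)
  if ("id" %in% names(table) && "id" %in% names(variants)) {
    idx <- match(variants$id, table$id)
  } else if (all(c("chrom", "pos") %in% names(table))) {
    idx <- match(paste(strip_chr(variants$chrom), variants$pos),
                 paste(strip_chr(table$chrom), table$pos))
  } else {
    stop("table must be keyed by `id` or by `chrom` + `pos`",
         call. = FALSE)
  }
  variants$gene_id <- table$gene_id[idx]
  variants$gene_distance <- NA_real_
  variants
}

parse_region <- function(region) {
  m <- regmatches(region,
                  regexec("^(chr[0-9XY]+|[0-9XY]+):([0-9]+)-([0-9]+)$",
                          region))[[1]]
  if (length(m) != 4L) stop("region must look like 'chr19:44905796-44909393'",
                            call. = FALSE)
  list(chrom = m[2], start = as.numeric(m[3]), end = as.numeric(m[4]))
}

#' Mask the APOE region
#'
#' Removes variants inside the APOE gene region (default GRCh38
#' chr19:44905796-44909393) extended by `flank` bp on both sides, with
#' inclusive boundaries.
#'
#' @param variants Data.frame with `chrom` and `pos`.
#' @param region Region string `chrom:start-end` (1-based inclusive).
#' @param flank Flank in bp added up- and downstream (default 1 Mb).
#' @return A list with `retained` and `dropped` subsets of `variants`
#'   and `n_dropped`.
#' @export
apoe_mask <- function(variants, region = "chr19:44905796-44909393",
                      flank = 1e6) {
  r <- parse_region(region)
  inside <- strip_chr(variants$chrom) == strip_chr(r$chrom) &
    variants$pos >= r$start - flank & variants$pos <= r$end + flank
  list(retained = variants[!inside, , drop = FALSE],
       dropped = variants[inside, , drop = FALSE],
       n_dropped = sum(inside))
}
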