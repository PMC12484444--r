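#' Write a dosage VCF
#'
#' Minimal VCFv4.2 writer carrying the effect-allele dosage in the
#' `DS` FORMAT field (and hard-called `GT` when dosages are integral).
#'
#' @param genotypes A `cellprs_genotypes` object (or list with
#'   `dosage` and `map`).
#' @param path Output path (plain text).
#' @return `path`, invisibly.
#' @export
write_dosage_vcf <- function(genotypes, path) {
  dos <- genotypes$dosage
  map <- genotypes$map
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage of ALT allele\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", rownames(dos)),
                     collapse = "\t")), con)
  gt_map <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  for (j in seq_len(ncol(dos))) {
    d <- dos[, j]
    gt <- ifelse(is.na(d), "./.",
                 gt_map[as.character(round(d))])
    gt[is.na(gt)] <- "./."
    ds <- ifelse(is.na(d), ".", format(d, trim = TRUE))
    writeLines(paste(c(map$chrom[j], map$pos[j], map$id[j], map$ref[j],
                       map$alt[j], ".", "PASS", ".", "GT:DS",
                       paste0(gt, ":", ds)), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read dosages from a VCF
#'
#' Uses the `DS` FORMAT field when present, otherwise counts ALT
#' alleles from `GT`.  Requires the `vcfR` package.
#'
#' @param path VCF file path.
#' @return A `cellprs_genotypes` list with `dosage` and `map`.
#' @export
read_dosage_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package", call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- v@fix
  has_ds <- any(grepl("DS", v@gt[, "FORMAT"]))
  if (has_ds) {
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    ds <- matrix(vapply(gsub("[|]", "/", gt), function(g) {
      if (is.na(g) || g == "./.") return(NA_real_)
      sum(as.integer(strsplit(g, "/")[[1]]))
    }, numeric(1)), nrow = nrow(gt), dimnames = dimnames(gt))
  }
  dosage <- t(ds)
  map <- data.frame(chrom = fx[, "CHROM"],
                    pos = as.integer(fx[, "POS"]),
                    id = fx[, "ID"], ref = fx[, "REF"],
                    alt = fx[, "ALT"], stringsAsFactors = FALSE)
  colnames(dosage) <- map$id
  structure(list(dosage = dosage, map = map, n = nrow(dosage)),
            class = "cellprs_genotypes")
}

#' Write gene annotation as GTF
#'
#' Emits one `gene` feature per interval (1-based inclusive, GTF
#' convention).
#'
#' @param annotation Data.frame with `gene_id`, `chrom`, `start`,
#'   `end`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_gtf <- function(annotation, path) {
  lines <- sprintf(
    "%s\tcellprs\tgene\t%d\t%d\t.\t+\t.\tgene_id \"%s\"; gene_name \"%s\";",
    annotation$chrom, annotation$start, annotation$end,
    annotation$gene_id, annotation$gene_id)
  writeLines(lines, path)
  invisible(path)
}

#' Read gene intervals from GTF or BED
#'
#' GTF files are read with `rtracklayer` (keeping `gene` features when
#' a feature type column is present); 4-column BED input is converted
#' from half-open 0-based to 1-based inclusive coordinates.
#'
#' @param path File path ending in `.gtf` or `.bed`.
#' @return Data.frame with `gene_id`, `chrom`, `start`, `end`.
#' @export
read_gene_annotation <- function(path) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    b <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
    return(data.frame(gene_id = b[[4]], chrom = b[[1]],
                      start = b[[2]] + 1L, end = b[[3]],
                      stringsAsFactors = FALSE))
  }
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading GTF requires the rtracklayer package", call. = FALSE)
  g <- as.data.frame(rtracklayer::import(path, format = "gtf"))
  if ("type" %in% names(g)) g <- g[as.character(g$type) == "gene", ]
  data.frame(gene_id = g$gene_id, chrom = as.character(g$seqnames),
             start = g$start, end = g$end, stringsAsFactors = FALSE)
}

#' Write single-cell counts as MatrixMarket sidecar trio
#'
#' Writes `matrix.mtx` (genes x cells, MatrixMarket), `genes.tsv`,
#' `barcodes.tsv` and `cell_meta.tsv` under `dir`.
#'
#' @param expression List with `counts` (cell x gene) and `cell_meta`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_counts_mtx <- function(expression, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- Matrix::Matrix(t(expression$counts), sparse = TRUE)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(rownames(m), file.path(dir, "genes.tsv"))
  writeLines(colnames(m), file.path(dir, "barcodes.tsv"))
  utils::write.table(expression$cell_meta,
                     file.path(dir, "cell_meta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read single-cell counts from a MatrixMarket directory
#'
#' @param dir Directory holding `matrix.mtx`, `genes.tsv`,
#'   `barcodes.tsv` and optionally `cell_meta.tsv`.
#' @return List with `counts` (cell x gene matrix) and `cell_meta`.
#' @export
read_counts_mtx <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  genes <- readLines(file.path(dir, "genes.tsv"))
  cells <- readLines(file.path(dir, "barcodes.tsv"))
  counts <- t(as.matrix(m))
  dimnames(counts) <- list(cells, genes)
  meta_path <- file.path(dir, "cell_meta.tsv")
  meta <- if (file.exists(meta_path))
    utils::read.table(meta_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  else data.frame(barcode = cells, cell_type = NA_character_)
  list(counts = counts, cell_meta = meta)
}

#' Write/read GWAS summary statistics TSV
#'
#' Column layout: `CHR`, `POS`, `ID`, `EA`, `OA`, `BETA`, `P`.
#'
#' @param sumstats Summary-statistic data.frame.
#' @param path File path.
#' @return `path` (writer) or the data.frame (reader).
#' @export
write_sumstats <- function(sumstats, path) {
  utils::write.table(sumstats[, c("CHR", "POS", "ID", "EA", "OA",
                                  "BETA", "P")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE,
                    colClasses = c(CHR = "character", EA = "character",
                                   OA = "character"))
}

#' Write the cell-weight matrix as TSV
#'
#' One row per gene, one column per cell type, a `# semantics:` header
#' comment recording the averaging convention.
#'
#' @param weights A `cell_weight_matrix`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_weights <- function(weights, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# semantics: %s",
                     attr(weights, "semantics") %||% "unspecified"), con)
  df <- data.frame(gene = rownames(weights),
                   as.data.frame(unclass(weights)[, , drop = FALSE]),
                   check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a cell-weight matrix TSV
#'
#' @param path File written by [write_weights()].
#' @return A `cell_weight_matrix`.
#' @export
read_weights <- function(path) {
  first <- readLines(path, n = 1)
  sem <- sub("^# semantics: *", "", first)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  w <- as.matrix(df[, -1, drop = FALSE])
  rownames(w) <- df[[1]]
  structure(w, absent_genes = character(0),
            cell_types = colnames(w),
            semantics = if (grepl("^#", first)) sem else NULL,
            class = c("cell_weight_matrix", class(w)))
}

#' Write a full synthetic cohort to disk
#'
#' Emits the generator's outputs in standard formats: dosage VCF, gene
#' GTF, MatrixMarket counts trio, phenotype and longitudinal CSVs, and
#' the summary-statistics TSV.
#'
#' @param cohort A `cellprs_cohort` from [simulate_cohort()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_dosage_vcf(cohort$genotypes, file.path(dir, "genotypes.vcf"))
  write_gene_gtf(cohort$annotation, file.path(dir, "genes.gtf"))
  write_counts_mtx(cohort$expression, file.path(dir, "expression"))
  utils::write.csv(cohort$phenotypes, file.path(dir, "phenotypes.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$longitudinal,
                   file.path(dir, "longitudinal.csv"), row.names = FALSE)
  write_sumstats(cohort$sumstats, file.path(dir, "sumstats.tsv"))
  invisible(dir)
}
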