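#' Log-normalize single-cell counts
#'
#' Per-cell library-size normalization followed by a natural-log
#' transform: `log(1 + count / cell_total * scale_factor)`, the
#' LogNormalize convention with a default scale factor of 1e6.
#' Cells with zero total count are dropped with a warning (their
#' normalization is undefined).
#'
#' @param counts Cell x gene matrix of non-negative counts (dense or
#'   `Matrix` sparse).
#' @param scale_factor Positive library-size target (default `1e6`).
#' @return A cell x gene matrix of normalized values, with attribute
#'   `dropped_cells` naming any removed zero-total cells.
#' @export
log_normalize <- function(counts, scale_factor = 1e6) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (!is.numeric(scale_factor) || scale_factor <= 0)
    stop("scale_factor must be positive", call. = FALSE)
  totals <- rowSums(counts)
  dropped <- character(0)
  if (any(totals == 0)) {
    dropped <- rownames(counts)[totals == 0]
    if (is.null(dropped)) dropped <- as.character(which(totals == 0))
    warning(sprintf("dropping %d cell(s) with zero total count",
                    sum(totals == 0)))
    counts <- counts[totals > 0, , drop = FALSE]
    totals <- totals[totals > 0]
  }
  out <- log1p(counts / totals * scale_factor)
  attr(out, "dropped_cells") <- dropped
  out
}

#' Average normalized expression per cell type
#'
#' Cells labelled `"None"` are removed first.  The default semantics
#' (`"expm1_mean"`) back-transforms the log-normalized values with
#' `expm1` and averages on the normalized-count scale, matching the
#' documented behaviour of the single-cell toolkit convention this
#' package follows; `"mean_of_log"` averages the log values directly.
#'
#' @param normalized Cell x gene matrix from [log_normalize()].
#' @param cell_types Character vector of per-cell labels, aligned to
#'   the rows of `normalized`.
#' @param method Averaging semantics (see Details).
#' @param expected_types Optional character vector; an error names any
#'   expected type with zero cells.
#' @return A gene x cell-type matrix of averages, with attribute
#'   `semantics` recording the method.
#' @export
average_expression_by_type <- function(normalized, cell_types,
                                       method = c("expm1_mean",
                                                  "mean_of_log"),
                                       expected_types = NULL) {
  method <- match.arg(method)
  if (length(cell_types) != nrow(normalized))
    stop("one label per cell required", call. = FALSE)
  keep <- cell_types != "None" & !is.na(cell_types)
  normalized <- normalized[keep, , drop = FALSE]
  cell_types <- cell_types[keep]
  if (nrow(normalized) == 0L) stop("no cells left after removing 'None'",
                                   call. = FALSE)
  types <- if (is.null(expected_types)) sort(unique(cell_types))
           else expected_types
  missing <- setdiff(types, unique(cell_types))
  if (length(missing))
    stop("cell type(s) with zero cells: ", paste(missing, collapse = ", "),
         call. = FALSE)
  vals <- if (method == "expm1_mean") expm1(normalized) else normalized
  avg <- vapply(types, function(ty)
    colMeans(vals[cell_types == ty, , drop = FALSE]),
    numeric(ncol(normalized)))
  if (is.null(dim(avg))) avg <- matrix(avg, ncol = length(types))
  dimnames(avg) <- list(colnames(normalized), types)
  attr(avg, "semantics") <- method
  avg
}

#' Percentage-expression weight matrix
#'
#' Converts per-type average expression into fractional weights by
#' dividing each gene's average in a cell type by the sum of its
#' averages across all cell types.  Every emitted row sums to 1; genes
#' with zero total average expression are excluded and recorded in the
#' `absent_genes` attribute rather than emitted as `NaN`.
#'
#' @param averages Gene x cell-type matrix of non-negative averages.
#' @return A gene x cell-type matrix of class `cell_weight_matrix`
#'   with rows summing to 1, attributes `absent_genes`, `cell_types`
#'   and `semantics`.
#' @export
percentage_weights <- function(averages) {
  averages <- as.matrix(averages)
  if (any(averages < 0)) stop("averages must be non-negative",
                              call. = FALSE)
  totals <- rowSums(averages)
  absent <- rownames(averages)[totals == 0]
  if (is.null(absent)) absent <- character(0)
  w <- averages[totals > 0, , drop = FALSE] / totals[totals > 0]
  structure(w,
            absent_genes = absent,
            cell_types = colnames(averages),
            semantics = attr(averages, "semantics"),
            class = c("cell_weight_matrix", class(w)))
}

#' @export
print.cell_weight_matrix <- function(x, ...) {
  cat(sprintf("<cell_weight_matrix> %d genes x %d cell types (%d absent)\n",
              nrow(x), ncol(x), length(attr(x, "absent_genes"))))
  cat("  semantics:", attr(x, "semantics") %||% "unspecified", "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cell-type weight matrix from raw counts
#'
#' Convenience wrapper running [log_normalize()],
#' [average_expression_by_type()] and [percentage_weights()] in
#' sequence.  An optional `label_map` collapses fine-grained
#' annotation labels onto the analysis cell types before averaging
#' (labels absent from the map become `"None"` and are filtered).
#'
#' @inheritParams log_normalize
#' @inheritParams average_expression_by_type
#' @param label_map Optional named character vector mapping raw labels
#'   to analysis cell types.
#' @return A `cell_weight_matrix` (see [percentage_weights()]).
#' @export
cell_weights <- function(counts, cell_types, scale_factor = 1e6,
                         method = "expm1_mean", label_map = NULL,
                         expected_types = NULL) {
  if (!is.null(label_map)) {
    mapped <- unname(label_map[cell_types])
    mapped[is.na(mapped)] <- "None"
    cell_types <- mapped
  }
  norm <- log_normalize(counts, scale_factor)
  if (nrow(norm) != nrow(counts))
    cell_types <- cell_types[rowSums(as.matrix(counts)) > 0]
  avg <- average_expression_by_type(norm, cell_types, method = method,
                                    expected_types = expected_types)
  percentage_weights(avg)
}
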