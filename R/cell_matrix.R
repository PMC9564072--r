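#' Single-cell expression container
#'
#' A light-weight genes x cells container used by every single-cell stage of
#' the pipeline. It holds a raw `counts` layer and, as the pipeline runs,
#' gains a `lognorm` (library-size normalized, log1p) and a `scaled`
#' (per-gene z-scored) layer. Per-cell metadata carries the patient of origin
#' and the clinical stage (I--IV).
#'
#' @param counts numeric matrix, genes in rows, cells in columns; finite and
#'   non-negative. Row names are gene identifiers, column names cell
#'   identifiers (generated when missing).
#' @param cell_meta data.frame with one row per cell and at least columns
#'   `patient_id` and `stage` (values in `"I".."IV"`). A `cell_id` column is
#'   added from the matrix column names when absent.
#' @return An object of class `cell_matrix`: a list with elements `counts`,
#'   `lognorm`, `scaled`, `gene_ids`, `cell_ids`, `cell_meta`.
#' @export
cell_matrix <- function(counts, cell_meta) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) stop("counts must be numeric")
  if (any(!is.finite(counts))) stop("counts must be finite")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("gene_%04d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("cell_%05d", seq_len(ncol(counts)))
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate cell ids")
  cell_meta <- as.data.frame(cell_meta)
  if (nrow(cell_meta) == 1 && ncol(counts) > 1)
    cell_meta <- cell_meta[rep(1, ncol(counts)), , drop = FALSE]
  if (nrow(cell_meta) != ncol(counts))
    stop("cell_meta must have one row per cell")
  if (is.null(cell_meta$cell_id)) cell_meta$cell_id <- colnames(counts)
  if (is.null(cell_meta$patient_id)) stop("cell_meta needs a patient_id column")
  if (is.null(cell_meta$stage)) stop("cell_meta needs a stage column")
  if (anyNA(cell_meta$stage)) stop("stage must be present for every cell")
  structure(
    list(counts = counts, lognorm = NULL, scaled = NULL,
         gene_ids = rownames(counts), cell_ids = colnames(counts),
         cell_meta = cell_meta),
    class = "cell_matrix")
}

#' @export
print.cell_matrix <- function(x, ...) {
  cat(sprintf("cell_matrix: %d genes x %d cells (%d patients)\n",
              length(x$gene_ids), length(x$cell_ids),
              length(unique(x$cell_meta$patient_id))))
  cat("layers:", paste(c("counts",
                         if (!is.null(x$lognorm)) "lognorm",
                         if (!is.null(x$scaled)) "scaled"), collapse = ", "),
      "\n")
  invisible(x)
}

#' Subset a cell_matrix by genes and/or cells
#'
#' All present layers and the metadata are subset consistently.
#'
#' @param m a [cell_matrix()].
#' @param genes gene identifiers or indices to keep (default all).
#' @param cells cell identifiers or indices to keep (default all).
#' @return A `cell_matrix` restricted to the requested genes and cells.
#' @export
subset_cells <- function(m, genes = NULL, cells = NULL) {
  stopifnot(inherits(m, "cell_matrix"))
  gi <- if (is.null(genes)) seq_along(m$gene_ids) else genes
  ci <- if (is.null(cells)) seq_along(m$cell_ids) else cells
  m$counts <- m$counts[gi, ci, drop = FALSE]
  if (!is.null(m$lognorm)) m$lognorm <- m$lognorm[gi, ci, drop = FALSE]
  if (!is.null(m$scaled)) m$scaled <- m$scaled[gi, ci, drop = FALSE]
  m$gene_ids <- rownames(m$counts)
  m$cell_ids <- colnames(m$counts)
  keep <- match(m$cell_ids, m$cell_meta$cell_id)
  m$cell_meta <- m$cell_meta[keep, , drop = FALSE]
  rownames(m$cell_meta) <- NULL
  m
}

# ordered clinical stages used throughout
stage_levels <- function() c("I", "II", "III", "IV")

stage_numeric <- function(stage) {
  as.integer(factor(as.character(stage), levels = stage_levels()))
}
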