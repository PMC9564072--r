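# Plain-text readers/writers for the pipeline's tabular interfaces.

#' Read a dense genes x samples expression TSV
#'
#' First column = gene id, remaining columns = samples.
#'
#' @param path TSV path.
#' @return Numeric matrix with gene row names.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write a simulated dataset bundle to plain-text files
#'
#' Writes the expression matrix (dense TSV), cell metadata, bulk matrix,
#' survival table, PPI edges, receptor-ligand pairs, drug reference tables
#' and the ground truth (JSON) into a directory, using the formats the
#' readers of this package and standard tools expect.
#'
#' @param dir output directory (created if needed).
#' @param cells a [cell_matrix()].
#' @param truth the `ground_truth`.
#' @param bulk optional [simulate_bulk_cohort()] result.
#' @param surv optional survival data.frame.
#' @param network optional [simulate_network_and_pairs()] result.
#' @param drugs optional [simulate_drug_reference()] result.
#' @return Invisibly, the directory path.
#' @export
write_sim_bundle <- function(dir, cells, truth, bulk = NULL, surv = NULL,
                             network = NULL, drugs = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wtsv <- function(x, f, row_label) {
    df <- data.frame(rownames(x), x, check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df)[1] <- row_label
    utils::write.table(df, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wtsv(cells$counts, "counts.tsv", "gene")
  utils::write.table(cells$cell_meta, file.path(dir, "cell_meta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bulk)) {
    wtsv(bulk$bulk, "bulk.tsv", "gene")
    wtsv(bulk$true_proportions, "true_proportions.tsv", "sample_id")
  }
  if (!is.null(surv))
    utils::write.table(surv, file.path(dir, "survival.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(network)) {
    utils::write.table(network$edges, file.path(dir, "edges.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(network$rl_pairs, file.path(dir, "rl_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(drugs)) {
    wtsv(drugs$cell_line_expr, "cell_line_expr.tsv", "gene")
    wtsv(drugs$response, "drug_response.tsv", "drug_id")
    utils::write.table(drugs$drug_targets, file.path(dir, "drug_targets.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    gt <- lapply(unclass(truth), function(x)
      if (is.null(names(x))) x else as.list(x))
    jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
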