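# Cluster markers, PPI subnetworks, branch-trend filtering, drug-target
# mapping, ridge sensitivity prediction and the two screening rules.

#' Cluster marker genes by AUROC and rank-sum test
#'
#' For every gene and cluster, computes the AUROC of expression separating
#' the cluster from the rest (equivalent to the scaled Mann-Whitney U
#' statistic) and a one-sided Wilcoxon rank-sum p-value (cluster > rest).
#' Markers must pass `auroc > auroc_min`, `p < p_max` and, as a surrogate
#' for manual curation, have a cluster mean above the overall mean.
#'
#' @param m a [cell_matrix()] with a `lognorm` layer.
#' @param clusters per-cell cluster labels.
#' @param auroc_min AUROC threshold (default 0.8, exclusive).
#' @param p_max p-value threshold (default 0.01).
#' @return data.frame `gene`, `cluster`, `auroc`, `p` of passing markers,
#'   sorted by cluster then decreasing AUROC.
#' @export
find_cluster_markers <- function(m, clusters, auroc_min = 0.8, p_max = 0.01) {
  stopifnot(inherits(m, "cell_matrix"))
  if (is.null(m$lognorm)) stop("find_cluster_markers needs the lognorm layer")
  if (is.list(clusters)) clusters <- clusters$labels
  clusters <- clusters[m$cell_ids]
  E <- m$lognorm
  overall <- rowMeans(E)
  R <- t(apply(E, 1, rank))
  out <- lapply(sort(unique(clusters)), function(k) {
    ink <- clusters == k
    n1 <- sum(ink); n2 <- sum(!ink)
    if (n1 == 0 || n2 == 0) return(NULL)
    r1 <- rowSums(R[, ink, drop = FALSE])
    u <- r1 - n1 * (n1 + 1) / 2
    auroc <- u / (n1 * n2)
    p <- wilcox_p_rows(E, ink, alternative = "greater")
    mean_in <- rowMeans(E[, ink, drop = FALSE])
    pass <- auroc > auroc_min & p < p_max & mean_in > overall
    if (!any(pass)) return(NULL)
    data.frame(gene = rownames(E)[pass], cluster = k, auroc = auroc[pass],
               p = p[pass], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    return(data.frame(gene = character(0), cluster = integer(0),
                      auroc = numeric(0), p = numeric(0)))
  rownames(out) <- NULL
  out[order(out$cluster, -out$auroc), ]
}

#' Induced PPI subnetwork on a gene list
#'
#' Builds the undirected subgraph induced by `genes` from an edge list,
#' dropping duplicate edges and self-loops (with a warning) and retaining
#' genes with no surviving edges as isolated nodes.
#'
#' @param genes character vector of node genes.
#' @param edges data.frame with columns `gene_a`, `gene_b` (and optionally
#'   `score`; rows below `score_min` are ignored).
#' @param score_min optional minimum edge score (default none).
#' @return An `igraph` graph on `genes`, with an `isolated` attribute listing
#'   nodes with degree zero.
#' @export
build_ppi_subnetwork <- function(genes, edges, score_min = NULL) {
  genes <- unique(genes)
  e <- edges
  if (!is.null(score_min) && !is.null(e$score))
    e <- e[e$score >= score_min, , drop = FALSE]
  e <- e[e$gene_a %in% genes & e$gene_b %in% genes, , drop = FALSE]
  self <- e$gene_a == e$gene_b
  key <- apply(cbind(pmin(e$gene_a, e$gene_b), pmax(e$gene_a, e$gene_b)),
               1, paste, collapse = "|")
  dup <- duplicated(key)
  if (any(self) || any(dup & !self))
    warning(sprintf("dropped %d self-loop(s) and %d duplicate edge(s)",
                    sum(self), sum(dup & !self)))
  e <- e[!self & !dup, , drop = FALSE]
  g <- igraph::graph_from_data_frame(e[, c("gene_a", "gene_b")],
                                     directed = FALSE,
                                     vertices = data.frame(name = genes))
  igraph::graph_attr(g, "isolated") <- genes[igraph::degree(g)[genes] == 0]
  g
}

#' Filter genes by opposite expression trends on the two paths
#'
#' Keeps genes significantly up-regulated along pseudo-time within Path II
#' and down-regulated within Path I: Spearman correlation of expression with
#' pseudo-time must satisfy `rho >= rho_min` (Path II) and `rho <= -rho_min`
#' (Path I), each with `p < p_max`.
#'
#' @param genes candidate gene ids.
#' @param m a [cell_matrix()] with `lognorm`.
#' @param traj a `trajectory` with both paths.
#' @param rho_min minimum absolute Spearman correlation (default 0.2).
#' @param p_max per-path p-value threshold (default 0.05).
#' @return data.frame `gene`, `rho_path1`, `p_path1`, `rho_path2`,
#'   `p_path2`, `keep`; the retained genes are `gene[keep]`.
#' @export
branch_trend_filter <- function(genes, m, traj, rho_min = 0.2, p_max = 0.05) {
  stopifnot(inherits(m, "cell_matrix"), inherits(traj, "trajectory"))
  br <- traj$branch[m$cell_ids]
  pt <- traj$pseudotime[m$cell_ids]
  i1 <- br == "PATH_I"; i2 <- br == "PATH_II"
  if (!any(i1) || !any(i2)) stop("both paths need cells for the trend filter")
  genes <- intersect(genes, m$gene_ids)
  spearman <- function(x, t) {
    if (stats::sd(x) == 0) return(c(rho = 0, p = 1))
    ct <- suppressWarnings(stats::cor.test(x, t, method = "spearman"))
    c(rho = unname(ct$estimate), p = ct$p.value)
  }
  res <- t(vapply(genes, function(g) {
    a <- spearman(m$lognorm[g, i1], pt[i1])
    b <- spearman(m$lognorm[g, i2], pt[i2])
    c(a, b)
  }, numeric(4)))
  out <- data.frame(gene = genes, rho_path1 = res[, 1], p_path1 = res[, 2],
                    rho_path2 = res[, 3], p_path2 = res[, 4],
                    stringsAsFactors = FALSE)
  out$keep <- out$rho_path2 >= rho_min & out$p_path2 < p_max &
    out$rho_path1 <= -rho_min & out$p_path1 < p_max
  rownames(out) <- NULL
  out
}

#' Map target genes to candidate drugs
#'
#' Inner-joins a target gene list with a drug-target table and ranks drugs
#' by their number of matched targets (multi-target drugs first).
#'
#' @param targets character vector of target genes.
#' @param table data.frame with `drug_id` (and optionally `drug_name`) and
#'   `target_gene`.
#' @return data.frame `drug_id`, `drug_name`, `n_targets`, `targets`
#'   (comma-separated), ordered by decreasing `n_targets`.
#' @export
map_drugs <- function(targets, table) {
  hit <- table[table$target_gene %in% targets, , drop = FALSE]
  if (nrow(hit) == 0)
    return(data.frame(drug_id = character(0), drug_name = character(0),
                      n_targets = integer(0), targets = character(0)))
  if (is.null(hit$drug_name)) hit$drug_name <- hit$drug_id
  sp <- split(hit$target_gene, hit$drug_id)
  nm <- vapply(split(hit$drug_name, hit$drug_id), `[`, character(1), 1)
  out <- data.frame(drug_id = names(sp), drug_name = nm,
                    n_targets = vapply(sp, function(x) length(unique(x)),
                                       integer(1)),
                    targets = vapply(sp, function(x)
                      paste(sort(unique(x)), collapse = ","), character(1)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(-out$n_targets, out$drug_id), ]
}

# ridge with intercept on standardized predictors, penalty chosen by GCV
.ridge_gcv <- function(X, y, lambda_grid) {
  n <- nrow(X)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  sv <- svd(Xc)
  d2 <- sv$d^2
  uty <- crossprod(sv$u, yc)
  best <- NULL; best_gcv <- Inf
  for (lam in lambda_grid) {
    shrink <- sv$d / (d2 + lam)
    beta <- sv$v %*% (shrink * uty)
    fitted <- Xc %*% beta
    df_eff <- sum(d2 / (d2 + lam)) + 1
    rss <- sum((yc - fitted)^2)
    gcv <- n * rss / (n - df_eff)^2
    if (gcv < best_gcv) {
      best_gcv <- gcv
      best <- list(beta = beta, lambda = lam)
    }
  }
  best$intercept <- mean(y) - sum(colMeans(X) * best$beta)
  best
}

#' Predict per-cell drug sensitivity from a cell-line reference
#'
#' For each drug, fits a ridge regression of the reference response (log
#' fold-change of viability; negative = sensitive) on the standardized
#' shared-gene expression of the reference cell lines, choosing the penalty
#' by generalized cross-validation over a fixed grid, then predicts a
#' sensitivity for every single cell. Cluster sensitivities are the mean
#' over member cells, path sensitivities the mean over cells of clusters
#' assigned (by majority cell branch) to each path, and the overall mean is
#' the plain (cell-count-weighted) mean over all cells.
#'
#' @param reference_expr genes x cell-lines expression matrix.
#' @param reference_response drugs x cell-lines response matrix (rows named
#'   by drug); drugs with fewer than 3 usable observations are skipped with
#'   a warning.
#' @param m a [cell_matrix()] with a `lognorm` layer.
#' @param clusters per-cell cluster labels.
#' @param traj optional `trajectory` for the per-path means.
#' @param lambda_grid ridge penalty grid (default `10^seq(-3, 3, 0.5)`).
#' @return A list of class `drug_screen`: `per_cell` (drugs x cells),
#'   `per_cluster` (drugs x clusters mean logFC), `overall`, `pathI_mean`,
#'   `pathII_mean` (NA without `traj`), `cluster_path` (the cluster-to-path
#'   assignment) and `lambda` (chosen penalty per drug).
#' @export
predict_sensitivity <- function(reference_expr, reference_response, m,
                                clusters, traj = NULL,
                                lambda_grid = 10^seq(-3, 3, by = 0.5)) {
  stopifnot(inherits(m, "cell_matrix"))
  if (is.null(m$lognorm)) stop("predict_sensitivity needs the lognorm layer")
  if (is.list(clusters)) clusters <- clusters$labels
  clusters <- clusters[m$cell_ids]
  shared <- intersect(rownames(reference_expr), m$gene_ids)
  if (length(shared) < 10)
    stop("fewer than 10 genes shared between reference and single-cell matrix")
  Xr <- t(reference_expr[shared, , drop = FALSE])   # lines x genes
  sds <- apply(Xr, 2, stats::sd)
  usable <- sds > 0
  Xr <- Xr[, usable, drop = FALSE]
  shared <- shared[usable]
  mu <- colMeans(Xr); sdv <- apply(Xr, 2, stats::sd)
  Xrs <- scale(Xr, center = mu, scale = sdv)
  Xc <- scale(t(m$lognorm[shared, , drop = FALSE]), center = mu, scale = sdv)

  drugs <- rownames(reference_response)
  per_cell <- matrix(NA_real_, length(drugs), ncol(m$lognorm),
                     dimnames = list(drugs, m$cell_ids))
  lambda <- stats::setNames(rep(NA_real_, length(drugs)), drugs)
  skipped <- character(0)
  for (d in drugs) {
    y <- as.numeric(reference_response[d, colnames(reference_expr)])
    ok <- is.finite(y)
    if (sum(ok) < 3) { skipped <- c(skipped, d); next }
    fit <- .ridge_gcv(Xrs[ok, , drop = FALSE], y[ok], lambda_grid)
    lambda[d] <- fit$lambda
    per_cell[d, ] <- as.numeric(Xc %*% fit$beta) + fit$intercept
  }
  if (length(skipped))
    warning(sprintf("skipped drug(s) with < 3 reference observations: %s",
                    paste(skipped, collapse = ", ")))
  keep <- setdiff(drugs, skipped)
  per_cell <- per_cell[keep, , drop = FALSE]

  ks <- sort(unique(clusters))
  per_cluster <- vapply(ks, function(k)
    rowMeans(per_cell[, clusters == k, drop = FALSE]),
    numeric(nrow(per_cell)))
  if (is.null(dim(per_cluster)))
    per_cluster <- matrix(per_cluster, nrow = nrow(per_cell))
  colnames(per_cluster) <- ks
  rownames(per_cluster) <- keep
  overall <- rowMeans(per_cell)

  pathI <- pathII <- stats::setNames(rep(NA_real_, length(keep)), keep)
  cluster_path <- NULL
  if (!is.null(traj)) {
    br <- traj$branch[m$cell_ids]
    cluster_path <- vapply(ks, function(k) {
      tb <- table(br[clusters == k])
      names(tb)[which.max(tb)]
    }, character(1))
    names(cluster_path) <- ks
    c1 <- ks[cluster_path == "PATH_I"]
    c2 <- ks[cluster_path == "PATH_II"]
    if (length(c1))
      pathI <- rowMeans(per_cell[, clusters %in% c1, drop = FALSE])
    if (length(c2))
      pathII <- rowMeans(per_cell[, clusters %in% c2, drop = FALSE])
  }
  structure(list(per_cell = per_cell, per_cluster = per_cluster,
                 overall = overall, pathI_mean = pathI, pathII_mean = pathII,
                 cluster_path = cluster_path, lambda = lambda[keep]),
            class = "drug_screen")
}

#' Screen for trajectory-blocking drugs
#'
#' A blocking drug must satisfy both conditions: (1) the mean predicted
#' logFC over all cells is below 0, and (2) the mean logFC of the Path II
#' clusters is below that of the Path I clusters (the drug hits the
#' direct-deterioration path harder).
#'
#' @param screen a [predict_sensitivity()] result with path means.
#' @return data.frame `drug_id`, `overall`, `pathI_mean`, `pathII_mean`,
#'   `passes_blocking`.
#' @export
screen_blocking <- function(screen) {
  stopifnot(inherits(screen, "drug_screen"))
  out <- data.frame(drug_id = names(screen$overall),
                    overall = as.numeric(screen$overall),
                    pathI_mean = as.numeric(screen$pathI_mean),
                    pathII_mean = as.numeric(screen$pathII_mean),
                    stringsAsFactors = FALSE)
  out$passes_blocking <- !is.na(out$pathI_mean) & !is.na(out$pathII_mean) &
    out$overall < 0 & out$pathII_mean < out$pathI_mean
  rownames(out) <- NULL
  out
}

#' Screen for cluster-specific drugs
#'
#' A cluster-specific drug must have (1) overall mean logFC below 0 and
#' (2) mean logFC over its targeted clusters below the mean over the
#' non-targeted clusters.
#'
#' @param screen a [predict_sensitivity()] result.
#' @param targeting named list mapping drug id to the cluster ids it
#'   targets.
#' @return data.frame `drug_id`, `overall`, `target_mean`, `nontarget_mean`,
#'   `passes_specific`, `cluster_specific_for` (comma-separated target
#'   clusters for passing drugs, `""` otherwise).
#' @export
screen_cluster_specific <- function(screen, targeting) {
  stopifnot(inherits(screen, "drug_screen"))
  ks <- colnames(screen$per_cluster)
  rows <- lapply(names(screen$overall), function(d) {
    tg <- as.character(targeting[[d]])
    tg <- intersect(tg, ks)
    nt <- setdiff(ks, tg)
    tm <- if (length(tg)) mean(screen$per_cluster[d, tg]) else NA_real_
    nm <- if (length(nt)) mean(screen$per_cluster[d, nt]) else NA_real_
    pass <- !is.na(tm) && !is.na(nm) && screen$overall[[d]] < 0 && tm < nm
    data.frame(drug_id = d, overall = screen$overall[[d] ],
               target_mean = tm, nontarget_mean = nm,
               passes_specific = pass,
               cluster_specific_for = if (pass) paste(tg, collapse = ",") else "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
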