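#' Receptor-ligand interaction permutation test between cluster pairs
#'
#' For every ordered cluster pair (a, b) and every receptor-ligand pair, the
#' interaction score is the average of the ligand's mean expression in
#' cluster a and the receptor's mean expression in cluster b. The null
#' distribution is obtained by permuting the cluster labels of the cells
#' `n_perm` times; the p-value uses the add-one convention
#' `(1 + #(null >= observed)) / (n_perm + 1)`, so it can never be zero.
#' Pairs with `p < 0.05` and score > 0 are flagged significant, and the
#' interaction count matrix aggregates significant pairs over both
#' directions of each cluster pair (set `aggregate_directions = FALSE` for a
#' directed count matrix).
#'
#' @param m a [cell_matrix()] with a `lognorm` layer.
#' @param clusters per-cell cluster labels (named vector or
#'   [cluster_cells()] result).
#' @param pairs data.frame with columns `ligand` and `receptor`; pairs whose
#'   genes are absent from `m` are skipped with a warning.
#' @param use_clusters optional subset of clusters to test (default all).
#' @param n_perm number of label permutations (default 2000, minimum 100).
#' @param seed integer seed for the permutations.
#' @param alpha significance level for the count matrix (default 0.05).
#' @param aggregate_directions sum both directions into one undirected count
#'   per cluster pair (default TRUE).
#' @return A list with `results` (data.frame: `cluster_a`, `cluster_b`,
#'   `ligand`, `receptor`, `mean_score`, `p`, `significant`) and
#'   `count_matrix` (clusters x clusters integer matrix).
#' @export
score_interactions <- function(m, clusters, pairs, use_clusters = NULL,
                               n_perm = 2000, seed = 1L, alpha = 0.05,
                               aggregate_directions = TRUE) {
  stopifnot(inherits(m, "cell_matrix"))
  if (is.null(m$lognorm)) stop("score_interactions needs the lognorm layer")
  if (n_perm < 100) stop("n_perm must be at least 100 for usable p-value resolution")
  if (is.list(clusters)) clusters <- clusters$labels
  clusters <- clusters[m$cell_ids]
  if (anyNA(clusters)) stop("clusters must label every cell")
  if (is.null(use_clusters)) use_clusters <- sort(unique(clusters))
  keep_cells <- clusters %in% use_clusters
  E <- m$lognorm[, keep_cells, drop = FALSE]
  lab <- factor(clusters[keep_cells], levels = use_clusters)

  ok <- pairs$ligand %in% m$gene_ids & pairs$receptor %in% m$gene_ids
  if (any(!ok))
    warning(sprintf("%d receptor-ligand pairs reference absent genes; skipped",
                    sum(!ok)))
  pairs <- pairs[ok, , drop = FALSE]
  if (nrow(pairs) == 0) stop("no receptor-ligand pairs left to test")
  genes <- unique(c(pairs$ligand, pairs$receptor))
  Eg <- E[genes, , drop = FALSE]

  cluster_means <- function(l) {
    # genes x clusters matrix of mean expression
    t(rowsum(t(Eg), l) / as.vector(table(l)))
  }
  M_obs <- cluster_means(lab)

  k <- length(use_clusters)
  cp <- expand.grid(a = seq_len(k), b = seq_len(k))
  cp <- cp[cp$a != cp$b, , drop = FALSE]
  np <- nrow(pairs)
  # observed scores: rows = (pair x cluster-pair)
  obs <- matrix(NA_real_, np, nrow(cp))
  li <- match(pairs$ligand, genes)
  ri <- match(pairs$receptor, genes)
  for (j in seq_len(nrow(cp)))
    obs[, j] <- (M_obs[li, cp$a[j]] + M_obs[ri, cp$b[j]]) / 2

  set.seed(seed)
  cnt <- matrix(0L, np, nrow(cp))
  nlab <- as.integer(lab)
  for (it in seq_len(n_perm)) {
    pl <- nlab[sample.int(length(nlab))]
    Mp <- t(rowsum(t(Eg), pl) / tabulate(pl, nbins = k))
    for (j in seq_len(nrow(cp))) {
      null_s <- (Mp[li, cp$a[j]] + Mp[ri, cp$b[j]]) / 2
      cnt[, j] <- cnt[, j] + (null_s >= obs[, j])
    }
  }
  pmat <- (1 + cnt) / (n_perm + 1)

  res <- data.frame(
    cluster_a = rep(use_clusters[cp$a], each = np),
    cluster_b = rep(use_clusters[cp$b], each = np),
    ligand = rep(pairs$ligand, nrow(cp)),
    receptor = rep(pairs$receptor, nrow(cp)),
    mean_score = as.vector(obs), p = as.vector(pmat),
    stringsAsFactors = FALSE)
  res$significant <- res$p < alpha & res$mean_score > 0

  cm <- matrix(0L, k, k, dimnames = list(use_clusters, use_clusters))
  sig <- res[res$significant, , drop = FALSE]
  if (nrow(sig)) {
    ia <- match(sig$cluster_a, use_clusters)
    ib <- match(sig$cluster_b, use_clusters)
    for (r in seq_along(ia)) cm[ia[r], ib[r]] <- cm[ia[r], ib[r]] + 1L
    if (aggregate_directions) {
      cm <- cm + t(cm)
    }
  }
  list(results = res, count_matrix = cm)
}
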