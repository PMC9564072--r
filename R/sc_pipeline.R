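#' Patient-level quality control
#'
#' Removes every cell of a patient that either contributed fewer than
#' `min_cells` cells or whose per-cell total-count distribution fails a
#' Shapiro-Wilk normality test at `normality_alpha`. Patients with very few
#' cells produce unstable, non-Gaussian expression summaries, so both
#' symptoms are screened.
#'
#' @param m a [cell_matrix()] with a counts layer.
#' @param min_cells minimum number of cells a patient must contribute
#'   (default 20).
#' @param normality_alpha significance level of the Shapiro-Wilk test on
#'   per-cell total counts (default 0.01).
#' @return A list with `cells` (the filtered `cell_matrix`) and `report`, a
#'   data.frame of removed patients with `n_cells`, `shapiro_p` and `reason`
#'   (`"low_cells"` or `"non_normal"`).
#' @export
qc_filter_patients <- function(m, min_cells = 20, normality_alpha = 0.01) {
  stopifnot(inherits(m, "cell_matrix"))
  totals <- colSums(m$counts)
  pat <- m$cell_meta$patient_id
  rows <- lapply(unique(pat), function(p) {
    tot <- totals[pat == p]
    n <- length(tot)
    if (n < min_cells)
      return(data.frame(patient_id = p, n_cells = n, shapiro_p = NA_real_,
                        reason = "low_cells", stringsAsFactors = FALSE))
    tt <- tot
    if (n > 5000) tt <- sort(tt)[round(seq(1, n, length.out = 5000))]
    sp <- if (stats::sd(tt) == 0) 0 else stats::shapiro.test(tt)$p.value
    if (sp < normality_alpha)
      return(data.frame(patient_id = p, n_cells = n, shapiro_p = sp,
                        reason = "non_normal", stringsAsFactors = FALSE))
    NULL
  })
  report <- do.call(rbind, rows)
  if (is.null(report))
    report <- data.frame(patient_id = character(0), n_cells = integer(0),
                         shapiro_p = numeric(0), reason = character(0))
  drop <- pat %in% report$patient_id
  if (all(drop))
    stop(sprintf(
      "QC removed every patient (min_cells = %d, normality_alpha = %g)",
      min_cells, normality_alpha))
  list(cells = subset_cells(m, cells = which(!drop)), report = report)
}

#' Library-size normalization and log transform
#'
#' Scales each cell's counts to a common total (`scale_factor`) and applies
#' `log(1 + x)`, storing the result as the `lognorm` layer. Gene order and
#' cell count are preserved.
#'
#' @param m a [cell_matrix()] with counts.
#' @param scale_factor target per-cell total after scaling (default 10000).
#' @return The `cell_matrix` with a `lognorm` layer added.
#' @export
normalize_log <- function(m, scale_factor = 1e4) {
  stopifnot(inherits(m, "cell_matrix"))
  totals <- colSums(m$counts)
  if (any(totals == 0)) stop("cells with zero total counts cannot be normalized")
  m$lognorm <- log1p(sweep(m$counts, 2, totals / scale_factor, "/"))
  m
}

#' Select highly variable genes
#'
#' Ranks genes by the variance of their standardized counts: each gene's
#' counts are centered at the gene mean and scaled by the Poisson expectation
#' `sqrt(mean)`, clipped at `clip`, and the variance of the clipped values is
#' the dispersion score. Genes varying more than a constant-mean count model
#' predicts score highest.
#'
#' @param m a [cell_matrix()] with counts.
#' @param n_hvg number of genes to keep (default 12000); if it exceeds the
#'   number of genes, all genes are returned with a warning.
#' @param clip clipping bound for the standardized counts (default
#'   `sqrt(n_cells)`).
#' @return Character vector of selected gene ids, ordered by decreasing
#'   dispersion score; the scores are attached as attribute `"score"`.
#' @export
select_hvg <- function(m, n_hvg = 12000, clip = NULL) {
  stopifnot(inherits(m, "cell_matrix"))
  n <- length(m$cell_ids)
  if (is.null(clip)) clip <- sqrt(n)
  if (n_hvg > length(m$gene_ids)) {
    warning("n_hvg exceeds the number of genes; using all genes")
    n_hvg <- length(m$gene_ids)
  }
  mu <- rowMeans(m$counts)
  sdv <- sqrt(pmax(mu, .Machine$double.eps))
  z <- pmin(pmax((m$counts - mu) / sdv, -clip), clip)
  score <- apply(z, 1, stats::var)
  score[mu == 0] <- 0
  ord <- order(score, decreasing = TRUE)
  sel <- m$gene_ids[ord[seq_len(n_hvg)]]
  attr(sel, "score") <- score[ord[seq_len(n_hvg)]]
  sel
}

#' Per-gene scaling (z-score) with clipping
#'
#' Standardizes every gene of the log-normalized layer to mean 0 and unit SD,
#' clipping at `+/-clip`; constant genes become all zeros. The result is
#' stored as the `scaled` layer.
#'
#' @param m a [cell_matrix()] with a `lognorm` layer (see [normalize_log()]).
#' @param clip clipping bound (default 10).
#' @return The `cell_matrix` with a `scaled` layer added.
#' @export
scale_genes <- function(m, clip = 10) {
  stopifnot(inherits(m, "cell_matrix"))
  if (is.null(m$lognorm)) stop("scale_genes needs the lognorm layer; run normalize_log first")
  mu <- rowMeans(m$lognorm)
  sdv <- apply(m$lognorm, 1, stats::sd)
  z <- (m$lognorm - mu) / ifelse(sdv == 0, 1, sdv)
  z[sdv == 0, ] <- 0
  m$scaled <- pmin(pmax(z, -clip), clip)
  m
}

#' Principal component analysis of the scaled layer
#'
#' Computes cell scores on the top principal components of the scaled
#' expression. Component orientation is made deterministic by flipping each
#' component so that its largest-magnitude gene loading is positive.
#'
#' @param m a [cell_matrix()] with a `scaled` layer.
#' @param n_components number of components (default 20, must not exceed
#'   `min(genes, cells)`).
#' @return A list with `scores` (cells x components), `rotation` (genes x
#'   components) and `explained_variance` (non-increasing component
#'   variances).
#' @export
run_pca <- function(m, n_components = 20) {
  stopifnot(inherits(m, "cell_matrix"))
  if (is.null(m$scaled)) stop("run_pca needs the scaled layer; run scale_genes first")
  x <- t(m$scaled)
  if (n_components > min(dim(x)))
    stop("n_components exceeds min(genes, cells)")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n_components)
  flip <- vapply(seq_len(n_components), function(j) {
    l <- pc$rotation[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x[, seq_len(n_components), drop = FALSE], 2, flip, "*")
  rotation <- sweep(pc$rotation[, seq_len(n_components), drop = FALSE], 2,
                    flip, "*")
  rownames(scores) <- m$cell_ids
  list(scores = scores, rotation = rotation,
       explained_variance = pc$sdev[seq_len(n_components)]^2)
}

#' Elbow rule for the number of principal components
#'
#' Returns the smallest dimension `d` such that the variance of component
#' `d + 1` falls below `drop_frac` of the first component's variance. This is
#' advisory: the pipeline default remains 20 components.
#'
#' @param explained_variance non-increasing component variances.
#' @param drop_frac relative-variance threshold (default 0.05).
#' @return The selected dimension; if no component ever drops below the
#'   threshold the full length is returned with a warning.
#' @export
elbow_select <- function(explained_variance, drop_frac = 0.05) {
  ev <- explained_variance
  if (length(ev) < 2) return(length(ev))
  rel <- ev[-1] / ev[1]
  d <- which(rel < drop_frac)[1]
  if (is.na(d)) {
    warning("no component fell below drop_frac; returning full length")
    return(length(ev))
  }
  d
}

#' Graph-based unsupervised clustering of cells
#'
#' Builds a k-nearest-neighbor graph in principal-component space (Euclidean
#' distance, undirected union of neighborhoods) and partitions it by seeded
#' modularity optimization (multi-level Louvain) at the given resolution.
#' Cluster labels are renumbered 1..K by decreasing size.
#'
#' @param scores cells x components matrix (from [run_pca()]).
#' @param k_neighbors neighborhood size (default 20; must be `< n_cells`).
#' @param resolution modularity resolution (default 0.8).
#' @param seed integer seed for the community search.
#' @return A list with `labels` (named integer vector, 1..K) and `K`.
#' @export
cluster_cells <- function(scores, k_neighbors = 20, resolution = 0.8,
                          seed = 1L) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (k_neighbors >= n) stop("k_neighbors must be smaller than the number of cells")
  d <- as.matrix(stats::dist(scores))
  nn <- t(apply(d, 1, function(r) order(r)[2:(k_neighbors + 1)]))
  edges <- cbind(rep(seq_len(n), k_neighbors), as.vector(nn))
  edges <- t(apply(edges, 1, sort))
  edges <- unique(edges)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  set.seed(seed)
  cm <- igraph::cluster_louvain(g, resolution = resolution)
  lab <- igraph::membership(cm)
  sizes <- table(lab)
  new_id <- stats::setNames(seq_along(sizes),
                            names(sort(sizes, decreasing = TRUE)))
  labels <- as.integer(new_id[as.character(lab)])
  names(labels) <- rownames(scores)
  list(labels = labels, K = max(labels))
}
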