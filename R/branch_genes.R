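# Branch-dependent expression testing at the branch point.
#
# The test follows the branch expression analysis modeling idea: cells before
# the branch are duplicated into both lineages, and for every gene a full
# model (spline in pseudo-time crossed with branch) is compared against a
# reduced model (spline only) by a likelihood-ratio test.

# build the duplicated design: PATH_I and PATH_II cells once each, PRE cells
# once per branch. Returns row indices into the cell set and branch factor.
.beam_rows <- function(branch) {
  pre <- which(branch == "PRE")
  p1 <- which(branch == "PATH_I")
  p2 <- which(branch == "PATH_II")
  idx <- c(pre, p1, pre, p2)
  br <- factor(c(rep("I", length(pre) + length(p1)),
                 rep("II", length(pre) + length(p2))), levels = c("I", "II"))
  list(idx = idx, branch = br, n_unique = length(pre) + length(p1) + length(p2))
}

#' Branch-dependent differential expression (spline likelihood-ratio test)
#'
#' For every gene, fits expression as a natural-spline function of
#' pseudo-time either shared between the two paths (reduced model) or with
#' branch-specific coefficients (full model), with pre-branch cells
#' duplicated into both lineages, and computes the likelihood-ratio
#' statistic. P-values come from the chi-squared distribution with degrees of
#' freedom equal to the parameter difference; to keep the statistic honest
#' about the information actually available, the Gaussian log-likelihood uses
#' the number of distinct cells rather than the number of (partly
#' duplicated) design rows. Q-values are Benjamini-Hochberg.
#'
#' @param m a [cell_matrix()] with a `lognorm` layer (Gaussian family) or
#'   counts (negative-binomial family). Cells must match `traj`.
#' @param traj a `trajectory` with both paths assigned.
#' @param spline_df natural-spline degrees of freedom (default 3).
#' @param family `"gaussian"` (default, on log-normalized values) or
#'   `"negative_binomial"` (on counts, slower).
#' @param genes optional subset of gene ids to test.
#' @return data.frame with `gene`, `llr`, `df`, `p`, `q`, `expressed_frac`
#'   (fraction of distinct cells with expression > 0), sorted by `q`.
#' @export
beam_test <- function(m, traj, spline_df = 3,
                      family = c("gaussian", "negative_binomial"),
                      genes = NULL) {
  stopifnot(inherits(m, "cell_matrix"), inherits(traj, "trajectory"))
  family <- match.arg(family)
  branch <- traj$branch[m$cell_ids]
  pt <- traj$pseudotime[m$cell_ids]
  if (anyNA(branch) || anyNA(pt))
    stop("trajectory does not cover every cell of the matrix")
  for (b in c("PATH_I", "PATH_II")) {
    nb <- sum(branch == b) + sum(branch == "PRE")
    if (nb < spline_df + 2)
      stop(sprintf("branch %s has too few cells (%d) for spline_df = %d",
                   b, nb, spline_df))
  }
  if (!any(branch == "PATH_II"))
    stop("trajectory has no PATH_II cells; branch test needs two paths")

  rows <- .beam_rows(branch)
  t_r <- pt[rows$idx]
  B <- splines::ns(t_r, df = spline_df)
  X_red <- stats::model.matrix(~B)
  X_full <- stats::model.matrix(~B * rows$branch)

  layer <- if (family == "gaussian") {
    if (is.null(m$lognorm)) stop("gaussian family needs the lognorm layer")
    m$lognorm
  } else m$counts
  if (is.null(genes)) genes <- m$gene_ids
  Y <- t(layer[genes, rows$idx, drop = FALSE])

  df_diff <- ncol(X_full) - ncol(X_red)
  n_eff <- rows$n_unique

  if (family == "gaussian") {
    qr_f <- qr(X_full)
    qr_r <- qr(X_red)
    rss_f <- colSums(qr.resid(qr_f, Y)^2)
    rss_r <- colSums(qr.resid(qr_r, Y)^2)
    eps <- .Machine$double.eps
    llr <- n_eff * log(pmax(rss_r, eps) / pmax(rss_f, eps))
    llr <- pmax(llr, 0)
    llr[rss_r < 1e-12 & rss_f < 1e-12] <- 0
  } else {
    if (!requireNamespace("MASS", quietly = TRUE))
      stop("the negative_binomial family requires the MASS package")
    llr <- vapply(seq_len(ncol(Y)), function(j) {
      y <- Y[, j]
      fit_f <- try(MASS::glm.nb(y ~ X_full - 1), silent = TRUE)
      fit_r <- try(MASS::glm.nb(y ~ X_red - 1), silent = TRUE)
      if (inherits(fit_f, "try-error") || inherits(fit_r, "try-error"))
        return(NA_real_)
      max(0, 2 * (as.numeric(stats::logLik(fit_f)) -
                    as.numeric(stats::logLik(fit_r))))
    }, numeric(1))
  }

  p <- stats::pchisq(llr, df = df_diff, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  expressed_frac <- rowMeans(layer[genes, , drop = FALSE] > 0)
  out <- data.frame(gene = genes, llr = llr, df = df_diff, p = p, q = q,
                    expressed_frac = expressed_frac,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$q, out$p), ]
}

#' Filter branch-test results
#'
#' Keeps genes that are both strongly branch-dependent (`q < q_max`) and
#' widely expressed (`expressed_frac > min_expressed_frac`).
#'
#' @param results a [beam_test()] data.frame.
#' @param q_max q-value cutoff (default `1e-8`).
#' @param min_expressed_frac minimum fraction of expressing cells
#'   (default 0.20, exclusive).
#' @return Character vector of retained gene ids (possibly empty).
#' @export
filter_branch_genes <- function(results, q_max = 1e-8,
                                min_expressed_frac = 0.20) {
  if (nrow(results) == 0) return(character(0))
  results$gene[results$q < q_max &
                 results$expressed_frac > min_expressed_frac]
}

#' Split branch genes into co-expression sets
#'
#' For each gene the full branch model is re-fit and evaluated on a fixed
#' pseudo-time grid for both branches; the two per-branch profiles are
#' concatenated, row-standardized, and clustered hierarchically (Ward
#' linkage on Euclidean distance) with the tree cut at `k` sets. The
#' standardized matrix is returned for heatmap display.
#'
#' @param genes gene ids (typically from [filter_branch_genes()]).
#' @param m a [cell_matrix()] with `lognorm`.
#' @param traj a `trajectory` with both paths.
#' @param k number of gene sets (default 2).
#' @param n_grid grid points per branch (default 50).
#' @param spline_df spline degrees of freedom (default 3).
#' @return A list with `gene_set` (named integer labels 1..k) and `matrix`
#'   (genes x 2*n_grid row-standardized fitted expression).
#' @export
cluster_branch_genes <- function(genes, m, traj, k = 2, n_grid = 50,
                                 spline_df = 3) {
  stopifnot(inherits(m, "cell_matrix"), inherits(traj, "trajectory"))
  if (length(genes) == 0) stop("no genes to cluster")
  branch <- traj$branch[m$cell_ids]
  pt <- traj$pseudotime[m$cell_ids]
  rows <- .beam_rows(branch)
  t_r <- pt[rows$idx]
  B <- splines::ns(t_r, df = spline_df)
  X_full <- stats::model.matrix(~B * rows$branch)
  Y <- t(m$lognorm[genes, rows$idx, drop = FALSE])
  beta <- qr.coef(qr(X_full), Y)
  beta[is.na(beta)] <- 0

  grid <- seq(min(t_r), max(t_r), length.out = n_grid)
  pred_branch <- function(br) {
    Bg <- stats::predict(B, grid)
    bf <- factor(rep(br, n_grid), levels = c("I", "II"))
    Xg <- stats::model.matrix(~Bg * bf)
    colnames(Xg) <- colnames(X_full)
    Xg %*% beta
  }
  fitted <- rbind(pred_branch("I"), pred_branch("II"))
  mat <- t(fitted)   # genes x (2*n_grid)
  mu <- rowMeans(mat)
  sdv <- apply(mat, 1, stats::sd)
  sdv[sdv == 0] <- 1
  mat <- (mat - mu) / sdv
  colnames(mat) <- c(sprintf("I_%02d", seq_len(n_grid)),
                     sprintf("II_%02d", seq_len(n_grid)))
  if (k == 1) {
    labels <- stats::setNames(rep(1L, length(genes)), genes)
  } else {
    hc <- stats::hclust(stats::dist(mat), method = "ward.D2")
    labels <- stats::setNames(stats::cutree(hc, k = k), genes)
  }
  list(gene_set = labels, matrix = mat)
}

#' Hypergeometric gene-set enrichment
#'
#' Tests each term of a collection for over-representation in a gene set
#' relative to a universe, with the upper-tail hypergeometric p-value
#' `P(X >= overlap)`. P-values are Benjamini-Hochberg adjusted, and a
#' q-value is derived from the adjusted p-values by rescaling with an
#' estimate of the null proportion (`pi0 = min(1, mean(p > 0.5) / 0.5)`).
#'
#' @param gene_set character vector of genes of interest (must be contained
#'   in `universe`).
#' @param universe background gene identifiers.
#' @param collections named list of term gene vectors (e.g. from
#'   [read_gmt()]). Terms with no overlap with the universe are skipped.
#' @param p_adjust_max,q_max reporting thresholds (default 0.05); results
#'   carry a `significant` flag rather than being dropped.
#' @return data.frame with `term`, `overlap`, `term_size`, `p`, `p_adjust`,
#'   `q`, `significant`, sorted by `p`.
#' @export
enrich <- function(gene_set, universe, collections,
                   p_adjust_max = 0.05, q_max = 0.05) {
  gene_set <- unique(gene_set)
  universe <- unique(universe)
  if (!all(gene_set %in% universe))
    stop("gene_set must be a subset of universe")
  N <- length(universe)
  n <- length(gene_set)
  rows <- lapply(names(collections), function(tm) {
    term <- intersect(collections[[tm]], universe)
    K <- length(term)
    if (K == 0) return(NULL)
    k <- length(intersect(term, gene_set))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, overlap = k, term_size = K, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(term = character(0), overlap = integer(0),
                      term_size = integer(0), p = numeric(0),
                      p_adjust = numeric(0), q = numeric(0),
                      significant = logical(0)))
  out$p_adjust <- stats::p.adjust(out$p, method = "BH")
  pi0 <- min(1, mean(out$p > 0.5) / 0.5)
  if (!is.finite(pi0) || pi0 <= 0) pi0 <- 1
  out$q <- pmin(1, out$p_adjust * pi0)
  out$significant <- out$p_adjust < p_adjust_max & out$q < q_max
  out[order(out$p), ]
}

#' Read a GMT gene-set file
#'
#' @param path path to a tab-separated GMT file (term, description,
#'   genes...).
#' @return Named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    f[-(1:2)]
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  out
}
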