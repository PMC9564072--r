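# Signature construction, bulk deconvolution, patient grouping, the
# pseudo-time score and survival analysis.

#' Build a cluster signature matrix from stage-restricted clusters
#'
#' For every cluster of `use_clusters`, genes are tested one-vs-rest (within
#' the restricted cluster set) by Wilcoxon rank-sum, and the log2 fold-change
#' of mean linear expression is computed. Genes passing `p < p_thr` and
#' `log2fc > lfc_thr` for any cluster form the signature rows; the signature
#' entries are the per-cluster mean log-expression of those genes.
#'
#' @param m a [cell_matrix()] with a `lognorm` layer.
#' @param clusters per-cell labels (named vector or [cluster_cells()]
#'   result).
#' @param use_clusters clusters that make up the stage (e.g. the stage-III
#'   cluster set); cells outside them are ignored.
#' @param p_thr,lfc_thr selection thresholds. Conventional settings are
#'   `p_thr = 0.01` with stage-III clusters and `p_thr = 1e-4` for the more
#'   heterogeneous stage-IV clusters, both with `lfc_thr = 1.5`.
#' @return A list of class `signature_matrix`: `sig` (genes x clusters mean
#'   log-expression), `selected` (data.frame gene/cluster/p/log2fc of the
#'   selecting cluster) and `thresholds`.
#' @export
build_signature <- function(m, clusters, use_clusters, p_thr = 0.01,
                            lfc_thr = 1.5) {
  stopifnot(inherits(m, "cell_matrix"))
  if (is.null(m$lognorm)) stop("build_signature needs the lognorm layer")
  if (is.list(clusters)) clusters <- clusters$labels
  clusters <- clusters[m$cell_ids]
  keep <- clusters %in% use_clusters
  if (!any(keep)) stop("no cells in the requested clusters")
  E <- m$lognorm[, keep, drop = FALSE]
  lab <- clusters[keep]
  lin <- expm1(E)

  sel <- lapply(use_clusters, function(k) {
    ink <- lab == k
    if (!any(ink) || all(ink)) return(NULL)
    p <- wilcox_p_rows(E, ink, alternative = "greater")
    lfc <- log2((rowMeans(lin[, ink, drop = FALSE]) + 1) /
                  (rowMeans(lin[, !ink, drop = FALSE]) + 1))
    pass <- p < p_thr & lfc > lfc_thr
    if (!any(pass)) return(NULL)
    data.frame(gene = rownames(E)[pass], cluster = k, p = p[pass],
               log2fc = lfc[pass], stringsAsFactors = FALSE)
  })
  sel <- do.call(rbind, sel)
  if (is.null(sel) || nrow(sel) == 0)
    stop(sprintf("no genes passed the signature thresholds (p < %g, log2fc > %g)",
                 p_thr, lfc_thr))
  genes <- unique(sel$gene)
  sig <- vapply(use_clusters, function(k)
    rowMeans(E[genes, lab == k, drop = FALSE]), numeric(length(genes)))
  colnames(sig) <- paste0("cluster_", use_clusters)
  rownames(sig) <- genes
  structure(list(sig = sig, selected = sel,
                 thresholds = c(p_thr = p_thr, lfc_thr = lfc_thr),
                 clusters = use_clusters),
            class = "signature_matrix")
}

# vectorized one-sided Wilcoxon rank-sum p-values per row (normal
# approximation with tie correction), testing group1 > group2
wilcox_p_rows <- function(E, in_group, alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  n1 <- sum(in_group); n2 <- sum(!in_group); n <- n1 + n2
  R <- t(apply(E, 1, rank))
  r1 <- rowSums(R[, in_group, drop = FALSE])
  u <- r1 - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  # tie correction per gene
  tie_term <- apply(E, 1, function(x) {
    tt <- table(x)
    sum(tt^3 - tt)
  })
  sig2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  sig2 <- pmax(sig2, .Machine$double.eps)
  z <- (u - mu - 0.5) / sqrt(sig2)   # continuity-corrected
  if (alternative == "greater")
    stats::pnorm(z, lower.tail = FALSE)
  else
    2 * stats::pnorm(abs(u - mu) / sqrt(sig2), lower.tail = FALSE)
}

#' Deconvolve bulk samples onto cluster signatures
#'
#' Estimates non-negative cluster weights per bulk sample by non-negative
#' least squares (default) or linear nu-support-vector regression with
#' negative coefficients zeroed, then renormalizes the weights to
#' proportions summing to one. Each sample gets a reconstruction Pearson
#' correlation and a permutation p-value (the null refits the sample with
#' its signature-gene values permuted); samples failing `p < 0.05` or
#' `correlation > 0.3` are flagged excluded.
#'
#' @param bulk genes x samples matrix (log-scale expression).
#' @param sig a [build_signature()] result or a plain genes x clusters
#'   matrix. At least `2 * n_clusters` signature genes must be shared with
#'   the bulk matrix.
#' @param method `"nnls"` (default) or `"nusvr"` (nu in 0.25/0.5/0.75, best
#'   by reconstruction RMSE).
#' @param n_perm permutations for the p-value (default 100; 0 skips it).
#' @param seed integer seed.
#' @param p_max,corr_min retention thresholds (defaults 0.05 and 0.3).
#' @return A list of class `deconv_result`: `P` (samples x clusters
#'   proportions, rows sum to 1), `pval`, `corr`, `excluded` (logical),
#'   `method`.
#' @export
deconvolve <- function(bulk, sig, method = c("nnls", "nusvr"), n_perm = 100,
                       seed = 1L, p_max = 0.05, corr_min = 0.3) {
  method <- match.arg(method)
  S <- if (inherits(sig, "signature_matrix")) sig$sig else as.matrix(sig)
  shared <- intersect(rownames(S), rownames(bulk))
  if (length(shared) < 2 * ncol(S))
    stop("fewer than 2 x n_clusters signature genes shared with the bulk matrix")
  S <- S[shared, , drop = FALSE]
  if (qr(S)$rank < ncol(S))
    warning("signature matrix is rank-deficient; proportions may not be unique")
  B <- bulk[shared, , drop = FALSE]

  fit_w <- function(y) {
    if (method == "nnls") {
      pracma::lsqnonneg(S, y)$x
    } else {
      best <- NULL; best_rmse <- Inf
      for (nu in c(0.25, 0.5, 0.75)) {
        fit <- e1071::svm(x = S, y = y, type = "nu-regression",
                          kernel = "linear", nu = nu, scale = FALSE)
        w <- as.vector(t(fit$coefs) %*% fit$SV)
        w[w < 0] <- 0
        rmse <- sqrt(mean((S %*% w - y)^2))
        if (rmse < best_rmse) { best <- w; best_rmse <- rmse }
      }
      best
    }
  }

  set.seed(seed)
  ns <- ncol(B)
  K <- ncol(S)
  P <- matrix(0, ns, K, dimnames = list(colnames(B), colnames(S)))
  corr <- numeric(ns); pval <- rep(NA_real_, ns)
  for (i in seq_len(ns)) {
    y <- B[, i]
    w <- fit_w(y)
    recon <- as.vector(S %*% w)
    corr[i] <- if (stats::sd(recon) == 0 || stats::sd(y) == 0) 0 else
      stats::cor(recon, y)
    if (sum(w) == 0) {
      warning(sprintf("sample %s: all-zero weights", colnames(B)[i]))
      P[i, ] <- NA_real_
    } else P[i, ] <- w / sum(w)
    if (n_perm > 0) {
      null_corr <- vapply(seq_len(n_perm), function(b) {
        yp <- y[sample.int(length(y))]
        wp <- fit_w(yp)
        rp <- as.vector(S %*% wp)
        if (stats::sd(rp) == 0) 0 else stats::cor(rp, yp)
      }, numeric(1))
      pval[i] <- (1 + sum(null_corr >= corr[i])) / (n_perm + 1)
    }
  }
  excluded <- (!is.na(pval) & pval >= p_max) | corr <= corr_min
  structure(list(P = P, pval = pval, corr = corr, excluded = excluded,
                 method = method), class = "deconv_result")
}

#' Ward hierarchical grouping of patients by cluster proportions
#'
#' Agglomerative clustering (Ward's method, `"ward.D"`, Euclidean distance)
#' of the proportion rows, cut at `k` groups.
#'
#' @param P samples x clusters proportion matrix (rows with NA are dropped).
#' @param k number of groups (default 2).
#' @return Named integer vector of group labels.
#' @export
ward_group <- function(P, k = 2) {
  P <- as.matrix(P)
  keep <- stats::complete.cases(P)
  P <- P[keep, , drop = FALSE]
  hc <- stats::hclust(stats::dist(P), method = "ward.D")
  stats::cutree(hc, k = k)
}

#' Patient pseudo-time score S = sum(P_i * T_i)
#'
#' Combines the deconvolved cluster proportions of each patient with the
#' cluster mean pseudo-times: `S = sum_i P_i * T_i`. Higher S means the
#' patient's inferred cell composition sits later on the trajectory. When
#' groups are supplied, the group score is the mean S of its members.
#'
#' @param P samples x clusters proportion matrix (a `deconv_result` is also
#'   accepted); column names `cluster_<i>` or plain cluster ids.
#' @param T_cluster named cluster pseudo-times from [cluster_pseudotime()];
#'   every cluster of `P` must be present.
#' @param groups optional named group labels per sample.
#' @return A list of class `patient_score`: `S` (named per-patient score)
#'   and `group_scores` (NULL without groups).
#' @export
pseudo_time_score <- function(P, T_cluster, groups = NULL) {
  if (inherits(P, "deconv_result")) P <- P$P
  P <- as.matrix(P)
  cl <- sub("^cluster_", "", colnames(P))
  missing <- setdiff(cl, names(T_cluster))
  if (length(missing))
    stop(sprintf("cluster(s) %s missing from the cluster pseudo-times",
                 paste(missing, collapse = ", ")))
  S <- as.vector(P %*% T_cluster[cl])
  names(S) <- rownames(P)
  gs <- NULL
  if (!is.null(groups)) {
    g <- groups[names(S)]
    gs <- tapply(S, g, mean)
  }
  structure(list(S = S, group_scores = gs), class = "patient_score")
}

#' Kaplan-Meier survival estimate per group
#'
#' Product-limit estimate of each group's survival function under right
#' censoring.
#'
#' @param surv data.frame with `time` (> 0) and `event` (0/1), one row per
#'   subject; a `sample_id` column is used to align with `groups` when
#'   `groups` is named.
#' @param groups group label per subject.
#' @return data.frame with `group`, `time`, `n_risk`, `n_event`, `surv`.
#' @export
km_estimate <- function(surv, groups) {
  groups <- .align_groups(surv, groups)
  if (any(table(groups) == 0)) stop("a group has zero subjects")
  fit <- survival::survfit(survival::Surv(surv$time, surv$event) ~ groups)
  strata <- if (is.null(fit$strata)) {
    rep(unique(as.character(groups)), length(fit$time))
  } else rep(sub("^groups=", "", names(fit$strata)), fit$strata)
  data.frame(group = strata, time = fit$time, n_risk = fit$n.risk,
             n_event = fit$n.event, surv = fit$surv,
             stringsAsFactors = FALSE)
}

#' Log-rank test between survival groups
#'
#' Standard observed-minus-expected log-rank statistic over the pooled event
#' times, with the hypergeometric variance and simultaneous handling of tied
#' events; the statistic is chi-squared with `groups - 1` degrees of
#' freedom.
#'
#' @inheritParams km_estimate
#' @return A list with `chi2`, `df`, `p`.
#' @export
log_rank_test <- function(surv, groups) {
  groups <- .align_groups(surv, groups)
  tab <- table(groups)
  if (any(tab == 0) || length(tab) < 2)
    stop("log-rank needs at least two non-empty groups")
  sd_ <- survival::survdiff(survival::Surv(surv$time, surv$event) ~ groups)
  df <- length(tab) - 1
  chi2 <- as.numeric(sd_$chisq)
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df = df, lower.tail = FALSE))
}

.align_groups <- function(surv, groups) {
  if (!is.null(names(groups)) && !is.null(surv$sample_id)) {
    g <- groups[as.character(surv$sample_id)]
    if (anyNA(g)) stop("groups do not cover every subject")
    return(g)
  }
  if (length(groups) != nrow(surv))
    stop("groups must have one label per subject")
  groups
}

#' Maximally selected log-rank cutpoint on a score
#'
#' Evaluates every distinct score value as a high/low threshold (both groups
#' at least `min_prop` of the cohort), picks the cut maximizing the log-rank
#' chi-squared statistic, and reports the groups and the raw log-rank
#' p-value at that cut. Because the cut is selected to maximize the
#' statistic, the reported p-value is selection-biased (anticonservative);
#' it is flagged as such and no multiplicity correction is applied.
#'
#' @param scores a [pseudo_time_score()] result or named numeric vector.
#' @param surv survival data.frame (`sample_id`, `time`, `event`).
#' @param min_prop minimum fraction of subjects per group (default 0.1).
#' @return A list with `cutpoint`, `groups` (named `"low"`/`"high"`),
#'   `chi2`, `p`, `selection_biased = TRUE`.
#' @export
score_cutpoint_groups <- function(scores, surv, min_prop = 0.1) {
  if (inherits(scores, "patient_score")) scores <- scores$S
  s <- scores[as.character(surv$sample_id)]
  if (anyNA(s)) stop("scores do not cover every subject")
  n <- length(s)
  cuts <- sort(unique(s))
  cuts <- cuts[-length(cuts)]               # 'high' group must be non-empty
  valid <- vapply(cuts, function(c0) {
    nh <- sum(s > c0)
    nh >= min_prop * n && (n - nh) >= min_prop * n
  }, logical(1))
  cuts <- cuts[valid]
  if (length(cuts) == 0)
    stop("no valid cutpoint: scores are constant or min_prop too large")
  stat <- vapply(cuts, function(c0) {
    g <- ifelse(s > c0, "high", "low")
    survival::survdiff(survival::Surv(surv$time, surv$event) ~ g)$chisq
  }, numeric(1))
  best <- which.max(stat)
  cut <- cuts[best]
  groups <- stats::setNames(ifelse(s > cut, "high", "low"), names(s))
  list(cutpoint = cut, groups = groups, chi2 = stat[best],
       p = stats::pchisq(stat[best], df = 1, lower.tail = FALSE),
       selection_biased = TRUE)
}
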