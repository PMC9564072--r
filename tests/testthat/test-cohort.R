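test_that("signature selection obeys its thresholds and recovers planted markers", {
  tc <- two_cluster_matrix(n_per = 40)
  counts <- tc$m$counts
  counts <- rbind(counts, flat = rep(5, ncol(counts)))
  m <- normalize_log(cell_matrix(counts, data.frame(patient_id = "p", stage = "I")))
  sig <- build_signature(m, tc$clusters, use_clusters = c(1, 2),
                         p_thr = 0.01, lfc_thr = 1.5)
  expect_true(all(c("markA", "markB") %in% rownames(sig$sig)))
  # a gene expressed identically everywhere can never be selected (lfc ~ 0)
  expect_false("flat" %in% rownames(sig$sig))
  expect_equal(colnames(sig$sig), c("cluster_1", "cluster_2"))
  # column means match direct cluster means of the kept genes
  for (k in 1:2) {
    cells <- names(tc$clusters)[tc$clusters == k]
    expect_equal(unname(sig$sig[, k]),
                 unname(rowMeans(m$lognorm[rownames(sig$sig), cells])))
  }
  expect_error(build_signature(m, tc$clusters, use_clusters = c(1, 2),
                               p_thr = 1e-30, lfc_thr = 50), "thresholds")
})

test_that("deconvolution recovers noiseless mixtures exactly and flags pure samples", {
  set.seed(12)
  S <- matrix(runif(60 * 3, 0.5, 3), nrow = 60,
              dimnames = list(paste0("g", 1:60), paste0("cluster_", 1:3)))
  w <- c(0.3, 0.7, 0)
  bulk <- cbind(s1 = as.vector(S %*% w), s2 = S[, 1])
  rownames(bulk) <- rownames(S)
  dec <- deconvolve(bulk, S, n_perm = 20, seed = 1)
  expect_equal(unname(dec$P["s1", ]), w, tolerance = 1e-6)
  expect_equal(unname(dec$P["s2", ]), c(1, 0, 0), tolerance = 1e-6)
  expect_true(all(dec$corr > 0.99))
  expect_true(all(!dec$excluded))
})

test_that("nu-SVR deconvolution approximates noiseless weights", {
  set.seed(13)
  S <- matrix(runif(80 * 3, 0.5, 3), nrow = 80,
              dimnames = list(paste0("g", 1:80), paste0("cluster_", 1:3)))
  w <- c(0.2, 0.5, 0.3)
  bulk <- cbind(s1 = as.vector(S %*% w))
  rownames(bulk) <- rownames(S)
  dec <- deconvolve(bulk, S, method = "nusvr", n_perm = 0, seed = 1)
  expect_lt(max(abs(dec$P["s1", ] - w)), 0.05)
})

test_that("deconvolution recovers noisy Dirichlet mixtures within tolerance", {
  sim <- sim_default()
  bulk <- simulate_bulk_cohort(sim$cells, sim$truth, sim$cfg)
  m <- normalize_log(sim$cells)
  sig <- build_signature(m, sim$truth$true_cluster,
                         use_clusters = sort(unique(sim$truth$true_cluster)),
                         p_thr = 0.01, lfc_thr = 1)
  dec <- deconvolve(bulk$bulk, sig, n_perm = 0, seed = 1)
  rmse <- sqrt(rowMeans((dec$P - bulk$true_proportions)^2))
  expect_lte(mean(rmse), 0.05)
  expect_equal(unname(rowSums(dec$P)), rep(1, nrow(dec$P)), tolerance = 1e-9)
})

test_that("deconvolution permutation p-values are uniform under a gene-permuted null", {
  set.seed(14)
  S <- matrix(runif(40 * 3, 0.5, 3), nrow = 40,
              dimnames = list(paste0("g", 1:40), paste0("k", 1:3)))
  # null samples: random vectors with no mixture structure
  bulk <- matrix(runif(40 * 60, 0.5, 3), nrow = 40,
                 dimnames = list(rownames(S), paste0("s", 1:60)))
  dec <- deconvolve(bulk, S, n_perm = 60, seed = 3)
  # permutation p-values are discrete, so KS ties are expected
  ks <- suppressWarnings(stats::ks.test(dec$pval, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("Ward grouping separates planted proportion archetypes", {
  set.seed(15)
  arch1 <- c(0.7, 0.1, 0.1, 0.1)   # cluster-7-dominant analogue
  arch2 <- c(0.1, 0.45, 0.05, 0.4) # two-cluster-dominant analogue
  P <- rbind(t(replicate(12, pmax(arch1 + rnorm(4, sd = 0.03), 0))),
             t(replicate(12, pmax(arch2 + rnorm(4, sd = 0.03), 0))))
  P <- P / rowSums(P)
  rownames(P) <- paste0("s", 1:24)
  g <- ward_group(P, k = 2)
  expect_equal(length(unique(g[1:12])), 1)
  expect_equal(length(unique(g[13:24])), 1)
  expect_false(g[1] == g[24])
  # k = n gives singletons; merge heights are monotone
  expect_equal(length(unique(ward_group(P, k = 24))), 24)
  hc <- stats::hclust(dist(P), method = "ward.D")
  expect_true(all(diff(hc$height) >= -1e-9))
})

test_that("the pseudo-time score is the exact proportion-weighted mean and linear in P", {
  P <- matrix(c(0.5, 0.5, 1, 0), nrow = 2, byrow = TRUE,
              dimnames = list(c("pa", "pb"), c("cluster_1", "cluster_2")))
  Tc <- c(`1` = 10, `2` = 20)
  ps <- pseudo_time_score(P, Tc)
  expect_identical(unname(ps$S), c(15, 10))
  # group scores are means of member scores
  ps2 <- pseudo_time_score(rbind(P, pc = c(0.2, 0.8)), Tc,
                           groups = c(pa = "g1", pb = "g2", pc = "g1"))
  expect_equal(unname(ps2$group_scores["g1"]), mean(c(15, 18)))
  # linearity to machine precision
  set.seed(16)
  for (i in 1:20) {
    p1 <- runif(2); p1 <- p1 / sum(p1)
    p2 <- runif(2); p2 <- p2 / sum(p2)
    a <- runif(1)
    s_mix <- pseudo_time_score(matrix(a * p1 + (1 - a) * p2, 1,
                                      dimnames = list("x", names(Tc))), Tc)$S
    s_sep <- a * sum(p1 * Tc) + (1 - a) * sum(p2 * Tc)
    expect_equal(unname(s_mix), s_sep, tolerance = 1e-12)
  }
  expect_error(pseudo_time_score(P, c(`1` = 10)), "cluster")
  # score bounded by the T range of contributing clusters
  expect_true(all(ps$S >= min(Tc) & ps$S <= max(Tc)))
})

test_that("KM estimate is 1 everywhere when no events occur", {
  surv <- data.frame(sample_id = paste0("s", 1:6),
                     time = c(5, 8, 3, 9, 4, 7), event = 0)
  km <- km_estimate(surv, rep(c("a", "b"), 3))
  expect_true(all(km$surv == 1))
  expect_error(km_estimate(surv, rep("a", 6)), NA)
})

test_that("log-rank on identical duplicated groups is exactly null", {
  base <- data.frame(sample_id = paste0("s", 1:5),
                     time = c(2, 4, 6, 8, 10), event = c(1, 1, 0, 1, 0))
  surv <- rbind(base, transform(base, sample_id = paste0("t", 1:5)))
  lr <- log_rank_test(surv, rep(c("a", "b"), each = 5))
  expect_lt(lr$chi2, 1e-9)
  expect_equal(lr$p, 1, tolerance = 1e-6)
})

test_that("log-rank chi-square matches the hand-computed O-E/V statistic", {
  surv <- data.frame(sample_id = paste0("s", 1:8),
                     time = c(1, 3, 4, 6, 7, 9, 12, 14),
                     event = c(1, 1, 0, 1, 1, 1, 0, 1))
  groups <- c("a", "a", "b", "a", "b", "b", "a", "b")
  lr <- log_rank_test(surv, groups)
  # oracle: pooled event times, hypergeometric moments
  o <- e <- v <- 0
  for (t0 in sort(unique(surv$time[surv$event == 1]))) {
    at_risk <- surv$time >= t0
    d <- sum(surv$time == t0 & surv$event == 1)
    n <- sum(at_risk)
    n1 <- sum(at_risk & groups == "a")
    d1 <- sum(surv$time == t0 & surv$event == 1 & groups == "a")
    o <- o + d1
    e <- e + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  expect_equal(lr$chi2, (o - e)^2 / v, tolerance = 1e-9)
})

test_that("cutpoint grouping finds a bimodal split and rejects constant scores", {
  set.seed(17)
  s <- c(rnorm(30, 10, 0.1), rnorm(30, 20, 0.1))
  names(s) <- paste0("s", 1:60)
  cfg <- sim_config(seed = 18, hazard_beta = 0.5, censor_rate = 0.2)
  surv <- simulate_survival(s, cfg)
  res <- score_cutpoint_groups(s, surv)
  # the chosen threshold separates the two modes exactly
  expect_true(all(res$groups[paste0("s", 1:30)] == "low"))
  expect_true(all(res$groups[paste0("s", 31:60)] == "high"))
  expect_true(res$selection_biased)
  # high group has worse survival (lower KM at end)
  km <- km_estimate(surv, res$groups)
  final <- tapply(km$surv, km$group, min)
  expect_lt(final["high"], final["low"])
  expect_error(score_cutpoint_groups(stats::setNames(rep(5, 60), names(s)), surv),
               "no valid cut")
})
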