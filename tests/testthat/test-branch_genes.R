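# small hand-made dataset with pseudotime, two paths and PRE cells; the
# log-normalized layer is set directly so each gene's branch structure is
# exactly the one constructed
beam_toy <- function(n = 30, seed = 21) {
  set.seed(seed)
  pt <- runif(n, 0, 10)
  br <- ifelse(pt < 4, "PRE", sample(c("PATH_I", "PATH_II"), n, replace = TRUE))
  e_same <- 1 + 0.3 * pt + rnorm(n, sd = 0.2)
  e_div <- e_same + ifelse(br == "PATH_II", 0.4 * pmax(0, pt - 4), 0)
  E <- rbind(flat = rnorm(n, 2, 0.2), same = e_same, div = e_div)
  colnames(E) <- sprintf("c%03d", 1:n)
  m <- cell_matrix(matrix(1, nrow(E), n, dimnames = dimnames(E)),
                   data.frame(patient_id = "p", stage = "I"))
  m$lognorm <- E
  traj <- structure(list(
    pseudotime = stats::setNames(pt, colnames(E)),
    branch = stats::setNames(br, colnames(E)),
    branch_vertex = 1L), class = "trajectory")
  list(m = m, traj = traj)
}

test_that("a gene whose values are exact copies across branches has zero likelihood ratio", {
  # mirrored construction: every path cell exists in both branches with the
  # same pseudotime and expression, so the branch terms can gain nothing
  set.seed(2)
  t_pre <- runif(10, 0, 4); t_path <- runif(10, 4, 10)
  pt <- c(t_pre, t_path, t_path)
  br <- c(rep("PRE", 10), rep("PATH_I", 10), rep("PATH_II", 10))
  y <- c(rnorm(10), rnorm(10))
  E <- rbind(copy = c(y[1:10], y[11:20], y[11:20]))
  colnames(E) <- sprintf("c%03d", seq_along(pt))
  m <- cell_matrix(matrix(1, 1, length(pt), dimnames = dimnames(E)),
                   data.frame(patient_id = "p", stage = "I"))
  m$lognorm <- E
  traj <- structure(list(pseudotime = stats::setNames(pt, colnames(E)),
                         branch = stats::setNames(br, colnames(E)),
                         branch_vertex = 1L), class = "trajectory")
  res <- beam_test(m, traj)
  expect_lt(res$llr, 1e-6)
  expect_gt(res$p, 0.999)
  # a noise-only gene is not called at stringent levels
  toy <- beam_toy()
  res_flat <- beam_test(toy$m, toy$traj, genes = "flat")
  expect_gt(res_flat$p, 0.001)
})

test_that("branch statistic equals a brute-force least-squares refit", {
  toy <- beam_toy()
  res <- beam_test(toy$m, toy$traj)
  # oracle: rebuild the duplicated design with lm() per gene
  br <- toy$traj$branch
  pre <- names(br)[br == "PRE"]
  p1 <- names(br)[br == "PATH_I"]
  p2 <- names(br)[br == "PATH_II"]
  ids <- c(pre, p1, pre, p2)
  branch <- factor(c(rep("I", length(pre) + length(p1)),
                     rep("II", length(pre) + length(p2))))
  t_r <- toy$traj$pseudotime[ids]
  n_unique <- length(c(pre, p1, p2))
  for (g in res$gene) {
    y <- toy$m$lognorm[g, ids]
    f_full <- lm(y ~ splines::ns(t_r, df = 3) * branch)
    f_red <- lm(y ~ splines::ns(t_r, df = 3))
    llr_o <- n_unique * log(sum(resid(f_red)^2) / sum(resid(f_full)^2))
    expect_equal(res$llr[res$gene == g], llr_o, tolerance = 1e-6)
  }
  expect_equal(unique(res$df), 4)
})

test_that("llr is invariant to relabeling the two paths", {
  toy <- beam_toy()
  res1 <- beam_test(toy$m, toy$traj)
  traj2 <- toy$traj
  swap <- c(PRE = "PRE", PATH_I = "PATH_II", PATH_II = "PATH_I")
  traj2$branch <- stats::setNames(swap[traj2$branch], names(traj2$branch))
  res2 <- beam_test(toy$m, traj2)
  expect_equal(res1$llr[order(res1$gene)], res2$llr[order(res2$gene)],
               tolerance = 1e-9)
})

test_that("too few cells on a branch is an error naming the branch", {
  toy <- beam_toy(n = 40)
  traj <- toy$traj
  # no PRE cells and a single PATH_II cell: branch II cannot support the fit
  keep <- c(names(traj$branch)[traj$branch == "PATH_I"],
            names(traj$branch)[traj$branch == "PATH_II"][1])
  m <- subset_cells(toy$m, cells = keep)
  traj$pseudotime <- traj$pseudotime[keep]
  traj$branch <- traj$branch[keep]
  expect_error(beam_test(m, traj), "PATH_II")
})

test_that("the branch-gene filter applies both thresholds literally", {
  res <- data.frame(gene = c("a", "b", "c", "d"),
                    llr = 1, df = 4,
                    p = c(1e-12, 1e-12, 0.2, 1e-12),
                    q = c(1e-9, 1e-9, 0.5, 1e-9),
                    expressed_frac = c(0.25, 0.10, 0.9, 0.201))
  expect_setequal(filter_branch_genes(res), c("a", "d"))
  empty <- res[0, ]
  expect_identical(filter_branch_genes(empty), character(0))
})

test_that("benjamini-hochberg q-values are monotone in p and bounded by 1", {
  toy <- beam_toy(n = 60, seed = 5)
  res <- beam_test(toy$m, toy$traj)
  ord <- order(res$p)
  expect_true(all(diff(res$q[ord]) >= -1e-12))
  expect_true(all(res$q <= 1))
})

test_that("gene-set splitting recovers two planted archetypes and standardizes rows", {
  set.seed(31)
  n <- 80
  pt <- runif(n, 0, 10)
  br <- ifelse(pt < 4, "PRE", rep_len(c("PATH_I", "PATH_II"), n))
  up2 <- 2 + ifelse(br == "PATH_II", 0.8, -0.8) * pmax(0, pt - 4)
  up1 <- 2 + ifelse(br == "PATH_I", 0.8, -0.8) * pmax(0, pt - 4)
  mk <- function(base, k) t(vapply(seq_len(k), function(i)
    rpois(n, exp(pmin(base + rnorm(n, sd = 0.05), 4))), numeric(n)))
  counts <- rbind(mk(up2, 5), mk(up1, 5))
  rownames(counts) <- c(paste0("u2_", 1:5), paste0("u1_", 1:5))
  colnames(counts) <- sprintf("c%03d", 1:n)
  m <- normalize_log(cell_matrix(counts, data.frame(patient_id = "p", stage = "I")))
  traj <- structure(list(pseudotime = stats::setNames(pt, colnames(counts)),
                         branch = stats::setNames(br, colnames(counts)),
                         branch_vertex = 1L), class = "trajectory")
  cb <- cluster_branch_genes(rownames(counts), m, traj, k = 2)
  expect_equal(length(unique(cb$gene_set[paste0("u2_", 1:5)])), 1)
  expect_equal(length(unique(cb$gene_set[paste0("u1_", 1:5)])), 1)
  expect_false(cb$gene_set[["u2_1"]] == cb$gene_set[["u1_1"]])
  expect_equal(unname(rowMeans(cb$matrix)), rep(0, 10), tolerance = 1e-9)
  expect_equal(unname(apply(cb$matrix, 1, sd)), rep(1, 10), tolerance = 1e-9)
  cb1 <- cluster_branch_genes(rownames(counts), m, traj, k = 1)
  expect_true(all(cb1$gene_set == 1))
})

test_that("hypergeometric enrichment matches exact enumeration and handles degenerate sets", {
  universe <- paste0("g", 1:20)
  term <- paste0("g", 1:5)
  gene_set <- paste0("g", c(1:4, 10))
  res <- enrich(gene_set, universe, list(T1 = term))
  # exhaustive oracle: all choose(20, 5) subsets of the universe
  combs <- utils::combn(20, length(gene_set))
  k_obs <- length(intersect(term, gene_set))
  tail_count <- sum(apply(combs, 2, function(s)
    length(intersect(paste0("g", s), term)) >= k_obs))
  expect_equal(res$p, tail_count / ncol(combs), tolerance = 1e-12)
  # disjoint set: overlap 0, p = 1 under the upper-tail convention
  res0 <- enrich(paste0("g", 10:14), universe, list(T1 = paste0("g", 1:5)))
  expect_equal(res0$overlap, 0)
  expect_equal(res0$p, 1)
  # universe == term == gene_set: no enrichment possible
  res1 <- enrich(universe, universe, list(T1 = universe))
  expect_equal(res1$p, 1)
  expect_error(enrich(c("zz"), universe, list(T1 = term)), "subset")
})

test_that("GMT round-trip feeds enrichment", {
  tf <- tempfile(fileext = ".gmt")
  writeLines(c("term1\tdesc\tg1\tg2\tg3", "term2\tdesc\tg4\tg5"), tf)
  gmt <- read_gmt(tf)
  expect_equal(gmt$term1, c("g1", "g2", "g3"))
  res <- enrich(c("g1", "g2"), paste0("g", 1:10), gmt)
  expect_equal(nrow(res), 2)
})
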