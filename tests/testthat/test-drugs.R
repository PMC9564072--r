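test_that("marker AUROC equals the brute-force U statistic and thresholds apply", {
  counts <- rbind(excl = c(8, 9, 10, 7, 0, 0, 0, 0, 0, 0, 0, 0),
                  part = c(5, 6, 1, 2, 3, 1, 0, 2, 1, 3, 2, 1),
                  flat = rep(3, 12))
  counts <- rbind(counts, pad = 30 - colSums(counts))  # equal library sizes
  colnames(counts) <- paste0("c", 1:12)
  m <- normalize_log(cell_matrix(counts, data.frame(patient_id = "p", stage = "I")))
  cl <- stats::setNames(rep(c(1, 2), c(4, 8)), colnames(counts))
  # brute-force AUROC: fraction of (in, out) pairs ranked correctly
  brute_auroc <- function(x, ink) {
    xi <- x[ink]; xo <- x[!ink]
    mean(outer(xi, xo, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  mk <- find_cluster_markers(m, cl, auroc_min = 0.8, p_max = 0.05)
  expect_true("excl" %in% mk$gene[mk$cluster == 1])
  expect_equal(mk$auroc[mk$gene == "excl"],
               brute_auroc(m$lognorm["excl", ], cl == 1))
  expect_equal(mk$auroc[mk$gene == "excl"], 1.0)
  expect_false("flat" %in% mk$gene)
})

test_that("null genes are essentially never called markers", {
  set.seed(19)
  counts <- matrix(rpois(500 * 60, 3), nrow = 500,
                   dimnames = list(paste0("g", 1:500), paste0("c", 1:60)))
  m <- normalize_log(cell_matrix(counts, data.frame(patient_id = "p", stage = "I")))
  cl <- stats::setNames(rep(1:3, each = 20), colnames(counts))
  mk <- find_cluster_markers(m, cl)
  expect_lte(nrow(mk) / (500 * 3), 0.001)
})

test_that("induced PPI subnetwork keeps isolated nodes and cleans edges", {
  edges <- data.frame(gene_a = c("a", "b", "a", "c", "x"),
                      gene_b = c("b", "a", "a", "d", "y"),
                      score = c(0.9, 0.8, 0.5, 0.7, 0.9))
  expect_warning(g <- build_ppi_subnetwork(c("a", "b", "c", "e"), edges),
                 "self-loop|duplicate")
  expect_setequal(igraph::V(g)$name, c("a", "b", "c", "e"))
  expect_equal(igraph::ecount(g), 1)            # only a-b survives
  expect_setequal(igraph::graph_attr(g, "isolated"), c("c", "e"))
  # no shared edges at all
  g0 <- build_ppi_subnetwork(c("p", "q"), edges)
  expect_equal(igraph::ecount(g0), 0)
  # induced edge count equals a brute-force pair check
  set.seed(20)
  genes <- paste0("n", 1:10)
  all_pairs <- t(combn(genes, 2))
  keep <- runif(nrow(all_pairs)) < 0.4
  big <- data.frame(gene_a = all_pairs[keep, 1], gene_b = all_pairs[keep, 2])
  sub <- paste0("n", 1:6)
  gi <- build_ppi_subnetwork(sub, big)
  brute <- sum(big$gene_a %in% sub & big$gene_b %in% sub)
  expect_equal(igraph::ecount(gi), brute)
})

test_that("branch-trend filter keeps opposite-trend genes and drops flat ones", {
  set.seed(21)
  n <- 120
  pt <- runif(n, 0, 10)
  br <- ifelse(pt < 4, "PRE", rep_len(c("PATH_I", "PATH_II"), n))
  up_in_2 <- ifelse(br == "PATH_II", pt, ifelse(br == "PATH_I", 10 - pt, 5))
  E <- rbind(trend = up_in_2, flat = rnorm(n, 2, 0.3))
  colnames(E) <- sprintf("c%03d", 1:n)
  m <- cell_matrix(matrix(1, 2, n, dimnames = dimnames(E)),
                   data.frame(patient_id = "p", stage = "I"))
  m$lognorm <- E
  traj <- structure(list(pseudotime = stats::setNames(pt, colnames(E)),
                         branch = stats::setNames(br, colnames(E))),
                    class = "trajectory")
  res <- branch_trend_filter(c("trend", "flat"), m, traj)
  expect_true(res$keep[res$gene == "trend"])
  expect_gte(res$rho_path2[res$gene == "trend"], 0.9)
  expect_lte(res$rho_path1[res$gene == "trend"], -0.9)
  expect_false(res$keep[res$gene == "flat"])
})

test_that("drug-target mapping ranks multi-target drugs first and matches a nested-loop join", {
  tab <- data.frame(drug_id = c("d1", "d1", "d2", "d3", "d3", "d3"),
                    drug_name = c("one", "one", "two", "three", "three", "three"),
                    target_gene = c("g1", "g2", "g1", "g1", "g2", "g3"))
  res <- map_drugs(c("g1", "g2", "g3"), tab)
  expect_equal(res$drug_id[1], "d3")
  expect_equal(res$n_targets, c(3, 2, 1))
  # brute-force join count
  brute <- sapply(unique(tab$drug_id), function(d) {
    n <- 0
    for (i in seq_len(nrow(tab)))
      if (tab$drug_id[i] == d && tab$target_gene[i] %in% c("g1", "g2", "g3"))
        n <- n + 1
    n
  })
  expect_equal(stats::setNames(res$n_targets, res$drug_id), brute[res$drug_id])
  expect_equal(nrow(map_drugs(character(0), tab)), 0)
})

test_that("ridge sensitivity prediction interpolates a noiseless linear response", {
  set.seed(22)
  genes <- paste0("g", 1:12)
  ref <- matrix(runif(12 * 40, 1, 5), nrow = 12,
                dimnames = list(genes, paste0("l", 1:40)))
  w <- c(-1, rep(0, 11))
  resp <- matrix(t(ref) %*% w, nrow = 1,
                 dimnames = list("dA", colnames(ref)))
  counts <- matrix(rpois(12 * 30, 8), nrow = 12,
                   dimnames = list(genes, paste0("c", 1:30)))
  m <- normalize_log(cell_matrix(counts, data.frame(patient_id = "p", stage = "I")))
  cl <- stats::setNames(rep(1:2, 15), colnames(counts))
  scr <- predict_sensitivity(ref, resp, m, cl, lambda_grid = c(1e-8))
  manual <- as.numeric(t(m$lognorm) %*% w)
  expect_equal(unname(scr$per_cell["dA", ]), manual, tolerance = 1e-6)
  # overall mean is the cell-count-weighted mean of per-cell predictions
  expect_equal(unname(scr$overall["dA"]), mean(manual))
  expect_equal(unname(scr$per_cluster["dA", "1"]),
               mean(manual[cl == 1]))
})

test_that("a response independent of expression predicts near the grand mean", {
  set.seed(23)
  genes <- paste0("g", 1:15)
  ref <- matrix(runif(15 * 50, 1, 5), nrow = 15,
                dimnames = list(genes, paste0("l", 1:50)))
  resp <- matrix(rnorm(50, 0, 0.5), nrow = 1,
                 dimnames = list("dN", colnames(ref)))
  counts <- matrix(rpois(15 * 40, 8), nrow = 15,
                   dimnames = list(genes, paste0("c", 1:40)))
  m <- normalize_log(cell_matrix(counts, data.frame(patient_id = "p", stage = "I")))
  cl <- stats::setNames(rep(1:2, 20), colnames(counts))
  scr <- predict_sensitivity(ref, resp, m, cl)
  se <- sd(resp) / sqrt(50)
  expect_lt(max(abs(scr$per_cluster["dN", ] - mean(resp))), 6 * se)
  # a drug with < 3 observations is skipped with a warning
  resp2 <- rbind(resp, dBad = c(1, 2, rep(NA, 48)))
  expect_warning(scr2 <- predict_sensitivity(ref, resp2, m, cl), "dBad")
  expect_false("dBad" %in% rownames(scr2$per_cell))
})

test_that("screening rules apply the stated conjunctions literally", {
  mk_screen <- function(overall, p1, p2, per_cluster) {
    structure(list(per_cluster = per_cluster,
                   overall = overall, pathI_mean = p1, pathII_mean = p2),
              class = "drug_screen")
  }
  pc <- matrix(c(-0.4, -0.1, 0.2, 0.1), nrow = 2, byrow = TRUE,
               dimnames = list(c("dx", "dy"), c("1", "2")))
  scr <- mk_screen(overall = c(dx = -0.3, dy = 0.2),
                   p1 = c(dx = -0.1, dy = 0.3), p2 = c(dx = -0.5, dy = 0.1),
                   per_cluster = pc)
  bl <- screen_blocking(scr)
  expect_true(bl$passes_blocking[bl$drug_id == "dx"])
  expect_false(bl$passes_blocking[bl$drug_id == "dy"])
  cs <- screen_cluster_specific(scr, list(dx = "1", dy = "1"))
  expect_true(cs$passes_specific[cs$drug_id == "dx"])
  expect_equal(cs$cluster_specific_for[cs$drug_id == "dx"], "1")
  expect_false(cs$passes_specific[cs$drug_id == "dy"])
  # pure function: identical input, identical output
  expect_identical(bl, screen_blocking(scr))
})

test_that("planted drugs from the generator pass their screens and the null drug fails", {
  pl <- pipeline_default()
  dr <- simulate_drug_reference(pl$truth, pl$cfg)
  scr <- predict_sensitivity(dr$cell_line_expr, dr$response, pl$m,
                             pl$truth$true_cluster, pl$traj)
  bl <- screen_blocking(scr)
  expect_true(bl$passes_blocking[bl$drug_id == dr$planted$blocking])
  expect_lt(scr$pathII_mean[dr$planted$blocking],
            scr$pathI_mean[dr$planted$blocking])
  cs <- screen_cluster_specific(
    scr, stats::setNames(list(as.character(dr$planted$target_cluster)),
                         dr$planted$specific))
  expect_true(cs$passes_specific[cs$drug_id == dr$planted$specific])
  # noise-free null drug: exactly zero response, fails "mean logFC < 0"
  cfg0 <- sim_config(seed = pl$cfg$seed, drug_noise_sd = 0)
  dr0 <- simulate_drug_reference(pl$truth, cfg0)
  scr0 <- predict_sensitivity(dr0$cell_line_expr, dr0$response, pl$m,
                              pl$truth$true_cluster, pl$traj)
  expect_lt(max(abs(scr0$per_cluster[dr0$planted$null, ])), 1e-8)
  bl0 <- screen_blocking(scr0)
  expect_false(bl0$passes_blocking[bl0$drug_id == dr0$planted$null])
})
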