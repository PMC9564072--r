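# Shared fixtures, memoized so expensive stages run once per test session.

fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = fixture_env))
    assign(key, force(expr), envir = fixture_env)
  get(key, envir = fixture_env)
}

# default-condition simulation used across modules
sim_default <- function() memo("sim_default", {
  cfg <- sim_config(seed = 1)
  c(simulate_single_cells(cfg), list(cfg = cfg))
})

# full single-cell pipeline (normalize -> HVG -> scale -> PCA -> cluster ->
# trajectory) on the default simulation
pipeline_default <- function() memo("pipeline_default", {
  sim <- sim_default()
  m <- normalize_log(sim$cells)
  hvg <- select_hvg(m, n_hvg = 1000)
  ms <- scale_genes(subset_cells(m, genes = hvg))
  pca <- run_pca(ms, n_components = 20)
  cl <- cluster_cells(pca$scores, seed = 1)
  pg <- learn_principal_graph(pca$scores, clusters = cl)
  traj <- suppressWarnings(root_and_order(pg, stages = ms$cell_meta$stage))
  traj <- suppressWarnings(detect_branch_and_paths(traj))
  list(m = m, ms = ms, pca = pca, cl = cl, pg = pg, traj = traj,
       truth = sim$truth, cfg = sim$cfg)
})

# small cell_matrix built by hand: two clusters with exclusive genes
two_cluster_matrix <- function(n_per = 50, seed = 42) {
  set.seed(seed)
  n <- 2 * n_per
  counts <- matrix(rpois(4 * n, 2), nrow = 4,
                   dimnames = list(c("ligA", "recB", "markA", "markB"),
                                   sprintf("c%03d", 1:n)))
  grp <- rep(1:2, each = n_per)
  counts["ligA", grp == 2] <- 0
  counts["recB", grp == 1] <- 0
  counts["markA", grp == 1] <- counts["markA", grp == 1] + 20
  counts["markB", grp == 2] <- counts["markB", grp == 2] + 20
  m <- cell_matrix(counts, data.frame(
    patient_id = "p1", stage = rep(c("I", "III"), each = n_per)))
  list(m = normalize_log(m), clusters = stats::setNames(grp, colnames(counts)))
}

# minimal trajectory object from ground truth (used to test operations
# downstream of trajectory inference in isolation)
truth_trajectory <- function(truth) {
  structure(list(pseudotime = truth$true_pseudotime,
                 branch = truth$true_branch,
                 branch_vertex = 1L),
            class = "trajectory")
}
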