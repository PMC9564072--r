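#' Configuration for the synthetic tumor-cohort generator
#'
#' Collects every tunable of the generator into one validated object. The
#' generator lays cancer cells on a Y-shaped developmental topology (a trunk
#' that splits at one branch point into two arms), draws negative-binomial
#' counts on top of it, mixes cluster profiles into noisy bulk samples,
#' simulates survival whose hazard increases with the true patient
#' pseudo-time score, and plants effective drugs and a network hub so that
#' downstream recovery can be checked against ground truth.
#'
#' @param n_genes,n_cells,n_clusters matrix dimensions and number of
#'   contiguous clusters tiling the topology (`n_clusters >= 4`: at least one
#'   trunk cluster and one per arm plus the branch neighborhood).
#' @param branch_time fraction of total pseudo-time, strictly in (0,1), at
#'   which the trunk splits.
#' @param n_marker_genes_per_cluster genes up-regulated in exactly one
#'   cluster.
#' @param n_branch_genes genes whose expression diverges between the two arms
#'   after the branch point (half up in arm II / down in arm I, half the
#'   converse).
#' @param n_time_genes genes drifting monotonically with pseudo-time on the
#'   whole topology; these give the trajectory its continuous geometry.
#' @param marker_effect,branch_effect,time_effect natural-log effect sizes:
#'   marker shift within the cluster, per-arm terminal deviation of branch
#'   genes, and total drift of time genes.
#' @param dispersion negative-binomial overdispersion (variance =
#'   mu + dispersion * mu^2); `0` gives Poisson counts.
#' @param library_size_cv coefficient of variation of per-cell library-size
#'   factors (log-normal); `0` gives equal libraries.
#' @param n_patients number of simulated patients cells are assigned to.
#' @param n_bulk_samples,dirichlet_alpha,bulk_noise_sd bulk cohort: number of
#'   samples, Dirichlet concentration of the mixing weights (use `Inf` for
#'   exactly equal weights), and SD of the Gaussian noise added on the
#'   log-expression scale.
#' @param stage_asymmetry asymmetry of clinical deterioration between the
#'   two arms, in \[0, 1): past the branch point, arm II progresses through
#'   the stages at rate `1 + stage_asymmetry` and arm I at
#'   `1 - stage_asymmetry`, so terminal arm-II cells reach stage IV directly
#'   while arm-I cells linger in stage III. Stages stay monotone in
#'   pseudo-time along every lineage.
#' @param hazard_beta effect of the centered pseudo-time score on the
#'   log-hazard of the exponential survival model.
#' @param censor_rate expected fraction of censored patients, in \[0,1\];
#'   censoring is uniform on (0, tau) with tau solved numerically.
#' @param n_cell_lines,n_drugs drug-reference dimensions.
#' @param drug_noise_sd SD of the residual noise on simulated drug response.
#' @param total_time pseudo-time span of the full trajectory (arbitrary
#'   units; the default 20 puts cluster mean pseudo-times in the range where
#'   patient scores are conventionally reported).
#' @param seed integer seed; identical configurations reproduce identical
#'   outputs.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000, n_cells = 600, n_clusters = 10,
                       branch_time = 0.4, n_marker_genes_per_cluster = 20,
                       n_branch_genes = 100, n_time_genes = 200,
                       marker_effect = 2, branch_effect = 2, time_effect = 1.5,
                       dispersion = 0.3, library_size_cv = 0.1,
                       stage_asymmetry = 0.25,
                       n_patients = 10, n_bulk_samples = 50,
                       dirichlet_alpha = 1, bulk_noise_sd = 0.2,
                       hazard_beta = 1, censor_rate = 0.3,
                       n_cell_lines = 40, n_drugs = 30, drug_noise_sd = 0.1,
                       total_time = 20, seed = 1L) {
  cfg <- list(n_genes = n_genes, n_cells = n_cells, n_clusters = n_clusters,
              branch_time = branch_time,
              n_marker_genes_per_cluster = n_marker_genes_per_cluster,
              n_branch_genes = n_branch_genes, n_time_genes = n_time_genes,
              marker_effect = marker_effect, branch_effect = branch_effect,
              time_effect = time_effect, dispersion = dispersion,
              library_size_cv = library_size_cv,
              stage_asymmetry = stage_asymmetry, n_patients = n_patients,
              n_bulk_samples = n_bulk_samples,
              dirichlet_alpha = dirichlet_alpha, bulk_noise_sd = bulk_noise_sd,
              hazard_beta = hazard_beta, censor_rate = censor_rate,
              n_cell_lines = n_cell_lines, n_drugs = n_drugs,
              drug_noise_sd = drug_noise_sd, total_time = total_time,
              seed = as.integer(seed))
  counts <- c("n_genes", "n_cells", "n_clusters", "n_patients",
              "n_bulk_samples", "n_cell_lines", "n_drugs")
  for (f in counts)
    if (length(cfg[[f]]) != 1 || cfg[[f]] < 1 || cfg[[f]] != round(cfg[[f]]))
      stop(sprintf("%s must be a positive count", f))
  if (cfg$n_clusters < 4)
    stop("n_clusters must be >= 4 (one trunk cluster and one per arm plus the branch neighborhood)")
  if (!(cfg$branch_time > 0 && cfg$branch_time < 1))
    stop("branch_time must lie strictly inside (0, 1)")
  for (f in c("dispersion", "library_size_cv", "bulk_noise_sd",
              "drug_noise_sd", "n_branch_genes", "n_time_genes",
              "n_marker_genes_per_cluster"))
    if (cfg[[f]] < 0) stop(sprintf("%s must be >= 0", f))
  if (!is.finite(cfg$hazard_beta)) stop("hazard_beta must be finite")
  if (cfg$censor_rate < 0 || cfg$censor_rate >= 1)
    stop("censor_rate must lie in [0, 1)")
  if (cfg$stage_asymmetry < 0 || cfg$stage_asymmetry >= 1)
    stop("stage_asymmetry must lie in [0, 1)")
  if (cfg$dirichlet_alpha <= 0) stop("dirichlet_alpha must be positive")
  if (cfg$total_time <= 0) stop("total_time must be positive")
  needed <- cfg$n_clusters * cfg$n_marker_genes_per_cluster +
    cfg$n_branch_genes + cfg$n_time_genes
  if (needed > cfg$n_genes)
    stop("n_genes too small for the requested marker/branch/time genes")
  class(cfg) <- "sim_config"
  cfg
}

# contiguous cluster tiling of the Y topology: trunk clusters first, then
# arm-I clusters, then arm-II clusters, each arm ordered by time
sim_cluster_layout <- function(cfg) {
  k <- cfg$n_clusters
  n_trunk <- max(1L, min(k - 2L, round(k * cfg$branch_time)))
  n_arm1 <- ceiling((k - n_trunk) / 2)
  n_arm2 <- k - n_trunk - n_arm1
  list(n_trunk = n_trunk, n_arm1 = n_arm1, n_arm2 = n_arm2)
}

# map (t, arm) to the generator's contiguous cluster id
sim_assign_cluster <- function(t_norm, arm, cfg) {
  lay <- sim_cluster_layout(cfg)
  bt <- cfg$branch_time
  cl <- integer(length(t_norm))
  pre <- arm == 0L
  cl[pre] <- pmin(lay$n_trunk,
                  1L + floor(t_norm[pre] / bt * lay$n_trunk))
  frac <- (t_norm - bt) / (1 - bt)
  a1 <- arm == 1L
  cl[a1] <- lay$n_trunk + pmin(lay$n_arm1, 1L + floor(frac[a1] * lay$n_arm1))
  a2 <- arm == 2L
  cl[a2] <- lay$n_trunk + lay$n_arm1 +
    pmin(lay$n_arm2, 1L + floor(frac[a2] * lay$n_arm2))
  cl
}

#' Simulate single cells on a branching trajectory
#'
#' Cells are placed uniformly on a Y-shaped topology: pseudo-time is uniform
#' on (0, `total_time`); cells past the branch point are assigned to one of
#' two arms with equal probability. Counts are negative-binomial with
#' log-mean = baseline + cluster-marker effect + time drift + arm-specific
#' branch effect. Clinical stages I--IV are assigned by pseudo-time quartile
#' so stage order follows developmental time, and cluster labels tile the
#' topology contiguously.
#'
#' @param config a [sim_config()].
#' @return A list with `cells` (a [cell_matrix()]) and `truth`, a
#'   `ground_truth` list exposing `true_cluster`, `true_pseudotime`,
#'   `true_branch` (`PRE`/`PATH_I`/`PATH_II`), `true_marker_genes`,
#'   `true_branch_genes` (with sign: `+1` = up in arm II / down in arm I),
#'   `true_time_genes` and the gene-effect matrix pieces needed by the other
#'   generators.
#' @export
simulate_single_cells <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_cells

  t_norm <- stats::runif(n)                      # position in (0,1)
  arm <- ifelse(t_norm < cfg$branch_time, 0L,
                sample(c(1L, 2L), n, replace = TRUE))
  pseudotime <- t_norm * cfg$total_time
  branch <- c("PRE", "PATH_I", "PATH_II")[arm + 1L]
  cluster <- sim_assign_cluster(t_norm, arm, cfg)

  # stage by quartile of clinical progression: progression equals t on the
  # trunk; past the branch, arm II deteriorates faster than arm I (the
  # direct-to-stage-IV path), keeping stage monotone in t on each lineage
  post <- pmax(0, t_norm - cfg$branch_time)
  rate <- ifelse(arm == 2L, 1 + cfg$stage_asymmetry,
                 ifelse(arm == 1L, 1 - cfg$stage_asymmetry, 1))
  progression <- pmin(1, pmin(t_norm, cfg$branch_time) + post * rate)
  qs <- stats::quantile(progression, probs = seq(0, 1, by = 0.25))
  stage <- stage_levels()[pmin(4L, findInterval(progression, qs,
                                                rightmost.closed = TRUE))]

  gene_ids <- sprintf("gene_%04d", seq_len(cfg$n_genes))
  n_mark <- cfg$n_clusters * cfg$n_marker_genes_per_cluster
  marker_idx <- if (n_mark > 0) seq_len(n_mark) else integer(0)
  branch_idx <- seq_len(cfg$n_branch_genes) + n_mark
  time_idx <- seq_len(cfg$n_time_genes) + n_mark + cfg$n_branch_genes

  marker_cluster <- rep(seq_len(cfg$n_clusters),
                        each = cfg$n_marker_genes_per_cluster)
  branch_dir <- rep_len(c(1, -1), cfg$n_branch_genes)   # +1: up in PATH_II
  time_dir <- rep_len(c(1, -1), cfg$n_time_genes)

  baseline <- stats::runif(cfg$n_genes, log(0.2), log(3))

  # log-mean per gene x cell
  logmu <- matrix(baseline, nrow = cfg$n_genes, ncol = n)
  if (n_mark > 0) {
    mc <- matrix(0, n_mark, n)
    same <- outer(marker_cluster, cluster, "==")
    mc[same] <- cfg$marker_effect
    logmu[marker_idx, ] <- logmu[marker_idx, ] + mc
  }
  if (cfg$n_time_genes > 0)
    logmu[time_idx, ] <- logmu[time_idx, ] +
      outer(time_dir * cfg$time_effect, t_norm)
  if (cfg$n_branch_genes > 0) {
    post <- pmax(0, (t_norm - cfg$branch_time) / (1 - cfg$branch_time))
    sgn <- ifelse(arm == 2L, 1, ifelse(arm == 1L, -1, 0))
    logmu[branch_idx, ] <- logmu[branch_idx, ] +
      outer(branch_dir * cfg$branch_effect, post * sgn)
  }

  libf <- if (cfg$library_size_cv > 0) {
    s2 <- log(1 + cfg$library_size_cv^2)
    exp(stats::rnorm(n, -s2 / 2, sqrt(s2)))
  } else rep(1, n)
  mu <- sweep(exp(logmu), 2, libf, "*")

  counts <- if (cfg$dispersion > 0) {
    matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / cfg$dispersion),
           nrow = cfg$n_genes)
  } else {
    matrix(stats::rpois(length(mu), lambda = mu), nrow = cfg$n_genes)
  }
  dimnames(counts) <- list(gene_ids, sprintf("cell_%05d", seq_len(n)))

  patient <- sprintf("patient_%02d", sample.int(cfg$n_patients, n,
                                                replace = TRUE))
  meta <- data.frame(cell_id = colnames(counts), patient_id = patient,
                     stage = stage, stringsAsFactors = FALSE)

  truth <- structure(list(
    true_cluster = stats::setNames(cluster, colnames(counts)),
    true_pseudotime = stats::setNames(pseudotime, colnames(counts)),
    true_branch = stats::setNames(branch, colnames(counts)),
    true_marker_genes = stats::setNames(marker_cluster,
                                        gene_ids[marker_idx]),
    true_branch_genes = stats::setNames(branch_dir, gene_ids[branch_idx]),
    true_time_genes = stats::setNames(time_dir, gene_ids[time_idx]),
    cluster_layout = sim_cluster_layout(cfg),
    baseline = stats::setNames(baseline, gene_ids)),
    class = "ground_truth")

  list(cells = cell_matrix(counts, meta), truth = truth)
}

# Dirichlet rows via gamma draws; alpha = Inf gives exactly equal weights
rdirichlet_rows <- function(n, k, alpha) {
  if (is.infinite(alpha)) return(matrix(1 / k, n, k))
  g <- matrix(stats::rgamma(n * k, shape = alpha, rate = 1), n, k)
  zero <- rowSums(g) == 0
  g[zero, ] <- 1
  g / rowSums(g)
}

#' Simulate a bulk cohort as noisy mixtures of cluster profiles
#'
#' Each bulk sample is a Dirichlet-weighted mixture of the per-cluster mean
#' log-expression profiles of the single-cell data, with Gaussian noise added
#' on the log scale. The mixing weights are recorded as ground-truth
#' proportions, each row summing to one.
#'
#' @param cells a [cell_matrix()] from [simulate_single_cells()].
#' @param truth the matching `ground_truth`.
#' @param config the [sim_config()].
#' @return A list with `bulk` (genes x samples matrix of log-scale
#'   expression), `true_proportions` (samples x clusters, rows on the
#'   simplex) and `profiles` (the genes x clusters mixture basis).
#' @export
simulate_bulk_cohort <- function(cells, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  m <- normalize_log(cells)
  cl <- truth$true_cluster[m$cell_ids]
  ks <- sort(unique(cl))
  profiles <- vapply(ks, function(k)
    rowMeans(m$lognorm[, cl == k, drop = FALSE]),
    numeric(length(m$gene_ids)))
  colnames(profiles) <- paste0("cluster_", ks)

  w <- rdirichlet_rows(config$n_bulk_samples, length(ks),
                       config$dirichlet_alpha)
  rownames(w) <- sprintf("sample_%03d", seq_len(config$n_bulk_samples))
  colnames(w) <- colnames(profiles)
  bulk <- profiles %*% t(w)
  if (config$bulk_noise_sd > 0)
    bulk <- bulk + matrix(stats::rnorm(length(bulk), 0, config$bulk_noise_sd),
                          nrow = nrow(bulk))
  bulk <- pmax(bulk, 0)
  colnames(bulk) <- rownames(w)
  list(bulk = bulk, true_proportions = w, profiles = profiles)
}

#' Simulate survival driven by a pseudo-time score
#'
#' Event times are exponential with rate `h0 * exp(beta * (S - mean(S)))`,
#' so a higher score means a proportionally higher hazard. Censoring is
#' independent uniform on (0, tau) with tau solved numerically so that the
#' expected censored fraction equals `censor_rate`.
#'
#' @param scores named numeric vector of per-patient scores (finite).
#' @param config the [sim_config()] (`hazard_beta`, `censor_rate`, `seed`).
#' @param h0 baseline hazard (per day); default gives a 500-day median at the
#'   mean score.
#' @return A data.frame (`sample_id`, `time`, `event`) with positive times
#'   and `event` 1 for observed deaths, 0 for censored.
#' @export
simulate_survival <- function(scores, config, h0 = log(2) / 500) {
  stopifnot(inherits(config, "sim_config"))
  if (any(!is.finite(scores))) stop("scores must be finite")
  if (!is.finite(config$hazard_beta)) stop("hazard_beta must be finite")
  set.seed(config$seed + 2L)
  lambda <- h0 * exp(config$hazard_beta * (scores - mean(scores)))
  t_event <- stats::rexp(length(scores), rate = lambda)
  if (config$censor_rate > 0) {
    # expected censored fraction if C ~ U(0, tau): mean over patients of
    # (1 - exp(-lambda*tau)) / (lambda*tau), decreasing in tau
    f <- function(log_tau) {
      tau <- exp(log_tau)
      mean((1 - exp(-lambda * tau)) / (lambda * tau)) - config$censor_rate
    }
    log_tau <- stats::uniroot(f, c(log(1e-4 / h0), log(1e4 / h0)),
                              extendInt = "downX")$root
    cens <- stats::runif(length(scores), 0, exp(log_tau))
    time <- pmin(t_event, cens)
    event <- as.integer(t_event <= cens)
  } else {
    time <- t_event
    event <- rep(1L, length(scores))
  }
  data.frame(sample_id = if (is.null(names(scores)))
    sprintf("sample_%03d", seq_along(scores)) else names(scores),
    time = pmax(time, .Machine$double.eps), event = event,
    stringsAsFactors = FALSE)
}

#' Simulate a drug-sensitivity reference with planted effective drugs
#'
#' Generates cell-line log-expression, a drug x cell-line response table of
#' viability log fold-changes (negative = sensitive), and a drug-target
#' table. Drug 1 (`drug_block`) is a planted trajectory-blocking drug: its
#' response loads negatively on the branch genes up-regulated in arm II, so
#' cells far along Path II are predicted most sensitive. Drug 2
#' (`drug_specific`) loads negatively on the marker genes of the terminal
#' arm-II cluster. Drug 3 (`drug_null`) has all-zero weights. Remaining
#' drugs get small random weights.
#'
#' @param truth `ground_truth` from [simulate_single_cells()].
#' @param config the [sim_config()].
#' @return A list with `cell_line_expr` (genes x lines), `response` (drugs x
#'   lines logFC matrix), `drug_targets` (data.frame `drug_id`, `drug_name`,
#'   `target_gene`) and `planted` (drug roles and the targeted cluster).
#' @export
simulate_drug_reference <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  genes <- names(truth$baseline)
  nl <- config$n_cell_lines
  expr <- matrix(stats::rnorm(length(genes) * nl,
                              mean = rep(truth$baseline + 1, nl), sd = 1),
                 nrow = length(genes),
                 dimnames = list(genes, sprintf("line_%02d", seq_len(nl))))
  expr <- pmax(expr, 0)

  path2_up <- names(truth$true_branch_genes)[truth$true_branch_genes > 0]
  target_cluster <- max(truth$true_cluster)       # terminal arm-II cluster
  spec_markers <- names(truth$true_marker_genes)[
    truth$true_marker_genes == target_cluster]

  nd <- config$n_drugs
  drug_ids <- sprintf("drug_%03d", seq_len(nd))
  drug_names <- c("drug_block", "drug_specific", "drug_null",
                  sprintf("drug_rand_%02d", seq_len(max(0, nd - 3))))[seq_len(nd)]

  W <- matrix(0, nrow = nd, ncol = length(genes),
              dimnames = list(drug_ids, genes))
  n_load <- min(10L, length(path2_up))
  block_genes <- path2_up[seq_len(n_load)]
  W[1, block_genes] <- -0.5
  spec_genes <- spec_markers[seq_len(min(10L, length(spec_markers)))]
  if (nd >= 2) W[2, spec_genes] <- -0.5
  if (nd >= 4) for (d in 4:nd) {
    g <- sample(genes, 5)
    W[d, g] <- stats::rnorm(5, 0, 0.05)
  }
  centered <- expr - rowMeans(expr)
  resp <- W %*% centered
  resp[1, ] <- resp[1, ] - 0.3
  if (nd >= 2) resp[2, ] <- resp[2, ] - 0.3
  if (config$drug_noise_sd > 0)
    resp <- resp + matrix(stats::rnorm(length(resp), 0, config$drug_noise_sd),
                          nrow = nd)

  tg <- lapply(seq_len(nd), function(d) {
    g <- colnames(W)[W[d, ] != 0]
    if (length(g) == 0) g <- character(0)
    if (length(g)) data.frame(drug_id = drug_ids[d], drug_name = drug_names[d],
                              target_gene = g, stringsAsFactors = FALSE)
  })
  drug_targets <- do.call(rbind, tg)
  rownames(resp) <- drug_ids

  list(cell_line_expr = expr, response = resp, drug_targets = drug_targets,
       planted = list(blocking = drug_ids[1],
                      specific = if (nd >= 2) drug_ids[2] else NULL,
                      null = if (nd >= 3) drug_ids[3] else NULL,
                      target_cluster = target_cluster,
                      blocking_genes = block_genes,
                      specific_genes = spec_genes))
}

#' Simulate a PPI edge list and receptor-ligand pairs
#'
#' Builds a random interaction graph over the marker and branch genes with
#' one planted high-centrality hub: the hub is attached to 60% of the nodes,
#' sits inside a planted clique, and every remaining node is tethered to a
#' hub neighbor so the graph is connected and the hub dominates all
#' centrality measures. Receptor-ligand pairs include one planted pair whose
#' ligand is a marker of one cluster and whose receptor is a marker of
#' another; the rest pair random genes.
#'
#' @param truth `ground_truth` from [simulate_single_cells()].
#' @param config the [sim_config()].
#' @param n_nodes number of network nodes (capped by available genes).
#' @param n_rl_pairs number of receptor-ligand pairs to emit.
#' @param ligand_cluster,receptor_cluster clusters whose markers form the
#'   planted pair (defaults: first two clusters).
#' @return A list with `edges` (data.frame `gene_a`, `gene_b`, `score`),
#'   `rl_pairs` (data.frame `ligand`, `receptor`), `hub` (the planted hub
#'   gene) and `planted_pair`.
#' @export
simulate_network_and_pairs <- function(truth, config, n_nodes = 40,
                                       n_rl_pairs = 20,
                                       ligand_cluster = 1L,
                                       receptor_cluster = 2L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 4L)
  pool <- c(names(truth$true_branch_genes), names(truth$true_marker_genes))
  n_nodes <- min(n_nodes, length(pool))
  if (n_nodes < 10) stop("too few marker/branch genes to build a network")
  # hub = a branch gene up-regulated in arm II (so it also survives the
  # branch-trend filter downstream)
  hub <- names(truth$true_branch_genes)[truth$true_branch_genes > 0][1]
  nodes <- unique(c(hub, sample(pool, n_nodes)))[seq_len(n_nodes)]

  others <- setdiff(nodes, hub)
  nbrs <- sample(others, ceiling(0.6 * n_nodes))
  edges <- data.frame(gene_a = hub, gene_b = nbrs, stringsAsFactors = FALSE)
  # planted clique around the hub: keeps the hub's own neighborhood dense so
  # it also ranks high on the local-density measures (clustering
  # coefficient, DMNC), not only the global ones
  clq <- c(hub, nbrs[seq_len(min(8, length(nbrs)))])
  cp <- t(utils::combn(clq, 2))
  edges <- rbind(edges, data.frame(gene_a = cp[, 1], gene_b = cp[, 2],
                                   stringsAsFactors = FALSE))
  # sparse background, avoiding pairs of hub neighbors: random triangles
  # through the hub would otherwise hand high local density to bystanders
  allp <- t(utils::combn(others, 2))
  both_nb <- allp[, 1] %in% nbrs & allp[, 2] %in% nbrs
  keep <- stats::runif(nrow(allp)) < 0.02 & !both_nb
  edges <- rbind(edges, data.frame(gene_a = allp[keep, 1],
                                   gene_b = allp[keep, 2],
                                   stringsAsFactors = FALSE))
  # tether stray nodes so the graph is connected through the hub side
  linked <- unique(c(edges$gene_a, edges$gene_b))
  stray <- setdiff(nodes, linked)
  if (length(stray))
    edges <- rbind(edges, data.frame(gene_a = stray,
                                     gene_b = sample(nbrs, length(stray),
                                                     replace = TRUE),
                                     stringsAsFactors = FALSE))
  key <- apply(edges, 1, function(r) paste(sort(r), collapse = "|"))
  edges <- edges[!duplicated(key) & edges$gene_a != edges$gene_b, ]
  edges$score <- round(stats::runif(nrow(edges), 0.4, 1), 3)
  rownames(edges) <- NULL

  lg <- names(truth$true_marker_genes)[truth$true_marker_genes == ligand_cluster][1]
  rc <- names(truth$true_marker_genes)[truth$true_marker_genes == receptor_cluster][1]
  if (is.na(lg) || is.na(rc)) stop("marker genes missing for planted RL pair")
  bg <- setdiff(names(truth$baseline), c(pool, lg, rc))
  n_null <- max(0, n_rl_pairs - 1)
  null_g <- sample(bg, 2 * n_null)
  rl <- rbind(data.frame(ligand = lg, receptor = rc, stringsAsFactors = FALSE),
              if (n_null > 0)
                data.frame(ligand = null_g[seq_len(n_null)],
                           receptor = null_g[n_null + seq_len(n_null)],
                           stringsAsFactors = FALSE))
  list(edges = edges, rl_pairs = rl, hub = hub,
       planted_pair = c(ligand = lg, receptor = rc,
                        cluster_a = ligand_cluster,
                        cluster_b = receptor_cluster))
}
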