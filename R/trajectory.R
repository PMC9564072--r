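#' Learn a principal graph over cluster or micro-cluster centroids
#'
#' Summarizes the cells by centroids in principal component space and
#' connects the centroids by a Euclidean minimum spanning tree. When a
#' cluster assignment is supplied the vertices are the cluster centroids
#' (one per cluster), anchoring the skeleton to the biology the clustering
#' already captured; otherwise `granularity` k-means micro-cluster
#' centroids are used and polished by elastic refinement. The tree is the
#' backbone along which pseudo-time is later measured; for Y-shaped data it
#' contains exactly one branching vertex.
#'
#' @param scores cells x components matrix.
#' @param clusters optional per-cell cluster labels (named vector or
#'   [cluster_cells()] result); when given, one vertex per cluster.
#' @param granularity number of micro-cluster centroids (default 12, must be
#'   at least 3; capped at the number of distinct cells with a warning). A
#'   coarse skeleton is deliberate: each centroid then averages away the
#'   cloud's lateral noise, whereas a fine skeleton starts tracing parallel
#'   strands through wide segments of the manifold.
#' @param seed seed for k-means initialization.
#' @param n_refine elastic refinement iterations (default 10; 0 disables):
#'   each iteration pulls every vertex toward the mean of its assigned cells
#'   blended with the mean of its tree neighbors, then refits the tree.
#' @param elasticity weight of the tree-neighbor mean in the refinement
#'   blend (default 0.3).
#' @return An object of class `principal_graph`: list with `graph` (igraph
#'   tree, edge attribute `weight` = Euclidean length), `centers` (vertices x
#'   components) and `scores`.
#' @export
learn_principal_graph <- function(scores, clusters = NULL, granularity = 12,
                                  seed = 1L, n_refine = 10,
                                  elasticity = 0.3) {
  scores <- as.matrix(scores)
  fit_mst <- function(cen) {
    d <- as.matrix(stats::dist(cen))
    g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                             weighted = TRUE)
    igraph::mst(g, weights = igraph::E(g)$weight)
  }
  if (!is.null(clusters)) {
    if (is.list(clusters)) clusters <- clusters$labels
    if (!is.null(names(clusters)) && !is.null(rownames(scores)))
      clusters <- clusters[rownames(scores)]
    if (length(clusters) != nrow(scores) || anyNA(clusters))
      stop("clusters must label every cell of the score matrix")
    ks <- sort(unique(clusters))
    if (length(ks) < 3) stop("need at least 3 clusters for a principal graph")
    centers <- t(vapply(ks, function(k)
      colMeans(scores[clusters == k, , drop = FALSE]),
      numeric(ncol(scores))))
    rownames(centers) <- as.character(ks)
    tree <- fit_mst(centers)
    return(structure(list(graph = tree, centers = centers, scores = scores,
                          clusters = stats::setNames(clusters,
                                                     rownames(scores)),
                          vertex_cluster = as.character(ks)),
                     class = "principal_graph"))
  }
  if (granularity < 3) stop("granularity must be at least 3")
  uniq <- unique(scores)
  if (granularity > nrow(uniq)) {
    warning("granularity exceeds the number of distinct cells; reducing")
    granularity <- nrow(uniq)
  }
  if (granularity == nrow(uniq)) {
    centers <- uniq                      # every distinct point is a vertex
  } else {
    set.seed(seed)
    km <- stats::kmeans(scores, centers = granularity, nstart = 10,
                        iter.max = 100)
    centers <- km$centers
  }
  tree <- fit_mst(centers)
  # elastic refinement: pull each vertex toward the mean of its assigned
  # cells and the mean of its tree neighbors, then refit the tree; this
  # straightens the skeleton and moves arm attachments to the junction
  for (it in seq_len(n_refine)) {
    dv <- vapply(seq_len(nrow(centers)), function(j)
      colSums((t(scores) - centers[j, ])^2), numeric(nrow(scores)))
    nearest <- max.col(-dv, ties.method = "first")
    adj <- igraph::as_adj_list(tree)
    new_centers <- centers
    for (j in seq_len(nrow(centers))) {
      cells <- which(nearest == j)
      data_mean <- if (length(cells)) colMeans(scores[cells, , drop = FALSE])
        else centers[j, ]
      nb <- as.integer(adj[[j]])
      nb_mean <- if (length(nb)) colMeans(centers[nb, , drop = FALSE])
        else centers[j, ]
      new_centers[j, ] <- (1 - elasticity) * data_mean + elasticity * nb_mean
    }
    if (max(abs(new_centers - centers)) < 1e-8) break
    centers <- new_centers
    tree <- fit_mst(centers)
  }
  structure(list(graph = tree, centers = centers, scores = scores,
                 clusters = NULL, vertex_cluster = NULL),
            class = "principal_graph")
}

# project point x onto segment (u, v); returns list(f in [0,1], dist2)
.project_segment <- function(x, u, v) {
  w <- v - u
  len2 <- sum(w * w)
  f <- if (len2 == 0) 0 else min(1, max(0, sum((x - u) * w) / len2))
  p <- u + f * w
  list(f = f, dist2 = sum((x - p)^2))
}

#' Root the principal graph and order cells in pseudo-time
#'
#' Chooses the root among the tree's leaf vertices (a trajectory starts at a
#' terminus) as the leaf whose assigned cells are most enriched for the
#' earliest observed clinical stage (ties broken by larger cell count, then
#' smaller vertex index), projects every cell onto its nearest
#' tree edge, and sets pseudo-time to the arc length from the root along the
#' tree to the projection point. Cells equidistant to two edges are assigned
#' to the edge whose nearer vertex has the smaller pseudo-time.
#'
#' @param pg a [learn_principal_graph()] result.
#' @param stages per-cell stage labels (`"I".."IV"`), aligned with the rows
#'   of `pg$scores`; required unless `root` is given.
#' @param root optional explicit root vertex index.
#' @return An object of class `trajectory`: list with `pseudotime` (named,
#'   >= 0), `branch` (all `"PRE"` until [detect_branch_and_paths()] runs),
#'   `cell_edge` (cells x 2 matrix of edge endpoints, parent first),
#'   `graph`, `centers`, `root_vertex`, `vertex_time` (arc length from root
#'   to each vertex) and `branch_vertex` (NA at this stage).
#' @export
root_and_order <- function(pg, stages = NULL, root = NULL) {
  stopifnot(inherits(pg, "principal_graph"))
  scores <- pg$scores
  centers <- pg$centers
  tree <- pg$graph
  nv <- nrow(centers)

  if (is.null(root)) {
    if (is.null(stages))
      stop("root must be supplied explicitly when no stage labels are given")
    stg <- stage_numeric(stages)
    # nearest-vertex assignment just for rooting
    dv <- vapply(seq_len(nv), function(j)
      colSums((t(scores) - centers[j, ])^2), numeric(nrow(scores)))
    nearest <- max.col(-dv, ties.method = "first")
    earliest <- min(stg)
    frac <- vapply(seq_len(nv), function(j) {
      s <- stg[nearest == j]
      if (length(s) == 0) -1 else mean(s == earliest)
    }, numeric(1))
    cnt <- tabulate(nearest, nbins = nv)
    leaves <- which(igraph::degree(tree) == 1)
    if (length(leaves) == 0) leaves <- seq_len(nv)
    root <- leaves[order(-frac[leaves], -cnt[leaves], leaves)[1]]
  }

  vertex_time <- as.numeric(igraph::distances(
    tree, v = root, weights = igraph::E(tree)$weight))

  el <- igraph::as_edgelist(tree, names = FALSE)
  elen <- igraph::E(tree)$weight
  n <- nrow(scores)
  best_d2 <- rep(Inf, n)
  best_pt <- numeric(n)
  best_edge <- matrix(NA_integer_, n, 2)
  tol <- 1e-12
  for (e in seq_len(nrow(el))) {
    u <- el[e, 1]; v <- el[e, 2]
    # orient parent (closer to root) first
    if (vertex_time[v] < vertex_time[u]) { tmp <- u; u <- v; v <- tmp }
    cu <- centers[u, ]; cv <- centers[v, ]
    w <- cv - cu
    len2 <- sum(w * w)
    f <- if (len2 == 0) rep(0, n) else
      pmin(1, pmax(0, as.numeric((scores - matrix(cu, n, length(cu),
                                                  byrow = TRUE)) %*% w) / len2))
    proj <- matrix(cu, n, length(cu), byrow = TRUE) + f %o% w
    d2 <- rowSums((scores - proj)^2)
    pt <- vertex_time[u] + f * sqrt(len2)
    upd <- d2 < best_d2 - tol |
      (abs(d2 - best_d2) <= tol & pt < best_pt)
    best_d2[upd] <- d2[upd]
    best_pt[upd] <- pt[upd]
    best_edge[upd, ] <- matrix(c(u, v), sum(upd), 2, byrow = TRUE)
  }
  pt <- stats::setNames(best_pt, rownames(scores))
  structure(list(pseudotime = pt,
                 branch = stats::setNames(rep("PRE", n), rownames(scores)),
                 cell_edge = best_edge, graph = tree, centers = centers,
                 root_vertex = root, vertex_time = vertex_time,
                 branch_vertex = NA_integer_, stages = stages,
                 clusters = pg$clusters,
                 vertex_cluster = pg$vertex_cluster),
            class = "trajectory")
}

#' Detect the branch point and assign Path I / Path II
#'
#' The branch vertex is the degree >= 3 tree vertex with the smallest
#' pseudo-time. Cutting the tree at that vertex, the component containing the
#' root stays `PRE`; of the downstream subtrees the two with the most cells
#' become the paths and any extra arm is merged into the path it attaches to
#' by the cheapest edge (with a warning). `PATH_II` is the arm whose terminal
#' cells (top pseudo-time quartile of the arm) have the later mean clinical
#' stage -- the arm deteriorating directly to stage IV -- with ties broken by
#' the longer arm. A linear tree yields no `PATH_II` cells and a warning.
#'
#' @param traj a [root_and_order()] result.
#' @param stages per-cell stage labels; defaults to those stored in `traj`.
#' @param min_branch_frac a degree >= 3 vertex only qualifies as the branch
#'   point if at least two of its downstream subtrees each hold this
#'   fraction of the cells (default 0.05); this ignores the short noise
#'   twigs a minimum spanning tree grows in high dimensions.
#' @return The `trajectory` with `branch` filled in (`PRE`, `PATH_I`,
#'   `PATH_II`) and `branch_vertex` set.
#' @export
detect_branch_and_paths <- function(traj, stages = NULL,
                                    min_branch_frac = 0.05) {
  stopifnot(inherits(traj, "trajectory"))
  if (is.null(stages)) stages <- traj$stages
  tree <- traj$graph
  deg <- igraph::degree(tree)
  cand <- which(deg >= 3)
  n_cells_total <- length(traj$pseudotime)

  # cells sit on edges; attribute each cell to its non-root-side endpoint's
  # component once a vertex is cut out
  cell_comp_at <- function(v) {
    g2 <- igraph::delete_vertices(tree, v)
    cm <- igraph::components(g2)$membership
    vmap <- rep(NA_integer_, igraph::vcount(tree))
    vmap[-v] <- cm
    cells <- if (!is.null(traj$vertex_cluster)) {
      vtx <- stats::setNames(seq_along(traj$vertex_cluster),
                             traj$vertex_cluster)
      vmap[vtx[as.character(traj$clusters)]]
    } else {
      apply(traj$cell_edge, 1, function(uv) {
        far <- uv[uv != v]
        vmap[far[1]]
      })
    }
    list(vmap = vmap, cells = cells)
  }

  second_arm <- vapply(cand, function(v) {
    cc <- cell_comp_at(v)
    rc <- cc$vmap[traj$root_vertex]
    if (is.na(rc)) return(NA_real_)        # root itself cannot branch paths
    down <- setdiff(unique(cc$vmap[!is.na(cc$vmap)]), rc)
    if (length(down) < 2) return(NA_real_)
    sizes <- sort(vapply(down, function(a) sum(cc$cells == a, na.rm = TRUE),
                         numeric(1)), decreasing = TRUE)
    if (sizes[2] < min_branch_frac * n_cells_total) return(NA_real_)
    sizes[2]
  }, numeric(1))
  cand <- cand[!is.na(second_arm)]
  second_arm <- second_arm[!is.na(second_arm)]

  if (length(cand) == 0) {
    warning("no branch point found; trajectory is linear (all cells PRE/PATH_I)")
    traj$branch_vertex <- NA_integer_
    return(traj)
  }
  # the genuine branch splits the downstream cells most evenly: take the
  # vertex whose second-largest downstream subtree is biggest (noise strands
  # capture a minority); ties go to the earliest vertex
  bv <- cand[order(-second_arm, traj$vertex_time[cand])][1]
  traj$branch_vertex <- bv
  traj$branch_candidates <- cand

  # components after removing the branch vertex; map each vertex to one
  g2 <- igraph::delete_vertices(tree, bv)
  comp <- igraph::components(g2)$membership
  vmap <- rep(NA_integer_, igraph::vcount(tree))
  vmap[-bv] <- comp

  # a cell belongs to the component of its edge endpoint that is not bv;
  # cells on edges incident to bv take the far endpoint's component. When
  # the skeleton is anchored to clusters, cells instead inherit their
  # cluster vertex's component (the cluster is the unit of lineage
  # membership, as in cluster-based lineage inference).
  if (!is.null(traj$vertex_cluster)) {
    vtx_of_cluster <- stats::setNames(seq_along(traj$vertex_cluster),
                                      traj$vertex_cluster)
    cell_comp <- vmap[vtx_of_cluster[as.character(traj$clusters)]]
  } else {
    cell_comp <- apply(traj$cell_edge, 1, function(uv) {
      far <- uv[uv != bv]
      vmap[far[1]]
    })
  }
  root_comp <- vmap[traj$root_vertex]
  arm_ids <- setdiff(unique(vmap[!is.na(vmap)]), root_comp)
  arm_cells <- vapply(arm_ids, function(a) sum(cell_comp == a, na.rm = TRUE),
                      numeric(1))
  ord <- order(-arm_cells)
  arms <- arm_ids[ord[seq_len(min(2, length(arm_ids)))]]

  if (length(arm_ids) > 2) {
    warning("more than two arms at the branch point; merging extras into the nearest kept arm")
    extras <- setdiff(arm_ids, arms)
    el <- igraph::as_edgelist(tree, names = FALSE)
    ew <- igraph::E(tree)$weight
    for (a in extras) {
      # nearest kept arm: centroid distance between arm vertex sets
      va <- which(vmap == a)
      dmin <- vapply(arms, function(k) {
        vk <- which(vmap == k)
        min(as.matrix(stats::dist(rbind(traj$centers[va, , drop = FALSE],
                                        traj$centers[vk, , drop = FALSE])))[
                                          seq_along(va),
                                          length(va) + seq_along(vk)])
      }, numeric(1))
      tgt <- arms[which.min(dmin)]
      vmap[vmap == a] <- tgt
      cell_comp[cell_comp == a & !is.na(cell_comp)] <- tgt
    }
  }
  if (length(arms) < 2) {
    warning("only one downstream arm; no PATH_II cells assigned")
    traj$branch[which(cell_comp == arms[1])] <- "PATH_I"
    return(traj)
  }

  arm_stat <- vapply(arms, function(a) {
    cells <- which(cell_comp == a)
    pt <- traj$pseudotime[cells]
    term <- cells[pt >= stats::quantile(pt, 0.75)]
    if (length(term) == 0) term <- cells
    if (is.null(stages)) return(NA_real_)
    mean(stage_numeric(stages[term]))
  }, numeric(1))
  arm_len <- vapply(arms, function(a) {
    el <- igraph::as_edgelist(tree, names = FALSE)
    inarm <- vmap[el[, 1]] %in% a & vmap[el[, 2]] %in% a
    sum(igraph::E(tree)$weight[inarm], na.rm = TRUE)
  }, numeric(1))
  if (anyNA(arm_stat) || abs(diff(arm_stat)) < 1e-12) {
    path2 <- arms[which.max(arm_len)]
  } else {
    path2 <- arms[which.max(arm_stat)]
  }
  path1 <- setdiff(arms, path2)

  traj$branch[which(cell_comp == path1)] <- "PATH_I"
  traj$branch[which(cell_comp == path2)] <- "PATH_II"
  # cells downstream in pseudotime but in the root component stay PRE
  traj
}

#' Mean pseudo-time per cluster
#'
#' Computes `T_i`, the arithmetic mean pseudo-time of the cells of each
#' cluster. These cluster pseudo-times are the `T_i` entering the patient
#' score `S = sum(P_i * T_i)`.
#'
#' @param traj a `trajectory`.
#' @param clusters per-cell cluster labels (named vector or the `labels`
#'   element of [cluster_cells()]).
#' @return Named numeric vector `T` over non-empty clusters.
#' @export
cluster_pseudotime <- function(traj, clusters) {
  stopifnot(inherits(traj, "trajectory"))
  if (is.list(clusters)) clusters <- clusters$labels
  pt <- traj$pseudotime
  if (!is.null(names(clusters)) && !is.null(names(pt)))
    clusters <- clusters[names(pt)]
  if (length(clusters) != length(pt))
    stop("clusters must label every cell of the trajectory")
  tv <- tapply(pt, clusters, mean)
  stats::setNames(as.numeric(tv), names(tv))
}
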