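# The twelve node-centrality measures used for hub mining: Degree, MCC,
# DMNC, MNC, EPC, BottleNeck, EcCentricity, Closeness, Radiality,
# Betweenness, Stress, ClusteringCoefficient. All are oriented so that
# larger = more central, and all are finite and >= 0 on any graph
# (distance-based measures are computed within connected components).

# number of shortest paths between all pairs: sigma[s,t] = (A^d(s,t))[s,t]
# (a walk of length exactly d(s,t) is necessarily a shortest path)
.shortest_path_counts <- function(A, D) {
  n <- nrow(A)
  sigma <- diag(1, n)
  maxd <- max(D[is.finite(D)])
  Ak <- diag(1, n)
  for (d in seq_len(max(1, maxd))) {
    Ak <- Ak %*% A
    hit <- which(D == d, arr.ind = TRUE)
    if (nrow(hit)) sigma[hit] <- Ak[hit]
  }
  sigma
}

# stress(v) = number of shortest s-t paths (s != v != t) passing through v
.stress_values <- function(A, D) {
  n <- nrow(A)
  sigma <- .shortest_path_counts(A, D)
  st <- numeric(n)
  for (v in seq_len(n)) {
    s_ok <- setdiff(seq_len(n), v)
    for (s in s_ok) for (t in s_ok) {
      if (t <= s) next
      if (!is.finite(D[s, t])) next
      if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
          D[s, v] + D[v, t] == D[s, t])
        st[v] <- st[v] + sigma[s, v] * sigma[v, t]
    }
  }
  st
}

# deterministic BFS shortest-path tree from s: each vertex's parent is its
# smallest-index neighbor one step closer to s
.sp_tree_parents <- function(A, D, s) {
  n <- nrow(A)
  parent <- rep(NA_integer_, n)
  for (v in seq_len(n)) {
    if (v == s || !is.finite(D[s, v])) next
    cand <- which(A[v, ] > 0 & D[s, ] == D[s, v] - 1)
    parent[v] <- min(cand)
  }
  parent
}

# BottleNeck: BN(v) = #{ s : the subtree of v in the shortest-path tree
# rooted at s contains more than a quarter of s's component }
.bottleneck_values <- function(A, D) {
  n <- nrow(A)
  bn <- numeric(n)
  for (s in seq_len(n)) {
    comp <- which(is.finite(D[s, ]))
    parent <- .sp_tree_parents(A, D, s)
    # subtree sizes: count descendants by walking parents
    size <- rep(0L, n)
    for (v in comp) {
      w <- v
      while (!is.na(parent[w])) {
        size[parent[w]] <- size[parent[w]] + 1L
        w <- parent[w]
      }
    }
    size[comp] <- size[comp] + 1L     # count the vertex itself
    thr <- length(comp) / 4
    hits <- comp[size[comp] > thr & comp != s]
    bn[hits] <- bn[hits] + 1
  }
  bn
}

# EPC: mean over Monte-Carlo edge-percolated copies (each edge kept
# independently with probability keep_prob) of the fraction of vertices in
# v's percolated component. Seeded and vectorized over repetitions.
.epc_values <- function(el, n, reps = 1000, keep_prob = 0.5, seed = 1L) {
  if (nrow(el) == 0) return(rep(1 / n, n))
  storage.mode(el) <- "integer"
  set.seed(seed)
  m <- nrow(el)
  acc <- numeric(n)
  for (r in seq_len(reps)) {
    keep <- stats::runif(m) < keep_prob
    # union-find over kept edges
    par <- seq_len(n)
    find <- function(x) { while (par[x] != x) { par[x] <<- par[par[x]]; x <- par[x] }; x }
    for (e in which(keep)) {
      a <- find(el[e, 1]); b <- find(el[e, 2])
      if (a != b) par[a] <- b
    }
    roots <- vapply(seq_len(n), find, integer(1))
    csize <- table(roots)
    acc <- acc + as.numeric(csize[as.character(roots)]) / n
  }
  acc / reps
}

#' Compute the twelve hub-mining centrality measures
#'
#' Computes, for every node of an undirected graph, the twelve topological
#' measures conventionally used for hub screening: `Degree`; `MCC` (maximal
#' clique centrality: sum over the maximal cliques containing the node of
#' `(|C| - 1)!`, counting cliques of size >= 2, so a triangle-free node's
#' MCC equals its degree); `DMNC` and `MNC` (density and size of the
#' maximum connected component of the node's neighborhood subgraph, with
#' DMNC = E / V^1.7); `EPC` (edge-percolation component: seeded Monte-Carlo
#' average, over copies of the graph with each edge kept independently with
#' probability 1/2, of the fraction of vertices left connected to the
#' node); `BottleNeck` (number of shortest-path trees in which the node's
#' subtree holds more than a quarter of the tree); `EcCentricity`
#' (reciprocal eccentricity within the component); `Closeness` (harmonic
#' closeness, sum of reciprocal distances); `Radiality` (component
#' diameter + 1 minus mean distance, averaged over the component);
#' `Betweenness` and `Stress` (shortest-path betweenness and the raw count
#' of shortest paths through the node); and `ClusteringCoefficient` (local
#' transitivity, 0 for degree < 2).
#'
#' @param graph an `igraph` undirected graph (or an edge-list data.frame
#'   accepted by [build_ppi_subnetwork()]).
#' @param epc_reps Monte-Carlo repetitions for EPC (default 1000).
#' @param seed seed for the EPC percolation draws.
#' @param node_limit refuse graphs larger than this for the exhaustive
#'   measures (default 2000); subset the network first.
#' @return data.frame, one row per node, with the node name and the twelve
#'   measures; all values finite and >= 0.
#' @export
compute_centralities <- function(graph, epc_reps = 1000, seed = 1L,
                                 node_limit = 2000) {
  g <- graph
  stopifnot(igraph::is_igraph(g))
  n <- igraph::vcount(g)
  if (n == 0) stop("empty graph")
  if (n > node_limit)
    stop(sprintf("graph has %d nodes (> node_limit = %d); subset the network first",
                 n, node_limit))
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  A <- (A > 0) + 0
  D <- igraph::distances(g, weights = NA)
  el <- igraph::as_edgelist(g, names = FALSE)

  degree <- rowSums(A)

  # MCC over maximal cliques of size >= 2
  mcc <- numeric(n)
  if (nrow(el) > 0) {
    cliques <- igraph::max_cliques(g, min = 2)
    for (cl in cliques) {
      idx <- as.integer(cl)
      mcc[idx] <- mcc[idx] + factorial(length(idx) - 1)
    }
  }

  # MNC / DMNC from the neighborhood subgraph
  mnc <- numeric(n); dmnc <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(A[v, ] > 0)
    if (length(nb) == 0) next
    sub <- A[nb, nb, drop = FALSE]
    gs <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected")
    comp <- igraph::components(gs)
    big <- which.max(comp$csize)
    vs <- which(comp$membership == big)
    mnc[v] <- length(vs)
    if (length(vs) >= 2) {
      esub <- sum(sub[vs, vs]) / 2
      dmnc[v] <- esub / length(vs)^1.7
    }
  }

  epc <- .epc_values(el, n, reps = epc_reps, seed = seed)
  bottleneck <- .bottleneck_values(A, D)

  ecc <- vapply(seq_len(n), function(v) {
    dv <- D[v, is.finite(D[v, ])]
    e <- max(dv)
    if (e == 0) 0 else 1 / e
  }, numeric(1))

  closeness <- vapply(seq_len(n), function(v) {
    dv <- D[v, ]
    sum(1 / dv[is.finite(dv) & dv > 0])
  }, numeric(1))

  comp_all <- igraph::components(g)$membership
  comp_diam <- vapply(seq_len(max(comp_all)), function(cid) {
    idx <- which(comp_all == cid)
    max(D[idx, idx, drop = FALSE])
  }, numeric(1))
  radiality <- vapply(seq_len(n), function(v) {
    same <- which(comp_all == comp_all[v] & seq_len(n) != v)
    if (length(same) == 0) return(0)
    sum(comp_diam[comp_all[v]] + 1 - D[v, same]) / length(same)
  }, numeric(1))

  betweenness <- igraph::betweenness(g, weights = NA)
  stress <- .stress_values(A, D)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  cc[is.na(cc)] <- 0

  nm <- igraph::V(g)$name
  if (is.null(nm)) nm <- as.character(seq_len(n))
  data.frame(node = nm, Degree = degree, MCC = mcc, DMNC = dmnc, MNC = mnc,
             EPC = epc, BottleNeck = bottleneck, EcCentricity = ecc,
             Closeness = closeness, Radiality = radiality,
             Betweenness = as.numeric(betweenness), Stress = stress,
             ClusteringCoefficient = cc, stringsAsFactors = FALSE)
}

#' Select hub nodes as the intersection of the per-measure top fractions
#'
#' For each centrality measure the nodes are ranked in decreasing order and
#' the top `ceil(top_frac * n)` are kept, together with every node tied with
#' the boundary value (so a measure that is constant keeps all nodes). The
#' hub set is the intersection of the kept sets across all measures.
#'
#' @param table a [compute_centralities()] data.frame.
#' @param top_frac fraction kept per measure (default 0.5).
#' @return Character vector of hub node names (possibly empty; a warning is
#'   emitted when the table has no nodes).
#' @export
select_hubs <- function(table, top_frac = 0.5) {
  if (nrow(table) == 0) {
    warning("empty centrality table; no hubs")
    return(character(0))
  }
  measures <- setdiff(colnames(table), "node")
  if (!is.null(table$Degree) && all(table$Degree == 0)) {
    warning("graph has no edges; no hubs")
    return(character(0))
  }
  n <- nrow(table)
  k <- ceiling(top_frac * n)
  keep <- lapply(measures, function(mname) {
    v <- table[[mname]]
    ord <- order(v, decreasing = TRUE)
    thr <- v[ord[k]]
    table$node[v >= thr]
  })
  Reduce(intersect, keep)
}
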