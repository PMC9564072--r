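# Brute-force reference implementations of the twelve centrality measures,
# plus exhaustive enumeration of small connected graphs up to isomorphism.
# Everything here is deliberately naive and independent of the package's
# implementation paths.

# ---- enumeration -----------------------------------------------------------

canon_key <- function(A) {
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  cp <- igraph::canonical_permutation(g)$labeling
  gc <- igraph::permute(g, cp)
  el <- igraph::as_edgelist(gc, names = FALSE)
  el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
  paste(nrow(A), paste(t(el), collapse = ","), sep = ":")
}

# all connected graphs on <= max_n vertices, one per isomorphism class,
# as adjacency matrices; built by vertex extension with canonical dedup
enumerate_connected_graphs <- function(max_n) {
  levels <- list(list(matrix(0, 1, 1)))
  for (n in 2:max_n) {
    seen <- new.env(parent = emptyenv())
    out <- list()
    subsets <- lapply(0:(2^(n - 1) - 1), function(mask)
      which(bitwAnd(mask, 2^(0:(n - 2))) > 0))
    for (A in levels[[n - 1]]) {
      for (nb in subsets) {
        B <- rbind(cbind(A, 0), 0)
        B[n, nb] <- 1
        B[nb, n] <- 1
        key <- canon_key(B)
        if (!exists(key, envir = seen)) {
          assign(key, TRUE, envir = seen)
          out[[length(out) + 1]] <- B
        }
      }
    }
    levels[[n]] <- out
  }
  conn <- list()
  for (n in seq_len(max_n)) for (A in levels[[n]]) {
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    if (igraph::components(g)$no == 1) conn[[length(conn) + 1]] <- A
  }
  conn
}

# ---- primitive oracles -----------------------------------------------------

# BFS all-pairs distances, no igraph
o_dist <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    D[s, s] <- 0
    frontier <- s
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- integer(0)
      for (v in frontier) {
        for (w in which(A[v, ] > 0)) {
          if (D[s, w] > d) { D[s, w] <- d; nxt <- c(nxt, w) }
        }
      }
      frontier <- unique(nxt)
    }
  }
  D
}

# enumerate all shortest s-t paths (as vertex sequences) by DFS that only
# steps one unit further from s
o_shortest_paths <- function(A, D, s, t) {
  if (!is.finite(D[s, t])) return(list())
  paths <- list()
  walk <- function(v, acc) {
    if (v == t) { paths[[length(paths) + 1]] <<- acc; return(invisible()) }
    for (w in which(A[v, ] > 0)) {
      if (D[s, w] == D[s, v] + 1 && D[w, t] == D[v, t] - 1)
        walk(w, c(acc, w))
    }
  }
  walk(s, s)
  paths
}

o_degree <- function(A) rowSums(A)

o_clustering <- function(A) {
  n <- nrow(A)
  vapply(seq_len(n), function(v) {
    nb <- which(A[v, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    sum(A[nb, nb]) / (k * (k - 1))
  }, numeric(1))
}

# maximal cliques by subset enumeration, then MCC
o_mcc <- function(A) {
  n <- nrow(A)
  mcc <- numeric(n)
  subsets <- lapply(1:(2^n - 1), function(mask) which(bitwAnd(mask, 2^(0:(n - 1))) > 0))
  is_clique <- vapply(subsets, function(S) {
    if (length(S) < 2) return(FALSE)
    all(A[S, S][upper.tri(diag(length(S)))] == 1)
  }, logical(1))
  cl <- subsets[is_clique]
  for (S in cl) {
    maximal <- !any(vapply(setdiff(seq_len(n), S), function(v)
      all(A[v, S] == 1), logical(1)))
    if (maximal) mcc[S] <- mcc[S] + factorial(length(S) - 1)
  }
  mcc
}

o_components <- function(A) {
  n <- nrow(A)
  comp <- rep(0L, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0) next
    cid <- cid + 1L
    frontier <- s
    comp[s] <- cid
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) for (w in which(A[v, ] > 0))
        if (comp[w] == 0) { comp[w] <- cid; nxt <- c(nxt, w) }
      frontier <- nxt
    }
  }
  comp
}

o_mnc_dmnc <- function(A) {
  n <- nrow(A)
  mnc <- numeric(n); dmnc <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(A[v, ] > 0)
    if (!length(nb)) next
    S <- A[nb, nb, drop = FALSE]
    comp <- o_components(S)
    sizes <- tabulate(comp)
    big <- which.max(sizes)
    vs <- which(comp == big)
    mnc[v] <- length(vs)
    if (length(vs) >= 2)
      dmnc[v] <- (sum(S[vs, vs]) / 2) / length(vs)^1.7
  }
  list(mnc = mnc, dmnc = dmnc)
}

o_eccentricity_centrality <- function(A) {
  D <- o_dist(A)
  vapply(seq_len(nrow(A)), function(v) {
    dv <- D[v, is.finite(D[v, ])]
    e <- max(dv)
    if (e == 0) 0 else 1 / e
  }, numeric(1))
}

o_closeness <- function(A) {
  D <- o_dist(A)
  vapply(seq_len(nrow(A)), function(v) {
    dv <- D[v, ]
    sum(1 / dv[is.finite(dv) & dv > 0])
  }, numeric(1))
}

o_radiality <- function(A) {
  D <- o_dist(A)
  comp <- o_components(A)
  n <- nrow(A)
  vapply(seq_len(n), function(v) {
    same <- which(comp == comp[v] & seq_len(n) != v)
    if (!length(same)) return(0)
    idx <- which(comp == comp[v])
    diam <- max(D[idx, idx])
    sum(diam + 1 - D[v, same]) / length(same)
  }, numeric(1))
}

o_betweenness_stress <- function(A) {
  n <- nrow(A)
  D <- o_dist(A)
  bet <- numeric(n); str_ <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(D[s, t]) || D[s, t] == 0) next
    paths <- o_shortest_paths(A, D, s, t)
    sigma <- length(paths)
    for (v in setdiff(seq_len(n), c(s, t))) {
      through <- sum(vapply(paths, function(p) v %in% p, logical(1)))
      str_[v] <- str_[v] + through
      bet[v] <- bet[v] + through / sigma
    }
  }
  list(betweenness = bet, stress = str_)
}

o_bottleneck <- function(A) {
  n <- nrow(A)
  D <- o_dist(A)
  bn <- numeric(n)
  for (s in seq_len(n)) {
    comp <- which(is.finite(D[s, ]))
    parent <- rep(NA_integer_, n)
    for (v in comp) {
      if (v == s) next
      cand <- which(A[v, ] > 0 & D[s, ] == D[s, v] - 1)
      parent[v] <- min(cand)
    }
    size <- rep(0L, n)
    for (v in comp) {
      w <- v
      repeat {
        size[w] <- size[w] + 1L
        if (is.na(parent[w])) break
        w <- parent[w]
      }
    }
    hits <- comp[size[comp] > length(comp) / 4 & comp != s]
    bn[hits] <- bn[hits] + 1
  }
  bn
}

# EPC with the same sampling scheme as the implementation (per repetition,
# runif(m) over edges in edge order, keep < 0.5) but reachability computed
# by boolean matrix closure instead of union-find
o_epc <- function(A, reps, seed) {
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  el <- igraph::as_edgelist(g, names = FALSE)
  n <- nrow(A)
  if (nrow(el) == 0) return(rep(1 / n, n))
  set.seed(seed)
  acc <- numeric(n)
  for (r in seq_len(reps)) {
    keep <- stats::runif(nrow(el)) < 0.5
    Ak <- matrix(0, n, n)
    for (e in which(keep)) {
      Ak[el[e, 1], el[e, 2]] <- 1
      Ak[el[e, 2], el[e, 1]] <- 1
    }
    R <- diag(n) + Ak
    for (i in seq_len(ceiling(log2(max(2, n))))) R <- (R %*% R > 0) + 0
    acc <- acc + rowSums(R > 0) / n
  }
  acc / reps
}

oracle_centralities <- function(A, epc_reps, epc_seed) {
  ms <- o_mnc_dmnc(A)
  bs <- o_betweenness_stress(A)
  data.frame(Degree = o_degree(A), MCC = o_mcc(A), DMNC = ms$dmnc,
             MNC = ms$mnc, EPC = o_epc(A, epc_reps, epc_seed),
             BottleNeck = o_bottleneck(A),
             EcCentricity = o_eccentricity_centrality(A),
             Closeness = o_closeness(A), Radiality = o_radiality(A),
             Betweenness = bs$betweenness, Stress = bs$stress,
             ClusteringCoefficient = o_clustering(A))
}

graph_from_adj <- function(A) {
  rownames(A) <- colnames(A) <- paste0("n", seq_len(nrow(A)))
  igraph::graph_from_adjacency_matrix(A, mode = "undirected")
}
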