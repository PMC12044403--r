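# All-pairs shortest path lengths by Dijkstra on a dense distance matrix.
# Inf entries are absent edges. Returns the matrix of geodesic distances.
.shortestPaths <- function(D) {
  n <- nrow(D)
  out <- matrix(Inf, n, n)
  for (src in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[src] <- 0
    visited <- logical(n)
    repeat {
      cand <- dist
      cand[visited] <- Inf
      u <- which.min(cand)
      if (!is.finite(cand[u])) break
      visited[u] <- TRUE
      nb <- which(!visited & is.finite(D[u, ]))
      if (length(nb)) {
        alt <- dist[u] + D[u, nb]
        upd <- alt < dist[nb]
        dist[nb[upd]] <- alt[upd]
      }
      if (all(visited)) break
    }
    out[src, ] <- dist
  }
  out
}

#' Network efficiency (mean inverse shortest path length)
#'
#' \code{E = 1/(m(m-1)) * sum_{i != j} 1/d_ij}, with \code{d_ij} the
#' shortest-path length through the (sub)graph and \code{1/Inf := 0} for
#' disconnected pairs. When all edge weights are at most 1 (distances at
#' least 1) the result lies in [0, 1]. With \code{subset}, the efficiency
#' of the subset-induced subgraph is returned: paths may not leave the
#' subset. Note: some of the EEG literature calls this quantity computed on
#' the whole graph "local efficiency"; canonically it is global efficiency.
#'
#' @param dist a \code{DistanceMatrix}.
#' @param subset optional character vector of node labels (>= 2) inducing
#'   the subgraph.
#' @return efficiency (scalar).
#' @export
networkEfficiency <- function(dist, subset = NULL) {
  D <- dist@D
  if (!is.null(subset)) {
    idx <- match(tolower(subset), tolower(dist@labels))
    if (anyNA(idx))
      stop("unknown label(s) in subset: ",
           paste(subset[is.na(idx)], collapse = ", "))
    if (length(idx) < 2) stop("subset must have at least 2 members")
    D <- D[idx, idx, drop = FALSE]
  }
  m <- nrow(D)
  sp <- .shortestPaths(D)
  inv <- 1 / sp
  inv[!is.finite(sp)] <- 0
  diag(inv) <- 0
  sum(inv) / (m * (m - 1))
}

#' Newman modularity of a partition
#'
#' \code{Q = sum_c (e_c/m_tot - (k_c/(2 m_tot))^2)} for an undirected
#' (optionally weighted) graph: \code{e_c} is the within-community weight
#' fraction numerator (sum of within-community edge weights), \code{k_c}
#' the community degree (strength) sum and \code{m_tot} the total edge
#' weight. An empty graph has Q = 0 by convention. Q is invariant under
#' community relabeling.
#'
#' @param adj a \code{ConnectivityMatrix} (nonnegative weights) or a plain
#'   symmetric matrix.
#' @param membership integer/character community id per node.
#' @return modularity Q.
#' @export
modularityQ <- function(adj, membership) {
  W <- if (is(adj, "ConnectivityMatrix")) adj@W else as.matrix(adj)
  n <- nrow(W)
  if (length(membership) != n) stop("partition must cover all nodes")
  comm <- as.integer(factor(membership))
  m2 <- sum(W)                       # 2 * m_tot for undirected
  if (m2 == 0) return(0)
  k <- rowSums(W)
  Q <- 0
  for (c in unique(comm)) {
    idx <- comm == c
    e_c <- sum(W[idx, idx, drop = FALSE])      # 2 * within weight
    k_c <- sum(k[idx])
    Q <- Q + e_c / m2 - (k_c / m2)^2
  }
  Q
}

# One Louvain local-moving pass on weight matrix W (possibly with
# self-loops from aggregation), starting from partition init.
# Returns list(membership, improved).
# Move score for node v joining community C (v removed from its own):
# proportional to w_{v,C} - Sigma_tot(C) * k_v / m2, with m2 = sum(W).
.louvainPass <- function(W, order_idx, init = seq_len(nrow(W))) {
  n <- nrow(W)
  comm <- init
  k <- rowSums(W)
  m2 <- sum(W)
  improved <- FALSE
  repeat {
    moved <- FALSE
    for (v in order_idx) {
      cv <- comm[v]
      nb <- which(W[v, ] > 0 & seq_len(n) != v)
      if (!length(nb)) next
      cand <- unique(c(comm[nb], cv))
      w_to <- vapply(cand, function(c0)
        sum(W[v, nb[comm[nb] == c0]]), numeric(1))
      sig <- vapply(cand, function(c0) {
        s <- sum(k[comm == c0])
        if (c0 == cv) s <- s - k[v]
        s
      }, numeric(1))
      score <- w_to - sig * k[v] / m2
      best <- cand[which.max(score)]
      if (best != cv && score[cand == best] > score[cand == cv] + 1e-12) {
        comm[v] <- best
        moved <- TRUE
        improved <- TRUE
      }
    }
    if (!moved) break
  }
  list(membership = as.integer(factor(comm)), improved = improved)
}

#' Louvain community detection
#'
#' Standard two-phase Louvain: greedy local node moving to the neighboring
#' community with the largest modularity gain, then aggregation of
#' communities into super-nodes, repeated until no pass improves Q. The
#' node sweep order is shuffled by \code{seed}, making runs reproducible.
#' Because greedy local moving can stall in local optima, the algorithm is
#' restarted \code{nRestarts} times with different sweep orders (derived
#' deterministically from \code{seed}) and the best-Q partition is
#' returned. An edgeless graph returns one community per node with Q = 0.
#'
#' @param adj a \code{ConnectivityMatrix} (binary or weighted, nonnegative)
#'   or plain symmetric matrix.
#' @param seed integer seed for the sweep orders (default 1).
#' @param nRestarts number of seeded restarts (default 10).
#' @return a \code{\link{GraphPartition}}.
#' @export
louvainPartition <- function(adj, seed = 1, nRestarts = 10) {
  best <- NULL
  for (r in seq_len(nRestarts)) {
    # odd restarts start from singletons, even ones from a random coarse
    # partition: diversifies the search basin beyond the sweep order
    cand <- .louvainOnce(adj, deriveSeed(seed, "louvain", r),
                         randomInit = r %% 2 == 0)
    if (is.null(best) || cand@Q > best@Q) best <- cand
  }
  best
}

.louvainOnce <- function(adj, seed, randomInit = FALSE) {
  labels <- if (is(adj, "ConnectivityMatrix")) adj@labels
            else rownames(adj) %||% as.character(seq_len(nrow(adj)))
  W0 <- if (is(adj, "ConnectivityMatrix")) adj@W else as.matrix(adj)
  if (any(W0 < 0)) stop("Louvain requires nonnegative weights")
  n <- nrow(W0)
  if (sum(W0) == 0) {
    return(new("GraphPartition", labels = labels,
               membership = seq_len(n), Q = 0))
  }
  membership <- withSeed(seed, {
    comm <- if (randomInit && n >= 3) {
      k <- sample(2:min(4, n - 1), 1)
      sample(rep(seq_len(k), length.out = n))
    } else seq_len(n)
    repeat {
      # node-level local moving on the original graph, starting from the
      # current partition (refinement: lets aggregated nodes split again)
      r1 <- .louvainPass(W0, sample(n), init = comm)
      comm <- r1$membership
      # aggregation cycle on the coarsened graph
      node_map <- comm
      W <- unname(t(rowsum(t(rowsum(W0, comm)), comm)))
      agg_improved <- FALSE
      repeat {
        res <- .louvainPass(W, sample(nrow(W)))
        if (!res$improved) break
        agg_improved <- TRUE
        node_map <- res$membership[node_map]
        if (length(unique(res$membership)) == nrow(W)) break
        groups <- res$membership
        W <- unname(t(rowsum(t(rowsum(W, groups)), groups)))
      }
      if (!agg_improved && !r1$improved) break
      comm <- as.integer(factor(node_map))
    }
    comm
  })
  membership <- as.integer(factor(membership))
  new("GraphPartition", labels = labels, membership = membership,
      Q = modularityQ(W0, membership))
}

#' Eigenvector centrality by power iteration
#'
#' Leading eigenvector of the (nonnegative, symmetric) adjacency matrix,
#' computed by power iteration with per-step normalization. Iteration runs
#' on \code{A + sI} with \code{s = max row sum}: the spectral shift leaves
#' eigenvectors unchanged but guarantees a unique dominant eigenvalue on
#' connected graphs (plain power iteration oscillates on bipartite graphs
#' such as stars). The sign is fixed nonnegative and the result has unit
#' Euclidean norm. On disconnected graphs centrality concentrates on the
#' dominant component. Invariant to global scaling of the adjacency.
#'
#' @param adj a \code{ConnectivityMatrix} or plain symmetric nonnegative
#'   matrix with at least one edge.
#' @param tol max-norm convergence tolerance (default 1e-10).
#' @param maxIter iteration cap (default 1000).
#' @return a \code{\link{CentralityVector}}.
#' @export
eigenvectorCentrality <- function(adj, tol = 1e-10, maxIter = 1000) {
  labels <- if (is(adj, "ConnectivityMatrix")) adj@labels
            else rownames(adj) %||% as.character(seq_len(nrow(adj)))
  A <- if (is(adj, "ConnectivityMatrix")) adj@W else as.matrix(adj)
  if (any(A < 0)) stop("adjacency must be nonnegative")
  if (sum(A) == 0) stop("adjacency has no edges")
  n <- nrow(A)
  shift <- max(rowSums(A))
  As <- A + diag(shift, n)
  x <- rep(1 / sqrt(n), n)
  for (it in seq_len(maxIter)) {
    y <- As %*% x
    y <- as.vector(y) / sqrt(sum(y^2))
    if (max(abs(y - x)) < tol) {
      x <- pmax(y, 0)
      x <- x / sqrt(sum(x^2))
      return(new("CentralityVector", labels = labels, values = x))
    }
    x <- y
  }
  stop("eigenvector centrality failed to converge within ", maxIter,
       " iterations")
}

#' Regional aggregation of a graph metric
#'
#' \code{mode = "efficiency"}: efficiency of the region-induced subgraph of
#' a \code{DistanceMatrix} (paths confined to the region's electrodes).
#' \code{mode = "centrality"}: mean eigenvector-centrality entry over the
#' region's electrodes.
#'
#' @param x a \code{DistanceMatrix} (efficiency) or
#'   \code{CentralityVector} (centrality).
#' @param region region name present in \code{map}.
#' @param map a \code{RegionMap} (default \code{defaultRegionMap()}).
#' @param mode "efficiency" or "centrality".
#' @return scalar regional value.
#' @export
regionalValue <- function(x, region, map = defaultRegionMap(),
                          mode = c("efficiency", "centrality")) {
  mode <- match.arg(mode)
  els <- regionElectrodes(map, region)
  labels <- channelLabels(x)
  missing <- els[!tolower(els) %in% tolower(labels)]
  if (length(missing))
    stop("region '", region, "' electrodes missing from data: ",
         paste(missing, collapse = ", "))
  if (mode == "efficiency") {
    if (!is(x, "DistanceMatrix"))
      stop("efficiency mode needs a DistanceMatrix")
    networkEfficiency(x, subset = els)
  } else {
    if (!is(x, "CentralityVector"))
      stop("centrality mode needs a CentralityVector")
    idx <- match(tolower(els), tolower(labels))
    mean(x@values[idx])
  }
}

#' Export per-electrode values as CSV
#'
#' Writes (electrode, value) rows for a \code{CentralityVector}, or
#' (electrode, community) for a \code{GraphPartition}; suitable for
#' external topographic plotting.
#'
#' @param x a \code{CentralityVector} or \code{GraphPartition}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeNodeCSV <- function(x, path) {
  df <- if (is(x, "CentralityVector")) {
    data.frame(electrode = x@labels, value = x@values)
  } else if (is(x, "GraphPartition")) {
    data.frame(electrode = x@labels, community = x@membership)
  } else stop("unsupported object")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
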