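# Independent oracles used to validate the package's graph and statistics
# implementations. These deliberately use different algorithms from the
# package code paths.

# All-pairs shortest paths by Floyd-Warshall (vs the package's Dijkstra).
oracleShortestPaths <- function(D) {
  n <- nrow(D)
  sp <- D
  diag(sp) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      sp[i, ] <- pmin(sp[i, ], sp[i, k] + sp[k, ])
  sp
}

oracleEfficiency <- function(D) {
  sp <- oracleShortestPaths(D)
  inv <- 1 / sp
  inv[!is.finite(sp)] <- 0
  diag(inv) <- 0
  sum(inv) / (nrow(D) * (nrow(D) - 1))
}

# Newman Q directly from the quality-function definition
# Q = (1/2m) * sum_ij (A_ij - k_i k_j / 2m) delta(c_i, c_j).
oracleModularity <- function(A, comm) {
  m2 <- sum(A)
  if (m2 == 0) return(0)
  k <- rowSums(A)
  delta <- outer(comm, comm, `==`)
  sum((A - outer(k, k) / m2) * delta) / m2
}

# Enumerate all set partitions of n elements (restricted growth strings).
allPartitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxc) {
    i <- length(prefix) + 1
    if (i > n) {
      out[[length(out) + 1]] <<- prefix
      return(invisible())
    }
    for (c in seq_len(maxc + 1))
      rec(c(prefix, c), max(maxc, c))
  }
  rec(integer(0), 0L)
  out
}

# Exhaustive maximum modularity over all partitions (n <= 8).
oracleMaxModularity <- function(A) {
  parts <- allPartitions(nrow(A))
  max(vapply(parts, function(p) oracleModularity(A, p), numeric(1)))
}

# Textbook pairwise Pearson correlation: covariance over product of SDs,
# computed with explicit sums.
oraclePearson <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
  sxy / (sqrt(sum((x - mean(x))^2) / (n - 1)) *
           sqrt(sum((y - mean(y))^2) / (n - 1)))
}

# Random symmetric nonnegative weight matrix with approx density p.
randomGraph <- function(n, p = 0.5, weighted = TRUE) {
  A <- matrix(0, n, n)
  ut <- which(upper.tri(A))
  on <- runif(length(ut)) < p
  w <- if (weighted) runif(length(ut), 0.1, 1) else 1
  A[ut[on]] <- (if (weighted) w[on] else 1)
  A + t(A)
}

# Circular mean of phase angles.
circularMean <- function(theta) Arg(mean(exp(1i * theta)))

# Convenience: frontal-region efficiency of one epoch via the package's
# public path (Pearson -> distance -> induced-subgraph efficiency).
epochRegionalEfficiency <- function(epoch, region, map) {
  pc <- pearsonConnectivity(epoch)
  dm <- connectivityToDistance(pc)
  regionalValue(dm, region, map, "efficiency")
}

# Metric table (subject, condition, task, value) for a study's epochs
# using a supplied per-epoch value function.
studyTable <- function(epochs, valueFn) {
  do.call(rbind, lapply(epochs, function(e)
    data.frame(subject = e@subjectId, condition = e@condition,
               task = e@task, value = valueFn(e),
               stringsAsFactors = FALSE)))
}
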