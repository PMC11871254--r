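# Fixture builders and brute-force oracles, written independently of the
# package implementations they check.

makeOtu <- function(m, kingdom = "bacteria", fg = NULL, sampleData = NULL) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("t%03d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("s%03d", seq_len(ncol(m)))
  OtuExperiment(m, kingdom = kingdom, functionalGroup = fg,
                sampleData = sampleData)
}

# A random count table with no constant taxon (regenerates rows as needed).
randomCountTable <- function(nTaxa, nSamples, lambda = 8) {
  m <- matrix(rpois(nTaxa * nSamples, lambda), nTaxa, nSamples,
              dimnames = list(sprintf("t%03d", seq_len(nTaxa)),
                              sprintf("s%03d", seq_len(nSamples))))
  repeat {
    const <- apply(m, 1L, function(v) length(unique(v)) == 1L)
    if (!any(const)) break
    m[const, ] <- rpois(sum(const) * nSamples, lambda)
  }
  m
}

# SignedNetwork from a 0/1 adjacency matrix (positive unit weights).
netFromAdj <- function(A, kingdom = "bacteria") {
  ids <- rownames(A)
  if (is.null(ids)) ids <- rownames(A) <- colnames(A) <-
      sprintf("n%02d", seq_len(nrow(A)))
  idx <- which(upper.tri(A) & A != 0, arr.ind = TRUE)
  edges <- if (nrow(idx)) {
    data.frame(from = ids[idx[, 1]], to = ids[idx[, 2]], weight = 0.9,
               stringsAsFactors = FALSE)
  } else NULL
  SignedNetwork(data.frame(id = ids, kingdom = kingdom,
                           stringsAsFactors = FALSE), edges)
}

completeAdj <- function(n) {
  A <- matrix(1, n, n) - diag(n)
  dimnames(A) <- list(sprintf("n%02d", 1:n), sprintf("n%02d", 1:n))
  A
}

starAdj <- function(n) {  # node 1 is the hub
  A <- matrix(0, n, n)
  A[1, 2:n] <- A[2:n, 1] <- 1
  dimnames(A) <- list(sprintf("n%02d", 1:n), sprintf("n%02d", 1:n))
  A
}

pathAdj <- function(n) {
  A <- matrix(0, n, n)
  for (i in seq_len(n - 1)) A[i, i + 1] <- A[i + 1, i] <- 1
  dimnames(A) <- list(sprintf("n%02d", 1:n), sprintf("n%02d", 1:n))
  A
}

randomAdj <- function(n, p = 0.25) {
  A <- matrix(0, n, n)
  A[upper.tri(A)] <- rbinom(n * (n - 1) / 2, 1, p)
  A <- A + t(A)
  dimnames(A) <- list(sprintf("n%02d", 1:n), sprintf("n%02d", 1:n))
  A
}

# All-pairs shortest paths by breadth-first search (Inf if unreachable).
bfsDistOracle <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); dist[s] <- 0
    frontier <- s
    while (length(frontier)) {
      nxt <- integer()
      for (u in frontier) {
        for (v in which(A[u, ] != 0)) {
          if (dist[v] > dist[u] + 1) {
            dist[v] <- dist[u] + 1
            nxt <- c(nxt, v)
          }
        }
      }
      frontier <- unique(nxt)
    }
    D[s, ] <- dist
  }
  D
}

efficiencyOracle <- function(A) {
  n <- nrow(A)
  if (n < 2) return(0)
  D <- bfsDistOracle(A)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (is.finite(D[i, j]) && D[i, j] > 0) tot <- tot + 1 / D[i, j]
  2 * tot / (n * (n - 1))
}

vulnerabilityOracle <- function(A) {
  E <- efficiencyOracle(A)
  n <- nrow(A)
  worst <- -Inf
  for (i in seq_len(n)) {
    Ei <- efficiencyOracle(A[-i, -i, drop = FALSE])
    worst <- max(worst, (E - Ei) / E)
  }
  worst
}

# Newman modularity of a given partition, by the definition
# Q = (1/2m) * sum_ij (A_ij - k_i k_j / 2m) * [c_i == c_j].
modularityOracle <- function(A, membership) {
  k <- rowSums(A)
  twoM <- sum(A)
  q <- 0
  n <- nrow(A)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (membership[i] == membership[j])
      q <- q + A[i, j] - k[i] * k[j] / twoM
  }
  unname(q / twoM)
}

# Spearman rho by explicit midranking then Pearson correlation.
spearmanOracle <- function(m) {
  rk <- t(apply(m, 1L, rank))
  cor(t(rk))
}

# All permutations of 1..n via filtering the full n^n grid (independent of
# the package's recursive generator).  Small n only.
permGridOracle <- function(n) {
  g <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  g[apply(g, 1L, function(r) length(unique(r)) == n), , drop = FALSE]
}

# ANOSIM R by direct looping over pairs.
anosimROracle <- function(d, groups) {
  n <- length(groups)
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  rk <- rank(d[upper.tri(d)])
  within <- groups[pairs[, 1]] == groups[pairs[, 2]]
  M <- n * (n - 1) / 2
  (mean(rk[!within]) - mean(rk[within])) / (M / 2)
}

# Closed-form natural connectivity of the complete graph K_n.
natConnKn <- function(n) log((exp(n - 1) + (n - 1) * exp(-1)) / n)

# Euclidean distance matrix of a points-in-rows matrix.
euclidDist <- function(pts) as.matrix(dist(pts))
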