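# Diversity, ordination and permutation statistics supporting the seasonal
# community comparison: richness/Shannon, Bray-Curtis, PCoA, ANOSIM and
# (partial) Mantel tests.  All permutation tests take an explicit seed and
# use the add-one rule p = (1 + #{null >= observed}) / (1 + nPerm); small
# designs can be tested exhaustively with `exact = TRUE`.

#' Observed richness of one sample
#' @param counts non-negative count vector.
#' @return number of taxa with count > 0.
#' @export
richness <- function(counts) {
  stopifnot(all(counts >= 0))
  sum(counts > 0)
}

#' Shannon diversity (natural log) of one sample
#' @param counts non-negative count vector with positive total.
#' @return H = -sum p_i log p_i in nats; lies in [0, log(richness)].
#' @export
shannonIndex <- function(counts) {
  stopifnot(all(counts >= 0))
  if (sum(counts) <= 0) stop("all-zero sample: Shannon index undefined")
  unname(vegan::diversity(counts, index = "shannon"))
}

#' Per-sample diversity table
#' @param x an [OtuExperiment-class].
#' @return data.frame with sample_id, richness, shannon.
#' @export
diversityTable <- function(x) {
  m <- otuCounts(x)
  data.frame(sample_id = colnames(m),
             richness = apply(m, 2L, richness),
             shannon = apply(m, 2L, shannonIndex),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Bray-Curtis dissimilarity between samples
#'
#' d(x, y) = sum|x_i - y_i| / sum(x_i + y_i) over taxa; entries in [0, 1].
#'
#' @param x an [OtuExperiment-class] or taxa-by-samples matrix with at
#'   least 2 samples and no all-zero sample.
#' @return symmetric samples-by-samples matrix with zero diagonal.
#' @export
brayCurtis <- function(x) {
  m <- if (is(x, "OtuExperiment")) otuCounts(x) else as.matrix(x)
  if (ncol(m) < 2L) stop("need at least 2 samples")
  tot <- colSums(m)
  if (any(tot <= 0))
    stop("sample '", colnames(m)[which(tot <= 0)[1L]],
         "' has zero total count")
  as.matrix(vegan::vegdist(t(m), method = "bray"))
}

.checkDistanceMatrix <- function(d) {
  d <- as.matrix(d)
  stopifnot(nrow(d) == ncol(d))
  if (max(abs(d - t(d))) > 1e-10) stop("distance matrix must be symmetric")
  if (any(d < 0)) stop("distances must be non-negative")
  d
}

#' Principal coordinates analysis (classical MDS)
#'
#' Gower double-centering of -d^2/2 followed by eigendecomposition.  Axes
#' are ordered by descending eigenvalue and scaled by the square root of
#' the (positive) eigenvalues, so Euclidean input is reproduced exactly.
#' Axes with negative eigenvalues are dropped (no Lingoes/Cailliez
#' correction); if fewer than `k` positive axes exist the result is
#' truncated and flagged, not an error.
#'
#' @param d symmetric distance matrix.
#' @param k number of axes requested (1 <= k <= n-1).
#' @return list with `coordinates` (samples x kept axes), `eigenvalues`
#'   (all n, descending), `truncated` (TRUE if fewer than `k` positive
#'   axes were available).
#' @export
pcoa <- function(d, k = 2L) {
  d <- .checkDistanceMatrix(d)
  n <- nrow(d)
  stopifnot(k >= 1L, k <= n - 1L)
  A <- -0.5 * d^2
  B <- A - rowMeans(A)
  B <- t(t(B) - colMeans(B))  # == J A J with J = I - 11'/n
  eg <- eigen((B + t(B)) / 2, symmetric = TRUE)
  tol <- 1e-8 * max(abs(eg$values), 1)
  npos <- sum(eg$values > tol)
  kEff <- min(k, npos)
  truncated <- kEff < k
  if (truncated)
    warning("only ", npos, " positive eigenvalue(s); returning ", kEff,
            " axis/axes")
  coords <- if (kEff > 0) {
    sweep(eg$vectors[, seq_len(kEff), drop = FALSE], 2L,
          sqrt(eg$values[seq_len(kEff)]), "*")
  } else {
    matrix(0, n, 0L)
  }
  rownames(coords) <- rownames(d)
  colnames(coords) <- if (kEff > 0) paste0("PCoA", seq_len(kEff))
  list(coordinates = coords, eigenvalues = eg$values, truncated = truncated)
}

.permTestResult <- function(statistic, p, nPerm, seed, method) {
  structure(list(statistic = statistic, p.value = p,
                 n.permutations = nPerm, seed = seed, method = method),
            class = "PermTestResult")
}

#' @export
print.PermTestResult <- function(x, ...) {
  cat(sprintf("%s: statistic = %.6g, p = %.6g (%s permutations)\n",
              x$method, x$statistic, x$p.value,
              format(x$n.permutations, big.mark = ",")))
  invisible(x)
}

# Shared ANOSIM R computation on a rank matrix of distances.
.anosimR <- function(rankMat, groups) {
  n <- length(groups)
  same <- outer(groups, groups, "==")
  ut <- upper.tri(rankMat)
  rW <- mean(rankMat[ut & same])
  rB <- mean(rankMat[ut & !same])
  M <- n * (n - 1) / 2
  (rB - rW) / (M / 2)
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based comparison of between-group vs within-group distances:
#' R = (mean between-group rank - mean within-group rank) / (M/2) with
#' M = n(n-1)/2, ranks taken over all pairwise distances (midranks for
#' ties).  Significance by permuting group labels, one-sided (greater).
#'
#' @param d symmetric distance matrix.
#' @param groups per-sample group labels; every group needs >= 2 samples.
#' @param nPerm number of random permutations (ignored when `exact`).
#' @param seed RNG seed for the permutations.
#' @param exact if TRUE, enumerate all n! label permutations (small n
#'   only) and report p = #{R_perm >= R_obs} / n!.
#' @return a `PermTestResult` (statistic = R in [-1, 1]).
#' @export
anosim <- function(d, groups, nPerm = 999L, seed = 1L, exact = FALSE) {
  d <- .checkDistanceMatrix(d)
  n <- nrow(d)
  groups <- as.character(groups)
  stopifnot(length(groups) == n)
  tab <- table(groups)
  if (length(tab) < 2L) stop("need at least 2 groups")
  if (any(tab < 2L)) stop("every group needs at least 2 samples")
  rankMat <- d
  rankMat[] <- 0
  ut <- upper.tri(d)
  rk <- rank(d[ut])  # midranks
  rankMat[ut] <- rk
  rankMat <- rankMat + t(rankMat)
  obs <- .anosimR(rankMat, groups)
  if (exact) {
    perms <- allPermutations(n)
    stat <- apply(perms, 1L, function(p) .anosimR(rankMat, groups[p]))
    pval <- sum(stat >= obs) / nrow(perms)
    nPerm <- nrow(perms)
  } else {
    stat <- withSeed(seed, vapply(seq_len(nPerm), function(i) {
      .anosimR(rankMat, groups[sample.int(n)])
    }, 0))
    pval <- (1 + sum(stat >= obs)) / (1 + nPerm)
  }
  .permTestResult(obs, pval, nPerm, seed, "ANOSIM")
}

#' Mantel test between two distance matrices
#'
#' Correlation of the upper-triangle vectors; significance by jointly
#' permuting rows and columns of `d2`, one-sided (greater).
#'
#' @param d1,d2 symmetric distance matrices over the same samples (same
#'   order).
#' @param nPerm number of random permutations (ignored when `exact`).
#' @param seed RNG seed.
#' @param method correlation type on the distance vectors (default
#'   Pearson).
#' @param exact if TRUE, enumerate all n! permutations (small n only).
#' @return a `PermTestResult` (statistic = Mantel r).
#' @export
mantel <- function(d1, d2, nPerm = 999L, seed = 1L,
                   method = c("pearson", "spearman"), exact = FALSE) {
  method <- match.arg(method)
  d1 <- .checkDistanceMatrix(d1); d2 <- .checkDistanceMatrix(d2)
  n <- nrow(d1)
  stopifnot(nrow(d2) == n, n >= 4L)
  v1 <- upperTri(d1)
  if (stats::sd(v1) == 0 || stats::sd(upperTri(d2)) == 0)
    stop("constant distance matrix: Mantel correlation undefined")
  obs <- stats::cor(v1, upperTri(d2), method = method)
  statFor <- function(p) stats::cor(v1, upperTri(d2[p, p]), method = method)
  if (exact) {
    perms <- allPermutations(n)
    stat <- apply(perms, 1L, statFor)
    pval <- sum(stat >= obs) / nrow(perms)
    nPerm <- nrow(perms)
  } else {
    stat <- withSeed(seed, vapply(seq_len(nPerm),
                                  function(i) statFor(sample.int(n)), 0))
    pval <- (1 + sum(stat >= obs)) / (1 + nPerm)
  }
  .permTestResult(obs, pval, nPerm, seed, paste0("Mantel (", method, ")"))
}

#' Partial Mantel test
#'
#' Partial correlation of `d1` and `d2` controlling for `d3`,
#' r(12|3) = (r12 - r13 r23) / sqrt((1 - r13^2)(1 - r23^2)) on the
#' upper-triangle vectors; significance by permuting `d2`.
#'
#' @inheritParams mantel
#' @param d3 the control distance matrix.
#' @return a `PermTestResult` (statistic = partial Mantel r).
#' @export
partialMantel <- function(d1, d2, d3, nPerm = 999L, seed = 1L,
                          method = c("pearson", "spearman"), exact = FALSE) {
  method <- match.arg(method)
  d1 <- .checkDistanceMatrix(d1); d2 <- .checkDistanceMatrix(d2)
  d3 <- .checkDistanceMatrix(d3)
  n <- nrow(d1)
  stopifnot(nrow(d2) == n, nrow(d3) == n, n >= 5L)
  v1 <- upperTri(d1); v3 <- upperTri(d3)
  r13 <- stats::cor(v1, v3, method = method)
  if (abs(r13) >= 1 - 1e-12)
    stop("control matrix is perfectly correlated with d1")
  statFor <- function(p) {
    v2 <- upperTri(d2[p, p])
    r12 <- stats::cor(v1, v2, method = method)
    r23 <- stats::cor(v2, v3, method = method)
    num <- r12 - r13 * r23
    den <- sqrt((1 - r13^2) * (1 - r23^2))
    if (den < 1e-12) {
      # d2 collinear with the control: the partial correlation tends to 0
      # when the numerator vanishes with it, and is undefined otherwise
      if (abs(num) < 1e-10) return(0)
      stop("control matrix is perfectly correlated with d2")
    }
    num / den
  }
  obs <- statFor(seq_len(n))
  if (exact) {
    perms <- allPermutations(n)
    stat <- apply(perms, 1L, statFor)
    pval <- sum(stat >= obs) / nrow(perms)
    nPerm <- nrow(perms)
  } else {
    stat <- withSeed(seed, vapply(seq_len(nPerm),
                                  function(i) statFor(sample.int(n)), 0))
    pval <- (1 + sum(stat >= obs)) / (1 + nPerm)
  }
  .permTestResult(obs, pval, nPerm, seed,
                  paste0("Partial Mantel (", method, ")"))
}
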