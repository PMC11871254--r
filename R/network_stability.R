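# The four-index network-stability suite: random-removal robustness,
# efficiency-based vulnerability, natural connectivity (plus its decay
# slope under progressive node removal), and abundance-weighted cohesion
# with a taxa-shuffle null model.  Every stochastic index takes an
# explicit seed.

# Unsigned, unweighted adjacency matrix of a SignedNetwork.
.adjacency <- function(net) {
  ids <- net@nodes$id
  k <- length(ids)
  A <- matrix(0, k, k, dimnames = list(ids, ids))
  ed <- net@edges
  if (nrow(ed)) {
    i <- match(ed$from, ids); j <- match(ed$to, ids)
    A[cbind(i, j)] <- 1; A[cbind(j, i)] <- 1
  }
  A
}

#' Network robustness under random node removal
#'
#' Per trial, `floor(removalFraction * N)` nodes are removed uniformly at
#' random; a surviving node persists iff it keeps at least one edge among
#' the survivors.  Robustness is persisting/N, reported as mean and sd
#' over trials.  An edgeless network has robustness 0.
#'
#' @param net a [SignedNetwork-class] with >= 2 nodes.
#' @param removalFraction fraction of nodes removed, in (0, 1).
#' @param trials number of random removal trials.
#' @param seed RNG seed.
#' @return list with `mean`, `sd`, `trials` (the per-trial values) and
#'   `params`.
#' @export
robustness <- function(net, removalFraction = 0.5, trials = 100L,
                       seed = 1L) {
  stopifnot(is(net, "SignedNetwork"),
            removalFraction > 0, removalFraction < 1, trials >= 1L)
  N <- nNodes(net)
  if (N < 2L) stop("need at least 2 nodes")
  A <- .adjacency(net)
  nRemove <- floor(removalFraction * N)
  vals <- withSeed(seed, vapply(seq_len(trials), function(i) {
    keep <- sort(sample.int(N, N - nRemove))
    if (length(keep) == 0L) return(0)
    deg <- rowSums(A[keep, keep, drop = FALSE])
    sum(deg > 0) / N
  }, 0))
  list(mean = mean(vals), sd = stats::sd(vals), trials = vals,
       params = list(removalFraction = removalFraction,
                     nTrials = trials, seed = seed))
}

# Global efficiency of an adjacency matrix: mean inverse shortest-path
# length over unordered pairs, unreachable pairs contributing 0.
.globalEfficiency <- function(g) {
  N <- igraph::vcount(g)
  if (N < 2L) return(0)
  D <- igraph::distances(g, weights = NA)
  inv <- 1 / D[upper.tri(D)]
  inv[!is.finite(inv)] <- 0
  sum(inv) * 2 / (N * (N - 1))
}

#' Network vulnerability (maximal efficiency loss)
#'
#' Global efficiency E = (2/(N(N-1))) sum 1/d(u,v) over unordered pairs on
#' the unsigned, unweighted skeleton (unreachable pairs contribute 0).
#' Vulnerability is the maximum over nodes i of (E - E_i)/E where E_i is
#' the efficiency of the graph with node i removed.
#'
#' @param net a [SignedNetwork-class] containing a connected component of
#'   at least 3 nodes.
#' @return vulnerability (a single number; 0 for graphs whose node
#'   removals never reduce efficiency, e.g. complete graphs).
#' @export
vulnerability <- function(net) {
  stopifnot(is(net, "SignedNetwork"))
  g <- asIgraph(net)
  N <- igraph::vcount(g)
  if (N < 3L) stop("need at least 3 nodes")
  if (max(igraph::components(g)$csize) < 3L)
    stop("need a connected component with at least 3 nodes")
  E <- .globalEfficiency(g)
  drop <- vapply(seq_len(N), function(i) {
    .globalEfficiency(igraph::delete_vertices(g, i))
  }, 0)
  max((E - drop) / E)
}

#' Natural connectivity of a network
#'
#' The logarithm of the average exponentiated adjacency eigenvalue,
#' lambda-bar = ln((1/N) sum_i exp(lambda_i)), computed on the unsigned,
#' unweighted adjacency matrix with a log-sum-exp for stability.  A
#' spectral measure of path redundancy: 0 for an edgeless graph, larger
#' for denser, better-connected graphs.
#'
#' @param net a [SignedNetwork-class], an adjacency matrix, or an igraph
#'   graph.
#' @return lambda-bar (a single number).
#' @export
naturalConnectivity <- function(net) {
  A <- if (is(net, "SignedNetwork")) .adjacency(net)
  else if (inherits(net, "igraph"))
    as.matrix(igraph::as_adjacency_matrix(net))
  else as.matrix(net)
  if (nrow(A) == 0L) stop("empty network")
  A <- (A != 0) * 1
  diag(A) <- 0
  ev <- eigen((A + t(A)) / 2, symmetric = TRUE, only.values = TRUE)$values
  logMeanExp(ev)
}

#' Natural-connectivity decay under progressive random removal
#'
#' Per trial, nodes are removed one at a time in uniform random order up
#' to `floor(maxRemovedFraction * N)` removals, recording natural
#' connectivity of the remaining graph after each removal.  The series is
#' the mean lambda-bar at each removal count; the decay slope is the OLS
#' slope of mean lambda-bar against the number removed, with the Pearson
#' R of that fit.
#'
#' @param net a [SignedNetwork-class] with >= 5 nodes.
#' @param maxRemovedFraction furthest removal point, in (0, 1).
#' @param trials number of random removal orders.
#' @param seed RNG seed.
#' @return list with `series` (data.frame n_removed, lambda_bar),
#'   `slope`, `r` (Pearson R of the linear fit) and `params`.
#' @export
naturalConnectivityDecay <- function(net, maxRemovedFraction = 0.8,
                                     trials = 20L, seed = 1L) {
  stopifnot(is(net, "SignedNetwork"),
            maxRemovedFraction > 0, maxRemovedFraction < 1)
  N <- nNodes(net)
  if (N < 5L) stop("need at least 5 nodes")
  A <- .adjacency(net)
  m <- floor(maxRemovedFraction * N)
  stopifnot(m >= 2L)
  mat <- withSeed(seed, {
    out <- matrix(0, trials, m)
    for (tr in seq_len(trials)) {
      ord <- sample.int(N)
      for (r in seq_len(m)) {
        keep <- ord[(r + 1L):N]
        sub <- A[keep, keep, drop = FALSE]
        ev <- eigen(sub, symmetric = TRUE, only.values = TRUE)$values
        out[tr, r] <- logMeanExp(ev)
      }
    }
    out
  })
  series <- data.frame(n_removed = seq_len(m), lambda_bar = colMeans(mat))
  fit <- stats::lm(lambda_bar ~ n_removed, data = series)
  list(series = series,
       slope = unname(stats::coef(fit)[2L]),
       r = stats::cor(series$n_removed, series$lambda_bar),
       params = list(maxRemovedFraction = maxRemovedFraction,
                     nTrials = trials, seed = seed))
}

#' Community cohesion with a taxa-shuffle null model
#'
#' On relative abundances: (1) observed pairwise Pearson correlations
#' between taxa across samples; (2) a null expectation per pair from
#' `nullIters` iterations in which each taxon's abundance vector is
#' independently permuted across samples; (3) corrected correlations
#' r' = r - mean_null(r); (4) per-taxon connectedness: the mean of its
#' positive r' (and, separately, of its negative r') to all other taxa,
#' 0 when there are none; (5) per-sample cohesion: the abundance-weighted
#' sum C_pos(i) = sum_j ra_ij * connectedness_pos(j) (likewise C_neg).
#' The negative:positive ratio |C_neg|/C_pos is reported per sample with
#' its mean and sd; samples with C_pos = 0 are excluded and counted.
#'
#' With `nullCorrection = "pair"` (the classical method and the default)
#' the null expectation is subtracted per correlation pair; note the
#' resulting positive/negative components retain a sampling baseline of
#' order 1/sqrt(n_samples) even on structureless data, because the
#' positive part of a zero-mean correlation has positive expectation.
#' `nullCorrection = "connectedness"` instead subtracts the taxa-shuffle
#' null expectation of each taxon's connectedness, which calibrates the
#' components to ~0 on structureless data (at the cost that per-sample
#' components are no longer sign-constrained).
#'
#' @param x an [OtuExperiment-class] (or count/abundance matrix) with
#'   >= 5 samples.
#' @param nullIters taxa-shuffle iterations (>= 200 recommended).
#' @param seed RNG seed for the shuffles.
#' @param nullCorrection where the taxa-shuffle null expectation is
#'   subtracted: `"pair"` (default, classical) or `"connectedness"`.
#' @return list with `cohesionPos`, `cohesionNeg` (per sample),
#'   `connectednessPos`, `connectednessNeg` (per taxon), `ratio` (per
#'   sample, NA where undefined), `ratioMean`, `ratioSd`, `nExcluded`
#'   and `params`.
#' @export
cohesion <- function(x, nullIters = 200L, seed = 1L,
                     nullCorrection = c("pair", "connectedness")) {
  nullCorrection <- match.arg(nullCorrection)
  ra <- relativeAbundance(x)
  n <- ncol(ra)
  if (n < 5L) stop("need at least 5 samples for cohesion")
  varOk <- apply(ra, 1L, stats::sd) > 0
  if (!any(varOk)) stop("no taxon varies across samples")
  raV <- ra[varOk, , drop = FALSE]
  obs <- stats::cor(t(raV))
  posPart <- function(v) { v <- v[v > 0]; if (length(v)) mean(v) else 0 }
  negPart <- function(v) { v <- v[v < 0]; if (length(v)) mean(v) else 0 }
  connOf <- function(r) {
    diag(r) <- 0
    list(pos = apply(r, 1L, posPart), neg = apply(r, 1L, negPart))
  }
  kT <- nrow(raV)
  nullAcc <- withSeed(seed, {
    accR <- matrix(0, kT, kT)
    accPos <- accNeg <- numeric(kT)
    for (it in seq_len(nullIters)) {
      shuf <- t(apply(raV, 1L, sample))
      rN <- stats::cor(t(shuf))
      accR <- accR + rN
      if (nullCorrection == "connectedness") {
        cN <- connOf(rN)
        accPos <- accPos + cN$pos
        accNeg <- accNeg + cN$neg
      }
    }
    list(r = accR / nullIters, pos = accPos / nullIters,
         neg = accNeg / nullIters)
  })
  if (nullCorrection == "pair") {
    rp <- obs - nullAcc$r
    cc <- connOf(rp)
    connPos <- cc$pos
    connNeg <- cc$neg
  } else {
    cObs <- connOf(obs)
    connPos <- cObs$pos - nullAcc$pos
    connNeg <- cObs$neg - nullAcc$neg
  }
  # taxa with no variation contribute zero connectedness
  cp <- stats::setNames(numeric(nrow(ra)), rownames(ra))
  cn <- cp
  cp[rownames(raV)] <- connPos
  cn[rownames(raV)] <- connNeg
  Cpos <- as.numeric(crossprod(ra, cp))
  Cneg <- as.numeric(crossprod(ra, cn))
  names(Cpos) <- names(Cneg) <- colnames(ra)
  ratio <- ifelse(Cpos > 0, abs(Cneg) / Cpos, NA_real_)
  nExcluded <- sum(is.na(ratio))
  if (nExcluded > 0)
    warning(nExcluded, " sample(s) with zero positive cohesion excluded ",
            "from the ratio")
  list(cohesionPos = Cpos, cohesionNeg = Cneg,
       connectednessPos = cp, connectednessNeg = cn,
       ratio = ratio,
       ratioMean = mean(ratio, na.rm = TRUE),
       ratioSd = stats::sd(ratio[!is.na(ratio)]),
       nExcluded = nExcluded,
       params = list(nullIters = nullIters, seed = seed,
                     nullCorrection = nullCorrection))
}

#' Compare stability replicates across conditions (letter display)
#'
#' One-way ANOVA across conditions on per-trial stability replicates
#' (e.g. the robustness trials).  If the ANOVA is significant at `alpha`,
#' pairwise Welch t-tests with Holm correction define the groups; letters
#' are assigned deterministically in order of descending mean, with
#' conditions that are not significantly different sharing a letter.
#'
#' @param replicates named list (condition -> numeric vector of
#'   replicates, each of length >= 2).
#' @param alpha significance level.
#' @return list with `letters` (data.frame condition/mean/letters, in
#'   descending-mean order), `anovaF`, `anovaP`.
#' @export
compareStability <- function(replicates, alpha = 0.05) {
  stopifnot(is.list(replicates), length(replicates) >= 2L,
            !is.null(names(replicates)))
  if (any(vapply(replicates, length, 0L) < 2L))
    stop("every condition needs at least 2 replicates")
  df <- data.frame(
    value = unlist(replicates, use.names = FALSE),
    condition = factor(rep(names(replicates),
                           vapply(replicates, length, 0L))))
  fit <- stats::aov(value ~ condition, data = df)
  an <- summary(fit)[[1L]]
  Fv <- an[["F value"]][1L]
  pv <- an[["Pr(>F)"]][1L]
  means <- vapply(replicates, mean, 0)
  ord <- names(sort(means, decreasing = TRUE))
  if (is.na(pv) || pv >= alpha) {
    letters <- stats::setNames(rep("a", length(ord)), ord)
  } else {
    pw <- stats::pairwise.t.test(df$value, df$condition, pool.sd = FALSE,
                                 p.adjust.method = "holm")$p.value
    lookup <- function(a, b) {
      p <- NA_real_
      if (a %in% rownames(pw) && b %in% colnames(pw) && !is.na(pw[a, b]))
        p <- pw[a, b]
      else if (b %in% rownames(pw) && a %in% colnames(pw) &&
               !is.na(pw[b, a]))
        p <- pw[b, a]
      p
    }
    groups <- list()
    for (cond in ord) {
      joined <- FALSE
      for (gi in seq_along(groups)) {
        if (all(vapply(groups[[gi]],
                       function(m) isTRUE(lookup(cond, m) >= alpha),
                       TRUE))) {
          groups[[gi]] <- c(groups[[gi]], cond)
          joined <- TRUE
        }
      }
      if (!joined) groups[[length(groups) + 1L]] <- cond
    }
    pool <- base::letters
    letters <- stats::setNames(vapply(ord, function(cond) {
      paste(pool[which(vapply(groups, function(g) cond %in% g, TRUE))],
            collapse = "")
    }, ""), ord)
  }
  list(letters = data.frame(condition = ord, mean = means[ord],
                            letters = unname(letters[ord]),
                            row.names = NULL, stringsAsFactors = FALSE),
       anovaF = Fv, anovaP = pv)
}
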