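# The four stability indices and the cross-condition letter display.

test_that("robustness is exact on complete and edgeless graphs", {
  rb <- robustness(netFromAdj(completeAdj(10)), removalFraction = 0.5,
                   trials = 50, seed = 1)
  expect_true(all(rb$trials == 0.5))
  expect_equal(rb$sd, 0)
  empty <- SignedNetwork(data.frame(id = paste0("n", 1:6),
                                    kingdom = "bacteria"))
  expect_equal(robustness(empty, trials = 10, seed = 1)$mean, 0)
})

test_that("robustness agrees with exhaustive enumeration on the 5-star", {
  # remove 2 of 5: enumerate all C(5,2) = 10 removal sets
  A <- starAdj(5)
  sets <- combn(5, 2)
  vals <- apply(sets, 2, function(rm) {
    keep <- setdiff(1:5, rm)
    sub <- A[keep, keep]
    sum(rowSums(sub) > 0) / 5
  })
  exact <- mean(vals)
  rb <- robustness(netFromAdj(A), removalFraction = 0.4, trials = 1000,
                   seed = 2)
  se <- sd(rb$trials) / sqrt(length(rb$trials))
  expect_lt(abs(rb$mean - exact), 3 * se + 1e-12)
  # determinism
  rb2 <- robustness(netFromAdj(A), removalFraction = 0.4, trials = 1000,
                    seed = 2)
  expect_identical(rb$trials, rb2$trials)
})

test_that("robustness Monte-Carlo mean is stable as trials double", {
  set.seed(51)
  net <- netFromAdj(randomAdj(20, 0.15))
  r1 <- robustness(net, trials = 200, seed = 3)
  r2 <- robustness(net, trials = 400, seed = 4)
  expect_lt(abs(r1$mean - r2$mean), 3 * r1$sd / sqrt(200) + 1e-12)
  # survivors can never exceed the unremoved fraction
  expect_lte(r1$mean, 0.5 + 1e-12)
})

test_that("vulnerability matches hand values and a BFS oracle", {
  expect_equal(vulnerability(netFromAdj(completeAdj(5))), 0)
  expect_equal(vulnerability(netFromAdj(pathAdj(3))), 1)
  set.seed(52)
  tried <- 0
  for (i in 1:20) {
    A <- randomAdj(12, p = 0.25)
    if (max(igraph::components(
      igraph::graph_from_adjacency_matrix(A, "undirected"))$csize) < 3)
      next
    tried <- tried + 1
    expect_equal(vulnerability(netFromAdj(A)), vulnerabilityOracle(A),
                 tolerance = 1e-12)
  }
  expect_gte(tried, 15)
  expect_error(vulnerability(netFromAdj(matrix(0, 2, 2))), "at least 3")
})

test_that("natural connectivity matches closed forms", {
  # edgeless graph: all eigenvalues zero
  empty <- SignedNetwork(data.frame(id = paste0("n", 1:7),
                                    kingdom = "bacteria"))
  expect_equal(naturalConnectivity(empty), 0, tolerance = 1e-12)
  # complete graphs: spectrum {n-1, -1 x (n-1)}
  for (n in c(3, 4, 10, 20)) {
    expect_equal(naturalConnectivity(netFromAdj(completeAdj(n))),
                 natConnKn(n), tolerance = 1e-9)
  }
  # one edge plus isolates: spectrum {+1, -1, 0...}
  for (N in c(4, 9)) {
    A <- matrix(0, N, N); A[1, 2] <- A[2, 1] <- 1
    dimnames(A) <- list(paste0("n", 1:N), paste0("n", 1:N))
    expect_equal(naturalConnectivity(netFromAdj(A)),
                 log((exp(1) + exp(-1) + N - 2) / N), tolerance = 1e-12)
  }
})

test_that("natural-connectivity decay is seeded and monotone on K20", {
  net <- netFromAdj(completeAdj(20))
  d1 <- naturalConnectivityDecay(net, trials = 5, seed = 9)
  d2 <- naturalConnectivityDecay(net, trials = 5, seed = 9)
  expect_identical(d1$series, d2$series)
  # K_n shrinks strictly along any removal order
  expect_true(all(diff(d1$series$lambda_bar) < 0))
  expect_lt(d1$slope, 0)
  # the reported slope is the closed-form OLS slope of the series
  x <- d1$series$n_removed; y <- d1$series$lambda_bar
  beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(d1$slope, beta, tolerance = 1e-12)
  expect_equal(d1$r, cor(x, y), tolerance = 1e-12)
})

test_that("cohesion ranks planted co-varying taxa above independent filler", {
  set.seed(53)
  base <- cumsum(rnorm(36))            # a shared trajectory
  pack <- rbind(p1 = 60 + 12 * base, p2 = 55 + 11 * base,
                p3 = 70 + 13 * base)
  pack <- pmax(round(pack), 1)
  filler <- matrix(rpois(8 * 36, 40), 8, 36,
                   dimnames = list(paste0("f", 1:8), NULL))
  m <- rbind(pack, filler)
  colnames(m) <- paste0("s", 1:36)
  co <- cohesion(m, nullIters = 100, seed = 1)
  expect_gt(min(co$connectednessPos[c("p1", "p2", "p3")]),
            max(co$connectednessPos[paste0("f", 1:8)]))
  expect_true(all(co$cohesionPos >= 0))
  expect_true(all(co$cohesionNeg <= 0))
})

test_that("cohesion is stable under sample relabelling", {
  set.seed(54)
  m <- randomCountTable(10, 12, lambda = 30)
  perm <- sample(ncol(m))
  c1 <- cohesion(m, nullIters = 600, seed = 2)
  c2 <- cohesion(m[, perm], nullIters = 600, seed = 2)
  # observed correlations are permutation-invariant; only the Monte-Carlo
  # null estimate moves, so per-sample values agree up to null noise
  expect_lt(max(abs(unname(c2$cohesionPos) - unname(c1$cohesionPos[perm]))),
            0.02)
  expect_lt(max(abs(unname(c2$cohesionNeg) - unname(c1$cohesionNeg[perm]))),
            0.02)
})

test_that("the null neg:pos cohesion ratio stays of order unity", {
  # structureless (taxa-shuffled) input: the classical pair-level
  # correction leaves positive and negative components with comparable
  # magnitudes, so the ratio sits near 1 (slightly above it on
  # compositional data, where closure tilts correlations negative)
  set.seed(55)
  rs <- vapply(1:8, function(s) {
    m <- randomCountTable(25, 36, lambda = 60)
    shuffled <- t(apply(m, 1, sample))
    dimnames(shuffled) <- dimnames(m)
    suppressWarnings(cohesion(shuffled, nullIters = 100,
                              seed = s)$ratioMean)
  }, 0)
  expect_true(all(rs > 0.7 & rs < 1.6))
})

test_that("connectedness-level null correction calibrates to zero", {
  set.seed(56)
  vals <- replicate(5, {
    m <- randomCountTable(30, 36, lambda = 50)
    co <- suppressWarnings(
      cohesion(m, nullIters = 200, seed = sample.int(1e6, 1),
               nullCorrection = "connectedness"))
    c(mean(co$cohesionPos), mean(co$cohesionNeg))
  })
  expect_lt(abs(mean(vals[1, ])), 0.02)
  expect_lt(abs(mean(vals[2, ])), 0.02)
})

test_that("stability comparison assigns deterministic letter groups", {
  same <- list(a = rep(0.5, 20), b = rep(0.5, 20), c = rep(0.5, 20))
  cs <- compareStability(same)
  expect_true(all(cs$letters$letters == "a"))

  set.seed(57)
  far <- list(high = rnorm(100, 0.5, 0.01), low = rnorm(100, 0.1, 0.01))
  cs2 <- compareStability(far)
  expect_lt(cs2$anovaP, 1e-10)
  expect_false(cs2$letters$letters[1] == cs2$letters$letters[2])
  expect_equal(cs2$letters$condition[1], "high")  # descending mean order

  # ANOVA F matches the textbook decomposition on a hand-made 2x3 layout
  reps <- list(g1 = c(1, 2, 3), g2 = c(2, 3, 4))
  cs3 <- compareStability(reps)
  grand <- mean(unlist(reps))
  ssb <- sum(vapply(reps, function(v) length(v) * (mean(v) - grand)^2, 0))
  ssw <- sum(vapply(reps, function(v) sum((v - mean(v))^2), 0))
  expect_equal(cs3$anovaF, (ssb / 1) / (ssw / 4), tolerance = 1e-12)
  expect_error(compareStability(list(a = 1, b = c(1, 2))), "at least 2")
})

test_that("the +BP robustness comparison yields a defined letter outcome", {
  # weak coupling: +BP should not change the robustness letter; under a
  # strong planted hub the pipeline must still produce defined letters
  for (rho in c(0.2, 0.65)) {
    links <- lapply(sprintf("B%03d", 1:2), function(b)
      list(predator = "P001", prey = b, rho = rho))
    cfg <- simConfig(nBacteria = 15, nProtists = 3, nBacterivores = 3,
                     seqDepth = 20000, seasonEffectSd = 0,
                     modules = list(list(taxa = sprintf("B%03d", 5:10),
                                         rho = 0.8)),
                     trophicLinks = links, seed = 61)
    g <- generateCommunity(cfg)
    otu <- filterPrevalence(g$otu, minSamples = 1)
    bact <- otu[kingdom(otu) == "bacteria", ]
    bp <- otu[kingdom(otu) == "protist", ]
    solo <- buildNetwork(spearmanMatrix(bact), kingdom = kingdom(bact))
    aug <- augmentWithBp(bact, bp)
    cmp <- compareStability(list(
      bacteria = robustness(solo, trials = 50, seed = 1)$trials,
      bp_added = robustness(aug, trials = 50, seed = 2)$trials))
    expect_true(all(nchar(cmp$letters$letters) >= 1))
    if (rho == 0.2)
      expect_true(any(grepl("a", cmp$letters$letters)))
  }
})
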