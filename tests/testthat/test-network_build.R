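# Spearman correlation, threshold networks, single-kingdom and +BP
# variants, and the cross-kingdom census.

test_that("Spearman matrix matches a midrank-then-Pearson oracle", {
  m <- rbind(up = 1:6, up2 = c(2, 4, 6, 8, 10, 12), down = 6:1)
  colnames(m) <- paste0("s", 1:6)
  cr <- spearmanMatrix(m)
  expect_equal(cr@rho["up", "up2"], 1)
  expect_equal(cr@rho["up", "down"], -1)
  expect_equal(cr@p["up", "down"], 0)
  expect_equal(diag(cr@rho), setNames(rep(1, 3), rownames(m)))

  # ties handled by midranks
  a <- c(3, 3, 1, 5, 2, 8, 8, 4, 6)
  b <- c(2, 7, 7, 1, 5, 5, 9, 3, 3)
  mt <- rbind(a = a, b = b); colnames(mt) <- paste0("s", 1:9)
  expect_equal(spearmanMatrix(mt)@rho["a", "b"],
               cor(rank(a), rank(b)), tolerance = 1e-12)

  # brute-force oracle over random tables, and t-approximation p-values
  set.seed(21)
  for (i in 1:10) {
    r <- randomCountTable(10, 9)
    cr <- spearmanMatrix(r)
    expect_equal(cr@rho, spearmanOracle(r), tolerance = 1e-12)
    rho <- cr@rho[1, 2]
    tt <- rho * sqrt((9 - 2) / (1 - rho^2))
    expect_equal(cr@p[1, 2], 2 * pt(-abs(tt), 7), tolerance = 1e-12)
  }

  const <- rbind(c = rep(4, 6), v = 1:6)
  colnames(const) <- paste0("s", 1:6)
  expect_error(spearmanMatrix(const), "'c'")
  expect_error(spearmanMatrix(m[, 1:3]), "at least 4 samples")
})

test_that("network construction thresholds strictly on |rho| and p", {
  ids <- paste0("t", 1:4)
  rho <- diag(4)
  rho[1, 2] <- rho[2, 1] <- 0.9
  rho[3, 4] <- rho[4, 3] <- -0.7
  rho[1, 3] <- rho[3, 1] <- 0.6     # at the boundary: excluded (strict)
  rho[2, 4] <- rho[4, 2] <- 0.95
  p <- matrix(0.001, 4, 4); diag(p) <- 0
  p[2, 4] <- p[4, 2] <- 0.2          # fails the p threshold
  dimnames(rho) <- dimnames(p) <- list(ids, ids)
  cr <- new("CorrelationResult", taxonIds = ids, rho = rho, p = p,
            nSamples = 9L)
  net <- buildNetwork(cr, kingdom = rep("bacteria", 4))
  ed <- networkEdges(net)
  expect_equal(nrow(ed), 2L)
  key <- paste(pmin(ed$from, ed$to), pmax(ed$from, ed$to))
  expect_setequal(key, c("t1 t2", "t3 t4"))
  expect_equal(nNodes(net), 4L)  # isolated nodes retained
  expect_identical(ed$sign, ifelse(ed$weight >= 0, "+", "-"))

  # all |rho| <= 0.6: no edges, all nodes isolated
  rho0 <- diag(4); rho0[upper.tri(rho0)] <- 0.5
  rho0[lower.tri(rho0)] <- t(rho0)[lower.tri(rho0)]
  dimnames(rho0) <- list(ids, ids)
  cr0 <- new("CorrelationResult", taxonIds = ids, rho = rho0,
             p = p * 0, nSamples = 9L)
  net0 <- buildNetwork(cr0, kingdom = rep("bacteria", 4))
  expect_equal(nEdges(net0), 0L)
  expect_equal(nNodes(net0), 4L)
})

test_that("edge selection matches a brute-force double loop", {
  set.seed(22)
  for (rep in 1:5) {
    k <- 12
    r <- randomCountTable(k, 9)
    cr <- spearmanMatrix(r)
    net <- buildNetwork(cr, rMin = 0.5, pMax = 0.1,
                        kingdom = rep("bacteria", k))
    cnt <- 0L
    for (i in 1:(k - 1)) for (j in (i + 1):k)
      if (abs(cr@rho[i, j]) > 0.5 && cr@p[i, j] < 0.1) cnt <- cnt + 1L
    expect_equal(nEdges(net), cnt)
    # positive and negative fractions partition the edge set
    ed <- networkEdges(net)
    if (nrow(ed))
      expect_equal(sum(ed$sign == "+") + sum(ed$sign == "-"), nrow(ed))
  }
})

test_that("edge set is invariant under taxon reordering", {
  set.seed(23)
  r <- randomCountTable(10, 9)
  cr1 <- spearmanMatrix(r)
  perm <- sample(nrow(r))
  cr2 <- spearmanMatrix(r[perm, ])
  n1 <- buildNetwork(cr1, rMin = 0.5, pMax = 0.1,
                     kingdom = rep("bacteria", 10))
  n2 <- buildNetwork(cr2, rMin = 0.5, pMax = 0.1,
                     kingdom = rep("bacteria", 10))
  key <- function(net) {
    ed <- networkEdges(net)
    sort(paste(pmin(ed$from, ed$to), pmax(ed$from, ed$to)))
  }
  expect_identical(key(n1), key(n2))
})

test_that("single-kingdom networks are induced subgraphs", {
  nodes <- data.frame(id = c("b1", "b2", "b3", "p1", "p2"),
                      kingdom = c("bacteria", "bacteria", "bacteria",
                                  "protist", "protist"))
  edges <- data.frame(from = c("b1", "b2", "b1", "p1"),
                      to = c("b2", "b3", "p1", "p2"),
                      weight = c(0.8, -0.7, 0.9, 0.65))
  net <- SignedNetwork(nodes, edges)
  sub <- singleKingdom(net, "bacteria")
  expect_equal(nNodes(sub), 3L)
  ed <- networkEdges(sub)
  # an edge survives iff both endpoints are bacterial
  kd <- setNames(nodes$kingdom, nodes$id)
  keepOracle <- sum(kd[edges$from] == "bacteria" &
                      kd[edges$to] == "bacteria")
  expect_equal(nrow(ed), keepOracle)
  expect_false("p1" %in% c(ed$from, ed$to))
  # all-bacteria network: identity
  bn <- SignedNetwork(nodes[1:3, ], edges[1:2, ])
  expect_equal(nEdges(singleKingdom(bn, "bacteria")), 2L)
  expect_error(singleKingdom(bn, "protist"), "no nodes")
})

test_that("+BP augmentation adds only cross-kingdom relations by default", {
  # a planted strong bacterivore-bacterium link appears in the +BP network
  # and cannot appear in the single-kingdom network
  cfg <- simConfig(nBacteria = 12, nProtists = 4, nBacterivores = 4,
                   seqDepth = 30000, seasonEffectSd = 0,
                   trophicLinks = list(list(predator = "P001",
                                            prey = "B001", rho = 0.95)),
                   seed = 31)
  g <- generateCommunity(cfg)
  otu <- filterPrevalence(g$otu, minSamples = 1)
  bact <- otu[kingdom(otu) == "bacteria", ]
  bp <- otu[kingdom(otu) == "protist", ]
  aug <- augmentWithBp(bact, bp)
  solo <- buildNetwork(spearmanMatrix(bact), kingdom = kingdom(bact))
  ed <- networkEdges(aug)
  key <- paste(pmin(ed$from, ed$to), pmax(ed$from, ed$to))
  expect_true("B001 P001" %in% key)
  edS <- networkEdges(solo)
  expect_false(any(grepl("^P", c(edS$from, edS$to))))
  # node bookkeeping: all retained bacteria plus all retained BP taxa
  expect_equal(nNodes(aug), nrow(bact) + nrow(bp))
  # BP-BP edges excluded by default, admitted behind the flag
  kd <- setNames(networkNodes(aug)$kingdom, networkNodes(aug)$id)
  expect_false(any(kd[ed$from] == "protist" & kd[ed$to] == "protist"))
  aug2 <- augmentWithBp(bact, bp, includeBpBp = TRUE)
  expect_gte(nEdges(aug2), nEdges(aug))
  # mismatched samples are rejected
  expect_error(augmentWithBp(bact, bp[, 1:10]), "same samples")
})

test_that("cross-kingdom census groups by the protist endpoint's mode", {
  nodes <- data.frame(id = c("b1", "b2", "p1", "p2", "p3"),
                      kingdom = c("bacteria", "bacteria", "protist",
                                  "protist", "protist"),
                      functional_group = c(NA, NA, "phototroph",
                                           "phototroph", "bacterivore"))
  edges <- data.frame(from = c("b1", "b2", "b1", "b1"),
                      to = c("p1", "p2", "p3", "b2"),
                      weight = c(0.7, 0.8, -0.9, 0.85))
  net <- SignedNetwork(nodes, edges)
  cen <- crossKingdomEdgeCensus(net)
  got <- setNames(cen$n_edges, cen$functional_group)
  expect_equal(unname(got["phototroph"]), 2L)
  expect_equal(unname(got["bacterivore"]), 1L)
  expect_equal(sum(cen$n_edges), 3L)  # conservation: sum == cross total
  # no cross edges: all zeros
  bn <- SignedNetwork(nodes[1:2, ], edges[4, ])
  expect_true(all(crossKingdomEdgeCensus(bn)$n_edges == 0L))
  # unmapped protists count as unknown
  nodes2 <- nodes; nodes2$functional_group[3] <- NA
  cen2 <- crossKingdomEdgeCensus(SignedNetwork(nodes2, edges))
  expect_equal(cen2$n_edges[cen2$functional_group == "unknown"], 1L)
})

test_that("networks round-trip as edge/node TSVs", {
  nodes <- data.frame(id = c("a", "b"), kingdom = "bacteria")
  net <- SignedNetwork(nodes, data.frame(from = "a", to = "b",
                                         weight = -0.8))
  ef <- tempfile(); nf <- tempfile()
  writeNetwork(net, ef, nf)
  ed <- read.delim(ef)
  expect_equal(ed$source, "a")
  expect_equal(ed$sign, "-")
  expect_equal(nrow(read.delim(nf)), 2L)
})
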