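# Signed Spearman co-occurrence networks: pairwise correlation, threshold
# network construction (|rho| > 0.6, p < 0.05 by default), single-kingdom
# and bacterivore-augmented ("+BP") variants, and the cross-kingdom edge
# census by protist functional group.

#' Pairwise Spearman correlation matrix with t-approximation p-values
#'
#' rho is Pearson correlation on midranks (average ranks for ties); the
#' two-sided p-value uses t = r sqrt((n-2)/(1-r^2)) with n-2 degrees of
#' freedom, and p = 0 when |rho| = 1.  Constant taxa have no defined rank
#' correlation and raise an error naming the taxon — filter first (see
#' [filterPrevalence()]).
#'
#' @param x an [OtuExperiment-class] or taxa-by-samples matrix with >= 4
#'   samples.
#' @return a [CorrelationResult-class].
#' @export
spearmanMatrix <- function(x) {
  m <- if (is(x, "OtuExperiment")) otuCounts(x) else as.matrix(x)
  n <- ncol(m)
  if (n < 4L) stop("need at least 4 samples for correlation networks")
  constant <- apply(m, 1L, function(v) length(unique(v)) == 1L)
  if (any(constant))
    stop("taxon '", rownames(m)[which(constant)[1L]],
         "' is constant across samples; Spearman correlation is undefined")
  rho <- stats::cor(t(m), method = "spearman")
  rho <- (rho + t(rho)) / 2
  rho[rho > 1] <- 1; rho[rho < -1] <- -1
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, 0))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(rho) >= 1 - 1e-15] <- 0
  diag(rho) <- 1; diag(p) <- 0
  new("CorrelationResult", taxonIds = rownames(m), rho = rho, p = p,
      nSamples = as.integer(n))
}

#' Threshold a correlation matrix into a signed network
#'
#' An edge joins taxa i and j iff |rho_ij| > `rMin` AND p_ij < `pMax`
#' (strict inequalities).  Isolated nodes are retained.  Edge weight is
#' rho; edge sign is the sign of rho.
#'
#' @param corr a [CorrelationResult-class].
#' @param rMin correlation-magnitude threshold in (0, 1).
#' @param pMax p-value threshold in (0, 1).
#' @param kingdom named (or positionally matching) per-taxon kingdom
#'   labels.
#' @param functionalGroup optional named per-taxon feeding-mode labels.
#' @param bhCorrect if TRUE, Benjamini-Hochberg adjust the upper-triangle
#'   p-values before thresholding (the classical criterion uses raw p).
#' @return a [SignedNetwork-class].
#' @export
buildNetwork <- function(corr, rMin = 0.6, pMax = 0.05, kingdom,
                         functionalGroup = NULL, bhCorrect = FALSE) {
  stopifnot(is(corr, "CorrelationResult"),
            rMin > 0, rMin < 1, pMax > 0, pMax < 1)
  ids <- corr@taxonIds
  if (!is.null(names(kingdom))) kingdom <- kingdom[ids]
  stopifnot(length(kingdom) == length(ids))
  fg <- if (is.null(functionalGroup)) rep(NA_character_, length(ids)) else {
    if (!is.null(names(functionalGroup))) unname(functionalGroup[ids])
    else functionalGroup
  }
  p <- corr@p
  if (bhCorrect) {
    ut <- upper.tri(p)
    adj <- stats::p.adjust(p[ut], method = "BH")
    p[ut] <- adj
    p[lower.tri(p)] <- t(p)[lower.tri(p)]
  }
  sel <- which(upper.tri(p) & abs(corr@rho) > rMin & p < pMax, arr.ind = TRUE)
  nodes <- data.frame(id = ids, kingdom = as.character(kingdom),
                      functional_group = fg, stringsAsFactors = FALSE)
  edges <- if (nrow(sel)) {
    data.frame(from = ids[sel[, 1L]], to = ids[sel[, 2L]],
               weight = corr@rho[sel], stringsAsFactors = FALSE)
  } else NULL
  SignedNetwork(nodes, edges)
}

#' Induced single-kingdom subnetwork
#'
#' @param net a [SignedNetwork-class].
#' @param kingdom kingdom to retain (`"bacteria"` or `"protist"`).
#' @return the induced subgraph: nodes of that kingdom and edges with both
#'   endpoints retained.
#' @export
singleKingdom <- function(net, kingdom) {
  stopifnot(is(net, "SignedNetwork"), kingdom %in% KINGDOMS)
  nodes <- net@nodes[net@nodes$kingdom == kingdom, , drop = FALSE]
  if (nrow(nodes) == 0L) stop("no nodes of kingdom '", kingdom, "'")
  keep <- net@edges$from %in% nodes$id & net@edges$to %in% nodes$id
  SignedNetwork(nodes, net@edges[keep, , drop = FALSE])
}

#' Bacterial network augmented with bacterivorous protozoans (+BP)
#'
#' Spearman correlations are computed jointly on the concatenated
#' bacteria + BP table; the network keeps bacteria-bacteria and
#' bacteria-BP edges passing the thresholds.  BP-BP edges are excluded by
#' default ("adding BP relationships to the bacterial community") but can
#' be kept with `includeBpBp = TRUE`.
#'
#' @param bact bacterial [OtuExperiment-class].
#' @param bp bacterivorous-protist [OtuExperiment-class] over the same
#'   samples.
#' @inheritParams buildNetwork
#' @param includeBpBp keep protist-protist edges as well.
#' @return a [SignedNetwork-class] whose node set is all retained bacteria
#'   plus all retained BP taxa.
#' @export
augmentWithBp <- function(bact, bp, rMin = 0.6, pMax = 0.05,
                          includeBpBp = FALSE, bhCorrect = FALSE) {
  stopifnot(is(bact, "OtuExperiment"), is(bp, "OtuExperiment"))
  if (!setequal(colnames(bact), colnames(bp)))
    stop("bacteria and BP tables must cover the same samples")
  bp <- bp[, colnames(bact)]
  if (any(rownames(bp) %in% rownames(bact)))
    stop("taxon ids overlap between the two tables")
  m <- rbind(otuCounts(bact), otuCounts(bp))
  kd <- c(kingdom(bact), kingdom(bp))
  fg <- c(functionalGroup(bact), functionalGroup(bp))
  corr <- spearmanMatrix(m)
  net <- buildNetwork(corr, rMin = rMin, pMax = pMax, kingdom = kd,
                      functionalGroup = fg, bhCorrect = bhCorrect)
  if (!includeBpBp && nrow(net@edges)) {
    kdMap <- stats::setNames(net@nodes$kingdom, net@nodes$id)
    drop <- kdMap[net@edges$from] == "protist" &
      kdMap[net@edges$to] == "protist"
    net <- SignedNetwork(net@nodes, net@edges[!drop, , drop = FALSE])
  }
  net
}

#' Census of cross-kingdom edges by protist functional group
#'
#' Counts edges joining a bacterial and a protist node, grouped by the
#' protist endpoint's feeding mode.  Protist nodes without a mapping count
#' as `"unknown"`.
#'
#' @param net a [SignedNetwork-class].
#' @param feedingModeMap optional named character vector (taxon ->
#'   functional group) overriding the network's node attributes.
#' @return data.frame over the full feeding-mode vocabulary with columns
#'   `functional_group` and `n_edges`; `sum(n_edges)` equals the total
#'   number of cross-kingdom edges.
#' @export
crossKingdomEdgeCensus <- function(net, feedingModeMap = NULL) {
  stopifnot(is(net, "SignedNetwork"))
  nodes <- net@nodes
  fg <- stats::setNames(nodes$functional_group, nodes$id)
  if (!is.null(feedingModeMap)) {
    hit <- names(feedingModeMap)[names(feedingModeMap) %in% nodes$id]
    fg[hit] <- feedingModeMap[hit]
  }
  kd <- stats::setNames(nodes$kingdom, nodes$id)
  counts <- stats::setNames(integer(length(FEEDING_MODES)), FEEDING_MODES)
  ed <- net@edges
  if (nrow(ed)) {
    cross <- kd[ed$from] != kd[ed$to]
    protEnd <- ifelse(kd[ed$from] == "protist", ed$from, ed$to)[cross]
    grp <- fg[protEnd]
    grp[is.na(grp)] <- "unknown"
    tab <- table(factor(grp, levels = FEEDING_MODES))
    counts[names(tab)] <- as.integer(tab)
  }
  data.frame(functional_group = FEEDING_MODES, n_edges = unname(counts),
             stringsAsFactors = FALSE)
}

#' Write a network as edge-list and node-attribute TSVs
#'
#' The edge list (source, target, weight, sign) and node table (id,
#' kingdom, functional_group) are directly importable by Gephi.
#'
#' @param net a [SignedNetwork-class].
#' @param edgePath,nodePath output paths.
#' @return invisible character vector of the two paths.
#' @export
writeNetwork <- function(net, edgePath, nodePath) {
  ed <- net@edges
  colnames(ed)[colnames(ed) == "from"] <- "source"
  colnames(ed)[colnames(ed) == "to"] <- "target"
  utils::write.table(ed, edgePath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(net@nodes, nodePath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(edgePath, nodePath))
}
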