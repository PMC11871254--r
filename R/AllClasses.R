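#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom SummarizedExperiment rowData<- colData<-
NULL

#' OtuExperiment: an OTU count table with kingdom annotation
#'
#' A thin extension of \linkS4class{SummarizedExperiment} holding a single
#' `counts` assay of non-negative integer OTU (or genus) counts, taxa in
#' rows and samples in columns.  Per-taxon annotation lives in
#' `rowData` (`kingdom`, one of `"bacteria"` or `"protist"`; optional
#' `taxonomy` lineage strings and `functional_group` labels for protists)
#' and per-sample annotation in `colData` (typically `season`, `depth_m`,
#' `replicate` plus environmental covariates).
#'
#' @slot ... inherited from SummarizedExperiment.
#' @export
setClass("OtuExperiment", contains = "SummarizedExperiment")

setValidity("OtuExperiment", function(object) {
  msg <- character()
  if (!("counts" %in% SummarizedExperiment::assayNames(object)))
    return("assay 'counts' is required")
  m <- assay(object, "counts")
  if (nrow(m) < 1L || ncol(m) < 2L)
    msg <- c(msg, "need at least 1 taxon and 2 samples")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "taxon ids (rownames) must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids (colnames) must be present and unique")
  if (any(!is.finite(m)) || any(m < 0))
    msg <- c(msg, "counts must be finite and non-negative")
  if (any(abs(m - round(m)) > 1e-8))
    msg <- c(msg, "counts must be integers")
  kd <- rowData(object)$kingdom
  if (is.null(kd)) {
    msg <- c(msg, "rowData must carry a 'kingdom' column")
  } else if (!all(kd %in% KINGDOMS)) {
    msg <- c(msg, sprintf("kingdom labels must be in {%s}",
                          paste(KINGDOMS, collapse = ", ")))
  }
  fg <- rowData(object)$functional_group
  if (!is.null(fg) && !all(is.na(fg) | fg %in% FEEDING_MODES))
    msg <- c(msg, "functional_group labels outside the allowed vocabulary")
  if (length(msg)) msg else TRUE
})

#' Construct an OtuExperiment
#'
#' @param counts non-negative integer matrix, taxa x samples, with unique
#'   rownames (taxon ids) and colnames (sample ids).
#' @param kingdom character vector, one of `"bacteria"`/`"protist"` per
#'   taxon; a single value is recycled.
#' @param taxonomy optional per-taxon lineage strings.
#' @param functionalGroup optional per-taxon feeding-mode labels (protists);
#'   see [feedingModes()] for the vocabulary.
#' @param sampleData optional per-sample `DataFrame`/`data.frame` with
#'   rownames matching the sample ids (e.g., season, depth_m, replicate).
#' @return an [OtuExperiment-class] object.
#' @examples
#' m <- matrix(rpois(12, 5), 3, 4,
#'             dimnames = list(paste0("t", 1:3), paste0("s", 1:4)))
#' OtuExperiment(m, kingdom = "bacteria")
#' @export
OtuExperiment <- function(counts, kingdom, taxonomy = NULL,
                          functionalGroup = NULL, sampleData = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (length(kingdom) == 1L) kingdom <- rep(kingdom, nrow(counts))
  rd <- DataFrame(kingdom = as.character(kingdom), row.names = rownames(counts))
  if (!is.null(taxonomy)) rd$taxonomy <- as.character(taxonomy)
  if (!is.null(functionalGroup))
    rd$functional_group <- as.character(functionalGroup)
  if (is.null(sampleData)) {
    cd <- DataFrame(row.names = colnames(counts))
  } else {
    cd <- as(sampleData, "DataFrame")
    if (!setequal(rownames(cd), colnames(counts)))
      stop("sampleData rownames must match the sample ids")
    cd <- cd[colnames(counts), , drop = FALSE]
  }
  new("OtuExperiment",
      SummarizedExperiment(assays = list(counts = counts),
                           rowData = rd, colData = cd))
}

#' CorrelationResult: pairwise Spearman correlations with p-values
#'
#' Symmetric rank-correlation (`rho`) and two-sided p-value (`p`) matrices
#' over a set of taxa, with the number of samples the correlations were
#' computed from.
#'
#' @slot taxonIds character taxon ids (row/col order of the matrices).
#' @slot rho symmetric matrix in [-1, 1] with unit diagonal.
#' @slot p symmetric matrix in [0, 1] with zero diagonal.
#' @slot nSamples integer number of samples.
#' @export
setClass("CorrelationResult",
         representation(taxonIds = "character", rho = "matrix",
                        p = "matrix", nSamples = "integer"))

setValidity("CorrelationResult", function(object) {
  msg <- character()
  k <- length(object@taxonIds)
  if (!all(dim(object@rho) == k) || !all(dim(object@p) == k))
    msg <- c(msg, "rho and p must be square over taxonIds")
  if (max(abs(object@rho - t(object@rho))) > 1e-10 ||
      max(abs(object@p - t(object@p))) > 1e-10)
    msg <- c(msg, "rho and p must be symmetric")
  if (any(abs(object@rho) > 1 + 1e-12))
    msg <- c(msg, "|rho| must be <= 1")
  if (any(abs(diag(object@rho) - 1) > 1e-12))
    msg <- c(msg, "diag(rho) must be 1")
  if (any(object@p < 0 | object@p > 1))
    msg <- c(msg, "p must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' SignedNetwork: a signed, weighted co-occurrence network
#'
#' Undirected graph over taxa.  Nodes carry `kingdom` and (optionally)
#' `functional_group` attributes; each edge carries the correlation that
#' created it as `weight` and its `sign` (`"+"` or `"-"`).  Isolated nodes
#' are retained so that node-removal statistics see the full taxon set.
#'
#' @slot nodes data.frame with columns `id`, `kingdom`, `functional_group`.
#' @slot edges data.frame with columns `from`, `to`, `weight`, `sign`.
#' @export
setClass("SignedNetwork",
         representation(nodes = "data.frame", edges = "data.frame"))

setValidity("SignedNetwork", function(object) {
  nd <- object@nodes; ed <- object@edges
  msg <- character()
  if (!all(c("id", "kingdom") %in% names(nd)))
    msg <- c(msg, "nodes need 'id' and 'kingdom' columns")
  else if (anyDuplicated(nd$id))
    msg <- c(msg, "node ids must be unique")
  if (!all(c("from", "to", "weight", "sign") %in% names(ed)))
    msg <- c(msg, "edges need 'from', 'to', 'weight', 'sign' columns")
  else if (nrow(ed)) {
    if (any(ed$from == ed$to)) msg <- c(msg, "self-loops are not allowed")
    if (!all(c(ed$from, ed$to) %in% nd$id))
      msg <- c(msg, "edge endpoints must be nodes")
    if (!all(ed$sign == ifelse(ed$weight >= 0, "+", "-")))
      msg <- c(msg, "edge sign must match the sign of its weight")
    key <- paste(pmin(ed$from, ed$to), pmax(ed$from, ed$to))
    if (anyDuplicated(key)) msg <- c(msg, "at most one edge per node pair")
  }
  if (length(msg)) msg else TRUE
})

#' @param nodes data.frame with at least `id` and `kingdom` columns.
#' @param edges data.frame with `from`, `to`, `weight` columns (`sign` is
#'   derived from `weight` when absent).
#' @rdname SignedNetwork-class
#' @export
SignedNetwork <- function(nodes, edges = NULL) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  if (is.null(nodes$functional_group)) nodes$functional_group <- NA_character_
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric(), sign = character(),
                        stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    if (is.null(edges$sign)) edges$sign <- ifelse(edges$weight >= 0, "+", "-")
  }
  rownames(nodes) <- NULL; rownames(edges) <- NULL
  new("SignedNetwork", nodes = nodes, edges = edges)
}

setMethod("show", "OtuExperiment", function(object) {
  kd <- table(rowData(object)$kingdom)
  cat(sprintf("OtuExperiment: %d taxa x %d samples (%s)\n",
              nrow(object), ncol(object),
              paste(sprintf("%s: %d", names(kd), kd), collapse = ", ")))
  callNextMethod()
})

setMethod("show", "CorrelationResult", function(object) {
  cat(sprintf("CorrelationResult: %d taxa, n = %d samples\n",
              length(object@taxonIds), object@nSamples))
})

setMethod("show", "SignedNetwork", function(object) {
  ed <- object@edges
  cat(sprintf("SignedNetwork: %d nodes, %d edges (%d positive, %d negative)\n",
              nrow(object@nodes), nrow(ed),
              sum(ed$sign == "+"), sum(ed$sign == "-")))
})
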