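#' @importFrom SummarizedExperiment colData
#' @export
SummarizedExperiment::colData

#' @importFrom SummarizedExperiment rowData
#' @export
SummarizedExperiment::rowData

#' @rdname OtuExperiment-class
#' @param x,object an object.
#' @export
setGeneric("otuCounts", function(x) standardGeneric("otuCounts"))

#' @rdname OtuExperiment-class
#' @export
setGeneric("kingdom", function(x) standardGeneric("kingdom"))

#' @rdname OtuExperiment-class
#' @export
setGeneric("functionalGroup", function(x) standardGeneric("functionalGroup"))

#' @rdname OtuExperiment-class
#' @export
setGeneric("taxonomyLineage", function(x) standardGeneric("taxonomyLineage"))

#' @rdname SignedNetwork-class
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @rdname SignedNetwork-class
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname SignedNetwork-class
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' @rdname SignedNetwork-class
#' @export
setGeneric("nEdges", function(x) standardGeneric("nEdges"))

#' @rdname SignedNetwork-class
#' @export
setGeneric("asIgraph", function(x, ...) standardGeneric("asIgraph"))

#' Counts matrix of an OtuExperiment
#' @rdname OtuExperiment-class
#' @export
setMethod("otuCounts", "OtuExperiment",
          function(x) assay(x, "counts"))

#' @rdname OtuExperiment-class
#' @export
setMethod("kingdom", "OtuExperiment", function(x) {
  stats::setNames(as.character(rowData(x)$kingdom), rownames(x))
})

#' @rdname OtuExperiment-class
#' @export
setMethod("functionalGroup", "OtuExperiment", function(x) {
  fg <- rowData(x)$functional_group
  if (is.null(fg)) fg <- rep(NA_character_, nrow(x))
  stats::setNames(as.character(fg), rownames(x))
})

#' @rdname OtuExperiment-class
#' @export
setMethod("taxonomyLineage", "OtuExperiment", function(x) {
  tx <- rowData(x)$taxonomy
  if (is.null(tx)) tx <- rep(NA_character_, nrow(x))
  stats::setNames(as.character(tx), rownames(x))
})

#' @rdname SignedNetwork-class
#' @export
setMethod("networkNodes", "SignedNetwork", function(x) x@nodes)

#' @rdname SignedNetwork-class
#' @export
setMethod("networkEdges", "SignedNetwork", function(x) x@edges)

#' @rdname SignedNetwork-class
#' @export
setMethod("nNodes", "SignedNetwork", function(x) nrow(x@nodes))

#' @rdname SignedNetwork-class
#' @export
setMethod("nEdges", "SignedNetwork", function(x) nrow(x@edges))

#' Convert a SignedNetwork to an igraph graph
#'
#' The returned graph is undirected; edge `weight` and `sign` and node
#' `kingdom`/`functional_group` attributes are carried over.  Stability
#' indices operate on the unsigned, unweighted skeleton of this graph.
#'
#' @param x a [SignedNetwork-class].
#' @param ... unused.
#' @return an [igraph::igraph] object.
#' @export
setMethod("asIgraph", "SignedNetwork", function(x, ...) {
  g <- igraph::graph_from_data_frame(
    x@edges[, c("from", "to", "weight", "sign")],
    directed = FALSE, vertices = x@nodes)
  g
})
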