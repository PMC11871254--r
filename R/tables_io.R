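# Reading, writing, normalising and filtering OTU tables and the small
# annotation tables around them.  All on-disk formats are UTF-8 TSV.

#' Read a taxa-by-samples OTU count table from TSV
#'
#' Expects a tab-separated file whose first column holds taxon ids and whose
#' header row holds sample ids; all remaining cells must be non-negative
#' integer counts.
#'
#' @param path path to the TSV file.
#' @param kingdom kingdom label applied to every taxon in the file
#'   (`"bacteria"` or `"protist"`).
#' @param functionalGroup optional named character vector (taxon id ->
#'   feeding mode) merged into the row annotation; unmapped taxa get `NA`.
#' @return an [OtuExperiment-class] preserving the file's row and column
#'   order.
#' @export
readOtuTable <- function(path, kingdom, functionalGroup = NULL) {
  stopifnot(length(kingdom) == 1L, kingdom %in% KINGDOMS)
  raw <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(raw) < 3L)
    stop("malformed OTU table '", path, "': need a taxon-id column and >= 2 samples")
  ids <- raw[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate taxon id in '", path, "': ",
         ids[duplicated(ids)][1L])
  samples <- colnames(raw)[-1L]
  if (anyDuplicated(samples))
    stop("duplicate sample id in '", path, "': ",
         samples[duplicated(samples)][1L])
  m <- matrix(NA_real_, nrow(raw), length(samples),
              dimnames = list(ids, samples))
  for (j in seq_along(samples)) {
    v <- suppressWarnings(as.numeric(raw[[j + 1L]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1L]
      stop(sprintf("non-numeric cell in '%s' at taxon '%s', sample '%s'",
                   path, ids[bad], samples[j]))
    }
    m[, j] <- v
  }
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative count in '%s' at taxon '%s', sample '%s'",
                 path, ids[bad[1L]], samples[bad[2L]]))
  }
  fg <- if (is.null(functionalGroup)) NULL else
    unname(functionalGroup[ids])
  OtuExperiment(m, kingdom = kingdom, functionalGroup = fg)
}

#' Write an OtuExperiment to TSV
#'
#' Inverse of [readOtuTable()]: first column `taxon_id`, one column per
#' sample, integer counts.
#'
#' @param x an [OtuExperiment-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeOtuTable <- function(x, path) {
  m <- otuCounts(x)
  df <- data.frame(taxon_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample-metadata table from TSV
#'
#' Requires columns `sample_id`, `season`, `depth_m`, `replicate`; any
#' further columns are treated as environmental covariates and kept as-is.
#' Each (season, depth, replicate) triple must be unique.
#'
#' @param path path to the TSV file.
#' @return a [S4Vectors::DataFrame] keyed by sample id (rownames).
#' @export
readSampleMetadata <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "season", "depth_m", "replicate")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("metadata '", path, "' lacks required column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in metadata: ",
         df$sample_id[duplicated(df$sample_id)][1L])
  if (!all(df$season %in% SEASONS))
    stop("season labels must be in {", paste(SEASONS, collapse = ", "), "}")
  key <- paste(df$season, df$depth_m, df$replicate)
  if (anyDuplicated(key))
    stop("duplicate (season, depth_m, replicate) triple: ",
         key[duplicated(key)][1L])
  out <- DataFrame(df[setdiff(colnames(df), "sample_id")],
                   row.names = df$sample_id)
  out
}

#' Attach sample metadata to an OtuExperiment
#'
#' @param x an [OtuExperiment-class].
#' @param metadata a `DataFrame`/`data.frame` keyed by sample id; its sample
#'   set must equal the table's sample set.
#' @return `x` with `colData` replaced by the metadata (reordered to match).
#' @export
attachSampleMetadata <- function(x, metadata) {
  md <- as(metadata, "DataFrame")
  if (!setequal(rownames(md), colnames(x)))
    stop("metadata sample ids do not match the OTU table's sample ids")
  colData(x) <- md[colnames(x), , drop = FALSE]
  validObject(x)
  x
}

#' Read a two-column taxon-to-feeding-mode map from TSV
#'
#' The feeding-mode vocabulary is closed: algivore, bacterivore, mycophage,
#' nonselective omnivore, parasite, phototroph, raptor, saprotroph, unknown.
#'
#' @param path path to a two-column TSV (taxon id, functional group).
#' @return named character vector (taxon id -> functional group).
#' @export
readFeedingModes <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("feeding-mode map must have two columns")
  grp <- as.character(df[[2L]])
  bad <- setdiff(unique(grp), FEEDING_MODES)
  if (length(bad))
    stop("unknown feeding mode(s): ", paste(bad, collapse = ", "))
  stats::setNames(grp, as.character(df[[1L]]))
}

#' The closed protist feeding-mode vocabulary
#' @return character vector of the nine allowed functional-group labels.
#' @export
feedingModes <- function() FEEDING_MODES

#' Per-sample relative abundances
#'
#' Divides each sample column by its total count, so each column sums to 1.
#'
#' @param x an [OtuExperiment-class] or a non-negative taxa-by-samples
#'   matrix.
#' @return matrix of proportions with the input's dimnames.
#' @export
relativeAbundance <- function(x) {
  m <- if (is(x, "OtuExperiment")) otuCounts(x) else as.matrix(x)
  tot <- colSums(m)
  if (any(tot <= 0)) {
    bad <- colnames(m)[which(tot <= 0)[1L]]
    if (is.null(bad)) bad <- which(tot <= 0)[1L]
    stop("sample '", bad, "' has zero total count")
  }
  sweep(m, 2L, tot, "/")
}

#' Filter taxa by prevalence and total abundance
#'
#' Retains exactly the taxa observed (count > 0) in at least `minSamples`
#' samples AND with a total count of at least `minTotal`.  The sample set is
#' never changed.  Spearman correlation on nearly-all-zero taxa is
#' degenerate, so co-occurrence networks are built from tables filtered
#' this way (the pipeline default keeps taxa present in at least a third of
#' the samples under analysis).
#'
#' @param x an [OtuExperiment-class].
#' @param minSamples minimum number of samples a taxon must be present in.
#' @param minTotal minimum total count across samples.
#' @return the filtered [OtuExperiment-class].
#' @export
filterPrevalence <- function(x, minSamples = 0L, minTotal = 0L) {
  stopifnot(minSamples >= 0, minTotal >= 0)
  m <- otuCounts(x)
  keep <- rowSums(m > 0) >= minSamples & rowSums(m) >= minTotal
  if (!any(keep))
    stop("prevalence filter (minSamples=", minSamples, ", minTotal=",
         minTotal, ") would remove every taxon")
  x[keep, ]
}

#' Write a square distance matrix to TSV (ids as header row and column)
#' @param d named square matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeDistanceMatrix <- function(d, path) {
  df <- data.frame(id = rownames(d), d, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a square distance matrix written by [writeDistanceMatrix()]
#' @param path input path.
#' @return named square matrix.
#' @export
readDistanceMatrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}
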