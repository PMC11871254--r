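# Seeded generator of synthetic seasonal bacteria+protist communities with
# planted correlation blocks and predator-prey (bacterivore-bacterium)
# couplings.  The generative chain is Gaussian copula -> per-season
# log-mean shifts -> log-normal abundances -> multinomial sequencing, so
# planted latent correlations survive as rank correlations in the counts
# while the observed table stays compositional and overdispersed.

#' Configuration of a synthetic seasonal community
#'
#' The default design mirrors a seasonal lake survey: 4 seasons x 3 depths
#' x 3 replicates = 36 samples.  Taxon ids are `B001..` for bacteria and
#' `P001..` for protists; the first `nBacterivores` protists are labelled
#' `bacterivore`, the rest `phototroph` (the two dominant protist
#' functional groups in lake communities).
#'
#' @param nBacteria number of bacterial taxa.
#' @param nProtists number of protist taxa.
#' @param nBacterivores number of protists labelled as bacterivores
#'   (`<= nProtists`).
#' @param seasons season labels (subset of spring/summer/autumn/winter).
#' @param depths sampling depths in metres.
#' @param replicates replicates per season x depth (>= 2).
#' @param seqDepth sequencing reads per sample (>= 100).
#' @param modules list of planted correlation blocks, each a
#'   `list(taxa = <ids>, rho = <latent correlation in (-1,1)>)`.
#' @param trophicLinks list of planted predator-prey couplings, each a
#'   `list(predator = <bacterivore id>, prey = <bacterial id>,
#'   rho = <signed latent correlation>)`; positive by default since grazers
#'   track their prey's abundance.
#' @param seasonEffectSd sd of per-taxon, per-season log-mean shifts
#'   (drives seasonal ordination structure).
#' @param dispersionSd sd of the log-normal abundance noise; the correlated
#'   latent field enters through this term.
#' @param baselineSd sd of per-taxon baseline log-means (taxon abundance
#'   heterogeneity).
#' @param seed integer seed; the whole generator is a pure function of the
#'   configuration including this seed.
#' @return a validated `SimConfig` (list); construction fails if the
#'   implied latent correlation matrix is not positive definite.
#' @export
simConfig <- function(nBacteria = 100L, nProtists = 30L, nBacterivores = 10L,
                      seasons = SEASONS, depths = c(0, 3, 6),
                      replicates = 3L, seqDepth = 20000L,
                      modules = list(), trophicLinks = list(),
                      seasonEffectSd = 0.8, dispersionSd = 1.0,
                      baselineSd = 1.5, seed = 1L) {
  stopifnot(nBacteria >= 1L, nProtists >= 0L,
            replicates >= 2L, seqDepth >= 100L,
            seasonEffectSd >= 0, dispersionSd >= 0, baselineSd >= 0)
  if (nBacterivores > nProtists)
    stop("nBacterivores must not exceed nProtists")
  if (!all(seasons %in% SEASONS)) stop("unknown season label")
  cfg <- list(nBacteria = as.integer(nBacteria),
              nProtists = as.integer(nProtists),
              nBacterivores = as.integer(nBacterivores),
              seasons = seasons, depths = depths,
              replicates = as.integer(replicates),
              seqDepth = as.integer(seqDepth),
              modules = modules, trophicLinks = trophicLinks,
              seasonEffectSd = seasonEffectSd, dispersionSd = dispersionSd,
              baselineSd = baselineSd, seed = as.integer(seed))
  cfg$taxonIds <- c(sprintf("B%03d", seq_len(nBacteria)),
                    if (nProtists > 0) sprintf("P%03d", seq_len(nProtists)))
  cfg$kingdom <- c(rep("bacteria", nBacteria), rep("protist", nProtists))
  fg <- c(rep(NA_character_, nBacteria),
          rep("phototroph", nProtists))
  if (nBacterivores > 0)
    fg[nBacteria + seq_len(nBacterivores)] <- "bacterivore"
  cfg$functionalGroup <- fg
  cfg$Sigma <- .latentCorrelation(cfg)   # also validates the planted layout
  class(cfg) <- "SimConfig"
  cfg
}

# Build (and validate) the latent correlation matrix implied by the planted
# blocks and trophic links.
.latentCorrelation <- function(cfg) {
  ids <- cfg$taxonIds
  k <- length(ids)
  S <- diag(k)
  dimnames(S) <- list(ids, ids)
  bacterivores <- ids[cfg$kingdom == "protist" &
                        cfg$functionalGroup == "bacterivore"]
  for (b in cfg$modules) {
    if (!all(c("taxa", "rho") %in% names(b)))
      stop("each module needs 'taxa' and 'rho'")
    if (abs(b$rho) >= 1) stop("module |rho| must be < 1")
    miss <- setdiff(b$taxa, ids)
    if (length(miss)) stop("unknown module taxa: ", paste(miss, collapse = ", "))
    for (i in b$taxa) for (j in b$taxa) if (i != j) S[i, j] <- b$rho
  }
  for (tl in cfg$trophicLinks) {
    if (!all(c("predator", "prey", "rho") %in% names(tl)))
      stop("each trophic link needs 'predator', 'prey' and 'rho'")
    if (abs(tl$rho) >= 1) stop("trophic |rho| must be < 1")
    if (!(tl$predator %in% bacterivores))
      stop("trophic predator '", tl$predator,
           "' is not a bacterivore-labelled protist")
    if (!(tl$prey %in% ids[cfg$kingdom == "bacteria"]))
      stop("trophic prey '", tl$prey, "' is not a bacterial taxon")
    S[tl$predator, tl$prey] <- S[tl$prey, tl$predator] <- tl$rho
  }
  ok <- tryCatch({ chol(S); TRUE }, error = function(e) FALSE)
  if (!ok)
    stop("planted blocks/links imply a non-positive-definite latent ",
         "correlation matrix")
  S
}

#' Generate a synthetic seasonal community
#'
#' Draws one taxa-by-samples count table under the configuration's planted
#' structure: (1) a latent multivariate normal field per sample with the
#' block/trophic correlation matrix, (2) per-taxon, per-season log-mean
#' shifts, (3) exponentiation to log-normal abundances, (4) a multinomial
#' draw of `seqDepth` reads per sample (column sums are exactly
#' `seqDepth`).  The same configuration (including seed) yields
#' bit-identical output.
#'
#' @param cfg a `SimConfig` from [simConfig()].
#' @return list with elements
#'   \describe{
#'     \item{otu}{[OtuExperiment-class] with season/depth/replicate in
#'       `colData` and kingdom/functional group in `rowData`.}
#'     \item{truth}{`SyntheticTruth` list: `plantedAdjacency` (symmetric
#'       signed latent-correlation matrix, zero diagonal),
#'       `moduleAssignment` (taxon -> block id or `NA`), `trophicPairs`
#'       (data.frame predator/prey/sign).}
#'   }
#' @export
generateCommunity <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  ids <- cfg$taxonIds
  k <- length(ids)
  design <- expand.grid(replicate = seq_len(cfg$replicates),
                        depth_m = cfg$depths, season = cfg$seasons,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design <- design[, c("season", "depth_m", "replicate")]
  sampleIds <- sprintf("%s_d%g_r%d", design$season, design$depth_m,
                       design$replicate)
  n <- nrow(design)
  R <- chol(cfg$Sigma)
  counts <- withSeed(cfg$seed, {
    mu <- stats::rnorm(k, 0, cfg$baselineSd)
    shift <- matrix(stats::rnorm(k * length(cfg$seasons), 0,
                                 cfg$seasonEffectSd),
                    k, length(cfg$seasons),
                    dimnames = list(ids, cfg$seasons))
    Z <- crossprod(R, matrix(stats::rnorm(k * n), k, n))  # cov = Sigma
    out <- matrix(0, k, n, dimnames = list(ids, sampleIds))
    for (j in seq_len(n)) {
      logA <- mu + shift[, design$season[j]] + cfg$dispersionSd * Z[, j]
      out[, j] <- stats::rmultinom(1L, cfg$seqDepth,
                                   prob = exp(logA - max(logA)))
    }
    out
  })
  md <- DataFrame(design, row.names = sampleIds)
  otu <- OtuExperiment(counts, kingdom = cfg$kingdom,
                       functionalGroup = cfg$functionalGroup,
                       sampleData = md)
  planted <- cfg$Sigma - diag(k)
  moduleAssignment <- stats::setNames(rep(NA_integer_, k), ids)
  for (i in seq_along(cfg$modules))
    moduleAssignment[cfg$modules[[i]]$taxa] <- i
  trophicPairs <- if (length(cfg$trophicLinks)) {
    data.frame(predator = vapply(cfg$trophicLinks, `[[`, "", "predator"),
               prey = vapply(cfg$trophicLinks, `[[`, "", "prey"),
               sign = ifelse(vapply(cfg$trophicLinks, `[[`, 0, "rho") >= 0,
                             "+", "-"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(predator = character(), prey = character(),
               sign = character(), stringsAsFactors = FALSE)
  }
  truth <- structure(list(plantedAdjacency = planted,
                          moduleAssignment = moduleAssignment,
                          trophicPairs = trophicPairs),
                     class = "SyntheticTruth")
  list(otu = otu, truth = truth)
}

#' Signed edge set implied by the planted structure
#'
#' @param truth a `SyntheticTruth` from [generateCommunity()].
#' @return data.frame with columns `from`, `to`, `sign`, `source`
#'   (`"block"` or `"trophic"`), one row per nonzero upper-triangle entry
#'   of the planted adjacency.
#' @export
truthEdgeSet <- function(truth) {
  stopifnot(inherits(truth, "SyntheticTruth"))
  A <- truth$plantedAdjacency
  ids <- rownames(A)
  idx <- which(upper.tri(A) & A != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(data.frame(from = character(), to = character(),
                      sign = character(), source = character(),
                      stringsAsFactors = FALSE))
  from <- ids[idx[, 1L]]; to <- ids[idx[, 2L]]
  trKey <- paste(pmin(truth$trophicPairs$predator, truth$trophicPairs$prey),
                 pmax(truth$trophicPairs$predator, truth$trophicPairs$prey))
  key <- paste(pmin(from, to), pmax(from, to))
  data.frame(from = from, to = to,
             sign = ifelse(A[idx] > 0, "+", "-"),
             source = ifelse(key %in% trKey, "trophic", "block"),
             stringsAsFactors = FALSE)
}

#' Write the planted truth edge set to TSV
#' @param truth a `SyntheticTruth`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTruth <- function(truth, path) {
  utils::write.table(truthEdgeSet(truth), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
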