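# End-to-end orchestration of the seasonal +-BP experiment: per season and
# per condition (bacteria-only / +BP) it builds the co-occurrence network,
# its topology and stability reports, plus the community-level diversity,
# ordination and permutation statistics, writing everything as TSV with a
# hash manifest so a run is a pure function of (config, seed).

#' Pipeline configuration
#'
#' @param mode `"synthetic"` (simulate the community) or `"files"` (read
#'   the four input tables from disk).
#' @param sim a `SimConfig` (synthetic mode); its own seed is overridden
#'   by `seed`.
#' @param files named list with paths `bacteria`, `protists`, `metadata`,
#'   `feedingModes` (files mode).
#' @param outDir output directory (created if absent).
#' @param rMin,pMax,bhCorrect,includeBpBp network thresholds, see
#'   [buildNetwork()] and [augmentWithBp()].
#' @param minPrevalenceFrac per-season prevalence filter: a taxon must be
#'   present in at least this fraction of the subset's samples.
#' @param removalFraction,trials robustness parameters.
#' @param nullIters cohesion taxa-shuffle iterations.
#' @param maxRemovedFraction,decayTrials natural-connectivity decay
#'   parameters.
#' @param nPerm permutations for ANOSIM and Mantel.
#' @param seed master seed; per-stage seeds are derived with
#'   [childSeed()].
#' @return validated `PipelineConfig` list.
#' @export
pipelineConfig <- function(mode = c("synthetic", "files"),
                           sim = simConfig(), files = NULL,
                           outDir = tempfile("micronetstab_run_"),
                           rMin = 0.6, pMax = 0.05, bhCorrect = FALSE,
                           includeBpBp = FALSE,
                           minPrevalenceFrac = 1 / 3,
                           removalFraction = 0.5, trials = 50L,
                           nullIters = 200L,
                           maxRemovedFraction = 0.8, decayTrials = 10L,
                           nPerm = 999L, seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "files") {
    need <- c("bacteria", "protists", "metadata", "feedingModes")
    if (is.null(files) || !all(need %in% names(files)))
      stop("files mode needs paths: ", paste(need, collapse = ", "))
  }
  stopifnot(rMin > 0, rMin < 1, pMax > 0, pMax < 1,
            removalFraction > 0, removalFraction < 1,
            maxRemovedFraction > 0, maxRemovedFraction < 1,
            minPrevalenceFrac >= 0, minPrevalenceFrac <= 1)
  structure(list(mode = mode, sim = sim, files = files, outDir = outDir,
                 rMin = rMin, pMax = pMax, bhCorrect = bhCorrect,
                 includeBpBp = includeBpBp,
                 minPrevalenceFrac = minPrevalenceFrac,
                 removalFraction = removalFraction,
                 trials = as.integer(trials),
                 nullIters = as.integer(nullIters),
                 maxRemovedFraction = maxRemovedFraction,
                 decayTrials = as.integer(decayTrials),
                 nPerm = as.integer(nPerm), seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipelineConfig()]; a `sim` block
#' mirrors [simConfig()] (with `modules`/`trophicLinks` as lists of maps).
#'
#' @param path YAML file path.
#' @param ... overrides passed on to [pipelineConfig()].
#' @return a `PipelineConfig`.
#' @export
readPipelineConfig <- function(path, ...) {
  y <- yaml::read_yaml(path)
  simArgs <- y$sim
  y$sim <- NULL
  args <- utils::modifyList(y, list(...))
  if (!is.null(simArgs))
    args$sim <- do.call(simConfig, simArgs)
  do.call(pipelineConfig, args)
}

.stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  out <- tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  message(sprintf("[%s] done in %.2fs", name,
                  proc.time()[["elapsed"]] - t0))
  out
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full seasonal +-BP pipeline
#'
#' For each season: prevalence-filter that season's samples, build the
#' bacteria-only and +BP networks at the configured thresholds, and
#' compute topology, robustness, vulnerability, natural connectivity with
#' its decay slope, cohesion (on that season's bacterial relative
#' abundances) and the cross-kingdom edge census.  Across seasons:
#' diversity per sample, Bray-Curtis + PCoA, ANOSIM by season, a Mantel
#' test between the bacterial and the bacterivore community distances,
#' and a letter display comparing robustness across seasons and between
#' the two conditions.  All artifacts are written to `cfg$outDir` and
#' listed in `manifest.tsv` with their MD5 hashes; the manifest is a pure
#' function of (config, seed).
#'
#' @param cfg a `PipelineConfig` from [pipelineConfig()].
#' @return invisibly, a list with `manifest` (data.frame file/md5) and
#'   `results` (the in-memory reports).
#' @export
runPipeline <- function(cfg) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()

  dat <- .stage("load", {
    if (cfg$mode == "synthetic") {
      sim <- cfg$sim
      sim$seed <- childSeed(cfg$seed, "simulate")
      sim <- do.call(simConfig, sim[c("nBacteria", "nProtists",
                                      "nBacterivores", "seasons", "depths",
                                      "replicates", "seqDepth", "modules",
                                      "trophicLinks", "seasonEffectSd",
                                      "dispersionSd", "baselineSd",
                                      "seed")])
      g <- generateCommunity(sim)
      fm <- functionalGroup(g$otu)
      fm <- fm[!is.na(fm)]
      list(otu = g$otu, truth = g$truth, feedingModes = fm)
    } else {
      fm <- readFeedingModes(cfg$files$feedingModes)
      bact <- readOtuTable(cfg$files$bacteria, "bacteria")
      prot <- readOtuTable(cfg$files$protists, "protist",
                           functionalGroup = fm)
      md <- readSampleMetadata(cfg$files$metadata)
      if (!setequal(colnames(bact), colnames(prot)))
        stop("bacteria and protist tables cover different samples")
      prot <- prot[, colnames(bact)]
      counts <- rbind(otuCounts(bact), otuCounts(prot))
      fg <- c(functionalGroup(bact), functionalGroup(prot))
      otu <- OtuExperiment(counts,
                           kingdom = c(kingdom(bact), kingdom(prot)),
                           functionalGroup = fg)
      otu <- attachSampleMetadata(otu, md)
      list(otu = otu, truth = NULL, feedingModes = fm)
    }
  })
  otu <- dat$otu
  md <- colData(otu)
  seasonsPresent <- unique(as.character(md$season))
  bact <- otu[kingdom(otu) == "bacteria", ]
  fg <- functionalGroup(otu)
  bpIds <- names(fg)[!is.na(fg) & fg == "bacterivore"]
  bp <- otu[rownames(otu) %in% bpIds, ]

  paths["otu_table"] <- writeOtuTable(otu, file.path(cfg$outDir,
                                                     "otu_table.tsv"))
  paths["metadata"] <- .writeTsv(
    data.frame(sample_id = rownames(md), as.data.frame(md),
               check.names = FALSE),
    file.path(cfg$outDir, "sample_metadata.tsv"))
  if (!is.null(dat$truth))
    paths["truth"] <- writeTruth(dat$truth,
                                 file.path(cfg$outDir, "truth_edges.tsv"))

  div <- .stage("diversity", diversityTable(bact))
  paths["diversity"] <- .writeTsv(div, file.path(cfg$outDir,
                                                 "diversity.tsv"))

  ord <- .stage("ordination", {
    bc <- brayCurtis(bact)
    pc <- pcoa(bc, k = 2L)
    an <- anosim(bc, as.character(md$season),
                 nPerm = cfg$nPerm, seed = childSeed(cfg$seed, "anosim"))
    mt <- if (nrow(bp) >= 1L && all(colSums(otuCounts(bp)) > 0)) {
      mantel(bc, brayCurtis(bp), nPerm = cfg$nPerm,
             seed = childSeed(cfg$seed, "mantel"))
    } else NULL
    list(bc = bc, pc = pc, anosim = an, mantel = mt)
  })
  paths["bray_curtis"] <- writeDistanceMatrix(
    ord$bc, file.path(cfg$outDir, "bray_curtis.tsv"))
  paths["pcoa"] <- .writeTsv(
    data.frame(sample_id = rownames(ord$pc$coordinates),
               ord$pc$coordinates, check.names = FALSE),
    file.path(cfg$outDir, "pcoa.tsv"))
  permRows <- data.frame(
    test = "anosim_season", statistic = ord$anosim$statistic,
    p_value = ord$anosim$p.value,
    n_permutations = ord$anosim$n.permutations,
    stringsAsFactors = FALSE)
  if (!is.null(ord$mantel))
    permRows <- rbind(permRows, data.frame(
      test = "mantel_bacteria_vs_bp", statistic = ord$mantel$statistic,
      p_value = ord$mantel$p.value,
      n_permutations = ord$mantel$n.permutations,
      stringsAsFactors = FALSE))
  paths["perm_tests"] <- .writeTsv(permRows,
                                   file.path(cfg$outDir, "perm_tests.tsv"))

  conditions <- c("bacteria", "bp_added")
  topoRows <- NULL
  stabRows <- NULL
  censusRows <- NULL
  decayRows <- NULL
  robTrials <- list()
  results <- list(data = dat, diversity = div, ordination = ord,
                  seasons = list())

  for (ss in seasonsPresent) {
    keep <- as.character(md$season) == ss
    minS <- ceiling(cfg$minPrevalenceFrac * sum(keep))
    bactS <- filterPrevalence(bact[, keep], minSamples = minS)
    bpS <- tryCatch(filterPrevalence(bp[, keep], minSamples = minS),
                    error = function(e) NULL)
    nets <- .stage(paste0("network_", ss), {
      bnet <- buildNetwork(spearmanMatrix(bactS), rMin = cfg$rMin,
                           pMax = cfg$pMax, kingdom = kingdom(bactS),
                           functionalGroup = functionalGroup(bactS),
                           bhCorrect = cfg$bhCorrect)
      anet <- if (!is.null(bpS)) {
        augmentWithBp(bactS, bpS, rMin = cfg$rMin, pMax = cfg$pMax,
                      includeBpBp = cfg$includeBpBp,
                      bhCorrect = cfg$bhCorrect)
      } else bnet
      list(bacteria = bnet, bp_added = anet)
    })
    seasonRes <- list(networks = nets)
    for (cond in conditions) {
      net <- nets[[cond]]
      tag <- paste0(ss, "_", cond)
      paths[paste0("edges_", tag)] <- file.path(cfg$outDir,
                                                paste0("edges_", tag, ".tsv"))
      paths[paste0("nodes_", tag)] <- file.path(cfg$outDir,
                                                paste0("nodes_", tag, ".tsv"))
      writeNetwork(net, paths[paste0("edges_", tag)],
                   paths[paste0("nodes_", tag)])
      topo <- .stage(paste0("topology_", tag), {
        cbind(season = ss, condition = cond,
              topology(net, seed = childSeed(cfg$seed,
                                             paste0("topology_", tag))))
      })
      topoRows <- rbind(topoRows, topo)
      stab <- .stage(paste0("stability_", tag), {
        rob <- robustness(net, removalFraction = cfg$removalFraction,
                          trials = cfg$trials,
                          seed = childSeed(cfg$seed,
                                           paste0("robustness_", tag)))
        vul <- tryCatch(vulnerability(net), error = function(e) NA_real_)
        nc <- naturalConnectivity(net)
        dec <- if (nNodes(net) >= 5L) {
          naturalConnectivityDecay(
            net, maxRemovedFraction = cfg$maxRemovedFraction,
            trials = cfg$decayTrials,
            seed = childSeed(cfg$seed, paste0("decay_", tag)))
        } else NULL
        list(robustness = rob, vulnerability = vul,
             naturalConnectivity = nc, decay = dec)
      })
      robTrials[[tag]] <- stab$robustness$trials
      coh <- .stage(paste0("cohesion_", tag), {
        tab <- if (cond == "bacteria") bactS else {
          if (is.null(bpS)) bactS else
            OtuExperiment(rbind(otuCounts(bactS), otuCounts(bpS)),
                          kingdom = c(kingdom(bactS), kingdom(bpS)))
        }
        cohesion(tab, nullIters = cfg$nullIters,
                 seed = childSeed(cfg$seed, paste0("cohesion_", tag)))
      })
      stabRows <- rbind(stabRows, data.frame(
        season = ss, condition = cond,
        robustness_mean = stab$robustness$mean,
        robustness_sd = stab$robustness$sd,
        vulnerability = stab$vulnerability,
        natural_connectivity = stab$naturalConnectivity,
        nat_conn_slope = if (is.null(stab$decay)) NA_real_ else
          stab$decay$slope,
        nat_conn_fit_r = if (is.null(stab$decay)) NA_real_ else
          stab$decay$r,
        cohesion_ratio_mean = coh$ratioMean,
        cohesion_ratio_sd = coh$ratioSd,
        stringsAsFactors = FALSE))
      if (!is.null(stab$decay))
        decayRows <- rbind(decayRows, cbind(season = ss, condition = cond,
                                            stab$decay$series))
      if (cond == "bp_added") {
        cen <- crossKingdomEdgeCensus(net, dat$feedingModes)
        censusRows <- rbind(censusRows, cbind(season = ss, cen))
      }
      seasonRes[[cond]] <- list(topology = topo, stability = stab,
                                cohesion = coh)
    }
    results$seasons[[ss]] <- seasonRes
  }

  paths["topology"] <- .writeTsv(topoRows,
                                 file.path(cfg$outDir, "topology.tsv"))
  paths["stability"] <- .writeTsv(stabRows,
                                  file.path(cfg$outDir, "stability.tsv"))
  if (!is.null(decayRows))
    paths["nat_conn_decay"] <- .writeTsv(
      decayRows, file.path(cfg$outDir, "nat_conn_decay.tsv"))
  if (!is.null(censusRows))
    paths["cross_kingdom_census"] <- .writeTsv(
      censusRows, file.path(cfg$outDir, "cross_kingdom_census.tsv"))

  cmp <- .stage("compare_stability", {
    bacteriaTrials <- robTrials[paste0(seasonsPresent, "_bacteria")]
    names(bacteriaTrials) <- seasonsPresent
    seasonLetters <- if (length(bacteriaTrials) >= 2L)
      compareStability(bacteriaTrials) else NULL
    bpLetters <- lapply(seasonsPresent, function(ss) {
      compareStability(robTrials[paste0(ss, "_", conditions)])
    })
    names(bpLetters) <- seasonsPresent
    list(seasons = seasonLetters, bp = bpLetters)
  })
  results$compare <- cmp
  cmpRows <- NULL
  if (!is.null(cmp$seasons))
    cmpRows <- cbind(comparison = "across_seasons_bacteria",
                     cmp$seasons$letters)
  for (ss in seasonsPresent)
    cmpRows <- rbind(cmpRows, cbind(comparison = paste0("bp_effect_", ss),
                                    cmp$bp[[ss]]$letters))
  paths["stability_letters"] <- .writeTsv(
    cmpRows, file.path(cfg$outDir, "stability_letters.tsv"))

  results$topology <- topoRows
  results$stability <- stabRows
  results$census <- censusRows

  manifest <- data.frame(
    artifact = names(paths),
    file = basename(unname(paths)),
    md5 = unname(tools::md5sum(unname(paths))),
    seed = cfg$seed,
    stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$artifact), ]
  .writeTsv(manifest, file.path(cfg$outDir, "manifest.tsv"))
  invisible(list(manifest = manifest, results = results))
}

#' Trophic ratio of bacterivorous protozoans to specific bacteria
#'
#' Per group of samples (e.g. season): the ratio of summed BP abundance to
#' summed specific-bacteria abundance, averaged over the group's samples,
#' together with the Pearson correlation of the two summed abundance
#' series across those samples (two-sided p).  Samples whose bacterial
#' sum is zero are excluded from the ratio mean and counted.
#'
#' @param bp bacterivore [OtuExperiment-class] (or matrix).
#' @param bacteria specific-bacteria [OtuExperiment-class] (or matrix)
#'   over the same samples.
#' @param groups per-sample grouping labels (single group if NULL).
#' @return data.frame with columns `group`, `ratio`, `r`, `p`,
#'   `n_excluded`.
#' @export
trophicRatio <- function(bp, bacteria, groups = NULL) {
  mbp <- if (is(bp, "OtuExperiment")) otuCounts(bp) else as.matrix(bp)
  mb <- if (is(bacteria, "OtuExperiment")) otuCounts(bacteria) else
    as.matrix(bacteria)
  if (!identical(colnames(mbp), colnames(mb))) {
    if (!setequal(colnames(mbp), colnames(mb)))
      stop("BP and bacteria tables must cover the same samples")
    mbp <- mbp[, colnames(mb), drop = FALSE]
  }
  if (is.null(groups)) groups <- rep("all", ncol(mb))
  stopifnot(length(groups) == ncol(mb))
  sbp <- colSums(mbp); sb <- colSums(mb)
  do.call(rbind, lapply(unique(as.character(groups)), function(g) {
    idx <- which(as.character(groups) == g)
    ok <- idx[sb[idx] > 0]
    ratio <- if (length(ok)) mean(sbp[ok] / sb[ok]) else NA_real_
    if (length(idx) >= 3L && stats::sd(sbp[idx]) > 0 &&
        stats::sd(sb[idx]) > 0) {
      ct <- stats::cor.test(sbp[idx], sb[idx])
      r <- unname(ct$estimate); p <- ct$p.value
    } else {
      r <- NA_real_; p <- NA_real_
    }
    data.frame(group = g, ratio = ratio, r = r, p = p,
               n_excluded = length(idx) - length(ok),
               stringsAsFactors = FALSE)
  }))
}
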