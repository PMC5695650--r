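#' @include simulate.R preprocess.R block.R connectivity.R io.R
NULL

#' Default end-to-end run configuration
#'
#' Returns the full parameter tree driving [runPipeline()]: protocol,
#' cohort scenario, per-stage preprocessing parameters, statistics
#' (significance level, quantile, bootstrap size, FDR family, detrend
#' mode, zero-weight convention, reference color) and connectivity
#' options. Every run writes a copy of its configuration beside its
#' outputs, and identical configuration plus seed reproduces the bundle.
#'
#' @param seed integer master seed
#' @return nested named list
#' @export
defaultRunConfig <- function(seed = 1L) {
  list(
    seed = seed,
    protocol = list(nBlocks = 15L, onDuration = 20, offRange = c(17, 27),
                    baseline = 480, recovery = 900),
    cohort = list(nSubjects = 14L, scenario = "headline",
                  colors = c("red", "green", "blue"), fs = 50,
                  fnirsParams = c("O2Hb", "HHb", "tHb", "StO2"),
                  includeSystemic = FALSE, ampVariability = 0.15,
                  artifacts = NULL),
    preprocess = c(preprocessDefaults(), list(channels = NULL)),
    stats = list(alpha = 0.05, tau = 0.5, nBoot = 2000L,
                 fdrFamily = "signals_x_intervals", detrendMode = "anchor",
                 zeroWeight = "zero", referenceColor = "red",
                 groupParam = "O2Hb"),
    connectivity = list(enabled = FALSE, weightTransform = "abs",
                        deletedAsZero = FALSE, alpha = 0.05),
    outDir = NULL
  )
}

#' @rdname defaultRunConfig
#' @param config a run configuration list
#' @param path file path for the YAML copy
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname defaultRunConfig
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- defaultRunConfig()
  mergeList <- function(a, b) {
    for (nm in names(b))
      a[[nm]] <- if (is.list(a[[nm]]) && is.list(b[[nm]]))
        mergeList(a[[nm]], b[[nm]]) else b[[nm]]
    a
  }
  cfg <- mergeList(base, cfg)
  for (nm in c("offRange")) # yaml reads numeric vectors as lists
    cfg$protocol[[nm]] <- as.numeric(unlist(cfg$protocol[[nm]]))
  cfg$cohort$colors <- as.character(unlist(cfg$cohort$colors))
  cfg$cohort$fnirsParams <- as.character(unlist(cfg$cohort$fnirsParams))
  cfg$preprocess$mwaBand <- as.numeric(unlist(cfg$preprocess$mwaBand))
  cfg
}

# run block analysis for one subject x color
analyzeSubject <- function(recording, cfg, covariates, subjectId) {
  pp <- preprocessRecording(recording, cfg$preprocess,
                            channels = cfg$preprocess$channels)
  blocks <- segmentTrials(pp, signals = intersect(canonicalAnalysisSignals(),
                                                  channelNames(pp)))
  blocks <- lapply(blocks, function(b)
    intervalMedians(normalizeDetrend(b, cfg$stats$detrendMode)))
  res <- subjectLevelGate(blocks, alpha = cfg$stats$alpha,
                          family = cfg$stats$fdrFamily,
                          covariates = covariates, subjectId = subjectId)
  list(result = res, blocks = blocks)
}

#' Run the full simulation-to-report pipeline
#'
#' Simulates (or ingests) a crossover cohort, preprocesses every
#' recording, runs the block-average branch (trial segmentation,
#' normalization, interval medians, subject-level signed-rank gate,
#' group-level quantile regression per region and color plus a full model
#' with color contrasts, age and gender), optionally the connectivity
#' branch (per-trial masked Spearman matrices, group averages per color,
#' per-subject network metrics, between-color rank-sum comparisons), and
#' writes a reproducible report bundle.
#'
#' The machine-readable summary flags a region x color response as
#' significant when the per-color group stimulus model (intercept-only
#' median regression over the gated, zero-weighted pooled left+right
#' responses) has a bootstrap CI excluding zero.
#'
#' @param config configuration list from [defaultRunConfig()]
#' @param cohort optionally, a pre-generated cohort (as from
#'   [generateCohort()]) to analyze instead of simulating one
#' @return (invisibly) list with elements \code{results} (subject results),
#'   \code{regionColor} (per region x color significance table),
#'   \code{contrasts} (full-model terms per region), \code{connectivity}
#'   (group matrices, per-subject metrics, comparisons; NULL if disabled),
#'   and \code{summary}
#' @export
runPipeline <- function(config = defaultRunConfig(), cohort = NULL) {
  cfg <- config
  if (is.null(cohort))
    cohort <- generateCohort(
      nSubjects = cfg$cohort$nSubjects, seed = cfg$seed,
      scenario = cfg$cohort$scenario, colors = cfg$cohort$colors,
      fs = cfg$cohort$fs, fnirsParams = cfg$cohort$fnirsParams,
      includeSystemic = cfg$cohort$includeSystemic,
      ampVariability = cfg$cohort$ampVariability,
      timelineArgs = cfg$protocol[c("nBlocks", "onDuration", "offRange",
                                    "baseline", "recovery")],
      artifactArgs = cfg$cohort$artifacts)
  colors <- cfg$cohort$colors
  nSub <- length(cohort$profiles)
  results <- list()
  blocksAll <- list()
  for (i in seq_len(nSub)) {
    prof <- cohort$profiles[[i]]
    for (color in colors) {
      key <- paste(prof@subjectId, color, sep = ".")
      an <- analyzeSubject(cohort$recordings[[i]][[color]], cfg,
                           covariates = list(color = color,
                                             age = prof@age,
                                             gender = prof@gender),
                           subjectId = prof@subjectId)
      results[[key]] <- an$result
      blocksAll[[key]] <- an$blocks
    }
  }
  param <- cfg$stats$groupParam
  regions <- c("VC", "PFC")
  ## per-color stimulus models and full contrast models
  rcRows <- list()
  ctRows <- list()
  for (rg in regions) {
    sigs <- regionSignals(rg, param)
    if (!all(sigs %in% rownames(results[[1L]]@blockAverage))) next
    for (color in colors) {
      sub <- Filter(function(r) identical(r@covariates$color, color),
                    results)
      gm <- groupQuantileRegression(sub, sigs, terms = character(),
                                    tau = cfg$stats$tau,
                                    nBoot = cfg$stats$nBoot,
                                    seed = childSeed(cfg$seed, 11L),
                                    zeroWeight = cfg$stats$zeroWeight)
      rcRows[[paste(rg, color)]] <- data.frame(
        region = rg, color = color,
        estimate = if (gm@indeterminate) NA_real_ else gm@coefficients[[1L]],
        lower = if (gm@indeterminate) NA_real_ else gm@ci[1L, 1L],
        upper = if (gm@indeterminate) NA_real_ else gm@ci[2L, 1L],
        nGated = gm@nGated,
        significant = !gm@indeterminate && gm@significant[[1L]],
        stringsAsFactors = FALSE)
    }
    if (length(colors) >= 2L) {
      gm <- groupQuantileRegression(results, sigs,
                                    terms = c("color", "age", "gender"),
                                    tau = cfg$stats$tau,
                                    nBoot = cfg$stats$nBoot,
                                    seed = childSeed(cfg$seed, 13L),
                                    referenceColor = cfg$stats$referenceColor,
                                    zeroWeight = cfg$stats$zeroWeight)
      if (!gm@indeterminate) {
        tab <- data.frame(
          region = rg, term = gm@terms, estimate = gm@coefficients,
          lower = gm@ci[1L, ], upper = gm@ci[2L, ],
          significant = gm@significant, row.names = NULL,
          stringsAsFactors = FALSE)
        # derived pairwise contrast between the two non-reference colors
        nonref <- grep("^color", gm@terms, value = TRUE)
        if (length(nonref) == 2L) {
          d <- gm@bootstrap[, nonref[2L]] - gm@bootstrap[, nonref[1L]]
          est2 <- gm@coefficients[[nonref[2L]]] -
            gm@coefficients[[nonref[1L]]]
          qd <- quantile(d, c(0.025, 0.975), na.rm = TRUE)
          lo2 <- min(qd[1L], est2); hi2 <- max(qd[2L], est2)
          tab <- rbind(tab, data.frame(
            region = rg, term = paste(nonref[2L], "-", nonref[1L]),
            estimate = est2, lower = lo2, upper = hi2,
            significant = lo2 > 0 | hi2 < 0, row.names = NULL,
            stringsAsFactors = FALSE))
        }
        ctRows[[rg]] <- tab
      }
    }
  }
  regionColor <- if (length(rcRows))
    do.call(rbind, c(rcRows, list(make.row.names = FALSE))) else NULL
  contrasts <- if (length(ctRows))
    do.call(rbind, c(ctRows, list(make.row.names = FALSE))) else NULL
  ## connectivity branch
  conn <- NULL
  if (isTRUE(cfg$connectivity$enabled)) {
    conn <- connectivityBranch(results, blocksAll, colors, cfg)
  }
  summary <- list(regionColor = regionColor, contrasts = contrasts,
                  nSubjects = nSub, seed = cfg$seed)
  out <- list(results = results, regionColor = regionColor,
              contrasts = contrasts, connectivity = conn,
              summary = summary, config = cfg)
  if (!is.null(cfg$outDir)) writeBundle(out, cfg)
  invisible(out)
}

connectivityBranch <- function(results, blocksAll, colors, cfg) {
  perSubjectMetrics <- stats::setNames(vector("list", length(colors)),
                                       colors)
  groupMatrices <- list()
  for (color in colors) {
    keys <- grep(paste0("\\.", color, "$"), names(blocksAll), value = TRUE)
    allTrials <- list()
    metrics <- list()
    for (key in keys) {
      mats <- lapply(blocksAll[[key]], trialCorrelationMatrix,
                     alpha = cfg$connectivity$alpha)
      allTrials <- c(allTrials, mats)
      subjAvg <- averageMatrices(mats, cfg$connectivity$deletedAsZero)
      g <- toNetwork(subjAvg, cfg$connectivity$weightTransform)
      metrics[[key]] <- networkMetrics(g)
    }
    perSubjectMetrics[[color]] <- metrics
    groupMatrices[[color]] <- averageMatrices(allTrials,
                                              cfg$connectivity$deletedAsZero)
  }
  comparisons <- if (length(colors) >= 2L &&
                     all(lengths(perSubjectMetrics) >= 3L))
    compareColors(perSubjectMetrics) else NULL
  list(groupMatrices = groupMatrices,
       perSubjectMetrics = perSubjectMetrics,
       comparisons = comparisons)
}

writeBundle <- function(out, cfg) {
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  writeRunConfig(cfg, file.path(cfg$outDir, "config.yaml"))
  ba <- do.call(rbind, lapply(names(out$results), function(key) {
    r <- out$results[[key]]
    data.frame(subject = r@subjectId, color = r@covariates$color,
               signal = rownames(r@blockAverage),
               weight = r@weight,
               as.data.frame(r@blockAverage), row.names = NULL)
  }))
  names(ba)[5:11] <- paste0("interval", 1:7)
  data.table::fwrite(ba, file.path(cfg$outDir, "block_averages.tsv"),
                     sep = "\t")
  if (!is.null(out$regionColor))
    data.table::fwrite(out$regionColor,
                       file.path(cfg$outDir, "group_region_color.tsv"),
                       sep = "\t")
  if (!is.null(out$contrasts))
    data.table::fwrite(out$contrasts,
                       file.path(cfg$outDir, "group_contrasts.tsv"),
                       sep = "\t")
  if (!is.null(out$connectivity)) {
    for (color in names(out$connectivity$groupMatrices))
      writeConnectivityMatrix(out$connectivity$groupMatrices[[color]],
                              file.path(cfg$outDir,
                                        sprintf("connectivity_%s.tsv", color)))
    met <- do.call(rbind, lapply(names(out$connectivity$perSubjectMetrics),
      function(color) {
        lst <- out$connectivity$perSubjectMetrics[[color]]
        data.frame(color = color, key = names(lst),
                   do.call(rbind, lapply(lst, as.numeric)),
                   row.names = NULL)
      }))
    data.table::fwrite(met, file.path(cfg$outDir, "network_metrics.tsv"),
                       sep = "\t")
    if (!is.null(out$connectivity$comparisons))
      data.table::fwrite(out$connectivity$comparisons,
                         file.path(cfg$outDir, "network_comparisons.tsv"),
                         sep = "\t")
  }
  jsonlite::write_json(out$summary,
                       file.path(cfg$outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(cfg$outDir)
}
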