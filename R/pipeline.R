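## End-to-end orchestration: YAML run configs, seeded simulation or file
## input, per-condition periodicity / co-IP / neurite reports, and a
## reproducibility manifest.

.asConfig <- function(section, ctor, seed) {
  args <- section
  if (!is.null(seed)) args$seed <- seed
  do.call(ctor, args)
}

.validatePipelineConfig <- function(cfg) {
  known <- c("seed", "out", "periodicity", "control", "twocolor", "coip",
             "neurite")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop(sprintf("unknown config section(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  for (sec in c("periodicity", "control", "twocolor")) {
    if (!is.null(cfg[[sec]]) &&
        is.null(cfg[[sec]]$simulate) && is.null(cfg[[sec]]$input))
      stop(sprintf("section '%s' requests periodicity analysis without a localization input (need 'simulate' or 'input')",
                   sec), call. = FALSE)
  }
  invisible(TRUE)
}

.loadLocInput <- function(section, simFun, seed) {
  if (!is.null(section$simulate)) {
    cfg <- .asConfig(section$simulate, mpsSimConfig, seed)
    simFun(cfg)
  } else {
    list(localizations = readLocalizations(section$input$localizations),
         rois = readSegmentROIs(section$input$rois))
  }
}

#' Run the analysis pipeline from a structured config
#'
#' Executes the configured stages (periodicity on periodic and/or control
#' data, two-color cross-correlation, co-IP filtering, neurite metrics) in
#' order, writes curves, metrics and candidate lists to the output directory,
#' and finishes with a reproducibility manifest (seed, config hash, package
#' version, output hashes). The same config and seed reproduce the bundle
#' bit-identically.
#'
#' @param config path to a YAML config file, or an equivalent named list.
#'   Top-level keys: \code{seed}, \code{out}, and optional sections
#'   \code{periodicity}, \code{control}, \code{twocolor} (each with either
#'   \code{simulate:} generator parameters or \code{input:} file paths, plus
#'   optional \code{bin_size}, \code{max_lag}), \code{coip}
#'   (\code{simulate:} parameters), and \code{neurite} (\code{simulate:}
#'   parameters, optional \code{radius}).
#' @param outDir output directory; overrides the config's \code{out}.
#' @param seed integer seed; overrides the config's \code{seed}.
#' @return Invisibly, a list with the computed results and the manifest.
#' @export
runPipeline <- function(config, outDir = NULL, seed = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  .validatePipelineConfig(cfg)
  if (is.null(seed)) seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  if (is.null(outDir)) outDir <- if (is.null(cfg$out)) "mps-run" else cfg$out
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  outputs <- character(0)

  writeCurve <- function(curve, name) {
    f <- file.path(outDir, paste0(name, ".csv"))
    utils::write.table(data.frame(lag_nm = curve@lags, value = curve@values),
                       f, sep = ",", row.names = FALSE, quote = FALSE)
    outputs[[length(outputs) + 1L]] <<- f
  }
  writeJson <- function(x, name) {
    f <- file.path(outDir, paste0(name, ".json"))
    jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    outputs[[length(outputs) + 1L]] <<- f
  }

  for (sec in c("periodicity", "control")) {
    if (is.null(cfg[[sec]])) next
    s <- cfg[[sec]]
    simFun <- if (sec == "control") simulateUniformControl else simulateMpsLocalizations
    dat <- .loadLocInput(s, simFun, .subSeed(seed, sec))
    res <- mpsPeriodicity(dat$localizations, dat$rois,
                          binSize = s$bin_size %||% 10,
                          maxLag = s$max_lag %||% 600)
    writeCurve(res$curve, paste0(sec, "_autocorrelation"))
    m <- res$metrics
    writeJson(list(amplitude = m@amplitude, period_nm = m@period,
                   peak_lag_nm = m@peakLag, valley_lags_nm = m@valleyLags,
                   n_segments = res$curve@nAveraged),
              paste0(sec, "_metrics"))
    results[[sec]] <- res
  }

  if (!is.null(cfg$twocolor)) {
    s <- cfg$twocolor
    if (!is.null(s$simulate)) {
      s$simulate$nChannels <- 2L
      dat <- .loadLocInput(s, simulateTwoColorLocalizations,
                           .subSeed(seed, "twocolor"))
    } else {
      dat <- .loadLocInput(s, NULL, NULL)
    }
    cc <- mpsCrossCorrelation(dat$localizations, dat$rois,
                              binSize = s$bin_size %||% 10,
                              maxLag = s$max_lag %||% 600)
    writeCurve(cc$curve, "twocolor_crosscorrelation")
    results$twocolor <- cc
  }

  if (!is.null(cfg$coip)) {
    sim <- simulateSpectralCounts(.asConfig(cfg$coip$simulate, coipSimConfig,
                                            .subSeed(seed, "coip")))
    sc <- sim$counts
    baits <- sim$groundTruth$baits
    igG <- computeDnsaf(sc, "IgG")
    lists <- lapply(baits, function(b)
      foldChangeFilter(computeDnsaf(sc, b), igG))
    names(lists) <- baits
    inter <- intersectCandidates(lists)
    f <- file.path(outDir, "coip_candidates.txt")
    writeLines(candidateIds(inter$candidates), f)
    outputs[[length(outputs) + 1L]] <- f
    writeJson(as.list(inter$venn), "coip_venn")
    results$coip <- list(lists = lists, intersection = inter, sim = sim)
  }

  if (!is.null(cfg$neurite)) {
    scene <- simulateNeuriteScene(.asConfig(cfg$neurite$simulate,
                                            neuriteSceneConfig,
                                            .subSeed(seed, "neurite")))
    wid <- meanFiberWidth(scene$axonMask)
    bf <- dendriteBundlingFraction(scene$axonMask, scene$dendriteMask)
    syn <- synapseDensity(scene$prePuncta, scene$postPuncta,
                          scene$dendriteMask,
                          radius = cfg$neurite$radius %||% 266)
    writeJson(list(mean_axon_width_nm = wid@meanWidth,
                   bundling_fraction = bf,
                   synapse_density_per_um2 = syn$density,
                   n_synapses = syn$nMatched),
              "neurite_metrics")
    results$neurite <- list(width = wid, bundling = bf, synapses = syn,
                            scene = scene)
  }

  manifest <- list(
    package = "MPSkeleton",
    version = as.character(utils::packageVersion("MPSkeleton")),
    seed = seed,
    config_hash = .textHash(paste(deparse(cfg), collapse = "\n")),
    outputs = lapply(stats::setNames(outputs, basename(outputs)), function(f)
      .textHash(paste(readLines(f, warn = FALSE), collapse = "\n"))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
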