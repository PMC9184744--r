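#' @import methods
NULL

## ---- core data containers ---------------------------------------------------

#' Localizations: a table of single-molecule localizations
#'
#' Thin S4 wrapper around a data frame of localization coordinates in
#' nanometres, the unit of all periodicity analyses. Columns \code{x}, \code{y}
#' (nm), optional \code{z} (nm), \code{channel} (integer >= 1), \code{frame}
#' (integer >= 0) and optional \code{photons}.
#'
#' @slot data data.frame with the columns described above.
#' @export
setClass("Localizations", representation(data = "data.frame"))

setValidity("Localizations", function(object) {
  d <- object@data
  need <- c("x", "y", "channel", "frame")
  miss <- setdiff(need, names(d))
  if (length(miss)) return(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
  if (nrow(d)) {
    if (!all(is.finite(d$x)) || !all(is.finite(d$y)))
      return("coordinates must be finite")
    if (any(d$channel < 1)) return("channel must be >= 1")
    if (any(d$frame < 0)) return("frame must be >= 0")
    if ("z" %in% names(d) && !all(is.finite(d$z))) return("z must be finite")
  }
  TRUE
})

#' Construct a Localizations object
#'
#' @param x,y numeric coordinates in nm.
#' @param z optional numeric z coordinates in nm.
#' @param channel integer channel labels (>= 1), recycled.
#' @param frame integer frame indices (>= 0), recycled.
#' @param photons optional photon counts.
#' @return A \linkS4class{Localizations} object.
#' @examples
#' Localizations(x = c(0, 100), y = c(0, 0))
#' @export
Localizations <- function(x, y, z = NULL, channel = 1L, frame = 0L, photons = NULL) {
  n <- length(x)
  d <- data.frame(x = as.numeric(x), y = as.numeric(y))
  if (!is.null(z)) d$z <- as.numeric(z)
  d$channel <- as.integer(rep_len(channel, n))
  d$frame <- as.integer(rep_len(frame, n))
  if (!is.null(photons)) d$photons <- as.numeric(photons)
  if (n == 0L) {
    d <- data.frame(x = numeric(0), y = numeric(0),
                    channel = integer(0), frame = integer(0))
    if (!is.null(z)) d$z <- numeric(0)
    if (!is.null(photons)) d$photons <- numeric(0)
  }
  new("Localizations", data = d)
}

#' SegmentROI: a straight axon-segment region of interest
#'
#' A straight segment in global nm coordinates, defined by its two endpoints
#' and a half-width. Localizations within the half-width band and within the
#' axial extent belong to the segment.
#'
#' @slot a,b numeric(2), segment endpoints (nm).
#' @slot halfWidth half-width of the band around the axis (nm).
#' @slot label character label.
#' @export
setClass("SegmentROI", representation(a = "numeric", b = "numeric",
                                      halfWidth = "numeric", label = "character"))

setValidity("SegmentROI", function(object) {
  if (length(object@a) != 2L || length(object@b) != 2L)
    return("endpoints must be length-2 numeric")
  if (all(object@a == object@b)) return("endpoints must be distinct")
  if (object@halfWidth <= 0) return("halfWidth must be > 0")
  TRUE
})

#' Construct a SegmentROI
#'
#' @param a,b numeric(2) endpoints in nm.
#' @param halfWidth half-width in nm (> 0).
#' @param label segment label.
#' @return A \linkS4class{SegmentROI}.
#' @export
SegmentROI <- function(a, b, halfWidth, label = "") {
  new("SegmentROI", a = as.numeric(a), b = as.numeric(b),
      halfWidth = as.numeric(halfWidth), label = as.character(label))
}

#' Profile1D: a binned 1D localization profile
#'
#' Histogram of axial positions along a segment, the "1D projected signal"
#' from which correlation functions are computed. Bins are half-open
#' \code{[origin + i*binSize, origin + (i+1)*binSize)}.
#'
#' @slot binSize bin width (nm).
#' @slot origin left edge of the first bin (nm).
#' @slot counts non-negative numeric counts per bin.
#' @slot label segment label.
#' @export
setClass("Profile1D", representation(binSize = "numeric", origin = "numeric",
                                     counts = "numeric", label = "character"))

setValidity("Profile1D", function(object) {
  if (object@binSize <= 0) return("binSize must be > 0")
  if (any(object@counts < 0)) return("counts must be >= 0")
  TRUE
})

#' CorrelationCurve: a normalized 1D auto- or cross-correlation
#'
#' Lags are uniformly spaced with step equal to the profile bin size;
#' autocorrelation lags start at 0, cross-correlation lags are symmetric
#' about 0. A degenerate curve (zero-variance input) carries all-zero values
#' and \code{degenerate = TRUE}.
#'
#' @slot lags lag values (nm).
#' @slot values unitless correlation values.
#' @slot nAveraged number of per-segment curves averaged into this one.
#' @slot degenerate logical degeneracy flag.
#' @slot type "acf" or "ccf".
#' @export
setClass("CorrelationCurve", representation(lags = "numeric", values = "numeric",
                                            nAveraged = "integer",
                                            degenerate = "logical", type = "character"))

setValidity("CorrelationCurve", function(object) {
  if (length(object@lags) != length(object@values))
    return("lags and values must have equal length")
  if (length(object@lags) > 1L) {
    st <- diff(object@lags)
    if (max(abs(st - st[1])) > 1e-6) return("lags must be uniformly spaced")
  }
  TRUE
})

## ---- result containers ------------------------------------------------------

#' PeriodicityResult: amplitude and period of an averaged autocorrelation
#'
#' The periodicity statistic: amplitude is the value at the first peak
#' (~190 nm) minus the mean of the two first valleys (~95 and ~285 nm); the
#' period is the lag of the first peak.
#'
#' @slot amplitude unitless amplitude.
#' @slot period first-peak lag (nm); NA for degenerate curves.
#' @slot peakLag lag of the first peak (nm).
#' @slot valleyLags lags of the two valleys (nm).
#' @slot peakWindow,valleyWindows search windows used (nm).
#' @slot degenerate logical flag.
#' @export
setClass("PeriodicityResult", representation(amplitude = "numeric", period = "numeric",
                                             peakLag = "numeric", valleyLags = "numeric",
                                             peakWindow = "numeric", valleyWindows = "list",
                                             degenerate = "logical"))

#' PhaseEstimate: first-harmonic phase of a periodic profile
#'
#' @slot phase phase in radians, in [0, 2*pi).
#' @slot period period used (nm).
#' @slot strength unitless modulation strength in [0, 1].
#' @export
setClass("PhaseEstimate", representation(phase = "numeric", period = "numeric",
                                         strength = "numeric"))

#' TestResult: two-sample comparison of replicate-level amplitudes
#'
#' Classical pooled-variance two-sided t-test with group means and standard
#' errors of the mean.
#'
#' @slot means,sems group means and s.e.m. values.
#' @slot statistic t statistic.
#' @slot pValue two-sided p-value.
#' @slot n group sizes.
#' @export
setClass("TestResult", representation(means = "numeric", sems = "numeric",
                                      statistic = "numeric", pValue = "numeric",
                                      n = "integer"))

## ---- co-IP containers -------------------------------------------------------

#' SpectralCounts: per-protein, per-sample spectral counts
#'
#' Long-format spectral-count data for dNSAF scoring. Unique counts are per
#' (protein, sample, replicate); shared-peptide counts name the set of
#' proteins sharing each peptide.
#'
#' @slot proteins data.frame(protein_id, length).
#' @slot uniqueCounts data.frame(protein_id, sample, replicate, count).
#' @slot sharedCounts data.frame(peptide_id, sample, replicate, count, sharers)
#'   where \code{sharers} is a ";"-separated list of protein ids.
#' @export
setClass("SpectralCounts", representation(proteins = "data.frame",
                                          uniqueCounts = "data.frame",
                                          sharedCounts = "data.frame"))

setValidity("SpectralCounts", function(object) {
  p <- object@proteins
  if (!all(c("protein_id", "length") %in% names(p)))
    return("proteins must have protein_id and length")
  if (nrow(p) && any(p$length <= 0)) return("protein lengths must be > 0")
  if (anyDuplicated(p$protein_id)) return("duplicated protein_id")
  u <- object@uniqueCounts
  if (!all(c("protein_id", "sample", "replicate", "count") %in% names(u)))
    return("uniqueCounts must have protein_id, sample, replicate, count")
  if (nrow(u) && any(u$count < 0)) return("counts must be >= 0")
  s <- object@sharedCounts
  if (nrow(s)) {
    if (!all(c("peptide_id", "sample", "replicate", "count", "sharers") %in% names(s)))
      return("sharedCounts must have peptide_id, sample, replicate, count, sharers")
    ns <- vapply(strsplit(s$sharers, ";", fixed = TRUE), length, 1L)
    if (any(ns < 2L)) return("every shared peptide must name >= 2 proteins")
  }
  TRUE
})

#' Construct a SpectralCounts object
#'
#' @param proteins data.frame(protein_id, length in residues).
#' @param uniqueCounts data.frame(protein_id, sample, replicate, count).
#' @param sharedCounts optional data.frame(peptide_id, sample, replicate,
#'   count, sharers) with ";"-separated sharer ids.
#' @return A \linkS4class{SpectralCounts}.
#' @export
SpectralCounts <- function(proteins, uniqueCounts, sharedCounts = NULL) {
  if (is.null(sharedCounts))
    sharedCounts <- data.frame(peptide_id = character(0), sample = character(0),
                               replicate = integer(0), count = numeric(0),
                               sharers = character(0))
  new("SpectralCounts", proteins = as.data.frame(proteins),
      uniqueCounts = as.data.frame(uniqueCounts),
      sharedCounts = as.data.frame(sharedCounts))
}

#' DNSAFTable: dNSAF scores for one sample
#'
#' @slot sample sample label.
#' @slot table data.frame(protein_id, length, dSpC, dNSAF); dNSAF sums to 1.
#' @export
setClass("DNSAFTable", representation(sample = "character", table = "data.frame"))

#' CandidateList: an ordered, duplicate-free list of candidate proteins
#'
#' @slot ids ordered character vector of protein ids (no duplicates).
#' @slot scores optional named numeric scores (e.g. fold changes).
#' @slot provenance list recording how the list was produced.
#' @export
setClass("CandidateList", representation(ids = "character", scores = "numeric",
                                         provenance = "list"))

setValidity("CandidateList", function(object) {
  if (anyDuplicated(object@ids)) return("candidate ids must be unique")
  TRUE
})

#' Construct a CandidateList
#' @param ids character protein ids (deduplicated, order kept).
#' @param scores optional named numeric scores.
#' @param provenance list of provenance metadata.
#' @return A \linkS4class{CandidateList}.
#' @export
CandidateList <- function(ids, scores = numeric(0), provenance = list()) {
  ids <- as.character(ids)
  keep <- !duplicated(ids)
  new("CandidateList", ids = ids[keep],
      scores = if (length(scores)) scores[keep] else numeric(0),
      provenance = provenance)
}

## ---- image containers -------------------------------------------------------

#' MaskImage: a binary 2D image with physical pixel size
#'
#' Pixel centres sit at \code{(i - 0.5, j - 0.5) * pixelSize} in nm for 1-based
#' matrix indices (row i = y, column j = x).
#'
#' @slot mask logical matrix (TRUE = foreground).
#' @slot pixelSize pixel size in nm.
#' @export
setClass("MaskImage", representation(mask = "matrix", pixelSize = "numeric"))

setValidity("MaskImage", function(object) {
  if (!is.logical(object@mask)) return("mask must be a logical matrix")
  if (!length(object@mask)) return("mask must be non-empty")
  if (object@pixelSize <= 0) return("pixelSize must be > 0")
  TRUE
})

#' Construct a MaskImage
#' @param mask logical (or coercible) matrix.
#' @param pixelSize pixel size in nm.
#' @return A \linkS4class{MaskImage}.
#' @export
MaskImage <- function(mask, pixelSize) {
  m <- mask
  storage.mode(m) <- "logical"
  new("MaskImage", mask = m, pixelSize = as.numeric(pixelSize))
}

#' PunctaSet: point markers (e.g. synaptic puncta) in nm
#'
#' @slot coords n x 2 numeric matrix of (x, y) in nm.
#' @slot channel channel label, e.g. "pre" or "post".
#' @export
setClass("PunctaSet", representation(coords = "matrix", channel = "character"))

#' Construct a PunctaSet
#' @param coords n x 2 matrix (x, y) in nm.
#' @param channel channel label.
#' @return A \linkS4class{PunctaSet}.
#' @export
PunctaSet <- function(coords, channel = "pre") {
  coords <- matrix(as.numeric(coords), ncol = 2,
                   dimnames = list(NULL, c("x", "y")))
  new("PunctaSet", coords = coords, channel = as.character(channel))
}

#' BundleWidthResult: medial-axis fiber width of a mask
#'
#' @slot meanWidth mean width (nm).
#' @slot widths per-skeleton-pixel widths (nm).
#' @slot skeletonLength total skeleton length (nm).
#' @export
setClass("BundleWidthResult", representation(meanWidth = "numeric",
                                             widths = "numeric",
                                             skeletonLength = "numeric"))

## ---- simulation configs -----------------------------------------------------

#' MPSSimConfig: configuration of the periodic-skeleton localization generator
#'
#' Defaults reproduce the geometry the analyses assume: rings every 190 nm
#' along 2-um segments, finite labeling (Poisson localizations per ring),
#' 10-nm localization precision, 15-nm ring jitter and a 20% uniform
#' background.
#'
#' @slot nSegments number of segments.
#' @slot segmentLength segment length (nm).
#' @slot ringSpacing ring period d (nm).
#' @slot ringSd axial ring jitter s.d. (nm).
#' @slot locsPerRing mean localizations per ring (Poisson).
#' @slot locPrecision localization precision s.d. (nm).
#' @slot backgroundFraction fraction of localizations that are uniform
#'   background, in [0, 1).
#' @slot lateralSd lateral spread around the axis (nm).
#' @slot orientation "random" or numeric per-segment angles (radians).
#' @slot phase "random" or numeric per-segment phases in [0, d).
#' @slot nChannels 1 or 2.
#' @slot channelPhaseOffset channel-2 offset as a fraction of d, in [0, 1).
#' @slot seed integer seed.
#' @export
setClass("MPSSimConfig", representation(
  nSegments = "integer", segmentLength = "numeric", ringSpacing = "numeric",
  ringSd = "numeric", locsPerRing = "numeric", locPrecision = "numeric",
  backgroundFraction = "numeric", lateralSd = "numeric",
  orientation = "ANY", phase = "ANY", nChannels = "integer",
  channelPhaseOffset = "numeric", seed = "integer"))

setValidity("MPSSimConfig", function(object) {
  if (object@nSegments < 1L) return("field 'nSegments' must be >= 1")
  if (object@ringSpacing <= 0) return("field 'ringSpacing' must be > 0")
  if (object@segmentLength < 2 * object@ringSpacing)
    return("field 'segmentLength' must be >= 2 * ringSpacing")
  if (object@backgroundFraction < 0 || object@backgroundFraction >= 1)
    return("field 'backgroundFraction' must be in [0, 1)")
  if (object@ringSd < 0) return("field 'ringSd' must be >= 0")
  if (object@locPrecision < 0) return("field 'locPrecision' must be >= 0")
  if (object@lateralSd < 0) return("field 'lateralSd' must be >= 0")
  if (object@locsPerRing <= 0) return("field 'locsPerRing' must be > 0")
  if (!object@nChannels %in% c(1L, 2L)) return("field 'nChannels' must be 1 or 2")
  if (object@channelPhaseOffset < 0 || object@channelPhaseOffset >= 1)
    return("field 'channelPhaseOffset' must be in [0, 1)")
  if (is.numeric(object@phase) &&
      any(object@phase < 0 | object@phase >= object@ringSpacing))
    return("field 'phase' must be in [0, ringSpacing)")
  TRUE
})

#' Construct an MPSSimConfig
#'
#' @param nSegments number of axon segments (default 50).
#' @param segmentLength segment length in nm (default 2000).
#' @param ringSpacing ring period in nm (default 190).
#' @param ringSd axial ring jitter s.d. in nm (default 15).
#' @param locsPerRing mean localizations per ring (default 30).
#' @param locPrecision localization precision s.d. in nm (default 10).
#' @param backgroundFraction uniform background fraction in [0,1) (default 0.2).
#' @param lateralSd lateral spread s.d. in nm (default 40).
#' @param orientation "random" or per-segment angles in radians.
#' @param phase "random" or per-segment phases in nm, in [0, ringSpacing).
#' @param nChannels 1 or 2.
#' @param channelPhaseOffset channel-2 ring offset as a fraction of the period
#'   (default 0.5, i.e. anti-phase).
#' @param seed integer seed.
#' @return An \linkS4class{MPSSimConfig}.
#' @export
mpsSimConfig <- function(nSegments = 50L, segmentLength = 2000, ringSpacing = 190,
                         ringSd = 15, locsPerRing = 30, locPrecision = 10,
                         backgroundFraction = 0.2, lateralSd = 40,
                         orientation = "random", phase = "random",
                         nChannels = 1L, channelPhaseOffset = 0.5, seed = 1L) {
  obj <- try(new("MPSSimConfig",
                 nSegments = as.integer(nSegments),
                 segmentLength = as.numeric(segmentLength),
                 ringSpacing = as.numeric(ringSpacing),
                 ringSd = as.numeric(ringSd), locsPerRing = as.numeric(locsPerRing),
                 locPrecision = as.numeric(locPrecision),
                 backgroundFraction = as.numeric(backgroundFraction),
                 lateralSd = as.numeric(lateralSd), orientation = orientation,
                 phase = phase, nChannels = as.integer(nChannels),
                 channelPhaseOffset = as.numeric(channelPhaseOffset),
                 seed = as.integer(seed)), silent = TRUE)
  if (inherits(obj, "try-error"))
    stop(sprintf("invalid configuration: %s",
                 sub(".*invalid class.*object: ", "", attr(obj, "condition")$message)),
         call. = FALSE)
  obj
}

#' CoIPSimConfig: configuration of the co-IP spectral-count generator
#'
#' Emulates the three-bait (plus IgG control) co-immunoprecipitation design:
#' every protein draws Poisson baseline counts in the IgG samples, true
#' interactors are enriched by a fold multiplier in the bait samples, and a
#' fraction of counts is assigned to peptides shared between paired proteins.
#'
#' @slot nProteins,proteinLengths,nTrueInteractors,baitEnrichment,baselineCount
#'   see \code{\link{coipSimConfig}}.
#' @slot sharedPeptideFraction,nBaits,nReplicates,seed see
#'   \code{\link{coipSimConfig}}.
#' @export
setClass("CoIPSimConfig", representation(
  nProteins = "integer", proteinLengths = "numeric", nTrueInteractors = "integer",
  baitEnrichment = "numeric", baselineCount = "numeric",
  sharedPeptideFraction = "numeric", nBaits = "integer", nReplicates = "integer",
  seed = "integer"))

setValidity("CoIPSimConfig", function(object) {
  if (object@nProteins < 2L) return("field 'nProteins' must be >= 2")
  if (length(object@proteinLengths) != object@nProteins)
    return("field 'proteinLengths' must have nProteins entries")
  if (any(object@proteinLengths <= 0)) return("field 'proteinLengths' must be > 0")
  if (object@nTrueInteractors > object@nProteins)
    return("field 'nTrueInteractors' must be <= nProteins")
  if (object@baitEnrichment <= 1) return("field 'baitEnrichment' must be > 1")
  if (object@baselineCount <= 0) return("field 'baselineCount' must be > 0")
  if (object@sharedPeptideFraction < 0 || object@sharedPeptideFraction >= 1)
    return("field 'sharedPeptideFraction' must be in [0, 1)")
  if (object@nBaits < 1L) return("field 'nBaits' must be >= 1")
  if (object@nReplicates < 1L) return("field 'nReplicates' must be >= 1")
  TRUE
})

#' Construct a CoIPSimConfig
#'
#' @param nProteins number of proteins (default 60).
#' @param proteinLengths amino-acid lengths; default an even spread 200-1200.
#' @param nTrueInteractors number of true interactors (default 10).
#' @param baitEnrichment fold multiplier on interactor counts in bait samples
#'   (default 10, must be > 1).
#' @param baselineCount mean baseline spectral count (default 20).
#' @param sharedPeptideFraction fraction of each protein's counts carried by
#'   peptides shared with a partner protein (default 0.1).
#' @param nBaits number of bait pulldowns (default 3).
#' @param nReplicates biological replicates per sample (default 2).
#' @param seed integer seed.
#' @return A \linkS4class{CoIPSimConfig}.
#' @export
coipSimConfig <- function(nProteins = 60L, proteinLengths = NULL,
                          nTrueInteractors = 10L, baitEnrichment = 10,
                          baselineCount = 20, sharedPeptideFraction = 0.1,
                          nBaits = 3L, nReplicates = 2L, seed = 1L) {
  if (is.null(proteinLengths))
    proteinLengths <- round(seq(200, 1200, length.out = nProteins))
  obj <- try(new("CoIPSimConfig", nProteins = as.integer(nProteins),
                 proteinLengths = as.numeric(proteinLengths),
                 nTrueInteractors = as.integer(nTrueInteractors),
                 baitEnrichment = as.numeric(baitEnrichment),
                 baselineCount = as.numeric(baselineCount),
                 sharedPeptideFraction = as.numeric(sharedPeptideFraction),
                 nBaits = as.integer(nBaits), nReplicates = as.integer(nReplicates),
                 seed = as.integer(seed)), silent = TRUE)
  if (inherits(obj, "try-error"))
    stop(sprintf("invalid configuration: %s",
                 sub(".*invalid class.*object: ", "", attr(obj, "condition")$message)),
         call. = FALSE)
  obj
}

#' NeuriteSceneConfig: configuration of the neurite-scene generator
#'
#' Generates axon and dendrite masks (smooth random paths dilated to their
#' widths), optional axon-along-dendrite bundling, and paired pre/post
#' synaptic puncta on dendrites.
#'
#' @slot imageShape,pixelSize,nAxons,nDendrites see
#'   \code{\link{neuriteSceneConfig}}.
#' @slot axonWidth,dendriteWidth,bundlingProbability see
#'   \code{\link{neuriteSceneConfig}}.
#' @slot nSynapsePairs,pairOffsetSd,nOrphanPuncta,seed see
#'   \code{\link{neuriteSceneConfig}}.
#' @export
setClass("NeuriteSceneConfig", representation(
  imageShape = "integer", pixelSize = "numeric", nAxons = "integer",
  nDendrites = "integer", axonWidth = "numeric", dendriteWidth = "numeric",
  bundlingProbability = "numeric", nSynapsePairs = "integer",
  pairOffsetSd = "numeric", nOrphanPuncta = "integer", seed = "integer"))

setValidity("NeuriteSceneConfig", function(object) {
  if (length(object@imageShape) != 2L || any(object@imageShape < 16L))
    return("field 'imageShape' must be two dimensions >= 16")
  if (object@pixelSize <= 0) return("field 'pixelSize' must be > 0")
  if (object@axonWidth <= 0) return("field 'axonWidth' must be > 0")
  if (object@dendriteWidth <= 0) return("field 'dendriteWidth' must be > 0")
  ext <- min(object@imageShape) * object@pixelSize
  if (object@axonWidth >= ext || object@dendriteWidth >= ext)
    return("field 'axonWidth'/'dendriteWidth' must be smaller than the image extent")
  if (object@bundlingProbability < 0 || object@bundlingProbability > 1)
    return("field 'bundlingProbability' must be in [0, 1]")
  if (object@pairOffsetSd < 0) return("field 'pairOffsetSd' must be >= 0")
  if (object@nSynapsePairs < 0) return("field 'nSynapsePairs' must be >= 0")
  if (object@nOrphanPuncta < 0) return("field 'nOrphanPuncta' must be >= 0")
  TRUE
})

#' Construct a NeuriteSceneConfig
#'
#' @param imageShape image dimensions in pixels (rows, cols), default c(400, 400).
#' @param pixelSize pixel size in nm (default 133).
#' @param nAxons,nDendrites numbers of axon and dendrite paths.
#' @param axonWidth,dendriteWidth neurite widths in nm.
#' @param bundlingProbability probability that an axon is laid along a
#'   dendrite path.
#' @param nSynapsePairs number of paired pre/post puncta on dendrites.
#' @param pairOffsetSd per-coordinate s.d. of the pre/post offset (nm).
#' @param nOrphanPuncta unpaired puncta added per channel.
#' @param seed integer seed.
#' @return A \linkS4class{NeuriteSceneConfig}.
#' @export
neuriteSceneConfig <- function(imageShape = c(400L, 400L), pixelSize = 133,
                               nAxons = 8L, nDendrites = 5L,
                               axonWidth = 800, dendriteWidth = 1200,
                               bundlingProbability = 0.5, nSynapsePairs = 30L,
                               pairOffsetSd = 50, nOrphanPuncta = 10L, seed = 1L) {
  obj <- try(new("NeuriteSceneConfig", imageShape = as.integer(imageShape),
                 pixelSize = as.numeric(pixelSize), nAxons = as.integer(nAxons),
                 nDendrites = as.integer(nDendrites),
                 axonWidth = as.numeric(axonWidth),
                 dendriteWidth = as.numeric(dendriteWidth),
                 bundlingProbability = as.numeric(bundlingProbability),
                 nSynapsePairs = as.integer(nSynapsePairs),
                 pairOffsetSd = as.numeric(pairOffsetSd),
                 nOrphanPuncta = as.integer(nOrphanPuncta),
                 seed = as.integer(seed)), silent = TRUE)
  if (inherits(obj, "try-error"))
    stop(sprintf("invalid configuration: %s",
                 sub(".*invalid class.*object: ", "", attr(obj, "condition")$message)),
         call. = FALSE)
  obj
}
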