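## Synthetic single-molecule localization data for the periodic membrane
## skeleton: rings every ~190 nm along straight 2-um segments with finite
## labeling, localization precision, ring jitter, lateral spread and a
## uniform background; optional second channel with a phase-offset ring set.
##
## All draws use named substreams derived from the config seed, so adding a
## stochastic component never shifts the draws of existing ones, and the
## same config + seed always reproduces the same table.

# Place segment i on a coarse grid with enough clearance that rotated
# segments never overlap a neighbouring ROI band.
.segmentOrigin <- function(i, segLen) {
  pitch <- 2 * segLen + 1000
  c((((i - 1) %% 10)) * pitch, ((i - 1) %/% 10) * pitch)
}

# Draw per-segment localizations in the local (axial, lateral) frame for one
# channel. Ring centres at phase + (k + chOffset) * d for k = 0..floor(L/d).
.drawSegmentChannel <- function(cfg, phase, chOffset) {
  d <- cfg@ringSpacing
  L <- cfg@segmentLength
  kmax <- floor(L / d)
  centers <- phase + ((0:kmax) + chOffset) * d
  nPerRing <- stats::rpois(length(centers), cfg@locsPerRing)
  nRing <- sum(nPerRing)
  axial <- rep(centers, nPerRing)
  if (nRing > 0) {
    axial <- axial + stats::rnorm(nRing, 0, cfg@ringSd) +
      stats::rnorm(nRing, 0, cfg@locPrecision)
  }
  lateral <- stats::rnorm(nRing, 0, cfg@lateralSd)
  bf <- cfg@backgroundFraction
  if (bf > 0) {
    nBg <- stats::rpois(1L, length(centers) * cfg@locsPerRing * bf / (1 - bf))
    axial <- c(axial, stats::runif(nBg, 0, L))
    lateral <- c(lateral, stats::rnorm(nBg, 0, cfg@lateralSd))
  }
  cbind(axial = axial, lateral = lateral)
}

.segmentAngles <- function(cfg) {
  if (identical(cfg@orientation, "random"))
    .withSubstream(cfg@seed, "orientation",
                   stats::runif(cfg@nSegments, 0, 2 * pi))
  else rep_len(as.numeric(cfg@orientation), cfg@nSegments)
}

.segmentPhases <- function(cfg) {
  if (identical(cfg@phase, "random"))
    .withSubstream(cfg@seed, "phase",
                   stats::runif(cfg@nSegments, 0, cfg@ringSpacing))
  else rep_len(as.numeric(cfg@phase), cfg@nSegments)
}

.assembleSegments <- function(cfg, drawFun) {
  angles <- .segmentAngles(cfg)
  phases <- .segmentPhases(cfg)
  halfWidth <- max(6 * cfg@lateralSd, 50)
  rows <- vector("list", cfg@nSegments)
  rois <- vector("list", cfg@nSegments)
  for (i in seq_len(cfg@nSegments)) {
    org <- .segmentOrigin(i, cfg@segmentLength)
    th <- angles[i]
    u <- c(cos(th), sin(th))
    v <- c(-sin(th), cos(th))
    loc <- .withSubstream(cfg@seed, sprintf("segment:%d", i),
                          drawFun(cfg, phases[i]))
    if (nrow(loc)) {
      gx <- org[1] + loc[, "axial"] * u[1] + loc[, "lateral"] * v[1]
      gy <- org[2] + loc[, "axial"] * u[2] + loc[, "lateral"] * v[2]
      rows[[i]] <- data.frame(x = gx, y = gy,
                              channel = as.integer(loc[, "channel"]),
                              frame = seq_len(nrow(loc)) - 1L)
    }
    rois[[i]] <- SegmentROI(org, org + cfg@segmentLength * u, halfWidth,
                            sprintf("seg%02d", i))
  }
  tab <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(tab))
    tab <- data.frame(x = numeric(0), y = numeric(0),
                      channel = integer(0), frame = integer(0))
  rownames(tab) <- NULL
  list(locs = new("Localizations", data = tab), rois = rois, phases = phases)
}

#' Simulate localizations from a periodic membrane skeleton
#'
#' For each segment, ring centres are placed at \code{phase + k*d} for
#' \code{k = 0..floor(L/d)}; each ring emits Poisson(\code{locsPerRing})
#' localizations jittered axially by the ring s.d. and the localization
#' precision and laterally by \code{lateralSd}; an additional uniform
#' background makes up the configured fraction of each segment's
#' localizations. Segments are placed at their orientations in global nm
#' coordinates; each ROI records the true axis. Identical configs (same seed)
#' give identical output.
#'
#' @param config an \linkS4class{MPSSimConfig}.
#' @return List with \code{localizations} (\linkS4class{Localizations}),
#'   \code{rois} (list of \linkS4class{SegmentROI}) and \code{groundTruth}
#'   (list with \code{period}, per-segment \code{phases}, and
#'   \code{expectedCount}).
#' @examples
#' sim <- simulateMpsLocalizations(mpsSimConfig(nSegments = 3L, seed = 7L))
#' nLocalizations(sim$localizations)
#' @export
simulateMpsLocalizations <- function(config) {
  stopifnot(is(config, "MPSSimConfig"))
  validObject(config)
  res <- .assembleSegments(config, function(cfg, phase) {
    loc <- .drawSegmentChannel(cfg, phase, 0)
    cbind(loc, channel = rep(1, nrow(loc)))
  })
  nRings <- floor(config@segmentLength / config@ringSpacing) + 1
  expected <- config@nSegments * nRings * config@locsPerRing /
    (1 - config@backgroundFraction)
  list(localizations = res$locs, rois = res$rois,
       groundTruth = list(period = config@ringSpacing, phases = res$phases,
                          expectedCount = expected))
}

#' Simulate two-color localizations with a channel phase offset
#'
#' Channel 1 rings sit at \code{phase + k*d}; channel 2 rings at
#' \code{phase + (k + channelPhaseOffset)*d}. With the default half-period
#' offset the two channels form alternating (anti-phase) periodic patterns.
#' All noise terms are as in \code{\link{simulateMpsLocalizations}}.
#'
#' @param config an \linkS4class{MPSSimConfig} with \code{nChannels = 2}.
#' @return As \code{\link{simulateMpsLocalizations}}; the ground truth also
#'   records \code{channelOffsetNm}.
#' @export
simulateTwoColorLocalizations <- function(config) {
  stopifnot(is(config, "MPSSimConfig"))
  validObject(config)
  if (config@nChannels != 2L)
    .configError("nChannels", "must be 2 for two-color simulation")
  off <- config@channelPhaseOffset
  res <- .assembleSegments(config, function(cfg, phase) {
    l1 <- .drawSegmentChannel(cfg, phase, 0)
    l2 <- .drawSegmentChannel(cfg, phase, off)
    rbind(cbind(l1, channel = rep(1, nrow(l1))),
          cbind(l2, channel = rep(2, nrow(l2))))
  })
  list(localizations = res$locs, rois = res$rois,
       groundTruth = list(period = config@ringSpacing, phases = res$phases,
                          channelOffsetNm = off * config@ringSpacing))
}

#' Simulate a uniform (non-periodic) control
#'
#' Positions are uniform along each segment with the same expected count per
#' segment as the periodic case (rings plus background); no periodic
#' structure is present, so the averaged autocorrelation amplitude should be
#' near zero.
#'
#' @param config an \linkS4class{MPSSimConfig}.
#' @return List with \code{localizations} and \code{rois}.
#' @export
simulateUniformControl <- function(config) {
  stopifnot(is(config, "MPSSimConfig"))
  validObject(config)
  res <- .assembleSegments(config, function(cfg, phase) {
    nRings <- floor(cfg@segmentLength / cfg@ringSpacing) + 1
    n <- stats::rpois(1L, nRings * cfg@locsPerRing / (1 - cfg@backgroundFraction))
    cbind(axial = stats::runif(n, 0, cfg@segmentLength),
          lateral = stats::rnorm(n, 0, cfg@lateralSd),
          channel = rep(1, n))
  })
  list(localizations = res$locs, rois = res$rois)
}
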