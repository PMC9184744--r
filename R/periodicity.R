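## Periodicity statistics: projection, binned profiles, normalized auto- and
## cross-correlation, the amplitude/period statistic, phase estimation,
## phase-aligned averaging and condition comparison.

.EPS_VAR <- 1e-12

#' Project localizations onto a segment axis
#'
#' Returns the 1D axial positions (nm) of localizations along an axis. With an
#' explicit \linkS4class{SegmentROI} the axial local coordinate is used; with
#' \code{axis = "auto"} the axis is the principal eigenvector of the 2D
#' coordinate covariance through the centroid, with the sign chosen so the
#' positions span \code{[0, max)}.
#'
#' @param locs a \linkS4class{Localizations}.
#' @param axis a \linkS4class{SegmentROI} or \code{"auto"}.
#' @return Numeric vector of positions in nm.
#' @examples
#' projectToAxis(Localizations(x = c(0, 100, 200), y = c(0, 0, 0)), "auto")
#' @export
projectToAxis <- function(locs, axis = "auto") {
  stopifnot(is(locs, "Localizations"))
  d <- locs@data
  if (is(axis, "SegmentROI")) {
    v <- axis@b - axis@a
    u <- v / sqrt(sum(v^2))
    return((d$x - axis@a[1]) * u[1] + (d$y - axis@a[2]) * u[2])
  }
  if (!identical(axis, "auto"))
    stop("axis must be a SegmentROI or \"auto\"", call. = FALSE)
  if (nrow(d) < 2L)
    stop("analysis error: need >= 2 localizations for axis = \"auto\"", call. = FALSE)
  xy <- cbind(d$x, d$y)
  ctr <- colMeans(xy)
  cc <- sweep(xy, 2, ctr)
  S <- crossprod(cc) / nrow(cc)
  eg <- eigen(S, symmetric = TRUE)
  u <- eg$vectors[, 1]
  # deterministic sign: positive x component (positive y if vertical)
  if (u[1] < 0 || (u[1] == 0 && u[2] < 0)) u <- -u
  pos <- cc %*% u
  pos <- pos - min(pos)
  as.numeric(pos)
}

#' Bin 1D positions into a Profile1D
#'
#' Histogram with half-open bins \code{[origin + i*b, origin + (i+1)*b)}; a
#' position exactly on an interior edge falls in the upper bin. Positions
#' outside the range are dropped (their number is reported via a message).
#'
#' @param positions numeric positions in nm.
#' @param binSize bin width in nm (default 10).
#' @param range numeric(2), the binned interval \code{[range[1], range[2])}.
#' @param label segment label carried on the profile.
#' @return A \linkS4class{Profile1D}.
#' @examples
#' profileCounts(binProfile(c(5, 15), 10, c(0, 20)))
#' @export
binProfile <- function(positions, binSize = 10, range, label = "") {
  if (binSize <= 0) stop("binSize must be > 0", call. = FALSE)
  if (missing(range) || diff(range) <= 0 || any(!is.finite(range)))
    stop("empty or non-finite range", call. = FALSE)
  nb <- ceiling((range[2] - range[1]) / binSize - 1e-9)
  idx <- floor((positions - range[1]) / binSize)
  inside <- idx >= 0 & idx < nb
  dropped <- sum(!inside)
  if (dropped > 0)
    message(sprintf("binProfile: dropped %d position(s) outside range", dropped))
  counts <- tabulate(idx[inside] + 1L, nbins = nb)
  new("Profile1D", binSize = as.numeric(binSize), origin = as.numeric(range[1]),
      counts = as.numeric(counts), label = as.character(label))
}

# Overlap-normalized, mean-subtracted correlation between two equal-length
# numeric vectors at a single integer lag (l >= 0 pairs a_i with b_{i+l}).
.corAtLag <- function(a, b, am, bm, l) {
  n <- length(a)
  if (l >= 0) {
    i <- seq_len(n - l)
    mean((a[i] - am) * (b[i + l] - bm))
  } else {
    i <- seq.int(1 - l, n)
    mean((a[i] - am) * (b[i + l] - bm))
  }
}

#' 1D autocorrelation of a binned profile
#'
#' Computes the normalized autocorrelation
#' \deqn{g(l) = \frac{\sum_i (c_i - \bar c)(c_{i+l} - \bar c)/N_{overlap}(l)}{s^2}}
#' with the profile mean and (population) variance, using the no-wraparound
#' overlapping-region estimator, so that \eqn{g(0) = 1}. A zero-variance
#' profile yields a degenerate all-zero curve rather than an error.
#'
#' @param profile a \linkS4class{Profile1D}.
#' @param maxLag maximum lag in nm (default 600; use >= 285 nm for the
#'   amplitude statistic).
#' @return A \linkS4class{CorrelationCurve} with lags \code{0..maxLag}.
#' @export
autocorrelation <- function(profile, maxLag = 600) {
  stopifnot(is(profile, "Profile1D"))
  b <- profile@binSize
  c0 <- profile@counts
  n <- length(c0)
  if (n < 2L) stop("profile must have >= 2 bins", call. = FALSE)
  nl <- min(floor(maxLag / b), n - 1L)
  lags <- (0:nl) * b
  m <- mean(c0)
  v <- mean((c0 - m)^2)
  if (v < .EPS_VAR)
    return(new("CorrelationCurve", lags = lags, values = rep(0, nl + 1L),
               nAveraged = 1L, degenerate = TRUE, type = "acf"))
  vals <- vapply(0:nl, function(l) .corAtLag(c0, c0, m, m, l) / v, 0)
  new("CorrelationCurve", lags = lags, values = vals, nAveraged = 1L,
      degenerate = FALSE, type = "acf")
}

#' 1D cross-correlation between two binned profiles
#'
#' Symmetric-lag cross-correlation normalized by \eqn{\sqrt{s_a^2 s_b^2}}.
#' The sign convention pairs \code{a_i} with \code{b_{i+l}}: a positive-lag
#' extremum means features of profile b sit at larger coordinates than the
#' matching features of profile a. Restricted to lags >= 0,
#' \code{crossCorrelation(p, p)} equals \code{autocorrelation(p)}.
#'
#' @param profileA,profileB \linkS4class{Profile1D} objects sharing bin size,
#'   origin and length.
#' @param maxLag maximum |lag| in nm.
#' @return A \linkS4class{CorrelationCurve} with lags \code{-maxLag..maxLag}.
#' @export
crossCorrelation <- function(profileA, profileB, maxLag = 600) {
  stopifnot(is(profileA, "Profile1D"), is(profileB, "Profile1D"))
  if (abs(profileA@binSize - profileB@binSize) > 1e-9 ||
      abs(profileA@origin - profileB@origin) > 1e-9 ||
      length(profileA@counts) != length(profileB@counts))
    stop("profiles must share bin size, origin and length", call. = FALSE)
  b <- profileA@binSize
  a <- profileA@counts
  bb <- profileB@counts
  n <- length(a)
  nl <- min(floor(maxLag / b), n - 1L)
  lags <- (-nl:nl) * b
  am <- mean(a); bm <- mean(bb)
  va <- mean((a - am)^2); vb <- mean((bb - bm)^2)
  if (va < .EPS_VAR || vb < .EPS_VAR)
    return(new("CorrelationCurve", lags = lags, values = rep(0, 2L * nl + 1L),
               nAveraged = 1L, degenerate = TRUE, type = "ccf"))
  vals <- vapply(-nl:nl, function(l) .corAtLag(a, bb, am, bm, l) / sqrt(va * vb), 0)
  new("CorrelationCurve", lags = lags, values = vals, nAveraged = 1L,
      degenerate = FALSE, type = "ccf")
}

#' Average correlation curves over segments
#'
#' Unweighted per-lag mean over non-degenerate curves sharing a lag grid;
#' degenerate curves are excluded (their number is reported via a message).
#'
#' @param curves list of \linkS4class{CorrelationCurve}.
#' @return A \linkS4class{CorrelationCurve} with
#'   \code{nAveraged} = number of curves included.
#' @export
averageCurves <- function(curves) {
  stopifnot(length(curves) >= 1L)
  deg <- vapply(curves, function(x) x@degenerate, TRUE)
  if (any(deg))
    message(sprintf("averageCurves: excluded %d degenerate curve(s)", sum(deg)))
  curves <- curves[!deg]
  if (!length(curves))
    stop("no non-degenerate curves to average", call. = FALSE)
  lag0 <- curves[[1]]@lags
  for (cv in curves)
    if (length(cv@lags) != length(lag0) || max(abs(cv@lags - lag0)) > 1e-6)
      stop("curves must share a common lag grid", call. = FALSE)
  vals <- rowMeans(vapply(curves, function(x) x@values, numeric(length(lag0))))
  new("CorrelationCurve", lags = lag0, values = vals,
      nAveraged = length(curves), degenerate = FALSE,
      type = curves[[1]]@type)
}

#' Locate an extremum of a correlation curve inside a lag window
#'
#' @param curve a \linkS4class{CorrelationCurve}.
#' @param window numeric(2) lag window in nm (inclusive).
#' @param what "max" or "min".
#' @return List with \code{lag} and \code{value}; ties break toward the
#'   smaller lag.
#' @export
curveExtremum <- function(curve, window, what = c("max", "min")) {
  what <- match.arg(what)
  idx <- which(curve@lags >= window[1] & curve@lags <= window[2])
  if (!length(idx))
    stop("curve does not cover the requested window", call. = FALSE)
  v <- curve@values[idx]
  j <- if (what == "max") which.max(v) else which.min(v)
  list(lag = curve@lags[idx][j], value = v[j])
}

#' Amplitude and period of an averaged autocorrelation curve
#'
#' The periodicity statistic: the peak is the maximum of the curve in the
#' peak window (default 140-240 nm, around the ~190-nm period), the valleys
#' are the minima in the two valley windows (defaults 50-140 and 240-330 nm,
#' around ~95 and ~285 nm), the amplitude is the peak value minus the mean of
#' the two valley values, and the period is the first-peak lag.
#'
#' @param curve a \linkS4class{CorrelationCurve} covering the valley windows.
#' @param peakWindow numeric(2) peak search window in nm.
#' @param valleyWindows list of two numeric(2) valley windows in nm.
#' @return A \linkS4class{PeriodicityResult}. For a degenerate curve the
#'   amplitude is 0 and the period NA.
#' @export
periodicityMetrics <- function(curve, peakWindow = c(140, 240),
                               valleyWindows = list(c(50, 140), c(240, 330))) {
  stopifnot(is(curve, "CorrelationCurve"))
  if (max(curve@lags) < max(valleyWindows[[2]], peakWindow))
    stop("curve shorter than the search windows", call. = FALSE)
  if (curve@degenerate)
    return(new("PeriodicityResult", amplitude = 0, period = NA_real_,
               peakLag = NA_real_, valleyLags = c(NA_real_, NA_real_),
               peakWindow = peakWindow, valleyWindows = valleyWindows,
               degenerate = TRUE))
  pk <- curveExtremum(curve, peakWindow, "max")
  v1 <- curveExtremum(curve, valleyWindows[[1]], "min")
  v2 <- curveExtremum(curve, valleyWindows[[2]], "min")
  new("PeriodicityResult",
      amplitude = pk$value - mean(c(v1$value, v2$value)),
      period = pk$lag, peakLag = pk$lag, valleyLags = c(v1$lag, v2$lag),
      peakWindow = as.numeric(peakWindow),
      valleyWindows = valleyWindows, degenerate = FALSE)
}

#' First-harmonic phase of a periodic profile
#'
#' Projects the mean-subtracted profile onto the first harmonic at a fixed
#' period: \eqn{z = \sum_i (c_i - \bar c) e^{-i 2\pi x_i / T}} over bin
#' centres \eqn{x_i}; the reported phase is the peak-position angle
#' \eqn{-\arg z} mapped to \eqn{[0, 2\pi)} (a profile peaked at \eqn{x_0} has
#' phase \eqn{2\pi x_0 / T}; a peak at 0 gives phase 0) and the strength is
#' \eqn{|z| / \sum_i |c_i - \bar c|}.
#'
#' @param profile a \linkS4class{Profile1D} spanning at least two periods.
#' @param period period T in nm (> 0).
#' @return A \linkS4class{PhaseEstimate}. Zero-variance profiles return
#'   strength 0 and phase 0 by convention.
#' @export
estimatePhase <- function(profile, period) {
  stopifnot(is(profile, "Profile1D"), period > 0)
  if (length(profile@counts) * profile@binSize < 2 * period)
    stop("profile must span >= 2 periods", call. = FALSE)
  cts <- profile@counts
  m <- mean(cts)
  dev <- cts - m
  if (mean(dev^2) < .EPS_VAR)
    return(new("PhaseEstimate", phase = 0, period = as.numeric(period), strength = 0))
  x <- binCenters(profile)
  z <- sum(dev * exp(-1i * 2 * pi * x / period))
  # report the peak-position angle: a profile peaked at x0 has phase
  # 2*pi*x0/period, so aligning by -phase*period/(2*pi) moves the peak to 0
  ph <- (-Arg(z)) %% (2 * pi)
  new("PhaseEstimate", phase = ph, period = as.numeric(period),
      strength = Mod(z) / sum(abs(dev)))
}

# Circular shift of a numeric vector by a (possibly fractional) number of
# bins with linear interpolation; positive shift moves content toward
# smaller indices (new[j] = old[j + s]).
.circShift <- function(v, shiftBins) {
  n <- length(v)
  k <- floor(shiftBins)
  w <- shiftBins - k
  idx1 <- ((seq_len(n) - 1 + k) %% n) + 1
  idx2 <- ((seq_len(n) + k) %% n) + 1
  (1 - w) * v[idx1] + w * v[idx2]
}

#' Phase-align paired profiles and average them
#'
#' For each (reference, partner) pair, both profiles are circularly shifted
#' (with linear interpolation, modulo the period) by minus the reference
#' phase, so that every reference peak moves to position 0; the shifted
#' profiles are then averaged per channel. The output spans an integer number
#' of periods. This reproduces the aligned average 1D distributions used to
#' read off whether a partner channel sits on the reference stripes or midway
#' between them.
#'
#' @param referenceProfiles,partnerProfiles equal-length lists of
#'   \linkS4class{Profile1D} with a common bin size.
#' @param period period in nm.
#' @return List with elements \code{reference} and \code{partner}, each an
#'   averaged \linkS4class{Profile1D} spanning an integer number of periods.
#' @export
alignAndAverage <- function(referenceProfiles, partnerProfiles, period) {
  if (length(referenceProfiles) != length(partnerProfiles))
    stop("reference and partner profile lists must have equal length", call. = FALSE)
  if (!length(referenceProfiles)) stop("empty profile lists", call. = FALSE)
  b <- referenceProfiles[[1]]@binSize
  for (p in c(referenceProfiles, partnerProfiles))
    if (abs(p@binSize - b) > 1e-9)
      stop("profiles must share a common bin size", call. = FALSE)
  nbinsMin <- min(vapply(c(referenceProfiles, partnerProfiles),
                         function(p) length(p@counts), 1L))
  nper <- floor(nbinsMin * b / period)
  if (nper < 1L) stop("profiles must span at least one period", call. = FALSE)
  nbins <- floor(nper * period / b)
  refM <- matrix(0, nbins, length(referenceProfiles))
  parM <- matrix(0, nbins, length(referenceProfiles))
  for (i in seq_along(referenceProfiles)) {
    ref <- referenceProfiles[[i]]@counts[seq_len(nbins)]
    par <- partnerProfiles[[i]]@counts[seq_len(nbins)]
    ph <- estimatePhase(referenceProfiles[[i]], period)
    # reference peak sits at x = phase*T/2pi; shift content by +that many bins
    sBins <- (ph@phase * period / (2 * pi)) / b
    refM[, i] <- .circShift(ref, sBins)
    parM[, i] <- .circShift(par, sBins)
  }
  mk <- function(counts) new("Profile1D", binSize = b, origin = 0,
                             counts = rowMeans(counts), label = "aligned average")
  list(reference = mk(refM), partner = mk(parM))
}

#' Compare replicate-level amplitudes between two conditions
#'
#' Classical two-sample pooled-variance Student's t-test, two-sided, with
#' group means and standard errors of the mean, as used to compare
#' periodicity amplitudes across biological replicates. When both groups have
#' (numerically) zero variance, the statistic is 0 / p = 1 for equal means
#' and +/-Inf / p = 0 for different means instead of failing.
#'
#' @param amplitudesA,amplitudesB numeric vectors of per-replicate values
#'   (each of length >= 2).
#' @return A \linkS4class{TestResult}.
#' @examples
#' compareConditions(c(0.8, 0.9, 1.0), c(0.3, 0.4, 0.35))
#' @export
compareConditions <- function(amplitudesA, amplitudesB) {
  a <- as.numeric(amplitudesA); b <- as.numeric(amplitudesB)
  if (length(a) < 2L || length(b) < 2L)
    stop("need >= 2 values per group", call. = FALSE)
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / (n1 + n2 - 2)
  if (sp2 < .EPS_VAR) {
    dm <- mean(a) - mean(b)
    tstat <- if (abs(dm) < .EPS_VAR) 0 else sign(dm) * Inf
    p <- if (tstat == 0) 1 else 0
  } else {
    ht <- stats::t.test(a, b, var.equal = TRUE)
    tstat <- unname(ht$statistic)
    p <- ht$p.value
  }
  new("TestResult", means = c(mean(a), mean(b)),
      sems = c(stats::sd(a) / sqrt(n1), stats::sd(b) / sqrt(n2)),
      statistic = tstat, pValue = p, n = c(n1, n2))
}

## ---- convenience wrappers ---------------------------------------------------

# Per-segment binned profile for one channel, in the segment-local frame.
.segmentProfile <- function(locs, roi, binSize, channel = NULL) {
  seg <- extractSegment(locs, roi)
  d <- locData(seg)
  if (!is.null(channel)) d <- d[d$channel == channel, , drop = FALSE]
  suppressMessages(
    binProfile(d$x, binSize, c(0, segmentLength(roi)), label = roi@label))
}

#' Averaged autocorrelation and periodicity metrics for a set of segments
#'
#' Extracts each segment, bins the axial positions, computes per-segment
#' autocorrelations, averages them, and reports the amplitude/period
#' statistic of the averaged curve.
#'
#' @param locs a \linkS4class{Localizations} in global coordinates.
#' @param rois list of \linkS4class{SegmentROI}.
#' @param binSize bin width in nm (default 10).
#' @param maxLag maximum lag in nm (default 600).
#' @param channel restrict to one channel (default: all localizations).
#' @return List with \code{curve} (averaged \linkS4class{CorrelationCurve}),
#'   \code{metrics} (\linkS4class{PeriodicityResult}) and \code{profiles}.
#' @export
mpsPeriodicity <- function(locs, rois, binSize = 10, maxLag = 600, channel = NULL) {
  profiles <- lapply(rois, function(r) .segmentProfile(locs, r, binSize, channel))
  curves <- lapply(profiles, autocorrelation, maxLag = maxLag)
  avg <- averageCurves(curves)
  list(curve = avg, metrics = periodicityMetrics(avg), profiles = profiles)
}

#' Averaged two-channel cross-correlation for a set of segments
#'
#' Per segment, bins each channel's axial positions and cross-correlates
#' them (channel a vs channel b), then averages the per-segment curves.
#'
#' @param locs a two-channel \linkS4class{Localizations}.
#' @param rois list of \linkS4class{SegmentROI}.
#' @param channels integer(2): reference and partner channel.
#' @param binSize bin width in nm (default 10).
#' @param maxLag maximum |lag| in nm (default 600).
#' @return List with \code{curve} (averaged symmetric-lag
#'   \linkS4class{CorrelationCurve}) and the per-channel profile lists.
#' @export
mpsCrossCorrelation <- function(locs, rois, channels = c(1L, 2L),
                                binSize = 10, maxLag = 600) {
  profA <- lapply(rois, function(r) .segmentProfile(locs, r, binSize, channels[1]))
  profB <- lapply(rois, function(r) .segmentProfile(locs, r, binSize, channels[2]))
  curves <- mapply(crossCorrelation, profA, profB,
                   MoreArgs = list(maxLag = maxLag), SIMPLIFY = FALSE)
  list(curve = averageCurves(curves), reference = profA, partner = profB)
}
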