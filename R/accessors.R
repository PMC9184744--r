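## Accessor and show methods.

#' @rdname accessors
#' @export
setMethod("locData", "Localizations", function(x) x@data)

#' @rdname accessors
#' @export
setMethod("nLocalizations", "Localizations", function(x) nrow(x@data))

#' @rdname accessors
#' @export
setMethod("segmentLength", "SegmentROI", function(x) sqrt(sum((x@b - x@a)^2)))

#' @rdname accessors
#' @export
setMethod("binCenters", "Profile1D", function(x)
  x@origin + (seq_along(x@counts) - 0.5) * x@binSize)

#' @rdname accessors
#' @export
setMethod("profileCounts", "Profile1D", function(x) x@counts)

#' @rdname accessors
#' @export
setMethod("corLags", "CorrelationCurve", function(x) x@lags)

#' @rdname accessors
#' @export
setMethod("corValues", "CorrelationCurve", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("isDegenerate", "CorrelationCurve", function(x) x@degenerate)

#' @rdname accessors
#' @export
setMethod("corAmplitude", "PeriodicityResult", function(x) x@amplitude)

#' @rdname accessors
#' @export
setMethod("corPeriod", "PeriodicityResult", function(x) x@period)

#' @rdname accessors
#' @export
setMethod("phaseRadians", "PhaseEstimate", function(x) x@phase)

#' @rdname accessors
#' @export
setMethod("phaseStrength", "PhaseEstimate", function(x) x@strength)

#' @rdname accessors
#' @export
setMethod("candidateIds", "CandidateList", function(x) x@ids)

#' @rdname accessors
#' @export
setMethod("dnsafValues", "DNSAFTable", function(x)
  stats::setNames(x@table$dNSAF, x@table$protein_id))

#' @rdname accessors
#' @export
setMethod("maskMatrix", "MaskImage", function(x) x@mask)

#' @rdname accessors
#' @export
setMethod("pixelSize", "MaskImage", function(x) x@pixelSize)

#' @rdname accessors
#' @export
setMethod("punctaCoords", "PunctaSet", function(x) x@coords)

#' @rdname accessors
#' @export
setMethod("meanWidth", "BundleWidthResult", function(x) x@meanWidth)

setMethod("show", "Localizations", function(object) {
  d <- object@data
  cat(sprintf("Localizations: %d localization(s), %d channel(s)%s\n",
              nrow(d), length(unique(d$channel)),
              if ("z" %in% names(d)) ", 3D" else ""))
  if (nrow(d)) {
    cat(sprintf("  x: [%.1f, %.1f] nm; y: [%.1f, %.1f] nm\n",
                min(d$x), max(d$x), min(d$y), max(d$y)))
  }
})

setMethod("show", "SegmentROI", function(object) {
  cat(sprintf("SegmentROI '%s': (%.1f, %.1f) -> (%.1f, %.1f) nm, length %.1f nm, half-width %.1f nm\n",
              object@label, object@a[1], object@a[2], object@b[1], object@b[2],
              segmentLength(object), object@halfWidth))
})

setMethod("show", "Profile1D", function(object) {
  cat(sprintf("Profile1D '%s': %d bins of %.1f nm from %.1f nm (total count %.0f)\n",
              object@label, length(object@counts), object@binSize,
              object@origin, sum(object@counts)))
})

setMethod("show", "CorrelationCurve", function(object) {
  cat(sprintf("CorrelationCurve (%s): lags %.0f..%.0f nm, %d curve(s) averaged%s\n",
              object@type, min(object@lags), max(object@lags), object@nAveraged,
              if (object@degenerate) " [degenerate]" else ""))
})

setMethod("show", "PeriodicityResult", function(object) {
  if (object@degenerate) {
    cat("PeriodicityResult: degenerate curve (amplitude 0, period undefined)\n")
  } else {
    cat(sprintf("PeriodicityResult: amplitude %.3f, period %.0f nm (peak %.0f nm; valleys %.0f, %.0f nm)\n",
                object@amplitude, object@period, object@peakLag,
                object@valleyLags[1], object@valleyLags[2]))
  }
})

setMethod("show", "PhaseEstimate", function(object) {
  cat(sprintf("PhaseEstimate: %.3f rad (%.1f deg) at period %.0f nm, strength %.3f\n",
              object@phase, object@phase * 180 / pi, object@period, object@strength))
})

setMethod("show", "TestResult", function(object) {
  cat(sprintf("Two-sided unpaired t-test: t = %.4g, p = %.4g\n",
              object@statistic, object@pValue))
  cat(sprintf("  group 1: mean %.4g +/- %.4g s.e.m. (n = %d)\n",
              object@means[1], object@sems[1], object@n[1]))
  cat(sprintf("  group 2: mean %.4g +/- %.4g s.e.m. (n = %d)\n",
              object@means[2], object@sems[2], object@n[2]))
})

setMethod("show", "SpectralCounts", function(object) {
  cat(sprintf("SpectralCounts: %d protein(s), samples: %s; %d shared-peptide record(s)\n",
              nrow(object@proteins),
              paste(unique(object@uniqueCounts$sample), collapse = ", "),
              nrow(object@sharedCounts)))
})

setMethod("show", "DNSAFTable", function(object) {
  cat(sprintf("DNSAFTable for sample '%s': %d protein(s), sum(dNSAF) = %.6f\n",
              object@sample, nrow(object@table), sum(object@table$dNSAF)))
})

setMethod("show", "CandidateList", function(object) {
  cat(sprintf("CandidateList: %d candidate(s)\n", length(object@ids)))
  if (length(object@ids))
    cat("  ", paste(utils::head(object@ids, 10), collapse = ", "),
        if (length(object@ids) > 10) "..." else "", "\n")
})

setMethod("show", "MaskImage", function(object) {
  cat(sprintf("MaskImage: %d x %d px at %.1f nm/px, %d foreground px (%.1f%%)\n",
              nrow(object@mask), ncol(object@mask), object@pixelSize,
              sum(object@mask), 100 * mean(object@mask)))
})

setMethod("show", "PunctaSet", function(object) {
  cat(sprintf("PunctaSet ('%s'): %d puncta\n", object@channel, nrow(object@coords)))
})

setMethod("show", "BundleWidthResult", function(object) {
  cat(sprintf("BundleWidthResult: mean width %.1f nm over %.1f nm of skeleton\n",
              object@meanWidth, object@skeletonLength))
})
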