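# Projection, binning, correlation statistics, phase, alignment and the
# replicate comparison.

test_that("projection recovers axial positions and is rotation invariant", {
  locs <- Localizations(x = c(0, 100, 200), y = c(0, 0, 0))
  expect_equal(projectToAxis(locs, "auto"), c(0, 100, 200))
  th <- 45 * pi / 180
  locsR <- Localizations(x = c(0, 100, 200) * cos(th),
                         y = c(0, 100, 200) * sin(th))
  expect_equal(projectToAxis(locsR, "auto"), c(0, 100, 200), tolerance = 1e-6)
  expect_error(projectToAxis(Localizations(1, 1), "auto"), "analysis error")
})

test_that("auto axis equals the closed-form principal eigenvector", {
  # anisotropic 10-point toy cloud
  px <- c(0, 1, 2, 3.5, 5, 6, 7.2, 8, 9, 10) * 100
  py <- c(5, 12, 18, 40, 52, 55, 70, 83, 88, 104)
  locs <- Localizations(px, py)
  pos <- projectToAxis(locs, "auto")
  # independent 2x2 eigen-solution: angle = atan2(2b, a - c) / 2
  cx <- px - mean(px); cy <- py - mean(py)
  a <- mean(cx^2); b <- mean(cx * cy); c2 <- mean(cy^2)
  ang <- atan2(2 * b, a - c2) / 2
  ref <- cx * cos(ang) + cy * sin(ang)
  ref <- ref - min(ref)
  if (abs(ref[1] - pos[1]) > 1e-6) ref <- max(ref) - ref   # sign convention
  expect_equal(pos, ref, tolerance = 1e-6)
})

test_that("binning follows the half-open upper-bin convention", {
  p <- binProfile(c(5, 15), 10, c(0, 20))
  expect_equal(profileCounts(p), c(1, 1))
  # a position exactly on an interior edge falls in the upper bin
  p2 <- binProfile(c(10), 10, c(0, 30))
  expect_equal(profileCounts(p2), c(0, 1, 0))
  expect_error(binProfile(1:3, 10, c(5, 5)), "range")
  expect_message(binProfile(c(5, 25), 10, c(0, 20)), "dropped 1")
})

test_that("binned uniform draws pass a chi-square uniformity check", {
  set.seed(17)
  pos <- runif(1000, 0, 500)
  cts <- profileCounts(binProfile(pos, 10, c(0, 500)))
  e <- 1000 / length(cts)
  x2 <- sum((cts - e)^2 / e)
  p <- pchisq(x2, df = length(cts) - 1, lower.tail = FALSE)
  expect_gt(p, 0.01)
})

test_that("autocorrelation matches the brute-force oracle and normalizes g(0)=1", {
  p <- new("Profile1D", binSize = 1, origin = 0, counts = c(1, 2, 3, 4), label = "")
  g <- autocorrelation(p, maxLag = 2)
  expect_equal(corValues(g), c(1, 1 / 3, -0.6), tolerance = 1e-12)
  expect_equal(corValues(g), oracleAcf(c(1, 2, 3, 4), 2), tolerance = 1e-12)
  # random profiles of length <= 50
  set.seed(3)
  for (n in c(10, 27, 50)) {
    cts <- rpois(n, 5)
    prof <- new("Profile1D", binSize = 10, origin = 0,
                counts = as.numeric(cts), label = "")
    g <- autocorrelation(prof, maxLag = (n - 1) * 10)
    expect_lt(max(abs(corValues(g) - oracleAcf(cts, n - 1))), 1e-10)
    expect_equal(corValues(g)[1], 1)
  }
})

test_that("cosine profiles have cosine autocorrelation", {
  prof <- cosineProfile(period = 190, binSize = 10, lengthNm = 2000)
  g <- autocorrelation(prof, 600)
  v <- corValues(g); l <- corLags(g)
  expect_lt(abs(v[l == 190] - 1), 0.05)
  expect_lt(abs(v[l == 100] + 1), 0.12)  # nearest bin to the 95-nm valley
})

test_that("degenerate profiles give flagged all-zero curves, not errors", {
  flat <- new("Profile1D", binSize = 10, origin = 0, counts = rep(3, 60), label = "")
  g <- autocorrelation(flat, 300)
  expect_true(isDegenerate(g))
  expect_true(all(corValues(g) == 0))
  g2 <- crossCorrelation(flat, cosineProfile(lengthNm = 600), 200)
  expect_true(isDegenerate(g2))
})

test_that("cross-correlation obeys the shift theorem, symmetry and the oracle", {
  # periodic profile circularly shifted by +3 bins
  n <- 60
  a <- 2 + cos(2 * pi * (0:(n - 1)) / 12)
  b <- a[((0:(n - 1) - 3) %% n) + 1]   # b_i = a_{i-3}: features moved to larger x
  pa <- new("Profile1D", binSize = 10, origin = 0, counts = a, label = "")
  pb <- new("Profile1D", binSize = 10, origin = 0, counts = b, label = "")
  cc <- crossCorrelation(pa, pb, 200)
  # nearest extremum to zero lag sits at +3 bins (one period is 120 nm)
  pk <- curveExtremum(cc, c(-55, 55), "max")
  expect_equal(pk$lag, 30)
  # identical profiles peak at 0 with value 1
  cc0 <- crossCorrelation(pa, pa, 200)
  expect_equal(curveExtremum(cc0, c(-55, 55), "max")$lag, 0)
  expect_equal(corValues(cc0)[corLags(cc0) == 0], 1, tolerance = 1e-12)
  # ccf(a, b)(l) = ccf(b, a)(-l)
  ccr <- crossCorrelation(pb, pa, 200)
  expect_equal(corValues(cc), rev(corValues(ccr)), tolerance = 1e-12)
  # positive lags of ccf(p, p) equal the autocorrelation
  acf0 <- autocorrelation(pa, 200)
  expect_equal(corValues(cc0)[corLags(cc0) >= 0], corValues(acf0),
               tolerance = 1e-12)
  # brute-force oracle on small random profiles
  set.seed(8)
  x <- rpois(40, 6); y <- rpois(40, 6)
  cx <- crossCorrelation(new("Profile1D", binSize = 5, origin = 0,
                             counts = as.numeric(x), label = ""),
                         new("Profile1D", binSize = 5, origin = 0,
                             counts = as.numeric(y), label = ""), 100)
  expect_lt(max(abs(corValues(cx) - oracleCcf(x, y, 20))), 1e-10)
  # mismatched binning is rejected
  expect_error(crossCorrelation(pa, new("Profile1D", binSize = 5, origin = 0,
                                        counts = a, label = "")), "share")
})

test_that("anti-phase cosines cross-correlate to -1 at zero lag with a ~95 nm maximum", {
  pa <- cosineProfile(period = 190, phaseNm = 0)
  pb <- cosineProfile(period = 190, phaseNm = 95)
  cc <- crossCorrelation(pa, pb, 300)
  v0 <- corValues(cc)[corLags(cc) == 0]
  expect_lt(abs(v0 + 1), 0.05)
  pk <- curveExtremum(cc, c(10, 190), "max")
  expect_lte(abs(pk$lag - 95), 10)
})

test_that("curve averaging is the per-lag mean with degenerate exclusion", {
  p <- cosineProfile()
  g <- autocorrelation(p, 400)
  expect_equal(corValues(averageCurves(list(g, g, g))), corValues(g))
  gneg <- new("CorrelationCurve", lags = corLags(g), values = -corValues(g),
              nAveraged = 1L, degenerate = FALSE, type = "acf")
  expect_true(all(abs(corValues(averageCurves(list(g, gneg)))) < 1e-12))
  flat <- autocorrelation(new("Profile1D", binSize = 10, origin = 0,
                              counts = rep(1, 200), label = ""), 400)
  expect_message(avg <- averageCurves(list(g, flat)), "degenerate")
  expect_identical(avg@nAveraged, 1L)
  expect_error(suppressMessages(averageCurves(list(flat))), "non-degenerate")
})

test_that("periodicity metrics implement the peak-minus-valleys definition", {
  # hand-built curve: 0.2 at 180 nm, -0.3 at 90, -0.1 at 280, 0 elsewhere
  lags <- seq(0, 400, 10)
  vals <- rep(0, length(lags))
  vals[lags == 180] <- 0.2
  vals[lags == 90] <- -0.3
  vals[lags == 280] <- -0.1
  curve <- new("CorrelationCurve", lags = lags, values = vals,
               nAveraged = 1L, degenerate = FALSE, type = "acf")
  m <- periodicityMetrics(curve)
  expect_equal(corAmplitude(m), 0.4)
  expect_equal(corPeriod(m), 180)
  expect_equal(m@valleyLags, c(90, 280))
  # sampled cosine: period 190 within a bin, amplitude ~ 2
  g <- autocorrelation(cosineProfile(), 600)
  mc <- periodicityMetrics(g)
  expect_lte(abs(corPeriod(mc) - 190), 10)
  expect_lt(abs(corAmplitude(mc) - 2), 0.2)
  # degenerate curve: amplitude 0, period undefined
  dg <- new("CorrelationCurve", lags = lags, values = 0 * lags,
            nAveraged = 1L, degenerate = TRUE, type = "acf")
  md <- periodicityMetrics(dg)
  expect_equal(corAmplitude(md), 0)
  expect_true(is.na(corPeriod(md)))
  expect_error(periodicityMetrics(autocorrelation(cosineProfile(), 200)),
               "windows")
})

test_that("phase estimation matches known cosine phases and generator truth", {
  p0 <- cosineProfile(phaseNm = 0, lengthNm = 1900)    # integer periods
  expect_lt(circDist(phaseRadians(estimatePhase(p0, 190)), 0), 1e-6)
  p5 <- cosineProfile(phaseNm = 95, lengthNm = 1900)
  expect_lt(circDist(phaseRadians(estimatePhase(p5, 190)), pi), 1e-6)
  expect_lt(circDist(phaseRadians(estimatePhase(cosineProfile(phaseNm = 60, lengthNm = 1900), 190)),
                     2 * pi * 60 / 190), 1e-6)
  flat <- new("Profile1D", binSize = 10, origin = 0, counts = rep(2, 60), label = "")
  pe <- estimatePhase(flat, 190)
  expect_equal(phaseStrength(pe), 0)
  expect_equal(phaseRadians(pe), 0)
  # noisy synthetic segments with generator-known phases
  for (phi in c(0, 60, 150)) {
    cfg <- mpsSimConfig(nSegments = 1L, phase = phi, orientation = 0, seed = 21L)
    sim <- simulateMpsLocalizations(cfg)
    seg <- extractSegment(sim$localizations, sim$rois[[1]])
    prof <- suppressMessages(binProfile(locData(seg)$x, 10, c(0, 2000)))
    est <- estimatePhase(prof, 190)
    expect_lt(circDist(phaseRadians(est), 2 * pi * phi / 190),
              2 * pi * 10 / 190)
  }
})

test_that("phase alignment restores the average that random phases wash out", {
  set.seed(12)
  phases <- runif(40, 0, 190)
  refs <- lapply(phases, function(ph) cosineProfile(phaseNm = ph, lengthNm = 1900))
  # unaligned average is nearly flat
  plain <- rowMeans(vapply(refs, profileCounts,
                           numeric(length(profileCounts(refs[[1]])))))
  expect_lt(max(plain) - min(plain), 0.5)
  out <- alignAndAverage(refs, refs, 190)
  aligned <- profileCounts(out$reference)
  expect_gt(max(aligned) - min(aligned), 1.8)  # single-profile peak-to-trough is 2
  # all-zero phases: output equals the plain average over the same span
  refs0 <- lapply(1:5, function(i) cosineProfile(phaseNm = 0, lengthNm = 1900))
  out0 <- alignAndAverage(refs0, refs0, 190)
  nb <- length(profileCounts(out0$reference))
  expect_equal(profileCounts(out0$reference),
               profileCounts(refs0[[1]])[seq_len(nb)], tolerance = 1e-9)
  expect_error(alignAndAverage(refs, refs[-1], 190), "equal length")
})

test_that("partners offset by half a period average midway between reference peaks", {
  set.seed(23)
  phases <- runif(25, 0, 190)
  refs <- lapply(phases, function(ph) cosineProfile(phaseNm = ph, lengthNm = 1900))
  partners <- lapply(phases, function(ph) cosineProfile(phaseNm = ph + 95, lengthNm = 1900))
  out <- alignAndAverage(refs, partners, 190)
  xr <- binCenters(out$reference)
  refPeak <- xr[which.max(profileCounts(out$reference))]
  parPeak <- xr[which.max(profileCounts(out$partner))]
  delta <- (parPeak - refPeak) %% 190
  expect_lte(min(abs(delta - 95), abs(delta - 95 - 190)), 15)
})

test_that("condition comparison equals the pooled-variance textbook formula", {
  r <- compareConditions(c(1, 2, 3), c(2, 3, 4))
  o <- oracleTTest(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r@statistic, o$t, tolerance = 1e-12)
  expect_equal(r@pValue, o$p, tolerance = 1e-12)
  expect_equal(r@sems, c(sd(1:3) / sqrt(3), sd(2:4) / sqrt(3)))
  # identical groups: t = 0, p = 1
  same <- compareConditions(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same@statistic, 0)
  expect_equal(same@pValue, 1)
  # zero variance in both groups with different means: defined limit, no crash
  degen <- compareConditions(c(2, 2), c(5, 5))
  expect_equal(degen@pValue, 0)
  expect_true(is.infinite(degen@statistic))
  expect_error(compareConditions(1, c(1, 2)), ">= 2")
})
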