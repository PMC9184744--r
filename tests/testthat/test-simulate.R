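# Synthetic-data generators: determinism, construction guarantees and
# analytic count expectations.

test_that("noise-free simulation places every localization on the ring lattice", {
  cfg <- mpsSimConfig(nSegments = 3L, backgroundFraction = 0, ringSd = 0,
                      locPrecision = 0, lateralSd = 0, phase = 0, seed = 5L)
  sim <- simulateMpsLocalizations(cfg)
  for (roi in sim$rois) {
    seg <- extractSegment(sim$localizations, roi)
    pos <- locData(seg)$x
    expect_gt(length(pos), 0)
    expect_true(all(abs(pos / 190 - round(pos / 190)) < 1e-6))
    # spacing histogram of sorted distinct positions has the single value d
    spacing <- diff(sort(unique(round(pos, 6))))
    expect_true(all(abs(spacing - 190) < 1e-6))
  }
})

test_that("simulation is deterministic in the seed and count-conserving", {
  cfg <- mpsSimConfig(nSegments = 5L, seed = 7L)
  s1 <- simulateMpsLocalizations(cfg)
  s2 <- simulateMpsLocalizations(cfg)
  expect_identical(locData(s1$localizations), locData(s2$localizations))
  expect_identical(s1$groundTruth$phases, s2$groundTruth$phases)
  s3 <- simulateMpsLocalizations(mpsSimConfig(nSegments = 5L, seed = 8L))
  expect_false(identical(locData(s1$localizations), locData(s3$localizations)))
  # uniform control and two-color generators are deterministic too
  c1 <- simulateUniformControl(cfg)
  c2 <- simulateUniformControl(cfg)
  expect_identical(locData(c1$localizations), locData(c2$localizations))
})

test_that("total localization count matches the analytic expectation", {
  cfg <- mpsSimConfig(nSegments = 50L, segmentLength = 2000, ringSpacing = 190,
                      locsPerRing = 30, backgroundFraction = 0.2, seed = 1L)
  sim <- simulateMpsLocalizations(cfg)
  expected <- 50 * (floor(2000 / 190) + 1) * 30 / (1 - 0.2)
  expect_equal(sim$groundTruth$expectedCount, expected)
  expect_lt(abs(nLocalizations(sim$localizations) - expected),
            3 * sqrt(expected))
})

test_that("two-color construction honours the channel phase offset", {
  base <- list(nSegments = 2L, backgroundFraction = 0, ringSd = 0,
               locPrecision = 0, lateralSd = 0, phase = 0, nChannels = 2L,
               seed = 3L)
  # zero offset: identical position multisets
  sim0 <- simulateTwoColorLocalizations(
    do.call(mpsSimConfig, c(base, channelPhaseOffset = 0)))
  d0 <- locData(extractSegment(sim0$localizations, sim0$rois[[1]]))
  expect_equal(sort(unique(round(d0$x[d0$channel == 1], 6))),
               sort(unique(round(d0$x[d0$channel == 2], 6))))
  # half-period offset: channel 2 = channel 1 + d/2
  sim5 <- simulateTwoColorLocalizations(
    do.call(mpsSimConfig, c(base, channelPhaseOffset = 0.5)))
  d5 <- locData(extractSegment(sim5$localizations, sim5$rois[[1]]))
  p1 <- sort(unique(round(d5$x[d5$channel == 1], 6)))
  p2 <- sort(unique(round(d5$x[d5$channel == 2], 6)))
  expect_equal(p2, p1 + 95)
  expect_equal(sim5$groundTruth$channelOffsetNm, 95)
  # single-channel config is rejected
  expect_error(simulateTwoColorLocalizations(mpsSimConfig(nChannels = 1L)),
               "nChannels")
})

test_that("invalid simulation configs raise errors naming the field", {
  expect_error(mpsSimConfig(segmentLength = 0), "segmentLength")
  expect_error(mpsSimConfig(backgroundFraction = 1), "backgroundFraction")
  expect_error(mpsSimConfig(locsPerRing = 0), "locsPerRing")
  expect_error(coipSimConfig(baitEnrichment = 1), "baitEnrichment")
  expect_error(coipSimConfig(nProteins = 5L, nTrueInteractors = 6L),
               "nTrueInteractors")
  expect_error(neuriteSceneConfig(axonWidth = 0), "axonWidth")
  expect_error(neuriteSceneConfig(imageShape = c(64L, 64L), pixelSize = 100,
                                  dendriteWidth = 1e6), "Width")
})

test_that("spectral-count simulation is deterministic and shared counts reduce correctly", {
  cfg <- coipSimConfig(seed = 11L)
  s1 <- simulateSpectralCounts(cfg)
  s2 <- simulateSpectralCounts(cfg)
  expect_identical(s1$counts@uniqueCounts, s2$counts@uniqueCounts)
  expect_identical(s1$counts@sharedCounts, s2$counts@sharedCounts)
  # with no shared peptides every count is unique and dNSAF is plain NSAF
  s0 <- simulateSpectralCounts(coipSimConfig(sharedPeptideFraction = 0, seed = 11L))
  expect_identical(nrow(s0$counts@sharedCounts), 0L)
  d <- computeDnsaf(s0$counts, "bait1", combine = 1L)
  u <- s0$counts@uniqueCounts
  u <- u[u$sample == "bait1" & u$replicate == 1L, ]
  u <- u[match(s0$counts@proteins$protein_id, u$protein_id), ]
  expect_equal(d@table$dNSAF,
               unname(oracleNsaf(u$count, s0$counts@proteins$length)),
               tolerance = 1e-12)
})

test_that("strong enrichment without shared peptides is fully recovered", {
  cfg <- coipSimConfig(baitEnrichment = 10, baselineCount = 20,
                       sharedPeptideFraction = 0, nReplicates = 1L, seed = 2L)
  sim <- simulateSpectralCounts(cfg)
  igg <- computeDnsaf(sim$counts, "IgG")
  truth <- names(which(sim$groundTruth$interactor))
  for (b in sim$groundTruth$baits) {
    kept <- candidateIds(foldChangeFilter(computeDnsaf(sim$counts, b), igg))
    expect_true(all(truth %in% kept))
  }
})

test_that("neurite scenes recover widths, bundling extremes and pair counts", {
  # deterministic
  cfg <- neuriteSceneConfig(seed = 9L)
  sc1 <- simulateNeuriteScene(cfg)
  sc2 <- simulateNeuriteScene(cfg)
  expect_identical(maskMatrix(sc1$axonMask), maskMatrix(sc2$axonMask))
  expect_identical(punctaCoords(sc1$prePuncta), punctaCoords(sc2$prePuncta))
  # zero-offset pairs with no orphans are counted exactly at 266 nm
  sc0 <- simulateNeuriteScene(neuriteSceneConfig(pairOffsetSd = 0,
                                                 nOrphanPuncta = 0L, seed = 4L))
  syn <- synapseDensity(sc0$prePuncta, sc0$postPuncta, sc0$dendriteMask,
                        radius = 266)
  expect_identical(syn$nMatched, sc0$groundTruth$nSynapsePairs)
  # bundling probability 1 vs 0 against ground-truth path overlap
  bAll <- simulateNeuriteScene(neuriteSceneConfig(bundlingProbability = 1,
                                                  nDendrites = 3L, nAxons = 12L,
                                                  imageShape = c(512L, 512L),
                                                  seed = 6L))
  bNone <- simulateNeuriteScene(neuriteSceneConfig(bundlingProbability = 0,
                                                   nDendrites = 3L, nAxons = 12L,
                                                   imageShape = c(512L, 512L),
                                                   seed = 6L))
  expect_equal(bAll$groundTruth$bundledFraction, 1)
  expect_equal(bNone$groundTruth$bundledFraction, 0)
  expect_gt(dendriteBundlingFraction(bAll$axonMask, bAll$dendriteMask), 0.85)
  # incidental crossings only for unbundled axons
  expect_lt(dendriteBundlingFraction(bNone$axonMask, bNone$dendriteMask), 0.35)
})
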