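# MPSkeleton

Quantitative analysis of the neuronal **membrane-associated periodic
skeleton (MPS)** — the ~190-nm lattice of actin rings and spectrin tetramers
that lines axons — from single-molecule localization microscopy data, for
researchers quantifying protein periodicity along neurites and the
companion co-IP and neurite-interaction readouts used alongside it.

## What it computes

**Periodicity of localization data.** Localizations of a straight ~2-µm
axon segment are projected onto the segment axis, binned (10 nm), and
autocorrelated with the overlap-normalized estimator

    g(l) = [ Σ_i (c_i − c̄)(c_{i+l} − c̄) / N_overlap(l) ] / s² ,   g(0) = 1.

Per-segment curves are averaged over tens of segments. The **amplitude** of
the averaged curve — value at the first peak (~190 nm) minus the mean of the
two first valleys (~95 and ~285 nm) — measures the degree of periodicity;
the **period** is the first-peak lag. Two-color data are compared by
symmetric-lag cross-correlation (anti-phase components peak near half the
period, a 180° phase shift) and by phase-aligned averaging of the 1D
profiles. Replicate-level amplitudes are compared with a two-sided
pooled-variance t-test (mean ± s.e.m.).

**Co-IP candidate filtering.** Distributed normalized spectral abundance
factors (dNSAF): shared-peptide counts are distributed among sharers in
proportion to unique counts, length-normalized, and normalized to sum to 1
per sample. Candidates are kept when the bait-to-IgG fold change is
strictly greater than 1, intersected across baits (with Venn counts), or
pooled as an annotation-restricted union (e.g. transmembrane proteins).

**Neurite interaction metrics.** Otsu binarization, medial-axis mean fiber
width (Zhang–Suen thinning + Euclidean distance transform), axon–dendrite
bundling fraction along the dendrite skeleton, and synapse density from
greedy one-to-one pre/post puncta matching within 266 nm.

**Synthetic data.** Seeded generators emulate all inputs — periodic and
uniform-control localizations, two-color data with a configurable phase
offset, bait/IgG spectral-count tables with shared peptides, and neurite
scenes with bundling and synaptic puncta — so every stage is testable
without raw data.

## A worked example

```r
library(MPSkeleton)

sim <- simulateMpsLocalizations(mpsSimConfig(seed = 1L))   # 50 segments, 2 um
res <- mpsPeriodicity(sim$localizations, sim$rois)
res$metrics
#> PeriodicityResult: amplitude 1.066, period 190 nm (peak 190 nm; valleys 90, 290 nm)
```

The period of 190 nm recovers the configured ring spacing to one 10-nm bin,
and the amplitude (1.07) is the peak-minus-valleys periodicity statistic —
about half the theoretical maximum of ~2, as expected with a 20% uniform
background and finite labeling. A uniform control is flat:

```r
ctl <- simulateUniformControl(mpsSimConfig(seed = 3L))
corAmplitude(mpsPeriodicity(ctl$localizations, ctl$rois)$metrics)
#> [1] 0.0299
```

Two-color data with channel-2 rings midway between channel-1 rings show the
anti-phase geometry:

```r
sim2 <- simulateTwoColorLocalizations(
  mpsSimConfig(nChannels = 2L, channelPhaseOffset = 0.5, seed = 2L))
cc <- mpsCrossCorrelation(sim2$localizations, sim2$rois)
curveExtremum(cc$curve, c(10, 190), "max")$lag
#> [1] 100        # ~half of the 190-nm period -> ~180 degree phase shift
```

An end-to-end run (simulation, periodicity, co-IP filter, neurite metrics,
reproducibility manifest) is driven by a YAML config:

```r
runPipeline(system.file("extdata", "demo-config.yaml", package = "MPSkeleton"),
            outDir = "mps-demo", seed = 1L)
```

## Package tour

| file | contents |
|---|---|
| `R/AllClasses.R` | S4 containers and simulation configs (with validity) |
| `R/simulate-*.R` | synthetic-data generators |
| `R/io.R` | localization/ROI/puncta/mask I/O, segment extraction |
| `R/periodicity.R` | projection, binning, correlations, amplitude/period, phase, alignment, t-test |
| `R/coip.R` | dNSAF, fold-change filter, intersection/pooling |
| `R/neurite.R` | Otsu, skeleton width, bundling, synapse density |
| `R/pipeline.R` | YAML-driven orchestration with manifest |
| `vignettes/mps-quantification.Rmd` | methods, design choices, limitations |
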