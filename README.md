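# smTFmap

Quantitative analysis of clustered transcription-factor binding-site maps
from single-molecule localization microscopy, and simulation of what that
clustering does to nuclear target search.

Live-cell single-molecule tracking of a transcription factor such as Sox2
yields catalogs of *stable binding sites* — positions where a molecule
dwelled essentially motionless (every step and the end-to-end displacement
below 50 nm) for seconds. These catalogs are spatial point patterns in the
nucleus, and the scientific questions are spatial-statistics questions: are
the sites clustered, how strongly and at what scale; how do site clusters
relate to other nuclear territories (heterochromatin, Pol II); how does
molecule mobility differ inside and outside those territories; and what
does clustering of absorbing targets do to the time a diffusing factor
needs to find one. smTFmap implements that entire tool chain, driven by
synthetic generators with retained ground truth so every estimator can be
validated against a known answer.

## What the package computes

**Clustering statistics.** The 3D pair-correlation function is estimated
from pair counts against a matched random catalog,

    g(r) = [N_R(N_R - 1) / (N(N - 1))] * DD(r) / RR(r),

with the random catalog drawn uniform in a declared sphere or in the 3D
convex hull of the data. Complete spatial randomness gives g = 1 at all r;
clustered catalogs start far above 1 and decay. The decay is summarised by
a fluctuation model, g(r) = (A exp(-r/eps) + 1) convolved with the PSF
pair-correlation kernel of width sigma-bar (sigma-bar^2 = s^2 + a^2/12):
A is proportional to the in-cluster density enrichment, eps to cluster
size.

**Localization and tracking.** 3D Gaussian PSF fitting (model
I = A0 exp(-(x-x0)^2/2s_xy^2 - (y-y0)^2/2s_xy^2 - (z-z0)^2/2s_z^2) + B),
the photon-count uncertainty estimator
Delta^2 = (s^2 + a^2/12)/N * (16/9 + 4 tau), block-centroid drift
correction, greedy nearest-neighbour linking under a maximum-diffusion
search radius, and dwell-based stable-site extraction.

**Field maps.** Kernel-density intensity maps of localizations, masked FFT
auto-/cross-correlation c(r) with exact mask normalisation
N(r) = FFT^-1(|FFT(mask)|^2) on zero-padded arrays, pixel-wise Pearson
correlation with background gating, relative fluorescence intensity
(RFI), outline registration, and in-mask permutation nulls.

**Diffusion.** Track splitting at region-mask boundaries, MSD fits
(MSD = 2 d D t) with R-squared gating, and Gaussian-mixture decomposition
of log10 D histograms into bound / slow / fast populations.

**Target search.** A first-passage Monte Carlo simulator: Brownian steps
of S.D. sqrt(2 D dt) per axis inside a reflecting 5 um nucleus with
thousands of non-overlapping absorbing targets (radius 40 nm, centers
>= 80 nm apart), recording the first-passage time tau3D per trial.
Derived quantities: the Fold of Delay (mean tau3D clustered / uniform),
one- and two-component exponential decompositions of tau3D, and the
Smoluchowski closed form tau3D = 1/(4 pi R D rho).

**ChIP-exo.** 5'-end reduction of stranded reads, a smoothed
local-maximum stand-in peak caller, greedy pairing of forward/reverse
peaks within 20 bp into bound regions (the interval between the two peak
midpoints), chromosome-bin densities and TSS-distance CDFs.

## Worked example

```r
library(smTFmap)

## a clustered stable-site catalog with known ground truth
sites <- genClusteredPoints(3000, 30, sigma = 200, minSeparation = 0,
                            volume = sphereVolume(2.5), seed = 42)

## pair correlation against a 10x random catalog, 50 nm bins
gr <- pairCorrelation3d(sites, deltaR = 50, randomFactor = 10,
                        rMax = 1500, seed = 43)
gr
#> CorrelationCurve: 31 bins, dr = 50 nm, r in [25, 1525] nm
#>   N = 3000 data points, NR = 30000 random points
head(round(gValues(gr), 2))
#> [1] 8.28 7.56 7.39 6.76 5.99 5.31

## fluctuation-model fit: amplitude ~ in-cluster enrichment, eps ~ size
fitFluctuationModel(gr, sBar = 15, aBar = 10)
#> FluctuationFit: A = 9.4, eps = 283.4 nm (sigmaBar = 15.3 nm)

## does clustering slow the target search? (desk-scale nucleus)
uni <- placeTargets(700, sphereVolume(2), seed = 44)
clu <- placeTargets(700, sphereVolume(2), mode = "cluster",
                    sigma = 200, nClusters = 7, seed = 45)
fu  <- simulateFirstPassage(uni, nTrials = 200, seed = 46)
fc  <- simulateFirstPassage(clu, nTrials = 200, seed = 47)
fod <- foldOfDelay(fc, fu, nBoot = 200, seed = 48)
#> Fold of Delay: 11.85 (95% CI 9.81-14.83)
```

The g(r) curve starts near 8 and decays toward 1 over ~1 um — the
signature of ~200 nm clusters; the fitted amplitude and range recover
the generator's geometry. The fold of delay above 1 shows that packing
the same 700 targets into 7 tight clusters makes the average search an
order of magnitude slower than uniformly scattered targets.

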