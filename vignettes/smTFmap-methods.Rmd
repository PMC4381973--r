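---
title: "Methods and design of smTFmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of smTFmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smTFmap)
```

smTFmap quantifies the spatial organisation of stable transcription-factor
binding sites mapped by single-molecule localization microscopy and models
the consequences of that organisation for diffusive target search. This
vignette is the package's account of its models, parameters, numerical
choices and limitations. Everything empirical shown here is computed by the
package at run time; the test suite asserts the same properties at fixed
seeds.

## The measurement model

A fluorescently tagged factor bound stably to chromatin appears as a
diffraction-limited spot. The forward model for a spot in a 3D stack is an
isotropic-in-xy Gaussian on a constant background,

$$I(x,y,z) = A_0\,
e^{-\frac{(x-x_0)^2}{2\sigma_{xy}^2}}
e^{-\frac{(y-y_0)^2}{2\sigma_{xy}^2}}
e^{-\frac{(z-z_0)^2}{2\sigma_z^2}} + B,$$

sampled at voxel centers $(i-\tfrac12)\,a$ (voxel size $a$, default 100 nm
isotropic as in bead calibration stacks) with Poisson shot noise on the
expected counts. `fitSpot()` inverts this model by Levenberg–Marquardt
least squares with the background fitted per spot and the axial width
fitted independently per spot; bounds $\sigma_{xy} \in [50, 500]$ nm and
$\sigma_z \in [100, 1500]$ nm stabilise fits on dim spots. The integrated
photon count $N$ is the background-subtracted sum of voxels within
$3\sigma$ of the fitted center, and $\tau = B/A_0$ is the
background-to-peak ratio. The per-axis localization uncertainty follows
the photon-count estimator

$$\Delta^2 = \frac{\sigma^2 + a^2/12}{N}\left(\frac{16}{9} + 4\tau\right),$$

which at $\tau = 0$ reduces to $16(\sigma^2+a^2/12)/(9N)$ and vanishes as
$N \to \infty$. The test suite checks that the empirical scatter of
refitted noisy spots sits on the scale this estimator predicts; the
estimator is a lower-bound-style approximation, so agreement is asserted
within a factor of two, not as an identity.

Stage drift is corrected by block centroids: the displacement of the mean
localization position over consecutive 50-frame blocks, subtracted
per block (`driftCorrect()`). This assumes the underlying site population
is stationary over a block. Datasets whose block-to-block rate exceeds
800 nm/min are rejected rather than rescued — heavy drift breaks the
stationarity assumption that makes the correction valid. The correction
is idempotent by construction.

## Tracks, stable sites and their time structure

`linkTracks()` links localizations frame to frame by greedy nearest
neighbour under a search radius derived from a maximum diffusion
coefficient, $r_\mathrm{max} = \sqrt{2 d\, D_\mathrm{max}\, \Delta t}$
(default $D_\mathrm{max} = 0.05\ \mu m^2/s$, the bound-molecule tracking
condition); ties resolve by smallest distance, then earliest index, and
the default gap closure is one frame (conservative against false merges;
longer gaps have no principled criterion here). Every detection
ends up in exactly one track.

A track is a *stable binding event* when every step and the end-to-end
displacement stay below 50 nm and the dwell lasts at least the cutoff
(3 s for 3D mapping; 2 s for 2D maps). Durations are counted as
$n_\mathrm{frames}\times\Delta t$ so that a single-frame detection under
the slow 500 ms acquisition contributes 0.5 s; under fast acquisition
single-frame events are discarded. Each qualifying event is counted once,
at the mean of its localizations — this is what makes the later
pair-correlation analysis insensitive to repeat localizations of one
molecule. `residenceStats()`, `detectionsPerFrame()` and `arrivalCdf()`
(with `canopyCluster()` at the 400 nm canopy radius) provide the temporal
profiles used to judge labelling/bleaching equilibrium and per-cluster
site accumulation.

## Pair correlation and the fluctuation model

The clustering statistic is the pair-correlation function estimated from
pair counts (`pairCorrelation3d()`): non-redundant pairwise distances of
the catalog are histogrammed into half-open 50 nm bins (DD), the same is
done for a uniform random catalog ten times larger in the same volume
(RR), and

$$\hat g(r) = \frac{N_R(N_R-1)}{N(N-1)}\,\frac{DD(r)}{RR(r)}.$$

The normalisation is the standard pair-count (Peebles–Hauser) prefactor:
pair counts scale with the square of catalog size, and this is the unique
prefactor under which complete spatial randomness gives
$\hat g \equiv 1$ — the defining property of the statistic and the one
the uniform-catalog tests assert. Bins with $RR = 0$ are reported as NA,
never divided through. The random catalog is drawn in the sphere declared
on the catalog when one is declared; otherwise uniform in the 3D convex
hull of the data (`convexHull3d()`, an incremental quickhull written for
this package because no installed package provides a 3D hull). For
synthetic spherical data the declared sphere avoids the inward bias a
hull of finite samples has. Re-drawing the random catalog
(`errorDraws`) yields a per-bin spread that serves as the estimator's
uncertainty.

Clustered catalogs are summarised by the fluctuation model: clusters of
no particular shape, randomly placed, give an exponential excess

$$g_\mathrm{enh}(r) = A\,e^{-r/\varepsilon} + 1,$$

with $A$ proportional to the in-cluster density relative to the global
density and $\varepsilon$ proportional to cluster size. What the
microscope observes is this correlation blurred by localization error,
modelled as convolution with the PSF pair-correlation kernel

$$g_\mathrm{PSF}(r) = \frac{1}{8\pi^{3/2}\bar\sigma^3}
e^{-r^2/4\bar\sigma^2},\qquad \bar\sigma^2 = \bar s^2 + \bar a^2/12 .$$

The kernel has unit mass in 3D, so the baseline 1 is preserved. The
stochastic multiple-appearance term is taken as zero because stable sites
are counted once (above). The 3D isotropic convolution reduces exactly to
a 1D integral,

$$ (e^{-\cdot/\varepsilon}\!\otimes g_\mathrm{PSF})(r) =
\frac{1}{2\sqrt{\pi}\,\bar\sigma\, r}\int_0^\infty s\,e^{-s/\varepsilon}
\left[e^{-(r-s)^2/4\bar\sigma^2} - e^{-(r+s)^2/4\bar\sigma^2}\right]ds,$$

evaluated by trapezoid quadrature on a grid refined to at least four
points per $\bar\sigma$ (capped at $2\times10^5$ points); the kernel
reduces to the plain exponential as $\bar\sigma \to 0$, which the tests
check at the 1% level. `fitFluctuationModel()` fits $(A, \varepsilon)$ by
Levenberg–Marquardt with $A \ge 0$; curves within 0.02 of flat pin
$A = 0$ rather than fitting noise, and uniform simulated catalogs are
fitted with the plain exponential (`psf = FALSE`). Parameter recovery on
forward-model curves with 1% noise is within 5% across
$A \in [0.8, 30]$, $\varepsilon \in [100, 400]$ nm, and fitted
amplitudes order strictly with generator cluster density.

## Intensity maps and masked correlation

2D localization maps are rendered by a separable Gaussian kernel density
on a 100×100 grid (kernel S.D. 2 grid units), evaluated at pixel centers
so the density integrates to 1 over the field; the physical bandwidth is
therefore 2 pixels whatever the nucleus size, and the pixel size (field
edge / 100, canonically 160 nm) travels on the `IntensityMap`. Wide-field
channels are background-subtracted (median pixel, unbiased while signal
covers less than half the frame) and max-normalised; masks are pixels at
or above 0.2 of the maximum.

Map correlations use the FFT form with exact mask normalisation,

$$c(\vec r) = \mathrm{Re}\frac{\mathrm{FFT}^{-1}
\left(\mathrm{FFT}(I_1)\,\overline{\mathrm{FFT}(I_2)}\right)}
{\rho_1 \rho_2\, N(\vec r)},\qquad
N(\vec r) = \mathrm{FFT}^{-1}\left(|\mathrm{FFT}(M)|^2\right),$$

on arrays zero-padded to twice the linear size so the circular transform
implements the linear correlation and $N(\vec r)$ counts mask-overlap
pixels exactly; lags whose overlap is below 16 pixels are undefined
rather than noisily normalised. The 2D correlation is angularly averaged
in 1-pixel radial bins and reported for $r$ above the pixel scale. On toy
grids the FFT path equals a shift-and-sum double loop to $10^{-10}$, and
the result is invariant to zeroing the arrays outside the mask. Two
caveats shape the generators and the interpretation: the estimator
assumes stationarity of the intensity process *within* the mask (the
synthetic pair generator therefore scatters cluster centers up to one
cluster-plus-kernel width beyond the mask; a process that genuinely dims
toward the nuclear rim will read as long-range correlation), and a
single nucleus carries irreducible cluster-sampling noise of roughly
±0.03 in the large-$r$ limit, which is why correlation summaries are
averaged over several nuclei, as they are over cells in practice.

`pixelCorrelation()` gates background as pixels low in both channels at
the same 0.2 threshold used for masks (one consistent threshold) before
computing Pearson's rho; `rfi()` is the background-corrected region/
surround intensity ratio; `registerByOutline()` aligns nuclei by the
integer shift maximising mask cross-correlation, exact for pure
translations.

## Diffusion analysis

`splitTracksByMask()` cuts tracks at mask-boundary crossings without ever
re-linking (tracking happened without knowledge of the mask, and
splitting must not manufacture connectivity); fragment detections sum
exactly to the input. `estimateD()` fits MSD versus lag over lags 1–4 —
short lags keep the MSD points weakly correlated; longer fits trade bias
for variance — on the longest consecutive run of at least 8 frames, and
converts by $\mathrm{MSD} = 2dDt$ with $d$ the track dimensionality.
Fits with $R^2 < 0.8$ are flagged unaccepted: this is a data-quality
gate for real data, and because it preferentially removes bound
(noise-floor) tracks it is disabled in ground-truth recovery tests. The
bound-population floor set by localization noise is *not* subtracted;
reported bound-state $D$ values are upper bounds, stated as such.

Population structure is fitted as a Gaussian mixture on $\log_{10} D$
(`dHistogramMixture()`), because the bound and free populations sit two
decades apart and linear-scale Gaussians cannot represent both; this is
a deliberate reinterpretation of "Gaussian peaks" fitted to log-binned
histograms. With several candidate component counts the BIC picks the
model; labelled two-population mixtures at the canonical conditions
(64% bound at 0.017 µm²/s, 36% free at 1.4 µm²/s, 10 ms frames) are
recovered within 10 percentage points of weight at 300 tracks and within
15 down to 50 tracks.

## The target-search simulator

Target search is reduced to a random-walk trapping problem: a point
particle takes independent per-axis Gaussian steps of S.D.
$\sqrt{2D\,\delta t}$ inside a reflecting sphere (nucleus radius 5 µm,
$D = 10\ \mu m^2/s$) containing $n$ absorbing spheres (radius 40 nm,
centers at least 80 nm apart so targets never overlap; 7000 at full
scale). A trial ends when the end-of-step position lies inside any
target — binding probability 1 — and the elapsed time is the
first-passage time $\tau_{3D}$.

Numerical choices, each with its reason:

* **Time step.** The default is $\delta t = 10\ \mu s$, which makes the
  per-axis step $\approx 14$ nm, a third of the target radius, so targets
  cannot be stepped over unnoticed ("the space is not under-sampled").
  A 10 ms step at $D = 10\ \mu m^2/s$ would mean 450 nm steps — an
  11-target-diameter leap per step — and is exposed only as an explicit
  option. The absorption test is end-of-step only (no continuous-path
  bridge); the small default step is what keeps the resulting
  under-detection negligible.
* **Boundary.** Radial reflection: an overshoot to radius $r > R$ is
  folded back to $2R - r$ along the same direction. At step/R of order
  $10^{-3}$ this is indistinguishable from exact specular reflection off
  the chord intersection point, which would cost a root-solve per
  boundary event; rejection resampling is available
  (`boundary = "resample"`) and results are insensitive at default
  parameters. No trajectory point ever lies outside the nucleus.
* **Neighbour lookup.** Targets live in a cell grid with cell size at
  least the target radius, so the 27-cell neighbourhood suffices; grid
  and brute-force lookups consume the RNG identically and produce
  bit-identical trajectories, hit times and hit indices — asserted in the
  tests, not assumed.
* **Censoring.** Trials are capped at $10^7$ steps; censored trials are
  reported with their flag, never dropped silently, and excluded (with a
  warning) from fold-of-delay means.
* **Placement.** Rejection sampling against the same cell grid, with an
  attempt budget of 100 draws per point; infeasible packings fail with an
  explicit error rather than looping forever. Cluster centers are
  redrawn on every call, so each simulation experiment sees fresh
  geometry unless a seed pins it.

Derived statistics: `foldOfDelay()` (mean clustered / mean uniform
$\tau_{3D}$ with a bootstrap CI), `fitExponential()` (MLE; the
two-component mixture by EM with a moment-based split start, collapsing
to one component when the lifetimes degenerate), the likelihood-ratio
comparison `compareExponentialModels()` (chi-square, 2 df, 0.01 level),
and the Smoluchowski dilute limit $\tau_{3D} = 1/(4\pi R D \rho)$, which
uniform targets at a tenth of the default density reproduce within a
factor of two — the expected accuracy of a point-sink, infinite-medium
formula applied to a confined, finite-density system.

The simulation suite runs at a desk scale chosen to keep the full
property sweep within minutes on one CPU while preserving every trend:
nucleus 2 µm, 700 targets, 100 trials × 10 repeats per condition, sigma
sweep {400, 300, 200} nm, cluster-count sweep {3, 7, 20}. Fold of delay
exceeds 1 for every clustered arrangement, grows as sigma shrinks,
falls as clusters multiply, and release-shell injection times grow with
the releasing radius; tightly clustered targets need the two-component
exponential while uniform targets do not.

## ChIP-exo bound regions

ChIP-exo trims fragments to the protein–DNA cross-link, which the 5' end
of each mapped read marks: `readsToFivePrime()` takes the start on the
forward strand and the end on the reverse strand (read count conserved).
Peak calling on these per-strand profiles is a deliberately simple
stand-in for a dedicated genome-track caller: Gaussian smoothing, local
maxima above a height floor, extents at half maximum, higher summits
winning overlaps. Its job is to be exact on synthetic piles (recall at
least 95% on generated sites), not to replicate any specific caller.

`pairPeaks()` forms bound regions from forward/reverse peak pairs whose
midpoints — integer division by two, i.e. rounded down, since the
original rounding is unrecorded — lie within 20 bp, greedily by
increasing distance with ties broken by the leftmost coordinate, each
peak used at most once. By default the forward peak's midpoint may not
lie downstream of the reverse peak's (the cross-linking geometry);
a flag relaxes this since the original script's rule is unknown. The
region spans from the smaller to the larger midpoint. Downstream,
`chromBinDensity()` counts the top-7000-by-score regions in 500 equal
bins per chromosome and `tssDistanceCdf()` computes positional distances
$|{\rm midpoint} - {\rm TSS}|$ to the nearest TSS (not the between-range
gap convention of range algebra, which is one less) with an optional
uniform-random genomic reference. Read trimming and depth normalisation
are upstream concerns; a plain scaling utility (`scaleToDepth()`) is
provided.

## Synthetic data: what it does and does not emulate

Every analysis in the package is exercised on generated data with
retained ground truth: uniform and Gaussian-clustered point catalogs with
hard-core separation (labels kept), Brownian and mixture track sets
(population labels kept), PSF-rendered spot stacks with Poisson noise,
co-localized/segregated intensity-map pairs sharing a controlled fraction
of cluster centers, and paired strand-specific peak lists with truth
tables. Identical seeds give bit-identical outputs; geometric constraints
are enforced exactly and checked by brute-force scans in the tests.

The generators emulate the statistical structure the estimators assume —
and only that. Photophysics is reduced to at most a constant detection
probability: no blinking or bleaching kinetics, so passing tests say
nothing about repeat-localization artifacts in real data. Camera noise is
Poisson only. Track mixtures switch populations between tracks, never
within one (no binding/unbinding transitions mid-track). Clustered
catalogs have isotropic Gaussian clusters with uniformly placed centers —
no nuclear substructure, no exclusion zones such as nucleoli. Conclusions
about real nuclei therefore rest on the estimators being correct and
well-calibrated, which is what the suite establishes, not on the
generators being biologically complete.

## Known limitations

* Bound-population $D$ estimates carry the static localization-noise
  floor; they are not corrected.
* The fluctuation model's absolute amplitude depends on the declared
  PSF width $\bar\sigma$; only relative comparisons between conditions
  fitted with the same $\bar\sigma$ are meaningful.
* The masked correlation reads genuine radial intensity gradients within
  the mask as long-range correlation (stationarity assumption).
* The exponential-mixture EM is biased for heavily overlapping
  lifetimes (ratio under ~16 with a minority slow component); the
  likelihood-ratio test remains calibrated, the point estimates less so.
* The stand-in peak caller is plumbing with guaranteed behaviour on
  synthetic data, not a reimplementation of any published caller.
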