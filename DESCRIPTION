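Package: smTFmap
Title: Cluster Analysis and Target-Search Simulation for Single-Molecule
    Transcription-Factor Binding-Site Maps
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying the spatial organisation of stable
    transcription-factor binding sites mapped by single-molecule
    localization microscopy, and for modelling its consequences for
    target search. Implements 3D Gaussian PSF spot fitting with the
    photon-count localization-uncertainty estimator, block-centroid
    drift correction, nearest-neighbour track linking and dwell-based
    stable-site extraction, the Peebles-Hauser 3D pair-correlation
    estimator with random catalogs drawn in a declared sphere or in the
    3D convex hull of the data, a PSF-convolved exponential fluctuation
    model of clustering, masked FFT auto- and cross-correlation of 2D
    intensity maps with kernel-density rendering, region-split MSD
    diffusion analysis with Gaussian-mixture decomposition, a
    first-passage Monte Carlo simulator of diffusive target search in a
    bounded nucleus with absorbing targets (fold-of-delay, exponential
    decompositions, Smoluchowski closed forms), and ChIP-exo
    strand-specific peak pairing into bound regions with chromosome-bin
    densities and TSS-distance profiles. Synthetic-data generators with
    retained ground truth drive all analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    minpack.lm,
    mclust,
    S4Vectors,
    IRanges,
    GenomicRanges,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
biocViews: SingleCell, Spatial, PeakDetection, ChIPSeq, Clustering
RoxygenNote: 7.3.3
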