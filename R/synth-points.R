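#' Uniform point catalog in a nuclear volume
#'
#' Draws `n` points i.i.d. uniform in a spherical nuclear volume, the
#' complete-spatial-randomness reference for all clustering statistics
#' (its pair correlation is 1 at every separation). An optional hard-core
#' minimum separation can be enforced by rejection.
#'
#' @param n number of points.
#' @param volume a [NuclearVolume-class] sphere (default 5 um radius).
#' @param minSeparation hard minimum pairwise distance in nm (0 = none).
#' @param seed integer seed; identical seed and parameters give identical
#'   output.
#' @param maxAttemptsFactor attempt budget, as a multiple of `n`, before a
#'   min-separation placement is declared infeasible.
#' @return a [PointCatalog-class] carrying the declared volume.
#' @examples
#' cat7k <- genUniformPoints(7000, sphereVolume(5), seed = 1)
#' @export
genUniformPoints <- function(n, volume = sphereVolume(5), minSeparation = 0,
                             seed = NULL, maxAttemptsFactor = 100) {
    n <- checkCount(n, "n")
    stopifnot(is(volume, "NuclearVolume"), volume@shape == "sphere")
    minSeparation <- checkPositive(minSeparation, "minSeparation", strict = FALSE)
    pts <- withSeed(seed,
        cpp_place_uniform(n, volume@radius, minSeparation,
                          max(1e4, maxAttemptsFactor * n)))
    pts <- sweep(pts, 2, volume@center, "+")
    PointCatalog(pts, volume = volume,
                 metadata = list(generator = "uniform", seed = seed,
                                 min_separation_nm = minSeparation))
}

#' Gaussian-clustered point catalog in a nuclear volume
#'
#' Cluster centers are drawn uniform in the sphere and resampled on every
#' call; members are isotropic Gaussian displacements (S.D. `sigma`) around
#' their center, rejected and redrawn when they fall outside the volume or
#' violate the global hard minimum separation. Ground-truth cluster labels
#' are retained on the catalog. Tighter `sigma` (or fewer clusters at fixed
#' total count) gives denser packing.
#'
#' @param n total number of points.
#' @param nClusters number of clusters (members split as evenly as
#'   possible).
#' @param sigma per-cluster isotropic Gaussian S.D., nm.
#' @param minSeparation hard minimum pairwise distance in nm across the
#'   whole catalog (0 = none).
#' @param volume a [NuclearVolume-class] sphere.
#' @param seed integer seed.
#' @param maxAttemptsFactor attempt budget multiple before failing with an
#'   infeasible-packing error.
#' @return a [PointCatalog-class] with cluster labels and, in its metadata,
#'   the cluster centers used.
#' @examples
#' cl <- genClusteredPoints(700, 7, sigma = 200, minSeparation = 80,
#'                          volume = sphereVolume(2), seed = 1)
#' table(clusterLabels(cl))
#' @export
genClusteredPoints <- function(n, nClusters, sigma, minSeparation = 0,
                               volume = sphereVolume(5), seed = NULL,
                               maxAttemptsFactor = 100) {
    n <- checkCount(n, "n")
    nClusters <- checkCount(nClusters, "nClusters")
    if (n < nClusters) stop("need n >= nClusters")
    sigma <- checkPositive(sigma, "sigma")
    minSeparation <- checkPositive(minSeparation, "minSeparation", strict = FALSE)
    stopifnot(is(volume, "NuclearVolume"), volume@shape == "sphere")

    nPer <- rep(n %/% nClusters, nClusters)
    extra <- n %% nClusters
    if (extra > 0) nPer[seq_len(extra)] <- nPer[seq_len(extra)] + 1

    res <- withSeed(seed, {
        centers <- runifSphere(nClusters, volume@radius)
        pts <- cpp_place_clustered(centers, as.integer(nPer), sigma,
                                   volume@radius, minSeparation,
                                   max(1e4, maxAttemptsFactor * n))
        list(centers = centers, pts = pts)
    })
    pts <- sweep(res$pts, 2, volume@center, "+")
    centers <- sweep(res$centers, 2, volume@center, "+")
    labels <- rep(seq_len(nClusters), nPer)
    PointCatalog(pts, volume = volume, labels = labels,
                 metadata = list(generator = "gaussian-cluster", seed = seed,
                                 sigma_nm = sigma,
                                 min_separation_nm = minSeparation,
                                 centers = centers))
}
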