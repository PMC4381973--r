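# Independent brute-force oracles used across the suite. These never call
# the package's accelerated code paths.

# non-redundant pairwise-distance histogram on half-open bins [e_k, e_{k+1})
bruteForcePairHist <- function(pts, edges) {
    dmat <- as.matrix(dist(pts))
    dv <- dmat[upper.tri(dmat)]
    counts <- integer(length(edges) - 1)
    for (k in seq_along(counts))
        counts[k] <- sum(dv >= edges[k] & dv < edges[k + 1])
    counts
}

# smallest pairwise distance by full scan
bruteForceMinDist <- function(pts) {
    dmat <- as.matrix(dist(pts))
    min(dmat[upper.tri(dmat)])
}

# per-point neighbour counts by full scan
bruteForceNeighborCounts <- function(pts, radius) {
    dmat <- as.matrix(dist(pts))
    diag(dmat) <- Inf
    rowSums(dmat <= radius)
}

# masked shift-and-sum correlation with the same lag convention as the
# package's FFT path: corr[lag k] = sum_x I1[x] I2[x - k]
bruteMaskedCorrelation <- function(I1, I2, mask, lagsX, lagsY,
                                   minOverlapPx = 1) {
    V1 <- I1 * mask; V2 <- I2 * mask
    rho1 <- mean(I1[mask]); rho2 <- mean(I2[mask])
    n1 <- nrow(I1); n2 <- ncol(I1)
    out <- matrix(NA_real_, length(lagsX), length(lagsY))
    for (a in seq_along(lagsX)) for (b in seq_along(lagsY)) {
        kx <- lagsX[a]; ky <- lagsY[b]
        s <- 0; nov <- 0
        for (x in seq_len(n1)) for (y in seq_len(n2)) {
            x2 <- x - kx; y2 <- y - ky
            if (x2 >= 1 && x2 <= n1 && y2 >= 1 && y2 <= n2) {
                s <- s + V1[x, y] * V2[x2, y2]
                nov <- nov + mask[x, y] * mask[x2, y2]
            }
        }
        if (nov >= minOverlapPx) out[a, b] <- s / (rho1 * rho2 * nov)
    }
    out
}

# nearest-TSS distance by full scan per region midpoint
bruteNearestTssDistance <- function(midChrom, midPos, tssChrom, tssPos) {
    vapply(seq_along(midPos), function(i) {
        same <- tssChrom == midChrom[i]
        if (!any(same)) return(NA_real_)
        min(abs(tssPos[same] - midPos[i]))
    }, numeric(1))
}

# per-chromosome equal-width binning of midpoints by direct tally
bruteChromBins <- function(chrom, mids, chromSizes, binsPerChrom) {
    out <- list()
    for (cn in names(chromSizes)) {
        width <- chromSizes[[cn]] / binsPerChrom
        counts <- integer(binsPerChrom)
        for (m in mids[chrom == cn]) {
            b <- min(max(ceiling(m / width), 1), binsPerChrom)
            counts[b] <- counts[b] + 1
        }
        out[[cn]] <- counts
    }
    out
}
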