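#' Paired strand-specific peak lists with known sites
#'
#' Emulates the cross-linking geometry that ChIP-exo produces around a
#' protein-bound site: each true site emits one forward-strand ("left")
#' peak upstream and one reverse-strand ("right") peak downstream, their
#' midpoints separated by `leftRightOffsetBp` plus integer jitter. The
#' truth table ties every peak back to its site so pairing recall can be
#' scored exactly.
#'
#' @param nSites number of true bound sites.
#' @param chromSizes named integer vector of chromosome lengths, bp.
#' @param leftRightOffsetBp midpoint separation between the left and right
#'   peak of a site, bp.
#' @param jitterBp peaks are shifted by integer jitter uniform in
#'   [-jitterBp, jitterBp].
#' @param peakWidthBp width of each emitted peak, bp.
#' @param minGapBp minimum distance between site midpoints on a chromosome,
#'   bp (keeps sites resolvable).
#' @param seed integer seed.
#' @return list: `left` and `right` (GRanges with score), `truth`
#'   (data.frame: chrom, site_mid, left_mid, right_mid).
#' @examples
#' gp <- genStrandPeaks(20, c(chr1 = 1e6), seed = 1)
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
#' @export
genStrandPeaks <- function(nSites, chromSizes, leftRightOffsetBp = 10,
                           jitterBp = 0, peakWidthBp = 11, minGapBp = 200,
                           seed = NULL) {
    nSites <- checkCount(nSites, "nSites")
    stopifnot(length(chromSizes) >= 1, !is.null(names(chromSizes)))
    withSeed(seed, {
        chrom <- sample(names(chromSizes), nSites, replace = TRUE,
                        prob = chromSizes / sum(chromSizes))
        mids <- integer(nSites)
        for (cn in unique(chrom)) {
            idx <- which(chrom == cn)
            limit <- chromSizes[[cn]]
            # spaced site midpoints by rejection
            got <- integer(0)
            while (length(got) < length(idx)) {
                cand <- sample.int(limit - 2 * minGapBp, 1) + minGapBp
                if (!length(got) || min(abs(got - cand)) >= minGapBp)
                    got <- c(got, cand)
            }
            mids[idx] <- got
        }
        jit <- function(n) if (jitterBp > 0)
            sample(seq(-jitterBp, jitterBp), n, replace = TRUE) else integer(n)
        leftMid <- mids - leftRightOffsetBp %/% 2 + jit(nSites)
        rightMid <- leftMid + leftRightOffsetBp + jit(nSites)
        half <- peakWidthBp %/% 2
        score <- round(runif(nSites, 20, 100))
        left <- GRanges(chrom,
                        IRanges(start = leftMid - half,
                                end = leftMid - half + peakWidthBp - 1),
                        strand = "+", score = score)
        right <- GRanges(chrom,
                         IRanges(start = rightMid - half,
                                 end = rightMid - half + peakWidthBp - 1),
                         strand = "-", score = score)
        truth <- data.frame(site = seq_len(nSites), chrom = chrom,
                            site_mid = mids, left_mid = leftMid,
                            right_mid = rightMid)
        list(left = left, right = right, truth = truth)
    })
}

#' Synthetic stranded 5'-end reads around known sites
#'
#' Generates single-end reads whose 5' ends pile up a fixed distance
#' upstream (forward strand) and downstream (reverse strand) of each true
#' site midpoint, with Gaussian scatter - the raw-material for the 5'-end
#' reduction and stand-in peak caller.
#'
#' @param nSites number of true sites.
#' @param chromSizes named integer vector of chromosome lengths.
#' @param readsPerSite reads per site and strand.
#' @param crosslinkOffsetBp distance from site midpoint to the 5'-end mode
#'   on each strand.
#' @param spreadBp Gaussian S.D. of 5'-end scatter, bp.
#' @param readLengthBp read length, bp.
#' @param seed integer seed.
#' @return list: `reads` (GRanges, stranded), `truth` (site midpoints).
#' @importFrom GenomicRanges GRanges strand
#' @importFrom IRanges IRanges
#' @export
genSiteReads <- function(nSites, chromSizes, readsPerSite = 50,
                         crosslinkOffsetBp = 15, spreadBp = 3,
                         readLengthBp = 36, seed = NULL) {
    nSites <- checkCount(nSites, "nSites")
    withSeed(seed, {
        chrom <- sample(names(chromSizes), nSites, replace = TRUE,
                        prob = chromSizes / sum(chromSizes))
        mids <- vapply(chrom, function(cn)
            sample.int(chromSizes[[cn]] - 2000L, 1) + 1000L, integer(1))
        rows <- vector("list", nSites)
        for (i in seq_len(nSites)) {
            fwd5 <- round(mids[i] - crosslinkOffsetBp +
                          rnorm(readsPerSite, sd = spreadBp))
            rev5 <- round(mids[i] + crosslinkOffsetBp +
                          rnorm(readsPerSite, sd = spreadBp))
            rows[[i]] <- data.frame(
                chrom = chrom[i],
                start = c(fwd5, rev5 - readLengthBp + 1),
                strand = rep(c("+", "-"), each = readsPerSite),
                site = i)
        }
        d <- do.call(rbind, rows)
        reads <- GRanges(d$chrom,
                         IRanges(start = d$start, width = readLengthBp),
                         strand = d$strand, site = d$site)
        list(reads = reads,
             truth = data.frame(site = seq_len(nSites), chrom = chrom,
                                site_mid = as.integer(mids)))
    })
}
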