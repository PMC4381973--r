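#' Reduce mapped reads to their 5'-end cross-linking points
#'
#' ChIP-exo trims each fragment to the protein-DNA cross-linking point,
#' which the 5' end of the mapped read marks: the start coordinate on the
#' forward strand, the end coordinate on the reverse strand. Read count is
#' conserved: positions sum to the number of input reads.
#'
#' @param reads a stranded GRanges of mapped reads.
#' @return data.frame: chrom, pos (1-based), strand, count.
#' @examples
#' library(GenomicRanges)
#' r <- GRanges("chr1", IRanges(101, 150), strand = "+")
#' readsToFivePrime(r)   # pos 101
#' @importFrom GenomicRanges seqnames start end strand
#' @export
readsToFivePrime <- function(reads) {
    st <- as.character(strand(reads))
    if (any(st == "*")) stop("all reads must be stranded")
    pos <- ifelse(st == "+", start(reads), end(reads))
    d <- data.frame(chrom = as.character(seqnames(reads)), pos = pos,
                    strand = st)
    agg <- aggregate(list(count = rep(1L, nrow(d))),
                     d[, c("chrom", "pos", "strand")], sum)
    agg[order(agg$chrom, agg$strand, agg$pos), , drop = FALSE]
}

# Gaussian-smooth a sparse position/count profile over its spanned range
smoothProfile <- function(pos, count, sd) {
    lo <- min(pos); hi <- max(pos)
    y <- numeric(hi - lo + 1)
    y[pos - lo + 1] <- count
    half <- max(1L, ceiling(4 * sd))
    kern <- dnorm(seq(-half, half), sd = sd)
    sm <- stats::filter(c(numeric(half), y, numeric(half)), kern,
                        sides = 2)
    list(pos = lo:hi, y = as.numeric(sm[(half + 1):(half + length(y))]))
}

#' Stand-in strand-specific peak caller
#'
#' A simple smoothed local-maximum caller standing in for a dedicated
#' genome-track peak caller: per chromosome and strand the 5'-end counts
#' are Gaussian-smoothed, local maxima above `minHeight` become peak
#' summits, and each peak extends over the contiguous region above half
#' its summit height. Overlapping extents are resolved in favour of the
#' higher summit.
#'
#' @param fivePrime data.frame from [readsToFivePrime()] (chrom, pos,
#'   strand, count).
#' @param smoothingSd Gaussian smoothing S.D., bp.
#' @param minHeight minimum smoothed summit height (in smoothed counts).
#' @return GRanges of peaks with `score` (summit height) and `summit`
#'   (position) metadata, stranded.
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
#' @importFrom stats dnorm aggregate
#' @export
callPeaksStandin <- function(fivePrime, smoothingSd = 5, minHeight = 2) {
    out <- list()
    for (key in split(fivePrime,
                      list(fivePrime$chrom, fivePrime$strand), drop = TRUE)) {
        if (!nrow(key)) next
        prof <- smoothProfile(key$pos, key$count, smoothingSd)
        y <- prof$y; n <- length(y)
        if (n < 3) next
        isMax <- y >= minHeight &
                 y >= c(-Inf, y[-n]) & y > c(y[-1], -Inf)
        summits <- which(isMax)
        if (!length(summits)) next
        ord <- summits[order(y[summits], decreasing = TRUE)]
        taken <- rep(FALSE, n)
        rows <- list()
        for (s in ord) {
            if (taken[s]) next
            hm <- y[s] / 2
            a <- s; while (a > 1 && y[a - 1] >= hm) a <- a - 1
            b <- s; while (b < n && y[b + 1] >= hm) b <- b + 1
            if (any(taken[a:b])) next
            taken[a:b] <- TRUE
            rows[[length(rows) + 1]] <-
                data.frame(chrom = key$chrom[1], start = prof$pos[a],
                           end = prof$pos[b], strand = key$strand[1],
                           score = y[s], summit = prof$pos[s])
        }
        out <- c(out, rows)
    }
    if (!length(out)) {
        gr <- GRanges()
        gr$score <- numeric(0); gr$summit <- integer(0)
        return(gr)
    }
    d <- do.call(rbind, out)
    GRanges(d$chrom, IRanges(d$start, d$end), strand = d$strand,
            score = d$score, summit = d$summit)
}

peakMidpoint <- function(gr) (start(gr) + end(gr)) %/% 2

#' Pair strand-specific peaks into bound regions
#'
#' Greedy pairing of forward-strand ("left") and reverse-strand ("right")
#' peaks whose midpoints lie within `maxDist` bp on the same chromosome:
#' candidate pairs are taken in order of increasing midpoint distance
#' (ties broken by the leftmost coordinate), each peak used at most once.
#' The bound region spans from the smaller to the larger of the two
#' midpoints (midpoints are rounded down). By default the left peak's
#' midpoint must not lie downstream of the right peak's, matching the
#' cross-linking geometry; `requireOrder = FALSE` relaxes this.
#'
#' @param left GRanges of forward-strand peaks (with `score`).
#' @param right GRanges of reverse-strand peaks (with `score`).
#' @param maxDist maximum midpoint distance, bp (default 20).
#' @param requireOrder left midpoint <= right midpoint?
#' @return GRanges of bound regions with metadata left_mid, right_mid,
#'   dist, score (sum of the paired peak scores); unpaired peak counts in
#'   `metadata(result)$unpaired`.
#' @examples
#' library(GenomicRanges)
#' L <- GRanges("chr1", IRanges(95, 105), strand = "+", score = 1)
#' R <- GRanges("chr1", IRanges(105, 115), strand = "-", score = 1)
#' pairPeaks(L, R)   # region [100, 110]
#' @importFrom GenomicRanges GRanges seqnames start end
#' @importFrom S4Vectors metadata metadata<-
#' @importFrom IRanges IRanges
#' @export
pairPeaks <- function(left, right, maxDist = 20, requireOrder = TRUE) {
    midL <- peakMidpoint(left); midR <- peakMidpoint(right)
    lc <- as.character(seqnames(left)); rc <- as.character(seqnames(right))
    lScore <- if (!is.null(left$score)) left$score else rep(0, length(left))
    rScore <- if (!is.null(right$score)) right$score else rep(0, length(right))

    cand <- list()
    for (cn in intersect(unique(lc), unique(rc))) {
        li <- which(lc == cn); ri <- which(rc == cn)
        for (i in li) {
            d <- midR[ri] - midL[i]
            ok <- abs(d) <= maxDist
            if (requireOrder) ok <- ok & d >= 0
            if (any(ok))
                cand[[length(cand) + 1]] <-
                    data.frame(l = i, r = ri[ok], dist = abs(d[ok]))
        }
    }
    usedL <- rep(FALSE, length(left)); usedR <- rep(FALSE, length(right))
    rows <- list()
    if (length(cand)) {
        cand <- do.call(rbind, cand)
        cand <- cand[order(cand$dist, pmin(midL[cand$l], midR[cand$r])), ,
                     drop = FALSE]
        for (k in seq_len(nrow(cand))) {
            i <- cand$l[k]; j <- cand$r[k]
            if (usedL[i] || usedR[j]) next
            usedL[i] <- TRUE; usedR[j] <- TRUE
            rows[[length(rows) + 1]] <- data.frame(
                chrom = lc[i], start = min(midL[i], midR[j]),
                end = max(midL[i], midR[j]), left_mid = midL[i],
                right_mid = midR[j], dist = cand$dist[k],
                score = lScore[i] + rScore[j])
        }
    }
    gr <- if (length(rows)) {
        d <- do.call(rbind, rows)
        GRanges(d$chrom, IRanges(d$start, d$end), left_mid = d$left_mid,
                right_mid = d$right_mid, dist = d$dist, score = d$score)
    } else {
        g0 <- GRanges()
        g0$left_mid <- integer(0); g0$right_mid <- integer(0)
        g0$dist <- integer(0); g0$score <- numeric(0)
        g0
    }
    metadata(gr)$unpaired <- c(left = sum(!usedL), right = sum(!usedR))
    gr
}

#' Bound-region density over chromosome bins
#'
#' Regions are ranked by score genome-wide, the top `topN` retained, and
#' their midpoints counted in `binsPerChrom` equal-width bins per
#' chromosome. Bin counts sum to the number of retained regions.
#'
#' @param regions GRanges of bound regions with `score`.
#' @param chromSizes named integer vector of chromosome lengths, bp.
#' @param binsPerChrom bins per chromosome (default 500).
#' @param topN regions retained genome-wide (default 7000; Inf keeps all).
#' @return data.frame: chrom, bin (1-based), binStart, binEnd, count.
#' @importFrom GenomicRanges seqnames start end
#' @export
chromBinDensity <- function(regions, chromSizes, binsPerChrom = 500,
                            topN = 7000) {
    if (length(regions) > topN) {
        keep <- order(regions$score, decreasing = TRUE)[seq_len(topN)]
        regions <- regions[keep]
    }
    mids <- (start(regions) + end(regions)) %/% 2
    chrom <- as.character(seqnames(regions))
    rows <- lapply(names(chromSizes), function(cn) {
        width <- chromSizes[[cn]] / binsPerChrom
        binStart <- floor((seq_len(binsPerChrom) - 1) * width) + 1
        binEnd <- floor(seq_len(binsPerChrom) * width)
        m <- mids[chrom == cn]
        bin <- pmin(pmax(ceiling(m / width), 1), binsPerChrom)
        data.frame(chrom = cn, bin = seq_len(binsPerChrom),
                   binStart = binStart, binEnd = binEnd,
                   count = tabulate(bin, nbins = binsPerChrom))
    })
    do.call(rbind, rows)
}

#' Distances from bound regions to the nearest TSS
#'
#' For each bound-region midpoint, the absolute distance to the nearest
#' transcription start site, returned with the empirical CDF (non-
#' decreasing, ending at 1) and, optionally, a matched reference built
#' from uniform random genomic positions.
#'
#' @param regions GRanges of bound regions.
#' @param tss GRanges (width-1 positions or any ranges; start is used) or
#'   data.frame with chrom and pos columns.
#' @param chromSizes named vector, needed for the random reference.
#' @param randomReference draw a matched uniform-random reference?
#' @param seed integer seed for the reference.
#' @return list: `distances`, `cdf` (data.frame distance, cdf),
#'   `randomDistances` (or NULL).
#' @importFrom GenomicRanges GRanges seqnames start end
#' @importFrom IRanges IRanges
#' @export
tssDistanceCdf <- function(regions, tss, chromSizes = NULL,
                           randomReference = FALSE, seed = NULL) {
    if (is.data.frame(tss))
        tss <- GRanges(tss$chrom, IRanges(tss$pos, width = 1))
    tssChrom <- as.character(seqnames(tss))
    tssPos <- start(tss)
    # positional distance |midpoint - TSS| (not the between-range gap)
    nearestDist <- function(chrom, pos) {
        out <- numeric(0)
        for (cn in unique(chrom)) {
            tp <- sort(tssPos[tssChrom == cn])
            if (!length(tp)) next
            p <- pos[chrom == cn]
            idx <- findInterval(p, tp)
            lo <- pmax(idx, 1); hi <- pmin(idx + 1, length(tp))
            out <- c(out, pmin(abs(p - tp[lo]), abs(p - tp[hi])))
        }
        out
    }
    midPos <- (start(regions) + end(regions)) %/% 2
    midChrom <- as.character(seqnames(regions))
    dists <- nearestDist(midChrom, midPos)
    sorted <- sort(dists)
    cdf <- data.frame(distance = sorted,
                      cdf = seq_along(sorted) / length(sorted))
    randomDistances <- NULL
    if (randomReference) {
        stopifnot(!is.null(chromSizes))
        randomDistances <- withSeed(seed, {
            cn <- sample(names(chromSizes), length(midPos), replace = TRUE,
                         prob = chromSizes / sum(chromSizes))
            pos <- vapply(cn, function(x) sample.int(chromSizes[[x]], 1),
                          integer(1))
            nearestDist(cn, pos)
        })
    }
    list(distances = dists, cdf = cdf, randomDistances = randomDistances)
}

#' Scale counts to a target depth
#'
#' Optional depth-normalisation utility (e.g. scale a library to 40
#' million mapped reads before comparing conditions).
#'
#' @param counts numeric vector of counts.
#' @param targetDepth desired total.
#' @return scaled counts (numeric).
#' @export
scaleToDepth <- function(counts, targetDepth = 4e7) {
    tot <- sum(counts)
    if (tot <= 0) stop("no counts to scale")
    counts * (targetDepth / tot)
}
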