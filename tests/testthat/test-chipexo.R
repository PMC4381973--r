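suppressPackageStartupMessages(library(GenomicRanges))

test_that("5'-end reduction takes start on + and end on -, conserving reads", {
    r <- GRanges(c("chr1", "chr1"), IRanges(c(101, 101), c(150, 150)),
                 strand = c("+", "-"))
    fp <- readsToFivePrime(r)
    expect_equal(fp$pos[fp$strand == "+"], 101)
    expect_equal(fp$pos[fp$strand == "-"], 150)
    expect_equal(sum(fp$count), 2L)

    # toy pile: counts equal a manual tally
    pos <- c(10, 10, 10, 12, 15, 15)
    reads <- GRanges("chr2", IRanges(pos, width = 30), strand = "+")
    fp2 <- readsToFivePrime(reads)
    expect_equal(fp2$count[order(fp2$pos)], c(3L, 1L, 2L))
    expect_equal(sum(fp2$count), 6L)
    expect_error(readsToFivePrime(GRanges("chr1", IRanges(1, 10))),
                 "stranded")
})

test_that("the stand-in peak caller resolves isolated and nearby piles", {
    fp <- data.frame(chrom = "chr1", pos = c(500, 501, 502),
                     strand = "+", count = c(5L, 8L, 5L))
    pk <- callPeaksStandin(fp, smoothingSd = 2, minHeight = 1)
    expect_equal(length(pk), 1L)
    expect_equal(pk$summit, 501)

    two <- data.frame(chrom = "chr1", pos = c(500, 501, 600, 601),
                      strand = "+", count = 6L)
    pk2 <- callPeaksStandin(two, smoothingSd = 3, minHeight = 1)
    expect_equal(length(pk2), 2L)
})

test_that("peak calling on generated reads recovers at least 95% of sites", {
    cs <- c(chr1 = 2e6, chr2 = 1e6)
    sr <- genSiteReads(50, cs, readsPerSite = 40, seed = 1)
    fp <- readsToFivePrime(sr$reads)
    pk <- callPeaksStandin(fp, smoothingSd = 5, minHeight = 2)
    fwd <- pk[strand(pk) == "+"]
    hits <- sapply(seq_len(nrow(sr$truth)), function(i) {
        same <- as.character(seqnames(fwd)) == sr$truth$chrom[i]
        any(same & abs(fwd$summit - sr$truth$site_mid[i]) < 50)
    })
    expect_gte(mean(hits), 0.95)
})

test_that("peak pairing follows the midpoint window rule", {
    L <- GRanges("chr1", IRanges(95, 105), strand = "+", score = 2)
    R <- GRanges("chr1", IRanges(105, 115), strand = "-", score = 3)
    br <- pairPeaks(L, R, maxDist = 20)
    expect_equal(length(br), 1L)
    expect_equal(start(br), 100)
    expect_equal(end(br), 110)
    expect_equal(br$score, 5)

    far <- GRanges("chr1", IRanges(125, 135), strand = "-", score = 1)
    expect_equal(length(pairPeaks(L, far, maxDist = 20)), 0L)

    # each peak used at most once; output bounded by the smaller list
    L2 <- GRanges("chr1", IRanges(c(95, 99), c(105, 109)), strand = "+",
                  score = c(1, 1))
    br2 <- pairPeaks(L2, R, maxDist = 20)
    expect_equal(length(br2), 1L)
    expect_equal(metadata(br2)$unpaired[["left"]], 1L)
})

test_that("order enforcement can be relaxed", {
    L <- GRanges("chr1", IRanges(195, 205), strand = "+", score = 1)
    R <- GRanges("chr1", IRanges(175, 185), strand = "-", score = 1)
    expect_equal(length(pairPeaks(L, R, maxDist = 20)), 0L)
    expect_equal(length(pairPeaks(L, R, maxDist = 20,
                                  requireOrder = FALSE)), 1L)
})

test_that("generated peak lists pair perfectly at the design offset", {
    cs <- c(chr1 = 2e6, chr2 = 1.5e6)
    gp <- genStrandPeaks(60, cs, leftRightOffsetBp = 10, jitterBp = 0,
                        seed = 2)
    br <- pairPeaks(gp$left, gp$right, maxDist = 20)
    expect_equal(length(br), 60L)
    # recovered regions sit on the true sites
    ord <- order(as.character(seqnames(br)), start(br))
    tr <- gp$truth[order(gp$truth$chrom, gp$truth$left_mid), ]
    expect_equal(start(br)[ord], tr$left_mid)
    gp30 <- genStrandPeaks(60, cs, leftRightOffsetBp = 30, seed = 3)
    expect_equal(length(pairPeaks(gp30$left, gp30$right, maxDist = 20)), 0L)
})

test_that("chromosome bin densities equal a direct tally and sum to the input", {
    cs <- c(chr1 = 1e6, chr2 = 5e5)
    gp <- genStrandPeaks(80, cs, seed = 4)
    br <- pairPeaks(gp$left, gp$right)
    bd <- chromBinDensity(br, cs, binsPerChrom = 500, topN = 7000)
    expect_equal(sum(bd$count), length(br))
    mids <- (start(br) + end(br)) %/% 2
    oracle <- bruteChromBins(as.character(seqnames(br)), mids, cs, 500)
    for (cn in names(cs))
        expect_equal(bd$count[bd$chrom == cn], oracle[[cn]])
    # top-N retention by score
    bd2 <- chromBinDensity(br, cs, binsPerChrom = 500, topN = 10)
    expect_equal(sum(bd2$count), 10L)
})

test_that("TSS distance CDF equals the brute-force nearest scan", {
    cs <- c(chr1 = 1e6)
    set.seed(5)
    tss <- data.frame(chrom = "chr1", pos = sort(sample.int(1e6, 40)))
    gp <- genStrandPeaks(30, cs, seed = 6)
    br <- pairPeaks(gp$left, gp$right)
    res <- tssDistanceCdf(br, tss)
    mids <- (start(br) + end(br)) %/% 2
    oracle <- bruteNearestTssDistance(as.character(seqnames(br)), mids,
                                      tss$chrom, tss$pos)
    expect_equal(sort(res$distances), sort(oracle))
    expect_true(all(diff(res$cdf$cdf) >= 0))
    expect_equal(tail(res$cdf$cdf, 1), 1)

    # midpoint exactly at a TSS gives distance 0
    atTss <- GRanges("chr1", IRanges(tss$pos[1], tss$pos[1]))
    expect_equal(tssDistanceCdf(atTss, tss)$distances, 0)
    # single TSS at 1000, midpoint 1500: distance 500
    one <- tssDistanceCdf(GRanges("chr1", IRanges(1500, 1500)),
                          data.frame(chrom = "chr1", pos = 1000))
    expect_equal(one$distances, 500)
})

test_that("depth scaling hits its target total", {
    x <- c(10, 20, 70)
    expect_equal(sum(scaleToDepth(x, 4e7)), 4e7)
    expect_error(scaleToDepth(numeric(0)), "no counts")
})
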