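# Text and image I/O in the conventions used throughout the package:
# localization/track tables as CSV with nm coordinates, peak lists as
# 6-column BED (0-based half-open, strand in column 6), image stacks as
# multi-page TIFF.

#' Read and write localization / track tables
#'
#' CSV with header columns track_id (tracks only), frame, x_nm, y_nm,
#' z_nm. Units are nm throughout.
#'
#' @param file path.
#' @param tracks a [TrackSet-class] (write) .
#' @param dt frame interval for the [TrackSet-class] built on read, s.
#' @return `readTrackCsv` a [TrackSet-class]; `readLocalizationsCsv` a
#'   data.frame; the writers return the file path invisibly.
#' @export
readTrackCsv <- function(file, dt) {
    d <- read.table(file, header = TRUE, sep = ",")
    TrackSet(d, dt = dt)
}

#' @rdname readTrackCsv
#' @export
writeTrackCsv <- function(tracks, file) {
    write.table(trackData(tracks), file, sep = ",", row.names = FALSE,
                quote = FALSE)
    invisible(file)
}

#' @rdname readTrackCsv
#' @export
readLocalizationsCsv <- function(file) {
    read.table(file, header = TRUE, sep = ",")
}

#' BED import/export for stranded peak lists
#'
#' 6-column BED: chrom, start (0-based), end (half-open), name, score,
#' strand. Conversion to the 1-based closed coordinates used internally
#' happens here and only here.
#'
#' @param file path.
#' @param gr a GRanges with `score` (write).
#' @return `readBedPeaks` a GRanges; `writeBedPeaks` the path, invisibly.
#' @importFrom GenomicRanges GRanges seqnames start end strand
#' @importFrom IRanges IRanges
#' @export
readBedPeaks <- function(file) {
    d <- read.table(file, header = FALSE, sep = "\t",
                    col.names = c("chrom", "start", "end", "name", "score",
                                  "strand"))
    GRanges(d$chrom, IRanges(d$start + 1, d$end), strand = d$strand,
            score = d$score, name = d$name)
}

#' @rdname readBedPeaks
#' @export
writeBedPeaks <- function(gr, file) {
    d <- data.frame(chrom = as.character(seqnames(gr)),
                    start = start(gr) - 1, end = end(gr),
                    name = if (!is.null(gr$name)) gr$name else ".",
                    score = if (!is.null(gr$score)) gr$score else 0,
                    strand = as.character(strand(gr)))
    write.table(d, file, sep = "\t", row.names = FALSE, col.names = FALSE,
                quote = FALSE)
    invisible(file)
}

#' Multi-page TIFF image-stack I/O
#'
#' Stacks are stored page-per-z-slice; intensities are rescaled to [0, 1]
#' on write (TIFF stores normalised floats) with the scale factor kept in
#' the function's return value, and can be re-scaled on read.
#'
#' @param stack 3D array (x, y, z).
#' @param file path.
#' @param scale multiply intensities on read.
#' @return `readTiffStack` a 3D array; `writeTiffStack` the maximum
#'   intensity used for normalisation, invisibly.
#' @export
writeTiffStack <- function(stack, file) {
    m <- max(stack)
    pages <- lapply(seq_len(dim(stack)[3]), function(k)
        t(stack[, , k]) / max(m, 1e-12))
    tiff::writeTIFF(pages, file, bits.per.sample = 32L)
    invisible(m)
}

#' @rdname writeTiffStack
#' @export
readTiffStack <- function(file, scale = 1) {
    pages <- tiff::readTIFF(file, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    arr <- array(0, dim = c(ncol(pages[[1]]), nrow(pages[[1]]),
                            length(pages)))
    for (k in seq_along(pages)) arr[, , k] <- t(pages[[k]])
    arr * scale
}
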