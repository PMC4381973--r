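# shared internal helpers

#' @importFrom stats rnorm runif rpois rexp dexp fft ecdf
#' @importFrom graphics hist
#' @importFrom utils head tail read.table write.table
NULL

# Evaluate expr under set.seed(seed) without disturbing the caller's RNG
# stream; seed = NULL uses (and advances) the current stream.
withSeed <- function(seed, expr) {
    if (is.null(seed)) return(eval.parent(substitute(expr)))
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
    eval.parent(substitute(expr))
}

# n points uniform in a sphere (nm), plain R path used by small generators
runifSphere <- function(n, radius, center = c(0, 0, 0)) {
    out <- matrix(NA_real_, n, 3)
    got <- 0
    while (got < n) {
        m <- ceiling((n - got) * 2)
        cand <- matrix(runif(3 * m, -radius, radius), m, 3)
        keep <- rowSums(cand^2) <= radius^2
        take <- min(sum(keep), n - got)
        if (take > 0) {
            out[(got + 1):(got + take), ] <- cand[keep, , drop = FALSE][seq_len(take), ]
            got <- got + take
        }
    }
    sweep(out, 2, center, "+")
}

sphereVolumeUm3 <- function(radiusNm) (4 / 3) * pi * (radiusNm / 1000)^3

checkCount <- function(x, name, min = 1) {
    if (length(x) != 1 || !is.finite(x) || x < min || x != round(x))
        stop(sprintf("'%s' must be a single integer >= %d", name, min))
    as.integer(x)
}

checkPositive <- function(x, name, strict = TRUE) {
    if (length(x) != 1 || !is.finite(x) || (strict && x <= 0) || (!strict && x < 0))
        stop(sprintf("'%s' must be a single %s number", name,
                     if (strict) "positive" else "non-negative"))
    as.numeric(x)
}
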