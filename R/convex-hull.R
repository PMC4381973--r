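#' 3D convex hull of a point set
#'
#' Incremental (beneath-beyond) convex hull in three dimensions, returning
#' triangular facets with outward normals, plane offsets and the enclosed
#' volume. Used to define the sampling volume of the pair-correlation random
#' catalog when no sphere is declared for the catalog.
#'
#' @param pts n x 3 numeric matrix (nm). At least 4 points not all coplanar.
#' @param eps numeric tolerance for the visibility test, scaled by the data
#'   extent.
#' @return a list with elements `facets` (m x 3 vertex indices), `normals`
#'   (m x 3 unit outward normals), `offsets` (plane offsets: a point p is
#'   inside iff normals %*% p <= offsets for all facets), `volume` (nm^3)
#'   and `interior` (an interior point).
#' @examples
#' cube <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
#' h <- convexHull3d(cube)
#' h$volume   # 1
#' @export
convexHull3d <- function(pts, eps = 1e-9) {
    pts <- as.matrix(pts)
    stopifnot(ncol(pts) == 3)
    n <- nrow(pts)
    if (n < 4) stop("need at least 4 points for a 3D hull")
    scale <- max(apply(pts, 2, function(v) diff(range(v))))
    if (scale == 0) stop("degenerate point set")
    tol <- eps * scale

    # initial tetrahedron from extreme points
    i1 <- which.min(pts[, 1]); i2 <- which.max(pts[, 1])
    if (i1 == i2) stop("degenerate point set")
    d12 <- pts[i2, ] - pts[i1, ]
    # farthest from the line i1-i2
    relp <- sweep(pts, 2, pts[i1, ])
    crossn <- cbind(relp[, 2] * d12[3] - relp[, 3] * d12[2],
                    relp[, 3] * d12[1] - relp[, 1] * d12[3],
                    relp[, 1] * d12[2] - relp[, 2] * d12[1])
    i3 <- which.max(rowSums(crossn^2))
    if (sqrt(sum(crossn[i3, ]^2)) <= tol * sqrt(sum(d12^2)))
        stop("points are collinear")
    nrm <- crossProd(pts[i2, ] - pts[i1, ], pts[i3, ] - pts[i1, ])
    dist4 <- abs(relp %*% nrm)
    i4 <- which.max(dist4)
    if (dist4[i4] <= tol * sqrt(sum(nrm^2))) stop("points are coplanar")

    interior <- colMeans(pts[c(i1, i2, i3, i4), ])
    facets <- rbind(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))
    geo <- facetGeometry(facets, pts, interior)
    normals <- geo$normals; offsets <- geo$offsets

    rest <- setdiff(seq_len(n), c(i1, i2, i3, i4))
    for (p in rest) {
        vis <- drop(normals %*% pts[p, ]) > offsets + tol
        if (!any(vis)) next
        # horizon: edges used by exactly one visible facet
        visF <- facets[vis, , drop = FALSE]
        edges <- rbind(visF[, c(1, 2)], visF[, c(1, 3)], visF[, c(2, 3)])
        edges <- t(apply(edges, 1, sort))
        key <- paste(edges[, 1], edges[, 2])
        horizon <- edges[key %in% names(which(table(key) == 1)), , drop = FALSE]
        facets <- facets[!vis, , drop = FALSE]
        normals <- normals[!vis, , drop = FALSE]
        offsets <- offsets[!vis]
        if (nrow(horizon)) {
            newF <- cbind(horizon, p)
            geo <- facetGeometry(newF, pts, interior)
            facets <- rbind(facets, newF)
            normals <- rbind(normals, geo$normals)
            offsets <- c(offsets, geo$offsets)
        }
    }

    # star-shaped volume from the interior point
    a <- pts[facets[, 1], , drop = FALSE]
    b <- pts[facets[, 2], , drop = FALSE]
    cc <- pts[facets[, 3], , drop = FALSE]
    a <- sweep(a, 2, interior); b <- sweep(b, 2, interior); cc <- sweep(cc, 2, interior)
    dets <- a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
            a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
            a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
    vol <- sum(abs(dets)) / 6

    dimnames(facets) <- NULL
    list(facets = facets, normals = normals, offsets = offsets,
         volume = vol, interior = interior)
}

crossProd <- function(u, v) {
    c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
      u[1] * v[2] - u[2] * v[1])
}

# outward unit normals and offsets for facet rows, oriented away from an
# interior point
facetGeometry <- function(facets, pts, interior) {
    m <- nrow(facets)
    normals <- matrix(0, m, 3)
    offsets <- numeric(m)
    for (f in seq_len(m)) {
        v <- facets[f, ]
        nrm <- crossProd(pts[v[2], ] - pts[v[1], ], pts[v[3], ] - pts[v[1], ])
        len <- sqrt(sum(nrm^2))
        if (len == 0) { normals[f, ] <- c(0, 0, 1); offsets[f] <- Inf; next }
        nrm <- nrm / len
        off <- sum(nrm * pts[v[1], ])
        if (sum(nrm * interior) > off) { nrm <- -nrm; off <- -off }
        normals[f, ] <- nrm
        offsets[f] <- off
    }
    list(normals = normals, offsets = offsets)
}

#' Test points against a convex hull
#'
#' @param hull result of [convexHull3d()].
#' @param pts m x 3 matrix.
#' @param tol slack on the half-space test (nm).
#' @return logical vector, TRUE for points inside or on the hull.
#' @export
inHull3d <- function(hull, pts, tol = 1e-7) {
    pts <- as.matrix(pts)
    proj <- pts %*% t(hull$normals)
    rowSums(proj > matrix(hull$offsets + tol, nrow(pts), length(hull$offsets),
                          byrow = TRUE)) == 0
}

# uniform sample inside a hull by rejection from its bounding box
runifHull3d <- function(n, hull, pts) {
    lo <- apply(pts, 2, min); hi <- apply(pts, 2, max)
    out <- matrix(NA_real_, n, 3)
    got <- 0
    while (got < n) {
        m <- max(1000, ceiling((n - got) * 2.5))
        cand <- cbind(runif(m, lo[1], hi[1]), runif(m, lo[2], hi[2]),
                      runif(m, lo[3], hi[3]))
        keep <- inHull3d(hull, cand)
        take <- min(sum(keep), n - got)
        if (take > 0) {
            out[(got + 1):(got + take), ] <- cand[keep, , drop = FALSE][seq_len(take), ]
            got <- got + take
        }
    }
    out
}
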