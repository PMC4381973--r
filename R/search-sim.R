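#' Place absorbing targets in a nucleus
#'
#' Positions `n` non-overlapping spherical targets (capture radius
#' `radius`, centers at least `minSeparation` apart, default twice the
#' radius so spheres cannot touch) inside a spherical nucleus, either
#' uniformly or as Gaussian clusters whose centers are redrawn on every
#' call. Placement is rejection sampling against a spatial grid with a
#' bounded attempt budget; infeasible packings fail explicitly.
#'
#' @param n number of targets (7000 at full scale).
#' @param volume a [NuclearVolume-class] sphere (default 5 um radius).
#' @param radius target capture radius, nm (40 by default; 30 for the
#'   small-target control).
#' @param minSeparation minimum center-to-center distance, nm (default
#'   2 * radius).
#' @param mode "uniform" or "cluster".
#' @param sigma cluster S.D., nm (cluster mode).
#' @param nClusters number of clusters (cluster mode).
#' @param seed integer seed.
#' @param maxAttemptsFactor attempt budget multiple.
#' @return a [TargetSet-class].
#' @examples
#' ts <- placeTargets(700, sphereVolume(2), seed = 1)
#' @export
placeTargets <- function(n, volume = sphereVolume(5), radius = 40,
                         minSeparation = 2 * radius,
                         mode = c("uniform", "cluster"), sigma = NULL,
                         nClusters = NULL, seed = NULL,
                         maxAttemptsFactor = 100) {
    mode <- match.arg(mode)
    radius <- checkPositive(radius, "radius")
    if (minSeparation < 2 * radius)
        warning("minSeparation < 2 * radius allows overlapping targets")
    catg <- if (mode == "uniform") {
        genUniformPoints(n, volume, minSeparation = minSeparation,
                         seed = seed, maxAttemptsFactor = maxAttemptsFactor)
    } else {
        stopifnot(!is.null(sigma), !is.null(nClusters))
        genClusteredPoints(n, nClusters, sigma,
                           minSeparation = minSeparation, volume = volume,
                           seed = seed, maxAttemptsFactor = maxAttemptsFactor)
    }
    new("TargetSet", centers = coords(catg), radius = radius,
        volume = volume, labels = clusterLabels(catg))
}

#' First-passage Monte Carlo simulation of target search
#'
#' Propagates a diffusing factor by independent per-axis Gaussian steps of
#' S.D. sqrt(2 D dt) inside a reflecting spherical nucleus until it first
#' enters any target sphere (binding probability 1), recording the
#' first-passage time tau3D of each trial. Injection points are drawn
#' uniform in the nucleus outside all targets, or uniform on a shell of
#' given radius about the cluster center (the re-release geometry). Trials
#' exceeding the step cap are censored and reported, never dropped.
#'
#' The default time step (10 us at D = 10 um^2/s) keeps the per-axis step
#' near 14 nm, well under the 40 nm target radius, so space is not
#' under-sampled; target lookup uses a cell grid whose results are
#' identical to brute-force checking (`bruteForce = TRUE`).
#'
#' @param targets a [TargetSet-class].
#' @param nTrials number of independent trials.
#' @param D diffusion coefficient, um^2/s (default 10).
#' @param dt time step, s (default 1e-5).
#' @param injection "uniform" or "shell".
#' @param releasingRadius shell radius, nm (shell injection; must not
#'   exceed the nucleus radius).
#' @param shellCenter center of the release shell, nm; defaults to the
#'   centroid of the targets (the cluster center).
#' @param maxSteps per-trial step cap (censoring).
#' @param boundary "reflect" (radial reflection) or "resample" (redraw the
#'   step until it stays inside).
#' @param bruteForce check every target each step instead of the grid
#'   (identical results; for validation).
#' @param keepFirstTrajectory store the first trial's full path.
#' @param seed integer seed.
#' @return a [FirstPassageResult-class].
#' @examples
#' ts <- placeTargets(200, sphereVolume(1), seed = 1)
#' fp <- simulateFirstPassage(ts, nTrials = 20, seed = 2)
#' mean(tau3d(fp))
#' @export
simulateFirstPassage <- function(targets, nTrials, D = 10, dt = 1e-5,
                                 injection = c("uniform", "shell"),
                                 releasingRadius = NULL, shellCenter = NULL,
                                 maxSteps = 1e7,
                                 boundary = c("reflect", "resample"),
                                 bruteForce = FALSE,
                                 keepFirstTrajectory = FALSE, seed = NULL) {
    injection <- match.arg(injection)
    boundary <- match.arg(boundary)
    nTrials <- checkCount(nTrials, "nTrials")
    D <- checkPositive(D, "D")
    dt <- checkPositive(dt, "dt")
    vol <- nuclearVolume(targets)
    R <- vol@radius
    ctr <- vol@center
    tr <- targetRadius(targets)
    stepSd <- sqrt(2 * D * dt) * 1000
    if (stepSd >= tr)
        warning(sprintf(
            "per-axis step %.1f nm >= target radius %.1f nm: space is under-sampled, reduce dt",
            stepSd, tr))
    centers <- sweep(targetCenters(targets), 2, ctr)   # nucleus-centered

    res <- withSeed(seed, {
        starts <- if (injection == "uniform") {
            out <- matrix(NA_real_, nTrials, 3); got <- 0
            while (got < nTrials) {
                cand <- runifSphere(2 * (nTrials - got), R)
                free <- !cpp_points_in_targets(centers, tr, cand)
                take <- min(sum(free), nTrials - got)
                if (take > 0) {
                    out[(got + 1):(got + take), ] <-
                        cand[free, , drop = FALSE][seq_len(take), ]
                    got <- got + take
                }
            }
            out
        } else {
            if (is.null(releasingRadius))
                stop("shell injection needs a releasingRadius")
            if (releasingRadius > R)
                stop("releasing radius lies outside the nucleus")
            c0 <- if (is.null(shellCenter)) colMeans(centers) else
                shellCenter - ctr
            dirs <- matrix(rnorm(3 * nTrials), ncol = 3)
            dirs <- dirs / sqrt(rowSums(dirs^2))
            pts <- sweep(dirs * releasingRadius, 2, c0, "+")
            # clip shell points that leave the nucleus back onto its surface
            rr <- sqrt(rowSums(pts^2))
            bad <- rr > R
            if (any(bad)) pts[bad, ] <- pts[bad, ] * (0.999 * R / rr[bad])
            pts
        }
        cpp_first_passage(centers, tr, starts, stepSd, R, maxSteps,
                          bruteForce, if (boundary == "reflect") 0L else 1L,
                          keepFirstTrajectory)
    })
    traj <- if (keepFirstTrajectory)
        sweep(res$trajectory, 2, ctr, "+") else matrix(numeric(0), 0, 3)
    new("FirstPassageResult",
        tau = as.numeric(res$tau_steps) * dt,
        hitIndex = as.integer(res$hit),
        censored = as.logical(res$censored),
        config = list(D = D, dt = dt, stepSdNm = stepSd,
                      nucleusRadiusNm = R, targetRadiusNm = tr,
                      nTargets = nrow(centers), injection = injection,
                      releasingRadius = releasingRadius,
                      boundary = boundary, maxSteps = maxSteps, seed = seed),
        trajectory = traj)
}

#' Shell-release first-passage simulation
#'
#' Convenience wrapper for the re-release geometry: injection uniform on a
#' shell of radius `releasingRadius` about the target-cluster center.
#' tau3D shrinks as the release point approaches the cluster center (local
#' target concentration rises).
#'
#' @inheritParams simulateFirstPassage
#' @return a [FirstPassageResult-class].
#' @export
simulateRelease <- function(targets, releasingRadius, nTrials, D = 10,
                            dt = 1e-5, shellCenter = NULL, maxSteps = 1e7,
                            seed = NULL, ...) {
    simulateFirstPassage(targets, nTrials, D = D, dt = dt,
                         injection = "shell",
                         releasingRadius = releasingRadius,
                         shellCenter = shellCenter, maxSteps = maxSteps,
                         seed = seed, ...)
}

#' Fold of Delay between clustered and uniform target arrangements
#'
#' Ratio of the mean first-passage time under clustered targets to the
#' mean under matched uniform targets (same count, radius and nucleus);
#' values above 1 mean clustering slows the global search. A bootstrap
#' confidence interval over trials is attached. Censored trials are
#' excluded from the means (with a warning).
#'
#' @param clustered,uniform [FirstPassageResult-class] objects.
#' @param nBoot bootstrap resamples (0 skips the CI).
#' @param seed integer seed for the bootstrap.
#' @return list: `ratio`, `ci` (2.5/97.5 percentiles or NULL),
#'   `meanClustered`, `meanUniform`.
#' @export
foldOfDelay <- function(clustered, uniform, nBoot = 200, seed = NULL) {
    tc <- tau3d(clustered)[!isCensored(clustered)]
    tu <- tau3d(uniform)[!isCensored(uniform)]
    if (any(isCensored(clustered)) || any(isCensored(uniform)))
        warning("censored trials excluded from the fold-of-delay means")
    if (!length(tc) || !length(tu)) stop("no uncensored trials")
    ratio <- mean(tc) / mean(tu)
    ci <- NULL
    if (nBoot > 0) {
        bs <- withSeed(seed, vapply(seq_len(nBoot), function(i)
            mean(sample(tc, replace = TRUE)) /
            mean(sample(tu, replace = TRUE)), numeric(1)))
        ci <- unname(quantile(bs, c(0.025, 0.975)))
    }
    list(ratio = ratio, ci = ci, meanClustered = mean(tc),
         meanUniform = mean(tu))
}

#' Exponential decomposition of first-passage times
#'
#' Maximum-likelihood fit of tau3D samples to a single exponential
#' Density(tau) = exp(-tau/t)/t or a two-component mixture
#' F exp(-tau/t1)/t1 + (1-F) exp(-tau/t2)/t2 (EM). Strongly clustered
#' targets bifurcate the search into a fast local and a slow long-range
#' component, which the likelihood-ratio test against the single
#' exponential picks up.
#'
#' @param tau positive samples, s (a [FirstPassageResult-class] is also
#'   accepted; censored trials are dropped).
#' @param k 1 or 2 components.
#' @param maxIter EM iterations (k = 2).
#' @return object of class `ExpFit`: list with `k`, `t` (k = 1) or `t1`,
#'   `t2`, `F` (k = 2, t1 <= t2, F the fast fraction), `logLik`, `aic`,
#'   `collapsed` (TRUE when the two components degenerated to one).
#' @examples
#' x <- rexp(500, rate = 1 / 5)
#' fitExponential(x, k = 1)$t
#' @export
fitExponential <- function(tau, k = 1, maxIter = 500) {
    if (is(tau, "FirstPassageResult")) tau <- tau3d(tau)[!isCensored(tau)]
    tau <- tau[is.finite(tau) & tau > 0]
    n <- length(tau)
    if (n < 50) warning("fewer than 50 samples; lifetime estimates unstable")
    stopifnot(k %in% c(1, 2))
    if (k == 1) {
        t1 <- mean(tau)
        ll <- sum(dexp(tau, rate = 1 / t1, log = TRUE))
        out <- list(k = 1L, t = t1, logLik = ll, aic = 2 - 2 * ll)
        class(out) <- "ExpFit"
        return(out)
    }
    # EM for a two-component exponential mixture, moment-split start
    q <- quantile(tau, c(0.25, 0.9), names = FALSE)
    t1 <- max(q[1], 1e-12); t2 <- max(q[2], 2 * t1); F <- 0.5
    ll <- -Inf
    for (it in seq_len(maxIter)) {
        d1 <- F * dexp(tau, 1 / t1); d2 <- (1 - F) * dexp(tau, 1 / t2)
        tot <- d1 + d2
        tot[tot == 0] <- .Machine$double.xmin
        w <- d1 / tot
        F <- mean(w)
        t1 <- sum(w * tau) / max(sum(w), 1e-12)
        t2 <- sum((1 - w) * tau) / max(sum(1 - w), 1e-12)
        llNew <- sum(log(tot))
        if (is.finite(llNew) && llNew - ll < 1e-10 && it > 10) { ll <- llNew; break }
        ll <- llNew
    }
    if (t1 > t2) { tmp <- t1; t1 <- t2; t2 <- tmp; F <- 1 - F }
    collapsed <- (t2 - t1) / t2 < 1e-3 || F < 1e-4 || F > 1 - 1e-4
    if (collapsed) {
        t1 <- t2 <- mean(tau); F <- 1
        ll <- sum(dexp(tau, rate = 1 / t1, log = TRUE))
    }
    out <- list(k = 2L, t1 = t1, t2 = t2, F = F, logLik = ll,
                aic = 6 - 2 * ll, collapsed = collapsed)
    class(out) <- "ExpFit"
    out
}

#' @export
print.ExpFit <- function(x, ...) {
    if (x$k == 1) {
        cat(sprintf("ExpFit: single component, t = %.4g s (logLik %.1f)\n",
                    x$t, x$logLik))
    } else {
        cat(sprintf("ExpFit: two components, t1 = %.4g s (F = %.2f), t2 = %.4g s (logLik %.1f)%s\n",
                    x$t1, x$F, x$t2, x$logLik,
                    if (x$collapsed) " [collapsed to one]" else ""))
    }
    invisible(x)
}

#' Likelihood-ratio comparison of the exponential models
#'
#' @param tau positive samples (or a [FirstPassageResult-class]).
#' @return list: `fit1`, `fit2`, `stat` (2 * delta logLik), `pValue`
#'   (chi-square, 2 df), `twoComponentPreferred` at the 0.01 level.
#' @importFrom stats pchisq
#' @export
compareExponentialModels <- function(tau) {
    f1 <- fitExponential(tau, k = 1)
    f2 <- fitExponential(tau, k = 2)
    stat <- max(0, 2 * (f2$logLik - f1$logLik))
    p <- pchisq(stat, df = 2, lower.tail = FALSE)
    list(fit1 = f1, fit2 = f2, stat = stat, pValue = p,
         twoComponentPreferred = p < 0.01 && !f2$collapsed)
}

#' Smoluchowski diffusion-limited first-passage time
#'
#' Closed-form dilute-limit association: kon = 4 pi R D, the observed rate
#' kon* = kon rho for target density rho, and tau3D = 1 / (4 pi R D rho).
#' Doubling the density halves the search time.
#'
#' @param R target capture radius, nm.
#' @param D diffusion coefficient, um^2/s.
#' @param rho target number density, targets per um^3.
#' @return expected tau3D, s.
#' @examples
#' smoluchowskiTau(40, 10, 7000 / ((4 / 3) * pi * 5^3))
#' @export
smoluchowskiTau <- function(R, D, rho) {
    R <- checkPositive(R, "R"); D <- checkPositive(D, "D")
    rho <- checkPositive(rho, "rho")
    1 / (4 * pi * (R / 1000) * D * rho)
}

#' Round-trip validation of the Brownian propagator
#'
#' Generates tracks at an assigned diffusion coefficient and re-estimates
#' it through the MSD pipeline, repeating to assess bias and spread; the
#' discretised propagator and the estimator agree within sampling error.
#'
#' @param D assigned diffusion coefficient, um^2/s.
#' @param dt frame interval, s.
#' @param nTracks tracks per repeat (100 as in the full-scale check).
#' @param nFrames frames per track.
#' @param nRepeats independent repeats.
#' @param seed integer seed.
#' @return list: `perRepeat` (mean recovered D per repeat), `mean`, `sd`,
#'   `bias` (relative).
#' @export
validateBrownian <- function(D, dt, nTracks = 100, nFrames = 30,
                             nRepeats = 5, seed = NULL) {
    res <- withSeed(seed, vapply(seq_len(nRepeats), function(i) {
        ts <- genBrownianTracks(D, dt, nTracks, nFrames, seed = NULL)
        est <- estimateD(ts, r2Min = 0)
        mean(est$D)
    }, numeric(1)))
    list(perRepeat = res, mean = mean(res), sd = sd(res),
         bias = if (D > 0) (mean(res) - D) / D else mean(res))
}
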