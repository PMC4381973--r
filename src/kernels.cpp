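#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

// Cell-list spatial index over an axis-aligned bounding cube, used by the
// pair counter, the min-separation placer and the first-passage simulator.
// head/next linked lists; cell size must be >= the query radius so that the
// 27-cell neighbourhood is sufficient.
struct CellGrid {
    double lo[3];
    double cell;
    int ncell[3];
    std::vector<int> head;   // cell -> first point index (or -1)
    std::vector<int> next;   // point -> next point in same cell (or -1)
    const double* x;
    const double* y;
    const double* z;
    int n;

    void init(const double* xs, const double* ys, const double* zs, int npts,
              double lox, double loy, double loz, double extent, double cellSize) {
        x = xs; y = ys; z = zs; n = npts;
        lo[0] = lox; lo[1] = loy; lo[2] = loz;
        cell = cellSize;
        for (int k = 0; k < 3; ++k) {
            ncell[k] = std::max(1, (int)std::ceil(extent / cell));
        }
        head.assign((size_t)ncell[0] * ncell[1] * ncell[2], -1);
        next.assign(npts, -1);
    }
    inline int clampIdx(double v, int axis) const {
        int i = (int)std::floor((v - lo[axis]) / cell);
        if (i < 0) i = 0;
        if (i >= ncell[axis]) i = ncell[axis] - 1;
        return i;
    }
    inline int cellOf(double px, double py, double pz) const {
        return (clampIdx(px, 0) * ncell[1] + clampIdx(py, 1)) * ncell[2] + clampIdx(pz, 2);
    }
    inline void insert(int i) {
        int c = cellOf(x[i], y[i], z[i]);
        next[i] = head[c];
        head[c] = i;
    }
    // visit all stored points in the 27-cell neighbourhood of (px,py,pz)
    template <typename F>
    inline void forNeighbours(double px, double py, double pz, F fun) const {
        int ix = clampIdx(px, 0), iy = clampIdx(py, 1), iz = clampIdx(pz, 2);
        for (int dx = -1; dx <= 1; ++dx) {
            int jx = ix + dx; if (jx < 0 || jx >= ncell[0]) continue;
            for (int dy = -1; dy <= 1; ++dy) {
                int jy = iy + dy; if (jy < 0 || jy >= ncell[1]) continue;
                for (int dz = -1; dz <= 1; ++dz) {
                    int jz = iz + dz; if (jz < 0 || jz >= ncell[2]) continue;
                    int c = (jx * ncell[1] + jy) * ncell[2] + jz;
                    for (int i = head[c]; i != -1; i = next[i]) fun(i);
                }
            }
        }
    }
};

static inline double sq(double v) { return v * v; }

// Non-redundant pair counts histogrammed on `edges` (ascending, half-open
// [e_k, e_{k+1})). Distances beyond the last edge are ignored.
// [[Rcpp::export]]
IntegerVector cpp_pair_count(NumericMatrix coords, NumericVector edges) {
    const int n = coords.nrow();
    const int nb = edges.size() - 1;
    if (nb < 1) stop("need at least two bin edges");
    const double rmax = edges[nb];
    const double rmax2 = rmax * rmax;
    std::vector<double> xs(n), ys(n), zs(n);
    double lo[3] = {R_PosInf, R_PosInf, R_PosInf}, hi[3] = {R_NegInf, R_NegInf, R_NegInf};
    for (int i = 0; i < n; ++i) {
        xs[i] = coords(i, 0); ys[i] = coords(i, 1); zs[i] = coords(i, 2);
        double p[3] = {xs[i], ys[i], zs[i]};
        for (int k = 0; k < 3; ++k) { lo[k] = std::min(lo[k], p[k]); hi[k] = std::max(hi[k], p[k]); }
    }
    double extent = std::max({hi[0] - lo[0], hi[1] - lo[1], hi[2] - lo[2], rmax});
    CellGrid g;
    g.init(xs.data(), ys.data(), zs.data(), n, lo[0], lo[1], lo[2], extent, rmax);
    std::vector<long long> counts(nb, 0);
    const double* ev = edges.begin();
    for (int i = 0; i < n; ++i) {
        g.forNeighbours(xs[i], ys[i], zs[i], [&](int j) {
            // j < i: each unordered pair counted once
            double d2 = sq(xs[i] - xs[j]) + sq(ys[i] - ys[j]) + sq(zs[i] - zs[j]);
            if (d2 < rmax2) {
                double d = std::sqrt(d2);
                if (d >= ev[0]) {
                    int b = (int)(std::upper_bound(ev, ev + nb + 1, d) - ev) - 1;
                    if (b >= 0 && b < nb) counts[b]++;
                }
            }
        });
        g.insert(i);
    }
    IntegerVector out(nb);
    for (int b = 0; b < nb; ++b) out[b] = (int)counts[b];
    return out;
}

// TRUE if all pairwise distances >= minSep.
// [[Rcpp::export]]
bool cpp_min_sep_ok(NumericMatrix coords, double minSep) {
    const int n = coords.nrow();
    if (n < 2 || minSep <= 0) return true;
    std::vector<double> xs(n), ys(n), zs(n);
    double lo[3] = {R_PosInf, R_PosInf, R_PosInf}, hi[3] = {R_NegInf, R_NegInf, R_NegInf};
    for (int i = 0; i < n; ++i) {
        xs[i] = coords(i, 0); ys[i] = coords(i, 1); zs[i] = coords(i, 2);
        double p[3] = {xs[i], ys[i], zs[i]};
        for (int k = 0; k < 3; ++k) { lo[k] = std::min(lo[k], p[k]); hi[k] = std::max(hi[k], p[k]); }
    }
    double extent = std::max({hi[0] - lo[0], hi[1] - lo[1], hi[2] - lo[2], minSep});
    CellGrid g;
    g.init(xs.data(), ys.data(), zs.data(), n, lo[0], lo[1], lo[2], extent, minSep);
    const double ms2 = minSep * minSep;
    bool ok = true;
    for (int i = 0; i < n && ok; ++i) {
        g.forNeighbours(xs[i], ys[i], zs[i], [&](int j) {
            double d2 = sq(xs[i] - xs[j]) + sq(ys[i] - ys[j]) + sq(zs[i] - zs[j]);
            if (d2 < ms2) ok = false;
        });
        if (!ok) break;
        g.insert(i);
    }
    return ok;
}

static inline void runifSphere(double R, double* out) {
    // rejection from the bounding cube; uses the R RNG stream
    for (;;) {
        double px = (2.0 * unif_rand() - 1.0) * R;
        double py = (2.0 * unif_rand() - 1.0) * R;
        double pz = (2.0 * unif_rand() - 1.0) * R;
        if (px * px + py * py + pz * pz <= R * R) {
            out[0] = px; out[1] = py; out[2] = pz; return;
        }
    }
}

// n points uniform in a sphere of radius R (nm), all pairwise >= minSep.
// Fails after maxAttempts candidate draws.
// [[Rcpp::export]]
NumericMatrix cpp_place_uniform(int n, double R, double minSep, double maxAttempts) {
    if (n < 1) stop("n must be >= 1");
    NumericMatrix out(n, 3);
    std::vector<double> xs(n), ys(n), zs(n);
    CellGrid g;
    bool useGrid = (minSep > 0);
    if (useGrid) g.init(xs.data(), ys.data(), zs.data(), n, -R, -R, -R, 2.0 * R, minSep);
    const double ms2 = minSep * minSep;
    double attempts = 0;
    int placed = 0;
    double cand[3];
    while (placed < n) {
        if (++attempts > maxAttempts)
            stop("could not place %d points at min separation %g nm within the attempt budget (infeasible packing?)", n, minSep);
        runifSphere(R, cand);
        bool ok = true;
        if (useGrid) {
            g.forNeighbours(cand[0], cand[1], cand[2], [&](int j) {
                if (sq(cand[0] - xs[j]) + sq(cand[1] - ys[j]) + sq(cand[2] - zs[j]) < ms2) ok = false;
            });
        }
        if (ok) {
            xs[placed] = cand[0]; ys[placed] = cand[1]; zs[placed] = cand[2];
            if (useGrid) g.insert(placed);
            out(placed, 0) = cand[0]; out(placed, 1) = cand[1]; out(placed, 2) = cand[2];
            ++placed;
        }
    }
    return out;
}

// Gaussian members around given cluster centers, inside the sphere, pairwise
// >= minSep (globally, across clusters). nPer[i] members for center i.
// [[Rcpp::export]]
NumericMatrix cpp_place_clustered(NumericMatrix centers, IntegerVector nPer,
                                  double sigma, double R, double minSep,
                                  double maxAttempts) {
    const int nc = centers.nrow();
    int n = 0;
    for (int i = 0; i < nc; ++i) n += nPer[i];
    NumericMatrix out(n, 3);
    std::vector<double> xs(n), ys(n), zs(n);
    CellGrid g;
    bool useGrid = (minSep > 0);
    if (useGrid) g.init(xs.data(), ys.data(), zs.data(), n, -R, -R, -R, 2.0 * R, minSep);
    const double ms2 = minSep * minSep;
    double attempts = 0;
    int placed = 0;
    for (int c = 0; c < nc; ++c) {
        for (int m = 0; m < nPer[c]; ++m) {
            for (;;) {
                if (++attempts > maxAttempts)
                    stop("could not place clustered points at min separation %g nm within the attempt budget (infeasible packing?)", minSep);
                double cand[3] = {centers(c, 0) + sigma * norm_rand(),
                                  centers(c, 1) + sigma * norm_rand(),
                                  centers(c, 2) + sigma * norm_rand()};
                if (cand[0] * cand[0] + cand[1] * cand[1] + cand[2] * cand[2] > R * R) continue;
                bool ok = true;
                if (useGrid) {
                    g.forNeighbours(cand[0], cand[1], cand[2], [&](int j) {
                        if (sq(cand[0] - xs[j]) + sq(cand[1] - ys[j]) + sq(cand[2] - zs[j]) < ms2) ok = false;
                    });
                }
                if (ok) {
                    xs[placed] = cand[0]; ys[placed] = cand[1]; zs[placed] = cand[2];
                    if (useGrid) g.insert(placed);
                    out(placed, 0) = cand[0]; out(placed, 1) = cand[1]; out(placed, 2) = cand[2];
                    ++placed;
                    break;
                }
            }
        }
    }
    return out;
}

// Per-point count of other points within `radius` (canopy neighbour count).
// [[Rcpp::export]]
IntegerVector cpp_neighbor_count(NumericMatrix coords, double radius) {
    const int n = coords.nrow();
    IntegerVector out(n);
    if (n < 2 || radius <= 0) return out;
    std::vector<double> xs(n), ys(n), zs(n);
    double lo[3] = {R_PosInf, R_PosInf, R_PosInf}, hi[3] = {R_NegInf, R_NegInf, R_NegInf};
    for (int i = 0; i < n; ++i) {
        xs[i] = coords(i, 0); ys[i] = coords(i, 1); zs[i] = coords(i, 2);
        double p[3] = {xs[i], ys[i], zs[i]};
        for (int k = 0; k < 3; ++k) { lo[k] = std::min(lo[k], p[k]); hi[k] = std::max(hi[k], p[k]); }
    }
    double extent = std::max({hi[0] - lo[0], hi[1] - lo[1], hi[2] - lo[2], radius});
    CellGrid g;
    g.init(xs.data(), ys.data(), zs.data(), n, lo[0], lo[1], lo[2], extent, radius);
    const double r2 = radius * radius;
    for (int i = 0; i < n; ++i) {
        g.forNeighbours(xs[i], ys[i], zs[i], [&](int j) {
            double d2 = sq(xs[i] - xs[j]) + sq(ys[i] - ys[j]) + sq(zs[i] - zs[j]);
            if (d2 <= r2) { out[i]++; out[j]++; }
        });
        g.insert(i);
    }
    return out;
}

// TRUE for query points lying inside (or on) any target sphere.
// [[Rcpp::export]]
LogicalVector cpp_points_in_targets(NumericMatrix targets, double targetRadius,
                                    NumericMatrix pts) {
    const int nt = targets.nrow();
    const int np = pts.nrow();
    LogicalVector out(np);
    if (nt == 0) return out;
    std::vector<double> tx(nt), ty(nt), tz(nt);
    double lo[3] = {R_PosInf, R_PosInf, R_PosInf}, hi[3] = {R_NegInf, R_NegInf, R_NegInf};
    for (int i = 0; i < nt; ++i) {
        tx[i] = targets(i, 0); ty[i] = targets(i, 1); tz[i] = targets(i, 2);
        double p[3] = {tx[i], ty[i], tz[i]};
        for (int k = 0; k < 3; ++k) { lo[k] = std::min(lo[k], p[k]); hi[k] = std::max(hi[k], p[k]); }
    }
    double extent = std::max({hi[0] - lo[0], hi[1] - lo[1], hi[2] - lo[2], targetRadius});
    CellGrid g;
    g.init(tx.data(), ty.data(), tz.data(), nt, lo[0], lo[1], lo[2], extent, targetRadius);
    for (int i = 0; i < nt; ++i) g.insert(i);
    const double r2 = targetRadius * targetRadius;
    for (int p = 0; p < np; ++p) {
        bool inside = false;
        g.forNeighbours(pts(p, 0), pts(p, 1), pts(p, 2), [&](int i) {
            if (!inside &&
                sq(pts(p, 0) - tx[i]) + sq(pts(p, 1) - ty[i]) + sq(pts(p, 2) - tz[i]) <= r2)
                inside = true;
        });
        out[p] = inside;
    }
    return out;
}

// First-passage Brownian simulation with absorbing spherical targets in a
// reflecting spherical nucleus. One RNG draw pattern per step regardless of
// the neighbour-lookup mode, so grid and brute-force runs are trajectory-
// identical under the same seed. Lengths in nm; tau returned in steps.
// boundary: 0 = radial reflection, 1 = resample the step until inside.
// [[Rcpp::export]]
List cpp_first_passage(NumericMatrix targets, double targetRadius,
                       NumericMatrix starts, double stepSd, double R,
                       double maxSteps, bool bruteForce, int boundary,
                       bool keepFirstTrajectory) {
    const int nt = targets.nrow();
    const int ntrial = starts.nrow();
    std::vector<double> tx(nt), ty(nt), tz(nt);
    for (int i = 0; i < nt; ++i) { tx[i] = targets(i, 0); ty[i] = targets(i, 1); tz[i] = targets(i, 2); }
    CellGrid g;
    double cellSize = std::max(targetRadius, 2.0 * R / 128.0);
    g.init(tx.data(), ty.data(), tz.data(), nt, -R, -R, -R, 2.0 * R, cellSize);
    for (int i = 0; i < nt; ++i) g.insert(i);
    const double tr2 = targetRadius * targetRadius;

    NumericVector tauSteps(ntrial);
    IntegerVector hit(ntrial);
    LogicalVector censored(ntrial);
    std::vector<double> trajx, trajy, trajz;

    for (int t = 0; t < ntrial; ++t) {
        double px = starts(t, 0), py = starts(t, 1), pz = starts(t, 2);
        double steps = 0;
        int hitIdx = -1;
        bool keep = keepFirstTrajectory && t == 0;
        if (keep) { trajx.push_back(px); trajy.push_back(py); trajz.push_back(pz); }
        while (steps < maxSteps) {
            double nx, ny, nz;
            for (;;) {
                nx = px + stepSd * norm_rand();
                ny = py + stepSd * norm_rand();
                nz = pz + stepSd * norm_rand();
                double r = std::sqrt(nx * nx + ny * ny + nz * nz);
                if (r <= R) break;
                if (boundary == 0) {
                    double f = (2.0 * R - r) / r;   // fold the radial overshoot back inside
                    if (f <= 0) continue;            // pathological giant step: redraw
                    nx *= f; ny *= f; nz *= f;
                    break;
                }
                // boundary == 1: redraw the whole step
            }
            px = nx; py = ny; pz = nz;
            steps += 1;
            if (keep) { trajx.push_back(px); trajy.push_back(py); trajz.push_back(pz); }
            if (bruteForce) {
                for (int i = 0; i < nt; ++i) {
                    if (sq(px - tx[i]) + sq(py - ty[i]) + sq(pz - tz[i]) <= tr2) { hitIdx = i; break; }
                }
            } else {
                g.forNeighbours(px, py, pz, [&](int i) {
                    if (hitIdx == -1 &&
                        sq(px - tx[i]) + sq(py - ty[i]) + sq(pz - tz[i]) <= tr2) hitIdx = i;
                });
            }
            if (hitIdx != -1) break;
            if (((long long)steps) % 262144 == 0) Rcpp::checkUserInterrupt();
        }
        tauSteps[t] = steps;
        hit[t] = hitIdx + 1;          // 1-based, 0 = censored
        censored[t] = (hitIdx == -1);
    }
    List out = List::create(_["tau_steps"] = tauSteps, _["hit"] = hit,
                            _["censored"] = censored);
    if (keepFirstTrajectory) {
        int m = trajx.size();
        NumericMatrix tr(m, 3);
        for (int i = 0; i < m; ++i) { tr(i, 0) = trajx[i]; tr(i, 1) = trajy[i]; tr(i, 2) = trajz[i]; }
        out["trajectory"] = tr;
    }
    return out;
}
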