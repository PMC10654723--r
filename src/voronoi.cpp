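// 3D Voronoi facet adjacency by direct bisector-plane clipping, plus the
// label-shuffle loop for the permutation null.
//
// The Voronoi facet between cells i and j is the part of their bisector
// plane closer to i (and j) than to every other cell, intersected with the
// clipping box. It is computed as a 2D polygon in the bisector plane,
// clipped (Sutherland-Hodgman) by the half-planes induced by the box faces
// and by the bisectors with the other cells. Cells i and j share a facet
// iff the resulting polygon area exceeds a tolerance.

#include <Rcpp.h>
#include <array>
#include <vector>
#include <cmath>
#include <utility>
#include <algorithm>

using namespace Rcpp;

struct P2 { double x, y; };

// Clip convex polygon by half-plane a*x + b*y <= c.
static void clip_halfplane(std::vector<P2> &poly, double a, double b,
                           double c) {
    if (poly.empty()) return;
    std::vector<P2> out;
    out.reserve(poly.size() + 2);
    const size_t n = poly.size();
    for (size_t k = 0; k < n; ++k) {
        const P2 &p = poly[k];
        const P2 &q = poly[(k + 1) % n];
        double fp = a * p.x + b * p.y - c;
        double fq = a * q.x + b * q.y - c;
        bool pin = fp <= 0.0, qin = fq <= 0.0;
        if (pin) out.push_back(p);
        if (pin != qin) {
            double t = fp / (fp - fq);
            out.push_back({p.x + t * (q.x - p.x), p.y + t * (q.y - p.y)});
        }
    }
    poly.swap(out);
}

static double poly_area(const std::vector<P2> &poly) {
    if (poly.size() < 3) return 0.0;
    double s = 0.0;
    for (size_t k = 0; k < poly.size(); ++k) {
        const P2 &p = poly[k];
        const P2 &q = poly[(k + 1) % poly.size()];
        s += p.x * q.y - q.x * p.y;
    }
    return 0.5 * std::fabs(s);
}

// Orthonormal basis (e1, e2) of the plane with unit normal u.
static void plane_basis(const double *u, double *e1, double *e2) {
    // pick the axis least aligned with u
    int ax = 0;
    double amin = std::fabs(u[0]);
    if (std::fabs(u[1]) < amin) { amin = std::fabs(u[1]); ax = 1; }
    if (std::fabs(u[2]) < amin) { ax = 2; }
    double v[3] = {0, 0, 0};
    v[ax] = 1.0;
    // e1 = normalize(v - (v.u) u)
    double d = v[0] * u[0] + v[1] * u[1] + v[2] * u[2];
    for (int k = 0; k < 3; ++k) e1[k] = v[k] - d * u[k];
    double n1 = std::sqrt(e1[0] * e1[0] + e1[1] * e1[1] + e1[2] * e1[2]);
    for (int k = 0; k < 3; ++k) e1[k] /= n1;
    // e2 = u x e1
    e2[0] = u[1] * e1[2] - u[2] * e1[1];
    e2[1] = u[2] * e1[0] - u[0] * e1[2];
    e2[2] = u[0] * e1[1] - u[1] * e1[0];
}

// Area of the region of the plane (origin m, basis e1/e2) satisfying all
// constraints a.x <= b (3D half-spaces), starting from a centred square of
// half-width H.
static double clipped_plane_area(const double *m, const double *e1,
        const double *e2, const std::vector<std::array<double, 4>> &cons,
        double H, double tol) {
    std::vector<P2> poly = {{-H, -H}, {H, -H}, {H, H}, {-H, H}};
    for (const auto &cn : cons) {
        const double *a = cn.data();
        double b = cn[3];
        double a1 = a[0] * e1[0] + a[1] * e1[1] + a[2] * e1[2];
        double a2 = a[0] * e2[0] + a[1] * e2[1] + a[2] * e2[2];
        double c = b - (a[0] * m[0] + a[1] * m[1] + a[2] * m[2]);
        clip_halfplane(poly, a1, a2, c);
        if (poly.size() < 3) return 0.0;
        if (poly_area(poly) <= tol) return poly_area(poly);
    }
    return poly_area(poly);
}

// Bisector half-space "closer to p than to q": a.x <= b with
// a = q - p, b = (|q|^2 - |p|^2)/2.
static std::array<double, 4> bisector(const double *p, const double *q) {
    std::array<double, 4> c;
    double b = 0.0;
    for (int k = 0; k < 3; ++k) {
        c[k] = q[k] - p[k];
        b += 0.5 * (q[k] * q[k] - p[k] * p[k]);
    }
    c[3] = b;
    return c;
}

// [[Rcpp::export]]
List cpp_voronoi_adjacency(NumericMatrix pts, NumericVector lo,
        NumericVector hi, List cand, double facet_tol) {
    const int n = pts.nrow();
    std::vector<std::array<double, 3>> P(n);
    for (int i = 0; i < n; ++i)
        for (int k = 0; k < 3; ++k) P[i][k] = pts(i, k);

    double diag = 0.0, ctr[3];
    for (int k = 0; k < 3; ++k) {
        diag += (hi[k] - lo[k]) * (hi[k] - lo[k]);
        ctr[k] = 0.5 * (lo[k] + hi[k]);
    }
    diag = std::sqrt(diag);

    // box half-spaces: x_k >= lo_k  ->  -x_k <= -lo_k ; x_k <= hi_k
    std::vector<std::array<double, 4>> boxcons;
    for (int k = 0; k < 3; ++k) {
        std::array<double, 4> c1 = {0, 0, 0, 0}, c2 = {0, 0, 0, 0};
        c1[k] = -1.0; c1[3] = -lo[k];
        c2[k] = 1.0;  c2[3] = hi[k];
        boxcons.push_back(c1);
        boxcons.push_back(c2);
    }

    // candidate pairs (i < j)
    std::vector<std::pair<int, int>> pairs;
    std::vector<std::vector<int>> candv(n);
    for (int i = 0; i < n; ++i) {
        IntegerVector ci = cand[i];
        candv[i].assign(ci.begin(), ci.end());
        for (int j : candv[i])
            if (j > i) pairs.push_back({i, j});
            else if (j < i) pairs.push_back({j, i});
    }
    std::sort(pairs.begin(), pairs.end());
    pairs.erase(std::unique(pairs.begin(), pairs.end()), pairs.end());

    std::vector<int> ei, ej;
    std::vector<double> areas;
    std::vector<bool> boundary(n, false);

    for (const auto &pr : pairs) {
        int i = pr.first, j = pr.second;
        double m[3], u[3], nn = 0.0;
        for (int k = 0; k < 3; ++k) {
            m[k] = 0.5 * (P[i][k] + P[j][k]);
            u[k] = P[j][k] - P[i][k];
            nn += u[k] * u[k];
        }
        nn = std::sqrt(nn);
        if (nn <= 0.0) continue; // coincident points: no bisector
        for (int k = 0; k < 3; ++k) u[k] /= nn;
        double e1[3], e2[3];
        plane_basis(u, e1, e2);

        // constraints: box + bisectors with union of candidates of i and j
        std::vector<std::array<double, 4>> cons = boxcons;
        std::vector<int> ks = candv[i];
        ks.insert(ks.end(), candv[j].begin(), candv[j].end());
        std::sort(ks.begin(), ks.end());
        ks.erase(std::unique(ks.begin(), ks.end()), ks.end());
        for (int k : ks)
            if (k != i && k != j)
                cons.push_back(bisector(P[i].data(), P[k].data()));

        double off = 0.0;
        for (int k = 0; k < 3; ++k)
            off += (m[k] - ctr[k]) * (m[k] - ctr[k]);
        double H = 2.0 * (diag + std::sqrt(off)) + 1.0;
        double area = clipped_plane_area(m, e1, e2, cons, H, facet_tol);
        if (area > facet_tol) {
            ei.push_back(i + 1);
            ej.push_back(j + 1);
            areas.push_back(area);
        }
    }

    // boundary flag: does cell i's region reach a box face?
    for (int i = 0; i < n; ++i) {
        for (int f = 0; f < 6 && !boundary[i]; ++f) {
            int ax = f / 2;
            bool upper = f % 2;
            double m[3] = {ctr[0], ctr[1], ctr[2]};
            m[ax] = upper ? hi[ax] : lo[ax];
            double u[3] = {0, 0, 0};
            u[ax] = 1.0;
            double e1[3], e2[3];
            plane_basis(u, e1, e2);
            std::vector<std::array<double, 4>> cons;
            for (int k = 0; k < 3; ++k) {
                if (k == ax) continue;
                std::array<double, 4> c1 = {0, 0, 0, 0}, c2 = {0, 0, 0, 0};
                c1[k] = -1.0; c1[3] = -lo[k];
                c2[k] = 1.0;  c2[3] = hi[k];
                cons.push_back(c1);
                cons.push_back(c2);
            }
            for (int k : candv[i])
                if (k != i)
                    cons.push_back(bisector(P[i].data(), P[k].data()));
            double H = 2.0 * diag + 1.0;
            if (clipped_plane_area(m, e1, e2, cons, H, facet_tol) >
                facet_tol)
                boundary[i] = true;
        }
    }

    return List::create(
        Named("i") = wrap(ei), Named("j") = wrap(ej),
        Named("area") = wrap(areas), Named("boundary") = wrap(boundary));
}

// Permutation null for nearest-neighbor identity composition.
// nn: 1-based nearest-neighbor index per cell; labs: 1-based label codes;
// query: 1-based label code of the query class, or 0 for "all cells"
// (self = own label). Returns per-shuffle self percentage and per-shuffle
// neighbor-label composition percentages (n_shuffles x n_levels).
// [[Rcpp::export]]
List cpp_shuffle_null(IntegerVector nn, IntegerVector labs, int query,
        int n_levels, int n_shuffles) {
    const int n = labs.size();
    std::vector<int> perm(labs.begin(), labs.end());
    NumericVector selfpct(n_shuffles);
    NumericMatrix comp(n_shuffles, n_levels);
    std::vector<double> cnt(n_levels);

    for (int s = 0; s < n_shuffles; ++s) {
        // Fisher-Yates using R's RNG
        for (int i = n - 1; i > 0; --i) {
            int j = (int)(unif_rand() * (i + 1));
            if (j > i) j = i;
            std::swap(perm[i], perm[j]);
        }
        std::fill(cnt.begin(), cnt.end(), 0.0);
        int nq = 0, nself = 0;
        for (int i = 0; i < n; ++i) {
            int qlab = (query == 0) ? perm[i] : query;
            if (perm[i] != qlab) continue;
            ++nq;
            int nb = perm[nn[i] - 1];
            cnt[nb - 1] += 1.0;
            if (nb == qlab) ++nself;
        }
        if (nq > 0) {
            selfpct[s] = 100.0 * nself / nq;
            for (int l = 0; l < n_levels; ++l)
                comp(s, l) = 100.0 * cnt[l] / nq;
        } else {
            selfpct[s] = NA_REAL;
            for (int l = 0; l < n_levels; ++l) comp(s, l) = NA_REAL;
        }
    }
    return List::create(Named("self") = selfpct, Named("comp") = comp);
}
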