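#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
#include <queue>
using namespace Rcpp;

// The 13 unique lattice directions (one of each antipodal pair of the
// 26-neighbourhood); texture statistics are accumulated symmetrically.
static const int DIRS[13][3] = {
    {1, 0, 0}, {0, 1, 0}, {0, 0, 1},
    {1, 1, 0}, {1, -1, 0}, {1, 0, 1}, {1, 0, -1}, {0, 1, 1}, {0, 1, -1},
    {1, 1, 1}, {1, 1, -1}, {1, -1, 1}, {1, -1, -1}};

static inline R_xlen_t lin(int x, int y, int z, int nx, int ny) {
    return (R_xlen_t)x + (R_xlen_t)nx * ((R_xlen_t)y + (R_xlen_t)ny * (R_xlen_t)z);
}

// Linear-interpolated order statistic on a sorted vector, R type-7 convention.
static double quantile7(const std::vector<double> &sorted, double p) {
    const size_t m = sorted.size();
    if (m == 1) return sorted[0];
    double h = p * (double)(m - 1);
    size_t lo = (size_t)std::floor(h);
    size_t hi = lo + 1 < m ? lo + 1 : lo;
    double w = h - (double)lo;
    return sorted[lo] * (1.0 - w) + sorted[hi] * w;
}

struct GlcmFeat {
    double contrast, correlation, energy, homogeneity, entropy;
};

// Five co-occurrence statistics from a (dense) symmetric count matrix.
static GlcmFeat glcm_features(const std::vector<double> &counts, int L) {
    GlcmFeat f = {0, 0, 0, 0, 0};
    double tot = 0;
    for (int i = 0; i < L * L; ++i) tot += counts[i];
    if (tot <= 0) return f;
    std::vector<double> px(L, 0.0);
    double mu = 0;
    for (int i = 0; i < L; ++i)
        for (int j = 0; j < L; ++j) {
            double p = counts[i + L * j] / tot;
            if (p <= 0) continue;
            f.contrast += p * (i - j) * (i - j);
            f.energy += p * p;
            f.homogeneity += p / (1.0 + std::abs(i - j));
            f.entropy -= p * std::log2(p);
            px[i] += p;
        }
    for (int i = 0; i < L; ++i) mu += px[i] * i;
    double var = 0;
    for (int i = 0; i < L; ++i) var += px[i] * (i - mu) * (i - mu);
    if (var > 0) {
        double acc = 0;
        for (int i = 0; i < L; ++i)
            for (int j = 0; j < L; ++j) {
                double p = counts[i + L * j] / tot;
                if (p > 0) acc += p * (i - mu) * (j - mu);
            }
        f.correlation = acc / var;  // symmetric matrix: sigma_x == sigma_y
    }
    return f;
}

// Per-voxel local feature map: 13 first-order + 5 co-occurrence statistics
// over a window clipped to the mask.  `codes` holds 0-based quantized gray
// levels (VOI-wide equal-width bins); raw `values` feed the first-order
// moments.  Returns an n_voxel x 18 matrix in mask-scan order plus the raw
// center-voxel intensity (used later to order habitat labels).
// [[Rcpp::export]]
List cpp_voxel_feature_map(NumericVector values, IntegerVector codes,
                           LogicalVector mask, IntegerVector dims,
                           IntegerVector half, int nlevels) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const int hx = half[0], hy = half[1], hz = half[2];
    std::vector<int> vx, vy, vz;
    for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
            for (int x = 0; x < nx; ++x)
                if (mask[lin(x, y, z, nx, ny)]) {
                    vx.push_back(x); vy.push_back(y); vz.push_back(z);
                }
    const int n = (int)vx.size();
    NumericMatrix feat(n, 18);
    NumericVector intensity(n);
    IntegerMatrix coords(n, 3);
    std::vector<double> counts((size_t)nlevels * nlevels);
    std::vector<double> nb;        // raw neighbourhood values
    std::vector<int> nbx, nby, nbz;
    std::vector<double> hist(nlevels);

    for (int v = 0; v < n; ++v) {
        const int cx = vx[v], cy = vy[v], cz = vz[v];
        coords(v, 0) = cx + 1; coords(v, 1) = cy + 1; coords(v, 2) = cz + 1;
        intensity[v] = values[lin(cx, cy, cz, nx, ny)];
        nb.clear(); nbx.clear(); nby.clear(); nbz.clear();
        std::fill(hist.begin(), hist.end(), 0.0);
        const int x0 = std::max(0, cx - hx), x1 = std::min(nx - 1, cx + hx);
        const int y0 = std::max(0, cy - hy), y1 = std::min(ny - 1, cy + hy);
        const int z0 = std::max(0, cz - hz), z1 = std::min(nz - 1, cz + hz);
        for (int z = z0; z <= z1; ++z)
            for (int y = y0; y <= y1; ++y)
                for (int x = x0; x <= x1; ++x) {
                    R_xlen_t id = lin(x, y, z, nx, ny);
                    if (!mask[id]) continue;
                    nb.push_back(values[id]);
                    nbx.push_back(x); nby.push_back(y); nbz.push_back(z);
                    hist[codes[id]] += 1.0;
                }
        const int m = (int)nb.size();
        double s = 0, s2 = 0;
        double mn = nb[0], mx = nb[0];
        for (int i = 0; i < m; ++i) {
            s += nb[i]; s2 += nb[i] * nb[i];
            if (nb[i] < mn) mn = nb[i];
            if (nb[i] > mx) mx = nb[i];
        }
        const double mean = s / m;
        double m2 = 0, m3 = 0, m4 = 0;
        for (int i = 0; i < m; ++i) {
            double d = nb[i] - mean;
            m2 += d * d; m3 += d * d * d; m4 += d * d * d * d;
        }
        m2 /= m; m3 /= m; m4 /= m;           // population moments
        const double sd = std::sqrt(m2);
        std::vector<double> sorted(nb);
        std::sort(sorted.begin(), sorted.end());
        const double median = quantile7(sorted, 0.5);
        const double p10 = quantile7(sorted, 0.10);
        const double p90 = quantile7(sorted, 0.90);
        // robust MAD: mean absolute deviation inside [P10, P90]
        double rsum = 0; int rn = 0;
        for (int i = 0; i < m; ++i)
            if (nb[i] >= p10 && nb[i] <= p90) { rsum += nb[i]; ++rn; }
        double rmad = 0;
        if (rn > 0) {
            double rmean = rsum / rn, acc = 0;
            for (int i = 0; i < m; ++i)
                if (nb[i] >= p10 && nb[i] <= p90) acc += std::abs(nb[i] - rmean);
            rmad = acc / rn;
        }
        double entropy = 0, uniformity = 0;
        for (int l = 0; l < nlevels; ++l)
            if (hist[l] > 0) {
                double p = hist[l] / m;
                entropy -= p * std::log2(p);
                uniformity += p * p;
            }
        // neighbourhood co-occurrence (13 directions, symmetric, pooled)
        std::fill(counts.begin(), counts.end(), 0.0);
        for (int i = 0; i < m; ++i) {
            const int px = nbx[i], py = nby[i], pz = nbz[i];
            const int ci = codes[lin(px, py, pz, nx, ny)];
            for (int d = 0; d < 13; ++d) {
                const int qx = px + DIRS[d][0], qy = py + DIRS[d][1],
                          qz = pz + DIRS[d][2];
                if (qx < x0 || qx > x1 || qy < y0 || qy > y1 || qz < z0 || qz > z1)
                    continue;
                R_xlen_t qid = lin(qx, qy, qz, nx, ny);
                if (!mask[qid]) continue;
                const int cj = codes[qid];
                counts[ci + nlevels * cj] += 1.0;
                counts[cj + nlevels * ci] += 1.0;
            }
        }
        GlcmFeat g = glcm_features(counts, nlevels);
        feat(v, 0) = mean;        feat(v, 1) = median;
        feat(v, 2) = sd;          feat(v, 3) = m2;
        feat(v, 4) = sd > 0 ? m3 / (sd * sd * sd) : 0.0;
        feat(v, 5) = m2 > 0 ? m4 / (m2 * m2) - 3.0 : 0.0;
        feat(v, 6) = s2;          feat(v, 7) = entropy;
        feat(v, 8) = uniformity;  feat(v, 9) = mn;
        feat(v, 10) = mx;         feat(v, 11) = mx - mn;
        feat(v, 12) = rmad;
        feat(v, 13) = g.contrast; feat(v, 14) = g.correlation;
        feat(v, 15) = g.energy;   feat(v, 16) = g.homogeneity;
        feat(v, 17) = g.entropy;
    }
    return List::create(_["features"] = feat, _["intensity"] = intensity,
                        _["coords"] = coords);
}

// Region-level symmetric co-occurrence count matrix over the whole VOI
// (13 directions, both orientations), distance 1 voxel.
// [[Rcpp::export]]
NumericMatrix cpp_region_glcm(IntegerVector codes, LogicalVector mask,
                              IntegerVector dims, int nlevels) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    NumericMatrix counts(nlevels, nlevels);
    for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
            for (int x = 0; x < nx; ++x) {
                R_xlen_t id = lin(x, y, z, nx, ny);
                if (!mask[id]) continue;
                const int ci = codes[id];
                for (int d = 0; d < 13; ++d) {
                    const int qx = x + DIRS[d][0], qy = y + DIRS[d][1],
                              qz = z + DIRS[d][2];
                    if (qx < 0 || qx >= nx || qy < 0 || qy >= ny || qz < 0 ||
                        qz >= nz)
                        continue;
                    R_xlen_t qid = lin(qx, qy, qz, nx, ny);
                    if (!mask[qid]) continue;
                    const int cj = codes[qid];
                    counts(ci, cj) += 1.0;
                    counts(cj, ci) += 1.0;
                }
            }
    return counts;
}

// Gray-level run-length counts pooled over the 13 directions.
// Row = gray level (1-based), column = run length.
// [[Rcpp::export]]
NumericMatrix cpp_region_glrlm(IntegerVector codes, LogicalVector mask,
                               IntegerVector dims, int nlevels) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const int maxlen = nx + ny + nz;
    NumericMatrix counts(nlevels, maxlen);
    for (int d = 0; d < 13; ++d) {
        const int dx = DIRS[d][0], dy = DIRS[d][1], dz = DIRS[d][2];
        for (int z = 0; z < nz; ++z)
            for (int y = 0; y < ny; ++y)
                for (int x = 0; x < nx; ++x) {
                    R_xlen_t id = lin(x, y, z, nx, ny);
                    if (!mask[id]) continue;
                    const int c = codes[id];
                    // run starts where the predecessor breaks the run
                    const int px = x - dx, py = y - dy, pz = z - dz;
                    bool starts = true;
                    if (px >= 0 && px < nx && py >= 0 && py < ny && pz >= 0 &&
                        pz < nz) {
                        R_xlen_t pid = lin(px, py, pz, nx, ny);
                        if (mask[pid] && codes[pid] == c) starts = false;
                    }
                    if (!starts) continue;
                    int len = 1;
                    int qx = x + dx, qy = y + dy, qz = z + dz;
                    while (qx >= 0 && qx < nx && qy >= 0 && qy < ny && qz >= 0 &&
                           qz < nz) {
                        R_xlen_t qid = lin(qx, qy, qz, nx, ny);
                        if (!mask[qid] || codes[qid] != c) break;
                        ++len; qx += dx; qy += dy; qz += dz;
                    }
                    counts(c, std::min(len, maxlen) - 1) += 1.0;
                }
    }
    return counts;
}

// Size-zone decomposition: 26-connected components of equal gray level.
// Returns a two-column matrix (gray level 1-based, zone size).
// [[Rcpp::export]]
IntegerMatrix cpp_region_glszm(IntegerVector codes, LogicalVector mask,
                               IntegerVector dims) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    std::vector<char> seen((size_t)nx * ny * nz, 0);
    std::vector<int> lev, siz;
    std::queue<std::array<int, 3> > q;
    for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
            for (int x = 0; x < nx; ++x) {
                R_xlen_t id = lin(x, y, z, nx, ny);
                if (!mask[id] || seen[id]) continue;
                const int c = codes[id];
                int size = 0;
                seen[id] = 1;
                q.push({{x, y, z}});
                while (!q.empty()) {
                    std::array<int, 3> p = q.front(); q.pop();
                    ++size;
                    for (int dz = -1; dz <= 1; ++dz)
                        for (int dy = -1; dy <= 1; ++dy)
                            for (int dx = -1; dx <= 1; ++dx) {
                                if (!dx && !dy && !dz) continue;
                                const int ax = p[0] + dx, ay = p[1] + dy,
                                          az = p[2] + dz;
                                if (ax < 0 || ax >= nx || ay < 0 || ay >= ny ||
                                    az < 0 || az >= nz)
                                    continue;
                                R_xlen_t aid = lin(ax, ay, az, nx, ny);
                                if (!mask[aid] || seen[aid] || codes[aid] != c)
                                    continue;
                                seen[aid] = 1;
                                q.push({{ax, ay, az}});
                            }
                }
                lev.push_back(c);
                siz.push_back(size);
            }
    IntegerMatrix out((int)lev.size(), 2);
    for (int i = 0; i < (int)lev.size(); ++i) {
        out(i, 0) = lev[i]; out(i, 1) = siz[i];
    }
    return out;
}

// Physical (mm) Euclidean distance from every voxel to the nearest target
// voxel, computed exactly up to `cap`; beyond the cap the value is +Inf.
// Brute-force window scan: adequate for the small caps used by ring
// dilation and boundary perturbation.
// [[Rcpp::export]]
NumericVector cpp_capped_distance(LogicalVector target, IntegerVector dims,
                                  NumericVector spacing, double cap) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
    const int rx = (int)std::floor(cap / sx), ry = (int)std::floor(cap / sy),
              rz = (int)std::floor(cap / sz);
    struct Off { int dx, dy, dz; double d; };
    std::vector<Off> offs;
    for (int dz = -rz; dz <= rz; ++dz)
        for (int dy = -ry; dy <= ry; ++dy)
            for (int dx = -rx; dx <= rx; ++dx) {
                double d = std::sqrt(dx * sx * dx * sx + dy * sy * dy * sy +
                                     dz * sz * dz * sz);
                if (d <= cap) offs.push_back({dx, dy, dz, d});
            }
    std::sort(offs.begin(), offs.end(),
              [](const Off &a, const Off &b) { return a.d < b.d; });
    NumericVector out((R_xlen_t)nx * ny * nz, R_PosInf);
    for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
            for (int x = 0; x < nx; ++x) {
                R_xlen_t id = lin(x, y, z, nx, ny);
                if (target[id]) { out[id] = 0.0; continue; }
                for (size_t k = 0; k < offs.size(); ++k) {
                    const int qx = x + offs[k].dx, qy = y + offs[k].dy,
                              qz = z + offs[k].dz;
                    if (qx < 0 || qx >= nx || qy < 0 || qy >= ny || qz < 0 ||
                        qz >= nz)
                        continue;
                    if (target[lin(qx, qy, qz, nx, ny)]) {
                        out[id] = offs[k].d;
                        break;
                    }
                }
            }
    return out;
}
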