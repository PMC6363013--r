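#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline int idx3(int x, int y, int z, int nx, int ny) {
    return x + nx * (y + ny * z);
}

// Merged 3D co-occurrence counts: 13 unique unit offsets, both orderings,
// pairs counted only when both voxels lie inside the mask.
// [[Rcpp::export]]
NumericMatrix cpp_glcm(IntegerVector levels, LogicalVector mask,
                       IntegerVector dim, int Q) {
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    static const int offs[13][3] = {
        {1, 0, 0}, {0, 1, 0}, {1, 1, 0}, {-1, 1, 0},
        {0, 0, 1}, {1, 0, 1}, {-1, 0, 1}, {0, 1, 1}, {0, -1, 1},
        {1, 1, 1}, {-1, 1, 1}, {1, -1, 1}, {-1, -1, 1}};
    NumericMatrix counts(Q, Q);
    for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
            for (int x = 0; x < nx; ++x) {
                const int i = idx3(x, y, z, nx, ny);
                if (!mask[i]) continue;
                const int li = levels[i];
                for (int o = 0; o < 13; ++o) {
                    const int xx = x + offs[o][0];
                    const int yy = y + offs[o][1];
                    const int zz = z + offs[o][2];
                    if (xx < 0 || xx >= nx || yy < 0 || yy >= ny ||
                        zz < 0 || zz >= nz)
                        continue;
                    const int j = idx3(xx, yy, zz, nx, ny);
                    if (!mask[j]) continue;
                    const int lj = levels[j];
                    counts(li - 1, lj - 1) += 1.0;
                    counts(lj - 1, li - 1) += 1.0;
                }
            }
    return counts;
}

// Zones = maximal 26-connected components of constant gray level inside the
// mask. Returns a two-column matrix (gray level, zone size), one row per zone.
// [[Rcpp::export]]
IntegerMatrix cpp_glszm_zones(IntegerVector levels, LogicalVector mask,
                              IntegerVector dim) {
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    const int n = nx * ny * nz;
    std::vector<char> seen(n, 0);
    std::vector<int> glist, slist, stack;
    stack.reserve(256);
    for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
            for (int x = 0; x < nx; ++x) {
                const int i0 = idx3(x, y, z, nx, ny);
                if (!mask[i0] || seen[i0]) continue;
                const int g = levels[i0];
                int size = 0;
                seen[i0] = 1;
                stack.clear();
                stack.push_back(i0);
                while (!stack.empty()) {
                    const int i = stack.back();
                    stack.pop_back();
                    ++size;
                    const int cz = i / (nx * ny);
                    const int cy = (i / nx) % ny;
                    const int cx = i % nx;
                    for (int dz = -1; dz <= 1; ++dz)
                        for (int dy = -1; dy <= 1; ++dy)
                            for (int dx = -1; dx <= 1; ++dx) {
                                if (!dx && !dy && !dz) continue;
                                const int xx = cx + dx, yy = cy + dy,
                                          zz = cz + dz;
                                if (xx < 0 || xx >= nx || yy < 0 ||
                                    yy >= ny || zz < 0 || zz >= nz)
                                    continue;
                                const int j = idx3(xx, yy, zz, nx, ny);
                                if (!mask[j] || seen[j] || levels[j] != g)
                                    continue;
                                seen[j] = 1;
                                stack.push_back(j);
                            }
                }
                glist.push_back(g);
                slist.push_back(size);
            }
    IntegerMatrix out(glist.size(), 2);
    for (size_t k = 0; k < glist.size(); ++k) {
        out(k, 0) = glist[k];
        out(k, 1) = slist[k];
    }
    return out;
}

// Slice-wise 2D quadrature filtering: response = sqrt(even^2 + odd^2).
// Computed only inside the given 1-based inclusive x/y/z ranges (zeros
// elsewhere); replicate boundary at slice edges. If `sel` is non-empty it
// further restricts computation to voxels with sel != 0 (masked-statistics
// fast path; skipped voxels stay 0).
// [[Rcpp::export]]
NumericVector cpp_gabor_response(NumericVector vol, IntegerVector dim,
                                 NumericMatrix ke, NumericMatrix ko,
                                 IntegerVector xr, IntegerVector yr,
                                 IntegerVector zr, IntegerVector sel) {
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    const int kx = ke.nrow(), ky = ke.ncol();
    const int hx = kx / 2, hy = ky / 2;
    const bool useSel = sel.size() > 0;
    const double *v = REAL(vol);
    std::vector<double> kev(kx * ky), kov(kx * ky);
    for (int b = 0; b < ky; ++b)
        for (int a = 0; a < kx; ++a) {
            kev[a + kx * b] = ke(a, b);
            kov[a + kx * b] = ko(a, b);
        }
    NumericVector out(nx * ny * nz);
    out.attr("dim") = dim;
    for (int z = zr[0] - 1; z <= zr[1] - 1; ++z)
        for (int y = yr[0] - 1; y <= yr[1] - 1; ++y) {
            const bool yEdge = (y - hy < 0) || (y + hy >= ny);
            for (int x = xr[0] - 1; x <= xr[1] - 1; ++x) {
                const int i0 = idx3(x, y, z, nx, ny);
                if (useSel && sel[i0] == 0) continue;
                double se = 0.0, so = 0.0;
                if (!yEdge && x - hx >= 0 && x + hx < nx) {
                    // interior: no clamping
                    for (int b = 0; b < ky; ++b) {
                        const double *vp =
                            v + idx3(x - hx, y + b - hy, z, nx, ny);
                        const double *kep = &kev[kx * b];
                        const double *kop = &kov[kx * b];
                        for (int a = 0; a < kx; ++a) {
                            se += vp[a] * kep[a];
                            so += vp[a] * kop[a];
                        }
                    }
                } else {
                    for (int b = 0; b < ky; ++b) {
                        int yy = y + b - hy;
                        if (yy < 0) yy = 0;
                        if (yy >= ny) yy = ny - 1;
                        for (int a = 0; a < kx; ++a) {
                            int xx = x + a - hx;
                            if (xx < 0) xx = 0;
                            if (xx >= nx) xx = nx - 1;
                            const double vv = v[idx3(xx, yy, z, nx, ny)];
                            se += vv * kev[a + kx * b];
                            so += vv * kov[a + kx * b];
                        }
                    }
                }
                out[i0] = std::sqrt(se * se + so * so);
            }
        }
    return out;
}

// Separable 3D Gaussian smoothing, zero boundary, kernel radius ceil(3*sigma).
// [[Rcpp::export]]
NumericVector cpp_smooth3(NumericVector vol, IntegerVector dim,
                          NumericVector sigma) {
    const int nd[3] = {dim[0], dim[1], dim[2]};
    std::vector<double> cur(vol.begin(), vol.end());
    std::vector<double> nxt(cur.size());
    const int nx = nd[0], ny = nd[1], nz = nd[2];
    const long strides[3] = {1L, (long)nx, (long)nx * ny};
    const int lens[3] = {nx, ny, nz};
    for (int ax = 0; ax < 3; ++ax) {
        const double s = sigma[ax];
        if (s <= 1e-8) continue;
        const int r = (int)std::ceil(3.0 * s);
        std::vector<double> k(2 * r + 1);
        double ksum = 0.0;
        for (int t = -r; t <= r; ++t) {
            k[t + r] = std::exp(-0.5 * t * t / (s * s));
            ksum += k[t + r];
        }
        for (int t = 0; t <= 2 * r; ++t) k[t] /= ksum;
        const long st = strides[ax];
        const int n = lens[ax];
        const int u = (ax == 0) ? 1 : 0;         // the two other axes
        const int w = (ax == 2) ? 1 : 2;
        for (int j = 0; j < lens[w]; ++j)
            for (int i = 0; i < lens[u]; ++i) {
                const long base = strides[u] * i + strides[w] * j;
                for (int pos = 0; pos < n; ++pos) {
                    const int t0 = std::max(-r, -pos);
                    const int t1 = std::min(r, n - 1 - pos);
                    double acc = 0.0;
                    const double *cp = &cur[base + (long)pos * st];
                    const double *kp = &k[r];
                    for (int t = t0; t <= t1; ++t)
                        acc += kp[t] * cp[(long)t * st];
                    nxt[base + (long)pos * st] = acc;
                }
            }
        cur.swap(nxt);
    }
    NumericVector out(cur.begin(), cur.end());
    out.attr("dim") = dim;
    return out;
}

static inline double triArea(const double *p, const double *q,
                             const double *r) {
    const double u[3] = {q[0] - p[0], q[1] - p[1], q[2] - p[2]};
    const double v[3] = {r[0] - p[0], r[1] - p[1], r[2] - p[2]};
    const double cx = u[1] * v[2] - u[2] * v[1];
    const double cy = u[2] * v[0] - u[0] * v[2];
    const double cz = u[0] * v[1] - u[1] * v[0];
    return 0.5 * std::sqrt(cx * cx + cy * cy + cz * cz);
}

static inline void interp(const double *pa, double va, const double *pb,
                          double vb, double iso, double *out) {
    const double t = (iso - va) / (vb - va);
    for (int c = 0; c < 3; ++c) out[c] = pa[c] + t * (pb[c] - pa[c]);
}

// Iso-surface area by marching tetrahedra (6 tetrahedra per cell, shared
// main diagonal). The field must be below iso on its border.
// [[Rcpp::export]]
double cpp_mesh_area(NumericVector field, IntegerVector dim,
                     NumericVector sp, double iso) {
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    static const int C[8][3] = {{0, 0, 0}, {1, 0, 0}, {0, 1, 0}, {1, 1, 0},
                                {0, 0, 1}, {1, 0, 1}, {0, 1, 1}, {1, 1, 1}};
    static const int T[6][4] = {{0, 1, 3, 7}, {0, 3, 2, 7}, {0, 2, 6, 7},
                                {0, 6, 4, 7}, {0, 4, 5, 7}, {0, 5, 1, 7}};
    double area = 0.0;
    double pos[8][3], val[8];
    for (int z = 0; z < nz - 1; ++z)
        for (int y = 0; y < ny - 1; ++y)
            for (int x = 0; x < nx - 1; ++x) {
                bool anyAbove = false, anyBelow = false;
                for (int c = 0; c < 8; ++c) {
                    const int xx = x + C[c][0], yy = y + C[c][1],
                              zz = z + C[c][2];
                    val[c] = field[idx3(xx, yy, zz, nx, ny)];
                    pos[c][0] = xx * sp[0];
                    pos[c][1] = yy * sp[1];
                    pos[c][2] = zz * sp[2];
                    if (val[c] > iso) anyAbove = true; else anyBelow = true;
                }
                if (!anyAbove || !anyBelow) continue;
                for (int t = 0; t < 6; ++t) {
                    int above[4], below[4];
                    int na = 0, nb = 0;
                    for (int c = 0; c < 4; ++c) {
                        const int v = T[t][c];
                        if (val[v] > iso) above[na++] = v;
                        else below[nb++] = v;
                    }
                    if (na == 0 || na == 4) continue;
                    double p1[3], p2[3], p3[3], p4[3];
                    if (na == 1 || na == 3) {
                        const int apex = (na == 1) ? above[0] : below[0];
                        const int *rest = (na == 1) ? below : above;
                        interp(pos[apex], val[apex], pos[rest[0]],
                               val[rest[0]], iso, p1);
                        interp(pos[apex], val[apex], pos[rest[1]],
                               val[rest[1]], iso, p2);
                        interp(pos[apex], val[apex], pos[rest[2]],
                               val[rest[2]], iso, p3);
                        area += triArea(p1, p2, p3);
                    } else {
                        // two above (a0,a1), two below (b0,b1): quad
                        interp(pos[above[0]], val[above[0]], pos[below[0]],
                               val[below[0]], iso, p1);
                        interp(pos[above[0]], val[above[0]], pos[below[1]],
                               val[below[1]], iso, p2);
                        interp(pos[above[1]], val[above[1]], pos[below[1]],
                               val[below[1]], iso, p3);
                        interp(pos[above[1]], val[above[1]], pos[below[0]],
                               val[below[0]], iso, p4);
                        area += triArea(p1, p2, p3);
                        area += triArea(p1, p3, p4);
                    }
                }
            }
    return area;
}
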