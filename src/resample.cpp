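#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// 3D resampling of axis-aligned volumes under a rigid transform.
// Interpolation orders: 0 (nearest), 1 (trilinear), 3 (cubic B-spline with
// interpolating prefilter, mirror boundary).

static const double kPole3 = -0.26794919243112270647; // sqrt(3) - 2

// In-place causal/anticausal recursive filter along one line (Unser's
// interpolating cubic B-spline prefilter, mirror-without-repeat boundary).
static void prefilter_line(double* c, int n, int stride) {
    if (n == 1) return;
    const double z = kPole3;
    const double gain = 6.0; // (1 - z) * (1 - 1/z)
    for (int i = 0; i < n; ++i) c[i * stride] *= gain;
    // causal initialization over the mirrored (reflect-without-repeat)
    // extension: truncated geometric sum when the line is long enough,
    // exact closed form otherwise
    int horizon = (int)std::ceil(std::log(1e-14) / std::log(std::fabs(z)));
    double sum;
    if (horizon < n) {
        sum = c[0];
        double zk = z;
        for (int k = 1; k < horizon; ++k) {
            sum += zk * c[k * stride];
            zk *= z;
        }
    } else {
        const double z_n1 = std::pow(z, n - 1);
        sum = c[0] + z_n1 * c[(n - 1) * stride];
        double zk = z;
        for (int k = 1; k < n - 1; ++k) {
            sum += (zk + z_n1 * z_n1 / zk) * c[k * stride];
            zk *= z;
        }
        sum /= (1.0 - z_n1 * z_n1);
    }
    c[0] = sum;
    for (int i = 1; i < n; ++i)
        c[i * stride] += z * c[(i - 1) * stride];
    // anticausal initialization
    c[(n - 1) * stride] = (z / (z * z - 1.0)) *
        (c[(n - 1) * stride] + z * c[(n - 2) * stride]);
    for (int i = n - 2; i >= 0; --i)
        c[i * stride] = z * (c[(i + 1) * stride] - c[i * stride]);
}

// [[Rcpp::export]]
NumericVector cpp_bspline_prefilter(NumericVector vol, IntegerVector dim) {
    int nx = dim[0], ny = dim[1], nz = dim[2];
    NumericVector out = clone(vol);
    double* p = REAL(out);
    // along x
    for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j)
            prefilter_line(p + (size_t)k * nx * ny + (size_t)j * nx, nx, 1);
    // along y
    for (int k = 0; k < nz; ++k)
        for (int i = 0; i < nx; ++i)
            prefilter_line(p + (size_t)k * nx * ny + i, ny, nx);
    // along z
    for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i)
            prefilter_line(p + (size_t)j * nx + i, nz, nx * ny);
    return out;
}

static inline int mirror_index(int i, int n) {
    if (n == 1) return 0;
    const int period = 2 * (n - 1);
    i = std::abs(i) % period;
    return (i >= n) ? period - i : i;
}

static inline void cubic_weights(double t, double* w) {
    const double t2 = t * t, t3 = t2 * t;
    w[0] = (1.0 - 3.0 * t + 3.0 * t2 - t3) / 6.0;
    w[1] = (4.0 - 6.0 * t2 + 3.0 * t3) / 6.0;
    w[2] = (1.0 + 3.0 * t + 3.0 * t2 - 3.0 * t3) / 6.0;
    w[3] = t3 / 6.0;
}

// src: raw intensities (order 0/1) or prefiltered coefficients (order 3).
// rot is a 3x3 matrix (column-major), applied as
//   p = rot * (w - center) + center + trans
// with w the world coordinate of the target voxel; the source is sampled
// at p. Samples whose continuous source index leaves [0, n-1] on any axis
// get `fill` (may be NA for validity masking).
// [[Rcpp::export]]
NumericVector cpp_resample3d(NumericVector src, IntegerVector sdim,
                             NumericVector sspacing, NumericVector sorigin,
                             IntegerVector tdim, NumericVector tspacing,
                             NumericVector torigin,
                             NumericMatrix rot, NumericVector trans,
                             NumericVector center,
                             int order, double fill) {
    const int sx = sdim[0], sy = sdim[1], sz = sdim[2];
    const int tx = tdim[0], ty = tdim[1], tz = tdim[2];
    NumericVector out((size_t)tx * ty * tz);
    const double* s = REAL(src);
    double* o = REAL(out);
    const double r11 = rot(0, 0), r12 = rot(0, 1), r13 = rot(0, 2);
    const double r21 = rot(1, 0), r22 = rot(1, 1), r23 = rot(1, 2);
    const double r31 = rot(2, 0), r32 = rot(2, 1), r33 = rot(2, 2);
    const size_t sxy = (size_t)sx * sy;
    size_t idx = 0;
    for (int k = 0; k < tz; ++k) {
        const double wz = torigin[2] + k * tspacing[2] - center[2];
        for (int j = 0; j < ty; ++j) {
            const double wy = torigin[1] + j * tspacing[1] - center[1];
            for (int i = 0; i < tx; ++i, ++idx) {
                const double wx = torigin[0] + i * tspacing[0] - center[0];
                const double px = r11 * wx + r12 * wy + r13 * wz + center[0] + trans[0];
                const double py = r21 * wx + r22 * wy + r23 * wz + center[1] + trans[1];
                const double pz = r31 * wx + r32 * wy + r33 * wz + center[2] + trans[2];
                const double ux = (px - sorigin[0]) / sspacing[0];
                const double uy = (py - sorigin[1]) / sspacing[1];
                const double uz = (pz - sorigin[2]) / sspacing[2];
                if (ux < 0 || ux > sx - 1 || uy < 0 || uy > sy - 1 ||
                    uz < 0 || uz > sz - 1) {
                    o[idx] = fill;
                    continue;
                }
                if (order == 0) {
                    int ix = (int)std::lround(ux);
                    int iy = (int)std::lround(uy);
                    int iz = (int)std::lround(uz);
                    o[idx] = s[(size_t)iz * sxy + (size_t)iy * sx + ix];
                } else if (order == 1) {
                    int ix = (int)std::floor(ux), iy = (int)std::floor(uy),
                        iz = (int)std::floor(uz);
                    if (ix == sx - 1) --ix;
                    if (iy == sy - 1) --iy;
                    if (iz == sz - 1) --iz;
                    if (ix < 0) ix = 0;
                    if (iy < 0) iy = 0;
                    if (iz < 0) iz = 0;
                    const double fx = ux - ix, fy = uy - iy, fz = uz - iz;
                    double v = 0.0;
                    for (int dz = 0; dz < 2; ++dz) {
                        const double wzc = dz ? fz : 1.0 - fz;
                        for (int dy = 0; dy < 2; ++dy) {
                            const double wyc = dy ? fy : 1.0 - fy;
                            for (int dx = 0; dx < 2; ++dx) {
                                const double wxc = dx ? fx : 1.0 - fx;
                                v += wxc * wyc * wzc *
                                     s[(size_t)(iz + dz) * sxy +
                                       (size_t)(iy + dy) * sx + (ix + dx)];
                            }
                        }
                    }
                    o[idx] = v;
                } else { // order == 3
                    const int bx = (int)std::floor(ux), by = (int)std::floor(uy),
                              bz = (int)std::floor(uz);
                    double wx4[4], wy4[4], wz4[4];
                    cubic_weights(ux - bx, wx4);
                    cubic_weights(uy - by, wy4);
                    cubic_weights(uz - bz, wz4);
                    double v = 0.0;
                    for (int dz = 0; dz < 4; ++dz) {
                        const int iz = mirror_index(bz - 1 + dz, sz);
                        for (int dy = 0; dy < 4; ++dy) {
                            const int iy = mirror_index(by - 1 + dy, sy);
                            const double wyz = wy4[dy] * wz4[dz];
                            for (int dx = 0; dx < 4; ++dx) {
                                const int ix = mirror_index(bx - 1 + dx, sx);
                                v += wx4[dx] * wyz *
                                     s[(size_t)iz * sxy + (size_t)iy * sx + ix];
                            }
                        }
                    }
                    o[idx] = v;
                }
            }
        }
    }
    out.attr("dim") = tdim;
    return out;
}
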