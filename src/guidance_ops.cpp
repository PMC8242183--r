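#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// L1 guidance terms: for each integer shift s, the field
// d_s = x - circshift(x, s) - g_s contributes sum(|d_s|) to the
// regularizer and (I - circshift^{-1}) sign(d_s) to its subgradient.
// Shifts wrap circularly; sign(0) = 0.

// [[Rcpp::export]]
List cpp_guidance_eval(NumericVector x, IntegerVector dim,
                       IntegerMatrix shifts, List fields,
                       bool want_subgrad) {
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    const size_t nvox = (size_t)nx * ny * nz;
    const double* xp = REAL(x);
    double reg = 0.0;
    NumericVector subgrad;
    double* gp = nullptr;
    if (want_subgrad) {
        subgrad = NumericVector(nvox);
        gp = REAL(subgrad);
    }
    std::vector<double> sg(want_subgrad ? nvox : 0);
    std::vector<int> wx(nx), wy(ny), wz(nz), fx(nx), fy(ny), fz(nz);
    const int nshift = shifts.nrow();
    for (int m = 0; m < nshift; ++m) {
        const int a = shifts(m, 0), b = shifts(m, 1), c = shifts(m, 2);
        const NumericVector fld = fields[m];
        const double* fp = REAL(fld);
        // wrapped source index per axis: circshift(x, s)[i] = x[i - s]
        for (int i = 0; i < nx; ++i) wx[i] = ((i - a) % nx + nx) % nx;
        for (int j = 0; j < ny; ++j) wy[j] = ((j - b) % ny + ny) % ny;
        for (int k = 0; k < nz; ++k) wz[k] = ((k - c) % nz + nz) % nz;
        size_t idx = 0;
        for (int k = 0; k < nz; ++k) {
            const size_t zo = (size_t)wz[k] * nx * ny;
            for (int j = 0; j < ny; ++j) {
                const size_t yo = zo + (size_t)wy[j] * nx;
                for (int i = 0; i < nx; ++i, ++idx) {
                    const double d = xp[idx] - xp[yo + wx[i]] - fp[idx];
                    reg += std::fabs(d);
                    if (want_subgrad)
                        sg[idx] = (d > 0.0) - (d < 0.0);
                }
            }
        }
        if (want_subgrad) {
            // accumulate sign(d) - circshift(sign(d), -s)
            for (int i = 0; i < nx; ++i) fx[i] = ((i + a) % nx + nx) % nx;
            for (int j = 0; j < ny; ++j) fy[j] = ((j + b) % ny + ny) % ny;
            for (int k = 0; k < nz; ++k) fz[k] = ((k + c) % nz + nz) % nz;
            idx = 0;
            for (int k = 0; k < nz; ++k) {
                const size_t zo = (size_t)fz[k] * nx * ny;
                for (int j = 0; j < ny; ++j) {
                    const size_t yo = zo + (size_t)fy[j] * nx;
                    for (int i = 0; i < nx; ++i, ++idx)
                        gp[idx] += sg[idx] - sg[yo + fx[i]];
                }
            }
        }
    }
    if (want_subgrad) {
        subgrad.attr("dim") = dim;
        return List::create(_["regularizer"] = reg,
                            _["subgrad"] = subgrad);
    }
    return List::create(_["regularizer"] = reg);
}
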