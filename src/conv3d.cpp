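// Blocked im2col 3D convolution kernels. The gather index vector `ivec`
// (built once per layer/batch shape in R) maps (output voxel, kernel offset)
// pairs to input rows; 0 means "outside the zero-padded volume". Patches are
// staged through a fixed-size buffer and multiplied with R's BLAS, so no
// volume-sized temporary is ever allocated.
#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
using namespace Rcpp;

static const int MAX_BUF_DOUBLES = 1 << 21; // 16 MB staging buffer

// Forward: Y (nout x Cout) = im2col(x) %*% W, W is (k3*Cin) x Cout with
// kernel offset fastest within input channel.
// [[Rcpp::export]]
NumericMatrix cpp_conv_fwd(NumericMatrix x, IntegerVector ivec, int nout,
                           int k3, NumericMatrix W) {
    int cin = x.ncol();
    int kc = k3 * cin;
    int cout = W.ncol();
    if (W.nrow() != kc) stop("weight rows do not match k3 * in_channels");
    R_xlen_t nin = x.nrow();
    NumericMatrix Y(nout, cout);
    int bs = MAX_BUF_DOUBLES / (kc > 0 ? kc : 1);
    if (bs < 1) bs = 1;
    if (bs > nout) bs = nout;
    std::vector<double> buf((size_t) bs * kc);
    const double *xp = REAL(x);
    const int *ip = INTEGER(ivec);
    double *yp = REAL(Y);
    const double one = 1.0, zero = 0.0;
    for (int r0 = 0; r0 < nout; r0 += bs) {
        int nb = std::min(bs, nout - r0);
        for (int j = 0; j < kc; ++j) {
            int k = j % k3, c = j / k3;
            const int *col = ip + (R_xlen_t) k * nout + r0;
            const double *xc = xp + (R_xlen_t) c * nin;
            double *b = buf.data() + (size_t) j * nb;
            for (int r = 0; r < nb; ++r) {
                int i = col[r];
                b[r] = (i > 0) ? xc[i - 1] : 0.0;
            }
        }
        F77_CALL(dgemm)("N", "N", &nb, &cout, &kc, &one, buf.data(), &nb,
                        REAL(W), &kc, &zero, yp + r0, &nout
                        FCONE FCONE);
    }
    return Y;
}

// Weight gradient: dW = t(im2col(x)) %*% dY, accumulated blockwise.
// [[Rcpp::export]]
NumericMatrix cpp_conv_dw(NumericMatrix x, IntegerVector ivec, int nout,
                          int k3, NumericMatrix dY) {
    int cin = x.ncol();
    int kc = k3 * cin;
    int cout = dY.ncol();
    if (dY.nrow() != nout) stop("dY rows do not match output voxels");
    R_xlen_t nin = x.nrow();
    NumericMatrix dW(kc, cout);
    int bs = MAX_BUF_DOUBLES / (kc > 0 ? kc : 1);
    if (bs < 1) bs = 1;
    if (bs > nout) bs = nout;
    std::vector<double> buf((size_t) bs * kc);
    const double *xp = REAL(x);
    const int *ip = INTEGER(ivec);
    const double *dyp = REAL(dY);
    const double one = 1.0;
    for (int r0 = 0; r0 < nout; r0 += bs) {
        int nb = std::min(bs, nout - r0);
        for (int j = 0; j < kc; ++j) {
            int k = j % k3, c = j / k3;
            const int *col = ip + (R_xlen_t) k * nout + r0;
            const double *xc = xp + (R_xlen_t) c * nin;
            double *b = buf.data() + (size_t) j * nb;
            for (int r = 0; r < nb; ++r) {
                int i = col[r];
                b[r] = (i > 0) ? xc[i - 1] : 0.0;
            }
        }
        F77_CALL(dgemm)("T", "N", &kc, &cout, &nb, &one, buf.data(), &nb,
                        dyp + r0, &nout, &one, REAL(dW), &kc
                        FCONE FCONE);
    }
    return dW;
}

// Input gradient: scatter-add of dY %*% t(W) through the gather map.
// [[Rcpp::export]]
NumericMatrix cpp_conv_dx(NumericMatrix dY, IntegerVector ivec, int nout,
                          int k3, NumericMatrix W, int nin) {
    int cout = W.ncol();
    int kc = W.nrow();
    int cin = kc / k3;
    if (dY.nrow() != nout) stop("dY rows do not match output voxels");
    NumericMatrix dX(nin, cin);
    int bs = MAX_BUF_DOUBLES / (kc > 0 ? kc : 1);
    if (bs < 1) bs = 1;
    if (bs > nout) bs = nout;
    std::vector<double> buf((size_t) bs * kc);
    const int *ip = INTEGER(ivec);
    const double *dyp = REAL(dY);
    double *dxp = REAL(dX);
    const double one = 1.0, zero = 0.0;
    for (int r0 = 0; r0 < nout; r0 += bs) {
        int nb = std::min(bs, nout - r0);
        F77_CALL(dgemm)("N", "T", &nb, &kc, &cout, &one, dyp + r0, &nout,
                        REAL(W), &kc, &zero, buf.data(), &nb
                        FCONE FCONE);
        for (int j = 0; j < kc; ++j) {
            int k = j % k3, c = j / k3;
            const int *col = ip + (R_xlen_t) k * nout + r0;
            double *dxc = dxp + (R_xlen_t) c * nin;
            const double *b = buf.data() + (size_t) j * nb;
            for (int r = 0; r < nb; ++r) {
                int i = col[r];
                if (i > 0) dxc[i - 1] += b[r];
            }
        }
    }
    return dX;
}
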