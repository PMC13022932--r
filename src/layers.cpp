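// Fused max-pool and batch-norm kernels (forward + backward).
#include <Rcpp.h>
using namespace Rcpp;

// Max over k3 gathered candidates per output row and channel; records the
// argmax offset for the backward pass. ivec: 0 = outside (treated as -Inf).
// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericMatrix x, IntegerVector ivec, int nout, int k3) {
    int C = x.ncol();
    R_xlen_t nin = x.nrow();
    NumericMatrix y(nout, C);
    IntegerMatrix arg(nout, C);
    const double *xp = REAL(x);
    const int *ip = INTEGER(ivec);
    double *yp = REAL(y);
    int *ap = INTEGER(arg);
    for (int c = 0; c < C; ++c) {
        const double *xc = xp + (R_xlen_t) c * nin;
        double *yc = yp + (R_xlen_t) c * nout;
        int *ac = ap + (R_xlen_t) c * nout;
        for (int r = 0; r < nout; ++r) {
            double best = R_NegInf;
            int bk = 1;
            for (int k = 0; k < k3; ++k) {
                int i = ip[(R_xlen_t) k * nout + r];
                if (i > 0) {
                    double v = xc[i - 1];
                    if (v > best) { best = v; bk = k + 1; }
                }
            }
            yc[r] = best;
            ac[r] = bk;
        }
    }
    return List::create(_["y"] = y, _["arg"] = arg);
}

// [[Rcpp::export]]
NumericMatrix cpp_maxpool_bwd(NumericMatrix dy, IntegerMatrix arg,
                              IntegerVector ivec, int nout, int k3, int nin) {
    int C = dy.ncol();
    NumericMatrix dx(nin, C);
    const double *dyp = REAL(dy);
    const int *ap = INTEGER(arg);
    const int *ip = INTEGER(ivec);
    double *dxp = REAL(dx);
    for (int c = 0; c < C; ++c) {
        const double *dyc = dyp + (R_xlen_t) c * nout;
        const int *ac = ap + (R_xlen_t) c * nout;
        double *dxc = dxp + (R_xlen_t) c * nin;
        for (int r = 0; r < nout; ++r) {
            int i = ip[(R_xlen_t) (ac[r] - 1) * nout + r];
            if (i > 0) dxc[i - 1] += dyc[r];
        }
    }
    return dx;
}

// Batch norm over all rows (batch x spatial) per channel, biased variance.
// [[Rcpp::export]]
List cpp_bn_fwd(NumericMatrix x, NumericVector gamma, NumericVector beta,
                double eps) {
    int C = x.ncol();
    R_xlen_t n = x.nrow();
    NumericMatrix y(n, C), xhat(n, C);
    NumericVector istd(C);
    const double *xp = REAL(x);
    double *yp = REAL(y), *hp = REAL(xhat);
    for (int c = 0; c < C; ++c) {
        const double *xc = xp + n * c;
        double *yc = yp + n * c, *hc = hp + n * c;
        double s = 0, s2 = 0;
        for (R_xlen_t r = 0; r < n; ++r) { s += xc[r]; s2 += xc[r] * xc[r]; }
        double mu = s / n;
        double var = s2 / n - mu * mu;
        if (var < 0) var = 0;
        double is = 1.0 / std::sqrt(var + eps);
        istd[c] = is;
        double g = gamma[c], b = beta[c];
        for (R_xlen_t r = 0; r < n; ++r) {
            double h = (xc[r] - mu) * is;
            hc[r] = h;
            yc[r] = g * h + b;
        }
    }
    return List::create(_["y"] = y, _["xhat"] = xhat, _["istd"] = istd);
}

// [[Rcpp::export]]
List cpp_bn_bwd(NumericMatrix dy, NumericMatrix xhat, NumericVector istd,
                NumericVector gamma) {
    int C = dy.ncol();
    R_xlen_t n = dy.nrow();
    NumericMatrix dx(n, C);
    NumericVector dgamma(C), dbeta(C);
    const double *dyp = REAL(dy), *hp = REAL(xhat);
    double *dxp = REAL(dx);
    for (int c = 0; c < C; ++c) {
        const double *dyc = dyp + n * c, *hc = hp + n * c;
        double *dxc = dxp + n * c;
        double s1 = 0, s2 = 0, dg = 0, db = 0;
        double g = gamma[c];
        for (R_xlen_t r = 0; r < n; ++r) {
            double dh = dyc[r] * g;
            s1 += dh;
            s2 += dh * hc[r];
            dg += dyc[r] * hc[r];
            db += dyc[r];
        }
        dgamma[c] = dg;
        dbeta[c] = db;
        double m1 = s1 / n, m2 = s2 / n, is = istd[c];
        for (R_xlen_t r = 0; r < n; ++r) {
            double dh = dyc[r] * g;
            dxc[r] = (dh - m1 - hc[r] * m2) * is;
        }
    }
    return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                        _["dbeta"] = dbeta);
}
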