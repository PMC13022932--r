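#include <Rcpp.h>
using namespace Rcpp;

// Row gather with a zero slot: idx holds 1-based row indices into x, or 0
// meaning "outside the padded volume" (filled with `fill`, normally 0).
// Returns an length(idx) x ncol(x) matrix. Hot path of im2col convolution.
// [[Rcpp::export]]
NumericMatrix cpp_gather_rows(NumericMatrix x, IntegerVector idx, double fill) {
    R_xlen_t m = idx.size();
    int nc = x.ncol();
    R_xlen_t nr = x.nrow();
    NumericMatrix out((int) m, nc);
    double *xp = REAL(x);
    double *op = REAL(out);
    int *ip = INTEGER(idx);
    for (int c = 0; c < nc; ++c) {
        double *xc = xp + (R_xlen_t) c * nr;
        double *oc = op + (R_xlen_t) c * m;
        for (R_xlen_t r = 0; r < m; ++r) {
            int i = ip[r];
            oc[r] = (i > 0) ? xc[i - 1] : fill;
        }
    }
    return out;
}

// Scatter-add: the adjoint of cpp_gather_rows. Accumulates rows of dp into
// an n x ncol(dp) zero matrix at positions idx (0 entries are dropped).
// [[Rcpp::export]]
NumericMatrix cpp_scatter_add_rows(NumericMatrix dp, IntegerVector idx, int n) {
    R_xlen_t m = idx.size();
    if (m != (R_xlen_t) dp.nrow())
        stop("idx length must equal nrow(dp)");
    int nc = dp.ncol();
    NumericMatrix out(n, nc);
    double *pp = REAL(dp);
    double *op = REAL(out);
    int *ip = INTEGER(idx);
    for (int c = 0; c < nc; ++c) {
        double *pc = pp + (R_xlen_t) c * m;
        double *oc = op + (R_xlen_t) c * n;
        for (R_xlen_t r = 0; r < m; ++r) {
            int i = ip[r];
            if (i > 0) oc[i - 1] += pc[r];
        }
    }
    return out;
}
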