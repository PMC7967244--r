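/* 1-D convolution forward/backward kernels for the per-lead scale paths.
 *
 * Arrays follow the R layout used by the training code: inputs and
 * activations are column-major (n, L, cin) / (n, Lout, F) doubles, weights
 * are (K, cin, F), biases length F.  Each kernel lowers the convolution to
 * an im2col patch matrix and a BLAS dgemm; the patch matrix is rebuilt in
 * the backward pass rather than cached, trading a cheap copy for memory.
 * ReLU is fused into the forward pass; the backward pass recovers the
 * ReLU mask from the stored activations (a > 0 exactly when the
 * pre-activation was positive).
 */

#define USE_FC_LEN_T
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <R_ext/BLAS.h>
#include <string.h>
#ifndef FCONE
# define FCONE
#endif

/* Fill the (n*Lout, K*cin) im2col matrix: column c*K + k holds
 * x[, t*stride + k, c] stacked over t. */
static void fill_im2col(const double *x, double *xcol, int n, int L,
                        int cin, int K, int stride, int Lout)
{
    const size_t nL = (size_t)n * L, nLout = (size_t)n * Lout;
    for (int c = 0; c < cin; c++)
        for (int k = 0; k < K; k++) {
            double *dst = xcol + ((size_t)c * K + k) * nLout;
            const double *src = x + (size_t)c * nL + (size_t)k * n;
            for (int t = 0; t < Lout; t++)
                memcpy(dst + (size_t)t * n, src + (size_t)t * stride * n,
                       sizeof(double) * n);
        }
}

/* x (n, L, cin), W (K, cin, F), b (F), stride -> a (n, Lout, F) */
SEXP C_conv1d_forward(SEXP x_, SEXP W_, SEXP b_, SEXP stride_)
{
    const double *x = REAL(x_), *W = REAL(W_), *b = REAL(b_);
    const int *xd = INTEGER(getAttrib(x_, R_DimSymbol));
    const int *wd = INTEGER(getAttrib(W_, R_DimSymbol));
    const int n = xd[0], L = xd[1], cin = xd[2];
    const int K = wd[0], F = wd[2];
    const int stride = asInteger(stride_);
    const int Lout = (L - K) / stride + 1;
    const int m = n * Lout, kc = K * cin;

    double *xcol = (double *) R_alloc((size_t)m * kc, sizeof(double));
    fill_im2col(x, xcol, n, L, cin, K, stride, Lout);

    SEXP a_ = PROTECT(alloc3DArray(REALSXP, n, Lout, F));
    double *a = REAL(a_);
    const double one = 1.0, zero = 0.0;
    F77_CALL(dgemm)("N", "N", &m, &F, &kc, &one, xcol, &m, W, &kc,
                    &zero, a, &m FCONE FCONE);
    for (int f = 0; f < F; f++) {
        double *af = a + (size_t)f * m;
        const double bf = b[f];
        for (int j = 0; j < m; j++) {
            const double z = af[j] + bf;
            af[j] = z > 0.0 ? z : 0.0;
        }
    }
    UNPROTECT(1);
    return a_;
}

/* dA (n, Lout, F), x (n, L, cin), a (n, Lout, F), W (K, cin, F), stride,
 * need_dx -> list(dW (K, cin, F), db (F), dx (n, L, cin) | NULL) */
SEXP C_conv1d_backward(SEXP dA_, SEXP x_, SEXP a_, SEXP W_, SEXP stride_,
                       SEXP need_dx_)
{
    const double *dA = REAL(dA_), *x = REAL(x_), *a = REAL(a_),
                 *W = REAL(W_);
    const int *xd = INTEGER(getAttrib(x_, R_DimSymbol));
    const int *wd = INTEGER(getAttrib(W_, R_DimSymbol));
    const int n = xd[0], L = xd[1], cin = xd[2];
    const int K = wd[0], F = wd[2];
    const int stride = asInteger(stride_);
    const int Lout = (L - K) / stride + 1;
    const int need_dx = asLogical(need_dx_);
    const int m = n * Lout, kc = K * cin;
    const double one = 1.0, zero = 0.0;

    /* dZ = dA masked by ReLU */
    double *dZ = (double *) R_alloc((size_t)m * F, sizeof(double));
    for (size_t j = 0; j < (size_t)m * F; j++)
        dZ[j] = a[j] > 0.0 ? dA[j] : 0.0;

    double *xcol = (double *) R_alloc((size_t)m * kc, sizeof(double));
    fill_im2col(x, xcol, n, L, cin, K, stride, Lout);

    SEXP dW_ = PROTECT(alloc3DArray(REALSXP, K, cin, F));
    SEXP db_ = PROTECT(allocVector(REALSXP, F));
    double *dW = REAL(dW_), *db = REAL(db_);
    F77_CALL(dgemm)("T", "N", &kc, &F, &m, &one, xcol, &m, dZ, &m,
                    &zero, dW, &kc FCONE FCONE);
    for (int f = 0; f < F; f++) {
        const double *zf = dZ + (size_t)f * m;
        double s = 0.0;
        for (int j = 0; j < m; j++) s += zf[j];
        db[f] = s;
    }

    SEXP dx_ = R_NilValue;
    int nprot = 2;
    if (need_dx) {
        double *dxcol = (double *) R_alloc((size_t)m * kc, sizeof(double));
        F77_CALL(dgemm)("N", "T", &m, &kc, &F, &one, dZ, &m, W, &kc,
                        &zero, dxcol, &m FCONE FCONE);
        dx_ = PROTECT(alloc3DArray(REALSXP, n, L, cin));
        nprot++;
        double *dx = REAL(dx_);
        memset(dx, 0, sizeof(double) * (size_t)n * L * cin);
        const size_t nL = (size_t)n * L;
        for (int c = 0; c < cin; c++)
            for (int k = 0; k < K; k++) {
                const double *src = dxcol + ((size_t)c * K + k) * (size_t)m;
                double *dst = dx + (size_t)c * nL + (size_t)k * n;
                for (int t = 0; t < Lout; t++) {
                    const double *st = src + (size_t)t * n;
                    double *dt = dst + (size_t)t * stride * n;
                    for (int i = 0; i < n; i++) dt[i] += st[i];
                }
            }
    }

    SEXP out = PROTECT(allocVector(VECSXP, 3));
    nprot++;
    SET_VECTOR_ELT(out, 0, dW_);
    SET_VECTOR_ELT(out, 1, db_);
    SET_VECTOR_ELT(out, 2, dx_);
    SEXP nm = PROTECT(allocVector(STRSXP, 3));
    nprot++;
    SET_STRING_ELT(nm, 0, mkChar("dW"));
    SET_STRING_ELT(nm, 1, mkChar("db"));
    SET_STRING_ELT(nm, 2, mkChar("dx"));
    setAttrib(out, R_NamesSymbol, nm);
    UNPROTECT(nprot);
    return out;
}

static const R_CallMethodDef call_entries[] = {
    {"C_conv1d_forward",  (DL_FUNC) &C_conv1d_forward,  4},
    {"C_conv1d_backward", (DL_FUNC) &C_conv1d_backward, 6},
    {NULL, NULL, 0}
};

void R_init_ecgmi(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, call_entries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
    R_forceSymbols(dll, TRUE);
}
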