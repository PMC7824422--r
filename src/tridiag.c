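/* Top-k eigenpairs of a symmetric tridiagonal matrix via LAPACK dstevr.
   Used for Slepian (DPSS) taper construction, where the dense problem is
   too slow at N = 1000. */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Lapack.h>

#ifndef FCONE
#define FCONE
#endif

SEXP C_tridiag_topk(SEXP d_, SEXP e_, SEXP k_)
{
    int n = LENGTH(d_);
    int k = asInteger(k_);
    if (k < 1 || k > n)
        error("k must be in [1, n]");
    if (LENGTH(e_) != n - 1)
        error("off-diagonal must have length n - 1");

    /* dstevr overwrites d and e */
    double *d = (double *) R_alloc(n, sizeof(double));
    double *e = (double *) R_alloc(n, sizeof(double));
    memcpy(d, REAL(d_), n * sizeof(double));
    memcpy(e, REAL(e_), (n - 1) * sizeof(double));

    int il = n - k + 1, iu = n, m = 0, info = 0;
    double vl = 0.0, vu = 0.0, abstol = 0.0;

    SEXP w_ = PROTECT(allocVector(REALSXP, k));
    SEXP z_ = PROTECT(allocMatrix(REALSXP, n, k));
    int *isuppz = (int *) R_alloc(2 * k, sizeof(int));

    /* workspace query */
    double wkopt;
    int iwkopt, lwork = -1, liwork = -1;
    F77_CALL(dstevr)("V", "I", &n, d, e, &vl, &vu, &il, &iu, &abstol,
                     &m, REAL(w_), REAL(z_), &n, isuppz,
                     &wkopt, &lwork, &iwkopt, &liwork, &info FCONE FCONE);
    if (info != 0)
        error("dstevr workspace query failed (info = %d)", info);

    lwork = (int) wkopt;
    liwork = iwkopt;
    double *work = (double *) R_alloc(lwork, sizeof(double));
    int *iwork = (int *) R_alloc(liwork, sizeof(int));

    F77_CALL(dstevr)("V", "I", &n, d, e, &vl, &vu, &il, &iu, &abstol,
                     &m, REAL(w_), REAL(z_), &n, isuppz,
                     work, &lwork, iwork, &liwork, &info FCONE FCONE);
    if (info != 0)
        error("dstevr failed (info = %d)", info);
    if (m != k)
        error("dstevr returned %d of %d requested eigenpairs", m, k);

    SEXP out = PROTECT(allocVector(VECSXP, 2));
    SET_VECTOR_ELT(out, 0, w_);   /* ascending eigenvalues */
    SET_VECTOR_ELT(out, 1, z_);   /* matching eigenvectors (columns) */
    SEXP nms = PROTECT(allocVector(STRSXP, 2));
    SET_STRING_ELT(nms, 0, mkChar("values"));
    SET_STRING_ELT(nms, 1, mkChar("vectors"));
    setAttrib(out, R_NamesSymbol, nms);
    UNPROTECT(4);
    return out;
}
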