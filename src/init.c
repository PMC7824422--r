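#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

SEXP C_tridiag_topk(SEXP d_, SEXP e_, SEXP k_);

static const R_CallMethodDef CallEntries[] = {
    {"C_tridiag_topk", (DL_FUNC) &C_tridiag_topk, 3},
    {NULL, NULL, 0}
};

void R_init_erspconn(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
    R_forceSymbols(dll, TRUE);
}
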