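#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

void csc_initmod(void (*odeparms)(int *, double *));
void csc_derivs(int *, double *, double *, double *, double *, int *);
void csc_fast_derivs(int *, double *, double *, double *, double *, int *);

static const R_CMethodDef CEntries[] = {
    {"csc_initmod",    (DL_FUNC) &csc_initmod,    1},
    {"csc_derivs",     (DL_FUNC) &csc_derivs,     6},
    {"csc_fast_derivs",(DL_FUNC) &csc_fast_derivs,6},
    {NULL, NULL, 0}
};

void R_init_cscburst(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
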