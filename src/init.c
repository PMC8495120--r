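#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

void pbpk_initmod(void (*odeparms)(int *, double *));
void pbpk_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip);

static const R_CMethodDef CEntries[] = {
    {"pbpk_initmod", (DL_FUNC) &pbpk_initmod, 1},
    {"pbpk_derivs",  (DL_FUNC) &pbpk_derivs,  6},
    {NULL, NULL, 0}
};

void R_init_permpbpk(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    /* keep dynamic lookup enabled: deSolve resolves the model symbols
       by name at run time */
    R_useDynamicSymbols(dll, TRUE);
}
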