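/* Pin the BLAS thread count at runtime.
 *
 * Multi-threaded OpenBLAS parallelises its matrix-product reductions in a
 * way that is not bitwise reproducible between calls. Every numeric
 * contract in this package (training trajectories, cross-validation grids)
 * promises bit-identical results for identical seeds, so the thread count
 * is forced to one when the package loads. The symbol is resolved
 * dynamically: on systems with a different BLAS this is a silent no-op.
 */
#include <R.h>
#include <Rinternals.h>

#ifdef _WIN32
SEXP ctseg_set_blas_threads(SEXP n)
{
    return ScalarLogical(0);
}
#else
#include <dlfcn.h>

SEXP ctseg_set_blas_threads(SEXP n)
{
    void (*set_threads)(int);
    *(void **)(&set_threads) = dlsym(RTLD_DEFAULT, "openblas_set_num_threads");
    if (set_threads == NULL)
        *(void **)(&set_threads) = dlsym(RTLD_DEFAULT, "goto_set_num_threads");
    if (set_threads == NULL)
        return ScalarLogical(0);
    set_threads(asInteger(n));
    return ScalarLogical(1);
}
#endif

static const R_CallMethodDef call_entries[] = {
    {"ctseg_set_blas_threads", (DL_FUNC) &ctseg_set_blas_threads, 1},
    {NULL, NULL, 0}
};

void R_init_ctseg(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, call_entries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
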