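/* Minimal binding to the GLPK primal simplex.
 *
 * Solves   opt  c'x   s.t.  rlb <= A x <= rub,  clb <= x <= cub
 * where each row/column bound pair encodes free / lower / upper / double /
 * fixed bounds (infinities permitted).
 */
#include <R.h>
#include <Rinternals.h>
#include <float.h>
#include <math.h>
#include <glpk.h>

static int bound_type(double lo, double up)
{
    int lo_fin = R_FINITE(lo), up_fin = R_FINITE(up);
    if (lo_fin && up_fin) return (lo == up) ? GLP_FX : GLP_DB;
    if (lo_fin) return GLP_LO;
    if (up_fin) return GLP_UP;
    return GLP_FR;
}

SEXP C_glpk_solve(SEXP obj, SEXP Amat, SEXP rlb, SEXP rub,
                  SEXP clb, SEXP cub, SEXP maximize)
{
    int n = LENGTH(obj);
    int m = LENGTH(rlb);
    double *a = REAL(Amat); /* m x n, column major */
    glp_prob *lp = glp_create_prob();
    glp_set_obj_dir(lp, asLogical(maximize) ? GLP_MAX : GLP_MIN);
    glp_add_rows(lp, m > 0 ? m : 0);
    glp_add_cols(lp, n);

    for (int i = 0; i < m; i++) {
        double lo = REAL(rlb)[i], up = REAL(rub)[i];
        glp_set_row_bnds(lp, i + 1, bound_type(lo, up),
                         R_FINITE(lo) ? lo : 0.0, R_FINITE(up) ? up : 0.0);
    }
    for (int j = 0; j < n; j++) {
        double lo = REAL(clb)[j], up = REAL(cub)[j];
        glp_set_col_bnds(lp, j + 1, bound_type(lo, up),
                         R_FINITE(lo) ? lo : 0.0, R_FINITE(up) ? up : 0.0);
        glp_set_obj_coef(lp, j + 1, REAL(obj)[j]);
    }

    /* sparse triplet load */
    int nnz = 0;
    for (int j = 0; j < n; j++)
        for (int i = 0; i < m; i++)
            if (a[i + (size_t) j * m] != 0.0) nnz++;
    if (nnz > 0) {
        int *ia = (int *) R_alloc(nnz + 1, sizeof(int));
        int *ja = (int *) R_alloc(nnz + 1, sizeof(int));
        double *ar = (double *) R_alloc(nnz + 1, sizeof(double));
        int k = 1;
        for (int j = 0; j < n; j++)
            for (int i = 0; i < m; i++) {
                double v = a[i + (size_t) j * m];
                if (v != 0.0) { ia[k] = i + 1; ja[k] = j + 1; ar[k] = v; k++; }
            }
        glp_load_matrix(lp, nnz, ia, ja, ar);
    }

    glp_smcp parm;
    glp_init_smcp(&parm);
    parm.msg_lev = GLP_MSG_OFF;
    parm.presolve = GLP_OFF;
    int ret = glp_simplex(lp, &parm);
    int status = glp_get_status(lp);

    SEXP out = PROTECT(allocVector(VECSXP, 3));
    SEXP xs = PROTECT(allocVector(REALSXP, n));
    for (int j = 0; j < n; j++) REAL(xs)[j] = glp_get_col_prim(lp, j + 1);
    SET_VECTOR_ELT(out, 0, ScalarInteger(ret == 0 ? status : -ret));
    SET_VECTOR_ELT(out, 1, xs);
    SET_VECTOR_ELT(out, 2, ScalarReal(glp_get_obj_val(lp)));
    SEXP nm = PROTECT(allocVector(STRSXP, 3));
    SET_STRING_ELT(nm, 0, mkChar("status"));
    SET_STRING_ELT(nm, 1, mkChar("x"));
    SET_STRING_ELT(nm, 2, mkChar("objective"));
    setAttrib(out, R_NamesSymbol, nm);
    glp_delete_prob(lp);
    UNPROTECT(3);
    return out;
}

#include <R_ext/Rdynload.h>

static const R_CallMethodDef call_entries[] = {
    {"C_glpk_solve", (DL_FUNC) &C_glpk_solve, 7},
    {NULL, NULL, 0}
};

void R_init_sccnet(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, call_entries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
    R_forceSymbols(dll, TRUE);
}
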