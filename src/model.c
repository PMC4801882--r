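/* Right-hand sides of the five-compartment B-cell population model and its
 * ten-compartment labeled/unlabeled (BrdU) extension, for use with deSolve.
 *
 * Parameter vector (length 14), order shared with the R side:
 *   0 S        source inflow into pro-/pre-B (cells / 6 h)
 *   1 gamma    max pro-/pre-B proliferation rate
 *   2 K        carrying capacity for pro-/pre-B + BM mature recirculating
 *   3 delta_oe pro-/pre-B -> immature differentiation
 *   4 delta_r  immature -> pro-/pre-B reflux
 *   5 mu_i     immature death
 *   6 delta_i_t  immature -> transitional
 *   7 delta_i_re immature -> BM mature recirculating
 *   8 mu_re    BM mature recirculating death
 *   9 phi_BM   BM mature -> splenic mature flow
 *  10 mu_t     transitional death
 *  11 delta_t  transitional -> splenic mature
 *  12 phi_s    splenic mature -> BM mature flow
 *  13 eps_spl  exit from splenic mature
 *
 * State order: B_oe, B_i, B_Mrec, B_t, B_Mspl (totals model);
 * the labeled model stacks the five unlabeled then the five labeled pools.
 * All rates are per 6-h time unit.
 */
#include <R.h>
#include <R_ext/Rdynload.h>

static double p[14];

void bcd_initmod(void (*odeparms)(int *, double *))
{
    int n = 14;
    odeparms(&n, p);
}

#define S_      p[0]
#define GAMMA   p[1]
#define K_      p[2]
#define D_OE    p[3]
#define D_R     p[4]
#define MU_I    p[5]
#define D_IT    p[6]
#define D_IRE   p[7]
#define MU_RE   p[8]
#define PHI_BM  p[9]
#define MU_T    p[10]
#define D_T     p[11]
#define PHI_S   p[12]
#define EPS_SPL p[13]

void bcd_derivs_pop(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    double lam = 1.0 - (y[0] + y[2]) / K_;
    ydot[0] = S_ + GAMMA * lam * y[0] - D_OE * y[0] + D_R * y[1];
    ydot[1] = D_OE * y[0] - (MU_I + D_IT + D_R + D_IRE) * y[1];
    ydot[2] = D_IRE * y[1] + PHI_S * y[4] - (MU_RE + PHI_BM) * y[2];
    ydot[3] = D_IT * y[1] - (MU_T + D_T) * y[3];
    ydot[4] = D_T * y[3] + PHI_BM * y[2] - (PHI_S + EPS_SPL) * y[4];
}

void bcd_derivs_brdu(int *neq, double *t, double *y, double *ydot,
                     double *yout, int *ip)
{
    double *U = y, *L = y + 5;
    double *dU = ydot, *dL = ydot + 5;
    double lam = 1.0 - (U[0] + L[0] + U[2] + L[2]) / K_;
    double out_i = MU_I + D_IT + D_R + D_IRE;

    /* unlabeled: the source is never labeled; a dividing unlabeled cell
     * leaves this pool */
    dU[0] = S_ - GAMMA * lam * U[0] - D_OE * U[0] + D_R * U[1];
    dU[1] = D_OE * U[0] - out_i * U[1];
    dU[2] = D_IRE * U[1] + PHI_S * U[4] - (MU_RE + PHI_BM) * U[2];
    dU[3] = D_IT * U[1] - (MU_T + D_T) * U[3];
    dU[4] = D_T * U[3] + PHI_BM * U[2] - (PHI_S + EPS_SPL) * U[4];

    /* labeled: each unlabeled division yields two labeled daughters,
     * a labeled division nets one extra labeled cell */
    dL[0] = GAMMA * lam * (2.0 * U[0] + L[0]) - D_OE * L[0] + D_R * L[1];
    dL[1] = D_OE * L[0] - out_i * L[1];
    dL[2] = D_IRE * L[1] + PHI_S * L[4] - (MU_RE + PHI_BM) * L[2];
    dL[3] = D_IT * L[1] - (MU_T + D_T) * L[3];
    dL[4] = D_T * L[3] + PHI_BM * L[2] - (PHI_S + EPS_SPL) * L[4];
}

static const R_CMethodDef cMethods[] = {
    {"bcd_initmod",     (DL_FUNC) &bcd_initmod,     1},
    {"bcd_derivs_pop",  (DL_FUNC) &bcd_derivs_pop,  6},
    {"bcd_derivs_brdu", (DL_FUNC) &bcd_derivs_brdu, 6},
    {NULL, NULL, 0}
};

void R_init_bcelldyn(DllInfo *dll)
{
    R_registerRoutines(dll, cMethods, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
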