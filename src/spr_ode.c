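/* Compiled right-hand sides for the SPR binding-kinetics ODE models,
 * evaluated by deSolve. Time is in seconds, response in RU, analyte
 * concentration in M (held fixed within a phase; the R wrapper integrates
 * association and dissociation separately).
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

/* ---- bivalent analyte: parms = ka1, kd1, ka2, kd2, Bmax, C ---- */
static double bparms[6];

void init_bivalent(void (*odeparms)(int *, double *))
{
    int n = 6;
    odeparms(&n, bparms);
}

/* y[0] = R1 (singly bound), y[1] = R2 (doubly bound).
 * Free surface sites = Bmax - R1 - R2; the second binding step consumes
 * surface sites, so ka2 carries RU^-1 s^-1 units. Response = R1 + R2.
 */
void derivs_bivalent(int *neq, double *t, double *y, double *ydot,
                     double *yout, int *ip)
{
    double ka1 = bparms[0], kd1 = bparms[1], ka2 = bparms[2],
           kd2 = bparms[3], bmax = bparms[4], conc = bparms[5];
    double freeb = bmax - y[0] - y[1];
    ydot[0] = ka1 * conc * freeb - kd1 * y[0]
              - ka2 * y[0] * freeb + kd2 * y[1];
    ydot[1] = ka2 * y[0] * freeb - kd2 * y[1];
}

/* ---- two independent sites: parms = ka1, kd1, ka2, kd2, Bmax1, Bmax2, C */
static double tparms[7];

void init_two_site(void (*odeparms)(int *, double *))
{
    int n = 7;
    odeparms(&n, tparms);
}

/* y[0], y[1]: response bound at site 1 / site 2; each site is an
 * independent Langmuir surface, both ka in M^-1 s^-1.
 */
void derivs_two_site(int *neq, double *t, double *y, double *ydot,
                     double *yout, int *ip)
{
    double ka1 = tparms[0], kd1 = tparms[1], ka2 = tparms[2],
           kd2 = tparms[3], b1 = tparms[4], b2 = tparms[5],
           conc = tparms[6];
    ydot[0] = ka1 * conc * (b1 - y[0]) - kd1 * y[0];
    ydot[1] = ka2 * conc * (b2 - y[1]) - kd2 * y[1];
}

static const R_CMethodDef cMethods[] = {
    {"derivs_bivalent", (DL_FUNC) &derivs_bivalent, 6, NULL},
    {"derivs_two_site", (DL_FUNC) &derivs_two_site, 6, NULL},
    {NULL, NULL, 0, NULL}
};

void R_init_epibind(DllInfo *dll)
{
    R_registerRoutines(dll, cMethods, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
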