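/* Compiled right-hand sides for the four organoid growth models,
 * in the deSolve compiled-model convention (initfunc + derivs).
 *
 * State is in cell counts, time in days.  Parameter layouts must match
 * the R-side callers in R/kinetics.R exactly.
 */
#include <R.h>
#include <math.h>

static double parms[10];

/* Gaussian chemo kill pulse C(t) = a * exp(-b * (t - Tc)^2) */
static double chemo_rate(double t, double a, double b, double Tc)
{
    double dt = t - Tc;
    return a * exp(-b * dt * dt);
}

/* Two-wave radiation kill pulse, unit (1 day^2) Gaussian widths */
static double radio_rate(double t, double u1, double u2, double T1, double T2)
{
    double d1 = t - T1, d2 = t - T2;
    return u1 * exp(-d1 * d1) + u2 * exp(-d2 * d2);
}

/* ---- logistic: parms = lam, K ---- */
void pdto_init_logistic(void (*odeparms)(int *, double *))
{
    int n = 2;
    odeparms(&n, parms);
}

void pdto_d_logistic(int *neq, double *t, double *y, double *ydot,
                     double *yout, int *ip)
{
    double lam = parms[0], K = parms[1];
    ydot[0] = lam * y[0] * (1.0 - y[0] / K);
}

/* ---- chemo: parms = lam, K, a, b, Tc ---- */
void pdto_init_chemo(void (*odeparms)(int *, double *))
{
    int n = 5;
    odeparms(&n, parms);
}

void pdto_d_chemo(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    double lam = parms[0], K = parms[1];
    double C = chemo_rate(*t, parms[2], parms[3], parms[4]);
    ydot[0] = (lam - C) * y[0] * (1.0 - y[0] / K);
}

/* ---- radio: parms = lam, K, u1, u2, T1, T2, mu; state = (A, I) ---- */
void pdto_init_radio(void (*odeparms)(int *, double *))
{
    int n = 7;
    odeparms(&n, parms);
}

void pdto_d_radio(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    double lam = parms[0], K = parms[1], mu = parms[6];
    double R = radio_rate(*t, parms[2], parms[3], parms[4], parms[5]);
    double g = 1.0 - (y[0] + y[1]) / K;
    ydot[0] = (lam - R) * y[0] * g;
    ydot[1] = R * y[0] * g - mu * y[1];
}

/* ---- chemoradiation: parms = lam, K, a, b, Tc, u1, u2, T1, T2, mu;
 *      state = (A, I); chemo kill acts on active cells only ---- */
void pdto_init_crt(void (*odeparms)(int *, double *))
{
    int n = 10;
    odeparms(&n, parms);
}

void pdto_d_crt(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    double lam = parms[0], K = parms[1], mu = parms[9];
    double C = chemo_rate(*t, parms[2], parms[3], parms[4]);
    double R = radio_rate(*t, parms[5], parms[6], parms[7], parms[8]);
    double g = 1.0 - (y[0] + y[1]) / K;
    ydot[0] = (lam - R - C) * y[0] * g;
    ydot[1] = R * y[0] * g - mu * y[1];
}
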