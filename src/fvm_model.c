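/* Compiled finite-volume right-hand side for the invasion model
 *
 *   du/dt = T(t) [ d/dx ( D(u) du/dx ) + R(u) ],  zero-flux boundaries,
 *
 * on an equally spaced vertex-centred mesh (half control volumes at the
 * boundaries), called directly by deSolve's integrators so no R-level
 * function call happens per step. Mechanism forms and parameters arrive
 * through the parms vector:
 *
 *   p[0]  dx
 *   p[1]  K
 *   p[2]  delay form: 0 none, 1 logistic, 2 probit, 3 cloglog
 *   p[3]  alpha1   p[4]  alpha2
 *   p[5]  diffusivity form: 0 constant, 1 porous, 2 generalized, 3 extended
 *   p[6..10]  beta1..beta5
 *   p[11] reaction form: 0 logistic, 1 gompertz, 2 richards
 *   p[12] gamma1  p[13] gamma2
 *
 * Densities are clipped at zero when evaluating D and R (fractional-power
 * diffusivities are undefined for negative u, and small undershoots are
 * mesh artifacts). Genuinely pathological parameters still produce
 * NaN/overflow, which the integrator reports as a failed solve.
 */

#include <R.h>
#include <Rmath.h>

static double parms[14];

void mechdisc_initmod(void (*odeparms)(int *, double *))
{
    int n = 14;
    odeparms(&n, parms);
}

static double eval_T(double t)
{
    double a1 = parms[3], a2 = parms[4];
    switch ((int) parms[2]) {
    case 1:  return 1.0 / (1.0 + exp(-a1 - a2 * t));
    case 2:  return pnorm(a1 + a2 * t, 0.0, 1.0, 1, 0);
    case 3:  return 1.0 - exp(-exp(a1 + a2 * t));
    default: return 1.0;
    }
}

static double eval_D(double u)
{
    double s = u / parms[1];
    switch ((int) parms[5]) {
    case 1:  return parms[6] * s;
    case 2:  return parms[6] + parms[7] * R_pow(s, parms[8]);
    case 3:  return parms[6] + parms[7] * R_pow(s, parms[8]) +
                    parms[9] * R_pow(s, parms[10]);
    default: return parms[6];
    }
}

static double eval_R(double u)
{
    double K = parms[1], g1 = parms[12];
    switch ((int) parms[11]) {
    case 1:  return u <= 0.0 ? 0.0 : g1 * u * log(K / u);
    case 2:  return g1 * u * (1.0 - R_pow(u / K, parms[13]));
    default: return g1 * u * (1.0 - u / K);
    }
}

static double clip0(double u) { return u > 0.0 ? u : 0.0; }

void mechdisc_derivs(int *neq, double *t, double *y, double *ydot,
                     double *yout, int *ip)
{
    int Np = *neq, i;
    double dx = parms[0];
    double T = eval_T(*t);
    double D_prev = eval_D(clip0(y[0]));
    double flux_w = 0.0;

    for (i = 0; i < Np - 1; i++) {
        double D_next = eval_D(clip0(y[i + 1]));
        double flux_e = 0.5 * (D_prev + D_next) * (y[i + 1] - y[i]) / dx;
        if (i == 0)
            ydot[0] = T * (2.0 / dx * flux_e + eval_R(clip0(y[0])));
        else
            ydot[i] = T * ((flux_e - flux_w) / dx + eval_R(clip0(y[i])));
        flux_w = flux_e;
        D_prev = D_next;
    }
    ydot[Np - 1] = T * (-2.0 / dx * flux_w + eval_R(clip0(y[Np - 1])));
    (void) yout; (void) ip;
}
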