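/* Compiled right-hand sides for the tumor-immune checkpoint system,
 * called by deSolve's lsoda through the compiled-function interface.
 *
 * Shared base parameter order (indices 0..12):
 *   r, eta, delta, lambda_T, d_T, c1, c2, K_A1, K_A2, K_TQ, q0, d_A1, d_A2
 * Constant-epsilon mode appends eps at index 13 (14 total).
 * Dynamic mode appends k_basal, K_V, alpha_A1, alpha_A2, d_eps (18 total).
 * State order: V, T, A1, A2 [, eps].
 */

#include <R.h>

static double p_const[14];
static double p_dyn[18];

void pdl1_init_const(void (*odeparms)(int *, double *))
{
    int n = 14;
    odeparms(&n, p_const);
}

void pdl1_init_dyn(void (*odeparms)(int *, double *))
{
    int n = 18;
    odeparms(&n, p_dyn);
}

static void base_core(const double *y, double eps, const double *p, double *ydot)
{
    double V = y[0], T = y[1], A1 = y[2], A2 = y[3];
    double phi = p[5] * A1 / (p[5] * A1 + p[7]);
    double Q = p[10] * T * (T + eps * V) * (1.0 - phi);
    double sat2 = p[6] * A2 / (p[8] + p[6] * A2);
    double F = (p[2] + p[3] * T * sat2) / (1.0 + Q / p[9]);

    ydot[0] = p[0] * V - p[1] * V * T;
    ydot[1] = F - p[4] * T;
    ydot[2] = -p[11] * A1;
    ydot[3] = -p[12] * A2;
}

void pdl1_derivs_const(int *neq, double *t, double *y, double *ydot,
                       double *yout, int *ip)
{
    base_core(y, p_const[13], p_const, ydot);
}

void pdl1_derivs_dyn(int *neq, double *t, double *y, double *ydot,
                     double *yout, int *ip)
{
    const double *p = p_dyn;
    double V = y[0], A1 = y[2], A2 = y[3], eps = y[4];

    base_core(y, eps, p, ydot);

    {
        double satV = V / (p[14] + V);
        double sat2 = p[6] * A2 / (p[8] + p[6] * A2);
        double phi = p[5] * A1 / (p[5] * A1 + p[7]);
        ydot[4] = p[13] * satV + p[16] * satV * sat2
                  - p[15] * phi * eps - p[17] * eps;
    }
}
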