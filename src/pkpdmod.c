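/* Coupled PK/PD right-hand side for deSolve.
 *
 * States (amounts per kg body weight unless noted):
 *   y[0] Aa    absorption depot (ng/kg)
 *   y[1] A1    central compartment (ng/kg)
 *   y[2] A2    first peripheral compartment (ng/kg)
 *   y[3] A3    second peripheral compartment (ng/kg)
 *   y[4] Eact  active thromboxane synthase (ng)
 *
 * Parameters (order fixed, see R/solver.R):
 *   0 ka     1/h
 *   1 v      ml/kg
 *   2 vmax   ng/h/kg   (Michaelis-Menten elimination)
 *   3 km     ng/ml
 *   4 cl     ml/h/kg   (linear elimination)
 *   5 k12, 6 k21, 7 k13, 8 k31   1/h inter-compartment rates
 *   9 ksyn   ng/h
 *  10 kdeg   1/h
 *  11 kirr   ml/ng/h  (second-order irreversible inactivation)
 *  12 elim_mm   1 = Michaelis-Menten, 0 = linear
 *  13 pd_on     1 = integrate Eact, 0 = hold at 0 derivative
 */

#include <R.h>

static double parms[14];

void txspkpd_initmod(void (*odeparms)(int *, double *))
{
    int n = 14;
    odeparms(&n, parms);
}

void txspkpd_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    double ka = parms[0], v = parms[1], vmax = parms[2], km = parms[3];
    double cl = parms[4];
    double k12 = parms[5], k21 = parms[6], k13 = parms[7], k31 = parms[8];
    double ksyn = parms[9], kdeg = parms[10], kirr = parms[11];
    int elim_mm = parms[12] != 0.0;
    int pd_on = parms[13] != 0.0;

    double conc = y[1] / v;
    double elim = elim_mm ? vmax * conc / (km + conc) : cl * conc;

    ydot[0] = -ka * y[0];
    ydot[1] = ka * y[0] - elim
        - k12 * y[1] + k21 * y[2]
        - k13 * y[1] + k31 * y[3];
    ydot[2] = k12 * y[1] - k21 * y[2];
    ydot[3] = k13 * y[1] - k31 * y[3];
    ydot[4] = pd_on ? ksyn - kdeg * y[4] - kirr * conc * y[4] : 0.0;
}
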