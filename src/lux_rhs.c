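/* Compiled right-hand side of the bacterial luciferase single-turnover
 * scheme, in the deSolve compiled-model convention.
 *
 * States (µM):
 *   y[0] F    free reduced flavin (FMNH2)
 *   y[1] E    free luciferase
 *   y[2] I1   E.FMNH2            (Intermediate I)
 *   y[3] I2   E.FMNHOOH          (Intermediate II, C(4a)-hydroperoxyflavin)
 *   y[4] A    free aldehyde (decanal)
 *   y[5] I2A  E.FMNOOH.RCOH      (Intermediate IIA)
 *   y[6] Q    cumulative emitted-quanta proxy (integral of k4*I2A)
 *   y[7] Sd   flavin lost to autoxidation   (integral of kd*F)
 *   y[8] Sdd  flavin lost to dark decay     (integral of kdd*I2)
 *
 * Sd/Sdd are bookkeeping sinks: F+I1+I2+I2A+Q+Sd+Sdd is conserved at F0
 * and E+I1+I2+I2A at E0 (enzyme is released by the dark-decay and
 * catalytic steps). Oxygen is folded into the pseudo-first-order k2.
 */
#include <R.h>

static double parms[8];
#define kd   parms[0]
#define kdd  parms[1]
#define k1   parms[2]
#define k2   parms[3]
#define k3   parms[4]
#define km3  parms[5]
#define k4   parms[6]
#define km1  parms[7]   /* 0 in the default irreversible model */

void lux_initmod(void (*odeparms)(int *, double *))
{
    int n = 8;
    odeparms(&n, parms);
}

void lux_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    double F = y[0], E = y[1], I1 = y[2], I2 = y[3], A = y[4], I2A = y[5];
    double bind1 = k1 * E * F;      /* flavin binding     */
    double bind3 = k3 * I2 * A;     /* aldehyde binding   */

    ydot[0] = -bind1 - kd * F + km1 * I1;                    /* F   */
    ydot[1] = -bind1 + kdd * I2 + k4 * I2A + km1 * I1;       /* E   */
    ydot[2] =  bind1 - k2 * I1 - km1 * I1;                   /* I1  */
    ydot[3] =  k2 * I1 - kdd * I2 - bind3 + km3 * I2A;       /* I2  */
    ydot[4] = -bind3 + km3 * I2A;                            /* A   */
    ydot[5] =  bind3 - km3 * I2A - k4 * I2A;                 /* I2A */
    ydot[6] =  k4 * I2A;                                     /* Q   */
    ydot[7] =  kd * F;                                       /* Sd  */
    ydot[8] =  kdd * I2;                                     /* Sdd */
}
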