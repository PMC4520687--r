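/* Three-state 6-MP metabolism right-hand side for deSolve.
 *
 * States: x_g (6-MP in gut, pmol), x_c (6-MP in plasma, pmol),
 *         x_m (6-TGN in RBCs, pmol / 8e8 RBCs).
 * Parms (in order): k_ab, k_el, k_cm, K, k_me, nu_cm, infusion.
 * Oral boluses are handled as deSolve "add" events on x_g from the R side.
 */
#include <R.h>

static double parms[7];
#define k_ab  parms[0]
#define k_el  parms[1]
#define k_cm  parms[2]
#define Km    parms[3]
#define k_me  parms[4]
#define nu_cm parms[5]
#define d_in  parms[6]

void pk6mp_init(void (*odeparms)(int *, double *))
{
    int n = 7;
    odeparms(&n, parms);
}

void pk6mp_deriv(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    double conv = k_cm * y[1] / (Km + y[1]);
    ydot[0] = -k_ab * y[0] + d_in;
    ydot[1] =  k_ab * y[0] - k_el * y[1] - conv;
    ydot[2] =  nu_cm * conv - k_me * y[2];
}
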