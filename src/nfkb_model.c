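/* Right-hand side of the reduced 6-variable NF-kB model, in the
 * parameter/state layout used by deSolve's compiled-code interface.
 * Time unit is seconds; all variables are non-dimensional fractions.
 *
 * parms: 13 rate constants, then TR (TNF indicator, 0/1) and A20KO
 * (1 zeroes the A20 synthesis term, realizing the A20 knockout).
 */
#include <R.h>

static double parms[15];

#define k_deg  parms[0]
#define k1     parms[1]
#define k2     parms[2]
#define k3     parms[3]
#define a2     parms[4]
#define a3     parms[5]
#define delta  parms[6]
#define eps    parms[7]
#define c_deg  parms[8]
#define c4a    parms[9]
#define c5a    parms[10]
#define c3a    parms[11]
#define i1a    parms[12]
#define TR     parms[13]
#define A20KO  parms[14]

void nfkb_initmod(void (* odeparms)(int *, double *))
{
    int n = 15;
    odeparms(&n, parms);
}

void nfkb_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    double IKKn  = y[0], IKKa = y[1], NFkBn = y[2];
    double A20   = y[3], IkBa = y[4], IkBat = y[5];

    /* IKKa-driven degradation of IkBa bound in (NFkB|IkBa) complexes
     * (complex level = 1 - NFkBn) releases NFkB; the Michaelis-type
     * factor delta/(IkBa+delta) is the fraction escaping recapture by
     * free IkBa, IkBa/(IkBa+delta) the fraction consuming free IkBa. */
    double release = a3 * IKKa * (1.0 - NFkBn);
    /* IkBa nuclear import removing nuclear NFkB */
    double import  = i1a * IkBa * NFkBn / (NFkBn + eps);

    ydot[0] = k_deg - k_deg * IKKn - TR * k1 * IKKn;
    ydot[1] = TR * k1 * IKKn - (k3 + k_deg + TR * k2 * A20) * IKKa;
    ydot[2] = release * delta / (IkBa + delta) - import;
    ydot[3] = (1.0 - A20KO) * c_deg * NFkBn - c_deg * A20;
    ydot[4] = c4a * IkBat - c5a * IkBa - a2 * IKKa * IkBa
              - release * IkBa / (IkBa + delta) - import;
    ydot[5] = c3a * NFkBn - c3a * IkBat;
}
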