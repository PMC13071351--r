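/* Right-hand side of the meta-ecosystem ODE system, compiled for deSolve.
 *
 * State layout: y = (N_1..N_n, P_1..P_n, C_1..C_n).
 * Parameter vector layout (packed by pack_parms() on the R side, padded to
 * NPARMS so the initializer length is fixed):
 *   [0]      n (patch count, <= MAXN)
 *   [1..11]  I_N, e_N, m_P, m_C, a_P, b_P, a_C, b_C, r_P, r_C, d_N
 *   [12]     d_P (producer spatial-flow rate; 0 in the default model)
 *   [13..13+n-1]      per-patch consumer dispersal rates d_C[i]
 *   [13+n .. ]        S_N, S_C, S_P column-major n x n connectivity matrices
 *                     (rows = receiving patch, column sums zero)
 */
#include <R.h>

#define MAXN 16
#define NPARMS (13 + MAXN + 3 * MAXN * MAXN)

static double parms[NPARMS];

void metanest_initmod(void (*odeparms)(int *, double *))
{
    int n = NPARMS;
    odeparms(&n, parms);
}

void metanest_derivs(int *neq, double *t, double *y, double *ydot,
                     double *yout, int *ip)
{
    const int n = (int) parms[0];
    const double IN = parms[1], eN = parms[2], mP = parms[3], mC = parms[4],
                 aP = parms[5], bP = parms[6], aC = parms[7], bC = parms[8],
                 rP = parms[9], rC = parms[10], dN = parms[11],
                 dP = parms[12];
    const double *dC = parms + 13;
    const double *SN = parms + 13 + n;
    const double *SC = SN + n * n;
    const double *SP = SC + n * n;
    const double *N = y, *P = y + n, *C = y + 2 * n;
    int i, j;

    for (i = 0; i < n; i++) {
        double fP = aP * N[i] / (bP + N[i]);
        double fC = aC * P[i] / (bC + P[i]);
        double sN = 0.0, sC = 0.0, sP = 0.0;
        for (j = 0; j < n; j++) {
            sN += SN[i + n * j] * N[j];
            sC += SC[i + n * j] * C[j];
            sP += SP[i + n * j] * P[j];
        }
        ydot[i]         = IN - eN * N[i] + mP * rP * P[i] + mC * rC * C[i]
                          - P[i] * fP + dN * sN;
        ydot[n + i]     = P[i] * fP - mP * P[i] - C[i] * fC + dP * sP;
        ydot[2 * n + i] = C[i] * fC - mC * C[i] + dC[i] * sC;
    }
}
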