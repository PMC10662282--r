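/* Compiled right-hand side of the nitrogen-enzyme ODE system for deSolve's
 * compiled-model interface. Mirrors the reference implementation in
 * R/kinetics.R (codeal_rhs) exactly; the test suite pins the two together.
 *
 * State layout: y[0..5] six inorganic N pools (NH4,NO3,NO2,NO,N2O,N2),
 * y[6..11] enzyme pools (same substrate order), y[12] organic N,
 * y[13] cumulative boundary inputs, y[14] cumulative exports.
 *
 * Parameter vector (26): Vmax[6], Ks[6], pEP, rE, kmin, Vup_NH4, Vup_NO3,
 * Kup_NH4, Kup_NO3, gNO, gN2O, N2_boundary, dynamic_n2, bnf_inhibition,
 * alloc_floor, scheme (0=A0, 1=A1, 2=A2).
 *
 * Forcings (5, linearly interpolated by deSolve): B, I_NH4, I_NO3, L,
 * fplant.
 */
#include <R.h>

static double p[26];
static double forc[5];

void codeal_initmod(void (*odeparms)(int *, double *))
{
    int N = 26;
    odeparms(&N, p);
}

void codeal_initforc(void (*odeforcs)(int *, double *))
{
    int N = 5;
    odeforcs(&N, forc);
}

void codeal_derivs(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    const double *Vmax = p, *Ks = p + 6;
    const double pEP = p[12], rE = p[13], kmin = p[14];
    const double Vup1 = p[15], Vup2 = p[16], Kup1 = p[17], Kup2 = p[18];
    const double gNO = p[19], gN2O = p[20], N2b = p[21];
    const int dynamic = (int) p[22], inhib = (int) p[23];
    const double flr = p[24];
    const int scheme = (int) p[25];
    const double B = forc[0], I1 = forc[1], I2 = forc[2], L = forc[3],
                 fp = forc[4];
    double N[6], E[6], sat[6], Fe[6], w[6], sw = 0.0;
    int i;

    for (i = 0; i < 6; i++) {
        N[i] = y[i] > 0 ? y[i] : 0;
        E[i] = y[6 + i] > 0 ? y[6 + i] : 0;
    }
    if (!dynamic) N[5] = N2b;
    for (i = 0; i < 6; i++) {
        sat[i] = N[i] / (Ks[i] + N[i]);
        Fe[i] = Vmax[i] * E[i] * sat[i];
        double Nf = N[i] < flr ? flr : N[i];
        w[i] = scheme == 0 ? Nf : (scheme == 1 ? Nf / Ks[i] : Ks[i] / Nf);
        sw += w[i];
    }
    if (inhib) Fe[5] *= 1 - sat[0];

    double ON = y[12] > 0 ? y[12] : 0;
    double Fmin = kmin * ON;
    double U1 = Vup1 * fp * N[0] / (Kup1 + N[0]);
    double U2 = Vup2 * fp * N[1] / (Kup2 + N[1]);
    double GNO = gNO * N[3], GN2O = gN2O * N[4];

    ydot[0] = Fmin + Fe[5] - Fe[0] - U1 + I1;
    ydot[1] = Fe[0] - Fe[1] - U2 + I2;
    ydot[2] = Fe[1] - Fe[2];
    ydot[3] = Fe[2] - Fe[3] - GNO;
    ydot[4] = Fe[3] - Fe[4] - GN2O;
    ydot[5] = dynamic ? Fe[4] - Fe[5] : 0;
    for (i = 0; i < 6; i++)
        ydot[6 + i] = (w[i] / sw) * pEP * B - rE * E[i];
    ydot[12] = L - Fmin;
    ydot[13] = I1 + I2 + L + (dynamic ? 0 : Fe[5]);
    ydot[14] = U1 + U2 + GNO + GN2O + (dynamic ? 0 : Fe[4]);
}
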