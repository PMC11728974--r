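/* Compiled right-hand side of the cybernetic eicosanoid model for deSolve.
 *
 * The parameter vector packed by the R side (see pack_parms() in
 * R/simulate.R) carries the variant id, the control switch, the kinetic
 * constants in a fixed order per variant, and the tabulated input profiles
 * (piecewise-linear, constant extrapolation). State ordering matches
 * cyber_network$state_names.
 */

#include <R.h>
#include <math.h>

#define CYBERLIPID_PARMS_LEN 512

static double p[CYBERLIPID_PARMS_LEN];

void cyberlipid_init(void (*odeparms)(int *, double *))
{
    int n = CYBERLIPID_PARMS_LEN;
    odeparms(&n, p);
}

/* linear interpolation with constant extrapolation, clipped at 0 */
static double interp_input(double t, int n, const double *tg, const double *vg)
{
    double v;
    int i;
    if (n == 1 || t <= tg[0]) v = vg[0];
    else if (t >= tg[n - 1]) v = vg[n - 1];
    else {
        for (i = 1; tg[i] < t; i++) ;
        v = vg[i - 1] + (vg[i] - vg[i - 1]) * (t - tg[i - 1]) / (tg[i] - tg[i - 1]);
    }
    return v > 0 ? v : 0;
}

static double mm(double k, double Km, double S)
{
    double den = Km + S;
    if (den <= 0) return R_NaN; /* 0/0 guard: poisons the step */
    return k * S / den;
}

void cyberlipid_derivs(int *neq, double *t, double *y, double *ydot,
                       double *yout, int *ip)
{
    int variant = (int) p[0];
    int cybernetic = (int) p[1];
    double kATP = p[2], dATP = p[3], ATP0 = p[4];
    const double *k = p + 5;
    int ngrid = (int) p[40];
    const double *tg = p + 41;
    const double *AAg = tg + ngrid;
    const double *O3g = AAg + ngrid;

    double AA = interp_input(*t, ngrid, tg, AAg);
    double O3 = interp_input(*t, ngrid, tg, O3g);
    double ATP = ATP0 * exp(-dATP * *t);
    double atpf = 1 + kATP * ATP;

    double yc[13];
    int i, ns = *neq;
    for (i = 0; i < ns; i++) yc[i] = y[i] > 0 ? y[i] : 0;

    if (variant == 1) {
        /* EPA variant: states PGH2 PGD2 PGE2 PGJ2 dPGD2 dhkPGD2 PGH3 PGD3
         * PGE3 eCOX ePtgds ePtges edhkPGD2; constants k[0..34]:
         * kPGH2 kPGH3 kPGD2 kPGD3 kPGE2 kPGE3 kdhkPGD2 kPGJ2 kdPGD2
         * gPGH2 gPGH3 gPGD2 gPGD3 gPGE2 gPGE3 gPGJ2 gdPGD2 gdhkPGD2
         * aCOX bCOX kePGH2 KmAA kePGH3 KmEPA
         * aPtgds bPtgds kePtgds KmPtgds aPtges bPtges kePtges KmPtges
         * bdhk kedhk Kmdhk */
        double PGH2 = yc[0], PGD2 = yc[1], PGE2 = yc[2], PGJ2 = yc[3],
               dPGD2 = yc[4], dhk = yc[5], PGH3 = yc[6], PGD3 = yc[7],
               PGE3 = yc[8], eCOX = yc[9], ePtgds = yc[10], ePtges = yc[11],
               edhk = yc[12];
        double rho1 = k[0] * eCOX * AA;
        double rho2 = k[1] * eCOX * O3;
        double tot = rho1 + rho2;
        double u1 = 0.5, u2 = 0.5, v1 = 1, v2 = 1;
        if (cybernetic && tot > 0) {
            double m = rho1 > rho2 ? rho1 : rho2;
            u1 = rho1 / tot; u2 = rho2 / tot;
            v1 = rho1 / m;   v2 = rho2 / m;
        }
        double S23 = PGH2 + PGH3;
        ydot[0] = v1 * k[0] * AA * eCOX * atpf - k[9] * PGH2
                  - k[2] * PGH2 * ePtgds - k[4] * PGH2 * ePtges;
        ydot[6] = v2 * k[1] * O3 * eCOX * atpf - k[10] * PGH3
                  - k[3] * PGH3 * ePtgds - k[5] * PGH3 * ePtges;
        ydot[1] = k[2] * PGH2 * ePtgds - k[11] * PGD2 - k[6] * PGD2 * edhk
                  - k[7] * PGD2 - k[8] * PGD2;
        ydot[7] = k[3] * PGH3 * ePtgds - k[12] * PGD3;
        ydot[2] = k[4] * PGH2 * ePtges - k[13] * PGE2;
        ydot[8] = k[5] * PGH3 * ePtges - k[14] * PGE3;
        ydot[3] = k[7] * PGD2 - k[15] * PGJ2;
        ydot[4] = k[8] * PGD2 - k[16] * dPGD2;
        ydot[5] = k[6] * PGD2 * edhk - k[17] * dhk;
        ydot[9] = k[18] + u1 * mm(k[20], k[21], AA) + u2 * mm(k[22], k[23], O3)
                  - k[19] * eCOX;
        ydot[10] = k[24] + mm(k[26], k[27], S23) - k[25] * ePtgds;
        ydot[11] = k[28] + mm(k[30], k[31], S23) - k[29] * ePtges;
        ydot[12] = mm(k[33], k[34], PGD2) - k[32] * edhk;
    } else {
        /* DHA variant: states PGH2 PGD2 PGE2 PGJ2 dPGD2 dhkPGD2 PD eCOX
         * ePtgds ePtges edhkPGD2; constants k[0..30]:
         * kPGH2 kPD kPGD2 kPGE2 kdhkPGD2 kPGJ2 kdPGD2
         * gPGH2 gPD gPGD2 gPGE2 gPGJ2 gdPGD2 gdhkPGD2
         * aCOX bCOX kePGH2 KmAA kePD KmDHA
         * aPtgds bPtgds kePtgds KmPtgds aPtges bPtges kePtges KmPtges
         * bdhk kedhk Kmdhk */
        double PGH2 = yc[0], PGD2 = yc[1], PGE2 = yc[2], PGJ2 = yc[3],
               dPGD2 = yc[4], dhk = yc[5], PD = yc[6], eCOX = yc[7],
               ePtgds = yc[8], ePtges = yc[9], edhk = yc[10];
        double rho1 = k[0] * eCOX * AA;
        double rho2 = k[1] * eCOX * O3;
        double tot = rho1 + rho2;
        double u1 = 0.5, u2 = 0.5, v1 = 1, v2 = 1;
        if (cybernetic && tot > 0) {
            double m = rho1 > rho2 ? rho1 : rho2;
            u1 = rho1 / tot; u2 = rho2 / tot;
            v1 = rho1 / m;   v2 = rho2 / m;
        }
        ydot[0] = v1 * k[0] * AA * eCOX * atpf - k[7] * PGH2
                  - k[2] * PGH2 * ePtgds - k[3] * PGH2 * ePtges;
        ydot[6] = v2 * k[1] * O3 * eCOX * atpf - k[8] * PD;
        ydot[1] = k[2] * PGH2 * ePtgds - k[9] * PGD2 - k[4] * PGD2 * edhk
                  - k[5] * PGD2 - k[6] * PGD2;
        ydot[2] = k[3] * PGH2 * ePtges - k[10] * PGE2;
        ydot[3] = k[5] * PGD2 - k[11] * PGJ2;
        ydot[4] = k[6] * PGD2 - k[12] * dPGD2;
        ydot[5] = k[4] * PGD2 * edhk - k[13] * dhk;
        ydot[7] = k[14] + u1 * mm(k[16], k[17], AA) + u2 * mm(k[18], k[19], O3)
                  - k[15] * eCOX;
        ydot[8] = k[20] + mm(k[22], k[23], PGH2) - k[21] * ePtgds;
        ydot[9] = k[24] + mm(k[26], k[27], PGH2) - k[25] * ePtges;
        ydot[10] = mm(k[29], k[30], PGD2) - k[28] * edhk;
    }
}
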