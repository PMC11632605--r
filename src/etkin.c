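/* Compiled right-hand side of the two-compartment ET-1 kinetics model.
 *
 * States (concentrations pmol/L unless noted):
 *   y[0] BigET   tissue Big ET-1
 *   y[1] Tt      total (free + bound) ET-1, tissue
 *   y[2] Tp      total (free + bound) ET-1, plasma
 *   y[3] I       antagonist plasma concentration (one-compartment PK)
 *   y[4] Ce      antagonist effect-compartment concentration (PD delay)
 *   y[5] cumCl   cumulative ET-1 amount cleared by internalization (pmol)
 *   y[6] cumPr   cumulative ET-1 amount produced from Big ET-1 (pmol)
 *
 * Parameters (see R/kinetics.R for packing):
 *   0 Kd  1 Vp  2 Vt  3 Kpt  4 Ktp  5 Kint
 *   6 RAp 7 RBp 8 RAt 9 RBt
 *   10 ProdBigET (pmol/L/min)  11 kconv (/min)
 *   12 Kia  13 Kib           (<= 0 encodes infinite affinity constant,
 *                             i.e. no inhibition of that receptor)
 *   14 ke0  (<= 0: no effect compartment, tissue sees plasma I)
 *   15 inf_ET1 (pmol/min)  16 inf_BigET (pmol/min)  17 inf_antag (pmol/min)
 *   18 kel_antag (/min)  19 V_antag (L)
 *   20 step_mode (0/1)   21 I_step (pmol/L, used when step_mode == 1)
 */
#include <R.h>
#include <math.h>

#define NPARMS 22
static double parms[NPARMS];

void etkin_init(void (*odeparms)(int *, double *))
{
    int n = NPARMS;
    odeparms(&n, parms);
}

/* free ligand u from total T with two receptor classes at effective
 * dissociation constants KdA, KdB: safeguarded Newton with bisection
 * fallback on [0, T]; g(u) is strictly increasing. */
static double free_ligand_c(double T, double RA, double RB,
                            double KdA, double KdB)
{
    double lo, hi, u, b, disc, gu, dg, un;
    int i;
    if (T <= 0.0) return 0.0;
    if (KdA == KdB || RB == 0.0 || RA == 0.0) {
        /* collapse to the quadratic; pick the class that is present */
        double R = RA + RB;
        double Kq = (RA > 0.0) ? KdA : KdB;
        if (RA > 0.0 && RB > 0.0) Kq = KdA; /* equal case */
        if (R == 0.0) return T;
        b = T - R - Kq;
        disc = sqrt(b * b + 4.0 * Kq * T);
        u = (b >= 0.0) ? 0.5 * (b + disc) : 2.0 * Kq * T / (disc - b);
        if (u < 0.0) u = 0.0;
        if (u > T) u = T;
        return u;
    }
    lo = 0.0; hi = T;
    b = T - (RA + RB) - (KdA < KdB ? KdA : KdB);
    {
        double Kq = (KdA < KdB ? KdA : KdB);
        disc = sqrt(b * b + 4.0 * Kq * T);
        u = (b >= 0.0) ? 0.5 * (b + disc) : 2.0 * Kq * T / (disc - b);
    }
    if (u <= lo || u >= hi) u = 0.5 * T;
    for (i = 0; i < 100; i++) {
        gu = u + RA * u / (KdA + u) + RB * u / (KdB + u) - T;
        if (fabs(gu) <= 1e-12 * T) return u;
        if (gu > 0.0) hi = u; else lo = u;
        dg = 1.0 + RA * KdA / ((KdA + u) * (KdA + u))
                 + RB * KdB / ((KdB + u) * (KdB + u));
        un = u - gu / dg;
        u = (un <= lo || un >= hi) ? 0.5 * (lo + hi) : un;
    }
    return 0.5 * (lo + hi);
}

void etkin_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    double Kd = parms[0], Vp = parms[1], Vt = parms[2];
    double Kpt = parms[3], Ktp = parms[4], Kint = parms[5];
    double RAp = parms[6], RBp = parms[7], RAt = parms[8], RBt = parms[9];
    double ProdBigET = parms[10], kconv = parms[11];
    double Kia = parms[12], Kib = parms[13], ke0 = parms[14];
    double inf_ET1 = parms[15], inf_BigET = parms[16], inf_antag = parms[17];
    double kel = parms[18], Va = parms[19];
    int step_mode = (int) parms[20];
    double I_step = parms[21];

    double Ipl = step_mode ? I_step : y[3];
    double Itis = (ke0 > 0.0) ? y[4] : Ipl;

    double KdAp = (Kia > 0.0) ? Kd * (1.0 + Ipl / Kia) : Kd;
    double KdBp = (Kib > 0.0) ? Kd * (1.0 + Ipl / Kib) : Kd;
    double KdAt = (Kia > 0.0) ? Kd * (1.0 + Itis / Kia) : Kd;
    double KdBt = (Kib > 0.0) ? Kd * (1.0 + Itis / Kib) : Kd;

    double ut = free_ligand_c(y[1], RAt, RBt, KdAt, KdBt);
    double up = free_ligand_c(y[2], RAp, RBp, KdAp, KdBp);

    double CAt = RAt * ut / (KdAt + ut), CBt = RBt * ut / (KdBt + ut);
    double CAp = RAp * up / (KdAp + up), CBp = RBp * up / (KdBp + up);

    double ProdET1 = kconv * y[0] * Vt;            /* pmol/min */
    double clear_t = Kint * Vt * (CAt + CBt);      /* pmol/min */
    double clear_p = Kint * Vp * (CAp + CBp);      /* pmol/min */

    ydot[0] = ProdBigET - kconv * y[0] + inf_BigET / Vt;
    ydot[1] = (ProdET1 - Ktp * Vt * ut + Kpt * Vp * up - clear_t) / Vt;
    ydot[2] = (Ktp * Vt * ut - Kpt * Vp * up - clear_p + inf_ET1) / Vp;
    ydot[3] = step_mode ? 0.0 : inf_antag / Va - kel * y[3];
    ydot[4] = (ke0 > 0.0) ? ke0 * (Ipl - y[4]) : 0.0;
    ydot[5] = clear_t + clear_p;
    ydot[6] = ProdET1;

    if (ip[0] >= 6) {
        yout[0] = ut;  yout[1] = up;
        yout[2] = CAt; yout[3] = CBt;
        yout[4] = CAp; yout[5] = CBp;
    }
}
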