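/* Right-hand sides for the four IKKbeta phosphorylation model variants,
 * in the compiled-function form expected by deSolve.
 *
 * Parameter vector (filled by ikk_initmod):
 *   p[0]  variant code: 0 original, 1 traf, 2 double_phos, 3 irreversible_inhibitor
 *   p[1]  il_dose (nM)          p[2]  uv_on (0/1)        p[3]  onset time (s)
 *   p[4]  k_a   p[5] k_i   p[6] k_p   p[7] k_dp   p[8] k_uv
 *   p[9..11] extension rates (k_aut,k_du | k_ph1,k_ph2,k_dph | k_xa,k_inh)
 *
 * State vector (redundant conservation partners are integrated explicitly so
 * that conservation residuals measure true solver drift):
 *   y[0] ILR  y[1] ILRc  y[2] IKKp  y[3] PP2A  y[4] IKK
 *   traf:        y[5] Tu  y[6] T
 *   double_phos: y[5] Yp  y[6] Ypp  y[7] Y
 *   inhibitor:   y[5] X   y[6] Xa   y[7] I
 */
#include <R.h>

#define N_PARMS 12
static double p[N_PARMS];

void ikk_initmod(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, p);
}

void ikk_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    int variant = (int) p[0];
    double il = (*t >= p[3]) ? p[1] : 0.0;
    double uv = (*t >= p[3]) ? p[2] : 0.0;
    double k_a = p[4], k_i = p[5], k_p = p[6], k_dp = p[7], k_uv = p[8];
    double ILRc = y[1], IKKp = y[2], PP2A = y[3], IKK = y[4];
    double kin = ILRc;

    ydot[0] = -k_a * il * y[0];
    ydot[1] = k_a * il * y[0] - k_i * ILRc;
    ydot[3] = -k_uv * uv * PP2A;

    switch (variant) {
    case 1: {                   /* TRAF positive feedback */
        double k_aut = p[9], k_du = p[10];
        double Tu = y[5], T = y[6];
        ydot[5] = k_aut * (ILRc + Tu) * T - k_du * Tu;
        ydot[6] = -ydot[5];
        kin = Tu;
        break;
    }
    case 2: {                   /* double phosphorylation */
        double k_ph1 = p[9], k_ph2 = p[10], k_dph = p[11];
        double Yp = y[5], Ypp = y[6], Y = y[7];
        ydot[5] = k_ph1 * ILRc * Y - k_ph2 * ILRc * Yp;
        ydot[6] = k_ph2 * ILRc * Yp - k_dph * Ypp;
        ydot[7] = -k_ph1 * ILRc * Y + k_dph * Ypp;
        kin = Ypp;
        break;
    }
    case 3: {                   /* irreversible inhibitor */
        double k_xa = p[9], k_inh = p[10];
        double X = y[5], Xa = y[6], I = y[7];
        ydot[5] = -k_xa * ILRc * X;
        ydot[6] = k_xa * ILRc * X - k_inh * Xa * I;
        ydot[7] = -k_inh * Xa * I;
        kin = Xa;
        break;
    }
    default:
        break;                  /* original: kin = ILRc */
    }

    ydot[2] = k_p * kin * IKK - k_dp * PP2A * IKKp;
    ydot[4] = -ydot[2];
}
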