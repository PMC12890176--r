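/* Compiled right-hand side of the burn + local-irradiation model for
 * deSolve. Parameter vector: the 73 canonical parameters in the order of
 * rci_param_names(), followed by the radiation dose DR (Gy). State vector:
 * the 16 states in the order of rci_state_names(). Must stay in lockstep
 * with the reference R implementation rci_rhs(). */

#include <R.h>
#include <math.h>

#define N_PARMS 74

static double parms[N_PARMS];

/* inhibition saturations */
#define N1_inf      parms[0]
#define N2_inf      parms[1]
#define M11_inf     parms[2]
#define M12_inf     parms[3]
#define M2_inf      parms[4]
#define F_inf       parms[5]
#define L21_inf     parms[6]
#define L22_inf     parms[7]
#define Deb_dam_inf parms[8]
#define Deb_H       parms[9]
#define N_H         parms[10]
#define M1_H        parms[11]
/* radiation-related */
#define gamma_n     parms[12]
#define gamma_m     parms[13]
#define gamma_l     parms[14]
#define gamma_f     parms[15]
#define omega_m2    parms[16]
#define omega_f     parms[17]
#define omega_dam   parms[18]
/* damage / debris */
#define kdn         parms[19]
#define kdm1        parms[20]
#define rho_dam     parms[21]
#define kdf         parms[22]
#define kdnp        parms[23]
#define kdm1p       parms[24]
#define kdm2p       parms[25]
#define ddeb        parms[26]
/* neutrophils */
#define snr         parms[27]
#define dnr         parms[28]
#define knd         parms[29]
#define knp         parms[30]
#define knn         parms[31]
#define knm1p       parms[32]
#define knm2p       parms[33]
#define dn          parms[34]
/* monocytes / macrophages */
#define smr         parms[35]
#define dmr_ud      parms[36]
#define dmr_d       parms[37]
#define km1d        parms[38]
#define km1p        parms[39]
#define km1n        parms[40]
#define km1m1       parms[41]
#define km1l1       parms[42]
#define km2m1       parms[43]
#define km2m2       parms[44]
#define km2l2       parms[45]
#define theta_m1m2  parms[46]
#define dm1         parms[47]
#define dm2         parms[48]
/* lymphocytes */
#define slr         parms[49]
#define dlr_ud      parms[50]
#define dlr_d       parms[51]
#define kl1         parms[52]
#define kl2         parms[53]
#define dl          parms[54]
/* fibroblasts */
#define sf          parms[55]
#define ksttb_ud    parms[56]
#define ksttb_d     parms[57]
#define kf          parms[58]
#define alpha_dam   parms[59]
#define alpha_m2    parms[60]
#define dfr_ud      parms[61]
#define dfr_d       parms[62]
#define df          parms[63]
/* pathogen */
#define kpg         parms[64]
#define P_inf       parms[65]
#define kpb         parms[66]
#define sb          parms[67]
#define mu_b        parms[68]
#define kbp         parms[69]
#define kpn         parms[70]
#define kpm1        parms[71]
#define kpm2        parms[72]
/* exposure */
#define DOSE        parms[73]

void rci_initmod(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, parms);
}

static double sq(double x) { return x * x; }

/* Hill with exponent 6 (structural constant of the collateral terms). */
static double hill6(double x, double xh)
{
    double x6 = x * x * x;
    double h6 = xh * xh * xh;
    x6 *= x6;
    h6 *= h6;
    return x6 / (h6 + x6);
}

/* dose-dependent recovery of blood influx */
static double vfun(double t, double gamma)
{
    if (DOSE == 0.0) return 1.0;
    return 1.0 - exp(-gamma * DOSE * t);
}

void rci_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    /* clip at 0: phagocytosis terms can overshoot numerically */
    double N_st = fmax(y[0], 0.0), M_ud = fmax(y[1], 0.0);
    double M_d  = fmax(y[2], 0.0), F_ud = fmax(y[3], 0.0);
    double F_d  = fmax(y[4], 0.0), L_ud = fmax(y[5], 0.0);
    double L_d  = fmax(y[6], 0.0), Dam  = fmax(y[7], 0.0);
    double Deb  = fmax(y[8], 0.0), N    = fmax(y[9], 0.0);
    double M1   = fmax(y[10], 0.0), M2  = fmax(y[11], 0.0);
    double F    = fmax(y[12], 0.0), L1  = fmax(y[13], 0.0);
    double L2   = fmax(y[14], 0.0), P   = fmax(y[15], 0.0);

    double inh_m2l2 = 1.0 + sq(M2 / M2_inf) + sq(L2 / L21_inf);
    double Rn  = (knd * Deb + knp * P + knn * N) / inh_m2l2;
    double Rm1 = (km1d * Deb + km1p * P + km1n * N + km1m1 * M1 +
                  km1l1 * L1) / inh_m2l2;
    double Rm2 = (km2m1 * M1 + km2m2 * M2 + km2l2 * L2) /
        (1.0 + sq(N / N1_inf) + sq(M1 / M11_inf) + sq(F / F_inf));
    double Rl1 = (kl1 * M1) / (1.0 + sq(L2 / L21_inf));
    double Rl2 = (kl2 * M2) / (1.0 + sq(F / F_inf));

    /* M2 activation inhibited by damaged macrophages only for DR >= 2 Gy */
    double Rm2_eff = (DOSE >= 2.0) ? Rm2 / (1.0 + sq(M_d / omega_m2)) : Rm2;

    double l2inh = 1.0 + sq(L2 / L22_inf);
    double gen_n  = kdn * hill6(N / l2inh, N_H);
    double gen_m1 = kdm1 * hill6(M1 / l2inh, M1_H);

    double res_core = Dam / (1.0 + sq(Deb / Deb_dam_inf));
    double deb_sat = Deb / (Deb_H + Deb);
    double inh_n1 = 1.0 + sq(N / N1_inf);
    double m1_phag = knm1p * N * (M1 / inh_n1);

    /* damage & debris */
    ydot[7] = gen_n + gen_m1 - rho_dam * res_core -
        (F / (1.0 + sq(F_d / omega_dam))) * kdf * res_core;
    ydot[8] = gen_n + gen_m1 - kdnp * N * deb_sat -
        kdm1p * (M1 / inh_n1) * deb_sat -
        kdm2p * (M2 / inh_n1) * deb_sat - ddeb * Deb;

    /* neutrophils */
    ydot[0] = vfun(*t, gamma_n) * snr * Dam - Rn * N_st - dnr * N_st;
    ydot[9] = Rn * N_st - m1_phag - knm2p * N * (M2 / inh_n1) - dn * N;

    /* monocytes / macrophages */
    ydot[1] = vfun(*t, gamma_m) * smr - Rm1 * M_ud - Rm2_eff * M_ud -
        dmr_ud * M_ud;
    ydot[2] = -Rm1 * M_d - Rm2_eff * M_d - dmr_d * M_d;
    ydot[10] = Rm1 * (M_ud + M_d) - theta_m1m2 * m1_phag - dm1 * M1;
    ydot[11] = Rm2_eff * (M_ud + M_d) + theta_m1m2 * m1_phag - dm2 * M2;

    /* lymphocytes */
    ydot[5] = vfun(*t, gamma_l) * slr - Rl1 * L_ud - Rl2 * L_ud -
        dlr_ud * L_ud;
    ydot[6] = -Rl1 * L_d - Rl2 * L_d - dlr_d * L_d;
    ydot[13] = Rl1 * (L_ud + L_d) - dl * L1;
    ydot[14] = Rl2 * (L_ud + L_d) - dl * L2;

    /* fibroblasts */
    ydot[3] = vfun(*t, gamma_f) * sf - ksttb_ud * F_ud - dfr_ud * F_ud;
    ydot[4] = -ksttb_d * F_d - dfr_d * F_d;
    ydot[12] = (1.0 / (1.0 + sq(F_d / omega_f))) *
        (F / (1.0 + sq(N / N2_inf) + sq(M1 / M12_inf))) *
        (kf + alpha_dam * Dam + alpha_m2 * M2) +
        ksttb_ud * F_ud + ksttb_d * F_d - df * F;

    /* pathogen */
    ydot[15] = kpg * P * (1.0 - P / P_inf) -
        kpb * sb * P / (mu_b + kbp * P) -
        kpn * P * N - kpm1 * P * (M1 / inh_n1) - kpm2 * P * (M2 / inh_n1);
}
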