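/* Compiled right-hand side of the eight-variable model, in the deSolve
 * compiled-model convention. Parameter order must match .t2d_param_order
 * in R/parameters.R, with the active intake fraction appended last. */

#include <R.h>
#include <math.h>

#define NPARMS 57
static double parms[NPARMS];

#define k_w        parms[0]
#define DE_i_b     parms[1]
#define DE_e       parms[2]
#define hgt        parms[3]
#define E_G0       parms[4]
#define HGP_b      parms[5]
#define HGP_max    parms[6]
#define alpha_HGP  parms[7]
#define k_I        parms[8]
#define Vol        parms[9]
#define alpha_ISR  parms[10]
#define K_ISR      parms[11]
#define alpha_M    parms[12]
#define K_M        parms[13]
#define K_siF      parms[14]
#define alpha_SiF  parms[15]
#define c_f        parms[16]
#define F_Ra0      parms[17]
#define F_Ra1      parms[18]
#define FMR_a      parms[19]
#define FMR_b      parms[20]
#define tau_theta  parms[21]
#define n_theta    parms[22]
#define K_theta    parms[23]
#define tau_Si     parms[24]
#define S_i_b      parms[25]
#define M_FFA      parms[26]
#define n_Si       parms[27]
#define K_Si_FFA   parms[28]
#define K_Si_theta parms[29]
#define P_ng       parms[30]
#define P_max      parms[31]
#define n_P        parms[32]
#define alpha_P    parms[33]
#define A_b        parms[34]
#define A_max      parms[35]
#define n_A        parms[36]
#define alpha_A    parms[37]
#define s_pair     parms[38]
#define tau_beta   parms[39]
#define tau_sigma  parms[40]
#define sigma_b    parms[41]
#define s_gu_max   parms[42]
#define K_gu       parms[43]
#define n_gu       parms[44]
#define K_gd       parms[45]
#define n_gd       parms[46]
#define s_ffa_max  parms[47]
#define K_sf       parms[48]
#define n_sf       parms[49]
#define s_th_max   parms[50]
#define K_st       parms[51]
#define n_st       parms[52]
#define DE_frac    parms[56]

static double hill(double x, double K, double n)
{
    double xn, Kn;
    if (x <= 0.0) return 0.0;
    xn = pow(x, n);
    Kn = pow(K, n);
    return xn / (xn + Kn);
}

void t2d_initparms(void (*odeparms)(int *, double *))
{
    int n = NPARMS;
    odeparms(&n, parms);
}

void t2d_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    double W = y[0], G = y[1], I = y[2], FFA = y[3];
    double theta = y[4], S_i = y[5], beta = y[6], sigma = y[7];
    double BMI, FM, act, HGP, M, ISR, Ra_max, Ra, Rd;
    double theta_inf, S_i_inf, sigma_inf, P, A;

    BMI = W / (hgt * hgt);
    FM = (FMR_a * BMI + FMR_b) * W;
    act = S_i * I;
    HGP = HGP_b + HGP_max * alpha_HGP / (alpha_HGP + act);
    M = hill(G, alpha_M, K_M);
    ISR = sigma * hill(M, alpha_ISR, K_ISR);
    Ra_max = F_Ra0 + F_Ra1 * FM;
    Ra = Ra_max / (1.0 + pow(act / K_siF, alpha_SiF));
    Rd = c_f * W * FFA;
    theta_inf = hill(BMI, K_theta, n_theta);
    S_i_inf = S_i_b * (1.0 - M_FFA * hill(FFA, K_Si_FFA, n_Si)) *
        (1.0 - hill(theta, K_Si_theta, n_theta));
    P = P_max * hill(ISR, alpha_P, n_P);
    A = A_b + A_max * hill(M, alpha_A, n_A);
    sigma_inf = sigma_b * (s_gu_max * hill(G, K_gu, n_gu) -
        hill(G, K_gd, n_gd) * s_ffa_max * hill(FFA, K_sf, n_sf) -
        s_th_max * hill(theta, K_st, n_st));
    if (sigma_inf < 0.0) sigma_inf = 0.0;

    ydot[0] = k_w * DE_frac * DE_i_b - DE_e * W;
    ydot[1] = HGP - (E_G0 + act) * G;
    ydot[2] = beta * ISR / Vol - k_I * I;
    ydot[3] = Ra - Rd;
    ydot[4] = (theta_inf - theta) / tau_theta;
    ydot[5] = (S_i_inf - S_i) / tau_Si;
    ydot[6] = (P_ng + (P - A) * beta - s_pair * beta * beta) / tau_beta;
    ydot[7] = (sigma_inf - sigma) / tau_sigma;
}
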