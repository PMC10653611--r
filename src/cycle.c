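/* Right-hand side of the plant cell-cycle network ODE system, in the
 * compiled-model form used by deSolve (derivs + root function).
 *
 * State vector (13):
 *   0 V      cell volume
 *   1 CA_T   total CDKA:CYCD
 *   2 KRP_T  total KRP
 *   3 E2FA_T total E2FA
 *   4 E2FB
 *   5 RBR_T  total RBR
 *   6 FBL17
 *   7 CB_T   total CDKA/B:CYCB
 *   8 MYB3_T total MYB3R3
 *   9 MYB4_T total MYB3R4
 *  10 SMR_T  total SMR
 *  11 SCF
 *  12 APC
 *
 * All species are protein *masses*; synthesis of size-dependent proteins
 * scales with V, mediated degradation uses mass/V concentrations, and the
 * fast binding/phosphorylation layer is resolved algebraically at every
 * evaluation (quasi-steady-state).
 */

#include <R.h>
#include <math.h>

#define N_PARMS 54

static double parms[N_PARMS];

/* parameter slots (kept in step with .cycle_param_order in R/parameters.R) */
#define r_gr        parms[0]
#define r_ca        parms[1]
#define d_ca        parms[2]
#define d_ca_scf    parms[3]
#define d_ca_apc    parms[4]
#define kD_ca_krp   parms[5]
#define r_krp       parms[6]
#define r_krp_myb4  parms[7]
#define d_krp       parms[8]
#define d_krp_fbl17 parms[9]
#define r_e2fa      parms[10]
#define d_e2fa      parms[11]
#define kD_e2fa_rbr parms[12]
#define kat_e2fa    parms[13]
#define r_e2fb      parms[14]
#define r_e2fb_e2fa parms[15]
#define d_e2fb      parms[16]
#define r_rbr       parms[17]
#define d_rbr       parms[18]
#define kdp_ca      parms[19]
#define r_fbl17     parms[20]
#define r_fbl17_e2fa parms[21]
#define d_fbl17     parms[22]
#define r_cb        parms[23]
#define r_cb_e2fb   parms[24]
#define kI_myb3     parms[25]
#define kat_e2fb    parms[26]
#define d_cb        parms[27]
#define d_cb_apc    parms[28]
#define kD_cb_smr   parms[29]
#define r_myb3      parms[30]
#define d_myb3      parms[31]
#define kdp_cb      parms[32]
#define r_myb4      parms[33]
#define r_myb4_myb4 parms[34]
#define kat_myb4    parms[35]
#define d_myb4      parms[36]
#define kdp_cb1     parms[37]
#define r_smr       parms[38]
#define d_smr       parms[39]
#define d_smr_cdkb  parms[40]
#define kdp_cb2     parms[41]
#define r_scf       parms[42]
#define r_scf_e2fb  parms[43]
#define d_scf       parms[44]
#define r_apc       parms[45]
#define r_apc_myb4  parms[46]
#define d_apc       parms[47]
#define sd_krp      parms[48]
#define sd_rbr      parms[49]
#define sd_myb3     parms[50]
#define sd_smr      parms[51]
#define root_var    parms[52]
#define root_theta  parms[53]

void cycle_initmod(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, parms);
}

/* smaller root of the mass-action binding quadratic, in the
 * cancellation-free form 2ab / (s + sqrt(s^2 - 4ab)), s = a + b + kD V */
static double qss_complex_c(double a, double b, double V, double kD)
{
    double s, disc;
    if (a <= 0.0 || b <= 0.0)
        return 0.0;
    s = a + b + kD * V;
    disc = s * s - 4.0 * a * b;
    if (disc < 0.0)
        disc = 0.0;
    return 2.0 * a * b / (s + sqrt(disc));
}

/* phosphorylated share of B_T given kinase mass A */
static double phospho_c(double A, double kdp, double V, double BT)
{
    if (A <= 0.0)
        return 0.0;
    return A / (A + kdp * V) * BT;
}

/* saturating transcriptional activation A / (kat A + V) */
static double sat_c(double A, double kat, double V)
{
    if (A <= 0.0)
        return 0.0;
    return A / (kat * A + V);
}

/* algebraic (quasi-steady-state) layer; alg must hold 13 doubles */
static void algebra(const double *y, double *alg)
{
    double V = y[0];
    double ca_t = y[1] > 0.0 ? y[1] : 0.0;
    double krp_t = y[2] > 0.0 ? y[2] : 0.0;
    double e2fa_t = y[3] > 0.0 ? y[3] : 0.0;
    double rbr_t = y[5] > 0.0 ? y[5] : 0.0;
    double cb_t = y[7] > 0.0 ? y[7] : 0.0;
    double myb3_t = y[8] > 0.0 ? y[8] : 0.0;
    double myb4_t = y[9] > 0.0 ? y[9] : 0.0;
    double smr_t = y[10] > 0.0 ? y[10] : 0.0;

    double ca_krp = qss_complex_c(ca_t, krp_t, V, kD_ca_krp);
    double ca = ca_t - ca_krp;
    double rbr_p = phospho_c(ca, kdp_ca, V, rbr_t);
    double rbr_u = rbr_t - rbr_p;
    double e2fa_rbr = qss_complex_c(e2fa_t, rbr_u, V, kD_e2fa_rbr);
    double e2fa = e2fa_t - e2fa_rbr;
    double cb_smr = qss_complex_c(cb_t, smr_t, V, kD_cb_smr);
    double cb = cb_t - cb_smr;
    double myb3_p = phospho_c(cb, kdp_cb, V, myb3_t);
    double myb3_u = myb3_t - myb3_p;
    double myb4_p = phospho_c(cb, kdp_cb1, V, myb4_t);
    double smr_p = phospho_c(cb, kdp_cb2, V, smr_t);
    double smr_u = smr_t - smr_p;

    alg[0] = ca_krp;  alg[1] = ca;      alg[2] = rbr_p;  alg[3] = rbr_u;
    alg[4] = e2fa_rbr; alg[5] = e2fa;   alg[6] = cb_smr; alg[7] = cb;
    alg[8] = myb3_p;  alg[9] = myb3_u;  alg[10] = myb4_p;
    alg[11] = smr_p;  alg[12] = smr_u;
}

void cycle_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    double a[13];
    double V = y[0];
    double ind_krp, ind_rbr, ind_myb3, ind_smr;

    algebra(y, a);

    ind_krp = sd_krp > 0.0 ? V : 1.0;
    ind_rbr = sd_rbr > 0.0 ? V : 1.0;
    ind_myb3 = sd_myb3 > 0.0 ? V : 1.0;
    ind_smr = sd_smr > 0.0 ? V : 1.0;

    /* volume */
    ydot[0] = r_gr * V;
    /* CDKA:CYCD_T: basal synthesis, SCF- and APC-mediated resetting */
    ydot[1] = r_ca * V -
        (d_ca + d_ca_scf * y[11] / V + d_ca_apc * y[12] / V) * y[1];
    /* KRP_T: basal + MYB3R4-driven synthesis, FBL17-mediated degradation */
    ydot[2] = (r_krp + r_krp_myb4 * sat_c(a[10], kat_myb4, V)) * ind_krp -
        (d_krp + d_krp_fbl17 * y[6] / V) * y[2];
    /* E2FA_T */
    ydot[3] = r_e2fa * V - d_e2fa * y[3];
    /* E2FB: induced by free E2FA */
    ydot[4] = (r_e2fb + r_e2fb_e2fa * sat_c(a[5], kat_e2fa, V)) * V -
        d_e2fb * y[4];
    /* RBR_T */
    ydot[5] = r_rbr * ind_rbr - d_rbr * y[5];
    /* FBL17: induced by free E2FA */
    ydot[6] = (r_fbl17 + r_fbl17_e2fa * sat_c(a[5], kat_e2fa, V)) * V -
        d_fbl17 * y[6];
    /* CDKA/B:CYCB_T: E2FB-driven synthesis repressed by unphosphorylated
     * MYB3R3 in the saturating denominator; APC-mediated degradation */
    ydot[7] = (r_cb + r_cb_e2fb * y[4] /
               (kat_e2fb * y[4] + V + kI_myb3 * a[9])) * V -
        (d_cb + d_cb_apc * y[12] / V) * y[7];
    /* MYB3R3_T */
    ydot[8] = r_myb3 * ind_myb3 - d_myb3 * y[8];
    /* MYB3R4_T: autoactivation through its phosphorylated form */
    ydot[9] = (r_myb4 + r_myb4_myb4 * sat_c(a[10], kat_myb4, V)) * V -
        d_myb4 * y[9];
    /* SMR_T: unphosphorylated decays at d_smr, phosphorylated at d_smr_cdkb */
    ydot[10] = r_smr * ind_smr - d_smr * a[12] - d_smr_cdkb * a[11];
    /* SCF: induced by E2FB */
    ydot[11] = (r_scf + r_scf_e2fb * sat_c(y[4], kat_e2fb, V)) * V -
        d_scf * y[11];
    /* APC: induced by phosphorylated MYB3R4 */
    ydot[12] = (r_apc + r_apc_myb4 * sat_c(a[10], kat_myb4, V)) * V -
        d_apc * y[12];

    if (*ip > 0) {
        int i;
        if (*ip < 13)
            error("insufficient output slots for the algebraic layer");
        for (i = 0; i < 13; i++)
            yout[i] = a[i];
    }
}

/* Event function: signed distance of the transition readout from its
 * threshold. root_var selects the readout (1 = free-E2FA fraction of
 * E2FA_T, 2 = phosphorylated fraction of MYB3R4_T). */
void cycle_root(int *neq, double *t, double *y, int *ng, double *gout,
                double *out, int *ip)
{
    double a[13];
    double frac = 0.0;

    algebra(y, a);
    if (root_var < 1.5) {
        if (y[3] > 0.0)
            frac = a[5] / y[3];
    } else {
        if (y[9] > 0.0)
            frac = a[10] / y[9];
    }
    gout[0] = frac - root_theta;
}
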