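/* Gestational PBPK model for a permethrin isomer in the pregnant rat.
 *
 * Permeability parameters of the diffusion-limited tissues are unitless
 * permeability:flow ratios; the effective permeability-surface area
 * product is ps_T * Q_T(t).
 *
 * Compiled right-hand side for deSolve.  Amounts in mg, time in hours,
 * volumes in L, flows in L/h, concentrations in mg/L.  Gestational time
 * enters through t (hours since gestational day 0) unless the physiology
 * is frozen at a fixed gestational day (parameter freeze_gd >= 0).
 *
 * State layout (1-based, must match pbpk_state_names() on the R side):
 *  1 A_St      stomach lumen            15 A_MaB   mammary capillary blood
 *  2 A_Int     intestinal lumen         16 A_Ma    mammary tissue
 *  3 A_GI      GI tract tissue          17 A_SpB   slowly perfused blood
 *  4 A_Liv     liver                    18 A_Sp    slowly perfused tissue
 *  5 A_Rp      rapidly perfused         19 A_Blood maternal blood
 *  6 A_Pla     placenta                 20 A_Blood_F fetal blood (litter)
 *  7 A_BrB     brain capillary blood    21 A_Liv_F   fetal liver
 *  8 A_Br      brain tissue             22 A_BrB_F   fetal brain blood
 *  9 A_MuB     muscle capillary blood   23 A_Br_F    fetal brain tissue
 * 10 A_Mu      muscle tissue            24 A_RB_F    fetal rest of body
 * 11 A_KiB     kidney capillary blood   25 A_met_liv  cumulative hepatic met.
 * 12 A_Ki      kidney tissue            26 A_met_blood cumulative blood met.
 * 13 A_FaB     fat capillary blood      27 A_met_gi   cumulative GI met.
 * 14 A_Fa      fat tissue               28 A_fec      cumulative fecal excr.
 */

#include <R.h>
#include <math.h>

#define NPARMS 79
static double parms[NPARMS];

/* chemical parameters */
#define pc_liv     parms[0]
#define pc_gi      parms[1]
#define pc_fat     parms[2]
#define pc_mam     parms[3]
#define pc_musc    parms[4]
#define pc_brain   parms[5]
#define pc_kid     parms[6]
#define pc_pla     parms[7]
#define pc_sp      parms[8]
#define pc_rp      parms[9]
#define ps_brain   parms[10]
#define ps_kid     parms[11]
#define ps_fat     parms[12]
#define ps_mam     parms[13]
#define ps_musc    parms[14]
#define ps_sp      parms[15]
#define k_si       parms[16]
#define k_ai       parms[17]
#define k_fec      parms[18]
#define cl_gi      parms[19]
#define cl_blood   parms[20]
#define cl_liv     parms[21]
#define sc_ktrans1 parms[22]
#define sc_ktrans2 parms[23]
#define pc_liv_f   parms[24]
#define pc_brain_f parms[25]
#define pc_rb_f    parms[26]
#define ps_brain_f parms[27]
/* maternal physiology */
#define bw0        parms[28]
#define bw15       parms[29]
#define bw20       parms[30]
#define qci0       parms[31]
#define qci20      parms[32]
#define fv_blood   parms[33]
#define fv_gi      parms[34]
#define fv_liv     parms[35]
#define fv_musc    parms[36]
#define fv_brain   parms[37]
#define fv_kid     parms[38]
#define fv_np      parms[39]
#define fv_rp      parms[40]
#define v_mam0     parms[41]
#define v_mam20    parms[42]
#define v_fat0     parms[43]
#define v_fat20    parms[44]
#define v_pla20    parms[45]
#define fq_livout  parms[46]
#define fq_gi      parms[47]
#define fq_liv     parms[48]
#define fq_musc    parms[49]
#define fq_brain   parms[50]
#define fq_kid     parms[51]
#define fq_sp      parms[52]
#define q_mam0     parms[53]
#define q_mam20    parms[54]
#define q_fat0     parms[55]
#define q_fat20    parms[56]
#define q_pla20    parms[57]
#define bv_brain   parms[58]
#define bv_musc    parms[59]
#define bv_kid     parms[60]
#define bv_fat     parms[61]
#define bv_mam     parms[62]
#define bv_sp      parms[63]
/* fetal physiology */
#define bw_f20     parms[64]
#define qci_f      parms[65]
#define fv_blood_f parms[66]
#define v_brain_f20 parms[67]
#define v_liv_f20  parms[68]
#define fq_brain_f parms[69]
#define fq_liv_f   parms[70]
#define bv_brain_f parms[71]
#define bv_rb_f    parms[72]
#define n_fetuses  parms[73]
/* configuration */
#define onset_gd   parms[74]
#define logi_rate  parms[75]
#define vol_floor  parms[76]
#define freeze_gd  parms[77]
#define ktrans_basis parms[78]  /* 0 maternal BW, 1 litter BW, 2 per-fetus BW */

void pbpk_initmod(void (*odeparms)(int *, double *))
{
    int n = NPARMS;
    odeparms(&n, parms);
}

static double lin20(double gd, double v0, double v20)
{
    return v0 + (v20 - v0) * gd / 20.0;
}

/* normalised logistic growth: exactly 0 at conceptus onset,
 * endpoint at GD20, midpoint GD15 */
static double logi20(double gd, double vend)
{
    double s, s0, s1;
    if (gd <= onset_gd) return 0.0;
    s  = 1.0 / (1.0 + exp(-logi_rate * (gd   - 15.0)));
    s0 = 1.0 / (1.0 + exp(-logi_rate * (onset_gd - 15.0)));
    s1 = 1.0 / (1.0 + exp(-logi_rate * (20.0 - 15.0)));
    return vend * (s - s0) / (s1 - s0);
}

static double bw_mat(double gd)
{
    if (gd <= 15.0) return bw0 + (bw15 - bw0) * gd / 15.0;
    return bw15 + (bw20 - bw15) * (gd - 15.0) / 5.0;
}

static double flr(double v)
{
    return (v > vol_floor) ? v : vol_floor;
}

void pbpk_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    double gd = (freeze_gd >= 0.0) ? freeze_gd : (*t / 24.0);
    if (gd < 0.0) gd = 0.0;
    if (gd > 20.0) gd = 20.0;

    double bw   = bw_mat(gd);
    double qc0  = qci0 * bw0;
    double qc   = lin20(gd, qci0, qci20) * bw;

    /* maternal volumes */
    double v_blood = fv_blood * bw0;
    double v_gi    = fv_gi   * bw0;
    double v_liv   = fv_liv  * bw0;
    double v_rpt   = fv_rp   * bw0;
    double fv_sp   = 1.0 - (fv_blood + fv_gi + fv_liv + fv_musc +
                            fv_brain + fv_kid + fv_rp) - fv_np;
    double v_musc  = fv_musc  * bw0;
    double v_brainv= fv_brain * bw0;
    double v_kidv  = fv_kid   * bw0;
    double v_spv   = fv_sp    * bw0;
    double v_fat   = lin20(gd, v_fat0, v_fat20);
    double v_mam   = lin20(gd, v_mam0, v_mam20);
    double v_pla   = logi20(gd, v_pla20);

    /* maternal flows */
    double q_gi   = fq_gi   * qc0;
    double q_liv  = fq_liv  * qc0;
    double q_lout = fq_livout * qc0;
    double q_musc = fq_musc * qc0;
    double q_brn  = fq_brain * qc0;
    double q_kid  = fq_kid  * qc0;
    double q_sp   = fq_sp   * qc0;
    double q_mam  = lin20(gd, q_mam0, q_mam20);
    double q_fat  = lin20(gd, q_fat0, q_fat20);
    double q_pla  = logi20(gd, q_pla20);
    double q_rp   = qc - (q_gi + q_liv + q_musc + q_brn + q_kid +
                          q_sp + q_mam + q_fat + q_pla);

    double c_art = y[18] / flr(v_blood);

    /* oral absorption chain */
    ydot[0] = -k_si * y[0];
    ydot[1] =  k_si * y[0] - k_ai * y[1] - k_fec * y[1];
    ydot[27] = k_fec * y[1];

    /* GI tissue, flow-limited, portal outflow to liver */
    double c_gi  = y[2] / flr(v_gi);
    double cv_gi = c_gi / pc_gi;
    double met_gi = cl_gi * bw * cv_gi;
    ydot[2] = q_gi * (c_art - cv_gi) + k_ai * y[1] - met_gi;
    ydot[26] = met_gi;

    /* liver, flow-limited */
    double c_liv  = y[3] / flr(v_liv);
    double cv_liv = c_liv / pc_liv;
    double met_liv = cl_liv * bw * cv_liv;
    ydot[3] = q_liv * c_art + q_gi * cv_gi - q_lout * cv_liv - met_liv;
    ydot[24] = met_liv;

    /* rapidly perfused, flow-limited */
    double cv_rp = (y[4] / flr(v_rpt)) / pc_rp;
    ydot[4] = q_rp * (c_art - cv_rp);

    /* diffusion-limited maternal tissues: pairs (capillary blood, tissue) */
    double venous = q_lout * cv_liv + q_rp * cv_rp;
    /* brain */
    {
        double vtb = bv_brain * v_brainv, vt = (1.0 - bv_brain) * v_brainv;
        double ctb = y[6] / flr(vtb), ct = y[7] / flr(vt);
        double ex = ps_brain * q_brn * (ctb - ct / pc_brain);
        ydot[6] = q_brn * (c_art - ctb) - ex;
        ydot[7] = ex;
        venous += q_brn * ctb;
    }
    /* muscle */
    {
        double vtb = bv_musc * v_musc, vt = (1.0 - bv_musc) * v_musc;
        double ctb = y[8] / flr(vtb), ct = y[9] / flr(vt);
        double ex = ps_musc * q_musc * (ctb - ct / pc_musc);
        ydot[8] = q_musc * (c_art - ctb) - ex;
        ydot[9] = ex;
        venous += q_musc * ctb;
    }
    /* kidney */
    {
        double vtb = bv_kid * v_kidv, vt = (1.0 - bv_kid) * v_kidv;
        double ctb = y[10] / flr(vtb), ct = y[11] / flr(vt);
        double ex = ps_kid * q_kid * (ctb - ct / pc_kid);
        ydot[10] = q_kid * (c_art - ctb) - ex;
        ydot[11] = ex;
        venous += q_kid * ctb;
    }
    /* fat */
    {
        double vtb = bv_fat * v_fat, vt = (1.0 - bv_fat) * v_fat;
        double ctb = y[12] / flr(vtb), ct = y[13] / flr(vt);
        double ex = ps_fat * q_fat * (ctb - ct / pc_fat);
        ydot[12] = q_fat * (c_art - ctb) - ex;
        ydot[13] = ex;
        venous += q_fat * ctb;
    }
    /* mammary gland */
    {
        double vtb = bv_mam * v_mam, vt = (1.0 - bv_mam) * v_mam;
        double ctb = y[14] / flr(vtb), ct = y[15] / flr(vt);
        double ex = ps_mam * q_mam * (ctb - ct / pc_mam);
        ydot[14] = q_mam * (c_art - ctb) - ex;
        ydot[15] = ex;
        venous += q_mam * ctb;
    }
    /* slowly perfused */
    {
        double vtb = bv_sp * v_spv, vt = (1.0 - bv_sp) * v_spv;
        double ctb = y[16] / flr(vtb), ct = y[17] / flr(vt);
        double ex = ps_sp * q_sp * (ctb - ct / pc_sp);
        ydot[16] = q_sp * (c_art - ctb) - ex;
        ydot[17] = ex;
        venous += q_sp * ctb;
    }

    /* placenta and fetal sub-model: frozen before conceptus onset */
    int conceptus = (gd > onset_gd) && (v_pla > vol_floor);
    double cv_pla = 0.0;
    if (conceptus) {
        double c_pla = y[5] / flr(v_pla);
        cv_pla = c_pla / pc_pla;

        double bw1f = logi20(gd, bw_f20);
        double bwF  = n_fetuses * bw1f;
        double kbase = (ktrans_basis >= 2.0) ? bw1f :
                       (ktrans_basis >= 1.0) ? bwF : bw;
        double ktrans1 = sc_ktrans1 * pow(kbase, 0.75);
        double ktrans2 = sc_ktrans2 * pow(kbase, 0.75);
        double v_blood_fl = flr(fv_blood_f * bwF);
        double v_brain_fl = n_fetuses * logi20(gd, v_brain_f20);
        double v_liv_fl   = flr(n_fetuses * logi20(gd, v_liv_f20));
        double v_rb_fl    = flr(bwF - v_brain_fl - v_liv_fl -
                                fv_blood_f * bwF);
        double qc_f  = qci_f * bwF;
        double q_br_f = fq_brain_f * qc_f;
        double q_li_f = fq_liv_f * qc_f;
        double q_rb_f = qc_f - q_br_f - q_li_f;

        double c_art_f = y[19] / v_blood_fl;
        ydot[5] = q_pla * (c_art - cv_pla) - ktrans1 * cv_pla +
                  ktrans2 * c_art_f;

        double cv_liv_f = (y[20] / v_liv_fl) / pc_liv_f;
        ydot[20] = q_li_f * (c_art_f - cv_liv_f);

        double vtb = flr(bv_brain_f * v_brain_fl);
        double vt  = flr((1.0 - bv_brain_f) * v_brain_fl);
        double ctb = y[21] / vtb, ct = y[22] / vt;
        double ex = ps_brain_f * q_br_f * (ctb - ct / pc_brain_f);
        ydot[21] = q_br_f * (c_art_f - ctb) - ex;
        ydot[22] = ex;

        double cv_rb_f = (y[23] / v_rb_fl) / pc_rb_f;
        ydot[23] = q_rb_f * (c_art_f - cv_rb_f);

        ydot[19] = ktrans1 * cv_pla - ktrans2 * c_art_f +
                   q_li_f * cv_liv_f + q_rb_f * cv_rb_f + q_br_f * ctb -
                   qc_f * c_art_f;
    } else {
        ydot[5] = 0.0;
        ydot[19] = ydot[20] = ydot[21] = ydot[22] = ydot[23] = 0.0;
        q_pla = 0.0;  /* no arterial draw before onset */
    }
    venous += q_pla * cv_pla;

    /* maternal blood */
    double met_blood = cl_blood * bw * c_art;
    double q_draws = q_gi + q_liv + q_musc + q_brn + q_kid + q_sp +
                     q_mam + q_fat + q_pla + q_rp;
    ydot[18] = venous - q_draws * c_art - met_blood;
    ydot[25] = met_blood;
}
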