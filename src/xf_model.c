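/* Compiled right-hand side of the central-carbon-metabolism ODE system.
 *
 * This is a performance mirror of the reference R implementation
 * (.flux_core / .xf_rhs in R/rates.R and R/simulate.R); the two paths are
 * asserted equivalent in the test suite. Parameters arrive as one packed
 * double vector: the template parameter block (see xf_params_idx.h, order =
 * names(default_params())), a knockout mask per reaction, scenario flags,
 * TF overrides, and the compiled regulation-map edges.
 */

#include <R.h>
#include <math.h>

#define P(i) parms[i]
#include "xf_params_idx.h"

/* state indices (order = .xf_species in R/state.R) */
enum {
  I_G6P, I_F6P, I_FBP, I_GAP, I_PEP, I_PYR, I_AcCoA, I_PG6,
  I_Ru5P, I_X5P, I_R5P, I_S7P, I_E4P,
  I_ICIT, I_AKG, I_SUC, I_FUM, I_MAL, I_OAA, I_GLX,
  I_XYLin, I_XYLU, I_ATP, I_NADH, I_NADPH, I_AcAcCoA, I_HMGCoA,
  I_GLC, I_XYL, I_ACE, I_MVA, I_X, N_STATE
};

/* flux indices (order = flux names in .make_trajectory) */
enum {
  F_PTS, F_NPTS, F_Pgi, F_Pfk, F_Fbp, F_Fba, F_L_Emp, F_Pyk, F_Pps,
  F_PDH, F_Pfl, F_G6PDH, F_PGDH, F_Rpe, F_Rpi, F_TktA, F_Tal, F_TktB,
  F_CS, F_ICDH, F_aKGDH, F_SDH, F_Fum, F_MDH, F_Icl, F_MS, F_Ppc,
  F_Pck, F_Mez, F_PTACK, F_Acs, F_LDH, F_ADH, F_Udh, F_NOX, F_XT, F_Xyi,
  F_Xyk, F_OP, F_ATPase, F_AtoB, F_HMGS, F_HMGR, F_Glk, N_FLUX
};

#define MAX_EDGES 32
#define OFF_KO       N_TEMPLATE             /* N_FLUX entries            */
#define OFF_FLAGS    (OFF_KO + N_FLUX)      /* aerobic mva chemostat D   */
                                            /* feed_glc feed_xyl feed_ace thr */
#define OFF_TFOV     (OFF_FLAGS + 8)        /* 4 flags + 4 values        */
#define OFF_NEDGE    (OFF_TFOV + 8)
#define OFF_EDGES    (OFF_NEDGE + 1)        /* 4 doubles per edge        */
#define N_PARMS_TOT  (OFF_EDGES + 4 * MAX_EDGES)

static double parms[N_PARMS_TOT];

void xf_initmod(void (*odeparms)(int *, double *)) {
  int n = N_PARMS_TOT;
  odeparms(&n, parms);
}

static double mm(double S, double K) { return S / (K + S); }
static double clamp0(double x) { return x > 0 ? x : 0; }

static double rl_rev1(double A, double B, double vmax, double Ka,
                      double Kb, double Keq) {
  return vmax * (A / Ka - B / (Ka * Keq)) / (1 + A / Ka + B / Kb);
}

static double rl_rev2(double A, double B, double Pp, double Q, double vmax,
                      double K, double Keq) {
  return vmax * (A * B - Pp * Q / Keq) / ((K + A + Pp) * (K + B + Q));
}

/* TF activities (mirror of tf_activities), tf[0..3] = Crp Cra ArcA XylR,
 * plus EIIA-P fraction in *phi_out */
static void tf_act(double *y, int aerobic, double *tf, double *phi_out) {
  double r = (y[I_PEP] + 0.01) / (y[I_PYR] + 0.01);
  double phi = r / (K_EIIA + r);
  double crp = pow(phi, n_Crp) / (pow(K_Crp_phi, n_Crp) + pow(phi, n_Crp));
  double fbp = clamp0(y[I_FBP]);
  double cra = pow(K_Cra_FBP, n_Cra) /
    (pow(K_Cra_FBP, n_Cra) + pow(fbp, n_Cra));
  double arca;
  if (aerobic) {
    double nad = N_total - y[I_NADH];
    double rr = y[I_NADH] / (nad > 1e-9 ? nad : 1e-9);
    arca = pow(rr, n_ArcA) / (pow(K_ArcA, n_ArcA) + pow(rr, n_ArcA));
  } else {
    arca = ArcA_anaerobic;
  }
  double xi = clamp0(y[I_XYLin]);
  double xylr = pow(xi, n_XylR) / (pow(K_XylR, n_XylR) + pow(xi, n_XylR));
  tf[0] = crp; tf[1] = cra; tf[2] = arca; tf[3] = xylr;
  for (int i = 0; i < 4; i++) {
    if (tf[i] < 0) tf[i] = 0;
    if (tf[i] > 1) tf[i] = 1;
    if (parms[OFF_TFOV + i] > 0.5) tf[i] = parms[OFF_TFOV + 4 + i];
  }
  *phi_out = phi;
}

/* regulation factors per flux from the packed edge table */
static void reg_factors(const double *tf, double *fm) {
  double refs[4] = { ref_Crp, ref_Cra, ref_ArcA, ref_XylR };
  for (int i = 0; i < N_FLUX; i++) fm[i] = 1.0;
  int ne = (int) parms[OFF_NEDGE];
  for (int e = 0; e < ne; e++) {
    const double *ed = parms + OFF_EDGES + 4 * e;
    int target = (int) ed[0];
    int tfi = (int) ed[1];
    double sign = ed[2], c0 = ed[3], a = tf[tfi];
    double f;
    if (sign > 0) {
      f = c0 + (1 - c0) * a;
    } else {
      f = c0 + (1 - c0) / (1 - refs[tfi]) * (1 - a);
      if (f < 0) f = 0;
    }
    fm[target] *= f;
  }
}

static void fluxes(double *y, const double *tf, double *v) {
  int aerobic = parms[OFF_FLAGS] > 0.5;
  int mva = parms[OFF_FLAGS + 1] > 0.5;
  double fm[N_FLUX];
  reg_factors(tf, fm);

  double ADP  = A_total - y[I_ATP];   if (ADP < 1e-9)  ADP = 1e-9;
  double NAD  = N_total - y[I_NADH];  if (NAD < 1e-9)  NAD = 1e-9;
  double NADP = NP_total - y[I_NADPH]; if (NADP < 1e-9) NADP = 1e-9;

  double glc = clamp0(y[I_GLC]) / MW_GLC * 1000;
  double ace = clamp0(y[I_ACE]) / MW_ACE * 1000;
  double r = (y[I_PEP] + 0.01) / (y[I_PYR] + 0.01);
  double eiia = EIIA_total * (1 - r / (K_EIIA + r));

  double G6P = clamp0(y[I_G6P]), F6P = clamp0(y[I_F6P]);
  double FBP = clamp0(y[I_FBP]), GAP = clamp0(y[I_GAP]);
  double PEP = clamp0(y[I_PEP]), PYR = clamp0(y[I_PYR]);
  double AcCoA = clamp0(y[I_AcCoA]), PG6 = clamp0(y[I_PG6]);
  double Ru5P = clamp0(y[I_Ru5P]), X5P = clamp0(y[I_X5P]);
  double R5P = clamp0(y[I_R5P]), S7P = clamp0(y[I_S7P]);
  double E4P = clamp0(y[I_E4P]), ICIT = clamp0(y[I_ICIT]);
  double AKG = clamp0(y[I_AKG]), SUC = clamp0(y[I_SUC]);
  double FUM = clamp0(y[I_FUM]), MAL = clamp0(y[I_MAL]);
  double OAA = clamp0(y[I_OAA]), GLX = clamp0(y[I_GLX]);
  double ATP = clamp0(y[I_ATP]), NADH = clamp0(y[I_NADH]);
  double NADPH = clamp0(y[I_NADPH]);

  v[F_PTS] = vmax_PTS * mm(glc, K_PTS_GLC) * mm(PEP, K_PTS_PEP) /
    (1 + pow(G6P / K_PTS_G6P, n_PTS_G6P));
  v[F_NPTS] = vmax_NPTS * fm[F_NPTS] * glc /
    (K_NPTS_GLC + (1 + eiia / K_I_NPTS) * glc) * mm(ATP, 0.3) /
    (1 + pow(G6P / K_NPTS_G6P, 2));
  v[F_Pgi] = rl_rev1(G6P, F6P, vmax_Pgi, K_Pgi_G6P, K_Pgi_F6P, Keq_Pgi);
  v[F_Pfk] = vmax_Pfk * mm(F6P, K_Pfk_F6P) * mm(ATP, K_Pfk_ATP);
  v[F_Fbp] = vmax_Fbp * mm(FBP, K_Fbp_FBP);
  v[F_Fba] = vmax_Fba * mm(FBP, K_Fba_FBP);
  v[F_L_Emp] = vmax_Emp * mm(GAP, K_Emp_GAP) * mm(NAD, K_Emp_NAD) *
    mm(ADP, K_Emp_ADP) / (1 + pow(NADH / Ki_Emp_NADH, n_Emp_NADH));
  v[F_Pyk] = vmax_Pyk * fm[F_Pyk] * mm(PEP, K_Pyk_PEP) *
    mm(ADP, K_Pyk_ADP) * (a0_Pyk + (1 - a0_Pyk) * mm(FBP, Ka_Pyk_FBP));
  v[F_Pps] = vmax_Pps * mm(PYR, K_Pps_PYR) * mm(ATP, K_Pps_ATP);
  v[F_PDH] = vmax_PDH * mm(PYR, K_PDH_PYR) * mm(NAD, K_PDH_NAD) /
    (1 + pow(NADH / Ki_PDH_NADH, n_PDH_NADH));
  v[F_Pfl] = vmax_Pfl * fm[F_Pfl] * mm(PYR, K_Pfl_PYR);
  v[F_G6PDH] = vmax_G6PDH * fm[F_G6PDH] * mm(G6P, K_G6PDH_G6P) *
    mm(NADP, K_G6PDH_NADP) /
    (1 + pow(NADPH / Ki_G6PDH_NADPH, n_G6PDH_NADPH));
  v[F_PGDH] = vmax_PGDH * fm[F_PGDH] * mm(PG6, K_PGDH_PG6) *
    mm(NADP, K_PGDH_NADP);
  v[F_Rpe] = rl_rev1(Ru5P, X5P, vmax_Rpe, K_Rpe, K_Rpe, Keq_Rpe);
  v[F_Rpi] = rl_rev1(Ru5P, R5P, vmax_Rpi, K_Rpi, K_Rpi, Keq_Rpi);
  v[F_TktA] = rl_rev2(X5P, R5P, S7P, GAP, vmax_TktA, K_TktA, Keq_TktA);
  v[F_Tal] = rl_rev2(S7P, GAP, E4P, F6P, vmax_Tal, K_Tal, Keq_Tal);
  v[F_TktB] = rl_rev2(X5P, E4P, F6P, GAP, vmax_TktB, K_TktB, Keq_TktB);
  v[F_CS] = vmax_CS * fm[F_CS] * mm(AcCoA, K_CS_AcCoA) * mm(OAA, K_CS_OAA);
  v[F_ICDH] = vmax_ICDH * fm[F_ICDH] * mm(ICIT, K_ICDH_ICIT) *
    mm(NADP, K_ICDH_NADP);
  v[F_aKGDH] = vmax_aKGDH * fm[F_aKGDH] * mm(AKG, K_aKGDH_AKG) *
    mm(NAD, K_aKGDH_NAD) * mm(ADP, 0.3);
  v[F_SDH] = vmax_SDH * fm[F_SDH] * mm(SUC, K_SDH_SUC) *
    mm(NAD, K_aKGDH_NAD);
  v[F_Fum] = vmax_Fum * mm(FUM, K_Fum_FUM);
  v[F_MDH] = vmax_MDH * fm[F_MDH] * mm(MAL, K_MDH_MAL) * mm(NAD, K_MDH_NAD);
  v[F_Icl] = vmax_Icl * mm(ICIT, K_Icl_ICIT);
  v[F_MS] = vmax_MS * mm(GLX, K_MS_GLX) * mm(AcCoA, K_MS_AcCoA);
  v[F_Ppc] = vmax_Ppc * mm(PEP, K_Ppc_PEP) / (1 + OAA / Ki_Ppc_OAA);
  v[F_Pck] = vmax_Pck * mm(OAA, K_Pck_OAA) * mm(ATP, K_Pck_ATP);
  v[F_Mez] = vmax_Mez * mm(MAL, K_Mez_MAL) * mm(NADP, K_Mez_NADP);
  v[F_PTACK] = vmax_PTACK * mm(AcCoA, K_PTACK_AcCoA) * mm(ADP, K_PTACK_ADP);
  v[F_Acs] = vmax_Acs * fm[F_Acs] * mm(ace, K_Acs_ACE) * mm(ATP, 0.3);
  v[F_LDH] = vmax_LDH * mm(PYR, K_LDH_PYR) *
    NADH * NADH / (K_LDH_NADH * K_LDH_NADH + NADH * NADH);
  v[F_ADH] = vmax_ADH * mm(AcCoA, K_ADH_AcCoA) *
    NADH * NADH / (K_ADH_NADH * K_ADH_NADH + NADH * NADH);
  v[F_Udh] = vmax_Udh * mm(NADPH, K_Udh_NADPH) * mm(NAD, K_Udh_NAD);
  v[F_NOX] = vmax_NOX * pow(NADH, n_NOX) /
    (pow(K_NOX_NADH, n_NOX) + pow(NADH, n_NOX));

  double xylm = clamp0(y[I_XYL]) / MW_XYL * 1000;
  v[F_XT] = vmax_XT * fm[F_XT] * mm(ATP, K_XT_ATP) * xylm /
    (K_XYL + (1 + eiia / K_I) * xylm);
  v[F_Xyi] = vmax_Xyi * fm[F_Xyi] * mm(clamp0(y[I_XYLin]), K_XYLin);
  double xu = clamp0(y[I_XYLU]);
  v[F_Xyk] = vmax_Xyk * fm[F_Xyk] * xu * ATP /
    (K_XYLU * K_Xyk_ATP + K_Xyk_ATP * xu + K_XYLU * ATP + xu * ATP);

  v[F_OP] = 0;
  if (aerobic) {
    double v_resp = vmax_resp * fm[F_OP] * mm(NADH, K_resp_NADH) *
      mm(ADP, K_resp_ADP);
    v[F_OP] = PO_ratio * v_resp;
  }
  v[F_ATPase] = vmax_ATPase * mm(ATP, K_ATPase_ATP);

  v[F_AtoB] = v[F_HMGS] = v[F_HMGR] = 0;
  if (mva) {
    v[F_AtoB] = vmax_AtoB * pow(AcCoA, n_AtoB) /
      (pow(K_AtoB_AcCoA, n_AtoB) + pow(AcCoA, n_AtoB)) /
      (1 + clamp0(y[I_AcAcCoA]) / Ki_AtoB_AcAcCoA);
    v[F_HMGS] = vmax_HMGS * mm(clamp0(y[I_AcAcCoA]), K_HMGS_AcAcCoA) *
      mm(AcCoA, K_HMGS_AcCoA) / (1 + clamp0(y[I_HMGCoA]) / Ki_HMGS_HMGCoA);
    v[F_HMGR] = vmax_HMGR * mm(clamp0(y[I_HMGCoA]), K_HMGR_HMGCoA) *
      NADPH * NADPH / (K_HMGR_NADPH * K_HMGR_NADPH + NADPH * NADPH);
  }

  for (int i = 0; i < N_FLUX; i++) v[i] *= parms[OFF_KO + i];
  v[F_Glk] = v[F_NPTS];
}

/* saturable growth-proportional demand */
static double dr(double mu, double dem, double conc) {
  double c = clamp0(conc);
  return mu * dem * c / (c + 0.05);
}

void xf_derivs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip) {
  int aerobic = parms[OFF_FLAGS] > 0.5;
  double tf[4], phi, v[N_FLUX];
  tf_act(y, aerobic, tf, &phi);
  fluxes(y, tf, v);

  double v_atp = v[F_OP] + v[F_L_Emp] + v[F_Pyk] + v[F_PTACK] +
    v[F_aKGDH] - v[F_Glk] - v[F_Pfk] - v[F_Pps] - v[F_Pck] - v[F_Acs] -
    v[F_XT] - v[F_Xyk];
  double v_nadph = (nadph_first_term >= 1 ? v[F_G6PDH] : v[F_L_Emp]) +
    v[F_PGDH] + v[F_ICDH] + v[F_Mez];
  double ace = clamp0(y[I_ACE]);
  double mu = k_ATP * v_atp * k_ACE / (k_ACE + ace);
  if (mu < 0) mu = 0;

  double net[N_STATE];
  net[I_G6P] = v[F_PTS] + v[F_NPTS] - v[F_Pgi] - v[F_G6PDH] -
    dr(mu, bm_G6P, y[I_G6P]);
  net[I_F6P] = v[F_Pgi] + v[F_Fbp] + v[F_Tal] + v[F_TktB] - v[F_Pfk] -
    dr(mu, bm_F6P, y[I_F6P]);
  net[I_FBP] = v[F_Pfk] - v[F_Fbp] - v[F_Fba];
  net[I_GAP] = 2 * v[F_Fba] + v[F_TktA] + v[F_TktB] - v[F_Tal] -
    v[F_L_Emp] - dr(mu, bm_GAP, y[I_GAP]);
  net[I_PEP] = v[F_L_Emp] + v[F_Pps] + v[F_Pck] - v[F_Pyk] - v[F_PTS] -
    v[F_Ppc] - dr(mu, bm_PEP, y[I_PEP]);
  net[I_PYR] = v[F_Pyk] + v[F_PTS] + v[F_Mez] - v[F_PDH] - v[F_Pfl] -
    v[F_Pps] - v[F_LDH] - dr(mu, bm_PYR, y[I_PYR]);
  net[I_AcCoA] = v[F_PDH] + v[F_Pfl] + v[F_Acs] - v[F_CS] - v[F_PTACK] -
    v[F_MS] - v[F_ADH] - 2 * v[F_AtoB] - v[F_HMGS] -
    dr(mu, bm_AcCoA, y[I_AcCoA]);
  net[I_PG6] = v[F_G6PDH] - v[F_PGDH];
  net[I_Ru5P] = v[F_PGDH] - v[F_Rpe] - v[F_Rpi];
  net[I_X5P] = v[F_Rpe] + v[F_Xyk] - v[F_TktA] - v[F_TktB];
  net[I_R5P] = v[F_Rpi] - v[F_TktA] - dr(mu, bm_R5P, y[I_R5P]);
  net[I_S7P] = v[F_TktA] - v[F_Tal];
  net[I_E4P] = v[F_Tal] - v[F_TktB] - dr(mu, bm_E4P, y[I_E4P]);
  net[I_ICIT] = v[F_CS] - v[F_ICDH] - v[F_Icl];
  net[I_AKG] = v[F_ICDH] - v[F_aKGDH] - dr(mu, bm_AKG, y[I_AKG]);
  net[I_SUC] = v[F_aKGDH] + v[F_Icl] - v[F_SDH];
  net[I_FUM] = v[F_SDH] - v[F_Fum];
  net[I_MAL] = v[F_Fum] + v[F_MS] - v[F_MDH] - v[F_Mez];
  net[I_OAA] = v[F_MDH] + v[F_Ppc] - v[F_CS] - v[F_Pck] -
    dr(mu, bm_OAA, y[I_OAA]);
  net[I_GLX] = v[F_Icl] - v[F_MS];
  net[I_XYLin] = v[F_XT] - v[F_Xyi];
  net[I_XYLU] = v[F_Xyi] - v[F_Xyk];
  net[I_ATP] = v[F_L_Emp] + v[F_Pyk] + v[F_aKGDH] + v[F_PTACK] +
    v[F_OP] - v[F_Glk] - v[F_Pfk] - v[F_Pps] - v[F_Pck] - v[F_Acs] -
    v[F_XT] - v[F_Xyk] - v[F_ATPase] -
    dr(mu, bm_ATP, y[I_ATP]);
  net[I_NADH] = v[F_L_Emp] + v[F_PDH] + v[F_aKGDH] + v[F_SDH] +
    v[F_MDH] + v[F_Udh] - v[F_OP] / PO_ratio - v[F_LDH] - 2 * v[F_ADH] -
    v[F_NOX];
  net[I_NADPH] = v[F_G6PDH] + v[F_PGDH] + v[F_ICDH] + v[F_Mez] -
    2 * v[F_HMGR] - v[F_Udh] - dr(mu, k_Anabolism, y[I_NADPH]);
  net[I_AcAcCoA] = v[F_AtoB] - v[F_HMGS];
  net[I_HMGCoA] = v[F_HMGS] - v[F_HMGR];

  double cf = 1 / vol_cyto;
  for (int i = 0; i <= I_HMGCoA; i++) {
    double dil = (i == I_ATP || i == I_NADH || i == I_NADPH)
      ? 0 : mu * clamp0(y[i]);
    ydot[i] = net[i] * cf - dil;
  }

  double X = clamp0(y[I_X]);
  ydot[I_GLC] = -(v[F_PTS] + v[F_NPTS]) * X * MW_GLC / 1000;
  ydot[I_XYL] = -v[F_XT] * X * MW_XYL / 1000;
  ydot[I_ACE] = (v[F_PTACK] - v[F_Acs]) * X * MW_ACE / 1000;
  ydot[I_MVA] = v[F_HMGR] * X * MW_MVA / 1000;
  ydot[I_X] = mu * X;
  if (parms[OFF_FLAGS + 2] > 0.5) {          /* chemostat */
    double D = parms[OFF_FLAGS + 3];
    ydot[I_GLC] += D * (parms[OFF_FLAGS + 4] - y[I_GLC]);
    ydot[I_XYL] += D * (parms[OFF_FLAGS + 5] - y[I_XYL]);
    ydot[I_ACE] += D * (parms[OFF_FLAGS + 6] - y[I_ACE]);
    ydot[I_MVA] += -D * y[I_MVA];
    ydot[I_X] += -D * y[I_X];
  }

  if (ip[0] >= 9 + N_FLUX) {
    yout[0] = mu; yout[1] = v_atp; yout[2] = v_nadph;
    yout[3] = tf[0]; yout[4] = tf[1]; yout[5] = tf[2]; yout[6] = tf[3];
    yout[7] = phi; yout[8] = cAMP_max * phi;
    for (int i = 0; i < N_FLUX; i++) yout[9 + i] = v[i];
  }
}

/* terminal event: both substrates below the depletion threshold */
void xf_root(int *neq, double *t, double *y, int *ng, double *gout,
             double *out, int *ip) {
  double thr = parms[OFF_FLAGS + 7];
  double hi = y[I_GLC] > y[I_XYL] ? y[I_GLC] : y[I_XYL];
  gout[0] = hi - thr;
}
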