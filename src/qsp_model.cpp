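// Core ODE right-hand side for the nine-compartment tumour-immune model.
//
// Compartments: central, peripheral, four tumours (primary, lung1, lung2,
// other) and three tumour-draining lymph nodes (primary, lung, other).
// Units: cells for cell counts, nM for soluble species, molecules/cell for
// surface species, day for time (diameters are derived in R, in cm).
//
// The same core is exposed twice: via deSolve's compiled-model interface
// (derivs_tnbc / initmod_tnbc) for speed, and as Rcpp-exported helpers so
// the R-level kinetic-law functions and tests hit the identical code path.

#include <Rcpp.h>
#include <cmath>
#include <string>
#include <vector>
#include <map>

using namespace Rcpp;

// ---------------------------------------------------------------- layout

static const int N_TUMOR = 4;   // primary, lung1, lung2, other
static const int N_LN    = 3;   // primary, lung, other
static const int N_CLONE = 5;
static const int N_EPI   = 8;   // neo-epitopes; index 8 (9th) = self antigen

static const int TUM_OF_LN[N_TUMOR] = {0, 1, 1, 2}; // draining LN per tumour

// central / peripheral blocks (13 entries each)
static const int CEN = 0;
static const int PER = 13;
enum { BC_DRUG = 0, BC_N4, BC_N8, BC_TCYT /*8*/, BC_TH = 11, BC_TREG = 12 };

static const int TUM0 = 26, TUM_LEN = 42;
enum {
  TC_CANCER = 0 /*5*/, TC_DEAD = 5, TC_K = 6, TC_TCYT = 7 /*8*/,
  TC_TEX = 15, TC_TH = 16, TC_TREG = 17, TC_M1 = 18, TC_M2 = 19,
  TC_MDSC = 20, TC_APCI = 21, TC_APCM = 22, TC_AG = 23 /*9*/,
  TC_IL10 = 32, TC_IL12 = 33, TC_IFNG = 34, TC_TGFB = 35, TC_CCL2 = 36,
  TC_ANGIO = 37, TC_ARGI = 38, TC_NO = 39, TC_PDL1 = 40, TC_DRUG = 41
};

static const int LN0 = TUM0 + N_TUMOR * TUM_LEN, LN_LEN = 15;
enum {
  LC_N4 = 0, LC_N8 = 1, LC_APCM = 2, LC_TACT = 3 /*8*/,
  LC_TTH = 11, LC_TTREG = 12, LC_IL2 = 13, LC_DRUG = 14
};

static const int N_STATE = LN0 + N_LN * LN_LEN; // 239

static const char *TUMOR_NAME[N_TUMOR] =
  {"tumor_primary", "tumor_lung1", "tumor_lung2", "tumor_other"};
static const char *LN_NAME[N_LN] = {"ln_primary", "ln_lung", "ln_other"};

static std::vector<std::string> make_state_names() {
  std::vector<std::string> nm(N_STATE);
  const char *blk[2] = {"central", "peripheral"};
  for (int b = 0; b < 2; ++b) {
    int o = (b == 0) ? CEN : PER;
    std::string p = std::string(blk[b]) + ".";
    nm[o + BC_DRUG] = p + "drug";
    nm[o + BC_N4] = p + "naive_cd4";
    nm[o + BC_N8] = p + "naive_cd8";
    for (int e = 0; e < N_EPI; ++e)
      nm[o + BC_TCYT + e] = p + "tcyt." + std::to_string(e + 1);
    nm[o + BC_TH] = p + "th";
    nm[o + BC_TREG] = p + "treg";
  }
  for (int t = 0; t < N_TUMOR; ++t) {
    int o = TUM0 + t * TUM_LEN;
    std::string p = std::string(TUMOR_NAME[t]) + ".";
    for (int c = 0; c < N_CLONE; ++c)
      nm[o + TC_CANCER + c] = p + "cancer." + std::to_string(c + 1);
    nm[o + TC_DEAD] = p + "dead";
    nm[o + TC_K] = p + "K";
    for (int e = 0; e < N_EPI; ++e)
      nm[o + TC_TCYT + e] = p + "tcyt." + std::to_string(e + 1);
    nm[o + TC_TEX] = p + "tcyt_exhausted";
    nm[o + TC_TH] = p + "th";
    nm[o + TC_TREG] = p + "treg";
    nm[o + TC_M1] = p + "m1";
    nm[o + TC_M2] = p + "m2";
    nm[o + TC_MDSC] = p + "mdsc";
    nm[o + TC_APCI] = p + "apc_immature";
    nm[o + TC_APCM] = p + "apc_mature";
    for (int e = 0; e < N_EPI + 1; ++e)
      nm[o + TC_AG + e] = p + "ag." + std::to_string(e + 1);
    nm[o + TC_IL10] = p + "il10";
    nm[o + TC_IL12] = p + "il12";
    nm[o + TC_IFNG] = p + "ifng";
    nm[o + TC_TGFB] = p + "tgfb";
    nm[o + TC_CCL2] = p + "ccl2";
    nm[o + TC_ANGIO] = p + "angio";
    nm[o + TC_ARGI] = p + "argi";
    nm[o + TC_NO] = p + "no";
    nm[o + TC_PDL1] = p + "pdl1";
    nm[o + TC_DRUG] = p + "drug";
  }
  for (int l = 0; l < N_LN; ++l) {
    int o = LN0 + l * LN_LEN;
    std::string p = std::string(LN_NAME[l]) + ".";
    nm[o + LC_N4] = p + "naive_cd4";
    nm[o + LC_N8] = p + "naive_cd8";
    nm[o + LC_APCM] = p + "apc_mature";
    for (int e = 0; e < N_EPI; ++e)
      nm[o + LC_TACT + e] = p + "tact." + std::to_string(e + 1);
    nm[o + LC_TTH] = p + "tact_th";
    nm[o + LC_TTREG] = p + "tact_treg";
    nm[o + LC_IL2] = p + "il2";
    nm[o + LC_DRUG] = p + "drug";
  }
  return nm;
}

// ---------------------------------------------------------- parameters

static std::vector<std::string> make_par_names() {
  std::vector<std::string> nm;
  auto add = [&](const std::string &s) { nm.push_back(s); };
  auto addi = [&](const std::string &s, int n) {
    for (int i = 1; i <= n; ++i) add(s + "_" + std::to_string(i));
  };
  // cancer growth / death / capacity
  addi("k_growth", N_CLONE);
  add("k_death_cancer"); add("ln_cap");
  add("k_kill"); add("kd_ratio_half");
  add("k_k_growth"); add("k_k_decay"); add("k_min_capacity");
  add("k_max_capacity");
  add("ec50_angio_k");
  add("k_angio_cancer"); add("k_angio_m2"); add("k_deg_angio");
  add("v_cell"); add("k_clear_dead");
  // antigen release / degradation, clone x epitope expression (0/1)
  add("k_ag_release"); add("k_self_ag_release"); add("k_deg_ag");
  for (int c = 1; c <= N_CLONE; ++c)
    for (int e = 1; e <= N_EPI; ++e)
      add("epitope_expr_" + std::to_string(c) + "_" + std::to_string(e));
  // APCs
  addi("apc0", N_TUMOR);
  add("k_apc_turnover"); add("k_apc_mat"); add("ec50_ag_apc");
  add("a_il12_apc"); add("ec50_il12_apc"); add("ec50_il10_apc");
  add("k_apc_mig"); add("k_apc_death");
  // antigen presentation (quasi-steady pMHC per epitope + self)
  add("pmax_pmhc"); add("alpha_pmhc");
  addi("kd_pmhc", N_EPI + 1);
  // T-cell activation
  add("k_act_cd8"); add("k_act_th"); add("k_act_treg");
  add("ec50_apc_act"); add("n_tcr"); add("ec50_tcr");
  add("d_tcr"); add("d_cd28"); add("d_il2"); add("ec50_il2_div");
  add("cd28_total"); add("ctla4_total"); add("b7_total");
  add("kd_cd28_b7"); add("kd_ctla4_b7"); add("conv_synapse");
  add("k_egress");
  add("k_il2_sec"); add("k_deg_il2");
  // naive T-cell trafficking
  add("k_thymic_cd4"); add("k_thymic_cd8"); add("k_death_naive");
  add("q_c2ln"); add("q_ln2c"); add("q_c2p"); add("q_p2c");
  // effector T cells
  add("k_death_t"); add("k_death_treg"); add("q_infil"); add("f_vasc");
  add("k_exh_pd1"); add("k_exh_il10"); add("ec50_il10_exh");
  add("k_trans_th_treg"); add("ec50_tgfb_trans"); add("ec50_argi_trans");
  // PD-1 checkpoint
  add("pd1_total"); add("pdl2_level");
  add("kd_pd1_pdl1"); add("kd_pd1_pdl2"); add("kd_pd1_drug");
  add("conv_surface"); add("n_pd1"); add("ec50_pd1");
  // killing suppression
  add("ec50_tgfb_kill"); add("ec50_argi_kill"); add("ec50_no_kill");
  // myeloid
  addi("k_rec_m1", N_TUMOR); addi("k_rec_mdsc", N_TUMOR);
  add("ec50_ccl2");
  addi("k_pol_m1m2", N_TUMOR); add("k_pol_m2m1");
  add("a_il10_pol"); add("ec50_il10_pol");
  add("a_tgfb_pol"); add("ec50_tgfb_pol");
  add("a_il12_pol"); add("ec50_il12_pol");
  add("a_ifng_pol"); add("ec50_ifng_pol");
  add("k_death_mac"); add("k_death_mdsc");
  add("k_phag"); add("ec50_phag_c"); add("h_sirpa"); add("ec50_il10_phag");
  // cytokines
  add("k_il10_m2"); add("k_il10_treg"); add("k_deg_il10");
  add("k_il12_m1"); add("k_deg_il12");
  add("k_tgfb_m2"); add("k_deg_tgfb");
  add("k_ccl2_cancer"); add("k_deg_ccl2");
  add("k_ifng_tcyt"); add("k_deg_ifng");
  add("k_argi_mdsc"); add("k_deg_argi");
  add("k_no_mdsc"); add("k_deg_no");
  // PD-L1 expression
  add("pdl1_base"); add("k_pdl1_relax"); add("a_pdl1_ifng");
  add("ec50_pdl1_ifng");
  // clonotypes per neo-epitope specificity
  add("n_clonotypes");
  // pharmacokinetics
  add("v_central"); add("v_peripheral"); add("v_tumor"); add("v_ln");
  add("k_cl_drug"); add("q_cp_drug"); add("q_ct_drug");
  add("q_t2ln_drug"); add("q_ln2c_drug"); add("mw_drug");
  return nm;
}

static std::vector<std::string> &par_names() {
  static std::vector<std::string> nm = make_par_names();
  return nm;
}
static std::vector<std::string> &state_names() {
  static std::vector<std::string> nm = make_state_names();
  return nm;
}
static int PI(const std::string &s) {
  static std::map<std::string, int> idx;
  if (idx.empty())
    for (size_t i = 0; i < par_names().size(); ++i) idx[par_names()[i]] = (int)i;
  std::map<std::string, int>::iterator it = idx.find(s);
  if (it == idx.end()) stop("unknown parameter: " + s);
  return it->second;
}

// parameter storage for the deSolve compiled interface
static std::vector<double> PARMS;

// ------------------------------------------------------------- helpers

static inline double pos(double x) { return x > 0.0 ? x : 0.0; }
static inline double hill(double x, double ec50) {
  x = pos(x); return x / (x + ec50);
}
static inline double hilln(double x, double ec50, double n) {
  x = pos(x);
  if (x <= 0.0) return 0.0;
  double xn = std::pow(x, n), en = std::pow(ec50, n);
  return xn / (xn + en);
}
static inline double inh(double x, double ec50) { // EC50/(EC50+x)
  return ec50 / (ec50 + pos(x));
}

// Competitive quasi-equilibrium on PD-1: receptor and both ligands are
// depleted; the antibody is assumed in molar excess (free ~ total).
// Solves the scalar conservation equation for free receptor by bisection.
static void checkpoint_core(double r_tot, double l1_tot, double l2_tot,
                            double drug, double kd1, double kd2, double kdd,
                            double *f_lig, double *f_drug) {
  if (r_tot <= 0.0) { *f_lig = 0.0; *f_drug = 0.0; return; }
  double dterm = 1.0 + drug / kdd;
  double lo = 0.0, hi = r_tot / dterm, r = hi;
  for (int it = 0; it < 80; ++it) {
    r = 0.5 * (lo + hi);
    double bound = r * dterm
      + l1_tot * (r / kd1) / (1.0 + r / kd1)
      + l2_tot * (r / kd2) / (1.0 + r / kd2);
    if (bound > r_tot) hi = r; else lo = r;
  }
  r = 0.5 * (lo + hi);
  double b1 = l1_tot * (r / kd1) / (1.0 + r / kd1);
  double b2 = l2_tot * (r / kd2) / (1.0 + r / kd2);
  *f_lig = (b1 + b2) / r_tot;
  *f_drug = r * (drug / kdd) / r_tot;
  if (*f_lig < 0) *f_lig = 0; if (*f_lig > 1) *f_lig = 1;
  if (*f_drug < 0) *f_drug = 0; if (*f_drug > 1) *f_drug = 1;
}

// CD28 / CTLA-4 competition for the pooled B7 (CD80/CD86) ligand in the
// immune synapse; solves free-ligand conservation by bisection and returns
// the occupied fraction of CD28.
static double synapse_cd28_core(double cd28, double ctla4, double b7,
                                double kd28, double kd4) {
  if (b7 <= 0.0 || cd28 <= 0.0) return 0.0;
  double lo = 0.0, hi = b7, b = b7;
  for (int it = 0; it < 80; ++it) {
    b = 0.5 * (lo + hi);
    double tot = b + cd28 * b / (kd28 + b) + ctla4 * b / (kd4 + b);
    if (tot > b7) hi = b; else lo = b;
  }
  b = 0.5 * (lo + hi);
  return b / (kd28 + b);
}

static inline double gompertz_log(double K, double n_tot, double ln_cap) {
  double lg = std::log(K / (n_tot > 1.0 ? n_tot : 1.0));
  if (lg < -ln_cap) lg = -ln_cap;
  return lg;
}

// ------------------------------------------------------------- the RHS

static void rhs_core(double t, const double *y, double *dy, const double *p) {
  (void)t;
  // cached parameter indices (resolved once)
  static const int iKG0 = PI("k_growth_1");
  static const int iKDC = PI("k_death_cancer"), iLNC = PI("ln_cap");
  static const int iKK = PI("k_kill"), iKDR = PI("kd_ratio_half");
  static const int iKKG = PI("k_k_growth"), iKKD = PI("k_k_decay");
  static const int iKMIN = PI("k_min_capacity"), iECA = PI("ec50_angio_k");
  static const int iKMAX = PI("k_max_capacity");
  static const int iANC = PI("k_angio_cancer"), iANM = PI("k_angio_m2");
  static const int iDGA = PI("k_deg_angio");
  static const int iVC = PI("v_cell"), iCLD = PI("k_clear_dead");
  static const int iAGR = PI("k_ag_release"), iSAGR = PI("k_self_ag_release");
  static const int iDAG = PI("k_deg_ag");
  static const int iEXPR0 = PI("epitope_expr_1_1");
  static const int iAPC00 = PI("apc0_1");
  static const int iAPCT = PI("k_apc_turnover"), iAPCM = PI("k_apc_mat");
  static const int iECAG = PI("ec50_ag_apc");
  static const int iA12 = PI("a_il12_apc"), iEC12A = PI("ec50_il12_apc");
  static const int iEC10A = PI("ec50_il10_apc");
  static const int iMIG = PI("k_apc_mig"), iAPCD = PI("k_apc_death");
  static const int iPMX = PI("pmax_pmhc"), iALP = PI("alpha_pmhc");
  static const int iKDP0 = PI("kd_pmhc_1");
  static const int iACT8 = PI("k_act_cd8"), iACTH = PI("k_act_th");
  static const int iACTR = PI("k_act_treg");
  static const int iECAPC = PI("ec50_apc_act");
  static const int iNTCR = PI("n_tcr"), iECTCR = PI("ec50_tcr");
  static const int iDTCR = PI("d_tcr"), iDCD28 = PI("d_cd28");
  static const int iDIL2 = PI("d_il2"), iEC2D = PI("ec50_il2_div");
  static const int iC28 = PI("cd28_total"), iCT4 = PI("ctla4_total");
  static const int iB7 = PI("b7_total");
  static const int iKD28 = PI("kd_cd28_b7"), iKD4 = PI("kd_ctla4_b7");
  static const int iCSYN = PI("conv_synapse");
  static const int iEGR = PI("k_egress");
  static const int iIL2S = PI("k_il2_sec"), iIL2D = PI("k_deg_il2");
  static const int iTH4 = PI("k_thymic_cd4"), iTH8 = PI("k_thymic_cd8");
  static const int iKDN = PI("k_death_naive");
  static const int iQCL = PI("q_c2ln"), iQLC = PI("q_ln2c");
  static const int iQCP = PI("q_c2p"), iQPC = PI("q_p2c");
  static const int iKDT = PI("k_death_t"), iKDTR = PI("k_death_treg");
  static const int iQIN = PI("q_infil"), iFV = PI("f_vasc");
  static const int iEXP1 = PI("k_exh_pd1"), iEX10 = PI("k_exh_il10");
  static const int iEC10E = PI("ec50_il10_exh");
  static const int iTRANS = PI("k_trans_th_treg");
  static const int iECTGT = PI("ec50_tgfb_trans"), iECART = PI("ec50_argi_trans");
  static const int iPD1T = PI("pd1_total"), iPDL2 = PI("pdl2_level");
  static const int iKD1 = PI("kd_pd1_pdl1"), iKD2 = PI("kd_pd1_pdl2");
  static const int iKDD = PI("kd_pd1_drug");
  static const int iCSRF = PI("conv_surface");
  static const int iNPD = PI("n_pd1"), iECPD = PI("ec50_pd1");
  static const int iECTGK = PI("ec50_tgfb_kill"), iECARK = PI("ec50_argi_kill");
  static const int iECNOK = PI("ec50_no_kill");
  static const int iRM10 = PI("k_rec_m1_1"), iRMD0 = PI("k_rec_mdsc_1");
  static const int iECCL = PI("ec50_ccl2");
  static const int iP120 = PI("k_pol_m1m2_1"), iP21 = PI("k_pol_m2m1");
  static const int iA10P = PI("a_il10_pol"), iEC10P = PI("ec50_il10_pol");
  static const int iATGP = PI("a_tgfb_pol"), iECTGP = PI("ec50_tgfb_pol");
  static const int iA12P = PI("a_il12_pol"), iEC12P = PI("ec50_il12_pol");
  static const int iAIFP = PI("a_ifng_pol"), iECIFP = PI("ec50_ifng_pol");
  static const int iKDM = PI("k_death_mac"), iKDMD = PI("k_death_mdsc");
  static const int iPHG = PI("k_phag"), iECPH = PI("ec50_phag_c");
  static const int iSIRP = PI("h_sirpa"), iEC10PH = PI("ec50_il10_phag");
  static const int i10M2 = PI("k_il10_m2"), i10TR = PI("k_il10_treg");
  static const int iD10 = PI("k_deg_il10");
  static const int i12M1 = PI("k_il12_m1"), iD12 = PI("k_deg_il12");
  static const int iTGM2 = PI("k_tgfb_m2"), iDTG = PI("k_deg_tgfb");
  static const int iCCC = PI("k_ccl2_cancer"), iDCC = PI("k_deg_ccl2");
  static const int iIFT = PI("k_ifng_tcyt"), iDIF = PI("k_deg_ifng");
  static const int iARM = PI("k_argi_mdsc"), iDAR = PI("k_deg_argi");
  static const int iNOM = PI("k_no_mdsc"), iDNO = PI("k_deg_no");
  static const int iPDLB = PI("pdl1_base"), iPDLR = PI("k_pdl1_relax");
  static const int iPDLA = PI("a_pdl1_ifng"), iECPDL = PI("ec50_pdl1_ifng");
  static const int iVCEN = PI("v_central"), iVPER = PI("v_peripheral");
  static const int iVTUM = PI("v_tumor"), iVLN = PI("v_ln");
  static const int iCL = PI("k_cl_drug"), iQCPD = PI("q_cp_drug");
  static const int iQCT = PI("q_ct_drug"), iQTL = PI("q_t2ln_drug");
  static const int iQL2C = PI("q_ln2c_drug");

  for (int i = 0; i < N_STATE; ++i) dy[i] = 0.0;

  // synapse CD28 occupancy: constant in state (fixed CTLA-4 level)
  double conv_syn = p[iCSYN];
  double f_cd28 = synapse_cd28_core(p[iC28] * conv_syn, p[iCT4] * conv_syn,
                                    p[iB7] * conv_syn,
                                    p[iKD28], p[iKD4]);

  // per-LN accumulators: antigen pools from draining tumours
  double ln_ag[N_LN][N_EPI + 1];
  for (int l = 0; l < N_LN; ++l)
    for (int e = 0; e <= N_EPI; ++e) ln_ag[l][e] = 0.0;

  // ------------------------------------------------ tumour compartments
  for (int tt = 0; tt < N_TUMOR; ++tt) {
    const int o = TUM0 + tt * TUM_LEN;
    const int ln = TUM_OF_LN[tt];
    const int lo = LN0 + ln * LN_LEN;

    double Ctot = 0.0;
    for (int c = 0; c < N_CLONE; ++c) Ctot += pos(y[o + TC_CANCER + c]);
    double dead = pos(y[o + TC_DEAD]);
    double K = y[o + TC_K];
    double Ttot = 0.0;
    for (int e = 0; e < N_EPI; ++e) Ttot += pos(y[o + TC_TCYT + e]);
    double th = pos(y[o + TC_TH]), treg = pos(y[o + TC_TREG]);
    double m1 = pos(y[o + TC_M1]), m2 = pos(y[o + TC_M2]);
    double mdsc = pos(y[o + TC_MDSC]);
    double apci = pos(y[o + TC_APCI]), apcm = pos(y[o + TC_APCM]);
    double il10 = pos(y[o + TC_IL10]), il12 = pos(y[o + TC_IL12]);
    double ifng = pos(y[o + TC_IFNG]), tgfb = pos(y[o + TC_TGFB]);
    double ccl2 = pos(y[o + TC_CCL2]), angio = pos(y[o + TC_ANGIO]);
    double argi = pos(y[o + TC_ARGI]), no = pos(y[o + TC_NO]);
    double pdl1 = pos(y[o + TC_PDL1]), drug = pos(y[o + TC_DRUG]);

    // PD-1 occupancy and Hill inhibition
    double conv = p[iCSRF];
    double f_lig, f_drug;
    checkpoint_core(p[iPD1T] * conv, pdl1 * conv, p[iPDL2] * conv, drug,
                    p[iKD1], p[iKD2], p[iKDD], &f_lig, &f_drug);
    double h_pd1 = hilln(f_lig, p[iECPD], p[iNPD]);

    // cytotoxic T-cell killing (ratio-dependent, checkpoint/cytokine-inhibited)
    double kill = 0.0;
    if (Ctot > 0.0 && Ttot > 0.0) {
      double R = Ttot / (Ctot > 1.0 ? Ctot : 1.0);
      kill = p[iKK] * Ctot * (R / (R + p[iKDR])) * (1.0 - h_pd1)
        * inh(tgfb, p[iECTGK]) * inh(argi, p[iECARK]) * inh(no, p[iECNOK]);
    }
    // M1 phagocytosis of cancer cells
    double phag = 0.0;
    if (Ctot > 0.0 && m1 > 0.0) {
      phag = p[iPHG] * m1 * hill(Ctot, p[iECPH]) * (1.0 - h_pd1)
        * (1.0 - p[iSIRP]) * inh(il10, p[iEC10PH]);
    }

    // cancer clones: Gompertz growth, first-order apoptosis, kill/phag
    // apportioned proportional to clone abundance
    double lg = gompertz_log(K > 1.0 ? K : 1.0, Ctot, p[iLNC]);
    double death_flux[N_CLONE];
    for (int c = 0; c < N_CLONE; ++c) {
      double nc = pos(y[o + TC_CANCER + c]);
      double share = (Ctot > 0.0) ? nc / Ctot : 0.0;
      double apopt = p[iKDC] * nc;
      double killed = (kill + phag) * share;
      dy[o + TC_CANCER + c] = p[iKG0 + c] * nc * lg - apopt - killed;
      death_flux[c] = apopt + kill * share; // phagocytosed cells are consumed
    }
    double death_tot = 0.0;
    for (int c = 0; c < N_CLONE; ++c) death_tot += death_flux[c];

    dy[o + TC_DEAD] = death_tot - p[iCLD] * dead;

    // carrying capacity driven by angiogenic factor; smooth floor at the
    // baseline vascular support K_min and ceiling at K_max (regularized so
    // the RHS stays continuous at both bounds)
    double kg = p[iKKG] * K * hill(angio, p[iECA]) *
      (1.0 - K / p[iKMAX]);
    double kd = p[iKKD] * (K - p[iKMIN]);
    dy[o + TC_K] = kg - kd;

    dy[o + TC_ANGIO] = p[iANC] * Ctot + p[iANM] * m2 - p[iDGA] * angio;

    // antigen release from dying cancer cells (per-clone epitope expression)
    for (int e = 0; e < N_EPI; ++e) {
      double rel = 0.0;
      for (int c = 0; c < N_CLONE; ++c)
        rel += p[iEXPR0 + c * N_EPI + e] * death_flux[c];
      dy[o + TC_AG + e] = p[iAGR] * rel - p[iDAG] * pos(y[o + TC_AG + e]);
      ln_ag[ln][e] += pos(y[o + TC_AG + e]);
    }
    dy[o + TC_AG + N_EPI] =
      p[iSAGR] * death_tot - p[iDAG] * pos(y[o + TC_AG + N_EPI]);
    ln_ag[ln][N_EPI] += pos(y[o + TC_AG + N_EPI]);

    // APCs: turnover toward baseline, antigen-driven maturation
    // (IL-12 promotes, IL-10 inhibits), mature APCs migrate to draining LN
    double ag_tot = 0.0;
    for (int e = 0; e <= N_EPI; ++e) ag_tot += pos(y[o + TC_AG + e]);
    double mat = p[iAPCM] * apci * hill(ag_tot, p[iECAG])
      * (1.0 + p[iA12] * hill(il12, p[iEC12A])) * inh(il10, p[iEC10A]);
    dy[o + TC_APCI] = p[iAPCT] * (p[iAPC00 + tt] - apci) - mat;
    dy[o + TC_APCM] = mat - p[iMIG] * apcm - p[iAPCD] * apcm;
    dy[lo + LC_APCM] += p[iMIG] * apcm;

    // T-cell infiltration from central blood, scaled by tumour volume and
    // vascular volume fraction
    double vol = (Ctot + dead) * p[iVC]; // mL
    double inf_scale = p[iQIN] * vol * p[iFV];
    double exh_rate = p[iEXP1] * h_pd1 + p[iEX10] * hill(il10, p[iEC10E]);
    double exh_sum = 0.0;
    for (int e = 0; e < N_EPI; ++e) {
      double infil = inf_scale * pos(y[CEN + BC_TCYT + e]);
      double te = pos(y[o + TC_TCYT + e]);
      dy[o + TC_TCYT + e] = infil - p[iKDT] * te - exh_rate * te;
      dy[CEN + BC_TCYT + e] -= infil;
      exh_sum += exh_rate * te;
    }
    dy[o + TC_TEX] = exh_sum - p[iKDT] * pos(y[o + TC_TEX]);

    double infil_th = inf_scale * pos(y[CEN + BC_TH]);
    double infil_tr = inf_scale * pos(y[CEN + BC_TREG]);
    dy[CEN + BC_TH] -= infil_th;
    dy[CEN + BC_TREG] -= infil_tr;
    double trans = p[iTRANS] * (hill(tgfb, p[iECTGT]) + hill(argi, p[iECART]));
    dy[o + TC_TH] = infil_th - (p[iKDT] + exh_rate + trans) * th;
    dy[o + TC_TREG] = infil_tr + trans * th - p[iKDTR] * treg;

    // myeloid: CCL2-mediated recruitment, reversible polarization
    double h_ccl2 = hill(ccl2, p[iECCL]);
    double rec_m1 = p[iRM10 + tt] * h_ccl2 * vol * p[iFV];
    double rec_md = p[iRMD0 + tt] * h_ccl2 * vol * p[iFV];
    double pol12 = p[iP120 + tt] * m1 *
      (1.0 + p[iA10P] * hill(il10, p[iEC10P]) + p[iATGP] * hill(tgfb, p[iECTGP]));
    double pol21 = p[iP21] * m2 *
      (1.0 + p[iA12P] * hill(il12, p[iEC12P]) + p[iAIFP] * hill(ifng, p[iECIFP]));
    dy[o + TC_M1] = rec_m1 - pol12 + pol21 - p[iKDM] * m1;
    dy[o + TC_M2] = pol12 - pol21 - p[iKDM] * m2;
    dy[o + TC_MDSC] = rec_md - p[iKDMD] * mdsc;

    // cytokines / soluble mediators
    dy[o + TC_IL10] = p[i10M2] * m2 + p[i10TR] * treg - p[iD10] * il10;
    dy[o + TC_IL12] = p[i12M1] * m1 - p[iD12] * il12;
    dy[o + TC_TGFB] = p[iTGM2] * m2 - p[iDTG] * tgfb;
    dy[o + TC_CCL2] = p[iCCC] * Ctot - p[iDCC] * ccl2;
    dy[o + TC_IFNG] = p[iIFT] * Ttot - p[iDIF] * ifng;
    dy[o + TC_ARGI] = p[iARM] * mdsc - p[iDAR] * argi;
    dy[o + TC_NO] = p[iNOM] * mdsc - p[iDNO] * no;

    // PD-L1: relaxation toward baseline + IFN-gamma induced level
    double pdl1_tgt = p[iPDLB] * (1.0 + p[iPDLA] * hill(ifng, p[iECPDL]));
    dy[o + TC_PDL1] = p[iPDLR] * (pdl1_tgt - pdl1);

    // drug: central <-> tumour exchange, tumour -> draining LN lymph flow
    double Dc = pos(y[CEN + BC_DRUG]);
    double jin = p[iQCT] * (Dc - drug);            // nmol/day ( / L conc )
    double jlymph = p[iQTL] * drug;
    dy[o + TC_DRUG] += (jin - jlymph) / p[iVTUM];
    dy[CEN + BC_DRUG] -= jin / p[iVCEN];
    dy[lo + LC_DRUG] += jlymph / p[iVLN];
  }

  // -------------------------------------------------- lymph nodes
  for (int l = 0; l < N_LN; ++l) {
    const int o = LN0 + l * LN_LEN;
    double n4 = pos(y[o + LC_N4]), n8 = pos(y[o + LC_N8]);
    double apcm = pos(y[o + LC_APCM]);
    double il2 = pos(y[o + LC_IL2]);

    dy[o + LC_APCM] += -p[iAPCD] * apcm;

    double h_apc = hill(apcm, p[iECAPC]);
    double f_il2 = hill(il2, p[iEC2D]);

    // per-epitope activation of naive CD8 T cells
    double act8_tot = 0.0;
    for (int e = 0; e < N_EPI; ++e) {
      double ag = ln_ag[l][e];
      double pmhc = p[iPMX] * ag / (ag + p[iALP] * p[iKDP0 + e]);
      double h_tcr = hilln(pmhc, p[iECTCR], p[iNTCR]);
      double act = p[iACT8] * n8 * h_apc * h_tcr;
      double ndiv = p[iDTCR] * h_tcr + p[iDCD28] * f_cd28 + p[iDIL2] * f_il2;
      double out = act * std::pow(2.0, ndiv);
      double tact = pos(y[o + LC_TACT + e]);
      dy[o + LC_TACT + e] = out - (p[iEGR] + p[iKDT]) * tact;
      dy[CEN + BC_TCYT + e] += p[iEGR] * tact;
      act8_tot += act;
    }
    // self-antigen-driven activation of Th and Treg from naive CD4
    double ags = ln_ag[l][N_EPI];
    double pmhcs = p[iPMX] * ags / (ags + p[iALP] * p[iKDP0 + N_EPI]);
    double h_tcrs = hilln(pmhcs, p[iECTCR], p[iNTCR]);
    double ndivs = p[iDTCR] * h_tcrs + p[iDCD28] * f_cd28 + p[iDIL2] * f_il2;
    double amp = std::pow(2.0, ndivs);
    double act_th = p[iACTH] * n4 * h_apc * h_tcrs;
    double act_tr = p[iACTR] * n4 * h_apc * h_tcrs;
    double tth = pos(y[o + LC_TTH]), ttr = pos(y[o + LC_TTREG]);
    dy[o + LC_TTH] = act_th * amp - (p[iEGR] + p[iKDT]) * tth;
    dy[o + LC_TTREG] = act_tr * amp - (p[iEGR] + p[iKDT]) * ttr;
    dy[CEN + BC_TH] += p[iEGR] * tth;
    dy[CEN + BC_TREG] += p[iEGR] * ttr;

    dy[o + LC_IL2] = p[iIL2S] * tth - p[iIL2D] * il2;

    // naive trafficking central <-> LN; consumption by activation
    dy[o + LC_N4] = p[iQCL] * pos(y[CEN + BC_N4]) - p[iQLC] * n4
      - p[iKDN] * n4 - act_th - act_tr;
    dy[o + LC_N8] = p[iQCL] * pos(y[CEN + BC_N8]) - p[iQLC] * n8
      - p[iKDN] * n8 - act8_tot;
    dy[CEN + BC_N4] += p[iQLC] * n4 - p[iQCL] * pos(y[CEN + BC_N4]);
    dy[CEN + BC_N8] += p[iQLC] * n8 - p[iQCL] * pos(y[CEN + BC_N8]);

    // LN drug drains back to the central compartment
    double jout = p[iQL2C] * pos(y[o + LC_DRUG]);
    dy[o + LC_DRUG] -= jout / p[iVLN];
    dy[CEN + BC_DRUG] += jout / p[iVCEN];
  }

  // -------------------------------------- central / peripheral pools
  double n4c = pos(y[CEN + BC_N4]), n8c = pos(y[CEN + BC_N8]);
  double n4p = pos(y[PER + BC_N4]), n8p = pos(y[PER + BC_N8]);
  dy[CEN + BC_N4] += p[iTH4] - p[iKDN] * n4c - p[iQCP] * n4c + p[iQPC] * n4p;
  dy[CEN + BC_N8] += p[iTH8] - p[iKDN] * n8c - p[iQCP] * n8c + p[iQPC] * n8p;
  dy[PER + BC_N4] = p[iQCP] * n4c - (p[iQPC] + p[iKDN]) * n4p;
  dy[PER + BC_N8] = p[iQCP] * n8c - (p[iQPC] + p[iKDN]) * n8p;
  for (int e = 0; e < N_EPI; ++e)
    dy[CEN + BC_TCYT + e] -= p[iKDT] * pos(y[CEN + BC_TCYT + e]);
  dy[CEN + BC_TH] -= p[iKDT] * pos(y[CEN + BC_TH]);
  dy[CEN + BC_TREG] -= p[iKDTR] * pos(y[CEN + BC_TREG]);
  // peripheral effector pools are inert placeholders (no tumour there)
  for (int e = 0; e < N_EPI; ++e) dy[PER + BC_TCYT + e] = 0.0;
  dy[PER + BC_TH] = 0.0; dy[PER + BC_TREG] = 0.0;

  // drug: clearance + central <-> peripheral exchange
  double Dc = pos(y[CEN + BC_DRUG]), Dp = pos(y[PER + BC_DRUG]);
  double jcp = p[iQCPD] * (Dc - Dp);
  dy[CEN + BC_DRUG] += (-p[iCL] * Dc * p[iVCEN] - jcp) / p[iVCEN];
  dy[PER + BC_DRUG] += jcp / p[iVPER];
}

// ------------------------------------------- deSolve compiled interface

extern "C" {

void initmod_tnbc(void (*odeparms)(int *, double *)) {
  int n = (int)par_names().size();
  PARMS.assign(n, 0.0);
  odeparms(&n, PARMS.data());
}

void derivs_tnbc(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip) {
  (void)yout; (void)ip;
  if (*neq != N_STATE) return;
  rhs_core(*t, y, ydot, PARMS.data());
}

} // extern "C"

// ------------------------------------------------------- registration
//
// A hand-written init so that the deSolve entry points (plain C symbols)
// are registered alongside the Rcpp .Call wrappers.

#include <R_ext/Rdynload.h>

extern "C" {
SEXP _tnbcqsp_qsp_state_names_cpp(void);
SEXP _tnbcqsp_qsp_param_names_cpp(void);
SEXP _tnbcqsp_qsp_rhs_cpp(SEXP, SEXP, SEXP);
SEXP _tnbcqsp_qsp_checkpoint_cpp(SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP);
SEXP _tnbcqsp_qsp_synapse_cd28_cpp(SEXP, SEXP, SEXP, SEXP, SEXP);

static const R_CallMethodDef CallEntries[] = {
  {"_tnbcqsp_qsp_state_names_cpp", (DL_FUNC) &_tnbcqsp_qsp_state_names_cpp, 0},
  {"_tnbcqsp_qsp_param_names_cpp", (DL_FUNC) &_tnbcqsp_qsp_param_names_cpp, 0},
  {"_tnbcqsp_qsp_rhs_cpp", (DL_FUNC) &_tnbcqsp_qsp_rhs_cpp, 3},
  {"_tnbcqsp_qsp_checkpoint_cpp", (DL_FUNC) &_tnbcqsp_qsp_checkpoint_cpp, 7},
  {"_tnbcqsp_qsp_synapse_cd28_cpp", (DL_FUNC) &_tnbcqsp_qsp_synapse_cd28_cpp, 5},
  {NULL, NULL, 0}
};

static const R_CMethodDef CEntries[] = {
  {"initmod_tnbc", (DL_FUNC) &initmod_tnbc, 1},
  {"derivs_tnbc", (DL_FUNC) &derivs_tnbc, 6},
  {NULL, NULL, 0}
};

void R_init_tnbcqsp(DllInfo *dll) {
  R_registerRoutines(dll, CEntries, CallEntries, NULL, NULL);
  R_useDynamicSymbols(dll, TRUE);
}
} // extern "C"

// ------------------------------------------------------- Rcpp exports

// [[Rcpp::export]]
CharacterVector qsp_state_names_cpp() {
  return wrap(state_names());
}

// [[Rcpp::export]]
CharacterVector qsp_param_names_cpp() {
  return wrap(par_names());
}

// [[Rcpp::export]]
NumericVector qsp_rhs_cpp(double t, NumericVector y, NumericVector p) {
  if ((int)y.size() != N_STATE) stop("state vector has wrong length");
  if ((int)p.size() != (int)par_names().size())
    stop("parameter vector has wrong length");
  for (int i = 0; i < (int)y.size(); ++i)
    if (!R_finite(y[i]))
      stop("non-finite state entry: " + state_names()[i]);
  NumericVector dy(N_STATE);
  rhs_core(t, y.begin(), dy.begin(), p.begin());
  for (int i = 0; i < N_STATE; ++i)
    if (!R_finite(dy[i]))
      stop("non-finite derivative for species: " + state_names()[i]);
  dy.names() = wrap(state_names());
  return dy;
}

// [[Rcpp::export]]
NumericVector qsp_checkpoint_cpp(double receptor_total, double pdl1,
                                 double pdl2, double drug, double kd1,
                                 double kd2, double kdd) {
  double fl, fd;
  checkpoint_core(receptor_total, pdl1, pdl2, drug, kd1, kd2, kdd, &fl, &fd);
  return NumericVector::create(_["bound_ligand_fraction"] = fl,
                               _["bound_drug_fraction"] = fd);
}

// [[Rcpp::export]]
double qsp_synapse_cd28_cpp(double cd28_total, double ctla4_total,
                            double b7_total, double kd_cd28, double kd_ctla4) {
  return synapse_cd28_core(cd28_total, ctla4_total, b7_total,
                           kd_cd28, kd_ctla4);
}
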