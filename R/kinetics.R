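#' Gompertzian growth rate of a cancer clone
#'
#' Cancer-clone growth follows a modified Gompertzian law: the per-cell
#' growth rate is proportional to \code{log(K / N_total)}, where \code{K} is
#' the (dynamic) carrying capacity supported by the tumour vasculature and
#' \code{N_total} the total cancer-cell burden across all clones. When the
#' burden exceeds the capacity the logarithm turns negative (net cell loss);
#' its magnitude is clipped at \code{ln_cap} to bound system stiffness.
#'
#' @param n_clone Cells in the clone.
#' @param n_total Total cancer cells in the lesion (all clones).
#' @param K Carrying capacity, cells; must be positive.
#' @param k_growth Clone growth-rate constant, 1/day.
#' @param ln_cap Clip on the magnitude of the negative log term.
#' @return Growth rate in cells/day.
#' @examples
#' gompertz_growth_rate(1e6, 1e6, 1e9, 0.01)  # ~6.9e4 cells/day
#' @export
gompertz_growth_rate <- function(n_clone, n_total, K, k_growth, ln_cap = 10) {
  if (any(!is.finite(c(n_clone, n_total, K, k_growth))))
    stop("non-finite input to gompertz_growth_rate (corrupted state?)")
  stopifnot(n_clone >= 0, n_total >= 0, K > 0, k_growth >= 0)
  lg <- log(K / max(n_total, 1))
  lg <- max(lg, -ln_cap)
  k_growth * n_clone * lg
}

#' Carrying-capacity (tumour vasculature) dynamics
#'
#' The carrying capacity grows with angiogenic-factor stimulation (saturating
#' in the factor concentration) and decays at a first-order rate, so the
#' vasculature regresses when angiogenic support is withdrawn.
#'
#' With the default bounds (\code{K_min = 0}, \code{K_max = Inf}) the rate
#' is exactly \code{k_K_growth K A/(A + ec50) - k_K_decay K}; finite bounds
#' regularize it smoothly so the capacity stays between the baseline
#' vascular support and the vascular ceiling.
#'
#' @param K Carrying capacity, cells (> 0).
#' @param angiogenic_factor Angiogenic-factor concentration, nM.
#' @param k_K_growth,k_K_decay Vasculature growth/decay rates, 1/day.
#' @param ec50_angio Half-saturation of the angiogenic stimulus, nM.
#' @param K_min,K_max Smooth lower/upper capacity bounds, cells.
#' @return dK/dt in cells/day.
#' @export
carrying_capacity_rate <- function(K, angiogenic_factor, k_K_growth,
                                   k_K_decay, ec50_angio,
                                   K_min = 0, K_max = Inf) {
  stopifnot(K > 0, angiogenic_factor >= 0)
  A <- angiogenic_factor
  k_K_growth * K * A / (A + ec50_angio) * (1 - K / K_max) -
    k_K_decay * (K - K_min)
}

#' Quasi-equilibrium PD-1 checkpoint occupancy
#'
#' Competitive binding of PD-1 to its ligands PD-L1/PD-L2 and to the
#' blocking antibody, solved at quasi-equilibrium from the conservation
#' equations (receptor and ligands depleted; the antibody is in molar
#' excess). Surface densities (molecules/cell) are converted to synapse
#' concentrations through \code{conv_surface}.
#'
#' @param receptor_total Total PD-1, molecules/cell.
#' @param pdl1,pdl2 Ligand surface densities, molecules/cell.
#' @param drug Antibody concentration in the compartment, nM.
#' @param kd_pdl1,kd_pdl2,kd_drug Dissociation constants, nM.
#' @param conv_surface nM per (molecule/cell) conversion factor.
#' @return Named vector with \code{bound_ligand_fraction} and
#'   \code{bound_drug_fraction}, both in \[0, 1\].
#' @export
checkpoint_occupancy <- function(receptor_total, pdl1, pdl2 = 0, drug = 0,
                                 kd_pdl1 = 8000, kd_pdl2 = 2000,
                                 kd_drug = 0.03, conv_surface = 1) {
  if (any(c(receptor_total, pdl1, pdl2, drug) < 0))
    stop("negative totals in checkpoint_occupancy")
  stopifnot(kd_pdl1 > 0, kd_pdl2 > 0, kd_drug > 0)
  qsp_checkpoint_cpp(receptor_total * conv_surface, pdl1 * conv_surface,
                     pdl2 * conv_surface, drug, kd_pdl1, kd_pdl2, kd_drug)
}

#' CD28 occupancy under CTLA-4 competition in the immune synapse
#'
#' CD28 and CTLA-4 compete for the pooled CD80/CD86 (B7) ligand; the
#' two-receptor/one-ligand equilibrium is solved for the free ligand and the
#' occupied CD28 fraction is returned. CTLA-4 level is a fixed parameter
#' (CTLA-4-directed therapy is out of scope).
#'
#' @param cd28_total,ctla4_total,b7_total Surface densities, molecules/cell.
#' @param kd_cd28,kd_ctla4 Dissociation constants, nM.
#' @param conv_synapse nM per (molecule/cell) conversion in the synapse.
#' @return CD28 occupied fraction in \[0, 1\].
#' @export
synapse_cd28_occupancy <- function(cd28_total, ctla4_total, b7_total,
                                   kd_cd28 = 4000, kd_ctla4 = 200,
                                   conv_synapse = 1) {
  stopifnot(cd28_total >= 0, ctla4_total >= 0, b7_total >= 0)
  qsp_synapse_cd28_cpp(cd28_total * conv_synapse, ctla4_total * conv_synapse,
                       b7_total * conv_synapse, kd_cd28, kd_ctla4)
}

#' Ratio-dependent cytotoxic killing rate
#'
#' Killing of cancer cells by tumour-infiltrating cytotoxic T cells depends
#' saturably on the effector:target ratio, is reduced by PD-1 engagement,
#' and is inhibited by TGF-beta, arginase-I and nitric oxide.
#'
#' @param C_total Cancer cells in the lesion.
#' @param Tcyt Active cytotoxic T cells (all specificities pooled).
#' @param pd1_inhibition PD-1 Hill inhibition in \[0, 1\].
#' @param tgfb,argi,no Suppressive-mediator concentrations, nM.
#' @param k_kill Maximal killing rate constant, 1/day.
#' @param kd_ratio_half T:C ratio at half-maximal killing.
#' @param ec50_tgfb,ec50_argi,ec50_no Inhibition half-max constants, nM.
#' @return Total kill flux in cells/day. Apportioning across clones
#'   (proportional to clone abundance) is handled by the ODE right-hand side.
#' @export
cytotoxic_killing_rate <- function(C_total, Tcyt, pd1_inhibition = 0,
                                   tgfb = 0, argi = 0, no = 0,
                                   k_kill = 2, kd_ratio_half = 0.3,
                                   ec50_tgfb = 0.5, ec50_argi = 20,
                                   ec50_no = 20) {
  stopifnot(C_total >= 0, Tcyt >= 0,
            pd1_inhibition >= 0, pd1_inhibition <= 1)
  if (C_total == 0 || Tcyt == 0) return(0)
  R <- Tcyt / max(C_total, 1)
  k_kill * C_total * R / (R + kd_ratio_half) * (1 - pd1_inhibition) *
    (ec50_tgfb / (ec50_tgfb + tgfb)) *
    (ec50_argi / (ec50_argi + argi)) *
    (ec50_no / (ec50_no + no))
}

#' Naive T-cell activation flux and division number
#'
#' Activation of naive T cells in a lymph node is driven by TCR ligation by
#' peptide-MHC on mature APCs (Hill function) and saturating APC
#' availability. The number of divisions of activated cells is a linear sum
#' of TCR, CD28 (competitively inhibited by CTLA-4) and IL-2 contributions;
#' the activated output is amplified by \code{2^n_divisions}.
#'
#' @param naive Naive T cells available.
#' @param mAPC Mature APCs in the lymph node.
#' @param pmhc_level Presented peptide-MHC level (dimensionless).
#' @param il2 IL-2 concentration, nM.
#' @param f_cd28 CD28 occupied fraction (see [synapse_cd28_occupancy()]).
#' @param k_act Activation rate constant, 1/day.
#' @param ec50_apc APC half-saturation, cells.
#' @param ec50_tcr,n_tcr TCR Hill constants.
#' @param d_tcr,d_cd28,d_il2 Division-number weights.
#' @param ec50_il2 IL-2 half-saturation, nM.
#' @return List with \code{activation} (cells/day leaving the naive pool),
#'   \code{n_divisions}, and \code{output} (cells/day entering the activated
#'   pool, \code{activation * 2^n_divisions}).
#' @export
tcell_activation_flux <- function(naive, mAPC, pmhc_level, il2 = 0,
                                  f_cd28 = 0, k_act = 0.1, ec50_apc = 1e5,
                                  ec50_tcr = 0.3, n_tcr = 2,
                                  d_tcr = 2, d_cd28 = 1.5, d_il2 = 1,
                                  ec50_il2 = 1) {
  stopifnot(naive >= 0, mAPC >= 0, pmhc_level >= 0, il2 >= 0)
  h_tcr <- if (pmhc_level > 0)
    pmhc_level^n_tcr / (pmhc_level^n_tcr + ec50_tcr^n_tcr) else 0
  act <- k_act * naive * mAPC / (mAPC + ec50_apc) * h_tcr
  ndiv <- d_tcr * h_tcr + d_cd28 * f_cd28 + d_il2 * il2 / (il2 + ec50_il2)
  list(activation = act, n_divisions = ndiv, output = act * 2^ndiv)
}

#' Myeloid-cell fluxes in a tumour compartment
#'
#' CCL2-mediated recruitment of M1 macrophages and MDSCs (scaled by the
#' vascular exchange surface), reversible M1/M2 polarization modulated by
#' IL-10/TGF-beta (towards M2) and IL-12/IFN-gamma (towards M1), and
#' checkpoint- and IL-10-inhibited phagocytosis of cancer cells.
#'
#' @param state Named list or vector with entries \code{m1, m2, mdsc,
#'   cancer, ccl2, il10, il12, ifng, tgfb} (cells / nM).
#' @param params Full model parameter vector ([default_parameters()]).
#' @param tumor_index Tumour compartment index 1-4 (selects per-tumour
#'   recruitment/polarization rates).
#' @param volume_mL Lesion volume in mL (vascular scaling of recruitment).
#' @param pd1_inhibition PD-1 Hill inhibition acting on macrophages.
#' @return Named list of fluxes in cells/day: \code{M1_recruit,
#'   MDSC_recruit, M1toM2, M2toM1, phagocytosis}.
#' @export
myeloid_fluxes <- function(state, params = default_parameters(),
                           tumor_index = 1, volume_mL = 1,
                           pd1_inhibition = 0) {
  s <- as.list(state)
  p <- params
  h <- function(x, ec) x / (x + ec)
  h_ccl2 <- h(s$ccl2, p[["ec50_ccl2"]])
  vfac <- volume_mL * p[["f_vasc"]]
  rec_m1 <- p[[paste0("k_rec_m1_", tumor_index)]] * h_ccl2 * vfac
  rec_md <- p[[paste0("k_rec_mdsc_", tumor_index)]] * h_ccl2 * vfac
  pol12 <- p[[paste0("k_pol_m1m2_", tumor_index)]] * s$m1 *
    (1 + p[["a_il10_pol"]] * h(s$il10, p[["ec50_il10_pol"]]) +
       p[["a_tgfb_pol"]] * h(s$tgfb, p[["ec50_tgfb_pol"]]))
  pol21 <- p[["k_pol_m2m1"]] * s$m2 *
    (1 + p[["a_il12_pol"]] * h(s$il12, p[["ec50_il12_pol"]]) +
       p[["a_ifng_pol"]] * h(s$ifng, p[["ec50_ifng_pol"]]))
  phag <- p[["k_phag"]] * s$m1 * h(s$cancer, p[["ec50_phag_c"]]) *
    (1 - pd1_inhibition) * (1 - p[["h_sirpa"]]) /
    (1 + s$il10 / p[["ec50_il10_phag"]])
  list(M1_recruit = rec_m1, MDSC_recruit = rec_md,
       M1toM2 = pol12, M2toM1 = pol21, phagocytosis = phag)
}

#' Lesion diameter from cancer-cell count
#'
#' Treats the lesion as a sphere made up of the cancer-cell volume only
#' (immune and stromal volume are ignored, a documented simplification):
#' \code{d = (6 N v_cell / pi)^(1/3)} in cm.
#'
#' @param cancer_cells_total Total cancer cells in the lesion.
#' @param cell_volume Volume of one cell in mL.
#' @return Diameter in cm (0 when the lesion is empty).
#' @examples
#' tumor_diameter(1e9, 1e-9)  # ~1.24 cm
#' @export
tumor_diameter <- function(cancer_cells_total, cell_volume = 1e-9) {
  stopifnot(all(cancer_cells_total >= 0), cell_volume >= 0)
  (6 * cancer_cells_total * cell_volume / pi)^(1 / 3)
}

#' PD-1 pathway inhibition relief by checkpoint blockade
#'
#' The inhibitory strength of the PD-1 pathway is a Hill function of the
#' ligand-bound PD-1 fraction; antibody binding displaces ligand occupancy
#' and thereby relieves the inhibition.
#'
#' @inheritParams checkpoint_occupancy
#' @param n_pd1,ec50_pd1 Hill constants on the bound-ligand fraction.
#' @return Hill inhibition value in \[0, 1\] (decreasing in \code{drug}).
#' @export
pd1_inhibition_relief <- function(receptor_total, pdl1, pdl2 = 0, drug = 0,
                                  kd_pdl1 = 8000, kd_pdl2 = 2000,
                                  kd_drug = 0.03, conv_surface = 1,
                                  n_pd1 = 2, ec50_pd1 = 0.5) {
  occ <- checkpoint_occupancy(receptor_total, pdl1, pdl2, drug,
                              kd_pdl1, kd_pdl2, kd_drug, conv_surface)
  b <- occ[["bound_ligand_fraction"]]
  if (b <= 0) return(0)
  b^n_pd1 / (b^n_pd1 + ec50_pd1^n_pd1)
}
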