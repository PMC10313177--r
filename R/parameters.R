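#' Canonical parameter and state-vector names
#'
#' The ODE core works on flat numeric vectors. These helpers expose the
#' canonical ordering so configuration files, samplers and outputs all agree.
#'
#' @return Character vector of names in canonical order.
#' @export
qsp_param_names <- function() qsp_param_names_cpp()

#' @rdname qsp_param_names
#' @export
qsp_state_names <- function() qsp_state_names_cpp()

#' Default kinetic, structural and pharmacokinetic parameters
#'
#' Returns the full named parameter vector of the model with default values.
#' Units follow the package convention: cells for cell counts, nM for soluble
#' species, molecules/cell for surface species, day for time. Defaults are
#' representative literature-scale values for a human metastatic TNBC
#' setting; they are documented in the methods vignette and are fully
#' overridable (all cohort-level variability is applied on top of them).
#'
#' @return Named numeric vector, in the canonical order of
#'   [qsp_param_names()].
#' @export
default_parameters <- function() {
  p <- stats::setNames(numeric(length(qsp_param_names())), qsp_param_names())

  ## -- cancer growth (1/day) and capacity dynamics
  p[paste0("k_growth_", 1:5)] <- c(0.035, 0.040, 0.045, 0.050, 0.055)
  p["k_death_cancer"] <- 0.005
  p["ln_cap"]         <- 10          # clip on |ln(K/N)| when N > K
  p["k_kill"]         <- 2.0
  p["kd_ratio_half"]  <- 0.3         # T:C ratio at half-maximal killing
  p["k_k_growth"]     <- 0.08
  p["k_k_decay"]      <- 0.04
  p["k_min_capacity"] <- 1e7         # baseline vascular support, cells
  p["k_max_capacity"] <- 1e11        # vascular ceiling, cells (~5.8 cm)
  p["ec50_angio_k"]   <- 0.5         # nM
  p["k_angio_cancer"] <- 1e-7        # nM/cell/day
  p["k_angio_m2"]     <- 5e-7
  p["k_deg_angio"]    <- 0.1
  p["v_cell"]         <- 1e-9        # mL per cancer cell
  p["k_clear_dead"]   <- 0.1

  ## -- antigen release and degradation
  p["k_ag_release"]      <- 1e-9     # nM per dying cell
  p["k_self_ag_release"] <- 2e-9
  p["k_deg_ag"]          <- 0.1
  ## clone x neo-epitope expression (binary); clones differ in burden
  expr <- matrix(0, 5, 8)
  expr[1, 1:4] <- 1
  expr[2, 3:6] <- 1
  expr[3, 5:8] <- 1
  expr[4, c(1, 8)] <- 1
  expr[5, c(2, 7)] <- 1
  for (cl in 1:5) for (e in 1:8)
    p[sprintf("epitope_expr_%d_%d", cl, e)] <- expr[cl, e]

  ## -- antigen-presenting cells
  p[paste0("apc0_", 1:4)] <- 1e6
  p["k_apc_turnover"] <- 0.1
  p["k_apc_mat"]      <- 0.3
  p["ec50_ag_apc"]    <- 0.05        # nM total antigen
  p["a_il12_apc"]     <- 1
  p["ec50_il12_apc"]  <- 1
  p["ec50_il10_apc"]  <- 2
  p["k_apc_mig"]      <- 0.3
  p["k_apc_death"]    <- 0.05

  ## -- quasi-steady antigen presentation
  p["pmax_pmhc"]  <- 1
  p["alpha_pmhc"] <- 0.1
  p[paste0("kd_pmhc_", 1:9)] <- c(0.5, 0.8, 1.0, 1.2, 0.6, 1.5, 0.9, 1.1, 2.0)

  ## -- T-cell activation in lymph nodes
  p["k_act_cd8"]    <- 0.1
  p["k_act_th"]     <- 0.08
  p["k_act_treg"]   <- 0.025
  p["ec50_apc_act"] <- 1e5
  p["n_tcr"]        <- 2
  p["ec50_tcr"]     <- 0.3
  p["d_tcr"]        <- 2
  p["d_cd28"]       <- 1.5
  p["d_il2"]        <- 1
  p["ec50_il2_div"] <- 1             # nM
  p["cd28_total"]   <- 2e4           # molecules/cell
  p["ctla4_total"]  <- 2e3
  p["b7_total"]     <- 3e4
  p["kd_cd28_b7"]   <- 4000          # nM, low-affinity CD28:B7
  p["kd_ctla4_b7"]  <- 200           # nM, high-affinity CTLA-4:B7
  p["conv_synapse"] <- 1             # nM per molecule/cell in the synapse
  p["k_egress"]     <- 0.5
  p["k_il2_sec"]    <- 1e-8          # nM/cell/day
  p["k_deg_il2"]    <- 2

  ## -- naive T-cell homeostasis and trafficking
  p["k_thymic_cd4"] <- 1e7           # cells/day
  p["k_thymic_cd8"] <- 5e6
  p["k_death_naive"] <- 0.002
  p["q_c2ln"] <- 0.05                # 1/day, per lymph node
  p["q_ln2c"] <- 0.6
  p["q_c2p"]  <- 0.3
  p["q_p2c"]  <- 0.1

  ## -- effector T cells
  p["k_death_t"]    <- 0.02
  p["k_death_treg"] <- 0.02
  p["q_infil"]      <- 0.1           # 1/day per (mL x vascular fraction)
  p["f_vasc"]       <- 0.05
  p["k_exh_pd1"]    <- 0.05
  p["k_exh_il10"]   <- 0.02
  p["ec50_il10_exh"] <- 1
  p["k_trans_th_treg"] <- 0.02
  p["ec50_tgfb_trans"] <- 1
  p["ec50_argi_trans"] <- 20

  ## -- PD-1 checkpoint
  p["pd1_total"]   <- 3000           # molecules/cell
  p["pdl2_level"]  <- 1000
  p["kd_pd1_pdl1"] <- 8000           # nM (surface-equivalent)
  p["kd_pd1_pdl2"] <- 2000
  p["kd_pd1_drug"] <- 0.03           # nM, pembrolizumab
  p["conv_surface"] <- 1             # nM per molecule/cell
  p["n_pd1"]   <- 2
  p["ec50_pd1"] <- 0.5               # on the bound-ligand fraction

  ## -- suppression of cytotoxicity
  p["ec50_tgfb_kill"] <- 0.5         # nM
  p["ec50_argi_kill"] <- 20
  p["ec50_no_kill"]   <- 20

  ## -- myeloid compartment
  p[paste0("k_rec_m1_", 1:4)]   <- 5e7   # cells/day per (mL x f_vasc)
  p[paste0("k_rec_mdsc_", 1:4)] <- 2e7
  p["ec50_ccl2"] <- 5
  p[paste0("k_pol_m1m2_", 1:4)] <- 0.1
  p["k_pol_m2m1"]  <- 0.05
  p["a_il10_pol"]  <- 2;   p["ec50_il10_pol"] <- 1
  p["a_tgfb_pol"]  <- 2;   p["ec50_tgfb_pol"] <- 1
  p["a_il12_pol"]  <- 2;   p["ec50_il12_pol"] <- 1
  p["a_ifng_pol"]  <- 2;   p["ec50_ifng_pol"] <- 0.2
  p["k_death_mac"]  <- 0.02
  p["k_death_mdsc"] <- 0.05
  p["k_phag"]      <- 0.05
  p["ec50_phag_c"] <- 1e8
  p["h_sirpa"]     <- 0.5            # constant SIRP-alpha inhibition
  p["ec50_il10_phag"] <- 1

  ## -- cytokines (secretion nM/cell/day, degradation 1/day)
  p["k_il10_m2"]   <- 1e-8;  p["k_il10_treg"] <- 1e-8; p["k_deg_il10"] <- 1
  p["k_il12_m1"]   <- 5e-9;  p["k_deg_il12"] <- 1
  p["k_tgfb_m2"]   <- 2e-8;  p["k_deg_tgfb"] <- 2
  p["k_ccl2_cancer"] <- 1e-8; p["k_deg_ccl2"] <- 0.5
  p["k_ifng_tcyt"] <- 1e-9;  p["k_deg_ifng"] <- 2
  p["k_argi_mdsc"] <- 1e-7;  p["k_deg_argi"] <- 1
  p["k_no_mdsc"]   <- 1e-7;  p["k_deg_no"]   <- 1

  ## -- PD-L1 expression dynamics
  p["pdl1_base"]   <- 5e4            # molecules/cell
  p["k_pdl1_relax"] <- 0.2
  p["a_pdl1_ifng"] <- 4
  p["ec50_pdl1_ifng"] <- 0.2

  p["n_clonotypes"] <- 20            # TCR clonotypes per specificity

  ## -- pembrolizumab pharmacokinetics (linear mammillary system)
  p["v_central"]    <- 5             # L
  p["v_peripheral"] <- 4
  p["v_tumor"]      <- 0.05
  p["v_ln"]         <- 0.02
  p["k_cl_drug"]    <- 0.05          # 1/day from central (CL ~ 0.25 L/day;
                                     # effective t1/2 ~ 25 d after distribution)
  p["q_cp_drug"]    <- 0.5           # L/day
  p["q_ct_drug"]    <- 0.01
  p["q_t2ln_drug"]  <- 0.002
  p["q_ln2c_drug"]  <- 0.02
  p["mw_drug"]      <- 1.49e5        # g/mol

  p
}

#' Merge parameter overrides onto the defaults
#'
#' @param overrides Named numeric vector or list of parameter values.
#' @param base Parameter vector to start from (defaults to
#'   [default_parameters()]).
#' @return Full named parameter vector.
#' @export
build_parameters <- function(overrides = NULL, base = default_parameters()) {
  p <- base
  if (!is.null(overrides) && length(overrides)) {
    overrides <- unlist(overrides)
    unknown <- setdiff(names(overrides), names(p))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    p[names(overrides)] <- overrides
  }
  validate_parameters(p)
  p
}

#' @keywords internal
validate_parameters <- function(p) {
  stopifnot(identical(names(p), qsp_param_names()))
  if (any(!is.finite(p))) stop("non-finite parameter value")
  if (any(p < 0)) stop("negative parameter value: ",
                       paste(names(p)[p < 0], collapse = ", "))
  hills <- p[c("n_tcr", "n_pd1")]
  if (any(hills < 1)) stop("Hill coefficients must be >= 1")
  invisible(p)
}
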