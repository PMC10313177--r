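## Pembrolizumab pharmacokinetics and dosing.

#' Dosing regimen
#'
#' @param dose_mg Dose per administration, mg.
#' @param interval_days Interval between doses, days.
#' @param n_doses Number of doses; by default enough to cover
#'   \code{duration_days}.
#' @param start_day First dose day (relative to treatment start).
#' @param duration_days Used to derive \code{n_doses} when not given.
#' @return Object of class \code{qsp_regimen}.
#' @export
regimen <- function(dose_mg = 200, interval_days = 21, n_doses = NULL,
                    start_day = 0, duration_days = 730) {
  stopifnot(dose_mg >= 0, interval_days > 0)
  if (is.null(n_doses))
    n_doses <- max(1L, ceiling((duration_days - start_day) / interval_days))
  structure(list(dose_mg = dose_mg, interval_days = interval_days,
                 n_doses = as.integer(n_doses), start_day = start_day),
            class = "qsp_regimen")
}

#' Dose times of a regimen
#' @param reg A [regimen()].
#' @param duration_days Truncate to doses given strictly before this day.
#' @return Numeric vector of dose days.
#' @export
dose_times <- function(reg, duration_days = Inf) {
  tt <- reg$start_day + reg$interval_days * (seq_len(reg$n_doses) - 1)
  tt[tt < duration_days]
}

#' Intravenous bolus administration into the central compartment
#'
#' Increments the central drug concentration by
#' \code{dose_mg / (MW * V_central)} (converted to nM); all other species
#' are unchanged. Doses are instantaneous, a negligible simplification at
#' 3-week spacing.
#'
#' @param state Named model state vector.
#' @param dose_mg Dose in mg (>= 0).
#' @param params Full parameter vector (molecular weight, central volume).
#' @return Updated state vector.
#' @export
administer_dose <- function(state, dose_mg, params) {
  if (dose_mg < 0) stop("negative dose")
  state["central.drug"] <- state["central.drug"] +
    dose_delta_nM(dose_mg, params)
  state
}

dose_delta_nM <- function(dose_mg, params) {
  # mg -> g -> mol -> mol/L -> nM
  dose_mg / 1000 / params[["mw_drug"]] / params[["v_central"]] * 1e9
}

#' Drug-subsystem derivatives (linear mammillary PK)
#'
#' Evaluates the pharmacokinetic right-hand side alone: clearance from the
#' central compartment, central/peripheral and central/tumour exchange, and
#' unidirectional tumour-to-draining-lymph-node lymph flow with return to
#' the central compartment. Total drug mass is conserved up to the
#' clearance integral.
#'
#' @param drug_state Named vector of drug concentrations (nM) for
#'   \code{central, peripheral}, the four tumours and the three lymph nodes
#'   (names as in [qsp_state_names()], e.g. \code{"tumor_lung1.drug"}).
#' @param params Full parameter vector.
#' @return Named vector of concentration derivatives, nM/day.
#' @export
pk_rhs <- function(drug_state, params) {
  y <- initial_state(params)
  y[] <- 0
  y[names(drug_state)] <- drug_state
  d <- model_rhs(0, y, params)
  d[grep("\\.drug$", names(d))]
}

#' Drug-compartment volumes (L)
#' @param params Full parameter vector.
#' @return Named vector of volumes matching the \code{*.drug} species.
#' @export
pk_volumes <- function(params) {
  c(central.drug = params[["v_central"]],
    peripheral.drug = params[["v_peripheral"]],
    stats::setNames(rep(params[["v_tumor"]], 4),
                    paste0(tumor_compartments(), ".drug")),
    stats::setNames(rep(params[["v_ln"]], 3),
                    paste0(c("ln_primary", "ln_lung", "ln_other"), ".drug")))
}

#' Dosing event table for the integrator
#' @param reg A [regimen()].
#' @param params Full parameter vector.
#' @param t_offset Day offset added to dose times.
#' @param duration_days Truncation horizon.
#' @return data.frame of additive events on the central drug concentration.
#' @export
dose_events <- function(reg, params, t_offset = 0, duration_days = Inf) {
  tt <- dose_times(reg, duration_days)
  if (!length(tt) || reg$dose_mg == 0)
    return(data.frame(var = character(), time = numeric(),
                      value = numeric(), method = character()))
  data.frame(var = "central.drug", time = tt + t_offset,
             value = dose_delta_nM(reg$dose_mg, params), method = "add",
             stringsAsFactors = FALSE)
}
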