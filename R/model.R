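## State-vector construction and ODE integration.

#' Compartment table of the model
#'
#' @return data.frame with compartment \code{name}, \code{kind} (blood,
#'   tissue, tumor, lymph_node) and, for tumours, the draining lymph node.
#' @export
qsp_compartments <- function() {
  data.frame(
    name = c("central", "peripheral",
             "tumor_primary", "tumor_lung1", "tumor_lung2", "tumor_other",
             "ln_primary", "ln_lung", "ln_other"),
    kind = c("blood", "tissue", rep("tumor", 4), rep("lymph_node", 3)),
    draining_ln = c(NA, NA, "ln_primary", "ln_lung", "ln_lung", "ln_other",
                    NA, NA, NA),
    stringsAsFactors = FALSE
  )
}

tumor_compartments <- function() {
  c("tumor_primary", "tumor_lung1", "tumor_lung2", "tumor_other")
}
met_compartments <- function() {
  c("tumor_lung1", "tumor_lung2", "tumor_other")
}
ln_of_tumor <- function(tumor) {
  c(tumor_primary = "ln_primary", tumor_lung1 = "ln_lung",
    tumor_lung2 = "ln_lung", tumor_other = "ln_other")[tumor]
}

state_index <- function(pattern) {
  grep(pattern, qsp_state_names())
}

#' Initial model state
#'
#' Builds the pre-seeding state: naive T-cell pools at their closed-form
#' trafficking steady state, immature APCs at their baseline density,
#' carrying capacities at the configured minimum, everything else zero.
#' Cancer cells are introduced later by seeding events.
#'
#' @param params Full parameter vector ([default_parameters()]).
#' @return Named numeric state vector.
#' @export
initial_state <- function(params = default_parameters()) {
  p <- params
  y <- stats::setNames(numeric(length(qsp_state_names())), qsp_state_names())

  ## closed-form steady state of the linear naive-T trafficking system
  naive_ss <- function(thy) {
    kd <- p[["k_death_naive"]]
    qcl <- p[["q_c2ln"]]; qlc <- p[["q_ln2c"]]
    qcp <- p[["q_c2p"]]; qpc <- p[["q_p2c"]]
    denom <- kd + 3 * qcl + qcp -
      qcp * qpc / (qpc + kd) - 3 * qcl * qlc / (qlc + kd)
    cen <- thy / denom
    list(central = cen,
         peripheral = qcp * cen / (qpc + kd),
         ln = qcl * cen / (qlc + kd))
  }
  s4 <- naive_ss(p[["k_thymic_cd4"]])
  s8 <- naive_ss(p[["k_thymic_cd8"]])
  y["central.naive_cd4"] <- s4$central
  y["central.naive_cd8"] <- s8$central
  y["peripheral.naive_cd4"] <- s4$peripheral
  y["peripheral.naive_cd8"] <- s8$peripheral
  for (l in c("ln_primary", "ln_lung", "ln_other")) {
    y[paste0(l, ".naive_cd4")] <- s4$ln
    y[paste0(l, ".naive_cd8")] <- s8$ln
  }
  for (i in seq_along(tumor_compartments())) {
    tc <- tumor_compartments()[i]
    y[paste0(tc, ".K")] <- p[["k_min_capacity"]]
    y[paste0(tc, ".apc_immature")] <- p[[paste0("apc0_", i)]]
    y[paste0(tc, ".pdl1")] <- p[["pdl1_base"]]
  }
  y
}

#' ODE right-hand side of the full model
#'
#' Assembles the time derivative of the complete state vector from all
#' kinetic laws (Gompertzian clonal growth, capacity dynamics, antigen
#' release and presentation, T-cell activation/trafficking/killing/
#' exhaustion, myeloid dynamics, cytokines, checkpoint binding, drug PK).
#' Thin wrapper around the compiled core used by the integrator.
#'
#' @param t Time, day.
#' @param state Named state vector (see [qsp_state_names()]).
#' @param params Full parameter vector.
#' @return Named derivative vector, cells/day or nM/day per species.
#' @export
model_rhs <- function(t, state, params) {
  qsp_rhs_cpp(t, as.numeric(state), as.numeric(params))
}

## default solver settings: stiff solver, 1-day output grid
solver_atol <- function() {
  nm <- qsp_state_names()
  atol <- rep(1e-3, length(nm))  # cells
  soluble <- grepl("\\.(il10|il12|ifng|tgfb|ccl2|angio|argi|no|il2|drug|ag\\.)",
                   nm) | grepl("\\.ag\\.", nm)
  atol[soluble] <- 1e-9          # nM
  atol
}

#' Integrate the model over a time span
#'
#' Uses a stiff implicit solver (\code{deSolve::lsoda}) on the compiled
#' right-hand side with a fixed 1-day output grid. Negative excursions
#' beyond \code{10 * atol} are clipped to zero with a warning.
#'
#' @param state Initial named state vector.
#' @param params Full parameter vector.
#' @param t0,t1 Integration span, days (output at whole days).
#' @param events Optional \code{data.frame(var, time, value, method)} passed
#'   to deSolve (dosing, metastatic seeding).
#' @param rtol,hmax Solver controls.
#' @return Matrix of states, rows = days \code{t0:t1}, columns = species;
#'   attribute \code{"times"} holds the day grid.
#' @export
simulate_path <- function(state, params, t0, t1, events = NULL,
                          rtol = 1e-6, hmax = NULL) {
  times <- seq(floor(t0), ceiling(t1))
  ev <- NULL
  if (!is.null(events) && nrow(events)) {
    events$var <- as.character(events$var)
    events <- events[order(events$time), ]
    stopifnot(all(events$time %in% times))
    ev <- list(data = events)
  }
  out <- deSolve::ode(
    y = stats::setNames(as.numeric(state), qsp_state_names()),
    times = times, parms = as.numeric(params),
    func = "derivs_tnbc", initfunc = "initmod_tnbc", dllname = "tnbcqsp",
    nout = 0, method = "lsoda", rtol = rtol, atol = solver_atol(),
    hmax = if (is.null(hmax)) 1 else hmax, maxsteps = 20000,
    events = ev
  )
  if (attr(out, "istate")[1] < 0)
    stop("ODE solver failed (istate = ", attr(out, "istate")[1], ")")
  y <- out[, -1, drop = FALSE]
  colnames(y) <- qsp_state_names()
  atol <- solver_atol()
  neg <- sweep(y, 2, -10 * atol, `<`)
  if (any(neg)) {
    bad <- unique(colnames(y)[which(neg, arr.ind = TRUE)[, 2]])
    warning("negative excursions clipped for: ",
            paste(utils::head(bad, 5), collapse = ", "))
  }
  y[y < 0] <- 0
  attr(y, "times") <- times
  y
}

#' Per-lesion diameters from a state snapshot or trajectory
#'
#' @param y Named state vector, or state matrix from [simulate_path()].
#' @param params Parameter vector (for the cell volume).
#' @param compartments Tumour compartments to report.
#' @return Named vector (snapshot) or matrix (trajectory) of diameters, cm.
#' @export
lesion_diameters <- function(y, params,
                             compartments = tumor_compartments()) {
  v <- params[["v_cell"]]
  one <- function(st) {
    vapply(compartments, function(tc) {
      tumor_diameter(sum(st[paste0(tc, ".cancer.", 1:5)]), v)
    }, numeric(1))
  }
  if (is.matrix(y)) t(apply(y, 1, one)) else one(y)
}

#' Total cancer cells of a lesion
#' @param y Named state vector or state matrix.
#' @param compartment Tumour compartment name.
#' @return Cell count (vector over rows for a matrix).
#' @export
cancer_total <- function(y, compartment) {
  idx <- paste0(compartment, ".cancer.", 1:5)
  if (is.matrix(y)) rowSums(y[, idx, drop = FALSE]) else sum(y[idx])
}
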