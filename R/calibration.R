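## Calibration utilities: immune-cell abundance of metastases against
## transcriptome-derived relative-abundance targets, and trial-level
## handles (lung-metastasis prevalence, baseline diameter median).

## cell types tallied for abundance comparisons; MDSCs are proxied by
## monocyte estimates in deconvolution-derived targets
abundance_cell_types <- function() {
  c("tcyt", "th", "treg", "m1", "m2", "mdsc", "apc")
}

tally_tumor_cells <- function(state, compartment) {
  y <- state
  g <- function(sp) unname(y[paste0(compartment, ".", sp)])
  c(cancer = sum(y[paste0(compartment, ".cancer.", 1:5)]),
    tcyt = sum(y[paste0(compartment, ".tcyt.", 1:8)]) +
      g("tcyt_exhausted"),
    th = g("th"), treg = g("treg"), m1 = g("m1"), m2 = g("m2"),
    mdsc = g("mdsc"), apc = g("apc_immature") + g("apc_mature"))
}

#' Cell fractions of a tumour compartment
#'
#' Count of each cell type divided by the total number of cells in the
#' tumour, cancer and immune cells included.
#'
#' @param state Named state vector.
#' @param compartment Tumour compartment name.
#' @return Named fraction vector over [abundance_cell_types()].
#' @export
cell_fractions <- function(state, compartment) {
  n <- tally_tumor_cells(state, compartment)
  tot <- sum(n)
  if (tot <= 0) return(stats::setNames(rep(NA_real_,
    length(abundance_cell_types())), abundance_cell_types()))
  (n / tot)[abundance_cell_types()]
}

#' Relative immune-cell abundance of a metastasis versus the primary
#'
#' Ratio of per-type cell fractions, metastasis over matched primary,
#' evaluated on two state snapshots taken at comparable burden (the
#' reference simulation compares lesions at a matched 1 cm diameter).
#'
#' @param met_state,primary_state Named state vectors.
#' @param met_compartment,primary_compartment Compartment names.
#' @return Named ratio vector; NA where the primary fraction is zero.
#' @export
simulated_relative_abundance <- function(met_state, primary_state,
                                         met_compartment = "tumor_lung1",
                                         primary_compartment =
                                           "tumor_primary") {
  fm <- cell_fractions(met_state, met_compartment)
  fp <- cell_fractions(primary_state, primary_compartment)
  out <- fm / fp
  out[!is.finite(out)] <- NA_real_
  out[fp == 0] <- NA_real_
  out
}

#' Mean squared log-ratio loss against abundance targets
#'
#' Ratios are multiplicative, so the loss is squared error in log space,
#' averaged over the matched (cell type, site) entries; 0 iff every
#' matched simulated ratio equals its target.
#'
#' @param sim Named ratio vector(s): either a single named vector or a
#'   list keyed by site (\code{lung}, \code{other}).
#' @param targets data.frame with columns \code{cell_type}, \code{site},
#'   \code{ratio} (see [read_abundance_targets()]).
#' @return Scalar loss >= 0.
#' @export
abundance_loss <- function(sim, targets) {
  if (!is.list(sim) || is.null(names(sim)) || is.numeric(sim))
    sim <- list(lung = sim, other = sim)
  errs <- c()
  for (i in seq_len(nrow(targets))) {
    site <- targets$site[i]; ct <- targets$cell_type[i]
    sv <- sim[[site]][ct]
    if (is.null(sv) || is.na(sv) || sv <= 0) next
    errs <- c(errs, (log(sv) - log(targets$ratio[i]))^2)
  }
  if (!length(errs)) stop("no overlap between simulated and target entries")
  mean(errs)
}

#' Reference-patient simulation for abundance calibration
#'
#' Simulates a single reference patient with an intact primary tumour and
#' one lung plus one other metastasis, all seeded together, and captures
#' each lesion's compartment state at the first day its diameter reaches
#' the reference size (matched-burden comparison, default 1 cm).
#'
#' @param params Full parameter vector.
#' @param ref_diameter_cm Matched lesion diameter.
#' @param max_days Simulation horizon.
#' @return List of per-lesion state snapshots (\code{tumor_primary},
#'   \code{tumor_lung1}, \code{tumor_other}) or an error if a lesion never
#'   reaches the reference size.
#' @export
reference_abundance_states <- function(params, ref_diameter_cm = 1,
                                       max_days = 800) {
  lesions <- c("tumor_primary", "tumor_lung1", "tumor_other")
  y <- initial_state(params)
  ev <- do.call(rbind, lapply(lesions, function(tc) data.frame(
    var = paste0(tc, ".cancer.", 1:5), time = 0, value = 100 / 5,
    method = "add", stringsAsFactors = FALSE)))
  snaps <- list()
  t0 <- 0
  repeat {
    t1 <- min(t0 + 100, max_days)
    path <- simulate_path(y, params, t0, t1,
                          events = if (t0 == 0) ev else NULL)
    dd <- lesion_diameters(path, params, lesions)
    for (tc in lesions) {
      if (!is.null(snaps[[tc]])) next
      hit <- which(dd[, tc] >= ref_diameter_cm)
      if (length(hit)) snaps[[tc]] <- path[hit[1], ]
    }
    if (length(snaps) == length(lesions) || t1 >= max_days) break
    y <- path[nrow(path), ]
    t0 <- t1
  }
  if (length(snaps) < length(lesions))
    stop("reference lesion(s) never reached ", ref_diameter_cm, " cm")
  snaps
}

## free parameters for metastasis calibration: per-site multipliers on
## recruitment, polarization and baseline APC density (slots 2:3 = lung,
## slot 4 = other; slot 1 = primary stays fixed)
apply_met_scales <- function(params, scales) {
  fam <- c(rec_m1 = "k_rec_m1", rec_mdsc = "k_rec_mdsc",
           pol_m1m2 = "k_pol_m1m2", apc0 = "apc0")
  for (nm in names(scales)) {
    parts <- strsplit(nm, "\\.")[[1]]  # e.g. "lung.rec_m1"
    site <- parts[1]; f <- fam[parts[2]]
    slots <- if (site == "lung") paste0(f, "_", 2:3) else paste0(f, "_4")
    params[slots] <- params[slots] * scales[[nm]]
  }
  params
}

#' Fit metastatic immune-compartment parameters to abundance targets
#'
#' Bounded derivative-free (Nelder-Mead on log-scaled multipliers)
#' minimization of [abundance_loss()] on a single reference patient. Free
#' parameters are per-site multipliers on the macrophage/MDSC recruitment
#' rates, the M1-to-M2 polarization rate and the baseline APC density of
#' the metastatic compartments.
#'
#' @param targets Abundance-target data.frame.
#' @param params Starting parameter vector.
#' @param free Names of free multipliers, subset of
#'   \code{site.family} with site in \{lung, other\} and family in
#'   \{rec_m1, rec_mdsc, pol_m1m2, apc0\}.
#' @param budget Maximum objective evaluations.
#' @param bounds Multiplier bounds (log-scale box).
#' @param ref_diameter_cm Matched-burden comparison diameter.
#' @return List: \code{scales} (fitted multipliers), \code{params}
#'   (updated vector), \code{loss}, \code{initial_loss}, \code{trace}.
#' @export
fit_metastasis_params <- function(targets, params = default_parameters(),
                                  free = c("lung.rec_m1", "lung.rec_mdsc",
                                           "lung.pol_m1m2", "lung.apc0",
                                           "other.rec_m1", "other.apc0"),
                                  budget = 200, bounds = c(0.1, 10),
                                  ref_diameter_cm = 1) {
  if (!length(free)) {
    return(list(scales = numeric(0), params = params, loss = NA_real_,
                initial_loss = NA_real_, trace = data.frame()))
  }
  lb <- log(bounds[1]); ub <- log(bounds[2])
  trace <- list()
  objective <- function(x) {
    x <- pmin(pmax(x, lb), ub)
    scales <- stats::setNames(exp(x), free)
    p <- apply_met_scales(params, scales)
    loss <- try({
      snaps <- reference_abundance_states(p, ref_diameter_cm)
      sim <- list(
        lung = simulated_relative_abundance(snaps$tumor_lung1,
                                            snaps$tumor_primary,
                                            "tumor_lung1"),
        other = simulated_relative_abundance(snaps$tumor_other,
                                             snaps$tumor_primary,
                                             "tumor_other"))
      abundance_loss(sim, targets)
    }, silent = TRUE)
    if (inherits(loss, "try-error")) loss <- 1e6
    trace[[length(trace) + 1]] <<- c(x, loss = loss)
    loss
  }
  init <- rep(0, length(free))
  f0 <- objective(init)
  fit <- stats::optim(init, objective, method = "Nelder-Mead",
                      control = list(maxit = budget))
  best <- pmin(pmax(fit$par, lb), ub)
  loss <- fit$value
  if (loss > f0) {        # optimizer contract: never worse than start
    warning("budget exhausted without improvement; returning start")
    best <- init; loss <- f0
  }
  scales <- stats::setNames(exp(best), free)
  list(scales = scales, params = apply_met_scales(params, scales),
       loss = loss, initial_loss = f0,
       trace = as.data.frame(do.call(rbind, trace)))
}

#' Calibrate trial-level handles of a population specification
#'
#' One-dimensional searches on repeated scaled cohort generations:
#' the lung seeding-time median is tuned (bisection on the log scale,
#' prevalence is monotone decreasing in the median) to the lung-metastasis
#' prevalence target, and the initial-diameter distribution median is
#' tuned (proportional secant updates) to the target median baseline
#' diameter.
#'
#' @param spec Starting [population_spec()] (its \code{n_patients} sets the
#'   scaled cohort size; generation is deterministic given its seed).
#' @param target_lung_prevalence Target fraction of accepted patients with
#'   lung metastases (default 0.65).
#' @param target_median_diameter_cm Target cohort median baseline diameter
#'   (default 1.65 cm).
#' @param tol_prevalence,tol_diameter_cm Acceptance tolerances (a warning
#'   is emitted if unmet within the budget).
#' @param budget Maximum cohort generations per handle.
#' @param median_bounds Search bounds for the lung seeding median, days.
#' @return List: calibrated \code{spec}, achieved \code{lung_prevalence}
#'   and \code{median_diameter_cm}, and the evaluation \code{trace}.
#' @export
calibrate_trial_handles <- function(spec,
                                    target_lung_prevalence = 0.65,
                                    target_median_diameter_cm = 1.65,
                                    tol_prevalence = 0.05,
                                    tol_diameter_cm = 0.1,
                                    budget = 8,
                                    median_bounds = c(20, 1000)) {
  trace <- list()
  eval_spec <- function(s) {
    ch <- generate_cohort(s)
    out <- list(prev = lung_met_prevalence(ch),
                med = median_baseline_diameter(ch),
                n = length(ch))
    trace[[length(trace) + 1]] <<- c(seed_median_lung = s$seed_median_lung,
                                     diameter_median_cm =
                                       s$diameter_median_cm,
                                     prev = out$prev, med = out$med)
    out
  }

  ## handle 1: lung seeding median -> prevalence (monotone decreasing)
  lo <- log(median_bounds[1]); hi <- log(median_bounds[2])
  s <- spec
  res <- eval_spec(s)
  if (abs(res$prev - target_lung_prevalence) > tol_prevalence) {
    f_lo <- f_hi <- NULL
    for (it in seq_len(budget)) {
      mid <- exp((lo + hi) / 2)
      s$seed_median_lung <- mid
      res <- eval_spec(s)
      if (abs(res$prev - target_lung_prevalence) <= tol_prevalence) break
      if (res$prev > target_lung_prevalence) lo <- log(mid) else
        hi <- log(mid)
    }
    if (abs(res$prev - target_lung_prevalence) > tol_prevalence)
      warning("lung prevalence target not met within tolerance (",
              round(res$prev, 3), " vs ", target_lung_prevalence, ")")
  }

  ## handle 2: diameter-distribution median -> cohort median (near
  ## pass-through; proportional secant)
  for (it in seq_len(4)) {
    if (abs(res$med - target_median_diameter_cm) <= tol_diameter_cm) break
    s$diameter_median_cm <- s$diameter_median_cm *
      target_median_diameter_cm / res$med
    res <- eval_spec(s)
  }
  if (abs(res$med - target_median_diameter_cm) > tol_diameter_cm)
    warning("median diameter target not met within tolerance (",
            round(res$med, 3), " vs ", target_median_diameter_cm, ")")

  list(spec = s, lung_prevalence = res$prev,
       median_diameter_cm = res$med,
       trace = as.data.frame(do.call(rbind, trace)))
}
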