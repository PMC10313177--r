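## Virtual-patient generation: Latin hypercube sampling, stochastic
## metastatic seeding, pre-treatment burn-in and acceptance filtering.

#' Default list of varied parameters
#'
#' Roughly twenty high-impact parameters are varied across virtual patients
#' as log-normal distributions centred on the defaults: clone growth rates,
#' killing rate, PD-L1 baseline, exhaustion rate, infiltration rate,
#' activation rate, T-cell clonotype number, Th-to-Treg trans-differentiation,
#' peptide-MHC dissociation constants, and (with per-tumour scope, drawn
#' independently for every tumour) myeloid recruitment rates and baseline
#' APC density. Metastatic seeding times and the per-patient target
#' diameter are sampled alongside as patient attributes.
#'
#' @param params Reference parameter vector supplying the medians.
#' @return data.frame with columns \code{name, dist, p1, p2, scope}
#'   (\code{dist}: lognormal with \code{p1} = meanlog, \code{p2} = sdlog;
#'   uniform with min/max; normal with mean/sd).
#' @export
default_varied_params <- function(params = default_parameters()) {
  ln <- function(name, sdlog, scope = "per_patient") {
    med <- if (scope == "per_tumor") params[[paste0(name, "_1")]]
           else params[[name]]
    data.frame(name = name, dist = "lognormal", p1 = log(med), p2 = sdlog,
               scope = scope, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(
    lapply(paste0("k_growth_", 1:5), ln, sdlog = 0.25),
    list(
      ln("k_kill", 0.4), ln("pdl1_base", 0.5), ln("k_exh_pd1", 0.4),
      ln("q_infil", 0.5), ln("k_act_cd8", 0.3), ln("n_clonotypes", 0.3),
      ln("k_trans_th_treg", 0.3)
    ),
    lapply(paste0("kd_pmhc_", 1:8), ln, sdlog = 0.4),
    list(
      ln("k_rec_m1", 0.4, scope = "per_tumor"),
      ln("k_rec_mdsc", 0.4, scope = "per_tumor"),
      ln("apc0", 0.5, scope = "per_tumor")
    )
  ))
}

#' Virtual-population specification
#'
#' @param n_patients Number of virtual patients to sample.
#' @param varied_params data.frame as [default_varied_params()].
#' @param fixed_params Named overrides applied to [default_parameters()].
#' @param seed Integer RNG seed; the whole cohort is deterministic given it.
#' @param diameter_median_cm,diameter_sdlog Log-normal distribution of the
#'   per-patient target (initial) lesion diameter; the median is the
#'   calibration handle for the baseline-diameter target.
#' @param seed_median_lung,seed_sdlog_lung Log-normal metastatic seeding-time
#'   distribution for the two lung compartments, days; the median is the
#'   calibration handle for lung-metastasis prevalence.
#' @param seed_median_other,seed_sdlog_other Same for the other-metastasis
#'   compartment.
#' @param n_seed_cells Cancer cells introduced at each seeding event.
#' @param max_burnin_days Burn-in horizon; patients whose lesions never
#'   reach their target diameter by then are rejected.
#' @param primary_tumor_intact If TRUE the primary tumour is seeded at day 0
#'   and counts as a lesion; default FALSE (primary resected).
#' @return Object of class \code{population_spec}.
#' @export
population_spec <- function(n_patients = 200,
                            varied_params = default_varied_params(),
                            fixed_params = NULL,
                            seed = 1L,
                            diameter_median_cm = 1.65,
                            diameter_sdlog = 0.25,
                            seed_median_lung = 150,
                            seed_sdlog_lung = 0.8,
                            seed_median_other = 100,
                            seed_sdlog_other = 0.8,
                            n_seed_cells = 100,
                            max_burnin_days = 1500,
                            primary_tumor_intact = FALSE) {
  stopifnot(n_patients >= 0, diameter_median_cm >= 0,
            seed_median_lung > 0, seed_median_other > 0)
  base <- build_parameters(fixed_params)
  known <- qsp_param_names()
  for (i in seq_len(nrow(varied_params))) {
    nm <- varied_params$name[i]
    ok <- if (varied_params$scope[i] == "per_tumor")
      all(paste0(nm, "_", 1:4) %in% known) else nm %in% known
    if (!ok) stop("varied parameter does not resolve to a model parameter: ",
                  nm)
    if (!varied_params$dist[i] %in% c("lognormal", "uniform", "normal"))
      stop("invalid distribution: ", varied_params$dist[i])
  }
  structure(list(
    n_patients = as.integer(n_patients), varied_params = varied_params,
    base_params = base, seed = as.integer(seed),
    diameter_median_cm = diameter_median_cm, diameter_sdlog = diameter_sdlog,
    seed_median_lung = seed_median_lung, seed_sdlog_lung = seed_sdlog_lung,
    seed_median_other = seed_median_other,
    seed_sdlog_other = seed_sdlog_other,
    n_seed_cells = n_seed_cells, max_burnin_days = max_burnin_days,
    primary_tumor_intact = isTRUE(primary_tumor_intact)
  ), class = "population_spec")
}

q_of_dist <- function(u, dist, p1, p2) {
  switch(dist,
         lognormal = stats::qlnorm(u, meanlog = p1, sdlog = p2),
         uniform = stats::qunif(u, min = p1, max = p2),
         normal = stats::qnorm(u, mean = p1, sd = p2),
         stop("invalid distribution: ", dist))
}

#' Latin hypercube sampling of virtual-patient parameters
#'
#' Stratified LHS: one stratum per patient per varied dimension with random
#' permutation across dimensions. Per-tumour-scope parameters occupy one
#' independent dimension per tumour compartment. Seeding times (log-normal
#' per metastatic compartment) and the per-patient target diameter are
#' sampled in the same hypercube. Deterministic given the spec seed.
#'
#' @param spec A [population_spec()].
#' @return List of patients: each a list with the full \code{params} vector,
#'   \code{seed_times} (days, named by metastatic compartment),
#'   \code{target_diameter_cm}, and the per-tumour initial clone composition
#'   (symmetric Dirichlet).
#' @export
sample_parameters <- function(spec) {
  stopifnot(inherits(spec, "population_spec"), spec$n_patients >= 1)
  vp <- spec$varied_params
  dims <- list()
  for (i in seq_len(nrow(vp))) {
    if (vp$scope[i] == "per_tumor") {
      for (t in 1:4)
        dims[[paste0(vp$name[i], "_", t)]] <- vp[i, ]
    } else dims[[vp$name[i]]] <- vp[i, ]
  }
  special <- c("seed_time_lung1", "seed_time_lung2", "seed_time_other",
               "target_diameter_cm")
  d <- length(dims) + length(special)
  n <- spec$n_patients

  set.seed(spec$seed)
  cube <- lhs::randomLHS(n, d)
  colnames(cube) <- c(names(dims), special)

  patients <- vector("list", n)
  for (j in seq_len(n)) {
    p <- spec$base_params
    for (nm in names(dims)) {
      dd <- dims[[nm]]
      p[[nm]] <- q_of_dist(cube[j, nm], dd$dist, dd$p1, dd$p2)
    }
    p[["n_clonotypes"]] <- max(1, round(p[["n_clonotypes"]]))
    seed_times <- c(
      tumor_lung1 = stats::qlnorm(unname(cube[j, "seed_time_lung1"]),
                                  log(spec$seed_median_lung),
                                  spec$seed_sdlog_lung),
      tumor_lung2 = stats::qlnorm(unname(cube[j, "seed_time_lung2"]),
                                  log(spec$seed_median_lung),
                                  spec$seed_sdlog_lung),
      tumor_other = stats::qlnorm(unname(cube[j, "seed_time_other"]),
                                  log(spec$seed_median_other),
                                  spec$seed_sdlog_other))
    target_d <- stats::qlnorm(unname(cube[j, "target_diameter_cm"]),
                              log(spec$diameter_median_cm),
                              spec$diameter_sdlog)
    ## per-tumour initial clone composition: symmetric Dirichlet(1)
    g <- matrix(stats::rgamma(4 * 5, shape = 1), 4, 5)
    comp <- g / rowSums(g)
    rownames(comp) <- tumor_compartments()
    patients[[j]] <- list(
      id = sprintf("vp%04d", j), params = p, seed_times = seed_times,
      target_diameter_cm = target_d, clone_comp = comp,
      primary_tumor_intact = spec$primary_tumor_intact,
      n_seed_cells = spec$n_seed_cells
    )
  }
  patients
}

#' Metastatic seeding schedule for one patient
#'
#' Converts sampled seeding times into integrator events introducing
#' \code{n_seed_cells} cancer cells (split by the tumour's clone
#' composition) into each metastatic compartment. Times are shifted so the
#' earliest seeding (day 0 for an intact primary) starts the simulation,
#' and rounded to the 1-day grid. Compartments whose time exceeds the
#' burn-in horizon are never seeded; no seeding occurs after treatment
#' starts.
#'
#' @param patient A patient from [sample_parameters()].
#' @param max_burnin_days Burn-in horizon, days.
#' @return List with \code{times} (named, days, NA when never seeded) and
#'   the event data.frame \code{events}.
#' @export
seed_metastases <- function(patient, max_burnin_days = 1500) {
  tt <- patient$seed_times
  if (patient$primary_tumor_intact) {
    tt <- c(tumor_primary = 0, tt)
  } else {
    tt <- tt - min(tt)  # earliest metastatic seeding starts the clock
  }
  tt <- round(tt)
  tt[tt > max_burnin_days] <- NA
  ev <- NULL
  for (tc in names(tt)) {
    if (is.na(tt[tc])) next
    comp <- patient$clone_comp[tc, ]
    ev <- rbind(ev, data.frame(
      var = paste0(tc, ".cancer.", 1:5), time = tt[[tc]],
      value = patient$n_seed_cells * comp, method = "add",
      stringsAsFactors = FALSE))
  }
  list(times = tt, events = ev)
}

#' Pre-treatment burn-in of one virtual patient
#'
#' Integrates the untreated model from the earliest seeding until any
#' lesion reaches the patient's target diameter (accepted; the state at
#' that day becomes the treatment baseline) or until the burn-in horizon
#' (rejected). Solver failures are flagged separately from filter
#' rejections.
#'
#' @param patient A patient from [sample_parameters()].
#' @param max_burnin_days Horizon, days.
#' @param chunk_days Integration chunk length between diameter checks.
#' @return The patient augmented with \code{accepted}, \code{failed},
#'   \code{baseline_state}, \code{baseline_day} and \code{seeded} times.
#' @export
burn_in <- function(patient, max_burnin_days = 1500, chunk_days = 100) {
  sched <- seed_metastases(patient, max_burnin_days)
  patient$seeded <- sched$times
  lesions <- names(sched$times)[!is.na(sched$times)]
  patient$accepted <- FALSE
  patient$failed <- FALSE
  if (!length(lesions)) return(patient)

  y <- initial_state(patient$params)
  t0 <- 0
  res <- try({
    repeat {
      t1 <- min(t0 + chunk_days, max_burnin_days)
      ev <- sched$events[sched$events$time >= t0 & sched$events$time <= t1, ]
      path <- simulate_path(y, patient$params, t0, t1, events = ev)
      dd <- lesion_diameters(path, patient$params, lesions)
      hit <- which(apply(dd, 1, max) >= patient$target_diameter_cm)
      if (length(hit)) {
        day <- attr(path, "times")[hit[1]]
        patient$accepted <- TRUE
        patient$baseline_day <- day
        patient$baseline_state <- path[hit[1], ]
        break
      }
      y <- path[nrow(path), ]
      t0 <- t1
      if (t0 >= max_burnin_days) break
    }
    TRUE
  }, silent = TRUE)
  if (inherits(res, "try-error")) {
    patient$failed <- TRUE
    patient$accepted <- FALSE
  }
  patient
}

#' Generate an accepted virtual cohort
#'
#' Samples \code{n_patients} parameter sets, runs the seeding and burn-in
#' for each, and returns the accepted patients only. The attributes
#' \code{n_sampled}, \code{n_accepted}, \code{n_failed} and \code{seed}
#' form the audit record.
#'
#' @param spec A [population_spec()].
#' @param quiet Suppress the progress message.
#' @return List of accepted patients (class \code{qsp_cohort}).
#' @export
generate_cohort <- function(spec, quiet = TRUE) {
  if (spec$n_patients < 1) stop("empty cohort requested (n_patients = 0)")
  patients <- sample_parameters(spec)
  out <- lapply(patients, burn_in,
                max_burnin_days = spec$max_burnin_days)
  failed <- vapply(out, function(p) p$failed, logical(1))
  accepted <- vapply(out, function(p) isTRUE(p$accepted), logical(1))
  if (!quiet)
    message(sum(accepted), "/", length(out), " accepted (",
            sum(failed), " solver failures)")
  if (!any(accepted))
    stop("no virtual patient reached the target diameter; ",
         "rescale the seeding/diameter distributions")
  cohort <- out[accepted]
  structure(cohort, class = "qsp_cohort",
            n_sampled = length(out), n_accepted = sum(accepted),
            n_failed = sum(failed), seed = spec$seed, spec = spec)
}

#' Lesions present at baseline for one accepted patient
#'
#' A lesion is present when its compartment was seeded on or before the
#' baseline day and holds at least one cancer cell at baseline.
#'
#' @param patient Accepted patient.
#' @return Character vector of tumour compartments.
#' @export
baseline_lesions <- function(patient) {
  stopifnot(isTRUE(patient$accepted))
  cand <- names(patient$seeded)[!is.na(patient$seeded) &
                                  patient$seeded <= patient$baseline_day]
  cand[vapply(cand, function(tc)
    cancer_total(patient$baseline_state, tc) >= 1, logical(1))]
}

#' Fraction of accepted patients with at least one lung lesion at baseline
#' @param cohort A [generate_cohort()] result.
#' @return Fraction in \[0, 1\].
#' @export
lung_met_prevalence <- function(cohort) {
  has <- vapply(cohort, function(p)
    any(c("tumor_lung1", "tumor_lung2") %in% baseline_lesions(p)),
    logical(1))
  mean(has)
}

#' Median per-patient maximum baseline lesion diameter
#' @param cohort A [generate_cohort()] result.
#' @return Median diameter, cm.
#' @export
median_baseline_diameter <- function(cohort) {
  dmax <- vapply(cohort, function(p) {
    les <- baseline_lesions(p)
    if (!length(les)) return(NA_real_)
    max(lesion_diameters(p$baseline_state, p$params, les))
  }, numeric(1))
  stats::median(dmax, na.rm = TRUE)
}

#' Cohort manifest table
#' @param cohort A [generate_cohort()] result.
#' @return data.frame: id, baseline day, seeding times and baseline
#'   diameters per lesion.
#' @export
cohort_manifest <- function(cohort) {
  do.call(rbind, lapply(cohort, function(p) {
    dd <- lesion_diameters(p$baseline_state, p$params)
    data.frame(id = p$id, baseline_day = p$baseline_day,
               seed_lung1 = p$seeded[["tumor_lung1"]],
               seed_lung2 = p$seeded[["tumor_lung2"]],
               seed_other = p$seeded[["tumor_other"]],
               diam_primary = dd[["tumor_primary"]],
               diam_lung1 = dd[["tumor_lung1"]],
               diam_lung2 = dd[["tumor_lung2"]],
               diam_other = dd[["tumor_other"]],
               stringsAsFactors = FALSE)
  }))
}
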