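## Treatment simulation, RECIST v1.1 response classification and
## trial-level summaries.

#' Simulate pembrolizumab treatment for one accepted patient
#'
#' Integrates the model from the patient's baseline state with bolus doses
#' applied at the regimen times (time 0 = treatment start). Records the
#' full state on a 1-day grid and per-lesion diameters on the assessment
#' grid.
#'
#' @param patient Accepted patient from [generate_cohort()].
#' @param reg A [regimen()]; dose 0 reproduces the untreated continuation.
#' @param duration_days Simulated treatment duration.
#' @param assessment_interval Days between response assessments.
#' @return List with \code{trajectories} (data.frame: lesion, compartment,
#'   time_day, diameter_mm at assessment times), \code{states} (daily state
#'   matrix) and \code{lesions}.
#' @export
simulate_treatment <- function(patient, reg = regimen(),
                               duration_days = 730,
                               assessment_interval = 63) {
  stopifnot(isTRUE(patient$accepted),
            duration_days >= assessment_interval)
  lesions <- baseline_lesions(patient)
  ev <- dose_events(reg, patient$params, duration_days = duration_days)
  path <- simulate_path(patient$baseline_state, patient$params,
                        0, duration_days, events = ev)
  assess <- seq(0, duration_days, by = assessment_interval)
  dd <- lesion_diameters(path[match(assess, attr(path, "times")), ,
                              drop = FALSE],
                         patient$params, lesions)
  traj <- do.call(rbind, lapply(seq_along(lesions), function(i) {
    data.frame(lesion = i, compartment = lesions[i], time_day = assess,
               diameter_mm = 10 * dd[, i], stringsAsFactors = FALSE)
  }))
  list(trajectories = traj, states = path, lesions = lesions,
       assessment_days = assess)
}

#' Sum of target-lesion diameters at an assessment time
#'
#' Lesions below the complete-response (disappearance) threshold
#' contribute 0 to the sum.
#'
#' @param trajectories Trajectory data.frame from [simulate_treatment()].
#' @param t Assessment day (must be on the assessment grid).
#' @param cr_threshold_mm Lesion disappearance threshold, mm.
#' @return Sum of diameters, mm.
#' @export
sum_of_diameters <- function(trajectories, t, cr_threshold_mm = 2) {
  d <- trajectories$diameter_mm[trajectories$time_day == t]
  if (!length(d)) stop("t is not on the assessment grid")
  sum(ifelse(d < cr_threshold_mm, 0, d))
}

#' RECIST v1.1 classification of a lesion-diameter series
#'
#' Applies RECIST v1.1 to per-lesion diameters on the assessment grid:
#' complete response (CR) when every lesion is below the disappearance
#' threshold; partial response (PR) when the sum of diameters is at most
#' 70\% of baseline; progressive disease (PD) when the sum is at least
#' 120\% of the nadir (smallest sum so far, including baseline) with an
#' absolute increase of at least 5 mm. Stable disease requires the absence
#' of PD maintained for a minimum duration from treatment start; a patient
#' who neither responds nor maintains SD for that window is classified PD.
#' The best overall response across assessments is reported, with no
#' confirmation scan required.
#'
#' @param trajectories Trajectory data.frame from [simulate_treatment()]
#'   (baseline row at day 0 included).
#' @param assessment_interval Days between assessments (default 63, i.e.
#'   9 weeks).
#' @param sd_min_days Minimum duration for SD (default 168, i.e. 24 weeks).
#' @param cr_threshold_mm Lesion disappearance threshold, mm.
#' @return List of class \code{response_record}: \code{status} (factor
#'   CR/PR/SD/PD), \code{time_to_response} and \code{duration_of_response}
#'   (days, NA unless CR/PR), \code{progressed_by_end}, and the assessment
#'   \code{sums}.
#' @export
classify_recist <- function(trajectories, assessment_interval = 63,
                            sd_min_days = 168, cr_threshold_mm = 2) {
  tt <- sort(unique(trajectories$time_day))
  if (!length(tt)) stop("empty diameter series")
  stopifnot(tt[1] == 0)
  sums <- vapply(tt, function(t)
    sum_of_diameters(trajectories, t, cr_threshold_mm), numeric(1))
  all_gone <- vapply(tt, function(t) {
    d <- trajectories$diameter_mm[trajectories$time_day == t]
    all(d < cr_threshold_mm)
  }, logical(1))

  baseline <- sums[1]
  n <- length(tt)
  cat_at <- character(n)
  cat_at[1] <- "baseline"
  nadir <- baseline
  pd_time <- NA_real_
  for (i in 2:n) {
    s <- sums[i]
    if (all_gone[i]) {
      cat_at[i] <- "CR"
    } else if (s <= 0.7 * baseline) {
      cat_at[i] <- "PR"
    } else if (s >= 1.2 * nadir && (s - nadir) >= 5) {
      cat_at[i] <- "PD"
      if (is.na(pd_time)) pd_time <- tt[i]
    } else {
      cat_at[i] <- "none"
    }
    nadir <- min(nadir, s)
  }

  resp_idx <- which(cat_at %in% c("CR", "PR"))
  first_pd <- which(cat_at == "PD")[1]
  status <- NA_character_
  ttr <- NA_real_
  dor <- NA_real_
  if (length(resp_idx) && (is.na(first_pd) || resp_idx[1] < first_pd)) {
    status <- if (any(cat_at[resp_idx] == "CR")) "CR" else "PR"
    ttr <- tt[resp_idx[1]]
    end <- if (!is.na(first_pd) && first_pd > resp_idx[1])
      tt[first_pd] else tt[n]
    dor <- end - ttr
  } else {
    # no response: SD requires a non-PD assessment at or beyond the
    # minimum SD window (measured from treatment start)
    last_non_pd <- if (is.na(first_pd)) tt[n] else tt[first_pd - 1]
    status <- if (last_non_pd >= sd_min_days) "SD" else "PD"
  }
  structure(list(
    status = factor(status, levels = c("CR", "PR", "SD", "PD")),
    time_to_response = ttr, duration_of_response = dor,
    progressed_by_end = !is.na(first_pd),
    sums = stats::setNames(sums, tt)
  ), class = "response_record")
}

#' Run the virtual clinical trial on a cohort
#'
#' @param cohort Accepted cohort from [generate_cohort()].
#' @param reg A [regimen()].
#' @param duration_days,assessment_interval,sd_min_days See
#'   [simulate_treatment()] and [classify_recist()].
#' @param keep_states Keep full daily state matrices (memory-heavy).
#' @return List of class \code{qsp_trial}: per-patient \code{records},
#'   \code{trajectories}, ids, and the ids of nonevaluable patients
#'   (solver failures, excluded with a log attribute).
#' @export
run_trial <- function(cohort, reg = regimen(), duration_days = 730,
                      assessment_interval = 63, sd_min_days = 168,
                      keep_states = FALSE) {
  records <- list(); trajs <- list(); ids <- character(0)
  nonevaluable <- character(0)
  for (p in cohort) {
    sim <- try(simulate_treatment(p, reg, duration_days,
                                  assessment_interval), silent = TRUE)
    if (inherits(sim, "try-error")) {
      nonevaluable <- c(nonevaluable, p$id)
      next
    }
    rec <- classify_recist(sim$trajectories, assessment_interval,
                           sd_min_days)
    ids <- c(ids, p$id)
    records[[p$id]] <- rec
    sim$states <- if (keep_states) sim$states else NULL
    trajs[[p$id]] <- sim$trajectories
  }
  structure(list(records = records, trajectories = trajs, ids = ids,
                 nonevaluable = nonevaluable,
                 regimen = reg, duration_days = duration_days),
            class = "qsp_trial")
}

#' Responder labels (CR/PR/SD = responder)
#' @param records List of \code{response_record}s (or a \code{qsp_trial}).
#' @return Named logical vector.
#' @export
responder_labels <- function(records) {
  if (inherits(records, "qsp_trial")) records <- records$records
  vapply(records, function(r)
    as.character(r$status) %in% c("CR", "PR", "SD"), logical(1))
}

#' Trial-level endpoint summary with bootstrap confidence intervals
#'
#' Overall response rate (CR/PR over all evaluable patients), median
#' duration of response and time to response (CR/PR patients only), and
#' percentile-bootstrap 95\% confidence intervals.
#'
#' @param records List of \code{response_record}s (or a \code{qsp_trial}).
#' @param n_boot Bootstrap resamples.
#' @param seed RNG seed for the bootstrap (logged in the output).
#' @return List with \code{orr}, \code{median_dor}, \code{median_ttr},
#'   their \code{ci} entries, \code{n}, and the bootstrap seed.
#' @export
trial_summary <- function(records, n_boot = 1000, seed = 1L) {
  if (inherits(records, "qsp_trial")) records <- records$records
  stopifnot(length(records) >= 1)
  status <- vapply(records, function(r) as.character(r$status), character(1))
  is_resp <- status %in% c("CR", "PR")
  ttr <- vapply(records, function(r) r$time_to_response, numeric(1))[is_resp]
  dor <- vapply(records, function(r) r$duration_of_response,
                numeric(1))[is_resp]
  orr <- mean(is_resp)
  set.seed(seed)
  n <- length(records)
  boot <- replicate(n_boot, {
    idx <- sample.int(n, n, replace = TRUE)
    bi <- is_resp[idx]
    c(orr = mean(bi),
      dor = if (any(bi)) stats::median(vapply(records[idx][bi], function(r)
        r$duration_of_response, numeric(1))) else NA_real_,
      ttr = if (any(bi)) stats::median(vapply(records[idx][bi], function(r)
        r$time_to_response, numeric(1))) else NA_real_)
  })
  ci <- function(x) if (all(is.na(x))) c(NA_real_, NA_real_) else
    stats::quantile(x, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  list(
    n = n, orr = orr, orr_ci = ci(boot["orr", ]),
    median_dor = if (length(dor)) stats::median(dor) else NA_real_,
    dor_ci = ci(boot["dor", ]),
    median_ttr = if (length(ttr)) stats::median(ttr) else NA_real_,
    ttr_ci = ci(boot["ttr", ]),
    n_responders = sum(is_resp), boot_seed = seed, n_boot = n_boot
  )
}
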