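## Parameter-influence analyses: subgroup ranking over varied-parameter
## values and cohort-level perturbation of fixed parameters.

#' Table of varied-parameter values across a cohort
#'
#' @param cohort Accepted cohort.
#' @param params Parameter names; defaults to every parameter that varies
#'   across the cohort.
#' @return data.frame with \code{id} and one column per parameter.
#' @export
cohort_parameter_table <- function(cohort, params = NULL) {
  all_p <- do.call(rbind, lapply(cohort, function(p) p$params))
  rownames(all_p) <- vapply(cohort, function(p) p$id, character(1))
  if (is.null(params)) {
    vr <- apply(all_p, 2, function(x) stats::sd(x) > 0)
    params <- colnames(all_p)[vr]
  }
  out <- data.frame(id = rownames(all_p), all_p[, params, drop = FALSE],
                    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Response-probability ranking of varied parameters
#'
#' Reuses the biomarker subgroup machinery with parameter values as the
#' candidates: multiple uniformly spaced cutoffs per parameter over its
#' observed range, above/below subgroups, size filter, and ranking by the
#' maximum response probability attained.
#'
#' @param cohort Accepted cohort.
#' @param responder Named logical responder labels ([responder_labels()]).
#' @param n_cutoffs Cutoffs per parameter (default 15).
#' @param min_size Minimum subgroup size (default 20).
#' @param params Optional subset of parameter names.
#' @return data.frame ranked by decreasing best response probability;
#'   constant parameters are excluded.
#' @export
parameter_subgroup_ranking <- function(cohort, responder, n_cutoffs = 15,
                                       min_size = 20, params = NULL) {
  tab <- cohort_parameter_table(cohort, params)
  tab$responder <- unname(responder[tab$id])
  class(tab) <- c("biomarker_table", "data.frame")
  rank_candidates(tab, metric = "rp", n_thresholds = n_cutoffs,
                  min_size = min_size, n_boot = 0)
}

#' Perturb a fixed model parameter across the whole cohort
#'
#' Scales one (fixed, cohort-constant) parameter by each factor, re-runs
#' the identical treatment simulation for every patient, and reports the
#' overall response rate and the status transition matrix (PD / SD / PR-CR
#' before vs after) relative to the unperturbed run.
#'
#' @param cohort Accepted cohort.
#' @param name Parameter name (scalar or per-tumour family base name).
#' @param factors Scaling factors, each in \[0.5, 1.5\].
#' @param reg A [regimen()].
#' @param duration_days,assessment_interval Trial settings.
#' @return List of per-factor results: \code{factor}, \code{orr},
#'   \code{transition} (3x3 count matrix, rows = baseline category).
#' @export
perturb_fixed_parameter <- function(cohort, name,
                                    factors = c(0.5, 0.75, 1.25, 1.5),
                                    reg = regimen(), duration_days = 730,
                                    assessment_interval = 63) {
  nm <- qsp_param_names()
  slots <- if (name %in% nm) name else {
    fam <- paste0(name, "_", 1:4)
    if (!all(fam %in% nm)) stop("unknown parameter: ", name)
    fam
  }
  stopifnot(all(factors >= 0.5 & factors <= 1.5))
  collapse <- function(status)
    factor(ifelse(status %in% c("CR", "PR"), "PR-CR", status),
           levels = c("PD", "SD", "PR-CR"))
  run_at <- function(f) {
    ch <- lapply(cohort, function(p) {
      p$params[slots] <- p$params[slots] * f
      p
    })
    trial <- run_trial(ch, reg, duration_days, assessment_interval)
    vapply(trial$records, function(r) as.character(r$status), character(1))
  }
  base_status <- run_at(1)
  lapply(factors, function(f) {
    st <- if (f == 1) base_status else run_at(f)
    common <- intersect(names(base_status), names(st))
    trans <- table(baseline = collapse(base_status[common]),
                   perturbed = collapse(st[common]))
    list(parameter = name, factor = f,
         orr = mean(st %in% c("CR", "PR")),
         transition = unclass(trans))
  })
}
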