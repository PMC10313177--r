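## Configuration, fixtures and result serialization.

#' Read a run configuration file
#'
#' YAML configuration with blocks \code{population} (passed to
#' [population_spec()]), \code{fixed_params}, \code{regimen} (passed to
#' [regimen()]) and \code{trial} (duration, assessment interval, SD
#' window). Missing blocks fall back to package defaults.
#'
#' @param path YAML file path.
#' @return List of class \code{run_config} with \code{spec}, \code{regimen}
#'   and \code{trial} settings plus the raw config and its hash.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  pop <- cfg$population %||% list()
  if (!is.null(cfg$fixed_params)) pop$fixed_params <- cfg$fixed_params
  spec <- do.call(population_spec, pop)
  regc <- cfg$regimen %||% list()
  reg <- do.call(regimen, regc)
  trial <- list(duration_days = cfg$trial$duration_days %||% 730,
                assessment_interval = cfg$trial$assessment_interval %||% 63,
                sd_min_days = cfg$trial$sd_min_days %||% 168)
  structure(list(spec = spec, regimen = reg, trial = trial, raw = cfg,
                 hash = config_hash(cfg)),
            class = "run_config")
}

config_hash <- function(cfg) {
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE)
  # small stable checksum (sum of char codes, base 36) for output headers
  v <- utf8ToInt(paste(s, collapse = ""))
  format(as.hexmode(sum(v * seq_along(v)) %% .Machine$integer.max),
         width = 8)
}

write_csv_with_header <- function(df, path, meta) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", names(meta), ": ", unlist(meta)), con)
  utils::write.csv(df, con, row.names = FALSE)
}

#' Export trial tables (waterfall, spider, response)
#'
#' @param trial A [run_trial()] result.
#' @param out_dir Output directory (created if missing).
#' @param meta Named list written as \code{#} header lines (seed, config
#'   hash).
#' @return Invisibly, the list of written file paths.
#' @export
export_trial_tables <- function(trial, out_dir, meta = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  meta <- c(list(package = "tnbcqsp",
                 version = as.character(utils::packageVersion("tnbcqsp"))),
            meta)

  resp <- do.call(rbind, lapply(trial$ids, function(id) {
    r <- trial$records[[id]]
    data.frame(id = id, status = as.character(r$status),
               time_to_response = r$time_to_response,
               duration_of_response = r$duration_of_response,
               progressed_by_end = r$progressed_by_end,
               stringsAsFactors = FALSE)
  }))

  pct_change <- function(id) {
    tr <- trial$trajectories[[id]]
    tt <- sort(unique(tr$time_day))
    s <- vapply(tt, function(t) sum_of_diameters(tr, t), numeric(1))
    data.frame(id = id, time_day = tt,
               pct_change = 100 * (s - s[1]) / s[1],
               stringsAsFactors = FALSE)
  }
  spider <- do.call(rbind, lapply(trial$ids, pct_change))

  waterfall <- do.call(rbind, lapply(trial$ids, function(id) {
    pc <- pct_change(id)
    best <- min(pc$pct_change[-1])
    data.frame(id = id, best_pct_change = best, stringsAsFactors = FALSE)
  }))
  waterfall <- waterfall[order(-waterfall$best_pct_change), ]

  files <- c(response = file.path(out_dir, "response.csv"),
             waterfall = file.path(out_dir, "waterfall.csv"),
             spider = file.path(out_dir, "spider.csv"))
  write_csv_with_header(resp, files["response"], meta)
  write_csv_with_header(waterfall, files["waterfall"], meta)
  write_csv_with_header(spider, files["spider"], meta)
  invisible(files)
}

#' Fast fixture cohort with planted biomarker structure
#'
#' Generates a small cohort with fast dynamics (small target diameters,
#' early seeding, short burn-in) for tests and examples, then assigns
#' responder labels by a noisy threshold rule on one designated baseline
#' candidate. The labels are synthetic by construction (documented as
#' such): they give a known ground truth for the biomarker-recovery
#' checks, independent of treatment simulation noise.
#'
#' @param n Number of sampled patients.
#' @param seed RNG seed.
#' @param planted_candidate Candidate column driving response.
#' @param noise Label flip probability (Bernoulli, applied symmetrically).
#' @return List with the \code{cohort}, the biomarker \code{table}
#'   (responder labels attached) and \code{planted_candidate}.
#' @export
make_fixture_cohort <- function(n = 50, seed = 1L,
                                planted_candidate = "frac_tcyt_t_central",
                                noise = 0.05) {
  if (n < 1) stop("empty fixture cohort requested")
  spec <- population_spec(
    n_patients = n, seed = seed,
    diameter_median_cm = 0.6, diameter_sdlog = 0.2,
    seed_median_lung = 30, seed_sdlog_lung = 0.6,
    seed_median_other = 25, seed_sdlog_other = 0.6,
    max_burnin_days = 400)
  cohort <- generate_cohort(spec)
  tab <- extract_candidates(cohort)
  v <- tab[[planted_candidate]]
  ## plant the rule on the subgroup cutoff closest to the median so the
  ## labelling threshold is exactly recoverable by the subgroup scan
  cuts <- seq(min(v, na.rm = TRUE), max(v, na.rm = TRUE),
              length.out = 10)[2:9]
  thr <- cuts[which.min(abs(cuts - stats::median(v, na.rm = TRUE)))]
  set.seed(seed + 1L)
  lab <- v >= thr
  flip <- stats::runif(length(lab)) < noise
  lab[flip] <- !lab[flip]
  lab[is.na(lab)] <- FALSE
  tab$responder <- lab
  list(cohort = cohort, table = tab, planted_candidate = planted_candidate)
}

#' Load the synthetic metastasis abundance-target table
#'
#' The shipped fixture encodes qualitative directions of immune-cell
#' abundance in metastases relative to matched primary tumours (reduced
#' lymphocyte fractions in metastases) with wide tolerances; MDSC targets
#' are monocyte-proxied. It is a synthetic stand-in: users substitute
#' their own deconvolution-derived table for real calibrations.
#'
#' @param path CSV path; defaults to the packaged fixture.
#' @return data.frame: cell_type, site, estimator, ratio, tolerance.
#' @export
read_abundance_targets <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "synthetic_abundance_targets.csv",
                        package = "tnbcqsp")
  tab <- utils::read.csv(path, comment.char = "#",
                         stringsAsFactors = FALSE)
  stopifnot(all(c("cell_type", "site", "estimator", "ratio") %in%
                  names(tab)),
            all(tab$ratio > 0))
  tab
}
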