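## shared fixtures, built once per test run

.fixture_env <- new.env(parent = emptyenv())

small_cohort <- function(n = 10, seed = 3) {
  key <- paste0("cohort_", n, "_", seed)
  if (is.null(.fixture_env[[key]])) {
    spec <- population_spec(n_patients = n, seed = seed)
    .fixture_env[[key]] <- generate_cohort(spec)
  }
  .fixture_env[[key]]
}

fast_fixture <- function(n = 50, seed = 5) {
  key <- paste0("fx_", n, "_", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- make_fixture_cohort(n = n, seed = seed)
  .fixture_env[[key]]
}

## synthetic biomarker table: responder is a noisy threshold function of x1
synthetic_table <- function(n = 60, seed = 1, noise = 0.1, k = 3) {
  set.seed(seed)
  tab <- data.frame(id = sprintf("p%03d", seq_len(n)))
  for (j in seq_len(k)) tab[[paste0("x", j)]] <- stats::runif(n)
  lab <- tab$x1 >= 0.5
  flip <- stats::runif(n) < noise
  lab[flip] <- !lab[flip]
  tab$responder <- lab
  class(tab) <- c("biomarker_table", "data.frame")
  tab
}

## trajectory builder for RECIST tests: lesion diameters (mm) by assessment
traj_from_sums <- function(diams_mm, interval = 63) {
  stopifnot(is.matrix(diams_mm))
  if (nrow(diams_mm) == 0)
    return(data.frame(lesion = integer(), compartment = character(),
                      time_day = numeric(), diameter_mm = numeric()))
  tt <- (seq_len(nrow(diams_mm)) - 1) * interval
  do.call(rbind, lapply(seq_len(ncol(diams_mm)), function(i)
    data.frame(lesion = i, compartment = paste0("lesion", i),
               time_day = tt, diameter_mm = diams_mm[, i])))
}
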