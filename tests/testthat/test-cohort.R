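test_that("Latin hypercube sampling stratifies each varied dimension", {
  vp <- data.frame(name = "k_kill", dist = "uniform", p1 = 0, p2 = 1,
                   scope = "per_patient", stringsAsFactors = FALSE)
  spec <- population_spec(n_patients = 4, varied_params = vp, seed = 2)
  pats <- sample_parameters(spec)
  v <- sapply(pats, function(p) p$params[["k_kill"]])
  # exactly one draw in each quartile
  expect_equal(sort(findInterval(v, c(0.25, 0.5, 0.75))), 0:3)
})

test_that("sampling is deterministic given the seed", {
  spec <- population_spec(n_patients = 6, seed = 11)
  a <- sample_parameters(spec)
  b <- sample_parameters(spec)
  expect_identical(a, b)
  spec2 <- population_spec(n_patients = 6, seed = 12)
  c2 <- sample_parameters(spec2)
  expect_false(identical(a, c2))
})

test_that("large-sample mean honours the sampling-error bound", {
  vp <- data.frame(name = "k_kill", dist = "normal", p1 = 2, p2 = 0.3,
                   scope = "per_patient", stringsAsFactors = FALSE)
  spec <- population_spec(n_patients = 1000, varied_params = vp, seed = 4)
  pats <- sample_parameters(spec)
  v <- sapply(pats, function(p) p$params[["k_kill"]])
  expect_lt(abs(mean(v) - 2), 4 * 0.3 / sqrt(1000))
})

test_that("per-tumour scope draws independent values per tumour", {
  spec <- population_spec(n_patients = 5, seed = 8)
  pats <- sample_parameters(spec)
  v <- sapply(pats, function(p) stats::sd(p$params[paste0("k_rec_m1_", 1:4)]))
  expect_true(all(v > 0))
})

test_that("unknown names and bad distributions are rejected", {
  bad <- data.frame(name = "not_a_param", dist = "uniform", p1 = 0, p2 = 1,
                    scope = "per_patient", stringsAsFactors = FALSE)
  expect_error(population_spec(varied_params = bad), "does not resolve")
  bad2 <- data.frame(name = "k_kill", dist = "cauchy", p1 = 0, p2 = 1,
                     scope = "per_patient", stringsAsFactors = FALSE)
  expect_error(population_spec(varied_params = bad2),
               "invalid distribution")
})

test_that("seeding schedule starts the clock at the earliest lesion", {
  spec <- population_spec(n_patients = 3, seed = 21)
  pats <- sample_parameters(spec)
  s <- seed_metastases(pats[[1]])
  expect_equal(min(s$times, na.rm = TRUE), 0)
  expect_true(all(s$events$value >= 0))
  # each seeded compartment receives the configured number of cells
  for (tc in names(s$times)[!is.na(s$times)]) {
    got <- sum(s$events$value[grepl(tc, s$events$var)])
    expect_equal(got, 100)
  }
  # identical on rerun
  expect_identical(seed_metastases(pats[[1]]), s)
})

test_that("burn-in rejects non-growing patients and accepts growers", {
  spec <- population_spec(n_patients = 2, seed = 5, max_burnin_days = 400)
  pats <- sample_parameters(spec)
  ok <- burn_in(pats[[1]], max_burnin_days = 1500)
  expect_true(ok$accepted)
  expect_gte(max(lesion_diameters(ok$baseline_state, ok$params,
                                  baseline_lesions(ok))),
             ok$target_diameter_cm)
  # zero growth rates never reach the target
  p0 <- pats[[2]]
  p0$params[paste0("k_growth_", 1:5)] <- 0
  no <- burn_in(p0, max_burnin_days = 300)
  expect_false(no$accepted)
  expect_false(no$failed)
})

test_that("acceptance is monotone in the target diameter", {
  spec <- population_spec(n_patients = 8, seed = 13, max_burnin_days = 500)
  pats <- sample_parameters(spec)
  acc <- function(scale) {
    sum(sapply(pats, function(p) {
      p$target_diameter_cm <- p$target_diameter_cm * scale
      burn_in(p, max_burnin_days = 500)$accepted
    }))
  }
  a1 <- acc(1); a2 <- acc(2.5)
  expect_lte(a2, a1)
})

test_that("cohort generation filters, audits and stays reproducible", {
  expect_error(generate_cohort(population_spec(n_patients = 0)), "empty")
  ch <- small_cohort(n = 10, seed = 3)
  expect_s3_class(ch, "qsp_cohort")
  expect_equal(attr(ch, "n_sampled"), 10)
  expect_true(all(sapply(ch, function(p) p$accepted)))
  man <- cohort_manifest(ch)
  expect_equal(nrow(man), length(ch))
  # the accepted baseline diameters sit at the sampled targets
  med <- median_baseline_diameter(ch)
  expect_gt(med, 1.0); expect_lt(med, 2.5)
  # rerun equality
  ch2 <- generate_cohort(population_spec(n_patients = 10, seed = 3))
  expect_identical(cohort_manifest(ch2), man)
})
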