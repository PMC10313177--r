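test_that("relative abundance is a ratio of independent tallies", {
  p <- default_parameters()
  y <- initial_state(p)
  fill <- function(y, tc, tcyt, th, treg, m1, m2, mdsc, cancer = 1e8) {
    y[paste0(tc, ".cancer.1")] <- cancer
    for (e in 1:8) y[paste0(tc, ".tcyt.", e)] <- tcyt / 8
    y[paste0(tc, ".th")] <- th; y[paste0(tc, ".treg")] <- treg
    y[paste0(tc, ".m1")] <- m1; y[paste0(tc, ".m2")] <- m2
    y[paste0(tc, ".mdsc")] <- mdsc
    y
  }
  y <- fill(y, "tumor_primary", 1e6, 5e5, 2e5, 1e6, 8e5, 3e5)
  # identical composition: all ratios one
  y_same <- fill(y, "tumor_lung1", 1e6, 5e5, 2e5, 1e6, 8e5, 3e5)
  # apc_immature baselines differ per slot; align them for the identity
  y_same["tumor_lung1.apc_immature"] <- y_same["tumor_primary.apc_immature"]
  r <- simulated_relative_abundance(y_same, y_same)
  expect_equal(unname(r), rep(1, 7))
  # doubled Treg count at equal totals: Treg ratio 2
  y2 <- fill(y, "tumor_lung1", 1e6, 5e5, 4e5, 1e6, 8e5, 1e5)
  y2["tumor_lung1.apc_immature"] <- y2["tumor_primary.apc_immature"]
  r2 <- simulated_relative_abundance(y2, y2, "tumor_lung1", "tumor_primary")
  tot_p <- sum(tnbcqsp:::tally_tumor_cells(y2, "tumor_primary"))
  tot_m <- sum(tnbcqsp:::tally_tumor_cells(y2, "tumor_lung1"))
  expect_equal(unname(r2["treg"]), (4e5 / tot_m) / (2e5 / tot_p))
  # recount oracle: fractions recomputed by hand agree exactly
  hand <- (1e6 / tot_m) / (1e6 / tot_p)
  expect_equal(unname(r2["m1"]), hand)
  # zero primary fraction: ratio absent
  y3 <- y2
  y3["tumor_primary.mdsc"] <- 0
  r3 <- simulated_relative_abundance(y3, y3, "tumor_lung1", "tumor_primary")
  expect_true(is.na(r3[["mdsc"]]))
})

test_that("abundance loss is a symmetric squared log-ratio error", {
  tg1 <- data.frame(cell_type = "m1", site = "lung", estimator = "e",
                    ratio = 1)
  expect_equal(abundance_loss(list(lung = c(m1 = 1)), tg1), 0)
  expect_equal(abundance_loss(list(lung = c(m1 = 2)), tg1), log(2)^2)
  tg2 <- data.frame(cell_type = "m1", site = "lung", estimator = "e",
                    ratio = 2)
  expect_equal(abundance_loss(list(lung = c(m1 = 1)), tg2),
               abundance_loss(list(lung = c(m1 = 2)), tg1))
  expect_error(abundance_loss(list(lung = c(zz = 1)), tg1), "no overlap")
})

test_that("fitting respects the optimizer contract", {
  tg <- read_abundance_targets()
  # no free parameters: input returned unchanged
  p <- default_parameters()
  fit0 <- fit_metastasis_params(tg, p, free = character(0))
  expect_identical(fit0$params, p)
  # tiny budget: loss never exceeds the starting loss
  fit1 <- suppressWarnings(
    fit_metastasis_params(tg, p, free = c("lung.rec_m1", "lung.apc0"),
                          budget = 12))
  expect_lte(fit1$loss, fit1$initial_loss)
  expect_true(nrow(fit1$trace) >= 2)
})

test_that("self-generated abundance targets are recovered", {
  p <- default_parameters()
  true_scales <- c(lung.rec_m1 = 0.6, lung.apc0 = 0.5)
  pt <- tnbcqsp:::apply_met_scales(p, as.list(true_scales))
  snaps <- reference_abundance_states(pt)
  sim <- simulated_relative_abundance(snaps$tumor_lung1,
                                      snaps$tumor_primary, "tumor_lung1")
  tg <- data.frame(cell_type = names(sim), site = "lung",
                   estimator = "self", ratio = unname(sim))
  tg <- tg[is.finite(tg$ratio) & tg$ratio > 0, ]
  fit <- fit_metastasis_params(tg, p, free = names(true_scales),
                               budget = 120)
  expect_true(all(abs(fit$scales / true_scales - 1) < 0.1))
  expect_lt(fit$loss, fit$initial_loss)
})

test_that("trial-handle calibration reaches its targets on a small cohort", {
  spec <- population_spec(n_patients = 60, seed = 19)
  cal <- calibrate_trial_handles(spec,
                                 target_lung_prevalence = 0.65,
                                 target_median_diameter_cm = 1.65,
                                 tol_prevalence = 0.08,
                                 tol_diameter_cm = 0.1, budget = 6)
  expect_lt(abs(cal$lung_prevalence - 0.65), 0.081)
  expect_lt(abs(cal$median_diameter_cm - 1.65), 0.11)
  # the calibrated spec reproduces its targets when regenerated
  ch <- generate_cohort(cal$spec)
  expect_lt(abs(lung_met_prevalence(ch) - cal$lung_prevalence), 1e-12)
})
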