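test_that("sum of diameters adds target lesions and zeroes vanished ones", {
  tr <- traj_from_sums(cbind(c(10, 10), c(12, 1), c(8, 8)))
  expect_equal(sum_of_diameters(tr, 0), 30)
  expect_equal(sum_of_diameters(tr, 63), 18)  # 1 mm lesion counts as gone
  tr1 <- traj_from_sums(cbind(c(15, 14)))
  expect_equal(sum_of_diameters(tr1, 63), 14)
  expect_error(sum_of_diameters(tr, 999), "assessment grid")
})

test_that("RECIST truth table over hand-crafted trajectories", {
  classify <- function(m, ...) {
    r <- classify_recist(traj_from_sums(m), ...)
    as.character(r$status)
  }
  b <- 30  # baseline sum, single lesion unless stated
  cases <- list(
    # 1 constant series maintained 24+ weeks: SD
    list(m = cbind(rep(b, 5)), want = "SD"),
    # 2 -33% at week 9, sustained: PR
    list(m = cbind(c(b, 20, 20, 20)), want = "PR"),
    # 3 +33% and +10 mm over nadir: PD
    list(m = cbind(c(b, 40, 40, 40)), want = "PD"),
    # 4 disappearance of every lesion: CR
    list(m = cbind(c(b, 1, 0, 0)), want = "CR"),
    # 5 exactly -30%: PR boundary included
    list(m = cbind(c(b, 21, 21, 21)), want = "PR"),
    # 6 +20% but below the 5 mm absolute minimum: no PD, stays SD
    list(m = cbind(c(20, 24, 24, 24)), want = "SD"),
    # 7 +20% of nadir and +5 mm: PD via the nadir reference after shrink
    list(m = cbind(c(b, 20, 20, 26, 26)), want = "PR"),
    # 8 response then progression: best response PR, progression recorded
    list(m = cbind(c(b, 20, 40, 40)), want = "PR"),
    # 9 early progression before the SD window: PD
    list(m = cbind(c(b, 37, 37, 37)), want = "PD"),
    # 10 shrink not reaching -30%, maintained: SD
    list(m = cbind(c(b, 25, 25, 25)), want = "SD"),
    # 11 two lesions, one vanishes but the other persists: PR not CR
    list(m = cbind(c(15, 1, 1, 1), c(15, 9, 9, 9)), want = "PR"),
    # 12 series too short to document SD: PD by default
    list(m = cbind(c(b, 28, 28)), want = "PD")
  )
  for (i in seq_along(cases)) {
    expect_equal(classify(cases[[i]]$m), cases[[i]]$want,
                 label = paste("case", i))
  }
  # timing details
  r2 <- classify_recist(traj_from_sums(cases[[2]]$m))
  expect_equal(r2$time_to_response, 63)
  expect_equal(r2$duration_of_response, 189 - 63)
  expect_false(r2$progressed_by_end)
  r8 <- classify_recist(traj_from_sums(cases[[8]]$m))
  expect_equal(r8$time_to_response, 63)
  expect_equal(r8$duration_of_response, 126 - 63)
  expect_true(r8$progressed_by_end)
  # case 7: nadir 20, 26 = +30% and +6 mm -> progression after response
  r7 <- classify_recist(traj_from_sums(cases[[7]]$m))
  expect_true(r7$progressed_by_end)
  expect_error(classify_recist(traj_from_sums(matrix(nrow = 0, ncol = 1))),
               "empty")
})

test_that("classification is scale-invariant up to the absolute PD rule", {
  m <- cbind(c(30, 20, 20, 20))
  for (f in c(0.5, 1, 3)) {
    r <- classify_recist(traj_from_sums(m * f))
    expect_equal(as.character(r$status), "PR")
  }
})

test_that("trial summary computes rates and bootstrap intervals", {
  mk <- function(status, ttr = NA, dor = NA) {
    structure(list(status = factor(status,
                                   levels = c("CR", "PR", "SD", "PD")),
                   time_to_response = ttr, duration_of_response = dor,
                   progressed_by_end = FALSE), class = "response_record")
  }
  # 5 responders of 20
  recs <- c(lapply(1:5, function(i) mk("PR", 63, 200 + i)),
            lapply(1:15, function(i) mk("PD")))
  names(recs) <- sprintf("p%02d", 1:20)
  s <- trial_summary(recs, n_boot = 500, seed = 9)
  expect_equal(s$orr, 0.25)
  expect_equal(s$median_ttr, 63)
  expect_true(s$orr_ci[1] <= s$orr && s$orr <= s$orr_ci[2])
  # all PD: ORR 0 with degenerate interval, endpoints absent not zero
  recs0 <- lapply(1:8, function(i) mk("PD"))
  names(recs0) <- sprintf("q%02d", 1:8)
  s0 <- trial_summary(recs0, n_boot = 100, seed = 1)
  expect_equal(s0$orr, 0)
  expect_equal(s0$orr_ci, c(0, 0))
  expect_true(is.na(s0$median_dor))
  # CI width shrinks roughly like 1/sqrt(n)
  width <- function(n) {
    r <- c(lapply(seq_len(n / 4), function(i) mk("PR", 63, 100)),
           lapply(seq_len(3 * n / 4), function(i) mk("PD")))
    names(r) <- sprintf("w%04d", seq_along(r))
    s <- trial_summary(r, n_boot = 400, seed = 2)
    diff(s$orr_ci)
  }
  expect_gt(width(40), 1.6 * width(400))
  # determinism under seed
  s1 <- trial_summary(recs, n_boot = 200, seed = 5)
  s2 <- trial_summary(recs, n_boot = 200, seed = 5)
  expect_identical(s1, s2)
})

test_that("treatment simulation responds to the regimen", {
  ch <- small_cohort()
  pat <- ch[[1]]
  sim <- simulate_treatment(pat, regimen(), duration_days = 189)
  expect_equal(sort(unique(sim$trajectories$time_day)), seq(0, 189, 63))
  expect_true(all(sim$trajectories$diameter_mm >= 0))
  # the baseline assessment equals the burn-in exit diameters
  d0 <- sim$trajectories$diameter_mm[sim$trajectories$time_day == 0]
  want <- 10 * lesion_diameters(pat$baseline_state, pat$params,
                                sim$lesions)
  expect_equal(d0, unname(want))
})
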