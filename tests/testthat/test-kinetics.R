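test_that("Gompertz growth rate matches the closed form and its limits", {
  # empty clone and at-capacity burden contribute nothing
  expect_equal(gompertz_growth_rate(0, 1e6, 1e9, 0.05), 0)
  expect_equal(gompertz_growth_rate(1e6, 1e9, 1e9, 0.05), 0)
  # direct evaluation: k n ln(K/N)
  expect_equal(gompertz_growth_rate(1e6, 1e6, 1e9, 0.01),
               0.01 * 1e6 * log(1e3))
  # overflow guard: log term clipped at -ln_cap when N > K
  expect_equal(gompertz_growth_rate(10, 1e30, 1, 1, ln_cap = 10),
               -10 * 10)
  expect_error(gompertz_growth_rate(NaN, 1, 1, 1), "non-finite")
})

test_that("carrying-capacity rate balances at half saturation", {
  expect_equal(carrying_capacity_rate(1e9, 0, 0.1, 0, 0.5), 0)
  # A = EC50 with growth = 2x decay: exact balance
  expect_equal(carrying_capacity_rate(1e9, 0.5, 0.1, 0.05, 0.5), 0)
  # saturation limit (k_growth - k_decay) K
  expect_equal(carrying_capacity_rate(1e9, 1e12, 0.1, 0.05, 0.5),
               (0.1 * 1e12 / (1e12 + 0.5) - 0.05) * 1e9,
               tolerance = 1e-9)
  # monotone in A
  a <- sapply(c(0, 0.1, 1, 10), function(A)
    carrying_capacity_rate(1e9, A, 0.1, 0.05, 0.5))
  expect_true(all(diff(a) > 0))
})

test_that("cytotoxic killing: half-max ratio and full suppression", {
  expect_equal(cytotoxic_killing_rate(1e6, 0), 0)
  expect_equal(cytotoxic_killing_rate(1e6, 1e6, pd1_inhibition = 1), 0)
  # R = kd_ratio_half gives half-maximal killing
  expect_equal(
    cytotoxic_killing_rate(1e6, 0.3 * 1e6, k_kill = 1, kd_ratio_half = 0.3),
    5e5)
  # each suppressive mediator at its EC50 halves the rate
  base <- cytotoxic_killing_rate(1e6, 3e5, k_kill = 1)
  supp <- cytotoxic_killing_rate(1e6, 3e5, k_kill = 1, tgfb = 0.5,
                                 ec50_tgfb = 0.5)
  expect_equal(supp, base / 2)
})

test_that("T-cell activation flux follows the Hill and linear-sum forms", {
  z <- tcell_activation_flux(1e6, 1e6, 0)
  expect_equal(z$activation, 0)
  # all division inputs zero: amplification 2^0 = 1
  z0 <- tcell_activation_flux(1e6, 1e9, 10, il2 = 0, f_cd28 = 0,
                              d_tcr = 0)
  expect_equal(z0$n_divisions, 0)
  expect_equal(z0$output, z0$activation)
  # d_tcr h + d_cd28 f + d_il2 f with all fractions 0.5 -> n = 2, 4x
  h <- 0.5
  pm <- 0.3  # pmhc = ec50 -> h_tcr = 0.5
  z1 <- tcell_activation_flux(1e6, 1e9, pm, il2 = 1, f_cd28 = 0.5,
                              ec50_apc = 0, d_tcr = 2, d_cd28 = 1,
                              d_il2 = 1, ec50_il2 = 1)
  expect_equal(z1$n_divisions, 2 * h + 1 * 0.5 + 1 * 0.5)
  expect_equal(z1$output / z1$activation, 4)
})

test_that("myeloid fluxes reduce to hand computation at EC50 inputs", {
  p <- default_parameters()
  s <- list(m1 = 1e5, m2 = 2e5, mdsc = 1e4, cancer = 1e8,
            ccl2 = 0, il10 = 0, il12 = 0, ifng = 0, tgfb = 0)
  fx <- myeloid_fluxes(s, p, tumor_index = 1, volume_mL = 1)
  # no CCL2: no recruitment; no cytokines: baseline polarization
  expect_equal(fx$M1_recruit, 0)
  expect_equal(fx$MDSC_recruit, 0)
  expect_equal(fx$M1toM2, p[["k_pol_m1m2_1"]] * s$m1)
  expect_equal(fx$M2toM1, p[["k_pol_m2m1"]] * s$m2)
  # every modulating input at its EC50: factors of one half
  s2 <- within(s, {
    ccl2 <- p[["ec50_ccl2"]]; il10 <- p[["ec50_il10_pol"]]
    tgfb <- p[["ec50_tgfb_pol"]]; il12 <- p[["ec50_il12_pol"]]
    ifng <- p[["ec50_ifng_pol"]]
  })
  fx2 <- myeloid_fluxes(s2, p, tumor_index = 1, volume_mL = 2)
  expect_equal(fx2$M1_recruit,
               p[["k_rec_m1_1"]] * 0.5 * 2 * p[["f_vasc"]])
  expect_equal(fx2$M1toM2,
               p[["k_pol_m1m2_1"]] * s$m1 *
                 (1 + 0.5 * p[["a_il10_pol"]] + 0.5 * p[["a_tgfb_pol"]]))
  expect_equal(fx2$M2toM1,
               p[["k_pol_m2m1"]] * s$m2 *
                 (1 + 0.5 * p[["a_il12_pol"]] + 0.5 * p[["a_ifng_pol"]]))
})

test_that("tumour diameter follows the spherical cell-volume law", {
  expect_equal(tumor_diameter(0), 0)
  expect_equal(tumor_diameter(1e9, 1e-9), (6 / pi)^(1 / 3))
  # doubling the cell count scales the diameter by 2^(1/3)
  expect_equal(tumor_diameter(2e9) / tumor_diameter(1e9), 2^(1 / 3))
  # strictly increasing
  d <- tumor_diameter(c(1e6, 1e7, 1e8))
  expect_true(all(diff(d) > 0))
})
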