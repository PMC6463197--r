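test_that("within-lab reproducibility is the QC-chart RSD", {
  expect_equal(u_repro_from_qc(rep(5, 20)), 0)
  x <- with_mean_sd(rnorm(20), 5, 0.4)
  expect_equal(u_repro_from_qc(x), 8.0, tolerance = 1e-12)
  set.seed(13)
  y <- rnorm(24, 5, 0.4)  # 8% CV
  est <- u_repro_from_qc(y)
  band <- sd_band(8, n = 24)
  expect_gt(est, band[1])
  expect_lt(est, band[2])
  expect_warning(u_repro_from_qc(rnorm(12, 5, 0.1)), "fewer than 20")
  expect_error(u_repro_from_qc(5), "at least 2")
  expect_error(u_repro_from_qc(c(5, -1, 4)), "finite and > 0")
})

test_that("bias components give B_r, the SE of the mean, and its relative form", {
  b0 <- bias_components(rep(5, 10), 5)
  expect_equal(b0[["b_r_pct"]], 0)
  set.seed(23)
  x <- with_mean_sd(rnorm(9), 5, 0.3)
  expect_warning(b <- bias_components(x, 5), "fewer than 10")
  expect_equal(b[["u_cm"]], 0.1, tolerance = 1e-12)     # 0.3 / sqrt(9)
  expect_equal(b[["u_r_cm_pct"]], 2.0, tolerance = 1e-12)
  y <- with_mean_sd(rnorm(10), 0.87 * 5, 0.2)
  expect_equal(bias_components(y, 5)[["b_r_pct"]], -13.0, tolerance = 1e-9)
  expect_error(bias_components(rep(5, 10), 0), "> 0")
})

test_that("standard-purity uncertainty comes from certificate or rectangular rule", {
  expect_equal(u_ref_from_certificate(2.0, 2), 1.0)
  expect_equal(u_ref_from_certificate(0.5, 2), 0.25)
  expect_equal(u_ref_from_certificate(0, 2), 0)
  expect_error(u_ref_from_certificate(1, 0), "> 0")
  expect_equal(u_ref_from_purity(100), 0)
  expect_equal(u_ref_from_purity(96), 0.5 * 4 / sqrt(3), tolerance = 1e-12)
  expect_equal(round(u_ref_from_purity(96), 2), 1.15)
  expect_equal(u_ref_from_purity(97), 0.866, tolerance = 5e-4)
  expect_error(u_ref_from_purity(0), "purity")
  expect_error(u_ref_from_purity(101), "purity")
  # certificate takes precedence over purity in the panel rule
  m <- load_method()
  expect_equal(u_ref_for_analyte(m$panel, "Hexachlorobenzene"), 1.0)
  expect_equal(u_ref_for_analyte(m$panel, "Lindane"), 0.5 * 3 / sqrt(3),
               tolerance = 1e-12)
})

test_that("combination is root-sum-of-squares, sign-blind in the bias and monotone", {
  expect_equal(combine_budget(0, 0, 0, 0),
               c(u_r_tot_pct = 0, U_r_tot_pct = 0))
  t1 <- combine_budget(8.01, -4.66, 0.909, 1.15)
  expect_equal(t1[["u_r_tot_pct"]], 9.38, tolerance = 0.005)
  expect_equal(t1[["U_r_tot_pct"]], 18.8, tolerance = 0.05)
  t2 <- combine_budget(6.04, -13.0, 0.451, 0.866)
  expect_equal(t2[["u_r_tot_pct"]], 14.4, tolerance = 0.05)
  expect_equal(t2[["U_r_tot_pct"]], 28.7, tolerance = 0.05)
  set.seed(31)
  for (i in 1:25) {
    u <- runif(4, 0, 15)
    expect_equal(combine_budget(u[1], -u[2], u[3], u[4]),
                 combine_budget(u[1], u[2], u[3], u[4]), tolerance = 1e-12)
    bigger <- combine_budget(u[1] + 1, u[2], u[3], u[4])
    expect_gte(bigger[["u_r_tot_pct"]],
               combine_budget(u[1], u[2], u[3], u[4])[["u_r_tot_pct"]])
  }
  expect_error(combine_budget(Inf, 0, 0, 0), "finite")
  expect_error(combine_budget(-1, 0, 0, 0), ">= 0")
})

test_that("a simulated QC pipeline recovers injected CV, bias and purity terms", {
  set.seed(47)
  rec <- 0.95  # -5% injected bias
  chart <- rnorm(20, 5 * rec, 5 * rec * 0.08)
  reps <- rnorm(10, 5 * rec, 5 * rec * 0.08)
  b <- uncertainty_budget(chart, reps, c_ref = 5,
                          u_ref = u_ref_from_purity(96))
  band_cv <- sd_band(8 * rec / (rec), n = 20)  # RSD is scale-free
  expect_gt(b$u_r_repro_pct, band_cv[1])
  expect_lt(b$u_r_repro_pct, band_cv[2])
  # B_r within +/- 3 SE of the injected -5%
  se_b <- 8 / sqrt(10)
  expect_lt(abs(b$b_r_pct - (-5)), 3 * se_b)
  expect_equal(b$u_r_ref_pct, 1.1547, tolerance = 5e-4)
  expect_equal(b$u_r_tot_pct,
               sqrt(b$u_r_repro_pct^2 + b$b_r_pct^2 + b$u_r_cm_pct^2 +
                      b$u_r_ref_pct^2), tolerance = 1e-12)
  expect_equal(b$U_r_tot_pct, 2 * b$u_r_tot_pct, tolerance = 1e-12)
})
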