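test_that("limits are 3x and 10x the replicate SD, so LOQ = (10/3) LOD", {
  expect_warning(lim0 <- limits_from_replicates(rep(0.1, 8), 0.1), "replicates")
  expect_equal(lim0$lod, 0)
  expect_equal(lim0$loq, 0)
  set.seed(3)
  x <- with_mean_sd(rnorm(10), 0.1, 0.0092)
  lim <- limits_from_replicates(x, 0.1)
  expect_equal(lim$sd_at_spike, 0.0092, tolerance = 1e-12)
  expect_equal(lim$lod, 0.0276, tolerance = 1e-12)
  expect_equal(lim$loq, 0.092, tolerance = 1e-12)
  # identity holds for arbitrary replicate sets
  for (i in 1:20) {
    y <- rnorm(10, 0.1, runif(1, 0.001, 0.05))
    l <- limits_from_replicates(y, 0.1)
    expect_equal(l$loq, (10 / 3) * l$lod, tolerance = 1e-12)
    expect_equal(l$sd_at_spike, sd_oracle(y), tolerance = 1e-12)
  }
  expect_error(limits_from_replicates(0.1, 0.1), "at least 2")
})

test_that("replicate LOQ estimates fall in the chi-square band of the true value", {
  set.seed(11)
  sd_true <- 0.009
  x <- rnorm(10, 0.1, sd_true)
  lim <- suppressWarnings(limits_from_replicates(x, 0.1))
  band <- sd_band(10 * sd_true, n = 10)
  expect_gt(lim$loq, band[1])
  expect_lt(lim$loq, band[2])
})

test_that("recovery applies the SANTE acceptability rule", {
  r <- recovery(rep(5, 5), 5)
  expect_equal(r$recovery_pct, 100)
  expect_equal(r$rsd_pct, 0)
  expect_true(r$acceptable)
  # 57% recovery is tolerated when consistent
  lowc <- with_mean_sd(rnorm(5), 0.57 * 5, 0.1)
  rl <- recovery(lowc, 5)
  expect_equal(rl$recovery_pct, 57, tolerance = 1e-9)
  expect_true(rl$acceptable)
  # ... but not with RSD above 20%
  lown <- with_mean_sd(rnorm(5), 0.57 * 5, 0.25 * 0.57 * 5)
  expect_false(recovery(lown, 5)$acceptable)
  # above 140% is always out
  expect_false(recovery(rep(1.45 * 5, 3), 5)$acceptable)
  expect_error(recovery(numeric(0), 5), "no determined")
  expect_error(recovery(5, 0), "> 0")
})

test_that("intra-day precision is the sample RSD", {
  expect_equal(precision_intra(rep(5, 10)), 0)
  expect_equal(precision_intra(c(4.8, 5.0, 5.2)), 4.0, tolerance = 1e-12)
  set.seed(5)
  x <- rnorm(10, 5, 0.15)  # 3% CV
  expect_equal(precision_intra(x), sd_oracle(x) / mean(x) * 100,
               tolerance = 1e-12)
  band <- sd_band(3, n = 10)
  expect_gt(precision_intra(x), band[1])
  expect_lt(precision_intra(x), band[2])
})

test_that("inter-day precision pools days by default and matches intra on one pool", {
  expect_equal(precision_inter(rep(list(rep(5, 4)), 4)), 0)
  x <- c(4.8, 5.0, 5.2)
  expect_equal(precision_inter(list(x[1:2], x[3]), method = "pooled"),
               precision_intra(x))
  # 4x4 design built with exact day means and exact within-day SD 0.15:
  # the pooled variance has the closed form
  #   [sum_d (n_d - 1) s_d^2 + sum_d n_d (mean_d - grand)^2] / (N - 1)
  set.seed(19)
  mu <- c(4.8, 4.95, 5.05, 5.2)
  days <- lapply(mu, function(m) with_mean_sd(rnorm(4), m, 0.15))
  est <- precision_inter(days)
  ss <- 4 * 3 * 0.15^2 + 4 * sum((mu - 5)^2)
  expect_equal(est, sqrt(ss / 15) / 5 * 100, tolerance = 1e-10)
  # removing the between-day spread lowers the pooled estimate to within-only
  centered <- lapply(days, function(d) d - mean(d) + 5)
  expect_lt(precision_inter(centered), est)
  expect_equal(precision_inter(centered), 0.15 / 5 * 100 *
                 sqrt(4 * 3 / 15), tolerance = 1e-10)
  # ANOVA estimator is finite and at least the within-day component
  est_anova <- precision_inter(days, method = "anova")
  expect_true(is.finite(est_anova))
  expect_gte(est_anova, 3 * sqrt(4 * 3 / 15) - 1e-9)
  expect_error(precision_inter(list(c(1, 2))), "2 days")
  expect_error(precision_inter(list(c(1, 2), numeric(0))), "empty day")
})

test_that("trueness recovery and bias satisfy R - 100 = B_r", {
  tr <- trueness(6.47, 7.25)
  expect_equal(round(tr[["recovery_pct"]]), 89)
  expect_equal(tr[["rel_bias_pct"]], tr[["recovery_pct"]] - 100)
  expect_equal(trueness(5, 5), c(recovery_pct = 100, rel_bias_pct = 0))
  tr2 <- trueness(0.467, 0.742)
  expect_equal(round(tr2[["recovery_pct"]]), 63)
  set.seed(2)
  for (i in 1:25) {
    m <- runif(1, 0.1, 50); ref <- runif(1, 0.1, 50)
    t <- trueness(m, ref)
    expect_equal(t[["recovery_pct"]] - 100, t[["rel_bias_pct"]],
                 tolerance = 1e-12)
  }
  expect_error(trueness(5, 0), "> 0")
})

test_that("SRM comparison flags means outside the certified interval", {
  ok <- srm_compare(rep(7.25, 3), 7.25, 0.83)
  expect_true(ok$in_certified_range)
  expect_equal(ok$trueness_pct, 100)
  out1 <- srm_compare(rep(0.467, 3), 0.742, 0.027, analyte = "BDE-28")
  expect_false(out1$in_certified_range)
  expect_equal(round(out1$trueness_pct), 63)
  out2 <- srm_compare(rep(0.89, 3), 1.14, 0.18, analyte = "Lindane")
  expect_false(out2$in_certified_range)
  # a mean exactly on the boundary counts as inside
  border <- srm_compare(rep(5.77 + 0.80, 3), 5.77, 0.80)
  expect_true(border$in_certified_range)
  # overlap rule when the determined expanded uncertainty is supplied
  ov <- srm_compare(rep(0.89, 3), 1.14, 0.18, determined_expanded_u = 0.26)
  expect_true(ov$in_certified_range)
  expect_error(srm_compare(rep(1, 3), NA, 0.1), "certified")
})

test_that("values below the LOQ are censored in reporting only", {
  out <- censor_below_loq(c(0.05, 0.5), loq = 0.092)
  expect_identical(out$reported, c("<0.092", "0.5"))
  expect_identical(out$censored, c(TRUE, FALSE))
  expect_equal(out$value, c(0.05, 0.5))  # numeric values kept uncensored
})
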