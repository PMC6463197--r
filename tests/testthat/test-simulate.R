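test_that("seeded batches are reproducible and noise-free areas are proportional", {
  panel <- tiny_panel()
  cfg <- sim_config(panel, params = tiny_params(), seed = 99)
  b1 <- make_validation_batch(cfg)
  b2 <- make_validation_batch(cfg)
  expect_identical(b1, b2)
  b3 <- make_validation_batch(sim_config(panel, params = tiny_params(),
                                         seed = 100))
  expect_false(identical(b1$peak_area, b3$peak_area))

  cfg0 <- sim_config(panel, params = tiny_params(), noise_cv_pct = 0,
                     lipid_suppression_coeff = 0, seed = 1)
  a <- simulate_area(c(1, 2, 4), cfg0, "A1")
  expect_equal(a / a[1], c(1, 2, 4), tolerance = 1e-12)
  expect_equal(a[1], 1e4 * 2 * 1)  # base_scale x rrf x conc
})

test_that("higher lipid content attenuates the simulated signal", {
  panel <- tiny_panel()
  cfg <- sim_config(panel, params = tiny_params(), noise_cv_pct = 0,
                    lipid_suppression_coeff = 0.04, seed = 1)
  a_perch <- simulate_area(5, cfg, "IS", lipid_pct = 3)
  a_trout <- simulate_area(5, cfg, "IS", lipid_pct = 8.2)
  a_salmon <- simulate_area(5, cfg, "IS", lipid_pct = 16)
  expect_gt(a_perch, a_trout)
  expect_gt(a_trout, a_salmon)
  # suppression applies equally to analyte and IS, preserving the ratio
  r3 <- simulate_area(5, cfg, "A1", lipid_pct = 3) / a_perch
  r16 <- simulate_area(5, cfg, "A1", lipid_pct = 16) / a_salmon
  expect_equal(r3, r16, tolerance = 1e-12)
})

test_that("the default batch plan matches the validation study design", {
  m <- load_method()
  cfg <- sim_config(m$panel, srm = m$srm, seed = 5)
  b <- make_validation_batch(cfg)
  n_inj <- function(pattern)
    length(unique(paste(b$batch_id, b$run_index)[grepl(pattern, b$batch_id)]))
  expect_equal(n_inj("^loq_"), 2 * 10)       # 10 limit replicates, paired
  expect_equal(n_inj("^cal_"), 7)            # 7-level calibration
  expect_equal(n_inj("^rec"), 2 * 5 * 5)     # 5 levels x n = 5, paired
  expect_equal(n_inj("^qc_intra_"), 2 * 10)
  expect_equal(n_inj("^qc_inter_"), 2 * 16)  # 4 days x 4 replicates
  expect_equal(n_inj("^qc_chart_"), 2 * 24)
  expect_equal(n_inj("^srm_"), 2 * 3)
  expect_equal(n_inj("^me_mm_"), 5)
  expect_equal(n_inj("^me_solv_"), 5)
  # every injection carries all 16 compounds and validates against the schema
  expect_equal(nrow(b) %% 16, 0L)
  expect_silent(validate_measurements(b, m$panel))
  # recovery spike levels are those of the study
  expect_setequal(unique(b$spike_conc[grepl("^rec", b$batch_id) &
                                        b$analyte == "Lindane"]),
                  c(1, 5, 15, 30, 60))
})

test_that("a zero-noise batch round-trips recoveries exactly", {
  panel <- tiny_panel()
  params <- tiny_params(me = c(-10, 20, 5), recovery = c(80, 110, 100))
  cfg <- sim_config(panel, params = params, noise_cv_pct = 0, seed = 3)
  b <- make_validation_batch(cfg)
  det <- quantify_standard_addition(b, panel)
  rec <- det[grepl("^rec", det$batch_id), ]
  expect_equal(rec$conc[rec$analyte == "A1"] / rec$spike_conc[rec$analyte == "A1"],
               rep(0.80, sum(rec$analyte == "A1")), tolerance = 1e-10)
  expect_equal(rec$conc[rec$analyte == "A2"] / rec$spike_conc[rec$analyte == "A2"],
               rep(1.10, sum(rec$analyte == "A2")), tolerance = 1e-10)
})

test_that("the QC-chart RSD recovers the injected replicate CV", {
  panel <- tiny_panel()
  cfg <- sim_config(panel, params = tiny_params(), noise_cv_pct = 8, seed = 21)
  b <- make_validation_batch(cfg)
  det <- quantify_standard_addition(b, panel)
  chart <- det$conc[grepl("^qc_chart_", det$batch_id) & det$analyte == "A1"]
  expect_length(chart, 24L)
  est <- u_repro_from_qc(chart)
  band <- sd_band(8, n = 24)
  expect_gt(est, band[1])
  expect_lt(est, band[2])
})

test_that("simulator configuration is validated", {
  panel <- tiny_panel()
  expect_error(sim_config(panel, params = tiny_params()[1:2, ]),
               "cover every panel analyte")
  bad <- tiny_params(); bad$recovery_true_pct[1] <- 200
  expect_error(sim_config(panel, params = bad), "recovery_true_pct")
  expect_error(sim_config(panel, params = tiny_params(),
                          plan = list(bogus = 1)), "unknown plan")
  nop <- tiny_panel(); nop$is_conc[3] <- NA
  expect_error(sim_config(nop, params = tiny_params()), "is_conc")
})
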