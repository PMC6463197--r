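test_that("the packaged method definition loads fully cross-linked", {
  m <- load_method()
  expect_s3_class(m$panel, "analyte_panel")
  expect_equal(nrow(m$panel), 16L)
  expect_equal(sum(m$panel$role == "analyte"), 14L)
  expect_equal(sum(m$panel$role == "internal_standard"), 2L)
  # every analyte's internal-standard reference resolves
  tgt <- m$panel$role == "analyte"
  expect_true(all(m$panel$is_ref[tgt] %in%
                    m$panel$name[m$panel$role == "internal_standard"]))
  expect_equal(m$panel$is_ref[m$panel$name == "BDE-47"], "BDE-77")
  expect_equal(is_concentration(m$panel, "Tetrachloro-m-xylene"), 10)
  expect_equal(is_concentration(m$panel, "BDE-77"), 20)
  expect_equal(nrow(m$srm), 9L)
  expect_s3_class(m$ecoscale, "ecoscale_ledger")
})

test_that("panel validation rejects malformed definitions", {
  base <- data.frame(name = c("X", "IS"), role = c("analyte", "internal_standard"),
                     is_ref = c("IS", ""), purity_pct = c(99, 99),
                     stringsAsFactors = FALSE)
  expect_s3_class(analyte_panel(base), "analyte_panel")
  expect_error(analyte_panel(base[0, ]), "no analytes")
  dup <- rbind(base, base[1, ])
  expect_error(analyte_panel(dup), "duplicate")
  bad_is <- base; bad_is$is_ref[1] <- "nope"
  expect_error(analyte_panel(bad_is), "unknown internal standard")
  bad_purity <- base; bad_purity$purity_pct[1] <- 104
  expect_error(analyte_panel(bad_purity), "purity")
  bad_purity$purity_pct[1] <- 0
  expect_error(analyte_panel(bad_purity), "purity")
})

test_that("measurement tables round-trip through CSV and are validated", {
  m <- load_method()
  rec <- data.frame(
    analyte = rep(c("BDE-47", "BDE-77"), 5),
    batch_id = rep(sprintf("spk_r%d", 1:5), each = 2),
    run_index = 1L,
    sample_type = "spiked_sample",
    spike_conc = rep(c(5, 20), 5),
    addition_conc = NA_real_,
    peak_area = seq(1000, 1900, length.out = 10),
    lipid_pct = 16, moisture_pct = 58,
    stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".csv")
  write_measurements(rec, path)
  back <- read_measurements(path, m$panel)
  expect_equal(nrow(back), 10L)
  expect_identical(back$analyte, rec$analyte)
  expect_identical(back$batch_id, rec$batch_id)
  expect_identical(back$sample_type, rec$sample_type)
  expect_equal(back$peak_area, rec$peak_area, tolerance = 1e-12)
  expect_equal(back$lipid_pct, rec$lipid_pct)  # matrix descriptor retained

  bad <- rec; bad$peak_area[4] <- -5
  expect_error(validate_measurements(bad, m$panel), "row.*4|4")
  unk <- rec; unk$analyte[3] <- "not-a-compound"
  expect_error(validate_measurements(unk, m$panel), "unknown analyte")
  nn <- rec; nn$peak_area <- as.character(nn$peak_area); nn$peak_area[2] <- "x"
  expect_error(validate_measurements(nn, m$panel), "unparseable")
  sa <- rec; sa$sample_type[1] <- "standard_addition"
  expect_error(validate_measurements(sa, m$panel), "addition_conc")
})

test_that("method reader rejects unknown-analyte SRM rows and empty panels", {
  doc <- yaml::read_yaml(method_path())
  doc$srm_certified[[1]]$analyte <- "mystery"
  p <- tempfile(fileext = ".yaml"); yaml::write_yaml(doc, p)
  expect_error(read_method_definition(p), "unknown analyte")
  doc2 <- yaml::read_yaml(method_path())
  doc2$analytes <- list()
  p2 <- tempfile(fileext = ".yaml"); yaml::write_yaml(doc2, p2)
  expect_error(read_method_definition(p2), "no analytes")
})
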