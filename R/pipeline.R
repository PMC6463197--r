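unknown_sample_types <- c("spiked_sample", "unknown", "qc", "srm")

# mean blank peak area per analyte (0 when no blank injections exist)
blank_means <- function(records, panel) {
  out <- stats::setNames(rep(0, nrow(panel)), panel$name)
  bl <- records[records$sample_type == "blank", ]
  if (nrow(bl)) {
    m <- tapply(bl$peak_area, bl$analyte, mean)
    out[names(m)] <- m
  }
  out
}

#' Internal-standard response ratios per injection
#'
#' Collapses a long measurement table into one response ratio per injection
#' and analyte: the (optionally blank-corrected) analyte area divided by the
#' area of its assigned internal standard from the same injection.
#'
#' @param records measurement table (see [read_measurements()]).
#' @param panel an [analyte_panel()].
#' @param blank_correct subtract the mean blank area per analyte (default
#'   `TRUE`; no-op when the table has no blank injections).
#' @return data frame: `batch_id`, `run_index`, `sample_type`, `analyte`,
#'   `spike_conc`, `addition_conc`, `lipid_pct`, `ratio`.
#' @export
injection_ratios <- function(records, panel, blank_correct = TRUE) {
  records <- validate_measurements(records, panel)
  role <- panel$role[match(records$analyte, panel$name)]
  is_ref <- panel$is_ref[match(records$analyte, panel$name)]
  key <- paste(records$batch_id, records$run_index, sep = "\r")
  isr <- records[role == "internal_standard", ]
  is_lookup <- stats::setNames(isr$peak_area,
                               paste(isr$batch_id, isr$run_index, isr$analyte,
                                     sep = "\r"))
  tgt <- which(role == "analyte")
  is_area <- is_lookup[paste(key[tgt], is_ref[tgt], sep = "\r")]
  if (any(is.na(is_area)))
    stop("injection(s) missing the internal-standard peak: ",
         paste(utils::head(unique(records$batch_id[tgt][is.na(is_area)]), 5),
               collapse = ", "))
  blanks <- if (blank_correct) blank_means(records, panel)
            else stats::setNames(rep(0, nrow(panel)), panel$name)
  ratio <- response_ratio(records$peak_area[tgt], unname(is_area),
                          blanks[records$analyte[tgt]])
  data.frame(batch_id = records$batch_id[tgt],
             run_index = records$run_index[tgt],
             sample_type = records$sample_type[tgt],
             analyte = records$analyte[tgt],
             spike_conc = records$spike_conc[tgt],
             addition_conc = records$addition_conc[tgt],
             lipid_pct = records$lipid_pct[tgt],
             ratio = unname(ratio),
             stringsAsFactors = FALSE)
}

#' Quantify by single-point standard addition
#'
#' Pairs every unknown-type analysis (`spiked_sample`, `unknown`, `qc`,
#' `srm`) with the `standard_addition` analysis sharing its `batch_id`;
#' replicate analyses on either side of a pair are averaged at the
#' response-ratio level before Eq.-style inversion by
#' [standard_addition_conc()].
#'
#' @param records measurement table.
#' @param panel an [analyte_panel()].
#' @param blank_correct blank-correct the ratios (default `FALSE`: the
#'   standard-addition estimator needs no blank term).
#' @return data frame: `batch_id`, `sample_type`, `analyte`, `spike_conc`,
#'   `lipid_pct`, `conc` (determined concentration, ug/kg).
#' @export
quantify_standard_addition <- function(records, panel, blank_correct = FALSE) {
  rat <- injection_ratios(records, panel, blank_correct = blank_correct)
  unk <- rat[rat$sample_type %in% unknown_sample_types, ]
  add <- rat[rat$sample_type == "standard_addition", ]
  if (!nrow(unk) || !nrow(add))
    stop("standard-addition quantification needs paired unknown and addition analyses")
  agg_u <- stats::aggregate(ratio ~ batch_id + analyte, data = unk, FUN = mean)
  meta <- unk[!duplicated(paste(unk$batch_id, unk$analyte, sep = "\r")),
              c("batch_id", "analyte", "sample_type", "spike_conc", "lipid_pct")]
  agg_u <- merge(agg_u, meta, by = c("batch_id", "analyte"))
  agg_a <- stats::aggregate(cbind(ratio, addition_conc) ~ batch_id + analyte,
                            data = add, FUN = mean)
  m <- merge(agg_u, agg_a, by = c("batch_id", "analyte"),
             suffixes = c("_u", "_a"))
  if (!nrow(m)) stop("no unknown/standard-addition pairs share a batch_id")
  m$conc <- standard_addition_conc(m$addition_conc, m$ratio_u, m$ratio_a)
  m[order(m$analyte, m$batch_id),
    c("batch_id", "sample_type", "analyte", "spike_conc", "lipid_pct", "conc")]
}

#' Fit per-analyte calibrations from standard injections
#'
#' @param records measurement table.
#' @param panel an [analyte_panel()].
#' @param source `"matrix"` (matrix-matched standards, default) or
#'   `"solvent"`.
#' @param batches optional regular expression selecting calibration
#'   `batch_id`s (e.g. `"^cal_"` to exclude matrix-effect replicates).
#' @param blank_correct blank-correct the ratios (default `TRUE`).
#' @return named list of [fit_calibration()] objects, one per analyte.
#' @export
calibration_curves <- function(records, panel,
                               source = c("matrix", "solvent"),
                               batches = NULL, blank_correct = TRUE) {
  source <- match.arg(source)
  type <- if (source == "matrix") "matrix_matched_standard" else "solvent_standard"
  rat <- injection_ratios(records, panel, blank_correct = blank_correct)
  rat <- rat[rat$sample_type == type, ]
  if (!is.null(batches)) rat <- rat[grepl(batches, rat$batch_id), ]
  if (!nrow(rat)) stop("no ", type, " injections found")
  lapply(split(rat, rat$analyte), function(d) {
    is_name <- panel$is_ref[match(d$analyte[1], panel$name)]
    fit_calibration(d$spike_conc, d$ratio,
                    is_conc = is_concentration(panel, is_name),
                    analyte = d$analyte[1])
  })
}

#' Quantify unknown-type analyses against a fitted calibration
#'
#' External-calibration counterpart to [quantify_standard_addition()]; used
#' to demonstrate that, unlike the standard-addition estimator, calibration
#' against neat solvent standards inherits the matrix effect.
#'
#' @param records measurement table.
#' @param panel an [analyte_panel()].
#' @param curves result of [calibration_curves()].
#' @param blank_correct blank-correct the unknown ratios to match the curves
#'   (default `TRUE`).
#' @return data frame: `batch_id`, `sample_type`, `analyte`, `spike_conc`,
#'   `conc`.
#' @export
quantify_by_calibration <- function(records, panel, curves,
                                    blank_correct = TRUE) {
  rat <- injection_ratios(records, panel, blank_correct = blank_correct)
  unk <- rat[rat$sample_type %in% unknown_sample_types, ]
  unk <- unk[unk$analyte %in% names(curves), ]
  if (!nrow(unk)) stop("no unknown-type injections to quantify")
  unk$conc <- vapply(seq_len(nrow(unk)), function(i)
    predict(curves[[unk$analyte[i]]], ratio = unk$ratio[i]), numeric(1))
  unk[, c("batch_id", "sample_type", "analyte", "spike_conc", "conc")]
}

#' Matrix effects for every analyte from replicate standard pairs
#'
#' @param records measurement table.
#' @param panel an [analyte_panel()].
#' @param matrix_batches,solvent_batches regular expressions selecting the
#'   matrix-matched and solvent replicate injections (defaults match the
#'   simulator's `me_mm_*` / `me_solv_*` naming).
#' @param convention see [matrix_effect()].
#' @return data frame: `analyte`, `me_pct`, `rsd_pct`, `n`.
#' @export
matrix_effect_table <- function(records, panel, matrix_batches = "^me_mm_",
                                solvent_batches = "^me_solv_",
                                convention = "paper") {
  mm <- records[grepl(matrix_batches, records$batch_id), ]
  sv <- records[grepl(solvent_batches, records$batch_id), ]
  if (!nrow(mm) || !nrow(sv)) return(NULL)
  res <- lapply(sort(unique(mm$analyte)), function(a) {
    am <- mm$peak_area[mm$analyte == a][order(mm$batch_id[mm$analyte == a])]
    as <- sv$peak_area[sv$analyte == a][order(sv$batch_id[sv$analyte == a])]
    me <- matrix_effect(am, as, convention = convention, analyte = a)
    data.frame(analyte = a, me_pct = me$me_pct, rsd_pct = me$rsd_pct,
               n = me$n, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Run the full validation pipeline on a measurement table
#'
#' Quantifies every paired analysis by single-point standard addition and
#' assembles the per-analyte validation report: linearity (R^2, RRF RSD) from
#' the matrix-matched calibration, LOD/LOQ from the limit replicates,
#' recovery per spike level, intra-/inter-day precision, trueness from the
#' intra-day QC series, the top-down uncertainty budget (QC chart +
#' repeatability bias + standard purity), matrix effects and the SRM
#' comparison where the inputs exist. Experiments are recognised by the
#' documented `batch_id` prefixes (`cal_`, `solv_`, `me_mm_`/`me_solv_`,
#' `rec<level>_`, `loq_`, `qc_intra_`, `qc_inter_d<d>_`, `qc_chart_`,
#' `srm_`), the convention emitted by [make_validation_batch()].
#'
#' @param records measurement table (data frame or CSV path).
#' @param method a [read_method_definition()] result (or an `analyte_panel`,
#'   in which case no SRM comparison or Eco-Scale block is attached).
#' @param c_ref_qc reference concentration of the QC samples, ug/kg
#'   (default 5).
#' @param inter_method inter-day precision estimator, `"pooled"` or
#'   `"anova"`.
#' @param me_convention matrix-effect denominator convention (see
#'   [matrix_effect()]).
#' @param seed seed recorded in the provenance block (the pipeline itself is
#'   deterministic given its inputs).
#' @return object of class `"validation_report"`.
#' @export
validate_method <- function(records, method, c_ref_qc = 5,
                            inter_method = "pooled",
                            me_convention = "paper", seed = NA_integer_) {
  input_path <- NULL
  if (is.character(records)) {
    input_path <- records
    panel0 <- if (inherits(method, "halo_method")) method$panel else method
    records <- read_measurements(records, panel0)
  }
  if (inherits(method, "analyte_panel"))
    method <- structure(list(panel = method, srm = NULL, ecoscale = NULL,
                             path = "<panel>"), class = "halo_method")
  panel <- method$panel
  records <- validate_measurements(records, panel)
  targets <- sort(panel$name[panel$role == "analyte"])

  curves <- tryCatch(
    calibration_curves(records, panel, source = "matrix", batches = "^cal_"),
    error = function(e) NULL)
  if (is.null(curves))
    curves <- tryCatch(calibration_curves(records, panel, source = "matrix"),
                       error = function(e) NULL)
  me_tab <- matrix_effect_table(records, panel, convention = me_convention)
  det <- quantify_standard_addition(records, panel)

  pick <- function(prefix, a)
    det$conc[grepl(prefix, det$batch_id) & det$analyte == a]

  rows <- list(); budgets <- list(); recov <- list(); srm_rows <- list()
  for (a in targets) {
    cal <- curves[[a]]
    loq_det <- pick("^loq_", a)
    lim <- if (length(loq_det) >= 2) {
      spike <- unique(det$spike_conc[grepl("^loq_", det$batch_id) &
                                       det$analyte == a])[1]
      suppressWarnings(limits_from_replicates(loq_det, spike, analyte = a))
    } else NULL
    # per-level recovery
    rec_det <- det[grepl("^rec", det$batch_id) & det$analyte == a, ]
    if (nrow(rec_det)) {
      for (lev in sort(unique(rec_det$spike_conc))) {
        r <- recovery(rec_det$conc[rec_det$spike_conc == lev], lev, analyte = a)
        recov[[length(recov) + 1L]] <-
          data.frame(analyte = a, spike_level = lev,
                     recovery_pct = r$recovery_pct, rsd_pct = r$rsd_pct,
                     n = r$n, acceptable = r$acceptable,
                     stringsAsFactors = FALSE)
      }
    }
    qc_intra <- pick("^qc_intra_", a)
    qc_chart <- pick("^qc_chart_", a)
    inter_det <- det[grepl("^qc_inter_d", det$batch_id) & det$analyte == a, ]
    pre_intra <- if (length(qc_intra) >= 2) precision_intra(qc_intra) else NA_real_
    pre_inter <- if (nrow(inter_det)) {
      day <- sub("^qc_inter_(d[0-9]+)_.*$", "\\1", inter_det$batch_id)
      precision_inter(split(inter_det$conc, day), method = inter_method)
    } else NA_real_
    tru <- if (length(qc_intra)) trueness(mean(qc_intra), c_ref_qc)
           else c(recovery_pct = NA_real_, rel_bias_pct = NA_real_)
    if (length(qc_chart) >= 2 && length(qc_intra) >= 2) {
      budgets[[a]] <- suppressWarnings(uncertainty_budget(
        qc_chart, qc_intra, c_ref = c_ref_qc,
        u_ref = u_ref_for_analyte(panel, a), analyte = a))
    }
    if (!is.null(method$srm)) {
      srm_det <- pick("^srm_", a)
      j <- match(a, method$srm$analyte)
      if (length(srm_det) >= 2 && !is.na(j)) {
        s <- srm_compare(srm_det, method$srm$certified_conc[j],
                         method$srm$certified_expanded_u[j], analyte = a)
        srm_rows[[length(srm_rows) + 1L]] <-
          data.frame(analyte = a, certified_conc = s$certified_conc,
                     determined_mean = s$mean, trueness_pct = s$trueness_pct,
                     rsd_pct = s$rsd_pct,
                     in_certified_range = s$in_certified_range, n = s$n,
                     stringsAsFactors = FALSE)
      }
    }
    rows[[a]] <- data.frame(
      analyte = a,
      linear_range = if (!is.null(cal)) cal$linear_range else NA_character_,
      r_squared = if (!is.null(cal)) cal$r.squared else NA_real_,
      rrf = if (!is.null(cal)) cal$rrf_mean else NA_real_,
      rrf_rsd_pct = if (!is.null(cal)) cal$rrf_rsd_pct else NA_real_,
      lod = if (!is.null(lim)) lim$lod else NA_real_,
      loq = if (!is.null(lim)) lim$loq else NA_real_,
      pre_intra_rsd_pct = pre_intra,
      pre_inter_rsd_pct = pre_inter,
      recovery_pct = unname(tru["recovery_pct"]),
      b_r_pct = unname(tru["rel_bias_pct"]),
      stringsAsFactors = FALSE)
  }

  report <- list(
    table = do.call(rbind, rows),
    recovery_table = if (length(recov)) do.call(rbind, recov) else NULL,
    matrix_effects = me_tab,
    calibrations = curves,
    budgets = budgets,
    budget_table = if (length(budgets)) budget_table(budgets) else NULL,
    srm_table = if (length(srm_rows)) do.call(rbind, srm_rows) else NULL,
    ecoscale = method$ecoscale,
    determinations = det,
    c_ref_qc = c_ref_qc,
    provenance = list(
      package_version = as.character(utils::packageVersion("halovalid")),
      seed = seed,
      n_records = nrow(records),
      method_path = method$path,
      input_md5 = if (!is.null(input_path)) unname(tools::md5sum(input_path))
                  else NA_character_,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  )
  rownames(report$table) <- NULL
  class(report) <- "validation_report"
  report
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Method validation report (", nrow(x$table), " analytes)\n", sep = "")
  print.data.frame(summary(x)$table, row.names = FALSE)
  if (!is.null(x$budget_table)) {
    cat("\nTop-down uncertainty budgets (%):\n")
    bt <- x$budget_table
    bt[-1] <- lapply(bt[-1], function(v) signif(v, 3))
    print.data.frame(bt[, 1:7], row.names = FALSE)
  }
  if (!is.null(x$ecoscale))
    cat(sprintf("\nEco-Scale score: %d (%s)\n", x$ecoscale$score,
                x$ecoscale$classification))
  invisible(x)
}

#' Summarise a validation report at reporting precision
#'
#' Full numeric precision is kept inside the report object; this summary
#' applies the conventional reporting style (limits to 2 significant
#' figures, recoveries and biases to whole numbers except near zero, RSDs to
#' 2 significant figures).
#'
#' @param object a [validate_method()] report.
#' @param ... unused.
#' @return list of class `"summary.validation_report"` with rounded `table`,
#'   `budget_table`, `srm_table`.
#' @export
summary.validation_report <- function(object, ...) {
  t <- object$table
  t$r_squared <- round(t$r_squared, 5)
  for (col in c("rrf", "rrf_rsd_pct", "lod", "loq", "pre_intra_rsd_pct",
                "pre_inter_rsd_pct"))
    t[[col]] <- signif(t[[col]], 2)
  t$recovery_pct <- round(t$recovery_pct)
  t$b_r_pct <- signif(t$b_r_pct, 2)
  bt <- object$budget_table
  if (!is.null(bt)) bt[-1] <- lapply(bt[-1], function(v) signif(v, 3))
  out <- list(table = t, budget_table = bt, srm_table = object$srm_table)
  class(out) <- "summary.validation_report"
  out
}

#' @export
print.summary.validation_report <- function(x, ...) {
  print.data.frame(x$table, row.names = FALSE)
  invisible(x)
}

#' Write a validation report to disk
#'
#' Emits the full-precision report as JSON plus flat CSV tables and a
#' plain-text summary.
#'
#' @param report a [validate_method()] result.
#' @param dir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  json_path <- file.path(dir, "report.json")
  payload <- list(table = report$table,
                  recovery_table = report$recovery_table,
                  matrix_effects = report$matrix_effects,
                  budget_table = report$budget_table,
                  srm_table = report$srm_table,
                  ecoscale = if (!is.null(report$ecoscale))
                    list(items = report$ecoscale$items,
                         total_penalty = report$ecoscale$total_penalty,
                         score = report$ecoscale$score,
                         classification = report$ecoscale$classification),
                  provenance = report$provenance)
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  paths <- c(paths, json_path)
  for (nm in c("table", "recovery_table", "budget_table", "srm_table")) {
    if (!is.null(report[[nm]])) {
      p <- file.path(dir, paste0(nm, ".csv"))
      utils::write.csv(report[[nm]], p, row.names = FALSE)
      paths <- c(paths, p)
    }
  }
  txt <- file.path(dir, "summary.txt")
  con <- file(txt, "w"); sink(con); print(report); sink(); close(con)
  paths <- c(paths, txt)
  invisible(paths)
}

#' Run the pipeline from a configuration file
#'
#' The YAML configuration names a `method` definition file and either a
#' `measurements` CSV or a `simulate` block (passed to [sim_config()];
#' `simulate: {}` uses the defaults). Optional keys: `seed` (default 1),
#' `c_ref_qc`, `out_dir` (when present the report is written there).
#'
#' @param config path to the YAML configuration.
#' @return the [validate_method()] report, invisibly.
#' @export
run_pipeline <- function(config) {
  cfgdoc <- yaml::read_yaml(config)
  base <- dirname(normalizePath(config))
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  if (is.null(cfgdoc$method)) stop("config stage [method]: no method file given")
  method <- tryCatch(read_method_definition(resolve(cfgdoc$method)),
                     error = function(e) stop("config stage [method]: ",
                                              conditionMessage(e)))
  seed <- if (!is.null(cfgdoc$seed)) as.integer(cfgdoc$seed) else 1L
  if (!is.null(cfgdoc$measurements)) {
    records <- tryCatch(read_measurements(resolve(cfgdoc$measurements),
                                          method$panel),
                        error = function(e) stop("config stage [measurements]: ",
                                                 conditionMessage(e)))
  } else if (!is.null(cfgdoc$simulate) || isTRUE(cfgdoc$simulate)) {
    sim_args <- cfgdoc$simulate
    if (!is.list(sim_args)) sim_args <- list()
    sim_args$panel <- method$panel
    sim_args$srm <- method$srm
    if (is.null(sim_args$seed)) sim_args$seed <- seed
    cfg <- do.call(sim_config, sim_args)
    records <- make_validation_batch(cfg)
  } else {
    stop("config stage [input]: give 'measurements' or a 'simulate' block")
  }
  c_ref <- if (!is.null(cfgdoc$c_ref_qc)) cfgdoc$c_ref_qc else 5
  report <- tryCatch(validate_method(records, method, c_ref_qc = c_ref,
                                     seed = seed),
                     error = function(e) stop("config stage [validate]: ",
                                              conditionMessage(e)))
  if (!is.null(cfgdoc$out_dir)) write_report(report, resolve(cfgdoc$out_dir))
  invisible(report)
}
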