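#' Default per-analyte simulation parameters
#'
#' Response factors, matrix effects and process recoveries for the standard
#' panel, read from the packaged defaults table (values chosen to mirror the
#' magnitudes reported for spiked chub homogenate batches). Analytes absent
#' from the table fall back to a response factor of 1, no matrix effect and
#' 100% recovery.
#'
#' @param panel an [analyte_panel()].
#' @return data frame with `name`, `rrf_true`, `me_true_pct`,
#'   `recovery_true_pct`, one row per panel row.
#' @export
default_sim_parameters <- function(panel) {
  path <- system.file("extdata", "sim_defaults.csv", package = "halovalid")
  defaults <- utils::read.csv(path, stringsAsFactors = FALSE)
  i <- match(panel$name, defaults$name)
  out <- data.frame(name = panel$name,
                    rrf_true = ifelse(is.na(i), 1, defaults$rrf_true[i]),
                    me_true_pct = ifelse(is.na(i), 0, defaults$me_true_pct[i]),
                    recovery_true_pct = ifelse(is.na(i), 100,
                                               defaults$recovery_true_pct[i]),
                    stringsAsFactors = FALSE)
  out$recovery_true_pct[panel$role == "internal_standard"] <- 100
  out
}

#' Configuration for the synthetic peak-area batch generator
#'
#' Defines the true data-generating process behind a validation batch:
#' per-analyte response factors, signed matrix effects and process
#' recoveries, the replicate coefficient of variation, lipid-dependent
#' signal suppression, and the batch plan (which experiments, how many
#' replicates). Defaults reproduce the study design of a within-laboratory
#' validation on chub homogenate: a 7-level matrix-matched calibration
#' (0.1-60 ug/kg), recovery at 1/5/15/30/60 ug/kg with n = 5, ten limit
#' replicates at 0.1 ug/kg, QC samples at 5 ug/kg (10 intra-day, 4 x 4
#' inter-day, a 24-point QC chart), five matrix-effect replicate pairs at
#' 5 ug/kg, and triplicate SRM-like analyses.
#'
#' @param panel an [analyte_panel()]; internal standards must carry
#'   `is_conc`.
#' @param params per-analyte parameter data frame as returned by
#'   [default_sim_parameters()]; may be edited before the call.
#' @param noise_cv_pct replicate coefficient of variation of the recovered
#'   analyte amount, percent (default 8, the magnitude of typical QC-chart
#'   RSDs for this kind of method).
#' @param instrument_cv_pct additional per-peak multiplicative noise,
#'   percent (default 0; preparation noise dominates replicate variation).
#' @param lipid_suppression_coeff exponential signal attenuation per percent
#'   lipid, applied equally to analytes and internal standards (default
#'   0.04: a 16%-lipid salmon extract shows roughly 60% of the signal of a
#'   3%-lipid perch extract).
#' @param lipid_ref_pct reference lipid content (percent) at which the lipid
#'   term is unity. Defaults to the matrix-effect evaluation matrix
#'   (`plan$qc_lipid_pct`), so that `me_true_pct` is exactly the matrix
#'   effect a matrix-versus-solvent comparison at that lipid content
#'   measures; lipid suppression then models the additional attenuation of
#'   fattier samples relative to that matrix.
#' @param base_scale peak-area counts per (ug/kg x unit response factor).
#' @param background_area mean blank-level background area, counts
#'   (default 0).
#' @param seed integer seed; every draw in [make_validation_batch()] flows
#'   from it.
#' @param plan named list overriding any of the default batch-plan entries
#'   (see Details in the package vignette): `calibration_levels`, `blanks`,
#'   `solvent_levels`, `me_level`, `me_reps`, `recovery_levels`,
#'   `recovery_reps`, `loq_level`, `loq_reps`, `qc_level`, `qc_intra_reps`,
#'   `qc_inter_days`, `qc_inter_reps`, `qc_chart_n`, `srm_reps`,
#'   `addition_conc`, `lipid_pct`, `moisture_pct`, `srm_lipid_pct`.
#' @param srm optional data frame of certified values (`analyte`,
#'   `certified_conc`); when present, SRM-like replicates are generated at
#'   the certified concentrations.
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(panel, params = default_sim_parameters(panel),
                       noise_cv_pct = 8, instrument_cv_pct = 0,
                       lipid_suppression_coeff = 0.04, lipid_ref_pct = NULL,
                       base_scale = 1e4, background_area = 0, seed = 1L,
                       plan = list(), srm = NULL) {
  stopifnot(inherits(panel, "analyte_panel"))
  stopifnot(noise_cv_pct >= 0, instrument_cv_pct >= 0, base_scale > 0)
  if (any(params$recovery_true_pct <= 0 | params$recovery_true_pct > 150))
    stop("recovery_true_pct must be in (0, 150]")
  if (!all(panel$name %in% params$name))
    stop("params must cover every panel analyte")
  is_rows <- panel$role == "internal_standard"
  if (any(is.na(panel$is_conc[is_rows])))
    stop("internal standards need is_conc for simulation")
  default_plan <- list(
    calibration_levels = c(0.1, 0.5, 1, 5, 15, 30, 60),
    blanks = 3L,
    solvent_levels = c(0.1, 0.5, 1, 5, 15, 30, 60),
    me_level = 5, me_reps = 5L,
    recovery_levels = c(1, 5, 15, 30, 60), recovery_reps = 5L,
    loq_level = 0.1, loq_reps = 10L,
    qc_level = 5, qc_intra_reps = 10L,
    qc_inter_days = 4L, qc_inter_reps = 4L,
    qc_chart_n = 24L,
    srm_reps = 3L,
    addition_conc = 10,
    lipid_pct = 1.9, moisture_pct = 80,
    qc_lipid_pct = 5.2, qc_moisture_pct = 75,
    srm_lipid_pct = 10.2, srm_moisture_pct = 71.4
  )
  unknown_plan <- setdiff(names(plan), names(default_plan))
  if (length(unknown_plan))
    stop("unknown plan entries: ", paste(unknown_plan, collapse = ", "))
  default_plan[names(plan)] <- plan
  if (is.null(lipid_ref_pct)) lipid_ref_pct <- default_plan$qc_lipid_pct
  structure(list(panel = panel, params = params,
                 noise_cv_pct = noise_cv_pct,
                 instrument_cv_pct = instrument_cv_pct,
                 lipid_suppression_coeff = lipid_suppression_coeff,
                 lipid_ref_pct = lipid_ref_pct,
                 base_scale = base_scale, background_area = background_area,
                 seed = as.integer(seed), plan = default_plan, srm = srm),
            class = "sim_config")
}

# truncated multiplicative noise factor: 1 + eps, eps ~ N(0, cv/100), > 0
noise_factor <- function(n, cv_pct) {
  if (cv_pct == 0) return(rep(1, n))
  pmax(1 + stats::rnorm(n, 0, cv_pct / 100), .Machine$double.eps)
}

sim_param <- function(cfg, analyte, what) {
  i <- match(analyte, cfg$params$name)
  if (any(is.na(i))) stop("analyte not in simulation parameters: ",
                          paste(analyte[is.na(i)], collapse = ", "))
  cfg$params[[what]][i]
}

#' Simulate a single peak area
#'
#' One draw from the generator's area model:
#' `area = base_scale * rrf * (conc * recovery/100 + addition_conc) *
#' (1 + ME/100) * exp(-k_lipid * (lipid_pct - lipid_ref_pct)) * noise`, with
#' multiplicative noise truncated above zero. Matrix effect and lipid
#' suppression apply only to matrix analyses (`in_matrix = TRUE`); internal
#' standards are always simulated with 100% recovery. Uses the current RNG state, so seed the
#' session (or call through [make_validation_batch()]) for reproducibility.
#'
#' @param conc analyte concentration in the sample (ug/kg, >= 0).
#' @param cfg a [sim_config()].
#' @param analyte analyte name (vectorised; recycled against `conc`).
#' @param lipid_pct sample lipid content, percent.
#' @param in_matrix logical: matrix analysis (default) or neat solvent.
#' @param addition_conc standard-addition amount present in the extract
#'   (ug/kg, fully recovered; default 0).
#' @param prep_factor optional fixed preparation-noise factor(s); when
#'   supplied, the stochastic noise on the recovered amount is replaced by
#'   this factor (used by the batch generator to share one preparation draw
#'   between the paired unknown and standard-addition analyses).
#' @return peak area(s), counts.
#' @export
simulate_area <- function(conc, cfg, analyte, lipid_pct = 0,
                          in_matrix = TRUE, addition_conc = 0,
                          prep_factor = NULL) {
  stopifnot(all(conc >= 0))
  n <- max(length(conc), length(analyte))
  conc <- rep_len(conc, n); analyte <- rep_len(analyte, n)
  lipid_pct <- rep_len(lipid_pct, n)
  addition_conc <- rep_len(addition_conc, n)
  in_matrix <- rep_len(in_matrix, n)
  rrf <- sim_param(cfg, analyte, "rrf_true")
  rec <- sim_param(cfg, analyte, "recovery_true_pct") / 100
  me <- sim_param(cfg, analyte, "me_true_pct") / 100
  if (is.null(prep_factor)) prep_factor <- noise_factor(n, cfg$noise_cv_pct)
  prep_factor <- rep_len(prep_factor, n)
  amount <- conc * rec * prep_factor + addition_conc
  me_f <- ifelse(in_matrix, 1 + me, 1)
  lipid_f <- ifelse(in_matrix,
                    exp(-cfg$lipid_suppression_coeff *
                          (lipid_pct - cfg$lipid_ref_pct)), 1)
  area <- cfg$base_scale * rrf * amount * me_f * lipid_f
  area <- area * noise_factor(n, cfg$instrument_cv_pct)
  area + cfg$background_area
}

# one injection: rows for every panel compound, given per-analyte sample concs
injection_rows <- function(cfg, batch_id, run_index, sample_type, conc_by_name,
                           lipid_pct, moisture_pct, in_matrix = TRUE,
                           addition_by_name = NULL, prep_by_name = NULL,
                           recovered = TRUE) {
  panel <- cfg$panel
  nm <- panel$name
  conc <- conc_by_name[nm]
  conc[panel$role == "internal_standard"] <-
    panel$is_conc[panel$role == "internal_standard"]
  addition <- if (is.null(addition_by_name)) rep(0, length(nm))
              else ifelse(is.na(addition_by_name[nm]), 0, addition_by_name[nm])
  prep <- if (is.null(prep_by_name)) NULL else {
    p <- prep_by_name[nm]
    p[is.na(p)] <- 1  # internal standards / untracked compounds: no prep noise
    p
  }
  eff_conc <- conc
  if (!recovered) {
    # post-extraction spike (matrix-matched standard): no process recovery
    rec <- sim_param(cfg, nm, "recovery_true_pct") / 100
    eff_conc <- conc / ifelse(panel$role == "internal_standard", 1, rec)
  }
  area <- simulate_area(eff_conc, cfg, nm, lipid_pct = lipid_pct,
                        in_matrix = in_matrix, addition_conc = addition,
                        prep_factor = prep)
  data.frame(analyte = nm, batch_id = batch_id, run_index = run_index,
             sample_type = sample_type,
             spike_conc = unname(conc),
             addition_conc = ifelse(addition > 0, addition, NA_real_),
             peak_area = unname(area),
             lipid_pct = lipid_pct, moisture_pct = moisture_pct,
             stringsAsFactors = FALSE)
}

#' Generate a full synthetic validation batch
#'
#' Emits, as one long measurement table, every experiment of the default
#' validation design: blanks, matrix-matched and solvent calibration
#' standards, matrix-effect replicate pairs, recovery replicates at five
#' levels, limit replicates, intra-day / inter-day / QC-chart quality-control
#' series and SRM-like replicates, each quantifiable by single-point standard
#' addition (every spiked replicate is paired with a standard-addition
#' analysis sharing its `batch_id`). All randomness flows from `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return data frame of measurement records (see [read_measurements()]).
#' @export
make_validation_batch <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  panel <- cfg$panel
  plan <- cfg$plan
  targets <- panel$name[panel$role == "analyte"]
  zero <- stats::setNames(rep(0, nrow(panel)), panel$name)
  out <- list()
  add_vec <- stats::setNames(rep(NA_real_, nrow(panel)), panel$name)
  add_vec[targets] <- plan$addition_conc

  emit <- function(rows) out[[length(out) + 1L]] <<- rows

  # paired unknown + standard-addition analyses of one prepared sample
  sa_pair <- function(batch_id, sample_type, conc_named, lipid, moist) {
    prep <- stats::setNames(rep(1, nrow(panel)), panel$name)
    prep[targets] <- noise_factor(length(targets), cfg$noise_cv_pct)
    emit(injection_rows(cfg, batch_id, 1L, sample_type, conc_named,
                        lipid, moist, prep_by_name = prep))
    emit(injection_rows(cfg, batch_id, 2L, "standard_addition", conc_named,
                        lipid, moist, addition_by_name = add_vec,
                        prep_by_name = prep))
  }

  spike_all <- function(level) {
    v <- zero; v[targets] <- level; v
  }

  # blanks
  for (b in seq_len(plan$blanks))
    emit(injection_rows(cfg, sprintf("blank_b%d", b), 1L, "blank", zero,
                        plan$lipid_pct, plan$moisture_pct))
  # matrix-matched calibration (post-extraction spikes: recovery not incurred)
  for (j in seq_along(plan$calibration_levels))
    emit(injection_rows(cfg, sprintf("cal_L%d", j), 1L,
                        "matrix_matched_standard",
                        spike_all(plan$calibration_levels[j]),
                        plan$lipid_pct, plan$moisture_pct, recovered = FALSE))
  # solvent standards
  for (j in seq_along(plan$solvent_levels))
    emit(injection_rows(cfg, sprintf("solv_L%d", j), 1L, "solvent_standard",
                        spike_all(plan$solvent_levels[j]), 0, NA_real_,
                        in_matrix = FALSE, recovered = FALSE))
  # matrix-effect replicate pairs at one level
  for (r in seq_len(plan$me_reps)) {
    emit(injection_rows(cfg, sprintf("me_mm_r%d", r), 1L,
                        "matrix_matched_standard", spike_all(plan$me_level),
                        plan$qc_lipid_pct, plan$qc_moisture_pct,
                        recovered = FALSE))
    emit(injection_rows(cfg, sprintf("me_solv_r%d", r), 1L,
                        "solvent_standard", spike_all(plan$me_level),
                        0, NA_real_, in_matrix = FALSE, recovered = FALSE))
  }
  # recovery replicates
  for (j in seq_along(plan$recovery_levels))
    for (r in seq_len(plan$recovery_reps))
      sa_pair(sprintf("rec%g_r%d", plan$recovery_levels[j], r),
              "spiked_sample", spike_all(plan$recovery_levels[j]),
              plan$lipid_pct, plan$moisture_pct)
  # limit replicates
  for (r in seq_len(plan$loq_reps))
    sa_pair(sprintf("loq_r%02d", r), "spiked_sample",
            spike_all(plan$loq_level), plan$lipid_pct, plan$moisture_pct)
  # QC series
  for (r in seq_len(plan$qc_intra_reps))
    sa_pair(sprintf("qc_intra_r%02d", r), "qc", spike_all(plan$qc_level),
            plan$qc_lipid_pct, plan$qc_moisture_pct)
  for (d in seq_len(plan$qc_inter_days))
    for (r in seq_len(plan$qc_inter_reps))
      sa_pair(sprintf("qc_inter_d%d_r%d", d, r), "qc",
              spike_all(plan$qc_level), plan$qc_lipid_pct,
              plan$qc_moisture_pct)
  for (i in seq_len(plan$qc_chart_n))
    sa_pair(sprintf("qc_chart_%02d", i), "qc", spike_all(plan$qc_level),
            plan$qc_lipid_pct, plan$qc_moisture_pct)
  # SRM-like replicates at the certified concentrations
  if (!is.null(cfg$srm) && nrow(cfg$srm)) {
    conc <- zero
    conc[cfg$srm$analyte] <- cfg$srm$certified_conc
    for (r in seq_len(plan$srm_reps))
      sa_pair(sprintf("srm_r%d", r), "srm", conc,
              plan$srm_lipid_pct, plan$srm_moisture_pct)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
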