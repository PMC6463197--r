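#' Within-lab reproducibility from a quality-control chart
#'
#' The random-error component of the top-down budget: the sample RSD (in
#' percent) of at least 20 independent consecutive QC-chart determinations.
#'
#' @param values determined QC concentrations (ug/kg), finite and > 0.
#' @return RSD in percent.
#' @export
u_repro_from_qc <- function(values) {
  if (length(values) < 2) stop("need at least 2 QC values")
  if (!all(is.finite(values)) || any(values <= 0))
    stop("QC values must be finite and > 0")
  if (length(values) < 20)
    warning("fewer than 20 QC-chart values; reproducibility estimate is weak")
  rsd_pct(values)
}

#' Systematic components: relative bias and uncertainty of the mean
#'
#' From n replicate QC determinations against the reference (spiked)
#' concentration c_ref: B_r = (mean - c_ref)/c_ref x 100 (signed),
#' u_cm = SD/sqrt(n) (standard uncertainty of the mean), and
#' u_r,cm = u_cm/c_ref x 100.
#'
#' @param qc_values replicate determined concentrations (ug/kg).
#' @param c_ref reference concentration (ug/kg, > 0).
#' @return named vector `c(b_r_pct, u_r_cm_pct, u_cm, n)`.
#' @export
bias_components <- function(qc_values, c_ref) {
  if (c_ref <= 0) stop("c_ref must be > 0")
  n <- length(qc_values)
  if (n < 2) stop("need at least 2 replicate QC values")
  if (n < 10) warning("fewer than 10 replicates for the bias components")
  b_r <- (mean(qc_values) - c_ref) / c_ref * 100
  u_cm <- stats::sd(qc_values) / sqrt(n)
  c(b_r_pct = b_r, u_r_cm_pct = u_cm / c_ref * 100, u_cm = u_cm, n = n)
}

#' Standard-purity uncertainty from a certificate
#'
#' Divides the expanded relative uncertainty stated on the supplier's
#' certificate by its coverage factor (k = 2 by default).
#'
#' @param U_r_ref_pct expanded relative uncertainty, percent (>= 0).
#' @param k coverage factor (> 0, default 2).
#' @return standard relative uncertainty, percent.
#' @export
u_ref_from_certificate <- function(U_r_ref_pct, k = 2) {
  if (any(k <= 0)) stop("coverage factor must be > 0")
  if (any(U_r_ref_pct < 0)) stop("expanded uncertainty must be >= 0")
  U_r_ref_pct / k
}

#' Standard-purity uncertainty from the stated purity
#'
#' Rectangular-distribution estimate used when no certificate uncertainty is
#' available: u_r,ref = 0.5 x (100 - y) / sqrt(3), y the purity in percent.
#'
#' @param purity_pct stated purity, percent, in (0, 100].
#' @return standard relative uncertainty, percent.
#' @export
u_ref_from_purity <- function(purity_pct) {
  if (any(purity_pct <= 0 | purity_pct > 100))
    stop("purity must be in (0, 100]")
  0.5 * (100 - purity_pct) / sqrt(3)
}

#' Standard-purity uncertainty for a panel analyte
#'
#' Certificate-based when the panel carries `cert_expanded_u_pct` (divided by
#' `cert_coverage_k`), otherwise the rectangular-distribution estimate from
#' the purity.
#'
#' @param panel an [analyte_panel()].
#' @param analyte analyte name.
#' @return standard relative uncertainty, percent.
#' @export
u_ref_for_analyte <- function(panel, analyte) {
  i <- match(analyte, panel$name)
  if (is.na(i)) stop("unknown analyte: ", analyte)
  u_cert <- panel$cert_expanded_u_pct[i]
  if (!is.na(u_cert)) u_ref_from_certificate(u_cert, panel$cert_coverage_k[i])
  else u_ref_from_purity(panel$purity_pct[i])
}

#' Combine the four relative uncertainty components
#'
#' Error-propagation (root-sum-of-squares) combination of the within-lab
#' reproducibility, the relative bias (signed, entered squared and
#' uncorrected), the uncertainty of the systematic error and the
#' standard-purity uncertainty, followed by expansion with the coverage
#' factor (default k = 2, ~95% confidence).
#'
#' @param u_repro within-lab reproducibility, percent.
#' @param b_r relative bias, percent (signed).
#' @param u_cm relative uncertainty of the systematic error, percent.
#' @param u_ref standard-purity relative uncertainty, percent.
#' @param k coverage factor for expansion (default 2).
#' @return named vector `c(u_r_tot_pct, U_r_tot_pct)`; vectorised over the
#'   components.
#' @export
combine_budget <- function(u_repro, b_r, u_cm, u_ref, k = 2) {
  if (any(!is.finite(c(u_repro, b_r, u_cm, u_ref))))
    stop("all components must be finite")
  if (any(u_repro < 0) || any(u_cm < 0) || any(u_ref < 0))
    stop("components other than the bias must be >= 0")
  u_tot <- unname(sqrt(u_repro^2 + b_r^2 + u_cm^2 + u_ref^2))
  if (length(u_tot) == 1L) c(u_r_tot_pct = u_tot, U_r_tot_pct = k * u_tot)
  else cbind(u_r_tot_pct = u_tot, U_r_tot_pct = k * u_tot)
}

#' Assemble a top-down uncertainty budget for one analyte
#'
#' Computes the four components from a QC chart (reproducibility), a
#' repeatability QC series against its reference concentration (bias terms)
#' and the standard-purity information, and combines them.
#'
#' @param qc_chart QC-chart determined concentrations (>= 20 recommended).
#' @param bias_values repeatability QC determinations (>= 10 recommended).
#' @param c_ref reference concentration of the QC samples (ug/kg).
#' @param u_ref standard-purity relative uncertainty, percent (see
#'   [u_ref_for_analyte()]).
#' @param analyte optional name.
#' @param k coverage factor (default 2).
#' @return list of class `"uncertainty_budget"` with the four components,
#'   `u_r_tot_pct`, `U_r_tot_pct`, `c_ref`, `n_qc`, `n_bias`.
#' @export
uncertainty_budget <- function(qc_chart, bias_values, c_ref, u_ref,
                               analyte = NA_character_, k = 2) {
  u_repro <- u_repro_from_qc(qc_chart)
  bias <- bias_components(bias_values, c_ref)
  tot <- combine_budget(u_repro, bias["b_r_pct"], bias["u_r_cm_pct"], u_ref, k)
  structure(list(analyte = analyte,
                 u_r_repro_pct = u_repro,
                 b_r_pct = unname(bias["b_r_pct"]),
                 u_r_cm_pct = unname(bias["u_r_cm_pct"]),
                 u_r_ref_pct = u_ref,
                 u_r_tot_pct = unname(tot["u_r_tot_pct"]),
                 U_r_tot_pct = unname(tot["U_r_tot_pct"]),
                 c_ref = c_ref, k = k,
                 n_qc = length(qc_chart), n_bias = unname(bias["n"])),
            class = "uncertainty_budget")
}

#' @export
print.uncertainty_budget <- function(x, ...) {
  cat(sprintf("Top-down uncertainty budget%s (c_ref %.3g ug/kg):\n",
              if (!is.na(x$analyte)) paste0(" for ", x$analyte) else "", x$c_ref))
  cat(sprintf("  u_r,repro %.3g%%  B_r %+.3g%%  u_r,cm %.3g%%  u_r,ref %.3g%%\n",
              x$u_r_repro_pct, x$b_r_pct, x$u_r_cm_pct, x$u_r_ref_pct))
  cat(sprintf("  combined u_r,tot %.3g%%, expanded U_r,tot %.3g%% (k = %g)\n",
              x$u_r_tot_pct, x$U_r_tot_pct, x$k))
  invisible(x)
}

#' Turn a list of uncertainty budgets into a table
#'
#' @param budgets list of [uncertainty_budget()] objects.
#' @return data frame with one row per analyte and the six budget columns.
#' @export
budget_table <- function(budgets) {
  do.call(rbind, lapply(budgets, function(b)
    data.frame(analyte = b$analyte, u_r_repro_pct = b$u_r_repro_pct,
               b_r_pct = b$b_r_pct, u_r_cm_pct = b$u_r_cm_pct,
               u_r_ref_pct = b$u_r_ref_pct, u_r_tot_pct = b$u_r_tot_pct,
               U_r_tot_pct = b$U_r_tot_pct, n_qc = b$n_qc, n_bias = b$n_bias,
               stringsAsFactors = FALSE)))
}
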