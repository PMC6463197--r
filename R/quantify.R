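#' Blank-corrected internal-standard response ratio
#'
#' The basic quantity of ratio-based MRM quantification: the analyte peak
#' area, corrected for the procedural blank, divided by the peak area of the
#' assigned internal standard from the same injection.
#'
#' @param area_analyte analyte peak area (counts).
#' @param area_is internal-standard peak area (counts, > 0).
#' @param area_blank blank peak area to subtract (counts, default 0).
#' @return numeric ratio; negative values (blank exceeding the signal) are
#'   returned with a warning.
#' @export
response_ratio <- function(area_analyte, area_is, area_blank = 0) {
  if (any(is.na(area_is)) || any(area_is == 0))
    stop("undefined response ratio: internal-standard area is zero")
  if (any(area_blank < 0)) stop("blank area must be >= 0")
  r <- (area_analyte - area_blank) / area_is
  if (any(r < 0))
    warning("blank exceeds analyte signal; negative response ratio")
  r
}

#' Fit a matrix-matched calibration line
#'
#' Ordinary least-squares regression of the blank-corrected response ratio on
#' the spiked concentration, plus the relative-response-factor (RRF) view of
#' linearity: at each level, RRF = response ratio x (c_IS / c), i.e. the
#' blank-corrected analyte/IS area ratio normalised by the analyte/IS
#' concentration ratio. A constant RRF across levels (RSD near zero) is the
#' ratio-scale statement of proportional response.
#'
#' @param conc spiked concentrations (ug/kg), at least 3 distinct positive
#'   levels.
#' @param ratio blank-corrected response ratios, same length.
#' @param is_conc internal-standard concentration (ug/kg) used to normalise
#'   the RRF.
#' @param analyte optional analyte name carried into the result.
#' @param weights optional regression weights (default unweighted).
#' @return object of class `"calibration"`: the `lm` fit plus `r.squared`,
#'   `rrf` (per-level RRFs), `rrf_mean`, `rrf_rsd_pct`, `levels` and
#'   `linear_range`.
#' @export
fit_calibration <- function(conc, ratio, is_conc, analyte = NA_character_,
                            weights = NULL) {
  stopifnot(length(conc) == length(ratio), is_conc > 0)
  if (any(conc <= 0)) stop("calibration concentrations must be > 0")
  if (length(unique(conc)) < 3)
    stop("need at least 3 distinct concentration levels")
  fit <- if (is.null(weights)) stats::lm(ratio ~ conc)
         else stats::lm(ratio ~ conc, weights = weights)
  r2 <- summary(fit)$r.squared
  rrf <- ratio * (is_conc / conc)
  out <- list(
    analyte = analyte,
    fit = fit,
    r.squared = r2,
    rrf = rrf,
    rrf_mean = mean(rrf),
    rrf_rsd_pct = rsd_pct(rrf),
    is_conc = is_conc,
    levels = data.frame(conc = conc, ratio = ratio),
    linear_range = paste0(format(min(conc), trim = TRUE), "-",
                          format(max(conc), trim = TRUE))
  )
  class(out) <- "calibration"
  out
}

#' @export
print.calibration <- function(x, ...) {
  cat("Matrix-matched calibration",
      if (!is.na(x$analyte)) paste0("for ", x$analyte), "\n")
  cat(sprintf("  levels: %d (%s ug/kg)\n", nrow(x$levels), x$linear_range))
  cat(sprintf("  slope %.5g, intercept %.5g, R^2 = %.6f\n",
              stats::coef(x$fit)[2], stats::coef(x$fit)[1], x$r.squared))
  cat(sprintf("  RRF mean %.3g, RSD %.2f%%\n", x$rrf_mean, x$rrf_rsd_pct))
  invisible(x)
}

#' @export
coef.calibration <- function(object, ...) stats::coef(object$fit)

#' @export
residuals.calibration <- function(object, ...) stats::residuals(object$fit)

#' Predict concentration from a response ratio, or ratio from concentration
#'
#' @param object a [fit_calibration()] result.
#' @param ratio response ratios to invert into concentrations (default
#'   behaviour, solvent- or matrix-matched-calibration quantification).
#' @param conc concentrations at which to evaluate the fitted line instead.
#' @param ... unused.
#' @return numeric vector.
#' @export
predict.calibration <- function(object, ratio = NULL, conc = NULL, ...) {
  b <- stats::coef(object$fit)
  if (!is.null(conc)) return(unname(b[1] + b[2] * conc))
  if (is.null(ratio)) stop("supply 'ratio' or 'conc'")
  if (b[2] == 0) stop("zero calibration slope")
  unname((ratio - b[1]) / b[2])
}

#' @export
plot.calibration <- function(x, ...) {
  plot(x$levels$conc, x$levels$ratio,
       xlab = "concentration (ug/kg)", ylab = "response ratio",
       main = if (!is.na(x$analyte)) x$analyte else "calibration", ...)
  graphics::abline(x$fit)
  invisible(x)
}

#' Single-point standard-addition quantification
#'
#' One analysis of the unknown and one of the unknown plus a known addition:
#' c = c_ad * r_u / (r_a - r_u), where r_u = A_i/A_IS from the unknown and
#' r_a = A_(i+ad)/A_ISsa from the addition analysis. Because any proportional
#' signal suppression or enhancement scales both ratios equally, the estimate
#' is immune to matrix effects by construction.
#'
#' @param c_ad added concentration (ug/kg, > 0).
#' @param ratio_unknown response ratio of the unknown analysis.
#' @param ratio_added response ratio of the standard-addition analysis.
#' @return estimated concentration (ug/kg), vectorised.
#' @export
standard_addition_conc <- function(c_ad, ratio_unknown, ratio_added) {
  if (any(c_ad <= 0)) stop("addition concentration must be > 0")
  denom <- ratio_added - ratio_unknown
  if (any(denom <= 0))
    stop("non-quantifiable: standard addition did not increase the response")
  c_ad * ratio_unknown / denom
}

#' Matrix-effect evaluation
#'
#' Signed percent enhancement (positive) or suppression (negative) of the
#' chromatographic response in a matrix-matched extract relative to a neat
#' solvent standard. The default convention places the matrix-matched area in
#' the denominator: ME% = (matrix - solvent) / matrix * 100; the conventional
#' solvent-denominator form is available via `convention = "conventional"`.
#' Replicates are paired by order when the two lists have equal length;
#' otherwise means are compared ("unpaired mode", with the per-replicate RSD
#' taken from the matrix areas against the solvent mean).
#'
#' @param areas_matrix peak areas in matrix-matched standards (counts).
#' @param areas_solvent peak areas in solvent standards (counts).
#' @param convention `"paper"` (matrix denominator, default) or
#'   `"conventional"` (solvent denominator).
#' @param analyte optional name carried into the result.
#' @return list of class `"matrix_effect"`: `me_pct`, `rsd_pct`, `n`,
#'   `convention`, `paired`.
#' @export
matrix_effect <- function(areas_matrix, areas_solvent,
                          convention = c("paper", "conventional"),
                          analyte = NA_character_) {
  convention <- match.arg(convention)
  if (!length(areas_matrix) || !length(areas_solvent))
    stop("both replicate lists must be non-empty")
  if (any(areas_matrix == 0) && convention == "paper")
    stop("matrix-matched area of zero: matrix effect undefined")
  if (any(areas_solvent == 0) && convention == "conventional")
    stop("solvent area of zero: matrix effect undefined")
  me_of <- function(m, s) {
    if (convention == "paper") (m - s) / m * 100 else (m - s) / s * 100
  }
  paired <- length(areas_matrix) == length(areas_solvent)
  if (paired) {
    per_rep <- me_of(areas_matrix, areas_solvent)
  } else {
    per_rep <- me_of(areas_matrix, mean(areas_solvent))
  }
  out <- list(analyte = analyte,
              me_pct = if (paired) mean(per_rep)
                       else me_of(mean(areas_matrix), mean(areas_solvent)),
              rsd_pct = if (length(per_rep) >= 2) stats::sd(per_rep) else NA_real_,
              n = length(per_rep),
              convention = convention,
              paired = paired)
  class(out) <- "matrix_effect"
  out
}

#' @export
print.matrix_effect <- function(x, ...) {
  cat(sprintf("Matrix effect%s: %+.2f%% (%s of per-replicate ME %.2g, n = %d, %s, %s)\n",
              if (!is.na(x$analyte)) paste0(" for ", x$analyte) else "",
              x$me_pct, "SD", x$rsd_pct, x$n,
              if (x$paired) "paired" else "unpaired mode", x$convention))
  invisible(x)
}

# sample relative standard deviation in percent (n-1 denominator)
rsd_pct <- function(x) {
  if (length(x) < 2) stop("need at least 2 values for an RSD")
  m <- mean(x)
  if (m == 0) stop("RSD undefined: mean is zero")
  stats::sd(x) / abs(m) * 100
}
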