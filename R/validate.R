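#' Detection and quantification limits from replicate spikes
#'
#' LOD and LOQ are defined as 3 and 10 times the sample standard deviation of
#' replicate determinations of a low-level spike (typically n = 10 at
#' 0.1 ug/kg), so LOQ = (10/3) x LOD exactly.
#'
#' @param determined determined concentrations (ug/kg).
#' @param spike_level spike concentration of the replicates (ug/kg).
#' @param analyte optional name.
#' @return list of class `"limit_result"`: `sd_at_spike`, `lod`, `loq`,
#'   `spike_level`, `n`.
#' @export
limits_from_replicates <- function(determined, spike_level,
                                   analyte = NA_character_) {
  n <- length(determined)
  if (n < 2) stop("need at least 2 replicate determinations")
  if (n < 6) warning("fewer than 6 replicates: limits will be unstable")
  else if (n < 10) warning("fewer than 10 replicates for limit estimation")
  s <- stats::sd(determined)
  structure(list(analyte = analyte, sd_at_spike = s, lod = 3 * s,
                 loq = 10 * s, spike_level = spike_level, n = n),
            class = "limit_result")
}

#' @export
print.limit_result <- function(x, ...) {
  cat(sprintf("LOD %.3g, LOQ %.3g ug/kg (SD %.3g at %.3g ug/kg, n = %d)\n",
              x$lod, x$loq, x$sd_at_spike, x$spike_level, x$n))
  invisible(x)
}

#' Recovery of a spiked level
#'
#' Mean determined concentration over the spike level, in percent, with the
#' replicate RSD and the SANTE/11813/2017 acceptability rule: consistent
#' recoveries outside 70-120% are tolerated provided they stay within
#' 30-140% with RSD <= 20%.
#'
#' @param determined determined concentrations (ug/kg).
#' @param spike_level spike concentration (ug/kg, > 0).
#' @param analyte optional name.
#' @return list of class `"recovery_result"`: `recovery_pct`, `rsd_pct`, `n`,
#'   `spike_level`, `acceptable`.
#' @export
recovery <- function(determined, spike_level, analyte = NA_character_) {
  if (!length(determined)) stop("no determined values")
  if (spike_level <= 0) stop("spike_level must be > 0")
  rec <- mean(determined) / spike_level * 100
  rsd <- if (length(determined) >= 2) rsd_pct(determined) else NA_real_
  acceptable <- rec >= 30 && rec <= 140 && (is.na(rsd) || rsd <= 20)
  structure(list(analyte = analyte, spike_level = spike_level,
                 recovery_pct = rec, rsd_pct = rsd, n = length(determined),
                 acceptable = acceptable),
            class = "recovery_result")
}

#' @export
print.recovery_result <- function(x, ...) {
  cat(sprintf("Recovery %.1f%% (RSD %.1f%%, n = %d) at %.3g ug/kg [%s]\n",
              x$recovery_pct, x$rsd_pct, x$n, x$spike_level,
              if (x$acceptable) "acceptable" else "not acceptable"))
  invisible(x)
}

#' Intra-day precision
#'
#' Sample RSD (in percent) of replicate QC determinations within one day.
#'
#' @param determined determined concentrations (ug/kg), n >= 2.
#' @return RSD in percent.
#' @export
precision_intra <- function(determined) rsd_pct(determined)

#' Inter-day precision
#'
#' Default: total RSD over all day-by-replicate values pooled together.
#' `method = "anova"` instead decomposes the one-way (day) design and returns
#' the intermediate-precision RSD sqrt(s_within^2 + s_between^2)/mean x 100,
#' with the between-day variance truncated at zero.
#'
#' @param by_day list of numeric vectors, one per day (>= 2 days, >= 2
#'   replicates each).
#' @param method `"pooled"` (default) or `"anova"`.
#' @return RSD in percent.
#' @export
precision_inter <- function(by_day, method = c("pooled", "anova")) {
  method <- match.arg(method)
  if (length(by_day) < 2) stop("need at least 2 days")
  if (any(vapply(by_day, length, 1L) == 0)) stop("empty day in QC design")
  if (method == "pooled") return(rsd_pct(unlist(by_day)))
  if (any(vapply(by_day, length, 1L) < 2)) stop("ANOVA needs >= 2 replicates per day")
  values <- unlist(by_day)
  day <- factor(rep(seq_along(by_day), vapply(by_day, length, 1L)))
  fit <- stats::aov(values ~ day)
  ms <- summary(fit)[[1]][["Mean Sq"]]
  msb <- ms[1]; msw <- ms[2]
  n0 <- mean(vapply(by_day, length, 1L))  # exact for balanced designs
  s2_between <- max((msb - msw) / n0, 0)
  sqrt(msw + s2_between) / mean(values) * 100
}

#' Trueness against a reference value
#'
#' Mean recovery R = mean/reference x 100 and signed relative bias
#' B_r = (mean - reference)/reference x 100, so R - 100 = B_r identically.
#'
#' @param mean_measured mean determined concentration (ug/kg).
#' @param reference reference concentration (ug/kg, > 0).
#' @return named vector `c(recovery_pct, rel_bias_pct)`.
#' @export
trueness <- function(mean_measured, reference) {
  if (any(reference <= 0)) stop("reference must be > 0")
  rec <- mean_measured / reference * 100
  c(recovery_pct = rec, rel_bias_pct = rec - 100)
}

#' Compare replicate determinations with a certified reference material
#'
#' Trueness of the replicate mean against the certified concentration, plus a
#' range check: when the expanded uncertainty of the determined mean is
#' supplied, the check asks whether the certified interval [c +/- U] overlaps
#' [mean +/- U_det]; otherwise whether the mean falls inside [c +/- U]
#' (boundary inclusive).
#'
#' @param determined determined concentrations (ug/kg), n >= 2, or a single
#'   mean if `determined_expanded_u` is given.
#' @param certified_conc certified concentration (ug/kg).
#' @param certified_expanded_u expanded uncertainty of the certified value
#'   (ug/kg).
#' @param determined_expanded_u optional expanded uncertainty of the
#'   determined mean (ug/kg).
#' @param analyte optional name.
#' @return list of class `"srm_result"`: `mean`, `trueness_pct`, `rsd_pct`,
#'   `in_certified_range`, `n`.
#' @export
srm_compare <- function(determined, certified_conc, certified_expanded_u,
                        determined_expanded_u = NULL,
                        analyte = NA_character_) {
  if (is.na(certified_conc) || certified_conc <= 0)
    stop("missing or invalid certified value", if (!is.na(analyte)) paste0(" for ", analyte))
  if (length(determined) < 2 && is.null(determined_expanded_u))
    stop("need n >= 2 replicates (or a mean with its expanded uncertainty)")
  m <- mean(determined)
  tr <- trueness(m, certified_conc)
  lo <- certified_conc - certified_expanded_u
  hi <- certified_conc + certified_expanded_u
  # boundary-inclusive under floating point: a mean exactly on the interval
  # edge counts as inside
  eps <- sqrt(.Machine$double.eps) * max(1, abs(hi), abs(lo))
  in_range <- if (!is.null(determined_expanded_u)) {
    (m - determined_expanded_u) <= hi + eps && (m + determined_expanded_u) >= lo - eps
  } else {
    m >= lo - eps && m <= hi + eps
  }
  structure(list(analyte = analyte, mean = m,
                 trueness_pct = unname(tr["recovery_pct"]),
                 rel_bias_pct = unname(tr["rel_bias_pct"]),
                 rsd_pct = if (length(determined) >= 2) rsd_pct(determined) else NA_real_,
                 certified_conc = certified_conc,
                 certified_expanded_u = certified_expanded_u,
                 in_certified_range = in_range,
                 n = length(determined)),
            class = "srm_result")
}

#' @export
print.srm_result <- function(x, ...) {
  cat(sprintf("SRM comparison%s: mean %.3g vs certified %.3g +/- %.2g ug/kg; trueness %.0f%% [%s]\n",
              if (!is.na(x$analyte)) paste0(" for ", x$analyte) else "",
              x$mean, x$certified_conc, x$certified_expanded_u, x$trueness_pct,
              if (x$in_certified_range) "within certified range" else "outside certified range"))
  invisible(x)
}

#' Censor reported concentrations below the LOQ
#'
#' Mirrors the reporting convention for survey tables: values below the
#' quantification limit are shown as "<LOQ" with the numeric limit attached;
#' the numeric vector and a logical censoring flag are kept alongside.
#'
#' @param values determined concentrations (ug/kg).
#' @param loq quantification limit (ug/kg).
#' @param digits significant digits for display (default 2).
#' @return data frame with `value`, `censored`, `reported` columns.
#' @export
censor_below_loq <- function(values, loq, digits = 2) {
  censored <- values < loq
  reported <- ifelse(censored, paste0("<", signif(loq, digits)),
                     as.character(signif(values, digits)))
  data.frame(value = values, censored = censored, reported = reported,
             stringsAsFactors = FALSE)
}
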