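#' Construct a validated analyte panel
#'
#' An analyte panel is the method definition: one row per compound monitored
#' by the MRM method, including the two internal standards. Each target
#' analyte names the internal standard against which its response ratios are
#' formed. Standard purities (and, where available, the expanded relative
#' uncertainty from the supplier's certificate) feed the standard-purity
#' component of the uncertainty budget.
#'
#' @param x data frame with columns `name`, `role` (`"analyte"` or
#'   `"internal_standard"`), `is_ref` (name of the assigned internal
#'   standard; empty for internal-standard rows), `rt_min`,
#'   `quant_transition`, `qual_transition` (text, e.g. `"225>190 @15V"`),
#'   `purity_pct`, and optionally `cert_expanded_u_pct`, `cert_coverage_k`
#'   and `is_conc` (spiking concentration of each internal standard, ug/kg).
#' @return the same data frame, validated and with defaults filled, of class
#'   `"analyte_panel"`.
#' @export
analyte_panel <- function(x) {
  stopifnot(is.data.frame(x))
  required <- c("name", "role", "is_ref", "purity_pct")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols))
    stop("analyte panel is missing columns: ", paste(missing_cols, collapse = ", "))
  x$name <- as.character(x$name)
  x$role <- as.character(x$role)
  x$is_ref <- as.character(x$is_ref)
  if (nrow(x) == 0L) stop("no analytes in panel")
  if (anyDuplicated(x$name))
    stop("duplicate analyte name(s): ",
         paste(unique(x$name[duplicated(x$name)]), collapse = ", "))
  if (!all(x$role %in% c("analyte", "internal_standard")))
    stop("role must be 'analyte' or 'internal_standard'")
  if (!any(x$role == "analyte")) stop("no analytes in panel")
  bad_purity <- !is.na(x$purity_pct) & (x$purity_pct <= 0 | x$purity_pct > 100)
  if (any(bad_purity))
    stop("purity_pct outside (0, 100] for: ",
         paste(x$name[bad_purity], collapse = ", "))
  if (is.null(x$cert_expanded_u_pct)) x$cert_expanded_u_pct <- NA_real_
  if (is.null(x$cert_coverage_k)) x$cert_coverage_k <- 2
  x$cert_coverage_k[is.na(x$cert_coverage_k)] <- 2
  if (is.null(x$is_conc)) x$is_conc <- NA_real_
  if (is.null(x$rt_min)) x$rt_min <- NA_real_
  if (is.null(x$quant_transition)) x$quant_transition <- NA_character_
  if (is.null(x$qual_transition)) x$qual_transition <- NA_character_
  # cross-link: every analyte row must name an existing internal-standard row
  is_names <- x$name[x$role == "internal_standard"]
  tgt <- x$role == "analyte"
  unknown <- !(x$is_ref[tgt] %in% is_names)
  if (any(unknown))
    stop("analyte(s) reference unknown internal standard: ",
         paste(x$name[tgt][unknown], collapse = ", "))
  rownames(x) <- NULL
  class(x) <- c("analyte_panel", "data.frame")
  x
}

#' @export
print.analyte_panel <- function(x, ...) {
  cat("Analyte panel:", sum(x$role == "analyte"), "analytes,",
      sum(x$role == "internal_standard"), "internal standards\n")
  print.data.frame(x[, c("name", "role", "is_ref", "rt_min", "purity_pct")], ...)
  invisible(x)
}

#' Spiking concentration of an internal standard
#'
#' @param panel an [analyte_panel()].
#' @param is_name internal-standard name.
#' @return concentration in ug/kg.
#' @export
is_concentration <- function(panel, is_name) {
  i <- match(is_name, panel$name)
  if (is.na(i) || panel$role[i] != "internal_standard")
    stop("unknown internal standard: ", is_name)
  conc <- panel$is_conc[i]
  if (is.na(conc)) stop("no spiking concentration recorded for ", is_name)
  conc
}

#' Read a method definition file
#'
#' The method definition is a YAML (or JSON) document with three blocks:
#' `analytes` (the MRM panel, see [analyte_panel()]), optional
#' `srm_certified` (certified reference-material concentrations, ug/kg, with
#' expanded uncertainties) and optional `ecoscale` (the greenness penalty
#' ledger, see [score_ledger()]).
#'
#' @param path file path.
#' @return list of class `"halo_method"` with elements `panel`
#'   (an `analyte_panel`), `srm` (data frame or `NULL`) and `ecoscale`
#'   (an `ecoscale_ledger` or `NULL`).
#' @export
read_method_definition <- function(path) {
  if (!file.exists(path)) stop("method definition not found: ", path)
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(doc$analytes) || length(doc$analytes) == 0L)
    stop("no analytes in method definition")
  to_df <- function(lst) {
    if (is.data.frame(lst)) return(lst)
    fields <- unique(unlist(lapply(lst, names)))
    out <- lapply(fields, function(f) {
      vals <- lapply(lst, function(row) if (is.null(row[[f]])) NA else row[[f]])
      unlist(vals, use.names = FALSE)
    })
    names(out) <- fields
    as.data.frame(out, stringsAsFactors = FALSE)
  }
  panel <- to_df(doc$analytes)
  if (is.null(panel$is_ref)) panel$is_ref <- ""
  panel$is_ref[is.na(panel$is_ref)] <- ""
  panel <- analyte_panel(panel)

  srm <- NULL
  if (!is.null(doc$srm_certified)) {
    srm <- to_df(doc$srm_certified)
    names(srm)[names(srm) == "certified"] <- "certified_conc"
    stopifnot(all(c("analyte", "certified_conc", "certified_expanded_u") %in% names(srm)))
    if (any(srm$certified_conc <= 0)) stop("certified_conc must be > 0")
    unknown <- !(srm$analyte %in% panel$name)
    if (any(unknown))
      stop("SRM certified value for unknown analyte: ",
           paste(srm$analyte[unknown], collapse = ", "))
  }

  eco <- NULL
  if (!is.null(doc$ecoscale)) {
    items <- to_df(doc$ecoscale)
    eco <- score_ledger(items)
  }

  structure(list(panel = panel, srm = srm, ecoscale = eco, path = path),
            class = "halo_method")
}

#' @export
print.halo_method <- function(x, ...) {
  cat("MRM method definition (", basename(x$path), ")\n", sep = "")
  cat("  analytes:           ", sum(x$panel$role == "analyte"), "\n")
  cat("  internal standards: ", sum(x$panel$role == "internal_standard"), "\n")
  cat("  SRM certified values:", if (is.null(x$srm)) 0 else nrow(x$srm), "\n")
  cat("  Eco-Scale ledger:   ", if (is.null(x$ecoscale)) "absent" else
      paste0(nrow(x$ecoscale$items), " items, score ", x$ecoscale$score), "\n")
  invisible(x)
}

# column order of the measurement-table CSV schema
measurement_columns <- function() {
  c("analyte", "batch_id", "run_index", "sample_type", "spike_conc",
    "addition_conc", "peak_area", "lipid_pct", "moisture_pct")
}

sample_types <- function() {
  c("blank", "solvent_standard", "matrix_matched_standard", "spiked_sample",
    "unknown", "standard_addition", "qc", "srm")
}

#' Read a peak-area measurement table
#'
#' Long-format delimited text, one peak area per row. Columns: `analyte`,
#' `batch_id` (identifies the prepared sample; an unknown analysis and its
#' standard-addition analysis share a `batch_id`), `run_index` (ordinal
#' injection within the batch), `sample_type`, `spike_conc` (ug/kg wet
#' weight, 0 for unspiked), `addition_conc` (ug/kg, standard-addition rows
#' only), `peak_area` (counts), and optional `lipid_pct`, `moisture_pct`.
#'
#' @param path CSV file path.
#' @param panel an [analyte_panel()] used to resolve analyte names; rows for
#'   unknown analytes are rejected with their row numbers.
#' @return data frame of measurement records.
#' @export
read_measurements <- function(path, panel) {
  if (!file.exists(path)) stop("measurement table not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_measurements(raw, panel)
}

#' Validate an in-memory measurement table
#'
#' @param records data frame with the columns of [read_measurements()].
#' @param panel an [analyte_panel()].
#' @return the validated, typed data frame.
#' @export
validate_measurements <- function(records, panel) {
  stopifnot(is.data.frame(records))
  needed <- c("analyte", "batch_id", "run_index", "sample_type",
              "spike_conc", "peak_area")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols))
    stop("measurement table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  if (is.null(records$addition_conc)) records$addition_conc <- NA_real_
  if (is.null(records$lipid_pct)) records$lipid_pct <- NA_real_
  if (is.null(records$moisture_pct)) records$moisture_pct <- NA_real_
  records$analyte <- as.character(records$analyte)
  records$batch_id <- as.character(records$batch_id)
  records$sample_type <- as.character(records$sample_type)
  for (col in c("run_index", "spike_conc", "addition_conc", "peak_area",
                "lipid_pct", "moisture_pct")) {
    v <- records[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(!is.na(v) & v != "" & is.na(vn))
      if (length(bad))
        stop("unparseable numeric '", col, "' at row(s): ",
             paste(utils::head(bad, 5), collapse = ", "))
      records[[col]] <- vn
    }
  }
  unknown <- which(!(records$analyte %in% panel$name))
  if (length(unknown))
    stop("unknown analyte(s) at row(s) ",
         paste(utils::head(unknown, 5), collapse = ", "), ": ",
         paste(unique(records$analyte[unknown]), collapse = ", "))
  bad_type <- which(!(records$sample_type %in% sample_types()))
  if (length(bad_type))
    stop("invalid sample_type at row(s): ",
         paste(utils::head(bad_type, 5), collapse = ", "))
  neg <- which(!is.na(records$peak_area) & records$peak_area < 0)
  if (length(neg))
    stop("negative peak_area at row(s): ", paste(utils::head(neg, 5), collapse = ", "))
  negs <- which(!is.na(records$spike_conc) & records$spike_conc < 0)
  if (length(negs))
    stop("negative spike_conc at row(s): ", paste(utils::head(negs, 5), collapse = ", "))
  target <- panel$role[match(records$analyte, panel$name)] == "analyte"
  sa <- records$sample_type == "standard_addition" & target
  bad_ad <- which(sa & (is.na(records$addition_conc) | records$addition_conc <= 0))
  if (length(bad_ad))
    stop("standard_addition rows need addition_conc > 0; offending row(s): ",
         paste(utils::head(bad_ad, 5), collapse = ", "))
  records[, union(measurement_columns(), names(records))]
}

#' Write a measurement table
#'
#' @param records data frame of measurement records.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(records, path) {
  cols <- intersect(measurement_columns(), names(records))
  utils::write.csv(records[, cols], path, row.names = FALSE, na = "")
  invisible(path)
}
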