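#' Analytical Eco-Scale greenness score
#'
#' Scores an analytical procedure as 100 (ideal green analysis) minus the sum
#' of penalty points assigned to reagents, instruments, occupational hazard
#' and waste. Scores of at least 75 classify as "excellent", at least 50 as
#' "acceptable", below 50 as "inadequate" green analysis.
#'
#' @param items data frame with columns `category` (one of `reagent`,
#'   `instrument`, `occupational_hazard`, `waste`), `label`, optional
#'   `amount_note`, and non-negative integer `penalty_points`. An empty data
#'   frame scores 100.
#' @param thresholds two cut-offs, `c(excellent = 75, acceptable = 50)`.
#' @return list of class `"ecoscale_ledger"`: `items`, `total_penalty`,
#'   `score`, `classification`.
#' @export
score_ledger <- function(items,
                         thresholds = c(excellent = 75, acceptable = 50)) {
  if (is.null(items) || nrow(items) == 0L) {
    items <- data.frame(category = character(), label = character(),
                        amount_note = character(), penalty_points = integer(),
                        stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(items))
  if (!all(c("category", "label", "penalty_points") %in% names(items)))
    stop("ledger items need 'category', 'label' and 'penalty_points' columns")
  if (is.null(items$amount_note)) items$amount_note <- ""
  ok_cat <- c("reagent", "instrument", "occupational_hazard", "waste")
  if (nrow(items) && !all(items$category %in% ok_cat))
    stop("unknown penalty category; expected one of: ",
         paste(ok_cat, collapse = ", "))
  if (any(items$penalty_points < 0)) stop("penalty points must be >= 0")
  total <- as.integer(sum(items$penalty_points))
  score <- 100L - total
  classification <- if (score >= thresholds[["excellent"]]) {
    "excellent green analysis"
  } else if (score >= thresholds[["acceptable"]]) {
    "acceptable green analysis"
  } else {
    "inadequate green analysis"
  }
  structure(list(items = items, total_penalty = total, score = score,
                 classification = classification),
            class = "ecoscale_ledger")
}

#' @export
print.ecoscale_ledger <- function(x, ...) {
  cat("Analytical Eco-Scale assessment\n")
  if (nrow(x$items)) {
    for (cat_name in unique(x$items$category)) {
      sub <- x$items[x$items$category == cat_name, ]
      cat("  [", cat_name, "]\n", sep = "")
      for (i in seq_len(nrow(sub)))
        cat(sprintf("    %-32s %s%3d\n", sub$label[i],
                    if (nzchar(sub$amount_note[i]))
                      sprintf("(%s) ", sub$amount_note[i]) else "",
                    sub$penalty_points[i]))
    }
  }
  cat(sprintf("  total penalty points: %d\n", x$total_penalty))
  cat(sprintf("  Eco-Scale score: %d -> %s\n", x$score, x$classification))
  invisible(x)
}
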