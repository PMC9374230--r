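#' Read a SWOT indicator weight table
#'
#' @param path CSV with columns \code{origin} (\code{internal}/
#'   \code{external}), \code{group} (\code{strengths}, \code{weaknesses},
#'   \code{opportunities}, \code{threats}), \code{indicator}, \code{weight}.
#' @return validated data.frame of indicators.
#' @export
readSwotTable <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("origin", "group", "indicator", "weight")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0)
    stopWithClass(paste0("SWOT table is missing required column(s): ",
                         paste(missing_cols, collapse = ", ")),
                  "phytosurvey_schema_error")
  validateSwotTable(tab)
}

validateSwotTable <- function(tab) {
  tab$origin <- tolower(trimws(tab$origin))
  tab$group <- tolower(trimws(tab$group))
  bad <- setdiff(unique(tab$group), .SWOT_GROUPS)
  if (length(bad) > 0)
    stopWithClass(paste0("unknown SWOT group: ", paste(bad, collapse = ", ")),
                  "phytosurvey_validation_error")
  internal <- tab$group %in% c("strengths", "weaknesses")
  expected <- ifelse(internal, "internal", "external")
  if (!all(tab$origin == expected))
    stopWithClass("origin must be internal for strengths/weaknesses and external for opportunities/threats",
                  "phytosurvey_validation_error")
  if (anyDuplicated(paste(tab$group, tab$indicator, sep = "\r")))
    stopWithClass("duplicate (group, indicator)",
                  "phytosurvey_duplicate_error")
  if (any(is.na(tab$weight)) || any(tab$weight <= 0))
    stopWithClass("weights must be positive", "phytosurvey_domain_error")
  if (any(tab$weight < 100 | tab$weight > 1000))
    warning("weight(s) outside the nominal 100-1000 range; accepted as-is")
  tab
}

#' SWOT importance coefficients and group subtotals
#'
#' Each indicator's importance coefficient is its weight over the total
#' weight of all indicators across all four groups: IC_i = W_i / sum(W).
#' The exact coefficients sum to 1 and group subtotals partition it.
#' Reported cells are rounded half-up to \code{reportDecimals}; all
#' arithmetic uses the unrounded values.  The reported per-group weight
#' cell follows the source convention of the group weight sum divided by 10
#' and rounded — a display convention only, never used in IC math.
#'
#' @param indicators data.frame as from [readSwotTable()] (columns
#'   \code{origin}, \code{group}, \code{indicator}, \code{weight}).
#' @param reportDecimals decimals for the reported (rounded) columns;
#'   default 2.
#' @return A [SwotResult-class].
#' @examples
#' sw <- swotRiverine()
#' res <- computeImportanceCoefficients(sw)
#' icTable(res)[icTable(res)$indicator == "Size of area", ]
#' @export
computeImportanceCoefficients <- function(indicators, reportDecimals = 2L) {
  if (is.character(indicators) && length(indicators) == 1)
    indicators <- readSwotTable(indicators)
  if (nrow(indicators) == 0)
    stopWithClass("no indicators supplied", "phytosurvey_empty_error")
  tab <- validateSwotTable(indicators)
  total <- sum(tab$weight)
  tab$ic <- tab$weight / total
  tab$ic_reported <- roundHalfUp(tab$ic, reportDecimals)
  group_order <- intersect(.SWOT_GROUPS, unique(tab$group))
  groups <- do.call(rbind, lapply(group_order, function(g) {
    w <- sum(tab$weight[tab$group == g])
    data.frame(group = g, weight = w,
               subtotal_weight_reported = roundHalfUp(w / 10, 0),
               subtotal_ic = w / total,
               subtotal_ic_reported = roundHalfUp(w / total, reportDecimals),
               stringsAsFactors = FALSE)
  }))
  new("SwotResult", indicators = tab, groups = groups,
      totalWeight = total, grandTotalIC = sum(tab$ic),
      reportDecimals = as.integer(reportDecimals))
}

#' Published riverine SWOT indicator weights
#'
#' The 29-indicator SWOT weight table from a published riverine conservation assessment
#' (11 strengths, 6 weaknesses, 7 opportunities, 5 threats; total weight
#' 2070), shipped with the package as a worked input for
#' [computeImportanceCoefficients()].
#'
#' @return data.frame with columns \code{origin}, \code{group},
#'   \code{indicator}, \code{weight}.
#' @export
swotRiverine <- function() {
  path <- system.file("extdata", "swot_riverine.csv", package = "phytosurvey",
                      mustWork = TRUE)
  suppressWarnings(readSwotTable(path))
}
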