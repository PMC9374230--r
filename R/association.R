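#' Pearson correlation with t-test and significance flag
#'
#' Sample Pearson r with the usual t reference test
#' (t = r sqrt((n-2)/(1-r^2)) on n-2 df, two-sided) and a report flag:
#' \code{"**"} for p <= 0.01, \code{"*"} for 0.01 < p <= 0.05, otherwise
#' empty.
#'
#' @param x,y numeric vectors of equal length n >= 3, neither constant.
#' @return data.frame (one row): \code{r}, \code{n}, \code{t_statistic},
#'   \code{p_value}, \code{flag}.
#' @examples
#' pearsonWithTest(1:4, c(2, 1, 4, 3))$r  # 0.6
#' @export
pearsonWithTest <- function(x, y) {
  if (length(x) != length(y))
    stopWithClass("x and y must have the same length",
                  "phytosurvey_schema_error")
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3)
    stopWithClass("need at least three complete pairs",
                  "phytosurvey_empty_error")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stopWithClass("correlation undefined for a constant vector",
                  "phytosurvey_undefined_correlation_error")
  ct <- stats::cor.test(x, y, method = "pearson")
  p <- ct$p.value
  data.frame(r = unname(ct$estimate), n = n,
             t_statistic = unname(ct$statistic), p_value = p,
             flag = if (p <= 0.01) "**" else if (p <= 0.05) "*" else "",
             stringsAsFactors = FALSE)
}

#' Pairwise correlations among phytosociological parameters
#'
#' Lower-triangle Pearson correlations over the (site, species) rows of a
#' phytosociology table pooled across sites — e.g. relative frequency vs
#' relative density vs cover.  Rows with missing values in a pair are
#' dropped pairwise.
#'
#' @param phyto output of [computePhytosociology()].
#' @param variables at least two column names of \code{phyto}.
#' @return data.frame: \code{var_a}, \code{var_b}, \code{r}, \code{n},
#'   \code{t_statistic}, \code{p_value}, \code{flag}.
#' @export
correlationTable <- function(phyto,
                             variables = c("relative_frequency",
                                           "relative_density",
                                           "relative_cover")) {
  unknown <- setdiff(variables, names(phyto))
  if (length(unknown) > 0)
    stopWithClass(paste0("unknown variable(s): ",
                         paste(unknown, collapse = ", ")),
                  "phytosurvey_schema_error")
  if (length(variables) < 2)
    stopWithClass("need at least two variables",
                  "phytosurvey_schema_error")
  pairs <- utils::combn(variables, 2)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    res <- pearsonWithTest(phyto[[a]], phyto[[b]])
    cbind(data.frame(var_a = a, var_b = b, stringsAsFactors = FALSE), res)
  }))
  rownames(out) <- NULL
  out
}
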