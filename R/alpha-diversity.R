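checkAbundances <- function(x) {
  x <- as.numeric(x)
  if (any(is.na(x)) || any(x < 0))
    stopWithClass("abundances must be non-negative and non-missing",
                  "phytosurvey_domain_error")
  if (sum(x) <= 0)
    stopWithClass("diversity undefined for an all-zero abundance vector",
                  "phytosurvey_undefined_index_error")
  x[x > 0]
}

#' Shannon diversity index (natural log)
#'
#' H = -sum(p_i log p_i) with p_i = x_i / sum(x); zero abundances drop out.
#'
#' @param abundances non-negative abundance vector with positive sum.
#' @return H in nats; 0 for a single species, at most log(S).
#' @examples
#' shannonIndex(c(5, 5, 5, 5))  # log(4)
#' @export
shannonIndex <- function(abundances) {
  x <- checkAbundances(abundances)
  p <- x / sum(x)
  -sum(p * log(p))
}

#' Simpson diversity index
#'
#' Dominance form D = sum(p_i^2); Gini-Simpson form 1 - D (the default, the
#' convention of common community-ecology software).
#'
#' @param abundances non-negative abundance vector with positive sum.
#' @param variant \code{"gini"} (1 - sum p^2, default) or
#'   \code{"dominance"} (sum p^2).
#' @return unitless index in [0, 1].
#' @examples
#' simpsonIndex(c(5, 5, 5, 5))  # 0.75 = 1 - 1/4
#' @export
simpsonIndex <- function(abundances, variant = c("gini", "dominance")) {
  variant <- match.arg(variant)
  x <- checkAbundances(abundances)
  p <- x / sum(x)
  D <- sum(p^2)
  if (variant == "gini") 1 - D else D
}

#' Pielou evenness
#'
#' J = H / log(S), the Shannon index divided by the natural log of the
#' number of species; 1 for a perfectly even community.  Undefined for a
#' single species (log S = 0).
#'
#' @param abundances non-negative abundance vector with at least two
#'   positive entries.
#' @return J in [0, 1].
#' @export
pielouEvenness <- function(abundances) {
  x <- checkAbundances(abundances)
  if (length(x) < 2)
    stopWithClass("evenness undefined for fewer than two species",
                  "phytosurvey_undefined_index_error")
  shannonIndex(x) / log(length(x))
}

#' Species richness index
#'
#' Richness corrected for sample size.  Margalef's index divides (S - 1) by
#' a logarithm of N; both the natural-log and the log10 denominators are in
#' circulation, so the method is an explicit, mandatory choice in reports.
#' Menhinick's index is S / sqrt(N).
#'
#' @param S species count (>= 1).
#' @param N total individuals (>= S).
#' @param method \code{"margalef_ln"}, \code{"margalef_log10"} or
#'   \code{"menhinick"}.
#' @return unitless richness index.
#' @examples
#' richnessIndex(45, 95, "margalef_log10")  # 44 / log10(95)
#' @export
richnessIndex <- function(S, N,
                          method = c("margalef_ln", "margalef_log10",
                                     "menhinick")) {
  method <- match.arg(method)
  if (any(S < 1) || any(N < S))
    stopWithClass("need S >= 1 and N >= S", "phytosurvey_domain_error")
  if (method != "menhinick" && any(N <= 1))
    stopWithClass("Margalef richness undefined for N <= 1",
                  "phytosurvey_undefined_index_error")
  switch(method,
         margalef_ln = (S - 1) / log(N),
         margalef_log10 = (S - 1) / log10(N),
         menhinick = S / sqrt(N))
}

#' Per-site diversity table
#'
#' Applies the alpha-diversity indices to every row of a site-level
#' community matrix: species count S, total individuals N, Shannon H (nats),
#' Gini-Simpson, Pielou evenness (NA where S = 1) and a richness index.
#'
#' @param mat a [CommunityMatrix-class] or plain abundance matrix with row
#'   labels.
#' @param richnessMethod passed to [richnessIndex()]; recorded in the output
#'   so reports always carry the formula used.
#' @param simpsonVariant passed to [simpsonIndex()].
#' @return data.frame with one row per matrix row: \code{site}, \code{S},
#'   \code{N}, \code{shannon}, \code{simpson}, \code{evenness},
#'   \code{richness}, \code{richness_method}.
#' @export
diversityTable <- function(mat, richnessMethod = "margalef_ln",
                           simpsonVariant = "gini") {
  m <- as(mat, "matrix")
  if (is.null(rownames(m)))
    stopWithClass("matrix rows must be labelled", "phytosurvey_schema_error")
  rows <- lapply(rownames(m), function(site) {
    x <- m[site, ]
    if (sum(x) <= 0)
      stopWithClass(paste0("site ", site, " has no individuals; ",
                           "indices undefined"),
                    "phytosurvey_undefined_index_error")
    S <- sum(x > 0)
    N <- sum(x)
    data.frame(site = site, S = S, N = N,
               shannon = shannonIndex(x),
               simpson = simpsonIndex(x, simpsonVariant),
               evenness = if (S >= 2) pielouEvenness(x) else NA_real_,
               richness = richnessIndex(S, N, richnessMethod),
               richness_method = richnessMethod,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Two-sample Wilcoxon rank-sum comparison
#'
#' Two-sided Mann-Whitney-Wilcoxon test.  With \code{mode = "auto"} the
#' exact distribution is used when the combined sample size is at most 12
#' and there are no ties; otherwise the normal approximation with tie and
#' continuity corrections.  The method actually used is recorded.
#'
#' @param x,y numeric samples (each non-empty).
#' @param mode \code{"auto"}, \code{"exact"} or \code{"normal"}.
#' @return data.frame (one row): \code{statistic} (Mann-Whitney U for the
#'   first sample), \code{p_value}, \code{method}
#'   (\code{"exact"}/\code{"normal_approx"}), \code{n_x}, \code{n_y}.
#' @examples
#' wilcoxonRankSum(c(1, 2), c(3, 4))$p_value  # 1/3 by exact enumeration
#' @export
wilcoxonRankSum <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  if (length(x) < 1 || length(y) < 1)
    stopWithClass("both groups must be non-empty",
                  "phytosurvey_empty_error")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- switch(mode,
                  auto = (length(x) + length(y) <= 12) && !ties,
                  exact = TRUE,
                  normal = FALSE)
  if (exact && ties)
    stopWithClass("exact Wilcoxon p is unavailable with ties",
                  "phytosurvey_domain_error")
  wt <- suppressWarnings(stats::wilcox.test(
    x, y, alternative = "two.sided", exact = exact, correct = TRUE))
  p <- wt$p.value
  # fully tied data: zero-variance normal approximation; no evidence of shift
  if (is.nan(p)) p <- 1
  data.frame(statistic = unname(wt$statistic),
             p_value = min(1, p),
             method = if (exact) "exact" else "normal_approx",
             n_x = length(x), n_y = length(y),
             stringsAsFactors = FALSE)
}

#' Pairwise rank-sum comparisons of a diversity index across soil groups
#'
#' For every pair of soil texture classes with at least one site each,
#' compares a per-site diversity column with [wilcoxonRankSum()].
#'
#' @param diversity output of [diversityTable()].
#' @param soil soil table as from [readSoilTable()] (columns \code{site},
#'   \code{texture}).
#' @param metric diversity column to compare (default \code{"shannon"}).
#' @param mode passed to [wilcoxonRankSum()].
#' @return data.frame: \code{group_a}, \code{group_b}, \code{statistic},
#'   \code{p_value}, \code{method}, \code{n_a}, \code{n_b}.
#' @export
groupComparisonTable <- function(diversity, soil, metric = "shannon",
                                 mode = "auto") {
  if (!metric %in% names(diversity))
    stopWithClass(paste0("unknown diversity column: ", metric),
                  "phytosurvey_schema_error")
  tex <- soil$texture[match(diversity$site, soil$site)]
  if (any(is.na(tex)))
    stopWithClass("soil table lacks texture for some sites",
                  "phytosurvey_schema_error")
  groups <- split(diversity[[metric]], tex)
  groups <- groups[lengths(groups) >= 1]
  labs <- names(groups)
  if (length(labs) < 2)
    stopWithClass("need at least two texture groups",
                  "phytosurvey_degenerate_design_error")
  pairs <- utils::combn(labs, 2)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    w <- wilcoxonRankSum(groups[[a]], groups[[b]], mode = mode)
    data.frame(group_a = a, group_b = b, statistic = w$statistic,
               p_value = w$p_value, method = w$method,
               n_a = w$n_x, n_b = w$n_y, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
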