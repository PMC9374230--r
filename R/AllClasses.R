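#' @import methods
NULL

.HABITS <- c("herb", "shrub", "tree")
.LIFE_CYCLES <- c("annual", "perennial")
.SOIL_TEXTURES <- c("loam", "clay_loam", "sandy_loam", "sand", "clay")
.SWOT_GROUPS <- c("strengths", "weaknesses", "opportunities", "threats")
.OBS_COLUMNS <- c("site", "quadrat", "species", "family", "habit",
                  "life_cycle", "count", "cover_class", "intercept_length")

#' Validated long-format quadrat survey
#'
#' Container for a quadrat-based vegetation survey recorded in long (tidy)
#' form: one row per (site, quadrat, species) with a count of individuals and
#' optional cover information.  Layers (herb, shrub, tree) are sampled with
#' quadrats of different areas; those areas travel with the dataset because
#' the density denominator depends on them.
#'
#' @slot observations data.frame with columns \code{site}, \code{quadrat},
#'   \code{species}, \code{family}, \code{habit}, \code{life_cycle},
#'   \code{count}, \code{cover_class}, \code{intercept_length}.  The last
#'   five may contain \code{NA} where unrecorded (counts never).
#' @slot layerAreas named numeric, quadrat area in square metres per habit
#'   layer; default 1 (herb), 25 (shrub), 100 (tree).
#' @slot quadratsPerSite named integer, number of quadrats sampled per site.
#'
#' @seealso [readQuadratTable()], [simulateSurvey()], [buildCommunityMatrix()]
#' @exportClass SurveyDataset
setClass("SurveyDataset",
  representation(
    observations = "data.frame",
    layerAreas = "numeric",
    quadratsPerSite = "integer"
  )
)

setValidity("SurveyDataset", function(object) {
  obs <- object@observations
  msgs <- character()
  missing_cols <- setdiff(.OBS_COLUMNS, names(obs))
  if (length(missing_cols) > 0)
    return(paste("observations missing column(s):",
                 paste(missing_cols, collapse = ", ")))
  if (nrow(obs) > 0) {
    if (!all(obs$habit %in% .HABITS))
      msgs <- c(msgs, paste("unknown habit value(s):",
                paste(unique(setdiff(obs$habit, .HABITS)), collapse = ", ")))
    lc <- obs$life_cycle[!is.na(obs$life_cycle)]
    if (!all(lc %in% .LIFE_CYCLES))
      msgs <- c(msgs, "life_cycle must be 'annual' or 'perennial'")
    if (any(is.na(obs$count)) || any(obs$count < 0))
      msgs <- c(msgs, "count must be a non-negative integer")
    cc <- obs$cover_class[!is.na(obs$cover_class)]
    if (length(cc) > 0 && (any(cc < 1) || any(cc > 6) || any(cc != round(cc))))
      msgs <- c(msgs, "cover_class must be an integer in 1..6 when present")
    il <- obs$intercept_length[!is.na(obs$intercept_length)]
    if (length(il) > 0 && any(il < 0))
      msgs <- c(msgs, "intercept_length must be non-negative")
    key <- paste(obs$site, obs$quadrat, obs$species, sep = "\r")
    if (anyDuplicated(key))
      msgs <- c(msgs, "duplicate (site, quadrat, species) record(s)")
    if (!all(obs$site %in% names(object@quadratsPerSite)))
      msgs <- c(msgs, "every observed site must appear in quadratsPerSite")
  }
  la <- object@layerAreas
  if (is.null(names(la)) || !all(.HABITS %in% names(la)))
    msgs <- c(msgs, "layerAreas must be named for herb, shrub and tree")
  else if (any(la[.HABITS] <= 0))
    msgs <- c(msgs, "layerAreas must be strictly positive")
  if (length(object@quadratsPerSite) > 0 &&
      (is.null(names(object@quadratsPerSite)) ||
       any(object@quadratsPerSite < 1)))
    msgs <- c(msgs, "quadratsPerSite must be named positive integers")
  if (length(msgs) == 0) TRUE else msgs
})

#' Construct a SurveyDataset
#'
#' @param observations data.frame of quadrat observations; required columns
#'   \code{site}, \code{quadrat}, \code{species}, \code{habit}, \code{count};
#'   optional \code{family}, \code{life_cycle}, \code{cover_class},
#'   \code{intercept_length} (filled with \code{NA} if absent).  Species
#'   names are whitespace-normalised and case-folded to
#'   "Genus epithet" form before matching.
#' @param layerAreas named numeric quadrat areas (m^2) per habit layer.
#' @param quadratsPerSite named integer, quadrats sampled per site; if
#'   \code{NULL}, inferred as the number of distinct quadrat ids per site.
#' @return A validated [SurveyDataset-class] object.
#' @examples
#' obs <- data.frame(site = "S1", quadrat = c("q1", "q1", "q2"),
#'                   species = c("Poa annua", "Cynodon dactylon", "Poa annua"),
#'                   habit = "herb", count = c(4, 2, 1))
#' SurveyDataset(obs)
#' @export
SurveyDataset <- function(observations,
                          layerAreas = c(herb = 1, shrub = 25, tree = 100),
                          quadratsPerSite = NULL) {
  required <- c("site", "quadrat", "species", "habit", "count")
  missing_cols <- setdiff(required, names(observations))
  if (length(missing_cols) > 0)
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  obs <- as.data.frame(observations, stringsAsFactors = FALSE)
  for (col in setdiff(.OBS_COLUMNS, names(obs)))
    obs[[col]] <- rep(if (col %in% c("count", "cover_class",
                                     "intercept_length"))
      NA_real_ else NA_character_, nrow(obs))
  obs <- obs[, .OBS_COLUMNS]
  obs$site <- as.character(obs$site)
  obs$quadrat <- as.character(obs$quadrat)
  obs$species <- normalizeSpeciesNames(obs$species)
  obs$habit <- tolower(trimws(as.character(obs$habit)))
  obs$family <- as.character(obs$family)
  obs$life_cycle <- tolower(trimws(as.character(obs$life_cycle)))
  # empty cells from CSV round-trips are missing values
  obs$family[!is.na(obs$family) & obs$family == ""] <- NA_character_
  obs$life_cycle[!is.na(obs$life_cycle) & obs$life_cycle == ""] <-
    NA_character_
  obs$count <- as.numeric(obs$count)
  obs$cover_class <- as.numeric(obs$cover_class)
  obs$intercept_length <- as.numeric(obs$intercept_length)
  if (nrow(obs) > 0 && any(!is.na(obs$count) & obs$count != round(obs$count)))
    stop("count must be integral")
  if (is.null(quadratsPerSite)) {
    quadratsPerSite <- vapply(
      split(obs$quadrat, obs$site),
      function(q) length(unique(q)), integer(1))
  }
  qps <- as.integer(quadratsPerSite)
  names(qps) <- names(quadratsPerSite)
  new("SurveyDataset", observations = obs,
      layerAreas = layerAreas, quadratsPerSite = qps)
}

#' Sites-by-species (or quadrats-by-species) abundance matrix
#'
#' A numeric matrix whose rows are sampling units (sites, or (site, quadrat)
#' pairs) and whose columns are species, cells holding summed counts.  The
#' canonical substrate for diversity indices and Bray-Curtis dissimilarity.
#'
#' @slot .Data numeric matrix, non-negative, unique dimnames.
#' @slot level either \code{"site"} or \code{"quadrat"}.
#' @seealso [buildCommunityMatrix()]
#' @exportClass CommunityMatrix
setClass("CommunityMatrix",
  contains = "matrix",
  representation(level = "character")
)

setValidity("CommunityMatrix", function(object) {
  m <- object@.Data
  msgs <- character()
  if (!is.numeric(m)) msgs <- c(msgs, "cells must be numeric")
  else if (any(m < 0)) msgs <- c(msgs, "cells must be non-negative")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    msgs <- c(msgs, "row and column labels are required")
  else {
    if (anyDuplicated(rownames(m))) msgs <- c(msgs, "duplicate row labels")
    if (anyDuplicated(colnames(m))) msgs <- c(msgs, "duplicate column labels")
  }
  if (!object@level %in% c("site", "quadrat"))
    msgs <- c(msgs, "level must be 'site' or 'quadrat'")
  if (length(msgs) == 0) TRUE else msgs
})

#' One-way PERMANOVA result
#'
#' Output of [permanova()]: the partition of squared dissimilarity into
#' between- and within-group components, the pseudo-F ratio, and a
#' permutation p-value.
#'
#' @slot pseudoF pseudo-F ratio.
#' @slot R2 SS_between / SS_total.
#' @slot dfBetween,dfWithin degrees of freedom (a - 1, N - a).
#' @slot ssBetween,ssWithin,ssTotal sums of squared dissimilarities.
#' @slot pValue permutation p-value, (#\{F_perm >= F_obs\} + 1)/(n_perm + 1).
#' @slot nPermutations number of random permutations.
#' @slot seed RNG seed used for the permutations.
#' @exportClass PermanovaResult
setClass("PermanovaResult",
  representation(
    pseudoF = "numeric", R2 = "numeric",
    dfBetween = "integer", dfWithin = "integer",
    ssBetween = "numeric", ssWithin = "numeric", ssTotal = "numeric",
    pValue = "numeric", nPermutations = "integer", seed = "integer"
  )
)

setValidity("PermanovaResult", function(object) {
  msgs <- character()
  if (object@pValue < 1 / (object@nPermutations + 1) - 1e-12 ||
      object@pValue > 1 + 1e-12)
    msgs <- c(msgs, "pValue outside [1/(n_perm+1), 1]")
  if (is.finite(object@R2) && (object@R2 < -1e-12 || object@R2 > 1 + 1e-12))
    msgs <- c(msgs, "R2 outside [0, 1]")
  if (length(msgs) == 0) TRUE else msgs
})

#' Principal coordinates ordination result
#'
#' Output of [pcoa()]: coordinates for the positive-eigenvalue axes of the
#' Gower-centred matrix, the full eigenvalue spectrum of retained axes, the
#' proportion of (positive) inertia each axis explains, and the mass of
#' negative eigenvalues (a diagnostic for non-Euclidean dissimilarities).
#'
#' @slot coordinates sites x axes matrix, eigenvectors scaled by
#'   sqrt(eigenvalue).
#' @slot eigenvalues non-increasing eigenvalues of retained axes.
#' @slot proportionExplained per-axis share of the positive eigenvalue sum.
#' @slot correction \code{"none"} or \code{"cailliez"}.
#' @slot negativeEigenvalueMass sum of absolute negative eigenvalues.
#' @exportClass PcoaResult
setClass("PcoaResult",
  representation(
    coordinates = "matrix", eigenvalues = "numeric",
    proportionExplained = "numeric", correction = "character",
    negativeEigenvalueMass = "numeric"
  )
)

setValidity("PcoaResult", function(object) {
  msgs <- character()
  ev <- object@eigenvalues
  if (length(ev) > 1 && any(diff(ev) > 1e-8 * max(abs(ev), 1)))
    msgs <- c(msgs, "eigenvalues must be non-increasing")
  pe <- object@proportionExplained
  if (length(pe) > 0 && sum(pe) > 1 + 1e-8)
    msgs <- c(msgs, "proportionExplained sums to more than 1")
  if (!object@correction %in% c("none", "cailliez"))
    msgs <- c(msgs, "correction must be 'none' or 'cailliez'")
  if (length(msgs) == 0) TRUE else msgs
})

#' Quantitative SWOT scoring result
#'
#' Output of [computeImportanceCoefficients()]: per-indicator importance
#' coefficients IC_i = W_i / sum(W) over all indicators, group subtotals,
#' and the reported (rounded) forms alongside the exact values.
#'
#' @slot indicators data.frame: origin, group, indicator, weight, ic
#'   (exact), ic_reported (rounded half-up).
#' @slot groups data.frame: group, weight, subtotal_weight_reported
#'   (weight/10 rounded, a reporting convention), subtotal_ic (exact),
#'   subtotal_ic_reported.
#' @slot totalWeight sum of all indicator weights.
#' @slot grandTotalIC always 1 before rounding.
#' @slot reportDecimals decimals used for the reported columns.
#' @exportClass SwotResult
setClass("SwotResult",
  representation(
    indicators = "data.frame", groups = "data.frame",
    totalWeight = "numeric", grandTotalIC = "numeric",
    reportDecimals = "integer"
  )
)

setValidity("SwotResult", function(object) {
  msgs <- character()
  if (abs(sum(object@indicators$ic) - 1) > 1e-12)
    msgs <- c(msgs, "exact ICs must sum to 1")
  if (abs(sum(object@groups$subtotal_ic) - object@grandTotalIC) > 1e-12)
    msgs <- c(msgs, "group subtotal ICs must partition the grand total")
  if (length(msgs) == 0) TRUE else msgs
})
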