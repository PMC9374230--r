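#' Read a long-format quadrat observation table
#'
#' Reads the canonical long (tidy) CSV: one row per (site, quadrat, species)
#' with the count of individuals and optional family, life cycle, Daubenmire
#' cover class (1-6) and line-intercept length.  Absent species are implicit;
#' no zero rows are required.
#'
#' @param path path to a CSV file with header; required columns \code{site},
#'   \code{quadrat}, \code{species}, \code{habit}, \code{count}; optional
#'   \code{family}, \code{life_cycle}, \code{cover_class},
#'   \code{intercept_length}.
#' @param layerAreas named numeric, quadrat area (m^2) per habit layer.
#' @param quadratsPerSite optional named integer overriding the number of
#'   quadrats sampled per site (by default inferred from distinct quadrat
#'   ids, 4 per site in the reference design).
#' @return A [SurveyDataset-class].
#' @export
readQuadratTable <- function(path,
                             layerAreas = c(herb = 1, shrub = 25, tree = 100),
                             quadratsPerSite = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("site", "quadrat", "species", "habit", "count")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0)
    stopWithClass(paste0("quadrat table is missing required column(s): ",
                         paste(missing_cols, collapse = ", ")),
                  "phytosurvey_schema_error")
  key <- paste(tab$site, tab$quadrat, normalizeSpeciesNames(tab$species),
               sep = "\r")
  if (anyDuplicated(key)) {
    dup <- tab[duplicated(key), c("site", "quadrat", "species"), drop = FALSE]
    stopWithClass(paste0("duplicate (site, quadrat, species) record: ",
                         paste(dup[1, ], collapse = " / ")),
                  "phytosurvey_duplicate_error")
  }
  ds <- tryCatch(
    SurveyDataset(tab, layerAreas = layerAreas,
                  quadratsPerSite = quadratsPerSite),
    error = function(e) stopWithClass(conditionMessage(e),
                                      "phytosurvey_validation_error"))
  ds
}

#' Write a SurveyDataset back to CSV
#'
#' Inverse of [readQuadratTable()]: a written file read back reproduces the
#' dataset exactly.
#'
#' @param dataset a [SurveyDataset-class].
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeQuadratTable <- function(dataset, path) {
  stopifnot(is(dataset, "SurveyDataset"))
  utils::write.csv(observations(dataset), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a per-site soil table
#'
#' One row per site with texture class and the numeric covariates used by
#' the downstream group comparisons and ordination overlays.
#'
#' @param path CSV with columns \code{site}, \code{texture}, \code{moisture},
#'   \code{pH}, \code{EC}, \code{OM}, \code{P}, \code{K}.
#' @return data.frame of validated soil records (one per site).
#' @details Validation: texture must be one of \code{loam}, \code{clay_loam},
#'   \code{sandy_loam}, \code{sand}, \code{clay}; moisture in [0, 100]; pH in
#'   (0, 14); EC, OM, P, K non-negative.
#' @export
readSoilTable <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("site", "texture", "moisture", "pH", "EC", "OM", "P", "K")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0)
    stopWithClass(paste0("soil table is missing required column(s): ",
                         paste(missing_cols, collapse = ", ")),
                  "phytosurvey_schema_error")
  validateSoilTable(tab)
}

validateSoilTable <- function(tab) {
  tab$site <- as.character(tab$site)
  tab$texture <- tolower(trimws(tab$texture))
  if (anyDuplicated(tab$site))
    stopWithClass("duplicate site in soil table",
                  "phytosurvey_duplicate_error")
  bad <- setdiff(unique(tab$texture), .SOIL_TEXTURES)
  if (length(bad) > 0)
    stopWithClass(paste0("unknown soil texture: ",
                         paste(bad, collapse = ", ")),
                  "phytosurvey_validation_error")
  if (any(tab$moisture < 0 | tab$moisture > 100, na.rm = TRUE))
    stopWithClass("moisture outside [0, 100]", "phytosurvey_range_error")
  if (any(tab$pH <= 0 | tab$pH >= 14, na.rm = TRUE))
    stopWithClass("pH outside (0, 14)", "phytosurvey_range_error")
  for (col in c("EC", "OM", "P", "K"))
    if (any(tab[[col]] < 0, na.rm = TRUE))
      stopWithClass(paste(col, "must be non-negative"),
                    "phytosurvey_range_error")
  tab
}

#' Pool quadrat observations into an abundance matrix
#'
#' @param dataset a [SurveyDataset-class].
#' @param level \code{"site"} (cells are counts summed over the site's
#'   quadrats) or \code{"quadrat"} (rows are \code{site:quadrat} pairs).
#' @return A [CommunityMatrix-class]; columns in lexicographic species order.
#' @examples
#' obs <- data.frame(site = "S1", quadrat = c("q1", "q2"),
#'                   species = "Poa annua", habit = "herb", count = c(2, 3))
#' buildCommunityMatrix(SurveyDataset(obs))  # cell (S1, Poa annua) = 5
#' @export
buildCommunityMatrix <- function(dataset, level = c("site", "quadrat")) {
  level <- match.arg(level)
  stopifnot(is(dataset, "SurveyDataset"))
  obs <- observations(dataset)
  if (nrow(obs) == 0)
    stopWithClass("dataset has no observations", "phytosurvey_empty_error")
  rows <- if (level == "site") obs$site else paste(obs$site, obs$quadrat,
                                                   sep = ":")
  species <- sort(unique(obs$species))
  units <- sort(unique(rows))
  m <- matrix(0, nrow = length(units), ncol = length(species),
              dimnames = list(units, species))
  agg <- stats::aggregate(obs$count, by = list(unit = rows, sp = obs$species),
                          FUN = sum)
  m[cbind(agg$unit, agg$sp)] <- agg$x
  new("CommunityMatrix", m, level = level)
}

#' Import a wide site-by-species abundance matrix
#'
#' Alternative import for data already pooled to a sites x species table
#' (first column = site label, remaining columns = species).  The long
#' quadrat CSV remains the canonical input; quadrat-level statistics
#' (frequency, per-quadrat density) are not available from a wide import.
#'
#' @param path CSV path.
#' @return A [CommunityMatrix-class] at site level.
#' @export
readWideCommunityMatrix <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(tab) < 2)
    stopWithClass("wide matrix needs a site column plus species columns",
                  "phytosurvey_schema_error")
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(tab[[1]])
  colnames(m) <- normalizeSpeciesNames(colnames(m))
  m <- m[, order(colnames(m)), drop = FALSE]
  new("CommunityMatrix", m, level = "site")
}
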