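#' Floristic summary counts
#'
#' Counts species, genera (first whitespace token of the binomial),
#' families and habit tallies, per taxonomic group (if a \code{group}
#' column is present) and in total.
#'
#' @param x a checklist data.frame with columns \code{species},
#'   \code{family}, \code{habit} and optionally \code{group}, or a
#'   [SurveyDataset-class] (summarised over its distinct species).
#' @return data.frame: \code{group}, \code{families}, \code{genera},
#'   \code{species}, \code{herbs}, \code{shrubs}, \code{trees}; last row is
#'   the total.  Empty input gives an all-zero total row.
#' @examples
#' floristicSummary(syntheticChecklist())
#' @export
floristicSummary <- function(x) {
  if (is(x, "SurveyDataset")) {
    obs <- observations(x)
    x <- unique(obs[, c("species", "family", "habit")])
  }
  if (nrow(x) == 0)
    return(data.frame(group = "Total", families = 0L, genera = 0L,
                      species = 0L, herbs = 0L, shrubs = 0L, trees = 0L,
                      stringsAsFactors = FALSE))
  for (col in c("species", "family", "habit"))
    if (!col %in% names(x))
      stopWithClass(paste0("checklist is missing column: ", col),
                    "phytosurvey_schema_error")
  x <- unique(x[, intersect(c("species", "family", "habit", "group"),
                            names(x))])
  genus <- vapply(strsplit(x$species, "\\s+"), `[`, character(1), 1)
  odd <- grepl("[^A-Za-z].*", substr(genus, 1, 1)) | nchar(genus) < 2
  if (any(odd))
    warning("genus token(s) look abbreviated or hybrid: ",
            paste(unique(genus[odd]), collapse = ", "))
  tally <- function(idx, label) {
    data.frame(group = label,
               families = length(unique(x$family[idx][!is.na(x$family[idx])])),
               genera = length(unique(genus[idx])),
               species = length(unique(x$species[idx])),
               herbs = sum(x$habit[idx] == "herb", na.rm = TRUE),
               shrubs = sum(x$habit[idx] == "shrub", na.rm = TRUE),
               trees = sum(x$habit[idx] == "tree", na.rm = TRUE),
               stringsAsFactors = FALSE)
  }
  out <- if ("group" %in% names(x)) {
    do.call(rbind, lapply(unique(x$group), function(g)
      tally(which(x$group == g), g)))
  } else NULL
  rbind(out, tally(seq_len(nrow(x)), "Total"))
}

#' Run the full survey analysis pipeline
#'
#' Orchestrates: input validation, community matrix construction,
#' phytosociology, alpha diversity (plus pairwise rank-sum comparisons
#' across soil texture groups), log10(x+1) transform, Bray-Curtis,
#' one-way PERMANOVA over soil texture, PCoA, phytosociological parameter
#' correlations, and quantitative SWOT scoring.  Stages whose inputs are
#' absent are skipped with a notice; every written output is deterministic
#' given the seed.
#'
#' @param quadrats path to a long quadrat CSV, or a [SurveyDataset-class];
#'   \code{NULL} skips all community stages.
#' @param soil path to a soil CSV or a soil data.frame; \code{NULL} skips
#'   the group comparisons and PERMANOVA.
#' @param swot path to a SWOT weight CSV or an indicator data.frame;
#'   \code{NULL} skips SWOT scoring.
#' @param outDir output directory for the CSV/JSON report files.
#' @param richnessMethod,coverSource,simpsonVariant method choices recorded
#'   in the run report.
#' @param nPermutations,seed PERMANOVA permutation count and seed; a seed is
#'   required whenever a stochastic stage runs.
#' @param runPermanova set \code{TRUE} to insist on PERMANOVA (error rather
#'   than skip when the soil table is missing).
#' @return (invisibly) a list with the in-memory results and the run report.
#' @export
runAll <- function(quadrats = NULL, soil = NULL, swot = NULL,
                   outDir = ".",
                   richnessMethod = "margalef_ln",
                   coverSource = "class_midpoint",
                   simpsonVariant = "gini",
                   nPermutations = 999, seed = NULL,
                   runPermanova = !is.null(soil)) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  report <- list(
    package_version = as.character(utils::packageVersion("phytosurvey")),
    config = list(richness_method = richnessMethod,
                  cover_source = coverSource,
                  simpson_variant = simpsonVariant,
                  n_permutations = nPermutations, seed = seed,
                  correlation_unit = "(site, species) rows pooled over sites"),
    stages = character())
  results <- list()
  note <- function(msg) message("phytosurvey: ", msg)
  wcsv <- function(x, name) utils::write.csv(
    x, file.path(outDir, name), row.names = FALSE, na = "")

  if (runPermanova && is.null(soil))
    stopWithClass("PERMANOVA requested but no soil table given",
                  "phytosurvey_config_error")
  if (runPermanova && is.null(seed))
    stopWithClass("a seed is required when PERMANOVA runs",
                  "phytosurvey_config_error")

  if (!is.null(soil) && is.character(soil)) soil <- readSoilTable(soil)
  else if (!is.null(soil)) soil <- validateSoilTable(soil)

  if (!is.null(quadrats)) {
    ds <- if (is.character(quadrats)) readQuadratTable(quadrats) else quadrats
    results$dataset <- ds
    results$floristic <- floristicSummary(ds)
    wcsv(results$floristic, "floristic_summary.csv")
    cm <- buildCommunityMatrix(ds, level = "site")
    results$community <- cm
    results$phyto <- computePhytosociology(ds, coverSource = coverSource)
    wcsv(results$phyto, "phytosociology.csv")
    results$diversity <- diversityTable(cm, richnessMethod = richnessMethod,
                                        simpsonVariant = simpsonVariant)
    wcsv(results$diversity, "diversity.csv")
    results$correlations <- correlationTable(
      results$phyto,
      variables = if (coverSource == "none")
        c("relative_frequency", "relative_density")
      else c("relative_frequency", "relative_density", "relative_cover"))
    wcsv(results$correlations, "correlations.csv")

    trans <- log10Plus1(cm)
    d <- brayCurtis(trans)
    utils::write.csv(as.data.frame(d), file.path(outDir, "distance.csv"))
    results$distance <- d
    if (nrow(d) >= 3) {
      results$pcoa <- pcoa(d)
      co <- as.data.frame(scores(results$pcoa))
      co <- cbind(site = rownames(co), co)
      wcsv(co, "pcoa_coords.csv")
      wcsv(data.frame(axis = seq_along(eigenvalues(results$pcoa)),
                      eigenvalue = eigenvalues(results$pcoa)),
           "pcoa_eigen.csv")
    }
    if (!is.null(soil)) {
      results$group_tests <- groupComparisonTable(results$diversity, soil)
      wcsv(results$group_tests, "group_tests.csv")
      tex <- soil$texture[match(rownames(d), soil$site)]
      results$permanova <- permanova(d, tex,
                                     nPermutations = nPermutations,
                                     seed = seed)
      pm <- results$permanova
      jsonlite::write_json(
        list(pseudo_F = pm@pseudoF, R2 = pm@R2,
             df_between = pm@dfBetween, df_within = pm@dfWithin,
             p_value = pm@pValue, n_permutations = pm@nPermutations,
             seed = pm@seed),
        file.path(outDir, "permanova.json"), auto_unbox = TRUE, digits = NA)
      report$stages <- c(report$stages, "group_tests", "permanova")
    } else {
      note("no soil table; skipping group comparisons and PERMANOVA")
    }
    report$stages <- c(report$stages, "survey_io", "phytosociology",
                       "alpha_diversity", "beta_ordination",
                       "association_stats")
  } else {
    note("no quadrat table; skipping community stages")
  }

  if (!is.null(swot)) {
    results$swot <- computeImportanceCoefficients(
      if (is.character(swot)) readSwotTable(swot) else swot)
    wcsv(icTable(results$swot), "swot_result.csv")
    wcsv(groupSummary(results$swot), "swot_groups.csv")
    report$stages <- c(report$stages, "swot_quant")
    report$swot_note <- paste(
      "printed subtotal ICs for strengths/threats in the reference table",
      "(0.42 / 0.17) are not reproducible from IC = W / sum(W);",
      "computed values are reported")
  } else {
    note("no SWOT table; skipping SWOT scoring")
  }

  report$outputs <- list.files(outDir)
  jsonlite::write_json(report, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(results, list(report = report)))
}
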