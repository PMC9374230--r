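#' @rdname SurveyDataset-class
#' @param object a \code{SurveyDataset}
#' @export
setGeneric("observations", function(object) standardGeneric("observations"))

#' @rdname SurveyDataset-class
#' @export
setMethod("observations", "SurveyDataset", function(object) object@observations)

#' @rdname SurveyDataset-class
#' @export
setGeneric("layerAreas", function(object) standardGeneric("layerAreas"))

#' @rdname SurveyDataset-class
#' @export
setMethod("layerAreas", "SurveyDataset", function(object) object@layerAreas)

#' @rdname SurveyDataset-class
#' @export
setGeneric("quadratsPerSite", function(object) standardGeneric("quadratsPerSite"))

#' @rdname SurveyDataset-class
#' @export
setMethod("quadratsPerSite", "SurveyDataset",
          function(object) object@quadratsPerSite)

#' @rdname SurveyDataset-class
#' @export
setGeneric("nSites", function(object) standardGeneric("nSites"))

#' @rdname SurveyDataset-class
#' @export
setMethod("nSites", "SurveyDataset",
          function(object) length(object@quadratsPerSite))

setMethod("show", "SurveyDataset", function(object) {
  obs <- object@observations
  cat("SurveyDataset:", nrow(obs), "observations,",
      length(unique(obs$species)), "species,",
      length(object@quadratsPerSite), "site(s),",
      sum(object@quadratsPerSite), "quadrat(s)\n")
  cat("  layer areas (m^2):",
      paste(names(object@layerAreas), object@layerAreas,
            sep = "=", collapse = ", "), "\n")
})

setMethod("show", "CommunityMatrix", function(object) {
  cat("CommunityMatrix (level =", object@level, "):",
      nrow(object), "x", ncol(object),
      "| total individuals:", sum(object@.Data), "\n")
})

#' @rdname PermanovaResult-class
#' @param object a \code{PermanovaResult}
#' @export
setGeneric("pseudoF", function(object) standardGeneric("pseudoF"))

#' @rdname PermanovaResult-class
#' @export
setMethod("pseudoF", "PermanovaResult", function(object) object@pseudoF)

#' @rdname PermanovaResult-class
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))

#' @rdname PermanovaResult-class
#' @export
setMethod("pValue", "PermanovaResult", function(object) object@pValue)

#' @rdname PermanovaResult-class
#' @export
setGeneric("rSquared", function(object) standardGeneric("rSquared"))

#' @rdname PermanovaResult-class
#' @export
setMethod("rSquared", "PermanovaResult", function(object) object@R2)

setMethod("show", "PermanovaResult", function(object) {
  cat("One-way PERMANOVA (", object@nPermutations, "permutations )\n")
  cat(sprintf("  pseudo-F = %.4f on (%d, %d) df, R2 = %.4f, p = %.4g\n",
              object@pseudoF, object@dfBetween, object@dfWithin,
              object@R2, object@pValue))
})

#' @rdname PcoaResult-class
#' @param object a \code{PcoaResult}
#' @export
setGeneric("scores", function(object) standardGeneric("scores"))

#' @rdname PcoaResult-class
#' @export
setMethod("scores", "PcoaResult", function(object) object@coordinates)

#' @rdname PcoaResult-class
#' @export
setGeneric("eigenvalues", function(object) standardGeneric("eigenvalues"))

#' @rdname PcoaResult-class
#' @export
setMethod("eigenvalues", "PcoaResult", function(object) object@eigenvalues)

#' @rdname PcoaResult-class
#' @export
setGeneric("proportionExplained",
           function(object) standardGeneric("proportionExplained"))

#' @rdname PcoaResult-class
#' @export
setMethod("proportionExplained", "PcoaResult",
          function(object) object@proportionExplained)

setMethod("show", "PcoaResult", function(object) {
  cat("PCoA:", nrow(object@coordinates), "points,",
      ncol(object@coordinates), "positive axes (correction:",
      object@correction, ")\n")
  if (length(object@proportionExplained) >= 2)
    cat(sprintf("  PC1 %.1f%%, PC2 %.1f%% of positive inertia\n",
                100 * object@proportionExplained[1],
                100 * object@proportionExplained[2]))
  if (object@negativeEigenvalueMass > 0)
    cat("  negative eigenvalue mass:", object@negativeEigenvalueMass, "\n")
})

#' @rdname SwotResult-class
#' @param object a \code{SwotResult}
#' @export
setGeneric("icTable", function(object) standardGeneric("icTable"))

#' @rdname SwotResult-class
#' @export
setMethod("icTable", "SwotResult", function(object) object@indicators)

#' @rdname SwotResult-class
#' @export
setGeneric("groupSummary", function(object) standardGeneric("groupSummary"))

#' @rdname SwotResult-class
#' @export
setMethod("groupSummary", "SwotResult", function(object) object@groups)

#' @rdname SwotResult-class
#' @export
setGeneric("totalWeight", function(object) standardGeneric("totalWeight"))

#' @rdname SwotResult-class
#' @export
setMethod("totalWeight", "SwotResult", function(object) object@totalWeight)

setMethod("show", "SwotResult", function(object) {
  cat("Quantitative SWOT:", nrow(object@indicators),
      "indicators, total weight", object@totalWeight, "\n")
  g <- object@groups
  for (i in seq_len(nrow(g)))
    cat(sprintf("  %-13s W = %4d  subtotal IC = %.2f\n",
                g$group[i], as.integer(g$weight[i]),
                g$subtotal_ic_reported[i]))
})
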