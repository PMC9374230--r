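#' Daubenmire cover-class midpoint
#'
#' Converts the ordinal 1-6 visual cover class (Braun-Blanquet scale as
#' modified by Daubenmire; class boundaries 0-5, 5-25, 25-50, 50-75, 75-95,
#' 95-100 percent) to the class midpoint in percent cover.
#'
#' @param coverClass integer vector with values in 1..6.
#' @return numeric percent cover midpoint(s).
#' @examples
#' daubenmireMidpoint(1:6)  # 2.5 15 37.5 62.5 85 97.5
#' @export
daubenmireMidpoint <- function(coverClass) {
  midpoints <- c(2.5, 15.0, 37.5, 62.5, 85.0, 97.5)
  cc <- as.numeric(coverClass)
  ok <- is.na(cc) | (cc %in% 1:6)
  if (!all(ok))
    stopWithClass(paste0("cover class outside 1..6: ",
                         paste(unique(cc[!ok]), collapse = ", ")),
                  "phytosurvey_domain_error")
  midpoints[cc]
}

#' Per-site phytosociological statistics
#'
#' Computes, for every (site, species) pair, the seven quadrat statistics of
#' classical phytosociology:
#' \describe{
#'   \item{frequency}{100 x quadrats containing the species / quadrats
#'     sampled at the site (the species' own layer).}
#'   \item{density}{100 x summed individuals / total area sampled for the
#'     species' layer (quadrats x layer area, m^2), i.e. individuals per
#'     100 m^2.}
#'   \item{cover}{percent cover, from Daubenmire class midpoints averaged
#'     over the site's quadrats (absent quadrats count as zero), from
#'     line-intercept lengths, or absent.}
#'   \item{composition}{100 x individuals of the species / individuals of
#'     all species at the site.}
#'   \item{relative_frequency, relative_cover}{frequency and cover as a
#'     percentage of their site totals across species, so each sums to 100
#'     within a site.}
#'   \item{relative_density}{100 x individuals of the species / individuals
#'     of all species at the site (the classical area-free form, which also
#'     sums to 100; within a single layer it coincides with
#'     density / site-total density).}
#' }
#'
#' Species lacking cover information are excluded from the relative-cover
#' normalisation (missing is not zero); their \code{cover} and
#' \code{relative_cover} are \code{NA}.
#'
#' @param dataset a [SurveyDataset-class].
#' @param coverSource \code{"class_midpoint"} (default), \code{"intercept"}
#'   or \code{"none"}.
#' @param transectLength named numeric per site (metres) used as the
#'   line-intercept cover denominator; if \code{NULL}, the site's total
#'   intercept length across species is used (cover then coincides with
#'   relative cover).
#' @return data.frame with one row per (site, species): columns \code{site},
#'   \code{species}, \code{habit}, \code{frequency}, \code{density},
#'   \code{cover}, \code{composition}, \code{relative_frequency},
#'   \code{relative_density}, \code{relative_cover}.
#' @examples
#' obs <- data.frame(site = "S1", quadrat = rep(c("q1","q2","q3","q4"), 2),
#'                   species = rep(c("Poa annua", "Cyperus iria"), each = 4),
#'                   habit = "herb", count = c(2, 1, 2, 1, 1, 1, 0, 0))
#' obs <- obs[obs$count > 0, ]
#' computePhytosociology(SurveyDataset(obs), coverSource = "none")
#' @export
computePhytosociology <- function(dataset,
                                  coverSource = c("class_midpoint",
                                                  "intercept", "none"),
                                  transectLength = NULL) {
  coverSource <- match.arg(coverSource)
  stopifnot(is(dataset, "SurveyDataset"))
  obs <- observations(dataset)
  if (nrow(obs) == 0)
    stopWithClass("dataset has no observations", "phytosurvey_empty_error")
  areas <- layerAreas(dataset)
  qps <- quadratsPerSite(dataset)

  out <- do.call(rbind, lapply(split(obs, obs$site), function(so) {
    site <- so$site[1]
    nq <- qps[[site]]
    if (is.na(nq) || nq < 1)
      stopWithClass(paste0("no quadrats recorded for site ", site),
                    "phytosurvey_undefined_frequency_error")
    total_n <- sum(so$count)
    if (total_n <= 0)
      stopWithClass(paste0("site ", site, " has zero total individuals; ",
                           "relative measures undefined"),
                    "phytosurvey_undefined_relative_error")
    per_sp <- split(so, so$species)
    rows <- do.call(rbind, lapply(per_sp, function(sp) {
      habit <- sp$habit[1]
      n <- sum(sp$count)
      freq <- 100 * length(unique(sp$quadrat[sp$count > 0])) / nq
      dens <- 100 * n / (nq * areas[[habit]])
      cov <- switch(coverSource,
        none = NA_real_,
        class_midpoint = {
          cc <- sp$cover_class[!is.na(sp$cover_class)]
          if (length(cc) == 0) NA_real_
          else sum(daubenmireMidpoint(cc)) / nq
        },
        intercept = {
          il <- sp$intercept_length[!is.na(sp$intercept_length)]
          if (length(il) == 0) NA_real_ else sum(il)
        })
      data.frame(site = site, species = sp$species[1], habit = habit,
                 frequency = freq, density = dens, cover = cov,
                 composition = 100 * n / total_n,
                 stringsAsFactors = FALSE)
    }))
    if (coverSource == "intercept") {
      denom <- if (!is.null(transectLength)) transectLength[[site]]
               else sum(rows$cover, na.rm = TRUE)
      if (is.null(denom) || is.na(denom) || denom <= 0)
        stopWithClass(paste0("no intercept denominator for site ", site),
                      "phytosurvey_undefined_relative_error")
      rows$cover <- 100 * rows$cover / denom
    }
    rows$relative_frequency <- 100 * rows$frequency / sum(rows$frequency)
    # individuals of the species over individuals of all species (the
    # classical area-free form); within a single layer this equals
    # density / site total density
    rows$relative_density <- rows$composition
    covered <- !is.na(rows$cover)
    rows$relative_cover <- NA_real_
    if (any(covered))
      rows$relative_cover[covered] <-
        100 * rows$cover[covered] / sum(rows$cover[covered])
    rows
  }))
  rownames(out) <- NULL
  out[order(out$site, out$species), ]
}
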