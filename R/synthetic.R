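#' Configuration for the synthetic survey generator
#'
#' Defaults emulate the reference study design: 12 sites x 4 quadrats (48
#' quadrats), a 120-species pool with a 89/16/15 herb/shrub/tree mix,
#' per-site richness drawn uniformly in 18..45, and a soil assignment of 8
#' loam, 2 clay-loam, 1 sandy-loam and 1 sand site.
#'
#' @param nSites number of sites.
#' @param quadratsPerSite quadrats sampled per site (all layers).
#' @param speciesPool size of the regional species pool.
#' @param siteRichnessRange integer pair, uniform range of per-site species
#'   counts.
#' @param habitProportions named fractions over herb/shrub/tree (sum 1);
#'   realised as fixed pool counts by largest-remainder rounding.
#' @param soilAssignment character vector of length \code{nSites}, texture
#'   per site.
#' @param effectSize delta >= 0: species preferred by a site's texture group
#'   are favoured in site composition by a factor exp(delta); 0 gives a
#'   fully exchangeable (null) community.
#' @param abundanceMeanlog,abundanceSdlog mean and sd of per-species
#'   log-abundance (the site-level abundance of a present species is
#'   log-normal with these marginal parameters, split equally between a
#'   persistent species effect and site-level noise).
#' @param seed integer; single source of randomness (sub-streams per stage).
#' @return a \code{list} of class \code{"SimConfig"}.
#' @export
simConfig <- function(nSites = 12L,
                      quadratsPerSite = 4L,
                      speciesPool = 120L,
                      siteRichnessRange = c(18L, 45L),
                      habitProportions = c(herb = 89, shrub = 16,
                                           tree = 15) / 120,
                      soilAssignment = NULL,
                      effectSize = 0,
                      abundanceMeanlog = 1.0,
                      abundanceSdlog = 0.8,
                      seed = 1L) {
  if (is.null(soilAssignment)) {
    soilAssignment <- rep("loam", nSites)
    if (nSites >= 12) {
      soilAssignment[c(2, 7)] <- "clay_loam"
      soilAssignment[8] <- "sandy_loam"
      soilAssignment[10] <- "sand"
    } else if (nSites >= 4) {
      soilAssignment[seq_len(2)] <- c("clay_loam", "sandy_loam")
    }
  }
  if (length(soilAssignment) != nSites)
    stopWithClass("soilAssignment must give one texture per site",
                  "phytosurvey_config_error")
  if (abs(sum(habitProportions) - 1) > 1e-8)
    stopWithClass("habitProportions must sum to 1",
                  "phytosurvey_config_error")
  if (siteRichnessRange[1] < 1 || siteRichnessRange[2] > speciesPool ||
      siteRichnessRange[1] > siteRichnessRange[2])
    stopWithClass("siteRichnessRange must lie within [1, speciesPool]",
                  "phytosurvey_config_error")
  if (effectSize < 0)
    stopWithClass("effectSize must be >= 0", "phytosurvey_config_error")
  structure(list(nSites = as.integer(nSites),
                 quadratsPerSite = as.integer(quadratsPerSite),
                 speciesPool = as.integer(speciesPool),
                 siteRichnessRange = as.integer(siteRichnessRange),
                 habitProportions = habitProportions,
                 soilAssignment = soilAssignment,
                 effectSize = effectSize,
                 abundanceMeanlog = abundanceMeanlog,
                 abundanceSdlog = abundanceSdlog,
                 seed = as.integer(seed)),
            class = "SimConfig")
}

# largest-remainder allocation of n items to parents in given proportions
allocateCounts <- function(n, props) {
  raw <- n * props
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  base
}

#' Generate a seeded synthetic quadrat survey
#'
#' Draws a multi-site, multi-layer quadrat survey with the statistical
#' structure the downstream analyses assume.  Stages (each on its own
#' sub-stream of \code{config$seed}, so a stage can be regenerated
#' independently):
#' \enumerate{
#'   \item pool setup: fixed habit, life cycle, family and texture-preference
#'     block per species; persistent species log-abundance effect; Daubenmire
#'     cover class assigned by abundance rank (commoner species get higher
#'     classes);
#'   \item site composition: per-site richness uniform in the configured
#'     range; species sampled without replacement with weight exp(delta) for
#'     the site texture's preferred block;
#'   \item site-level abundances: log-normal around the species effect,
#'     rounded up to at least one individual;
#'   \item quadrat scatter: individuals split over quadrats multinomially
#'     (uniform);
#'   \item soil covariates: texture from the configuration, numeric
#'     covariates near the reference survey's reported values
#'     (pH ~ N(8.2, 0.2), K ~ N(130, 25) ppm, ...).
#' }
#'
#' @param config a [simConfig()] object.
#' @return list with elements \code{dataset} (a [SurveyDataset-class]) and
#'   \code{soil} (a soil data.frame as from [readSoilTable()]).
#' @examples
#' sim <- simulateSurvey(simConfig(seed = 1))
#' sim$dataset
#' @export
simulateSurvey <- function(config = simConfig()) {
  stopifnot(inherits(config, "SimConfig"))
  P <- config$speciesPool
  textures <- unique(config$soilAssignment)

  # stage 1: species pool
  pool <- withSeed(deriveSeed(config$seed, 1L), {
    habit_counts <- allocateCounts(P, config$habitProportions)
    habit <- rep(names(config$habitProportions), habit_counts)
    n_fam <- max(1L, round(P * 51 / 120))
    data.frame(
      species = sprintf("Genus%03d specium%03d",
                        ceiling(seq_len(P) * 0.875), seq_len(P)),
      family = sample(sprintf("Family%02d", seq_len(n_fam)), P,
                      replace = TRUE),
      habit = sample(habit),
      life_cycle = sample(c("annual", "perennial"), P, replace = TRUE),
      pref_texture = rep_len(textures, P),
      log_effect = stats::rnorm(P, config$abundanceMeanlog,
                                config$abundanceSdlog / sqrt(2)),
      stringsAsFactors = FALSE)
  })
  # visual cover estimation tracks abundance only loosely: the cover class
  # ranks a latent score with a 0.5 loading on the species abundance effect
  pool$cover_class <- withSeed(deriveSeed(config$seed, 6L), {
    z <- scale(pool$log_effect)[, 1]
    latent <- 0.5 * z + sqrt(1 - 0.25) * stats::rnorm(P)
    as.integer(cut(rank(latent, ties.method = "first"),
                   breaks = 6, labels = FALSE))
  })

  sites <- sprintf("S%02d", seq_len(config$nSites))

  # stage 2: which species occur at each site
  occupancy <- withSeed(deriveSeed(config$seed, 2L), {
    lapply(seq_len(config$nSites), function(i) {
      rich <- sample(seq(config$siteRichnessRange[1],
                         config$siteRichnessRange[2]), 1)
      w <- ifelse(pool$pref_texture == config$soilAssignment[i],
                  exp(config$effectSize), 1)
      sort(sample.int(P, rich, prob = w))
    })
  })

  # stage 3: site-level abundances
  abundances <- withSeed(deriveSeed(config$seed, 3L), {
    lapply(seq_len(config$nSites), function(i) {
      idx <- occupancy[[i]]
      pmax(1, ceiling(exp(stats::rnorm(length(idx), pool$log_effect[idx],
                                       config$abundanceSdlog / sqrt(2)))))
    })
  })

  # stage 4: scatter individuals over quadrats
  q <- config$quadratsPerSite
  obs <- withSeed(deriveSeed(config$seed, 4L), {
    do.call(rbind, lapply(seq_len(config$nSites), function(i) {
      idx <- occupancy[[i]]
      split_counts <- vapply(abundances[[i]], function(n)
        as.vector(stats::rmultinom(1, n, rep(1 / q, q))), numeric(q))
      # split_counts: q x length(idx)
      keep <- split_counts > 0
      data.frame(
        site = sites[i],
        quadrat = rep(sprintf("Q%d", seq_len(q)), times = length(idx))[keep],
        species = rep(pool$species[idx], each = q)[keep],
        family = rep(pool$family[idx], each = q)[keep],
        habit = rep(pool$habit[idx], each = q)[keep],
        life_cycle = rep(pool$life_cycle[idx], each = q)[keep],
        count = split_counts[keep],
        cover_class = rep(pool$cover_class[idx], each = q)[keep],
        stringsAsFactors = FALSE)
    }))
  })

  # stage 5: soil covariates near the reference survey's reported values
  rtrunc <- function(n, mean, sd, lo, hi) pmin(hi, pmax(lo,
    stats::rnorm(n, mean, sd)))
  soil <- withSeed(deriveSeed(config$seed, 5L), {
    n <- config$nSites
    data.frame(site = sites,
               texture = config$soilAssignment,
               moisture = round(rtrunc(n, 30, 8, 5, 60), 1),
               pH = round(rtrunc(n, 8.2, 0.2, 6.5, 9.5), 2),
               EC = round(rtrunc(n, 0.6, 0.25, 0.05, 2), 2),
               OM = round(rtrunc(n, 0.7, 0.1, 0.1, 3), 2),
               P = round(rtrunc(n, 6, 1.5, 0.5, 20), 1),
               K = round(rtrunc(n, 130, 25, 50, 300)),
               stringsAsFactors = FALSE)
  })

  qps <- rep(config$quadratsPerSite, config$nSites)
  names(qps) <- sites
  list(dataset = SurveyDataset(obs, quadratsPerSite = qps), soil = soil,
       config = config)
}

#' Write a simulated survey to disk
#'
#' Emits \code{quadrats.csv}, \code{soil.csv} and a \code{sim_config.json}
#' echo of the generating configuration.  Byte-identical across reruns with
#' the same configuration.
#'
#' @param sim output of [simulateSurvey()].
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeSimulatedSurvey <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeQuadratTable(sim$dataset, file.path(dir, "quadrats.csv"))
  utils::write.csv(sim$soil, file.path(dir, "soil.csv"), row.names = FALSE)
  jsonlite::write_json(unclass(sim$config),
                       file.path(dir, "sim_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Synthetic species checklist with the reference survey's marginal totals
#'
#' A deterministic stand-in for the study's species checklist (which is not
#' machine-readable in the source): 120 species in 105 genera and 51
#' families, split into 96 dicots (40 families, 85 genera), 17 monocots
#' (4 families, 13 genera), 6 pteridophytes and 1 bryophyte, with a habit
#' mix of 89 herbs, 16 shrubs and 15 trees.  Names are synthetic; only the
#' counting structure matches the published totals.
#'
#' @return data.frame: \code{species} (binomial), \code{family},
#'   \code{habit}, \code{group}.
#' @export
syntheticChecklist <- function() {
  build <- function(prefix, n_species, n_genera, n_families) {
    genus_per_family <- allocateCounts(n_genera, rep(1 / n_families,
                                                     n_families))
    family_of_genus <- rep(seq_len(n_families), genus_per_family)
    species_per_genus <- allocateCounts(n_species, rep(1 / n_genera,
                                                       n_genera))
    genus_of_species <- rep(seq_len(n_genera), species_per_genus)
    data.frame(
      species = sprintf("%sgenus%03d epitheton%03d", prefix,
                        genus_of_species, seq_len(n_species)),
      family = sprintf("%sfamily%02d", prefix,
                       family_of_genus[genus_of_species]),
      stringsAsFactors = FALSE)
  }
  dicots <- build("Di", 96, 85, 40)
  dicots$habit <- c(rep("tree", 15), rep("shrub", 16), rep("herb", 65))
  dicots$group <- "dicot"
  monocots <- build("Mono", 17, 13, 4)
  monocots$habit <- "herb"
  monocots$group <- "monocot"
  ferns <- build("Pterido", 6, 6, 6)
  ferns$habit <- "herb"
  ferns$group <- "pteridophyte"
  moss <- build("Bryo", 1, 1, 1)
  moss$habit <- "herb"
  moss$group <- "bryophyte"
  out <- rbind(dicots, monocots, ferns, moss)
  out$species <- normalizeSpeciesNames(out$species)
  out
}
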