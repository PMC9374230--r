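test_that("Daubenmire midpoints follow the fixed class table", {
  expect_equal(daubenmireMidpoint(1:6),
               c(2.5, 15.0, 37.5, 62.5, 85.0, 97.5))
  expect_error(daubenmireMidpoint(7), class = "phytosurvey_domain_error")
  expect_error(daubenmireMidpoint(0), class = "phytosurvey_domain_error")
})

test_that("two-herb hand example reproduces the printed formulas", {
  # counts 6 and 2 across 4 quadrats of 1 m^2; second species in 2/4 quadrats
  obs <- data.frame(
    site = "S1",
    quadrat = c("q1", "q2", "q3", "q4", "q1", "q2"),
    species = c(rep("Poa annua", 4), rep("Cyperus iria", 2)),
    habit = "herb",
    count = c(2, 1, 2, 1, 1, 1))
  phy <- computePhytosociology(SurveyDataset(obs), coverSource = "none")
  poa <- phy[phy$species == "Poa annua", ]
  cyp <- phy[phy$species == "Cyperus iria", ]
  expect_equal(poa$density, 150)   # 100 * 6 / 4 m^2
  expect_equal(cyp$density, 50)
  expect_equal(poa$relative_density, 75)
  expect_equal(cyp$relative_density, 25)
  expect_equal(cyp$frequency, 50)  # present in 2 of 4 quadrats
  expect_equal(poa$frequency, 100)
})

test_that("a single species present everywhere scores 100 on all measures", {
  obs <- data.frame(site = "S1", quadrat = paste0("q", 1:4),
                    species = "Poa annua", habit = "herb", count = 3)
  phy <- computePhytosociology(SurveyDataset(obs), coverSource = "none")
  expect_equal(phy$frequency, 100)
  expect_equal(phy$relative_frequency, 100)
  expect_equal(phy$relative_density, 100)
  expect_equal(phy$composition, 100)
})

test_that("relative measures sum to 100 per site and are scale-invariant", {
  sim <- simulateSurvey(simConfig(seed = 3))
  phy <- computePhytosociology(sim$dataset)
  sums <- aggregate(
    phy[, c("relative_frequency", "relative_density", "composition")],
    by = list(site = phy$site), FUN = sum)
  expect_true(all(abs(sums$relative_frequency - 100) < 1e-9))
  expect_true(all(abs(sums$relative_density - 100) < 1e-9))
  expect_true(all(abs(sums$composition - 100) < 1e-9))
  rc <- aggregate(phy$relative_cover, by = list(site = phy$site),
                  FUN = function(v) sum(v, na.rm = TRUE))
  expect_true(all(abs(rc$x - 100) < 1e-9))

  # multiply all counts at every site by 7: relative forms unchanged
  obs <- observations(sim$dataset)
  obs$count <- obs$count * 7
  phy7 <- computePhytosociology(
    SurveyDataset(obs, quadratsPerSite = quadratsPerSite(sim$dataset)))
  for (col in c("relative_frequency", "relative_density",
                "relative_cover", "composition"))
    expect_equal(phy7[[col]], phy[[col]], tolerance = 1e-12)
})

test_that("frequency is invariant to permuting quadrat labels", {
  obs <- toyObservations()
  phy1 <- computePhytosociology(SurveyDataset(obs), coverSource = "none")
  relabel <- c(q1 = "q3", q2 = "q4", q3 = "q2", q4 = "q1")
  obs2 <- obs
  obs2$quadrat <- unname(relabel[obs$quadrat])
  phy2 <- computePhytosociology(SurveyDataset(obs2), coverSource = "none")
  expect_equal(phy1$frequency, phy2$frequency)
})

test_that("density uses the layer's own quadrat area", {
  obs <- data.frame(site = "S1", quadrat = c("q1", "q1"),
                    species = c("Poa annua", "Acacia nilotica"),
                    habit = c("herb", "tree"), count = c(10, 10))
  phy <- computePhytosociology(
    SurveyDataset(obs, quadratsPerSite = c(S1 = 1L)), coverSource = "none")
  expect_equal(phy$density[phy$habit == "herb"], 1000)  # 10 per 1 m^2
  expect_equal(phy$density[phy$habit == "tree"], 10)    # 10 per 100 m^2
})

test_that("cover comes from class midpoints, missing cover is not zero", {
  obs <- data.frame(site = "S1", quadrat = c("q1", "q2", "q1"),
                    species = c("Poa annua", "Poa annua", "Cyperus iria"),
                    habit = "herb", count = 1,
                    cover_class = c(4, 2, NA))
  phy <- computePhytosociology(
    SurveyDataset(obs, quadratsPerSite = c(S1 = 2L)))
  poa <- phy[phy$species == "Poa annua", ]
  expect_equal(poa$cover, (62.5 + 15) / 2)
  # species without cover information: NA cover, excluded from RC
  cyp <- phy[phy$species == "Cyperus iria", ]
  expect_true(is.na(cyp$cover) && is.na(cyp$relative_cover))
  expect_equal(poa$relative_cover, 100)
})

test_that("intercept cover uses the transect denominator", {
  obs <- data.frame(site = "S1", quadrat = "q1",
                    species = c("Poa annua", "Cyperus iria"),
                    habit = "herb", count = c(1, 1),
                    intercept_length = c(3, 1))
  ds <- SurveyDataset(obs, quadratsPerSite = c(S1 = 1L))
  phy <- computePhytosociology(ds, coverSource = "intercept",
                               transectLength = c(S1 = 10))
  expect_equal(sort(phy$cover), c(10, 30))
  expect_equal(sort(phy$relative_cover), c(25, 75))
  # default denominator: total intercept, cover == relative cover
  phy2 <- computePhytosociology(ds, coverSource = "intercept")
  expect_equal(phy2$cover, phy2$relative_cover)
})

test_that("degenerate sites are rejected with informative errors", {
  obs <- data.frame(site = "S1", quadrat = "q1", species = "Poa annua",
                    habit = "herb", count = 0)
  expect_error(
    computePhytosociology(SurveyDataset(obs), coverSource = "none"),
    class = "phytosurvey_undefined_relative_error")
})
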