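test_that("Shannon index matches direct summation and closed forms", {
  expect_equal(shannonIndex(10), 0)
  expect_equal(shannonIndex(c(5, 5, 5, 5)), log(4))
  # direct -sum(p log p) oracle for a skewed vector
  x <- c(4, 3, 2, 1)
  p <- x / sum(x)
  expect_equal(shannonIndex(x), -sum(p * log(p)))
  expect_equal(shannonIndex(x), 1.279854, tolerance = 1e-6)
  expect_equal(shannonIndex(c(0, 7, 0, 3)), shannonIndex(c(7, 3)))
  expect_error(shannonIndex(c(0, 0)),
               class = "phytosurvey_undefined_index_error")
})

test_that("Simpson index supports gini and dominance forms", {
  expect_equal(simpsonIndex(10), 0)
  expect_equal(simpsonIndex(c(5, 5, 5, 5)), 0.75)
  expect_equal(simpsonIndex(c(4, 3, 2, 1)), 1 - (0.16 + 0.09 + 0.04 + 0.01))
  expect_equal(simpsonIndex(c(4, 3, 2, 1), "dominance"), 0.30)
  expect_error(simpsonIndex(numeric(0)),
               class = "phytosurvey_undefined_index_error")
})

test_that("alpha indices agree with the vegan reference implementation", {
  skip_if_not_installed("vegan")
  set.seed(42)
  for (i in 1:5) {
    x <- rpois(20, 5) + 1
    expect_equal(shannonIndex(x), unname(vegan::diversity(x, "shannon")))
    expect_equal(simpsonIndex(x), unname(vegan::diversity(x, "simpson")))
  }
})

test_that("Pielou evenness is H / ln S with its domain rules", {
  expect_equal(pielouEvenness(c(7, 7, 7)), 1)
  expect_equal(pielouEvenness(c(4, 3, 2, 1)), 1.279854 / log(4),
               tolerance = 1e-6)
  expect_error(pielouEvenness(1), class = "phytosurvey_undefined_index_error")
})

test_that("richness indices implement all three formulas", {
  expect_equal(richnessIndex(1, 50, "margalef_ln"), 0)
  expect_equal(richnessIndex(45, 95, "margalef_log10"), 44 / log10(95))
  expect_equal(richnessIndex(45, 95, "margalef_log10"), 22.25,
               tolerance = 2e-4)
  expect_equal(richnessIndex(16, 64, "menhinick"), 2)
  expect_error(richnessIndex(2, 1), class = "phytosurvey_domain_error")
  expect_error(richnessIndex(1, 1, "margalef_ln"),
               class = "phytosurvey_undefined_index_error")
})

test_that("uniform vectors maximise H and gini-Simpson; merging decreases both", {
  set.seed(7)
  for (i in 1:20) {
    S <- sample(2:15, 1)
    x <- rpois(S, 10) + 1
    expect_lte(shannonIndex(x), log(S) + 1e-12)
    expect_lte(simpsonIndex(x), 1 - 1 / S + 1e-12)
    # merge two equal-abundance species -> strictly lower diversity
    y <- c(x, x[1])          # duplicate abundance
    merged <- c(x[-1], 2 * x[1])
    expect_lt(shannonIndex(merged), shannonIndex(y))
    expect_lt(simpsonIndex(merged), simpsonIndex(y))
  }
})

test_that("diversity table applies the indices row-wise", {
  m <- rbind(site1 = c(5, 5), site2 = c(9, 1))
  dt <- diversityTable(m)
  expect_equal(dt$shannon, c(log(2), 0.325083), tolerance = 1e-6)
  expect_equal(dt$S, c(2L, 2L))
  expect_equal(dt$N, c(10, 10))
  # identical rows give identical index rows
  m2 <- rbind(a = c(3, 2, 1), b = c(3, 2, 1))
  dt2 <- diversityTable(m2)
  expect_equal(dt2[1, -1], dt2[2, -1], ignore_attr = TRUE)
  expect_error(diversityTable(rbind(a = c(0, 0), b = c(1, 1))),
               class = "phytosurvey_undefined_index_error")
})

test_that("diversity table on a synthetic survey satisfies the invariants", {
  sim <- simulateSurvey(simConfig(seed = 5))
  dt <- diversityTable(buildCommunityMatrix(sim$dataset))
  expect_equal(nrow(dt), 12L)
  expect_true(all(dt$shannon >= 0 & dt$shannon <= log(dt$S) + 1e-12))
  expect_true(all(dt$simpson >= 0 & dt$simpson <= 1))
  expect_true(all(dt$evenness >= 0 & dt$evenness <= 1))
  expect_true(all(dt$S >= 1))
})

test_that("Wilcoxon rank-sum: exact enumeration, ties, and mode selection", {
  w <- wilcoxonRankSum(c(1, 2), c(3, 4))
  expect_equal(w$p_value, 1 / 3, tolerance = 1e-12)
  expect_equal(w$method, "exact")
  # identical groups with ties -> normal approximation, p = 1
  w2 <- wilcoxonRankSum(c(2, 2, 2), c(2, 2, 2))
  expect_equal(w2$method, "normal_approx")
  expect_equal(w2$p_value, 1)
  # above the auto threshold the normal path is taken
  w3 <- wilcoxonRankSum(seq(0.5, 7, 1), 1:8)
  expect_equal(w3$method, "normal_approx")
  expect_error(wilcoxonRankSum(numeric(0), 1),
               class = "phytosurvey_empty_error")
})

test_that("exact Wilcoxon p equals the enumeration oracle (exhaustive n <= 8)", {
  set.seed(1)
  for (n1 in 1:4) for (n2 in n1:(8 - n1)) {
    for (rep in 1:3) {
      vals <- sample(100, n1 + n2)   # tie-free
      x <- vals[seq_len(n1)]
      y <- vals[-seq_len(n1)]
      expect_equal(wilcoxonRankSum(x, y, mode = "exact")$p_value,
                   enumWilcoxonP(x, y), tolerance = 1e-12,
                   info = paste("n1 =", n1, "n2 =", n2))
    }
  }
})

test_that("exact and normal Wilcoxon p agree for moderate tie-free samples", {
  set.seed(2)
  for (rep in 1:10) {
    vals <- sample(1000, 12)
    x <- vals[1:6]; y <- vals[7:12]
    pe <- wilcoxonRankSum(x, y, mode = "exact")$p_value
    pn <- wilcoxonRankSum(x, y, mode = "normal")$p_value
    expect_lt(abs(pe - pn), 0.05)
  }
})

test_that("group comparisons cover every texture pair", {
  sim <- simulateSurvey(simConfig(seed = 9))
  dt <- diversityTable(buildCommunityMatrix(sim$dataset))
  gc <- groupComparisonTable(dt, sim$soil)
  expect_equal(nrow(gc), choose(4, 2))
  expect_true(all(gc$p_value > 0 & gc$p_value <= 1))
})
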