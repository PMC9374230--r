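test_that("log10(x+1) maps counts as expected and rejects negatives", {
  m <- rbind(a = c(0, 9), b = c(99, 1))
  t <- log10Plus1(m)
  expect_equal(t, rbind(a = c(0, 1), b = c(2, log10(2))))
  expect_error(log10Plus1(rbind(a = -1, b = 1)),
               class = "phytosurvey_domain_error")
  # CommunityMatrix in, CommunityMatrix out
  sim <- simulateSurvey(simConfig(seed = 2))
  cm <- buildCommunityMatrix(sim$dataset)
  expect_s4_class(log10Plus1(cm), "CommunityMatrix")
})

test_that("Bray-Curtis matches hand values and the vegan oracle", {
  expect_equal(brayCurtis(rbind(a = c(2, 0, 1), b = c(1, 1, 0)))["a", "b"],
               0.6)
  expect_equal(brayCurtis(rbind(a = c(2, 0), b = c(0, 3)))["a", "b"], 1)
  expect_equal(brayCurtis(rbind(a = c(1, 2), b = c(1, 2)))["a", "b"], 0)

  skip_if_not_installed("vegan")
  set.seed(10)
  m <- matrix(rpois(60, 4), nrow = 6,
              dimnames = list(paste0("s", 1:6), paste0("sp", 1:10)))
  m[1, ] <- m[1, ] + 1  # guard against zero rows
  expect_equal(brayCurtis(m),
               as.matrix(vegan::vegdist(m, "bray")),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("Bray-Curtis is invariant to column order and zero columns", {
  set.seed(11)
  m <- matrix(rpois(40, 3) + 1, nrow = 4,
              dimnames = list(paste0("s", 1:4), paste0("sp", 1:10)))
  d <- brayCurtis(m)
  expect_equal(brayCurtis(m[, sample(ncol(m))]), d)
  expect_equal(brayCurtis(cbind(m, zzz = 0)), d)
  expect_error(brayCurtis(rbind(a = c(1, 2), b = c(0, 0))),
               class = "phytosurvey_undefined_dissimilarity_error")
  expect_error(brayCurtis(rbind(a = c(1, 2), b = c(0, 0))), "b")
})

test_that("PERMANOVA matches vegan::adonis2 on F and R2", {
  skip_if_not_installed("vegan")
  set.seed(12)
  m <- matrix(rpois(120, 6) + 1, nrow = 12)
  rownames(m) <- paste0("s", 1:12)
  colnames(m) <- paste0("sp", 1:10)
  groups <- rep(c("a", "b", "c"), each = 4)
  d <- brayCurtis(m)
  res <- permanova(d, groups, nPermutations = 199, seed = 1)
  ad <- vegan::adonis2(as.dist(d) ~ g, data = data.frame(g = groups),
                       permutations = 199)
  expect_equal(pseudoF(res), ad$F[1], tolerance = 1e-10)
  expect_equal(rSquared(res), ad$R2[1], tolerance = 1e-10)
  expect_equal(res@dfBetween, ad$Df[1])
  expect_equal(res@dfWithin, ad$Df[2])
})

test_that("PERMANOVA on perfectly separated clusters matches enumeration", {
  # within-distance 0, between-distance 1, 3 + 3 rows: only the original
  # partition (and its relabeling) separates, so the exhaustive p is
  # 2 / choose(6, 3) = 0.1; the sampled p estimates it
  d <- matrix(1, 6, 6)
  d[1:3, 1:3] <- 0
  d[4:6, 4:6] <- 0
  dimnames(d) <- list(paste0("r", 1:6), paste0("r", 1:6))
  res <- permanova(d, rep(c("x", "y"), each = 3),
                   nPermutations = 999, seed = 42)
  expect_true(is.infinite(pseudoF(res)))
  expect_equal(rSquared(res), 1)
  expect_lt(abs(pValue(res) - 0.1), 0.04)
})

test_that("PERMANOVA p is invariant to group names, F to the seed", {
  set.seed(13)
  m <- matrix(rpois(80, 5) + 1, nrow = 8,
              dimnames = list(paste0("s", 1:8), paste0("sp", 1:10)))
  d <- brayCurtis(m)
  g1 <- rep(c("a", "b"), each = 4)
  g2 <- rep(c("zebra", "yak"), each = 4)
  r1 <- permanova(d, g1, 199, seed = 5)
  r2 <- permanova(d, g2, 199, seed = 5)
  expect_equal(pValue(r1), pValue(r2))
  expect_equal(pseudoF(r1), pseudoF(r2))
  r3 <- permanova(d, g1, 199, seed = 99)
  expect_equal(pseudoF(r3), pseudoF(r1))  # statistic free of the seed
})

test_that("PERMANOVA rejects degenerate designs and missing seeds", {
  d <- as.matrix(dist(1:4)); dimnames(d) <- list(1:4, 1:4)
  expect_error(permanova(d, rep("a", 4), 199, seed = 1),
               class = "phytosurvey_degenerate_design_error")
  expect_error(permanova(d, c("a", "a", "b", "b"), 199),
               class = "phytosurvey_domain_error")
  expect_error(permanova(d, c("a", "a", "b", "b"), 9, seed = 1),
               class = "phytosurvey_domain_error")
})

test_that("PCoA reproduces Euclidean configurations within 1e-8", {
  pd <- planarDistances(10, seed = 21)
  res <- pcoa(pd$d)
  expect_equal(as.matrix(dist(scores(res))), pd$d,
               tolerance = 1e-8, ignore_attr = TRUE)
  # eigenvalues non-increasing, proportions sum to 1 over positive axes
  expect_true(all(diff(eigenvalues(res)) <= 1e-12))
  expect_equal(sum(proportionExplained(res)), 1)
  expect_equal(res@negativeEigenvalueMass, 0, tolerance = 1e-8)
})

test_that("PCoA of an equilateral triangle gives two equal axes", {
  d <- matrix(1, 3, 3) - diag(3)
  dimnames(d) <- list(letters[1:3], letters[1:3])
  res <- pcoa(d)
  ev <- eigenvalues(res)
  expect_equal(ev, c(0.5, 0.5), tolerance = 1e-10)  # zero axis dropped
  # cross-check the spectrum against base cmdscale
  ref <- cmdscale(as.dist(d), k = 2, eig = TRUE)$eig
  expect_equal(ev, ref[1:2], tolerance = 1e-10)
})

test_that("PCoA agrees with ape::pcoa, including the Cailliez correction", {
  skip_if_not_installed("ape")
  set.seed(21)  # sparse counts: Bray-Curtis here is non-Euclidean
  m <- matrix(rpois(70, 1.2), nrow = 7,
              dimnames = list(paste0("s", 1:7), paste0("sp", 1:10)))
  m[rowSums(m) == 0, 1] <- 1
  d <- brayCurtis(m)
  res <- pcoa(d)
  ref <- ape::pcoa(as.dist(d))
  npos <- ncol(scores(res))
  expect_equal(eigenvalues(res)[seq_len(npos)],
               ref$values$Eigenvalues[seq_len(npos)], tolerance = 1e-8)
  expect_true(res@negativeEigenvalueMass > 0)  # Bray-Curtis is non-Euclidean
  # Cailliez-corrected distances are Euclidean: no negative mass remains
  resc <- pcoa(d, correction = "cailliez")
  expect_equal(resc@negativeEigenvalueMass, 0, tolerance = 1e-6)
  refc <- ape::pcoa(as.dist(d), correction = "cailliez")
  k <- min(3, ncol(scores(resc)))
  expect_equal(abs(cor(scores(resc)[, 1], refc$vectors.cor[, 1])), 1,
               tolerance = 1e-6)
})

test_that("duplicated rows coincide in the ordination", {
  pd <- planarDistances(5, seed = 23)
  d <- pd$d
  d <- rbind(cbind(d, d[, 3]), c(d[3, ], 0))
  labs <- c(rownames(pd$d), "dup")
  dimnames(d) <- list(labs, labs)
  res <- pcoa(d)
  expect_equal(scores(res)["dup", ], scores(res)["p3", ], tolerance = 1e-8)
  expect_error(pcoa(d[1:2, 1:2]),
               class = "phytosurvey_degenerate_input_error")
})
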