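# small in-code fixtures shared across test files

toyObservations <- function() {
  data.frame(
    site = "S1",
    quadrat = c("q1", "q2", "q3", "q4", "q1", "q2"),
    species = c(rep("Poa annua", 4), rep("Cyperus iria", 2)),
    habit = "herb",
    count = c(2, 1, 2, 1, 1, 1),
    stringsAsFactors = FALSE)
}

twoSiteDataset <- function() {
  obs <- rbind(
    data.frame(site = "S1", quadrat = c("q1", "q2"),
               species = "Poa annua", habit = "herb", count = c(2, 3)),
    data.frame(site = "S1", quadrat = "q1",
               species = "Acacia nilotica", habit = "tree", count = 1),
    data.frame(site = "S2", quadrat = c("q1", "q2"),
               species = c("Cyperus iria", "Poa annua"), habit = "herb",
               count = c(4, 1)))
  SurveyDataset(obs, quadratsPerSite = c(S1 = 2L, S2 = 2L))
}

# exact two-sided Mann-Whitney p by full enumeration over rank assignments
enumWilcoxonP <- function(x, y) {
  n <- length(x) + length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  subsets <- utils::combn(n, length(x))
  u_all <- apply(subsets, 2, function(idx)
    sum(idx) - length(x) * (length(x) + 1) / 2)
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# planar point set -> Euclidean distance matrix
planarDistances <- function(n, seed) {
  set.seed(seed)
  pts <- cbind(runif(n), runif(n))
  rownames(pts) <- paste0("p", seq_len(n))
  list(points = pts, d = as.matrix(dist(pts)))
}
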