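#' log10(x + 1) abundance transform
#'
#' The standard zero-safe log10 transform for count data, applied before
#' dissimilarity computation.  Zeros map to zero.
#'
#' @param mat a [CommunityMatrix-class] or non-negative matrix.
#' @return object of the same class with transformed cells.
#' @export
log10Plus1 <- function(mat) {
  m <- as(mat, "matrix")
  if (any(m < 0))
    stopWithClass("negative abundances cannot be log-transformed",
                  "phytosurvey_domain_error")
  out <- log10(m + 1)
  if (is(mat, "CommunityMatrix"))
    new("CommunityMatrix", out, level = mat@level)
  else out
}

#' Bray-Curtis dissimilarity matrix
#'
#' BC_ij = sum_k |x_ik - x_jk| / sum_k (x_ik + x_jk) over species k.
#' All-zero species columns are pruned first (they cannot affect the
#' result).  0 for identical rows, 1 for rows with no shared species.
#'
#' @param mat a [CommunityMatrix-class] or non-negative matrix with at least
#'   two labelled rows, each with positive total.
#' @return symmetric numeric matrix with zero diagonal, cells in [0, 1],
#'   labelled like the input rows.
#' @examples
#' m <- rbind(a = c(2, 0, 1), b = c(1, 1, 0))
#' brayCurtis(m)["a", "b"]  # 3/5
#' @export
brayCurtis <- function(mat) {
  m <- as(mat, "matrix")
  if (nrow(m) < 2)
    stopWithClass("need at least two rows", "phytosurvey_empty_error")
  zero_rows <- rownames(m)[rowSums(m) <= 0]
  if (length(zero_rows) > 0)
    stopWithClass(paste0("dissimilarity undefined for all-zero row(s): ",
                         paste(zero_rows, collapse = ", ")),
                  "phytosurvey_undefined_dissimilarity_error")
  m <- m[, colSums(m) > 0, drop = FALSE]
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    xi <- m[i, ]
    for (j in (i + 1):n) {
      xj <- m[j, ]
      d[i, j] <- d[j, i] <- sum(abs(xi - xj)) / sum(xi + xj)
    }
  }
  d
}

permanovaSS <- function(d2, groups, labs) {
  N <- nrow(d2)
  ss_total <- sum(d2[upper.tri(d2)]) / N
  ss_within <- 0
  for (g in labs) {
    idx <- which(groups == g)
    if (length(idx) > 1) {
      sub <- d2[idx, idx, drop = FALSE]
      ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
    }
  }
  c(total = ss_total, within = ss_within)
}

#' One-way PERMANOVA on a dissimilarity matrix
#'
#' Permutational multivariate analysis of variance for a single grouping
#' factor (Anderson's construction): SS_total = sum of squared
#' dissimilarities over all pairs divided by N; SS_within sums the analogous
#' group-internal quantities; pseudo-F = (SS_between/(a-1)) /
#' (SS_within/(N-a)).  Significance is assessed by freely permuting whole
#' rows (group labels); the p-value is (#\{F_perm >= F_obs\} + 1) /
#' (n_permutations + 1), ties counting as at least as extreme.
#'
#' @param d symmetric dissimilarity matrix with zero diagonal (e.g. from
#'   [brayCurtis()]).
#' @param groups group label per row (length nrow(d)); at least two distinct
#'   groups.
#' @param nPermutations number of random permutations (>= 99; default 999).
#' @param seed integer seed for the permutation stream (required for
#'   reproducibility).
#' @return A [PermanovaResult-class].
#' @export
permanova <- function(d, groups, nPermutations = 999, seed) {
  d <- as.matrix(d)
  N <- nrow(d)
  if (length(groups) != N)
    stopWithClass("one group label per row is required",
                  "phytosurvey_schema_error")
  groups <- as.character(groups)
  labs <- unique(groups)
  a <- length(labs)
  if (a < 2)
    stopWithClass("PERMANOVA needs at least two groups",
                  "phytosurvey_degenerate_design_error")
  if (nPermutations < 99)
    stopWithClass("use at least 99 permutations",
                  "phytosurvey_domain_error")
  if (missing(seed))
    stopWithClass("a seed is required for the permutation stream",
                  "phytosurvey_domain_error")
  d2 <- d^2
  ss <- permanovaSS(d2, groups, labs)
  ss_between <- ss["total"] - ss["within"]
  df_b <- a - 1L
  df_w <- N - a
  f_obs <- (ss_between / df_b) / (ss["within"] / df_w)
  f_perm <- withSeed(seed, vapply(seq_len(nPermutations), function(k) {
    g <- sample(groups)
    ssk <- permanovaSS(d2, g, labs)
    ((ssk["total"] - ssk["within"]) / df_b) / (ssk["within"] / df_w)
  }, numeric(1)))
  # perfect separation gives 0/0 = NaN within permutations where it recurs;
  # treat any non-finite permuted F as at least as extreme as an infinite
  # observed F, never as extreme as a finite one
  if (is.finite(f_obs)) {
    n_ge <- sum(f_perm >= f_obs, na.rm = TRUE)
  } else {
    n_ge <- sum(!is.finite(f_perm))
  }
  p <- (n_ge + 1) / (nPermutations + 1)
  new("PermanovaResult",
      pseudoF = unname(f_obs), R2 = unname(ss_between / ss["total"]),
      dfBetween = as.integer(df_b), dfWithin = as.integer(df_w),
      ssBetween = unname(ss_between), ssWithin = unname(ss["within"]),
      ssTotal = unname(ss["total"]),
      pValue = p, nPermutations = as.integer(nPermutations),
      seed = as.integer(seed))
}

gowerCenter <- function(d) {
  n <- nrow(d)
  J <- diag(n) - matrix(1 / n, n, n)
  -0.5 * J %*% (d^2) %*% J
}

#' Principal coordinates analysis (metric multidimensional scaling)
#'
#' Embeds a dissimilarity matrix in Euclidean space: Gower double-centring
#' B = -1/2 J D^2 J, eigendecomposition, coordinates = eigenvectors scaled
#' by the square root of their (positive) eigenvalues.  Axes with
#' |eigenvalue| below 1e-10 times the largest are dropped as numerical
#' zeros.  Negative eigenvalues (non-Euclidean input) are reported as a
#' mass; the Cailliez correction adds the smallest constant to all
#' off-diagonal dissimilarities that makes the configuration Euclidean.
#'
#' @param d symmetric dissimilarity matrix, at least 3 rows.
#' @param correction \code{"none"} (default) or \code{"cailliez"}.
#' @return A [PcoaResult-class].
#' @export
pcoa <- function(d, correction = c("none", "cailliez")) {
  correction <- match.arg(correction)
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3)
    stopWithClass("PCoA needs at least three rows",
                  "phytosurvey_degenerate_input_error")
  if (correction == "cailliez")
    d <- d + cailliezConstant(d) * (1 - diag(n))
  B <- gowerCenter(d)
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  vals <- eig$values
  keep <- abs(vals) >= 1e-10 * max(abs(vals), .Machine$double.eps)
  vals <- vals[keep]
  vecs <- eig$vectors[, keep, drop = FALSE]
  pos <- vals > 0
  coords <- sweep(vecs[, pos, drop = FALSE], 2, sqrt(vals[pos]), `*`)
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("PC", seq_len(ncol(coords)))
  new("PcoaResult",
      coordinates = coords,
      eigenvalues = vals,
      proportionExplained = vals[pos] / sum(vals[pos]),
      correction = correction,
      negativeEigenvalueMass = sum(abs(vals[vals < 0])))
}

# Cailliez (1983): smallest c such that d + c (off-diagonal) is Euclidean,
# the largest real eigenvalue of the 2n x 2n block matrix below
cailliezConstant <- function(d) {
  n <- nrow(d)
  delta1 <- gowerCenter(d)
  delta2 <- {
    J <- diag(n) - matrix(1 / n, n, n)
    -0.5 * J %*% d %*% J
  }
  M <- rbind(cbind(matrix(0, n, n), 2 * delta1),
             cbind(-diag(n), -4 * delta2))
  ev <- eigen(M, only.values = TRUE)$values
  max(Re(ev[abs(Im(ev)) < 1e-8]), 0)
}
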