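#' Smouse-Peakall genotypic distance between individuals
#'
#' Per locus, the squared distance is half the squared Euclidean distance
#' between allele-count vectors, giving the canonical codominant values
#' AA-AA = 0, AA-AB = 1, AB-CD = 2, AA-BC = 3, AA-BB = 4; locus distances
#' are summed over loci where both individuals are genotyped. Pairs sharing
#' no genotyped locus get a missing distance (flagged).
#'
#' @param genotypes a [genotype_table()].
#' @return a [distance_matrix()] (with `NA` for non-comparable pairs, in
#'   which case attribute `"incomplete"` is `TRUE`).
#' @export
genotypic_distance <- function(genotypes) {
  gt <- genotypes
  n <- length(gt$samples)
  total <- matrix(0, n, n)
  shared <- matrix(0L, n, n)
  for (l in seq_along(gt$loci)) {
    al <- locus_alleles(gt, l)
    ok <- al[, 1L] > 0L
    codes <- sort(unique(c(al[ok, 1L], al[ok, 2L])))
    X <- matrix(0, n, length(codes))
    rows <- which(ok)
    i1 <- cbind(rows, match(al[rows, 1L], codes))
    i2 <- cbind(rows, match(al[rows, 2L], codes))
    X[i1] <- X[i1] + 1
    X[i2] <- X[i2] + 1
    sq <- rowSums(X^2)
    D2 <- outer(sq, sq, "+") - 2 * tcrossprod(X)
    both <- outer(ok, ok, "&")
    total[both] <- total[both] + 0.5 * pmax(D2[both], 0)
    shared <- shared + both
  }
  total[shared == 0L] <- NA_real_
  diag(total) <- 0
  d <- distance_matrix(total, labels = gt$samples, allow_na = TRUE)
  attr(d, "incomplete") <- anyNA(total)
  d
}

#' Distance matrix from scalar values or planar coordinates
#'
#' Absolute differences for a single trait (e.g. oridonin percent dry
#' weight), Euclidean norm for two-column coordinates. The `log` transform
#' applies the natural log to off-diagonal distances (the usual
#' isolation-by-distance transform) and errors on zero distances, which
#' should be jittered or excluded first.
#'
#' @param values numeric vector, or two-column matrix of planar coordinates;
#'   names/rownames used as labels.
#' @param transform `"identity"` or `"log"`.
#' @param labels optional labels overriding names.
#' @return a [distance_matrix()].
#' @export
scalar_distance_matrix <- function(values, transform = c("identity", "log"),
                                   labels = NULL) {
  transform <- match.arg(transform)
  if (is.matrix(values) || is.data.frame(values)) {
    values <- as.matrix(values)
    if (ncol(values) != 2L) stop("coordinate input must have two columns")
    if (is.null(labels)) labels <- rownames(values)
    d <- as.matrix(stats::dist(values))
  } else {
    if (is.null(labels)) labels <- names(values)
    d <- abs(outer(values, values, "-"))
  }
  if (transform == "log") {
    off <- d[upper.tri(d) | lower.tri(d)]
    if (any(off <= 0))
      stop("log of a zero distance: jitter duplicate values or exclude them")
    d[upper.tri(d) | lower.tri(d)] <- log(off)
  }
  distance_matrix(d, labels = labels,
                  allow_negative = transform == "log")
}

#' Principal coordinate analysis (classical metric MDS)
#'
#' Gower double-centering of `-d^2 / 2` followed by eigendecomposition;
#' coordinates are eigenvectors scaled by the square root of their
#' eigenvalues. Negative eigenvalues (non-Euclidean input) are reported but
#' excluded from the percent-of-variation denominator.
#'
#' @param d a [distance_matrix()] (complete).
#' @param n_axes number of axes to retain (default: all positive).
#' @return list of class `pcoa_result`: `coordinates` (samples x axes),
#'   `eigenvalues` (all), `percent` (per positive axis, sums to 100).
#' @export
pcoa <- function(d, n_axes = NULL) {
  m <- unclass(d)
  if (anyNA(m)) stop("PCoA requires a complete distance matrix")
  if (any(abs(m - t(m)) > 1e-8)) stop("non-symmetric input")
  n <- nrow(m)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (m^2) %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  pos <- which(e$values > 1e-9 * max(abs(e$values)))
  if (length(pos) == 0L)
    stop("degenerate distance matrix: no positive eigenvalues")
  if (is.null(n_axes)) n_axes <- length(pos)
  keep <- pos[seq_len(min(n_axes, length(pos)))]
  coords <- e$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(e$values[keep]), length(keep))
  rownames(coords) <- rownames(m)
  colnames(coords) <- paste0("axis", seq_along(keep))
  structure(list(coordinates = coords, eigenvalues = e$values,
                 percent = 100 * e$values[pos] / sum(e$values[pos])),
            class = "pcoa_result")
}

upper_vec <- function(m) m[upper.tri(m)]

#' Mantel test of matrix correspondence
#'
#' Pearson correlation of the off-diagonal upper triangles, with a null
#' built by simultaneously permuting rows and columns of the second matrix.
#' One-tailed (greater) with the add-one convention
#' `p = (1 + #\{r_perm >= r_obs\}) / (n + 1)`, the conventional direction
#' for isolation-by-distance tests.
#'
#' @param d1,d2 [distance_matrix()] objects over the same labels.
#' @param n_permutations permutation count (the study used 999).
#' @param seed integer RNG seed.
#' @return list of class `mantel_result`: `r`, `p`, `n_permutations`,
#'   `n_samples`, `seed`.
#' @export
mantel_test <- function(d1, d2, n_permutations = 999, seed = 1L) {
  m1 <- unclass(d1); m2 <- unclass(d2)
  if (!identical(dim(m1), dim(m2))) stop("matrices differ in size")
  if (!is.null(rownames(m1)) && !is.null(rownames(m2))) {
    if (!setequal(rownames(m1), rownames(m2)))
      stop("matrices have mismatched labels")
    m2 <- m2[rownames(m1), rownames(m1)]
  }
  if (anyNA(m1) || anyNA(m2)) stop("Mantel test requires complete matrices")
  x <- upper_vec(m1)
  if (stats::sd(x) == 0 || stats::sd(upper_vec(m2)) == 0)
    stop("constant matrix: correlation undefined")
  r_obs <- stats::cor(x, upper_vec(m2))
  n <- nrow(m1)
  set.seed(seed)
  xc <- x - mean(x)
  xs <- sqrt(sum(xc^2))
  r_perm <- vapply(seq_len(n_permutations), function(i) {
    idx <- sample.int(n)
    y <- upper_vec(m2[idx, idx])
    yc <- y - mean(y)
    sum(xc * yc) / (xs * sqrt(sum(yc^2)))
  }, numeric(1))
  structure(list(r = r_obs,
                 p = (1 + sum(r_perm >= r_obs)) / (n_permutations + 1),
                 n_permutations = n_permutations, n_samples = n,
                 seed = seed),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test: N = %d, r_xy = %.3f, p = %.4g (%d permutations)\n",
              x$n_samples, x$r, x$p, x$n_permutations))
  invisible(x)
}
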