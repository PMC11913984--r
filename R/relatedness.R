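#' VanRaden method-1 genomic relationship matrix
#'
#' `K = Z Z' / (2 * sum_j p_j (1 - p_j))` with `Z = G - 2p`, where `G` is
#' the 0/1/2 genotype matrix and `p` the supplied reference allele
#' frequencies. The reference frequencies are a required, explicit
#' argument: using training-set frequencies at selection time versus base-
#' cycle frequencies for reporting changes the location of GEBVs (the
#' base-cycle convention anchors the mean GEBV of the base population at
#' zero). Markers monomorphic in the reference set are dropped from both
#' numerator and denominator with a warning.
#'
#' @param geno n x m genotype matrix in 0/1/2 coding (complete; impute
#'   upstream).
#' @param ref_freqs Length-m reference allele frequencies.
#' @return Object of class `grm`: list with `K` (n x n), `ids`,
#'   `ref_freqs` (polymorphic markers only), `keep` (logical length m),
#'   `denom`.
#' @export
vanraden_grm <- function(geno, ref_freqs) {
  geno <- as.matrix(geno)
  stopifnot(ncol(geno) == length(ref_freqs))
  if (anyNA(geno)) stop("missing genotypes: impute upstream")
  keep <- ref_freqs > 0 & ref_freqs < 1
  if (!any(keep)) stop("all markers monomorphic in the reference set")
  if (!all(keep)) {
    warning(sprintf("%d monomorphic markers dropped from GRM", sum(!keep)))
  }
  p <- ref_freqs[keep]
  Z <- sweep(geno[, keep, drop = FALSE], 2, 2 * p)
  denom <- 2 * sum(p * (1 - p))
  K <- tcrossprod(Z) / denom
  ids <- rownames(geno)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(geno)))
  dimnames(K) <- list(ids, ids)
  structure(list(K = K, ids = ids, ref_freqs = p, keep = keep,
                 denom = denom), class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("<grm> %d individuals, %d markers, denom = %.3f\n",
              length(x$ids), length(x$ref_freqs), x$denom))
  invisible(x)
}

#' Train-by-candidate genomic relationship block
#'
#' Applies the same centering and denominator as [vanraden_grm()] to the
#' stacked genotype set and returns the train x new block. Both inputs
#' must cover the identical marker set (same columns, same order).
#'
#' @param geno_train,geno_new Genotype matrices in 0/1/2 coding.
#' @param ref_freqs Length-m reference allele frequencies.
#' @return Matrix (n_train x n_new).
#' @export
cross_grm <- function(geno_train, geno_new, ref_freqs) {
  geno_train <- as.matrix(geno_train)
  geno_new <- as.matrix(geno_new)
  if (ncol(geno_train) != ncol(geno_new)) {
    stop("marker sets must be identical between training and new genotypes")
  }
  ct <- colnames(geno_train); cn <- colnames(geno_new)
  if (!is.null(ct) && !is.null(cn) && !identical(ct, cn)) {
    stop("marker sets must be identical between training and new genotypes")
  }
  stopifnot(ncol(geno_train) == length(ref_freqs))
  keep <- ref_freqs > 0 & ref_freqs < 1
  if (!any(keep)) stop("all markers monomorphic in the reference set")
  p <- ref_freqs[keep]
  Zt <- sweep(geno_train[, keep, drop = FALSE], 2, 2 * p)
  Zn <- sweep(geno_new[, keep, drop = FALSE], 2, 2 * p)
  tcrossprod(Zt, Zn) / (2 * sum(p * (1 - p)))
}

#' Modified Rogers' distance
#'
#' For biallelic markers, `MRD(a, b) = sqrt(mean((p_a - p_b)^2))` over
#' markers, which ranges in \[0, 1\] and is a metric on allele-frequency
#' vectors. Individuals enter via their genotype-derived frequencies
#' (0, 0.5, 1 = genotype / 2); populations via mean allele frequencies.
#'
#' @param freqs_a,freqs_b Equal-length allele-frequency vectors.
#' @return Distance in \[0, 1\].
#' @export
mrd <- function(freqs_a, freqs_b) {
  if (length(freqs_a) != length(freqs_b)) {
    stop("frequency vectors differ in length")
  }
  sqrt(mean((freqs_a - freqs_b)^2))
}

#' Pairwise modified Rogers' distances
#'
#' @param freq_mat Matrix with one row per unit (individual or population)
#'   and one column per marker, entries in \[0, 1\]. For individuals pass
#'   `genotypes(pop) / 2`.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
mrd_matrix <- function(freq_mat) {
  freq_mat <- as.matrix(freq_mat)
  m <- ncol(freq_mat)
  g2 <- rowSums(freq_mat^2)
  d2 <- (outer(g2, g2, "+") - 2 * tcrossprod(freq_mat)) / m
  d2[d2 < 0] <- 0
  d <- sqrt(d2)
  diag(d) <- 0
  dimnames(d) <- list(rownames(freq_mat), rownames(freq_mat))
  d
}

#' Principal coordinate analysis (classical scaling)
#'
#' Double-centers the squared distance matrix, eigendecomposes it, and
#' returns coordinates on the leading axes together with the percentage of
#' variance explained (eigenvalue over the sum of positive eigenvalues).
#'
#' @param d Square symmetric non-negative distance matrix, zero diagonal.
#' @param n_axes Number of axes to return (default 2).
#' @return List with `coords` (n x n_axes), `eigenvalues` (all),
#'   `percent_explained` (per returned axis).
#' @export
pcoa <- function(d, n_axes = 2L) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (ncol(d) != n || max(abs(d - t(d))) > 1e-8) {
    stop("distance matrix must be square and symmetric")
  }
  if (any(d < 0) || any(abs(diag(d)) > 1e-12)) {
    stop("distance matrix must be non-negative with zero diagonal")
  }
  J <- diag(n) - 1 / n
  B <- -0.5 * J %*% (d^2) %*% J
  es <- eigen((B + t(B)) / 2, symmetric = TRUE)
  pos <- pmax(es$values, 0)
  n_axes <- min(n_axes, n)
  coords <- es$vectors[, seq_len(n_axes), drop = FALSE] %*%
    diag(sqrt(pos[seq_len(n_axes)]), n_axes)
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("PCo", seq_len(n_axes))
  tot <- sum(pos)
  pct <- if (tot > 0) 100 * pos[seq_len(n_axes)] / tot else rep(0, n_axes)
  list(coords = coords, eigenvalues = es$values, percent_explained = pct)
}

#' Pedigree validation by marker profiles
#'
#' Fraction of markers at which an offspring 0/1/2 genotype is Mendelian-
#' consistent with the stated parent pair (for a DH or selfed offspring
#' pass the same parent twice). A trio is flagged when the rate falls
#' below `threshold`.
#'
#' @param offspring,mother,father Genotype vectors in 0/1/2 coding.
#' @param threshold Consistency rate below which the trio is flagged.
#' @return List with `rate`, `n_inconsistent`, `flag`.
#' @export
pedigree_check <- function(offspring, mother, father, threshold = 0.98) {
  stopifnot(length(offspring) == length(mother),
            length(mother) == length(father))
  # possible gametes: genotype 0 -> {0}; 1 -> {0,1}; 2 -> {1}
  min_o <- (mother == 2) + (father == 2)
  max_o <- (mother >= 1) + (father >= 1)
  ok <- offspring >= min_o & offspring <= max_o
  rate <- mean(ok)
  list(rate = rate, n_inconsistent = sum(!ok), flag = rate < threshold)
}
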