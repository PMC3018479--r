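#' Population-structure covariates by principal components
#'
#' Eigen-decomposition of the column-standardized genotype matrix. Missing
#' calls are mean-imputed per marker for this computation only (the stored
#' genotype matrix is untouched). Markers should be MAF-filtered first;
#' zero-variance (monomorphic) columns are dropped with a warning.
#'
#' @param G A [genotype_matrix()] (MAF-filtered).
#' @param n_axes Number of component axes to keep (default 2, the number
#'   usually interpreted for structured crop germplasm).
#' @return An object of class `q_matrix`: list with `scores` (accession x
#'   `n_axes` matrix), `explained_variance` (per kept axis, proportion of
#'   total), `accession_ids` and `n_axes`. Axes are ordered by decreasing
#'   explained variance.
#' @export
pca_structure <- function(G, n_axes = 2) {
  stopifnot(inherits(G, "genotype_matrix"))
  n <- length(G$accession_ids)
  m <- length(G$marker_ids)
  if (n_axes >= min(n, m)) {
    stop("n_axes must be smaller than min(n_accessions, n_markers)")
  }
  X <- G$calls
  storage.mode(X) <- "double"
  cm <- colMeans(X, na.rm = TRUE)
  idx <- which(is.na(X), arr.ind = TRUE)
  if (nrow(idx)) X[idx] <- cm[idx[, 2L]]
  v <- apply(X, 2L, stats::var)
  degenerate <- !is.finite(v) | v < .Machine$double.eps
  if (any(degenerate)) {
    warning(sum(degenerate), " zero-variance marker(s) dropped before PCA; ",
            "was the MAF filter applied?")
    X <- X[, !degenerate, drop = FALSE]
    if (ncol(X) < 2L) stop("too few polymorphic markers for PCA")
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  scores <- pc$x[, seq_len(n_axes), drop = FALSE]
  rownames(scores) <- G$accession_ids
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = scores,
                 explained_variance = ev[seq_len(n_axes)],
                 accession_ids = G$accession_ids,
                 n_axes = n_axes),
            class = "q_matrix")
}

#' @export
print.q_matrix <- function(x, ...) {
  cat("q_matrix:", length(x$accession_ids), "accessions,", x$n_axes,
      "axes; explained variance:",
      paste(round(x$explained_variance, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Loiselle relative-kinship matrix
#'
#' Pairwise relatedness by the Loiselle et al. (1995) allele-frequency
#' correlation estimator. Per locus l with reference-panel allele
#' frequency p_l and individual allele frequencies x (0 or 1 for inbred,
#' haploid-coded lines), the pair (i, j) contributes the cross-product
#' (x_il - p_l)(x_jl - p_l) plus the small-sample bias term
#' p_l(1 - p_l)/(n_l - 1), where n_l is the number of individuals typed at
#' the locus. The multilocus coefficient is the ratio of summed
#' contributions to the summed polymorphic-information denominators
#' p_l(1 - p_l) — i.e. loci are weighted by their denominator. Missing
#' calls are excluded pairwise; the denominator for a pair only includes
#' loci where both members are typed.
#'
#' Coefficients below zero mean a pair is less related than two random
#' individuals from the panel; apply [floor_negative()] before using the
#' matrix as a mixed-model covariance.
#'
#' @param G A [genotype_matrix()]; monomorphic markers are ignored.
#' @param n_markers Optionally subsample this many polymorphic markers
#'   (seeded; mirrors panels where a random subset of SNPs is used).
#' @param subsample_seed RNG seed for the subsample.
#' @return A symmetric accession x accession numeric matrix of class
#'   `kinship_matrix`. A pair with no co-observed polymorphic marker gets
#'   `NA` with a warning.
#' @export
loiselle_kinship <- function(G, n_markers = NULL, subsample_seed = 1L) {
  stopifnot(inherits(G, "genotype_matrix"))
  maf <- marker_maf(G)
  poly <- names(maf)[!is.na(maf) & maf > 0]
  if (length(poly) < 2L) stop("need at least 2 polymorphic markers")
  if (!is.null(n_markers) && n_markers < length(poly)) {
    set.seed(subsample_seed)
    poly <- sort(sample(poly, n_markers))
  }
  X <- G$calls[, poly, drop = FALSE]
  storage.mode(X) <- "double"
  obs <- !is.na(X)
  n_l <- colSums(obs)
  usable <- n_l >= 2L
  X <- X[, usable, drop = FALSE]
  obs <- obs[, usable, drop = FALSE]
  n_l <- n_l[usable]
  p <- colMeans(X, na.rm = TRUE)
  v <- p * (1 - p)

  C <- sweep(X, 2L, p)          # x - p
  C[!obs] <- 0
  Mnum <- C %*% t(C)            # sum over co-observed loci of cross-products
  Mobs <- obs * 1
  ## denominator and bias summed over the pair's co-observed loci
  D <- Mobs %*% (t(Mobs) * v)
  B <- Mobs %*% (t(Mobs) * (v / (n_l - 1)))
  Kmat <- (Mnum + B) / D
  Kmat[D <= 0] <- NA_real_
  if (anyNA(Kmat)) {
    warning("some accession pairs share no co-observed polymorphic marker")
  }
  Kmat <- (Kmat + t(Kmat)) / 2  # enforce exact symmetry
  dimnames(Kmat) <- list(G$accession_ids, G$accession_ids)
  class(Kmat) <- c("kinship_matrix", class(Kmat))
  Kmat
}

#' Floor negative kinship coefficients at zero
#'
#' Negative coefficients (pairs less related than random) are set to zero;
#' all other entries are unchanged. Idempotent.
#'
#' @param K A kinship matrix.
#' @return The floored matrix, same class and dimnames.
#' @export
floor_negative <- function(K) {
  K[!is.na(K) & K < 0] <- 0
  K
}
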