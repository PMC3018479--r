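# shared fixtures, built in code

# hand-sized genotype matrix with a map and qc scores
tiny_genotypes <- function() {
  calls <- matrix(
    c(0L, 1L, 0L, 1L, 0L,
      0L, 1L, 1L, NA, 0L,
      1L, 0L, 0L, 1L, 1L,
      1L, NA, 1L, 0L, 1L),
    nrow = 4L, byrow = TRUE,
    dimnames = list(paste0("acc", 1:4), paste0("mk", 1:5)))
  map <- data.frame(marker = paste0("mk", 1:5),
                    chrom = c("1", "1", "1", "2", NA),
                    pos_cM = c(0, 5.5, 30, 12, NA),
                    stringsAsFactors = FALSE)
  qc <- stats::setNames(c(0.9, 0.95, 0.55, 0.8, 0.99), paste0("mk", 1:5))
  genotype_matrix(calls, map = map, qc = qc)
}

# random genotype matrix without structure, named dims
random_genotypes <- function(n = 30, m = 40, missing = 0.05, seed = 1) {
  set.seed(seed)
  p <- runif(m, 0.2, 0.8)
  calls <- vapply(p, function(pp) rbinom(n, 1L, pp), integer(n))
  calls[matrix(runif(n * m) < missing, n, m)] <- NA
  dimnames(calls) <- list(sprintf("a%02d", seq_len(n)),
                          sprintf("m%02d", seq_len(m)))
  map <- data.frame(marker = colnames(calls),
                    chrom = as.character(rep(1:2, length.out = m)),
                    pos_cM = rep(seq(0, 50, length.out = ceiling(m / 2)),
                                 2)[seq_len(m)],
                    stringsAsFactors = FALSE)
  genotype_matrix(calls, map = map)
}

# small default-architecture simulation, cached per seed within a test run
.sim_cache <- new.env(parent = emptyenv())
cached_sim <- function(seed = 1, ...) {
  key <- paste0("s", seed, "_", paste(c(...), collapse = "_"))
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- simulate_germplasm(sim_config(seed = seed, ...))
  }
  .sim_cache[[key]]
}

# independent naive Loiselle estimator: plain loops over loci and pairs
loiselle_bruteforce <- function(X) {
  n <- nrow(X)
  m <- ncol(X)
  out <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    num <- den <- 0
    for (l in seq_len(m)) {
      xl <- X[, l]
      nl <- sum(!is.na(xl))
      if (nl < 2L) next
      p <- mean(xl, na.rm = TRUE)
      v <- p * (1 - p)
      if (v == 0) next
      if (!is.na(xl[i]) && !is.na(xl[j])) {
        num <- num + (xl[i] - p) * (xl[j] - p) + v / (nl - 1)
        den <- den + v
      }
    }
    out[i, j] <- if (den > 0) num / den else NA_real_
  }
  out
}

# independent dense-matrix ML profile likelihood for the mixed model
mixed_ll_dense <- function(delta, yv, Xm, Kmat) {
  n <- length(yv)
  V <- delta * Kmat + diag(n)
  Vi <- solve(V)
  b <- solve(t(Xm) %*% Vi %*% Xm, t(Xm) %*% Vi %*% yv)
  r <- yv - Xm %*% b
  s2 <- drop(t(r) %*% Vi %*% r) / n
  -0.5 * (n * log(2 * pi * s2) + n +
            as.numeric(determinant(V)$modulus))
}
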