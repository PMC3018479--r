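test_that("BH adjustment matches hand-computed values and is monotone", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(0.037), 0.037)
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  # NA entries excluded, not dropped
  out <- fdr_adjust(c(0.01, NA, 0.02))
  expect_true(is.na(out[2]))
  expect_equal(out[c(1, 3)], fdr_adjust(c(0.01, 0.02)))
  # monotone and never below the raw p
  set.seed(1)
  p <- stats::runif(50)
  adj <- fdr_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
})

test_that("a marker identical to the trait ranks first under every model", {
  # unstructured panel with independent markers: no LD ties
  G <- random_genotypes(n = 60, m = 30, missing = 0, seed = 20)
  y <- stats::setNames(as.numeric(G$calls[, 5]), G$accession_ids)
  Q <- pca_structure(G, 2)
  K <- floor_negative(loiselle_kinship(G))
  for (mod in c("M", "M+Q", "M+K", "M+Q+K")) {
    res <- fit_single_marker(G, y, model = mod, Q = Q, K = K)
    best <- res$marker[which.min(res$p_value)]
    expect_identical(best, G$marker_ids[5])
  }
})

test_that("mixed model with diagonal K collapses onto the fixed model", {
  G <- random_genotypes(n = 40, m = 25, missing = 0, seed = 21)
  set.seed(22)
  y <- stats::setNames(stats::rnorm(40), G$accession_ids)
  K0 <- diag(40) * 0  # zero genetic covariance
  dimnames(K0) <- list(G$accession_ids, G$accession_ids)
  rM <- fit_single_marker(G, y, model = "M")
  rK <- fit_single_marker(G, y, model = "M+K", K = K0)
  expect_equal(rK$p_value, rM$p_value, tolerance = 1e-6)
})

test_that("ML mixed fit matches a brute-force variance-ratio grid search", {
  set.seed(9)
  n <- 8
  Km <- tcrossprod(matrix(stats::rnorm(n * 3), n, 3)) / 3 + diag(n) * 0.5
  dimnames(Km) <- list(paste0("a", 1:n), paste0("a", 1:n))
  X <- cbind(1, stats::rnorm(n), stats::rbinom(n, 1, 0.5))
  y <- drop(X %*% c(1, 0.5, 0.8)) + stats::rnorm(n)
  fit <- ml_mixed_fit(y, X, Km)
  grid <- exp(seq(-12, 12, length.out = 8001))
  lls <- vapply(grid, function(dl) mixed_ll_dense(dl, y, X, Km), 0)
  expect_lt(abs(fit$log_lik - max(lls)), 1e-4)
  expect_gte(fit$log_lik, max(lls) - 1e-8)
})

test_that("exact per-marker refit agrees with the fast scan on clean data", {
  sim <- cached_sim(seed = 23, n_accessions = 50, markers_per_chromosome = 10,
                    n_chromosomes = 2, missing_rate = 0, causal_spec = list())
  G <- sim$genotypes
  set.seed(24)
  y <- stats::setNames(stats::rnorm(50), G$accession_ids)
  Q <- pca_structure(G, 2)
  K <- floor_negative(loiselle_kinship(G))
  fast <- fit_single_marker(G, y, model = "M+Q", Q = Q)
  slow <- fit_single_marker(G, y, model = "M+Q", Q = Q, exact = TRUE)
  expect_equal(fast$p_value, slow$p_value, tolerance = 1e-8)
  # mixed: fast reuses null variance components, exact refits per marker;
  # with no missing data they agree closely on a null trait
  fastK <- fit_single_marker(G, y, model = "M+Q+K", Q = Q, K = K)
  slowK <- fit_single_marker(G, y, model = "M+Q+K", Q = Q, K = K,
                             exact = TRUE)
  expect_equal(fastK$p_value, slowK$p_value, tolerance = 0.05)
})

test_that("p-values are invariant to accession order", {
  sim <- cached_sim(seed = 25, n_accessions = 40, markers_per_chromosome = 12,
                    n_chromosomes = 2, causal_spec = list())
  G <- sim$genotypes
  set.seed(26)
  y <- stats::setNames(stats::rnorm(40), G$accession_ids)
  K <- floor_negative(loiselle_kinship(G))
  r1 <- fit_single_marker(G, y, model = "M+K", K = K)
  perm <- rev(G$accession_ids)
  G2 <- subset_genotypes(G, accessions = perm)
  r2 <- fit_single_marker(G2, y, model = "M+K", K = K)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-6)
})

test_that("monomorphic markers get NA p and stay out of the FDR", {
  G <- random_genotypes(n = 30, m = 10, missing = 0, seed = 27)
  G$calls[, 3] <- 1L
  set.seed(28)
  y <- stats::setNames(stats::rnorm(30), G$accession_ids)
  res <- fit_single_marker(G, y, model = "M")
  expect_true(is.na(res$p_value[3]))
  expect_true(is.na(res$fdr_adjusted_p[3]))
  expect_equal(res$fdr_adjusted_p[-3], fdr_adjust(res$p_value[-3]))
})

test_that("genome_scan orders by map and flags adjusted significance", {
  expect_equal(nrow(genome_scan(data.frame(marker = character(),
                                           model = character(),
                                           p_value = numeric(),
                                           fdr_adjusted_p = numeric(),
                                           minus_log10_p = numeric()),
                                tiny_genotypes())), 0L)

  sim <- cached_sim(seed = 2)
  suppressMessages(G <- maf_filter(qc_filter(sim$genotypes)))
  Q <- pca_structure(G, 2)
  K <- floor_negative(loiselle_kinship(G))
  res <- fit_single_marker(G, sim$phenotypes, "rowtype", "M+Q+K",
                           Q = Q, K = K)
  scan <- genome_scan(res, G, alpha = 0.05)
  expect_false(is.unsorted(scan$chrom))
  within <- tapply(scan$pos_cM, scan$chrom, is.unsorted)
  expect_false(any(within))
  # the flagged markers include one within 10 cM of the true row-type locus
  vrs1 <- sim$truth$config$causal_spec[[4]]
  flagged <- scan[scan$significant, ]
  expect_true(any(flagged$chrom == as.character(vrs1$chromosome) &
                    abs(flagged$pos_cM - vrs1$position_cM) <= 10))
})

test_that("structure-confounded null markers shrink from M to M+Q to M+Q+K", {
  sim <- cached_sim(seed = 30)
  suppressMessages(G <- maf_filter(qc_filter(sim$genotypes)))
  Q <- pca_structure(G, 2)
  K <- floor_negative(loiselle_kinship(G))
  spec <- sim$truth$config$causal_spec
  near <- rep(FALSE, length(G$marker_ids))
  for (cl in spec) {
    near <- near | (!is.na(G$map$chrom) &
                      G$map$chrom == as.character(cl$chromosome) &
                      abs(G$map$pos_cM - cl$position_cM) <= 10)
  }
  nullm <- G$marker_ids[!near]
  counts <- vapply(c("M", "M+Q", "M+Q+K"), function(mod) {
    res <- fit_single_marker(G, sim$phenotypes, "rowtype", mod,
                             Q = Q, K = K)
    sig <- res$marker[!is.na(res$fdr_adjusted_p) &
                        res$fdr_adjusted_p < 0.05]
    sum(sig %in% nullm)
  }, 0)
  expect_lte(counts[["M+Q+K"]], counts[["M+Q"]])
  expect_lte(counts[["M+Q"]], counts[["M"]])
})
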