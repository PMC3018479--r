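test_that("gate selection is strict and hand-countable", {
  fake <- data.frame(marker = sprintf("m%02d", 1:10),
                     p_value = seq(0.001, 0.5, length.out = 10),
                     fdr_adjusted_p = c(0.05, 0.10, 0.15, 0.19, 0.20,
                                        0.21, 0.30, 0.50, 0.80, 1.00))
  sel <- suppressMessages(select_candidates(fake, 0.20))
  expect_identical(sel, sprintf("m%02d", 1:4))  # 0.19 in, 0.20 and 0.21 out
  none <- suppressMessages(select_candidates(
    transform(fake, fdr_adjusted_p = fdr_adjusted_p + 1), 0.20))
  expect_length(none, 0L)
})

test_that("pair enumeration reproduces n(n-1)/2 with no self/dup pairs", {
  p196 <- enumerate_pairs(sprintf("m%03d", 1:196))
  expect_equal(nrow(p196), 19110L)
  p59 <- enumerate_pairs(sprintf("m%03d", 1:59))
  expect_equal(nrow(p59), 1711L)
  p2 <- enumerate_pairs(c("a", "b"))
  expect_equal(nrow(p2), 1L)
  expect_equal(nrow(enumerate_pairs("a")), 0L)
  expect_false(any(p59$marker_a == p59$marker_b))
  key <- paste(pmin(p59$marker_a, p59$marker_b),
               pmax(p59$marker_a, p59$marker_b))
  expect_false(any(duplicated(key)))
})

test_that("interaction LRT has df 3 for complete pairs and is symmetric", {
  set.seed(31)
  n <- 80
  acc <- sprintf("a%02d", 1:n)
  ga <- stats::setNames(rbinom(n, 1, 0.5), acc)
  gb <- stats::setNames(rbinom(n, 1, 0.5), acc)
  y <- stats::setNames(stats::rnorm(n), acc)
  Qs <- matrix(stats::rnorm(2 * n), n, 2, dimnames = list(acc, c("PC1", "PC2")))
  r <- interaction_lrt(ga, gb, y, Qs)
  expect_equal(r$df, 3L)
  r2 <- interaction_lrt(gb, ga, y, Qs)
  expect_equal(r$lrt_stat, r2$lrt_stat, tolerance = 1e-10)
  expect_equal(r$p_value, r2$p_value, tolerance = 1e-10)

  # empty interaction cell reduces the estimable df
  gb2 <- ga  # identical markers: b and a:b aliased with a
  r3 <- interaction_lrt(ga, gb2, y, Qs)
  expect_lt(r3$df, 3L)
})

test_that("null interaction LRT is chi-square calibrated (mean ~ df)", {
  set.seed(32)
  reps <- 300
  out <- vapply(seq_len(reps), function(i) {
    n <- 100
    acc <- sprintf("a%03d", seq_len(n))
    Qs <- matrix(stats::rnorm(2 * n), n, 2,
                 dimnames = list(acc, c("PC1", "PC2")))
    y <- stats::setNames(drop(Qs %*% c(0.5, -0.3)) + stats::rnorm(n), acc)
    ga <- stats::setNames(stats::rbinom(n, 1, 0.4), acc)
    gb <- stats::setNames(stats::rbinom(n, 1, 0.4), acc)
    r <- interaction_lrt(ga, gb, y, Qs)
    c(r$lrt_stat, r$df, r$p_value)
  }, numeric(3))
  mc_se <- stats::sd(out[1, ]) / sqrt(reps)
  expect_lt(abs(mean(out[1, ]) - mean(out[2, ])), 3 * mc_se)
  # size of the p < 0.05 test stays near nominal
  expect_lt(mean(out[3, ] < 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("a pair that determines a binary trait is flagged perfect", {
  set.seed(33)
  n <- 50
  acc <- sprintf("a%02d", seq_len(n))
  ga <- stats::setNames(stats::rbinom(n, 1, 0.5), acc)
  gb <- stats::setNames(stats::rbinom(n, 1, 0.5), acc)
  y <- stats::setNames(as.numeric(ga == 1 & gb == 0), acc)
  Qs <- matrix(stats::rnorm(n), n, 1, dimnames = list(acc, "PC1"))
  r <- interaction_lrt(ga, gb, y, Qs)
  expect_true(r$perfect_flag)
  expect_equal(r$p_value, 0)
  expect_true(is.na(r$minus_log10_p))
  ranked <- rank_interactions(rbind(
    r, interaction_lrt(ga, stats::setNames(stats::rbinom(n, 1, 0.5), acc),
                       y, Qs)))
  expect_equal(ranked$rank[1], 1L)
  expect_true(ranked$perfect_flag[1])
})

test_that("competition ranking reproduces the shared-tie pattern", {
  res <- data.frame(marker_a = letters[1:5], marker_b = LETTERS[1:5],
                    lrt_stat = c(50.1, 50.1, 50.0, 50.0, 49.6),
                    df = 3L, p_value = NA_real_, minus_log10_p = NA_real_,
                    perfect_flag = FALSE, n_used = 100L,
                    inestimable = FALSE, stringsAsFactors = FALSE)
  expect_equal(rank_interactions(res)$rank, c(1L, 1L, 3L, 3L, 5L))

  res$lrt_stat <- c(5, 4, 3, 2, 1)
  expect_equal(rank_interactions(res)$rank, 1:5)

  res$perfect_flag <- TRUE
  res$lrt_stat <- Inf
  expect_equal(rank_interactions(res)$rank, rep(1L, 5))
})

test_that("the causal allele-type pair tops the gated interaction scan", {
  sim <- cached_sim(seed = 3)
  suppressMessages(G <- maf_filter(qc_filter(sim$genotypes)))
  Q <- pca_structure(G, 2)
  K <- floor_negative(loiselle_kinship(G))
  res <- fit_single_marker(G, sim$phenotypes, "days_to_flowering", "M+Q+K",
                           Q = Q, K = K)
  cand <- suppressMessages(select_candidates(res, 0.20))
  expect_true(all(c("VRN1like_AT", "VRN2like_AT") %in% cand))
  it <- suppressMessages(
    interaction_scan(G, sim$phenotypes, Q, cand, trait = "days_to_flowering"))
  hit <- which((it$marker_a == "VRN1like_AT" & it$marker_b == "VRN2like_AT") |
                 (it$marker_a == "VRN2like_AT" & it$marker_b == "VRN1like_AT"))
  expect_length(hit, 1L)
  expect_lte(it$rank[hit], 5L)
})
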