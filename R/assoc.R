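## Single-marker association scans: M, M+Q, M+K, M+Q+K.
## Mixed models use maximum likelihood (not REML) so that -2 log likelihood
## differences between models with different fixed effects are valid; the
## kinship covariance is handled by one spectral decomposition of K, which
## reduces every fit to a 1-D profile optimization over the variance ratio
## delta = sigma2_g / sigma2_e.

.normalize_model <- function(model) {
  m <- toupper(gsub("[+ ]", "", model))
  switch(m,
         "M" = "M", "MQ" = "M+Q", "MK" = "M+K", "MQK" = "M+Q+K",
         stop("unknown model '", model,
              "'; use one of M, M+Q, M+K, M+Q+K"))
}

## profile ML log-likelihood at variance ratio delta on rotated data
.ml_ll_rotated <- function(delta, yr, Xr, d) {
  w <- 1 / (delta * d + 1)
  sw <- sqrt(w)
  fit <- stats::lm.fit(Xr * sw, yr * sw)
  rss <- sum(fit$residuals^2)
  n <- length(yr)
  -0.5 * (n * log(2 * pi * rss / n) + n + sum(log(delta * d + 1)))
}

#' Maximum-likelihood linear mixed model with a kinship random effect
#'
#' Fits y = X beta + u + e with u ~ N(0, sigma2_g K) and independent
#' residuals by full maximum likelihood. The spectral decomposition
#' K = U D U' rotates the model so the profile likelihood depends on the
#' single variance ratio delta = sigma2_g / sigma2_e, which is optimized
#' on the log scale (the boundary delta = 0 is checked explicitly).
#' Eigenvalues of K below zero (possible after flooring an empirical
#' kinship estimate) are clamped to zero.
#'
#' @param y Numeric response vector.
#' @param X Fixed-effects design matrix (include the intercept column).
#' @param K Kinship matrix aligned with `y`, or a precomputed
#'   `eigen(K, symmetric = TRUE)` result.
#' @return List: `delta`, `sigma2_e`, `sigma2_g`, `beta` (GLS estimates),
#'   `se` (their standard errors, ML scale), `log_lik`, `n`, `rank`.
#' @export
ml_mixed_fit <- function(y, X, K) {
  n <- length(y)
  stopifnot(nrow(X) == n)
  eig <- if (is.list(K) && !is.null(K$vectors)) K
         else eigen(unclass(K), symmetric = TRUE)
  d <- pmax(eig$values, 0)
  U <- eig$vectors
  yr <- drop(crossprod(U, y))
  Xr <- crossprod(U, X)

  obj <- function(ld) .ml_ll_rotated(exp(ld), yr, Xr, d)
  opt <- stats::optimize(obj, interval = c(-12, 12), maximum = TRUE,
                         tol = 1e-8)
  ll0 <- .ml_ll_rotated(0, yr, Xr, d)
  if (ll0 >= opt$objective) {
    delta <- 0; ll <- ll0
  } else {
    delta <- exp(opt$maximum); ll <- opt$objective
  }
  sw <- sqrt(1 / (delta * d + 1))
  Xw <- Xr * sw
  yw <- yr * sw
  fit <- stats::lm.fit(Xw, yw)
  p <- fit$rank
  if (p < ncol(Xw)) stop("fixed-effects design is rank deficient")
  rss <- sum(fit$residuals^2)
  sigma2_e <- rss / n
  XtX_inv <- solve(crossprod(Xw))
  beta <- fit$coefficients
  se <- sqrt(diag(XtX_inv) * sigma2_e * n / (n - p))
  list(delta = delta, sigma2_e = sigma2_e, sigma2_g = delta * sigma2_e,
       beta = beta, se = se, log_lik = ll, n = n, rank = p)
}

## vectorized per-marker OLS F-tests after projecting out X0
.scan_ols <- function(y, X0, Gmat, poly_ok) {
  q0 <- qr(X0)
  r0 <- q0$rank
  n <- length(y)
  ey <- qr.resid(q0, y)
  Eg <- qr.resid(q0, Gmat)
  gg <- colSums(Eg^2)
  gy <- colSums(Eg * ey)
  est <- poly_ok & gg > n * .Machine$double.eps
  beta <- ifelse(est, gy / gg, NA_real_)
  rss0 <- sum(ey^2)
  rss1 <- rss0 - ifelse(est, gy^2 / gg, 0)
  df2 <- n - r0 - 1L
  Fst <- (rss0 - rss1) / (rss1 / df2)
  p <- ifelse(est, stats::pf(Fst, 1, df2, lower.tail = FALSE), NA_real_)
  list(effect = beta, p_value = p)
}

## validate/prune the covariate design; drop aliased columns with a message
.build_design <- function(n, Q_scores = NULL) {
  X0 <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(Q_scores)) {
    X0 <- cbind(X0, Q_scores)
    q <- qr(X0)
    if (q$rank < ncol(X0)) {
      keep <- q$pivot[seq_len(q$rank)]
      dropped <- colnames(X0)[setdiff(seq_len(ncol(X0)), keep)]
      message("dropping collinear covariate column(s): ",
              paste(dropped, collapse = ", "))
      X0 <- X0[, sort(keep), drop = FALSE]
      if (qr(X0)$rank < ncol(X0)) {
        stop("covariate matrix remains singular; collinear columns: ",
             paste(colnames(X0), collapse = ", "))
      }
    }
  }
  X0
}

## extract one trait as a named numeric vector
.trait_vector <- function(pheno, trait) {
  if (is.numeric(pheno) && !is.null(names(pheno))) return(pheno)
  stopifnot(is.data.frame(pheno),
            all(c("accession", "trait", "value") %in% names(pheno)))
  sub <- pheno[pheno$trait == trait, , drop = FALSE]
  if (!nrow(sub)) stop("trait '", trait, "' not found in phenotype table")
  stats::setNames(sub$value, sub$accession)
}

#' Single-marker association scan under one of four nested models
#'
#' Tests each marker against a trait under: `M` (marker fixed effect
#' only), `M+Q` (plus structure covariates), `M+K` (plus a random
#' polygenic effect with covariance proportional to the kinship matrix)
#' or `M+Q+K` (both). Fixed-effects models use an F-test on the marker
#' term; kinship models are ML linear mixed models ([ml_mixed_fit()])
#' where, by default, the variance components are estimated once under
#' the no-marker null and reused for every marker (the usual
#' population-parameters-previously-determined approximation), with the
#' marker tested by a Wald/F statistic on its coefficient. Binary traits
#' are analyzed on the 0/1 scale in the same machinery.
#'
#' In the default fast mode, missing genotype calls are mean-imputed per
#' marker; `exact = TRUE` instead refits each marker on its complete
#' cases, re-estimating the variance components per marker (reference
#' implementation for small panels). Monomorphic markers get `NA`
#' p-values and are excluded from the FDR adjustment.
#'
#' @param G A [genotype_matrix()] (QC- and MAF-filtered).
#' @param pheno Phenotype table (`accession`, `trait`, `value`) or a named
#'   numeric vector.
#' @param trait Trait name (ignored when `pheno` is a vector).
#' @param model `"M"`, `"M+Q"`, `"M+K"` or `"M+Q+K"` (compact forms
#'   `"MQ"`, `"MK"`, `"MQK"` also accepted).
#' @param Q A [pca_structure()] result or a plain score matrix with
#'   accession rownames; required for the Q models.
#' @param K A kinship matrix (floored); required for the K models.
#' @param exact Per-marker complete-case refit instead of the fast
#'   mean-imputed scan.
#' @return Data frame with columns `marker`, `model`, `effect`,
#'   `p_value`, `fdr_adjusted_p`, `n_used`, `minus_log10_p`.
#' @export
fit_single_marker <- function(G, pheno, trait = NULL,
                              model = c("M", "M+Q", "M+K", "M+Q+K"),
                              Q = NULL, K = NULL, exact = FALSE) {
  stopifnot(inherits(G, "genotype_matrix"))
  model <- .normalize_model(if (length(model) > 1L) model[1L] else model)
  use_q <- model %in% c("M+Q", "M+Q+K")
  use_k <- model %in% c("M+K", "M+Q+K")
  if (use_q && is.null(Q)) stop("model ", model, " requires Q")
  if (use_k && is.null(K)) stop("model ", model, " requires K")

  y_all <- .trait_vector(pheno, trait)
  acc <- G$accession_ids
  acc <- acc[acc %in% names(y_all)[!is.na(y_all)]]
  Qs <- NULL
  if (use_q) {
    Qs <- if (inherits(Q, "q_matrix")) Q$scores else Q
    acc <- acc[acc %in% rownames(Qs)]
  }
  if (use_k) acc <- acc[acc %in% rownames(K)]
  n <- length(acc)
  if (n < 5L) stop("too few accessions with complete trait/covariate data")
  y <- unname(y_all[acc])
  if (use_q) Qs <- Qs[acc, , drop = FALSE]
  X0 <- .build_design(n, Qs)

  Gm <- G$calls[acc, , drop = FALSE]
  storage.mode(Gm) <- "double"
  n_nonmiss <- colSums(!is.na(Gm))
  v <- apply(Gm, 2L, function(g) stats::var(g, na.rm = TRUE))
  poly_ok <- n_nonmiss >= 2L & !is.na(v) & v > 0

  if (!exact) {
    cm <- colMeans(Gm, na.rm = TRUE)
    idx <- which(is.na(Gm), arr.ind = TRUE)
    if (nrow(idx)) Gm[idx] <- cm[idx[, 2L]]
    if (use_k) {
      eig <- eigen(unclass(K)[acc, acc], symmetric = TRUE)
      null_fit <- ml_mixed_fit(y, X0, eig)
      w <- 1 / (null_fit$delta * pmax(eig$values, 0) + 1)
      A <- sqrt(w) * t(eig$vectors)
      sc <- .scan_ols(drop(A %*% y), A %*% X0, A %*% Gm, poly_ok)
    } else {
      sc <- .scan_ols(y, X0, Gm, poly_ok)
    }
    eff <- sc$effect; pv <- sc$p_value
    n_used <- rep(n, ncol(Gm))
  } else {
    m <- ncol(Gm)
    eff <- pv <- rep(NA_real_, m)
    n_used <- integer(m)
    for (j in seq_len(m)) {
      ok <- !is.na(Gm[, j])
      n_used[j] <- sum(ok)
      if (!poly_ok[j]) next
      Xf <- cbind(X0[ok, , drop = FALSE], marker = Gm[ok, j])
      if (qr(Xf)$rank < ncol(Xf)) next
      if (use_k) {
        fit <- ml_mixed_fit(y[ok], Xf, unclass(K)[acc[ok], acc[ok]])
        b <- fit$beta[ncol(Xf)]; s <- fit$se[ncol(Xf)]
        Fst <- (b / s)^2
        pv[j] <- stats::pf(Fst, 1, fit$n - fit$rank, lower.tail = FALSE)
        eff[j] <- b
      } else {
        sc <- .scan_ols(y[ok], X0[ok, , drop = FALSE],
                        Gm[ok, j, drop = FALSE], TRUE)
        eff[j] <- sc$effect; pv[j] <- sc$p_value
      }
    }
  }

  out <- data.frame(marker = colnames(Gm), model = model, effect = eff,
                    p_value = pv, fdr_adjusted_p = fdr_adjust(pv),
                    n_used = n_used, minus_log10_p = -log10(pv),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values, order-preserving and capped at 1; `NA`
#' entries (e.g. monomorphic markers) are excluded from the adjustment and
#' returned as `NA`.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as `p`.
#' @export
fdr_adjust <- function(p) {
  out <- p
  ok <- !is.na(p)
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Genome scan table ordered by map position
#'
#' Joins association results to the genetic map, orders by chromosome and
#' cM, and flags markers significant at `alpha` after FDR adjustment.
#'
#' @param results Data frame from [fit_single_marker()].
#' @param map Map data frame (`marker`, `chrom`, `pos_cM`) or a
#'   [genotype_matrix()].
#' @param alpha Significance level on the adjusted p-values (default
#'   0.05).
#' @return Data frame: `marker`, `chrom`, `pos_cM`, `model`, `p_value`,
#'   `fdr_adjusted_p`, `minus_log10_p`, `significant`, ordered by
#'   chromosome then position.
#' @export
genome_scan <- function(results, map, alpha = 0.05) {
  if (inherits(map, "genotype_matrix")) map <- map$map
  if (!nrow(results)) {
    return(data.frame(marker = character(), chrom = character(),
                      pos_cM = numeric(), model = character(),
                      p_value = numeric(), fdr_adjusted_p = numeric(),
                      minus_log10_p = numeric(), significant = logical(),
                      stringsAsFactors = FALSE))
  }
  i <- match(results$marker, map$marker)
  out <- data.frame(marker = results$marker, chrom = map$chrom[i],
                    pos_cM = map$pos_cM[i], model = results$model,
                    p_value = results$p_value,
                    fdr_adjusted_p = results$fdr_adjusted_p,
                    minus_log10_p = results$minus_log10_p,
                    significant = !is.na(results$fdr_adjusted_p) &
                      results$fdr_adjusted_p < alpha,
                    stringsAsFactors = FALSE)
  out[order(out$chrom, out$pos_cM, method = "radix", na.last = TRUE), ,
      drop = FALSE]
}
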