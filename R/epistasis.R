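#' Select candidate markers for the interaction scan
#'
#' Markers whose FDR-adjusted p-value under the M+Q+K model falls strictly
#' below the gate threshold (default 0.20) enter the all-pairs interaction
#' scan. `use = "raw"` gates on raw p-values instead (both counts are
#' reported in the message).
#'
#' @param assoc Data frame from [fit_single_marker()] under M+Q+K.
#' @param threshold Gate threshold (default 0.20).
#' @param use Gate on `"adjusted"` (default) or `"raw"` p-values.
#' @return Character vector of selected marker ids (possibly empty).
#' @export
select_candidates <- function(assoc, threshold = 0.20,
                              use = c("adjusted", "raw")) {
  use <- match.arg(use)
  padj <- assoc$fdr_adjusted_p
  praw <- assoc$p_value
  sel_adj <- !is.na(padj) & padj < threshold
  sel_raw <- !is.na(praw) & praw < threshold
  sel <- if (use == "adjusted") sel_adj else sel_raw
  message("select_candidates: ", sum(sel), " markers below ", threshold,
          " (", use, " p; adjusted would give ", sum(sel_adj),
          ", raw would give ", sum(sel_raw), ")")
  if (!any(sel)) {
    message("no candidate markers; interaction scan will be skipped")
  }
  assoc$marker[sel]
}

#' All unordered marker pairs
#'
#' @param markers Character vector of marker ids.
#' @return Data frame with columns `marker_a`, `marker_b`; exactly
#'   n(n-1)/2 rows, no self-pairs, no duplicates. Fewer than two markers
#'   give zero rows.
#' @export
enumerate_pairs <- function(markers) {
  markers <- unique(markers)
  if (length(markers) < 2L) {
    return(data.frame(marker_a = character(), marker_b = character(),
                      stringsAsFactors = FALSE))
  }
  cb <- utils::combn(markers, 2L)
  data.frame(marker_a = cb[1L, ], marker_b = cb[2L, ],
             stringsAsFactors = FALSE)
}

## ML -2 log likelihood of an OLS fit: n log(2 pi RSS/n) + n
.rss_and_rank <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  list(rss = sum(fit$residuals^2), rank = fit$rank)
}

#' Two-marker interaction likelihood-ratio test
#'
#' Compares, by maximum likelihood, the full model
#' `trait ~ structure + marker_a + marker_b + marker_a:marker_b` with the
#' reduced model `trait ~ structure` on the same complete-case accession
#' set. The statistic is the difference of the two -2 log likelihoods and
#' is referred to a chi-square whose degrees of freedom equal the
#' difference in estimable fixed-effect parameters (3 for two complete
#' biallelic markers; fewer when a term is inestimable, e.g. an empty
#' interaction cell). Kinship is deliberately absent: the reduced model
#' contains only the population structure.
#'
#' For a binary trait, a full-model residual sum of squares of zero means
#' the four genotype combinations predict the trait without error: the
#' result is flagged `perfect_flag` with p-value 0 and undefined -log10 p.
#'
#' @param ga,gb Numeric 0/1 genotype vectors named by accession, or
#'   marker ids looked up in `G`.
#' @param pheno Phenotype table or named trait vector (see
#'   [fit_single_marker()]).
#' @param Q A [pca_structure()] result or score matrix with accession
#'   rownames.
#' @param G Optional [genotype_matrix()] used to resolve marker ids.
#' @param trait Trait name when `pheno` is a table.
#' @return One-row data frame: `marker_a`, `marker_b`, `lrt_stat`, `df`,
#'   `p_value`, `minus_log10_p`, `perfect_flag`, `n_used`,
#'   `inestimable`.
#' @export
interaction_lrt <- function(ga, gb, pheno, Q, G = NULL, trait = NULL) {
  resolve <- function(g) {
    if (is.character(g) && length(g) == 1L) {
      if (is.null(G)) stop("marker ids need `G` to be supplied")
      stats::setNames(as.numeric(G$calls[, g]), G$accession_ids)
    } else g
  }
  ga_v <- resolve(ga); gb_v <- resolve(gb)
  name_a <- if (is.character(ga) && length(ga) == 1L) ga else "marker_a"
  name_b <- if (is.character(gb) && length(gb) == 1L) gb else "marker_b"
  y_all <- .trait_vector(pheno, trait)
  Qs <- if (inherits(Q, "q_matrix")) Q$scores else Q

  acc <- Reduce(intersect, list(names(y_all)[!is.na(y_all)],
                                names(ga_v)[!is.na(ga_v)],
                                names(gb_v)[!is.na(gb_v)],
                                rownames(Qs)))
  n <- length(acc)
  out <- data.frame(marker_a = name_a, marker_b = name_b,
                    lrt_stat = NA_real_, df = NA_integer_,
                    p_value = NA_real_, minus_log10_p = NA_real_,
                    perfect_flag = FALSE, n_used = n, inestimable = TRUE,
                    stringsAsFactors = FALSE)
  if (n < 5L) return(out)
  y <- unname(y_all[acc])
  X0 <- .build_design(n, Qs[acc, , drop = FALSE])
  a <- unname(ga_v[acc]); b <- unname(gb_v[acc])
  Xf <- cbind(X0, a = a, b = b, ab = a * b)

  red <- .rss_and_rank(X0, y)
  full <- .rss_and_rank(Xf, y)
  df <- full$rank - red$rank
  if (df < 1L) return(out)
  out$df <- df
  out$inestimable <- FALSE

  binary <- all(y %in% c(0, 1))
  if (binary && full$rss < 1e-10) {
    out$lrt_stat <- Inf
    out$p_value <- 0
    out$perfect_flag <- TRUE
    return(out)
  }
  if (full$rss <= 0) full$rss <- .Machine$double.xmin
  lrt <- n * log(red$rss / full$rss)
  out$lrt_stat <- max(lrt, 0)
  out$p_value <- stats::pchisq(out$lrt_stat, df, lower.tail = FALSE)
  out$minus_log10_p <- if (out$p_value > 0) -log10(out$p_value) else {
    ## chi-square upper tail on the log scale, still finite
    -stats::pchisq(out$lrt_stat, df, lower.tail = FALSE,
                   log.p = TRUE) / log(10)
  }
  out
}

#' FDR-gated all-pairs interaction scan
#'
#' Runs [interaction_lrt()] for every pair of candidate markers and ranks
#' the results with [rank_interactions()].
#'
#' @param G A [genotype_matrix()].
#' @param pheno,trait,Q See [interaction_lrt()].
#' @param candidates Character vector of gated marker ids (from
#'   [select_candidates()]).
#' @return Ranked data frame of interaction results (one row per pair).
#' @export
interaction_scan <- function(G, pheno, Q, candidates, trait = NULL) {
  pairs <- enumerate_pairs(candidates)
  if (!nrow(pairs)) {
    message("interaction_scan: fewer than 2 candidates, nothing to test")
    return(rank_interactions(
      interaction_lrt(numeric(0), numeric(0), pheno, Q,
                      trait = trait)[0, , drop = FALSE]))
  }
  y_all <- .trait_vector(pheno, trait)
  rows <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    rows[[k]] <- interaction_lrt(pairs$marker_a[k], pairs$marker_b[k],
                                 y_all, Q, G = G)
  }
  rank_interactions(do.call(rbind, rows))
}

#' Competition ranking of interaction results
#'
#' Sorts by LRT statistic descending with perfect-prediction results
#' first; statistics equal within `tie_tol` share the lowest rank and the
#' next distinct value's rank skips accordingly (1, 1, 3 pattern).
#'
#' @param results Data frame from [interaction_lrt()] rows.
#' @param tie_tol Tie tolerance on the statistic (default 1e-9).
#' @return The results sorted, with a `rank` column added.
#' @export
rank_interactions <- function(results, tie_tol = 1e-9) {
  if (!nrow(results)) {
    results$rank <- integer(0)
    return(results)
  }
  key <- results$lrt_stat
  key[is.na(key)] <- -Inf
  key[results$perfect_flag] <- Inf
  ord <- order(-key)
  results <- results[ord, , drop = FALSE]
  key <- key[ord]
  rk <- integer(length(key))
  rk[1L] <- 1L
  for (i in seq_along(key)[-1L]) {
    tied <- (is.infinite(key[i]) && key[i] == key[i - 1L]) ||
      (is.finite(key[i]) && is.finite(key[i - 1L]) &&
         abs(key[i] - key[i - 1L]) <= tie_tol)
    rk[i] <- if (tied) rk[i - 1L] else i
  }
  results$rank <- rk
  rownames(results) <- NULL
  results
}
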