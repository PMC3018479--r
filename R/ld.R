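#' Pairwise linkage disequilibrium with Fisher exact significance
#'
#' For inbred lines haplotypes are observed directly, so for each marker
#' pair the 2x2 haplotype count table over pairwise-complete accessions
#' gives r-squared, the squared correlation of haplotype frequencies
#' ((p_AB - p_A p_B)^2 / (p_A p_a p_B p_b)), and a two-sided Fisher exact
#' p-value. Pairs on the same (known) chromosome carry their cM distance
#' and `linked_flag = TRUE`; pairs on different or unknown chromosomes are
#' unlinked with undefined distance.
#'
#' @param G A [genotype_matrix()] (MAF-filtered within the analysis scope).
#' @param accessions Optional accession subset defining the scope (e.g. one
#'   germplasm group).
#' @param markers Optional marker subset.
#' @param p_for Which pairs get a Fisher p-value: `"all"`, `"linked"`
#'   (same chromosome only, cheaper when only the decay fit needs
#'   significance) or `"none"`.
#' @param min_obs Pairs with fewer complete observations are skipped
#'   (default 2); the number skipped is attached as attribute `n_skipped`.
#' @return Data frame with columns `marker_a`, `marker_b`, `r2`,
#'   `p_value`, `distance_cM`, `linked_flag`, `n_obs`.
#' @export
pairwise_ld <- function(G, accessions = NULL, markers = NULL,
                        p_for = c("all", "linked", "none"), min_obs = 2L) {
  stopifnot(inherits(G, "genotype_matrix"))
  p_for <- match.arg(p_for)
  G <- subset_genotypes(G, markers = markers, accessions = accessions)
  X <- G$calls
  storage.mode(X) <- "double"
  m <- ncol(X)
  if (m < 2L) stop("need at least 2 markers")

  ## pairwise-complete counts via indicator cross-products
  obs <- !is.na(X)
  X0 <- X; X0[!obs] <- 0
  n11 <- t(X0) %*% X0                       # both carry allele B
  nB_a <- t(X0) %*% obs                     # a is B, b observed
  nB_b <- t(obs * 1) %*% X0                 # a observed, b is B
  nobs <- t(obs * 1) %*% (obs * 1)

  ut <- which(upper.tri(nobs), arr.ind = TRUE)
  ia <- ut[, 1L]; ib <- ut[, 2L]
  n <- nobs[ut]
  keep <- n >= min_obs
  n_skipped <- sum(!keep)
  ia <- ia[keep]; ib <- ib[keep]; n <- n[keep]
  c11 <- n11[ut][keep]
  ca <- nB_a[ut][keep]
  cb <- nB_b[ut][keep]

  pa <- ca / n
  pb <- cb / n
  pab <- c11 / n
  Dld <- pab - pa * pb
  den <- pa * (1 - pa) * pb * (1 - pb)
  r2 <- ifelse(den > 0, Dld^2 / den, NA_real_)
  r2 <- pmin(pmax(r2, 0), 1)

  chra <- G$map$chrom[ia]; chrb <- G$map$chrom[ib]
  posa <- G$map$pos_cM[ia]; posb <- G$map$pos_cM[ib]
  linked <- !is.na(chra) & !is.na(chrb) & chra == chrb &
    !is.na(posa) & !is.na(posb)
  dist <- ifelse(linked, abs(posa - posb), NA_real_)

  pv <- rep(NA_real_, length(ia))
  if (p_for != "none") {
    do_p <- if (p_for == "linked") which(linked) else seq_along(ia)
    for (k in do_p) {
      tab <- matrix(c(c11[k], cb[k] - c11[k],
                      ca[k] - c11[k], n[k] - ca[k] - cb[k] + c11[k]),
                    2L, 2L)
      pv[k] <- stats::fisher.test(tab)$p.value
    }
  }

  out <- data.frame(marker_a = G$marker_ids[ia],
                    marker_b = G$marker_ids[ib],
                    r2 = r2, p_value = pv, distance_cM = dist,
                    linked_flag = linked, n_obs = as.integer(n),
                    stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Parametric LD significance threshold from unlinked pairs
#'
#' Fits a Box-Cox power transformation (maximum-likelihood lambda) to the
#' r-squared values of unlinked marker pairs after a fixed small shift
#' (+1e-6, since r-squared can be exactly 0 and the transform needs
#' positive input), takes the parametric 95th percentile
#' (mean + 1.645 sd) on the transformed scale, and back-transforms to the
#' r-squared scale. Values of r-squared above this threshold on the same
#' chromosome are taken as linkage-driven LD.
#'
#' With fewer than 30 values a warning is issued and the empirical 95th
#' percentile is returned instead; degenerate (all-equal) input gives `NA`
#' with attribute `reason`.
#'
#' @param unlinked_r2 Numeric vector of r-squared values from unlinked
#'   (different-chromosome) pairs.
#' @param shift Positivity shift (default 1e-6).
#' @return Threshold on the r-squared scale (attributes `lambda`,
#'   `method`), or `NA` when not estimable.
#' @export
unlinked_threshold <- function(unlinked_r2, shift = 1e-6) {
  x <- unlinked_r2[!is.na(unlinked_r2)]
  if (length(x) == 0L) {
    return(structure(NA_real_, reason = "no unlinked r2 values"))
  }
  if (stats::sd(x) < .Machine$double.eps^0.5) {
    return(structure(NA_real_, reason = "degenerate: all unlinked r2 equal"))
  }
  if (length(x) < 30L) {
    warning("fewer than 30 unlinked r2 values; ",
            "falling back to the empirical 95th percentile")
    return(structure(stats::quantile(x, 0.95, names = FALSE),
                     method = "empirical"))
  }
  xs <- x + shift
  bc <- MASS::boxcox(xs ~ 1, lambda = seq(-5, 5, 0.01), plotit = FALSE)
  lambda <- bc$x[which.max(bc$y)]
  y <- if (abs(lambda) < 1e-8) log(xs) else (xs^lambda - 1) / lambda
  thr_y <- mean(y) + stats::qnorm(0.95) * stats::sd(y)
  thr <- if (abs(lambda) < 1e-8) {
    exp(thr_y)
  } else {
    base <- lambda * thr_y + 1
    if (base <= 0) return(structure(NA_real_, reason = "back-transform undefined"))
    base^(1 / lambda)
  }
  thr <- min(max(thr - shift, 0), 1)
  structure(thr, lambda = lambda, method = "boxcox-parametric")
}

#' Extent of linkage disequilibrium from a loess decay curve
#'
#' Restricts same-chromosome pairs to those with significant LD
#' (Fisher p below `p_cut`), fits a second-degree loess of r-squared on cM
#' distance with pointwise confidence bands, and takes the smallest
#' distance at which the fitted curve crosses the threshold baseline from
#' above as the extent of LD. The confidence-interval endpoints come from
#' the analogous crossings of the lower and upper bands.
#'
#' Not estimable when fewer than `min_pairs` significant pairs remain,
#' when the only significant pairs all have r-squared 1 (a threshold of 1
#' cannot be crossed), when the threshold itself is `NA`, or when the
#' fitted curve never exceeds the threshold; the `reason` field says which.
#'
#' @param pairs Data frame from [pairwise_ld()] (may contain unlinked
#'   pairs; only linked ones are used).
#' @param threshold_r2 Baseline from [unlinked_threshold()].
#' @param conf Confidence level of the pointwise bands (default 0.90).
#' @param span Loess span (default 0.5).
#' @param p_cut Significance cut for pairs entering the fit (default
#'   0.001).
#' @param min_pairs Minimum number of significant pairs (default 10).
#' @param grid_step Evaluation grid step in cM for crossing detection
#'   (default 0.01); crossings are located by linear interpolation.
#' @param label Chromosome or panel label carried through to the result.
#' @return A list of class `ld_extent`: `label`, `threshold_r2`,
#'   `extent_cM` (`NA` when not estimable), `ci_low_cM`, `ci_high_cM`,
#'   `n_pairs_used`, `span`, `conf`, `reason` (`NA` when estimable).
#' @export
ld_extent <- function(pairs, threshold_r2, conf = 0.90, span = 0.5,
                      p_cut = 0.001, min_pairs = 10L, grid_step = 0.01,
                      label = "panel") {
  res <- list(label = label, threshold_r2 = as.numeric(threshold_r2),
              extent_cM = NA_real_, ci_low_cM = NA_real_,
              ci_high_cM = NA_real_, n_pairs_used = 0L, span = span,
              conf = conf, reason = NA_character_)
  class(res) <- "ld_extent"
  fail <- function(why) { res$reason <- why; res }

  sig <- pairs[pairs$linked_flag & !is.na(pairs$p_value) &
                 pairs$p_value < p_cut & !is.na(pairs$r2) &
                 !is.na(pairs$distance_cM), , drop = FALSE]
  res$n_pairs_used <- nrow(sig)
  if (is.na(threshold_r2)) return(fail("threshold not estimable"))
  if (nrow(sig) < min_pairs) {
    return(fail(sprintf("only %d significant pairs (need %d)",
                        nrow(sig), min_pairs)))
  }
  if (all(sig$r2 >= 1 - 1e-12)) {
    return(fail("all significant pairs have r2 = 1"))
  }

  fit <- stats::loess(r2 ~ distance_cM, data = sig, span = span, degree = 2,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  grid <- seq(0, max(sig$distance_cM), by = grid_step)
  pr <- stats::predict(fit, newdata = data.frame(distance_cM = grid),
                       se = TRUE)
  z <- stats::qnorm(0.5 + conf / 2)
  curve <- pr$fit
  upper <- pr$fit + z * pr$se.fit
  lower <- pr$fit - z * pr$se.fit

  cross_down <- function(yv) {
    ok <- is.finite(yv)
    i <- which(ok[-length(yv)] & ok[-1L] &
                 yv[-length(yv)] >= threshold_r2 & yv[-1L] < threshold_r2)
    if (!length(i)) return(NA_real_)
    i <- i[1L]
    frac <- (yv[i] - threshold_r2) / (yv[i] - yv[i + 1L])
    unname(grid[i] + frac * grid_step)
  }
  ext <- cross_down(curve)
  if (is.na(ext)) {
    if (max(curve, na.rm = TRUE) < threshold_r2) {
      return(fail("fitted curve never exceeds the threshold"))
    }
    return(fail("fitted curve does not cross the threshold from above"))
  }
  res$extent_cM <- ext
  res$ci_low_cM <- cross_down(lower)
  res$ci_high_cM <- cross_down(upper)
  ## lower band sits under the curve so it crosses earlier; if a band never
  ## crosses, that endpoint is undefined
  res
}

#' @export
print.ld_extent <- function(x, ...) {
  if (is.na(x$extent_cM)) {
    cat("ld_extent [", x$label, "]: not estimable (", x$reason, ")\n",
        sep = "")
  } else {
    cat(sprintf("ld_extent [%s]: %.2f cM (%.0f%% CI %.2f-%.2f), %d pairs\n",
                x$label, x$extent_cM, 100 * x$conf, x$ci_low_cM,
                x$ci_high_cM, x$n_pairs_used))
  }
  invisible(x)
}

#' Per-chromosome LD extent and panel average
#'
#' Applies [ld_extent()] chromosome by chromosome against a common
#' threshold and reports the unweighted mean of the estimable extents as
#' the panel-average extent.
#'
#' @param pairs Data frame from [pairwise_ld()].
#' @param threshold_r2 Baseline from [unlinked_threshold()].
#' @param ... Passed to [ld_extent()].
#' @param G The [genotype_matrix()] the pairs came from (supplies the map).
#' @return List with `per_chromosome` (data frame: chrom, extent_cM,
#'   ci_low_cM, ci_high_cM, n_pairs_used, reason) and `mean_extent_cM`.
#' @export
ld_extent_by_chromosome <- function(pairs, threshold_r2, G, ...) {
  stopifnot(inherits(G, "genotype_matrix"))
  chrom_of <- stats::setNames(G$map$chrom, G$map$marker)
  pr_chrom <- chrom_of[pairs$marker_a]
  chroms <- sort(unique(pr_chrom[pairs$linked_flag]))
  rows <- lapply(chroms, function(ch) {
    est <- ld_extent(pairs[pairs$linked_flag & pr_chrom == ch, , drop = FALSE],
                     threshold_r2, label = ch, ...)
    data.frame(chrom = ch, extent_cM = est$extent_cM,
               ci_low_cM = est$ci_low_cM, ci_high_cM = est$ci_high_cM,
               n_pairs_used = est$n_pairs_used, reason = est$reason,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  list(per_chromosome = per,
       mean_extent_cM = mean(per$extent_cM, na.rm = TRUE))
}
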