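#' Genotype matrix for inbred (homozygous) accessions
#'
#' Container for accession x marker biallelic calls, an optional genetic map
#' and optional per-marker quality-control scores. Accessions are inbred
#' lines, so each call is one of the two alleles (coded 0/1) or missing.
#'
#' @param calls Integer or numeric matrix of 0/1/NA calls with accessions in
#'   rows and markers in columns. Dimnames are required and must be unique.
#' @param map Optional data frame with columns `marker`, `chrom`, `pos_cM`.
#'   Markers absent from the map, or with `NA` chromosome/position, are
#'   treated as having unknown position. Positions must be nonnegative.
#' @param qc Optional named numeric vector of per-marker quality scores in
#'   \[0, 1\] (e.g. array cluster-quality scores). Unnamed markers are
#'   treated as unscored.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `calls` (0/1/NA integer matrix), `accession_ids`, `marker_ids`,
#'   `map` (data frame, one row per marker, `chrom`/`pos_cM` possibly `NA`)
#'   and `qc` (numeric vector aligned to markers, `NA` when unscored).
#' @export
genotype_matrix <- function(calls, map = NULL, qc = NULL) {
  if (!is.matrix(calls)) stop("`calls` must be a matrix")
  acc <- rownames(calls)
  mrk <- colnames(calls)
  if (is.null(acc) || is.null(mrk)) {
    stop("`calls` must have accession rownames and marker colnames")
  }
  if (anyDuplicated(acc)) {
    stop("duplicate accession id: ", acc[duplicated(acc)][1L])
  }
  if (anyDuplicated(mrk)) {
    stop("duplicate marker id: ", mrk[duplicated(mrk)][1L])
  }
  storage.mode(calls) <- "integer"
  bad <- !(is.na(calls) | calls == 0L | calls == 1L)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop("non-biallelic call at accession '", acc[idx[1L]],
         "', marker '", mrk[idx[2L]], "'")
  }

  full_map <- data.frame(marker = mrk, chrom = NA_character_,
                         pos_cM = NA_real_, stringsAsFactors = FALSE)
  if (!is.null(map)) {
    need <- c("marker", "chrom", "pos_cM")
    if (!all(need %in% names(map))) {
      stop("map must have columns marker, chrom, pos_cM")
    }
    if (anyDuplicated(map$marker)) {
      stop("duplicate marker id in map: ",
           map$marker[duplicated(map$marker)][1L])
    }
    i <- match(mrk, map$marker)
    full_map$chrom <- as.character(map$chrom)[i]
    full_map$pos_cM <- as.numeric(map$pos_cM)[i]
    if (any(full_map$pos_cM < 0, na.rm = TRUE)) {
      stop("map positions must be nonnegative")
    }
  }

  full_qc <- rep(NA_real_, length(mrk))
  names(full_qc) <- mrk
  if (!is.null(qc)) {
    if (is.null(names(qc))) stop("`qc` must be a named vector")
    if (any(qc < 0 | qc > 1, na.rm = TRUE)) stop("qc scores must be in [0,1]")
    full_qc[intersect(names(qc), mrk)] <-
      qc[intersect(names(qc), mrk)]
  }

  structure(
    list(calls = calls, accession_ids = acc, marker_ids = mrk,
         map = full_map, qc = full_qc),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  n_known <- sum(!is.na(x$map$pos_cM))
  cat("genotype_matrix:", length(x$accession_ids), "accessions x",
      length(x$marker_ids), "markers\n")
  cat("  mapped markers:", n_known, " missing calls:",
      round(mean(is.na(x$calls)), 4), "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Subset a genotype matrix by markers and/or accessions
#'
#' @param G A [genotype_matrix()].
#' @param markers,accessions Character vectors of ids to keep (order
#'   preserved as given); `NULL` keeps all.
#' @return A `genotype_matrix` restricted to the requested ids.
#' @export
subset_genotypes <- function(G, markers = NULL, accessions = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (is.null(markers)) markers <- G$marker_ids
  if (is.null(accessions)) accessions <- G$accession_ids
  if (!all(markers %in% G$marker_ids)) stop("unknown marker id requested")
  if (!all(accessions %in% G$accession_ids)) stop("unknown accession id requested")
  calls <- G$calls[accessions, markers, drop = FALSE]
  map <- G$map[match(markers, G$map$marker), , drop = FALSE]
  rownames(map) <- NULL
  genotype_matrix(calls, map = map, qc = G$qc[markers])
}

#' Per-marker minor allele frequency
#'
#' Computed on non-missing calls only. Markers with no non-missing calls
#' get `NA`.
#'
#' @param G A [genotype_matrix()].
#' @return Named numeric vector of MAF in \[0, 0.5\].
#' @export
marker_maf <- function(G) {
  stopifnot(inherits(G, "genotype_matrix"))
  p <- colMeans(G$calls, na.rm = TRUE)
  p[is.nan(p)] <- NA_real_
  pmin(p, 1 - p)
}

#' Per-marker missing-call fraction
#'
#' @param G A [genotype_matrix()].
#' @return Named numeric vector of missing fractions in \[0, 1\].
#' @export
marker_missingness <- function(G) {
  stopifnot(inherits(G, "genotype_matrix"))
  colMeans(is.na(G$calls))
}
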