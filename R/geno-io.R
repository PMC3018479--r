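#' Read genotype, map and QC tables
#'
#' File dialect (all tab-separated, header row mandatory):
#' \describe{
#'   \item{genotype TSV}{first column `accession`, remaining columns one per
#'     marker, cells coded `A`, `B` or `NA` (empty also accepted as missing).
#'     Inbred lines: one allele per cell.}
#'   \item{map TSV}{columns `marker`, `chrom`, `pos_cM`; unknown positions
#'     are written as `NA` and preserved as unknown, not dropped.}
#'   \item{QC TSV}{columns `marker`, `qc_score` with scores in \[0, 1\].}
#' }
#' Allele `A` is coded 0 and `B` is coded 1 internally.
#'
#' @param path Genotype TSV path.
#' @param map_path Optional map TSV path.
#' @param qc_path Optional QC TSV path.
#' @return A validated [genotype_matrix()].
#' @export
read_genotypes <- function(path, map_path = NULL, qc_path = NULL) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (names(raw)[1L] != "accession") {
    stop("genotype file must start with an 'accession' column: ", path)
  }
  acc <- raw[[1L]]
  if (anyDuplicated(acc)) {
    stop("duplicate accession id '", acc[duplicated(acc)][1L],
         "' at line ", which(duplicated(acc))[1L] + 1L, " of ", path)
  }
  mrk <- names(raw)[-1L]
  if (anyDuplicated(mrk)) {
    stop("duplicated marker id '", mrk[duplicated(mrk)][1L], "' in ", path)
  }
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  cells[cells == "" | cells == "NA"] <- NA
  bad <- !is.na(cells) & !(cells %in% c("A", "B"))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop("invalid genotype code '", cells[idx[1L], idx[2L]], "' at line ",
         idx[1L] + 1L, " (accession '", acc[idx[1L]], "', marker '",
         mrk[idx[2L]], "') of ", path)
  }
  calls <- matrix(NA_integer_, nrow(cells), ncol(cells),
                  dimnames = list(acc, mrk))
  calls[cells == "A"] <- 0L
  calls[cells == "B"] <- 1L

  map <- NULL
  if (!is.null(map_path)) {
    map <- utils::read.table(map_path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, na.strings = "NA")
    if (!all(c("marker", "chrom", "pos_cM") %in% names(map))) {
      stop("map file must have columns marker, chrom, pos_cM: ", map_path)
    }
  }
  qc <- NULL
  if (!is.null(qc_path)) {
    qtab <- utils::read.table(qc_path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
    if (!all(c("marker", "qc_score") %in% names(qtab))) {
      stop("QC file must have columns marker, qc_score: ", qc_path)
    }
    qc <- stats::setNames(as.numeric(qtab$qc_score), qtab$marker)
  }
  genotype_matrix(calls, map = map, qc = qc)
}

#' Write genotype, map and QC tables
#'
#' Inverse of [read_genotypes()]; round-trips calls, map and QC fields
#' losslessly.
#'
#' @param G A [genotype_matrix()].
#' @param path Genotype TSV path to write.
#' @param map_path Optional map TSV path.
#' @param qc_path Optional QC TSV path.
#' @return Invisibly, the paths written.
#' @export
write_genotypes <- function(G, path, map_path = NULL, qc_path = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  codes <- matrix(NA_character_, nrow(G$calls), ncol(G$calls),
                  dimnames = dimnames(G$calls))
  codes[G$calls == 0L] <- "A"
  codes[G$calls == 1L] <- "B"
  out <- data.frame(accession = G$accession_ids, codes,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(map_path)) {
    utils::write.table(G$map, map_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(qc_path)) {
    utils::write.table(
      data.frame(marker = names(G$qc), qc_score = unname(G$qc)),
      qc_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(c(path, map_path, qc_path))
}

#' Read and write phenotype tables
#'
#' Long-format TSV with columns `accession`, `trait`, `value`. Censored
#' days-to-flowering values equal the censor constant exactly; binary traits
#' are coded 0/1. Missing values allowed.
#'
#' @param path Phenotype TSV path.
#' @return Data frame with columns `accession`, `trait`, `value`.
#' @export
read_phenotypes <- function(path) {
  ph <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = "NA")
  if (!all(c("accession", "trait", "value") %in% names(ph))) {
    stop("phenotype file must have columns accession, trait, value: ", path)
  }
  ph$value <- as.numeric(ph$value)
  ph
}

#' @rdname read_phenotypes
#' @param pheno Phenotype data frame to write.
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.table(pheno[, c("accession", "trait", "value")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Marker quality-control filter
#'
#' Retains exactly the markers with known map position (when
#' `require_position`), missing-call fraction not above `max_missing`, and
#' quality score not below `min_qc`. Markers without a quality score pass
#' the score criterion (they were never scored by the assay). Surviving
#' calls are never modified, only whole markers dropped. The number of
#' markers removed by each criterion is attached as attribute `removed`
#' and reported via `message()`.
#'
#' @param G A [genotype_matrix()].
#' @param max_missing Maximum tolerated missing fraction (default 0.10:
#'   markers with more than 10\% missing data are excluded).
#' @param min_qc Minimum quality score (default 0.6).
#' @param require_position Drop markers with unknown map position
#'   (default `TRUE`).
#' @return Filtered `genotype_matrix` (possibly with zero markers).
#' @export
qc_filter <- function(G, max_missing = 0.10, min_qc = 0.6,
                      require_position = TRUE) {
  stopifnot(inherits(G, "genotype_matrix"),
            max_missing >= 0, max_missing <= 1, min_qc >= 0, min_qc <= 1)
  miss <- marker_missingness(G)
  no_pos <- require_position & (is.na(G$map$chrom) | is.na(G$map$pos_cM))
  too_missing <- miss > max_missing
  low_qc <- !is.na(G$qc) & G$qc < min_qc
  keep <- !(no_pos | too_missing | low_qc)
  removed <- c(unknown_position = sum(no_pos),
               excess_missing = sum(too_missing),
               low_qc = sum(low_qc))
  message("qc_filter: kept ", sum(keep), "/", length(keep),
          " markers (removed: position=", removed[1L],
          ", missing=", removed[2L], ", qc=", removed[3L], ")")
  out <- subset_genotypes(G, markers = G$marker_ids[keep])
  attr(out, "removed") <- removed
  out
}

#' Minor-allele-frequency filter
#'
#' Removes markers whose MAF (on non-missing calls) is strictly below
#' `min_maf`; monomorphic markers and markers with all calls missing are
#' always removed (the latter with a warning). A marker with MAF exactly
#' equal to `min_maf` is retained.
#'
#' @param G A [genotype_matrix()].
#' @param min_maf MAF threshold (default 0.05).
#' @return Filtered `genotype_matrix`.
#' @export
maf_filter <- function(G, min_maf = 0.05) {
  stopifnot(inherits(G, "genotype_matrix"), min_maf >= 0, min_maf <= 0.5)
  maf <- marker_maf(G)
  all_missing <- is.na(maf)
  if (any(all_missing)) {
    warning(sum(all_missing), " marker(s) with all calls missing removed")
  }
  keep <- !all_missing & maf >= min_maf & maf > 0
  message("maf_filter: kept ", sum(keep), "/", length(keep), " markers")
  out <- subset_genotypes(G, markers = G$marker_ids[keep])
  attr(out, "removed") <- sum(!keep)
  out
}

#' Reduce a tri-allelic site to a biallelic marker
#'
#' For a polymorphism with exactly three observed states (e.g. a SNP with
#' three nucleotides or an indel with three alleles), the calls carrying
#' the least-frequent state are converted to missing data and the two
#' remaining states form the biallelic marker. Ties for the minor state
#' are broken by the lexicographically first tied label (logged).
#'
#' @param site Character vector of per-accession state labels (`NA`
#'   allowed for missing).
#' @return The input vector with the minor state replaced by `NA`;
#'   attribute `dropped_state` records the label set to missing (or `NA`
#'   if the site already had two or fewer states).
#' @export
binarize_multiallelic <- function(site) {
  stopifnot(is.character(site) || is.factor(site))
  site <- as.character(site)
  tab <- table(site)
  n_states <- length(tab)
  if (n_states > 3L) {
    stop("site has ", n_states, " observed states; only the 3-state case ",
         "is defined")
  }
  if (n_states <= 2L) {
    attr(site, "dropped_state") <- NA_character_
    return(site)
  }
  minors <- names(tab)[tab == min(tab)]
  drop <- sort(minors)[1L]
  if (length(minors) > 1L) {
    message("binarize_multiallelic: tie among {",
            paste(sort(minors), collapse = ", "),
            "}; dropping lexicographically first '", drop, "'")
  }
  site[site == drop] <- NA_character_
  attr(site, "dropped_state") <- drop
  site
}
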