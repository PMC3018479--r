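#' Call haplotypes from an alignment of gene sequences
#'
#' Haplotypes are equivalence classes of full aligned sequences, numbered
#' by first occurrence after sorting accession ids (so the numbering does
#' not depend on input order). SNP sites are alignment columns with at
#' least two distinct non-gap characters; gap characters (`-`) are a
#' distinct state for haplotype equivalence (deletion alleles are
#' haplotype-defining) but are excluded when counting SNP sites.
#'
#' @param aligned_seqs Named character vector of equal-length aligned
#'   sequences (one per accession), or anything coercible with
#'   `as.character` that keeps names (e.g. a `Biostrings::DNAStringSet`).
#' @param gene Gene label carried through to the result.
#' @return An object of class `haplotype_set`: `gene`, `sequences`,
#'   `snp_sites` (column indices), `haplotype_of` (accession -> haplotype
#'   id `"H1"`, `"H2"`, ...), `n_haplotypes`.
#' @export
call_haplotypes <- function(aligned_seqs, gene = "gene") {
  seqs <- toupper(as.character(aligned_seqs))
  if (is.null(names(seqs)) && !is.null(names(aligned_seqs))) {
    names(seqs) <- names(aligned_seqs)
  }
  if (is.null(names(seqs))) stop("sequences must be named by accession")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    stop("alignment error: sequences have unequal lengths (",
         paste(sort(unique(lens)), collapse = ", "), ")")
  }
  seqs <- seqs[sort(names(seqs))]
  chars <- do.call(rbind, strsplit(seqs, ""))

  snp_sites <- which(apply(chars, 2L, function(col) {
    length(unique(col[col != "-"])) >= 2L
  }))

  first_seen <- seqs[!duplicated(seqs)]
  hap_of <- paste0("H", match(seqs, first_seen))
  names(hap_of) <- names(seqs)
  structure(list(gene = gene, sequences = seqs,
                 snp_sites = as.integer(snp_sites),
                 haplotype_of = hap_of,
                 n_haplotypes = length(first_seen)),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat("haplotype_set [", x$gene, "]: ", length(x$sequences),
      " accessions, ", length(x$snp_sites), " SNP sites, ",
      x$n_haplotypes, " haplotypes\n", sep = "")
  invisible(x)
}

#' Read an aligned FASTA file
#'
#' Thin wrapper for alignments of equal-length gene sequences.
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_alignment_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    s <- Biostrings::readBStringSet(path)
    return(stats::setNames(as.character(s), names(s)))
  }
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  id <- cumsum(hdr)
  nm <- sub("^>\\s*", "", lines[hdr])
  seqs <- vapply(split(lines[!hdr], id[!hdr]), paste0, "", collapse = "")
  stats::setNames(unname(seqs), nm)
}

#' Build an allele-type ("synthetic") marker from haplotypes or features
#'
#' Summarizes a gene's functional state as one binary dominant/recessive
#' call per accession, driven entirely by a rule table: haplotype ids (or
#' feature values such as gene presence/absence, deletion type) map to
#' calls. An observed haplotype with no rule entry and no declared default
#' gives a missing call with a warning — a novel allele needs an explicit
#' biological judgment, the marker builder never invents one.
#'
#' @param haps A [call_haplotypes()] result, or a named character vector
#'   of per-accession feature values.
#' @param rule Named character vector or two-column data frame
#'   (`pattern`, `call`) mapping haplotype ids/feature values to
#'   `"dominant"`/`"recessive"`.
#' @param locus Locus label for the marker (e.g. `"VRN-H1_AT"`).
#' @param default Optional call for unmapped haplotypes (`NULL` = none).
#' @return An object of class `allele_type_marker`: `locus`, `calls`
#'   (accession -> `"dominant"`/`"recessive"`/`NA`), `rule`.
#' @export
build_allele_type_marker <- function(haps, rule, locus = "locus",
                                     default = NULL) {
  feat <- if (inherits(haps, "haplotype_set")) {
    haps$haplotype_of
  } else {
    stats::setNames(as.character(haps), names(haps))
  }
  if (is.null(names(feat))) stop("feature vector must be named by accession")
  if (is.data.frame(rule)) {
    rule <- stats::setNames(as.character(rule$call), rule$pattern)
  }
  if (anyDuplicated(names(rule))) {
    dup <- names(rule)[duplicated(names(rule))]
    if (any(tapply(rule, names(rule), function(x) length(unique(x))) > 1L)) {
      stop("configuration error: contradictory rule entries for ",
           paste(unique(dup), collapse = ", "))
    }
    rule <- rule[!duplicated(names(rule))]
  }
  if (!all(rule %in% c("dominant", "recessive"))) {
    stop("rule calls must be 'dominant' or 'recessive'")
  }
  calls <- unname(rule[feat])
  unmapped <- !is.na(feat) & !(feat %in% names(rule))
  if (any(unmapped)) {
    if (!is.null(default)) {
      calls[unmapped] <- default
    } else {
      warning("no rule entry (and no default) for: ",
              paste(unique(feat[unmapped]), collapse = ", "),
              "; calls set missing")
    }
  }
  names(calls) <- names(feat)
  structure(list(locus = locus, calls = calls, rule = rule),
            class = "allele_type_marker")
}

#' Numeric coding of an allele-type marker
#'
#' 0 = dominant, 1 = recessive (matching the simulator's `_AT` marker
#' coding), ready to join a genotype matrix.
#'
#' @param marker An [build_allele_type_marker()] result.
#' @return Named integer vector (NA for missing calls).
#' @export
allele_type_calls <- function(marker) {
  stopifnot(inherits(marker, "allele_type_marker"))
  out <- ifelse(is.na(marker$calls), NA_integer_,
                as.integer(marker$calls == "recessive"))
  names(out) <- names(marker$calls)
  out
}

#' Multi-locus haplotypes over allele-type markers
#'
#' Enumerates the observed combinations of dominant/recessive calls across
#' L biallelic allele-type loci. The possible space is 2^L; accessions
#' with any missing call are excluded from the observed counts and
#' reported separately.
#'
#' @param markers List of [build_allele_type_marker()] results (length
#'   >= 1).
#' @return List: `observed` (data frame of combination and accession
#'   count, one column per locus), `n_observed`, `n_possible` (= 2^L),
#'   `n_excluded` (accessions with a missing call).
#' @export
multilocus_haplotypes <- function(markers) {
  stopifnot(length(markers) >= 1L,
            all(vapply(markers, inherits, TRUE, "allele_type_marker")))
  acc <- Reduce(intersect, lapply(markers, function(m) names(m$calls)))
  L <- length(markers)
  mat <- vapply(markers, function(m) m$calls[acc], character(length(acc)))
  if (length(acc) == 1L) mat <- matrix(mat, nrow = 1L)
  colnames(mat) <- vapply(markers, `[[`, "", "locus")
  complete <- rowSums(is.na(mat)) == 0L
  combos <- apply(mat[complete, , drop = FALSE], 1L, paste, collapse = "|")
  tab <- table(combos)
  obs <- if (length(tab)) {
    parts <- do.call(rbind, strsplit(names(tab), "|", fixed = TRUE))
    colnames(parts) <- colnames(mat)
    data.frame(parts, n_accessions = as.integer(tab),
               stringsAsFactors = FALSE, row.names = NULL)
  } else {
    data.frame(n_accessions = integer(0))
  }
  list(observed = obs, n_observed = length(tab), n_possible = 2^L,
       n_excluded = sum(!complete))
}
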