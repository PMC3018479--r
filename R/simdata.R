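#' Describe a causal locus for the germplasm simulator
#'
#' A causal locus carries a set of functional haplotype labels (allele
#' types), each classified as dominant or recessive, and per-subpopulation
#' frequencies used when labelling founder haplotypes. Several distinct
#' recessive labels at one locus model the loss-of-function situation where
#' independent mutations collapse to a single recessive phenotype.
#'
#' @param name Locus label (e.g. `"VRN1like"`).
#' @param chromosome Chromosome index (1-based).
#' @param position_cM Map position in cM.
#' @param allele_types Character vector of at least two haplotype labels.
#' @param dominance_map Named character vector mapping every label to
#'   `"dominant"` or `"recessive"`.
#' @param subpop_freqs Optional list, one named probability vector per
#'   subpopulation (frequencies of the allele types among that
#'   subpopulation's founders). `NULL` means uniform in every subpopulation.
#' @param role One of `"vrn1"`, `"vrn2"`, `"vrn3"`, `"vrs1"`, `"none"`;
#'   ties the locus to a trait rule.
#' @return A `causal_locus` object (list).
#' @export
causal_locus <- function(name, chromosome, position_cM, allele_types,
                         dominance_map, subpop_freqs = NULL,
                         role = c("none", "vrn1", "vrn2", "vrn3", "vrs1")) {
  role <- match.arg(role)
  if (length(allele_types) < 2L) {
    stop("causal locus '", name, "' needs at least 2 allele types")
  }
  if (!all(allele_types %in% names(dominance_map))) {
    stop("causal locus '", name, "': every allele type needs a dominance call")
  }
  if (!all(dominance_map %in% c("dominant", "recessive"))) {
    stop("dominance calls must be 'dominant' or 'recessive'")
  }
  if (!is.null(subpop_freqs)) {
    ok <- vapply(subpop_freqs, function(f) {
      all(allele_types %in% names(f)) && all(f >= 0) && sum(f) > 0
    }, logical(1L))
    if (!all(ok)) stop("invalid subpop_freqs for causal locus '", name, "'")
  }
  structure(list(name = name, chromosome = chromosome,
                 position_cM = position_cM, allele_types = allele_types,
                 dominance_map = dominance_map[allele_types],
                 subpop_freqs = subpop_freqs, role = role),
            class = "causal_locus")
}

#' Default causal architecture: epistatic vernalization plus row type
#'
#' Encodes the two model trait architectures on a barley-like 7-chromosome
#' map: three vernalization loci (`VRN1like` on 5, `VRN2like` on 4,
#' `VRN3like` on 7) whose dominance combination determines vernalization
#' sensitivity epistatically, and one inflorescence locus (`VRS1like` on 2)
#' with one dominant wild-type and three distinct recessive loss-of-function
#' haplotypes that all collapse to the six-rowed phenotype.
#'
#' Subpopulation 1 is winter six-rowed germplasm (vernalization-sensitive
#' allele combination common), subpopulation 2 spring six-rowed, any further
#' subpopulations spring two-rowed — so both traits are strongly confounded
#' with structure, as in real breeding germplasm.
#'
#' @param n_subpops Number of subpopulations the frequencies are laid out
#'   for.
#' @return List of [causal_locus()] objects.
#' @export
default_causal_spec <- function(n_subpops = 4) {
  stopifnot(n_subpops >= 1)
  winter <- 1L
  spring6 <- if (n_subpops >= 2L) 2L else integer(0)
  freqs <- function(win, spr) {
    lapply(seq_len(n_subpops), function(s) if (s == winter) win else spr)
  }
  vrs1_freqs <- lapply(seq_len(n_subpops), function(s) {
    if (s == winter) {
      c(Vrs1.wt = 0.05, vrs1.a1 = 0.55, vrs1.a2 = 0.30, vrs1.a3 = 0.10)
    } else if (s %in% spring6) {
      c(Vrs1.wt = 0.05, vrs1.a1 = 0.30, vrs1.a2 = 0.45, vrs1.a3 = 0.20)
    } else {
      c(Vrs1.wt = 0.96, vrs1.a1 = 0.02, vrs1.a2 = 0.01, vrs1.a3 = 0.01)
    }
  })
  list(
    causal_locus("VRN1like", 5, 137.2,
                 c("Vrn1.sp", "vrn1.w"),
                 c(Vrn1.sp = "dominant", vrn1.w = "recessive"),
                 freqs(c(Vrn1.sp = 0.05, vrn1.w = 0.95),
                       c(Vrn1.sp = 0.85, vrn1.w = 0.15)),
                 role = "vrn1"),
    causal_locus("VRN2like", 4, 119.1,
                 c("Vrn2.present", "vrn2.deleted"),
                 c(Vrn2.present = "dominant", vrn2.deleted = "recessive"),
                 freqs(c(Vrn2.present = 0.95, vrn2.deleted = 0.05),
                       c(Vrn2.present = 0.15, vrn2.deleted = 0.85)),
                 role = "vrn2"),
    causal_locus("VRN3like", 7, 35.0,
                 c("Vrn3.sp", "vrn3.w"),
                 c(Vrn3.sp = "dominant", vrn3.w = "recessive"),
                 freqs(c(Vrn3.sp = 0.10, vrn3.w = 0.90),
                       c(Vrn3.sp = 0.15, vrn3.w = 0.85)),
                 role = "vrn3"),
    causal_locus("VRS1like", 2, 86.6,
                 c("Vrs1.wt", "vrs1.a1", "vrs1.a2", "vrs1.a3"),
                 c(Vrs1.wt = "dominant", vrs1.a1 = "recessive",
                   vrs1.a2 = "recessive", vrs1.a3 = "recessive"),
                 vrs1_freqs,
                 role = "vrs1")
  )
}

#' Simulation configuration
#'
#' Defines a structured inbred germplasm panel: `n_subpops` admixed
#' subpopulations (Dirichlet admixture, concentration `admixture_alpha`),
#' founder-mosaic haplotypes whose segment lengths are exponential with
#' mean `ld_block_decay_cM` (this sets the within-subpopulation LD decay
#' scale), subpopulation allele-frequency divergence `fst`
#' (Balding-Nichols), uniform random missingness, and the causal trait
#' architecture of [default_causal_spec()].
#'
#' @param n_accessions Number of inbred accessions.
#' @param n_subpops Number of subpopulations.
#' @param admixture_alpha Dirichlet concentration; small values give
#'   mostly-assigned accessions with occasional admixture.
#' @param n_chromosomes,markers_per_chromosome,map_length_cM Map layout;
#'   markers are evenly spaced on `[0, map_length_cM]`.
#' @param ld_block_decay_cM Expected founder-mosaic segment length (cM).
#' @param missing_rate Fraction of genotype cells set missing, in \[0, 1).
#' @param maf_floor Ancestral allele frequencies are drawn uniformly on
#'   `[maf_floor, 1 - maf_floor]`.
#' @param fst Subpopulation divergence in (0, 1); 0 disables divergence.
#' @param founders_per_subpop Size of each subpopulation's founder pool;
#'   small pools give strong block LD.
#' @param causal_spec List of [causal_locus()] objects.
#' @param noise_sd_days Gaussian noise s.d. added to insensitive flowering
#'   times (days).
#' @param insensitive_range Range (days) that vernalization-insensitive
#'   accessions flower in, before noise.
#' @param censor_day Experiment termination day; sensitive accessions are
#'   assigned exactly this value (default 150).
#' @param qc_low_frac Fraction of simulated marker QC scores falling below
#'   0.6 (exercises the QC filter).
#' @param unknown_pos_frac Fraction of background markers given an unknown
#'   map position.
#' @param seed Integer RNG seed; a fixed seed gives bit-identical output.
#' @return A validated `sim_config` object (list).
#' @export
sim_config <- function(n_accessions = 200, n_subpops = 4,
                       admixture_alpha = 0.1, n_chromosomes = 7,
                       markers_per_chromosome = 50, map_length_cM = 150,
                       ld_block_decay_cM = 5, missing_rate = 0.02,
                       maf_floor = 0.05, fst = 0.2,
                       founders_per_subpop = 16,
                       causal_spec = default_causal_spec(n_subpops),
                       noise_sd_days = 3, insensitive_range = c(32, 69),
                       censor_day = 150L, qc_low_frac = 0.05,
                       unknown_pos_frac = 0.02, seed = 1L) {
  stopifnot(n_accessions >= 1, n_subpops >= 1, n_chromosomes >= 1,
            markers_per_chromosome >= 1, founders_per_subpop >= 1,
            map_length_cM > 0, ld_block_decay_cM > 0,
            missing_rate >= 0, missing_rate < 1,
            maf_floor >= 0, maf_floor <= 0.5,
            fst >= 0, fst < 1, admixture_alpha > 0,
            noise_sd_days >= 0, censor_day > 0,
            qc_low_frac >= 0, qc_low_frac <= 1,
            unknown_pos_frac >= 0, unknown_pos_frac < 1)
  for (cl in causal_spec) {
    if (!inherits(cl, "causal_locus")) stop("causal_spec entries must be causal_locus objects")
    if (cl$chromosome < 1 || cl$chromosome > n_chromosomes ||
        cl$position_cM < 0 || cl$position_cM > map_length_cM) {
      stop("configuration error: causal locus '", cl$name,
           "' lies off the generated map")
    }
    if (!is.null(cl$subpop_freqs) && length(cl$subpop_freqs) != n_subpops) {
      stop("configuration error: causal locus '", cl$name,
           "' has subpop_freqs for ", length(cl$subpop_freqs),
           " subpopulations, config has ", n_subpops)
    }
  }
  structure(list(
    n_accessions = as.integer(n_accessions),
    n_subpops = as.integer(n_subpops),
    admixture_alpha = admixture_alpha,
    n_chromosomes = as.integer(n_chromosomes),
    markers_per_chromosome = as.integer(markers_per_chromosome),
    map_length_cM = map_length_cM,
    ld_block_decay_cM = ld_block_decay_cM,
    missing_rate = missing_rate, maf_floor = maf_floor, fst = fst,
    founders_per_subpop = as.integer(founders_per_subpop),
    causal_spec = causal_spec, noise_sd_days = noise_sd_days,
    insensitive_range = insensitive_range,
    censor_day = as.integer(censor_day), qc_low_frac = qc_low_frac,
    unknown_pos_frac = unknown_pos_frac, seed = as.integer(seed)),
    class = "sim_config")
}

#' Vernalization-sensitivity trait rule
#'
#' Of the eight possible dominance combinations at the three vernalization
#' loci, exactly one is sensitive: a dominant VRN2-type allele (repressor
#' present) together with recessive VRN1- and VRN3-type alleles. Sensitive
#' accessions do not flower within the experiment and are assigned exactly
#' `censor_day` days; insensitive accessions flower at a day drawn
#' uniformly on `insensitive_range` plus Gaussian noise, truncated to stay
#' strictly below `censor_day`.
#'
#' Noise draws are consumed for every accession regardless of
#' sensitivity, so the output is reproducible from the RNG state alone.
#'
#' @param alleles List or data frame with character components `vrn1`,
#'   `vrn2`, `vrn3`: per-accession haplotype labels (`NA` = missing).
#' @param dominance_maps Named list (`vrn1`, `vrn2`, `vrn3`) of named
#'   character vectors mapping labels to `"dominant"`/`"recessive"`.
#' @param noise_sd_days,censor_day,insensitive_range See [sim_config()].
#' @return Numeric days-to-flowering vector; accessions with a missing
#'   label at any of the three loci get `NA` and are listed in attribute
#'   `flagged`.
#' @export
assign_vernalization_phenotype <- function(alleles, dominance_maps,
                                           noise_sd_days = 3,
                                           censor_day = 150,
                                           insensitive_range = c(32, 69)) {
  loci <- c("vrn1", "vrn2", "vrn3")
  stopifnot(all(loci %in% names(alleles)), all(loci %in% names(dominance_maps)))
  call_at <- function(l) {
    lab <- as.character(alleles[[l]])
    known <- !is.na(lab)
    if (any(known & !(lab %in% names(dominance_maps[[l]])))) {
      stop("unknown haplotype label at locus ", l)
    }
    unname(dominance_maps[[l]][lab])
  }
  v1 <- call_at("vrn1"); v2 <- call_at("vrn2"); v3 <- call_at("vrn3")
  n <- length(v1)
  flagged <- which(is.na(v1) | is.na(v2) | is.na(v3))
  sensitive <- v2 == "dominant" & v1 == "recessive" & v3 == "recessive"

  base <- stats::runif(n, insensitive_range[1L], insensitive_range[2L]) +
    stats::rnorm(n, 0, noise_sd_days)
  base <- pmin(pmax(base, 1), censor_day - 1)
  out <- ifelse(sensitive, as.numeric(censor_day), base)
  out[flagged] <- NA_real_
  attr(out, "flagged") <- flagged
  out
}

#' Row-type trait rule
#'
#' Any recessive (loss-of-function) haplotype at the VRS1-type locus gives
#' the six-rowed phenotype; the dominant wild type suppresses
#' lateral-spikelet development and gives two-rowed. Several distinct
#' recessive haplotypes therefore collapse to the same phenotype.
#'
#' @param vrs1_haplotype Character vector of haplotype labels (`NA`
#'   allowed).
#' @param dominance_map Named character vector mapping labels to
#'   `"dominant"`/`"recessive"`.
#' @return Character vector in `{"two-rowed", "six-rowed", NA}`.
#' @export
assign_rowtype_phenotype <- function(vrs1_haplotype, dominance_map) {
  lab <- as.character(vrs1_haplotype)
  known <- !is.na(lab)
  if (any(known & !(lab %in% names(dominance_map)))) {
    bad <- lab[known & !(lab %in% names(dominance_map))][1L]
    stop("unknown VRS1-type haplotype label '", bad, "'")
  }
  calls <- unname(dominance_map[lab])
  ifelse(is.na(calls), NA_character_,
         ifelse(calls == "recessive", "six-rowed", "two-rowed"))
}

#' Simulate a structured inbred germplasm panel
#'
#' Generates accessions as founder mosaics: each subpopulation owns a small
#' pool of founder haplotypes drawn from Balding-Nichols subpopulation
#' allele frequencies; each accession draws Dirichlet admixture
#' proportions, then each chromosome is tiled with exponential-length
#' segments copied from founders of subpopulations sampled by those
#' proportions. Small founder pools plus segment copying produce LD that
#' decays with cM distance at scale `ld_block_decay_cM`, while frequency
#' divergence makes PCA separate subpopulations.
#'
#' Causal loci are carried on the founders: every founder holds one allele
#' type per causal locus (frequencies per subpopulation), so causal
#' haplotypes are in LD with neighbouring background markers. For each
#' causal locus the emitted marker matrix contains the allele-type marker
#' `<name>_AT` (B allele = recessive functional state) and one tag SNP per
#' haplotype label (`<name>_SNP_<label>`, B = carries that haplotype),
#' mimicking within-gene SNPs. Both phenotypes are then assigned from the
#' trait rules ([assign_vernalization_phenotype()],
#' [assign_rowtype_phenotype()]).
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_germplasm`:
#'   \describe{
#'     \item{genotypes}{[genotype_matrix()] with map and simulated QC
#'       scores.}
#'     \item{phenotypes}{Long data frame (`accession`, `trait`, `value`)
#'       with traits `days_to_flowering` (censored at `censor_day`) and
#'       `rowtype` (0 = two-rowed, 1 = six-rowed).}
#'     \item{truth}{Ground truth: `subpop_assignments` (admixture matrix),
#'       `main_subpop`, `causal_genotypes` (accession x locus labels),
#'       `founder_mosaic`, `trait_rules`, `pheno_seed`, `config`.}
#'   }
#' @export
simulate_germplasm <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_accessions
  K <- config$n_subpops
  Fp <- config$founders_per_subpop
  n_founders <- K * Fp
  nchr <- config$n_chromosomes
  m_chr <- config$markers_per_chromosome
  L <- config$map_length_cM

  ## background marker map: evenly spaced per chromosome
  base_map <- do.call(rbind, lapply(seq_len(nchr), function(ch) {
    data.frame(marker = sprintf("c%d_m%03d", ch, seq_len(m_chr)),
               chrom = as.character(ch),
               pos_cM = seq(0, L, length.out = m_chr),
               stringsAsFactors = FALSE)
  }))
  M <- nrow(base_map)

  ## founder background haplotypes (Balding-Nichols subpop frequencies)
  p0 <- stats::runif(M, config$maf_floor, 1 - config$maf_floor)
  psub <- matrix(NA_real_, K, M)
  for (s in seq_len(K)) {
    if (config$fst > 0) {
      shp1 <- p0 * (1 - config$fst) / config$fst
      shp2 <- (1 - p0) * (1 - config$fst) / config$fst
      psub[s, ] <- stats::rbeta(M, shp1, shp2)
    } else {
      psub[s, ] <- p0
    }
  }
  founder_subpop <- rep(seq_len(K), each = Fp)
  founder_calls <- matrix(0L, n_founders, M)
  for (f in seq_len(n_founders)) {
    founder_calls[f, ] <- stats::rbinom(M, 1L, psub[founder_subpop[f], ])
  }

  ## founder causal labels
  spec <- config$causal_spec
  founder_causal <- lapply(spec, function(cl) {
    labs <- character(n_founders)
    for (s in seq_len(K)) {
      pr <- if (is.null(cl$subpop_freqs)) {
        rep(1, length(cl$allele_types))
      } else cl$subpop_freqs[[s]][cl$allele_types]
      labs[founder_subpop == s] <-
        sample(cl$allele_types, Fp, replace = TRUE, prob = pr)
    }
    labs
  })
  names(founder_causal) <- vapply(spec, `[[`, "", "name")

  ## admixture proportions
  Q_true <- matrix(0, n, K)
  for (i in seq_len(n)) {
    g <- stats::rgamma(K, shape = config$admixture_alpha)
    if (sum(g) <= 0) g[sample.int(K, 1L)] <- 1
    Q_true[i, ] <- g / sum(g)
  }
  acc_ids <- sprintf("acc%03d", seq_len(n))
  rownames(Q_true) <- acc_ids
  colnames(Q_true) <- sprintf("subpop%d", seq_len(K))

  ## founder mosaic per accession x chromosome
  calls <- matrix(NA_integer_, n, M, dimnames = list(acc_ids, base_map$marker))
  n_causal <- length(spec)
  causal_geno <- matrix(NA_character_, n, n_causal,
                        dimnames = list(acc_ids, names(founder_causal)))
  mosaic <- vector("list", n)
  chr_cols <- split(seq_len(M), base_map$chrom)[as.character(seq_len(nchr))]
  for (i in seq_len(n)) {
    mosaic[[i]] <- vector("list", nchr)
    for (ch in seq_len(nchr)) {
      bp <- c(0)
      while (bp[length(bp)] < L) {
        bp <- c(bp, bp[length(bp)] +
                  stats::rexp(1L, rate = 1 / config$ld_block_decay_cM))
      }
      n_seg <- length(bp) - 1L
      seg_sub <- sample.int(K, n_seg, replace = TRUE, prob = Q_true[i, ])
      seg_founder <- (seg_sub - 1L) * Fp + sample.int(Fp, n_seg, replace = TRUE)
      cols <- chr_cols[[ch]]
      seg_of <- findInterval(base_map$pos_cM[cols], bp,
                             rightmost.closed = TRUE)
      seg_of[seg_of < 1L] <- 1L
      calls[i, cols] <- founder_calls[cbind(seg_founder[seg_of], cols)]
      for (l in seq_len(n_causal)) {
        if (spec[[l]]$chromosome == ch) {
          sg <- findInterval(spec[[l]]$position_cM, bp, rightmost.closed = TRUE)
          sg <- max(sg, 1L)
          causal_geno[i, l] <- founder_causal[[l]][seg_founder[sg]]
        }
      }
      mosaic[[i]][[ch]] <- data.frame(start_cM = bp[-length(bp)],
                                      end_cM = pmin(bp[-1L], L),
                                      founder = seg_founder)
    }
  }
  names(mosaic) <- acc_ids

  ## embed causal markers: allele-type marker + per-haplotype tag SNPs
  causal_cols <- list()
  causal_map <- list()
  for (l in seq_len(n_causal)) {
    cl <- spec[[l]]
    lab <- causal_geno[, l]
    at <- as.integer(cl$dominance_map[lab] == "recessive")
    nm_at <- paste0(cl$name, "_AT")
    causal_cols[[nm_at]] <- at
    causal_map[[nm_at]] <- data.frame(marker = nm_at,
                                      chrom = as.character(cl$chromosome),
                                      pos_cM = cl$position_cM,
                                      stringsAsFactors = FALSE)
    ## tag SNPs only where they are informative beyond the allele-type
    ## marker: at a biallelic functional locus a haplotype indicator is the
    ## allele-type column itself (and gene SNPs riding on presence/absence
    ## polymorphism tend to fail array QC anyway)
    if (length(cl$allele_types) <= 2L) next
    for (ht in cl$allele_types) {
      nm <- paste0(cl$name, "_SNP_", ht)
      causal_cols[[nm]] <- as.integer(lab == ht)
      causal_map[[nm]] <- data.frame(marker = nm,
                                     chrom = as.character(cl$chromosome),
                                     pos_cM = cl$position_cM,
                                     stringsAsFactors = FALSE)
    }
  }
  if (length(causal_cols)) {
    calls <- cbind(calls, do.call(cbind, causal_cols))
    full_map <- rbind(base_map, do.call(rbind, causal_map))
  } else {
    full_map <- base_map
  }
  rownames(full_map) <- NULL
  Mtot <- ncol(calls)

  ## missingness, QC scores, unknown positions
  if (config$missing_rate > 0) {
    mask <- matrix(stats::runif(n * Mtot) < config$missing_rate, n, Mtot)
    calls[mask] <- NA_integer_
  }
  qc <- numeric(Mtot)
  low <- stats::runif(Mtot) < config$qc_low_frac
  qc[low] <- 0.6 * stats::rbeta(sum(low), 2, 2)
  qc[!low] <- 0.6 + 0.4 * stats::rbeta(sum(!low), 5, 1.5)
  if (Mtot > M) qc[(M + 1L):Mtot] <- 0.99  # curated assays for causal markers
  names(qc) <- colnames(calls)
  if (config$unknown_pos_frac > 0 && M > 0) {
    n_unk <- round(config$unknown_pos_frac * M)
    if (n_unk > 0) {
      unk <- sample.int(M, n_unk)
      full_map$chrom[unk] <- NA_character_
      full_map$pos_cM[unk] <- NA_real_
    }
  }

  G <- genotype_matrix(calls, map = full_map, qc = qc)

  ## phenotypes from truth labels under a dedicated, stored seed
  pheno_seed <- (config$seed + 104729L) %% .Machine$integer.max
  truth <- list(
    subpop_assignments = Q_true,
    main_subpop = max.col(Q_true),
    causal_genotypes = causal_geno,
    founder_mosaic = mosaic,
    trait_rules = c("vernalization_epistasis", "rowtype_recessive"),
    pheno_seed = pheno_seed,
    config = config)
  phenotypes <- regenerate_phenotypes(truth)

  structure(list(genotypes = G, phenotypes = phenotypes, truth = truth),
            class = "sim_germplasm")
}

#' Recompute phenotypes from simulation ground truth
#'
#' Re-applies the trait rules to the stored causal genotypes under the
#' stored phenotype seed; by construction this reproduces the emitted
#' phenotype table exactly.
#'
#' @param truth The `truth` element of a [simulate_germplasm()] result.
#' @return Long phenotype data frame (`accession`, `trait`, `value`).
#' @export
regenerate_phenotypes <- function(truth) {
  config <- truth$config
  spec <- config$causal_spec
  roles <- vapply(spec, `[[`, "", "role")
  nms <- vapply(spec, `[[`, "", "name")
  acc_ids <- rownames(truth$causal_genotypes)
  out <- list()

  set.seed(truth$pheno_seed)
  if (all(c("vrn1", "vrn2", "vrn3") %in% roles)) {
    pick <- function(r) truth$causal_genotypes[, which(roles == r)[1L]]
    dmap <- function(r) spec[[which(roles == r)[1L]]]$dominance_map
    days <- assign_vernalization_phenotype(
      list(vrn1 = pick("vrn1"), vrn2 = pick("vrn2"), vrn3 = pick("vrn3")),
      list(vrn1 = dmap("vrn1"), vrn2 = dmap("vrn2"), vrn3 = dmap("vrn3")),
      noise_sd_days = config$noise_sd_days,
      censor_day = config$censor_day,
      insensitive_range = config$insensitive_range)
    out[["days"]] <- data.frame(accession = acc_ids,
                                trait = "days_to_flowering",
                                value = as.numeric(days),
                                stringsAsFactors = FALSE)
  }
  if ("vrs1" %in% roles) {
    l <- which(roles == "vrs1")[1L]
    rt <- assign_rowtype_phenotype(truth$causal_genotypes[, l],
                                   spec[[l]]$dominance_map)
    out[["rowtype"]] <- data.frame(accession = acc_ids, trait = "rowtype",
                                   value = as.numeric(rt == "six-rowed"),
                                   stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(accession = character(), trait = character(),
                      value = numeric(), stringsAsFactors = FALSE))
  }
  ph <- do.call(rbind, out)
  rownames(ph) <- NULL
  ph
}

#' @export
print.sim_germplasm <- function(x, ...) {
  cat("sim_germplasm:", length(x$genotypes$accession_ids), "accessions,",
      length(x$genotypes$marker_ids), "markers,",
      ncol(x$truth$causal_genotypes), "causal loci\n")
  invisible(x)
}
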