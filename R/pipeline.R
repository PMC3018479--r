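#' Pipeline run configuration
#'
#' Bundles every stage's parameters. Inputs are either a [sim_config()]
#' (simulated panel) or paths to genotype/map/QC/phenotype TSVs in the
#' [read_genotypes()] dialect. Defaults mirror the workflow's standard
#' thresholds: 10\% missing, 0.6 QC score, 0.05 MAF, LD significance cut
#' 0.001, interaction gate 0.20, scan alpha 0.05.
#'
#' @param sim A [sim_config()], or `NULL` when reading files.
#' @param genotype_path,map_path,qc_path,phenotype_path Input TSVs
#'   (ignored when `sim` is given).
#' @param out_dir Output directory (created if needed).
#' @param max_missing,min_qc,require_position [qc_filter()] thresholds.
#' @param min_maf [maf_filter()] threshold.
#' @param n_axes Structure axes for [pca_structure()].
#' @param kinship_n_markers Optional marker subsample for
#'   [loiselle_kinship()].
#' @param gate Interaction-scan gate on adjusted M+Q+K p-values.
#' @param alpha Significance level for scan flags.
#' @param ld_p_cut,ld_span,ld_conf LD-extent parameters.
#' @param seed Integer seed governing every stochastic stage.
#' @return A `run_config` object (list).
#' @export
run_config <- function(sim = NULL, genotype_path = NULL, map_path = NULL,
                       qc_path = NULL, phenotype_path = NULL,
                       out_dir = tempfile("structAM_run_"),
                       max_missing = 0.10, min_qc = 0.6,
                       require_position = TRUE, min_maf = 0.05,
                       n_axes = 2, kinship_n_markers = NULL,
                       gate = 0.20, alpha = 0.05, ld_p_cut = 0.001,
                       ld_span = 0.5, ld_conf = 0.90, seed = 1L) {
  if (is.null(sim)) {
    for (p in c(genotype_path, map_path, phenotype_path)) {
      if (!is.null(p) && !file.exists(p)) stop("input path not found: ", p)
    }
    if (is.null(genotype_path) || is.null(phenotype_path)) {
      stop("either `sim` or genotype_path + phenotype_path must be given")
    }
  } else {
    stopifnot(inherits(sim, "sim_config"))
  }
  stopifnot(max_missing >= 0, max_missing <= 1, min_qc >= 0, min_qc <= 1,
            min_maf >= 0, min_maf <= 0.5, gate > 0, gate <= 1,
            alpha > 0, alpha < 1, ld_p_cut > 0, ld_p_cut < 1,
            ld_span > 0, ld_conf > 0, ld_conf < 1, n_axes >= 1)
  structure(as.list(environment()), class = "run_config")
}

#' Run the full association-mapping pipeline
#'
#' Seven stages, each writing its outputs as TSV under `out_dir` and
#' logging counts in and out: (1) simulate or ingest the genotype,
#' map and phenotype tables; (2) marker filters (QC then MAF); (3)
#' structure covariates by PCA; (4) Loiselle kinship with negative
#' flooring; (5) LD decay extent per chromosome against the Box-Cox
#' unlinked threshold; (6) single-marker scans under all four models per
#' trait; (7) FDR-gated interaction scan per trait (skipped, with a note,
#' when the gate selects fewer than two markers). A `manifest.json`
#' records the stage outputs, parameters and md5 hashes; rerunning with
#' the same config and seed reproduces identical outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a run report list: `manifest`, `genotypes`,
#'   `structure`, `kinship`, `ld`, `assoc` (per trait/model),
#'   `interactions` (per trait), `truth` (when simulated).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  manifest <- list(package = "structAM",
                   version = as.character(utils::packageVersion("structAM")),
                   seed = config$seed, stages = list())
  note <- function(stage, files, params = list(), info = list()) {
    manifest$stages[[stage]] <<- c(list(outputs = files, params = params),
                                   info)
  }
  set.seed(config$seed)

  ## stage 1: inputs
  truth <- NULL
  if (!is.null(config$sim)) {
    sim <- simulate_germplasm(config$sim)
    G0 <- sim$genotypes
    pheno <- sim$phenotypes
    truth <- sim$truth
    write_genotypes(G0, out("genotypes.tsv"), out("map.tsv"), out("qc.tsv"))
    write_phenotypes(pheno, out("phenotypes.tsv"))
    truth_tab <- data.frame(accession = rownames(truth$causal_genotypes),
                            truth$causal_genotypes,
                            main_subpop = truth$main_subpop,
                            stringsAsFactors = FALSE, check.names = FALSE)
    utils::write.table(truth_tab, out("sim_truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    note("input", c("genotypes.tsv", "map.tsv", "qc.tsv", "phenotypes.tsv",
                    "sim_truth.tsv"),
         params = list(source = "simulated", seed = config$sim$seed),
         info = list(n_accessions = length(G0$accession_ids),
                     n_markers = length(G0$marker_ids)))
  } else {
    G0 <- read_genotypes(config$genotype_path, config$map_path,
                         config$qc_path)
    pheno <- read_phenotypes(config$phenotype_path)
    note("input", character(0),
         params = list(source = "files", genotype = config$genotype_path),
         info = list(n_accessions = length(G0$accession_ids),
                     n_markers = length(G0$marker_ids)))
  }

  ## stage 2: marker filters
  G1 <- qc_filter(G0, max_missing = config$max_missing,
                  min_qc = config$min_qc,
                  require_position = config$require_position)
  G <- maf_filter(G1, min_maf = config$min_maf)
  filt <- data.frame(marker = G$marker_ids, stringsAsFactors = FALSE)
  utils::write.table(filt, out("markers_kept.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  note("filter", "markers_kept.tsv",
       params = list(max_missing = config$max_missing,
                     min_qc = config$min_qc, min_maf = config$min_maf,
                     require_position = config$require_position),
       info = list(n_in = length(G0$marker_ids),
                   n_after_qc = length(G1$marker_ids),
                   n_after_maf = length(G$marker_ids)))

  ## stage 3: structure
  Q <- pca_structure(G, n_axes = config$n_axes)
  qtab <- data.frame(accession = Q$accession_ids, Q$scores,
                     check.names = FALSE)
  utils::write.table(qtab, out("structure_Q.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  note("structure", "structure_Q.tsv",
       params = list(n_axes = config$n_axes),
       info = list(explained_variance = unname(Q$explained_variance)))

  ## stage 4: kinship
  K <- floor_negative(loiselle_kinship(G,
                                       n_markers = config$kinship_n_markers,
                                       subsample_seed = config$seed))
  ktab <- data.frame(accession = rownames(K), unclass(K),
                     check.names = FALSE)
  utils::write.table(ktab, out("kinship_K.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  note("kinship", "kinship_K.tsv",
       params = list(estimator = "loiselle", floored = TRUE,
                     n_markers = config$kinship_n_markers))

  ## stage 5: LD decay extent
  ld_pairs <- pairwise_ld(G, p_for = "linked")
  thr <- unlinked_threshold(ld_pairs$r2[!ld_pairs$linked_flag])
  ext <- ld_extent_by_chromosome(ld_pairs, thr, G, conf = config$ld_conf,
                                 span = config$ld_span,
                                 p_cut = config$ld_p_cut)
  utils::write.table(ext$per_chromosome, out("ld_extent.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  note("ld", "ld_extent.tsv",
       params = list(p_cut = config$ld_p_cut, span = config$ld_span,
                     conf = config$ld_conf),
       info = list(threshold_r2 = as.numeric(thr),
                   mean_extent_cM = ext$mean_extent_cM))

  ## stage 6: single-marker scans, four models per trait
  traits <- unique(pheno$trait)
  models <- c("M", "M+Q", "M+K", "M+Q+K")
  assoc <- list()
  scan_files <- character(0)
  for (tr in traits) {
    assoc[[tr]] <- list()
    for (mod in models) {
      res <- fit_single_marker(G, pheno, trait = tr, model = mod,
                               Q = Q, K = K)
      assoc[[tr]][[mod]] <- res
      scan <- genome_scan(res, G, alpha = config$alpha)
      f <- sprintf("scan_%s_%s.tsv", tr, gsub("\\+", "", mod))
      utils::write.table(scan, out(f), sep = "\t", quote = FALSE,
                         row.names = FALSE)
      scan_files <- c(scan_files, f)
    }
  }
  note("assoc", scan_files,
       params = list(models = models, alpha = config$alpha),
       info = list(traits = traits))

  ## stage 7: gated interaction scans
  interactions <- list()
  inter_files <- character(0)
  inter_notes <- list()
  for (tr in traits) {
    cand <- select_candidates(assoc[[tr]][["M+Q+K"]],
                              threshold = config$gate)
    if (length(cand) < 2L) {
      inter_notes[[tr]] <- sprintf(
        "interaction scan skipped for '%s': %d candidate marker(s)",
        tr, length(cand))
      message(inter_notes[[tr]])
      next
    }
    itab <- interaction_scan(G, pheno, Q, cand, trait = tr)
    interactions[[tr]] <- itab
    f <- sprintf("interactions_%s.tsv", tr)
    utils::write.table(itab, out(f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    inter_files <- c(inter_files, f)
    inter_notes[[tr]] <- sprintf("%d candidates, %d pairs tested",
                                 length(cand), nrow(itab))
  }
  note("interact", inter_files, params = list(gate = config$gate),
       info = list(notes = inter_notes))

  all_files <- list.files(config$out_dir, pattern = "\\.tsv$",
                          full.names = TRUE)
  manifest$hashes <- as.list(tools::md5sum(all_files))
  names(manifest$hashes) <- basename(all_files)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")

  invisible(list(manifest = manifest, genotypes = G, structure = Q,
                 kinship = K, ld = ext, ld_threshold = as.numeric(thr),
                 assoc = assoc, interactions = interactions,
                 truth = truth))
}
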