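test_that("simulation is deterministic and respects the missing rate", {
  cfg <- sim_config(n_accessions = 30, n_subpops = 1, missing_rate = 0,
                    markers_per_chromosome = 15,
                    causal_spec = default_causal_spec(1),
                    map_length_cM = 150, seed = 5)
  sim1 <- simulate_germplasm(cfg)
  expect_equal(sum(is.na(sim1$genotypes$calls)), 0L)

  sim2 <- simulate_germplasm(cfg)
  expect_identical(sim1, sim2)

  cfg2 <- sim_config(n_accessions = 30, missing_rate = 0.1, seed = 5,
                     n_chromosomes = 2, markers_per_chromosome = 40,
                     unknown_pos_frac = 0,
                     causal_spec = list())
  sim3 <- simulate_germplasm(cfg2)
  expect_gt(mean(is.na(sim3$genotypes$calls)), 0.05)
  expect_lt(mean(is.na(sim3$genotypes$calls)), 0.15)
})

test_that("off-map causal loci are a configuration error", {
  bad <- causal_locus("X", chromosome = 9, position_cM = 10,
                      allele_types = c("a", "b"),
                      c(a = "dominant", b = "recessive"))
  expect_error(sim_config(n_chromosomes = 7, causal_spec = list(bad)),
               "configuration error")
  bad2 <- causal_locus("Y", chromosome = 1, position_cM = 500,
                       allele_types = c("a", "b"),
                       c(a = "dominant", b = "recessive"))
  expect_error(sim_config(map_length_cM = 150, causal_spec = list(bad2)),
               "off the generated map")
})

test_that("LD decays with cM distance within a subpopulation", {
  cfg <- sim_config(n_accessions = 120, n_subpops = 2, fst = 0.35,
                    n_chromosomes = 1, markers_per_chromosome = 500,
                    map_length_cM = 100, causal_spec = list(),
                    missing_rate = 0.01, seed = 11)
  sim <- simulate_germplasm(cfg)
  sub <- rownames(sim$truth$subpop_assignments)[sim$truth$main_subpop == 1]
  pr <- pairwise_ld(sim$genotypes, accessions = sub, p_for = "none")
  near <- pr$linked_flag & pr$distance_cM < 1
  far <- pr$linked_flag & pr$distance_cM > 20
  expect_gt(mean(pr$r2[near], na.rm = TRUE), mean(pr$r2[far], na.rm = TRUE))
})

test_that("exactly one of the eight dominance combinations is sensitive", {
  combos <- expand.grid(vrn1 = c("dom", "rec"), vrn2 = c("dom", "rec"),
                        vrn3 = c("dom", "rec"), stringsAsFactors = FALSE)
  maps <- list(vrn1 = c(dom = "dominant", rec = "recessive"),
               vrn2 = c(dom = "dominant", rec = "recessive"),
               vrn3 = c(dom = "dominant", rec = "recessive"))
  set.seed(1)
  days <- assign_vernalization_phenotype(as.list(combos), maps,
                                         censor_day = 150)
  expect_equal(sum(days == 150), 1L)
  sensitive <- combos[days == 150, ]
  expect_identical(unname(unlist(sensitive)), c("rec", "dom", "rec"))
  expect_true(all(days[days != 150] < 150))

  # a dominant VRN1-type allele always flowers
  set.seed(2)
  d2 <- assign_vernalization_phenotype(
    list(vrn1 = rep("dom", 8), vrn2 = combos$vrn2, vrn3 = combos$vrn3),
    maps, censor_day = 150)
  expect_true(all(d2 < 150))

  # missing label flags the accession
  set.seed(3)
  d3 <- assign_vernalization_phenotype(
    list(vrn1 = c("dom", NA), vrn2 = c("rec", "rec"), vrn3 = c("rec", "rec")),
    maps)
  expect_true(is.na(d3[2]))
  expect_equal(attr(d3, "flagged"), 2L)
})

test_that("row-type rule collapses distinct recessive haplotypes", {
  dmap <- c(Vrs1.wt = "dominant", vrs1.a1 = "recessive",
            vrs1.a2 = "recessive", vrs1.a3 = "recessive")
  expect_identical(assign_rowtype_phenotype("Vrs1.wt", dmap), "two-rowed")
  expect_identical(assign_rowtype_phenotype(c("vrs1.a1", "vrs1.a2"), dmap),
                   c("six-rowed", "six-rowed"))
  expect_error(assign_rowtype_phenotype("novel", dmap), "unknown")
  # default architecture offers at least two distinct recessive labels
  spec <- default_causal_spec(4)
  vrs1 <- spec[[which(vapply(spec, `[[`, "", "role") == "vrs1")]]
  expect_gte(sum(vrs1$dominance_map == "recessive"), 2L)
})

test_that("phenotypes are exactly reproducible from stored truth", {
  sim <- cached_sim(seed = 2)
  expect_identical(regenerate_phenotypes(sim$truth), sim$phenotypes)
  # admixture proportions sum to one
  expect_equal(unname(rowSums(sim$truth$subpop_assignments)),
               rep(1, nrow(sim$truth$subpop_assignments)))
})

test_that("row type is confounded with simulated population structure", {
  sim <- cached_sim(seed = 2)
  rt <- sim$phenotypes$value[sim$phenotypes$trait == "rowtype"]
  tab <- table(rt, sim$truth$main_subpop)
  p <- suppressWarnings(stats::chisq.test(tab)$p.value)
  expect_lt(p, 1e-6)
})
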