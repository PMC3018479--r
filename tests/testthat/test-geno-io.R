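test_that("genotype files round-trip losslessly and validate on read", {
  G <- tiny_genotypes()
  gp <- withr::local_tempfile(fileext = ".tsv")
  mp <- withr::local_tempfile(fileext = ".tsv")
  qp <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(G, gp, mp, qp)
  G2 <- read_genotypes(gp, mp, qp)
  expect_identical(G2$calls, G$calls)
  expect_equal(G2$map, G$map)
  expect_equal(G2$qc, G$qc)
  expect_equal(dim(G2), c(4L, 5L))

  # duplicated marker id is a parse error naming the marker
  lines <- readLines(gp)
  lines[1] <- sub("mk2", "mk1", lines[1])
  writeLines(lines, gp)
  expect_error(read_genotypes(gp), "mk1")

  # invalid code names the offending line
  write_genotypes(G, gp)
  lines <- readLines(gp)
  lines[3] <- sub("\tB", "\tX", lines[3])
  writeLines(lines, gp)
  expect_error(read_genotypes(gp), "line 3")
})

test_that("simulated matrices survive a write/read round trip", {
  sim <- cached_sim(seed = 3, n_accessions = 40, markers_per_chromosome = 10)
  G <- sim$genotypes
  gp <- withr::local_tempfile(fileext = ".tsv")
  mp <- withr::local_tempfile(fileext = ".tsv")
  qp <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(G, gp, mp, qp)
  G2 <- read_genotypes(gp, mp, qp)
  expect_identical(G2$calls, G$calls)
  expect_equal(G2$map$pos_cM, G$map$pos_cM)
  expect_equal(G2$qc, G$qc)
})

test_that("qc_filter applies the three exclusion rules and is idempotent", {
  # fixture: 5 markers; mk3 has qc 0.55, mk4/mk5 unknown position on the
  # tiny map? build a dedicated 20-accession fixture instead
  set.seed(7)
  calls <- matrix(rbinom(20 * 5, 1L, 0.5), 20, 5,
                  dimnames = list(sprintf("a%02d", 1:20), paste0("mk", 1:5)))
  calls[1:3, 4] <- NA  # 3/20 = 15% missing
  map <- data.frame(marker = paste0("mk", 1:5),
                    chrom = c("1", NA, "1", "1", NA),
                    pos_cM = c(1, NA, 2, 3, NA), stringsAsFactors = FALSE)
  qc <- stats::setNames(c(0.9, 0.9, 0.55, 0.9, 0.9), paste0("mk", 1:5))
  G <- genotype_matrix(calls, map, qc)
  suppressMessages(out <- qc_filter(G, max_missing = 0.10, min_qc = 0.6))
  # 2 unknown position, 1 low qc, 1 excess missing -> only mk1 survives
  expect_identical(out$marker_ids, "mk1")
  expect_identical(out$calls[, "mk1"], calls[, "mk1"])

  suppressMessages(again <- qc_filter(out))
  expect_identical(again$calls, out$calls)

  # marker with 11% missing on 100 accessions is removed
  calls2 <- matrix(rbinom(100 * 2, 1L, 0.5), 100, 2,
                   dimnames = list(sprintf("x%03d", 1:100), c("keep", "drop")))
  calls2[1:11, "drop"] <- NA
  G2 <- genotype_matrix(calls2,
                        data.frame(marker = c("keep", "drop"),
                                   chrom = "1", pos_cM = c(1, 2)))
  suppressMessages(out2 <- qc_filter(G2))
  expect_identical(out2$marker_ids, "keep")

  # all clean -> no-op
  suppressMessages(out3 <- qc_filter(out2))
  expect_identical(out3$calls, out2$calls)
})

test_that("maf_filter removes rare and monomorphic markers, boundary kept", {
  # 10 markers with hand-set counts among 100 accessions
  n <- 100
  freq <- c(0, 0.01, 0.04, 0.05, 0.06, 0.10, 0.30, 0.50, 0.96, 1)
  calls <- vapply(freq, function(f) {
    c(rep(1L, round(f * n)), rep(0L, n - round(f * n)))
  }, integer(n))
  dimnames(calls) <- list(sprintf("a%03d", 1:n), sprintf("f%02d", 1:10))
  G <- genotype_matrix(calls)
  suppressMessages(out <- maf_filter(G, 0.05))
  # survivors: maf 0.05 (exactly at boundary, kept), 0.06, 0.30, 0.50, 0.96->maf 0.04 removed
  expect_identical(out$marker_ids, c("f04", "f05", "f06", "f07", "f08"))
  # 4/100 minor alleles -> removed; monomorphic -> removed
  expect_false("f03" %in% out$marker_ids)
  expect_false("f01" %in% out$marker_ids)
  expect_false("f10" %in% out$marker_ids)
  # idempotent, calls untouched
  suppressMessages(again <- maf_filter(out, 0.05))
  expect_identical(again$calls, out$calls)
})

test_that("tri-allelic sites collapse by dropping the minor state", {
  site <- rep(c("A", "B", "C"), c(50, 40, 10))
  out <- binarize_multiallelic(site)
  expect_true(all(is.na(out[site == "C"])))
  expect_identical(attr(out, "dropped_state"), "C")

  # already biallelic: unchanged
  two <- rep(c("A", "B"), c(50, 50))
  expect_identical(as.vector(binarize_multiallelic(two)), two)

  # tie among minors: lexicographically first dropped
  tie <- rep(c("B", "A", "C"), c(10, 10, 80))
  out2 <- suppressMessages(binarize_multiallelic(tie))
  expect_identical(attr(out2, "dropped_state"), "A")
  expect_true(all(is.na(out2[tie == "A"])))

  expect_error(binarize_multiallelic(c("A", "B", "C", "D")), "3-state")
})
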