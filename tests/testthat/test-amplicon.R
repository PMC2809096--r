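# Amplicon preprocessing and two-timepoint community comparison.

library(Biostrings)

test_that("demultiplexing partitions reads and trims barcodes", {
  reads <- DNAStringSet(c(r1 = "ACGTAGGGTTT", r2 = "ACGTACCCAAA",
                          r3 = "TTTTTGGGCCC", r4 = "ACG"))
  map <- data.frame(barcode = c("ACGTA", "GGGGG"),
                    sample = c("S1", "S2"))
  out <- demultiplex(reads, map)
  expect_equal(as.character(out$samples$S1),
               c(r1 = "GGGTTT", r2 = "CCCAAA"))
  expect_length(out$samples$S2, 0)
  # partition: every read lands exactly once
  expect_equal(sum(lengths(out$samples)) + length(out$unassigned),
               length(reads))
  expect_setequal(names(out$unassigned), c("r3", "r4"))

  expect_error(
    demultiplex(reads, data.frame(barcode = c("ACGTA", "ACGTA"),
                                  sample = c("a", "b"))),
    "duplicate")
  expect_error(
    demultiplex(reads, data.frame(barcode = "ACG", sample = "a")),
    "length")
})

test_that("length filter keeps the inclusive boundary", {
  reads <- DNAStringSet(c(a = paste(rep("A", 219), collapse = ""),
                          b = paste(rep("C", 220), collapse = ""),
                          c = paste(rep("G", 300), collapse = "")))
  kept <- lengthFilter(reads)
  expect_setequal(names(kept), c("b", "c"))
  expect_length(lengthFilter(DNAStringSet()), 0)
  expect_length(lengthFilter(reads, ampliconParams(minLength = 1)), 3)
})

test_that("phylotype tallying and relative abundance", {
  tab <- tallyPhylotypes(list(
    t0 = c("Bacillus_1", "Bacillus_1", "Stack_2"),
    t1 = c("Stack_2", "Stack_2", "Stack_2", "Bacillus_1")))
  expect_s4_class(tab, "PhylotypeTable")
  expect_equal(counts(tab)["Bacillus_1", "t0"], 2L)
  p0 <- relativeAbundance(tab, "t0")
  expect_equal(sum(p0), 1)
  expect_equal(unname(p0["Bacillus_1"]), 2 / 3)
  empty <- phylotypeTable(matrix(0L, 2, 1,
                                 dimnames = list(c("x", "y"), "s")))
  expect_error(relativeAbundance(empty, "s"), "zero total")
})

test_that("Bray-Curtis matches its definition and vegan", {
  p <- c(a = 0.5, b = 0.5, c = 0)
  q <- c(a = 0, b = 0.5, c = 0.5)
  expect_equal(brayCurtis(p, q), 0.5)
  expect_equal(brayCurtis(p, p), 0)
  expect_equal(brayCurtis(c(a = 1), c(b = 1)), 1)  # disjoint support
  expect_error(brayCurtis(c(a = 0), c(a = 0)), "all-zero")

  skip_if_not_installed("vegan")
  set.seed(14)
  for (i in 1:8) {
    x <- runif(6); y <- runif(6)
    x <- x / sum(x); y <- y / sum(y)
    names(x) <- names(y) <- letters[1:6]
    expect_equal(brayCurtis(x, y),
                 as.numeric(vegan::vegdist(rbind(x, y), "bray")),
                 tolerance = 1e-12)
  }
})

test_that("Bray-Curtis is symmetric and bounded on random profiles", {
  set.seed(3)
  for (i in 1:20) {
    x <- runif(8); y <- runif(8)
    names(x) <- names(y) <- paste0("p", 1:8)
    bc1 <- brayCurtis(x, y); bc2 <- brayCurtis(y, x)
    expect_identical(bc1, bc2)
    expect_gte(bc1, 0); expect_lte(bc1, 1)
  }
})

test_that("fold enrichment distinguishes exact ratios from bounds", {
  params <- ampliconParams()
  p1 <- c(big = 0.044, lowT0 = 0.009, gone = 0, steady = 0.5,
          rest = 0.447)
  p0 <- c(big = 0.002, lowT0 = 0, gone = 0.01, steady = 0.5,
          rest = 0.488)
  fe <- foldEnrichment(p1, p0, params)
  expect_equal(fe$fold[fe$phylotype == "big"], 22)
  expect_false(fe$lowerBound[fe$phylotype == "big"])
  # below-detection t0: lower bound p1 / tau, flagged
  low <- fe[fe$phylotype == "lowT0", ]
  expect_equal(low$fold, 0.009 / 0.0009)
  expect_true(low$lowerBound)
  expect_equal(low$label, ">=10.0")
  # extinct at t1 reported as 0, not dropped
  expect_equal(fe$fold[fe$phylotype == "gone"], 0)
  expect_equal(fe$fold[fe$phylotype == "steady"], 1)
  # rank-abundance order: sorted by t1 abundance
  expect_equal(fe$phylotype[1:2], c("steady", "rest"))
})

test_that("fold enrichment recovers a planted 22-fold change", {
  sp <- demoCommunitySpec()
  tab <- makePhylotypeTables(sp, depth = 1e6, seed = 21)
  fe <- foldEnrichment(relativeAbundance(tab, "t1"),
                        relativeAbundance(tab, "t0"))
  got <- fe$fold[fe$phylotype == "Stackebrandtia_like"]
  expect_gt(got, 22 * 0.8)
  expect_lt(got, 22 * 1.2)
})

test_that("identical distributions give vanishing dissimilarity at depth", {
  sp <- communitySpec(
    taxa = data.frame(label = letters[1:4],
                      abundance = c(0.4, 0.3, 0.2, 0.1),
                      fold = c(1, 1, 1, 1)))
  tab <- makePhylotypeTables(sp, depth = 1e6, seed = 8)
  bc <- brayCurtis(relativeAbundance(tab, "t0"),
                   relativeAbundance(tab, "t1"))
  expect_lt(bc, 0.01)
  expect_error(makePhylotypeTables(sp, depth = 0, seed = 1), "> 0")
})

test_that("phylotype tables round-trip through TSV", {
  sp <- demoCommunitySpec()
  tab <- makePhylotypeTables(sp, depth = 1000, seed = 2)
  path <- tempfile(fileext = ".tsv")
  writePhylotypeTable(tab, path)
  back <- readPhylotypeTable(path)
  expect_equal(counts(back), counts(tab))
})
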