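# Six-frame translation, contig scanning, depth weighting and the
# grouped GH inventory.

library(Biostrings)

test_that("six-frame translation follows the codon table conventions", {
  expect_equal(sixFrameTranslate("ATGGCC")[["+1"]], "MA")
  expect_equal(sixFrameTranslate("TTA")[["-1"]], "*")
  expect_equal(sixFrameTranslate("ATGNCC")[["+1"]], "MX")
  expect_equal(sixFrameTranslate("AT")[["+1"]], "")
  # frame +1 of the reverse complement equals frame -1 of the input
  set.seed(17)
  for (i in 1:10) {
    dna <- paste(sample(c("A", "C", "G", "T"), 20 + i, replace = TRUE),
                 collapse = "")
    rc <- as.character(reverseComplement(DNAString(dna)))
    expect_identical(sixFrameTranslate(dna)[["-1"]],
                     sixFrameTranslate(rc)[["+1"]])
    expect_identical(sixFrameTranslate(dna)[["-2"]],
                     sixFrameTranslate(rc)[["+2"]])
  }
  # agreement with the Biostrings translation on whole codon spans
  for (i in 1:5) {
    dna <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
                 collapse = "")
    expect_identical(sixFrameTranslate(dna)[["+1"]],
                     as.character(translate(DNAString(dna))))
  }
})

test_that("contig weight is reads x read length / contig length", {
  contigs <- depthContigSet(
    DNAStringSet(c(c1 = paste(rep("A", 4000), collapse = ""),
                   c2 = paste(rep("C", 400), collapse = ""))),
    c(100L, 1L))
  w <- contigWeight(contigs)
  expect_equal(unname(w), c(10, 1))
  # linearity in read counts
  w2 <- contigWeight(depthContigSet(contigSeqs(contigs), c(200L, 2L)))
  expect_equal(unname(w2), 2 * unname(w))
})

test_that("scanning recovers planted genes and applies the best-hit rule", {
  cat0 <- smallCatalog(6, profileLength = 40)
  sp <- communitySpec(
    taxa = data.frame(label = "A", abundance = 1, fold = 1),
    genes = data.frame(label = "A", family = c("GH5", "GH2"),
                       count = c(1L, 1L)),
    contigLength = c(500, 1500))
  b <- buildContigSet(sp, cat0$profiles, 55)
  hits <- scanContigs(b$contigs, cat0$profiles, cat0$catalog)
  # every planted family is found on its contig
  for (r in seq_len(nrow(b$truth))) {
    tr <- b$truth[r, ]
    h <- hits[hits$contig == tr$contig & hits$family == tr$family, ]
    expect_equal(nrow(h), 1)
    # hit span overlaps the planted gene
    expect_lt(max(h$ntBegin, tr$start), min(h$ntEnd, tr$end))
  }
  # GH2 has two profiles: best-hit rule leaves exactly one GH2 hit
  gh2 <- hits[hits$family == "GH2", ]
  expect_equal(nrow(gh2), length(unique(gh2$contig)))
})

test_that("random non-coding contigs produce no hits at the threshold", {
  cat0 <- smallCatalog(6, profileLength = 40)
  profs <- cat0$profiles[c("PF_GH5", "PF_GH9")]
  catal <- cat0$catalog[cat0$catalog$profile %in% names(profs), ]
  set.seed(1234)
  seqs <- vapply(1:400, function(i)
    paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
          collapse = ""), character(1))
  names(seqs) <- paste0("r", 1:400)
  contigs <- depthContigSet(DNAStringSet(seqs), rep(1L, 400))
  hits <- scanContigs(contigs, profs, catal)
  # false positive rate below 1% of contig x profile trials
  expect_lte(nrow(hits), 0.01 * 400 * 2)
})

test_that("inventory percentages are normalised and scale-invariant", {
  cat0 <- smallCatalog(6, profileLength = 40)
  sp <- demoCommunitySpec(contigLength = c(800, 1800))
  b <- buildContigSet(sp, cat0$profiles, 91, depthScale = 40)
  hits <- scanContigs(b$contigs, cat0$profiles, cat0$catalog)
  inv <- inventoryTable(hits, b$contigs, cat0$catalog)
  expect_equal(sum(inv$percent), 100, tolerance = 1e-9)
  gt <- attr(inv, "groupTotals")
  expect_equal(sum(gt$total), 100, tolerance = 1e-9)

  # doubling every contig's read count changes nothing
  doubled <- depthContigSet(contigSeqs(b$contigs),
                            2L * nReads(b$contigs))
  inv2 <- inventoryTable(hits, doubled, cat0$catalog)
  expect_equal(inv2$percent, inv$percent, tolerance = 1e-12)

  # multiplying one contig's depth by 10 multiplies its family weight
  oneContig <- hits$contig[hits$family == "GH51"][1]
  nr <- nReads(b$contigs)
  nr[names(b$contigs) == oneContig] <- 10L * nr[names(b$contigs) == oneContig]
  inv3 <- inventoryTable(hits, depthContigSet(contigSeqs(b$contigs), nr),
                         cat0$catalog)
  wBefore <- inv$weight[inv$family == "GH51"]
  wAfter <- inv3$weight[inv3$family == "GH51"]
  contigShare <- contigWeight(b$contigs)[oneContig]
  expect_equal(wAfter, wBefore + 9 * unname(contigShare),
               tolerance = 1e-9)

  expect_error(inventoryTable(hits[0, ], b$contigs, cat0$catalog),
               "no domain hits")
})

test_that("group totals reproduce hand-computed sums", {
  catalog <- data.frame(
    family = c("F1", "F2", "F3"),
    profile = c("p1", "p2", "p3"),
    group = c("cellulases", "cellulases", "debranching"))
  gt <- groupTotals(c(F1 = 3.5, F2 = 7.1, F3 = 21.2), catalog)
  expect_equal(gt$total[gt$group == "cellulases"], 10.6)
  expect_equal(gt$total[gt$group == "debranching"], 21.2)
  expect_equal(gt$total[gt$group == "endohemicellulases"], 0)
  expect_error(groupTotals(c(F9 = 1), catalog), "absent")
  expect_error(groupTotals(c(F1 = 1),
                           transform(catalog, group = "no-such-group")),
               "unknown functional group")
})

test_that("planted family proportions are recovered by the inventory", {
  cat0 <- smallCatalog(6, profileLength = 40)
  sp <- plantedProportionSpec()
  # depthScale 100: expected coverage 10x for the rarest taxon, so the
  # whole community sits comfortably above 5x simulated coverage
  b <- buildContigSet(sp, cat0$profiles, 2024, depthScale = 100)
  covByTaxon <- tapply(
    contigWeight(b$contigs)[unique(b$truth[c("contig", "taxon")])$contig],
    unique(b$truth[c("contig", "taxon")])$taxon, mean)
  expect_gte(min(covByTaxon), 5)
  hits <- scanContigs(b$contigs, cat0$profiles, cat0$catalog)
  inv <- inventoryTable(hits, b$contigs, cat0$catalog)
  want <- c(GH5 = 40, GH10 = 30, GH43 = 20, GH9 = 10)
  for (fam in names(want)) {
    got <- inv$percent[inv$family == fam]
    expect_lt(abs(got - want[[fam]]), 5,
              label = paste(fam, "percent", round(got, 2)))
  }
})

test_that("GH fraction of genes counts overlapping calls", {
  cat0 <- smallCatalog(6, profileLength = 40)
  b <- oneGeneCommunity("GH5", 12, cat0)
  hits <- scanContigs(b$contigs, cat0$profiles, cat0$catalog)
  genes <- callGenes(contigSeqs(b$contigs)[[1]], names(b$contigs)[1],
                     minOrfLength = 90)
  frac <- ghFractionOfGenes(hits, genes)
  expect_gt(frac, 0)
  expect_lte(frac, 100)
  expect_equal(ghFractionOfGenes(hits[0, ], genes), 0)
  expect_error(ghFractionOfGenes(hits, genes[0]), "no predicted genes")
})

test_that("family catalog TSV round trip and validation", {
  cat0 <- smallCatalog(6)
  path <- tempfile(fileext = ".tsv")
  writeFamilyCatalog(cat0$catalog, path)
  back <- readFamilyCatalog(path)
  expect_equal(back$family, cat0$catalog$family)
  expect_equal(back$group, cat0$catalog$group)
  bad <- transform(cat0$catalog, group = "mystery")
  expect_error(writeFamilyCatalog(bad, path), "unknown functional group")
})
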