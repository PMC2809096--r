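# Ground-truth generators: planted genes, planted frameshifts, gas and
# composition series.

library(Biostrings)

test_that("community spec validity enforces balanced abundances", {
  expect_error(communitySpec(
    data.frame(label = c("a", "b"), abundance = c(0.6, 0.6),
               fold = c(1, 1))), "sum to 1")
  expect_error(communitySpec(
    data.frame(label = c("a", "b"), abundance = c(0.5, 0.5),
               fold = c(2, 1))), "t1 abundances")
  expect_error(communitySpec(
    data.frame(label = c("a", "b"), abundance = c(0.5, 0.5),
               fold = c(-1, 3))))
})

test_that("built contigs embed their genes at the truth coordinates", {
  cat0 <- smallCatalog(5)
  sp <- demoCommunitySpec(contigLength = c(800, 1800))
  b <- buildContigSet(sp, cat0$profiles, 77)
  expect_s4_class(b$contigs, "DepthContigSet")
  expect_gt(nrow(b$truth), 0)
  for (r in seq_len(nrow(b$truth))) {
    tr <- b$truth[r, ]
    g <- subseq(contigSeqs(b$contigs)[[tr$contig]], tr$start, tr$end)
    if (tr$strand == "-") g <- reverseComplement(g)
    pep <- as.character(translate(g))
    # ATG .. single terminal stop encoding the sampled peptide
    expect_identical(pep, paste0(tr$peptide, "*"))
  }
  # taxa without genes still contribute contigs with no truth entries
  noGene <- setdiff(unique(sp@taxa$label), unique(sp@genes$label))
  expect_length(
    intersect(b$truth$taxon, noGene), 0)

  # byte-identical rerun under the same seed
  b2 <- buildContigSet(sp, cat0$profiles, 77)
  expect_identical(as.character(contigSeqs(b$contigs)),
                   as.character(contigSeqs(b2$contigs)))
  expect_identical(nReads(b$contigs), nReads(b2$contigs))

  expect_error(buildContigSet(
    communitySpec(data.frame(label = "a", abundance = 1, fold = 1),
                  data.frame(label = "a", family = "GH999", count = 1L)),
    cat0$profiles, 1), "GH999")
})

test_that("read counts scale with taxon abundance", {
  cat0 <- smallCatalog(5)
  sp <- communitySpec(
    taxa = data.frame(label = c("A", "B"), abundance = c(0.9, 0.1),
                      fold = c(1, 1)),
    genes = data.frame(label = c("A", "B"), family = c("GH5", "GH5"),
                       count = c(20L, 20L)),
    contigLength = c(400, 700))
  b <- buildContigSet(sp, cat0$profiles, 123, depthScale = 300)
  truthByContig <- unique(b$truth[c("contig", "taxon")])
  nr <- setNames(nReads(b$contigs), names(b$contigs))
  len <- setNames(width(contigSeqs(b$contigs)), names(b$contigs))
  perRead <- nr[truthByContig$contig] / len[truthByContig$contig]
  byTaxon <- tapply(perRead, truthByContig$taxon, mean)
  ratio <- byTaxon[["A"]] / byTaxon[["B"]]
  # Poisson means differ 9-fold; wide tolerance covers sampling noise
  expect_gt(ratio, 6)
  expect_lt(ratio, 13)
})

test_that("zero-rate error model returns input unchanged", {
  cat0 <- smallCatalog(5)
  b <- oneGeneCommunity("GH5", 8, cat0)
  pl <- plantFrameshifts(b$contigs, errorModel(0, subsProb = 0), seed = 1)
  expect_identical(as.character(contigSeqs(pl$contigs)),
                   as.character(contigSeqs(b$contigs)))
  expect_equal(nrow(pl$edits), 0)
})

test_that("indel counts follow the binomial error model", {
  set.seed(42)
  dna <- paste(sample(c("A", "C", "G", "T"), 60000, replace = TRUE),
               collapse = "")
  contigs <- depthContigSet(DNAStringSet(c(c1 = dna)), 1L)
  runs <- compostGH:::.homopolymerRuns(dna, 2L)
  R <- nrow(runs)
  expect_gt(R, 8000)
  pl <- plantFrameshifts(contigs, errorModel(0.01), seed = 9)
  got <- nrow(pl$edits)
  sigma <- sqrt(R * 0.01 * 0.99)
  expect_lt(abs(got - R * 0.01), 3 * sigma)
  # every edit sits inside a homopolymer run of length >= 2
  hit <- vapply(pl$edits$posOrig, function(p)
    any(runs$start <= p & runs$end >= p), logical(1))
  expect_true(all(hit))
})

test_that("a planted indel shifts the downstream translation", {
  # genes need enough interior for a forced indel 60 nt from both ends
  cat0 <- smallCatalog(5, profileLength = 60)
  b <- oneGeneCommunity("GH9", 31, cat0)
  tr <- b$truth[1, ]
  pl <- plantFrameshifts(b$contigs, errorModel(), seed = 5,
                         truth = b$truth,
                         forcePerContig = setNames(1L, tr$contig))
  expect_equal(nrow(pl$edits), 1)
  mut <- contigSeqs(pl$contigs)[[1]]
  g <- subseq(mut, tr$start,
              tr$end + ifelse(pl$edits$kind == "duplicate", 1L, -1L))
  if (tr$strand == "-") g <- reverseComplement(g)
  g <- subseq(g, 1, length(g) - length(g) %% 3L)
  pepMut <- as.character(translate(g, if.fuzzy.codon = "X"))
  expect_false(identical(pepMut, paste0(tr$peptide, "*")))
})

test_that("gas series invert the mass-balance formulas", {
  gas <- makeGasSeries(function(t) rep(2, length(t)),
                       function(t) rep(1.4, length(t)),
                       F = 1000, interval = 0.05, tEnd = 10)
  r <- respirationRates(gas)
  expect_equal(r$cer, rep(2, nrow(gas)), tolerance = 1e-12)
  expect_equal(r$our, rep(1.4, nrow(gas)), tolerance = 1e-12)
  expect_equal(integrateRates(r$t_day, r$cer), 2 * 10, tolerance = 1e-9)

  # zero respiration: effluent equals influent
  g0 <- makeGasSeries(function(t) 0 * t, function(t) 0 * t, tEnd = 1)
  expect_equal(g0$co2_out, g0$co2_in)
  expect_equal(g0$o2_out, g0$o2_in)

  expect_error(
    makeGasSeries(function(t) 0 * t, function(t) rep(1000, length(t)),
                  F = 1, o2In = 0.23), "negative")
})

test_that("composition tables encode the requested losses exactly", {
  ini <- c(lig = 314, glu = 260, xyl = 170, gal = 18, ara = 23,
           man = 0.4)
  losses <- c(0.17, 0.27, 0.31, 0.33, 0.30, 1.0)
  tab <- makeCompositionTable(ini, losses, 0.115, 0.175)
  expect_equal(tab$final_adjusted_g_per_kg, unname(ini * (1 - losses)))
  # round trip through the composition module recovers the loss vector
  rep0 <- compositionReport(tab)
  expect_equal(rep0$lossPercent, 100 * losses, tolerance = 1e-12)
  # and the measured-final route agrees after ash adjustment
  tab2 <- tab[, c("name", "initial_g_per_kg", "final_measured_g_per_kg")]
  rep2 <- compositionReport(tab2, ashInitial = 0.115, ashFinal = 0.175)
  expect_equal(rep2$lossPercent, 100 * losses, tolerance = 1e-12)

  none <- makeCompositionTable(ini, rep(0, 6), 0.115, 0.175)
  expect_equal(none$final_adjusted_g_per_kg, unname(ini))

  expect_error(makeCompositionTable(ini, losses, 0.115, 0.175,
                                    solidsLossTarget = 0.5),
               "inconsistent")
  expect_error(makeCompositionTable(ini, c(losses[-6], 1.2),
                                    0.115, 0.175), "\\[0, 1\\]")
})

test_that("contig FASTA + sidecar round trip", {
  cat0 <- smallCatalog(5)
  b <- oneGeneCommunity("GH5", 4, cat0)
  fa <- tempfile(fileext = ".fasta"); tsv <- tempfile(fileext = ".tsv")
  writeDepthContigs(b$contigs, fa, tsv)
  back <- readDepthContigs(fa, tsv)
  expect_identical(as.character(contigSeqs(back)),
                   as.character(contigSeqs(b$contigs)))
  expect_identical(nReads(back), nReads(b$contigs))
})
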