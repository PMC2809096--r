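# Translated search, candidate filtering, frameshift detection and
# correction, ORF calling and truncation assessment.

library(Biostrings)

test_that("translated search finds an exact in-frame encoding", {
  cat0 <- smallCatalog(7, profileLength = 60, matchProb = 1)
  b <- oneGeneCommunity("GH5", 3, cat0)
  ref <- cat0$refs[cat0$refs$family == "GH5", ]
  hsps <- translatedSearch(b$contigs, ref)
  h <- hsps[hsps$ref == ref$id, ]
  best <- h[which.max(h$score), ]
  expect_equal(best$refBegin, 1)
  expect_equal(best$refEnd, nchar(ref$peptide))
  expect_lt(best$evalue, 1e-20)
  tr <- b$truth[1, ]
  expect_equal(best$strand, tr$strand)
  expect_lte(abs(best$ntBegin - tr$start), 3)
  expect_error(translatedSearch(b$contigs, ref[0, ]), "empty reference")
})

test_that("E-values follow the Karlin-Altschul formula", {
  params <- recoveryParams(lambda = 0.318, K = 0.134)
  bits <- compostGH:::.bitScore(30, params)
  expect_equal(compostGH:::.eValue(bits, 100, 100), 0.0963,
               tolerance = 1e-3)
  # monotone decreasing in raw score for fixed m, n
  e <- compostGH:::.eValue(compostGH:::.bitScore(seq(10, 100, 10),
                                                 params), 200, 500)
  expect_true(all(diff(e) < 0))
})

test_that("alignment scores equal the quadratic-time oracle", {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  subst <- get("BLOSUM62")[aa, aa]
  set.seed(6)
  for (i in 1:50) {
    q <- sample(aa, sample(3:12, 1), replace = TRUE)
    r <- sample(aa, sample(3:12, 1), replace = TRUE)
    got <- compostGH:::.sw_local_cpp(match(q, aa) - 1L,
                                     match(r, aa) - 1L,
                                     subst, 11, 1)
    want <- oracleLocalAlign(q, r, subst, 11, 1)
    expect_equal(got$score, want,
                 info = paste(paste(q, collapse = ""),
                              paste(r, collapse = "")))
  }
})

test_that("candidate filter applies coverage, E-value and EC rules", {
  refs <- data.frame(id = c("rA", "rB"),
                     peptide = c(strrep("K", 300), strrep("K", 300)),
                     ec = c("3.2.1.4", NA), family = c("GH5", "GH5"))
  hsp <- function(ref, rb, re, evalue) {
    data.frame(contig = "c1", ref = ref, frame = "+1", strand = "+",
               ntBegin = 1, ntEnd = 3 * (re - rb + 1),
               refBegin = rb, refEnd = re, score = 500, bits = 200,
               evalue = evalue)
  }
  # coverage 271/300 = 0.903 passes; 269/300 fails
  pass <- candidateFilter(hsp("rA", 10, 280, 1e-50), refs)
  expect_equal(nrow(pass), 1)
  expect_equal(pass$coverage, 271 / 300)
  expect_equal(nrow(candidateFilter(hsp("rA", 12, 280, 1e-50), refs)), 0)
  # E-value rule
  expect_equal(nrow(candidateFilter(hsp("rA", 1, 300, 1e-9), refs)), 0)
  # EC absent fails regardless of score
  expect_equal(nrow(candidateFilter(hsp("rB", 1, 300, 1e-80), refs)), 0)
  # chained coverage: two HSPs whose union covers 90%
  two <- rbind(hsp("rA", 1, 150, 1e-40), hsp("rA", 140, 280, 1e-35))
  expect_equal(candidateFilter(two, refs)$coverage,
               280 / 300)
})

test_that("frameshift boundaries sit between frame-switching HSPs", {
  h <- data.frame(contig = "c", ref = "r",
                  frame = c("+1", "+3"), strand = c("+", "+"),
                  ntBegin = c(100, 331), ntEnd = c(330, 600),
                  refBegin = c(1, 78), refEnd = c(77, 167),
                  score = c(300, 350), bits = c(140, 160),
                  evalue = c(1e-30, 1e-35))
  b <- detectFrameshiftCandidates(h, recoveryParams(editPad = 12))
  expect_equal(nrow(b), 1)
  expect_equal(b$begin, 330 - 12)
  expect_equal(b$end, 331 + 12)
  # single HSP: nothing to correct
  expect_equal(nrow(detectFrameshiftCandidates(h[1, ])), 0)
  # same frame twice: no boundary
  h2 <- h; h2$frame <- c("+1", "+1")
  expect_equal(nrow(detectFrameshiftCandidates(h2)), 0)
  # three HSPs, two frame switches
  h3 <- rbind(h, transform(h[2, ], frame = "+2", ntBegin = 601,
                           ntEnd = 800, refBegin = 168, refEnd = 230))
  expect_equal(nrow(detectFrameshiftCandidates(h3)), 2)
  # both strands: chimeric, refuse
  h4 <- h; h4$strand <- c("+", "-")
  expect_error(detectFrameshiftCandidates(h4), "chimeric")
})

test_that("correction is idempotent on clean genes", {
  cat0 <- smallCatalog(7, profileLength = 60, matchProb = 1)
  for (fam in c("GH5", "GH10")) {
    b <- oneGeneCommunity(fam, 41, cat0)
    ref <- cat0$refs[cat0$refs$family == fam, ]
    res <- correctFrameshifts(as.character(contigSeqs(b$contigs)[[1]]),
                              ref$peptide)
    expect_equal(nrow(res$edits), 0)
    expect_identical(res$sequence,
                     as.character(contigSeqs(b$contigs)[[1]]))
  }
})

test_that("a single planted deletion is exactly reverted", {
  cat0 <- smallCatalog(7, profileLength = 80, matchProb = 1)
  found <- 0
  for (s in 1:6) {
    b <- oneGeneCommunity("GH9", 100 + s, cat0)
    tr <- b$truth[1, ]
    pl <- plantFrameshifts(b$contigs, errorModel(), seed = 200 + s,
                           truth = b$truth,
                           forcePerContig = setNames(1L, tr$contig))
    if (pl$edits$kind != "delete") next
    found <- found + 1
    ref <- cat0$refs[cat0$refs$family == "GH9", ]
    orig <- as.character(contigSeqs(b$contigs)[[1]])
    res <- correctFrameshifts(as.character(contigSeqs(pl$contigs)[[1]]),
                              ref$peptide)
    # exactly one compensating duplication, restoring the original
    # contig and hence the unmutated alignment score
    expect_equal(nrow(res$edits), 1)
    expect_equal(res$edits$kind, "duplicate")
    expect_identical(res$sequence, orig)
    origScore <- compostGH:::.chainScore(
      if (tr$strand == "-")
        as.character(reverseComplement(DNAString(orig))) else orig,
      ref$peptide, recoveryParams(), "+")
    expect_equal(res$score, origScore)
    # idempotent on its own output
    res2 <- correctFrameshifts(res$sequence, ref$peptide)
    expect_equal(nrow(res2$edits), 0)
  }
  expect_gte(found, 2)
})

test_that("accepted edits never decrease the alignment score", {
  cat0 <- smallCatalog(7, profileLength = 80, matchProb = 1)
  for (s in 1:5) {
    b <- oneGeneCommunity("GH43", 300 + s, cat0)
    pl <- plantFrameshifts(b$contigs, errorModel(), seed = 400 + s,
                           truth = b$truth,
                           forcePerContig = setNames(2L,
                                                     b$truth$contig[1]))
    ref <- cat0$refs[cat0$refs$family == "GH43", ]
    res <- correctFrameshifts(as.character(contigSeqs(pl$contigs)[[1]]),
                              ref$peptide)
    if (nrow(res$edits)) {
      expect_true(all(res$edits$scoreAfter >= res$edits$scoreBefore))
      expect_true(all(diff(c(res$edits$scoreBefore[1],
                             res$edits$scoreAfter)) > 0))
    }
  }
})

test_that("ORF calling recovers planted genes on both strands", {
  # genes must clear the 300 nt ORF threshold: 120 codons + start/stop
  cat0 <- smallCatalog(7, profileLength = 120, matchProb = 0.85)
  plus <- minus <- 0
  for (s in 1:8) {
    b <- oneGeneCommunity("GH5", 500 + s, cat0)
    tr <- b$truth[1, ]
    genes <- callGenes(contigSeqs(b$contigs)[[1]], tr$contig)
    hit <- genes[start(genes) == tr$start & end(genes) == tr$end]
    expect_equal(length(hit), 1)
    expect_equal(as.character(strand(hit)), tr$strand)
    expect_identical(S4Vectors::mcols(hit)$peptide, tr$peptide)
    # any additional call can only be a shadow ORF inside the gene span
    other <- genes[!(start(genes) == tr$start & end(genes) == tr$end)]
    if (length(other)) {
      expect_true(all(start(other) >= tr$start - 3 &
                        end(other) <= tr$end + 3))
    }
    if (tr$strand == "+") plus <- plus + 1 else minus <- minus + 1
  }
  expect_gt(plus, 0); expect_gt(minus, 0)
  # a 360 nt stop-free stretch with an ATG is called; 120 nt is not
  expect_length(callGenes(strrep("ATGAAA", 60), "short",
                          minOrfLength = 300), 1)
  expect_length(callGenes(strrep("ATGAAA", 20), "short",
                          minOrfLength = 300), 0)
})

test_that("truncation is attributed only to contig edges", {
  base <- data.frame(contig = "c", ref = "r", frame = "+1",
                     strand = "+", score = 100, bits = 50,
                     evalue = 1e-20)
  # alignment starts at reference residue 1: no N truncation
  h <- cbind(base, ntBegin = 200, ntEnd = 500, refBegin = 1,
             refEnd = 100)
  t1 <- truncationAssessment(h, refLen = 140, contigLen = 502)
  expect_equal(t1$nTruncation, 0)
  # C-terminal shortfall with the contig ending flush: truncation 40
  expect_equal(t1$cTruncation, 40)
  # same shortfall but ample contig remains: genuine end, not truncation
  t2 <- truncationAssessment(h, refLen = 140, contigLen = 600)
  expect_equal(t2$cTruncation, 0)
  # minus strand: the N terminus faces the contig end
  hm <- cbind(base[, setdiff(names(base), "strand")], strand = "-",
              ntBegin = 10, ntEnd = 310, refBegin = 30, refEnd = 140)
  t3 <- truncationAssessment(hm, refLen = 140, contigLen = 312)
  expect_equal(t3$nTruncation, 29)
  expect_equal(t3$cTruncation, 0)
})

test_that("end-to-end recovery reports corrected candidates", {
  cat0 <- smallCatalog(7, profileLength = 80, matchProb = 1)
  sp <- communitySpec(
    taxa = data.frame(label = "A", abundance = 1, fold = 1),
    genes = data.frame(label = "A", family = c("GH5", "GH9"),
                       count = c(1L, 1L)),
    contigLength = c(1000, 1600))
  b <- buildContigSet(sp, cat0$profiles, 9)
  pl <- plantFrameshifts(b$contigs, errorModel(), seed = 10,
                         truth = b$truth,
                         forcePerContig = setNames(
                           rep(1L, length(unique(b$truth$contig))),
                           unique(b$truth$contig)))
  rec <- recoverFullLength(pl$contigs, cat0$refs)
  expect_gt(nrow(rec$candidates), 0)
  expect_true(all(rec$candidates$coverage >= 0.9))
  expect_true(all(!is.na(rec$candidates$ec)))
  # corrections recorded in the edit log match the candidate counts
  expect_equal(sum(rec$candidates$nCorrections), nrow(rec$edits))
})

test_that("enzyme reference FASTA round-trips EC annotations", {
  cat0 <- smallCatalog(7)
  path <- tempfile(fileext = ".fasta")
  writeEnzymeReferences(cat0$refs, path)
  back <- readEnzymeReferences(path)
  expect_equal(back$id, cat0$refs$id)
  expect_equal(back$peptide, cat0$refs$peptide)
  expect_equal(is.na(back$ec), is.na(cat0$refs$ec))
  expect_equal(back$family, cat0$refs$family)
})
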