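# Small shared fixtures, built in code at test time.

# compact catalog (short profiles) for fast scanning tests
smallCatalog <- function(seed = 4L, profileLength = 30, matchProb = 0.85) {
  makeDemoCatalog(seed, profileLength = profileLength,
                  matchProb = matchProb)
}

# a one-taxon, one-gene community on contigs long enough for recovery
oneGeneCommunity <- function(family, seed, catalog,
                             contigLength = c(1000, 1500)) {
  sp <- communitySpec(
    taxa = data.frame(label = "A", abundance = 1, fold = 1),
    genes = data.frame(label = "A", family = family, count = 1L),
    contigLength = contigLength)
  buildContigSet(sp, catalog$profiles, seed, depthScale = 20)
}

# four-taxon community with planted family proportions 40/30/20/10 by
# expected depth weight: one gene (and one family) per contig and equal
# contig counts per taxon, so expected family weight is proportional to
# taxon abundance alone
plantedProportionSpec <- function() {
  communitySpec(
    taxa = data.frame(label = c("T40", "T30", "T20", "T10"),
                      abundance = c(0.4, 0.3, 0.2, 0.1),
                      fold = c(1, 1, 1, 1)),
    genes = data.frame(label = c("T40", "T30", "T20", "T10"),
                       family = c("GH5", "GH10", "GH43", "GH9"),
                       count = c(6L, 6L, 6L, 6L)),
    contigLength = c(250, 500))
}
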