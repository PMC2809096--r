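## Shared internal helpers: residue coding, rounding, codon tables.

# canonical 20-letter amino-acid alphabet, alphabetical one-letter order;
# all emission matrices and the C++ kernels index residues in this order
AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' @noRd
.aaCodes <- function(pep) {
  ch <- strsplit(pep, "")[[1]]
  code <- match(ch, AA20) - 1L
  code[ch == "X"] <- 20L
  code[ch == "*"] <- 21L
  bad <- is.na(code)
  if (any(bad))
    stop("residue(s) outside alphabet (not one of ", paste(AA20, collapse = ""),
         ", X, *): ", paste(unique(ch[bad]), collapse = ", "))
  code
}

# round half away from zero; base round() is round-half-even, which does not
# match conventional table presentation (e.g. 26.5 -> 27)
#' @noRd
.roundHalfUp <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# codon -> amino acid map (standard code; identical to the bacterial table
# for elongation codons) as a fast named lookup
#' @noRd
.codonTable <- function() {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
}

# synonymous codons per amino acid, for reverse translation
#' @noRd
.codonsByAA <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), as.character(gc))
}

#' @noRd
.asDNAString <- function(x) {
  if (is(x, "DNAString")) x else Biostrings::DNAString(as.character(x))
}

# guard segment with stop codons in all three frames of both strands
# (self reverse-complementary); used by the contig generator to insulate
# planted genes from surrounding sequence
#' @noRd
.FRAME_GUARD <- "TAGATAGATAGATCTATCTATCTA"

#' @noRd
.homopolymerRuns <- function(seq, minLen = 2L) {
  ch <- strsplit(as.character(seq), "")[[1]]
  if (length(ch) == 0L)
    return(data.frame(start = integer(), end = integer(),
                      base = character(), length = integer()))
  r <- rle(ch)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$lengths >= minLen
  data.frame(start = starts[keep], end = ends[keep],
             base = r$values[keep], length = r$lengths[keep],
             stringsAsFactors = FALSE)
}
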