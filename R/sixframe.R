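## Six-frame translation of contig DNA.

#' Translate a DNA sequence in all six reading frames
#'
#' Frames +1..+3 translate the forward strand at offsets 0..2; frames
#' -1..-3 translate the reverse complement at offsets 0..2. Stop codons are
#' emitted as \code{*}; codons containing \code{N} are emitted as \code{X}.
#' Trailing bases that do not fill a codon are dropped; sequences shorter
#' than 3 nt in a frame yield an empty peptide.
#'
#' @param dna a [Biostrings::DNAString], or a character scalar
#' @return named character vector of six peptides
#'   (\code{"+1","+2","+3","-1","-2","-3"})
#' @examples
#' sixFrameTranslate("ATGGCC")[["+1"]]  # "MA"
#' @export
sixFrameTranslate <- function(dna) {
  dna <- .asDNAString(dna)
  rc <- Biostrings::reverseComplement(dna)
  frames <- c("+1" = 0L, "+2" = 1L, "+3" = 2L,
              "-1" = 0L, "-2" = 1L, "-3" = 2L)
  out <- vapply(seq_along(frames), function(i) {
    s <- if (i <= 3) dna else rc
    off <- frames[[i]]
    n <- length(s) - off
    n <- n - n %% 3L
    if (n < 3L) return("")
    .translateQuick(as.character(subseq(s, off + 1L, off + n)))
  }, character(1))
  names(out) <- names(frames)
  out
}

# fast codon-table translation used in inner loops; N-containing codons -> X
#' @noRd
.translateQuick <- local({
  tbl <- NULL
  function(seqChar) {
    if (is.null(tbl)) {
      t0 <- .codonTable()
      tbl <<- t0
    }
    n <- nchar(seqChar)
    if (n < 3L) return("")
    starts <- seq.int(1L, n - 2L, by = 3L)
    codons <- substring(seqChar, starts, starts + 2L)
    aa <- tbl[codons]
    aa[is.na(aa)] <- "X"
    paste(aa, collapse = "")
  }
})
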