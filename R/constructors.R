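## User-facing constructors.

#' Construct a ProfileHMM from explicit probabilities
#'
#' @param name profile name
#' @param family GH family the profile annotates
#' @param matchEmis L x 20 match emission probability matrix (rows sum to 1),
#'   residue columns in alphabetical one-letter order
#' @param insEmis L x 20 insert emission probabilities; default uniform
#' @param trans L x 7 transition probabilities out of each node, columns
#'   \code{MM, MI, MD, IM, II, DM, DD}; default a weakly gappy profile
#' @param background length-20 background residue frequencies; default
#'   uniform 1/20
#' @return a [ProfileHMM]
#' @examples
#' p <- profileHMM("toy", "GH5",
#'                 matchEmis = consensusEmissions("MKLV", 0.9))
#' profileLength(p)
#' @export
profileHMM <- function(name, family, matchEmis,
                       insEmis = NULL, trans = NULL,
                       background = rep(1 / 20, 20)) {
  L <- nrow(matchEmis)
  colnames(matchEmis) <- AA20
  if (is.null(insEmis))
    insEmis <- matrix(1 / 20, L, 20, dimnames = list(NULL, AA20))
  if (is.null(trans))
    trans <- defaultTransitions(L)
  colnames(trans) <- c("MM", "MI", "MD", "IM", "II", "DM", "DD")
  new("ProfileHMM", name = name, family = family,
      matchEmis = matchEmis, insEmis = insEmis, trans = trans,
      background = background)
}

#' Default profile transition probabilities
#'
#' Mildly gap-tolerant node transitions used by the synthetic profile
#' builder: match-to-match 0.95, small open probabilities for inserts and
#' deletes, geometric gap extension. The last node transitions
#' deterministically towards the end state.
#'
#' @param L number of match states
#' @return L x 7 transition probability matrix
#' @export
defaultTransitions <- function(L) {
  tr <- matrix(rep(c(0.95, 0.03, 0.02, 0.70, 0.30, 0.70, 0.30), each = L),
               nrow = L, ncol = 7,
               dimnames = list(NULL, c("MM", "MI", "MD", "IM", "II",
                                       "DM", "DD")))
  tr[L, ] <- c(1, 0, 0, 1, 0, 1, 0)
  tr
}

#' Match emissions concentrated on a consensus peptide
#'
#' Builds an L x 20 emission matrix placing probability \code{p} on the
#' consensus residue of each position and spreading the remainder uniformly.
#'
#' @param consensus consensus peptide (characters from the 20-letter
#'   alphabet)
#' @param p probability mass on the consensus residue (default 0.85)
#' @return emission probability matrix
#' @export
consensusEmissions <- function(consensus, p = 0.85) {
  ch <- strsplit(consensus, "")[[1]]
  idx <- match(ch, AA20)
  if (anyNA(idx))
    stop("consensus contains non-canonical residues: ",
         paste(unique(ch[is.na(idx)]), collapse = ", "))
  m <- matrix((1 - p) / 19, length(ch), 20, dimnames = list(NULL, AA20))
  m[cbind(seq_along(idx), idx)] <- p
  m
}

#' Construct a DepthContigSet
#'
#' @param sequences a [Biostrings::DNAStringSet] (or named character vector)
#'   of contig sequences
#' @param nReads integer vector of read counts per contig
#' @return a [DepthContigSet]
#' @export
depthContigSet <- function(sequences, nReads) {
  if (!is(sequences, "DNAStringSet"))
    sequences <- Biostrings::DNAStringSet(sequences)
  new("DepthContigSet", sequences = sequences,
      nReads = as.integer(nReads))
}

#' Construct a PhylotypeTable
#'
#' @param counts integer matrix, phylotypes x samples, with dimnames
#' @return a [PhylotypeTable]
#' @export
phylotypeTable <- function(counts) {
  storage.mode(counts) <- "integer"
  new("PhylotypeTable", counts = counts)
}

#' Declare a synthetic two-timepoint community
#'
#' @param taxa data.frame with columns \code{label}, \code{abundance} (t0),
#'   \code{fold} (t1/t0 change). Both the t0 abundances and the implied t1
#'   abundances (\code{abundance * fold}) must sum to 1.
#' @param genes data.frame with columns \code{label}, \code{family},
#'   \code{count}: how many genes of each GH family each taxon carries.
#'   Default: no genes.
#' @param contigLength target contig length range in nt
#' @return a [CommunitySpec]
#' @examples
#' sp <- communitySpec(
#'   taxa = data.frame(label = c("A", "B"),
#'                     abundance = c(0.8, 0.2),
#'                     fold = c(0.5, 3)),
#'   genes = data.frame(label = "A", family = "GH5", count = 2))
#' @export
communitySpec <- function(taxa, genes = NULL,
                          contigLength = c(1200, 3000)) {
  if (is.null(genes))
    genes <- data.frame(label = character(), family = character(),
                        count = integer())
  new("CommunitySpec", taxa = taxa, genes = genes,
      contigLength = as.numeric(contigLength))
}

#' Homopolymer indel error model
#'
#' Default per-run indel probability grows linearly with run length,
#' \code{0.002 * (runLength - 1)} capped at 0.05, mimicking the
#' run-length-dependent miscalls of pyrosequencing; the magnitude is a free
#' parameter of the simulator, not an empirical estimate.
#'
#' @param indelProb function(runLength) -> probability, or a single number
#'   applied to every run
#' @param subsProb per-base substitution probability (default 0)
#' @return an [ErrorModel]
#' @export
errorModel <- function(indelProb = NULL, subsProb = 0) {
  if (is.null(indelProb)) {
    indelProb <- function(runLength) pmin(0.002 * (runLength - 1), 0.05)
  } else if (is.numeric(indelProb)) {
    p <- indelProb
    indelProb <- function(runLength) rep(p, length(runLength))
  }
  new("ErrorModel", indelProb = indelProb, subsProb = subsProb)
}
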