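## S4 classes for the pipeline's central objects.

#' ProfileHMM: a single-domain profile hidden Markov model
#'
#' Container for one glycoside-hydrolase family domain model: per-match-state
#' emission probabilities over the 20 canonical residues, insert-state
#' emissions, node transition probabilities and background residue
#' frequencies. Emissions and transitions are stored as probabilities;
#' scoring converts to log-odds bits against the background.
#'
#' @slot name profile name (e.g. \code{"PF00150"})
#' @slot family GH family id the profile annotates (e.g. \code{"GH5"})
#' @slot matchEmis L x 20 matrix of match emission probabilities, rows = match
#'   states, columns in alphabetical one-letter residue order
#' @slot insEmis L x 20 matrix of insert emission probabilities
#' @slot trans L x 7 matrix of transition probabilities out of node k, columns
#'   \code{MM, MI, MD, IM, II, DM, DD}
#' @slot background length-20 background residue frequencies
#'
#' @seealso [profileHMM()], [viterbiLocal()], [readHMMER()]
#' @exportClass ProfileHMM
setClass("ProfileHMM",
  representation(name = "character", family = "character",
                 matchEmis = "matrix", insEmis = "matrix",
                 trans = "matrix", background = "numeric"))

setValidity("ProfileHMM", function(object) {
  L <- nrow(object@matchEmis)
  msg <- character()
  if (L < 1L) msg <- c(msg, "profile must have at least one match state")
  if (ncol(object@matchEmis) != 20L || ncol(object@insEmis) != 20L)
    msg <- c(msg, "emission matrices must have 20 columns")
  if (nrow(object@insEmis) != L || nrow(object@trans) != L)
    msg <- c(msg, "insEmis and trans must have one row per match state")
  if (ncol(object@trans) != 7L)
    msg <- c(msg, "trans must have 7 columns (MM,MI,MD,IM,II,DM,DD)")
  if (length(object@background) != 20L)
    msg <- c(msg, "background must have length 20")
  if (L >= 1L && ncol(object@matchEmis) == 20L) {
    if (any(abs(rowSums(object@matchEmis) - 1) > 1e-6))
      msg <- c(msg, "match emission rows must sum to 1")
    if (any(abs(rowSums(object@insEmis) - 1) > 1e-6))
      msg <- c(msg, "insert emission rows must sum to 1")
    if (any(object@matchEmis < 0) || any(object@insEmis < 0) ||
        any(object@trans < 0))
      msg <- c(msg, "probabilities must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' DepthContigSet: assembled contigs with read-depth sidecar
#'
#' A set of assembly contigs together with the number of reads that went into
#' each contig, the quantity the depth-weighting step turns into an
#' approximate fold-coverage (and hence population abundance) weight.
#'
#' @slot sequences a [Biostrings::DNAStringSet] of contig sequences
#' @slot nReads integer vector, reads per contig (>= 1), parallel to
#'   \code{sequences}
#'
#' @seealso [depthContigSet()], [contigWeight()], [scanContigs()]
#' @exportClass DepthContigSet
setClass("DepthContigSet",
  representation(sequences = "DNAStringSet", nReads = "integer"))

setValidity("DepthContigSet", function(object) {
  msg <- character()
  if (length(object@nReads) != length(object@sequences))
    msg <- c(msg, "nReads must be parallel to sequences")
  if (length(object@nReads) && any(object@nReads < 1L))
    msg <- c(msg, "nReads must be >= 1 for every contig")
  if (is.null(names(object@sequences)) ||
      anyDuplicated(names(object@sequences)))
    msg <- c(msg, "contigs must carry unique names")
  bad <- grepl("[^ACGTN]", as.character(object@sequences))
  if (any(bad))
    msg <- c(msg, "contig sequences must be over {A,C,G,T,N}")
  if (length(msg)) msg else TRUE
})

#' PhylotypeTable: per-sample counts of SSU rRNA phylotypes
#'
#' Count matrix with phylotypes as rows and samples as columns; the basis for
#' relative abundance profiles, Bray-Curtis dissimilarity and fold-enrichment
#' reports between composting timepoints.
#'
#' @slot counts integer matrix, phylotypes x samples, non-negative, with
#'   row and column names
#'
#' @seealso [phylotypeTable()], [relativeAbundance()], [brayCurtis()]
#' @exportClass PhylotypeTable
setClass("PhylotypeTable", representation(counts = "matrix"))

setValidity("PhylotypeTable", function(object) {
  m <- object@counts
  msg <- character()
  if (!is.numeric(m)) msg <- c(msg, "counts must be numeric")
  else {
    if (any(m < 0)) msg <- c(msg, "counts must be non-negative")
    if (any(m != floor(m))) msg <- c(msg, "counts must be integers")
  }
  if (is.null(rownames(m)) || is.null(colnames(m)))
    msg <- c(msg, "counts must have phylotype row names and sample column names")
  if (length(msg)) msg else TRUE
})

#' CommunitySpec: ground-truth description of a two-timepoint community
#'
#' Declares the taxa of a synthetic composting community, their relative
#' abundances at the initial timepoint, their fold changes to the final
#' timepoint, and the GH gene complement of each taxon. All synthetic inputs
#' (phylotype tables, contigs, read depths) are derived from this object so
#' that downstream recovery can be tested against known truth.
#'
#' @slot taxa data.frame with columns \code{label}, \code{abundance} (t0
#'   relative abundance), \code{fold} (t1/t0 fold change)
#' @slot genes data.frame with columns \code{label}, \code{family},
#'   \code{count}: GH gene complement per taxon
#' @slot contigLength length-2 numeric, target contig length range (nt)
#'
#' @seealso [communitySpec()], [buildContigSet()], [makePhylotypeTables()]
#' @exportClass CommunitySpec
setClass("CommunitySpec",
  representation(taxa = "data.frame", genes = "data.frame",
                 contigLength = "numeric"))

setValidity("CommunitySpec", function(object) {
  tx <- object@taxa
  msg <- character()
  need <- c("label", "abundance", "fold")
  if (!all(need %in% names(tx)))
    msg <- c(msg, "taxa needs columns label, abundance, fold")
  else {
    if (abs(sum(tx$abundance) - 1) > 1e-9)
      msg <- c(msg, "t0 abundances must sum to 1 (tolerance 1e-9)")
    if (abs(sum(tx$abundance * tx$fold) - 1) > 1e-9)
      msg <- c(msg, "t1 abundances (abundance * fold) must sum to 1 (tolerance 1e-9)")
    if (any(tx$fold <= 0)) msg <- c(msg, "fold changes must be > 0")
    if (anyDuplicated(tx$label)) msg <- c(msg, "taxon labels must be unique")
  }
  gn <- object@genes
  if (!all(c("label", "family", "count") %in% names(gn)))
    msg <- c(msg, "genes needs columns label, family, count")
  else {
    if (any(gn$count < 0)) msg <- c(msg, "gene counts must be >= 0")
    if (all(need %in% names(tx)) && !all(gn$label %in% tx$label))
      msg <- c(msg, "gene complement refers to unknown taxa")
  }
  if (length(object@contigLength) != 2L ||
      any(object@contigLength < 1) ||
      object@contigLength[1] > object@contigLength[2])
    msg <- c(msg, "contigLength must be an increasing length-2 range")
  if (length(msg)) msg else TRUE
})

#' ErrorModel: 454-style homopolymer indel error model
#'
#' Probability model for the single-base insertions/deletions that
#' pyrosequencing introduces inside homopolymer runs, plus an optional
#' per-base substitution rate.
#'
#' @slot indelProb function(runLength) -> per-run indel probability in [0,1]
#' @slot subsProb per-base substitution probability in [0,1]
#'
#' @seealso [errorModel()], [plantFrameshifts()]
#' @exportClass ErrorModel
setClass("ErrorModel",
  representation(indelProb = "function", subsProb = "numeric"))

setValidity("ErrorModel", function(object) {
  msg <- character()
  p <- object@subsProb
  if (length(p) != 1L || p < 0 || p > 1)
    msg <- c(msg, "subsProb must be a single probability in [0,1]")
  test <- vapply(2:12, object@indelProb, numeric(1))
  if (any(test < 0 | test > 1))
    msg <- c(msg, "indelProb must return probabilities in [0,1]")
  if (length(msg)) msg else TRUE
})

# the five functional-group headings of the weighted GH inventory
GH_GROUPS <- c("cellulases", "endohemicellulases", "cell wall elongation",
               "debranching", "oligosaccharide-degrading")

#' @noRd
.validateCatalog <- function(catalog) {
  need <- c("family", "profile", "group")
  if (!is.data.frame(catalog) || !all(need %in% names(catalog)))
    stop("catalog must be a data.frame with columns family, profile, group")
  bad <- setdiff(unique(catalog$group), GH_GROUPS)
  if (length(bad))
    stop("unknown functional group(s): ", paste(bad, collapse = ", "),
         "; expected one of: ", paste(GH_GROUPS, collapse = ", "))
  if (anyDuplicated(catalog$profile))
    stop("each profile may belong to only one family")
  invisible(catalog)
}
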