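## Generics and accessor/show methods.

#' Number of reads per contig
#' @param x a [DepthContigSet]
#' @return integer vector of read counts, one per contig
#' @export
setGeneric("nReads", function(x) standardGeneric("nReads"))

#' Contig sequences
#' @param x a [DepthContigSet]
#' @return a [Biostrings::DNAStringSet]
#' @export
setGeneric("contigSeqs", function(x) standardGeneric("contigSeqs"))

#' Number of match states of a profile HMM
#' @param x a [ProfileHMM]
#' @return integer scalar
#' @export
setGeneric("profileLength", function(x) standardGeneric("profileLength"))

#' GH family annotated by a profile
#' @param x a [ProfileHMM]
#' @return character scalar
#' @export
setGeneric("ghFamily", function(x) standardGeneric("ghFamily"))

#' @rdname nReads
#' @export
setMethod("nReads", "DepthContigSet", function(x) x@nReads)

#' @rdname contigSeqs
#' @export
setMethod("contigSeqs", "DepthContigSet", function(x) x@sequences)

#' @rdname profileLength
#' @export
setMethod("profileLength", "ProfileHMM", function(x) nrow(x@matchEmis))

#' @rdname ghFamily
#' @export
setMethod("ghFamily", "ProfileHMM", function(x) x@family)

#' @describeIn phylotypeTable phylotype x sample count matrix
#' @param object a [PhylotypeTable]
#' @export
setMethod("counts", "PhylotypeTable", function(object) object@counts)

#' @export
setMethod("names", "DepthContigSet", function(x) names(x@sequences))

#' @export
setMethod("length", "DepthContigSet", function(x) length(x@sequences))

#' @export
setMethod("[", "DepthContigSet", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, names(x@sequences))
  new("DepthContigSet", sequences = x@sequences[i], nReads = x@nReads[i])
})

setMethod("show", "DepthContigSet", function(object) {
  cat("DepthContigSet with", length(object), "contigs\n")
  w <- Biostrings::width(object@sequences)
  if (length(object)) {
    cat("  length: ", min(w), "-", max(w), " nt; total ", sum(w), " nt\n",
        sep = "")
    cat("  reads per contig: ", min(object@nReads), "-", max(object@nReads),
        "\n", sep = "")
  }
})

setMethod("show", "ProfileHMM", function(object) {
  cat("ProfileHMM ", object@name, " (family ", object@family, "), ",
      profileLength(object), " match states\n", sep = "")
})

setMethod("show", "PhylotypeTable", function(object) {
  m <- object@counts
  cat("PhylotypeTable:", nrow(m), "phylotypes x", ncol(m), "samples\n")
  cat("  samples:", paste(colnames(m), collapse = ", "), "\n")
  cat("  total counts:", paste(colSums(m), collapse = ", "), "\n")
})

setMethod("show", "CommunitySpec", function(object) {
  cat("CommunitySpec with", nrow(object@taxa), "taxa,",
      sum(object@genes$count), "planted GH genes\n")
})
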