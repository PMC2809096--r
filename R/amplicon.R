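## SSU rRNA amplicon preprocessing and two-timepoint community comparison.

#' Amplicon processing parameters
#'
#' @param barcodeLength barcode length in nt prefixed to each read
#'   (default 5)
#' @param minLength minimum retained read length in nt, measured after
#'   barcode trimming, boundary inclusive (default 220)
#' @param detectionThreshold detection floor tau as a proportion of total
#'   sample reads (default 0.0009, i.e. 0.09%)
#' @return a list of class \code{AmpliconParams}
#' @export
ampliconParams <- function(barcodeLength = 5, minLength = 220,
                           detectionThreshold = 0.0009) {
  stopifnot(barcodeLength >= 1, minLength >= 1,
            detectionThreshold > 0, detectionThreshold < 1)
  structure(list(barcodeLength = as.integer(barcodeLength),
                 minLength = as.integer(minLength),
                 detectionThreshold = detectionThreshold),
            class = "AmpliconParams")
}

#' Demultiplex barcoded amplicon reads
#'
#' A read is assigned to a sample iff its first \code{barcodeLength} bases
#' exactly match that sample's barcode; the barcode is trimmed from
#' assigned reads. Assigned plus unassigned reads partition the input.
#'
#' @param reads a [Biostrings::DNAStringSet]
#' @param barcodeMap data.frame with columns \code{barcode}, \code{sample}
#' @param params an [ampliconParams()] list
#' @return list with \code{samples} (named list of trimmed
#'   \code{DNAStringSet}s) and \code{unassigned}
#' @export
demultiplex <- function(reads, barcodeMap, params = ampliconParams()) {
  bc <- barcodeMap$barcode
  if (anyDuplicated(bc)) stop("duplicate barcodes in barcode map")
  if (any(nchar(bc) != params$barcodeLength))
    stop("all barcodes must have length ", params$barcodeLength)
  prefix <- as.character(subseq(reads, 1L,
                                pmin(width(reads), params$barcodeLength)))
  prefix[width(reads) < params$barcodeLength] <- NA
  idx <- match(prefix, bc)
  samples <- lapply(seq_len(nrow(barcodeMap)), function(i) {
    r <- reads[!is.na(idx) & idx == i]
    subseq(r, params$barcodeLength + 1L, width(r))
  })
  names(samples) <- barcodeMap$sample
  list(samples = samples, unassigned = reads[is.na(idx)])
}

#' Filter reads by length
#'
#' Retains reads with length >= \code{minLength} (inclusive boundary).
#'
#' @param reads a [Biostrings::DNAStringSet]
#' @param params an [ampliconParams()] list
#' @return the retained reads
#' @export
lengthFilter <- function(reads, params = ampliconParams()) {
  reads[width(reads) >= params$minLength]
}

#' Tally phylotype labels into a count table
#'
#' Exact-label tallying: each read's phylotype is taken from its name
#' (the token before the first whitespace or \code{;}). This replaces OTU
#' clustering for synthetic reads that carry their phylotype of origin; a
#' table from an external clustering tool can be substituted via
#' [phylotypeTable()].
#'
#' @param sampleReads named list, one [Biostrings::DNAStringSet] (or
#'   character vector of labels) per sample
#' @return a [PhylotypeTable]
#' @export
tallyPhylotypes <- function(sampleReads) {
  labs <- lapply(sampleReads, function(r) {
    x <- if (is.character(r)) r else names(r)
    if (is.null(x)) stop("reads must be named with phylotype labels")
    sub("[;[:space:]].*$", "", x)
  })
  phylotypes <- sort(unique(unlist(labs)))
  m <- vapply(labs, function(x) {
    as.integer(table(factor(x, levels = phylotypes)))
  }, integer(length(phylotypes)))
  dim(m) <- c(length(phylotypes), length(labs))
  dimnames(m) <- list(phylotypes, names(sampleReads))
  phylotypeTable(m)
}

#' Relative abundance profile of one sample
#'
#' @param table a [PhylotypeTable]
#' @param sample sample (column) name or index
#' @return named numeric vector of proportions summing to 1
#' @export
relativeAbundance <- function(table, sample) {
  stopifnot(is(table, "PhylotypeTable"))
  x <- counts(table)[, sample]
  tot <- sum(x)
  if (tot <= 0) stop("sample '", sample, "' has zero total counts")
  x / tot
}

#' Bray-Curtis dissimilarity between two abundance profiles
#'
#' BC(p, q) = sum |p_i - q_i| / sum (p_i + q_i) over the union of labels
#' (absent labels contribute 0). Symmetric; 0 iff identical; 1 iff the
#' supports are disjoint.
#'
#' @param p,q named numeric abundance vectors
#' @return dissimilarity in [0, 1]
#' @export
brayCurtis <- function(p, q) {
  labels <- union(names(p), names(q))
  if (is.null(labels)) {
    if (length(p) != length(q))
      stop("unnamed profiles must have equal length")
    pv <- p; qv <- q
  } else {
    pv <- setNames(numeric(length(labels)), labels)
    qv <- pv
    pv[names(p)] <- p
    qv[names(q)] <- q
  }
  denom <- sum(pv + qv)
  if (denom <= 0) stop("both profiles are all-zero")
  sum(abs(pv - qv)) / denom
}

#' Per-phylotype fold enrichment between timepoints
#'
#' For phylotypes at or above the detection floor tau at t0 the enrichment
#' is the exact ratio p_t1 / p_t0; below the floor only the lower bound
#' p_t1 / tau can be claimed, flagged with \code{lowerBound = TRUE} and a
#' \code{">="} prefix in the display label. Phylotypes absent at t1 are
#' reported as 0. Rows are ordered by t1 abundance (rank-abundance
#' overlay order).
#'
#' @param pT1,pT0 named abundance profiles (proportions) at the final and
#'   initial timepoint
#' @param params an [ampliconParams()] list supplying tau
#' @return data.frame: \code{phylotype}, \code{pT0}, \code{pT1},
#'   \code{fold}, \code{lowerBound}, \code{label}
#' @export
foldEnrichment <- function(pT1, pT0, params = ampliconParams()) {
  tau <- params$detectionThreshold
  labels <- union(names(pT1), names(pT0))
  p1 <- setNames(numeric(length(labels)), labels)
  p0 <- p1
  p1[names(pT1)] <- pT1
  p0[names(pT0)] <- pT0
  exact <- p0 >= tau
  fold <- ifelse(exact, p1 / p0, p1 / tau)
  fold[p1 == 0 & !exact] <- 0
  bound <- !exact & p1 > 0
  out <- data.frame(phylotype = labels, pT0 = unname(p0), pT1 = unname(p1),
                    fold = unname(fold), lowerBound = unname(bound),
                    label = paste0(ifelse(bound, ">=", ""),
                                   sprintf("%.1f", fold)),
                    stringsAsFactors = FALSE)
  out[order(-out$pT1), , drop = FALSE]
}
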