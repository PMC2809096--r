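## GH-family inventory: profile-HMM scanning of six-frame-translated
## contigs, best-hit resolution, read-depth weighting and Table-style
## functional-group aggregation.

#' Weighting and scanning parameters for the GH inventory
#'
#' @param medianReadLength median read length in nt used by the depth
#'   weighting (weight = nReads * medianReadLength / contigLength); default
#'   400
#' @param scoreThreshold minimum Viterbi bit score for a domain hit;
#'   default 25, deliberately conservative
#' @return a list of class \code{WeightingParams}
#' @export
weightingParams <- function(medianReadLength = 400, scoreThreshold = 25) {
  stopifnot(medianReadLength > 0)
  structure(list(medianReadLength = medianReadLength,
                 scoreThreshold = scoreThreshold),
            class = "WeightingParams")
}

#' Best local profile-HMM alignment of a peptide
#'
#' Single-hit local (Plan7-style) Viterbi: the alignment may enter at any
#' match state (uniform entry probability 1/L) and exit from any match
#' state (free exit). The score is the summed emission log-odds plus
#' transition log-probabilities in bits, maximised over paths. \code{X}
#' residues score 0 bits at any emitting state; alignments never cross a
#' \code{*} (stop). If no path scores above 0 bits the sentinel
#' \code{-Inf} is returned.
#'
#' @param profile a [ProfileHMM]
#' @param peptide character scalar over the 20 canonical residues plus
#'   \code{X} and \code{*}
#' @return list with \code{score} (bits), \code{begin}, \code{end}
#'   (1-based peptide span; \code{NA} when score is \code{-Inf})
#' @export
viterbiLocal <- function(profile, peptide) {
  stopifnot(is(profile, "ProfileHMM"))
  if (!nzchar(peptide))
    return(list(score = -Inf, begin = NA_integer_, end = NA_integer_))
  codes <- .aaCodes(peptide)
  bg <- profile@background
  mLO <- log2(sweep(profile@matchEmis, 2, bg, "/"))
  iLO <- log2(sweep(profile@insEmis, 2, bg, "/"))
  tr <- log2(profile@trans)
  res <- .viterbi_local_cpp(mLO, iLO, tr, codes)
  list(score = res$score, begin = res$begin, end = res$end)
}

#' Scan contigs for GH family domains
#'
#' For every contig x profile, takes the best single-hit local Viterbi
#' score over the six translation frames; hits are kept when the bit score
#' reaches \code{scoreThreshold}. For families represented by more than one
#' profile (2-domain families), only the best-scoring hit per
#' (contig, family) pair is retained, so a contig contributes at most once
#' per family.
#'
#' @param contigs a [DepthContigSet]
#' @param profiles named list of [ProfileHMM] objects
#' @param catalog family catalog data.frame with columns \code{family},
#'   \code{profile}, \code{group} (see [makeDemoCatalog()])
#' @param params a [weightingParams()] list
#' @return data.frame of domain hits: \code{contig}, \code{family},
#'   \code{profile}, \code{frame}, \code{score} (bits), \code{pepBegin},
#'   \code{pepEnd} (1-based span in the frame translation), \code{ntBegin},
#'   \code{ntEnd} (1-based closed span on the forward strand)
#' @export
scanContigs <- function(contigs, profiles, catalog,
                        params = weightingParams()) {
  .validateCatalog(catalog)
  if (!length(profiles)) stop("catalog/profile list is empty")
  famOf <- setNames(catalog$family, catalog$profile)
  missing <- setdiff(names(profiles), names(famOf))
  if (length(missing))
    stop("profiles absent from catalog: ", paste(missing, collapse = ", "))
  seqs <- contigSeqs(contigs)
  hits <- vector("list", length(seqs))
  bgCache <- lapply(profiles, function(pr) {
    bg <- pr@background
    list(mLO = log2(sweep(pr@matchEmis, 2, bg, "/")),
         iLO = log2(sweep(pr@insEmis, 2, bg, "/")),
         tr = log2(pr@trans))
  })
  for (ci in seq_along(seqs)) {
    frames <- sixFrameTranslate(seqs[[ci]])
    codes <- lapply(frames, function(p)
      if (nzchar(p)) .aaCodes(p) else integer())
    rows <- list()
    for (pn in names(profiles)) {
      pc <- bgCache[[pn]]
      bestScore <- -Inf; bestFrame <- NA; bestSpan <- c(NA, NA)
      for (fr in names(frames)) {
        if (!length(codes[[fr]])) next
        res <- .viterbi_local_cpp(pc$mLO, pc$iLO, pc$tr, codes[[fr]])
        if (res$score > bestScore) {
          bestScore <- res$score
          bestFrame <- fr
          bestSpan <- c(res$begin, res$end)
        }
      }
      if (is.finite(bestScore) && bestScore >= params$scoreThreshold) {
        nt <- .pepSpanToNt(bestSpan[1], bestSpan[2], bestFrame,
                           length(seqs[[ci]]))
        rows[[length(rows) + 1L]] <- data.frame(
          contig = names(seqs)[ci], family = unname(famOf[pn]),
          profile = pn, frame = bestFrame, score = bestScore,
          pepBegin = bestSpan[1], pepEnd = bestSpan[2],
          ntBegin = nt[1], ntEnd = nt[2], stringsAsFactors = FALSE)
      }
    }
    if (length(rows)) {
      df <- do.call(rbind, rows)
      # best-hit rule: one hit per (contig, family)
      df <- df[order(-df$score), , drop = FALSE]
      df <- df[!duplicated(df$family), , drop = FALSE]
      hits[[ci]] <- df
    }
  }
  hits <- hits[!vapply(hits, is.null, logical(1))]
  if (!length(hits))
    return(data.frame(contig = character(), family = character(),
                      profile = character(), frame = character(),
                      score = numeric(), pepBegin = integer(),
                      pepEnd = integer(), ntBegin = integer(),
                      ntEnd = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}

# peptide span within a frame translation -> forward-strand nt span
#' @noRd
.pepSpanToNt <- function(aaBegin, aaEnd, frame, contigLen) {
  off <- as.integer(substr(frame, 2, 2)) - 1L
  ntB <- off + 3L * (aaBegin - 1L) + 1L
  ntE <- off + 3L * aaEnd
  if (startsWith(frame, "+")) c(ntB, ntE)
  else c(contigLen - ntE + 1L, contigLen - ntB + 1L)
}

#' Approximate fold-coverage weight of a contig
#'
#' weight = nReads x medianReadLength / contigLength. Dominant populations
#' assemble into deeper contigs and therefore contribute proportionally
#' more to the weighted inventory.
#'
#' @param contigs a [DepthContigSet]
#' @param params a [weightingParams()] list
#' @return numeric vector of weights, named by contig
#' @export
contigWeight <- function(contigs, params = weightingParams()) {
  len <- width(contigSeqs(contigs))
  if (any(len == 0)) stop("zero-length contig")
  w <- nReads(contigs) * params$medianReadLength / len
  setNames(w, names(contigs))
}

#' Depth-weighted GH family inventory
#'
#' Aggregates domain hits into the weighted family inventory: each family's
#' weight is the summed fold-coverage weight of the contigs it hits (one
#' count per contig-family pair), expressed as a percentage of the total GH
#' weight, then summed into the five functional groups.
#'
#' @param hits data.frame from [scanContigs()]
#' @param contigs the scanned [DepthContigSet]
#' @param catalog family catalog data.frame (columns \code{family},
#'   \code{profile}, \code{group}); families without hits are reported at 0
#' @param params a [weightingParams()] list
#' @return data.frame with one row per catalog family: \code{family},
#'   \code{group}, \code{weight}, \code{percent}; attribute
#'   \code{"groupTotals"} holds the per-group percentage totals
#' @export
inventoryTable <- function(hits, contigs, catalog,
                           params = weightingParams()) {
  .validateCatalog(catalog)
  if (!nrow(hits)) stop("no domain hits: nothing to inventory")
  if (!all(hits$contig %in% names(contigs)))
    stop("hits refer to contigs absent from the contig set")
  w <- contigWeight(contigs, params)
  key <- !duplicated(hits[c("contig", "family")])
  hu <- hits[key, , drop = FALSE]
  famW <- tapply(w[hu$contig], hu$family, sum)
  fams <- unique(catalog[c("family", "group")])
  out <- data.frame(family = fams$family, group = fams$group,
                    weight = as.numeric(famW[fams$family]),
                    stringsAsFactors = FALSE)
  out$weight[is.na(out$weight)] <- 0
  out$percent <- 100 * out$weight / sum(out$weight)
  attr(out, "groupTotals") <- groupTotals(
    setNames(out$percent, out$family), catalog)
  out
}

#' Functional-group totals of per-family percentages
#'
#' Sums per-family inventory percentages into the five functional groups
#' (cellulases, endohemicellulases, cell wall elongation, debranching,
#' oligosaccharide-degrading).
#'
#' @param familyPercents named numeric vector (names = family ids) of
#'   per-family percentages
#' @param catalog family catalog data.frame mapping family to group
#' @return data.frame with columns \code{group}, \code{total}
#' @export
groupTotals <- function(familyPercents, catalog) {
  .validateCatalog(catalog)
  fams <- unique(catalog[c("family", "group")])
  grp <- setNames(fams$group, fams$family)
  known <- names(familyPercents) %in% names(grp)
  if (!all(known))
    stop("families absent from catalog: ",
         paste(names(familyPercents)[!known], collapse = ", "))
  tot <- tapply(familyPercents, grp[names(familyPercents)], sum)
  total <- as.numeric(tot[GH_GROUPS])
  total[is.na(total)] <- 0
  data.frame(group = GH_GROUPS, total = total, stringsAsFactors = FALSE)
}

#' Percentage of predicted genes carrying a GH domain
#'
#' Unweighted gene-level fraction: the percentage of called genes whose
#' span overlaps a domain hit on the same contig.
#'
#' @param hits data.frame from [scanContigs()] (needs \code{contig},
#'   \code{ntBegin}, \code{ntEnd})
#' @param genes a [GenomicRanges::GRanges] of predicted genes from
#'   [callGenes()], seqnames = contig ids
#' @return percentage in [0, 100]
#' @export
ghFractionOfGenes <- function(hits, genes) {
  if (!length(genes)) stop("no predicted genes")
  if (!nrow(hits)) return(0)
  hitGR <- GRanges(hits$contig, IRanges(hits$ntBegin, hits$ntEnd))
  ov <- findOverlaps(genes, hitGR, ignore.strand = TRUE)
  100 * length(unique(S4Vectors::queryHits(ov))) / length(genes)
}
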