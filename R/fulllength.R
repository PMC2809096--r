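## Recovery of candidate full-length lignocellulolytic genes from contigs:
## translated local search against an EC-annotated reference enzyme set,
## coverage/E-value/EC filtering, homopolymer frameshift detection and
## single-base correction, ORF calling and truncation assessment.

#' Parameters for full-length enzyme recovery
#'
#' Karlin-Altschul defaults are the standard published BLOSUM62 constants;
#' gap penalties follow the common BLASTX defaults (open 11, extend 1).
#'
#' @param eMax maximum E-value of the best HSP (default 1e-10)
#' @param minTargetCoverage minimum fraction of the reference covered by
#'   the union of chained HSP reference spans (default 0.90)
#' @param minContigLength minimum contig length searched (default 1000 nt)
#' @param gapOpen,gapExtend affine gap penalties (a gap of length g costs
#'   gapOpen + g * gapExtend)
#' @param lambda,K Karlin-Altschul parameters for bit score and E-value
#' @param editPad half-width W of the edit search window around a frameshift
#'   boundary, in nt (default 12)
#' @param maxIterations maximum correction iterations (default 10)
#' @param minHspBits minimum HSP bit score retained by the search
#'   (default 15; keeps partial-gene HSPs while dropping noise)
#' @param minSegmentAA minimum stop-free segment length searched (aa)
#' @param frameshiftPenalty raw-score cost of positing one frameshift
#'   when chaining split HSPs during correction (default 25): large
#'   enough that rejoining fragments strictly improves the objective,
#'   small enough that a genuine distant frameshift is never cheaper to
#'   "bridge" through garbled codons than to correct
#' @return a list of class \code{RecoveryParams}
#' @export
recoveryParams <- function(eMax = 1e-10, minTargetCoverage = 0.90,
                           minContigLength = 1000,
                           gapOpen = 11, gapExtend = 1,
                           lambda = 0.3176, K = 0.134,
                           editPad = 12, maxIterations = 10,
                           minHspBits = 15, minSegmentAA = 8,
                           frameshiftPenalty = 25) {
  stopifnot(eMax > 0, minTargetCoverage > 0, minTargetCoverage <= 1)
  structure(list(eMax = eMax, minTargetCoverage = minTargetCoverage,
                 minContigLength = minContigLength,
                 gapOpen = gapOpen, gapExtend = gapExtend,
                 lambda = lambda, K = K, editPad = as.integer(editPad),
                 maxIterations = as.integer(maxIterations),
                 minHspBits = minHspBits,
                 minSegmentAA = as.integer(minSegmentAA),
                 frameshiftPenalty = frameshiftPenalty),
            class = "RecoveryParams")
}

# BLOSUM62 extended with X (scores from the standard matrix) in the
# package's residue-code order (AA20, then X)
#' @noRd
.substMatrix <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      data("BLOSUM62", package = "Biostrings", envir = environment())
      B <- get("BLOSUM62", envir = environment())
      ord <- c(AA20, "X")
      m <<- B[ord, ord]
    }
    m
  }
})

#' @noRd
.bitScore <- function(raw, params) {
  (params$lambda * raw - log(params$K)) / log(2)
}

#' @noRd
.eValue <- function(bits, m, n) m * n * 2^(-bits)

# stop-free segments (1-based aa coordinates) of a frame translation
#' @noRd
.stopFreeSegments <- function(pep) {
  ch <- strsplit(pep, "")[[1]]
  stops <- c(0L, which(ch == "*"), length(ch) + 1L)
  segs <- data.frame(begin = head(stops, -1) + 1L, end = stops[-1] - 1L)
  segs[segs$end >= segs$begin, , drop = FALSE]
}

# core translated search of one DNA sequence against one reference peptide;
# returns HSPs over all six frames (or the three frames of one strand)
#' @noRd
.searchOneRef <- function(dnaChar, refPep, params, strands = c("+", "-")) {
  dna <- Biostrings::DNAString(dnaChar)
  frames <- sixFrameTranslate(dna)
  use <- substr(names(frames), 1, 1) %in% strands
  frames <- frames[use]
  rCodes <- .aaCodes(refPep)
  subst <- .substMatrix()
  n <- sum(nchar(frames))
  m <- nchar(refPep)
  rows <- list()
  for (fr in names(frames)) {
    pep <- frames[[fr]]
    if (!nzchar(pep)) next
    segs <- .stopFreeSegments(pep)
    segs <- segs[segs$end - segs$begin + 1L >= params$minSegmentAA, ,
                 drop = FALSE]
    pepCodes <- .aaCodes(pep)
    for (si in seq_len(nrow(segs))) {
      sb <- segs$begin[si]; se <- segs$end[si]
      res <- .sw_local_cpp(pepCodes[sb:se], rCodes, subst,
                           params$gapOpen, params$gapExtend)
      if (res$score <= 0) next
      bits <- .bitScore(res$score, params)
      if (bits < params$minHspBits) next
      aaB <- sb + res$qBegin - 1L
      aaE <- sb + res$qEnd - 1L
      nt <- .pepSpanToNt(aaB, aaE, fr, length(dna))
      rows[[length(rows) + 1L]] <- data.frame(
        frame = fr, strand = substr(fr, 1, 1),
        ntBegin = nt[1], ntEnd = nt[2],
        refBegin = res$rBegin, refEnd = res$rEnd,
        score = res$score, bits = bits,
        evalue = .eValue(bits, m, n), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(frame = character(), strand = character(),
                      ntBegin = integer(), ntEnd = integer(),
                      refBegin = integer(), refEnd = integer(),
                      score = numeric(), bits = numeric(),
                      evalue = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Translated local search of contigs against reference enzymes
#'
#' For each contig of at least \code{minContigLength} nt, aligns every
#' stop-free segment of all six frame translations against each reference
#' peptide with affine-gap Smith-Waterman (BLOSUM62), reporting HSPs with
#' bit score \eqn{S' = (\lambda S - \ln K) / \ln 2} and E-value
#' \eqn{E = m n 2^{-S'}}, where m is the reference length and n the total
#' translated length searched.
#'
#' @param contigs a [DepthContigSet] or named \code{DNAStringSet}
#' @param refs reference data.frame with columns \code{id}, \code{peptide},
#'   \code{ec} (may be \code{NA}), \code{family} (see
#'   [readEnzymeReferences()])
#' @param params a [recoveryParams()] list
#' @return data.frame of HSPs: \code{contig}, \code{ref}, \code{frame},
#'   \code{strand}, \code{ntBegin}, \code{ntEnd} (1-based closed, forward
#'   strand), \code{refBegin}, \code{refEnd} (aa), \code{score} (raw),
#'   \code{bits}, \code{evalue}. Contigs shorter than
#'   \code{minContigLength} are skipped with a message.
#' @export
translatedSearch <- function(contigs, refs, params = recoveryParams()) {
  if (!nrow(refs)) stop("empty reference set")
  seqs <- if (is(contigs, "DepthContigSet")) contigSeqs(contigs) else contigs
  lens <- width(seqs)
  short <- lens < params$minContigLength
  if (any(short))
    message(sum(short), " contig(s) below ", params$minContigLength,
            " nt skipped")
  seqs <- seqs[!short]
  out <- list()
  for (ci in seq_along(seqs)) {
    dnaChar <- as.character(seqs[[ci]])
    for (ri in seq_len(nrow(refs))) {
      hs <- .searchOneRef(dnaChar, refs$peptide[ri], params)
      if (nrow(hs)) {
        hs$contig <- names(seqs)[ci]
        hs$ref <- refs$id[ri]
        out[[length(out) + 1L]] <- hs
      }
    }
  }
  if (!length(out))
    return(data.frame(contig = character(), ref = character(),
                      frame = character(), strand = character(),
                      ntBegin = integer(), ntEnd = integer(),
                      refBegin = integer(), refEnd = integer(),
                      score = numeric(), bits = numeric(),
                      evalue = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[c("contig", "ref", "frame", "strand", "ntBegin", "ntEnd",
        "refBegin", "refEnd", "score", "bits", "evalue")]
}

#' Filter (contig, reference) pairs to full-length candidates
#'
#' A pair passes iff (i) the union of its HSP reference spans covers at
#' least \code{minTargetCoverage} of the reference length, (ii) its best
#' HSP has E-value at most \code{eMax}, and (iii) the reference has a known
#' enzymatic function (an EC number).
#'
#' @param hsps data.frame from [translatedSearch()]
#' @param refs reference data.frame (columns \code{id}, \code{peptide},
#'   \code{ec})
#' @param params a [recoveryParams()] list
#' @return data.frame with one row per passing pair: \code{contig},
#'   \code{ref}, \code{coverage}, \code{bestEvalue}, \code{nHsp},
#'   \code{strand}
#' @export
candidateFilter <- function(hsps, refs, params = recoveryParams()) {
  if (!nrow(hsps))
    return(data.frame(contig = character(), ref = character(),
                      coverage = numeric(), bestEvalue = numeric(),
                      nHsp = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  refLen <- setNames(nchar(refs$peptide), refs$id)
  refEC <- setNames(refs$ec, refs$id)
  keyed <- split(hsps, paste(hsps$contig, hsps$ref, sep = "\r"))
  rows <- lapply(keyed, function(h) {
    cov <- sum(width(reduce(IRanges(h$refBegin, h$refEnd)))) /
      refLen[[h$ref[1]]]
    data.frame(contig = h$contig[1], ref = h$ref[1], coverage = cov,
               bestEvalue = min(h$evalue), nHsp = nrow(h),
               strand = if (length(unique(h$strand)) == 1L) h$strand[1]
                        else "both",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  ecOK <- !is.na(refEC[out$ref]) & nzchar(refEC[out$ref])
  out[out$coverage >= params$minTargetCoverage &
      out$bestEvalue <= params$eMax & ecOK, , drop = FALSE]
}

#' Delineate candidate frameshift boundaries
#'
#' Orders the HSPs of one (contig, reference) pair along the reference;
#' every junction between consecutive HSPs whose frames differ (same
#' strand) yields a boundary: the contig interval between the two HSP
#' spans, padded by +/- \code{editPad} nt.
#'
#' @param hsps HSPs of a single (contig, reference) pair
#' @param params a [recoveryParams()] list
#' @return data.frame with columns \code{begin}, \code{end} (1-based
#'   closed contig interval), \code{frameLeft}, \code{frameRight}; zero
#'   rows when no frameshift is indicated
#' @export
detectFrameshiftCandidates <- function(hsps, params = recoveryParams()) {
  if (!nrow(hsps)) stop("at least one HSP required")
  if (length(unique(hsps$strand)) > 1L)
    stop("HSPs on both strands: chimeric candidate, not corrected")
  h <- hsps[order(hsps$refBegin, hsps$refEnd), , drop = FALSE]
  out <- list()
  if (nrow(h) > 1L) {
    for (i in seq_len(nrow(h) - 1L)) {
      if (h$frame[i] == h$frame[i + 1L]) next
      lo <- min(h$ntEnd[i], h$ntBegin[i + 1L], h$ntEnd[i + 1L],
                h$ntBegin[i])
      hi <- max(h$ntEnd[i], h$ntBegin[i + 1L])
      # interval between the two spans (they may abut or slightly overlap)
      gapLo <- min(h$ntEnd[i], h$ntBegin[i + 1L])
      gapHi <- max(h$ntEnd[i], h$ntBegin[i + 1L])
      out[[length(out) + 1L]] <- data.frame(
        begin = gapLo - params$editPad, end = gapHi + params$editPad,
        frameLeft = h$frame[i], frameRight = h$frame[i + 1L],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(begin = integer(), end = integer(),
                      frameLeft = character(), frameRight = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# translated-alignment objective used during correction: the best chain
# of stop-free-segment HSPs (three frames of one strand) ordered along
# the reference, with overlapped reference residues penalised at an
# upper-bound per-residue rate. A naive sum over split HSPs would
# double-count overlaps and can rank a frameshifted gene above its
# restored form; a single-alignment maximum would let one opposite-sign
# edit "bridge" two nearby same-sign indels into a lossy full-length
# alignment. The chained score increases exactly when a correction
# genuinely rejoins fragments.
#' @noRd
.chainScore <- function(dnaChar, refPep, params, strand = "+") {
  if (strand == "-")
    dnaChar <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(dnaChar)))
  .translated_chain_score_cpp(dnaChar, .aaCodes(refPep), .substMatrix(),
                              params$gapOpen, params$gapExtend,
                              params$minSegmentAA, .codonCodes(),
                              12, params$frameshiftPenalty,
                              .CHAIN_FLOOR)
}

# minimum raw score for an HSP to join the correction chain; weak
# spurious segment alignments below this would feed the greedy search an
# endless trickle of sub-junction "improvements"
.CHAIN_FLOOR <- 40

# codon index (16a + 4b + c over A<C<G<T) -> residue code map
#' @noRd
.codonCodes <- local({
  v <- NULL
  function() {
    if (is.null(v)) {
      bases <- c("A", "C", "G", "T")
      cods <- paste0(rep(bases, each = 16),
                     rep(rep(bases, each = 4), 4),
                     rep(bases, 16))
      aa <- as.character(Biostrings::GENETIC_CODE[cods])
      code <- match(aa, AA20) - 1L
      code[aa == "*"] <- 21L
      v <<- code
    }
    v
  }
})

#' Correct homopolymer frameshifts against a reference enzyme
#'
#' Iterative greedy ascent: frameshift boundaries are delineated from the
#' current HSP set; within each boundary window every single-base deletion
#' and every single-base duplication is evaluated, and the edit giving the
#' largest strict improvement of the translated-alignment score is applied.
#' Boundaries are re-detected and the process repeats until no boundary
#' remains, no edit improves the score, or \code{maxIterations} is reached.
#' Equal-scoring edits prefer the longer homopolymer run, then the leftmost
#' position (the pyrosequencing error mechanism lives in long runs).
#' Accepted edits never decrease the score, and the procedure is idempotent
#' on corrected input.
#'
#' @param contig a [Biostrings::DNAString] or character scalar
#' @param refPep reference peptide (character)
#' @param params a [recoveryParams()] list
#' @return list with \code{sequence} (corrected contig, character),
#'   \code{edits} (data.frame: \code{position}, 1-based in the working
#'   sequence the edit was applied to; \code{positionInput}, the same
#'   site in the coordinates of the uncorrected input (gene-strand
#'   orientation); \code{positionForward}, that site on the input's
#'   forward strand; \code{kind} (\code{"delete"} or \code{"duplicate"});
#'   \code{base}; \code{runLength} (homopolymer run length at the site);
#'   \code{scoreBefore}; \code{scoreAfter}), and \code{score} (final
#'   translated-alignment raw score)
#' @export
correctFrameshifts <- function(contig, refPep, params = recoveryParams()) {
  seqChar <- as.character(.asDNAString(contig))
  # establish strand from an initial search
  h0 <- .searchOneRef(seqChar, refPep, params)
  if (!nrow(h0))
    return(list(sequence = seqChar,
                edits = .emptyEdits(), score = 0))
  strands <- unique(h0$strand)
  if (length(strands) > 1L) {
    # restrict to the strand carrying the best HSP; both-strand pairs with
    # comparable evidence are chimeric and rejected upstream
    strands <- h0$strand[which.max(h0$score)]
    h0 <- h0[h0$strand == strands, , drop = FALSE]
  }
  minus <- strands == "-"
  work <- if (minus)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(seqChar)))
  else seqChar
  res <- .correctForward(work, refPep, params)
  if (minus) {
    res$sequence <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(res$sequence)))
    if (nrow(res$edits)) {
      res$edits$positionForward <- nchar(seqChar) -
        res$edits$positionInput + 1L
      res$edits$strand <- "-"
    }
  } else if (nrow(res$edits)) {
    res$edits$positionForward <- res$edits$positionInput
    res$edits$strand <- "+"
  }
  res
}

#' @noRd
.emptyEdits <- function() {
  data.frame(position = integer(), positionInput = integer(),
             kind = character(), base = character(),
             runLength = integer(), scoreBefore = numeric(),
             scoreAfter = numeric(), lenBefore = integer(),
             stringsAsFactors = FALSE)
}

# greedy correction with the gene on the forward strand of `work`.
# The search is confined to the region spanned by the initial HSPs plus
# a margin; flanking sequence cannot contain correctable evidence and
# rescoring it for every candidate edit would dominate the runtime.
#' @noRd
.correctForward <- function(work, refPep, params) {
  full <- work
  h0 <- .searchOneRef(full, refPep, params, strands = "+")
  # only HSPs strong enough to join the scoring chain can define the
  # search region or a productive boundary; sub-floor HSPs cannot move
  # the objective, so edits in their windows never improve
  h0 <- h0[h0$score >= .CHAIN_FLOOR, , drop = FALSE]
  lo0 <- 1L; hi0 <- nchar(full)
  if (nrow(h0)) {
    lo0 <- max(1L, min(h0$ntBegin) - 150L)
    hi0 <- min(nchar(full), max(h0$ntEnd) + 150L)
  }
  prefix <- substr(full, 1L, lo0 - 1L)
  suffix <- substr(full, hi0 + 1L, nchar(full))
  work <- substr(full, lo0, hi0)

  edits <- .emptyEdits()
  seen <- new.env(parent = emptyenv())
  assign(work, TRUE, envir = seen)
  # map from current working coordinates back to input coordinates
  # (point indels shift everything downstream; a duplicated base keeps
  # its template's input coordinate)
  idxMap <- seq.int(lo0, hi0)
  refCodes <- .aaCodes(refPep)
  subst <- .substMatrix()
  codonCodes <- .codonCodes()
  score <- .chainScore(work, refPep, params, "+")
  for (iter in seq_len(params$maxIterations)) {
    h <- .searchOneRef(work, refPep, params, strands = "+")
    h <- h[h$score >= .CHAIN_FLOOR, , drop = FALSE]
    if (!nrow(h)) break
    h$contig <- "w"; h$ref <- "r"
    bounds <- detectFrameshiftCandidates(h, params)
    if (!nrow(bounds)) break
    n <- nchar(work)
    # merge overlapping boundary windows, evaluate every candidate edit
    # in each, and apply the globally best strictly-improving edit. The
    # chained objective already makes "bridging" two nearby same-sign
    # indels with one wrong-sign edit unprofitable, so the largest gain
    # is the correct greedy choice; preferring small first-window gains
    # instead can churn through the iteration budget.
    wins <- IRanges(pmax(1L, bounds$begin), pmin(n, bounds$end))
    wins <- reduce(wins)
    bestEdit <- NULL
    bestGain <- 0
    for (bi in seq_along(wins)) {
      r <- .best_edit_cpp(work, start(wins)[bi], end(wins)[bi], score,
                          refCodes, subst, params$gapOpen,
                          params$gapExtend, params$minSegmentAA,
                          codonCodes, 12, params$frameshiftPenalty,
                          .CHAIN_FLOOR)
      better <- r[1] > bestGain + 1e-9
      tie <- r[1] > 1e-9 && !is.null(bestEdit) &&
        abs(r[1] - bestGain) <= 1e-9 &&
        (r[4] > bestEdit$runLength ||
         (r[4] == bestEdit$runLength && r[2] < bestEdit$position))
      if (better || tie) {
        pos <- as.integer(r[2])
        bestGain <- r[1]
        bestEdit <- list(position = pos,
                         kind = c("delete", "duplicate")[r[3]],
                         base = substr(work, pos, pos),
                         runLength = as.integer(r[4]),
                         scoreAfter = r[5])
      }
    }
    if (is.null(bestEdit)) break
    bestEdit$sequence <- .applyEdit(work, bestEdit$position,
                                    bestEdit$kind)
    if (exists(bestEdit$sequence, envir = seen)) {
      warning("oscillating edit search; stopping correction")
      break
    }
    edits <- rbind(edits, data.frame(
      position = bestEdit$position,
      positionInput = idxMap[bestEdit$position], kind = bestEdit$kind,
      base = bestEdit$base, runLength = bestEdit$runLength,
      scoreBefore = score, scoreAfter = bestEdit$scoreAfter,
      lenBefore = nchar(work), stringsAsFactors = FALSE))
    idxMap <- if (bestEdit$kind == "delete") idxMap[-bestEdit$position]
      else append(idxMap, idxMap[bestEdit$position],
                  after = bestEdit$position)
    work <- bestEdit$sequence
    assign(work, TRUE, envir = seen)
    score <- bestEdit$scoreAfter
  }
  list(sequence = paste0(prefix, work, suffix), edits = edits,
       score = score)
}

#' @noRd
.applyEdit <- function(seqChar, pos, kind) {
  if (kind == "delete")
    paste0(substr(seqChar, 1, pos - 1),
           substr(seqChar, pos + 1, nchar(seqChar)))
  else
    paste0(substr(seqChar, 1, pos), substr(seqChar, pos, nchar(seqChar)))
}

#' Call genes on a (corrected) contig with a simple ORF caller
#'
#' Per frame (both strands), maximal stop-free intervals of at least
#' \code{minOrfLength} nt are located; the gene starts at the most
#' upstream ATG/GTG/TTG start codon in the interval and extends through
#' the terminating stop codon (when one follows the interval). Coordinates
#' are reported 1-based closed on the forward strand with a strand flag.
#' This is a deliberate lightweight substitute for a trained gene model;
#' output is flagged with \code{caller = "orf-caller"}.
#'
#' @param contig [Biostrings::DNAString] or character
#' @param contigName seqname used in the returned ranges
#' @param minOrfLength minimum stop-free interval length in nt
#'   (default 300)
#' @return a [GenomicRanges::GRanges] with metadata columns \code{frame},
#'   \code{peptide} (translation from start to last codon before the
#'   stop), \code{caller}
#' @export
callGenes <- function(contig, contigName = "contig", minOrfLength = 300) {
  dna <- .asDNAString(contig)
  n <- length(dna)
  frames <- sixFrameTranslate(dna)
  startCodons <- c("ATG", "GTG", "TTG")
  res <- list()
  for (fr in names(frames)) {
    pep <- frames[[fr]]
    if (!nzchar(pep)) next
    off <- as.integer(substr(fr, 2, 2)) - 1L
    segs <- .stopFreeSegments(pep)
    if (!nrow(segs)) next
    segs <- segs[3L * (segs$end - segs$begin + 1L) >= minOrfLength, ,
                 drop = FALSE]
    src <- if (startsWith(fr, "+")) dna else Biostrings::reverseComplement(dna)
    srcChar <- as.character(src)
    for (si in seq_len(nrow(segs))) {
      aaIdx <- segs$begin[si]:segs$end[si]
      ntStarts <- off + 3L * (aaIdx - 1L) + 1L
      cods <- substring(srcChar, ntStarts, ntStarts + 2L)
      hit <- which(cods %in% startCodons)
      if (!length(hit)) next
      aaStart <- aaIdx[hit[1]]
      ntB <- off + 3L * (aaStart - 1L) + 1L
      ntE <- off + 3L * segs$end[si]
      hasStop <- ntE + 3L <= length(src) &&
        substr(as.character(frames[[fr]]), segs$end[si] + 1L,
               segs$end[si] + 1L) == "*"
      if (hasStop) ntE <- ntE + 3L
      pepGene <- substr(pep, aaStart, segs$end[si])
      if (startsWith(fr, "+")) {
        b <- ntB; e <- ntE; strandCh <- "+"
      } else {
        b <- n - ntE + 1L; e <- n - ntB + 1L; strandCh <- "-"
      }
      res[[length(res) + 1L]] <- data.frame(
        begin = b, end = e, strand = strandCh, frame = fr,
        peptide = pepGene, stringsAsFactors = FALSE)
    }
  }
  if (!length(res))
    return(GRanges(seqnames = character(), ranges = IRanges(),
                   strand = character(),
                   frame = character(), peptide = character(),
                   caller = character()))
  df <- do.call(rbind, res)
  gr <- GRanges(seqnames = contigName, ranges = IRanges(df$begin, df$end),
                strand = df$strand)
  mcols(gr)$frame <- df$frame
  mcols(gr)$peptide <- df$peptide
  mcols(gr)$caller <- "orf-caller"
  gr
}

#' Assess potential N/C-terminal truncation at contig edges
#'
#' When a candidate's alignment to its reference leaves reference residues
#' uncovered at an end AND the alignment abuts the contig end (within
#' \code{edgeSlack} nt), the uncovered residues are reported as a
#' potential truncation caused by the end of the contig. If ample contig
#' remains beyond the alignment the shortfall is a genuine end, not a
#' truncation, and 0 is reported.
#'
#' @param hsps HSPs of the candidate (one contig-reference pair, one
#'   strand)
#' @param refLen reference peptide length (aa)
#' @param contigLen contig length (nt)
#' @param edgeSlack max distance in nt between alignment end and contig
#'   end to attribute the shortfall to the contig edge (default 3)
#' @return list with \code{nTruncation} and \code{cTruncation} (aa)
#' @export
truncationAssessment <- function(hsps, refLen, contigLen, edgeSlack = 3) {
  stopifnot(nrow(hsps) >= 1)
  refCovB <- min(hsps$refBegin)
  refCovE <- max(hsps$refEnd)
  ntLo <- min(hsps$ntBegin)
  ntHi <- max(hsps$ntEnd)
  minus <- hsps$strand[1] == "-"
  # contig edge adjacent to the reference N-terminus
  nEdgeGap <- if (minus) contigLen - ntHi else ntLo - 1L
  cEdgeGap <- if (minus) ntLo - 1L else contigLen - ntHi
  nTrunc <- if (refCovB > 1L && nEdgeGap <= edgeSlack) refCovB - 1L else 0L
  cTrunc <- if (refCovE < refLen && cEdgeGap <= edgeSlack)
    refLen - refCovE else 0L
  list(nTruncation = nTrunc, cTruncation = cTrunc)
}

#' Recover candidate full-length enzymes from contigs
#'
#' End-to-end wrapper: translated search of all sufficiently long contigs
#' against the EC-annotated reference set, candidate filtering
#' (coverage >= 90%, E <= eMax, EC present), frameshift correction against
#' the single best reference per contig, ORF calling on the corrected
#' contig, and truncation assessment.
#'
#' @param contigs a [DepthContigSet] or named \code{DNAStringSet}
#' @param refs reference data.frame (\code{id}, \code{peptide}, \code{ec},
#'   \code{family})
#' @param params a [recoveryParams()] list
#' @return list with \code{candidates} (data.frame: contig, ref, ec,
#'   family, coverage, bestEvalue, nCorrections, nTruncation, cTruncation,
#'   peptide, sequence) and \code{edits} (edit log across contigs)
#' @export
recoverFullLength <- function(contigs, refs, params = recoveryParams()) {
  hsps <- translatedSearch(contigs, refs, params)
  passing <- candidateFilter(hsps, refs, params)
  # one candidate per contig: the best-covered, lowest-E reference
  passing <- passing[order(passing$contig, passing$bestEvalue,
                           -passing$coverage), , drop = FALSE]
  passing <- passing[!duplicated(passing$contig), , drop = FALSE]
  seqs <- if (is(contigs, "DepthContigSet")) contigSeqs(contigs) else contigs
  cand <- list()
  editLog <- list()
  for (i in seq_len(nrow(passing))) {
    cid <- passing$contig[i]
    rid <- passing$ref[i]
    ref <- refs[refs$id == rid, ]
    corr <- correctFrameshifts(as.character(seqs[[cid]]), ref$peptide,
                               params)
    h2 <- .searchOneRef(corr$sequence, ref$peptide, params)
    if (nrow(h2)) {
      h2 <- h2[h2$strand == h2$strand[which.max(h2$score)], , drop = FALSE]
      trunc <- truncationAssessment(h2, nchar(ref$peptide),
                                    nchar(corr$sequence))
      cov <- sum(width(reduce(IRanges(h2$refBegin, h2$refEnd)))) /
        nchar(ref$peptide)
    } else {
      trunc <- list(nTruncation = NA_integer_, cTruncation = NA_integer_)
      cov <- NA_real_
    }
    genes <- callGenes(corr$sequence, cid)
    pep <- NA_character_
    if (length(genes) && nrow(h2)) {
      aln <- IRanges(min(h2$ntBegin), max(h2$ntEnd))
      ov <- findOverlaps(IRanges(start(genes), end(genes)), aln)
      if (length(ov)) {
        gi <- queryHits(ov)[which.max(width(genes)[queryHits(ov)])]
        pep <- mcols(genes)$peptide[gi]
      }
    }
    cand[[length(cand) + 1L]] <- data.frame(
      contig = cid, ref = rid, ec = ref$ec, family = ref$family,
      coverage = cov, bestEvalue = passing$bestEvalue[i],
      nCorrections = nrow(corr$edits),
      nTruncation = trunc$nTruncation, cTruncation = trunc$cTruncation,
      peptide = pep, sequence = corr$sequence, stringsAsFactors = FALSE)
    if (nrow(corr$edits)) {
      corr$edits$contig <- cid
      editLog[[length(editLog) + 1L]] <- corr$edits
    }
  }
  list(candidates = if (length(cand)) do.call(rbind, cand) else
         data.frame(),
       edits = if (length(editLog)) do.call(rbind, editLog) else
         .emptyEdits())
}
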