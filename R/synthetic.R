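## Synthetic-data generators: every pipeline input can be produced with
## known ground truth (planted genes, planted indels, known rates and
## losses), so each downstream stage is testable without external data.

#' Sample a protein from a family profile
#'
#' Walks the match states of the profile in order and samples one residue
#' per state from its emission distribution (inserts and deletes are not
#' sampled; the result has exactly one residue per match state).
#' Deterministic for a fixed (profile, seed).
#'
#' @param profile a [ProfileHMM] with at least one match state
#' @param seed integer seed
#' @return peptide (character scalar)
#' @export
sampleFamilyProtein <- function(profile, seed) {
  stopifnot(is(profile, "ProfileHMM"))
  L <- profileLength(profile)
  if (L < 1L) stop("empty profile")
  set.seed(seed)
  idx <- apply(profile@matchEmis, 1, function(p) sample.int(20L, 1L, prob = p))
  paste(AA20[idx], collapse = "")
}

# random filler interleaved with frame guards every <= 200 nt, so long
# background stretches can never contain a callable (>= 300 nt) ORF
#' @noRd
.guardedFiller <- function(len, guard) {
  if (len <= 0) return("")
  out <- ""
  while (nchar(out) < len)
    out <- paste0(out, .randomSpacer(min(200L, len)), guard)
  substr(out, 1, len)
}

#' @noRd
.randomSpacer <- function(len, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
}

# reverse-translate a peptide with uniformly sampled synonymous codons
#' @noRd
.reverseTranslate <- function(pep) {
  byAA <- .codonsByAA()
  ch <- strsplit(pep, "")[[1]]
  cods <- vapply(ch, function(a) {
    cc <- byAA[[a]]
    cc[sample.int(length(cc), 1L)]
  }, character(1))
  paste(cods, collapse = "")
}

#' Build a synthetic contig set with planted GH genes
#'
#' Each taxon's genes are sampled from their family profiles, reverse
#' translated with uniformly sampled synonymous codons (standard code,
#' ATG start, single stop), and embedded in contigs separated by random
#' intergenic spacer. Every gene is insulated by a short guard segment
#' carrying stop codons in all six frames, so ORF calling recovers exactly
#' the planted coordinates. Contig read counts are Poisson with mean
#' \code{depthScale * abundance_t1 * length / 400}, the inverse of the
#' depth-weighting formula, floored at 1 read.
#'
#' @param spec a [CommunitySpec]
#' @param profiles named list of [ProfileHMM]; must contain at least one
#'   profile per family in the spec's gene complement (the first profile
#'   of each family is sampled from)
#' @param seed integer seed
#' @param depthScale expected fold coverage of a taxon at relative
#'   abundance 1 (default 50)
#' @param spacerRange intergenic spacer length range in nt; kept below the
#'   ORF-calling threshold so spacers can never harbour spurious calls
#' @return list with \code{contigs} (a [DepthContigSet]) and \code{truth}
#'   (data.frame: \code{contig}, \code{taxon}, \code{geneId},
#'   \code{family}, \code{strand}, \code{start}, \code{end} (1-based
#'   closed, forward strand, including the stop codon), \code{peptide})
#' @export
buildContigSet <- function(spec, profiles, seed, depthScale = 50,
                           spacerRange = c(50, 250)) {
  stopifnot(is(spec, "CommunitySpec"))
  famOf <- vapply(profiles, ghFamily, character(1))
  needed <- unique(spec@genes$family)
  missing <- setdiff(needed, famOf)
  if (length(missing))
    stop("no profile available for family(ies): ",
         paste(missing, collapse = ", "))
  set.seed(seed)
  guard <- .FRAME_GUARD
  maxLen <- spec@contigLength[2]
  contigs <- character()
  nReadsV <- integer()
  truth <- list()
  contigNo <- 0L
  for (ti in seq_len(nrow(spec@taxa))) {
    taxon <- spec@taxa$label[ti]
    ab1 <- spec@taxa$abundance[ti] * spec@taxa$fold[ti]
    gn <- spec@genes[spec@genes$label == taxon, , drop = FALSE]
    genes <- list()
    for (gi in seq_len(nrow(gn))) {
      fam <- gn$family[gi]
      prof <- profiles[[which(famOf == fam)[1]]]
      for (k in seq_len(gn$count[gi])) {
        pep <- sampleFamilyProtein(prof, sample.int(.Machine$integer.max, 1L))
        nt <- paste0("ATG", .reverseTranslate(pep),
                     sample(c("TAA", "TGA", "TAG"), 1L))
        genes[[length(genes) + 1L]] <- list(family = fam, nt = nt,
                                            pep = paste0("M", pep))
      }
    }
    genes <- if (length(genes)) genes[sample.int(length(genes))] else genes
    gIdx <- 1L
    repeat {
      contigNo <- contigNo + 1L
      cid <- sprintf("contig_%04d", contigNo)
      parts <- .randomSpacer(sample(spacerRange[1]:spacerRange[2], 1L))
      rows <- list()
      while (gIdx <= length(genes)) {
        g <- genes[[gIdx]]
        addLen <- 2L * nchar(guard) + nchar(g$nt) +
          sample(spacerRange[1]:spacerRange[2], 1L)
        if (nchar(parts) + addLen > maxLen && length(rows)) break
        minus <- runif(1) < 0.5
        geneSeq <- if (minus)
          as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(g$nt)))
        else g$nt
        startPos <- nchar(parts) + nchar(guard) + 1L
        parts <- paste0(parts, guard, geneSeq, guard,
                        .randomSpacer(sample(spacerRange[1]:spacerRange[2],
                                             1L)))
        rows[[length(rows) + 1L]] <- data.frame(
          contig = cid, taxon = taxon,
          geneId = sprintf("%s_g%03d", cid, length(rows) + 1L),
          family = g$family, strand = if (minus) "-" else "+",
          start = startPos, end = startPos + nchar(g$nt) - 1L,
          peptide = g$pep, stringsAsFactors = FALSE)
        gIdx <- gIdx + 1L
        if (nchar(parts) >= spec@contigLength[1]) break
      }
      # pad every contig to the declared minimum length (for gene-poor
      # taxa this yields background-only contigs)
      if (nchar(parts) < spec@contigLength[1]) {
        tgt <- sample(floor(spec@contigLength[1]):floor(maxLen), 1L)
        parts <- paste0(parts,
                        .guardedFiller(max(0L, tgt - nchar(parts)), guard))
      }
      contigs[cid] <- parts
      truth <- c(truth, rows)
      lenC <- nchar(parts)
      nReadsV <- c(nReadsV,
                   max(1L, rpois(1L, depthScale * ab1 * lenC / 400)))
      if (gIdx > length(genes)) break
    }
  }
  truthDf <- if (length(truth)) do.call(rbind, truth) else
    data.frame(contig = character(), taxon = character(),
               geneId = character(), family = character(),
               strand = character(), start = integer(), end = integer(),
               peptide = character(), stringsAsFactors = FALSE)
  list(contigs = depthContigSet(Biostrings::DNAStringSet(contigs), nReadsV),
       truth = truthDf)
}

#' Plant homopolymer indels (and optional substitutions) into contigs
#'
#' Emulates pyrosequencing error: each homopolymer run of length >= 2
#' acquires, with probability \code{indelProb(runLength)}, a single-base
#' indel — either deletion of one run base or duplication of one run base.
#' Substitutions are applied per base at \code{subsProb}, sparing the stop
#' codons of planted genes when a truth table is supplied. With
#' \code{forcePerContig}, exactly that many runs are mutated per contig,
#' chosen uniformly among runs lying in planted gene interiors (requires
#' \code{truth}).
#'
#' @param contigs a [DepthContigSet]
#' @param model an [errorModel()]
#' @param seed integer seed
#' @param truth optional truth table from [buildContigSet()]
#' @param forcePerContig optional named integer vector (contig -> number
#'   of forced indels)
#' @param minSpacing minimum separation in nt between forced indel runs
#'   (default 60): greedy score-ascent correction can resolve indels
#'   whose evidence windows are disjoint; compensating indel pairs
#'   closer than the delineation resolution are not single-edit
#'   correctable
#' @return list with \code{contigs} (mutated [DepthContigSet]) and
#'   \code{edits} (data.frame: \code{contig}, \code{posOrig},
#'   \code{posMut} (position in the mutated sequence), \code{kind},
#'   \code{base}, \code{runLength}, \code{runStart}, \code{runEnd}
#'   (original run span) and \code{runStartMut}, \code{runEndMut}, the
#'   surviving run span in mutated coordinates — a compensating
#'   correction is "within the run" iff it falls in this span)
#' @export
plantFrameshifts <- function(contigs, model, seed = 1L, truth = NULL,
                             forcePerContig = NULL, minSpacing = 60L) {
  stopifnot(is(contigs, "DepthContigSet"), is(model, "ErrorModel"))
  set.seed(seed)
  seqs <- as.character(contigSeqs(contigs))
  editRows <- list()
  for (cid in names(seqs)) {
    s <- seqs[[cid]]
    runs <- .homopolymerRuns(s, minLen = 2L)
    if (!is.null(forcePerContig) && cid %in% names(forcePerContig)) {
      if (is.null(truth))
        stop("forcePerContig requires the truth table")
      tg <- truth[truth$contig == cid, , drop = FALSE]
      # a frameshift is only delineable when both flanking gene fragments
      # still align; keep forced indels >= 60 nt (20 codons) from gene ends
      inside <- rep(FALSE, nrow(runs))
      for (k in seq_len(nrow(tg)))
        inside <- inside | (runs$start >= tg$start[k] + 60L &
                            runs$end <= tg$end[k] - 60L)
      pool <- which(inside)
      nWant <- forcePerContig[[cid]]
      if (length(pool) < nWant)
        stop("contig ", cid, " has only ", length(pool),
             " eligible homopolymer runs inside genes")
      # sample runs with the error model's run-length weighting, so the
      # forced fixture reproduces where the error process actually hits
      w <- model@indelProb(runs$length[pool])
      if (all(w <= 0)) w <- rep(1, length(pool))
      ord <- sample.int(length(pool), length(pool), prob = w)
      chosen <- integer()
      for (ri in pool[ord]) {
        if (length(chosen) == nWant) break
        if (!length(chosen) ||
            all(abs(runs$start[ri] - runs$start[chosen]) >= minSpacing))
          chosen <- c(chosen, ri)
      }
      if (length(chosen) < nWant)
        stop("contig ", cid, ": cannot place ", nWant, " indels ",
             minSpacing, " nt apart; gene too short or runs too sparse")
    } else {
      p <- model@indelProb(runs$length)
      chosen <- which(runif(nrow(runs)) < p)
    }
    edits <- list()
    for (ri in chosen) {
      pos <- sample(runs$start[ri]:runs$end[ri], 1L)
      kind <- sample(c("delete", "duplicate"), 1L)
      edits[[length(edits) + 1L]] <- data.frame(
        contig = cid, posOrig = pos, kind = kind,
        base = runs$base[ri], runLength = runs$length[ri],
        runStart = runs$start[ri], runEnd = runs$end[ri],
        stringsAsFactors = FALSE)
    }
    if (length(edits)) {
      ed <- do.call(rbind, edits)
      ed <- ed[order(-ed$posOrig), , drop = FALSE]  # apply right-to-left
      for (k in seq_len(nrow(ed)))
        s <- .applyEdit(s, ed$posOrig[k], ed$kind[k])
      delta <- ifelse(ed$kind == "duplicate", 1L, -1L)
      shift <- function(p, k) p + sum(delta[ed$posOrig < ed$posOrig[k]])
      ed$posMut <- vapply(seq_len(nrow(ed)), function(k)
        shift(ed$posOrig[k], k), integer(1))
      # surviving span of the mutated run in mutated coordinates: the
      # run grows by one base for a duplication, shrinks by one for a
      # deletion; the compensating correction must land inside it
      ed$runStartMut <- vapply(seq_len(nrow(ed)), function(k)
        shift(ed$runStart[k], k), integer(1))
      ed$runEndMut <- vapply(seq_len(nrow(ed)), function(k)
        shift(ed$runEnd[k], k) + delta[k], integer(1))
      editRows[[length(editRows) + 1L]] <- ed
    }
    # substitutions
    if (model@subsProb > 0) {
      nS <- nchar(s)
      hitPos <- which(runif(nS) < model@subsProb)
      if (!is.null(truth)) {
        tg <- truth[truth$contig == cid, , drop = FALSE]
        for (k in seq_len(nrow(tg))) {
          stopSpan <- if (tg$strand[k] == "+")
            (tg$end[k] - 2L):tg$end[k] else tg$start[k]:(tg$start[k] + 2L)
          hitPos <- setdiff(hitPos, stopSpan)
        }
      }
      for (pp in hitPos) {
        old <- substr(s, pp, pp)
        substr(s, pp, pp) <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
      }
    }
    seqs[[cid]] <- s
  }
  ed <- if (length(editRows)) do.call(rbind, editRows) else
    data.frame(contig = character(), posOrig = integer(),
               kind = character(), base = character(),
               runLength = integer(), runStart = integer(),
               runEnd = integer(), posMut = integer(),
               runStartMut = integer(), runEndMut = integer(),
               stringsAsFactors = FALSE)
  rownames(ed) <- NULL
  list(contigs = depthContigSet(Biostrings::DNAStringSet(seqs),
                                nReads(contigs)),
       edits = ed)
}

#' Multinomial phylotype tables for the two timepoints
#'
#' Draws \code{depth} reads per sample from the spec's t0 and t1
#' abundance vectors.
#'
#' @param spec a [CommunitySpec]
#' @param depth reads per sample (> 0)
#' @param seed integer seed
#' @return a [PhylotypeTable] with samples \code{t0}, \code{t1}
#' @export
makePhylotypeTables <- function(spec, depth, seed) {
  stopifnot(is(spec, "CommunitySpec"))
  if (depth <= 0) stop("sequencing depth must be > 0")
  set.seed(seed)
  p0 <- spec@taxa$abundance
  p1 <- p0 * spec@taxa$fold
  m <- cbind(t0 = rmultinom(1, depth, p0)[, 1],
             t1 = rmultinom(1, depth, p1)[, 1])
  rownames(m) <- spec@taxa$label
  phylotypeTable(m)
}

#' Generate a gas time series from known rate profiles
#'
#' Emits influent/effluent concentrations that invert the mass-balance
#' formulas exactly: co2_out = co2_in + CER(t)/F and
#' o2_out = o2_in - OUR(t)/F, so the respiration module recovers the
#' generating profiles to machine precision.
#'
#' @param cerFun,ourFun functions of time (days) giving the true rates,
#'   mg gas day^-1 gdw^-1
#' @param F air flow rate, mg air day^-1 gdw^-1 (> 0)
#' @param interval sampling interval in days (default 20 minutes)
#' @param tEnd end of incubation, days
#' @param co2In,o2In influent mass fractions
#' @return data.frame with columns \code{t_day, F, co2_in, co2_out,
#'   o2_in, o2_out, event}
#' @export
makeGasSeries <- function(cerFun, ourFun, F = 2000, interval = 20 / 1440,
                          tEnd = 31, co2In = 5e-4, o2In = 0.23) {
  if (F <= 0) stop("air flow rate F must be > 0")
  t <- seq(0, tEnd, by = interval)
  co2Out <- co2In + cerFun(t) / F
  o2Out <- o2In - ourFun(t) / F
  if (any(co2Out < 0) || any(o2Out < 0))
    stop("rate profiles imply negative gas concentrations")
  data.frame(t_day = t, F = F, co2_in = co2In, co2_out = co2Out,
             o2_in = o2In, o2_out = o2Out, event = 0L)
}

#' Generate a composition table with known losses
#'
#' final_adjusted = initial * (1 - loss); the measured final (per kg of
#' final dry solids) is back-computed through the ash-conservation solids
#' loss, so the composition module's round trip recovers the generating
#' loss vector exactly.
#'
#' @param initial named numeric vector, g per kg initial dry mix
#' @param losses loss fractions in [0, 1], parallel to \code{initial}
#' @param ashInitial,ashFinal ash fractions of total dry solids
#' @param solidsLossTarget optional: declared total-solids loss; an error
#'   is raised if the ash pair implies a different value (inconsistent
#'   inputs)
#' @return data.frame with columns \code{name, initial_g_per_kg,
#'   final_adjusted_g_per_kg, final_measured_g_per_kg}
#' @export
makeCompositionTable <- function(initial, losses, ashInitial, ashFinal,
                                 solidsLossTarget = NULL) {
  if (length(initial) != length(losses))
    stop("initial and losses must be parallel")
  if (any(losses < 0 | losses > 1)) stop("losses must lie in [0, 1]")
  sl <- solidsLoss(ashInitial, ashFinal)
  if (!is.null(solidsLossTarget) && abs(solidsLossTarget - sl) > 1e-9)
    stop("ash pair implies solids loss ", signif(sl, 4),
         ", inconsistent with declared ", solidsLossTarget)
  adj <- initial * (1 - losses)
  data.frame(name = names(initial), initial_g_per_kg = unname(initial),
             final_adjusted_g_per_kg = unname(adj),
             final_measured_g_per_kg = unname(adj / (1 - sl)),
             stringsAsFactors = FALSE)
}

#' Demo GH family catalog with profiles and reference enzymes
#'
#' Builds a compact, fully synthetic stand-in for a curated GH profile
#' catalog: one consensus-concentrated profile per family (two for GH2,
#' exercising the multi-profile best-hit rule), the five functional-group
#' assignments, and an EC-annotated reference peptide per family (the
#' profile consensus preceded by M). One reference (\code{GH16_ref}) is
#' left without an EC number to exercise the known-function filter.
#'
#' @param seed integer seed
#' @param profileLength match states per profile (default 80)
#' @param matchProb consensus emission probability (default 0.85)
#' @return list with \code{catalog} (data.frame: family, profile, group,
#'   activity), \code{profiles} (named list of [ProfileHMM]) and
#'   \code{refs} (data.frame: id, peptide, ec, family)
#' @export
makeDemoCatalog <- function(seed = 42L, profileLength = 80,
                            matchProb = 0.85) {
  fams <- data.frame(
    family = c("GH5", "GH9", "GH10", "GH51", "GH16", "GH2", "GH2", "GH43"),
    profile = c("PF_GH5", "PF_GH9", "PF_GH10", "PF_GH51", "PF_GH16",
                "PF_GH2a", "PF_GH2b", "PF_GH43"),
    group = c("cellulases", "cellulases", "endohemicellulases",
              "debranching", "cell wall elongation",
              "oligosaccharide-degrading", "oligosaccharide-degrading",
              "oligosaccharide-degrading"),
    activity = c("cellulase", "endoglucanase", "endo-1,4-beta-xylanase",
                 "alpha-L-arabinofuranosidase", "xyloglucanase",
                 "beta-galactosidase", "beta-galactosidase",
                 "arabinase/xylosidase"),
    stringsAsFactors = FALSE)
  set.seed(seed)
  profiles <- list()
  for (i in seq_len(nrow(fams))) {
    cons <- paste(sample(AA20, profileLength, replace = TRUE),
                  collapse = "")
    profiles[[fams$profile[i]]] <- profileHMM(
      fams$profile[i], fams$family[i],
      consensusEmissions(cons, matchProb))
  }
  ec <- c(GH5 = "3.2.1.4", GH9 = "3.2.1.4", GH10 = "3.2.1.8",
          GH51 = "3.2.1.55", GH16 = NA, GH2 = "3.2.1.23",
          GH43 = "3.2.1.37")
  refFams <- unique(fams$family)
  refs <- data.frame(
    id = paste0(refFams, "_ref"),
    peptide = vapply(refFams, function(f) {
      pr <- profiles[[fams$profile[fams$family == f][1]]]
      paste0("M", paste(AA20[apply(pr@matchEmis, 1, which.max)],
                        collapse = ""))
    }, character(1)),
    ec = unname(ec[refFams]),
    family = refFams, stringsAsFactors = FALSE)
  list(catalog = fams, profiles = profiles, refs = refs)
}
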