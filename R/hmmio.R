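## Read/write a pragmatic subset of the HMMER3 ASCII .hmm profile format:
## header fields NAME/DESC/LENG/ALPH and the model section (match emissions,
## insert emissions, node transitions as negative natural-log probabilities,
## '*' for probability zero). Annotation columns beyond the emission values
## (MAP/CONS/RF/...) are written as placeholders and ignored on read.

.fmtNegLn <- function(p) {
  ifelse(p <= 0, "*", sprintf("%.5f", -log(p)))
}

.parseNegLn <- function(tok) {
  v <- numeric(length(tok))
  star <- tok == "*"
  v[!star] <- exp(-as.numeric(tok[!star]))
  v
}

#' Write profile HMMs to a HMMER3 ASCII file
#'
#' @param profiles a [ProfileHMM] or list of them
#' @param path output file
#' @return invisibly, \code{path}
#' @seealso [readHMMER()]
#' @export
writeHMMER <- function(profiles, path) {
  if (is(profiles, "ProfileHMM")) profiles <- list(profiles)
  con <- file(path, "w")
  on.exit(close(con))
  for (pr in profiles) {
    L <- profileLength(pr)
    writeLines(c(
      "HMMER3/f [compostGH profile writer]",
      paste0("NAME  ", pr@name),
      paste0("DESC  family:", pr@family),
      paste0("LENG  ", L),
      "ALPH  amino",
      paste0("HMM      ", paste(sprintf("%8s", AA20), collapse = " ")),
      paste0("         ", paste(sprintf("%8s",
        c("m->m", "m->i", "m->d", "i->m", "i->i", "d->m", "d->d")),
        collapse = " "))), con)
    compo <- colMeans(pr@matchEmis)
    writeLines(paste0("  COMPO ",
      paste(sprintf("%8s", .fmtNegLn(compo)), collapse = " ")), con)
    writeLines(paste0("        ",
      paste(sprintf("%8s", .fmtNegLn(pr@insEmis[1, ])), collapse = " ")), con)
    # node-0 (begin) transitions; informational only: local entry is uniform
    writeLines(paste0("        ",
      paste(sprintf("%8s", .fmtNegLn(c(1, 0, 0, 1, 0, 1, 0))),
            collapse = " ")), con)
    for (k in seq_len(L)) {
      writeLines(paste0(sprintf("%7d ", k),
        paste(sprintf("%8s", .fmtNegLn(pr@matchEmis[k, ])), collapse = " "),
        sprintf("%7d - - - -", k)), con)
      writeLines(paste0("        ",
        paste(sprintf("%8s", .fmtNegLn(pr@insEmis[k, ])), collapse = " ")),
        con)
      writeLines(paste0("        ",
        paste(sprintf("%8s", .fmtNegLn(pr@trans[k, ])), collapse = " ")),
        con)
    }
    writeLines("//", con)
  }
  invisible(path)
}

#' Read profile HMMs from a HMMER3 ASCII file
#'
#' Parses the subset of the format the package writes (and that standard
#' Pfam files contain): NAME, DESC, LENG, ALPH and the emission/transition
#' body. The GH family is recovered from a \code{DESC family:<id>} line when
#' present; otherwise it must be supplied by the family catalog.
#'
#' @param path a .hmm file, possibly with several concatenated models
#' @return a named list of [ProfileHMM] objects
#' @seealso [writeHMMER()]
#' @export
readHMMER <- function(path) {
  lines <- readLines(path)
  starts <- grep("^HMMER3", lines)
  if (!length(starts)) stop("not a HMMER3 ASCII file: ", path)
  ends <- grep("^//", lines)
  if (length(ends) < length(starts))
    stop("truncated HMMER3 file: missing '//' terminator")
  out <- list()
  for (b in seq_along(starts)) {
    block <- lines[starts[b]:ends[b]]
    getField <- function(key) {
      ln <- grep(paste0("^", key, "\\s"), block, value = TRUE)
      if (!length(ln)) return(NA_character_)
      sub(paste0("^", key, "\\s+"), "", ln[1])
    }
    name <- getField("NAME")
    L <- as.integer(getField("LENG"))
    alph <- getField("ALPH")
    if (!identical(tolower(alph), "amino"))
      stop("unsupported alphabet '", alph, "' in profile ", name)
    desc <- getField("DESC")
    fam <- if (!is.na(desc) && grepl("family:", desc))
      sub(".*family:(\\S+).*", "\\1", desc) else NA_character_
    hmmAt <- grep("^HMM\\s", block)[1]
    body <- block[(hmmAt + 2):length(block)]
    body <- body[!grepl("^//", body)]
    toks <- lapply(body, function(x) strsplit(trimws(x), "\\s+")[[1]])
    # drop optional COMPO line plus the two node-0 lines
    i <- 1
    if (identical(toks[[1]][1], "COMPO")) i <- i + 1
    i <- i + 2
    matchEmis <- matrix(0, L, 20, dimnames = list(NULL, AA20))
    insEmis <- matrix(0, L, 20, dimnames = list(NULL, AA20))
    trans <- matrix(0, L, 7,
                    dimnames = list(NULL, c("MM", "MI", "MD", "IM", "II",
                                            "DM", "DD")))
    for (k in seq_len(L)) {
      mt <- toks[[i]]
      if (as.integer(mt[1]) != k)
        stop("node numbering mismatch at node ", k, " in profile ", name)
      matchEmis[k, ] <- .parseNegLn(mt[2:21])
      insEmis[k, ] <- .parseNegLn(toks[[i + 1]][1:20])
      trans[k, ] <- .parseNegLn(toks[[i + 2]][1:7])
      i <- i + 3
    }
    # renormalise away formatting round-off
    matchEmis <- matchEmis / rowSums(matchEmis)
    insEmis <- insEmis / rowSums(insEmis)
    out[[name]] <- profileHMM(name, fam, matchEmis, insEmis, trans)
  }
  out
}
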