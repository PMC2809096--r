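## Plain-text readers and writers for the pipeline's file formats:
## contig FASTA + read-count sidecar, phylotype tables, family catalogs,
## EC-annotated reference FASTA, truth tables.

#' Write contigs as FASTA plus a read-count sidecar
#'
#' @param contigs a [DepthContigSet]
#' @param fastaPath output FASTA (60-column wrap)
#' @param sidecarPath output TSV with columns \code{contig_id, n_reads}
#' @return invisibly, \code{fastaPath}
#' @export
writeDepthContigs <- function(contigs, fastaPath, sidecarPath) {
  writeXStringSet(contigSeqs(contigs), fastaPath, width = 60)
  write.table(data.frame(contig_id = names(contigs),
                         n_reads = nReads(contigs)),
              sidecarPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(fastaPath)
}

#' Read contigs from FASTA plus a read-count sidecar
#'
#' @param fastaPath contig FASTA
#' @param sidecarPath TSV with columns \code{contig_id, n_reads}
#' @return a [DepthContigSet]
#' @export
readDepthContigs <- function(fastaPath, sidecarPath) {
  seqs <- readDNAStringSet(fastaPath)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  side <- read.delim(sidecarPath, stringsAsFactors = FALSE)
  idx <- match(names(seqs), side$contig_id)
  if (anyNA(idx))
    stop("sidecar is missing contig(s): ",
         paste(names(seqs)[is.na(idx)], collapse = ", "))
  depthContigSet(seqs, side$n_reads[idx])
}

#' Write a phylotype table as TSV
#'
#' @param table a [PhylotypeTable]
#' @param path output TSV (first column \code{phylotype}, one column per
#'   sample)
#' @return invisibly, \code{path}
#' @export
writePhylotypeTable <- function(table, path) {
  m <- counts(table)
  write.table(data.frame(phylotype = rownames(m), m, check.names = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phylotype table from TSV
#'
#' @param path TSV written by [writePhylotypeTable()]
#' @return a [PhylotypeTable]
#' @export
readPhylotypeTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  phylotypeTable(m)
}

#' Write a family catalog as TSV
#'
#' @param catalog data.frame with columns \code{family, profile, group,
#'   activity}
#' @param path output TSV
#' @return invisibly, \code{path}
#' @export
writeFamilyCatalog <- function(catalog, path) {
  .validateCatalog(catalog)
  write.table(catalog, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a family catalog TSV
#'
#' @param path TSV with columns \code{family, profile, group} (and
#'   optionally \code{activity})
#' @return validated data.frame
#' @export
readFamilyCatalog <- function(path) {
  .validateCatalog(read.delim(path, stringsAsFactors = FALSE))
}

#' Write reference enzymes as FASTA with id|EC|family headers
#'
#' @param refs data.frame with columns \code{id, peptide, ec, family};
#'   missing EC numbers are written as an empty field
#' @param path output FASTA
#' @return invisibly, \code{path}
#' @export
writeEnzymeReferences <- function(refs, path) {
  aa <- Biostrings::AAStringSet(refs$peptide)
  names(aa) <- paste(refs$id,
                     ifelse(is.na(refs$ec), "", refs$ec),
                     refs$family, sep = "|")
  writeXStringSet(aa, path, width = 60)
  invisible(path)
}

#' Read reference enzymes from FASTA with id|EC|family headers
#'
#' @param path FASTA whose headers are \code{id|EC|family} (empty EC field
#'   means no known enzymatic function)
#' @return data.frame with columns \code{id, peptide, ec, family}
#' @export
readEnzymeReferences <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  parts <- strsplit(sub("\\s.*$", "", names(aa)), "\\|")
  bad <- lengths(parts) != 3L
  if (any(bad))
    stop("malformed reference header(s); expected id|EC|family")
  ec <- vapply(parts, `[`, character(1), 2)
  ec[!nzchar(ec)] <- NA_character_
  data.frame(id = vapply(parts, `[`, character(1), 1),
             peptide = as.character(aa), ec = ec,
             family = vapply(parts, `[`, character(1), 3),
             stringsAsFactors = FALSE)
}
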