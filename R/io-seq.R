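#' Read a FASTA file as a named character vector
#'
#' Sequences are uppercased; any character outside `ACGTN` raises an error
#' naming the offending record (amplicon work in this package is strictly
#' nucleotide).
#'
#' @param path file path.
#' @param allow_iupac allow IUPAC ambiguity codes (used for primer files).
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path, allow_iupac = FALSE) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  ok_chars <- if (allow_iupac) "ACGTNRYSWKMBDHV" else "ACGTN"
  bad <- grepl(sprintf("[^%s]", ok_chars), seqs)
  if (any(bad))
    stop("non-nucleotide characters in record(s): ",
         paste(names(seqs)[bad], collapse = ", "))
  seqs
}

#' Write sequences to FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Read a FASTQ file (Sanger quality encoding)
#'
#' @param path file path.
#' @return data.frame with columns `id`, `seq` (uppercase), `qual` (Sanger
#'   string, Phred offset 33).
#' @export
read_fastq <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) %% 4 != 0) stop("truncated FASTQ: line count not multiple of 4")
  ids <- sub("^@", "", lines[seq(1, length(lines), 4)])
  ids <- sub("\\s.*$", "", ids)
  seqs <- toupper(lines[seq(2, length(lines), 4)])
  qual <- lines[seq(4, length(lines), 4)]
  if (any(nchar(seqs) != nchar(qual))) stop("FASTQ sequence/quality length mismatch")
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("non-ACGTN characters in record(s): ", paste(ids[bad], collapse = ", "))
  data.frame(id = ids, seq = seqs, qual = qual, stringsAsFactors = FALSE)
}

#' Write reads to FASTQ (Sanger encoding)
#' @param reads data.frame with `id`, `seq`, `qual`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  out <- character(4 * nrow(reads))
  out[seq(1, length(out), 4)] <- paste0("@", reads$id)
  out[seq(2, length(out), 4)] <- reads$seq
  out[seq(3, length(out), 4)] <- "+"
  out[seq(4, length(out), 4)] <- reads$qual
  writeLines(out, path)
  invisible(path)
}

#' Decode a Sanger quality string into Phred scores
#' @param qual quality string (offset 33).
#' @return Integer vector of Phred scores.
#' @export
phred_scores <- function(qual) as.integer(charToRaw(qual)) - 33L

#' Encode Phred scores as a Sanger quality string
#' @param scores integer Phred scores.
#' @return Quality string.
#' @export
phred_string <- function(scores) rawToChar(as.raw(scores + 33L))
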