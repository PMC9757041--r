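#' Read an assembly from FASTA
#'
#' Wraps [Biostrings::readDNAStringSet()] with the validation this pipeline
#' relies on: unique record names, alphabet restricted to A/C/G/T/N, and a
#' soft-mask track preserved from lowercase input (sequences are returned
#' uppercased; the original lowercase runs are kept as an IRangesList in the
#' `mask` attribute).
#'
#' @param path FASTA file.
#' @param kind "contigs" (no N runs allowed) or "scaffolds".
#' @return A `DNAStringSet` with attributes `kind` and `mask`.
#' @export
read_fasta <- function(path, kind = c("scaffolds", "contigs")) {
  kind <- match.arg(kind)
  seqs <- Biostrings::readBStringSet(path)
  nm <- names(seqs)
  if (is.null(nm) || anyNA(nm) || any(nm == "")) {
    stop("FASTA records must all be named", call. = FALSE)
  }
  nm <- sub("\\s.*$", "", nm)
  if (anyDuplicated(nm)) {
    stop("duplicate FASTA record name: ", nm[duplicated(nm)][1], call. = FALSE)
  }
  names(seqs) <- nm
  chars <- Biostrings::uniqueLetters(seqs)
  bad <- setdiff(chars, c("A", "C", "G", "T", "N", "a", "c", "g", "t", "n"))
  if (length(bad)) {
    stop("illegal characters in FASTA (first offending record: ",
         nm[which(vapply(seq_along(seqs), function(i) {
           any(Biostrings::uniqueLetters(seqs[i]) %in% bad)
         }, logical(1)))[1]], "): ", paste(bad, collapse = ""), call. = FALSE)
  }
  # soft-mask track: runs of lowercase per record
  mask <- lapply(seq_along(seqs), function(i) {
    r <- charToRaw(as.character(seqs[[i]]))
    low <- r >= charToRaw("a") & r <= charToRaw("z")
    ir <- IRanges::IRanges(low)
    ir
  })
  names(mask) <- nm
  out <- Biostrings::DNAStringSet(toupper(seqs))
  names(out) <- nm
  if (kind == "contigs" && any(Biostrings::letterFrequency(out, "N") > 0)) {
    stop("contigs may not contain N runs", call. = FALSE)
  }
  attr(out, "kind") <- kind
  attr(out, "mask") <- IRanges::IRangesList(mask)
  out
}

#' Write an assembly to FASTA
#'
#' @param seqs `DNAStringSet` (or named character vector).
#' @param path output file.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 80L) {
  if (!methods::is(seqs, "XStringSet")) {
    seqs <- Biostrings::DNAStringSet(seqs)
  }
  Biostrings::writeXStringSet(seqs, path, width = width)
  invisible(path)
}

#' Read reads from FASTQ (or FASTA)
#'
#' @param path FASTQ/FASTA file; format auto-detected from the first byte.
#' @return A `DNAStringSet` of reads (qualities are not retained; the
#'   pipeline's error model is substitution-only and quality-agnostic).
#' @export
read_reads <- function(path) {
  first <- readChar(path, 1L, useBytes = TRUE)
  if (identical(first, "@")) {
    Biostrings::readDNAStringSet(path, format = "fastq")
  } else {
    Biostrings::readDNAStringSet(path, format = "fasta")
  }
}

#' Write reads to FASTQ with uniform qualities
#'
#' Phred+33 encoding with a single uniform quality character (default "I",
#' Q40), matching the simulator's quality-agnostic error model.
#'
#' @param reads `DNAStringSet` of reads (named).
#' @param path output FASTQ.
#' @param qual_char single quality character.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, qual_char = "I") {
  quals <- Biostrings::BStringSet(vapply(Biostrings::width(reads), function(w) {
    strrep(qual_char, w)
  }, character(1)))
  q <- Biostrings::QualityScaledDNAStringSet(
    reads, Biostrings::PhredQuality(quals)
  )
  Biostrings::writeQualityScaledXStringSet(q, path)
  invisible(path)
}
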