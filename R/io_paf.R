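#' Read PAF alignments
#'
#' Parses the 12 mandatory PAF columns plus the `cg:Z` CIGAR and `tp:A`
#' alignment-type tags when present. PAF's 0-based half-open coordinates
#' are converted to the 1-based closed convention used throughout the
#' package; for "-" strand records the query interval keeps PAF's
#' convention (coordinates on the original read, target interval
#' unaffected).
#'
#' @param path PAF file.
#' @return data.frame with columns `qname,qlen,qstart,qend,strand,tname,
#'   tlen,tstart,tend,nmatch,alen,mapq,cigar,tp`.
#' @export
read_paf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 12L)) {
    stop("PAF line ", which(ncol < 12L)[1], " has fewer than 12 columns",
         call. = FALSE)
  }
  get <- function(i) vapply(fields, `[`, character(1), i)
  tag <- function(prefix) {
    vapply(fields, function(f) {
      hit <- f[startsWith(f, prefix)]
      if (length(hit)) sub(prefix, "", hit[1], fixed = TRUE) else NA_character_
    }, character(1))
  }
  data.frame(
    qname = get(1), qlen = as.integer(get(2)),
    qstart = as.integer(get(3)) + 1L, qend = as.integer(get(4)),
    strand = get(5),
    tname = get(6), tlen = as.integer(get(7)),
    tstart = as.integer(get(8)) + 1L, tend = as.integer(get(9)),
    nmatch = as.numeric(get(10)), alen = as.numeric(get(11)),
    mapq = as.integer(get(12)),
    cigar = tag("cg:Z:"), tp = tag("tp:A:"),
    stringsAsFactors = FALSE
  )
}

#' Write PAF alignments
#'
#' Inverse of [read_paf()]: converts the package's 1-based closed
#' coordinates back to PAF 0-based half-open and appends `tp:A`/`cg:Z`
#' tags when the columns are present and non-NA.
#'
#' @param aln data.frame as returned by [read_paf()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_paf <- function(aln, path) {
  lines <- paste(aln$qname, aln$qlen, aln$qstart - 1L, aln$qend, aln$strand,
                 aln$tname, aln$tlen, aln$tstart - 1L, aln$tend,
                 aln$nmatch, aln$alen, aln$mapq, sep = "\t")
  if (!is.null(aln$tp)) {
    has <- !is.na(aln$tp)
    lines[has] <- paste0(lines[has], "\ttp:A:", aln$tp[has])
  }
  if (!is.null(aln$cigar)) {
    has <- !is.na(aln$cigar)
    lines[has] <- paste0(lines[has], "\tcg:Z:", aln$cigar[has])
  }
  writeLines(lines, path)
  invisible(path)
}

# Parse a CIGAR string into (op, len) pairs.
parse_cigar <- function(cigar) {
  if (is.na(cigar) || !nzchar(cigar)) return(NULL)
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  if (length(lens) != length(ops)) {
    stop("malformed CIGAR: ", cigar, call. = FALSE)
  }
  list(op = ops, len = lens)
}
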