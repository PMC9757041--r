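#' Subsample reads to a target coverage
#'
#' Whole reads are drawn without replacement in a seed-determined shuffled
#' order until the cumulative base count first reaches
#' `genome_size * target_coverage`; the subset may overshoot the target by
#' at most one read. If the target exceeds the available bases, all reads
#' are returned with a warning.
#'
#' @param reads `DNAStringSet`.
#' @param genome_size genome size in bp used to convert coverage to bases.
#' @param target_coverage desired fold coverage.
#' @param seed integer seed controlling the shuffle.
#' @return `DNAStringSet` subset of `reads`.
#' @export
subsample_to_coverage <- function(reads, genome_size, target_coverage, seed) {
  stopifnot(target_coverage > 0, genome_size > 0)
  target <- genome_size * target_coverage
  total <- sum(Biostrings::width(reads))
  if (target >= total) {
    warning(sprintf("requested %.0f bases but only %.0f available; returning all reads",
                    target, total))
    return(reads)
  }
  ord <- with_seed(seed, sample.int(length(reads)))
  cum <- cumsum(as.numeric(Biostrings::width(reads)[ord]))
  n <- which(cum >= target)[1]
  reads[sort(ord[seq_len(n)])]
}

#' Trim reads from both ends
#'
#' Each read loses `trim_each_end` bases from both ends; reads shorter than
#' `min_len` after trimming are discarded. Order is preserved.
#'
#' @param reads `DNAStringSet`.
#' @param trim_each_end bases removed from each end.
#' @param min_len minimum surviving read length (default 2000).
#' @return trimmed `DNAStringSet`.
#' @export
trim_reads <- function(reads, trim_each_end, min_len = 2000L) {
  stopifnot(trim_each_end >= 0)
  if (trim_each_end == 0) return(reads)
  w <- Biostrings::width(reads)
  keep <- (w - 2 * trim_each_end) >= min_len
  out <- reads[keep]
  Biostrings::subseq(out, start = trim_each_end + 1L,
                     end = Biostrings::width(out) - trim_each_end)
}

#' Read-length statistics
#'
#' Median, N50 (shortest read such that reads of that length or longer sum
#' to at least half the total bases) and total bases.
#'
#' @param reads `DNAStringSet` or numeric lengths.
#' @return list with `median`, `n50`, `total_bases`, `n_reads`.
#' @export
length_stats <- function(reads) {
  lens <- if (methods::is(reads, "XStringSet")) {
    Biostrings::width(reads)
  } else {
    as.numeric(reads)
  }
  if (!length(lens)) stop("no reads", call. = FALSE)
  lens_desc <- sort(lens, decreasing = TRUE)
  cum <- cumsum(lens_desc)
  n50 <- lens_desc[which(cum >= sum(lens) / 2)[1]]
  list(median = stats::median(lens), n50 = n50,
       total_bases = sum(lens), n_reads = length(lens))
}
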