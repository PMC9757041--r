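#' Count canonical k-mers
#'
#' Exact canonical k-mer counting (a k-mer and its reverse complement are
#' the same entity; the lexicographically smaller encoding is stored).
#' Windows containing non-ACGT characters (e.g. N) are skipped. Counting is
#' done in compiled code with a rolling 2-bit encoding; k is limited to
#' [11, 26] so that every canonical code is exactly representable as a
#' double (the defaults used throughout are k = 18 for QV/completeness and
#' k = 21 for genome-size estimation).
#'
#' @param sequences `DNAStringSet` or character vector of sequences.
#' @param k k-mer length, 11-26.
#' @return An object of class `kmer_db`: list with `k`, sorted numeric
#'   `code`, `count`, `total_distinct`, `total_instances` and `histogram`
#'   (data.frame `count`, `freq`).
#' @export
count_kmers <- function(sequences, k = 18L) {
  if (methods::is(sequences, "XStringSet")) {
    sequences <- as.character(sequences)
  }
  res <- .count_kmers_cpp(toupper(sequences), as.integer(k))
  histogram <- kmer_histogram(res$count)
  structure(
    list(k = as.integer(k), code = res$code, count = res$count,
         total_distinct = length(res$code),
         total_instances = sum(res$count),
         histogram = histogram),
    class = "kmer_db"
  )
}

kmer_histogram <- function(counts) {
  if (!length(counts)) {
    return(data.frame(count = integer(), freq = numeric()))
  }
  tab <- table(counts)
  data.frame(count = as.integer(names(tab)), freq = as.numeric(tab))
}

#' @export
print.kmer_db <- function(x, ...) {
  cat(sprintf("kmer_db: k=%d, %d distinct, %.0f instances\n",
              x$k, x$total_distinct, x$total_instances))
  invisible(x)
}

#' Decode k-mer codes back to sequences
#' @param db a `kmer_db`.
#' @param n how many (from the sorted head) to decode.
#' @return character vector of k-mers.
#' @export
kmer_strings <- function(db, n = length(db$code)) {
  .decode_kmers_cpp(utils::head(db$code, n), db$k)
}

#' Reliable-count threshold from a k-mer histogram
#'
#' Read k-mer spectra are bimodal: an error peak at low counts and a
#' coverage peak at the sequencing depth. K-mers below the valley between
#' the two are treated as likely sequencing errors. Returns the count at
#' the first local minimum; falls back to 2 when the histogram is unimodal.
#'
#' @param histogram data.frame with `count` and `freq` columns (as stored
#'   in a `kmer_db`), or a `kmer_db`.
#' @return integer threshold (minimum reliable count).
#' @export
reliable_threshold <- function(histogram) {
  if (inherits(histogram, "kmer_db")) histogram <- histogram$histogram
  if (!nrow(histogram)) stop("empty k-mer histogram", call. = FALSE)
  maxc <- max(histogram$count)
  f <- numeric(maxc)
  f[histogram$count] <- histogram$freq
  if (maxc >= 3) {
    cum <- cumsum(f)
    for (cc in 2:(maxc - 1)) {
      # a valley needs an error peak before it: mass below the candidate
      if (cum[cc - 1] > 0 && f[cc] <= f[cc - 1] && f[cc] < f[cc + 1]) {
        return(as.integer(cc))
      }
    }
  }
  2L
}

#' Consensus quality (QV) from assembly and read k-mer databases
#'
#' Assembly k-mers absent from an independent read set are taken as
#' consensus errors. With P the fraction of assembly k-mer instances not
#' found in the reads, the per-base error rate is
#' E = 1 - (1 - P)^(1/k) and QV = -10 log10 E (Phred scale). Presence in
#' the reads, not count agreement, is what is compared. When the assembly
#' contains no read-absent k-mers, QV is capped at `cap`.
#'
#' @param assembly_db,read_db `kmer_db` objects with equal k.
#' @param cap QV ceiling when no assembly-only k-mers exist (default 99).
#' @return list with `qv`, `p_absent`, `absent_instances`,
#'   `total_instances`.
#' @export
kmer_qv <- function(assembly_db, read_db, cap = 99) {
  stopifnot(inherits(assembly_db, "kmer_db"), inherits(read_db, "kmer_db"))
  if (assembly_db$k != read_db$k) {
    stop("assembly and read databases must share k", call. = FALSE)
  }
  if (!assembly_db$total_distinct) {
    stop("empty assembly k-mer database", call. = FALSE)
  }
  present <- assembly_db$code %in% read_db$code
  absent_instances <- sum(assembly_db$count[!present])
  total <- assembly_db$total_instances
  p <- absent_instances / total
  qv <- if (p == 0) cap else {
    err <- 1 - (1 - p)^(1 / assembly_db$k)
    min(-10 * log10(err), cap)
  }
  list(qv = qv, p_absent = p, absent_instances = absent_instances,
       total_instances = total)
}

#' k-mer completeness of an assembly
#'
#' Percentage of reliable read k-mers (count >= threshold, i.e. unlikely to
#' be sequencing errors) that are present in the assembly.
#'
#' @param assembly_db,read_db `kmer_db` objects with equal k.
#' @param threshold minimum read count for a k-mer to be considered
#'   reliable; default from [reliable_threshold()] on the read histogram.
#' @return list with `completeness` (percent), `reliable_total`,
#'   `reliable_found`, `threshold`.
#' @export
kmer_completeness <- function(assembly_db, read_db,
                              threshold = reliable_threshold(read_db)) {
  stopifnot(inherits(assembly_db, "kmer_db"), inherits(read_db, "kmer_db"))
  if (assembly_db$k != read_db$k) {
    stop("assembly and read databases must share k", call. = FALSE)
  }
  reliable <- read_db$code[read_db$count >= threshold]
  if (!length(reliable)) {
    return(list(completeness = 0, reliable_total = 0L, reliable_found = 0L,
                threshold = threshold))
  }
  found <- sum(reliable %in% assembly_db$code)
  list(completeness = 100 * found / length(reliable),
       reliable_total = length(reliable), reliable_found = found,
       threshold = threshold)
}

#' Genome size from a read k-mer histogram
#'
#' The standard spectrum estimate: total k-mer instances above the
#' reliable-count threshold divided by the modal (coverage-peak) count.
#'
#' @param histogram data.frame `count`/`freq` or a `kmer_db` of reads.
#' @param k k-mer length (informational; the estimate is in k-mer space).
#' @return estimated genome size in bp (numeric).
#' @export
genome_size_from_histogram <- function(histogram, k = 21L) {
  if (inherits(histogram, "kmer_db")) histogram <- histogram$histogram
  thr <- reliable_threshold(histogram)
  h <- histogram[histogram$count >= thr, , drop = FALSE]
  if (!nrow(h)) {
    stop("no k-mer coverage peak above the error threshold; ",
         "higher read coverage is needed for a genome-size estimate",
         call. = FALSE)
  }
  modal <- h$count[which.max(h$freq)]
  if (modal <= thr) {
    stop("k-mer histogram has no separated coverage peak; ",
         "higher read coverage is needed for a genome-size estimate",
         call. = FALSE)
  }
  # frequency-weighted peak position is less sensitive to the discrete
  # mode wobbling between adjacent counts than the raw mode
  win <- h[h$count >= 0.6 * modal & h$count <= 1.4 * modal, , drop = FALSE]
  peak <- stats::weighted.mean(win$count, win$freq)
  sum(h$count * h$freq) / peak
}

#' k-mer QC summary for an assembly against reads
#'
#' Convenience wrapper building both databases and reporting QV,
#' completeness and the reliable threshold in one call.
#'
#' @param assembly,reads sequences (`DNAStringSet` or character).
#' @param k k-mer length (default 18).
#' @return data.frame with `qv`, `completeness`, `reliable_threshold`.
#' @export
kmer_qc <- function(assembly, reads, k = 18L) {
  adb <- count_kmers(assembly, k)
  rdb <- count_kmers(reads, k)
  thr <- reliable_threshold(rdb)
  data.frame(
    qv = kmer_qv(adb, rdb)$qv,
    completeness = kmer_completeness(adb, rdb, thr)$completeness,
    reliable_threshold = thr
  )
}
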