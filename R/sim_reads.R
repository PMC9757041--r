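#' Simulate long reads from a genome
#'
#' Read lengths are log-normal with the profile's median; start positions
#' are uniform over the genome (chromosomes weighted by length);
#' substitution errors are applied at the profile's per-base rate. Under
#' the HiFi profile, a read overlapping a GA/GAA low-complexity tract of
#' length L (tract extended by `dropout_flank` on both sides) is retained
#' with probability 2^(-L / dropout_halflife) — the coverage-dropout
#' phenomenon that leaves such tracts unspanned; CLR reads have no
#' dropout. Deterministic under `seed`.
#'
#' @param genome a `sim_genome` (or list with `sequences` and `truth`).
#' @param profile a [read_profile()].
#' @param target_coverage fold coverage of generated reads (coverage
#'   outside dropout regions).
#' @param seed integer seed.
#' @return `DNAStringSet` of retained reads. Attribute `placements` is a
#'   data.frame with one row per *generated* read (`read`, `chrom`,
#'   `start`, `end`, `strand`, `retained`); only retained reads appear in
#'   the returned set.
#' @export
simulate_reads <- function(genome, profile, target_coverage = 30, seed = 1L) {
  stopifnot(inherits(profile, "read_profile"), target_coverage > 0)
  sequences <- genome$sequences
  truth <- genome$truth
  with_seed(seed, {
    widths <- Biostrings::width(sequences)
    total <- sum(as.numeric(widths))
    mean_len <- profile$median_len * exp(profile$len_dispersion^2 / 2)
    n <- ceiling(total * target_coverage / mean_len)

    lens <- pmin(round(stats::rlnorm(n, log(profile$median_len),
                                     profile$len_dispersion)),
                 max(widths))
    lens <- pmax(lens, 50L)
    chrom_idx <- sample.int(length(sequences), n, replace = TRUE,
                            prob = widths / total)
    lens <- pmin(lens, widths[chrom_idx])
    starts <- floor(stats::runif(n, 1, widths[chrom_idx] - lens + 2))
    ends <- starts + lens - 1L
    strands <- sample(c("+", "-"), n, replace = TRUE)

    placements <- data.frame(
      read = sprintf("read%06d", seq_len(n)),
      chrom = names(sequences)[chrom_idx],
      start = as.integer(starts), end = as.integer(ends),
      strand = strands, retained = TRUE, stringsAsFactors = FALSE
    )

    # HiFi dropout over low-complexity tracts
    if (is.finite(profile$dropout_halflife)) {
      lc <- truth[S4Vectors::mcols(truth)$feature_class %in%
                    c("low_complexity_GA", "low_complexity_GAA")]
      if (length(lc)) {
        reads_gr <- GenomicRanges::GRanges(
          placements$chrom,
          IRanges::IRanges(placements$start, placements$end))
        lc_ext <- GenomicRanges::resize(
          lc, GenomicRanges::width(lc) + 2L * profile$dropout_flank,
          fix = "center")
        hits <- GenomicRanges::findOverlaps(reads_gr, lc_ext,
                                            ignore.strand = TRUE)
        if (length(hits)) {
          l_tract <- GenomicRanges::width(lc)[S4Vectors::subjectHits(hits)]
          p_keep <- 2^(-l_tract / profile$dropout_halflife)
          drop <- stats::runif(length(hits)) > p_keep
          dropped <- unique(S4Vectors::queryHits(hits)[drop])
          placements$retained[dropped] <- FALSE
        }
      }
    }

    kept <- which(placements$retained)
    kp <- placements[kept, , drop = FALSE]
    # bulk extraction per chromosome, then vectorised reverse-complement
    reads <- Biostrings::DNAStringSet(rep("", nrow(kp)))
    for (chr in unique(kp$chrom)) {
      sel <- which(kp$chrom == chr)
      reads[sel] <- Biostrings::extractAt(
        sequences[[chr]], IRanges::IRanges(kp$start[sel], kp$end[sel]))
    }
    neg <- kp$strand == "-"
    if (any(neg)) reads[neg] <- Biostrings::reverseComplement(reads[neg])
    # substitution errors: per-read binomial counts, in-place edits
    if (profile$per_base_error > 0) {
      w <- Biostrings::width(reads)
      k <- stats::rbinom(length(reads), w, profile$per_base_error)
      idx <- which(k > 0)
      if (length(idx)) {
        chars <- as.character(reads)
        bases <- c("A", "C", "G", "T")
        for (i in idx) {
          pos <- sample.int(w[i], k[i])
          for (p in pos) {
            old <- substr(chars[i], p, p)
            substr(chars[i], p, p) <- sample(setdiff(bases, old), 1)
          }
        }
        reads <- Biostrings::DNAStringSet(chars)
      }
    }
    names(reads) <- kp$read
    attr(reads, "placements") <- placements
    attr(reads, "profile") <- profile
    reads
  })
}

#' True-placement alignments for simulated reads
#'
#' Converts the simulator's known read placements into PAF-style primary
#' alignment records (full-length match, CIGAR `<len>M`), the input
#' expected by [genome_wide_depth()] and [allele_pileup()]. This bypasses
#' an actual aligner: placements are exact by construction.
#'
#' @param reads output of [simulate_reads()].
#' @param genome the `sim_genome` the reads were drawn from (for target
#'   lengths).
#' @return data.frame in [read_paf()] layout.
#' @export
alignments_from_truth <- function(reads, genome) {
  pl <- attr(reads, "placements")
  pl <- pl[pl$retained, , drop = FALSE]
  tlen <- stats::setNames(Biostrings::width(genome$sequences),
                          names(genome$sequences))
  w <- pl$end - pl$start + 1L
  data.frame(
    qname = pl$read, qlen = w, qstart = 1L, qend = w,
    strand = pl$strand,
    tname = pl$chrom, tlen = as.integer(tlen[pl$chrom]),
    tstart = pl$start, tend = pl$end,
    nmatch = w, alen = w, mapq = 60L,
    cigar = paste0(w, "M"), tp = "P",
    stringsAsFactors = FALSE
  )
}
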