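# Seed-and-chain local matching.
#
# All library-based similarity search in the package (annotate_library,
# count_unit_matches_on_reads) goes through one engine: exact seed words
# drawn from the consensus are located in the subject sequences with
# Biostrings::matchPDict, seed hits on the same strand are merged into
# blocks when separated by at most `max_gap` unmatched bases, and block
# identity is estimated afterwards by local alignment of sampled chunks.
# Substitution-dominated divergence (the regime simulated here and typical
# of HiFi data) leaves seed hits dense enough that block boundaries track
# the true match boundaries to within a few bases.

# Concatenate subjects with N spacers so one matchPDict call covers all.
.concat_subjects <- function(seqs, spacer_len) {
  w <- Biostrings::width(seqs)
  spacer <- strrep("N", spacer_len)
  big <- paste(as.character(seqs), collapse = spacer)
  offsets <- cumsum(c(0, utils::head(w + spacer_len, -1)))
  list(subject = Biostrings::DNAString(big), offsets = offsets, widths = w)
}

# Map merged hit ranges on the concatenated subject back to per-sequence
# coordinates. Ranges never span spacers (patterns are ACGT-only).
.split_ranges <- function(ir, offsets, widths, names) {
  if (!length(ir)) {
    return(data.frame(seqname = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  idx <- findInterval(IRanges::start(ir), offsets + 1)
  data.frame(
    seqname = names[idx],
    start = IRanges::start(ir) - offsets[idx],
    end = IRanges::end(ir) - offsets[idx],
    stringsAsFactors = FALSE
  )
}

# All overlapping seed words of a consensus (unique, ACGT only).
.seed_words <- function(consensus, seed_len) {
  s <- as.character(consensus)
  n <- nchar(s) - seed_len + 1L
  if (n < 1L) stop("consensus shorter than seed length", call. = FALSE)
  words <- unique(substring(s, seq_len(n), seq_len(n) + seed_len - 1L))
  words[!grepl("[^ACGT]", words)]
}

# Find matched blocks of `consensus` (either strand) in `subjects`.
# Returns data.frame: seqname, start, end, width, strand.
seed_match_blocks <- function(subjects, consensus, seed_len = 12L,
                              max_gap = 50L, min_len = NULL) {
  if (!methods::is(subjects, "XStringSet")) {
    subjects <- Biostrings::DNAStringSet(subjects)
  }
  if (is.null(names(subjects))) {
    names(subjects) <- paste0("seq", seq_along(subjects))
  }
  consensus <- Biostrings::DNAString(toupper(as.character(consensus)))
  cc <- .concat_subjects(subjects, seed_len)
  one_strand <- function(cons) {
    words <- .seed_words(cons, seed_len)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(words))
    m <- Biostrings::matchPDict(pd, cc$subject)
    ir <- IRanges::reduce(unlist(m), min.gapwidth = max_gap + 1L)
    .split_ranges(ir, cc$offsets, cc$widths, names(subjects))
  }
  fwd <- one_strand(consensus)
  rev <- one_strand(Biostrings::reverseComplement(consensus))
  if (nrow(fwd)) fwd$strand <- "+"
  if (nrow(rev)) rev$strand <- "-"
  out <- rbind(
    if (nrow(fwd)) fwd else NULL,
    if (nrow(rev)) rev else NULL
  )
  if (is.null(out) || !nrow(out)) {
    return(data.frame(seqname = character(), start = integer(),
                      end = integer(), width = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  out$width <- out$end - out$start + 1L
  if (!is.null(min_len)) out <- out[out$width > min_len, , drop = FALSE]
  rownames(out) <- NULL
  out[order(out$seqname, out$start), , drop = FALSE]
}

# Estimate identity of a matched block against the consensus by local
# alignment of sampled chunks. `tandem` aligns unit-sized chunks against a
# doubled consensus (rotation-proof); otherwise chunks are aligned to the
# consensus itself.
block_identity <- function(block_seq, consensus, tandem = FALSE,
                           max_chunks = 4L) {
  block_seq <- Biostrings::DNAString(as.character(block_seq))
  consensus <- Biostrings::DNAString(toupper(as.character(consensus)))
  ulen <- length(consensus)
  blen <- length(block_seq)
  target <- if (tandem) {
    Biostrings::DNAString(strrep(as.character(consensus), 2L))
  } else {
    consensus
  }
  # cap chunk size: identity is estimated from samples, and alignment is
  # quadratic in chunk length
  chunk_len <- min(blen, ulen, 1000L)
  n_chunks <- min(max_chunks, max(1L, blen %/% chunk_len))
  starts <- unique(round(seq(1, blen - chunk_len + 1, length.out = n_chunks)))
  pids <- vapply(starts, function(st) {
    chunk <- Biostrings::subseq(block_seq, st, st + chunk_len - 1L)
    # global-local: the whole chunk must align somewhere in the target,
    # so edge mismatches are counted instead of clipped away
    aln <- Biostrings::pairwiseAlignment(
      chunk, target, type = "global-local",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -2),
      gapOpening = 4, gapExtension = 2
    )
    Biostrings::pid(aln, type = "PID2") / 100
  }, numeric(1))
  mean(pids)
}

# Extend a seed block outward while the flanking sequence still matches
# the uncovered remainder of the consensus (probe identity >= floor), so
# that identity is verified over the element's full extent rather than
# its seed-dense core. A truncated element (random or N flank) stops
# extension immediately. Works in oriented (consensus-strand) space.
refine_block_extent <- function(seq, start, end, strand, consensus,
                                probe = 50L, floor = 0.6) {
  ulen <- nchar(as.character(consensus))
  blen <- end - start + 1L
  if (blen >= ulen) return(c(start, end))
  slen <- nchar(as.character(seq))
  block <- Biostrings::subseq(seq, start, end)
  if (strand == "-") block <- Biostrings::reverseComplement(block)
  aln <- Biostrings::pairwiseAlignment(
    block, consensus, type = "global-local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -2),
    gapOpening = 4, gapExtension = 2)
  srange <- c(Biostrings::start(Biostrings::subject(aln)),
              Biostrings::end(Biostrings::subject(aln)))
  probe_pid <- function(a, b) {
    if (!nchar(a) || nchar(a) != nchar(b)) return(0)
    mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
  }
  cons <- as.character(consensus)
  # uncovered consensus on the oriented-left and oriented-right side
  ext_l <- 0L
  while (srange[1] - ext_l > 1L) {
    step <- min(probe, srange[1] - ext_l - 1L)
    # position of the probe in subject coordinates
    if (strand == "+") {
      lo <- start - ext_l - step
      if (lo < 1L) break
      pseq <- as.character(Biostrings::subseq(seq, lo, lo + step - 1L))
    } else {
      hi <- end + ext_l + step
      if (hi > slen) break
      pseq <- as.character(Biostrings::reverseComplement(
        Biostrings::subseq(seq, hi - step + 1L, hi)))
    }
    pcons <- substr(cons, srange[1] - ext_l - step, srange[1] - ext_l - 1L)
    if (probe_pid(pseq, pcons) < floor) break
    ext_l <- ext_l + step
  }
  ext_r <- 0L
  while (srange[2] + ext_r < ulen) {
    step <- min(probe, ulen - srange[2] - ext_r)
    if (strand == "+") {
      hi <- end + ext_r + step
      if (hi > slen) break
      pseq <- as.character(Biostrings::subseq(seq, hi - step + 1L, hi))
    } else {
      lo <- start - ext_r - step
      if (lo < 1L) break
      pseq <- as.character(Biostrings::reverseComplement(
        Biostrings::subseq(seq, lo, lo + step - 1L)))
    }
    pcons <- substr(cons, srange[2] + ext_r + 1L, srange[2] + ext_r + step)
    if (probe_pid(pseq, pcons) < floor) break
    ext_r <- ext_r + step
  }
  if (strand == "+") {
    c(start - ext_l, end + ext_r)
  } else {
    c(start - ext_r, end + ext_l)
  }
}
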