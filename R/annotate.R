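#' Find telomere arrays
#'
#' Maximal runs of tandem telomere-motif copies on either strand. Exact
#' motif occurrences are chained when consecutive copies are at most one
#' mutated copy apart; a run is reported when it holds at least
#' `min_copies` copies with at most 10% of them mismatching.
#'
#' @param sequences `DNAStringSet` (named) or single sequence.
#' @param motif telomere motif (default "CCCTAAA").
#' @param min_copies minimum tandem copies (default 10).
#' @return `GRanges` with `feature_class = "telomere"`, strand, and a
#'   `copies` column.
#' @export
find_telomere_arrays <- function(sequences, motif = "CCCTAAA",
                                 min_copies = 10L) {
  stopifnot(nchar(motif) >= 4)
  sequences <- .as_named_set(sequences)
  mlen <- nchar(motif)
  scan <- function(seq, pat, strand) {
    m <- Biostrings::matchPattern(pat, seq)
    st <- Biostrings::start(m)
    if (!length(st)) return(NULL)
    # chain: allow skipping at most one mutated copy between exact copies
    grp <- cumsum(c(TRUE, diff(st) > 2L * mlen | diff(st) %% mlen != 0))
    out <- lapply(split(st, grp), function(s) {
      total <- (s[length(s)] - s[1]) %/% mlen + 1L
      matched <- length(s)
      if (matched < 1 || (total - matched) / total > 0.1) return(NULL)
      if (total < min_copies) return(NULL)
      data.frame(start = s[1], end = s[length(s)] + mlen - 1L,
                 strand = strand, copies = total)
    })
    do.call(rbind, out)
  }
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(motif)))
  res <- lapply(names(sequences), function(nm) {
    hits <- rbind(scan(sequences[[nm]], motif, "+"),
                  scan(sequences[[nm]], rc, "-"))
    if (is.null(hits) || !nrow(hits)) return(NULL)
    hits$chrom <- nm
    hits
  })
  res <- do.call(rbind, res)
  if (is.null(res)) return(.empty_features())
  gr <- feature_granges(res$chrom, res$start, res$end, "telomere",
                        res$strand, copies = res$copies)
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

.as_named_set <- function(sequences) {
  if (!methods::is(sequences, "XStringSet")) {
    sequences <- Biostrings::DNAStringSet(sequences)
  }
  if (is.null(names(sequences))) {
    names(sequences) <- paste0("seq", seq_along(sequences))
  }
  sequences
}

.empty_features <- function() {
  feature_granges(character(), integer(), integer(), character())
}

#' Find tandem satellite arrays by monomer-seeded scan
#'
#' Seeds from the monomer consensus (both orientations) are located in the
#' subject and chained into strand blocks; adjacent blocks form an array.
#' Monomer count is the array span divided by the monomer length; mean
#' identity is estimated by local alignment of sampled monomer-sized
#' chunks against the doubled consensus (rotation-invariant). On
#' substitution-diverged arrays the reported boundaries track the true
#' edges to within one monomer.
#'
#' @param sequences `DNAStringSet` or single sequence.
#' @param monomer monomer consensus, 50-20000 bp.
#' @param min_identity minimum mean identity (default 0.8).
#' @param min_array_len minimum array span in bp (default 2 monomers).
#' @param seed_len seed word length (default 12).
#' @return list: `arrays` (`GRanges`, class `centromere_satellite`, with
#'   `monomer_count` and `mean_identity`), `strand_blocks` (`GRanges` with
#'   an `array` index column).
#' @export
find_tandem_arrays <- function(sequences, monomer, min_identity = 0.8,
                               min_array_len = NULL, seed_len = 12L) {
  mlen <- nchar(as.character(monomer))
  if (mlen < 50 || mlen > 20000) {
    stop("monomer must be 50-20000 bp", call. = FALSE)
  }
  if (mlen <= seed_len) stop("monomer shorter than seed size", call. = FALSE)
  if (is.null(min_array_len)) min_array_len <- 2L * mlen
  sequences <- .as_named_set(sequences)
  blocks <- seed_match_blocks(sequences, monomer, seed_len = seed_len,
                              max_gap = mlen, min_len = mlen)
  if (!nrow(blocks)) {
    return(list(arrays = .empty_features(), strand_blocks = .empty_features()))
  }
  bl_gr <- feature_granges(blocks$seqname, blocks$start, blocks$end,
                           "centromere_satellite", blocks$strand)
  bl_gr <- GenomicRanges::sort(bl_gr, ignore.strand = TRUE)
  # arrays: blocks (either strand) merged across gaps up to one monomer
  arr <- GenomicRanges::reduce(bl_gr, min.gapwidth = mlen,
                               ignore.strand = TRUE)
  arr <- arr[GenomicRanges::width(arr) >= min_array_len]
  if (!length(arr)) {
    return(list(arrays = .empty_features(), strand_blocks = .empty_features()))
  }
  # identity per strand block (oriented), length-weighted per array, so
  # that chunks never straddle an inversion boundary
  ov0 <- GenomicRanges::findOverlaps(bl_gr, arr, ignore.strand = TRUE)
  ident <- vapply(seq_along(arr), function(i) {
    bl <- bl_gr[S4Vectors::queryHits(ov0)[S4Vectors::subjectHits(ov0) == i]]
    ids <- vapply(seq_along(bl), function(b) {
      s <- Biostrings::subseq(
        sequences[[as.character(GenomicRanges::seqnames(bl))[b]]],
        GenomicRanges::start(bl)[b], GenomicRanges::end(bl)[b])
      if (as.character(GenomicRanges::strand(bl))[b] == "-") {
        s <- Biostrings::reverseComplement(s)
      }
      block_identity(s, monomer, tandem = TRUE)
    }, numeric(1))
    stats::weighted.mean(ids, GenomicRanges::width(bl))
  }, numeric(1))
  keep <- ident >= min_identity
  arr <- arr[keep]
  ident <- ident[keep]
  arrays <- feature_granges(
    as.character(GenomicRanges::seqnames(arr)),
    GenomicRanges::start(arr), GenomicRanges::end(arr),
    rep("centromere_satellite", length(arr)),
    monomer_count = round(GenomicRanges::width(arr) / mlen),
    mean_identity = ident
  )
  ov <- GenomicRanges::findOverlaps(bl_gr, arrays, ignore.strand = TRUE)
  sb <- bl_gr[S4Vectors::queryHits(ov)]
  S4Vectors::mcols(sb)$array <- S4Vectors::subjectHits(ov)
  list(arrays = arrays, strand_blocks = sb)
}

#' Find GA/GAA low-complexity tracts
#'
#' Maximal intervals in which the fraction of bases covered by exact motif
#' occurrences (on either strand, so GA covers TC and GAA covers TTC) is
#' at least `min_purity`. Candidate intervals are built by merging motif
#' matches across gaps of up to `gap_tol` bases and then filtered by
#' purity; the purity is reported per interval. Detection is
#' strand-symmetric by construction.
#'
#' @param sequences `DNAStringSet` or single sequence.
#' @param motif_classes motifs to scan (default c("GA", "GAA")).
#' @param min_len minimum tract length (>= 50; default 100).
#' @param min_purity minimum covered-base fraction in (0.5, 1].
#' @param gap_tol maximum uncovered gap merged into a tract (default 10).
#' @return `GRanges` with class `low_complexity_GA` / `low_complexity_GAA`
#'   and a `purity` (score) column.
#' @export
find_low_complexity <- function(sequences, motif_classes = c("GA", "GAA"),
                                min_len = 100L, min_purity = 0.85,
                                gap_tol = 10L) {
  stopifnot(min_len >= 50, min_purity > 0.5, min_purity <= 1)
  sequences <- .as_named_set(sequences)
  res <- list()
  for (motif in motif_classes) {
    cls <- paste0("low_complexity_", motif)
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(motif)))
    for (nm in names(sequences)) {
      cov <- IRanges::IRanges()
      for (pat in unique(c(motif, rc))) {
        m <- Biostrings::matchPattern(pat, sequences[[nm]])
        cov <- c(cov, methods::as(m, "IRanges"))
      }
      cov <- IRanges::reduce(cov)
      if (!length(cov)) next
      cand <- IRanges::reduce(cov, min.gapwidth = gap_tol + 1L)
      cand <- cand[IRanges::width(cand) >= min_len]
      if (!length(cand)) next
      # trim weakly attached edge runs: an outermost covered run shorter
      # than the gap separating it from the rest drags purity down
      cand <- do.call(c, lapply(seq_along(cand), function(i) {
        runs <- IRanges::restrict(cov, IRanges::start(cand)[i],
                                  IRanges::end(cand)[i])
        while (length(runs) > 1) {
          gap_l <- IRanges::start(runs)[2] - IRanges::end(runs)[1] - 1L
          gap_r <- IRanges::start(runs)[length(runs)] -
            IRanges::end(runs)[length(runs) - 1] - 1L
          if (IRanges::width(runs)[1] <= gap_l) {
            runs <- runs[-1]
          } else if (IRanges::width(runs)[length(runs)] <= gap_r) {
            runs <- runs[-length(runs)]
          } else {
            break
          }
        }
        IRanges::IRanges(min(IRanges::start(runs)),
                         max(IRanges::end(runs)))
      }))
      cand <- cand[IRanges::width(cand) >= min_len]
      if (!length(cand)) next
      covered <- vapply(seq_along(cand), function(i) {
        sum(IRanges::width(IRanges::restrict(
          cov, IRanges::start(cand)[i], IRanges::end(cand)[i])))
      }, numeric(1))
      purity <- covered / IRanges::width(cand)
      keep <- purity >= min_purity
      if (!any(keep)) next
      res[[length(res) + 1L]] <- data.frame(
        chrom = nm, start = IRanges::start(cand)[keep],
        end = IRanges::end(cand)[keep], class = cls,
        purity = purity[keep], stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, res)
  if (is.null(res)) return(.empty_features())
  gr <- feature_granges(res$chrom, res$start, res$end, res$class,
                        score = res$purity)
  S4Vectors::mcols(gr)$purity <- res$purity
  # where GA and GAA candidates overlap, the purer call wins
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  ov <- GenomicRanges::findOverlaps(gr, drop.self = TRUE,
                                    drop.redundant = TRUE,
                                    ignore.strand = TRUE)
  if (length(ov)) {
    drop <- ifelse(
      S4Vectors::mcols(gr)$purity[S4Vectors::queryHits(ov)] >=
        S4Vectors::mcols(gr)$purity[S4Vectors::subjectHits(ov)],
      S4Vectors::subjectHits(ov), S4Vectors::queryHits(ov))
    gr <- gr[-unique(drop)]
  }
  gr
}

#' Annotate sequences with a repeat library
#'
#' Seed-and-chain local matching of each library entry (both strands),
#' with per-entry minimum match length and identity thresholds. Identity
#' is estimated by local alignment of sampled chunks; overlapping hits of
#' one entry are merged. Entries of tandem classes (rDNAs, satellite) are
#' verified against the doubled consensus so rotated matches score fully.
#'
#' @param sequences `DNAStringSet` or single sequence.
#' @param library data.frame with columns `name`, `class`, `consensus`,
#'   `min_match_len`, `min_identity` (defaults 100 bp / 0.8 applied where
#'   columns are missing).
#' @return `GRanges` with `feature_class`, `entry`, `identity` columns.
#' @export
annotate_library <- function(sequences, library) {
  stopifnot(nrow(library) >= 1)
  assert_class_known(library$class, "library class")
  if (is.null(library$min_match_len)) library$min_match_len <- 100L
  if (is.null(library$min_identity)) library$min_identity <- 0.8
  sequences <- .as_named_set(sequences)
  tandem_classes <- c("rDNA_5S", "rDNA_45S", "centromere_satellite",
                      "telomere")
  res <- list()
  for (e in seq_len(nrow(library))) {
    blocks <- seed_match_blocks(sequences, library$consensus[e],
                                min_len = library$min_match_len[e])
    if (!nrow(blocks)) next
    tandem <- library$class[e] %in% tandem_classes
    # sub-consensus blocks: push the boundaries out to the element's true
    # extent before judging identity, so a uniformly diverged element is
    # not accepted on the strength of its seed-dense core
    for (i in seq_len(nrow(blocks))) {
      ext <- refine_block_extent(sequences[[blocks$seqname[i]]],
                                 blocks$start[i], blocks$end[i],
                                 blocks$strand[i], library$consensus[e])
      blocks$start[i] <- ext[1]
      blocks$end[i] <- ext[2]
    }
    blocks$width <- blocks$end - blocks$start + 1L
    ident <- vapply(seq_len(nrow(blocks)), function(i) {
      s <- Biostrings::subseq(sequences[[blocks$seqname[i]]],
                              blocks$start[i], blocks$end[i])
      if (blocks$strand[i] == "-") s <- Biostrings::reverseComplement(s)
      block_identity(s, library$consensus[e], tandem = tandem)
    }, numeric(1))
    keep <- ident >= library$min_identity[e]
    if (!any(keep)) next
    blocks <- blocks[keep, , drop = FALSE]
    gr <- feature_granges(blocks$seqname, blocks$start, blocks$end,
                          rep(library$class[e], nrow(blocks)),
                          blocks$strand,
                          entry = library$name[e],
                          identity = ident[keep])
    # merge overlapping hits of this entry (strand of the longer wins)
    red <- GenomicRanges::reduce(gr, ignore.strand = TRUE,
                                 with.revmap = TRUE)
    if (length(red) < length(gr)) {
      revmap <- S4Vectors::mcols(red)$revmap
      pick <- vapply(revmap, function(ix) {
        ix[which.max(GenomicRanges::width(gr)[ix])]
      }, integer(1))
      merged <- feature_granges(
        as.character(GenomicRanges::seqnames(red)),
        GenomicRanges::start(red), GenomicRanges::end(red),
        rep(library$class[e], length(red)),
        as.character(GenomicRanges::strand(gr))[pick],
        entry = library$name[e],
        identity = vapply(revmap, function(ix) {
          mean(S4Vectors::mcols(gr)$identity[ix])
        }, numeric(1)))
      gr <- merged
    }
    res[[length(res) + 1L]] <- gr
  }
  if (!length(res)) return(.empty_features())
  out <- do.call(c, res)
  GenomicRanges::sort(out, ignore.strand = TRUE)
}

#' Resolve overlapping annotations by class hierarchy
#'
#' Where classes overlap, the higher-priority class keeps its full extent
#' and lower-priority intervals are truncated or dropped, so that every
#' base carries at most one class. The operation is idempotent and
#' conserves every base of the top-priority class.
#'
#' @param annotations `GRanges` with a `feature_class` column.
#' @param hierarchy character vector, highest priority first; must cover
#'   every class present.
#' @return non-overlapping, sorted `GRanges`.
#' @export
merge_hierarchy <- function(annotations, hierarchy = default_hierarchy) {
  assert_class_known(hierarchy, "hierarchy class")
  present <- unique(S4Vectors::mcols(annotations)$feature_class)
  missing <- setdiff(present, hierarchy)
  if (length(missing)) {
    stop("annotation classes missing from hierarchy: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  covered <- GenomicRanges::GRanges()
  out <- list()
  for (cls in hierarchy) {
    sub <- annotations[S4Vectors::mcols(annotations)$feature_class == cls]
    if (!length(sub)) next
    unstranded <- GenomicRanges::GRanges(
      GenomicRanges::seqnames(sub),
      IRanges::ranges(sub))
    GenomeInfoDb::seqlevels(covered) <- union(
      GenomeInfoDb::seqlevels(covered), GenomeInfoDb::seqlevels(unstranded))
    GenomeInfoDb::seqlevels(unstranded) <- GenomeInfoDb::seqlevels(covered)
    kept <- GenomicRanges::setdiff(GenomicRanges::reduce(unstranded),
                                   covered, ignore.strand = TRUE)
    if (length(kept)) {
      # inherit strand from the donor interval with the largest overlap
      ov <- GenomicRanges::findOverlaps(kept, sub, ignore.strand = TRUE)
      ovw <- IRanges::width(IRanges::pintersect(
        IRanges::ranges(kept)[S4Vectors::queryHits(ov)],
        IRanges::ranges(sub)[S4Vectors::subjectHits(ov)]))
      best <- tapply(seq_along(ov), S4Vectors::queryHits(ov), function(ix) {
        S4Vectors::subjectHits(ov)[ix[which.max(ovw[ix])]]
      })
      strand <- rep("*", length(kept))
      strand[as.integer(names(best))] <-
        as.character(GenomicRanges::strand(sub))[unlist(best)]
      out[[cls]] <- feature_granges(
        as.character(GenomicRanges::seqnames(kept)),
        GenomicRanges::start(kept), GenomicRanges::end(kept),
        rep(cls, length(kept)), strand)
      covered <- GenomicRanges::union(covered, kept, ignore.strand = TRUE)
    }
  }
  if (!length(out)) return(.empty_features())
  GenomicRanges::sort(do.call(c, unname(out)), ignore.strand = TRUE)
}

#' Windowed pairwise identity map
#'
#' Splits a region into fixed-size windows and computes the best local
#' alignment identity between every window pair on both strands — the
#' windowed dot-plot style view used to compare satellite array structure.
#'
#' @param region_seq sequence (`DNAString` or character) of the region.
#' @param window window size in bp (default 5000).
#' @param min_align_len minimum local alignment length for a reportable
#'   identity (default half the window); weaker pairs get NA.
#' @return list: `identity` (symmetric matrix, diagonal 1), `strand`
#'   (character matrix), `windows` (data.frame of window coordinates).
#' @export
identity_map <- function(region_seq, window = 5000L,
                         min_align_len = window %/% 2L) {
  region_seq <- Biostrings::DNAString(as.character(region_seq))
  n <- length(region_seq) %/% window
  if (n < 2) stop("region shorter than two windows", call. = FALSE)
  wins <- lapply(seq_len(n), function(i) {
    Biostrings::subseq(region_seq, (i - 1L) * window + 1L, i * window)
  })
  id <- diag(1, n)
  strand <- matrix(".", n, n)
  diag(strand) <- "+"
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      fwd <- Biostrings::pairwiseAlignment(
        wins[[i]], wins[[j]], type = "local", substitutionMatrix = mat,
        gapOpening = 4, gapExtension = 2)
      rev <- Biostrings::pairwiseAlignment(
        wins[[i]], Biostrings::reverseComplement(wins[[j]]),
        type = "local", substitutionMatrix = mat,
        gapOpening = 4, gapExtension = 2)
      best <- if (Biostrings::score(fwd) >= Biostrings::score(rev)) {
        list(aln = fwd, strand = "+")
      } else {
        list(aln = rev, strand = "-")
      }
      alen <- Biostrings::nchar(Biostrings::pattern(best$aln))
      if (alen >= min_align_len) {
        id[i, j] <- id[j, i] <- Biostrings::pid(best$aln, "PID2") / 100
        strand[i, j] <- strand[j, i] <- best$strand
      } else {
        id[i, j] <- id[j, i] <- NA_real_
      }
    }
  }
  windows <- data.frame(window = seq_len(n),
                        start = (seq_len(n) - 1L) * window + 1L,
                        end = seq_len(n) * window)
  list(identity = id, strand = strand, windows = windows)
}

#' Full repeat annotation of an assembly
#'
#' Runs the telomere, satellite, low-complexity and library annotators and
#' resolves overlaps with [merge_hierarchy()].
#'
#' @param sequences `DNAStringSet`.
#' @param library repeat library data.frame (see [annotate_library()]);
#'   the entry of class `centromere_satellite` seeds the tandem-array
#'   scan and is excluded from plain library matching.
#' @param telomere_motif telomere motif.
#' @param hierarchy class priority for overlap resolution.
#' @param lc_min_len,lc_min_purity low-complexity thresholds.
#' @return non-overlapping `GRanges` annotation.
#' @export
annotate_assembly <- function(sequences, library,
                              telomere_motif = "CCCTAAA",
                              hierarchy = default_hierarchy,
                              lc_min_len = 100L, lc_min_purity = 0.85) {
  sequences <- .as_named_set(sequences)
  parts <- list()
  parts$tel <- find_telomere_arrays(sequences, telomere_motif)
  sat <- library[library$class == "centromere_satellite", , drop = FALSE]
  if (nrow(sat)) {
    ta <- find_tandem_arrays(sequences, sat$consensus[1])
    parts$sat <- ta$arrays
  }
  parts$lc <- find_low_complexity(sequences, min_len = lc_min_len,
                                  min_purity = lc_min_purity)
  lib <- library[!library$class %in% c("centromere_satellite", "telomere"), ,
                 drop = FALSE]
  if (nrow(lib)) parts$lib <- annotate_library(sequences, lib)
  parts <- Filter(length, parts)
  if (!length(parts)) return(.empty_features())
  anno <- do.call(c, lapply(unname(parts), function(g) {
    S4Vectors::mcols(g) <- S4Vectors::mcols(g)["feature_class"]
    g
  }))
  merge_hierarchy(anno, hierarchy)
}
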