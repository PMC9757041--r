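#' Classify scaffold gaps by flanking (or patch) repeats
#'
#' Each gap's cause is the highest-priority annotated class intersecting
#' either flank window. When a donor patch sequence is available for a
#' gap, the low-complexity classes are additionally tested on the patch
#' itself (the gap's true content outranks its surroundings for GA/GAA
#' tracts, which are exactly what assemblers drop). Gaps with no
#' annotated flank element are `"unknown"`.
#'
#' @param scaffolds `DNAStringSet` of scaffold sequences.
#' @param annotation `GRanges` annotation in scaffold coordinates.
#' @param plan optional [scaffold_plan] locating the gaps (otherwise
#'   N-runs are used).
#' @param flank_window bp of flank inspected on each side (default 2000).
#' @param donor_patches optional character vector (length = number of
#'   gaps, NA allowed) of patch sequences recovered for each gap.
#' @param hierarchy class priority.
#' @return data.frame of gap records: `scaffold`, `gap_start`, `gap_end`,
#'   `left_flank_end`, `gap_len_estimate`, `cause`.
#' @export
classify_gaps <- function(scaffolds, annotation, plan = NULL,
                          flank_window = 2000L, donor_patches = NULL,
                          hierarchy = default_hierarchy) {
  gaps <- find_gaps(scaffolds, plan)
  if (!nrow(gaps)) {
    gaps$cause <- character(0)
    gaps$left_flank_end <- integer(0)
    return(gaps)
  }
  if (!is.null(donor_patches) && length(donor_patches) != nrow(gaps)) {
    stop("donor_patches must have one entry per gap", call. = FALSE)
  }
  prio <- stats::setNames(seq_along(hierarchy), hierarchy)
  anno_chrom <- as.character(GenomicRanges::seqnames(annotation))
  widths <- stats::setNames(Biostrings::width(scaffolds), names(scaffolds))
  cause <- character(nrow(gaps))
  for (i in seq_len(nrow(gaps))) {
    cause[i] <- "unknown"
    # donor patch content takes precedence for low-complexity classes
    if (!is.null(donor_patches) && !is.na(donor_patches[i]) &&
        nzchar(donor_patches[i])) {
      lc <- find_low_complexity(donor_patches[i],
                                min_len = max(50L, min(
                                  100L, nchar(donor_patches[i]))))
      if (length(lc)) {
        best <- which.max(GenomicRanges::width(lc))
        if (GenomicRanges::width(lc)[best] >=
            0.5 * nchar(donor_patches[i])) {
          cause[i] <- S4Vectors::mcols(lc)$feature_class[best]
          next
        }
      }
    }
    w <- widths[[gaps$scaffold[i]]]
    lo <- max(1L, gaps$gap_start[i] - flank_window)
    hi <- min(w, gaps$gap_end[i] + flank_window)
    a <- annotation[anno_chrom == gaps$scaffold[i]]
    inflank <- (GenomicRanges::end(a) >= lo &
                  GenomicRanges::start(a) < gaps$gap_start[i]) |
      (GenomicRanges::start(a) <= hi &
         GenomicRanges::end(a) > gaps$gap_end[i])
    if (any(inflank)) {
      cls <- S4Vectors::mcols(a)$feature_class[inflank]
      cause[i] <- cls[order(prio[cls])[1]]
    }
  }
  gaps$left_flank_end <- gaps$gap_start - 1L
  gaps$cause <- cause
  gaps
}

# locate an anchor sequence in the donor set; exact match first, seeded +
# identity-verified fallback. Returns data.frame(donor,start,end,strand)
# of hits.
.locate_anchor <- function(anchor, donor, anchor_identity, seed_len = 200L) {
  anchor <- Biostrings::DNAString(anchor)
  hits <- list()
  for (nm in names(donor)) {
    for (std in c("+", "-")) {
      subj <- donor[[nm]]
      pat <- if (std == "+") anchor else Biostrings::reverseComplement(anchor)
      m <- Biostrings::matchPattern(pat, subj)
      if (length(m)) {
        hits[[length(hits) + 1L]] <- data.frame(
          donor = nm, start = Biostrings::start(m),
          end = Biostrings::end(m), strand = std,
          stringsAsFactors = FALSE)
      }
    }
  }
  hits <- do.call(rbind, hits)
  if (!is.null(hits) && nrow(hits)) return(hits)
  # seeded fallback: exact core word, then identity check over the span
  core <- Biostrings::subseq(anchor,
                             max(1L, length(anchor) %/% 2L - seed_len %/% 2L),
                             width = min(seed_len, length(anchor)))
  out <- list()
  for (nm in names(donor)) {
    for (std in c("+", "-")) {
      pat <- if (std == "+") core else Biostrings::reverseComplement(core)
      m <- Biostrings::matchPattern(pat, donor[[nm]])
      for (k in seq_along(m)) {
        off <- Biostrings::start(m)[k] -
          (max(1L, length(anchor) %/% 2L - seed_len %/% 2L) - 1L)
        st <- off
        en <- off + length(anchor) - 1L
        if (st < 1 || en > length(donor[[nm]])) next
        span <- Biostrings::subseq(donor[[nm]], st, en)
        if (std == "-") span <- Biostrings::reverseComplement(span)
        pid <- Biostrings::pid(Biostrings::pairwiseAlignment(
          anchor, span, type = "global"), "PID1") / 100
        if (pid >= anchor_identity) {
          out[[length(out) + 1L]] <- data.frame(
            donor = nm, start = st, end = en, strand = std,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  hits <- do.call(rbind, out)
  if (is.null(hits)) {
    data.frame(donor = character(), start = integer(), end = integer(),
               strand = character(), stringsAsFactors = FALSE)
  } else {
    hits
  }
}

#' Patch scaffold gaps from a donor assembly
#'
#' For each gap, the two gap-adjacent flank anchors are located in the
#' donor assembly; when both anchor uniquely, on the same donor contig, in
#' a consistent orientation and order, the gap's N run is replaced by the
#' donor sequence between the anchors. Bases outside replaced gap spans
#' are never altered. Failure reasons are recorded per gap:
#' `no_anchor`, `ambiguous_anchor`, `inconsistent_anchors`,
#' `span_too_long`.
#'
#' @param scaffolds `DNAStringSet` of scaffolds with N gaps.
#' @param donor `DNAStringSet` donor assembly.
#' @param plan optional [scaffold_plan] locating gaps.
#' @param anchor_len flank anchor length (default 5000).
#' @param anchor_identity minimum anchor identity for seeded matches
#'   (default 0.99).
#' @param max_span donor spans longer than this are rejected as likely
#'   mis-anchoring (default 50000).
#' @return list: `scaffolds` (patched `DNAStringSet`), `gaps` (data.frame
#'   with `patch_len`, `patch_source`, `patch_seq`, `reason`).
#' @export
patch_gaps <- function(scaffolds, donor, plan = NULL, anchor_len = 5000L,
                       anchor_identity = 0.99, max_span = 50000L) {
  gaps <- find_gaps(scaffolds, plan)
  gaps$patch_len <- rep(NA_integer_, nrow(gaps))
  gaps$patch_source <- rep(NA_character_, nrow(gaps))
  gaps$patch_seq <- rep(NA_character_, nrow(gaps))
  gaps$reason <- rep(NA_character_, nrow(gaps))
  if (!nrow(gaps)) return(list(scaffolds = scaffolds, gaps = gaps))
  out <- as.list(as.character(scaffolds))
  names(out) <- names(scaffolds)
  # patch right-to-left so earlier gap coordinates stay valid
  ord <- order(gaps$scaffold, -gaps$gap_start)
  for (i in ord) {
    sc <- gaps$scaffold[i]
    seq <- out[[sc]]
    gs <- gaps$gap_start[i]; ge <- gaps$gap_end[i]
    left <- substr(seq, max(1L, gs - anchor_len), gs - 1L)
    right <- substr(seq, ge + 1L, min(nchar(seq), ge + anchor_len))
    if (nchar(left) < 500L || nchar(right) < 500L ||
        grepl("N", left, fixed = TRUE) || grepl("N", right, fixed = TRUE)) {
      gaps$reason[i] <- "no_anchor"
      next
    }
    lh <- .locate_anchor(left, donor, anchor_identity)
    rh <- .locate_anchor(right, donor, anchor_identity)
    if (!nrow(lh) || !nrow(rh)) {
      gaps$reason[i] <- "no_anchor"
      next
    }
    if (nrow(lh) > 1 || nrow(rh) > 1) {
      gaps$reason[i] <- "ambiguous_anchor"
      next
    }
    ok <- lh$donor == rh$donor & lh$strand == rh$strand &
      ((lh$strand == "+" & lh$end < rh$start) |
         (lh$strand == "-" & rh$end < lh$start))
    if (!ok) {
      gaps$reason[i] <- "inconsistent_anchors"
      next
    }
    if (lh$strand == "+") {
      span_start <- lh$end + 1L; span_end <- rh$start - 1L
    } else {
      span_start <- rh$end + 1L; span_end <- lh$start - 1L
    }
    span <- if (span_end < span_start) "" else {
      as.character(Biostrings::subseq(donor[[lh$donor]],
                                      span_start, span_end))
    }
    if (lh$strand == "-" && nzchar(span)) {
      span <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(span)))
    }
    if (nchar(span) > max_span) {
      gaps$reason[i] <- "span_too_long"
      next
    }
    out[[sc]] <- paste0(substr(seq, 1L, gs - 1L), span,
                        substr(seq, ge + 1L, nchar(seq)))
    gaps$patch_len[i] <- nchar(span)
    gaps$patch_source[i] <- lh$donor
    gaps$patch_seq[i] <- span
  }
  patched <- Biostrings::DNAStringSet(unlist(out))
  names(patched) <- names(scaffolds)
  list(scaffolds = patched, gaps = gaps[order(gaps$scaffold,
                                              gaps$gap_start), ,
                                        drop = FALSE])
}

#' Concordance of two sets of gap-size estimates
#'
#' Pairs gap-size estimates from two sources (e.g. optical-map estimates
#' and recovered patch lengths) by scaffold and gap position and reports
#' the Pearson correlation. With fewer than 3 complete pairs, or a
#' zero-variance vector, `r` is NA with a warning.
#'
#' @param estimates_a,estimates_b data.frames with `scaffold`,
#'   `gap_start` and `estimate` columns.
#' @return list: `pairs` (merged data.frame), `r` (Pearson correlation or
#'   NA).
#' @export
gap_size_concordance <- function(estimates_a, estimates_b) {
  pairs <- merge(estimates_a, estimates_b,
                 by = c("scaffold", "gap_start"),
                 suffixes = c("_a", "_b"))
  pairs <- pairs[!is.na(pairs$estimate_a) & !is.na(pairs$estimate_b), ,
                 drop = FALSE]
  r <- NA_real_
  if (nrow(pairs) < 3) {
    warning("fewer than 3 matched gap pairs; correlation omitted")
  } else if (stats::sd(pairs$estimate_a) == 0 ||
             stats::sd(pairs$estimate_b) == 0) {
    warning("constant estimate vector; correlation undefined")
  } else {
    r <- stats::cor(pairs$estimate_a, pairs$estimate_b)
  }
  list(pairs = pairs, r = r)
}
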