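#' Primary/secondary allele pileup
#'
#' Builds, for every assembly position covered by primary alignments, the
#' count of the most frequent (primary) and second most frequent
#' (secondary) read base. A faithfully assembled locus shows secondary
#' counts near zero; a collapsed duplication shows recurrent secondary
#' alleles at the sites where the collapsed copies diverge; sequencing
#' bias raises the primary depth without secondary support.
#'
#' @param alignments data.frame in [read_paf()] layout with `cg:Z` CIGARs
#'   (`tp:A:S` secondary records are dropped; records without a CIGAR are
#'   skipped with a warning).
#' @param reads `DNAStringSet` of the aligned reads (named).
#' @param assembly `DNAStringSet` of the target sequences.
#' @param region optional `"chr:start-end"` (or list) restricting the
#'   track.
#' @return data.frame track: `chrom`, `pos`, `depth`, `primary`,
#'   `secondary`.
#' @export
allele_pileup <- function(alignments, reads, assembly, region = NULL) {
  aln <- alignments[is.na(alignments$tp) | alignments$tp == "P", ,
                    drop = FALSE]
  no_cigar <- is.na(aln$cigar)
  if (any(no_cigar)) {
    warning(sum(no_cigar), " alignments without CIGAR skipped")
    aln <- aln[!no_cigar, , drop = FALSE]
  }
  if (!is.null(region) && is.character(region)) {
    m <- regexec("^(.+):([0-9]+)-([0-9]+)$", region)
    m <- regmatches(region, m)[[1]]
    region <- list(tname = m[2], start = as.integer(m[3]),
                   end = as.integer(m[4]))
  }
  targets <- if (is.null(region)) names(assembly) else region$tname
  base_code <- integer(256)
  base_code[utf8ToInt("A")] <- 1L
  base_code[utf8ToInt("C")] <- 2L
  base_code[utf8ToInt("G")] <- 3L
  base_code[utf8ToInt("T")] <- 4L
  tracks <- list()
  for (tn in targets) {
    lo <- if (is.null(region)) 1L else region$start
    hi <- if (is.null(region)) {
      Biostrings::width(assembly)[names(assembly) == tn]
    } else {
      region$end
    }
    wlen <- hi - lo + 1L
    counts <- matrix(0L, nrow = 4L, ncol = wlen)
    sub <- aln[aln$tname == tn & aln$tstart <= hi & aln$tend >= lo, ,
               drop = FALSE]
    for (k in seq_len(nrow(sub))) {
      rd <- reads[[sub$qname[k]]]
      if (sub$strand[k] == "-") {
        rd <- Biostrings::reverseComplement(rd)
        qs <- length(rd) - sub$qend[k] + 1L
      } else {
        qs <- sub$qstart[k]
      }
      cig <- parse_cigar(sub$cigar[k])
      tpos <- sub$tstart[k]
      qpos <- qs
      rchars <- utf8ToInt(as.character(rd))
      for (ci in seq_along(cig$op)) {
        op <- cig$op[ci]; len <- cig$len[ci]
        if (op %in% c("M", "=", "X")) {
          t0 <- tpos; t1 <- tpos + len - 1L
          c0 <- max(t0, lo); c1 <- min(t1, hi)
          if (c0 <= c1) {
            qoff <- qpos + (c0 - t0)
            codes <- base_code[rchars[qoff:(qoff + (c1 - c0))]]
            cols <- (c0:c1) - lo + 1L
            keep <- codes > 0L
            if (any(keep)) {
              idx <- cbind(codes[keep], cols[keep])
              counts[idx] <- counts[idx] + 1L
            }
          }
          tpos <- tpos + len; qpos <- qpos + len
        } else if (op %in% c("I", "S")) {
          qpos <- qpos + len
        } else if (op %in% c("D", "N")) {
          tpos <- tpos + len
        }
      }
    }
    depth <- colSums(counts)
    prim <- apply(counts, 2, max)
    sec <- apply(counts, 2, function(x) sort(x, decreasing = TRUE)[2])
    tracks[[tn]] <- data.frame(
      chrom = tn, pos = lo:hi, depth = depth,
      primary = prim, secondary = sec, stringsAsFactors = FALSE)
  }
  do.call(rbind, tracks)
}

#' Flag collapsed and coverage-biased regions from an allele track
#'
#' Marker positions (secondary count >= `min_secondary`) recurring at
#' `min_run` or more positions within `cluster_gap` of one another are
#' flagged `collapsed` — sequencing errors do not recur at fixed
#' positions, diverged collapsed copies do. Runs where the primary depth
#' exceeds the upper depth band without secondary support are
#' `coverage_bias`. Everything else is `normal`.
#'
#' @param track data.frame from [allele_pileup()].
#' @param min_secondary minimum secondary-allele count at a marker
#'   position (default 2).
#' @param min_run minimum marker positions per collapsed cluster
#'   (default 5).
#' @param depth_band numeric length-2 (lo, hi); default mean +/- 3 SD of
#'   the track depth.
#' @param cluster_gap maximum bp between markers of one cluster
#'   (default 2000).
#' @return data.frame: `chrom`, `start`, `end`, `label`.
#' @export
flag_regions <- function(track, min_secondary = 2L, min_run = 5L,
                         depth_band = NULL, cluster_gap = 2000L) {
  if (is.null(depth_band)) {
    depth_band <- mean(track$depth) + c(-3, 3) * stats::sd(track$depth)
  }
  out <- list()
  for (tn in unique(track$chrom)) {
    tr <- track[track$chrom == tn, , drop = FALSE]
    flagged <- IRanges::IRanges()
    # collapsed: clustered recurrent secondary alleles
    marker <- tr$pos[tr$secondary >= min_secondary]
    if (length(marker)) {
      grp <- cumsum(c(TRUE, diff(marker) > cluster_gap))
      for (g in split(marker, grp)) {
        if (length(g) >= min_run) {
          out[[length(out) + 1L]] <- data.frame(
            chrom = tn, start = g[1], end = g[length(g)],
            label = "collapsed", stringsAsFactors = FALSE)
          flagged <- c(flagged, IRanges::IRanges(g[1], g[length(g)]))
        }
      }
    }
    # coverage bias: elevated primary depth, no secondary support
    hot <- tr$primary > depth_band[2] & tr$secondary < min_secondary
    ir <- IRanges::reduce(IRanges::IRanges(hot), min.gapwidth = 50L)
    ir <- ir[IRanges::width(ir) >= min_run]
    if (length(ir)) {
      bias_start <- tr$pos[IRanges::start(ir)]
      bias_end <- tr$pos[IRanges::end(ir)]
      keep <- !IRanges::overlapsAny(
        IRanges::IRanges(bias_start, bias_end), flagged)
      if (any(keep)) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = tn, start = bias_start[keep], end = bias_end[keep],
          label = "coverage_bias", stringsAsFactors = FALSE)
        flagged <- c(flagged, IRanges::IRanges(bias_start[keep],
                                               bias_end[keep]))
      }
    }
    # normal: the complement over the track extent
    span <- IRanges::IRanges(min(tr$pos), max(tr$pos))
    normal <- IRanges::setdiff(span, IRanges::reduce(flagged))
    if (length(normal)) {
      out[[length(out) + 1L]] <- data.frame(
        chrom = tn, start = IRanges::start(normal),
        end = IRanges::end(normal), label = "normal",
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}
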