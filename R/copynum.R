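#' Count rDNA unit matches on raw reads
#'
#' Locates matches of a tandem-gene unit consensus (e.g. a ~500 bp 5S rDNA
#' unit) directly on unassembled long reads and counts unit hits. A
#' contiguous tandem stretch on one read is a single local match; it is
#' counted as `round(block_len / unit_len)` unit hits (at least one), so
#' each unit instance on each read contributes one count. Blocks no longer
#' than `min_match` are discarded.
#'
#' @param reads `DNAStringSet` of reads.
#' @param unit unit consensus sequence (`DNAString` or character).
#' @param min_match minimum match length in bp (default 100; matches must
#'   be strictly longer).
#' @param seed_len,max_gap seed-and-chain engine tuning.
#' @return list with `matches` (total unit-hit count), `blocks`
#'   (data.frame of matched blocks).
#' @export
count_unit_matches_on_reads <- function(reads, unit, min_match = 100L,
                                        seed_len = 12L, max_gap = 50L) {
  unit_len <- nchar(as.character(unit))
  stopifnot(unit_len >= min_match)
  blocks <- seed_match_blocks(reads, unit, seed_len = seed_len,
                              max_gap = max_gap, min_len = min_match)
  hits <- if (nrow(blocks)) pmax(1L, round(blocks$width / unit_len)) else integer()
  blocks$unit_hits <- hits
  list(matches = sum(hits), blocks = blocks)
}

#' Genome-wide read depth from alignments
#'
#' Mean per-base depth of primary alignments over a region, computed from
#' PAF records (records tagged `tp:A:S` — secondary — are excluded;
#' untagged records are treated as primary).
#'
#' @param alignments data.frame as from [read_paf()].
#' @param region list/character: target name, start, end (1-based closed).
#'   Character form `"chr:start-end"` is accepted.
#' @return mean fold-coverage (numeric).
#' @export
genome_wide_depth <- function(alignments, region) {
  if (is.character(region)) {
    m <- regmatches(region,
                    regexec("^(.+):([0-9]+)-([0-9]+)$", region))[[1]]
    if (length(m) != 4) stop("malformed region: ", region, call. = FALSE)
    region <- list(tname = m[2], start = as.integer(m[3]),
                   end = as.integer(m[4]))
  }
  if (region$end < region$start) stop("empty region", call. = FALSE)
  aln <- alignments[is.na(alignments$tp) | alignments$tp == "P", ,
                    drop = FALSE]
  aln <- aln[aln$tname == region$tname, , drop = FALSE]
  if (!nrow(aln)) return(0)
  ov_start <- pmax(aln$tstart, region$start)
  ov_end <- pmin(aln$tend, region$end)
  covered <- sum(pmax(0, ov_end - ov_start + 1))
  covered / (region$end - region$start + 1)
}

#' Read-based copy number
#'
#' Unit matches counted on raw reads, normalised by genome-wide read
#' depth; the integer part is reported (363,615 matches at depth 121.864
#' gives 2983 copies).
#'
#' @param match_count unit matches from [count_unit_matches_on_reads()].
#' @param depth genome-wide fold coverage from [genome_wide_depth()].
#' @return integer copy estimate.
#' @export
#' @examples
#' read_based_copies(363615, 121.864)  # 2983
read_based_copies <- function(match_count, depth) {
  if (depth <= 0) stop("depth must be positive", call. = FALSE)
  as.integer(match_count / depth)
}

#' Assembly-based copy number
#'
#' Annotated span divided by the unit length (integer division).
#'
#' @param annotated_len total bp annotated as the unit's class.
#' @param unit_len unit length in bp.
#' @return integer copy estimate.
#' @export
assembly_based_copies <- function(annotated_len, unit_len) {
  stopifnot(unit_len > 0)
  as.integer(annotated_len %/% unit_len)
}

#' Span implied by a copy number
#'
#' @param copies unit copies.
#' @param unit_len unit length in bp.
#' @return span in bp (exact product). Use [bp_to_mb()] for the truncated
#'   Mb report (1055 copies of 10.7 kb span 11,288,500 bp, reported as
#'   11.28 Mb).
#' @export
span_from_copies <- function(copies, unit_len) {
  stopifnot(unit_len > 0)
  copies * unit_len
}

#' Copy-number estimate table
#'
#' Assembles read-based and assembly-based estimates of a tandem unit into
#' one report row each, with their raw inputs.
#'
#' @param unit_name label for the unit.
#' @param match_count,depth read-based inputs (optional).
#' @param annotated_len,unit_len assembly-based inputs (optional;
#'   `unit_len` required when either estimate is requested).
#' @return data.frame with `unit`, `method`, `copies`, `span_bp` and input
#'   columns.
#' @export
copy_estimates <- function(unit_name, unit_len, match_count = NULL,
                           depth = NULL, annotated_len = NULL) {
  rows <- list()
  if (!is.null(match_count) && !is.null(depth)) {
    cp <- read_based_copies(match_count, depth)
    rows$read <- data.frame(
      unit = unit_name, method = "read_based", copies = cp,
      span_bp = span_from_copies(cp, unit_len),
      match_count = match_count, depth = depth,
      annotated_len = NA_real_, unit_len = unit_len
    )
  }
  if (!is.null(annotated_len)) {
    cp <- assembly_based_copies(annotated_len, unit_len)
    rows$asm <- data.frame(
      unit = unit_name, method = "assembly_based", copies = cp,
      span_bp = span_from_copies(cp, unit_len),
      match_count = NA_real_, depth = NA_real_,
      annotated_len = annotated_len, unit_len = unit_len
    )
  }
  do.call(rbind, unname(rows))
}
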