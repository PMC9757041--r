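#' Technology-style break models
#'
#' Per-feature-class break probabilities for [fragment_assembly()]. The
#' CLR-style model breaks in every satellite array and rDNA cluster (the
#' repeats CLR assemblies cannot traverse); the HiFi-style model breaks at
#' every GA/GAA low-complexity tract (where HiFi coverage drops out) and
#' at 45S rDNA arrays.
#'
#' @return named numeric vector: class -> break probability.
#' @export
break_model_clr <- function() {
  c(centromere_satellite = 1, rDNA_45S = 1, rDNA_5S = 1)
}

#' @rdname break_model_clr
#' @export
break_model_hifi <- function() {
  c(low_complexity_GA = 1, low_complexity_GAA = 1, rDNA_45S = 1)
}

# interior margin left on each side of a removed span so the causal
# feature remains annotatable at the resulting contig edges
.break_margin <- function(len) {
  m <- pmax(60L, pmin(2000L, as.integer(floor(0.15 * len))))
  ifelse(len - 2L * m < 20L, pmax(1L, (len - 20L) %/% 2L), m)
}

#' Fragment a genome into surrogate contigs with known break causes
#'
#' Emulates an assembler's failure modes without running an assembler:
#' for each truth feature whose class has a break probability under
#' `break_model`, a break is planted (with that probability) by removing
#' the interior of the feature, leaving margins so the cause remains
#' visible at the new contig edges. Contigs are the inter-break segments;
#' an AGP plan reconnects them into one scaffold per chromosome with
#' N-gaps of the true removed length, and the true cause of every gap is
#' recorded.
#'
#' @param genome a `sim_genome`.
#' @param break_model named numeric vector of per-class break
#'   probabilities ([break_model_clr()], [break_model_hifi()] or custom).
#' @param seed integer seed.
#' @return list of class `sim_assembly`: `contigs` (`DNAStringSet`),
#'   `plan` ([scaffold_plan]), `scaffolds` (`DNAStringSet` with N gaps),
#'   `gap_truth` (data.frame: scaffold, gap index, removed coordinates on
#'   the source chromosome, cause, gap length), `genome`.
#' @export
fragment_assembly <- function(genome, break_model, seed = 1L) {
  assert_class_known(names(break_model), "break model class")
  truth <- genome$truth
  sequences <- genome$sequences
  with_seed(seed, {
    feats <- truth[S4Vectors::mcols(truth)$feature_class %in%
                     names(break_model)]
    p <- break_model[S4Vectors::mcols(feats)$feature_class]
    broken <- feats[stats::runif(length(feats)) < p]

    contig_rows <- list()
    agp_rows <- list()
    gap_rows <- list()
    contigs <- list()
    for (chrom in names(sequences)) {
      chrom_len <- Biostrings::width(sequences)[names(sequences) == chrom]
      b <- broken[GenomicRanges::seqnames(broken) == chrom]
      b <- GenomicRanges::sort(b, ignore.strand = TRUE)
      if (length(b)) {
        len <- GenomicRanges::width(b)
        m <- .break_margin(len)
        rem_start <- GenomicRanges::start(b) + m
        rem_end <- GenomicRanges::end(b) - m
        cause <- S4Vectors::mcols(b)$feature_class
      } else {
        rem_start <- integer(0); rem_end <- integer(0)
        cause <- character(0)
      }
      seg_start <- c(1L, rem_end + 1L)
      seg_end <- c(rem_start - 1L, chrom_len)
      n_seg <- length(seg_start)
      cnames <- sprintf("%s_ctg%d", chrom, seq_len(n_seg))
      for (i in seq_len(n_seg)) {
        contigs[[cnames[i]]] <- Biostrings::subseq(
          sequences[[chrom]], seg_start[i], seg_end[i])
      }
      # AGP: W and N rows alternating, one scaffold per chromosome
      pos <- 0L; part <- 0L
      for (i in seq_len(n_seg)) {
        w <- seg_end[i] - seg_start[i] + 1L
        part <- part + 1L
        agp_rows[[length(agp_rows) + 1L]] <- data.frame(
          object = chrom, object_beg = pos + 1L, object_end = pos + w,
          part_number = part, component_type = "W",
          component_id = cnames[i], component_beg = 1L, component_end = w,
          orientation = "+", gap_length = NA_integer_,
          gap_type = NA_character_, linkage = NA_character_,
          linkage_evidence = NA_character_, stringsAsFactors = FALSE)
        pos <- pos + w
        if (i < n_seg) {
          g <- rem_end[i] - rem_start[i] + 1L
          part <- part + 1L
          agp_rows[[length(agp_rows) + 1L]] <- data.frame(
            object = chrom, object_beg = pos + 1L, object_end = pos + g,
            part_number = part, component_type = "N",
            component_id = NA_character_, component_beg = NA_integer_,
            component_end = NA_integer_, orientation = NA_character_,
            gap_length = g, gap_type = "scaffold", linkage = "yes",
            linkage_evidence = "map", stringsAsFactors = FALSE)
          gap_rows[[length(gap_rows) + 1L]] <- data.frame(
            scaffold = chrom, gap_index = i,
            removed_start = rem_start[i], removed_end = rem_end[i],
            cause = cause[i], gap_len = g, stringsAsFactors = FALSE)
          pos <- pos + g
        }
      }
    }
    contigs <- Biostrings::DNAStringSet(contigs)
    plan <- new_scaffold_plan(do.call(rbind, agp_rows))
    gap_truth <- if (length(gap_rows)) {
      do.call(rbind, gap_rows)
    } else {
      data.frame(scaffold = character(), gap_index = integer(),
                 removed_start = integer(), removed_end = integer(),
                 cause = character(), gap_len = integer(),
                 stringsAsFactors = FALSE)
    }
    structure(
      list(contigs = contigs, plan = plan,
           scaffolds = scaffold_from_plan(plan, contigs),
           gap_truth = gap_truth, genome = genome),
      class = "sim_assembly"
    )
  })
}
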