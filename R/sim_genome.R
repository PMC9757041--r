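# Genome construction: each chromosome is
#   telomere | arm 1 | satellite array | arm 2 | telomere
# with rDNA arrays, the organellar insertion, TE copies and low-complexity
# tracts embedded in the arms separated by background spacers of at least
# `min_spacer` bp, so that every planted feature is unambiguous within any
# flank/edge window up to that size.

# one satellite array: whole monomer copies, per-copy substitution
# divergence, split into alternating-orientation blocks at monomer
# boundaries. Returns list(seq, blocks = data.frame(offset,len,strand)).
build_satellite_array <- function(monomer, array_len, divergence,
                                  n_blocks) {
  mlen <- nchar(monomer)
  copies <- as.integer(array_len %/% mlen)
  if (copies <= 0) return(NULL)
  n_blocks <- max(1L, min(n_blocks, copies))
  # block boundaries uniform at monomer boundaries
  cuts <- sort(sample(seq_len(copies - 1), n_blocks - 1))
  sizes <- diff(c(0L, cuts, copies))
  monos <- vapply(seq_len(copies), function(i) mutate_seq(monomer, divergence),
                  character(1))
  strands <- rep(c("+", "-"), length.out = n_blocks)
  off <- 0L
  blocks <- vector("list", n_blocks)
  seqs <- character(n_blocks)
  for (b in seq_len(n_blocks)) {
    idx <- (off + 1L):(off + sizes[b])
    s <- paste(monos[idx], collapse = "")
    if (strands[b] == "-") {
      s <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }
    seqs[b] <- s
    blocks[[b]] <- data.frame(len = nchar(s), strand = strands[b],
                              copies = sizes[b])
    off <- off + sizes[b]
  }
  list(seq = paste(seqs, collapse = ""), blocks = do.call(rbind, blocks),
       copies = copies)
}

lc_tract_seq <- function(motif, len) {
  copies <- max(1L, as.integer(len %/% nchar(motif)))
  strrep(motif, copies)
}

#' Build a synthetic genome with planted ground truth
#'
#' Deterministic under `config$seed`: two calls with the same config give
#' byte-identical sequences and truth. Feature placement: the satellite
#' array sits mid-chromosome flanked by two arms; the 5S rDNA array and the
#' organellar insertion go to chromosome 1, the 45S rDNA array is placed
#' subtelomerically on the last chromosome's first arm; low-complexity
#' tracts and TE copies are distributed round-robin over all arms.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_genome`: `sequences` (`DNAStringSet`),
#'   `truth` (`GRanges`, sorted and non-overlapping, with `feature_class`,
#'   `copies`, `motif` columns), `library` (data.frame repeat library:
#'   name, class, consensus, min_match_len, min_identity) and `config`.
#' @export
build_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, build_genome_impl(config))
}

build_genome_impl <- function(config) {
  tel <- strrep(config$telomere_motif, config$telomere_copies)
  tel_len <- nchar(tel)

  # per-arm feature queues -------------------------------------------------
  n_arms <- 2L * config$n_chromosomes
  arm_feats <- vector("list", n_arms)   # list of feature descriptors
  add_feat <- function(arm, feat) {
    arm_feats[[arm]] <<- c(arm_feats[[arm]], list(feat))
  }
  if (config$rdna5S_copies > 0) {
    add_feat(1L, list(class = "rDNA_5S",
                      seq = strrep(config$rdna5S_unit, config$rdna5S_copies),
                      copies = config$rdna5S_copies, motif = NA))
  }
  if (config$organellar_insert_len > 0) {
    add_feat(2L, list(class = "organellar", seq = config$organellar_genome,
                      copies = 1L, motif = NA))
  }
  if (config$rdna45S_copies > 0) {
    arm45 <- n_arms - 1L  # first arm of last chromosome, subtelomeric
    add_feat(arm45, list(class = "rDNA_45S",
                         seq = strrep(config$rdna45S_unit,
                                      config$rdna45S_copies),
                         copies = config$rdna45S_copies, motif = NA,
                         subtelomeric = TRUE))
  }
  lc <- config$lc_tracts
  if (nrow(lc)) {
    for (i in seq_len(nrow(lc))) {
      cls <- if (lc$motif[i] == "GA") "low_complexity_GA" else "low_complexity_GAA"
      add_feat(((i - 1L) %% n_arms) + 1L,
               list(class = cls, seq = lc_tract_seq(lc$motif[i], lc$length[i]),
                    copies = NA, motif = lc$motif[i]))
    }
  }
  if (config$n_te_copies > 0 && length(config$te_library)) {
    for (i in seq_len(config$n_te_copies)) {
      te <- config$te_library[[((i - 1L) %% length(config$te_library)) + 1L]]
      add_feat(((i - 1L + nrow(lc)) %% n_arms) + 1L,
               list(class = "TE", seq = mutate_seq(te, 0.02),
                    copies = 1L, motif = NA))
    }
  }

  # satellite arrays (one per chromosome) ----------------------------------
  sats <- lapply(seq_len(config$n_chromosomes), function(i) {
    if (config$satellite_array_len <= 0) return(NULL)
    build_satellite_array(config$satellite_monomer,
                          config$satellite_array_len,
                          config$satellite_divergence,
                          config$n_strand_blocks)
  })

  chrom_seqs <- character(config$n_chromosomes)
  truth_rows <- list()
  push_truth <- function(chrom, start, end, class, strand = "*",
                         copies = NA, motif = NA) {
    truth_rows[[length(truth_rows) + 1L]] <<- data.frame(
      chrom = chrom, start = start, end = end, feature_class = class,
      strand = strand, copies = copies, motif = motif,
      stringsAsFactors = FALSE)
  }

  for (ci in seq_len(config$n_chromosomes)) {
    chrom <- sprintf("chr%d", ci)
    sat <- sats[[ci]]
    sat_len <- if (is.null(sat)) 0L else nchar(sat$seq)
    arm_len <- (config$chrom_length - 2L * tel_len - sat_len) %/% 2L
    if (arm_len < config$min_spacer * 2L) {
      stop(sprintf(
        "chrom_length %d too small: satellite array (%d bp) plus telomeres leave arms of %d bp",
        config$chrom_length, sat_len, arm_len), call. = FALSE)
    }
    build_arm <- function(arm_idx) {
      feats <- arm_feats[[arm_idx]]
      feat_lens <- vapply(feats, function(f) nchar(f$seq), integer(1))
      n_spacers <- length(feats) + 1L
      spare <- arm_len - sum(feat_lens) - n_spacers * config$min_spacer
      if (spare < 0) {
        biggest <- if (length(feats)) feats[[which.max(feat_lens)]]$class else "spacer"
        stop(sprintf(
          "chrom_length too small on %s arm %d: feature '%s' overflows by %d bp",
          chrom, arm_idx, biggest, -spare), call. = FALSE)
      }
      # subtelomeric features keep their outer spacer at the minimum
      extra <- if (length(feats)) {
        prop <- stats::runif(n_spacers)
        sub_tel <- vapply(feats, function(f) isTRUE(f$subtelomeric),
                          logical(1))
        if (any(sub_tel) && arm_idx %% 2L == 1L) prop[1] <- 0
        round(spare * prop / sum(prop))
      } else {
        spare
      }
      # fix rounding so the arm length is exact
      extra[length(extra)] <- extra[length(extra)] +
        (spare - sum(extra))
      parts <- character(0)
      feat_pos <- list()
      pos <- 0L
      for (i in seq_len(n_spacers)) {
        sp_len <- config$min_spacer + extra[i]
        parts <- c(parts, random_dna(sp_len, config$gc_background))
        pos <- pos + sp_len
        if (i <= length(feats)) {
          f <- feats[[i]]
          feat_pos[[i]] <- list(class = f$class, start = pos + 1L,
                                end = pos + nchar(f$seq),
                                copies = f$copies, motif = f$motif)
          parts <- c(parts, f$seq)
          pos <- pos + nchar(f$seq)
        }
      }
      list(seq = paste(parts, collapse = ""), feats = feat_pos, len = pos)
    }
    arm1 <- build_arm(2L * ci - 1L)
    arm2 <- build_arm(2L * ci)

    # assemble chromosome, recording truth in chromosome coordinates
    offset <- 0L
    push_truth(chrom, 1L, tel_len, "telomere", "+",
               copies = config$telomere_copies)
    offset <- tel_len
    for (f in arm1$feats) {
      push_truth(chrom, offset + f$start, offset + f$end, f$class,
                 copies = f$copies, motif = f$motif)
    }
    offset <- offset + arm1$len
    if (!is.null(sat)) {
      boff <- offset
      for (b in seq_len(nrow(sat$blocks))) {
        push_truth(chrom, boff + 1L, boff + sat$blocks$len[b],
                   "centromere_satellite", sat$blocks$strand[b],
                   copies = sat$blocks$copies[b])
        boff <- boff + sat$blocks$len[b]
      }
      offset <- offset + nchar(sat$seq)
    }
    for (f in arm2$feats) {
      push_truth(chrom, offset + f$start, offset + f$end, f$class,
                 copies = f$copies, motif = f$motif)
    }
    offset <- offset + arm2$len
    push_truth(chrom, offset + 1L, offset + tel_len, "telomere", "-",
               copies = config$telomere_copies)
    chrom_seqs[ci] <- paste0(tel, arm1$seq,
                             if (is.null(sat)) "" else sat$seq,
                             arm2$seq, tel)
  }

  truth_df <- do.call(rbind, truth_rows)
  truth <- feature_granges(truth_df$chrom, truth_df$start, truth_df$end,
                           truth_df$feature_class, truth_df$strand,
                           copies = truth_df$copies, motif = truth_df$motif)
  truth <- GenomicRanges::sort(truth, ignore.strand = TRUE)
  sequences <- Biostrings::DNAStringSet(chrom_seqs)
  names(sequences) <- sprintf("chr%d", seq_len(config$n_chromosomes))

  library_df <- data.frame(
    name = c("satellite_monomer", "rDNA_5S_unit", "rDNA_45S_unit",
             names(config$te_library), "organellar_genome"),
    class = c("centromere_satellite", "rDNA_5S", "rDNA_45S",
              rep("TE", length(config$te_library)), "organellar"),
    consensus = c(config$satellite_monomer, config$rdna5S_unit,
                  config$rdna45S_unit, unname(unlist(config$te_library)),
                  config$organellar_genome),
    min_match_len = 100L, min_identity = 0.8,
    stringsAsFactors = FALSE
  )

  structure(
    list(sequences = sequences, truth = truth, library = library_df,
         config = config),
    class = "sim_genome"
  )
}

#' @export
print.sim_genome <- function(x, ...) {
  cat(sprintf("sim_genome: %d chromosomes, %.2f Mb, %d truth features\n",
              length(x$sequences),
              sum(Biostrings::width(x$sequences)) / 1e6,
              length(x$truth)))
  invisible(x)
}
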