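#' Classify the repeat closest to each contig edge
#'
#' For every contig longer than `min_contig`, the annotated element
#' nearest to each edge within the first `edge_window` bases is reported
#' as the likely break cause for that edge; edges with no annotated
#' element in the window are called `non_repetitive`. Distance ties are
#' broken by class hierarchy priority.
#'
#' @param assembly `DNAStringSet` of contigs (or numeric widths, named).
#' @param annotation `GRanges` annotation on the same contig coordinates.
#' @param edge_window bp from each edge considered (default 2000).
#' @param min_contig contigs must be strictly longer than this (default
#'   10000).
#' @param hierarchy tie-break priority (default [default_hierarchy]).
#' @return data.frame: `contig`, `side` ("left"/"right"), `cause`,
#'   `distance_to_edge`.
#' @export
edge_elements <- function(assembly, annotation, edge_window = 2000L,
                          min_contig = 10000L,
                          hierarchy = default_hierarchy) {
  widths <- if (methods::is(assembly, "XStringSet")) {
    stats::setNames(Biostrings::width(assembly), names(assembly))
  } else {
    assembly
  }
  widths <- widths[widths > min_contig]
  if (!length(widths)) {
    return(data.frame(contig = character(), side = character(),
                      cause = character(), distance_to_edge = integer(),
                      stringsAsFactors = FALSE))
  }
  prio <- stats::setNames(seq_along(hierarchy), hierarchy)
  anno_chrom <- as.character(GenomicRanges::seqnames(annotation))
  rows <- lapply(names(widths), function(ctg) {
    w <- widths[[ctg]]
    a <- annotation[anno_chrom == ctg]
    call_side <- function(side) {
      if (side == "left") {
        win_lo <- 1L; win_hi <- min(edge_window, w)
        dist <- pmax(0L, GenomicRanges::start(a) - 1L)
      } else {
        win_lo <- max(1L, w - edge_window + 1L); win_hi <- w
        dist <- pmax(0L, w - GenomicRanges::end(a))
      }
      inwin <- GenomicRanges::start(a) <= win_hi &
        GenomicRanges::end(a) >= win_lo
      if (!any(inwin)) {
        return(data.frame(contig = ctg, side = side,
                          cause = "non_repetitive",
                          distance_to_edge = NA_integer_,
                          stringsAsFactors = FALSE))
      }
      d <- dist[inwin]
      cls <- S4Vectors::mcols(a)$feature_class[inwin]
      best <- order(d, prio[cls])[1]
      data.frame(contig = ctg, side = side, cause = cls[best],
                 distance_to_edge = as.integer(d[best]),
                 stringsAsFactors = FALSE)
    }
    rbind(call_side("left"), call_side("right"))
  })
  do.call(rbind, rows)
}

#' Summarise break causes across contig edges
#'
#' Per-class edge fractions plus the combined centromere + rDNA fraction,
#' reported both over all edges and over non-telomeric edges (a
#' telomere-capped edge is a finished chromosome end, not a break).
#'
#' @param edge_calls data.frame from [edge_elements()].
#' @return list: `per_class` (data.frame `cause`, `n`, `fraction`),
#'   `combined_cen_rdna` and `combined_cen_rdna_nontelomeric` (fractions),
#'   `n_edges`, `n_nontelomeric`.
#' @export
break_cause_summary <- function(edge_calls) {
  if (!nrow(edge_calls)) stop("no edge calls", call. = FALSE)
  tab <- table(edge_calls$cause)
  per_class <- data.frame(cause = names(tab), n = as.integer(tab),
                          fraction = as.numeric(tab) / nrow(edge_calls),
                          stringsAsFactors = FALSE)
  per_class <- per_class[order(-per_class$n), , drop = FALSE]
  cen_rdna <- c("centromere_satellite", "rDNA_5S", "rDNA_45S")
  nontel <- edge_calls[edge_calls$cause != "telomere", , drop = FALSE]
  list(
    per_class = per_class,
    combined_cen_rdna = mean(edge_calls$cause %in% cen_rdna),
    combined_cen_rdna_nontelomeric =
      if (nrow(nontel)) mean(nontel$cause %in% cen_rdna) else NA_real_,
    n_edges = nrow(edge_calls),
    n_nontelomeric = nrow(nontel)
  )
}
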