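#' NGx contiguity statistic
#'
#' NG50 (the default x = 50) is the length of the shortest contig such that
#' contigs of that length or longer cover at least 50% of a fixed reference
#' genome size — unlike N50, the denominator is the reference size, not the
#' assembly size, which makes assemblies of very different total lengths
#' comparable. If the cumulative assembly length never reaches x% of the
#' reference, 0 is returned with a warning (an assembly can legitimately be
#' smaller than the reference).
#'
#' @param contig_lengths numeric vector of contig lengths.
#' @param reference_size fixed reference genome size in bp.
#' @param x percentage threshold in (0, 100].
#' @return The NGx length in bp (0 if unreached).
#' @export
#' @examples
#' ngx(c(60, 50, 40), 100)        # 60
#' ngx(c(30, 30, 30, 20), 150)    # 30
ngx <- function(contig_lengths, reference_size, x = 50) {
  stopifnot(reference_size > 0, x > 0, x <= 100)
  if (!length(contig_lengths)) {
    warning("empty contig length list; NGx undefined, returning 0")
    return(0)
  }
  lens <- sort(as.numeric(contig_lengths), decreasing = TRUE)
  target <- reference_size * x / 100
  cum <- cumsum(lens)
  i <- which(cum >= target)
  if (!length(i)) {
    warning(sprintf("assembly covers only %.1f%% of the reference; NG%g unreached, returning 0",
                    100 * cum[length(cum)] / reference_size, x))
    return(0)
  }
  lens[i[1]]
}

#' Cumulative contiguity curve
#'
#' Contigs ordered from largest to smallest; the cumulative length is
#' expressed as a fraction of the estimated genome size, giving the curve
#' used to compare assemblies against a genome-size line.
#'
#' @param contig_lengths numeric vector of contig lengths (or a
#'   `DNAStringSet`, whose widths are used).
#' @param genome_size_estimate genome size used to normalise.
#' @return data.frame with `rank`, `length`, `cumulative_bp`,
#'   `cumulative_frac`.
#' @export
contiguity_curve <- function(contig_lengths, genome_size_estimate) {
  if (methods::is(contig_lengths, "XStringSet")) {
    contig_lengths <- Biostrings::width(contig_lengths)
  }
  lens <- sort(as.numeric(contig_lengths), decreasing = TRUE)
  data.frame(
    rank = seq_along(lens),
    length = lens,
    cumulative_bp = cumsum(lens),
    cumulative_frac = cumsum(lens) / genome_size_estimate
  )
}

#' Contiguity report for an assembly
#'
#' @param assembly `DNAStringSet` or numeric contig lengths.
#' @param reference_size fixed reference size for NGx.
#' @param x NGx percentages to report (default 50).
#' @return list of class `contiguity_report`: `total_len`, `largest`,
#'   `n_contigs`, `ngx` (named vector) and `curve`.
#' @export
summarize_contiguity <- function(assembly, reference_size, x = 50) {
  lens <- if (methods::is(assembly, "XStringSet")) {
    Biostrings::width(assembly)
  } else {
    as.numeric(assembly)
  }
  ng <- vapply(x, function(xx) ngx(lens, reference_size, xx), numeric(1))
  names(ng) <- paste0("NG", x)
  structure(
    list(total_len = sum(lens),
         largest = if (length(lens)) max(lens) else 0,
         n_contigs = length(lens),
         ngx = ng,
         curve = contiguity_curve(lens, reference_size)),
    class = "contiguity_report"
  )
}

#' @export
print.contiguity_report <- function(x, ...) {
  cat(sprintf("contiguity: %d contigs, total %.2f Mb, largest %.2f Mb\n",
              x$n_contigs, x$total_len / 1e6, x$largest / 1e6))
  for (nm in names(x$ngx)) {
    cat(sprintf("  %s = %.2f Mb\n", nm, x$ngx[[nm]] / 1e6))
  }
  invisible(x)
}
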