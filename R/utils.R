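#' @useDynLib asmforensics, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @keywords internal
"_PACKAGE"

#' Recognised repeat/feature classes
#'
#' The controlled vocabulary used by every annotation, edge-call and
#' gap-classification function, ordered by the default overlap-resolution
#' hierarchy (highest priority first): organellar insertions outrank rDNAs,
#' which outrank the centromeric satellite, telomeres, low-complexity tracts
#' and transposable elements. `non_repetitive` is the sentinel for "no
#' repeat found".
#'
#' @format Character vector of class names.
#' @export
feature_classes <- c(
  "organellar", "rDNA_45S", "rDNA_5S", "centromere_satellite",
  "telomere", "low_complexity_GA", "low_complexity_GAA", "TE",
  "non_repetitive"
)

#' Default class hierarchy for overlap resolution
#'
#' Organellar sequence > rDNAs (45S over 5S) > satellite > telomere >
#' low-complexity > TE. Used by [merge_hierarchy()], [edge_elements()] and
#' [classify_gaps()] unless overridden.
#'
#' @export
default_hierarchy <- setdiff(feature_classes, "non_repetitive")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Truncate (not round) to a fixed number of decimals
#'
#' Reporting rule for megabase spans and percentages: 11.2885 Mb is printed
#' as 11.28, and 83.126% as 83.12. Truncation toward zero, vectorised.
#'
#' @param x numeric vector.
#' @param digits decimals kept (default 2).
#' @return Truncated numeric vector.
#' @export
#' @examples
#' trunc_digits(11.2885, 2)  # 11.28
trunc_digits <- function(x, digits = 2) {
  trunc(x * 10^digits) / 10^digits
}

#' Megabases, truncated to two decimals
#' @param bp base pairs.
#' @return numeric, Mb truncated to 2 decimals.
#' @export
bp_to_mb <- function(bp) trunc_digits(bp / 1e6, 2)

assert_class_known <- function(classes, where = "feature class") {
  bad <- setdiff(classes, feature_classes)
  if (length(bad)) {
    stop(sprintf("unknown %s: %s", where, paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  invisible(classes)
}

#' Build a feature GRanges
#'
#' Thin constructor ensuring the `feature_class` metadata column is present
#' and drawn from [feature_classes].
#'
#' @param chrom,start,end chromosome names and 1-based closed coordinates.
#' @param feature_class class label per interval.
#' @param strand strand ("+", "-" or "*").
#' @param ... further metadata columns.
#' @return A `GRanges` with a `feature_class` column.
#' @export
feature_granges <- function(chrom, start, end, feature_class,
                            strand = "*", ...) {
  assert_class_known(feature_class)
  if (length(strand) == 1L) strand <- rep(strand, length(chrom))
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start, end = end),
    strand = strand
  )
  S4Vectors::mcols(gr)$feature_class <- feature_class
  extra <- list(...)
  for (nm in names(extra)) S4Vectors::mcols(gr)[[nm]] <- extra[[nm]]
  gr
}

# message to stderr, gated by option(asmforensics.verbose)
af_log <- function(fmt, ...) {
  if (isTRUE(getOption("asmforensics.verbose", FALSE))) {
    message(sprintf(fmt, ...))
  }
  invisible(NULL)
}

# Draw a reproducible child seed (< 2^31) from the current RNG stream.
child_seed <- function() sample.int(.Machine$integer.max, 1L)

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
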