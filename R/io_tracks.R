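#' Write features to BED6
#'
#' The feature class goes in the BED name field; coordinates are converted
#' from the internal 1-based closed convention to BED's 0-based half-open.
#'
#' @param features `GRanges` with a `feature_class` column.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(features, path) {
  sc <- S4Vectors::mcols(features)$score
  if (is.null(sc)) sc <- rep(0, length(features))
  strand <- as.character(GenomicRanges::strand(features))
  strand[strand == "*"] <- "."
  lines <- paste(as.character(GenomicRanges::seqnames(features)),
                 GenomicRanges::start(features) - 1L,
                 GenomicRanges::end(features),
                 S4Vectors::mcols(features)$feature_class,
                 sc, strand, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read features from BED6
#'
#' @param path BED6 file whose name field holds the feature class.
#' @return `GRanges` with `feature_class` and `score` columns.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") &
                   !startsWith(lines, "#")]
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 6L)) {
    stop("BED line ", which(lengths(f) < 6L)[1], " has fewer than 6 columns",
         call. = FALSE)
  }
  get <- function(i) vapply(f, `[`, character(1), i)
  start0 <- as.integer(get(2))
  end <- as.integer(get(3))
  if (any(start0 < 0 | end <= start0)) {
    stop("BED interval with start >= end", call. = FALSE)
  }
  strand <- get(6)
  strand[!strand %in% c("+", "-")] <- "*"
  feature_granges(get(1), start0 + 1L, end, get(4), strand,
                  score = as.numeric(get(5)))
}

#' Write features to GFF3
#'
#' @param features `GRanges` with a `feature_class` column.
#' @param path output file.
#' @param source value for the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path, source = "asmforensics") {
  strand <- as.character(GenomicRanges::strand(features))
  strand[strand == "*"] <- "."
  sc <- S4Vectors::mcols(features)$score
  sc <- if (is.null(sc)) rep(".", length(features)) else as.character(sc)
  attrs <- sprintf("ID=feat%d;class=%s", seq_along(features),
                   S4Vectors::mcols(features)$feature_class)
  lines <- paste(as.character(GenomicRanges::seqnames(features)), source,
                 S4Vectors::mcols(features)$feature_class,
                 GenomicRanges::start(features),
                 GenomicRanges::end(features),
                 sc, strand, ".", attrs, sep = "\t")
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Read features from GFF3
#'
#' The feature class is taken from the type column (column 3), which must
#' be a member of [feature_classes].
#'
#' @param path GFF3 file.
#' @return `GRanges` with a `feature_class` column.
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 9L)) {
    stop("GFF3 line ", which(lengths(f) < 9L)[1], " has fewer than 9 columns",
         call. = FALSE)
  }
  get <- function(i) vapply(f, `[`, character(1), i)
  strand <- get(7)
  strand[!strand %in% c("+", "-")] <- "*"
  score <- suppressWarnings(as.numeric(get(6)))
  score[is.na(score)] <- 0
  feature_granges(get(1), as.integer(get(4)), as.integer(get(5)),
                  assert_class_known(get(3)), strand, score = score)
}

#' Write a plain TSV report
#'
#' @param df data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tsv_report <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
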