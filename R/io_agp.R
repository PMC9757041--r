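#' Scaffold plans (AGP v2.1)
#'
#' A scaffold plan is a data.frame in AGP column order (class
#' `"scaffold_plan"`): `object`, `object_beg`, `object_end`, `part_number`,
#' `component_type` ("W" for placed contigs, "N"/"U" for gaps), and either
#' `component_id`/`component_beg`/`component_end`/`orientation` (W rows) or
#' `gap_length`/`gap_type`/`linkage`/`linkage_evidence` (N/U rows).
#' Coordinates are 1-based inclusive as in the AGP specification; "U" rows
#' carry the conventional placeholder length 100 with `gap_length` recorded
#' as NA internally.
#'
#' @name scaffold_plan
NULL

new_scaffold_plan <- function(df) {
  class(df) <- c("scaffold_plan", "data.frame")
  df
}

validate_scaffold_plan <- function(plan, contig_lengths = NULL) {
  for (obj in unique(plan$object)) {
    p <- plan[plan$object == obj, , drop = FALSE]
    p <- p[order(p$part_number), , drop = FALSE]
    expect_beg <- c(1L, utils::head(p$object_end, -1) + 1L)
    off <- which(p$object_beg != expect_beg)
    if (length(off)) {
      stop(sprintf(
        "AGP coordinate discontinuity in object '%s' at part %d (line %d)",
        obj, p$part_number[off[1]], off[1]), call. = FALSE)
    }
    span <- p$object_end - p$object_beg + 1L
    w <- p$component_type == "W"
    comp_len <- p$component_end[w] - p$component_beg[w] + 1L
    if (any(span[w] != comp_len)) {
      stop(sprintf("AGP W component span mismatch in object '%s'", obj),
           call. = FALSE)
    }
    if (!is.null(contig_lengths)) {
      known <- p$component_id[w] %in% names(contig_lengths)
      if (any(known) &&
          any(p$component_end[w][known] >
              contig_lengths[p$component_id[w][known]])) {
        stop(sprintf("AGP component extends past contig end in '%s'", obj),
             call. = FALSE)
      }
    }
  }
  invisible(plan)
}

#' Read an AGP v2.1 file
#'
#' @param path AGP file; `#` comment lines are skipped.
#' @return A [scaffold_plan] data.frame.
#' @export
read_agp <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) stop("empty AGP file", call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 8L)) {
    stop("AGP line ", which(ncol < 8L)[1], " has fewer than 8 columns",
         call. = FALSE)
  }
  get <- function(i) vapply(fields, function(f) f[i] %||% NA_character_,
                            character(1))
  df <- data.frame(
    object = get(1), object_beg = as.integer(get(2)),
    object_end = as.integer(get(3)), part_number = as.integer(get(4)),
    component_type = get(5),
    component_id = NA_character_, component_beg = NA_integer_,
    component_end = NA_integer_, orientation = NA_character_,
    gap_length = NA_integer_, gap_type = NA_character_,
    linkage = NA_character_, linkage_evidence = NA_character_,
    stringsAsFactors = FALSE
  )
  is_gap <- df$component_type %in% c("N", "U")
  df$component_id[!is_gap] <- get(6)[!is_gap]
  df$component_beg[!is_gap] <- as.integer(get(7)[!is_gap])
  df$component_end[!is_gap] <- as.integer(get(8)[!is_gap])
  df$orientation[!is_gap] <- get(9)[!is_gap]
  df$gap_length[is_gap & df$component_type == "N"] <-
    as.integer(get(6)[is_gap & df$component_type == "N"])
  df$gap_type[is_gap] <- get(7)[is_gap]
  df$linkage[is_gap] <- get(8)[is_gap]
  df$linkage_evidence[is_gap] <- get(9)[is_gap]
  plan <- new_scaffold_plan(df)
  validate_scaffold_plan(plan)
  plan
}

#' Write an AGP v2.1 file
#'
#' @param plan a [scaffold_plan].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_agp <- function(plan, path) {
  validate_scaffold_plan(plan)
  is_gap <- plan$component_type %in% c("N", "U")
  col6 <- ifelse(is_gap,
                 ifelse(plan$component_type == "U", "100",
                        as.character(plan$gap_length)),
                 plan$component_id)
  col7 <- ifelse(is_gap, plan$gap_type, as.character(plan$component_beg))
  col8 <- ifelse(is_gap, plan$linkage, as.character(plan$component_end))
  col9 <- ifelse(is_gap, plan$linkage_evidence, plan$orientation)
  lines <- paste(plan$object, plan$object_beg, plan$object_end,
                 plan$part_number, plan$component_type,
                 col6, col7, col8, col9, sep = "\t")
  writeLines(c("##agp-version\t2.1", lines), path)
  invisible(path)
}

#' Assemble scaffold sequences from a plan and contigs
#'
#' W components are copied (reverse-complemented for orientation "-"),
#' N/U gaps become runs of `N` of the recorded (or placeholder 100) length.
#'
#' @param plan a [scaffold_plan].
#' @param contigs `DNAStringSet` of component sequences.
#' @return `DNAStringSet` of scaffold sequences.
#' @export
scaffold_from_plan <- function(plan, contigs) {
  validate_scaffold_plan(plan, stats::setNames(Biostrings::width(contigs),
                                               names(contigs)))
  objs <- unique(plan$object)
  out <- lapply(objs, function(obj) {
    p <- plan[plan$object == obj, , drop = FALSE]
    p <- p[order(p$part_number), , drop = FALSE]
    parts <- lapply(seq_len(nrow(p)), function(i) {
      if (p$component_type[i] %in% c("N", "U")) {
        strrep("N", ifelse(is.na(p$gap_length[i]), 100L, p$gap_length[i]))
      } else {
        if (!p$component_id[i] %in% names(contigs)) {
          stop("unknown component: ", p$component_id[i], call. = FALSE)
        }
        s <- Biostrings::subseq(contigs[[p$component_id[i]]],
                                p$component_beg[i], p$component_end[i])
        if (identical(p$orientation[i], "-")) {
          s <- Biostrings::reverseComplement(s)
        }
        as.character(s)
      }
    })
    paste0(unlist(parts), collapse = "")
  })
  res <- Biostrings::DNAStringSet(unlist(out))
  names(res) <- objs
  res
}

#' Locate gaps in scaffolds
#'
#' Gaps are taken from an AGP plan when given; otherwise they are inferred
#' from runs of `N` in the scaffold sequences (a run of n `N`s is a gap of
#' estimated length n).
#'
#' @param scaffolds `DNAStringSet` of scaffold sequences.
#' @param plan optional [scaffold_plan].
#' @return data.frame: `scaffold`, `gap_start`, `gap_end` (1-based closed,
#'   scaffold coordinates), `gap_len_estimate` (NA for AGP "U" gaps).
#' @export
find_gaps <- function(scaffolds, plan = NULL) {
  if (!is.null(plan)) {
    is_gap <- plan$component_type %in% c("N", "U")
    g <- plan[is_gap, , drop = FALSE]
    return(data.frame(
      scaffold = g$object, gap_start = g$object_beg, gap_end = g$object_end,
      gap_len_estimate = ifelse(g$component_type == "U", NA_integer_,
                                g$gap_length),
      stringsAsFactors = FALSE
    ))
  }
  res <- lapply(names(scaffolds), function(nm) {
    m <- gregexpr("N+", as.character(scaffolds[[nm]]))[[1]]
    if (m[1] == -1) return(NULL)
    len <- attr(m, "match.length")
    data.frame(scaffold = nm, gap_start = as.integer(m),
               gap_end = as.integer(m) + len - 1L,
               gap_len_estimate = len,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res)) {
    res <- data.frame(scaffold = character(), gap_start = integer(),
                      gap_end = integer(), gap_len_estimate = integer(),
                      stringsAsFactors = FALSE)
  }
  res
}
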