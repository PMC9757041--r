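# Map a scaffold-coordinate annotation onto the component contigs of an
# AGP plan (components are colinear "+" subranges of the scaffold).
annotation_on_contigs <- function(plan, annotation) {
  w <- plan[plan$component_type == "W", , drop = FALSE]
  anno_chrom <- as.character(GenomicRanges::seqnames(annotation))
  rows <- lapply(seq_len(nrow(w)), function(i) {
    a <- annotation[anno_chrom == w$object[i] &
                      GenomicRanges::start(annotation) <= w$object_end[i] &
                      GenomicRanges::end(annotation) >= w$object_beg[i]]
    if (!length(a)) return(NULL)
    st <- pmax(GenomicRanges::start(a), w$object_beg[i]) -
      w$object_beg[i] + w$component_beg[i]
    en <- pmin(GenomicRanges::end(a), w$object_end[i]) -
      w$object_beg[i] + w$component_beg[i]
    data.frame(chrom = w$component_id[i], start = st, end = en,
               feature_class = S4Vectors::mcols(a)$feature_class,
               strand = as.character(GenomicRanges::strand(a)),
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) return(.empty_features())
  feature_granges(rows$chrom, rows$start, rows$end, rows$feature_class,
                  rows$strand)
}

#' Run the full synthetic forensics pipeline
#'
#' Simulate a genome, HiFi-like reads and two surrogate assemblies (a
#' HiFi-style one broken at low-complexity tracts and 45S arrays, and a
#' CLR-style donor broken at satellite/rDNA arrays), then run every
#' forensic stage: repeat annotation, contiguity metrics, k-mer QV and
#' completeness, contig-edge break causes, gap classification, gap
#' patching with the donor, gap-size concordance and 5S copy-number
#' estimation. All stage outputs are written under `out_dir` and recorded
#' in a checksummed manifest.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @param coverage read coverage to simulate (default 20).
#' @param profile a [read_profile()] (default HiFi).
#' @param k k-mer size for QV/completeness (default 18).
#' @return list of class `pipeline_report`: per-stage results plus
#'   `manifest` (data.frame of outputs with md5 checksums).
#' @export
run_pipeline <- function(config = sim_config(), out_dir = tempfile("afrun"),
                         coverage = 20, profile = read_profile("hifi"),
                         k = 18L) {
  if (!inherits(config, "sim_config")) {
    stop("config must be a sim_config object", call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  emit <- function(path) {
    outputs <<- c(outputs, path)
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  genome <- stage("simulate_genome", {
    g <- build_genome(config)
    write_fasta(g$sequences, emit(file.path(out_dir, "genome.fasta")))
    write_bed(g$truth, emit(file.path(out_dir, "truth.bed")))
    write_gff3(g$truth, emit(file.path(out_dir, "truth.gff3")))
    g
  })
  genome_size <- sum(Biostrings::width(genome$sequences))

  reads <- stage("simulate_reads", {
    r <- simulate_reads(genome, profile, target_coverage = coverage,
                        seed = config$seed + 1L)
    write_fastq(r, emit(file.path(out_dir, "reads.fastq")))
    r
  })
  alignments <- alignments_from_truth(reads, genome)
  write_paf(alignments, emit(file.path(out_dir, "reads.paf")))

  hifi_asm <- stage("fragment_assembly", {
    a <- fragment_assembly(genome, break_model_hifi(),
                           seed = config$seed + 2L)
    write_fasta(a$contigs, emit(file.path(out_dir, "hifi_contigs.fasta")))
    write_agp(a$plan, emit(file.path(out_dir, "hifi_scaffolds.agp")))
    write_tsv_report(a$gap_truth,
                     emit(file.path(out_dir, "gap_truth.tsv")))
    a
  })
  donor_asm <- stage("donor_assembly", {
    fragment_assembly(genome, break_model_clr(), seed = config$seed + 3L)
  })

  annotation <- stage("annotate", {
    anno <- annotate_assembly(genome$sequences, genome$library,
                              telomere_motif = config$telomere_motif)
    write_gff3(anno, emit(file.path(out_dir, "annotation.gff3")))
    anno
  })

  contiguity <- stage("metrics", {
    summarize_contiguity(hifi_asm$contigs, genome_size)
  })

  qc <- stage("kmer_qc", {
    qc <- kmer_qc(hifi_asm$scaffolds, reads, k = k)
    write_tsv_report(qc, emit(file.path(out_dir, "kmer_qc.tsv")))
    qc
  })

  edges <- stage("edge_forensics", {
    ctg_anno <- annotation_on_contigs(hifi_asm$plan, annotation)
    calls <- edge_elements(hifi_asm$contigs, ctg_anno)
    write_tsv_report(calls, emit(file.path(out_dir, "edge_calls.tsv")))
    list(calls = calls, summary = break_cause_summary(calls))
  })

  gap_work <- stage("gap_forensics", {
    patched <- patch_gaps(hifi_asm$scaffolds, donor_asm$contigs,
                          plan = hifi_asm$plan)
    records <- classify_gaps(hifi_asm$scaffolds, annotation,
                             plan = hifi_asm$plan,
                             donor_patches = patched$gaps$patch_seq)
    records$patch_len <- patched$gaps$patch_len
    records$patch_source <- patched$gaps$patch_source
    write_tsv_report(records, emit(file.path(out_dir, "gap_records.tsv")))
    write_fasta(patched$scaffolds,
                emit(file.path(out_dir, "patched_scaffolds.fasta")))
    conc <- gap_size_concordance(
      data.frame(scaffold = records$scaffold, gap_start = records$gap_start,
                 estimate = records$gap_len_estimate),
      data.frame(scaffold = records$scaffold, gap_start = records$gap_start,
                 estimate = records$patch_len))
    list(records = records, patched = patched$scaffolds,
         concordance = conc)
  })

  copies <- stage("copy_number", {
    unit <- genome$library[genome$library$class == "rDNA_5S", ]
    cnt <- count_unit_matches_on_reads(reads, unit$consensus[1])
    depth_region <- sprintf("chr1:1-%d",
                            Biostrings::width(genome$sequences)[1])
    depth <- genome_wide_depth(alignments, depth_region)
    anno_5S <- sum(GenomicRanges::width(
      annotation[S4Vectors::mcols(annotation)$feature_class == "rDNA_5S"]))
    est <- copy_estimates("rDNA_5S", nchar(unit$consensus[1]),
                          match_count = cnt$matches, depth = depth,
                          annotated_len = anno_5S)
    write_tsv_report(est, emit(file.path(out_dir, "copy_estimates.tsv")))
    est
  })

  manifest <- data.frame(
    file = basename(outputs),
    md5 = unname(tools::md5sum(outputs)),
    stringsAsFactors = FALSE
  )
  manifest <- rbind(manifest, data.frame(
    file = c(".seed", ".package_version"),
    md5 = c(as.character(config$seed),
            as.character(utils::packageVersion("asmforensics"))),
    stringsAsFactors = FALSE))
  write_tsv_report(manifest, file.path(out_dir, "manifest.tsv"))

  structure(
    list(genome = genome, reads_n = length(reads),
         contiguity = contiguity, kmer_qc = qc,
         edges = edges, gaps = gap_work, copies = copies,
         annotation = annotation, assembly = hifi_asm,
         donor = donor_asm, manifest = manifest, out_dir = out_dir),
    class = "pipeline_report"
  )
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("asmforensics pipeline report\n")
  cat(sprintf("  genome: %.2f Mb in %d chromosomes; %d reads simulated\n",
              sum(Biostrings::width(x$genome$sequences)) / 1e6,
              length(x$genome$sequences), x$reads_n))
  cat(sprintf("  contigs: %d (NG50 %.0f bp); QV %.1f; completeness %.2f%%\n",
              x$contiguity$n_contigs, x$contiguity$ngx[["NG50"]],
              x$kmer_qc$qv, x$kmer_qc$completeness))
  cat(sprintf("  gaps: %d, patched: %d; 5S copies (read-based): %d\n",
              nrow(x$gaps$records), sum(!is.na(x$gaps$records$patch_len)),
              x$copies$copies[x$copies$method == "read_based"]))
  invisible(x)
}
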