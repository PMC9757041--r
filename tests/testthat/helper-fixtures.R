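# Shared fixtures, built once per test run and cached. The default
# simulated genome (2 x 1 Mb chromosomes) is the package's reference
# study condition; expensive derived objects (annotation, reads) are
# memoised so multiple test files can share them.

af_fixture <- local({
  cache <- new.env(parent = emptyenv())
  function(name) {
    if (!exists(name, envir = cache, inherits = FALSE)) {
      value <- switch(
        name,
        genome = build_genome(sim_config(seed = 7)),
        annotation = suppressWarnings(annotate_assembly(
          af_fixture("genome")$sequences,
          af_fixture("genome")$library,
          telomere_motif = af_fixture("genome")$config$telomere_motif)),
        reads30 = simulate_reads(af_fixture("genome"),
                                 read_profile("hifi"),
                                 target_coverage = 30, seed = 9),
        stop("unknown fixture: ", name)
      )
      assign(name, value, envir = cache)
    }
    get(name, envir = cache)
  }
})

# base-coverage of class `cls` truth recovered by annotation `anno`
recovered_fraction <- function(truth, anno, cls) {
  t <- GenomicRanges::reduce(
    truth[S4Vectors::mcols(truth)$feature_class == cls],
    ignore.strand = TRUE)
  a <- GenomicRanges::reduce(
    anno[S4Vectors::mcols(anno)$feature_class == cls],
    ignore.strand = TRUE)
  tp <- sum(GenomicRanges::width(
    GenomicRanges::intersect(t, a, ignore.strand = TRUE)))
  list(recovered = tp / sum(GenomicRanges::width(t)),
       false_bases = sum(GenomicRanges::width(a)) - tp,
       truth_bases = sum(GenomicRanges::width(t)))
}

# quick GRanges constructor for tests
gr <- function(chrom, start, end, class, strand = "*", ...) {
  feature_granges(chrom, start, end, class, strand, ...)
}
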