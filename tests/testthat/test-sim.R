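test_that("genome builder is deterministic and honours feature sizing", {
  g1 <- build_genome(sim_config(seed = 41, chrom_length = 4e5,
                                satellite_array_len = 5e4,
                                rdna5S_copies = 100L, rdna45S_copies = 2L))
  g2 <- build_genome(sim_config(seed = 41, chrom_length = 4e5,
                                satellite_array_len = 5e4,
                                rdna5S_copies = 100L, rdna45S_copies = 2L))
  expect_identical(as.character(g1$sequences), as.character(g2$sequences))
  expect_identical(g1$truth, g2$truth)
  # rDNA_5S span is exactly copies x unit length
  t5 <- g1$truth[S4Vectors::mcols(g1$truth)$feature_class == "rDNA_5S"]
  expect_equal(sum(GenomicRanges::width(t5)), 100 * 500)
})

test_that("satellite_array_len = 0 plants no satellite", {
  g <- build_genome(sim_config(seed = 3, chrom_length = 3e5,
                               satellite_array_len = 0,
                               rdna5S_copies = 50L, rdna45S_copies = 0L))
  expect_false("centromere_satellite" %in%
                 S4Vectors::mcols(g$truth)$feature_class)
})

test_that("oversized features raise a sizing error naming the feature", {
  cfg <- sim_config(seed = 3, chrom_length = 1e5,
                    satellite_array_len = 2e4, rdna5S_copies = 400L)
  expect_error(build_genome(cfg), "rDNA_5S|overflows|too small")
})

test_that("truth features are sorted, non-overlapping and class-complete", {
  g <- af_fixture("genome")
  tr <- g$truth
  expect_true(all(S4Vectors::mcols(tr)$feature_class %in% feature_classes))
  by_chrom <- split(tr, GenomicRanges::seqnames(tr))
  for (b in by_chrom) {
    st <- GenomicRanges::start(b)
    en <- GenomicRanges::end(b)
    expect_true(all(diff(st) > 0))
    expect_true(all(utils::head(en, -1) < utils::tail(st, -1)))
  }
})

test_that("error-free reads are exact substrings of the genome", {
  g <- build_genome(sim_config(seed = 5, chrom_length = 2e5,
                               satellite_array_len = 2e4,
                               rdna5S_copies = 40L, rdna45S_copies = 0L,
                               n_chromosomes = 1L))
  reads <- simulate_reads(g, read_profile("hifi", per_base_error = 0,
                                          median_len = 1000),
                          target_coverage = 3, seed = 2)
  pl <- attr(reads, "placements")
  pl <- pl[pl$retained, ]
  for (i in sample(nrow(pl), 25)) {
    expected <- Biostrings::subseq(g$sequences[[pl$chrom[i]]],
                                   pl$start[i], pl$end[i])
    if (pl$strand[i] == "-") {
      expected <- Biostrings::reverseComplement(expected)
    }
    expect_identical(as.character(reads[[pl$read[i]]]),
                     as.character(expected))
  }
})

test_that("read lengths follow the stated median and coverage hits target", {
  g <- build_genome(sim_config(seed = 5, chrom_length = 5e5,
                               satellite_array_len = 0, rdna5S_copies = 0L,
                               rdna45S_copies = 0L, n_chromosomes = 1L,
                               lc_tracts = data.frame(motif = character(),
                                                      length = integer())))
  reads <- simulate_reads(g, read_profile("hifi", median_len = 2000,
                                          len_dispersion = 0.25),
                          target_coverage = 20, seed = 4)
  w <- Biostrings::width(reads)
  expect_gt(stats::median(w), 2000 * 0.95)
  expect_lt(stats::median(w), 2000 * 1.05)
  # mean coverage within 3 standard errors of target (no dropout regions)
  cov <- sum(as.numeric(w)) / 5e5
  se <- stats::sd(w) * sqrt(length(w)) / 5e5
  expect_lt(abs(cov - 20), max(3 * se, 0.5))
})

test_that("CLR reads span GA tracts while HiFi reads drop out as 2^(-L/h)", {
  tract_len <- 2100L
  cfg <- sim_config(seed = 11, n_chromosomes = 1L, chrom_length = 2e5,
                    satellite_array_len = 0, rdna5S_copies = 0L,
                    rdna45S_copies = 0L, organellar_insert_len = 0L,
                    n_te_copies = 0L,
                    lc_tracts = data.frame(motif = "GA",
                                           length = tract_len))
  g <- build_genome(cfg)
  tr <- g$truth[S4Vectors::mcols(g$truth)$feature_class ==
                  "low_complexity_GA"]
  expect_equal(GenomicRanges::width(tr), tract_len)

  # CLR: coverage inside the tract within 15% of the genome-wide mean
  ratios <- vapply(1:10, function(s) {
    r <- simulate_reads(g, read_profile("clr", median_len = 5000,
                                        per_base_error = 0),
                        target_coverage = 25, seed = 100 + s)
    pl <- attr(r, "placements")
    pl <- pl[pl$retained, ]
    inside <- pmin(pl$end, GenomicRanges::end(tr)) -
      pmax(pl$start, GenomicRanges::start(tr)) + 1
    cov_in <- sum(pmax(0, inside)) / tract_len
    cov_all <- sum(pl$end - pl$start + 1) / 2e5
    cov_in / cov_all
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 1), 0.15)

  # HiFi with halflife 700: spanning reads retained at ~2^(-3) = 0.125
  halflife <- 700
  kept <- 0L; total <- 0L
  for (s in 1:6) {
    r <- simulate_reads(g, read_profile("hifi", median_len = 6000,
                                        dropout_halflife = halflife,
                                        dropout_flank = 0),
                        target_coverage = 25, seed = 200 + s)
    pl <- attr(r, "placements")
    span <- pl$start <= GenomicRanges::start(tr) &
      pl$end >= GenomicRanges::end(tr)
    kept <- kept + sum(pl$retained[span])
    total <- total + sum(span)
  }
  p_expected <- 2^(-tract_len / halflife)
  p_obs <- kept / total
  tol <- 4 * sqrt(p_expected * (1 - p_expected) / total)
  expect_lt(abs(p_obs - p_expected), tol)
})

test_that("fragmentation plants the configured breaks and AGP round-trips", {
  g <- af_fixture("genome")
  # no breaks: one contig per chromosome, scaffolds identical to genome
  none <- fragment_assembly(g, c(centromere_satellite = 0), seed = 1)
  expect_equal(length(none$contigs), length(g$sequences))
  expect_identical(as.character(none$scaffolds),
                   as.character(g$sequences))

  hifi <- fragment_assembly(g, break_model_hifi(), seed = 5)
  n_lc <- sum(S4Vectors::mcols(g$truth)$feature_class %in%
                c("low_complexity_GA", "low_complexity_GAA"))
  n_45S <- sum(S4Vectors::mcols(g$truth)$feature_class == "rDNA_45S")
  expect_equal(nrow(hifi$gap_truth), n_lc + n_45S)
  expect_true(all(
    hifi$gap_truth$cause[hifi$gap_truth$cause != "rDNA_45S"] %in%
      c("low_complexity_GA", "low_complexity_GAA")))
  # gap coordinates in the AGP match the removed spans exactly
  gaps <- find_gaps(hifi$scaffolds, hifi$plan)
  expect_equal(gaps$gap_start, hifi$gap_truth$removed_start)
  expect_equal(gaps$gap_len_estimate, hifi$gap_truth$gap_len)
  # replacing each N gap with the removed truth span restores the genome
  restored <- vapply(names(g$sequences), function(chrom) {
    s <- as.character(hifi$scaffolds[[chrom]])
    gt <- hifi$gap_truth[hifi$gap_truth$scaffold == chrom, , drop = FALSE]
    for (i in seq_len(nrow(gt))) {
      span <- as.character(Biostrings::subseq(
        g$sequences[[chrom]], gt$removed_start[i], gt$removed_end[i]))
      substr(s, gt$removed_start[i], gt$removed_end[i]) <- span
    }
    s
  }, character(1))
  expect_identical(unname(restored), unname(as.character(g$sequences)))

  # CLR-like model: every satellite block interval contains >= 1 break
  clr <- fragment_assembly(g, break_model_clr(), seed = 6)
  sat <- g$truth[S4Vectors::mcols(g$truth)$feature_class ==
                   "centromere_satellite"]
  brk <- GenomicRanges::GRanges(
    clr$gap_truth$scaffold,
    IRanges::IRanges(clr$gap_truth$removed_start,
                     clr$gap_truth$removed_end))
  expect_true(all(GenomicRanges::countOverlaps(sat, brk,
                                               ignore.strand = TRUE) >= 1))
  expect_error(fragment_assembly(g, c(nonsense_class = 1)), "unknown")
})
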