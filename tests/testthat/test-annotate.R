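test_that("telomere arrays are found on both strands with a copy floor", {
  set.seed(1)
  bg <- random_dna(2000, 0.4)
  seq_fwd <- paste0(strrep("CCCTAAA", 100), bg)
  hits <- find_telomere_arrays(seq_fwd, "CCCTAAA", min_copies = 60)
  expect_equal(length(hits), 1L)
  expect_equal(GenomicRanges::start(hits), 1L)
  expect_equal(GenomicRanges::end(hits), 700L)
  expect_equal(as.character(GenomicRanges::strand(hits)), "+")

  seq_rev <- paste0(bg, strrep("TTTAGGG", 100))
  hits <- find_telomere_arrays(seq_rev, "CCCTAAA", min_copies = 60)
  expect_equal(as.character(GenomicRanges::strand(hits)), "-")
  expect_equal(GenomicRanges::end(hits), nchar(seq_rev))

  # 59 copies under a 60-copy floor: no call
  short <- paste0(strrep("CCCTAAA", 59), bg)
  expect_equal(length(find_telomere_arrays(short, "CCCTAAA",
                                           min_copies = 60)), 0L)
})

test_that("tandem array scan recovers exact and diverged arrays", {
  set.seed(2)
  mono <- random_dna(178, 0.4)
  bg1 <- random_dna(3000, 0.4); bg2 <- random_dna(10000, 0.4)
  exact <- paste0(bg1, strrep(mono, 50), bg2)
  ta <- find_tandem_arrays(exact, mono)
  expect_equal(length(ta$arrays), 1L)
  expect_equal(S4Vectors::mcols(ta$arrays)$monomer_count, 50)
  expect_gte(S4Vectors::mcols(ta$arrays)$mean_identity, 0.999)
  # boundaries within one monomer of truth
  expect_lt(abs(GenomicRanges::start(ta$arrays) - (nchar(bg1) + 1)), 178)
  expect_lt(abs(GenomicRanges::end(ta$arrays) -
                  (nchar(bg1) + 50 * 178)), 178)

  # 5% diverged: count within +/-1, identity in [0.93, 0.97]
  div <- local({
    set.seed(33)
    copies <- vapply(1:50, function(i) {
      asmforensics:::mutate_seq(mono, 0.05)
    }, character(1))
    paste0(bg1, paste(copies, collapse = ""), bg2)
  })
  ta <- find_tandem_arrays(div, mono)
  expect_equal(length(ta$arrays), 1L)
  expect_lte(abs(S4Vectors::mcols(ta$arrays)$monomer_count - 50), 1)
  expect_gt(S4Vectors::mcols(ta$arrays)$mean_identity, 0.93)
  expect_lt(S4Vectors::mcols(ta$arrays)$mean_identity, 0.97)

  # two arrays split by 10 kb unique sequence stay separate
  two <- paste0(bg1, strrep(mono, 30), bg2, strrep(mono, 40), bg1)
  ta <- find_tandem_arrays(two, mono)
  expect_equal(length(ta$arrays), 2L)
  expect_error(find_tandem_arrays(two, "ACGTACGT"), "50-20000")
})

test_that("low-complexity tracts are found with purity on either strand", {
  set.seed(3)
  bg <- random_dna(3000, 0.5)
  ga <- paste0(bg, strrep("GA", 500), bg)
  hits <- find_low_complexity(ga)
  expect_equal(length(hits), 1L)
  expect_equal(S4Vectors::mcols(hits)$feature_class, "low_complexity_GA")
  expect_equal(GenomicRanges::width(hits), 1000L)
  expect_equal(S4Vectors::mcols(hits)$purity, 1.0)

  # TTC tract = reverse strand of GAA
  ttc <- paste0(bg, strrep("TTC", 300), bg)
  hits <- find_low_complexity(ttc)
  expect_equal(S4Vectors::mcols(hits)$feature_class, "low_complexity_GAA")

  # (GA)x100 with 10 scattered substitutions, compared to a
  # sliding-window purity oracle
  tract <- strrep("GA", 100)
  set.seed(17)
  pos <- sort(sample(10:190, 10))
  for (p in pos) substr(tract, p, p) <- "T"
  noisy <- paste0(bg, tract, bg)
  hits <- find_low_complexity(noisy, min_len = 100, min_purity = 0.85)
  expect_equal(length(hits), 1L)
  expect_gte(GenomicRanges::width(hits), 180)
  # oracle: fraction of bases inside exact GA/TC matches over the call
  called <- substr(noisy, GenomicRanges::start(hits),
                   GenomicRanges::end(hits))
  m <- gregexpr("GA|TC", called)[[1]]
  covered <- length(unique(unlist(
    lapply(m, function(s) s + 0:1))))
  expect_gte(covered / nchar(called), 0.85)
})

test_that("low-complexity detection is strand-symmetric", {
  set.seed(4)
  s <- paste0(random_dna(1000, 0.5), strrep("GAA", 200),
              random_dna(500, 0.5), strrep("GA", 300),
              random_dna(800, 0.5))
  fwd <- find_low_complexity(s)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  rev <- find_low_complexity(rc)
  expect_equal(length(fwd), length(rev))
  expect_setequal(S4Vectors::mcols(fwd)$feature_class,
                  S4Vectors::mcols(rev)$feature_class)
  # mirrored coordinates
  n <- nchar(s)
  expect_setequal(GenomicRanges::start(fwd),
                  sort(n - GenomicRanges::end(rev) + 1))
})

test_that("library annotation respects match length and identity floors", {
  set.seed(5)
  unit <- random_dna(500, 0.5)
  bg <- random_dna(4000, 0.4)
  lib <- data.frame(name = "u5S", class = "rDNA_5S", consensus = unit,
                    min_match_len = 100L, min_identity = 0.9,
                    stringsAsFactors = FALSE)
  one <- paste0(bg, unit, bg)
  hits <- annotate_library(one, lib)
  expect_equal(length(hits), 1L)
  expect_equal(S4Vectors::mcols(hits)$feature_class, "rDNA_5S")
  expect_lte(abs(GenomicRanges::start(hits) - (nchar(bg) + 1)), 5)
  expect_lte(abs(GenomicRanges::end(hits) - (nchar(bg) + 500)), 5)

  # nothing similar: empty annotation
  expect_equal(length(annotate_library(bg, lib)), 0L)

  # a diverged copy measured at < 90% identity by a pairwise-alignment
  # oracle is rejected at min_identity 0.9 but found at 0.8
  degraded <- local({
    set.seed(99)
    asmforensics:::mutate_seq(unit, 0.12)
  })
  oracle_pid <- Biostrings::pid(Biostrings::pairwiseAlignment(
    Biostrings::DNAString(degraded), Biostrings::DNAString(unit),
    type = "global"), "PID1") / 100
  expect_lt(oracle_pid, 0.9)
  two <- paste0(bg, degraded, bg)
  expect_equal(length(annotate_library(two, lib)), 0L)
  lib$min_identity <- 0.8
  expect_equal(length(annotate_library(two, lib)), 1L)
})

test_that("hierarchy merge keeps the priority class whole", {
  # organellar [100,400) over TE [300,600) -> organellar keeps its extent,
  # TE is truncated to [400,600)
  anno <- gr(c("c", "c"), c(100, 300), c(399, 599),
             c("organellar", "TE"))
  merged <- merge_hierarchy(anno)
  df <- as.data.frame(merged)
  org <- df[df$feature_class == "organellar", ]
  te <- df[df$feature_class == "TE", ]
  expect_equal(c(org$start, org$end), c(100, 399))
  expect_equal(c(te$start, te$end), c(400, 599))

  # disjoint input unchanged
  disj <- gr(c("c", "c"), c(1, 1000), c(10, 1100), c("TE", "rDNA_5S"))
  m2 <- merge_hierarchy(disj)
  expect_equal(sort(GenomicRanges::start(m2)), c(1, 1000))

  # identical intervals: only the higher-priority class survives
  same <- gr(c("c", "c"), c(5, 5), c(50, 50), c("rDNA_5S", "TE"))
  m3 <- merge_hierarchy(same)
  expect_equal(S4Vectors::mcols(m3)$feature_class, "rDNA_5S")

  expect_error(merge_hierarchy(anno, hierarchy = c("TE")), "missing")
})

test_that("hierarchy merge is idempotent and leaves no overlapping bases", {
  set.seed(6)
  anno <- gr(rep("c", 30),
             start <- sample(1:5000, 30),
             start + sample(50:500, 30, replace = TRUE),
             sample(setdiff(feature_classes, "non_repetitive"), 30,
                    replace = TRUE))
  m1 <- merge_hierarchy(anno)
  m2 <- merge_hierarchy(m1)
  expect_equal(as.data.frame(m1)[, c("start", "end", "feature_class")],
               as.data.frame(m2)[, c("start", "end", "feature_class")])
  expect_equal(
    sum(GenomicRanges::width(m1)),
    sum(GenomicRanges::width(GenomicRanges::reduce(m1,
                                                   ignore.strand = TRUE))))
  # the top-priority class present keeps every base
  top <- default_hierarchy[default_hierarchy %in%
                             S4Vectors::mcols(anno)$feature_class][1]
  before <- sum(GenomicRanges::width(GenomicRanges::reduce(
    anno[S4Vectors::mcols(anno)$feature_class == top],
    ignore.strand = TRUE)))
  after <- sum(GenomicRanges::width(
    m1[S4Vectors::mcols(m1)$feature_class == top]))
  expect_equal(after, before)
})

test_that("identity map flags duplicated and diverged windows", {
  set.seed(7)
  win <- 1000L
  a <- random_dna(win, 0.5)
  b <- local({ set.seed(8); asmforensics:::mutate_seq(a, 0.05) })
  u <- random_dna(win, 0.5)
  region <- paste0(a, a, b, u)
  im <- identity_map(region, window = win)
  expect_equal(dim(im$identity), c(4, 4))
  expect_equal(diag(im$identity), rep(1, 4))
  expect_equal(im$identity[1, 2], 1.0, tolerance = 1e-6)
  expect_gt(im$identity[1, 3], 0.90)
  expect_lt(im$identity[1, 3], 0.98)
  expect_true(is.na(im$identity[1, 4]))
  expect_error(identity_map(a, window = win), "two windows")
})

test_that("full annotation recovers planted repeats on the default genome", {
  g <- af_fixture("genome")
  anno <- af_fixture("annotation")
  # >= 99% of planted non-satellite repeat bases, >= 95% of satellite
  for (cls in c("telomere", "rDNA_5S", "rDNA_45S", "organellar",
                "low_complexity_GA", "low_complexity_GAA")) {
    r <- recovered_fraction(g$truth, anno, cls)
    expect_gte(r$recovered, 0.99)
  }
  sat <- recovered_fraction(g$truth, anno, "centromere_satellite")
  expect_gte(sat$recovered, 0.95)
  # <= 1% false annotated bases overall
  tr_all <- GenomicRanges::reduce(g$truth, ignore.strand = TRUE)
  an_all <- GenomicRanges::reduce(anno, ignore.strand = TRUE)
  fp <- sum(GenomicRanges::width(GenomicRanges::setdiff(
    an_all, tr_all, ignore.strand = TRUE)))
  expect_lte(fp / sum(GenomicRanges::width(an_all)), 0.01)
})
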