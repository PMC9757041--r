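# independent oracle: enumerate all k-windows, canonicalise in R
naive_kmer_counts <- function(seqs, k) {
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  all <- unlist(lapply(seqs, function(s) {
    n <- nchar(s) - k + 1
    if (n < 1) return(character(0))
    w <- substring(s, 1:n, 1:n + k - 1)
    w[!grepl("[^ACGT]", w)]
  }))
  if (!length(all)) return(table(character(0)))
  canon <- vapply(all, function(w) min(w, rc(w)), character(1))
  table(canon)
}

test_that("k-mer counting agrees with a naive enumeration oracle", {
  set.seed(20)
  seqs <- c(random_dna(900, 0.5), random_dna(500, 0.3),
            paste0(random_dna(100, 0.5), "NN", random_dna(100, 0.5)))
  for (k in c(11, 18, 21)) {
    db <- count_kmers(seqs, k)
    oracle <- naive_kmer_counts(seqs, k)
    expect_equal(db$total_distinct, length(oracle))
    expect_equal(db$total_instances, sum(oracle))
    got <- stats::setNames(db$count, kmer_strings(db))
    expect_equal(sort(names(got)), sort(names(oracle)))
    expect_equal(unname(got[names(oracle)]), unname(as.numeric(oracle)))
  }
})

test_that("canonicalisation makes a sequence and its reverse complement equal", {
  set.seed(21)
  s <- random_dna(2000, 0.5)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  db1 <- count_kmers(s, 18)
  db2 <- count_kmers(rc, 18)
  expect_equal(db1$code, db2$code)
  expect_equal(db1$count, db2$count)
  # short periodic sequence: 23 windows, at most 4 distinct canonical k-mers
  db <- count_kmers(strrep("ACGT", 10), 18)
  expect_equal(db$total_instances, 23)
  expect_lte(db$total_distinct, 4)
  # all-N sequence: empty database
  expect_equal(count_kmers(strrep("N", 100), 18)$total_distinct, 0)
})

test_that("reliable threshold finds the error/coverage valley", {
  # bimodal: error peak at 1-2, valley at 4, coverage peak at 30
  h <- data.frame(count = c(1, 2, 3, 4, 5, 20, 30, 40),
                  freq = c(1000, 300, 60, 10, 40, 200, 400, 150))
  expect_equal(reliable_threshold(h), 4L)
  # unimodal (error-only): fallback 2
  h2 <- data.frame(count = 1:5, freq = c(1000, 400, 100, 20, 5))
  expect_equal(reliable_threshold(h2), 2L)
  expect_error(reliable_threshold(data.frame(count = integer(),
                                             freq = numeric())), "empty")
})

test_that("QV follows the closed-form error model", {
  set.seed(22)
  genome <- random_dna(10000, 0.5)
  # error-free reads covering every position at least twice
  starts <- seq(1, 9001, by = 500)
  reads <- substring(genome, starts, pmin(starts + 999, 10000))
  rdb <- count_kmers(reads, 18)
  adb <- count_kmers(genome, 18)
  # faithful assembly: no assembly-only k-mers, QV at the cap
  expect_equal(kmer_qv(adb, rdb)$qv, 99)

  # one interior substitution: 18 novel k-mers out of 9983 instances
  mutated <- genome
  old <- substr(mutated, 5000, 5000)
  substr(mutated, 5000, 5000) <- setdiff(c("A", "C", "G", "T"), old)[1]
  mdb <- count_kmers(mutated, 18)
  res <- kmer_qv(mdb, rdb)
  expect_equal(res$total_instances, 10000 - 18 + 1)
  expect_equal(res$absent_instances, 18)
  p <- 18 / 9983
  qv_expected <- -10 * log10(1 - (1 - p)^(1 / 18))
  expect_lt(abs(res$qv - qv_expected), 0.1)

  # completely wrong assembly: P = 1, QV = 0
  set.seed(23)
  junk <- count_kmers(random_dna(5000, 0.5), 18)
  expect_equal(kmer_qv(junk, count_kmers("ACGTACGTACGTACGTACGTACG", 18))$qv,
               0)
  expect_error(kmer_qv(count_kmers(character(0), 18), rdb), "empty")
  expect_error(kmer_qv(adb, count_kmers(reads, 21)), "share k")
})

test_that("QV decreases monotonically with introduced substitutions", {
  set.seed(24)
  genome <- random_dna(20000, 0.5)
  starts <- seq(1, 19001, by = 400)
  rdb <- count_kmers(substring(genome, starts,
                               pmin(starts + 799, 20000)), 18)
  qvs <- vapply(c(0, 2, 10, 25, 50), function(nerr) {
    m <- genome
    if (nerr > 0) {
      pos <- seq(100, 19900, length.out = nerr)
      for (p in round(pos)) {
        old <- substr(m, p, p)
        substr(m, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1]
      }
    }
    kmer_qv(count_kmers(m, 18), rdb)$qv
  }, numeric(1))
  expect_true(all(diff(qvs) < 0))
})

test_that("completeness reflects missing assembly fractions", {
  set.seed(25)
  genome <- random_dna(20000, 0.5)
  starts <- seq(1, 19001, by = 400)
  reads <- substring(genome, starts, pmin(starts + 799, 20000))
  rdb <- count_kmers(reads, 18)
  full <- kmer_completeness(count_kmers(genome, 18), rdb, threshold = 1)
  expect_equal(full$completeness, 100)
  # assembly missing a 10% unique region: ~90% completeness
  partial <- paste0(substr(genome, 1, 9000), substr(genome, 11001, 20000))
  pc <- kmer_completeness(count_kmers(partial, 18), rdb, threshold = 1)
  expect_lt(abs(pc$completeness - 90), 1.5)
  empty <- count_kmers(character(0), 18)
  expect_equal(kmer_completeness(empty, rdb, threshold = 1)$completeness, 0)
})

test_that("genome size estimation divides spectrum mass by the peak", {
  # constructed histogram: 1e6 distinct k-mers all at count 40
  h <- data.frame(count = 40, freq = 1e6)
  expect_equal(genome_size_from_histogram(h), 1e6)
  # low-coverage spectrum: no separated peak -> error
  h1 <- data.frame(count = c(1, 2), freq = c(5e5, 1e3))
  expect_error(genome_size_from_histogram(h1), "coverage")
})

test_that("genome size from simulated error-free reads is within 2%", {
  g <- build_genome(sim_config(seed = 31, n_chromosomes = 1L,
                               chrom_length = 3e5,
                               satellite_array_len = 2e4,
                               rdna5S_copies = 40L, rdna45S_copies = 1L))
  # uniform-coverage error-free reads (the estimator models the PCR-free
  # short-read regime: no low-complexity dropout)
  reads <- simulate_reads(g, read_profile("clr", per_base_error = 0),
                          target_coverage = 40, seed = 6)
  est <- genome_size_from_histogram(count_kmers(reads, 21))
  truth <- sum(Biostrings::width(g$sequences))
  expect_lt(abs(est - truth) / truth, 0.02)
})
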