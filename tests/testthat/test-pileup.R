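make_aln <- function(qname, tstart, len, tname = "t", strand = "+") {
  data.frame(qname = qname, qlen = len, qstart = 1L, qend = len,
             strand = strand, tname = tname, tlen = 10000L,
             tstart = tstart, tend = tstart + len - 1L,
             nmatch = len, alen = len, mapq = 60L,
             cigar = paste0(len, "M"), tp = "P", stringsAsFactors = FALSE)
}

test_that("pileup counts primary and secondary bases per column", {
  set.seed(50)
  ref <- random_dna(200, 0.5)
  asm <- Biostrings::DNAStringSet(c(t = ref))
  # 6 identical reads: secondary zero everywhere covered
  reads <- Biostrings::DNAStringSet(
    stats::setNames(rep(ref, 6), paste0("r", 1:6)))
  aln <- do.call(rbind, lapply(1:6, function(i) {
    make_aln(paste0("r", i), 1L, 200L)
  }))
  tr <- allele_pileup(aln, reads, asm)
  expect_equal(tr$depth, rep(6, 200))
  expect_equal(tr$primary, rep(6, 200))
  expect_equal(tr$secondary, rep(0, 200))

  # a 50/50 split column: primary 10, secondary 10
  alt <- ref
  old <- substr(alt, 100, 100)
  substr(alt, 100, 100) <- setdiff(c("A", "C", "G", "T"), old)[1]
  reads2 <- Biostrings::DNAStringSet(
    stats::setNames(c(rep(ref, 10), rep(alt, 10)), paste0("q", 1:20)))
  aln2 <- do.call(rbind, lapply(1:20, function(i) {
    make_aln(paste0("q", i), 1L, 200L)
  }))
  tr2 <- allele_pileup(aln2, reads2, asm)
  expect_equal(tr2$primary[100], 10)
  expect_equal(tr2$secondary[100], 10)
  expect_equal(tr2$secondary[99], 0)
})

test_that("pileup agrees with a naive per-column oracle", {
  set.seed(51)
  ref <- random_dna(500, 0.5)
  asm <- Biostrings::DNAStringSet(c(t = ref))
  n <- 40
  starts <- sample(1:300, n, replace = TRUE)
  lens <- sample(50:200, n, replace = TRUE)
  strands <- sample(c("+", "-"), n, replace = TRUE)
  seqs <- character(n)
  for (i in 1:n) {
    s <- asmforensics:::mutate_seq(substr(ref, starts[i],
                                          starts[i] + lens[i] - 1L), 0.02)
    seqs[i] <- if (strands[i] == "-") {
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    } else {
      s
    }
  }
  reads <- Biostrings::DNAStringSet(stats::setNames(seqs, paste0("r", 1:n)))
  aln <- do.call(rbind, lapply(1:n, function(i) {
    make_aln(paste0("r", i), starts[i], lens[i], strand = strands[i])
  }))
  tr <- allele_pileup(aln, reads, asm)

  # oracle: stack aligned bases column by column
  cols <- matrix(0L, 4, 500)
  bases <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  for (i in 1:n) {
    s <- seqs[i]
    if (strands[i] == "-") {
      s <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(s)))
    }
    ch <- strsplit(s, "")[[1]]
    for (j in seq_along(ch)) {
      cols[bases[[ch[j]]], starts[i] + j - 1L] <-
        cols[bases[[ch[j]]], starts[i] + j - 1L] + 1L
    }
  }
  expect_equal(tr$depth, colSums(cols))
  expect_equal(tr$primary, apply(cols, 2, max))
  expect_equal(tr$secondary,
               apply(cols, 2, function(x) sort(x, decreasing = TRUE)[2]))
})

test_that("alignments without CIGAR are skipped with a warning", {
  set.seed(52)
  ref <- random_dna(100, 0.5)
  asm <- Biostrings::DNAStringSet(c(t = ref))
  reads <- Biostrings::DNAStringSet(c(r1 = ref))
  aln <- make_aln("r1", 1L, 100L)
  aln$cigar <- NA_character_
  expect_warning(tr <- allele_pileup(aln, reads, asm), "skipped")
  expect_equal(sum(tr$depth), 0)
})

test_that("region flagging separates collapse, bias and normal", {
  # synthetic track: 10 kb at depth 30; positions 2000-2500 with recurrent
  # secondary ~10; positions 6000-7000 at doubled primary, no secondary
  pos <- 1:10000
  depth <- rep(30, 10000); prim <- rep(30, 10000); sec <- rep(0, 10000)
  mark <- seq(2000, 2500, by = 50)
  sec[mark] <- 10; prim[mark] <- 20
  hot <- 6000:7000
  depth[hot] <- 60; prim[hot] <- 60
  track <- data.frame(chrom = "t", pos = pos, depth = depth,
                      primary = prim, secondary = sec)
  fl <- flag_regions(track, depth_band = c(10, 45))
  col <- fl[fl$label == "collapsed", ]
  expect_equal(nrow(col), 1)
  expect_lte(col$start, 2000)
  expect_gte(col$end, 2500)
  bias <- fl[fl$label == "coverage_bias", ]
  expect_equal(nrow(bias), 1)
  expect_gte(bias$start, 5999)
  expect_lte(bias$end, 7001)
  expect_true("normal" %in% fl$label)

  # uniform faithful region: everything normal
  quiet <- data.frame(chrom = "t", pos = 1:2000, depth = 30,
                      primary = 30, secondary = 0)
  fq <- flag_regions(quiet, depth_band = c(10, 45))
  expect_equal(unique(fq$label), "normal")
})

test_that("a planted collapse is detected with >= 90% base sensitivity", {
  set.seed(53)
  flank <- random_dna(10000, 0.4)
  copyA <- random_dna(10000, 0.4)
  copyB <- asmforensics:::mutate_seq(copyA, 0.02)
  tail_seq <- random_dna(10000, 0.4)
  genome_seq <- paste0(flank, copyA, tail_seq, copyB)
  gen <- structure(list(
    sequences = Biostrings::DNAStringSet(c(chrT = genome_seq)),
    truth = feature_granges(character(), integer(), integer(),
                            character())), class = "sim_genome")
  reads <- simulate_reads(gen, read_profile("hifi", median_len = 1500,
                                            per_base_error = 0),
                          target_coverage = 30, seed = 3)
  pl <- attr(reads, "placements")
  pl <- pl[pl$retained, ]
  # assembly drops copyB; copyB reads map onto copyA coordinates
  asm <- Biostrings::DNAStringSet(c(asm1 = substr(genome_seq, 1, 30000)))
  inB <- pl$start >= 30001
  st <- ifelse(inB, pl$start - 20000L, pl$start)
  en <- ifelse(inB, pl$end - 20000L, pl$end)
  keep <- st >= 1 & en <= 30000
  w <- (en - st + 1L)[keep]
  aln <- data.frame(
    qname = pl$read[keep], qlen = w, qstart = 1L, qend = w,
    strand = pl$strand[keep], tname = "asm1", tlen = 30000L,
    tstart = st[keep], tend = en[keep], nmatch = w, alen = w,
    mapq = 60L, cigar = paste0(w, "M"), tp = "P",
    stringsAsFactors = FALSE)
  track <- allele_pileup(aln, reads, asm, region = "asm1:1-30000")
  fl <- flag_regions(track)
  col <- fl[fl$label == "collapsed", , drop = FALSE]
  covered <- sum(pmax(0, pmin(col$end, 20000) - pmax(col$start, 10001) + 1))
  expect_gte(covered / 10000, 0.9)
  # flagged collapse stays inside the duplicated region
  expect_true(all(col$start >= 9500 & col$end <= 20500))

  # faithful assembly of the same reads yields zero collapsed bases
  asm_full <- Biostrings::DNAStringSet(c(asm1 = genome_seq))
  w2 <- pl$end - pl$start + 1L
  aln2 <- data.frame(
    qname = pl$read, qlen = w2, qstart = 1L, qend = w2,
    strand = pl$strand, tname = "asm1", tlen = nchar(genome_seq),
    tstart = pl$start, tend = pl$end, nmatch = w2, alen = w2,
    mapq = 60L, cigar = paste0(w2, "M"), tp = "P",
    stringsAsFactors = FALSE)
  track2 <- allele_pileup(aln2, reads, asm_full,
                          region = sprintf("asm1:1-%d", nchar(genome_seq)))
  fl2 <- flag_regions(track2)
  expect_equal(nrow(fl2[fl2$label == "collapsed", ]), 0)
})
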