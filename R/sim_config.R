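#' Random DNA of a given GC content
#'
#' @param n length in bp.
#' @param gc GC fraction.
#' @return character scalar DNA sequence.
#' @export
random_dna <- function(n, gc = 0.5) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# substitute bases at `rate`; substitutions never reproduce the original
mutate_seq <- function(seq, rate) {
  if (rate <= 0 || !nchar(seq)) return(seq)
  n <- nchar(seq)
  k <- stats::rbinom(1, n, rate)
  if (k == 0) return(seq)
  pos <- sample.int(n, k)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
              G = c("A", "C", "T"), T = c("A", "C", "G"))
  chars[pos] <- vapply(chars[pos], function(b) {
    sample(alt[[b]] %||% c("A", "C", "G", "T"), 1)
  }, character(1))
  paste(chars, collapse = "")
}

#' Simulation configuration
#'
#' Defines the planted composition of a plant-like synthetic genome:
#' telomeres built from a [CCCTAAA] motif, a Mb-scale (here scaled down)
#' centromeric satellite array of a ~178 bp monomer split into
#' alternating-orientation strand blocks, 5S (~500 bp unit) and 45S
#' (10.7 kb unit) rDNA arrays, GA/GAA low-complexity tracts in the
#' 290-2326 bp range observed for residual assembly gaps, an organellar
#' insertion and a handful of TE copies on a background of fixed GC
#' content. All fixed consensus sequences (monomer, 5S unit, 45S unit, TE
#' library, organellar genome) are generated deterministically from
#' `seed`, so identical configs produce byte-identical genomes.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length chromosome length in bp.
#' @param satellite_monomer satellite monomer sequence (default: a fixed
#'   178 bp sequence derived from `seed`).
#' @param satellite_array_len target satellite array length in bp (rounded
#'   down to whole monomers; 0 disables the array).
#' @param satellite_divergence per-base substitution rate within the array.
#' @param n_strand_blocks number of alternating-orientation satellite
#'   blocks.
#' @param rdna5S_unit 5S unit sequence (default fixed 500 bp from `seed`).
#' @param rdna5S_copies 5S unit copies.
#' @param rdna45S_unit_len 45S unit length (default 10700).
#' @param rdna45S_copies 45S unit copies.
#' @param telomere_motif telomere motif (default "CCCTAAA").
#' @param telomere_copies motif copies per telomere.
#' @param lc_tracts data.frame with `motif` ("GA"/"GAA") and `length`
#'   columns; default 6 tracts with lengths drawn uniformly from
#'   [290, 2326].
#' @param organellar_insert_len organellar insertion length.
#' @param te_library character vector of TE consensus sequences (default 4
#'   fixed 3 kb sequences from `seed`).
#' @param n_te_copies TE copies planted per genome.
#' @param gc_background background GC fraction (default 0.36, plant-like).
#' @param min_spacer minimum background spacing between planted features.
#' @param seed master integer seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 2L,
                       chrom_length = 1e6,
                       satellite_monomer = NULL,
                       satellite_array_len = 150000,
                       satellite_divergence = 0.05,
                       n_strand_blocks = 3L,
                       rdna5S_unit = NULL,
                       rdna5S_copies = 400L,
                       rdna45S_unit_len = 10700L,
                       rdna45S_copies = 6L,
                       telomere_motif = "CCCTAAA",
                       telomere_copies = 100L,
                       lc_tracts = NULL,
                       organellar_insert_len = 20000L,
                       te_library = NULL,
                       n_te_copies = 8L,
                       gc_background = 0.36,
                       min_spacer = 5000L,
                       seed = 1L) {
  stopifnot(n_chromosomes >= 1, chrom_length > 0,
            satellite_divergence >= 0, satellite_divergence < 1,
            nchar(telomere_motif) >= 4, gc_background > 0,
            gc_background < 1)
  cfg <- with_seed(seed + 777L, {
    if (is.null(satellite_monomer)) satellite_monomer <- random_dna(178, 0.4)
    if (is.null(rdna5S_unit)) rdna5S_unit <- random_dna(500, 0.5)
    rdna45S_unit <- random_dna(rdna45S_unit_len, 0.55)
    if (is.null(te_library)) {
      te_library <- vapply(1:4, function(i) random_dna(3000, 0.4),
                           character(1))
      names(te_library) <- paste0("TE", seq_along(te_library))
    }
    if (is.null(names(te_library))) {
      names(te_library) <- paste0("TE", seq_along(te_library))
    }
    organellar_genome <- random_dna(organellar_insert_len, 0.45)
    if (is.null(lc_tracts)) {
      lc_tracts <- data.frame(
        motif = sample(c("GA", "GAA"), 6, replace = TRUE,
                       prob = c(0.7, 0.3)),
        length = round(stats::runif(6, 290, 2326))
      )
    }
    list(satellite_monomer = toupper(satellite_monomer),
         rdna5S_unit = toupper(rdna5S_unit),
         rdna45S_unit = rdna45S_unit,
         te_library = te_library,
         organellar_genome = organellar_genome,
         lc_tracts = lc_tracts)
  })
  stopifnot(all(cfg$lc_tracts$motif %in% c("GA", "GAA")),
            all(cfg$lc_tracts$length > 0))
  structure(
    list(n_chromosomes = as.integer(n_chromosomes),
         chrom_length = as.integer(chrom_length),
         satellite_monomer = cfg$satellite_monomer,
         satellite_array_len = satellite_array_len,
         satellite_divergence = satellite_divergence,
         n_strand_blocks = as.integer(n_strand_blocks),
         rdna5S_unit = cfg$rdna5S_unit,
         rdna5S_copies = as.integer(rdna5S_copies),
         rdna45S_unit = cfg$rdna45S_unit,
         rdna45S_unit_len = as.integer(rdna45S_unit_len),
         rdna45S_copies = as.integer(rdna45S_copies),
         telomere_motif = toupper(telomere_motif),
         telomere_copies = as.integer(telomere_copies),
         lc_tracts = cfg$lc_tracts,
         organellar_insert_len = as.integer(organellar_insert_len),
         organellar_genome = cfg$organellar_genome,
         te_library = cfg$te_library,
         n_te_copies = as.integer(n_te_copies),
         gc_background = gc_background,
         min_spacer = as.integer(min_spacer),
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Long-read profile
#'
#' Read-length and error model for the simulator. Lengths are log-normal,
#' parameterised by their median and a dispersion (sdlog). HiFi-mode reads
#' are >99% accurate and suffer a coverage dropout over GA/GAA
#' low-complexity tracts: a read overlapping a tract of length L (extended
#' by `dropout_flank` on both sides) is retained with probability
#' 2^(-L / dropout_halflife). CLR-mode reads are noisier but span
#' low-complexity tracts without loss (halflife forced to Inf).
#'
#' @param mode "hifi" or "clr".
#' @param median_len median read length in bp.
#' @param len_dispersion sdlog of the log-normal length distribution.
#' @param per_base_error substitution rate (hifi <= 0.01).
#' @param dropout_halflife tract length (bp) at which a spanning read
#'   survives with probability 0.5 (hifi only).
#' @param dropout_flank bp beyond the tract over which the coverage
#'   depression extends.
#' @return list of class `read_profile`.
#' @export
read_profile <- function(mode = c("hifi", "clr"),
                         median_len = if (mode == "clr") 6000 else 2000,
                         len_dispersion = 0.25,
                         per_base_error = if (mode == "clr") 0.12 else 0.001,
                         dropout_halflife = 700,
                         dropout_flank = 2000) {
  mode <- match.arg(mode)
  if (mode == "hifi" && per_base_error > 0.01) {
    stop("hifi per-base error must be <= 0.01", call. = FALSE)
  }
  if (mode == "clr") dropout_halflife <- Inf
  structure(
    list(mode = mode, median_len = median_len,
         len_dispersion = len_dispersion,
         per_base_error = per_base_error,
         dropout_halflife = dropout_halflife,
         dropout_flank = dropout_flank),
    class = "read_profile"
  )
}
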