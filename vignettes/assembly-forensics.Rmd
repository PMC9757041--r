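---
title: "Assembly forensics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembly forensics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements:
what is being modelled, which parameters matter, what the synthetic data
do and do not emulate, and where a design was genuinely open, why it was
resolved the way it was.

## The problem

Long-read assemblies of repeat-rich plant genomes fail at characteristic
sequences. Assemblies from noisy continuous long reads (CLR) break in
megabase centromeric satellite arrays and in 5S/45S ribosomal DNA
clusters. High-fidelity (HiFi) reads assemble straight through those —
but HiFi sequencing depth collapses over short GA/TC and GAA/TTC
low-complexity tracts, so the few gaps left in otherwise
telomere-to-telomere HiFi assemblies sit precisely on such tracts, which
are only a few hundred to a couple of thousand bp long. Diagnosing an
assembly therefore requires: a repeat annotation that names the usual
suspects, contiguity and consensus-quality metrics, a classifier for
what sits at contig edges and in scaffold gaps, a patching operation
that recovers gap content from a complementary assembly, copy-number
estimates for tandem gene families that assemblies routinely collapse or
expand, and a pileup diagnostic that separates true collapses from mere
coverage bias.

## Coordinates and containers

All intervals are `GRanges` (1-based, closed), the native convention of
the Bioconductor stack this package is built on; BED (0-based,
half-open) and AGP/GFF3/PAF conventions are converted exactly once, at
the file boundary. Sequences are `DNAStringSet`s. Feature classes form a
fixed vocabulary (`feature_classes`) with a default priority order
(`default_hierarchy`): organellar insertions outrank rDNAs (45S over 5S,
which the source ordering leaves unspecified), then satellite, telomere,
low-complexity, TE. Ties at equal distance in edge classification are
broken by this same order.

## Annotation

*Telomeres.* Exact motif matches (default `CCCTAAA`, either strand) are
chained into tandem runs; one mutated copy may be skipped between exact
copies, and a run is reported if it has at least `min_copies` copies
with at most 10% of them mismatching. Default `min_copies = 10` — low
enough to find partial telomeres at contig ends; the simulator plants
100-copy telomeres.

*Satellite arrays.* Detection is monomer-seeded, not de novo: every
12-mer of the supplied monomer (both orientations) is matched exactly,
and hits merge into strand blocks across gaps up to one monomer length.
Adjacent blocks form an array; monomer count is span divided by monomer
length. Identity is estimated per strand block — never across an
inversion boundary — by aligning sampled monomer-sized chunks against
the doubled consensus (doubling makes the estimate rotation-invariant),
and averaging weighted by block length. With 12-mer seeds, a seed
survives a uniformly diverged copy with probability (1−d)^12 (0.54 at
d = 0.05), so seed hits stay dense and boundaries track the true array
edges to within a few bases; the contract tested is within one monomer.

*Low-complexity tracts.* A tract is a maximal interval in which the
fraction of bases covered by exact motif matches (GA or its complement
TC; GAA/TTC) is at least `min_purity` (default 0.85, length ≥ 100 bp).
Candidates are built by merging matches across gaps up to 10 bp; edge
runs shorter than the gap attaching them are trimmed, which keeps a pure
tract's boundaries exact even when stray dimers sit nearby. Detection is
strand-symmetric by construction. Where GA and GAA calls overlap, the
purer call wins.

*Library elements* (rDNA units, TEs, organellar genomes). One
seed-and-chain engine serves both annotation and read-based unit
counting: exact 12-mer seeds from the consensus, hits merged into blocks
across ≤ 50 bp gaps, identity verified afterwards by global-local
alignment of sampled chunks (≤ 1 kb, ≤ 4 per block — alignment cost is
quadratic in chunk length, and identity is an average, so sampling
suffices). Global-local rather than local alignment is deliberate: local
alignment clips divergent ends and overstates identity. For blocks
shorter than the consensus, boundaries are first pushed outward while
50 bp probes of flanking sequence still match the uncovered consensus
remainder (probe identity ≥ 0.6); this prevents a uniformly diverged
element from being accepted on the strength of its seed-dense core,
while leaving genuinely truncated elements (at contig edges) untouched.
Per-entry thresholds default to 100 bp minimum match and 0.8 minimum
identity; the source workflow's masking-score cutoff is tool-internal
and deliberately replaced by these two explicit, reproducible knobs.

*Hierarchy merge.* Higher-priority classes keep their full extent;
lower-priority intervals are truncated or dropped, so every base carries
at most one class. The operation is idempotent, and the top class
present conserves all its bases — both are tested properties.

*Identity maps.* `identity_map()` tiles a region into windows (default
5 kb) and reports the best global-local alignment identity between every
window pair on both strands, with the strand of the best hit — the
windowed dot-plot view used to compare satellite array structure. Cost
is quadratic in window count; intended for single arrays, not
chromosomes.

## Contiguity, QV, completeness, genome size

NGx uses a fixed reference size as denominator (default x = 50). When
the cumulative assembly never reaches x% of the reference the function
returns 0 with a warning — an explicit sentinel, not an error, because
comparing assemblies smaller than the reference is routine. Ties in
contig length cannot affect the result (the cumulative sum is taken over
a sorted vector).

k-mer counting is exact and canonical (lexicographic minimum of k-mer
and reverse complement), implemented in C++ with a rolling 2-bit
encoding; windows containing N are skipped. k is restricted to [11, 26]
so every canonical code is exactly representable in a double (4^26 <
2^53); the defaults in use are k = 18 (QV/completeness) and k = 21
(genome size). QV compares k-mer *presence*, not counts: with P the
fraction of assembly k-mer instances absent from the reads,
E = 1 − (1−P)^(1/k), QV = −10·log₁₀E, capped at 99 when no
assembly-only k-mer exists (a finite reportable value). Completeness is
the fraction of reliable read k-mers (count at or above the first local
minimum between the error and coverage peaks of the read spectrum;
fallback 2 when unimodal) found in the assembly. The genome-size
estimate divides spectrum mass above that threshold by the coverage
peak, where the peak is a frequency-weighted mean over counts within
±40% of the mode — the discrete mode alone wobbles between adjacent
counts and biases the ratio by several percent. The estimator assumes
uniform read coverage (its natural input is PCR-free short reads);
feeding it HiFi reads whose coverage drops over low-complexity tracts
underestimates size by roughly the footprint of the dropout shadows,
and the tests exercise it with uniform-coverage reads for that reason.

All paired read databases are treated as one pool; paired-end merging is
an input detail, not a model choice.

## Break and gap forensics

Edge classification considers contigs strictly longer than 10 kb and the
first 2 kb from each edge; the nearest annotated element wins, distance
ties resolved by hierarchy. Both a per-edge summary and the combined
centromere+rDNA fraction are reported, over all edges and over
non-telomeric edges — a telomere-capped edge is a finished chromosome
end, not a break, and published break fractions do not state which
denominator they use, so the summary reports both.

Gap classification takes the highest-priority class intersecting either
2 kb flank; when a donor patch sequence exists for a gap, the
low-complexity classes are tested on the patch itself first and, if a
tract covers at least half the patch, that class is the cause — the
gap's actual content outranks its surroundings exactly for the repeat
class that assemblers drop. AGP "U" gaps (unknown length) participate in
classification but are excluded from size concordance.

Patching anchors the 5 kb of sequence adjacent to each gap side in the
donor: exact full-anchor match first, then a seeded fallback verified at
≥ 0.99 identity. Both anchors must hit uniquely, on one donor contig, in
consistent orientation and order; the donor span between them replaces
the gap. Spans above 50 kb are rejected as likely mis-anchoring
(confirmed real patches are ≤ ~2.3 kb; the cap is configurable). Failure
reasons are recorded per gap, and bases outside replaced spans are never
touched (tested). Gaps are processed right-to-left so scaffold
coordinates stay valid during replacement.

## Copy number

Unit matches are counted directly on reads: a contiguous tandem stretch
on a read is one matched block, counted as `round(block_len/unit_len)`
unit hits (minimum one for blocks longer than the 100 bp floor) — each
unit instance on each read counts once, and the estimate is unbiased
under uniform coverage. Division by genome-wide depth reports the
*integer part*: the published arithmetic (363,615/121.864 → 2983)
implies truncation, and the package truncates consistently — including
megabase spans reported to two decimals (11,288,500 bp → 11.28 Mb) and
percentages (83.126 → 83.12). Depth is computed from primary alignments
only. At desk scale the dominant error is the sampling fluctuation of
local coverage around the array (±2% at 30× with 2 kb reads), which is
why read/assembly agreement is tested at 5%.

## Collapse vs coverage bias

`allele_pileup()` counts, per position, the most and second-most
frequent read base from primary alignments (CIGAR-aware; records
without CIGAR are skipped with a warning). `flag_regions()` calls
"collapsed" where a secondary allele recurs (count ≥ 2, mirroring the
cited pileup tool's marker threshold) at ≥ 5 positions within 2 kb of
one another — sequencing errors do not recur at fixed positions,
diverged collapsed copies do — and "coverage_bias" where primary depth
exceeds the depth band (default mean ± 3 SD of the track) without
secondary support. The run-length and band defaults are this package's
own choices; the source describes the phenomenon visually.

## The simulator

Each chromosome is telomere | arm | satellite array | arm | telomere.
Arms host the 5S array, the organellar insertion, a subtelomeric 45S
array (on the last chromosome, as in real karyotypes), TE copies and
GA/GAA tracts, separated by at least 5 kb of background (36% GC) so
every planted feature is unambiguous within any 2 kb window. Defaults
are desk-scale versions of the study conditions: 2 × 1 Mb chromosomes,
a ~150 kb satellite array of a 178 bp monomer at 5% divergence in 3
alternating-orientation strand blocks, 400 × 500 bp 5S units, 6 × 10.7
kb 45S units, 20 kb organellar insertion, six low-complexity tracts
with lengths drawn from [290, 2326] bp (the observed range of real
HiFi-assembly patches), telomeres of 100 motif copies. All consensus
sequences derive deterministically from the single config seed; same
config, same genome, byte for byte.

Reads are log-normal in length (median-parameterised; the scaled-down
default is a 2 kb median against the real ~20 kb, keeping test run
times in minutes), substitution errors only. The HiFi dropout is
modelled as exponential: a read overlapping a GA/GAA tract of length L
(extended by `dropout_flank` = 2 kb, the scale over which real coverage
depressions extend beyond the tract) is retained with probability
2^(−L/halflife), halflife 700 bp. The source material shows the
phenomenon but fits no curve; the exponential form was chosen for its
single parameter and closed-form retention probability, which the test
suite verifies against simulation — it is a stand-in, not a claim about
polymerase chemistry. CLR mode has no dropout and ~12% error.

`fragment_assembly()` emulates assembler failure without an assembler:
for each truth feature whose class draws a break under the model
(CLR-style: satellite and rDNAs; HiFi-style: low-complexity tracts and
45S), the feature's interior is removed, leaving margins (60 bp to 2 kb,
15% of feature length) so the cause remains annotatable at the new
contig edges; the removed span becomes an AGP gap of exactly that
length, with the true cause recorded. This makes flank-based gap
classification, byte-exact patch restoration and AGP round-tripping all
simultaneously testable, and mirrors the real situation in which the
recovered patches *are* the low-complexity tracts.

What the simulator does not emulate: indels (the error model is
substitution-only, so CIGARs are single match runs), diploidy and
heterozygosity, optical maps, satellite higher-order structure, and
sequence-composition biases beyond the GA-tract dropout. Tests passing
on these conditions show the forensic logic is correct under its stated
model, not that it is robust to aligner artefacts or structural noise
in real data.

## Problem sizes and budgets

The default test conditions are the 2 Mb two-chromosome genome above,
with 20–30× simulated reads; the full suite (≈ 2,600 assertions) runs in
about two minutes, and the acceptance script in under a minute. The
pileup oracle is exercised on ≤ 30 kb regions; identity maps on 1 kb
windows; k-mer property tests on 10–20 kb constructions where expected
values can be enumerated or written in closed form.

## Known limitations

- Seed-and-chain matching assumes substitution-dominated divergence;
  indel-rich repeats would fragment blocks and need alignment-based
  chaining.
- The k-mer counter is in-memory; it is sized for desk-scale genomes
  (≲ 100 Mb of reads), not production datasets.
- `patch_gaps()` requires unique anchors; a gap inside a repeat longer
  than the 5 kb anchor cannot be patched and is reported as ambiguous
  rather than guessed.
- Read-based copy estimates inherit the local-coverage sampling noise of
  the region holding the array; at production scale (hundreds of Mb,
  whole-chromosome depth windows) this term is negligible, at desk scale
  it is the error budget.
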