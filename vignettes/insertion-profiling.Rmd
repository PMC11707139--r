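---
title: "Profiling transposon insertion sites from self-reporting junction reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling transposon insertion sites from self-reporting junction reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The analysis problem

piggyBac-superfamily transposons integrate almost exclusively into the host
tetramer TTAA, duplicating it on both sides of the insertion (the target-site
duplication, TSD).  Genome-wide integration profiling with a self-reporting
transposon produces *junction reads*: each read begins with a
transposon-derived prefix (an amplification primer running through the
terminal bases of the terminal inverted repeat, TIR), continues through the
duplicated TTAA, and ends in the 3′ genomic flank.  Recovering an insertion
catalogue from such reads takes five steps, each implemented here as a
composable, data-frame-in/tibble-out function:

1. **Trim** (`trim_reads()`): remove the transposon prefix, keeping the last
   `K` transposon bases for the junction logo, and discard reads lacking the
   transposon sequence.
2. **Map** (`build_kmer_index()`, `map_fragments()`): place the genomic
   fragment uniquely on the reference.
3. **Call** (`call_sites()`): canonicalize alignments to TTAA coordinates,
   validate the TSD against the reference, and normalize read counts to
   peaks per million (ppm).
4. **Profile** (`build_position_profile()`): the junction position frequency
   matrix and its per-position information content, the data behind sequence
   logos.
5. **Annotate and compare** (`*_feature_distribution()`,
   `compare_profiles()`): classify insertions by genomic feature against a
   TTAA-normalized expectation and compare conditions by a chi-square
   homogeneity test.

A first-class synthetic-data generator (`sim_config()`, `generate_genome()`,
`simulate_insertions()`, `simulate_reads()`) emulates the library structure
with known ground truth, so every stage is testable without external data.

## Coordinate canon and the TSD

All internal coordinates are 0-based half-open; GFF3's 1-based inclusive
convention is converted at the file boundary only.  An insertion site is the
coordinate of the first base of its TTAA tetramer.

TTAA is its own reverse complement.  The simulator exploits this: a forward
(F) junction read carries the plus-strand sequence starting at the TSD, and a
reverse (R) read carries the reverse complement of the sequence *ending* at
the TSD — both begin `prefix + TTAA…`.  The site caller inverts this: a
plus-strand alignment's site is its start, a minus-strand alignment's site is
`start + fragment_length − 4`.  Both strand cases of one insertion therefore
collapse to a single canonical coordinate, which the tests assert on every
simulated event.

## Parameters that matter

* `transposon_prefix` (simulator and `trim_config()`): the primer + TIR-tip
  sequence at the start of every junction read.  The default is a synthetic
  20-mer stand-in — real libraries must supply their own primer sequence.
* `retain_tail` `K` (default 4 nt): transposon bases kept on the trimmed
  read.  With `K = 4` and logo length `L = 15`, logo positions 1–4 are the
  TIR tip, 5–8 the TSD, 9–15 genomic flank.
* `max_mismatch_rate` `e` (default 0.10): the prefix is accepted with up to
  `floor(e × prefix_length)` mismatches.  The floor makes the accept/reject
  boundary exact and testable (an 8-mer prefix at `e = 0.10` tolerates zero
  mismatches; at `e = 0.15`, one).
* `min_genomic_length` (default 20 nt): fragments shorter than this after
  trimming are discarded as uninformative for unique placement.
* `k` (default 15) and `max_mismatches` (default 3): seed length and
  Hamming budget of the mapper, sized for 30–50 nt fragments.
* `error_rate`, `background_fraction`: per-base substitution probability and
  the fraction of reads that are random genomic fragments without a prefix.

## The mapper and its guarantee

The mapper is a deliberately small seed-and-extend scheme: candidate loci
come from the first N-free `k`-mer of the fragment (both strands, the minus
strand via the reverse-complemented fragment), and every candidate is scored
by full-length Hamming distance.  `unique` requires a single minimum within
budget; ties are `ambiguous` and only `unique` placements reach the site
caller.  There is no randomness anywhere in mapping.

The single-seed design carries an explicit contract: a fragment is guaranteed
to be recovered when its junction-proximal seed is exact, which holds for
every error-free read and for the overwhelming majority of reads at a 1%
substitution rate.  The test suite checks the mapper field-by-field against
an exhaustive scan of every position and strand, with planted mutations
restricted to the region outside the anchoring seed — inside the seed the
scheme is by design blind, which is the trade it makes for simplicity.  This
is a desk-scale stand-in for a production aligner, not a replacement for one.

## ppm and counting conventions

`ppm_i = read_count_i / Σ read_count × 10⁶` over retained (TSD-valid) sites,
so ppm sums to one million.  The denominator is junction reads, not distinct
sites; both tallies are kept in the site table so either convention is
recoverable.  Chromosome and feature fractions use distinct-site counting
(each insertion counts once regardless of depth); read-weighted feature
tallies are available via `insertion_feature_distribution(weight_by_reads =
TRUE)`.  Sites whose reference window is not TTAA are dropped by default —
the junction logo of real libraries shows an essentially invariant TSD, so
non-TTAA junctions are treated as artifacts — and can be kept, flagged, with
`keep_invalid = TRUE` (they are then excluded from the ppm denominator).

## Information content

For position `p` with base frequencies `f_pb`,
`IC_p = 2 + Σ_b f_pb log2 f_pb` bits, with `0·log2 0 = 0`, against a uniform
background and without small-sample correction.  This keeps the 2-bit
ceiling exact: a fully conserved position scores exactly 2.0, which the
tests assert at 10⁻⁹ tolerance on error-free simulations.  `N` bases are
ignored (they reduce the position total).  The profile is built from
read-derived windows (TIR tail as sequenced, errors included), not from
reference-extracted sequence, so it reflects what the sequencer saw.

## Feature annotation and the TTAA-normalized null

Because insertion is restricted to TTAA, the right null distribution for
feature enrichment is the feature composition of TTAA *motifs*, not of
genomic base pairs; both are computed and reported side by side.  Flattening
assigns every base exactly one class with precedence
`CDS > UTR > intron > intergenic` — the annotation formats do not force a
rule for bases that are coding in one transcript and intronic in another, so
coding-first was chosen as the conventional reading and is applied
uniformly (a TTAA motif spanning two classes is classified by its start
base; one deterministic, oracle-checkable rule).

`compare_profiles()` builds the 2×C contingency table, drops classes with
zero column total (so `df = nonzero classes − 1`), computes
`X² = Σ (O−E)²/E` and the analytic upper-tail p-value, and flags expected
counts below 5 (`warn` by default, or `merge_into_other`).

## What the generator emulates — and what it does not

The generator produces i.i.d. random genomes at a configurable GC content
with non-overlapping gene models (5′UTR, alternating CDS exons and introns,
3′UTR) placed by stick-breaking of each contig's free space, insertions
sampled from the genome's TTAA pool without replacement and with per-class
weights, and junction reads with constant placeholder qualities,
substitution-only errors, and a configurable background fraction.  Each
contig is regenerated (up to 25 draws) if it carries fewer than one TTAA per
kb, so insertion sampling never starves.

It deliberately does not model: indels or quality-dependent errors, PCR
duplicates or fragment-size effects, paired ends, repeats and low-mappability
regions, heterochromatin accessibility, or SNPs against the reference.
Passing tests therefore demonstrate the correctness of the *computation* —
trimming arithmetic, coordinate canonicalization, TSD validation,
normalization, the statistics — on libraries whose reads behave ideally;
they do not certify performance on real libraries, where mappability and
chromatin effects depress intergenic recovery in ways this package reports
but cannot correct.

## Numerical and design choices

* Deterministic throughout: every stochastic stage derives its RNG state
  from the configuration seed, and re-running a pipeline writes
  byte-identical files (reports carry a version banner but no timestamps).
* Simulation sizes used by the test suite: the standard study is a 100 kb,
  4-contig genome with 200 insertions × 20 reads and 10% background
  (end-to-end checks run in seconds); the chi-square type-I calibration
  samples 500 sites per replicate from a 2 Mb genome so the TTAA pool is
  ≥ 20× the draw — sampling without replacement from a pool comparable to
  the draw would deflate the statistic by roughly `(N−n)/(N−1)` and make the
  calibration measure the pool, not the test.
* Degenerate inputs are contracts, not crashes: empty FASTQ yields an empty
  stream; an empty alignment set yields an empty site table; zero usable
  logo reads, an all-zero count vector, or a TTAA-free genome raise errors
  that name the problem.
* Ties in the palindrome scanner's greedy reduction break by score, then
  length, then leftmost start; motif ranking breaks count ties by canonical
  text.  Both scanners are exact (no fuzzy matching) because the motifs they
  target are exact short repeats.

## Known limitations

* 3′ sequencing-adapter trimming is not implemented; simulated reads never
  contain adapters, but real libraries with short fragments would need a
  preliminary adapter-trimming pass.
* The CKII scanner implements the minimal S/T-X-X-D/E consensus only;
  dedicated kinase-site predictors use wider context and will not agree on
  every site.
* The mapper holds the whole k-mer index in memory and is intended for
  desk-scale genomes (≤ a few Mb); mapping against a full mammalian genome
  should use a production aligner, after which `call_sites()` and everything
  downstream apply unchanged to its unique alignments.
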