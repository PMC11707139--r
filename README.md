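# srtmap

Genome-wide profiling of piggyBac-superfamily transposon insertions from
self-reporting junction reads — trimming, mapping, TTAA site calling with
TSD validation, junction sequence logos, TTAA-normalized feature enrichment
with chi-square comparison, and transposon-end/protein motif scanners — with
a ground-truth simulator so every stage is verifiable end to end.

## The problem

piggyBac-family transposons insert almost exclusively at the host tetramer
**TTAA** and duplicate it on both sides of the insertion (the target-site
duplication, TSD). Self-reporting transposon libraries read outward across
the junction, so each informative read is

```
[primer + TIR terminal bases] [TTAA] [3' genomic flank]
```

Turning millions of such reads into an insertion catalogue requires: anchored
removal of the transposon prefix (reads without it are discarded), unique
placement of the genomic fragment on the reference, canonicalization of both
read orientations to one TTAA coordinate (TTAA is its own reverse
complement, so a plus-strand site is the alignment start and a minus-strand
site is `start + fragment_length − 4`), TSD validation against the
reference, and normalization to **ppm** (peaks per million):

```
ppm_i = read_count_i / Σ_j read_count_j × 10^6
```

Sequence preference at the junction is summarized by per-position Shannon
information content over the first *L* nucleotides (TIR tail + TSD + flank):

```
IC_p = 2 + Σ_b f_pb · log2 f_pb   (bits; 0·log2 0 ≡ 0)
```

so a fully conserved position scores 2 bits. Because insertion is restricted
to TTAA, feature enrichment is judged against the feature composition of the
genome's TTAA *motifs* (not raw base pairs), and insertion profiles of two
conditions are compared by a chi-square homogeneity test on their
feature-class counts.

The package is tidyverse-native: stage functions take a data frame (reads,
fragments, alignments, sites) first and return tibbles or small result
objects with `tidy()`/`glance()` methods and `autoplot()`/`plot_*()`
figures, so stages compose with the pipe.

## Worked example

Simulate the standard study — a 100 kb annotated genome, 200 TTAA
insertions, 20 junction reads each, 10% background reads — and run the full
analysis:

```r
library(srtmap)

cfg <- sim_config(seed = 7, n_insertions = 200, reads_per_insertion = 20,
                  background_fraction = 0.1)
gen <- generate_genome(cfg)
ev  <- simulate_insertions(gen$genome, gen$annotation, cfg)
sim <- simulate_reads(gen$genome, ev, cfg)

tr <- trim_reads(sim$reads, trim_config(cfg$transposon_prefix))
glance(tr)
#> # A tibble: 1 × 4
#>   input trimmed no_transposon too_short
#>   <int>   <int>         <int>     <int>
#> 1  4444    4000           444         0

mp <- map_fragments(tr, build_kmer_index(gen$genome), gen$genome)
st <- call_sites(mp, gen$genome)
st
#> <site_table> 200 valid site(s), 4000 reads used
#> # A tibble: 200 × 7
#>    contig ttaa_start read_count plus_count minus_count   ppm ttaa_valid
#>    <chr>       <int>      <int>      <int>       <int> <dbl> <lgl>
#>  1 chr1           55         20         20           0  5000 TRUE
#>  2 chr1          881         20          0          20  5000 TRUE
#>  ...

evaluate_site_calls(st, sim$truth)
#> # A tibble: 1 × 5
#>   n_called n_truth n_matched precision recall
#>      <int>   <int>     <int>     <dbl>  <dbl>
#> 1      200     200       200         1      1
```

Every background read (444 of 4,444) is rejected at trimming, all 4,000
junction reads map uniquely, and the 200 called sites recover the simulated
truth exactly, each on a reference TTAA. The junction logo shows the
expected structure — positions 1–8 (TIR tip + TSD) fully conserved at 2
bits, the genomic flank essentially uniform:

```r
round(build_position_profile(tr, L = 15)$bits, 3)
#>  [1] 2.000 2.000 2.000 2.000 2.000 2.000 2.000 2.000 0.001 0.019 0.012
#> [12] 0.022 0.013 0.010 0.009
```

Feature annotation against the TTAA-normalized expectation, and the
chi-square comparison (here: observed insertions vs the TTAA pool they were
drawn from, so no difference is expected):

```r
cmp <- compare_profiles(insertion_feature_distribution(st, gen$annotation),
                        ttaa_feature_distribution(gen$genome, gen$annotation))
cmp
#> <profile_comparison> X-squared = 0.8888, df = 3, p = 0.8281
```

`run_pipeline(cfg, out_dir = "out")` performs all of the above in one call
and writes FASTQ/BED/TSV outputs plus a JSON manifest; re-running with the
same configuration reproduces the outputs byte for byte.
`find_repeated_motifs()`, `find_imperfect_palindromes()` and
`scan_ckii_sites()` cover the transposon-end architecture and
phosphorylation-motif scans.

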