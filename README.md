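# chromoshatter

Detection and reconstruction of radiation-induced chromoanagenesis from
binned short-read dosage, in R.

Chromoanagenesis — the catastrophic shattering and random reassembly of a
single chromosome — can be induced in plants by irradiating pollen before
fertilisation. In an F1 hybrid population where only the paternal genome
was irradiated, each sibling carries a private set of copy-number lesions,
and a rare individual carries tens of clustered copy-number variants (CNVs)
confined to one chromosome, joined by novel DNA junctions. `chromoshatter`
implements the complete short-read analysis for this design as a
tidyverse-native pipeline (tibbles in, tibbles out), together with a seeded
synthetic-data generator that emulates such a population with full
rearrangement truth, so every stage is testable without external data.

## The method

For lines `l = 1..n` and genomic bins `b` (non-overlapping, 100 kb or
10 kb), the **standardized relative read coverage** is

```
relcov(l, b) = 2 * frac(l, b) / mean_l' frac(l', b)
```

where `frac(l, b)` is the fraction of line `l`'s reads whose first end
falls in bin `b`. A euploid diploid bin reads out at exactly 2. Segment
boundaries are called where the level shift between the running medians of
3 bins on each side exceeds 0.7 and the shifted level persists for at
least 3 consecutive bins; segments are assigned the integer copy state
nearest their mean, kept only when private to a single line, and a line
with more than 10 segments clustered on one chromosome arm is classified
as shattered. Parental origin is confirmed from binned paternal SNP allele
frequencies: a region with one maternal and `k` paternal copies is
expected at `k / (1 + k)` — 0.5, 2/3, 3/4, 4/5 for `k = 1..4`, 0 for a
paternal loss.

Novel junctions are discovered from discordant read pairs: for every pair
of non-adjacent 10 kb bins at least 2 kb apart, supporting pairs are
counted per line; a candidate is kept when its support reaches the line's
pseudo-junction threshold (half the mean read coverage spanning arbitrary
5 kb bin boundaries, accounting for single-copy junctions in a diploid)
and no sibling shows any support there. Supporting reads are assembled by
a greedy exact-overlap assembler, the contig is mapped back by maximal
exact prefix/suffix matching on either strand, and the junction is typed
from the matched intervals: 1–11 bp overlap = microhomology, none =
perfect join, 1–18 bp of unmatched novel sequence = insertion, with an
orientation class (head-to-tail, tail-to-head, head-to-head,
tail-to-tail; head = lower reference coordinate). A breakpoint graph over
the blocks between breakpoints, with block multiplicities from dosage,
is walked to emit maximal unambiguous rearranged pieces. Finally,
breakpoint context is tested by comparing gene/repeat density in 10 kb
and 100 kb windows around breakpoints against 1,000 randomized datasets
of 1,000 pseudo-breakpoints each (enrichment ratio = observed mean
density / mean of randomized means, with an empirical rank p-value).

## Worked example

```r
library(chromoshatter)
library(dplyr)

pop <- simulate_population(
  chrom_sizes = c(chr1 = 2e6, chr2 = 2e6),
  n_shattering = 1, n_lesion = 0, n_no_lesion = 8,
  n_blocks = 24, modes = "chromoanasynthesis",
  depth = 30, seed = 101)

grid <- bin_grid(pop$reference, 10000)
relcov <- relative_coverage(bin_counts(pop$placements, grid))
segs <- filter_unique(detect_cnv_all(relcov))
classify_lines(segs, lines = pop$lines$line) %>%
  filter(group != "no_lesion")
#> # A tibble: 1 x 4
#>   line  group      n_cnv max_arm
#>   <chr> <chr>      <int>   <int>
#> 1 F1_01 shattering    14      14
```

Line `F1_01` carries 14 private CNV segments on one chromosome arm —
more than the 10 that define clustered change — so it is classified as
shattered; its siblings show no calls. `plot_dosage(relcov, "F1_01")`
draws the dosage track with guide lines at copy states 1–3, and

```r
baf <- bin_paternal_fraction(pop$placements, pop$reference$snps, grid)
assign_parental_origin(segs, baf) %>% count(parental_origin)
#> # A tibble: 2 x 2
#>   parental_origin     n
#>   <chr>           <int>
#> 1 paternal           12
#> 2 unknown             2
```

assigns the segments to a gain or loss of the paternal (irradiated)
copy; the two `unknown` calls are detected segments whose boundaries
absorbed a neighbouring sub-detectable block, pulling the observed
allele fraction outside the 0.08 tolerance of their nominal state. With `with_sequence = TRUE` the same population supports the full
junction stage (`call_junctions()`, `assemble_pieces()`,
`enrichment_analysis()`); `run_pipeline(pipeline_config(), outdir)` runs
all stages end-to-end and writes TSV outputs plus a summary JSON.

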