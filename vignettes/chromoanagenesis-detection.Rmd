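---
title: "Detecting chromoanagenesis from binned short-read dosage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting chromoanagenesis from binned short-read dosage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromoshatter)
library(dplyr)
```

## The biological setting and the model

Pollen irradiated before fertilisation carries double-strand breaks into
the zygote. In an F1 population from such a cross, every sibling inherits
one intact maternal genome and one damaged paternal genome: most lines
carry a handful of large scattered indels, and a rare line carries a
chromosome that was pulverised in a micronucleus and religated in random
order — chromoanagenesis. Two signatures distinguish its flavours:
**chromothripsis** (breakage and end-joining) oscillates between few copy
states, total dosage 1–3 here, while **chromoanasynthesis**
(replication-template switching) additionally duplicates and triplicates
fragments, reaching states up to 5. `chromoshatter` detects both from
three per-line summaries of short-read data: binned read counts, binned
parental SNP allele counts, and discordant read-pair placements.

All coordinates are 0-based half-open; bin `b` of size `s` covers
`[b*s, (b+1)*s)`.

### Dosage

With lines `l` and bins `b`, relative coverage is
`2 * frac(l,b) / mean_l frac(l,b)`, so the across-line mean of every bin
is exactly 2 by construction. Two properties of this standardization
matter for state calling and are handled explicitly:

* **Extreme-state shrinkage.** The bin mean includes the aberrant line
  itself, so with `n` lines a true state `s` reads out at
  `r(s, n) = n*s / (s/2 + n - 1)`; at `n = 9` a quadruplication (state 5)
  appears at 4.29 and the shift between adjacent high states falls below
  the 0.7 threshold. Under the population's own design assumption — each
  rearrangement is private to one line, so at most one line is aberrant
  per bin — this map is invertible. `detect_cnv()` therefore rescales the
  track through the inverse of `r(., n)` before applying the >0.7 / 3-bin
  rule and rounding to integer states (`level_scale = "copy"`, the
  default; `"relative"` applies the rule to raw values, and
  `mode = "literal"` uses the plain adjacent-bin difference).
* **Genome-size dilution.** A line whose derived genome is enlarged by
  duplications has all its per-bin fractions diluted by the larger
  denominator. The effect is negligible when the rearranged region is a
  tiny fraction of the genome (as on a full-size genome) but visible on
  the compact simulated genomes used for testing, so each line's track is
  first re-centred so that its genome-wide median sits at 2. For a
  euploid line this is a no-op.

Boundary calling compares running medians of `min_run = 3` bins on each
side of each candidate boundary (robust to single-bin noise, unlike the
literal adjacent-bin difference); candidate boundaries are grouped by
shift sign and localized at sharp adjacent differences where available,
at shift peaks otherwise, and adjacent equal-state runs are re-merged.
Copy states round to the nearest integer with ties toward diploid.
Segments are retained when they span at least 3 bins, differ from state
2, and are private to a single line (both boundaries of any other line's
segment more than one bin away). A line with more than 10 segments on
one chromosome arm is `shattering`; with at least one segment, `lesion`;
otherwise `no_lesion`. Centromere positions are optional — without them
each chromosome is one arm, which only makes the shattering call more
conservative.

### Parental origin

Paternal allele fractions pooled in bins (at least `min_snp_obs = 10`
observations, a repository default; the source analysis does not state a
floor) sit at `k/(1+k)` for `k` paternal copies against the fixed single
maternal copy: 0, 1/2, 2/3, 3/4, 4/5. The default tolerance 0.08 is half
the smallest gap between the levels relevant at these depths (0.5 vs
2/3); `general_grid = TRUE` scores all maternal/paternal splits instead
of fixing one maternal copy, which recognises maternal losses at 100%
paternal fraction.

### Junctions

Junction evidence is modelled as **discordant read pairs** whose ends
flank the new adjacency (a read whose body crosses the junction is
placed on the side holding most of it, like a clipped alignment). For a
junction on one haplotype, the expected number of supporting pairs at
total depth `D`, read length `R` and insert `I` is about
`(D / (4R)) * (I - R)`; the detection threshold is half the mean read
coverage spanning arbitrary 5 kb bin boundaries, about `D/2`. The
simulator's default library (150 PE, 700 bp insert) makes the expected
support ~27 against a threshold of ~15 at 30x, a deliberate long-insert
design so that junction-spanning evidence clears the background
threshold with Poisson margin.

Discovery counts pairs over non-adjacent 10 kb bin pairs with at least
2 kb end separation (both conditions, since "non-adjacent" already
implies 10 kb separation for within-chromosome pairs); bin pairs
adjacent in both coordinates are clustered before thresholding, because
a junction's support splits when its flanking reads straddle a bin edge.
A cluster is kept when its summed support reaches the line's threshold
(inclusive) and every other line has strictly zero pairs over the same
bins. Each cluster's reads are assembled greedily by longest exact
suffix–prefix overlap (minimum 25 bp; ties resolved toward the
lexicographically smallest merged sequence); every assembled fragment is
mapped, since one cluster can legitimately contain two distinct
junctions, and fragments from one side only map contiguously and are
discarded. Mapping finds the maximal exact prefix and suffix matches of
the contig (20-mer seeds, both strands); overlap of the matched contig
intervals is microhomology (1–11 bp expected), a gap is an insertion
(1–18 bp), neither is a perfect join; larger values are flagged atypical
but retained. Orientation combines the two breakpoint sides, head being
the lower reference coordinate: head-to-tail and tail-to-head run in the
same direction, head-to-head and tail-to-tail involve an inversion. Under
this definitional rule a forward prefix joined to a reverse-complemented
suffix classifies tail-to-tail.

Exact matching is adequate here because assembly and mapping operate on
the same reference that placements were simulated from; for real data,
externally assembled contigs can be fed directly to `map_contig()`.

### Reconstruction

Breakpoints partition the rearranged region into lettered blocks; block
multiplicity is the paternal copy number (dosage state minus the
maternal copy). Junction edges connect block ends, and walks alternate
block traversals with junction edges, using each edge once and each
block at most its multiplicity, extending only while exactly one unused
continuation exists. Around duplicated blocks several continuations
compete and the walk is cut rather than guessed — deliberately yielding
more, shorter pieces instead of unsupported adjacencies, which mirrors
how far a manual reconstruction can go. Piece base pairs always equal
the sum of block length times usage.

### Enrichment and the detection bootstrap

Breakpoint context is measured as feature density in 10 kb and 100 kb
windows centred on each breakpoint (clipped at chromosome ends with the
denominator adjusted — windows are clipped, not discarded). The null
distribution draws 1,000 datasets of 1,000 pseudo-breakpoints (5 kb bin
boundaries, sampled without replacement within a dataset) and records
dataset means. The enrichment ratio divides the observed mean by the
mean of these means. Because the direction of a "one-sample t-test"
between one observed set and 1,000 randomized sets is ambiguous, the
package tests the randomized means against the observed mean as the
reference value and reports it as `p_t`, but treats the assumption-free
empirical rank `p_emp = (1 + #{rand >= obs}) / (B + 1)` as primary — it
matches the randomization design exactly and never degenerates.

`detection_bootstrap()` resamples the observed detection record (34
breakpoints found at 50 copy-number shifts, rate 0.68) to ask how
surprising zero detections in 7 further shifts would be. The closed form
is `(1 - 0.68)^7 = 3.4e-4`, and the Monte-Carlo estimate converges to it
by construction. A published value of 0.0081 for this quantity is not
reproducible from the stated inputs; the package implements the stated
resampling and reports both numbers rather than tuning toward either.

## The synthetic population

The generator emulates the study design end to end: a multi-chromosome
diploid reference with mutually disjoint gene and repeat intervals
(slot-placed so realized base fractions track the request), parental
SNPs (maternal allele = reference base), and nine F1 lines — 2
shattering, 4 lesion, 3 no-lesion by default — at 25–50x total coverage
(default 30x). Shattering plans tile a region with at least 12 blocks of
at least 20 kb (so every copy change spans two 10 kb bins), draw copy
counts 0–2 (chromothripsis) or 0–4 with at least one amplification
(chromoanasynthesis), shuffle the retained copies with a 25% inversion
rate, and re-draw any adjacency that restores the reference (such a join
leaves no detectable junction). Lesion lines carry 1–7 indels of
40–120 kb — scaled so the per-line indel burden stays a few percent of
the compact test genome, as in the study population relative to a full
genome — with deletions and tandem duplications of the paternal copy
only. Reads are placement records, not FASTQ: positions, strands,
junction-spanning marks and SNP-allele observations, which is exactly
what the analysis consumes; base-call errors, mappability and GC bias
are deliberately out of scope, so passing tests demonstrate method
correctness, not robustness to real-world mapping artefacts.

When sequence is enabled, junction structure is *planted* into the
generated reference: a microhomology junction's two ends genuinely share
its homology bases, insertions carry novel bases, and single-base
mismatches at the flanks pin each junction's classification. Ends shared
by several junctions can make a flank constraint unsatisfiable; rather
than forcing the plan, the generator re-derives each junction's realized
class and breakpoints from the final sequence (any residual flank
identity becomes extra microhomology, shifting the breakpoint along it —
the same ambiguity real microhomology junctions carry), so the truth
tables always describe what a base-exact caller should report.

## Problem sizes, numerical choices, known limitations

* Test and example populations use 2 x 2 Mb genomes, chosen so the full
  simulate–dose–junction cycle runs in minutes; the dosage acceptance
  checks use one aberrant line among nine, which is the regime the
  standardization inversion assumes. On such compact genomes,
  overlapping rearrangements across lines (rare on a full-size genome)
  can locally violate the single-aberrant-line assumption and cost
  individual segment calls; group classification is robust to this.
* Ties in copy-state rounding resolve toward diploid; uncovered bins are
  treated as diploid for segmentation and flagged `missing` upstream.
* The uniqueness filters are strict (zero sibling support for junction
  bin pairs; both boundaries within one bin for shared segments);
  stray-read tolerances are configurable but default to the strict
  reading.
* Junction support attribution assigns a cluster's summed support to
  each junction resolved from it.
* The pipeline (`run_pipeline()`) seeds every stage from one
  configuration seed; reruns are byte-identical. Stage outputs are plain
  TSVs, so any stage can be re-examined or re-run from disk.
* Reconstruction does not attempt karyotype phasing or centromere
  retention logic, and `validated` is metadata for junctions confirmed
  by an external assay, never computed.
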