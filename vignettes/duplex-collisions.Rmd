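---
title: "Mapping-position collisions in duplex consensus variant calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping-position collisions in duplex consensus variant calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(umicollide)
library(dplyr)
```

## The problem

Calling somatic variants at allele fractions below 1% — circulating tumour
DNA monitoring, residual disease, contamination tracking — requires
suppressing errors that occur far more often than the variants themselves.
Duplex consensus calling does this by reconstructing, for every sequenced
DNA molecule, the base calls of *both* original strands: a true variant was
present on both strands of the input duplex, whereas polymerase errors,
sequencing errors and single-strand damage (e.g. cytosine deamination in
FFPE material) appear on only one.

Reconstructing molecules from reads requires grouping PCR duplicates back
to their source molecule. Two grouping keys are in common use:

* **position only** — reads sharing the same fragment mapping coordinates
  `(contig, start, end)` are assumed to come from one molecule;
* **position + UMI** — a double-stranded unique molecular identifier
  ligated before amplification disambiguates molecules that happen to share
  coordinates.

Position-only grouping fails when two distinct input molecules share their
fragment coordinates — a *collision*. The colliding molecules' reads are
merged into one group; if the variant-bearing molecule contributes fewer
reads than its reference-bearing partner, the variant is voted out during
consensus building and its molecular evidence disappears. Collision
frequency depends on the fragmentation process: random shearing spreads
fragment ends almost uniformly, while cell-free DNA is cut by nucleases in
the linkers between nucleosomes, concentrating fragment ends on a
restricted set of recurrent positions (and amplicon sequencing fixes the
ends completely, making every co-amplified molecule collide).

This package provides (i) closed-form models for detection limits and
molecular yield, (ii) a synthetic read generator with strand-tracked
duplicates, duplex UMIs and three fragmentation regimes, (iii) both
grouping modes with duplex consensus collapsing and threshold calling, and
(iv) collision and signal-loss analytics, so the position-only versus UMI
comparison can be reproduced end to end on simulated data.

## Closed-form models

With `N` sequenced molecules overlapping a locus and a variant allele
fraction `VAF`, the number of variant-supporting molecules is
`N_alt ~ Binomial(N, VAF)` (assuming every converted molecule is sequenced
at least once, which the recommended >= 5 reads/molecule coverage ensures).
`detection_probability(N, vaf, min_alt)` evaluates
`P(N_alt >= min_alt)` through the binomial survival function — exact and
stable for `N` well past 10^5; no Poisson approximation is used because the
binomial form is exact and costs nothing. Detection of a VAF = 0.1% variant
with 95% probability needs about 3000 molecules:

```{r}
required_molecules(vaf = 0.001, target_prob = 0.95, min_alt = 1)
```

Molecular yield follows `N = 300 * input_ng * LCR`, with 300 genome
equivalents per nanogram of human dsDNA and `LCR` the library conversion
rate, so 3000 molecules at 50% conversion require 20 ng of input
(`molecular_count(20, 0.5)`). `umi_read_overhead()` gives the fraction of
read length spent on the barcode (a 16 bp UMI costs 11% of a 150 bp read).
Probabilities are reported to users rounded to whole percents
(`percent_label()`); raw fractions are kept internally.

## What the simulator emulates

`simulate_panel()` builds a synthetic capture panel — by default 110
variant loci (70 SNVs, 20 deletions, 20 insertions) over a 46 kbp contig
with a concrete reference sequence. Indels are atomic alleles anchored at
one position; no realignment is modelled.

`simulate_reads()` then draws:

1. **Molecules.** The total count is Poisson with mean
   `300 * input_ng * lcr`. Each molecule is anchored at a uniformly chosen
   panel locus, so per-locus molecular depth is about `N / 110`. Each
   covered locus carries the alternative allele independently with
   probability `vaf` (a two-genotype mixture at low `vaf`; configurations
   reject `vaf > 0.5` because mixture semantics break beyond that point).
2. **Fragment ends.** `random_shear` draws Gaussian lengths (truncated at
   50 bp) and uniform starts around the anchored locus. `nucleosomal`
   places cuts near the linker midpoints of a fixed phased grid with period
   `core_len + linker_len_mean` (147 + 38 bp by default), Gaussian jitter
   (5 bp) and rare intra-core cuts (1%); fragments span one nucleosome unit
   with probability 0.88 and extend geometrically otherwise. The paper's
   sources give no linker or jitter values for cfDNA; these defaults were
   chosen once as physiologically plausible values that reproduce the
   qualitative ordering of collision rates (nucleosomal > random shear) and
   are ordinary configuration, not calibration targets.
3. **UMIs and strands.** Each molecule gets an independent random duplex
   UMI pair (4 bp per strand by default, matching common 4-5 bp duplex
   barcodes). Duplicate counts per strand are Poisson with mean
   `reads_per_molecule_mean / 2` (default 5 reads/molecule overall); zero
   duplicates on one strand intentionally produces simplex molecules.
   Top-strand reads report the pair as `(umi_top, umi_bottom)`,
   bottom-strand reads swapped — the standard duplex convention.
4. **Errors.** Single-strand lesions are placed per strand at
   `lesion_rate` per base *before* amplification, so every duplicate of
   that strand inherits them; sequencing substitutions are drawn
   independently per read at `seq_error_rate`; UMI bases err at
   `umi_error_rate`. Reads store calls sparsely (explicit alleles at
   covered panel loci plus any deviant position); unrecorded covered
   positions are reference.

Reads are emitted as already-aligned records — the analysis starts after
alignment, so fragment coordinates are known exactly and no sequence
assembly is simulated. Coordinates are 0-based half-open internally and
1-based in all exported tables.

The presets `preset_config("FF" | "FFPE" | "cfDNA")` encode the three study
conditions: FF = 100 ng, random shear, low damage; FFPE = 25 ng, random
shear, 25x the FF lesion rate; cfDNA = 12.5 ng, nucleosomal, ~170-190 bp
fragments. Their conversion rates (0.04, 0.14, 0.6) were fixed once so the
expected molecule counts land near the average molecular yields these
conditions produce in practice (about 1200, 1050 and 2250 molecules).

**What is not simulated:** base-quality variation (a constant quality is
implied by the single `seq_error_rate`), GC/AT-dependent conversion bias,
adapter and hairpin artifacts, indel sequencing errors (substitutions
only — indel *variants* are carried as intact alleles), multi-phase
nucleosome arrays (one fixed phase per contig), and double-strand damage
(lesions never co-occur at one position on both strands). Passing tests
therefore demonstrate the logic of grouping, collapsing and collision
accounting — not that real libraries match these error spectra.

## Grouping, consensus and calling rules

`group_reads()` groups by fragment key alone (`position_only`) or
additionally single-linkage-clusters the canonicalized UMI pairs within
each fragment key at Hamming distance <= 1 on the concatenated pair
(`with_umis`). The canonical pair is `min(u1+u2, u2+u1)` lexicographically,
which makes the two strands of one molecule co-cluster. Design choices made
where the convention is genuinely open:

* the one-mismatch tolerance applies to the concatenated canonical pair
  (not per UMI) — the minimal reading of "one mismatch" for a duplex pair;
* single-linkage clustering with the lexicographically smallest member UMI
  as the cluster label — order-independent and free of count-asymmetry
  heuristics (directional/adjacency correction is deliberately out of
  scope);
* the fragment key uses both endpoints plus the contig, which is what
  collision semantics on fragments require.

`collapse_groups()` discards simplex groups and groups with fewer than 3
total reads, forms a per-strand majority consensus requiring >= 70%
within-strand consistency among the reads covering the position, and emits
an allele only when both strand consensuses agree; anything else is a
no-call. The 3-read minimum is interpreted as *total reads per group* (the
duplex requirement already guarantees one per strand); requiring 3 per
strand would discard most duplexes at 5 reads/molecule. Consistency is
computed over reads covering the locus, and a disagreement between two
valid strand consensuses yields a no-call rather than reference — the
conservative choice that avoids manufacturing reference evidence.
No-calls are excluded from pileup numerators *and* denominators.
Consensus is a plain majority vote; no base-quality weighting is applied
because no weighting scheme is part of the procedure being modelled.

`pileup()` counts supporting molecules per (position, allele);
`call_variants()` thresholds that count. `raw_pileup_call()` is the
no-grouping baseline operating on read fractions, which keeps duplicated
single-strand noise fully visible. Sensitivity is the called fraction of
truth loci. Specificity uses the theoretical false-call space: each
position without an expected variant admits 5 possible false calls (three
substitutions, an insertion, a deletion); the same count is reported as
false positives per kb. The ROC sweeps the molecule-support threshold from
1 to one past the maximum observed count, uses the false-call rate (the
specificity complement, not a per-read FPR) as its x-axis for internal
consistency, anchors at (0,0) and (1,1), and integrates by trapezoid.

## Collision analytics

`collision_rate()` groups reads by position and counts groups containing
two or more distinct molecules — resolved from simulator truth when
`molecule_id` is available, otherwise from UMI clusters. A group with k
colliding molecules counts as *one* colliding group (the rate is a
fraction of read groups, not of collision events). When both truth and
UMIs exist, truth is the oracle and UMI-based counting is validated
against it, separating UMI-assignment error from collision measurement.
`enumerate_dilutions()` reproduces the in-silico dilution design: subsets
of variant-free background samples are merged (multiset union with
sample-tagged identifiers, mirroring FASTQ concatenation — no cross-sample
deduplication) with a variant sample, keeping one combination per total
input amount and a minimum step between successive totals (20/10/5 ng for
FF/FFPE/cfDNA in the study design). Backgrounds are sorted by input
descending and subsets enumerated in binary-counter order purely to make
the keep-first rule deterministic. `alt_signal_loss()` then reports, per
dilution point, the variant-supporting molecule count under both grouping
modes and the fraction lost by position-only grouping.

## Numerical and testing choices

Binomial tails are evaluated with `pbinom(..., lower.tail = FALSE)` —
log-space internally, safe for very large `N`. `required_molecules()` uses
doubling plus binary search on the monotone detection probability, so the
returned `N` is exactly the smallest satisfying the target. Interval
coverage counts use sorted-endpoint `findInterval` arithmetic. Ties in a
strand consensus can never reach the 70% threshold with two candidates, so
tie-breaking is moot except at a single read, where the read is its own
majority.

Simulation-based tests run at deliberately modest problem sizes — panels
of 20-110 loci, 300-10,000 molecules, 3-10 seeds per property — chosen so
that each stochastic assertion has comfortable statistical margin (pilot
runs placed the observed effects several standard errors from the decision
boundaries) while the whole suite stays fast. Stochastic comparisons
pool counts across seeds rather than averaging ratios, which keeps
denominators binomially interpretable. The lesion-suppression check
conditions on molecules that were actually collapsed, since un-collapsed
molecules never reach the caller; with 5 reads per strand, suppression is
essentially deterministic (a lesion can only survive if the opposite
strand independently reaches the same non-reference consensus).

## Limitations

Absolute collision rates depend on the true distribution of fragment ends,
which the fixed-phase nucleosome grid only caricatures; the package
therefore targets orderings and monotonicities (nucleosomal > random
shear, loss increasing with input, VAF-independence of loss) rather than
published collision percentages. Observed sensitivities and FP/kb from
real libraries reflect capture efficiency, damage spectra and depth
profiles that the generator does not attempt to match. The detection model
assumes every converted molecule is sequenced at least once; at low
reads/molecule the simulator (which drops unsequenced strands and thin
groups) is the more faithful account, and the two deliberately diverge
there.
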