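# umicollide

Tools for studying when unique molecular identifiers (UMIs) are worth their
cost in duplex consensus variant calling — and when read mapping positions
alone are enough.

## The scientific problem

Detecting somatic variants below 1% allele fraction (ctDNA monitoring,
residual disease) requires collapsing PCR duplicates into per-molecule,
per-strand consensus sequences so that single-strand errors can be vetoed
by the opposite strand. Duplicates can be grouped back to their source
molecule either by their fragment mapping coordinates alone or by
coordinates plus an exogenous duplex UMI. Position-only grouping breaks
down when two distinct input molecules share the same fragment coordinates
(a *collision*): their reads merge into one group and an outnumbered
variant molecule is voted out, silently deleting true signal. Collisions
are rare for randomly sheared DNA, frequent for cell-free DNA (nucleases
cut in the linkers between nucleosomes, so fragment ends recur at a
restricted set of positions), and universal for amplicons.

`umicollide` implements the full comparison on synthetic data:

* **models** — exact binomial detection limits and molecular yield.
  With `N` molecules at a given `VAF`, variant-supporting molecules follow
  `N_alt ~ Binomial(N, VAF)`; detection of at least `k` such molecules has
  probability `P(N_alt >= k)`, and the expected molecular yield from
  `input_ng` nanograms at library conversion rate `LCR` is
  `N = 300 x input_ng x LCR`.
* **simulate** — a generator of strand-tracked, UMI-tagged, PCR-duplicated
  aligned reads over a capture panel (default: 110 variant loci across
  46 kbp), with random-shear and nucleosome-guided fragmentation,
  strand-specific pre-amplification lesions and sequencing errors.
* **grouping / consensus** — position-only and position+UMI read grouping
  (single-linkage UMI clustering at <= 1 mismatch), simplex/duplex
  classification, and duplex consensus collapsing (>= 3 reads per group,
  >= 70% within-strand consistency, both strands must agree).
* **calling** — molecule-count pileup, threshold calling, a no-grouping
  baseline, sensitivity, false positives per kb (against the 5-per-position
  theoretical false-call space), ROC and AUC.
* **collision** — collision rates, molecule-count discrepancy, in-silico
  dilution series and quantification of variant signal lost to collisions.

## Worked example

How likely is it to see at least two variant molecules at VAF 0.2% given
the molecular yield of a sequencing run?

```r
library(umicollide)

detection_probability(c(1000, 1900), vaf = 0.002, min_alt = 2)
#> [1] 0.5942651 0.8928584
percent_label(detection_probability(c(1000, 1900), 0.002, 2))
#> [1] "59%" "89%"

required_molecules(vaf = 0.001, target_prob = 0.95)   # molecules for MRD-grade detection
#> [1] 2995
molecular_count(input_ng = 20, lcr = 0.5)             # yield of 20 ng at 50% conversion
#> [1] 3000
```

A duplex run of ~1,000 molecules per locus detects a 0.2% variant (two
molecules required) 59% of the time; ~1,900 molecules raise that to 89% —
molecular count, not error rate, is the first-order determinant of
sensitivity. Reaching 95% detection at VAF 0.1% needs ~3,000 molecules,
i.e. 20 ng of input at 50% library conversion.

End-to-end comparison of the two grouping modes on nucleosome-fragmented
(cfDNA-like) synthetic data at high molecular depth:

```r
panel <- simulate_panel(seed = 1)                       # 110 loci / 46 kbp
cfg <- preset_config("cfDNA", panel = panel, vaf = 0.03,
                     seed = 11, input_ng = 50)
exp <- run_experiment(cfg)
exp$comparison
#> # A tibble: 2 × 6
#>   mode            auc min_molecules sensitivity specificity fp_per_kb
#>   <chr>         <dbl>         <int>       <dbl>       <dbl>     <dbl>
#> 1 with_umis     0.932             2       0.555           1         0
#> 2 position_only 0.891             2       0.473           1         0
exp$collision$collision_rate
#> [1] 0.08949658
```

With 9% of position groups containing colliding molecules, UMI-aware
grouping calls 55.5% of the panel variants at the 2-molecule threshold
versus 47.3% for position-only grouping — the collision cost the models
and the dilution analytics quantify. On randomly sheared DNA at study-like
depths (`preset_config("FF")`) the two modes give identical results, which
is why UMIs are optional there.

`autoplot(exp$performance$with_umis)` draws the ROC;
`tidy()`/`glance()` return the curve and one-row summaries.

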