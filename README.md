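# cnvscan

Segment-based case/control association testing for copy-number variants
(CNVs) called from SNP genotyping arrays.

## The problem

Rare CNVs — deletions (copy states 0/1) and duplications (copy states
3/4) relative to the diploid state — can be compared between two cohorts
by asking, at every array probe, whether carriers of a given CNV type
are more frequent in cases than in controls. `cnvscan` implements that
scan and everything around it for studies that consume PennCNV-style
call lists (it does not call CNVs from intensities):

1. **Sample QC** — inclusion requires call rate > 98%, Log R Ratio SD
   < 0.30, |GC wave factor| < 0.05 and CNV call count < 100 (all strict),
   plus duplicate removal and a PC-outlier ancestry screen.
2. **Per-probe association** — at each probe and CNV type, the 2×2
   carrier table `[[a, N1−a], [b, N2−b]]` is tested with a two-sided
   Fisher exact test (minimum-likelihood rule: the sum of all
   hypergeometric table probabilities not exceeding the observed
   table's).
3. **CNVR segmentation** — runs of nominally significant probes
   (p < 0.05, one type, one enrichment direction, consecutive
   significant probes ≤ 1 Mb apart) collapse into copy-number-variation
   regions (CNVRs); the association is narrowed to the local p-value
   minimum, and regions with fewer than 3 carriers in the enriched
   cohort are dropped.
4. **Artifact filters** — CNVRs overlapping telomere/centromere bands,
   "peninsulas" (a significant edge of a common CNV created by variable
   boundary truncation, betrayed by contributing calls extending into
   non-significant flanking probes), GC-extreme or probe-sparse spans,
   and regions driven by samples recurring across many CNVRs are
   flagged, never silently removed.
5. **Multiple testing** — the Bonferroni denominator is the number of
   *testable* regions: runs of consecutive probes whose case carrier
   frequency reaches 0.150% (e.g. 171 tests give a bar of
   p = 2.92×10⁻⁴).
6. **Replication** — carrier status in an independent cohort is tested
   by logistic regression with the first three principal components as
   covariates (Wald test; Firth-penalised fallback under separation),
   gated on same-direction support, and combined with the discovery
   p-value by Fisher's method (X² = −2Σln pᵢ on 2k df). A vectorised
   score-test scan supplies the genomic inflation factor
   λ = median(χ²)/0.4549.
7. **Annotation & enrichment** — overlapped (or nearest proximal) genes
   per CNVR, and hypergeometric category enrichment with
   Benjamini–Hochberg adjustment under a one-gene-per-locus rule.

A synthetic-data generator (`simulate_dataset()`, `demo_config()`)
builds full-scale cohorts with planted CNVRs, peninsula and bias-sample
confounders and QC-failing samples, so the whole pipeline is testable
without any external data.

## Worked example

```r
library(cnvscan)

# published-scale carrier tables: 87 vs 4 carriers in 7,313 vs 2,701
fisher_exact_two_sided(87, 4, 7313, 2701)
#> [1] 3.332695e-08
bonferroni_bar(171, 0.05)
#> [1] 0.0002923977

# full pipeline on the packaged synthetic cohorts
cfg <- demo_config(42)
sim <- simulate_dataset(cfg)
tracks <- demo_tracks(cfg)
d <- run_discovery(sim$marker_map, sim$samples, sim$calls,
                   exclusion_track = tracks$exclusion,
                   gene_track = tracks$genes)
d
#> CNV discovery: 9994/10014 samples included, 5536 calls, 10000 probes
#>   significant probes: 108 del / 79 dup; CNVRs: 17 del / 16 dup (14 flagged)
#>   effective tests: 12, Bonferroni bar: 0.00417, passing: 3
d$cnvrs[d$cnvrs$pass_bar, c("chrom", "start", "end", "type",
                            "p_discovery", "case_carriers",
                            "control_carriers")]
#>    chrom    start      end type  p_discovery case_carriers control_carriers
#> 3   chr1  4980000  5170000  dup 2.119327e-08            88                4
#> 9   chr2  7980000  8130000  del 2.192257e-06            43                0
#> 17  chr3 11990000 12110000  del 2.967245e-04            27                0
```

The three regions passing the bar are exactly the three clean planted
loci (87/4 duplication, 42/0 and 26/0 deletions — carrier counts drift
by a few background calls); the planted telomere, GC-extreme, peninsula
and bias-sample confounders all surface as CNVRs but carry filter flags.

Replication against an independent simulated cohort pair:

```r
rep_sim <- simulate_dataset(demo_replication_config(43))
rep <- run_replication(d, rep_sim$calls, rep_sim$samples)
sum(rep$cnvrs$replicated)   # the three planted loci, same direction
#> [1] 3
```

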