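---
title: "Methods: segment-based CNV case/control association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segment-based CNV case/control association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvscan)
```

# The statistical model

`cnvscan` compares the frequency of copy-number variants between two
cohorts genotyped on SNP arrays. Its unit of observation is the
*carrier*: a sample with at least one CNV call of a given type
(deletion, copy state 0/1; duplication, copy state 3/4) whose span
covers a probe. At probe $i$ and type $t$ the data are a 2×2 table

$$\begin{pmatrix} a_i & N_1 - a_i \\ b_i & N_2 - b_i \end{pmatrix}$$

with $a_i$ carrier cases of $N_1$, $b_i$ carrier controls of $N_2$.
The cohort denominators are the full post-QC cohort sizes at every
probe; there is no per-probe missingness model. Because recurrent CNVs
are rare, the table is tested with the Fisher exact test, two-sided by
the minimum-likelihood rule: the p-value sums the probabilities of all
tables with the same margins whose hypergeometric probability does not
exceed the observed table's (relative tolerance $10^{-7}$, the same
rule as `stats::fisher.test`). Two properties of this convention are
worth knowing:

* it reproduces two-sided values such as $P(42,0) = 3.9\times10^{-6}$
  where the one-sided tail would give about half that, and
* it is **not** monotone at single steps in $a$ for fixed $b$: the set
  of opposite-tail tables included changes discretely, so for instance
  $P(4,0) > P(3,0)$ at $N_1 = 7313, N_2 = 2701$. The test suite
  asserts strict decrease at lag 2 instead; this is a property of the
  convention, not an implementation artifact.

`fisher_exact_two_sided()` is a vectorised `dhyper` tail sum with
memoisation over repeated tables, because the genome scan evaluates the
same small tables at thousands of probes. It is cross-checked in the
tests against exhaustive table enumeration from binomial coefficients
(every table with cohort sizes up to 40) and against
`stats::fisher.test`.

# Segmentation into CNVRs

Probes with $p < \alpha$ (default 0.05), one type and one enrichment
direction are chained while consecutive significant probes lie within
`max_gap_bp` (default 1 Mb); each chain is a copy-number-variation
region (CNVR) spanning its first to last significant probe. Within a
region the association is narrowed to the *local p-value minimum* — the
best probe, leftmost on ties — and the region's carrier counts are the
best probe's. Regions whose enriched-cohort carrier count at the best
probe falls below `min_case_carriers` (default 3) are dropped: three
carriers is the minimal recurrence from which a frequency difference
can reach nominal significance and be reproducible, playing the role a
minor-allele-frequency floor plays in SNP association. Deletions and
duplications are segmented independently and chains never cross
chromosome boundaries. Segmentation is deterministic, idempotent and
order-independent; the tests hold it equal to a brute-force chain
finder on a thousand random probe-statistic vectors.

# Multiple testing

The Bonferroni denominator is *not* the number of significant regions —
that denominator would shrink exactly when the data are null, making
the bar lenient and the family-wise error rate anti-conservative (we
measured 16% on null simulations under that reading). Instead the
pipeline counts **testable regions**: maximal runs of consecutive
probes whose case carrier frequency reaches `min_case_frequency`
(default 0.150%, i.e. 11 of 7,313 cases). Runs of neighbouring probes
carry redundant statistics — the same calls cover them — so each run is
one test. Overlapping deletion and duplication regions are merged by
`effective_test_count()` (union-find over interval overlaps), so a
locus testable for both types counts once; with 101 deletion and 76
duplication regions of which 6 pairs overlap, 171 tests result and the
bar is $0.05/171 = 2.92\times10^{-4}$. On 100 null simulations
(500/500 samples, 5,000 probes, 0.5% per-probe carrier rate) no region
passes this bar in all 100 runs.

# Artifact filters

All four screens *flag* regions rather than deleting them, so the audit
trail is complete and re-application is idempotent. The criteria are
qualitative in origin; every number below is an explicit,
configuration-exposed operationalisation (`filter_params()`).

* **Positional** (`telomere_centromere`): any 1-bp overlap with a
  supplied exclusion track of telomere/centromere-proximal cytobands.
* **Peninsula** (`peninsula`): a false-positive significant subregion
  at the variably truncated edge of a common CNV. Signature: the calls
  contributing to the region also extend into flanking probes that are
  *not* significant. Flagged when at least `peninsula_fraction` (0.5)
  of contributing calls cover `peninsula_extension_probes` (5) or more
  non-significant flank probes beyond either boundary. Both
  comparisons are `>=`, so a region exactly at the fraction is flagged.
* **GC / coverage** (`gc_extreme`, `low_coverage`, `gc_unknown`):
  span-mean probe GC outside (0.25, 0.75) — extreme GC produces
  hybridisation bias — or fewer than 1 probe per 100 kb over the span.
* **Sample bias** (`sample_bias`): samples carried in more than
  `max_cnvrs_per_sample` (3) distinct significant regions (typically
  atypical intensity waves that survive per-sample QC) are removed and
  the best-probe table is recomputed; the region is flagged only if the
  signal collapses (enriched carriers fall below `min_case_carriers` or
  the recomputed p rises above $\alpha$). A region with ample
  independent carriers survives.

# Sample quality control

Inclusion requires call rate > 0.98, LRR standard deviation < 0.30,
|GC wave factor| < 0.05 and CNV call count < 100 — all strict
inequalities, so boundary values fail — plus two screens that need
auxiliary input: duplicate exclusion (from a supplied pairwise-identity
table, keeping the lexicographically smallest id per connected
cluster) and an ancestry screen. The ancestry rule in the underlying
design ("clear ethnicity by PCA scoring") names no numeric criterion;
we operationalise it as exclusion beyond `pca_sd_limit` (default 6)
standard deviations from the included-set centroid on PC1 and PC2,
recomputed over two rounds so that extreme outliers do not mask milder
ones. Exclusions record the first failing reason in a fixed order
(call rate, LRR, GCWF, call count, duplicate, PC outlier).

# Replication and population structure

Replication carrier status is evaluated over the discovery span with
any-overlap semantics (the locus-matching rule is otherwise
under-determined), then tested by logistic regression of cohort on
carrier state with the first three principal components as covariates.
The per-locus p-value is a two-sided Wald test on the carrier
coefficient (a likelihood-ratio variant is available via
`test = "lrt"`). Rare CNVs frequently produce zero carriers in one
cohort — complete or quasi-complete separation, where maximum
likelihood diverges — which is detected from the carrier-by-cohort
table and handled by a Firth-penalised fit (Jeffreys-prior score
correction with hat-matrix diagonals, written in-package); the result
is reported with `separation_detected = TRUE`, never silently.
Replication is gated on *same-direction* support before any
combination: a reversed direction is never "replicated" regardless of
its p-value. Discovery and replication p-values are then combined by
Fisher's method, $X^2 = -2\sum_i \ln p_i \sim \chi^2_{2k}$; a single
p-value combines to itself and zero inputs are an error the caller
must floor.

The stratification diagnostic is the genomic inflation factor
$\lambda = \mathrm{median}(\chi^2_{\mathrm{obs}})/0.4549$. Because a
stable $\lambda$ needs thousands of per-locus tests,
`inflation_scan()` computes Rao score tests at the covariate-only null
(fitted once; each locus then costs one pass over the samples). With
no covariates this is exactly the Pearson chi-square test, which the
suite uses as an oracle. On stratified synthetic data (control PC1
shifted by 1, carrier log-odds increasing by 0.6 per PC1 unit)
uncorrected $\lambda$ runs above 10, and the three PCs as covariates
restore $\lambda$ to within 5% of 1.

# The synthetic-data generator

`simulate_dataset()` emulates what this pipeline actually consumes: a
marker map (equally spaced probes, smooth mid-range GC with
deterministic GC-extreme zones), a sample sheet with QC metrics and
Gaussian PCs, and a PennCNV-style call list containing

* planted recurrent CNVRs with *exact* case/control carrier counts,
  each call covering the planted span plus independent uniform
  boundary jitter (the least-assumption stand-in for variable boundary
  truncation of HMM calling);
* peninsula confounders: a common core at equal frequency in both
  cohorts plus case calls extending past the core into an edge segment;
* bias samples planted into several distinct loci at once;
* noisy samples (LRR SD above 0.30, call counts above 100) that QC
  must remove exactly;
* uniform background calls at a configurable per-sample Poisson rate.

The packaged discovery configuration (`demo_config()`) uses full-scale
cohorts of 7,313 cases and 2,701 controls on a 10,000-probe map, with
clean planted loci at carrier counts typical of genome-wide-significant
rare CNVs ((87,4) duplication, (42,0) and (26,0) deletions), one
planted region inside a telomere band, one inside a GC-extreme zone, a
peninsula, six bias loci driven by twenty recurrent case samples, and
twenty noisy samples. Twenty bias carriers (rather than the three-carrier
minimum) keep every bias locus nominally significant even when a stray
background control call lands on its probes, so the bias filter — not
the significance threshold — is what removes them. The replication
configuration (`demo_replication_config()`) re-plants the three clean
loci at carrier counts whose PC-corrected logistic p-values on clean
tables are about $2\times10^{-4}$, 0.007 and 0.008; its background rate
is set lower (0.2 calls/sample) because those tables are weak by
design and the replication stage being emulated found such loci
significant, which bounds the span-overlapping noise a faithful
stand-in may add.

What the generator does **not** emulate: raw LRR/BAF intensities (QC
metrics are drawn, not derived), linkage disequilibrium between probes,
genotype-derived principal components (PCs are simulated Gaussian
clusters), platform differences between cohorts, and non-uniform probe
spacing. Passing tests therefore demonstrate the statistical machinery
and its artifact filters under a controlled generative model, not
calling accuracy on real intensity data.

# Numerical choices and degenerate inputs

* Fisher p-values: `dhyper` tail sums; ties in the minimum-likelihood
  comparison use relative tolerance $10^{-7}$.
* Probes with no carriers in either cohort get $p = 1$ and direction
  `neither`; such probes never seed regions.
* Best-probe ties break to the leftmost probe; duplicate-cluster
  retention breaks to the smallest sample id; nearest-gene ties break
  to the smaller gene start. All tie-breaks are deterministic and
  documented.
* Firth fitting damps Newton steps to length 5 on the log-odds scale
  and reports non-convergence explicitly.
* `fisher_combine()` rejects $p = 0$; `run_replication()` floors its
  replication p at the smallest positive double before combining.
* Coordinates are 1-based inclusive internally; BED input converts at
  the boundary and the conversion is its own inverse.

# Problem sizes in the test suite

Unit tests run on cohorts of tens to hundreds of samples and maps of
30–800 probes. The end-to-end checks use the full-scale packaged
configurations above; the inflation check uses 20,000 carrier blocks of
500/500 samples (the acceptance script uses 40,000, where the median's
sampling error contributes about ±0.015 to $\lambda$); the family-wise
error check runs 100 null simulations of 500/500 samples × 5,000
probes. These sizes were chosen so each property is measured with
comfortable statistical margin while the whole suite completes in a
few minutes.

# Known limitations

* The effective-test count reconciles overlapping deletion/duplication
  regions by union-find merging; other reasonable conventions (e.g.
  counting each type separately) give slightly different bars.
* The peninsula rule needs the per-probe statistics of the flanks; a
  region at a chromosome end with no flanking probes can extend in only
  one direction.
* Enrichment uses a transparent hypergeometric test with the
  one-gene-per-locus restriction and BH adjustment; it does not
  reproduce any external annotation service's clustering, and its
  results depend entirely on the category table supplied.
* PCs are inputs throughout; computing them from genotypes is out of
  scope.
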