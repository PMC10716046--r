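---
title: "Methods: dual-initiation promoter analysis from CAGE 5' ends"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-initiation promoter analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette describes the models and procedures `dualinit` implements,
the parameters that matter, the numerical choices behind them, and what
the synthetic-data tests do and do not establish about real data.

## The analysis model

A CAGE library reduces to a table of CTSS — (contig, position, strand)
triples with raw tag counts per sample. The analysis makes three layers
of structure out of this table.

**Promoter units.** CTSS supported by at least 0.5 TPM in one sample are
clustered per contig and strand into tag clusters wherever consecutive
CTSS lie within 20 bp; clusters are trimmed to the positions of the 10th
and 90th percentiles of their expression, clusters above 5 TPM are kept,
and trimmed clusters from all samples are aggregated into consensus
clusters wherever spans fall within 100 bp. Consensus clusters
overlapping the window ±500 bp around an annotated TSS (same strand) are
assigned to that gene; where several clusters map to one gene their
expression is merged by summation.

**Initiator classes.** Every CTSS is classified from the genome: the
(−1,+1) dinucleotide in transcript orientation gives YR (CA, CG, TA,
TG), YC (CC, TC) or OTHER; YC starts are subtyped from the first five
transcribed bases (five pyrimidines = TOP; four of five = TOP-deg;
otherwise YC-other), and transcripts other than 5′TOP are scanned for an
internal TOP (an unbroken run of five pyrimidines within the first
50 nt). Class expression is summed per consensus cluster and sample;
OTHER is carried separately and excluded from YC:YR ratios.

**DIP dynamics.** A promoter is a dual-initiation promoter when both
classes exceed 1 TPM in a strict majority of samples. Per sample the
ratio is r = (YC + ε)/(YR + ε) with ε = 0.01 TPM; the normalized ratio
divides by the promoter's mean r, so its mean is exactly 1 and
distributions are comparable across promoters. Changes between matched
conditions are tested promoter-wise as d = log₂ r₁ − log₂ r₂ with a
one-sample two-tailed t-test across promoters; cohort-level class totals
are contrasted with Pearson's chi-squared (no continuity correction) on
rounded TPM sums; trajectory genes are DIPs whose cohort-level ratio is
strictly monotone along a given cohort order.

## Tag-count normalization

CAGE tag counts follow an approximate power law: the reverse-cumulative
count of sites with at least c tags is close to a line of slope −α in
log–log space. Libraries of different depth and steepness are made
comparable by fitting that line per sample by least squares over the raw
counts in `fit_range` (default [5, 1000]) and mapping each count onto a
common reference law with slope −α_ref (default 1.05) and total tag
count t_ref (default 10⁶, so normalized values are TPM):

c′ = (c / x0_s)^(a_s / α_ref) · x0_r

where x0_s and x0_r are the counts at which the fitted and reference
laws reach rank 1. The mapping is strictly increasing, so ranks are
always preserved. The reference intercept is fixed by matching the
law's total tag count to t_ref through the continuous Pareto total
(α/(α−1)·x0^α·(1−x0^(1−α)) = t_ref, solved by `uniroot`); the
alternative convention — fixing the rank-1 count directly — differs only
by a constant factor and is not exposed. A sample whose fit is
infeasible (fewer than two distinct counts in range, or zero variance)
falls back to plain count/total × 10⁶ scaling with a warning.

A sample drawn exactly from the reference law is a fixed point of the
mapping to within discreteness (< 5% relative error in the fit range),
and re-fitting normalized values returns α_ref within ±0.05; both are
asserted in the test suite.

## Parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `alpha_ref`, `t_ref` | 1.05, 10⁶ | reference power law (slope, total tags) |
| `fit_range` | [5, 1000] | raw-count window for the per-sample fit |
| `ctss_support_tpm` | 0.5 | TPM needed in ≥ 1 sample to enter clustering |
| `max_gap` | 20 bp | neighbor distance merged into one tag cluster |
| `q_low`, `q_high` | 0.1, 0.9 | expression percentiles trimming cluster edges |
| `min_cluster_tpm` | 5 | cluster floor, strict >, pooled TPM by default |
| `consensus_dist` | 100 bp | span gap aggregated into a consensus cluster |
| `promoter_window` | ±500 bp | promoter region around an annotated TSS |
| `min_class_tpm` | 1 | per-class threshold for DIP calling, strict > |
| `majority_fraction` | 0.5 | fraction of samples that must qualify, strict > |
| `pseudocount` (ε) | 0.01 TPM | added to both terms of YC:YR ratios |
| `internal_window`, `internal_run` | 50, 5 nt | internal-TOP scan |
| `upstream`, `downstream` | 150, 50 bp | motif window around the dominant CTSS |
| `rel_score_threshold` | 0.9 | PWM relative score counting as a hit |
| PWM `pseudocount`, `background` | 0.8, uniform | log-odds conversion |

The promoter window width is a choice, not a given — annotation
conventions for "promoter region" vary — and the default ±500 bp is
exposed in `clustering_params()` for sensitivity analysis. Likewise
the > 5 TPM cluster filter is applied to the pooled TPM across the run's
samples by default ("per transcriptional cluster"), with a per-sample
mode available (`filter_mode = "per_sample"`).

## Design choices where the procedure was open

* **Trimming rule.** The trimmed start is the smallest member position
  whose left-inclusive cumulative TPM reaches q_low·total, and the
  trimmed end the smallest position reaching q_high·total. This is
  deterministic, resolves ties 5′-most, and guarantees the trimmed span
  retains at least (q_high − q_low) of the mass. A perfectly uniform
  cluster therefore trims only its right edge: the left cumulative
  reaches the 10% threshold already at the first position.
* **TOP-deg reading.** "Four of five pyrimidines" is read
  combinatorially — a purine at any one of positions 2–5 — not as the
  literal ordered string C-Y-Y-Y-R. Exhaustive enumeration of the 256
  C-led pentamers gives 16 TOP, 64 TOP-deg and 176 YC-other.
* **Internal TOP scope.** Only 5′TOP transcripts are exempt from the
  internal-TOP scan; TOP-deg transcripts are scanned by default, with
  `exempt_top_deg = TRUE` to exempt them as well.
* **N handling.** Any N in a decisive window demotes the call (OTHER /
  YC-other / not assessed) with a flag; classification never guesses.
* **G-correction.** Deterministic per position: an observed 5′ G that
  does not match the genome shifts the position one base in the
  transcript 3′ direction; the probabilistic variant is not implemented
  because only the mismatch case is defined.
* **Strandedness.** Tag and consensus clustering are strand-specific
  throughout: initiator classes are strand-defined, so merging across
  strands would corrupt class totals. Motif scanning covers both strands
  by default (`scan_both_strands`), since a binding site is generally
  orientation-independent; Fisher's test is two-sided.
* **Dominant CTSS ties** resolve to the 5′-most position in transcript
  orientation.
* **Majority rule.** "Majority of samples" is a strict > 50% of the
  run's samples; an absolute override (`majority_n`) exists for designs
  where a fixed sample count is wanted.
* **Cohort means of ratios** use the mean of log₂ r (the geometric mean
  of r) for trajectory ordering, so up- and down-shifts weigh equally.
* **Chi-squared on TPM.** Class totals are TPM, not counts; values are
  rounded and a zero cell triggers a Haldane +0.5 correction with a
  flag. This mirrors figure-level practice and is labeled as such.
* **Batch testing.** Where many promoter-level tests run in one batch,
  Benjamini–Hochberg FDR (`fdr_adjust()`) is reported alongside raw p.
* **Degenerate paired test.** Zero variance with a nonzero mean d is
  reported as p = 0 with a `degenerate` flag rather than NA, so a
  perfectly uniform shift is not silently dropped.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
with every feature recorded as ground truth:

* Promoters sit on alternating contigs and strands, 1 kb apart, each
  with four CTSS in an 18-bp core (two YC 5′-most, then two YR, at
  within-class weights 0.7/0.3). The local genome is rewritten so each
  CTSS carries its intended initiator context; YC CTSS receive a TOP /
  TOP-deg / YC-other pentamer at 25/25/50%.
* 70% of promoters are dual; the rest emit only YR tags (observed
  non-dual promoters are almost exclusively YR).
* Per-promoter YC fractions are Beta-distributed per cohort with means
  0.35 / 0.25 / 0.15 (responsive / moderate / non-responsive,
  concentration 10), echoing the observed range of roughly a third of
  transcripts starting with C in the most radiotherapy-responsive
  samples down to 15% in the least responsive. These are simulation
  conveniences, not estimates.
* A configurable fraction of dual promoters (default 10%) is planted
  with a strictly ordered cohort trajectory (logit offsets ±1.2 around
  a promoter-level base fraction).
* Tag weights follow a Pareto law with exponent 1.05 truncated at 10⁴
  (finite dynamic range); each sample distributes 10⁶ tags
  multinomially over the designed CTSS. In irradiated libraries YC mass
  is multiplied per cohort by 0.55 / 0.716 / 0.951, the observed 45%,
  28.4% and 4.9% depletions.
* Intergenic noise tags land uniformly (2 per kb, counts 1–3) outside
  promoter cores, with whatever initiator context the random genome
  offers.
* The motif consensus (default CCGGAAGT, an ETS-like site) is written
  at −60 bp from the TSS into trajectory ("signature") promoters at
  rate 0.3 and other promoters at rate 0.1.

Because promoter tag weights multiply per-promoter class fractions and
within-promoter weights, the CTSS-level count distribution follows the
planted power law exactly in its tail (the weight mixture is bounded, so
the tail index is preserved) but is flatter in the body: with 1,000
promoters at depth 10⁶ the reverse-cumulative slope fitted over counts
[100, 10⁴] recovers −1.05 within ±0.1, while the default [5, 1000]
window, which sits in the mixture body at this promoter density, fits
nearer −0.86. Real libraries, with far more promoters per tag, place the
default window in the power-law regime.

**What the synthetic tests show — and don't.** Passing recovery tests
(DIP sensitivity/FDR, Spearman of estimated vs true YC fraction,
trajectory recall, null selection rate ≈ 1/3! = 1/6, motif-enrichment
calibration and power) establishes that the pipeline's inference is
correct under its own model: multinomial sampling noise, power-law
expression, clean promoter geometry, ideal annotation. They do not
establish robustness to features the generator deliberately omits:
mappability artifacts, FFPE degradation bias, sequencing error,
mis-annotation, promoters wider than one cluster, or overdispersion
beyond multinomial. Conclusions about real libraries rest on the
procedure matching its published use, not on these simulations.

## Numerical notes and degenerate inputs

* Problem sizes were chosen for desk-scale verification: the standard
  recovery design uses 1,000 promoters × 6 samples × 10⁶ tags;
  calibration loops use 100–200 replicates of direct simulations.
* The reference-law intercept is solved by `uniroot` on [1+10⁻⁹, 10¹⁵]
  at tolerance 10⁻⁹; the fit uses distinct counts only, so ties do not
  overweight.
* Empty inputs flow through: an empty CTSS table classifies to an empty
  call table, clustering an empty table yields no clusters, and
  re-aggregating consensus output is a no-op (idempotence is tested).
* Out-of-range genome fetches error rather than truncate; motif windows
  truncated at contig edges are scanned over the available range with a
  flag.
* A uniform PFM yields a degenerate PWM (zero score range); it is
  flagged and scores 0 everywhere rather than dividing by zero.
* Ratios are finite by construction (ε > 0); a YR-free promoter
  reports a large finite ratio, flagged only through the ε-sensitivity
  of downstream summaries.

## Known limitations

* The supplementary gene lists of the source study (trajectory and
  signature sets) are not redistributable here; the set-intersection
  mechanics are fully tested on synthetic sets, and the published
  intersection counts can be checked by dropping the lists under
  `inst/extdata/supplementary_gene_lists/`.
* Read mapping, enhancer calling, promoter shape metrics, differential
  expression modeling and gene-ontology lookups are out of scope; the
  package starts from CTSS tables and delegates DE analysis to
  dedicated tools.
* Power-law normalization assumes the fit range samples the law; very
  shallow libraries (< ~10⁴ tags) may fall back to plain TPM scaling.
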