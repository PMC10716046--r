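# dualinit

Dual-initiation promoter analysis from CAGE 5′ ends.

## The problem

CAGE-seq reads mark transcription start sites (CTSS) at single-base
resolution. The (−1,+1) dinucleotide at each start falls into two
functionally distinct initiator classes: **YR** (pyrimidine–purine: CA,
CG, TA, TG), the canonical initiator, and **YC** (pyrimidine–cytosine:
CC, TC), the non-canonical class associated with 5′ terminal
oligopyrimidine (5′TOP) transcripts. Many promoters emit both classes at
once — *dual-initiation promoters* (DIPs) — and the balance of YC to YR
transcription shifts with cellular state, for example between cancer
cohorts, between radiotherapy-responsive and non-responsive tumors, and
upon irradiation.

`dualinit` implements the full desk-side analysis for anyone with
per-sample CTSS tag tables, a genome FASTA and a GTF annotation:

* **CTSS pipeline** — untemplated-G correction, power-law tag-count
  normalization to a reference law (slope −α, α = 1.05; total 10⁶ tags),
  tag clustering (max gap 20 bp, support ≥ 0.5 TPM), trimming to the
  10th–90th expression percentiles, the > 5 TPM cluster filter,
  cross-sample consensus clustering (≤ 100 bp), and promoter annotation.
* **Initiator classification** — YR / YC / other per CTSS; YC subtypes
  from the first five transcribed bases (CYYYY = TOP, 4/5 pyrimidines =
  TOP-deg, otherwise YC-other); internal-TOP detection (unbroken run of
  five pyrimidines within the first 50 nt).
* **DIP dynamics** — DIP calling (> 1 TPM in both classes in a majority
  of samples), YC:YR ratios r = (YC+ε)/(YR+ε) and promoter-normalized
  ratios r̃ = r / mean(r), paired t-tests of log₂ ratio changes,
  chi-squared contrasts of class totals, trajectory-gene selection
  (cohort-mean ratio strictly monotone along a cohort order), gene-set
  intersections, and small closed forms (qPCR YC-by-subtraction,
  doubling time T·ln2 / ln(X/50 000), relative survival).
* **Motif enrichment** — JASPAR PFM → log-odds PWM, relative-score
  scanning of the window −150…+50 bp around each consensus cluster's
  dominant CTSS (hit at ≥ 90% of the score range), Fisher's exact test
  of a gene set against all other consensus clusters.
* **Synthetic data** — a seeded generator emitting a genome with
  engineered initiator contexts, a GTF, per-sample BED6 tag tables with
  power-law counts, cohort-dependent YC fractions, irradiation effects,
  planted motifs and a full ground-truth table, so every stage is
  verifiable offline.

## Worked example

Simulate a six-sample cohort design (responsive / moderately responsive /
non-responsive, two samples each) and run the pipeline:

```r
library(dualinit)

cfg <- synthetic_config(seed = 7, n_promoters = 200, depth = 2e5)
gen <- generate_genome_and_annotation(cfg)
sim <- generate_ctss_samples(cfg, gen)

run <- run_pipeline(sim$ctss, gen$genome, gen$genes)
summary(run)
#> Pipeline summary
#>   CTSS: 2932   consensus clusters: 1310   genes: 200   DIPs: 140
#>   per-sample YC content of consensus-cluster expression:
#>     responsive_1              22.1%
#>     responsive_2              22.1%
#>     moderate_1                16.1%
#>     moderate_2                16.1%
#>     non_responsive_1          12.7%
#>     non_responsive_2          12.7%
```

The YC content (YC / (YC+YR) expression over consensus clusters) falls
monotonically from the responsive to the non-responsive cohort — the
generator's planted gradient, recovered by the pipeline. Trajectory genes
are DIPs whose cohort-mean YC:YR ratio is strictly ordered along the
cohort ranking:

```r
cohorts <- setNames(sim$sample_sheet$cohort, sim$sample_sheet$sample)
traj <- trajectory_select(run$ratios$r, cohorts, cfg$cohorts)
length(traj$selected)
#> [1] 68

truth_compare(run, sim$truth, traj)[c("dip_sensitivity", "dip_fdr",
                                      "spearman_yc_fraction",
                                      "trajectory_recall")]
#> $dip_sensitivity     [1] 1
#> $dip_fdr             [1] 0
#> $spearman_yc_fraction [1] 0.982
#> $trajectory_recall   [1] 1
```

All 140 true dual promoters are recovered with no false calls, the
estimated per-promoter YC fraction tracks the truth (Spearman ρ = 0.98),
and every planted trajectory gene is selected.
`write_run_report(run, "out/")` writes the consensus BED, the class-TPM
matrices, the DIP table, ratio tables and a plain-text report.

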