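# twohitscan

Integrated germline + tumour sequencing analysis for validating candidate
cancer-predisposition genes under the two-hit model, motivated by familial
high-grade serous ovarian carcinoma (HGSOC) studies in which roughly half the
hereditary component remains unexplained.

A case-control burden screen nominates genes whose rare germline
loss-of-function (LoF) alleles are enriched in cases; `twohitscan` then
provides the tumour-side machinery that turns candidate genes into validated
(or invalidated) ones:

* **Burden statistics** — per-gene rare-LoF allele counting and exact
  case-control enrichment: the cross-product odds ratio
  `OR = a_case (N_ctrl − a_ctrl) / ((N_case − a_case) a_ctrl)`, one-sided
  exact hypergeometric p-values `P(X ≥ a_case)`, conditional exact CIs, and
  within-group p-value ranking. A packaged fixture carries the published
  HGSOC counts (496 cases vs gnomAD / MGRB / Lifepool controls).
* **Purity model** — the forward model
  `v = (p·m_v + (1−p)·g) / (p·n_t + 2(1−p))` for the expected VAF of a
  variant in `m_v` of `n_t` tumour copies at purity `p`; purity estimation by
  inverting it for clonal somatic variants on single-copy LOH segments
  (`p̂ = 2v/(1+v)`), plus a multi-estimator consensus (unweighted mean).
* **Somatic filtering** — final-stage filters with a purity-adjusted VAF
  cut-off `max(0.03, 0.2·p/2)`, gnomAD AF ≤ 1e-4, ±150 bp target extension,
  per-rule removal audit, and pooling of unique SBS across tumours.
* **Allelic-status ("two-hit") classification** — binomial likelihood
  scoring of balanced-het / WT-lost (deletion or CN-LOH) / variant-lost
  hypotheses at purity-adjusted expected VAFs, gated by the local
  allele-specific copy-number state, with somatic second hits and promoter
  methylation upgrading the call (`WT_LOST_BY_SOMATIC_HIT`,
  `VARIANT_LOST_WT_METHYLATED`, ...), and gene-level summaries.
* **HRD scar score** — unweighted LOH + TAI + LST on smoothed
  allele-specific segments, no ploidy adjustment, HRD-high at total ≥ 63.
* **Signature refitting** — SBS96 catalogue construction
  (pyrimidine-strand convention), non-negative least-squares exposures, and
  a bootstrap sparsity filter (default B = 1000, 1% threshold, α = 0.05).
* **Synthetic data** — generators for cohorts, tumours (planted allelic
  fate, planted scar events, configurable purity/depth) and signature
  mixtures, with ground truth, so every stage is testable without
  access-controlled patient data.

See `vignettes/twohit-validation-methods.Rmd` for the model details and
design decisions.

## Worked example

Burden screen from the packaged counts:

```r
library(twohitscan)
counts <- hgsoc_lof_counts()
tb <- burden_table(counts, control_cohorts = "gnomad")
tb[tb$gene %in% c("PALB2", "MAP6D1"),
   c("gene", "a_case", "af_case_percent", "a_ctrl", "odds_ratio",
     "ci_low", "ci_high", "p_one_sided", "rank")]
#>     gene a_case af_case_percent a_ctrl odds_ratio ci_low ci_high p_one_sided rank
#> 1  PALB2      3           0.302     86       4.17  0.841    12.6     0.03854    1
#> 7 MAP6D1      3           0.302      9      39.83  6.925   159.6     0.00012    1
```

PALB2 carries 3 LoF alleles among 992 case chromosomes (AF 0.30%) versus 86
among 118,190 gnomAD chromosomes: odds ratio 4.2, one-sided exact p = 0.039
— enrichment consistent with a moderate-risk predisposition gene. Ranks are
per group (proposed / candidate), so both genes rank first in theirs.

Tumour side, on a simulated carrier tumour with a planted fate and scars:

```r
tm <- gen_tumor(purity = 0.65, depth_mean = 90, gene_fate = "WT_LOST",
                scar_spec = c(loh = 2, tai = 1, lst = 1), seed = 11)

est <- purity_from_somatic_vaf(tm$sample$purity_informative,
                               tm$sample$profile)
est
#> purity 0.617 (somatic_vaf, n = 2) - depth-weighted mean of 2v/(1+v)

seg <- tm$sample$profile$segments
gv <- tm$sample$germline_variant
locus <- seg[seg$chrom == gv$chrom & seg$start <= gv$pos &
               seg$end >= gv$pos, ]
classify_allelic_status(gv, locus, est$value)
#> SIM-TUMOR / GENE1: WT_LOST (biallelic: YES)

hrd_score(tm$sample$profile, tm$sample$arms)
#> HRD score 4 (LOH 2 + TAI 1 + LST 1): HRD-low (threshold 63)
```

The TP53-like somatic variants recover the planted purity (0.62 vs 0.65
true); the germline variant's tumour VAF on a (total 1, minor 0) segment
calls loss of the wildtype allele — biallelic inactivation, the tumour-side
evidence that validates a candidate gene; and the scar counters return
exactly the planted (2, 1, 1) events, far below the ≥ 63 HRD-high rule.

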