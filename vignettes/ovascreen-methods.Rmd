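---
title: "Methods: the ovascreen prioritization and screening cascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the ovascreen prioritization and screening cascade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovascreen)
```

## The problem

Targeted-panel sequencing of ovarian tumors of different aggressiveness
— borderline tumors without (`BOT`) and with (`BOT.V600E`) the BRAF
V600E variant, low-grade (`lgOvCa`) and high-grade (`hgOvCa`)
carcinomas — yields per-sample variant calls that must be reduced to a
trustworthy per-gene alteration profile before any group comparison or
biomarker claim is possible. `ovascreen` implements that reduction and
the downstream statistics as one reproducible cascade:

1. **coverage exclusion** — a (sample, region) pair with mean coverage
   depth strictly below 5 reads is masked; when all of a gene's regions
   are masked for a sample the gene is `MISSING` (not "unaltered") for
   that sample and is excluded pairwise downstream;
2. **allele-fraction gate** — calls with VAF = AD~alt~ / (AD~ref~ +
   AD~alt~) strictly below 0.10 are removed (polymerase artefacts and
   variants too rare to validate);
3. **quality gates** — inclusive minima: alternate bases ≥ 2, call
   quality ≥ 20, mapping quality ≥ 20, depth ≥ 5;
4. **class partition** — SNPs (single-base substitutions) versus
   non-SNPs (indels, MNPs, breakpoints, symbolic alleles), analyzed
   independently and merged for combined profiles;
5. **annotation retention** — per-transcript annotations are
   consolidated (worst case across transcripts), LOW/MODIFIER impacts
   are dropped, and a variant is kept iff it has an adverse clinical
   significance (R1), a damaging SIFT/PolyPhen prediction (R2), is
   novel (R3), has all three prediction fields empty (R4), or has
   MAX_AF < 0.01 (R5);
6. **binarization** — per gene and sample, 1 iff at least one retained
   variant, under three impact strata (`HIGH_OR_MODERATE`, `HIGH`,
   `MODERATE`);
7. **group contrasts** — per gene, 2×2 altered/unaltered tables for all
   six group pairs, chi-squared or Fisher's exact test;
8. **biomarker screen** — matched univariable/multivariable Cox and
   logistic models per gene, endpoint and clinical subgroup, with
   bootstrap cross-validated AUC.

## Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| `min_mean_depth` | 5 | reads | regions with poorer enrichment cannot distinguish "wild type" from "not sequenced" |
| `min_fraction` | 0.10 | fraction | removes polymerase errors and sub-validatable variants |
| `min_alt_bases` | 2 | reads | a single supporting read is not a call |
| `min_qual`, `min_mapq` | 20 | phred | conventional Q20 floor |
| `min_depth` | 5 | reads | call-level analogue of the region gate |
| `rare_af` | 0.01 | fraction | population-rare cutoff for retention rule R5 |
| `alpha` | 0.05 | — | per-contrast significance; uncorrected by default (see below) |
| `auc_floor` | 0.65 | — | minimum discriminative ability of a "matched" model (strict `>`) |
| `B` | 1000 | replicates | bootstrap depth for the cross-validated AUC |

Boundary readings are fixed once and tested: every "minimum X of N"
gate is **inclusive** (a call at qual = 20 or depth = 5 passes), while
the allele-fraction clause removes **strictly below** 0.10 (a call at
exactly 0.10 passes), and a region at mean depth exactly 5.0 is kept.

## Group contrasts

The binarized matrix is compared per gene between each pair of groups.
The test is chosen by the standard expected-cell-count rule: Fisher's
exact test when any expected count is below 5, otherwise the
chi-squared test *without* continuity correction. Both the rule and
the correction are configurable (`rule = "fisher"` forces the exact
test everywhere; `p_adjust = "BH"` switches on Benjamini–Hochberg).
The default report is intentionally uncorrected, mirroring the common
presentation of per-gene comparison tables; treat it as screening, not
confirmation. The per-sample variant-count distributions are compared
with the Kruskal–Wallis omnibus test and pairwise Wilcoxon rank-sum
tests (exact for small tie-free samples, continuity-corrected normal
approximation otherwise; all-identical counts give `NA` by convention).

## Biomarker screening

Endpoints are class-specific: borderline tumors use relapse-free
survival and the microinvasion/implants flag; high-grade carcinomas
use overall survival, disease-free survival (restricted to patients in
complete remission), complete remission and platinum sensitivity.
Low-grade carcinoma subgroups are refused — ten patients cannot
support multivariable inference. Fixed covariate sets: BOTS adjust for
chemotherapy administration, primary-tumor status, histotype and age;
hgOvCa for histotype, FIGO stage and residual tumor category.

The gene enters as its binarized 0/1 indicator. For survival
endpoints the model AUC is the time-dependent AUC of the linear
predictor with **cumulative cases and dynamic controls**: at horizon
*t* (default: the median observed event time of the subgroup, always
configurable because no canonical horizon exists), cases are patients
with an observed event by *t*, controls are patients still at risk
beyond *t*, and patients censored before *t* are excluded. The
bootstrap AUC resamples patients with replacement, refits, evaluates
on the replicate, and averages over `B` replicates; it is fully
deterministic given a seed. ROC cutoffs use the Youden index
J = sensitivity + specificity − 1, ties broken toward the lowest
cutoff; Kaplan–Meier curves above/below the cutoff are compared by the
log-rank test.

A gene/endpoint/subgroup combination is **matched** when the
univariable and multivariable models are both significant at `alpha`,
their effect estimates lie on the same side of 1, and *all four* AUC
values (apparent and bootstrap, both models) strictly exceed
`auc_floor`. The "both AUCs" reading resolves an ambiguity in the
source procedure; it is the stricter of the two readings and is
config-free on purpose. Models skipped for degeneracy (zero events,
constant indicator, one outcome class) or flagged for separation
(divergent coefficients or standard errors) never match; separation is
reported rather than penalized away, to stay faithful to the described
workflow. Proportional-hazards diagnostics (scaled Schoenfeld residual
test at α = 0.05) set `ph_ok = FALSE` on violation but do not exclude
a model.

## The synthetic cohort generator

The generator emulates exactly the features the cascade must be tested
against, with defaults fixed once as the package's stated world:

* **cohort structure** — group sizes 53/23/10/139; serous histotype
  ~80%; ages normal around 55 years (BOT.V600E shifted to 42, since
  V600E tumors occur in younger patients), clipped to [18, 95]; all
  borderline tumors have no residual disease; TP53 accumulation defined
  for carcinomas only.
* **alteration frequencies** — per (gene, group, stratum)
  probabilities. The source study publishes no numeric per-gene
  frequencies, so the defaults are placeholders shaped after its
  qualitative patterns (TP53/BRCA1 high-impact concentrated in hgOvCa,
  KRAS in BOT and lgOvCa, NRAS in lgOvCa, BRAF fixed at 1.0 in
  BOT.V600E — the group-defining variant — over a 0.05/0.02
  moderate/high background).
* **decoys** — each decoy call violates exactly one gate (VAF, depth,
  qual, mapq, alt-base count, impact, or the retention rules) and
  carries that gate's tag, so filter tests can attribute every removal.
  Sub-threshold VAF decoys default to 2 per sample, other families to
  0.5.
* **survival** — exponential baseline hazards with group-specific
  medians (OS 240/240/100/40 months; RFS 180/180/60/24; DFS 18 for
  hgOvCa), the simplest proportional-hazards-consistent choice;
  planted log-hazard-ratios multiply the individual hazard; censoring
  by an independent exponential calibrated to the configured censored
  fraction (default 0.3).
* **responses** — logistic with baselines CR 0.65, PS 0.55,
  microinvasion/implants 0.15, plus planted log-odds-ratios.
* **conventions** — AD is (reference, alternate) and may sum to less
  than DP; coordinates are 1-based inclusive; one seed fixes every
  byte of the serialized bundle.

What it deliberately does **not** emulate: read-level data (FASTQ/BAM),
sequencing-error processes, tumor purity and subclonality, linkage
between variants, or correlation between genes. A green test therefore
establishes that the cascade's logic and statistics behave as
specified under a proportional-hazards, independent-genes world — not
that the package reproduces the source study's patient-level numbers,
which would require the restricted sequencing data.

## Numerical choices and degenerate inputs

* Calls with zero total allele depth are removed with a distinct
  logged reason (`no_allele_evidence`), never a fatal error.
* Multi-allelic VCF records are split one row per alternate allele
  with per-allele AD before filtering.
* A 2×2 table with an empty altered/unaltered column is reported with
  p = 1 and `test_used = "degenerate"`; an empty group margin makes the
  contrast "absent" (`NA`).
* Transcript consolidation worst-case order: impact HIGH > MODERATE >
  LOW > MODIFIER; SIFT deleterious > deleterious_low_confidence >
  tolerated_low_confidence > tolerated; PolyPhen probably_damaging >
  possibly_damaging > unknown > benign; MAX_AF takes the minimum.
  Score suffixes like `deleterious(0.01)` are stripped; `""`, `"-"`
  and `NA` all count as empty.
* The retention reason code records the *first* rule that fires in the
  order R1→R5; the order changes attribution only, never membership.
* Parameter-recovery checks are Monte-Carlo: at n = 2000 a single
  estimate of log(7.06) has standard error ≈ 0.15 (discordant cells
  are rare under a strong odds ratio), so the tests compare the mean
  of 20 replicate estimates — Monte-Carlo error ≈ 0.03 — against the
  ±0.15 band, which then measures correctness rather than one draw's
  luck.
* Bootstrap depth is scaled to B = 50–100 inside the heavier test
  simulations (B only changes the Monte-Carlo error of the mean
  replicate AUC, ≈ 0.015 at B = 50); the user-facing default stays
  B = 1000.

## Known limitations

* The per-gene default frequencies are not calibrated to any real
  cohort; use `cohort_config(gene_freqs = ...)` for study-specific
  worlds.
* The time-dependent AUC estimator ignores censoring between 0 and the
  horizon beyond excluding those patients (no IPCW correction); at the
  default horizon and moderate censoring this is a small conservative
  bias, and the bootstrap comparison inherits it symmetrically.
* Incidentally enriched neighbour genes (KCNMB3, FBXW7-AS1) are flagged
  but share the panel statistics; CRNDE is dropped from reports by
  default (`drop_genes`), as its analysis belongs elsewhere.
* The cascade assumes one consolidated annotation row per variant can
  be formed; conflicting multi-sample annotation tables are a data
  error, not a recoverable state.
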