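---
title: "Methods: cfDNA residual disease and donor chimerism after allogeneic transplant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cfDNA residual disease and donor chimerism after allogeneic transplant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfmrd)
library(dplyr)
```

This vignette is the package's account of its science: the models behind
each analysis, the parameters that matter, what the synthetic-data
generator does and does not emulate, and the design choices made where
the underlying clinical methodology left the details open.

## Study design the package assumes

Adults transplanted for myeloid malignancies are sampled at a
pre-transplant baseline and at days 28, 56 and 84 after the stem-cell
infusion (day 0). Plasma cfDNA is sequenced on a large gene panel at
every timepoint; bone marrow is sequenced at baseline and around day 84.
Presumed host-germline mutations and variants attributed to donor
transmission are excluded before any residual-disease computation,
because both track engraftment biology rather than the malignant clone.
Actual sampling days may drift from the schedule; `nominal_day()` aligns
days within ±14 days of a scheduled timepoint to it (ties go to the
nearer nominal day, the earlier one on an exact tie).

## Residual-disease burden: the geometric-mean VAF

A sample's burden summary is the geometric mean of the VAFs of all
somatic mutations detected in it, on the percent scale, reported to two
decimals. The geometric mean is the natural choice for VAFs spanning
three orders of magnitude (0.03%–60% in the packaged cohort): it is
scale-equivariant and not dominated by a single high-VAF clone.

Two numerical rules matter:

* **No pseudo-count, no zero-fill.** An undetected mutation is excluded,
  never entered as zero — a single zero annihilates the product, and
  zero-filling would contradict every tabulated value. A sample with no
  mutations has an undefined GM and is reported "NE".
* **NE vs ND.** A tested, mutation-free sample (NE, count 0) is distinct
  from a sample never taken (ND, count missing). ND samples are skipped
  in clearance logic rather than read as negative: a subject whose final
  sample was never drawn cannot be called cleared on that basis.

## Donor chimerism from informative SNPs

The chimerism estimator formalizes the "median VAF difference over
informative SNPs" rule as a per-SNP inversion of the linear mixture
model

$$v_i = h\,g_{R,i} + (1-h)\,g_{D,i},$$

where $h$ is the host cfDNA fraction and $g_{R}, g_{D} \in \{0, \tfrac12, 1\}$
are genotype alt-allele fractions. Each informative SNP
($g_R \ne g_D$) yields $\hat h_i = (v_i - g_D)/(g_R - g_D)$, and the
sample estimate is the median of the $\hat h_i$. For opposite-homozygote
SNPs this *is* the VAF difference from the donor genotype; for
homozygote-versus-heterozygote SNPs the same formula rescales the
half-signal by 2, which keeps the rule genotype-aware while preserving
its behaviour on fully informative SNPs. Whether the original
methodology rescaled half-signal SNPs is not documented; this
formalization is the package's choice and is flagged here deliberately.

Numerical choices:

* **Per-SNP clamping** of $\hat h_i$ to $[0,1]$ *before* the median, so
  one noisy SNP cannot contribute an impossible mixture fraction; the
  output is therefore always in $[0,100]$ percent.
* **Even counts** take the mean of the two central values (the ordinary
  sample median).
* **`min_informative = 3`** (panel default 16 SNPs at allele frequency
  0.5 leaves 10 informative in expectation, by exact Hardy–Weinberg
  enumeration: any two unequal alt-fractions differ by at least ½, so
  the informative probability is $1 - \sum_i p_i^2 = 0.625$). Below 3
  the sample is "not evaluable", never guessed.
* **No depth weighting by default** — the published rule implies none; a
  depth-weighted median is available behind `weight_by_depth = TRUE` for
  panels with very uneven coverage.
* **Rounding** to 1 decimal place for reporting; the unrounded host
  fraction is kept on the fit object (tests against the least-squares
  grid oracle use it).

A trend over a chimerism series is `falling`/`rising` only when *every*
successive difference moves by at least δ = 2 percentage points (the
published trends are graphical only; 2 points is roughly twice the
binomial standard error of the estimator at depth 5,000 and separates
sampling noise from engraftment dynamics).

## Adverse-risk clearance classification

Subjects are classified by the fate of adverse-risk mutations (the
ELN/Pethema/NCRI gene list shipped as editable YAML; WT1 is included
exactly as that list states it, although some schemes treat it
differently, and FLT3-ITD is a symbol distinct from FLT3 point
mutations):

* `not_evaluable` — no post-transplant plasma sample with gene-level
  data (e.g. death before the final sampling, remaining samples ND);
* `no_adverse_ever` — no adverse-risk mutation at diagnosis or before
  transplant;
* `persistent_adverse` — adverse-risk mutation in plasma at the **last
  evaluable** post-transplant timepoint (day 84 when available);
* `mrd_negative_pre` — no mutations at all in pre-transplant marrow or
  plasma;
* `cleared_pre` — adverse-risk disease at diagnosis but none in
  **pre-transplant plasma**;
* `cleared_post` — adverse-risk mutations in pre-transplant plasma,
  none at the last evaluable plasma timepoint.

Two rules here were genuinely open and deserve their rationale:

* **"Cleared before transplant" is judged on plasma, not marrow.** One
  packaged subject (003) carried an adverse BCOR mutation in
  pre-transplant marrow while plasma was negative. Reading pre-transplant
  clearance on the plasma compartment is consistent with a
  plasma-centric surveillance protocol and is the reading under which
  the packaged cohort's group sizes (2 MRD-negative + 2 cleared-pre = 4
  cleared before transplant; 5 cleared after; 9 persistent) match its
  published narrative.
* **Persistence is judged at the last evaluable timepoint** ("last
  evaluable wins"): a mutation absent at an interim draw but back at the
  final one is persistent. Interim timepoints in the packaged cohort
  carry only count/GM summaries, not per-gene identities, so gene-level
  persistence is decidable only at baseline and day 84 there; simulated
  cohorts carry gene-level data everywhere.

Diagnosis-era adverse status comes from subject metadata
(`adverse_at_diagnosis`), not recomputation — diagnostic panels are not
part of the dataset.

## Impending-relapse flag

The flag combines the two readouts: it fires when, between two
consecutive post-transplant plasma timepoints, the GM rises at least
R = 3-fold **or** the mutation count rises by at least C = 3, **and**
cfDNA donor chimerism falls by at least δ = 2 points over the same
interval. The published observation is qualitative ("dramatic rise…
in association with a fall in donor chimerism"); R, C and δ are
configurable defaults chosen to be well clear of technical noise at
depth 5,000 while catching a clone whose cfDNA share doubles every two
weeks between monthly draws (a 4-week doubling-time-14 regrowth is a
4-fold rise in expectation).

## The synthetic cohort: what it emulates

`simulate_cohort()` generates cohorts with the statistical structure the
analysis assumes, with full ground truth:

* **Genotypes.** Donor and recipient SNP genotypes are independent
  Hardy–Weinberg draws at allele frequency 0.5 (16 SNPs).
* **Host fraction.** The tumour-derived cfDNA fraction decays from
  $1 - h_\mathrm{eng}$ with a 10-day half-life (engraftment clearance);
  relapsing subjects add a clone regrowing with a 14-day doubling time
  from day 40. The host fraction is this tumour fraction plus a
  constant engrafted floor $h_\mathrm{eng} = 0.05$ (non-haematopoietic
  tissue turnover), capped at 1.
* **Somatic VAFs.** A single heterozygous clone per subject:
  VAF$(t)$ = CCF × tumour fraction$(t)$ / 2, with per-mutation cancer
  cell fractions back-calculated from baseline VAFs drawn uniformly on
  0.2–50%. This is the simplest generative story producing the observed
  VAF magnitudes; it deliberately omits multi-clone phylogenies,
  copy-number distortion and cfDNA fragment-length biology.
* **Noise and detection.** Every variant and SNP observation is a
  binomial read count at depth 5,000 (configurable); observed VAFs below
  the 0.02% limit of detection are dropped (the smallest tabulated VAF
  in the packaged cohort is 0.03%).
* **Planted confounders.** With configurable probabilities a subject
  carries one heterozygous host-germline variant (expected VAF
  $50h(t)$%) and one donor-transmitted variant (expected VAF
  $50(1-h(t))$%), for testing the origin-annotation heuristic.
* **Free parameters not fixed by the study design.** The regrowing
  clone's cfDNA share at onset (`relapse_seed_fraction = 0.04`) and the
  tumour fraction defining the programmed clinical relapse day
  (`relapse_burden_fraction = 0.5`, putting relapse near day 91 at
  defaults) were chosen once, by the power reasoning above: a 4% clone
  at onset makes the day-56→84 GM rise ≈3.3-fold, above the flag
  threshold, while keeping documented relapse after the day-84 draw.
* **Determinism.** All randomness flows from one seed; each subject
  draws from a counter-derived substream, so subject *k* is unchanged
  when the cohort grows.

Passing recovery tests on these cohorts therefore shows that the
estimators invert the package's *own* generative model at realistic
depth and panel size — not that they are robust to everything real
cfDNA does (CHIP clones of non-malignant origin, copy-number-driven VAF
shifts, variable extraction efficiency, or marrow/plasma sampling
discordance are all outside the model). The relapse-flag recovery
metric is additionally reported among *MRD-detectable* relapses: a
programmed relapse whose clone never yields a detectable mutation under
the panel's limit of detection cannot be flagged by any MRD-based rule,
so overall sensitivity conflates assay physics with estimator quality.

## Origin annotation

Where a variant table arrives without origin labels, `annotate_origin()`
applies a heuristic the source methodology only implies: a variant whose
pre-transplant VAF lies in the heterozygous band [40, 60]% or homozygous
band [90, 100]% in every pre-transplant compartment is host germline; a
variant absent at baseline, present at every later draw, and tracking
half the concurrent donor fraction within ±10 points is donor
transmitted. The bands are configurable; a somatic clone that happens to
sit at germline-like VAF in a single compartment is indistinguishable
under this rule and will be excluded — a documented false-positive mode
of the heuristic, not of the classification downstream of it.

## Statistics

Marrow-versus-plasma VAF comparisons use the Wilcoxon matched-pair
signed-rank test with a value of 0 assigned to mutations detected in
only one compartment. Zero differences (mutations absent from both, or
numerically equal) are dropped per the standard signed-rank convention —
stated explicitly because the zero-assignment rule creates many such
pairs. The null distribution is exact for up to 25 tie-free non-zero
pairs (validated in the tests against full $2^n$ sign enumeration),
otherwise a normal approximation with continuity correction; mid-ranks
handle ties. Mutation-count comparisons use the tie-corrected
Kruskal–Wallis test as the source methodology specifies (a paired test
might seem more natural for per-subject counts; the package implements
what was described). All p-values are two-sided. Survival bookkeeping
stops at OS/RFS time computation with censoring at last follow-up
(365-day study horizon); no Kaplan–Meier or Cox modelling is attempted
because only medians and counts are reported upstream.

The two headline p-values attached to the pre-transplant
marrow-versus-plasma comparison depend on the complete mutation lists
(including appendix-level calls not in the per-gene tables) and are not
reproduced; the tests instead verify the direction of both effects on
the packaged tables, whose per-gene rows do reproduce the 92-vs-61
mutation counts and the 7.53%/3.02% median VAFs exactly.

## The packaged cohort and its discrepancies

The bundled dataset transcribes the cohort's two printed tables: a
per-sample count/GM summary at six sample slots per subject, and
per-gene VAF lists at baseline and day 84. The two tables disagree in
thirteen cells (count tensions where one table lists a mutation the
other lacks, and two cells where equal counts still yield a different
GM). Both versions are retained verbatim; `load_hsct_cohort()` ships the
disagreement list as `$discrepancies`, and the integrity tests verify
that every *unflagged* cell's GM is reproduced from the per-gene VAFs
within ±0.05 (input-rounding tolerance) — and that every flagged cell
genuinely disagrees. Two VAF tokens are printed with a slash in the
decimal position ("0/73", "0/37"); they are shipped as printed and
normalized by the reader with a warning. Obvious gene-symbol typos are
normalized (DMNT3A→DNMT3A, MAP3Ki4→MAP3K14, "NFI I"→NF1); symbols
without an unambiguous correction ("TP31", "KRCC2") are kept as printed
— neither is on the adverse-risk list either way.

## Problem sizes and runtimes

The test suite runs the chimerism calibration at 200 mixtures × 16 SNPs
× depth 5,000, the depth-monotonicity check at 120 mixtures per depth
(500/5,000/50,000), the relapse-flag recovery at 100 programmed
relapses, and the noise-free-limit check at depth $10^7$ (where binomial
SD at a 50% VAF is ~0.016 points, comfortably inside the 0.1-point
assertion). These sizes give stable Monte-Carlo estimates at a few
seconds each; all fixture-based checks are instantaneous.

## Known limitations

* Single-clone, copy-neutral VAF model; no clonal evolution.
* Chimerism assumes exactly two DNA sources (no transfusion chimerism,
  twin grafts, or secondary donors).
* The origin heuristic needs a pre-transplant sample and, for donor
  transmission, concurrent chimerism estimates; without them variants
  default to somatic.
* CHIP versus true MRD cannot be distinguished from these data; the
  classification is agnostic about the biological source of persistent
  non-adverse mutations.
* Interim (day 28/56) per-gene identities are absent from the packaged
  cohort, so fixture-based clearance is a baseline-versus-day-84
  contrast.
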