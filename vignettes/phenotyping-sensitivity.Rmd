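---
title: "How EMR phenotyping choices propagate into genetic risk score associations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How EMR phenotyping choices propagate into genetic risk score associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenogrs)
library(dplyr)
```

## The question

Electronic medical records collect labs for care, not research: there is no
baseline visit, and the number and timing of measurements differ wildly
across patients. Any analysis of a repeated lab value therefore starts with
a phenotyping decision — which of a patient's many HDL cholesterol values
*is* their HDL-C? Reasonable conventions include the median of everything
on file, the first or the last value, or medians stratified by whether the
patient had started a lipid-lowering drug. If downstream genetic effect
estimates moved materially with that choice, every EMR-based association
study would carry a hidden analyst degree of freedom.

`phenogrs` implements the full chain needed to study this question
quantitatively: a seeded synthetic-EMR generator, a medication-lexicon note
scanner, the five HDL-C phenotype definitions, unweighted and weighted
seven-SNP genetic risk scores, and the sex-adjusted regressions whose
effect sizes are compared across definitions.

## The model

For subject $i$ with genotypes $g_{ik} \in \{0,1,2\}$ (count of the effect
allele at SNP $k$, $k = 1,\dots,K$ with $K = 7$), the genetic risk score is

$$\mathrm{GRS}_i \;=\; \frac{\sum_{k \in M_i} w_k\, g_{ik}}{|M_i|},$$

where $M_i$ is the set of SNPs with a non-missing call for subject $i$,
and $w_k = 1$ for the unweighted score or $w_k = \beta_k$ (the packaged
per-allele effect estimates) for the weighted score. The divisor $|M_i|$
makes the score an *average per-SNP contribution*: the unweighted score
lives in $[0, 2]$, missing genotypes shrink the denominator rather than
being imputed, and a subject with no calls at all has an undefined score.

Each phenotype definition $y^{(d)}_i$ is then regressed as

$$y^{(d)}_i = \alpha + \beta_d\, \mathrm{GRS}_i + \gamma\, \mathbb{1}[\text{female}_i] + \varepsilon_i$$

by ordinary least squares on complete cases. The report collects
$(\hat\beta_d, \mathrm{SE}, \mathrm{CI}_{95}, p)$ per definition, draws the
forest plot, and screens heterogeneity with pairwise
$z = (\hat\beta_1 - \hat\beta_2)/\sqrt{\mathrm{SE}_1^2 + \mathrm{SE}_2^2}$.
Because all definitions are computed on the same subjects the estimates
are strongly positively correlated, so this $z$ overstates true
discrepancies; it is emitted as a labeled descriptive screen, never as a
calibrated test. The substantive claim is read off the forest plot as
mutual overlap of the 95% intervals.

Note a unit subtlety: because the score is a per-SNP *average*, the slope
on the unweighted GRS aggregates the per-allele effects. If every SNP
shifts the trait by $\gamma$ per allele, the implied regression slope is
$K\gamma$, not $\gamma$ — with the default $\gamma = -2$ mg/dl, the
recovered slope is $-14$ mg/dl per score unit.

## The five phenotype definitions

Starting from all labs drawn at age $\ge 18$ (calendar comparison against
the 18th birthday; the birthday itself qualifies):

* **all** — median of every eligible lab;
* **first** / **last** — the value at the earliest / latest lab date;
* **premed** — median of labs strictly before the first dated medication
  mention; subjects with no mention ever contribute *all* their labs here;
* **postmed** — median of labs on or after that date; undefined for
  never-medicated subjects.

Medication evidence comes from scanning clinical notes against a packaged
lexicon of lipid-lowering drugs — generic names, brand names and class
terms across fibrates, niacin, resins, cholesterol-absorption inhibitors,
statins and fixed-dose combinations. Matching is case-insensitive exact
substring on word boundaries after stripping trademark glyphs. Two
deliberate properties follow: misspelled names do **not** match (no fuzzy
matching), and negated mentions ("denies taking statins") **do** — both
are documented false-negative/false-positive sources of a plain term
search, and the misspelling path can be exercised in simulation via
`misspelling_rate`.

Choices the data cannot make for us, fixed as conventions and covered by
tests:

* a lab dated the same day as the first mention counts as
  *post*-medication (it cannot be confirmed medication-naive);
* even-count medians are the mean of the two middle order statistics;
* same-date first/last ties resolve to the minimum (first) and maximum
  (last) value — EMRs carry no reliable intraday ordering;
* the pre and post strata partition a medicated subject's labs, so one
  subject can contribute to both definitions and the per-definition `n`
  differ.

## What the generator emulates — and what it does not

`simulate_cohort()` draws, per subject: sex; a birth date making the
subject adult across the observation window; genotypes
$g_{ik} \sim \mathrm{Binomial}(2, f_k)$; a random intercept
$b_i \sim N(0, \sigma_b^2)$; with probability `prob_ever_medicated` a
medication start date uniform in the window, a start-of-therapy note dated
exactly at it and further mentions after it; and labs

$$y_{ij} = \beta_0 + \gamma_{\mathrm{sex}}\mathbb{1}[\text{female}] +
\textstyle\sum_k \gamma_k g_{ik} + \delta\,\mathbb{1}[t_{ij} \ge t^{\mathrm{med}}_i] +
b_i + \varepsilon_{ij}.$$

Defaults, with the reasoning:

| parameter | default | why |
|---|---|---|
| `effect_allele_freqs` | 0.45–0.70, sum 4.0 | modal total risk-allele count of 8 out of 14 |
| `per_allele_effects` | $-2$ mg/dl each | equal effects keep the implied GRS slope exact ($-14$); the packaged weight-table betas remain available when a weighted-score contrast is wanted |
| `intercept_beta0` | 63 mg/dl | places the all-labs median near 51 mg/dl after the mean genetic load ($\approx -16$) and sex mix ($+4$) |
| `sex_effect` | $+8$ mg/dl | typical female–male HDL-C gap |
| `medication_effect_delta` | $-3$ mg/dl | small step at therapy start, matching a modestly lower post-medication median |
| `prob_ever_medicated` | 0.42 | roughly the share of subjects with medication evidence in EMR lipid cohorts |
| `labs_per_subject_dist` | Poisson(3) | median of about three measurements per record |
| `obs_noise_sd`, `subject_noise_sd` | 10, 8 mg/dl | total SD ≈ 13 mg/dl, a realistic HDL-C dispersion |
| `prob_minor_age` | 0.05 | a minority of labs predate the 18th birthday, exercising the adult filter |

The generator is deliberately simpler than a real EMR. It does not emulate
clinical language beyond short templated sentences, ICD codes, informative
visit timing (sicker patients visiting more), analyte unit changes,
assay drift, fasting status, or medication discontinuation — the
medication effect is a single step at the start date, the simplest model
consistent with a pre/post dichotomy. Passing tests therefore demonstrate
that the *algorithms* are correct and that the statistical machinery is
calibrated under a well-specified generative model; they do not
demonstrate robustness to the messiness of real clinical text or to
informative observation processes.

The genotype file is written as a minimal VCF v4.2 in which the effect
allele is randomly the REF or the ALT allele per SNP, so the downstream
orientation step (flipping dosage $d \to 2-d$ when the effect allele is
REF) is genuinely exercised rather than trivially satisfied.

## Numerical and design choices

* Missing values: never imputed. The GRS uses the non-missing-SNP
  denominator; regressions are complete-case per definition, so `n`
  varies across the five results and is reported with each.
* Confidence intervals and p-values are t-based with $n - 3$ degrees of
  freedom — indistinguishable from normal-based at cohort sizes, correct
  at small n.
* Sex is coded female = 1; the GRS coefficient is invariant to this
  choice.
* Degenerate inputs fail loudly: a constant GRS raises a singular-design
  error, fewer than three complete cases an insufficient-data error, a
  lab predating birth or an orphan subject id a data error, and every
  simulation-config violation names its field.
* All randomness flows from one integer seed; the pipeline derives a
  per-stage child seed so a rerun is byte-identical (verified by sha256
  manifests in the test suite).

## Simulation studies shipped with the package

The test suite runs three seeded studies, sized to be informative while
keeping a full check quick: a type-I-error study (2,000 replicates of
n = 1,000 single-lab cohorts with all per-allele effects zero; empirical
size must sit in 0.035–0.065 at $\alpha = 0.05$), a recovery study (200
replicates at n = 5,000 with $\gamma = -2$; the mean slope must fall
within two Monte-Carlo SEs of $-14$ and 95% CI coverage in 92–98%), and a
full-pipeline consistency study (one 4,000-subject cohort with a
time-invariant genetic effect and a medication step; all five definitions'
intervals must mutually overlap, and with equal score weights the weighted
and unweighted t statistics must agree in magnitude to $10^{-6}$ — the
weighted score is then an exact, sign-flipped rescaling).

## A worked run

```{r example, eval = FALSE}
run <- run_pipeline(pipeline_config(out_dir = "run1", seed = 42,
                                    n_subjects = 2000))
run$comparison$associations |>
  filter(grs_mode == "unweighted") |>
  select(phenotype_definition, n, beta, ci95_low, ci95_high)
autoplot(run$comparison)
plot_risk_allele_histogram(read_grs(run$paths[["grs"]]))
```

## Limitations

* The lexicon scan has no negation, section or temporality handling; its
  false-positive behaviour is by construction, not an oversight, and is
  the main reason pre/post stratification can misclassify labs in real
  notes.
* The pairwise heterogeneity z ignores the between-definition correlation
  induced by shared subjects; treat it as descriptive.
* The weighted score treats the packaged per-allele estimates as abstract
  weights; their absolute scale is not interpreted.
* Conclusions about robustness to phenotyping decisions transfer to real
  cohorts only to the extent the generative model's assumptions
  (time-invariant genetic effect, additive step medication effect,
  non-informative lab timing) hold there.
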