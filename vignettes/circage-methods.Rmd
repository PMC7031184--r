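---
title: "circage: methods, models and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{circage: methods, models and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circage)
```

# The problem

Circular RNAs (circRNAs) arise when a downstream splice donor joins an
upstream acceptor, producing a covalently closed transcript whose
back-spliced junction (BSJ) is the only sequence evidence distinguishing
it from its linear host. Because circRNAs resist exonucleolytic decay they
accumulate with age, and profiling them in blood across young and old
donors — then following candidates into a population cohort, senescent
primary cells, and a mouse strain panel — is a natural design for asking
whether specific circRNAs track aging phenotypes. `circage` implements
that analysis chain with a synthetic-data layer that replaces the
(undeposited) raw data, so every inferential step can be validated by
recovering planted truth.

# Quantification

## The bpm statistic

For circRNA $i$ in one library, with BSJ read count $j_i$, host-gene
canonical read count $c_i$, and $n$ detected circRNAs,

$$\mathrm{bpm}_i = \frac{j_i}{\sum_{a=1}^n j_a + \sum_{b=1}^n c_b}
\times 10^6 .$$

The denominator is the combined circular and linear read mass of the
circRNA-producing loci, which makes bpm comparable across libraries of
different depth without requiring total mapped reads. Two consequences
are used as test invariants: $\sum_i \mathrm{bpm}_i = 10^6 \sum j / D$
(equal to $10^6$ exactly when all canonical counts vanish), and invariance
under rescaling all counts by a constant.

Both summation indices run over circRNAs, so a gene hosting two circRNAs
contributes its canonical count twice. We keep this literal reading as the
default (`canonical = "per_circ"`) because it is what the formula states;
a `per_gene` variant that counts each host once is available, since the
intent is ambiguous when host genes are shared. With the default
simulation (one host gene per circRNA) the two coincide.

## Presence, classes and ranking

Presence in a pool is called from the RNase R-treated library only —
RNase R degrades linear RNA, so the treated library is the
circRNA-enriched evidence and the mock library serves as a treatment
control, not as a detection channel. The default threshold is 2 BSJ reads:
a single chimeric read is a common alignment artifact. Classes are then
set-theoretic: `young_only`, `old_only`, `shared`.

Shared circRNAs are ranked by $|\log_2$ fold change$|$ with a pseudocount
equal to the bpm equivalent of one read in the smaller library
($\varepsilon = 10^6/\min(D_y, D_o)$). This choice ties the pseudocount to
the resolution of the data: no shared circRNA can display a fold change
larger than what one read could explain. Ties break by the larger of the
two bpm values, then lexically — making candidate selection fully
deterministic.

Top-decile host-gene extraction uses the ceiling rule
($\lceil 0.10\,n\rceil$), so a non-empty profile always contributes at
least one gene, and deduplicates hosts preserving abundance order.

## Bar scaling

Junction read depths are mapped to integer bars
$\mathrm{round}(1 + 9(d - d_{\min})/(d_{\max} - d_{\min}))$ with
round-half-up (base R's `round()` is half-to-even, which would make
reported bars depend on parity). A constant depth vector maps every
junction to 10 bars: each junction is simultaneously the minimum and the
maximum, and the maximum branch wins.

# Over-representation

Host genes are tested against user-supplied GMT gene sets by the
two-sided hypergeometric test: with universe size $N$, set size $m$,
query size $q$ and overlap $k$,
$p_\mathrm{enrich} = P(X \ge k)$, $p_\mathrm{deplete} = P(X \le k)$,
$p_{2} = \min(1, 2\min(p_\mathrm{enrich}, p_\mathrm{deplete}))$, followed
by Holm's step-down procedure across sets ("Bonferroni step-down" in the
pathway-tool vocabulary). The test suite checks these probabilities
against exhaustive enumeration of all $\binom{N}{q}$ draws for
$N \le 12$, to $10^{-12}$. No pathway database ships with the package:
collections are snapshots with their own versioning, and results only
reproduce against the same snapshot; the universe defaults to all genes
hosting any detected circRNA but is configurable.

# The parental longevity score

Participants aged 65+ are scored. Parents who died prematurely (mothers
before 49, fathers before 52 years) are excluded. Each remaining parental
age at death is standardized within the eligible, non-premature parents of
the same sex using the sample SD (ddof = 1); the PLS is the unweighted
mean of the available parental Z-scores, and deliberately **not**
re-standardized: the average of two imperfectly correlated unit-variance
scores has SD below 1, which is what cohort summaries report (SD ≈ 0.8);
re-standardizing would contradict them. Single-parent scores are allowed
by default (`require_both = TRUE` disables this). Short / intermediate /
long-lived categories per parent are derived from tertiles of a normal
distribution fitted to the usable ages at death and reported for
description; association models use the continuous score. Z-scores are
computed within the eligible subsample rather than the full cohort — the
score is defined relative to the population actually analysed.

# Association models

## Orientation

All models are OLS with the shared confounder set: BMI, sex, education,
study site, smoking, WBC differentials, plus age for the non-age models.
Education and smoking enter as single ordinal columns by default: full
dummy coding of 6 education levels costs 5 df per model at n ≈ 300, which
is a poor trade; a flag restores dummy coding. Missingness is handled by
listwise deletion per model, with `n_used` reported per row, since the
different outcome availabilities naturally produce different n.

Orientation is chosen per outcome to match the scale on which such
coefficients are conventionally reported: for age and PLS, expression is
the dependent variable (β = expression change per year / per PLS unit);
for grip strength, grip is the dependent variable (β = kg per unit
relative expression). Both orientations are available and the one used is
recorded in every result row. The longitudinal grip design pairs baseline
expression with follow-up grip without baseline-grip adjustment (a
change-score adjustment is available by flag but not default, as it
changes the estimand).

Significance is flagged against the **unrounded** Bonferroni threshold
$\alpha/n_\mathrm{tests}$; the rounded (half-up) threshold exists only for
table reporting, so 0.05/15 prints as 0.003 and 0.05/4 as 0.013 while
flags use 0.00333… and 0.0125.

## qPCR normalization

Four steps: (1) technical replicates collapse by median Ct (robust to a
single failed well); (2) per-sample ΔCt against the arithmetic mean Ct
across assays, which is exactly the geometric mean on the $2^{-Ct}$
expression scale; (3) $E = 2^{-\Delta Ct}$; (4) per-assay division by the
geometric mean across samples, so every assay's geometric-mean relative
expression is exactly 1 (a test invariant, to $10^{-10}$). "Undetermined"
wells must be coded NA — never Ct 50, which would fabricate signal.
Samples with no usable Ct are dropped with a warning; assays missing in
more than half the samples are flagged but retained.

## Senescence comparison

Early vs late passage is compared per circRNA by one-way ANOVA on the
normalized expression of biological replicates. With two groups this is
algebraically the pooled-variance t-test ($t^2 = F$), which the suite
verifies numerically on random instances. The degenerate all-equal case
reports $F = 0, p = 1$ rather than NaN. circRNAs lacking detectable Ct in
either passage group are `expressed = FALSE` and excluded from testing;
dysregulation counting then uses distinct-circRNA semantics (significant
in several cell types counts once), with the fraction reported as a whole
percent — the worked example from the published early/late p-value table
yields 7 of 12 (58%).

## Mouse strain-lifespan regression

Mouse panels are normalized by ΔCt against the geometric mean of three
endogenous controls (Pol2ra, Trfc, Ipo8 — equivalently the arithmetic
mean of their Cts), then per-circRNA global-geometric-mean scaling across
the tissue's samples; normalized expression is regressed on median strain
lifespan per circRNA, within the `all`, `young` or `old` stratum.
circRNAs with no Ct anywhere in a tissue propagate as not-detected rows
(the "ND" convention), never as zeros.

# The synthetic-data layer

The generators state a world; their defaults are fixed and not tuned to
test outcomes.

* **Pools**: class sizes default to the planted profile 184 shared / 431
  young-only / 1592 old-only (2207 total). BSJ counts are negative
  binomial (mean 60 in a mock library, dispersion 0.2; variance
  $\mu + \phi\mu^2$) because pooled junction counts are over-dispersed;
  no count model is prescribed upstream, so NB is our choice. RNase R is
  modeled as two multiplicative factors — linear retention 0.05 and
  circular enrichment 5 — the simplest parameterization of "removes
  linear RNA, spares circles". Shared fold changes are
  $N(0, 1.5^2)$ on the log2 scale, split symmetrically across pools.
  Library sizes are scaled down by roughly two orders of magnitude from
  the real 157–167M-read pools; bpm is depth-normalized, so this changes
  only count noise, not expectations.
* **Cohort**: covariates are drawn from the published summary
  distributions (decade-band age frequencies clamped to [30, 94], BMI
  N(27.15, 4.35²) clamped to [15.01, 42.99], WBC percentages similarly,
  categorical covariates at the reported proportions). Parental deaths
  are sex-specific normals (means 74/71, SD 11) with a planted 5%
  premature fraction and 5% missingness. Expression is
  $1 + \text{loadings} + \beta\,(\text{outcome} - \bar{\cdot}) +
  N(0, 0.2^2)$; default confounder loadings are small BMI and neutrophil
  slopes so adjustment is exercised. The planted recovery effect
  (β = −0.065 on PLS) mirrors the largest reported cohort effect.
* **Senescence plates**: 4 cell types × early/late × 3 biological × 3
  technical replicates; late Ct = early baseline − shift + noise
  (biological SD 0.15, technical SD 0.1 Ct). Note that the ΔCt step
  redistributes a single assay's shift slightly across the other assays
  of the same sample (by shift/n_assays), a real property of global-mean
  normalization that the power tests inherit.
* **Mouse panel**: 6 strains × young/old × 7 animals per group per
  tissue, matching the reported per-tissue sample sizes (~90 spleen). The
  strain lifespans are **synthetic placeholders** (22–33 months) — the
  source names the strains but not their median lifespans. circRNA Ct is
  constructed as $\overline{Ct}_\mathrm{ref} - \log_2(1 + s\,L)$ plus
  noise, so reference-normalized expression has expectation
  $1 + sL$.

What a green recovery test establishes: the estimator is unbiased (to
Monte-Carlo resolution) for effects planted under this world's
assumptions — linear effects, Gaussian noise, covariates independent of
expression except through planted loadings. What it does not establish:
robustness to the real data's features absent here — batch effects,
expression-dependent dropout, correlated WBC-expression structure,
non-linear age trajectories.

# Numerical choices and edge cases

* Round-half-up (`floor(x·10^d + 0.5)/10^d`) for reported thresholds and
  bar counts; base `round()`'s banker's rounding would report 0.05/4 as
  0.012.
* The global-geometric-mean scaling in the mouse normalization divides by
  a constant that itself contains the planted signal, attenuating a
  young-stratum slope by ~3–4% at the default effect size. This is a
  property of the method, not a bug; measured over 200 replicates the
  mean estimate remains within 2 Monte-Carlo SE of the plant.
* Rank-deficient association designs (including constant covariate
  columns) raise an error naming the aliased columns rather than
  silently dropping them.
* All generator randomness flows from one integer seed; the pipeline
  derives stage seeds as `(seed·7919 + offset·104729) mod (2^31 − 1)`, so
  per-stage reruns reproduce exactly and identical configs yield
  byte-identical outputs and manifests (no timestamps in the manifest;
  config fingerprint by FNV-1a over canonical JSON).

# Known limitations

* BSJ detection itself is upstream and out of scope: inputs are junction
  count tables, not reads.
* The hypergeometric layer reproduces the testing machinery, not any
  specific pathway-database result, which is snapshot-dependent.
* Printed cohort, senescence and mouse coefficients from the motivating
  study are not recomputable (no deposited data); the package's claims
  are therefore about correctness under planted truth plus the
  arithmetic-recoverable worked examples (class counts, thresholds,
  dysregulation fractions).
* No mixed-effects or survival modeling; the mouse regression treats
  animals as independent given strain lifespan, as in the source design.
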