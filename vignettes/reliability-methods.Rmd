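---
title: "Agreement methodology for multi-observer dental staging studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Agreement methodology for multi-observer dental staging studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dentagree)
```

## Setting

A dental age estimation (DAE) reliability study has a crossed design:
$n$ subjects (panoramic radiographs), $R$ observers, two reading
sessions, and several third molars (FDI 18/28/38/48) per subject, each
staged under several methods. Three of the methods here are ordinal
stagings — Kullman (7 stages, mandibular teeth only), Demirjian (8
stages A–H), Gleiser–Hunt as modified by Köhler (10 stages) — and one
is a continuous index, Cameriere's third molar maturity index I3M
(open-apex width over tooth length, $\ge 0$, shrinking to 0 as the
apex closes). Any cell may instead be marked NA (not assessable, e.g.
image distortion).

The analysis unit for pooled coefficients is the **(subject, tooth)
pair**: an "Overall" table for a four-tooth method stacks
$50 \times 4 = 200$ units rated by 9 observers, i.e. 1800 cells, and
per-jaw tables stack the two maxillary or two mandibular teeth. This
convention is what makes the reported observation totals come out as
multiples of 450 per tooth before NA exclusion. It treats teeth within
a subject as exchangeable units, ignoring their within-subject
correlation; the consequence is discussed under *Limitations*.

## Agreement coefficients

### Weighted agreement and the chance terms

Let $r_{iq}$ be the number of raters placing unit $i$ in category $q$,
$r_i = \sum_q r_{iq}$, and let $W = (w_{kl})$ be a symmetric agreement
weight matrix with unit diagonal. Observed agreement averages the
weighted concordance of all rater pairs within each unit (units with
$r_i < 2$ carry no pairwise information and are excluded from $p_a$,
though they still count toward reported observation totals and the
prevalence estimates):

$$p_a = \frac{1}{n'} \sum_{i:\, r_i \ge 2} \sum_q
  \frac{r_{iq}\,(r^{\star}_{iq} - 1)}{r_i (r_i - 1)},
  \qquad r^{\star}_{iq} = \sum_l w_{ql}\, r_{il}.$$

The coefficients differ only in the chance term:

* **Gwet's AC1/AC2**: $p_e = \frac{T_w}{Q(Q-1)} \sum_q \pi_q (1 -
  \pi_q)$ with $\pi_q$ the across-unit mean classification proportion
  and $T_w = \sum_{kl} w_{kl}$. Identity weights give AC1; any ordinal
  weighting gives AC2.
* **Fleiss-type kappa**: $p_e = \sum_q \pi_q^2$.
* **Cohen's weighted kappa** (two ratings): $p_o = \sum_{kl} w_{kl}
  p_{kl}$ against $p_e = \sum_{kl} w_{kl} p_{k\cdot} p_{\cdot l}$.

All return $(p_a - p_e)/(1 - p_e)$.

The practical difference is the *kappa paradox*: with a dominant
category (say stage H at 95% prevalence), $\sum \pi_q^2 \to 1$ and
kappa collapses even at 90% raw agreement, while Gwet's
$\sum \pi_q(1-\pi_q) \to 0$ keeps the chance correction honest:

```{r paradox}
x <- c(rep("H", 18), "H", "G")
y <- c(rep("H", 18), "G", "H")
cohen_kappa_weighted(cbind(x, y), kind = "identity")$coefficient
gwet_ac(rating_matrix_from_values(
  cbind(x, y), staging_scheme("DEM", LETTERS[1:8], 38L)))$coefficient
```

This is why AC1 is the right instrument for NA concordance (NA
prevalence is a few percent by design) and AC2 the headline
inter-observer statistic for staging.

### Weights and the category-exclusion rule

Four weight kinds are provided over $Q$ ordered categories at distance
$d = |k - l|$: identity; linear $1 - d/(Q-1)$; quadratic
$1 - d^2/(Q-1)^2$; and the ordinal pairs-combination weighting
$1 - \binom{d+1}{2} / \binom{Q}{2}$, the recommended choice for ordinal
stages (small penalties for one-stage discrepancies, penalty 1 for the
extreme pair). AC2 here uses ordinal weights by default; the weighted
intra-observer kappa uses the same kind for consistency (the study
methodology names no kind for the kappa; this is a package choice,
configurable via `weights_kind`).

Stages never used by any observer *in the analyzed table* are excluded
before the weight matrix is built (`observed_categories()`), applied
per analysis matrix rather than globally per method — the reading we
adopt of "categories not presented in the evaluations of any of the
observers". For the empirically relevant case — unused stages at the
tails of the distribution — the exclusion shrinks every off-diagonal
weight, i.e. it is conservative. Note the caveat: dropping a category
*interior* to two observed ones (possible in principle, rare in
practice) reduces both the distance and the alphabet size and can
locally *raise* a weight; the conservatism claim is a tail-exclusion
property, and the test suite checks it exactly there.

### Variance estimation

Multi-rater coefficients use the unit-level linearization: with
per-unit contributions $AC_i = (p_{a,i} - p_e)/(1-p_e)$ corrected for
the chance-term influence,
$AC_i^{*} = AC_i - 2(1 - AC)\,(p_{e,i} - p_e)/(1 - p_e)$, the variance
is $\widehat{V} = \frac{1}{n(n-1)} \sum_i (AC_i^{*} - AC)^2$ (no
finite-population correction — the 50 radiographs stand for a
population, they are not one). The suite cross-checks this against a
leave-one-unit-out jackknife (agreement within 10% at $n = 120$).
Weighted Cohen's kappa uses the Fleiss–Cohen–Everitt large-sample
variance. Confidence intervals are $\pm 1.96\,\mathrm{SE}$ truncated
to $[-1, 1]$ (published tables print intervals reaching exactly
1.000). Degenerate inputs — a single observed category, or two constant
raters, where the chance term reaches 1 — return a *flagged* result
rather than an error, so batch pipelines keep going; real staging data
can be constant on a tooth.

### ICC for the continuous index

I3M reliability uses the intraclass correlation from the two-way
crossed ANOVA, absolute agreement, single measures:

$$\mathrm{ICC}(A,1) = \frac{MS_R - MS_E}
  {MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)},$$

which charges systematic rater offsets ($MS_C$) against agreement — the
right form when observers' raw measurements must be interchangeable.
The two-way *mixed* and *random* formulations share this point
estimate; the mixed reading only changes interpretation. Confidence
intervals use the standard F-based (McGraw–Wong) interval and the
p-value the $MS_R/MS_E$ F-test. Subjects with incomplete rater rows
are dropped listwise (the ANOVA needs balance) with the dropped count
reported — which is why published per-tooth ICC totals are multiples
of $k$ slightly below $n \times k$.

### NA concordance

Assessability agreement recodes every cell to NA / not-NA — a total
recoding, so *all* cells enter (900 per two-tooth method, 1800
overall for four-tooth methods) with no exclusion — and computes
unweighted AC1 with both binary categories always retained: with no NA
anywhere, $\pi = (1, 0)$, $p_e = 0$ and AC1 is exactly 1. A per-rater
NA-prevalence audit flags any rater above 5%; it is a descriptive
flag, not a gate.

### Benchmarks

Kappa-type coefficients are labelled on the Landis–Koch bins (<0 poor,
0–0.20 slight, 0.21–0.40 fair, 0.41–0.60 moderate, 0.61–0.80
substantial, 0.81–1.0 almost perfect); ICC on Portney–Watkins (<0.5
poor, 0.5–0.75 moderate, 0.75–0.9 good, ≥0.9 excellent). These verbal
bins were designed for kappa-family statistics; applied to AC1/AC2
they should be read as conventions, not calibrated guarantees.

## The rating simulator and power analysis

### Mechanism

`simulate_ratings()` draws, per unit, a latent stage $L \sim \pi$;
each rater independently reports $L$ with probability $\rho$ and
otherwise an independent draw from $\pi$. Two properties make this
mechanism the right tool:

* **Exact marginal preservation**: each rater's ratings are iid $\pi$
  for *every* $\rho$ — the correlation knob cannot distort the stage
  distribution being emulated.
* **Analytic anchor**: pairwise match probability is
  $\rho^2 + (1-\rho^2)\sum_q \pi_q^2$; under uniform marginals with
  identity weights the large-sample expected AC1 is exactly $\rho^2$,
  which the suite verifies at $\rho \in \{0, 0.5, 0.775, 1\}$
  ($n = 200$, 1000 replicates, within $\pm 0.02$).

One statistical subtlety: raters within a matrix share the latent
draws, so *per-rater* goodness-of-fit statistics computed on the same
matrix are strongly positively correlated (and naive chi-squares on
cells pooled across raters are variance-inflated). Marginal
preservation is therefore tested on a single rater per simulated
matrix, where the multinomial reference is exactly calibrated.

Marginals come in three named shapes: `uniform`; `skew_low`
($\pi_q \propto 0.7^{\,q-1}$, mass at early stages) and its mirror
`skew_high`. The published study states skewed distributions without
printing them; the truncated-geometric ratio 0.7 is the package's
choice of a strong but not degenerate skew (the most extreme of 7–10
categories keeps ~1–3% mass).

### Calibration, power, minimum n

`calibrate_rho()` bisects $\rho$ against the Monte Carlo mean
coefficient (monotone in $\rho$), reusing one seed across bisection
steps (common random numbers), so calibration is deterministic given a
seed. Defaults (400 replicates per step, tolerance 0.004) put the
calibrated mean well within the $\pm 0.02$ contract.

`estimate_power()` simulates rating matrices at a calibrated $\rho$
and counts rejections of the one-sided normal test
$(AC_2 - AC_0)/\mathrm{SE} > z_{1-\alpha}$; `min_n_for_power()` walks
an ascending n-grid per (marginal, category-count) condition and
extracts the smallest n with power at or above the target, with the
overall recommendation the maximum over conditions. The study's
configuration — 9 raters; 7, 8, 10 categories; uniform and both skewed
marginals; true AC2 0.6 vs null 0.4; $\alpha = 0.05$ one-sided (the
level is the package's assumption; the methodology states one-sided
tests without one); grid $\{5, 10, \dots, 50\}$ — is the default.

Replication sizes are worth a word. At the calibrated truth the power
at $n = 25$ in the binding skewed conditions is only ~0.815, so a
1000-replicate estimate (Monte Carlo SE ≈ 0.012) lands below the 0.8
threshold often enough to push the extracted minimum up a grid step.
The analysis driver uses 2000 replicates per grid point;
`scripts/acceptance.R` uses 8000 with 4000-replicate calibration
steps, which pins each power estimate to about half a percentage point
and makes the extracted minimum stable across seeds. These are
precision choices for estimating a fixed quantity, not changes to the
design being emulated.

### Precision-based sample sizes

Two routes, matching the two planning traditions:

* `bonett_icc_n()` — the closed form
  $n = \lceil 8 z^2 (1-\rho)^2 (1 + (k-1)\rho)^2 / (k(k-1)w^2) + 1
  \rceil$ for the ICC arm ($w$ the full CI width). At $\rho = 0.8$,
  $k = 9$, half-width 0.1: 25 subjects.
* `precision_n_simulated()` — a generic simulation search for the
  smallest n whose Monte Carlo *median* 95% CI half-width meets a
  demand, for Fleiss-type kappa, AC1 or AC2. This is the package's
  stand-in for closed-form multi-rater kappa planning: the published
  kappa-based figure (48) depends on unstated skewed category
  probabilities, so it is not reproducible as printed; the search
  provides the same decision with explicit, checkable inputs and obeys
  the expected monotonicities (looser demand, never more subjects).

## The synthetic study generator

No raw rating table is published, so `generate_study()` fabricates one
with the study's design and printed marginal structure; every
generating parameter is returned in a truth record so the pipeline can
be validated by parameter recovery (`recover_parameters()`).

Choices, fixed once:

* **Stage marginals and NA rates** per (method, tooth) from the
  published descriptive table (counts out of 450 session-1 cells).
  NA is imposed independently of stage — the real causes (ghost
  shadows, sinus superimposition) cluster anatomically, which is
  deliberately not modeled.
* **Inter-observer correlation** `inter_rho = 0.9` per ordinal method,
  placing simulated AC2 in the 0.87–0.94 band that trained observers
  reach in such studies.
* **Session dependence**: a session-2 ordinal rating repeats session 1
  with probability `intra_repeat_agreement = 0.95`, else is
  regenerated from the same latent stage; intra-observer kappa is then
  approximately the repeat probability plus a chance-match bonus,
  giving kappas ≈ 0.99 (the upper end of the published 0.85–1.00
  range) and an analytically tractable check.
* **I3M**: subject truths are log-normal matched to the printed
  medians (0.27 / 0.26) and quartile ratios (log-normal is the natural
  positive-support choice; the published table gives no distributional
  form), observer readings multiply the truth by log-normal noise with
  $\sigma_{\log} = 0.05$ (~5% error), and both sessions draw fresh
  noise — identical repeated measurements are as good as impossible,
  exactly the metric-method behaviour the study describes. Values are
  written at 2 decimals, as measured indices are. The implied
  inter-observer ICC,
  $(e^{\sigma^2}-1)\big/\!\left((e^{\sigma^2}-1) +
  e^{\sigma^2}(e^{\tau^2}-1)\right) \approx 0.993$, is the recovery
  target.
* Ages uniform on [14, 23.99) with 19 male / 31 female; chronological
  age is exposure date minus birth date at 365.25 days/year.

What passing on synthetic data does *not* show: robustness to
stage-dependent missingness, to observer-specific severity biases
(every simulated observer shares one $\rho$), or to within-subject
correlation between teeth. Estimates on real radiograph data inherit
none of the generator's guarantees.

## Numerical conventions and degenerate inputs

* Stage labels are strings; ordinal position within the scheme is the
  only numeric handle (avoids the A-vs-1 ambiguity across methods).
  NA markers `NA`, `N/A`, `""` (case-insensitive) are accepted on
  input and normalized.
* Dates are ISO-8601; decimal ages use 365.25 days/year.
* CIs truncated to $[-1, 1]$; coefficients print at 3 decimals,
  percentages at 1, as in the published tables.
* Degenerate tables (single observed category; both paired raters
  constant; zero total variance for ICC) yield flagged results, not
  errors; empty selections and incomplete designs raise immediately
  with the offending rows named.
* All simulation entry points take explicit integer seeds; identical
  seeds give byte-identical outputs (including the written CSV of a
  generated study).

## Problem sizes in the test suite

Exhaustive oracle equivalence runs over all 2-rater tables with up to
4 units and 3 categories (~7.7k tables) plus 500 random multi-rater
tables with missing cells, at tolerance $10^{-12}$ against brute-force
implementations of the defining formulas. Monte Carlo checks use
$n = 200$ with 1000 replicates (analytic AC1 limit), $n = 500$,
$k = 9$ with 200 replicates (ICC recovery), and 8000/4000 replicates
for the power grid, sizes at which each check's Monte Carlo error is
several times smaller than its tolerance.

## Limitations

* Pooled coefficients treat (subject, tooth) pairs as independent
  units; within-subject correlation across teeth makes the pooled SEs
  mildly optimistic. Per-tooth tables carry no such caveat.
* Krippendorff's alpha and average-measure ICC forms are not
  implemented; nor are closed-form AC variance sample-size formulas.
* The benchmark labels are conventions transplanted from the kappa
  literature; AC1/AC2 values sit systematically higher than kappas on
  the same data, so cross-study comparisons should compare like with
  like.
* The generator emulates marginal structure, not image content; it
  cannot validate stage *assignment*, only the agreement machinery
  downstream of it.
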