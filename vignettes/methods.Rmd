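---
title: "Peer networks and academic well-being: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peer networks and academic well-being: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peerwell)
```

## The setting

Classroom surveys of adolescent cohorts often collect *cooperation
nominations*: every student registered in a school's two surveyed grades is
listed in a directory, and each participant names up to five schoolmates
they prefer to work with or ask for advice on schoolwork. The resulting
directed, bounded-out-degree graph — one per school — carries information
at two levels. A student's *position* (how many schoolmates they name, how
many name them, whether they are isolated) describes their social standing;
the school network's *structure* (density, degree centralization, ego
clustering, and the school's self-reported connectedness climate) describes
the social environment all its students share. `peerwell` implements the
full path from the three raw survey tables to standardized multilevel
estimates of how position and structure relate to two academic well-being
outcomes, schoolwork engagement and school burnout.

## Data model and cleaning rules

Three CSV tables (comma-separated, UTF-8, header row mandatory, missing =
empty cell) define a cohort:

* `roster.csv` — one row per registered student: `student_id`, `school_id`,
  `country_code`, `grade` (1 or 2), `class_id`, `sex` (`female`/`male`),
  `age` (integer 12–19), `participated`, `fas1..fas4` (0–3). Identifiers
  are opaque strings. A duplicated `student_id` is a hard error; an
  out-of-range age keeps the record but blanks the value with a warning.
* `nominations.csv` — `ego_id`, `alter_id`, `rank`. Cleaning drops, in this
  order and with per-rule tallies: unknown egos, egos who did not
  participate, unknown alters, cross-school alters, self-nominations,
  duplicated (ego, alter) pairs; egos with more than five surviving rows
  are truncated to the five best ranks. Cleaning is idempotent.
* `items.csv` — `student_id`, `eda1..3` (0–5), `ssbi1..3` (1–6),
  `conn1..5` (1–4); out-of-range values are blanked with a warning.

Two design points deserve emphasis. First, the network universe of a school
is **all registered students of the two grades**, so non-respondents remain
nodes: they cannot send ties (their out-degree is structurally zero) but
they can receive them. Second, because of that asymmetry the percentage of
*isolated* students (no ties either way) is computed over participating
respondents only, while density, centralization and clustering use the full
node set. We know of no authoritative statement of how such surveys treat
nominations of non-participants; keeping them as receivable nodes is our
interpretation and is flagged here as such.

## Scales

All scales are scored complete-case (a score exists only if every
contributing item was answered):

* engagement = mean of the three EDA items (0–5);
* burnout = mean of SSBI items 1 (inadequacy) and 2 (cynicism) on 1–6 —
  item 3 (exhaustion) is excluded because its consistency with the first
  two is too poor to pool, which makes burnout the one scale where item
  order is meaningful;
* connectedness = mean of the five climate items (1–4), then averaged over
  a school's participating students to give the school connectedness
  climate;
* family affluence = sum of the four items (a tertile categorisation is a
  plausible alternative; the sum is the default).

The explicit complete-case rule is documented for engagement and burnout in
this family of instruments; we extend the same rule to connectedness and
FAS as an assumption. Internal consistency is Cronbach's
$\alpha = \frac{k}{k-1}\bigl(1 - \sum_j s_j^2 / s_T^2\bigr)$ on complete
cases, with the `n` used reported alongside.

## Network metrics

With $n$ nodes and $E$ directed edges,

* density $= 100\,E/(n(n-1))$;
* centralization $= 100 \sum_i (c_{\max} - c_i)/(n-1)^2$ with $c_i$ the
  **in-degree**. The verbal anchors of the index — zero when every student
  has the same number of nominations, one hundred when a single student is
  the only one connected to all others — pin the Freeman form; we choose
  in-degree as the default direction because nominations *received* are the
  unbounded, inequality-bearing quantity (out-degree is capped at five by
  the instrument). `mode = "out"` and `mode = "total"` are provided for
  sensitivity analyses, the total variant normalised by its own maximum
  $2(n-1)(n-2)$, attained by the mutual star;
* ego clustering = directed tie density among the ego's **out-neighbours**;
  egos with fewer than two alters are excluded from the school average
  because the density of an empty pair set is undefined. Ties are
  unweighted and nomination rank is ignored throughout.

Every metric is implemented directly from the edge table; `igraph` is used
only as a container/conversion layer, which lets it serve as an independent
cross-check in the test suite alongside brute-force enumeration oracles
(all random directed graphs with $n \le 15$, 200 seeds).

## The estimation layer

For each outcome we fit seven bivariate and one multivariate linear mixed
model with `lme4`: a random intercept per school, country as fixed-effect
dummies, and SES (FAS), age and sex as controls. Outcome, network terms and
controls are z-scored (sample SD, $n-1$) on each model's complete-case
estimation sample, so fixed effects are standardized betas; binary
covariates (sex, isolation) are z-scored like continuous ones, and
unstandardized scale information is retained in the result object. Models
use maximum likelihood, not REML, so that $-2\log L$ is comparable across
fixed-effect specifications. Wald 95% intervals and normal-approximation
p-values are reported — appropriate at cohort sizes in the thousands — with
stars at p < 0.01 (\*\*\*), < 0.05 (\*\*), < 0.1 (\*). A boundary fit
(school variance estimated at zero) is a warning, not an error. Variance
inflation factors come from auxiliary least-squares regressions of each
predictor on the others.

"School as a grouping factor nested in country" admits two readings; the
default treats country as fixed effects (it is also a control variable) and
school as random, and `nesting = "country_nested"` fits random intercepts
for country and school-within-country instead. The choice is recorded in
every result object.

## The synthetic cohort generator

The generator produces cohorts with the shape and first two moments of a
six-city, 48-school, two-grade classroom survey, together with the full
ground truth, so that the pipeline can be validated by parameter recovery.
Defaults (all overridable through `synth_config()`):

* 6 countries × 8 schools × 220 registered students in 2 grades × 5
  classes; participation Bernoulli(0.794); 51.9% female; integer ages
  centred on 15.24 (SD ≈ 1.0), clipped to 12–19.
* Out-degree of each participant drawn from a beta-binomial on 0–5 with
  mean 3.43 and SD 1.45 (shape parameters solved from these moments).
* Alter choice weighted by *friendship group* (random partitions of each
  class into groups of ~5, weight 2000), class (weight 2), and a lognormal
  "attractiveness" weight (σ = 1.45) that concentrates received
  nominations; a triadic-closure pass then rewires 10% of ties toward
  alters of the ego's other alters. Together these reproduce average ego
  clustering near 40%, in-degree SD near 2.25 and isolation near 1.4%
  (about 1% designated isolates, stratified per school, plus endogenous
  isolation).
* School connectedness climate Normal(3.05, 0.19) truncated at ±2 SD —
  truncation keeps every school's mean inside the published between-school
  range and away from the response floor of the bounded scales — plus
  student-level deviation (SD 0.5) and item noise (SD 0.6).
* Latent outcomes are linear in the **z-scored realized covariates** with
  planted standardized effects (burnout: popularity −0.07, centralization
  −0.07, clustering +0.03, connectedness −0.59; engagement: activity
  +0.03, popularity +0.03, density +0.04, connectedness +0.85), a small
  school random intercept (0.4% of score variance per outcome) and
  residuals sized so the observed scores hit mean/SD targets of 3.08/1.24
  (burnout) and 2.09/1.43 (engagement). Planting on realized covariates
  makes the pipeline's standardized betas directly comparable to the
  planted vector; the school-connectedness covariate is computed from the
  generated connectedness *items* exactly as the pipeline will compute it,
  so there is no errors-in-variables gap between truth and estimation.

### Ordinal items and the response grid

Items are parallel measures $x_{ij} = T_i + e_{ij}$ discretized to their
ordinal ranges by rounding. For a k-item scale with score-variance target
$V$ and latent inter-item correlation $\rho$, the true-score variance is
$s^2 = V k\rho/(k\rho + 1 - \rho)$ and the Gaussian item noise is
$w - 1/12$ with $w = s^2(1-\rho)/\rho$: the $1/12$ is the rounding
(quantization) variance, so $\rho$ — and hence $\alpha$ (0.76 for the three
engagement items, 0.62 for burnout items 1–2) — holds for the discretized
items. Clipping at the ends of the grid has no closed form; the generator
therefore (i) *pre-distorts* the latent mean through the inverse of the
item response function $g(t) = E[\mathrm{clip}(\mathrm{round}(t+e))]$, so
the expected observed score is exactly linear in the planted covariates
even near the floor of the engagement scale, and (ii) carries three small
grid-compensation constants (fitted once by large-n simulation and stored
in the source) that undo the residual effect of clipping on reliability and
slopes. The excluded third burnout item is generated deliberately
inconsistent with items 1–2 (loading 0.25), mimicking the reliability
failure that motivates its exclusion.

### The burnout–engagement correlation

A structural fact worth recording: with the two connectedness effects
planted at −0.59 and +0.85 on the *same* covariate, the scores' structural
covariance alone is about −0.50 standardized, while the reliability targets
cap the within-scale residual channels well below what would be needed to
lift the observed correlation to the target −0.32. No generating process in
which both scales' residuals are independent of the items can satisfy all
of these at once. The generator therefore allows **positively correlated
measurement noise across the two scales** — shared method variance, the
standard psychometric account for two scales answered in the same
questionnaire sitting — solved in closed form per run, followed by a small
deterministic tilt of the engagement latent along the realized burnout
score that pins the observed (discretized) correlation at the target
exactly. The solved parameters are part of `truth.json`.

### What the generator does *not* emulate

Schools are exchangeable: identical size and identical structural
parameters, so between-school variation in density, clustering and
centralization is sampling variation only and is smaller than in a real
multi-country survey where schools differ in size and cohesion (a real
survey's mean school density is also higher than ours for exactly that
reason — smaller schools have fewer possible ties). Mean realized
centralization (~6%) is somewhat above typical published values, the price
of matching the in-degree dispersion with lognormal weights. There is no
peer selection or influence dynamics, no non-response bias (participation
and item missingness are completely at random), no measurement
non-invariance across countries, and sex/age/SES have no planted effects.
Passing recovery tests on these cohorts therefore validates the pipeline's
arithmetic and estimation, not any causal claim about real students.

## Numerical and testing choices

* All randomness flows from one seed; identical (config, seed) give
  byte-identical CSV files.
* Degenerate inputs: schools with fewer than two students are rejected
  (density undefined); centralization requires $n \ge 3$; an edgeless
  school has density 0 and missing clustering; constant predictors are
  dropped from a model with a warning; a constant column is an error for
  standardization itself.
* The test suite validates every metric against brute-force enumeration and
  igraph on 200 random graphs, the scales against closed forms
  (Spearman–Brown), VIF against `car::vif`, the mixed models against OLS in
  the zero-variance limit and against simulation for variance-component
  recovery, and the whole pipeline by planted-effect recovery: on the
  default 48-school cohort every planted beta is recovered within ±0.05 in
  a single cohort and within ±0.02 in the mean over 100 cohorts (the small
  school-level intercept variance is what makes school-level effects
  estimable at 48 schools to this precision). Problem sizes in the suite —
  tiny four-school cohorts for unit tests, 20 cohorts for descriptive
  calibration, 100 for recovery — were chosen to keep the full suite around
  three to four minutes.
* Acceptance-style checks use the spec of the survey's published
  descriptives as calibration anchors (out-degree 3.43, in-degree SD 2.25,
  isolation 1.40%, clustering 40.17%, connectedness 3.04 with school means
  in [2.42, 3.45], burnout 3.08, engagement 2.09, α 0.76/0.62,
  r(burnout, engagement) −0.32), each within 10% relative or 0.03 absolute
  for correlations and reliabilities.
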