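# peerwell

Peer nomination networks and academic well-being in school cohorts.

`peerwell` is an R package for analysing **sociometric peer-nomination
surveys** of the kind run in multi-city school studies: every student
registered in a school's two surveyed grades is listed in a directory, and
each participant names up to five schoolmates they prefer to do schoolwork
with. The package takes the three raw tables such a survey produces — a
student roster, a bounded nomination edge list, and ordinal item responses —
and carries them through scale scoring, within-school network analysis and
standardized multilevel regression. It is aimed at social-epidemiology and
school-health researchers who want this pipeline reproducible and testable
end to end.

Because real survey microdata of this kind are rarely shareable, the package
also includes a **calibrated synthetic cohort generator with known ground
truth**, so every stage — cleaning rules, psychometrics, graph metrics,
mixed models — can be verified by parameter recovery instead of against an
inaccessible dataset.

## What it computes

**Ego-level network position** (on the full registered node set of each
school, non-respondents included):

* *social activity* — out-degree (0–5, capped by the instrument),
* *popularity* — in-degree (uncapped),
* *isolation* — no incoming and no outgoing ties; the percentage of
  isolates is reported over participating students.

**School-level network structure**, as percentages:

* *density* = 100·E / (n(n−1)) over ordered pairs;
* *Freeman degree centralization* = 100·Σᵢ(c_max − cᵢ) / (n−1)², on
  in-degree by default (0 for degree-regular networks, 100 for the in-star);
  out- and total-degree variants are available;
* *average ego clustering* — the mean over egos with ≥ 2 alters of
  100·(directed ties among the ego's out-neighbours)/(a(a−1));
* *school connectedness* — the school mean (range 1–4) of a five-item
  self-report climate scale.

**Scale scoring** with complete-case rules: schoolwork engagement (mean of
3 items on 0–5), school burnout (mean of items 1–2 of the short inventory
on 1–6; the exhaustion item is excluded for poor consistency),
connectedness (mean of 5 items on 1–4), family affluence (sum of 4 items),
plus Cronbach's α = (k/(k−1))(1 − Σs²ⱼ/s²_T) per scale.

**Inference**: Pearson correlation tables; bivariate and multivariate
linear mixed models of each outcome on the seven network terms with a
random intercept per school, country fixed effects and SES/age/sex
controls, fitted by maximum likelihood; outcome and predictors are z-scored
on the estimation sample, so coefficients are standardized betas with Wald
95% CIs; variance inflation factors from auxiliary regressions; −2
log-likelihood per model.

## Worked example

```r
library(peerwell)

cohort    <- generate_cohort(synth_config(seed = 1))
scores    <- score_scales(cohort$items, cohort$roster)
positions <- cohort_positions(cohort$roster, cohort$nominations)
summaries <- summarize_schools(cohort$roster, cohort$nominations, scores)
cohort
#> Synthetic school cohort: 10560 students in 48 schools (6 countries), 28316 nominations, seed 1
head(summaries, 3)
#>   school_id n_nodes density_pct centralization_pct clustering_pct pct_isolated mean_connectedness
#> 1      BE01     220        1.24               3.34           43.6        0.559               3.20
#> 2      BE02     220        1.17               6.17           37.3        1.765               3.37
#> 3      BE03     220        1.24               3.34           38.2        1.143               2.69
```

Each row is one school: 220 registered students, ~1.2% of all possible
directed ties realized, mild centralization, strong clustering (schoolmates
one wants to work with tend to pick each other), and a connectedness
climate between roughly 2.7 and 3.4 on the 1–4 scale.

```r
frame <- build_analysis_frame(cohort$roster, scores, positions, summaries)
fit_multilevel(frame, "burnout",
               c("activity", "popularity", "isolated", "density",
                 "centralization", "clustering", "connectedness"))
#> Multilevel model (multivariate, ML): burnout ~ activity + popularity + isolated + density +
#>   centralization + clustering + connectedness + fas + age + sex + country + (1 | school_id)
#>   n = 7975 students in 48 schools, -2LL = 18943.4
#>   activity        beta =  0.003  [-0.016,  0.021]
#>   popularity      beta = -0.074  [-0.092, -0.057] ***
#>   isolated        beta =  0.001  [-0.017,  0.020]
#>   density         beta = -0.012  [-0.037,  0.014]
#>   centralization  beta = -0.063  [-0.086, -0.039] ***
#>   clustering      beta =  0.022  [-0.002,  0.046] *
#>   connectedness   beta = -0.612  [-0.635, -0.589] ***
```

The betas are in SD units: one SD more school connectedness is associated
with 0.61 SD less school burnout; popular students report slightly less
burnout. Because this cohort is synthetic, the generator's ground truth
(`cohort$truth$planted`) says what the answers should have been
(popularity −0.07, centralization −0.07, clustering +0.03, connectedness
−0.59) — the fit recovers them.

`run_pipeline(config = synth_config(seed = 1), out_dir = "run1")` executes
the whole sequence (validate → score → network → correlations → 7 bivariate
+ 1 multivariate model per outcome → report tables) and writes every
artifact, including a planted-versus-recovered comparison, under `run1/`.
A thin command-line front end with `simulate | validate | score | network |
fit | run-all` subcommands is installed at
`inst/scripts/peerwell-cli.R`.

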