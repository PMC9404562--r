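---
title: "Methods: the succinate-consumer screen and cohort statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the succinate-consumer screen and cohort statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(succscreen)
```

This vignette is the package's account of its methods: the models it
solves, the screening protocol, the statistical machinery of the clinical
arm, what the synthetic generators emulate, and the numerical and design
choices that were genuinely open.

## Constraint-based growth model

An organism is a `metabolic_model`: metabolites with compartments, reactions
with a stoichiometry map and finite flux bounds (mmol/gDW/h), one biomass
reaction carrying the objective, and a set of exchange reactions. Exchange
reactions follow the community sign convention — exactly one extracellular
metabolite with coefficient $-1$, so negative flux is uptake and positive
flux is secretion. This convention is *asserted at load*, not configurable,
because every downstream phenotype classification depends on it.

Flux balance analysis maximizes biomass production $c^\top v$ over the flux
polytope $\{v : Sv = 0,\ lb \le v \le ub\}$. The solver is a dense
two-phase full-tableau primal simplex written for this package, using
Bland's anti-cycling rule, a pivot tolerance of $10^{-9}$, and a post-hoc
feasibility verification at $10^{-6}$ (`solve_fba()` refuses to return a
vector violating mass balance or bounds). Bland's rule costs a few extra
pivots but makes every solve deterministic and finite — repeated runs are
bit-identical, which the batch screen relies on. All model bounds are
required finite (the conventional $\pm 1000$ cap), so programs are always
bounded; an unbounded status can therefore only signal a malformed model
and is surfaced as an error, never clamped.

The FBA optimum is generally degenerate: many flux vectors achieve maximal
growth, and "the" succinate flux of an optimal solution is not well
defined. The package therefore reports, per condition, the
*flux-variability interval* of the succinate exchange — its minimum and
maximum over all flux vectors reaching at least a fraction (default 0.999)
of optimal growth — and offers parsimonious FBA (minimize $\sum_i |v_i|$
at fixed optimal growth, via flux splitting $v = p - q$) when a canonical
single vector is wanted. Classifying from an interval rather than from an
arbitrary solver vertex is what makes the screen's labels independent of
pivot order.

## The nutrient-limitation screen

A `medium_condition` maps exchange ids to maximum uptake magnitudes; applying
it sets each listed exchange's lower bound to $-\text{cap}$, all unlisted
exchanges to $0$ (absent), and never touches upper bounds — secretion of
waste products must not be blocked by medium choice. Oxygen is a separate
axis: its bound is controlled solely by the medium's aerobic flag
(cap when aerobic, $0$ when anaerobic), never by the nutrient iteration.

The screen (`single_nonlimiting_screen()`) first determines the *usable
nutrients*: all non-oxygen exchanges except those that can never run
negative while the organism grows (minimum exchange flux $\ge 0$ subject to
growth $\ge$ `growth_epsilon` under an all-open medium). The all-open probe
is run aerobically with every cap at `nonlimiting_uptake` — the most
permissive condition, so no aerobically-usable nutrient is missed. Then,
for each usable nutrient $n$ and each oxygen state, one condition is built:
$n$ at cap 1000 (`nonlimiting_uptake`), every other usable nutrient at cap
10 (`limiting_uptake`), everything else absent. The limiting magnitude 10
is the protocol's operative constant; the non-limiting cap is only bounded
below by the protocol ("more than 20"), so the default 1000 makes it
effectively unconstrained, and a test verifies the consumer labels do not
flip between caps 20 and 1000. When aerobic, the oxygen cap equals the
limiting cap — oxygen availability should not be the growth-dominating
nutrient of a condition. Succinate is iterated like any other nutrient; the
succinate-non-limiting condition is in fact the decisive one for consumer
phenotypes.

Each condition is labeled from growth $\mu$ and the succinate interval
$[s^-, s^+]$ with `flux_epsilon` $\varepsilon = 10^{-6}$:

| label        | rule                                              |
|--------------|---------------------------------------------------|
| no_growth    | $\mu <$ `growth_epsilon`                          |
| consumer     | $s^+ < -\varepsilon$ (uptake is obligatory)       |
| producer     | $s^- > +\varepsilon$ (secretion is obligatory)    |
| facultative  | $s^- < -\varepsilon \le s^+$                      |
| neutral      | otherwise                                         |

The rules partition every input (a property test checks totality and
exclusivity). The species verdict aggregates records: `clear_consumer`
requires a consumer label in at least `clear_consumer_fraction` (default
0.8) of growth-supporting conditions *and* a consumer/facultative gut
record. "Almost all conditions" has no canonical number; 0.8 is an explicit
knob, not a claim about any particular study's cutoff. No-growth conditions
are excluded from the denominator — a species cannot consume while dead.

The gut simulation applies a western-diet medium anaerobically (a warning
is issued if the medium claims otherwise). A diet is defined over a
universal exchange namespace; nutrients the model cannot exchange are
dropped before application, whereas `apply_medium()` itself is strict about
unknown ids — the loose behavior is deliberate and local to the gut step.
The shipped `western_diet_demo.tsv` lists 12 carbon sources (succinate
included) at cap 10, anaerobic.

## Toy organisms with closed-form phenotypes

The generator builds three archetypes around a single abstract energy
currency (one metabolite standing in for ATP/NADH bookkeeping), which keeps
every program hand-solvable while still coupling growth to exchange:

* **Consumer**: succinate $\to$ propionate $+\ y\,$energy, propionate
  secretion-only, biomass consumes energy — emulating the
  succinate-to-propionate cross-feeding metabolism of known gut succinate
  consumers. Decoy nutrients feed energy at yields drawn uniformly from
  $[0.1, 1] \times y$ — strictly poorer substrates. That relative draw is
  what guarantees the closed form: with the decoy non-limiting, reaching
  $99.9\,\%$ of optimal growth still requires succinate uptake of at least
  $9.99 - y_d/y > 8.99$, so every growth-supporting condition is a
  consumer record and the verdict is `clear_consumer` for *any* draw. With
  succinate non-limiting, uptake saturates the cap exactly
  ($s^- = -1000$).
* **Producer**: glucose $\to y_s\,$succinate $+\ y_e\,$energy, so secretion
  is stoichiometrically coupled to growth ($s = y_s \cdot$ glucose uptake);
  with glucose non-limiting and the full-optimum interval, the secretion
  interval is the point $[1000\,y_s, 1000\,y_s]$.
* **Inert**: a succinate exchange exists but no reaction touches its
  metabolite, so mass balance forces zero flux — every interval is
  $[0, 0]$.

`make_suite()` draws primary yields uniformly from $[0.1, 1]$ and decoy
counts from $0$–$3$, fully seeded. These toys emulate growth-coupled
uptake/secretion and nutrient choice; they do *not* emulate genome-scale
network redundancy, maintenance costs, thermodynamics, or cross-feeding
between organisms — so a perfect screen score on the suite demonstrates the
protocol's correctness, not predictive accuracy on real reconstructions.

## Candidate funnel

Marker-gene hits (scpC, cat1, sdh, ach) are thresholded with strict
inequalities — identity $> 80$, e-value $< 10^{-5}$ — and the two
statistics must pass *on the same hit*: a hit is one alignment, so its
identity and e-value are not separable across hits. Any of the four genes
qualifies a strain. Annotation filtering retains human-gut residents
without known pathogenic activity whose assemblies are available; the
recorded exclusion reason is the first failing check in the fixed order
not_gut, pathogen, no_assembly. The packaged synthetic fixture is built so
that 89 of 120 strains pass the thresholds and 22 survive annotation — the
funnel *shape* of the discovery setting this package emulates, with
entirely synthetic strains.

## Cohort statistics

`kendall_tau_b()` computes $\tau_b$ by explicit pair counting with tie
corrections in both margins. Its p-value uses the tie-adjusted normal
approximation of the concordance statistic $S$ for $n > 8$, and exact
enumeration of the permutation distribution (conditional on both tie
patterns) for $n \le 8$, where the normal approximation is poor; both are
two-sided. The exact path matches the reference exact distribution on
untied data, and the normal path matches the reference tie-corrected
approximation to $10^{-10}$.

`dirichlet_clr()` propagates count uncertainty in compositional taxa data:
each instance draws every subject's composition from
Dirichlet(counts $+\ 0.5$) and centers the log abundances per subject. The
$0.5$ pseudo-count is the common Jeffreys-style choice and is exposed as a
parameter. The default 128 instances are summarized per taxon by the
*median* tau and median p across instances — a robust, documented
aggregation choice (the instance design itself does not dictate one).

`mvalue_regression()` is ordinary least squares reported in the
conventional clinical layout: unstandardized B, SE, 95 % CI from the t
quantile, standardized Beta $= B\,\mathrm{sd}(x)/\mathrm{sd}(y)$,
per-predictor p, multiple R and $R^2$. Rank-deficient designs fail with
the collinear columns named. `fit_mvalue_model()` chains the standard
two-stage procedure: univariate screening at p $< 0.05$ (threshold
configurable; the convention is assumed, not prescribed), then the
multivariable fit on the survivors. No multiple-testing correction is
applied by default, mirroring common clinical reporting; `p.adjust` can be
applied downstream by the user.

## The synthetic cohort

`simulate_cohort()` draws standard-normal scores, couples plasma and fecal
succinate through a Gaussian copula with correlation
$\rho = \sin(\pi\tau/2)$ — the exact Kendall-to-Pearson conversion for
elliptical copulas, so the *rank* association is targeted directly and is
invariant to the marginal transforms — and maps margins to the reference
summaries (normal, or log-normal for nonnegative right-skewed labs such as
insulin, triglycerides and the succinate concentrations). The M-value is
generated as
$M = 29.984 - 0.071\,\text{plasma} - 3.377\,\text{HbA1c} + \epsilon$.

Defaults were fixed once, from the reference cohort's published report,
before any testing: the coefficients and intercept are the published ones;
plasma succinate marginals (mean 97, SD 16.4 µM) are back-derived so the
published standardized coefficient ($-0.444$) and M-value mean (4.64) are
jointly consistent (Table-style summaries do not report succinate itself);
fecal succinate (mean 25, SD 12 µg/g) is set from the murine fecal range
since no human summary exists. The residual SD is 1.6: the
published-fit-implied value ($\approx 1.8$) puts the power to detect the
succinate coefficient at $n = 25$ near 0.8, and the generator is meant to
be a comfortably powered synthetic setting, so the default is chosen for
$\approx 0.9$ power (two-sided $t$, df 22) rather than borderline. The
generated M-value SD consequently runs slightly above the published 2.62 —
the generator reproduces the published *model*, not every marginal
simultaneously (they are not mutually consistent under independent
predictors).

Taxa counts use a rank-abundance log-linear baseline with per-subject
log-normal noise (SD 0.5, overdispersion), multinomial sampling at
negative-binomial depths (mean 20 000, size 10, floor 1000), and one taxon
whose log abundance rises by 0.8 per SD of M-value — large enough for the
median-tau association to recover its sign reliably at $n = 25$.

## Numerical choices and degenerate inputs

* LP: pivot tolerance $10^{-9}$; post-hoc verification $10^{-6}$; phase-1
  residual above $10^{-7}$ reports infeasibility.
* Vertex-enumeration oracle (tests only): fixes $n - \mathrm{rank}(S)$
  variables at bounds, solves the rest exactly, tolerance $10^{-8}$.
* `flux_epsilon` and `growth_epsilon` default to $10^{-6}$ — three orders
  above solver noise, three below any real flux in the toys.
* Constant vectors are an error in `kendall_tau_b()` (the tie-corrected
  denominator vanishes). All-zero count rows are an error in
  `dirichlet_clr()` with the subject named.
* Empty medium, empty screen records, missing succinate annotation, and
  unknown medium ids all fail loudly with instructive messages.

## Problem sizes in the shipped tests

The test and acceptance runs use sizes chosen to exercise every property
at desk scale: 200 random models (up to 8 reactions) for the LP oracle,
150 generated organisms (10 per archetype over 5 seeds) for ground-truth
recovery, 500 cohort replicates for copula calibration, 200 replicates for
power, and a 10 000-subject cohort for consistency checks. The full suite
runs in about a minute on one CPU.

## Known limitations

* Single-organism FBA only: no community simulation, so cross-feeding —
  central to succinate ecology — is outside the model, by design.
* The JSON dialect covers stoichiometry, bounds and one objective; no
  gene–protein–reaction rules, no SBML.
* Verdict thresholds (`clear_consumer_fraction`, `fva_fraction`) are
  conventions exposed as parameters; conclusions about borderline species
  can shift with them.
* The cohort generator's covariates are mutually independent apart from
  the modeled links; real clinical covariates are not.
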