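---
title: "Detecting post-reproductive lifespans from ovarian corpora counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting post-reproductive lifespans from ovarian corpora counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(physprr)
```

## The problem

In most mammals the reproductive system ages at the same pace as the rest
of the body and females reproduce until death. A handful of species —
humans and several toothed whales among them — instead show *accelerated*
reproductive senescence: ovarian activity ceases well before the end of
life, and a substantial fraction of adult female-years are lived by
post-reproductive females. Demonstrating this in wild cetaceans is hard
because it requires age-specific fecundity *and* survival, which long-term
observational studies rarely provide.

`physprr` implements a physiological route around that problem. Each
ovulation leaves a permanent scar (a corpus luteum that regresses to a
corpus albicans) in the ovary, so the cumulative corpora count of a dead
female, paired with an independent age estimate (dentinal growth layers),
records her ovulation history. Cross-sectional samples of dead females —
strandings, by-catch, drive hunts — then carry enough information to
estimate both age-specific ovarian activity and survivorship, and from
them the population-level prevalence of post-reproductive life.

## The model, stage by stage

### Ovarian activity from corpora counts

Records are first restricted to ages from the **age of first ovulation**
(the smallest age with a non-zero corpora count; zero-count records at
exactly that age are kept, because they inform the intercept — the source
tables do not say how such records were treated, so this is our choice).

`corpora_fit()` fits two ordinary least squares models to corpora count
$C$ versus age $x$:

$$C = \beta_0 + \beta_1 x \quad\text{and}\quad
  C = \beta_0 + \beta_1 x + \beta_2 x^2 ,$$

and selects between them by AIC under the Gaussian likelihood. The linear
model is the null (constant ovulation rate); AIC ties resolve to it. If
the selected model leaves adjusted $R^2 \le 0.1$ the species is classified
`none`: corpora do not measure ovarian activity there, and no further
analysis is done. Note that AIC's two-unit penalty accepts a spurious
quadratic with probability $P(\chi^2_1 > 2) \approx 0.16$ under the linear
null, so on truly linear data the quadratic classification is a
recognised false-positive mode — about one species in six — rather than a
defect of the implementation.

**Ovarian activity** is the derivative of the fitted curve,
$m(x) = \max(0,\, \beta_1 + 2\beta_2 x)$: the instantaneous rate of new
corpora formation, used as the physiological proxy for age-specific
fecundity. Negative values are an artefact of the quadratic form and are
clipped to zero.

### The relative rate of reproductive senescence

To compare reproductive against somatic ageing across species, activity is
normalised to 1 at the age of first ovulation $a_B$ and age to the unit
interval over the observed adult span $[a_B, a_{\max}]$. The statistic is
the magnitude of the normalised activity slope,

$$\rho = \frac{2\,|\beta_2|\,(a_{\max} - a_B)}{m(a_B)} .$$

$\rho = 1$ means activity declines linearly to zero exactly at the oldest
observed age; $\rho > 1$ means ovarian activity ceases *before* the end of
life — reproductive senescence outpacing somatic senescence. Because
activity under the quadratic model declines linearly, normalising by its
value at $a_B$ or by its maximum are identical for declining fits; we fix
the $a_B$ convention. $\rho$ is invariant to rescaling of the corpora
counts.

### Survivorship from a standing age sample

A cross-sectional sample of dead females approximates the standing age
distribution $c(x)$. In a stationary population $c(x) \propto l(x)$;
sampling noise, however, makes raw per-age counts non-monotone, so
`build_cohorts()` first constructs **variable-width age cohorts** scanning
from the oldest individual: the oldest bin holds only the female(s) at the
maximum age (ages cannot be split, so ties stay together), and each
younger bin is extended a whole year at a time until it holds *strictly
more* females than the previously formed bin ("more than one whale" is
read as strictly greater than the older neighbour's count). If the
youngest bin cannot exceed its neighbour its count is raised to match —
never lowering the neighbour, which keeps the construction conservative
about late-life survival. Ages are floored to whole years, the resolution
of the source tables.

Survivorship is then read off the cohorts with the decline **spread evenly
through the ages represented in each cohort**: the cohort's count anchors
survival at its youngest age and interpolates linearly to the next older
cohort's anchor. We considered the alternative literal reading — dividing
each cohort's count equally over its ages as a flat per-age density — but
that produces non-monotone survivorship whenever a narrow old bin follows
a wide sparse one (a single oldest female after a multi-year bin, which is
the rule, not the exception, in sparse-tailed samples), defeating the
monotonicity the binning exists to guarantee; the even-decline reading
preserves it by construction. For width-one bins the two readings
coincide.

Population growth tilts a standing age distribution relative to
survivorship: $c(x) \propto l(x) e^{-rx}$. `survival_from_cohorts()`
therefore applies the stable-population correction

$$l(x) \propto \hat c_x\, e^{r x}, \qquad l(B) = 1 ,$$

for a growth scenario $r$, and refuses any $r$ that would make $l$
increase with age. Three scenarios bracket the unknown true growth rate:
shrinking ($r = -0.1$/yr, a population losing 10% a year), stable
($r = 0$), and growing ($r = r_{\max}$, the largest rate the age structure
supports, capped at $+0.1$/yr — `max_feasible_growth()` computes it as the
minimum over adjacent ages of $\ln(\hat c_x / \hat c_{x+1})$, floored at
zero). These bounds bracket observed cetacean population trends.

### Post-reproductive representation

Let $T(x)$ be the expected female-years lived above age $x$ per female
reaching adulthood, computed from $l$ with deaths spread uniformly within
each year of age (trapezoidal person-years; survivors at the final table
age are taken to die there, again conservative). With

* **age B** — entry into the adult population, the first age in the
  truncated data, and
* **age M** — the age by which 95% of total fecundity
  $\int m(x)\,dx$ has been completed (`age_m()` integrates the piecewise
  linear schedule exactly and inverts the quadratic segment containing the
  crossing, so no grid refinement is needed),

the **physiological post-reproductive representation** is

$$\text{Phys-PrR} = \frac{T(M)}{T(B)} \in [0, 1],$$

the proportion of adult female-years lived after reproductive cessation.
$T(M)/T(B)$ is the standard life-table form of post-reproductive
representation and is what we implement. $M$ is computed from the fecundity schedule alone, so it is
shared across growth scenarios, while $T$ changes with $r$; PrR is
consequently non-decreasing in $r$.

### Significance

Sampling noise alone produces non-zero PrR. `prr_significance()` simulates
the null of *reproductive senescence equal to somatic senescence*:
fecundity proportional to survivorship, $m_0(x) \propto l(x)$, under which
any apparent post-reproductive window is artefactual. Each of $n_{pops}$
(default 1000) null populations draws $n_{ind}$ (default 1000) individual
ages from the standing-age law the estimator itself assumes,
$c(x) \propto l(x)e^{-rx}$, rebuilds a life table with the *full* cohort
pipeline — so binning noise is inside the null — and evaluates PrR at the
null's own age $M_0$. The upper tail uses an add-one pseudocount,
$p^+ = (1 + \#\{PrR_0 \ge PrR_{obs}\})/(n_{pops}+1)$, avoiding $p = 0$
from finite simulation, and the reported two-tailed $p$ doubles the
smaller tail. One could instead draw null ages from the cohort death
distribution implied by $l$; we sample the standing law because it is the
generative assumption of the estimator itself, making the test exactly
calibrated (the measured upper-tail type-I error at
$\alpha = 0.05$ over 400 null replicates is computed by the test suite and
`scripts/acceptance.R`). A species is concluded to have post-reproductive
lifespans only when the stable-scenario test is significant *and* the
upper tail is the small one — a significantly *low* PrR must not trigger
the label.

### Ancestral-state reconstruction

Presence/absence of post-reproductive lifespans across species is modelled
as a two-state continuous-time Markov chain with a single rate $q$ in both
directions (equal-rates model), whose transition probabilities are
$P(\text{stay}) = (1 + e^{-2qt})/2$. `er_loglik()` computes the exact tree
likelihood by post-order pruning (with partial-likelihood rescaling);
`fit_er_rate()` maximises it on the log-rate scale over
$[10^{-8}, 100/\text{tree height}]$, flagging boundary solutions (which
arise whenever all tips share a state); `ancestral_marginals()` combines
downward and upward partial likelihoods into per-node marginal
("proportional") probabilities. The root prior is uniform — the stationary
distribution of the symmetric chain. Polytomies are handled natively by
the pruning product. Newick input is parsed by `ape`; the likelihood,
optimisation and marginals are this package's own, and the test suite
cross-checks them against both brute-force state enumeration and
`ape::ace`.

## The synthetic-data generator

No corpora tables ship with the package, so `simulate_species()` generates
cross-sectional datasets with known truth. Each simulated female's
observed age is drawn from the standing distribution
$l(x)e^{-rx}$ implied by a survival model (fixed age at death, or a
per-year death-probability schedule) on whole-year ages; her corpora count
is Poisson with mean $\int_{maturity}^{age} \lambda$, the integral of a
piecewise-linear ovulation-rate function $\lambda(x) \ge 0$ — Poisson
being the minimal noise model for a counting process. Optional pregnancy
flags are Bernoulli with probability proportional to current $\lambda$,
so pregnancy and ovulation cease together; optional Gaussian age error
(redrawn below the minimum observed age) re-creates the age-estimation
robustness check, with the error magnitude exposed as a parameter since
the source does not print one.

The reference study condition used throughout the tests and the acceptance
script is a population with maturity at 5 yr, ovulation declining linearly
from 1/yr at maturity to zero at age 20 — half the adult span — and
survival to $\omega = 35$ yr: the canonical "cessation at half the adult
lifespan with long post-cessation survival" archetype. Sample sizes follow
the analysis defaults (500–2000 females, 1000 × 1000 significance
simulations; the calibration study uses 400 replicates of 200 populations,
sizes chosen to make Monte-Carlo error small relative to the tolerances
being checked).

What the generator does *not* emulate: corpora regression or
poly-ovulation (assumed age-independent and hence harmless to the method),
hunting selectivity on age, age heaping, or multi-population mixtures.
Passing recovery tests on synthetic data therefore shows the pipeline's
internal consistency under its own assumptions, not robustness to those
real-data complications.

## Numerical choices

* AIC ties (|ΔAIC| < 1e−9) go to the linear null.
* The activity grid includes the clipping kink as a node, so schedules are
  exactly piecewise linear and `age_m()` is exact.
* Survivorship feasibility is checked with a 1e−10 tolerance and tiny
  floating-point jitter is removed with a running minimum.
* The rate optimiser compares the interior optimum against both interval
  endpoints; near-flat likelihood ridges (common on small trees) make the
  arg-max ill-conditioned even though the maximum value is sharp, which is
  why the tests compare likelihoods, not rates, against a dense grid.
* Sub-seeds for pipeline stages are derived deterministically from the
  master seed and the stage name, so stages can be re-run independently.

## Known limitations

* **Attenuation of $\rho$ and $M$.** The population-level truth "activity
  reaches zero at age $x_0$" makes the *cumulative* corpora curve
  quadratic up to $x_0$ and flat beyond. An OLS parabola fitted across the
  whole adult span cannot reproduce that kink: its vertex lands
  systematically beyond $x_0$, so $\rho$ is biased towards 1 and $M$
  upward whenever cessation occurs well before the oldest age and data
  exist beyond it. The recovery analyses in the test suite and
  `scripts/acceptance.R` measure this directly on the half-span archetype:
  the median fitted $\rho$ sits near 1.5 where the generator truth is 2,
  and stable-scenario PrR is correspondingly underestimated. The bias is
  intrinsic to the quadratic-fit estimator, shrinks as cessation
  approaches the end of life (the vertex-recovery test, where deaths occur
  at cessation, is unbiased), and is conservative: it understates, never
  overstates, post-reproductive life.
* **Late-life survival is underestimated** by construction (smoothing only
  raises young bins, terminal survivors die at the oldest observed age,
  rare old ages are under-sampled), again conservative for PrR.
* Corpora measure *physiological* capacity, not realised reproduction;
  females may stop breeding before ovulation ceases, so Phys-PrR is a
  lower bound on observational PrR.
* The growing scenario depends on the age structure through
  $r_{\max}$ and can collapse to the stable scenario when the standing
  counts are locally flat.
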