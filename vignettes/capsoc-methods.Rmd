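---
title: "Methods: dyadic social integration and female survival"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dyadic social integration and female survival}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

In long-lived group-living mammals, a recurring question is whether more
socially integrated individuals survive longer. Answering it from field
data raises two linked statistical problems. First, individuals are
observed unevenly -- some are followed hundreds of times a year, others a
handful -- so any raw interaction rate confounds sociality with
observation effort, and a point estimate hides very different amounts of
uncertainty. Second, survival must be modeled on annual, time-varying
covariates (age, dominance rank, group size, and the sociality measure
itself) while carrying the first problem's uncertainty forward rather
than discarding it.

`capsoc` implements a two-stage pipeline for this design, built around
adult females in multi-group populations such as white-faced capuchins:

1. **Aggregation + Social Relations Model (SRM).** Behavioral event
   streams are reduced to annual dyadic *count / opportunity* tables for
   five interaction measures -- grooming giving, grooming receiving,
   coalitionary-support giving and receiving, and undirected foraging
   proximity -- against three partner datasets (all group members, adult
   females only, adult males only). A multilevel binomial SRM then yields,
   for every female-year, a zero-centered logit-scale *integration offset*
   with a posterior mean and SD.
2. **Accelerated failure time (AFT) survival model.** Annual
   adult-female survival is regressed on one integration measure at a
   time, with the offset entering as a latent covariate whose prior is the
   stage-one posterior -- so poorly observed females contribute weak
   information instead of biased certainty.

## Stage one: from events to dyad-years

The aggregation rules are deliberately mechanical; each has a
corresponding naive loop implementation in the test suite that the
vectorised builders must match exactly on randomized toy streams.

* **Grooming** is scored within 10-minute focal follows. For an ordered
  dyad (i, j) in a calendar year, opportunities are the follows of i plus
  the follows of j at times when both were co-resident (same group at the
  follow's start date); the count is the number of those follows in which
  i groomed j at least once. Scoring grooming dichotomously per follow
  makes the binomial denominator exact.
* **Coalitionary support.** The aggression stream is segmented per group
  into 5-minute windows anchored at the first event of each burst (a new
  window opens at the first event at least 5 minutes after the current
  anchor). Anchoring at events rather than at clock boundaries makes the
  segmentation invariant to clock offset; that choice is a package
  decision where field protocols differ. Within a window, i joins j if i
  aggressed j's opponent or j's victim; no within-window ordering is
  required, which makes two individuals who attack the same target mutual
  joiners. Joining is dichotomous per window. Everyone co-resident during
  a conflict had the opportunity to join either side, so opportunities for
  (i, j) count the windows where j was a participant and i was
  co-resident.
* **Foraging proximity** is undirected. Group scans in the foraging
  context qualify for a dyad when one member is the scan subject and the
  other co-resident; qualifying scans are thinned per dyad (greedy from
  the earliest) so retained scans are at least 10 minutes apart, and the
  count is the number of retained scans in which the partner was within 5
  body lengths (about 1 m). A missing neighbor distance is treated as
  beyond the threshold, with a warning.

The subject side of every dataset is adult females (age at least 5
years); adulthood and the partner-type restriction are evaluated at the
event's date, so a female entering adulthood mid-study contributes from
that moment on. Partner datasets are always rebuilt from the raw event
base rather than by subsetting aggregated rows. A dyad-year row exists
only when opportunities are positive.

## Stage one: the Social Relations Model

For one behavior and partner dataset, with counts $y_{ijt}$ and
opportunities $n_{ijt}$:

$$y_{ijt} \sim \mathrm{Binomial}(n_{ijt}, p_{ijt}), \qquad
\operatorname{logit} p_{ijt} = \alpha + y_t + g_{it} + r_{jt}$$

for directed behaviors, and $\alpha + y_t + s_{it} + s_{jt}$ for
undirected foraging. The offsets $g$ (giving), $r$ (receiving) and $s$
are independent Normal$(0, \sigma)$ families per individual-year, with
half-Normal(1) priors on each $\sigma$ and Normal(0, 2.5) on $\alpha$;
year offsets $y_t$ are a zero-centered random family (omitted when the
table spans a single year, where they are unidentifiable from the
intercept). The supplementary details of the original field analysis are
not public, so this is the minimal structure that supports the pipeline's
stated outputs -- per-female-year offsets with honest uncertainty; dyad-
level effects and giving-receiving correlations are deliberately left
out of the default model.

Sampling runs on JAGS via `rjags`, with two or more chains and
reproducible chain RNGs derived from one seed. Convergence is summarised
by split-$\hat R$ computed in-package (vectorised over the thousands of
offset nodes, where generic diagnostics are impractically slow) with a
1.05 flag threshold, plus effective sample sizes from `coda`. Posterior
means shrink toward zero for sparsely observed individuals and posterior
SDs grow -- the two properties the survival stage depends on, and both
are asserted by tests.

## Stage two: the survival model

Each adult female-year contributes a Bernoulli death indicator with

$$p_{it} = 1 - \exp\{-\Delta\, e^{-\eta_{it}}\}, \qquad
\eta_{it} = \mu + \beta_s s^*_{it} + \beta_a \mathrm{age}_{it} +
\beta_r \mathrm{rank}_{it} + \beta_g \mathrm{gs}_{it} + u_i + v_{g(i)}$$

with $\Delta = 365.25$ days. This is a piecewise-exponential AFT on a
log-days timescale: $e^{\eta}$ is an expected remaining lifetime in
days, so positive coefficients lengthen life, and the intercept sits near
$\log$(lifetime in days) $\approx 9.5$. The parametric family is the
simplest one consistent with annual time-varying covariates and that
coefficient scale; deaths are assigned a full year's exposure. Age enters
only linearly (adult mortality in this kind of population is
approximately linear in age on this scale).

Covariates are standardized over the analysis rows (mean 0, SD 1), and
the integration SD is divided by the same scale as the integration mean
so the mean-plus-or-minus-SD interval survives the transformation; the
scaling record is retained for back-transforming predictions. The
integration covariate is latent: $s^*_{it} \sim
\mathrm{Normal}(\hat m_{it}, \hat s_{it})$ with the stage-one posterior
mean and SD. Inflating every $\hat s_{it}$ must widen the posterior of
$\beta_s$ -- that contract is an acceptance test. Priors: Normal(9.5, 2)
on $\mu$, Normal(0, 1) on slopes, half-Normal(1) on the random-intercept
SDs; 89% central credible intervals are reported throughout, and
prediction curves evaluate the annual death probability over the
integration range with other covariates at their means and random
intercepts at zero.

The full battery fits one model per measure and partner dataset (five
measures, three datasets) under one shared configuration, continuing
past flagged fits and recording them in the manifest. A lag-1 variant
pairs survival in year $t$ with integration in year $t-1$, dropping each
female's first observed year.

## The synthetic study generator

Because the motivating field data are not deposited, the package
validates itself by parameter recovery on synthetic studies whose ground
truth is known. The generator emulates: multiple social groups; per-
individual persistent latent propensities on the logit scale (giving and
receiving per directed behavior, one undirected foraging propensity)
plus small annual jitter, so lag-0 and lag-1 analyses are both
exercisable; focal follows, conflict bursts and group scans drawn from
logistic models in those propensities with realistic opportunity
denominators; male migration with replacement; rank as a persistent
per-female uniform quantile, re-ranked to [0, 1] within group-years
among survivors; annual group size as a monthly census mean with small
observation noise; and annual survival drawn from the same AFT likelihood
the package fits, driven by the *true* grooming-giving propensity (never
by its estimates). Group composition varies naturally because male and
immature counts are Poisson around their configured means; female counts
are exact. Membership is truncated at each death before events are
generated.

Default conditions are a 10-group, 15-year study with 8 adult females, 4
males and 6 immatures per group, observation densities about one fifth
of a high-intensity field site (7 follows per individual-year, 64
conflict intervals and 417 scans per group-year; a `paper_scale` preset
multiplies by 5), baseline logits of -4 (grooming), -3.5 (support) and
-2 (foraging), giving/receiving SDs of 1.0/0.5 (grooming) and 0.8/0.5
(support), an undirected SD of 0.8, survival truth $\mu = 9.46$,
$\beta_s = 0.5$, $\beta_a = -0.5$, $\beta_r = -0.25$, $\beta_g = 0.25$
and random-intercept SDs of 0.3. These sizes produce roughly 1 200
female-years and 60-70 deaths -- the same order as a real two-decade
study -- while keeping a desk-scale runtime. The generator applies its
survival coefficients on fixed internal scalings (age centered at 15
with scale 7; rank at 0.5 with scale 0.29; group size at the configured
expected size with scale 2; sociality by its own generative SD) so the
sequential year-by-year process is well defined; the analysis stage
standardizes empirically, so recovered coefficients match the truth up
to the small ratio between empirical and generative scales.

What the generator does *not* emulate -- and hence what passing recovery
tests cannot certify about real data -- includes fission-fusion and
dispersal dynamics beyond male migration, kinship structure, observer
bias correlated with sociality, births during the study, male or
immature mortality, and rank dynamics. The generator's measurement
stand-in for SRM output (truth plus Normal noise of SD 0.3) is labelled
synthetic and used only to test the survival stage in isolation.

## Numerical choices and degenerate inputs

* All randomness is seeded; pipeline stages derive their seeds from one
  master seed by a fixed documented rule (`derive_seed()`), so reruns are
  byte-identical.
* Split-$\hat R$ uses the classic split-chain variance-ratio form;
  constant chains report 1.
* Measurement SDs are floored at $10^{-6}$ before being turned into JAGS
  precisions, so an exactly-zero SD degenerates gracefully to a fixed
  covariate.
* Zero-variance covariates, duplicated female-years and unknown
  individual ids abort with classed errors; grooming events outside any
  follow, third-party grooming records and missing scan distances warn
  and are skipped.
* Undirected dyads are stored once in lexicographic order; ties in the
  foraging thinning are broken by scan order after a stable time sort.
* Test and example runs use deliberately reduced problem sizes (2-6
  groups, 3-8 years, hundreds of MCMC draws) chosen to exercise every
  code path at desk scale; the recovery checks that need power use the
  default study above with longer chains.

## Known limitations

The SRM's random-effect structure is the minimal one (no dyad effects,
no within-individual giving-receiving correlation by default); the AFT
family is fixed rather than estimated; death-year exposure is a full
year; and the two stages are fit sequentially, so stage-one uncertainty
propagates through the latent covariate but stage-two information never
flows back into the integration estimates.
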