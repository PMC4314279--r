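---
title: "A two-locus model of pollinator-mediated divergence in Ophrys orchids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-locus model of pollinator-mediated divergence in Ophrys orchids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ophrysim)
library(dplyr)
```

## The biological system and the model

The sexually deceptive orchids *Ophrys sphegodes* and *O. exaltata* are
pollinated by male bees that the flowers lure by mimicking female sex
pheromones — cuticular hydrocarbon blends dominated by alkenes. The two
species differ in alkene double-bond position: *O. sphegodes* produces mostly
9- and 12-alkenes and attracts *Andrena nigroaenea*; *O. exaltata* produces
7-alkenes and attracts *Colletes cunicularius*. Because each bee is repelled
by the other species' alkene classes, this single chemical axis doubles as
the premating reproductive barrier. Biosynthetically the axis is controlled
by two stearoyl–ACP desaturase genes: functional *SAD2* alleles ("+") drive
9-/12-alkene production, functional *SAD5* alleles drive 7-alkenes, and a
hypothesized *trans*-acting dominant suppressor (*SUS*) segregating in
*O. sphegodes* can silence *SAD5* expression entirely.

`ophrysim` implements this system as a four-step pipeline:

1. **Expression to scent.** Linear models of `ln(amount + 1)` of each alkene
   class on `sqrt`-transformed allelic expression of *SAD2A* and *SAD5A*,
   with AIC term selection over the candidate set {`sqrt(X2)`, `sqrt(X5)`,
   `sqrt(X2)·sqrt(X5)`} (`fit_alkene_models()`).
2. **Scent to attraction.** A Poisson log-link GLM of each pollinator's
   visit counts on linear and quadratic alkene terms, fitted to data in
   which scent–visitation pairings are permuted 300 times within treatment
   groups (`permute_within_groups()`, `fit_attraction_glm()`).
3. **Genotype landscape.** All diploid genotypes at the two (or three) loci
   are pushed through both fitted models with additive expression dosage and
   dominant *SUS* suppression, repeating the calculation 500 times with
   every coefficient drawn uniformly within its 95% confidence interval
   (`predict_genotype_landscape()`). Attraction is scaled to the
   pure-species reference genotype for each pollinator.
4. **Population dynamics.** A discrete-generation stochastic simulation:
   500 pollinators per generation each visit two plants drawn by attraction
   weight, each pollination event contributes all 64 Mendelian offspring of
   the parents at the three unlinked loci, the pool is capped at 1000, and
   every functional allele mutates to nonfunctional at rate $10^{-5}$
   (`run_simulation()`, `run_scenario_grid()`).

Pollination success stands in for total fitness: the system shows no
appreciable postmating isolation, so offspring number is assumed to be
limited by pollinator visits alone.

## The synthetic-data generator and its calibrated ground truth

Real expression/scent and behavioral data for this system live in an
external repository; the package instead ships a generator
(`generate_expression_scent()`, `generate_choice_trials()`) plus one fixed,
versioned parameter set, `ophrys_ground_truth()`, whose constants were
chosen once — analytically, before any simulation — to reproduce the
qualitative structure of the fitted system:

* 7-alkenes depend only on *SAD5A* expression, 9-alkenes only on *SAD2A*,
  and 12-alkenes on *SAD2A* plus a negative *SAD2A×SAD5A* interaction
  (the two desaturases plausibly compete for a shared C16 precursor).
* *C. cunicularius* attraction rises with 7-alkenes toward an interior
  optimum (positive linear, negative quadratic) and falls with 9- and
  12-alkenes. *A. nigroaenea* attraction is carried mainly by 12-alkenes
  (with a quadratic term) and suppressed strongly by 7-alkenes.
* The net gain in scaled *C. cunicularius* attraction from adding one
  functional *SAD5* allele, averaged over all six background genotypes, is
  about 27%, while the corresponding *SAD2* gain for *A. nigroaenea* is
  about 3% — a sevenfold or greater asymmetry. No genotype exceeds 50%
  scaled attraction to both pollinators, and the F1 genotype (+-/+-) stays
  below 50% for both.

One structural consequence deserves emphasis. The *SAD2* gain effect is a
telescoping average: summed over the no-7-alkene background row it equals
$1 - A_{an}(--/--)$. An average gain of only ~3% therefore *forces* the
null genotype --/-- to be almost as attractive to *A. nigroaenea* (~0.83
scaled) as *O. sphegodes* itself. In other words, a small net *SAD2* effect
means *A. nigroaenea* responds only weakly to the presence of 9-/12-alkenes
and strongly to the absence of 7-alkenes. This is consistent with the much
lower variance explained for that pollinator, and it is what makes the
evolutionary asymmetry below possible at all.

Expression is drawn on the square-root scale from a normal truncated at
zero around the species mean; a species mean of exactly zero encodes an
unexpressed allele class and yields exact zeros. Scent is drawn as
`ln(amount + 1) = linear predictor + normal residual`, back-transformed and
floored at zero; visit counts are Poisson draws from the log-quadratic
attraction model at log-normally jittered group prototype blends.

```{r fixture}
truth <- ophrys_ground_truth()
head(generate_expression_scent(truth, n_per_species = 4, seed = 1))
```

### What the generator emulates — and what it does not

The generator reproduces the *statistical* structure the analysis assumes:
two species clusters of expression, log-linear expression–scent relations
with tunable residual noise, and Poisson visitation with a log-quadratic
scent dependence. It does not emulate per-compound chemistry (only the
three class sums), developmental or seasonal covariates, shared-plot
pseudo-replication in the behavioral assays, or overdispersed visit counts.
A green test suite therefore shows that the pipeline recovers the structure
it assumes from data of realistic size and noise — not that field data obey
that structure.

## Numerical and design choices

* **Transforms.** `ln(amount + 1)` rather than `ln(amount)`, because pure
  species genuinely lack the other species' alkene classes and zero amounts
  must be representable; the paired back-transform is `exp(·) − 1` floored
  at zero. Expression enters as `sqrt(X)`; amounts enter the attraction GLM
  untransformed.
* **Term selection.** The exhaustive best-AIC subset is the package default
  for both model spaces (8 linear subsets per alkene class; 27
  hierarchy-respecting Poisson subsets, a quadratic term being admitted only
  with its linear term). Greedy bidirectional stepwise search is provided as
  `method = "stepwise"` for fidelity to common practice, but it is
  path-dependent: on weak-signal data it can stop in a local AIC optimum
  (for instance retaining `sqrt(X2)` and the interaction when the global
  optimum is `sqrt(X5)` alone), so the exhaustive search is the reference
  and the two are only expected to agree when the data carry a clear signal.
  The selection deliberately does *not* impose marginality on the
  expression interaction, so a model can keep `sqrt(X2)·sqrt(X5)` without
  the *SAD5* main effect — the selected structure for 12-alkenes.
* **Pooled permutations.** The 300 permutation rounds are pooled into one
  GLM fit rather than averaged over 300 separate fits. Pooling
  pseudo-replicates each trial, so the nominal Wald intervals are
  anti-conservative; `ci_inflate = TRUE` widens them by `sqrt(n_perm)` for
  users who want honest single-experiment uncertainty (off by default).
* **CI perturbation.** Coefficients are drawn *uniformly* and
  *independently* within their 95% intervals — a literal reading of
  "varying within the confidence interval". Ignoring the coefficient
  covariance overstates the joint parameter uncertainty; this is a
  documented limitation, not an estimator of the posterior.
* **Scaling reference.** Scaled attraction divides by the model-predicted
  raw attraction of the pure-species genotype for that pollinator (--/++
  for *C. cunicularius*, ++/-- for *A. nigroaenea*), recomputed inside each
  perturbation round so the reference is exactly 1 in every round. Values
  above 1 are reported unclipped; only the simulator's visitation weights
  clip to [0, 1].
* **Dosage.** Heterozygote expression is half the homozygote reference — an
  additive assumption the data cannot test; it is the simplest model
  consistent with allelic expression.
* **Visitation.** Each pollinator draws two *distinct* plants with
  probability proportional to clipped scaled attraction (successive
  weighted sampling without replacement, implemented by rejection). If at
  most one plant has positive weight for a species, its pollinators make no
  event; if a whole generation makes no event, the population persists
  unchanged, so extinction cannot occur. A Bernoulli-acceptance mode
  (uniform picks, each accepted with probability equal to its attraction)
  is available via `visit_mode = "bernoulli"`.
* **Mutation.** Loss-of-function applies to "+" alleles and, by default,
  also to "S" suppressor alleles (`mutate_sus = TRUE`) so the suppressor is
  not an immortal allele; mutation runs after the offspring pool is
  subsampled, and no allele is ever gained de novo.
* **Caching.** The simulator precomputes one attraction value per
  (genotype, pollinator) pair from the *plug-in* (unperturbed) model
  estimates; the perturbation machinery quantifies landscape uncertainty
  but does not re-perturb inside the generational loop.

## Parameter recovery and an honest caveat about censoring

With the committed fixture, the three expression–scent refits on 30
individuals per species explain roughly 30–85% of variance, bracketing the
moderate explanatory power typical of real scent data. Coefficient
*recovery*, however, is benchmarked on a variant ground truth with raised
intercepts: with field-realistic near-zero baselines, flooring amounts at
zero censors the `ln(amount + 1)` response for a third or more of the
off-class rows, and ordinary least squares is then no longer an unbiased
estimator of the latent coefficients — a caveat that applies equally to
fitting real data containing true zeros. In the uncensored regime the
pooled 95%-CI coverage of both the OLS and the Poisson-GLM refits is at its
nominal ~95% level (the acceptance script recomputes both).

## The landscape and the speciation asymmetry

```{r landscape}
land <- predict_genotype_landscape(
  enumerate_genotypes(), alkene_model_from_truth(truth),
  attraction_model_from_truth(truth, "cc"),
  attraction_model_from_truth(truth, "an"),
  ref_expr = reference_expression(truth), n_perturb = 1
)
land %>% select(label, attraction_cc_point, attraction_an_point)
net_allele_gain_effect(land, "SAD5", "cc", column = "point")
net_allele_gain_effect(land, "SAD2", "an", column = "point")
```

The landscape is a two-peaked surface with an "adaptive valley" of
intermediate genotypes unattractive to both bees. Because the *SAD5* gain
effect dwarfs the *SAD2* gain effect, the valley is crossable in one
direction only: a single *SAD5A* allele arising in an *O. sphegodes*
population enjoys a severalfold visitation advantage with *C. cunicularius*
present and can establish and carry the population to the *O. exaltata*
genotype, whereas a single *SAD2A* allele in *O. exaltata* is nearly
neutral for *A. nigroaenea* attraction and is expected to be lost. With
*SUS* fixed in *O. sphegodes*, a new *SAD5A* allele is silenced and the
forward route closes too. The replicated scenario runs in
`tests/testthat/test-acceptance.R` and `scripts/acceptance.R` quantify
exactly this: F1-founded populations collapse toward the pure species,
*O. exaltata* evolves from *O. sphegodes* under *C. cunicularius* (and not
under *SUS*), and *O. sphegodes* never evolves from *O. exaltata* within
the simulated horizon.

```{r dynamics, fig.width = 6, fig.height = 3.5}
land27 <- predict_genotype_landscape(
  enumerate_genotypes(include_sus = TRUE), alkene_model_from_truth(truth),
  attraction_model_from_truth(truth, "cc"),
  attraction_model_from_truth(truth, "an"),
  ref_expr = reference_expression(truth), n_perturb = 1
)
traj <- run_simulation(
  sim_config(founder_scenario = "all_F1", pollinator_ratio = "1:1",
             generations = 200, seed = 42),
  land27
)
autoplot(traj)
```

## Problem sizes used by the test suite

The shipped tests and the acceptance script run the study conditions at
their stated scale where the science depends on it — 1000 individuals, 500
pollinators, 1000 generations, 300 permutation rounds, 500 perturbation
rounds, 100 recovery seeds, 20 replicate seeds per dynamic scenario — and
use smaller populations only for structural checks (round trips,
conservation laws, determinism) where scale is immaterial. Replicate counts
for the dynamics were chosen so that outcome rates of 0%, ~100% and
"strictly fewer with *SUS*" are unambiguous.

## Known limitations

* Coefficient perturbation ignores estimation covariance and the pooled
  permutation fit understates coefficient uncertainty (see above); the
  landscape intervals are descriptive, not inferential.
* The attraction models are evaluated far from the data only along genotype
  predictions; the positive quadratic 12-alkene term in the fixture's
  *A. nigroaenea* model would extrapolate badly beyond the genotype range.
* The simulation has no spatial structure, phenology, pollen limitation or
  seed-dispersal economics, and pollinator pools are fixed per generation.
* Minor desaturase contributors (*SAD1*, *SAD6*) are deliberately ignored;
  the two-locus architecture is the object of study, not a complete
  biosynthetic model.
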