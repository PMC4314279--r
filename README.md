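# ophrysim

Pollinator-mediated selection and speciation at two desaturase loci in
sexually deceptive *Ophrys* orchids.

*Ophrys sphegodes* and *O. exaltata* attract different male bees
(*Andrena nigroaenea* and *Colletes cunicularius*) by mimicking female sex
pheromones with floral alkenes. Alkene double-bond position — 9-/12-alkenes
versus 7-alkenes — is controlled by two stearoyl–ACP desaturase genes:
functional *SAD2* alleles ("+") drive 9-/12-alkene production and functional
*SAD5* alleles drive 7-alkenes, with a hypothesized dominant suppressor
(*SUS*) of *SAD5* segregating in *O. sphegodes*. Since each bee is repelled
by the other species' alkenes, this one chemical axis is also the premating
reproductive barrier.

`ophrysim` models that architecture end to end, for evolutionary ecologists
who want to explore how effect sizes at few loci shape speciation routes:

1. **Expression → scent**: linear models of ln(amount + 1) of the 7-, 9- and
   12-alkene class sums on sqrt-transformed allelic expression
   (candidate terms √X₂, √X₅ and √X₂·√X₅; exhaustive best-AIC selection) —
   `fit_alkene_models()`.
2. **Scent → attraction**: per pollinator, a Poisson log-link GLM of visit
   counts on linear + quadratic alkene amounts, fitted on within-group
   permutations (300 rounds) of the scent–visitation pairings —
   `permute_within_groups()`, `fit_attraction_glm()`, so that
   log A = β₀ + Σc (βc·Yc + γc·Yc²).
3. **Genotype landscape**: all 9 two-locus (27 with *SUS*) diploid genotypes
   pushed through both models with additive dosage, dominant suppression and
   500 rounds of uniform coefficient perturbation within the 95% CIs;
   attraction scaled to the pure-species reference genotype —
   `predict_genotype_landscape()`, `net_allele_gain_effect()`.
4. **Population dynamics**: discrete generations, 1000 plants, 500
   pollinators each visiting two attraction-weighted plants, 64 Mendelian
   offspring per pollination event, a 1000-offspring cap and loss-of-function
   mutation at 10⁻⁵ per allele — `run_simulation()`, `run_scenario_grid()`.

A synthetic-data generator (`generate_expression_scent()`,
`generate_choice_trials()`) with a committed, calibrated ground truth
(`ophrys_ground_truth()`) supplies data with the statistical structure the
analysis assumes; `read_expression_scent()` / `read_choice_trials()` ingest
user CSVs with the same columns.

## Worked example

```r
library(ophrysim)

truth <- ophrys_ground_truth()
land <- predict_genotype_landscape(
  enumerate_genotypes(), alkene_model_from_truth(truth),
  attraction_model_from_truth(truth, "cc"),
  attraction_model_from_truth(truth, "an"),
  ref_expr = reference_expression(truth), n_perturb = 1
)
land[, c("label", "attraction_cc_point", "attraction_an_point")]
#>   label attraction_cc_point attraction_an_point
#> 1 ++/--         0.004581484          1.00000000
#> 2 ++/+-         0.036021185          0.19988522
#> 3 ++/++         0.175869351          0.01189413
#> 4 +-/--         0.017598803          0.85997206
#> 5 +-/+-         0.107059457          0.19730459
#> 6 +-/++         0.505914419          0.01178937
#> 7 --/--         0.043090889          0.82995650
#> 8 --/+-         0.219860789          0.19606274
#> 9 --/++         1.000000000          0.01173066

net_allele_gain_effect(land, "SAD5", "cc", column = "point")
#> [1] 0.2694188
net_allele_gain_effect(land, "SAD2", "an", column = "point")
#> [1] 0.02900491
```

Each row is one *SAD2*/*SAD5* genotype ("+" functional, "−" nonfunctional);
the attraction columns are visitation predictions scaled so the pure-species
genotype (−−/++ for *C. cunicularius*, ++/−− for *A. nigroaenea*) equals 1.
The pure genotypes are attractive only to their own pollinator, every
intermediate is below 50% for both bees, and the net allele-gain effects
show the asymmetry that drives the dynamics: adding a functional *SAD5*
allele raises *C. cunicularius* attraction by ~27 percentage points on
average, while a functional *SAD2* allele buys only ~3 points of
*A. nigroaenea* attraction. In simulations
(`run_simulation()`, founders `sphegodes_plus_one_SAD5A` versus
`exaltata_plus_one_SAD2A`) that asymmetry makes *O. exaltata* reachable from
*O. sphegodes* whenever *C. cunicularius* is present — unless *SUS* is fixed
— while the reverse route essentially never completes.

`autoplot()` methods draw the landscape (attraction or alkene composition
per genotype) and trajectory (class frequencies over generations);
`run_full_pipeline(out_dir)` chains all four steps from data generation to
the 40-cell scenario grid and writes CSV/JSON artifacts plus an MD5
manifest. See the methods vignette
(`vignettes/ophrys-two-locus-model.Rmd`) for the model assumptions, tunable
parameters and known limitations.

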