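# Population simulation: founders, Mendelian mating, generation stepping.

small_config <- function(...) {
  args <- list(n_init = 60, n_max = 60, n_pollinators = 30, generations = 10,
               record_every = 5)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

test_that("founder scenarios produce the specified compositions", {
  cfg <- sim_config(founder_scenario = "all_F1", sus_regime = "absent")
  pop <- initialize_population(cfg)
  expect_identical(nrow(pop), 1000L)
  expect_true(all(pop[, "sad2"] == 1 & pop[, "sad5"] == 1 & pop[, "sus"] == 0))

  cfg <- sim_config(founder_scenario = "mix_1to1")
  pop <- initialize_population(cfg)
  expect_identical(sum(pop[, "sad2"] == 2 & pop[, "sad5"] == 0), 500L)
  expect_identical(sum(pop[, "sad2"] == 0 & pop[, "sad5"] == 2), 500L)

  cfg <- sim_config(founder_scenario = "sphegodes_plus_one_SAD5A",
                    sus_regime = "fixed_in_sphegodes")
  pop <- initialize_population(cfg)
  expect_identical(sum(pop[, "sad5"] == 1), 1L)   # single heterozygous carrier
  expect_identical(sum(pop[, "sad5"] == 2), 0L)
  expect_true(all(pop[, "sus"] == 2))             # SS fixed in sphegodes founders

  cfg <- sim_config(founder_scenario = "exaltata_plus_one_SAD2A",
                    sus_regime = "fixed_in_sphegodes")
  pop <- initialize_population(cfg)
  expect_identical(sum(pop[, "sad2"] == 1), 1L)
  expect_true(all(pop[, "sus"] == 0))             # exaltata founders carry no S

  expect_error(sim_config(founder_scenario = "bottleneck"), "arg")
  expect_error(sim_config(n_init = 2000, n_max = 1000), "n_init")
  expect_error(sim_config(mu = 2), "mu")
})

test_that("mating enumerates all 64 Mendelian transmissions", {
  # homozygous opposite parents force a uniform F1 outcome
  off <- mate_genotypes(c(2, 0, 0), c(0, 2, 0))
  expect_identical(dim(off), c(64L, 3L))
  expect_true(all(off[, "sad2"] == 1 & off[, "sad5"] == 1 & off[, "sus"] == 0))
  # selfing a triple homozygote reproduces it 64 times
  off <- mate_genotypes(c(2, 2, 2), c(2, 2, 2))
  expect_true(all(off == 2))
  # double heterozygote cross: 1:2:1 per locus, against the brute-force oracle
  off <- mate_genotypes(c(1, 1, 1), c(1, 1, 1))
  expect_identical(locus_distribution(off), locus_distribution(oracle_mate(c(1, 1, 1), c(1, 1, 1))))
  expect_identical(unname(locus_distribution(off)[, 1]), c(16L, 32L, 16L))
  # random spot checks across the parent-pair space
  for (s in 1:10) {
    set.seed(70 + s)
    pa <- sample(0:2, 3, replace = TRUE)
    pb <- sample(0:2, 3, replace = TRUE)
    expect_identical(locus_distribution(mate_genotypes(pa, pb)),
                     locus_distribution(oracle_mate(pa, pb)))
  }
})

test_that("generations conserve size and closure and mutation only loses alleles", {
  land <- fixture_point_landscape()
  # no pollinators: the population persists unchanged
  cfg <- small_config(founder_scenario = "all_F1", n_pollinators = 0, mu = 0, seed = 1)
  pop <- initialize_population(cfg)
  stepped <- withr::with_seed(1, step_generation(pop, cfg, ophrysim:::attraction_cache(land)))
  expect_identical(unclass(stepped)[, ], unclass(pop)[, ])

  # monomorphic homozygote population is closed under mating without mutation
  cfg <- small_config(founder_scenario = "mix_1to1", mu = 0, seed = 2,
                      pollinator_ratio = "1:0")
  cache <- ophrysim:::attraction_cache(land)
  pop <- initialize_population(cfg)
  pop[, "sad2"] <- 2L
  pop[, "sad5"] <- 0L
  withr::with_seed(3, {
    for (i in 1:5) pop <- step_generation(pop, cfg, cache)
  })
  expect_true(all(pop[, "sad2"] == 2 & pop[, "sad5"] == 0))
  expect_lte(nrow(pop), cfg$n_max)

  # attraction-positive population refills to exactly n_max
  cfg <- small_config(founder_scenario = "mix_1to1", mu = 0, seed = 4)
  pop <- withr::with_seed(5, step_generation(initialize_population(cfg), cfg, cache))
  expect_identical(nrow(pop), cfg$n_max)

  # drastic mutation rate can only reduce the functional-allele count
  cfg_mu <- small_config(founder_scenario = "mix_1to1", mu = 0.5, seed = 6)
  pop0 <- initialize_population(cfg_mu)
  pop1 <- withr::with_seed(7, step_generation(pop0, cfg_mu, cache))
  expect_lt(sum(pop1[, 1:2]) / nrow(pop1), sum(pop0[, 1:2]) / nrow(pop0))
})

test_that("equal attraction makes allele frequencies trendless (no selection)", {
  # Class frequencies are not conserved under random mating (pure classes mix
  # into hybrids on the way to Hardy-Weinberg proportions), but without
  # attraction differences the functional-allele frequency at each locus is a
  # neutral martingale: its mean change over replicates is zero.
  flat <- flat_landscape(0.5)
  cache <- ophrysim:::attraction_cache(flat)
  deltas <- t(vapply(1:40, function(s) {
    cfg <- sim_config(n_init = 200, n_max = 200, n_pollinators = 100,
                      generations = 25, record_every = 25,
                      founder_scenario = "mix_1to1", mu = 0, seed = 3000 + s)
    withr::with_seed(cfg$seed, {
      pop <- initialize_population(cfg)
      p0 <- colMeans(pop[, c("sad2", "sad5")]) / 2
      for (i in seq_len(cfg$generations)) pop <- step_generation(pop, cfg, cache)
      colMeans(pop[, c("sad2", "sad5")]) / 2 - p0
    })
  }, numeric(2)))
  for (l in 1:2) {
    se <- stats::sd(deltas[, l]) / sqrt(nrow(deltas))
    expect_lt(abs(mean(deltas[, l])), 3 * se + 0.01)
  }
})

test_that("trajectories record a conserved frequency grid deterministically", {
  land <- fixture_point_landscape()
  cfg <- small_config(founder_scenario = "all_F1", generations = 20,
                      record_every = 5, seed = 11)
  traj <- run_simulation(cfg, land)
  df <- as.data.frame(traj)
  expect_setequal(unique(df$generation), c(0, 5, 10, 15, 20))
  sums <- tapply(df$frequency, df$generation, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  geno <- tidy(traj, "genotypes")
  gsums <- tapply(geno$frequency, geno$generation, sum)
  expect_true(all(abs(gsums - 1) < 1e-12))
  expect_false(attr(traj, "extinct"))

  traj2 <- run_simulation(cfg, land)
  expect_identical(as.data.frame(traj), as.data.frame(traj2))

  # a zero-generation run records only the founder state
  cfg0 <- small_config(founder_scenario = "all_F1", generations = 0, seed = 1)
  traj0 <- run_simulation(cfg0, land)
  expect_identical(unique(as.data.frame(traj0)$generation), 0L)
  expect_equal(
    as.data.frame(traj0)$frequency[as.data.frame(traj0)$class == "F1_like"], 1
  )
})

test_that("genotype classification follows functional-allele presence", {
  expect_identical(
    classify_genotype(c(2, 1, 0, 0, 1, 0), c(0, 0, 2, 1, 1, 0)),
    c("sphegodes_like", "sphegodes_like", "exaltata_like", "exaltata_like",
      "F1_like", "null")
  )
})

test_that("the scenario grid crosses ratios, founders and suppressor regimes", {
  land <- fixture_point_landscape()
  base <- sim_config(n_init = 40, n_max = 40, n_pollinators = 20,
                     generations = 20, record_every = 10, seed = 9)
  grid <- run_scenario_grid(land, base)
  expect_identical(length(unique(grid$scenario_id)), 40L)
  counts <- table(grid$scenario_id)
  expect_true(all(counts == 3 * 4))  # 3 recorded generations x 4 classes
  sums <- tapply(grid$frequency, list(grid$scenario_id, grid$generation), sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})
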