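# Model step 4: discrete-generation stochastic simulation of a plant
# population pollinated by two bee species, with loss-of-function mutation,
# attraction-weighted visitation and Mendelian 64-offspring enumeration.

POLLINATOR_RATIOS <- c("1:0", "3:1", "1:1", "1:3", "0:1")
FOUNDER_SCENARIOS <- c(
  "mix_1to1", "all_F1", "sphegodes_plus_one_SAD5A", "exaltata_plus_one_SAD2A"
)
SUS_REGIMES <- c("absent", "fixed_in_sphegodes")
GENOTYPE_CLASSES <- c("sphegodes_like", "exaltata_like", "F1_like", "null")

#' Configuration of one population simulation
#'
#' Bundles and validates the simulation settings: population size cap,
#' loss-of-function mutation rate, pollinator pool and species ratio
#' (*A. nigroaenea* : *C. cunicularius*), founder composition, suppressor
#' regime and the recording grid.
#'
#' @param n_init Founder population size (default 1000).
#' @param n_max Maximum population size; offspring pools larger than this are
#'   uniformly subsampled (default 1000).
#' @param mu Loss-of-function probability per functional allele per
#'   generation (default `1e-5`).
#' @param n_pollinators Total pollinators per generation (default 500).
#' @param pollinator_ratio *A. nigroaenea* : *C. cunicularius* ratio, as a
#'   string (`"1:0"`, `"3:1"`, `"1:1"`, `"1:3"`, `"0:1"`) or a nonnegative
#'   numeric pair `c(an, cc)`.
#' @param generations Number of generations to simulate (default 1000).
#' @param record_every Recording interval in generations (default 20).
#' @param founder_scenario One of `"mix_1to1"` (1:1 *O. sphegodes* ++/-- and
#'   *O. exaltata* --/++), `"all_F1"` (+-/+-),
#'   `"sphegodes_plus_one_SAD5A"` (++/-- plus a single heterozygous *SAD5A*
#'   carrier) or `"exaltata_plus_one_SAD2A"` (--/++ plus a single *SAD2A*
#'   carrier).
#' @param sus_regime `"absent"` (all founders ss) or `"fixed_in_sphegodes"`
#'   (SS in sphegodes-type founders, ss in exaltata-type, Ss in F1 founders).
#' @param visit_mode `"weighted"` (default): each pollinator picks two
#'   distinct plants with probability proportional to their clipped scaled
#'   attraction. `"bernoulli"`: two uniform picks, each accepted with
#'   probability equal to its clipped attraction; the event requires both.
#' @param mutate_sus Apply the loss rate `mu` also to "S" alleles (S -> s)?
#'   Default `TRUE`, so the suppressor is not an immortal allele.
#' @param seed RNG seed for [run_simulation()].
#' @return A validated list of class `ophrys_sim_config`.
#' @export
sim_config <- function(n_init = 1000, n_max = 1000, mu = 1e-5,
                       n_pollinators = 500, pollinator_ratio = "1:1",
                       generations = 1000, record_every = 20,
                       founder_scenario = FOUNDER_SCENARIOS,
                       sus_regime = SUS_REGIMES,
                       visit_mode = c("weighted", "bernoulli"),
                       mutate_sus = TRUE, seed = 1) {
  founder_scenario <- match.arg(founder_scenario)
  sus_regime <- match.arg(sus_regime)
  visit_mode <- match.arg(visit_mode)
  assert_scalar_number(n_init, "n_init", lower = 1)
  assert_scalar_number(n_max, "n_max", lower = 1)
  if (n_init > n_max) abort("`n_init` must not exceed `n_max`")
  assert_scalar_number(mu, "mu", lower = 0, upper = 1)
  assert_scalar_number(n_pollinators, "n_pollinators", lower = 0)
  assert_scalar_number(generations, "generations", lower = 0)
  assert_scalar_number(record_every, "record_every", lower = 1)
  assert_scalar_number(seed, "seed")
  shares <- parse_pollinator_ratio(pollinator_ratio, n_pollinators)
  structure(
    list(
      n_init = as.integer(n_init), n_max = as.integer(n_max), mu = mu,
      n_pollinators = as.integer(n_pollinators),
      pollinator_ratio = paste0(format_share(pollinator_ratio)),
      n_an = shares[["an"]], n_cc = shares[["cc"]],
      generations = as.integer(generations),
      record_every = as.integer(record_every),
      founder_scenario = founder_scenario, sus_regime = sus_regime,
      visit_mode = visit_mode, mutate_sus = isTRUE(mutate_sus),
      seed = as.integer(seed)
    ),
    class = "ophrys_sim_config"
  )
}

parse_pollinator_ratio <- function(ratio, n_pollinators) {
  if (is.character(ratio)) {
    parts <- suppressWarnings(as.numeric(strsplit(ratio, ":", fixed = TRUE)[[1]]))
    if (length(parts) != 2 || any(!is.finite(parts))) {
      abort("`pollinator_ratio` string must look like 'an:cc', e.g. '3:1'")
    }
    ratio <- parts
  }
  if (!is.numeric(ratio) || length(ratio) != 2 || any(ratio < 0) || sum(ratio) == 0) {
    abort("`pollinator_ratio` must be a nonnegative pair with a positive sum")
  }
  n_an <- round(n_pollinators * ratio[1] / sum(ratio))
  c(an = as.integer(n_an), cc = as.integer(n_pollinators - n_an))
}

format_share <- function(ratio) {
  if (is.character(ratio)) ratio else paste(ratio, collapse = ":")
}

#' Classify a genotype into the field's reporting classes
#'
#' Partition by presence of functional alleles: at least one "+" at *SAD2*
#' only is *O. sphegodes*-like; at *SAD5* only, *O. exaltata*-like; at both,
#' F1-hybrid-like; at neither, null. *SUS* is ignored for classification.
#'
#' @param sad2,sad5 Integer vectors of functional-allele counts (0-2).
#' @return Character vector over
#'   `c("sphegodes_like", "exaltata_like", "F1_like", "null")`.
#' @examples
#' classify_genotype(c(2, 0, 1, 0), c(0, 2, 1, 0))
#' @export
classify_genotype <- function(sad2, sad5) {
  has2 <- sad2 >= 1
  has5 <- sad5 >= 1
  dplyr::case_when(
    has2 & !has5 ~ "sphegodes_like",
    !has2 & has5 ~ "exaltata_like",
    has2 & has5 ~ "F1_like",
    TRUE ~ "null"
  )
}

#' Founder population for a simulation scenario
#'
#' @param config An [sim_config()] object.
#' @return A `population` object: integer matrix of allele counts (columns
#'   `sad2`, `sad5`, `sus`, one row per individual) with a `generation`
#'   attribute of 0.
#' @examples
#' pop <- initialize_population(sim_config(n_init = 10, founder_scenario = "all_F1"))
#' head(pop)
#' @export
initialize_population <- function(config) {
  stopifnot(inherits(config, "ophrys_sim_config"))
  n <- config$n_init
  sph <- c(2L, 0L)
  exa <- c(0L, 2L)
  f1 <- c(1L, 1L)
  # founder_type tracks which species' SUS background each founder gets
  geno <- switch(config$founder_scenario,
    mix_1to1 = {
      n_sph <- n %/% 2L
      rbind(
        matrix(sph, n_sph, 2, byrow = TRUE),
        matrix(exa, n - n_sph, 2, byrow = TRUE)
      )
    },
    all_F1 = matrix(f1, n, 2, byrow = TRUE),
    sphegodes_plus_one_SAD5A = {
      m <- matrix(sph, n, 2, byrow = TRUE)
      m[1, ] <- c(2L, 1L)
      m
    },
    exaltata_plus_one_SAD2A = {
      m <- matrix(exa, n, 2, byrow = TRUE)
      m[1, ] <- c(1L, 2L)
      m
    }
  )
  sus <- if (config$sus_regime == "absent") {
    rep(0L, n)
  } else {
    # Fixed in O. sphegodes: SS in sphegodes-type founders, ss in
    # exaltata-type, Ss in F1 founders.
    switch(config$founder_scenario,
      mix_1to1 = ifelse(geno[, 1] == 2L, 2L, 0L),
      all_F1 = rep(1L, n),
      sphegodes_plus_one_SAD5A = rep(2L, n),
      exaltata_plus_one_SAD2A = rep(0L, n)
    )
  }
  pop <- cbind(sad2 = geno[, 1], sad5 = geno[, 2], sus = as.integer(sus))
  attr(pop, "generation") <- 0L
  class(pop) <- c("ophrys_population", class(pop))
  pop
}

# Per-allele transmission table: contributions of a parent's two alleles at a
# locus, indexed by the parent's functional-allele count + 1.
TRANSMISSION <- rbind(`0` = c(0L, 0L), `1` = c(0L, 1L), `2` = c(1L, 1L))

#' Mendelian offspring enumeration of one pollination event
#'
#' Each pollination event produces the 64 = 4^3 offspring that carry all
#' possible combinations of the four ordered maternal x paternal allele
#' transmissions at each of the three unlinked loci. Every offspring allele
#' occurs in the contributing parent at that locus.
#'
#' @param parent_a,parent_b Integer vectors `c(sad2, sad5, sus)` of
#'   functional/suppressor allele counts (0-2 each).
#' @return A 64 x 3 integer matrix of offspring allele counts.
#' @examples
#' off <- mate_genotypes(c(2, 0, 0), c(0, 2, 0))
#' unique(off)  # all offspring are +-/+-/ss
#' @export
mate_genotypes <- function(parent_a, parent_b) {
  stopifnot(length(parent_a) == 3, length(parent_b) == 3,
            all(parent_a %in% 0:2), all(parent_b %in% 0:2))
  combo <- 0:63
  out <- matrix(0L, 64, 3, dimnames = list(NULL, c("sad2", "sad5", "sus")))
  for (l in 1:3) {
    q <- (combo %/% 4L^(l - 1L)) %% 4L      # 0..3 transmission index at locus l
    i <- q %% 2L + 1L                       # maternal allele pick
    j <- q %/% 2L + 1L                      # paternal allele pick
    out[, l] <- TRANSMISSION[parent_a[l] + 1L, i] + TRANSMISSION[parent_b[l] + 1L, j]
  }
  out
}

# Attraction lookup built from a landscape: clipped plug-in scaled attraction
# per (sad2, sad5, sus) genotype, used as visitation weights.
attraction_cache <- function(landscape) {
  assert_columns(landscape,
                 c("sad2", "sad5", "attraction_cc_point", "attraction_an_point"),
                 "`landscape`")
  sus <- landscape$sus %||% rep(0L, nrow(landscape))
  key <- landscape$sad2 * 9L + landscape$sad5 * 3L + sus + 1L
  cc <- rep(NA_real_, 27)
  an <- rep(NA_real_, 27)
  cc[key] <- pmin(pmax(landscape$attraction_cc_point, 0), 1)
  an[key] <- pmin(pmax(landscape$attraction_an_point, 0), 1)
  list(cc = cc, an = an)
}

pop_keys <- function(pop) pop[, 1] * 9L + pop[, 2] * 3L + pop[, 3] + 1L

# Draw `g` weighted distinct plant pairs; returns a 2-column index matrix.
# Successive rejection reproduces weighted sampling without replacement; a
# pollinator whose second pick cannot differ from the first (only one plant
# with positive weight) makes no event.
draw_visit_pairs <- function(g, w) {
  if (g == 0 || sum(w) <= 0 || sum(w > 0) < 2) {
    return(matrix(integer(0), 0, 2))
  }
  n <- length(w)
  first <- sample.int(n, g, replace = TRUE, prob = w)
  second <- sample.int(n, g, replace = TRUE, prob = w)
  for (iter in 1:100) {
    bad <- which(second == first)
    if (length(bad) == 0) break
    second[bad] <- sample.int(n, length(bad), replace = TRUE, prob = w)
  }
  ok <- second != first
  cbind(first[ok], second[ok])
}

# Bernoulli-acceptance visitation: uniform picks, each accepted with
# probability equal to its clipped attraction; event requires both.
draw_visit_pairs_bernoulli <- function(g, w) {
  if (g == 0) return(matrix(integer(0), 0, 2))
  n <- length(w)
  first <- sample.int(n, g, replace = TRUE)
  second <- sample.int(n, g, replace = TRUE)
  retry <- second == first
  while (any(retry)) {
    second[retry] <- sample.int(n, sum(retry), replace = TRUE)
    retry <- second == first
  }
  accept <- runif(g) < w[first] & runif(g) < w[second]
  cbind(first[accept], second[accept])
}

#' Advance the population by one generation
#'
#' One generation comprises: (1) pollinators are split between the two bee
#' species by the configured ratio; (2) each pollinator visits two distinct
#' plants drawn by its species' attraction weights (scaled attraction clipped
#' to \[0, 1\]); a species to which total attraction is zero makes no events;
#' (3) every pollination event contributes the 64 Mendelian offspring of
#' [mate_genotypes()]; (4) the offspring pool replaces the population
#' (non-overlapping generations), uniformly subsampled to `n_max` if larger;
#' an empty pool leaves the previous population unchanged; (5) each "+"
#' allele (and each "S" allele when `mutate_sus`) is independently lost with
#' probability `mu`.
#'
#' @param pop A `population` matrix from [initialize_population()].
#' @param config An [sim_config()] object.
#' @param cache Attraction lookup from the landscape (internal; built by
#'   [run_simulation()]).
#' @return The next `population`.
#' @keywords internal
step_generation <- function(pop, config, cache) {
  keys <- pop_keys(pop)
  w_an <- cache$an[keys]
  w_cc <- cache$cc[keys]
  if (anyNA(w_an) || anyNA(w_cc)) {
    abort("landscape does not cover all genotypes present in the population; build it from enumerate_genotypes(include_sus = TRUE)")
  }

  draw <- if (config$visit_mode == "weighted") draw_visit_pairs else draw_visit_pairs_bernoulli
  pairs <- rbind(draw(config$n_an, w_an), draw(config$n_cc, w_cc))
  n_events <- nrow(pairs)

  if (n_events > 0) {
    pool_size <- n_events * 64L
    if (pool_size > config$n_max) {
      keep <- sample.int(pool_size, config$n_max)
    } else {
      keep <- seq_len(pool_size)
    }
    # Decompose kept pool indices into (event, transmission combo) and build
    # only the surviving offspring.
    ev <- (keep - 1L) %/% 64L + 1L
    combo <- (keep - 1L) %% 64L
    off <- matrix(0L, length(keep), 3,
                  dimnames = list(NULL, c("sad2", "sad5", "sus")))
    for (l in 1:3) {
      q <- (combo %/% 4L^(l - 1L)) %% 4L
      i <- q %% 2L + 1L
      j <- q %/% 2L + 1L
      a_cnt <- pop[pairs[ev, 1], l] + 1L
      b_cnt <- pop[pairs[ev, 2], l] + 1L
      off[, l] <- TRANSMISSION[cbind(a_cnt, i)] + TRANSMISSION[cbind(b_cnt, j)]
    }
    new_pop <- off
  } else {
    # No pollination event: the population persists unchanged.
    new_pop <- pop
    attr(new_pop, "generation") <- attr(pop, "generation") + 1L
    return(new_pop)
  }

  # Irreversible loss-of-function mutation.
  if (config$mu > 0) {
    n <- nrow(new_pop)
    loci <- if (config$mutate_sus) 1:3 else 1:2
    for (l in loci) {
      new_pop[, l] <- new_pop[, l] - rbinom(n, new_pop[, l], config$mu)
    }
  }
  attr(new_pop, "generation") <- attr(pop, "generation") + 1L
  class(new_pop) <- c("ophrys_population", "matrix", "array")
  new_pop
}

record_state <- function(pop) {
  cls <- classify_genotype(pop[, 1], pop[, 2])
  class_freq <- vapply(GENOTYPE_CLASSES, function(k) mean(cls == k), numeric(1))
  lab <- genotype_label(pop[, 1], pop[, 2], pop[, 3])
  geno_freq <- table(lab) / nrow(pop)
  list(classes = class_freq, genotypes = geno_freq)
}

#' Run one population simulation scenario
#'
#' Iterates [step_generation()] for `config$generations` generations and
#' records the frequencies of the genotype classes (*O. sphegodes*-like,
#' *O. exaltata*-like, F1-like, null) and of each raw genotype at generation
#' 0 and every `record_every` generations. Deterministic given `config$seed`.
#'
#' @param config An [sim_config()] object.
#' @param landscape An `ophrys_landscape` covering every genotype the
#'   simulation can produce (use [enumerate_genotypes()] with
#'   `include_sus = TRUE` when suppressor alleles can be present).
#' @return An `ophrys_trajectory` tibble (`generation`, `class`, `frequency`)
#'   with attributes `genotypes` (per-genotype frequency records), `config`
#'   and `extinct` (always `FALSE`: the empty-pool persistence rule excludes
#'   extinction).
#' @examples
#' truth <- ophrys_ground_truth()
#' land <- predict_genotype_landscape(
#'   enumerate_genotypes(TRUE), alkene_model_from_truth(truth),
#'   attraction_model_from_truth(truth, "cc"),
#'   attraction_model_from_truth(truth, "an"),
#'   reference_expression(truth), n_perturb = 1
#' )
#' traj <- run_simulation(
#'   sim_config(n_init = 50, n_max = 50, n_pollinators = 25,
#'              generations = 20, record_every = 10,
#'              founder_scenario = "all_F1", seed = 1),
#'   land
#' )
#' traj
#' @export
run_simulation <- function(config, landscape) {
  stopifnot(inherits(config, "ophrys_sim_config"))
  cache <- attraction_cache(landscape)
  with_seed_or_not(config$seed, {
    pop <- initialize_population(config)
    records <- list(`0` = record_state(pop))
    for (gen in seq_len(config$generations)) {
      pop <- step_generation(pop, config, cache)
      if (gen %% config$record_every == 0) {
        records[[as.character(gen)]] <- record_state(pop)
      }
    }
    build_trajectory(records, config)
  })
}

build_trajectory <- function(records, config) {
  gens <- as.integer(names(records))
  classes <- purrr::map_dfr(seq_along(records), function(i) {
    tibble(
      generation = gens[i],
      class = GENOTYPE_CLASSES,
      frequency = unname(records[[i]]$classes)
    )
  })
  genotypes <- purrr::map_dfr(seq_along(records), function(i) {
    gf <- records[[i]]$genotypes
    tibble(
      generation = gens[i],
      label = names(gf),
      frequency = as.numeric(gf)
    )
  })
  out <- classes
  attr(out, "genotypes") <- genotypes
  attr(out, "config") <- config
  attr(out, "extinct") <- FALSE
  class(out) <- c("ophrys_trajectory", class(out))
  out
}

#' @export
glance.ophrys_trajectory <- function(x, ...) {
  config <- attr(x, "config")
  final <- x[x$generation == max(x$generation), ]
  tibble(
    founder_scenario = config$founder_scenario,
    pollinator_ratio = config$pollinator_ratio,
    sus_regime = config$sus_regime,
    generations = config$generations,
    final_sphegodes_like = final$frequency[final$class == "sphegodes_like"],
    final_exaltata_like = final$frequency[final$class == "exaltata_like"],
    final_F1_like = final$frequency[final$class == "F1_like"],
    final_null = final$frequency[final$class == "null"],
    extinct = attr(x, "extinct")
  )
}

#' Run the full scenario grid of the speciation model
#'
#' Crosses the five pollinator ratios, four founder scenarios and two
#' suppressor regimes (40 scenarios), running one simulation per cell with a
#' per-cell seed derived from `seed`.
#'
#' @param landscape An `ophrys_landscape` built with `include_sus = TRUE`.
#' @param base_config Settings shared by all cells (ratio, founder and
#'   suppressor fields are overwritten per cell).
#' @param seed Master seed from which per-scenario seeds are derived.
#' @return A tidy long tibble: `scenario_id`, `pollinator_ratio`,
#'   `founder_scenario`, `sus_regime`, `generation`, `class`, `frequency`;
#'   the individual `ophrys_trajectory` objects are attached as attribute
#'   `"trajectories"`.
#' @export
run_scenario_grid <- function(landscape, base_config = sim_config(), seed = base_config$seed) {
  grid <- expand.grid(
    sus_regime = SUS_REGIMES,
    founder_scenario = FOUNDER_SCENARIOS,
    pollinator_ratio = POLLINATOR_RATIOS,
    stringsAsFactors = FALSE
  )
  seeds <- spawn_seeds(seed, nrow(grid))
  trajectories <- vector("list", nrow(grid))
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- sim_config(
      n_init = base_config$n_init, n_max = base_config$n_max,
      mu = base_config$mu, n_pollinators = base_config$n_pollinators,
      pollinator_ratio = grid$pollinator_ratio[i],
      generations = base_config$generations,
      record_every = base_config$record_every,
      founder_scenario = grid$founder_scenario[i],
      sus_regime = grid$sus_regime[i],
      visit_mode = base_config$visit_mode,
      mutate_sus = base_config$mutate_sus,
      seed = seeds[i]
    )
    traj <- run_simulation(cfg, landscape)
    trajectories[[i]] <- traj
    rows[[i]] <- traj %>%
      as_tibble() %>%
      mutate(
        scenario_id = sprintf("an%s_%s_%s", gsub(":", "to", grid$pollinator_ratio[i]),
                              grid$founder_scenario[i], grid$sus_regime[i]),
        pollinator_ratio = grid$pollinator_ratio[i],
        founder_scenario = grid$founder_scenario[i],
        sus_regime = grid$sus_regime[i],
        .before = 1
      )
  }
  out <- bind_rows(rows)
  attr(out, "trajectories") <- trajectories
  out
}
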