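# End-to-end pipeline: synthetic data (or user CSVs) -> alkene regressions ->
# attraction GLMs -> genotype landscapes (with and without SUS) -> scenario
# grid, with a hashed output manifest.

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
          class = "ophrysim_pipeline_error")
  })
}

#' Run the four-step pipeline end to end
#'
#' Chains every model step: generates expression/scent and choice-trial
#' tables from the ground truth (or ingests user CSVs), fits the alkene
#' regressions and both pollinators' attraction GLMs, builds the genotype
#' landscape with and without the *SUS* suppressor, runs the 40-cell
#' simulation scenario grid, and writes every artifact plus a manifest of MD5
#' hashes to `out_dir`. A single master `seed` deterministically spawns the
#' per-stage seeds, so two runs with the same inputs and seed produce
#' identical manifests.
#'
#' @param out_dir Output directory (created if missing).
#' @param params Ground-truth parameter set used for data generation and for
#'   the homozygote reference expression.
#' @param seed Master seed.
#' @param expression_file,choice_file Optional user CSVs replacing the
#'   generated data (formats of [read_expression_scent()] /
#'   [read_choice_trials()]).
#' @param n_per_species,n_trials_per_group Generator sizes.
#' @param n_perm Permutation rounds for the attraction fits (default 300).
#' @param n_perturb CI-perturbation rounds for the landscape (default 500).
#' @param grid_config Base [sim_config()] shared by all scenario-grid cells.
#' @param run_grid Run the 40-cell scenario grid (the slowest stage)?
#'   Default `TRUE`.
#' @return Invisibly, a list with the fitted models, both landscapes, the
#'   grid results (or `NULL`) and the manifest tibble (`file`, `md5`).
#' @export
run_full_pipeline <- function(out_dir,
                              params = ophrys_ground_truth(),
                              seed = params$seed,
                              expression_file = NULL,
                              choice_file = NULL,
                              n_per_species = NULL,
                              n_trials_per_group = 10,
                              n_perm = 300,
                              n_perturb = 500,
                              grid_config = sim_config(),
                              run_grid = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- spawn_seeds(seed, 5)
  path <- function(...) file.path(out_dir, ...)

  run_stage("simdata", {
    if (is.null(expression_file)) {
      expr_data <- generate_expression_scent(params, n_per_species, seed = seeds[1])
      write_expression_scent(expr_data, path("expression_scent.csv"))
    } else {
      expr_data <- read_expression_scent(expression_file)
    }
    if (is.null(choice_file)) {
      trials <- generate_choice_trials(params, n_trials_per_group, seed = seeds[2])
      write_choice_trials(trials, path("choice_trials.csv"))
    } else {
      trials <- read_choice_trials(choice_file)
    }
  })

  run_stage("fit_alkenes", {
    alkene_fit <- fit_alkene_models(expr_data)
    write_model_json(alkene_fit, path("alkene_model.json"))
  })

  run_stage("fit_attraction", {
    expanded <- permute_within_groups(trials, n_perm = n_perm, seed = seeds[3])
    attraction_cc <- fit_attraction_glm(expanded, "C_cunicularius")
    attraction_an <- fit_attraction_glm(expanded, "A_nigroaenea")
    write_model_json(attraction_cc, path("attraction_cc.json"))
    write_model_json(attraction_an, path("attraction_an.json"))
  })

  landscapes <- run_stage("landscape", {
    # Re-read the serialized models: downstream stages consume the files the
    # earlier stages wrote, so a missing artifact is detected here.
    alkene_fit <- read_model_json(path("alkene_model.json"))
    attraction_cc <- read_model_json(path("attraction_cc.json"))
    attraction_an <- read_model_json(path("attraction_an.json"))
    ref_expr <- reference_expression(params)
    land_nosus <- predict_genotype_landscape(
      enumerate_genotypes(include_sus = FALSE), alkene_fit,
      attraction_cc, attraction_an, ref_expr,
      n_perturb = n_perturb, seed = seeds[4]
    )
    land_sus <- predict_genotype_landscape(
      enumerate_genotypes(include_sus = TRUE), alkene_fit,
      attraction_cc, attraction_an, ref_expr,
      n_perturb = n_perturb, seed = seeds[4]
    )
    readr::write_csv(as_tibble(land_nosus), path("landscape_no_sus.csv"))
    readr::write_csv(as_tibble(land_sus), path("landscape_with_sus.csv"))
    list(no_sus = land_nosus, with_sus = land_sus)
  })

  grid <- NULL
  if (isTRUE(run_grid)) {
    grid <- run_stage("simulate", {
      g <- run_scenario_grid(landscapes$with_sus, grid_config, seed = seeds[5])
      readr::write_csv(as_tibble(g), path("trajectories_classes.csv"))
      geno_long <- purrr::map_dfr(
        attr(g, "trajectories"),
        function(tr) {
          cfg <- attr(tr, "config")
          attr(tr, "genotypes") %>%
            mutate(
              founder_scenario = cfg$founder_scenario,
              pollinator_ratio = cfg$pollinator_ratio,
              sus_regime = cfg$sus_regime, .before = 1
            )
        }
      )
      geno_wide <- tidyr::pivot_wider(
        geno_long, names_from = "label", values_from = "frequency",
        values_fill = 0
      )
      readr::write_csv(geno_wide, path("trajectories_genotypes.csv"))
      g
    })
  }

  files <- sort(list.files(out_dir, full.names = TRUE))
  manifest <- tibble(
    file = basename(files),
    md5 = unname(tools::md5sum(files))
  )
  readr::write_csv(manifest, path("manifest.csv"))

  invisible(list(
    landscapes = landscapes, grid = grid, manifest = manifest, out_dir = out_dir
  ))
}
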