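test_that("battery assembly attaches the mandated controls", {
  bat <- assemble_battery(
    outcomes = c("prevalence_fdb", "hatch_rate"),
    predictors = c("brain_volume_ml", "innovation_count",
                   "n_pairs_aviculture"))
  cells <- vapply(bat, function(s)
    paste(attr(s, "cell")[["outcome"]], s$focal_predictor, sep = "~"),
    character(1))
  # pairs predictor only appears for hatch rate
  expect_false("prevalence_fdb~n_pairs_aviculture" %in% cells)
  expect_true("hatch_rate~n_pairs_aviculture" %in% cells)
  for (s in bat) {
    if (s$focal_predictor == "brain_volume_ml")
      expect_true("body_mass_g" %in% s$covariates)
    if (s$focal_predictor == "innovation_count")
      expect_true("research_effort_papers" %in% s$covariates)
    if (attr(s, "cell")[["outcome"]] == "hatch_rate")
      expect_true("natural_fecundity" %in% s$covariates)
  }
  expect_silent(validate_battery(bat))
})

test_that("screened confounds and collinear partners become covariates", {
  coll <- data.frame(predictor_a = "brain_volume_ml",
                     predictor_b = "habitat_breadth",
                     p = 0.01, flagged = TRUE)
  bat <- assemble_battery(
    outcomes = "prevalence_fdb",
    predictors = c("brain_volume_ml", "habitat_breadth"),
    screened = list(brain_volume_ml = "prop_standard_cage"),
    collinear = coll)
  s1 <- bat[[1]]
  expect_setequal(s1$covariates,
                  c("body_mass_g", "prop_standard_cage", "habitat_breadth"))
  expect_true("brain_volume_ml" %in% bat[[2]]$covariates)
})

test_that("invariant-violating specs are refused by name", {
  bad <- list(model_spec("prevalence_fdb", "brain_volume_ml",
                         family = "gaussian"))
  expect_error(validate_battery(bad), "body_mass_g")
  bad2 <- bat_spec <- model_spec("hatch_rate", "iucn_rank",
                                 family = "gaussian")
  expect_error(validate_battery(list(bad2)), "natural_fecundity")
})

test_that("run_battery recovers a planted effect end to end", {
  cfg <- sim_config(n_species = 50, n_trees_block = 15, jitter = 0.15,
                    seed = 61)
  study <- simulate_study(cfg, effects = list(
    prevalence_fdb = c(pct_diet_handling = 1.2)))
  bat <- assemble_battery(
    outcomes = c("prevalence_fdb", "prevalence_oral_sb"),
    predictors = c("pct_diet_handling", "habitat_breadth"))
  run_cfg <- default_config()
  run_cfg$seed <- 61
  res <- run_battery(study$data, bat, study$tree, study$block,
                     config = run_cfg)
  expect_equal(nrow(res$table), 4L)
  focal <- res$table[res$table$outcome == "prevalence_fdb" &
                       res$table$predictor == "pct_diet_handling", ]
  expect_equal(focal$sign, "+")
  expect_true(focal$significant)
  expect_true(focal$partial_r2 > 0 && focal$partial_r2 < 1)
})

test_that("a single-tree block reproduces consensus-only fits", {
  cfg <- sim_config(n_species = 30, n_trees_block = 1, jitter = 0,
                    seed = 62)
  study <- simulate_study(cfg)
  bat <- assemble_battery(outcomes = "prevalence_fdb",
                          predictors = "habitat_breadth")
  res <- run_battery(study$data, bat, study$tree, study$block,
                     config = default_config())
  single <- fit_pgls(study$data, bat[[1]], study$tree)
  expect_equal(res$table$median_beta,
               unname(single$coefficients["habitat_breadth"]),
               tolerance = 1e-10)
  expect_equal(res$table$ci95_low, res$table$ci95_high, tolerance = 1e-12)
})

test_that("identical config and seed give byte-identical outputs", {
  cfg <- sim_config(n_species = 25, n_trees_block = 4, jitter = 0.1,
                    seed = 63)
  study <- simulate_study(cfg)
  bat <- assemble_battery(outcomes = "prevalence_fdb",
                          predictors = "habitat_breadth")
  run_once <- function(dir) {
    res <- run_battery(study$data, bat, study$tree, study$block,
                       config = default_config())
    write_results(res, dir)
    dir
  }
  d1 <- run_once(file.path(tempdir(), "runA"))
  d2 <- run_once(file.path(tempdir(), "runB"))
  for (f in c("results_table.tsv", "results.json", "run.log")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("species table validation enforces the column conventions", {
  d <- data.frame(species = c("a", "b"), prevalence_fdb = c(0.2, 1.4))
  expect_error(validate_species_data(d), "prevalence_fdb")
  d2 <- data.frame(species = c("a", "a"), x = 1:2)
  expect_error(validate_species_data(d2), "duplicated")
  d3 <- data.frame(species = c("a", "b"), iucn_rank = c(1, 7))
  expect_error(validate_species_data(d3), "iucn_rank")
})
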