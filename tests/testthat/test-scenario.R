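test_that("a null scenario is the exact identity on every outcome", {
  pop <- small_generated_pop(n = 1000, seed = 51)
  cfg <- run_config(pop, bootstrap_replicates = 0, seed = 2, verbose = FALSE)
  for (sc in list(tax_scenario(0), tax_scenario(0.2, pass_through = 0))) {
    res <- run_scenario(cfg, sc)
    expect_true(all(res$individual_effects$delta_e_kcal == 0))
    expect_true(all(res$individual_effects$delta_w_kg == 0))
    expect_identical(res$individual_effects$bmi_post,
                     res$individual_effects$bmi_pre)
    expect_true(all(res$energy$mean_delta_e_kcal == 0))
    expect_true(all(res$bmi$mean_delta_bmi == 0))
    expect_true(all(res$prevalence$relative_change_pct == 0))
  }
})

test_that("a higher tax shifts taxed consumption more", {
  pop <- small_generated_pop(n = 1000, seed = 51)
  e <- default_elasticities(pop$catalogue)
  base <- as.matrix(pop$individuals[paste0("cons_", pop$catalogue$name)])
  colnames(base) <- pop$catalogue$name
  taxed <- pop$catalogue$name[pop$catalogue$taxed]
  drop20 <- sum(base[, taxed]) -
    sum(consumption_shift(e, price_change(tax_scenario(0.2), pop$catalogue),
                          base)[, taxed])
  drop30 <- sum(base[, taxed]) -
    sum(consumption_shift(e, price_change(tax_scenario(0.3), pop$catalogue),
                          base)[, taxed])
  expect_gt(drop30, drop20)
})

test_that("identical config and seed give identical scenario results", {
  cfg1 <- run_config(population_config(n_individuals = 800),
                     bootstrap_replicates = 50, seed = 5, verbose = FALSE)
  cfg2 <- run_config(population_config(n_individuals = 800),
                     bootstrap_replicates = 50, seed = 5, verbose = FALSE)
  r1 <- run_scenario(cfg1, tax_scenario(0.25))
  r2 <- run_scenario(cfg2, tax_scenario(0.25))
  expect_identical(r1$energy, r2$energy)
  expect_identical(r1$bmi, r2$bmi)
  expect_identical(r1$prevalence, r2$prevalence)
})

test_that("run_scenario equals the hand-composed stages on the 10-person fixture", {
  pop <- ten_person_fixture()
  cfg <- run_config(pop, bootstrap_replicates = 0, seed = 3, verbose = FALSE)
  sc <- tax_scenario(0.20)
  res <- run_scenario(cfg, sc)

  e <- default_elasticities(pop$catalogue)
  base <- as.matrix(pop$individuals[paste0("cons_", pop$catalogue$name)])
  colnames(base) <- pop$catalogue$name
  shifted <- consumption_shift(e, price_change(sc, pop$catalogue), base)
  ec <- energy_change(pop, shifted)
  dw <- weight_change_at_horizon(steady_state_weight_change(ec$delta_e_kcal),
                                 sc$horizon_years)
  wo <- apply_weight_change(pop$individuals, dw)

  expect_identical(res$individual_effects$delta_e_kcal, ec$delta_e_kcal)
  expect_identical(res$individual_effects$delta_w_kg, wo$delta_w_kg)
  expect_identical(res$individual_effects$bmi_post, wo$bmi_post)

  # table rows equal direct weighted means over the same individuals
  w <- pop$individuals$survey_weight
  ov <- res$energy[res$energy$sex == "all" & res$energy$age_group == "all", ]
  expect_equal(ov$mean_delta_e_kcal, weighted.mean(ec$delta_e_kcal, w),
               tolerance = 1e-12)
  men <- res$bmi[res$bmi$sex == "male" & res$bmi$age_group == "all", ]
  msel <- pop$individuals$sex == "male"
  expect_equal(men$mean_delta_bmi,
               weighted.mean(wo$bmi_post[msel] - wo$bmi_pre[msel], w[msel]),
               tolerance = 1e-12)

  # prevalence table agrees with the standalone prevalence_change()
  # (tiny fixture: some strata legitimately have zero baseline obesity)
  pc <- suppressWarnings(prevalence_change(pop, wo$bmi_post, wo$bmi_pre))
  merged <- merge(as.data.frame(res$prevalence), as.data.frame(pc),
                  by = c("sex", "age_group", "measure"))
  expect_equal(merged$prevalence_pre.x, merged$prevalence_pre.y,
               tolerance = 1e-12)
  expect_equal(merged$prevalence_post.x, merged$prevalence_post.y,
               tolerance = 1e-12)
})

test_that("every reporting stratum appears exactly once per table", {
  pop <- small_generated_pop(n = 500, seed = 53)
  cfg <- run_config(pop, bootstrap_replicates = 0, verbose = FALSE)
  res <- run_scenario(cfg, tax_scenario(0.2))
  key <- paste(res$energy$sex, res$energy$age_group)
  expect_equal(anyDuplicated(key), 0L)
  expect_equal(nrow(res$energy), 21L)  # 1 + 2 + 6 + 12
  expect_equal(nrow(res$prevalence), 21L * 3L)
})

test_that("sensitivity at 80% pass-through scales energy change exactly", {
  pop <- small_generated_pop(n = 600, seed = 55)
  cfg <- run_config(pop, scenarios = list(tax_scenario(0.2), tax_scenario(0.3)),
                    bootstrap_replicates = 0, seed = 4, verbose = FALSE)
  sens <- run_sensitivity(cfg, pass_through_values = c(1, 0.8))
  for (lab in c("tax20", "tax30")) {
    full <- sens$results$pt100[[paste0(lab, "_pt100")]]
    part <- sens$results$pt80[[paste0(lab, "_pt80")]]
    expect_equal(part$individual_effects$delta_e_kcal,
                 0.8 * full$individual_effects$delta_e_kcal, tolerance = 1e-12)
    # attenuated BMI change in magnitude, overall
    expect_lt(abs(part$bmi$mean_delta_bmi[1]), abs(full$bmi$mean_delta_bmi[1]))
  }
  # pass-through 1.0 equals the main run
  main <- run_scenario(cfg, tax_scenario(0.2))
  expect_equal(sens$results$pt100$tax20_pt100$energy, main$energy)
  expect_error(run_sensitivity(cfg, pass_through_values = c(1.2)), "\\(0, 1\\]")
  expect_error(run_sensitivity(cfg, pass_through_values = 0), "\\(0, 1\\]")
})

test_that("reports are written once per scenario and refuse to overwrite", {
  pop <- small_generated_pop(n = 300, seed = 57)
  cfg <- run_config(pop, bootstrap_replicates = 0, verbose = FALSE)
  res <- lapply(list(tax_scenario(0.2), tax_scenario(0.25), tax_scenario(0.3)),
                function(s) run_scenario(cfg, s))
  dir <- withr::local_tempdir()
  files <- render_reports(res, dir)
  expect_length(files, 12L)  # 3 scenarios x (3 CSV + 1 JSON)
  expect_true(all(file.exists(files)))
  expect_true(any(grepl("tax20_pt100_energy\\.csv$", files)))
  expect_true(any(grepl("tax25_pt100_bmi\\.csv$", files)))
  expect_true(any(grepl("tax30_pt100_prevalence\\.csv$", files)))

  expect_error(render_reports(res, dir), "force")
  expect_silent(render_reports(res, dir, force = TRUE))

  js <- jsonlite::read_json(file.path(dir, "tax20_pt100_summary.json"))
  expect_equal(js$scenario$tax_rate, 0.2)
})

test_that("taxing only soft drinks is expressible purely via configuration", {
  pop <- small_generated_pop(n = 2000, seed = 59)
  cfg <- run_config(pop, bootstrap_replicates = 0, verbose = FALSE)
  res <- run_scenario(cfg, tax_scenario(0.2, taxed_categories = "soda"))
  dv <- res$individual_effects
  # only soda's price moved; other taxed categories keep their volume
  base <- as.matrix(pop$individuals[paste0("cons_", pop$catalogue$name)])
  colnames(base) <- pop$catalogue$name
  e <- default_elasticities(pop$catalogue)
  pct <- price_change(tax_scenario(0.2, taxed_categories = "soda"),
                      pop$catalogue)
  shifted <- consumption_shift(e, pct, base)
  expect_equal(unname(shifted[, "other_ssb"]), unname(base[, "other_ssb"]))
  expect_equal(unname(shifted[, "soda"]), unname(base[, "soda"]) * 0.8)
  # substitution is smaller than under the full taxed set
  full <- run_scenario(cfg, tax_scenario(0.2))
  expect_lt(res$energy$mean_delta_e_kcal[1], full$energy$mean_delta_e_kcal[1])
})

test_that("a YAML run configuration reproduces the in-code one", {
  yaml_file <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "population:",
    "  n_individuals: 400",
    "seed: 6",
    "bootstrap_replicates: 0",
    "verbose: false",
    "scenarios:",
    "  - tax_rate: 0.2",
    "  - tax_rate: 0.3",
    "    pass_through: 0.8"
  ), yaml_file)
  cfg <- read_run_config(yaml_file)
  expect_s3_class(cfg, "run_config")
  expect_length(cfg$scenarios, 2L)
  expect_equal(cfg$scenarios[[2]]$pass_through, 0.8)
  res <- run_scenario(cfg)
  direct <- run_scenario(run_config(population_config(n_individuals = 400),
                                    bootstrap_replicates = 0, seed = 6,
                                    verbose = FALSE),
                         tax_scenario(0.2))
  expect_equal(res$energy, direct$energy)
})

test_that("stage errors carry the stage name", {
  cfg <- run_config(population_config(n_individuals = 100),
                    elasticities = elasticity_matrix(
                      matrix(-1, 1, 1, dimnames = list("x", "x"))),
                    bootstrap_replicates = 0, verbose = FALSE)
  expect_error(run_scenario(cfg, tax_scenario(0.2)), "\\[elasticities\\]")
})
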