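test_that("price change is tax x pass-through on taxed categories only", {
  cat8 <- default_catalogue()
  pct <- price_change(tax_scenario(0.20), cat8)
  expect_equal(unname(pct[cat8$taxed]), rep(20, 4))
  expect_equal(unname(pct[!cat8$taxed]), rep(0, 4))

  expect_equal(max(price_change(tax_scenario(0.20, pass_through = 0.8), cat8)), 16)
  expect_true(all(price_change(tax_scenario(0), cat8) == 0))

  # scenario restricted to one category, with an unknown name rejected
  pct_soda <- price_change(tax_scenario(0.25, taxed_categories = "soda"), cat8)
  expect_equal(unname(pct_soda["soda"]), 25)
  expect_equal(sum(pct_soda != 0), 1L)
  expect_error(price_change(tax_scenario(0.2, taxed_categories = "cola"), cat8),
               "cola.*soda")
})

test_that("elasticity matrix validates shape and warns on positive own-price", {
  expect_error(elasticity_matrix(matrix(1:6, 2, 3)), "square")
  expect_error(elasticity_matrix(matrix(1, 2, 2),
                                 categories = c("a", "a")), "unique")
  expect_warning(elasticity_matrix(matrix(c(0.5, 0, 0, -1), 2, 2,
                                          dimnames = list(c("a", "b"),
                                                          c("a", "b")))),
                 "positive own-price")
})

test_that("linear consumption shift follows the first-order elasticity rule", {
  cats <- c("a", "b")
  e <- elasticity_matrix(matrix(c(-1, 0, 0, 0), 2, 2, byrow = TRUE,
                                dimnames = list(cats, cats)))
  q <- c(a = 250, b = 100)
  shifted <- consumption_shift(e, c(a = 20, b = 0), q)
  expect_equal(unname(shifted), c(250 * 0.8, 100))

  # cross elasticity: +0.3 toward b when a's price rises 20% -> +6%
  e2 <- elasticity_matrix(matrix(c(-1, 0, 0.3, 0), 2, 2, byrow = TRUE,
                                 dimnames = list(cats, cats)))
  shifted2 <- consumption_shift(e2, c(a = 20, b = 0), q)
  expect_equal(unname(shifted2["b"]), 100 * 1.06)

  # all elasticities zero: unchanged exactly
  e0 <- elasticity_matrix(matrix(0, 2, 2, dimnames = list(cats, cats)))
  expect_identical(consumption_shift(e0, c(a = 20, b = 0), q), q)

  # zero floor binds when the linear response would go negative
  e3 <- suppressWarnings(
    elasticity_matrix(matrix(c(-3, 0, 0, 0), 2, 2, byrow = TRUE,
                             dimnames = list(cats, cats))))
  shifted3 <- consumption_shift(e3, c(a = 40, b = 0), q)
  expect_equal(unname(shifted3["a"]), 0)

  expect_error(consumption_shift(e, c(a = 20, b = 0, c = 0), q),
               "dimension mismatch")
})

test_that("log-form shift applies the constant-elasticity rule", {
  cats <- c("a", "b")
  e <- elasticity_matrix(matrix(c(-1, 0, 0.3, 0), 2, 2, byrow = TRUE,
                                dimnames = list(cats, cats)))
  q <- c(a = 250, b = 100)
  shifted <- consumption_shift(e, c(a = 20, b = 0), q, form = "log")
  expect_equal(unname(shifted["a"]), 250 * 1.2^-1)
  expect_equal(unname(shifted["b"]), 100 * 1.2^0.3)
})

test_that("energy change is the density-weighted volume change, per person", {
  pop <- ten_person_fixture()
  cat8 <- pop$catalogue
  e <- default_elasticities(cat8)
  pct <- price_change(tax_scenario(0.20), cat8)
  base <- as.matrix(pop$individuals[paste0("cons_", cat8$name)])
  colnames(base) <- cat8$name
  shifted <- consumption_shift(e, pct, base)
  ec <- energy_change(pop, shifted)

  # identity: delta E = sum of per-category volume change x density
  dens <- cat8$energy_density
  for (i in seq_len(10)) {
    expect_equal(ec$delta_e_kcal[i], sum((shifted[i, ] - base[i, ]) * dens))
  }

  # hand case: only a taxed 0.4 kcal/mL category, own elasticity -1, -20%
  cat2 <- toy_catalogue()
  p2 <- fixture_population(tibble::tibble(
    id = 1L, sex = "male", age_group = "20-29", height_m = 1.8,
    weight_kg = 80, survey_weight = 1,
    cons_taxed_drink = 250, cons_plain = 500
  ), cat2)
  e2 <- elasticity_matrix(matrix(c(-1, 0, 0, 0), 2, 2, byrow = TRUE,
                                 dimnames = list(cat2$name, cat2$name)))
  s2 <- consumption_shift(e2, price_change(tax_scenario(0.20), cat2),
                          matrix(c(250, 500), 1, dimnames = list(NULL, cat2$name)))
  ec2 <- energy_change(p2, s2)
  expect_equal(ec2$delta_e_kcal, -250 * 0.2 * 0.4)  # -20 kcal/day

  # zero baseline consumption -> zero energy change
  p0 <- fixture_population(tibble::tibble(
    id = 1L, sex = "male", age_group = "20-29", height_m = 1.8,
    weight_kg = 80, survey_weight = 1, cons_taxed_drink = 0, cons_plain = 0
  ), cat2)
  s0 <- consumption_shift(e2, price_change(tax_scenario(0.20), cat2),
                          matrix(0, 1, 2, dimnames = list(NULL, cat2$name)))
  expect_equal(energy_change(p0, s0)$delta_e_kcal, 0)
})

test_that("null scenarios leave consumption and energy unchanged exactly", {
  pop <- ten_person_fixture()
  e <- default_elasticities(pop$catalogue)
  base <- as.matrix(pop$individuals[paste0("cons_", pop$catalogue$name)])
  colnames(base) <- pop$catalogue$name
  for (sc in list(tax_scenario(0), tax_scenario(0.2, pass_through = 0))) {
    shifted <- consumption_shift(e, price_change(sc, pop$catalogue), base)
    expect_identical(shifted, base)
    expect_true(all(energy_change(pop, shifted)$delta_e_kcal == 0))
  }
})

test_that("energy change scales exactly with pass-through under linear form", {
  pop <- ten_person_fixture()
  e <- default_elasticities(pop$catalogue)
  base <- as.matrix(pop$individuals[paste0("cons_", pop$catalogue$name)])
  colnames(base) <- pop$catalogue$name
  full <- energy_change(pop, consumption_shift(
    e, price_change(tax_scenario(0.2, pass_through = 1), pop$catalogue), base))
  part <- energy_change(pop, consumption_shift(
    e, price_change(tax_scenario(0.2, pass_through = 0.8), pop$catalogue), base))
  expect_equal(part$delta_e_kcal, 0.8 * full$delta_e_kcal, tolerance = 1e-12)
})

test_that("taxed volume falls strictly with the tax until the floor binds", {
  cat2 <- toy_catalogue()
  e <- elasticity_matrix(matrix(c(-1, 0, 0, 0), 2, 2, byrow = TRUE,
                                dimnames = list(cat2$name, cat2$name)))
  q <- c(taxed_drink = 200, plain = 100)
  vols <- sapply(seq(0, 1.6, by = 0.2), function(tr) {
    consumption_shift(e, price_change(tax_scenario(tr), cat2), q)[["taxed_drink"]]
  })
  pre_floor <- vols[vols > 0]
  expect_true(all(diff(pre_floor) < 0))
  expect_equal(vols[length(vols)], 0)  # 160% tax x -1 elasticity floors demand
})

test_that("weighted group mean of energy change equals a per-individual loop", {
  pop <- small_generated_pop(n = 500, seed = 31)
  e <- default_elasticities(pop$catalogue)
  base <- as.matrix(pop$individuals[paste0("cons_", pop$catalogue$name)])
  colnames(base) <- pop$catalogue$name
  pct <- price_change(tax_scenario(0.25), pop$catalogue)
  ec <- energy_change(pop, consumption_shift(e, pct, base))

  # brute-force loop, one individual at a time
  loop_de <- vapply(seq_len(nrow(base)), function(i) {
    si <- consumption_shift(e, pct, base[i, ])
    sum((si - base[i, ]) * pop$catalogue$energy_density)
  }, numeric(1))
  expect_equal(ec$delta_e_kcal, loop_de, tolerance = 1e-12)

  w <- pop$individuals$survey_weight
  expect_equal(sum(w * ec$delta_e_kcal) / sum(w),
               weighted.mean(loop_de, w), tolerance = 1e-12)
})

test_that("elasticity CSV roundtrip preserves the matrix", {
  e <- default_elasticities()
  path <- withr::local_tempfile(fileext = ".csv")
  write_elasticity_csv(e, path)
  back <- read_elasticity_csv(path)
  expect_equal(unclass(back), unclass(e), tolerance = 1e-12,
               ignore_attr = "class")
})
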