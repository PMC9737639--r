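# Hand-built fixtures used across tests. All constructed in code so every
# expected value can be recomputed by eye.

# Wrap a hand-written individual table as an ssb_population.
fixture_population <- function(individuals, catalogue = default_catalogue()) {
  individuals$sex <- factor(as.character(individuals$sex),
                            levels = c("male", "female"))
  individuals$age_group <- factor(as.character(individuals$age_group),
                                  levels = c("20-29", "30-39", "40-49",
                                             "50-59", "60-69", "70+"))
  if (!"bmi" %in% names(individuals)) {
    individuals$bmi <- individuals$weight_kg / individuals$height_m^2
  }
  structure(list(individuals = individuals, catalogue = catalogue,
                 config = NULL, seed = 0L),
            class = "ssb_population")
}

# Two-category toy catalogue: one taxed 0.4 kcal/mL drink, one plain water.
toy_catalogue <- function() {
  beverage_catalogue(name = c("taxed_drink", "plain"),
                     energy_density = c(0.4, 0),
                     taxed = c(TRUE, FALSE))
}

# Ten adults with printed consumption values over the default 8-category
# catalogue; used for stage-composition and per-individual oracle checks.
ten_person_fixture <- function() {
  cat8 <- default_catalogue()
  cons <- matrix(c(
    # soda milk_sw sports other  milk  juice coffee water
      300,   0,     0,    50,     0,   100,   200,  500,
        0,  80,     0,     0,   200,     0,   400,  800,
      150,   0,    60,     0,     0,   250,   100,  300,
        0,   0,     0,     0,   300,   150,   500, 1000,
      600,  50,     0,   120,     0,     0,    50,  200,
       90,   0,     0,    30,   100,   200,   300,  600,
        0,   0,     0,     0,     0,     0,   250,  900,
      220,  40,    30,    60,    50,    80,   150,  400,
       40,   0,     0,    10,   250,   300,   350,  700,
      500,   0,    90,   200,     0,    50,     0,  100
  ), nrow = 10, byrow = TRUE, dimnames = list(NULL, cat8$name))
  ind <- tibble::tibble(
    id = 1:10,
    sex = rep(c("male", "female"), 5),
    age_group = c("20-29", "30-39", "20-29", "70+", "40-49",
                  "50-59", "60-69", "30-39", "70+", "20-29"),
    height_m = c(1.78, 1.62, 1.70, 1.55, 1.83, 1.60, 1.58, 1.75, 1.52, 1.80),
    weight_kg = c(82, 70, 95, 58, 110, 64, 55, 88, 73, 68),
    survey_weight = c(1.5, 2.0, 0.8, 1.2, 1.0, 2.5, 1.8, 0.9, 1.1, 1.6)
  )
  cons_df <- tibble::as_tibble(as.data.frame(cons))
  names(cons_df) <- paste0("cons_", cat8$name)
  fixture_population(dplyr::bind_cols(ind, cons_df), cat8)
}

# Small generated population shared by pipeline tests (cheap but realistic).
small_generated_pop <- function(n = 2000, seed = 11) {
  generate_population(population_config(n_individuals = n), seed = seed)
}
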