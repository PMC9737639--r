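#' Configuration for the synthetic adult population generator
#'
#' The generator emulates the joint structure a beverage-tax simulation
#' needs from national consumption and anthropometry surveys: per-person
#' daily beverage volumes by category, sex, six adult age bands, height,
#' weight and a survey expansion weight. Defaults are calibrated to the
#' published Brazilian adult baseline: overall SSB intake near 176 mL/day
#' (about 67 kcal/day), soft drinks near 65% of SSB volume, an age
#' gradient from 268.6 mL/day at ages 20--29 down to 105.5 mL/day at 70+,
#' male/female means near 208/153 mL/day, and non-sweetened caloric
#' beverages near 576 mL/day (about 153 kcal/day). Values not published at
#' stratum level (intermediate age bands, category zero-consumption rates,
#' dispersion, BMI and height distributions) are package defaults, not
#' survey facts, and every one is overridable here.
#'
#' Consumption is drawn per category from a zero-inflated gamma: a point
#' mass at zero (many adults report none of a given beverage on a one-day
#' recall) and a right-skewed gamma for consumers, with the stratum mean
#' matched exactly in expectation.
#'
#' BMI is drawn lognormally per sex with parameters solved in closed form
#' from two target exceedance probabilities, `P(BMI >= 25)` and
#' `P(BMI >= 30)`, so configured overweight/obesity prevalences are
#' reproduced in expectation. Height is normal per sex; weight is derived
#' as `BMI * height^2`. Consumption and BMI are independent by default.
#'
#' @param n_individuals Number of adults to draw.
#' @param catalogue A [beverage_catalogue()]; defaults to
#'   [default_catalogue()].
#' @param ssb_volume_overall,ssb_volume_age20_29,ssb_volume_age70plus
#'   Overall mean SSB volume (mL/day) and the two age-gradient anchors.
#'   Intermediate age-band means follow a monotone power interpolation
#'   between the anchors, with the exponent solved so the
#'   population-weighted mean equals `ssb_volume_overall`.
#' @param ssb_volume_male,ssb_volume_female Target mean SSB volume by sex;
#'   converted to multiplicative sex factors normalised within each age
#'   band (so age-band means are preserved across sexes).
#' @param ssb_shares Named shares of SSB volume per taxed category
#'   (must sum to 1). Default: soft drinks 65%, other sugary drinks 20%,
#'   sweetened milk drinks 10%, sports/energy drinks 5%.
#' @param nonsweet_volume_overall Mean volume of non-sweetened caloric
#'   beverages, excluding water (mL/day).
#' @param nonsweet_age_ramp Length-2 relative ramp (youngest, oldest) for
#'   non-sweetened caloric volume; increases with age (milk and coffee
#'   intake rise with age) and is rescaled to match the overall mean.
#' @param nonsweet_shares Named shares of non-sweetened caloric volume
#'   (milk, fruit juice, coffee/tea); fruit juice plus coffee/tea default
#'   to 94% of the caloric non-sweetened volume.
#' @param water_volume Mean plain-water volume (mL/day), age/sex flat.
#' @param zero_probability Named per-category probability of zero
#'   consumption on the recall day.
#' @param gamma_shape Gamma shape of the positive consumption part;
#'   the consumer-level coefficient of variation is `1/sqrt(gamma_shape)`.
#' @param age_shares Named population shares of the six age bands.
#' @param male_share Population share of men.
#' @param height_mean,height_sd Named (`male`, `female`) height
#'   distribution parameters in metres.
#' @param overweight_or_obese_prev,obesity_prev Named (`male`, `female`)
#'   target probabilities `P(BMI >= 25)` and `P(BMI >= 30)`; the obesity
#'   value must be strictly smaller within each sex.
#' @param total_population_scale Sum of survey weights, i.e. the adult
#'   population the sample expands to.
#' @param weight_cv_shape Gamma shape for the mildly heterogeneous survey
#'   weights (larger = more uniform).
#' @return A list of class `population_config`.
#' @export
population_config <- function(n_individuals = 50000,
                              catalogue = default_catalogue(),
                              ssb_volume_overall = 176,
                              ssb_volume_age20_29 = 268.6,
                              ssb_volume_age70plus = 105.5,
                              ssb_volume_male = 208,
                              ssb_volume_female = 153,
                              ssb_shares = c(soda = 0.65, other_ssb = 0.20,
                                             milk_sweetened = 0.10,
                                             sports_energy = 0.05),
                              nonsweet_volume_overall = 576,
                              nonsweet_age_ramp = c(450, 720),
                              nonsweet_shares = c(milk = 0.06,
                                                  fruit_juice = 0.30,
                                                  coffee_tea = 0.64),
                              water_volume = 800,
                              zero_probability = c(soda = 0.45,
                                                   milk_sweetened = 0.80,
                                                   sports_energy = 0.90,
                                                   other_ssb = 0.60,
                                                   milk = 0.60,
                                                   fruit_juice = 0.55,
                                                   coffee_tea = 0.15,
                                                   water = 0.05),
                              gamma_shape = 0.8,
                              age_shares = c("20-29" = 0.21, "30-39" = 0.21,
                                             "40-49" = 0.18, "50-59" = 0.15,
                                             "60-69" = 0.13, "70+" = 0.12),
                              male_share = 0.47,
                              height_mean = c(male = 1.73, female = 1.61),
                              height_sd = c(male = 0.07, female = 0.065),
                              overweight_or_obese_prev = c(male = 0.57,
                                                           female = 0.62),
                              obesity_prev = c(male = 0.22, female = 0.30),
                              total_population_scale = 152e6,
                              weight_cv_shape = 4) {
  if (!inherits(catalogue, "beverage_catalogue")) {
    abort("`catalogue` must be a beverage_catalogue.")
  }
  check_number(n_individuals, "n_individuals", min = 1)
  for (f in c("ssb_volume_overall", "ssb_volume_age20_29",
              "ssb_volume_age70plus", "ssb_volume_male", "ssb_volume_female",
              "nonsweet_volume_overall", "water_volume",
              "total_population_scale")) {
    check_number(get(f), f, min = 0)
  }
  check_number(gamma_shape, "gamma_shape", min = 0, allow_zero = FALSE)
  check_number(weight_cv_shape, "weight_cv_shape", min = 0, allow_zero = FALSE)
  check_probability(male_share, "male_share")
  if (length(nonsweet_age_ramp) != 2 || any(nonsweet_age_ramp < 0)) {
    abort("`nonsweet_age_ramp` must be two nonnegative numbers.")
  }

  if (!setequal(names(age_shares), AGE_LEVELS) ||
      abs(sum(age_shares) - 1) > 1e-8 || any(age_shares < 0)) {
    abort("`age_shares` must be nonnegative, named by the six age bands, and sum to 1.")
  }
  taxed_names <- ssb_category_names(catalogue)
  if (!setequal(names(ssb_shares), taxed_names) ||
      abs(sum(ssb_shares) - 1) > 1e-8 || any(ssb_shares < 0)) {
    abort("`ssb_shares` must be nonnegative, named by the taxed categories, and sum to 1.")
  }
  caloric_names <- nonsweet_caloric_names(catalogue)
  if (!setequal(names(nonsweet_shares), caloric_names) ||
      abs(sum(nonsweet_shares) - 1) > 1e-8 || any(nonsweet_shares < 0)) {
    abort("`nonsweet_shares` must be nonnegative, named by the untaxed caloric categories, and sum to 1.")
  }
  if (!all(catalogue$name %in% names(zero_probability))) {
    abort("`zero_probability` must name every catalogue category.")
  }
  for (nm in names(zero_probability)) {
    check_probability(zero_probability[[nm]], sprintf("zero_probability[%s]", nm))
  }
  for (sx in SEX_LEVELS) {
    check_probability(overweight_or_obese_prev[[sx]],
                      sprintf("overweight_or_obese_prev[%s]", sx))
    check_probability(obesity_prev[[sx]], sprintf("obesity_prev[%s]", sx))
    if (obesity_prev[[sx]] >= overweight_or_obese_prev[[sx]]) {
      abort(sprintf(
        "`obesity_prev[%s]` must be strictly below `overweight_or_obese_prev[%s]`.",
        sx, sx))
    }
    check_number(height_mean[[sx]], sprintf("height_mean[%s]", sx),
                 min = 0, allow_zero = FALSE)
    check_number(height_sd[[sx]], sprintf("height_sd[%s]", sx), min = 0)
  }

  structure(
    list(
      n_individuals = as.integer(n_individuals),
      catalogue = catalogue,
      ssb_volume_overall = ssb_volume_overall,
      ssb_volume_age20_29 = ssb_volume_age20_29,
      ssb_volume_age70plus = ssb_volume_age70plus,
      ssb_volume_male = ssb_volume_male,
      ssb_volume_female = ssb_volume_female,
      ssb_shares = ssb_shares[taxed_names],
      nonsweet_volume_overall = nonsweet_volume_overall,
      nonsweet_age_ramp = nonsweet_age_ramp,
      nonsweet_shares = nonsweet_shares[caloric_names],
      water_volume = water_volume,
      zero_probability = zero_probability[catalogue$name],
      gamma_shape = gamma_shape,
      age_shares = age_shares[AGE_LEVELS],
      male_share = male_share,
      height_mean = height_mean,
      height_sd = height_sd,
      overweight_or_obese_prev = overweight_or_obese_prev,
      obesity_prev = obesity_prev,
      total_population_scale = total_population_scale,
      weight_cv_shape = weight_cv_shape
    ),
    class = "population_config"
  )
}

# Monotone power interpolation of the SSB age gradient between the two
# anchors, with the exponent solved so the age-share-weighted mean hits the
# overall target. Returns the six age-band means (both sexes combined).
solve_age_gradient <- function(lo, hi, shares, overall) {
  if (hi == lo) {
    if (abs(overall - lo) > 1e-9) {
      abort("flat age anchors are incompatible with a different overall mean.")
    }
    return(rep(lo, 6L))
  }
  curve <- function(p) lo + (hi - lo) * ((6 - seq_len(6)) / 5)^p
  f <- function(p) sum(shares * curve(p)) - overall
  # p -> 0 piles mass at the young anchor; p -> inf at the old anchor.
  lo_p <- 1e-3
  hi_p <- 50
  if (f(lo_p) < 0 || f(hi_p) > 0) {
    abort(paste0("`ssb_volume_overall` is not attainable between the two age ",
                 "anchors under the configured `age_shares`."))
  }
  p <- uniroot(f, c(lo_p, hi_p), tol = 1e-10)$root
  curve(p)
}

#' Per-stratum target consumption means implied by a configuration
#'
#' Expands the overall targets, age anchors and sex ratios of a
#' [population_config()] into the full sex x age-band x category grid of
#' mean daily volumes the generator draws from. Sex factors are
#' normalised within age bands, so combined-sex age-band means equal the
#' interpolated age gradient, and the population-weighted grand mean
#' equals the configured overall targets exactly.
#'
#' @param config A `population_config`.
#' @return A tibble with columns `sex`, `age_group`, `category`,
#'   `mean_ml`.
#' @export
stratum_targets <- function(config) {
  stopifnot(inherits(config, "population_config"))
  cat <- config$catalogue
  age_means <- solve_age_gradient(config$ssb_volume_age70plus,
                                  config$ssb_volume_age20_29,
                                  config$age_shares,
                                  config$ssb_volume_overall)
  # Sex factors: ratio from the sex targets, normalised so the
  # share-weighted mean over sexes is 1 within every age band.
  ratio <- if (config$ssb_volume_female > 0) {
    config$ssb_volume_male / config$ssb_volume_female
  } else {
    1
  }
  sf_female <- 1 / (config$male_share * ratio + (1 - config$male_share))
  sex_factor <- c(male = sf_female * ratio, female = sf_female)

  ramp <- seq(config$nonsweet_age_ramp[1], config$nonsweet_age_ramp[2],
              length.out = 6L)
  ramp_mean <- sum(config$age_shares * ramp)
  nonsweet_means <- if (ramp_mean > 0) {
    ramp * config$nonsweet_volume_overall / ramp_mean
  } else {
    rep(0, 6L)
  }

  grid <- tidyr::expand_grid(sex = SEX_LEVELS, age_group = AGE_LEVELS,
                             category = cat$name)
  g <- match(grid$age_group, AGE_LEVELS)
  mean_ml <- numeric(nrow(grid))
  taxed <- cat$taxed[match(grid$category, cat$name)]
  is_water <- cat$energy_density[match(grid$category, cat$name)] == 0 & !taxed

  ssb_rows <- taxed
  mean_ml[ssb_rows] <- age_means[g[ssb_rows]] *
    sex_factor[grid$sex[ssb_rows]] *
    config$ssb_shares[grid$category[ssb_rows]]

  ns_rows <- !taxed & !is_water
  mean_ml[ns_rows] <- nonsweet_means[g[ns_rows]] *
    config$nonsweet_shares[grid$category[ns_rows]]

  mean_ml[is_water] <- config$water_volume

  grid$mean_ml <- unname(mean_ml)
  grid
}

# Lognormal BMI parameters from two exceedance targets:
# P(BMI >= 25) = p25, P(BMI >= 30) = p30 (p30 < p25).
solve_bmi_lognormal <- function(p25, p30) {
  z25 <- qnorm(1 - p25)
  z30 <- qnorm(1 - p30)
  sigma <- log(30 / 25) / (z30 - z25)
  mu <- log(25) - sigma * z25
  c(meanlog = mu, sdlog = sigma)
}

#' Generate a seeded synthetic adult population
#'
#' Draws `config$n_individuals` adults: sex, age band, height, weight
#' (via a per-sex lognormal BMI), a positive survey expansion weight
#' normalised to `config$total_population_scale`, and per-category daily
#' beverage volumes from a zero-inflated gamma whose stratum means match
#' [stratum_targets()] in expectation. The draw is fully reproducible:
#' identical `(config, seed)` give bit-identical populations, and the
#' caller's RNG state is left untouched.
#'
#' @param config A [population_config()].
#' @param seed Integer seed.
#' @return A list of class `ssb_population` with elements `individuals`
#'   (tibble: `id`, `sex`, `age_group`, `height_m`, `weight_kg`, `bmi`,
#'   `survey_weight`, one `cons_<category>` column per catalogue entry),
#'   `catalogue`, `config`, `seed`.
#' @examples
#' pop <- generate_population(population_config(n_individuals = 500), seed = 1)
#' baseline_summary(pop)
#' @export
generate_population <- function(config = population_config(), seed) {
  stopifnot(inherits(config, "population_config"))
  n <- config$n_individuals
  cat <- config$catalogue
  targets <- stratum_targets(config)

  individuals <- with_seed(seed, {
    sex <- factor(ifelse(stats::runif(n) < config$male_share, "male", "female"),
                  levels = SEX_LEVELS)
    age_group <- factor(sample(AGE_LEVELS, n, replace = TRUE,
                               prob = config$age_shares),
                        levels = AGE_LEVELS)

    height <- rnorm(n, mean = config$height_mean[as.character(sex)],
                    sd = config$height_sd[as.character(sex)])
    height <- pmax(height, 1.2)  # guard the extreme tail

    bmi <- numeric(n)
    for (sx in SEX_LEVELS) {
      idx <- which(sex == sx)
      par <- solve_bmi_lognormal(config$overweight_or_obese_prev[[sx]],
                                 config$obesity_prev[[sx]])
      bmi[idx] <- rlnorm(length(idx), par[["meanlog"]], par[["sdlog"]])
    }
    weight <- bmi * height^2
    bmi <- weight / height^2  # store the form the pipeline recomputes

    w <- rgamma(n, shape = config$weight_cv_shape,
                rate = config$weight_cv_shape)
    w <- w * config$total_population_scale / sum(w)

    cons <- matrix(0, nrow = n, ncol = nrow(cat),
                   dimnames = list(NULL, cat$name))
    stratum_key <- interaction(sex, age_group, drop = FALSE)
    tkey <- interaction(factor(targets$sex, SEX_LEVELS),
                        factor(targets$age_group, AGE_LEVELS), drop = FALSE)
    for (cname in cat$name) {
      p0 <- config$zero_probability[[cname]]
      trow <- targets[targets$category == cname, ]
      mlookup <- trow$mean_ml[match(stratum_key, tkey[targets$category == cname])]
      drinks <- stats::runif(n) >= p0
      pos_mean <- ifelse(drinks & mlookup > 0, mlookup / (1 - p0), 0)
      draw <- numeric(n)
      k <- config$gamma_shape
      on_rows <- which(pos_mean > 0)
      draw[on_rows] <- rgamma(length(on_rows), shape = k,
                              scale = pos_mean[on_rows] / k)
      cons[, cname] <- draw
    }

    out <- tibble::tibble(
      id = seq_len(n),
      sex = sex,
      age_group = age_group,
      height_m = height,
      weight_kg = weight,
      bmi = bmi,
      survey_weight = w
    )
    cons_df <- tibble::as_tibble(as.data.frame(cons))
    names(cons_df) <- paste0("cons_", cat$name)
    dplyr::bind_cols(out, cons_df)
  })

  structure(
    list(individuals = individuals, catalogue = cat,
         config = config, seed = as.integer(seed)),
    class = "ssb_population"
  )
}

#' @export
print.ssb_population <- function(x, ...) {
  cat(sprintf("<ssb_population> %d adults, %d beverage categories, seed %d\n",
              nrow(x$individuals), nrow(x$catalogue), x$seed))
  cat(sprintf("  expands to %.3g persons (sum of survey weights)\n",
              sum(x$individuals$survey_weight)))
  invisible(x)
}

# Consumption columns as an n x K matrix in catalogue order.
consumption_matrix <- function(pop) {
  stopifnot(inherits(pop, "ssb_population"))
  m <- as.matrix(pop$individuals[paste0("cons_", pop$catalogue$name)])
  colnames(m) <- pop$catalogue$name
  m
}

#' Write / read a population as delimited text
#'
#' The individual table goes to a UTF-8 CSV with a header row; consumption
#' columns keep their `cons_<category>` prefix. The catalogue (and, when
#' available, generator provenance) is written as YAML next to the CSV so
#' a population file is self-describing.
#'
#' @param pop An `ssb_population`.
#' @param path CSV destination.
#' @param meta_path YAML destination for catalogue + provenance; default
#'   replaces the CSV extension with `.yaml`. `NULL` skips it.
#' @return `path`, invisibly.
#' @export
write_population_csv <- function(pop, path, meta_path = sub("\\.csv$", ".yaml", path)) {
  stopifnot(inherits(pop, "ssb_population"))
  write.csv(pop$individuals, path, row.names = FALSE, fileEncoding = "UTF-8")
  if (!is.null(meta_path)) {
    meta <- list(
      catalogue = lapply(seq_len(nrow(pop$catalogue)), function(i) {
        list(name = pop$catalogue$name[i],
             energy_density = pop$catalogue$energy_density[i],
             taxed = pop$catalogue$taxed[i])
      }),
      seed = pop$seed,
      n_individuals = nrow(pop$individuals)
    )
    yaml::write_yaml(meta, meta_path)
  }
  invisible(path)
}

#' @rdname write_population_csv
#' @param catalogue Catalogue for the file being read; defaults to the
#'   catalogue recorded in the YAML sidecar when present, else
#'   [default_catalogue()].
#' @export
read_population_csv <- function(path, catalogue = NULL,
                                meta_path = sub("\\.csv$", ".yaml", path)) {
  if (is.null(catalogue) && !is.null(meta_path) && file.exists(meta_path)) {
    meta <- yaml::read_yaml(meta_path)
    catalogue <- beverage_catalogue(
      name = vapply(meta$catalogue, `[[`, character(1), "name"),
      energy_density = vapply(meta$catalogue, `[[`, numeric(1), "energy_density"),
      taxed = vapply(meta$catalogue, `[[`, logical(1), "taxed")
    )
  }
  if (is.null(catalogue)) catalogue <- default_catalogue()
  ind <- tibble::as_tibble(read.csv(path, fileEncoding = "UTF-8"))
  need <- c("id", "sex", "age_group", "height_m", "weight_kg", "survey_weight",
            paste0("cons_", catalogue$name))
  missing <- setdiff(need, names(ind))
  if (length(missing)) {
    abort(sprintf("population file lacks columns: %s",
                  paste(missing, collapse = ", ")))
  }
  ind$sex <- factor(ind$sex, levels = SEX_LEVELS)
  ind$age_group <- factor(ind$age_group, levels = AGE_LEVELS)
  if (!"bmi" %in% names(ind)) ind$bmi <- ind$weight_kg / ind$height_m^2
  structure(list(individuals = ind, catalogue = catalogue,
                 config = NULL, seed = NA_integer_),
            class = "ssb_population")
}
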