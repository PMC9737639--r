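#' Assemble an end-to-end run configuration
#'
#' Bundles everything one simulation run needs: the population (an
#' existing [generate_population()] object, a [population_config()] to
#' generate from, or a CSV path), the elasticity matrix, the tax
#' scenarios, weight-model and bootstrap parameters, and a master seed.
#' Per-stage seeds are derived from the master seed by fixed offsets
#' (population: `seed + 1000`; bootstrap: `seed + 2000`) so each stage is
#' independently reproducible.
#'
#' @param population An `ssb_population`, a `population_config`, or a
#'   path to a population CSV.
#' @param elasticities An [elasticity_matrix()]; `NULL` uses
#'   [default_elasticities()] over the population's catalogue.
#' @param scenarios List of [tax_scenario()]s; at least one. Defaults to
#'   the three headline scenarios (20/25/30%, full pass-through).
#' @param weight_model A [weight_model_params()].
#' @param bootstrap_replicates Bootstrap replicates for table confidence
#'   intervals; 0 disables CIs.
#' @param demand_form `"linear"` or `"log"`, see [consumption_shift()].
#' @param seed Master integer seed.
#' @param verbose Emit per-stage summaries to stderr.
#' @return A list of class `run_config`.
#' @export
run_config <- function(population,
                       elasticities = NULL,
                       scenarios = list(tax_scenario(0.20),
                                        tax_scenario(0.25),
                                        tax_scenario(0.30)),
                       weight_model = weight_model_params(),
                       bootstrap_replicates = 500,
                       demand_form = c("linear", "log"),
                       seed = 1,
                       verbose = TRUE) {
  demand_form <- match.arg(demand_form)
  if (length(scenarios) == 0) abort("`scenarios` must hold at least one tax_scenario.")
  if (inherits(scenarios, "tax_scenario")) scenarios <- list(scenarios)
  for (s in scenarios) {
    if (!inherits(s, "tax_scenario")) abort("`scenarios` must be tax_scenario objects.")
  }
  if (!(inherits(population, "ssb_population") ||
        inherits(population, "population_config") ||
        (is.character(population) && length(population) == 1L))) {
    abort("`population` must be an ssb_population, a population_config, or a CSV path.")
  }
  if (is.character(population) && !file.exists(population)) {
    abort(sprintf("population file not found: %s", population))
  }
  check_number(bootstrap_replicates, "bootstrap_replicates", min = 0)
  stopifnot(inherits(weight_model, "weight_model_params"))
  structure(list(population = population, elasticities = elasticities,
                 scenarios = scenarios, weight_model = weight_model,
                 bootstrap_replicates = as.integer(bootstrap_replicates),
                 demand_form = demand_form, seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "run_config")
}

resolve_population <- function(config) {
  pop <- config$population
  if (inherits(pop, "ssb_population")) return(pop)
  if (inherits(pop, "population_config")) {
    return(generate_population(pop, seed = config$seed + 1000L))
  }
  read_population_csv(pop)
}

resolve_elasticities <- function(config, catalogue) {
  e <- config$elasticities
  if (is.null(e)) return(default_elasticities(catalogue))
  if (is.character(e)) e <- read_elasticity_csv(e)
  if (!identical(rownames(e), catalogue$name)) {
    abort("elasticity matrix category order does not match the population catalogue.")
  }
  e
}

run_log <- function(config, stage, fmt, ...) {
  if (isTRUE(config$verbose)) {
    message(sprintf("[ssbtax:%s] %s", stage, sprintf(fmt, ...)))
  }
}

# --- stratum aggregation machinery -----------------------------------------

# The 12 elementary sex x age cells, in a fixed order.
stratum_cells <- function() {
  tidyr::expand_grid(sex = SEX_LEVELS, age_group = AGE_LEVELS)
}

# Integer cell id per individual (1..12).
cell_id <- function(sex, age) {
  cells <- stratum_cells()
  match(paste(as.character(sex), as.character(age)),
        paste(cells$sex, cells$age_group))
}

# 15 x 12 membership matrix mapping reporting strata to elementary cells.
stratum_membership <- function() {
  defs <- stratum_definitions()
  cells <- stratum_cells()
  S <- matrix(FALSE, nrow(defs), nrow(cells))
  for (i in seq_len(nrow(defs))) {
    sel <- rep(TRUE, nrow(cells))
    if (defs$sex[i] != "all") sel <- sel & cells$sex == defs$sex[i]
    if (defs$age_group[i] != "all") sel <- sel & cells$age_group == defs$age_group[i]
    S[i, ] <- sel
  }
  storage.mode(S) <- "double"
  S
}

# Sum x within each of the 12 cells (cells absent from g contribute 0).
cell_sums <- function(x, g) {
  as.numeric(rowsum(c(x, numeric(12)), c(g, 1:12)))
}

# --- scenario execution -----------------------------------------------------

#' Run one tax scenario end to end
#'
#' Executes the pipeline demand model -> energy change -> weight/BMI
#' change -> prevalence outcomes on the configured population, and
#' assembles the three report tables (per-stratum mean energy change,
#' mean BMI change, and prevalence change) with percentile-bootstrap
#' confidence intervals. Deterministic given `(config, scenario)`.
#'
#' @param config A [run_config()].
#' @param scenario A [tax_scenario()]; defaults to the first scenario in
#'   the config.
#' @return A list of class `scenario_result` with elements `scenario`,
#'   `energy`, `bmi`, `prevalence` (tibbles), `individual_effects`
#'   (per-person deltas), `n_clamped`, and run metadata.
#' @export
run_scenario <- function(config, scenario = config$scenarios[[1]]) {
  stopifnot(inherits(config, "run_config"), inherits(scenario, "tax_scenario"))
  pop <- withCallingHandlers(
    resolve_population(config),
    error = function(e) abort(paste0("[population] ", conditionMessage(e)))
  )
  elast <- withCallingHandlers(
    resolve_elasticities(config, pop$catalogue),
    error = function(e) abort(paste0("[elasticities] ", conditionMessage(e)))
  )
  run_log(config, "population", "%d adults, expands to %.4g persons",
          nrow(pop$individuals), sum(pop$individuals$survey_weight))

  pct <- price_change(scenario, pop$catalogue)
  run_log(config, "demand", "scenario %s: price change %+.1f%% on {%s}",
          scenario$label, max(pct), paste(names(pct)[pct != 0], collapse = ", "))

  base_cons <- consumption_matrix(pop)
  shifted <- consumption_shift(elast, pct, base_cons, form = config$demand_form)
  n_floored <- sum(shifted == 0 & base_cons > 0)
  if (n_floored > 0) {
    run_log(config, "demand", "%d consumption entries floored at zero", n_floored)
  }
  ec <- energy_change(pop, shifted)
  run_log(config, "energy", "mean unweighted energy change %+.3f kcal/day",
          mean(ec$delta_e_kcal))

  wm <- config$weight_model
  dw_ss <- steady_state_weight_change(ec$delta_e_kcal, wm)
  dw <- weight_change_at_horizon(dw_ss, scenario$horizon_years, wm)
  wo <- apply_weight_change(pop$individuals, dw, wm)
  run_log(config, "weight", "mean weight change %+.4f kg at %g y (%d clamped)",
          mean(wo$delta_w_kg), scenario$horizon_years, attr(wo, "clamped"))

  ind <- pop$individuals
  effects <- tibble::tibble(
    id = ind$id, sex = ind$sex, age_group = ind$age_group,
    survey_weight = ind$survey_weight,
    delta_e_kcal = ec$delta_e_kcal,
    delta_w_kg = wo$delta_w_kg,
    bmi_pre = wo$bmi_pre, bmi_post = wo$bmi_post
  )

  tables <- scenario_tables(effects)
  if (config$bootstrap_replicates > 0) {
    tables <- add_bootstrap_cis(tables, effects,
                                B = config$bootstrap_replicates,
                                seed = config$seed + 2000L)
  }
  run_log(config, "outcomes",
          "overall mean dE %+.3f kcal/day, mean dBMI %+.4f kg/m^2",
          tables$energy$mean_delta_e_kcal[1], tables$bmi$mean_delta_bmi[1])

  structure(list(scenario = scenario,
                 energy = tables$energy, bmi = tables$bmi,
                 prevalence = tables$prevalence,
                 individual_effects = effects,
                 n_clamped = attr(wo, "clamped"),
                 demand_form = config$demand_form,
                 weight_model = wm,
                 bootstrap_replicates = config$bootstrap_replicates,
                 seed = config$seed),
            class = "scenario_result")
}

# Point-estimate tables over the 15 reporting strata.
scenario_tables <- function(effects) {
  defs <- stratum_definitions()
  S <- stratum_membership()
  g <- cell_id(effects$sex, effects$age_group)
  w <- effects$survey_weight

  den <- as.numeric(S %*% cell_sums(w, g))
  nn <- as.numeric(S %*% cell_sums(rep(1, length(g)), g))
  mean_of <- function(v) as.numeric(S %*% cell_sums(v * w, g)) / den

  energy <- dplyr::bind_cols(defs, tibble::tibble(
    n = as.integer(nn), population = den,
    mean_delta_e_kcal = mean_of(effects$delta_e_kcal)
  ))
  bmi <- dplyr::bind_cols(defs, tibble::tibble(
    n = as.integer(nn), population = den,
    mean_delta_bmi = mean_of(effects$bmi_post - effects$bmi_pre)
  ))

  prev <- lapply(PREVALENCE_MEASURES, function(m) {
    pre <- 100 * as.numeric(S %*% cell_sums(w * bmi_indicator(effects$bmi_pre, m), g)) / den
    post <- 100 * as.numeric(S %*% cell_sums(w * bmi_indicator(effects$bmi_post, m), g)) / den
    dplyr::bind_cols(defs, tibble::tibble(
      measure = m, population = den,
      prevalence_pre = pre, prevalence_post = post,
      relative_change_pct = ifelse(pre == 0, NA_real_, 100 * (post - pre) / pre),
      count_change = den * (post - pre) / 100
    ))
  })
  list(energy = energy, bmi = bmi, prevalence = dplyr::bind_rows(prev))
}

# Percentile-bootstrap CIs for every table statistic, from one shared set
# of resamples so the tables are coherent.
add_bootstrap_cis <- function(tables, effects, B, seed) {
  n <- nrow(effects)
  S <- stratum_membership()
  g0 <- cell_id(effects$sex, effects$age_group)
  w0 <- effects$survey_weight
  de <- effects$delta_e_kcal
  dbmi <- effects$bmi_post - effects$bmi_pre
  pre_ind <- lapply(PREVALENCE_MEASURES, bmi_indicator, bmi = effects$bmi_pre)
  post_ind <- lapply(PREVALENCE_MEASURES, bmi_indicator, bmi = effects$bmi_post)

  n_strata <- nrow(S)
  reps_e <- matrix(NA_real_, n_strata, B)
  reps_b <- matrix(NA_real_, n_strata, B)
  reps_p <- lapply(PREVALENCE_MEASURES, function(m) matrix(NA_real_, n_strata, B))

  with_seed(seed, {
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      g <- g0[idx]; w <- w0[idx]
      den <- as.numeric(S %*% cell_sums(w, g))
      reps_e[, b] <- as.numeric(S %*% cell_sums(w * de[idx], g)) / den
      reps_b[, b] <- as.numeric(S %*% cell_sums(w * dbmi[idx], g)) / den
      for (m in seq_along(PREVALENCE_MEASURES)) {
        pre <- 100 * as.numeric(S %*% cell_sums(w * pre_ind[[m]][idx], g)) / den
        post <- 100 * as.numeric(S %*% cell_sums(w * post_ind[[m]][idx], g)) / den
        reps_p[[m]][, b] <- ifelse(pre == 0, NA_real_, 100 * (post - pre) / pre)
      }
    }
  })

  ci <- function(m) {
    t(apply(m, 1L, quantile, probs = c(0.025, 0.975), na.rm = TRUE, names = FALSE))
  }
  eci <- ci(reps_e); bci <- ci(reps_b)
  tables$energy$ci_low <- eci[, 1]; tables$energy$ci_high <- eci[, 2]
  tables$bmi$ci_low <- bci[, 1]; tables$bmi$ci_high <- bci[, 2]
  pci <- lapply(reps_p, ci)
  tables$prevalence$ci_low <- NA_real_
  tables$prevalence$ci_high <- NA_real_
  for (m in seq_along(PREVALENCE_MEASURES)) {
    rows <- tables$prevalence$measure == PREVALENCE_MEASURES[m]
    tables$prevalence$ci_low[rows] <- pci[[m]][, 1]
    tables$prevalence$ci_high[rows] <- pci[[m]][, 2]
  }
  tables
}

#' @export
print.scenario_result <- function(x, ...) {
  ov_e <- x$energy$mean_delta_e_kcal[1]
  ov_b <- x$bmi$mean_delta_bmi[1]
  cat(sprintf("<scenario_result> %s (%s demand form)\n",
              x$scenario$label, x$demand_form))
  cat(sprintf("  overall mean energy change: %+.2f kcal/day\n", ov_e))
  cat(sprintf("  overall mean BMI change:    %+.4f kg/m^2 at %g y\n",
              ov_b, x$scenario$horizon_years))
  ob <- x$prevalence[x$prevalence$sex == "all" & x$prevalence$age_group == "all" &
                       x$prevalence$measure == "obese", ]
  cat(sprintf("  obesity prevalence: %.2f%% -> %.2f%% (relative %+.2f%%)\n",
              ob$prevalence_pre, ob$prevalence_post, ob$relative_change_pct))
  invisible(x)
}

#' Pass-through sensitivity analysis
#'
#' Re-runs every configured scenario at each supplied pass-through rate
#' and compares overall outcomes against the full (100%) pass-through
#' reference. Under the default linear demand form, individual energy
#' changes scale exactly with the pass-through rate.
#'
#' @param config A [run_config()].
#' @param pass_through_values Values in `(0, 1]`; default `c(1, 0.8)`.
#' @return A list of class `sensitivity_result`: `results` (nested list,
#'   `results[[pass_through]][[scenario_label]]`) and `comparison`, a
#'   tibble of overall mean energy/BMI change per scenario and
#'   pass-through with deltas versus the reference.
#' @export
run_sensitivity <- function(config, pass_through_values = c(1, 0.8)) {
  stopifnot(inherits(config, "run_config"))
  if (any(pass_through_values <= 0 | pass_through_values > 1)) {
    abort("`pass_through_values` must lie in (0, 1].")
  }
  pts <- unique(c(1, pass_through_values))  # reference first
  results <- list()
  rows <- list()
  for (pt in pts) {
    key <- sprintf("pt%g", 100 * pt)
    results[[key]] <- list()
    for (s in config$scenarios) {
      s2 <- tax_scenario(s$tax_rate, pass_through = pt,
                         taxed_categories = s$taxed_categories,
                         horizon_years = s$horizon_years)
      res <- run_scenario(config, s2)
      results[[key]][[s2$label]] <- res
      rows[[length(rows) + 1L]] <- tibble::tibble(
        tax_rate = s$tax_rate, pass_through = pt,
        mean_delta_e_kcal = res$energy$mean_delta_e_kcal[1],
        mean_delta_bmi = res$bmi$mean_delta_bmi[1]
      )
    }
  }
  comparison <- dplyr::bind_rows(rows)
  ref <- comparison[comparison$pass_through == 1,
                    c("tax_rate", "mean_delta_e_kcal", "mean_delta_bmi")]
  names(ref)[2:3] <- c("ref_delta_e_kcal", "ref_delta_bmi")
  comparison <- dplyr::left_join(comparison, ref, by = "tax_rate")
  comparison$delta_vs_ref_e <- comparison$mean_delta_e_kcal - comparison$ref_delta_e_kcal
  comparison$delta_vs_ref_bmi <- comparison$mean_delta_bmi - comparison$ref_delta_bmi
  keep <- comparison$pass_through %in% pass_through_values
  structure(list(results = results, comparison = comparison[keep, ]),
            class = "sensitivity_result")
}

#' Write scenario report files
#'
#' One energy, one BMI and one prevalence CSV per scenario (named by the
#' scenario label) plus a JSON summary of the overall rows. Refuses to
#' overwrite existing report files unless `force = TRUE`.
#'
#' @param results A `scenario_result` or a list of them.
#' @param dir Output directory (created if missing).
#' @param force Overwrite existing report files.
#' @return Character vector of files written, invisibly.
#' @export
render_reports <- function(results, dir, force = FALSE) {
  if (inherits(results, "scenario_result")) results <- list(results)
  if (length(results) == 0) abort("`results` must hold at least one scenario_result.")
  for (r in results) {
    if (!inherits(r, "scenario_result")) abort("`results` must be scenario_result objects.")
  }
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("cannot create output directory: %s", dir))
  }
  if (file.access(dir, mode = 2) != 0) {
    abort(sprintf("output directory is not writable: %s", dir))
  }
  planned <- unlist(lapply(results, function(r) {
    file.path(dir, paste0(r$scenario$label,
                          c("_energy.csv", "_bmi.csv", "_prevalence.csv",
                            "_summary.json")))
  }))
  existing <- planned[file.exists(planned)]
  if (length(existing) && !force) {
    abort(sprintf("report files already exist (use force = TRUE): %s",
                  paste(basename(existing), collapse = ", ")))
  }
  written <- character(0)
  for (r in results) {
    lab <- r$scenario$label
    f_e <- file.path(dir, paste0(lab, "_energy.csv"))
    f_b <- file.path(dir, paste0(lab, "_bmi.csv"))
    f_p <- file.path(dir, paste0(lab, "_prevalence.csv"))
    f_j <- file.path(dir, paste0(lab, "_summary.json"))
    write.csv(r$energy, f_e, row.names = FALSE)
    write.csv(r$bmi, f_b, row.names = FALSE)
    write.csv(r$prevalence, f_p, row.names = FALSE)
    ov <- function(df) df[df$sex == "all" & df$age_group == "all", ]
    summary <- list(
      scenario = list(label = lab, tax_rate = r$scenario$tax_rate,
                      pass_through = r$scenario$pass_through,
                      horizon_years = r$scenario$horizon_years),
      overall = list(
        mean_delta_e_kcal = ov(r$energy)$mean_delta_e_kcal,
        mean_delta_bmi = ov(r$bmi)$mean_delta_bmi,
        prevalence = ov(r$prevalence)[c("measure", "prevalence_pre",
                                        "prevalence_post",
                                        "relative_change_pct", "count_change")]
      )
    )
    jsonlite::write_json(summary, f_j, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    written <- c(written, f_e, f_b, f_p, f_j)
  }
  invisible(written)
}

#' Bar chart of relative prevalence change by stratum
#'
#' Mirrors the usual presentation of prevalence impacts: one bar per sex
#' x age band, faceted by measure, for a single scenario result.
#' Requires ggplot2.
#'
#' @param result A `scenario_result`.
#' @param measures Measures to show.
#' @return A ggplot object.
#' @export
plot_prevalence_change <- function(result,
                                   measures = c("overweight", "obese")) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    abort("ggplot2 is required for plotting.")
  }
  stopifnot(inherits(result, "scenario_result"))
  df <- result$prevalence
  df <- df[df$measure %in% measures & df$sex != "all" & df$age_group != "all", ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age_group,
                                   y = .data$relative_change_pct,
                                   fill = .data$sex)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::facet_wrap(~measure) +
    ggplot2::labs(x = "age group",
                  y = "relative prevalence change (%)",
                  title = result$scenario$label) +
    ggplot2::theme_minimal()
}

#' Read a run configuration from YAML
#'
#' Sections: `population` (either `csv: <path>` or [population_config()]
#' arguments), `elasticities` (`csv: <path>` or omitted for the default
#' matrix), `scenarios` (list of [tax_scenario()] arguments),
#' `weight_model` ([weight_model_params()] arguments),
#' `bootstrap_replicates`, `demand_form`, `seed`.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  pop <- if (!is.null(y$population$csv)) {
    y$population$csv
  } else {
    args <- y$population
    args <- args[intersect(names(args), names(formals(population_config)))]
    do.call(population_config, args)
  }
  elast <- if (!is.null(y$elasticities$csv)) {
    read_elasticity_csv(y$elasticities$csv)
  } else {
    NULL
  }
  scenarios <- if (is.null(y$scenarios)) {
    eval(formals(run_config)$scenarios)
  } else {
    lapply(y$scenarios, function(s) do.call(tax_scenario, s))
  }
  wm <- if (is.null(y$weight_model)) {
    weight_model_params()
  } else {
    do.call(weight_model_params,
            y$weight_model[intersect(names(y$weight_model),
                                     names(formals(weight_model_params)))])
  }
  run_config(population = pop, elasticities = elast, scenarios = scenarios,
             weight_model = wm,
             bootstrap_replicates = y$bootstrap_replicates %||% 500,
             demand_form = y$demand_form %||% "linear",
             seed = y$seed %||% 1,
             verbose = y$verbose %||% TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
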