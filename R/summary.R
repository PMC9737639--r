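#' Survey-weighted baseline consumption summary
#'
#' Weighted mean daily volume (mL) and energy (kcal) per beverage
#' category, plus SSB-group and non-sweetened-caloric-group totals, by
#' sex, by age band, by sex x age band, and overall. Energy is volume
#' times the category energy density; the non-sweetened group excludes
#' water (zero energy density) to match the caloric-beverage convention.
#' The soft-drink share column reports the weighted soft-drink volume as
#' a percentage of the weighted SSB volume.
#'
#' @param pop An `ssb_population` (or anything with the same shape, e.g.
#'   from [read_population_csv()]).
#' @return A tibble: one row per stratum (`sex` and/or `age_group` equal
#'   to `"all"` for marginals), columns `n`, `population`, one
#'   `vol_<category>` per catalogue entry, `ssb_volume`, `ssb_kcal`,
#'   `nonsweet_volume`, `nonsweet_kcal`, `soft_drink_share_pct`.
#' @export
baseline_summary <- function(pop) {
  stopifnot(inherits(pop, "ssb_population"))
  ind <- pop$individuals
  if (nrow(ind) == 0) abort("population is empty.")
  cat <- pop$catalogue
  cons <- consumption_matrix(pop)

  ssb <- ssb_category_names(cat)
  nonsweet <- nonsweet_caloric_names(cat)
  dens <- stats::setNames(cat$energy_density, cat$name)

  per <- tibble::tibble(
    sex = as.character(ind$sex),
    age_group = as.character(ind$age_group),
    w = ind$survey_weight,
    ssb_volume = rowSums(cons[, ssb, drop = FALSE]),
    ssb_kcal = as.numeric(cons[, ssb, drop = FALSE] %*% dens[ssb]),
    nonsweet_volume = rowSums(cons[, nonsweet, drop = FALSE]),
    nonsweet_kcal = as.numeric(cons[, nonsweet, drop = FALSE] %*% dens[nonsweet]),
    soda_volume = if ("soda" %in% colnames(cons)) cons[, "soda"] else NA_real_
  )
  volcols <- tibble::as_tibble(as.data.frame(cons))
  names(volcols) <- paste0("vol_", cat$name)
  per <- dplyr::bind_cols(per, volcols)

  summarise_group <- function(df) {
    dplyr::summarise(
      df,
      n = dplyr::n(),
      population = sum(.data$w),
      dplyr::across(dplyr::all_of(c(paste0("vol_", cat$name),
                                    "ssb_volume", "ssb_kcal",
                                    "nonsweet_volume", "nonsweet_kcal")),
                    ~ weighted_mean(.x, .data$w)),
      soft_drink_share_pct = 100 * sum(.data$soda_volume * .data$w) /
        sum(.data$ssb_volume * .data$w),
      .groups = "drop"
    )
  }

  overall <- summarise_group(per) |>
    dplyr::mutate(sex = "all", age_group = "all", .before = 1)
  by_sex <- per |> dplyr::group_by(.data$sex) |> summarise_group() |>
    dplyr::mutate(age_group = "all", .after = "sex")
  by_age <- per |> dplyr::group_by(.data$age_group) |> summarise_group() |>
    dplyr::mutate(sex = "all", .before = 1)
  by_both <- per |> dplyr::group_by(.data$sex, .data$age_group) |>
    summarise_group()

  dplyr::bind_rows(overall, by_sex, by_age, by_both)
}
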