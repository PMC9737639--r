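#' Build a beverage catalogue
#'
#' A catalogue is the ordered list of beverage categories the simulation
#' works over. Each category carries an energy density (kcal per mL) and a
#' flag saying whether the tax applies to it. Consumption vectors, the
#' elasticity matrix and price-change vectors are all indexed by catalogue
#' order, so the order is part of the contract.
#'
#' @param name Character vector of unique category labels.
#' @param energy_density Numeric vector, kcal per mL, all `>= 0`. Zero is
#'   valid (water).
#' @param taxed Logical vector marking the categories the tax applies to.
#' @return A tibble of class `beverage_catalogue` with columns `name`,
#'   `energy_density`, `taxed`.
#' @seealso [default_catalogue()]
#' @export
beverage_catalogue <- function(name, energy_density, taxed) {
  if (length(name) == 0) abort("a catalogue needs at least one category.")
  if (anyDuplicated(name)) {
    abort(sprintf("`name` must be unique; duplicated: %s",
                  paste(unique(name[duplicated(name)]), collapse = ", ")))
  }
  if (length(energy_density) != length(name) || length(taxed) != length(name)) {
    abort("`name`, `energy_density` and `taxed` must have equal length.")
  }
  if (!is.numeric(energy_density) || any(!is.finite(energy_density)) ||
      any(energy_density < 0)) {
    abort("`energy_density` must be finite and >= 0 (kcal/mL).")
  }
  if (!is.logical(taxed) || anyNA(taxed)) abort("`taxed` must be TRUE/FALSE.")
  out <- tibble::tibble(
    name = as.character(name),
    energy_density = as.numeric(energy_density),
    taxed = taxed
  )
  class(out) <- c("beverage_catalogue", class(out))
  out
}

#' Default eight-category beverage catalogue
#'
#' Four sugar-sweetened beverage (SSB) classes — soft drinks, sweetened
#' milk drinks, sports/energy drinks, other sugary drinks — all taxed by
#' default, plus the four untaxed substitution categories: milk, fruit
#' juice, coffee/tea, and water.
#'
#' Energy densities are package defaults, calibrated so that the default
#' synthetic population's category volume mix reproduces the Brazilian
#' adult baseline of roughly 176 mL/day of SSBs carrying about 67 kcal/day
#' (average near 0.38 kcal/mL) and 576 mL/day of non-sweetened caloric
#' beverages carrying about 153 kcal/day (average near 0.27 kcal/mL). Each
#' density can be overridden by building a custom catalogue.
#'
#' @return A `beverage_catalogue` with 8 rows; exactly 4 are taxed.
#' @examples
#' default_catalogue()
#' @export
default_catalogue <- function() {
  beverage_catalogue(
    name = c("soda", "milk_sweetened", "sports_energy", "other_ssb",
             "milk", "fruit_juice", "coffee_tea", "water"),
    energy_density = c(0.37, 0.60, 0.35, 0.32,
                       0.61, 0.45, 0.15, 0.00),
    taxed = c(TRUE, TRUE, TRUE, TRUE,
              FALSE, FALSE, FALSE, FALSE)
  )
}

# Names of the SSB (taxed-by-default) classes in the default catalogue.
ssb_category_names <- function(catalogue) {
  catalogue$name[catalogue$taxed]
}

# Non-sweetened caloric categories: untaxed with positive energy density
# (water is excluded from "caloric beverage" summaries).
nonsweet_caloric_names <- function(catalogue) {
  catalogue$name[!catalogue$taxed & catalogue$energy_density > 0]
}
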