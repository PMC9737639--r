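#' Own- and cross-price demand elasticity matrix
#'
#' Entry `(j, i)` is the percentage change in demand for category `j` per
#' 1% change in the price of category `i`: the diagonal holds own-price
#' elasticities (economically expected to be negative), off-diagonal
#' entries cross-price elasticities (positive values mean substitution
#' toward `j` when `i` gets dearer). Row and column order must match the
#' beverage catalogue the population uses.
#'
#' @param values Square numeric matrix (K x K).
#' @param categories Character vector of K category names, in catalogue
#'   order; defaults to the dimnames of `values`.
#' @return A matrix of class `elasticity_matrix` with dimnames set.
#' @seealso [default_elasticities()], [read_elasticity_csv()]
#' @export
elasticity_matrix <- function(values, categories = rownames(values)) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) abort("elasticity matrix must be square.")
  if (is.null(categories) || length(categories) != nrow(values)) {
    abort("`categories` must name every row/column of the matrix.")
  }
  if (anyDuplicated(categories)) abort("category names must be unique.")
  if (any(!is.finite(values))) abort("elasticities must be finite.")
  storage.mode(values) <- "double"
  dimnames(values) <- list(categories, categories)
  pos_own <- diag(values) > 0
  if (any(pos_own)) {
    warn(sprintf("positive own-price elasticity for: %s",
                 paste(categories[pos_own], collapse = ", ")))
  }
  class(values) <- c("elasticity_matrix", class(values))
  values
}

#' Illustrative default elasticity matrix
#'
#' The elasticities estimated for the Brazilian beverage demand system
#' are not published at category level, so this matrix is an illustrative
#' stand-in, not an estimate: own-price elasticity -1.0 for every taxed
#' SSB class, own-price -0.7 for untaxed categories, a total cross-price
#' substitution of +0.7 from the taxed group spread evenly over the three
#' untaxed caloric beverages (milk, fruit juice, coffee/tea; +0.175 each
#' per taxed category) and a small +0.05 total toward water. Under a 20%
#' fully passed-through tax it reproduces the published overall
#' energy-balance regime (taxed intake falls, substitution overshoots,
#' net daily energy change near +8 kcal). Replication of the original
#' results requires supplying the estimated matrix via
#' [elasticity_matrix()] or [read_elasticity_csv()].
#'
#' @param catalogue A [beverage_catalogue()].
#' @return An `elasticity_matrix` over the catalogue's categories.
#' @export
default_elasticities <- function(catalogue = default_catalogue()) {
  k <- nrow(catalogue)
  e <- matrix(0, k, k, dimnames = list(catalogue$name, catalogue$name))
  taxed <- catalogue$name[catalogue$taxed]
  caloric <- nonsweet_caloric_names(catalogue)
  water <- setdiff(catalogue$name[!catalogue$taxed], caloric)
  diag(e) <- ifelse(catalogue$taxed, -1.0, -0.7)
  e[caloric, taxed] <- 0.7 / length(taxed)
  if (length(water)) e[water, taxed] <- 0.05 / length(taxed)
  elasticity_matrix(e)
}

#' Read / write an elasticity matrix as CSV
#'
#' Plain CSV with category names in the header row and first column;
#' entry `(j, i)` in row `j`, column `i`.
#'
#' @param path File path.
#' @export
read_elasticity_csv <- function(path) {
  df <- read.csv(path, row.names = 1, check.names = FALSE)
  elasticity_matrix(as.matrix(df), categories = rownames(df))
}

#' @rdname read_elasticity_csv
#' @param e An `elasticity_matrix`.
#' @export
write_elasticity_csv <- function(e, path) {
  write.csv(as.data.frame(unclass(e)), path, row.names = TRUE)
  invisible(path)
}

#' Define a tax scenario
#'
#' @param tax_rate Ad-valorem tax as a fraction (0.20 = 20%).
#' @param pass_through Fraction of the tax reaching the retail price, in
#'   `[0, 1]`; 1 is full pass-through, 0.8 the usual partial-competition
#'   sensitivity value.
#' @param taxed_categories Category names the tax applies to; defaults to
#'   the catalogue's taxed flags at evaluation time (`NULL`).
#' @param horizon_years Evaluation horizon for the weight model; default
#'   3 years.
#' @param label Optional scenario label for reports; defaults to e.g.
#'   `"tax20_pt100"`.
#' @return A list of class `tax_scenario`.
#' @export
tax_scenario <- function(tax_rate, pass_through = 1,
                         taxed_categories = NULL, horizon_years = 3,
                         label = NULL) {
  check_number(tax_rate, "tax_rate", min = 0)
  check_number(pass_through, "pass_through", min = 0, max = 1)
  check_number(horizon_years, "horizon_years", min = 0)
  if (is.null(label)) {
    label <- sprintf("tax%g_pt%g", 100 * tax_rate, 100 * pass_through)
  }
  structure(list(tax_rate = tax_rate, pass_through = pass_through,
                 taxed_categories = taxed_categories,
                 horizon_years = horizon_years, label = label),
            class = "tax_scenario")
}

# Resolve the taxed-category set of a scenario against a catalogue.
resolve_taxed <- function(scenario, catalogue) {
  taxed <- scenario$taxed_categories
  if (is.null(taxed)) taxed <- catalogue$name[catalogue$taxed]
  unknown <- setdiff(taxed, catalogue$name)
  if (length(unknown)) {
    abort(sprintf("unknown taxed categories: %s. Valid names: %s",
                  paste(unknown, collapse = ", "),
                  paste(catalogue$name, collapse = ", ")))
  }
  taxed
}

#' Per-category retail price change implied by a tax scenario
#'
#' Assuming an ad-valorem tax with partial or full pass-through, the
#' retail price of each taxed category rises by
#' `tax_rate * pass_through * 100` percent; untaxed categories are
#' unaffected.
#'
#' @param scenario A [tax_scenario()].
#' @param catalogue A [beverage_catalogue()].
#' @return Named numeric vector of percentage price changes, in catalogue
#'   order.
#' @examples
#' price_change(tax_scenario(0.20), default_catalogue())
#' @export
price_change <- function(scenario, catalogue) {
  stopifnot(inherits(scenario, "tax_scenario"),
            inherits(catalogue, "beverage_catalogue"))
  taxed <- resolve_taxed(scenario, catalogue)
  pct <- stats::setNames(numeric(nrow(catalogue)), catalogue$name)
  pct[taxed] <- scenario$tax_rate * scenario$pass_through * 100
  pct
}

#' Shift consumption through the demand system
#'
#' First-order linear response (default): the percentage demand change of
#' category `j` is `sum_i e[j, i] * pct_price[i]`, applied
#' multiplicatively to every individual's baseline volume and floored at
#' zero (demand cannot go negative). The same percentage change applies
#' to all individuals regardless of sex or age. The multiplicative
#' (log/constant-elasticity) form
#' `q' = q * prod_i (1 + dp_i/100)^e[j,i]` is available via
#' `form = "log"`.
#'
#' @param elasticities An [elasticity_matrix()] in catalogue order.
#' @param price_pct Named percentage price-change vector from
#'   [price_change()].
#' @param consumption Numeric matrix (individuals x categories) or a
#'   single consumption vector, in catalogue order.
#' @param form `"linear"` (default) or `"log"`.
#' @return Shifted consumption with the same shape as `consumption`.
#' @export
consumption_shift <- function(elasticities, price_pct, consumption,
                              form = c("linear", "log")) {
  form <- match.arg(form)
  vec_in <- is.null(dim(consumption))
  q <- if (vec_in) {
    matrix(consumption, nrow = 1,
           dimnames = list(NULL, names(consumption)))
  } else {
    as.matrix(consumption)
  }
  k <- ncol(q)
  if (nrow(elasticities) != k || length(price_pct) != k) {
    abort(sprintf(
      "dimension mismatch: %d consumption categories, %d x %d elasticities, %d prices.",
      k, nrow(elasticities), ncol(elasticities), length(price_pct)))
  }
  if (!is.null(colnames(q)) && !is.null(rownames(elasticities)) &&
      !identical(colnames(q), rownames(elasticities))) {
    abort("consumption and elasticity category order differ.")
  }
  mult <- switch(form,
    linear = 1 + as.numeric(unclass(elasticities) %*% price_pct) / 100,
    log = apply(unclass(elasticities), 1L,
                function(row) prod((1 + price_pct / 100)^row))
  )
  shifted <- sweep(q, 2L, mult, `*`)
  shifted[shifted < 0] <- 0
  if (vec_in) drop(shifted) else shifted
}

#' Per-individual energy-intake change
#'
#' The daily energy change of an individual is the sum over categories of
#' the volume change times the category energy density. Substitution
#' toward untaxed caloric beverages can make the net change positive even
#' though taxed intake falls.
#'
#' @param pop An `ssb_population`.
#' @param shifted Shifted consumption matrix from [consumption_shift()],
#'   aligned with `pop` (same rows, catalogue column order).
#' @param catalogue Catalogue; defaults to the population's.
#' @return A tibble with `id`, `delta_e_kcal`, and one
#'   `dvol_<category>` column per category (mL/day, signed).
#' @export
energy_change <- function(pop, shifted, catalogue = pop$catalogue) {
  stopifnot(inherits(pop, "ssb_population"))
  base <- consumption_matrix(pop)
  shifted <- as.matrix(shifted)
  if (!all(dim(shifted) == dim(base))) {
    abort("`shifted` is not aligned with the population's consumption matrix.")
  }
  dvol <- shifted - base
  dens <- stats::setNames(catalogue$energy_density, catalogue$name)
  de <- as.numeric(dvol %*% dens[colnames(base)])
  out <- tibble::tibble(id = pop$individuals$id, delta_e_kcal = de)
  dv <- tibble::as_tibble(as.data.frame(dvol))
  names(dv) <- paste0("dvol_", colnames(base))
  dplyr::bind_cols(out, dv)
}
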