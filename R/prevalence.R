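#' Classify BMI into normal / overweight / obese
#'
#' Adult cut-offs: overweight is `25 <= BMI < 30`, obesity `BMI >= 30`;
#' anything below 25 is pooled as `normal` (the simulation does not
#' distinguish underweight).
#'
#' @param bmi Numeric BMI values, kg/m^2; must be finite and positive.
#' @return Factor with levels `normal`, `overweight`, `obese`.
#' @examples
#' classify_bmi(c(24.999, 25, 29.999, 30))
#' @export
classify_bmi <- function(bmi) {
  if (!is.numeric(bmi) || any(!is.finite(bmi)) || any(bmi <= 0)) {
    abort("`bmi` must be finite and positive.")
  }
  cut(bmi, breaks = c(0, 25, 30, Inf), labels = c("normal", "overweight", "obese"),
      right = FALSE)
}

#' Survey-weighted prevalence of a BMI class
#'
#' `100 * sum(w * [class]) / sum(w)`.
#'
#' @param bmi Numeric BMI values.
#' @param weights Nonnegative survey weights, not all zero.
#' @param class One of `"overweight"`, `"obese"`,
#'   `"overweight_or_obese"` (BMI >= 25).
#' @return Prevalence in percent.
#' @export
weighted_prevalence <- function(bmi, weights,
                                class = c("overweight", "obese",
                                          "overweight_or_obese")) {
  class <- match.arg(class)
  if (length(bmi) == 0) abort("empty stratum: no individuals to summarise.")
  ind <- bmi_indicator(bmi, class)
  100 * weighted_mean(ind, weights)
}

bmi_indicator <- function(bmi, class) {
  cls <- classify_bmi(bmi)
  switch(class,
         overweight = as.numeric(cls == "overweight"),
         obese = as.numeric(cls == "obese"),
         overweight_or_obese = as.numeric(cls != "normal"))
}

PREVALENCE_MEASURES <- c("overweight", "obese", "overweight_or_obese")

#' Pre/post prevalence change by stratum
#'
#' Weighted prevalence of each BMI class before and after the tax, the
#' relative change in percent (`100 * (post - pre) / pre`; positive
#' means the prevalence rises), and the change in expansion-weighted
#' person counts, for every sex x age stratum plus sex margins and
#' overall. The whole population is classified on both sides, so
#' individuals may enter overweight from below or leave it upward into
#' obesity. `restrict_to_baseline_excess = TRUE` switches to the
#' restricted reading in which individuals below BMI 25 at baseline are
#' ignored on the post side as well (no entry from the normal class).
#'
#' @param pop An `ssb_population`.
#' @param bmi_post Post-tax BMI vector aligned with `pop$individuals`
#'   (e.g. from [apply_weight_change()]).
#' @param bmi_pre Baseline BMI; defaults to the population's.
#' @param restrict_to_baseline_excess Restrict to baseline BMI >= 25.
#' @return Tidy tibble: `sex`, `age_group` (with `"all"` margins),
#'   `measure`, `population`, `prevalence_pre`, `prevalence_post`,
#'   `relative_change_pct`, `count_change`. Strata with zero baseline
#'   prevalence report `NA` relative change with a warning.
#' @export
prevalence_change <- function(pop, bmi_post,
                              bmi_pre = pop$individuals$bmi,
                              restrict_to_baseline_excess = FALSE) {
  stopifnot(inherits(pop, "ssb_population"))
  ind <- pop$individuals
  if (length(bmi_post) != nrow(ind) || length(bmi_pre) != nrow(ind)) {
    abort("`bmi_pre`/`bmi_post` must align with the population.")
  }
  if (restrict_to_baseline_excess) {
    keep <- bmi_pre >= 25
    return(prevalence_change_table(ind$sex[keep], ind$age_group[keep],
                                   ind$survey_weight[keep],
                                   bmi_pre[keep], bmi_post[keep]))
  }
  prevalence_change_table(ind$sex, ind$age_group, ind$survey_weight,
                          bmi_pre, bmi_post)
}

prevalence_change_table <- function(sex, age, w, bmi_pre, bmi_post) {
  defs <- stratum_definitions()
  rows <- lapply(seq_len(nrow(defs)), function(i) {
    sel <- stratum_selector(defs$sex[i], defs$age_group[i], sex, age)
    if (!any(sel)) return(NULL)
    wi <- w[sel]
    res <- lapply(PREVALENCE_MEASURES, function(m) {
      pre <- 100 * weighted_mean(bmi_indicator(bmi_pre[sel], m), wi)
      post <- 100 * weighted_mean(bmi_indicator(bmi_post[sel], m), wi)
      rel <- if (pre == 0) NA_real_ else 100 * (post - pre) / pre
      tibble::tibble(
        sex = defs$sex[i], age_group = defs$age_group[i], measure = m,
        population = sum(wi),
        prevalence_pre = pre, prevalence_post = post,
        relative_change_pct = rel,
        count_change = sum(wi) * (post - pre) / 100
      )
    })
    dplyr::bind_rows(res)
  })
  out <- dplyr::bind_rows(rows)
  if (anyNA(out$relative_change_pct)) {
    warn("zero baseline prevalence in at least one stratum: relative change reported as NA.")
  }
  out
}

# The 21 reporting strata: overall, each sex, each age band (sexes
# combined), and each sex x age band.
stratum_definitions <- function() {
  dplyr::bind_rows(
    tibble::tibble(sex = "all", age_group = "all"),
    tidyr::expand_grid(sex = SEX_LEVELS, age_group = "all"),
    tidyr::expand_grid(sex = "all", age_group = AGE_LEVELS),
    tidyr::expand_grid(sex = SEX_LEVELS, age_group = AGE_LEVELS)
  )
}

stratum_selector <- function(def_sex, def_age, sex, age) {
  sel <- rep(TRUE, length(sex))
  if (def_sex != "all") sel <- sel & (as.character(sex) == def_sex)
  if (def_age != "all") sel <- sel & (as.character(age) == def_age)
  sel
}

#' Percentile bootstrap confidence interval
#'
#' Nonparametric bootstrap over individuals: rows of `data` are resampled
#' with replacement (survey weights travel with their rows), the
#' statistic is recomputed on each replicate, and the 2.5th/97.5th
#' percentiles are returned. Seeded and reproducible; the caller's RNG
#' state is untouched.
#'
#' @param statistic Function of a resampled `data` returning a numeric
#'   scalar (or fixed-length vector).
#' @param data Data frame of individuals.
#' @param B Number of replicates, `>= 1`; default 1000.
#' @param seed Integer seed.
#' @param level Confidence level, default 0.95.
#' @return For a scalar statistic, named numeric `c(low, high)`; for a
#'   vector statistic, a matrix with rows `low` and `high`.
#' @export
bootstrap_ci <- function(statistic, data, B = 1000, seed = 1, level = 0.95) {
  check_number(B, "B", min = 1)
  n <- nrow(data)
  if (is.null(n) || n == 0) abort("`data` must have rows to resample.")
  reps <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      as.numeric(statistic(data[idx, , drop = FALSE]))
    }, FUN.VALUE = numeric(length(statistic(data))))
  })
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  if (is.null(dim(reps))) {
    q <- quantile(reps, probs, na.rm = TRUE, names = FALSE)
    return(c(low = q[1], high = q[2]))
  }
  out <- apply(reps, 1L, quantile, probs = probs, na.rm = TRUE, names = FALSE)
  rownames(out) <- c("low", "high")
  out
}
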