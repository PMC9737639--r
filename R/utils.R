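# Internal helpers shared across modules.

#' @importFrom rlang abort warn
#' @importFrom stats rgamma rlnorm rnorm quantile qnorm uniroot
#' @importFrom utils read.csv write.csv
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG stream afterwards so simulations do not perturb each other.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single finite number.")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Weighted arithmetic mean with explicit zero-weight guard.
weighted_mean <- function(x, w) {
  if (length(x) != length(w)) abort("`x` and `w` must have equal length.")
  if (any(w < 0)) abort("weights must be nonnegative.")
  sw <- sum(w)
  if (sw <= 0) abort("weights must not all be zero.")
  sum(x * w) / sw
}

check_number <- function(x, field, min = -Inf, max = Inf, allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", field))
  }
  if (x < min || x > max || (!allow_zero && x == 0)) {
    abort(sprintf("`%s` must be in [%s, %s]%s; got %s.",
                  field, format(min), format(max),
                  if (allow_zero) "" else " and nonzero", format(x)))
  }
  invisible(x)
}

check_probability <- function(x, field) check_number(x, field, min = 0, max = 1)

#' Sex and age-group levels used throughout the package
#'
#' Adults only: six ten-year age bands from 20--29 up to an open-ended 70+
#' band. Children are outside the modelled population.
#'
#' @name strata-levels
#' @keywords internal
SEX_LEVELS <- c("male", "female")

#' @rdname strata-levels
#' @keywords internal
AGE_LEVELS <- c("20-29", "30-39", "40-49", "50-59", "60-69", "70+")
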