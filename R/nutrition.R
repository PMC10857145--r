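#' Trapezoidal membership specification for one nutrient
#'
#' Defines the fuzzy "adequate amount" set for a nutrient as a trapezoid:
#' membership rises linearly from 0 at `a` to 1 at `b`, stays 1 on the
#' plateau `[b, c]`, and falls back to 0 at `d`. Degenerate plateaus
#' (`b == c`) and one-sided trapezoids (`a == b`, useful for "less is
#' better" nutrients such as sodium or sugar) are allowed.
#'
#' @param a,b,c,d Breakpoints in the nutrient's own units, `a <= b <= c <= d`.
#' @return An object of class `membership_spec`.
#' @examples
#' spec <- membership_spec(0, 100, 200, 400)
#' membership(300, spec) # 0.5, halfway down the falling ramp
#' @export
membership_spec <- function(a, b, c, d) {
  vals <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(vals))) stop_mealrl("membership breakpoints must be finite")
  if (!(a <= b && b <= c && c <= d)) {
    stop_mealrl("membership breakpoints must satisfy a <= b <= c <= d")
  }
  structure(as.list(vals), class = "membership_spec")
}

#' @export
print.membership_spec <- function(x, ...) {
  cat(sprintf("<membership_spec> ramp [%g, %g], plateau [%g, %g], ramp [%g, %g]\n",
              x$a, x$b, x$b, x$c, x$c, x$d))
  invisible(x)
}

#' Evaluate a trapezoidal membership function
#'
#' @param value Nutrient amount (non-negative, same units as the spec).
#' @param spec A [membership_spec()].
#' @return Membership degree in `[0, 1]`. Vectorized over `value`.
#' @export
membership <- function(value, spec) {
  if (!inherits(spec, "membership_spec")) stop_mealrl("`spec` must be a membership_spec")
  if (any(!is.finite(value)) || any(value < 0)) {
    stop_mealrl("nutrient values must be finite and non-negative")
  }
  a <- spec$a; b <- spec$b; c <- spec$c; d <- spec$d
  up <- if (b > a) (value - a) / (b - a) else as.numeric(value >= b)
  down <- if (d > c) (d - value) / (d - c) else as.numeric(value <= c)
  clip(pmin(up, down), 0, 1)
}

#' Prerow value: fuzzy nutrition-adequacy score
#'
#' Aggregates per-nutrient membership degrees into a single score in
#' `[0, 1]`. The score equals the worst nutrient's membership minus the
#' mean deficit of the remaining nutrients:
#' \deqn{PV = \mu_{min} - \frac{1}{n}\sum_{i \ne i_{min}} (1 - \mu_i)}
#' clipped to `[0, 1]`. A meal whose every nutrient sits inside its
#' plateau scores 1; each deficient nutrient drags the score down, with
#' the single worst nutrient acting as a hard cap. Scores of 0.7+ are
#' conventionally read as "acceptable" and 0.9+ as "optimal"
#' (see [pv_label()]).
#'
#' A `method = "reciprocal"` variant,
#' \eqn{PV = \mu_{min} \cdot n^{-1} \sum_{i \ne i_{min}} (1/\mu_i - 1)},
#' is kept for auditability; it rewards *imbalance* (it is 0 when all
#' memberships are 1) and is not used anywhere by default.
#'
#' @param memberships Numeric vector of membership degrees in `[0, 1]`.
#' @param floor Small positive constant; memberships below it are raised to
#'   it before use (guards the reciprocal variant's division).
#' @param method `"deficit"` (default) or `"reciprocal"`.
#' @return A list of class `pv_result`: `pv`, `memberships`, `n`,
#'   `worst_nutrient` (index of the minimizing entry).
#' @examples
#' prerow_value(c(0.5, 1, 1))$pv      # 0.5
#' prerow_value(c(0.5, 0.8, 1))$pv    # 0.4333...
#' @export
prerow_value <- function(memberships, floor = 1e-6,
                         method = c("deficit", "reciprocal")) {
  method <- match.arg(method)
  mu <- as.numeric(memberships)
  if (length(mu) == 0L) stop_mealrl("`memberships` must be non-empty")
  if (any(!is.finite(mu)) || any(mu < 0) || any(mu > 1)) {
    stop_mealrl("memberships must lie in [0, 1]")
  }
  mu <- pmax(mu, floor)
  n <- length(mu)
  i_min <- which.min(mu)
  rest <- mu[-i_min]
  pv <- switch(method,
    deficit    = mu[i_min] - sum(1 - rest) / n,
    reciprocal = mu[i_min] * sum(1 / rest - 1) / n
  )
  structure(
    list(pv = clip(pv, 0, 1), memberships = mu, n = n, worst_nutrient = i_min),
    class = "pv_result"
  )
}

#' @export
print.pv_result <- function(x, ...) {
  cat(sprintf("<pv_result> PV = %.4f over %d nutrients (worst: #%d, mu = %.3f)\n",
              x$pv, x$n, x$worst_nutrient, x$memberships[x$worst_nutrient]))
  invisible(x)
}

#' Default per-meal membership specs for the seven tracked nutrients
#'
#' One trapezoid per nutrient, intended for a single meal (roughly one
#' third of common adult daily reference intakes). "Less is better"
#' nutrients (sodium, sugar, fat) plateau from zero; nutrients with both
#' deficiency and excess concerns are two-sided. All breakpoints are in
#' the units of the corresponding catalogue column and can be overridden
#' per user via `nutrient_targets` in the user profile.
#'
#' @return Named list of [membership_spec()] objects, one per
#'   [nutrient_names()] entry.
#' @export
default_membership_specs <- function() {
  list(
    calories       = membership_spec(50, 250, 700, 1100),
    carbohydrate_g = membership_spec(0, 10, 80, 160),
    sodium_mg      = membership_spec(0, 0, 700, 1600),
    sugar_g        = membership_spec(0, 0, 15, 45),
    fiber_g        = membership_spec(0, 1, 15, 60),
    protein_g      = membership_spec(0, 5, 45, 90),
    fat_g          = membership_spec(0, 0, 30, 70)
  )
}

resolve_membership_specs <- function(profile = NULL, use_defaults = TRUE) {
  specs <- if (use_defaults) default_membership_specs() else list()
  targets <- profile$nutrient_targets
  if (!is.null(targets)) {
    for (nm in names(targets)) {
      t <- targets[[nm]]
      specs[[nm]] <- if (inherits(t, "membership_spec")) t else
        membership_spec(t[[1]], t[[2]], t[[3]], t[[4]])
    }
  }
  missing <- setdiff(nutrient_names(), names(specs))
  if (length(missing) > 0L) {
    stop_mealrl("no membership spec for nutrient(s): ",
                paste(missing, collapse = ", "))
  }
  specs[nutrient_names()]
}

#' Score one meal's nutritional adequacy
#'
#' Evaluates the trapezoidal membership of each of the seven tracked
#' nutrients against the user's targets (or the shipped defaults) and
#' aggregates them with [prerow_value()].
#'
#' @param meal A one-row meal tibble or a named list/vector containing the
#'   seven [nutrient_names()] values.
#' @param profile Optional user profile (see [user_profile()]); its
#'   `nutrient_targets` override the defaults per nutrient.
#' @param use_defaults If `FALSE`, every nutrient must have a target in the
#'   profile.
#' @inheritParams prerow_value
#' @return A `pv_result`.
#' @export
score_meal_nutrition <- function(meal, profile = NULL, use_defaults = TRUE,
                                 method = c("deficit", "reciprocal")) {
  specs <- resolve_membership_specs(profile, use_defaults)
  vals <- vapply(nutrient_names(), function(nm) {
    v <- if (is.data.frame(meal)) meal[[nm]][1] else meal[[nm]]
    if (is.null(v) || is.na(v)) stop_mealrl("meal is missing nutrient `", nm, "`")
    as.numeric(v)
  }, numeric(1))
  mu <- vapply(nutrient_names(), function(nm) membership(vals[[nm]], specs[[nm]]),
               numeric(1))
  prerow_value(mu, method = match.arg(method))
}

# PV for every row of a catalogue at once (used by environments/evaluation).
catalogue_pv <- function(catalogue, profile = NULL) {
  specs <- resolve_membership_specs(profile)
  mu <- sapply(nutrient_names(), function(nm) {
    membership(catalogue[[nm]], specs[[nm]])
  })
  mu <- matrix(mu, nrow = nrow(catalogue))
  apply(mu, 1L, function(m) prerow_value(m)$pv)
}

#' Label a Prerow value
#'
#' Maps a PV score to the conventional qualitative bands: 0.9 and above is
#' `"optimal"`, 0.7 and above `"acceptable"`, anything lower
#' `"below acceptable"`.
#'
#' @param pv Numeric vector of PV scores in `[0, 1]`.
#' @return Character vector of labels.
#' @export
pv_label <- function(pv) {
  if (any(!is.finite(pv)) || any(pv < 0) || any(pv > 1)) {
    stop_mealrl("`pv` must lie in [0, 1]")
  }
  ifelse(pv >= 0.9, "optimal",
         ifelse(pv >= 0.7, "acceptable", "below acceptable"))
}
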