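#' @importFrom stats rnorm runif setNames cor
#' @importFrom utils head tail
#' @importFrom rlang .data
#' @useDynLib mealrl, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Canonical nutrient column names
#'
#' The seven nutrients tracked per meal, in fixed order: energy (kcal),
#' carbohydrate, sodium, sugar, fiber, protein and fat. All catalogue
#' readers, the nutrition score and the synthetic generator use this order.
#'
#' @return Character vector of length 7.
#' @export
nutrient_names <- function() {
  c("calories", "carbohydrate_g", "sodium_mg", "sugar_g",
    "fiber_g", "protein_g", "fat_g")
}

stop_mealrl <- function(...) stop(..., call. = FALSE)

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_mealrl(sprintf("`%s` must be a single finite number", name))
  }
  invisible(x)
}

# Derive a stream of child seeds from one master seed, all < 2^31.
derive_seeds <- function(seed, n, salt = 0L) {
  withr::with_seed(as.integer(seed) + as.integer(salt), {
    sample.int(.Machine$integer.max - 1L, n)
  })
}
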