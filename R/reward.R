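#' Normalize a 1-5 rating to the unit interval
#'
#' Affine map `(rating - 1) / 4`, so 1 maps to 0 and 5 to 1.
#'
#' @param rating Integer rating(s) in 1..5.
#' @return Numeric in `[0, 1]`.
#' @export
normalize_rating <- function(rating) {
  if (any(!is.finite(rating)) || any(rating < 1 | rating > 5) ||
      any(rating != round(rating))) {
    stop_mealrl("`rating` must be an integer in 1..5")
  }
  (rating - 1) / 4
}

#' Reward component weights
#'
#' Weights for the rating (`w_r`), nutrition (`w_n`) and preference
#' (`w_p`) components of the scalar reward. Any non-negative values are
#' accepted and normalized to sum to one. The defaults put weight 0.4 on
#' nutrition and 0.3 each on acceptance rating and preference.
#'
#' @param w_r,w_n,w_p Non-negative weights.
#' @return Named numeric vector of class `reward_weights`, summing to 1.
#' @export
reward_weights <- function(w_r = 0.3, w_n = 0.4, w_p = 0.3) {
  w <- c(w_r = w_r, w_n = w_n, w_p = w_p)
  if (any(!is.finite(w)) || any(w < 0) || sum(w) == 0) {
    stop_mealrl("reward weights must be non-negative and not all zero")
  }
  structure(w / sum(w), class = "reward_weights")
}

#' Compose the scalar reward
#'
#' Weighted sum \eqn{r = w_r r_u + w_n n + w_p p} of the normalized user
#' rating, the Prerow nutrition value and the TOPSIS preference score,
#' each in `[0, 1]`; the result therefore also lies in `[0, 1]`.
#'
#' @param ru Normalized rating in `[0, 1]`.
#' @param n Nutrition (PV) score in `[0, 1]`.
#' @param p Preference (TOPSIS) score in `[0, 1]`.
#' @param weights A [reward_weights()] vector.
#' @return Scalar reward in `[0, 1]`.
#' @export
compose_reward <- function(ru, n, p, weights = reward_weights()) {
  comp <- c(ru, n, p)
  if (any(!is.finite(comp))) stop_mealrl("reward components must be finite")
  if (any(comp < 0 | comp > 1)) stop_mealrl("reward components must lie in [0, 1]")
  if (!inherits(weights, "reward_weights")) weights <- do.call(reward_weights, as.list(weights))
  unname(weights[["w_r"]] * ru + weights[["w_n"]] * n + weights[["w_p"]] * p)
}
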