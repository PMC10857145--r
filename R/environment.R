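#' Interactive meal-recommendation environment
#'
#' Wraps one user as a reinforcement-learning environment. The state is
#' the user's latent taste vector from the collaborative-filtering model
#' (optionally concatenated with the last-recommended meal's normalized
#' nutrient vector and a meal-type one-hot). A step recommends the
#' chosen candidate meal, obtains a rating from the rating oracle,
#' composes the scalar reward from the normalized rating, the meal's
#' Prerow nutrition value and its TOPSIS preference score, and advances
#' the state by an online update of the user's latent vector with the
#' fresh rating.
#'
#' @param profile [user_profile()] of the simulated or real user.
#' @param catalogue Candidate meal tibble, already filtered by
#'   [apply_hard_constraints()]; defines the fixed action space.
#' @param model Fitted [fit_svd()] collaborative-filtering model.
#' @param weights [reward_weights()].
#' @param rating_oracle Function `(user_id, meal_id) -> rating in 1..5`
#'   (a simulated user, a replay of logged ratings, or a live user).
#' @param context_features Append meal-context features to the latent
#'   state (default `FALSE`, latent vector only).
#' @param eta Online latent-update learning rate.
#' @return Environment object (class `meal_env`) with functions
#'   `reset()`, `step(action)`, `state_dim`, `n_actions`, and read access
#'   to per-candidate `pv` scores.
#' @export
make_environment <- function(profile, catalogue, model, weights = reward_weights(),
                             rating_oracle, context_features = FALSE,
                             eta = 0.05) {
  if (nrow(catalogue) == 0L) stop_mealrl("empty candidate set")
  if (!profile$user_id %in% model$users) {
    stop_mealrl("user ", profile$user_id, " is unknown to the CF model")
  }
  env <- new.env(parent = emptyenv())
  env$profile <- profile
  env$catalogue <- catalogue
  env$model0 <- model          # pristine copy restored on reset()
  env$model <- model
  env$weights <- weights
  env$oracle <- rating_oracle
  env$eta <- eta
  env$context_features <- context_features
  env$pv <- catalogue_pv(catalogue, profile)
  env$n_actions <- nrow(catalogue)
  env$uidx <- match(profile$user_id, model$users)
  env$midx <- match(catalogue$meal_id, model$meals)
  env$last_action <- 0L

  nut <- as.matrix(catalogue[nutrient_names()])
  env$nut_norm <- sweep(nut, 2L, pmax(apply(nut, 2L, max), 1e-12), "/")
  type_levels <- c("breakfast", "lunch", "dinner")
  env$type_onehot <- outer(catalogue$meal_type, type_levels, `==`) * 1

  env$state <- function() {
    s <- env$model$U[env$uidx, ]
    if (env$context_features) {
      ctx <- if (env$last_action > 0L) {
        c(env$nut_norm[env$last_action, ], env$type_onehot[env$last_action, ])
      } else {
        numeric(ncol(env$nut_norm) + 3L)
      }
      s <- c(s, ctx)
    }
    s
  }
  env$state_dim <- length(env$state())

  env$reset <- function() {
    env$model <- env$model0
    env$last_action <- 0L
    env$state()
  }

  env$predicted_acceptance <- function() {
    raw <- env$model$mu + env$model$bu[env$uidx] + env$model$bm[env$midx] +
      as.numeric(env$model$M[env$midx, , drop = FALSE] %*% env$model$U[env$uidx, ])
    (clip(raw, 1, 5) - 1) / 4
  }

  env$preference <- function() {
    taste <- env$predicted_acceptance()
    extractors <- default_criterion_extractors(env$profile)
    extractors$nutrition <- function(cat) env$pv
    extractors$taste <- function(cat) taste
    preference_score(env$catalogue, env$profile, extractors)
  }

  env$step <- function(action) {
    if (action < 1 || action > env$n_actions) stop_mealrl("invalid action index")
    meal_id <- env$catalogue$meal_id[action]
    rating <- env$oracle(env$profile$user_id, meal_id)
    ru <- normalize_rating(rating)
    n <- env$pv[action]
    p <- env$preference()[action]
    reward <- compose_reward(ru, n, p, env$weights)
    env$model <- update_user_latent(env$model, env$uidx, env$midx[action],
                                    rating, eta = env$eta)
    env$last_action <- as.integer(action)
    list(state = env$state(), reward = reward, meal_id = meal_id,
         rating = rating, ru = ru, n = n, p = p)
  }

  class(env) <- c("meal_env", "rl_env")
  env
}

#' @export
print.meal_env <- function(x, ...) {
  cat(sprintf("<meal_env> user %s, %d candidate meals, state dim %d\n",
              x$profile$user_id, x$n_actions, x$state_dim))
  invisible(x)
}

#' Deterministic multi-armed bandit environment
#'
#' A single-state environment with fixed per-arm rewards, used as a
#' known-optimum diagnostic for the agent: the optimal policy is simply
#' the arm with the largest reward.
#'
#' @param arm_rewards Numeric vector of deterministic rewards in `[0, 1]`.
#' @return Environment object (class `bandit_env`) with the same surface
#'   as [make_environment()].
#' @export
make_bandit_environment <- function(arm_rewards = c(0.1, 0.2, 0.3, 0.4, 0.9)) {
  if (any(arm_rewards < 0 | arm_rewards > 1)) {
    stop_mealrl("arm rewards must lie in [0, 1]")
  }
  env <- new.env(parent = emptyenv())
  env$arms <- arm_rewards
  env$n_actions <- length(arm_rewards)
  env$state_dim <- 1L
  env$reset <- function() 1
  env$step <- function(action) {
    r <- env$arms[action]
    list(state = 1, reward = r, meal_id = as.character(action),
         rating = NA_integer_, ru = NA_real_, n = NA_real_, p = NA_real_)
  }
  class(env) <- c("bandit_env", "rl_env")
  env
}
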