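#' Generate a synthetic meal-recommendation world
#'
#' Builds a fully seeded simulated study population: a meal catalogue
#' with per-meal-type log-normal nutrient vectors spanning realistic
#' single-meal magnitudes (roughly 100-800 kcal), a user population with
#' low-rank latent taste structure, a ground-truth utility
#' \eqn{u^*(user, meal) \in [0, 1]} that is an affine map of the
#' standardized latent inner product (clipped at the unit bounds, so the
#' rating surface stays low-rank bilinear except in the tails), and a
#' sparse set of observed ratings
#' \eqn{clip(round(1 + 4 u^* + N(0, \sigma)), 1, 5)} sampled at the
#' requested density. Taste (the latent structure) is generated
#' independently of the nutrient vectors, so a nutritious meal is not
#' automatically a liked meal.
#'
#' @param n_users,n_meals Population sizes (defaults 200 users, 100 meals).
#' @param k_true Rank of the latent taste structure (default 4).
#' @param noise_sd Rating noise standard deviation on the 1-5 scale
#'   (default 0.3).
#' @param density Fraction of user-meal pairs observed (default 0.1).
#' @param seed Integer seed; the world is a deterministic function of it.
#' @return List of class `synthetic_world`: `catalogue`, `users`
#'   (profiles), `interactions`, `u_star` (users x meals matrix),
#'   `noise_sd`, `seed`.
#' @export
generate_world <- function(n_users = 200, n_meals = 100, k_true = 4,
                           noise_sd = 0.3, density = 0.1, seed = 1) {
  if (k_true < 1) stop_mealrl("`k_true` must be >= 1")
  if (density <= 0 || density > 1) stop_mealrl("`density` must be in (0, 1]")

  withr::with_seed(seed, {
    user_ids <- sprintf("u%03d", seq_len(n_users))
    meal_ids <- sprintf("m%03d", seq_len(n_meals))
    meal_type <- sample(c("breakfast", "lunch", "dinner"), n_meals, replace = TRUE)

    rln <- function(mean_val, sdlog, lo, hi) {
      clip(stats::rlnorm(n_meals, log(mean_val), sdlog), lo, hi)
    }
    cal_mean <- c(breakfast = 320, lunch = 450, dinner = 480)[meal_type]
    catalogue <- tibble::tibble(
      meal_id = meal_ids,
      name = paste("synthetic meal", seq_len(n_meals)),
      meal_type = meal_type,
      calories = clip(stats::rlnorm(n_meals, log(cal_mean), 0.45), 80, 1200),
      carbohydrate_g = rln(30, 0.6, 0, 180),
      sodium_mg = rln(500, 0.7, 0, 2500),
      sugar_g = rln(8, 0.9, 0, 80),
      fiber_g = rln(3, 0.8, 0, 30),
      protein_g = rln(20, 0.6, 0, 90),
      fat_g = rln(15, 0.6, 0, 80),
      cost = round(rln(8, 0.5, 1, 40), 2),
      prep_minutes = round(rln(25, 0.5, 5, 120)),
      contains_gluten = runif(n_meals) < 0.3
    )

    P <- matrix(rnorm(n_users * k_true), n_users, k_true)
    Q <- matrix(rnorm(n_meals * k_true), n_meals, k_true)
    raw <- P %*% t(Q) / sqrt(k_true)
    u_star <- clip(0.5 + raw / 4, 0, 1)
    dimnames(u_star) <- list(user_ids, meal_ids)

    observed <- which(matrix(runif(n_users * n_meals) < density,
                             n_users, n_meals), arr.ind = TRUE)
    noise <- rnorm(nrow(observed), 0, noise_sd)
    ratings <- clip(round(1 + 4 * u_star[observed] + noise), 1, 5)
    interactions <- tibble::tibble(
      user_id = user_ids[observed[, 1]],
      meal_id = meal_ids[observed[, 2]],
      rating = as.integer(ratings),
      timestamp = seq_len(nrow(observed))
    )
  })

  unrated <- setdiff(meal_ids, unique(interactions$meal_id))
  if (length(unrated) > 0L) {
    warning(sprintf("%d meal(s) have no raters at density %.2f",
                    length(unrated), density), call. = FALSE)
  }
  users <- lapply(user_ids, function(uid) user_profile(uid))
  names(users) <- user_ids

  structure(
    list(catalogue = catalogue, users = users, interactions = interactions,
         u_star = u_star, noise_sd = noise_sd, density = density,
         k_true = k_true, seed = seed),
    class = "synthetic_world"
  )
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("<synthetic_world> %d users x %d meals, %d ratings, noise sd %.2f (seed %d)\n",
              nrow(x$u_star), ncol(x$u_star), nrow(x$interactions),
              x$noise_sd, x$seed))
  invisible(x)
}

#' Simulated-user rating oracle
#'
#' Returns a callable `(user_id, meal_id) -> rating` drawing
#' \eqn{clip(round(1 + 4 u^* + N(0, \sigma)), 1, 5)} from the session
#' RNG stream, acting as the human in the loop during training and
#' evaluation.
#'
#' @param world A [generate_world()] result.
#' @param noise_sd Override of the world's rating noise.
#' @return Function of `(user_id, meal_id)` returning an integer rating.
#' @export
rating_oracle <- function(world, noise_sd = NULL) {
  sd_use <- noise_sd %||% world$noise_sd
  function(user_id, meal_id) {
    if (!user_id %in% rownames(world$u_star)) stop_mealrl("unknown user: ", user_id)
    if (!meal_id %in% colnames(world$u_star)) stop_mealrl("unknown meal: ", meal_id)
    u <- world$u_star[user_id, meal_id]
    as.integer(clip(round(1 + 4 * u + rnorm(1, 0, sd_use)), 1, 5))
  }
}

#' Write a synthetic world to the on-disk schemas
#'
#' Emits `meals.csv`, `interactions.csv` and `users.json` in the formats
#' read by [read_meal_catalogue()], [read_interactions()] and
#' [read_user_profile()].
#'
#' @param world A [generate_world()] result.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_meal_catalogue(world$catalogue, file.path(dir, "meals.csv"))
  write_interactions(world$interactions, file.path(dir, "interactions.csv"))
  profiles <- lapply(world$users, function(p) {
    list(user_id = p$user_id, demographics = p$demographics,
         hard_constraints = p$hard_constraints)
  })
  jsonlite::write_json(unname(profiles), file.path(dir, "users.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
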