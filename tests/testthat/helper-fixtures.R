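# In-code fixtures shared across test files.

# A tiny hand-written catalogue: one meal per type plus an extra dinner.
# Nutrient values chosen to sit inside the default membership plateaus
# except where a test needs a deficient nutrient.
tiny_catalogue <- function() {
  tibble::tibble(
    meal_id = c("b1", "l1", "d1", "d2"),
    name = c("porridge", "bean salad", "grilled fish", "salt bomb"),
    meal_type = c("breakfast", "lunch", "dinner", "dinner"),
    calories = c(350, 500, 450, 600),
    carbohydrate_g = c(40, 55, 30, 45),
    sodium_mg = c(300, 450, 500, 1400),
    sugar_g = c(5, 8, 3, 12),
    fiber_g = c(6, 9, 3, 2),
    protein_g = c(12, 18, 35, 20),
    fat_g = c(8, 14, 12, 28),
    cost = c(3, 6, 9, 7),
    prep_minutes = c(10, 20, 30, 25),
    contains_gluten = c(TRUE, FALSE, FALSE, FALSE)
  )
}

tiny_interactions <- function() {
  tibble::tibble(
    user_id = c("u1", "u1", "u2", "u2", "u3"),
    meal_id = c("b1", "l1", "b1", "d1", "d1"),
    rating = c(4L, 5L, 2L, 3L, 5L),
    timestamp = 1:5
  )
}

# Small world for pipeline tests: fast to fit and train on.
small_world <- function(seed = 1) {
  suppressWarnings(generate_world(n_users = 40, n_meals = 24, k_true = 2,
                                  noise_sd = 0.3, density = 0.3, seed = seed))
}

# Step-by-step TOPSIS oracle written independently of the package
# implementation (explicit loops, no shared helpers).
topsis_oracle <- function(A, weights, directions) {
  m <- nrow(A); n <- ncol(A)
  w <- weights / sum(weights)
  R <- matrix(0, m, n)
  for (j in 1:n) {
    nrm <- sqrt(sum(A[, j]^2))
    for (i in 1:m) R[i, j] <- if (nrm > 0) A[i, j] / nrm else 0
  }
  Tm <- matrix(0, m, n)
  for (j in 1:n) for (i in 1:m) Tm[i, j] <- R[i, j] * w[j]
  best <- numeric(n); worst <- numeric(n)
  for (j in 1:n) {
    if (directions[j] == "benefit") {
      best[j] <- max(Tm[, j]); worst[j] <- min(Tm[, j])
    } else {
      best[j] <- min(Tm[, j]); worst[j] <- max(Tm[, j])
    }
  }
  s <- numeric(m)
  for (i in 1:m) {
    db <- sqrt(sum((Tm[i, ] - best)^2))
    dw <- sqrt(sum((Tm[i, ] - worst)^2))
    s[i] <- if (db + dw > 0) dw / (dw + db) else 0.5
  }
  s
}

# Always-pleased / always-displeased simulated raters.
constant_oracle <- function(rating) function(user_id, meal_id) as.integer(rating)
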