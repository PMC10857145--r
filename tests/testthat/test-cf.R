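test_that("rating matrix indexes users and meals stably", {
  ints <- tiny_interactions()
  rm <- build_rating_matrix(ints, users = c("u1", "u2", "u3"),
                            meals = tiny_catalogue())
  expect_equal(Matrix::nnzero(rm$R), 5)
  expect_equal(rm$R["u2", "d1"], 3)
  expect_equal(rm$R["u1", "l1"], 5)
  # interaction referencing an unknown meal is skipped with a warning
  ints2 <- rbind(ints, tibble::tibble(user_id = "u1", meal_id = "nope",
                                      rating = 4L, timestamp = 9))
  expect_warning(rm2 <- build_rating_matrix(ints2, c("u1", "u2", "u3"),
                                            tiny_catalogue()),
                 "unknown")
  expect_equal(Matrix::nnzero(rm2$R), 5)
  # empty input still yields a valid object
  rm3 <- build_rating_matrix(ints[0, ], users = "u1", meals = "m1")
  expect_equal(Matrix::nnzero(rm3$R), 0)
})

noiseless_rank2 <- function() {
  set.seed(9)
  U0 <- matrix(rnorm(5 * 2, sd = 0.5), 5, 2)
  M0 <- matrix(rnorm(6 * 2, sd = 0.5), 6, 2)
  R <- 3 + U0 %*% t(M0)
  stopifnot(all(R > 1), all(R < 5))
  ints <- tibble::tibble(
    user_id = rep(sprintf("u%d", 1:5), 6),
    meal_id = rep(sprintf("m%d", 1:6), each = 5),
    rating = as.numeric(R),
    timestamp = seq_len(30)
  )
  build_rating_matrix(ints, sprintf("u%d", 1:5), sprintf("m%d", 1:6))
}

test_that("SGD factorization recovers a complete noiseless rank-2 matrix", {
  rm <- noiseless_rank2()
  fit <- fit_svd(rm, k = 2, epochs = 800, lr = 0.02, reg = 0, seed = 1)
  pred <- fit$mu + outer(fit$bu, fit$bm, "+") + fit$U %*% t(fit$M)
  expect_lt(sqrt(mean((pred - as.matrix(rm$R))^2)), 1e-2)
})

test_that("constant matrices are absorbed by the bias terms", {
  ints <- expand.grid(user_id = sprintf("u%d", 1:4), meal_id = sprintf("m%d", 1:5),
                      stringsAsFactors = FALSE)
  ints$rating <- 4; ints$timestamp <- seq_len(nrow(ints))
  rm <- build_rating_matrix(tibble::as_tibble(ints))
  fit <- fit_svd(rm, k = 2, epochs = 200, lr = 0.02, reg = 0.01, seed = 1)
  pred <- predict_acceptance(fit, "u1")
  expect_equal(pred$rating, rep(4, 5), tolerance = 0.02)
})

test_that("fits are bitwise-reproducible for a fixed seed", {
  w <- small_world()
  rm <- build_rating_matrix(w$interactions, names(w$users), w$catalogue)
  f1 <- fit_svd(rm, k = 3, epochs = 20, seed = 5)
  f2 <- fit_svd(rm, k = 3, epochs = 20, seed = 5)
  expect_identical(f1$U, f2$U)
  expect_identical(f1$M, f2$M)
  a1 <- fit_svd(rm, k = 3, epochs = 20, seed = 5, optimizer = "als", reg = 1)
  a2 <- fit_svd(rm, k = 3, epochs = 20, seed = 5, optimizer = "als", reg = 1)
  expect_identical(a1$U, a2$U)
  expect_error(fit_svd(rm, k = 24), "k")
})

clip_manual <- function(x) pmin(pmax(x, 1), 5)

test_that("predictions stay in range and cold entities fall back to biases", {
  w <- small_world()
  rm <- build_rating_matrix(w$interactions, names(w$users), w$catalogue)
  fit <- fit_svd(rm, k = 3, epochs = 40, seed = 5)
  pred <- predict_acceptance(fit, "u001")
  expect_true(all(pred$rating >= 1 & pred$rating <= 5))
  expect_true(all(pred$acceptance >= 0 & pred$acceptance <= 1))
  expect_equal(pred$acceptance, (pred$rating - 1) / 4)
  expect_message(cold <- predict_acceptance(fit, "stranger", "m001"), "cold user")
  expect_equal(cold$rating, clip_manual(fit$mu + fit$bm[1]), tolerance = 1e-12)
})

test_that("held-out RMSE beats the global-mean predictor", {
  w <- small_world()
  split <- split_interactions(w$interactions, 0.7, seed = 3)
  rm <- build_rating_matrix(split$train, names(w$users), w$catalogue)
  fit <- fit_svd(rm, k = 2, epochs = 60, reg = 1.2, optimizer = "als")
  test <- split$test
  pred <- vapply(seq_len(nrow(test)), function(i) {
    predict_acceptance(fit, test$user_id[i], test$meal_id[i])$rating
  }, numeric(1))
  rmse_model <- sqrt(mean((pred - test$rating)^2))
  rmse_mean <- sqrt(mean((mean(split$train$rating) - test$rating)^2))
  expect_lt(rmse_model, rmse_mean)
})

test_that("online latent update moves only the rated user toward the rating", {
  w <- small_world()
  rm <- build_rating_matrix(w$interactions, names(w$users), w$catalogue)
  fit <- fit_svd(rm, k = 3, epochs = 40, seed = 5)
  u <- "u001"; m <- "m001"
  before <- predict_acceptance(fit, u, m)$rating
  # zero-error update is a fixed point
  r_now <- fit$mu + fit$bu[1] + fit$bm[1] + sum(fit$U[1, ] * fit$M[1, ])
  if (r_now >= 1 && r_now <= 5) {
    same <- update_user_latent(fit, u, m, r_now, eta = 0.1, reg = 0)
    expect_equal(same$U, fit$U, tolerance = 1e-12)
  }
  # repeated updates converge monotonically toward the observed rating
  target <- if (before < 3) 5 else 1
  f <- fit
  errs <- numeric(30)
  for (i in 1:30) {
    f <- update_user_latent(f, u, m, target, eta = 0.05, reg = 0)
    errs[i] <- abs(predict_acceptance(f, u, m)$rating - target)
  }
  expect_true(all(diff(errs) <= 1e-9))
  expect_lt(errs[30], abs(before - target))
  # locality: only row u changed
  expect_equal(f$U[-1, ], fit$U[-1, ])
  expect_equal(f$M, fit$M)
  expect_warning(update_user_latent(fit, u, "nope", 4), "unknown meal")
})
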