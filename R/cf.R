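#' Build the sparse user-meal rating matrix
#'
#' Maps user and meal identifiers to stable row/column indices and stores
#' observed ratings in a sparse matrix. Interactions referencing meals
#' absent from the catalogue (or users absent from `users`, when given)
#' are skipped with a warning.
#'
#' @param interactions Deduplicated interaction tibble.
#' @param users Optional character vector fixing the user universe and
#'   order; defaults to users present in the interactions.
#' @param meals Optional character vector (or catalogue tibble) fixing the
#'   meal universe and order.
#' @return Object of class `rating_matrix`: sparse `R` (users x meals,
#'   0 = unobserved), `users`, `meals`.
#' @export
build_rating_matrix <- function(interactions, users = NULL, meals = NULL) {
  if (is.data.frame(meals)) meals <- meals$meal_id
  users <- users %||% unique(interactions$user_id)
  meals <- meals %||% unique(interactions$meal_id)
  ui <- match(interactions$user_id, users)
  mi <- match(interactions$meal_id, meals)
  bad <- is.na(ui) | is.na(mi)
  if (any(bad)) {
    warning(sprintf("skipped %d interaction(s) referencing unknown users/meals",
                    sum(bad)), call. = FALSE)
  }
  R <- Matrix::sparseMatrix(
    i = ui[!bad], j = mi[!bad], x = as.numeric(interactions$rating[!bad]),
    dims = c(length(users), length(meals)),
    dimnames = list(users, meals)
  )
  structure(list(R = R, users = users, meals = meals), class = "rating_matrix")
}

#' @export
print.rating_matrix <- function(x, ...) {
  cat(sprintf("<rating_matrix> %d users x %d meals, %d observed ratings (%.1f%% dense)\n",
              length(x$users), length(x$meals), Matrix::nnzero(x$R),
              100 * Matrix::nnzero(x$R) / prod(dim(x$R))))
  invisible(x)
}

#' Fit latent factors by regularized matrix factorization
#'
#' Factorizes the sparse rating matrix as \eqn{R \approx \mu + b_u + b_m
#' + U M^T}, minimizing squared error over the *observed* entries only
#' with L2 regularization (a classical dense SVD is undefined on a matrix
#' with missing entries). Two optimizers are available:
#'
#' * `"sgd"` (default): Funk-style stochastic gradient descent with bias
#'   terms, per-visit penalty `reg`, and optional harmonic learning-rate
#'   decay. This is also the update rule used online, one rating at a
#'   time, by [update_user_latent()].
#' * `"als"`: alternating ridge regression without bias terms, started
#'   from a mean-imputed truncated SVD. Here `reg` is an *absolute* ridge
#'   penalty per latent vector, so lightly-rated users are not over-shrunk
#'   relative to heavily-rated ones; the fit is deterministic and
#'   converges to a stationary point of the penalized least-squares
#'   objective. Preferred when prediction accuracy on sparse data is the
#'   goal.
#'
#' Deterministic for a fixed seed in both modes.
#'
#' @param rm A [build_rating_matrix()] result.
#' @param k Latent dimension, `1 <= k < min(dim)` (default 16).
#' @param epochs SGD passes over the data, or ALS sweeps (default 100).
#' @param lr SGD initial learning rate (default 0.01; ignored by ALS).
#' @param reg L2 penalty: per-visit for SGD (default 0.02), absolute ridge
#'   for ALS (a value near 1 works well on 1-5 ratings).
#' @param lr_decay Harmonic learning-rate decay: epoch `e` uses
#'   `lr / (1 + lr_decay * e)` (default 0, constant rate; SGD only).
#' @param seed Integer seed.
#' @param init `"random"` or `"svd"` (mean-imputed truncated SVD start;
#'   ALS always uses `"svd"`).
#' @param optimizer `"sgd"` or `"als"`.
#' @return Object of class `cf_model`: `U`, `M`, `bu`, `bm`, `mu`,
#'   `users`, `meals`, `k`, `rmse` (training trace; per epoch for SGD,
#'   final for ALS).
#' @export
fit_svd <- function(rm, k = 16, epochs = 100, lr = 0.01, reg = 0.02,
                    lr_decay = 0, seed = 1, init = c("random", "svd"),
                    optimizer = c("sgd", "als")) {
  init <- match.arg(init)
  optimizer <- match.arg(optimizer)
  stopifnot(inherits(rm, "rating_matrix"))
  R <- rm$R
  obs <- Matrix::which(R != 0, arr.ind = TRUE)
  if (nrow(obs) == 0L) stop_mealrl("rating matrix has no observed entries")
  if (k < 1 || k >= min(dim(R))) {
    stop_mealrl("`k` must satisfy 1 <= k < min(#users, #meals)")
  }
  r <- R[obs]
  mu <- mean(r)
  n_u <- nrow(R); n_m <- ncol(R)

  svd_start <- function() {
    dense <- as.matrix(R)
    dense[dense == 0] <- mu
    sv <- svd(dense - mu, nu = k, nv = k)
    s <- sqrt(sv$d[seq_len(k)])
    list(U = sv$u %*% diag(s, k), M = sv$v %*% diag(s, k))
  }

  if (optimizer == "als") {
    start <- svd_start()
    fit <- als_ridge(start$U, start$M,
                     as.integer(obs[, 1] - 1L), as.integer(obs[, 2] - 1L),
                     as.numeric(r - mu), as.integer(epochs), reg)
    resid <- r - (mu + rowSums(fit$U[obs[, 1], , drop = FALSE] *
                                 fit$M[obs[, 2], , drop = FALSE]))
    bu <- numeric(n_u); bm <- numeric(n_m)
    rmse <- sqrt(mean(resid^2))
  } else {
    withr::with_seed(seed, {
      if (init == "svd") {
        start <- svd_start()
        U <- start$U; M <- start$M
      } else {
        U <- matrix(rnorm(n_u * k, sd = 0.1), n_u, k)
        M <- matrix(rnorm(n_m * k, sd = 0.1), n_m, k)
      }
      order <- vapply(seq_len(epochs), function(e) sample.int(nrow(obs)) - 1L,
                      integer(nrow(obs)))
    })
    fit <- funk_svd_sgd(U, M, numeric(n_u), numeric(n_m), mu,
                        as.integer(obs[, 1] - 1L), as.integer(obs[, 2] - 1L),
                        as.numeric(r), order, lr, reg, lr_decay)
    bu <- as.numeric(fit$bu); bm <- as.numeric(fit$bm)
    rmse <- as.numeric(fit$rmse)
  }
  structure(
    list(U = fit$U, M = fit$M, bu = bu, bm = bm,
         mu = mu, users = rm$users, meals = rm$meals, k = k,
         rmse = rmse,
         hyper = list(epochs = epochs, lr = lr, reg = reg,
                      lr_decay = lr_decay, seed = seed, init = init,
                      optimizer = optimizer)),
    class = "cf_model"
  )
}

#' @export
print.cf_model <- function(x, ...) {
  cat(sprintf("<cf_model> %d users x %d meals, k = %d, final train RMSE %.4f\n",
              length(x$users), length(x$meals), x$k, tail(x$rmse, 1)))
  invisible(x)
}

#' Predict acceptance for user-meal pairs
#'
#' Predicted rating \eqn{\hat r = clip(\mu + b_u + b_m + U_u \cdot M_m, 1, 5)}
#' plus its normalization \eqn{(\hat r - 1)/4 \in [0,1]}. Cold users fall
#' back to \eqn{\mu + b_m}, cold meals to \eqn{\mu + b_u} (bias-only).
#'
#' @param model A [fit_svd()] model.
#' @param user Single user id (character) or index.
#' @param meal Meal ids (character), indices, or `NULL` for all meals.
#' @return Tibble with `meal_id`, `rating` (in `[1, 5]`) and `acceptance`
#'   (in `[0, 1]`).
#' @export
predict_acceptance <- function(model, user, meal = NULL) {
  u <- if (is.character(user)) match(user, model$users) else as.integer(user)
  mi <- if (is.null(meal)) seq_along(model$meals) else
    if (is.character(meal)) match(meal, model$meals) else as.integer(meal)
  cold_meal <- is.na(mi)
  if (is.na(u)) {
    message("cold user: falling back to global + meal bias")
    raw <- model$mu + ifelse(cold_meal, 0, model$bm[mi])
  } else {
    raw <- model$mu + model$bu[u] +
      ifelse(cold_meal, 0,
             model$bm[mi] + as.numeric(model$M[mi, , drop = FALSE] %*% model$U[u, ]))
  }
  r_hat <- clip(raw, 1, 5)
  tibble::tibble(
    meal_id = if (is.null(meal)) model$meals else
      ifelse(cold_meal, as.character(meal), model$meals[mi]),
    rating = r_hat,
    acceptance = (r_hat - 1) / 4
  )
}

#' Online update of one user's latent vector
#'
#' Performs a single SGD step on the observed squared error for the pair
#' `(user, meal)`, touching only that user's latent row and bias:
#' \eqn{U_u \leftarrow U_u + \eta (e M_m - \lambda U_u)} with
#' \eqn{e = r - \hat r}. Meal factors stay frozen, so fresh ratings move
#' the user's state without perturbing the shared meal representation.
#'
#' @param model A `cf_model`.
#' @param user User id or index.
#' @param meal Meal id or index; unknown meals are a warning no-op.
#' @param rating Observed rating in `[1, 5]`.
#' @param eta Learning rate (default 0.05).
#' @param reg L2 penalty on the user vector (default 0).
#' @param update_bias Also update the user bias term (default `TRUE`).
#' @return The model with the updated user row.
#' @export
update_user_latent <- function(model, user, meal, rating, eta = 0.05, reg = 0,
                               update_bias = TRUE) {
  if (rating < 1 || rating > 5) stop_mealrl("`rating` must lie in [1, 5]")
  u <- if (is.character(user)) match(user, model$users) else as.integer(user)
  m <- if (is.character(meal)) match(meal, model$meals) else as.integer(meal)
  if (is.na(u)) stop_mealrl("unknown user")
  if (is.na(m) || m < 1 || m > length(model$meals)) {
    warning("unknown meal: latent update skipped", call. = FALSE)
    return(model)
  }
  pred <- model$mu + model$bu[u] + model$bm[m] +
    sum(model$U[u, ] * model$M[m, ])
  e <- rating - pred
  model$U[u, ] <- model$U[u, ] + eta * (e * model$M[m, ] - reg * model$U[u, ])
  if (update_bias) model$bu[u] <- model$bu[u] + eta * (e - reg * model$bu[u])
  model
}
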