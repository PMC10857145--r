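#' Registered comparison methods
#'
#' Four recommenders are compared: `"cfrl"` (the full agent: deep
#' Q-learning over collaborative-filtering states with the composite
#' reward), `"cf"` (pure collaborative filtering: pick the highest
#' predicted acceptance per slot, ignoring nutrition and preference),
#' `"nutrition"` (the same Q-learning loop with the rating weight set to
#' zero, so the reward is nutrition + preference only), and
#' `"nutrition_pref"` (no learning: TOPSIS ranking with the Prerow value
#' as an explicit criterion, top-ranked meal per slot).
#'
#' @return Character vector of method names.
#' @export
method_registry <- function() c("cfrl", "cf", "nutrition", "nutrition_pref")

# Shared per-run experiment: fit CF, build environments, produce a plan
# per evaluation user with the requested method, score the plan meals.
run_experiment <- function(method, world, seed,
                           config = NULL, cf_k = 4,
                           n_train_users = 10, n_eval_users = 20,
                           train_frac = 0.7) {
  seeds <- derive_seeds(seed, 6)
  split <- split_interactions(world$interactions, train_frac, seed = seeds[1])
  rm <- build_rating_matrix(split$train,
                            users = names(world$users),
                            meals = world$catalogue)
  model <- fit_svd(rm, k = cf_k, epochs = 60, reg = 1.2, optimizer = "als",
                   seed = seeds[2])
  config <- config %||% agent_config(episodes = 200, steps_per_episode = 3,
                                     epsilon_decay = 0.985,
                                     terminal_steps = TRUE, seed = seeds[3])
  config$seed <- as.integer(seeds[3])

  uids <- names(world$users)
  picks <- withr::with_seed(seeds[4], {
    list(train = sample(uids, min(n_train_users, length(uids))),
         eval = sample(uids, min(n_eval_users, length(uids))))
  })
  oracle <- rating_oracle(world)
  weights <- switch(method,
    cfrl = reward_weights(),
    nutrition = reward_weights(w_r = 0, w_n = 0.4, w_p = 0.3),
    reward_weights()
  )
  env_for <- function(uid) {
    make_environment(world$users[[uid]], world$catalogue, model,
                     weights = weights, rating_oracle = oracle)
  }

  agent <- if (method %in% c("cfrl", "nutrition")) {
    train_agent(lapply(picks$train, env_for), config)
  } else {
    NULL
  }

  plan_rows <- withr::with_seed(seeds[5], {
    lapply(picks$eval, function(uid) {
      env <- env_for(uid)
      plan <- switch(method,
        cfrl = ,
        nutrition = recommend_plan(agent, env),
        cf = plan_cf_only(env),
        nutrition_pref = plan_nutrition_preference(env),
        stop_mealrl("unknown method `", method, "`; registered: ",
                    paste(method_registry(), collapse = ", "))
      )
      plan$user_id <- uid
      plan$accept <- vapply(plan$meal_id, function(mid) oracle(uid, mid),
                            integer(1))
      plan
    })
  })
  dplyr::bind_rows(plan_rows)
}

# CF-only baseline: argmax predicted acceptance within each slot.
plan_cf_only <- function(env, meal_types = c("breakfast", "lunch", "dinner")) {
  acc <- env$predicted_acceptance()
  pref <- env$preference()
  rows <- lapply(meal_types, function(mt) {
    idx <- which(env$catalogue$meal_type == mt)
    if (length(idx) == 0L) stop_mealrl("no candidate meals for slot: ", mt)
    best <- idx[which.max(acc[idx])]
    tibble::tibble(meal_type = mt, meal_id = env$catalogue$meal_id[best],
                   name = env$catalogue$name[best],
                   preference = pref[best], pv = env$pv[best],
                   predicted_rating = 1 + 4 * acc[best])
  })
  dplyr::bind_rows(rows)
}

# Non-learning baseline: TOPSIS ranking with the Prerow value as an
# explicit criterion; the top-ranked meal per slot is recommended.
plan_nutrition_preference <- function(env,
                                      meal_types = c("breakfast", "lunch", "dinner")) {
  pref <- env$preference()
  acc <- env$predicted_acceptance()
  rows <- lapply(meal_types, function(mt) {
    idx <- which(env$catalogue$meal_type == mt)
    if (length(idx) == 0L) stop_mealrl("no candidate meals for slot: ", mt)
    best <- idx[which.max(pref[idx])]
    tibble::tibble(meal_type = mt, meal_id = env$catalogue$meal_id[best],
                   name = env$catalogue$name[best],
                   preference = pref[best], pv = env$pv[best],
                   predicted_rating = 1 + 4 * acc[best])
  })
  dplyr::bind_rows(rows)
}

#' Evaluate one method over repeated seeded runs
#'
#' Runs the full pipeline `runs` times with per-run seeds derived from
#' the master seed: train/test split, collaborative-filtering fit, agent
#' training where the method learns, greedy plan generation for a sample
#' of evaluation users, and scoring of every recommended meal by its
#' Prerow value, TOPSIS preference score and the simulated user's rating.
#'
#' @param method One of [method_registry()].
#' @param world A [generate_world()] result.
#' @param runs Number of repetitions (default 10).
#' @param seed Master seed.
#' @param ... Passed to the per-run experiment (`config`, `cf_k`,
#'   `n_train_users`, `n_eval_users`, `train_frac`).
#' @return List of class `method_result`: `method`, `avg_pv`, `avg_pref`,
#'   `avg_accept`, `n_runs`, `per_run` (tibble of per-run averages),
#'   `plans` (all recommended meals).
#' @export
evaluate_method <- function(method, world, runs = 10, seed = 1, ...) {
  method <- match.arg(method, method_registry())
  if (runs < 1) stop_mealrl("`runs` must be >= 1")
  run_seeds <- derive_seeds(seed, runs, salt = 101L)
  plans <- lapply(seq_len(runs), function(i) {
    p <- run_experiment(method, world, run_seeds[i], ...)
    p$run <- i
    p
  })
  plans <- dplyr::bind_rows(plans)
  per_run <- dplyr::summarise(
    dplyr::group_by(plans, .data$run),
    avg_pv = mean(.data$pv), avg_pref = mean(.data$preference),
    avg_accept = mean(.data$accept), .groups = "drop"
  )
  structure(
    list(method = method,
         avg_pv = mean(per_run$avg_pv),
         avg_pref = mean(per_run$avg_pref),
         avg_accept = mean(per_run$avg_accept),
         n_runs = runs, per_run = per_run, plans = plans),
    class = "method_result"
  )
}

#' @export
print.method_result <- function(x, ...) {
  cat(sprintf("<method_result> %s: avg PV %.3f, avg preference %.3f, avg acceptance %.2f (%d runs)\n",
              x$method, x$avg_pv, x$avg_pref, x$avg_accept, x$n_runs))
  invisible(x)
}

#' Compare registered methods on one synthetic world
#'
#' Evaluates each requested method with [evaluate_method()] under the
#' same master seed and assembles a comparison table (average PV on
#' 0-1, average preference score on 0-1, average acceptance on 1-5),
#' plus a one-way ANOVA across methods on the per-run acceptance scores
#' as a convenience.
#'
#' @param world A [generate_world()] result.
#' @param methods Methods to compare (default all of [method_registry()]).
#' @param runs Repetitions per method.
#' @param seed Master seed.
#' @param ... Passed through to [evaluate_method()].
#' @return List of class `method_comparison`: `table` (one row per
#'   method), `results` (named list of `method_result`), `anova`.
#' @export
compare_methods <- function(world, methods = method_registry(), runs = 10,
                            seed = 1, ...) {
  results <- lapply(methods, evaluate_method, world = world, runs = runs,
                    seed = seed, ...)
  names(results) <- methods
  tab <- dplyr::bind_rows(lapply(results, function(r) {
    tibble::tibble(method = r$method, avg_pv = r$avg_pv,
                   avg_pref = r$avg_pref, avg_accept = r$avg_accept,
                   n_runs = r$n_runs)
  }))
  per_run <- dplyr::bind_rows(lapply(results, function(r) {
    dplyr::mutate(r$per_run, method = r$method)
  }))
  anova_fit <- if (length(methods) > 1 && runs > 1) {
    stats::aov(avg_accept ~ method, data = per_run)
  } else {
    NULL
  }
  structure(list(table = tab, results = results, anova = anova_fit,
                 per_run = per_run, seed = seed),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat("<method_comparison>\n")
  print(as.data.frame(x$table), row.names = FALSE, digits = 3)
  invisible(x)
}

#' Exhaustive grid search over hyperparameters
#'
#' Evaluates an objective at every combination of the supplied parameter
#' values with a fixed per-cell seed and returns the argmax, with ties
#' broken toward the earliest cell in grid order.
#'
#' @param grid Named list of parameter value vectors.
#' @param objective Function `(params, seed) -> scalar` where `params` is
#'   a named list for one cell; larger is better.
#' @param seed Master seed; cell seeds are derived from it.
#' @return List with `best` (named list), `best_value`, and `table`
#'   (one row per cell with its objective value).
#' @export
grid_search <- function(grid, objective, seed = 1) {
  if (length(grid) == 0L || any(lengths(grid) == 0L)) {
    stop_mealrl("`grid` must be a non-empty named list of value vectors")
  }
  cells <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cell_seeds <- derive_seeds(seed, nrow(cells), salt = 7L)
  values <- vapply(seq_len(nrow(cells)), function(i) {
    objective(as.list(cells[i, , drop = FALSE]), cell_seeds[i])
  }, numeric(1))
  best_i <- which.max(values)  # which.max takes the first maximum: stable
  tab <- tibble::as_tibble(cells)
  tab$objective <- values
  list(best = as.list(cells[best_i, , drop = FALSE]),
       best_value = values[best_i], table = tab)
}
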