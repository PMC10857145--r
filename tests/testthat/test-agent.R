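make_test_env <- function(world = small_world(), uid = "u001",
                          weights = reward_weights(),
                          oracle = NULL) {
  rm <- build_rating_matrix(world$interactions, names(world$users),
                            world$catalogue)
  model <- fit_svd(rm, k = 2, epochs = 30, reg = 1.2, optimizer = "als")
  make_environment(world$users[[uid]], world$catalogue, model,
                   weights = weights,
                   rating_oracle = oracle %||% rating_oracle(world))
}
`%||%` <- function(x, y) if (is.null(x)) y else x

test_that("environment reset is deterministic and steps stay in contract", {
  w <- small_world()
  env <- make_test_env(w)
  expect_identical(env$reset(), env$reset())
  withr::with_seed(3, {
    for (a in sample(env$n_actions, 5)) {
      out <- env$step(a)
      expect_gte(out$reward, 0); expect_lte(out$reward, 1)
      expect_length(out$state, env$state_dim)
      # reward conservation: composite equals the weighted components
      expect_equal(out$reward,
                   compose_reward(out$ru, out$n, out$p, env$weights))
    }
  })
  expect_error(env$step(0), "invalid action")
})

test_that("a top rating on a poorly-predicted meal raises its predicted acceptance", {
  w <- small_world()
  env <- make_test_env(w, oracle = constant_oracle(5))
  env$reset()
  worst <- which.min(env$predicted_acceptance())
  before <- env$predicted_acceptance()[worst]
  env$step(worst)
  expect_gt(env$predicted_acceptance()[worst], before)
})

test_that("context features extend the state vector when enabled", {
  w <- small_world()
  rm <- build_rating_matrix(w$interactions, names(w$users), w$catalogue)
  model <- fit_svd(rm, k = 2, epochs = 30, reg = 1.2, optimizer = "als")
  env <- make_environment(w$users[["u001"]], w$catalogue, model,
                          rating_oracle = rating_oracle(w),
                          context_features = TRUE)
  expect_equal(env$state_dim, 2 + 7 + 3)
  withr::with_seed(1, out <- env$step(3))
  expect_length(out$state, env$state_dim)
})

test_that("training runs the episode loop deterministically", {
  env <- make_bandit_environment(c(0.2, 0.8))
  cfg <- agent_config("methods", episodes = 20, steps_per_episode = 2,
                      hidden = c(16), seed = 3)
  a1 <- train_agent(env, cfg)
  a2 <- train_agent(env, cfg)
  expect_identical(a1$net$W, a2$net$W)
  expect_identical(a1$episodes, a2$episodes)
  expect_equal(nrow(a1$episodes), 40)
  expect_equal(max(a1$episodes$episode), 20)
  # epsilon decays multiplicatively to the floor, constant within episodes
  eps <- unique(a1$episodes[, c("episode", "epsilon")])
  expect_equal(eps$epsilon,
               pmax(0.05, cfg$epsilon0 * cfg$epsilon_decay^(eps$episode - 1)))
  # zero-episode runs return the untrained network and empty log
  a0 <- train_agent(env, agent_config("methods", episodes = 0, hidden = c(16)))
  expect_equal(nrow(a0$episodes), 0)
})

test_that("the agent finds the best arm of a deterministic bandit", {
  wins <- 0L
  for (s in 1:3) {
    env <- make_bandit_environment(c(0.1, 0.2, 0.3, 0.4, 0.9))
    cfg <- agent_config("experiments", episodes = 120, steps_per_episode = 1,
                        epsilon_decay = 0.97, seed = s)
    ag <- train_agent(env, cfg)
    wins <- wins + (select_action(ag$net, env$reset(), 0) == 5L)
  }
  expect_gte(wins, 2L)
})

test_that("greedy plans fill every slot with in-range scores", {
  w <- small_world()
  env <- make_test_env(w)
  cfg <- agent_config("experiments", episodes = 15, steps_per_episode = 3,
                      terminal_steps = TRUE, seed = 2)
  ag <- train_agent(env, cfg)
  plan <- recommend_plan(ag, env)
  expect_equal(plan$meal_type, c("breakfast", "lunch", "dinner"))
  expect_true(all(plan$meal_id %in% w$catalogue$meal_id))
  expect_true(all(plan$pv >= 0 & plan$pv <= 1))
  expect_true(all(plan$preference >= 0 & plan$preference <= 1))
  expect_true(all(plan$predicted_rating >= 1 & plan$predicted_rating <= 5))
  # catalogue with exactly one meal per type returns that plan
  cat1 <- tiny_catalogue()[1:3, ]
  ints <- tibble::tibble(user_id = rep(c("u1", "u2"), each = 3),
                         meal_id = rep(cat1$meal_id, 2),
                         rating = c(4L, 3L, 5L, 2L, 4L, 3L),
                         timestamp = 1:6)
  rm <- build_rating_matrix(ints, c("u1", "u2"), cat1)
  model <- fit_svd(rm, k = 1, epochs = 20, seed = 1)
  env1 <- make_environment(user_profile("u1"), cat1, model,
                           rating_oracle = constant_oracle(4))
  plan1 <- recommend_plan(q_network(env1$state_dim, env1$n_actions,
                                    hidden = c(8), seed = 1), env1)
  expect_equal(plan1$meal_id, cat1$meal_id)
  expect_error(
    recommend_plan(ag, env, meal_types = "brunch"),
    "brunch"
  )
})

test_that("rewards collected by a greedy plan beat random plans on known utilities", {
  w <- small_world(seed = 4)
  env <- make_test_env(w, uid = "u002")
  cfg <- agent_config("experiments", episodes = 120, steps_per_episode = 3,
                      epsilon_decay = 0.97, terminal_steps = TRUE, seed = 6)
  ag <- train_agent(env, cfg)
  plan <- recommend_plan(ag, env)
  true_u <- w$u_star["u002", plan$meal_id]
  pvs <- env$pv[match(plan$meal_id, w$catalogue$meal_id)]
  greedy_quality <- mean(0.3 * true_u + 0.4 * pvs)
  withr::with_seed(8, {
    rand_quality <- replicate(100, {
      idx <- c(sample(which(w$catalogue$meal_type == "breakfast"), 1),
               sample(which(w$catalogue$meal_type == "lunch"), 1),
               sample(which(w$catalogue$meal_type == "dinner"), 1))
      mean(0.3 * w$u_star["u002", idx] + 0.4 * env$pv[idx])
    })
  })
  expect_gte(greedy_quality, stats::median(rand_quality))
})
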