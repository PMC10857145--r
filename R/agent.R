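#' Agent configuration
#'
#' Hyperparameters for the deep Q-learning agent. Two named presets are
#' shipped: `"experiments"` (the default: learning rate 25e-4, discount
#' 0.99, 300 episodes) and `"methods"` (learning rate 0.01, discount
#' 0.95). Exploration starts at `epsilon0` and decays multiplicatively
#' per episode to `epsilon_min`.
#'
#' @param preset `"experiments"` or `"methods"`, or `NULL` for fully
#'   manual settings.
#' @param lr Learning rate.
#' @param gamma Discount factor in `[0, 1]`.
#' @param epsilon0,epsilon_min,epsilon_decay Exploration schedule.
#' @param episodes Number of training episodes K.
#' @param steps_per_episode Time steps T per episode (default 3, one
#'   breakfast/lunch/dinner round).
#' @param replay_capacity,minibatch Replay memory size and sample size.
#' @param hidden Hidden layer sizes of the Q-network.
#' @param optimizer `"adam"` (default) or `"sgd"`.
#' @param target_sync Sync period (in updates) for an optional frozen
#'   target network; `0` (default) bootstraps from the online network.
#' @param terminal_steps Store every transition as terminal (default
#'   `FALSE`: only the last step of an episode is terminal). In the meal
#'   domain one slot's reward does not depend on the other slots of the
#'   day, so the day-plan episode is really `T` independent decisions;
#'   setting this treats it that way and removes the bootstrap term,
#'   which is statistically much better behaved at small sample sizes.
#' @param seed Master seed for the run.
#' @return List of class `agent_config`.
#' @export
agent_config <- function(preset = c("experiments", "methods"),
                         lr = NULL, gamma = NULL,
                         epsilon0 = 1, epsilon_min = 0.05,
                         epsilon_decay = 0.995,
                         episodes = 300, steps_per_episode = 3,
                         replay_capacity = 10000, minibatch = 32,
                         hidden = c(128, 64, 32),
                         optimizer = "adam", target_sync = 0,
                         terminal_steps = FALSE, seed = 1) {
  if (!is.null(preset)) {
    preset <- match.arg(preset)
    defaults <- switch(preset,
      experiments = list(lr = 25e-4, gamma = 0.99),
      methods = list(lr = 0.01, gamma = 0.95)
    )
    lr <- lr %||% defaults$lr
    gamma <- gamma %||% defaults$gamma
  }
  if (is.null(lr) || is.null(gamma)) {
    stop_mealrl("`lr` and `gamma` are required when no preset is used")
  }
  stopifnot(lr > 0, gamma >= 0, gamma <= 1,
            epsilon0 >= 0, epsilon0 <= 1, epsilon_min >= 0,
            replay_capacity >= minibatch, episodes >= 0, steps_per_episode >= 1)
  structure(
    list(lr = lr, gamma = gamma, epsilon0 = epsilon0,
         epsilon_min = epsilon_min, epsilon_decay = epsilon_decay,
         episodes = as.integer(episodes),
         steps_per_episode = as.integer(steps_per_episode),
         replay_capacity = as.integer(replay_capacity),
         minibatch = as.integer(minibatch), hidden = hidden,
         optimizer = optimizer, target_sync = as.integer(target_sync),
         terminal_steps = isTRUE(terminal_steps),
         seed = as.integer(seed), preset = preset %||% "custom"),
    class = "agent_config"
  )
}

#' Train a deep Q-learning agent on interactive recommendation
#'
#' Runs `episodes` training episodes. Each episode picks one environment
#' (user) round-robin from `envs`, resets it, and executes
#' `steps_per_episode` steps: epsilon-greedy action selection, an
#' environment step (rating, reward, latent-state update), storage of the
#' transition in the replay memory, and one minibatch Q-update. The last
#' step of an episode is terminal (no bootstrap), and because rewards lie
#' in `[0, 1]` the bootstrap target is clipped at `steps_per_episode`,
#' the largest feasible return (see [q_update()]). Epsilon decays
#' multiplicatively after every episode. Fully deterministic for a fixed
#' config seed.
#'
#' @param envs A single environment or list of environments sharing
#'   `state_dim` and `n_actions` (see [make_environment()]).
#' @param config An [agent_config()].
#' @param net Optional pre-built [q_network()]; by default one is created
#'   to match the environments.
#' @return List of class `trained_agent`: `net`, `config`, and `episodes`
#'   (a tibble with one row per step: episode, step, meal_id, reward, ru,
#'   n, p, epsilon, loss).
#' @export
train_agent <- function(envs, config = agent_config(), net = NULL) {
  if (inherits(envs, "rl_env")) envs <- list(envs)
  if (length(envs) == 0L) stop_mealrl("need at least one environment")
  sd1 <- envs[[1]]$state_dim; na1 <- envs[[1]]$n_actions
  for (e in envs) {
    if (e$state_dim != sd1 || e$n_actions != na1) {
      stop_mealrl("all environments must share state_dim and n_actions")
    }
  }
  net <- net %||% q_network(sd1, na1, hidden = config$hidden,
                            seed = config$seed, optimizer = config$optimizer)
  if (config$episodes == 0L) {
    return(structure(list(net = net, config = config,
                          episodes = empty_episode_log()),
                     class = "trained_agent"))
  }
  buf <- replay_buffer(config$replay_capacity)
  target_net <- if (config$target_sync > 0L) net else NULL
  eps <- config$epsilon0
  log_rows <- vector("list", config$episodes * config$steps_per_episode)
  row <- 0L
  n_updates <- 0L

  withr::with_seed(config$seed, {
    for (k in seq_len(config$episodes)) {
      env <- envs[[((k - 1L) %% length(envs)) + 1L]]
      s <- env$reset()
      for (t in seq_len(config$steps_per_episode)) {
        a <- select_action(net, s, eps)
        out <- env$step(a)
        done <- config$terminal_steps || t == config$steps_per_episode
        buffer_push(buf, list(state = s, action = a, reward = out$reward,
                              next_state = out$state, done = done))
        batch <- buffer_sample(buf, config$minibatch)
        upd <- q_update(net, batch, config$lr, config$gamma, target_net,
                        target_clip = config$steps_per_episode)
        net <- upd$net
        if (!is.finite(upd$loss)) stop_mealrl("non-finite training loss")
        n_updates <- n_updates + 1L
        if (config$target_sync > 0L && n_updates %% config$target_sync == 0L) {
          target_net <- net
        }
        row <- row + 1L
        log_rows[[row]] <- tibble::tibble(
          episode = k, step = t, meal_id = out$meal_id,
          reward = out$reward, ru = out$ru, n = out$n, p = out$p,
          epsilon = eps, loss = upd$loss
        )
        s <- out$state
      }
      eps <- max(config$epsilon_min, eps * config$epsilon_decay)
    }
  })

  structure(list(net = net, config = config,
                 episodes = dplyr::bind_rows(log_rows)),
            class = "trained_agent")
}

empty_episode_log <- function() {
  tibble::tibble(episode = integer(), step = integer(), meal_id = character(),
                 reward = numeric(), ru = numeric(), n = numeric(),
                 p = numeric(), epsilon = numeric(), loss = numeric())
}

#' @export
print.trained_agent <- function(x, ...) {
  n_ep <- if (nrow(x$episodes)) max(x$episodes$episode) else 0L
  cat(sprintf("<trained_agent> %d episodes, mean reward %.3f (last 50: %.3f)\n",
              n_ep,
              if (nrow(x$episodes)) mean(x$episodes$reward) else NA_real_,
              if (nrow(x$episodes)) mean(tail(x$episodes$reward, 50)) else NA_real_))
  invisible(x)
}

#' Greedy meal plan, one meal per slot
#'
#' Selects, with exploration off, the highest-valued candidate within
#' each requested meal-type slot and reports its preference score,
#' Prerow value and predicted acceptance rating.
#'
#' @param agent A [train_agent()] result (or a bare `q_network`).
#' @param env A [make_environment()] for the target user.
#' @param meal_types Slots to fill (default breakfast, lunch, dinner).
#' @return Tibble with one row per slot: `meal_type`, `meal_id`, `name`,
#'   `preference`, `pv`, `predicted_rating`.
#' @export
recommend_plan <- function(agent, env,
                           meal_types = c("breakfast", "lunch", "dinner")) {
  net <- if (inherits(agent, "trained_agent")) agent$net else agent
  s <- env$reset()
  q <- q_forward(net, s)[1L, ]
  pref <- env$preference()
  acc <- env$predicted_acceptance()
  rows <- lapply(meal_types, function(mt) {
    idx <- which(env$catalogue$meal_type == mt)
    if (length(idx) == 0L) stop_mealrl("no candidate meals for slot: ", mt)
    best <- idx[which.max(q[idx])]
    tibble::tibble(
      meal_type = mt,
      meal_id = env$catalogue$meal_id[best],
      name = if ("name" %in% names(env$catalogue)) env$catalogue$name[best] else NA_character_,
      preference = pref[best],
      pv = env$pv[best],
      predicted_rating = 1 + 4 * acc[best]
    )
  })
  dplyr::bind_rows(rows)
}
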