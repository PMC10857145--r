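#' Feed-forward Q-network
#'
#' A fully connected network mapping a state vector to one action value
#' per candidate meal: rectified-linear hidden layers (default sizes
#' 128, 64, 32), a linear output head, squared-error loss. Weights use
#' He initialization. Training uses either the plain Q-learning gradient
#' step or Adam (the default).
#'
#' @param state_dim Input dimension.
#' @param n_actions Output dimension (number of candidate meals).
#' @param hidden Integer vector of hidden layer sizes; `integer(0)` gives
#'   a linear network (useful for hand-checkable degenerate cases).
#' @param seed Seed for weight initialization.
#' @param optimizer `"adam"` or `"sgd"`.
#' @param bias Include additive bias terms (default `TRUE`). Disable to
#'   obtain the pure weight-vector parameterization of the textbook
#'   Q-learning update.
#' @return Object of class `q_network`.
#' @export
q_network <- function(state_dim, n_actions, hidden = c(128, 64, 32),
                      seed = 1, optimizer = c("adam", "sgd"), bias = TRUE) {
  optimizer <- match.arg(optimizer)
  sizes <- c(state_dim, hidden, n_actions)
  L <- length(sizes) - 1L
  withr::with_seed(seed, {
    W <- lapply(seq_len(L), function(l) {
      matrix(rnorm(sizes[l] * sizes[l + 1L], sd = sqrt(2 / sizes[l])),
             sizes[l], sizes[l + 1L])
    })
  })
  # zero output head: initial Q == 0 everywhere, so early bootstrap targets
  # are the observed rewards rather than the max of init noise over actions
  W[[L]][] <- 0
  b <- lapply(seq_len(L), function(l) numeric(sizes[l + 1L]))
  adam <- list(
    mW = lapply(W, function(w) w * 0), vW = lapply(W, function(w) w * 0),
    mb = lapply(b, function(x) x * 0), vb = lapply(b, function(x) x * 0),
    t = 0L
  )
  structure(list(W = W, b = b, sizes = sizes, L = L, optimizer = optimizer,
                 adam = adam, state_dim = state_dim, n_actions = n_actions,
                 bias = bias),
            class = "q_network")
}

#' @export
print.q_network <- function(x, ...) {
  cat(sprintf("<q_network> %s (%s)\n", paste(x$sizes, collapse = " -> "),
              x$optimizer))
  invisible(x)
}

relu <- function(x) x * (x > 0)

#' Forward pass: action values for a batch of states
#'
#' @param net A [q_network()].
#' @param states Numeric matrix (batch x state_dim) or a single state
#'   vector.
#' @param keep_activations Return intermediate activations (used by the
#'   backward pass).
#' @return Matrix of Q-values (batch x n_actions), or a list with
#'   activations when requested.
#' @export
q_forward <- function(net, states, keep_activations = FALSE) {
  X <- if (is.matrix(states)) states else matrix(states, nrow = 1L)
  acts <- vector("list", net$L + 1L)
  acts[[1L]] <- X
  H <- X
  for (l in seq_len(net$L)) {
    Z <- H %*% net$W[[l]]
    Z <- sweep(Z, 2L, net$b[[l]], "+")
    H <- if (l < net$L) relu(Z) else Z
    acts[[l + 1L]] <- H
  }
  if (keep_activations) list(q = H, activations = acts) else H
}

# One gradient step minimizing 0.5 * mean_i delta_i^2 where delta is the
# TD error on the taken actions only. `grad_out` is (batch x n_actions)
# with -delta at the taken action (d loss / d Q).
backprop_step <- function(net, acts, grad_out, lr) {
  B <- nrow(grad_out)
  G <- grad_out
  dW <- vector("list", net$L)
  db <- vector("list", net$L)
  for (l in rev(seq_len(net$L))) {
    dW[[l]] <- crossprod(acts[[l]], G) / B
    db[[l]] <- if (net$bias) colSums(G) / B else net$b[[l]] * 0
    if (l > 1L) {
      G <- (G %*% t(net$W[[l]])) * (acts[[l]] > 0)
    }
  }
  if (net$optimizer == "adam") {
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    net$adam$t <- net$adam$t + 1L
    t <- net$adam$t
    for (l in seq_len(net$L)) {
      net$adam$mW[[l]] <- b1 * net$adam$mW[[l]] + (1 - b1) * dW[[l]]
      net$adam$vW[[l]] <- b2 * net$adam$vW[[l]] + (1 - b2) * dW[[l]]^2
      net$adam$mb[[l]] <- b1 * net$adam$mb[[l]] + (1 - b1) * db[[l]]
      net$adam$vb[[l]] <- b2 * net$adam$vb[[l]] + (1 - b2) * db[[l]]^2
      mW_hat <- net$adam$mW[[l]] / (1 - b1^t)
      vW_hat <- net$adam$vW[[l]] / (1 - b2^t)
      mb_hat <- net$adam$mb[[l]] / (1 - b1^t)
      vb_hat <- net$adam$vb[[l]] / (1 - b2^t)
      net$W[[l]] <- net$W[[l]] - lr * mW_hat / (sqrt(vW_hat) + eps)
      net$b[[l]] <- net$b[[l]] - lr * mb_hat / (sqrt(vb_hat) + eps)
    }
  } else {
    for (l in seq_len(net$L)) {
      net$W[[l]] <- net$W[[l]] - lr * dW[[l]]
      net$b[[l]] <- net$b[[l]] - lr * db[[l]]
    }
  }
  net
}

#' One Q-learning update on a minibatch of transitions
#'
#' Applies the update
#' \eqn{w \leftarrow w + \alpha [r + \gamma \max_a \hat Q(s', a) - \hat Q(s, a)] \nabla_w \hat Q(s, a)},
#' i.e. a gradient step on the squared temporal-difference error, with the
#' bootstrap target taken from the online network (or a frozen target
#' network when supplied). Transitions flagged `done` use the bare reward
#' as target.
#'
#' @param net A [q_network()].
#' @param batch List of transitions, each a list with `state`, `action`
#'   (1-based), `reward`, `next_state`, optional `done`.
#' @param alpha Learning rate.
#' @param gamma Discount factor in `[0, 1]`.
#' @param target_net Optional frozen network for the bootstrap target.
#' @param target_clip Upper bound applied to the bootstrap target
#'   (default `Inf`, no clipping). When rewards are bounded in `[0, 1]`
#'   and episodes have `T` steps, no true return exceeds `T`, so clipping
#'   at `T` caps the well-known max-operator overestimation spiral
#'   without biasing feasible values.
#' @return List with the updated `net` and the mean squared TD error
#'   `loss`.
#' @export
q_update <- function(net, batch, alpha, gamma, target_net = NULL,
                     target_clip = Inf) {
  if (length(batch) == 0L) stop_mealrl("minibatch must be non-empty")
  S <- do.call(rbind, lapply(batch, `[[`, "state"))
  S2 <- do.call(rbind, lapply(batch, `[[`, "next_state"))
  a <- vapply(batch, `[[`, numeric(1), "action")
  r <- vapply(batch, `[[`, numeric(1), "reward")
  done <- vapply(batch, function(tr) isTRUE(tr$done), logical(1))

  fwd <- q_forward(net, S, keep_activations = TRUE)
  q_sa <- fwd$q[cbind(seq_along(a), a)]
  q_next <- q_forward(target_net %||% net, S2)
  target <- pmin(r + gamma * apply(q_next, 1L, max) * !done, target_clip)
  delta <- target - q_sa
  if (any(!is.finite(delta))) stop_mealrl("non-finite TD error")

  grad_out <- matrix(0, nrow(fwd$q), ncol(fwd$q))
  grad_out[cbind(seq_along(a), a)] <- -delta
  net <- backprop_step(net, fwd$activations, grad_out, alpha)
  list(net = net, loss = mean(delta^2))
}

#' Epsilon-greedy action selection
#'
#' With probability `epsilon` a uniform random candidate, otherwise the
#' argmax of the network's action values (ties broken toward the lowest
#' index). Draws come from the session RNG, so a seed set by the caller
#' makes the sequence reproducible.
#'
#' @param net A [q_network()].
#' @param state State vector.
#' @param epsilon Exploration probability in `[0, 1]`.
#' @return Action index (1-based).
#' @export
select_action <- function(net, state, epsilon) {
  if (epsilon < 0 || epsilon > 1) stop_mealrl("`epsilon` must lie in [0, 1]")
  if (epsilon > 0 && runif(1) < epsilon) {
    sample.int(net$n_actions, 1L)
  } else {
    q <- q_forward(net, state)
    which.max(q[1L, ])
  }
}

#' Bounded FIFO replay buffer
#'
#' Stores transitions up to `capacity`; once full, the oldest transition
#' is evicted first. Minibatches are sampled uniformly without
#' replacement.
#'
#' @param capacity Maximum number of stored transitions.
#' @return Object of class `replay_buffer` (an environment).
#' @export
replay_buffer <- function(capacity = 10000) {
  buf <- new.env(parent = emptyenv())
  buf$data <- vector("list", capacity)
  buf$capacity <- as.integer(capacity)
  buf$n <- 0L       # number stored
  buf$head <- 0L    # next write position (circular)
  class(buf) <- "replay_buffer"
  buf
}

#' @rdname replay_buffer
#' @param buf A replay buffer.
#' @param transition List with `state`, `action`, `reward`, `next_state`,
#'   optional `done`.
#' @export
buffer_push <- function(buf, transition) {
  buf$head <- (buf$head %% buf$capacity) + 1L
  buf$data[[buf$head]] <- transition
  buf$n <- min(buf$n + 1L, buf$capacity)
  invisible(buf)
}

#' @rdname replay_buffer
#' @param size Minibatch size; capped at the current buffer size.
#' @export
buffer_sample <- function(buf, size) {
  if (buf$n == 0L) stop_mealrl("replay buffer is empty")
  idx <- sample.int(buf$n, min(size, buf$n))
  buf$data[idx]
}

#' @rdname replay_buffer
#' @export
buffer_size <- function(buf) buf$n
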