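#' Training configuration for the TD learners
#'
#' @param iterations Number of gradient (or tabular-update) iterations.
#' @param learning_rate Step size `alpha` (default 1e-4, the network
#'   default; tabular toys typically use a larger value such as 0.1).
#' @param gamma Discount factor in `(0, 1]` (default 0.9).
#' @param batch_size Mini-batch size (default 32).
#' @param target_sync_interval How often (in iterations) the DDQN target
#'   network copies the primary parameters (default 500).
#' @param seed Integer seed; full training runs are deterministic given the
#'   seed.
#' @param checkpoint_iterations Optional increasing vector of iterations at
#'   which parameter snapshots are saved (e.g. `c(3000, 10000, 20000, 30000)`).
#' @param hidden Hidden layer widths of the Q-network (default
#'   `c(128, 128)`).
#' @param target_clip Optional length-2 interval to which TD targets are
#'   clipped. With terminal-only rewards of -15/+15 no true action value can
#'   leave `[-15, 15]`, so clipping to the attainable return range cannot
#'   bias in-range values but prevents the max-bootstrap inflation loop.
#'   `NULL` (default) disables clipping.
#' @param weight_decay Decoupled per-iteration multiplicative decay applied
#'   to the network weights after each update (e.g. 1e-4). Shrinks weight
#'   components that receive no gradient -- the Q-values of actions unseen
#'   in a state region are otherwise unconstrained extrapolations, and the
#'   greedy argmax would chase them. Default 0.
#' @return Object of class `training_config`.
#' @export
training_config <- function(iterations,
                            learning_rate = 1e-4,
                            gamma = 0.9,
                            batch_size = 32L,
                            target_sync_interval = 500L,
                            seed = 1L,
                            checkpoint_iterations = NULL,
                            hidden = c(128L, 128L),
                            target_clip = NULL,
                            weight_decay = 0) {
  if (!is.numeric(iterations) || iterations < 1) {
    stop("iterations must be >= 1", call. = FALSE)
  }
  if (learning_rate <= 0 || learning_rate > 1) {
    stop("learning_rate must lie in (0, 1]", call. = FALSE)
  }
  if (gamma <= 0 || gamma > 1) stop("gamma must lie in (0, 1]", call. = FALSE)
  if (batch_size < 1) stop("batch_size must be >= 1", call. = FALSE)
  if (target_sync_interval < 1) {
    stop("target_sync_interval must be >= 1", call. = FALSE)
  }
  if (!is.null(checkpoint_iterations)) {
    checkpoint_iterations <- sort(unique(as.integer(checkpoint_iterations)))
    if (any(checkpoint_iterations < 1) ||
        max(checkpoint_iterations) > iterations) {
      stop("checkpoint_iterations must lie in 1..iterations", call. = FALSE)
    }
  }
  if (!is.null(target_clip) &&
      (length(target_clip) != 2 || target_clip[1] >= target_clip[2])) {
    stop("target_clip must be an increasing length-2 interval", call. = FALSE)
  }
  if (weight_decay < 0) stop("weight_decay must be >= 0", call. = FALSE)
  structure(list(iterations = as.integer(iterations),
                 learning_rate = learning_rate, gamma = gamma,
                 batch_size = as.integer(batch_size),
                 target_sync_interval = as.integer(target_sync_interval),
                 seed = as.integer(seed),
                 checkpoint_iterations = checkpoint_iterations,
                 hidden = as.integer(hidden),
                 target_clip = target_clip,
                 weight_decay = weight_decay),
            class = "training_config")
}

#' SARSA temporal-difference target
#'
#' The on-policy target `r + gamma * Q(s', a')`, where `a'` is the action
#' actually taken at the next block in the logged data; terminal transitions
#' return the bare reward (no bootstrapping).
#'
#' @param transitions A `transition_set`.
#' @param q Q-function (see [q_values()]).
#' @param gamma Discount factor.
#' @param idx Optional row subset.
#' @return Numeric vector of targets.
#' @export
td_target_sarsa <- function(transitions, q, gamma, idx = NULL) {
  if (is.null(idx)) idx <- seq_along(transitions$actions)
  term <- transitions$terminal[idx]
  if (any(!term & is.na(transitions$next_actions[idx]))) {
    stop("non-terminal transition is missing its next action", call. = FALSE)
  }
  target <- transitions$rewards[idx]
  nt <- idx[!term]
  if (length(nt)) {
    ns <- if (transitions$type == "tabular") transitions$next_states[nt] else
      transitions$next_states[nt, , drop = FALSE]
    qn <- q_values(q, ns)
    target[!term] <- target[!term] +
      gamma * qn[cbind(seq_len(nrow(qn)), transitions$next_actions[nt] + 1L)]
  }
  target
}

#' Double-DQN temporal-difference target
#'
#' The primary network selects the next action (`a* = argmax_a
#' primary(s', a)`), the target network evaluates it: the target is
#' `r + gamma * target(s', a*)`. Terminal transitions return the bare reward
#' regardless of the networks. With `primary == target` this reduces to the
#' plain Q-learning max target.
#'
#' @param transitions A `transition_set`.
#' @param primary,target Q-functions sharing an architecture.
#' @param gamma Discount factor.
#' @param idx Optional row subset.
#' @return Numeric vector of targets.
#' @export
td_target_ddqn <- function(transitions, primary, target, gamma, idx = NULL) {
  if (is.null(idx)) idx <- seq_along(transitions$actions)
  term <- transitions$terminal[idx]
  out <- transitions$rewards[idx]
  nt <- idx[!term]
  if (length(nt)) {
    ns <- if (transitions$type == "tabular") transitions$next_states[nt] else
      transitions$next_states[nt, , drop = FALSE]
    qp <- q_values(primary, ns)
    a_star <- max.col(qp, ties.method = "first")
    qt <- q_values(target, ns)
    out[!term] <- out[!term] + gamma * qt[cbind(seq_len(nrow(qt)), a_star)]
  }
  out
}

state_standardizer <- function(S) {
  mu <- colMeans(S)
  sg <- apply(S, 2, stats::sd)
  sg[!is.finite(sg) | sg == 0] <- 1
  list(center = mu, scale = sg)
}

new_trained_model <- function(type, q, loss, checkpoints, config) {
  structure(list(type = type, q = q, loss = loss,
                 checkpoints = checkpoints, config = config),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained_model: %s, %d iterations, final smoothed loss %.4f>\n",
              x$type, length(x$loss),
              mean(utils::tail(x$loss, min(200, length(x$loss))))))
  invisible(x)
}

# Shared mini-batch trainer for the network learners.
train_qnet_core <- function(transitions, config, method) {
  set.seed(config$seed)
  S <- transitions$states
  std <- state_standardizer(S)
  primary <- q_network(n_in = ncol(S), hidden = config$hidden,
                       n_out = transitions$n_actions,
                       center = std$center, scale = std$scale)
  target_net <- primary
  st <- adam_state(primary)
  n <- nrow(S)
  loss <- numeric(config$iterations)
  checkpoints <- list()
  for (it in seq_len(config$iterations)) {
    idx <- sample.int(n, config$batch_size, replace = TRUE)
    y <- if (method == "sarsa") {
      td_target_sarsa(transitions, primary, config$gamma, idx)
    } else if (method == "ddqn") {
      td_target_ddqn(transitions, primary, target_net, config$gamma, idx)
    } else {  # single-network DQN: selection and evaluation share weights
      td_target_ddqn(transitions, primary, primary, config$gamma, idx)
    }
    if (!is.null(config$target_clip)) {
      y <- pmin(config$target_clip[2], pmax(config$target_clip[1], y))
    }
    X <- S[idx, , drop = FALSE]
    fw <- qnet_forward(primary, X, keep = TRUE)
    g <- qnet_grad(primary, fw, transitions$actions[idx], y)
    upd <- adam_update(primary, g, st, config$learning_rate)
    primary <- upd$net
    st <- upd$state
    if (config$weight_decay > 0) {
      for (l in seq_along(primary$W)) {
        primary$W[[l]] <- primary$W[[l]] * (1 - config$weight_decay)
      }
    }
    loss[it] <- g$loss
    if (method == "ddqn" && it %% config$target_sync_interval == 0) {
      target_net <- primary
    }
    if (!is.null(config$checkpoint_iterations) &&
        it %in% config$checkpoint_iterations) {
      checkpoints[[as.character(it)]] <- primary
    }
  }
  new_trained_model(method, primary, loss, checkpoints, config)
}

# Tabular learners used for the dynamic-programming oracle checks.
train_tab_sarsa <- function(transitions, config) {
  set.seed(config$seed)
  Q <- matrix(0, transitions$n_states, transitions$n_actions)
  n <- length(transitions$actions)
  a <- config$learning_rate
  loss <- numeric(config$iterations)
  checkpoints <- list()
  # the sequential traversal applies the same update as td_target_sarsa,
  # inlined because oracle-equivalence runs take millions of scalar steps
  g <- config$gamma
  sv <- transitions$states
  av <- transitions$actions + 1L
  rv <- transitions$rewards
  nsv <- transitions$next_states
  nav <- transitions$next_actions + 1L
  tv <- transitions$terminal
  if (any(!tv & is.na(nav))) {
    stop("non-terminal transition is missing its next action", call. = FALSE)
  }
  for (it in seq_len(config$iterations)) {
    i <- ((it - 1L) %% n) + 1L  # strictly sequential data-order traversal
    y <- if (tv[i]) rv[i] else rv[i] + g * Q[nsv[i], nav[i]]
    delta <- y - Q[sv[i], av[i]]
    Q[sv[i], av[i]] <- Q[sv[i], av[i]] + a * delta
    loss[it] <- delta * delta
    if (!is.null(config$checkpoint_iterations) &&
        it %in% config$checkpoint_iterations) {
      checkpoints[[as.character(it)]] <- Q
    }
  }
  new_trained_model("sarsa", Q, loss, checkpoints, config)
}

train_tab_q <- function(transitions, config, double = TRUE) {
  set.seed(config$seed)
  Q <- matrix(0, transitions$n_states, transitions$n_actions)
  Qt <- Q
  n <- length(transitions$actions)
  a <- config$learning_rate
  loss <- numeric(config$iterations)
  checkpoints <- list()
  for (it in seq_len(config$iterations)) {
    idx <- sample.int(n, config$batch_size, replace = TRUE)
    y <- if (double) {
      td_target_ddqn(transitions, Q, Qt, config$gamma, idx)
    } else {
      td_target_ddqn(transitions, Q, Q, config$gamma, idx)
    }
    for (j in seq_along(idx)) {
      i <- idx[j]
      s <- transitions$states[i]; act <- transitions$actions[i] + 1L
      delta <- y[j] - Q[s, act]
      Q[s, act] <- Q[s, act] + a * delta
      loss[it] <- loss[it] + delta^2
    }
    loss[it] <- loss[it] / length(idx)
    if (double && it %% config$target_sync_interval == 0) Qt <- Q
    if (!is.null(config$checkpoint_iterations) &&
        it %in% config$checkpoint_iterations) {
      checkpoints[[as.character(it)]] <- Q
    }
  }
  new_trained_model(if (double) "ddqn" else "qlearning", Q, loss,
                    checkpoints, config)
}

#' Train the on-policy SARSA model
#'
#' Mini-batch squared-error regression of `Q(s, a)` onto the SARSA target
#' `r + gamma * Q(s', a')`, where `a'` is the logged next action, over the
#' shared 25-128-128-5 Q-network. Batches of `batch_size` transitions are
#' sampled uniformly from the transition table; training is deterministic
#' given the seed. For tabular transition sets the update is applied in
#' strict data order (one transition per iteration), mirroring the
#' sequential on-policy traversal, which is what the dynamic-programming
#' oracle checks use.
#'
#' @param transitions A `transition_set` from [build_transitions()] or
#'   [tabular_transitions()].
#' @param config A [training_config()].
#' @return A `trained_model` with the Q-function, full loss history and any
#'   checkpoint snapshots.
#' @export
train_sarsa <- function(transitions, config) {
  if (length(transitions$actions) == 0) stop("empty transition set", call. = FALSE)
  if (transitions$type == "tabular") train_tab_sarsa(transitions, config)
  else train_qnet_core(transitions, config, "sarsa")
}

#' Train the double deep Q-network
#'
#' Two identically structured Q-networks: the primary network selects the
#' highest-valued next action and is updated by gradient descent on the
#' squared TD error; the target network evaluates the selected action and is
#' never updated by backpropagation -- its parameters are copied from the
#' primary every `target_sync_interval` iterations. Snapshots are saved at
#' `checkpoint_iterations` for the off-policy checkpoint evaluation.
#'
#' @inheritParams train_sarsa
#' @param double With `FALSE`, selection and evaluation use the same network
#'   (plain DQN/Q-learning); used to demonstrate the overestimation the
#'   double estimator controls.
#' @return A `trained_model`.
#' @export
train_ddqn <- function(transitions, config, double = TRUE) {
  if (length(transitions$actions) == 0) stop("empty transition set", call. = FALSE)
  if (transitions$type == "tabular") train_tab_q(transitions, config, double)
  else train_qnet_core(transitions, config, if (double) "ddqn" else "dqn")
}
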