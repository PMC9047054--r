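# Q-network: a fully connected 25 -> 128 -> 128 -> 5 multilayer perceptron
# with rectified-linear hidden units and a linear output head, trained by
# mini-batch squared-error regression of Q(s, a) onto temporal-difference
# targets. Implemented directly with matrix algebra; the Adam update keeps
# the small default learning rate (1e-4) workable for TD targets of
# magnitude up to 15.

#' Initialize a Q-network
#'
#' Weights are drawn from zero-mean normals scaled by layer fan-in and
#' truncated to `[-1, 1]`; biases start at zero. Inputs are standardized with
#' the stored `center`/`scale` before the first layer, so raw clinical state
#' vectors can be fed directly.
#'
#' @param n_in Number of state inputs (default 25).
#' @param hidden Hidden layer widths (default `c(128, 128)`).
#' @param n_out Number of actions (default 5).
#' @param center,scale Standardization applied to inputs (defaults: none).
#' @return Object of class `q_network`.
#' @export
q_network <- function(n_in = 25L, hidden = c(128L, 128L), n_out = 5L,
                      center = rep(0, n_in), scale = rep(1, n_in)) {
  sizes <- c(n_in, hidden, n_out)
  W <- list(); b <- list()
  for (l in seq_len(length(sizes) - 1L)) {
    sd_l <- 1 / sqrt(sizes[l])
    w <- stats::rnorm(sizes[l] * sizes[l + 1L], 0, sd_l)
    w <- pmin(1, pmax(-1, w))
    W[[l]] <- matrix(w, sizes[l], sizes[l + 1L])
    b[[l]] <- numeric(sizes[l + 1L])
  }
  structure(list(W = W, b = b, sizes = sizes,
                 center = center, scale = scale),
            class = "q_network")
}

qnet_scale_input <- function(net, X) {
  sweep(sweep(X, 2, net$center), 2, net$scale, "/")
}

qnet_forward <- function(net, X, keep = FALSE) {
  nl <- length(net$W)
  A <- qnet_scale_input(net, X)
  pre <- vector("list", nl)
  act <- vector("list", nl + 1L)
  act[[1L]] <- A
  for (l in seq_len(nl)) {
    Z <- A %*% net$W[[l]]
    Z <- sweep(Z, 2, net$b[[l]], "+")
    pre[[l]] <- Z
    A <- if (l < nl) pmax(Z, 0) else Z
    act[[l + 1L]] <- A
  }
  if (keep) list(Q = A, pre = pre, act = act) else A
}

# Gradient of mean squared error of Q(s, a_i) against `target`, restricted to
# the taken actions.
qnet_grad <- function(net, fw, actions, target) {
  nl <- length(net$W)
  B <- nrow(fw$Q)
  G <- matrix(0, B, ncol(fw$Q))
  sel <- cbind(seq_len(B), actions + 1L)
  G[sel] <- 2 * (fw$Q[sel] - target) / B
  dW <- vector("list", nl); db <- vector("list", nl)
  for (l in rev(seq_len(nl))) {
    dW[[l]] <- crossprod(fw$act[[l]], G)
    db[[l]] <- colSums(G)
    if (l > 1L) {
      G <- (G %*% t(net$W[[l]])) * (fw$pre[[l - 1L]] > 0)
    }
  }
  list(dW = dW, db = db,
       loss = mean((fw$Q[sel] - target)^2))
}

adam_state <- function(net) {
  zero_like <- function(p) lapply(p, function(x) x * 0)
  list(mW = zero_like(net$W), vW = zero_like(net$W),
       mb = zero_like(net$b), vb = zero_like(net$b), t = 0L)
}

adam_update <- function(net, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  st$t <- st$t + 1L
  c1 <- 1 - beta1^st$t
  c2 <- 1 - beta2^st$t
  for (l in seq_along(net$W)) {
    st$mW[[l]] <- beta1 * st$mW[[l]] + (1 - beta1) * grads$dW[[l]]
    st$vW[[l]] <- beta2 * st$vW[[l]] + (1 - beta2) * grads$dW[[l]]^2
    net$W[[l]] <- net$W[[l]] - lr * (st$mW[[l]] / c1) /
      (sqrt(st$vW[[l]] / c2) + eps)
    st$mb[[l]] <- beta1 * st$mb[[l]] + (1 - beta1) * grads$db[[l]]
    st$vb[[l]] <- beta2 * st$vb[[l]] + (1 - beta2) * grads$db[[l]]^2
    net$b[[l]] <- net$b[[l]] - lr * (st$mb[[l]] / c1) /
      (sqrt(st$vb[[l]] / c2) + eps)
  }
  list(net = net, state = st)
}

#' Q-values for a batch of states
#'
#' Evaluates a Q-function for a matrix of states (network case) or a vector
#' of integer state identifiers (tabular case, where `q` is an
#' `n_states x n_actions` matrix).
#'
#' @param q A `q_network`, a trained model, or a numeric Q-table matrix.
#' @param states State matrix (rows = samples) or integer state ids.
#' @return Numeric matrix of Q-values, one row per state, one column per
#'   action.
#' @export
q_values <- function(q, states) {
  if (inherits(q, "trained_model")) q <- q$q
  if (inherits(q, "q_network")) {
    if (is.null(dim(states))) states <- matrix(states, nrow = 1)
    return(qnet_forward(q, states))
  }
  if (is.matrix(q)) {
    return(q[as.integer(states), , drop = FALSE])
  }
  stop("q must be a q_network, trained model, or Q-table matrix", call. = FALSE)
}

#' Greedy actions of a Q-function
#'
#' Per-state argmax of the Q-values; ties are broken deterministically toward
#' the lower action index.
#'
#' @inheritParams q_values
#' @return Integer vector of actions `0..n_actions-1`.
#' @export
predict_actions <- function(q, states) {
  qv <- q_values(q, states)
  as.integer(apply(qv, 1, which.max)) - 1L
}

#' Softmax action probabilities of a Q-function
#'
#' The action report uses a softmax over Q-values; the greedy action is the
#' highest-probability action, so [predict_actions()] and the argmax of these
#' probabilities agree.
#'
#' @inheritParams q_values
#' @return Matrix of per-state action probabilities (rows sum to 1).
#' @export
action_probabilities <- function(q, states) {
  qv <- q_values(q, states)
  e <- exp(qv - apply(qv, 1, max))
  e / rowSums(e)
}

#' Save a trained model as a JSON parameter archive
#'
#' Writes the Q-function parameters (weights, biases, input standardization)
#' together with metadata (learner type, training configuration, loss-curve
#' summary) to a single JSON file. Checkpoint snapshots are not archived;
#' re-train with `checkpoint_iterations` to regenerate them.
#'
#' @param model A `trained_model` with a network Q-function.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  if (!inherits(model, "trained_model") || !inherits(model$q, "q_network")) {
    stop("only network trained models can be archived", call. = FALSE)
  }
  q <- model$q
  payload <- list(
    type = model$type,
    sizes = q$sizes,
    center = q$center,
    scale = q$scale,
    W = lapply(q$W, function(w) list(dim = dim(w), data = as.numeric(w))),
    b = q$b,
    config = model$config[c("iterations", "learning_rate", "gamma",
                            "batch_size", "target_sync_interval", "seed",
                            "weight_decay")],
    target_clip = model$config$target_clip,
    final_smoothed_loss = mean(utils::tail(model$loss,
                                           min(200, length(model$loss))))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model archived by [write_model()]
#'
#' @param path JSON file path.
#' @return A `trained_model` (without loss history or checkpoints).
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  net <- structure(list(
    W = lapply(p$W, function(w) {
      d <- unlist(w$dim)
      matrix(unlist(w$data), d[1], d[2])
    }),
    b = lapply(p$b, function(x) as.numeric(unlist(x))),
    sizes = as.integer(unlist(p$sizes)),
    center = as.numeric(unlist(p$center)),
    scale = as.numeric(unlist(p$scale))
  ), class = "q_network")
  structure(list(type = p$type, q = net, loss = numeric(0),
                 checkpoints = list(), config = p$config),
            class = "trained_model")
}
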