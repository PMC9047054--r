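#' Attribute trajectory rewards to blocks
#'
#' Off-policy estimators need a per-sample reward, but the clinical reward is
#' terminal-only. Each block is therefore attributed its trajectory's
#' terminal reward discounted back to that block,
#' `r_i = gamma^(T - t) * R_T`; `gamma = 1` gives undiscounted attribution.
#'
#' @param blocks Rewarded blocks (columns `patient_id`, `bloc`, `reward`,
#'   `terminal`).
#' @param gamma Attribution discount in `(0, 1]` (default 0.99).
#' @return Numeric vector aligned with the (patient, bloc)-ordered rows of
#'   `blocks`.
#' @export
attribute_rewards <- function(blocks, gamma = 0.99) {
  if (gamma <= 0 || gamma > 1) stop("gamma must lie in (0, 1]", call. = FALSE)
  ord <- order(blocks$patient_id, blocks$bloc)
  if (any(ord != seq_len(nrow(blocks)))) {
    stop("blocks must be ordered by patient and bloc", call. = FALSE)
  }
  r <- numeric(nrow(blocks))
  for (pid in unique(blocks$patient_id)) {
    i <- which(blocks$patient_id == pid)
    Tn <- length(i)
    r[i] <- gamma^(rev(seq_len(Tn)) - 1) * blocks$reward[i[Tn]]
  }
  r
}

#' Fit the behavior-policy propensity model
#'
#' Multinomial logistic regression of the logged action on the 25
#' standardized state features, fitted on training blocks. The per-sample
#' propensity of the logged action is floored at `clip` before any inverse
#' weighting, controlling the variance blow-up of near-zero probabilities.
#'
#' @param blocks Training blocks with the state features and an `action`
#'   column (0..4).
#' @param clip Probability floor applied to logged propensities (default
#'   0.01).
#' @return Object of class `propensity_model`.
#' @export
fit_propensities <- function(blocks, clip = 0.01) {
  feats <- state_features()
  miss <- setdiff(c(feats, "action"), names(blocks))
  if (length(miss)) {
    stop("blocks missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  X <- as.matrix(blocks[, feats, drop = FALSE])
  std <- state_standardizer(X)
  Xs <- sweep(sweep(X, 2, std$center), 2, std$scale, "/")
  df <- as.data.frame(Xs)
  df$.action <- factor(blocks$action, levels = 0:4)
  fit <- nnet::multinom(.action ~ ., data = df, trace = FALSE, maxit = 300,
                        MaxNWts = 2000)
  structure(list(fit = fit, center = std$center, scale = std$scale,
                 clip = clip,
                 levels = sort(unique(blocks$action))),
            class = "propensity_model")
}

#' Full behavior action distribution per state
#'
#' @param model A [fit_propensities()] model.
#' @param blocks Blocks with the state feature columns.
#' @return Matrix (n x 5) of action probabilities; rows sum to 1.
#' @export
propensity_matrix <- function(model, blocks) {
  X <- as.matrix(blocks[, state_features(), drop = FALSE])
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  P <- stats::predict(model$fit, newdata = as.data.frame(Xs), type = "probs")
  if (is.null(dim(P))) P <- matrix(P, nrow = 1)
  colnames(P) <- as.character(0:4)
  P
}

#' Logged-action propensities
#'
#' @param model A [fit_propensities()] model.
#' @param blocks Evaluation blocks with state features.
#' @param actions Logged actions (default `blocks$action`).
#' @return Numeric vector of clipped propensities `pi_i` of the logged
#'   actions; attribute `clipped_fraction` reports how many hit the floor.
#' @export
logged_propensities <- function(model, blocks, actions = blocks$action) {
  if (!all(actions %in% model$levels)) {
    stop("logged action absent from the propensity training data",
         call. = FALSE)
  }
  P <- propensity_matrix(model, blocks)
  p <- P[cbind(seq_len(nrow(P)), actions + 1L)]
  clipped <- mean(p < model$clip)
  p <- pmax(p, model$clip)
  attr(p, "clipped_fraction") <- clipped
  p
}

#' Consistency indicator between AI and clinical actions
#'
#' `A_i = 1` where the policy's action equals the logged clinical action,
#' else 0.
#'
#' @param policy_actions,logged_actions Equal-length integer vectors.
#' @return Integer vector of 0/1.
#' @export
consistency_indicator <- function(policy_actions, logged_actions) {
  if (length(policy_actions) != length(logged_actions)) {
    stop("policy and logged action vectors differ in length", call. = FALSE)
  }
  as.integer(policy_actions == logged_actions)
}

check_ips_args <- function(A, r, p) {
  if (!all(A %in% c(0L, 1L))) stop("A must be 0/1", call. = FALSE)
  if (any(A == 1 & (is.na(p) | p <= 0))) {
    stop("zero or missing propensity on a consistent sample", call. = FALSE)
  }
}

#' Inverse propensity scoring estimate of policy value
#'
#' `V_IPS = (1/N) * sum_i A_i * r_i / pi_i(x_i)`.
#'
#' @param A Consistency indicators (0/1).
#' @param r Per-sample attributed rewards.
#' @param p Propensities of the logged actions (positive wherever `A = 1`).
#' @return The IPS value estimate.
#' @export
ips_estimate <- function(A, r, p) {
  check_ips_args(A, r, p)
  mean(ifelse(A == 1, r / p, 0))
}

#' Fit the direct outcome (reward regression) model
#'
#' Ridge regression of the attributed reward on the state features, fitted
#' only where the AI and clinical policies agree (`A = 1`), i.e. an estimate
#' of `m(x) = E(r | A = 1, x)`. Predictions are defined (finite) for any
#' finite state, including states outside the consistent subset.
#'
#' @param states State matrix (n x p).
#' @param r Attributed rewards.
#' @param A Consistency indicators.
#' @param min_consistent Minimum number of `A = 1` samples (default 30).
#' @param lambda Ridge penalty (default 0.01).
#' @return Object of class `outcome_model`; use [predict_outcome()] for
#'   `m(x)`.
#' @export
fit_outcome_model <- function(states, r, A, min_consistent = 30L,
                              lambda = 0.01) {
  keep <- which(A == 1)
  if (length(keep) < min_consistent) {
    stop("too few consistent samples to fit the outcome model (",
         length(keep), " < ", min_consistent, ")", call. = FALSE)
  }
  X <- states[keep, , drop = FALSE]
  y <- r[keep]
  if (stats::sd(y) == 0) {
    return(structure(list(constant = y[1]), class = "outcome_model"))
  }
  fit <- glmnet::glmnet(X, y, alpha = 0, lambda = lambda)
  structure(list(fit = fit, constant = NULL), class = "outcome_model")
}

#' Predict rewards from the outcome model
#'
#' @param model An [fit_outcome_model()] object.
#' @param states State matrix.
#' @return Numeric vector `m(x)`.
#' @export
predict_outcome <- function(model, states) {
  if (!is.null(model$constant)) return(rep(model$constant, nrow(states)))
  as.numeric(stats::predict(model$fit, newx = states))
}

#' Direct (model-based) estimate of policy value
#'
#' `V_model = (1/N) * sum_i [A_i * r_i + (1 - A_i) * m(x_i)]`: the logged
#' reward where the policies agree, the regression-imputed reward elsewhere.
#'
#' @param A Consistency indicators.
#' @param r Attributed rewards.
#' @param m Predicted rewards `m(x_i)`.
#' @return The direct-method value estimate.
#' @export
model_estimate <- function(A, r, m) {
  if (!all(A %in% c(0L, 1L))) stop("A must be 0/1", call. = FALSE)
  mean(ifelse(A == 1, r, 0) + (1 - A) * m)
}

#' Doubly-robust estimate of policy value
#'
#' `V_DR = (1/N) * sum_i [A_i * (r_i - m(x_i)) / pi_i + m(x_i)]`, unbiased
#' when either the propensities or the outcome model are correct. The
#' algebraically equivalent form
#' `(1/N) * sum_i [A_i * r_i / pi_i - (A_i - pi_i) / pi_i * m(x_i)]` is
#' evaluated as a cross-check and must agree to 1e-10.
#'
#' @inheritParams ips_estimate
#' @param m Predicted rewards `m(x_i)`.
#' @return The DR value estimate, with attribute `alt_form` carrying the
#'   second-form value.
#' @export
dr_estimate <- function(A, r, p, m) {
  check_ips_args(A, r, p)
  v4 <- mean(ifelse(A == 1, (r - m) / p, 0) + m)
  # second printed form; (A - p)/p equals -1 exactly when A = 0, so the
  # propensity of inconsistent samples never enters
  v5 <- mean(ifelse(A == 1, r / p - (1 - p) / p * m, m))
  if (abs(v4 - v5) > 1e-10 * max(1, abs(v4))) {
    stop("doubly-robust estimator forms disagree beyond tolerance",
         call. = FALSE)
  }
  attr(v4, "alt_form") <- v5
  v4
}

#' Full off-policy evaluation of one policy
#'
#' Computes the consistency indicator against the logged actions, fits the
#' outcome model on the consistent subset, and reports the IPS, direct and
#' doubly-robust value estimates together with the logged-data baseline
#' (mean attributed reward).
#'
#' @param policy_actions Policy actions per evaluation block.
#' @param logged_actions Logged clinical actions.
#' @param r Attributed rewards (see [attribute_rewards()]).
#' @param states State matrix.
#' @param p Logged-action propensities (see [logged_propensities()]).
#' @param min_consistent,lambda Passed to [fit_outcome_model()].
#' @return List of class `ope_result`: `V_ips`, `V_model`, `V_dr`,
#'   `baseline`, `n`, `n_consistent`, plus the per-sample `A`, `m`.
#' @export
evaluate_policy <- function(policy_actions, logged_actions, r, states, p,
                            min_consistent = 30L, lambda = 0.01) {
  A <- consistency_indicator(policy_actions, logged_actions)
  om <- fit_outcome_model(states, r, A, min_consistent, lambda)
  m <- predict_outcome(om, states)
  structure(list(
    V_ips = ips_estimate(A, r, p),
    V_model = model_estimate(A, r, m),
    V_dr = as.numeric(dr_estimate(A, r, p, m)),
    baseline = mean(r),
    n = length(r),
    n_consistent = sum(A),
    A = A, m = m
  ), class = "ope_result")
}

#' Evaluate DDQN checkpoints against the logged test data
#'
#' For every checkpoint snapshot of a trained model, computes the greedy
#' policy on the evaluation blocks and its IPS, direct and doubly-robust
#' value estimates, alongside the logged-data mean attributed reward
#' baseline (the "original data" row of a checkpoint report).
#'
#' @param model A `trained_model` with checkpoint snapshots.
#' @param blocks Imputed, discretized, rewarded evaluation blocks.
#' @param prop_model A [fit_propensities()] model fitted on training blocks.
#' @param gamma_attr Reward-attribution discount (default 0.99).
#' @param min_consistent,lambda Passed to [fit_outcome_model()].
#' @return data.frame with one row per checkpoint: `checkpoint`, `V_ips`,
#'   `V_model`, `V_dr`, `baseline`, `n`, `n_consistent`, `clipped_fraction`.
#' @export
evaluate_checkpoints <- function(model, blocks, prop_model,
                                 gamma_attr = 0.99, min_consistent = 30L,
                                 lambda = 0.01) {
  if (length(model$checkpoints) == 0) {
    stop("model carries no checkpoint snapshots", call. = FALSE)
  }
  blocks <- blocks[order(blocks$patient_id, blocks$bloc), , drop = FALSE]
  states <- as.matrix(blocks[, state_features(), drop = FALSE])
  r <- attribute_rewards(blocks, gamma_attr)
  p <- logged_propensities(prop_model, blocks)
  rows <- lapply(names(model$checkpoints), function(ck) {
    q <- model$checkpoints[[ck]]
    acts <- predict_actions(q, states)
    res <- evaluate_policy(acts, blocks$action, r, states, p,
                           min_consistent, lambda)
    data.frame(checkpoint = as.integer(ck), V_ips = res$V_ips,
               V_model = res$V_model, V_dr = res$V_dr,
               baseline = res$baseline, n = res$n,
               n_consistent = res$n_consistent,
               clipped_fraction = attr(p, "clipped_fraction"))
  })
  out <- do.call(rbind, rows)
  out[order(out$checkpoint), , drop = FALSE]
}
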