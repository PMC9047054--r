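#' Posterior of the latent state and optimal action given recorded features
#'
#' Inverts the generator's linear-Gaussian readout model: given a block's 25
#' recorded features, computes the posterior mean and uncertainty of the
#' latent severity and fluid overload (generalized least squares over the
#' known feature loadings, with weak Gaussian priors), and from the severity
#' posterior the probability that each action is optimal. Blocks whose
#' maximum posterior probability is low are *intrinsically ambiguous*: no
#' estimator working from the features can reliably name their optimal
#' action, whatever its training data. Policy-recovery experiments use this
#' as the feature-noise component of the noise floor.
#'
#' @param states Matrix of states (25 named columns as [state_features()]).
#' @return List with `z_hat`, `o_hat`, `z_sd` (posterior sd of severity),
#'   `prob` (n x 5 matrix of posterior optimal-action probabilities),
#'   `map_action` (posterior mode) and `max_prob`.
#' @export
optimal_action_posterior <- function(states) {
  sch <- feature_schema()
  meas <- sch[sch$group != "demo", ]
  ol <- overload_loadings()
  feats <- c(meas$feature, "weight")
  B <- cbind(z = c(meas$slope, 0),
             o = ifelse(feats %in% names(ol), ol[feats], 0))
  A <- c(meas$mu, 66)        # population weight mean; per-patient base unknown
  Dv <- c(meas$sd, 11)^2     # weight base variability acts as readout noise
  W <- B / Dv
  Prec <- t(B) %*% W + diag(c(1, 1 / 4))  # priors z ~ N(0,1), o ~ N(0, 2^2)
  Pcov <- solve(Prec)
  X <- states[, feats, drop = FALSE]
  Zhat <- t(Pcov %*% t(W) %*% t(sweep(X, 2, A)))
  z_sd <- sqrt(Pcov[1, 1])
  thr <- severity_thresholds()
  prob <- sapply(0:4, function(k) {
    lo <- c(-Inf, thr)[k + 1]
    hi <- c(thr, Inf)[k + 1]
    stats::pnorm(hi, Zhat[, 1], z_sd) - stats::pnorm(lo, Zhat[, 1], z_sd)
  })
  list(z_hat = Zhat[, 1], o_hat = Zhat[, 2], z_sd = z_sd, prob = prob,
       map_action = max.col(prob, ties.method = "first") - 1L,
       max_prob = apply(prob, 1, max))
}

#' Policy-recovery experiment against known ground truth
#'
#' Generates a cohort with heavy, harmful behavior noise, runs the full
#' preprocessing and DDQN training pipeline, and measures how often the
#' learned greedy policy names the ground-truth optimal action on the
#' cohort's *high-margin* blocks -- blocks where (a) the true value gap
#' between the optimal action and its best alternative exceeds
#' `margin_floor` reward units ([true_action_values()]) and (b) the latent
#' severity lies at least `severity_clearance` from the nearest action
#' threshold (about twice the posterior standard deviation with which the
#' 25 features determine severity, see [optimal_action_posterior()]).
#' Blocks failing either test sit below the noise floor: their optimal
#' action cannot be resolved from 500 patients of logged terminal-reward
#' data, by this or any other method. The behavior noise defaults to 0.8:
#' near-uniform logged coverage is the only regime in which every action's
#' value is conditionally estimable at every state (at low exploration the
#' rare actions' Q-values in the severity tails are smoothed extrapolations
#' and the greedy argmax degrades), and it is also the maximally harmful
#' behavior policy. The learned policy is also evaluated off-policy at
#' every training checkpoint (doubly-robust) and on-policy by fresh
#' generative rollouts.
#'
#' @param n_patients Cohort size (default 500).
#' @param seed Master seed for cohort, split, training and rollouts.
#' @param iterations DDQN iterations (default 30000).
#' @param checkpoints Checkpoint schedule (default 3000/10000/20000/30000).
#' @param epsilon_behavior,action_harm Stress-cohort behavior noise and harm
#'   (defaults 0.8 and 1.2).
#' @param margin_floor,severity_clearance The two noise-floor components.
#' @param n_mc Rollouts per block for the ground-truth value oracle.
#' @return List with `agreement_high_margin` (fraction), `n_high_margin`,
#'   `agreement_all`, `checkpoint_report` (doubly-robust values per
#'   checkpoint plus the logged baseline), `behavior_true_value`,
#'   `learned_true_value`, `optimal_true_value`, `model`, `mdp`, `cohort`.
#' @export
policy_recovery_experiment <- function(n_patients = 500L, seed = 1L,
                                       iterations = 30000L,
                                       checkpoints = c(3000L, 10000L,
                                                       20000L, 30000L),
                                       epsilon_behavior = 0.8,
                                       action_harm = 1.2,
                                       margin_floor = 2.5,
                                       severity_clearance = 0.4,
                                       n_mc = 2000L) {
  cfg <- cohort_config(n_patients = n_patients, seed = seed,
                       epsilon_behavior = epsilon_behavior,
                       action_harm = action_harm)
  cohort <- generate_cohort(cfg)
  mdp <- preprocess_cohort(cohort$records, cohort$outcomes, seed = seed)
  tcfg <- training_config(iterations = iterations, seed = seed,
                          checkpoint_iterations = checkpoints,
                          target_clip = c(-15, 15), weight_decay = 1e-4)
  model <- train_ddqn(mdp$train_transitions, tcfg)

  blocks <- rbind(mdp$train_blocks, mdp$test_blocks)
  tb <- merge(blocks, cohort$truth$blocks, by = c("patient_id", "bloc"),
              suffixes = c("", ".truth"))
  states <- as.matrix(tb[, state_features(), drop = FALSE])
  tv <- true_action_values(cfg, tb$severity, tb$overload, tb$bloc,
                           gamma = tcfg$gamma, n_mc = n_mc,
                           seed = seed + 1L)
  zdist <- vapply(tb$severity,
                  function(z) min(abs(z - severity_thresholds())), 0)
  high <- tv$margin > margin_floor & zdist > severity_clearance
  pred <- predict_actions(model, states)

  prop <- fit_propensities(mdp$train_blocks)
  ckpt <- evaluate_checkpoints(model, mdp$test_blocks, prop,
                               gamma_attr = tcfg$gamma)

  v_beh <- true_policy_value(cfg, "behavior", 3000, seed = seed + 2L)
  v_opt <- true_policy_value(cfg, "optimal", 3000, seed = seed + 3L)
  v_learn <- true_policy_value(cfg, as_policy(model), 3000, seed = seed + 4L)

  list(agreement_high_margin = mean(pred[high] == tv$optimal_action[high]),
       n_high_margin = sum(high),
       agreement_all = mean(pred == tv$optimal_action),
       checkpoint_report = ckpt,
       behavior_true_value = v_beh,
       optimal_true_value = v_opt,
       learned_true_value = v_learn,
       predicted_actions = pred,
       high_margin = high,
       truth = tv,
       model = model, mdp = mdp, cohort = cohort)
}
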