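#' Configuration for the synthetic ICU cohort generator
#'
#' The generator emulates a sepsis fluid-therapy cohort as a Markov decision
#' process with two scalar latents per patient: *severity* (an AR(1) process
#' driving most physiologic readouts and the death hazard) and *fluid
#' overload* (a leaky accumulator of fluid mismanagement, read out by CVP,
#' weight gain, respiratory rate, oxygenation and base excess). The 25 state
#' features are noisy affine readouts of the latents, clipped to physiologic
#' ranges. The severity-optimal fluid-balance action infuses for acutely ill
#' (high-severity) patients and drains for recovering ones, by severity
#' quintile; every unit of deviation from it adds
#' one unit to the overload accumulator, which decays by a factor 0.7 per
#' 6-hour block. The clinicians' (behavior) policy takes the optimal action
#' with probability `1 - epsilon_behavior` and otherwise acts uniformly.
#'
#' Stays end by competing per-block risks evaluated after each action: death
#' with hazard `plogis(mortality_intercept + severity + action_harm *
#' overload)`, alive discharge with hazard `plogis(-2.3 - 0.7 * severity)`
#' (sicker patients stay longer), and administrative end-of-observation at
#' `max_blocks` (counted as ICU survival). The reward is terminal-only:
#' +15 at the last block if the patient survived, -15 if they died. Both
#' latents are visible (noisily) through the state, so the decision process
#' is Markov in the recorded features and the optimal policy is recoverable
#' from logged data.
#'
#' @param n_patients Number of patients (>= 1).
#' @param seed Integer seed; identical configurations generate identical
#'   cohorts.
#' @param max_blocks Maximum number of 6-hour blocks per patient (default 18,
#'   i.e. 108 hours).
#' @param epsilon_behavior Probability in `[0, 1)` that the behavior policy
#'   deviates from the severity-optimal action (uniform over all five actions
#'   when it deviates).
#' @param severity_persistence AR(1) coefficient of the latent severity, in
#'   `[0, 1)`.
#' @param action_harm Non-negative death log-odds per unit of fluid overload
#'   in the per-block death hazard.
#' @param missingness_rates Named vector of per-feature missingness rates in
#'   `[0, 1)`; defaults to the schema rates. Laboratory features are made
#'   block-sparse (measured every 2-4 blocks at a cadence implied by their
#'   rate) so forward-fill imputation is exercised; other features are blanked
#'   completely at random.
#' @param outlier_injection_rate Fraction of emitted records replaced by
#'   out-of-physiologic-range values, to exercise the outlier rules.
#' @param mortality_intercept Baseline per-block death-hazard log-odds at
#'   severity 0 with no overload. `-Inf` forces universal survival, `+Inf`
#'   universal death.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients,
                          seed = 1L,
                          max_blocks = 18L,
                          epsilon_behavior = 0.2,
                          severity_persistence = 0.7,
                          action_harm = 1.2,
                          missingness_rates = NULL,
                          outlier_injection_rate = 0.002,
                          mortality_intercept = -4.6) {
  if (!is.numeric(n_patients) || length(n_patients) != 1 || is.na(n_patients) ||
      n_patients < 1) {
    stop("invalid config: n_patients must be a positive count", call. = FALSE)
  }
  if (max_blocks < 1) stop("invalid config: max_blocks must be >= 1", call. = FALSE)
  rate_ok <- function(x) is.numeric(x) && all(!is.na(x)) && all(x >= 0) && all(x < 1)
  if (!rate_ok(epsilon_behavior)) {
    stop("invalid config: epsilon_behavior must lie in [0, 1)", call. = FALSE)
  }
  if (!rate_ok(severity_persistence)) {
    stop("invalid config: severity_persistence must lie in [0, 1)", call. = FALSE)
  }
  if (!is.numeric(action_harm) || action_harm < 0) {
    stop("invalid config: action_harm must be >= 0", call. = FALSE)
  }
  if (!rate_ok(outlier_injection_rate)) {
    stop("invalid config: outlier_injection_rate must lie in [0, 1)", call. = FALSE)
  }
  sch <- feature_schema()
  rates <- stats::setNames(sch$missing_rate, sch$feature)
  if (!is.null(missingness_rates)) {
    if (is.null(names(missingness_rates)) ||
        !all(names(missingness_rates) %in% sch$feature)) {
      stop("invalid config: missingness_rates must be named by schema features",
           call. = FALSE)
    }
    if (!rate_ok(missingness_rates)) {
      stop("invalid config: missingness rates must lie in [0, 1)", call. = FALSE)
    }
    rates[names(missingness_rates)] <- missingness_rates
  }
  structure(list(
    n_patients = as.integer(n_patients),
    seed = as.integer(seed),
    max_blocks = as.integer(max_blocks),
    epsilon_behavior = epsilon_behavior,
    severity_persistence = severity_persistence,
    action_harm = action_harm,
    missingness_rates = rates,
    outlier_injection_rate = outlier_injection_rate,
    mortality_intercept = mortality_intercept
  ), class = "cohort_config")
}

# Severity cut points defining the optimal action. Standard-normal quintiles,
# so that under the stationary severity distribution each optimal action
# carries ~20% of blocks and the fitted quintile action bins line up with the
# generative balance clusters.
severity_thresholds <- function() stats::qnorm(c(0.2, 0.4, 0.6, 0.8))

# Generative fluid-balance cluster centers (mL) per action 0..4 and their
# within-cluster spread. Negative values = net fluid removal.
balance_centers <- function() c(-160, -75, -22, 22, 95)
balance_spread <- function() 18

# Per-block decay of the fluid-overload accumulator.
overload_decay <- function() 0.7

# Overload readouts: how one unit of overload shifts each feature
# (fluid retention raises CVP, weight and work of breathing; pulmonary
# edema degrades gas exchange; dilution lowers base excess).
overload_loadings <- function() {
  c(cvp = 2.0, weight = 1.2, resp_rate = 1.2, po2 = -6, spo2 = -0.6,
    base_excess = -1.0)
}

# Per-block competing hazards evaluated after each action: death depends on
# the updated severity and overload; alive discharge is likelier for less
# severe patients (sicker patients stay longer).
death_hazard <- function(z, o, config) {
  stats::plogis(config$mortality_intercept + z + config$action_harm * o)
}

discharge_hazard <- function(z) stats::plogis(-2.3 - 0.7 * z)

# Optimal action for a severity value: acutely ill patients (higher severity)
# need fluid resuscitation (positive balance, higher action index);
# recovering patients benefit from de-resuscitation (negative balance).
optimal_action_for <- function(z) findInterval(z, severity_thresholds())

# Build the full 25-column state matrix for one block index. `z` is the
# severity, `o` the fluid overload of the active patients.
make_state_matrix <- function(z, o, bloc, gender, age, weight, meas) {
  n <- length(z)
  X <- matrix(NA_real_, n, length(state_features()),
              dimnames = list(NULL, state_features()))
  ol <- overload_loadings()
  X[, "bloc"] <- bloc
  X[, "gender"] <- gender
  X[, "age"] <- age
  X[, "weight"] <- weight + ol[["weight"]] * o
  for (j in seq_len(nrow(meas))) {
    f <- meas$feature[j]
    v <- meas$mu[j] + meas$slope[j] * z + stats::rnorm(n, 0, meas$sd[j])
    if (f %in% names(ol)) v <- v + ol[[f]] * o
    X[, f] <- pmin(meas$hi[j], pmax(meas$lo[j], v))
  }
  X
}

# Core trajectory simulator shared by generate_cohort() and
# true_policy_value(). `policy` is "behavior", "optimal", "uniform", or a
# function(states_matrix) -> integer actions 0..4. Assumes the RNG has been
# seeded by the caller. After each block's action the updated latents are
# exposed to the competing death/discharge hazards; the block at which a
# patient is absorbed is their terminal block.
simulate_trajectories <- function(config, n, policy = "behavior",
                                  with_features = FALSE) {
  max_b <- config$max_blocks
  want_feats <- with_features || is.function(policy)
  sch <- feature_schema()
  meas <- sch[sch$group != "demo", ]
  eps <- config$epsilon_behavior
  rho <- config$severity_persistence
  dec <- overload_decay()
  ctr <- balance_centers()

  gender <- stats::rbinom(n, 1, 0.6)
  age <- round(pmin(95, pmax(18, stats::rnorm(n, 60, 13))))
  weight <- round(pmin(150, pmax(35, stats::rnorm(n, 66, 11))), 1)
  z <- stats::rnorm(n)
  o <- numeric(n)              # overload entering the current block
  alive_in <- rep(TRUE, n)     # still in the ICU before this block
  died <- integer(n)
  n_blocks <- integer(n)
  z_term <- numeric(n)
  o_term <- numeric(n)

  rows <- vector("list", max_b)
  feats <- if (want_feats) vector("list", max_b) else NULL
  for (t in seq_len(max_b)) {
    act <- which(alive_in)
    if (!length(act)) break
    m <- length(act)
    zt <- z[act]
    ot <- o[act]
    a_star <- optimal_action_for(zt)
    P <- matrix(eps / 5, m, 5)
    P[cbind(seq_len(m), a_star + 1L)] <- P[cbind(seq_len(m), a_star + 1L)] + (1 - eps)
    X <- NULL
    if (want_feats) {
      X <- make_state_matrix(zt, ot, t, gender[act], age[act], weight[act], meas)
      feats[[t]] <- X
    }
    a <- if (is.function(policy)) {
      as.integer(policy(X))
    } else if (policy == "behavior") {
      u <- stats::runif(m)
      as.integer(rowSums(t(apply(P, 1, cumsum)) < u))
    } else if (policy == "optimal") {
      a_star
    } else if (policy == "uniform") {
      sample(0:4, m, replace = TRUE)
    } else {
      stop("unknown policy: ", policy, call. = FALSE)
    }
    if (any(is.na(a) | a < 0 | a > 4)) {
      stop("policy returned actions outside 0..4", call. = FALSE)
    }
    dev <- abs(a - a_star)
    balance <- ctr[a + 1L] + stats::rnorm(m, 0, balance_spread())
    rows[[t]] <- data.frame(
      patient_id = act, bloc = t, severity = zt, overload = ot,
      optimal_action = a_star, action = a, deviation = dev, balance = balance,
      p0 = P[, 1], p1 = P[, 2], p2 = P[, 3], p3 = P[, 4], p4 = P[, 5]
    )
    # latent update, then competing risks
    o_next <- dec * ot + dev
    z_next <- rho * zt + sqrt(1 - rho^2) * stats::rnorm(m)
    h_die <- death_hazard(z_next, o_next, config)
    dies <- stats::runif(m) < h_die
    leaves <- !dies & (stats::runif(m) < discharge_hazard(z_next))
    if (t == max_b) leaves <- !dies   # end of observation counts as survival
    ends <- dies | leaves
    idx_end <- act[ends]
    died[idx_end] <- as.integer(dies[ends])
    n_blocks[idx_end] <- t
    z_term[idx_end] <- zt[ends]
    o_term[idx_end] <- o_next[ends]
    alive_in[idx_end] <- FALSE
    cont <- act[!ends]
    z[cont] <- z_next[!ends]
    o[cont] <- o_next[!ends]
  }
  blocks <- do.call(rbind, rows)
  ord <- order(blocks$patient_id, blocks$bloc)
  blocks <- blocks[ord, , drop = FALSE]
  rownames(blocks) <- NULL
  patients <- data.frame(
    patient_id = seq_len(n), n_blocks = n_blocks, gender = gender, age = age,
    weight = weight, terminal_severity = z_term, terminal_overload = o_term,
    died = died
  )
  F <- NULL
  if (want_feats) {
    F <- do.call(rbind, feats)[ord, , drop = FALSE]
  }
  list(blocks = blocks, patients = patients, features = F)
}

#' Generate a synthetic ICU sepsis cohort
#'
#' Simulates trajectories under the behavior policy, renders them as a
#' long-format raw records table (one row per observed measurement) with the
#' configured missingness and injected out-of-range values, and returns the
#' generative ground truth separately so no downstream stage can leak it.
#'
#' @param config A [cohort_config()].
#' @return A list of class `fluid_cohort`:
#' \describe{
#'   \item{records}{data.frame with columns `patient_id`, `block_time_hours`,
#'     `feature`, `value`. Fluid input/output volumes appear as features
#'     `fluid_input` / `fluid_output`; the per-block balance is
#'     `fluid_input - fluid_output` (negative = net removal).}
#'   \item{outcomes}{data.frame `patient_id`, `outcome` (1 = died in ICU,
#'     0 = survived).}
#'   \item{truth}{list with block-level ground truth (`blocks`: latent
#'     severity and overload, optimal action, realized action, behavior
#'     propensities `p0..p4`, generative balance) and patient-level ground
#'     truth (`patients`).}
#' }
#' @examples
#' cohort <- generate_cohort(cohort_config(n_patients = 20, seed = 1))
#' head(cohort$records)
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    stop("config must be a cohort_config", call. = FALSE)
  }
  set.seed(config$seed)
  sim <- simulate_trajectories(config, config$n_patients,
                               policy = "behavior", with_features = TRUE)
  blocks <- sim$blocks
  F <- sim$features
  nb <- nrow(blocks)
  rates <- config$missingness_rates
  sch <- feature_schema()
  labs <- lab_features()
  meas_feats <- sch$feature[sch$group != "demo"]

  # observation masks
  jitter <- stats::runif(nb, 0, 6)
  time_h <- (blocks$bloc - 1) * 6 + jitter
  frames <- list()
  for (f in meas_feats) {
    if (f %in% labs) {
      # block-sparse cadence implied by the target missingness rate
      period <- min(4L, max(2L, as.integer(round(1 / (1 - rates[[f]])))))
      phase <- sample.int(period, config$n_patients, replace = TRUE)
      obs <- (blocks$bloc %% period) == (phase[blocks$patient_id] %% period)
    } else {
      obs <- stats::runif(nb) >= rates[[f]]
    }
    if (!any(obs)) next
    frames[[f]] <- data.frame(
      patient_id = blocks$patient_id[obs],
      block_time_hours = time_h[obs],
      feature = f,
      value = F[obs, f]
    )
  }
  for (f in c("gender", "age", "weight")) {
    frames[[f]] <- data.frame(
      patient_id = blocks$patient_id, block_time_hours = time_h,
      feature = f, value = F[, f]
    )
  }
  base_vol <- stats::runif(nb, 100, 1500)
  frames[["fluid_input"]] <- data.frame(
    patient_id = blocks$patient_id, block_time_hours = time_h,
    feature = "fluid_input", value = base_vol + pmax(blocks$balance, 0)
  )
  frames[["fluid_output"]] <- data.frame(
    patient_id = blocks$patient_id, block_time_hours = time_h,
    feature = "fluid_output", value = base_vol + pmax(-blocks$balance, 0)
  )
  records <- do.call(rbind, frames)
  records <- records[order(records$patient_id, records$block_time_hours,
                           records$feature), , drop = FALSE]
  rownames(records) <- NULL

  # inject out-of-range values to exercise the outlier rules
  inj <- outlier_injection_values()
  can <- records$feature %in% names(inj)
  hit <- which(can & stats::runif(nrow(records)) < config$outlier_injection_rate)
  for (i in hit) {
    v <- inj[[records$feature[i]]]
    records$value[i] <- v[sample.int(length(v), 1)]
  }

  outcomes <- data.frame(patient_id = sim$patients$patient_id,
                         outcome = sim$patients$died)
  structure(list(
    records = records,
    outcomes = outcomes,
    truth = list(blocks = blocks, patients = sim$patients)
  ), class = "fluid_cohort")
}

#' Monte-Carlo value of a policy under the generative model
#'
#' Simulates fresh trajectories from the generative process, following the
#' given policy at every block, and returns the mean terminal reward
#' (+15 survival / -15 death) with its standard error. This is the oracle
#' against which off-policy estimates can be compared on synthetic cohorts.
#'
#' @param config A [cohort_config()] describing the generative process (its
#'   `n_patients` and `seed` fields are ignored here).
#' @param policy `"behavior"`, `"optimal"`, `"uniform"`, or a function that
#'   maps a matrix of states (rows = patients, 25 named columns as in
#'   [state_features()]) to integer actions 0..4.
#' @param n_rollouts Number of fresh patient trajectories (>= 1).
#' @param seed Integer seed for the rollouts.
#' @return List with `value`, `se`, `n_rollouts`, `mortality`.
#' @export
true_policy_value <- function(config, policy, n_rollouts, seed = 1L) {
  if (!inherits(config, "cohort_config")) {
    stop("config must be a cohort_config", call. = FALSE)
  }
  if (!is.numeric(n_rollouts) || n_rollouts < 1) {
    stop("n_rollouts must be >= 1", call. = FALSE)
  }
  set.seed(seed)
  sim <- simulate_trajectories(config, as.integer(n_rollouts), policy = policy,
                               with_features = FALSE)
  r <- ifelse(sim$patients$died == 1, -15, 15)
  list(value = mean(r),
       se = stats::sd(r) / sqrt(length(r)),
       n_rollouts = length(r),
       mortality = mean(sim$patients$died))
}

#' Ground-truth action values and optimal-action margins
#'
#' For blocks with known latent severity, overload and block index, computes
#' by Monte-Carlo rollout of the generative dynamics the true expected
#' discounted terminal reward of taking each action now and acting optimally
#' thereafter (expectation over the severity diffusion and the competing
#' death/discharge risks). The margin -- the gap between the optimal
#' action's value and the best alternative -- quantifies how strongly the
#' data can ever identify the optimal action at a block; policy-recovery
#' experiments condition on it.
#'
#' @param config The [cohort_config()] that generated the cohort.
#' @param severity,overload,bloc Aligned vectors of ground-truth block
#'   values (from `truth$blocks`).
#' @param gamma Discount used to express the values (default 0.9, matching
#'   the learners).
#' @param n_mc Monte-Carlo rollouts per block and action (default 2000).
#' @param seed RNG seed.
#' @return List with `q` (n x 5 matrix of true action values),
#'   `optimal_action` (argmax, 0..4) and `margin` (value gap to the best
#'   alternative).
#' @export
true_action_values <- function(config, severity, overload, bloc,
                               gamma = 0.9, n_mc = 2000L, seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  n <- length(severity)
  stopifnot(length(overload) == n, length(bloc) == n)
  set.seed(seed)
  rho <- config$severity_persistence
  dec <- overload_decay()
  max_b <- config$max_blocks
  Q <- matrix(NA_real_, n, 5)
  # process blocks in chunks; each (block, action) pair is rolled out n_mc
  # times with vectorized per-step updates
  chunk <- max(1L, 200000L %/% n_mc)
  for (start in seq(1, n, by = chunk)) {
    ii <- start:min(start + chunk - 1L, n)
    k <- length(ii)
    N <- k * 5L * n_mc
    zi <- rep(severity[ii], each = 5L * n_mc)
    oi <- rep(overload[ii], each = 5L * n_mc)
    bi <- rep(bloc[ii], each = 5L * n_mc)
    ai <- rep(rep(0:4, each = n_mc), times = k)
    first <- rep(TRUE, N)
    active <- rep(TRUE, N)
    val <- numeric(N)
    disc <- rep(1, N)
    z <- zi; o <- oi; b <- bi
    while (any(active)) {
      w <- which(active)
      a_star <- optimal_action_for(z[w])
      dev <- ifelse(first[w], abs(ai[w] - a_star), 0)
      o_next <- dec * o[w] + dev
      z_next <- rho * z[w] + sqrt(1 - rho^2) * stats::rnorm(length(w))
      h_die <- death_hazard(z_next, o_next, config)
      dies <- stats::runif(length(w)) < h_die
      leaves <- !dies & (stats::runif(length(w)) < discharge_hazard(z_next))
      at_cap <- b[w] >= max_b
      leaves <- leaves | (at_cap & !dies)
      ends <- dies | leaves
      val[w[ends]] <- disc[w[ends]] * ifelse(dies[ends], -15, 15)
      active[w[ends]] <- FALSE
      cont <- w[!ends]
      z[cont] <- z_next[!ends]
      o[cont] <- o_next[!ends]
      b[cont] <- b[cont] + 1L
      disc[cont] <- disc[cont] * gamma
      first[cont] <- FALSE
    }
    vals <- matrix(val, nrow = n_mc)   # columns: action within block
    mq <- colMeans(vals)
    Q[ii, ] <- matrix(mq, ncol = 5, byrow = TRUE)
  }
  opt <- max.col(Q, ties.method = "first") - 1L
  marg <- apply(Q, 1, function(q) {
    s <- sort(q, decreasing = TRUE)
    s[1] - s[2]
  })
  list(q = Q, optimal_action = opt, margin = marg)
}

#' Wrap a trained Q-model as a rollout policy
#'
#' @param model A trained model from [train_sarsa()] or [train_ddqn()].
#' @return A function mapping a state matrix to greedy actions, suitable for
#'   [true_policy_value()].
#' @export
as_policy <- function(model) {
  function(states) predict_actions(model, states)
}
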