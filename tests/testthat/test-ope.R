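test_that("reward attribution discounts the terminal reward backwards", {
  blocks <- data.frame(patient_id = c(1, 1, 1, 2), bloc = c(1, 2, 3, 1),
                       reward = c(0, 0, 15, -15),
                       terminal = c(FALSE, FALSE, TRUE, TRUE))
  r <- attribute_rewards(blocks, gamma = 0.9)
  expect_equal(r, c(15 * 0.81, 15 * 0.9, 15, -15))
  expect_equal(attribute_rewards(blocks, gamma = 1), c(15, 15, 15, -15))
  expect_error(attribute_rewards(blocks, gamma = 0), "gamma")
})

test_that("consistency indicator is the elementwise equality of policies", {
  expect_equal(consistency_indicator(c(2, 3, 4), c(2, 0, 4)), c(1L, 0L, 1L))
  expect_equal(consistency_indicator(0:4, 0:4), rep(1L, 5))
  expect_equal(consistency_indicator(0:2, 3:5), rep(0L, 3))
  expect_error(consistency_indicator(1:2, 1:3), "length")
})

test_that("the printed estimator formulas evaluate as stated", {
  # inverse propensity scoring
  expect_equal(ips_estimate(c(1, 1), c(15, -15), c(0.5, 0.5)), 0)
  expect_equal(ips_estimate(rep(0L, 4), rep(NA_real_, 4), rep(0.2, 4)), 0)
  expect_equal(ips_estimate(rep(1L, 3), c(3, 6, 9), rep(1, 3)), 6)
  expect_error(ips_estimate(1L, 15, 0), "propensity")
  # direct model estimate
  expect_equal(model_estimate(c(1, 0), c(15, NA), c(10, 5)), 10)
  expect_equal(model_estimate(rep(1, 3), c(1, 2, 3), rep(99, 3)), 2)
  expect_equal(model_estimate(rep(0, 3), rep(NA_real_, 3), c(1, 2, 3)), 2)
  # doubly robust estimate
  expect_equal(as.numeric(dr_estimate(c(1, 0), c(15, NA), c(0.5, NA),
                                      c(10, 5))), 12.5)
  # when the outcome model is exact on consistent samples, DR collapses to
  # the model mean
  A <- c(1, 1, 0, 0)
  r <- c(4, 8, NA, NA)
  m <- c(4, 8, 2, 6)
  expect_equal(as.numeric(dr_estimate(A, r, c(0.3, 0.7, NA, NA), m)), mean(m))
})

test_that("the two printed doubly-robust forms are algebraically identical", {
  set.seed(12)
  for (rep in 1:1000) {
    n <- sample(3:40, 1)
    A <- rbinom(n, 1, 0.5)
    r <- rnorm(n, 0, 15)
    p <- runif(n, 0.05, 1)
    m <- rnorm(n, 0, 10)
    v <- dr_estimate(A, r, p, m)
    eq5 <- mean(ifelse(A == 1, r / p, 0) - (A - p) / p * m)
    expect_lt(abs(as.numeric(v) - eq5), 1e-10)
    expect_lt(abs(as.numeric(v) - attr(v, "alt_form")), 1e-10)
  }
})

test_that("aggregates are invariant to sample order", {
  set.seed(3)
  n <- 200
  A <- rbinom(n, 1, 0.4)
  r <- rnorm(n, 0, 10)
  p <- runif(n, 0.1, 1)
  m <- rnorm(n)
  perm <- sample(n)
  expect_equal(ips_estimate(A, r, p), ips_estimate(A[perm], r[perm], p[perm]))
  expect_equal(model_estimate(A, r, m),
               model_estimate(A[perm], r[perm], m[perm]))
  expect_equal(as.numeric(dr_estimate(A, r, p, m)),
               as.numeric(dr_estimate(A[perm], r[perm], p[perm], m[perm])))
})

test_that("propensity model recovers known behavior probabilities", {
  fix <- small_mdp()
  prop <- fit_propensities(fix$mdp$train_blocks)
  P <- propensity_matrix(prop, fix$mdp$test_blocks)
  expect_true(all(abs(rowSums(P) - 1) < 1e-9))
  p <- logged_propensities(prop, fix$mdp$test_blocks)
  expect_true(all(p >= prop$clip & p <= 1))
  # calibration: mean predicted propensity per action tracks its frequency
  Ptr <- propensity_matrix(prop, fix$mdp$train_blocks)
  freq <- tabulate(fix$mdp$train_blocks$action + 1L, 5) /
    nrow(fix$mdp$train_blocks)
  expect_lt(max(abs(colMeans(Ptr) - freq)), 0.02)
  # a logged action never seen in training is an error
  prop$levels <- c(0L, 1L)
  expect_error(logged_propensities(prop, fix$mdp$test_blocks),
               "absent")
})

test_that("propensities approach uniform under a uniform behavior policy", {
  co <- generate_cohort(cohort_config(n_patients = 400, seed = 21,
                                      epsilon_behavior = 0.999))
  mdp <- preprocess_cohort(co$records, co$outcomes, seed = 2)
  prop <- fit_propensities(mdp$train_blocks)
  p <- logged_propensities(prop, mdp$test_blocks)
  expect_lt(abs(mean(p) - 0.2), 0.03)
})

test_that("outcome model fits the consistent subset and extrapolates
           finitely", {
  set.seed(5)
  n <- 300
  X <- matrix(rnorm(n * 25), n, 25, dimnames = list(NULL, state_features()))
  beta <- c(3, -2, rep(0, 23))
  r <- as.numeric(X %*% beta) + rnorm(n, 0, 1)
  A <- rbinom(n, 1, 0.6)
  om <- fit_outcome_model(X, r, A, lambda = 1e-3)
  mhat <- predict_outcome(om, X)
  expect_true(all(is.finite(mhat)))
  # parameter recovery on the linear surface
  fit_lm <- lm(r[A == 1] ~ X[A == 1, 1] + X[A == 1, 2])
  se <- coef(summary(fit_lm))[2:3, 2]
  co_ridge <- as.numeric(coef(om$fit))[2:3]
  expect_lt(abs(co_ridge[1] - 3), 2.5 * se[1] + 0.1)
  expect_lt(abs(co_ridge[2] + 2), 2.5 * se[2] + 0.1)
  # constant rewards give a constant model
  om2 <- fit_outcome_model(X, rep(7, n), A)
  expect_equal(predict_outcome(om2, X[1:5, ]), rep(7, 5))
  # extrapolation far outside the consistent support stays finite
  far <- matrix(50, 2, 25, dimnames = list(NULL, state_features()))
  expect_true(all(is.finite(predict_outcome(om, far))))
  expect_error(fit_outcome_model(X, r, rep(0L, n)), "too few")
})

test_that("doubly-robust estimation is unbiased when either component is
           correct, unlike IPS under corrupted propensities", {
  # 5-action contextual bandit with known truth, 200 replicates
  set.seed(2024)
  n <- 400
  # E[f(x, pi_e(x))] = 5 + 4 * E|x| for f below with pi_e = argmax over a
  truth_value <- 5 + 4 * sqrt(2 / pi)
  res <- t(sapply(1:200, function(rep) {
    x <- rnorm(n)
    # behavior: 0.4 on the policy action, 0.15 elsewhere
    pi_true <- 0.4
    take_pol <- rbinom(n, 1, pi_true)
    a_pol <- ifelse(x > 0, 4L, 0L)                   # evaluated policy
    a_other <- (a_pol + sample(1:4, n, replace = TRUE)) %% 5L
    a <- ifelse(take_pol == 1, a_pol, a_other)
    f <- function(x, a) 5 + 2 * x * (a - 2)          # true reward surface
    r <- f(x, a) + rnorm(n, 0, 3)
    A <- as.integer(a == a_pol)
    m_true <- f(x, a_pol)
    p_true <- rep(pi_true, n)
    p_bad <- rep(0.8, n)                             # corrupted propensities
    m_bad <- rep(0, n)                               # misspecified model
    c(dr_pi_ok = as.numeric(dr_estimate(A, r, p_true, m_bad)),
      dr_m_ok = as.numeric(dr_estimate(A, r, p_bad, m_true)),
      ips_ok = ips_estimate(A, r, p_true),
      ips_bad = ips_estimate(A, r, p_bad))
  }))
  expect_lt(abs(mean(res[, "dr_pi_ok"]) - truth_value), 0.5)
  expect_lt(abs(mean(res[, "dr_m_ok"]) - truth_value), 0.5)
  # IPS is visibly biased under the corrupted propensities while DR is not
  expect_gt(abs(mean(res[, "ips_bad"]) - truth_value), 1.5)
  # variance ordering under correct propensities with an informative model
  res2 <- t(sapply(1:200, function(rep) {
    x <- rnorm(n)
    take_pol <- rbinom(n, 1, 0.4)
    a_pol <- ifelse(x > 0, 4L, 0L)
    a_other <- (a_pol + sample(1:4, n, replace = TRUE)) %% 5L
    a <- ifelse(take_pol == 1, a_pol, a_other)
    f <- function(x, a) 5 + 2 * x * (a - 2)
    r <- f(x, a) + rnorm(n, 0, 3)
    A <- as.integer(a == a_pol)
    c(dr = as.numeric(dr_estimate(A, r, rep(0.4, n), f(x, a_pol))),
      ips = ips_estimate(A, r, rep(0.4, n)))
  }))
  expect_lte(var(res2[, "dr"]), var(res2[, "ips"]))
})

test_that("self-evaluation of the behavior policy matches the logged mean", {
  fix <- small_mdp()
  mdp <- fix$mdp
  blocks <- mdp$test_blocks
  prop <- fit_propensities(mdp$train_blocks)
  r <- attribute_rewards(blocks, 0.99)
  p <- logged_propensities(prop, blocks)
  states <- as.matrix(blocks[, state_features()])
  # a literal copy of the logged actions is consistent everywhere, so the
  # direct estimate equals the logged mean exactly
  res_id <- evaluate_policy(blocks$action, blocks$action, r, states,
                            rep(1, nrow(blocks)), min_consistent = 10)
  expect_equal(res_id$n_consistent, nrow(blocks))
  expect_equal(res_id$V_model, res_id$baseline)
  expect_equal(res_id$V_ips, res_id$baseline)
  expect_equal(res_id$V_dr, res_id$baseline)
  # evaluating a fresh draw from the fitted behavior policy: its DR value
  # estimates the behavior value, i.e. the logged mean, within noise
  set.seed(10)
  P <- propensity_matrix(prop, blocks)
  draw <- apply(P, 1, function(pr) sample(0:4, 1, prob = pr))
  A <- consistency_indicator(draw, blocks$action)
  om <- fit_outcome_model(states, r, A, min_consistent = 10)
  m <- predict_outcome(om, states)
  vdr <- dr_estimate(A, r, p, m)
  psi <- ifelse(A == 1, (r - m) / p, 0) + m
  se <- sd(psi - r) / sqrt(length(r))
  expect_lt(abs(as.numeric(vdr) - mean(r)), 3 * se + 0.5)
})

test_that("checkpoint evaluation reports one row per snapshot with the
           baseline", {
  fix <- small_mdp()
  mdp <- fix$mdp
  cfg <- training_config(iterations = 400, seed = 2,
                         checkpoint_iterations = c(200, 400),
                         target_clip = c(-15, 15))
  m <- train_ddqn(mdp$train_transitions, cfg)
  prop <- fit_propensities(mdp$train_blocks)
  rep <- evaluate_checkpoints(m, mdp$test_blocks, prop, min_consistent = 10)
  expect_equal(rep$checkpoint, c(200L, 400L))
  expect_true(all(is.finite(rep$V_dr)))
  expect_equal(rep$baseline[1], rep$baseline[2])
  expect_true(all(rep$n == nrow(mdp$test_blocks)))
  m$checkpoints <- list()
  expect_error(evaluate_checkpoints(m, mdp$test_blocks, prop,
                                    min_consistent = 10), "checkpoint")
})
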