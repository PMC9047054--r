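test_that("SARSA target matches the printed update formula on a toy", {
  # Q == 0, terminal reward 15: target is 15 and one update at alpha = 0.1
  # moves the entry to 1.5
  tr <- tabular_transitions(states = 1L, actions = 0L, rewards = 15,
                            next_states = 1L, next_actions = NA,
                            terminal = TRUE, n_states = 1L, n_actions = 2L)
  Q <- matrix(0, 1, 2)
  expect_equal(td_target_sarsa(tr, Q, gamma = 0.9), 15)
  m <- train_sarsa(tr, training_config(iterations = 1, learning_rate = 0.1,
                                       gamma = 0.9))
  expect_equal(m$q[1, 1], 1.5)
  # gamma = 0: target is the bare reward whatever Q holds
  tr2 <- tabular_transitions(1L, 0L, 7, 1L, 1L, FALSE, 1L, 2L)
  Qbig <- matrix(100, 1, 2)
  expect_equal(td_target_sarsa(tr2, Qbig, gamma = 1e-12), 7, tolerance = 1e-9)
  # r = 0 and Q(s',a') = 0 leave Q unchanged (fixed point)
  tr3 <- tabular_transitions(1L, 0L, 0, 1L, 1L, FALSE, 1L, 2L)
  m3 <- train_sarsa(tr3, training_config(iterations = 10, learning_rate = 0.5,
                                         gamma = 0.9))
  expect_equal(m3$q, matrix(0, 1, 2))
  # missing next action on a non-terminal transition is an error
  tr4 <- tabular_transitions(1L, 0L, 0, 1L, NA, FALSE, 1L, 2L)
  expect_error(td_target_sarsa(tr4, Q, 0.9), "next action")
})

test_that("DDQN target splits selection and evaluation between networks", {
  tr <- tabular_transitions(states = 1L, actions = 0L, rewards = 0,
                            next_states = 2L, next_actions = 0L,
                            terminal = FALSE, n_states = 2L, n_actions = 5L)
  primary <- rbind(rep(0, 5), c(1, 3, 2, 0, 0))
  target <- rbind(rep(0, 5), c(5, 1, 9, 0, 0))
  # primary selects action 1 (its argmax at s'), target evaluates it: 0.9 * 1
  expect_equal(td_target_ddqn(tr, primary, target, gamma = 0.9), 0.9)
  # primary == target reduces to the plain Q-learning max target
  expect_equal(td_target_ddqn(tr, primary, primary, gamma = 0.9), 0.9 * 3)
  # terminal transitions never bootstrap
  tr_term <- tabular_transitions(1L, 0L, -15, 2L, NA, TRUE, 2L, 5L)
  expect_equal(td_target_ddqn(tr_term, primary, target, gamma = 0.9), -15)
})

test_that("sequential tabular SARSA reproduces on-policy evaluation of the
           logged chain data", {
  tr <- chain_mdp_transitions(n_episodes = 300, seed = 1)
  gamma <- 0.9
  oracle <- empirical_onpolicy_q(tr, gamma)
  # constant-alpha SARSA orbits its fixed point with amplitude ~ alpha, so a
  # small step size is needed to certify 0.01 agreement
  cfg <- training_config(iterations = 3000000, learning_rate = 0.002,
                         gamma = gamma, seed = 2)
  m <- train_sarsa(tr, cfg)
  expect_lt(max(abs(m$q - oracle)), 0.01)
})

test_that("tabular DDQN recovers the value-iteration solution on an
           enumerable deterministic MDP", {
  tr <- toy3_mdp()
  gamma <- 0.9
  oracle <- toy3_value_iteration(gamma)
  cfg <- training_config(iterations = 8000, learning_rate = 0.2,
                         gamma = gamma, batch_size = 16,
                         target_sync_interval = 50, seed = 3)
  m <- train_ddqn(tr, cfg)
  expect_lt(max(abs(m$q[1:2, ] - oracle[1:2, ])), 0.01)
  expect_equal(max.col(m$q[1:2, , drop = FALSE]),
               max.col(oracle[1:2, , drop = FALSE]))
})

test_that("training runs are deterministic under a fixed seed", {
  fix <- small_mdp()
  tr <- fix$mdp$train_transitions
  cfg <- training_config(iterations = 300, seed = 11,
                         checkpoint_iterations = c(100, 300))
  m1 <- train_sarsa(tr, cfg)
  m2 <- train_sarsa(tr, cfg)
  expect_identical(m1$q, m2$q)
  expect_identical(m1$loss, m2$loss)
  d1 <- train_ddqn(tr, cfg)
  d2 <- train_ddqn(tr, cfg)
  expect_identical(d1$q, d2$q)
  expect_length(d1$checkpoints, 2)
  expect_identical(names(d1$checkpoints), c("100", "300"))
  expect_equal(length(d1$loss), 300)
})

test_that("network SARSA loss decreases fast-then-slow under smoothing", {
  fix <- small_mdp()
  m <- train_sarsa(fix$mdp$train_transitions,
                   training_config(iterations = 4000, seed = 5,
                                   target_clip = c(-15, 15)))
  smooth <- stats::filter(m$loss, rep(1 / 500, 500), sides = 1)
  smooth <- smooth[!is.na(smooth)]
  early <- mean(smooth[1:200])
  late <- mean(utils::tail(smooth, 200))
  expect_lt(late, early)
  # early decline is steeper than late decline
  n <- length(smooth)
  drop_early <- smooth[1] - smooth[round(n / 3)]
  drop_late <- smooth[round(2 * n / 3)] - smooth[n]
  expect_gt(drop_early, drop_late)
})

test_that("a zero-reward dataset drives Q toward zero", {
  fix <- small_mdp()
  tr <- fix$mdp$train_transitions
  tr$rewards <- rep(0, length(tr$rewards))
  m <- train_sarsa(tr, training_config(iterations = 3000, seed = 6))
  qv <- q_values(m, tr$states[1:200, ])
  expect_lt(max(abs(qv)), 1)
})

test_that("gamma = 0 reduces the learner to conditional mean rewards", {
  # discretized toy: two state ids, rewards depend on (state, action)
  set.seed(8)
  n <- 4000
  s <- sample(1:2, n, replace = TRUE)
  a <- sample(0:1, n, replace = TRUE)
  r <- ifelse(s == 1, ifelse(a == 0, 2, -1), ifelse(a == 0, -3, 4)) +
    rnorm(n, 0, 0.5)
  tr <- tabular_transitions(s, a, r, s, a, rep(TRUE, n), 2L, 2L)
  m <- train_ddqn(tr, training_config(iterations = 60000, learning_rate = 0.01,
                                      gamma = 1e-12, seed = 2))
  emp <- matrix(c(mean(r[s == 1 & a == 0]), mean(r[s == 2 & a == 0]),
                  mean(r[s == 1 & a == 1]), mean(r[s == 2 & a == 1])), 2, 2)
  expect_lt(max(abs(m$q - emp)), 0.15)
})

test_that("double estimation controls the max-Q overestimation of single
           networks", {
  # one decision state fans out to a noisy-reward terminal layer; true Q* = 0
  biases <- sapply(1:20, function(s) {
    set.seed(1000 + s)
    n <- 150
    a <- sample(0:4, n, replace = TRUE)
    r <- rnorm(n, 0, 4)
    tr <- tabular_transitions(rep(2L, n), a, r, rep(2L, n), NA,
                              rep(TRUE, n), 2L, 5L)
    # prepend transitions from the decision state bootstrapping into state 2
    tr0 <- tabular_transitions(c(rep(1L, 50), rep(2L, n)),
                               c(sample(0:4, 50, replace = TRUE), a),
                               c(rep(0, 50), r),
                               c(rep(2L, 50), rep(2L, n)),
                               c(sample(0:4, 50, replace = TRUE), rep(NA, n)),
                               c(rep(FALSE, 50), rep(TRUE, n)), 2L, 5L)
    cfg <- training_config(iterations = 4000, learning_rate = 0.1,
                           gamma = 0.95, batch_size = 8,
                           target_sync_interval = 200, seed = s)
    m_dd <- train_ddqn(tr0, cfg, double = TRUE)
    m_q <- train_ddqn(tr0, cfg, double = FALSE)
    c(ddqn = max(m_dd$q[1, ]), qlearn = max(m_q$q[1, ]))
  })
  expect_lte(mean(biases["ddqn", ]), mean(biases["qlearn", ]))
})

test_that("greedy action prediction breaks ties toward the lower index", {
  Q <- rbind(c(0, 0, 1, 0, 0), c(1, 1, 0, 0, 0), c(0, 0, 0, 0, 0))
  expect_equal(predict_actions(Q, 1:3), c(2L, 0L, 0L))
  probs <- action_probabilities(Q, 1:3)
  expect_equal(rowSums(probs), rep(1, 3))
  expect_equal(apply(probs, 1, which.max) - 1L, c(2L, 0L, 0L))
})

test_that("training config validates its numeric domains", {
  expect_error(training_config(0), "iterations")
  expect_error(training_config(10, gamma = 0), "gamma")
  expect_error(training_config(10, gamma = 1.5), "gamma")
  expect_error(training_config(10, learning_rate = 0), "learning_rate")
  expect_error(training_config(10, target_sync_interval = 0), "sync")
  expect_error(training_config(10, checkpoint_iterations = 20), "checkpoint")
  expect_error(training_config(10, target_clip = c(2, 1)), "target_clip")
  expect_error(train_sarsa(tabular_transitions(integer(0), integer(0),
                                               numeric(0), integer(0),
                                               integer(0), logical(0), 1L, 2L),
                           training_config(10)), "empty")
})
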