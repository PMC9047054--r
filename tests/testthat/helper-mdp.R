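# Enumerable toy MDPs and dynamic-programming oracles for the learner tests.
# The oracles are independent of the package's TD code: they solve the
# Bellman equations of the *logged* data (empirical transitions) or of the
# known MDP by plain fixed-point iteration.

# Deterministic 4-state chain: action 0 advances (reward 0, +15 on entering
# the terminal state from state 3 at the end of an episode), action 1 stays.
# Episodes are rolled out under a fixed stochastic behavior policy.
chain_mdp_transitions <- function(n_episodes = 300, seed = 1,
                                  p_advance = 0.7) {
  set.seed(seed)
  s_v <- integer(0); a_v <- integer(0); r_v <- numeric(0)
  ns_v <- integer(0); na_v <- integer(0); term_v <- logical(0)
  for (ep in seq_len(n_episodes)) {
    s <- 1L
    steps <- list()
    repeat {
      a <- if (stats::runif(1) < p_advance) 0L else 1L
      s_next <- if (a == 0L) s + 1L else s
      r <- if (s_next == 4L) 15 else 0
      steps[[length(steps) + 1L]] <- c(s, a, r, s_next)
      s <- s_next
      if (s == 4L || length(steps) >= 30) break
    }
    for (i in seq_along(steps)) {
      st <- steps[[i]]
      terminal <- i == length(steps)
      s_v <- c(s_v, st[1]); a_v <- c(a_v, st[2]); r_v <- c(r_v, st[3])
      ns_v <- c(ns_v, st[4])
      na_v <- c(na_v, if (terminal) NA_integer_ else steps[[i + 1L]][2])
      term_v <- c(term_v, terminal)
    }
  }
  tabular_transitions(s_v, a_v, r_v, ns_v, na_v, term_v,
                      n_states = 4L, n_actions = 2L)
}

# On-policy Q of the logged data: fixed point of the empirical SARSA Bellman
# operator Q(s,a) = mean over logged transitions from (s,a) of
# r + gamma * (terminal ? 0 : Q(s',a')).
empirical_onpolicy_q <- function(tr, gamma, iters = 2000) {
  Q <- matrix(0, tr$n_states, tr$n_actions)
  for (k in seq_len(iters)) {
    targ <- tr$rewards +
      ifelse(tr$terminal, 0,
             gamma * Q[cbind(tr$next_states, tr$next_actions + 1L)])
    Qn <- Q
    for (s in seq_len(tr$n_states)) for (a in seq_len(tr$n_actions)) {
      i <- tr$states == s & tr$actions == a - 1L
      if (any(i)) Qn[s, a] <- mean(targ[i])
    }
    if (max(abs(Qn - Q)) < 1e-12) return(Qn)
    Q <- Qn
  }
  Q
}

# Deterministic 3-state, 2-action MDP with full (s, a) coverage in the log.
# Action 0 from state s moves to s+1 with reward s; action 1 jumps straight
# to the terminal state 3 with reward 1. Terminal entry ends the episode.
toy3_mdp <- function() {
  # enumerate each (s, a) several times so batch sampling sees everything
  grid <- expand.grid(s = 1:2, a = 0:1, rep = 1:25)
  s <- grid$s; a <- grid$a
  ns <- ifelse(a == 0L, s + 1L, 3L)
  r <- ifelse(a == 0L, as.numeric(s), 1)
  term <- ns == 3L
  # next action (for SARSA completeness): advance
  na <- ifelse(term, NA_integer_, 0L)
  tabular_transitions(s, a, r, ns, na, term, n_states = 3L, n_actions = 2L)
}

# Value iteration on the known deterministic toy MDP.
toy3_value_iteration <- function(gamma, iters = 1000) {
  Q <- matrix(0, 3, 2)
  for (k in seq_len(iters)) {
    Qn <- Q
    for (s in 1:2) {
      # action 0: reward s, next s+1 (terminal if s+1 == 3)
      Qn[s, 1] <- s + if (s + 1 < 3) gamma * max(Q[s + 1, ]) else 0
      # action 1: reward 1, terminal
      Qn[s, 2] <- 1
    }
    if (max(abs(Qn - Q)) < 1e-12) return(Qn)
    Q <- Qn
  }
  Q
}
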