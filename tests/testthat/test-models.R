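test_that("initial-value schemes assign eta slots per model definition", {
  roles <- c(H = "pref_high", L = "pref_low", NH = "novel_high",
             NL = "novel_low")
  m1 <- rl_model("RL1")
  q <- init_values(m1, rl_params(0.3, 1, 0.5, m1), roles)
  expect_equal(unname(q), rep(0.5, 4))

  m2 <- rl_model("RL2")
  q <- init_values(m2, rl_params(0.3, 1, c(0.8, 0.5), m2), roles)
  expect_equal(q, c(H = 0.8, L = 0.5, NH = 0.5, NL = 0.5))

  m3 <- rl_model("RL3")
  q <- init_values(m3, rl_params(0.3, 1, c(0.8, 0.2), m3), roles)
  expect_equal(q, c(H = 0.8, L = 0.2, NH = 0.8, NL = 0.8))

  m4 <- rl_model("RL4")
  q <- init_values(m4, rl_params(0.3, 1, c(0.9, 0.1, 0.5), m4), roles)
  expect_equal(q, c(H = 0.9, L = 0.1, NH = 0.5, NL = 0.5))

  # nesting: RL4 with tied etas is RL1
  q4 <- init_values(m4, rl_params(0.3, 1, rep(0.37, 3), m4), roles)
  q1 <- init_values(m1, rl_params(0.3, 1, 0.37, m1), roles)
  expect_identical(unname(q4), unname(q1))

  # idm_only stimuli have no slot
  expect_error(init_values(m2, rl_params(0.3, 1, c(0.8, 0.5), m2),
                           c(X = "idm_only")), "idm_only")
})

test_that("parameter bounds are enforced at construction", {
  m <- rl_model("RL2")
  expect_error(rl_params(-0.1, 1, c(0.5, 0.5), m), "alpha")
  expect_error(rl_params(0.5, 11, c(0.5, 0.5), m), "beta")
  expect_error(rl_params(0.5, 1, c(0.5, 1.2), m), "etas")
  expect_error(rl_params(0.5, 1, 0.5, m), "2 eta")
  m_tight <- rl_model("RL1", beta_max = 1)
  expect_error(rl_params(0.5, 1.5, 0.5, m_tight), "beta")
  expect_silent(rl_params(0.5, 0.9, 0.5, m_tight))
})

test_that("delta-rule update matches hand evaluation and limits", {
  expect_equal(update_q(0.5, 1, 0.2), 0.6)
  q <- runif(10)
  expect_equal(update_q(q, 1, 0), q)         # no learning
  expect_equal(update_q(q, rep(1, 10), 1), rep(1, 10))  # full update
  expect_error(update_q(1.2, 1, 0.5), "q must")
  expect_error(update_q(0.5, 2, 0.5), "reward")
  expect_error(update_q(0.5, 1, 1.5), "alpha")
})

test_that("softmax choice probability: value, symmetry, monotonicity", {
  expect_equal(choice_prob(0.4, 0.4, 3), 0.5)
  expect_equal(choice_prob(0.9, 0.1, 0), 0.5)
  expect_equal(choice_prob(1, 0, 1), 1 / (1 + exp(-1)), tolerance = 1e-12)
  # complement identity to machine precision over random inputs
  set.seed(1)
  a <- runif(200); b <- runif(200); beta <- runif(200, 0, 10)
  expect_equal(choice_prob(a, b, beta) + choice_prob(b, a, beta),
               rep(1, 200), tolerance = 1e-14)
  # strictly increasing in the value difference and in beta
  d <- seq(-1, 1, by = 0.1)
  expect_true(all(diff(choice_prob(d, 0, 2)) > 0))
  expect_true(all(diff(choice_prob(0.8, 0.3, seq(0, 10, 1))) > 0))
  expect_error(choice_prob(Inf, 0, 1), "finite")
  expect_error(choice_prob(1, 0, -1), "beta")
})

test_that("session log-likelihood equals the brute-force oracle on all
           3-trial choice patterns and a longer random session", {
  m <- rl_model("RL2")
  p <- rl_params(0.35, 4, c(0.7, 0.4), m)
  roles <- c(A = "pref_high", B = "novel_low")
  pats <- expand.grid(t1 = c("A", "B"), t2 = c("A", "B"), t3 = c("A", "B"),
                      stringsAsFactors = FALSE)
  rewards <- c(1L, 0L, 1L)
  for (i in seq_len(nrow(pats))) {
    ch <- unlist(pats[i, ])
    trials <- toy_gamble(ch, rewards)
    got <- session_loglik(m, p, trials, roles)
    idx <- ifelse(ch == "A", 1L, 2L)
    want <- oracle_loglik(idx, 3L - idx, rewards, c(0.7, 0.4), 0.35, 4)
    expect_equal(got, want, tolerance = 1e-12)
  }
  # longer session, all four models, random parameters
  set.seed(7)
  ch <- sample(c("A", "B"), 60, replace = TRUE)
  rw <- rbinom(60, 1, 0.5)
  trials <- toy_gamble(ch, rw)
  idx <- ifelse(ch == "A", 1L, 2L)
  for (mn in c("RL1", "RL2", "RL3", "RL4")) {
    mm <- rl_model(mn)
    pp <- rl_params(runif(1), runif(1, 0, 8), runif(mm$n_eta), mm)
    q0 <- init_values(mm, pp, roles)
    expect_equal(session_loglik(mm, pp, trials, roles),
                 oracle_loglik(idx, 3L - idx, rw, unname(q0), pp$alpha, pp$beta),
                 tolerance = 1e-12)
  }
})

test_that("single equal-value trial gives log(1/2); tied-eta models nest
           RL1 exactly", {
  m1 <- rl_model("RL1")
  trials <- toy_gamble("A", 1L)
  roles <- c(A = "pref_high", B = "novel_low")
  expect_equal(session_loglik(m1, rl_params(0.2, 5, 0.5, m1), trials, roles),
               log(0.5), tolerance = 1e-12)
  set.seed(11)
  ch <- sample(c("A", "B"), 40, replace = TRUE)
  long <- toy_gamble(ch, rbinom(40, 1, 0.6))
  ll1 <- session_loglik(m1, rl_params(0.3, 2, 0.6, m1), long, roles)
  for (mn in c("RL2", "RL3", "RL4")) {
    mm <- rl_model(mn)
    llk <- session_loglik(mm, rl_params(0.3, 2, rep(0.6, mm$n_eta), mm),
                          long, roles)
    expect_identical(llk, ll1)
  }
})

test_that("Q values stay in [0,1] for binary rewards (closure property)", {
  set.seed(3)
  m <- rl_model("RL4")
  roles <- c(A = "pref_high", B = "pref_low", C = "novel_high",
             D = "novel_low")
  for (rep in 1:25) {
    p <- rl_params(runif(1), runif(1, 0, 10), runif(3), m)
    sched <- build_gamble_schedule("pref_high_prob", "A", "B",
                                   c("P1", "P2", "C", "D"),
                                   trials_per_pair = 30)
    sim <- simulate_session(m, p, sched)
    rl <- setNames(sched$stimuli$role, sched$stimuli$stimulus_id)
    traj <- q_trajectory(m, p, sim, rl)
    expect_true(all(traj$q_value >= 0 & traj$q_value <= 1))
  }
})

test_that("q_trajectory: flat when never chosen, final reward at alpha=1,
           and the hand-computed 3-trial series", {
  m <- rl_model("RL1")
  roles <- c(A = "pref_high", B = "novel_low")
  trials <- toy_gamble(c("A", "A", "A"), c(1L, 0L, 1L))
  p <- rl_params(0.5, 2, 0.3, m)
  traj <- q_trajectory(m, p, trials, roles)
  b <- traj[traj$stimulus_id == "B", ]
  expect_equal(b$q_value, rep(0.3, 4))          # never chosen: flat at Q0
  a <- traj[traj$stimulus_id == "A", ]
  expect_equal(a$q_value,
               oracle_q_series(c(TRUE, TRUE, TRUE), c(1, 0, 1), 0.3, 0.5),
               tolerance = 1e-12)
  # alpha = 1: final value is the last received reward
  p1 <- rl_params(1, 2, 0.3, m)
  traj1 <- q_trajectory(m, p1, trials, roles)
  a1 <- traj1[traj1$stimulus_id == "A", ]
  expect_equal(a1$q_value[length(a1$q_value)], 1)
})

test_that("simulate_session respects limits and matches the closed-form
           first-trial choice probability", {
  m <- rl_model("RL2")
  sched <- build_gamble_schedule("pref_high_prob", "H", "L",
                                 c("N1", "N2", "N3", "N4"),
                                 trials_per_pair = 2)
  # near-deterministic regime: first trial of the preferred pair goes to H
  p_det <- rl_params(0.3, 10, c(1, 0), m)
  set.seed(5)
  hits <- replicate(200, {
    sim <- simulate_session(m, p_det, sched)
    hp <- sim[sim$pair_id == "high_pref_pair", ]
    hp$chosen_stim[1] == "H"
  })
  expect_gte(mean(hits), 0.99)
  # alpha = 0, equal initial values: long-run choice rate about one half
  p0 <- rl_params(0, 2, c(0.5, 0.5), m)
  sched50 <- build_gamble_schedule("pref_high_prob", "H", "L",
                                   c("N1", "N2", "N3", "N4"),
                                   trials_per_pair = 40)
  set.seed(6)
  rates <- replicate(60, {
    sim <- simulate_session(m, p0, sched50)
    mean(sim$chosen_stim == sim$left_stim)
  })
  expect_equal(mean(rates), 0.5, tolerance = 0.02)
  # Monte-Carlo first-trial rate vs choice_prob(eta1, eta2, beta)
  p <- rl_params(0.3, 5.3, c(0.7, 0.4), m)
  set.seed(8)
  first <- replicate(4000, {
    sim <- simulate_session(m, p, sched)
    hp <- sim[sim$pair_id == "high_pref_pair", ]
    hp$chosen_stim[1] == "H"
  })
  expect_equal(mean(first), choice_prob(0.7, 0.4, 5.3), tolerance = 0.025)
})
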