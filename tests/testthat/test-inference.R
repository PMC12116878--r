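test_that("tempered log posterior: reductions, support, and a probe-point
           oracle recomputation", {
  m <- rl_model("RL2")
  prior <- rl_prior(m)
  roles <- c(A = "pref_high", B = "novel_low")
  trials <- toy_gamble(c("A", "B", "A"), c(1L, 1L, 0L))
  unit <- list(trials = trials, roles = roles)
  x <- c(0.4, 3, 0.6, 0.35)
  # tau = 1 is the ordinary log posterior
  lp1 <- log_tempered_posterior(m, x, unit, prior, tau = 1)
  ll <- session_loglik(m, rl_params(0.4, 3, c(0.6, 0.35), m), trials, roles)
  expect_equal(as.numeric(lp1), ll + prior$log_d(x), tolerance = 1e-12)
  # probe point vs straight-line oracle recomputation
  want <- oracle_loglik(c(1L, 2L, 1L), c(2L, 1L, 2L), c(1, 1, 0),
                        c(0.6, 0.35), 0.4, 3)
  expect_equal(attr(lp1, "loglik"), want, tolerance = 1e-10)
  # tempering scales only the likelihood part
  lp_t <- log_tempered_posterior(m, x, unit, prior, tau = 0.25)
  expect_equal(as.numeric(lp_t), 0.25 * want + prior$log_d(x),
               tolerance = 1e-10)
  # single equal-value trial: log(1/2) + prior constant
  one <- list(trials = toy_gamble("A", 1L), roles = roles)
  lp_one <- log_tempered_posterior(m, c(0.4, 3, 0.5, 0.5), one, prior, 1)
  expect_equal(as.numeric(lp_one), log(0.5) + prior$log_d(x),
               tolerance = 1e-12)
  # out-of-support points are rejected by contract
  expect_identical(as.numeric(
    log_tempered_posterior(m, c(1.4, 3, 0.5, 0.5), one, prior, 1)), -Inf)
})

test_that("WBIC grows when the dataset is duplicated and agrees for
           identical models", {
  m <- rl_model("RL1")
  roles <- c(A = "pref_high", B = "novel_low")
  set.seed(15)
  ch <- sample(c("A", "B"), 50, replace = TRUE, prob = c(0.7, 0.3))
  trials <- toy_gamble(ch, rbinom(50, 1, 0.6))
  unit <- list(trials = trials, roles = roles)
  w1 <- wbic_unit(m, unit, control = light_control(), seed = 5)
  dup <- trials
  dup$trial_index <- dup$trial_index + 50L
  both <- rbind(trials, dup)
  w2 <- wbic_unit(m, list(trials = both, roles = roles),
                  control = light_control(), seed = 5)
  expect_gt(as.numeric(w2), as.numeric(w1))
  # same model, same data, different seeds: equal within Monte-Carlo error
  w1b <- wbic_unit(m, unit, control = light_control(), seed = 6)
  expect_lt(abs(as.numeric(w1) - as.numeric(w1b)),
            4 * (attr(w1, "mcse") + attr(w1b, "mcse")) + 0.3)
})

test_that("Bayes factors: value, bins, reciprocity", {
  eq <- bayes_factor(10, 10)
  expect_equal(eq$bf, 1)
  expect_equal(eq$label, "unimportant")
  b <- bayes_factor(100, 100 + log(110))
  expect_equal(b$bf, 110, tolerance = 1e-9)
  expect_equal(b$label, "strong")
  # anti-symmetry
  ab <- bayes_factor(3, 7); ba <- bayes_factor(7, 3)
  expect_equal(ab$bf, 1 / ba$bf, tolerance = 1e-12)
  expect_equal(ba$favoured, "b")
  expect_equal(ba$bf_reported, ab$bf_reported)
  # bin boundaries
  expect_equal(kass_raftery_label(1), "unimportant")
  expect_equal(kass_raftery_label(2.999), "unimportant")
  expect_equal(kass_raftery_label(3), "positive")
  expect_equal(kass_raftery_label(19.999), "positive")
  expect_equal(kass_raftery_label(20), "strong")
  expect_equal(kass_raftery_label(149.99), "strong")
  expect_equal(kass_raftery_label(150), "very strong")
  expect_error(kass_raftery_label(0.5))
})

test_that("model comparison table is ordered, labelled, and handles a
           single model", {
  set.seed(16)
  m <- rl_model("RL2")
  p <- rl_params(0.35, 5.3, c(0.75, 0.35), m)
  unit <- simulate_unit_for_test(m, p)
  cmp <- suppressWarnings(
    rl_compare(list(unit), c("RL1", "RL2"), control = light_control(),
               seed = 7))
  expect_s3_class(cmp, "rl_comparison")
  expect_equal(cmp$delta_wbic[1], 0)
  expect_true(is.na(cmp$bf_vs_best[1]))
  expect_true(all(diff(cmp$wbic) >= 0))
  one <- suppressWarnings(
    rl_compare(list(unit), "RL1", control = light_control(), seed = 8))
  expect_equal(nrow(one), 1)
  expect_equal(one$label, "single model")
})

test_that("maximum likelihood respects model nesting (RL4 >= RL2/RL3 >= RL1)", {
  set.seed(17)
  m <- rl_model("RL2")
  p <- rl_params(0.3, 4, c(0.8, 0.3), m)
  unit <- simulate_unit_for_test(m, p)
  ml <- vapply(c("RL1", "RL2", "RL3", "RL4"), function(mn) {
    mm <- rl_model(mn)
    best <- -Inf
    nll <- function(x) -as.numeric(session_loglik(
      mm, rl_params(x[1], x[2], x[-(1:2)], mm), unit$trials, unit$roles))
    for (s in 1:5) {
      set.seed(s)
      x0 <- c(runif(1, 0.05, 0.95), runif(1, 0.5, 9.5),
              runif(mm$n_eta, 0.05, 0.95))
      o <- optim(x0, nll, method = "L-BFGS-B",
                 lower = mm$lower + 1e-6, upper = mm$upper - 1e-6)
      best <- max(best, -o$value)
    }
    best
  }, numeric(1))
  tol <- 1e-4
  expect_gte(ml["RL4"], ml["RL2"] - tol)
  expect_gte(ml["RL4"], ml["RL3"] - tol)
  expect_gte(ml["RL2"], ml["RL1"] - tol)
  expect_gte(ml["RL3"], ml["RL1"] - tol)
})

test_that("rl_fit: reproducibility, prior-dominated shrinkage, and method
           contracts", {
  set.seed(18)
  m <- rl_model("RL2")
  p <- rl_params(0.4, 5.3, c(0.7, 0.4), m)
  unit <- simulate_unit_for_test(m, p, trials_per_pair = 25)
  f1 <- suppressWarnings(rl_fit(unit, "RL2", control = light_control(), seed = 19))
  f2 <- suppressWarnings(rl_fit(unit, "RL2", control = light_control(), seed = 19))
  expect_identical(coef(f1), coef(f2))
  # prior-dominated regime: a single uninformative trial leaves the
  # posterior mean near the prior mean
  tiny <- list(trials = toy_gamble("A", 1L),
               roles = c(A = "pref_high", B = "novel_low"))
  f0 <- suppressWarnings(rl_fit(tiny, "RL2",
                                control = sampler_control(2, 1500, 500),
                                seed = 20))
  est <- coef(f0)[1, ]
  expect_equal(unname(est["alpha"]), 0.5, tolerance = 0.06)
  expect_equal(unname(est["beta"]), 5, tolerance = 0.6)
  # method contracts
  pr <- predict(f1)
  expect_true(all(pr$fitted > 0 & pr$fitted < 1))
  expect_equal(nrow(pr), nrow(unit$trials))
  r <- residuals(f1)
  expect_true(all(abs(r) < 1))
  sim <- simulate(f1, seed = 21)
  expect_equal(nrow(sim), nrow(unit$trials))
  expect_true(all(sim$reward %in% 0:1))
  ll <- logLik(f1)
  expect_true(is.finite(as.numeric(ll)))
  expect_equal(attr(ll, "nobs"), nrow(unit$trials))
  s <- summary(f1)
  expect_equal(s$table$parameter, c("alpha", "beta", "eta1", "eta2"))
  vt <- value_table(f1)
  expect_setequal(vt$stim_type, c("idm", "novel"))
  expect_true(all(vt$initial >= 0 & vt$final <= 1))
})

test_that("pooled fitting collapses all participants into one unit", {
  study <- generate_study(n_participants = 2, seed = 30)
  f <- suppressWarnings(rl_fit(study, "RL1",
                               control = light_control(iter = 200), seed = 31,
                               pool = TRUE))
  expect_equal(nrow(coef(f)), 1)
  expect_equal(rownames(coef(f)), "pooled")
})

test_that("recovery report plumbing: degenerate grids flagged, confusion
           rows sum to the replicate count", {
  m <- rl_model("RL1")
  fixed <- rl_params(0.3, 5, 0.5, m)
  pr <- suppressWarnings(parameter_recovery(
    "RL1", n_datasets = 3, design = edm_design(trials_per_pair = 10),
    truth_sampler = list(fixed), control = light_control(iter = 200),
    seed = 32))
  expect_true(all(is.na(pr$summary$cor)))
  expect_true(all(pr$summary$degenerate))
  mr <- suppressWarnings(model_recovery(
    c("RL1", "RL2"), n_datasets_per_model = 2,
    design = edm_design(trials_per_pair = 10),
    control = light_control(iter = 150), seed = 33))
  expect_equal(unname(rowSums(mr$confusion)), c(2L, 2L))
})

test_that("alpha recovery does not degrade when trials per pair increase
           (25 vs 100, paired truths)", {
  ctrl <- sampler_control(2, 1000, 500)
  rmse_at <- function(tpp) {
    pr <- suppressWarnings(parameter_recovery(
      "RL2", n_datasets = 15, design = edm_design(trials_per_pair = tpp),
      control = ctrl, seed = 55))   # same seed: identical true parameters
    pr$summary$rmse[pr$summary$parameter == "alpha"]
  }
  expect_gte(rmse_at(25), rmse_at(100))
})
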