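test_that("chosen-frequency contrast matches a hand computation and the
           generator's direction", {
  # hand-computable toy: high (0.6, 0.7, 0.8) vs low (0.2, 0.1, 0.3)
  # diffs (0.4, 0.6, 0.5): t = 0.5 / (0.1 / sqrt(3)) = 8.6603, d = 5
  r <- prefrl:::paired_t(c(0.6, 0.7, 0.8), c(0.2, 0.1, 0.3))
  expect_equal(r$statistic, 0.5 / (0.1 / sqrt(3)), tolerance = 1e-10)
  expect_equal(r$effect_size, 5, tolerance = 1e-10)
  expect_equal(r$df2, 2)
  expect_equal(r$p_value, 2 * pt(-abs(8.66025403784), 2), tolerance = 1e-8)
  # all-equal input: t = 0, flagged degenerate
  r0 <- prefrl:::paired_t(c(0.5, 0.5), c(0.5, 0.5))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  # on a generated study the direction is high > low, and the statistic
  # agrees with an independent recomputation from the raw trials (a noisy
  # preference world keeps the per-participant frequencies non-constant)
  study <- generate_study(design = study_design(n_participants = 6,
                                                latent_spread = 1.5),
                          seed = 41)
  res <- pref_frequency_contrast(study)
  expect_gt(res$statistic, 0)
  hand <- independent_freq_contrast(study)
  expect_equal(res$statistic, hand$t, tolerance = 1e-8)
  expect_equal(res$effect_size, hand$d, tolerance = 1e-8)
})

test_that("correct-rate table counts the 70% choices out of 50 trials", {
  study <- generate_study(n_participants = 3, seed = 42)
  rt <- correct_rate_table(study)
  expect_equal(nrow(rt), 3 * 2 * 3)
  expect_true(all(rt$n_trials == 50))
  expect_true(all(rt$correct_rate >= 0 & rt$correct_rate <= 1))
  # recompute one cell by hand
  g <- study$gamble_trials
  st <- study$stimuli
  cell <- g[g$participant_id == "p001" & g$task_type == "pref_high_prob" &
              g$pair_id == "novel_pair", ]
  hi <- st$stimulus_id[st$participant_id == "p001" &
                         !is.na(st$reward_prob) & st$reward_prob == 0.7]
  want <- mean(cell$chosen_stim %in% hi)
  got <- rt$correct_rate[rt$participant_id == "p001" &
                           rt$task_type == "pref_high_prob" &
                           rt$pair_id == "novel_pair"]
  expect_equal(got, want)
})

test_that("two-factor repeated-measures ANOVA matches the contrast-score
           oracle on a 4-participant toy", {
  set.seed(43)
  y <- matrix(runif(16), 4, 4)   # columns: A1B1, A2B1, A1B2, A2B2
  cells <- expand.grid(participant_id = paste0("s", 1:4),
                       task_type = c("a1", "a2"), stim_type = c("b1", "b2"))
  cells$correct_rate <- as.numeric(y)
  res <- rm_anova_2x2(cells, alpha = 1.01)  # force simple effects
  oa <- rm_contrast_oracle(y, c(1, -1, 1, -1))    # main effect of A
  ob <- rm_contrast_oracle(y, c(1, 1, -1, -1))    # main effect of B
  oi <- rm_contrast_oracle(y, c(1, -1, -1, 1))    # interaction
  for (nm_o in list(list("task_type", oa), list("stim_type", ob),
                    list("task_type:stim_type", oi))) {
    row <- res[res$effect == nm_o[[1]], ]
    expect_equal(row$statistic, nm_o[[2]]$F, tolerance = 1e-8)
    expect_equal(row$p_value, nm_o[[2]]$p, tolerance = 1e-8)
    expect_equal(row$df2, nm_o[[2]]$df2)
    expect_equal(row$effect_size, nm_o[[2]]$eta_p, tolerance = 1e-8)
  }
  # simple effects: pooled-error F with df (1, 2(n-1))
  se <- res[grepl(" at ", res$effect), ]
  expect_equal(nrow(se), 4)
  expect_true(all(se$df2 == 6))
  # identical values in all cells: all F = 0
  cells$correct_rate <- 0.6
  res0 <- rm_anova_2x2(cells)
  expect_true(all(res0$statistic == 0))
  expect_true(all(res0$p_value == 1))
})

test_that("simple pooled-error effects agree with slice t-tests when the
           error strata are homogeneous", {
  set.seed(44)
  n <- 30
  base <- rnorm(n)
  y <- cbind(base + rnorm(n, 0.5, 0.2), base + rnorm(n, 0, 0.2),
             base + rnorm(n, 0.2, 0.2), base + rnorm(n, 0, 0.2))
  cells <- expand.grid(participant_id = sprintf("s%02d", 1:n),
                       task_type = c("a1", "a2"), stim_type = c("b1", "b2"))
  cells$correct_rate <- as.numeric(y)
  res <- rm_anova_2x2(cells, alpha = 1.01)
  f_pool <- res$statistic[res$effect == "task_type at stim_type=b1"]
  t_slice <- prefrl:::paired_t(y[, 1], y[, 2])$statistic
  expect_equal(f_pool, t_slice^2, tolerance = 0.35)
})

test_that("above-chance tests: exact chance, degenerate certainty, and a
           hand-checked vector", {
  rt <- data.frame(participant_id = paste0("p", 1:3),
                   task_type = "pref_high_prob", pair_id = "novel_pair",
                   n_trials = 50, correct_rate = c(0.6, 0.7, 0.62))
  res <- above_chance_tests(rt)
  x <- c(0.6, 0.7, 0.62)
  t_hand <- (mean(x) - 0.5) / (sd(x) / sqrt(3))
  expect_equal(res$statistic, t_hand, tolerance = 1e-10)
  rt$correct_rate <- 0.5
  expect_equal(above_chance_tests(rt)$statistic, 0)
  rt$correct_rate <- 1.0
  res1 <- above_chance_tests(rt)
  expect_true(is.infinite(res1$statistic) && res1$statistic > 0)
  expect_equal(res1$flag, "degenerate")
})

test_that("Holm adjustment: worked example and monotonicity", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.04), method = "holm"),
               c(0.03, 0.04, 0.04))
  set.seed(45)
  for (i in 1:20) {
    p <- runif(6)
    adj <- p.adjust(p, method = "holm")
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
  }
})

test_that("rating comparisons produce Holm-adjusted pairwise contrasts and
           identical ratings give adjusted p = 1", {
  study <- generate_study(n_participants = 6, seed = 46)
  res <- rating_comparisons(study)
  expect_equal(nrow(res), 2 * 6)   # 2 tasks x choose(4, 2)
  expect_true(all(res$p_adj >= res$p_value - 1e-15))
  # preferred stimulus carries the top mean rating in both tasks
  st <- study$stimuli
  r <- merge(study$ratings, st[c("participant_id", "task_set",
                                 "stimulus_id", "role", "pair_id")],
             by = c("participant_id", "task_set", "stimulus_id"))
  keep <- r$role %in% c("pref_high", "pref_low") |
    (!is.na(r$pair_id) & r$pair_id == "novel_pair")
  means <- tapply(r$rating[keep], r$role[keep], mean)
  expect_equal(names(which.max(means)), "pref_high")
  # constant ratings
  s2 <- study
  s2$ratings$rating <- 3L
  res2 <- rating_comparisons(s2)
  expect_true(all(res2$p_adj == 1))
})

test_that("first-trial proportions identify the designated stimulus and
           handle a deterministic chooser", {
  study <- toy_study()
  ft <- first_trial_choice(study)
  # both toy participants choose A (pref_high) first in the high pair,
  # N2 (not pref_low) in the low pair, N3 (the 70% one) in the novel pair
  expect_equal(ft$proportion[ft$pair_id == "high_pref_pair"], 1.0)
  expect_equal(ft$proportion[ft$pair_id == "low_pref_pair"], 0.0)
  expect_equal(ft$proportion[ft$pair_id == "novel_pair"], 1.0)
  expect_equal(unname(ft$n), rep(2, 3))
})

test_that("three-factor value ANOVA matches the contrast oracle and flags
           missing cells", {
  set.seed(47)
  n <- 5
  vals <- expand.grid(participant_id = paste0("s", 1:n),
                      task_type = "pref_high_prob",
                      stim_type = c("idm", "novel"), prob = c("high", "low"),
                      stringsAsFactors = FALSE)
  vals$initial <- runif(nrow(vals))
  vals$final <- runif(nrow(vals))
  res <- value_stage_anova(vals)
  # oracle on the 2x2x2 layout: columns ordered over (stim, prob, stage)
  wide <- matrix(0, n, 8)
  k <- 0
  for (vt in c("initial", "final")) for (pr in c("high", "low"))
    for (stp in c("idm", "novel")) {
      k <- k + 1
      sel <- vals$stim_type == stp & vals$prob == pr
      wide[, k] <- vals[sel, vt][order(vals$participant_id[sel])]
    }
  # main effect of value type: initial (cols 1:4) vs final (cols 5:8)
  o_vt <- rm_contrast_oracle(wide, c(1, 1, 1, 1, -1, -1, -1, -1))
  row <- res[res$effect == "pref_high_prob: value_type", ]
  expect_equal(row$statistic, o_vt$F, tolerance = 1e-8)
  expect_equal(row$p_value, o_vt$p, tolerance = 1e-8)
  # main effect of stimulus type: idm (odd cols) vs novel (even cols)
  o_st <- rm_contrast_oracle(wide, c(1, -1, 1, -1, 1, -1, 1, -1))
  row <- res[res$effect == "pref_high_prob: stim_type", ]
  expect_equal(row$statistic, o_st$F, tolerance = 1e-8)
  expect_equal(row$effect_size, o_st$eta_p, tolerance = 1e-8)
  # all-equal values: every F zero
  vals$initial <- 0.4; vals$final <- 0.4
  res0 <- value_stage_anova(vals)
  anova_rows <- !grepl(" at | vs ", res0$effect)
  expect_true(all(res0$statistic[anova_rows] == 0))
  # missing cells error
  expect_error(value_stage_anova(vals[vals$stim_type == "idm" |
                                        vals$prob == "high", ]),
               "missing cells")
})

test_that("type-I error of the battery's tests is near nominal under null
           data", {
  set.seed(48)
  n <- 12
  rate_t <- type_one_error(
    null_gen = function(i) matrix(rnorm(2 * n), n, 2),
    test_fn = function(d) prefrl:::paired_t(d[, 1], d[, 2])$p_value,
    n_sims = 400)
  expect_lt(abs(rate_t - 0.05), 0.035)
})
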