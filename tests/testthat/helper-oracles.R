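# Independent straight-line oracles and small fixture builders. These stay
# deliberately naive (plain loops, textbook formulas) so they share no code
# path with the package internals they check.

# Trial-by-trial log-likelihood of the delta-rule/softmax model.
oracle_loglik <- function(chosen, other, reward, q0, alpha, beta) {
  q <- q0
  ll <- 0
  for (t in seq_along(chosen)) {
    p <- 1 / (1 + exp(-beta * (q[chosen[t]] - q[other[t]])))
    ll <- ll + log(p)
    q[chosen[t]] <- q[chosen[t]] + alpha * (reward[t] - q[chosen[t]])
  }
  ll
}

# Q series of one stimulus under the same model.
oracle_q_series <- function(chosen_is_stim, reward, q0, alpha) {
  q <- q0
  out <- q0
  for (t in seq_along(chosen_is_stim)) {
    if (chosen_is_stim[t]) q <- q + alpha * (reward[t] - q)
    out <- c(out, q)
  }
  out
}

# Gambling-trial data frame for one participant and one task.
toy_gamble <- function(chosen, reward, left = "A", right = "B",
                       task_type = "pref_high_prob", pair_id = "high_pref_pair",
                       pid = "p1") {
  n <- length(chosen)
  data.frame(participant_id = pid, task_type = task_type, pair_id = pair_id,
             trial_index = seq_len(n), left_stim = left, right_stim = right,
             chosen_stim = chosen, reward = as.integer(reward),
             stringsAsFactors = FALSE)
}

# Repeated-measures ANOVA oracle for fully-crossed 2-level within designs:
# the F of every effect equals the squared one-sample t of the subject-level
# +/- contrast scores (textbook equivalence, independent of stats::aov).
# cells: matrix n x 2^k, columns in the order of expand.grid over factors.
rm_contrast_oracle <- function(cells, contrast) {
  score <- as.numeric(cells %*% contrast) / (length(contrast) / 2)
  n <- length(score)
  tval <- mean(score) / (sd(score) / sqrt(n))
  F <- tval^2
  list(F = F, df1 = 1, df2 = n - 1,
       p = 2 * pt(-abs(tval), n - 1),
       eta_p = F / (F + (n - 1)))
}

# Small fully-valid handmade study: 2 participants, one task set each with
# a 3-trial preference phase and a 6-trial gambling phase (2 per pair).
toy_study <- function() {
  pt <- do.call(rbind, lapply(c("p1", "p2"), function(pid) {
    data.frame(participant_id = pid, task_set = 1L, block = 1L,
               trial_index = 1:3,
               left_stim = c("A", "A", "B"), right_stim = c("B", "C", "C"),
               chosen_stim = c("A", "A", "C"), stringsAsFactors = FALSE)
  }))
  gt <- do.call(rbind, lapply(c("p1", "p2"), function(pid) {
    data.frame(participant_id = pid, task_type = "pref_high_prob",
               pair_id = rep(c("high_pref_pair", "low_pref_pair",
                               "novel_pair"), each = 2),
               trial_index = c(1L, 4L, 2L, 5L, 3L, 6L),
               left_stim = rep(c("A", "B", "N3"), each = 2),
               right_stim = rep(c("N1", "N2", "N4"), each = 2),
               chosen_stim = c("A", "A", "N2", "B", "N3", "N4"),
               reward = c(1L, 1L, 1L, 0L, 1L, 0L),
               stringsAsFactors = FALSE)
  }))
  gt$trial_index <- ave(gt$trial_index, gt$participant_id,
                        FUN = function(x) rank(x))
  st <- do.call(rbind, lapply(c("p1", "p2"), function(pid) {
    data.frame(participant_id = pid, task_set = 1L,
               task_type = c(rep("pref_high_prob", 6), NA),
               stimulus_id = c("A", "N1", "B", "N2", "N3", "N4", "C"),
               role = c("pref_high", "novel_low", "pref_low", "novel_high",
                        "novel_high", "novel_low", "idm_only"),
               pair_id = c("high_pref_pair", "high_pref_pair",
                           "low_pref_pair", "low_pref_pair",
                           "novel_pair", "novel_pair", NA),
               reward_prob = c(0.7, 0.3, 0.3, 0.7, 0.7, 0.3, NA),
               stringsAsFactors = FALSE)
  }))
  rt <- do.call(rbind, lapply(c("p1", "p2"), function(pid) {
    data.frame(participant_id = pid, task_set = 1L,
               stimulus_id = c("A", "B", "N3", "N4"),
               rating = c(5L, 2L, 4L, 3L), stringsAsFactors = FALSE)
  }))
  rl_study(pt, gt, ratings = rt, stimuli = st)
}

light_control <- function(chains = 2, iter = 400, warmup = 300)
  sampler_control(chains = chains, iter = iter, warmup = warmup)

# One simulated participant (both gambling tasks) as a fitting unit.
simulate_unit_for_test <- function(model, params, trials_per_pair = 50)
  prefrl:::simulate_unit(model, params, edm_design(trials_per_pair))

# Independent recomputation of the chosen-frequency contrast from raw
# trials (base table arithmetic + stats::t.test).
independent_freq_contrast <- function(study) {
  st <- study$stimuli
  pt <- study$pref_trials
  pids <- sort(unique(st$participant_id))
  one <- function(pid, role) {
    rows <- st[st$participant_id == pid & st$role == role, ]
    mean(sapply(seq_len(nrow(rows)), function(i) {
      d <- pt[pt$participant_id == pid & pt$task_set == rows$task_set[i], ]
      sid <- rows$stimulus_id[i]
      pres <- sum(d$left_stim == sid | d$right_stim == sid)
      sum(d$chosen_stim == sid) / pres
    }))
  }
  hi <- sapply(pids, one, role = "pref_high")
  lo <- sapply(pids, one, role = "pref_low")
  tt <- t.test(hi, lo, paired = TRUE)
  list(t = unname(tt$statistic), d = mean(hi - lo) / sd(hi - lo))
}
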