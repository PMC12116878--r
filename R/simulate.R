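#' Preference-judgment trial schedule
#'
#' 105 trials from 7 stimuli in 5 blocks of 21: within each block every
#' unordered pair (choose(7, 2) = 21) appears exactly once in random order,
#' so each stimulus is presented 6 times per block, 30 times overall.
#' Left/right positions are randomized per trial.
#'
#' @param stim_ids Character vector of 7 stimulus ids.
#' @return Data frame `block, trial_index, left_stim, right_stim`.
#' @export
build_pref_schedule <- function(stim_ids) {
  stopifnot(length(stim_ids) == 7L, !anyDuplicated(stim_ids))
  pairs <- t(combn(stim_ids, 2L))
  blocks <- lapply(1:5, function(b) {
    ord <- sample.int(nrow(pairs))
    p <- pairs[ord, , drop = FALSE]
    flip <- runif(nrow(p)) < 0.5
    data.frame(block = b,
               left_stim = ifelse(flip, p[, 2], p[, 1]),
               right_stim = ifelse(flip, p[, 1], p[, 2]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, blocks)
  out$trial_index <- seq_len(nrow(out))
  out[c("block", "trial_index", "left_stim", "right_stim")]
}

#' Simulate one participant's preference-judgment choices
#'
#' Choices follow a logistic rule on latent preference strengths:
#' `P(left) = plogis(sensitivity * (v_left - v_right))`. With `delta > 0`
#' the latent preference of the chosen stimulus increases and the rejected
#' one decreases by `delta` after every trial (choice-induced preference
#' change as a generative option only).
#'
#' @param latent Named numeric vector of latent preference strengths.
#' @param schedule A schedule from [build_pref_schedule()].
#' @param sensitivity Logistic slope, `>= 0`.
#' @param delta Drift increment, `>= 0`; 0 disables drift.
#' @return The schedule with a `chosen_stim` column appended.
#' @export
simulate_idm_participant <- function(latent, schedule, sensitivity = 2,
                                     delta = 0) {
  stopifnot(sensitivity >= 0, delta >= 0)
  v <- latent
  n <- nrow(schedule)
  chosen <- character(n)
  u <- runif(n)
  for (t in seq_len(n)) {
    l <- schedule$left_stim[t]; r <- schedule$right_stim[t]
    p_left <- plogis(sensitivity * (v[l] - v[r]))
    ch <- if (u[t] < p_left) l else r
    chosen[t] <- ch
    if (delta > 0) {
      rej <- if (ch == l) r else l
      v[ch] <- v[ch] + delta
      v[rej] <- v[rej] - delta
    }
  }
  schedule$chosen_stim <- chosen
  schedule
}

#' Gambling-task schedule for one task
#'
#' Three fixed pairs, each presented `trials_per_pair` times in random
#' interleaved order, one member of each pair rewarded at 70% and the other
#' at 30%:
#'
#' * `high_pref_pair`: the most-chosen IDM stimulus against a previously
#'   unseen partner. Under `task_type = "pref_high_prob"` the preferred
#'   stimulus carries 0.70; under `"pref_low_prob"` it carries 0.30.
#' * `low_pref_pair`: the least-chosen IDM stimulus against a second unseen
#'   partner, with the reward assignment opposite to the preferred
#'   stimulus's.
#' * `novel_pair`: two unseen stimuli at 0.70 vs 0.30.
#'
#' @param task_type `"pref_high_prob"` or `"pref_low_prob"`.
#' @param pref_high,pref_low Ids of the IDM preference extremes (distinct).
#' @param novel_ids Four ids for the unseen stimuli: partner of the
#'   preferred stimulus, partner of the least-preferred stimulus, and the
#'   novel pair.
#' @param trials_per_pair Presentations per pair (default 50).
#' @param probs Reward probabilities `c(high, low)` (default 0.70/0.30).
#' @return List with `stimuli` (id, role, pair_id, reward_prob) and
#'   `trials` (task_type, pair_id, trial_index, left_stim, right_stim).
#' @export
build_gamble_schedule <- function(task_type, pref_high, pref_low, novel_ids,
                                  trials_per_pair = 50,
                                  probs = c(0.70, 0.30)) {
  task_type <- match.arg(task_type, TASK_TYPES)
  stopifnot(pref_high != pref_low, length(novel_ids) == 4L)
  p_hi <- probs[1]; p_lo <- probs[2]
  p_pref <- if (task_type == "pref_high_prob") p_hi else p_lo
  stimuli <- data.frame(
    stimulus_id = c(pref_high, novel_ids[1], pref_low, novel_ids[2],
                    novel_ids[3], novel_ids[4]),
    role = c("pref_high", NA, "pref_low", NA, "novel_high", "novel_low"),
    pair_id = rep(PAIR_IDS, each = 2),
    reward_prob = c(p_pref, p_hi + p_lo - p_pref,
                    p_hi + p_lo - p_pref, p_pref,
                    p_hi, p_lo),
    stringsAsFactors = FALSE
  )
  novel_role <- ifelse(stimuli$reward_prob >= 0.5, "novel_high", "novel_low")
  stimuli$role[is.na(stimuli$role)] <- novel_role[is.na(stimuli$role)]
  pair_seq <- sample(rep(PAIR_IDS, each = trials_per_pair))
  n <- length(pair_seq)
  flip <- runif(n) < 0.5
  first <- stimuli$stimulus_id[match(pair_seq, stimuli$pair_id)]
  second <- stimuli$stimulus_id[match(pair_seq, stimuli$pair_id) + 1L]
  trials <- data.frame(
    task_type = task_type,
    pair_id = pair_seq,
    trial_index = seq_len(n),
    left_stim = ifelse(flip, second, first),
    right_stim = ifelse(flip, first, second),
    stringsAsFactors = FALSE
  )
  list(stimuli = stimuli, trials = trials)
}

#' Default per-participant generating parameters
#'
#' The study-world defaults: learning rate drawn uniformly on
#' `[0.1, 0.6]`; inverse temperature fixed at 5.3, calibrated so that with
#' an initial-value gap of 0.3 the population first-trial choice rate of
#' the preferred stimulus is the reported 83% (`plogis(5.3 * 0.3) = 0.83`);
#' eta slots chosen per model so the high-preference slot exceeds the
#' others (RL2: 0.7 vs 0.4). All overridable.
#'
#' @param alpha_range Range of the uniform learning-rate draw.
#' @param beta Inverse temperature (fixed across participants).
#' @param etas Named list of default eta vectors per model, or `NULL` for
#'   the built-in table.
#' @return A function `f(model)` drawing one [rl_params()] from the current
#'   RNG stream.
#' @export
default_param_sampler <- function(alpha_range = c(0.1, 0.6), beta = 5.3,
                                  etas = NULL) {
  if (is.null(etas))
    etas <- list(RL1 = 0.4, RL2 = c(0.7, 0.4), RL3 = c(0.6, 0.2),
                 RL4 = c(0.7, 0.1, 0.4))
  function(model) {
    rl_params(alpha = runif(1, alpha_range[1], alpha_range[2]),
              beta = min(beta, model$beta_max),
              etas = etas[[model$name]], model = model)
  }
}

#' Study design constants
#'
#' Defaults mirror the experimental design: 42 participants, 7 IDM stimuli
#' presented 30 times each over 105 trials in 5 blocks, 3 gambling pairs
#' presented 50 times each at 70%/30% reward, two counterbalanced task
#' sets with disjoint stimuli. Generator-only knobs: the latent preference
#' spread (equally spaced on `[-spread, spread]`, permuted per set), the
#' IDM choice sensitivity, the choice-induced drift `delta`, and the
#' rating model `round(clip(intercept + a * z_latent +
#' b * (Q_final - 0.5) + noise, 1, 5))`.
#'
#' @param n_participants Number of participants (>= 2, even for exact
#'   counterbalancing).
#' @param trials_per_pair Gambling presentations per pair.
#' @param reward_probs `c(high, low)` Bernoulli reward probabilities.
#' @param latent_spread Half-range of the equally spaced latent
#'   preferences.
#' @param sensitivity IDM logistic sensitivity.
#' @param delta Choice-induced preference drift (0 = off).
#' @param rating Rating-model constants `a`, `b`, `intercept`, `sd`.
#' @return List of design constants.
#' @export
study_design <- function(n_participants = 42, trials_per_pair = 50,
                         reward_probs = c(0.70, 0.30), latent_spread = 9,
                         sensitivity = 2, delta = 0,
                         rating = list(a = 0.8, b = 2, intercept = 3, sd = 0.5)) {
  stopifnot(n_participants >= 2, trials_per_pair >= 1,
            all(reward_probs >= 0 & reward_probs <= 1), delta >= 0)
  list(n_participants = n_participants, trials_per_pair = trials_per_pair,
       reward_probs = reward_probs, latent_spread = latent_spread,
       sensitivity = sensitivity, delta = delta, rating = rating)
}

#' Generate a complete synthetic study
#'
#' Per participant: two task sets with disjoint stimulus namespaces, each
#' consisting of a 105-trial preference-judgment task on 7 stimuli, a
#' 150-trial gambling task (3 pairs x 50) simulated from the generating
#' RL model, and 5-point ratings of every stimulus used in the set. One
#' set runs the preferred-stimulus-high-probability gambling task and the
#' other the low-probability task; execution order alternates across
#' participants (counterbalanced). The preference extremes that anchor the
#' gambling pairs are taken from the simulated IDM chosen frequencies
#' (lexicographic tie-break), exactly as in the experimental procedure.
#'
#' @param n_participants Number of participants (overrides `design`).
#' @param generating_model An [rl_model()] used to simulate gambling
#'   choices.
#' @param param_sampler Function `f(model)` returning one [rl_params()];
#'   see [default_param_sampler()].
#' @param design Design constants from [study_design()].
#' @param seed Master seed; the study is fully reproducible from it.
#' @return An [rl_study()] with `truth` attached: generating model name,
#'   per-participant parameters, latents, intended extremes, set-to-task
#'   map and the seed.
#' @export
generate_study <- function(n_participants = NULL,
                           generating_model = rl_model("RL2"),
                           param_sampler = default_param_sampler(),
                           design = study_design(), seed = 1) {
  if (!is.null(n_participants)) design$n_participants <- n_participants
  n <- design$n_participants
  stopifnot(n >= 2)
  with_seed(seed, {
    pref <- list(); gamb <- list(); rate <- list(); stim <- list()
    truth_p <- vector("list", n)
    base_latents <- seq(-design$latent_spread, design$latent_spread,
                        length.out = 7)
    for (p in seq_len(n)) {
      pid <- sprintf("p%03d", p)
      set_types <- if (p %% 2 == 1) TASK_TYPES else rev(TASK_TYPES)
      params <- param_sampler(generating_model)
      tp <- list(params = list(alpha = params$alpha, beta = params$beta,
                               etas = params$etas),
                 sets = list())
      for (s in 1:2) {
        task_type <- set_types[s]
        idm_ids <- sprintf("%s_s%d_i%02d", pid, s, 1:7)
        nov_ids <- sprintf("%s_s%d_n%02d", pid, s, 1:4)
        latent <- setNames(sample(base_latents), idm_ids)
        sched <- build_pref_schedule(idm_ids)
        idm <- simulate_idm_participant(latent, sched, design$sensitivity,
                                        design$delta)
        idm$participant_id <- pid
        idm$task_set <- s
        pref[[length(pref) + 1L]] <-
          idm[c("participant_id", "task_set", "block", "trial_index",
                "left_stim", "right_stim", "chosen_stim")]
        freqs <- chosen_frequency(idm)
        ext <- label_preference_extremes(setNames(freqs$freq, freqs$stimulus_id),
                                         tie_break = "lexicographic")
        gs <- build_gamble_schedule(task_type, ext["pref_high"], ext["pref_low"],
                                    nov_ids, design$trials_per_pair,
                                    design$reward_probs)
        sess <- simulate_session(generating_model, params, gs)
        sess$participant_id <- pid
        gamb[[length(gamb) + 1L]] <-
          sess[c("participant_id", "task_type", "pair_id", "trial_index",
                 "left_stim", "right_stim", "chosen_stim", "reward")]
        st <- gs$stimuli
        idm_only <- setdiff(idm_ids, st$stimulus_id)
        st <- rbind(st, data.frame(stimulus_id = idm_only, role = "idm_only",
                                   pair_id = NA_character_,
                                   reward_prob = NA_real_,
                                   stringsAsFactors = FALSE))
        st$participant_id <- pid
        st$task_set <- s
        st$task_type <- ifelse(st$role == "idm_only", NA_character_, task_type)
        stim[[length(stim) + 1L]] <-
          st[c("participant_id", "task_set", "task_type", "stimulus_id",
               "role", "pair_id", "reward_prob")]
        rate[[length(rate) + 1L]] <-
          simulate_ratings(pid, s, st, latent, generating_model, params,
                           sess, design$rating)
        tp$sets[[s]] <- list(task_type = task_type, latent = as.list(latent),
                             intended_high = names(latent)[which.max(latent)],
                             intended_low = names(latent)[which.min(latent)],
                             labelled_high = unname(ext["pref_high"]),
                             labelled_low = unname(ext["pref_low"]))
      }
      truth_p[[p]] <- tp
      names(truth_p)[p] <- pid
    }
    truth <- list(generating_model = generating_model$name,
                  seed = seed,
                  design = design[c("n_participants", "trials_per_pair",
                                    "reward_probs", "latent_spread",
                                    "sensitivity", "delta")],
                  participants = truth_p)
    rl_study(do.call(rbind, pref), do.call(rbind, gamb),
             ratings = do.call(rbind, rate), stimuli = do.call(rbind, stim),
             truth = truth, design = design)
  })
}

# Ratings: monotone noisy transform of latent preference (z-scored within
# the 7 IDM stimuli; 0 for stimuli first seen in the gambling task) plus a
# learned-value contribution from the final Q under the generating truth.
simulate_ratings <- function(pid, task_set, stim_tbl, latent, model, params,
                             session, rating) {
  roles <- setNames(stim_tbl$role, stim_tbl$stimulus_id)
  edm <- stim_tbl$stimulus_id[stim_tbl$role != "idm_only"]
  traj <- q_trajectory(model, params, session, roles[edm])
  qfin <- vapply(edm, function(id) {
    qs <- traj$q_value[traj$stimulus_id == id]
    qs[length(qs)]
  }, numeric(1))
  z <- setNames(rep(0, nrow(stim_tbl)), stim_tbl$stimulus_id)
  z[names(latent)] <- as.numeric(scale(latent))
  mu <- rating$intercept + rating$a * z
  mu[edm] <- mu[edm] + rating$b * (qfin - 0.5)
  raw <- mu + rnorm(length(mu), 0, rating$sd)
  data.frame(participant_id = pid, task_set = task_set,
             stimulus_id = names(z),
             rating = as.integer(pmin(5, pmax(1, round(raw)))),
             stringsAsFactors = FALSE)
}
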