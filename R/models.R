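#' Reinforcement-learning model specifications
#'
#' The four candidate models share the same delta-rule value update and
#' softmax choice rule and differ only in how the free initial-value
#' parameters (the eta slots) are assigned to stimulus classes in the
#' gambling task:
#'
#' * `RL1`: one slot; high-preference, low-preference and novel stimuli all
#'   start at the same `eta`.
#' * `RL2`: two slots; the high-preference stimulus starts at `eta1`, every
#'   other stimulus at `eta2`.
#' * `RL3`: two slots; the low-preference stimulus starts at `eta2`,
#'   high-preference and novel stimuli share `eta1`.
#' * `RL4`: three slots; high-preference (`eta1`), low-preference (`eta2`)
#'   and novel (`eta3`) stimuli all start at distinct free values.
#'
#' Stimulus roles `novel_high` and `novel_low` (novel stimuli with high and
#' low reward probability) always share the "novel" slot; `idm_only` stimuli
#' never enter the gambling task and have no slot.
#'
#' @param name Model name, one of `"RL1"`, `"RL2"`, `"RL3"`, `"RL4"`.
#' @param beta_max Upper bound of the inverse temperature. The design
#'   document prints the bound as 1; the package default is the conventional
#'   10 (see the methods vignette), and either bound can be requested here.
#' @return An object of class `rl_model`: name, role-to-slot map, number of
#'   eta slots, parameter bounds.
#' @examples
#' m <- rl_model("RL2")
#' m$slots
#' @export
rl_model <- function(name = c("RL1", "RL2", "RL3", "RL4"), beta_max = 10) {
  name <- match.arg(name)
  stopifnot(is.numeric(beta_max), length(beta_max) == 1L, beta_max > 0)
  slots <- switch(name,
    RL1 = c(pref_high = 1L, pref_low = 1L, novel = 1L),
    RL2 = c(pref_high = 1L, pref_low = 2L, novel = 2L),
    RL3 = c(pref_high = 1L, pref_low = 2L, novel = 1L),
    RL4 = c(pref_high = 1L, pref_low = 2L, novel = 3L)
  )
  n_eta <- max(slots)
  par_names <- c("alpha", "beta", if (n_eta == 1L) "eta" else paste0("eta", seq_len(n_eta)))
  structure(
    list(name = name, slots = slots, n_eta = n_eta,
         beta_max = beta_max, par_names = par_names,
         lower = c(0, 0, rep(0, n_eta)),
         upper = c(1, beta_max, rep(1, n_eta))),
    class = "rl_model"
  )
}

#' @export
print.rl_model <- function(x, ...) {
  cat("Q-learning model", x$name, "(", x$n_eta, "initial-value slot(s) )\n")
  cat("  role -> slot:", paste(names(x$slots), x$slots, sep = "=", collapse = ", "), "\n")
  cat("  bounds: alpha [0,1], beta [0,", x$beta_max, "], eta [0,1]\n", sep = "")
  invisible(x)
}

#' Parameter set for an RL model
#'
#' Validates bounds at construction: `alpha` and every eta in `[0, 1]`,
#' `beta` in `[0, beta_max]` of the model.
#'
#' @param alpha Learning rate.
#' @param beta Softmax inverse temperature.
#' @param etas Numeric vector of initial values, one per slot of `model`.
#' @param model An [rl_model()].
#' @return Object of class `rl_params`.
#' @export
rl_params <- function(alpha, beta, etas, model) {
  stopifnot(inherits(model, "rl_model"))
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha < 0 || alpha > 1)
    stop("alpha must be a single value in [0, 1]", call. = FALSE)
  if (!is.numeric(beta) || length(beta) != 1L || is.na(beta) || beta < 0 || beta > model$beta_max)
    stop("beta must be a single value in [0, ", model$beta_max, "]", call. = FALSE)
  etas <- as.numeric(etas)
  if (length(etas) != model$n_eta)
    stop("model ", model$name, " needs ", model$n_eta, " eta value(s), got ",
         length(etas), call. = FALSE)
  if (any(is.na(etas)) || any(etas < 0) || any(etas > 1))
    stop("all etas must lie in [0, 1]", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, etas = etas, model = model$name),
            class = "rl_params")
}

#' @export
print.rl_params <- function(x, ...) {
  cat("rl_params (", x$model, "): alpha=", signif(x$alpha, 4),
      " beta=", signif(x$beta, 4),
      " etas=", paste(signif(x$etas, 4), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Parameter vector <-> rl_params (vector order: alpha, beta, eta...)
params_to_vec <- function(params) c(params$alpha, params$beta, params$etas)

vec_to_params <- function(x, model) {
  rl_params(alpha = x[1], beta = x[2], etas = x[-(1:2)], model = model)
}

# Map stimulus roles onto eta-slot indices for a model.
role_slot <- function(model, roles) {
  key <- ifelse(roles %in% c("novel_high", "novel_low"), "novel", roles)
  bad <- setdiff(unique(key), names(model$slots))
  if (length(bad) > 0)
    stop("no initial-value slot for role(s): ", paste(bad, collapse = ", "),
         " (idm_only stimuli cannot enter the gambling task)", call. = FALSE)
  unname(model$slots[key])
}

#' Initial Q values for a set of stimuli
#'
#' Each stimulus starts at the eta value of the slot its role maps to under
#' the model's initial-value scheme; the trial counter starts at zero.
#'
#' @param model An [rl_model()].
#' @param params An [rl_params()] for that model.
#' @param roles Character vector of stimulus roles (`pref_high`, `pref_low`,
#'   `novel_high`, `novel_low`), named by stimulus id.
#' @return Named numeric vector of initial values.
#' @examples
#' m <- rl_model("RL2")
#' p <- rl_params(0.3, 2, c(0.8, 0.5), m)
#' init_values(m, p, c(A = "pref_high", B = "novel_low"))
#' @export
init_values <- function(model, params, roles) {
  stopifnot(inherits(model, "rl_model"), inherits(params, "rl_params"))
  if (params$model != model$name)
    stop("params were built for model ", params$model, ", not ", model$name,
         call. = FALSE)
  q0 <- params$etas[role_slot(model, roles)]
  names(q0) <- names(roles)
  q0
}

#' Delta-rule value update
#'
#' Returns `q + alpha * (reward - q)` for the chosen option; the caller
#' leaves rejected options untouched. With rewards in \{0, 1\} and
#' `q` in `[0, 1]` the result stays in `[0, 1]` (convex combination).
#'
#' @param q Current value(s) in `[0, 1]`.
#' @param reward Observed reward(s), 0 or 1.
#' @param alpha Learning rate in `[0, 1]`.
#' @export
update_q <- function(q, reward, alpha) {
  if (any(q < 0 | q > 1)) stop("q must lie in [0, 1]", call. = FALSE)
  if (!all(reward %in% c(0, 1))) stop("reward must be 0 or 1", call. = FALSE)
  if (any(alpha < 0 | alpha > 1)) stop("alpha must lie in [0, 1]", call. = FALSE)
  q + alpha * (reward - q)
}

#' Softmax probability of the chosen option
#'
#' `1 / (1 + exp(-beta * (q_chosen - q_rejected)))`, computed through
#' [stats::plogis()] for numerical stability.
#'
#' @param q_chosen,q_rejected Values of the chosen and rejected options.
#' @param beta Inverse temperature, `>= 0`.
#' @export
choice_prob <- function(q_chosen, q_rejected, beta) {
  if (any(!is.finite(q_chosen)) || any(!is.finite(q_rejected)) || any(!is.finite(beta)))
    stop("choice_prob needs finite inputs", call. = FALSE)
  if (any(beta < 0)) stop("beta must be >= 0", call. = FALSE)
  plogis(beta * (q_chosen - q_rejected))
}

# ---------------------------------------------------------------------------
# Session encoding: gambling trials for one participant, ordered by
# (task_type, trial_index), as integer index triplets into a stimulus table.
# Values are shared across the interleaved pairs of a task and never cross
# tasks (disjoint stimuli), so one pass over the ordered trials suffices.
encode_session <- function(trials, stim_roles) {
  stopifnot(is.data.frame(trials))
  ord <- order(trials$task_type, trials$trial_index)
  trials <- trials[ord, , drop = FALSE]
  ids <- names(stim_roles)
  li <- match(trials$left_stim, ids)
  ri <- match(trials$right_stim, ids)
  if (anyNA(li) || anyNA(ri))
    stop("trial references a stimulus absent from the stimulus table: ",
         paste(unique(c(trials$left_stim[is.na(li)], trials$right_stim[is.na(ri)])),
               collapse = ", "), call. = FALSE)
  chose_left <- trials$chosen_stim == trials$left_stim
  list(
    chosen = ifelse(chose_left, li, ri),
    other = ifelse(chose_left, ri, li),
    reward = as.integer(trials$reward),
    roles = stim_roles,
    ids = ids,
    n = nrow(trials),
    trials = trials
  )
}

#' Session log-likelihood of a gambling dataset under an RL model
#'
#' Composes the delta-rule update and softmax choice rule over an ordered
#' trial sequence: the probability of each recorded choice is evaluated at
#' the current values, then only the chosen stimulus's value is updated with
#' the observed reward. Trials are ordered by `(task_type, trial_index)`;
#' stimuli of the two gambling tasks are disjoint, so values never leak
#' across tasks.
#'
#' @param model An [rl_model()].
#' @param params An [rl_params()].
#' @param trials Data frame of gambling trials for one participant
#'   (columns `task_type`, `trial_index`, `left_stim`, `right_stim`,
#'   `chosen_stim`, `reward`).
#' @param roles Named character vector mapping each stimulus id appearing in
#'   `trials` to its role.
#' @return Total log-likelihood (a single number).
#' @export
session_loglik <- function(model, params, trials, roles) {
  enc <- encode_session(trials, roles)
  session_loglik_enc(model, params, enc)
}

# Fast path used by the samplers: pre-encoded session, raw parameter vector.
session_loglik_enc <- function(model, params, enc) {
  q0 <- params$etas[role_slot(model, enc$roles)]
  cpp_session_loglik(enc$chosen, enc$other, enc$reward, q0,
                     params$alpha, params$beta)
}

# Same, for x = c(alpha, beta, etas) and a precomputed slot index vector.
loglik_vec <- function(x, enc, slot_idx) {
  cpp_session_loglik(enc$chosen, enc$other, enc$reward,
                     x[-(1:2)][slot_idx], x[1], x[2])
}

#' Q-value trajectories over a gambling session
#'
#' Replays the delta rule over the recorded trials and returns, per
#' stimulus, the value before the first trial of its pair (the initial
#' value, from [init_values()]) and after every subsequent presentation of
#' its pair. A stimulus that is never chosen keeps a flat series at its
#' initial value.
#'
#' @inheritParams session_loglik
#' @return Data frame with columns `task_type`, `pair_id`, `stimulus_id`,
#'   `role`, `step` (0 = before the pair's first trial), `q_value`.
#'   `step` runs to the number of presentations of that stimulus's pair.
#' @export
q_trajectory <- function(model, params, trials, roles) {
  enc <- encode_session(trials, roles)
  q0 <- params$etas[role_slot(model, enc$roles)]
  path <- cpp_q_path(enc$chosen, enc$reward, q0, params$alpha)
  tr <- enc$trials
  out <- vector("list", length(enc$ids))
  for (j in seq_along(enc$ids)) {
    id <- enc$ids[j]
    rows <- which(tr$left_stim == id | tr$right_stim == id)
    if (length(rows) == 0) next
    out[[j]] <- data.frame(
      task_type = tr$task_type[rows[1]],
      pair_id = if ("pair_id" %in% names(tr)) tr$pair_id[rows[1]] else NA_character_,
      stimulus_id = id,
      role = unname(enc$roles[j]),
      step = 0:length(rows),
      q_value = c(q0[j], path[rows, j]),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' Simulate a gambling session from an RL model
#'
#' Generative direction of the model: on each scheduled trial the choice is
#' drawn from the softmax probability at the current values, the reward of
#' each stimulus is an independent Bernoulli draw at its reward probability
#' (the unchosen stimulus's counterfactual draw is made but never revealed),
#' and only the chosen stimulus's value is updated.
#'
#' @param model An [rl_model()].
#' @param params An [rl_params()].
#' @param schedule A gamble schedule from [build_gamble_schedule()], or a
#'   list with elements `trials` (data frame: `task_type`, `pair_id`,
#'   `trial_index`, `left_stim`, `right_stim`) and `stimuli` (data frame:
#'   `stimulus_id`, `role`, `reward_prob`).
#' @return Data frame of simulated trials with `chosen_stim` and `reward`
#'   columns appended. Reproducible from the RNG state (seed upstream).
#' @export
simulate_session <- function(model, params, schedule) {
  st <- schedule$stimuli
  tr <- schedule$trials
  roles <- setNames(st$role, st$stimulus_id)
  q0 <- params$etas[role_slot(model, roles)]
  li <- match(tr$left_stim, st$stimulus_id)
  ri <- match(tr$right_stim, st$stimulus_id)
  n <- nrow(tr)
  rew_left <- rbinom(n, 1L, st$reward_prob[li])
  rew_right <- rbinom(n, 1L, st$reward_prob[ri])
  u <- runif(n)
  sim <- cpp_simulate_choices(li, ri, rew_left, rew_right, q0,
                              params$alpha, params$beta, u)
  tr$chosen_stim <- ifelse(sim$choose_left == 1L, tr$left_stim, tr$right_stim)
  tr$reward <- sim$reward
  tr
}
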