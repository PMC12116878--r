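#' Prior specification over an RL model's parameter box
#'
#' Uniform by default over the stated bounds (`alpha`, eta in `[0, 1]`,
#' `beta` in `[0, beta_max]`); only bounds are reported for the parameters, so
#' the uniform is the reference prior. A custom log-density over the same
#' box may be supplied.
#'
#' @param model An [rl_model()].
#' @param log_density Optional function of the parameter vector returning a
#'   log prior density over the box; `NULL` means uniform.
#' @return Object of class `prior_spec` with `lower`, `upper`, `log_d`.
#' @export
rl_prior <- function(model, log_density = NULL) {
  stopifnot(inherits(model, "rl_model"))
  lower <- model$lower
  upper <- model$upper
  const <- -sum(log(upper - lower))
  log_d <- if (is.null(log_density)) {
    function(x) {
      if (any(x < lower) || any(x > upper)) -Inf else const
    }
  } else {
    function(x) {
      if (any(x < lower) || any(x > upper)) -Inf else log_density(x)
    }
  }
  structure(list(lower = lower, upper = upper, log_d = log_d,
                 par_names = model$par_names),
            class = "prior_spec")
}

#' Tempered log posterior at a parameter point
#'
#' `tau * sum(session log-likelihoods) + log prior`; `tau = 1` is the
#' ordinary posterior and `tau = 1/log(n)` the WBIC temperature.
#' Parameters outside the prior support return `-Inf` (rejected by
#' contract, not an error).
#'
#' @param model An [rl_model()].
#' @param params An [rl_params()] or a bare parameter vector
#'   `c(alpha, beta, etas)`.
#' @param data A list of per-participant gambling data, each element a list
#'   with `trials` and `roles` (as for [session_loglik()]), or a single
#'   such element.
#' @param prior An [rl_prior()].
#' @param tau Sampling temperature, `> 0`.
#' @return Log tempered posterior, with the total untempered log-likelihood
#'   attached as attribute `"loglik"`.
#' @export
log_tempered_posterior <- function(model, params, data, prior, tau = 1) {
  stopifnot(tau > 0)
  x <- if (inherits(params, "rl_params")) params_to_vec(params) else params
  lpr <- prior$log_d(x)
  if (!is.finite(lpr)) return(structure(-Inf, loglik = -Inf))
  if (!is.null(data$trials)) data <- list(data)
  p <- vec_to_params(x, model)
  ll <- sum(vapply(data, function(u)
    session_loglik(model, p, u$trials, u$roles), numeric(1)))
  structure(tau * ll + lpr, loglik = ll)
}

#' Draws from the tempered posterior of one fitting unit
#'
#' Runs the random-walk Metropolis sampler on `tau * log-likelihood +
#' log prior` for one fitting unit (by default one participant's two
#' gambling tasks with shared parameters).
#'
#' @inheritParams log_tempered_posterior
#' @param unit A list with `trials` and `roles` for the fitting unit.
#' @param control A [sampler_control()].
#' @param seed Integer seed.
#' @return A `posterior_draws` object (see [mh_sample()]) with parameter
#'   names attached.
#' @export
sample_posterior <- function(model, unit, prior = rl_prior(model), tau = 1,
                             control = sampler_control(), seed = 1) {
  enc <- encode_session(unit$trials, unit$roles)
  slot_idx <- role_slot(model, enc$roles)
  log_post <- function(x) {
    ll <- loglik_vec(x, enc, slot_idx)
    structure(tau * ll + prior$log_d(x), loglik = ll)
  }
  out <- mh_sample(log_post, prior$lower, prior$upper, control, seed)
  colnames(out$draws) <- model$par_names
  out$tau <- tau
  out$model <- model$name
  out$n_trials <- enc$n
  out
}

#' WBIC of one fitting unit
#'
#' The widely applicable Bayesian information criterion: the posterior
#' expectation of the negative total log-likelihood under the posterior
#' tempered at `tau = 1/log(n)`, with `n` the number of trials entering
#' the unit's likelihood. Computed from a single tempered MCMC run; lower
#' is better, and WBIC approximates the negative log marginal likelihood.
#'
#' @inheritParams sample_posterior
#' @return WBIC value with attributes `mcse` (Monte-Carlo standard error,
#'   treating draws as independent), `n`, `flagged`.
#' @export
wbic_unit <- function(model, unit, prior = rl_prior(model),
                      control = sampler_control(), seed = 1) {
  enc <- encode_session(unit$trials, unit$roles)
  n <- enc$n
  if (n < 2) stop("WBIC needs n >= 2 trials (temperature 1/log n)", call. = FALSE)
  ps <- sample_posterior(model, unit, prior, tau = 1 / log(n), control, seed)
  w <- mean(-ps$loglik)
  structure(w, mcse = sd(-ps$loglik) / sqrt(length(ps$loglik)),
            n = n, flagged = ps$flagged)
}

#' WBIC for an arbitrary model via tempered MCMC
#'
#' Generic form used for cross-checks against closed-form or quadrature
#' marginal likelihoods: supply any log-likelihood function over a box
#' with a uniform prior.
#'
#' @param loglik_fn Function of the parameter vector returning the total
#'   log-likelihood of the data.
#' @param lower,upper Prior box.
#' @param n Number of observations entering `loglik_fn` (sets the
#'   temperature `1/log(n)`).
#' @param control,seed As in [mh_sample()].
#' @return WBIC value with attribute `mcse`.
#' @export
wbic_mcmc <- function(loglik_fn, lower, upper, n,
                      control = sampler_control(), seed = 1) {
  stopifnot(n >= 2)
  tau <- 1 / log(n)
  const <- -sum(log(upper - lower))
  log_post <- function(x) {
    ll <- loglik_fn(x)
    structure(tau * ll + const, loglik = ll)
  }
  ps <- mh_sample(log_post, lower, upper, control, seed)
  structure(mean(-ps$loglik),
            mcse = sd(-ps$loglik) / sqrt(length(ps$loglik)),
            flagged = ps$flagged)
}

#' Bayes factor from two WBIC values
#'
#' WBIC approximates the negative log marginal likelihood, so
#' `BF_ab = exp(wbic_b - wbic_a)`. The Kass-Raftery category is attached:
#' 1-3 unimportant, 3-20 positive, 20-150 strong, over 150 very strong.
#' A Bayes factor below 1 is reported as the reciprocal in favour of the
#' second model.
#'
#' @param wbic_a,wbic_b WBIC of models a and b.
#' @return List with `bf` (as defined, possibly < 1), `bf_reported`
#'   (the >= 1 reciprocal form), `favoured` (`"a"` or `"b"`), `label`.
#' @export
bayes_factor <- function(wbic_a, wbic_b) {
  stopifnot(is.finite(wbic_a), is.finite(wbic_b))
  log_bf <- wbic_b - wbic_a
  favoured <- if (log_bf >= 0) "a" else "b"
  bf_rep <- exp(abs(log_bf))
  list(bf = exp(log_bf), bf_reported = bf_rep, favoured = favoured,
       label = kass_raftery_label(bf_rep))
}

#' @rdname bayes_factor
#' @param bf A Bayes factor `>= 1`.
#' @export
kass_raftery_label <- function(bf) {
  stopifnot(bf >= 1)
  if (bf < 3) "unimportant"
  else if (bf < 20) "positive"
  else if (bf < 150) "strong"
  else "very strong"
}

# Per-participant fitting units from a study: trials + roles of the
# stimuli entering the gambling task.
fit_units <- function(study) {
  stopifnot(inherits(study, "rl_study"))
  st <- study$stimuli[study$stimuli$role != "idm_only", , drop = FALSE]
  pids <- unique(study$gamble_trials$participant_id)
  units <- lapply(pids, function(pid) {
    trials <- study$gamble_trials[study$gamble_trials$participant_id == pid, ,
                                  drop = FALSE]
    sp <- st[st$participant_id == pid, , drop = FALSE]
    list(participant_id = pid, trials = trials,
         roles = setNames(sp$role, sp$stimulus_id))
  })
  names(units) <- pids
  units
}

#' Fit an RL model to a study by tempered-posterior MCMC
#'
#' The central fitting function. By default each participant is fitted
#' separately (both gambling tasks jointly, shared `alpha`, `beta` and eta
#' slots; values never cross tasks because their stimuli are disjoint) and
#' point estimates are posterior means at `tau = 1`. With `pool = TRUE` a
#' single parameter set is fitted to all participants at once.
#'
#' @param study An [rl_study()], or a single fitting unit (list with
#'   `trials` and `roles`).
#' @param model An [rl_model()] or a model name.
#' @param prior An [rl_prior()]; defaults to uniform over the bounds.
#' @param control A [sampler_control()].
#' @param seed Master seed; per-participant seeds are derived from it.
#' @param pool Fit one parameter set to all participants jointly?
#' @param keep_draws Keep the full posterior draws per participant?
#' @return Object of class `rl_fit` with methods [coef()], [summary()],
#'   [logLik()], [predict()], [residuals()], [simulate()], [plot()],
#'   [q_trajectories()] and [value_table()].
#' @examples
#' \donttest{
#' study <- generate_study(n_participants = 2, seed = 7)
#' fit <- rl_fit(study, "RL2", control = sampler_control(2, 300, 200), seed = 7)
#' coef(fit)
#' }
#' @export
rl_fit <- function(study, model = "RL2", prior = NULL,
                   control = sampler_control(), seed = 1, pool = FALSE,
                   keep_draws = TRUE) {
  if (is.character(model)) model <- rl_model(model)
  if (is.null(prior)) prior <- rl_prior(model)
  units <- if (inherits(study, "rl_study")) fit_units(study)
           else list(unit = study)
  if (pool) {
    pooled <- list(
      participant_id = "pooled",
      trials = do.call(rbind, lapply(units, `[[`, "trials")),
      roles = do.call(c, unname(lapply(units, `[[`, "roles")))
    )
    units <- list(pooled = pooled)
  }
  seeds <- spawn_seeds(seed, length(units))
  per <- vector("list", length(units))
  for (i in seq_along(units)) {
    ps <- sample_posterior(model, units[[i]], prior, tau = 1, control,
                           seed = seeds[i])
    est <- colMeans(ps$draws)
    per[[i]] <- list(
      participant_id = units[[i]]$participant_id,
      estimate = est,
      post_sd = apply(ps$draws, 2, sd),
      rhat = ps$rhat,
      accept_rate = mean(ps$accept_rate),
      flagged = ps$flagged,
      loglik_at_mean = session_loglik_enc(
        model, vec_to_params(est, model),
        encode_session(units[[i]]$trials, units[[i]]$roles)),
      draws = if (keep_draws) ps$draws else NULL
    )
  }
  names(per) <- names(units)
  structure(list(model = model, prior = prior, control = control,
                 seed = seed, pool = pool, units = units, per = per),
            class = "rl_fit")
}

#' @export
print.rl_fit <- function(x, ...) {
  cm <- coef(x)
  cat("rl_fit:", x$model$name, "fitted to", nrow(cm),
      if (x$pool) "pooled unit(s)" else "participant(s)", "\n")
  cat("  posterior-mean parameters (averaged over units):\n")
  print(round(colMeans(cm), 4))
  fl <- vapply(x$per, `[[`, logical(1), "flagged")
  if (any(fl)) cat("  convergence flagged for:",
                   paste(names(x$per)[fl], collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.rl_fit <- function(object, ...) {
  m <- do.call(rbind, lapply(object$per, `[[`, "estimate"))
  rownames(m) <- names(object$per)
  m
}

#' @export
logLik.rl_fit <- function(object, ...) {
  ll <- sum(vapply(object$per, `[[`, numeric(1), "loglik_at_mean"))
  n <- sum(vapply(object$units, function(u) nrow(u$trials), numeric(1)))
  structure(ll, df = length(object$model$par_names) * length(object$per),
            nobs = n, class = "logLik")
}

#' @export
summary.rl_fit <- function(object, ...) {
  cm <- coef(object)
  sdm <- do.call(rbind, lapply(object$per, `[[`, "post_sd"))
  rh <- do.call(rbind, lapply(object$per, `[[`, "rhat"))
  tab <- data.frame(
    parameter = colnames(cm),
    mean = colMeans(cm),
    sd_across_units = apply(cm, 2, sd),
    mean_post_sd = colMeans(sdm),
    max_rhat = apply(rh, 2, max),
    row.names = NULL
  )
  out <- list(model = object$model$name, n_units = nrow(cm), table = tab,
              flagged = names(object$per)[
                vapply(object$per, `[[`, logical(1), "flagged")])
  class(out) <- "summary.rl_fit"
  out
}

#' @export
print.summary.rl_fit <- function(x, ...) {
  cat("Model", x$model, "--", x$n_units, "fitting unit(s)\n")
  print(x$table, digits = 4)
  if (length(x$flagged) > 0)
    cat("convergence flagged:", paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}

#' @export
predict.rl_fit <- function(object, type = c("chosen", "left"), ...) {
  type <- match.arg(type)
  out <- lapply(names(object$per), function(pid) {
    unit <- object$units[[pid]]
    p <- vec_to_params(object$per[[pid]]$estimate, object$model)
    enc <- encode_session(unit$trials, unit$roles)
    q0 <- p$etas[role_slot(object$model, enc$roles)]
    path <- cpp_q_path(enc$chosen, enc$reward, q0, p$alpha)
    nb <- nrow(path)
    q_before <- rbind(q0, path)[seq_len(nb), , drop = FALSE]
    qc <- q_before[cbind(seq_len(nb), enc$chosen)]
    qo <- q_before[cbind(seq_len(nb), enc$other)]
    pr_chosen <- plogis(p$beta * (qc - qo))
    tr <- enc$trials
    tr$p_chosen <- pr_chosen
    chose_left <- tr$chosen_stim == tr$left_stim
    tr$p_left <- ifelse(chose_left, pr_chosen, 1 - pr_chosen)
    tr
  })
  res <- do.call(rbind, out)
  if (type == "chosen") res$fitted <- res$p_chosen else res$fitted <- res$p_left
  res
}

#' @export
residuals.rl_fit <- function(object, ...) {
  pr <- predict(object, type = "left")
  as.numeric(pr$chosen_stim == pr$left_stim) - pr$p_left
}

#' @export
simulate.rl_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  reps <- lapply(seq_len(nsim), function(r) {
    sims <- lapply(names(object$per), function(pid) {
      unit <- object$units[[pid]]
      p <- vec_to_params(object$per[[pid]]$estimate, object$model)
      st <- data.frame(stimulus_id = names(unit$roles),
                       role = unname(unit$roles),
                       stringsAsFactors = FALSE)
      # reward probabilities: 0.7 for *_high-prob roles under the task map
      out <- lapply(split(unit$trials, unit$trials$task_type), function(tr) {
        ids <- unique(c(tr$left_stim, tr$right_stim))
        sti <- st[st$stimulus_id %in% ids, , drop = FALSE]
        sti$reward_prob <- role_reward_prob(sti$role, tr$task_type[1])
        sim <- simulate_session(object$model, p,
                                list(stimuli = sti, trials = tr[
                                  c("task_type", "pair_id", "trial_index",
                                    "left_stim", "right_stim")]))
        sim$participant_id <- pid
        sim
      })
      do.call(rbind, out)
    })
    do.call(rbind, sims)
  })
  if (nsim == 1) reps[[1]] else reps
}

# Reward probability implied by a role within a task.
role_reward_prob <- function(role, task_type, probs = c(0.70, 0.30)) {
  p_pref <- if (task_type == "pref_high_prob") probs[1] else probs[2]
  ifelse(role == "pref_high", p_pref,
    ifelse(role == "pref_low", probs[1] + probs[2] - p_pref,
      ifelse(role == "novel_high", probs[1], probs[2])))
}

#' Q-value trajectories of a fitted model
#'
#' Replays each participant's recorded gambling trials under the
#' posterior-mean parameters and returns the per-stimulus value series
#' (step 0 is the initial value).
#'
#' @param fit An [rl_fit()].
#' @return Data frame `participant_id, task_type, pair_id, stimulus_id,
#'   role, step, q_value`.
#' @export
q_trajectories <- function(fit) {
  stopifnot(inherits(fit, "rl_fit"))
  out <- lapply(names(fit$per), function(pid) {
    unit <- fit$units[[pid]]
    p <- vec_to_params(fit$per[[pid]]$estimate, fit$model)
    tr <- q_trajectory(fit$model, p, unit$trials, unit$roles)
    tr$participant_id <- pid
    tr[c("participant_id", setdiff(names(tr), "participant_id"))]
  })
  do.call(rbind, out)
}

#' Initial and final fitted values per stimulus
#'
#' Convenience layout for the three-factor value analysis: one row per
#' participant, gambling task and stimulus, with the fitted initial and
#' final values, the stimulus class (IDM vs novel) and its reward
#' probability class. Novel cells use the novel pair (the IDM-anchored
#' pairs' unseen partners are excluded so the design is a clean 2 x 2).
#'
#' @param fit An [rl_fit()].
#' @return Data frame `participant_id, task_type, stim_type, prob,
#'   stimulus_id, initial, final`.
#' @export
value_table <- function(fit) {
  traj <- q_trajectories(fit)
  keep <- traj$role %in% c("pref_high", "pref_low") |
    (traj$pair_id == "novel_pair" & !is.na(traj$pair_id))
  traj <- traj[keep, , drop = FALSE]
  key <- paste(traj$participant_id, traj$task_type, traj$stimulus_id)
  out <- do.call(rbind, lapply(split(traj, key), function(d) {
    d <- d[order(d$step), ]
    role <- d$role[1]
    task <- d$task_type[1]
    prob <- role_reward_prob(role, task)
    data.frame(participant_id = d$participant_id[1], task_type = task,
               stim_type = if (role %in% c("pref_high", "pref_low")) "idm" else "novel",
               prob = if (prob >= 0.5) "high" else "low",
               stimulus_id = d$stimulus_id[1],
               initial = d$q_value[1], final = d$q_value[nrow(d)],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' @export
plot.rl_fit <- function(x, ...) {
  traj <- q_trajectories(x)
  keep <- traj$role %in% c("pref_high", "pref_low") |
    (!is.na(traj$pair_id) & traj$pair_id == "novel_pair")
  traj <- traj[keep, , drop = FALSE]
  traj$line <- paste(traj$role, ifelse(traj$role %in% c("pref_high", "pref_low"),
                                       "idm", "novel"))
  old <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(old))
  for (tt in sort(unique(traj$task_type))) {
    d <- traj[traj$task_type == tt, ]
    agg <- stats::aggregate(q_value ~ role + step, data = d, FUN = mean)
    plot(NULL, xlim = range(agg$step), ylim = c(0, 1),
         xlab = "presentation of pair", ylab = "mean fitted Q", main = tt)
    roles <- unique(agg$role)
    cols <- c(pref_high = "red3", pref_low = "green4",
              novel_high = "red3", novel_low = "green4")
    ltys <- c(pref_high = 1, pref_low = 1, novel_high = 2, novel_low = 2)
    for (r in roles) {
      a <- agg[agg$role == r, ]
      lines(a$step, a$q_value, col = cols[[r]], lty = ltys[[r]],
            lwd = if (r == "pref_high") 2.5 else 1.5)
    }
    legend("bottomright", legend = roles, col = cols[roles],
           lty = ltys[roles], cex = 0.7, bty = "n")
  }
  invisible(traj)
}

#' Compare RL models on one study by WBIC
#'
#' Fits every candidate model to the same data (per-participant tempered
#' runs, study WBIC = sum over participants), ranks by WBIC and reports
#' the Bayes factor of the best model over each rival with its
#' Kass-Raftery category.
#'
#' @param study An [rl_study()] or list of fitting units.
#' @param models Character vector of model names (>= 1).
#' @param beta_max Inverse-temperature bound shared by all models.
#' @param control A [sampler_control()].
#' @param seed Master seed.
#' @return Object of class `rl_comparison`: data frame `model, wbic,
#'   delta_wbic, bf_vs_best, label, flagged`, best model first.
#' @export
rl_compare <- function(study, models = c("RL1", "RL2", "RL3", "RL4"),
                       beta_max = 10, control = sampler_control(), seed = 1) {
  stopifnot(length(models) >= 1)
  units <- if (inherits(study, "rl_study")) fit_units(study) else study
  seeds <- spawn_seeds(seed, length(models) * length(units))
  k <- 0L
  rows <- lapply(models, function(mn) {
    model <- rl_model(mn, beta_max = beta_max)
    prior <- rl_prior(model)
    ws <- lapply(units, function(u) {
      k <<- k + 1L
      wbic_unit(model, u, prior, control, seed = seeds[k])
    })
    data.frame(model = mn, wbic = sum(unlist(ws)),
               flagged = any(vapply(ws, function(w)
                 isTRUE(attr(w, "flagged")), logical(1))),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  best <- which.min(tab$wbic)
  tab$delta_wbic <- tab$wbic - tab$wbic[best]
  if (nrow(tab) > 1) {
    bfl <- lapply(seq_len(nrow(tab)), function(i) {
      if (i == best) list(bf = NA_real_, label = "best")
      else {
        b <- bayes_factor(tab$wbic[best], tab$wbic[i])
        list(bf = b$bf_reported, label = b$label)
      }
    })
    tab$bf_vs_best <- vapply(bfl, `[[`, numeric(1), "bf")
    tab$label <- vapply(bfl, `[[`, character(1), "label")
  } else {
    tab$bf_vs_best <- NA_real_
    tab$label <- "single model"
  }
  tab <- tab[order(tab$wbic), c("model", "wbic", "delta_wbic",
                                "bf_vs_best", "label", "flagged")]
  rownames(tab) <- NULL
  structure(tab, class = c("rl_comparison", "data.frame"))
}

#' @export
print.rl_comparison <- function(x, ...) {
  cat("WBIC model comparison (lower is better; BF of best over rival)\n")
  print.data.frame(x, digits = 6, row.names = FALSE)
  invisible(x)
}
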