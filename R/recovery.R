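#' Single-participant gambling design for recovery simulations
#'
#' Builds the role scaffold of one synthetic participant for the
#' generative direction only: both gambling tasks (preferred stimulus at
#' high, then low, reward probability), three pairs each, with declared
#' preference roles (recovery simulations skip the preference-judgment
#' phase; roles are given, not estimated).
#'
#' @param trials_per_pair Presentations per pair (default 50, the
#'   experimental value).
#' @param probs Reward probabilities `c(high, low)`.
#' @return List of two schedules as returned by [build_gamble_schedule()].
#' @export
edm_design <- function(trials_per_pair = 50, probs = c(0.70, 0.30)) {
  lapply(seq_along(TASK_TYPES), function(i) {
    tt <- TASK_TYPES[i]
    build_gamble_schedule(
      tt,
      pref_high = sprintf("t%d_ph", i), pref_low = sprintf("t%d_pl", i),
      novel_ids = sprintf("t%d_n%02d", i, 1:4),
      trials_per_pair = trials_per_pair, probs = probs
    )
  })
}

# Simulate one participant (both tasks) under a design; returns a fitting
# unit (trials + roles).
simulate_unit <- function(model, params, design) {
  sims <- lapply(design, function(sched) simulate_session(model, params, sched))
  trials <- do.call(rbind, sims)
  roles <- do.call(c, lapply(design, function(sched)
    setNames(sched$stimuli$role, sched$stimuli$stimulus_id)))
  list(participant_id = "sim", trials = trials, roles = roles)
}

#' Default sampler of true parameters for recovery studies
#'
#' Draws span the generative regime of the synthetic study world while
#' avoiding the box boundaries (uniform priors shrink boundary estimates
#' inward, which would bias recovery summaries): `alpha ~ U(0.1, 0.6)`,
#' `beta ~ U(0.2, 0.8) * beta_max` (2 to 8 at the default bound), each
#' eta `~ U(0.2, 0.8)` independently.
#'
#' @param model An [rl_model()].
#' @return One [rl_params()] drawn from the current RNG stream.
#' @export
recovery_truth_sampler <- function(model) {
  rl_params(alpha = runif(1, 0.1, 0.6),
            beta = runif(1, 0.2, 0.8) * model$beta_max,
            etas = runif(model$n_eta, 0.2, 0.8),
            model = model)
}

#' Parameter recovery study
#'
#' Simulate-and-refit: draw true parameters, simulate one participant's
#' two gambling tasks, fit by tempered-posterior MCMC at `tau = 1`, and
#' compare posterior-mean estimates to truth by correlation, bias and
#' RMSE per parameter. A parameter whose true values have zero variance
#' (degenerate grid) gets `NA` correlation and is flagged.
#'
#' @param model An [rl_model()] or model name.
#' @param n_datasets Number of simulated participants.
#' @param design Design from [edm_design()].
#' @param truth_sampler Function `f(model)` drawing one true
#'   [rl_params()]; default [recovery_truth_sampler()]. May also be a
#'   list of fixed [rl_params()] recycled over datasets.
#' @param control A [sampler_control()].
#' @param seed Master seed.
#' @return Object of class `recovery_report` (parameter mode): `summary`
#'   data frame (`parameter, cor, bias, rmse, degenerate`), `truth` and
#'   `estimate` matrices.
#' @export
parameter_recovery <- function(model = "RL2", n_datasets = 50,
                               design = edm_design(),
                               truth_sampler = recovery_truth_sampler,
                               control = sampler_control(), seed = 1) {
  if (is.character(model)) model <- rl_model(model)
  prior <- rl_prior(model)
  seeds <- spawn_seeds(seed, 2L * n_datasets)
  d <- length(model$par_names)
  truth <- matrix(NA_real_, n_datasets, d, dimnames = list(NULL, model$par_names))
  est <- truth
  for (i in seq_len(n_datasets)) {
    sim <- with_seed(seeds[i], {
      params <- if (is.function(truth_sampler)) truth_sampler(model)
                else truth_sampler[[(i - 1L) %% length(truth_sampler) + 1L]]
      list(params = params, unit = simulate_unit(model, params, design))
    })
    ps <- sample_posterior(model, sim$unit, prior, tau = 1, control,
                           seed = seeds[n_datasets + i])
    truth[i, ] <- params_to_vec(sim$params)
    est[i, ] <- colMeans(ps$draws)
  }
  summ <- data.frame(
    parameter = model$par_names,
    cor = vapply(seq_len(d), function(j) {
      if (sd(truth[, j]) == 0) NA_real_ else cor(truth[, j], est[, j])
    }, numeric(1)),
    bias = colMeans(est - truth),
    rmse = sqrt(colMeans((est - truth)^2)),
    degenerate = vapply(seq_len(d), function(j) sd(truth[, j]) == 0, logical(1)),
    row.names = NULL
  )
  structure(list(mode = "parameter", model = model$name, summary = summ,
                 truth = truth, estimate = est, n_datasets = n_datasets),
            class = "recovery_report")
}

#' Model recovery study
#'
#' For each generating model: simulate datasets, compute every candidate
#' model's WBIC on each dataset, select the minimiser, and tabulate the
#' generating-by-selected confusion matrix. Rows sum to
#' `n_datasets_per_model`.
#'
#' @param models Character vector of candidate model names.
#' @param n_datasets_per_model Simulated datasets per generating model.
#' @param generating_params Named list mapping each generating model name
#'   to either a fixed [rl_params()] or a function `f(model)` drawing one
#'   (alpha drawn fresh per dataset by the default, see Details). `NULL`
#'   uses [default_param_sampler()] values with `alpha ~ U(0.1, 0.6)`.
#' @param design Design from [edm_design()].
#' @param beta_max Shared inverse-temperature bound.
#' @param control A [sampler_control()].
#' @param seed Master seed.
#' @return Object of class `recovery_report` (model mode) with the
#'   `confusion` matrix.
#' @export
model_recovery <- function(models = c("RL1", "RL2", "RL3", "RL4"),
                           n_datasets_per_model = 20,
                           generating_params = NULL,
                           design = edm_design(), beta_max = 10,
                           control = sampler_control(), seed = 1) {
  gen_models <- names(generating_params)
  if (is.null(generating_params)) {
    gen_models <- models
    sampler <- default_param_sampler()
    generating_params <- setNames(lapply(gen_models, function(mn) {
      force(mn); function(model) sampler(model)
    }), gen_models)
  }
  confusion <- matrix(0L, length(gen_models), length(models),
                      dimnames = list(generating = gen_models,
                                      selected = models))
  seeds <- spawn_seeds(seed, length(gen_models) * n_datasets_per_model)
  k <- 0L
  for (g in gen_models) {
    gmodel <- rl_model(g, beta_max = beta_max)
    for (r in seq_len(n_datasets_per_model)) {
      k <- k + 1L
      unit <- with_seed(seeds[k], {
        gp <- generating_params[[g]]
        params <- if (is.function(gp)) gp(gmodel) else gp
        simulate_unit(gmodel, params, design)
      })
      cmp <- rl_compare(list(unit), models, beta_max = beta_max,
                        control = control, seed = seeds[k])
      sel <- cmp$model[1]
      confusion[g, sel] <- confusion[g, sel] + 1L
    }
  }
  structure(list(mode = "model", confusion = confusion,
                 n_datasets_per_model = n_datasets_per_model),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  if (x$mode == "parameter") {
    cat("Parameter recovery (", x$model, ", ", x$n_datasets, " datasets)\n", sep = "")
    print(x$summary, digits = 3)
    if (any(x$summary$degenerate))
      cat("note: degenerate (zero-variance) true values for:",
          paste(x$summary$parameter[x$summary$degenerate], collapse = ", "), "\n")
  } else {
    cat("Model recovery confusion matrix (rows sum to",
        x$n_datasets_per_model, ")\n")
    print(x$confusion)
  }
  invisible(x)
}
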