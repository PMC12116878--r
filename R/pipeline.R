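#' Run configuration
#'
#' Validated configuration for seeded end-to-end runs. All design defaults
#' mirror the experimental constants (42 participants, 105 preference
#' trials in 5 blocks of 21, 30 presentations per stimulus, 50 trials per
#' gambling pair at 70%/30% reward); `seed` is mandatory.
#'
#' @param seed Master seed (required).
#' @param out_dir Output directory for stage artifacts.
#' @param n_participants,trials_per_pair,reward_probs Design constants,
#'   see [study_design()].
#' @param beta_max Inverse-temperature bound used for generation bounds,
#'   priors and fitting.
#' @param generating_model Model generating the synthetic study.
#' @param fit_model Model used for point estimates and trajectories.
#' @param models Candidate set for the WBIC comparison.
#' @param sampler A [sampler_control()].
#' @param recover_datasets Datasets per condition for the recovery stage.
#' @param extra Free-form list merged into the config.
#' @return Object of class `run_config`.
#' @export
run_config <- function(seed, out_dir = tempfile("prefrl_run_"),
                       n_participants = 42, trials_per_pair = 50,
                       reward_probs = c(0.70, 0.30), beta_max = 10,
                       generating_model = "RL2", fit_model = "RL2",
                       models = c("RL1", "RL2", "RL3", "RL4"),
                       sampler = sampler_control(),
                       recover_datasets = 10, extra = list()) {
  if (missing(seed) || is.null(seed))
    stop("run_config: a master seed is mandatory", call. = FALSE)
  stopifnot(all(reward_probs >= 0 & reward_probs <= 1), beta_max > 0,
            n_participants >= 2)
  cfg <- c(list(seed = as.integer(seed), out_dir = out_dir,
                n_participants = n_participants,
                trials_per_pair = trials_per_pair,
                reward_probs = reward_probs, beta_max = beta_max,
                generating_model = generating_model, fit_model = fit_model,
                models = models, sampler = sampler,
                recover_datasets = recover_datasets), extra)
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path Path to a JSON file whose top-level fields are
#'   [run_config()] arguments.
#' @export
run_config_from_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- intersect(names(raw), names(formals(run_config)))
  extra <- raw[setdiff(names(raw), c(known, "sampler"))]
  args <- raw[setdiff(known, c("sampler", "extra"))]
  if (!is.null(raw$sampler)) args$sampler <- do.call(sampler_control, as.list(raw$sampler))
  args$extra <- extra
  do.call(run_config, args)
}

#' Seeded end-to-end pipeline
#'
#' Runs the requested stages in dependency order and writes each stage's
#' artifacts plus a manifest (`manifest.json`: per stage, the files
#' written with their MD5 hashes, the seed and the package version; no
#' timestamps, so reruns with identical configs are byte-identical).
#' Stages:
#'
#' * `simulate` — generate the synthetic study, write the four CSVs and
#'   `truth.json`.
#' * `fit` — fit `fit_model`, write posterior-mean parameters and the
#'   fitted value trajectories.
#' * `compare` — WBIC comparison of `models`, written as a CSV mirroring
#'   the model-comparison table (model, WBIC, BF vs best, category).
#' * `analyze` — behavioural battery plus the value-stage ANOVA, one CSV
#'   row per statistic.
#' * `recover` — parameter and model recovery at `recover_datasets`
#'   datasets, written as CSV + JSON summaries.
#'
#' Later stages read earlier artifacts from `out_dir`; a missing
#' dependency raises an error naming the stage to run first.
#'
#' @param config A [run_config()].
#' @param stages Subset of
#'   `c("simulate", "fit", "compare", "analyze", "recover")`.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "fit", "compare", "analyze")) {
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, c("simulate", "fit", "compare", "analyze",
                                "recover"), several.ok = TRUE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- spawn_seeds(config$seed, 5)
  manifest <- list(seed = config$seed,
                   package_version = as.character(utils::packageVersion("prefrl")),
                   stages = list())
  design <- study_design(n_participants = config$n_participants,
                         trials_per_pair = config$trials_per_pair,
                         reward_probs = config$reward_probs)
  gen_model <- rl_model(config$generating_model, beta_max = config$beta_max)
  add_stage <- function(name, files, params = list()) {
    manifest$stages[[name]] <<- list(
      params = params,
      files = lapply(files, function(f)
        list(path = basename(f), md5 = unname(tools::md5sum(f)))))
  }
  study <- NULL
  need_study <- function(stage) {
    if (!is.null(study)) return(study)
    if (!file.exists(file.path(config$out_dir, "gamble_trials.csv")))
      stop("stage '", stage, "' needs study data: run the 'simulate' ",
           "stage first", call. = FALSE)
    read_study(config$out_dir)
  }
  fit <- NULL
  if ("simulate" %in% stages) {
    message("[simulate] generating study: ", config$n_participants,
            " participants, model ", config$generating_model)
    study <- generate_study(generating_model = gen_model, design = design,
                            seed = seeds[1])
    files <- write_study(study, config$out_dir)
    add_stage("simulate", files,
              list(n_participants = config$n_participants,
                   generating_model = config$generating_model,
                   seed = seeds[1]))
  }
  if ("fit" %in% stages) {
    study <- need_study("fit")
    message("[fit] model ", config$fit_model)
    fit <- rl_fit(study, rl_model(config$fit_model, beta_max = config$beta_max),
                  control = config$sampler, seed = seeds[2], keep_draws = FALSE)
    pf <- file.path(config$out_dir, "fitted_params.csv")
    cm <- data.frame(participant_id = rownames(coef(fit)), coef(fit),
                     row.names = NULL)
    write.csv(cm, pf, row.names = FALSE, quote = FALSE)
    tf <- file.path(config$out_dir, "trajectories.csv")
    write.csv(q_trajectories(fit), tf, row.names = FALSE, quote = FALSE)
    add_stage("fit", c(pf, tf),
              list(fit_model = config$fit_model, seed = seeds[2]))
  }
  if ("compare" %in% stages) {
    study <- need_study("compare")
    message("[compare] WBIC over ", paste(config$models, collapse = ", "))
    cmp <- rl_compare(study, config$models, beta_max = config$beta_max,
                      control = config$sampler, seed = seeds[3])
    cf <- file.path(config$out_dir, "model_comparison.csv")
    write.csv(as.data.frame(cmp), cf, row.names = FALSE, quote = FALSE)
    add_stage("compare", cf, list(models = config$models, seed = seeds[3]))
  }
  if ("analyze" %in% stages) {
    study <- need_study("analyze")
    if (is.null(fit)) {
      if (!file.exists(file.path(config$out_dir, "fitted_params.csv")))
        stop("stage 'analyze' needs fitted parameters: run the 'fit' ",
             "stage first", call. = FALSE)
      fit <- rl_fit(study, rl_model(config$fit_model, beta_max = config$beta_max),
                    control = config$sampler, seed = seeds[2],
                    keep_draws = FALSE)
    }
    message("[analyze] behavioural battery")
    stats_tab <- rbind(
      pref_frequency_contrast(study),
      rm_anova_2x2(study),
      above_chance_tests(study),
      rating_comparisons(study),
      value_stage_anova(fit)
    )
    sf <- file.path(config$out_dir, "behavioral_stats.csv")
    write.csv(stats_tab, sf, row.names = FALSE)
    ff <- file.path(config$out_dir, "first_trial_choice.csv")
    write.csv(first_trial_choice(study), ff, row.names = FALSE, quote = FALSE)
    add_stage("analyze", c(sf, ff), list(seed = seeds[2]))
  }
  if ("recover" %in% stages) {
    message("[recover] parameter and model recovery, ",
            config$recover_datasets, " datasets per condition")
    pr <- parameter_recovery(config$fit_model,
                             n_datasets = config$recover_datasets,
                             design = edm_design(config$trials_per_pair,
                                                 config$reward_probs),
                             control = config$sampler, seed = seeds[4])
    mr <- model_recovery(config$models,
                         n_datasets_per_model = config$recover_datasets,
                         design = edm_design(config$trials_per_pair,
                                             config$reward_probs),
                         beta_max = config$beta_max,
                         control = config$sampler, seed = seeds[5])
    prf <- file.path(config$out_dir, "parameter_recovery.csv")
    write.csv(pr$summary, prf, row.names = FALSE, quote = FALSE)
    mrf <- file.path(config$out_dir, "model_recovery.csv")
    write.csv(as.data.frame.matrix(mr$confusion), mrf, quote = FALSE)
    rjf <- file.path(config$out_dir, "recovery_summary.json")
    jsonlite::write_json(
      list(parameter = pr$summary,
           model_confusion = as.data.frame.matrix(mr$confusion)),
      rjf, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    add_stage("recover", c(prf, mrf, rjf),
              list(n_datasets = config$recover_datasets,
                   seeds = seeds[4:5]))
  }
  mf <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}
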