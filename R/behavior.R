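#' @name behavioral-analysis
#' @title Behavioural test battery
#' @description
#' The non-model statistics of the two-stage design: the high-vs-low
#' preference chosen-frequency contrast, correct-response-rate tables and
#' their two-factor repeated-measures ANOVA, above-chance tests, Holm
#' corrected pairwise rating comparisons, first-trial choice proportions,
#' and the three-factor ANOVA on fitted initial/final values. Every test
#' returns rows with columns `effect, statistic, df1, df2, p_value,
#' effect_size, es_type, p_adj, flag`. Effect sizes follow the reported
#' conventions: Cohen's d for paired t (mean difference / SD of the
#' differences) and partial eta squared for ANOVA effects. No sphericity
#' corrections are applied: all within factors have two levels.
NULL

stat_row <- function(effect, statistic, df1, df2, p_value,
                     effect_size = NA_real_, es_type = NA_character_,
                     p_adj = NA_real_, flag = NA_character_) {
  data.frame(effect = effect, statistic = statistic, df1 = df1, df2 = df2,
             p_value = p_value, effect_size = effect_size, es_type = es_type,
             p_adj = p_adj, flag = flag, stringsAsFactors = FALSE)
}

# Paired t with Cohen's d; degenerate zero-variance differences are
# flagged rather than erroring (t = 0 when all differences are zero,
# +/-Inf otherwise).
paired_t <- function(x, y, effect = "paired t") {
  d <- x - y
  n <- length(d)
  if (n < 2) stop("paired t needs n >= 2", call. = FALSE)
  s <- sd(d)
  m <- mean(d)
  if (s == 0) {
    tval <- if (m == 0) 0 else sign(m) * Inf
    p <- if (m == 0) 1 else 0
    return(stat_row(effect, tval, NA_real_, n - 1, p,
                    effect_size = if (m == 0) 0 else sign(m) * Inf,
                    es_type = "cohen_d", flag = "degenerate"))
  }
  tval <- m / (s / sqrt(n))
  p <- 2 * pt(-abs(tval), n - 1)
  stat_row(effect, tval, NA_real_, n - 1, p,
           effect_size = m / s, es_type = "cohen_d")
}

one_sample_t <- function(x, mu, effect) {
  n <- length(x)
  s <- sd(x)
  m <- mean(x)
  if (n < 2 || s == 0) {
    tval <- if (m == mu) 0 else sign(m - mu) * Inf
    p <- if (m == mu) 1 else 0
    return(stat_row(effect, tval, NA_real_, n - 1, p,
                    effect_size = if (s == 0) NA_real_ else (m - mu) / s,
                    es_type = "cohen_d", flag = "degenerate"))
  }
  tval <- (m - mu) / (s / sqrt(n))
  stat_row(effect, tval, NA_real_, n - 1, 2 * pt(-abs(tval), n - 1),
           effect_size = (m - mu) / s, es_type = "cohen_d")
}

#' High- vs low-preference chosen-frequency contrast
#'
#' Per participant, the chosen frequency of the stimulus labelled
#' high-preference and of the one labelled low-preference is averaged over
#' the two preference-judgment tasks, then contrasted by a paired t-test
#' with Cohen's d.
#'
#' @param study An [rl_study()].
#' @return One stat row (see [behavioral-analysis]).
#' @export
pref_frequency_contrast <- function(study) {
  freqs <- chosen_frequency(study$pref_trials)
  st <- study$stimuli
  pids <- unique(st$participant_id)
  if (length(pids) < 2) stop("need >= 2 participants", call. = FALSE)
  get_freq <- function(pid, role) {
    rows <- st[st$participant_id == pid & st$role == role, ]
    mean(vapply(seq_len(nrow(rows)), function(i) {
      f <- freqs[freqs$participant_id == pid &
                   freqs$task_set == rows$task_set[i] &
                   freqs$stimulus_id == rows$stimulus_id[i], "freq"]
      f[1]
    }, numeric(1)))
  }
  hi <- vapply(pids, get_freq, numeric(1), role = "pref_high")
  lo <- vapply(pids, get_freq, numeric(1), role = "pref_low")
  paired_t(hi, lo, "chosen frequency: high vs low preference")
}

#' Correct-response rates per participant, task and pair
#'
#' "Correct" is the choice of the 70%-reward stimulus (the normative
#' answer under asymmetric reward). Pairs with zero trials are excluded
#' with a warning.
#'
#' @param study An [rl_study()].
#' @return Data frame `participant_id, task_type, pair_id, n_trials,
#'   correct_rate`.
#' @export
correct_rate_table <- function(study) {
  gt <- study$gamble_trials
  st <- study$stimuli
  hi_ids <- st$stimulus_id[!is.na(st$reward_prob) & st$reward_prob >= 0.5]
  correct <- gt$chosen_stim %in% hi_ids
  agg <- stats::aggregate(correct ~ participant_id + task_type + pair_id,
                          data = cbind(gt, correct = correct), FUN = mean)
  n <- stats::aggregate(correct ~ participant_id + task_type + pair_id,
                        data = cbind(gt, correct = correct), FUN = length)
  out <- agg
  names(out)[names(out) == "correct"] <- "correct_rate"
  out$n_trials <- n$correct
  zero <- out$n_trials == 0
  if (any(zero)) {
    warning("pairs with zero trials excluded", call. = FALSE)
    out <- out[!zero, ]
  }
  out[order(out$participant_id, out$task_type, out$pair_id),
      c("participant_id", "task_type", "pair_id", "n_trials", "correct_rate")]
}

#' Collapse the correct-rate table to the 2 x 2 cell layout
#'
#' Stimulus type is `"idm"` (the mean of the two preference-anchored
#' pairs) vs `"novel"` (the novel pair), within each gambling task.
#'
#' @param rate_table From [correct_rate_table()].
#' @return Data frame `participant_id, task_type, stim_type, correct_rate`.
#' @export
collapse_rates <- function(rate_table) {
  rate_table$stim_type <- ifelse(rate_table$pair_id == "novel_pair",
                                 "novel", "idm")
  stats::aggregate(correct_rate ~ participant_id + task_type + stim_type,
                   data = rate_table, FUN = mean)
}

#' Two-factor repeated-measures ANOVA on correct rates
#'
#' Gambling task type (preferred stimulus at high vs low probability) by
#' stimulus type (IDM vs novel pairs), both within subject. Main effects
#' and the interaction come from the standard univariate partitioning
#' (each effect tested against its own subject-interaction stratum);
#' when the interaction reaches `alpha`, simple main effects of task type
#' within each stimulus type (and vice versa) are appended, tested against
#' the error pooled across the effect's own and the interaction stratum
#' (df `2(n-1)`).
#'
#' @param cells Data frame `participant_id, task_type, stim_type,
#'   correct_rate` (from [collapse_rates()]), or an [rl_study()].
#' @param alpha Significance level gating the simple-effect follow-up.
#' @return Stat rows with partial eta squared.
#' @export
rm_anova_2x2 <- function(cells, alpha = 0.05) {
  if (inherits(cells, "rl_study"))
    cells <- collapse_rates(correct_rate_table(cells))
  need_cols(cells, c("participant_id", "task_type", "stim_type",
                     "correct_rate"), "rm_anova_2x2")
  res <- rm_anova(cells, dv = "correct_rate",
                  within = c("task_type", "stim_type"),
                  id = "participant_id")
  out <- res$table
  int <- out[out$effect == "task_type:stim_type", ]
  if (nrow(int) == 1 && is.finite(int$p_value) && int$p_value < alpha) {
    out <- rbind(out,
                 simple_effects_2x2(cells, res, "task_type", "stim_type"),
                 simple_effects_2x2(cells, res, "stim_type", "task_type"))
  }
  out
}

# Full univariate repeated-measures decomposition for fully-crossed
# within-subject designs (all factors within), via stats::aov Error
# strata. Returns per-effect stat rows plus the raw SS bookkeeping.
rm_anova <- function(data, dv, within, id) {
  df <- data
  df[[id]] <- factor(df[[id]])
  for (w in within) df[[w]] <- factor(df[[w]])
  rhs <- paste(within, collapse = "*")
  fml <- stats::as.formula(paste(dv, "~", rhs, "+ Error(", id, "/(", rhs, "))"))
  fit <- aov(fml, data = df)
  sm <- summary(fit)
  rows <- list()
  ss_err <- list()
  for (stratum in names(sm)) {
    tab <- sm[[stratum]][[1]]
    effects <- trimws(rownames(tab))
    resid_i <- which(effects == "Residuals")
    if (length(resid_i) == 0) next
    sse <- tab[resid_i, "Sum Sq"]
    dfe <- tab[resid_i, "Df"]
    for (i in setdiff(seq_along(effects), resid_i)) {
      eff <- effects[i]
      ssf <- tab[i, "Sum Sq"]
      fval <- tab[i, "F value"]
      pval <- tab[i, "Pr(>F)"]
      flag <- NA_character_
      if (ssf < 1e-12 && sse < 1e-12) {
        # neither effect nor error variance (all cells equal): F = 0
        fval <- 0; pval <- 1; flag <- "degenerate"
      }
      rows[[length(rows) + 1L]] <- stat_row(
        effect = eff, statistic = fval, df1 = tab[i, "Df"],
        df2 = dfe, p_value = pval,
        effect_size = if (ssf + sse > 0) ssf / (ssf + sse) else 0,
        es_type = "partial_eta_sq", flag = flag)
      ss_err[[eff]] <- c(ss = sse, df = dfe)
    }
  }
  list(table = do.call(rbind, rows), ss_err = ss_err)
}

# Simple main effects of `factor_a` within each level of `factor_b` for a
# 2 x 2 within design, with the error pooled across the a and a:b strata.
simple_effects_2x2 <- function(cells, res, factor_a, factor_b) {
  nm_int <- grep(":", names(res$ss_err), value = TRUE)[1]
  ea <- res$ss_err[[factor_a]]
  ei <- res$ss_err[[nm_int]]
  ms_pool <- (ea["ss"] + ei["ss"]) / (ea["df"] + ei["df"])
  df_pool <- unname(ea["df"] + ei["df"])
  lev_a <- sort(unique(cells[[factor_a]]))
  lev_b <- sort(unique(cells[[factor_b]]))
  n <- length(unique(cells$participant_id))
  dvn <- setdiff(names(cells), c("participant_id", factor_a, factor_b))[1]
  out <- lapply(lev_b, function(b) {
    sl <- cells[cells[[factor_b]] == b, ]
    y1 <- sl[sl[[factor_a]] == lev_a[1], ]
    y2 <- sl[sl[[factor_a]] == lev_a[2], ]
    y1 <- y1[order(y1$participant_id), dvn]
    y2 <- y2[order(y2$participant_id), dvn]
    ss_simple <- n * mean(y1 - y2)^2 / 2
    f <- unname(ss_simple / ms_pool)
    stat_row(paste0(factor_a, " at ", factor_b, "=", b),
             f, 1, df_pool, 1 - stats::pf(f, 1, df_pool),
             effect_size = unname(ss_simple / (ss_simple + ea["ss"] + ei["ss"])),
             es_type = "partial_eta_sq")
  })
  do.call(rbind, out)
}

#' Above-chance tests of correct-response rates
#'
#' One-sample t against the 0.5 chance level, per gambling task and pair.
#' Zero-variance inputs (e.g. all rates 1.0) are flagged with an infinite
#' statistic rather than an error.
#'
#' @param rate_table From [correct_rate_table()], or an [rl_study()].
#' @return Stat rows, one per task x pair.
#' @export
above_chance_tests <- function(rate_table) {
  if (inherits(rate_table, "rl_study"))
    rate_table <- correct_rate_table(rate_table)
  cells <- split(rate_table,
                 list(rate_table$task_type, rate_table$pair_id), drop = TRUE)
  out <- lapply(cells, function(d)
    one_sample_t(d$correct_rate, 0.5,
                 paste0("correct rate vs 0.5: ", d$task_type[1], " / ",
                        d$pair_id[1])))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pairwise rating comparisons with Holm correction
#'
#' Within each gambling task, the four rated stimuli of interest (the
#' high- and low-preference stimuli and the two novel-pair stimuli) are
#' compared by all pairwise paired t-tests; p-values are Holm-adjusted
#' within task.
#'
#' @param study An [rl_study()] with ratings.
#' @return Stat rows with `p_adj`.
#' @export
rating_comparisons <- function(study) {
  if (is.null(study$ratings)) stop("study has no ratings", call. = FALSE)
  st <- study$stimuli
  st <- st[st$role %in% c("pref_high", "pref_low") |
             (!is.na(st$pair_id) & st$pair_id == "novel_pair"), ]
  st$category <- ifelse(st$role == "pref_high", "pref_high",
                   ifelse(st$role == "pref_low", "pref_low",
                     ifelse(st$role == "novel_high", "novel_70", "novel_30")))
  r <- merge(study$ratings, st[c("participant_id", "task_set", "stimulus_id",
                                 "task_type", "category")],
             by = c("participant_id", "task_set", "stimulus_id"))
  out <- list()
  for (tt in sort(unique(r$task_type))) {
    d <- r[r$task_type == tt, ]
    wide <- stats::reshape(d[c("participant_id", "category", "rating")],
                           idvar = "participant_id", timevar = "category",
                           direction = "wide")
    cats <- sub("^rating\\.", "", setdiff(names(wide), "participant_id"))
    prs <- combn(cats, 2)
    rows <- lapply(seq_len(ncol(prs)), function(j) {
      a <- wide[[paste0("rating.", prs[1, j])]]
      b <- wide[[paste0("rating.", prs[2, j])]]
      paired_t(a, b, paste0("rating ", tt, ": ", prs[1, j], " vs ", prs[2, j]))
    })
    tab <- do.call(rbind, rows)
    tab$p_adj <- p.adjust(tab$p_value, method = "holm")
    out[[tt]] <- tab
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' First-trial choice proportions
#'
#' For each gambling task and pair, the proportion of participants who
#' chose the designated stimulus on that pair's first presentation. The
#' designated stimulus is the IDM-preferred member for the
#' high-preference pair, the IDM-least-preferred member for the
#' low-preference pair, and the 70%-reward member for the novel pair.
#'
#' @param study An [rl_study()].
#' @return Data frame `task_type, pair_id, designated_role, n, proportion`.
#' @export
first_trial_choice <- function(study) {
  gt <- study$gamble_trials
  st <- study$stimuli
  desig_role <- c(high_pref_pair = "pref_high", low_pref_pair = "pref_low",
                  novel_pair = "novel_high")
  key <- paste(gt$participant_id, gt$task_type, gt$pair_id)
  firsts <- do.call(rbind, lapply(split(gt, key), function(d)
    d[which.min(d$trial_index), ]))
  firsts$designated <- vapply(seq_len(nrow(firsts)), function(i) {
    row <- firsts[i, ]
    st$stimulus_id[st$participant_id == row$participant_id &
                     !is.na(st$task_type) & st$task_type == row$task_type &
                     !is.na(st$pair_id) & st$pair_id == row$pair_id &
                     st$role == desig_role[[row$pair_id]]][1]
  }, character(1))
  firsts$hit <- firsts$chosen_stim == firsts$designated
  agg <- stats::aggregate(hit ~ task_type + pair_id, data = firsts,
                          FUN = mean)
  n <- stats::aggregate(hit ~ task_type + pair_id, data = firsts,
                        FUN = length)
  data.frame(task_type = agg$task_type, pair_id = agg$pair_id,
             designated_role = desig_role[agg$pair_id], n = n$hit,
             proportion = agg$hit, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Three-factor ANOVA on fitted initial and final values
#'
#' Per gambling task: a within-subject ANOVA of the fitted Q values with
#' factors stimulus type (IDM vs novel), reward probability (high vs low)
#' and value type (initial vs final), followed by the planned simple
#' effects: the stimulus-type effect separately at the initial and final
#' stage, the reward-probability effect at the final stage, and the
#' initial-vs-final change within each stimulus x probability cell
#' (each simple effect is a paired contrast within its slice, F(1, n-1)).
#'
#' @param values A [value_table()] data frame, or an [rl_fit()].
#' @return Stat rows, with the task name prefixed to each effect.
#' @export
value_stage_anova <- function(values) {
  if (inherits(values, "rl_fit")) values <- value_table(values)
  need_cols(values, c("participant_id", "task_type", "stim_type", "prob",
                      "initial", "final"), "value_stage_anova")
  long <- rbind(
    data.frame(values[c("participant_id", "task_type", "stim_type", "prob")],
               value_type = "initial", q = values$initial),
    data.frame(values[c("participant_id", "task_type", "stim_type", "prob")],
               value_type = "final", q = values$final)
  )
  out <- list()
  for (tt in sort(unique(long$task_type))) {
    d <- long[long$task_type == tt, ]
    miss <- with(d, table(participant_id, stim_type, prob, value_type))
    if (any(miss == 0)) stop("value_stage_anova: missing cells for task ",
                             tt, call. = FALSE)
    res <- rm_anova(d, dv = "q", within = c("stim_type", "prob", "value_type"),
                    id = "participant_id")
    tab <- res$table
    tab$effect <- paste0(tt, ": ", tab$effect)
    sl <- list()
    for (vt in c("initial", "final")) {
      s <- d[d$value_type == vt, ]
      agg <- stats::aggregate(q ~ participant_id + stim_type, data = s, FUN = mean)
      w <- stats::reshape(agg, idvar = "participant_id", timevar = "stim_type",
                          direction = "wide")
      sl[[length(sl) + 1L]] <- within(
        paired_t(w$q.idm, w$q.novel,
                 paste0(tt, ": stim_type at value_type=", vt)), {
          statistic <- statistic^2; df1 <- 1; es_type <- "partial_eta_sq"
          effect_size <- statistic / (statistic + df2)
        })
    }
    s <- d[d$value_type == "final", ]
    agg <- stats::aggregate(q ~ participant_id + prob, data = s, FUN = mean)
    w <- stats::reshape(agg, idvar = "participant_id", timevar = "prob",
                        direction = "wide")
    sl[[length(sl) + 1L]] <- within(
      paired_t(w$q.high, w$q.low, paste0(tt, ": prob at value_type=final")), {
        statistic <- statistic^2; df1 <- 1; es_type <- "partial_eta_sq"
        effect_size <- statistic / (statistic + df2)
      })
    for (stp in c("idm", "novel")) for (pr in c("high", "low")) {
      s <- d[d$stim_type == stp & d$prob == pr, ]
      w <- stats::reshape(s[c("participant_id", "value_type", "q")],
                          idvar = "participant_id", timevar = "value_type",
                          direction = "wide")
      sl[[length(sl) + 1L]] <- paired_t(
        w$q.initial, w$q.final,
        paste0(tt, ": initial vs final at ", stp, "/", pr))
    }
    out[[tt]] <- rbind(tab, do.call(rbind, sl))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Empirical type-I error of a test under null simulations
#'
#' Helper for calibration checks: applies `test_fn` to `n_sims` null
#' datasets drawn by `null_gen` and returns the rejection rate at `alpha`.
#'
#' @param null_gen Function of the replicate index returning a dataset.
#' @param test_fn Function of a dataset returning a p-value.
#' @param n_sims Number of simulations.
#' @param alpha Nominal level.
#' @export
type_one_error <- function(null_gen, test_fn, n_sims = 1000, alpha = 0.05) {
  p <- vapply(seq_len(n_sims), function(i) test_fn(null_gen(i)), numeric(1))
  mean(p < alpha)
}
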