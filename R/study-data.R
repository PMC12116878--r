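#' @name study-data
#' @title Study containers and tidy CSV input/output
#'
#' @description
#' A study is held as an object of class `rl_study`: four tidy data frames
#' plus optional generating truth.
#'
#' * `pref_trials`: preference-judgment (IDM) choices —
#'   `participant_id, task_set, block, trial_index, left_stim, right_stim,
#'   chosen_stim`. No reward exists in this phase.
#' * `gamble_trials`: gambling (EDM) choices —
#'   `participant_id, task_type, pair_id, trial_index, left_stim,
#'   right_stim, chosen_stim, reward` with `reward` in \{0, 1\}.
#' * `ratings`: 5-point subjective preference ratings —
#'   `participant_id, task_set, stimulus_id, rating`.
#' * `stimuli`: per participant and task set, each stimulus's `role`
#'   (`pref_high`, `pref_low`, `novel_high`, `novel_low`, `idm_only`),
#'   gambling `pair_id` and `reward_prob` (NA outside the gambling task).
#'
#' `task_type` is `pref_high_prob` (the IDM-preferred stimulus is rewarded
#' at 70%) or `pref_low_prob` (at 30%); `pair_id` is `high_pref_pair`,
#' `low_pref_pair` or `novel_pair`. Trial indices are 1-based, per
#' participant and task.
NULL

TASK_TYPES <- c("pref_high_prob", "pref_low_prob")
PAIR_IDS <- c("high_pref_pair", "low_pref_pair", "novel_pair")
ROLES <- c("pref_high", "pref_low", "novel_high", "novel_low", "idm_only")

#' Assemble and validate a study object
#'
#' Checks every invariant of the container (see [study-data]): required
#' columns, known factor levels, `chosen_stim` a member of its pair,
#' rewards in \{0, 1\}, ratings in 1..5, and gapless 1-based trial indices
#' per participant and task. Violations raise errors naming the offending
#' column or row.
#'
#' @param pref_trials,gamble_trials,ratings,stimuli Data frames as
#'   described in [study-data]; `ratings` and `stimuli` may be `NULL`.
#' @param truth Optional list of generating-truth metadata.
#' @param design Optional list of design constants.
#' @return An object of class `rl_study`.
#' @export
rl_study <- function(pref_trials, gamble_trials, ratings = NULL,
                     stimuli = NULL, truth = NULL, design = NULL) {
  pref_trials <- validate_pref_trials(pref_trials)
  gamble_trials <- validate_gamble_trials(gamble_trials)
  if (!is.null(ratings)) ratings <- validate_ratings(ratings)
  if (is.null(stimuli)) {
    stimuli <- derive_stimulus_table(pref_trials, gamble_trials)
  } else {
    stimuli <- validate_stimuli(stimuli)
  }
  structure(list(pref_trials = pref_trials, gamble_trials = gamble_trials,
                 ratings = ratings, stimuli = stimuli, truth = truth,
                 design = design),
            class = "rl_study")
}

#' @export
print.rl_study <- function(x, ...) {
  np <- length(unique(x$gamble_trials$participant_id))
  cat("rl_study:", np, "participant(s);",
      nrow(x$pref_trials), "preference trials;",
      nrow(x$gamble_trials), "gambling trials;",
      if (is.null(x$ratings)) 0 else nrow(x$ratings), "ratings\n")
  if (!is.null(x$truth))
    cat("  generating truth attached (model ", x$truth$generating_model, ")\n", sep = "")
  invisible(x)
}

need_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0)
    stop(what, ": missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  invisible(df)
}

check_tokens <- function(x, allowed, col, what) {
  bad <- setdiff(unique(as.character(x)), allowed)
  if (length(bad) > 0)
    stop(what, ": unknown ", col, " token(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
}

check_chosen_in_pair <- function(df, what) {
  bad <- which(df$chosen_stim != df$left_stim & df$chosen_stim != df$right_stim)
  if (length(bad) > 0)
    stop(what, ": chosen_stim not a member of the presented pair at row(s) ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  same <- which(df$left_stim == df$right_stim)
  if (length(same) > 0)
    stop(what, ": left_stim equals right_stim at row(s) ",
         paste(head(same, 5), collapse = ", "), call. = FALSE)
}

check_gapless <- function(df, by, what) {
  key <- do.call(paste, c(df[by], sep = "\r"))
  for (k in unique(key)) {
    idx <- sort(df$trial_index[key == k])
    if (!identical(as.integer(idx), seq_along(idx)))
      stop(what, ": trial_index not gapless 1..n for ",
           gsub("\r", " / ", k), call. = FALSE)
  }
}

validate_pref_trials <- function(df) {
  need_cols(df, c("participant_id", "task_set", "block", "trial_index",
                  "left_stim", "right_stim", "chosen_stim"), "pref_trials")
  df$task_set <- as.integer(df$task_set)
  check_tokens(df$task_set, c("1", "2"), "task_set", "pref_trials")
  if (any(df$block < 1) || any(df$trial_index < 1))
    stop("pref_trials: block and trial_index must be >= 1", call. = FALSE)
  check_chosen_in_pair(df, "pref_trials")
  check_gapless(df, c("participant_id", "task_set"), "pref_trials")
  df
}

validate_gamble_trials <- function(df) {
  need_cols(df, c("participant_id", "task_type", "pair_id", "trial_index",
                  "left_stim", "right_stim", "chosen_stim", "reward"),
            "gamble_trials")
  check_tokens(df$task_type, TASK_TYPES, "task_type", "gamble_trials")
  check_tokens(df$pair_id, PAIR_IDS, "pair_id", "gamble_trials")
  bad <- which(!(df$reward %in% c(0L, 1L)))
  if (length(bad) > 0)
    stop("gamble_trials: reward must be 0 or 1; offending row(s): ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  df$reward <- as.integer(df$reward)
  check_chosen_in_pair(df, "gamble_trials")
  ord <- order(df$participant_id, df$task_type, df$trial_index)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  check_gapless(df, c("participant_id", "task_type"), "gamble_trials")
  df
}

validate_ratings <- function(df) {
  need_cols(df, c("participant_id", "task_set", "stimulus_id", "rating"),
            "ratings")
  if (any(!(df$rating %in% 1:5)))
    stop("ratings: rating must be an integer in 1..5", call. = FALSE)
  df$rating <- as.integer(df$rating)
  df$task_set <- as.integer(df$task_set)
  df
}

validate_stimuli <- function(df) {
  need_cols(df, c("participant_id", "task_set", "task_type", "stimulus_id",
                  "role", "pair_id", "reward_prob"), "stimuli")
  check_tokens(df$role, ROLES, "role", "stimuli")
  check_tokens(df$task_type[!is.na(df$task_type)], TASK_TYPES, "task_type", "stimuli")
  check_tokens(df$pair_id[!is.na(df$pair_id)], PAIR_IDS, "pair_id", "stimuli")
  rp <- df$reward_prob[!is.na(df$reward_prob)]
  if (any(rp < 0 | rp > 1))
    stop("stimuli: reward_prob must lie in [0, 1]", call. = FALSE)
  df
}

# Reconstruct roles and reward probabilities when no stimulus table is on
# disk. Roles follow the experimental definition: preference extremes come
# from IDM chosen frequencies, never a priori; the 70% member of the novel
# pair is identified from its empirical reward rate over presentations.
derive_stimulus_table <- function(pref_trials, gamble_trials) {
  out <- list()
  for (pid in unique(gamble_trials$participant_id)) {
    gp <- gamble_trials[gamble_trials$participant_id == pid, , drop = FALSE]
    pp <- pref_trials[pref_trials$participant_id == pid, , drop = FALSE]
    for (tt in unique(gp$task_type)) {
      gt <- gp[gp$task_type == tt, , drop = FALSE]
      # which task set does this task belong to? the set whose IDM stimuli
      # appear in the task's IDM-derived pairs
      idm_ids <- unique(c(gt$left_stim, gt$right_stim))
      sets <- unique(pp$task_set)
      set_of <- NA_integer_
      for (s in sets) {
        ps <- pp[pp$task_set == s, ]
        if (any(idm_ids %in% unique(c(ps$left_stim, ps$right_stim)))) set_of <- s
      }
      ps <- pp[pp$task_set == set_of, , drop = FALSE]
      freqs <- chosen_frequency(ps)
      ext <- label_preference_extremes(setNames(freqs$freq, freqs$stimulus_id))
      rows <- stim_rows_for_task(gt, ps, ext, tt, set_of, pid)
      out[[length(out) + 1L]] <- rows
    }
  }
  do.call(rbind, out)
}

stim_rows_for_task <- function(gt, ps, ext, task_type, task_set, pid) {
  idm_stim <- unique(c(ps$left_stim, ps$right_stim))
  all_stim <- unique(c(gt$left_stim, gt$right_stim))
  role <- setNames(rep(NA_character_, length(all_stim)), all_stim)
  prob <- setNames(rep(NA_real_, length(all_stim)), all_stim)
  pair <- setNames(rep(NA_character_, length(all_stim)), all_stim)
  for (pidr in unique(gt$pair_id)) {
    tp <- gt[gt$pair_id == pidr, ]
    members <- unique(c(tp$left_stim, tp$right_stim))
    pair[members] <- pidr
    if (pidr == "high_pref_pair") {
      anchor <- intersect(members, ext["pref_high"])
      if (length(anchor) != 1L)
        stop("high_pref_pair of participant ", pid,
             " does not contain the most-chosen IDM stimulus", call. = FALSE)
      role[anchor] <- "pref_high"
      p_anchor <- if (task_type == "pref_high_prob") 0.70 else 0.30
      prob[anchor] <- p_anchor
      partner <- setdiff(members, anchor)
      prob[partner] <- 1 - p_anchor
      role[partner] <- if (prob[partner] >= 0.5) "novel_high" else "novel_low"
    } else if (pidr == "low_pref_pair") {
      anchor <- intersect(members, ext["pref_low"])
      if (length(anchor) != 1L)
        stop("low_pref_pair of participant ", pid,
             " does not contain the least-chosen IDM stimulus", call. = FALSE)
      role[anchor] <- "pref_low"
      p_anchor <- if (task_type == "pref_high_prob") 0.30 else 0.70
      prob[anchor] <- p_anchor
      partner <- setdiff(members, anchor)
      prob[partner] <- 1 - p_anchor
      role[partner] <- if (prob[partner] >= 0.5) "novel_high" else "novel_low"
    } else {
      # novel pair: identify the 70% member from empirical reward rates of
      # chosen presentations (separable at 50 trials per pair)
      rate <- vapply(members, function(s) {
        ch <- tp$chosen_stim == s
        if (!any(ch)) return(NA_real_)
        mean(tp$reward[ch])
      }, numeric(1))
      hi <- members[which.max(rate)]
      lo <- setdiff(members, hi)
      role[hi] <- "novel_high"; prob[hi] <- 0.70
      role[lo] <- "novel_low"; prob[lo] <- 0.30
    }
  }
  rest <- setdiff(idm_stim, all_stim)
  data.frame(
    participant_id = pid,
    task_set = task_set,
    task_type = c(rep(task_type, length(all_stim)), rep(NA_character_, length(rest))),
    stimulus_id = c(all_stim, rest),
    role = c(unname(role), rep("idm_only", length(rest))),
    pair_id = c(unname(pair), rep(NA_character_, length(rest))),
    reward_prob = c(unname(prob), rep(NA_real_, length(rest))),
    stringsAsFactors = FALSE
  )
}

#' Write / read a study as tidy CSV files
#'
#' `write_study()` writes `pref_trials.csv`, `gamble_trials.csv`,
#' `ratings.csv`, `stimuli.csv` and, when generating truth is attached,
#' `truth.json` into `dir`. `read_study()` reads them back, re-validating
#' every invariant; `stimuli.csv` is optional on read (roles are then
#' re-derived from the IDM chosen frequencies and the empirical reward
#' rates, exactly as the experimental procedure defines them). The pair
#' `write_study()` / `read_study()` is the identity on valid studies.
#'
#' @param study An `rl_study`.
#' @param dir Directory (created if needed).
#' @return `write_study()` the file paths invisibly; `read_study()` an
#'   `rl_study`.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "rl_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    pref_trials = file.path(dir, "pref_trials.csv"),
    gamble_trials = file.path(dir, "gamble_trials.csv"),
    ratings = file.path(dir, "ratings.csv"),
    stimuli = file.path(dir, "stimuli.csv")
  )
  write.csv(study$pref_trials, paths["pref_trials"], row.names = FALSE, quote = FALSE)
  write.csv(study$gamble_trials, paths["gamble_trials"], row.names = FALSE, quote = FALSE)
  if (!is.null(study$ratings))
    write.csv(study$ratings, paths["ratings"], row.names = FALSE, quote = FALSE)
  write.csv(study$stimuli, paths["stimuli"], row.names = FALSE, quote = FALSE)
  if (!is.null(study$truth)) {
    jsonlite::write_json(study$truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths <- c(paths, truth = file.path(dir, "truth.json"))
  }
  invisible(paths)
}

#' @rdname write_study
#' @export
read_study <- function(dir) {
  rd <- function(f) read.csv(file.path(dir, f), stringsAsFactors = FALSE,
                             fileEncoding = "UTF-8")
  pt <- rd("pref_trials.csv")
  gt <- rd("gamble_trials.csv")
  ratings <- if (file.exists(file.path(dir, "ratings.csv"))) rd("ratings.csv") else NULL
  stimuli <- if (file.exists(file.path(dir, "stimuli.csv"))) {
    st <- rd("stimuli.csv")
    st$task_type <- as.character(st$task_type)
    st$pair_id <- as.character(st$pair_id)
    st
  } else NULL
  truth <- if (file.exists(file.path(dir, "truth.json")))
    jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE) else NULL
  rl_study(pt, gt, ratings = ratings, stimuli = stimuli, truth = truth)
}

#' Chosen frequency of each stimulus in the preference-judgment task
#'
#' For each participant, task set and stimulus: the number of trials in
#' which the stimulus was chosen divided by the number of trials in which
#' it was presented. Stimuli listed in `stimuli` but never presented are
#' excluded with a warning. Frequencies are reported per task set;
#' averaging the two sets is done by the behavioural contrasts.
#'
#' @param pref_trials Data frame of preference trials (see [study-data]).
#' @param stimuli Optional character vector of expected stimulus ids.
#' @return Data frame `participant_id, task_set, stimulus_id, n_presented,
#'   n_chosen, freq`.
#' @export
chosen_frequency <- function(pref_trials, stimuli = NULL) {
  df <- pref_trials
  long <- rbind(
    data.frame(participant_id = df$participant_id, task_set = df$task_set,
               stimulus_id = df$left_stim, chosen = df$chosen_stim == df$left_stim),
    data.frame(participant_id = df$participant_id, task_set = df$task_set,
               stimulus_id = df$right_stim, chosen = df$chosen_stim == df$right_stim)
  )
  agg_n <- stats::aggregate(chosen ~ participant_id + task_set + stimulus_id,
                            data = long, FUN = length)
  agg_c <- stats::aggregate(chosen ~ participant_id + task_set + stimulus_id,
                            data = long, FUN = sum)
  out <- agg_n
  names(out)[names(out) == "chosen"] <- "n_presented"
  out$n_chosen <- agg_c$chosen
  out$freq <- out$n_chosen / out$n_presented
  if (!is.null(stimuli)) {
    missing <- setdiff(stimuli, unique(out$stimulus_id))
    if (length(missing) > 0)
      warning("stimuli never presented, excluded: ",
              paste(missing, collapse = ", "), call. = FALSE)
  }
  out[order(out$participant_id, out$task_set, out$stimulus_id), ]
}

#' Label the preference extremes from chosen frequencies
#'
#' The most- and least-chosen stimuli become the high- and low-preference
#' stimuli of the gambling task. Ties are an error by default (they do not
#' arise at 30 presentations per stimulus in practice); for simulation
#' sweeps an explicit deterministic lexicographic tie-break can be opted
#' into.
#'
#' @param freqs Named numeric vector of chosen frequencies (names are
#'   stimulus ids), at least 2 long.
#' @param tie_break `"error"` (default) or `"lexicographic"`.
#' @return Named character vector `c(pref_high = ..., pref_low = ...)`.
#' @export
label_preference_extremes <- function(freqs, tie_break = c("error", "lexicographic")) {
  tie_break <- match.arg(tie_break)
  if (length(freqs) < 2 || is.null(names(freqs)))
    stop("freqs must be a named vector with >= 2 stimuli", call. = FALSE)
  hi_ids <- names(freqs)[freqs == max(freqs)]
  lo_ids <- names(freqs)[freqs == min(freqs)]
  if ((length(hi_ids) > 1 || length(lo_ids) > 1) && tie_break == "error")
    stop("tie at the preference extreme(s): max {",
         paste(hi_ids, collapse = ", "), "}, min {",
         paste(lo_ids, collapse = ", "), "}", call. = FALSE)
  hi <- sort(hi_ids)[1]
  lo <- sort(lo_ids)[1]
  if (hi == lo) lo <- sort(setdiff(lo_ids, hi))[1]
  if (is.na(lo)) {
    # all frequencies equal and only one stimulus id in both sets
    lo <- sort(setdiff(names(freqs), hi))[1]
  }
  c(pref_high = hi, pref_low = lo)
}
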