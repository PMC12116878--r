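#' Random-walk Metropolis sampler on a box
#'
#' Reference sampler for the tempered posteriors: a Gaussian random walk
#' with reflection at the box boundaries (a symmetric proposal, so the
#' acceptance ratio is the plain posterior ratio). Per-chain proposal
#' scales are adapted during warm-up by Robbins-Monro toward a target
#' acceptance rate and then frozen. Split-chain R-hat is reported per
#' parameter and the result is flagged (with a warning, never silently)
#' when any R-hat exceeds the threshold.
#'
#' @param log_post Function of the parameter vector returning the log
#'   target; an optional `"loglik"` attribute on the value (the untempered
#'   log-likelihood) is recorded per draw for WBIC.
#' @param lower,upper Numeric bounds of the box (the prior support).
#' @param control A [sampler_control()] list.
#' @param seed Integer seed; identical seeds give identical draws.
#' @return Object of class `posterior_draws`: `draws` (matrix, kept
#'   iterations x parameters), `chain` id per draw, `loglik` per draw,
#'   `accept_rate` per chain, `rhat` per parameter, `flagged`.
#' @export
mh_sample <- function(log_post, lower, upper, control = sampler_control(),
                      seed = 1) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(upper > lower))
  n_chains <- control$chains
  n_keep <- control$iter
  n_warm <- control$warmup
  width <- upper - lower
  draws <- matrix(NA_real_, n_chains * n_keep, d)
  loglik <- rep(NA_real_, n_chains * n_keep)
  lp_keep <- rep(NA_real_, n_chains * n_keep)
  chain_id <- rep(seq_len(n_chains), each = n_keep)
  accept_rate <- numeric(n_chains)
  chain_seeds <- spawn_seeds(seed, n_chains)
  for (ch in seq_len(n_chains)) {
    with_seed(chain_seeds[ch], {
      x <- lower + width * runif(d, 0.1, 0.9)
      lp <- log_post(x)
      ll <- attr(lp, "loglik")
      s_global <- control$init_scale
      shape <- width / mean(width)
      run_mean <- x; run_m2 <- rep(0, d)   # Welford stats over warm-up
      n_acc <- 0L
      total <- n_warm + n_keep
      for (t in seq_len(total)) {
        prop <- reflect(x + rnorm(d) * (s_global * shape), lower, upper)
        lp_new <- log_post(prop)
        if (is.finite(lp_new) &&
            (lp_new - lp > 0 || log(runif(1)) < lp_new - lp)) {
          x <- prop; lp <- lp_new; ll <- attr(lp_new, "loglik")
          acc <- 1
        } else acc <- 0
        if (t <= n_warm && control$adapt) {
          # global scale: Robbins-Monro toward the target acceptance rate;
          # per-parameter shape: running posterior sd (diagonal adaptation)
          s_global <- s_global * exp((acc - control$target_accept) / sqrt(t))
          dlt <- x - run_mean
          run_mean <- run_mean + dlt / t
          run_m2 <- run_m2 + dlt * (x - run_mean)
          if (t >= max(50L, n_warm %/% 4L) && t %% 25L == 0L) {
            sds <- sqrt(run_m2 / (t - 1))
            if (all(sds > 0)) shape <- sds / mean(sds)
          }
        }
        if (t > n_warm) {
          k <- (ch - 1L) * n_keep + (t - n_warm)
          draws[k, ] <- x
          lp_keep[k] <- as.numeric(lp)
          loglik[k] <- if (is.null(ll)) NA_real_ else ll
          n_acc <- n_acc + acc
        }
      }
      accept_rate[ch] <- n_acc / n_keep
    })
  }
  rhat <- split_rhat(draws, chain_id)
  flagged <- any(is.finite(rhat) & rhat > control$rhat_threshold)
  if (flagged)
    warning("sampler convergence flagged: max split R-hat = ",
            signif(max(rhat, na.rm = TRUE), 4), call. = FALSE)
  structure(list(draws = draws, chain = chain_id, loglik = loglik,
                 log_post = lp_keep, accept_rate = accept_rate, rhat = rhat,
                 flagged = flagged, control = control, seed = seed),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat("posterior_draws:", nrow(x$draws), "draws x", ncol(x$draws),
      "parameter(s) over", length(unique(x$chain)), "chain(s)\n")
  cat("  acceptance:", paste(signif(x$accept_rate, 3), collapse = ", "), "\n")
  cat("  split R-hat:", paste(signif(x$rhat, 4), collapse = ", "),
      if (x$flagged) " [FLAGGED]" else "", "\n")
  invisible(x)
}

#' Sampler configuration
#'
#' Defaults: 4 chains of 2,500 kept draws after 1,000 warm-up iterations,
#' Robbins-Monro adaptation toward 30% acceptance, split R-hat threshold
#' 1.05.
#'
#' @param chains,iter,warmup Chain count, kept draws per chain, warm-up
#'   iterations per chain.
#' @param target_accept Adaptation target acceptance rate.
#' @param init_scale Initial proposal scale as a fraction of each
#'   parameter's box width.
#' @param adapt Adapt proposal scales during warm-up?
#' @param rhat_threshold Convergence flag threshold.
#' @export
sampler_control <- function(chains = 4, iter = 2500, warmup = 1000,
                            target_accept = 0.3, init_scale = 0.1,
                            adapt = TRUE, rhat_threshold = 1.05) {
  stopifnot(chains >= 1, iter >= 1, warmup >= 0)
  list(chains = as.integer(chains), iter = as.integer(iter),
       warmup = as.integer(warmup), target_accept = target_accept,
       init_scale = init_scale, adapt = adapt,
       rhat_threshold = rhat_threshold)
}

# Reflect a proposal into [lower, upper] (period-2*width folding).
reflect <- function(x, lower, upper) {
  w <- upper - lower
  r <- (x - lower) %% (2 * w)
  lower + pmin(r, 2 * w - r)
}

# Split-chain R-hat (each chain halved, between/within variance ratio).
split_rhat <- function(draws, chain_id) {
  apply(draws, 2, function(v) {
    halves <- list()
    for (ch in unique(chain_id)) {
      vc <- v[chain_id == ch]
      h <- length(vc) %/% 2L
      if (h < 2L) return(NA_real_)
      halves <- c(halves, list(vc[1:h]), list(vc[(h + 1):(2 * h)]))
    }
    m <- length(halves)
    L <- length(halves[[1]])
    means <- vapply(halves, mean, numeric(1))
    vars <- vapply(halves, var, numeric(1))
    W <- mean(vars)
    B <- L * var(means)
    if (W <= 0) return(1)
    sqrt(((L - 1) / L * W + B / L) / W)
  })
}
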