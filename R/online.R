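#' Create an online bias estimator
#'
#' Stateful trial-by-trial estimator used both for live reward allocation
#' and for offline replay.  Trials are accumulated as they arrive; before
#' the stimulus set has been seen once (the first \code{start_trial}
#' trials), the bias estimates are the prior means.  From
#' \code{start_trial} on, the posterior is refit every
#' \code{config$refit_cadence} trials, warm-started from the previous
#' fit's final state.  The reward boundaries glide toward the current
#' posterior means of the perceptual biases by at most \code{max_step}
#' degrees per trial.
#'
#' @param priors A \code{\link{prior_spec}}.
#' @param config A \code{\link{sampler_config}}; for online use a reduced
#'   draw count (e.g. 1000 draws, 500 burn-in) and a cadence of 5-10
#'   trials keeps refits well inside typical inter-trial intervals.
#' @param max_step Boundary clamp, degrees per trial.
#' @param start_trial First trial count at which inference runs (default
#'   33: one pass through 11 stimulus values in 3 conditions).
#' @return An environment with functions \code{observe(condition,
#'   omega, choice)} (returns the boundaries applicable to the trial just
#'   observed), \code{boundaries()}, \code{means()}, \code{posterior()},
#'   \code{trace()}, and \code{n_seen()}.
#' @export
online_estimator <- function(priors = prior_spec(),
                             config = sampler_config(n_draws = 1000,
                                                     burn_in = 500,
                                                     refit_cadence = 1),
                             max_step = 1, start_trial = 33) {
  est <- new.env(parent = emptyenv())
  est$priors <- priors
  est$config <- config
  est$start_trial <- start_trial
  est$n <- 0L
  cap <- 1024L
  est$cond <- character(cap)
  est$omega <- numeric(cap)
  est$choice <- character(cap)
  prior_means <- c(P_L = if (priors$flat) 0 else priors$P_L_mean,
                   P_R = if (priors$flat) 0 else priors$P_R_mean,
                   D = if (priors$flat) 0 else priors$D_mean)
  est$means <- prior_means
  est$fit <- NULL
  est$state <- NULL
  est$rstate <- reward_state(boundary_L = prior_means[["P_L"]],
                             boundary_R = prior_means[["P_R"]],
                             max_step = max_step)
  est$trace <- list()
  est$refit_seconds <- numeric(0)

  refit <- function() {
    trials <- data.frame(condition = est$cond[seq_len(est$n)],
                         omega_deg = est$omega[seq_len(est$n)],
                         choice = est$choice[seq_len(est$n)])
    elapsed <- system.time(
      fit <- suppressWarnings(
        fit_posterior(trials, est$priors, est$config, state = est$state))
    )[["elapsed"]]
    est$refit_seconds <- c(est$refit_seconds, elapsed)
    est$fit <- fit
    est$state <- fit$state
    est$means <- fit$means[c("P_L", "P_R", "D")]
    est$trace[[length(est$trace) + 1L]] <-
      data.frame(t = est$n, P_L = fit$means[["P_L"]],
                 P_R = fit$means[["P_R"]], D = fit$means[["D"]],
                 sd_P_L = fit$sds[["P_L"]], sd_P_R = fit$sds[["P_R"]],
                 sd_D = fit$sds[["D"]], seconds = elapsed)
    invisible(fit)
  }

  est$observe <- function(condition, omega, choice) {
    est$n <- est$n + 1L
    if (est$n > length(est$omega)) {
      grow <- length(est$omega)
      est$cond <- c(est$cond, character(grow))
      est$omega <- c(est$omega, numeric(grow))
      est$choice <- c(est$choice, character(grow))
    }
    est$cond[est$n] <- condition
    est$omega[est$n] <- omega
    est$choice[est$n] <- choice
    due <- est$n >= est$start_trial &&
      (est$n - est$start_trial) %% est$config$refit_cadence == 0
    if (due) refit()
    est$rstate <- update_boundary(est$rstate, est$means, "L", est$n)
    est$rstate <- update_boundary(est$rstate, est$means, "R", est$n)
    est$rstate$boundary
  }
  est$boundaries <- function() est$rstate$boundary
  est$means_now <- function() est$means
  est$posterior <- function() est$fit
  est$get_trace <- function() do.call(rbind, est$trace)
  est$n_seen <- function() est$n
  est
}

#' Replay a recorded session through the online estimator
#'
#' Runs the identical computation path as live reward allocation over a
#' recorded trial table: the posterior is refit per cadence, the reward
#' boundary glides under the per-trial clamp, and a hypothetical reward is
#' recomputed for every trial from the evolving boundary (recorded rewards
#' in the input are never overwritten).  Replaying a synthetic session
#' reproduces the live run's boundary trajectory exactly under the same
#' seed and cadence, since it is the same code.
#'
#' @param trials Trial table (see \code{\link{read_trials}} for the
#'   schema); choices must be present.
#' @param priors A \code{\link{prior_spec}}.
#' @param config A \code{\link{sampler_config}}.
#' @param max_step Boundary clamp, degrees per trial.
#' @param latency_budget Seconds per refit above which a warning is
#'   emitted (online use sits between trials; the reference setting is a
#'   3-3.5 s inter-trial interval).
#' @return List with \code{trials} (input plus \code{reward_replayed} and
#'   \code{boundary_deg} columns), \code{trace} (refit-by-refit posterior
#'   means/SDs and timing), and \code{posterior} (the final fit).
#' @export
replay_session <- function(trials, priors = prior_spec(),
                           config = sampler_config(n_draws = 1000,
                                                   burn_in = 500,
                                                   refit_cadence = 10),
                           max_step = 1, latency_budget = 3) {
  .check_trials(trials)
  est <- online_estimator(priors, config, max_step = max_step)
  n <- nrow(trials)
  reward <- logical(n)
  bnd <- numeric(n)
  for (i in seq_len(n)) {
    b <- est$observe(trials$condition[i], trials$omega_deg[i], trials$choice[i])
    bi <- b[[trials$condition[i]]]
    reward[i] <- decide_reward(trials$choice[i], trials$omega_deg[i], bi)
    bnd[i] <- bi
  }
  if (length(est$refit_seconds) && max(est$refit_seconds) > latency_budget)
    warning(sprintf("slowest refit took %.2f s, over the %.2f s latency budget",
                    max(est$refit_seconds), latency_budget))
  out <- trials
  out$reward_replayed <- as.integer(reward)
  out$boundary_deg <- bnd
  list(trials = out, trace = est$get_trace(), posterior = est$posterior())
}
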