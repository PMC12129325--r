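#' Criterion-learning agent configuration
#'
#' The agent perceives each stimulus with its context's perceptual bias
#' plus Gaussian internal noise, chooses by MAP against a decision
#' criterion, and updates the criterion from reward feedback with the
#' sign-simplified temporal-difference rule (see
#' \code{\link{update_criterion}}).  Defaults (learning rate 0.04 deg per
#' trial, internal noise 16 deg) approximate learning speeds and
#' psychometric slopes seen in trained macaques.
#'
#' Note the learning rate here is unrelated to the Gamma shape
#' hyperparameter of the sensory-noise prior; they live under different
#' config keys on purpose.
#'
#' @param alpha Learning rate, degrees per trial (>= 0).
#' @param Sigma Internal noise SD, degrees; scalar or per-condition
#'   (L, N, R).
#' @param criterion_mode \code{"independent"}: one criterion per
#'   condition; \code{"shared"}: a single criterion for all conditions.
#' @return An object of class \code{rl_agent_config}.
#' @export
rl_agent_config <- function(alpha = 0.04, Sigma = 16,
                            criterion_mode = c("independent", "shared")) {
  criterion_mode <- match.arg(criterion_mode)
  if (alpha < 0) stop("learning rate must be nonnegative")
  Sigma <- rep_len(Sigma, 3)
  if (any(Sigma <= 0)) stop("internal noise must be positive")
  structure(list(alpha = alpha, Sigma = Sigma,
                 criterion_mode = criterion_mode),
            class = "rl_agent_config")
}

#' Agent percept of a stimulus
#'
#' Gaussian draw centered on the stimulus shifted by the context's
#' perceptual bias: \eqn{\hat\omega \sim N(\omega - P_k, \Sigma_k)}.
#'
#' @param omega Stimulus, degrees.
#' @param P Perceptual bias of the trial's context, degrees.
#' @param Sigma Internal noise SD, degrees.
#' @return Perceived value(s), degrees.
#' @export
perceive <- function(omega, P, Sigma) {
  if (any(Sigma <= 0)) stop("internal noise must be positive")
  stats::rnorm(max(length(omega), length(P)), omega - P, Sigma)
}

#' MAP choice against a decision criterion
#'
#' @param omega_hat Perceived stimulus value, degrees.
#' @param psi Decision criterion, degrees.
#' @return +1 (right) if the percept is at or above the criterion, else
#'   -1 (left); the tie resolves rightward for determinism.
#' @export
choose_map <- function(omega_hat, psi) {
  if (any(!is.finite(omega_hat)) || any(!is.finite(psi))) stop("non-finite input")
  ifelse(omega_hat >= psi, 1, -1)
}

#' Agent's predicted reward probability
#'
#' The agent's confidence that its choice is correct:
#' \eqn{\hat\theta = \Phi((\hat\omega - \psi)/\Sigma)} and
#' \eqn{q = \max(\hat\theta, 1 - \hat\theta)}, computed from the
#' pre-update criterion.
#'
#' @param omega_hat Perceived value, degrees.
#' @param psi Decision criterion (pre-update), degrees.
#' @param Sigma Internal noise SD, degrees.
#' @return Confidence \eqn{q \in [0.5, 1]}.
#' @export
predicted_q <- function(omega_hat, psi, Sigma) {
  if (any(Sigma <= 0)) stop("internal noise must be positive")
  theta <- stats::pnorm((omega_hat - psi) / Sigma)
  pmax(theta, 1 - theta)
}

#' Temporal-difference criterion update
#'
#' \deqn{\psi_t = \psi_{t-1} - \alpha\, C\, (r - q)}
#' with signed choice \eqn{C \in \{-1, +1\}}, reward \eqn{r \in \{0, 1\}},
#' and confidence \eqn{q} from the pre-update criterion.  Because
#' \eqn{|r - q| \le 1}, no single trial moves the criterion by more than
#' \eqn{\alpha} degrees.
#'
#' @param psi Criterion before the update, degrees.
#' @param C Signed choice (-1 left, +1 right).
#' @param r Reward (0/1 or logical).
#' @param q Predicted reward probability, in \[0.5, 1].
#' @param alpha Learning rate, degrees per trial.
#' @return Updated criterion, degrees.
#' @export
update_criterion <- function(psi, C, r, q, alpha) {
  if (any(!C %in% c(-1, 1))) stop("C must be -1 or +1")
  if (any(q < 0.5 - 1e-12) || any(q > 1)) stop("q must lie in [0.5, 1]")
  psi - alpha * C * (as.numeric(r) - q)
}

.STRATEGY_CODE <- c(veridical = 0L, random_ambiguous = 1L,
                    always_ambiguous = 2L, never_ambiguous = 3L,
                    oracle = 4L)

# Ground-truth perceptual bias per trial and condition, as an n x 3 matrix
# (columns L, N, R); the neutral column is always zero.
.truth_matrix <- function(tg, truth, drift) {
  n <- length(tg)
  PL <- rep(truth$P_L, n)
  PR <- rep(truth$P_R, n)
  if (!is.null(drift)) {
    if (!is.null(drift$L)) PL <- perceptual_bias_at(tg, drift$L)
    if (!is.null(drift$R)) PR <- perceptual_bias_at(tg, drift$R)
  }
  cbind(PL, rep(0, n), PR)
}

# One estimated-strategy session driven in R: the agent chooses trial by
# trial while the online estimator refits per cadence and supplies the
# reward boundary.
.run_estimated_session <- function(design, Ptrue, psi, agent, est) {
  n <- nrow(design)
  shared <- agent$criterion_mode == "shared"
  kidx <- match(design$condition, .COND_LEVELS)
  choice <- integer(n)
  reward <- integer(n)
  for (i in seq_len(n)) {
    k <- kidx[i]
    om <- design$omega_deg[i]
    psi_k <- if (shared) psi[1] else psi[k]
    om_hat <- stats::rnorm(1, om - Ptrue[i, k], agent$Sigma[k])
    C <- if (om_hat >= psi_k) 1L else -1L
    b <- est$observe(design$condition[i], om,
                     if (C == 1L) "right" else "left")
    bk <- b[[design$condition[i]]]
    r <- as.integer(decide_reward(if (C == 1L) "right" else "left", om, bk))
    theta <- stats::pnorm((om_hat - psi_k) / agent$Sigma[k])
    q <- max(theta, 1 - theta)
    psi_new <- psi_k - agent$alpha * C * (r - q)
    if (shared) psi[] <- psi_new else psi[k] <- psi_new
    choice[i] <- C
    reward[i] <- r
  }
  list(choice = choice, reward = reward, psi = psi)
}

#' Simulate training experiments under a reward strategy
#'
#' Runs replicate multi-session training experiments of the
#' criterion-learning agent and summarizes each session by the learned
#' criteria and maximum-likelihood psychometric fits per condition.  This
#' is the test bed for comparing reward strategies: veridical and
#' ambiguous-trial strategies let the agent cancel its own perceptual
#' bias over sessions, while oracle and estimated-bias rewards keep the
#' measured biases at the truth.
#'
#' @param strategy A \code{\link{reward_strategy}} (or a kind string).
#' @param agent An \code{\link{rl_agent_config}}.
#' @param truth Ground-truth \code{\link{bias_set}}; the agent has no
#'   decision bias of its own, so \code{D} is typically 0 here.
#' @param n_sessions,n_reps Sessions per experiment and independent
#'   replicate experiments.
#' @param n_blocks,grid Session design (defaults: 30 blocks of the
#'   11-direction grid, i.e., 990 trials).
#' @param symmetric_grid If \code{TRUE}, each condition's stimulus grid is
#'   translated by its true perceptual bias, removing stimulus-range
#'   asymmetry around the reward boundary.
#' @param drift Optional list with \code{\link{gradual_change}} profiles
#'   for conditions \code{L} and/or \code{R}; trial indices are global
#'   across sessions.
#' @param estimator_opts For the \code{"estimated"} strategy: list with
#'   \code{priors} (\code{prior_spec}), \code{config}
#'   (\code{sampler_config}; reduced draws and cadence > 1 keep long runs
#'   tractable), \code{max_step}, and \code{prior_update}
#'   (\code{"none"} or \code{"hypermodel"} to refresh the session prior
#'   from all completed sessions of the same replicate).
#' @param seed Master seed, split per (replicate, session).
#' @param keep_psi If \code{TRUE}, attach the full criterion trajectories
#'   (one matrix per replicate) as attribute \code{"psi_trace"}.
#' @return Tidy data frame with one row per (rep, session, condition):
#'   \code{psi_end}, \code{B_hat}, \code{S_hat}, \code{identifiable},
#'   \code{reward_rate}, and for the estimated strategy the session-final
#'   posterior means \code{est_P}.
#' @export
run_rl_experiment <- function(strategy, agent = rl_agent_config(),
                              truth = bias_set(20, -10, 0),
                              n_sessions = 50, n_reps = 10,
                              n_blocks = 30, grid = seq(-40, 40, by = 8),
                              symmetric_grid = FALSE, drift = NULL,
                              estimator_opts = NULL, seed = 1,
                              keep_psi = FALSE) {
  if (is.character(strategy)) strategy <- reward_strategy(strategy)
  stopifnot(inherits(strategy, "reward_strategy"))
  estimated <- strategy$kind == "estimated"
  if (estimated && is.null(estimator_opts)) estimator_opts <- list()
  seeds <- matrix(split_seed(seed, n_reps * n_sessions), n_reps, n_sessions)
  centers <- if (symmetric_grid)
    c(L = truth$P_L, N = 0, R = truth$P_R) else NULL
  shared <- agent$criterion_mode == "shared"
  n_per_session <- n_blocks * length(grid) * 3
  rows <- vector("list", n_reps * n_sessions)
  psi_traces <- if (keep_psi) vector("list", n_reps) else NULL

  for (rep_i in seq_len(n_reps)) {
    psi <- c(0, 0, 0)
    session_stats <- NULL
    if (keep_psi)
      psi_traces[[rep_i]] <- matrix(NA_real_, n_sessions * n_per_session, 3)
    for (ses in seq_len(n_sessions)) {
      set.seed(seeds[rep_i, ses])
      design <- make_design(n_blocks, grid, centers = centers)
      tg <- design$t + (ses - 1) * n_per_session
      Ptrue <- .truth_matrix(tg, truth, drift)
      est_means <- c(P_L = NA_real_, P_R = NA_real_)
      if (!estimated) {
        res <- rl_session(design$omega_deg,
                          match(design$condition, .COND_LEVELS) - 1L,
                          Ptrue, psi, agent$alpha, agent$Sigma,
                          .STRATEGY_CODE[[strategy$kind]],
                          numeric(nrow(design)), strategy$random_prob,
                          shared)
        psi <- res$psi_end
        choice <- res$choice
        reward <- res$reward
        if (keep_psi)
          psi_traces[[rep_i]][(ses - 1) * n_per_session + seq_len(n_per_session), ] <-
            res$psi
      } else {
        priors_s <- estimator_opts$priors %||% prior_spec()
        if (identical(estimator_opts$prior_update, "hypermodel") &&
            !is.null(session_stats) && nrow(session_stats) >= 2) {
          hyper <- fit_hypermodel(session_stats,
                                  X = matrix(1, nrow(session_stats), 1),
                                  intercept = FALSE,
                                  seed = seeds[rep_i, ses])
          priors_s <- session_prior_from_hyper(hyper, 1)
          priors_s$S_shape <- (estimator_opts$priors %||% prior_spec())$S_shape
          priors_s$S_rate <- (estimator_opts$priors %||% prior_spec())$S_rate
        }
        cfg <- estimator_opts$config %||%
          sampler_config(n_draws = 1000, burn_in = 500, refit_cadence = 10)
        est <- online_estimator(priors_s, cfg,
                                max_step = estimator_opts$max_step %||% 1)
        res <- .run_estimated_session(design, Ptrue, psi, agent, est)
        psi <- res$psi
        choice <- res$choice
        reward <- res$reward
        fit <- est$posterior()
        if (!is.null(fit)) {
          est_means <- fit$means[c("P_L", "P_R")]
          session_stats <- rbind(session_stats, data.frame(
            P_L_mean = fit$means[["P_L"]], P_L_sd = fit$sds[["P_L"]],
            P_R_mean = fit$means[["P_R"]], P_R_sd = fit$sds[["P_R"]],
            D_mean = fit$means[["D"]], D_sd = fit$sds[["D"]]))
        }
      }
      choice_lab <- ifelse(choice > 0, "right", "left")
      out <- lapply(c("L", "N", "R"), function(kk) {
        sel <- design$condition == kk
        f <- fit_empirical_bias(design$omega_deg[sel], choice_lab[sel])
        data.frame(rep = rep_i, session = ses, condition = kk,
                   psi_end = if (shared) psi[1]
                             else psi[match(kk, .COND_LEVELS)],
                   B_hat = f$B, S_hat = f$S, identifiable = f$identifiable,
                   reward_rate = mean(reward[sel]),
                   est_P = if (kk == "L") est_means[["P_L"]]
                           else if (kk == "R") est_means[["P_R"]]
                           else NA_real_)
      })
      rows[[(rep_i - 1) * n_sessions + ses]] <- do.call(rbind, out)
    }
  }
  result <- do.call(rbind, rows)
  rownames(result) <- NULL
  if (keep_psi) attr(result, "psi_trace") <- psi_traces
  result
}

`%||%` <- function(a, b) if (is.null(a)) b else a
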