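# Componentwise adaptive random-walk Metropolis for small, cheap
# posteriors (hypermodel weights and scales).  Adaptation runs only
# during burn-in.
.mh_small <- function(logpost, init, scales, n_draws = 4000, burn_in = 1000) {
  p <- length(init)
  x <- init
  lsc <- log(scales)
  lp <- logpost(x)
  if (!is.finite(lp)) stop("initial point has zero posterior density")
  keep <- matrix(NA_real_, n_draws - burn_in, p)
  for (it in seq_len(n_draws)) {
    for (i in seq_len(p)) {
      cand <- x
      cand[i] <- x[i] + exp(lsc[i]) * stats::rnorm(1)
      lp_cand <- logpost(cand)
      acc <- is.finite(lp_cand) && log(stats::runif(1)) < lp_cand - lp
      if (acc) {
        x <- cand
        lp <- lp_cand
      }
      if (it <= burn_in)
        lsc[i] <- max(-10, min(5, lsc[i] + it^-0.6 * ((acc) - 0.44)))
    }
    if (it > burn_in) keep[it - burn_in, ] <- x
  }
  keep
}

.session_stats <- function(sessions) {
  if (is.data.frame(sessions)) return(sessions)
  do.call(rbind, lapply(sessions, function(f) {
    stopifnot(inherits(f, "posterior_summary"))
    data.frame(P_L_mean = f$means[["P_L"]], P_L_sd = f$sds[["P_L"]],
               P_R_mean = f$means[["P_R"]], P_R_sd = f$sds[["P_R"]],
               D_mean = f$means[["D"]], D_sd = f$sds[["D"]])
  }))
}

#' Fit the multi-session linear hypermodel
#'
#' Pools per-session bias posteriors across sessions whose task variables
#' (e.g., heading direction and eccentricity) vary, modeling each
#' perceptual bias as a linear function of the covariates:
#' \eqn{P \sim N(\beta^\top X, \sigma)}, with weakly informative
#' \eqn{N(0, 1000)} hyperpriors on each weight and on \eqn{\log\sigma}
#' (the log scale keeps \eqn{\sigma} positive).  The fit is the two-stage
#' empirical-Bayes path: per-session posterior means enter as
#' observations with their posterior SDs as known measurement error, so
#' the marginal likelihood of session \eqn{i} is
#' \eqn{N(\beta^\top X_i,\ \sqrt{\sigma^2 + se_i^2})}.
#'
#' The decision bias carries no covariate model; its session prior is
#' centered at zero with SD equal to the empirical SD of the per-session
#' decision-bias posterior means (floored at 2 deg so a run of lucky
#' sessions cannot collapse the prior).
#'
#' @param sessions Either a list of \code{posterior_summary} objects or a
#'   data frame with columns \code{P_L_mean}, \code{P_L_sd},
#'   \code{P_R_mean}, \code{P_R_sd}, \code{D_mean}, \code{D_sd}.
#' @param X Covariate matrix, one row per session (same column order for
#'   every session).
#' @param intercept Prepend an intercept column (default \code{TRUE}; a
#'   pure through-origin model cannot represent a context bias at zero
#'   heading).
#' @param n_draws,burn_in MCMC settings for the hypermodel posterior.
#' @param seed Optional seed.
#' @return An object of class \code{hyper_posterior} with draws, means
#'   and SDs for \eqn{\beta_L, \beta_R, \sigma_L, \sigma_R}, plus
#'   \code{tau_D}.
#' @export
fit_hypermodel <- function(sessions, X, intercept = TRUE,
                           n_draws = 4000, burn_in = 1000, seed = NULL) {
  stats_df <- .session_stats(sessions)
  n <- nrow(stats_df)
  if (n < 2) stop("need at least 2 sessions")
  X <- as.matrix(X)
  if (nrow(X) != n) stop("covariate rows must match sessions")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (intercept) X <- cbind(`(Intercept)` = 1, X)
  p <- ncol(X)
  if (qr(X)$rank < p)
    warning("singular covariate matrix: weights in the null space stay prior-dominated")
  if (!is.null(seed)) {
    had <- exists(".Random.seed", globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv())
    on.exit(if (had) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }

  fit_side <- function(m, se) {
    logpost <- function(par) {
      beta <- par[seq_len(p)]
      sigma <- exp(par[p + 1])
      sum(stats::dnorm(m, drop(X %*% beta), sqrt(sigma^2 + se^2), log = TRUE)) +
        sum(stats::dnorm(beta, 0, 1000, log = TRUE)) +
        stats::dnorm(par[p + 1], 0, 1000, log = TRUE)
    }
    ls <- stats::lsfit(X, m, intercept = FALSE)
    init <- c(ls$coefficients, log(max(stats::sd(ls$residuals), 1)))
    draws <- .mh_small(logpost, init, c(rep(2, p), 0.5), n_draws, burn_in)
    colnames(draws) <- c(colnames(X), "log_sigma")
    draws
  }
  dl <- fit_side(stats_df$P_L_mean, stats_df$P_L_sd)
  dr <- fit_side(stats_df$P_R_mean, stats_df$P_R_sd)
  summarize <- function(d) {
    beta <- d[, seq_len(p), drop = FALSE]
    sigma <- exp(d[, p + 1])
    list(beta_draws = beta, sigma_draws = sigma,
         beta_mean = colMeans(beta), beta_sd = apply(beta, 2, stats::sd),
         beta_ci95 = apply(beta, 2, stats::quantile, c(0.025, 0.975)),
         sigma_mean = mean(sigma))
  }
  structure(list(L = summarize(dl), R = summarize(dr),
                 tau_D = max(stats::sd(stats_df$D_mean), 2),
                 intercept = intercept, p = p,
                 covariates = colnames(X), n_sessions = n),
            class = "hyper_posterior")
}

#' @export
print.hyper_posterior <- function(x, ...) {
  cat(sprintf("hyper_posterior over %d sessions (%s)\n", x$n_sessions,
              paste(x$covariates, collapse = ", ")))
  cat("  beta_L:", paste(sprintf("%.3g", x$L$beta_mean), collapse = ", "),
      sprintf(" sigma_L: %.3g\n", x$L$sigma_mean))
  cat("  beta_R:", paste(sprintf("%.3g", x$R$beta_mean), collapse = ", "),
      sprintf(" sigma_R: %.3g\n", x$R$sigma_mean))
  cat(sprintf("  tau_D: %.3g\n", x$tau_D))
  invisible(x)
}

#' Session prior from the hypermodel
#'
#' Maps a new session's covariates through the fitted hypermodel:
#' perceptual-bias prior means are \eqn{\hat\beta^\top X}, prior SDs are
#' the posterior means of \eqn{\sigma}, and the decision-bias prior is
#' \eqn{N(0, \tau_D)}.
#'
#' Perceptual prior SDs are floored at \code{sd_floor} (default 1 deg):
#' with few sessions the residual scale \eqn{\sigma} can collapse toward
#' zero when the between-session scatter happens to fall below the
#' per-session measurement error, and a near-degenerate prior would pin
#' the next session's estimates to the regression prediction.
#'
#' @param hyper A \code{\link{fit_hypermodel}} result.
#' @param X Covariate vector for the new session (without the intercept
#'   term if the hypermodel added one).
#' @param base A \code{\link{prior_spec}} supplying the noise and lapse
#'   priors, which the hypermodel does not touch.
#' @param sd_floor Minimum perceptual-bias prior SD, degrees.
#' @return A \code{\link{prior_spec}} ready for
#'   \code{\link{fit_posterior}} or \code{\link{online_estimator}}.
#' @export
session_prior_from_hyper <- function(hyper, X, base = prior_spec(),
                                     sd_floor = 1) {
  stopifnot(inherits(hyper, "hyper_posterior"))
  x <- as.numeric(X)
  if (hyper$intercept) x <- c(1, x)
  if (length(x) != hyper$p) stop("covariate dimension mismatch")
  prior_spec(P_L_mean = sum(hyper$L$beta_mean * x),
             P_L_sd = max(hyper$L$sigma_mean, sd_floor),
             P_R_mean = sum(hyper$R$beta_mean * x),
             P_R_sd = max(hyper$R$sigma_mean, sd_floor),
             D_mean = 0, D_sd = hyper$tau_D,
             S_shape = base$S_shape, S_rate = base$S_rate,
             lapse_shape1 = base$lapse_shape1,
             lapse_shape2 = base$lapse_shape2)
}

#' Fit every session of a multi-session data set
#'
#' Convenience wrapper: runs \code{\link{fit_posterior}} on each
#' session's trials and returns the per-session posterior summaries plus
#' the stacked summary table \code{\link{fit_hypermodel}} consumes.
#'
#' @param session_list List of trial tables.
#' @param priors,config Passed to \code{\link{fit_posterior}}.
#' @return List with \code{fits} and \code{stats}.
#' @export
fit_sessions <- function(session_list, priors = prior_spec(),
                         config = sampler_config(n_draws = 2000,
                                                 burn_in = 1000)) {
  fits <- lapply(session_list, fit_posterior, priors = priors, config = config)
  list(fits = fits, stats = .session_stats(fits))
}
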