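#' Sampler configuration
#'
#' @param n_draws Total MCMC iterations per chain (default 5000).
#' @param burn_in Iterations discarded from the start of each chain
#'   (default 2500); proposal scales adapt only during burn-in, so the
#'   retained draws come from a fixed-kernel Metropolis chain.
#' @param n_chains Number of chains.  One chain is the online default;
#'   use 4 for offline validation so the split-chain convergence
#'   diagnostic has between-chain information.
#' @param seed Optional integer seed; chains use \code{seed + chain - 1}.
#' @param refit_cadence Trials between online posterior refits (default 1,
#'   i.e., refit after every trial once inference has started).
#' @param warm_start Whether online refits start from the previous
#'   posterior's final state and proposal scales.
#' @param rhat_threshold Split-chain convergence statistic above which a
#'   fit is flagged as non-converged.
#' @return An object of class \code{sampler_config}.
#' @export
sampler_config <- function(n_draws = 5000, burn_in = 2500, n_chains = 1,
                           seed = NULL, refit_cadence = 1, warm_start = TRUE,
                           rhat_threshold = 1.05) {
  if (burn_in < 0 || burn_in >= n_draws) stop("need 0 <= burn_in < n_draws")
  if (n_chains < 1) stop("need at least one chain")
  structure(list(n_draws = n_draws, burn_in = burn_in, n_chains = n_chains,
                 seed = seed, refit_cadence = refit_cadence,
                 warm_start = warm_start, rhat_threshold = rhat_threshold),
            class = "sampler_config")
}

.COND_LEVELS <- c("L", "N", "R")
.RAW_NAMES <- c("P_L", "P_R", "D", "logS_L", "logS_N", "logS_R",
                "lambda1_L", "lambda1_N", "lambda1_R",
                "lambda2_L", "lambda2_N", "lambda2_R")

.check_trials <- function(trials) {
  req <- c("condition", "omega_deg", "choice")
  miss <- setdiff(req, names(trials))
  if (length(miss)) stop("trials table lacks columns: ", paste(miss, collapse = ", "))
  bad <- which(!trials$condition %in% .COND_LEVELS)
  if (length(bad)) stop("unknown condition label in row(s) ",
                        paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(!trials$choice %in% c("left", "right"))
  if (length(bad)) stop("unknown choice label in row(s) ",
                        paste(utils::head(bad, 5), collapse = ", "))
  if (any(!is.finite(trials$omega_deg))) stop("non-finite stimulus value")
  invisible(trials)
}

# Aggregate trials to binomial counts per (condition, stimulus) cell.
.aggregate_trials <- function(trials) {
  k <- match(trials$condition, .COND_LEVELS) - 1L
  key <- paste(k, trials$omega_deg)
  right <- as.numeric(trials$choice == "right")
  n <- tapply(right, key, length)
  r <- tapply(right, key, sum)
  parts <- strsplit(names(n), " ", fixed = TRUE)
  list(cond = as.integer(vapply(parts, `[[`, "", 1L)),
       omega = as.numeric(vapply(parts, `[[`, "", 2L)),
       n = as.numeric(n), r = as.numeric(r))
}

.prior_clist <- function(priors, tied = TRUE, empirical = NULL) {
  if (is.null(empirical)) {
    list(bias_mean = c(priors$P_L_mean, priors$P_R_mean, priors$D_mean),
         bias_sd = c(priors$P_L_sd, priors$P_R_sd, priors$D_sd),
         bias_flat = priors$flat, flat_lo = -180, flat_hi = 180,
         gamma_shape = priors$S_shape, gamma_rate = priors$S_rate,
         beta_a = priors$lapse_shape1, beta_b = priors$lapse_shape2)
  } else {
    # untied slots are ordered (B_L, B_R, B_N)
    list(bias_mean = c(empirical$B_L$mean, empirical$B_R$mean, empirical$B_N$mean),
         bias_sd = c(empirical$B_L$sd, empirical$B_R$sd, empirical$B_N$sd),
         bias_flat = FALSE, flat_lo = -180, flat_hi = 180,
         gamma_shape = priors$S_shape, gamma_rate = priors$S_rate,
         beta_a = priors$lapse_shape1, beta_b = priors$lapse_shape2)
  }
}

.default_init <- function(clist) {
  biases <- if (clist$bias_flat) c(0, 0, 0) else clist$bias_mean
  c(biases, log(clist$gamma_shape / clist$gamma_rate),
    rep(stats::qlogis(clist$beta_a / (clist$beta_a + clist$beta_b)), 6))
}

.fix_vector <- function(fix) {
  fixed <- rep(FALSE, 12)
  vals <- rep(NA_real_, 12)
  if (is.null(fix)) return(list(fixed = fixed, vals = vals))
  if (!is.null(fix$S)) {
    fixed[4:6] <- TRUE
    vals[4:6] <- log(rep_len(fix$S, 3))
  }
  if (!is.null(fix$lapse)) {
    fixed[7:12] <- TRUE
    vals[7:12] <- stats::qlogis(pmax(rep_len(fix$lapse, 6), 1e-12))
  }
  list(fixed = fixed, vals = vals)
}

.transform_draws <- function(raw, tied) {
  out <- matrix(NA_real_, nrow(raw), 15)
  colnames(out) <- c("P_L", "P_R", "D", "B_L", "B_N", "B_R",
                     "S_L", "S_N", "S_R",
                     "lambda1_L", "lambda1_N", "lambda1_R",
                     "lambda2_L", "lambda2_N", "lambda2_R")
  if (tied) {
    out[, "P_L"] <- raw[, 1]; out[, "P_R"] <- raw[, 2]; out[, "D"] <- raw[, 3]
    out[, "B_L"] <- raw[, 1] + raw[, 3]
    out[, "B_N"] <- raw[, 3]
    out[, "B_R"] <- raw[, 2] + raw[, 3]
  } else {
    out[, "B_L"] <- raw[, 1]; out[, "B_R"] <- raw[, 2]; out[, "B_N"] <- raw[, 3]
    out[, "P_L"] <- raw[, 1] - raw[, 3]
    out[, "P_R"] <- raw[, 2] - raw[, 3]
    out[, "D"] <- raw[, 3]
  }
  out[, 7:9] <- exp(raw[, 4:6])
  out[, 10:15] <- stats::plogis(raw[, 7:12])
  out
}

# Evaluate expr under a temporary seed, restoring the caller's RNG
# stream afterwards so seeded fits never perturb surrounding simulations.
.with_preserved_rng <- function(expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

.run_chains <- function(agg, clist, tied, config, fix, state = NULL) {
  if (!is.null(config$seed))
    return(.with_preserved_rng(.run_chains_impl(agg, clist, tied, config,
                                                fix, state)))
  .run_chains_impl(agg, clist, tied, config, fix, state)
}

.run_chains_impl <- function(agg, clist, tied, config, fix, state = NULL) {
  fv <- .fix_vector(fix)
  init0 <- .default_init(clist)
  init0[fv$fixed] <- fv$vals[fv$fixed]
  scales0 <- c(rep(2, 3), rep(0.2, 3), rep(0.8, 6))
  raw <- vector("list", config$n_chains)
  finals <- NULL
  for (ch in seq_len(config$n_chains)) {
    if (!is.null(config$seed)) set.seed(config$seed + ch - 1L)
    init <- init0
    scales <- scales0
    adapt <- TRUE
    if (!is.null(state) && ch == 1L) {
      init <- state$final_x
      init[fv$fixed] <- fv$vals[fv$fixed]
      scales <- state$final_scales
    } else if (ch > 1L) {
      jitter <- c(stats::rnorm(3, 0, pmin(clist$bias_sd, 20)),
                  stats::rnorm(3, 0, 0.2), stats::rnorm(6, 0, 0.5))
      jitter[fv$fixed] <- 0
      init <- init + jitter
    }
    res <- mh_psychofit(agg$cond, agg$omega, agg$n, agg$r, clist, tied,
                        config$n_draws, config$burn_in, init, scales,
                        fv$fixed, adapt)
    raw[[ch]] <- res$draws
    if (ch == 1L) finals <- list(final_x = res$final_x,
                                 final_scales = res$final_scales,
                                 accept_rate = res$accept_rate)
  }
  list(raw = raw, state = finals)
}

# Effective sample size via Geyer's initial positive sequence.
.ess <- function(x) {
  n <- length(x)
  if (stats::var(x) == 0) return(n)
  lag_max <- min(n - 1, 500)
  rho <- stats::acf(x, lag.max = lag_max, plot = FALSE)$acf[-1]
  s <- 0
  i <- 1
  while (i < length(rho)) {
    pair <- rho[i] + rho[i + 1]
    if (pair < 0) break
    s <- s + pair
    i <- i + 2
  }
  n / (1 + 2 * s)
}

# Split-chain convergence statistic (each chain halved).
.split_rhat <- function(chains) {
  halves <- list()
  for (x in chains) {
    m <- length(x) %/% 2
    halves <- c(halves, list(x[1:m], x[(m + 1):(2 * m)]))
  }
  m <- length(halves)
  n <- length(halves[[1]])
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, stats::var, 0)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

.summarize_fit <- function(raw_list, tied, config, n_trials) {
  draws_list <- lapply(raw_list, .transform_draws, tied = tied)
  draws <- do.call(rbind, draws_list)
  pn <- colnames(draws)
  means <- colMeans(draws)
  sds <- apply(draws, 2, stats::sd)
  ci68 <- apply(draws, 2, stats::quantile, probs = c(0.16, 0.84))
  ci95 <- apply(draws, 2, stats::quantile, probs = c(0.025, 0.975))
  ess <- vapply(pn, function(p) sum(vapply(draws_list, function(d) .ess(d[, p]), 0)), 0)
  rhat <- vapply(pn, function(p) .split_rhat(lapply(draws_list, function(d) d[, p])), 0)
  core <- c("P_L", "P_R", "D", "S_L", "S_N", "S_R")
  converged <- all(rhat[core] < config$rhat_threshold, na.rm = TRUE)
  structure(list(draws = draws, means = means, sds = sds,
                 ci68 = ci68, ci95 = ci95, ess = ess, rhat = rhat,
                 converged = converged, n_trials_used = n_trials,
                 n_chains = config$n_chains,
                 n_kept = nrow(draws), seed = config$seed, tied = tied),
            class = "posterior_summary")
}

#' Fit the hierarchical observer model by MCMC
#'
#' Computes the joint posterior over the perceptual biases \eqn{P_L, P_R},
#' the shared decision bias \eqn{D}, the per-condition sensory noises
#' \eqn{S_k}, and the lapse rates, given 2AFC trials from the three
#' interleaved contexts.  The empirical bias of each condition is tied to
#' the latent biases (\eqn{B_L = P_L + D}, \eqn{B_N = D},
#' \eqn{B_R = P_R + D}), which is what lets the neutral condition anchor
#' the decision bias.  Sampling uses componentwise adaptive random-walk
#' Metropolis on unconstrained scales (log for noise SDs, logit for lapse
#' rates), with proposal scales adapted only during burn-in.
#'
#' @param trials Data frame with columns \code{condition}
#'   (\code{"L"}/\code{"N"}/\code{"R"}), \code{omega_deg}, and
#'   \code{choice} (\code{"left"}/\code{"right"}).
#' @param priors A \code{\link{prior_spec}}.
#' @param config A \code{\link{sampler_config}}.
#' @param fix Optional list to clamp parameters at known values, e.g.
#'   \code{list(S = 15, lapse = 0)}; clamped parameters are not sampled.
#' @param state Optional warm-start state (\code{final_x},
#'   \code{final_scales}) from a previous fit's \code{$state}.
#' @return A \code{posterior_summary}: transformed draws, posterior means,
#'   SDs, central 68\% and 95\% intervals, effective sample sizes, the
#'   split-chain convergence statistic, and a \code{converged} flag.  The
#'   warm-start state is attached as \code{$state}.
#' @export
fit_posterior <- function(trials, priors = prior_spec(),
                          config = sampler_config(), fix = NULL,
                          state = NULL) {
  .check_trials(trials)
  if (nrow(trials) == 0) stop("no trials to fit")
  if (!any(trials$condition == "N"))
    warning("no neutral trials: the decision bias posterior is prior-driven")
  agg <- .aggregate_trials(trials)
  clist <- .prior_clist(priors)
  run <- .run_chains(agg, clist, TRUE, config, fix,
                     state = if (isTRUE(config$warm_start)) state else NULL)
  out <- .summarize_fit(run$raw, TRUE, config, nrow(trials))
  out$state <- run$state
  if (!out$converged)
    warning("convergence statistic above threshold; treat this fit with caution")
  out
}

#' Flat-prior (maximum-likelihood-like) fit
#'
#' Identical model to \code{\link{fit_posterior}} but with the three bias
#' priors replaced by Uniform(-180, 180); with enough data the posterior
#' means approach the maximum-likelihood estimates.
#'
#' @inheritParams fit_posterior
#' @return A \code{posterior_summary}.
#' @export
fit_flat <- function(trials, priors = prior_spec(), config = sampler_config(),
                     fix = NULL, state = NULL) {
  fit_posterior(trials, flat_priors(priors), config, fix, state)
}

#' Empirical-bias-prior baseline fit
#'
#' The comparison estimator: each condition's psychometric function is fit
#' with a Gaussian prior on its own empirical bias only (no cross-condition
#' tying), as an off-the-shelf Bayesian psychometric package would do.
#' Perceptual biases are then recovered by subtracting the neutral
#' condition draw-wise: \eqn{P_L = B_L - B_N}, \eqn{P_R = B_R - B_N}
#' (the three condition posteriors are independent, so variances add).
#' Matched empirical-bias priors are typically built with
#' \code{\link{convolve_bias_priors}}.
#'
#' @inheritParams fit_posterior
#' @param empirical_priors List with elements \code{B_L}, \code{B_N},
#'   \code{B_R}, each a list with \code{mean} and \code{sd}.
#' @return A \code{posterior_summary} (untied model).
#' @export
fit_baseline_empirical <- function(trials, empirical_priors,
                                   priors = prior_spec(),
                                   config = sampler_config(), fix = NULL,
                                   state = NULL) {
  .check_trials(trials)
  stopifnot(all(c("B_L", "B_N", "B_R") %in% names(empirical_priors)))
  agg <- .aggregate_trials(trials)
  clist <- .prior_clist(priors, tied = FALSE, empirical = empirical_priors)
  run <- .run_chains(agg, clist, FALSE, config, fix,
                     state = if (isTRUE(config$warm_start)) state else NULL)
  out <- .summarize_fit(run$raw, FALSE, config, nrow(trials))
  out$state <- run$state
  out
}

#' @export
print.posterior_summary <- function(x, ...) {
  core <- c("P_L", "P_R", "D", "S_L", "S_N", "S_R")
  cat(sprintf("posterior_summary: %d trials, %d draws (%d chain%s)%s\n",
              x$n_trials_used, x$n_kept, x$n_chains,
              if (x$n_chains > 1) "s" else "",
              if (x$converged) "" else "  [NOT CONVERGED]"))
  tab <- data.frame(mean = round(x$means[core], 2),
                    sd = round(x$sds[core], 2),
                    `q16` = round(x$ci68[1, core], 2),
                    `q84` = round(x$ci68[2, core], 2),
                    ess = round(x$ess[core]),
                    rhat = round(x$rhat[core], 3))
  print(tab)
  invisible(x)
}

#' Serialize a posterior summary to JSON
#'
#' Writes means, SDs, intervals and diagnostics (not the raw draws) to a
#' JSON file; optionally writes the draws to a CSV alongside.
#'
#' @param x A \code{posterior_summary}.
#' @param path Output JSON path.
#' @param draws_csv Optional CSV path for the raw draws.
#' @return \code{path}, invisibly.
#' @export
write_posterior_json <- function(x, path, draws_csv = NULL) {
  stopifnot(inherits(x, "posterior_summary"))
  obj <- list(means = as.list(x$means), sds = as.list(x$sds),
              ci68 = apply(x$ci68, 2, as.list), ci95 = apply(x$ci95, 2, as.list),
              ess = as.list(round(x$ess, 1)), rhat = as.list(round(x$rhat, 4)),
              converged = x$converged, n_trials_used = x$n_trials_used,
              n_kept = x$n_kept, n_chains = x$n_chains, seed = x$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(draws_csv))
    utils::write.csv(as.data.frame(x$draws), draws_csv, row.names = FALSE)
  invisible(path)
}
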