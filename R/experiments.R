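#' Run a canned simulation experiment
#'
#' Reproduces the package's standard simulation protocols at configurable
#' scale and writes tidy CSV outputs plus a JSON manifest (full config,
#' seeds, package version) so every output is regenerable from the
#' manifest alone.  Available experiments:
#' \describe{
#'   \item{\code{strategy_comparison}}{Strategy-comparison training run of the
#'     criterion-learning agent (per-session criteria and fitted
#'     empirical biases).}
#'   \item{\code{recovery}}{Ground-truth recovery: replicate
#'     990-trial sessions with the stationary reference parameter set,
#'     full posterior fits, truth vs posterior means.}
#'   \item{\code{shrinkage}}{Prior-width sweep: posterior means
#'     after 100 trials under mismatched priors of varying SD.}
#'   \item{\code{drift}}{Slowly decaying perceptual biases tracked by
#'     the estimated-bias reward method with hypermodel prior updates.}
#'   \item{\code{sequential}}{Recovery with and without win-stay /
#'     lose-shift sequential choice effects on matched seeds.}
#'   \item{\code{online_session}}{Replay a recorded trials CSV through
#'     the online estimator (requires \code{trials_csv}; optional
#'     \code{priors_yaml}).}
#' }
#'
#' @param experiment Experiment name (see above).
#' @param out_dir Output directory (created if missing).
#' @param seed Master seed.
#' @param reps,sessions,draws,cadence Scale factors; defaults are modest
#'   desk-scale settings, not the full reference scale.
#' @param strategy Reward strategy kind for \code{strategy_comparison}.
#' @param trials_csv,priors_yaml Inputs for \code{online_session}.
#' @return Invisibly, a list of the files written.
#' @export
run_canned_experiment <- function(experiment, out_dir = ".", seed = 1,
                                  reps = 3, sessions = 10, draws = 2000,
                                  cadence = 10, strategy = "veridical",
                                  trials_csv = NULL, priors_yaml = NULL) {
  known <- c("strategy_comparison", "recovery", "shrinkage", "drift",
             "sequential", "online_session")
  if (!experiment %in% known)
    stop("unknown experiment '", experiment, "'; choose one of: ",
         paste(known, collapse = ", "))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  cfg <- list(experiment = experiment, seed = seed, reps = reps,
              sessions = sessions, draws = draws, cadence = cadence,
              strategy = strategy,
              package_version = as.character(utils::packageVersion("perceptbias")))
  files <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE, na = "NA")
    files <<- c(files, path)
    path
  }

  if (experiment == "strategy_comparison") {
    res <- run_rl_experiment(strategy, n_sessions = sessions, n_reps = reps,
                             seed = seed)
    emit(res, sprintf("strategy_%s_sessions.csv", strategy))
  } else if (experiment == "recovery") {
    truth <- bias_set(20, -10, 10)
    seeds <- split_seed(seed, reps)
    rows <- lapply(seq_len(reps), function(i) {
      trials <- simulate_session(make_design(seed = seeds[i]), truth,
                                 S = 15, seed = seeds[i] + 1L)
      fit <- fit_posterior(trials,
                           prior_spec(P_L_mean = 20, P_R_mean = -10,
                                      D_mean = 10),
                           sampler_config(n_draws = draws,
                                          burn_in = draws %/% 2,
                                          seed = seeds[i]))
      data.frame(rep = i, P_L = fit$means[["P_L"]], P_R = fit$means[["P_R"]],
                 D = fit$means[["D"]], S_N = fit$means[["S_N"]],
                 truth_P_L = truth$P_L, truth_P_R = truth$P_R,
                 truth_D = truth$D)
    })
    emit(do.call(rbind, rows), "recovery.csv")
  } else if (experiment == "shrinkage") {
    truth <- bias_set(20, -20, 10)
    widths <- c(0.1, 1, 2, 5, 10, 20)
    seeds <- split_seed(seed, reps * length(widths))
    i <- 0
    rows <- lapply(widths, function(w) do.call(rbind, lapply(seq_len(reps),
      function(r) {
        i <<- i + 1
        design <- make_design(n_blocks = 4, seed = seeds[i])
        trials <- simulate_session(design[design$t <= 100, ], truth, S = 15,
                                   seed = seeds[i] + 1L)
        fit <- fit_posterior(trials,
                             prior_spec(P_L_mean = 10, P_L_sd = w,
                                        P_R_mean = -10, P_R_sd = w,
                                        D_mean = 0, D_sd = w),
                             sampler_config(n_draws = draws,
                                            burn_in = draws %/% 2,
                                            seed = seeds[i]))
        data.frame(prior_sd = w, rep = r, P_L = fit$means[["P_L"]],
                   P_R = fit$means[["P_R"]], D = fit$means[["D"]])
      })))
    emit(do.call(rbind, rows), "shrinkage.csv")
  } else if (experiment == "drift") {
    drift <- list(L = gradual_change(20, 3, 10 * 990, 41 * 990),
                  R = gradual_change(-10, 3, 10 * 990, 41 * 990))
    res <- run_rl_experiment(
      "estimated", rl_agent_config(alpha = 0.0004),
      truth = bias_set(20, -10, 0), n_sessions = sessions, n_reps = reps,
      drift = drift,
      estimator_opts = list(
        priors = prior_spec(P_L_mean = 20, P_R_mean = -10),
        config = sampler_config(n_draws = draws, burn_in = draws %/% 2,
                                refit_cadence = cadence),
        prior_update = "hypermodel"),
      seed = seed)
    emit(res, "drift_sessions.csv")
  } else if (experiment == "sequential") {
    truth <- bias_set(20, -10, 10)
    seeds <- split_seed(seed, reps)
    rows <- lapply(seq_len(reps), function(i) do.call(rbind, lapply(
      c(0, 0.25), function(tse) {
        design <- make_design(seed = seeds[i])
        trials <- simulate_session(design, truth, S = 15, T_se = tse,
                                   seed = seeds[i] + 1L)
        fit <- fit_posterior(trials,
                             prior_spec(P_L_mean = 20, P_R_mean = -10,
                                        D_mean = 10),
                             sampler_config(n_draws = draws,
                                            burn_in = draws %/% 2,
                                            seed = seeds[i]))
        data.frame(rep = i, T_se = tse, P_L = fit$means[["P_L"]],
                   P_R = fit$means[["P_R"]], D = fit$means[["D"]],
                   sd_P_L = fit$sds[["P_L"]], sd_P_R = fit$sds[["P_R"]])
      })))
    emit(do.call(rbind, rows), "sequential.csv")
  } else if (experiment == "online_session") {
    if (is.null(trials_csv)) stop("online_session requires trials_csv")
    trials <- read_trials(trials_csv)
    priors <- if (is.null(priors_yaml)) prior_spec()
              else read_prior_spec(priors_yaml)
    res <- replay_session(trials, priors,
                          sampler_config(n_draws = draws,
                                         burn_in = draws %/% 2,
                                         refit_cadence = cadence,
                                         seed = seed))
    emit(res$trials, "online_trials.csv")
    emit(res$trace, "online_trace.csv")
    pj <- file.path(out_dir, "online_posterior.json")
    write_posterior_json(res$posterior, pj)
    files <- c(files, pj)
  }

  manifest <- file.path(out_dir, paste0(experiment, "_manifest.json"))
  jsonlite::write_json(cfg, manifest, auto_unbox = TRUE, pretty = TRUE)
  files <- c(files, manifest)
  invisible(files)
}
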