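#' Block-randomized session design
#'
#' Builds the stimulus order for one session: every block presents each
#' (stimulus direction x condition) pair exactly once in a fresh random
#' order, so condition counts are exactly balanced per block and per
#' session.  Defaults give 30 blocks x 11 directions (-40 to +40 deg in
#' 8-deg steps) x 3 conditions = 990 trials.
#'
#' @param n_blocks Number of blocks.
#' @param grid Stimulus directions in degrees, strictly increasing.
#' @param conditions Condition labels (fixed to L/N/R ordering).
#' @param centers Optional named offsets (\code{L}, \code{N}, \code{R})
#'   added to the grid per condition; used for the symmetric-grid variant
#'   in which each condition's stimuli are centered on its true bias.
#' @param seed Optional seed for the block permutations.
#' @return Data frame with columns \code{t}, \code{block},
#'   \code{condition}, \code{omega_deg}.
#' @export
make_design <- function(n_blocks = 30, grid = seq(-40, 40, by = 8),
                        conditions = c("L", "N", "R"), centers = NULL,
                        seed = NULL) {
  if (length(grid) == 0) stop("empty stimulus grid")
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be strictly increasing")
  if (!is.null(seed)) set.seed(seed)
  cells <- expand.grid(omega_deg = grid, condition = conditions,
                       stringsAsFactors = FALSE)
  if (!is.null(centers))
    cells$omega_deg <- cells$omega_deg + unname(centers[cells$condition])
  blocks <- lapply(seq_len(n_blocks), function(b) {
    perm <- cells[sample.int(nrow(cells)), ]
    perm$block <- b
    perm
  })
  out <- do.call(rbind, blocks)
  out$t <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("t", "block", "condition", "omega_deg")]
}

#' Sinusoidal decision-bias drift
#'
#' Within-session drift profile used to probe robustness to a
#' non-stationary decision bias: \eqn{D_n = A \sin(\pi n / T)} with
#' defaults \eqn{A = 10} deg, \eqn{T = 2000} trials.
#'
#' @param n Trial index (0-based in the profile's own convention).
#' @param amplitude Peak decision bias, degrees.
#' @param period Half-period scale in trials.
#' @return Decision bias at trial \code{n}, degrees.
#' @export
decision_bias_at <- function(n, amplitude = 10, period = 2000) {
  if (any(n < 0)) stop("trial index must be nonnegative")
  amplitude * sin(pi * n / period)
}

#' Piecewise-linear gradual change specification
#'
#' Describes a perceptual bias that holds at \code{P0} until trial
#' \code{t_b1}, decreases linearly to \code{P0 / s} between \code{t_b1}
#' and \code{t_b2}, and stays at \code{P0 / s} afterwards.  In the
#' multi-session drift scenario the change spans sessions 11 through 41
#' of 990-trial sessions, i.e. \code{t_b1 = 10 * 990} and
#' \code{t_b2 = 41 * 990}.
#'
#' @param P0 Initial bias, degrees.
#' @param s Steepness factor (>= 1); the plateau is \code{P0 / s}.
#' @param t_b1,t_b2 Trial indices bounding the change, \code{t_b1 < t_b2}.
#' @return An object of class \code{gradual_change}.
#' @export
gradual_change <- function(P0, s = 3, t_b1 = 10 * 990, t_b2 = 41 * 990) {
  if (t_b1 >= t_b2) stop("need t_b1 < t_b2")
  if (s < 1) stop("steepness factor must be >= 1")
  structure(list(P0 = P0, s = s, t_b1 = t_b1, t_b2 = t_b2),
            class = "gradual_change")
}

#' Evaluate a gradual-change bias profile
#'
#' @param t Trial index (vectorized).
#' @param spec A \code{\link{gradual_change}}.
#' @return Perceptual bias at trial \code{t}, degrees.
#' @export
perceptual_bias_at <- function(t, spec) {
  stopifnot(inherits(spec, "gradual_change"))
  frac <- (t - spec$t_b1) / (spec$t_b2 - spec$t_b1)
  mid <- spec$P0 - (spec$s - 1) * spec$P0 / spec$s * frac
  ifelse(t <= spec$t_b1, spec$P0,
         ifelse(t >= spec$t_b2, spec$P0 / spec$s, mid))
}

#' Win-stay / lose-shift override of a candidate choice
#'
#' With probability \code{T_se} the subject ignores the stimulus and
#' repeats the previous choice if it was rewarded, or switches to the
#' alternative if it was not; otherwise the stimulus-driven candidate
#' choice stands.  The first trial of a session passes through.
#'
#' @param candidate_choice Stimulus-driven choice (\code{"left"}/\code{"right"}).
#' @param prev_choice,prev_reward Previous trial's choice and reward flag
#'   (\code{NA} on the first trial).
#' @param T_se Probability of applying the history-based strategy.
#' @return The final choice.
#' @export
apply_sequential_effect <- function(candidate_choice, prev_choice,
                                    prev_reward, T_se) {
  if (T_se < 0 || T_se > 1) stop("T_se must be in [0, 1]")
  if (is.na(prev_choice) || is.na(prev_reward) || T_se == 0)
    return(candidate_choice)
  if (stats::runif(1) >= T_se) return(candidate_choice)
  if (prev_reward) prev_choice
  else if (prev_choice == "right") "left" else "right"
}

#' Simulate choices for one session from the observer model
#'
#' Generates a choice for every design trial via the psychometric
#' function, with the empirical bias of condition \eqn{k} equal to
#' \eqn{P_k + D}.  Biases may drift: \code{D_fun} maps a global trial
#' index to the decision bias, and \code{P_fun(t, condition)} to the
#' perceptual bias (the neutral condition always has perceptual bias 0).
#' Optionally applies a win-stay/lose-shift sequential effect, in which
#' case rewards are needed trial-by-trial and are generated relative to
#' the ground-truth perceptual bias boundaries.
#'
#' @param design A design from \code{\link{make_design}}.
#' @param truth A \code{\link{bias_set}} with the stationary ground truth.
#' @param S Sensory noise, degrees; scalar or named per-condition vector.
#' @param lapse Length-2 lapse rates \code{c(lambda1, lambda2)}; the
#'   generator default is zero lapses.
#' @param D_fun,P_fun Optional drift profiles (see above); trial indices
#'   passed to them are \code{t + t_offset}.
#' @param t_offset Global trial offset, for multi-session drift schedules.
#' @param T_se Sequential-effect probability (0 disables; 0.25 is the
#'   reference non-extreme setting).
#' @param seed Optional seed.
#' @return The design with added columns \code{choice}, \code{reward}
#'   (NA unless a sequential effect forced reward generation), and the
#'   generating \code{B_true}.
#' @export
simulate_session <- function(design, truth, S = 15, lapse = c(0, 0),
                             D_fun = NULL, P_fun = NULL, t_offset = 0,
                             T_se = 0, seed = NULL) {
  stopifnot(inherits(truth, "bias_set"))
  if (!is.null(seed)) set.seed(seed)
  S <- if (length(S) == 1) c(L = S, N = S, R = S) else S
  n <- nrow(design)
  tg <- design$t + t_offset
  P <- ifelse(design$condition == "L", truth$P_L,
              ifelse(design$condition == "R", truth$P_R, 0))
  if (!is.null(P_fun)) {
    drift <- vapply(seq_len(n), function(i) P_fun(tg[i], design$condition[i]), 0)
    P <- ifelse(design$condition == "N", 0, drift)
  }
  D <- if (is.null(D_fun)) rep(truth$D, n) else D_fun(tg)
  B <- P + D
  theta <- choice_prob(design$omega_deg, B, unname(S[design$condition]),
                       lapse[1], lapse[2])
  out <- design
  out$B_true <- B
  if (T_se == 0) {
    out$choice <- sample_choice(theta)
    out$reward <- NA_integer_
  } else {
    choice <- character(n)
    reward <- integer(n)
    prev_choice <- NA_character_
    prev_reward <- NA
    for (i in seq_len(n)) {
      cand <- sample_choice(theta[i])
      choice[i] <- apply_sequential_effect(cand, prev_choice, prev_reward, T_se)
      bnd <- if (design$condition[i] == "L") P[i]
             else if (design$condition[i] == "R") P[i] else 0
      reward[i] <- as.integer(decide_reward(choice[i], design$omega_deg[i], bnd))
      prev_choice <- choice[i]
      prev_reward <- reward[i] == 1L
    }
    out$choice <- choice
    out$reward <- reward
  }
  out
}

#' Derive per-session and per-trial seeds from a master seed
#'
#' One master seed per experiment is split deterministically into
#' independent substream seeds, so any session can be regenerated in
#' isolation.
#'
#' @param master Master seed (integer).
#' @param n Number of substream seeds.
#' @return Integer vector of \code{n} seeds, each below 2^31.
#' @export
split_seed <- function(master, n) {
  set.seed(master)
  sample.int(.Machine$integer.max - 1L, n)
}

.TRIALS_COLS <- c("session_id", "t", "condition", "omega_deg", "choice",
                  "reward", "boundary_deg")

#' Read / write / validate trial tables
#'
#' Trials serialize to a headered CSV with columns \code{session_id},
#' \code{t}, \code{condition} (L/N/R), \code{omega_deg}, \code{choice}
#' (left/right), \code{reward} (0/1/NA), \code{boundary_deg} (float/NA);
#' comma-separated, UTF-8, "." decimal, NA for missing, degrees
#' everywhere.
#'
#' @param trials Trial table; missing optional columns are filled with NA.
#' @param path CSV path.
#' @return \code{read_trials} returns the validated data frame;
#'   \code{write_trials} returns \code{path} invisibly.
#' @export
write_trials <- function(trials, path) {
  for (col in .TRIALS_COLS) if (is.null(trials[[col]])) trials[[col]] <- NA
  utils::write.csv(trials[, .TRIALS_COLS], path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  trials <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_trials(trials)
}

#' @rdname write_trials
#' @export
validate_trials <- function(trials) {
  miss <- setdiff(c("t", "condition", "omega_deg", "choice"), names(trials))
  if (length(miss))
    stop("trial table lacks required column(s): ", paste(miss, collapse = ", "))
  .check_trials(trials)
  if (any(!is.finite(trials$t)) || any(trials$t <= 0))
    stop("trial indices must be positive")
  if (!is.null(trials$session_id)) {
    for (sid in unique(trials$session_id)) {
      tt <- trials$t[trials$session_id == sid | is.na(trials$session_id)]
      if (any(diff(tt) <= 0))
        stop("trial index must be strictly increasing within session ", sid)
    }
  }
  trials
}
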