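#' Reward decision relative to a boundary
#'
#' A choice is rewarded when it falls on the correct side of the reward
#' boundary: left choices for stimuli left of the boundary, right choices
#' for stimuli right of it.  A stimulus exactly on the boundary is
#' rewarded regardless of choice (deterministic tie-break; exact ties have
#' measure zero when boundaries come from continuous posteriors).
#'
#' @param choice \code{"left"} or \code{"right"} (vectorized).
#' @param omega Stimulus value(s), degrees.
#' @param boundary Reward boundary, degrees.
#' @return Logical: reward delivered.
#' @export
decide_reward <- function(choice, omega, boundary) {
  if (any(!is.finite(omega)) || any(!is.finite(boundary)))
    stop("omega and boundary must be finite")
  (choice == "left" & omega < boundary) |
    (choice == "right" & omega > boundary) |
    omega == boundary
}

#' Is a trial ambiguous under conventional rewarding?
#'
#' A biased-context trial is ambiguous when its stimulus lies in the
#' closed interval between the veridical boundary (0) and that context's
#' ground-truth perceptual bias, so the "correct" answer is undefined.
#' Neutral-context trials are never ambiguous.  Ground truth is only
#' available in simulation.
#'
#' @param omega Stimulus value(s), degrees.
#' @param condition Condition label(s): \code{"L"}, \code{"N"}, \code{"R"}.
#' @param truth A \code{\link{bias_set}} with the ground-truth biases.
#' @return Logical.
#' @export
is_ambiguous <- function(omega, condition, truth) {
  stopifnot(inherits(truth, "bias_set"))
  P <- ifelse(condition == "L", truth$P_L,
              ifelse(condition == "R", truth$P_R, 0))
  condition != "N" & omega >= pmin(0, P) & omega <= pmax(0, P)
}

#' Reward strategy specification
#'
#' @param kind One of \code{"veridical"}, \code{"random_ambiguous"},
#'   \code{"always_ambiguous"}, \code{"never_ambiguous"}, \code{"oracle"},
#'   \code{"estimated"}.
#' @param random_prob Reward probability on ambiguous trials under
#'   \code{"random_ambiguous"} (default 0.5; other labs have used 0.8 or
#'   1.0, so it is configurable).
#' @return An object of class \code{reward_strategy}.
#' @export
reward_strategy <- function(kind = c("veridical", "random_ambiguous",
                                     "always_ambiguous", "never_ambiguous",
                                     "oracle", "estimated"),
                            random_prob = 0.5) {
  kind <- match.arg(kind)
  if (random_prob < 0 || random_prob > 1) stop("random_prob must be in [0, 1]")
  structure(list(kind = kind, random_prob = random_prob),
            class = "reward_strategy")
}

#' Per-condition reward boundary state with a step clamp
#'
#' Holds the current reward boundary for each biased condition.  Boundary
#' moves are clamped to \code{max_step} degrees per trial (a fail-safe so
#' a misaligned prior cannot jerk the boundary around early in a session);
#' the neutral condition's boundary is fixed at 0.
#'
#' @param boundary_L,boundary_R Initial boundaries, degrees (typically the
#'   prior means of the perceptual biases).
#' @param max_step Maximum boundary change per trial, degrees (default 1,
#'   i.e., 1 percent of an 80-degree stimulus range).
#' @return An object of class \code{reward_state}.
#' @export
reward_state <- function(boundary_L = 0, boundary_R = 0, max_step = 1) {
  stopifnot(is.finite(boundary_L), is.finite(boundary_R), max_step > 0)
  structure(list(boundary = c(L = boundary_L, N = 0, R = boundary_R),
                 max_step = max_step, last_update_trial = 0L),
            class = "reward_state")
}

#' Move a reward boundary toward a posterior-mean proposal
#'
#' The proposed boundary is the posterior mean of the condition's
#' perceptual bias (the decision-bias estimate is never added: the reward
#' boundary lives in stimulus coordinates around the task reference).
#' The applied boundary moves from its previous value toward the proposal
#' by at most \code{max_step} degrees.
#'
#' @param state A \code{\link{reward_state}}.
#' @param posterior A \code{posterior_summary}, or a named numeric vector
#'   containing \code{P_L} / \code{P_R} means (e.g., prior means before
#'   the first posterior is available).
#' @param condition \code{"L"} or \code{"R"}.
#' @param trial Trial index, recorded for bookkeeping.
#' @return The updated \code{reward_state}.
#' @export
update_boundary <- function(state, posterior, condition, trial = NA_integer_) {
  stopifnot(inherits(state, "reward_state"), condition %in% c("L", "R"))
  means <- if (inherits(posterior, "posterior_summary")) posterior$means else posterior
  proposal <- unname(means[[paste0("P_", condition)]])
  prev <- state$boundary[[condition]]
  delta <- max(min(proposal - prev, state$max_step), -state$max_step)
  state$boundary[[condition]] <- prev + delta
  state$last_update_trial <- trial
  state
}

#' Apply a reward strategy to one trial
#'
#' Dispatches on the strategy kind: \code{veridical} rewards relative to
#' boundary 0; \code{oracle} relative to the ground-truth perceptual bias
#' of the trial's condition; \code{estimated} relative to the current
#' boundary in \code{state}; the ambiguous variants behave veridically
#' outside the ambiguous band and reward always / never / with probability
#' \code{random_prob} inside it.
#'
#' @param strategy A \code{\link{reward_strategy}}.
#' @param choice,omega,condition The trial: choice label, stimulus
#'   (degrees), condition label.
#' @param truth Ground-truth \code{\link{bias_set}} (required by the
#'   oracle and ambiguity-based kinds; simulation only).
#' @param state A \code{\link{reward_state}} (required by
#'   \code{"estimated"}).
#' @return List with \code{reward} (logical) and \code{boundary} (degrees)
#'   actually used.
#' @export
strategy_reward <- function(strategy, choice, omega, condition,
                            truth = NULL, state = NULL) {
  stopifnot(inherits(strategy, "reward_strategy"))
  kind <- strategy$kind
  needs_truth <- kind %in% c("oracle", "random_ambiguous",
                             "always_ambiguous", "never_ambiguous")
  if (needs_truth && is.null(truth))
    stop("strategy '", kind, "' requires ground-truth biases")
  boundary <- switch(kind,
    veridical = 0,
    random_ambiguous = 0,
    always_ambiguous = 0,
    never_ambiguous = 0,
    oracle = if (condition == "L") truth$P_L
             else if (condition == "R") truth$P_R else 0,
    estimated = {
      if (is.null(state)) stop("strategy 'estimated' requires a reward_state")
      state$boundary[[condition]]
    })
  if (needs_truth && kind != "oracle" && is_ambiguous(omega, condition, truth)) {
    reward <- switch(kind,
      random_ambiguous = stats::runif(1) < strategy$random_prob,
      always_ambiguous = TRUE,
      never_ambiguous = FALSE)
    return(list(reward = reward, boundary = NA_real_))
  }
  list(reward = unname(decide_reward(choice, omega, boundary)),
       boundary = unname(boundary))
}
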