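#' Probability of a rightward choice under the observer model
#'
#' The psychometric function is a cumulative Gaussian with lapse asymptotes:
#' \deqn{\theta = \lambda_1 + (1 - \lambda_1 - \lambda_2)\,
#'   \Phi\!\left(\frac{\omega - B}{S}\right)}
#' where \eqn{B} is the empirical bias (the horizontal shift of the curve,
#' in degrees), \eqn{S > 0} the sensory noise (the SD of the underlying
#' Gaussian, in degrees), and \eqn{\lambda_1}, \eqn{\lambda_2} the lower and
#' upper lapse rates.  Angles are plain degrees with no wraparound; the
#' tasks this model targets span a few tens of degrees around a reference.
#'
#' @param omega Stimulus value(s) in degrees; positive means rightward of
#'   the reference.
#' @param bias Empirical bias \eqn{B} in degrees.
#' @param sigma Sensory noise \eqn{S} in degrees; must be positive.
#' @param lapse_low,lapse_high Lapse rates \eqn{\lambda_1}, \eqn{\lambda_2};
#'   each in \[0, 1) with \code{lapse_low + lapse_high < 1}.
#' @return Probability (or vector of probabilities) of a rightward choice,
#'   bounded by \code{lapse_low} and \code{1 - lapse_high}.
#' @examples
#' choice_prob(0, bias = 0, sigma = 15)          # 0.5 at the bias
#' choice_prob(15, bias = 0, sigma = 15)         # one noise-SD to the right
#' @export
choice_prob <- function(omega, bias, sigma, lapse_low = 0, lapse_high = 0) {
  if (any(!is.finite(omega))) stop("'omega' must be finite")
  if (any(!is.finite(sigma)) || any(sigma <= 0)) stop("'sigma' must be positive")
  if (lapse_low < 0 || lapse_low >= 1 || lapse_high < 0 || lapse_high >= 1 ||
      lapse_low + lapse_high >= 1)
    stop("lapse rates must lie in [0, 1) with lapse_low + lapse_high < 1")
  lapse_low + (1 - lapse_low - lapse_high) * stats::pnorm((omega - bias) / sigma)
}

#' Draw a binary choice from the Bernoulli observer
#'
#' @param theta Probability (or vector of probabilities) of a rightward
#'   choice, in \[0, 1].
#' @return Character vector of \code{"left"} / \code{"right"}.  Uses the
#'   session RNG, so results are reproducible under \code{set.seed()}.
#' @export
sample_choice <- function(theta) {
  if (any(!is.finite(theta)) || any(theta < 0) || any(theta > 1))
    stop("'theta' must lie in [0, 1]")
  ifelse(stats::runif(length(theta)) < theta, "right", "left")
}

#' Convert between choice codings
#'
#' Choices are stored as \code{"left"}/\code{"right"} strings in trial
#' tables, coded right = 1 / left = 0 for the Bernoulli observer model and
#' right = +1 / left = -1 for the criterion-learning agent.
#'
#' @param choice Character vector of \code{"left"}/\code{"right"}.
#' @param coding \code{"binary"} (right = 1, left = 0) or \code{"signed"}
#'   (right = +1, left = -1).
#' @return Numeric vector in the requested coding.
#' @export
choice_code <- function(choice, coding = c("binary", "signed")) {
  coding <- match.arg(coding)
  if (!all(choice %in% c("left", "right"))) stop("choices must be 'left' or 'right'")
  b <- as.numeric(choice == "right")
  if (coding == "binary") b else 2 * b - 1
}

#' Inverse of \code{choice_code}
#' @param x Numeric vector coded binary (0/1) or signed (-1/+1).
#' @return Character vector of \code{"left"}/\code{"right"}.
#' @export
choice_decode <- function(x) {
  if (!all(x %in% c(-1, 0, 1))) stop("unrecognized choice coding")
  ifelse(x > 0, "right", "left")
}

#' Bundle ground-truth or estimated biases
#'
#' A bias set holds the two context-specific perceptual biases and the
#' decision bias shared across contexts.  The empirical bias measured in
#' each context is their sum: \eqn{B_L = P_L + D}, \eqn{B_N = D},
#' \eqn{B_R = P_R + D}.
#'
#' @param P_L,P_R Perceptual biases (degrees) in the leftward- and
#'   rightward-context conditions.
#' @param D Decision bias (degrees), common to all three conditions.
#' @return An object of class \code{bias_set}.
#' @export
bias_set <- function(P_L, P_R, D) {
  vals <- c(P_L = P_L, P_R = P_R, D = D)
  if (any(!is.finite(vals))) stop("biases must be finite")
  structure(as.list(vals), class = "bias_set")
}

#' @export
print.bias_set <- function(x, ...) {
  cat(sprintf("bias_set: P_L = %g, P_R = %g, D = %g (deg)\n", x$P_L, x$P_R, x$D))
  invisible(x)
}

#' Empirical biases implied by a bias set
#'
#' @param biases A \code{\link{bias_set}}.
#' @return Named numeric vector \code{c(B_L, B_N, B_R)} in degrees.
#' @examples
#' empirical_biases(bias_set(P_L = 20, P_R = -10, D = 10))  # 30, 10, 0
#' @export
empirical_biases <- function(biases) {
  stopifnot(inherits(biases, "bias_set"))
  c(B_L = biases$P_L + biases$D, B_N = biases$D, B_R = biases$P_R + biases$D)
}

.neg_loglik_probit <- function(par, om, n, r) {
  th <- stats::pnorm((om - par[1]) / exp(par[2]))
  th <- pmin(pmax(th, 1e-12), 1 - 1e-12)
  -sum(r * log(th) + (n - r) * log1p(-th))
}

#' Maximum-likelihood psychometric fit for one condition
#'
#' Fits a lapse-free cumulative-Gaussian psychometric function by maximum
#' likelihood, returning the empirical bias and sensory noise.  The
#' optimizer is restarted from several bias values placed at quantiles of
#' the stimulus grid (sensory-noise starts at half and twice the grid span
#' over 10) and the best run is kept; on exactly tied likelihoods the
#' lowest bias estimate wins, so the fit is deterministic.  When all
#' choices are identical the bias is not identifiable; the fit then returns
#' the extreme grid value on the appropriate side, flagged
#' \code{identifiable = FALSE}.
#'
#' @param omega Stimulus values in degrees, one per trial.
#' @param choice Choices as \code{"left"}/\code{"right"} (or 0/1 coding).
#' @return List with elements \code{B}, \code{S} (degrees),
#'   \code{identifiable}, and \code{loglik}.
#' @export
fit_empirical_bias <- function(omega, choice) {
  if (is.character(choice) || is.factor(choice))
    choice <- choice_code(as.character(choice), "binary")
  if (length(omega) != length(choice)) stop("omega and choice lengths differ")
  if (length(unique(omega)) < 2) stop("need at least 2 distinct stimulus values")
  agg <- stats::aggregate(cbind(n = rep(1, length(omega)), r = choice),
                          by = list(om = omega), FUN = sum)
  if (all(agg$r == agg$n) || all(agg$r == 0)) {
    side <- if (all(agg$r == agg$n)) min(agg$om) else max(agg$om)
    return(list(B = side, S = NA_real_, identifiable = FALSE, loglik = 0))
  }
  span <- diff(range(agg$om))
  b_starts <- unname(stats::quantile(agg$om, c(0.25, 0.5, 0.75)))
  s_starts <- c(span / 20, span / 5)
  best <- NULL
  for (b0 in b_starts) for (s0 in s_starts) {
    fit <- stats::optim(c(b0, log(s0)), .neg_loglik_probit,
                        om = agg$om, n = agg$n, r = agg$r,
                        method = "Nelder-Mead",
                        control = list(maxit = 500, reltol = 1e-10))
    if (is.null(best) || fit$value < best$value - 1e-9 ||
        (abs(fit$value - best$value) <= 1e-9 && fit$par[1] < best$par[1]))
      best <- fit
  }
  list(B = best$par[1], S = exp(best$par[2]),
       identifiable = TRUE, loglik = -best$value)
}
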