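#' Prior specification for the hierarchical observer model
#'
#' Gaussian priors on the two perceptual biases and the decision bias,
#' Gamma priors (shape/rate) on the sensory-noise SDs (shared across the
#' three conditions by default, overridable per condition), and a shared
#' Beta prior on all lapse rates.  Setting \code{flat = TRUE} replaces the
#' three bias priors with Uniform(-180, 180), which makes the bias
#' estimates maximum-likelihood-like; the noise and lapse priors are kept.
#'
#' Defaults mirror a motion-discrimination training setting: sensory noise
#' Gamma(8, 0.5) (mean 16 deg, rate parameterization) and lapse
#' Beta(1, 10).
#'
#' @param P_L_mean,P_L_sd,P_R_mean,P_R_sd Gaussian prior on the
#'   leftward/rightward-context perceptual biases (degrees).
#' @param D_mean,D_sd Gaussian prior on the shared decision bias (degrees).
#' @param S_shape,S_rate Gamma prior on sensory noise; scalars are
#'   recycled across conditions, or supply length-3 vectors ordered
#'   (L, N, R).
#' @param lapse_shape1,lapse_shape2 Beta prior on every lapse rate.
#' @param flat If \code{TRUE}, bias priors are Uniform(-180, 180).
#' @return An object of class \code{prior_spec}.
#' @export
prior_spec <- function(P_L_mean = 0, P_L_sd = 5,
                       P_R_mean = 0, P_R_sd = 5,
                       D_mean = 0, D_sd = 10,
                       S_shape = 8, S_rate = 0.5,
                       lapse_shape1 = 1, lapse_shape2 = 10,
                       flat = FALSE) {
  S_shape <- rep_len(S_shape, 3)
  S_rate <- rep_len(S_rate, 3)
  sds <- c(P_L_sd, P_R_sd, D_sd)
  if (any(!is.finite(sds)) || any(sds <= 0)) stop("prior SDs must be positive")
  if (any(S_shape <= 0) || any(S_rate <= 0) || lapse_shape1 <= 0 || lapse_shape2 <= 0)
    stop("Gamma and Beta hyperparameters must be positive")
  structure(list(
    P_L_mean = P_L_mean, P_L_sd = P_L_sd,
    P_R_mean = P_R_mean, P_R_sd = P_R_sd,
    D_mean = D_mean, D_sd = D_sd,
    S_shape = S_shape, S_rate = S_rate,
    lapse_shape1 = lapse_shape1, lapse_shape2 = lapse_shape2,
    flat = isTRUE(flat)
  ), class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  if (x$flat) {
    cat("prior_spec: biases ~ Uniform(-180, 180)\n")
  } else {
    cat(sprintf("prior_spec: P_L ~ N(%g, %g), P_R ~ N(%g, %g), D ~ N(%g, %g)\n",
                x$P_L_mean, x$P_L_sd, x$P_R_mean, x$P_R_sd, x$D_mean, x$D_sd))
  }
  cat(sprintf("  S ~ Gamma(shape %s, rate %s); lapses ~ Beta(%g, %g)\n",
              paste(x$S_shape, collapse = "/"), paste(x$S_rate, collapse = "/"),
              x$lapse_shape1, x$lapse_shape2))
  invisible(x)
}

#' Flat-bias variant of a prior specification
#' @param priors A \code{\link{prior_spec}}; defaults keep the standard
#'   noise and lapse priors.
#' @return The same specification with \code{flat = TRUE}.
#' @export
flat_priors <- function(priors = prior_spec()) {
  priors$flat <- TRUE
  priors
}

#' Prior over an empirical bias from perceptual and decision priors
#'
#' The empirical bias is the sum of independent Gaussian perceptual and
#' decision biases, so its prior is Gaussian with the summed mean and
#' root-sum-square SD.  This is the construction used to hand matched
#' priors to an estimator that can only place priors on empirical biases.
#'
#' @param perc_mean,perc_sd Gaussian prior on the perceptual bias.
#' @param dec_mean,dec_sd Gaussian prior on the decision bias.
#' @return List with \code{mean} and \code{sd} of the empirical-bias prior.
#' @examples
#' convolve_bias_priors(20, 10, 10, 10)  # mean 30, sd sqrt(200)
#' @export
convolve_bias_priors <- function(perc_mean, perc_sd, dec_mean, dec_sd) {
  if (perc_sd < 0 || dec_sd < 0) stop("prior SDs must be nonnegative")
  list(mean = perc_mean + dec_mean, sd = sqrt(perc_sd^2 + dec_sd^2))
}

#' Read / write a prior specification as YAML
#'
#' Every hyperparameter of \code{\link{prior_spec}} appears under an
#' explicit key, so configs are self-documenting.
#'
#' @param path File path.
#' @param priors A \code{prior_spec} (for writing).
#' @return \code{read_prior_spec} returns a \code{prior_spec};
#'   \code{write_prior_spec} returns \code{path} invisibly.
#' @export
read_prior_spec <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(prior_spec, cfg)
}

#' @rdname read_prior_spec
#' @export
write_prior_spec <- function(priors, path) {
  stopifnot(inherits(priors, "prior_spec"))
  yaml::write_yaml(unclass(priors), path)
  invisible(path)
}
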