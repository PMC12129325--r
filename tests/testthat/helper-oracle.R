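# Independent brute-force oracles.  These never call the package's
# sampler: the grid posterior integrates the likelihood directly on a
# lattice, and the CDF oracle integrates the normal density numerically.

# Standard normal CDF by numerical integration of the density.
phi_oracle <- function(z) {
  vapply(z, function(zz)
    stats::integrate(function(x) exp(-x^2 / 2) / sqrt(2 * pi),
                     -Inf, zz, rel.tol = 1e-10)$value, 0)
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Exact (lattice) posterior over (P_L, P_R, D) with sensory noise and
# lapses fixed.  Exploits the conditional factorization given D: the
# L-condition likelihood depends on P_L + D only, the R-condition on
# P_R + D, and the neutral condition on D, so marginals reduce to sums
# over two nested lattices.
grid_posterior_biases <- function(trials, lattice, S = 15, lapse = 0,
                                  priors = NULL) {
  stopifnot(!is.unsorted(lattice))
  cond_ll_on <- function(kk, Bvec) {
    sel <- trials$condition == kk
    om <- trials$omega_deg[sel]
    right <- as.numeric(trials$choice[sel] == "right")
    agg_n <- tapply(right, om, length)
    agg_r <- tapply(right, om, sum)
    oms <- as.numeric(names(agg_n))
    vapply(Bvec, function(B) {
      th <- lapse + (1 - 2 * lapse) * stats::pnorm((oms - B) / S)
      th <- pmin(pmax(th, 1e-12), 1 - 1e-12)
      sum(agg_r * log(th) + (agg_n - agg_r) * log1p(-th))
    }, 0)
  }
  lp_bias <- function(v, mean, sd) {
    if (is.null(priors)) rep(0, length(v)) else -0.5 * ((v - mean) / sd)^2
  }
  nL <- length(lattice)
  # log-likelihood matrices over (P, D) via the sum P + D
  ML <- outer(lattice, lattice, `+`)
  MR <- ML
  llL_vals <- cond_ll_on("L", sort(unique(as.vector(ML))))
  llR_vals <- cond_ll_on("R", sort(unique(as.vector(MR))))
  sums <- sort(unique(as.vector(ML)))
  ML[] <- llL_vals[match(as.vector(ML), sums)]
  MR[] <- llR_vals[match(as.vector(MR), sums)]
  llN <- cond_ll_on("N", lattice)
  lpPL <- if (is.null(priors)) rep(0, nL) else
    lp_bias(lattice, priors$P_L_mean, priors$P_L_sd)
  lpPR <- if (is.null(priors)) rep(0, nL) else
    lp_bias(lattice, priors$P_R_mean, priors$P_R_sd)
  lpD <- if (is.null(priors)) rep(0, nL) else
    lp_bias(lattice, priors$D_mean, priors$D_sd)

  A <- llN + lpD                                   # D-terms
  WL <- vapply(seq_len(nL), function(k) log_sum_exp(ML[, k] + lpPL), 0)
  WR <- vapply(seq_len(nL), function(k) log_sum_exp(MR[, k] + lpPR), 0)
  lm_PL <- lpPL + vapply(seq_len(nL), function(i)
    log_sum_exp(ML[i, ] + A + WR), 0)
  lm_PR <- lpPR + vapply(seq_len(nL), function(j)
    log_sum_exp(MR[j, ] + A + WL), 0)
  lm_D <- A + WL + WR
  norm <- function(lm) {
    p <- exp(lm - max(lm))
    p / sum(p)
  }
  list(lattice = lattice,
       P_L = norm(lm_PL), P_R = norm(lm_PR), D = norm(lm_D))
}

# Bin MCMC draws onto the oracle lattice (cell edges at midpoints) and
# return the total-variation distance to the oracle marginal.
tv_to_oracle <- function(draws, oracle_marginal, lattice) {
  edges <- c(-Inf, lattice[-length(lattice)] + diff(lattice) / 2, Inf)
  counts <- table(cut(draws, edges))
  0.5 * sum(abs(counts / sum(counts) - oracle_marginal))
}

# Direct maximum-likelihood estimate of all 12 observer-model parameters
# with lapses and noise free, via general-purpose optimization; used as
# the large-n limit oracle for the flat-prior fit.
ml_biases_oracle <- function(trials) {
  negll <- function(par) {
    B <- c(par[1] + par[3], par[3], par[2] + par[3])
    S <- exp(par[4:6])
    ll <- 0
    for (i in 1:3) {
      kk <- c("L", "N", "R")[i]
      sel <- trials$condition == kk
      th <- stats::pnorm((trials$omega_deg[sel] - B[i]) / S[i])
      th <- pmin(pmax(th, 1e-10), 1 - 1e-10)
      right <- trials$choice[sel] == "right"
      ll <- ll + sum(log(th[right])) + sum(log1p(-th[!right]))
    }
    -ll
  }
  fit <- stats::optim(c(10, -5, 5, log(15), log(15), log(15)), negll,
                      method = "BFGS", control = list(maxit = 500))
  c(P_L = fit$par[1], P_R = fit$par[2], D = fit$par[3])
}
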