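#' Create a metainference restraint state
#'
#' Holds the sampled nuisance parameters of the Gaussian-noise metainference
#' energy: one uncertainty sigma_bias per replica and data point (describing
#' random and systematic errors of data and forward model), a shared
#' intensity scale lambda relating calculated to experimental data, and the
#' per-datapoint standard error of the mean sigma_sem from replica
#' averaging. sigma_bias is sampled by Monte Carlo under a Jeffreys prior
#' (p(sigma) proportional to 1/sigma; configurable to uniform) within
#' bounds; lambda under a flat prior within its bounds.
#'
#' @param n_replicas Number of replicas.
#' @param targets Target (experimental) intensities d_i, length N_d.
#' @param temperature Temperature in K. Default 300.
#' @param lambda_bounds Flat-prior bounds for the scale, default `c(0.5, 1.5)`.
#' @param sample_lambda Sample lambda by MC? Default `TRUE`.
#' @param sigma0 Initial sigma_bias; default 10% of `abs(targets)`.
#' @param sigma_bounds Prior bounds for sigma_bias; default
#'   `c(1e-3, 10) * mean(abs(targets))`.
#' @param sigma_prior `"jeffreys"` (default) or `"uniform"`.
#' @param mc_step Log-space random-walk step for sigma proposals. Default 0.6.
#' @param lambda_step Uniform proposal half-width for lambda. Default 0.05.
#' @param per_datapoint One sigma per data point (default `TRUE`); `FALSE`
#'   collapses to a single sigma shared across data points (still per
#'   replica).
#' @return Object of class `meta_state`.
#' @export
meta_state <- function(n_replicas, targets, temperature = 300,
                       lambda_bounds = c(0.5, 1.5), sample_lambda = TRUE,
                       sigma0 = NULL, sigma_bounds = NULL,
                       sigma_prior = c("jeffreys", "uniform"),
                       mc_step = 0.6, lambda_step = 0.05,
                       per_datapoint = TRUE) {
  sigma_prior <- match.arg(sigma_prior)
  nd <- length(targets)
  scale <- mean(abs(targets))
  if (scale == 0) scale <- 1
  if (is.null(sigma_bounds)) sigma_bounds <- c(1e-3, 10) * scale
  if (is.null(sigma0)) sigma0 <- pmax(0.1 * abs(targets), sigma_bounds[1])
  sb <- matrix(rep(sigma0, each = n_replicas), n_replicas, nd)
  sb <- pmin(pmax(sb, sigma_bounds[1]), sigma_bounds[2])
  structure(list(
    n_replicas = n_replicas, targets = as.numeric(targets),
    temperature = temperature, kT = KB * temperature,
    sigma_bias = sb, sigma_sem = rep(0, nd),
    lambda = 1.0, lambda_bounds = lambda_bounds, sample_lambda = sample_lambda,
    sigma_bounds = sigma_bounds, sigma_prior = sigma_prior,
    mc_step = mc_step, lambda_step = lambda_step,
    per_datapoint = per_datapoint,
    mc_accept = c(sigma = 0, lambda = 0), mc_try = c(sigma = 0, lambda = 0)
  ), class = "meta_state")
}

#' Bias-weighted replica average of forward-model values
#'
#' Each replica contributes to the average with weight
#' w(X_r) = exp(V_PB(CV(X_r), t) / (kB T)), the parallel-bias metadynamics
#' reweighting factor (uniform when no bias is present). Weights are
#' computed with a max shift for overflow safety and normalized to sum 1.
#'
#' @param values Matrix of forward values, replicas x data points (a vector
#'   is treated as a single data point's per-replica values).
#' @param bias_potentials Per-replica V_PB in kJ/mol; default all zero.
#' @param temperature K.
#' @return Object of class `forward_average`: list with `mean` (length
#'   N_d), `weights` (length N_r) and `values` (the input matrix).
#' @export
replica_average <- function(values, bias_potentials = NULL, temperature = 300) {
  if (is.vector(values)) values <- matrix(values, ncol = 1)
  nr <- nrow(values)
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop("non-finite forward value at replica ", bad[1], ", datapoint ", bad[2])
  }
  if (is.null(bias_potentials)) bias_potentials <- rep(0, nr)
  if (!all(is.finite(bias_potentials))) stop("non-finite bias potential")
  v <- bias_potentials / (KB * temperature)
  w <- exp(v - max(v))
  w <- w / sum(w)
  structure(list(mean = as.numeric(crossprod(values, w)), weights = w,
                 values = values), class = "forward_average")
}

#' Standard error of the mean across replicas
#'
#' Estimates sigma_sem, the statistical error of the replica average caused
#' by finite conformational sampling: the standard deviation across
#' replicas of the per-replica windowed means, divided by sqrt(N_r). With a
#' single replica the estimate is 0 (the inferential-structure-
#' determination limit) and a message is emitted.
#'
#' @param values Either a replicas x datapoints matrix of windowed means,
#'   or a 3-d array time x replicas x datapoints, in which case the time
#'   window is averaged per replica first.
#' @return Numeric vector of sigma_sem per data point.
#' @export
sigma_sem <- function(values) {
  if (length(dim(values)) == 3) {
    values <- apply(values, c(2, 3), mean)
  }
  if (is.vector(values)) values <- matrix(values, ncol = 1)
  nr <- nrow(values)
  if (nr < 2) {
    message("single replica: sigma_sem = 0 (ISD limit)")
    return(rep(0, ncol(values)))
  }
  apply(values, 2, stats::sd) / sqrt(nr)
}

## total per-(replica, datapoint) variance matrix
.sigma2_total <- function(state) {
  sweep(state$sigma_bias^2, 2, state$sigma_sem^2, "+")
}

#' Metainference restraint energy
#'
#' The Gaussian-noise metainference energy (excluding the force-field term,
#' which the sampler adds outside):
#' E = sum_r sum_i kT (lambda fbar_i - d_i)^2 / (2 sigma_{r,i}^2)
#'   + (kT/2) ln(2 pi sigma_{r,i}^2) + E_sigma,
#' with sigma_{r,i}^2 = sigma_bias_{r,i}^2 + sigma_sem_i^2. E_sigma encodes
#' the error prior: kT ln sigma per sampled sigma_bias for the Jeffreys
#' prior (zero for uniform). Lambda multiplies the calculated average.
#'
#' @param avg `forward_average` over the current replicas.
#' @param state `meta_state` (carries the targets).
#' @return List with `total` (kJ/mol) and the decomposition `mismatch`,
#'   `normalization`, `prior`, plus `per_datapoint` mismatch energies.
#' @export
metainference_energy <- function(avg, state) {
  kT <- state$kT
  d <- state$targets
  m <- state$lambda * avg$mean - d
  s2 <- .sigma2_total(state)
  if (any(s2 == 0 & rep(m^2, each = nrow(s2)) > 0)) {
    stop("zero total uncertainty with nonzero mismatch: degenerate likelihood")
  }
  mism_mat <- kT * sweep(1 / (2 * s2), 2, m^2, "*")
  mismatch <- sum(mism_mat)
  normalization <- sum(kT / 2 * log(2 * pi * s2))
  prior <- if (state$sigma_prior == "jeffreys") sum(kT * log(state$sigma_bias)) else 0
  list(total = mismatch + normalization + prior,
       mismatch = mismatch, normalization = normalization, prior = prior,
       per_datapoint = colSums(mism_mat))
}

#' Metainference restraint forces on one replica
#'
#' Gradient of the metainference energy through the forward model for a
#' given replica: dE/dr = sum_i [ sum_r kT lambda (lambda fbar_i - d_i) /
#' sigma_{r,i}^2 ] w_rho df_i(X_rho)/dr. Returns the force (negative
#' gradient) on the bead centers of that replica.
#'
#' @param avg `forward_average`.
#' @param state `meta_state`.
#' @param gradients List over data points of M x 3 matrices: the gradient
#'   of the replica's forward model f_i with respect to its bead centers.
#' @param replica Replica index rho whose forces are requested.
#' @return M x 3 matrix of forces (kJ/mol/Angstrom).
#' @export
metainference_forces <- function(avg, state, gradients, replica) {
  kT <- state$kT
  d <- state$targets
  m <- state$lambda * avg$mean - d
  s2 <- .sigma2_total(state)
  coef <- kT * state$lambda * m * colSums(1 / s2)   # per datapoint
  w <- avg$weights[replica]
  G <- matrix(0, nrow(gradients[[1]]), 3)
  for (i in seq_along(coef)) G <- G + coef[i] * w * gradients[[i]]
  -G
}

#' Monte-Carlo update of uncertainties and scale
#'
#' One Metropolis sweep: every sigma_bias_{r,i} receives a log-space
#' random-walk proposal (accepted with min(1, exp(-dE/kT) * sigma'/sigma),
#' the Jacobian factor making the chain correct for the sigma-space
#' posterior), then lambda receives a uniform proposal, rejected outright
#' outside its flat prior bounds. Since the energy is separable in the
#' individual sigmas given the replica-averaged mismatch, all sigma updates
#' are evaluated independently and vectorized. Uses R's global RNG; seed
#' with [set.seed()] for reproducibility.
#'
#' @param state `meta_state`.
#' @param avg `forward_average`.
#' @param n_sweeps Number of sweeps per call. Default 1.
#' @return Updated `meta_state` (with acceptance counters advanced).
#' @export
mc_update <- function(state, avg, n_sweeps = 1) {
  kT <- state$kT
  d <- state$targets
  nr <- state$n_replicas; nd <- length(d)
  jeff <- state$sigma_prior == "jeffreys"
  for (s in seq_len(n_sweeps)) {
    m2 <- (state$lambda * avg$mean - d)^2           # per datapoint
    m2m <- matrix(m2, nr, nd, byrow = TRUE)
    sem2 <- matrix(state$sigma_sem^2, nr, nd, byrow = TRUE)
    sig <- state$sigma_bias
    if (state$per_datapoint) {
      prop <- sig * exp(state$mc_step * matrix(stats::rnorm(nr * nd), nr, nd))
    } else {
      ## one sigma per replica shared across datapoints
      fac <- exp(state$mc_step * stats::rnorm(nr))
      prop <- sig * fac
    }
    eterm <- function(sb) {
      s2 <- sb^2 + sem2
      m2m / (2 * s2) + 0.5 * log(2 * pi * s2) + if (jeff) log(sb) else 0
    }
    if (state$per_datapoint) {
      dE <- eterm(prop) - eterm(sig)                # per (r,i), units kT
      lacc <- -dE + log(prop / sig)                 # Jacobian of log-walk
      ok <- log(stats::runif(nr * nd)) < lacc
      ok <- ok & prop >= state$sigma_bounds[1] & prop <= state$sigma_bounds[2]
      sig[ok] <- prop[ok]
      state$mc_try["sigma"] <- state$mc_try["sigma"] + nr * nd
      state$mc_accept["sigma"] <- state$mc_accept["sigma"] + sum(ok)
    } else {
      dE <- rowSums(eterm(prop) - eterm(sig))
      lacc <- -dE + nd * log(prop[, 1] / sig[, 1])
      ok <- log(stats::runif(nr)) < lacc
      ok <- ok & prop[, 1] >= state$sigma_bounds[1] & prop[, 1] <= state$sigma_bounds[2]
      sig[ok, ] <- prop[ok, , drop = FALSE]
      state$mc_try["sigma"] <- state$mc_try["sigma"] + nr
      state$mc_accept["sigma"] <- state$mc_accept["sigma"] + sum(ok)
    }
    state$sigma_bias <- sig
    if (state$sample_lambda) {
      lam_new <- state$lambda + stats::runif(1, -state$lambda_step, state$lambda_step)
      state$mc_try["lambda"] <- state$mc_try["lambda"] + 1
      if (lam_new >= state$lambda_bounds[1] && lam_new <= state$lambda_bounds[2]) {
        s2 <- .sigma2_total(state)
        mism <- function(l) sum(sweep(1 / (2 * s2), 2, (l * avg$mean - d)^2, "*"))
        dE <- mism(lam_new) - mism(state$lambda)    # kT units
        if (log(stats::runif(1)) < -dE) {
          state$lambda <- lam_new
          state$mc_accept["lambda"] <- state$mc_accept["lambda"] + 1
        }
      }
    }
  }
  state
}

#' MC acceptance rates
#'
#' @param state `meta_state`.
#' @return Named numeric vector of acceptance fractions for sigma and lambda.
#' @export
mc_acceptance <- function(state) {
  out <- state$mc_accept / pmax(state$mc_try, 1)
  out[state$mc_try == 0] <- NA_real_
  out
}
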