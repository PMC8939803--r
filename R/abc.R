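#' Independent uniform prior on the model parameters
#'
#' Non-informative box prior for the seven-dimensional parameter vector.
#' The default bounds bracket the magnitudes the deposition data can
#' plausibly inform: deposition rates up to 200/s, attenuation up to 10
#' (damping to exp(-10) at full albumin coverage), and platelet speeds
#' between 1 um/s and 1 cm/s.
#'
#' @param p_Ad,p_Ag,p_T,p_F,a_T,vzAP,vzNAP length-2 numeric `(low, high)`
#'   bounds per parameter, `0 <= low < high`.
#' @return A list of class `"prior_spec"` with a `7 x 2` `bounds` matrix.
#' @export
prior_spec <- function(p_Ad = c(0, 200), p_Ag = c(0, 200), p_T = c(0, 200),
                       p_F = c(0, 200), a_T = c(0, 10),
                       vzAP = c(1e-6, 1e-2), vzNAP = c(1e-6, 1e-2)) {
  b <- rbind(p_Ad = p_Ad, p_Ag = p_Ag, p_T = p_T, p_F = p_F, a_T = a_T,
             vzAP = vzAP, vzNAP = vzNAP)
  colnames(b) <- c("low", "high")
  if (any(b[, "low"] < 0) || any(b[, "low"] > b[, "high"]))
    stop("prior bounds need 0 <= low <= high per parameter", call. = FALSE)
  structure(list(bounds = b), class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat("Independent uniform prior:\n")
  print(x$bounds)
  invisible(x)
}

#' Draw parameter vectors from the prior
#' @param prior a [prior_spec()].
#' @param n number of draws.
#' @return `n x 7` matrix.
#' @export
sample_prior <- function(prior, n) {
  b <- prior$bounds
  m <- vapply(seq_len(nrow(b)),
              function(j) stats::runif(n, b[j, 1], b[j, 2]), numeric(n))
  if (n == 1) m <- matrix(m, nrow = 1)
  colnames(m) <- rownames(b)
  m
}

in_prior_support <- function(theta, prior) {
  b <- prior$bounds
  all(theta >= b[, "low"] & theta <= b[, "high"])
}

# The forward model + distance wrapped for the samplers.  `simulator` maps a
# named parameter vector to a series (or any numeric object the distance
# understands); the default is the platelet model at `config`.
make_model <- function(observed, proj, config, simulator = NULL) {
  if (is.null(simulator))
    simulator <- function(theta) simulate_deposition(as_params(theta), config)
  obs_vec <- if (inherits(observed, "deposition_series")) {
    series_to_vector(observed)
  } else {
    as.numeric(observed)
  }
  dist_fun <- function(sim) {
    v <- if (inherits(sim, "deposition_series")) series_to_vector(sim) else
      as.numeric(sim)
    summary_distance(v, obs_vec, proj)
  }
  list(simulate = simulator, distance = dist_fun)
}

new_posterior_samples <- function(samples, distances, epsilon_schedule,
                                  acceptance_rate, method, subject_id, seed) {
  colnames(samples) <- param_names()
  structure(list(samples = samples, distances = distances,
                 epsilon_schedule = epsilon_schedule,
                 acceptance_rate = acceptance_rate, method = method,
                 subject_id = subject_id, seed = seed),
            class = "posterior_samples")
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat(sprintf("ABC posterior (%s): %d samples", x$method, nrow(x$samples)))
  if (!is.null(x$subject_id)) cat(" for subject", x$subject_id)
  cat(sprintf("\n  acceptance rate %.3g, final epsilon %.4g\n",
              x$acceptance_rate, utils::tail(x$epsilon_schedule, 1)))
  invisible(x)
}

#' Rejection ABC
#'
#' The fundamental likelihood-free rejection sampler: draw `theta` from the
#' prior, simulate, and accept when the summary distance to the observation
#' is below `epsilon` (indicator kernel).  Accepted draws are samples from
#' the ABC posterior, which converges to the true posterior as
#' `epsilon -> 0` and to the prior as `epsilon -> Inf`.
#'
#' @param observed the observed `"deposition_series"` (or numeric vector for
#'   a custom simulator).
#' @param prior a [prior_spec()].
#' @param proj a `"summary_projection"` defining the distance, or `NULL` for
#'   raw Euclidean distance.
#' @param config a [device_config()] for the forward simulations.
#' @param epsilon acceptance tolerance (> 0; `Inf` accepts everything).
#' @param n_accept target number of accepted samples.
#' @param max_draws cap on total prior draws.
#' @param simulator optional replacement forward model
#'   `function(theta) -> series/vector` (for toy models and checks).
#' @param seed integer seed.
#' @param subject_id optional label carried into the result.
#' @return A `"posterior_samples"` object.
#' @export
abc_rejection <- function(observed, prior = prior_spec(), proj = NULL,
                          config = device_config(), epsilon,
                          n_accept = 100, max_draws = 50 * n_accept,
                          simulator = NULL, seed = NULL, subject_id = NULL) {
  stopifnot(epsilon > 0)
  if (!is.null(seed)) set.seed(seed)
  model <- make_model(observed, proj, config, simulator)
  acc <- matrix(NA_real_, n_accept, 7)
  dst <- numeric(n_accept)
  n_acc <- 0L; n_try <- 0L
  while (n_acc < n_accept && n_try < max_draws) {
    theta <- drop(sample_prior(prior, 1))
    n_try <- n_try + 1L
    d <- model$distance(model$simulate(theta))
    if (d < epsilon) {
      n_acc <- n_acc + 1L
      acc[n_acc, ] <- theta
      dst[n_acc] <- d
    }
  }
  if (n_acc == 0L)
    stop("no acceptances in ", max_draws,
         " draws; increase epsilon", call. = FALSE)
  new_posterior_samples(acc[seq_len(n_acc), , drop = FALSE],
                        dst[seq_len(n_acc)], epsilon_schedule = epsilon,
                        acceptance_rate = n_acc / n_try,
                        method = "rejection", subject_id = subject_id,
                        seed = seed)
}

#' Simulated-annealing ABC (SABC)
#'
#' Population Monte Carlo under the exponential acceptance kernel
#' `exp(-d/epsilon)`: each of `n_particles` particles proposes a Gaussian
#' random-walk move each generation and accepts it with probability
#' `min(1, exp(-(d_new - d_old)/epsilon_g))`, while the tolerance
#' `epsilon_g` is annealed adaptively: each generation it is set to the
#' 20th percentile of the current population's distances, so it keeps
#' decreasing towards 0 as the population concentrates.  Proposal scales are
#' `proposal_scale` times the current per-coordinate population standard
#' deviation, refreshed every generation; moves leaving the prior support
#' are rejected.
#'
#' @inheritParams abc_rejection
#' @param n_particles population size (also the number of returned samples).
#' @param n_generations number of annealing generations.
#' @param proposal_scale random-walk scale as a fraction of the population
#'   standard deviation.
#' @param init_factor the initial population keeps the best `n_particles`
#'   of `init_factor * n_particles` prior-predictive draws.
#' @param init_samples optional warm start: a `"posterior_samples"` object
#'   (e.g. from [abc_rejection_table()]) or a parameter matrix used as the
#'   initial population instead of prior-predictive screening.
#' @param resample_ess importance resampling triggers when the effective
#'   sample size falls below this fraction of `n_particles`; `1` resamples
#'   every generation (favouring reliability over diversity in short runs).
#' @return A `"posterior_samples"` object; `epsilon_schedule` holds the
#'   annealed tolerances and `generation_median_distance` the distance
#'   trajectory.
#' @export
sabc_sample <- function(observed, prior = prior_spec(), proj = NULL,
                        config = device_config(), n_particles = 510,
                        n_generations = 20, proposal_scale = 0.5,
                        init_factor = 4, init_samples = NULL,
                        resample_ess = 0.5, simulator = NULL, seed = NULL,
                        subject_id = NULL) {
  stopifnot(n_particles >= 2, n_generations >= 1)
  if (!is.null(seed)) set.seed(seed)
  model <- make_model(observed, proj, config, simulator)

  if (!is.null(init_samples)) {
    # warm start from an existing sample cloud (e.g. reference-table
    # rejection output); distances are re-simulated for particles that
    # come without one
    if (inherits(init_samples, "posterior_samples")) {
      theta <- init_samples$samples
      d <- init_samples$distances
    } else {
      theta <- as.matrix(init_samples)
      d <- apply(theta, 1, function(th) model$distance(model$simulate(th)))
    }
    stopifnot(ncol(theta) == 7)
    if (nrow(theta) != n_particles) {
      idx <- sample.int(nrow(theta), n_particles,
                        replace = nrow(theta) < n_particles)
      theta <- theta[idx, , drop = FALSE]
      d <- d[idx]
    }
  } else {
    # initial population: prior-predictive screening keeps the best
    # n_particles of init_factor * n_particles prior draws, so the
    # annealing starts from basins already compatible with the data
    n_init <- init_factor * n_particles
    theta0 <- sample_prior(prior, n_init)
    d0 <- apply(theta0, 1, function(th) model$distance(model$simulate(th)))
    keep <- order(d0)[seq_len(n_particles)]
    theta <- theta0[keep, , drop = FALSE]
    d <- d0[keep]
  }
  # random-walk moves are made on log10 scale for parameters whose prior
  # spans orders of magnitude (the platelet speeds); the acceptance ratio
  # carries the Jacobian factor prod(v'/v) so the uniform prior is
  # preserved
  log_coords <- which(prior$bounds[, "low"] > 0 &
                        prior$bounds[, "high"] / prior$bounds[, "low"] > 100)
  schedule <- numeric(n_generations)
  med_trace <- numeric(n_generations)
  n_prop <- 0L; n_acc <- 0L
  for (g in seq_len(n_generations)) {
    # adaptive annealing: the tolerance tracks the shrinking population,
    # so epsilon keeps decreasing towards 0 instead of stalling at a
    # pre-set floor
    eps_g <- max(stats::quantile(d, 0.2), 1e-12)
    schedule[g] <- eps_g
    # importance resampling under the exponential kernel when the
    # effective sample size drops: stragglers stuck at large distances are
    # replaced by copies of particles compatible with the data, which the
    # move step then re-diversifies
    w <- exp(-(d - min(d)) / eps_g)
    w <- w / sum(w)
    ess <- 1 / sum(w^2)
    if (ess < n_particles * resample_ess) {
      idx <- sample.int(n_particles, n_particles, replace = TRUE, prob = w)
      theta <- theta[idx, , drop = FALSE]
      d <- d[idx]
    }
    work <- theta
    work[, log_coords] <- log10(work[, log_coords])
    sds <- pmax(apply(work, 2, stats::sd), 1e-12) * proposal_scale
    for (i in seq_len(n_particles)) {
      u <- work[i, ] + stats::rnorm(7, 0, sds)
      prop <- u
      prop[log_coords] <- 10^u[log_coords]
      n_prop <- n_prop + 1L
      if (!in_prior_support(prop, prior)) next
      d_new <- model$distance(model$simulate(prop))
      jac <- prod(prop[log_coords] / theta[i, log_coords])
      if (stats::runif(1) < jac * exp(-(d_new - d[i]) / eps_g)) {
        theta[i, ] <- prop
        work[i, ] <- u
        d[i] <- d_new
        n_acc <- n_acc + 1L
      }
    }
    med_trace[g] <- stats::median(d)
  }
  if (all(apply(theta, 2, stats::sd) == 0))
    warning("SABC population collapsed to a single point", call. = FALSE)
  out <- new_posterior_samples(theta, d, epsilon_schedule = schedule,
                               acceptance_rate = n_acc / n_prop,
                               method = "sabc", subject_id = subject_id,
                               seed = seed)
  out$generation_median_distance <- med_trace
  out
}

#' Fit the deposition model to one subject by ABC
#'
#' The per-subject model fit: runs likelihood-free posterior sampling
#' (SABC by default) for the seven deposition parameters given one observed
#' deposition series, using the learned discriminative summary distance.
#' The result behaves like a classed model fit: `coef()` returns the MAP
#' estimate (mode of the kernel-smoothed posterior), `summary()` tabulates
#' posterior quantiles, `simulate()` draws posterior predictive series and
#' `plot()` shows the marginal posteriors.
#'
#' @inheritParams sabc_sample
#' @param method `"sabc"` or `"rejection"`.
#' @param ... passed to [sabc_sample()] or [abc_rejection()] (e.g.
#'   `n_particles`, `n_generations`, `epsilon`, `n_accept`).
#' @param bandwidth kernel bandwidth for the MAP estimate (on standardized
#'   coordinates).
#' @return An object of class `"abc_fit"`.
#' @examples
#' \donttest{
#' cfg <- device_config(scale = 0.05, dt = 0.1)
#' th0 <- deposition_params(50, 20, 1, 5e-3, 3, 2e-4, 1e-4)
#' obs <- simulate_deposition(th0, cfg, seed = 7)
#' fit <- abc_fit(obs, config = cfg, method = "sabc", n_particles = 64,
#'                n_generations = 6, seed = 1)
#' coef(fit)
#' }
#' @export
abc_fit <- function(observed, prior = prior_spec(), proj = NULL,
                    config = device_config(), method = c("sabc", "rejection"),
                    ..., bandwidth = 0.45, seed = NULL, subject_id = NULL) {
  method <- match.arg(method)
  samples <- switch(method,
    sabc = sabc_sample(observed, prior, proj, config, ..., seed = seed,
                       subject_id = subject_id),
    rejection = abc_rejection(observed, prior, proj, config, ..., seed = seed,
                              subject_id = subject_id))
  map <- map_estimate(samples, bandwidth = bandwidth, prior = prior)
  structure(list(posterior = samples, map = map, observed = observed,
                 prior = prior, projection = proj, config = config,
                 method = method, bandwidth = bandwidth,
                 subject_id = subject_id, call = match.call()),
            class = "abc_fit")
}

#' @export
print.abc_fit <- function(x, ...) {
  cat("ABC fit of the platelet deposition model (", x$method, ")\n", sep = "")
  if (!is.null(x$subject_id)) cat("  subject:", x$subject_id, "\n")
  cat("  posterior samples:", nrow(x$posterior$samples), "\n")
  cat("  MAP estimate:\n")
  print(signif(x$map$theta_hat, 4))
  invisible(x)
}

#' @export
coef.abc_fit <- function(object, ...) object$map$theta_hat

#' @export
summary.abc_fit <- function(object, probs = c(0.025, 0.25, 0.5, 0.75, 0.975),
                            ...) {
  q <- t(apply(object$posterior$samples, 2, stats::quantile, probs = probs))
  out <- list(quantiles = q, map = object$map$theta_hat,
              acceptance_rate = object$posterior$acceptance_rate,
              method = object$method, n = nrow(object$posterior$samples))
  class(out) <- "summary.abc_fit"
  out
}

#' @export
print.summary.abc_fit <- function(x, ...) {
  cat("ABC posterior summary (", x$method, ", ", x$n, " samples, ",
      sprintf("acceptance %.3g", x$acceptance_rate), ")\n", sep = "")
  print(signif(cbind(MAP = x$map, x$quantiles), 4))
  invisible(x)
}

#' @export
plot.abc_fit <- function(x, which = param_names(), ...) {
  old <- graphics::par(mfrow = c(2, ceiling(length(which) / 2)),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (p in which) {
    s <- x$posterior$samples[, p]
    graphics::hist(s, breaks = 30, main = p, xlab = p, freq = FALSE,
                   col = "grey85", border = "grey40", ...)
    graphics::abline(v = x$map$theta_hat[[p]], col = "darkred", lwd = 2)
  }
  invisible(x)
}

#' Posterior predictive simulation from a fitted model
#'
#' @param object an `"abc_fit"`.
#' @param nsim number of posterior predictive draws.
#' @param seed master seed for the draw-specific simulation seeds.
#' @param ... unused.
#' @return A `"predictive_ensemble"` (see [posterior_predictive()]).
#' @export
simulate.abc_fit <- function(object, nsim = 500, seed = NULL, ...) {
  posterior_predictive(object$posterior, object$config, n_draws = nsim,
                       seed = seed)
}

#' Posterior predictive residuals of a fitted model
#'
#' Observed series minus the pointwise posterior predictive median, per
#' observable and observation time.
#'
#' @param object an `"abc_fit"`.
#' @param nsim posterior predictive draws behind the median.
#' @param seed master seed for the predictive simulations.
#' @param ... unused.
#' @return Data frame: `observable`, `time_s`, `observed`, `predicted`,
#'   `residual`.
#' @export
residuals.abc_fit <- function(object, nsim = 100, seed = NULL, ...) {
  ens <- posterior_predictive(object$posterior, object$config,
                              n_draws = nsim, seed = seed)
  band <- credible_band(ens)
  obs <- object$observed
  obs_vec <- c(obs$n_clusters_per_mm2, obs$mean_cluster_size_cells,
               obs$n_platelet_per_ul)
  data.frame(observable = band$observable, time_s = band$time_s,
             observed = obs_vec, predicted = band$median,
             residual = obs_vec - band$median)
}

#' Marginal credible intervals of a posterior sample cloud
#'
#' @param samples a `"posterior_samples"` or `"abc_fit"`.
#' @param level interval mass.
#' @return `7 x 2` matrix of equal-tailed interval bounds.
#' @export
credible_interval <- function(samples, level = 0.95) {
  if (inherits(samples, "abc_fit")) samples <- samples$posterior
  a <- (1 - level) / 2
  t(apply(samples$samples, 2, stats::quantile, probs = c(a, 1 - a)))
}
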