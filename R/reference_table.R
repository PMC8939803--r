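#' Prior-predictive reference table
#'
#' Simulates a large table of (parameter, series) pairs from the prior.
#' The table can back rejection ABC for many subjects at once: the
#' simulations are paid for once and each subject only costs distance
#' computations, which makes cohort-wide inference tractable.
#'
#' @param prior a [prior_spec()].
#' @param config a [device_config()].
#' @param n number of prior draws.
#' @param seed integer seed.
#' @param simulator optional replacement forward model.
#' @return A list of class `"reference_table"` with `theta` (n x 7) and
#'   `x` (n x d flattened series matrix).
#' @export
reference_table <- function(prior = prior_spec(), config = device_config(),
                            n = 10000, seed = NULL, simulator = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(simulator))
    simulator <- function(theta) simulate_deposition(as_params(theta), config)
  theta <- sample_prior(prior, n)
  first <- simulator(theta[1, ])
  v1 <- if (inherits(first, "deposition_series")) series_to_vector(first) else
    as.numeric(first)
  x <- matrix(NA_real_, n, length(v1))
  colnames(x) <- names(v1)
  x[1, ] <- v1
  for (i in 2:n) {
    s <- simulator(theta[i, ])
    x[i, ] <- if (inherits(s, "deposition_series")) series_to_vector(s) else
      as.numeric(s)
  }
  structure(list(theta = theta, x = x, n = n, prior = prior, seed = seed),
            class = "reference_table")
}

#' @export
print.reference_table <- function(x, ...) {
  cat("ABC reference table:", x$n, "prior-predictive draws,",
      ncol(x$x), "observables\n")
  invisible(x)
}

#' Rejection ABC against a reference table
#'
#' Accepts the `n_accept` table entries nearest to the observation in the
#' summary distance (equivalently: rejection ABC with epsilon set to the
#' realized `n_accept`-th nearest distance).
#'
#' @param observed a `"deposition_series"` or numeric vector.
#' @param table a [reference_table()].
#' @param proj a `"summary_projection"` or `NULL` for raw Euclidean
#'   distance.
#' @param n_accept number of accepted samples.
#' @param subject_id optional label.
#' @return A `"posterior_samples"` object.
#' @export
abc_rejection_table <- function(observed, table, proj = NULL,
                                n_accept = 100, subject_id = NULL) {
  stopifnot(inherits(table, "reference_table"), n_accept >= 1,
            n_accept <= table$n)
  obs_vec <- if (inherits(observed, "deposition_series"))
    series_to_vector(observed) else as.numeric(observed)
  if (is.null(proj)) {
    p0 <- obs_vec
    pts <- table$x
  } else {
    p0 <- project_summary(obs_vec, proj)
    pts <- t(apply(table$x, 1, project_summary, proj = proj))
  }
  d <- sqrt(rowSums(sweep(pts, 2, p0)^2))
  idx <- order(d)[seq_len(n_accept)]
  new_posterior_samples(table$theta[idx, , drop = FALSE], d[idx],
                        epsilon_schedule = max(d[idx]),
                        acceptance_rate = n_accept / table$n,
                        method = "rejection_table", subject_id = subject_id,
                        seed = table$seed)
}
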